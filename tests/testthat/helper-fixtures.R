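# shared helpers: tiny sequence/alignment builders used across tests

aa20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# random amino-acid string, optionally excluding letters (e.g. "F" so no
# accidental motif anchor can occur)
random_aa <- function(n, exclude = character(0)) {
  paste(sample(setdiff(aa20, exclude), n, replace = TRUE), collapse = "")
}

# plant a single strict VQ window of `type` at position `pos` in an
# F-free background
planted_motif_seq <- function(len, pos, type = "LTG") {
  stopifnot(pos + 9 <= len)
  bg <- strsplit(random_aa(len, exclude = "F"), "")[[1]]
  win <- c("F", sample(setdiff(aa20, "F"), 3, TRUE), "V", "Q",
           sample(setdiff(aa20, "F"), 1), strsplit(type, "")[[1]])
  bg[pos:(pos + 9)] <- win
  paste(bg, collapse = "")
}

write_tmp <- function(lines, ext = ".tsv") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

# distances implied by a phylo tree (the additive matrix)
tree_distances <- function(phy) {
  ape::cophenetic.phylo(phy)
}
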