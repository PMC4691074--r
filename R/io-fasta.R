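#' Read a FASTA file into a tibble
#'
#' Reads protein or nucleotide FASTA into a two-column tibble. Sequences are
#' uppercased and whitespace-stripped; record order is preserved; the id is
#' the first whitespace-delimited token after `>`.
#'
#' Validation is strict: an empty file, a duplicated id, or a residue outside
#' the 20 standard amino acids / IUPAC nucleotides (plus `X`, `N`, `*`, `-`)
#' is an error, the latter reported with its line number.
#'
#' @param path path to an (uncompressed or gzipped) FASTA file.
#' @return a tibble with columns `id`, `sequence`.
#' @seealso [write_fasta()]
#' @export
#' @examples
#' tf <- tempfile(fileext = ".faa")
#' writeLines(c(">a", "MKV", "Q", ">b", "FF"), tf)
#' read_fasta(tf)
read_fasta <- function(path) {
  if (!file.exists(path)) vq_abort(paste0("file does not exist: ", path))
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*$", lines)
  line_no <- which(keep)        # original line numbers for diagnostics
  lines <- lines[keep]
  hdr <- grepl("^>", lines)
  if (length(lines) == 0L || !any(hdr)) vq_abort("no records")
  if (!hdr[1L]) vq_abort("no records: file does not start with '>'")

  # legal residue alphabet: amino acids + nucleotide ambiguity subset the
  # pipeline tolerates
  legal <- "ACDEFGHIKLMNPQRSTVWYXBZJUO*-"
  rec <- cumsum(hdr)
  ids <- sub("^>\\s*(\\S+).*$", "\\1", lines[hdr])
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) {
    vq_abort(paste0("duplicate id: ", paste(unique(dup), collapse = ", ")))
  }
  body_idx <- which(!hdr)
  for (i in body_idx) {
    ln <- toupper(gsub("\\s", "", lines[i]))
    bad <- gsub(paste0("[", legal, "]"), "", ln)
    if (nchar(bad) > 0L) {
      vq_abort(sprintf(
        "illegal character '%s' at line %d", substr(bad, 1L, 1L), line_no[i]
      ))
    }
  }
  seqs <- vapply(split(lines[!hdr], rec[!hdr]), function(x) {
    toupper(gsub("\\s", "", paste(x, collapse = "")))
  }, character(1))
  out <- rep("", length(ids))
  out[as.integer(names(seqs))] <- seqs
  tibble(id = ids, sequence = out)
}

#' Write a tibble of sequences to FASTA
#'
#' @param seqs a data frame with columns `id` and `sequence`.
#' @param path output path.
#' @param width line width for wrapping (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  stopifnot(all(c("id", "sequence") %in% names(seqs)))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(seqs))) {
    writeLines(paste0(">", seqs$id[i]), con)
    s <- seqs$sequence[i]
    starts <- seq(1L, max(nchar(s), 1L), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}
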