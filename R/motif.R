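#' Consensus patterns for the VQ motif
#'
#' The VQ motif core consensus is the 10-residue window
#' `FxxxVQxL/F/VTG`: an `F` anchor, three arbitrary residues, the
#' name-giving `VQ` dipeptide, one arbitrary residue, and a three-residue
#' tail whose variable first and third positions define the motif *type
#' code* (e.g. `LTG`, `FTG`, `LTV`). All Chinese-cabbage-type motifs share
#' the `T` at window position 9, so the strict pattern fixes it; the relaxed
#' pattern additionally tolerates `H` in place of `Q` (a variant reported in
#' other species) and frees position 9 for cross-species scans.
#'
#' Patterns are PROSITE-like strings: elements separated by `-`, where an
#' element is a residue letter, `x`, `x(n)`, or a bracketed choice `[QH]`.
#'
#' @param relaxed use the relaxed cross-species pattern?
#' @return a PROSITE-like pattern string.
#' @export
vq_pattern <- function(relaxed = FALSE) {
  if (relaxed) "F-x(3)-V-[QH]-x(4)" else "F-x(3)-V-Q-x-x-T-x"
}

# compile a PROSITE-like pattern into a fixed-width regex (returns the regex
# and the window width)
compile_pattern <- function(pattern) {
  elems <- strsplit(pattern, "-", fixed = TRUE)[[1]]
  rx <- character(0)
  width <- 0L
  for (e in elems) {
    m <- regmatches(e, regexec("^x\\((\\d+)\\)$", e))[[1]]
    if (length(m) == 2L) {
      k <- as.integer(m[2])
      rx <- c(rx, sprintf(".{%d}", k)); width <- width + k
    } else if (e == "x") {
      rx <- c(rx, "."); width <- width + 1L
    } else if (grepl("^\\[[A-Z]+\\]$", e)) {
      rx <- c(rx, e); width <- width + 1L
    } else if (grepl("^[A-Z]$", e)) {
      rx <- c(rx, e); width <- width + 1L
    } else {
      vq_abort(paste0("cannot parse pattern element: ", e))
    }
  }
  list(regex = paste0(rx, collapse = ""), width = width)
}

#' Scan proteins for the VQ consensus motif
#'
#' Slides the 10-residue VQ consensus over each sequence and reports every
#' match, including overlapping ones, left to right. Each hit carries the
#' matched window, the three-letter type code (window positions 8-10) used
#' to subclassify family members, and the residue at window position 6
#' (normally `Q`).
#'
#' @param proteins a data frame with columns `id` and `sequence`.
#' @param relaxed use the relaxed pattern (see [vq_pattern()])?
#' @param pattern override the PROSITE-like pattern entirely.
#' @return a tibble with columns `protein_id`, `start` (1-based position of
#'   the `F` anchor), `window`, `type_code`, `variant_q6`. Proteins shorter
#'   than the window or without a match contribute no rows.
#' @export
#' @examples
#' scan_vq(tibble::tibble(id = "p1", sequence = "AAAFQWEVQSLTGAAA"))
scan_vq <- function(proteins, relaxed = FALSE, pattern = NULL) {
  stopifnot(all(c("id", "sequence") %in% names(proteins)))
  if (any(!nzchar(proteins$sequence))) vq_abort("empty sequence")
  pat <- compile_pattern(pattern %||% vq_pattern(relaxed))
  # lookahead makes overlapping matches visible
  rx <- paste0("(?=", pat$regex, ")")
  rows <- purrr::map2(proteins$id, toupper(proteins$sequence), function(id, s) {
    if (nchar(s) < pat$width) return(NULL)
    m <- gregexpr(rx, s, perl = TRUE)[[1]]
    if (m[1] == -1L) return(NULL)
    starts <- as.integer(m)
    win <- substring(s, starts, starts + pat$width - 1L)
    tibble(
      protein_id = id, start = starts, window = win,
      type_code = substring(win, pat$width - 2L, pat$width),
      variant_q6 = substring(win, 6L, 6L)
    )
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0L) {
    out <- tibble(protein_id = character(), start = integer(),
                  window = character(), type_code = character(),
                  variant_q6 = character())
  }
  out
}

#' Tally motif types across a proteome
#'
#' Each protein contributes the type code of its leftmost strict hit (the
#' family convention assigns exactly one motif type per protein; the
#' leftmost rule makes the assignment deterministic when a sequence carries
#' more than one window). Proteins without a hit are counted in
#' `n_proteins_scanned` only.
#'
#' @param proteins a data frame with columns `id` and `sequence`.
#' @param all_hits if `TRUE`, tally every hit instead of one per protein.
#' @inheritParams scan_vq
#' @return an object of class `vq_motif_census`: a list with `census`
#'   (tibble `type_code`, `n`), `n_proteins_with_hit`, `n_proteins_scanned`.
#' @export
classify_census <- function(proteins, relaxed = FALSE, pattern = NULL,
                            all_hits = FALSE) {
  if (nrow(proteins) == 0L) vq_abort("empty protein list")
  hits <- scan_vq(proteins, relaxed = relaxed, pattern = pattern)
  picked <- if (all_hits) hits else {
    hits %>% group_by(.data$protein_id) %>%
      slice(1L) %>% ungroup()
  }
  census <- picked %>% count(.data$type_code, sort = TRUE, name = "n")
  structure(
    list(census = census,
         n_proteins_with_hit = dplyr::n_distinct(hits$protein_id),
         n_proteins_scanned = nrow(proteins)),
    class = "vq_motif_census"
  )
}

#' @export
print.vq_motif_census <- function(x, ...) {
  cat(sprintf("VQ motif census: %d/%d proteins with a hit\n",
              x$n_proteins_with_hit, x$n_proteins_scanned))
  print(x$census)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.vq_motif_census <- function(x, ...) x$census

#' @exportS3Method generics::glance
glance.vq_motif_census <- function(x, ...) {
  tibble(n_types = nrow(x$census),
         n_proteins_with_hit = x$n_proteins_with_hit,
         n_proteins_scanned = x$n_proteins_scanned)
}
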