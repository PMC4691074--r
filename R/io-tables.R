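#' Read a gene table (locus coordinates and CDS lengths)
#'
#' Parses a TSV with one row per gene carrying its name, locus id, chromosome,
#' strand and genomic span. The span may be given either as separate
#' `start`/`end` columns or as a single `location` column formatted
#' `"start-end"` (hyphen or en-dash), with optional thousands separators --
#' including misplaced ones, since all commas are stripped before parsing.
#' Coordinates are 1-based inclusive.
#'
#' A CDS length that is not a positive multiple of 3 raises a warning but the
#' row is kept; `start > end` is an error.
#'
#' @param path path to a TSV with columns `gene_name`, `locus_id`, `chrom`,
#'   `strand`, `cds_length` and either `location` or `start` + `end`.
#' @return a tibble of gene models: `gene_name`, `locus_id`, `chrom`,
#'   `strand` (`"+"`/`"-"`), `start`, `end`, `cds_length` (all coordinates
#'   integer bp).
#' @export
read_gene_table <- function(path) {
  tb <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                        col_types = readr::cols(.default = "c"))
  names(tb) <- tolower(names(tb))
  need <- c("gene_name", "locus_id", "chrom", "strand", "cds_length")
  miss <- setdiff(need, names(tb))
  if (length(miss) > 0L) {
    vq_abort(paste0("gene table missing columns: ", paste(miss, collapse = ", ")))
  }
  if ("location" %in% names(tb)) {
    loc <- parse_location(tb$location)
    tb$start <- loc$start
    tb$end <- loc$end
  } else if (all(c("start", "end") %in% names(tb))) {
    tb$start <- as.integer(gsub("[,  ]", "", tb$start))
    tb$end <- as.integer(gsub("[,  ]", "", tb$end))
  } else {
    vq_abort("gene table needs either a 'location' column or 'start' and 'end'")
  }
  tb$strand <- ifelse(tb$strand %in% c("-", "−", "–"), "-", "+")
  tb$cds_length <- as.integer(gsub(",", "", tb$cds_length))
  bad <- which(tb$start > tb$end)
  if (length(bad) > 0L) {
    vq_abort(sprintf("start > end for gene '%s' (%d > %d)",
                     tb$gene_name[bad[1]], tb$start[bad[1]], tb$end[bad[1]]))
  }
  off <- which(tb$cds_length <= 0L | tb$cds_length %% 3L != 0L)
  if (length(off) > 0L) {
    warning(sprintf("cds_length not a positive multiple of 3 for: %s",
                    paste(tb$gene_name[off], collapse = ", ")), call. = FALSE)
  }
  tb %>%
    select("gene_name", "locus_id", "chrom", "strand", "start", "end",
           "cds_length") %>%
    as_tibble()
}

# "6,588,703-6,588,999" (hyphen or en-dash, arbitrary comma placement)
# -> integer start/end
parse_location <- function(x) {
  x <- gsub("[,  ]", "", x)
  parts <- stringr::str_split_fixed(x, "[-–−]", 2L)
  if (any(parts[, 2] == "")) {
    vq_abort(paste0("malformed location: ", x[parts[, 2] == ""][1]))
  }
  list(start = as.integer(parts[, 1]), end = as.integer(parts[, 2]))
}

#' Read a synteny / locus-group table
#'
#' One row per family member gene, carrying the ancestral-karyotype block it
#' maps to, the reference-species locus anchoring the group (may be empty for
#' unanchored genes), and the subgenome the copy resides on. Members sharing a
#' non-empty `ref_locus` form one locus group; unanchored members are
#' singleton groups.
#'
#' @param path path to a TSV with columns `block`, `tpck_chrom`, `ref_locus`,
#'   `gene_name`, `subgenome`.
#' @return a tibble with those columns plus `group_id` (the grouping key).
#' @export
read_synteny_table <- function(path) {
  tb <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                        col_types = readr::cols(.default = "c"))
  names(tb) <- tolower(names(tb))
  need <- c("block", "tpck_chrom", "ref_locus", "gene_name", "subgenome")
  miss <- setdiff(need, names(tb))
  if (length(miss) > 0L) {
    vq_abort(paste0("synteny table missing columns: ",
                    paste(miss, collapse = ", ")))
  }
  tb <- tb %>% mutate(dplyr::across(dplyr::everything(),
                                    ~ ifelse(is.na(.x), "", .x)))
  ok <- c("LF", "MF1", "MF2", "unassigned")
  bad <- setdiff(unique(tb$subgenome), ok)
  if (length(bad) > 0L) {
    vq_abort(paste0("unknown subgenome label: ", paste(bad, collapse = ", ")))
  }
  dupm <- tb %>% count(.data$ref_locus, .data$gene_name) %>%
    filter(.data$ref_locus != "", .data$n > 1L)
  if (nrow(dupm) > 0L) {
    vq_abort(paste0("duplicated member within a locus group: ",
                    paste(dupm$gene_name, collapse = ", ")))
  }
  tb %>%
    mutate(group_id = ifelse(.data$ref_locus == "",
                             paste0("unanchored:", .data$gene_name),
                             .data$ref_locus)) %>%
    select("block", "tpck_chrom", "ref_locus", "gene_name", "subgenome",
           "group_id") %>%
    as_tibble()
}

#' Read a qRT-PCR Ct table
#'
#' Long-format replicate-level cycle-threshold values for a target gene and
#' the constitutive reference gene measured in the same reaction plate.
#'
#' @param path path to a TSV with columns `gene`, `condition`, `timepoint`,
#'   `replicate`, `ct_target`, `ct_reference`.
#' @return a tibble with those columns (`replicate` integer, Ct numeric).
#' @export
read_ct_table <- function(path) {
  tb <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                        col_types = readr::cols(.default = "c"))
  names(tb) <- tolower(names(tb))
  need <- c("gene", "condition", "timepoint", "replicate",
            "ct_target", "ct_reference")
  miss <- setdiff(need, names(tb))
  if (length(miss) > 0L) {
    vq_abort(paste0("ct table missing columns: ", paste(miss, collapse = ", ")))
  }
  tb <- tb %>% mutate(replicate = as.integer(.data$replicate),
                      ct_target = as.numeric(.data$ct_target),
                      ct_reference = as.numeric(.data$ct_reference))
  if (any(!is.finite(tb$ct_target)) || any(!is.finite(tb$ct_reference)) ||
      any(tb$ct_target <= 0) || any(tb$ct_reference <= 0)) {
    vq_abort("ct values must be finite and > 0")
  }
  as_tibble(tb[need])
}
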