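#' Protein length implied by a CDS length
#'
#' A coding sequence of `n` bp encodes `n/3 - 1` residues: one codon per
#' residue plus the stop codon, which is not translated.
#'
#' @param cds_length CDS length(s) in bp; must be positive multiples of 3.
#' @return integer amino-acid count(s).
#' @export
#' @examples
#' protein_length_from_cds(297) # 98
protein_length_from_cds <- function(cds_length) {
  if (any(cds_length <= 0L) || any(cds_length %% 3L != 0L)) {
    vq_abort("cds_length must be a positive multiple of 3")
  }
  as.integer(cds_length / 3L - 1L)
}

# cached data assets
mass_table <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      tb <- readr::read_tsv(vq_asset("residue_masses_average.tsv"),
                            show_col_types = FALSE)
      cache <<- setNames(tb$mass_da, tb$residue)
    }
    cache
  }
})

#' pKa tables for isoelectric-point calculation
#'
#' Per-group dissociation constants for the ionizable side chains
#' (D, E, C, Y acidic; H, K, R basic) and the two termini. The default set
#' is the Bjellqvist-style table used by the ExPASy ProtParam service; an
#' EMBOSS-style alternative is shipped for sensitivity checks. Both live as
#' editable TSV assets under `inst/extdata/`.
#'
#' @param set `"bjellqvist"` (default) or `"emboss"`, or a path to a TSV
#'   with columns `group`, `pka`, `charge`.
#' @return a tibble with columns `group`, `pka`, `charge`.
#' @export
pka_table <- function(set = c("bjellqvist", "emboss")) {
  path <- if (file.exists(set[1])) set[1] else {
    set <- match.arg(set)
    vq_asset(paste0("pka_", set, ".tsv"))
  }
  tb <- readr::read_tsv(path, show_col_types = FALSE)
  stopifnot(all(c("group", "pka", "charge") %in% names(tb)),
            all(tb$pka > 0 & tb$pka < 14),
            all(c("D", "E", "C", "Y", "K", "R", "H", "Nterm", "Cterm")
                %in% tb$group))
  tb
}

#' Average molecular weight of a protein
#'
#' Sum of average (not monoisotopic) residue masses plus one water
#' (18.0153 Da). The unknown residue `X` contributes zero mass but counts
#' toward the length.
#'
#' @param sequence amino-acid string(s) over the 20 standard letters plus `X`.
#' @return molecular weight(s) in daltons.
#' @export
#' @examples
#' molecular_weight("G")  # 75.07
molecular_weight <- function(sequence) {
  masses <- mass_table()
  vapply(toupper(sequence), function(s) {
    aa <- strsplit(s, "")[[1]]
    bad <- setdiff(aa, names(masses))
    if (length(bad) > 0L) {
      vq_abort(paste0("illegal residue: ", paste(unique(bad), collapse = ", ")))
    }
    sum(masses[aa]) + 18.0153
  }, numeric(1), USE.NAMES = FALSE)
}

#' Net charge of a protein at a given pH
#'
#' Henderson-Hasselbalch sum over ionizable groups: each basic group
#' contributes `1/(1+10^(pH-pKa))`, each acidic group `-1/(1+10^(pKa-pH))`.
#' Every ionizable side chain counts once per occurrence, plus both termini.
#'
#' @param sequence amino-acid string.
#' @param ph pH value(s).
#' @param pka a pKa table from [pka_table()].
#' @return net charge (elementary charges), vectorised over `ph`.
#' @export
net_charge <- function(sequence, ph, pka = pka_table()) {
  aa <- strsplit(toupper(sequence), "")[[1]]
  counts <- c(table(aa)[intersect(unique(aa), pka$group)],
              Nterm = 1, Cterm = 1)
  counts <- counts[!is.na(counts)]
  tb <- pka[match(names(counts), pka$group), ]
  vapply(ph, function(p) {
    basic <- tb$charge == "basic"
    pos <- sum(counts[basic] / (1 + 10^(p - tb$pka[basic])))
    neg <- sum(counts[!basic] / (1 + 10^(tb$pka[!basic] - p)))
    pos - neg
  }, numeric(1))
}

#' Theoretical isoelectric point
#'
#' The pH at which the net charge crosses zero, found by bisection on
#' `[0, 14]`. The charge is strictly decreasing in pH, so bisection is
#' unconditionally convergent; iteration stops when `|Q| < 1e-4` or the
#' bracket is narrower than 0.001 pH units.
#'
#' @inheritParams net_charge
#' @return pI in pH units.
#' @export
isoelectric_point <- function(sequence, pka = pka_table()) {
  vapply(sequence, function(s) {
    lo <- 0; hi <- 14
    qlo <- net_charge(s, lo, pka); qhi <- net_charge(s, hi, pka)
    if (qlo <= 0) return(lo)   # all-acid edge case
    if (qhi >= 0) return(hi)
    for (i in 1:100) {
      mid <- (lo + hi) / 2
      q <- net_charge(s, mid, pka)
      # |Q| is the primary stop; the interval bound is a numerical backstop
      if (abs(q) < 1e-4 || (hi - lo) < 1e-9) return(mid)
      if (q > 0) lo <- mid else hi <- mid
    }
    vq_abort("pI bisection failed to converge")
  }, numeric(1), USE.NAMES = FALSE)
}

#' Derived physicochemical properties for a set of proteins
#'
#' Convenience wrapper computing, per sequence: length (aa), average
#' molecular weight (kDa, rounded to 2 decimals in the `mw_kda` column;
#' full precision kept in `mw_da`) and theoretical pI.
#'
#' @param proteins a data frame with columns `id` and `sequence`.
#' @param pka a pKa table from [pka_table()].
#' @return a tibble: `id`, `length_aa`, `mw_da`, `mw_kda`, `pi`.
#' @export
protein_props <- function(proteins, pka = pka_table()) {
  stopifnot(all(c("id", "sequence") %in% names(proteins)))
  mw <- molecular_weight(proteins$sequence)
  tibble(
    id = proteins$id,
    length_aa = nchar(proteins$sequence),
    mw_da = mw,
    mw_kda = round(mw / 1000, 2),
    pi = round(isoelectric_point(proteins$sequence, pka), 2)
  )
}
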