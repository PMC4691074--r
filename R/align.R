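#' Global pairwise protein alignment
#'
#' Needleman-Wunsch global alignment with affine gap costs over a standard
#' substitution matrix (BLOSUM62 by default), via \pkg{Biostrings}.
#' Percent identity is exact matches over alignment columns; percent
#' similarity additionally counts substitution pairs with a positive
#' matrix score as matches. Gap columns count toward the denominator.
#'
#' @param a,b amino-acid strings (non-empty).
#' @param matrix_name substitution matrix name available in
#'   \pkg{Biostrings} (default `"BLOSUM62"`).
#' @param gap_open,gap_extend affine gap penalties (positive costs).
#' @return a list of class `vq_pairwise`: `alignment` (tibble `id`,
#'   `aligned`), `score`, `identity_pct`, `similarity_pct`, `n_columns`.
#' @export
#' @examples
#' global_align("MKVQ", "MKVQ")$identity_pct # 100
global_align <- function(a, b, matrix_name = "BLOSUM62",
                         gap_open = 10, gap_extend = 0.5) {
  if (!nzchar(a) || !nzchar(b)) vq_abort("empty sequence")
  subst <- get_subst_matrix(matrix_name)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    type = "global", substitutionMatrix = subst,
    gapOpening = gap_open, gapExtension = gap_extend
  )
  al_a <- as.character(Biostrings::alignedPattern(pa))
  al_b <- as.character(Biostrings::alignedSubject(pa))
  structure(
    c(list(alignment = tibble(id = c("a", "b"), aligned = c(al_a, al_b)),
           score = Biostrings::score(pa)),
      alignment_stats(al_a, al_b, subst)),
    class = "vq_pairwise"
  )
}

get_subst_matrix <- function(matrix_name) {
  e <- new.env()
  utils::data(list = matrix_name, package = "Biostrings", envir = e)
  get(matrix_name, envir = e)
}

# identity/similarity over two gapped strings
alignment_stats <- function(x, y, subst) {
  cx <- strsplit(x, "")[[1]]
  cy <- strsplit(y, "")[[1]]
  ncol <- length(cx)
  both <- cx != "-" & cy != "-"
  ident <- sum(cx == cy & both)
  mism <- which(both & cx != cy)
  pos <- if (length(mism) > 0L) {
    sum(subst[cbind(cx[mism], cy[mism])] > 0)
  } else 0L
  list(identity_pct = 100 * ident / ncol,
       similarity_pct = 100 * (ident + pos) / ncol,
       n_columns = ncol)
}

#' @export
print.vq_pairwise <- function(x, ...) {
  cat(sprintf("global alignment: score %.1f, identity %.1f%%, similarity %.1f%% over %d columns\n",
              x$score, x$identity_pct, x$similarity_pct, x$n_columns))
  invisible(x)
}

# ---- progressive MSA ------------------------------------------------------

aa_alphabet <- function() strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# a profile: list(rows = named character vector of gapped strings,
#                 freq = L x 20 residue-frequency matrix)
new_profile <- function(ids, gapped) {
  alpha <- aa_alphabet()
  chars <- do.call(rbind, strsplit(gapped, ""))
  freq <- t(apply(chars, 2, function(col) {
    col <- col[col != "-" & col %in% alpha]
    tab <- table(factor(col, levels = alpha))
    if (sum(tab) == 0) rep(0, length(alpha)) else as.numeric(tab) / sum(tab)
  }))
  if (length(gapped) == 1L || nchar(gapped[1]) == 1L) {
    freq <- matrix(freq, ncol = length(alpha))
  }
  list(ids = ids, rows = setNames(gapped, ids), freq = freq)
}

# align two profiles by Needleman-Wunsch with linear gap cost; returns the
# merged profile. Deterministic traceback preference: diagonal, up, left.
align_profiles <- function(p1, p2, subst, gap = 8) {
  alpha <- aa_alphabet()
  B <- subst[alpha, alpha]
  S <- p1$freq %*% B %*% t(p2$freq)          # column-pair scores
  n1 <- nrow(S); n2 <- ncol(S)
  M <- matrix(0, n1 + 1L, n2 + 1L)
  M[1, ] <- -gap * (0:n2)
  M[, 1] <- -gap * (0:n1)
  for (i in seq_len(n1)) {
    tmp <- pmax(M[i, 1:n2] + S[i, ], M[i, 2:(n2 + 1L)] - gap)
    acc <- numeric(n2)
    prev <- M[i + 1L, 1]
    for (j in seq_len(n2)) {
      prev <- max(tmp[j], prev - gap)
      acc[j] <- prev
    }
    M[i + 1L, 2:(n2 + 1L)] <- acc
  }
  # traceback
  i <- n1; j <- n2
  path1 <- integer(0); path2 <- integer(0)
  eps <- 1e-9
  while (i > 0L || j > 0L) {
    if (i > 0L && j > 0L &&
        abs(M[i + 1L, j + 1L] - (M[i, j] + S[i, j])) < eps) {
      path1 <- c(i, path1); path2 <- c(j, path2); i <- i - 1L; j <- j - 1L
    } else if (i > 0L &&
               abs(M[i + 1L, j + 1L] - (M[i, j + 1L] - gap)) < eps) {
      path1 <- c(i, path1); path2 <- c(0L, path2); i <- i - 1L
    } else {
      path1 <- c(0L, path1); path2 <- c(j, path2); j <- j - 1L
    }
  }
  expand <- function(rows, idx) {
    vapply(rows, function(r) {
      ch <- strsplit(r, "")[[1]]
      paste0(ifelse(idx == 0L, "-", ch[pmax(idx, 1L)]), collapse = "")
    }, character(1))
  }
  rows <- c(expand(p1$rows, path1), expand(p2$rows, path2))
  new_profile(names(rows), unname(rows))
}

#' Progressive multiple sequence alignment
#'
#' A deliberately simple progressive aligner: pairwise Needleman-Wunsch
#' distances (`1 - identity/100`) feed a neighbor-joining guide tree, and
#' profiles are merged leaf-to-root with profile-profile Needleman-Wunsch
#' (linear gap cost). Deterministic given the input order; no iterative
#' refinement.
#'
#' @param seqs a data frame with columns `id` and `sequence` (>= 2 rows).
#' @inheritParams global_align
#' @param gap linear gap cost for the profile-merge stage.
#' @return an object of class `vq_msa`: list with `alignment` (tibble
#'   `id`, `aligned`, in input order) and `n_columns`.
#' @export
progressive_msa <- function(seqs, matrix_name = "BLOSUM62",
                            gap_open = 10, gap_extend = 0.5, gap = 8) {
  stopifnot(all(c("id", "sequence") %in% names(seqs)))
  n <- nrow(seqs)
  if (n < 2L) vq_abort("progressive_msa needs at least 2 sequences")
  if (anyDuplicated(seqs$id)) vq_abort("duplicate sequence ids")
  subst <- get_subst_matrix(matrix_name)
  if (n == 2L) {
    pa <- global_align(seqs$sequence[1], seqs$sequence[2], matrix_name,
                       gap_open, gap_extend)
    al <- tibble(id = seqs$id, aligned = pa$alignment$aligned)
    return(structure(list(alignment = al,
                          n_columns = nchar(al$aligned[1])),
                     class = "vq_msa"))
  }
  # guide distances from pairwise identity
  d <- matrix(0, n, n, dimnames = list(seqs$id, seqs$id))
  for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
    pa <- global_align(seqs$sequence[i], seqs$sequence[j], matrix_name,
                       gap_open, gap_extend)
    d[i, j] <- d[j, i] <- 1 - pa$identity_pct / 100
  }
  guide <- nj_tree(d)
  profiles <- setNames(
    lapply(seq_len(n), function(i) new_profile(seqs$id[i], seqs$sequence[i])),
    seqs$id
  )
  prof <- merge_by_guide(guide, profiles, subst, gap)
  rows <- prof$rows[seqs$id]
  structure(list(alignment = tibble(id = seqs$id, aligned = unname(rows)),
                 n_columns = nchar(rows[[1]])),
            class = "vq_msa")
}

# post-order traversal of the (arbitrarily rooted) guide tree, merging
# child profiles pairwise
merge_by_guide <- function(guide, profiles, subst, gap) {
  edge <- guide$edge
  ntip <- length(guide$tip.label)
  root <- ntip + 1L
  rec <- function(node) {
    if (node <= ntip) return(profiles[[guide$tip.label[node]]])
    kids <- edge[edge[, 1] == node, 2]
    ps <- lapply(kids, rec)
    Reduce(function(a, b) align_profiles(a, b, subst, gap), ps)
  }
  rec(root)
}

#' @export
print.vq_msa <- function(x, ...) {
  cat(sprintf("multiple alignment: %d sequences x %d columns\n",
              nrow(x$alignment), x$n_columns))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.vq_msa <- function(x, ...) x$alignment

#' Evolutionary distance matrix from an alignment
#'
#' p-distance is the fraction of mismatching residues over valid columns;
#' the Poisson correction is `-ln(1 - p)`. Under pairwise deletion a column
#' is valid for a pair when neither row has a gap there; under complete
#' deletion, columns with any gap are dropped for all pairs.
#'
#' @param msa a `vq_msa` object or a data frame with columns `id`,
#'   `aligned`.
#' @param model `"p"` (default) or `"poisson"`.
#' @param deletion `"pairwise"` (default) or `"complete"`.
#' @return a symmetric numeric matrix with ids as dimnames.
#' @export
distance_matrix <- function(msa, model = c("p", "poisson"),
                            deletion = c("pairwise", "complete")) {
  model <- match.arg(model)
  deletion <- match.arg(deletion)
  al <- if (inherits(msa, "vq_msa")) msa$alignment else as_tibble(msa)
  if (nrow(al) < 2L) vq_abort("need at least 2 aligned rows")
  chars <- do.call(rbind, strsplit(al$aligned, ""))
  rownames(chars) <- al$id
  if (deletion == "complete") {
    keep <- colSums(chars == "-") == 0L
    if (!any(keep)) vq_abort("no gap-free columns under complete deletion")
    chars <- chars[, keep, drop = FALSE]
  }
  n <- nrow(chars)
  d <- matrix(0, n, n, dimnames = list(al$id, al$id))
  for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
    ok <- chars[i, ] != "-" & chars[j, ] != "-"
    if (!any(ok)) {
      vq_abort(sprintf("no valid columns for pair %s / %s",
                       al$id[i], al$id[j]))
    }
    p <- sum(chars[i, ok] != chars[j, ok]) / sum(ok)
    if (model == "poisson") {
      if (p >= 1) vq_abort(sprintf("infinite Poisson distance for pair %s / %s",
                                   al$id[i], al$id[j]))
      p <- -log(1 - p)
    }
    d[i, j] <- d[j, i] <- p
  }
  d
}
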