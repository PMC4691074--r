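#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration with the Studier-Keppler Q criterion. Branch
#' lengths come from the standard two-point formulas; a negative branch
#' length is clamped to zero with the deficit moved to its sibling edge.
#' Ties in Q are broken by the lexicographically smallest taxon-pair ids
#' (an internal cluster inherits the smallest leaf id it contains), so the
#' result is deterministic.
#'
#' @param d a symmetric numeric distance matrix with taxon ids as dimnames
#'   (>= 3 taxa).
#' @return an unrooted tree of class `c("vq_phylo", "phylo")`.
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 3L) vq_abort("neighbor joining needs at least 3 taxa")
  if (is.null(rownames(d))) {
    rownames(d) <- colnames(d) <- paste0("t", seq_len(n))
  }
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-8))) {
    vq_abort("distance matrix is not symmetric")
  }
  frag <- rownames(d)              # newick fragments per active cluster
  key <- rownames(d)               # tie-break key: smallest leaf id inside
  bl <- function(x) sprintf("%.10g", x)

  while (n > 3L) {
    R <- rowSums(d)
    Q <- (n - 2) * d - outer(R, R, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q <= qmin + 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    pk <- vapply(seq_len(nrow(cand)), function(r) {
      ks <- sort(c(key[cand[r, 1]], key[cand[r, 2]]))
      paste(ks, collapse = "\r")
    }, character(1))
    pick <- cand[order(pk)[1], ]
    i <- pick[1]; j <- pick[2]
    dij <- d[i, j]
    bi <- dij / 2 + (R[i] - R[j]) / (2 * (n - 2))
    bj <- dij - bi
    if (bi < 0) { bj <- bj + bi; bi <- 0 }
    if (bj < 0) { bi <- bi + bj; bj <- 0 }
    newfrag <- paste0("(", frag[i], ":", bl(bi), ",", frag[j], ":", bl(bj), ")")
    newkey <- min(key[i], key[j])
    dk <- (d[i, ] + d[j, ] - dij) / 2
    keep <- setdiff(seq_len(n), c(i, j))
    d <- rbind(cbind(d[keep, keep, drop = FALSE], dk[keep]),
               c(dk[keep], 0))
    frag <- c(frag[keep], newfrag)
    key <- c(key[keep], newkey)
    rownames(d) <- colnames(d) <- key
    n <- n - 1L
  }
  b1 <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  b2 <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  b3 <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  b <- pmax(c(b1, b2, b3), 0)
  nwk <- paste0("(", frag[1], ":", bl(b[1]), ",", frag[2], ":", bl(b[2]),
                ",", frag[3], ":", bl(b[3]), ");")
  tr <- ape::read.tree(text = nwk)
  class(tr) <- c("vq_phylo", "phylo")
  tr
}

# canonical bipartition keys for the internal edges of an unrooted tree;
# the side NOT containing the alphabetically first tip labels the split
tree_splits <- function(phy) {
  labs <- phy$tip.label
  anchor <- sort(labs)[1]
  pp <- ape::prop.part(phy)
  all_tips <- seq_along(labs)
  keys <- vapply(seq_along(pp), function(k) {
    side <- pp[[k]]
    if (anchor %in% labs[side]) side <- setdiff(all_tips, side)
    if (length(side) < 2L || length(side) > length(labs) - 2L) {
      return(NA_character_)
    }
    paste(sort(labs[side]), collapse = "|")
  }, character(1))
  # node numbers corresponding to prop.part entries
  setNames(keys, length(labs) + seq_along(pp))
}

#' Bootstrap supports for a neighbor-joining tree
#'
#' Resamples alignment columns with replacement, rebuilds the distance
#' matrix and NJ tree per replicate, and annotates each internal edge of
#' the full-data tree with the percentage of replicates containing the
#' same bipartition. Reproducible for a fixed seed.
#'
#' @param msa a `vq_msa` object or data frame with columns `id`, `aligned`.
#' @param n_reps number of bootstrap replicates (>= 1).
#' @param seed integer RNG seed.
#' @inheritParams distance_matrix
#' @return the full-data tree (class `c("vq_phylo", "phylo")`) with
#'   integer supports in `node.label` (root and trivial splits empty).
#' @export
bootstrap_tree <- function(msa, n_reps = 1000L, seed = 1L,
                           model = c("p", "poisson"),
                           deletion = c("pairwise", "complete")) {
  model <- match.arg(model)
  deletion <- match.arg(deletion)
  if (n_reps < 1L) vq_abort("n_reps must be >= 1")
  al <- if (inherits(msa, "vq_msa")) msa$alignment else as_tibble(msa)
  ncols <- nchar(al$aligned[1])
  if (ncols < 2L) vq_abort("alignment has fewer than 2 columns")
  ref <- nj_tree(distance_matrix(al, model, deletion))
  ref_splits <- tree_splits(ref)
  counts <- setNames(rep(0L, sum(!is.na(ref_splits))),
                     ref_splits[!is.na(ref_splits)])
  chars <- do.call(rbind, strsplit(al$aligned, ""))
  set.seed(seed)
  for (r in seq_len(n_reps)) {
    idx <- sample.int(ncols, ncols, replace = TRUE)
    rep_al <- tibble(
      id = al$id,
      aligned = apply(chars[, idx, drop = FALSE], 1, paste, collapse = "")
    )
    rep_tree <- tryCatch(nj_tree(distance_matrix(rep_al, model, deletion)),
                         error = function(e) NULL)
    if (is.null(rep_tree)) next
    sp <- tree_splits(rep_tree)
    hit <- intersect(names(counts), sp[!is.na(sp)])
    counts[hit] <- counts[hit] + 1L
  }
  supports <- round(100 * counts / n_reps)
  node_lab <- rep("", ref$Nnode)
  for (nd in names(ref_splits)) {
    k <- ref_splits[[nd]]
    if (!is.na(k)) {
      node_lab[as.integer(nd) - length(ref$tip.label)] <-
        as.character(supports[[k]])
    }
  }
  ref$node.label <- node_lab
  ref
}

#' Cut a tree into k leaf groups
#'
#' Removes the `k - 1` longest internal edges (ties broken by higher
#' support, then by the lexicographic order of the split below the edge)
#' and returns the leaf sets of the resulting connected components. When
#' internal edges are exhausted (large `k`), terminal edges are cut next,
#' longest first, until `k` leaf-bearing groups exist.
#'
#' @param tree a `phylo` tree.
#' @param k number of groups, `1 <= k <=` leaf count.
#' @return a tibble with columns `id` (leaf label) and `group` (integer,
#'   numbered by first appearance in `tip.label` order).
#' @export
cut_subgroups <- function(tree, k) {
  ntip <- length(tree$tip.label)
  if (k < 1L || k > ntip) vq_abort("k must be between 1 and the leaf count")
  edge <- tree$edge
  len <- tree$edge.length %||% rep(1, nrow(edge))
  internal <- edge[, 2] > ntip
  sup <- rep(-Inf, nrow(edge))
  if (!is.null(tree$node.label)) {
    s <- suppressWarnings(as.numeric(tree$node.label[edge[, 2] - ntip]))
    sup[internal] <- ifelse(is.na(s[internal]), -Inf, s[internal])
  }
  splits <- tree_splits(tree)
  split_key <- rep("", nrow(edge))
  m <- match(as.character(edge[, 2]), names(splits))
  split_key[!is.na(m)] <- ifelse(is.na(splits[m[!is.na(m)]]), "",
                                 splits[m[!is.na(m)]])
  ord <- order(!internal,            # internal edges first
               -len, -sup, split_key)
  n_cut <- k - 1L
  repeat {
    comp <- local({
      keep <- setdiff(seq_len(nrow(edge)), head(ord, n_cut))
      par <- seq_len(ntip + tree$Nnode)
      find <- function(x) { while (par[x] != x) x <- par[x]; x }
      for (e in keep) {
        a <- find(edge[e, 1]); b <- find(edge[e, 2])
        if (a != b) par[a] <- b
      }
      vapply(seq_len(ntip), find, integer(1))
    })
    if (length(unique(comp)) >= k || n_cut >= nrow(edge)) break
    n_cut <- n_cut + 1L
  }
  grp <- match(comp, unique(comp))
  tibble(id = tree$tip.label, group = grp)
}
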