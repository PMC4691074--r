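#' Read and write Newick trees
#'
#' Thin wrappers around \pkg{ape}'s Newick support, with a parenthesis
#' balance check that reports the offending position and with integer
#' bootstrap supports carried as internal node labels.
#'
#' The round trip `read_newick(write_newick(t))` preserves topology, leaf
#' labels, branch lengths (to at least 6 decimals) and supports exactly.
#'
#' @param text a Newick string (terminated by `;`).
#' @return `read_newick()`: an object of class `phylo`;
#'   `write_newick()`: a Newick string.
#' @export
read_newick <- function(text) {
  depth <- cumsum((strsplit(text, "")[[1]] == "(") -
                  (strsplit(text, "")[[1]] == ")"))
  if (any(depth < 0L)) {
    vq_abort(sprintf("unbalanced parentheses at position %d",
                     which(depth < 0L)[1]))
  }
  if (length(depth) > 0L && depth[length(depth)] != 0L) {
    vq_abort(sprintf("unbalanced parentheses: %d unclosed at position %d",
                     depth[length(depth)], length(depth)))
  }
  tr <- tryCatch(ape::read.tree(text = text),
                 error = function(e) vq_abort(paste0("newick parse error: ",
                                                     conditionMessage(e))))
  if (is.null(tr)) vq_abort("newick parse error")
  tr
}

#' @param tree an object of class `phylo`, optionally with `node.label`
#'   holding integer supports.
#' @param digits decimal places for branch lengths (default 6).
#' @rdname read_newick
#' @export
write_newick <- function(tree, digits = 6L) {
  ape::write.tree(tree, digits = digits)
}
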