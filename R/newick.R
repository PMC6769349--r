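#' Write and read trees in Newick format
#'
#' Thin wrappers around [ape::write.tree()] / [ape::read.tree()] that enforce
#' the pipeline's contract: every leaf is labeled, branch lengths survive a
#' round trip to 6 decimals, and bootstrap supports are serialized as
#' internal node labels.
#'
#' @param tree An [ape::phylo] tree; internal `node.label` (if any) carries
#'   support values.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$tip.label) || any(!nzchar(tree$tip.label)) ||
      anyNA(tree$tip.label))
    stop("tree has unlabeled leaves", call. = FALSE)
  ape::write.tree(tree, file = path, digits = 10)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) {
  ape::read.tree(path)
}
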