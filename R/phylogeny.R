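# Distance-based phylogeny: pairwise p-distances, Saitou-Nei neighbor
# joining with deterministic tie-breaking, column-resampling bootstrap, and
# anchor-based subfamily assignment.

#' Pairwise p-distance matrix from protein sequences
#'
#' `d[i, j]` is the proportion of mismatched columns among the gap-free
#' columns of the global pairwise alignment of sequences i and j. Labels
#' are sorted so the matrix (and everything downstream) is invariant to the
#' input order of the sequences.
#'
#' @param proteins Named list of >= 3 protein [seq_record()]s.
#' @return Symmetric numeric matrix with zero diagonal, sorted labels as
#'   dimnames, and the pairwise gapped alignments stashed in
#'   `attr(, "alignments")` for bootstrap resampling.
#' @export
pdistance_matrix <- function(proteins) {
  if (length(proteins) < 3L) stop("need >= 3 sequences", call. = FALSE)
  names(proteins) <- vapply(proteins, `[[`, "", "id")
  labs <- sort(names(proteins))
  proteins <- proteins[labs]
  n <- length(labs)
  d <- matrix(0, n, n, dimnames = list(labs, labs))
  alns <- list()
  for (i in seq_len(n - 1L))
    for (j in seq(i + 1L, n)) {
      pd <- protein_pdistance(proteins[[i]], proteins[[j]])
      d[i, j] <- d[j, i] <- pd$pdist
      alns[[paste(labs[i], labs[j], sep = "|")]] <-
        list(a = pd$aligned_a, b = pd$aligned_b)
    }
  attr(d, "alignments") <- alns
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration under the standard Q-criterion. Ties in the Q
#' minimum break to the smallest `(i, j)` pair under sorted-label order;
#' negative branch-length estimates are clamped to zero and counted in
#' `attr(tree, "clamped")`. On an additive matrix the reconstructed path
#' lengths reproduce the input exactly; the result is an unrooted tree
#' represented with one trifurcating root.
#'
#' @param dm Symmetric distance matrix with labeled dimnames (n >= 3).
#' @return An [ape::phylo] tree.
#' @export
nj_tree <- function(dm) {
  dm <- as.matrix(dm)
  if (is.null(rownames(dm)) || !isTRUE(all.equal(dm, t(dm))))
    stop("distance matrix must be labeled and symmetric", call. = FALSE)
  ord <- order(rownames(dm))
  d <- dm[ord, ord, drop = FALSE]
  labels <- rownames(d)
  nodes <- labels        # current newick fragment per active node
  clamped <- 0L
  fmt <- function(x) {
    if (x < 0) { clamped <<- clamped + 1L; x <- 0 }
    sprintf("%.10g", x)
  }
  while (length(nodes) > 3L) {
    n <- length(nodes)
    r <- rowSums(d)
    q <- (n - 2) * d - outer(r, r, `+`)
    diag(q) <- Inf
    best <- c(NA_integer_, NA_integer_); bestq <- Inf
    for (i in seq_len(n - 1L))
      for (j in seq(i + 1L, n))
        if (q[i, j] < bestq) { bestq <- q[i, j]; best <- c(i, j) }
    i <- best[1]; j <- best[2]
    li <- d[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))
    lj <- d[i, j] - li
    merged <- sprintf("(%s:%s,%s:%s)", nodes[i], fmt(li), nodes[j], fmt(lj))
    du <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(n), c(i, j))
    d <- rbind(cbind(d[keep, keep, drop = FALSE], du[keep]),
               c(du[keep], 0))
    nodes <- c(nodes[keep], merged)
    m <- length(nodes)
    dimnames(d) <- list(seq_len(m), seq_len(m))
  }
  la <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  lb <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  lc <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  nwk <- sprintf("(%s:%s,%s:%s,%s:%s);", nodes[1], fmt(la),
                 nodes[2], fmt(lb), nodes[3], fmt(lc))
  tree <- ape::read.tree(text = nwk)
  attr(tree, "clamped") <- clamped
  tree
}

#' Neighbor-joining tree with bootstrap support
#'
#' The point tree is built from [pdistance_matrix()]. Each bootstrap
#' replicate resamples, for every sequence pair, the columns of that pair's
#' alignment with replacement and recomputes the p-distance; the RNG stream
#' of each (replicate, pair) cell is keyed to the seed, the replicate index
#' and the sorted pair labels, so supports do not depend on input order.
#' Support on an internal bipartition is the fraction of replicate trees
#' containing it, stored in `tree$node.label`.
#'
#' @param proteins Named list of >= 3 protein [seq_record()]s.
#' @param reps Number of bootstrap replicates (>= 1).
#' @param seed Integer seed.
#' @return An [ape::phylo] tree with numeric `node.label` supports in
#'   `[0, 1]`.
#' @export
bootstrap_support <- function(proteins, reps = 1000L, seed = 1L) {
  stopifnot(reps >= 1L)
  dm <- pdistance_matrix(proteins)
  alns <- attr(dm, "alignments")
  main <- nj_tree(dm)
  labs <- rownames(dm)
  n <- length(labs)
  cols <- lapply(alns, function(al)
    list(a = strsplit(al$a, "")[[1]], b = strsplit(al$b, "")[[1]]))
  boot <- vector("list", reps)
  for (r in seq_len(reps)) {
    db <- matrix(0, n, n, dimnames = list(labs, labs))
    for (i in seq_len(n - 1L))
      for (j in seq(i + 1L, n)) {
        key <- paste(labs[i], labs[j], sep = "|")
        ca <- cols[[key]]$a
        cb <- cols[[key]]$b
        idx <- with_seed(sub_seed(seed, paste(r, key)),
                         sample.int(length(ca), replace = TRUE))
        ka <- ca[idx]; kb <- cb[idx]
        keep <- ka != "-" & kb != "-"
        db[i, j] <- db[j, i] <- if (any(keep))
          mean(ka[keep] != kb[keep]) else 1 - sum(keep)
      }
    boot[[r]] <- nj_tree(db)
  }
  counts <- ape::prop.clades(main, boot, rooted = FALSE)
  counts[is.na(counts)] <- 0
  main$node.label <- counts / reps
  log_stage("phylogeny", "NJ tree on ", n, " taxa, ", reps,
            " bootstrap replicates")
  main
}

#' Assign subfamilies from anchored reference leaves
#'
#' Each unlabeled leaf inherits the subfamily of the smallest clade
#' containing it whose anchors all belong to one subfamily (and which
#' contains at least one anchor). Leaves whose every anchor-containing
#' ancestor mixes subfamilies are reported `"unassigned"` with a warning
#' rather than guessed.
#'
#' @param tree An [ape::phylo] tree.
#' @param anchors Named character vector: reference leaf label -> subfamily.
#'   Anchors must all be tree leaves.
#' @return Named character vector leaf -> subfamily (`"unassigned"` where
#'   undecidable).
#' @export
assign_subfamilies <- function(tree, anchors) {
  stopifnot(inherits(tree, "phylo"))
  tips <- tree$tip.label
  missing <- setdiff(names(anchors), tips)
  if (length(missing))
    stop("anchor(s) missing from tree: ", paste(missing, collapse = ", "),
         call. = FALSE)
  n_tip <- length(tips)
  parent <- integer(n_tip + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  # descendant tip sets per node, computed bottom-up over the edge list
  tipset <- vector("list", n_tip + tree$Nnode)
  for (i in seq_len(n_tip)) tipset[[i]] <- tips[i]
  for (e in rev(seq_len(nrow(tree$edge)))) {
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    tipset[[p]] <- c(tipset[[p]], tipset[[ch]])
  }
  out <- stats::setNames(rep(NA_character_, n_tip), tips)
  out[names(anchors)] <- anchors
  for (i in seq_len(n_tip)) {
    if (!is.na(out[tips[i]])) next
    node <- parent[i]
    assigned <- FALSE
    while (node != 0L) {
      fam <- unique(anchors[intersect(names(anchors), tipset[[node]])])
      if (length(fam) == 1L) {
        out[tips[i]] <- fam
        assigned <- TRUE
        break
      }
      if (length(fam) > 1L) break  # smallest anchored clade is mixed
      node <- parent[node]
    }
    if (!assigned) {
      out[tips[i]] <- "unassigned"
      warning("leaf '", tips[i], "' lies outside any single-subfamily ",
              "anchored clade; left unassigned", call. = FALSE)
    }
  }
  out
}
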