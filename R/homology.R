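# Bidirectional best-hit ortholog and threshold paralog calling on top of
# exact local alignment.

# Align every query against every target once (scores are symmetric, so
# callers reuse this matrix in both directions).
.align_all <- function(queries, targets, s) {
  res <- vector("list", length(queries) * length(targets))
  dim(res) <- c(length(queries), length(targets))
  dimnames(res) <- list(names(queries), names(targets))
  for (i in seq_along(queries))
    for (j in seq_along(targets))
      res[[i, j]] <- local_align(queries[[i]], targets[[j]], s)
  res
}

.score_of <- function(m) apply(m, c(1, 2), function(x) x[[1]]$score)

#' Best hit of each query in a target set
#'
#' Each query maps to its highest-scoring target under [local_align()];
#' score ties break to the lexicographically smallest target id.
#'
#' @param query_set,target_set Named lists of dna [seq_record()]s.
#' @param s A [scoring_scheme()].
#' @return Named character vector: query id -> best target id.
#' @export
best_hits <- function(query_set, target_set, s = scoring_scheme()) {
  stopifnot(length(query_set) > 0, length(target_set) > 0)
  aln <- .align_all(query_set, target_set, s)
  sc <- .score_of(aln)
  ord <- order(colnames(sc))  # lexicographic tie-break
  vapply(rownames(sc), function(q) {
    colnames(sc)[ord][which.max(sc[q, ord])]
  }, "")
}

.pair_row <- function(al, relation) {
  data.frame(id_a = al$id_a, id_b = al$id_b, relation = relation,
             score = al$score, aligned_len = al$aligned_len,
             identity = al$identity, strand = al$strand,
             stringsAsFactors = FALSE)
}

.empty_pairs <- function() {
  data.frame(id_a = character(), id_b = character(), relation = character(),
             score = numeric(), aligned_len = integer(),
             identity = numeric(), strand = character(),
             stringsAsFactors = FALSE)
}

#' Bidirectional best-hit orthologs between two species
#'
#' A pair is called an ortholog iff each sequence is the other's best hit
#' and the best local alignment spans more than `min_aln` gap-free columns
#' (strict `>`; 300 bp default).
#'
#' @param set_a,set_b Named lists of dna [seq_record()]s, one per species.
#' @param s A [scoring_scheme()].
#' @param min_aln Aligned-length floor in bp (strict >).
#' @return Data frame of homolog pairs (`id_a` from `set_a`): `id_a`,
#'   `id_b`, `relation = "ortholog"`, `score`, `aligned_len`, `identity`,
#'   `strand`.
#' @export
bbh_orthologs <- function(set_a, set_b, s = scoring_scheme(),
                          min_aln = 300L) {
  aln <- .align_all(set_a, set_b, s)
  sc <- .score_of(aln)
  orda <- order(rownames(sc)); ordb <- order(colnames(sc))
  best_ab <- vapply(rownames(sc), function(q) {
    row <- sc[q, ordb, drop = TRUE]
    colnames(sc)[ordb][which.max(row)]
  }, "")
  best_ba <- vapply(colnames(sc), function(t) {
    col <- sc[orda, t, drop = TRUE]
    rownames(sc)[orda][which.max(col)]
  }, "")
  rows <- list()
  for (q in names(best_ab)) {
    t <- best_ab[[q]]
    if (identical(best_ba[[t]], q)) {
      al <- aln[[q, t]]
      if (al$aligned_len > min_aln)
        rows[[length(rows) + 1L]] <- .pair_row(al, "ortholog")
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else .empty_pairs()
  log_stage("homology", nrow(out), " BBH ortholog pairs (min_aln > ",
            min_aln, ")")
  out
}

#' Threshold paralogs within one species
#'
#' All unordered pairs whose best local alignment spans more than `min_aln`
#' gap-free columns and reaches at least `min_identity` identity
#' (`aligned_len > min_aln`, `identity >= min_identity`).
#'
#' @param set Named list of dna [seq_record()]s from one species.
#' @param s A [scoring_scheme()].
#' @param min_aln Aligned-length floor in bp (strict >).
#' @param min_identity Identity floor (inclusive), fraction in (0, 1].
#' @return Data frame of paralog pairs (ids in sorted order within a pair).
#' @export
find_paralogs <- function(set, s = scoring_scheme(), min_aln = 300L,
                          min_identity = 0.40) {
  ids <- sort(names(set))
  rows <- list()
  if (length(ids) >= 2L)
    for (i in seq_len(length(ids) - 1L))
      for (j in seq(i + 1L, length(ids))) {
        al <- local_align(set[[ids[i]]], set[[ids[j]]], s)
        if (al$aligned_len > min_aln && al$identity >= min_identity)
          rows[[length(rows) + 1L]] <- .pair_row(al, "paralog")
      }
  out <- if (length(rows)) do.call(rbind, rows) else .empty_pairs()
  log_stage("homology", nrow(out), " paralog pairs (min_aln > ", min_aln,
            ", identity >= ", min_identity, ")")
  out
}
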