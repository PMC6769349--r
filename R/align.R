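#' Alignment scoring scheme
#'
#' BLAST-like nucleotide scores are the defaults: match +2, mismatch -3,
#' gap open -5, gap extend -2. A gap of length L is penalized
#' `gap_open + L * gap_extend`.
#'
#' @param match Positive match score.
#' @param mismatch Mismatch score (<= 0).
#' @param gap_open Gap-opening score (<= 0).
#' @param gap_extend Gap-extension score per gapped column (<= 0).
#' @return A `scoring_scheme` list.
#' @export
scoring_scheme <- function(match = 2, mismatch = -3, gap_open = -5,
                           gap_extend = -2) {
  if (match <= 0 || mismatch > 0 || gap_open > 0 || gap_extend > 0)
    stop("need match > 0 and mismatch/gap scores <= 0", call. = FALSE)
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend), class = "scoring_scheme")
}

.submat <- function(s) {
  Biostrings::nucleotideSubstitutionMatrix(match = s$match,
                                           mismatch = s$mismatch,
                                           baseOnly = TRUE)
}

.aln_stats <- function(pa) {
  a <- as.character(Biostrings::alignedPattern(pa))
  b <- as.character(Biostrings::alignedSubject(pa))
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  keep <- ca != "-" & cb != "-"
  aligned_len <- sum(keep)
  identity <- if (aligned_len) sum(ca[keep] == cb[keep]) / aligned_len else 0
  list(aligned_a = a, aligned_b = b, aligned_len = aligned_len,
       identity = identity)
}

#' Optimal local alignment of two DNA sequences
#'
#' Exact affine-gap Smith-Waterman (via [Biostrings::pairwiseAlignment()]),
#' the deterministic stand-in for heuristic BLASTN searches at gene-family
#' scale. Both strands of `b` are scanned and the better one kept; ties
#' between strands go to the forward strand.
#'
#' @param a,b dna [seq_record()]s (non-empty).
#' @param s A [scoring_scheme()].
#' @param both_strands Scan the reverse complement of `b` too?
#' @return An `alignment_result` list: `id_a`, `id_b`, `aligned_a`,
#'   `aligned_b`, `score`, `aligned_len` (columns where neither row is a
#'   gap), `identity` (matches / aligned_len), `strand` (`"+"` or `"-"`).
#' @export
local_align <- function(a, b, s = scoring_scheme(), both_strands = TRUE) {
  stopifnot(inherits(a, "seq_record"), inherits(b, "seq_record"))
  if (!nchar(a$residues) || !nchar(b$residues))
    stop("empty sequence", call. = FALSE)
  run <- function(bs) {
    Biostrings::pairwiseAlignment(Biostrings::DNAString(a$residues),
                                  Biostrings::DNAString(bs),
                                  type = "local",
                                  substitutionMatrix = .submat(s),
                                  gapOpening = -s$gap_open,
                                  gapExtension = -s$gap_extend)
  }
  fwd <- run(b$residues)
  best <- fwd; strand <- "+"
  if (both_strands) {
    rev <- run(revcomp(b$residues))
    if (Biostrings::score(rev) > Biostrings::score(fwd)) {
      best <- rev; strand <- "-"
    }
  }
  st <- .aln_stats(best)
  structure(c(list(id_a = a$id, id_b = b$id,
                   score = Biostrings::score(best), strand = strand), st),
            class = "alignment_result")
}

#' Global alignment p-distance between two protein sequences
#'
#' Needleman-Wunsch global alignment under a simple match/mismatch scheme;
#' p-distance = mismatched columns / gap-free columns.
#'
#' @param a,b protein [seq_record()]s.
#' @param gap_open,gap_extend Gap penalties (positive costs).
#' @return List with `pdist`, `aligned_len`.
#' @export
protein_pdistance <- function(a, b, gap_open = 10, gap_extend = 1) {
  sub <- matrix(-1, 26, 26,
                dimnames = list(LETTERS, LETTERS))
  diag(sub) <- 1
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a$residues), Biostrings::AAString(b$residues),
    type = "global", substitutionMatrix = sub,
    gapOpening = gap_open, gapExtension = gap_extend)
  st <- .aln_stats(pa)
  if (!st$aligned_len)
    stop("no gap-free columns aligning '", a$id, "' and '", b$id, "'",
         call. = FALSE)
  list(pdist = 1 - st$identity, aligned_len = st$aligned_len,
       aligned_a = st$aligned_a, aligned_b = st$aligned_b)
}
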