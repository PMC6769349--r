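#' Load a domain-pattern library
#'
#' Patterns are spacing patterns over residue classes: an ordered list of
#' elements `(residue class, min_gap, max_gap)` where the gap bounds the
#' number of arbitrary residues between an element and the next. A
#' per-pattern `max_mismatch` budget lets short tripeptide motifs tolerate
#' substitutions. The bundled library (`domain_patterns.tsv` under
#' `inst/extdata`) carries the family-diagnostic QLQ and WRC patterns plus
#' the C-terminal FFD and TQL tripeptides; it is an editable, auditable
#' surrogate for profile-HMM domain models, so genome-scale membership calls
#' should be treated as candidates rather than a reproduction of any HMM
#' scan.
#'
#' @param path TSV file; defaults to the bundled library.
#' @return Named list of `domain_pattern` objects.
#' @export
load_domain_patterns <- function(path = system.file("extdata",
                                                    "domain_patterns.tsv",
                                                    package = "grfevol")) {
  tab <- read_tsv(path)
  pats <- lapply(split(tab, tab$name), function(d) {
    d <- d[order(d$element), ]
    if (any(d$min_gap > d$max_gap))
      stop("pattern '", d$name[1], "': min_gap > max_gap", call. = FALSE)
    structure(list(name = d$name[1],
                   elements = Map(function(res, lo, hi)
                     list(residues = strsplit(res, "")[[1]],
                          min_gap = lo, max_gap = hi),
                     d$residues, d$min_gap, d$max_gap),
                   max_mismatch = d$max_mismatch[1]),
              class = "domain_pattern")
  })
  pats[unique(tab$name)]
}

# Try to match `pat` anchored at position `pos` (1-based) of residue vector
# `aa`, spending at most `budget` substitutions. Gaps are tried shortest
# first, so the reported span is the minimal (deterministic) match.
# Returns the end position of the match or NA.
.match_at <- function(aa, pat, pos, budget) {
  n <- length(aa)
  rec <- function(i, at, left) {
    if (i > length(pat$elements)) return(at - 1L)
    if (at > n) return(NA_integer_)
    el <- pat$elements[[i]]
    ok <- aa[at] %in% el$residues
    if (!ok) {
      if (left <= 0L) return(NA_integer_)
      left <- left - 1L
    }
    if (i == length(pat$elements)) return(at)
    for (g in el$min_gap:el$max_gap) {
      hit <- rec(i + 1L, at + 1L + g, left)
      if (!is.na(hit)) return(hit)
    }
    NA_integer_
  }
  rec(1L, pos, budget)
}

#' Scan a protein for a domain pattern
#'
#' Reports all non-overlapping leftmost matches in position order: scanning
#' left to right, the first position where the pattern matches yields a hit
#' spanning the minimal match, and scanning resumes after its end.
#'
#' @param protein A protein [seq_record()].
#' @param pattern A `domain_pattern` from [load_domain_patterns()].
#' @return Data frame of hits: `domain`, `start`, `end` (1-based residue
#'   positions), `matched_span`.
#' @export
scan_domain <- function(protein, pattern) {
  stopifnot(inherits(protein, "seq_record"), inherits(pattern,
                                                      "domain_pattern"))
  if (protein$alphabet != "protein")
    stop("scan_domain expects a protein record, got dna", call. = FALSE)
  aa <- strsplit(protein$residues, "")[[1]]
  hits <- list()
  pos <- 1L
  while (pos <= length(aa)) {
    end <- .match_at(aa, pattern, pos, pattern$max_mismatch)
    if (!is.na(end)) {
      hits[[length(hits) + 1L]] <-
        data.frame(domain = pattern$name, start = pos, end = end,
                   matched_span = paste(aa[pos:end], collapse = ""),
                   stringsAsFactors = FALSE)
      pos <- end + 1L
    } else {
      pos <- pos + 1L
    }
  }
  if (!length(hits))
    return(data.frame(domain = character(), start = integer(),
                      end = integer(), matched_span = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, hits)
}

#' Classify family membership from domain content
#'
#' A protein is called a family member iff it carries at least one QLQ hit
#' and at least one WRC hit; all hits are returned for reporting.
#'
#' @param protein A protein [seq_record()].
#' @param patterns Pattern library from [load_domain_patterns()].
#' @return List with `member` (logical) and `hits` (data frame over all
#'   patterns in the library).
#' @export
classify_member <- function(protein, patterns = load_domain_patterns()) {
  hits <- do.call(rbind, lapply(patterns, scan_domain, protein = protein))
  rownames(hits) <- NULL
  member <- any(hits$domain == "QLQ") && any(hits$domain == "WRC")
  list(member = member, hits = hits)
}
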