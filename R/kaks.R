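# Nei-Gojobori (1986) Ka/Ks: expected synonymous/nonsynonymous site counts
# with stop-excluded denominators, observed differences averaged over equal-
# weighted mutational pathways (stop-crossing pathways excluded), and
# Jukes-Cantor multiple-hit correction. These conventions are constants of
# the implementation and are exercised against brute-force enumeration in
# the test suite.

.genetic_code <- function() Biostrings::GENETIC_CODE
.stop_codons <- c("TAA", "TAG", "TGA")
.bases <- c("A", "C", "G", "T")

is_sense_codon <- function(codon) {
  nchar(codon) == 3L && !grepl("[^ACGT]", codon) &&
    !(codon %in% .stop_codons)
}

#' Expected synonymous and nonsynonymous sites of a codon (NG86)
#'
#' For each of the three positions, the synonymous site fraction is the
#' fraction of the single-base changes at that position that preserve the
#' encoded amino acid, with changes to stop codons excluded from the
#' denominator. Each position contributes one site, so
#' `syn_sites + nonsyn_sites = 3` for every sense codon.
#'
#' @param codon A 3-letter sense codon (A/C/G/T).
#' @return Named numeric vector `c(syn_sites, nonsyn_sites)`.
#' @examples
#' ng86_sites("TTT")  # 1/3 synonymous site (third position)
#' @export
ng86_sites <- function(codon) {
  codon <- toupper(codon)
  if (!is_sense_codon(codon))
    stop("not a sense codon: ", codon, call. = FALSE)
  key <- paste0("sites:", codon)
  hit <- .grfevol_cache[[key]]
  if (!is.null(hit)) return(hit)
  code <- .genetic_code()
  aa <- code[[codon]]
  syn <- 0
  for (pos in 1:3) {
    n_syn <- 0L; n_legal <- 0L
    for (b in setdiff(.bases, substr(codon, pos, pos))) {
      mut <- codon
      substr(mut, pos, pos) <- b
      if (mut %in% .stop_codons) next
      n_legal <- n_legal + 1L
      if (code[[mut]] == aa) n_syn <- n_syn + 1L
    }
    syn <- syn + n_syn / n_legal
  }
  out <- c(syn_sites = syn, nonsyn_sites = 3 - syn)
  assign(key, out, envir = .grfevol_cache)
  out
}

#' Synonymous and nonsynonymous differences between two codons (NG86)
#'
#' With k differing positions (1-3), every one of the k! orderings of the
#' single-base steps is a mutational pathway; pathways passing through a
#' stop codon are excluded, and synonymous/nonsynonymous step counts are
#' averaged with equal weight over the legal pathways, so
#' `syn + nonsyn = k`. If every pathway crosses a stop the column is
#' uncountable and `NA`s are returned.
#'
#' @param codon_a,codon_b Sense codons.
#' @return Named numeric vector `c(syn_diffs, nonsyn_diffs)`; `NA`s when no
#'   legal pathway exists.
#' @examples
#' ng86_differences("TTT", "TTC")  # one synonymous difference
#' @export
ng86_differences <- function(codon_a, codon_b) {
  codon_a <- toupper(codon_a); codon_b <- toupper(codon_b)
  if (!is_sense_codon(codon_a) || !is_sense_codon(codon_b))
    stop("not a sense codon: ", codon_a, "/", codon_b, call. = FALSE)
  key <- paste0("diff:", codon_a, codon_b)
  hit <- .grfevol_cache[[key]]
  if (!is.null(hit)) return(hit)
  code <- .genetic_code()
  diff_pos <- which(strsplit(codon_a, "")[[1]] != strsplit(codon_b, "")[[1]])
  k <- length(diff_pos)
  if (k == 0L) {
    out <- c(syn_diffs = 0, nonsyn_diffs = 0)
  } else {
    perms <- .permutations(diff_pos)
    syn_tot <- 0; nonsyn_tot <- 0; n_legal <- 0L
    for (ord in perms) {
      cur <- codon_a
      syn <- 0L; nonsyn <- 0L; legal <- TRUE
      for (pos in ord) {
        nxt <- cur
        substr(nxt, pos, pos) <- substr(codon_b, pos, pos)
        if (nxt %in% .stop_codons) { legal <- FALSE; break }
        if (code[[nxt]] == code[[cur]]) syn <- syn + 1L
        else nonsyn <- nonsyn + 1L
        cur <- nxt
      }
      if (legal) {
        syn_tot <- syn_tot + syn
        nonsyn_tot <- nonsyn_tot + nonsyn
        n_legal <- n_legal + 1L
      }
    }
    out <- if (n_legal == 0L) c(syn_diffs = NA_real_, nonsyn_diffs = NA_real_)
           else c(syn_diffs = syn_tot / n_legal,
                  nonsyn_diffs = nonsyn_tot / n_legal)
  }
  assign(key, out, envir = .grfevol_cache)
  out
}

.permutations <- function(x) {
  if (length(x) <= 1L) return(list(x))
  out <- list()
  for (i in seq_along(x))
    for (rest in .permutations(x[-i]))
      out[[length(out) + 1L]] <- c(x[i], rest)
  out
}

#' Jukes-Cantor correction of a proportion of differing sites
#'
#' `d = -(3/4) * log(1 - 4p/3)`; undefined (saturated) for `p >= 3/4`.
#'
#' @param p Observed proportion of differing sites (>= 0; NG86
#'   pathway-averaged proportions can exceed 1 for extremely diverged
#'   pairs, which is likewise saturation).
#' @return Corrected distance, or `NA` with a `"saturated"` attribute when
#'   `p >= 3/4`.
#' @export
jukes_cantor <- function(p) {
  if (p < 0) stop("p must be nonnegative", call. = FALSE)
  if (p >= 0.75) return(structure(NA_real_, saturated = TRUE))
  -0.75 * log(1 - 4 * p / 3)
}

#' Codon alignment container
#'
#' Paired codon columns for two coding sequences. Every codon is either
#' three unambiguous nucleotides or the gap triple `"---"`. Columns with a
#' gap or stop codon in either row are excluded from counting operations.
#'
#' @param id_a,id_b Sequence identifiers.
#' @param codons_a,codons_b Equal-length character vectors of codons.
#' @return A `codon_alignment` object.
#' @export
codon_alignment <- function(id_a, id_b, codons_a, codons_b) {
  stopifnot(length(codons_a) == length(codons_b))
  ok <- function(v) all(nchar(v) == 3L & (v == "---" | !grepl("[^ACGT]", v)))
  if (!ok(codons_a) || !ok(codons_b))
    stop("codons must be 3 unambiguous nucleotides or '---'", call. = FALSE)
  structure(list(id_a = id_a, id_b = id_b,
                 codons_a = toupper(codons_a), codons_b = toupper(codons_b),
                 n_codons = length(codons_a)),
            class = "codon_alignment")
}

# Columns counted by NG86: gap-free, stop-free in both rows.
.counted_columns <- function(aln) {
  sense_a <- vapply(aln$codons_a, is_sense_codon, TRUE)
  sense_b <- vapply(aln$codons_b, is_sense_codon, TRUE)
  which(sense_a & sense_b)
}

#' Back-translate a protein alignment onto its coding sequences
#'
#' Each protein alignment column maps to one codon column; protein gaps
#' become gap triples. The CDSs must translate (terminal stop dropped) to
#' exactly the ungapped protein rows.
#'
#' @param prot_aln List with gapped protein rows `aligned_a`, `aligned_b`
#'   (e.g. from [protein_pdistance()]).
#' @param cds_a,cds_b dna [seq_record()]s, valid ORFs.
#' @return A [codon_alignment()].
#' @export
backtranslate_alignment <- function(prot_aln, cds_a, cds_b) {
  build <- function(gapped, cds) {
    prot <- translate_orf(cds, strict_start = "silent")
    ungapped <- gsub("-", "", gapped, fixed = TRUE)
    if (ungapped != prot$residues) {
      exp <- strsplit(prot$residues, "")[[1]]
      got <- strsplit(ungapped, "")[[1]]
      at <- which(exp[seq_len(min(length(exp), length(got)))] !=
                  got[seq_len(min(length(exp), length(got)))])
      at <- if (length(at)) at[[1]] else min(length(exp), length(got)) + 1L
      stop("CDS '", cds$id, "' does not back-translate the aligned ",
           "protein row (first discordant residue position ", at, ")",
           call. = FALSE)
    }
    cols <- strsplit(gapped, "")[[1]]
    codons <- substring(cds$residues, seq(1L, nchar(cds$residues), 3L),
                        seq(3L, nchar(cds$residues), 3L))
    out <- character(length(cols))
    k <- 0L
    for (i in seq_along(cols)) {
      if (cols[i] == "-") out[i] <- "---"
      else { k <- k + 1L; out[i] <- codons[k] }
    }
    out
  }
  codon_alignment(cds_a$id, cds_b$id,
                  build(prot_aln$aligned_a, cds_a),
                  build(prot_aln$aligned_b, cds_b))
}

#' Codon-aware alignment of two coding sequences
#'
#' Globally aligns the translated proteins and back-translates the result.
#'
#' @param cds_a,cds_b dna [seq_record()]s, valid ORFs.
#' @return A [codon_alignment()].
#' @export
align_cds_pair <- function(cds_a, cds_b) {
  pa <- protein_pdistance(translate_orf(cds_a, strict_start = "silent"),
                          translate_orf(cds_b, strict_start = "silent"))
  backtranslate_alignment(pa, cds_a, cds_b)
}

#' NG86 Ka/Ks of a codon alignment
#'
#' Site counts are averaged over the two sequences and summed over counted
#' columns; observed differences are pathway-averaged per column. Both
#' proportions receive the Jukes-Cantor correction. Saturation
#' (`p >= 3/4`) in either class clears the corresponding validity flag;
#' when `Ks = 0` exactly the ratio is reported as `NA` (undefined), never
#' infinity.
#'
#' @param aln A [codon_alignment()].
#' @return A `kaks_result` list: `ka`, `ks`, `ratio`, `s_sites`, `n_sites`,
#'   `sd`, `nd`, `ka_valid`, `ks_valid`, `n_counted` (codon columns
#'   counted), `n_uncountable` (columns with no legal pathway).
#' @export
kaks <- function(aln) {
  stopifnot(inherits(aln, "codon_alignment"))
  cols <- .counted_columns(aln)
  if (!length(cols))
    stop("no countable codon columns in alignment ", aln$id_a, "/",
         aln$id_b, call. = FALSE)
  s_sites <- 0; n_sites <- 0; sd <- 0; nd <- 0; dropped <- 0L
  for (i in cols) {
    ca <- aln$codons_a[[i]]; cb <- aln$codons_b[[i]]
    d <- ng86_differences(ca, cb)
    if (anyNA(d)) { dropped <- dropped + 1L; next }
    sa <- ng86_sites(ca); sb <- ng86_sites(cb)
    s_sites <- s_sites + (sa[["syn_sites"]] + sb[["syn_sites"]]) / 2
    n_sites <- n_sites + (sa[["nonsyn_sites"]] + sb[["nonsyn_sites"]]) / 2
    sd <- sd + d[["syn_diffs"]]
    nd <- nd + d[["nonsyn_diffs"]]
  }
  ks <- if (s_sites > 0) jukes_cantor(sd / s_sites) else NA_real_
  ka <- if (n_sites > 0) jukes_cantor(nd / n_sites) else NA_real_
  ks_valid <- !is.na(ks)
  ka_valid <- !is.na(ka)
  ratio <- if (ka_valid && ks_valid && ks > 0) ka / ks else NA_real_
  structure(list(id_a = aln$id_a, id_b = aln$id_b,
                 ka = as.numeric(ka), ks = as.numeric(ks), ratio = ratio,
                 s_sites = s_sites, n_sites = n_sites, sd = sd, nd = nd,
                 ka_valid = ka_valid, ks_valid = ks_valid,
                 n_counted = length(cols) - dropped,
                 n_uncountable = dropped),
            class = "kaks_result")
}

#' Sliding-window Ka/Ks profile
#'
#' Windows are indexed on the ungapped nucleotide coordinates of the codon
#' alignment (gap columns removed): starts 0, `step`, `2*step`, ... while
#' `start + window_len` fits. Each window's Ka/Ks is computed on the codon
#' columns lying fully inside the window; invalid windows (saturation or
#' zero sites) are reported with their validity flag rather than dropped.
#'
#' @param aln A [codon_alignment()].
#' @param window_len Window length in bp (codon multiple recommended).
#' @param step Step size in bp.
#' @return A data.frame with class `sliding_window_profile`: `start_bp`
#'   (0-based), `midpoint_bp`, `ka`, `ks`, `ratio`, `ka_valid`, `ks_valid`.
#' @export
sliding_window_kaks <- function(aln, window_len = 150L, step = 9L) {
  stopifnot(inherits(aln, "codon_alignment"))
  gap_free <- aln$codons_a != "---" & aln$codons_b != "---"
  sub <- codon_alignment(aln$id_a, aln$id_b,
                         aln$codons_a[gap_free], aln$codons_b[gap_free])
  n_nt <- 3L * sub$n_codons
  empty <- data.frame(start_bp = integer(), midpoint_bp = numeric(),
                      ka = numeric(), ks = numeric(), ratio = numeric(),
                      ka_valid = logical(), ks_valid = logical())
  if (n_nt < window_len) {
    warning("alignment shorter than one window; empty profile",
            call. = FALSE)
    return(structure(empty, class = c("sliding_window_profile",
                                      "data.frame")))
  }
  starts <- seq(0L, n_nt - window_len, by = step)
  rows <- lapply(starts, function(st) {
    first <- ceiling(st / 3) + 1L
    last <- floor((st + window_len) / 3)
    res <- tryCatch(kaks(codon_alignment(aln$id_a, aln$id_b,
                                         sub$codons_a[first:last],
                                         sub$codons_b[first:last])),
                    error = function(e) NULL)
    if (is.null(res))
      data.frame(start_bp = st, midpoint_bp = st + window_len / 2,
                 ka = NA_real_, ks = NA_real_, ratio = NA_real_,
                 ka_valid = FALSE, ks_valid = FALSE)
    else
      data.frame(start_bp = st, midpoint_bp = st + window_len / 2,
                 ka = res$ka, ks = res$ks, ratio = res$ratio,
                 ka_valid = res$ka_valid, ks_valid = res$ks_valid)
  })
  structure(do.call(rbind, rows),
            class = c("sliding_window_profile", "data.frame"))
}

#' Divergence time from synonymous divergence
#'
#' `T = Ks / (2 * lambda)`, reported in million years (Mya). The default
#' rate is the grass-lineage synonymous substitution rate
#' `lambda = 6.5e-9` subs/site/year.
#'
#' @param ks Synonymous substitutions per synonymous site (>= 0).
#' @param lambda_rate Substitutions/site/year (> 0).
#' @return Data frame row: `t_mya`, `ks`, `lambda_rate`. Vectorized over
#'   `ks`.
#' @examples
#' divergence_time(0.15242)$t_mya  # 11.72461538 Mya
#' @export
divergence_time <- function(ks, lambda_rate = 6.5e-9) {
  if (any(ks < 0, na.rm = TRUE)) stop("negative ks", call. = FALSE)
  if (lambda_rate <= 0) stop("lambda_rate must be positive", call. = FALSE)
  data.frame(t_mya = ks / (2 * lambda_rate) / 1e6, ks = ks,
             lambda_rate = lambda_rate)
}

#' Classify selection from a Ka/Ks ratio
#'
#' Ratios above 1 indicate positive selection, below 1 purifying selection;
#' equality with 1 (within `tol`) is neutral. Undefined ratios return
#' `"undetermined"`.
#'
#' @param ratio Ka/Ks value (may be `NA`).
#' @param tol Equality tolerance around 1.
#' @return One of `"positive"`, `"neutral"`, `"purifying"`,
#'   `"undetermined"`. Vectorized.
#' @export
classify_selection <- function(ratio, tol = 1e-9) {
  vapply(ratio, function(r) {
    if (is.na(r)) "undetermined"
    else if (abs(r - 1) <= tol) "neutral"
    else if (r > 1) "positive"
    else "purifying"
  }, "")
}

#' Compare computed Ka/Ks against a reference table
#'
#' For each pair in `reference` (columns `id_a`, `id_b`, `ka`, `ks`),
#' aligns the named CDSs, computes NG86 Ka/Ks and reports the deviations.
#' Intended for checking against externally published per-pair values when
#' the underlying sequences are available.
#'
#' @param cds Named list of dna [seq_record()]s.
#' @param reference Data frame with `id_a`, `id_b`, `ka`, `ks`.
#' @param tol Agreement tolerance on Ka and Ks.
#' @return Data frame with computed values, deltas and a `within_tol` flag.
#' @export
compare_kaks_table <- function(cds, reference, tol = 0.01) {
  rows <- lapply(seq_len(nrow(reference)), function(i) {
    ref <- reference[i, ]
    res <- kaks(align_cds_pair(cds[[ref$id_a]], cds[[ref$id_b]]))
    data.frame(id_a = ref$id_a, id_b = ref$id_b,
               ka = res$ka, ks = res$ks,
               ka_ref = ref$ka, ks_ref = ref$ks,
               delta_ka = res$ka - ref$ka, delta_ks = res$ks - ref$ks,
               within_tol = isTRUE(abs(res$ka - ref$ka) <= tol &&
                                   abs(res$ks - ref$ks) <= tol))
  })
  do.call(rbind, rows)
}
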