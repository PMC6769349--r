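# Seeded generators for every input the pipeline consumes, each paired with
# a ground-truth record: codon sequences diverged under a target omega and
# Ks, duplicating families with known split times, promoters with planted
# motifs, and replicated Ct tables with known fold changes.

#' Simulation parameter set
#'
#' @param omega Target Ka/Ks (> 0): acceptance probability of a
#'   nonsynonymous proposal.
#' @param target_ks Expected synonymous substitutions per synonymous site
#'   between the two evolved copies (>= 0).
#' @param n_codons Number of sense codons (protein length; the simulated
#'   ORF is `3 * (n_codons + 1)` bp including the stop). Minimum 10.
#' @param lambda_rate Synonymous substitution rate, subs/site/year.
#' @param gc_content Codon-usage GC weighting, in (0, 1).
#' @param seed Integer seed.
#' @return A `sim_params` list.
#' @export
sim_params <- function(omega = 0.3, target_ks = 0.15, n_codons = 300L,
                       lambda_rate = 6.5e-9, gc_content = 0.5, seed = 1L) {
  stopifnot(omega > 0, target_ks >= 0, n_codons >= 10L,
            gc_content > 0, gc_content < 1, lambda_rate > 0)
  structure(list(omega = omega, target_ks = target_ks,
                 n_codons = as.integer(n_codons),
                 lambda_rate = lambda_rate, gc_content = gc_content,
                 seed = as.integer(seed)), class = "sim_params")
}

.sense_codons <- function() {
  code <- .genetic_code()
  setdiff(names(code), .stop_codons)
}

.codon_gc_weights <- function(gc) {
  codons <- .sense_codons()
  n_gc <- vapply(strsplit(codons, ""), function(x) sum(x %in% c("G", "C")),
                 0L)
  w <- (gc / 2)^n_gc * ((1 - gc) / 2)^(3L - n_gc)
  stats::setNames(w / sum(w), codons)
}

#' Simulate a coding sequence
#'
#' ATG start, sense codons drawn with GC-weighted usage, one terminal stop
#' codon; deterministic under the seed.
#'
#' @param p A [sim_params()].
#' @param id Record id.
#' @return A dna [seq_record()] of `3 * (n_codons + 1)` bp.
#' @examples
#' length(simulate_cds(sim_params(n_codons = 170)))  # 513-bp ORF
#' @export
simulate_cds <- function(p, id = "sim1") {
  stopifnot(inherits(p, "sim_params"))
  w <- .codon_gc_weights(p$gc_content)
  codons <- with_seed(sub_seed(p$seed, paste0("cds:", id)), {
    body <- sample(names(w), p$n_codons - 1L, replace = TRUE, prob = w)
    stop_codon <- sample(.stop_codons, 1L)
    c("ATG", body, stop_codon)
  })
  seq_record(id, paste(codons, collapse = ""), "dna")
}

# Evolve one lineage: propose uniform single-base changes (start and stop
# codons protected), accept synonymous changes with probability 1,
# nonsynonymous with probability omega, stop-creating never; run until the
# accepted synonymous event budget round(S * syn_per_site) is spent.
# Returns the codon vector plus realized event counts.
.evolve_lineage <- function(codons, syn_per_site, omega) {
  code <- .genetic_code()
  n <- length(codons)
  mutable <- 2:(n - 1L)
  s_anc <- sum(vapply(codons[mutable],
                      function(cd) ng86_sites(cd)[["syn_sites"]], 0))
  budget <- round(s_anc * syn_per_site)
  syn_done <- 0L; nonsyn_done <- 0L
  while (syn_done < budget) {
    i <- sample(mutable, 1L)
    pos <- sample.int(3L, 1L)
    old <- codons[[i]]
    b <- sample(setdiff(.bases, substr(old, pos, pos)), 1L)
    new <- old
    substr(new, pos, pos) <- b
    if (new %in% .stop_codons) next
    if (code[[new]] == code[[old]]) {
      codons[[i]] <- new
      syn_done <- syn_done + 1L
    } else if (stats::runif(1) < omega) {
      codons[[i]] <- new
      nonsyn_done <- nonsyn_done + 1L
    }
  }
  list(codons = codons, syn_events = syn_done, nonsyn_events = nonsyn_done,
       syn_sites = s_anc)
}

.codons_of <- function(rec) {
  s <- rec$residues
  substring(s, seq(1L, nchar(s), 3L), seq(3L, nchar(s), 3L))
}

#' Evolve a diverged pair of coding sequences
#'
#' Two independent lineages descend from the ancestor; per-site proposals
#' are uniform over nucleotides, accepted with probability 1 if synonymous,
#' `omega` if nonsynonymous and 0 if stop-creating. Each lineage's
#' synonymous event budget is tuned so the realized synonymous divergence of
#' the pair approximates `target_ks` (half per lineage). Start and stop
#' codons are protected so both copies remain valid ORFs.
#'
#' @param ancestor A dna [seq_record()] from [simulate_cds()].
#' @param p A [sim_params()].
#' @param ids Identifiers for the two copies.
#' @return List: `a`, `b` (dna [seq_record()]s), `truth` (realized event
#'   counts per lineage).
#' @export
evolve_pair <- function(ancestor, p, ids = c("copyA", "copyB")) {
  stopifnot(inherits(ancestor, "seq_record"), inherits(p, "sim_params"))
  codons <- .codons_of(ancestor)
  half <- p$target_ks / 2
  res <- with_seed(sub_seed(p$seed, paste0("pair:", ancestor$id)), {
    lapply(1:2, function(k) .evolve_lineage(codons, half, p$omega))
  })
  list(a = seq_record(ids[1], paste(res[[1]]$codons, collapse = ""), "dna"),
       b = seq_record(ids[2], paste(res[[2]]$codons, collapse = ""), "dna"),
       truth = data.frame(lineage = ids,
                          syn_events = c(res[[1]]$syn_events,
                                         res[[2]]$syn_events),
                          nonsyn_events = c(res[[1]]$nonsyn_events,
                                            res[[2]]$nonsyn_events),
                          syn_sites = c(res[[1]]$syn_sites,
                                        res[[2]]$syn_sites)))
}

#' Simulate a duplicating gene family with known split times
#'
#' A duplication history of sequential duplications at the given times
#' (million years ago), evolved at rate `lambda_rate` with selection
#' intensity `omega`: between consecutive events every live lineage
#' accumulates a synonymous event budget of `lambda * dt` per synonymous
#' site, the forward counterpart of the dating formula `T = Ks / (2
#' lambda)`. Duplications cycle through the live lineages deterministically.
#'
#' @param n_genes Number of genes (`length(split_times_mya) + 1`).
#' @param split_times_mya Positive duplication times in Mya, sorted
#'   ascending.
#' @param p A [sim_params()] (`target_ks` is ignored; times and
#'   `lambda_rate` set the divergence).
#' @param prefix Gene-id prefix.
#' @return List: `records` (named list of dna [seq_record()]s), `truth`
#'   (data frame of all true paralog pairs with `split_time_mya` and the
#'   expected synonymous divergence `expected_ks = 2 * lambda * T`).
#' @export
simulate_family <- function(n_genes, split_times_mya, p, prefix = "G") {
  stopifnot(inherits(p, "sim_params"),
            all(split_times_mya > 0), !is.unsorted(split_times_mya),
            n_genes == length(split_times_mya) + 1L)
  anc <- simulate_cds(p, paste0(prefix, "anc"))
  events <- sort(split_times_mya, decreasing = TRUE)
  lineages <- list(.codons_of(anc))
  ids <- paste0(prefix, 1L)
  split <- matrix(0, 1, 1, dimnames = list(ids, ids))
  with_seed(sub_seed(p$seed, paste0("family:", prefix)), {
    times <- c(events, 0)
    for (k in seq_along(events)) {
      # duplicate a live lineage (round-robin), then evolve to next event
      src <- ((k - 1L) %% length(lineages)) + 1L
      new_id <- paste0(prefix, length(lineages) + 1L)
      lineages[[length(lineages) + 1L]] <- lineages[[src]]
      old_ids <- ids
      ids <- c(ids, new_id)
      grown <- matrix(0, length(ids), length(ids),
                      dimnames = list(ids, ids))
      grown[old_ids, old_ids] <- split
      grown[new_id, old_ids] <- grown[old_ids, new_id] <-
        pmax(split[old_ids[src], old_ids], events[k])
      grown[new_id, old_ids[src]] <- grown[old_ids[src], new_id] <-
        events[k]
      split <- grown
      dt_years <- (times[k] - times[k + 1L]) * 1e6
      per_site <- p$lambda_rate * dt_years
      lineages <- lapply(lineages, function(cd)
        .evolve_lineage(cd, per_site, p$omega)$codons)
    }
  })
  records <- Map(function(id, cd)
    seq_record(id, paste(cd, collapse = ""), "dna"), ids, lineages)
  pairs <- which(upper.tri(split), arr.ind = TRUE)
  truth <- data.frame(id_a = ids[pairs[, 1]], id_b = ids[pairs[, 2]],
                      relation = "paralog",
                      split_time_mya = split[pairs],
                      expected_ks = 2 * p$lambda_rate * split[pairs] * 1e6,
                      stringsAsFactors = FALSE)
  list(records = records, truth = truth)
}

#' Simulate one-to-one ortholog sets for two species
#'
#' `n_genes` unrelated ancestral genes each split at `species_split_mya`;
#' the two copies evolve independently, giving a known one-to-one
#' cross-species pairing for benchmarking reciprocal-best-hit calling.
#'
#' @param n_genes Number of ancestral genes.
#' @param species_split_mya Species divergence time in Mya.
#' @param p A [sim_params()].
#' @return List: `set_a`, `set_b` (named record lists, ids `A_g<i>` /
#'   `B_g<i>`), `truth` (ortholog pairs with split time and expected Ks).
#' @export
simulate_ortholog_sets <- function(n_genes, species_split_mya, p) {
  stopifnot(inherits(p, "sim_params"), species_split_mya > 0)
  ks <- 2 * p$lambda_rate * species_split_mya * 1e6
  set_a <- list(); set_b <- list(); rows <- list()
  for (g in seq_len(n_genes)) {
    pg <- p
    pg$seed <- sub_seed(p$seed, paste0("orth", g))
    pg$target_ks <- ks
    anc <- simulate_cds(pg, paste0("anc_g", g))
    pair <- evolve_pair(anc, pg, ids = paste0(c("A_g", "B_g"), g))
    set_a[[pair$a$id]] <- pair$a
    set_b[[pair$b$id]] <- pair$b
    rows[[g]] <- data.frame(id_a = pair$a$id, id_b = pair$b$id,
                            relation = "ortholog",
                            split_time_mya = species_split_mya,
                            expected_ks = ks, stringsAsFactors = FALSE)
  }
  list(set_a = set_a, set_b = set_b, truth = do.call(rbind, rows))
}

.iupac_match <- function(code) {
  map <- list(A = "A", C = "C", G = "G", T = "T", R = c("A", "G"),
              Y = c("C", "T"), S = c("G", "C"), W = c("A", "T"),
              K = c("G", "T"), M = c("A", "C"), B = c("C", "G", "T"),
              D = c("A", "G", "T"), H = c("A", "C", "T"),
              V = c("A", "C", "G"), N = c("A", "C", "G", "T"))
  map[[code]]
}

# Instantiate an IUPAC pattern as a concrete sequence (sampling ambiguous
# positions uniformly).
.instantiate_iupac <- function(iupac) {
  paste(vapply(strsplit(iupac, "")[[1]],
               function(ch) sample(.iupac_match(ch), 1L), ""),
        collapse = "")
}

#' Plant cis-element motifs into synthetic promoters
#'
#' Uniform-composition background sequences with motif instances inserted
#' at recorded non-overlapping positions. Background matches of every
#' requested motif are screened and destroyed (a concrete position of the
#' match is mutated off-pattern), and the final sequence is re-verified, so
#' a scan of the listed motifs recovers exactly the planting table.
#'
#' @param genes Character vector of promoter/gene ids.
#' @param motif_counts Named integer vector (motif name -> copies per
#'   promoter), or a genes x motifs matrix for per-gene counts. Names must
#'   exist in `motifs`.
#' @param motifs Motif dictionary ([load_motif_dictionary()]).
#' @param promoter_len Promoter length in bp.
#' @param seed Integer seed.
#' @return List: `records` (named list of dna [seq_record()]s), `truth`
#'   (data frame `gene`, `motif`, `start`, `planted`).
#' @export
plant_promoters <- function(genes, motif_counts,
                            motifs = load_motif_dictionary(),
                            promoter_len = 2000L, seed = 1L) {
  if (is.null(dim(motif_counts))) {
    motif_counts <- matrix(rep(as.integer(motif_counts), length(genes)),
                           nrow = length(genes), byrow = TRUE,
                           dimnames = list(genes, names(motif_counts)))
  }
  wanted <- colnames(motif_counts)
  unknown <- setdiff(wanted, motifs$name)
  if (length(unknown))
    stop("motif(s) not in dictionary: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  pat <- stats::setNames(motifs$iupac, motifs$name)[wanted]
  if (any(rowSums(t(t(motif_counts) * (nchar(pat) + 1L))) > promoter_len))
    stop("requested counts do not fit in the promoter length",
         call. = FALSE)
  records <- list(); truth <- list()
  for (g in genes) {
    counts_g <- stats::setNames(as.integer(motif_counts[g, ]),
                                colnames(motif_counts))
    res <- with_seed(sub_seed(seed, paste0("prom:", g)),
                     .plant_one(g, counts_g, pat, promoter_len))
    records[[g]] <- res$record
    truth[[g]] <- res$truth
  }
  list(records = records, truth = do.call(rbind, truth))
}

.plant_one <- function(gene, counts, pat, promoter_len, max_tries = 200L) {
  scan_counts <- function(seq_chr) {
    subject <- Biostrings::DNAString(seq_chr)
    vapply(pat, function(p)
      length(Biostrings::matchPattern(p, subject, fixed = "subject")), 0L)
  }
  for (try in seq_len(max_tries)) {
    bg <- paste(sample(.bases, promoter_len, replace = TRUE),
                collapse = "")
    # destroy chance background matches of every listed motif
    for (rep in 1:20) {
      subject <- Biostrings::DNAString(bg)
      dirty <- FALSE
      for (m in names(pat)) {
        hits <- Biostrings::matchPattern(pat[[m]], subject,
                                         fixed = "subject")
        for (h in seq_along(hits)) {
          st <- Biostrings::start(hits)[h]
          chars <- strsplit(pat[[m]], "")[[1]]
          fix <- which(vapply(chars,
                              function(ch) length(.iupac_match(ch)) < 4L,
                              TRUE))[1]
          off <- setdiff(.bases, .iupac_match(chars[fix]))
          substr(bg, st + fix - 1L, st + fix - 1L) <- sample(off, 1L)
          dirty <- TRUE
        }
        if (dirty) break
      }
      if (!dirty) break
    }
    # plant at non-overlapping random positions
    occupied <- integer(0)
    placed <- list()
    ok <- TRUE
    for (m in names(pat)) {
      k <- counts[[m]]
      if (k == 0L) next
      inst_len <- nchar(pat[[m]])
      for (i in seq_len(k)) {
        cand <- setdiff(seq_len(promoter_len - inst_len + 1L), occupied)
        cand <- cand[vapply(cand, function(st)
          !any((st:(st + inst_len - 1L)) %in% occupied), TRUE)]
        if (!length(cand)) { ok <- FALSE; break }
        st <- sample(cand, 1L)
        inst <- .instantiate_iupac(pat[[m]])
        substr(bg, st, st + inst_len - 1L) <- inst
        occupied <- c(occupied, st:(st + inst_len - 1L))
        placed[[length(placed) + 1L]] <-
          data.frame(gene = gene, motif = m, start = st, planted = inst,
                     stringsAsFactors = FALSE)
      }
      if (!ok) break
    }
    if (!ok) next
    got <- scan_counts(bg)
    want <- vapply(names(pat), function(m) as.integer(counts[[m]]), 0L)
    if (all(got == want)) {
      truth <- if (length(placed)) do.call(rbind, placed)
               else data.frame(gene = character(), motif = character(),
                               start = integer(), planted = character(),
                               stringsAsFactors = FALSE)
      return(list(record = seq_record(gene, bg, "dna"), truth = truth))
    }
  }
  stop("could not realize the requested planting for '", gene,
       "' within ", max_tries, " attempts", call. = FALSE)
}

#' Simulate a replicated qPCR Ct table with known fold changes
#'
#' `ct_target = base - log2(fold) + noise`, `ct_reference = base_ref +
#' noise`, Gaussian noise with standard deviation `sigma` per technical
#' measurement. The control time point carries fold 1.
#'
#' @param true_folds Data frame `gene`, `time_point`, `fold` (> 0). A
#'   control row (fold 1) is added per gene if absent.
#' @param sigma Noise standard deviation in Ct units (>= 0).
#' @param reps Replicates per cell.
#' @param seed Integer seed.
#' @param control_time Control time point.
#' @param base,base_ref Baseline Ct of target and reference genes.
#' @return List: `ct` (Ct table for [relative_expression()]), `truth`
#'   (the completed fold table).
#' @export
simulate_ct <- function(true_folds, sigma = 0.1, reps = 3L, seed = 1L,
                        control_time = 0, base = 25, base_ref = 20) {
  stopifnot(sigma >= 0, reps >= 1L, all(true_folds$fold > 0))
  for (g in unique(true_folds$gene))
    if (!any(true_folds$gene == g & true_folds$time_point == control_time))
      true_folds <- rbind(true_folds,
                          data.frame(gene = g, time_point = control_time,
                                     fold = 1))
  rows <- list()
  for (i in seq_len(nrow(true_folds))) {
    tf <- true_folds[i, ]
    noise <- with_seed(sub_seed(seed, paste("ct", tf$gene, tf$time_point)),
                       stats::rnorm(2L * reps, 0, sigma))
    rows[[i]] <- data.frame(gene = tf$gene, condition = "treatment",
                            time_point = tf$time_point,
                            replicate = seq_len(reps),
                            ct_target = base - log2(tf$fold) +
                              noise[seq_len(reps)],
                            ct_reference = base_ref +
                              noise[reps + seq_len(reps)],
                            stringsAsFactors = FALSE)
  }
  ct <- do.call(rbind, rows)
  ord <- order(ct$gene, ct$time_point, ct$replicate)
  list(ct = ct[ord, , drop = FALSE],
       truth = true_folds[order(true_folds$gene, true_folds$time_point), ,
                          drop = FALSE])
}
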