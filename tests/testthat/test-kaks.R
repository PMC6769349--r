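test_that("NG86 site counts match single-base-mutant enumeration", {
  expect_equal(ng86_sites("TTT"),
               c(syn_sites = 1 / 3, nonsyn_sites = 8 / 3))
  expect_equal(ng86_sites("ATG"), c(syn_sites = 0, nonsyn_sites = 3))
  for (codon in SENSE) {
    o <- oracle_sites(codon)
    s <- ng86_sites(codon)
    expect_equal(unname(s), unname(o), info = codon)
    expect_equal(sum(s), 3, info = codon)  # site conservation
  }
  expect_error(ng86_sites("TAA"), "sense codon")
  expect_error(ng86_sites("TNT"), "sense codon")
})

test_that("NG86 differences match pathway enumeration for every codon pair", {
  expect_equal(ng86_differences("TTT", "TTC"),
               c(syn_diffs = 1, nonsyn_diffs = 0))
  expect_equal(ng86_differences("TTT", "TTT"),
               c(syn_diffs = 0, nonsyn_diffs = 0))
  # a 2-difference pair averaged over both pathways, by hand:
  # TTT->GTT(F->V, nonsyn)->GTA(syn) and TTT->TTA(F->L, nonsyn)->GTA(L->V, nonsyn)
  expect_equal(ng86_differences("TTT", "GTA"),
               c(syn_diffs = 0.5, nonsyn_diffs = 1.5))
  set.seed(2)
  sample_pairs <- expand.grid(a = SENSE, b = SENSE,
                              stringsAsFactors = FALSE)
  sample_pairs <- sample_pairs[sample(nrow(sample_pairs), 400), ]
  for (r in seq_len(nrow(sample_pairs))) {
    ca <- sample_pairs$a[r]; cb <- sample_pairs$b[r]
    got <- ng86_differences(ca, cb)
    want <- oracle_diffs(ca, cb)
    expect_equal(unname(got), unname(want), info = paste(ca, cb))
    k <- sum(strsplit(ca, "")[[1]] != strsplit(cb, "")[[1]])
    if (!anyNA(got)) expect_equal(sum(got), k, info = paste(ca, cb))
  }
})

test_that("Jukes-Cantor correction is exact, monotone and saturates", {
  expect_equal(jukes_cantor(0), 0)
  expect_true(is.na(jukes_cantor(0.75)))
  expect_true(attr(jukes_cantor(0.76), "saturated"))
  expect_equal(jukes_cantor(0.1), -0.75 * log(1 - 0.4 / 3))
  grid <- seq(0, 0.74, by = 0.01)
  vals <- vapply(grid, jukes_cantor, 0)
  expect_true(all(diff(vals) > 0))
  expect_true(all(vals >= grid))
  expect_true(is.na(jukes_cantor(1.4)))  # pathway proportions can pass 1
  expect_error(jukes_cantor(-0.1), "nonnegative")
})

test_that("back-translation maps protein columns onto codons", {
  p <- sim_params(n_codons = 40, seed = 14)
  cds <- simulate_cds(p, "a")
  same <- align_cds_pair(cds, seq_record("b", cds$residues, "dna"))
  expect_equal(same$n_codons, nchar(cds$residues) / 3 - 1)
  expect_false(any(same$codons_a == "---"))

  # one extra codon in b produces exactly one gap triple in a's row
  ins <- paste0(substr(cds$residues, 1, 60), "GCT",
                substr(cds$residues, 61, nchar(cds$residues)))
  with_ins <- align_cds_pair(cds, seq_record("b", ins, "dna"))
  expect_equal(sum(with_ins$codons_a == "---"), 1L)
  expect_equal(sum(with_ins$codons_b == "---"), 0L)

  # round trip: translating the codon rows reproduces the protein rows
  pr_a <- translate_orf(cds, strict_start = "silent")$residues
  got_a <- paste(vapply(with_ins$codons_a[with_ins$codons_a != "---"],
                        function(cd) Biostrings::GENETIC_CODE[[cd]], ""),
                 collapse = "")
  expect_equal(got_a, pr_a)

  # discordant CDS is rejected with the position named
  wrong <- seq_record("b", paste0("ATGGGG", substr(cds$residues, 7,
                                                   nchar(cds$residues))),
                      "dna")
  pa <- protein_pdistance(translate_orf(cds, strict_start = "silent"),
                          translate_orf(cds, strict_start = "silent"))
  expect_error(backtranslate_alignment(pa, cds, wrong),
               "discordant residue position")
})

test_that("kaks equals the composed brute-force oracle and is symmetric", {
  aln <- codon_alignment("a", "b", c("TTT", "ATG"), c("TTC", "ATG"))
  res <- kaks(aln)
  ora <- oracle_kaks(c("TTT", "ATG"), c("TTC", "ATG"))
  expect_equal(res$ks, ora$ks)
  expect_equal(res$ka, ora$ka)
  expect_equal(res$s_sites, ora$s_sites)
  expect_equal(res$s_sites + res$n_sites, 3 * res$n_counted)

  set.seed(77)
  ca <- sample(SENSE, 30, TRUE); cb <- sample(SENSE, 30, TRUE)
  res <- kaks(codon_alignment("a", "b", ca, cb))
  ora <- oracle_kaks(ca, cb)
  expect_equal(res$ka, ora$ka)
  expect_equal(res$ks, ora$ks)
  flipped <- kaks(codon_alignment("b", "a", cb, ca))
  expect_equal(flipped$ka, res$ka)
  expect_equal(flipped$ks, res$ks)

  ident <- kaks(codon_alignment("a", "b", ca, ca))
  expect_equal(c(ident$ka, ident$ks), c(0, 0))
  expect_true(is.na(ident$ratio))  # undefined at Ks = 0, never infinity
})

test_that("sliding windows tile the ungapped alignment on codon boundaries", {
  p <- sim_params(omega = 0.3, target_ks = 0.3, n_codons = 100, seed = 25)
  anc <- simulate_cds(p, "anc")
  pr <- evolve_pair(anc, p)
  aln <- align_cds_pair(pr$a, pr$b)  # 100 counted codons = 300 bp
  prof <- sliding_window_kaks(aln, window_len = 150L, step = 9L)
  expect_equal(nrow(prof), floor((300 - 150) / 9) + 1)  # 17 windows
  expect_equal(prof$start_bp, seq(0L, 144L, by = 9L))
  expect_true(all(prof$start_bp %% 3 == 0))  # codons never split
  expect_equal(prof$midpoint_bp, prof$start_bp + 75)
  # windows scatter around the global estimate (sign test, homogeneous pair)
  glob <- kaks(aln)
  valid <- prof$ratio[!is.na(prof$ratio)]
  expect_gt(sum(valid > glob$ratio), 0)
  expect_gt(sum(valid < glob$ratio), 0)
  short <- codon_alignment("a", "b", c("ATG", "TTT"), c("ATG", "TTC"))
  expect_warning(out <- sliding_window_kaks(short), "shorter than one")
  expect_equal(nrow(out), 0L)
})

test_that("divergence dating applies T = Ks / 2 lambda in Mya", {
  expect_equal(divergence_time(0.15242, 6.5e-9)$t_mya, 11.72461538,
               tolerance = 1e-8)
  expect_equal(divergence_time(0.09334, 6.5e-9)$t_mya, 7.18,
               tolerance = 1e-6)
  expect_equal(divergence_time(0)$t_mya, 0)
  expect_error(divergence_time(-0.1), "negative")
})

test_that("selection classes follow the Ka/Ks = 1 partition", {
  expect_equal(classify_selection(0.086), "purifying")
  expect_equal(classify_selection(1.0), "neutral")
  expect_equal(classify_selection(1.2), "positive")
  expect_equal(classify_selection(NA_real_), "undetermined")
  expect_equal(classify_selection(c(0.5, 1, 2)),
               c("purifying", "neutral", "positive"))
})
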