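test_that("ORF translation obeys the length relation and stop rules", {
  expect_equal(translate_orf(seq_record("m", "ATGTAA", "dna"))$residues,
               "M")
  # protein length = ORF/3 - 1 for simulated ORFs of assorted sizes
  for (n in c(10L, 170L, 551L)) {
    cds <- simulate_cds(sim_params(n_codons = n, seed = n), "x")
    prot <- translate_orf(cds)
    expect_equal(nchar(cds$residues), 3L * (n + 1L))
    expect_equal(nchar(prot$residues), nchar(cds$residues) / 3 - 1)
  }
  expect_error(translate_orf(seq_record("b", "ATGAAAA", "dna")),
               "divisible by 3")
  expect_error(translate_orf(seq_record("b", "ATGTAACCCTAA", "dna")),
               "internal stop codon at codon 2")
  expect_error(translate_orf(seq_record("b", "ATGAAACCC", "dna")),
               "stop codon")
  expect_warning(translate_orf(seq_record("b", "TTGAAATAA", "dna")),
                 "does not start with ATG")
  expect_error(translate_orf(seq_record("b", "TTGAAATAA", "dna"),
                             strict_start = "error"), "ATG")
  expect_silent(translate_orf(seq_record("b", "TTGAAATAA", "dna"),
                              strict_start = "silent"))
})

test_that("published ORF and protein lengths satisfy the ORF/3 - 1 relation", {
  tab <- read_tsv(system.file("extdata", "bamboo_family_table.tsv",
                              package = "grfevol"))
  expect_equal(tab$orf_length / 3 - 1, tab$protein_length)
  expect_equal(range(tab$protein_length), c(170, 551))
  # the column mean of the published MW values, recomputed (the quoted
  # family-average of 39,250.5 Da does not match its own column)
  expect_equal(mean(tab$mol_wt), 39182.58, tolerance = 1e-6)
  expect_gt(abs(mean(tab$mol_wt) - 39250.5), 50)
})

test_that("domain scanning reproduces plantings exactly", {
  pats <- load_domain_patterns()
  set.seed(21)
  # backgrounds free of Q (and W/H for WRC) cannot fake the cores
  qlq_inst <- function() paste0("Q", strrep("A", sample(2:4, 1)), "L",
                                strrep("A", sample(2:4, 1)), "Q")
  with_q <- lapply(1:100, function(i) {
    bg <- random_protein(paste0("p", i), 120, exclude = c("Q"))
    at <- sample(20:80, 1)
    seq_record(bg$id, paste0(substr(bg$residues, 1, at), qlq_inst(),
                             substr(bg$residues, at + 1, 120)), "protein")
  })
  without_q <- lapply(1:100, function(i)
    random_protein(paste0("n", i), 120, exclude = c("Q")))
  hits_with <- vapply(with_q, function(p) nrow(scan_domain(p, pats$QLQ)),
                      0L)
  hits_without <- vapply(without_q,
                         function(p) nrow(scan_domain(p, pats$QLQ)), 0L)
  expect_true(all(hits_with >= 1L))
  expect_true(all(hits_without == 0L))

  wrc_inst <- "WRCAAAAAACAAAAAAAACAAH"  # gaps 6, 8, 2 within bounds
  bg <- random_protein("w", 60, exclude = c("W", "C", "H"))
  planted <- seq_record("w", paste0(substr(bg$residues, 1, 30), wrc_inst,
                                    substr(bg$residues, 31, 60)), "protein")
  hit <- scan_domain(planted, pats$WRC)
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$start, 31L)
  expect_equal(hit$matched_span, wrc_inst)

  expect_equal(nrow(scan_domain(seq_record("a", strrep("A", 50), "protein"),
                                pats$WRC)), 0L)
  expect_error(scan_domain(seq_record("d", "ACGT", "dna"), pats$QLQ),
               "protein")
  # FFD tolerates one substitution but not two
  ffd_bg <- function(s) seq_record("f", paste0("AAAA", s, "AAAA"), "protein")
  expect_equal(nrow(scan_domain(ffd_bg("FFD"), pats$FFD)), 1L)
  expect_equal(nrow(scan_domain(ffd_bg("FAD"), pats$FFD)), 1L)
  expect_equal(nrow(scan_domain(ffd_bg("AAD"), pats$FFD)), 0L)
})

test_that("membership requires both QLQ and WRC", {
  pats <- load_domain_patterns()
  set.seed(5)
  bg <- random_protein("x", 80, exclude = c("Q", "W", "C", "H"))
  qlq <- "QAALAAQ"
  wrc <- "WRCAAAAAACAAAAAAAACAAH"
  both <- seq_record("b", paste0(bg$residues, qlq, "AAAA", wrc), "protein")
  qlq_only <- seq_record("q", paste0(bg$residues, qlq), "protein")
  none <- bg
  expect_true(classify_member(both, pats)$member)
  expect_false(classify_member(qlq_only, pats)$member)
  expect_false(classify_member(none, pats)$member)
  expect_equal(nrow(classify_member(none, pats)$hits), 0L)
})

test_that("molecular weight follows the bundled mass table and is additive", {
  masses <- read_tsv(system.file("extdata", "aa_masses.tsv",
                                 package = "grfevol"))
  g <- physicochemical_stats(seq_record("g", "G", "protein"))
  expect_equal(g$mol_wt, masses$mass[masses$residue == "G"] + 18.01524)
  set.seed(9)
  for (i in 1:20) {
    a <- random_protein("a", sample(3:40, 1))
    b <- random_protein("b", sample(3:40, 1))
    ab <- seq_record("ab", paste0(a$residues, b$residues), "protein")
    expect_equal(physicochemical_stats(ab)$mol_wt,
                 physicochemical_stats(a)$mol_wt +
                   physicochemical_stats(b)$mol_wt - 18.01524,
                 tolerance = 1e-10)
  }
  expect_error(physicochemical_stats(seq_record("x", "AXA", "protein")),
               "outside the 20-letter")
})

test_that("isoelectric point matches the fine-grid charge-scan oracle", {
  st <- physicochemical_stats(seq_record("aaa", "AAA", "protein"))
  expect_equal(st$pi, oracle_pi_grid("AAA"), tolerance = 1e-3)
  expect_lt(abs(peptide_charge("AAA", st$pi)), 1e-4)
  set.seed(31)
  for (i in 1:100) {
    pep <- random_protein("p", sample(5:60, 1))
    st <- physicochemical_stats(pep)
    expect_gt(st$pi, 0); expect_lt(st$pi, 14)
    expect_equal(st$pi, oracle_pi_grid(pep$residues), tolerance = 1e-3)
    expect_lt(abs(peptide_charge(pep$residues, st$pi)), 1e-4)
  }
})

test_that("family table recomputes means from per-gene values", {
  prots <- list(a = seq_record("a", "MGG", "protein"),
                b = seq_record("b", "MRRRR", "protein"))
  ft <- family_table(prots)
  expect_equal(ft$means[["mol_wt"]], mean(ft$table$mol_wt))
  expect_equal(ft$means[["length"]], 4)
})
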