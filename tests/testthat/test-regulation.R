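test_that("promoter scanning finds planted motifs, overlaps included", {
  motifs <- load_motif_dictionary()
  # hand-planted CGTCA at three known positions in a neutral background
  bg <- strrep("A", 200)
  for (at in c(11L, 61L, 150L))
    substr(bg, at, at + 4L) <- "CGTCA"
  hits <- scan_promoter(seq_record("g1", bg, "dna"), motifs)
  cg <- hits[hits$motif == "CGTCA-motif", ]
  expect_equal(cg$start, c(11L, 61L, 150L))
  expect_equal(unique(cg$matched), "CGTCA")
  polyA <- scan_promoter(seq_record("g2", strrep("A", 300), "dna"), motifs)
  expect_false("TGACG-motif" %in% polyA$motif)
  expect_error(scan_promoter(seq_record("g3", "ACGTN", "dna")),
               "unambiguous")
  # overlapping occurrences are all reported
  two <- scan_promoter(seq_record("g4", paste0(strrep("T", 20), "ACGTGTG",
                                               strrep("T", 20)), "dna"),
                       data.frame(name = c("m1", "m2"),
                                  iupac = c("ACGTG", "GTGTG"),
                                  category = "hormone", subcategory = "x"))
  expect_equal(nrow(two), 2L)
  expect_equal(sort(two$start), c(21L, 23L))
})

test_that("hit counts are additive over segments except at the boundary", {
  set.seed(33)
  motifs <- data.frame(name = "ABRE", iupac = "ACGTG",
                       category = "hormone", subcategory = "ABA")
  left <- paste0(strrep("T", 50), "ACGTG", strrep("T", 43), "AC")
  right <- paste0("GTG", strrep("T", 47), "ACGTG", strrep("T", 45))
  whole <- paste0(left, right)  # junction spells ACGTG across the boundary
  n_whole <- nrow(scan_promoter(seq_record("w", whole, "dna"), motifs))
  n_parts <- nrow(scan_promoter(seq_record("l", left, "dna"), motifs)) +
    nrow(scan_promoter(seq_record("r", right, "dna"), motifs))
  expect_equal(n_whole, n_parts + 1L)  # exactly the boundary-spanning match
})

test_that("seventeen planted promoters reproduce their planting table", {
  wanted <- c("CGTCA-motif" = 3L, "TGACG-motif" = 2L, "ABRE" = 2L,
              "GARE-motif" = 1L, "Skn-1_motif" = 2L)
  pl <- plant_promoters(sprintf("g%02d", 1:17), wanted, seed = 61)
  hits <- do.call(rbind, lapply(pl$records, scan_promoter))
  for (g in names(pl$records)) {
    for (m in names(wanted)) {
      got <- sum(hits$gene_id == g & hits$motif == m)
      expect_equal(got, unname(wanted[m]), info = paste(g, m))
    }
  }
  # recorded positions are exactly the scanned positions
  key <- function(d) sort(paste(d$gene, d$motif, d$start))
  listed <- hits[hits$motif %in% names(wanted), ]
  expect_equal(key(data.frame(gene = listed$gene_id, motif = listed$motif,
                              start = listed$start)), key(pl$truth))
  expect_equal(unique(nchar(record_strings(pl$records))), 2000L)
})

test_that("category summary computes per-category shares", {
  motifs <- load_motif_dictionary()
  single <- data.frame(gene_id = "g", motif = "CAT-box", start = 1,
                       matched = "GCCACT")
  cs <- category_summary(single, motifs)
  expect_equal(cs$per_motif$share[cs$per_motif$motif == "CAT-box"], 1)
  # hit table engineered to the published hormone split: the two
  # MeJA motifs appear 82 times among 147 hormone-element hits -> 56%
  mk <- function(motif, n) data.frame(gene_id = "g", motif = motif,
                                      start = seq_len(n), matched = "x")
  hits <- rbind(mk("CGTCA-motif", 41), mk("TGACG-motif", 41),
                mk("ABRE", 30), mk("GARE-motif", 20), mk("P-box", 15))
  cs <- category_summary(hits, motifs)
  meja <- cs$per_motif[cs$per_motif$subcategory == "MeJA", ]
  expect_equal(unique(meja$category_total), 147L)
  expect_equal(round(100 * sum(meja$share)), 56)
  empty <- category_summary(hits[0, ], motifs)
  expect_true(all(empty$per_motif$count == 0))
  expect_true(all(is.finite(empty$per_motif$share)))
})

test_that("relative expression follows 2^-ddCt with fold 1 at the control", {
  ct <- expand.grid(gene = "g1", time_point = c(0, 6),
                    replicate = 1:3, stringsAsFactors = FALSE)
  ct$ct_target <- ifelse(ct$time_point == 0, 25, 24)  # ddCt = -1
  ct$ct_reference <- 20
  fc <- relative_expression(ct, control_time = 0)
  expect_equal(fc$fold_change[fc$time_point == 0], 1)
  expect_equal(fc$fold_change[fc$time_point == 6], 2)
  # treatment identical to control
  ct$ct_target <- 25
  expect_equal(relative_expression(ct)$fold_change, c(1, 1))
  # reference-gene normalization: shifting every Ct of one time point by a
  # constant (a pipetting/plate effect) leaves fold changes unchanged
  ct$ct_target <- ifelse(ct$time_point == 0, 25, 23.3)
  base <- relative_expression(ct)
  shifted <- ct
  shift <- ifelse(shifted$time_point == 6, 1.7, 0)
  shifted$ct_target <- shifted$ct_target + shift
  shifted$ct_reference <- shifted$ct_reference + shift
  expect_equal(relative_expression(shifted)$fold_change, base$fold_change)
  expect_error(relative_expression(ct[ct$time_point != 0, ]),
               "no control time point")
})

test_that("significance stars follow the p < 0.05 / p < 0.01 rule", {
  mk <- function(dct0, dct6) {
    data.frame(gene = "g", time_point = rep(c(0, 6), each = 3),
               replicate = rep(1:3, 2), ct_target = 20 + c(dct0, dct6),
               ct_reference = 20)
  }
  same <- significance(mk(c(1, 1.1, 0.9), c(1, 1.1, 0.9)))
  expect_gt(same$p_value, 0.9)
  expect_equal(same$stars, "")
  far <- significance(mk(c(1, 1.1, 0.9), c(11, 11.1, 10.9)))  # ~100 sd away
  expect_lt(far$p_value, 0.01)
  expect_equal(far$stars, "**")
  # star band boundaries checked against the t-test p-value directly
  mid <- mk(c(1, 1.2, 0.8), c(1.5, 1.7, 1.3))
  p <- stats::t.test(c(1.5, 1.7, 1.3), c(1, 1.2, 0.8))$p.value
  got <- significance(mid)
  expect_equal(got$p_value, p)
  expect_equal(got$stars,
               if (p < 0.01) "**" else if (p < 0.05) "*" else "")
  one_rep <- mk(c(1, 1, 1), c(2, 2, 2))[c(1:3, 4), ]
  flagged <- significance(one_rep)
  expect_true(flagged$flagged)
  expect_equal(flagged$stars, "")
})

test_that("expression clustering recovers planted blocks deterministically", {
  set.seed(8)
  block <- function(center, genes) {
    t(vapply(genes, function(g) center + stats::rnorm(5, 0, 0.05),
             numeric(5)))
  }
  up <- c(1, 2, 3, 4, 5); down <- rev(up)
  mat <- rbind(block(up, paste0("u", 1:4)), block(down, paste0("d", 1:4)))
  cl <- cluster_expression(mat)
  ord <- cl$order
  first_half <- ord[1:4]
  expect_true(all(startsWith(first_half, "u")) ||
                all(startsWith(first_half, "d")))
  groups <- stats::cutree(cl$hclust, k = 2)
  expect_equal(adjusted_rand(groups, substr(names(groups), 1, 1)), 1)
  # identical rows merge first at height zero
  mat2 <- rbind(mat, u1b = mat["u1", ])
  cl2 <- cluster_expression(mat2)
  expect_equal(min(cl2$merge_heights), 0)
  pair <- cl2$hclust$labels[-cl2$hclust$merge[1, ]]
  expect_setequal(pair, c("u1", "u1b"))
  # input row order cannot change the result
  perm <- sample(nrow(mat))
  expect_equal(cluster_expression(mat[perm, ])$order, cl$order)
  # constant rows are flagged and placed last
  mat3 <- rbind(mat, flat = rep(1, 5))
  cl3 <- cluster_expression(mat3)
  expect_equal(cl3$flagged, "flat")
  expect_equal(utils::tail(cl3$order, 1), "flat")
})
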