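test_that("G4 association uses interval plus strand-aware 100 bp upstream", {
  # spec examples are 0-based half-open; translated through bed_to_gr
  prom_plus <- bed_to_gr("chr1", 1000L, 1200L, "+")
  prom_plus$id <- "p1"
  expect_true(associate_g4(prom_plus,
                           list(k = bed_to_gr("chr1", 950L, 1010L)))$assoc_k)
  # upstream window is [900, 1000): a peak ending at 900 does not touch it
  expect_false(associate_g4(prom_plus,
                            list(k = bed_to_gr("chr1", 890L, 900L)))$assoc_k)
  expect_true(associate_g4(prom_plus,
                           list(k = bed_to_gr("chr1", 899L, 901L)))$assoc_k)
  # minus-strand promoter: upstream is rightward
  prom_minus <- bed_to_gr("chr1", 1000L, 1200L, "-")
  prom_minus$id <- "p2"
  expect_true(associate_g4(prom_minus,
                           list(k = bed_to_gr("chr1", 1250L, 1260L)))$assoc_k)
  expect_false(associate_g4(prom_minus,
                            list(k = bed_to_gr("chr1", 1301L, 1320L)))$assoc_k)
  # strand-naive mode extends leftward regardless
  expect_false(associate_g4(prom_minus,
                            list(k = bed_to_gr("chr1", 950L, 990L)))$assoc_k)
  expect_true(associate_g4(prom_minus,
                           list(k = bed_to_gr("chr1", 950L, 990L)),
                           strand_aware = FALSE)$assoc_k)
  expect_error(associate_g4(prom_plus, list(k = prom_plus), upstream = -1),
               "non-negative")
})

test_that("association categories and peak-splitting invariance", {
  prom <- bed_to_gr(rep("chr1", 3), c(0L, 5000L, 10000L),
                    c(200L, 5200L, 10200L), "+")
  prom$id <- c("a", "b", "c")
  pk_k <- bed_to_gr("chr1", c(100L, 5100L), c(130L, 5130L))
  pk_h <- bed_to_gr("chr1", 100L, 130L)
  out <- associate_g4(prom, list(K = pk_k, H = pk_h))
  expect_identical(out$category, c("both", "one", "neither"))
  # splitting a peak into two abutting peaks changes nothing
  pk_split <- bed_to_gr("chr1", c(100L, 115L, 5100L), c(115L, 130L, 5130L))
  out2 <- associate_g4(prom, list(K = pk_split, H = pk_h))
  expect_identical(out2$category, out$category)
  # peak file order irrelevant
  out3 <- associate_g4(prom, list(K = rev(pk_k), H = pk_h))
  expect_identical(out3$category, out$category)
})

test_that("category enrichment matches exact enumeration oracles", {
  # identical distributions: p = 1, ratios 1
  ap <- c(rep("neither", 5), rep("one", 3), rep("both", 2))
  bg <- c(ap, ap)
  enr <- category_enrichment(ap, bg)
  expect_equal(enr$fisher_p, 1)
  expect_equal(enr$ratios, c(1, 1, 1))
  # 2x2 sub-table [[8,2],[1,5]] against hypergeometric enumeration
  ap2 <- c(rep("neither", 8), rep("one", 2))
  bg2 <- c(ap2, rep("neither", 1), rep("one", 5))
  enr2 <- category_enrichment(ap2, bg2)
  expect_equal(enr2$fisher_p,
               oracle_fisher_exact(rbind(c(8, 2), c(1, 5))), tolerance = 1e-9)
  # full 2x3 enumeration on random small tables (margins <= 12)
  set.seed(31)
  for (rep in 1:15) {
    tab <- matrix(rpois(6, 3), 2, 3)
    if (any(rowSums(tab) == 0) || sum(colSums(tab) > 0) < 2) next
    cats <- c("neither", "one", "both")
    ap_v <- rep(cats, tab[1, ])
    bg_v <- c(ap_v, rep(cats, tab[2, ]))
    got <- category_enrichment(ap_v, bg_v)
    expect_equal(got$fisher_p, oracle_fisher_exact(tab), tolerance = 1e-7)
  }
  # extreme separation on a 20-promoter toy
  ap3 <- rep("neither", 5)
  bg3 <- c(ap3, rep("both", 15))
  enr3 <- category_enrichment(ap3, bg3)
  expect_equal(enr3$fisher_p,
               oracle_fisher_exact(rbind(c(5, 0), c(0, 15))), tolerance = 1e-9)
  expect_gt(enr3$ratios[1], 1)
  expect_lt(enr3$fisher_p, 1e-3)
})

test_that("relative density is a bounded coverage fraction", {
  prom <- bed_to_gr(rep("chr1", 2), c(10000L, 30000L), c(10500L, 30400L),
                    c("+", "-"))
  # saturation: G4 covering everything -> all windows 1
  allg4 <- bed_to_gr("chr1", 0L, 50000L)
  d <- relative_density(prom, allg4, flank = 100, target_width = 200)
  expect_true(all(abs(d$values - 1) < 1e-12))
  expect_equal(d$N, (2 * 100 + 200) / 10)
  # no G4 -> all zero
  d0 <- relative_density(prom, GenomicRanges::GRanges(), flank = 100,
                         target_width = 200)
  expect_true(all(d0$values == 0))
  # one region fully covered, one empty -> 0.5 everywhere
  oneg4 <- bed_to_gr("chr1", 9000L, 11000L)
  d5 <- relative_density(prom[1:2], oneg4, flank = 100, target_width = 200)
  expect_true(all(abs(d5$values - 0.5) < 1e-12))
  expect_error(relative_density(prom, allg4, flank = 105), "multiple")
})

test_that("density profiles are M-weighted additive over disjoint sets", {
  set.seed(41)
  mk <- function(n, chrom) {
    st <- sort(sample(seq(5000, 200000, by = 700), n))
    gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(st, st + sample(200:600, n, TRUE)),
                                 strand = sample(c("+", "-"), n, TRUE))
    gr
  }
  g4 <- mk(150, "chr1")
  GenomicRanges::strand(g4) <- "*"
  a <- mk(7, "chr1"); b <- mk(11, "chr1")
  da <- relative_density(a, g4, flank = 200, target_width = 300)
  db <- relative_density(b, g4, flank = 200, target_width = 300)
  dab <- relative_density(c(a, b), g4, flank = 200, target_width = 300)
  expect_equal(dab$values,
               (da$M * da$values + db$M * db$values) / (da$M + db$M),
               tolerance = 1e-12)
  expect_true(all(dab$values >= 0 & dab$values <= 1))
  # literal printed denominator (width x N) is exposed but not a fraction
  dn <- relative_density(a, g4, flank = 200, target_width = 300,
                         denominator = "N")
  expect_equal(dn$values * dn$N, da$values * da$M, tolerance = 1e-12)
})

test_that("promoter signal means and rank-sum comparisons", {
  prom <- bed_to_gr(rep("chr1", 2), c(100L, 400L), c(200L, 500L), "+")
  prom$id <- c("a", "b")
  const <- bed_to_gr("chr1", 0L, 1000L)
  const$score <- 7
  out <- signal_at_promoters(prom, list(K = const))
  expect_equal(out$mean_K, c(7, 7))
  # partial coverage: base-weighted mean with missing bases = 0
  half <- bed_to_gr("chr1", 100L, 150L)
  half$score <- 4
  out2 <- signal_at_promoters(prom, list(K = half))
  expect_equal(out2$mean_K, c(2, 0))
  # two tracks give the condition-ordered delta
  t2 <- bed_to_gr("chr1", 0L, 1000L); t2$score <- 3
  out3 <- signal_at_promoters(prom, list(K = const, H = t2))
  expect_equal(out3$delta, c(4, 4))
  # missing contig warns and scores 0
  prom_m <- bed_to_gr("chrM", 0L, 10L, "+")
  expect_warning(o4 <- signal_at_promoters(prom_m, list(K = const)), "absent")
  expect_equal(o4$mean_K, 0)
  # exact one-tailed rank-sum oracle: {1,2} vs {3,4}, second greater
  expect_equal(compare_groups(c(3, 4), c(1, 2), "greater"), 1 / 6)
  expect_equal(oracle_ranksum_less(c(1, 2), c(3, 4)), 1 / 6)
  # no shift between groups: p well away from significance
  set.seed(8)
  x <- rnorm(40); y <- rnorm(40)
  p <- compare_groups(x, y, "greater")
  expect_gt(p, 0.05); expect_lt(p, 0.95)
})

test_that("directionality patterns follow the per-AP effect rules", {
  mk <- function(gene, dir, aK, aH)
    data.frame(gene_id = gene, direction = dir, assoc_K = aK, assoc_H = aH,
               stringsAsFactors = FALSE)
  # one AP up in K, G4 in K only -> promotes
  expect_equal(classify_directionality(mk("g1", "up_K", TRUE, FALSE))$pattern,
               "promotes")
  # one AP up in K, G4 in H only -> represses
  expect_equal(classify_directionality(mk("g2", "up_K", FALSE, TRUE))$pattern,
               "represses")
  # G4 in both conditions: neutral -> mixed (no non-neutral evidence)
  expect_equal(classify_directionality(mk("g3", "up_K", TRUE, TRUE))$pattern,
               "mixed")
  # AP1 up in K with K-only G4, AP2 up in H with H-only G4 -> bidirectional
  tab <- rbind(mk("g4", "up_K", TRUE, FALSE), mk("g4", "up_H", FALSE, TRUE))
  expect_equal(classify_directionality(tab)$pattern, "bidirectional_promotes")
  tab2 <- rbind(mk("g5", "up_K", FALSE, TRUE), mk("g5", "up_H", TRUE, FALSE))
  expect_equal(classify_directionality(tab2)$pattern,
               "bidirectional_represses")
  # promoting and repressing in the same gene -> mixed
  tab3 <- rbind(mk("g6", "up_K", TRUE, FALSE), mk("g6", "up_K", FALSE, TRUE))
  expect_equal(classify_directionality(tab3)$pattern, "mixed")
})
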