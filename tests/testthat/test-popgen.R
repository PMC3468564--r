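test_that("complete allele profiles type unambiguously", {
  tab <- m003_variant_sites()
  for (allele in c("H", "C1", "C2")) {
    prof <- setNames(tab[[paste0("state_", allele)]], tab$site_id)
    expect_identical(as.character(call_allele(prof, tab)), allele)
  }
})

test_that("partial haplotypes follow the splice-site and subtype votes", {
  tab <- m003_variant_sites()
  expect_identical(
    as.character(call_allele(c(rs1667354 = "A", rs1667366 = "T", rs935707 = "G"), tab)),
    "H")
  expect_identical(
    as.character(call_allele(c(rs1667354 = "G", rs16971886 = "A", rs3745770 = "G"), tab)),
    "C2")
  # C lineage with no subtype-discriminating site stays at the C label
  expect_identical(
    as.character(call_allele(c(rs1667354 = "G", rs935706 = "A"), tab)), "C")
})

test_that("contradictory profiles are demoted to unknown with a report", {
  tab <- m003_variant_sites()
  # A at rs1667354 says H, but A at rs935706 is the C-lineage state
  res <- call_allele(c(rs1667354 = "A", rs935706 = "A"), tab)
  expect_identical(as.character(res), "unknown")
  expect_true("rs935706" %in% attr(res, "conflicts"))
  # a state matching no allele at all
  res2 <- call_allele(c(rs1667354 = "C"), tab)
  expect_identical(as.character(res2), "unknown")
})

test_that("gene counting reproduces hand and enumeration results", {
  p <- allele_frequencies(c(HH = 653, HC = 490, CC = 101))
  expect_equal(unname(p["H"]), (2 * 653 + 490) / (2 * 1244), tolerance = 1e-12)
  expect_equal(round(unname(p["H"]), 2), 0.72)
  expect_equal(unname(allele_frequencies(c(HH = 10, HC = 0, CC = 0))["H"]), 1)
  # six-class counts against explicit allele-copy enumeration
  counts <- c(HH = 1, HC1 = 2, HC2 = 0, C1C1 = 1, C1C2 = 0, C2C2 = 0)
  copies <- c(rep("H", 2 * 1 + 2 + 0), rep("C1", 2 * 1 + 2 + 0), rep("C2", 0))
  p6 <- allele_frequencies(counts)
  expect_equal(unname(p6["H"]), mean(copies == "H"), tolerance = 1e-12)
  expect_equal(unname(p6["C1"]), mean(copies == "C1"), tolerance = 1e-12)
  expect_error(allele_frequencies(c(HH = 0, HC = 0, CC = 0)), "no individuals")
})

test_that("Hardy-Weinberg expectations match the closed form", {
  e <- hwe_expected(c(H = 0.72, C1 = 0.17, C2 = 0.11))
  expect_equal(unname(e["HH"]), 0.5184, tolerance = 1e-9)
  expect_equal(round(unname(e["HH"]), 2), 0.52)
  e2 <- hwe_expected(c(H = 0.39, C1 = 0.27, C2 = 0.34))
  expect_equal(round(unname(e2["HC2"]), 2), 0.27)
  e3 <- hwe_expected(c(H = 1, C1 = 0, C2 = 0))
  expect_identical(unname(e3["HH"]), 1)
  expect_identical(sum(e3[-1]), 0)
  set.seed(19)
  for (i in 1:20) {
    f <- rexp(3); f <- f / sum(f)
    expect_equal(sum(hwe_expected(setNames(f, c("H", "C1", "C2")))), 1,
                 tolerance = 1e-15)
  }
})

test_that("chi-square test matches a hand two-allele computation", {
  # perfect fit: expected counts are exactly observed
  exact <- c(HH = 49, HC1 = 28, HC2 = 14, C1C1 = 4, C1C2 = 4, C2C2 = 1)
  res <- hwe_chisq(exact)
  expect_equal(res$chi_square, 0, tolerance = 1e-9)
  expect_equal(res$p_value, 1, tolerance = 1e-9)
  expect_identical(res$df, 3)
  # one allele absent: df collapses to the two-allele case
  two <- c(HH = 49, HC1 = 42, HC2 = 0, C1C1 = 9, C1C2 = 0, C2C2 = 0)
  res2 <- hwe_chisq(two)
  p <- (2 * 49 + 42) / 200
  expect_equal(unname(res2$allele_freqs["H"]), p, tolerance = 1e-12)
  exp2 <- 100 * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  chi_hand <- sum((c(49, 42, 9) - exp2)^2 / exp2)
  expect_equal(res2$chi_square, chi_hand, tolerance = 1e-9)
  expect_identical(res2$df, 1)
})

test_that("rare classes are pooled into an adjacent heterozygote class", {
  counts <- c(HH = 180, HC1 = 16, HC2 = 3, C1C1 = 0, C1C2 = 1, C2C2 = 0)
  res <- hwe_chisq(counts)
  expect_gt(length(res$pooled), 0)
  expect_true(is.finite(res$chi_square))
})

test_that("collapsing C1 and C2 conserves totals", {
  x <- c(HH = 1, HC1 = 2, HC2 = 3, C1C1 = 4, C1C2 = 5, C2C2 = 6)
  col <- collapse_C(x)
  expect_identical(unname(col), c(1, 5, 15))
  expect_identical(sum(col), sum(x))
  tw <- collapse_C(c(HH = 0.52, HC1 = 0.24, HC2 = 0.16,
                     C1C1 = 0.04, C1C2 = 0.03, C2C2 = 0.01))
  expect_equal(unname(tw), c(0.52, 0.40, 0.08), tolerance = 1e-12)
  expect_equal(sum(tw), 1, tolerance = 1e-12)
})

test_that("recomputed expectations agree with the published panels at 2 d.p.", {
  panels <- table2_panels()
  classes <- c("HH", "HC1", "HC2", "C1C1", "C1C2", "C2C2")
  for (r in seq_len(nrow(panels))) {
    e <- hwe_expected(c(H = panels$p_H[r], C1 = panels$p_C1[r], C2 = panels$p_C2[r]))
    printed <- as.numeric(panels[r, paste0("exp_", classes)])
    expect_lt(max(abs(unname(e[classes]) - printed)), 0.01)
  }
})

test_that("sampled panels recover their generating allele frequencies", {
  cfg <- pop_sim_config(n_individuals = 100000, seed = 14)
  g <- simulate_genotypes(cfg)
  counts <- table(factor(g, levels = c("HH", "HC1", "HC2", "C1C1", "C1C2", "C2C2")))
  p <- allele_frequencies(setNames(as.numeric(counts), names(counts)))
  expect_lt(max(abs(p - cfg$allele_freqs)), 0.01)
})
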