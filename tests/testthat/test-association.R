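test_that("relative size is a plain scale-invariant ratio", {
  expect_equal(relative_size(34, 50), 0.68)
  expect_equal(relative_size(7, 7), 1)
  expect_equal(relative_size(3 * 34, 3 * 50), relative_size(34, 50))
  expect_error(relative_size(34, 0), "positive")
})

test_that("identical groups compare with zero difference and p = 1", {
  rec <- tibble::tibble(
    genotype = rep(c("HH", "CC"), each = 3),
    relative_head_size = rep(c(0.66, 0.68, 0.70), 2))
  res <- group_compare(rec)
  expect_equal(res$pairs$estimate, 0)
  expect_equal(res$pairs$p_value, 1)
})

test_that("the Welch statistic matches a by-hand computation", {
  x <- c(0.70, 0.68, 0.71, 0.69)
  y <- c(0.66, 0.67, 0.65, 0.68)
  rec <- tibble::tibble(genotype = rep(c("CC", "HH"), each = 4),
                        relative_head_size = c(x, y))
  res <- group_compare(rec)
  se <- sqrt(var(x) / 4 + var(y) / 4)
  t_hand <- (mean(x) - mean(y)) / se
  df_hand <- se^4 / ((var(x) / 4)^2 / 3 + (var(y) / 4)^2 / 3)
  expect_equal(res$pairs$statistic, t_hand, tolerance = 1e-12)
  expect_equal(res$pairs$df, df_hand, tolerance = 1e-9)
  expect_error(group_compare(rec[c(1, 5:8), ]), "fewer than 2")
})

test_that("a planted dominant effect is detected with high power", {
  hits <- vapply(1:50, function(r) {
    cfg <- pop_sim_config(effect_cc = 0.01, noise_sd = 0.02, seed = 3000 + r)
    ph <- simulate_phenotypes(simulate_genotypes(cfg), cfg)
    if (length(unique(ph$genotype)) < 3) return(NA)
    gc <- group_compare(ph)
    cc_hh <- gc$pairs$p_value[gc$pairs$group1 == "CC" & gc$pairs$group2 == "HH"]
    av <- anova_sequential(ph)
    c(cc_hh < 0.05 && av$p_value[av$term == "genotype"] < 0.05)
  }, logical(1))
  expect_gte(mean(hits, na.rm = TRUE), 0.8)
})

test_that("sequential ANOVA conserves the corrected total sum of squares", {
  cfg <- pop_sim_config(seed = 31)
  ph <- simulate_phenotypes(simulate_genotypes(cfg), cfg)
  av <- anova_sequential(ph)
  total <- sum((ph$relative_head_size - mean(ph$relative_head_size))^2)
  expect_equal(sum(av$sum_sq), total, tolerance = 1e-9 * total)
  expect_identical(av$term, c("genotype", "gestation_weeks", "body_weight",
                              "sex", "Residuals"))
  expect_identical(av$df[1:4], rep(1L, 4))
  expect_identical(av$df[5], nrow(ph) - 5L)
  expect_true(all(av$sum_sq >= 0))
})

test_that("row order never changes the ANOVA", {
  cfg <- pop_sim_config(n_individuals = 400, seed = 32)
  ph <- simulate_phenotypes(simulate_genotypes(cfg), cfg)
  av1 <- anova_sequential(ph)
  av2 <- anova_sequential(ph[sample(nrow(ph)), ])
  expect_equal(av1$sum_sq, av2$sum_sq, tolerance = 1e-12)
})

test_that("sequential equals marginal decomposition on an orthogonal design", {
  # balanced 2x2x2x2 design: all regressors mutually orthogonal after centring
  grid <- expand.grid(g = 0:1, w = c(-1, 1), b = c(-1, 1), s = 0:1)
  set.seed(33)
  rec <- tibble::tibble(
    genotype = ifelse(grid$g == 1, "CC", "HH"),
    gestation_weeks = 39 + grid$w,
    body_weight = 3200 + 100 * grid$b,
    sex = ifelse(grid$s == 1, "male", "female"),
    relative_head_size = 0.68 + 0.01 * grid$g + 0.002 * grid$w +
      rnorm(nrow(grid), 0, 0.005))
  orders <- list(
    c("genotype", "gestation_weeks", "body_weight", "sex"),
    c("sex", "body_weight", "gestation_weeks", "genotype"))
  av_a <- anova_sequential(rec, orders[[1]])
  av_b <- anova_sequential(rec, orders[[2]])
  for (term in orders[[1]]) {
    expect_equal(av_a$sum_sq[av_a$term == term],
                 av_b$sum_sq[av_b$term == term], tolerance = 1e-9)
  }
})

test_that("constant covariates are reported as rank deficiency", {
  cfg <- pop_sim_config(n_individuals = 100, seed = 34)
  ph <- simulate_phenotypes(simulate_genotypes(cfg), cfg)
  ph$body_weight <- 3000
  expect_error(anova_sequential(ph), "body_weight")
})

test_that("correlation matches the textbook formula and its edge cases", {
  pts <- tibble::tibble(allele_frequency = c(0.72, 0.71, 0.45, 0.42, 0.39),
                        mean_relative_size = c(0.660, 0.662, 0.671, 0.673, 0.676))
  res <- cross_population_correlation(pts)
  x <- pts$allele_frequency; y <- pts$mean_relative_size
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(res$r, r_hand, tolerance = 1e-12)
  t_hand <- r_hand * sqrt(3 / (1 - r_hand^2))
  expect_equal(res$p_value, 2 * stats::pt(-abs(t_hand), 3), tolerance = 1e-12)
  # collinear points
  col <- tibble::tibble(allele_frequency = 1:4 / 10,
                        mean_relative_size = 0.6 + (1:4) / 100)
  expect_equal(cross_population_correlation(col)$r, 1, tolerance = 1e-12)
  expect_error(cross_population_correlation(col[1:2, ]), "at least 3")
  flat <- tibble::tibble(allele_frequency = c(0.1, 0.1, 0.1),
                         mean_relative_size = c(0.6, 0.7, 0.8))
  expect_error(cross_population_correlation(flat), "zero variance")
})
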