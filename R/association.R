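# Head-size association stage: the relative-head-size phenotype, pairwise
# genotype-group comparisons, the dominant-coded sequential ANOVA, and the
# cross-population allele-frequency/phenotype correlation.

#' Relative head size
#'
#' The size-corrected phenotype: head circumference divided by height (both
#' in the same units, so the ratio is dimensionless).
#'
#' @param numerator,denominator Positive reals (vectors recycle as usual).
#' @return `numerator / denominator`.
#' @export
relative_size <- function(numerator, denominator) {
  if (any(denominator <= 0)) abort("denominator must be positive")
  numerator / denominator
}

#' Pairwise genotype-group comparisons of relative head size
#'
#' Group means plus Welch two-sample t-tests (the default; `pooled = TRUE`
#' switches to the equal-variance test) for every genotype pair, reported
#' with unadjusted p-values.
#'
#' @param records Phenotype tibble with columns `relative_head_size` and a
#'   grouping column (default `genotype`).
#' @param group Name of the grouping column.
#' @param pooled Use the pooled-variance t-test instead of Welch.
#' @return List with `groups` (tibble of per-group n/mean/sd) and `pairs`
#'   (tibble of `group1`, `group2`, `estimate` = mean1 - mean2, `statistic`,
#'   `df`, `p_value`).
#' @export
group_compare <- function(records, group = "genotype", pooled = FALSE) {
  stopifnot("relative_head_size" %in% names(records), group %in% names(records))
  g <- as.character(records[[group]])
  y <- records$relative_head_size
  lv <- sort(unique(g))
  sizes <- table(g)
  if (length(lv) < 2) abort("need at least two genotype groups")
  if (any(sizes < 2)) {
    abort(sprintf("group(s) with fewer than 2 records: %s",
                  paste(names(sizes)[sizes < 2], collapse = ", ")))
  }
  groups <- tibble(group = lv,
                   n = as.integer(sizes[lv]),
                   mean = vapply(lv, function(l) mean(y[g == l]), numeric(1)),
                   sd = vapply(lv, function(l) stats::sd(y[g == l]), numeric(1)))
  pairs <- combn(lv, 2, simplify = FALSE) |>
    purrr::map(function(pr) {
      tt <- t.test(y[g == pr[1]], y[g == pr[2]], var.equal = pooled)
      tibble(group1 = pr[1], group2 = pr[2],
             estimate = unname(diff(rev(tt$estimate))),
             statistic = unname(tt$statistic),
             df = unname(tt$parameter),
             p_value = tt$p.value)
    }) |>
    bind_rows()
  list(groups = groups, pairs = pairs)
}

#' Sequential (Type I) ANOVA of relative head size with dominant coding
#'
#' Fits `relative_head_size ~ genotype_cc + gestation_weeks + body_weight +
#' sex` (in the given term order) by least squares and decomposes the
#' corrected total sum of squares sequentially. The genotype enters as a
#' single dominant-coded indicator `1[genotype == "CC"]` (CC against pooled
#' HC + HH), so every non-residual term has one degree of freedom.
#'
#' @param records Phenotype tibble with `relative_head_size`, `genotype`
#'   (collapsed HH/HC/CC), `gestation_weeks`, `body_weight`, `sex`.
#' @param term_order Character vector ordering the model terms; any subset
#'   of `c("genotype", "gestation_weeks", "body_weight", "sex")`.
#' @return Tibble of class `anova_table`: `term`, `df`, `sum_sq`, `mean_sq`,
#'   `f_value`, `p_value`, ending with the residual row.
#' @export
anova_sequential <- function(records,
                             term_order = c("genotype", "gestation_weeks",
                                            "body_weight", "sex")) {
  needed <- unique(c("relative_head_size", setdiff(term_order, "genotype"),
                     if ("genotype" %in% term_order) "genotype"))
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols) > 0) {
    abort(sprintf("missing column(s): %s", paste(missing_cols, collapse = ", ")))
  }
  dat <- records[stats::complete.cases(records[needed]), needed, drop = FALSE]
  model_terms <- ifelse(term_order == "genotype", "genotype_cc", term_order)
  if ("genotype" %in% term_order) {
    dat$genotype_cc <- as.integer(dat$genotype == "CC")
  }
  if ("sex" %in% term_order) dat$sex <- factor(dat$sex)
  for (tm in model_terms) {
    v <- dat[[tm]]
    if (length(unique(v)) < 2) {
      abort(sprintf("term '%s' is constant: design is rank deficient", tm))
    }
  }
  fml <- stats::as.formula(paste("relative_head_size ~",
                                 paste(model_terms, collapse = " + ")))
  fit <- lm(fml, data = dat)
  av <- anova(fit)
  labels <- c(setNames(term_order, model_terms), Residuals = "Residuals")
  out <- tibble(
    term = unname(labels[rownames(av)]),
    df = av$Df,
    sum_sq = av$`Sum Sq`,
    mean_sq = av$`Mean Sq`,
    f_value = av$`F value`,
    p_value = av$`Pr(>F)`
  )
  attr(out, "fit") <- fit
  class(out) <- c("anova_table", class(out))
  out
}

#' @exportS3Method generics::glance
glance.anova_table <- function(x, ...) {
  tibble(total_sum_sq = sum(x$sum_sq),
         residual_df = x$df[x$term == "Residuals"],
         n = sum(x$df) + 1)
}

#' Cross-population correlation of allele frequency and mean phenotype
#'
#' Pearson correlation of per-population allele frequency against the mean
#' relative head size, with the two-sided t-test p-value on n - 2 degrees of
#' freedom.
#'
#' @param points Tibble with columns `allele_frequency` and
#'   `mean_relative_size` (one row per population; at least 3).
#' @return Tibble: `r`, `p_value`, `n`.
#' @export
cross_population_correlation <- function(points) {
  stopifnot(all(c("allele_frequency", "mean_relative_size") %in% names(points)))
  if (nrow(points) < 3) abort("need at least 3 populations")
  if (stats::sd(points$allele_frequency) == 0 ||
      stats::sd(points$mean_relative_size) == 0) {
    abort("zero variance in one coordinate")
  }
  ct <- cor.test(points$allele_frequency, points$mean_relative_size,
                 method = "pearson")
  tibble(r = unname(ct$estimate), p_value = ct$p.value, n = nrow(points))
}

#' @exportS3Method ggplot2::autoplot
autoplot.anova_table <- function(object, ...) {
  dat <- object[object$term != "Residuals", ]
  ggplot2::ggplot(dat, ggplot2::aes(x = stats::reorder(.data$term, -.data$sum_sq),
                                    y = .data$sum_sq)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "Sequential sum of squares")
}

#' Genotype-group boxplot of relative head size
#'
#' @param records Phenotype tibble with `genotype` and `relative_head_size`.
#' @return A ggplot object.
#' @export
plot_group_sizes <- function(records) {
  ggplot2::ggplot(records, ggplot2::aes(x = .data$genotype,
                                        y = .data$relative_head_size)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::labs(x = "Genotype (C = C1 + C2 combined)",
                  y = "Head circumference / height")
}
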