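# Population-level simulators: Hardy-Weinberg genotype draws for the
# three-allele (H/C1/C2) system and phenotype tables with a planted dominant
# genotype effect on relative head size.

.alleles3 <- c("H", "C1", "C2")
.geno6 <- c("HH", "HC1", "HC2", "C1C1", "C1C2", "C2C2")
.geno3 <- c("HH", "HC", "CC")

#' Configuration for population and phenotype simulation
#'
#' Defaults emulate the study cohort: allele frequencies of the Taiwanese
#' panel (H 0.72, C1 0.17, C2 0.11), 1,244 newborns, a dominant CC shift of
#' +0.01 on the head-circumference/height ratio, residual noise SD 0.02, and
#' a gestation slope of 0.002 per week. Covariates are drawn as gestation ~
#' Normal(39, 1.5) weeks truncated to [30, 43], sex ~ Bernoulli(0.5), body
#' weight ~ Normal(3200, 400) g.
#'
#' @param allele_freqs Named numeric over `H`, `C1`, `C2`; sums to 1.
#' @param n_individuals Positive integer.
#' @param effect_cc Additive shift of relative head size for the CC genotype
#'   class (dominant coding), in ratio units.
#' @param noise_sd Residual Gaussian SD of the ratio (> 0).
#' @param gestation_effect Slope of the ratio per gestation week (centred).
#' @param baseline Mean ratio for non-CC individuals at the mean gestation.
#' @param seed Integer seed.
#' @return A `pop_sim_config` list.
#' @export
pop_sim_config <- function(allele_freqs = c(H = 0.72, C1 = 0.17, C2 = 0.11),
                           n_individuals = 1244,
                           effect_cc = 0.01,
                           noise_sd = 0.02,
                           gestation_effect = 0.002,
                           baseline = 0.68,
                           seed = 1) {
  if (length(allele_freqs) != 3) abort("`allele_freqs` must have length 3")
  if (is.null(names(allele_freqs))) names(allele_freqs) <- .alleles3
  if (!setequal(names(allele_freqs), .alleles3)) {
    abort("`allele_freqs` must be named H/C1/C2")
  }
  allele_freqs <- allele_freqs[.alleles3]
  if (any(allele_freqs < 0)) abort("allele frequencies must be non-negative")
  if (abs(sum(allele_freqs) - 1) > 1e-12) {
    abort("allele frequencies must sum to 1 (within 1e-12)")
  }
  if (n_individuals < 1) abort("`n_individuals` must be positive")
  if (noise_sd < 0) abort("`noise_sd` must be non-negative")
  structure(list(allele_freqs = allele_freqs,
                 n_individuals = as.integer(n_individuals),
                 effect_cc = effect_cc, noise_sd = noise_sd,
                 gestation_effect = gestation_effect, baseline = baseline,
                 gestation_mean = 39, gestation_sd = 1.5,
                 gestation_range = c(30, 43),
                 weight_mean = 3200, weight_sd = 400,
                 seed = as.integer(seed)),
            class = "pop_sim_config")
}

# analytic HWE class probabilities over the 6 genotype classes
.hwe_probs6 <- function(p) {
  p <- p[.alleles3]
  c(HH = p[["H"]]^2, HC1 = 2 * p[["H"]] * p[["C1"]], HC2 = 2 * p[["H"]] * p[["C2"]],
    C1C1 = p[["C1"]]^2, C1C2 = 2 * p[["C1"]] * p[["C2"]], C2C2 = p[["C2"]]^2)
}

#' Draw genotypes under Hardy-Weinberg equilibrium
#'
#' Genotypes are drawn multinomially over the six classes with probabilities
#' p_i^2 (homozygotes) and 2 p_i p_j (heterozygotes).
#'
#' @param config A [pop_sim_config()].
#' @return Character vector of length `n_individuals` over
#'   `HH, HC1, HC2, C1C1, C1C2, C2C2`.
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "pop_sim_config"))
  probs <- .hwe_probs6(config$allele_freqs)
  .with_seed(config$seed, {
    sample(.geno6, config$n_individuals, replace = TRUE, prob = probs)
  })
}

#' Simulate phenotype records with a planted dominant genotype effect
#'
#' Relative head size = baseline + effect_cc * 1\[CC class\] +
#' gestation_effect * (weeks - mean weeks) + Gaussian(0, noise_sd).
#' Head circumference is reported as ratio x height so the record table
#' carries consistent raw measurements.
#'
#' @param genotypes Character vector of 6-class or collapsed 3-class labels.
#' @param config A [pop_sim_config()]; the phenotype draw uses
#'   `config$seed + 1` so genotypes and phenotypes are independent streams.
#' @return Tibble of phenotype records: `subject_id`, `genotype` (collapsed
#'   HH/HC/CC), `genotype6`, `sex`, `gestation_weeks`, `body_weight`,
#'   `height`, `head_circumference`, `relative_head_size`, `timepoint`.
#' @export
simulate_phenotypes <- function(genotypes, config) {
  stopifnot(inherits(config, "pop_sim_config"))
  known <- c(.geno6, .geno3)
  bad <- setdiff(unique(genotypes), known)
  if (length(bad) > 0) {
    abort(sprintf("unknown genotype label(s): %s", paste(bad, collapse = ", ")))
  }
  collapsed <- dplyr::case_when(
    genotypes %in% c("HH") ~ "HH",
    genotypes %in% c("HC1", "HC2", "HC") ~ "HC",
    TRUE ~ "CC"
  )
  n <- length(genotypes)
  .with_seed(config$seed + 1L, {
    gest <- rnorm(n, config$gestation_mean, config$gestation_sd)
    gest <- pmin(pmax(gest, config$gestation_range[1]), config$gestation_range[2])
    sex <- ifelse(rbinom(n, 1, 0.5) == 1, "male", "female")
    weight <- pmax(rnorm(n, config$weight_mean, config$weight_sd), 500)
    height <- pmax(rnorm(n, 50, 2), 30)
    ratio <- config$baseline +
      config$effect_cc * (collapsed == "CC") +
      config$gestation_effect * (gest - config$gestation_mean) +
      rnorm(n, 0, config$noise_sd)
    tibble(
      subject_id = sprintf("ind%05d", seq_len(n)),
      genotype = collapsed,
      genotype6 = genotypes,
      sex = sex,
      gestation_weeks = gest,
      body_weight = weight,
      height = height,
      head_circumference = ratio * height,
      relative_head_size = ratio,
      timepoint = "birth"
    )
  })
}
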