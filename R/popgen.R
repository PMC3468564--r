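# Allele typing from the diagnostic-site table, allele/genotype frequency
# arithmetic, and multi-allelic Hardy-Weinberg expectations and chi-square
# goodness of fit for the H/C1/C2 system.

# the three sites whose states separate the C1 and C2 subtypes
.c_subtype_sites <- c("rs16971886", "rs10405238", "rs3745770")
.h_vs_c_site <- "rs1667354"

#' Published genotype panels for seven populations
#'
#' Observed allele and genotype frequencies for the three-allele system in
#' seven population panels, together with the genotype frequencies expected
#' under Hardy-Weinberg equilibrium as printed (2 decimal places).
#'
#' @return Tibble with `population`, `n`, allele frequencies `p_H`, `p_C1`,
#'   `p_C2`, observed genotype frequencies `obs_*` and printed expectations
#'   `exp_*` over the six genotype classes.
#' @export
table2_panels <- function() {
  path <- system.file("extdata", "table2_genotype_panels.tsv",
                      package = "trioscan", mustWork = TRUE)
  readr::read_tsv(path, col_types = readr::cols(
    population = readr::col_character(), n = readr::col_integer(),
    .default = readr::col_double()
  ))
}

#' Collapsed genotype counts of the newborn cohort
#'
#' Counts of the HH / HC / CC genotype classes (C = C1 + C2 combined) in the
#' 1,244-newborn cohort used for the head-size association.
#'
#' @return One-row tibble: `population`, `n`, `n_HH`, `n_HC`, `n_CC`.
#' @export
taiwanese_counts <- function() {
  path <- system.file("extdata", "taiwanese_genotype_counts.tsv",
                      package = "trioscan", mustWork = TRUE)
  readr::read_tsv(path, col_types = readr::cols(
    population = readr::col_character(), .default = readr::col_integer()
  ))
}

#' Type a haplotype as H, C1, C2 or unknown
#'
#' The splice-site SNP rs1667354 separates the lineages (ancestral `A` means
#' H, derived `G` means C); within C the subtype is decided by majority vote
#' over the three C1/C2-discriminating sites. Any provided state that
#' contradicts the winning allele's full profile demotes the call to
#' `unknown`, with the conflicting sites reported in the `conflicts`
#' attribute.
#'
#' @param haplotype_states Named character vector or list mapping `site_id`
#'   to a single nucleotide; at least one diagnostic site required.
#' @param table Variant site table, defaulting to [m003_variant_sites()].
#' @return Single string: `"H"`, `"C1"`, `"C2"`, `"C"` (subtype undecidable)
#'   or `"unknown"`, with attribute `conflicts` listing contradictory sites.
#' @export
call_allele <- function(haplotype_states, table = m003_variant_sites()) {
  states <- unlist(haplotype_states)
  states <- states[names(states) %in% table$site_id]
  if (length(states) == 0) abort("no recognised diagnostic sites provided")

  profile_of <- function(allele) {
    setNames(table[[paste0("state_", allele)]], table$site_id)
  }
  conflicts_with <- function(allele) {
    prof <- profile_of(allele)
    names(states)[states != prof[names(states)]]
  }

  lineage <- if (.h_vs_c_site %in% names(states)) {
    s <- states[[.h_vs_c_site]]
    if (s == table$state_H[table$site_id == .h_vs_c_site]) "H"
    else if (s == table$state_C1[table$site_id == .h_vs_c_site]) "C"
    else return(structure("unknown", conflicts = .h_vs_c_site))
  } else {
    # fall back on whichever lineage profile matches better
    nh <- length(conflicts_with("H"))
    nc <- min(length(conflicts_with("C1")), length(conflicts_with("C2")))
    if (nh < nc) "H" else if (nc < nh) "C" else
      return(structure("unknown", conflicts = character(0)))
  }

  if (lineage == "H") {
    conf <- conflicts_with("H")
    if (length(conf) > 0) return(structure("unknown", conflicts = conf))
    return(structure("H", conflicts = character(0)))
  }

  sub_sites <- intersect(.c_subtype_sites, names(states))
  if (length(sub_sites) == 0) {
    conf1 <- conflicts_with("C1")
    conf2 <- conflicts_with("C2")
    if (length(conf1) == 0 || length(conf2) == 0) {
      return(structure("C", conflicts = character(0)))
    }
    return(structure("unknown", conflicts = intersect(conf1, conf2)))
  }
  votes <- vapply(sub_sites, function(sid) {
    s <- states[[sid]]
    row <- table[table$site_id == sid, ]
    if (s == row$state_C1 && s == row$state_C2) NA_character_
    else if (s == row$state_C1) "C1"
    else if (s == row$state_C2) "C2"
    else "?" # matches neither subtype
  }, character(1))
  if (any(votes == "?", na.rm = TRUE)) {
    return(structure("unknown", conflicts = sub_sites[which(votes == "?")]))
  }
  votes <- votes[!is.na(votes)]
  winner <- if (length(votes) == 0) "C"
  else if (sum(votes == "C1") > sum(votes == "C2")) "C1"
  else if (sum(votes == "C2") > sum(votes == "C1")) "C2"
  else "C"
  if (winner %in% c("C1", "C2")) {
    conf <- conflicts_with(winner)
    if (length(conf) > 0) return(structure("unknown", conflicts = conf))
  }
  structure(winner, conflicts = character(0))
}

#' Allele frequencies by gene counting
#'
#' Direct gene counting: each homozygote contributes two copies of its
#' allele, each heterozygote one of each. Accepts six-class (H/C1/C2) or
#' collapsed three-class (H/C) genotype counts.
#'
#' @param counts Named numeric of genotype counts: either
#'   `HH, HC1, HC2, C1C1, C1C2, C2C2` or `HH, HC, CC`.
#' @return Named numeric of allele frequencies (`H`, `C1`, `C2` or `H`, `C`).
#' @export
allele_frequencies <- function(counts) {
  counts <- unlist(counts)
  n <- sum(counts)
  if (n == 0) abort("no individuals: cannot compute allele frequencies")
  if (setequal(names(counts), .geno6)) {
    counts <- counts[.geno6]
    c(H = (2 * counts[["HH"]] + counts[["HC1"]] + counts[["HC2"]]) / (2 * n),
      C1 = (2 * counts[["C1C1"]] + counts[["HC1"]] + counts[["C1C2"]]) / (2 * n),
      C2 = (2 * counts[["C2C2"]] + counts[["HC2"]] + counts[["C1C2"]]) / (2 * n))
  } else if (setequal(names(counts), .geno3)) {
    counts <- counts[.geno3]
    c(H = (2 * counts[["HH"]] + counts[["HC"]]) / (2 * n),
      C = (2 * counts[["CC"]] + counts[["HC"]]) / (2 * n))
  } else {
    abort("`counts` must be named by the 6 genotype classes or the collapsed 3")
  }
}

#' Hardy-Weinberg expected genotype frequencies for three alleles
#'
#' @param freqs Named numeric (`H`, `C1`, `C2`) summing to 1.
#' @return Named numeric over the six genotype classes (`p^2` homozygotes,
#'   `2 p q` heterozygotes), summing to 1 exactly.
#' @export
hwe_expected <- function(freqs) {
  freqs <- unlist(freqs)
  if (is.null(names(freqs))) names(freqs) <- .alleles3
  if (any(freqs < 0)) abort("allele frequencies must be non-negative")
  p <- .hwe_probs6(freqs)
  p / sum(p) # renormalised so the six classes sum to 1 exactly
}

#' Chi-square goodness-of-fit test of Hardy-Weinberg equilibrium
#'
#' Allele frequencies are estimated from the counts by gene counting,
#' expectations follow [hwe_expected()], and the statistic is the usual sum
#' of (observed - expected)^2 / expected over the genotype classes. Degrees
#' of freedom are (classes - 1) - (independent allele frequencies
#' estimated); alleles with zero estimated frequency drop their classes and
#' reduce the df accordingly. Classes with expected count below 1 are pooled
#' into the heterozygote class sharing an allele with the largest
#' expectation (flagged in the output).
#'
#' @param counts Named six-class (or collapsed three-class) genotype counts.
#' @return List of class `hwe_test`: `allele_freqs`, `expected_freqs`,
#'   `observed`, `expected`, `chi_square`, `df`, `p_value`, `pooled`.
#' @export
hwe_chisq <- function(counts) {
  counts <- unlist(counts)
  n <- sum(counts)
  if (n <= 0) abort("empty genotype panel")
  freqs <- allele_frequencies(counts)
  if (setequal(names(counts), .geno3)) {
    classes <- .geno3
    exp_freq <- c(HH = freqs[["H"]]^2, HC = 2 * freqs[["H"]] * freqs[["C"]],
                  CC = freqs[["C"]]^2)
    allele_of <- list(HH = "H", HC = c("H", "C"), CC = "C")
  } else {
    counts <- counts[.geno6]
    classes <- .geno6
    exp_freq <- hwe_expected(freqs)
    allele_of <- list(HH = "H", HC1 = c("H", "C1"), HC2 = c("H", "C2"),
                      C1C1 = "C1", C1C2 = c("C1", "C2"), C2C2 = "C2")
  }
  present <- names(freqs)[freqs > 0]
  keep <- vapply(classes, function(cl) all(allele_of[[cl]] %in% present), logical(1))
  obs <- counts[classes][keep]
  expd <- (exp_freq[classes] * n)[keep]
  if (any(expd == 0 & obs > 0)) {
    abort("observed counts in a class with zero expectation: panel inconsistent")
  }
  het <- vapply(names(obs), function(cl) length(allele_of[[cl]]) == 2, logical(1))
  pooled <- character(0)
  while (length(obs) > 1 && min(expd) < 1) {
    k <- which.min(expd)
    cls <- names(obs)[k]
    cand <- setdiff(names(obs)[het[names(obs)]], cls)
    cand <- cand[vapply(cand, function(h) length(intersect(allele_of[[h]], allele_of[[cls]])) > 0, logical(1))]
    if (length(cand) == 0) cand <- setdiff(names(obs), cls)
    tgt <- cand[which.max(expd[cand])]
    obs[tgt] <- obs[tgt] + obs[k]
    expd[tgt] <- expd[tgt] + expd[k]
    obs <- obs[-k]; expd <- expd[-k]
    pooled <- c(pooled, cls)
  }
  n_alleles_est <- length(present) - 1
  df <- max(length(obs) - 1 - n_alleles_est, 1)
  chi <- sum((obs - expd)^2 / expd)
  out <- list(allele_freqs = freqs, expected_freqs = exp_freq,
              observed = counts[classes], expected = exp_freq[classes] * n,
              chi_square = chi, df = df,
              p_value = pchisq(chi, df, lower.tail = FALSE),
              pooled = pooled, n = n)
  class(out) <- "hwe_test"
  out
}

#' @export
print.hwe_test <- function(x, ...) {
  cat(sprintf("<hwe_test> chi-square = %.4f on %d df, p = %.4g (n = %d)\n",
              x$chi_square, x$df, x$p_value, x$n))
  invisible(x)
}

#' Collapse C1 and C2 into a single C allele
#'
#' @param counts Named six-class genotype counts (or frequencies).
#' @return Named three-class vector: `HH`, `HC = HC1 + HC2`,
#'   `CC = C1C1 + C1C2 + C2C2`; the total is preserved.
#' @export
collapse_C <- function(counts) {
  counts <- unlist(counts)
  if (!setequal(names(counts), .geno6)) {
    abort("`counts` must be named by the 6 genotype classes")
  }
  counts <- counts[.geno6]
  c(HH = counts[["HH"]],
    HC = counts[["HC1"]] + counts[["HC2"]],
    CC = counts[["C1C1"]] + counts[["C1C2"]] + counts[["C2C2"]])
}

#' @exportS3Method generics::tidy
tidy.hwe_test <- function(x, ...) {
  tibble(
    class = names(x$observed),
    observed = as.numeric(x$observed),
    expected = as.numeric(x$expected),
    expected_freq = as.numeric(x$expected_freqs)
  )
}

#' @exportS3Method generics::glance
glance.hwe_test <- function(x, ...) {
  tibble(chi_square = x$chi_square, df = x$df, p_value = x$p_value,
         n = x$n, n_pooled = length(x$pooled))
}
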