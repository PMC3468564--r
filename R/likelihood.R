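# Felsenstein pruning over the single internal node of the unrooted
# three-taxon tree, and maximum-likelihood fitting of the free-ratio codon
# model (shared kappa, branch-specific omega and length, F3x4 frequencies).

# site patterns over usable-ML columns as codon indices + multiplicities
.ml_patterns <- function(alignment) {
  use <- alignment[which(alignment$usable_ml), , drop = FALSE]
  if (nrow(use) == 0) abort("no usable columns for likelihood computation")
  ih <- match(use$human, .sense)
  ic <- match(use$chimp, .sense)
  io <- match(use$outgroup, .sense)
  key <- paste(ih, ic, io)
  first <- !duplicated(key)
  counts <- as.numeric(table(factor(key, levels = key[first])))
  list(h = ih[first], c = ic[first], o = io[first], w = counts,
       n = nrow(use))
}

.loglik_patterns <- function(pat, kappa, omega, tlen, freqs) {
  ps <- lapply(.branches, function(b) {
    q <- build_rate_generator(kappa, omega[[b]], freqs)
    .transition_matrix(q, freqs, tlen[[b]])
  })
  names(ps) <- .branches
  a <- freqs * ps$human[, pat$h, drop = FALSE]          # 61 x npat
  lik <- colSums(a * ps$chimp[, pat$c, drop = FALSE] *
                   ps$outgroup[, pat$o, drop = FALSE])
  if (any(lik <= 0)) return(-Inf)
  sum(pat$w * log(lik))
}

#' Log-likelihood of a codon trio alignment under the branch-specific model
#'
#' Sums, over usable columns, the log of the stationary-weighted product of
#' transition probabilities from the internal node to the three tips, each
#' branch using its own dN/dS and length.
#'
#' @param alignment A masked `codon_trio_alignment` with at least one
#'   usable column.
#' @param params A [codon_model_params()].
#' @return Log-likelihood (scalar).
#' @export
trio_log_likelihood <- function(alignment, params) {
  stopifnot(inherits(alignment, "codon_trio_alignment"),
            inherits(params, "codon_model_params"))
  if (any(is.na(alignment$usable_ml))) alignment <- mask_columns(alignment)
  pat <- .ml_patterns(alignment)
  .loglik_patterns(pat, params$kappa, params$omega_per_branch,
                   params$branch_lengths, params$codon_freqs)
}

.fit_bounds <- list(kappa = c(0.1, 20), omega = c(1e-4, 20), t = c(1e-8, 5))

#' Fit the free-ratio codon model to a trio alignment
#'
#' Maximises [trio_log_likelihood()] over kappa, three branch lengths and
#' three branch-specific omegas, with codon frequencies fixed at F3x4
#' empirical estimates from the alignment. Uses bounded quasi-Newton
#' (`L-BFGS-B`) from several seeded starts. Fitted parameters are converted
#' to expected per-branch substitution counts (branch length x proportion of
#' stationary flow that is nonsynonymous x column count) and to Ka/Ks with
#' mutational-opportunity site numbers evaluated at the fitted kappa.
#'
#' @param alignment Masked `codon_trio_alignment`.
#' @param min_columns Minimum usable columns required (default 50).
#' @param n_starts Number of optimizer starts (default 5).
#' @param seed Integer seed controlling the start points.
#' @return List of class `trio_ml_fit` with elements `params`
#'   ([codon_model_params()]), `loglik`, `counts` (a `branch_substitutions`
#'   tibble, `method = "ml"`), `convergence`, `n_columns`.
#' @export
fit_free_ratio <- function(alignment, min_columns = 50, n_starts = 5, seed = 1) {
  stopifnot(inherits(alignment, "codon_trio_alignment"))
  if (any(is.na(alignment$usable_ml))) alignment <- mask_columns(alignment)
  pat <- .ml_patterns(alignment)
  if (pat$n < min_columns) {
    abort(sprintf("only %d usable columns (< %d required)", pat$n, min_columns))
  }
  use <- alignment[which(alignment$usable_ml), , drop = FALSE]
  freqs <- .f3x4_freqs(c(use$human, use$chimp, use$outgroup))

  # degenerate alignment: no variation at all
  if (all(use$human == use$chimp & use$chimp == use$outgroup)) {
    params <- codon_model_params(2, c(human = 1, chimp = 1, outgroup = 1),
                                 c(human = 0, chimp = 0, outgroup = 0), freqs)
    counts <- .ml_counts(params, pat$n)
    # with t = 0 and identical tips the likelihood is the stationary draw
    loglik <- sum(pat$w * log(freqs[pat$h]))
    params$omega_per_branch[] <- NaN
    counts$n_syn <- counts$n_nonsyn <- 0
    fit <- list(params = params, loglik = loglik,
                counts = counts, convergence = 0L, n_columns = pat$n,
                degenerate = TRUE)
    class(fit) <- "trio_ml_fit"
    attr(fit$counts, "gene_id") <- attr(alignment, "gene_id")
    return(fit)
  }

  # crude divergence-based starting branch lengths
  pdiff <- c(
    human = mean(use$human != use$chimp | use$human != use$outgroup),
    chimp = mean(use$chimp != use$human | use$chimp != use$outgroup),
    outgroup = mean(use$outgroup != use$human | use$outgroup != use$chimp)
  ) / 2 + 0.01

  obj <- function(par) {
    kappa <- par[1]
    tlen <- setNames(par[2:4], .branches)
    omega <- setNames(par[5:7], .branches)
    -.loglik_patterns(pat, kappa, omega, tlen, freqs)
  }
  lower <- c(.fit_bounds$kappa[1], rep(.fit_bounds$t[1], 3), rep(.fit_bounds$omega[1], 3))
  upper <- c(.fit_bounds$kappa[2], rep(.fit_bounds$t[2], 3), rep(.fit_bounds$omega[2], 3))

  rng <- .local_rng(seed)
  best <- NULL
  conv <- 1L
  for (s in seq_len(n_starts)) {
    jitter <- if (s == 1) rep(1, 7) else exp(rng(7) * 0.5)
    start <- pmin(pmax(c(2, pdiff, rep(1, 3)) * jitter, lower * 1.01), upper * 0.99)
    res <- tryCatch(
      optim(start, obj, method = "L-BFGS-B", lower = lower, upper = upper,
            control = list(maxit = 500, factr = 1e7)),
      error = function(e) NULL
    )
    if (is.null(res)) next
    if (is.null(best) || res$value < best$value - 1e-9) best <- res
    if (res$convergence == 0) conv <- 0L
  }
  if (is.null(best)) abort("free-ratio fit failed to converge from any start")

  par <- best$par
  params <- codon_model_params(par[1], setNames(par[5:7], .branches),
                               setNames(par[2:4], .branches), freqs)
  counts <- .ml_counts(params, pat$n)
  attr(counts, "gene_id") <- attr(alignment, "gene_id")
  fit <- list(params = params, loglik = -best$value, counts = counts,
              convergence = conv, n_columns = pat$n, degenerate = FALSE)
  class(fit) <- "trio_ml_fit"
  fit
}

# expected per-branch counts and rates from fitted parameters
.ml_counts <- function(params, n_columns) {
  freqs <- params$codon_freqs
  sites <- count_sites(rep(.sense[1], n_columns), method = "mutational",
                       kappa = params$kappa, codon_freqs = freqs)
  # (count_sites "mutational" ignores the identity of the codons passed; it
  # only needs their number -- the split is a property of kappa and freqs)
  rows <- lapply(.branches, function(b) {
    omega <- params$omega_per_branch[[b]]
    tlen <- params$branch_lengths[[b]]
    if (is.nan(omega)) {
      frac_n <- NaN
    } else {
      q <- build_rate_generator(params$kappa, omega, freqs)
      flow_n <- sum(freqs * rowSums(q * .codon_pairs$nonsyn))
      flow_tot <- sum(freqs * rowSums(q * .codon_pairs$single))
      frac_n <- flow_n / flow_tot
    }
    n_tot <- tlen * n_columns
    tibble(
      branch = b,
      n_syn = n_tot * (1 - frac_n), n_nonsyn = n_tot * frac_n,
      syn_sites = unname(sites["syn_sites"]),
      nonsyn_sites = unname(sites["nonsyn_sites"]),
      ka = n_tot * frac_n / unname(sites["nonsyn_sites"]),
      ks = n_tot * (1 - frac_n) / unname(sites["syn_sites"]),
      method = "ml"
    )
  })
  out <- bind_rows(rows)
  class(out) <- c("branch_substitutions", class(out))
  out
}

#' @export
print.trio_ml_fit <- function(x, ...) {
  cat(sprintf("<trio_ml_fit> logL = %.4f over %d columns (kappa = %.3f)\n",
              x$loglik, x$n_columns, x$params$kappa))
  print(x$counts)
  invisible(x)
}

# self-contained RNG stream that does not disturb the global seed
.local_rng <- function(seed) {
  env <- new.env()
  env$state <- as.integer(seed)
  function(n) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(env$state)
    env$state <- env$state + 1L
    rnorm(n)
  }
}
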