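# Goldman-Yang-type codon substitution model with branch-specific dN/dS.
# State space: the 61 sense codons (see sense_codons()); stop codons are
# excluded from the generator and carry zero stationary frequency.

#' Parameters of the branch-specific codon substitution model
#'
#' Bundles the transition/transversion ratio `kappa`, one `omega` (dN/dS) and
#' one branch length per lineage of the unrooted human/chimp/outgroup trio,
#' and the stationary sense-codon frequencies. Branch lengths are expected
#' substitutions per codon site.
#'
#' @param kappa Positive transition/transversion rate ratio.
#' @param omega_per_branch Named numeric of length 3
#'   (`human`, `chimp`, `outgroup`), each non-negative.
#' @param branch_lengths Named numeric of length 3, non-negative.
#' @param codon_freqs Numeric vector of length 61 over [sense_codons()];
#'   non-negative, summing to 1 within `1e-12`. Defaults to equal frequencies.
#' @return An object of class `codon_model_params`.
#' @export
codon_model_params <- function(kappa = 2,
                               omega_per_branch = c(human = 1, chimp = 1, outgroup = 1),
                               branch_lengths = c(human = 0.1, chimp = 0.1, outgroup = 0.1),
                               codon_freqs = rep(1 / 61, 61)) {
  omega_per_branch <- .named3(omega_per_branch, "omega_per_branch")
  branch_lengths <- .named3(branch_lengths, "branch_lengths")
  if (!is.numeric(kappa) || length(kappa) != 1 || kappa <= 0) {
    abort("`kappa` must be a single positive number")
  }
  if (any(omega_per_branch < 0)) abort("omega values must be non-negative")
  if (any(branch_lengths < 0)) abort("branch lengths must be non-negative")
  .check_freqs(codon_freqs)
  structure(
    list(kappa = kappa, omega_per_branch = omega_per_branch,
         branch_lengths = branch_lengths, codon_freqs = as.numeric(codon_freqs)),
    class = "codon_model_params"
  )
}

.branches <- c("human", "chimp", "outgroup")

.named3 <- function(x, what) {
  if (length(x) != 3) abort(sprintf("`%s` must have length 3", what))
  if (is.null(names(x))) names(x) <- .branches
  if (!setequal(names(x), .branches)) {
    abort(sprintf("`%s` must be named human/chimp/outgroup", what))
  }
  x[.branches]
}

.check_freqs <- function(freqs) {
  if (length(freqs) != 61 || any(freqs < 0)) {
    abort("`codon_freqs` must be 61 non-negative values over the sense codons")
  }
  if (abs(sum(freqs) - 1) > 1e-12) {
    abort("`codon_freqs` must sum to 1 (within 1e-12)")
  }
  invisible(freqs)
}

#' Build the scaled instantaneous rate matrix of the codon model
#'
#' Off-diagonal rate i -> j is zero unless the codons differ at exactly one
#' position, and otherwise proportional to the target frequency, multiplied by
#' `kappa` for transitions and by `omega` for nonsynonymous changes. The
#' matrix is scaled so the mean substitution rate at stationarity is one per
#' unit branch length.
#'
#' @param kappa Transition/transversion rate ratio.
#' @param omega dN/dS ratio for this branch.
#' @param codon_freqs Stationary sense-codon frequencies (length 61, sum 1).
#' @param scale If `TRUE` (default) normalise total flow to 1; `FALSE` leaves
#'   the unscaled generator (used for mutational-opportunity site counting).
#' @return A 61 x 61 matrix with zero row sums, rows/cols named by codon.
#' @export
build_rate_generator <- function(kappa, omega, codon_freqs = rep(1 / 61, 61),
                                 scale = TRUE) {
  .check_freqs(codon_freqs)
  pr <- .codon_pairs
  q <- matrix(0, 61, 61, dimnames = list(.sense, .sense))
  q[pr$single] <- rep(codon_freqs, each = 61)[pr$single]
  q[pr$transition] <- q[pr$transition] * kappa
  q[pr$nonsyn] <- q[pr$nonsyn] * omega
  diag(q) <- -rowSums(q)
  if (scale) {
    flow <- -sum(codon_freqs * diag(q))
    if (flow > 0) q <- q / flow
  }
  q
}

# Transition probability matrix exp(Q t) via symmetrised eigendecomposition.
# The GY model is reversible, so D Q D^-1 with D = diag(sqrt(pi)) is
# symmetric; this is much faster and more stable than a general expm.
.transition_matrix <- function(q, codon_freqs, t) {
  if (t == 0) return(diag(61))
  pos <- codon_freqs > 0
  d <- sqrt(pmax(codon_freqs, 1e-300))
  s <- (d * q) %*% diag(1 / d)
  s <- (s + t(s)) / 2
  e <- eigen(s, symmetric = TRUE)
  p <- (e$vectors %*% (exp(e$values * t) * t(e$vectors))) * rep(d, each = 61) / d
  p[p < 0] <- 0
  p / rowSums(p)
}

#' Count synonymous and nonsynonymous sites
#'
#' Decomposes each codon's three positions into fractional synonymous and
#' nonsynonymous "sites". Under the uniform-mutation convention
#' (`method = "NG"`, Nei-Gojobori style) each position contributes the
#' fraction of its three possible single-nucleotide changes that are
#' synonymous; changes creating a stop codon count as nonsynonymous, so the
#' two site totals always sum to 3 x (number of codons). Under
#' `method = "mutational"` the split is the stationary synonymous flow
#' proportion of the neutral (`omega = 1`) generator evaluated at `kappa` and
#' `codon_freqs` (the convention used for the maximum-likelihood rates).
#'
#' @param codons Character vector of sense codons (an error on stop codons).
#' @param method `"NG"` (default) or `"mutational"`.
#' @param kappa,codon_freqs Model settings used by `method = "mutational"`.
#' @return Named numeric: `syn_sites`, `nonsyn_sites`.
#' @export
count_sites <- function(codons, method = c("NG", "mutational"),
                        kappa = 2, codon_freqs = rep(1 / 61, 61)) {
  method <- match.arg(method)
  if (length(codons) == 0) return(c(syn_sites = 0, nonsyn_sites = 0))
  bad <- codons %in% .stop_codons
  if (any(bad)) {
    abort(sprintf("stop codon encountered in count_sites(): %s",
                  paste(unique(codons[bad]), collapse = ", ")))
  }
  unknown <- !(codons %in% .sense)
  if (any(unknown)) {
    abort(sprintf("not a sense codon: %s",
                  paste(unique(codons[unknown]), collapse = ", ")))
  }
  n <- length(codons)
  if (method == "NG") {
    syn <- sum(.ng_syn_sites[codons])
    c(syn_sites = syn, nonsyn_sites = 3 * n - syn)
  } else {
    q <- build_rate_generator(kappa, 1, codon_freqs, scale = FALSE)
    syn_flow <- sum(codon_freqs * rowSums(q * ((!.codon_pairs$nonsyn) & .codon_pairs$single)))
    tot_flow <- sum(codon_freqs * rowSums(q * .codon_pairs$single))
    p_syn <- syn_flow / tot_flow
    c(syn_sites = 3 * n * p_syn, nonsyn_sites = 3 * n * (1 - p_syn))
  }
}

# per-codon NG synonymous site counts, cached at load
.ng_syn_sites <- local({
  vals <- vapply(.sense, function(cod) {
    ch <- strsplit(cod, "")[[1]]
    aa <- .aa_of(cod)
    syn <- 0
    for (pos in 1:3) {
      for (alt in setdiff(.nucs, ch[pos])) {
        mut <- ch
        mut[pos] <- alt
        mcod <- paste(mut, collapse = "")
        # stop codons count as nonsynonymous changes
        if (!(mcod %in% .stop_codons) && .aa_of(mcod) == aa) syn <- syn + 1 / 3
      }
    }
    syn
  }, numeric(1))
  vals
})

# F3x4-style codon frequencies from observed codons (positions x nucleotides),
# stops zeroed and renormalised.
.f3x4_freqs <- function(codons) {
  if (length(codons) == 0) return(rep(1 / 61, 61))
  mat <- do.call(rbind, strsplit(codons, ""))
  pf <- lapply(1:3, function(p) {
    tab <- table(factor(mat[, p], levels = .nucs))
    f <- as.numeric(tab) + 0.5 # mild pseudocount keeps all 61 states reachable
    f / sum(f)
  })
  ch <- do.call(rbind, strsplit(.sense, ""))
  f <- pf[[1]][match(ch[, 1], .nucs)] *
    pf[[2]][match(ch[, 2], .nucs)] *
    pf[[3]][match(ch[, 3], .nucs)]
  f / sum(f)
}
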