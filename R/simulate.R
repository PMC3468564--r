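# Seedable simulator of codon trios evolved under the branch-specific codon
# model: the internal-node sequence is drawn from the stationary frequencies
# and each tip evolves independently along its branch by sampling from the
# exact transition distribution (matrix exponential of the generator).

#' Configuration for a simulated codon trio
#'
#' @param n_codons Number of codons (positive integer).
#' @param branch_lengths Named numeric (`human`, `chimp`, `outgroup`):
#'   expected substitutions per codon site from the internal node.
#' @param omega_per_branch Named numeric of branch-specific dN/dS values.
#' @param kappa Transition/transversion rate ratio (default 2).
#' @param codon_freqs Stationary sense-codon frequencies (default equal).
#' @param scaling How branch lengths are interpreted. `"substitutions"`
#'   (default, the model convention): expected substitutions per codon on
#'   that branch, whatever its omega. `"mutation"`: expected substitutions a
#'   *neutral* gene would accumulate -- the mutational clock is held fixed
#'   across genes, so branches with omega > 1 accumulate proportionally more
#'   changes, as genes under positive selection do on a shared phylogeny.
#' @param seed Integer seed; every draw is deterministic given it.
#' @return A `trio_sim_config` list.
#' @export
trio_sim_config <- function(n_codons,
                            branch_lengths = c(human = 0.1, chimp = 0.1, outgroup = 0.2),
                            omega_per_branch = c(human = 1, chimp = 1, outgroup = 1),
                            kappa = 2,
                            codon_freqs = rep(1 / 61, 61),
                            scaling = c("substitutions", "mutation"),
                            seed = 1) {
  scaling <- match.arg(scaling)
  if (!is.numeric(n_codons) || length(n_codons) != 1 || n_codons < 1 ||
      n_codons != round(n_codons)) {
    abort("`n_codons` must be a positive integer")
  }
  params <- codon_model_params(kappa, omega_per_branch, branch_lengths, codon_freqs)
  structure(list(n_codons = as.integer(n_codons), params = params,
                 scaling = scaling, seed = as.integer(seed)),
            class = "trio_sim_config")
}

# run `expr` under a private RNG state, restoring the caller's state
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv(), inherits = FALSE)
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(expr)
}

#' Simulate a codon trio alignment under the branch-specific model
#'
#' @param config A [trio_sim_config()].
#' @return A gap-free masked `codon_trio_alignment` of `n_codons` columns,
#'   with the generating config attached as attribute `true_config`.
#' @export
simulate_codon_trio <- function(config) {
  stopifnot(inherits(config, "trio_sim_config"))
  params <- config$params
  .with_seed(config$seed, {
    n <- config$n_codons
    root <- sample.int(61, n, replace = TRUE, prob = params$codon_freqs)
    tips <- lapply(.branches, function(b) {
      omega <- params$omega_per_branch[[b]]
      q <- build_rate_generator(params$kappa, omega, params$codon_freqs)
      tlen <- params$branch_lengths[[b]]
      if (identical(config$scaling, "mutation")) {
        # total flow of this branch's generator relative to a neutral one,
        # both on the raw (unscaled) mutation scale
        raw <- build_rate_generator(params$kappa, omega, params$codon_freqs,
                                    scale = FALSE)
        raw1 <- build_rate_generator(params$kappa, 1, params$codon_freqs,
                                     scale = FALSE)
        tlen <- tlen * (-sum(params$codon_freqs * diag(raw))) /
          (-sum(params$codon_freqs * diag(raw1)))
      }
      p <- .transition_matrix(q, params$codon_freqs, tlen)
      out <- integer(n)
      for (s in unique(root)) {
        idx <- which(root == s)
        out[idx] <- sample.int(61, length(idx), replace = TRUE, prob = p[s, ])
      }
      .sense[out]
    })
    names(tips) <- .branches
    aln <- .new_codon_alignment(sprintf("sim_seed%d", config$seed),
                                tips$human, tips$chimp, tips$outgroup)
    aln <- mask_columns(aln)
    attr(aln, "true_config") <- config
    aln
  })
}

#' Simulate a gene set of codon trios with known true parameters
#'
#' Draws per-gene configurations from `config_sampler` and simulates each
#' trio, retaining the generating parameters for recovery testing.
#'
#' @param n_genes Number of genes (>= 1).
#' @param config_sampler Function `(gene_index, seed)` returning a
#'   [trio_sim_config()]. The default samples neutral genes of 300 codons
#'   with branch lengths 0.05/0.05/0.1.
#' @param seed Integer master seed; gene `i` uses seed `seed + i`.
#' @return List with `alignments` (named list of alignments) and `truth`
#'   (tibble of per-gene generating parameters).
#' @export
simulate_gene_set <- function(n_genes, config_sampler = NULL, seed = 1) {
  if (n_genes < 1) abort("`n_genes` must be >= 1")
  if (is.null(config_sampler)) {
    config_sampler <- function(i, seed_i) {
      trio_sim_config(300,
                      branch_lengths = c(human = 0.05, chimp = 0.05, outgroup = 0.1),
                      omega_per_branch = c(human = 1, chimp = 1, outgroup = 1),
                      seed = seed_i)
    }
  }
  alignments <- list()
  truth <- vector("list", n_genes)
  # (sampler contract: function(gene_index, per-gene seed) -> trio_sim_config)
  for (i in seq_len(n_genes)) {
    cfg <- config_sampler(i, seed + i)
    aln <- simulate_codon_trio(cfg)
    gid <- sprintf("gene%04d", i)
    attr(aln, "gene_id") <- gid
    alignments[[gid]] <- aln
    truth[[i]] <- tibble(
      gene_id = gid, n_codons = cfg$n_codons,
      kappa = cfg$params$kappa,
      omega_human = cfg$params$omega_per_branch[["human"]],
      omega_chimp = cfg$params$omega_per_branch[["chimp"]],
      omega_outgroup = cfg$params$omega_per_branch[["outgroup"]],
      t_human = cfg$params$branch_lengths[["human"]],
      t_chimp = cfg$params$branch_lengths[["chimp"]],
      t_outgroup = cfg$params$branch_lengths[["outgroup"]],
      seed = cfg$seed
    )
  }
  list(alignments = alignments, truth = bind_rows(truth))
}

#' Config sampler planting one positively selected gene among neutral genes
#'
#' Returns a sampler for [simulate_gene_set()] in which every gene is
#' neutral except one, which gets an elevated human-branch omega. Branch
#' lengths use the mutational-clock scaling so the planted gene accumulates
#' more nonsynonymous changes on the human lineage, as a positively selected
#' gene does on a shared phylogeny.
#'
#' @param planted_index Index of the planted gene (default 1).
#' @param omega_human Human-branch omega of the planted gene (default 5).
#' @param n_codons Codons per gene (default 300).
#' @param branch_lengths Shared branch lengths on the neutral clock scale.
#' @return A function usable as `config_sampler`.
#' @export
planted_gene_sampler <- function(planted_index = 1, omega_human = 5,
                                 n_codons = 300,
                                 branch_lengths = c(human = 0.05, chimp = 0.05,
                                                    outgroup = 0.1)) {
  function(i, seed_i) {
    om <- c(human = if (i == planted_index) omega_human else 1,
            chimp = 1, outgroup = 1)
    trio_sim_config(n_codons, branch_lengths = branch_lengths,
                    omega_per_branch = om, scaling = "mutation", seed = seed_i)
  }
}
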