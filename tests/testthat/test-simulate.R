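test_that("zero branch lengths reproduce the root at every tip", {
  cfg <- trio_sim_config(50, branch_lengths = c(human = 0, chimp = 0, outgroup = 0),
                         seed = 3)
  aln <- simulate_codon_trio(cfg)
  expect_identical(aln$human, aln$chimp)
  expect_identical(aln$chimp, aln$outgroup)
})

test_that("simulation is deterministic given the seed", {
  cfg <- trio_sim_config(100, seed = 12)
  a1 <- simulate_codon_trio(cfg)
  a2 <- simulate_codon_trio(cfg)
  expect_identical(a1$human, a2$human)
  expect_identical(a1$chimp, a2$chimp)
  expect_identical(a1$outgroup, a2$outgroup)
  a3 <- simulate_codon_trio(trio_sim_config(100, seed = 13))
  expect_false(identical(a1$human, a3$human))
})

test_that("simulated tips stay at the stationary codon distribution", {
  cfg <- trio_sim_config(10000,
                         branch_lengths = c(human = 5, chimp = 5, outgroup = 5),
                         seed = 8)
  aln <- simulate_codon_trio(cfg)
  tab <- table(factor(aln$human, levels = SENSE))
  gof <- suppressWarnings(stats::chisq.test(tab, p = rep(1 / 61, 61)))
  expect_gt(gof$p.value, 0.01)
})

test_that("parsimony recovers the generating human-branch dN/dS", {
  # twenty replicates under elevated human-branch omega; Ka/Ks uses the
  # kappa-aware site convention, since uniform-mutation sites carry a known
  # downward bias under transition enrichment (checked below)
  ratio_of <- function(res) {
    h <- res[res$branch == "human", ]
    (h$n_nonsyn / h$nonsyn_sites) / (h$n_syn / h$syn_sites)
  }
  sim <- function(r, t_human) {
    cfg <- trio_sim_config(2000,
                           branch_lengths = c(human = t_human, chimp = t_human / 3,
                                              outgroup = 2 * t_human / 3),
                           omega_per_branch = c(human = 2, chimp = 1, outgroup = 1),
                           seed = 9000 + r)
    simulate_codon_trio(cfg)
  }
  low <- vapply(1:20, function(r) {
    ratio_of(count_parsimony(sim(r, 0.05), sites = "mutational", kappa = 2))
  }, numeric(1))
  expect_lt(abs(mean(low) - 2), 0.3)
  # uniform-mutation sites under kappa = 2 shrink the ratio systematically
  ng <- vapply(1:5, function(r) {
    ratio_of(count_parsimony(sim(r, 0.05)))
  }, numeric(1))
  expect_lt(mean(ng), mean(low[1:5]))
})

test_that("neutral gene sets have mean excess near zero", {
  gs <- simulate_gene_set(200, seed = 42)
  sc <- scan_genes(gs$alignments, method = "parsimony")
  sem <- stats::sd(sc$excess) / sqrt(nrow(sc))
  expect_lt(abs(mean(sc$excess)), 2 * sem)
})

test_that("a single-gene set delegates to the single-trio simulator", {
  gs <- simulate_gene_set(1, seed = 5)
  cfg <- trio_sim_config(300,
                         branch_lengths = c(human = 0.05, chimp = 0.05, outgroup = 0.1),
                         omega_per_branch = c(human = 1, chimp = 1, outgroup = 1),
                         seed = 6)
  direct <- simulate_codon_trio(cfg)
  expect_identical(gs$alignments[[1]]$human, direct$human)
  expect_identical(gs$truth$omega_human, 1)
})

test_that("genotype sampler honours degenerate and exact frequencies", {
  cfg <- pop_sim_config(allele_freqs = c(H = 1, C1 = 0, C2 = 0),
                        n_individuals = 50, seed = 2)
  expect_identical(unique(simulate_genotypes(cfg)), "HH")
  cfg2 <- pop_sim_config(allele_freqs = c(H = 0.72, C1 = 0.17, C2 = 0.11),
                         n_individuals = 100000, seed = 3)
  g <- simulate_genotypes(cfg2)
  expect_lt(abs(mean(g == "HH") - 0.5184), 0.01)
  cfg3 <- pop_sim_config(allele_freqs = c(H = 0.5, C1 = 0.5, C2 = 0),
                         n_individuals = 100000, seed = 4)
  expect_lt(abs(mean(simulate_genotypes(cfg3) == "HC1") - 0.5), 0.01)
})

test_that("genotype frequencies converge to the analytic class probabilities", {
  cfg <- pop_sim_config(n_individuals = 100000, seed = 6)
  g <- simulate_genotypes(cfg)
  emp <- table(factor(g, levels = c("HH", "HC1", "HC2", "C1C1", "C1C2", "C2C2"))) /
    length(g)
  ana <- hwe_expected(cfg$allele_freqs)
  expect_lt(max(abs(as.numeric(emp) - as.numeric(ana))), 0.01)
})

test_that("noise-free phenotypes vary only through the gestation term", {
  cfg <- pop_sim_config(effect_cc = 0, noise_sd = 0, n_individuals = 500, seed = 7)
  ph <- simulate_phenotypes(simulate_genotypes(cfg), cfg)
  resid <- ph$relative_head_size - cfg$baseline -
    cfg$gestation_effect * (ph$gestation_weeks - cfg$gestation_mean)
  expect_lt(max(abs(resid)), 1e-12)
})

test_that("phenotype simulation rejects unknown genotype labels", {
  cfg <- pop_sim_config(seed = 8)
  expect_error(simulate_phenotypes(c("HH", "XY"), cfg), "unknown genotype")
})

test_that("phenotype covariates stay in plausible newborn ranges", {
  cfg <- pop_sim_config(n_individuals = 2000, seed = 9)
  ph <- simulate_phenotypes(simulate_genotypes(cfg), cfg)
  expect_true(all(ph$gestation_weeks >= 30 & ph$gestation_weeks <= 43))
  expect_true(all(ph$body_weight > 0))
  expect_true(all(ph$height > 0))
  expect_equal(ph$relative_head_size,
               relative_size(ph$head_circumference, ph$height),
               tolerance = 1e-12)
})
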