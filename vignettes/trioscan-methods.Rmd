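---
title: "Methods: lineage-polarized substitution screens and their downstream analyses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lineage-polarized substitution screens and their downstream analyses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trioscan)
```

trioscan implements a screen for genes with an excess of nonsynonymous
substitutions on the human lineage, on human/chimpanzee/outgroup codon
trios, together with the population-genetic analyses that follow once a
candidate gene is found: allele typing from diagnostic sites, multi-allelic
Hardy–Weinberg testing, and a genotype association with relative head size.
This vignette documents the models, the numerical choices, and what the
simulators do and do not emulate.

## The codon substitution model

Both the simulator and the likelihood machinery use a Goldman–Yang-type
model on the 61 sense codons. The instantaneous rate from codon *i* to *j*
is zero unless they differ at exactly one nucleotide, and otherwise

* proportional to the stationary frequency of the target codon π_j,
* multiplied by κ for transitions (A↔G, C↔T),
* multiplied by ω for nonsynonymous changes.

Each branch of the unrooted 3-taxon tree carries its own ω (the "free
ratio" configuration — the only standard configuration that yields
per-lineage counts) and its own length t_b; κ and π are shared. Every
generator is scaled so the mean substitution rate at stationarity is one,
making t_b the expected number of substitutions per codon on that branch.
Stop codons are excluded from the state space and carry zero frequency.

Likelihoods sum, per usable column, the stationary-weighted product of the
three tip transition probabilities over the 61 possible internal states
(Felsenstein pruning with a single internal node; the unrooted tree is
rooted there, which is valid under reversibility). Transition matrices are
computed by symmetrized eigendecomposition — the model is reversible, so
`diag(√π) Q diag(1/√π)` is symmetric — which is considerably faster inside
the optimizer than a general matrix exponential and is verified in the test
suite against an independent `Matrix::expm` to 10⁻⁹.

### Fitting

`fit_free_ratio()` maximises the likelihood over κ, three branch lengths
and three ωs (seven parameters) with `L-BFGS-B` under bounds κ ∈ [0.1, 20],
ω ∈ [10⁻⁴, 20], t ∈ [0, 5], from five seeded starts (jittered around κ = 2,
ω = 1, and a crude divergence-based t). Convergence tolerance is the
optimizer's default relative reduction (`factr = 10⁷`, about 10⁻⁸ on the
log-likelihood). Codon frequencies are fixed at F3x4 empirical estimates
(position-specific nucleotide frequencies multiplied and renormalised over
sense codons, with a 0.5 pseudocount per nucleotide so no state has
frequency zero). An alignment with no variation at all is returned as a
degenerate fit: all branch lengths zero, ω flagged `NaN` rather than
invented.

Fitted parameters convert to expected per-branch counts as
t_b × (nonsynonymous share of the stationary rate flow under ω_b) × number
of columns, and to rates Ka and Ks with mutational-opportunity site numbers
evaluated at the fitted κ and π. The parsimony route instead uses the
Nei–Gojobori uniform-mutation site convention; the two conventions are
deliberately kept distinct and are reported with a `method` tag.

## Parsimony lineage assignment

Per column the internal-node codon is inferred by two-of-three agreement,
and the change is charged to the disagreeing tip's branch. When all three
tips differ, the internal state is set to the outgroup codon — the
outgroup-rooting convention — charging one change set to each ingroup
branch; this is deterministic and errs toward the ingroup, which is
conservative for the excess statistic since it affects both ingroup
branches symmetrically. Codons differing at *k* > 1 positions average
synonymous/nonsynonymous tallies over all *k*! orderings of
single-nucleotide steps; orderings that pass through a stop codon at an
intermediate state are excluded, and if every ordering does, the direct
amino-acid comparison is used with all differing positions counted as
nonsynonymous. Counts are therefore fractional in general; integers arise
only in single-hit regimes.

Columns containing gaps or Ns are excluded everywhere. Columns containing a
stop codon are excluded from likelihood fitting (sense-codon state space)
but retained for parsimony, with stop-involving steps counted as
nonsynonymous: a nonsense substitution is a protein-changing event, and the
screen's headline count for its hit gene includes one.

Parsimony Ka/Ks carries a convention caveat worth knowing. With the default
uniform-mutation (Nei–Gojobori) site counts, each position's synonymous
share weights all three possible changes equally; when transitions are
enriched (κ > 1) the true synonymous opportunity is larger than that, so
Ka/Ks is shrunk by a roughly constant factor (about 0.8 at κ = 2) at any
divergence. `count_parsimony(sites = "mutational", kappa = ...)` switches
to the κ-weighted opportunity split, under which the ratio tracks the
generating ω at low divergence (a seeded recovery test in the suite); at
high divergence pathway averaging and outgroup-rooted polarization dilute
it further, which is why the screen's ranking statistic is the excess
*count difference*, not the ratio. The excess is unaffected by the site
convention.

The excess statistic is simply n_nonsyn(human) − n_nonsyn(chimp), positive
when the human lineage changed more. It is antisymmetric under swapping the
ingroup labels (a property test), and the scan ranks genes by it with ties
broken lexicographically so results are reproducible to the byte.

## Alignment construction

Trios are aligned at the protein level and back-translated. Pairwise and
profile alignment use a hand-rolled affine-gap Needleman–Wunsch (BLOSUM62,
gap open 10, gap extend 0.5, a gap run of length L costing
`open + extend × (L − 1)`); the human–chimp pair — the most similar — is
aligned first, then the outgroup is aligned to the resulting two-row
profile with mean column scores. The suite checks optimality against
brute-force enumeration for short sequences and against an independent
aligner (`Biostrings::pairwiseAlignment`) for longer ones. Back-translation
replaces each residue by its source codon and each gap by `---`; degapping
any row reproduces the input CDS exactly (a round-trip property test).
Positions are 1-based relative to the A (+1) of the start codon; codon
index = ⌈position / 3⌉. N-containing codons are masked, not imputed.

## The simulators

`simulate_codon_trio()` draws the internal-node sequence from π and evolves
each tip independently by sampling from the exact transition distribution
exp(Q_b t_b) — exact and fast at desk scale, with no need for event-level
(Gillespie) simulation. Everything is deterministic given the seed, and the
generating parameters ride along with the alignment for recovery tests.

Branch lengths admit two interpretations, chosen by `scaling`:

* `"substitutions"` (default, the model convention): t_b is the expected
  substitutions per codon on that branch regardless of ω_b.
* `"mutation"`: t_b is the expected substitutions a *neutral* gene would
  accumulate — the mutational clock is held fixed across genes, so a branch
  with ω > 1 accumulates proportionally more changes. This is how a
  positively selected gene behaves on a shared phylogeny, and it is the
  scaling used by `planted_gene_sampler()`: under unit-rate scaling a
  planted ω = 5 gene would change its substitution *count* only through the
  modest shift of the synonymous/nonsynonymous split, which is not what
  positive selection looks like.

`simulate_genotypes()` draws multinomially from the Hardy–Weinberg class
probabilities p_i² and 2 p_i p_j. `simulate_phenotypes()` builds

relative head size = baseline + effect_cc · 1[CC] +
gestation_effect · (weeks − 39) + N(0, noise_sd²)

with covariates gestation ~ N(39, 1.5²) weeks truncated to [30, 43], sex ~
Bernoulli(0.5), body weight ~ N(3200, 400²) g — plausible newborn ranges,
fully recorded in the config. The defaults emulate the study cohort:
allele frequencies (H, C1, C2) = (0.72, 0.17, 0.11), n = 1,244, baseline
ratio 0.68 (a 34 cm head circumference on a 50 cm newborn), a CC shift of
+0.01 with residual noise 0.02, and a gestation slope of 0.002 per week so
the gestation term carries variance comparable to the genotype term, as in
the published decomposition.

What the simulators do **not** emulate: indels (the C-allele 51-bp splice
deletion exists only in the variant table, never in simulated alignments),
rate heterogeneity across sites, recombination, demography, genotyping
error, and measurement error structure beyond i.i.d. Gaussian noise.
Passing tests therefore demonstrate correctness of the estimators under
the model, not robustness to real-data pathologies.

## The synthetic hit-gene trio

`build_m003_toy()` reconstructs a testable stand-in for the screen's hit
gene from the shipped diagnostic-site table: 660 codons, seeded filler
codons identical across species, and each variant site placed in a codon
context consistent with its annotated amino acids (contexts are solved by
enumeration over the 64 codons and chosen lexicographically first, so the
construction is deterministic; an unsatisfiable annotation is reported with
its site). The outgroup carries the inferred ancestral state: the
chimpanzee nucleotide at the human-derived sites, and the human nucleotide
at the single human-fixed synonymous site, where the change occurred on the
chimpanzee lineage. Parsimony on this trio yields 8 nonsynonymous changes
(7 missense + 1 nonsense) on the human branch, 1 synonymous change on the
chimpanzee branch, excess 8.

## Hardy–Weinberg testing

Allele frequencies come from gene counting; expectations from the
multi-allelic law. The chi-square statistic uses (classes − 1) − (alleles
estimated − 1) degrees of freedom — 3 for a three-allele panel — with
alleles of zero estimated frequency dropping their classes and the df
accordingly. Classes with expected count below 1 are pooled into the
heterozygote class sharing an allele with the largest expectation, a
deterministic small-sample rule flagged in the output. The published table
this emulates reports no test statistic, only the visual agreement of
observed and expected frequencies; the formal test here is this package's
own formalisation, and its null calibration (rejection rate 0.05 ± 0.02
under 1,000 simulated panels) is checked in the suite. Printed-table
emulation rounds half-to-even at 2 decimal places; full precision is kept
internally. Recomputing expectations from *printed* (2 d.p.) allele
frequencies reproduces the printed parenthetical cells to within one unit
in the last printed digit — exact agreement to ±0.005 is not attainable
because the source rounded its allele frequencies before printing (e.g.
0.42² = 0.1764 against a printed 0.17).

## The association stage

The phenotype is the plain ratio head circumference / height ("corrected by
height" is read as a ratio, which the source's own phrasing fixes; no
regression residualisation). Group comparisons are Welch two-sample t-tests
by default (the published pairwise p-values do not name their test;
`pooled = TRUE` switches to the equal-variance version), all pairs
reported unadjusted. The ANOVA is the sequential (Type I) decomposition in
the printed row order — genotype, gestation weeks, body weight, sex — with
genotype as a single dominant-coded indicator for CC, matching the
single-df rows of the published table. With four single-df terms the
residual df is n − 5 (1,239 at n = 1,244; the published 1,238 suggests one
excluded record, which is noted and not resolved). The published F and p
values themselves are not reproducible without the undeposited
individual-level data; the suite instead verifies SS conservation,
order-invariance properties, null calibration of the genotype term, and
power on planted effects. Cross-population correlations are Pearson with
the t-test on n − 2 df.

## Problem sizes and tolerances

The suite and acceptance script use desk-scale problem sizes chosen to
keep the whole run in minutes while leaving comfortable statistical
margins: likelihood-vs-enumeration on ≤ 5-codon alignments (agreement to
10⁻⁸); ω recovery on 20 replicates of 2,000 codons (mean within ±0.25 of
the generating 2.0); planted-gene detection on 20 scans of 100 genes of
300 codons; null calibrations on 1,000 replicates (±0.02 around 0.05);
pathway-counting equivalence over the full 61 × 61 codon-pair sweep. The
1,668-gene scale of the original screen is out of scope: its alignments
are cited from an archive, not deposited, and nothing in the method
depends on the gene count — the scan is embarrassingly per-gene.

## Known limitations

* No branch-site or site-heterogeneity models; ω is a branch property.
* The screen ranks; it attaches no significance to an excess value.
* Parsimony undercounts at high divergence (multiple hits); the agreement
  band with ML in the tests is restricted to the low-divergence regime
  where the screen operates.
* The allele typer requires phased haplotype states; it does not phase.
* The pooling rule for rare Hardy–Weinberg classes is one reasonable
  deterministic choice among several; with three common alleles it never
  triggers.
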