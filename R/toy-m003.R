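# Synthetic "toy" M003-A06/ZNF568 codon trio embedding the published
# diagnostic-site differences between the human H allele, the chimpanzee
# gene and an Old World monkey outgroup, in codon contexts consistent with
# the annotated amino acids. Filler codons are identical across species.

#' The M003-A06 diagnostic variant site table
#'
#' Fourteen coding-region sites distinguishing the human H, C1 and C2
#' alleles of M003-A06/ZNF568 from the chimpanzee gene: rsID (or a
#' placeholder for the unnamed synonymous site), position relative to the A
#' (+1) of the start codon, per-allele nucleotide states, and amino-acid
#' annotations (`Stop` for the nonsense change, `splicing` for the
#' splice-site variant, `-` where no residue is annotated).
#'
#' @return Tibble with columns `site_id`, `position`, `state_H`, `state_C1`,
#'   `state_C2`, `state_chimp`, `aa_H`, `aa_C1`, `aa_C2`, `aa_chimp`.
#' @export
m003_variant_sites <- function() {
  path <- system.file("extdata", "m003_variant_sites.tsv", package = "trioscan",
                      mustWork = TRUE)
  tab <- readr::read_tsv(path, col_types = readr::cols(
    position = readr::col_integer(), .default = readr::col_character()
  ))
  if (any(diff(tab$position) <= 0)) abort("variant positions must be strictly increasing")
  tab
}

# amino-acid annotation token -> one-letter code, or NA when unconstrained
.aa_token <- function(tok) {
  if (is.na(tok) || tok %in% c("-", "splicing")) return(NA_character_)
  out <- .aa3to1[[tok]]
  if (is.null(out)) abort(sprintf("unknown amino-acid annotation '%s'", tok))
  out
}

# Find codon contexts realizing a variant row: a codon carrying state_H at
# `offset` whose translation (and the translations after substituting the
# other alleles' states) matches every annotated amino acid. For rows with
# no annotation at all and differing H/chimp states the change must be
# synonymous (the table marks such rows as the synonymous difference).
.solve_context <- function(row, offset) {
  constraints <- list(
    c(row$state_H, .aa_token(row$aa_H)),
    c(row$state_C1, .aa_token(row$aa_C1)),
    c(row$state_C2, .aa_token(row$aa_C2)),
    c(row$state_chimp, .aa_token(row$aa_chimp))
  )
  all_unannotated <- all(vapply(constraints, function(x) is.na(x[2]), logical(1)))
  ok <- vapply(.codons64, function(cand) {
    if (substr(cand, offset, offset) != row$state_H) return(FALSE)
    for (con in constraints) {
      if (is.na(con[2])) next
      mut <- cand
      substr(mut, offset, offset) <- con[1]
      if (.code64[[mut]] != con[2]) return(FALSE)
    }
    if (all_unannotated && row$state_H != row$state_chimp) {
      mut <- cand
      substr(mut, offset, offset) <- row$state_chimp
      if (cand %in% .stop_codons || mut %in% .stop_codons) return(FALSE)
      if (.code64[[cand]] != .code64[[mut]]) return(FALSE)
    }
    TRUE
  }, logical(1))
  if (!any(ok)) {
    abort(sprintf(
      "no codon context realizes site %s (position %d): states H=%s C1=%s C2=%s chimp=%s",
      row$site_id, row$position, row$state_H, row$state_C1, row$state_C2,
      row$state_chimp))
  }
  .codons64[ok][1] # lexicographically first valid context, deterministic
}

#' Build the synthetic M003-A06 codon trio
#'
#' Constructs an in-frame CDS trio (human H allele, chimpanzee, outgroup) in
#' which every diagnostic site sits in a codon context consistent with its
#' annotated amino acids, all non-variant codons are identical across the
#' three species, and the outgroup carries the inferred ancestral state:
#' the chimpanzee nucleotide at the human-derived sites, and the human
#' nucleotide at the single human-fixed synonymous site where the change
#' occurred on the chimpanzee lineage.
#'
#' @param variants Variant site table, defaulting to [m003_variant_sites()].
#' @param seed Integer seed for the filler codons.
#' @param n_codons Total codons in the toy CDS (must cover every variant
#'   position; default 660).
#' @return A masked `codon_trio_alignment` (gene id `M003-A06-toy`) with the
#'   variant table attached as attribute `variants`.
#' @export
build_m003_toy <- function(variants = m003_variant_sites(), seed = 1,
                           n_codons = 660) {
  needed <- ceiling(max(variants$position) / 3)
  if (n_codons < needed) {
    abort(sprintf("`n_codons` must be at least %d to cover every variant site", needed))
  }
  filler <- .with_seed(seed, sample(.sense, n_codons, replace = TRUE))
  filler[1] <- "ATG"
  human <- chimp <- outgroup <- filler
  for (r in seq_len(nrow(variants))) {
    row <- variants[r, ]
    codon_idx <- ceiling(row$position / 3)
    offset <- ((row$position - 1) %% 3) + 1
    context <- .solve_context(row, offset)
    h <- context
    cmp <- context
    substr(cmp, offset, offset) <- row$state_chimp
    # ancestral (outgroup) state: chimp state unless the site is fixed in
    # humans (H = C1 = C2) and differs from chimp -- then the change is on
    # the chimpanzee lineage and the outgroup matches the human state
    chimp_derived <- row$state_H == row$state_C1 &&
      row$state_H == row$state_C2 && row$state_H != row$state_chimp
    og <- if (chimp_derived) h else cmp
    human[codon_idx] <- h
    chimp[codon_idx] <- cmp
    outgroup[codon_idx] <- og
  }
  aln <- .new_codon_alignment("M003-A06-toy", human, chimp, outgroup)
  aln <- mask_columns(aln)
  attr(aln, "variants") <- variants
  aln
}
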