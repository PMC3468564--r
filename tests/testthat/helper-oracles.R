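# Independent oracles used across the suite. Each re-derives a quantity by a
# route different from the package implementation (brute-force enumeration,
# closed forms, or a different library), so agreement is informative.

SENSE <- trioscan::sense_codons()
STOPS <- c("TAA", "TAG", "TGA")
NUCS <- c("A", "C", "G", "T")
AA_OF <- function(codon) unname(Biostrings::GENETIC_CODE[codon])

# ---- brute-force trio likelihood: explicit internal-state sum, Matrix::expm
oracle_trio_loglik <- function(alignment, params) {
  use <- alignment[which(alignment$usable_ml), , drop = FALSE]
  pmats <- lapply(c("human", "chimp", "outgroup"), function(b) {
    q <- trioscan::build_rate_generator(params$kappa,
                                        params$omega_per_branch[[b]],
                                        params$codon_freqs)
    as.matrix(Matrix::expm(q * params$branch_lengths[[b]]))
  })
  names(pmats) <- c("human", "chimp", "outgroup")
  ll <- 0
  for (r in seq_len(nrow(use))) {
    tot <- 0
    ih <- match(use$human[r], SENSE)
    ic <- match(use$chimp[r], SENSE)
    io <- match(use$outgroup[r], SENSE)
    for (s in 1:61) {
      tot <- tot + params$codon_freqs[s] *
        pmats$human[s, ih] * pmats$chimp[s, ic] * pmats$outgroup[s, io]
    }
    ll <- ll + log(tot)
  }
  ll
}

# ---- exhaustive pathway-ordering oracle (depth-first over step choices)
oracle_path_counts <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  diffs <- which(ca != cb)
  if (length(diffs) == 0) return(c(syn = 0, nonsyn = 0))
  acc <- list()
  walk <- function(cur, remaining, syn, nonsyn) {
    if (length(remaining) == 0) {
      acc[[length(acc) + 1]] <<- c(syn, nonsyn)
      return(invisible())
    }
    for (pos in remaining) {
      nxt <- cur
      nxt[pos] <- cb[pos]
      to <- paste(nxt, collapse = "")
      rem <- setdiff(remaining, pos)
      if (length(rem) > 0 && to %in% STOPS) next # stop as intermediate
      from <- paste(cur, collapse = "")
      step_nonsyn <- from %in% STOPS || to %in% STOPS || AA_OF(from) != AA_OF(to)
      walk(nxt, rem, syn + !step_nonsyn, nonsyn + step_nonsyn)
    }
  }
  walk(ca, diffs, 0, 0)
  if (length(acc) == 0) return(c(syn = 0, nonsyn = length(diffs)))
  m <- do.call(rbind, acc)
  c(syn = mean(m[, 1]), nonsyn = mean(m[, 2]))
}

# ---- brute-force global alignment with affine gaps (run cost go + ge*(L-1))
oracle_align_score <- function(row_a, row_b, smat, go, ge) {
  va <- strsplit(row_a, "")[[1]]
  vb <- strsplit(row_b, "")[[1]]
  score <- 0
  for (k in seq_along(va)) {
    if (va[k] != "-" && vb[k] != "-") score <- score + smat[va[k], vb[k]]
  }
  for (row in list(va, vb)) {
    r <- rle(row == "-")
    runs <- r$lengths[r$values]
    score <- score - sum(go + ge * (runs - 1))
  }
  score
}

oracle_best_alignment <- function(a, b, smat, go, ge) {
  va <- strsplit(a, "")[[1]]
  vb <- strsplit(b, "")[[1]]
  best <- -Inf
  rec <- function(i, j, ra, rb) {
    if (i > length(va) && j > length(vb)) {
      best <<- max(best, oracle_align_score(paste(ra, collapse = ""),
                                            paste(rb, collapse = ""),
                                            smat, go, ge))
      return(invisible())
    }
    if (i <= length(va) && j <= length(vb)) rec(i + 1, j + 1, c(ra, va[i]), c(rb, vb[j]))
    if (i <= length(va)) rec(i + 1, j, c(ra, va[i]), c(rb, "-"))
    if (j <= length(vb)) rec(i, j + 1, c(ra, "-"), c(rb, vb[j]))
  }
  rec(1, 1, character(0), character(0))
  best
}

# ---- per-codon synonymous-site enumeration (independent of the cached table)
oracle_ng_sites <- function(codons) {
  syn <- 0
  for (cod in codons) {
    ch <- strsplit(cod, "")[[1]]
    for (pos in 1:3) {
      for (alt in setdiff(NUCS, ch[pos])) {
        mut <- ch
        mut[pos] <- alt
        mcod <- paste(mut, collapse = "")
        if (!(mcod %in% STOPS) && AA_OF(mcod) == AA_OF(cod)) syn <- syn + 1 / 3
      }
    }
  }
  c(syn_sites = syn, nonsyn_sites = 3 * length(codons) - syn)
}

# hand-build a codon alignment from three codon vectors
make_alignment <- function(human, chimp, outgroup, gene_id = "test") {
  aln <- tibble::tibble(column = seq_along(human), human = human,
                        chimp = chimp, outgroup = outgroup,
                        usable_ml = NA, usable_parsimony = NA)
  attr(aln, "gene_id") <- gene_id
  class(aln) <- c("codon_trio_alignment", class(aln))
  trioscan::mask_columns(aln)
}
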