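# Outgroup-polarized parsimony assignment of synonymous/nonsynonymous
# changes to the three lineages of a codon trio, with pathway averaging over
# the orderings of multi-position codon differences.

# Average (syn, nonsyn) tallies over all orderings of single-nucleotide steps
# from codon `a` to codon `b`. Orderings passing through a stop codon at an
# intermediate state are excluded; if every ordering does, the direct
# amino-acid comparison is used and all differing positions count as
# nonsynonymous. Steps to or from a stop codon count as nonsynonymous.
.path_counts_raw <- function(a, b) {
  if (a == b) return(c(syn = 0, nonsyn = 0))
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  diffs <- which(ca != cb)
  k <- length(diffs)
  orders <- if (k == 1) list(diffs) else {
    perms <- .permutations(k)
    lapply(seq_len(nrow(perms)), function(r) diffs[perms[r, ]])
  }
  tallies <- matrix(NA_real_, length(orders), 2)
  for (oi in seq_along(orders)) {
    cur <- ca
    syn <- 0; nonsyn <- 0
    ok <- TRUE
    steps <- orders[[oi]]
    for (si in seq_along(steps)) {
      pos <- steps[si]
      nxt <- cur
      nxt[pos] <- cb[pos]
      from <- paste(cur, collapse = "")
      to <- paste(nxt, collapse = "")
      # intermediate stop states invalidate the ordering (endpoints allowed)
      if (si < length(steps) && to %in% .stop_codons) { ok <- FALSE; break }
      if (from %in% .stop_codons || to %in% .stop_codons) {
        nonsyn <- nonsyn + 1
      } else if (.aa_of(from) == .aa_of(to)) {
        syn <- syn + 1
      } else {
        nonsyn <- nonsyn + 1
      }
      cur <- nxt
    }
    if (ok) tallies[oi, ] <- c(syn, nonsyn)
  }
  valid <- stats::complete.cases(tallies)
  if (!any(valid)) return(c(syn = 0, nonsyn = k))
  c(syn = mean(tallies[valid, 1]), nonsyn = mean(tallies[valid, 2]))
}

.permutations <- function(k) {
  if (k == 1) return(matrix(1L, 1, 1))
  sub <- .permutations(k - 1)
  do.call(rbind, lapply(seq_len(k), function(first) {
    rest <- setdiff(seq_len(k), first)
    cbind(first, matrix(rest[sub], nrow(sub), k - 1))
  }))
}

# memoised wrapper
.path_cache <- new.env(parent = emptyenv())

#' Pathway-averaged substitution tallies between two codons
#'
#' @param a,b Codon strings (stops allowed; changes to/from a stop are
#'   nonsynonymous).
#' @return Named numeric: mean `syn` and `nonsyn` single-nucleotide steps
#'   over all stop-free orderings.
#' @export
codon_path_counts <- function(a, b) {
  key <- paste0(a, b)
  hit <- .path_cache[[key]]
  if (!is.null(hit)) return(hit)
  out <- .path_counts_raw(a, b)
  assign(key, out, envir = .path_cache)
  out
}

#' Parsimony lineage assignment of substitutions on a codon trio
#'
#' For each usable column the internal-node codon is inferred by two-of-three
#' agreement and changes are assigned to the branch whose tip differs. When
#' all three tips differ the internal state is set to the outgroup codon
#' (outgroup-rooting convention), assigning one change set to each ingroup
#' branch. Columns flagged unusable for parsimony (gaps, Ns) are skipped;
#' premature-stop columns are included, with stop-involving changes counted
#' as nonsynonymous. Site totals are computed over each tip's sense codons
#' in the counted columns, by default under the uniform-mutation
#' (Nei-Gojobori) convention; `sites = "mutational"` instead splits sites by
#' the stationary flow of the neutral model at `kappa`, which removes the
#' downward bias that uniform weighting gives Ka/Ks when transitions are
#' enriched (see [count_sites()]).
#'
#' @param alignment A masked `codon_trio_alignment` (see [mask_columns()]).
#' @param sites Site-counting convention: `"NG"` (default) or `"mutational"`.
#' @param kappa Transition/transversion ratio used by `sites = "mutational"`.
#' @return A tibble of class `branch_substitutions`, one row per branch:
#'   `branch`, `n_syn`, `n_nonsyn`, `syn_sites`, `nonsyn_sites`, `ka`, `ks`,
#'   `method = "parsimony"`.
#' @export
count_parsimony <- function(alignment, sites = c("NG", "mutational"), kappa = 2) {
  sites <- match.arg(sites)
  stopifnot(inherits(alignment, "codon_trio_alignment"))
  if (any(is.na(alignment$usable_parsimony))) alignment <- mask_columns(alignment)
  use <- alignment[alignment$usable_parsimony, , drop = FALSE]
  tally <- matrix(0, 3, 2, dimnames = list(.branches, c("syn", "nonsyn")))
  for (r in seq_len(nrow(use))) {
    h <- use$human[r]; c_ <- use$chimp[r]; o <- use$outgroup[r]
    if (h == c_ && c_ == o) next
    if (h == c_) {
      internal <- h
      tally["outgroup", ] <- tally["outgroup", ] + codon_path_counts(internal, o)
    } else if (h == o) {
      internal <- h
      tally["chimp", ] <- tally["chimp", ] + codon_path_counts(internal, c_)
    } else if (c_ == o) {
      internal <- c_
      tally["human", ] <- tally["human", ] + codon_path_counts(internal, h)
    } else {
      internal <- o
      tally["human", ] <- tally["human", ] + codon_path_counts(internal, h)
      tally["chimp", ] <- tally["chimp", ] + codon_path_counts(internal, c_)
    }
  }
  per_branch <- lapply(.branches, function(b) {
    tip <- use[[b]]
    sense <- tip[tip %in% .sense]
    st <- count_sites(sense, method = sites, kappa = kappa)
    tibble(
      branch = b,
      n_syn = tally[b, "syn"], n_nonsyn = tally[b, "nonsyn"],
      syn_sites = unname(st["syn_sites"]),
      nonsyn_sites = unname(st["nonsyn_sites"]),
      ka = if (st["nonsyn_sites"] > 0) tally[b, "nonsyn"] / st["nonsyn_sites"] else NA_real_,
      ks = if (st["syn_sites"] > 0) tally[b, "syn"] / st["syn_sites"] else NA_real_,
      method = "parsimony"
    )
  })
  out <- bind_rows(per_branch)
  attr(out, "gene_id") <- attr(alignment, "gene_id")
  class(out) <- c("branch_substitutions", class(out))
  out
}

#' Excess of nonsynonymous substitutions on the human lineage
#'
#' The screen's ranking statistic: (nonsynonymous changes assigned to the
#' human branch) minus (nonsynonymous changes assigned to the chimpanzee
#' branch). Positive values mean more changes on the human lineage.
#'
#' @param result A `branch_substitutions` table carrying human and chimp rows.
#' @return One-row tibble: `gene_id`, `excess`, `ka_human`, `ks_human`,
#'   `n_human`, `n_chimp`, `method`.
#' @export
excess_statistic <- function(result) {
  stopifnot(inherits(result, "branch_substitutions") ||
              all(c("branch", "n_nonsyn") %in% names(result)))
  hrow <- result[result$branch == "human", ]
  crow <- result[result$branch == "chimp", ]
  if (nrow(hrow) != 1 || nrow(crow) != 1) {
    abort("result must contain exactly one human and one chimp row")
  }
  tibble(
    gene_id = attr(result, "gene_id") %||% NA_character_,
    excess = hrow$n_nonsyn - crow$n_nonsyn,
    ka_human = hrow$ka, ks_human = hrow$ks,
    n_human = hrow$n_nonsyn, n_chimp = crow$n_nonsyn,
    method = hrow$method %||% NA_character_
  )
}
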