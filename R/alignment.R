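# In-frame codon alignment of a human/chimp/outgroup CDS trio: translate,
# align at the protein level (progressive pairwise-then-profile global
# alignment with affine gaps), back-translate to codons, and mask columns
# the substitution machinery must not use.

#' Construct a CDS trio
#'
#' @param gene_id Gene identifier.
#' @param human,chimp,outgroup In-frame coding sequences (A/C/G/T/N, length a
#'   multiple of 3). A missing leading ATG only warns: trios clipped to a
#'   shared open reading frame are common.
#' @return A `cds_trio` list.
#' @export
cds_trio <- function(gene_id, human, chimp, outgroup) {
  seqs <- c(human = toupper(human), chimp = toupper(chimp),
            outgroup = toupper(outgroup))
  for (role in names(seqs)) {
    s <- seqs[[role]]
    if (nchar(s) %% 3 != 0) {
      abort(sprintf("%s/%s: length %d not a multiple of 3", gene_id, role, nchar(s)))
    }
    if (grepl("[^ACGTN]", s)) {
      abort(sprintf("%s/%s: alphabet must be A/C/G/T/N", gene_id, role))
    }
    if (nchar(s) >= 3 && substr(s, 1, 3) != "ATG") {
      warn(sprintf("%s/%s does not start with ATG", gene_id, role))
    }
  }
  structure(list(gene_id = gene_id, sequences = as.list(seqs)),
            class = "cds_trio")
}

#' @export
print.cds_trio <- function(x, ...) {
  cat(sprintf("<cds_trio> %s: %s nt (human), %s nt (chimp), %s nt (outgroup)\n",
              x$gene_id, nchar(x$sequences$human), nchar(x$sequences$chimp),
              nchar(x$sequences$outgroup)))
  invisible(x)
}

.gap3 <- "---"

# tibble-backed codon alignment: one row per aligned codon column
.new_codon_alignment <- function(gene_id, human, chimp, outgroup) {
  out <- tibble(
    column = seq_along(human),
    human = human, chimp = chimp, outgroup = outgroup,
    usable_ml = NA, usable_parsimony = NA
  )
  attr(out, "gene_id") <- gene_id
  class(out) <- c("codon_trio_alignment", class(out))
  out
}

#' @export
print.codon_trio_alignment <- function(x, ...) {
  cat(sprintf("<codon_trio_alignment> %s: %d columns\n",
              attr(x, "gene_id") %||% "?", nrow(x)))
  NextMethod()
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.degap <- function(tokens) paste(tokens[tokens != .gap3], collapse = "")

# ---- protein-level global alignment -----------------------------------

.default_scoring <- function() {
  mat <- NULL
  utils::data("BLOSUM62", package = "Biostrings", envir = environment())
  list(matrix = get("BLOSUM62", envir = environment()),
       gap_open = 10, gap_extend = 0.5)
}

.score_lookup <- function(mat, a, b) {
  a[!a %in% rownames(mat)] <- "X"
  b[!b %in% colnames(mat)] <- "X"
  mat[cbind(a, b)]
}

# Affine-gap Needleman-Wunsch over two profiles (each a character matrix,
# rows = sequences, cols = alignment columns; "-" for gaps). Column-pair
# score is the mean substitution score over all non-gap residue pairs.
# Returns the merged profile.
.nw_profile <- function(prof_a, prof_b, scoring) {
  la <- ncol(prof_a); lb <- ncol(prof_b)
  smat <- scoring$matrix
  go <- scoring$gap_open; ge <- scoring$gap_extend
  # pairwise column scores
  colscore <- matrix(0, la, lb)
  for (i in seq_len(la)) {
    ra <- prof_a[, i]
    ra <- ra[ra != "-"]
    if (length(ra) == 0) { colscore[i, ] <- 0; next }
    for (j in seq_len(lb)) {
      rb <- prof_b[, j]
      rb <- rb[rb != "-"]
      if (length(rb) == 0) { colscore[i, j] <- 0; next }
      pairs <- expand.grid(a = ra, b = rb, stringsAsFactors = FALSE)
      colscore[i, j] <- mean(.score_lookup(smat, pairs$a, pairs$b))
    }
  }
  neg <- -Inf
  M <- matrix(neg, la + 1, lb + 1) # match/mismatch ends
  X <- matrix(neg, la + 1, lb + 1) # gap in B (consume A)
  Y <- matrix(neg, la + 1, lb + 1) # gap in A (consume B)
  M[1, 1] <- 0
  if (la >= 1) X[2:(la + 1), 1] <- -go - ge * (0:(la - 1))
  if (lb >= 1) Y[1, 2:(lb + 1)] <- -go - ge * (0:(lb - 1))
  ptrM <- matrix(0L, la + 1, lb + 1)
  ptrX <- matrix(0L, la + 1, lb + 1)
  ptrY <- matrix(0L, la + 1, lb + 1)
  for (i in seq_len(la)) {
    for (j in seq_len(lb)) {
      s <- colscore[i, j]
      cand <- c(M[i, j], X[i, j], Y[i, j])
      k <- which.max(cand)
      M[i + 1, j + 1] <- cand[k] + s
      ptrM[i + 1, j + 1] <- k
      candx <- c(M[i, j + 1] - go - ge, X[i, j + 1] - ge, Y[i, j + 1] - go - ge)
      kx <- which.max(candx)
      X[i + 1, j + 1] <- candx[kx]
      ptrX[i + 1, j + 1] <- kx
      candy <- c(M[i + 1, j] - go - ge, X[i + 1, j] - go - ge, Y[i + 1, j] - ge)
      ky <- which.max(candy)
      Y[i + 1, j + 1] <- candy[ky]
      ptrY[i + 1, j + 1] <- ky
    }
  }
  # traceback
  i <- la; j <- lb
  final <- c(M[la + 1, lb + 1], X[la + 1, lb + 1], Y[la + 1, lb + 1])
  state <- which.max(final)
  cols_a <- integer(0); cols_b <- integer(0) # 0 = gap column
  while (i > 0 || j > 0) {
    if (i == 0) {
      cols_a <- c(0L, cols_a); cols_b <- c(j, cols_b); j <- j - 1
    } else if (j == 0) {
      cols_a <- c(i, cols_a); cols_b <- c(0L, cols_b); i <- i - 1
    } else if (state == 1L) {
      cols_a <- c(i, cols_a); cols_b <- c(j, cols_b)
      state <- ptrM[i + 1, j + 1]
      i <- i - 1; j <- j - 1
    } else if (state == 2L) {
      cols_a <- c(i, cols_a); cols_b <- c(0L, cols_b)
      state <- ptrX[i + 1, j + 1]
      i <- i - 1
    } else {
      cols_a <- c(0L, cols_a); cols_b <- c(j, cols_b)
      state <- ptrY[i + 1, j + 1]
      j <- j - 1
    }
  }
  out_a <- matrix("-", nrow(prof_a), length(cols_a))
  out_a[, cols_a != 0] <- prof_a[, cols_a[cols_a != 0], drop = FALSE]
  out_b <- matrix("-", nrow(prof_b), length(cols_b))
  out_b[, cols_b != 0] <- prof_b[, cols_b[cols_b != 0], drop = FALSE]
  rbind(out_a, out_b)
}

#' Globally align the three proteins of a trio
#'
#' Progressive global alignment with affine gap penalties and a BLOSUM62
#' substitution matrix: the human and chimpanzee proteins (the most similar
#' pair) are aligned first, then the outgroup is aligned against that
#' two-sequence profile.
#'
#' @param proteins Named character vector or list with elements `human`,
#'   `chimp`, `outgroup`; non-empty amino-acid strings.
#' @param scoring List with `matrix` (substitution matrix), `gap_open`,
#'   `gap_extend`. Defaults to BLOSUM62 with open 10 / extend 0.5.
#' @return Named character vector of three equal-length gapped sequences.
#' @export
align_protein_trio <- function(proteins, scoring = .default_scoring()) {
  proteins <- lapply(.named3(unlist(proteins), "proteins"), as.character)
  if (any(nchar(proteins) == 0)) abort("empty protein sequence")
  ph <- matrix(strsplit(proteins$human, "")[[1]], nrow = 1)
  pc <- matrix(strsplit(proteins$chimp, "")[[1]], nrow = 1)
  po <- matrix(strsplit(proteins$outgroup, "")[[1]], nrow = 1)
  hc <- .nw_profile(ph, pc, scoring)
  all3 <- .nw_profile(hc, po, scoring)
  out <- apply(all3, 1, paste, collapse = "")
  names(out) <- .branches
  out
}

#' Back-translate a gapped protein alignment to codons
#'
#' Each amino acid is replaced by the codon it came from; each gap becomes the
#' three-character gap token `---`.
#'
#' @param protein_alignment Named character vector (`human`, `chimp`,
#'   `outgroup`) of equal-length gapped protein sequences.
#' @param trio The [cds_trio()] the proteins were translated from.
#' @return A `codon_trio_alignment` tibble (one row per codon column) with
#'   usability flags unset; run [mask_columns()] before counting.
#' @export
backtranslate <- function(protein_alignment, trio) {
  stopifnot(inherits(trio, "cds_trio"))
  protein_alignment <- .named3(unlist(protein_alignment), "protein_alignment")
  lens <- nchar(protein_alignment)
  if (length(unique(lens)) != 1) abort("gapped rows must have equal length")
  rows <- lapply(.branches, function(role) {
    prot <- strsplit(protein_alignment[[role]], "")[[1]]
    cds <- trio$sequences[[role]]
    codons <- .split_codons(cds)
    expect <- translate(cds)
    got <- paste(prot[prot != "-"], collapse = "")
    if (got != expect) {
      pos <- which(strsplit(expect, "")[[1]] != strsplit(got, "")[[1]])[1]
      abort(sprintf("protein/CDS mismatch for %s row at residue %s",
                    role, pos %||% "?"))
    }
    out <- rep(.gap3, length(prot))
    out[prot != "-"] <- codons
    out
  })
  names(rows) <- .branches
  .new_codon_alignment(trio$gene_id, rows$human, rows$chimp, rows$outgroup)
}

#' Build the masked codon alignment of a CDS trio
#'
#' Convenience wrapper: translate, align, back-translate, mask.
#'
#' @param trio A [cds_trio()].
#' @param scoring Protein alignment scoring, see [align_protein_trio()].
#' @return Masked `codon_trio_alignment`.
#' @export
align_trio <- function(trio, scoring = .default_scoring()) {
  prots <- vapply(trio$sequences[.branches], translate, character(1))
  mask_columns(backtranslate(align_protein_trio(prots, scoring), trio))
}

#' Flag alignment columns usable for substitution analysis
#'
#' Columns containing a gap or an `N` in any row are unusable everywhere.
#' Columns containing a stop codon are additionally excluded from
#' likelihood-based fitting (whose state space is the 61 sense codons) but
#' retained for parsimony/table-level classification, where changes to or
#' from a stop count as nonsynonymous.
#'
#' @param alignment A `codon_trio_alignment`.
#' @return The alignment with `usable_ml` and `usable_parsimony` filled in.
#' @export
mask_columns <- function(alignment) {
  stopifnot(inherits(alignment, "codon_trio_alignment"))
  tok <- cbind(alignment$human, alignment$chimp, alignment$outgroup)
  has_gap <- apply(tok == .gap3, 1, any)
  has_n <- apply(matrix(grepl("N", tok), nrow(tok)), 1, any)
  has_stop <- apply(matrix(tok %in% .stop_codons, nrow(tok)), 1, any)
  alignment$usable_parsimony <- !has_gap & !has_n
  alignment$usable_ml <- alignment$usable_parsimony & !has_stop
  alignment
}
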