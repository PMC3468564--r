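#' @importFrom rlang .data abort warn .env
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter select arrange bind_rows left_join group_by
#'   summarise ungroup row_number across all_of
#' @importFrom stats optim pchisq cor.test t.test rnorm rbinom runif anova lm
#'   setNames complete.cases
#' @importFrom utils combn
NULL

# Codon machinery shared by the simulator, the likelihood and the counters.
# All codon-indexed objects use the 61 sense codons of the standard code in
# lexicographic (A < C < G < T) order.

.nucs <- c("A", "C", "G", "T")

.codons64 <- as.vector(outer(outer(.nucs, .nucs, paste0), .nucs, paste0))
.codons64 <- sort(.codons64)

.stop_codons <- c("TAA", "TAG", "TGA")

#' The 61 sense codons of the standard genetic code
#'
#' Lexicographically ordered; this ordering indexes every codon-state vector
#' and rate matrix in the package.
#'
#' @return Character vector of length 61.
#' @export
sense_codons <- function() setdiff(.codons64, .stop_codons)

.sense <- setdiff(.codons64, .stop_codons)

# one-letter amino acid for each of the 64 codons (stop = "*")
.code64 <- local({
  gc <- Biostrings::GENETIC_CODE
  unname(gc[.codons64]) |> setNames(.codons64)
})

.aa_of <- function(codon) unname(.code64[codon])

# three-letter names as they appear in variant annotation tables
.aa3to1 <- c(
  Ala = "A", Arg = "R", Asn = "N", Asp = "D", Cys = "C", Gln = "Q",
  Glu = "E", Gly = "G", His = "H", Ile = "I", Leu = "L", Lys = "K",
  Met = "M", Phe = "F", Pro = "P", Ser = "S", Thr = "T", Trp = "W",
  Tyr = "Y", Val = "V", Stop = "*"
)

# transitions are A<->G and C<->T
.is_transition <- function(a, b) {
  (a == "A" & b == "G") | (a == "G" & b == "A") |
    (a == "C" & b == "T") | (a == "T" & b == "C")
}

# Pairwise structure over the 61 sense codons, computed once at load:
# single-nucleotide neighbours, transition flag, nonsynonymous flag.
.codon_pairs <- local({
  n <- length(.sense)
  mat <- do.call(rbind, strsplit(.sense, ""))
  single <- matrix(FALSE, n, n)
  trans <- matrix(FALSE, n, n)
  for (pos in 1:3) {
    other <- setdiff(1:3, pos)
    same_other <- outer(mat[, other[1]], mat[, other[1]], "==") &
      outer(mat[, other[2]], mat[, other[2]], "==")
    diff_here <- outer(mat[, pos], mat[, pos], "!=")
    hit <- same_other & diff_here
    single <- single | hit
    trans <- trans | (hit & outer(mat[, pos], mat[, pos], .is_transition))
  }
  aa <- .aa_of(.sense)
  list(single = single, transition = trans,
       nonsyn = outer(aa, aa, "!=") & single)
})

#' Translate an in-frame coding sequence
#'
#' Standard-code translation of a nucleotide string whose length is a multiple
#' of three. Stop codons translate to `"*"`; any codon containing `N` (or any
#' non-ACGT character) yields `"X"`.
#'
#' @param cds Nucleotide string (characters `A`, `C`, `G`, `T`, `N`).
#' @param code Named character vector mapping codons to one-letter amino
#'   acids; defaults to the standard genetic code.
#' @return Single amino-acid string.
#' @examples
#' translate("ATGCAC") # "MH"
#' translate("TGA")    # "*"
#' @export
translate <- function(cds, code = Biostrings::GENETIC_CODE) {
  stopifnot(is.character(cds), length(cds) == 1)
  cds <- toupper(cds)
  if (nchar(cds) %% 3 != 0) {
    abort(sprintf("CDS length %d is not a multiple of 3", nchar(cds)))
  }
  if (nchar(cds) == 0) return("")
  codons <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
  aa <- unname(code[codons])
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

.split_codons <- function(cds) {
  n <- nchar(cds)
  if (n == 0) return(character(0))
  substring(cds, seq(1, n, 3), seq(3, n, 3))
}
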