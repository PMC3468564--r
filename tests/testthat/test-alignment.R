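test_that("cds_trio validates its sequences", {
  expect_error(cds_trio("g", "ATGA", "ATGAAA", "ATGAAA"), "multiple of 3")
  expect_error(cds_trio("g", "ATGAAZ", "ATGAAA", "ATGAAA"), "alphabet")
  expect_warning(cds_trio("g", "CTGAAA", "ATGAAA", "ATGAAA"), "ATG")
})

test_that("identical proteins align gap-free", {
  al <- align_protein_trio(c(human = "MKVH", chimp = "MKVH", outgroup = "MKVH"))
  expect_identical(unname(al), rep("MKVH", 3))
})

test_that("a deleted residue is restored as an internal gap", {
  al <- align_protein_trio(c(human = "MKV", chimp = "MV", outgroup = "MKV"))
  expect_identical(unname(al["human"]), "MKV")
  expect_identical(unname(al["chimp"]), "M-V")
  expect_identical(unname(al["outgroup"]), "MKV")
})

test_that("pairwise alignment score attains the brute-force optimum", {
  scoring <- trioscan:::.default_scoring()
  set.seed(11)
  aas <- setdiff(rownames(scoring$matrix), c("B", "Z", "X", "*"))
  for (rep in 1:5) {
    a <- paste(sample(aas, sample(3:6, 1), replace = TRUE), collapse = "")
    b <- paste(sample(aas, sample(2:5, 1), replace = TRUE), collapse = "")
    prof <- trioscan:::.nw_profile(
      matrix(strsplit(a, "")[[1]], nrow = 1),
      matrix(strsplit(b, "")[[1]], nrow = 1), scoring)
    got <- oracle_align_score(paste(prof[1, ], collapse = ""),
                              paste(prof[2, ], collapse = ""),
                              scoring$matrix, scoring$gap_open, scoring$gap_extend)
    best <- oracle_best_alignment(a, b, scoring$matrix,
                                  scoring$gap_open, scoring$gap_extend)
    expect_equal(got, best)
  }
})

test_that("pairwise scores agree with an independent aligner", {
  # Biostrings charges gapOpening + gapExtension * L per run; our run cost is
  # gap_open + gap_extend * (L - 1), so gapOpening = 9.5 makes them identical
  scoring <- trioscan:::.default_scoring()
  set.seed(21)
  aas <- setdiff(rownames(scoring$matrix), c("B", "Z", "X", "*"))
  for (rep in 1:5) {
    a <- paste(sample(aas, 12, replace = TRUE), collapse = "")
    b <- paste(sample(aas, 10, replace = TRUE), collapse = "")
    prof <- trioscan:::.nw_profile(
      matrix(strsplit(a, "")[[1]], nrow = 1),
      matrix(strsplit(b, "")[[1]], nrow = 1), scoring)
    got <- oracle_align_score(paste(prof[1, ], collapse = ""),
                              paste(prof[2, ], collapse = ""),
                              scoring$matrix, scoring$gap_open, scoring$gap_extend)
    ref <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(a), Biostrings::AAString(b), type = "global",
      substitutionMatrix = scoring$matrix, gapOpening = 9.5,
      gapExtension = 0.5, scoreOnly = TRUE)
    expect_equal(got, ref)
  }
})

test_that("back-translation substitutes source codons and gap tokens", {
  trio <- cds_trio("g", "ATGGTT", "ATGGTT", "ATGGTT")
  aln <- backtranslate(c(human = "MV", chimp = "MV", outgroup = "MV"), trio)
  expect_identical(aln$human, c("ATG", "GTT"))
  gappy <- suppressWarnings(cds_trio("g", "ATGGTT", "ATGGTT", "GTT"))
  aln2 <- backtranslate(c(human = "M-V", chimp = "M-V", outgroup = "--V"), gappy)
  expect_identical(aln2$human, c("ATG", "---", "GTT"))
  expect_identical(aln2$outgroup, c("---", "---", "GTT"))
  expect_error(
    backtranslate(c(human = "MM", chimp = "MV", outgroup = "MV"), trio),
    "mismatch")
})

test_that("align-backtranslate round trip restores each CDS", {
  set.seed(31)
  for (rep in 1:10) {
    cfg <- trio_sim_config(sample(20:40, 1),
                           branch_lengths = c(human = 0.05, chimp = 0.05, outgroup = 0.1),
                           seed = 1000 + rep)
    sim <- simulate_codon_trio(cfg)
    seqs <- list(human = paste(sim$human, collapse = ""),
                 chimp = paste(sim$chimp, collapse = ""),
                 outgroup = paste(sim$outgroup, collapse = ""))
    # delete a couple of codons from the chimp CDS to force gaps
    codons <- trioscan:::.split_codons(seqs$chimp)
    drop <- sample(seq_along(codons), 2)
    seqs$chimp <- paste(codons[-drop], collapse = "")
    trio <- suppressWarnings(cds_trio("rt", seqs$human, seqs$chimp, seqs$outgroup))
    aln <- align_trio(trio)
    for (role in c("human", "chimp", "outgroup")) {
      restored <- paste(aln[[role]][aln[[role]] != "---"], collapse = "")
      expect_identical(restored, trio$sequences[[role]])
    }
  }
})

test_that("masking distinguishes gaps, Ns and premature stops", {
  aln <- make_alignment(c("ATG", "AAA", "TAA", "ANA"),
                        c("ATG", "---", "CAA", "AAA"),
                        c("ATG", "AAA", "CAA", "AAA"))
  expect_identical(aln$usable_parsimony, c(TRUE, FALSE, TRUE, FALSE))
  expect_identical(aln$usable_ml, c(TRUE, FALSE, FALSE, FALSE))
})
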