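# FASTA and manifest I/O for trio sequences.

#' Write a trio to FASTA
#'
#' Records are named `<gene>|human`, `<gene>|chimp`, `<gene>|outgroup`.
#' Alignments are written with their gap tokens; CDS trios ungapped.
#'
#' @param x A `cds_trio` or `codon_trio_alignment`.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_trio_fasta <- function(x, path) {
  if (inherits(x, "cds_trio")) {
    gid <- x$gene_id
    seqs <- unlist(x$sequences[.branches])
  } else if (inherits(x, "codon_trio_alignment")) {
    gid <- attr(x, "gene_id") %||% "gene"
    seqs <- c(human = paste(x$human, collapse = ""),
              chimp = paste(x$chimp, collapse = ""),
              outgroup = paste(x$outgroup, collapse = ""))
  } else {
    abort("`x` must be a cds_trio or codon_trio_alignment")
  }
  names(seqs) <- paste(gid, names(seqs), sep = "|")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Read a CDS trio from FASTA
#'
#' Expects records named `<gene>|human`, `<gene>|chimp`, `<gene>|outgroup`
#' (as written by [write_trio_fasta()]), or exactly three records in
#' human/chimp/outgroup order.
#'
#' @param path FASTA path.
#' @param gene_id Optional override of the gene id.
#' @return A [cds_trio()].
#' @export
read_trio_fasta <- function(path, gene_id = NULL) {
  ss <- Biostrings::readDNAStringSet(path)
  nm <- names(ss)
  roles <- sub("^.*\\|", "", nm)
  if (setequal(roles, .branches)) {
    gid <- gene_id %||% sub("\\|.*$", "", nm[1])
    seqs <- setNames(as.character(ss), roles)[.branches]
  } else if (length(ss) == 3) {
    gid <- gene_id %||% "gene"
    seqs <- setNames(as.character(ss), .branches)
  } else {
    abort("FASTA must contain a human/chimp/outgroup trio")
  }
  cds_trio(gid, seqs[["human"]], seqs[["chimp"]], seqs[["outgroup"]])
}

#' Read CDS trios from a FASTA file plus a manifest
#'
#' The manifest TSV has columns `gene_id`, `human_id`, `chimp_id`,
#' `outgroup_id` naming FASTA records.
#'
#' @param fasta_path FASTA with all sequences.
#' @param manifest_path Manifest TSV path.
#' @return Named list of [cds_trio()] objects.
#' @export
read_trio_manifest <- function(fasta_path, manifest_path) {
  ss <- Biostrings::readDNAStringSet(fasta_path)
  man <- readr::read_tsv(manifest_path, col_types = readr::cols(
    .default = readr::col_character()))
  needed <- c("gene_id", "human_id", "chimp_id", "outgroup_id")
  if (!all(needed %in% names(man))) {
    abort(sprintf("manifest must have columns %s", paste(needed, collapse = ", ")))
  }
  out <- lapply(seq_len(nrow(man)), function(i) {
    ids <- c(man$human_id[i], man$chimp_id[i], man$outgroup_id[i])
    missing_ids <- setdiff(ids, names(ss))
    if (length(missing_ids) > 0) {
      abort(sprintf("%s: FASTA record(s) not found: %s", man$gene_id[i],
                    paste(missing_ids, collapse = ", ")))
    }
    cds_trio(man$gene_id[i], as.character(ss[[ids[1]]]),
             as.character(ss[[ids[2]]]), as.character(ss[[ids[3]]]))
  })
  setNames(out, man$gene_id)
}

#' @exportS3Method generics::tidy
tidy.trio_ml_fit <- function(x, ...) {
  tibble(
    branch = .branches,
    omega = unname(x$params$omega_per_branch),
    branch_length = unname(x$params$branch_lengths),
    ka = x$counts$ka,
    ks = x$counts$ks
  )
}

#' @exportS3Method generics::glance
glance.trio_ml_fit <- function(x, ...) {
  tibble(loglik = x$loglik, kappa = x$params$kappa,
         n_columns = x$n_columns, convergence = x$convergence,
         degenerate = isTRUE(x$degenerate))
}
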