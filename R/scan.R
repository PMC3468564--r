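# Gene-set scan: run the per-gene lineage-substitution pipeline across many
# trios, rank by the excess-nonsynonymous statistic, and subset by genomic
# region around a focus gene.

#' Scan a collection of codon trio alignments
#'
#' Runs [count_parsimony()] or [fit_free_ratio()] on every alignment,
#' computes the excess statistic per gene, and ranks genes by excess in
#' descending order (ties broken by gene id). Per-gene failures are recorded
#' with a reason and excluded from the ranking; they never abort the scan.
#'
#' @param alignments Named list of `codon_trio_alignment` objects (names are
#'   gene ids; unnamed lists fall back on each alignment's own gene id).
#' @param method `"parsimony"` (default) or `"ml"`.
#' @param seed Seed forwarded to the ML optimizer starts.
#' @return Tibble of class `scan_table`: `gene_id`, `excess`, `ka_human`,
#'   `ks_human`, `n_human`, `n_chimp`, `method`, `rank`, plus a `failures`
#'   attribute (tibble of `gene_id`, `reason`).
#' @export
scan_genes <- function(alignments, method = c("parsimony", "ml"), seed = 1) {
  method <- match.arg(method)
  if (length(alignments) == 0) abort("empty alignment collection")
  ids <- names(alignments)
  if (is.null(ids)) {
    ids <- vapply(alignments, function(a) attr(a, "gene_id") %||% NA_character_,
                  character(1))
  }
  rows <- list()
  fails <- list()
  for (i in seq_along(alignments)) {
    gid <- ids[[i]]
    aln <- alignments[[i]]
    attr(aln, "gene_id") <- gid
    res <- tryCatch({
      counts <- if (method == "parsimony") count_parsimony(aln)
      else fit_free_ratio(aln, seed = seed)$counts
      attr(counts, "gene_id") <- gid
      excess_statistic(counts)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      fails[[length(fails) + 1]] <- tibble(gene_id = gid,
                                           reason = conditionMessage(res))
    } else {
      rows[[length(rows) + 1]] <- res
    }
  }
  if (length(rows) == 0) abort("every gene failed; nothing to rank")
  out <- bind_rows(rows) |>
    arrange(dplyr::desc(.data$excess), .data$gene_id) |>
    mutate(rank = row_number())
  attr(out, "failures") <- if (length(fails)) bind_rows(fails) else
    tibble(gene_id = character(0), reason = character(0))
  attr(out, "method") <- method
  class(out) <- c("scan_table", class(out))
  out
}

#' Subset a scan to a genomic window around a focus gene
#'
#' Retains genes on the focus gene's chromosome whose interval (1-based,
#' inclusive) intersects the focus interval widened by `window_bp` on each
#' side. The relative ranking of the full scan is preserved.
#'
#' @param table A `scan_table`.
#' @param loci Tibble of loci: `gene_id`, `chromosome`, `start`, `end`
#'   (1-based inclusive, `start <= end`).
#' @param focus Gene id of the focus gene (must be present in `table` and in
#'   `loci`).
#' @param window_bp Window half-width in base pairs (default 5,000,000).
#' @return The filtered `scan_table` joined to the locus columns.
#' @export
regional_subset <- function(table, loci, focus, window_bp = 5e6) {
  stopifnot(all(c("gene_id", "chromosome", "start", "end") %in% names(loci)))
  if (any(loci$start > loci$end)) abort("loci must satisfy start <= end")
  if (!(focus %in% table$gene_id)) abort(sprintf("focus gene '%s' absent from scan table", focus))
  frow <- loci[loci$gene_id == focus, ]
  if (nrow(frow) != 1) abort(sprintf("focus gene '%s' must appear exactly once in `loci`", focus))
  lo <- frow$start - window_bp
  hi <- frow$end + window_bp
  keep <- loci |>
    filter(.data$chromosome == frow$chromosome,
           .data$start <= hi, .data$end >= lo)
  out <- table |>
    filter(.data$gene_id %in% keep$gene_id) |>
    left_join(keep, by = "gene_id")
  class(out) <- c("scan_table", class(out))
  attr(out, "method") <- attr(table, "method")
  out
}

#' Plot-ready table for the excess-versus-Ka scatter
#'
#' Passes the human-branch Ka and the excess statistic through unchanged and
#' flags an optional highlight gene (the screen's "arrow" gene).
#'
#' @param table A `scan_table`.
#' @param highlight Optional gene id to flag.
#' @return Tibble: `gene_id`, `ka`, `excess`, `highlight`.
#' @export
scatter_data <- function(table, highlight = NULL) {
  if (nrow(table) == 0) abort("empty scan table")
  tibble(
    gene_id = table$gene_id,
    ka = table$ka_human,
    excess = table$excess,
    highlight = if (is.null(highlight)) FALSE else table$gene_id == highlight
  )
}

#' @exportS3Method ggplot2::autoplot
autoplot.scan_table <- function(object, highlight = NULL, ...) {
  dat <- scatter_data(object, highlight)
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$ka, y = .data$excess)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$highlight), show.legend = FALSE) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "black", `TRUE` = "red")) +
    ggplot2::labs(x = "Ka (human branch)",
                  y = "Excess nonsynonymous substitutions (human - chimp)")
  if (any(dat$highlight)) {
    p <- p + ggplot2::geom_text(
      data = dat[dat$highlight, ],
      ggplot2::aes(label = .data$gene_id), vjust = -1, colour = "red")
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
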