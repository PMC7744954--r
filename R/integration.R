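#' Per-cell gene-body methylation matrix
#'
#' Quantifies methylation over gene-body intervals in every cell
#' (delegating to [quantify_regions()]) and assembles a genes x cells
#' percentage matrix. A (gene, cell) entry is missing (`NA`) unless the
#' cell carries at least `min_calls` calls in that gene body — sparse
#' scBS-seq coverage makes low-count percentages unreliable.
#'
#' @param cells Named list of CpG call tables.
#' @param gene_intervals Domain set of gene bodies; `name` must be the
#'   gene id.
#' @param context Sequence context to quantify.
#' @param min_calls Minimum calls per (gene, cell) (default 5).
#' @return Numeric matrix (genes x cells) of percentages with `NA` for
#'   insufficient coverage.
#' @export
gene_body_methylation <- function(cells, gene_intervals, context = "CpG",
                                  min_calls = 5) {
  stopifnot(is.list(cells), !is.null(names(cells)))
  out <- matrix(NA_real_, nrow(gene_intervals), length(cells),
                dimnames = list(gene_intervals$name, names(cells)))
  for (i in seq_along(cells)) {
    q <- quantify_regions(cells[[i]], gene_intervals, context = context,
                          warn_unmatched = FALSE)
    ok <- q$total >= min_calls
    out[ok, i] <- q$pct[ok]
  }
  out
}

#' Per-cell correlation between expression and methylation of one gene
#'
#' Pearson correlation across cells between a gene's expression and its
#' gene-body methylation, using only cells with both measurements.
#'
#' @param expr_row Per-cell expression values (named or aligned with
#'   `meth_row`).
#' @param meth_row Per-cell gene-body methylation percentages (`NA` =
#'   missing).
#' @param min_cells Minimum co-observed cells to report a result
#'   (default 10).
#' @return A list: `n_cells`, `r`, `p` (two-sided t-based), `reported`
#'   (`FALSE` when too few cells), `constant` (`TRUE` when either
#'   vector is constant, leaving `r` undefined).
#' @export
expr_meth_correlation <- function(expr_row, meth_row, min_cells = 10) {
  ok <- !is.na(expr_row) & !is.na(meth_row)
  x <- expr_row[ok]; y <- meth_row[ok]
  n <- length(x)
  if (n < min_cells)
    return(list(n_cells = n, r = NA_real_, p = NA_real_,
                reported = FALSE, constant = NA))
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(n_cells = n, r = NA_real_, p = NA_real_,
                reported = TRUE, constant = TRUE))
  ct <- stats::cor.test(x, y, method = "pearson")
  list(n_cells = n, r = unname(ct$estimate), p = ct$p.value,
       reported = TRUE, constant = FALSE)
}

#' Couple gene expression with gene-body methylation across a gene set
#'
#' For every gene with both an expression row and a methylation row,
#' computes the per-cell Pearson coupling ([expr_meth_correlation()]),
#' the group difference in merged methylation (aged minus young
#' percentage points, pooling calls over cells of each group), and the
#' log2 fold change of mean normalised expression (aged vs young).
#'
#' @param expr Genes x cells log-normalised (or normalised) expression
#'   matrix.
#' @param meth Genes x cells gene-body methylation matrix from
#'   [gene_body_methylation()].
#' @param meth_counts Optional list of `meth`/`total` count matrices
#'   (as from [domain_counts()] on the gene intervals) used for the
#'   merged group methylation difference; when `NULL` the difference is
#'   the difference of group means of the percentage matrix.
#' @param age_groups Named vector of `"young"`/`"aged"` labels covering
#'   the methylation cells.
#' @param lfc Optional named per-gene log2 fold change (aged vs young)
#'   from [differential_mean_test()]; computed from `expr` group means
#'   when `NULL`.
#' @param min_cells Minimum co-observed cells per gene (default 10).
#' @return A `data.frame` per gene: `gene`, `n_cells`, `r`, `p`,
#'   `meth_diff_pp`, `lfc`, `reported`.
#' @export
couple_genes <- function(expr, meth, age_groups, meth_counts = NULL,
                         lfc = NULL, min_cells = 10) {
  genes <- intersect(rownames(expr), rownames(meth))
  shared <- intersect(colnames(expr), colnames(meth))
  stopifnot(length(genes) >= 1L, length(shared) >= 1L)
  ag <- age_groups[colnames(meth)]
  rows <- lapply(genes, function(g) {
    cc <- expr_meth_correlation(expr[g, shared], meth[g, shared],
                                min_cells = min_cells)
    if (is.null(meth_counts)) {
      md <- mean(meth[g, ag == "aged"], na.rm = TRUE) -
        mean(meth[g, ag == "young"], na.rm = TRUE)
    } else {
      pooled <- function(grp) {
        cols <- colnames(meth_counts$total)[ag[colnames(meth_counts$total)] == grp]
        tot <- sum(meth_counts$total[g, cols])
        if (tot == 0) return(NA_real_)
        100 * sum(meth_counts$meth[g, cols]) / tot
      }
      md <- pooled("aged") - pooled("young")
    }
    fc <- if (!is.null(lfc)) unname(lfc[g]) else {
      ge <- expr[g, ]
      grp <- age_groups[colnames(expr)]
      log2(mean(2^ge[grp == "aged"] - 1) + 1) -
        log2(mean(2^ge[grp == "young"] - 1) + 1)
    }
    data.frame(gene = g, n_cells = cc$n_cells, r = cc$r, p = cc$p,
               meth_diff_pp = md, lfc = fc, reported = cc$reported,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Overlap DMRs with gene intervals
#'
#' Half-open interval intersection (>= 1 bp) between DMR intervals and
#' gene bodies; many-to-many pairs are returned.
#'
#' @param dmrs Domain set of DMR intervals.
#' @param gene_intervals Domain set of gene bodies (`name` = gene id).
#' @return A list: `pairs` (`data.frame` of `dmr`, `gene`),
#'   `n_dmrs_overlapping`, `n_genes_overlapping`.
#' @export
overlap_dmrs_with_genes <- function(dmrs, gene_intervals) {
  if (nrow(dmrs) == 0L || nrow(gene_intervals) == 0L)
    return(list(pairs = data.frame(dmr = character(), gene = character(),
                                   stringsAsFactors = FALSE),
                n_dmrs_overlapping = 0L, n_genes_overlapping = 0L))
  hits <- GenomicRanges::findOverlaps(domains_to_granges(dmrs),
                                      domains_to_granges(gene_intervals))
  pairs <- data.frame(dmr = dmrs$name[S4Vectors::queryHits(hits)],
                      gene = gene_intervals$name[S4Vectors::subjectHits(hits)],
                      stringsAsFactors = FALSE)
  list(pairs = pairs,
       n_dmrs_overlapping = length(unique(pairs$dmr)),
       n_genes_overlapping = length(unique(pairs$gene)))
}

#' Concordance of expression fold change and methylation difference
#'
#' Pearson correlation, across genes, between the log2 expression fold
#' change and the merged methylation difference — positive when
#' age-related transcription changes feed forward into gene-body
#' methylation changes in the same direction.
#'
#' @param coupling Coupling table from [couple_genes()] (needs `lfc`
#'   and `meth_diff_pp`).
#' @return A list: `r`, `p`, `n_genes`, `skipped` (`TRUE` when fewer
#'   than 3 complete genes).
#' @export
foldchange_vs_methdiff <- function(coupling) {
  ok <- stats::complete.cases(coupling[, c("lfc", "meth_diff_pp")])
  d <- coupling[ok, , drop = FALSE]
  if (nrow(d) < 3L)
    return(list(r = NA_real_, p = NA_real_, n_genes = nrow(d),
                skipped = TRUE))
  ct <- stats::cor.test(d$lfc, d$meth_diff_pp, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n_genes = nrow(d),
       skipped = FALSE)
}

#' Correlation between CpG and non-CpG gene-body methylation
#'
#' For each gene, Pearson correlation across cells between gene-body
#' CpG and non-CpG (CHG+CHH) methylation percentages. Non-CpG
#' methylation in oocytes shares the targeting of de novo CpG
#' methylation, so a positive correlation is the biological
#' expectation.
#'
#' @param cells Named list of CpG call tables carrying both contexts.
#' @param gene_intervals Domain set of gene bodies.
#' @param min_calls Minimum calls per (gene, cell, context) (default 5).
#' @param min_cells Minimum co-observed cells per gene (default 10).
#' @return A `data.frame` per gene: `gene`, `n_cells`, `r`, `p`,
#'   `flagged` (insufficient co-observation or a constant context).
#' @export
cpg_vs_noncpg_correlation <- function(cells, gene_intervals,
                                      min_calls = 5, min_cells = 10) {
  cpg <- gene_body_methylation(cells, gene_intervals, context = "CpG",
                               min_calls = min_calls)
  ncp <- gene_body_methylation(cells, gene_intervals, context = "nonCpG",
                               min_calls = min_calls)
  rows <- lapply(rownames(cpg), function(g) {
    cc <- expr_meth_correlation(cpg[g, ], ncp[g, ], min_cells = min_cells)
    data.frame(gene = g, n_cells = cc$n_cells, r = cc$r, p = cc$p,
               flagged = !cc$reported || isTRUE(cc$constant),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
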