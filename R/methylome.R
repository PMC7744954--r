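#' Global methylation level of a cell
#'
#' Per-call global methylation: `100 * sum(meth) / sum(meth + unmeth)`
#' over all records of the requested context. With single-read binary
#' calls (the scBS-seq situation) per-call and per-site averages
#' coincide.
#'
#' @param calls A CpG call table.
#' @param context Context to summarise (`"CpG"`, `"CHG"`, `"CHH"`, or
#'   `"nonCpG"` for CHG+CHH combined).
#' @return Percentage in `[0, 100]`, or `NA_real_` (with a warning) when
#'   the context has no calls — never 0.
#' @export
global_methylation <- function(calls, context = "CpG") {
  sub <- subset_context(calls, context)
  if (nrow(sub) == 0L) {
    warning("no calls in context ", context, "; methylation undefined")
    return(NA_real_)
  }
  100 * sum(sub$meth) / sum(sub$meth + sub$unmeth)
}

subset_context <- function(calls, context) {
  if (identical(context, "nonCpG"))
    calls[calls$context %in% c("CHG", "CHH"), , drop = FALSE]
  else calls[calls$context == context, , drop = FALSE]
}

#' Per-cell QC metrics for single-cell methylomes
#'
#' Computes, per cell: the number of CpG sites covered, global CpG and
#' non-CpG methylation percentages, and average methylation over
#' X-chromosome CpG islands (a granulosa-cell contamination proxy:
#' somatic cells carry a methylated inactive X, oocytes do not).
#'
#' @param cells Named list of CpG call tables (names are cell ids).
#' @param x_cgi Optional domain set of X-chromosome CpG islands.
#' @param mapping_efficiency Optional named numeric vector of alignment
#'   mapping efficiencies (percent), as upstream metadata.
#' @return A `data.frame` with one row per cell: `cell_id`, `n_cpgs`,
#'   `global_cpg_pct`, `global_noncpg_pct`, `x_cgi_pct`,
#'   `mapping_efficiency`.
#' @export
methylome_qc <- function(cells, x_cgi = NULL, mapping_efficiency = NULL) {
  stopifnot(is.list(cells), length(cells) >= 1L)
  if (is.null(names(cells))) names(cells) <- paste0("cell_", seq_along(cells))
  rows <- lapply(names(cells), function(id) {
    calls <- cells[[id]]
    cpg <- subset_context(calls, "CpG")
    ncp <- subset_context(calls, "nonCpG")
    xp <- NA_real_
    if (!is.null(x_cgi) && nrow(cpg) > 0L) {
      # autosomal calls legitimately fall outside the X-island panel
      q <- quantify_regions(cpg, x_cgi, context = "CpG",
                            warn_unmatched = FALSE)
      tot <- sum(q$total, na.rm = TRUE)
      if (tot > 0) xp <- 100 * sum(q$meth, na.rm = TRUE) / tot
    }
    data.frame(
      cell_id = id,
      n_cpgs = nrow(cpg),
      global_cpg_pct = if (nrow(cpg)) 100 * sum(cpg$meth) / sum(cpg$meth + cpg$unmeth) else NA_real_,
      global_noncpg_pct = if (nrow(ncp)) 100 * sum(ncp$meth) / sum(ncp$meth + ncp$unmeth) else NA_real_,
      x_cgi_pct = xp,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$mapping_efficiency <-
    if (is.null(mapping_efficiency)) NA_real_
    else unname(mapping_efficiency[out$cell_id])
  out
}

#' Default QC thresholds for scBS-seq libraries
#'
#' Libraries are discarded when mapping efficiency is below 10%, fewer
#' than 500,000 CpGs are covered, more than 50% of covered CpGs are
#' methylated, or X-chromosome CpG-island methylation reaches 10%
#' (oocytes sit below 10%, contaminating granulosa cells above 20%, so
#' 10% is a safe cut).
#'
#' @param min_mapping_efficiency Minimum mapping efficiency (percent).
#' @param min_cpgs Minimum number of CpG sites covered.
#' @param max_global_meth Maximum global CpG methylation (percent).
#' @param max_x_cgi X-CGI methylation at or above this is contamination.
#' @return A named list of thresholds.
#' @export
qc_thresholds <- function(min_mapping_efficiency = 10,
                          min_cpgs = 500000,
                          max_global_meth = 50,
                          max_x_cgi = 10) {
  list(min_mapping_efficiency = min_mapping_efficiency,
       min_cpgs = min_cpgs,
       max_global_meth = max_global_meth,
       max_x_cgi = max_x_cgi)
}

#' Filter cells on scBS-seq QC rules
#'
#' Applies the QC rules of [qc_thresholds()] to a metrics table
#' (see [methylome_qc()]). Each discarded cell is annotated with every
#' rule it violated. The mapping-efficiency rule is evaluated only for
#' cells whose metadata carries a value; the X-CGI rule requires the
#' `x_cgi_pct` column to be populated when `check_x_cgi = TRUE`.
#'
#' @param metrics QC metrics `data.frame` from [methylome_qc()].
#' @param thresholds A list from [qc_thresholds()].
#' @param check_x_cgi Enable the X-CGI contamination check.
#' @return A list with `kept` and `discarded` (`metrics` rows plus a
#'   `reasons` column: `""` for kept cells, otherwise comma-separated
#'   rule names among `min_mapping_efficiency`, `min_cpgs`,
#'   `max_global_meth`, `x_cgi_contamination`).
#' @export
qc_filter <- function(metrics, thresholds = qc_thresholds(),
                      check_x_cgi = TRUE) {
  stopifnot(is.data.frame(metrics), nrow(metrics) >= 1L)
  if (check_x_cgi && all(is.na(metrics$x_cgi_pct)))
    stop("X-CGI check enabled but no x_cgi_pct values are available; ",
         "supply X-chromosome CpG island intervals to methylome_qc()")
  reasons <- lapply(seq_len(nrow(metrics)), function(i) {
    r <- character()
    me <- metrics$mapping_efficiency[i]
    if (!is.na(me) && me < thresholds$min_mapping_efficiency)
      r <- c(r, "min_mapping_efficiency")
    if (metrics$n_cpgs[i] < thresholds$min_cpgs)
      r <- c(r, "min_cpgs")
    if (!is.na(metrics$global_cpg_pct[i]) &&
          metrics$global_cpg_pct[i] > thresholds$max_global_meth)
      r <- c(r, "max_global_meth")
    if (check_x_cgi && !is.na(metrics$x_cgi_pct[i]) &&
          metrics$x_cgi_pct[i] >= thresholds$max_x_cgi)
      r <- c(r, "x_cgi_contamination")
    r
  })
  metrics$reasons <- vapply(reasons, paste, character(1), collapse = ",")
  keep <- lengths(reasons) == 0L
  list(kept = metrics[keep, , drop = FALSE],
       discarded = metrics[!keep, , drop = FALSE])
}

#' Quantify methylation over a set of regions
#'
#' Sums methylated and total calls of all sites falling in each region.
#' Regions are BED-style 0-based half-open; a 1-based call at position
#' `p` belongs to `[start, end)` iff `start < p <= end`. Regions with no
#' covered site are reported as missing (`pct = NA`), never as 0%.
#'
#' @param calls A CpG call table.
#' @param regions A domain set.
#' @param context Context to quantify (`"CpG"`, `"CHG"`, `"CHH"`,
#'   `"nonCpG"`).
#' @param warn_unmatched Warn when call chromosomes are absent from the
#'   region set.
#' @return A `data.frame` with one row per region: `name`, `class`,
#'   `meth`, `total`, `pct`.
#' @export
quantify_regions <- function(calls, regions, context = "CpG",
                             warn_unmatched = TRUE) {
  sub <- subset_context(calls, context)
  meth <- integer(nrow(regions)); total <- integer(nrow(regions))
  if (nrow(sub) > 0L) {
    # the seqinfo-merge warning duplicates the curated unmatched-chromosome
    # warning emitted below
    hits <- suppressWarnings(
      GenomicRanges::findOverlaps(calls_to_granges(sub),
                                  domains_to_granges(regions)))
    qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
    if (length(qh)) {
      meth  <- as.integer(rowsum_by(sub$meth[qh], sh, nrow(regions)))
      total <- as.integer(rowsum_by(sub$meth[qh] + sub$unmeth[qh], sh,
                                    nrow(regions)))
    }
    if (warn_unmatched) {
      unmatched <- !(sub$chrom %in% regions$chrom)
      if (any(unmatched))
        warning(sum(unmatched), " call(s) on chromosomes absent from ",
                "the region set (e.g. ", sub$chrom[which(unmatched)[1]], ")")
    }
  }
  data.frame(name = regions$name, class = regions$class,
             meth = meth, total = total,
             pct = ifelse(total > 0, 100 * meth / pmax(total, 1L), NA_real_),
             stringsAsFactors = FALSE)
}

rowsum_by <- function(x, index, n) {
  out <- numeric(n)
  s <- rowsum(x, index)
  out[as.integer(rownames(s))] <- s[, 1L]
  out
}

#' Merge single-cell call tables into a pseudobulk
#'
#' Counts are summed per (chromosome, position, context) across cells,
#' so a pseudobulk conserves every call of its member cells.
#'
#' @param cells List of CpG call tables.
#' @return A single merged CpG call table.
#' @export
merge_cells <- function(cells) {
  stopifnot(is.list(cells), length(cells) >= 1L)
  all <- do.call(rbind, lapply(cells, validate_calls))
  if (nrow(all) == 0L) return(empty_calls())
  key <- paste(all$chrom, all$pos, all$context, sep = "\r")
  meth <- rowsum(all$meth, key)
  unmeth <- rowsum(all$unmeth, key)
  first <- all[!duplicated(key), c("chrom", "pos", "context")]
  ord_key <- sort(unique(key))
  first <- first[match(ord_key, key[!duplicated(key)]), ]
  out <- data.frame(first,
                    meth = as.integer(meth[ord_key, 1L]),
                    unmeth = as.integer(unmeth[ord_key, 1L]),
                    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$pos, out$context), ]
  rownames(out) <- NULL
  out
}

#' Methylation of germline DMRs per merged group
#'
#' Quantifies methylation over imprinted germline DMRs (and related
#' control regions) in group-merged data, e.g. young vs aged pseudobulk
#' methylomes. Maternal gDMRs are expected highly methylated in oocytes
#' regardless of age; paternal gDMRs unmethylated. No thresholding is
#' applied; cells of the matrix without coverage are `NA`.
#'
#' @param groups Named list of merged CpG call tables (e.g.
#'   `list(young = ..., aged = ...)`).
#' @param gdmrs Domain set of gDMR intervals.
#' @return A numeric matrix, rows = gDMRs, columns = groups, percent
#'   methylation.
#' @export
gdmr_panel <- function(groups, gdmrs) {
  if (is.null(gdmrs) || nrow(gdmrs) == 0L)
    stop("an empty gDMR interval set was supplied")
  stopifnot(is.list(groups), !is.null(names(groups)))
  out <- vapply(groups, function(g)
    quantify_regions(g, gdmrs, warn_unmatched = FALSE)$pct,
    numeric(nrow(gdmrs)))
  out <- matrix(out, nrow = nrow(gdmrs),
                dimnames = list(gdmrs$name, names(groups)))
  out
}

#' Compare two groups of values with a rank-sum test
#'
#' Two-sided Wilcoxon rank-sum test; the exact null distribution is
#' enumerated for combined sample sizes up to 20 (without ties), and the
#' tie-corrected normal approximation used otherwise.
#'
#' @param values_a,values_b Numeric vectors (each of length >= 2).
#' @return A list with `statistic` (Mann-Whitney W for group a), `p`,
#'   and `method`.
#' @export
group_compare <- function(values_a, values_b) {
  stopifnot(length(values_a) >= 2L, length(values_b) >= 2L)
  n <- length(values_a) + length(values_b)
  ties <- anyDuplicated(c(values_a, values_b)) > 0L
  if (all(values_a == values_a[1L]) && all(values_b == values_b[1L]) &&
        values_a[1L] == values_b[1L]) {
    return(list(statistic = length(values_a) * length(values_b) / 2,
                p = 1, method = "degenerate (all values tied)"))
  }
  exact <- n <= 20L && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(values_a, values_b, exact = exact, correct = !exact))
  p <- wt$p.value
  if (is.na(p)) p <- 1
  list(statistic = unname(wt$statistic), p = min(p, 1),
       method = if (exact) "exact" else "normal approximation")
}
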