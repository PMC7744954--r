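#' Median-of-ratios size factors
#'
#' Per-cell size factors by the median-of-ratios method: each cell's
#' factor is the median, over genes with a nonzero geometric mean across
#' cells, of the ratio of the cell's count to that geometric mean.
#' Factors are rescaled to geometric mean 1. When no gene is expressed
#' in every cell the method is undefined and the function falls back to
#' total-count scaling (flagged via the `"fallback"` attribute and a
#' warning).
#'
#' @param counts Genes x cells count matrix.
#' @return Named numeric vector of per-cell size factors (geometric
#'   mean 1).
#' @export
size_factors <- function(counts) {
  stopifnot(ncol(counts) >= 2L)
  all_expr <- rowSums(counts > 0) == ncol(counts)
  if (!any(all_expr)) {
    warning("no gene is expressed in all cells; ",
            "falling back to total-count size factors")
    sf <- colSums(counts)
    sf <- sf / exp(mean(log(sf)))
    attr(sf, "fallback") <- "total_count"
    return(sf)
  }
  ref <- exp(rowMeans(log(counts[all_expr, , drop = FALSE])))
  sf <- apply(counts[all_expr, , drop = FALSE], 2, function(x) stats::median(x / ref))
  sf <- sf / exp(mean(log(sf)))
  sf
}

#' Log-normalised expression
#'
#' `log2(count / size_factor + 1)`, the transform used throughout the
#' downstream transcriptome analyses.
#'
#' @param counts Genes x cells count matrix.
#' @param sf Per-cell size factors; computed with [size_factors()] when
#'   missing.
#' @return Numeric matrix of the same shape.
#' @export
log_normalize <- function(counts, sf = NULL) {
  if (is.null(sf)) sf <- size_factors(counts)
  log2(sweep(counts, 2, sf, "/") + 1)
}

#' Transcript diversity per cell
#'
#' Number of genes detected at >= 1 raw count in each cell, the simplest
#' readout of transcriptome complexity.
#'
#' @param counts Genes x cells count matrix.
#' @return Named integer vector, one entry per cell.
#' @export
transcript_diversity <- function(counts) {
  colSums(counts >= 1L)
}

#' Classify chromatin state from an SN signature
#'
#' Oocytes are split into NSN (non-surrounded nucleolus, transcriptionally
#' active) and SN (surrounded nucleolus, silent, developmentally more
#' competent) states using genes known to be overexpressed at least
#' two-fold in SN oocytes. Cells are clustered hierarchically (Ward
#' linkage on Euclidean distances of per-gene z-scored log-normalised
#' signature expression) and cut into two clusters; the cluster with the
#' higher mean signature expression is labelled SN.
#'
#' @param counts Genes x cells count matrix.
#' @param signature Character vector of SN-overexpressed gene ids;
#'   unresolvable ids are dropped with a warning.
#' @param sf Optional size factors.
#' @return Character vector of labels (`"NSN"`/`"SN"`) named by cell,
#'   with attribute `"n_signature_used"`.
#' @export
classify_chromatin_state <- function(counts, signature, sf = NULL) {
  stopifnot(ncol(counts) >= 2L)
  found <- intersect(signature, rownames(counts))
  if (length(found) < length(signature))
    warning(length(signature) - length(found),
            " signature gene(s) not present in the matrix")
  if (length(found) < 5L)
    stop("need at least 5 resolvable signature genes; got ", length(found))
  ln <- log_normalize(counts, sf)[found, , drop = FALSE]
  sds <- apply(ln, 1, stats::sd)
  z <- ln[sds > 0, , drop = FALSE]
  if (nrow(z) == 0L) {
    warning("cells are indistinguishable on the signature; all labelled NSN")
    labels <- rep("NSN", ncol(counts))
    names(labels) <- colnames(counts)
    attr(labels, "n_signature_used") <- length(found)
    return(labels)
  }
  z <- t(scale(t(z)))
  hc <- stats::hclust(stats::dist(t(z)), method = "ward.D2")
  cl <- stats::cutree(hc, k = 2)
  mean_sig <- tapply(colMeans(ln), cl, mean)
  sn_cluster <- as.integer(names(which.max(mean_sig)))
  labels <- ifelse(cl == sn_cluster, "SN", "NSN")
  names(labels) <- colnames(counts)
  attr(labels, "n_signature_used") <- length(found)
  labels
}

#' Fisher's exact test on a 2x2 table
#'
#' Exact two-sided p-value: the sum of hypergeometric probabilities of
#' all tables (with the observed margins) no more probable than the
#' observed one.
#'
#' @param table_2x2 A 2x2 matrix of non-negative integer counts.
#' @return Two-sided p-value (1 for tables with a zero margin).
#' @export
fisher_proportion_test <- function(table_2x2) {
  m <- as.matrix(table_2x2)
  stopifnot(all(dim(m) == c(2L, 2L)), all(m >= 0), all(m == round(m)))
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) return(1)
  stats::fisher.test(m)$p.value
}

#' Principal components and covariate associations
#'
#' PCA on per-gene z-scored log-normalised expression of the
#' highest-variance genes, followed by a per-covariate simple linear
#' regression of each of the leading principal components on the
#' covariate (overall F-test p-value; factors enter as factors).
#'
#' @param counts Genes x cells count matrix.
#' @param covariates `data.frame` of per-cell covariates (rows aligned
#'   with the matrix columns), e.g. age group, chromatin state, number
#'   of detected genes.
#' @param n_top Number of top-variance genes (default 2000, capped at
#'   the number of informative genes).
#' @param n_pcs Number of leading components to score (default 5).
#' @param sf Optional size factors.
#' @return A list: `scores` (cells x PCs), `p` (covariates x PCs matrix
#'   of association p-values, `NA` for constant covariates),
#'   `var_explained`.
#' @export
pca_with_associations <- function(counts, covariates, n_top = 2000,
                                  n_pcs = 5, sf = NULL) {
  stopifnot(ncol(counts) >= 6L, nrow(covariates) == ncol(counts))
  ln <- log_normalize(counts, sf)
  v <- apply(ln, 1, stats::var)
  keep <- order(v, decreasing = TRUE)[seq_len(min(n_top, sum(v > 0)))]
  z <- t(scale(t(ln[keep, , drop = FALSE])))
  pc <- stats::prcomp(t(z), center = FALSE, scale. = FALSE)
  n_pcs <- min(n_pcs, ncol(pc$x))
  scores <- pc$x[, seq_len(n_pcs), drop = FALSE]
  p <- matrix(NA_real_, ncol(covariates), n_pcs,
              dimnames = list(names(covariates), colnames(scores)))
  for (j in seq_along(covariates)) {
    x <- covariates[[j]]
    if (length(unique(x[!is.na(x)])) < 2L) {
      warning("covariate ", names(covariates)[j], " is constant; skipped")
      next
    }
    if (is.character(x)) x <- factor(x)
    for (k in seq_len(n_pcs)) {
      fit <- stats::lm(scores[, k] ~ x)
      f <- summary(fit)$fstatistic
      p[j, k] <- stats::pf(f[1L], f[2L], f[3L], lower.tail = FALSE)
    }
  }
  list(scores = scores, p = p,
       var_explained = pc$sdev^2 / sum(pc$sdev^2))
}

#' Differential mean expression between two groups
#'
#' Per-gene two-sided Wilcoxon rank-sum test on size-factor-normalised
#' counts, with the log2 fold change of normalised group means
#' (pseudocount 1) and Benjamini-Hochberg adjustment. Genes with zero
#' counts in every cell are excluded and reported.
#'
#' @param counts Genes x cells count matrix.
#' @param groups Per-cell group labels (exactly two levels, e.g.
#'   `young`/`aged`); the log2 fold change is second level vs first
#'   (levels sorted, or factor levels as given).
#' @param sf Optional size factors.
#' @return A `data.frame` per tested gene: `gene`, `lfc`, `p`, `q`;
#'   excluded all-zero genes in attribute `"excluded"`.
#' @export
differential_mean_test <- function(counts, groups, sf = NULL) {
  groups <- as.factor(groups)
  stopifnot(nlevels(groups) == 2L, all(table(groups) >= 3L))
  if (is.null(sf)) sf <- size_factors(counts)
  norm <- sweep(counts, 2, sf, "/")
  nonzero <- rowSums(counts) > 0
  excluded <- rownames(counts)[!nonzero]
  norm <- norm[nonzero, , drop = FALSE]
  g1 <- groups == levels(groups)[1L]; g2 <- !g1
  lfc <- log2(rowMeans(norm[, g2, drop = FALSE]) + 1) -
    log2(rowMeans(norm[, g1, drop = FALSE]) + 1)
  p <- apply(norm, 1, function(x)
    suppressWarnings(stats::wilcox.test(x[g2], x[g1], exact = FALSE)$p.value))
  p[is.na(p)] <- 1  # constant genes
  out <- data.frame(gene = rownames(norm), lfc = lfc, p = p,
                    q = bh_fdr(p), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  out
}

#' Differential expression variability between two groups
#'
#' Tests, per gene, whether expression is more (or less) variable in
#' one group after removing the mean-variance trend. The statistic is
#' the difference (second group minus first) of residual log squared
#' coefficients of variation: within each group, `log CV^2` is
#' regressed on `log mean` across genes and the per-gene residual
#' taken. Significance comes from a group-label permutation null
#' (labels shuffled, statistic recomputed), with Benjamini-Hochberg
#' adjustment at a default 10% FDR.
#'
#' @param counts Genes x cells count matrix.
#' @param groups Two-level per-cell labels; >= 10 cells per group.
#' @param sf Optional size factors.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Seed for the permutation stream.
#' @param min_cells_expressed Genes expressed in fewer cells than this
#'   per group are excluded (default 5).
#' @return A `data.frame` per tested gene: `gene`, `statistic`
#'   (residual log CV^2 difference, positive = more variable in the
#'   second group), `p`, `q`.
#' @export
differential_variability_test <- function(counts, groups, sf = NULL,
                                          n_perm = 1000, seed = 1,
                                          min_cells_expressed = 5) {
  groups <- as.factor(groups)
  stopifnot(nlevels(groups) == 2L, all(table(groups) >= 10L))
  if (is.null(sf)) sf <- size_factors(counts)
  norm <- sweep(counts, 2, sf, "/")
  g2 <- groups == levels(groups)[2L]
  keep <- rowSums(counts[, !g2, drop = FALSE] > 0) >= min_cells_expressed &
    rowSums(counts[, g2, drop = FALSE] > 0) >= min_cells_expressed
  norm <- norm[keep, , drop = FALSE]
  if (nrow(norm) < 2L) stop("fewer than 2 genes pass the expression filter")

  obs <- resid_cv2(norm, g2) - resid_cv2(norm, !g2)
  n_cells <- ncol(norm)
  exceed <- numeric(nrow(norm))
  withr_seed(seed, {
    for (b in seq_len(n_perm)) {
      perm <- sample(n_cells)
      pg2 <- g2[perm]
      stat <- resid_cv2(norm, pg2) - resid_cv2(norm, !pg2)
      exceed <- exceed + (abs(stat) >= abs(obs))
    }
  })
  p <- (1 + exceed) / (1 + n_perm)
  out <- data.frame(gene = rownames(norm), statistic = obs, p = p,
                    q = bh_fdr(p), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

# Residual log CV^2 per gene within the cell subset `sel`: log CV^2
# minus its linear fit on log mean across genes. Genes with
# non-positive mean or zero variance get the trend value (residual 0).
resid_cv2 <- function(norm, sel) {
  x <- norm[, sel, drop = FALSE]
  m <- rowMeans(x)
  v <- rowSums((x - m)^2) / (ncol(x) - 1L)
  ok <- m > 0 & v > 0
  y <- rep(0, nrow(x))
  if (sum(ok) >= 3L) {
    ly <- log(v[ok] / m[ok]^2)
    lx <- log(m[ok])
    b <- stats::cov(lx, ly) / stats::var(lx)
    a <- mean(ly) - b * mean(lx)
    y[ok] <- ly - (a + b * lx)
  } else if (any(ok)) {
    y[ok] <- log(v[ok] / m[ok]^2) - mean(log(v[ok] / m[ok]^2))
  }
  y
}

#' Within-group pairwise cell distances on a gene subset
#'
#' Euclidean distances between all pairs of cells of the same group on
#' log-normalised expression of a gene subset (typically the
#' differentially variable genes), compared between groups with the
#' rank-sum test of [group_compare()]. Larger within-group distances
#' mean a more heterogeneous group.
#'
#' @param counts Genes x cells count matrix.
#' @param gene_subset Gene ids to use; all must resolve.
#' @param groups Two-level per-cell labels, >= 3 cells per group.
#' @param sf Optional size factors.
#' @return A list: `distances` (named list of numeric vectors per
#'   group), `p`, `statistic`, `median_distance` (per group).
#' @export
pairwise_distance_stat <- function(counts, gene_subset, groups, sf = NULL) {
  groups <- as.factor(groups)
  stopifnot(nlevels(groups) == 2L, all(table(groups) >= 3L))
  missing <- setdiff(gene_subset, rownames(counts))
  if (length(missing))
    stop("gene subset not resolvable: ", paste(missing, collapse = ", "))
  ln <- log_normalize(counts, sf)[gene_subset, , drop = FALSE]
  dists <- lapply(levels(groups), function(g)
    as.numeric(stats::dist(t(ln[, groups == g, drop = FALSE]))))
  names(dists) <- levels(groups)
  cmp <- group_compare(dists[[1L]], dists[[2L]])
  list(distances = dists, p = cmp$p, statistic = cmp$statistic,
       median_distance = vapply(dists, stats::median, numeric(1)))
}

#' Trend test across ordered clusters with maternal-effect enrichment
#'
#' Regresses each gene's log-normalised expression on the cluster index
#' treated as a continuous covariate (t-test on the slope, Bonferroni
#' adjustment), then asks whether maternal-effect genes rank higher
#' (smaller trend p-values) than the remaining genes with a one-sided
#' rank-sum test.
#'
#' @param counts Genes x cells count matrix.
#' @param cluster_ids Ordered integer cluster labels per cell (e.g.
#'   1-4), at least two distinct values.
#' @param maternal_genes Character vector of maternal-effect gene ids;
#'   unresolved ids are reported, and enrichment skipped when none
#'   resolve.
#' @param sf Optional size factors.
#' @return A list: `trend` (`data.frame` with `gene`, `slope`, `p`,
#'   `p_bonferroni`), `enrichment_p` (or `NA` when skipped),
#'   `unresolved_maternal`.
#' @export
cluster_trajectory_test <- function(counts, cluster_ids, maternal_genes,
                                    sf = NULL) {
  cluster_ids <- as.numeric(cluster_ids)
  stopifnot(length(cluster_ids) == ncol(counts))
  if (length(unique(cluster_ids)) < 2L)
    stop("need at least two distinct cluster ids")
  ln <- log_normalize(counts, sf)
  x <- cluster_ids - mean(cluster_ids)
  sxx <- sum(x^2)
  n <- length(x)
  slopes <- as.numeric(ln %*% x) / sxx
  fitted_err <- ln - rowMeans(ln) - outer(slopes, x)
  rss <- rowSums(fitted_err^2)
  se <- sqrt(rss / (n - 2L) / sxx)
  tstat <- ifelse(se > 0, slopes / se, 0)
  p <- 2 * stats::pt(-abs(tstat), df = n - 2L)
  p[se == 0 & slopes == 0] <- 1
  p[se == 0 & slopes != 0] <- 0
  trend <- data.frame(gene = rownames(counts), slope = slopes, p = p,
                      p_bonferroni = pmin(p * nrow(counts), 1),
                      stringsAsFactors = FALSE)
  found <- intersect(maternal_genes, rownames(counts))
  unresolved <- setdiff(maternal_genes, found)
  enr <- NA_real_
  if (length(found) > 0L) {
    is_mat <- trend$gene %in% found
    enr <- suppressWarnings(
      stats::wilcox.test(trend$p[is_mat], trend$p[!is_mat],
                         alternative = "less", exact = FALSE)$p.value)
  }
  list(trend = trend, enrichment_p = enr, unresolved_maternal = unresolved)
}

#' Detect a young-like subgroup among aged cells
#'
#' Aged cells are clustered (Ward linkage, Euclidean distance, two
#' clusters) on log-normalised expression of the age-associated genes;
#' the aged cluster whose centroid lies nearer the young-cell centroid
#' is flagged young-like.
#'
#' @param counts Genes x cells count matrix.
#' @param deg_set Non-empty character vector of age-associated gene ids.
#' @param age_groups Per-cell labels, `"young"`/`"aged"`.
#' @param sf Optional size factors.
#' @return Named logical vector over all cells: `TRUE` for aged cells in
#'   the young-like cluster, `FALSE` otherwise (always `FALSE` for young
#'   cells). All aged cells are flagged when the two aged clusters are
#'   equidistant degenerately (identical to young).
#' @export
young_like_subgroup <- function(counts, deg_set, age_groups, sf = NULL) {
  stopifnot(length(deg_set) >= 1L)
  age_groups <- as.character(age_groups)
  stopifnot(all(age_groups %in% c("young", "aged")),
            any(age_groups == "young"), any(age_groups == "aged"))
  aged_idx <- which(age_groups == "aged")
  flags <- rep(FALSE, ncol(counts))
  names(flags) <- colnames(counts)
  if (length(aged_idx) < 4L) {
    warning("fewer than 4 aged cells; young-like detection skipped")
    return(flags)
  }
  genes <- intersect(deg_set, rownames(counts))
  if (!length(genes)) stop("no age-associated gene resolves in the matrix")
  ln <- log_normalize(counts, sf)[genes, , drop = FALSE]
  young_centroid <- rowMeans(ln[, age_groups == "young", drop = FALSE])
  aged <- ln[, aged_idx, drop = FALSE]
  hc <- stats::hclust(stats::dist(t(aged)), method = "ward.D2")
  cl <- stats::cutree(hc, k = 2)
  d <- vapply(1:2, function(k)
    sqrt(sum((rowMeans(aged[, cl == k, drop = FALSE]) - young_centroid)^2)),
    numeric(1))
  young_like_cluster <- which.min(d)
  if (d[1L] == d[2L]) {
    flags[aged_idx] <- TRUE
    return(flags)
  }
  flags[aged_idx[cl == young_like_cluster]] <- TRUE
  flags
}
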