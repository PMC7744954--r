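#' Plan randomised pseudobulk combinations
#'
#' Builds `n_comb` random partitions of each age group into disjoint
#' pseudobulks of `group_size` cells. Within one combination, cells are
#' shuffled without replacement and chunked; the `n mod group_size`
#' leftover cells are excluded from that combination (they return in
#' later combinations under a different shuffle), so no cell is ever
#' reused within a combination.
#'
#' @param young_ids,aged_ids Character vectors of cell identifiers.
#' @param group_size Cells per pseudobulk (default 10).
#' @param n_comb Number of random combinations (default 100).
#' @param seed Integer seed; the plan is reproducible.
#' @return A list of `n_comb` plans, each a list with `combination_id`,
#'   `young`/`aged` (lists of cell-id vectors, one per pseudobulk) and
#'   `dropped` (cell ids left out of this combination).
#' @export
plan_combinations <- function(young_ids, aged_ids, group_size = 10,
                              n_comb = 100, seed = 1) {
  for (ids in list(young = young_ids, aged = aged_ids)) {
    if (length(ids) < 2L * group_size)
      stop("each group needs at least 2*group_size = ", 2L * group_size,
           " cells to form two pseudobulks; got ", length(ids))
  }
  if (anyDuplicated(c(young_ids, aged_ids)))
    stop("cell ids must be unique across groups")
  withr_seed(seed, {
    lapply(seq_len(n_comb), function(i) {
      part <- function(ids) {
        ids <- sample(ids)
        k <- (length(ids) %/% group_size) * group_size
        list(pbs = split(ids[seq_len(k)],
                         rep(seq_len(k / group_size), each = group_size)),
             dropped = ids[setdiff(seq_along(ids), seq_len(k))])
      }
      y <- part(young_ids); a <- part(aged_ids)
      list(combination_id = i, young = unname(y$pbs), aged = unname(a$pbs),
           dropped = c(y$dropped, a$dropped))
    })
  })
}

# Evaluate expr under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG stream afterwards.
withr_seed <- function(seed, expr) {
  has <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", globalenv()) else NULL
  on.exit(if (has) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  expr
}

#' Weighted logistic regression test for a differentially methylated domain
#'
#' Fits a binomial-family logistic regression of methylation proportion
#' on an age-group indicator across pseudobulk observations, with each
#' observation weighted by its total number of calls, and reports the
#' two-sided Wald p-value of the group coefficient. Because the model is
#' saturated in the two groups, the maximum-likelihood fit has the
#' pooled group proportions as fitted values, which this function
#' exploits to solve the score equations in closed form (identical to
#' iteratively reweighted least squares at convergence).
#'
#' When a pooled group proportion sits on the boundary (0% or 100%,
#' complete separation on the logit scale), a Haldane-Anscombe
#' continuity correction (adding half a call to each outcome of both
#' groups) is applied and the result flagged.
#'
#' @param young_pb,aged_pb Pseudobulk observations for each group: a
#'   two-column matrix (or list of length-2 vectors) of
#'   (methylated, total) call counts, one row per pseudobulk.
#' @return A list: `p` (two-sided Wald), `coefficient` (log odds ratio,
#'   aged vs young), `se`, `effect_pp` (difference of pooled
#'   percentages, aged minus young), `flagged` (boundary correction
#'   used).
#' @export
weighted_logit_test <- function(young_pb, aged_pb) {
  young_pb <- as_pb_matrix(young_pb); aged_pb <- as_pb_matrix(aged_pb)
  m1 <- sum(young_pb[, 1L]); n1 <- sum(young_pb[, 2L])
  m2 <- sum(aged_pb[, 1L]);  n2 <- sum(aged_pb[, 2L])
  if (n1 < 1 || n2 < 1) stop("each group needs at least one call")
  res <- logit_wald(m1, n1, m2, n2)
  list(p = res$p, coefficient = res$beta, se = res$se,
       effect_pp = 100 * (m2 / n2 - m1 / n1), flagged = res$flagged)
}

as_pb_matrix <- function(x) {
  if (is.list(x) && !is.data.frame(x)) x <- do.call(rbind, x)
  x <- as.matrix(x)
  if (ncol(x) != 2L) stop("pseudobulk observations must be (meth, total) pairs")
  if (any(x[, 1L] > x[, 2L]) || any(x < 0))
    stop("methylated calls must lie in [0, total]")
  x
}

# Vectorised closed-form Wald test for the group coefficient of a
# two-group weighted binomial logistic regression (see
# weighted_logit_test). All arguments are parallel vectors of pooled
# group counts. With tau2 > 0, a cell-level variance component is added
# to the variance of each pooled proportion (tau2 * ssq_g / n_g^2,
# where ssq_g is the sum of squared per-cell totals) and propagated to
# the log-odds scale by the delta method; tau2 = 0 recovers the plain
# binomial Wald standard error.
logit_wald <- function(m1, n1, m2, n2, tau2 = 0, ssq1 = 0, ssq2 = 0) {
  p1 <- m1 / n1; p2 <- m2 / n2
  flagged <- (m1 == 0 | m1 == n1 | m2 == 0 | m2 == n2)
  # Haldane-Anscombe correction where a group proportion is 0 or 1
  a1 <- ifelse(flagged, m1 + 0.5, m1); b1 <- ifelse(flagged, n1 + 1, n1)
  a2 <- ifelse(flagged, m2 + 0.5, m2); b2 <- ifelse(flagged, n2 + 1, n2)
  q1 <- a1 / b1; q2 <- a2 / b2
  v1 <- q1 * (1 - q1) / b1 + tau2 * ssq1 / b1^2
  v2 <- q2 * (1 - q2) / b2 + tau2 * ssq2 / b2^2
  beta <- log(q2 / (1 - q2)) - log(q1 / (1 - q1))
  se <- sqrt(v1 / (q1 * (1 - q1))^2 + v2 / (q2 * (1 - q2))^2)
  z <- beta / se
  p <- 2 * stats::pnorm(-abs(z))
  p[p1 == p2 & !flagged] <- 1  # guards rounding when proportions coincide
  list(p = p, beta = beta, se = se, flagged = flagged)
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjustment `q_i = min_{j >= i} m * p_(j) / j` with
#' monotonicity enforcement, as implemented by [stats::p.adjust()].
#'
#' @param pvals Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted q-values, same length and order as `pvals`.
#' @export
bh_fdr <- function(pvals) {
  if (length(pvals) == 0L) return(numeric(0))
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Per-cell methylation counts over domains
#'
#' Builds the (meth, total) count matrices consumed by the consensus
#' caller: one column per cell, one row per domain.
#'
#' @param cells Named list of CpG call tables.
#' @param domains Domain set to test (typically the hyper/hypo/inter
#'   tiling).
#' @param context Sequence context.
#' @return A list of two integer matrices `meth` and `total`
#'   (domains x cells).
#' @export
domain_counts <- function(cells, domains, context = "CpG") {
  stopifnot(is.list(cells), !is.null(names(cells)))
  meth <- matrix(0L, nrow(domains), length(cells),
                 dimnames = list(domains$name, names(cells)))
  total <- meth
  for (i in seq_along(cells)) {
    q <- quantify_regions(cells[[i]], domains, context = context,
                          warn_unmatched = FALSE)
    meth[, i] <- q$meth; total[, i] <- q$total
  }
  list(meth = meth, total = total)
}

#' Run the randomised pseudobulk consensus DMR test
#'
#' For every combination of the plan, forms pseudobulk methylation
#' counts per domain, tests each sufficiently covered domain with the
#' weighted logistic regression of [weighted_logit_test()], adjusts
#' p-values across domains within the combination by Benjamini-Hochberg,
#' and records significance. A domain is testable in a combination only
#' if every pseudobulk of both groups carries at least `min_calls` calls
#' in it; untested combinations are excluded from that domain's
#' consensus denominator.
#'
#' The pseudobulk replicates within each group carry residual degrees of
#' freedom beyond the binomial assumption; `overdispersion = "cell"`
#' (the default) uses them to estimate a genome-wide cell-level variance
#' component. Each cell's methylation rate is perturbed by technical
#' noise of variance `tau^2` on the proportion scale, so a pooled group
#' proportion has variance `p*(1-p)/N + tau^2 * sum(w_c^2)` with
#' coverage weights `w_c = n_c / N`. `tau^2` is estimated per
#' combination by method of moments from the scatter of pseudobulk
#' proportions about their pooled group proportion (excess over the
#' binomial expectation, pooled across domains, floored at 0), and the
#' Wald standard error of the group log-odds coefficient uses the
#' inflated variances via the delta method. With `tau = 0` this is
#' exactly the binomial Wald test. Without the correction the consensus
#' caller is anti-conservative: per-cell noise is absolute on the rate
#' scale, so it dominates the binomial term precisely in large
#' high-coverage domains and near-boundary rates. `"none"` keeps plain
#' binomial Wald errors.
#'
#' @param counts Output of [domain_counts()].
#' @param plans Output of [plan_combinations()].
#' @param q_threshold Per-combination BH significance threshold
#'   (default 0.05).
#' @param min_calls Minimum calls per pseudobulk per domain (default 10).
#' @param overdispersion `"cell"` (estimate a cell-level variance
#'   component from the pseudobulk replicates of each combination) or
#'   `"none"`.
#' @return A `data.frame` with one row per domain: `name`, `n_tested`,
#'   `n_significant`, `consensus_fraction`, `mean_effect_pp` (aged minus
#'   young percentage points, averaged over tested combinations),
#'   `mean_q`, plus attributes `n_comb` and `tau` (the per-combination
#'   cell-level standard deviations applied).
#' @export
dmr_test <- function(counts, plans, q_threshold = 0.05, min_calls = 10,
                     overdispersion = c("cell", "none")) {
  overdispersion <- match.arg(overdispersion)
  meth <- counts$meth; total <- counts$total
  total_sq <- total^2
  cells <- colnames(total)
  nd <- nrow(total)
  n_tested <- integer(nd); n_sig <- integer(nd)
  sum_eff <- numeric(nd); sum_q <- numeric(nd)
  taus <- numeric(0)
  for (plan in plans) {
    ym <- plan$young; am <- plan$aged
    idx <- function(pbs) lapply(pbs, function(p) match(p, cells))
    yi <- idx(ym); ai <- idx(am)
    if (anyNA(unlist(c(yi, ai))))
      stop("plan references cells absent from the count matrices")
    pb_mat <- function(M, ii) vapply(ii, function(j)
      .rowSums(M[, j, drop = FALSE], nd, length(j)), numeric(nd))
    yt <- pb_mat(total, yi); at <- pb_mat(total, ai)
    ok <- rowSums(cbind(yt, at) < min_calls) == 0L
    if (!any(ok)) next
    ycells <- unlist(yi); acells <- unlist(ai)
    m1 <- .rowSums(meth[, ycells, drop = FALSE], nd, length(ycells))
    n1 <- .rowSums(total[, ycells, drop = FALSE], nd, length(ycells))
    m2 <- .rowSums(meth[, acells, drop = FALSE], nd, length(acells))
    n2 <- .rowSums(total[, acells, drop = FALSE], nd, length(acells))
    tau2 <- 0
    if (overdispersion == "cell" && length(yi) + length(ai) > 2L) {
      # Method-of-moments pooling of the excess scatter of pseudobulk
      # proportions about the pooled group proportion, relative to the
      # squared-coverage weights that propagate a cell-level variance.
      yme <- pb_mat(meth, yi); ame <- pb_mat(meth, ai)
      ysq <- pb_mat(total_sq, yi); asq <- pb_mat(total_sq, ai)
      p1 <- m1 / n1; p2 <- m2 / n2
      usable <- ok & p1 > 0 & p1 < 1 & p2 > 0 & p2 < 1
      if (any(usable)) {
        # E[(p_pb - p_g)^2] = B_pb (1 - 2 w_pb) + sum_k w_k^2 B_k
        #   + tau2 [S_pb (1 - 2 w_pb) + sum_k w_k^2 S_k],
        # where B is the binomial variance of a pseudobulk proportion,
        # S its squared-coverage weight, and w_pb its share of the
        # group total; the w terms debias for p_g being estimated from
        # the same pseudobulks.
        moment <- function(mm, tt, sq, p, n_g) {
          mm <- mm[usable, , drop = FALSE]; tt <- tt[usable, , drop = FALSE]
          sq <- sq[usable, , drop = FALSE]
          pp <- mm / tt
          w <- tt / n_g
          B <- p * (1 - p) / tt
          S <- sq / tt^2
          c(num = sum((pp - p)^2 - (B * (1 - 2 * w) + rowSums(w^2 * B))),
            den = sum(S * (1 - 2 * w) + rowSums(w^2 * S)))
        }
        st <- moment(yme, yt, ysq, p1[usable], n1[usable]) +
          moment(ame, at, asq, p2[usable], n2[usable])
        tau2 <- max(0, st[["num"]] / st[["den"]])
      }
    }
    taus <- c(taus, sqrt(tau2))
    ssq1 <- .rowSums(total_sq[, ycells, drop = FALSE], nd, length(ycells))
    ssq2 <- .rowSums(total_sq[, acells, drop = FALSE], nd, length(acells))
    w <- logit_wald(m1[ok], n1[ok], m2[ok], n2[ok],
                    tau2 = tau2, ssq1 = ssq1[ok], ssq2 = ssq2[ok])
    q <- bh_fdr(w$p)
    n_tested[ok] <- n_tested[ok] + 1L
    n_sig[ok] <- n_sig[ok] + as.integer(q < q_threshold)
    sum_eff[ok] <- sum_eff[ok] + 100 * (m2[ok] / n2[ok] - m1[ok] / n1[ok])
    sum_q[ok] <- sum_q[ok] + q
  }
  out <- data.frame(
    name = rownames(total),
    n_tested = n_tested,
    n_significant = n_sig,
    consensus_fraction = ifelse(n_tested > 0, n_sig / pmax(n_tested, 1L), NA_real_),
    mean_effect_pp = ifelse(n_tested > 0, sum_eff / pmax(n_tested, 1L), NA_real_),
    mean_q = ifelse(n_tested > 0, sum_q / pmax(n_tested, 1L), NA_real_),
    stringsAsFactors = FALSE)
  attr(out, "n_comb") <- length(plans)
  attr(out, "tau") <- taus
  out
}

#' Call consensus DMRs
#'
#' A domain is carried forward as an age-associated DMR when it was
#' significant (BH q below `q_threshold`) in at least `consensus` of the
#' combinations in which it was testable. Domains testable in fewer than
#' `min_tested_fraction` of all combinations are excluded as
#' insufficiently tested. Direction is the sign of the mean aged-minus-
#' young effect: `hypo_in_aged` for negative, `hyper_in_aged` for
#' positive.
#'
#' @param results Per-domain summary from [dmr_test()].
#' @param q_threshold BH threshold used when counting significant
#'   combinations (informational; counting happens in [dmr_test()]).
#' @param consensus Minimum fraction of tested combinations that must be
#'   significant (default 0.95).
#' @param min_tested_fraction Minimum fraction of all combinations in
#'   which a domain must be testable (default 0.5).
#' @return A list with `dmrs` (rows of `results` passing consensus plus
#'   a `direction` column) and `insufficiently_tested` (domain names
#'   excluded for sparse testing).
#' @export
consensus_call <- function(results, q_threshold = 0.05, consensus = 0.95,
                           min_tested_fraction = 0.5) {
  n_comb <- attr(results, "n_comb")
  if (is.null(n_comb)) n_comb <- max(results$n_tested)
  low <- results$n_tested < min_tested_fraction * n_comb
  ok <- !low & !is.na(results$consensus_fraction) &
    results$consensus_fraction >= consensus
  dmrs <- results[ok, , drop = FALSE]
  dmrs$direction <- ifelse(dmrs$mean_effect_pp < 0, "hypo_in_aged",
                           "hyper_in_aged")
  rownames(dmrs) <- NULL
  list(dmrs = dmrs, insufficiently_tested = results$name[low])
}

#' Annotate consensus DMRs by domain class
#'
#' Counts DMRs per methylation-domain class (hyper, hypo, inter) and
#' compares each class's share against its expected genomic share (the
#' class's fraction of the tested domains) with a two-sided exact
#' binomial test.
#'
#' @param dmrs The `dmrs` table from [consensus_call()].
#' @param domains The domain set that was tested (supplies the class of
#'   every domain and the expected proportions).
#' @return A `data.frame` per class: `class`, `n_dmrs`,
#'   `fraction_of_dmrs`, `expected_fraction`, `p` (binomial test; `NA`
#'   when no DMRs were called).
#' @export
annotate_dmrs <- function(dmrs, domains) {
  cls <- domains$class[match(dmrs$name, domains$name)]
  classes <- sort(unique(domains$class))
  n <- nrow(dmrs)
  out <- do.call(rbind, lapply(classes, function(k) {
    x <- sum(cls == k, na.rm = TRUE)
    exp_p <- mean(domains$class == k)
    data.frame(class = k, n_dmrs = x,
               fraction_of_dmrs = if (n > 0) x / n else NA_real_,
               expected_fraction = exp_p,
               p = if (n > 0) stats::binom.test(x, n, exp_p)$p.value else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Classify cells from their DMR methylation profiles
#'
#' A transparent nearest-centroid classifier on per-cell DMR methylation
#' percentages with a missing-aware distance (mean squared difference
#' over DMRs observed in both the cell and the centroid). In
#' leave-one-out mode each cell is excluded from its own group centroid
#' before assignment, giving an honest accuracy estimate.
#'
#' @param cell_meth Numeric matrix of per-cell DMR methylation (DMRs x
#'   cells, `NA` for uncovered DMRs), e.g. assembled from
#'   [quantify_regions()] per cell.
#' @param labels Named character vector (or vector aligned with the
#'   columns) of training labels, at least two groups.
#' @param leave_one_out Exclude each cell from its own centroid
#'   (default `TRUE`).
#' @param min_dmrs Cells covering fewer DMRs than this are returned
#'   unclassified (`NA`; default 3).
#' @return Character vector of predicted labels, named by cell;
#'   `NA` for unclassifiable cells.
#' @export
classify_cells_by_dmrs <- function(cell_meth, labels, leave_one_out = TRUE,
                                   min_dmrs = 3) {
  stopifnot(is.matrix(cell_meth))
  if (!is.null(names(labels)) && !is.null(colnames(cell_meth)))
    labels <- labels[colnames(cell_meth)]
  labels <- as.character(labels)
  groups <- sort(unique(labels))
  if (length(groups) < 2L) stop("need at least two labelled groups")
  pred <- rep(NA_character_, ncol(cell_meth))
  names(pred) <- colnames(cell_meth)
  for (i in seq_len(ncol(cell_meth))) {
    x <- cell_meth[, i]
    if (sum(!is.na(x)) < min_dmrs) next
    d <- vapply(groups, function(g) {
      members <- which(labels == g)
      if (leave_one_out) members <- setdiff(members, i)
      if (!length(members)) return(NA_real_)
      centroid <- rowMeans(cell_meth[, members, drop = FALSE], na.rm = TRUE)
      shared <- !is.na(x) & !is.na(centroid)
      if (sum(shared) < min_dmrs) return(NA_real_)
      mean((x[shared] - centroid[shared])^2)
    }, numeric(1))
    if (all(is.na(d))) next
    pred[i] <- groups[which.min(d)]
  }
  pred
}
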