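test_that("size factors follow the median-of-ratios definition", {
  counts <- matrix(c(10L, 100L, 4L,
                     20L, 200L, 8L,
                     30L, 300L, 12L), nrow = 3, byrow = FALSE,
                   dimnames = list(c("g1", "g2", "g3"),
                                   c("c1", "c2", "c3")))
  sf <- size_factors(counts)
  ref <- exp(rowMeans(log(counts)))
  manual <- apply(counts, 2, function(x) median(x / ref))
  manual <- manual / exp(mean(log(manual)))
  expect_equal(unname(sf), unname(manual))
  expect_equal(exp(mean(log(sf))), 1)
})

test_that("size factors agree with the established reference estimator", {
  set.seed(9)
  mu <- rlnorm(300, 2, 1.3)
  depth <- c(0.5, 1, 1.5, 2, 0.8, 1.2)
  counts <- vapply(depth, function(d) rnbinom(300, mu = mu * d, size = 10),
                   numeric(300))
  dimnames(counts) <- list(sprintf("g%03d", 1:300), sprintf("c%d", 1:6))
  ours <- size_factors(counts)
  ref <- DESeq2::estimateSizeFactorsForMatrix(counts)
  ref <- ref / exp(mean(log(ref)))  # same geometric-mean-1 convention
  expect_equal(unname(ours), unname(ref), tolerance = 1e-10)
})

test_that("sparse matrices without an always-detected gene fall back", {
  counts <- matrix(c(0L, 5L, 3L, 0L), nrow = 2,
                   dimnames = list(c("g1", "g2"), c("c1", "c2")))
  expect_warning(sf <- size_factors(counts), "fall")
  expect_identical(attr(sf, "fallback"), "total_count")
  expect_equal(unname(sf), c(5, 3) / sqrt(15), ignore_attr = TRUE)
})

test_that("log-normalisation divides by the factor before the log", {
  counts <- matrix(c(4L, 8L), 1, dimnames = list("g", c("c1", "c2")))
  out <- log_normalize(counts, sf = c(1, 2))
  expect_equal(unname(out[1, ]), log2(c(5, 5)))
})

test_that("transcript diversity counts detected genes per cell", {
  counts <- matrix(c(0L, 1L, 5L, 0L, 0L, 2L), nrow = 3,
                   dimnames = list(c("g1", "g2", "g3"), c("c1", "c2")))
  expect_equal(unname(transcript_diversity(counts)), c(2L, 1L))
})

test_that("the chromatin-state split labels the high-signature cluster SN", {
  set.seed(14)
  n_cells <- 30; n_sn <- 9
  sig <- sprintf("sig%02d", 1:20)
  other <- sprintf("g%03d", 1:100)
  state <- rep(c("SN", "NSN"), c(n_sn, n_cells - n_sn))
  mu <- matrix(rlnorm(120, 2, 1), 120, n_cells,
               dimnames = list(c(sig, other), sprintf("c%02d", 1:n_cells)))
  mu[sig, ] <- rlnorm(20, 3.5, 0.4)
  mu[sig, state == "SN"] <- mu[sig, state == "SN"] * 4
  counts <- matrix(rnbinom(length(mu), mu = mu, size = 20), 120, n_cells,
                   dimnames = dimnames(mu))
  labels <- classify_chromatin_state(counts, sig)
  expect_identical(as.character(labels), state)
  expect_identical(attr(labels, "n_signature_used"), 20L)
})

test_that("unresolvable signature genes are dropped with a warning", {
  counts <- matrix(rpois(60, 10), 6, 10,
                   dimnames = list(sprintf("s%d", 1:6), sprintf("c%d", 1:10)))
  expect_warning(classify_chromatin_state(counts, c(rownames(counts), "absent")),
                 "not present")
  expect_error(
    suppressWarnings(classify_chromatin_state(counts, c("s1", "s2", "absent"))),
    "at least 5")
})

test_that("the exact proportion test enumerates the hypergeometric null", {
  set.seed(31)
  for (i in 1:25) {
    m <- matrix(rpois(4, 8), 2)
    expect_equal(fisher_proportion_test(m), fisher_enumeration(m),
                 tolerance = 1e-9)
  }
  expect_equal(fisher_proportion_test(matrix(c(0, 0, 5, 7), 2)), 1)
})

test_that("differential mean testing matches per-gene rank-sum oracles", {
  set.seed(55)
  groups <- rep(c("aged", "young"), each = 10)
  counts <- matrix(rnbinom(300 * 20, mu = 30, size = 5), 300, 20,
                   dimnames = list(sprintf("g%03d", 1:300),
                                   sprintf("c%02d", 1:20)))
  counts["g001", ] <- 0L  # never detected
  counts["g002", groups == "young"] <- counts["g002", groups == "young"] * 6L
  sf <- size_factors(counts)
  res <- differential_mean_test(counts, groups, sf = sf)
  expect_identical(attr(res, "excluded"), "g001")
  norm <- sweep(counts, 2, sf, "/")
  g <- "g002"
  ref <- suppressWarnings(
    wilcox.test(norm[g, groups == "young"], norm[g, groups == "aged"],
                exact = FALSE))
  expect_equal(res$p[res$gene == g], ref$p.value)
  ref_lfc <- log2(mean(norm[g, groups == "young"]) + 1) -
    log2(mean(norm[g, groups == "aged"]) + 1)
  expect_equal(res$lfc[res$gene == g], ref_lfc)
  expect_equal(res$q, p.adjust(res$p, "BH"))
  expect_lt(res$p[res$gene == g], 1e-3)
})

test_that("the variability statistic is positive for aged-inflated genes", {
  set.seed(77)
  groups <- rep(c("aged", "young"), each = 15)
  mu <- rlnorm(200, 3, 1)
  counts <- matrix(rnbinom(200 * 30, mu = mu, size = 8), 200, 30,
                   dimnames = list(sprintf("g%03d", 1:200),
                                   sprintf("c%02d", 1:30)))
  infl <- sprintf("g%03d", 1:10)
  counts[infl, groups == "aged"] <-
    matrix(rnbinom(10 * 15, mu = mu[1:10], size = 1), 10, 15)
  res <- differential_variability_test(counts, groups, n_perm = 200, seed = 3)
  # "aged" sorts before "young", so positive = more variable in young;
  # factor levels are alphabetical, hence statistic is young minus aged
  expect_true(median(res$statistic[res$gene %in% infl]) <
                median(res$statistic[!res$gene %in% infl]))
  expect_true(all(res$p >= 1 / 201 & res$p <= 1))
})

test_that("permutation p-values are reproducible under a fixed seed", {
  set.seed(88)
  groups <- rep(c("a", "b"), each = 10)
  counts <- matrix(rnbinom(50 * 20, mu = 20, size = 5), 50, 20,
                   dimnames = list(sprintf("g%02d", 1:50),
                                   sprintf("c%02d", 1:20)))
  r1 <- differential_variability_test(counts, groups, n_perm = 50, seed = 12)
  r2 <- differential_variability_test(counts, groups, n_perm = 50, seed = 12)
  expect_identical(r1, r2)
})

test_that("within-group pairwise distances compare group heterogeneity", {
  set.seed(41)
  tight <- matrix(rnorm(10 * 8, sd = 0.1), 10, 8)
  loose <- matrix(rnorm(10 * 8, sd = 3), 10, 8)
  counts <- matrix(rpois(10 * 16, 50), 10, 16,
                   dimnames = list(sprintf("g%02d", 1:10),
                                   sprintf("c%02d", 1:16)))
  groups <- rep(c("young", "aged"), each = 8)
  out <- pairwise_distance_stat(counts, rownames(counts), groups)
  expect_named(out$distances, c("aged", "young"))
  expect_length(out$distances$aged, choose(8, 2))
  ref <- group_compare(out$distances$aged, out$distances$young)
  expect_equal(out$p, ref$p)
  expect_error(pairwise_distance_stat(counts, "missing_gene", groups),
               "not resolvable")
})

test_that("cluster trend slopes match the per-gene regression oracle", {
  set.seed(61)
  clusters <- rep(1:4, each = 6)
  counts <- matrix(rnbinom(40 * 24, mu = 25, size = 10), 40, 24,
                   dimnames = list(sprintf("g%02d", 1:40),
                                   sprintf("c%02d", 1:24)))
  maternal <- c("g01", "g02", "g03")
  out <- cluster_trajectory_test(counts, clusters, maternal)
  ln <- log_normalize(counts, size_factors(counts))
  for (g in c("g01", "g17")) {
    fit <- summary(lm(ln[g, ] ~ clusters))$coefficients
    expect_equal(out$trend$slope[out$trend$gene == g], fit["clusters", "Estimate"])
    expect_equal(out$trend$p[out$trend$gene == g], fit["clusters", "Pr(>|t|)"])
  }
  expect_equal(out$trend$p_bonferroni, pmin(out$trend$p * 40, 1))
  expect_identical(out$unresolved_maternal, character(0))
})

test_that("declining maternal-effect genes enrich at small trend p-values", {
  set.seed(62)
  clusters <- rep(1:4, each = 8)
  mu <- matrix(30, 60, 32, dimnames = list(sprintf("g%02d", 1:60),
                                           sprintf("c%02d", 1:32)))
  maternal <- sprintf("g%02d", 1:8)
  mu[maternal, ] <- 30 * 2^(-0.8 * rep(clusters - 1, each = 8))
  counts <- matrix(rnbinom(length(mu), mu = mu, size = 10), 60, 32,
                   dimnames = dimnames(mu))
  out <- cluster_trajectory_test(counts, clusters, c(maternal, "ghost"))
  expect_lt(out$enrichment_p, 0.01)
  expect_identical(out$unresolved_maternal, "ghost")
})

test_that("aged cells resembling young expression are flagged young-like", {
  set.seed(71)
  degs <- sprintf("d%02d", 1:15)
  background <- sprintf("b%02d", 1:60)
  cells <- c(sprintf("y%02d", 1:10), sprintf("a%02d", 1:12))
  age <- rep(c("young", "aged"), c(10, 12))
  young_like_truth <- c(sprintf("a%02d", 1:5))
  mu <- matrix(20, 75, 22, dimnames = list(c(degs, background), cells))
  shifted <- age == "aged" & !(cells %in% young_like_truth)
  mu[degs, shifted] <- mu[degs, shifted] * 6
  counts <- matrix(rnbinom(length(mu), mu = mu, size = 20), 75, 22,
                   dimnames = dimnames(mu))
  flags <- young_like_subgroup(counts, degs, age)
  expect_identical(names(which(flags)), young_like_truth)
  expect_true(all(!flags[age == "young"]))
})

test_that("principal components associate with a planted group covariate", {
  set.seed(81)
  cells <- sprintf("c%02d", 1:24)
  grp <- rep(c("A", "B"), each = 12)
  mu <- matrix(rlnorm(200 * 24, 2.5, 1), 200, 24,
               dimnames = list(sprintf("g%03d", 1:200), cells))
  mu[1:40, grp == "B"] <- mu[1:40, grp == "B"] * 5
  counts <- matrix(rnbinom(length(mu), mu = mu, size = 10), 200, 24,
                   dimnames = dimnames(mu))
  covs <- data.frame(group = grp, flat = rep("x", 24),
                     stringsAsFactors = FALSE)
  expect_warning(out <- pca_with_associations(counts, covs, n_top = 100),
                 "constant")
  expect_lt(min(out$p["group", ], na.rm = TRUE), 1e-4)
  expect_true(all(is.na(out$p["flat", ])))
  expect_equal(sum(out$var_explained), 1)
})
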