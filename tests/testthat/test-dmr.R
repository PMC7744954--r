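test_that("combination plans partition cells into disjoint pseudobulks", {
  young <- sprintf("y%02d", 1:30); aged <- sprintf("a%02d", 1:32)
  plans <- plan_combinations(young, aged, group_size = 10, n_comb = 20,
                             seed = 11)
  expect_length(plans, 20)
  for (pl in plans) {
    expect_length(pl$young, 3)  # 30 cells / 10
    expect_length(pl$aged, 3)   # 32 cells / 10, 2 left over
    ids <- unlist(c(pl$young, pl$aged))
    expect_false(anyDuplicated(ids) > 0)
    expect_length(pl$dropped, 2)
    expect_true(all(pl$dropped %in% aged))
    expect_true(all(vapply(c(pl$young, pl$aged), length, 0L) == 10L))
  }
})

test_that("combination plans are reproducible and seed-sensitive", {
  young <- sprintf("y%02d", 1:20); aged <- sprintf("a%02d", 1:20)
  p1 <- plan_combinations(young, aged, seed = 5, n_comb = 5)
  p2 <- plan_combinations(young, aged, seed = 5, n_comb = 5)
  p3 <- plan_combinations(young, aged, seed = 6, n_comb = 5)
  expect_identical(p1, p2)
  expect_false(identical(p1, p3))
})

test_that("groups too small for two pseudobulks are rejected", {
  expect_error(plan_combinations(sprintf("y%d", 1:19),
                                 sprintf("a%d", 1:25), group_size = 10),
               "2\\*group_size")
})

test_that("the saturated weighted logit equals the two-proportion z-test", {
  # one pseudobulk per group: 40/100 vs 60/100
  out <- weighted_logit_test(cbind(40, 100), cbind(60, 100))
  p1 <- 0.4; p2 <- 0.6
  z <- (log(p2 / (1 - p2)) - log(p1 / (1 - p1))) /
    sqrt(1 / (100 * p1 * (1 - p1)) + 1 / (100 * p2 * (1 - p2)))
  expect_equal(out$p, 2 * pnorm(-abs(z)))
  expect_equal(out$effect_pp, 20)
  expect_false(out$flagged)
})

test_that("pooling over pseudobulks reproduces the combined-count fit", {
  young <- rbind(c(10, 50), c(20, 60))
  aged <- rbind(c(30, 50), c(35, 70))
  split_fit <- weighted_logit_test(young, aged)
  pooled_fit <- weighted_logit_test(cbind(30, 110), cbind(65, 120))
  expect_equal(split_fit$p, pooled_fit$p)
  expect_equal(split_fit$coefficient, pooled_fit$coefficient)
})

test_that("complete separation is handled by continuity correction", {
  out <- weighted_logit_test(cbind(0, 40), cbind(25, 50))
  expect_true(out$flagged)
  expect_true(is.finite(out$p) && out$p < 0.01)
  expect_true(is.finite(out$coefficient))
})

test_that("identical group proportions are never significant", {
  out <- weighted_logit_test(cbind(30, 60), cbind(45, 90))
  expect_equal(out$p, 1)
})

test_that("the cell-variance component widens but never shrinks the error", {
  base <- oomt:::logit_wald(30, 100, 55, 120)
  inflated <- oomt:::logit_wald(30, 100, 55, 120, tau2 = 0.01,
                                ssq1 = 900, ssq2 = 1100)
  expect_equal(oomt:::logit_wald(30, 100, 55, 120, tau2 = 0,
                                 ssq1 = 900, ssq2 = 1100)$se, base$se)
  expect_gt(inflated$se, base$se)
  expect_gt(inflated$p, base$p)
  # delta-method value: Var(logit p) = [p(1-p)/n + tau2 ssq/n^2] / (p(1-p))^2
  p1 <- 30 / 100; p2 <- 55 / 120
  v1 <- (p1 * (1 - p1) / 100 + 0.01 * 900 / 100^2) / (p1 * (1 - p1))^2
  v2 <- (p2 * (1 - p2) / 120 + 0.01 * 1100 / 120^2) / (p2 * (1 - p2))^2
  expect_equal(inflated$se, sqrt(v1 + v2))
})

test_that("BH adjustment is monotone, bounded and order-preserving", {
  set.seed(3)
  p <- runif(50)
  q <- bh_fdr(p)
  expect_true(all(q >= p - 1e-12))
  expect_true(all(q <= 1))
  expect_equal(order(q[order(p)]), seq_along(p))  # ranks preserved
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_identical(bh_fdr(numeric(0)), numeric(0))
})

test_that("domain counts sum each cell's calls within each domain", {
  cells <- list(
    c1 = cpg_calls("chr1", c(10L, 250L), "CpG", c(1L, 0L), c(0L, 1L)),
    c2 = cpg_calls("chr1", c(20L, 30L), "CpG", c(1L, 1L), c(0L, 0L)))
  cnt <- domain_counts(cells, toy_domains())
  expect_equal(cnt$meth["d1", "c1"], 1L)
  expect_equal(cnt$total["d1", "c2"], 2L)
  expect_equal(cnt$total["d2", "c1"], 1L)
  expect_equal(cnt$meth["d2", "c2"], 0L)
})

test_that("a strong planted difference reaches full consensus", {
  # noiseless counts: every null domain is identical across groups, the
  # planted domain is hypomethylated in every aged cell
  young <- sprintf("y%02d", 1:20); aged <- sprintf("a%02d", 1:20)
  nd <- 30
  total <- matrix(50L, nd, 40,
                  dimnames = list(sprintf("dom_%02d", 1:nd), c(young, aged)))
  meth <- matrix(25L, nd, 40, dimnames = dimnames(total))
  meth["dom_01", aged] <- 5L
  plans <- plan_combinations(young, aged, n_comb = 50, seed = 2)
  res <- dmr_test(list(meth = meth, total = total), plans)
  cc <- consensus_call(res)
  expect_identical(cc$dmrs$name, "dom_01")
  expect_identical(cc$dmrs$direction, "hypo_in_aged")
  expect_equal(cc$dmrs$consensus_fraction, 1)
})

test_that("sparsely covered domains are excluded from consensus", {
  young <- sprintf("y%02d", 1:20); aged <- sprintf("a%02d", 1:20)
  total <- matrix(30L, 2, 40,
                  dimnames = list(c("covered", "sparse"), c(young, aged)))
  total["sparse", ] <- 0L
  meth <- total
  meth["covered", ] <- 15L
  plans <- plan_combinations(young, aged, n_comb = 10, seed = 4)
  res <- dmr_test(list(meth = meth, total = total), plans)
  cc <- consensus_call(res)
  expect_identical(cc$insufficiently_tested, "sparse")
  expect_equal(res$n_tested[res$name == "sparse"], 0L)
})

test_that("DMR class composition is compared against the genomic share", {
  domains <- domain_set(chrom = "chr1",
                        start = seq(0L, 900L, 100L),
                        end = seq(100L, 1000L, 100L),
                        name = sprintf("d%02d", 1:10),
                        class = rep(c("hyper", "hypo"), 5))
  dmrs <- data.frame(name = c("d01", "d03", "d05"),
                     stringsAsFactors = FALSE)
  ann <- annotate_dmrs(dmrs, domains)
  expect_equal(ann$n_dmrs[ann$class == "hyper"], 3L)
  expect_equal(ann$fraction_of_dmrs[ann$class == "hyper"], 1)
  expect_equal(ann$expected_fraction, c(0.5, 0.5))
  expect_equal(ann$p[ann$class == "hyper"],
               binom.test(3, 3, 0.5)$p.value)
})

test_that("cells are classifiable from their DMR methylation profiles", {
  set.seed(21)
  n_dmr <- 12
  young_prof <- runif(n_dmr, 70, 95)
  aged_prof <- young_prof - 40
  m <- cbind(
    vapply(1:8, function(i) young_prof + rnorm(n_dmr, 0, 3), numeric(n_dmr)),
    vapply(1:8, function(i) aged_prof + rnorm(n_dmr, 0, 3), numeric(n_dmr)))
  colnames(m) <- c(sprintf("y%d", 1:8), sprintf("a%d", 1:8))
  labels <- setNames(rep(c("young", "aged"), each = 8), colnames(m))
  # sprinkle missingness: each cell misses a third of the DMRs
  for (j in seq_len(ncol(m))) m[sample(n_dmr, 4), j] <- NA
  pred <- classify_cells_by_dmrs(m, labels)
  expect_identical(unname(pred), unname(labels[colnames(m)]))
})

test_that("cells covering too few DMRs stay unclassified", {
  m <- matrix(c(90, 80, NA, NA, 10, 20, NA, NA), nrow = 4,
              dimnames = list(sprintf("d%d", 1:4), c("c1", "c2")))
  m[, "c2"] <- NA
  m[1, "c2"] <- 10
  labels <- c(c1 = "young", c2 = "aged")
  pred <- classify_cells_by_dmrs(m, labels, leave_one_out = FALSE)
  expect_true(is.na(pred["c2"]))
})
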