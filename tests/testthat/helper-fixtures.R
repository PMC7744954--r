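# Shared fixture builders for the test suite.

# A small deterministic call table spanning two chromosomes and all
# three contexts.
toy_calls <- function() {
  cpg_calls(
    chrom  = c("chr1", "chr1", "chr1", "chr1", "chr2", "chr1", "chr1"),
    pos    = c(100L, 150L, 200L, 250L, 100L, 120L, 130L),
    context = c("CpG", "CpG", "CpG", "CpG", "CpG", "CHG", "CHH"),
    meth   = c(1L, 0L, 1L, 1L, 0L, 1L, 0L),
    unmeth = c(0L, 1L, 0L, 1L, 1L, 0L, 1L))
}

# Two adjacent half-open domains on chr1 ([0,200) and [200,400)) and
# one on chr2.
toy_domains <- function() {
  domain_set(chrom = c("chr1", "chr1", "chr2"),
             start = c(0L, 200L, 0L),
             end   = c(200L, 400L, 500L),
             name  = c("d1", "d2", "d3"),
             class = c("hyper", "hypo", "inter"))
}

# Random (meth, total) pseudobulk observations with totals in
# [min_total, max_total].
random_pb <- function(n, min_total = 10, max_total = 200, rate = NULL) {
  total <- sample(seq(min_total, max_total), n, replace = TRUE)
  if (is.null(rate)) rate <- stats::runif(1, 0.05, 0.95)
  cbind(meth = stats::rbinom(n, total, rate), total = total)
}

# Reference Wald p-value for the group coefficient of a weighted
# binomial logistic regression, fit by stats::glm (IRLS).
glm_wald_reference <- function(young_pb, aged_pb) {
  d <- rbind(young_pb, aged_pb)
  grp <- factor(rep(c("young", "aged"), c(nrow(young_pb), nrow(aged_pb))),
                levels = c("young", "aged"))
  prop <- d[, 1] / d[, 2]
  fit <- suppressWarnings(
    stats::glm(prop ~ grp, family = stats::binomial(), weights = d[, 2]))
  co <- summary(fit)$coefficients
  list(p = co["grpaged", "Pr(>|z|)"],
       coefficient = co["grpaged", "Estimate"],
       se = co["grpaged", "Std. Error"])
}

# Exact two-sided Fisher p by direct hypergeometric enumeration over
# all tables with the observed margins.
fisher_enumeration <- function(m) {
  r1 <- sum(m[1, ]); c1 <- sum(m[, 1]); n <- sum(m)
  ks <- max(0, c1 - (n - r1)):min(r1, c1)
  probs <- stats::dhyper(ks, r1, n - r1, c1)
  obs <- stats::dhyper(m[1, 1], r1, n - r1, c1)
  sum(probs[probs <= obs * (1 + 1e-7)])
}
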