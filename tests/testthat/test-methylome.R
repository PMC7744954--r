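test_that("global methylation is the methylated fraction of calls", {
  calls <- toy_calls()
  # CpG records: meth 1,0,1,1,0 over 6 calls (one record carries 2 calls)
  expect_equal(global_methylation(calls, "CpG"), 100 * 3 / 6)
  expect_equal(global_methylation(calls, "CHG"), 100)
  expect_equal(global_methylation(calls, "CHH"), 0)
})

test_that("non-CpG context pools CHG and CHH calls", {
  calls <- toy_calls()
  expect_equal(global_methylation(calls, "nonCpG"), 100 * 1 / 2)
})

test_that("methylation of an uncovered context is undefined, not zero", {
  calls <- toy_calls()[toy_calls()$context == "CpG", ]
  expect_warning(out <- global_methylation(calls, "CHH"), "undefined")
  expect_identical(out, NA_real_)
})

test_that("region quantification follows half-open interval semantics", {
  # domain d1 = [0,200): a 1-based call at position 200 is its last base,
  # a call at position 201 opens d2 = [200,400)
  calls <- cpg_calls(chrom = "chr1", pos = c(200L, 201L), context = "CpG",
                     meth = c(1L, 1L), unmeth = c(0L, 0L))
  q <- quantify_regions(calls, toy_domains())
  expect_equal(q$total[q$name == "d1"], 1L)
  expect_equal(q$total[q$name == "d2"], 1L)
})

test_that("region quantification matches a brute-force sum", {
  set.seed(42)
  n <- 400
  meth <- rbinom(n, 1, 0.4)
  calls <- cpg_calls(chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
                     pos = sample(1:1000, n), context = "CpG",
                     meth = meth, unmeth = 1L - meth)
  d <- domain_set(chrom = c("chr1", "chr1", "chr2"),
                  start = c(0L, 300L, 100L), end = c(300L, 900L, 700L),
                  name = c("r1", "r2", "r3"),
                  class = c("hyper", "hypo", "inter"))
  q <- quantify_regions(calls, d)
  for (k in seq_len(nrow(d))) {
    inside <- calls$chrom == d$chrom[k] &
      calls$pos > d$start[k] & calls$pos <= d$end[k]
    expect_equal(q$meth[k], sum(calls$meth[inside]))
    expect_equal(q$total[k], sum(inside))
  }
})

test_that("regions without coverage are reported missing, not 0%", {
  calls <- cpg_calls("chr1", 50L, "CpG", 1L, 0L)
  q <- quantify_regions(calls, toy_domains(), warn_unmatched = FALSE)
  expect_true(is.na(q$pct[q$name == "d2"]))
  expect_equal(q$pct[q$name == "d1"], 100)
})

test_that("calls on chromosomes outside the region set raise a warning", {
  calls <- cpg_calls(c("chr1", "chrUn"), c(50L, 50L), "CpG",
                     c(1L, 1L), c(0L, 0L))
  expect_warning(quantify_regions(calls, toy_domains()), "chrUn")
})

test_that("merging cells conserves every call", {
  set.seed(7)
  cells <- lapply(1:4, function(i) {
    n <- sample(20:40, 1)
    meth <- rbinom(n, 1, 0.5)
    cpg_calls(chrom = "chr1", pos = sample(1:300, n), context = "CpG",
              meth = meth, unmeth = 1L - meth)
  })
  merged <- merge_cells(cells)
  expect_equal(sum(merged$meth), sum(vapply(cells, function(c) sum(c$meth), 0)))
  expect_equal(sum(merged$unmeth),
               sum(vapply(cells, function(c) sum(c$unmeth), 0)))
  # per-position counts equal the sum over member cells
  all <- do.call(rbind, cells)
  oracle <- rowsum(all$meth, all$pos)
  expect_equal(merged$meth[match(as.integer(rownames(oracle)), merged$pos)],
               as.integer(oracle[, 1]))
})

test_that("gDMR panels report group-level methylation per region", {
  gdmrs <- domain_set(chrom = "chr1", start = c(0L, 100L),
                      end = c(100L, 200L), name = c("m1", "p1"),
                      class = c("gdmr_maternal", "gdmr_paternal"))
  young <- cpg_calls("chr1", c(50L, 150L), "CpG", c(1L, 0L), c(0L, 1L))
  aged <- cpg_calls("chr1", c(60L, 160L), "CpG", c(1L, 0L), c(1L, 1L))
  panel <- gdmr_panel(list(young = young, aged = aged), gdmrs)
  expect_equal(panel["m1", "young"], 100)
  expect_equal(panel["m1", "aged"], 50)
  expect_equal(panel["p1", "aged"], 0)
  expect_error(gdmr_panel(list(young = young), gdmrs[0, ]), "empty")
})

test_that("QC metrics capture coverage, methylation and X-island signal", {
  x_cgi <- domain_set("chrX", 0L, 1000L, "xc1", "x_cgi")
  clean <- cpg_calls(c("chr1", "chr1", "chrX"), c(1L, 2L, 10L), "CpG",
                     c(1L, 0L, 0L), c(0L, 1L, 1L))
  qc <- methylome_qc(list(cell = clean), x_cgi = x_cgi,
                     mapping_efficiency = c(cell = 30))
  expect_equal(qc$n_cpgs, 3L)
  expect_equal(qc$global_cpg_pct, 100 / 3)
  expect_equal(qc$x_cgi_pct, 0)
  expect_equal(qc$mapping_efficiency, 30)
})

test_that("each QC rule discards exactly its violating cell", {
  metrics <- data.frame(
    cell_id = c("low_map", "few_cpgs", "hypermeth", "contaminated", "clean"),
    n_cpgs = c(6e5, 4e5, 6e5, 6e5, 6e5),
    global_cpg_pct = c(35, 35, 55, 35, 35),
    global_noncpg_pct = 2,
    x_cgi_pct = c(3, 3, 3, 25, 3),
    mapping_efficiency = c(8, 30, 30, 30, 30),
    stringsAsFactors = FALSE)
  out <- qc_filter(metrics)
  expect_identical(out$kept$cell_id, "clean")
  expect_identical(
    out$discarded$reasons,
    c("min_mapping_efficiency", "min_cpgs", "max_global_meth",
      "x_cgi_contamination"))
})

test_that("enabling the contamination check without X-island data errors", {
  metrics <- data.frame(cell_id = "c", n_cpgs = 6e5, global_cpg_pct = 35,
                        global_noncpg_pct = 2, x_cgi_pct = NA_real_,
                        mapping_efficiency = 30, stringsAsFactors = FALSE)
  expect_error(qc_filter(metrics), "X-CGI")
  expect_identical(qc_filter(metrics, check_x_cgi = FALSE)$kept$cell_id, "c")
})

test_that("cells without mapping metadata skip the mapping rule only", {
  metrics <- data.frame(cell_id = "c", n_cpgs = 6e5, global_cpg_pct = 35,
                        global_noncpg_pct = 2, x_cgi_pct = 3,
                        mapping_efficiency = NA_real_,
                        stringsAsFactors = FALSE)
  expect_identical(qc_filter(metrics)$kept$cell_id, "c")
})

test_that("group comparison uses the exact rank-sum null for small samples", {
  a <- c(1.1, 2.3, 3.7); b <- c(4.2, 5.9, 6.4, 7.7)
  ours <- group_compare(a, b)
  ref <- wilcox.test(a, b, exact = TRUE)
  expect_equal(ours$p, ref$p.value)
  expect_identical(ours$method, "exact")
})

test_that("tied groups fall back to the corrected normal approximation", {
  a <- c(1, 2, 2, 3); b <- c(2, 3, 4, 4)
  ours <- group_compare(a, b)
  ref <- suppressWarnings(wilcox.test(a, b, exact = FALSE, correct = TRUE))
  expect_equal(ours$p, ref$p.value)
})

test_that("identical degenerate groups are not a detectable difference", {
  out <- group_compare(rep(5, 4), rep(5, 6))
  expect_equal(out$p, 1)
})
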