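make_calls <- function(pos, meth, total, context = "CG", chrom = "chr1",
                       samples = NULL) {
  # meth/total: site x sample matrices
  if (is.null(samples)) samples <- paste0("s", seq_len(ncol(total)))
  colnames(meth) <- colnames(total) <- samples
  methylation_call_table(
    data.frame(chrom = chrom, pos = pos, strand = "+", context = context,
               stringsAsFactors = FALSE),
    meth, total)
}

test_that("smoothing pools windowed counts and window 0 is the identity", {
  # two sites 100 bp apart, fractions 0.2 and 0.8 with equal coverage
  calls <- make_calls(c(1000L, 1100L),
                      meth = matrix(c(2, 8), 2, 2),
                      total = matrix(10, 2, 2))
  sexes <- c("F", "M")
  mu <- smooth_methylation(calls, sexes, window_bp = 500)
  expect_equal(unname(mu[, "F"]), c(0.5, 0.5))
  mu0 <- smooth_methylation(calls, sexes, window_bp = 0)
  expect_equal(unname(mu0[, "F"]), c(0.2, 0.8))
  # isolated site keeps its own pooled fraction
  calls2 <- make_calls(c(1000L, 50000L),
                       meth = matrix(c(2, 8), 2, 2),
                       total = matrix(10, 2, 2))
  mu2 <- smooth_methylation(calls2, sexes, window_bp = 500)
  expect_equal(unname(mu2[, "M"]), c(0.2, 0.8))
})

test_that("smoothing respects chromosome and context boundaries", {
  calls <- methylation_call_table(
    data.frame(chrom = c("chr1", "chr1", "chr2"),
               pos = c(1000L, 1050L, 1000L),
               strand = "+", context = c("CG", "CHH", "CG")),
    matrix(c(10, 0, 0), 3, 2, dimnames = list(NULL, c("a", "b"))),
    matrix(10, 3, 2, dimnames = list(NULL, c("a", "b"))))
  mu <- smooth_methylation(calls, c("F", "M"), window_bp = 500)
  expect_equal(unname(mu[, "F"]), c(1, 0, 0))  # no cross-context pooling
})

test_that("site dispersion recovers simulated beta-binomial values", {
  set.seed(8)
  n <- 200  # pseudo-samples per sex
  rbb <- function(k, size, mu, phi) {
    a <- mu * (1 - phi) / phi; b <- (1 - mu) * (1 - phi) / phi
    rbinom(k, size, rbeta(k, a, b))
  }
  # phi = 0.2 at 30x coverage
  meth <- rbind(c(rbb(n, 30, 0.5, 0.2), rbb(n, 30, 0.5, 0.2)),
                c(rbinom(n, 30, 0.4), rbinom(n, 30, 0.4)))
  total <- matrix(30, 2, 2 * n)
  calls <- make_calls(c(1000L, 99000L), meth, total)
  sexes <- rep(c("F", "M"), each = n)
  mu <- smooth_methylation(calls, sexes, window_bp = 0)
  phi <- estimate_site_dispersion(calls, sexes, mu)
  expect_lt(abs(phi[1] - 0.2), 0.07)
  expect_lt(phi[2], 0.02)   # binomial site collapses toward the floor
})

test_that("single covered sample falls back to the dispersion floor", {
  calls <- make_calls(1000L, matrix(c(3, 0, 0, 0), 1, 4),
                      total = matrix(c(10, 0, 0, 0), 1, 4))
  sexes <- c("F", "F", "M", "M")
  mu <- smooth_methylation(calls, sexes, 0)
  phi <- estimate_site_dispersion(calls, sexes, mu)
  expect_equal(unname(phi), 1e-3)
})

test_that("DML Wald test: equal sexes give p = 1; planted deltas are caught", {
  calls <- make_calls(1000L, matrix(5, 1, 4), matrix(10, 1, 4))
  res <- wald_test_dml(calls, c("F", "F", "M", "M"))
  expect_equal(res$wald_stat, 0)
  expect_equal(res$p_value, 1)

  sim <- sim_small(seed = 21, dmr_count = 25,
                   dmr_length_range = c(200, 200),
                   dmr_delta_range = c(0.5, 0.5), coverage_mean = 30)
  sexes <- sexes_of(sim, colnames(sim$calls$meth))
  dml <- wald_test_dml(sim$calls, sexes)
  tr <- sim$truth$dmrs
  planted <- rep(FALSE, nrow(dml))
  for (j in seq_len(nrow(tr)))
    planted <- planted | (dml$chrom == tr$chrom[j] & dml$pos >= tr$start[j] &
                            dml$pos <= tr$end[j] & dml$context == tr$context[j])
  expect_gt(mean(dml$p_value[planted] < 0.001), 0.95)
})

test_that("DMR calling follows the length/count/density/merge rules", {
  # three candidates at 100/130/160 -> one region 100-160, all significant
  mk_dml <- function(pos, p) {
    data.frame(chrom = "chr1", pos = pos, context = "CG",
               mu_f = 0.8, mu_m = 0.2, phi = 0.01,
               wald_stat = 5, p_value = p, is_dml = p < 0.001,
               stringsAsFactors = FALSE)
  }
  d <- mk_dml(c(100L, 130L, 160L, 5000L, 9000L, 12000L),
              c(1e-4, 1e-4, 1e-4, 0.5, 0.5, 0.5))
  dmrs <- call_dmrs(d)
  expect_equal(nrow(dmrs), 1)
  expect_equal(dmrs$start, 100)
  expect_equal(dmrs$end, 160)
  expect_equal(dmrs$length, 61)
  expect_equal(dmrs$n_sites, 3)
  expect_equal(dmrs$n_significant, 3)

  # boundary on minimum length: span 50 kept, span 49 rejected
  d50 <- mk_dml(c(100L, 120L, 149L), rep(1e-4, 3))
  expect_equal(nrow(call_dmrs(d50)), 1)
  d49 <- mk_dml(c(100L, 120L, 148L), rep(1e-4, 3))
  expect_equal(nrow(call_dmrs(d49)), 0)

  # merge boundary: gap = start2 - end1 - 1, strict < 50
  d_merge <- mk_dml(c(100L, 130L, 160L, 200L, 230L, 260L), rep(1e-4, 6))
  m <- call_dmrs(d_merge, cluster_gap = 30)
  expect_equal(nrow(m), 1)      # gap 39 -> merged
  expect_equal(c(m$start, m$end), c(100, 260))
  d_apart <- mk_dml(c(100L, 130L, 160L, 216L, 246L, 276L), rep(1e-4, 6))
  m2 <- call_dmrs(d_apart, cluster_gap = 30)
  expect_equal(nrow(m2), 2)     # gap 55 -> kept apart
})

test_that("density rule: regions below 50% significant sites are dropped", {
  d <- data.frame(chrom = "chr1",
                  pos = c(100L, 120L, 140L, 160L, 180L, 200L, 220L),
                  context = "CG", mu_f = 0.7, mu_m = 0.3, phi = 0.01,
                  wald_stat = 3,
                  p_value = c(1e-4, 0.5, 0.5, 1e-4, 0.5, 0.5, 1e-4),
                  is_dml = FALSE, stringsAsFactors = FALSE)
  # 3 candidates, 7 analyzed sites in span 100-220 -> 3/7 < 0.5
  expect_equal(nrow(call_dmrs(d)), 0)
})

test_that("DMR recovery on planted regions reaches high sensitivity and precision", {
  sim <- sim_small(seed = 7, dmr_count = 30, dmr_length_range = c(200, 200),
                   dmr_delta_range = c(0.4, 0.4), coverage_mean = 20,
                   n_sites = c(CG = 2000, CHG = 300, CHH = 300))
  sexes <- sexes_of(sim, colnames(sim$calls$meth))
  dmrs <- call_dmrs(wald_test_dml(sim$calls, sexes))
  tr <- sim$truth$dmrs
  rec <- function(a, b) {
    hits <- 0
    for (i in seq_len(nrow(a))) {
      o <- pmin(a$end[i], b$end) - pmax(a$start[i], b$start) + 1
      if (any(b$chrom == a$chrom[i] & o > 0 &
                o >= 0.5 * (a$end[i] - a$start[i] + 1) &
                o >= 0.5 * (b$end - b$start + 1))) hits <- hits + 1
    }
    hits
  }
  expect_gte(rec(dmrs, tr) / nrow(dmrs), 0.8)   # precision
  expect_gte(rec(tr, dmrs) / nrow(tr), 0.8)     # sensitivity
  # determinism
  dmrs2 <- call_dmrs(wald_test_dml(sim$calls, sexes))
  expect_identical(dmrs, dmrs2)
})

test_that("genomic-context annotation follows precedence with compound labels", {
  gm <- local({
    g <- GenomicRanges::GRanges("chr1", IRanges::IRanges(5000, 9000), "+")
    g$gene_id <- "gA"; g$tss <- 5000; names(g) <- "gA"
    ex <- GenomicRanges::GRangesList(gA = GenomicRanges::GRanges(
      "chr1", IRanges::IRanges(c(5000, 7000), c(6000, 9000)), "+"))
    structure(list(genes = g, exons = ex), class = "GeneModelSet")
  })
  base <- data.frame(context = "CG", n_sites = 3L, n_significant = 3L,
                     mean_meth_f = 0.7, mean_meth_m = 0.2,
                     stringsAsFactors = FALSE)
  mk <- function(s, e) cbind(data.frame(chrom = "chr1", start = s, end = e,
                                        length = e - s + 1), base)
  expect_equal(annotate_genomic_context(mk(7100, 7300), gm)$genomic_context,
               "Exon")                 # inside exon 2, outside the promoter
  expect_equal(annotate_genomic_context(mk(6900, 7100), gm)$genomic_context,
               "Exon/Intron")          # spans the intron / exon-2 junction
  expect_equal(annotate_genomic_context(mk(6100, 6900), gm)$genomic_context,
               "Intron")
  expect_equal(annotate_genomic_context(mk(4500, 4800), gm)$genomic_context,
               "Promoter")
  expect_equal(annotate_genomic_context(mk(5100, 5200), gm)$genomic_context,
               "Promoter/Exon")        # within TSS+1000 and exon 1
  far <- annotate_genomic_context(mk(19000, 19100), gm)
  expect_equal(far$genomic_context, "Intergenic")
  expect_equal(far$assigned_gene, "gA")
  expect_equal(far$distance_to_gene, 9999)  # edge distance 19000 - 9000 - 1
})

test_that("per-sample DMR mean methylation averages site fractions", {
  calls <- make_calls(c(100L, 150L, 200L),
                      meth = cbind(c(2, 4, 9), c(0, 0, 0)),
                      total = cbind(c(10, 10, 10), c(10, 10, 0)))
  dmr <- data.frame(chrom = "chr1", start = 90, end = 210, length = 121,
                    context = "CG", n_sites = 3, n_significant = 3,
                    mean_meth_f = 0.5, mean_meth_m = 0.5)
  m <- dmr_mean_methylation(calls, dmr)
  expect_equal(unname(m[1, "s1"]), 0.5)           # mean(0.2, 0.4, 0.9)
  expect_equal(unname(m[1, "s2"]), 0)             # covered sites only
  # zero coverage everywhere -> missing
  calls0 <- make_calls(100L, matrix(0, 1, 2), matrix(0, 1, 2))
  expect_true(is.na(dmr_mean_methylation(calls0, dmr)[1, 1]))
})

test_that("context summary computes Cohen's d from pooled SDs", {
  set.seed(3)
  n <- 500
  meth_f <- rbinom(n, 50, 0.6); meth_m <- rbinom(n, 50, 0.5)
  calls <- make_calls(sort(sample.int(1e7, n)),
                      meth = cbind(meth_f, meth_m),
                      total = matrix(50, n, 2))
  cs <- context_summary(calls, c("F", "M"))
  expect_equal(cs$mean_f, 0.6, tolerance = 0.02)
  d_hand <- abs(cs$mean_f - cs$mean_m) / sqrt((cs$sd_f^2 + cs$sd_m^2) / 2)
  expect_equal(cs$cohens_d, d_hand)
  # identical sexes give d = 0
  calls_eq <- make_calls(c(100L, 20000L), cbind(c(3, 7), c(3, 7)),
                         matrix(10, 2, 2))
  expect_equal(context_summary(calls_eq, c("F", "M"))$cohens_d, 0)
})

test_that("simulated context baselines are recovered in the summary", {
  sim <- sim_small(seed = 15, dmr_count = 0)
  sexes <- sexes_of(sim, colnames(sim$calls$meth))
  cs <- context_summary(sim$calls, sexes)
  cfg_baseline <- c(CG = 0.6, CHG = 0.2, CHH = 0.15)
  for (ctx in names(cfg_baseline)) {
    expect_lt(abs(cs$mean_f[cs$context == ctx] - cfg_baseline[[ctx]]), 0.03)
    expect_lt(abs(cs$mean_m[cs$context == ctx] - cfg_baseline[[ctx]]), 0.03)
  }
})
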