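# Shared fixtures: tiny in-code datasets and independent oracle
# implementations used across test files.

make_counts_file <- function(path, genes = c("g1", "g2"),
                             lengths = c(1000, 2500),
                             counts = matrix(c(100, 50, 0, 7), 2, 2,
                                             dimnames = list(NULL,
                                                             c("s1", "s2")))) {
  df <- data.frame(gene_id = genes, length_bp = lengths, counts,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

make_meth_file <- function(path) {
  df <- data.frame(chrom = c("chr1", "chr1", "chr2"),
                   pos = c(100L, 50L, 10L),
                   strand = c("+", "-", "+"),
                   context = c("CG", "chh", "CHG"),
                   s1_meth = c(3L, 0L, 5L), s1_total = c(10L, 4L, 5L),
                   s2_meth = c(1L, 2L, 0L), s2_total = c(2L, 8L, 0L))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

make_gff3_file <- function(path, lines = NULL) {
  if (is.null(lines))
    lines <- c("##gff-version 3",
               "chr1\t.\tgene\t100\t200\t.\t+\t.\tID=gA",
               "chr1\t.\texon\t100\t140\t.\t+\t.\tID=gA.e1;Parent=gA",
               "chr1\t.\texon\t160\t200\t.\t+\t.\tID=gA.e2;Parent=gA",
               "chr2\t.\tgene\t100\t200\t.\t-\t.\tID=gB",
               "chr2\t.\texon\t100\t200\t.\t-\t.\tID=gB.e1;Parent=gB")
  writeLines(lines, path)
  path
}

# brute-force BH step-up used as the oracle against bh_fdr
bh_brute <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(1, adj)
  out
}

# exact hypergeometric upper tail by direct enumeration
hyper_enum <- function(k, K, n, N) {
  ks <- max(0, n - (N - K)):min(n, K)
  probs <- choose(K, ks) * choose(N - K, n - ks) / choose(N, n)
  sum(probs[ks >= k])
}

# pooled two-sample t statistic from the textbook formula
pooled_t <- function(x, y) {
  sp2 <- ((length(x) - 1) * var(x) + (length(y) - 1) * var(y)) /
    (length(x) + length(y) - 2)
  (mean(x) - mean(y)) / sqrt(sp2 * (1 / length(x) + 1 / length(y)))
}

# AUC as the fraction of concordant (class1, class2) pairs, enumerated
auc_enum <- function(score, outcome) {
  g <- split(score, outcome)
  pairs <- expand.grid(a = g[[1]], b = g[[2]])
  auc <- mean(pairs$b > pairs$a) + 0.5 * mean(pairs$b == pairs$a)
  max(auc, 1 - auc)
}

sim_small <- function(seed = 42, ...) {
  args <- list(seed = seed, n_genes = 400, dmr_count = 10,
               n_sites = c(CG = 500, CHG = 150, CHH = 150))
  dots <- list(...)
  args[names(dots)] <- dots
  simulate_experiment(do.call(simulation_config, args))
}

sexes_of <- function(sim, cols) {
  sim$metadata$sex[match(cols, sim$metadata$sample_id)]
}
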