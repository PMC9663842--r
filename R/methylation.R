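# Smoothed beta-binomial Wald DML testing, rule-based DMR calling,
# genomic-context annotation and global context summaries.

#' Moving-average smoothed group methylation means
#'
#' For each site and sex, the pooled fraction (sum methylated / sum total)
#' over all same-context sites within +/- window_bp/2 on the same
#' chromosome; a zero-coverage window yields NA.
#' @param calls MethylationCallTable (sorted by chrom, pos).
#' @param sexes per-sample sex vector aligned with call columns.
#' @param window_bp full smoothing window width; 0 disables smoothing.
#' @return site x 2 matrix of smoothed means (columns F, M) with
#'   attributes \code{wt} (window total reads) and \code{ws2} (window sum
#'   of squared per-cell read totals), both site x 2, used by the Wald
#'   variance of the pooled window estimator.
#' @export
smooth_methylation <- function(calls, sexes, window_bp = 500) {
  half <- window_bp / 2
  sites <- calls$sites
  mu <- matrix(NA_real_, nrow(sites), 2, dimnames = list(NULL, c("F", "M")))
  wt_out <- mu; ws2_out <- mu
  for (sx in c("F", "M")) {
    sel <- sexes == sx
    msum <- rowSums(calls$meth[, sel, drop = FALSE])
    tsum <- rowSums(calls$total[, sel, drop = FALSE])
    t2sum <- rowSums(calls$total[, sel, drop = FALSE]^2)
    key <- paste(sites$chrom, sites$context)
    for (k in unique(key)) {
      idx <- which(key == k)
      pos <- sites$pos[idx]
      # sites already sorted by pos within chrom
      cm <- c(0, cumsum(msum[idx])); ct <- c(0, cumsum(tsum[idx]))
      c2 <- c(0, cumsum(t2sum[idx]))
      lo <- findInterval(pos - half - 0.5, pos)      # last index < pos-half
      hi <- findInterval(pos + half + 0.5 - 1e-9, pos)
      wm <- cm[hi + 1] - cm[lo + 1]
      wt <- ct[hi + 1] - ct[lo + 1]
      mu[idx, sx] <- ifelse(wt > 0, wm / wt, NA_real_)
      wt_out[idx, sx] <- wt
      ws2_out[idx, sx] <- c2[hi + 1] - c2[lo + 1]
    }
  }
  attr(mu, "wt") <- wt_out
  attr(mu, "ws2") <- ws2_out
  mu
}

#' Per-site beta-binomial dispersion (method of moments)
#'
#' Pools squared deviations of per-sample fractions from each sex's smoothed
#' mean; solves the beta-binomial variance identity
#' Var(x/n) = mu(1-mu)(1 + (n-1) phi)/n for phi, clamped to
#' [phi_floor, 0.5]. Sites with fewer than two covered samples per sex get
#' the floor.
#' @param calls MethylationCallTable.
#' @param sexes per-sample sex vector.
#' @param mu smoothed means from \code{\link{smooth_methylation}}.
#' @param phi_floor,phi_ceiling clamp bounds.
#' @return per-site dispersion vector.
#' @export
estimate_site_dispersion <- function(calls, sexes, mu,
                                     phi_floor = 1e-3, phi_ceiling = 0.5) {
  k <- nrow(calls$sites)
  num <- numeric(k); den <- numeric(k); base <- numeric(k)
  enough <- rep(TRUE, k)
  for (sx in c("F", "M")) {
    sel <- sexes == sx
    tot <- calls$total[, sel, drop = FALSE]
    met <- calls$meth[, sel, drop = FALSE]
    cov <- tot > 0
    enough <- enough & rowSums(cov) >= 2
    m <- mu[, sx]
    fr <- met / tot
    d2 <- (fr - m)^2
    d2[!cov] <- 0
    mq <- m * (1 - m)
    num <- num + rowSums(d2) - mq * rowSums(ifelse(cov, 1 / tot, 0))
    den <- den + mq * rowSums(ifelse(cov, (tot - 1) / tot, 0))
  }
  phi <- ifelse(den > 0, num / den, phi_floor)
  phi[!enough | !is.finite(phi)] <- phi_floor
  pmin(phi_ceiling, pmax(phi_floor, phi))
}

#' Wald test for differentially methylated loci
#'
#' stat = (mu_F - mu_M) / sqrt(v_F + v_M) with v the phi-inflated binomial
#' variance of each sex's pooled estimator; the two-sided p-value uses a t
#' reference with (covered samples - 2) degrees of freedom, which keeps the
#' null calibrated in 6-vs-6 designs where the plug-in variance is noisy.
#' Sites with one sex entirely uncovered are skipped.
#' @param calls MethylationCallTable.
#' @param sexes per-sample sex vector.
#' @param window_bp smoothing window passed to
#'   \code{\link{smooth_methylation}}.
#' @param p_dml threshold used to flag a DML.
#' @return data.frame: chrom, pos, context, mu_f, mu_m, phi, wald_stat,
#'   p_value, is_dml.
#' @export
wald_test_dml <- function(calls, sexes, window_bp = 500, p_dml = 0.001) {
  mu <- smooth_methylation(calls, sexes, window_bp)
  phi <- estimate_site_dispersion(calls, sexes, mu)
  v <- matrix(NA_real_, nrow(calls$sites), 2, dimnames = list(NULL, c("F", "M")))
  wt <- attr(mu, "wt"); ws2 <- attr(mu, "ws2")
  for (sx in c("F", "M")) {
    m <- mu[, sx]
    mq <- pmax(m * (1 - m), 1e-6)
    # pooled window estimator: Var = mu(1-mu) sum_r n_r (1 + (n_r-1) phi) / N^2
    #                              = mu(1-mu) (N + phi (sum n_r^2 - N)) / N^2
    v[, sx] <- mq * (wt[, sx] + phi * (ws2[, sx] - wt[, sx])) / wt[, sx]^2
  }
  ok <- is.finite(mu[, "F"]) & is.finite(mu[, "M"])
  stat <- (mu[, "F"] - mu[, "M"]) / sqrt(v[, "F"] + v[, "M"])
  n_cov <- rowSums(calls$total > 0)
  p <- 2 * stats::pt(-abs(stat), df = pmax(2, n_cov - 2))
  p[mu[, "F"] == mu[, "M"]] <- 1
  out <- data.frame(chrom = calls$sites$chrom, pos = calls$sites$pos,
                    context = calls$sites$context,
                    mu_f = mu[, "F"], mu_m = mu[, "M"], phi = phi,
                    wald_stat = stat, p_value = p,
                    stringsAsFactors = FALSE)
  out <- out[ok, , drop = FALSE]
  out$is_dml <- out$p_value < p_dml
  rownames(out) <- NULL
  out
}

#' Call differentially methylated regions
#'
#' Per context and chromosome: sites at p < p_site seed candidate clusters
#' (inter-candidate gap <= cluster_gap); clusters are kept when span length
#' >= min_len, analyzed sites in span >= min_sites, and the significant
#' fraction >= min_pct_sig; surviving regions separated by fewer than
#' merge_gap intervening bases are merged with counts recomputed. Group
#' means are simple means of the span's smoothed site-level fractions.
#' @param dml output of \code{\link{wald_test_dml}}.
#' @param p_site candidate-site p threshold.
#' @param min_len minimum region length (bp, inclusive span).
#' @param min_sites minimum analyzed sites in span.
#' @param min_pct_sig minimum significant fraction among analyzed sites.
#' @param cluster_gap maximum gap between consecutive candidate sites.
#' @param merge_gap regions closer than this many intervening bases merge.
#' @return data.frame of DMRs: chrom, start, end, length, context, n_sites,
#'   n_significant, mean_meth_f, mean_meth_m.
#' @export
call_dmrs <- function(dml, p_site = 0.01, min_len = 50, min_sites = 3,
                      min_pct_sig = 0.5, cluster_gap = 100, merge_gap = 50) {
  out <- list()
  for (ctx in unique(dml$context)) {
    for (ch in unique(dml$chrom[dml$context == ctx])) {
      d <- dml[dml$context == ctx & dml$chrom == ch, , drop = FALSE]
      d <- d[order(d$pos), , drop = FALSE]
      cand <- which(d$p_value < p_site)
      if (length(cand) == 0) next
      cpos <- d$pos[cand]
      brk <- which(diff(cpos) > cluster_gap)
      starts <- c(1, brk + 1); ends <- c(brk, length(cpos))
      regions <- data.frame(start = cpos[starts], end = cpos[ends])
      # filter by span rules
      keep <- logical(nrow(regions))
      for (i in seq_len(nrow(regions))) {
        span <- d$pos >= regions$start[i] & d$pos <= regions$end[i]
        n_sites_i <- sum(span)
        n_sig <- sum(span & d$p_value < p_site)
        len <- regions$end[i] - regions$start[i] + 1
        keep[i] <- len >= min_len && n_sites_i >= min_sites &&
          n_sig / n_sites_i >= min_pct_sig
      }
      regions <- regions[keep, , drop = FALSE]
      if (nrow(regions) == 0) next
      # merge regions with < merge_gap intervening bases
      i <- 1
      while (i < nrow(regions)) {
        gap <- regions$start[i + 1] - regions$end[i] - 1
        if (gap < merge_gap) {
          regions$end[i] <- regions$end[i + 1]
          regions <- regions[-(i + 1), , drop = FALSE]
        } else i <- i + 1
      }
      for (i in seq_len(nrow(regions))) {
        span <- d$pos >= regions$start[i] & d$pos <= regions$end[i]
        out[[length(out) + 1]] <- data.frame(
          chrom = ch, start = regions$start[i], end = regions$end[i],
          length = regions$end[i] - regions$start[i] + 1, context = ctx,
          n_sites = sum(span),
          n_significant = sum(span & d$p_value < p_site),
          mean_meth_f = mean(d$mu_f[span]), mean_meth_m = mean(d$mu_m[span]),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0)
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      length = integer(), context = character(),
                      n_sites = integer(), n_significant = integer(),
                      mean_meth_f = numeric(), mean_meth_m = numeric(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- res[order(res$context, res$chrom, res$start), , drop = FALSE]
  stopifnot(all(res$length >= min_len), all(res$n_sites >= min_sites),
            all(res$n_significant / res$n_sites >= min_pct_sig))
  rownames(res) <- NULL
  res
}

#' Annotate DMRs with genomic context and nearest gene
#'
#' Precedence Promoter > Exon > Intron; the promoter is TSS +/- the stated
#' windows (strand-aware). When a DMR overlaps several feature classes of
#' its assigned gene the label is compound (e.g. "Exon/Intron"). DMRs
#' overlapping no gene are "Intergenic" and get the nearest gene by edge
#' distance (ties broken by gene id).
#' @param dmrs DMR data.frame from \code{\link{call_dmrs}}.
#' @param models GeneModelSet.
#' @param promoter_up,promoter_down promoter window around the TSS (bp).
#' @return the input with genomic_context, assigned_gene, distance_to_gene.
#' @export
annotate_genomic_context <- function(dmrs, models, promoter_up = 1000,
                                     promoter_down = 1000) {
  n <- nrow(dmrs)
  dmrs$genomic_context <- rep("Intergenic", n)
  dmrs$assigned_gene <- rep(NA_character_, n)
  dmrs$distance_to_gene <- rep(NA_real_, n)
  if (n == 0 || length(models$genes) == 0) return(dmrs)
  g <- models$genes
  dg <- GenomicRanges::GRanges(dmrs$chrom,
                               IRanges::IRanges(dmrs$start, dmrs$end))
  tss <- g$tss
  plus <- as.character(GenomicRanges::strand(g)) == "+"
  prom <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(g),
    IRanges::IRanges(pmax(1, ifelse(plus, tss - promoter_up, tss - promoter_down)),
                     ifelse(plus, tss + promoter_down, tss + promoter_up)))
  prom$gene_id <- g$gene_id
  body_hits <- GenomicRanges::findOverlaps(dg, g, ignore.strand = TRUE)
  prom_hits <- GenomicRanges::findOverlaps(dg, prom, ignore.strand = TRUE)
  for (i in seq_len(n)) {
    bh <- S4Vectors::subjectHits(body_hits)[S4Vectors::queryHits(body_hits) == i]
    ph <- S4Vectors::subjectHits(prom_hits)[S4Vectors::queryHits(prom_hits) == i]
    cand <- union(bh, ph)
    if (length(cand) == 0) {
      d <- GenomicRanges::distanceToNearest(dg[i], g, ignore.strand = TRUE)
      if (length(d) == 0) next
      j <- S4Vectors::subjectHits(d)
      dist <- S4Vectors::mcols(d)$distance
      same <- which(as.character(GenomicRanges::seqnames(g)) ==
                      as.character(GenomicRanges::seqnames(dg[i])))
      # distanceToNearest already restricts to same seqnames
      dmrs$genomic_context[i] <- "Intergenic"
      dmrs$assigned_gene[i] <- g$gene_id[j]
      dmrs$distance_to_gene[i] <- dist
      next
    }
    # assign the candidate gene with the largest overlap (promoter included)
    ov <- vapply(cand, function(j) {
      w <- 0
      if (j %in% bh)
        w <- max(w, min(dmrs$end[i], GenomicRanges::end(g)[j]) -
                   max(dmrs$start[i], GenomicRanges::start(g)[j]) + 1)
      if (j %in% ph)
        w <- max(w, min(dmrs$end[i], GenomicRanges::end(prom)[j]) -
                   max(dmrs$start[i], GenomicRanges::start(prom)[j]) + 1)
      w
    }, 0)
    ids <- g$gene_id[cand]
    best <- cand[order(-ov, ids)][1]
    id <- g$gene_id[best]
    labels <- character()
    if (best %in% ph) labels <- c(labels, "Promoter")
    if (best %in% bh) {
      ex <- models$exons[[id]]
      ex_ov <- GenomicRanges::countOverlaps(dg[i], ex, ignore.strand = TRUE) > 0
      intr <- gene_introns(models, id)
      in_ov <- length(intr) > 0 &&
        sum(IRanges::countOverlaps(IRanges::IRanges(dmrs$start[i], dmrs$end[i]),
                                   intr)) > 0
      if (ex_ov) labels <- c(labels, "Exon")
      if (in_ov) labels <- c(labels, "Intron")
    }
    if (length(labels) == 0) labels <- "Intergenic"
    dmrs$genomic_context[i] <- paste(labels, collapse = "/")
    dmrs$assigned_gene[i] <- id
    dmrs$distance_to_gene[i] <- 0
  }
  dmrs
}

#' Per-sample mean methylation within a DMR
#'
#' Unweighted mean of per-site fractions over same-context sites in the DMR
#' span; samples with no covered site get NA.
#' @param calls MethylationCallTable.
#' @param dmrs DMR data.frame.
#' @return DMR x sample matrix.
#' @export
dmr_mean_methylation <- function(calls, dmrs) {
  fr <- meth_fraction(calls)
  out <- matrix(NA_real_, nrow(dmrs), ncol(fr),
                dimnames = list(dmr_id(dmrs), colnames(fr)))
  for (i in seq_len(nrow(dmrs))) {
    sel <- calls$sites$chrom == dmrs$chrom[i] &
      calls$sites$pos >= dmrs$start[i] & calls$sites$pos <= dmrs$end[i] &
      calls$sites$context == dmrs$context[i]
    if (!any(sel)) next
    out[i, ] <- colMeans(fr[sel, , drop = FALSE], na.rm = TRUE)
  }
  out[is.nan(out)] <- NA_real_
  out
}

#' Canonical DMR identifier strings
#' @param dmrs DMR data.frame.
#' @return "chrom:start-end_context" ids.
#' @export
dmr_id <- function(dmrs) {
  sprintf("%s:%d-%d_%s", dmrs$chrom, dmrs$start, dmrs$end, dmrs$context)
}

#' Global per-context methylation summary with Cohen's D
#'
#' Site-level pooled fractions per sex (sum meth / sum total per site),
#' their mean and SD per sex, and the standardized mean difference
#' |m_F - m_M| / sqrt((sd_F^2 + sd_M^2)/2).
#' @param calls MethylationCallTable.
#' @param sexes per-sample sex vector.
#' @return data.frame: context, mean_f, sd_f, mean_m, sd_m, cohens_d.
#' @export
context_summary <- function(calls, sexes) {
  rows <- list()
  for (ctx in unique(calls$sites$context)) {
    sel <- calls$sites$context == ctx
    if (sum(sel) < 2) next
    stat <- list()
    for (sx in c("F", "M")) {
      sc <- sexes == sx
      m <- rowSums(calls$meth[sel, sc, drop = FALSE])
      t <- rowSums(calls$total[sel, sc, drop = FALSE])
      fr <- ifelse(t > 0, m / t, NA_real_)
      stat[[sx]] <- c(mean(fr, na.rm = TRUE), stats::sd(fr, na.rm = TRUE))
    }
    pooled <- sqrt((stat$F[2]^2 + stat$M[2]^2) / 2)
    rows[[ctx]] <- data.frame(
      context = ctx, mean_f = stat$F[1], sd_f = stat$F[2],
      mean_m = stat$M[1], sd_m = stat$M[2],
      cohens_d = if (pooled > 0) abs(stat$F[1] - stat$M[1]) / pooled else 0,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the methylation stage end-to-end
#' @param calls MethylationCallTable.
#' @param metadata metadata data.frame.
#' @param models GeneModelSet for annotation (optional).
#' @param ... passed to \code{\link{wald_test_dml}} / \code{\link{call_dmrs}}.
#' @return list with \code{dml}, \code{dmrs} (annotated when models given),
#'   \code{summary}.
#' @export
run_methylation_stage <- function(calls, metadata, models = NULL, ...) {
  sexes <- metadata$sex[match(colnames(calls$meth), metadata$sample_id)]
  dml <- wald_test_dml(calls, sexes)
  dmrs <- call_dmrs(dml, ...)
  if (!is.null(models)) dmrs <- annotate_genomic_context(dmrs, models)
  list(dml = dml, dmrs = dmrs, summary = context_summary(calls, sexes))
}
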