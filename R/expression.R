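# Differential expression: FPKM filtering, median-of-ratios normalization,
# method-of-moments NB dispersion, group-mean Wald test, BH FDR.

#' FPKM normalization
#'
#' fpkm[g,s] = count / (length_kb) / (library_size_millions).
#' @param expr ExpressionCountMatrix.
#' @return gene x sample FPKM matrix.
#' @export
fpkm <- function(expr) {
  counts <- expr$counts
  libs <- colSums(counts)
  if (any(libs == 0)) stop("sample with all-zero counts")
  t(t(counts / (expr$gene_length_bp / 1e3)) / (libs / 1e6))
}

#' Filter lowly expressed genes
#'
#' A gene is removed only when its mean FPKM is below the threshold in
#' both sexes.
#' @param fpkm_mat gene x sample FPKM matrix.
#' @param sexes per-sample sex vector ("M"/"F"), aligned with columns.
#' @param threshold FPKM cutoff (strict \code{<} for removal).
#' @return character vector of kept gene ids.
#' @export
filter_low_expression <- function(fpkm_mat, sexes, threshold = 0.2) {
  stopifnot(length(sexes) == ncol(fpkm_mat))
  if (!all(c("M", "F") %in% sexes)) stop("both sexes required")
  mm <- rowMeans(fpkm_mat[, sexes == "M", drop = FALSE])
  mf <- rowMeans(fpkm_mat[, sexes == "F", drop = FALSE])
  rownames(fpkm_mat)[mm >= threshold | mf >= threshold]
}

#' Median-of-ratios size factors
#'
#' Per-sample median of count/geometric-mean ratios over genes positive in
#' all samples, rescaled to geometric mean 1.
#' @param expr ExpressionCountMatrix or a counts matrix.
#' @return named numeric vector of size factors.
#' @export
size_factors_median_of_ratios <- function(expr) {
  counts <- if (inherits(expr, "ExpressionCountMatrix")) expr$counts else expr
  allpos <- rowSums(counts == 0) == 0
  if (!any(allpos)) stop("no gene with nonzero counts in every sample")
  sub <- counts[allpos, , drop = FALSE]
  loggeo <- rowMeans(log(sub))
  sf <- apply(sub, 2, function(cnt) exp(stats::median(log(cnt) - loggeo)))
  sf / exp(mean(log(sf)))
}

#' Method-of-moments negative-binomial dispersion
#'
#' Pooled across sex groups after removing the group-mean effect:
#' alpha = max(floor, (s^2 - mean) / mean^2) on normalized counts.
#' @param expr ExpressionCountMatrix or counts matrix.
#' @param sf size factors.
#' @param sexes per-sample sex vector.
#' @param alpha_floor lower bound on the dispersion.
#' @return per-gene dispersion vector.
#' @export
estimate_nb_dispersion <- function(expr, sf, sexes, alpha_floor = 1e-4) {
  counts <- if (inherits(expr, "ExpressionCountMatrix")) expr$counts else expr
  stopifnot(ncol(counts) >= 3)
  norm <- t(t(counts) / sf)
  groups <- unique(sexes)
  mbar <- rowMeans(norm)
  resid2 <- 0; df <- 0
  for (g in groups) {
    sel <- sexes == g
    gm <- rowMeans(norm[, sel, drop = FALSE])
    resid2 <- resid2 + rowSums((norm[, sel, drop = FALSE] - gm)^2)
    df <- df + sum(sel) - 1
  }
  s2 <- resid2 / df
  alpha <- (s2 - mbar) / mbar^2
  alpha[!is.finite(alpha)] <- alpha_floor
  pmax(alpha_floor, alpha)
}

#' Group-mean negative-binomial Wald test for sex differences
#'
#' log2FC = log2((mean normalized female + pc)/(mean normalized male + pc));
#' positive values mean higher expression in females. The standard error
#' comes from the delta method on NB group means; the Wald statistic is
#' referred to a t distribution with n - 2 degrees of freedom (small-sample
#' calibration at n = 12).
#'
#' @param expr ExpressionCountMatrix or counts matrix.
#' @param sf size factors.
#' @param dispersions per-gene NB dispersion.
#' @param sexes per-sample sex vector.
#' @param pseudocount added to both group means inside the ratio.
#' @return data.frame with gene_id, log2fc, lfcse, wald_stat, p_value, fdr.
#' @export
wald_test_de <- function(expr, sf, dispersions, sexes, pseudocount = 0.5) {
  counts <- if (inherits(expr, "ExpressionCountMatrix")) expr$counts else expr
  stopifnot(sum(sexes == "M") >= 2, sum(sexes == "F") >= 2)
  norm <- t(t(counts) / sf)
  fsel <- sexes == "F"; msel <- sexes == "M"
  mf <- rowMeans(norm[, fsel, drop = FALSE])
  mm <- rowMeans(norm[, msel, drop = FALSE])
  var_group <- function(m, sel) {
    # Var(K_s/sf_s) = mu/sf_s + alpha mu^2; mean over n has 1/n^2 sum
    n <- sum(sel)
    sapply_mu <- outer(m, 1 / sf[sel]) + dispersions * m^2
    rowSums(sapply_mu) / n^2
  }
  vf <- var_group(mf, fsel); vm <- var_group(mm, msel)
  log2fc <- log2((mf + pseudocount) / (mm + pseudocount))
  se_log2 <- sqrt(vf / (mf + pseudocount)^2 + vm / (mm + pseudocount)^2) / log(2)
  se_log2 <- pmax(se_log2, 1e-8)
  wald <- log2fc / se_log2
  df <- length(sexes) - 2
  p <- 2 * stats::pt(-abs(wald), df = df)
  p[mf == mm] <- 1
  res <- data.frame(gene_id = rownames(counts), log2fc = log2fc,
                    lfcse = se_log2, wald_stat = wald, p_value = p,
                    stringsAsFactors = FALSE, row.names = NULL)
  res$fdr <- bh_fdr(res$p_value)
  res
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment; NaN/NA inputs are passed through and excluded
#' from the ranking.
#' @param p numeric vector of p-values.
#' @return adjusted values in [0,1] (NA where input was NA).
#' @export
bh_fdr <- function(p) {
  out <- p
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values outside [0,1]")
  out[ok] <- stats::p.adjust(p[ok], method = "BH")
  out
}

#' Call differentially expressed genes
#' @param results output of \code{\link{wald_test_de}}.
#' @param fdr_max strict FDR bound.
#' @param lfc_min strict |log2FC| bound.
#' @return gene ids with fdr < fdr_max and |log2fc| > lfc_min.
#' @export
call_degs <- function(results, fdr_max = 0.05, lfc_min = 2) {
  results$gene_id[!is.na(results$fdr) & results$fdr < fdr_max &
                    abs(results$log2fc) > lfc_min]
}

#' Call integration candidate genes
#'
#' Candidates for the discriminant analysis: |log2FC| strictly above the
#' bound, regardless of FDR.
#' @param results output of \code{\link{wald_test_de}}.
#' @param lfc_min strict |log2FC| bound.
#' @return gene ids.
#' @export
call_candidates <- function(results, lfc_min = 1) {
  results$gene_id[abs(results$log2fc) > lfc_min]
}

#' Run the full differential-expression stage
#'
#' FPKM filter, size factors, dispersion, Wald test, FDR, and both gene
#' calls in one step.
#' @param expr ExpressionCountMatrix.
#' @param metadata metadata data.frame (sample_id, sex).
#' @param fpkm_threshold low-expression filter cutoff.
#' @return list with \code{results}, \code{fpkm}, \code{kept_genes},
#'   \code{size_factors}, \code{degs}, \code{candidates}.
#' @export
run_de_stage <- function(expr, metadata, fpkm_threshold = 0.2) {
  sexes <- metadata$sex[match(colnames(expr$counts), metadata$sample_id)]
  fp <- fpkm(expr)
  keep <- filter_low_expression(fp, sexes, fpkm_threshold)
  sub <- expression_count_matrix(expr$counts[keep, , drop = FALSE],
                                 expr$gene_length_bp[keep])
  sf <- size_factors_median_of_ratios(sub)
  disp <- estimate_nb_dispersion(sub, sf, sexes)
  res <- wald_test_de(sub, sf, disp, sexes)
  list(results = res, fpkm = fp, kept_genes = keep, size_factors = sf,
       degs = call_degs(res), candidates = call_candidates(res))
}
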