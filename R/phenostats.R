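# Phenotype comparison: Anderson-Darling normality, F-test variance
# equality and pooled-variance Student's t per fat-percentage trait.

#' Compare fat-percentage traits between sexes
#'
#' Per trait: Anderson-Darling normality test within each sex (estimated
#' mean/variance variant), an F test for variance equality, and a
#' two-sided pooled-variance Student's t test, flagged significant at
#' p < 0.05. Missing values are dropped pairwise with a warning.
#' @param metadata metadata data.frame with sample_id, sex and traits.
#' @param traits trait column names.
#' @param p_max significance threshold.
#' @return data.frame trait, ad_p_f, ad_p_m, f_test_p, t_stat, t_p,
#'   significant.
#' @export
compare_traits <- function(metadata, traits, p_max = 0.05) {
  rows <- list()
  for (tr in traits) {
    v <- metadata[[tr]]
    if (anyNA(v)) warning(sprintf("missing values in trait '%s' dropped", tr))
    f <- v[metadata$sex == "F" & !is.na(v)]
    m <- v[metadata$sex == "M" & !is.na(v)]
    stopifnot(length(f) >= 3, length(m) >= 3)
    ad <- function(x) tryCatch(nortest::ad.test(x)$p.value,
                               error = function(e) NA_real_)
    ft <- stats::var.test(f, m)
    tt <- stats::t.test(f, m, var.equal = TRUE)
    rows[[tr]] <- data.frame(trait = tr, ad_p_f = ad(f), ad_p_m = ad(m),
                             f_test_p = ft$p.value,
                             t_stat = unname(tt$statistic), t_p = tt$p.value,
                             significant = tt$p.value < p_max,
                             stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
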