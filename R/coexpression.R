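# Signed weighted co-expression networks per sex, static-cut module
# detection with k-means refinement, cross-sex Fisher overlap (DcoExp),
# and eigengene-trait correlation.

#' Remove defective genes and samples before network construction
#'
#' Drops zero-variance genes and genes/samples with more than 50% missing
#' values.
#' @param expr gene x sample numeric matrix (e.g. FPKM or log2 FPKM).
#' @return filtered matrix.
#' @export
good_samples_genes <- function(expr) {
  keep_s <- colMeans(is.na(expr)) <= 0.5
  expr <- expr[, keep_s, drop = FALSE]
  miss <- rowMeans(is.na(expr))
  v <- apply(expr, 1, stats::var, na.rm = TRUE)
  keep_g <- miss <= 0.5 & !is.na(v) & v > 0
  if (!any(keep_g)) stop("all genes removed by quality filter")
  expr[keep_g, , drop = FALSE]
}

#' Pick the soft-thresholding power for a signed network
#'
#' Returns the smallest power in 1..20 whose scale-free topology fit
#' reaches R^2 >= 0.8 (signed fit: the log-log degree regression must have
#' a negative slope); falls back to 12 when none qualifies.
#' @param expr gene x sample matrix.
#' @param powers candidate powers.
#' @param rsq_cut scale-free fit threshold.
#' @param fallback power used when no candidate fits.
#' @return integer power.
#' @export
pick_soft_threshold <- function(expr, powers = 1:20, rsq_cut = 0.8,
                                fallback = 12L) {
  cc <- stats::cor(t(expr), use = "pairwise.complete.obs")
  base <- (1 + cc) / 2
  for (beta in powers) {
    a <- base^beta
    diag(a) <- 1
    k <- rowSums(a) - 1
    # at high powers any correlation matrix looks scale-free while the
    # network degenerates; demand non-trivial connectivity
    if (stats::median(k) < 1) next
    fit <- scale_free_fit(k)
    if (!is.na(fit$rsq) && fit$slope < 0 && fit$rsq >= rsq_cut)
      return(as.integer(beta))
  }
  as.integer(fallback)
}

scale_free_fit <- function(k, n_breaks = 10) {
  k <- k[k > 0]
  if (length(unique(k)) < 3) return(list(rsq = NA_real_, slope = NA_real_))
  cuts <- cut(k, breaks = n_breaks)
  dk <- tapply(k, cuts, mean)
  pk <- tabulate(as.integer(cuts), nbins = n_breaks) / length(k)
  ok <- !is.na(dk) & pk > 0
  # a degree distribution occupying only a few bins cannot be called
  # scale-free at all; treat it as no fit
  if (sum(ok) < 5) return(list(rsq = NA_real_, slope = NA_real_))
  fit <- stats::lm(log10(pk[ok]) ~ log10(dk[ok]))
  list(rsq = summary(fit)$r.squared, slope = stats::coef(fit)[2])
}

#' Signed adjacency matrix
#'
#' a_ij = ((1 + cor(x_i, x_j)) / 2)^beta with unit diagonal; perfect
#' anticorrelation maps to 0.
#' @param expr gene x sample matrix.
#' @param beta soft-thresholding power.
#' @return gene x gene adjacency in [0,1].
#' @export
signed_adjacency <- function(expr, beta) {
  cc <- stats::cor(t(expr), use = "pairwise.complete.obs")
  a <- ((1 + cc) / 2)^beta
  diag(a) <- 1
  a
}

#' Topological overlap matrix
#'
#' TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i,k_j) + 1 - a_ij) with the
#' sum over u != i,j and k the connectivity excluding self; unit diagonal.
#' @param a adjacency matrix (symmetric, unit diagonal, values in [0,1]).
#' @return TOM similarity matrix.
#' @export
tom_similarity <- function(a) {
  stopifnot(isTRUE(all.equal(a, t(a))), all(diag(a) == 1))
  l <- a %*% a - a  # (A^2)_ij - a_ii a_ij - a_ij a_jj + a_ij with diag = 1
  k <- rowSums(a) - 1
  denom <- outer(k, k, pmin) + 1 - a
  tom <- l / denom
  diag(tom) <- 1
  tom
}

#' Detect modules by static tree cut on TOM dissimilarity
#'
#' Average-linkage hierarchical clustering on 1 - TOM, cut at a fixed
#' fraction of the tallest merge height; clusters below the minimum size
#' become "grey". Labels are "mod1", "mod2", ... by decreasing size.
#' Unstructured genes merge close to the top of the tree, so a cut just
#' below it isolates them while leaving coherent branches intact.
#' @param tom TOM matrix with gene rownames.
#' @param min_module_size smallest retained module.
#' @param cut_height fraction of the maximum merge height for the cut.
#' @return named character vector gene -> module label.
#' @export
detect_modules <- function(tom, min_module_size = 30, cut_height = 0.95) {
  genes <- rownames(tom)
  if (min_module_size > nrow(tom))
    return(stats::setNames(rep("grey", nrow(tom)), genes))
  hc <- stats::hclust(stats::as.dist(1 - tom), method = "average")
  h <- cut_height * max(hc$height)
  cl <- stats::cutree(hc, h = h)
  sizes <- table(cl)
  keep <- names(sizes)[sizes >= min_module_size]
  lab <- rep("grey", length(cl))
  keep <- keep[order(-sizes[keep])]
  for (i in seq_along(keep)) lab[cl == keep[i]] <- paste0("mod", i)
  stats::setNames(lab, genes)
}

#' Module eigengene
#'
#' First principal component of the standardized member-gene submatrix,
#' scaled to unit variance, with sign fixed so that its correlation with
#' the mean member profile is non-negative.
#' @param expr gene x sample matrix.
#' @param member_genes gene ids of the module (>= 2).
#' @return per-sample score vector.
#' @export
module_eigengene <- function(expr, member_genes) {
  stopifnot(length(member_genes) >= 2)
  x <- expr[member_genes, , drop = FALSE]
  xs <- t(scale(t(x)))
  if (anyNA(xs)) stop("singular member submatrix")
  pc <- stats::prcomp(t(xs), center = FALSE, scale. = FALSE)
  e <- pc$x[, 1]
  if (stats::sd(e) == 0) stop("singular member submatrix")
  e <- e / stats::sd(e)
  if (stats::cor(e, colMeans(xs)) < 0) e <- -e
  e
}

#' Refine a module assignment by k-means-style reallocation
#'
#' Iteratively recomputes module eigengenes and moves every assigned gene to
#' the module whose eigengene correlates best with its profile (distance
#' 1 - Pearson r); stops early at a fixed point. Modules falling below the
#' minimum size are dissolved to grey. After convergence, members whose
#' eigengene correlation (kME) falls below \code{min_kme} are released to
#' grey.
#' @param expr gene x sample matrix.
#' @param assignment named gene -> module vector ("grey" = unassigned).
#' @param iterations maximum number of reallocation sweeps.
#' @param min_module_size modules below this dissolve to grey.
#' @param min_kme minimum gene-eigengene correlation to stay in a module.
#' @return list of class \code{ModuleSet}: \code{assignment},
#'   \code{eigengenes} (module -> per-sample vector), \code{n_iter}.
#' @export
kmeans_refine <- function(expr, assignment, iterations = 20,
                          min_module_size = 30, min_kme = 0.5) {
  assignment <- assignment[rownames(expr)]
  mods <- setdiff(unique(assignment), "grey")
  if (length(mods) == 0)
    return(structure(list(assignment = assignment, eigengenes = list(),
                          n_iter = 0L), class = "ModuleSet"))
  n_iter <- 0L
  for (it in seq_len(iterations)) {
    mods <- setdiff(unique(assignment), "grey")
    if (length(mods) == 0) break
    eig <- lapply(mods, function(m)
      module_eigengene(expr, names(assignment)[assignment == m]))
    names(eig) <- mods
    em <- do.call(cbind, eig)
    assigned <- names(assignment)[assignment != "grey"]
    profile <- t(scale(t(expr[assigned, , drop = FALSE])))
    rmat <- stats::cor(t(profile), em)   # gene x module correlations
    best <- mods[max.col(rmat, ties.method = "first")]
    cur <- assignment[assigned]
    # ties keep the current module
    cur_r <- rmat[cbind(seq_along(assigned), match(cur, mods))]
    best_r <- rmat[cbind(seq_along(assigned), match(best, mods))]
    best[best_r <= cur_r + 1e-12] <- cur[best_r <= cur_r + 1e-12]
    n_iter <- it
    if (all(best == cur)) { assignment[assigned] <- best; break }
    assignment[assigned] <- best
    sz <- table(assignment[assignment != "grey"])
    small <- names(sz)[sz < min_module_size]
    assignment[assignment %in% small] <- "grey"
  }
  # kME filter: release weak members, then dissolve undersized modules
  mods <- setdiff(unique(assignment), "grey")
  if (length(mods) > 0 && min_kme > 0) {
    eig <- lapply(mods, function(m)
      module_eigengene(expr, names(assignment)[assignment == m]))
    names(eig) <- mods
    for (m in mods) {
      members <- names(assignment)[assignment == m]
      kme <- stats::cor(t(expr[members, , drop = FALSE]), eig[[m]])[, 1]
      assignment[members[kme < min_kme]] <- "grey"
    }
    sz <- table(assignment[assignment != "grey"])
    assignment[assignment %in% names(sz)[sz < min_module_size]] <- "grey"
  }
  mods <- setdiff(unique(assignment), "grey")
  eig <- lapply(mods, function(m)
    module_eigengene(expr, names(assignment)[assignment == m]))
  names(eig) <- mods
  structure(list(assignment = assignment, eigengenes = eig,
                 n_iter = n_iter), class = "ModuleSet")
}

#' Build a per-sex module set end-to-end
#'
#' Quality filter, soft threshold, signed adjacency, TOM, static-cut
#' detection and k-means refinement on one sex's samples.
#' @param expr gene x sample matrix (all samples).
#' @param sexes per-sample sex vector aligned with columns.
#' @param sex which sex to build ("M" or "F").
#' @param min_module_size smallest retained module.
#' @param beta soft power; NULL picks automatically.
#' @param center_samples remove each sample's mean log-expression before
#'   computing correlations. Residual library-composition variation shared
#'   by all genes survives FPKM normalization and, left in place, weakly
#'   correlates low-noise genes with each other in every network — a
#'   dependence that contaminates cross-network comparisons.
#' @return ModuleSet with \code{sex} and \code{soft_power} fields.
#' @export
build_modules <- function(expr, sexes, sex, min_module_size = 30,
                          beta = NULL, center_samples = TRUE) {
  x <- good_samples_genes(expr[, sexes == sex, drop = FALSE])
  if (center_samples) x <- sweep(x, 2, colMeans(x))
  if (is.null(beta)) beta <- pick_soft_threshold(x)
  a <- signed_adjacency(x, beta)
  tom <- tom_similarity(a)
  pre <- detect_modules(tom, min_module_size)
  ms <- kmeans_refine(x, pre, min_module_size = min_module_size)
  ms$sex <- sex
  ms$soft_power <- beta
  ms
}

#' Cross-sex module overlap Fisher test (DcoExp)
#'
#' For each module in one sex against every module of the other sex, a
#' one-sided (enrichment) Fisher exact test on the 2x2 overlap table over a
#' common gene background, BH-adjusted within each direction. A module is
#' sex-specific (differentially co-expressed) when no other-sex module
#' reaches FDR < 0.05 against it.
#'
#' The effective universe is restricted to genes assigned to a module in
#' both sexes: a gene's propensity to be clustered at all is correlated
#' between the two networks (it depends on gene-level noise), and leaving
#' never-clustered genes in the background inflates every overlap above its
#' hypergeometric expectation.
#' @param modules_m,modules_f ModuleSet for males and females.
#' @param background character vector of background gene ids.
#' @param fdr_max counterpart significance threshold.
#' @return data.frame with module, sex, best_match_module, fisher_p,
#'   fisher_fdr, specific.
#' @export
dcoexp_fisher <- function(modules_m, modules_f, background, fdr_max = 0.05) {
  get_sets <- function(ms) {
    mods <- setdiff(unique(ms$assignment), "grey")
    sets <- lapply(mods, function(m) names(ms$assignment)[ms$assignment == m])
    names(sets) <- mods
    sets
  }
  sets_m <- get_sets(modules_m); sets_f <- get_sets(modules_f)
  for (s in c(sets_m, sets_f))
    if (!all(s %in% background)) stop("module gene not in background")
  assigned_both <- intersect(unlist(sets_m, use.names = FALSE),
                             unlist(sets_f, use.names = FALSE))
  universe <- intersect(background, assigned_both)
  sets_m <- lapply(sets_m, intersect, y = universe)
  sets_f <- lapply(sets_f, intersect, y = universe)
  N <- length(universe)
  one_dir <- function(sets_a, sets_b, sex_label) {
    if (length(sets_a) == 0) return(NULL)
    rows <- list()
    for (a in names(sets_a)) {
      A <- sets_a[[a]]
      p <- vapply(names(sets_b), function(b) {
        B <- sets_b[[b]]
        k <- length(intersect(A, B))
        # one-sided hypergeometric upper tail P(X >= k)
        stats::phyper(k - 1, length(B), N - length(B), length(A),
                      lower.tail = FALSE)
      }, 0)
      rows[[a]] <- data.frame(module = a, sex = sex_label,
                              other = if (length(p)) names(sets_b) else NA,
                              fisher_p = if (length(p)) p else NA_real_,
                              stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    out$fisher_fdr <- bh_fdr(out$fisher_p)
    agg <- lapply(split(out, out$module), function(d) {
      i <- which.min(d$fisher_fdr)
      data.frame(module = d$module[1], sex = d$sex[1],
                 best_match_module = if (length(i)) d$other[i] else NA,
                 fisher_p = if (length(i)) d$fisher_p[i] else NA_real_,
                 fisher_fdr = if (length(i)) d$fisher_fdr[i] else NA_real_,
                 specific = if (length(i)) d$fisher_fdr[i] >= fdr_max else TRUE,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, agg)
  }
  res <- rbind(one_dir(sets_m, sets_f, "M"), one_dir(sets_f, sets_m, "F"))
  rownames(res) <- NULL
  res
}

#' Eigengene-trait Pearson correlation within sex
#'
#' Correlates each module eigengene with each fat-percentage trait using
#' only the samples of the module's own sex; two-sided t-based p-value.
#' @param module_set ModuleSet with a \code{sex} field; eigengene vectors
#'   must be named by sample id.
#' @param metadata metadata data.frame.
#' @param traits trait column names.
#' @param p_max significance threshold.
#' @return data.frame module, trait, pearson_r, p_value, significant.
#' @export
module_trait_correlation <- function(module_set, metadata, traits,
                                     p_max = 0.05) {
  rows <- list()
  for (m in names(module_set$eigengenes)) {
    e <- module_set$eigengenes[[m]]
    ids <- names(e)
    md <- metadata[match(ids, metadata$sample_id), , drop = FALSE]
    for (tr in traits) {
      v <- md[[tr]]
      if (is.null(v) || stats::sd(v, na.rm = TRUE) == 0 ||
          all(is.na(v))) {
        rows[[length(rows) + 1]] <- data.frame(
          module = m, trait = tr, pearson_r = NA_real_, p_value = NA_real_,
          significant = NA, stringsAsFactors = FALSE)
        next
      }
      ct <- stats::cor.test(e, v, method = "pearson")
      rows[[length(rows) + 1]] <- data.frame(
        module = m, trait = tr, pearson_r = unname(ct$estimate),
        p_value = ct$p.value, significant = ct$p.value < p_max,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
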