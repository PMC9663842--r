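# Multiblock sparse PLS-DA: block construction from candidate-gene
# expression and per-DMR mean methylation, sparse generalized CCA with an
# outcome dummy block, variable selection, DMR-gene pairing, overlap
# refit, and AUC evaluation.

#' Build the integration blocks
#'
#' mrna block = FPKM of candidate genes; meth block = per-DMR mean
#' methylation. Missing methylation values are imputed by the feature mean;
#' both blocks are z-scored per feature; zero-variance features are dropped.
#' @param fpkm_mat gene x sample FPKM matrix.
#' @param candidate_genes gene ids for the mrna block.
#' @param dmr_meth DMR x sample mean-methylation matrix.
#' @param metadata metadata data.frame with sample_id and sex.
#' @return list of class \code{BlockInput}: \code{blocks} (named list of
#'   sample x feature matrices), \code{outcome} (factor M/F), \code{samples}.
#' @export
build_blocks <- function(fpkm_mat, candidate_genes, dmr_meth, metadata) {
  stopifnot(length(candidate_genes) >= 1, nrow(dmr_meth) >= 1)
  samples <- colnames(fpkm_mat)
  stopifnot(identical(samples, colnames(dmr_meth)))
  outcome <- factor(metadata$sex[match(samples, metadata$sample_id)],
                    levels = c("M", "F"))
  prep <- function(x) {
    # x: sample x feature
    for (j in seq_len(ncol(x))) {
      v <- x[, j]
      if (anyNA(v)) x[is.na(v), j] <- mean(v, na.rm = TRUE)
    }
    keep <- apply(x, 2, stats::sd) > 0 & !apply(x, 2, anyNA)
    if (any(!keep))
      message(sprintf("dropped %d zero-variance/all-missing features",
                      sum(!keep)))
    scale(x[, keep, drop = FALSE])
  }
  mrna <- prep(t(fpkm_mat[candidate_genes, , drop = FALSE]))
  meth <- prep(t(dmr_meth))
  structure(list(blocks = list(mrna = mrna, meth = meth),
                 outcome = outcome, samples = samples),
            class = "BlockInput")
}

soft_threshold_keep <- function(w, keep) {
  # soft-threshold so exactly the keep largest-|w| entries stay nonzero
  p <- length(w)
  if (keep >= p) return(w)
  lambda <- sort(abs(w), decreasing = TRUE)[keep + 1]
  out <- sign(w) * pmax(abs(w) - lambda, 0)
  out
}

#' Fit a multiblock sparse PLS-DA model
#'
#' Sparse generalized canonical correlation with an outcome dummy block:
#' per component, block loadings are iteratively updated as design-weighted
#' sums of cross-covariances with the other blocks' scores and the outcome
#' score, soft-thresholded to keepX features, unit-normalized; blocks are
#' deflated by regression on their own scores between components.
#' @param block_input \code{\link{build_blocks}} output.
#' @param ncomp number of components (capped at the data rank).
#' @param keepX named list per block of per-component retained feature
#'   counts; NULL keeps all.
#' @param design block x block connection weight matrix in [0,1] including
#'   the outcome block "Y"; NULL = fully connected.
#' @param tol convergence tolerance on score change.
#' @param max_iter maximum inner iterations.
#' @return object of class \code{BlockSplsModel}: per-block loadings
#'   (feature x comp), scores (sample x comp), \code{Y}, \code{ncomp},
#'   \code{iterations}.
#' @export
fit_block_splsda <- function(block_input, ncomp = 2, keepX = NULL,
                             design = NULL, tol = 1e-6, max_iter = 100) {
  X <- lapply(block_input$blocks, function(b) as.matrix(b))
  bn <- names(X)
  outcome <- block_input$outcome
  stopifnot(min(table(outcome)) >= 2)
  n <- nrow(X[[1]])
  Y <- stats::model.matrix(~ outcome - 1)
  colnames(Y) <- levels(outcome)
  Y <- scale(Y, scale = FALSE)
  rank_cap <- min(n - 1, vapply(X, ncol, 0))
  if (ncomp > rank_cap) {
    warning(sprintf("ncomp reduced to %d (rank)", rank_cap))
    ncomp <- rank_cap
  }
  if (is.null(design)) {
    design <- matrix(1, length(bn) + 1, length(bn) + 1,
                     dimnames = list(c(bn, "Y"), c(bn, "Y")))
    diag(design) <- 0
  }
  if (is.null(keepX))
    keepX <- lapply(X, function(b) rep(ncol(b), ncomp))
  loadings <- lapply(X, function(b)
    matrix(0, ncol(b), ncomp, dimnames = list(colnames(b), NULL)))
  scores <- lapply(X, function(b) matrix(0, n, ncomp))
  iters <- integer(ncomp)
  Xd <- X
  for (h in seq_len(ncomp)) {
    a <- lapply(bn, function(b) {
      sv <- svd(crossprod(Xd[[b]], Y), nu = 1, nv = 0)
      v <- sv$u[, 1]
      v / sqrt(sum(v^2))
    })
    names(a) <- bn
    t_list <- lapply(bn, function(b) Xd[[b]] %*% a[[b]])
    names(t_list) <- bn
    u <- Y %*% (crossprod(Y, Reduce(`+`, t_list)) /
                  sqrt(sum((crossprod(Y, Reduce(`+`, t_list)))^2)))
    for (it in seq_len(max_iter)) {
      t_old <- t_list
      for (b in bn) {
        w <- rep(0, ncol(Xd[[b]]))
        for (k in bn) if (k != b && design[b, k] > 0)
          w <- w + design[b, k] * crossprod(Xd[[b]], t_list[[k]])[, 1]
        if (design[b, "Y"] > 0)
          w <- w + design[b, "Y"] * crossprod(Xd[[b]], u)[, 1]
        w <- soft_threshold_keep(w, keepX[[b]][h])
        nw <- sqrt(sum(w^2))
        if (nw == 0) w[which.max(abs(w))] <- 1 else w <- w / nw
        a[[b]] <- w
        t_list[[b]] <- Xd[[b]] %*% w
      }
      wy <- rep(0, ncol(Y))
      for (k in bn) if (design["Y", k] > 0)
        wy <- wy + design["Y", k] * crossprod(Y, t_list[[k]])[, 1]
      ny <- sqrt(sum(wy^2))
      if (ny > 0) u <- Y %*% (wy / ny)
      delta <- max(vapply(bn, function(b)
        max(abs(t_list[[b]] - t_old[[b]])), 0))
      if (delta < tol) break
    }
    if (it == max_iter && delta >= tol)
      warning(sprintf("component %d did not converge (delta = %.2e)", h, delta))
    iters[h] <- it
    for (b in bn) {
      loadings[[b]][, h] <- a[[b]]
      scores[[b]][, h] <- t_list[[b]]
      tb <- t_list[[b]]
      # deflate block by regression on its own score
      Xd[[b]] <- Xd[[b]] - tb %*% (crossprod(tb, Xd[[b]]) / sum(tb^2))
    }
  }
  for (b in bn) rownames(scores[[b]]) <- rownames(X[[b]])
  structure(list(loadings = loadings, scores = scores, Y = Y,
                 outcome = outcome, ncomp = ncomp, design = design,
                 keepX = keepX, iterations = iters,
                 feature_names = lapply(X, colnames)),
            class = "BlockSplsModel")
}

#' @export
print.BlockSplsModel <- function(x, ...) {
  cat(sprintf("BlockSplsModel: %d components; blocks: %s\n", x$ncomp,
              paste(sprintf("%s (%d features)", names(x$loadings),
                            vapply(x$loadings, nrow, 0)), collapse = ", ")))
  invisible(x)
}

#' Selected variables per block
#'
#' Features with a nonzero loading on either of the first two components,
#' ordered by decreasing maximal |loading|.
#' @param model BlockSplsModel.
#' @return named list of character vectors per block.
#' @export
select_variables <- function(model) {
  lapply(model$loadings, function(L) {
    mx <- apply(abs(L), 1, max)
    ids <- rownames(L)[mx > 0]
    ids[order(-mx[mx > 0], ids)]
  })
}

#' Pair selected DMRs with selected genes
#'
#' A DMR pairs with its annotation-assigned gene; the pair is kept when both
#' sides were selected. With \code{strict_within = TRUE} only DMRs
#' overlapping the gene (distance 0) pair.
#' @param selected_genes,selected_dmrs selected feature ids.
#' @param dmr_annotations annotated DMR data.frame (needs assigned_gene and
#'   distance_to_gene; rownames/ids per \code{\link{dmr_id}}).
#' @param strict_within require the DMR to lie within the gene.
#' @return list with \code{paired_genes}, \code{paired_dmrs}, \code{pairs}
#'   (data.frame gene_id, dmr).
#' @export
pair_dmrs_to_genes <- function(selected_genes, selected_dmrs,
                               dmr_annotations, strict_within = FALSE) {
  ann <- dmr_annotations
  ann$dmr <- dmr_id(ann)
  ann <- ann[ann$dmr %in% selected_dmrs & !is.na(ann$assigned_gene), ,
             drop = FALSE]
  if (strict_within)
    ann <- ann[!is.na(ann$distance_to_gene) & ann$distance_to_gene == 0, ,
               drop = FALSE]
  ann <- ann[ann$assigned_gene %in% selected_genes, , drop = FALSE]
  list(paired_genes = unique(ann$assigned_gene),
       paired_dmrs = unique(ann$dmr),
       pairs = data.frame(gene_id = ann$assigned_gene, dmr = ann$dmr,
                          stringsAsFactors = FALSE))
}

#' Refit the model on the paired feature sets
#'
#' Restricts both blocks to the DMR-gene pairing and refits/re-evaluates.
#' @param block_input original BlockInput.
#' @param paired_genes,paired_dmrs paired feature ids.
#' @param ... passed to \code{\link{fit_block_splsda}}.
#' @return list with \code{model} and \code{evaluation}.
#' @export
overlap_refit <- function(block_input, paired_genes, paired_dmrs, ...) {
  if (length(paired_genes) == 0 || length(paired_dmrs) == 0)
    stop("empty DMR-gene pairing: nothing to refit on")
  genes <- intersect(paired_genes, colnames(block_input$blocks$mrna))
  dmrs <- intersect(paired_dmrs, colnames(block_input$blocks$meth))
  if (length(genes) == 0 || length(dmrs) == 0)
    stop("paired features absent from blocks")
  sub <- structure(list(
    blocks = list(mrna = block_input$blocks$mrna[, genes, drop = FALSE],
                  meth = block_input$blocks$meth[, dmrs, drop = FALSE]),
    outcome = block_input$outcome, samples = block_input$samples),
    class = "BlockInput")
  model <- fit_block_splsda(sub, ...)
  list(model = model, evaluation = evaluate_auc(model))
}

#' Mann-Whitney AUC with normal-approximation significance
#'
#' AUC = U / (n1 n2) folded above 0.5; two-sided p from
#' z = (U - n1 n2 / 2) / sqrt(n1 n2 (n + 1) / 12) with tie correction.
#' @param score numeric score vector.
#' @param outcome two-level factor.
#' @return list(auc, p_value, u).
#' @export
auc_mann_whitney <- function(score, outcome) {
  g <- split(score, outcome)
  if (length(g) != 2 || any(lengths(g) == 0)) stop("need two non-empty classes")
  n1 <- length(g[[1]]); n2 <- length(g[[2]])
  r <- rank(c(g[[2]], g[[1]]))
  u <- sum(r[seq_len(n2)]) - n2 * (n2 + 1) / 2  # U for class 2 (e.g. F)
  auc <- u / (n1 * n2)
  auc_f <- max(auc, 1 - auc)
  n <- n1 + n2
  ties <- table(c(g[[1]], g[[2]]))
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
  z <- (u - n1 * n2 / 2) / sqrt(sigma2)
  p <- 2 * stats::pnorm(-abs(z))
  list(auc = auc_f, p_value = p, u = u)
}

#' Evaluate a fitted model's discriminant performance
#'
#' Per block and component: Mann-Whitney AUC of the score against the sex
#' outcome with two-sided normal-approximation p; a combined AUC over the
#' mean of the component scores; Pearson correlation between the two
#' blocks' scores per component.
#' @param model BlockSplsModel.
#' @return list of class \code{DiscriminantEvaluation}: \code{auc}
#'   (data.frame block, component, auc, p_value), \code{combined}
#'   (per-block), \code{cross_block_cor} (per component).
#' @export
evaluate_auc <- function(model) {
  outcome <- model$outcome
  bn <- names(model$scores)
  rows <- list(); comb <- list()
  for (b in bn) {
    for (h in seq_len(model$ncomp)) {
      r <- auc_mann_whitney(model$scores[[b]][, h], outcome)
      rows[[length(rows) + 1]] <- data.frame(
        block = b, component = h, auc = r$auc, p_value = r$p_value,
        stringsAsFactors = FALSE)
    }
    rc <- auc_mann_whitney(rowMeans(model$scores[[b]][, seq_len(model$ncomp),
                                                      drop = FALSE]), outcome)
    comb[[b]] <- data.frame(block = b, auc = rc$auc, p_value = rc$p_value,
                            stringsAsFactors = FALSE)
  }
  cross <- vapply(seq_len(model$ncomp), function(h)
    stats::cor(model$scores[[bn[1]]][, h], model$scores[[bn[2]]][, h]), 0)
  structure(list(auc = do.call(rbind, rows),
                 combined = do.call(rbind, comb),
                 cross_block_cor = abs(cross)),
            class = "DiscriminantEvaluation")
}

#' Run the integration stage end-to-end
#'
#' Builds blocks from DE candidates and annotated DMRs, fits the two
#' component model, selects variables, pairs DMRs to genes, refits on the
#' paired features and evaluates.
#' @param fpkm_mat gene x sample FPKM matrix.
#' @param candidates candidate gene ids (|log2FC| > 1).
#' @param dmrs annotated DMR data.frame.
#' @param calls MethylationCallTable.
#' @param metadata metadata data.frame.
#' @param keepX optional sparsity; NULL keeps all features.
#' @return list: blocks, model, selected, pairing, refit (model +
#'   evaluation), evaluation (initial fit).
#' @export
run_integration_stage <- function(fpkm_mat, candidates, dmrs, calls,
                                  metadata, keepX = NULL) {
  dm <- dmr_mean_methylation(calls, dmrs)
  blocks <- build_blocks(fpkm_mat, candidates, dm, metadata)
  model <- fit_block_splsda(blocks, keepX = keepX)
  evaluation <- evaluate_auc(model)
  selected <- select_variables(model)
  pairing <- pair_dmrs_to_genes(selected$mrna, selected$meth, dmrs)
  refit <- overlap_refit(blocks, pairing$paired_genes, pairing$paired_dmrs)
  list(blocks = blocks, model = model, evaluation = evaluation,
       selected = selected, pairing = pairing, refit = refit)
}
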