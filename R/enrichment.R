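# QTL-interval overlap and hypergeometric enrichment, generic term
# enrichment, and Jaccard similarity grouping of terms.

#' Overlap genes with QTL intervals
#'
#' 1-based inclusive interval intersection on matching chromosome names.
#' @param models GeneModelSet.
#' @param qtl QTL data.frame (qtl_id, trait, qtl_type, chrom, start, end).
#' @return data.frame with one row per (gene, QTL) overlap.
#' @export
annotate_qtl_overlap <- function(models, qtl) {
  g <- models$genes
  q <- GenomicRanges::GRanges(qtl$chrom, IRanges::IRanges(qtl$start, qtl$end))
  hits <- GenomicRanges::findOverlaps(g, q, ignore.strand = TRUE)
  data.frame(gene_id = g$gene_id[S4Vectors::queryHits(hits)],
             qtl_id = qtl$qtl_id[S4Vectors::subjectHits(hits)],
             trait = qtl$trait[S4Vectors::subjectHits(hits)],
             qtl_type = qtl$qtl_type[S4Vectors::subjectHits(hits)],
             stringsAsFactors = FALSE)
}

hyper_upper <- function(k, K, n, N) {
  # P(X >= k) for X ~ Hypergeometric(N, K, n)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' QTL trait / type enrichment
#'
#' For each trait (or type): k = overlapped QTLs of that trait, n = all
#' overlapped QTLs, K = database QTLs of the trait, N = database size;
#' hypergeometric upper-tail p, BH FDR across traits. Also returns the
#' share of each QTL type among the overlapped records.
#' @param overlaps output of \code{\link{annotate_qtl_overlap}}.
#' @param qtl_db full QTL database data.frame.
#' @param by group by "trait" or "qtl_type".
#' @return list with \code{enrichment} (data.frame) and \code{type_share}.
#' @export
qtl_enrichment <- function(overlaps, qtl_db, by = "trait") {
  stopifnot(nrow(overlaps) >= 1, by %in% c("trait", "qtl_type"))
  hit_qtl <- unique(overlaps[, c("qtl_id", by)])
  n <- nrow(hit_qtl)
  N <- nrow(qtl_db)
  groups <- unique(hit_qtl[[by]])
  rows <- list()
  for (tr in groups) {
    K <- sum(qtl_db[[by]] == tr)
    if (K == 0) next
    k <- sum(hit_qtl[[by]] == tr)
    rows[[tr]] <- data.frame(term_or_trait = tr, k = k, n = n, K = K, N = N,
                             p_value = hyper_upper(k, K, n, N),
                             stringsAsFactors = FALSE)
  }
  enr <- do.call(rbind, rows)
  enr$fdr <- bh_fdr(enr$p_value)
  rownames(enr) <- NULL
  share <- table(unique(overlaps[, c("qtl_id", "qtl_type")])$qtl_type)
  list(enrichment = enr,
       type_share = data.frame(qtl_type = names(share),
                               share = as.numeric(share) / sum(share),
                               stringsAsFactors = FALSE))
}

#' Hypergeometric term enrichment
#'
#' Standard over-representation test of a gene list against term gene sets
#' over a fixed background, with BH FDR.
#' @param query_genes query gene ids (subset of background).
#' @param term_table named list term -> character vector of genes.
#' @param background_genes background gene ids.
#' @param fdr_max threshold for the \code{enriched} flag.
#' @return data.frame term_or_trait, k, n, K, N, p_value, fdr, enriched.
#' @export
term_enrichment <- function(query_genes, term_table, background_genes,
                            fdr_max = 0.05) {
  stopifnot(all(query_genes %in% background_genes))
  N <- length(background_genes)
  n <- length(query_genes)
  rows <- list()
  for (term in names(term_table)) {
    ann <- intersect(term_table[[term]], background_genes)
    K <- length(ann)
    if (K == 0) next
    k <- length(intersect(query_genes, ann))
    rows[[term]] <- data.frame(term_or_trait = term, k = k, n = n, K = K,
                               N = N,
                               p_value = if (k == 0) 1 else
                                 hyper_upper(k, K, n, N),
                               stringsAsFactors = FALSE)
  }
  if (length(rows) == 0)
    return(data.frame(term_or_trait = character(), k = integer(),
                      n = integer(), K = integer(), N = integer(),
                      p_value = numeric(), fdr = numeric(),
                      enriched = logical()))
  enr <- do.call(rbind, rows)
  enr$fdr <- bh_fdr(enr$p_value)
  enr$enriched <- enr$fdr < fdr_max
  rownames(enr) <- NULL
  enr
}

#' Jaccard similarity grouping of terms
#'
#' J(A,B) = |A intersect B| / |A union B| on the terms' gene sets;
#' average-linkage hierarchical clustering on 1 - J cut into cut_k groups.
#' @param term_table named list term -> gene set.
#' @param terms which terms to include (>= 2).
#' @param cut_k number of groups.
#' @return list: \code{similarity} (matrix), \code{groups} (named vector).
#' @export
jaccard_term_grouping <- function(term_table, terms = names(term_table),
                                  cut_k = 2) {
  stopifnot(length(terms) >= 2)
  sets <- term_table[terms]
  m <- length(terms)
  J <- matrix(1, m, m, dimnames = list(terms, terms))
  for (i in seq_len(m - 1)) for (j in (i + 1):m) {
    a <- sets[[i]]; b <- sets[[j]]
    u <- length(union(a, b))
    J[i, j] <- J[j, i] <- if (u == 0) 0 else length(intersect(a, b)) / u
  }
  hc <- stats::hclust(stats::as.dist(1 - J), method = "average")
  groups <- stats::cutree(hc, k = min(cut_k, m))
  list(similarity = J, groups = groups)
}
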