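# Coordinates are 1-based inclusive throughout (GFF3 convention); this is the
# only convention under which printed DMR lengths equal end - start + 1.

#' Length of a 1-based inclusive genomic interval
#'
#' @param start,end 1-based inclusive positions (vectors recycled together).
#' @return Integer widths, \code{end - start + 1}.
#' @examples
#' interval_length(66088104, 66090171)  # 2068
#' @export
interval_length <- function(start, end) {
  stopifnot(all(start >= 1), all(end >= start))
  as.integer(end - start + 1)
}

stop_format <- function(path, line, msg) {
  stop(sprintf("format error in '%s' (line %d): %s", path, line, msg), call. = FALSE)
}

#' Construct an expression count matrix container
#'
#' @param counts integer gene x sample matrix with dimnames.
#' @param gene_length_bp per-gene transcript length in bp, named by gene.
#' @return An object of class \code{ExpressionCountMatrix}: a list with
#'   \code{counts} and \code{gene_length_bp}.
#' @export
expression_count_matrix <- function(counts, gene_length_bp) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(counts != round(counts))) stop("counts must be integers")
  gene_length_bp <- gene_length_bp[rownames(counts)]
  if (anyNA(gene_length_bp) && nrow(counts) > 0)
    stop("every gene needs a length")
  if (any(gene_length_bp <= 0) && nrow(counts) > 0) stop("gene lengths must be > 0")
  structure(list(counts = counts, gene_length_bp = gene_length_bp),
            class = "ExpressionCountMatrix")
}

#' @export
print.ExpressionCountMatrix <- function(x, ...) {
  cat(sprintf("ExpressionCountMatrix: %d genes x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  invisible(x)
}

#' Read a gene-level count table
#'
#' Expects a TSV with header \code{gene_id}, \code{length_bp}, then one
#' column per sample. Row and column order are preserved.
#'
#' @param path file path.
#' @return \code{\link{expression_count_matrix}} object.
#' @export
read_counts <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, colClasses = "character")
  if (ncol(df) < 2 || !identical(colnames(df)[1:2], c("gene_id", "length_bp")))
    stop_format(path, 1L, "header must start with gene_id, length_bp")
  n <- nrow(df)
  if (n == 0) {
    m <- matrix(0, 0, ncol(df) - 2,
                dimnames = list(character(), colnames(df)[-(1:2)]))
    return(expression_count_matrix(m, stats::setNames(numeric(0), character())))
  }
  lens <- suppressWarnings(as.numeric(df$length_bp))
  for (i in seq_len(n)) {
    if (is.na(lens[i]) || lens[i] <= 0)
      stop_format(path, i + 1L, "missing or non-positive length_bp")
  }
  cm <- as.matrix(df[, -(1:2), drop = FALSE])
  counts <- suppressWarnings(matrix(as.numeric(cm), nrow = n,
                                    dimnames = list(df$gene_id, colnames(cm))))
  bad <- which(is.na(counts) | counts < 0 | counts != round(counts),
               arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop_format(path, bad[1, 1] + 1L, "invalid (negative or non-integer) count")
  expression_count_matrix(counts, stats::setNames(lens, df$gene_id))
}

#' Write a gene-level count table
#' @param x ExpressionCountMatrix.
#' @param path output TSV path.
#' @export
write_counts <- function(x, path) {
  df <- data.frame(gene_id = rownames(x$counts),
                   length_bp = unname(x$gene_length_bp),
                   x$counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Construct a per-cytosine methylation call table
#'
#' @param sites data.frame with \code{chrom}, \code{pos} (1-based),
#'   \code{strand}, \code{context} (CG/CHG/CHH).
#' @param meth,total integer site x sample matrices of methylated and total
#'   read counts sharing column names.
#' @return Object of class \code{MethylationCallTable}, rows sorted by
#'   (chrom, pos).
#' @export
methylation_call_table <- function(sites, meth, total) {
  meth <- as.matrix(meth); total <- as.matrix(total)
  stopifnot(nrow(sites) == nrow(meth), nrow(sites) == nrow(total),
            identical(colnames(meth), colnames(total)))
  ctx <- toupper(as.character(sites$context))
  if (!all(ctx %in% c("CG", "CHG", "CHH")))
    stop("context must be one of CG, CHG, CHH")
  sites$context <- ctx
  if (any(meth > total)) stop("methylated_reads must not exceed total_reads")
  if (any(meth < 0) || any(total < 0)) stop("negative read counts")
  ord <- order(sites$chrom, sites$pos)
  sites <- sites[ord, , drop = FALSE]
  rownames(sites) <- NULL
  structure(list(sites = sites,
                 meth = meth[ord, , drop = FALSE],
                 total = total[ord, , drop = FALSE]),
            class = "MethylationCallTable")
}

#' @export
print.MethylationCallTable <- function(x, ...) {
  cat(sprintf("MethylationCallTable: %d sites x %d samples (%s)\n",
              nrow(x$sites), ncol(x$meth),
              paste(names(table(x$sites$context)), collapse = "/")))
  invisible(x)
}

#' Read per-cytosine methylation calls
#'
#' TSV with columns \code{chrom}, \code{pos}, \code{strand}, \code{context},
#' then for each sample a pair \code{<id>_meth}, \code{<id>_total}. Output is
#' sorted by (chrom, pos); contexts are upper-cased.
#'
#' @param path file path.
#' @return \code{MethylationCallTable}.
#' @export
read_methylation_calls <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  fixed <- c("chrom", "pos", "strand", "context")
  if (!identical(colnames(df)[1:4], fixed))
    stop_format(path, 1L, "header must start with chrom, pos, strand, context")
  rest <- colnames(df)[-(1:4)]
  is_meth <- grepl("_meth$", rest)
  samples <- sub("_meth$", "", rest[is_meth])
  if (!identical(rest, as.vector(rbind(paste0(samples, "_meth"),
                                       paste0(samples, "_total")))))
    stop_format(path, 1L, "sample columns must be <id>_meth, <id>_total pairs")
  ctx <- toupper(df$context)
  badc <- which(!ctx %in% c("CG", "CHG", "CHH"))
  if (length(badc) > 0)
    stop_format(path, badc[1] + 1L, paste("unknown context", df$context[badc[1]]))
  meth <- as.matrix(df[, paste0(samples, "_meth"), drop = FALSE])
  total <- as.matrix(df[, paste0(samples, "_total"), drop = FALSE])
  colnames(meth) <- colnames(total) <- samples
  badr <- which(rowSums(meth > total) > 0)
  if (length(badr) > 0)
    stop_format(path, badr[1] + 1L, "methylated_reads > total_reads")
  methylation_call_table(
    data.frame(chrom = as.character(df$chrom), pos = df$pos,
               strand = as.character(df$strand), context = ctx,
               stringsAsFactors = FALSE),
    meth, total)
}

#' Write per-cytosine methylation calls
#' @param x MethylationCallTable.
#' @param path output TSV path.
#' @export
write_methylation_calls <- function(x, path) {
  samples <- colnames(x$meth)
  out <- x$sites
  for (s in samples) {
    out[[paste0(s, "_meth")]] <- x$meth[, s]
    out[[paste0(s, "_total")]] <- x$total[, s]
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Builds one record per gene: body interval, merged exons, strand-aware TSS
#' (start on +, end on -). Exons extending past the gene body are clamped
#' with a warning; a missing strand is treated as "+" with a warning.
#'
#' @param path GFF3 file with \code{gene} and \code{exon} features.
#' @return A \code{GeneModelSet}: list with \code{genes} (a
#'   \code{GRanges} carrying \code{gene_id} and \code{tss}) and
#'   \code{exons} (a \code{GRangesList} named by gene).
#' @export
read_gene_models <- function(path) {
  gff <- rtracklayer::readGFF(path)
  gff <- as.data.frame(gff)
  gid <- function(d) {
    id <- d$ID
    if (!is.null(d$gene_id)) id <- ifelse(is.na(d$gene_id), id, d$gene_id)
    as.character(id)
  }
  g <- gff[gff$type == "gene", , drop = FALSE]
  e <- gff[gff$type == "exon", , drop = FALSE]
  strand <- as.character(g$strand)
  if (any(is.na(strand) | !strand %in% c("+", "-"))) {
    warning("missing strand treated as '+'")
    strand[is.na(strand) | !strand %in% c("+", "-")] <- "+"
  }
  ids <- gid(g)
  genes <- GenomicRanges::GRanges(
    seqnames = as.character(g$seqid),
    ranges = IRanges::IRanges(g$start, g$end), strand = strand)
  genes$gene_id <- ids
  genes$tss <- ifelse(strand == "+", g$start, g$end)
  names(genes) <- ids
  exon_parent <- as.character(e$Parent)
  exon_parent <- sub("^gene:", "", exon_parent)
  exl <- vector("list", length(ids)); names(exl) <- ids
  for (i in seq_along(ids)) {
    ei <- e[exon_parent == ids[i], , drop = FALSE]
    if (nrow(ei) == 0) {
      exl[[i]] <- IRanges::IRanges(g$start[i], g$end[i])  # single-exon default
      next
    }
    s <- pmax(ei$start, g$start[i]); en <- pmin(ei$end, g$end[i])
    if (any(s != ei$start | en != ei$end))
      warning(sprintf("exon outside gene body clamped for %s", ids[i]))
    exl[[i]] <- IRanges::reduce(IRanges::IRanges(s, en))
  }
  exons <- methods::as(
    GenomicRanges::GRangesList(lapply(seq_along(ids), function(i)
      GenomicRanges::GRanges(as.character(g$seqid)[i], exl[[i]],
                             strand = strand[i]))),
    "CompressedGRangesList")
  names(exons) <- ids
  structure(list(genes = genes, exons = exons), class = "GeneModelSet")
}

#' Intron intervals of a gene model
#' @param models GeneModelSet.
#' @param gene_id gene identifier.
#' @return IRanges of introns (body minus merged exons).
#' @export
gene_introns <- function(models, gene_id) {
  g <- models$genes[models$genes$gene_id == gene_id]
  body <- IRanges::IRanges(GenomicRanges::start(g), GenomicRanges::end(g))
  IRanges::setdiff(body, IRanges::ranges(models$exons[[gene_id]]))
}

#' Read sample metadata
#'
#' TSV with columns \code{sample_id}, \code{sex} (M/F), \code{age_days},
#' then one column per fat-percentage trait.
#' @param path file path.
#' @return data.frame keyed by sample_id.
#' @export
read_metadata <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  stopifnot(all(c("sample_id", "sex", "age_days") %in% colnames(df)))
  if (anyNA(df$sex) || !all(df$sex %in% c("M", "F")))
    stop("sex must be M or F, non-missing")
  traits <- setdiff(colnames(df), c("sample_id", "sex", "age_days"))
  for (tr in traits) {
    v <- df[[tr]]
    if (any(!is.na(v) & (v < 0 | v > 100)))
      stop(sprintf("trait '%s' outside [0,100]", tr))
  }
  df$sample_id <- as.character(df$sample_id)
  df
}

#' Write sample metadata
#' @param df metadata data.frame.
#' @param path output path.
#' @export
write_metadata <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a QTL interval table
#'
#' TSV with columns \code{qtl_id}, \code{trait}, \code{qtl_type},
#' \code{chrom}, \code{start}, \code{end}; coordinates 1-based inclusive
#' unless \code{zero_based_half_open = TRUE}.
#' @param path file path.
#' @param zero_based_half_open convert BED-style coordinates on read.
#' @return data.frame of QTL records.
#' @export
read_qtl <- function(path, zero_based_half_open = FALSE) {
  df <- utils::read.delim(path, check.names = FALSE)
  need <- c("qtl_id", "trait", "qtl_type", "chrom", "start", "end")
  stopifnot(all(need %in% colnames(df)))
  if (zero_based_half_open) df$start <- df$start + 1L
  if (any(df$start < 1) || any(df$end < df$start)) stop("invalid QTL interval")
  df
}

#' Write a QTL interval table
#' @param df QTL data.frame.
#' @param path output path.
#' @export
write_qtl <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Per-site methylation fractions
#' @param calls MethylationCallTable.
#' @return site x sample matrix of meth/total, NA where total is 0.
#' @export
meth_fraction <- function(calls) {
  fr <- calls$meth / calls$total
  fr[calls$total == 0] <- NA_real_
  fr
}
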