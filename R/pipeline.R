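# End-to-end orchestration: phenotype stats -> DE -> per-sex networks ->
# DcoExp -> DML/DMR -> integration -> module-trait -> enrichment, with
# per-stage outputs and a reproducibility manifest.

stage_seed <- function(global_seed, stage) {
  # stable per-stage seed: modular polynomial hash of the stage name
  h <- 17
  for (ch in utf8ToInt(stage)) h <- (h * 31 + ch) %% 2147483629
  as.integer((h + as.numeric(global_seed) * 7919) %% 2147483629)
}

#' Pipeline configuration
#'
#' Either \code{inputs} (paths to counts/methylation/gff3/qtl/metadata
#' files) or \code{simulate} (a \code{\link{simulation_config}}) must be
#' given.
#' @param inputs named list of input file paths.
#' @param simulate SimulationConfig to generate inputs instead.
#' @param out_dir output directory.
#' @param seed global seed fanned out to stages.
#' @param params named list of stage parameter overrides (fpkm_threshold,
#'   min_module_size, keepX, promoter window, DMR rule settings, ...).
#' @return list of class PipelineConfig.
#' @export
pipeline_config <- function(inputs = NULL, simulate = NULL,
                            out_dir = tempfile("sexomics_run"),
                            seed = 1L, params = list()) {
  if (is.null(inputs) && is.null(simulate))
    stop("either inputs or simulate must be provided")
  if (!is.null(inputs)) {
    need <- c("counts", "methylation", "gff3", "qtl", "metadata")
    missing_f <- setdiff(need, names(inputs))
    if (length(missing_f) > 0)
      stop("missing input paths: ", paste(missing_f, collapse = ", "))
    for (f in unlist(inputs)) if (!file.exists(f))
      stop("input file not found: ", f)
  }
  structure(list(inputs = inputs, simulate = simulate, out_dir = out_dir,
                 seed = as.integer(seed), params = params),
            class = "PipelineConfig")
}

#' Read a pipeline configuration from YAML
#' @param path YAML file; keys inputs/simulate/out_dir/seed/params.
#' @return PipelineConfig.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim <- NULL
  if (!is.null(y$simulate)) sim <- do.call(simulation_config, y$simulate)
  pipeline_config(inputs = y$inputs, simulate = sim,
                  out_dir = y$out_dir %||% tempfile("sexomics_run"),
                  seed = y$seed %||% 1L, params = y$params %||% list())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
}

#' Run the full pipeline
#'
#' Executes every stage in order and writes each stage's outputs under
#' \code{config$out_dir} plus a \code{manifest.json} capturing the seed and
#' parameters. The candidate-module report lists the differentially
#' co-expressed modules that harbour at least one integration-selected gene
#' and correlate significantly with at least one fat trait.
#' @param config PipelineConfig.
#' @return invisible list with every stage's in-memory results.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- config$params
  log_msg <- function(...) message(sprintf(...))

  ## inputs
  if (!is.null(config$simulate)) {
    log_msg("stage simulate: generating synthetic experiment")
    sim_cfg <- config$simulate
    sim_cfg$seed <- stage_seed(config$seed, "simulate")
    sim <- simulate_experiment(sim_cfg)
    write_experiment(sim, file.path(config$out_dir, "inputs"))
    counts <- sim$counts; calls <- sim$calls; models <- sim$gene_models
    qtl <- sim$qtl; metadata <- sim$metadata
  } else {
    counts <- read_counts(config$inputs$counts)
    calls <- read_methylation_calls(config$inputs$methylation)
    models <- read_gene_models(config$inputs$gff3)
    qtl <- read_qtl(config$inputs$qtl)
    metadata <- read_metadata(config$inputs$metadata)
    sim <- NULL
  }
  traits <- setdiff(colnames(metadata), c("sample_id", "sex", "age_days"))
  sexes <- metadata$sex[match(colnames(counts$counts), metadata$sample_id)]

  ## phenotype statistics
  log_msg("stage phenostats")
  pheno <- compare_traits(metadata, traits)
  write_tsv(pheno, file.path(config$out_dir, "trait_comparison.tsv"))

  ## differential expression
  log_msg("stage expression")
  de <- run_de_stage(counts, metadata,
                     fpkm_threshold = p$fpkm_threshold %||% 0.2)
  write_tsv(de$results, file.path(config$out_dir, "de_results.tsv"))
  writeLines(de$degs, file.path(config$out_dir, "degs.txt"))
  writeLines(de$candidates, file.path(config$out_dir, "candidate_genes.txt"))

  ## per-sex co-expression + DcoExp
  log_msg("stage coexpression")
  lf <- log2(de$fpkm[de$kept_genes, , drop = FALSE] + 1)
  mms <- p$min_module_size %||% 30
  set.seed(stage_seed(config$seed, "coexpression"))
  mod_m <- build_modules(lf, sexes, "M", min_module_size = mms)
  mod_f <- build_modules(lf, sexes, "F", min_module_size = mms)
  background <- rownames(good_samples_genes(lf))
  bg <- intersect(names(mod_m$assignment), names(mod_f$assignment))
  dco <- dcoexp_fisher(mod_m, mod_f, bg)
  write_tsv(dco, file.path(config$out_dir, "dcoexp.tsv"))
  write_tsv(data.frame(gene_id = names(mod_m$assignment),
                       module_m = mod_m$assignment),
            file.path(config$out_dir, "modules_M.tsv"))
  write_tsv(data.frame(gene_id = names(mod_f$assignment),
                       module_f = mod_f$assignment),
            file.path(config$out_dir, "modules_F.tsv"))

  ## methylation
  log_msg("stage methylation")
  meth <- run_methylation_stage(calls, metadata, models)
  write_tsv(meth$dml, file.path(config$out_dir, "dml.tsv"))
  write_tsv(meth$dmrs, file.path(config$out_dir, "dmr_annotated.tsv"))
  write_tsv(meth$summary, file.path(config$out_dir, "context_summary.tsv"))

  ## integration
  log_msg("stage integration")
  integ <- NULL
  if (length(de$candidates) >= 2 && nrow(meth$dmrs) >= 2) {
    integ <- run_integration_stage(de$fpkm, de$candidates, meth$dmrs, calls,
                                   metadata, keepX = p$keepX)
    jsonlite::write_json(
      list(auc = integ$refit$evaluation$auc,
           combined = integ$refit$evaluation$combined,
           cross_block_cor = integ$refit$evaluation$cross_block_cor,
           n_selected = lengths(integ$selected),
           n_paired_genes = length(integ$pairing$paired_genes),
           n_paired_dmrs = length(integ$pairing$paired_dmrs)),
      file.path(config$out_dir, "evaluation.json"),
      auto_unbox = TRUE, digits = NA, dataframe = "rows")
    writeLines(integ$selected$mrna,
               file.path(config$out_dir, "selected_genes.txt"))
    writeLines(integ$selected$meth,
               file.path(config$out_dir, "selected_dmrs.txt"))
  } else log_msg("integration skipped: too few candidates or DMRs")

  ## module-trait correlation on DcoExp modules harbouring selected genes
  log_msg("stage module-trait")
  modtrait <- rbind(module_trait_correlation(mod_m, metadata, traits),
                    module_trait_correlation(mod_f, metadata, traits))
  modtrait$sex <- rep(c("M", "F"),
                      c(length(mod_m$eigengenes) * length(traits),
                        length(mod_f$eigengenes) * length(traits)))
  write_tsv(modtrait, file.path(config$out_dir, "module_trait.tsv"))
  candidate_modules <- NULL
  if (!is.null(integ)) {
    sel_genes <- integ$selected$mrna
    spec_rows <- dco[dco$specific, , drop = FALSE]
    harb <- vapply(seq_len(nrow(spec_rows)), function(i) {
      ms <- if (spec_rows$sex[i] == "M") mod_m else mod_f
      members <- names(ms$assignment)[ms$assignment == spec_rows$module[i]]
      any(members %in% sel_genes)
    }, logical(1))
    sig_mod <- unique(modtrait$module[!is.na(modtrait$significant) &
                                        modtrait$significant])
    candidate_modules <- spec_rows[harb & spec_rows$module %in% sig_mod, ,
                                   drop = FALSE]
    write_tsv(candidate_modules,
              file.path(config$out_dir, "candidate_modules.tsv"))
  }

  ## enrichment
  log_msg("stage enrichment")
  enrich <- NULL
  if (!is.null(integ) && length(integ$selected$mrna) > 0) {
    sel_models <- structure(list(
      genes = models$genes[models$genes$gene_id %in% integ$selected$mrna],
      exons = models$exons[intersect(names(models$exons),
                                     integ$selected$mrna)]),
      class = "GeneModelSet")
    ov <- annotate_qtl_overlap(sel_models, qtl)
    if (nrow(ov) > 0) {
      enrich <- qtl_enrichment(ov, qtl)
      write_tsv(enrich$enrichment, file.path(config$out_dir,
                                             "qtl_enrichment.tsv"))
    }
  }

  ## manifest
  manifest <- list(package = "sexomics",
                   version = as.character(utils::packageVersion("sexomics")),
                   seed = config$seed,
                   params = config$params,
                   stages = c("phenostats", "expression", "coexpression",
                              "methylation", "integration", "module_trait",
                              "enrichment"),
                   n_samples = nrow(metadata))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(metadata = metadata, pheno = pheno, de = de,
                 modules = list(M = mod_m, F = mod_f), dcoexp = dco,
                 methylation = meth, integration = integ,
                 module_trait = modtrait,
                 candidate_modules = candidate_modules,
                 enrichment = enrich, sim = sim))
}
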