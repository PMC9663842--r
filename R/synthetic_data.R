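# Synthetic experiment generator: 6+6 lamb perirenal-fat design with planted
# sex effects in expression, methylation, co-expression structure and traits.

#' Simulation configuration
#'
#' Defaults describe the study design being emulated: 12 samples (6 per sex),
#' negative-binomial RNA-seq counts with a fraction of genes carrying a sex
#' log2 fold-change, beta-binomial WGBS calls with context-specific baseline
#' methylation (CG 0.6, CHG 0.2, CHH 0.15), planted differentially methylated
#' regions partly placed inside planted genes, sex-specific co-expressed gene
#' blocks, and fat-percentage traits correlated with a module's latent factor.
#'
#' @param n_per_sex samples per sex (>= 2).
#' @param n_genes number of genes.
#' @param n_sites named vector: sites per context over the whole genome.
#' @param genome named vector of chromosome lengths (bp).
#' @param de_fraction fraction of genes with a planted sex effect.
#' @param de_log2fc_range range of |log2FC| for planted genes.
#' @param dmr_count number of planted DMRs.
#' @param dmr_length_range planted DMR length range (bp).
#' @param dmr_delta_range range of the planted methylation difference.
#' @param dmr_in_gene_fraction fraction of planted DMRs placed inside planted
#'   DE genes' bodies.
#' @param context_baseline_mean named baseline methylation per context.
#' @param nb_dispersion_range per-gene NB dispersion range.
#' @param bb_dispersion_range per-site beta-binomial dispersion range.
#' @param coverage_mean mean WGBS coverage per site per sample.
#' @param zero_coverage_fraction fraction of site/sample cells left uncovered.
#' @param module_spec data.frame with columns \code{size},
#'   \code{within_cor}, \code{sex_specific} (logical), \code{sex} ("M"/"F",
#'   used when sex_specific).
#' @param trait_spec data.frame with columns \code{trait}, \code{module}
#'   (index into module_spec), \code{correlation}.
#' @param seed integer RNG seed.
#' @return list of class \code{SimulationConfig}.
#' @export
simulation_config <- function(n_per_sex = 6,
                              n_genes = 2000,
                              n_sites = c(CG = 3000, CHG = 1200, CHH = 1200),
                              genome = c(chr1 = 1e7, chr2 = 1e7, chr3 = 1e7),
                              de_fraction = 0.05,
                              de_log2fc_range = c(1, 4),
                              dmr_count = 40,
                              dmr_length_range = c(100, 400),
                              dmr_delta_range = c(0.3, 0.5),
                              dmr_in_gene_fraction = 0.5,
                              context_baseline_mean = c(CG = 0.6, CHG = 0.2, CHH = 0.15),
                              nb_dispersion_range = c(0.05, 0.3),
                              bb_dispersion_range = c(0.01, 0.1),
                              coverage_mean = 20,
                              zero_coverage_fraction = 0.02,
                              module_spec = default_module_spec(),
                              trait_spec = default_trait_spec(),
                              seed = 1L) {
  stopifnot(n_per_sex >= 2, de_fraction >= 0, de_fraction <= 1,
            all(dmr_delta_range > 0), all(dmr_delta_range < 1),
            all(context_baseline_mean >= 0), all(context_baseline_mean <= 1))
  if (dmr_count > 0 &&
      dmr_count * max(dmr_length_range) > sum(genome))
    stop("infeasible config: planted DMR footprint exceeds the genome")
  structure(as.list(environment()), class = "SimulationConfig")
}

#' Default co-expression module specification
#'
#' Five modules: one male-specific, one female-specific, three shared.
#' @param size genes per module.
#' @param within_cor target within-module correlation in the coherent sex.
#' @return data.frame consumed by \code{\link{simulation_config}}.
#' @export
default_module_spec <- function(size = 50, within_cor = 0.8) {
  data.frame(size = size,
             within_cor = within_cor,
             sex_specific = c(TRUE, TRUE, FALSE, FALSE, FALSE),
             sex = c("M", "F", "M", "M", "M"),
             stringsAsFactors = FALSE)
}

#' Default trait specification
#'
#' Fat-percentage traits; the first two track module latent factors.
#' @return data.frame consumed by \code{\link{simulation_config}}.
#' @export
default_trait_spec <- function() {
  data.frame(trait = c("renal", "pelvic", "renal_and_pelvic",
                       "leg_intramuscular", "leg_subcutaneous"),
             module = c(1L, 2L, NA, NA, NA),
             correlation = c(0.85, 0.85, 0, 0, 0),
             stringsAsFactors = FALSE)
}

rbetabinom <- function(n, size, mu, phi) {
  # Beta(mu(1-phi)/phi, (1-mu)(1-phi)/phi); phi = 0 is pure binomial
  out <- numeric(n)
  mu <- rep_len(mu, n); phi <- rep_len(phi, n); size <- rep_len(size, n)
  zero <- phi <= 0 | mu <= 0 | mu >= 1
  out[zero] <- stats::rbinom(sum(zero), size[zero], mu[zero])
  if (any(!zero)) {
    a <- mu[!zero] * (1 - phi[!zero]) / phi[!zero]
    b <- (1 - mu[!zero]) * (1 - phi[!zero]) / phi[!zero]
    p <- stats::rbeta(sum(!zero), a, b)
    out[!zero] <- stats::rbinom(sum(!zero), size[!zero], p)
  }
  out
}

#' Simulate a complete paired expression + methylation experiment
#'
#' Deterministic given \code{config$seed}. Returns every input the pipeline
#' consumes plus a ground-truth record of all planted effects.
#'
#' @param config a \code{\link{simulation_config}}.
#' @return list with \code{counts} (ExpressionCountMatrix), \code{calls}
#'   (MethylationCallTable), \code{gene_models} (GeneModelSet), \code{qtl}
#'   (data.frame), \code{metadata} (data.frame) and \code{truth}.
#' @export
simulate_experiment <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed)
  cfg <- config
  n <- 2 * cfg$n_per_sex
  samples <- c(sprintf("M%02d", seq_len(cfg$n_per_sex)),
               sprintf("F%02d", seq_len(cfg$n_per_sex)))
  sex <- rep(c("M", "F"), each = cfg$n_per_sex)

  metadata <- data.frame(sample_id = samples, sex = sex,
                         age_days = round(pmax(14, stats::rnorm(
                           n, mean = ifelse(sex == "M", 28.2, 24.2),
                           sd = ifelse(sex == "M", 4.9, 5.2))), 1),
                         stringsAsFactors = FALSE)

  gm <- simulate_gene_models(cfg)
  truth <- list()

  ## --- expression ---
  module_genes_n <- sum(cfg$module_spec$size)
  n_genes <- cfg$n_genes
  stopifnot(n_genes > module_genes_n)
  gene_ids <- gm$genes$gene_id
  n_de <- round(cfg$de_fraction * n_genes)
  # DE genes drawn outside the co-expression blocks (last genes are modules)
  free <- seq_len(n_genes - module_genes_n)
  de_idx <- if (n_de > 0) sort(sample(free, n_de)) else integer(0)
  lfc <- numeric(n_genes)
  if (n_de > 0) {
    mag <- stats::runif(n_de, cfg$de_log2fc_range[1], cfg$de_log2fc_range[2])
    lfc[de_idx] <- mag * sample(c(-1, 1), n_de, replace = TRUE)
  }
  truth$de <- data.frame(gene_id = gene_ids[de_idx],
                         log2fc = lfc[de_idx], stringsAsFactors = FALSE)

  base_mean <- exp(stats::rnorm(n_genes, log(150), 1.2))
  module_rows <- (n_genes - module_genes_n + 1):n_genes
  base_mean[module_rows] <- exp(stats::rnorm(module_genes_n, log(150), 0.3))
  disp <- stats::runif(n_genes, cfg$nb_dispersion_range[1],
                       cfg$nb_dispersion_range[2])
  sf <- exp(stats::runif(n, log(0.7), log(1.4)))

  # per-sample log2 offsets: sex effect split +/- lfc/2; module factor model
  log2_off <- matrix(0, n_genes, n)
  log2_off <- log2_off + outer(lfc / 2, ifelse(sex == "F", 1, -1))
  # latent module factors: orthogonal within each sex so the planted
  # partition is identifiable at small n (sample correlation between
  # distinct random factors over 6 samples is otherwise often large)
  n_mod <- nrow(cfg$module_spec)
  factors <- matrix(0, n_mod, n)
  for (sx in c("M", "F")) {
    cols <- which(sex == sx)
    act_mods <- which(!cfg$module_spec$sex_specific |
                        cfg$module_spec$sex == sx)
    k <- length(act_mods)
    if (k == 0) next
    if (k <= length(cols) - 1) {
      z <- scale(matrix(stats::rnorm(length(cols) * k), length(cols), k),
                 scale = FALSE)
      q <- qr.Q(qr(z))[, seq_len(k), drop = FALSE]
      factors[act_mods, cols] <- t(q) * sqrt(length(cols) - 1)
    } else {
      factors[act_mods, cols] <- stats::rnorm(k * length(cols))
    }
  }
  membership <- data.frame(gene_id = character(), module = integer(),
                           sex = character(), stringsAsFactors = FALSE)
  row0 <- n_genes - module_genes_n
  # every gene carries its own biological residual on top of counting
  # noise; module genes must not form a separable noise class, or they
  # would spuriously co-cluster in the sex where their factor is silent
  sigma_bio <- stats::runif(n_genes, 0.1, 0.6)
  resid <- matrix(stats::rnorm(n_genes * n), n_genes, n) * sigma_bio
  # per-gene log2-scale counting-noise variance (delta method on NB)
  sigma_c2_g <- (1 / pmax(base_mean, 1) + disp) / log(2)^2
  for (m in seq_len(nrow(cfg$module_spec))) {
    sz <- cfg$module_spec$size[m]
    rows <- row0 + seq_len(sz); row0 <- row0 + sz
    r <- cfg$module_spec$within_cor[m]
    # per-gene loading so every pair within the module has correlation r:
    # beta_g^2 = (sigma_bio_g^2 + sigma_c_g^2) * r / (1 - r)
    beta_g <- sqrt((sigma_bio[rows]^2 + sigma_c2_g[rows]) * r / (1 - r))
    act <- if (cfg$module_spec$sex_specific[m]) sex == cfg$module_spec$sex[m] else rep(TRUE, n)
    log2_off[rows, act] <- log2_off[rows, act] +
      cbind(beta_g) %*% factors[m, act, drop = FALSE]
    membership <- rbind(membership, data.frame(
      gene_id = gene_ids[rows], module = m,
      sex = if (cfg$module_spec$sex_specific[m]) cfg$module_spec$sex[m] else "both",
      stringsAsFactors = FALSE))
  }
  log2_off <- log2_off + resid
  mu <- base_mean * 2^log2_off * rep(sf, each = n_genes)
  counts <- matrix(stats::rnbinom(n_genes * n, mu = mu,
                                  size = 1 / rep(disp, n)),
                   n_genes, n, dimnames = list(gene_ids, samples))
  counts[base_mean == 0, ] <- 0
  gene_len <- stats::setNames(gm$gene_length_bp, gene_ids)
  expr <- expression_count_matrix(counts, gene_len)
  truth$modules <- membership
  truth$module_factors <- factors

  ## --- methylation ---
  de_granges <- gm$genes[gm$genes$gene_id %in% truth$de$gene_id]
  sim_meth <- simulate_methylation_internal(cfg, gm, samples, sex, de_granges)
  truth$dmrs <- sim_meth$truth_dmrs

  ## --- traits ---
  for (i in seq_len(nrow(cfg$trait_spec))) {
    tr <- cfg$trait_spec$trait[i]
    r <- cfg$trait_spec$correlation[i]
    mi <- cfg$trait_spec$module[i]
    base <- stats::rnorm(n)
    if (!is.na(mi) && r != 0) {
      f <- factors[mi, ]
      z <- r * (f - mean(f)) / stats::sd(f) + sqrt(1 - r^2) * base
    } else z <- base
    metadata[[tr]] <- round(pmin(100, pmax(0, 3 + 1.2 * z)), 3)
  }
  truth$trait_links <- cfg$trait_spec

  ## --- QTL database ---
  qtl <- simulate_qtl(cfg, gm)

  list(counts = expr, calls = sim_meth$calls, gene_models = gm$models,
       qtl = qtl, metadata = metadata, truth = truth)
}

simulate_gene_models <- function(cfg) {
  n_genes <- cfg$n_genes
  chroms <- names(cfg$genome)
  chrom <- sample(chroms, n_genes, replace = TRUE, prob = cfg$genome)
  len <- pmax(600L, round(exp(stats::rnorm(n_genes, log(2500), 0.6))))
  start <- vapply(seq_len(n_genes), function(i)
    sample.int(cfg$genome[[chrom[i]]] - len[i], 1), 1L)
  end <- start + len - 1L
  strand <- sample(c("+", "-"), n_genes, replace = TRUE)
  ids <- sprintf("gene%05d", seq_len(n_genes))
  genes <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end), strand)
  genes$gene_id <- ids
  genes$tss <- ifelse(strand == "+", start, end)
  names(genes) <- ids
  # two exons with one internal intron covering the middle fifth
  q <- cbind(start, start + round(len * 0.4),
             start + round(len * 0.6), end)
  exons <- GenomicRanges::GRangesList(lapply(seq_len(n_genes), function(i)
    GenomicRanges::GRanges(chrom[i],
                           IRanges::IRanges(c(q[i, 1], q[i, 3]),
                                            c(q[i, 2], q[i, 4])),
                           strand = strand[i])))
  names(exons) <- ids
  models <- structure(list(genes = genes, exons = exons), class = "GeneModelSet")
  list(models = models, genes = genes, gene_length_bp = len)
}

simulate_methylation_internal <- function(cfg, gm, samples, sex,
                                          target_genes = NULL) {
  n <- length(samples)
  chroms <- names(cfg$genome)
  site_list <- list()
  for (ctx in names(cfg$n_sites)) {
    k <- cfg$n_sites[[ctx]]
    chrom <- sample(chroms, k, replace = TRUE, prob = cfg$genome)
    pos <- vapply(seq_len(k), function(i)
      sample.int(cfg$genome[[chrom[i]]], 1), 1L)
    site_list[[ctx]] <- data.frame(chrom = chrom, pos = pos,
                                   strand = sample(c("+", "-"), k, TRUE),
                                   context = ctx, stringsAsFactors = FALSE)
  }
  sites <- do.call(rbind, site_list)

  # plant DMRs: contiguous runs of extra sites so region criteria are meetable
  truth_dmrs <- NULL
  if (cfg$dmr_count > 0) {
    host_genes <- if (!is.null(target_genes) && length(target_genes) > 0)
      target_genes else gm$genes
    n_in_gene <- round(cfg$dmr_in_gene_fraction * cfg$dmr_count)
    dmr_rows <- list()
    extra <- list()
    placed <- data.frame(chrom = character(), start = integer(),
                         end = integer(), stringsAsFactors = FALSE)
    for (d in seq_len(cfg$dmr_count)) {
      L <- round(stats::runif(1, cfg$dmr_length_range[1], cfg$dmr_length_range[2]))
      delta <- stats::runif(1, cfg$dmr_delta_range[1], cfg$dmr_delta_range[2])
      ctx <- "CG"
      # rejection sampling keeps planted regions well separated
      for (try in 1:100) {
        if (d <= n_in_gene && length(host_genes) > 0) {
          g <- host_genes[sample(length(host_genes), 1)]
          gs <- GenomicRanges::start(g); ge <- GenomicRanges::end(g)
          if (ge - gs > L + 2) {
            s0 <- gs + sample.int(max(1, ge - gs - L), 1)
          } else s0 <- gs
          ch <- as.character(GenomicRanges::seqnames(g))
        } else {
          ch <- sample(chroms, 1, prob = cfg$genome)
          s0 <- sample.int(cfg$genome[[ch]] - L, 1)
        }
        clash <- placed$chrom == ch & placed$start <= s0 + L + 1000 &
          placed$end >= s0 - 1000
        if (!any(clash)) break
      }
      placed <- rbind(placed, data.frame(chrom = ch, start = s0,
                                         end = s0 + L - 1L,
                                         stringsAsFactors = FALSE))
      e0 <- s0 + L - 1L
      n_sites_d <- max(5L, round(L / 40))
      pos_d <- sort(unique(round(seq(s0, e0, length.out = n_sites_d))))
      sign_d <- sample(c(-1, 1), 1)
      extra[[d]] <- data.frame(chrom = ch, pos = pos_d,
                               strand = "+", context = ctx,
                               dmr = d, stringsAsFactors = FALSE)
      base <- cfg$context_baseline_mean[[ctx]]
      mu_f <- min(0.98, max(0.02, base + sign_d * delta / 2))
      mu_m <- min(0.98, max(0.02, base - sign_d * delta / 2))
      dmr_rows[[d]] <- data.frame(chrom = ch, start = s0, end = max(pos_d),
                                  context = ctx, mu_f = mu_f, mu_m = mu_m,
                                  delta = mu_f - mu_m, stringsAsFactors = FALSE)
    }
    truth_dmrs <- do.call(rbind, dmr_rows)
    extra_df <- do.call(rbind, extra)
    sites <- rbind(sites, extra_df[, colnames(sites)])
    dmr_of_site <- c(rep(NA_integer_, nrow(sites) - nrow(extra_df)), extra_df$dmr)
  } else {
    dmr_of_site <- rep(NA_integer_, nrow(sites))
  }

  k <- nrow(sites)
  base <- cfg$context_baseline_mean[sites$context]
  # per-site baseline wobble so sites are not all identical
  site_mu <- pmin(0.98, pmax(0.02, base + stats::rnorm(k, 0, 0.05)))
  mu_f <- site_mu; mu_m <- site_mu
  pl <- !is.na(dmr_of_site)
  if (any(pl)) {
    mu_f[pl] <- truth_dmrs$mu_f[dmr_of_site[pl]]
    mu_m[pl] <- truth_dmrs$mu_m[dmr_of_site[pl]]
  }
  phi <- stats::runif(k, cfg$bb_dispersion_range[1], cfg$bb_dispersion_range[2])

  total <- matrix(stats::rpois(k * n, cfg$coverage_mean), k, n)
  total[total == 0] <- 1L
  drop <- matrix(stats::runif(k * n) < cfg$zero_coverage_fraction, k, n)
  total[drop] <- 0L
  meth <- matrix(0L, k, n)
  for (s in seq_len(n)) {
    mu_s <- if (sex[s] == "F") mu_f else mu_m
    cov_ok <- total[, s] > 0
    meth[cov_ok, s] <- rbetabinom(sum(cov_ok), total[cov_ok, s],
                                  mu_s[cov_ok], phi[cov_ok])
  }
  colnames(meth) <- colnames(total) <- samples
  calls <- methylation_call_table(sites, meth, total)
  list(calls = calls, truth_dmrs = truth_dmrs)
}

simulate_qtl <- function(cfg, gm) {
  chroms <- names(cfg$genome)
  n_qtl <- 60L
  traits <- c("carcass_fat_volume", "body_weight_slaughter", "milk_fa",
              "meat_fa", "loin_area")
  types <- c("Meat_and_Carcass", "Milk", "Production")
  chrom <- sample(chroms, n_qtl, replace = TRUE)
  len <- round(stats::runif(n_qtl, 5e4, 5e5))
  start <- vapply(seq_len(n_qtl), function(i)
    sample.int(cfg$genome[[chrom[i]]] - len[i], 1), 1L)
  data.frame(qtl_id = sprintf("QTL%04d", seq_len(n_qtl)),
             trait = sample(traits, n_qtl, TRUE),
             qtl_type = sample(types, n_qtl, TRUE),
             chrom = chrom, start = start, end = start + len - 1L,
             stringsAsFactors = FALSE)
}

#' Write a simulated experiment to disk
#'
#' Emits every on-disk format the pipeline reads plus \code{truth.json}.
#' @param sim result of \code{\link{simulate_experiment}}.
#' @param dir output directory (created if missing).
#' @return \code{dir}, invisibly.
#' @export
write_experiment <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_counts(sim$counts, file.path(dir, "counts.tsv"))
  write_methylation_calls(sim$calls, file.path(dir, "methylation.tsv"))
  write_metadata(sim$metadata, file.path(dir, "metadata.tsv"))
  write_qtl(sim$qtl, file.path(dir, "qtl.tsv"))
  write_gene_models_gff3(sim$gene_models, file.path(dir, "genes.gff3"))
  truth <- sim$truth
  truth$module_factors <- NULL
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(dir)
}

#' Write gene models as GFF3
#' @param models GeneModelSet.
#' @param path output path.
#' @export
write_gene_models_gff3 <- function(models, path) {
  g <- models$genes
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (i in seq_along(g)) {
    id <- g$gene_id[i]
    writeLines(sprintf("%s\t.\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                       as.character(GenomicRanges::seqnames(g)[i]),
                       GenomicRanges::start(g)[i], GenomicRanges::end(g)[i],
                       as.character(GenomicRanges::strand(g)[i]), id), con)
    ex <- models$exons[[id]]
    for (j in seq_along(ex)) {
      writeLines(sprintf("%s\t.\texon\t%d\t%d\t.\t%s\t.\tID=%s.e%d;Parent=%s",
                         as.character(GenomicRanges::seqnames(ex)[j]),
                         GenomicRanges::start(ex)[j], GenomicRanges::end(ex)[j],
                         as.character(GenomicRanges::strand(ex)[j]), id, j, id),
                 con)
    }
  }
  invisible(path)
}
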