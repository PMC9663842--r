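block_expr <- function(n_blocks = 2, size = 50, n_noise = 50, n_samp = 12,
                       r = 0.9, seed = 1) {
  # gene x sample matrix with planted correlated blocks
  set.seed(seed)
  beta <- sqrt(r / (1 - r))
  out <- lapply(seq_len(n_blocks), function(b) {
    f <- rnorm(n_samp)
    t(sapply(seq_len(size), function(i) beta * f + rnorm(n_samp)))
  })
  x <- do.call(rbind, out)
  if (n_noise > 0)
    x <- rbind(x, matrix(rnorm(n_noise * n_samp), n_noise, n_samp))
  rownames(x) <- sprintf("g%04d", seq_len(nrow(x)))
  colnames(x) <- sprintf("s%02d", seq_len(n_samp))
  x
}

test_that("quality filter drops constant and mostly-missing genes", {
  x <- matrix(rnorm(40), 4, 10,
              dimnames = list(paste0("g", 1:4), paste0("s", 1:10)))
  x[2, ] <- 5                      # zero variance
  x[3, 1:6] <- NA                  # 60% missing
  out <- good_samples_genes(x)
  expect_setequal(rownames(out), c("g1", "g4"))
  expect_identical(good_samples_genes(x[c(1, 4), ]), x[c(1, 4), ])
  expect_error(good_samples_genes(x[2, , drop = FALSE]), "all genes")
})

test_that("signed adjacency maps correlation as ((1+r)/2)^beta", {
  s <- 1:10
  x <- rbind(a = s, b = s, c = -s) + 0
  x <- x + matrix(rnorm(30, sd = 1e-6), 3)
  a6 <- signed_adjacency(x, 6)
  expect_equal(a6["a", "b"], 1, tolerance = 1e-4)
  expect_equal(a6["a", "c"], 0, tolerance = 1e-4)
  z <- matrix(rnorm(40), 4, 10)
  expect_equal(signed_adjacency(z, 6)[1, 2],
               ((1 + cor(z[1, ], z[2, ])) / 2)^6, tolerance = 1e-12)
})

test_that("TOM matches hand arithmetic on toy networks", {
  # 3-gene toy: TOM_12 = (a13 a23 + a12)/(min(k1,k2) + 1 - a12)
  a <- matrix(c(1, 0.5, 0.4,
                0.5, 1, 0.2,
                0.4, 0.2, 1), 3, 3,
              dimnames = list(paste0("g", 1:3), paste0("g", 1:3)))
  tom <- tom_similarity(a)
  expect_equal(tom["g1", "g2"], (0.4 * 0.2 + 0.5) / (min(0.9, 0.7) + 1 - 0.5))
  expect_equal(tom["g1", "g2"], 0.58 / 1.2)
  # 2-gene network: empty summation leaves TOM = a
  a2 <- matrix(c(1, 0.3, 0.3, 1), 2, 2,
               dimnames = list(c("x", "y"), c("x", "y")))
  expect_equal(tom_similarity(a2)["x", "y"], 0.3)
  # saturated network
  ones <- matrix(1, 3, 3, dimnames = dimnames(a))
  expect_equal(unname(tom_similarity(ones)), matrix(1, 3, 3))
})

test_that("soft threshold selection is deterministic and falls back on noise", {
  x <- block_expr(n_blocks = 3, size = 40, n_noise = 30, n_samp = 20)
  b1 <- pick_soft_threshold(x)
  expect_true(b1 %in% 1:20)
  expect_identical(b1, pick_soft_threshold(x))
  for (sd in 1:3) {
    set.seed(sd)
    noise <- matrix(rnorm(150 * 20), 150, 20,
                    dimnames = list(sprintf("n%03d", 1:150), NULL))
    expect_identical(pick_soft_threshold(noise), 12L)
  }
})

test_that("module detection recovers planted blocks and greys noise", {
  x <- block_expr(n_blocks = 2, size = 50, n_noise = 100, n_samp = 30,
                  r = 0.85, seed = 3)
  tom <- tom_similarity(signed_adjacency(x, 12))
  lab <- detect_modules(tom, min_module_size = 30)
  truth <- rep(c(1, 2, 0), c(50, 50, 100))
  mods <- setdiff(unique(lab), "grey")
  expect_equal(length(mods), 2)
  # planted blocks recovered nearly intact
  for (b in 1:2) {
    tab <- table(lab[truth == b])
    expect_gte(max(tab) / 50, 0.9)
  }
  # most unstructured genes stay grey
  expect_gte(mean(lab[truth == 0] == "grey"), 0.8)
  # pure-noise input: nothing but grey survives the size filter
  noise <- block_expr(n_blocks = 1, size = 2, n_noise = 150, n_samp = 30,
                      seed = 4)[-(1:2), ]
  tom_n <- tom_similarity(signed_adjacency(noise, 12))
  lab_n <- detect_modules(tom_n, min_module_size = 30)
  expect_gte(mean(lab_n == "grey"), 0.95)
  # oversized min_module_size sends everything to grey
  expect_true(all(detect_modules(tom, min_module_size = 1000) == "grey"))
})

test_that("module eigengene equals the leading principal component", {
  x <- block_expr(n_blocks = 1, size = 30, n_noise = 0, n_samp = 15)
  e <- module_eigengene(x, rownames(x))
  expect_equal(sd(e), 1)
  xs <- t(scale(t(x)))
  sv <- svd(xs)
  brute <- sv$v[, 1] * sv$d[1]      # leading PC scores by eigendecomposition
  expect_equal(abs(cor(e, brute)), 1, tolerance = 1e-10)
  # variance maximality against random unit combinations
  var_e <- var(colSums(xs * drop(cor(t(xs), e))) /
                 sqrt(sum(cor(t(xs), e)^2)))
  set.seed(4)
  for (i in 1:20) {
    w <- rnorm(nrow(xs)); w <- w / sqrt(sum(w^2))
    expect_lte(var(colSums(xs * w)), var_e + 1e-8)
  }
  # sign convention
  expect_gte(cor(e, colMeans(xs)), 0)
  # identical profiles: eigengene proportional to the common profile
  xx <- matrix(rep(1:10, 3), 3, 10, byrow = TRUE,
               dimnames = list(c("a", "b", "c"), NULL))
  xx <- xx + matrix(rnorm(30, sd = 1e-8), 3)
  ee <- module_eigengene(xx, c("a", "b", "c"))
  expect_equal(abs(cor(ee, 1:10)), 1, tolerance = 1e-6)
})

test_that("k-means refinement corrects a planted misassignment and is idempotent", {
  x <- block_expr(n_blocks = 2, size = 40, n_noise = 0, n_samp = 20,
                  r = 0.9, seed = 5)
  truth <- rep(c("mod1", "mod2"), each = 40)
  names(truth) <- rownames(x)
  # mislabel five genes from block A as B
  wrong <- truth
  wrong[1:5] <- "mod2"
  ms <- kmeans_refine(x, wrong, min_module_size = 10)
  expect_equal(unname(ms$assignment[1:5]), rep("mod1", 5))
  # already-converged input is a fixed point
  ms2 <- kmeans_refine(x, ms$assignment, min_module_size = 10)
  expect_identical(ms2$assignment, ms$assignment)
})

test_that("cross-sex Fisher overlap is symmetric and matches enumeration", {
  mk_ms <- function(assignment, sex) {
    structure(list(assignment = assignment, eigengenes = list(), sex = sex),
              class = "ModuleSet")
  }
  genes <- sprintf("g%02d", 1:60)
  am <- setNames(rep(c("mod1", "mod2", "grey"), each = 20), genes)
  af <- setNames(rep(c("modA", "grey", "modB"), each = 20), genes)
  res <- dcoexp_fisher(mk_ms(am, "M"), mk_ms(af, "F"), genes)
  # overlap p equals hypergeometric enumeration on the both-assigned universe
  universe <- intersect(names(am)[am != "grey"], names(af)[af != "grey"])
  A <- intersect(names(am)[am == "mod1"], universe)
  B <- intersect(names(af)[af == "modA"], universe)
  k <- length(intersect(A, B))
  p_exp <- hyper_enum(k, length(B), length(A), length(universe))
  expect_equal(res$fisher_p[res$module == "mod1" & res$sex == "M"], p_exp,
               tolerance = 1e-12)
  # swapping sexes swaps the table
  res_sw <- dcoexp_fisher(mk_ms(af, "M"), mk_ms(am, "F"), genes)
  expect_equal(sort(res$fisher_p), sort(res_sw$fisher_p))
  # identical module structure in both sexes: nothing is specific
  res_id <- dcoexp_fisher(mk_ms(am, "M"), mk_ms(am, "F"), genes)
  expect_false(any(res_id$specific))
  expect_error(dcoexp_fisher(mk_ms(am, "M"), mk_ms(af, "F"), genes[1:10]),
               "background")
})

test_that("a planted sex-specific block is flagged as differentially co-expressed", {
  sim <- sim_small(seed = 12, n_genes = 600, dmr_count = 0)
  de <- run_de_stage(sim$counts, sim$metadata)
  lf <- log2(de$fpkm[de$kept_genes, , drop = FALSE] + 1)
  sexes <- sexes_of(sim, colnames(lf))
  mm <- build_modules(lf, sexes, "M")
  mf <- build_modules(lf, sexes, "F")
  bg <- intersect(names(mm$assignment), names(mf$assignment))
  dco <- dcoexp_fisher(mm, mf, bg)
  tr <- sim$truth$modules
  match_mod <- function(ms, mi) {
    g <- intersect(tr$gene_id[tr$module == mi], names(ms$assignment))
    tab <- table(ms$assignment[g]); tab <- tab[names(tab) != "grey"]
    names(which.max(tab))
  }
  m_spec <- match_mod(mm, 1)   # male-specific planted block
  expect_true(dco$specific[dco$sex == "M" & dco$module == m_spec])
  # a shared planted block has a counterpart
  m_shared <- match_mod(mm, 3)
  expect_false(dco$specific[dco$sex == "M" & dco$module == m_shared])
})

test_that("eigengene-trait correlation is exact in degenerate directions", {
  e <- rnorm(6)
  names(e) <- sprintf("M%02d", 1:6)
  ms <- structure(list(assignment = c(a = "mod1", b = "mod1"),
                       eigengenes = list(mod1 = e), sex = "M"),
                  class = "ModuleSet")
  md <- data.frame(sample_id = names(e), sex = "M", age_days = 28,
                   tr_same = e - min(e), tr_opp = max(e) - e,
                   tr_flat = 5)
  out <- module_trait_correlation(ms, md, c("tr_same", "tr_opp", "tr_flat"))
  expect_equal(out$pearson_r[out$trait == "tr_same"], 1, tolerance = 1e-10)
  expect_equal(out$pearson_r[out$trait == "tr_opp"], -1, tolerance = 1e-10)
  expect_true(is.na(out$pearson_r[out$trait == "tr_flat"]))
})

test_that("independent traits rarely reach |r| near 1 at n = 6", {
  set.seed(66)
  hits <- replicate(200, {
    e <- rnorm(6); names(e) <- sprintf("M%02d", 1:6)
    ms <- structure(list(assignment = c(a = "mod1", b = "mod1"),
                         eigengenes = list(mod1 = e), sex = "M"),
                    class = "ModuleSet")
    md <- data.frame(sample_id = names(e), sex = "M", age_days = 28,
                     tr = abs(rnorm(6, 5)))
    abs(module_trait_correlation(ms, md, "tr")$pearson_r)
  })
  expect_gte(mean(hits < 0.81), 0.9)
})
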