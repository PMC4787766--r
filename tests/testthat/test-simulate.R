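test_that("the generated design matches the five-condition study layout", {
  d <- generate_design()
  expect_equal(nrow(d), 75)
  groups <- dplyr::distinct(d, condition, time_min)
  expect_equal(nrow(groups), 25)
  expect_true(all(table(d$condition, d$time_min)[
    cbind(groups$condition, as.character(groups$time_min))] == 3))
  expect_equal(sum(d$condition == "A66_noEGF"), 3)
  expect_true(all(d$time_min[d$condition == "A66_noEGF"] == 300))

  expect_equal(nrow(generate_design(replicates = 1)), 25)
  expect_equal(nrow(generate_design(conditions = "WT")), 18)
})

test_that("the generator is deterministic under a fixed seed", {
  cfg <- generator_config(n_genes = 100, seed = 11)
  a <- generate_dataset(cfg)
  b <- generate_dataset(cfg)
  expect_identical(a$dataset$counts, b$dataset$counts)
  expect_identical(a$truth$profile, b$truth$profile)
  expect_identical(a$sites$N, b$sites$N)
  c <- generate_dataset(generator_config(n_genes = 100, seed = 12))
  expect_false(identical(a$dataset$counts, c$dataset$counts))
})

test_that("counts follow the negative-binomial law of the planted means", {
  # standardized residuals (count - mu) / sqrt(mu + alpha mu^2) across all
  # gene/sample cells must have mean ~0 and variance ~1
  cfg <- generator_config(n_genes = 2000, seed = 4)
  sim <- generate_dataset(cfg)
  tr <- sim$truth
  ds <- sim$dataset
  gid <- sprintf("%s_t%03d", ds$samples$condition, ds$samples$time_min)
  q <- tr$baseline_mean * 2^tr$profile[, gid]
  mu <- sweep(q, 2, tr$library_sizes / colSums(q), `*`)
  alpha <- cfg$dispersion_a / mu + cfg$dispersion_b
  z <- (ds$counts - mu) / sqrt(mu + alpha * mu^2)
  expect_lt(abs(mean(z)), 0.01)
  expect_lt(abs(var(as.vector(z)) - 1), 0.05)
})

test_that("null-category cells match NB moments at their planted mean", {
  # Monte-Carlo moment check at fixed mu: pick cells with planted mean near
  # 100 and compare their standardized mean and variance to mu + alpha mu^2
  cfg <- generator_config(n_genes = 5000, seed = 9, library_size_cv = 0.02)
  sim <- generate_dataset(cfg)
  tr <- sim$truth
  ds <- sim$dataset
  gid <- sprintf("%s_t%03d", ds$samples$condition, ds$samples$time_min)
  q <- tr$baseline_mean * 2^tr$profile[, gid]
  mu <- sweep(q, 2, tr$library_sizes / colSums(q), `*`)
  sel <- abs(mu - 100) < 5
  expect_gt(sum(sel), 5000)
  ratio <- ds$counts[sel] / mu[sel]
  expect_lt(abs(mean(ratio) - 1), 0.03)
  alpha_bar <- mean(cfg$dispersion_a / mu[sel] + cfg$dispersion_b)
  v_expected <- mean(1 / mu[sel]) + alpha_bar
  expect_lt(abs(var(ratio) / v_expected - 1), 0.10)
})

test_that("planted categories partition the genes and counts are valid", {
  sim <- generate_dataset(generator_config(n_genes = 500, seed = 2))
  cats <- sim$truth$categories
  expect_setequal(cats$gene_id, rownames(sim$dataset$counts))
  expect_false(anyDuplicated(cats$gene_id) > 0)
  expect_true(all(sim$dataset$counts >= 0))
  expect_true(all(sim$dataset$counts == round(sim$dataset$counts)))
  # fractions are respected up to rounding
  frac <- table(cats$category)["null"] / nrow(cats)
  expect_lt(abs(frac - 0.50), 0.01)
})

test_that("library sizes vary with approximately the configured CV", {
  cvs <- vapply(1:20, function(s) {
    sim <- generate_dataset(generator_config(n_genes = 150, seed = s))
    lib <- colSums(sim$dataset$counts)
    sd(lib) / mean(lib)
  }, numeric(1))
  expect_lt(abs(mean(cvs) - 0.1) / 0.1, 0.30)
})

test_that("coherent planted profiles obey the PIP3 direction logic exactly", {
  sim <- generate_dataset(generator_config(n_genes = 800, seed = 6))
  tr <- sim$truth
  prof <- tr$profile_category
  groups <- tr$groups
  up <- tr$categories$gene_id[tr$categories$category == "coherent_up"]
  expect_gt(length(up), 0)
  wt <- groups$group_id[groups$condition == "WT"]
  pten <- groups$group_id[groups$condition == "PTEN_KO"]
  pik <- groups$group_id[groups$condition == "PIK3CA_H1047R"]
  a66 <- groups$group_id[groups$condition == "A66"]
  for (g in up) {
    expect_true(all(prof[g, pten] > prof[g, wt]))
    expect_true(all(prof[g, pik] > prof[g, wt]))
    expect_true(all(prof[g, a66] < prof[g, wt]))
  }
  down <- tr$categories$gene_id[tr$categories$category == "coherent_down"]
  for (g in down) {
    expect_true(all(prof[g, pten] < prof[g, wt]))
    expect_true(all(prof[g, a66] > prof[g, wt]))
  }
})

test_that("invalid generator configurations are rejected", {
  expect_error(generator_config(category_fractions = c(null = 0.5)),
               "missing")
  bad <- c(null = 0.6, chronic_pten = 0.2, chronic_pik3ca = 0.1,
           chronic_both = 0.05, egf_early_peak = 0.04, egf_late_peak = 0.03,
           pi3k_basal = 0.02, pi3k_induced = 0.01, coherent_up = 0.01,
           coherent_down = 0.01)  # sums to 1.06
  expect_error(generator_config(category_fractions = bad), "sum to 1")
  expect_error(generator_config(n_genes = -5), "positive")
  expect_error(generator_config(n_motifs = 3, n_active_motifs = 4),
               "n_active_motifs")
})

test_that("annotation enrichment behaves as configured", {
  sim <- generate_dataset(generator_config(n_genes = 2000, seed = 3))
  tr <- sim$truth

  # fixed seed reproduces the annotation exactly
  a1 <- generate_annotation(tr, seed = 5)
  a2 <- generate_annotation(tr, seed = 5)
  expect_identical(a1, a2)

  genes <- tr$categories$gene_id
  cat_genes <- genes[tr$categories$category == "chronic_pten"]
  # strong enrichment: designated term recovered at p < 1e-4 nearly always
  hits <- vapply(1:100, function(s) {
    ann <- generate_annotation(tr, enrichment_odds = 20, seed = s)
    memb <- unique(ann$gene_id[ann$term == "term_chronic_pten"])
    o <- length(intersect(memb, cat_genes))
    p <- phyper(o - 1, length(memb), length(genes) - length(memb),
                length(cat_genes), lower.tail = FALSE)
    p < 1e-4
  }, logical(1))
  expect_gte(mean(hits), 0.95)

  # no enrichment: designated-term Fisher p is approximately uniform
  p0 <- vapply(1:60, function(s) {
    ann <- generate_annotation(tr, enrichment_odds = 1, seed = 1000 + s)
    memb <- unique(ann$gene_id[ann$term == "term_chronic_pten"])
    o <- length(intersect(memb, cat_genes))
    phyper(o - 1, length(memb), length(genes) - length(memb),
           length(cat_genes), lower.tail = FALSE)
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(p0, "punif")$p.value), 0.01)
})
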