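test_that("KS statistic and p-value match their definitions", {
  x <- c(1, 2, 3)
  expect_equal(ks_two_sample(x, x)$statistic, 0)
  expect_equal(ks_two_sample(c(1, 2, 3), c(4, 5, 6))$statistic, 1)
  expect_error(ks_two_sample(numeric(0), 1), "non-empty")

  withr::with_seed(41, {
    for (i in 1:30) {
      x <- round(rnorm(sample(5:30, 1)), sample(0:2, 1))
      y <- round(rnorm(sample(5:30, 1), mean = runif(1, 0, 1)),
                 sample(0:2, 1))
      res <- ks_two_sample(x, y)
      expect_equal(res$statistic, oracle_d(x, y), tolerance = 1e-12)
      if (!anyDuplicated(c(x, y))) {
        expect_lt(abs(res$p_value -
                        oracle_ks_p(res$statistic, length(x), length(y))),
                  1e-6)
      }
    }
  })
})

test_that("Mann-Whitney U counts pairwise wins with half-ties", {
  expect_equal(mann_whitney_u(c(3, 4), c(1, 2))$statistic, 4)
  expect_equal(mann_whitney_u(c(1, 2), c(3, 4))$statistic, 0)
  expect_error(mann_whitney_u(1, numeric(0)), "non-empty")

  withr::with_seed(42, {
    for (i in 1:30) {
      x <- sample(1:8, sample(4:20, 1), replace = TRUE)
      y <- sample(1:8, sample(4:20, 1), replace = TRUE)
      u <- mann_whitney_u(x, y)
      expect_equal(u$statistic, oracle_u(x, y))
      # complementarity of the two one-sided statistics
      expect_equal(u$statistic + mann_whitney_u(y, x)$statistic,
                   length(x) * length(y))
      expect_equal(u$p_value, oracle_mw_p(x, y), tolerance = 1e-8)
    }
  })
})

test_that("rank statistics are invariant under monotone transforms", {
  withr::with_seed(43, {
    x <- rnorm(15)
    y <- rnorm(20, 0.5)
    f <- function(v) exp(2 * v) - 1
    expect_equal(ks_two_sample(x, y)$statistic,
                 ks_two_sample(f(x), f(y))$statistic)
    expect_equal(mann_whitney_u(x, y)$statistic,
                 mann_whitney_u(f(x), f(y))$statistic)
  })
})

test_that("hypergeometric enrichment reproduces closed-form probabilities", {
  ann <- tibble::tibble(gene_id = paste0("g", 1:5), term = "T")
  uni <- paste0("g", 1:20)
  res <- fisher_enrichment(paste0("g", 1:10), uni, ann)
  expect_equal(res$p_value, choose(15, 5) / choose(20, 10),
               tolerance = 1e-10)
  expect_equal(res$overlap, 5)

  # overlap at expectation is unremarkable
  ann2 <- tibble::tibble(gene_id = paste0("g", 1:10), term = "T")
  uni2 <- paste0("g", 1:100)
  res2 <- fisher_enrichment(paste0("g", seq(1, 100, by = 2)), uni2, ann2)
  expect_gte(res2$p_value, 0.4)

  # random annotations match the independent lchoose oracle
  withr::with_seed(44, {
    for (i in 1:20) {
      uni <- sprintf("g%03d", 1:80)
      ann <- tibble::tibble(
        gene_id = sample(uni, 60, replace = TRUE),
        term = sample(c("a", "b", "c"), 60, replace = TRUE)
      )
      gs <- sample(uni, 25)
      res <- fisher_enrichment(gs, uni, ann)
      for (j in seq_len(nrow(res))) {
        expect_equal(
          res$p_value[j],
          oracle_hyper_p(res$overlap[j], res$term_size[j], 80, 25),
          tolerance = 1e-10
        )
      }
    }
  })

  # completeness: upper tail at o plus lower tail at o-1 is exactly 1
  expect_equal(
    oracle_hyper_p(4, 10, 50, 20) + phyper(3, 10, 40, 20),
    1, tolerance = 1e-12
  )
  expect_error(fisher_enrichment("zz", uni2, ann2), "universe")
})

test_that("sample correlation matrices behave like correlation matrices", {
  withr::with_seed(45, {
    m <- matrix(rnorm(200), 20)
    colnames(m) <- paste0("s", 1:10)
    cm <- sample_correlation_matrix(m)
    expect_equal(cm, t(cm))
    expect_equal(unname(diag(cm)), rep(1, 10))
    expect_true(min(eigen(cm, symmetric = TRUE)$values) > -1e-10)

    m2 <- cbind(m, dup = m[, 1], neg = -m[, 1])
    cm2 <- sample_correlation_matrix(m2)
    expect_equal(unname(cm2["s1", "dup"]), 1)
    expect_equal(unname(cm2["s1", "neg"]), -1)

    # textbook formula on one pair
    r_manual <- sum(scale(m[, 1]) * scale(m[, 2])) / (nrow(m) - 1)
    expect_equal(unname(cm["s1", "s2"]), r_manual, tolerance = 1e-12)

    m3 <- cbind(m, const = rep(2, 20))
    expect_warning(cm3 <- sample_correlation_matrix(m3), "zero-variance")
    expect_true(is.na(cm3["const", "s1"]))
  })
})

test_that("PCA variance fractions are conserved and ranked", {
  withr::with_seed(46, {
    m <- matrix(rnorm(300), 30)
    colnames(m) <- paste0("s", 1:10)
    p <- pca_samples(m)
    expect_equal(sum(p$variance_fraction), 1, tolerance = 1e-10)
    expect_true(all(diff(p$variance_fraction) <= 1e-12))

    rank1 <- outer(rnorm(30), rnorm(10))
    colnames(rank1) <- paste0("s", 1:10)
    p1 <- pca_samples(rank1)
    expect_equal(p1$variance_fraction[1], 1, tolerance = 1e-10)
  })
})

test_that("replicates cluster and conditions separate in PCA", {
  sim <- generate_dataset(generator_config(n_genes = 400, seed = 47))
  lognorm <- log(normalize_counts(sim$dataset, "sizefactor") + 1)
  p <- pca_samples(lognorm, sim$dataset$samples)
  co <- tidy(p)
  co$group <- paste(co$condition, co$time_min)
  centroid <- stats::aggregate(cbind(PC1, PC2) ~ group, co, mean)
  within_var <- mean(unlist(lapply(split(co, co$group), function(g) {
    mean((g$PC1 - mean(g$PC1))^2 + (g$PC2 - mean(g$PC2))^2)
  })))
  between_var <- mean(centroid$PC1^2 + centroid$PC2^2) -
    mean(centroid$PC1)^2 - mean(centroid$PC2)^2
  expect_gt(between_var / within_var, 5)
})

test_that("score-distribution comparisons test matched motif targets", {
  fx_scores <- tibble::tibble(
    gene_id = rep(sprintf("g%02d", 1:20), 2),
    motif = rep(c("m1", "m2"), each = 20),
    s_m = c(1:20, rep(5, 20))
  )
  model <- structure(list(z = tibble::tibble(motif = c("m1", "m2"),
                                             z = c(5, 5))),
                     class = "pip3_motif_model")
  a <- sprintf("g%02d", 1:10)
  b <- sprintf("g%02d", 11:20)
  cmp <- compare_sm_distributions(fx_scores, a, b, model)
  expect_true(all(cmp$tested))
  expect_equal(cmp$motif[1], "m1")       # sorted by descending D
  expect_equal(cmp$ks_d[cmp$motif == "m1"], 1)
  expect_equal(cmp$ks_d[cmp$motif == "m2"], 0)

  # identical sets give D = 0 and MW p near 1
  expect_warning(same <- compare_sm_distributions(fx_scores, a, a, model),
                 "overlap")
  expect_true(all(same$ks_d == 0))
  expect_true(all(same$mw_p > 0.99))

  # too few targets are skipped with a note
  expect_warning(cmp2 <- compare_sm_distributions(fx_scores, a[1:3], b,
                                                  model),
                 "enough targets")
  expect_false(any(cmp2$tested))
})
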