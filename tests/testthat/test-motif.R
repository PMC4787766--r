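# small fitted model shared across blocks
motif_fixture <- function(seed = 13, n_prom = 40, n_motif = 3,
                          n_samp = 8, lambda = 1) {
  withr::with_seed(seed, {
    N <- matrix(rpois(n_prom * n_motif, 0.8), n_prom, n_motif,
                dimnames = list(sprintf("p%02d", 1:n_prom),
                                sprintf("m%d", 1:n_motif)))
    map <- tibble::tibble(promoter_id = rownames(N),
                          gene_id = sprintf("g%02d", 1:n_prom))
    sites <- motif_sites(N, map)
    A_true <- matrix(rnorm(n_motif * n_samp, sd = 0.5), n_motif, n_samp)
    E <- sweep(N, 2, colMeans(N)) %*% A_true +
      matrix(rnorm(n_prom * n_samp, sd = 0.1), n_prom)
    E <- E - rowMeans(E)
    E <- sweep(E, 2, colMeans(E))
    colnames(E) <- paste0("s", 1:n_samp)
    list(E = E, sites = sites,
         model = fit_motif_activities(E, sites, lambda = lambda))
  })
}

test_that("constant site columns have identically zero activity", {
  N <- matrix(2L, 10, 1, dimnames = list(paste0("p", 1:10), "m1"))
  sites <- motif_sites(N, tibble::tibble(promoter_id = rownames(N),
                                         gene_id = paste0("g", 1:10)))
  withr::with_seed(1, E <- matrix(rnorm(40), 10, 4,
                                  dimnames = list(rownames(N), NULL)))
  model <- fit_motif_activities(E, sites, lambda = 1)
  expect_equal(unname(model$activities), matrix(0, 1, 4))
})

test_that("the fit equals the closed-form ridge solution", {
  fx <- motif_fixture(n_prom = 6, n_motif = 2, n_samp = 3)
  Nc <- sweep(fx$sites$N, 2, colMeans(fx$sites$N))
  A_direct <- solve(crossprod(Nc) + diag(1, 2), crossprod(Nc, fx$E))
  A_direct <- A_direct - rowMeans(A_direct)
  expect_equal(unname(fx$model$activities), unname(A_direct),
               tolerance = 1e-10)
})

test_that("the ridge solution satisfies its normal equations", {
  fx <- motif_fixture()
  Nc <- fx$model$N_centered
  lam <- fx$model$lambda
  A_raw <- solve(crossprod(Nc) + diag(lam, ncol(Nc)), crossprod(Nc, fx$E))
  resid_norm <- max(abs((crossprod(Nc) + diag(lam, ncol(Nc))) %*% A_raw -
                          crossprod(Nc, fx$E)))
  expect_lt(resid_norm, 1e-8)
})

test_that("activities shrink monotonically to zero as lambda grows", {
  fx <- motif_fixture()
  norms <- vapply(10^seq(-2, 6, by = 1), function(lam) {
    m <- fit_motif_activities(fx$E, fx$sites, lambda = lam)
    sqrt(sum(m$activities^2))
  }, numeric(1))
  expect_true(all(diff(norms) <= 1e-10))
  expect_lt(norms[length(norms)], 1e-3)
  expect_error(fit_motif_activities(fx$E, fx$sites, lambda = -1), "lambda")
})

test_that("z-values are invariant to rescaling the expression matrix", {
  fx <- motif_fixture()
  m2 <- fit_motif_activities(fx$E * 7.3, fx$sites,
                             lambda = fx$model$lambda)
  expect_equal(m2$z$z, fx$model$z$z, tolerance = 1e-8)
})

test_that("activities are centered across samples per motif", {
  fx <- motif_fixture()
  expect_true(all(abs(rowMeans(fx$model$activities)) < 1e-12))
})

test_that("target scores measure the misfit increase of site removal", {
  fx <- motif_fixture()
  sc <- target_scores(fx$model)
  # only promoter/motif pairs with sites are scored, all non-negative
  N <- fx$sites$N
  expect_true(all(sc$s_pm >= 0))
  expect_true(all(N[cbind(sc$promoter_id, sc$motif)] > 0))

  # hand recomputation for one pair
  i <- which.max(sc$s_pm)
  p <- sc$promoter_id[i]
  m <- sc$motif[i]
  r <- fx$model$residuals[p, ]
  manual <- (sum((r + N[p, m] * fx$model$activities[m, ])^2) - sum(r^2)) /
    fx$model$residual_variance
  expect_equal(sc$s_pm[i], max(manual, 0), tolerance = 1e-10)

  # removing the sites from the input and refitting zeroes the score
  N2 <- N
  N2[p, m] <- 0L
  sites2 <- motif_sites(N2, fx$sites$promoter_map)
  m2 <- fit_motif_activities(fx$E, sites2, lambda = fx$model$lambda)
  sc2 <- target_scores(m2)
  expect_false(any(sc2$promoter_id == p & sc2$motif == m))
})

test_that("gene scores take the maximum across promoters", {
  sc <- structure(
    tibble::tibble(
      promoter_id = c("p1", "p2", "p3"),
      gene_id = c("g1", "g1", "g2"),
      motif = "m1",
      s_pm = c(5, 12, 7)
    ),
    class = c("pip3_target_scores", "tbl_df", "tbl", "data.frame")
  )
  sm <- dedup_to_genes(sc)
  expect_equal(sm$s_m[sm$gene_id == "g1"], 12)
  expect_equal(sm$s_m[sm$gene_id == "g2"], 7)

  # random multi-promoter instance equals a group-wise max oracle
  withr::with_seed(23, {
    n <- 60
    tab <- tibble::tibble(
      promoter_id = sprintf("p%02d", 1:n),
      gene_id = sprintf("g%02d", sample(1:20, n, replace = TRUE)),
      motif = sample(c("m1", "m2"), n, replace = TRUE),
      s_pm = runif(n, 0, 30)
    )
    sm2 <- dedup_to_genes(tab)
    agg <- aggregate(s_pm ~ gene_id + motif, tab, max)
    merged <- merge(sm2, agg, by.x = c("gene_id", "motif"),
                    by.y = c("gene_id", "motif"))
    expect_equal(merged$s_m, merged$s_pm)
  })

  sc$gene_id[1] <- NA
  expect_error(dedup_to_genes(sc), "no gene mapping")
})

test_that("the strong-target table applies both filters strictly", {
  fx <- motif_fixture()
  sm <- dedup_to_genes(target_scores(fx$model))

  # z filter: with an impossible threshold the table is empty
  expect_equal(nrow(strongly_regulated(sm, fx$model, z_threshold = 1e6)), 0)

  # s threshold is a strict inequality
  sm_edge <- tibble::tibble(gene_id = c("g1", "g2", "g3"),
                            motif = fx$model$z$motif[1],
                            s_m = c(19.99, 20, 20.01))
  out <- strongly_regulated(sm_edge, fx$model, s_threshold = 20,
                            z_threshold = 0)
  expect_equal(out$gene_id, "g3")

  # every reported pair passes both filters
  out2 <- strongly_regulated(sm, fx$model, s_threshold = 1, z_threshold = 1)
  keep <- fx$model$z$motif[fx$model$z$z >= 1]
  expect_true(all(out2$motif %in% keep))
  expect_true(all(out2$s_m > 1))

  # set annotation labels memberships
  gs <- gene_set_collection(list(top = out2$gene_id[1]),
                            universe = unique(sm$gene_id))
  out3 <- strongly_regulated(sm, fx$model, gene_sets = gs,
                             s_threshold = 1, z_threshold = 1)
  expect_equal(out3$sets[out3$gene_id == out2$gene_id[1]][1], "top")
})

test_that("promoter expression maps genes onto promoters and centers", {
  sim <- generate_dataset(generator_config(n_genes = 60, seed = 8))
  E <- promoter_expression(sim$dataset, sim$sites)
  expect_equal(nrow(E), nrow(sim$sites$N))
  expect_true(all(abs(colMeans(E)) < 1e-10))
  raw <- attr(E, "raw")
  # promoters of the same gene carry identical raw expression
  map <- sim$sites$promoter_map
  multi <- names(which(table(map$gene_id) > 1))[1]
  if (!is.na(multi)) {
    ps <- map$promoter_id[map$gene_id == multi]
    expect_equal(raw[ps[1], ], raw[ps[2], ])
  }
})
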