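#' Promoter-level expression matrix for motif activity inference
#'
#' Builds the response matrix of the motif activity model: log of
#' size-factor-normalized counts plus a pseudocount, with each gene's value
#' assigned to each of its promoters, then row- and column-centered.
#'
#' @param ds A `pip3_dataset`.
#' @param sites A `pip3_motif_sites` object.
#' @param size_factors Optional precomputed size factors.
#' @param pseudocount Added before taking logs.
#' @return Promoters x samples matrix (centered), with attribute
#'   `"raw"` holding the uncentered log expression.
#' @export
promoter_expression <- function(ds, sites, size_factors = NULL,
                                pseudocount = 1) {
  stopifnot(inherits(ds, "pip3_dataset"), inherits(sites, "pip3_motif_sites"))
  norm <- normalize_counts(ds, "sizefactor", size_factors = size_factors)
  gidx <- match(sites$promoter_map$gene_id, rownames(norm))
  if (anyNA(gidx)) {
    abort(paste0("promoter(s) mapping to unknown gene(s): ",
                 paste(head(sites$promoter_map$promoter_id[is.na(gidx)], 5),
                       collapse = ", ")))
  }
  raw <- log(norm[gidx, , drop = FALSE] + pseudocount)
  rownames(raw) <- sites$promoter_map$promoter_id
  E <- raw - rowMeans(raw)
  E <- sweep(E, 2, colMeans(E))
  attr(E, "raw") <- raw
  E
}

#' Fit motif activities by ridge regression
#'
#' Models centered promoter expression as a linear combination of the
#' promoters' motif site counts with unknown sample-specific motif
#' activities: for each sample `s`, `A[, s] = solve(t(Nc) Nc + lambda I,
#' t(Nc) E[, s])` where `Nc` is the column-centered site matrix.  Activities
#' are centered across samples per motif.  Activity standard errors come
#' from the ridge covariance `sigma_s^2 * (Nc'Nc + lI)^-1 Nc'Nc
#' (Nc'Nc + lI)^-1`, and each motif's significance is summarized as
#' `z_m = sqrt(mean_s (A_ms / se_ms)^2)`.
#'
#' @param E Promoters x samples centered expression (see
#'   [promoter_expression()]).
#' @param sites A `pip3_motif_sites` aligned to the rows of `E`.
#' @param lambda Positive ridge penalty, or `"cv"` to minimize held-out
#'   squared error by 5-fold promoter-wise cross-validation over a
#'   logarithmic grid.
#' @param cv_seed Seed of the cross-validation fold assignment.
#' @return A `pip3_motif_model` with elements `activities` (motifs x
#'   samples), `se`, `z` (tibble `motif`, `z`), `lambda`, `fitted`,
#'   `residuals`, `residual_variance` and the site matrix used.
#' @export
fit_motif_activities <- function(E, sites, lambda = "cv", cv_seed = 1) {
  stopifnot(inherits(sites, "pip3_motif_sites"))
  N <- sites$N[rownames(E), , drop = FALSE]
  Nc <- sweep(N, 2, colMeans(N))
  if (identical(lambda, "cv")) {
    lambda <- ridge_cv_lambda(Nc, E, seed = cv_seed)
  }
  if (!is.numeric(lambda) || lambda <= 0) {
    abort("lambda must be a positive number or \"cv\"")
  }
  fit <- ridge_solve(Nc, E, lambda)
  A <- fit$A - rowMeans(fit$A)
  fitted <- Nc %*% A
  resid <- E - fitted
  # per-sample residual variance, residual df = promoters - motifs
  dfr <- max(nrow(E) - ncol(N), 1)
  s2 <- colSums(resid^2) / dfr
  se <- sqrt(pmax(outer(fit$cov_diag, s2), 1e-300))
  z <- sqrt(rowMeans((A / se)^2))
  structure(
    list(activities = A, se = se,
         z = tibble(motif = colnames(N), z = unname(z)),
         lambda = lambda, sites = sites, N_centered = Nc,
         fitted = fitted, residuals = resid,
         residual_variance = mean(resid^2),
         sample_residual_variance = s2),
    class = "pip3_motif_model"
  )
}

ridge_solve <- function(Nc, E, lambda) {
  M <- crossprod(Nc) + diag(lambda, ncol(Nc))
  Mi <- solve(M)
  A <- Mi %*% crossprod(Nc, E)
  rownames(A) <- colnames(Nc)
  # sandwich covariance factor (unit residual variance)
  cov_diag <- diag(Mi %*% crossprod(Nc) %*% Mi)
  list(A = A, cov_diag = pmax(cov_diag, 0))
}

ridge_cv_lambda <- function(Nc, E, grid = 10^seq(-2, 3, length.out = 11),
                            n_folds = 5, seed = 1) {
  P <- nrow(Nc)
  folds <- withr::with_seed(seed, sample(rep_len(seq_len(n_folds), P)))
  err <- vapply(grid, function(lam) {
    tot <- 0
    for (f in seq_len(n_folds)) {
      tr <- folds != f
      M <- crossprod(Nc[tr, , drop = FALSE]) + diag(lam, ncol(Nc))
      A <- solve(M, crossprod(Nc[tr, , drop = FALSE], E[tr, , drop = FALSE]))
      pred <- Nc[!tr, , drop = FALSE] %*% A
      tot <- tot + sum((E[!tr, , drop = FALSE] - pred)^2)
    }
    tot
  }, numeric(1))
  grid[which.min(err)]
}

#' @export
print.pip3_motif_model <- function(x, ...) {
  cat(sprintf(
    "<pip3_motif_model> %d motifs x %d samples, lambda = %.4g, %d motifs with z >= 2\n",
    nrow(x$activities), ncol(x$activities), x$lambda, sum(x$z$z >= 2)))
  invisible(x)
}

#' @rdname fit_motif_activities
#' @param x A `pip3_motif_model`.
#' @param ... Unused.
#' @method tidy pip3_motif_model
#' @export
tidy.pip3_motif_model <- function(x, ...) {
  A <- x$activities
  out <- as_tibble(as.data.frame(A, check.names = FALSE))
  out$motif <- rownames(A)
  out <- tidyr::pivot_longer(out, -"motif", names_to = "sample_id",
                             values_to = "activity")
  se <- as.vector(t(x$se))
  mutate(out, se = se)
}

#' @rdname fit_motif_activities
#' @method glance pip3_motif_model
#' @export
glance.pip3_motif_model <- function(x, ...) {
  tibble(
    n_motifs = nrow(x$activities), n_samples = ncol(x$activities),
    n_promoters = nrow(x$N_centered), lambda = x$lambda,
    residual_variance = x$residual_variance,
    n_significant = sum(x$z$z >= 2)
  )
}

#' Activity profiles of the most significant motifs
#'
#' @param object A `pip3_motif_model`.
#' @param samples Optional sample sheet (`sample_id`, `condition`,
#'   `time_min`) used to draw profiles over time by condition.
#' @param n_motifs Number of top motifs by z to show.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot pip3_motif_model
#' @export
autoplot.pip3_motif_model <- function(object, samples = NULL, n_motifs = 6,
                                      ...) {
  top <- head(arrange(object$z, desc(.data$z)), n_motifs)$motif
  d <- filter(tidy(object), .data$motif %in% top)
  if (!is.null(samples)) {
    d <- left_join(d, samples, by = "sample_id")
    p <- ggplot2::ggplot(d, ggplot2::aes(.data$time_min, .data$activity,
                                         colour = .data$condition)) +
      ggplot2::stat_summary(fun = mean, geom = "line") +
      ggplot2::labs(x = "time (min)", y = "motif activity")
  } else {
    p <- ggplot2::ggplot(d, ggplot2::aes(.data$sample_id, .data$activity,
                                         group = 1)) +
      ggplot2::geom_line() +
      ggplot2::theme(axis.text.x = ggplot2::element_blank())
  }
  p + ggplot2::facet_wrap(~motif) + ggplot2::theme_minimal()
}

#' Per-promoter motif target scores
#'
#' Scores how strongly motif `m` regulates the gene behind promoter `p` as
#' the increase in residual sum of squares when the motif's sites are
#' removed from that promoter with activities held fixed, scaled by the
#' model's residual variance so scores are dimensionless:
#' `S_pm = (RSS_without - RSS_with) / residual_variance`, clipped at zero.
#' Only promoter/motif pairs with at least one binding site are scored
#' (pairs without sites have `S_pm = 0` identically).
#'
#' @param model A `pip3_motif_model`.
#' @return A `pip3_target_scores` tibble with columns `promoter_id`,
#'   `gene_id`, `motif`, `s_pm`.
#' @export
target_scores <- function(model) {
  stopifnot(inherits(model, "pip3_motif_model"))
  N <- model$sites$N
  A <- model$activities
  R <- model$residuals
  s2 <- model$residual_variance
  hits <- which(N > 0, arr.ind = TRUE)
  s_pm <- vapply(seq_len(nrow(hits)), function(i) {
    p <- hits[i, 1]
    m <- hits[i, 2]
    rp <- R[p, ]
    # removing the sites changes the prediction of promoter p by -N_pm * A_m
    sum((rp + N[p, m] * A[m, ])^2) - sum(rp^2)
  }, numeric(1))
  out <- tibble(
    promoter_id = rownames(N)[hits[, 1]],
    motif = colnames(N)[hits[, 2]],
    s_pm = pmax(s_pm / s2, 0)
  )
  out <- left_join(out, model$sites$promoter_map, by = "promoter_id")
  out <- select(out, "promoter_id", "gene_id", "motif", "s_pm")
  structure(arrange(out, .data$motif, desc(.data$s_pm)),
            class = c("pip3_target_scores", class(out)))
}

#' Collapse promoter scores to gene scores
#'
#' A gene with several promoters receives the maximum of its promoters'
#' scores, giving one score `S_m` per (gene, motif) pair.
#'
#' @param scores A `pip3_target_scores` tibble from [target_scores()].
#' @return Tibble with columns `gene_id`, `motif`, `s_m`.
#' @export
dedup_to_genes <- function(scores) {
  if (anyNA(scores$gene_id)) {
    abort(paste0("promoter(s) with no gene mapping: ",
                 paste(head(scores$promoter_id[is.na(scores$gene_id)], 5),
                       collapse = ", ")))
  }
  out <- summarise(group_by(scores, .data$gene_id, .data$motif),
                   s_m = max(.data$s_pm), .groups = "drop")
  arrange(out, .data$motif, desc(.data$s_m))
}

#' Most strongly regulated genes
#'
#' The analogue of a strongest-targets table: (motif, gene) pairs for
#' motifs whose activity significance passes `z_threshold` and genes whose
#' score strictly exceeds `s_threshold`, annotated with their gene-set
#' memberships.  Because the score scale depends on the data scale, the
#' absolute default threshold of 20 can be replaced by a quantile via
#' `s_quantile`.
#'
#' @param gene_scores Tibble from [dedup_to_genes()].
#' @param model The fitted `pip3_motif_model`.
#' @param gene_sets Optional [gene_set_collection()] used to annotate rows
#'   with comma-separated set labels.
#' @param s_threshold Keep genes with `s_m > s_threshold`.
#' @param z_threshold Keep motifs with `z >= z_threshold`.
#' @param s_quantile When non-`NULL`, overrides `s_threshold` with the
#'   given quantile of all scores.
#' @return Tibble `motif`, `gene_id`, `s_m`, `sets`, sorted by motif then
#'   descending score.
#' @export
strongly_regulated <- function(gene_scores, model, gene_sets = NULL,
                               s_threshold = 20, z_threshold = 2,
                               s_quantile = NULL) {
  if (!is.null(s_quantile)) {
    s_threshold <- quantile(gene_scores$s_m, s_quantile, names = FALSE)
  }
  keep_motifs <- model$z$motif[model$z$z >= z_threshold]
  out <- filter(gene_scores, .data$motif %in% keep_motifs,
                .data$s_m > s_threshold)
  labels <- if (is.null(gene_sets)) {
    rep("", nrow(out))
  } else {
    vapply(out$gene_id, function(g) {
      paste(names(gene_sets$sets)[vapply(gene_sets$sets, function(s)
        g %in% s, logical(1))], collapse = ",")
    }, character(1))
  }
  out <- mutate(out, sets = unname(labels))
  arrange(select(out, "motif", "gene_id", "s_m", "sets"),
          .data$motif, desc(.data$s_m))
}
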