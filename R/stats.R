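#' Two-sample Kolmogorov-Smirnov test
#'
#' D is the supremum distance between the two empirical CDFs; the p-value
#' uses the asymptotic Kolmogorov distribution with effective sample size
#' `n_x * n_y / (n_x + n_y)` (ties allowed, as for tied ranks the statistic
#' remains the ECDF supremum).
#'
#' @param x,y Non-empty numeric vectors.
#' @return Tibble with columns `statistic` (D) and `p_value`.
#' @export
ks_two_sample <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) abort("samples must be non-empty")
  res <- suppressWarnings(ks.test(x, y, exact = FALSE))
  tibble(statistic = unname(res$statistic), p_value = res$p.value)
}

#' Two-sample Mann-Whitney test
#'
#' U counts the pairs where `x` exceeds `y` (ties count one half).  The
#' two-sided p-value uses the normal approximation with tie-corrected
#' variance and continuity correction.
#'
#' @param x,y Non-empty numeric vectors.
#' @return Tibble with columns `statistic` (U of `x`) and `p_value`.
#' @export
mann_whitney_u <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) abort("samples must be non-empty")
  res <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = TRUE))
  p <- res$p.value
  # fully tied samples have zero variance; the distributions are identical
  if (is.na(p) || is.nan(p)) p <- 1
  tibble(statistic = unname(res$statistic), p_value = p)
}

#' Compare target-score distributions between two gene sets
#'
#' For every motif passing the significance threshold, collects the
#' per-gene scores `S_m` of the motif's targets inside each gene set and
#' tests the two distributions for equality with both the two-sample
#' Kolmogorov-Smirnov and the Mann-Whitney test.  Motifs with fewer than
#' `min_targets` scored targets in either set are skipped (recorded with
#' `NA` statistics).  Results are sorted by descending D.
#'
#' @param gene_scores Tibble from [dedup_to_genes()].
#' @param set_a,set_b Character vectors of gene ids.  Overlap is permitted
#'   but warned about.
#' @param model The fitted `pip3_motif_model` supplying motif z-values.
#' @param z_threshold Minimum motif z.
#' @param min_targets Minimum scored targets per set.
#' @return A `pip3_sm_comparison` tibble with columns `motif`, `z`, `n_a`,
#'   `n_b`, `ks_d`, `ks_p`, `mw_u`, `mw_p`, `tested`.
#' @export
compare_sm_distributions <- function(gene_scores, set_a, set_b, model,
                                     z_threshold = 2, min_targets = 5) {
  ov <- intersect(set_a, set_b)
  if (length(ov) > 0) {
    warn(sprintf("gene sets overlap in %d gene(s)", length(ov)))
  }
  motifs <- model$z$motif[model$z$z >= z_threshold]
  if (length(motifs) == 0) {
    warn("no motif passes the z threshold")
  }
  rows <- lapply(motifs, function(m) {
    sm <- filter(gene_scores, .data$motif == m)
    xa <- sm$s_m[sm$gene_id %in% set_a]
    xb <- sm$s_m[sm$gene_id %in% set_b]
    z <- model$z$z[model$z$motif == m]
    if (length(xa) < min_targets || length(xb) < min_targets) {
      return(tibble(motif = m, z = z, n_a = length(xa), n_b = length(xb),
                    ks_d = NA_real_, ks_p = NA_real_, mw_u = NA_real_,
                    mw_p = NA_real_, tested = FALSE))
    }
    ks <- ks_two_sample(xa, xb)
    mw <- mann_whitney_u(xa, xb)
    tibble(motif = m, z = z, n_a = length(xa), n_b = length(xb),
           ks_d = ks$statistic, ks_p = ks$p_value,
           mw_u = mw$statistic, mw_p = mw$p_value, tested = TRUE)
  })
  out <- bind_rows(rows)
  if (nrow(out) > 0 && !any(out$tested)) {
    warn("no motif has enough targets in both sets")
  }
  out <- arrange(out, desc(.data$tested), desc(.data$ks_d))
  structure(out, class = c("pip3_sm_comparison", class(out)))
}

#' Bar chart of distribution differences per motif
#'
#' @param object A `pip3_sm_comparison`.
#' @param ... Unused.
#' @return A ggplot of KS D per tested motif, sorted.
#' @method autoplot pip3_sm_comparison
#' @export
autoplot.pip3_sm_comparison <- function(object, ...) {
  d <- filter(as_tibble(object), .data$tested)
  d$motif <- factor(d$motif, levels = rev(d$motif))
  ggplot2::ggplot(d, ggplot2::aes(.data$ks_d, .data$motif)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "Kolmogorov-Smirnov D", y = NULL) +
    ggplot2::theme_minimal()
}

#' Term enrichment by the hypergeometric (one-sided Fisher) test
#'
#' For each term, tests over-representation of the term's members inside
#' the gene set against the universe with the upper-tail hypergeometric
#' probability.  Terms with no member in the universe are skipped.
#' Adjusted p-values (Benjamini-Hochberg) are reported alongside, but the
#' default significance call uses the raw p-value at `alpha`.
#'
#' @param gene_set Character vector of gene ids, a subset of `universe`.
#' @param universe Character vector of all gene ids.
#' @param annotation Tibble with columns `gene_id`, `term`.
#' @param alpha Raw-p significance level.
#' @return Tibble `term`, `overlap`, `set_size`, `term_size`,
#'   `universe_size`, `expected`, `p_value`, `padj`, `significant`,
#'   sorted by p-value.
#' @export
fisher_enrichment <- function(gene_set, universe, annotation, alpha = 0.05) {
  gene_set <- unique(gene_set)
  universe <- unique(universe)
  out <- setdiff(gene_set, universe)
  if (length(out) > 0) {
    abort(paste0("gene set member(s) outside the universe: ",
                 paste(head(out, 5), collapse = ", ")))
  }
  ann <- filter(annotation, .data$gene_id %in% universe)
  n_set <- length(gene_set)
  n_uni <- length(universe)
  terms <- split(ann$gene_id, ann$term)
  rows <- purrr::imap(terms, function(members, term) {
    members <- unique(members)
    K <- length(members)
    if (K == 0) return(NULL)
    o <- length(intersect(members, gene_set))
    tibble(
      term = term, overlap = o, set_size = n_set, term_size = K,
      universe_size = n_uni, expected = n_set * K / n_uni,
      p_value = phyper(o - 1, K, n_uni - K, n_set, lower.tail = FALSE)
    )
  })
  out <- bind_rows(rows)
  out <- mutate(out, padj = bh_adjust(.data$p_value),
                significant = .data$p_value < alpha)
  arrange(out, .data$p_value)
}

#' Pearson correlation matrix of samples
#'
#' @param x Genes x samples matrix of normalized expression.
#' @return Symmetric samples x samples correlation matrix with unit
#'   diagonal; zero-variance columns give `NA` entries with a warning.
#' @export
sample_correlation_matrix <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2) abort("at least 2 genes are required")
  zv <- apply(x, 2, function(col) var(col) < 1e-300)
  if (any(zv)) {
    warn(paste0("zero-variance sample column(s): ",
                paste(colnames(x)[zv], collapse = ", ")))
  }
  suppressWarnings(cor(x))
}

#' Principal component analysis of samples
#'
#' Singular value decomposition of the column-centered expression matrix;
#' samples are the observations.
#'
#' @param x Genes x samples matrix of normalized expression (typically log
#'   scale).
#' @param samples Optional sample sheet joined onto the coordinates.
#' @return A `pip3_pca`: `coordinates` (tibble of sample scores on
#'   PC1..PCn) and `variance_fraction` (per component, summing to 1).
#' @export
pca_samples <- function(x, samples = NULL) {
  x <- as.matrix(x)
  if (ncol(x) < 2) abort("at least 2 samples are required")
  pc <- prcomp(t(x), center = TRUE, scale. = FALSE)
  vf <- pc$sdev^2 / sum(pc$sdev^2)
  co <- as_tibble(as.data.frame(pc$x))
  co <- dplyr::bind_cols(tibble(sample_id = colnames(x)), co)
  if (!is.null(samples)) co <- left_join(co, samples, by = "sample_id")
  structure(list(coordinates = co, variance_fraction = vf),
            class = "pip3_pca")
}

#' @export
print.pip3_pca <- function(x, ...) {
  cat(sprintf("<pip3_pca> %d samples; PC1 %.1f%%, PC2 %.1f%% of variance\n",
              nrow(x$coordinates), 100 * x$variance_fraction[1],
              100 * x$variance_fraction[2]))
  invisible(x)
}

#' @rdname pca_samples
#' @param ... Unused.
#' @method tidy pip3_pca
#' @export
tidy.pip3_pca <- function(x, ...) x$coordinates

#' @rdname pca_samples
#' @method glance pip3_pca
#' @export
glance.pip3_pca <- function(x, ...) {
  tibble(pc = seq_along(x$variance_fraction),
         variance_fraction = x$variance_fraction)
}

#' PCA plot of samples
#'
#' @param object A `pip3_pca` built with a sample sheet.
#' @param ... Unused.
#' @return A ggplot of PC1 against PC2, coloured by condition and sized by
#'   time when available.
#' @method autoplot pip3_pca
#' @export
autoplot.pip3_pca <- function(object, ...) {
  d <- object$coordinates
  vf <- object$variance_fraction
  aes <- if (all(c("condition", "time_min") %in% names(d))) {
    ggplot2::aes(.data$PC1, .data$PC2, colour = .data$condition,
                 size = .data$time_min)
  } else {
    ggplot2::aes(.data$PC1, .data$PC2)
  }
  ggplot2::ggplot(d, aes) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::scale_size_continuous(range = c(1, 4)) +
    ggplot2::labs(x = sprintf("PC1 (%.1f%%)", 100 * vf[1]),
                  y = sprintf("PC2 (%.1f%%)", 100 * vf[2])) +
    ggplot2::theme_minimal()
}
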