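#' Scale and centre expression profiles
#'
#' Z-scores each gene row to mean 0 and population standard deviation 1.
#' Constant rows cannot be scaled; they are mapped to all-zero rows and
#' flagged in the `"constant"` attribute.
#'
#' @param x Genes x samples matrix of normalized expression values.
#' @return Scaled matrix with attribute `"constant"` (logical per row).
#' @export
scale_center_profiles <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 2) abort("at least 2 samples are required")
  mu <- rowMeans(x)
  cx <- x - mu
  s <- sqrt(rowMeans(cx^2))
  const <- s < 1e-12
  s[const] <- 1
  out <- cx / s
  out[const, ] <- 0
  attr(out, "constant") <- setNames(const, rownames(x))
  out
}

#' Partitioning around medoids
#'
#' PAM (k-medoids) on Euclidean dissimilarities.  Instances small enough to
#' enumerate (`choose(n, k) <= 5000`) are solved exactly over all medoid
#' subsets; larger ones use [cluster::pam()] (BUILD followed by SWAP).
#' Both paths are deterministic; `seed` is accepted for interface
#' uniformity.
#'
#' @param x Rows-are-objects numeric matrix.
#' @param k Number of clusters, `2 <= k <= nrow(x)`.
#' @param seed Unused; PAM is deterministic.
#' @return A `pip3_pam` list: `k`, `medoids` (row names), `labels`
#'   (integer vector named by row), `total_diss` (sum of distances of
#'   every object to its medoid).
#' @export
pam_cluster <- function(x, k, seed = NULL) {
  x <- as.matrix(x)
  if (k > nrow(x)) abort("k must not exceed the number of rows")
  if (k < 1) abort("k must be at least 1")
  n <- nrow(x)
  if (k == n) {
    med_idx <- seq_len(n)
    labels <- seq_len(n)
  } else if (choose(n, k) <= 5000) {
    # BUILD + SWAP is a local search; on instances this small the exact
    # medoid subset is affordable and strictly better
    d <- as.matrix(dist(x))
    best <- NULL
    best_tot <- Inf
    for (med in utils::combn(n, k, simplify = FALSE)) {
      tot <- sum(apply(d[, med, drop = FALSE], 1, min))
      if (tot < best_tot) {
        best_tot <- tot
        best <- med
      }
    }
    med_idx <- best
    labels <- apply(d[, med_idx, drop = FALSE], 1, which.min)
  } else {
    fit <- cluster::pam(x, k, metric = "euclidean", keep.diss = FALSE,
                        keep.data = FALSE, pamonce = 5)
    labels <- fit$clustering
    med_idx <- fit$id.med
  }
  d <- sqrt(rowSums((x - x[med_idx[labels], , drop = FALSE])^2))
  structure(
    list(k = k,
         medoids = rownames(x)[med_idx] %||% med_idx,
         labels = setNames(labels, rownames(x)),
         total_diss = sum(d)),
    class = "pip3_pam"
  )
}

jaccard <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0) return(1)
  length(intersect(a, b)) / u
}

#' Bootstrap Jaccard stability of a clustering
#'
#' Clusters the full matrix as reference, then repeatedly resamples rows
#' with replacement, re-clusters the resample (duplicates kept) with the
#' same `k`, and records for each reference cluster the maximum Jaccard
#' similarity between its members present in the resample and any resample
#' cluster's distinct members.
#'
#' @param x Genes x samples matrix (typically scaled profiles).
#' @param k Number of clusters.
#' @param n_boot Number of resamples.
#' @param seed Integer seed for the resampling.
#' @return List with `reference` (the `pip3_pam` solution on `x`) and
#'   `jaccard` (k x n_boot matrix of similarities).
#' @export
bootstrap_stability <- function(x, k, n_boot = 100, seed = 1) {
  x <- as.matrix(x)
  if (is.null(rownames(x))) rownames(x) <- paste0("r", seq_len(nrow(x)))
  ref <- pam_cluster(x, k)
  ref_members <- split(names(ref$labels), ref$labels)
  J <- matrix(NA_real_, k, n_boot)
  withr::with_seed(seed, {
    for (b in seq_len(n_boot)) {
      idx <- sample(nrow(x), replace = TRUE)
      xb <- x[idx, , drop = FALSE]
      rownames(xb) <- paste0(rownames(x)[idx], "#", seq_along(idx))
      fit <- pam_cluster(xb, k)
      support <- unique(rownames(x)[idx])
      boot_members <- split(rownames(x)[idx], fit$labels)
      boot_members <- lapply(boot_members, unique)
      for (j in seq_len(k)) {
        a <- intersect(ref_members[[j]], support)
        J[j, b] <- max(vapply(boot_members, jaccard, numeric(1), a = a))
      }
    }
  })
  list(reference = ref, jaccard = J)
}

#' Bootstrap stability profile over a range of k
#'
#' Runs [bootstrap_stability()] for each `k`, flags a cluster as stable
#' when its median Jaccard similarity is at least `jaccard_median` and the
#' standard deviation of its similarities is at most `sd_frac` of their
#' mean, and selects the optimal `k` with [select_optimal_k()].
#'
#' @param x Genes x samples matrix of scaled profiles.
#' @param k_range Contiguous range of k starting at 2; defaults to
#'   `2:min(10, floor(nrow(x) / 20))`.
#' @param n_boot Resamples per k.
#' @param seed Integer seed.
#' @param jaccard_median Stability threshold on the median similarity.
#' @param sd_frac Stability threshold on sd relative to the mean.
#' @return A `pip3_stability` object: per-k reference solutions, Jaccard
#'   distributions, a per-cluster summary table and `optimal_k`
#'   (`NA` when even k = 2 is unstable).
#' @export
cluster_stability <- function(x, k_range = NULL, n_boot = 100, seed = 1,
                              jaccard_median = 0.75, sd_frac = 0.10) {
  x <- as.matrix(x)
  k_range <- k_range %||% (2:max(2, min(10, floor(nrow(x) / 20))))
  if (k_range[1] != 2 || any(diff(k_range) != 1)) {
    abort("k_range must be a contiguous range starting at 2")
  }
  runs <- list()
  rows <- list()
  for (k in k_range) {
    bs <- bootstrap_stability(x, k, n_boot = n_boot, seed = seed + k)
    med <- apply(bs$jaccard, 1, median)
    mn <- rowMeans(bs$jaccard)
    sdv <- apply(bs$jaccard, 1, sd)
    sizes <- tabulate(bs$reference$labels, nbins = k)
    clusters <- seq_len(k)
    rows[[as.character(k)]] <- tibble(
      k = rep(k, k), cluster = clusters, size = sizes,
      median_jaccard = med, mean_jaccard = mn, sd_jaccard = sdv,
      stable = med >= jaccard_median & sdv <= sd_frac * mn
    )
    runs[[as.character(k)]] <- bs
  }
  summary <- bind_rows(rows)
  all_stable <- vapply(split(summary$stable, summary$k), all, logical(1))
  all_stable <- all_stable[as.character(k_range)]
  structure(
    list(summary = summary, runs = runs, k_range = k_range,
         all_stable = setNames(all_stable, k_range),
         optimal_k = select_optimal_k(setNames(all_stable, k_range)),
         thresholds = c(jaccard_median = jaccard_median,
                        sd_frac = sd_frac)),
    class = "pip3_stability"
  )
}

#' Select the optimal number of clusters
#'
#' Returns the largest k of the first contiguous run of all-stable
#' clusterings starting at k = 2.  This deliberately ignores the trivial
#' recovery of high Jaccard similarity at large k, where many small
#' clusters are reproduced by chance.  Returns `NA` when k = 2 is already
#' unstable.
#'
#' @param all_stable Logical vector named by k (contiguous from 2), or a
#'   `pip3_stability` object.
#' @return Integer k, or `NA_integer_`.
#' @export
select_optimal_k <- function(all_stable) {
  if (inherits(all_stable, "pip3_stability")) {
    all_stable <- all_stable$all_stable
  }
  ks <- as.integer(names(all_stable))
  if (ks[1] != 2) abort("stability flags must start at k = 2")
  if (!all_stable[1]) return(NA_integer_)
  run_end <- which(!all_stable)[1]
  if (is.na(run_end)) ks[length(ks)] else ks[run_end - 1]
}

#' @export
print.pip3_stability <- function(x, ...) {
  cat(sprintf("<pip3_stability> k in [%d, %d], optimal k = %s\n",
              min(x$k_range), max(x$k_range),
              ifelse(is.na(x$optimal_k), "none stable", x$optimal_k)))
  invisible(x)
}

#' @rdname cluster_stability
#' @param x A `pip3_stability` object.
#' @param ... Unused.
#' @method tidy pip3_stability
#' @export
tidy.pip3_stability <- function(x, ...) x$summary

#' @rdname cluster_stability
#' @method glance pip3_stability
#' @export
glance.pip3_stability <- function(x, ...) {
  tibble(
    k_min = min(x$k_range), k_max = max(x$k_range),
    n_stable_k = sum(x$all_stable), optimal_k = x$optimal_k
  )
}

#' Jaccard stability plot
#'
#' Boxplots of the bootstrap Jaccard distributions per cluster, faceted by
#' k, with the median stability threshold drawn.
#'
#' @param object A `pip3_stability` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot pip3_stability
#' @export
autoplot.pip3_stability <- function(object, ...) {
  d <- bind_rows(lapply(names(object$runs), function(k) {
    J <- object$runs[[k]]$jaccard
    tibble(k = as.integer(k),
           cluster = factor(rep(seq_len(nrow(J)), ncol(J))),
           jaccard = as.vector(J))
  }))
  ggplot2::ggplot(d, ggplot2::aes(.data$cluster, .data$jaccard)) +
    ggplot2::geom_boxplot(outlier.size = 0.4) +
    ggplot2::geom_hline(yintercept = object$thresholds["jaccard_median"],
                        linetype = 2, colour = "firebrick") +
    ggplot2::facet_wrap(~k, scales = "free_x", labeller = "label_both") +
    ggplot2::labs(y = "bootstrap Jaccard similarity") +
    ggplot2::theme_minimal()
}
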