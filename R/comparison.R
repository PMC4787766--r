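#' Specify a differential-expression comparison
#'
#' Three comparison designs are supported, mirroring the study's analysis
#' plan:
#' * `pairwise` - two condition/time groups against each other; the GLM
#'   holds a single two-level group factor, tested against the
#'   intercept-only model (default `alpha` 0.05).
#' * `timecourse` - one condition over several time points; a categorical
#'   time-factor model is tested against the model with the time factor
#'   removed (default `alpha` 0.01).
#' * `interaction` - two conditions over a shared time course; the full
#'   model holds condition, time and their interaction, and is tested
#'   against the reduced model retaining time only, so that both the
#'   condition and interaction terms are assessed jointly (default
#'   `alpha` 0.01).
#'
#' @param design_kind One of `"pairwise"`, `"timecourse"`, `"interaction"`.
#' @param condition_a Baseline condition.
#' @param condition_b Comparison condition (pairwise and interaction).
#' @param time_a,time_b Time points of the two pairwise groups.
#' @param times Time points of a time-course or interaction design.
#' @param alpha Significance level applied to adjusted p-values.
#' @param name Optional label used in output files.
#' @return A `pip3_comparison_spec`.
#' @export
comparison_spec <- function(design_kind = c("pairwise", "timecourse",
                                            "interaction"),
                            condition_a, condition_b = NULL,
                            time_a = NULL, time_b = NULL,
                            times = PIP3_TIMES,
                            alpha = NULL, name = NULL) {
  design_kind <- match.arg(design_kind)
  alpha <- alpha %||% if (design_kind == "pairwise") 0.05 else 0.01
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    abort("alpha must lie strictly between 0 and 1")
  }
  condition_a <- match.arg(condition_a, PIP3_CONDITIONS)
  if (!is.null(condition_b)) {
    condition_b <- match.arg(condition_b, PIP3_CONDITIONS)
  }
  if (design_kind == "pairwise") {
    if (is.null(condition_b) || is.null(time_a) || is.null(time_b)) {
      abort("pairwise comparisons need condition_a/b and time_a/b")
    }
  } else if (design_kind == "interaction" && is.null(condition_b)) {
    abort("interaction comparisons need condition_b")
  }
  structure(
    list(design_kind = design_kind, condition_a = condition_a,
         condition_b = condition_b, time_a = time_a, time_b = time_b,
         times = as.integer(times), alpha = alpha,
         name = name %||% design_kind),
    class = "pip3_comparison_spec"
  )
}

comparison_samples <- function(spec, samples) {
  if (spec$design_kind == "pairwise") {
    sel_a <- samples$condition == spec$condition_a &
      samples$time_min == spec$time_a
    sel_b <- samples$condition == spec$condition_b &
      samples$time_min == spec$time_b
    sel <- sel_a | sel_b
    grp <- ifelse(sel_a[sel], "A", "B")
  } else if (spec$design_kind == "timecourse") {
    sel <- samples$condition == spec$condition_a &
      samples$time_min %in% spec$times
    grp <- paste0("t", samples$time_min[sel])
  } else {
    sel <- samples$condition %in% c(spec$condition_a, spec$condition_b) &
      samples$time_min %in% spec$times
    grp <- paste(ifelse(samples$condition[sel] == spec$condition_a,
                        "A", "B"),
                 samples$time_min[sel], sep = "_t")
  }
  if (!any(sel)) abort("no samples match the comparison specification")
  list(sel = which(sel), group = grp,
       time = samples$time_min[sel],
       cond = samples$condition[sel])
}

#' Run a differential-expression comparison
#'
#' Fits negative-binomial group-means GLMs gene by gene (vectorized across
#' genes) with log size-factor offsets, estimates a per-gene dispersion by
#' Cox-Reid adjusted profile likelihood combined conservatively with a
#' fitted mean-dispersion trend (`max` of the two), and performs the
#' likelihood-ratio test of the full against the reduced model with a
#' chi-squared reference whose degrees of freedom equal the difference in
#' parameter counts.  P-values are Benjamini-Hochberg adjusted.
#'
#' For pairwise designs the reported `log2fc` is the fitted B-over-A fold
#' change; for time-course and interaction designs it is the signed
#' largest-magnitude per-level fold change (each time against the first
#' time, or condition B against A at each time).
#'
#' @param ds A `pip3_dataset`.
#' @param spec A [comparison_spec()].
#' @param size_factors Optional size factors (estimated from the full
#'   dataset when omitted).
#' @param dispersion `"trend"` (per-gene Cox-Reid combined with the trend,
#'   the default) or a fixed numeric value for all genes.
#' @return A `pip3_de` object; `tidy()` returns the per-gene table with
#'   columns `gene_id`, `log2fc`, `stat`, `df`, `pvalue`, `padj`,
#'   `significant`.
#' @export
run_comparison <- function(ds, spec, size_factors = NULL,
                           dispersion = "trend") {
  stopifnot(inherits(ds, "pip3_dataset"),
            inherits(spec, "pip3_comparison_spec"))
  sf <- size_factors %||% estimate_size_factors(ds$counts)
  cs <- comparison_samples(spec, ds$samples)
  Y <- ds$counts[, cs$sel, drop = FALSE]
  storage.mode(Y) <- "double"
  offsets <- log(sf[colnames(Y)])
  full_groups <- cs$group
  red_groups <- reduced_groups(spec, cs)
  if (length(unique(full_groups)) < 2 ||
      length(unique(full_groups)) <= length(unique(red_groups))) {
    abort("tested factor has fewer than 2 levels")
  }

  if (identical(dispersion, "trend")) {
    init <- nb_group_fit(Y, full_groups, offsets, 0.1)
    alpha_cr <- nb_disp_ml(Y, init$mu, full_groups, cox_reid = TRUE)
    base_mu <- rowMeans(init$mu)
    trend <- fit_dispersion_trend(alpha_cr, base_mu)
    alpha_gene <- pmax(alpha_cr, trend["a"] / base_mu + trend["b"])
  } else {
    stopifnot(is.numeric(dispersion), all(dispersion > 0))
    alpha_gene <- rep_len(dispersion, nrow(Y))
    trend <- c(a = NA_real_, b = NA_real_)
  }

  full <- nb_group_fit(Y, full_groups, offsets, alpha_gene)
  red <- nb_group_fit(Y, red_groups, offsets, alpha_gene)
  stat <- pmax(0, 2 * (full$loglik - red$loglik))
  df <- length(unique(full_groups)) - length(unique(red_groups))
  pvalue <- pchisq(stat, df = df, lower.tail = FALSE)
  padj <- bh_adjust(pvalue)

  lfc <- comparison_log2fc(spec, full, cs)
  table <- tibble(
    gene_id = rownames(Y),
    log2fc = unname(lfc),
    stat = stat,
    df = df,
    pvalue = pvalue,
    padj = padj,
    significant = padj < spec$alpha
  )
  structure(
    list(table = table, spec = spec, alpha = spec$alpha,
         size_factors = sf[colnames(Y)], dispersion = alpha_gene,
         dispersion_trend = trend, n_samples = ncol(Y)),
    class = "pip3_de"
  )
}

reduced_groups <- function(spec, cs) {
  if (spec$design_kind == "interaction") {
    paste0("t", cs$time)
  } else {
    rep("all", length(cs$group))
  }
}

comparison_log2fc <- function(spec, full, cs) {
  beta <- full$beta / log(2)  # group log2 means
  if (spec$design_kind == "pairwise") {
    return(beta[, "B"] - beta[, "A"])
  }
  if (spec$design_kind == "timecourse") {
    tcols <- paste0("t", sort(unique(cs$time)))
    d <- beta[, tcols[-1], drop = FALSE] - beta[, tcols[1]]
  } else {
    tt <- sort(unique(cs$time))
    d <- beta[, paste0("B_t", tt), drop = FALSE] -
      beta[, paste0("A_t", tt), drop = FALSE]
  }
  pick <- max.col(abs(d), ties.method = "first")
  d[cbind(seq_len(nrow(d)), pick)]
}

#' Signed significance outcomes of a comparison
#'
#' Collapses a DE result to one row per gene holding the significance flag
#' and the direction sign (+1 up, -1 down, 0 when not significant); for
#' time-course designs the direction is that of the largest-magnitude
#' deviation from baseline.
#'
#' @param de A `pip3_de` object.
#' @return Tibble with columns `gene_id`, `significant`, `sign`.
#' @export
de_signed_outcome <- function(de) {
  stopifnot(inherits(de, "pip3_de"))
  mutate(select(tidy(de), "gene_id", "significant", "log2fc"),
         sign = ifelse(.data$significant, sign(.data$log2fc), 0)) |>
    select("gene_id", "significant", "sign")
}

#' Genes called significant by a comparison
#'
#' @param de A `pip3_de` object.
#' @return Character vector of gene ids with `padj < alpha`.
#' @export
significant_genes <- function(de) {
  stopifnot(inherits(de, "pip3_de"))
  de$table$gene_id[de$table$significant]
}

#' @export
print.pip3_de <- function(x, ...) {
  cat(sprintf(
    "<pip3_de> %s '%s': %d genes, %d samples, %d significant at %g\n",
    x$spec$design_kind, x$spec$name, nrow(x$table), x$n_samples,
    sum(x$table$significant), x$alpha
  ))
  invisible(x)
}

#' @rdname run_comparison
#' @param x A `pip3_de` object.
#' @param ... Unused.
#' @method tidy pip3_de
#' @export
tidy.pip3_de <- function(x, ...) x$table

#' @rdname run_comparison
#' @method glance pip3_de
#' @export
glance.pip3_de <- function(x, ...) {
  tibble(
    name = x$spec$name,
    design_kind = x$spec$design_kind,
    n_genes = nrow(x$table),
    n_samples = x$n_samples,
    n_significant = sum(x$table$significant),
    alpha = x$alpha,
    trend_a = unname(x$dispersion_trend["a"]),
    trend_b = unname(x$dispersion_trend["b"])
  )
}

#' Volcano plot of a DE result
#'
#' @param object A `pip3_de` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot pip3_de
#' @export
autoplot.pip3_de <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(.data$log2fc, -log10(.data$padj),
                                  colour = .data$significant)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 adjusted p",
                  title = object$spec$name) +
    ggplot2::theme_minimal()
}
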