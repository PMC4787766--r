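#' Configuration of the synthetic time-course generator
#'
#' The generator emulates a five-condition EGF time-course design: wild-type
#' MCF10a-like cells (`WT`), the same cells under the p110-alpha inhibitor
#' A66 with EGF (`A66`) or without EGF (`A66_noEGF`, a single 300-minute
#' library group), and two chronically activated mutants (`PTEN_KO`,
#' `PIK3CA_H1047R`), each EGF-stimulated condition sampled at 0, 15, 40, 90,
#' 180 and 300 minutes in triplicate.  Counts are negative binomial with a
#' mean-dispersion trend `alpha(mu) = a/mu + b`, and genes carry planted
#' effects by category (see Details).
#'
#' @details Planted categories and their log2 effects (`E = effect_log2fc`):
#' * `null` - no planted effect.
#' * `chronic_pten`, `chronic_pik3ca`, `chronic_both` - baseline shifted by
#'   `+/-E` in the named mutant(s) at every time point (random sign per gene).
#' * `egf_early_peak` / `egf_late_peak` - EGF-driven impulse rising to `E`
#'   at 15-40 min (early) or 180-300 min (late) in every EGF-stimulated
#'   condition.
#' * `pi3k_basal` - shifted by `+/-E` in the `A66_noEGF` library only.
#' * `pi3k_induced` - early EGF impulse in WT and the mutants, attenuated by
#'   85 percent under A66.
#' * `coherent_up` - up by `E` in both mutants at all times, down by `E`
#'   under A66 (with and without EGF); `coherent_down` is the mirror image.
#'
#' Default category fractions mirror the qualitative structure of chronic
#' PIP3-pathway perturbation: chronic mutant effects touch an order of
#' magnitude more genes than acute pharmacological inhibition, and only a
#' small coherent core responds to every perturbation in a direction
#' consistent with PIP3 signalling logic.
#'
#' A subset of motifs is transcriptionally active: each active motif has an
#' activity profile over condition x time (amplitude
#' `motif_activity_amplitude`, in log2 expression per binding site) and its
#' binding sites are concentrated on the genes of a designated category, so
#' that motif-driven expression structure correlates with set membership.
#'
#' @param n_genes Number of genes.
#' @param seed Integer seed; the same seed reproduces the dataset exactly.
#' @param library_size_mean,library_size_cv Mean and coefficient of variation
#'   of per-sample library sizes.
#' @param dispersion_a,dispersion_b Parameters of the mean-dispersion trend.
#' @param category_fractions Named vector over the planted categories,
#'   summing to 1.
#' @param effect_log2fc Planted effect size in log2 units.
#' @param n_motifs,n_active_motifs Number of motifs and of transcriptionally
#'   active motifs among them.
#' @param motif_activity_amplitude Activity amplitude of active motifs
#'   (log2 per site).
#' @param promoters_per_gene_max Maximum number of promoters per gene.
#' @param replicates Replicates per condition/time group.
#'
#' @return A validated `pip3_generator_config` list.
#' @export
generator_config <- function(n_genes = 4000,
                             seed = 1,
                             library_size_mean = 5e5,
                             library_size_cv = 0.1,
                             dispersion_a = 1.0,
                             dispersion_b = 0.05,
                             category_fractions = NULL,
                             effect_log2fc = 2.0,
                             n_motifs = 20,
                             n_active_motifs = 4,
                             motif_activity_amplitude = 0.5,
                             promoters_per_gene_max = 2,
                             replicates = 3) {
  if (is.null(category_fractions)) {
    category_fractions <- c(
      null = 0.50, chronic_pten = 0.14, chronic_pik3ca = 0.12,
      chronic_both = 0.06, egf_early_peak = 0.07, egf_late_peak = 0.05,
      pi3k_basal = 0.03, pi3k_induced = 0.015,
      coherent_up = 0.0075, coherent_down = 0.0075
    )
  }
  miss <- setdiff(PIP3_CATEGORIES, names(category_fractions))
  if (length(miss) > 0) {
    abort(paste0("category_fractions missing: ", paste(miss, collapse = ", ")))
  }
  if (abs(sum(category_fractions) - 1) > 1e-9) {
    abort("category_fractions must sum to 1")
  }
  if (any(category_fractions < 0)) abort("category fractions must be >= 0")
  for (nm in c("n_genes", "library_size_mean", "library_size_cv",
               "dispersion_a", "dispersion_b", "replicates")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || v <= 0) {
      abort(paste0(nm, " must be a positive number"))
    }
  }
  if (effect_log2fc < 0) abort("effect_log2fc must be >= 0")
  if (n_active_motifs > n_motifs) abort("n_active_motifs > n_motifs")
  structure(
    list(
      n_genes = as.integer(n_genes), seed = as.integer(seed),
      library_size_mean = library_size_mean,
      library_size_cv = library_size_cv,
      dispersion_a = dispersion_a, dispersion_b = dispersion_b,
      category_fractions = category_fractions[PIP3_CATEGORIES],
      effect_log2fc = effect_log2fc,
      n_motifs = as.integer(n_motifs),
      n_active_motifs = as.integer(n_active_motifs),
      motif_activity_amplitude = motif_activity_amplitude,
      promoters_per_gene_max = as.integer(promoters_per_gene_max),
      replicates = as.integer(replicates)
    ),
    class = "pip3_generator_config"
  )
}

#' Generate the study's sample design
#'
#' Four EGF-stimulated conditions at six time points plus the single
#' unstimulated inhibitor-only group, each in triplicate: 25 groups, 75
#' samples under the defaults.
#'
#' @param conditions Conditions to include.
#' @param times EGF time points in minutes.
#' @param replicates Replicates per group.
#' @return Tibble with columns `sample_id`, `condition`, `time_min`,
#'   `replicate`.
#' @export
generate_design <- function(conditions = PIP3_CONDITIONS,
                            times = PIP3_TIMES,
                            replicates = 3) {
  conditions <- match.arg(conditions, PIP3_CONDITIONS, several.ok = TRUE)
  groups <- design_groups(conditions, times)
  out <- tidyr::crossing(groups, replicate = seq_len(replicates))
  out <- arrange(out, match(.data$condition, PIP3_CONDITIONS),
                 .data$time_min, .data$replicate)
  mutate(out,
         sample_id = sprintf("%s_t%03d_r%d", .data$condition,
                             .data$time_min, .data$replicate),
         .before = 1)
}

design_groups <- function(conditions, times) {
  g <- tidyr::crossing(condition = conditions, time_min = as.integer(times))
  # the unstimulated inhibitor-only condition has a single 300-min library
  g <- g[!(g$condition == "A66_noEGF" & g$time_min != 300L), ]
  arrange(g, match(.data$condition, PIP3_CONDITIONS), .data$time_min)
}

# EGF impulse shapes over PIP3_TIMES (fraction of full effect)
shape_early <- function() c(0, 1, 1, 0.5, 0.25, 0.1)
shape_late <- function() c(0, 0.1, 0.25, 0.5, 1, 1)

egf_conditions <- function() c("WT", "A66", "PTEN_KO", "PIK3CA_H1047R")

# planted category log2 effect over the design groups (one row)
category_profile <- function(category, groups, E, sign = 1) {
  p <- numeric(nrow(groups))
  tix <- match(groups$time_min, PIP3_TIMES)
  in_egf <- groups$condition %in% egf_conditions()
  switch(category,
    null = { },
    chronic_pten = { p[groups$condition == "PTEN_KO"] <- sign * E },
    chronic_pik3ca = { p[groups$condition == "PIK3CA_H1047R"] <- sign * E },
    chronic_both = {
      p[groups$condition %in% c("PTEN_KO", "PIK3CA_H1047R")] <- sign * E
    },
    egf_early_peak = { p[in_egf] <- E * shape_early()[tix[in_egf]] },
    egf_late_peak = { p[in_egf] <- E * shape_late()[tix[in_egf]] },
    pi3k_basal = { p[groups$condition == "A66_noEGF"] <- sign * E },
    pi3k_induced = {
      resp <- groups$condition %in% c("WT", "PTEN_KO", "PIK3CA_H1047R")
      p[resp] <- E * shape_early()[tix[resp]]
      att <- groups$condition == "A66"
      p[att] <- 0.15 * E * shape_early()[tix[att]]
    },
    coherent_up = {
      p[groups$condition %in% c("PTEN_KO", "PIK3CA_H1047R")] <- E
      p[groups$condition %in% c("A66", "A66_noEGF")] <- -E
    },
    coherent_down = {
      p[groups$condition %in% c("PTEN_KO", "PIK3CA_H1047R")] <- -E
      p[groups$condition %in% c("A66", "A66_noEGF")] <- E
    },
    abort(paste0("unknown category: ", category))
  )
  p
}

# activity profile (log2 per site) of a motif coupled to a category
motif_profile <- function(target_category, groups, amplitude) {
  switch(target_category,
    chronic_both = category_profile("chronic_both", groups, amplitude),
    egf_early_peak = category_profile("egf_early_peak", groups, amplitude),
    egf_late_peak = category_profile("egf_late_peak", groups, amplitude),
    coherent_up = category_profile("coherent_up", groups, amplitude),
    category_profile(target_category, groups, amplitude)
  )
}

#' Generate a synthetic dataset with known planted structure
#'
#' Draws a seeded dataset under the configured design together with the
#' ground truth needed to test every downstream stage: the planted category
#' of each gene, the noiseless planted expression profile, the motif site
#' matrix and the planted motif activity matrix.
#'
#' @param config A [generator_config()].
#' @return A list with elements `dataset` (a [pip3_dataset()]), `truth`
#'   (a `pip3_truth` list) and `sites` (a [motif_sites()] object).
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "pip3_generator_config"))
  withr::with_seed(config$seed, generate_dataset_impl(config))
}

generate_dataset_impl <- function(cfg) {
  G <- cfg$n_genes
  groups <- design_groups(PIP3_CONDITIONS, PIP3_TIMES)
  groups$group_id <- sprintf("%s_t%03d", groups$condition, groups$time_min)
  design <- generate_design(replicates = cfg$replicates)
  design$group_id <- sprintf("%s_t%03d", design$condition, design$time_min)
  K <- nrow(groups)

  gene_id <- sprintf("g%05d", seq_len(G))
  # exact partition into categories (largest-remainder rounding), shuffled
  n_cat <- floor(cfg$category_fractions * G)
  rem <- cfg$category_fractions * G - n_cat
  short <- G - sum(n_cat)
  if (short > 0) {
    bump <- order(rem, decreasing = TRUE)[seq_len(short)]
    n_cat[bump] <- n_cat[bump] + 1
  }
  category <- sample(rep(names(n_cat), n_cat))

  baseline_mean <- exp(runif(G, log(20), log(2000)))
  signs <- sample(c(-1, 1), G, replace = TRUE)

  profile_cat <- matrix(0, G, K, dimnames = list(gene_id, groups$group_id))
  for (cat in unique(category)) {
    idx <- which(category == cat)
    for (i in idx) {
      profile_cat[i, ] <- category_profile(cat, groups, cfg$effect_log2fc,
                                           sign = signs[i])
    }
  }

  # promoters and motif sites
  motifs <- sprintf("motif%02d", seq_len(cfg$n_motifs))
  active <- motifs[seq_len(cfg$n_active_motifs)]
  target_pool <- c("chronic_both", "egf_early_peak", "egf_late_peak",
                   "coherent_up")
  motif_targets <- setNames(
    rep(target_pool, length.out = cfg$n_active_motifs), active)

  n_prom <- 1L + rbinom(G, cfg$promoters_per_gene_max - 1L, 0.25)
  prom_ids <- unlist(lapply(seq_len(G), function(i) {
    sprintf("%s_p%d", gene_id[i], seq_len(n_prom[i]))
  }))
  promoter_map <- tibble(promoter_id = prom_ids,
                         gene_id = rep(gene_id, n_prom))
  P <- nrow(promoter_map)
  N <- matrix(0L, P, cfg$n_motifs,
              dimnames = list(promoter_map$promoter_id, motifs))
  prom_cat <- category[match(promoter_map$gene_id, gene_id)]
  for (m in motifs) {
    if (m %in% active) {
      # active motifs have focused regulons: dense sites on the coupled
      # category, sparse off-target sites elsewhere
      tgt <- prom_cat == motif_targets[[m]]
      N[tgt, m] <- 1L + rpois(sum(tgt), 1.5)
      N[!tgt, m] <- rpois(sum(!tgt), 0.02)
    } else {
      N[, m] <- rpois(P, 0.3)
    }
  }

  # planted activities (log2 per site) over groups
  A <- matrix(0, cfg$n_motifs, K, dimnames = list(motifs, groups$group_id))
  for (m in active) {
    A[m, ] <- motif_profile(motif_targets[[m]], groups,
                            cfg$motif_activity_amplitude)
  }

  # per-gene motif contribution: average over the gene's promoters
  effN <- rowsum(N, promoter_map$gene_id, reorder = FALSE)
  effN <- effN[gene_id, , drop = FALSE] / n_prom
  profile_motif <- effN %*% A

  profile_total <- profile_cat + profile_motif
  q <- baseline_mean * 2^profile_total           # genes x groups
  qs <- q[, match(design$group_id, groups$group_id), drop = FALSE]
  lib <- rlnorm(nrow(design),
                meanlog = log(cfg$library_size_mean) -
                  cfg$library_size_cv^2 / 2,
                sdlog = cfg$library_size_cv)
  mu <- sweep(qs, 2, lib / colSums(qs), `*`)
  alpha <- cfg$dispersion_a / mu + cfg$dispersion_b
  counts <- matrix(
    rnbinom(length(mu), size = 1 / alpha, mu = mu),
    nrow = G, dimnames = list(gene_id, design$sample_id)
  )

  genes <- tibble(
    gene_id = gene_id,
    length_bp = pmax(200L, as.integer(round(rlnorm(G, log(2000), 0.6))))
  )
  ds <- pip3_dataset(counts, select(design, -"group_id"), genes)
  sites <- motif_sites(N, promoter_map)
  truth <- structure(
    list(
      categories = tibble(gene_id = gene_id, category = category),
      baseline_mean = setNames(baseline_mean, gene_id),
      groups = select(groups, "group_id", "condition", "time_min"),
      profile_category = profile_cat,
      profile_motif = profile_motif,
      profile = profile_total,
      activity = A,
      motif_targets = motif_targets,
      active_motifs = active,
      library_sizes = setNames(lib, design$sample_id)
    ),
    class = "pip3_truth"
  )
  list(dataset = ds, truth = truth, sites = sites)
}

#' @export
print.pip3_truth <- function(x, ...) {
  cat(sprintf("<pip3_truth> %d genes, %d groups, %d active motifs\n",
              nrow(x$categories), nrow(x$groups), length(x$active_motifs)))
  invisible(x)
}

#' Generate term annotations enriched in planted categories
#'
#' Each planted category receives one designated term (`term_<category>`)
#' whose members are drawn from the category with the requested odds ratio
#' relative to the genome background; remaining background terms are
#' assigned uniformly at random.
#'
#' @param truth A `pip3_truth` from [generate_dataset()].
#' @param n_terms Total number of terms (at least one per category).
#' @param enrichment_odds Odds ratio of membership for category genes in
#'   their designated term; 1 means no enrichment.
#' @param seed Integer seed.
#' @param base_rate Background membership probability per gene and term.
#' @return Tibble with columns `gene_id`, `term` (one row per annotation).
#' @export
generate_annotation <- function(truth, n_terms = 50, enrichment_odds = 10,
                                seed = 1, base_rate = 0.02) {
  stopifnot(inherits(truth, "pip3_truth"), enrichment_odds >= 1)
  withr::with_seed(seed, {
    genes <- truth$categories$gene_id
    category <- truth$categories$category
    cats <- unique(category)
    odds0 <- base_rate / (1 - base_rate)
    p1 <- enrichment_odds * odds0 / (1 + enrichment_odds * odds0)
    rows <- list()
    for (cat in cats) {
      incat <- category == cat
      p <- ifelse(incat, p1, base_rate)
      memb <- runif(length(genes)) < p
      if (any(memb)) {
        rows[[cat]] <- tibble(gene_id = genes[memb],
                              term = paste0("term_", cat))
      }
    }
    n_bg <- max(0, n_terms - length(cats))
    for (j in seq_len(n_bg)) {
      memb <- runif(length(genes)) < base_rate
      if (any(memb)) {
        rows[[paste0("bg", j)]] <- tibble(gene_id = genes[memb],
                                          term = sprintf("term_bg%02d", j))
      }
    }
    arrange(bind_rows(rows), .data$term, .data$gene_id)
  })
}

#' Flatten annotations into the gene table's `terms` column
#'
#' @param annotation Tibble from [generate_annotation()].
#' @param gene_id Character vector of gene ids to annotate.
#' @return Character vector of semicolon-separated terms, "" when none.
#' @export
terms_column <- function(annotation, gene_id) {
  ann <- summarise(group_by(annotation, .data$gene_id),
                   terms = paste(sort(.data$term), collapse = ";"))
  out <- ann$terms[match(gene_id, ann$gene_id)]
  ifelse(is.na(out), "", out)
}
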