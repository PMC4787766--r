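#' Configuration of the end-to-end pipeline
#'
#' Bundles the generator configuration, the named comparison plan, and all
#' stage thresholds.  Thresholds are validated up front so an invalid
#' configuration aborts before any stage runs.
#'
#' @param generator A [generator_config()] describing the synthetic input
#'   (ignored when `input_dir` is given).
#' @param input_dir Optional directory holding `counts.tsv`, `samples.tsv`,
#'   `genes.tsv` and `promoters.tsv` to analyse instead of simulating.
#' @param seed Master seed for every stage's randomness.
#' @param alpha_pairwise,alpha_timecourse Significance levels on adjusted
#'   p-values for pairwise and time-course/interaction designs.
#' @param jaccard_median,jaccard_sd_frac Cluster stability thresholds.
#' @param n_boot Bootstrap resamples per k.
#' @param k_max Largest k profiled (capped at `floor(n/20)` per set).
#' @param cluster_max_genes Gene sets larger than this are subsampled to
#'   this size before stability profiling.
#' @param cluster_min_genes Gene sets smaller than this are not clustered.
#' @param s_threshold,z_threshold Strong-target score and motif z cutoffs.
#' @param lambda Ridge penalty of the motif model, or `"cv"`.
#' @param compare_sets The two gene-set labels whose score distributions
#'   are compared (falls back to the two sets with most targets when
#'   either yields no testable motif).
#' @return A `pip3_pipeline_config`.
#' @export
pipeline_config <- function(generator = generator_config(),
                            input_dir = NULL,
                            seed = 1,
                            alpha_pairwise = 0.05,
                            alpha_timecourse = 0.01,
                            jaccard_median = 0.75,
                            jaccard_sd_frac = 0.10,
                            n_boot = 100,
                            k_max = 6,
                            cluster_max_genes = 300,
                            cluster_min_genes = 40,
                            s_threshold = 20,
                            z_threshold = 2,
                            lambda = "cv",
                            compare_sets = c("A", "B")) {
  for (nm in c("alpha_pairwise", "alpha_timecourse")) {
    v <- get(nm)
    if (!is.numeric(v) || v <= 0 || v >= 1) {
      abort(paste0(nm, " must lie strictly between 0 and 1"))
    }
  }
  if (jaccard_median < 0 || jaccard_median > 1) {
    abort("jaccard_median must lie in [0, 1]")
  }
  if (jaccard_sd_frac <= 0) abort("jaccard_sd_frac must be positive")
  if (n_boot < 2) abort("n_boot must be at least 2")
  if (z_threshold < 0) abort("z_threshold must be non-negative")
  structure(
    list(generator = generator, input_dir = input_dir, seed = as.integer(seed),
         alpha_pairwise = alpha_pairwise, alpha_timecourse = alpha_timecourse,
         jaccard_median = jaccard_median, jaccard_sd_frac = jaccard_sd_frac,
         n_boot = as.integer(n_boot), k_max = as.integer(k_max),
         cluster_max_genes = as.integer(cluster_max_genes),
         cluster_min_genes = as.integer(cluster_min_genes),
         s_threshold = s_threshold, z_threshold = z_threshold,
         lambda = lambda, compare_sets = compare_sets),
    class = "pip3_pipeline_config"
  )
}

#' The pipeline's named comparison plan
#'
#' The seven comparisons of the analysis: the basal-PI3K contrast
#' (inhibitor without EGF against the unstimulated wild type), the
#' EGF-induced PI3K contrast (inhibitor against wild-type time courses),
#' EGF dependence in the wild type, chronic baseline contrasts for each
#' mutant, and the mutant-against-wild-type time-course interactions.
#'
#' @param cfg A [pipeline_config()].
#' @return Named list of [comparison_spec()]s.
#' @export
standard_comparisons <- function(cfg = pipeline_config()) {
  ap <- cfg$alpha_pairwise
  at <- cfg$alpha_timecourse
  list(
    basal_pi3k = comparison_spec("pairwise", condition_a = "WT",
                                 condition_b = "A66_noEGF", time_a = 0,
                                 time_b = 300, alpha = ap,
                                 name = "basal_pi3k"),
    induced_pi3k = comparison_spec("interaction", condition_a = "WT",
                                   condition_b = "A66", alpha = at,
                                   name = "induced_pi3k"),
    egf_dep_wt = comparison_spec("timecourse", condition_a = "WT",
                                 alpha = at, name = "egf_dep_wt"),
    chronic_pten = comparison_spec("pairwise", condition_a = "WT",
                                   condition_b = "PTEN_KO", time_a = 0,
                                   time_b = 0, alpha = ap,
                                   name = "chronic_pten"),
    chronic_pik3ca = comparison_spec("pairwise", condition_a = "WT",
                                     condition_b = "PIK3CA_H1047R",
                                     time_a = 0, time_b = 0, alpha = ap,
                                     name = "chronic_pik3ca"),
    induced_pten = comparison_spec("interaction", condition_a = "WT",
                                   condition_b = "PTEN_KO", alpha = at,
                                   name = "induced_pten"),
    induced_pik3ca = comparison_spec("interaction", condition_a = "WT",
                                     condition_b = "PIK3CA_H1047R",
                                     alpha = at, name = "induced_pik3ca")
  )
}

write_stage <- function(df, dir, file) {
  readr::write_tsv(df, file.path(dir, file), progress = FALSE)
  file
}

num_fmt <- function(df) {
  { for (j in names(df)) if (is.double(df[[j]])) df[[j]] <- signif(df[[j]], 10); df }
}

#' Run the full analysis pipeline
#'
#' Chains simulate, differential expression, set construction, cluster
#' stability, motif activities, score comparison, enrichment and QC, and
#' writes every stage's tables plus a summary and a checksum MANIFEST into
#' `out_dir`.  Re-running with an identical configuration reproduces every
#' output byte for byte.  If a stage fails, the run aborts naming the
#' stage, and `MANIFEST.tsv` marks the run incomplete.
#'
#' @param cfg A [pipeline_config()].
#' @param out_dir Output directory.
#' @param quiet Suppress per-stage progress messages.
#' @return A `pip3_pipeline_result` list (invisibly): paths, per-stage row
#'   counts, the summary tibble, and key fitted objects.
#' @export
run_pipeline <- function(cfg = pipeline_config(), out_dir, quiet = FALSE) {
  stopifnot(inherits(cfg, "pip3_pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  files <- character(0)
  log <- list()
  say <- function(...) if (!quiet) message(sprintf(...))
  stage <- "simulate"
  result <- tryCatch({
    # --- simulate / load ------------------------------------------------
    if (is.null(cfg$input_dir)) {
      gen <- cfg$generator
      gen$seed <- cfg$seed
      sim <- generate_dataset(gen)
      ds <- sim$dataset
      sites <- sim$sites
      truth <- sim$truth
      annotation <- generate_annotation(truth, seed = cfg$seed)
      ds$genes$terms <- terms_column(annotation, ds$genes$gene_id)
      files <- c(files, unname(write_dataset(ds, out_dir)))
      files <- c(files, file.path(out_dir, "promoters.tsv"))
      write_motif_sites(sites, file.path(out_dir, "promoters.tsv"))
      files <- c(files, file.path(out_dir, "truth.tsv"))
      readr::write_tsv(truth$categories, file.path(out_dir, "truth.tsv"),
                       progress = FALSE)
    } else {
      ds <- read_dataset(file.path(cfg$input_dir, "counts.tsv"),
                         file.path(cfg$input_dir, "samples.tsv"),
                         file.path(cfg$input_dir, "genes.tsv"))
      sites <- read_motif_sites(file.path(cfg$input_dir, "promoters.tsv"))
      truth <- NULL
      annotation <- annotation_from_genes(ds$genes)
    }
    say("[%s] %d genes x %d samples", stage, nrow(ds$counts), ncol(ds$counts))
    log$simulate <- dim(ds$counts)

    # --- differential expression ---------------------------------------
    stage <- "de"
    sf <- estimate_size_factors(ds)
    specs <- standard_comparisons(cfg)
    de <- lapply(specs, function(sp) run_comparison(ds, sp, size_factors = sf))
    for (nm in names(de)) {
      files <- c(files, write_stage(num_fmt(tidy(de[[nm]])), out_dir,
                                    paste0("de_", nm, ".tsv")))
      say("[%s] %s: %d significant", stage, nm,
          sum(de[[nm]]$table$significant))
    }
    log$de <- vapply(de, function(d) sum(d$table$significant), numeric(1))

    # --- gene sets ------------------------------------------------------
    stage <- "sets"
    universe <- rownames(ds$counts)
    sig <- lapply(de, significant_genes)
    wt <- build_wt_sets(sig$basal_pi3k, sig$induced_pi3k, sig$egf_dep_wt,
                        universe)
    mut <- build_mutant_sets(sig$chronic_pten, sig$chronic_pik3ca,
                             union(sig$induced_pten, sig$induced_pik3ca),
                             sig$egf_dep_wt, universe)
    coh <- coherence_filter(list(
      PTEN_chronic = de_signed_outcome(de$chronic_pten),
      PIK3CA_chronic = de_signed_outcome(de$chronic_pik3ca),
      A66_vs_WT = de_signed_outcome(de$induced_pi3k),
      A66_noEGF = de_signed_outcome(de$basal_pi3k),
      PTEN_induced = de_signed_outcome(de$induced_pten),
      PIK3CA_induced = de_signed_outcome(de$induced_pik3ca)
    ))
    all_sets <- gene_set_collection(
      c(wt$sets$sets, mut$sets$sets,
        list(coherent_up = coh$coherent_up,
             coherent_down = coh$coherent_down)),
      universe
    )
    files <- c(files, file.path(out_dir, "genesets.tsv"))
    write_gene_sets(all_sets, file.path(out_dir, "genesets.tsv"))
    set_sizes <- tibble(
      set_label = names(all_sets$sets),
      n_genes = vapply(all_sets$sets, length, integer(1))
    )
    files <- c(files, write_stage(set_sizes, out_dir, "set_sizes.tsv"))
    say("[%s] %s", stage,
        paste(set_sizes$set_label, set_sizes$n_genes, collapse = " "))
    log$sets <- setNames(set_sizes$n_genes, set_sizes$set_label)

    # --- cluster stability ---------------------------------------------
    stage <- "cluster"
    norm <- normalize_counts(ds, "sizefactor", size_factors = sf)
    lognorm <- log(norm + 1)
    cluster_labels <- list()
    stab_rows <- list()
    kopt <- list()
    to_cluster <- c("set1", "set2", "set3", "set4", "coherent_up",
                    "coherent_down")
    for (lab in to_cluster) {
      members <- all_sets$sets[[lab]]
      if (length(members) < cfg$cluster_min_genes) next
      if (length(members) > cfg$cluster_max_genes) {
        members <- withr::with_seed(cfg$seed,
          sort(sample(members, cfg$cluster_max_genes)))
      }
      X <- scale_center_profiles(lognorm[members, , drop = FALSE])
      kmax <- max(2, min(cfg$k_max, floor(length(members) / 20)))
      st <- cluster_stability(X, k_range = 2:kmax, n_boot = cfg$n_boot,
                              seed = cfg$seed,
                              jaccard_median = cfg$jaccard_median,
                              sd_frac = cfg$jaccard_sd_frac)
      kopt[[lab]] <- st$optimal_k
      kc <- if (is.na(st$optimal_k)) 2L else st$optimal_k
      labels <- st$runs[[as.character(kc)]]$reference$labels
      cluster_labels[[lab]] <- tibble(
        gene_id = names(labels), set_label = lab,
        k_opt = st$optimal_k, cluster = unname(labels))
      stab_rows[[lab]] <- mutate(tidy(st), set_label = lab, .before = 1)
      say("[%s] %s: optimal k = %s", stage, lab,
          ifelse(is.na(st$optimal_k), "none", st$optimal_k))
    }
    files <- c(files, write_stage(bind_rows(cluster_labels), out_dir,
                                  "clusters.tsv"))
    files <- c(files, write_stage(num_fmt(bind_rows(stab_rows)), out_dir,
                                  "stability.tsv"))
    log$cluster <- kopt

    # --- motif activities ----------------------------------------------
    stage <- "motifs"
    E <- promoter_expression(ds, sites, size_factors = sf)
    model <- fit_motif_activities(E, sites, lambda = cfg$lambda,
                                  cv_seed = cfg$seed)
    spm <- target_scores(model)
    sm <- dedup_to_genes(spm)
    strong <- strongly_regulated(sm, model, all_sets,
                                 s_threshold = cfg$s_threshold,
                                 z_threshold = cfg$z_threshold)
    act <- dplyr::bind_cols(tibble(motif = rownames(model$activities)),
                            as_tibble(as.data.frame(model$activities,
                                                    check.names = FALSE)))
    files <- c(files, write_stage(num_fmt(act), out_dir, "activities.tsv"))
    files <- c(files, write_stage(num_fmt(model$z), out_dir, "motif_z.tsv"))
    files <- c(files, write_stage(num_fmt(sm), out_dir, "sm_scores.tsv"))
    files <- c(files, write_stage(num_fmt(strong), out_dir,
                                  "strong_targets.tsv"))
    say("[%s] lambda = %.3g, %d motifs with z >= %g, %d strong targets",
        stage, model$lambda, sum(model$z$z >= cfg$z_threshold),
        cfg$z_threshold, nrow(strong))
    log$motifs <- c(lambda = model$lambda, strong = nrow(strong))

    # --- score-distribution comparison ----------------------------------
    stage <- "compare"
    cmp_sets <- cfg$compare_sets
    cmp <- suppressWarnings(compare_sm_distributions(
      sm, all_sets$sets[[cmp_sets[1]]], all_sets$sets[[cmp_sets[2]]],
      model, z_threshold = cfg$z_threshold))
    if (!any(cmp$tested)) {
      # fall back to the two sets with the most scored targets
      counts_by_set <- vapply(all_sets$sets, function(s)
        sum(sm$gene_id %in% s), integer(1))
      cmp_sets <- names(sort(counts_by_set, decreasing = TRUE))[1:2]
      cmp <- suppressWarnings(compare_sm_distributions(
        sm, all_sets$sets[[cmp_sets[1]]], all_sets$sets[[cmp_sets[2]]],
        model, z_threshold = cfg$z_threshold))
    }
    files <- c(files, write_stage(num_fmt(mutate(as_tibble(cmp),
      set_a = cmp_sets[1], set_b = cmp_sets[2])), out_dir, "comparison.tsv"))
    say("[%s] %s vs %s: top motif %s", stage, cmp_sets[1], cmp_sets[2],
        ifelse(any(cmp$tested), cmp$motif[1], "none"))
    log$compare <- cmp_sets

    # --- enrichment ------------------------------------------------------
    stage <- "enrich"
    enr <- bind_rows(lapply(names(all_sets$sets), function(lab) {
      s <- all_sets$sets[[lab]]
      if (length(s) == 0) return(NULL)
      mutate(fisher_enrichment(s, universe, annotation),
             set_label = lab, .before = 1)
    }))
    files <- c(files, write_stage(num_fmt(enr), out_dir, "enrichment.tsv"))
    log$enrich <- nrow(enr)

    # --- QC ---------------------------------------------------------------
    stage <- "qc"
    cm <- sample_correlation_matrix(lognorm)
    corr <- dplyr::bind_cols(tibble(sample_id = rownames(cm)),
                             as_tibble(as.data.frame(cm,
                                                     check.names = FALSE)))
    files <- c(files, write_stage(num_fmt(corr), out_dir, "corr.tsv"))
    pca <- pca_samples(lognorm, ds$samples)
    pca_tab <- mutate(tidy(pca)[, 1:4],
                      var_frac_pc1 = pca$variance_fraction[1],
                      var_frac_pc2 = pca$variance_fraction[2])
    files <- c(files, write_stage(num_fmt(pca_tab), out_dir, "pca.tsv"))

    # --- summary ----------------------------------------------------------
    stage <- "summary"
    n_sig <- vapply(de, function(d) sum(d$table$significant), numeric(1))
    butterfly <- butterfly_ratio(de)
    top_z <- head(arrange(model$z, desc(.data$z)), 5)
    top_d <- head(filter(as_tibble(cmp), .data$tested), 5)
    summary <- bind_rows(
      tibble(section = "significant_genes", key = names(n_sig),
             value = as.character(n_sig)),
      tibble(section = "set_sizes", key = set_sizes$set_label,
             value = as.character(set_sizes$n_genes)),
      tibble(section = "optimal_k", key = names(kopt),
             value = as.character(unlist(kopt))),
      tibble(section = "butterfly_ratio",
             key = c("chronic_over_acute", "chronic_over_acute_pairwise"),
             value = sprintf("%.4f", c(butterfly,
                                       attr(butterfly, "pairwise")))),
      tibble(section = "top_motifs_by_z", key = top_z$motif,
             value = sprintf("%.4f", top_z$z)),
      tibble(section = "top_motifs_by_D", key = top_d$motif,
             value = sprintf("%.4f", top_d$ks_d))
    )
    files <- c(files, write_stage(summary, out_dir, "summary.tsv"))
    list(de = de, sets = all_sets, model = model, sm = sm, cmp = cmp,
         summary = summary, butterfly = butterfly, kopt = kopt,
         truth = truth)
  }, error = function(e) {
    manifest_write(out_dir, files, complete = FALSE)
    abort(sprintf("pipeline failed at stage '%s': %s", stage,
                  conditionMessage(e)), parent = e)
  })

  files <- c(files, "MANIFEST.tsv")
  manifest_write(out_dir, setdiff(files, "MANIFEST.tsv"), complete = TRUE)
  say("pipeline complete in %.1f s", as.numeric(Sys.time() - t0, "secs"))
  invisible(structure(
    c(result, list(out_dir = out_dir, files = files, log = log,
                   config = cfg)),
    class = "pip3_pipeline_result"
  ))
}

#' Chronic-over-acute breadth ratio
#'
#' Quantifies the "butterfly" asymmetry of the perturbations: how many more
#' genes chronic genetic perturbation changes than acute pharmacological
#' inhibition does.  To compare breadth rather than statistical power, the
#' counts come from comparisons with matched designs and thresholds: the
#' two mutant-against-wild-type time-course interaction comparisons versus
#' the inhibitor-against-wild-type interaction comparison, all three with
#' identical sample layout and the same adjusted-p level.
#'
#' @param de Named list of `pip3_de` results containing `induced_pten`,
#'   `induced_pik3ca` and `induced_pi3k` (and, for the secondary pairwise
#'   variant, `chronic_pten` and `chronic_pik3ca`).
#' @param alpha Matched adjusted-p level (default 0.01, the time-course
#'   design level).
#' @return Mean significant-gene count of the two mutant comparisons
#'   divided by the acute inhibitor comparison's count.  Attribute
#'   `"pairwise"` carries the same ratio computed from the baseline-only
#'   pairwise chronic comparisons (a lower-powered design).
#' @export
butterfly_ratio <- function(de, alpha = 0.01) {
  count_at <- function(d) sum(d$table$padj < alpha, na.rm = TRUE)
  acute <- max(count_at(de$induced_pi3k), 1)
  main <- mean(c(count_at(de$induced_pten), count_at(de$induced_pik3ca))) /
    acute
  pw <- mean(c(count_at(de$chronic_pten), count_at(de$chronic_pik3ca))) /
    acute
  structure(main, pairwise = pw)
}

manifest_write <- function(out_dir, files, complete) {
  files <- basename(files)
  paths <- file.path(out_dir, files)
  ok <- file.exists(paths)
  mf <- tibble(
    file = files[ok],
    md5 = unname(tools::md5sum(paths[ok])),
    status = if (complete) "complete" else "incomplete"
  )
  readr::write_tsv(mf, file.path(out_dir, "MANIFEST.tsv"), progress = FALSE)
}

# rebuild a gene_id/term annotation from the genes table's terms column
annotation_from_genes <- function(genes) {
  if (!"terms" %in% names(genes)) return(tibble(gene_id = character(0),
                                                term = character(0)))
  keep <- !is.na(genes$terms) & genes$terms != ""
  tibble(gene_id = rep(genes$gene_id[keep],
                       lengths(strsplit(genes$terms[keep], ";"))),
         term = unlist(strsplit(genes$terms[keep], ";")))
}

#' @export
print.pip3_pipeline_result <- function(x, ...) {
  cat(sprintf("<pip3_pipeline_result> %s (%d files)\n", x$out_dir,
              length(x$files)))
  invisible(x)
}
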