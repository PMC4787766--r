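#' Venn-region partition of named gene sets
#'
#' Splits the union of the input sets into its `2^n - 1` non-empty-pattern
#' regions.  Region labels are the set labels joined by `&` (genes inside
#' every named set and outside all the others).
#'
#' @param named_sets Named list of character vectors of gene ids.
#' @param universe Character vector containing every member.
#' @return Tibble with columns `region` (label), `pattern`
#'   (binary membership string in input-set order) and `genes` (list
#'   column); regions partition the union of the inputs.
#' @export
venn_regions <- function(named_sets, universe) {
  stopifnot(length(named_sets) >= 1, !is.null(names(named_sets)))
  all_members <- unique(unlist(named_sets))
  out <- setdiff(all_members, universe)
  if (length(out) > 0) {
    abort(paste0("set member(s) outside the universe: ",
                 paste(head(out, 5), collapse = ", ")))
  }
  labs <- names(named_sets)
  memb <- vapply(named_sets, function(s) all_members %in% s,
                 logical(length(all_members)))
  if (length(all_members) == 1) memb <- matrix(memb, nrow = 1)
  pattern <- apply(memb, 1, function(r) paste(as.integer(r), collapse = ""))
  pats <- sort(unique(pattern))
  regions <- vapply(pats, function(p) {
    inset <- strsplit(p, "")[[1]] == "1"
    paste(labs[inset], collapse = "&")
  }, character(1))
  genes <- lapply(pats, function(p) sort(all_members[pattern == p]))
  tibble(pattern = pats, region = unname(regions), genes = genes)
}

region_lookup <- function(regions, pattern) {
  hit <- regions$genes[regions$pattern == pattern]
  if (length(hit) == 0) character(0) else hit[[1]]
}

#' Build the wild-type analysis gene sets (sets 1-4)
#'
#' Overlaps the three wild-type comparisons - genes responding to the basal
#' activity of PI3K (inhibitor without EGF against the unstimulated
#' baseline), genes whose EGF response is altered by acute PI3K inhibition
#' (EGF-induced activity), and all EGF-dependent genes - into the four
#' labelled sets:
#' * `set1` - basal and EGF-dependent, but not EGF-induced.
#' * `set2` - basal activity only.
#' * `set3` - basal and EGF-induced (regardless of EGF dependence).
#' * `set4` - EGF-induced and EGF-dependent, but not basal.
#'
#' The full seven-region partition is returned alongside, so alternative
#' readings of the region-to-label mapping can be recovered.
#'
#' @param basal,induced,egf_dep Character vectors of gene ids.
#' @param universe All gene ids in scope.
#' @param mapping Optional named list overriding the default label
#'   definitions; each element is a function of the three sets returning a
#'   character vector.
#' @return List with `sets` (a [gene_set_collection()] holding set1-set4)
#'   and `regions` (the full Venn partition over inputs named
#'   basal/induced/egf_dep).
#' @export
build_wt_sets <- function(basal, induced, egf_dep, universe,
                          mapping = NULL) {
  regions <- venn_regions(
    list(basal = basal, induced = induced, egf_dep = egf_dep), universe)
  mapping <- mapping %||% list(
    set1 = function(b, i, e) setdiff(intersect(b, e), i),
    set2 = function(b, i, e) setdiff(b, union(i, e)),
    set3 = function(b, i, e) intersect(b, i),
    set4 = function(b, i, e) setdiff(intersect(i, e), b)
  )
  sets <- lapply(mapping, function(f) f(basal, induced, egf_dep))
  list(sets = gene_set_collection(sets, universe), regions = regions)
}

#' Build the mutant analysis gene sets (sets A-H)
#'
#' Classifies genes by their chronic mutant pattern (affected by both
#' mutants, by PIK3CA H1047R only, by PTEN KO only, or by neither) crossed
#' with EGF dependence in the wild type:
#' * `A`/`B` - chronic in both mutants, EGF-dependent / EGF-insensitive.
#' * `C`/`D` - chronic in PIK3CA H1047R only, EGF-dependent / insensitive.
#' * `E`/`F` - chronic in PTEN KO only, EGF-dependent / insensitive.
#' * `G`/`H` - no chronic effect but affected during EGF stimulation in at
#'   least one mutant (`induced_combined`), EGF-dependent / insensitive.
#'
#' @param chronic_pten,chronic_pik3ca Genes changed by each mutation at
#'   baseline.
#' @param induced_combined Genes whose EGF time course differs in either
#'   mutant.
#' @param egf_dep EGF-dependent genes in the wild type.
#' @param universe All gene ids in scope.
#' @return List with `sets` (collection A-H) and `regions` (the full
#'   15-region partition of the four inputs).
#' @export
build_mutant_sets <- function(chronic_pten, chronic_pik3ca,
                              induced_combined, egf_dep, universe) {
  regions <- venn_regions(
    list(chronic_pten = chronic_pten, chronic_pik3ca = chronic_pik3ca,
         induced = induced_combined, egf_dep = egf_dep),
    universe
  )
  both <- intersect(chronic_pten, chronic_pik3ca)
  pik_only <- setdiff(chronic_pik3ca, chronic_pten)
  pten_only <- setdiff(chronic_pten, chronic_pik3ca)
  neither_induced <- setdiff(induced_combined,
                             union(chronic_pten, chronic_pik3ca))
  sets <- list(
    A = intersect(both, egf_dep),
    B = setdiff(both, egf_dep),
    C = intersect(pik_only, egf_dep),
    D = setdiff(pik_only, egf_dep),
    E = intersect(pten_only, egf_dep),
    F = setdiff(pten_only, egf_dep),
    G = intersect(neither_induced, egf_dep),
    H = setdiff(neither_induced, egf_dep)
  )
  list(sets = gene_set_collection(sets, universe), regions = regions)
}

#' Direction-coherence ("PIP3 logic") filter
#'
#' Retains genes whose responses across all six perturbation comparisons are
#' mutually consistent with the direction of PIP3 signalling: coherent-up
#' genes are significantly up in every PTEN-KO and PIK3CA-H1047R comparison
#' (chronic and EGF-induced) and significantly down in both A66 comparisons
#' (with and without EGF); coherent-down genes are the mirror image.  All
#' other genes are excluded.
#'
#' @param outcomes Named list of signed outcomes (from
#'   [de_signed_outcome()]) with names `PTEN_chronic`, `PIK3CA_chronic`,
#'   `A66_vs_WT`, `A66_noEGF`, `PTEN_induced`, `PIK3CA_induced`.
#' @return List with character vectors `coherent_up` and `coherent_down`.
#' @export
coherence_filter <- function(outcomes) {
  need <- c("PTEN_chronic", "PIK3CA_chronic", "A66_vs_WT", "A66_noEGF",
            "PTEN_induced", "PIK3CA_induced")
  miss <- setdiff(need, names(outcomes))
  if (length(miss) > 0) {
    abort(paste0("missing comparison(s): ", paste(miss, collapse = ", ")))
  }
  gene_id <- outcomes[[need[1]]]$gene_id
  signs <- vapply(need, function(nm) {
    o <- outcomes[[nm]]
    s <- o$sign[match(gene_id, o$gene_id)]
    if (anyNA(s)) abort(paste0("comparison '", nm,
                               "' is missing genes present in others"))
    s
  }, numeric(length(gene_id)))
  signs <- matrix(signs, nrow = length(gene_id),
                  dimnames = list(gene_id, need))
  up_pattern <- c(PTEN_chronic = 1, PIK3CA_chronic = 1, A66_vs_WT = -1,
                  A66_noEGF = -1, PTEN_induced = 1, PIK3CA_induced = 1)
  is_up <- rowSums(signs == rep(up_pattern[need], each = length(gene_id))) ==
    length(need)
  is_down <- rowSums(signs == rep(-up_pattern[need],
                                  each = length(gene_id))) == length(need)
  list(coherent_up = gene_id[is_up], coherent_down = gene_id[is_down])
}
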