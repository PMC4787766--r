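#' Assemble a validated expression dataset
#'
#' Bundles a gene-by-sample count matrix with its sample sheet and gene
#' annotation into a single validated object, the common currency of all
#' downstream stages.
#'
#' @param counts Integer matrix (genes x samples) with row and column names,
#'   or a data frame whose first column holds gene ids.
#' @param samples Data frame with columns `sample_id`, `condition`,
#'   `time_min`, `replicate`.  Column order of `counts` is rearranged to
#'   follow the sample sheet.
#' @param genes Data frame with columns `gene_id`, `length_bp` and an
#'   optional `terms` column (semicolon-separated annotation terms).
#'
#' @return A `pip3_dataset`: a list with elements `counts` (integer matrix),
#'   `samples` and `genes` (tibbles).
#' @export
pip3_dataset <- function(counts, samples, genes) {
  if (is.data.frame(counts)) {
    m <- as.matrix(counts[, -1, drop = FALSE])
    rownames(m) <- as.character(counts[[1]])
    counts <- m
  }
  samples <- as_tibble(samples)
  genes <- as_tibble(genes)
  ds <- structure(
    list(counts = counts, samples = samples, genes = genes),
    class = "pip3_dataset"
  )
  validate_dataset(ds)
}

#' Validate a dataset against its invariants
#'
#' Checks that counts are non-negative integers, that gene ids are unique and
#' match the annotation, that the sample sheet describes every count column
#' (and nothing else), that conditions and times belong to the study design,
#' that (condition, time, replicate) triples are unique, and that unstimulated
#' inhibitor-only (`A66_noEGF`) samples carry the single 300-minute library
#' the design provides.
#'
#' @param ds A `pip3_dataset`.
#' @return `ds`, invisibly unchanged, with columns ordered per sample sheet.
#' @export
validate_dataset <- function(ds) {
  counts <- ds$counts
  samples <- ds$samples
  genes <- ds$genes

  need <- c("sample_id", "condition", "time_min", "replicate")
  miss <- setdiff(need, names(samples))
  if (length(miss) > 0) {
    abort(paste0("sample sheet is missing column(s): ",
                 paste(miss, collapse = ", ")))
  }
  if (!all(c("gene_id", "length_bp") %in% names(genes))) {
    abort("gene annotation must have columns gene_id and length_bp")
  }
  if (anyDuplicated(rownames(counts))) {
    dup <- rownames(counts)[duplicated(rownames(counts))][1]
    abort(paste0("duplicate gene id in counts: ", dup))
  }
  if (anyDuplicated(genes$gene_id)) {
    abort(paste0("duplicate gene id in annotation: ",
                 genes$gene_id[duplicated(genes$gene_id)][1]))
  }
  if (!setequal(rownames(counts), genes$gene_id)) {
    abort("gene ids of counts and annotation do not match")
  }
  genes <- genes[match(rownames(counts), genes$gene_id), ]
  if (any(!is.finite(genes$length_bp)) || any(genes$length_bp <= 0)) {
    abort("gene lengths must be positive")
  }

  orphan <- setdiff(colnames(counts), samples$sample_id)
  if (length(orphan) > 0) {
    abort(paste0("count column(s) absent from sample sheet: ",
                 paste(orphan, collapse = ", ")))
  }
  absent <- setdiff(samples$sample_id, colnames(counts))
  if (length(absent) > 0) {
    abort(paste0("sample sheet row(s) with no count column: ",
                 paste(absent, collapse = ", ")))
  }
  counts <- counts[, samples$sample_id, drop = FALSE]

  bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts),
               arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(sprintf(
      "non-integer or negative count %s at gene '%s', sample '%s'",
      format(counts[bad[1, 1], bad[1, 2]]),
      rownames(counts)[bad[1, 1]], colnames(counts)[bad[1, 2]]
    ))
  }
  storage.mode(counts) <- "integer"

  badc <- setdiff(unique(samples$condition), PIP3_CONDITIONS)
  if (length(badc) > 0) {
    abort(paste0("unknown condition(s): ", paste(badc, collapse = ", ")))
  }
  badt <- setdiff(unique(samples$time_min), PIP3_TIMES)
  if (length(badt) > 0) {
    abort(paste0("unknown time point(s): ", paste(badt, collapse = ", ")))
  }
  key <- paste(samples$condition, samples$time_min, samples$replicate)
  if (anyDuplicated(key)) {
    abort(paste0("duplicate (condition, time, replicate) triple: ",
                 key[duplicated(key)][1]))
  }
  noegf <- samples$time_min[samples$condition == "A66_noEGF"]
  if (length(noegf) > 0 && any(noegf != 300L)) {
    abort("A66_noEGF samples must carry time_min = 300 only")
  }

  structure(list(counts = counts, samples = samples, genes = genes),
            class = "pip3_dataset")
}

#' @export
print.pip3_dataset <- function(x, ...) {
  cat(sprintf("<pip3_dataset> %d genes x %d samples, %d condition/time groups\n",
              nrow(x$counts), ncol(x$counts),
              nrow(distinct(x$samples, .data$condition, .data$time_min))))
  invisible(x)
}

#' @export
dim.pip3_dataset <- function(x) dim(x$counts)

#' Read a dataset from tab-separated files
#'
#' Reads a count matrix, a sample sheet and a gene annotation from TSV files
#' (header row, UTF-8, unquoted) and returns a validated dataset.  Parse
#' problems are reported naming the offending file, row and column.
#'
#' @param counts_path TSV with `gene_id` in the first column and one column
#'   per sample.
#' @param samples_path TSV with columns `sample_id`, `condition`, `time_min`,
#'   `replicate`.
#' @param genes_path TSV with columns `gene_id`, `length_bp` and optionally
#'   `terms`.
#' @return A validated [pip3_dataset()].
#' @export
read_dataset <- function(counts_path, samples_path, genes_path) {
  for (p in c(counts_path, samples_path, genes_path)) {
    if (!file.exists(p)) abort(paste0("file not found: ", p))
  }
  counts_df <- readr::read_tsv(counts_path, col_types = readr::cols(
    .default = readr::col_double(),
    gene_id = readr::col_character()
  ), progress = FALSE)
  if (names(counts_df)[1] != "gene_id") {
    abort(paste0(counts_path, ": first column must be gene_id, found '",
                 names(counts_df)[1], "'"))
  }
  num <- as.matrix(counts_df[, -1, drop = FALSE])
  frac <- which(is.finite(num) & num != round(num), arr.ind = TRUE)
  if (nrow(frac) > 0) {
    abort(sprintf(
      "%s: non-integer count %s at row %d (gene '%s'), column '%s'",
      counts_path, format(num[frac[1, 1], frac[1, 2]]), frac[1, 1] + 1L,
      counts_df$gene_id[frac[1, 1]], colnames(num)[frac[1, 2]]
    ))
  }
  samples <- readr::read_tsv(samples_path, col_types = readr::cols(
    sample_id = readr::col_character(),
    condition = readr::col_character(),
    time_min = readr::col_integer(),
    replicate = readr::col_integer()
  ), progress = FALSE)
  genes <- readr::read_tsv(genes_path, col_types = readr::cols(
    gene_id = readr::col_character(),
    length_bp = readr::col_double(),
    .default = readr::col_character()
  ), progress = FALSE)
  pip3_dataset(counts_df, samples, genes)
}

#' Write a dataset to tab-separated files
#'
#' Inverse of [read_dataset()]; `read_dataset()` on the written files
#' round-trips the dataset exactly, and re-writing what was read reproduces
#' the files byte for byte.
#'
#' @param ds A `pip3_dataset`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the three file paths, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    counts = file.path(dir, "counts.tsv"),
    samples = file.path(dir, "samples.tsv"),
    genes = file.path(dir, "genes.tsv")
  )
  counts_df <- bind_cols_counts(ds$counts)
  readr::write_tsv(counts_df, paths["counts"], progress = FALSE)
  readr::write_tsv(ds$samples, paths["samples"], progress = FALSE)
  readr::write_tsv(ds$genes, paths["genes"], progress = FALSE)
  invisible(paths)
}

bind_cols_counts <- function(m) {
  out <- as_tibble(as.data.frame(m, check.names = FALSE))
  dplyr::bind_cols(tibble(gene_id = rownames(m)), out)
}

#' Construct a gene-set collection
#'
#' A named list of gene sets over a declared gene universe; every member must
#' belong to the universe.
#'
#' @param sets Named list of character vectors of gene ids.
#' @param universe Character vector of all gene ids in scope.
#' @return A `pip3_gene_sets` object.
#' @export
gene_set_collection <- function(sets, universe) {
  if (is.null(names(sets)) || any(names(sets) == "")) {
    abort("every gene set must be named")
  }
  universe <- unique(as.character(universe))
  sets <- lapply(sets, function(x) unique(as.character(x)))
  for (lab in names(sets)) {
    out <- setdiff(sets[[lab]], universe)
    if (length(out) > 0) {
      abort(sprintf("gene set '%s' has member(s) outside the universe: %s",
                    lab, paste(head(out, 5), collapse = ", ")))
    }
  }
  structure(list(sets = sets, universe = universe), class = "pip3_gene_sets")
}

#' @export
print.pip3_gene_sets <- function(x, ...) {
  cat(sprintf("<pip3_gene_sets> %d sets over %d genes\n",
              length(x$sets), length(x$universe)))
  invisible(x)
}

#' Read and write gene-set collections
#'
#' `genesets.tsv` holds one (set_label, gene_id) pair per line; the universe
#' is stored under the reserved label `.universe` so that
#' `read_gene_sets(write_gene_sets(x)) == x` for any valid collection,
#' including collections containing empty sets (written with an empty
#' gene_id field).
#'
#' @param collection A `pip3_gene_sets` object.
#' @param path Path of the TSV file.
#' @return `write_gene_sets` returns `path` invisibly; `read_gene_sets`
#'   returns a `pip3_gene_sets`.
#' @export
write_gene_sets <- function(collection, path) {
  stopifnot(inherits(collection, "pip3_gene_sets"))
  rows <- purrr::imap(collection$sets, function(members, lab) {
    if (length(members) == 0) {
      tibble(set_label = lab, gene_id = "")
    } else {
      tibble(set_label = lab, gene_id = members)
    }
  })
  uni <- tibble(set_label = ".universe", gene_id = collection$universe)
  readr::write_tsv(bind_rows(bind_rows(rows), uni), path, progress = FALSE)
  invisible(path)
}

#' @rdname write_gene_sets
#' @export
read_gene_sets <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    set_label = readr::col_character(),
    gene_id = readr::col_character()
  ), progress = FALSE)
  df$gene_id[is.na(df$gene_id)] <- ""
  universe <- df$gene_id[df$set_label == ".universe"]
  df <- df[df$set_label != ".universe", , drop = FALSE]
  labs <- unique(df$set_label)
  sets <- lapply(labs, function(lab) {
    m <- df$gene_id[df$set_label == lab]
    m[m != ""]
  })
  names(sets) <- labs
  gene_set_collection(sets, universe)
}

#' Read and write motif site-count matrices
#'
#' `promoters.tsv` has columns `promoter_id`, `gene_id`, then one non-negative
#' integer column per motif.  Every promoter maps to exactly one gene; a gene
#' may own several promoters.
#'
#' @param sites A `pip3_motif_sites` object (see [motif_sites()]).
#' @param path Path of the TSV file.
#' @return `write_motif_sites` returns `path` invisibly; `read_motif_sites`
#'   returns a `pip3_motif_sites`.
#' @export
write_motif_sites <- function(sites, path) {
  stopifnot(inherits(sites, "pip3_motif_sites"))
  df <- dplyr::bind_cols(
    sites$promoter_map,
    as_tibble(as.data.frame(sites$N, check.names = FALSE))
  )
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_motif_sites
#' @export
read_motif_sites <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    promoter_id = readr::col_character(),
    gene_id = readr::col_character(),
    .default = readr::col_double()
  ), progress = FALSE)
  N <- as.matrix(df[, setdiff(names(df), c("promoter_id", "gene_id")),
                    drop = FALSE])
  rownames(N) <- df$promoter_id
  motif_sites(N, df[, c("promoter_id", "gene_id")])
}

#' Construct a motif site-count matrix
#'
#' @param N Promoters x motifs matrix of non-negative integer site counts,
#'   with promoter ids as row names and motif names as column names.
#' @param promoter_map Data frame with columns `promoter_id`, `gene_id`.
#' @return A `pip3_motif_sites` object.
#' @export
motif_sites <- function(N, promoter_map) {
  promoter_map <- as_tibble(promoter_map)
  if (!setequal(rownames(N), promoter_map$promoter_id) ||
      anyDuplicated(promoter_map$promoter_id)) {
    abort("promoter ids of the site matrix and map must match one-to-one")
  }
  if (any(N < 0) || any(N != round(N))) {
    abort("site counts must be non-negative integers")
  }
  N <- N[promoter_map$promoter_id, , drop = FALSE]
  structure(list(N = N, promoter_map = promoter_map),
            class = "pip3_motif_sites")
}
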