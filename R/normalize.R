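#' Median-of-ratios size factors
#'
#' For each sample, the size factor is the median over genes (restricted to
#' genes with strictly positive counts in every sample) of the ratio between
#' the sample's count and the gene's geometric mean across samples.
#'
#' @param counts Gene x sample count matrix, or a `pip3_dataset`.
#' @return Named numeric vector of positive size factors, one per sample.
#' @export
estimate_size_factors <- function(counts) {
  if (inherits(counts, "pip3_dataset")) counts <- counts$counts
  counts <- as.matrix(counts)
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos)) {
    abort(paste0(
      "no gene has positive counts in every sample; size factors are ",
      "undefined under the median-of-ratios method (consider filtering ",
      "samples or using a pseudo-reference)"
    ))
  }
  cp <- counts[pos, , drop = FALSE]
  ref <- exp(rowMeans(log(cp)))
  sf <- apply(cp / ref, 2, median)
  setNames(sf, colnames(counts))
}

#' Normalize a count matrix
#'
#' `sizefactor` divides each column by its median-of-ratios size factor;
#' `rpkm` computes reads per kilobase of gene model per million mapped reads,
#' with the library size taken as the column sum.
#'
#' @param ds A `pip3_dataset`.
#' @param mode `"sizefactor"` or `"rpkm"`.
#' @param size_factors Optional precomputed size factors.
#' @return Numeric matrix with the dimensions of the count matrix.
#' @export
normalize_counts <- function(ds, mode = c("sizefactor", "rpkm"),
                             size_factors = NULL) {
  stopifnot(inherits(ds, "pip3_dataset"))
  mode <- match.arg(mode)
  counts <- ds$counts
  if (mode == "sizefactor") {
    sf <- size_factors %||% estimate_size_factors(counts)
    sweep(counts, 2, sf, `/`)
  } else {
    len <- ds$genes$length_bp[match(rownames(counts), ds$genes$gene_id)]
    bad <- rownames(counts)[!is.finite(len) | len <= 0]
    if (length(bad) > 0) {
      abort(paste0("missing or invalid gene length for: ",
                   paste(head(bad, 5), collapse = ", ")))
    }
    libsize <- colSums(counts)
    counts / (len / 1000) %o% (libsize / 1e6)
  }
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment; `NA` values are propagated.
#'
#' @param pvalues Numeric vector of p-values in \code{[0, 1]}.
#' @return Numeric vector of adjusted p-values.
#' @export
bh_adjust <- function(pvalues) {
  ok <- !is.na(pvalues)
  if (any(pvalues[ok] < 0 | pvalues[ok] > 1)) {
    abort("p-values must lie in [0, 1]")
  }
  p.adjust(pvalues, method = "BH")
}
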