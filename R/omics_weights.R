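#' Median-of-ratios normalization of a UMI count matrix
#'
#' Computes per-sample size factors as the median, over genes with an
#' all-positive count row, of the ratio of each gene's count to its geometric
#' mean across samples, then divides each sample column by its factor. Genes
#' with a total count of zero are removed before factor computation; genes
#' containing any zero count are excluded from factor estimation but retained
#' in the normalized output.
#'
#' @param counts gene x sample matrix of nonnegative integers with gene ids
#'   as rownames, or a data frame/tibble whose first column holds gene ids.
#' @return object of class `mor_normalization`: list with `size_factors`
#'   (named numeric per sample), `normalized` (tibble: gene column + one
#'   column per sample), `removed_genes` (zero-total genes dropped).
#' @export
median_of_ratios <- function(counts) {
  if (is.data.frame(counts)) {
    genes <- as.character(counts[[1]])
    mat <- as.matrix(counts[, -1, drop = FALSE])
    rownames(mat) <- genes
  } else {
    mat <- as.matrix(counts)
    if (is.null(rownames(mat))) {
      abort("count matrix needs gene ids as rownames.")
    }
  }
  storage.mode(mat) <- "double"
  if (any(!is.finite(mat)) || any(mat < 0)) {
    abort("counts must be finite and nonnegative.")
  }
  if (anyDuplicated(rownames(mat))) abort("duplicate gene ids.")

  zero_total <- rowSums(mat) == 0
  removed <- rownames(mat)[zero_total]
  mat <- mat[!zero_total, , drop = FALSE]

  all_positive <- rowSums(mat > 0) == ncol(mat)
  if (!any(all_positive)) {
    abort(paste0("median-of-ratios normalization needs at least one gene ",
                 "with positive counts in every sample."))
  }
  ref <- mat[all_positive, , drop = FALSE]
  geomean <- exp(rowMeans(log(ref)))
  ratios <- sweep(ref, 1, geomean, "/")
  size_factors <- apply(ratios, 2, median)
  normalized <- sweep(mat, 2, size_factors, "/")

  structure(
    list(size_factors = size_factors,
         normalized = bind_cols(tibble(gene = rownames(mat)),
                                as_tibble(normalized)),
         removed_genes = removed),
    class = "mor_normalization")
}

#' @export
print.mor_normalization <- function(x, ...) {
  cat(sprintf("<mor_normalization> %d genes x %d samples; size factors: %s\n",
              nrow(x$normalized), length(x$size_factors),
              paste(signif(x$size_factors, 4), collapse = ", ")))
  invisible(x)
}

#' Gene weights from normalized expression
#'
#' The weight of each gene is `log2` of its mean normalized expression across
#' samples; genes at or above the threshold are flagged active. All-zero
#' genes get weight `-Inf` and are inactive. The default threshold -3
#' corresponds to a mean normalized expression of 0.125.
#'
#' @param normalized a [median_of_ratios()] result, or a tibble/matrix of
#'   normalized expression (same layouts as [median_of_ratios()] input).
#' @param threshold weight threshold on the log2 scale (default -3).
#' @return tibble with columns `gene`, `weight`, `active`; the threshold is
#'   stored as an attribute.
#' @export
gene_weights <- function(normalized, threshold = -3) {
  stopifnot_scalar_number(threshold, "threshold")
  if (inherits(normalized, "mor_normalization")) {
    normalized <- normalized$normalized
  }
  if (is.data.frame(normalized)) {
    genes <- as.character(normalized[[1]])
    mat <- as.matrix(normalized[, -1, drop = FALSE])
  } else {
    mat <- as.matrix(normalized)
    genes <- rownames(mat)
  }
  mean_expr <- rowMeans(mat)
  weight <- ifelse(mean_expr > 0, log2(mean_expr), -Inf)
  out <- tibble(gene = genes, weight = weight,
                active = weight >= threshold)
  attr(out, "threshold") <- threshold
  out
}
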