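#' Low-expression filter
#'
#' Retains features expressed (count > 0) in at least `min_samples` samples.
#' Genes and miRNAs should be filtered separately, as their library depths
#' and detection behaviour differ.
#'
#' @param counts non-negative integer matrix, features x samples.
#' @param min_samples minimum number of samples with a nonzero count
#'   (default 22). Alternatively give `min_fraction` and the threshold is
#'   `ceiling(min_fraction * ncol(counts))`.
#' @param min_fraction optional fraction of samples (e.g. 0.2) overriding
#'   `min_samples`.
#' @return character vector of retained feature ids, input order preserved.
#' @export
filter_low_expression <- function(counts, min_samples = 22L,
                                  min_fraction = NULL) {
  counts <- as.matrix(counts)
  if (nrow(counts) == 0L || ncol(counts) == 0L)
    stop("empty count matrix")
  if (anyNA(counts) || any(counts < 0))
    stop("counts must be non-negative with no missing values")
  if (!is.null(min_fraction)) {
    if (min_fraction <= 0 || min_fraction > 1)
      stop("min_fraction must be in (0, 1]")
    min_samples <- as.integer(ceiling(min_fraction * ncol(counts)))
  }
  min_samples <- as.integer(min_samples)
  if (is.na(min_samples) || min_samples <= 0L)
    stop("min_samples must be a positive integer")
  if (min_samples > ncol(counts))
    stop("min_samples (", min_samples, ") exceeds the number of samples (",
         ncol(counts), ")")
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("feature_", seq_len(nrow(counts)))
  nz <- rowSums(counts > 0)
  rownames(counts)[nz >= min_samples]
}

#' Align expression and GEBV matrices on their common samples
#'
#' Restricts a features x samples expression matrix and a samples x traits
#' GEBV matrix to the intersection of their sample ids, in the expression
#' matrix's order.
#'
#' @param expr numeric matrix, features x samples (colnames = sample ids).
#' @param gebv numeric matrix, samples x traits (rownames = sample ids).
#' @return list with elements `expr` and `gebv`, sample-aligned.
#' @export
align_samples <- function(expr, gebv) {
  expr <- as.matrix(expr)
  gebv <- as.matrix(gebv)
  es <- colnames(expr)
  gs <- rownames(gebv)
  if (is.null(es) || is.null(gs))
    stop("expression columns and GEBV rows must carry sample ids")
  common <- es[es %in% gs]
  if (length(common) == 0L)
    stop("no samples in common: expression has {",
         paste(utils::head(es, 3L), collapse = ", "),
         ", ...}, GEBVs have {", paste(utils::head(gs, 3L), collapse = ", "),
         ", ...}")
  list(expr = expr[, common, drop = FALSE],
       gebv = gebv[common, , drop = FALSE])
}

#' Log2 scaling of counts
#'
#' Convenience transform `log2(count + pseudocount)` so synthetic or raw
#' count matrices can be pushed through the correlation stages. It is a
#' plain monotone rescaling, not a variance-stabilising normalisation;
#' real datasets should arrive already normalised.
#'
#' @param counts non-negative matrix, features x samples.
#' @param pseudocount positive offset added before the log (default 1).
#' @return numeric matrix of the same shape.
#' @export
log_scale <- function(counts, pseudocount = 1) {
  if (!is.numeric(pseudocount) || length(pseudocount) != 1L ||
      pseudocount <= 0)
    stop("pseudocount must be a positive number")
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  log2(counts + pseudocount)
}
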