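#' Contrast-group selection by trait GEBV
#'
#' Picks the `group_size` samples with the largest GEBV for a trait (high
#' group) and the `group_size` smallest (low group). Ties are broken
#' deterministically by sample id, so the same table always yields the same
#' groups.
#'
#' @param gebv numeric matrix, samples x traits (rownames = sample ids).
#' @param trait trait id (column of `gebv`).
#' @param group_size samples per group (default 15).
#' @return a `contrast_design`: list with `label`, `high_samples`,
#'   `low_samples`.
#' @export
select_contrast_by_trait <- function(gebv, trait, group_size = 15L) {
  gebv <- as.matrix(gebv)
  if (!trait %in% colnames(gebv)) stop("unknown trait: ", trait)
  .contrast(stats::setNames(gebv[, trait], rownames(gebv)), trait, group_size)
}

#' Contrast-group selection by overall PCA score
#'
#' @param scores data.frame from [pca_scores()] (`sample_id`, `score`).
#' @param group_size samples per group (default 15).
#' @return a `contrast_design` labelled `"pca_score"`.
#' @export
select_contrast_by_score <- function(scores, group_size = 15L) {
  .contrast(stats::setNames(scores$score, scores$sample_id), "pca_score",
            group_size)
}

.contrast <- function(x, label, group_size) {
  group_size <- as.integer(group_size)
  if (is.na(group_size) || group_size <= 0L)
    stop("group_size must be a positive integer")
  n <- length(x)
  if (2L * group_size > n)
    stop("group_size ", group_size, " too large for ", n, " samples")
  ids <- names(x)
  if (is.null(ids)) stop("samples must carry ids")
  if (length(unique(x)) == 1L)
    warning("all values equal for '", label,
            "'; contrast groups filled by sample-id order")
  ord <- ids[order(x, ids)]
  lo <- ord[seq_len(group_size)]
  hi <- rev(ord)[seq_len(group_size)]
  structure(list(label = label, high_samples = hi, low_samples = lo),
            class = "contrast_design")
}

#' @export
print.contrast_design <- function(x, ...) {
  cat("Contrast design '", x$label, "': ", length(x$high_samples),
      " high vs ", length(x$low_samples), " low samples\n", sep = "")
  invisible(x)
}

#' Contrast design as a sample/group table
#'
#' @param design a `contrast_design`.
#' @return data.frame with columns `sample_id`, `group` (`high`/`low`).
#' @export
contrast_table <- function(design) {
  data.frame(
    sample_id = c(design$high_samples, design$low_samples),
    group = rep(c("high", "low"),
                c(length(design$high_samples), length(design$low_samples))),
    stringsAsFactors = FALSE)
}

#' Per-sample PCA score over all traits
#'
#' Standardises every trait column (mean 0, sd 1), performs a PCA on the
#' standardised GEBV matrix (eigendecomposition of the trait correlation
#' matrix) and scores each sample as the sum over principal components of its
#' PC coordinate weighted by the component's share of variance:
#' `A_i = sum_j w_j * sum_k loading_kj * Z_ik`, where `w_j` is the PC's
#' eigenvalue divided by the trace (`weight_mode = "proportion"`, default) or
#' the raw eigenvalue (`weight_mode = "eigenvalue"`). Eigenvector signs are
#' fixed by making each PC's largest-magnitude loading positive, so scores
#' are reproducible.
#'
#' @param gebv numeric matrix, samples x traits.
#' @param weight_mode `"proportion"` or `"eigenvalue"`.
#' @return data.frame with columns `sample_id`, `score`.
#' @export
pca_scores <- function(gebv, weight_mode = c("proportion", "eigenvalue")) {
  weight_mode <- match.arg(weight_mode)
  gebv <- as.matrix(gebv)
  if (nrow(gebv) < 2L) stop("at least 2 samples required")
  if (ncol(gebv) < 1L) stop("at least 1 trait required")
  sds <- apply(gebv, 2L, stats::sd)
  zero_sd <- sds == 0
  if (any(zero_sd)) {
    if (all(apply(gebv, 2L, function(c) length(unique(c))) == 1L) &&
        nrow(unique(gebv)) == 1L) {
      # all samples identical: standardised matrix is all-zero, scores 0
      return(data.frame(sample_id = rownames(gebv),
                        score = rep(0, nrow(gebv)),
                        stringsAsFactors = FALSE))
    }
    stop("constant trait column(s): ",
         paste(colnames(gebv)[zero_sd], collapse = ", "))
  }
  z <- scale(gebv)
  r <- stats::cor(gebv)
  eig <- eigen(r, symmetric = TRUE)
  load <- eig$vectors
  # deterministic sign: largest-|loading| entry of each PC made positive
  for (j in seq_len(ncol(load))) {
    k <- which.max(abs(load[, j]))
    if (load[k, j] < 0) load[, j] <- -load[, j]
  }
  w <- if (weight_mode == "proportion") eig$values / sum(eig$values)
       else eig$values
  pc <- z %*% load                      # sample PC coordinates
  score <- as.numeric(pc %*% w)
  data.frame(sample_id = rownames(gebv), score = score,
             stringsAsFactors = FALSE)
}

# Within-group Pearson correlation between a candidate row and a target
# column; zero-variance on either side gives 0 (with one warning upstream).
.safe_cor <- function(x, y) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

#' RIF1/RIF2 regulatory impact scores against GEBV targets
#'
#' For each candidate regulator i and target trait j, with high/low group
#' means of the trait's GEBV `eH_j`, `eL_j`, average abundance
#' `a_j = (eH_j + eL_j)/2`, difference `d_j = eH_j - eL_j`, and within-group
#' correlations `rH_ij`, `rL_ij` between candidate expression and the trait:
#' \deqn{RIF1_i = (1/n_t) \sum_j a_j d_j (rH_{ij} - rL_{ij})^2}
#' \deqn{RIF2_i = (1/n_t) \sum_j [(eH_j rH_{ij})^2 - (eL_j rL_{ij})^2]}
#' RIF1 rewards abundant, strongly differentially co-expressed candidates;
#' RIF2 rewards candidates whose expression predicts the target better in one
#' condition than the other. Raw scores are z-standardised across candidates
#' and a candidate is significant when either |z| reaches `z_cutoff`.
#'
#' @param candidates numeric matrix, candidate features x samples.
#' @param targets numeric matrix, samples x traits (GEBVs).
#' @param design a `contrast_design`; both groups need >= 3 samples.
#' @param z_cutoff significance cutoff on |z| (default 1.96).
#' @return a `rif_table` data.frame: `candidate_id`, `rif1_raw`, `rif2_raw`,
#'   `rif1_z`, `rif2_z`, `significant`.
#' @export
rif_scores <- function(candidates, targets, design, z_cutoff = 1.96) {
  stopifnot(inherits(design, "contrast_design"))
  candidates <- as.matrix(candidates)
  targets <- as.matrix(targets)
  if (nrow(candidates) < 2L)
    stop("z-standardisation needs at least 2 candidates")
  hi <- design$high_samples
  lo <- design$low_samples
  if (length(hi) < 3L || length(lo) < 3L)
    stop("each contrast group needs at least 3 samples")
  miss <- setdiff(c(hi, lo), intersect(colnames(candidates), rownames(targets)))
  if (length(miss))
    stop("design samples missing from inputs: ", paste(miss, collapse = ", "))

  ch <- candidates[, hi, drop = FALSE]
  cl <- candidates[, lo, drop = FALSE]
  th <- targets[hi, , drop = FALSE]
  tl <- targets[lo, , drop = FALSE]
  nt <- ncol(targets)
  eH <- colMeans(th)
  eL <- colMeans(tl)
  a <- (eH + eL) / 2
  d <- eH - eL

  rif1 <- numeric(nrow(candidates))
  rif2 <- numeric(nrow(candidates))
  warned <- FALSE
  for (i in seq_len(nrow(candidates))) {
    rH <- vapply(seq_len(nt), function(j) .safe_cor(ch[i, ], th[, j]),
                 numeric(1))
    rL <- vapply(seq_len(nt), function(j) .safe_cor(cl[i, ], tl[, j]),
                 numeric(1))
    if (anyNA(c(rH, rL))) {
      if (!warned) {
        warning("zero within-group variance for candidate '",
                rownames(candidates)[i],
                "' (or a target); correlation terms set to 0")
        warned <- TRUE
      }
      rH[is.na(rH)] <- 0
      rL[is.na(rL)] <- 0
    }
    rif1[i] <- mean(a * d * (rH - rL)^2)
    rif2[i] <- mean((eH * rH)^2 - (eL * rL)^2)
  }

  zstd <- function(x) {
    s <- stats::sd(x)
    if (s == 0) rep(0, length(x)) else (x - mean(x)) / s
  }
  z1 <- zstd(rif1)
  z2 <- zstd(rif2)
  out <- data.frame(
    candidate_id = rownames(candidates),
    rif1_raw = rif1, rif2_raw = rif2,
    rif1_z = z1, rif2_z = z2,
    significant = abs(z1) >= z_cutoff | abs(z2) >= z_cutoff,
    stringsAsFactors = FALSE)
  class(out) <- c("rif_table", "data.frame")
  out
}

.empty_rif <- function() {
  out <- data.frame(candidate_id = character(0), rif1_raw = numeric(0),
                    rif2_raw = numeric(0), rif1_z = numeric(0),
                    rif2_z = numeric(0), significant = logical(0),
                    stringsAsFactors = FALSE)
  class(out) <- c("rif_table", "data.frame")
  out
}

#' Per-trait RIF analyses
#'
#' One RIF analysis per trait: candidates are the features correlated to the
#' trait (from [combine_feature_trait_edges()]), the single target is the
#' trait's own GEBV column, and the contrast groups are the trait's GEBV
#' extremes.
#'
#' @param correlated data.frame from [combine_feature_trait_edges()].
#' @param expr numeric matrix, features x samples (genes and miRNAs).
#' @param gebv numeric matrix, samples x traits.
#' @param group_size samples per contrast group (default 15).
#' @param z_cutoff significance cutoff (default 1.96).
#' @return named list of `rif_table`s, one per trait in `gebv`.
#' @export
rif_per_trait <- function(correlated, expr, gebv, group_size = 15L,
                          z_cutoff = 1.96) {
  gebv <- as.matrix(gebv)
  expr <- as.matrix(expr)
  out <- list()
  for (trait in colnames(gebv)) {
    cand <- unique(correlated$feature_id[correlated$trait == trait])
    cand <- intersect(cand, rownames(expr))
    if (length(cand) < 2L) {
      warning("trait '", trait, "': fewer than 2 correlated features; ",
              "empty RIF table")
      out[[trait]] <- .empty_rif()
      next
    }
    design <- select_contrast_by_trait(gebv, trait, group_size)
    out[[trait]] <- rif_scores(expr[cand, , drop = FALSE],
                               gebv[, trait, drop = FALSE], design,
                               z_cutoff = z_cutoff)
  }
  out
}

#' Overall RIF against all traits (PCA-score contrast)
#'
#' Candidates are all features correlated to at least one trait; targets are
#' all trait GEBV columns; the contrast groups are the extremes of the
#' per-sample PCA score.
#'
#' @inheritParams rif_per_trait
#' @param weight_mode passed to [pca_scores()].
#' @return list with `rif` (a `rif_table`), `scores` (the score table) and
#'   `design` (the `contrast_design`).
#' @export
rif_overall <- function(correlated, expr, gebv, group_size = 15L,
                        z_cutoff = 1.96,
                        weight_mode = c("proportion", "eigenvalue")) {
  gebv <- as.matrix(gebv)
  expr <- as.matrix(expr)
  scores <- pca_scores(gebv, weight_mode = match.arg(weight_mode))
  design <- select_contrast_by_score(scores, group_size)
  cand <- intersect(unique(correlated$feature_id), rownames(expr))
  if (length(cand) < 2L) {
    warning("fewer than 2 correlated features overall; empty RIF table")
    return(list(rif = .empty_rif(), scores = scores, design = design))
  }
  rif <- rif_scores(expr[cand, , drop = FALSE], gebv, design,
                    z_cutoff = z_cutoff)
  list(rif = rif, scores = scores, design = design)
}
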