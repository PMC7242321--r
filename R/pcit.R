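#' Pairwise Pearson correlations for a node set
#'
#' Computes the full symmetric correlation matrix among node value vectors
#' (rows). Constant nodes make Pearson correlation undefined, so they are an
#' error here; callers that tolerate them (e.g. [pcit()]) must drop constant
#' rows first.
#'
#' @param values numeric matrix, nodes x samples; rownames are node ids.
#' @return symmetric correlation matrix with unit diagonal, dimnames = node ids.
#' @export
pearson_all <- function(values) {
  values <- as.matrix(values)
  if (ncol(values) < 3L)
    stop("at least 3 samples are required to correlate nodes")
  if (anyNA(values)) stop("missing values in node matrix")
  v <- apply(values, 1L, stats::var)
  if (any(v == 0)) {
    bad <- rownames(values)[v == 0]
    if (is.null(bad)) bad <- which(v == 0)
    stop("zero-variance node(s): ", paste(bad, collapse = ", "))
  }
  cc <- stats::cor(t(values))
  diag(cc) <- 1
  cc
}

#' First-order partial correlation from three pairwise correlations
#'
#' Correlation between x and y once the linear effect of z is removed:
#' `(r_xy - r_xz * r_yz) / sqrt((1 - r_xz^2) * (1 - r_yz^2))`.
#'
#' @param r_xy,r_xz,r_yz pairwise Pearson correlations, each in `[-1, 1]`.
#' @return the partial correlation of x and y given z. Vectorised.
#' @export
partial_correlation <- function(r_xy, r_xz, r_yz) {
  if (any(abs(c(r_xy, r_xz, r_yz)) > 1 + 1e-12))
    stop("correlations must lie in [-1, 1]")
  if (any(abs(r_xz) >= 1) || any(abs(r_yz) >= 1))
    stop("degenerate trio: |r| = 1 for a conditioning pair")
  (r_xy - r_xz * r_yz) / sqrt((1 - r_xz^2) * (1 - r_yz^2))
}

#' PCIT: partial-correlation and information-theory edge significance
#'
#' Runs the PCIT algorithm over a set of nodes (genes, miRNAs and/or traits).
#' For every trio of nodes the three first-order partial correlations are
#' compared against the direct correlations through a trio-specific tolerance
#' (the mean ratio of partial to direct correlation); an edge is significant
#' only if no third node can explain it away. Trios are streamed in the
#' compiled kernel, so memory use stays quadratic.
#'
#' Constant (zero-variance) nodes cannot be correlated and are dropped with a
#' warning before the analysis.
#'
#' @param values numeric matrix, nodes x samples, rownames = node ids.
#' @param roles character vector, one of `"gene"`, `"mirna"`, `"trait"` per
#'   node. Defaults to `"gene"` for all nodes.
#' @param node_subset optional character vector of node ids (or integer
#'   indices): restrict the analysis to these nodes.
#' @param rank_transform if `TRUE`, node vectors are rank-transformed first
#'   (Spearman-type analysis). Off by default: PCIT is defined on Pearson
#'   correlations.
#' @return an object of class `pcit_result`: list with `node_ids`, `roles`,
#'   `corr` (correlation matrix) and `sig` (logical significance matrix,
#'   symmetric with `FALSE` diagonal).
#' @export
pcit <- function(values, roles = NULL, node_subset = NULL,
                 rank_transform = FALSE) {
  values <- as.matrix(values)
  if (is.null(rownames(values)))
    rownames(values) <- paste0("node_", seq_len(nrow(values)))
  if (anyDuplicated(rownames(values)))
    stop("node ids must be unique")
  if (is.null(roles)) roles <- rep("gene", nrow(values))
  if (length(roles) != nrow(values))
    stop("roles must have one entry per node")

  keep <- apply(values, 1L, stats::var) > 0
  if (!all(keep)) {
    warning("dropping ", sum(!keep), " zero-variance node(s): ",
            paste(utils::head(rownames(values)[!keep], 5L), collapse = ", "))
    values <- values[keep, , drop = FALSE]
    roles <- roles[keep]
  }
  if (nrow(values) < 3L) stop("PCIT needs at least 3 (non-constant) nodes")

  if (rank_transform)
    values <- t(apply(values, 1L, rank))

  cc <- pearson_all(values)

  subset_idx <- integer(0)
  if (!is.null(node_subset)) {
    if (is.character(node_subset))
      subset_idx <- match(node_subset, rownames(values))
    else subset_idx <- as.integer(node_subset)
    if (anyNA(subset_idx)) stop("node_subset contains unknown node ids")
    subset_idx <- sort(unique(subset_idx)) - 1L
  }

  sig <- .pcit_kernel(cc, subset_idx)
  dimnames(sig) <- dimnames(cc)
  structure(
    list(node_ids = rownames(values), roles = stats::setNames(roles, rownames(values)),
         corr = cc, sig = sig),
    class = "pcit_result")
}

#' @export
print.pcit_result <- function(x, ...) {
  n <- length(x$node_ids)
  ne <- sum(x$sig[upper.tri(x$sig)])
  cat("PCIT result:", n, "nodes (",
      sum(x$roles == "gene"), "gene,", sum(x$roles == "mirna"), "miRNA,",
      sum(x$roles == "trait"), "trait ),", ne, "significant edges\n")
  invisible(x)
}

# Stack expression matrices and a GEBV matrix into one node x sample matrix
# with role labels, after checking sample alignment.
.node_stack <- function(genes, mirnas, gebv) {
  parts <- list()
  roles <- character(0)
  samples <- NULL
  add <- function(m, role) {
    if (is.null(m) || nrow(m) == 0L) return(invisible(NULL))
    if (is.null(samples)) samples <<- colnames(m)
    else if (!identical(colnames(m), samples))
      stop("inputs are not sample-aligned; run align_samples() first")
    parts[[length(parts) + 1L]] <<- m
    roles <<- c(roles, rep(role, nrow(m)))
  }
  if (!is.null(genes)) add(as.matrix(genes), "gene")
  if (!is.null(mirnas)) add(as.matrix(mirnas), "mirna")
  add(t(as.matrix(gebv)), "trait")
  values <- do.call(rbind, parts)
  if (anyDuplicated(rownames(values)))
    stop("duplicate node ids across genes/miRNAs/traits")
  list(values = values, roles = roles)
}

#' PCIT over genes, miRNAs and trait GEBVs ("PCIT general")
#'
#' Stacks gene expression, miRNA expression and the transposed GEBV matrix
#' into one node set (traits become nodes alongside features) and runs
#' [pcit()]. Inputs must share an identical sample order.
#'
#' @param genes numeric matrix genes x samples (may be `NULL` or 0-row).
#' @param mirnas numeric matrix miRNAs x samples (may be `NULL` or 0-row).
#' @param gebv numeric matrix samples x traits.
#' @inheritParams pcit
#' @return a `pcit_result` whose trait nodes carry role `"trait"`.
#' @export
run_pcit_general <- function(genes, mirnas, gebv, node_subset = NULL,
                             rank_transform = FALSE) {
  ns <- .node_stack(genes, mirnas, gebv)
  pcit(ns$values, ns$roles, node_subset = node_subset,
       rank_transform = rank_transform)
}

#' PCIT over miRNAs and trait GEBVs only ("PCIT miRNA")
#'
#' The miRNA-focused companion run: because miRNAs are far fewer than genes,
#' running them against the GEBVs without the gene background gives miRNA-trait
#' associations a second chance to pass the tolerance test.
#'
#' @inheritParams run_pcit_general
#' @return a `pcit_result`.
#' @export
run_pcit_mirna <- function(mirnas, gebv, node_subset = NULL,
                           rank_transform = FALSE) {
  ns <- .node_stack(NULL, mirnas, gebv)
  pcit(ns$values, ns$roles, node_subset = node_subset,
       rank_transform = rank_transform)
}

#' Extract the edge list of a PCIT result
#'
#' @param result a `pcit_result`.
#' @param significant_only keep only PCIT-significant edges (default `TRUE`).
#' @param source_run label recorded in the `source_run` column.
#' @return data.frame with columns `node_a`, `node_b`, `role_a`, `role_b`,
#'   `r`, `significant`, `source_run`. Pairs are unordered; each appears once
#'   with `node_a` before `node_b` in node order.
#' @export
pcit_edges <- function(result, significant_only = TRUE, source_run = "pcit") {
  stopifnot(inherits(result, "pcit_result"))
  ut <- upper.tri(result$sig)
  keep <- if (significant_only) result$sig & ut else ut
  ij <- which(keep, arr.ind = TRUE)
  data.frame(
    node_a = result$node_ids[ij[, 1L]],
    node_b = result$node_ids[ij[, 2L]],
    role_a = unname(result$roles[ij[, 1L]]),
    role_b = unname(result$roles[ij[, 2L]]),
    r = result$corr[keep],
    significant = result$sig[keep],
    source_run = source_run,
    stringsAsFactors = FALSE)
}

#' Combine feature-trait edges from the general and miRNA PCIT runs
#'
#' Takes the union of significant feature-trait edges from both analyses.
#' Each feature-trait pair is reported once, tagged with the run(s) that found
#' it; pairs found by both runs get `source = "both"` (the "repeated" flag).
#'
#' @param general `pcit_result` from [run_pcit_general()].
#' @param mirna_only `pcit_result` from [run_pcit_mirna()], or `NULL`.
#' @return data.frame with columns `trait`, `feature_id`, `feature_role`,
#'   `r` (from the general run when available, else the miRNA run),
#'   `source` in `{"general", "mirna", "both"}`.
#' @export
combine_feature_trait_edges <- function(general, mirna_only = NULL) {
  ft <- function(res, run) {
    if (is.null(res)) return(NULL)
    e <- pcit_edges(res, significant_only = TRUE, source_run = run)
    is_ft <- xor(e$role_a == "trait", e$role_b == "trait")
    e <- e[is_ft, , drop = FALSE]
    tr <- ifelse(e$role_a == "trait", e$node_a, e$node_b)
    fe <- ifelse(e$role_a == "trait", e$node_b, e$node_a)
    fr <- ifelse(e$role_a == "trait", e$role_b, e$role_a)
    data.frame(trait = tr, feature_id = fe, feature_role = fr, r = e$r,
               source = rep(run, nrow(e)), stringsAsFactors = FALSE)
  }
  g <- ft(general, "general")
  m <- ft(mirna_only, "mirna")
  if (!is.null(g) && !is.null(m)) {
    shared <- intersect(paste(g$trait, g$feature_id),
                        paste(m$trait, m$feature_id))
    # same id must not switch role between runs
    both_ids <- intersect(names(general$roles), names(mirna_only$roles))
    if (any(general$roles[both_ids] != mirna_only$roles[both_ids]))
      stop("conflicting node roles between the two PCIT runs")
    g$source[paste(g$trait, g$feature_id) %in% shared] <- "both"
    m <- m[!(paste(m$trait, m$feature_id) %in% shared), , drop = FALSE]
  }
  out <- rbind(g, m)
  if (is.null(out))
    out <- data.frame(trait = character(0), feature_id = character(0),
                      feature_role = character(0), r = numeric(0),
                      source = character(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(out$trait, out$feature_id), , drop = FALSE]
}
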