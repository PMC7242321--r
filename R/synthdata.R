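#' Simulation configuration
#'
#' Bundles and validates every knob of the synthetic-data generator. The
#' defaults emulate the study conditions the pipeline is designed for: 113
#' samples, 1,000 genes, 100 miRNAs, ten traits of which six form a
#' high-correlation GEBV block (pairwise r between 0.77 and 0.97, built from
#' single-factor loadings so the matrix is guaranteed positive
#' semi-definite) while the remaining traits are independent; 20 planted
#' linear feature-trait associations with effect size `beta = 0.75` against
#' unit noise (population correlation `0.75/sqrt(1 + 0.75^2) = 0.6`); and two
#' planted regulators that are strongly co-expressed with their trait only in
#' the high-score half of the samples (`regulator_beta = 2`, within-half
#' correlation about 0.89) and pure noise elsewhere.
#'
#' @param n_samples,n_genes,n_mirnas,n_traits dataset dimensions.
#' @param n_block number of traits in the correlated block (first `n_block`
#'   traits; 0 for none; default 6 or `n_traits`, whichever is smaller).
#' @param trait_mean common GEBV mean (default 4 genetic-sd units): breeding
#'   values are emitted on a base-shifted positive scale, as published EBVs
#'   usually are, so the RIF abundance terms behave like the positive target
#'   abundances of the original formulation. Correlation-based stages are
#'   location-invariant, so this affects only RIF.
#' @param block_lambda_range single-factor loading range generating the block
#'   correlations (`r_ij = lambda_i * lambda_j`).
#' @param trait_cor optional explicit trait correlation matrix (overrides the
#'   block construction); must be symmetric PSD with unit diagonal.
#' @param n_assoc number of planted feature-trait associations.
#' @param beta planted association effect size (per sd of GEBV).
#' @param n_regulators number of planted differential-co-expression
#'   regulators.
#' @param regulator_beta effect size of regulators inside the high-score half.
#' @param noise_sd residual expression noise sd.
#' @param count_mu,count_size negative-binomial mean and dispersion for
#'   [simulate_counts()].
#' @param zero_inflation probability that a count entry is structurally zero.
#' @param seed integer seed; every generator draw derives from it.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_samples = 113L, n_genes = 1000L, n_mirnas = 100L,
                       n_traits = 10L, n_block = NULL,
                       block_lambda_range = c(0.88, 0.985),
                       trait_cor = NULL, trait_mean = 4,
                       n_assoc = 20L, beta = 0.75,
                       n_regulators = 2L, regulator_beta = 3,
                       noise_sd = 1,
                       count_mu = 50, count_size = 2, zero_inflation = 0.8,
                       seed = 1L) {
  if (is.null(n_block)) n_block <- min(6L, as.integer(n_traits))
  cfg <- list(n_samples = as.integer(n_samples), n_genes = as.integer(n_genes),
              n_mirnas = as.integer(n_mirnas), n_traits = as.integer(n_traits),
              n_block = as.integer(n_block),
              block_lambda_range = block_lambda_range,
              trait_mean = trait_mean,
              n_assoc = as.integer(n_assoc), beta = beta,
              n_regulators = as.integer(n_regulators),
              regulator_beta = regulator_beta, noise_sd = noise_sd,
              count_mu = count_mu, count_size = count_size,
              zero_inflation = zero_inflation, seed = as.integer(seed))
  if (cfg$n_samples < 4L) stop("n_samples must be at least 4")
  if (cfg$n_traits < 1L) stop("n_traits must be at least 1")
  if (cfg$n_block > cfg$n_traits) stop("n_block cannot exceed n_traits")
  if (cfg$n_assoc > cfg$n_genes + cfg$n_mirnas)
    stop("more planted associations than features")
  if (cfg$n_regulators > cfg$n_genes)
    stop("more planted regulators than genes")
  if (cfg$zero_inflation < 0 || cfg$zero_inflation > 1)
    stop("zero_inflation must be in [0, 1]")
  if (is.null(trait_cor)) {
    trait_cor <- diag(cfg$n_traits)
    if (cfg$n_block >= 2L) {
      lambda <- seq(block_lambda_range[1L], block_lambda_range[2L],
                    length.out = cfg$n_block)
      blk <- outer(lambda, lambda)
      diag(blk) <- 1
      trait_cor[seq_len(cfg$n_block), seq_len(cfg$n_block)] <- blk
    }
  } else {
    trait_cor <- as.matrix(trait_cor)
    if (!isTRUE(all.equal(trait_cor, t(trait_cor))))
      stop("trait_cor must be symmetric")
    if (any(diag(trait_cor) != 1)) stop("trait_cor must have unit diagonal")
  }
  if (min(eigen(trait_cor, symmetric = TRUE, only.values = TRUE)$values) <
      -1e-8)
    stop("trait correlation matrix is not positive semi-definite")
  cfg$trait_cor <- trait_cor
  structure(cfg, class = "sim_config")
}

.trait_ids <- function(cfg) sprintf("trait%02d", seq_len(cfg$n_traits))
.sample_ids <- function(cfg) sprintf("s%03d", seq_len(cfg$n_samples))

#' Simulate a GEBV matrix
#'
#' Multivariate-normal GEBVs (common mean `trait_mean`, unit variances) with
#' the configured trait correlation structure.
#'
#' @param cfg a `sim_config`.
#' @return numeric matrix, samples x traits, with ids.
#' @export
simulate_gebv <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  g <- MASS::mvrnorm(cfg$n_samples, mu = rep(cfg$trait_mean, cfg$n_traits),
                     Sigma = cfg$trait_cor)
  g <- matrix(g, nrow = cfg$n_samples)
  dimnames(g) <- list(.sample_ids(cfg), .trait_ids(cfg))
  g
}

#' Simulate expression matrices with planted ground truth
#'
#' Background features are independent Gaussian noise. Planted trait-
#' associated features follow `beta * Z(GEBV_trait) + noise`. Planted
#' regulators follow `regulator_beta * Z(GEBV_trait) + noise` only inside the
#' high-score half of the samples (defined generator-side as the upper half
#' of the summed standardised GEBVs) and are pure noise in the other half --
#' differential co-expression by construction. Planted association slots are
#' spread round-robin over the traits, roughly 80% on genes and 20% on
#' miRNAs; regulators are genes tied to block traits (or to any trait when no
#' block is configured).
#'
#' @param cfg a `sim_config`.
#' @param gebv matrix from [simulate_gebv()] under the same config.
#' @return list with `genes`, `mirnas` (features x samples matrices) and
#'   `truth` (a `synthetic_truth`: data.frames `assoc` and `regulators`, the
#'   `high_half` sample ids, `trait_cor`, `seed`).
#' @export
simulate_expression <- function(cfg, gebv) {
  stopifnot(inherits(cfg, "sim_config"))
  gebv <- as.matrix(gebv)
  if (nrow(gebv) != cfg$n_samples || ncol(gebv) != cfg$n_traits)
    stop("gebv does not match the config dimensions")
  set.seed(cfg$seed + 1L)

  gene_ids <- sprintf("gene%04d", seq_len(cfg$n_genes))
  mirna_ids <- sprintf("mir%03d", seq_len(cfg$n_mirnas))
  samples <- rownames(gebv)
  z <- scale(gebv)

  genes <- matrix(stats::rnorm(cfg$n_genes * cfg$n_samples, sd = cfg$noise_sd),
                  nrow = cfg$n_genes, ncol = cfg$n_samples,
                  dimnames = list(gene_ids, samples))
  mirnas <- matrix(stats::rnorm(cfg$n_mirnas * cfg$n_samples,
                                sd = cfg$noise_sd),
                   nrow = cfg$n_mirnas, ncol = cfg$n_samples,
                   dimnames = list(mirna_ids, samples))

  # planted feature-trait associations: ~80% genes, rest miRNAs
  n_gene_assoc <- min(cfg$n_genes, ceiling(0.8 * cfg$n_assoc))
  n_mirna_assoc <- min(cfg$n_mirnas, cfg$n_assoc - n_gene_assoc)
  n_gene_assoc <- cfg$n_assoc - n_mirna_assoc
  assoc_genes <- if (n_gene_assoc)
    sample(gene_ids, n_gene_assoc) else character(0)
  assoc_mirnas <- if (n_mirna_assoc)
    sample(mirna_ids, n_mirna_assoc) else character(0)
  assoc_ids <- c(assoc_genes, assoc_mirnas)
  assoc_roles <- rep(c("gene", "mirna"), c(n_gene_assoc, n_mirna_assoc))
  assoc_traits <- .trait_ids(cfg)[
    rep_len(seq_len(cfg$n_traits), length(assoc_ids))]
  for (i in seq_along(assoc_ids)) {
    sig <- cfg$beta * z[, assoc_traits[i]] +
      stats::rnorm(cfg$n_samples, sd = cfg$noise_sd)
    if (assoc_roles[i] == "gene") genes[assoc_ids[i], ] <- sig
    else mirnas[assoc_ids[i], ] <- sig
  }

  # generator-side overall score and its high half
  score <- rowSums(z)
  ord <- order(-score, samples)
  high_half <- samples[ord][seq_len(ceiling(cfg$n_samples / 2))]
  is_high <- samples %in% high_half

  reg_pool <- setdiff(gene_ids, assoc_genes)
  reg_ids <- if (cfg$n_regulators)
    sample(reg_pool, cfg$n_regulators) else character(0)
  # regulators track the trait block's common factor (the summed
  # standardised block GEBVs), so their differential co-expression spans the
  # whole block rather than a single trait
  block_cols <- if (cfg$n_block >= 2L) seq_len(cfg$n_block)
    else seq_len(cfg$n_traits)
  factor_z <- as.numeric(scale(rowSums(z[, block_cols, drop = FALSE])))
  reg_traits <- rep("trait_block", length(reg_ids))
  for (i in seq_along(reg_ids)) {
    x <- stats::rnorm(cfg$n_samples, sd = cfg$noise_sd)
    x[is_high] <- x[is_high] + cfg$regulator_beta * factor_z[is_high]
    genes[reg_ids[i], ] <- x
  }

  truth <- structure(
    list(assoc = data.frame(feature_id = assoc_ids, role = assoc_roles,
                            trait = assoc_traits,
                            beta = rep(cfg$beta, length(assoc_ids)),
                            stringsAsFactors = FALSE),
         regulators = data.frame(feature_id = reg_ids,
                                 role = rep("gene", length(reg_ids)),
                                 trait = reg_traits,
                                 beta = rep(cfg$regulator_beta,
                                            length(reg_ids)),
                                 stringsAsFactors = FALSE),
         high_half = high_half,
         trait_cor = cfg$trait_cor,
         seed = cfg$seed),
    class = "synthetic_truth")
  list(genes = genes, mirnas = mirnas, truth = truth)
}

#' Simulate a raw count matrix
#'
#' Negative-binomial counts with per-entry structural zeros, for exercising
#' the low-expression filter. With `zero_inflation = 1` every entry is zero;
#' with `zero_inflation = 0` and a large mean essentially every feature
#' passes any sample cut-off.
#'
#' @param cfg a `sim_config`.
#' @param n_features number of features (default `n_genes`).
#' @return integer matrix, features x samples.
#' @export
simulate_counts <- function(cfg, n_features = cfg$n_genes) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 2L)
  n <- n_features * cfg$n_samples
  counts <- stats::rnbinom(n, mu = cfg$count_mu, size = cfg$count_size)
  zero <- stats::runif(n) < cfg$zero_inflation
  counts[zero] <- 0L
  matrix(as.integer(counts), nrow = n_features,
         dimnames = list(sprintf("feature%04d", seq_len(n_features)),
                         .sample_ids(cfg)))
}

#' Simulate a three-node chain (common-driver) construction
#'
#' Generates `x = z + e1`, `y = z + e2` with `z ~ N(0,1)` and independent
#' noise, the canonical conditional-independence benchmark for PCIT: x and y
#' are correlated only through z, so the x-y edge should be explained away
#' while x-z and y-z survive. The default `noise_sd = 2.75` (link correlation
#' about 0.34) maximises the finite-sample probability that the trio-wise
#' tolerance test resolves the structure at n = 100; see the methods
#' vignette for the derivation (the rejection rule cannot remove the
#' indirect edge of an isolated trio at all once the link correlation
#' exceeds about 0.58).
#'
#' @param n samples (default 100).
#' @param noise_sd sd of the independent noise terms (default 2.75).
#' @param seed integer seed.
#' @return numeric matrix with rows `x`, `y`, `z`.
#' @export
simulate_chain <- function(n = 100L, noise_sd = 2.75, seed = 1L) {
  set.seed(as.integer(seed))
  z <- stats::rnorm(n)
  x <- z + stats::rnorm(n, sd = noise_sd)
  y <- z + stats::rnorm(n, sd = noise_sd)
  rbind(x = x, y = y, z = z)
}

#' Simulate a full dataset and optionally write it to disk
#'
#' Runs [simulate_gebv()] and [simulate_expression()] (and, if
#' `with_counts`, [simulate_counts()]) and, when `dir` is given, writes the
#' TSVs the pipeline loaders read plus the truth tables and the config (for
#' provenance).
#'
#' @param cfg a `sim_config`.
#' @param dir optional output directory.
#' @param with_counts also simulate count matrices.
#' @return list with `gebv`, `genes`, `mirnas`, `truth` and (optionally)
#'   `counts`; when `dir` is given, also `paths`.
#' @export
simulate_dataset <- function(cfg, dir = NULL, with_counts = FALSE) {
  gebv <- simulate_gebv(cfg)
  ex <- simulate_expression(cfg, gebv)
  out <- list(gebv = gebv, genes = ex$genes, mirnas = ex$mirnas,
              truth = ex$truth)
  if (with_counts) out$counts <- simulate_counts(cfg)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    p <- list(
      gebv = file.path(dir, "gebv.tsv"),
      genes = file.path(dir, "genes.tsv"),
      mirnas = file.path(dir, "mirnas.tsv"),
      truth_assoc = file.path(dir, "truth_assoc.tsv"),
      truth_regulators = file.path(dir, "truth_regulators.tsv"),
      truth_high_half = file.path(dir, "truth_high_half.tsv"),
      config = file.path(dir, "sim_config.yaml"))
    write_matrix_tsv(gebv, p$gebv, id_col = "sample_id")
    write_matrix_tsv(ex$genes, p$genes, id_col = "feature_id")
    write_matrix_tsv(ex$mirnas, p$mirnas, id_col = "feature_id")
    write_tsv(ex$truth$assoc, p$truth_assoc)
    write_tsv(ex$truth$regulators, p$truth_regulators)
    write_tsv(data.frame(sample_id = ex$truth$high_half,
                         stringsAsFactors = FALSE), p$truth_high_half)
    cfg_out <- unclass(cfg)
    cfg_out$trait_cor <- NULL
    yaml::write_yaml(cfg_out, p$config)
    if (with_counts) {
      p$counts <- file.path(dir, "counts.tsv")
      write_matrix_tsv(out$counts, p$counts, id_col = "feature_id")
    }
    out$paths <- p
  }
  out
}
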