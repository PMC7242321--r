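# Contrast selection, PCA scores and the RIF1/RIF2 statistics.

make_gebv <- function(values, samples, traits = "t1") {
  matrix(values, nrow = length(samples),
         dimnames = list(samples, traits))
}

test_that("contrast groups are the GEBV extremes with deterministic ties", {
  ids <- sprintf("s%03d", 1:113)
  gebv <- make_gebv(1:113, ids)
  d <- select_contrast_by_trait(gebv, "t1", 15)
  expect_setequal(d$low_samples, ids[1:15])
  expect_setequal(d$high_samples, ids[99:113])
  expect_length(intersect(d$high_samples, d$low_samples), 0L)

  # 30 samples, groups of 15: every sample assigned
  gebv30 <- make_gebv(rnorm(30), sprintf("s%02d", 1:30))
  d30 <- select_contrast_by_trait(gebv30, "t1", 15)
  expect_setequal(c(d30$high_samples, d30$low_samples), rownames(gebv30))

  # all-equal values: tie-break by sample id with a warning
  flat <- make_gebv(rep(1, 10), sprintf("s%02d", 10:1))
  expect_warning(dt <- select_contrast_by_trait(flat, "t1", 3), "equal")
  expect_identical(sort(dt$low_samples), c("s01", "s02", "s03"))

  expect_error(select_contrast_by_trait(gebv, "t1", 0), "positive")
  expect_error(select_contrast_by_trait(gebv, "t1", 60), "too large")
  expect_error(select_contrast_by_trait(gebv, "nope", 5), "unknown trait")
})

test_that("pca_scores matches an independent svd oracle and its edge cases", {
  # all samples identical: all scores 0
  same <- matrix(3, 5, 2, dimnames = list(paste0("s", 1:5), c("a", "b")))
  expect_equal(pca_scores(same)$score, rep(0, 5))

  # single trait: score equals the standardised GEBV (varfraction 1)
  set.seed(11)
  g1 <- make_gebv(rnorm(20, 4), sprintf("s%02d", 1:20))
  sc1 <- pca_scores(g1)
  expect_equal(sc1$score, as.numeric(scale(g1[, 1])), tolerance = 1e-12)

  # 6-sample, 3-trait fixture vs from-scratch decomposition
  set.seed(12)
  g <- matrix(rnorm(18, 4), 6, 3,
              dimnames = list(paste0("s", 1:6), c("a", "b", "c")))
  expect_equal(pca_scores(g)$score, pca_scores_oracle(g), tolerance = 1e-9)
  expect_equal(pca_scores(g, "eigenvalue")$score,
               pca_scores_oracle(g, "eigenvalue"), tolerance = 1e-9)

  # invariance under per-trait affine rescaling (unit changes)
  g2 <- g
  g2[, 1] <- 1000 * g[, 1] + 7
  g2[, 3] <- 0.02 * g[, 3] - 5
  expect_equal(pca_scores(g2)$score, pca_scores(g)$score, tolerance = 1e-9)

  g3 <- g; g3[, 2] <- 1
  expect_error(pca_scores(g3), "constant trait")
})

test_that("select_contrast_by_score mirrors trait selection on the score", {
  set.seed(13)
  sc <- data.frame(sample_id = sprintf("s%02d", 1:20),
                   score = c(10:1, -(1:10)))
  d <- select_contrast_by_score(sc, 4)
  expect_setequal(d$high_samples, c("s01", "s02", "s03", "s04"))
  expect_setequal(d$low_samples, c("s17", "s18", "s19", "s20"))

  # symmetric scores: groups are mirror images
  sym <- data.frame(sample_id = sprintf("s%02d", 1:10),
                    score = c(5, -5, 3, -3, 1, -1, 2, -2, 4, -4))
  ds <- select_contrast_by_score(sym, 3)
  expect_setequal(-sym$score[match(ds$high_samples, sym$sample_id)],
                  sym$score[match(ds$low_samples, sym$sample_id)])
})

# deterministic fixture for rif_scores: 12 samples, 2 traits, 4 candidates
rif_fixture <- function() {
  ids <- sprintf("s%02d", 1:12)
  set.seed(14)
  gebv <- cbind(t1 = c(8, 7.5, 7, 6.5, 6, 5.5, 2, 1.8, 1.5, 1.2, 1, 0.5),
                t2 = c(6, 6.2, 5.9, 6.1, 5.8, 6.3, 3.1, 3, 2.9, 3.2, 2.8, 3))
  rownames(gebv) <- ids
  cand <- rbind(reg = c(scale(gebv[1:6, "t1"])[, 1] * 2 + rnorm(6, sd = .1),
                        rnorm(6)),
                c2 = rnorm(12), c3 = rnorm(12), c4 = rnorm(12))
  colnames(cand) <- ids
  design <- structure(list(label = "t1", high_samples = ids[1:6],
                           low_samples = ids[7:12]),
                      class = "contrast_design")
  list(cand = cand, gebv = gebv, design = design)
}

test_that("rif_scores implements the documented RIF1/RIF2 algebra", {
  f <- rif_fixture()
  rt <- rif_scores(f$cand, f$gebv, f$design)

  # independent re-computation for one candidate
  hi <- f$design$high_samples; lo <- f$design$low_samples
  for (cand_id in c("reg", "c3")) {
    r1 <- r2 <- 0
    for (j in colnames(f$gebv)) {
      eH <- mean(f$gebv[hi, j]); eL <- mean(f$gebv[lo, j])
      rH <- cor(f$cand[cand_id, hi], f$gebv[hi, j])
      rL <- cor(f$cand[cand_id, lo], f$gebv[lo, j])
      r1 <- r1 + (eH + eL) / 2 * (eH - eL) * (rH - rL)^2
      r2 <- r2 + (eH * rH)^2 - (eL * rL)^2
    }
    k <- which(rt$candidate_id == cand_id)
    expect_equal(rt$rif1_raw[k], r1 / 2, tolerance = 1e-12)
    expect_equal(rt$rif2_raw[k], r2 / 2, tolerance = 1e-12)
  }

  # z columns standardized
  expect_equal(mean(rt$rif1_z), 0, tolerance = 1e-9)
  expect_equal(sd(rt$rif1_z), 1, tolerance = 1e-9)
  expect_equal(mean(rt$rif2_z), 0, tolerance = 1e-9)
  expect_equal(sd(rt$rif2_z), 1, tolerance = 1e-9)
  expect_identical(rt$significant,
                   abs(rt$rif1_z) >= 1.96 | abs(rt$rif2_z) >= 1.96)
})

test_that("significance cutoff is inclusive at the boundary", {
  f <- rif_fixture()
  rt <- rif_scores(f$cand, f$gebv, f$design)
  k <- which.max(abs(rt$rif1_z))
  cut <- abs(rt$rif1_z[k])
  expect_gt(cut, abs(rt$rif2_z[k]))  # fixture guarantees rif1 dominates

  at <- rif_scores(f$cand, f$gebv, f$design, z_cutoff = cut)
  expect_true(at$significant[k])                       # |z| == cutoff
  above <- rif_scores(f$cand, f$gebv, f$design, z_cutoff = cut + 1e-9)
  expect_false(above$significant[k])                   # |z| just below
})

test_that("mirror-image groups give exactly zero raw scores", {
  # high and low groups see identical (candidate, GEBV) pairs:
  # group means equal, within-group correlations equal -> RIF1 = RIF2 = 0
  ids <- sprintf("s%02d", 1:12)
  half <- cbind(t1 = c(5, 3, 8, 1, 6, 4))
  gebv <- rbind(half, half)
  rownames(gebv) <- ids
  set.seed(15)
  block <- matrix(rnorm(12), 2, 6)
  cand <- cbind(block, block)
  dimnames(cand) <- list(c("cA", "cB"), ids)
  design <- structure(list(label = "t1", high_samples = ids[1:6],
                           low_samples = ids[7:12]),
                      class = "contrast_design")
  rt <- rif_scores(cand, gebv, design)
  expect_identical(rt$rif1_raw, c(0, 0))
  expect_identical(rt$rif2_raw, c(0, 0))
})

test_that("swapping groups negates raw scores but keeps significance", {
  f <- rif_fixture()
  rt <- rif_scores(f$cand, f$gebv, f$design)
  swapped <- structure(list(label = "t1",
                            high_samples = f$design$low_samples,
                            low_samples = f$design$high_samples),
                       class = "contrast_design")
  rt2 <- rif_scores(f$cand, f$gebv, swapped)
  expect_equal(rt2$rif1_raw, -rt$rif1_raw, tolerance = 1e-12)
  expect_equal(rt2$rif2_raw, -rt$rif2_raw, tolerance = 1e-12)
  expect_identical(rt2$significant, rt$significant)
})

test_that("rif_scores is equivariant under candidate relabeling", {
  f <- rif_fixture()
  rt <- rif_scores(f$cand, f$gebv, f$design)
  perm <- c(3, 1, 4, 2)
  rt_p <- rif_scores(f$cand[perm, ], f$gebv, f$design)
  expect_equal(rt_p[match(rt$candidate_id, rt_p$candidate_id), -1],
               rt[, -1], ignore_attr = TRUE)
})

test_that("degenerate candidates warn and too few candidates error", {
  f <- rif_fixture()
  cand <- f$cand
  cand["c4", f$design$high_samples] <- 1  # zero variance in the high group
  expect_warning(rt <- rif_scores(cand, f$gebv, f$design),
                 "zero within-group variance")
  expect_true(all(is.finite(rt$rif1_raw)))
  expect_error(rif_scores(f$cand[1, , drop = FALSE], f$gebv, f$design),
               "at least 2 candidates")
})

test_that("rif_per_trait runs one analysis per trait on its own candidates", {
  set.seed(16)
  n <- 40
  ids <- sprintf("s%03d", 1:n)
  gebv <- matrix(rnorm(3 * n, mean = 4), n, 3,
                 dimnames = list(ids, c("tA", "tB", "tC")))
  expr <- matrix(rnorm(6 * n), 6, n,
                 dimnames = list(paste0("g", 1:6), ids))
  correlated <- data.frame(
    trait = c("tA", "tA", "tA", "tB", "tB"),
    feature_id = c("g1", "g2", "g3", "g4", "g5"),
    feature_role = "gene", r = 0.5, source = "general")
  expect_warning(out <- rif_per_trait(correlated, expr, gebv, group_size = 10),
                 "tC")
  expect_named(out, c("tA", "tB", "tC"))
  expect_identical(nrow(out$tA), 3L)
  expect_identical(nrow(out$tB), 2L)
  expect_identical(nrow(out$tC), 0L)
})

test_that("rif_overall with one trait reduces to score-based single-trait RIF", {
  set.seed(17)
  n <- 40
  ids <- sprintf("s%03d", 1:n)
  gebv <- matrix(rnorm(n, mean = 4), n, 1, dimnames = list(ids, "tA"))
  expr <- matrix(rnorm(5 * n), 5, n, dimnames = list(paste0("g", 1:5), ids))
  correlated <- data.frame(trait = "tA", feature_id = paste0("g", 1:5),
                           feature_role = "gene", r = 0.4,
                           source = "general")
  ov <- rif_overall(correlated, expr, gebv, group_size = 10)
  # one PC, |loading| 1, varfraction 1: score is the standardised GEBV, so
  # the score contrast equals the trait contrast
  direct <- rif_scores(expr, gebv,
                       select_contrast_by_trait(gebv, "tA", 10))
  expect_equal(ov$rif, direct, ignore_attr = TRUE)
})

test_that("null candidates are rarely significant (loose calibration band)", {
  set.seed(18)
  frac <- numeric(60)
  ids <- sprintf("s%02d", 1:30)
  for (r in seq_along(frac)) {
    gebv <- matrix(rnorm(30 * 3, mean = 4), 30, 3,
                   dimnames = list(ids, c("a", "b", "c")))
    cand <- matrix(rnorm(50 * 30), 50, 30,
                   dimnames = list(sprintf("c%02d", 1:50), ids))
    des <- select_contrast_by_score(pca_scores(gebv), 15)
    rt <- rif_scores(cand, gebv, des)
    frac[r] <- mean(abs(rt$rif1_z) >= 1.96)
  }
  expect_gte(mean(frac), 0.005)
  expect_lte(mean(frac), 0.15)
})
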