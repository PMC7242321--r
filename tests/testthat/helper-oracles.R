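# Independent reference implementations used as oracles. These deliberately
# re-derive every quantity from first principles (literal loops, matrix
# inversion, svd) instead of sharing code with the package.

# literal triple-loop PCIT reference over a correlation matrix
pcit_bruteforce <- function(cc) {
  n <- nrow(cc)
  sig <- abs(cc) > 0
  diag(sig) <- FALSE
  if (n < 3L) return(sig)
  for (x in 1:(n - 2)) for (y in (x + 1):(n - 1)) for (z in (y + 1):n) {
    rxy <- cc[x, y]; rxz <- cc[x, z]; ryz <- cc[y, z]
    if (max(abs(c(rxy, rxz, ryz))) >= 1 - 1e-12) next
    pxy <- (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
    pxz <- (rxz - rxy * ryz) / sqrt((1 - rxy^2) * (1 - ryz^2))
    pyz <- (ryz - rxy * rxz) / sqrt((1 - rxy^2) * (1 - rxz^2))
    dir <- c(rxy, rxz, ryz)
    par <- c(pxy, pxz, pyz)
    ok <- dir != 0
    if (!any(ok)) next
    eps <- mean(par[ok] / dir[ok])
    if (abs(rxy) <= abs(eps * rxz) && abs(rxy) <= abs(eps * ryz))
      sig[x, y] <- sig[y, x] <- FALSE
    if (abs(rxz) <= abs(eps * rxy) && abs(rxz) <= abs(eps * ryz))
      sig[x, z] <- sig[z, x] <- FALSE
    if (abs(ryz) <= abs(eps * rxy) && abs(ryz) <= abs(eps * rxz))
      sig[y, z] <- sig[z, y] <- FALSE
  }
  sig
}

# partial correlation via inversion of the 3x3 correlation matrix
partial_cor_oracle <- function(r_xy, r_xz, r_yz) {
  R <- matrix(c(1, r_xy, r_xz,
                r_xy, 1, r_yz,
                r_xz, r_yz, 1), 3, 3)
  P <- solve(R)
  -P[1, 2] / sqrt(P[1, 1] * P[2, 2])
}

# a random *consistent* correlation triple (from actual data, so the 3x3
# matrix is guaranteed positive definite)
random_cor_triple <- function(n = 6) {
  repeat {
    m <- matrix(rnorm(3 * n), 3, n)
    cc <- cor(t(m))
    r <- c(cc[1, 2], cc[1, 3], cc[2, 3])
    if (max(abs(r)) < 0.999) return(r)
  }
}

# PCA-score oracle via svd of the standardised matrix (the package uses an
# eigendecomposition of the correlation matrix)
pca_scores_oracle <- function(gebv, weight_mode = "proportion") {
  z <- scale(gebv)
  sv <- svd(z)
  load <- sv$v
  eigv <- sv$d^2 / (nrow(gebv) - 1)
  for (j in seq_len(ncol(load))) {
    k <- which.max(abs(load[, j]))
    if (load[k, j] < 0) load[, j] <- -load[, j]
  }
  w <- if (weight_mode == "proportion") eigv / sum(eigv) else eigv
  as.numeric((z %*% load) %*% w)
}

# degree-sequence hub oracle: literal count + population sd
hub_oracle <- function(edges_a, edges_b, all_nodes, mult = 2) {
  deg <- sapply(all_nodes, function(v) sum(edges_a == v) + sum(edges_b == v))
  mu <- sum(deg) / length(deg)
  sdp <- sqrt(sum((deg - mu)^2) / length(deg))
  list(degree = deg, threshold = mu + mult * sdp,
       hubs = all_nodes[deg > mu + mult * sdp])
}

# small labelled expression matrix helper
toy_matrix <- function(values, features, samples) {
  matrix(values, nrow = length(features),
         dimnames = list(features, samples), byrow = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
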