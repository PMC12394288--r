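# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: brute-force enumeration, explicit loops and
# numeric integration only.

# Forward diffusion signal by explicit per-volume loop (independent of
# simulate_dwi's vectorised path).
forward_signal_oracle <- function(D, s0, bvals, bvecs) {
  sapply(seq_along(bvals), function(i) {
    g <- bvecs[i, ]
    s0 * exp(-bvals[i] * drop(t(g) %*% D %*% g))
  })
}

# Exact two-sided Mann-Whitney p by enumeration of all group assignments.
mw_exact_p_oracle <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(n1 + n2, n1)
  u_all <- apply(combs, 2, function(idx) {
    sum(r[idx]) - n1 * (n1 + 1) / 2
  })
  p_le <- mean(u_all <= u_obs)
  p_ge <- mean(u_all >= u_obs)
  min(1, 2 * min(p_le, p_ge))
}

# Exact two-sided Wilcoxon signed-rank p by enumeration of all sign
# patterns (zero differences removed first).
signrank_exact_p_oracle <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- signs %*% r
  p_le <- mean(v_all <= v_obs)
  p_ge <- mean(v_all >= v_obs)
  min(1, 2 * min(p_le, p_ge))
}

# Benjamini-Hochberg adjustment from the cumulative-minimum formula.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj_sorted <- rev(cummin(rev(m * p[o] / seq_len(m))))
  out <- numeric(m)
  out[o] <- pmin(adj_sorted, 1)
  out
}

# Mean of a Rician(nu, sigma) variable by numeric integration of x * pdf.
rician_mean_numeric <- function(nu, sigma) {
  pdf <- function(x) {
    x / sigma^2 * exp(-(x^2 + nu^2) / (2 * sigma^2)) *
      besselI(x * nu / sigma^2, 0, expon.scaled = TRUE) *
      exp(x * nu / sigma^2)
  }
  stats::integrate(function(x) x * pdf(x), 0, nu + 12 * sigma,
                   rel.tol = 1e-9)$value
}

# Two-sided p of a t statistic by numeric integration of the t density
# (independent of pt()).
t_pvalue_numeric <- function(t, df) {
  dens <- function(x) {
    gamma((df + 1) / 2) / (sqrt(df * pi) * gamma(df / 2)) *
      (1 + x^2 / df)^(-(df + 1) / 2)
  }
  2 * stats::integrate(dens, abs(t), Inf, rel.tol = 1e-10)$value
}

# Random symmetric positive-definite diffusion tensor with eigenvalues in
# a physiological range (mm^2/s).
random_spd_tensor <- function() {
  lam <- sort(stats::runif(3, 0.2e-3, 2.2e-3), decreasing = TRUE)
  Q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  Q %*% diag(lam) %*% t(Q)
}

# Assemble a tensor_field directly from a voxels x 6 matrix of tensor
# elements (Dxx, Dyy, Dzz, Dxy, Dxz, Dyz), bypassing fit_tensor().
tensor_field_manual <- function(T6, s0 = 100, dims = c(nrow(T6), 1L, 1L),
                                voxel_mm = 2.5) {
  stopifnot(prod(dims) == nrow(T6))
  tens <- array(0, dim = c(dims, 6))
  for (k in 1:6) tens[, , , k] <- array(T6[, k], dim = dims)
  evals <- array(0, dim = c(dims, 3))
  e1 <- array(0, dim = c(dims, 3))
  fa <- array(0, dim = dims)
  md <- array(0, dim = dims)
  for (i in seq_len(nrow(T6))) {
    D <- matrix(c(T6[i, 1], T6[i, 4], T6[i, 5],
                  T6[i, 4], T6[i, 2], T6[i, 6],
                  T6[i, 5], T6[i, 6], T6[i, 3]), 3, 3)
    es <- eigen(D, symmetric = TRUE)
    co <- arrayInd(i, dims)
    lam <- pmax(es$values, 0)
    for (k in 1:3) {
      evals[co[1], co[2], co[3], k] <- lam[k]
      e1[co[1], co[2], co[3], k] <- es$vectors[k, 1]
    }
    fa[co] <- compute_fa(lam)
    md[co] <- mean(lam)
  }
  cfa <- array(0, dim = c(dims, 3))
  for (k in 1:3) cfa[, , , k] <- fa * abs(e1[, , , k])
  structure(
    list(tensors = tens, s0 = array(s0, dim = dims),
         mask = array(TRUE, dim = dims), eigenvalues = evals, e1 = e1,
         fa = fa, md = md, color_fa = cfa,
         affine = diag(c(rep(voxel_mm, 3), 1)), method = "manual"),
    class = "tensor_field"
  )
}

# Compact phantom used by unit tests where full acquisition size is not
# the point.
small_phantom_spec <- function(...) {
  phantom_spec(dims = c(30L, 30L, 12L),
               proj_bounds = rbind(x = c(4L, 12L), y = c(8L, 22L),
                                   z = c(4L, 9L)),
               assoc_bounds = rbind(x = c(18L, 26L), y = c(8L, 22L),
                                    z = c(4L, 9L)),
               ...)
}
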