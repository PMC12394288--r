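# Diffusion-tensor estimation and derived scalar/colour maps.
#
# The single-tensor model predicts S = S0 * exp(-b g' D g) for unit gradient
# g and b-value b. Taking logs gives a linear system in the 6 unique tensor
# elements plus log S0, solved per voxel by OLS or by one-pass weighted
# least squares (weights = squared predicted signal from the OLS solution).

#' Log-linear diffusion-tensor design matrix
#'
#' Row i is
#' `(-b gx^2, -b gy^2, -b gz^2, -2b gx gy, -2b gx gz, -2b gy gz, 1)`
#' so that `row %*% c(Dxx, Dyy, Dzz, Dxy, Dxz, Dyz, log S0)` equals the
#' log signal. Rows of unweighted volumes are exactly `(0,...,0,1)`.
#'
#' @param gtab A [gradient_table()].
#' @return Numeric matrix, one row per volume, 7 columns.
#' @export
dti_design_matrix <- function(gtab) {
  stopifnot(inherits(gtab, "gradient_table"))
  b <- gtab$bvals
  g <- gtab$bvecs
  B <- cbind(
    -b * g[, 1]^2,
    -b * g[, 2]^2,
    -b * g[, 3]^2,
    -2 * b * g[, 1] * g[, 2],
    -2 * b * g[, 1] * g[, 3],
    -2 * b * g[, 2] * g[, 3],
    1
  )
  B[b < gtab$b0_threshold, 1:6] <- 0
  colnames(B) <- c("Dxx", "Dyy", "Dzz", "Dxy", "Dxz", "Dyz", "logS0")
  B
}

#' Fractional anisotropy from eigenvalues
#'
#' `FA = sqrt(3/2) * sqrt(sum((lambda - mean)^2)) / sqrt(sum(lambda^2))`,
#' defined as 0 in the all-zero (isotropic-zero) limit. Inputs must be
#' non-negative; clamping of small negative eigenvalues produced by noisy
#' fits happens upstream in [fit_tensor()].
#'
#' @param eigenvalues Length-3 numeric vector, or an n x 3 matrix of
#'   eigenvalue triples.
#' @return Scalar (or length-n vector) in `[0, 1]`.
#' @export
#' @examples
#' compute_fa(c(1.7, 0.3, 0.3) * 1e-3)  # 0.79902
compute_fa <- function(eigenvalues) {
  ev <- if (is.matrix(eigenvalues)) eigenvalues else rbind(eigenvalues)
  if (ncol(ev) != 3L) stop("eigenvalues must come in triples")
  if (any(ev < 0)) stop("negative eigenvalue passed to compute_fa()")
  ssq <- rowSums(ev^2)
  mu <- rowMeans(ev)
  dev <- rowSums((ev - mu)^2)
  fa <- ifelse(ssq == 0, 0, sqrt(1.5 * dev / ssq))
  fa <- pmin(fa, 1)
  if (is.matrix(eigenvalues)) fa else fa[[1]]
}

#' Fit diffusion tensors voxel-wise
#'
#' Solves the log-linearised tensor model per masked voxel. `"wls"` (the
#' default) performs one reweighting pass from the OLS solution with
#' weights equal to the squared predicted signal, the standard correction
#' for the log transform's noise heteroscedasticity. Signals at or below
#' zero are floored at `1e-4` times the voxel's b0 estimate before the log,
#' which leaves clean data untouched while avoiding `-Inf` under noise.
#'
#' Negative eigenvalues are clamped to zero before FA/MD so FA stays in
#' `[0, 1]`. Principal eigenvector signs are fixed by making the
#' largest-magnitude component positive (colour FA uses absolute values, so
#' the choice is cosmetic but keeps results deterministic).
#'
#' @param dwi A [dwi_volume()].
#' @param mask 3D logical array selecting voxels to fit. `NULL` uses a
#'   simple fallback: voxels whose mean b0 signal exceeds 1% of the robust
#'   maximum.
#' @param method `"wls"` or `"ols"`.
#' @param b_max Optional shell restriction: only volumes with
#'   `bval <= b_max` (plus all b0 volumes) enter the fit.
#' @return Object of class `tensor_field`: arrays `tensors` (x,y,z,6 in the
#'   order Dxx, Dyy, Dzz, Dxy, Dxz, Dyz; mm^2/s), `s0`, `mask`,
#'   `eigenvalues` (x,y,z,3, descending), `e1` (principal eigenvector),
#'   `fa`, `md`, `color_fa` (x,y,z,3 = FA-weighted |e1| components), and
#'   the `affine`.
#' @export
fit_tensor <- function(dwi, mask = NULL, method = c("wls", "ols"),
                       b_max = NULL) {
  stopifnot(inherits(dwi, "dwi_volume"))
  method <- match.arg(method)
  gtab <- dwi$gtab
  keep <- rep(TRUE, length(gtab$bvals))
  if (!is.null(b_max)) {
    keep <- gtab$bvals <= b_max | gtab$bvals < gtab$b0_threshold
  }
  bvals <- gtab$bvals[keep]
  if (sum(keep) < 7L) {
    stop("tensor fit needs at least 7 volumes, have ", sum(keep))
  }
  sub_gtab <- gradient_table(bvals, gtab$bvecs[keep, , drop = FALSE],
                             gtab$b0_threshold)
  B <- dti_design_matrix(sub_gtab)
  if (qr(B)$rank < 7L) {
    stop("rank-deficient design: gradient directions span fewer than 6 ",
         "independent tensor components")
  }

  dims <- dim(dwi$data)[1:3]
  nvox_total <- prod(dims)
  sig <- matrix(dwi$data, nrow = nvox_total)[, keep, drop = FALSE]

  is_b0 <- bvals < gtab$b0_threshold
  s0_est <- rowMeans(sig[, is_b0, drop = FALSE])

  if (is.null(mask)) {
    thr <- 0.01 * stats::quantile(s0_est, 0.99, names = FALSE)
    mask <- array(s0_est > thr, dim = dims)
  }
  if (!all(dim(mask) == dims)) stop("mask dimensions do not match volume")
  mask <- array(as.logical(mask), dim = dims)
  vox <- which(mask)
  if (!length(vox)) stop("empty mask: no voxels to fit")

  S <- t(sig[vox, , drop = FALSE])            # volumes x voxels
  s0v <- s0_est[vox]
  floor_v <- pmax(1e-4 * pmax(s0v, .Machine$double.eps),
                  .Machine$double.eps)
  S <- pmax(S, rep(floor_v, each = nrow(S)))
  Y <- log(S)

  coef <- qr.solve(B, Y)                      # OLS, 7 x voxels
  if (method == "wls") {
    W <- exp(2 * (B %*% coef))                # squared predicted signal
    coef <- solve_wls_batch(B, Y, W)
  }

  n <- length(vox)
  tens6 <- t(coef[1:6, , drop = FALSE])       # voxels x 6
  s0fit <- exp(coef[7, ])

  evals <- matrix(0, n, 3)
  e1 <- matrix(0, n, 3)
  D <- matrix(0, 3, 3)
  for (i in seq_len(n)) {
    d <- tens6[i, ]
    D[1, 1] <- d[1]; D[2, 2] <- d[2]; D[3, 3] <- d[3]
    D[1, 2] <- D[2, 1] <- d[4]
    D[1, 3] <- D[3, 1] <- d[5]
    D[2, 3] <- D[3, 2] <- d[6]
    es <- eigen(D, symmetric = TRUE)
    evals[i, ] <- pmax(es$values, 0)
    v <- es$vectors[, 1]
    if (v[which.max(abs(v))] < 0) v <- -v
    e1[i, ] <- v
  }

  fa_v <- compute_fa(evals)
  md_v <- rowMeans(evals)
  cfa_v <- fa_v * abs(e1)

  blank3 <- function() array(0, dim = dims)
  blank4 <- function(k) array(0, dim = c(dims, k))
  fill3 <- function(v) { a <- blank3(); a[vox] <- v; a }
  fill4 <- function(m) {
    a <- blank4(ncol(m))
    for (k in seq_len(ncol(m))) {
      s <- blank3(); s[vox] <- m[, k]; a[, , , k] <- s
    }
    a
  }

  structure(
    list(
      tensors = fill4(tens6),
      s0 = fill3(s0fit),
      mask = mask,
      eigenvalues = fill4(evals),
      e1 = fill4(e1),
      fa = fill3(fa_v),
      md = fill3(md_v),
      color_fa = fill4(cfa_v),
      affine = dwi$affine,
      method = method
    ),
    class = "tensor_field"
  )
}

# Batched per-voxel weighted least squares: for each voxel v solve
# (B' W_v B) c = B' W_v y. The normal-equation entries are linear in the
# weights, so all voxels' 7x7 systems are assembled with two matrix
# products; only the small solves remain in the loop.
solve_wls_batch <- function(B, Y, W) {
  p <- ncol(B)
  nv <- ncol(Y)
  idx <- which(upper.tri(matrix(0, p, p), diag = TRUE), arr.ind = TRUE)
  Bprod <- B[, idx[, 1], drop = FALSE] * B[, idx[, 2], drop = FALSE]
  A_flat <- crossprod(Bprod, W)               # p(p+1)/2 x voxels
  R_flat <- crossprod(B, W * Y)               # p x voxels (B' diag(w) y)
  coef <- matrix(0, p, nv)
  A <- matrix(0, p, p)
  for (v in seq_len(nv)) {
    A[idx] <- A_flat[, v]
    A[lower.tri(A)] <- t(A)[lower.tri(A)]
    coef[, v] <- solve(A, R_flat[, v])
  }
  coef
}

#' @export
print.tensor_field <- function(x, ...) {
  cat("<tensor_field> ", paste(dim(x$mask), collapse = " x "),
      " voxels, ", sum(x$mask), " in mask (", x$method %||% "given",
      " fit)\n", sep = "")
  if (sum(x$mask)) {
    cat("  FA range in mask: ",
        paste(signif(range(x$fa[x$mask]), 3), collapse = " - "), "\n",
        sep = "")
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Colour fractional-anisotropy map
#'
#' Channel c of the colour-FA map is `FA * |e1_c|`: red encodes
#' left-right (x), green anterior-posterior (y), blue superior-inferior
#' (z) principal-direction components. Each channel lies in `[0, 1]` and
#' never exceeds the voxel's FA.
#'
#' @param field A `tensor_field` from [fit_tensor()].
#' @return 4D array (x, y, z, 3).
#' @export
compute_color_fa <- function(field) {
  stopifnot(inherits(field, "tensor_field"))
  dims <- dim(field$fa)
  out <- array(0, dim = c(dims, 3))
  for (k in 1:3) out[, , , k] <- field$fa * abs(field$e1[, , , k])
  out
}

#' One-line summary of a tensor field
#' @param x A `tensor_field`.
#' @param ... Unused.
#' @return One-row tibble with voxel counts and FA/MD summaries in-mask.
#' @method glance tensor_field
#' @export
glance.tensor_field <- function(x, ...) {
  m <- x$mask
  tibble::tibble(
    n_voxels = length(m),
    n_mask = sum(m),
    fa_mean = mean(x$fa[m]),
    fa_max = max(x$fa[m]),
    md_mean = mean(x$md[m]),
    method = x$method %||% NA_character_
  )
}

#' Export FA, MD and colour-FA maps as NIfTI files
#'
#' @param field A `tensor_field`.
#' @param out_prefix Path prefix; writes `<prefix>_fa.nii.gz`,
#'   `<prefix>_md.nii.gz` and `<prefix>_color_fa.nii.gz`.
#' @return Invisibly, a named character vector of the written paths.
#' @export
export_maps <- function(field, out_prefix) {
  stopifnot(inherits(field, "tensor_field"))
  paths <- c(
    fa = paste0(out_prefix, "_fa.nii.gz"),
    md = paste0(out_prefix, "_md.nii.gz"),
    color_fa = paste0(out_prefix, "_color_fa.nii.gz")
  )
  write_scalar_map(field$fa, field$affine, paths[["fa"]])
  write_scalar_map(field$md, field$affine, paths[["md"]])
  write_scalar_map(field$color_fa, field$affine, paths[["color_fa"]])
  invisible(paths)
}
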