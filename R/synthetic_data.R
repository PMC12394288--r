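# Synthetic data: diffusion phantoms with a known ground-truth ALPS index,
# multi-shell signal simulation under Rician noise, and simulated
# longitudinal cohorts matching published group summaries.

#' Specify a two-slab ALPS phantom
#'
#' The phantom realises the ALPS geometry in a periventricular field: a
#' slab of z-oriented projection fibres (diagonal tensor
#' `diag(d_x, d_perp, d_principal)`) and a disjoint slab of y-oriented
#' association fibres (`diag(d_x, d_principal, d_perp)`), embedded in an
#' isotropic background. Both slabs share the perivascular x-diffusivity
#' `d_x`; the reference diffusivities perpendicular to fibre and
#' perivascular axes equal `d_perp`, so the ground-truth ALPS index is
#' `d_x / d_perp` by construction.
#'
#' @param dims Grid size in voxels (default `c(40, 40, 20)`).
#' @param voxel_mm Isotropic voxel edge (default 2.5 mm, the acquisition
#'   resolution the phantom emulates).
#' @param proj_bounds,assoc_bounds 3x2 integer matrices of inclusive
#'   1-based index bounds (rows x, y, z) for the two slabs.
#' @param d_x Common x-diffusivity of both slabs (mm^2/s).
#' @param d_perp Dyy of the projection slab and Dzz of the association
#'   slab (mm^2/s).
#' @param d_principal Dominant eigenvalue of each slab (z for projection,
#'   y for association); must exceed `d_x` and `d_perp` so the blue/green
#'   channel dominance of the colour-FA map holds.
#' @param d_background Isotropic background diffusivity (mm^2/s).
#' @param s0 Baseline (unweighted) signal, arbitrary scanner units.
#' @return Object of class `phantom_spec` with an added `true_alps`
#'   element.
#' @export
#' @examples
#' phantom_spec()$true_alps  # 1.25
phantom_spec <- function(dims = c(40L, 40L, 20L), voxel_mm = 2.5,
                         proj_bounds = rbind(x = c(6L, 16L),
                                             y = c(10L, 30L),
                                             z = c(5L, 15L)),
                         assoc_bounds = rbind(x = c(24L, 34L),
                                              y = c(10L, 30L),
                                              z = c(5L, 15L)),
                         d_x = 0.75e-3, d_perp = 0.6e-3,
                         d_principal = 1.6e-3, d_background = 0.7e-3,
                         s0 = 100) {
  stopifnot(length(dims) == 3L, all(dims >= 1), voxel_mm > 0, s0 > 0,
            all(c(d_x, d_perp, d_principal, d_background) > 0))
  if (d_principal <= d_x || d_principal <= d_perp) {
    stop("d_principal must exceed d_x and d_perp so that fibre-axis ",
         "channel dominance holds")
  }
  check_bounds <- function(b, label) {
    if (!all(dim(b) == c(3L, 2L))) stop(label, " must be a 3x2 matrix")
    if (any(b[, 1] > b[, 2])) stop(label, ": lower bound exceeds upper")
    if (any(b[, 1] < 1) || any(b[, 2] > dims)) {
      stop(label, " outside the grid")
    }
  }
  check_bounds(proj_bounds, "proj_bounds")
  check_bounds(assoc_bounds, "assoc_bounds")
  overlap <- all(proj_bounds[, 1] <= assoc_bounds[, 2] &
                 assoc_bounds[, 1] <= proj_bounds[, 2])
  if (overlap) stop("projection and association slabs overlap")
  structure(
    list(dims = as.integer(dims), voxel_mm = voxel_mm,
         proj_bounds = proj_bounds, assoc_bounds = assoc_bounds,
         d_x = d_x, d_perp = d_perp, d_principal = d_principal,
         d_background = d_background, s0 = s0,
         true_alps = d_x / d_perp),
    class = "phantom_spec"
  )
}

slab_mask <- function(dims, bounds) {
  m <- array(FALSE, dim = dims)
  m[bounds[1, 1]:bounds[1, 2],
    bounds[2, 1]:bounds[2, 2],
    bounds[3, 1]:bounds[3, 2]] <- TRUE
  m
}

#' Build the ground-truth tensor field of a phantom
#'
#' Returns a `tensor_field` (same container as [fit_tensor()] output)
#' whose tensors, eigensystem and derived maps are set analytically from
#' the specification — the reference against which fitted fields and the
#' recovered ALPS index are compared.
#'
#' @param spec A [phantom_spec()].
#' @return A `tensor_field` with an `affine` of `voxel_mm` times the
#'   identity (RAS+).
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  dims <- spec$dims
  proj <- slab_mask(dims, spec$proj_bounds)
  assoc <- slab_mask(dims, spec$assoc_bounds)
  if (any(proj & assoc)) stop("projection and association slabs overlap")
  bg <- !(proj | assoc)

  tens <- array(0, dim = c(dims, 6))
  set_diag <- function(tens, m, dxx, dyy, dzz) {
    t1 <- tens[, , , 1]; t1[m] <- dxx; tens[, , , 1] <- t1
    t2 <- tens[, , , 2]; t2[m] <- dyy; tens[, , , 2] <- t2
    t3 <- tens[, , , 3]; t3[m] <- dzz; tens[, , , 3] <- t3
    tens
  }
  tens <- set_diag(tens, proj, spec$d_x, spec$d_perp, spec$d_principal)
  tens <- set_diag(tens, assoc, spec$d_x, spec$d_principal, spec$d_perp)
  tens <- set_diag(tens, bg, spec$d_background, spec$d_background,
                   spec$d_background)

  evals <- array(0, dim = c(dims, 3))
  e1 <- array(0, dim = c(dims, 3))
  fill_eig <- function(evals, e1, m, lam, vec) {
    for (k in 1:3) {
      a <- evals[, , , k]; a[m] <- lam[k]; evals[, , , k] <- a
      b <- e1[, , , k]; b[m] <- vec[k]; e1[, , , k] <- b
    }
    list(evals = evals, e1 = e1)
  }
  r <- fill_eig(evals, e1, proj,
                sort(c(spec$d_x, spec$d_perp, spec$d_principal),
                     decreasing = TRUE), c(0, 0, 1))
  r <- fill_eig(r$evals, r$e1, assoc,
                sort(c(spec$d_x, spec$d_principal, spec$d_perp),
                     decreasing = TRUE), c(0, 1, 0))
  r <- fill_eig(r$evals, r$e1, bg, rep(spec$d_background, 3), c(1, 0, 0))
  evals <- r$evals; e1 <- r$e1

  ev_mat <- matrix(evals, ncol = 3)
  fa <- array(compute_fa(ev_mat), dim = dims)
  md <- array(rowMeans(ev_mat), dim = dims)
  cfa <- array(0, dim = c(dims, 3))
  for (k in 1:3) cfa[, , , k] <- fa * abs(e1[, , , k])

  affine <- diag(c(rep(spec$voxel_mm, 3), 1))
  structure(
    list(tensors = tens, s0 = array(spec$s0, dim = dims),
         mask = array(TRUE, dim = dims),
         eigenvalues = evals, e1 = e1, fa = fa, md = md, color_fa = cfa,
         affine = affine, method = "ground-truth", spec = spec),
    class = "tensor_field"
  )
}

#' Default search rectangles for a phantom
#'
#' Rectangles on the mid-slab axial slice of each slab — the stand-in for
#' the operator's manual delineation. The rectangles are inset from the
#' slab edges by `margin` voxels, mirroring how an operator draws the
#' search region well inside the fibre bundle; the inset also guarantees
#' the circular ROI stays within the homogeneous slab even when the peak
#' voxel lies on the rectangle border.
#'
#' @param spec A [phantom_spec()].
#' @param hemisphere Passed through to [search_rectangle()].
#' @param margin In-plane inset from the slab bounds, voxels.
#' @return List with `projection` and `association` rectangles.
#' @export
phantom_rectangles <- function(spec, hemisphere = "left", margin = 2L) {
  stopifnot(inherits(spec, "phantom_spec"))
  mid <- function(b) as.integer(round(mean(b[3, ])))
  inset <- function(b) {
    r <- c(b[1] + margin, b[2] - margin)
    if (r[1] > r[2]) stop("margin too large for slab extent")
    r
  }
  list(
    projection = search_rectangle(mid(spec$proj_bounds),
                                  inset(spec$proj_bounds[1, ]),
                                  inset(spec$proj_bounds[2, ]),
                                  hemisphere = hemisphere),
    association = search_rectangle(mid(spec$assoc_bounds),
                                   inset(spec$assoc_bounds[1, ]),
                                   inset(spec$assoc_bounds[2, ]),
                                   hemisphere = hemisphere)
  )
}

#' Quasi-uniform gradient directions by Fibonacci-sphere placement
#'
#' @param n Number of directions.
#' @return n x 3 matrix of unit vectors.
#' @export
fibonacci_directions <- function(n) {
  stopifnot(n >= 1)
  i <- seq_len(n) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(1 - z^2, 0))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Default multi-shell acquisition scheme
#'
#' One unweighted volume plus 30 directions at b = 711 s/mm^2 and 61
#' directions at b = 2400 s/mm^2, 92 volumes in total — the multi-shell
#' ALPS protocol the phantom emulates. The exact direction sets of
#' clinical scanners are vendor-specific, so quasi-uniform
#' Fibonacci-sphere directions are used.
#'
#' @param n_b0 Number of b0 volumes.
#' @param shell_dirs Directions per shell.
#' @param shell_bvals b-value of each shell (s/mm^2).
#' @return A [gradient_table()].
#' @export
default_gradient_table <- function(n_b0 = 1L, shell_dirs = c(30L, 61L),
                                   shell_bvals = c(711, 2400)) {
  stopifnot(length(shell_dirs) == length(shell_bvals))
  bvals <- c(rep(0, n_b0), rep(shell_bvals, shell_dirs))
  vecs <- do.call(rbind, lapply(shell_dirs, fibonacci_directions))
  bvecs <- rbind(matrix(0, n_b0, 3), vecs)
  gradient_table(bvals, bvecs)
}

#' Simulate a diffusion-weighted acquisition from a tensor field
#'
#' Applies the forward model `S = S0 * exp(-b g' D g)` volume by volume
#' and adds magnitude (Rician) noise:
#' `sqrt((S + e1)^2 + e2^2)` with `e1, e2 ~ Normal(0, sigma^2)`.
#' With `noise_sigma = 0` the noise-free closed form is returned exactly.
#' A Gaussian noise option is exposed for debugging.
#'
#' @param truth A `tensor_field` (e.g. from [make_phantom()]).
#' @param gtab A [gradient_table()].
#' @param noise_sigma Noise standard deviation in signal units
#'   (`s0 / SNR` for a target b0 signal-to-noise ratio).
#' @param seed Optional integer; fixing it makes the draw reproducible.
#' @param noise_model `"rician"` (default) or `"gaussian"`.
#' @return A [dwi_volume()].
#' @export
simulate_dwi <- function(truth, gtab, noise_sigma = 0, seed = NULL,
                         noise_model = c("rician", "gaussian")) {
  stopifnot(inherits(truth, "tensor_field"), inherits(gtab, "gradient_table"),
            noise_sigma >= 0)
  noise_model <- match.arg(noise_model)
  if (!is.null(seed)) set.seed(seed)
  dims <- dim(truth$mask)
  nvox <- prod(dims)
  nvol <- length(gtab$bvals)
  T6 <- matrix(truth$tensors, nrow = nvox)    # voxels x 6
  g <- gtab$bvecs
  b <- gtab$bvals
  # quadratic form g' D g for every (voxel, volume)
  Q <- T6 %*% rbind(g[, 1]^2, g[, 2]^2, g[, 3]^2,
                    2 * g[, 1] * g[, 2], 2 * g[, 1] * g[, 3],
                    2 * g[, 2] * g[, 3])
  S <- as.vector(truth$s0) * exp(-Q * rep(b, each = nvox))
  if (noise_sigma > 0) {
    if (noise_model == "rician") {
      e1 <- stats::rnorm(length(S), 0, noise_sigma)
      e2 <- stats::rnorm(length(S), 0, noise_sigma)
      S <- sqrt((S + e1)^2 + e2^2)
    } else {
      S <- pmax(S + stats::rnorm(length(S), 0, noise_sigma), 0)
    }
  }
  dwi_volume(array(S, dim = c(dims, nvol)), truth$affine, gtab)
}

#' Published group summaries of the left ALPS index
#'
#' Per-group mean (SD) of the left ALPS index over the study timepoints:
#' tap-test responders (R, n = 15), non-responders (NR, n = 6) and healthy
#' controls (HC, n = 8); 9 responders repeated imaging three months after
#' shunt surgery. These summaries parameterise the cohort simulator and
#' let the printed between-group baseline comparisons be recomputed.
#'
#' @return Tibble with columns `group`, `timepoint`, `n`, `mean`, `sd`.
#' @export
alps_reference_summaries <- function() {
  tibble::tibble(
    group = c("R", "R", "R", "NR", "NR", "HC"),
    timepoint = c("t0", "t1_postTT", "t3_postVPS", "t0", "t1_postTT", "t0"),
    n = c(15L, 15L, 9L, 6L, 6L, 8L),
    mean = c(1.003, 1.069, 1.120, 0.960, 0.991, 1.263),
    sd = c(0.108, 0.122, 0.117, 0.079, 0.078, 0.161)
  )
}

#' Simulate a longitudinal ALPS cohort
#'
#' Draws per-subject ALPS trajectories: each subject's values across their
#' group's timepoints follow a multivariate normal with the per-timepoint
#' means and SDs and a common (exchangeable) within-subject correlation —
#' the simplest construction with a controllable paired correlation for
#' exercising the paired tests. Follow-up imaging after shunt surgery is
#' limited to the first `n_followup` responders.
#'
#' @param summaries Tibble like [alps_reference_summaries()] (`group`,
#'   `timepoint`, `n`, `mean`, `sd`).
#' @param correlation Within-subject correlation between timepoints, in
#'   `[0, 1)`.
#' @param n_followup Number of responders with a `t3_postVPS` row.
#' @param seed Optional integer seed.
#' @return Tibble with `subject_id`, `group`, `timepoint`, `alps_index`.
#' @export
simulate_cohort <- function(summaries = alps_reference_summaries(),
                            correlation = 0.7, n_followup = 9L,
                            seed = NULL) {
  stopifnot(correlation >= 0, correlation < 1)
  if (any(summaries$sd < 0)) stop("SDs must be non-negative")
  if (any(summaries$n < 2)) stop("group sizes must be at least 2")
  if (!is.null(seed)) set.seed(seed)
  out <- purrr::map_dfr(unique(summaries$group), function(g) {
    sg <- summaries[summaries$group == g, ]
    k <- nrow(sg)
    n <- max(sg$n)
    R <- matrix(correlation, k, k); diag(R) <- 1
    Sigma <- diag(sg$sd, k) %*% R %*% diag(sg$sd, k)
    draws <- MASS::mvrnorm(n, mu = sg$mean, Sigma = Sigma)
    draws <- matrix(draws, nrow = n)
    tibble::tibble(
      subject_id = rep(sprintf("%s%02d", g, seq_len(n)), each = k),
      group = g,
      timepoint = rep(sg$timepoint, times = n),
      alps_index = as.vector(t(draws)),
      .subject_rank = rep(seq_len(n), each = k),
      .tp_n = rep(sg$n, times = n)
    )
  })
  out <- out[out$.subject_rank <= out$.tp_n, ]
  if (!is.null(n_followup)) {
    drop <- out$timepoint == "t3_postVPS" & out$.subject_rank > n_followup
    out <- out[!drop, ]
  }
  out$.subject_rank <- NULL
  out$.tp_n <- NULL
  out
}

#' Boxplots of a simulated (or measured) cohort
#'
#' Distribution of the ALPS index by group and timepoint.
#'
#' @param cohort Tibble with `group`, `timepoint`, `alps_index`.
#' @return A ggplot object.
#' @export
plot_cohort <- function(cohort) {
  ggplot2::ggplot(cohort,
                  ggplot2::aes(x = .data$timepoint, y = .data$alps_index,
                               fill = .data$group)) +
    ggplot2::geom_boxplot(position = ggplot2::position_dodge2(preserve = "single")) +
    ggplot2::labs(x = "timepoint", y = "left ALPS index", fill = "group") +
    ggplot2::theme_minimal()
}
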