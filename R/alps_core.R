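# The semi-automatic ALPS procedure: colour-channel isolation by percentile
# thresholding, peak-FA search inside operator rectangles, circular ROI
# placement, directional-diffusivity extraction and the ALPS index.
#
# Voxel coordinates throughout the R interface are 1-based (R convention);
# world coordinates are obtained by applying the affine to the 0-based
# index, matching the NIfTI transform definition.

#' Define a rectangular search region
#'
#' The operator delimits a rectangle on one axial slice of the
#' posterior periventricular white matter; the automatic steps search for
#' peak colour-FA voxels only inside it.
#'
#' @param slice_index Axial (z) voxel index, 1-based.
#' @param x_range,y_range Inclusive 1-based voxel-index bounds,
#'   length-2 integer vectors.
#' @param hemisphere `"left"` or `"right"`. The left hemisphere is the
#'   default throughout: shunt hardware is conventionally implanted on the
#'   right and its susceptibility artefacts contaminate right-sided
#'   measurements.
#' @return Object of class `search_rectangle`.
#' @export
search_rectangle <- function(slice_index, x_range, y_range,
                             hemisphere = c("left", "right")) {
  hemisphere <- match.arg(hemisphere)
  x_range <- as.integer(sort(x_range))
  y_range <- as.integer(sort(y_range))
  slice_index <- as.integer(slice_index)
  stopifnot(length(x_range) == 2L, length(y_range) == 2L,
            length(slice_index) == 1L)
  if (any(c(x_range, y_range, slice_index) < 1L)) {
    stop("rectangle bounds must be positive 1-based voxel indices")
  }
  structure(list(slice_index = slice_index, x_range = x_range,
                 y_range = y_range, hemisphere = hemisphere),
            class = "search_rectangle")
}

#' ALPS analysis configuration
#'
#' @param percentile Colour-channel threshold percentile inside the search
#'   rectangle (default 95).
#' @param roi_diameter_mm Diameter of the circular ROIs placed at the peak
#'   voxels (default 5 mm).
#' @param hemisphere Hemisphere analysed (default `"left"`).
#' @return Object of class `alps_config`.
#' @export
alps_config <- function(percentile = 95, roi_diameter_mm = 5,
                        hemisphere = c("left", "right")) {
  hemisphere <- match.arg(hemisphere)
  if (!(percentile > 0 && percentile < 100)) {
    stop("percentile must lie strictly between 0 and 100")
  }
  if (roi_diameter_mm <= 0) stop("roi_diameter_mm must be positive")
  structure(list(percentile = percentile, roi_diameter_mm = roi_diameter_mm,
                 hemisphere = hemisphere),
            class = "alps_config")
}

rect_indices <- function(rect, dims) {
  if (rect$slice_index > dims[3] ||
      rect$x_range[2] > dims[1] || rect$y_range[2] > dims[2]) {
    stop("search rectangle exceeds volume bounds (",
         paste(dims, collapse = " x "), ")")
  }
  list(x = rect$x_range[1]:rect$x_range[2],
       y = rect$y_range[1]:rect$y_range[2],
       z = rect$slice_index)
}

#' Isolate projection and association fibre voxels in a search rectangle
#'
#' Reduces the colour-FA map to a green-blue map inside the rectangle:
#' the projection mask keeps voxels whose blue channel (z-oriented fibres)
#' reaches the configured percentile of blue values in the rectangle *and*
#' is the dominant channel; the association mask does the same for green
#' (y-oriented fibres). Dominance ties go to the projection (blue) system,
#' so the two masks are disjoint. Percentiles interpolate linearly between
#' order statistics.
#'
#' @param color_fa 4D (x, y, z, 3) colour-FA array.
#' @param rect A [search_rectangle()].
#' @param cfg An [alps_config()].
#' @param channels Which fibre systems to isolate in this rectangle. With
#'   separate operator rectangles per system, only the matching channel is
#'   thresholded (and only it must contain anisotropic tissue).
#' @return List with logical 3D arrays `projection` and/or `association`.
#' @export
channel_masks <- function(color_fa, rect, cfg = alps_config(),
                          channels = c("projection", "association")) {
  channels <- match.arg(channels, several.ok = TRUE)
  stopifnot(length(dim(color_fa)) == 4L, dim(color_fa)[4] == 3L)
  dims <- dim(color_fa)[1:3]
  ri <- rect_indices(rect, dims)
  nvox <- length(ri$x) * length(ri$y)
  if (nvox < 1L) stop("empty search rectangle")
  if (nvox < 20L) {
    stop("search rectangle holds only ", nvox,
         " voxels; at least 20 are needed for a stable percentile")
  }
  red   <- color_fa[ri$x, ri$y, ri$z, 1, drop = TRUE]
  green <- color_fa[ri$x, ri$y, ri$z, 2, drop = TRUE]
  blue  <- color_fa[ri$x, ri$y, ri$z, 3, drop = TRUE]
  masks <- list()
  for (ch in channels) {
    vals <- if (ch == "projection") blue else green
    # channel values at numerical-noise level mean no oriented tissue
    if (all(vals <= 1e-6)) {
      stop("no anisotropic tissue in search region: ",
           if (ch == "projection") "blue" else "green",
           " channel is zero everywhere in the rectangle")
    }
    q <- stats::quantile(vals, cfg$percentile / 100, names = FALSE, type = 7)
    dominant <- if (ch == "projection") {
      blue >= green & blue >= red
    } else {
      green > blue & green >= red
    }
    sel <- vals >= q & dominant
    m <- array(FALSE, dim = dims)
    m[ri$x, ri$y, ri$z] <- sel
    masks[[ch]] <- m
  }
  masks
}

#' Locate the peak-value voxel of a channel within a mask
#'
#' Ties are broken by lexicographic (x, y, z) order so the result is
#' deterministic.
#'
#' @param channel 3D numeric array (one colour-FA channel).
#' @param mask Logical 3D array of candidate voxels.
#' @return Integer vector `c(x, y, z)`, 1-based.
#' @export
find_peak <- function(channel, mask) {
  stopifnot(all(dim(channel) == dim(mask)))
  idx <- which(mask)
  if (!length(idx)) stop("empty mask: no candidate voxels for peak search")
  vals <- channel[idx]
  cand <- idx[vals == max(vals)]
  coords <- arrayInd(cand, dim(channel))
  ord <- order(coords[, 1], coords[, 2], coords[, 3])
  as.integer(coords[ord[1], ])
}

#' Voxels of a circular in-plane ROI
#'
#' Collects the voxels of the centre's axial slice whose centre-to-centre
#' world distance (computed through the affine, in mm) is at most the ROI
#' radius, boundary inclusive. With 2.5 mm voxels and the default 5 mm
#' diameter this yields the 5-voxel cross: the four in-plane neighbours sit
#' at exactly one radius. ROIs reaching past the volume edge are clipped
#' with a warning.
#'
#' @param center Integer `c(x, y, z)`, 1-based voxel coordinate.
#' @param diameter_mm ROI diameter in mm.
#' @param affine 4x4 voxel-to-world transform.
#' @param dims Length-3 volume dimensions.
#' @return Integer matrix, one row per ROI voxel, columns x, y, z.
#' @export
circular_roi <- function(center, diameter_mm, affine, dims) {
  if (diameter_mm <= 0) stop("ROI diameter must be positive")
  center <- as.integer(center)
  stopifnot(length(center) == 3L)
  if (any(center < 1L) || any(center > dims)) {
    stop("ROI centre outside volume bounds")
  }
  radius <- diameter_mm / 2
  vox <- voxel_size(affine)
  # candidate in-plane index offsets covering the radius
  rx <- ceiling(radius / vox[1])
  ry <- ceiling(radius / vox[2])
  cand <- expand.grid(x = center[1] + (-rx:rx), y = center[2] + (-ry:ry))
  cand$z <- center[3]
  inb <- cand$x >= 1 & cand$x <= dims[1] & cand$y >= 1 & cand$y <= dims[2]
  A <- as.matrix(affine)
  world <- function(m) t(A %*% rbind(t(as.matrix(m)) - 1, 1))[, 1:3, drop = FALSE]
  cw <- world(matrix(center, nrow = 1))
  allw <- world(cand[, c("x", "y", "z")])
  d <- sqrt(rowSums((allw - matrix(cw, nrow(allw), 3, byrow = TRUE))^2))
  keep <- d <= radius + 1e-9
  if (any(keep & !inb)) {
    warning("circular ROI at (", paste(center, collapse = ", "),
            ") clipped at the volume edge: ", sum(keep & !inb),
            " voxel(s) dropped")
  }
  sel <- cand[keep & inb, c("x", "y", "z"), drop = FALSE]
  unname(as.matrix(sel))
}

#' Mean directional diffusivities over the ALPS ROIs
#'
#' Averages tensor elements in the scanner frame (not eigenvalues):
#' Dxx over both ROIs, Dyy over the projection ROI, Dzz over the
#' association ROI. In the ALPS geometry the x axis runs along the
#' perivascular spaces, perpendicular to both fibre systems.
#'
#' @param field A `tensor_field`.
#' @param proj_roi,assoc_roi Integer matrices of 1-based voxel coordinates
#'   (rows = voxels), as returned by [circular_roi()].
#' @return Named list `dx_proj`, `dy_proj`, `dx_assoc`, `dz_assoc`
#'   (mm^2/s).
#' @export
extract_diffusivities <- function(field, proj_roi, assoc_roi) {
  stopifnot(inherits(field, "tensor_field"))
  check_roi <- function(roi, label) {
    if (!is.matrix(roi) || ncol(roi) != 3L || nrow(roi) < 1L) {
      stop(label, " ROI must be a non-empty n x 3 coordinate matrix")
    }
    inmask <- field$mask[roi]
    if (!all(inmask)) {
      bad <- roi[!inmask, , drop = FALSE]
      stop(label, " ROI leaves the tensor mask at voxel(s): ",
           paste(apply(bad, 1, paste, collapse = ","), collapse = "; "))
    }
  }
  check_roi(proj_roi, "projection")
  check_roi(assoc_roi, "association")
  elem <- function(roi, k) {
    mean(field$tensors[cbind(roi, k)])
  }
  list(
    dx_proj = elem(proj_roi, 1L),
    dy_proj = elem(proj_roi, 2L),
    dx_assoc = elem(assoc_roi, 1L),
    dz_assoc = elem(assoc_roi, 3L)
  )
}

#' ALPS index from the four directional diffusivities
#'
#' `ALPS = mean(Dxx_proj, Dxx_assoc) / mean(Dyy_proj, Dzz_assoc)`.
#' The numerator captures diffusion along the perivascular (x) direction;
#' the denominator is the reference diffusivity perpendicular to both the
#' perivascular spaces and the respective fibre tracts. The ratio is
#' dimensionless and invariant under common rescaling of all four inputs;
#' values near 1 indicate no preferential perivascular diffusion.
#'
#' @param dx_proj,dy_proj,dx_assoc,dz_assoc Positive diffusivities
#'   (mm^2/s).
#' @return The ALPS index (positive scalar).
#' @export
#' @examples
#' compute_alps_index(1.2e-3, 0.6e-3, 1.0e-3, 0.8e-3)  # 1.5714
compute_alps_index <- function(dx_proj, dy_proj, dx_assoc, dz_assoc) {
  vals <- c(dx_proj, dy_proj, dx_assoc, dz_assoc)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all four diffusivities must be positive and finite")
  }
  ((dx_proj + dx_assoc) / 2) / ((dy_proj + dz_assoc) / 2)
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("[", stage, "] ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full semi-automatic ALPS pipeline on one subject
#'
#' Orchestrates tensor fitting, colour-FA computation, channel isolation,
#' peak search, circular-ROI placement, diffusivity extraction and the
#' index. Deterministic for fixed inputs; errors carry the name of the
#' failing stage. One rectangle may serve both fibre systems, or separate
#' rectangles may be supplied per channel.
#'
#' @param dwi A [dwi_volume()].
#' @param mask Optional 3D logical fit mask (see [fit_tensor()]).
#' @param rect_projection [search_rectangle()] searched for the blue
#'   (projection-fibre) peak.
#' @param rect_association Rectangle for the green (association-fibre)
#'   peak; defaults to `rect_projection`.
#' @param cfg An [alps_config()]; its hemisphere must agree with the
#'   rectangles'.
#' @param method Tensor estimator passed to [fit_tensor()].
#' @param b_max Optional shell restriction passed to [fit_tensor()].
#' @param field Optionally, a precomputed `tensor_field` (skips fitting).
#' @return Object of class `alps_result`: the four diffusivities, the
#'   index, peak coordinates, ROI voxel sets and the configuration used.
#' @export
run_alps <- function(dwi, mask = NULL, rect_projection,
                     rect_association = rect_projection,
                     cfg = alps_config(), method = "wls", b_max = NULL,
                     field = NULL) {
  stopifnot(inherits(rect_projection, "search_rectangle"),
            inherits(rect_association, "search_rectangle"),
            inherits(cfg, "alps_config"))
  for (r in list(rect_projection, rect_association)) {
    if (r$hemisphere != cfg$hemisphere) {
      stop("[config] rectangle hemisphere '", r$hemisphere,
           "' disagrees with configuration hemisphere '", cfg$hemisphere, "'")
    }
  }
  if (is.null(field)) {
    stopifnot(inherits(dwi, "dwi_volume"))
    field <- with_stage("fit", fit_tensor(dwi, mask, method = method,
                                          b_max = b_max))
  }
  cfa <- field$color_fa
  dims <- dim(field$mask)

  same_rect <- identical(rect_association, rect_projection)
  mp <- with_stage("channel", channel_masks(
    cfa, rect_projection, cfg,
    channels = if (same_rect) c("projection", "association") else "projection"
  ))
  ma <- if (same_rect) mp else {
    with_stage("channel",
               channel_masks(cfa, rect_association, cfg,
                             channels = "association"))
  }
  peak_p <- with_stage("peak", find_peak(cfa[, , , 3], mp$projection))
  peak_a <- with_stage("peak", find_peak(cfa[, , , 2], ma$association))
  roi_p <- with_stage("roi", circular_roi(peak_p, cfg$roi_diameter_mm,
                                          field$affine, dims))
  roi_a <- with_stage("roi", circular_roi(peak_a, cfg$roi_diameter_mm,
                                          field$affine, dims))
  dv <- with_stage("extract", extract_diffusivities(field, roi_p, roi_a))
  idx <- with_stage("index",
                    compute_alps_index(dv$dx_proj, dv$dy_proj,
                                       dv$dx_assoc, dv$dz_assoc))
  structure(
    list(
      dx_proj = dv$dx_proj, dy_proj = dv$dy_proj,
      dx_assoc = dv$dx_assoc, dz_assoc = dv$dz_assoc,
      alps_index = idx,
      proj_peak = peak_p, assoc_peak = peak_a,
      proj_roi = roi_p, assoc_roi = roi_a,
      hemisphere = cfg$hemisphere,
      config = cfg
    ),
    class = "alps_result"
  )
}

#' @export
print.alps_result <- function(x, ...) {
  cat("<alps_result> ", x$hemisphere, " ALPS index = ",
      signif(x$alps_index, 5), "\n", sep = "")
  cat(sprintf("  Dx_proj = %.4g  Dy_proj = %.4g  Dx_assoc = %.4g  Dz_assoc = %.4g mm^2/s\n",
              x$dx_proj, x$dy_proj, x$dx_assoc, x$dz_assoc))
  cat("  projection peak (", paste(x$proj_peak, collapse = ", "),
      "), association peak (", paste(x$assoc_peak, collapse = ", "),
      ")\n", sep = "")
  invisible(x)
}

#' Tidy an ALPS result into a one-row tibble
#'
#' @param x An `alps_result`.
#' @param ... Unused.
#' @return One-row tibble with the diffusivities, index, hemisphere and
#'   peak coordinates — the per-subject record written to cohort output
#'   tables.
#' @method tidy alps_result
#' @export
tidy.alps_result <- function(x, ...) {
  tibble::tibble(
    hemisphere = x$hemisphere,
    dx_proj = x$dx_proj, dy_proj = x$dy_proj,
    dx_assoc = x$dx_assoc, dz_assoc = x$dz_assoc,
    alps_index = x$alps_index,
    proj_peak_x = x$proj_peak[1], proj_peak_y = x$proj_peak[2],
    proj_peak_z = x$proj_peak[3],
    assoc_peak_x = x$assoc_peak[1], assoc_peak_y = x$assoc_peak[2],
    assoc_peak_z = x$assoc_peak[3],
    roi_diameter_mm = x$config$roi_diameter_mm,
    percentile = x$config$percentile
  )
}

#' @method glance alps_result
#' @export
glance.alps_result <- function(x, ...) {
  tibble::tibble(
    alps_index = x$alps_index,
    hemisphere = x$hemisphere,
    n_proj_roi = nrow(x$proj_roi),
    n_assoc_roi = nrow(x$assoc_roi)
  )
}

#' Write ROI masks of an ALPS result as a NIfTI overlay
#'
#' Voxels get value 1 in the projection ROI and 2 in the association ROI,
#' for quality-control overlay on the FA map.
#'
#' @param result An `alps_result`.
#' @param dims Volume dimensions.
#' @param affine 4x4 transform.
#' @param path Output NIfTI path.
#' @return Invisibly, `path`.
#' @export
write_roi_overlay <- function(result, dims, affine, path) {
  ov <- array(0, dim = dims)
  ov[result$proj_roi] <- 1
  ov[result$assoc_roi] <- 2
  write_scalar_map(ov, affine, path)
}

#' Plot an ALPS result over the colour-FA slice
#'
#' Renders the analysed axial slice of the colour-FA map with the search
#' peaks and circular ROIs marked.
#'
#' @param object An `alps_result`.
#' @param field The `tensor_field` the result came from.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot alps_result
#' @export
autoplot.alps_result <- function(object, field, ...) {
  z <- object$proj_peak[3]
  cfa <- field$color_fa
  dims <- dim(field$mask)
  df <- tidyr::expand_grid(x = seq_len(dims[1]), y = seq_len(dims[2]))
  df$fill <- grDevices::rgb(pmin(cfa[, , z, 1], 1)[cbind(df$x, df$y)],
                            pmin(cfa[, , z, 2], 1)[cbind(df$x, df$y)],
                            pmin(cfa[, , z, 3], 1)[cbind(df$x, df$y)])
  rois <- rbind(
    data.frame(x = object$proj_roi[, 1], y = object$proj_roi[, 2],
               roi = "projection"),
    data.frame(x = object$assoc_roi[, 1], y = object$assoc_roi[, 2],
               roi = "association")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$fill)) +
    ggplot2::scale_fill_identity() +
    ggplot2::geom_tile(data = rois,
                       ggplot2::aes(colour = .data$roi), fill = NA,
                       linewidth = 0.6) +
    ggplot2::scale_colour_manual(values = c(projection = "cyan",
                                            association = "yellow")) +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("ALPS index %.3f (axial slice %d)",
                                  object$alps_index, z),
                  colour = "ROI") +
    ggplot2::theme_minimal()
}
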