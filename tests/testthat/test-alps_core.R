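make_cfa <- function(dims, red = 0, green = 0, blue = 0) {
  cfa <- array(0, dim = c(dims, 3))
  cfa[, , , 1] <- red; cfa[, , , 2] <- green; cfa[, , , 3] <- blue
  cfa
}

test_that("channel masks follow the in-rectangle percentile rule", {
  dims <- c(10L, 10L, 3L)
  blue <- array(0, dim = dims)
  blue[, , 2] <- matrix(0.01 * (1:100), 10, 10)
  green <- array(0.001, dim = dims)
  cfa <- make_cfa(dims, red = 0, green = green, blue = blue)
  rect <- search_rectangle(2, c(1, 10), c(1, 10))
  masks <- channel_masks(cfa, rect, alps_config(percentile = 95))

  # brute-force threshold over the 100 rectangle values
  vals <- 0.01 * (1:100)
  thr <- quantile(vals, 0.95, names = FALSE, type = 7)
  expected <- array(FALSE, dims)
  expected[, , 2] <- matrix(vals >= thr, 10, 10)
  expect_identical(masks$projection, expected)
  # green never dominates blue here
  expect_true(all(!masks$association))
})

test_that("channel masks handle dominance, degenerate and small inputs", {
  dims <- c(10L, 10L, 1L)
  blue <- array(0.1, dim = dims); blue[3, 4, 1] <- 0.9
  cfa <- make_cfa(dims, green = 0.05, blue = blue)
  rect <- search_rectangle(1, c(1, 10), c(1, 10))
  masks <- channel_masks(cfa, rect)
  expect_true(masks$projection[3, 4, 1])
  expect_true(all(!(masks$projection & masks$association)))

  # zero green channel -> association error
  cfa0 <- make_cfa(dims, green = 0, blue = blue)
  expect_error(channel_masks(cfa0, rect), "no anisotropic tissue")

  # rectangle too small for a stable percentile
  tiny <- search_rectangle(1, c(1, 4), c(1, 4))
  expect_error(channel_masks(cfa, tiny), "20")

  # out-of-bounds rectangle
  expect_error(channel_masks(cfa, search_rectangle(1, c(1, 12), c(1, 10))),
               "bounds")
})

test_that("peak search breaks ties lexicographically", {
  dims <- c(20L, 32L, 25L)
  ch <- array(0, dim = dims)
  mask <- array(TRUE, dim = dims)
  ch[12, 30, 22] <- 0.9
  expect_equal(find_peak(ch, mask), c(12L, 30L, 22L))

  ch <- array(0, dim = dims)
  ch[5, 9, 22] <- 0.71
  ch[5, 10, 22] <- 0.71
  expect_equal(find_peak(ch, mask), c(5L, 9L, 22L))

  # degenerate: all equal -> lexicographically smallest masked voxel
  flat <- array(0.3, dim = dims)
  m2 <- array(FALSE, dim = dims); m2[4:6, 7:8, 3] <- TRUE
  expect_equal(find_peak(flat, m2), c(4L, 7L, 3L))

  expect_error(find_peak(flat, array(FALSE, dim = dims)), "empty mask")
})

test_that("circular ROI geometry is computed in world mm, inclusive", {
  aff <- diag(c(2.5, 2.5, 2.5, 1))
  dims <- c(30L, 40L, 20L)
  roi <- circular_roi(c(10, 20, 15), 5, aff, dims)
  expected <- rbind(c(9, 20, 15), c(10, 19, 15), c(10, 20, 15),
                    c(10, 21, 15), c(11, 20, 15))
  expect_equal(roi[order(roi[, 1], roi[, 2]), ], expected)

  # exhaustive distance check over the slice
  all_idx <- as.matrix(expand.grid(x = 1:30, y = 1:40))
  d <- sqrt(((all_idx[, 1] - 10) * 2.5)^2 + ((all_idx[, 2] - 20) * 2.5)^2)
  inside <- all_idx[d <= 2.5 + 1e-9, ]
  expect_equal(nrow(roi), nrow(inside))

  expect_equal(circular_roi(c(10, 20, 15), 2, aff, dims),
               matrix(c(10, 20, 15), 1))

  expect_warning(corner <- circular_roi(c(1, 1, 5), 5, aff, dims),
                 "clipped")
  expect_equal(nrow(corner), 3)

  expect_error(circular_roi(c(10, 20, 15), 0, aff, dims), "positive")
})

test_that("directional diffusivities are ROI means of tensor elements", {
  T6 <- rbind(
    c(1.2e-3, 0.6e-3, 1.6e-3, 0, 0, 0),   # projection-like voxel
    c(1.0e-3, 1.6e-3, 0.8e-3, 0, 0, 0),   # association-like voxel
    c(1.4e-3, 0.6e-3, 1.6e-3, 0, 0, 0)
  )
  field <- tensor_field_manual(T6, dims = c(3L, 1L, 1L))
  one <- function(i) matrix(c(i, 1L, 1L), 1)
  dv <- extract_diffusivities(field, one(1), one(2))
  expect_equal(unlist(dv),
               c(dx_proj = 1.2e-3, dy_proj = 0.6e-3,
                 dx_assoc = 1.0e-3, dz_assoc = 0.8e-3))

  # arithmetic mean over a two-voxel ROI
  dv2 <- extract_diffusivities(field, rbind(one(1), one(3)), one(2))
  expect_equal(dv2$dx_proj, 1.3e-3)

  field$mask[3, 1, 1] <- FALSE
  expect_error(extract_diffusivities(field, rbind(one(1), one(3)), one(2)),
               "3,1,1")
})

test_that("ALPS index arithmetic, scale invariance and guards", {
  expect_equal(compute_alps_index(1e-3, 1e-3, 1e-3, 1e-3), 1)
  expect_equal(compute_alps_index(1.2e-3, 0.6e-3, 1.0e-3, 0.8e-3),
               1.1 / 0.7, tolerance = 1e-12)
  expect_equal(compute_alps_index(2.4e-3, 1.2e-3, 2.0e-3, 1.6e-3),
               compute_alps_index(1.2e-3, 0.6e-3, 1.0e-3, 0.8e-3))
  expect_error(compute_alps_index(0, 1e-3, 1e-3, 1e-3), "positive")
})

test_that("end-to-end pipeline recovers the phantom ALPS index", {
  spec <- small_phantom_spec()
  truth <- make_phantom(spec)
  gtab <- default_gradient_table()
  dwi <- simulate_dwi(truth, gtab)
  rects <- phantom_rectangles(spec)
  res <- run_alps(dwi, rect_projection = rects$projection,
                  rect_association = rects$association)
  expect_equal(res$alps_index, spec$true_alps, tolerance = 1e-3)
  expect_equal(res$dx_proj, spec$d_x, tolerance = 1e-6)
  expect_equal(res$dy_proj, spec$d_perp, tolerance = 1e-6)

  # projection and association ROIs never overlap on separated slabs
  key <- function(m) apply(m, 1, paste, collapse = ",")
  expect_length(intersect(key(res$proj_roi), key(res$assoc_roi)), 0)

  # invariant under global S0 rescaling
  dwi3 <- dwi_volume(dwi$data * 3, dwi$affine, dwi$gtab)
  res3 <- run_alps(dwi3, rect_projection = rects$projection,
                   rect_association = rects$association)
  expect_equal(res3$alps_index, res$alps_index, tolerance = 1e-9)

  # tidy() exposes the per-subject record
  row <- tidy(res)
  expect_s3_class(row, "tbl_df")
  expect_equal(row$alps_index, res$alps_index)
  expect_equal(nrow(row), 1)
})

test_that("recovered index increases strictly with the x-diffusivity", {
  gtab <- default_gradient_table()
  idx <- sapply(c(0.55e-3, 0.75e-3, 0.95e-3), function(dx) {
    spec <- small_phantom_spec(d_x = dx)
    dwi <- simulate_dwi(make_phantom(spec), gtab)
    rects <- phantom_rectangles(spec)
    run_alps(dwi, rect_projection = rects$projection,
             rect_association = rects$association)$alps_index
  })
  expect_true(all(diff(idx) > 0))
})

test_that("isotropic volumes raise the channel-isolation error", {
  n <- 30 * 30 * 4
  T6 <- matrix(rep(c(0.8e-3, 0.8e-3, 0.8e-3, 0, 0, 0), each = n), n, 6)
  truth <- tensor_field_manual(T6, dims = c(30L, 30L, 4L))
  gtab <- default_gradient_table()
  dwi <- simulate_dwi(truth, gtab)
  rect <- search_rectangle(2, c(5, 25), c(5, 25))
  expect_error(
    run_alps(dwi, rect_projection = rect),
    "\\[channel\\].*no anisotropic tissue"
  )
})

test_that("hemisphere mismatch between rectangle and config is rejected", {
  rect <- search_rectangle(2, c(1, 10), c(1, 10), hemisphere = "right")
  expect_error(
    run_alps(NULL, rect_projection = rect, cfg = alps_config()),
    "hemisphere"
  )
})
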