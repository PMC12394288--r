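# File I/O for diffusion MRI: NIfTI volumes, FSL-dialect gradient schemes,
# delimited cohort tables.

#' Construct a gradient table
#'
#' A gradient table pairs one b-value (s/mm^2) and one unit gradient
#' direction with every volume of a diffusion acquisition. Volumes whose
#' b-value falls below `b0_threshold` are treated as unweighted (b0)
#' reference images; their direction vectors are irrelevant and left as
#' given. Directions of diffusion-weighted volumes are renormalised to unit
#' Euclidean length.
#'
#' @param bvals Numeric vector of b-values, one per volume (s/mm^2).
#' @param bvecs Numeric matrix with one row per volume and 3 columns
#'   (x, y, z components of the gradient direction).
#' @param b0_threshold b-value below which a volume counts as unweighted.
#'   The default, 50 s/mm^2, is the common neuroimaging convention; any
#'   value below the lowest shell is equivalent when explicit b = 0 volumes
#'   are present.
#' @return An object of class `gradient_table` with elements `bvals`,
#'   `bvecs` (unit rows for weighted volumes) and `b0_threshold`.
#' @export
#' @examples
#' gt <- gradient_table(c(0, 711, 711),
#'                      rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)))
#' gt$bvals
gradient_table <- function(bvals, bvecs, b0_threshold = 50) {
  bvals <- as.numeric(bvals)
  bvecs <- as.matrix(bvecs)
  storage.mode(bvecs) <- "double"
  dimnames(bvecs) <- NULL
  if (ncol(bvecs) != 3L) {
    stop("`bvecs` must have 3 columns (x, y, z), got ", ncol(bvecs))
  }
  if (length(bvals) != nrow(bvecs)) {
    stop("gradient count mismatch: ", length(bvals), " b-values but ",
         nrow(bvecs), " direction vectors")
  }
  if (any(!is.finite(bvals)) || any(!is.finite(bvecs))) {
    stop("b-values and directions must be finite")
  }
  if (any(bvals < 0)) stop("b-values must be non-negative")
  weighted <- bvals >= b0_threshold
  if (!any(!weighted)) {
    stop("no unweighted (b0) volume: smallest b-value is ", min(bvals),
         " s/mm^2 with b0_threshold ", b0_threshold)
  }
  nrm <- sqrt(rowSums(bvecs^2))
  if (any(weighted & nrm < 1e-8)) {
    stop("zero direction vector paired with b >= b0_threshold at volume(s) ",
         paste(which(weighted & nrm < 1e-8), collapse = ", "))
  }
  bvecs[weighted, ] <- bvecs[weighted, , drop = FALSE] / nrm[weighted]
  structure(
    list(bvals = bvals, bvecs = bvecs, b0_threshold = b0_threshold),
    class = "gradient_table"
  )
}

#' @export
print.gradient_table <- function(x, ...) {
  w <- x$bvals >= x$b0_threshold
  shells <- sort(unique(round(x$bvals[w])))
  cat("<gradient_table> ", length(x$bvals), " volumes: ",
      sum(!w), " b0, shells b = {", paste(shells, collapse = ", "),
      "} s/mm^2\n", sep = "")
  invisible(x)
}

# Tokenise one whitespace-separated numeric file, reporting the line/column
# of the first bad token.
parse_numeric_rows <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lapply(seq_along(lines), function(i) {
    toks <- strsplit(trimws(lines[[i]]), "[[:space:]]+")[[1]]
    vals <- suppressWarnings(as.numeric(toks))
    if (anyNA(vals)) {
      bad <- which(is.na(vals))[1]
      stop("non-numeric token '", toks[bad], "' in ", basename(path),
           " at line ", i, ", column ", bad, call. = FALSE)
    }
    vals
  })
}

#' Read an FSL-dialect bval/bvec gradient scheme
#'
#' The FSL dialect stores b-values as a single whitespace-separated row of N
#' numbers, and directions as three rows of N components (x, y and z row).
#' Counts must agree between the two files. Weighted directions are
#' renormalised to unit length.
#'
#' @param bval_path Path to the bval file.
#' @param bvec_path Path to the bvec file.
#' @inheritParams gradient_table
#' @return A [gradient_table()].
#' @export
read_gradients <- function(bval_path, bvec_path, b0_threshold = 50) {
  for (p in c(bval_path, bvec_path)) {
    if (!file.exists(p)) stop("gradient file not found: ", p)
  }
  brows <- parse_numeric_rows(bval_path)
  bvals <- unlist(brows)
  vrows <- parse_numeric_rows(bvec_path)
  if (length(vrows) != 3L) {
    stop("bvec file ", basename(bvec_path), " must have 3 rows, found ",
         length(vrows))
  }
  ncols <- lengths(vrows)
  if (length(unique(ncols)) != 1L) {
    stop("ragged bvec file: row lengths ", paste(ncols, collapse = ", "))
  }
  if (ncols[1] != length(bvals)) {
    stop("gradient count mismatch: ", length(bvals), " b-values in ",
         basename(bval_path), " but ", ncols[1], " directions in ",
         basename(bvec_path))
  }
  gradient_table(bvals, cbind(vrows[[1]], vrows[[2]], vrows[[3]]),
                 b0_threshold = b0_threshold)
}

#' Write a gradient table as FSL-dialect bval/bvec files
#'
#' @param gtab A [gradient_table()].
#' @param bval_path,bvec_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_gradients <- function(gtab, bval_path, bvec_path) {
  stopifnot(inherits(gtab, "gradient_table"))
  writeLines(paste(format(gtab$bvals, trim = TRUE, scientific = FALSE),
                   collapse = " "), bval_path)
  rows <- apply(t(gtab$bvecs), 1L, function(r) {
    paste(format(r, trim = TRUE, digits = 17), collapse = " ")
  })
  writeLines(rows, bvec_path)
  invisible(c(bval_path, bvec_path))
}

#' Construct a diffusion-weighted volume
#'
#' Bundles the 4D signal array (x, y, z, volume), the voxel-index to
#' world-mm affine (NIfTI RAS+ convention, applied to 0-based indices) and
#' the gradient table describing the acquisition.
#'
#' @param data 4D non-negative numeric array.
#' @param affine 4x4 invertible voxel-to-world transform.
#' @param gtab [gradient_table()] whose length matches the 4th dimension.
#' @return Object of class `dwi_volume`.
#' @export
dwi_volume <- function(data, affine, gtab) {
  if (length(dim(data)) != 4L) {
    stop("DWI data must be 4D (x, y, z, volume); got ",
         length(dim(data)), " dimensions")
  }
  stopifnot(inherits(gtab, "gradient_table"))
  if (dim(data)[4] != length(gtab$bvals)) {
    stop("volume count mismatch: data has ", dim(data)[4],
         " volumes but gradient table has ", length(gtab$bvals))
  }
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L))) stop("affine must be 4x4")
  det_a <- det(affine)
  if (!is.finite(det_a) || abs(det_a) < 1e-12) {
    stop("affine is not invertible")
  }
  edge <- sqrt(colSums(affine[1:3, 1:3]^2))
  if (any(edge <= 0)) stop("voxel edge lengths must be strictly positive")
  if (min(data, na.rm = TRUE) < 0) stop("signal must be non-negative")
  structure(list(data = data, affine = affine, gtab = gtab),
            class = "dwi_volume")
}

#' @export
print.dwi_volume <- function(x, ...) {
  d <- dim(x$data)
  vox <- signif(voxel_size(x$affine), 4)
  cat("<dwi_volume> ", paste(d[1:3], collapse = " x "), " voxels x ",
      d[4], " volumes, voxel ", paste(vox, collapse = " x "), " mm\n",
      sep = "")
  print(x$gtab)
  invisible(x)
}

#' Voxel edge lengths (mm) implied by an affine
#' @param affine 4x4 voxel-to-world matrix.
#' @return Length-3 numeric vector.
#' @export
voxel_size <- function(affine) sqrt(colSums(as.matrix(affine)[1:3, 1:3]^2))

#' Read a 4D NIfTI diffusion volume
#'
#' @param nifti_path Path to a NIfTI-1 file (.nii or .nii.gz).
#' @param gtab [gradient_table()] to validate the 4th dimension against.
#' @return A [dwi_volume()] whose affine is the file's xform.
#' @export
read_dwi <- function(nifti_path, gtab) {
  if (!file.exists(nifti_path)) stop("NIfTI file not found: ", nifti_path)
  img <- RNifti::readNifti(nifti_path)
  if (length(dim(img)) != 4L) {
    stop("expected a 4D diffusion volume, got ", length(dim(img)),
         "D in ", basename(nifti_path))
  }
  aff <- unclass(RNifti::xform(img))
  attributes(aff) <- list(dim = c(4L, 4L))
  dwi_volume(array(as.numeric(img), dim = dim(img)), aff, gtab)
}

#' Write a 4D diffusion volume to NIfTI
#'
#' @param dwi A [dwi_volume()].
#' @param path Output path (.nii or .nii.gz).
#' @param datatype NIfTI storage type; `"double"` keeps round-trips exact.
#' @return Invisibly, `path`.
#' @export
write_dwi <- function(dwi, path, datatype = "double") {
  stopifnot(inherits(dwi, "dwi_volume"))
  write_nifti_array(dwi$data, dwi$affine, path, datatype = datatype)
}

#' Write a 3D scalar map (FA, MD, ...) to NIfTI
#'
#' Values are stored as 32-bit float, the conventional precision for
#' derived diffusion maps; round-trips preserve values to float32
#' resolution and the affine exactly.
#'
#' @param map 3D numeric array with finite values.
#' @param affine 4x4 voxel-to-world transform.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_scalar_map <- function(map, affine, path) {
  if (!length(dim(map)) %in% c(3L, 4L)) {
    stop("scalar map must be 3D (or 4D for multi-channel maps)")
  }
  if (any(!is.finite(map))) {
    stop("scalar map contains non-finite values (",
         sum(!is.finite(map)), " voxel(s))")
  }
  write_nifti_array(map, affine, path, datatype = "float")
}

write_nifti_array <- function(arr, affine, path, datatype = "float") {
  img <- RNifti::asNifti(arr)
  aff <- as.matrix(affine)
  RNifti::sform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Read a NIfTI scalar map together with its affine
#'
#' @param path NIfTI file path.
#' @return List with `map` (numeric array) and `affine` (4x4 matrix).
#' @export
read_scalar_map <- function(path) {
  if (!file.exists(path)) stop("NIfTI file not found: ", path)
  img <- RNifti::readNifti(path)
  aff <- unclass(RNifti::xform(img))
  attributes(aff) <- list(dim = c(4L, 4L))
  list(map = array(as.numeric(img), dim = dim(img)), affine = aff)
}

#' Read a delimited cohort table
#'
#' Expects a header row; the delimiter is taken from the file extension
#' (`.csv` for comma, anything else tab). Empty fields become `NA` and are
#' propagated as missing, never as zero.
#'
#' @param path Path to a TSV/CSV file with at least the columns
#'   `subject_id`, `group`, `timepoint`, `alps_index`.
#' @return A tibble.
#' @export
read_cohort_table <- function(path) {
  if (!file.exists(path)) stop("cohort table not found: ", path)
  reader <- if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    readr::read_csv
  } else {
    readr::read_tsv
  }
  tab <- reader(path, show_col_types = FALSE, progress = FALSE)
  required <- c("subject_id", "group", "timepoint", "alps_index")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols)) {
    stop("cohort table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  key <- paste(tab$subject_id, tab$timepoint)
  if (anyDuplicated(key)) {
    stop("duplicate (subject_id, timepoint) rows: ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  }
  if (any(!is.na(tab$alps_index) & tab$alps_index <= 0)) {
    stop("alps_index values must be positive where present")
  }
  tab
}

#' Write a cohort table as TSV
#' @param tab Data frame of per-subject rows.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_cohort_table <- function(tab, path) {
  readr::write_tsv(tab, path)
  invisible(path)
}
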