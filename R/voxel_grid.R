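#' Voxel grids and binary masks
#'
#' A `voxel_grid` is a 3D scalar lattice with a per-axis voxel edge length in
#' millimetres.  A `binary_mask` is a voxel grid whose values are logical; it
#' additionally knows its foreground voxel count and physical volume.  All
#' grids belonging to one case (masks and modality images) must share the same
#' shape and spacing.
#'
#' Voxel centres sit at physical coordinate `(i - 1) * spacing` along each
#' axis, i.e. the first voxel centre is at 0 mm.  The first axis increases
#' toward the anatomical left, the second toward anterior, the third toward
#' superior.
#'
#' @param values A 3D numeric or logical array.
#' @param spacing Numeric vector of length 3: voxel edge lengths in mm,
#'   strictly positive.
#' @return `voxel_grid()` returns an object of class `"voxel_grid"`;
#'   `binary_mask()` an object of class `c("binary_mask", "voxel_grid")`.
#' @examples
#' m <- binary_mask(array(c(TRUE, rep(FALSE, 7)), c(2, 2, 2)), spacing = c(2, 2, 2))
#' n_voxels(m)
#' volume_mm3(m)
#' @export
voxel_grid <- function(values, spacing = c(1, 1, 1)) {
  if (!is.array(values) || length(dim(values)) != 3L) {
    abort("`values` must be a 3D array; 2D slices are not supported.")
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    abort("`spacing` must be 3 strictly positive voxel edge lengths in mm.")
  }
  structure(list(values = values, spacing = spacing), class = "voxel_grid")
}

#' @rdname voxel_grid
#' @export
binary_mask <- function(values, spacing = c(1, 1, 1)) {
  if (inherits(values, "voxel_grid")) {
    spacing <- values$spacing
    values <- values$values
  }
  if (!is.logical(values)) {
    if (!all(values %in% c(0, 1))) {
      abort("`values` must be logical or contain only 0 and 1; use `read_mask()` to threshold.")
    }
    values <- array(as.logical(values), dim(values))
  }
  g <- voxel_grid(values, spacing)
  class(g) <- c("binary_mask", "voxel_grid")
  g
}

#' @rdname voxel_grid
#' @param x A `voxel_grid` or `binary_mask`.
#' @export
grid_shape <- function(x) dim(x$values)

#' @rdname voxel_grid
#' @export
voxel_volume_mm3 <- function(x) prod(x$spacing)

#' @rdname voxel_grid
#' @export
n_voxels <- function(x) {
  stopifnot(inherits(x, "binary_mask"))
  sum(x$values)
}

#' @rdname voxel_grid
#' @export
volume_mm3 <- function(x) n_voxels(x) * voxel_volume_mm3(x)

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf(
    "<%s> %s voxels, spacing %s mm\n",
    class(x)[1],
    paste(dim(x$values), collapse = " x "),
    paste(format(x$spacing), collapse = " x ")
  ))
  if (inherits(x, "binary_mask")) {
    cat(sprintf("  foreground: %d voxels (%.1f mm^3)\n", n_voxels(x), volume_mm3(x)))
  } else {
    cat(sprintf(
      "  values in [%s, %s]\n",
      format(min(x$values)), format(max(x$values))
    ))
  }
  invisible(x)
}

# shared-geometry check used by every pairwise operation
check_same_geometry <- function(a, b, what = "grids") {
  if (!identical(dim(a$values), dim(b$values))) {
    abort(sprintf(
      "%s have mismatching shapes (%s vs %s).", what,
      paste(dim(a$values), collapse = "x"), paste(dim(b$values), collapse = "x")
    ))
  }
  if (!isTRUE(all.equal(a$spacing, b$spacing))) {
    abort(sprintf("%s have mismatching voxel spacing.", what))
  }
  invisible(TRUE)
}

#' Stretch intensities to the 12-bit range
#'
#' Linearly maps the observed intensity range of a grid onto \[0, 4095\], the
#' normalisation applied to every modality image before any intensity analysis.
#' A constant grid has no range to stretch and maps to all zeros.
#'
#' Note that the intensity-difference statistic (see
#' [intensity_difference()]) is invariant under pure rescaling but not under
#' this affine map, so the stretch must be applied *before* computing IDs,
#' never after.
#'
#' @param grid A `voxel_grid`.
#' @return A `voxel_grid` with values in \[0, 4095\].
#' @examples
#' g <- voxel_grid(array(c(0, 2, 4, 4, 2, 0, 2, 2), c(2, 2, 2)))
#' range(stretch_to_12bit(g)$values)
#' @export
stretch_to_12bit <- function(grid) {
  stopifnot(inherits(grid, "voxel_grid"))
  rng <- range(grid$values)
  v <- if (rng[1] == rng[2]) {
    array(0, dim(grid$values))
  } else {
    (grid$values - rng[1]) / (rng[2] - rng[1]) * 4095
  }
  voxel_grid(v, grid$spacing)
}
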