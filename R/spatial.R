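#' Brain centre
#'
#' Physical coordinate of the centre of the brain, used as the origin for
#' component position offsets.  The default is the unweighted centroid of the
#' brain-mask voxels (geometric centre of tissue); `"bbox"` uses the centre
#' of the mask's bounding box instead, for sensitivity checks.
#'
#' Voxel centres sit at `(index - 1) * spacing` mm per axis.
#'
#' @param brain A non-empty [binary_mask()] of the brain.
#' @param method `"centroid"` (default) or `"bbox"`.
#' @return Named numeric vector `c(x, y, z)` in mm.
#' @export
brain_center <- function(brain, method = c("centroid", "bbox")) {
  stopifnot(inherits(brain, "binary_mask"))
  method <- match.arg(method)
  if (n_voxels(brain) == 0L) abort("Brain mask is empty.")
  idx <- which(brain$values, arr.ind = TRUE)
  coords <- sweep(idx - 1, 2, brain$spacing, `*`)
  center <- switch(method,
    centroid = colMeans(coords),
    bbox = (apply(coords, 2, min) + apply(coords, 2, max)) / 2
  )
  setNames(as.numeric(center), .lw_axes)
}

#' Component centroid offsets from the brain centre
#'
#' Per component, the unweighted voxel centroid in mm and its signed offset
#' from the brain centre.  Signs follow the fixed axis convention: positive X
#' is the anatomical left, positive Y anterior (front), positive Z superior
#' (upper).
#'
#' @param cs A [label_components()] result.
#' @param center A [brain_center()] coordinate.
#' @return A tibble `label`, `centroid_x/y/z_mm`, `offset_x/y/z_mm`.
#' @export
component_offsets <- function(cs, center) {
  stopifnot(inherits(cs, "component_set"), length(center) == 3L)
  if (cs$n_components == 0L) {
    out <- tibble(label = integer())
    for (ax in .lw_axes) {
      out[[paste0("centroid_", ax, "_mm")]] <- numeric()
      out[[paste0("offset_", ax, "_mm")]] <- numeric()
    }
    return(out)
  }
  idx <- which(cs$labels > 0L, arr.ind = TRUE)
  lab <- cs$labels[cs$labels > 0L]
  coords <- sweep(idx - 1, 2, cs$spacing, `*`)
  cent <- vapply(1:3, function(a) {
    as.numeric(tapply(coords[, a], lab, mean))
  }, numeric(cs$n_components))
  cent <- matrix(cent, ncol = 3)
  out <- tibble(label = sort(unique(as.integer(lab))))
  for (a in 1:3) {
    out[[paste0("centroid_", .lw_axes[a], "_mm")]] <- cent[, a]
    out[[paste0("offset_", .lw_axes[a], "_mm")]] <- cent[, a] - center[a]
  }
  out
}

#' Half-brain concentration differences
#'
#' For each axis and component category, splits the components into the
#' positive and negative half of the brain (by the sign of the centroid
#' offset) and reports the percentage difference
#' `100 * (n_pos - n_neg) / (n_pos + n_neg)`.  Components sitting exactly on
#' the centre plane belong to neither half and are excluded from both counts;
#' a category whose components all sit on the plane is reported as `NA`.
#'
#' @param records A tibble with `category` and `offset_x/y/z_mm` columns
#'   (component records joined with [component_offsets()]).
#' @param by Extra grouping columns, e.g. `"side"`.
#' @return A tibble `axis`, `category` (and `by` columns), `n_positive`,
#'   `n_negative`, `pct_difference`.
#' @export
half_brain_differences <- function(records, by = intersect("side", names(records))) {
  stopifnot(is.data.frame(records), nrow(records) > 0L)
  purrr::map_dfr(.lw_axes, function(ax) {
    off <- records[[paste0("offset_", ax, "_mm")]]
    records |>
      dplyr::mutate(.off = off) |>
      dplyr::group_by(dplyr::across(dplyr::all_of(c(by, "category")))) |>
      dplyr::summarise(
        axis = ax,
        n_positive = sum(.data$.off > 0),
        n_negative = sum(.data$.off < 0),
        .groups = "drop"
      ) |>
      dplyr::mutate(
        pct_difference = ifelse(
          .data$n_positive + .data$n_negative > 0,
          100 * (.data$n_positive - .data$n_negative) /
            (.data$n_positive + .data$n_negative),
          NA_real_
        )
      )
  }) |>
    dplyr::relocate("axis")
}

#' Per-axis positional histograms
#'
#' Bins component centroid offsets per axis and category into bins of fixed
#' width centred on the brain centre: the bin around 0 spans
#' `[-w/2, w/2)`, its neighbours `[w/2, 3w/2)` and so on (left-closed).
#'
#' @inheritParams half_brain_differences
#' @param bin_width_mm Bin width, mm; must be positive.
#' @return A tibble `axis`, `category` (and `by` columns), `bin_center_mm`,
#'   `n`.  Bin counts per category sum to the category's record count.
#' @export
axis_histograms <- function(records, bin_width_mm = 10,
                            by = intersect("side", names(records))) {
  stopifnot(is.data.frame(records))
  if (bin_width_mm <= 0) abort("`bin_width_mm` must be positive.")
  purrr::map_dfr(.lw_axes, function(ax) {
    off <- records[[paste0("offset_", ax, "_mm")]]
    records |>
      dplyr::mutate(
        axis = ax,
        bin_center_mm = floor(off / bin_width_mm + 0.5) * bin_width_mm
      ) |>
      dplyr::count(dplyr::across(dplyr::all_of(c("axis", by, "category", "bin_center_mm"))),
                   name = "n")
  })
}
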