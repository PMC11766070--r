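#' Connected components of a binary mask
#'
#' Partitions the foreground of a mask into maximal connected components
#' under a 6- or 26-neighbour rule (3D; faces only, or faces plus edges and
#' corners).  Labelling is deterministic: component `k` is the one whose
#' first voxel comes `k`-th in column-major scan order.
#'
#' @param mask A [binary_mask()].
#' @param connectivity 26 (default) or 6.
#' @return An object of class `"component_set"`: a list with `labels` (an
#'   integer array, 0 = background), `n_components`, `connectivity`,
#'   `spacing`, and `components`, a tibble with one row per component
#'   (`label`, `n_voxels`, `volume_mm3`).
#' @examples
#' a <- array(FALSE, c(4, 4, 4)); a[1, 1, 1] <- TRUE; a[4, 4, 4] <- TRUE
#' label_components(binary_mask(a), connectivity = 6)
#' @export
label_components <- function(mask, connectivity = 26) {
  stopifnot(inherits(mask, "binary_mask"))
  if (!connectivity %in% c(6, 26)) abort("`connectivity` must be 6 or 26.")
  d <- dim(mask$values)
  lab <- label_components_cpp(as.logical(mask$values), as.integer(d),
                              as.integer(connectivity))
  n_comp <- attr(lab, "n_components")
  labels <- array(as.integer(lab), d)
  comp <- if (n_comp > 0) {
    sizes <- tabulate(labels[labels > 0L], nbins = n_comp)
    tibble(label = seq_len(n_comp), n_voxels = sizes,
           volume_mm3 = sizes * prod(mask$spacing))
  } else {
    tibble(label = integer(), n_voxels = integer(), volume_mm3 = numeric())
  }
  structure(
    list(labels = labels, n_components = as.integer(n_comp),
         connectivity = as.integer(connectivity), spacing = mask$spacing,
         components = comp),
    class = "component_set"
  )
}

#' @export
print.component_set <- function(x, ...) {
  cat(sprintf("<component_set> %d component(s), %d-connectivity, %s grid\n",
              x$n_components, x$connectivity,
              paste(dim(x$labels), collapse = "x")))
  if (x$n_components > 0) print(head(x$components, 10))
  invisible(x)
}

#' Overlap graph between two component sets
#'
#' The bipartite overlap structure between ground-truth and detection
#' components: one edge per pair of components sharing at least one voxel,
#' weighted by the shared voxel count.  Edge weights sum to the whole-volume
#' true-positive count.
#'
#' @param gt_cs,det_cs [label_components()] results for the ground-truth and
#'   detection masks of one case.
#' @return A tibble with columns `gt_label`, `det_label`, `shared_voxels`,
#'   ordered by `gt_label` then `det_label`.
#' @export
overlap_graph <- function(gt_cs, det_cs) {
  stopifnot(inherits(gt_cs, "component_set"), inherits(det_cs, "component_set"))
  if (!identical(dim(gt_cs$labels), dim(det_cs$labels))) {
    abort("Component sets live on different grids.")
  }
  both <- gt_cs$labels > 0L & det_cs$labels > 0L
  if (!any(both)) {
    return(tibble(gt_label = integer(), det_label = integer(),
                  shared_voxels = integer()))
  }
  g <- gt_cs$labels[both]
  d <- det_cs$labels[both]
  # count pairs through a single integer key; labels are dense 1..n
  key <- (as.numeric(g) - 1) * det_cs$n_components + as.numeric(d)
  tab <- table(key)
  k <- as.numeric(names(tab))
  tibble(
    gt_label = as.integer((k - 1) %/% det_cs$n_components + 1),
    det_label = as.integer((k - 1) %% det_cs$n_components + 1),
    shared_voxels = as.integer(tab)
  ) |>
    dplyr::arrange(.data$gt_label, .data$det_label)
}

#' Per-component Dice coefficient
#'
#' For every component on one side, the Dice coefficient between the
#' component's voxel set and the *union* of all opposite-side components that
#' share at least one voxel with it:
#' `2 * shared / (n_voxels + union_voxels)`.  A component with no overlapping
#' counterpart scores 0.  Using the union of overlapping counterparts (rather
#' than the single best match or the full opposite mask) lets one detection
#' blob credit several ground-truth lesions it covers, while remote
#' components cannot distort the score.
#'
#' @param cs The side's [label_components()] result.
#' @param graph The case's [overlap_graph()].
#' @param other_cs The opposite side's component set.
#' @param side `"gt"` or `"detection"`: which columns of `graph` refer to
#'   `cs`.
#' @return A tibble `label`, `n_voxels`, `volume_mm3`, `shared_voxels`,
#'   `counterpart_union_voxels`, `dsc`.
#' @export
component_dsc <- function(cs, graph, other_cs, side = c("gt", "detection")) {
  side <- match.arg(side)
  own_col <- if (side == "gt") "gt_label" else "det_label"
  other_col <- if (side == "gt") "det_label" else "gt_label"
  base <- cs$components
  if (nrow(base) == 0L) {
    return(dplyr::mutate(base, shared_voxels = integer(),
                         counterpart_union_voxels = integer(), dsc = numeric()))
  }
  other_sizes <- other_cs$components$n_voxels
  per_comp <- graph |>
    dplyr::group_by(label = .data[[own_col]]) |>
    dplyr::summarise(
      shared_voxels = sum(.data$shared_voxels),
      counterpart_union_voxels = sum(other_sizes[unique(.data[[other_col]])]),
      .groups = "drop"
    )
  base |>
    dplyr::left_join(per_comp, by = "label") |>
    dplyr::mutate(
      shared_voxels = dplyr::coalesce(.data$shared_voxels, 0L),
      counterpart_union_voxels = dplyr::coalesce(.data$counterpart_union_voxels, 0L),
      dsc = ifelse(.data$shared_voxels > 0,
                   2 * .data$shared_voxels /
                     (.data$n_voxels + .data$counterpart_union_voxels),
                   0)
    )
}

#' Categorise a per-component Dice value
#'
#' Found when `dsc >= tau_found`; Partial when `tau_partial <= dsc <
#' tau_found`; Missed when `dsc < tau_partial`.  Both lower boundaries are
#' inclusive, so exactly 0.5 is Found and exactly 0.05 is Partial under the
#' defaults.
#'
#' @param dsc Numeric vector of per-component Dice coefficients in \[0, 1\].
#' @param config An [eval_config()].
#' @return Character vector over `"Found"`, `"Partial"`, `"Missed"`.
#' @export
categorize_dsc <- function(dsc, config = eval_config()) {
  ifelse(dsc >= config$tau_found, "Found",
         ifelse(dsc >= config$tau_partial, "Partial", "Missed"))
}

#' Classify every component on both sides
#'
#' Applies the per-component Dice computation and the Found / Partially Found
#' / Missed taxonomy independently to the ground-truth side and the detection
#' side of one case.  The sides share the overlap graph but are classified by
#' the same rule without exclusivity: a single detection component may render
#' several ground-truth components Found.
#'
#' On the detection side the categories read as Good Detection, Partially
#' Good Detection and Missed Detection (false positive); the category codes
#' are the same.
#'
#' @inheritParams component_dsc
#' @param gt_cs,det_cs Component sets of the two sides.
#' @param config An [eval_config()].
#' @return A tibble of component records for both sides: `side` ("gt" or
#'   "detection"), `label`, `n_voxels`, `volume_mm3`, `shared_voxels`,
#'   `counterpart_union_voxels`, `dsc`, `category`.
#' @export
classify_components <- function(gt_cs, det_cs,
                                graph = overlap_graph(gt_cs, det_cs),
                                config = eval_config()) {
  gt_rec <- component_dsc(gt_cs, graph, det_cs, side = "gt")
  det_rec <- component_dsc(det_cs, graph, gt_cs, side = "detection")
  dplyr::bind_rows(
    dplyr::mutate(gt_rec, side = "gt", .before = 1),
    dplyr::mutate(det_rec, side = "detection", .before = 1)
  ) |>
    dplyr::mutate(category = categorize_dsc(.data$dsc, config))
}

#' Category summary table
#'
#' Summarises one side's component records the way a component-based results
#' table is printed: per category the component count, the percentage of all
#' components, and the percentage of the side's total component volume, plus
#' a totals row.  Percentages are kept at full precision here; rendering
#' rounds to one decimal.
#'
#' @param records Component records for one side (one `side` value), as
#'   produced by [classify_components()].
#' @return A tibble `category`, `n`, `pct_components`, `pct_volume` with a
#'   final `"Total"` row.
#' @export
category_table <- function(records) {
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0L) abort("No components to tabulate.")
  if (length(unique(records$side %||% "gt")) > 1L) {
    abort("`category_table()` summarises one side at a time; filter `side` first.")
  }
  total_n <- nrow(records)
  total_vol <- sum(records$volume_mm3)
  tab <- records |>
    dplyr::group_by(category = factor(.data$category, levels = .lw_categories)) |>
    dplyr::summarise(n = dplyr::n(), vol = sum(.data$volume_mm3), .groups = "drop") |>
    tidyr::complete(category, fill = list(n = 0L, vol = 0)) |>
    dplyr::mutate(
      pct_components = 100 * .data$n / total_n,
      pct_volume = if (total_vol > 0) 100 * .data$vol / total_vol else NA_real_,
      category = as.character(.data$category)
    ) |>
    dplyr::select("category", "n", "pct_components", "pct_volume")
  dplyr::bind_rows(
    tab,
    tibble(category = "Total", n = total_n,
           pct_components = 100,
           pct_volume = if (total_vol > 0) 100 else NA_real_)
  )
}

#' Dice-threshold sweep
#'
#' For each threshold `tau`, how many components on each side reach a
#' per-component Dice of at least `tau`, and how much component volume they
#' carry.  Counts and volumes are non-increasing in `tau`.
#'
#' @param records Component records from [classify_components()] (both sides).
#' @param thresholds Strictly increasing Dice thresholds in (0, 1].
#' @return A tibble `threshold`, `side`, `n_components`, `volume_mm3`,
#'   `pct_components`, `pct_volume` (percentages of the side's totals).
#' @export
threshold_sweep <- function(records, thresholds = eval_config()$sweep_thresholds) {
  stopifnot(is.data.frame(records))
  if (is.unsorted(thresholds, strictly = TRUE)) {
    abort("`thresholds` must be strictly increasing.")
  }
  totals <- records |>
    dplyr::group_by(.data$side) |>
    dplyr::summarise(total_n = dplyr::n(), total_vol = sum(.data$volume_mm3),
                     .groups = "drop")
  tidyr::expand_grid(threshold = thresholds, side = unique(records$side)) |>
    dplyr::left_join(totals, by = "side") |>
    dplyr::rowwise() |>
    dplyr::mutate(
      n_components = sum(records$side == .data$side &
                           records$dsc >= .data$threshold),
      volume_mm3 = sum(records$volume_mm3[records$side == .data$side &
                                            records$dsc >= .data$threshold])
    ) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      pct_components = 100 * .data$n_components / .data$total_n,
      pct_volume = ifelse(.data$total_vol > 0,
                          100 * .data$volume_mm3 / .data$total_vol, NA_real_)
    ) |>
    dplyr::select("threshold", "side", "n_components", "volume_mm3",
                  "pct_components", "pct_volume")
}
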