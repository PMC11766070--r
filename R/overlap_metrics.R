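#' Whole-volume overlap metrics
#'
#' The whole-abnormal-volume evaluation compares the complete detection mask
#' `A` against the complete ground-truth mask `B` of a case, voxel by voxel:
#'
#' * Dice similarity coefficient, `DSC = 2|A intersect B| / (|A| + |B|)`
#' * Sensitivity (recall), `TP / (TP + FN)`
#' * Precision, `TP / (TP + FP)`
#'
#' A metric whose denominator is zero (e.g. sensitivity on an empty ground
#' truth) is reported as `NA` ("undefined") and excluded from aggregate
#' statistics, never coerced to 0 or 1.
#'
#' @param gt,det [binary_mask()] objects on the same geometry: reference
#'   ground truth and detection.
#' @return `confusion_counts()` returns a one-row tibble with integer columns
#'   `tp`, `fp`, `fn`.
#' @examples
#' gt <- binary_mask(array(c(rep(TRUE, 4), rep(FALSE, 23)), c(3, 3, 3)))
#' det <- binary_mask(array(c(rep(TRUE, 3), FALSE, TRUE, TRUE, TRUE,
#'                            rep(FALSE, 20)), c(3, 3, 3)))
#' case_metrics(confusion_counts(gt, det), gt, det)
#' @export
confusion_counts <- function(gt, det) {
  stopifnot(inherits(gt, "binary_mask"), inherits(det, "binary_mask"))
  check_same_geometry(gt, det, "gt and detection masks")
  tp <- sum(gt$values & det$values)
  tibble(tp = tp, fp = n_voxels(det) - tp, fn = n_voxels(gt) - tp)
}

#' @rdname confusion_counts
#' @param counts Output of `confusion_counts()` for the same mask pair.
#' @param config An [eval_config()]; supplies the volume strata edges.
#' @return `case_metrics()` returns a one-row tibble: `dsc`, `sensitivity`,
#'   `precision`, `gt_volume_cm3`, `detected_volume_cm3`, `volume_group`.
#' @export
case_metrics <- function(counts, gt, det, config = eval_config()) {
  stopifnot(is.data.frame(counts), nrow(counts) == 1L)
  tp <- counts$tp; fp <- counts$fp; fn <- counts$fn
  safe_ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  gt_cm3 <- volume_mm3(gt) / 1000
  det_cm3 <- volume_mm3(det) / 1000
  tibble(
    dsc = safe_ratio(2 * tp, 2 * tp + fp + fn),
    sensitivity = safe_ratio(tp, tp + fn),
    precision = safe_ratio(tp, tp + fp),
    gt_volume_cm3 = gt_cm3,
    detected_volume_cm3 = det_cm3,
    volume_group = volume_group(gt_cm3, config)
  )
}

#' Assign case-volume strata
#'
#' Cases are stratified by ground-truth abnormal volume into
#' `[0, e1)`, `[e1, e2]`, and `(e2, Inf)` cm^3, with default edges 10 and
#' 100 cm^3.  The middle stratum includes both of its edges, so a 10 cm^3
#' case falls in "10-100".
#'
#' @param gt_volume_cm3 Numeric vector of case volumes, cm^3.
#' @inheritParams case_metrics
#' @return Character vector of stratum labels (`"<10"`, `"10-100"`, `">100"`
#'   under the defaults).
#' @export
volume_group <- function(gt_volume_cm3, config = eval_config()) {
  e <- config$volume_group_edges
  labels <- volume_group_labels(config)
  out <- ifelse(gt_volume_cm3 < e[1], labels[1],
                ifelse(gt_volume_cm3 <= e[2], labels[2], labels[3]))
  as.character(out)
}

volume_group_labels <- function(config = eval_config()) {
  e <- config$volume_group_edges
  c(sprintf("<%g", e[1]), sprintf("%g-%g", e[1], e[2]), sprintf(">%g", e[2]))
}

#' Cohort summary statistics
#'
#' Summarises per-case metrics the way a cohort results table is laid out:
#' mean, standard deviation, median, 25th and 75th percentile, minimum and
#' maximum per metric.  Undefined (NA) metric values are excluded; the count
#' of excluded cases is reported per metric.  Quantiles use linear
#' interpolation between order statistics.
#'
#' @param metrics Tibble of per-case metrics as built by [case_metrics()]
#'   (rows bound together), containing at least `dsc`, `sensitivity`,
#'   `precision`.
#' @param which Metric columns to summarise.
#' @return A tibble with one row per metric and columns `metric`, `mean`,
#'   `sd`, `median`, `q25`, `q75`, `min`, `max`, `n`, `n_undefined`.
#' @export
cohort_stats <- function(metrics,
                         which = c("dsc", "sensitivity", "precision")) {
  stopifnot(is.data.frame(metrics))
  if (nrow(metrics) == 0L) abort("No cases to summarise.")
  purrr::map_dfr(which, function(m) {
    x <- metrics[[m]]
    ok <- x[!is.na(x)]
    if (length(ok) == 0L) {
      return(tibble(metric = m, mean = NA_real_, sd = NA_real_,
                    median = NA_real_, q25 = NA_real_, q75 = NA_real_,
                    min = NA_real_, max = NA_real_,
                    n = 0L, n_undefined = length(x)))
    }
    tibble(
      metric = m,
      mean = mean(ok),
      sd = if (length(ok) > 1L) sd(ok) else 0,
      median = median(ok),
      q25 = unname(quantile(ok, 0.25)),
      q75 = unname(quantile(ok, 0.75)),
      min = min(ok),
      max = max(ok),
      n = length(ok),
      n_undefined = sum(is.na(x))
    )
  })
}

#' Volume-stratified metrics
#'
#' Splits the cohort into the volume strata of the configuration and
#' summarises each stratum.  By default each case contributes its own metric
#' value ("per-case averaging"); with `pooled = TRUE` the confusion counts
#' are summed over the stratum first and the metrics computed once from the
#' pooled voxel counts, which weights cases by size.
#'
#' @inheritParams cohort_stats
#' @param config An [eval_config()].
#' @param pooled Pool voxel counts per stratum instead of averaging per-case
#'   metrics.  Pooling requires `tp`, `fp`, `fn` columns in `metrics`.
#' @return A tibble keyed by `volume_group`; empty strata appear with
#'   `n = 0`.
#' @export
grouped_metrics <- function(metrics, config = eval_config(), pooled = config$pooled_groups) {
  stopifnot(is.data.frame(metrics), nrow(metrics) > 0L)
  labels <- volume_group_labels(config)
  if (pooled) {
    if (!all(c("tp", "fp", "fn") %in% names(metrics))) {
      abort("Pooled stratified metrics need `tp`, `fp`, `fn` columns.")
    }
    out <- metrics |>
      dplyr::group_by(volume_group = factor(.data$volume_group, levels = labels)) |>
      dplyr::summarise(
        n = dplyr::n(),
        dsc = 2 * sum(.data$tp) / (2 * sum(.data$tp) + sum(.data$fp) + sum(.data$fn)),
        sensitivity = sum(.data$tp) / (sum(.data$tp) + sum(.data$fn)),
        precision = sum(.data$tp) / (sum(.data$tp) + sum(.data$fp)),
        .groups = "drop"
      ) |>
      tidyr::complete(volume_group, fill = list(n = 0L)) |>
      dplyr::mutate(volume_group = as.character(.data$volume_group))
    return(out)
  }
  split_stats <- metrics |>
    dplyr::mutate(volume_group = factor(.data$volume_group, levels = labels)) |>
    dplyr::group_by(.data$volume_group, .drop = FALSE) |>
    dplyr::group_modify(function(df, key) {
      if (nrow(df) == 0L) return(tibble(metric = character()))
      cohort_stats(df)
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(volume_group = as.character(.data$volume_group))
  split_stats
}

#' Ground-truth versus detected volume correlation
#'
#' Correlation between per-case ground-truth and detected abnormal volumes
#' across a cohort (product-moment by default, rank-based optionally).
#'
#' @param gt_volumes,det_volumes Equal-length numeric vectors, cm^3.
#' @param method `"pearson"` or `"spearman"`.
#' @return A single correlation coefficient, or `NA` when fewer than two
#'   cases or either vector is constant.
#' @export
volume_correlation <- function(gt_volumes, det_volumes,
                               method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(length(gt_volumes) == length(det_volumes))
  if (length(gt_volumes) < 2L ||
      isTRUE(sd(gt_volumes) == 0) || isTRUE(sd(det_volumes) == 0)) {
    return(NA_real_)
  }
  cor(gt_volumes, det_volumes, method = method)
}
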