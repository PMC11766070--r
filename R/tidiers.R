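#' Tidy views of an evaluation
#'
#' `tidy()` returns the requested table of a cohort evaluation as a tibble;
#' `glance()` condenses the whole run into one row.
#'
#' @param x A `"lesion_eval"` from [evaluate_cohort()].
#' @param type Which table: per-case metrics (`"cases"`), pooled component
#'   records (`"components"`), cohort statistics (`"stats"`), stratified
#'   statistics (`"groups"`), category tables (`"categories"`), the
#'   threshold sweep (`"sweep"`), half-brain differences (`"half_brain"`),
#'   positional histograms (`"histograms"`), or the volume-versus-intensity
#'   summary (`"volume_intensity"`).
#' @param ... Unused, for generic consistency.
#' @return A tibble.
#' @export
tidy.lesion_eval <- function(x, type = c("cases", "components", "stats",
                                         "groups", "categories", "sweep",
                                         "half_brain", "histograms",
                                         "volume_intensity"), ...) {
  type <- match.arg(type)
  out <- switch(type,
    cases = x$cases,
    components = x$components,
    stats = x$cohort_stats,
    groups = x$grouped_stats,
    categories = dplyr::bind_rows(
      gt = x$category_gt, detection = x$category_detection, .id = "side"),
    sweep = x$sweep,
    half_brain = x$half_brain,
    histograms = x$histograms,
    volume_intensity = x$volume_intensity %||%
      abort("No intensity data in this evaluation.")
  )
  as_tibble(out)
}

#' @rdname tidy.lesion_eval
#' @export
glance.lesion_eval <- function(x, ...) {
  s <- x$cohort_stats
  pick <- function(metric) s$mean[s$metric == metric]
  gt_tab <- x$category_gt
  found_pct <- gt_tab$pct_components[gt_tab$category == "Found"]
  tibble(
    n_cases = nrow(x$cases),
    n_gt_components = sum(x$components$side == "gt"),
    n_detection_components = sum(x$components$side == "detection"),
    mean_dsc = pick("dsc"),
    mean_sensitivity = pick("sensitivity"),
    mean_precision = pick("precision"),
    volume_correlation = x$volume_correlation,
    gt_found_pct = found_pct,
    n_warnings = length(x$warnings)
  )
}

#' @export
tidy.case_eval <- function(x, type = c("metrics", "components"), ...) {
  type <- match.arg(type)
  as_tibble(switch(type, metrics = x$metrics, components = x$components))
}

#' @export
glance.case_eval <- function(x, ...) {
  dplyr::bind_cols(
    x$metrics[, c("case_id", "dsc", "sensitivity", "precision")],
    tibble(
      n_gt_components = sum(x$components$side == "gt"),
      n_detection_components = sum(x$components$side == "detection"),
      n_warnings = length(x$warnings)
    )
  )
}
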