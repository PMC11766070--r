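#' Evaluation configuration
#'
#' Collects every tunable of the evaluation framework.  The defaults encode
#' the component taxonomy used throughout: a component whose per-component
#' Dice coefficient reaches `tau_found` (0.5) is *Found* (a *Good Detection*
#' on the detection side); one reaching `tau_partial` (0.05) but not
#' `tau_found` is *Partially Found*; anything below `tau_partial` is
#' *Missed*.  Both boundaries are inclusive at the lower edge.
#'
#' @param tau_found Dice threshold (inclusive) for the Found category.
#' @param tau_partial Dice threshold (inclusive) for the Partially Found
#'   category; must satisfy `0 < tau_partial < tau_found <= 1`.
#' @param connectivity Voxel neighbourhood for component labelling: 26
#'   (faces, edges and corners; the default) or 6 (faces only).
#' @param volume_group_edges Case-volume strata boundaries in cm^3.  The
#'   default `c(10, 100)` yields strata `[0, 10)`, `[10, 100]`, `(100, Inf)`.
#' @param sweep_thresholds Ordered Dice thresholds for the threshold sweep.
#' @param correlation Correlation flavour for ground-truth versus detected
#'   volume, `"pearson"` (default) or `"spearman"`.
#' @param brain_center_method `"centroid"` (geometric centre of the brain
#'   mask, the default) or `"bbox"` (bounding-box centre).
#' @param bin_width_mm Bin width for positional histograms, mm.
#' @param pooled_groups Compute volume-stratified metrics from pooled voxel
#'   counts instead of averaging per-case metrics.
#' @return An object of class `"lw_config"`.
#' @export
eval_config <- function(tau_found = 0.5,
                        tau_partial = 0.05,
                        connectivity = 26,
                        volume_group_edges = c(10, 100),
                        sweep_thresholds = seq(0.05, 0.95, by = 0.05),
                        correlation = c("pearson", "spearman"),
                        brain_center_method = c("centroid", "bbox"),
                        bin_width_mm = 10,
                        pooled_groups = FALSE) {
  if (!(tau_partial > 0 && tau_partial < tau_found && tau_found <= 1)) {
    abort("Thresholds must satisfy 0 < tau_partial < tau_found <= 1.")
  }
  if (!connectivity %in% c(6, 26)) abort("`connectivity` must be 6 or 26.")
  if (length(volume_group_edges) != 2L || diff(volume_group_edges) <= 0 ||
      any(volume_group_edges <= 0)) {
    abort("`volume_group_edges` must be two increasing positive values (cm^3).")
  }
  if (is.unsorted(sweep_thresholds, strictly = TRUE) ||
      any(sweep_thresholds <= 0) || any(sweep_thresholds > 1)) {
    abort("`sweep_thresholds` must be strictly increasing in (0, 1].")
  }
  if (bin_width_mm <= 0) abort("`bin_width_mm` must be positive.")
  structure(
    list(
      tau_found = tau_found,
      tau_partial = tau_partial,
      connectivity = as.integer(connectivity),
      volume_group_edges = volume_group_edges,
      sweep_thresholds = sweep_thresholds,
      correlation = match.arg(correlation),
      brain_center_method = match.arg(brain_center_method),
      bin_width_mm = bin_width_mm,
      pooled_groups = isTRUE(pooled_groups)
    ),
    class = "lw_config"
  )
}

#' @export
print.lw_config <- function(x, ...) {
  cat("<lw_config>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-20s %s\n", nm, paste(format(x[[nm]]), collapse = " ")))
  }
  invisible(x)
}

#' Read or write a configuration file
#'
#' Plain `key = value` text; unknown keys fail loudly.  Vector-valued fields
#' use comma-separated values.
#'
#' @param path File path.
#' @return `read_config()` returns an [eval_config()] with file values
#'   overriding the defaults.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("Config file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !grepl("^#", lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) != 2L
  if (any(bad)) abort(sprintf("Malformed config line: %s", lines[bad][1]))
  keys <- trimws(vapply(kv, `[[`, "", 1L))
  vals <- trimws(vapply(kv, `[[`, "", 2L))
  defaults <- eval_config()
  numeric_keys <- c("tau_found", "tau_partial", "connectivity",
                    "volume_group_edges", "sweep_thresholds", "bin_width_mm")
  args <- list()
  for (i in seq_along(keys)) {
    k <- keys[i]
    if (!k %in% names(defaults)) abort(sprintf("Unknown config key: %s", k))
    v <- strsplit(vals[i], ",", fixed = TRUE)[[1]]
    v <- trimws(v)
    args[[k]] <- if (k %in% numeric_keys) as.numeric(v)
                 else if (k == "pooled_groups") as.logical(v)
                 else v
  }
  do.call(eval_config, args)
}

#' @rdname read_config
#' @param config An [eval_config()].
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "lw_config"))
  lines <- vapply(names(config), function(nm) {
    sprintf("%s = %s", nm, paste(format(config[[nm]], trim = TRUE), collapse = ","))
  }, "")
  writeLines(lines, path)
  invisible(path)
}
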