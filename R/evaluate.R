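#' Evaluate a single case
#'
#' Runs the full per-case analysis: whole-volume confusion counts and
#' metrics, connected-component extraction on both masks, overlap matching,
#' per-component Dice and category, centroid offsets from the brain centre,
#' and per-component intensity differences against the healthy VOI for every
#' modality present.
#'
#' @param bundle A [case_bundle()].
#' @param config An [eval_config()].
#' @return A list of class `"case_eval"`: `case_id`, `counts`, `metrics`
#'   (one-row tibble), `components` (both sides, with positions and
#'   intensities), `brain_center_mm`, `voi` (per-modality VOI stats),
#'   `warnings` (validation report).
#' @export
evaluate_case <- function(bundle, config = eval_config()) {
  stopifnot(inherits(bundle, "case_bundle"))
  warnings <- validate_bundle(bundle)
  counts <- confusion_counts(bundle$gt, bundle$detection)
  metrics <- dplyr::bind_cols(
    tibble(case_id = bundle$case_id),
    case_metrics(counts, bundle$gt, bundle$detection, config),
    counts
  )

  gt_cs <- label_components(bundle$gt, config$connectivity)
  det_cs <- label_components(bundle$detection, config$connectivity)
  graph <- overlap_graph(gt_cs, det_cs)
  records <- classify_components(gt_cs, det_cs, graph, config)

  center <- brain_center(bundle$brain, config$brain_center_method)
  pos <- dplyr::bind_rows(
    dplyr::mutate(component_offsets(gt_cs, center), side = "gt"),
    dplyr::mutate(component_offsets(det_cs, center), side = "detection")
  )
  records <- dplyr::left_join(records, pos, by = c("side", "label"))

  voi <- NULL
  if (length(bundle$modalities) && n_voxels(bundle$healthy_voi) > 0L) {
    voi <- purrr::imap_dfr(bundle$modalities, function(mod, nm) {
      voi_stats(bundle$healthy_voi, mod, name = nm)
    })
    ints <- dplyr::bind_rows(
      dplyr::mutate(component_intensity(gt_cs, bundle$modalities,
                                        bundle$healthy_voi), side = "gt"),
      dplyr::mutate(component_intensity(det_cs, bundle$modalities,
                                        bundle$healthy_voi), side = "detection")
    )
    records <- dplyr::left_join(records, ints, by = c("side", "label"))
  }

  structure(
    list(case_id = bundle$case_id, counts = counts, metrics = metrics,
         components = dplyr::mutate(records, case_id = bundle$case_id,
                                    .before = 1),
         brain_center_mm = center, voi = voi, warnings = warnings,
         config = config),
    class = "case_eval"
  )
}

#' Evaluate a cohort
#'
#' Applies [evaluate_case()] to every case of a cohort and assembles the two
#' evaluation experiments: the whole-abnormal-volume experiment (per-case
#' metrics, cohort statistics, volume strata, ground-truth versus detected
#' volume correlation) and the single-component experiment (component
#' records pooled across cases, category tables per side, the Dice-threshold
#' sweep, positional and intensity summaries).  Category tables pool
#' components over the cohort, the way a multi-exam component table is
#' reported; per-case tables can be derived from `components`.
#'
#' Unreadable or invalid cases are skipped with a logged warning; the run
#' fails only if no case survives.
#'
#' @param x A `"phantom_cohort"`, a list of [case_bundle()]s, a single
#'   bundle, or a manifest path (see [read_manifest()]).
#' @param config An [eval_config()].
#' @param quiet Suppress per-case progress messages.
#' @return An object of class `"lesion_eval"`; see [tidy.lesion_eval()] for
#'   the tabular views.
#' @export
evaluate_cohort <- function(x, config = eval_config(), quiet = TRUE) {
  bundles <- cohort_bundles(x)
  if (length(bundles) == 0L) abort("No cases to evaluate.")
  evals <- list()
  warnings <- character()
  for (i in seq_along(bundles)) {
    b <- tryCatch(
      if (is.function(bundles[[i]])) bundles[[i]]() else bundles[[i]],
      error = function(e) e
    )
    if (inherits(b, "error")) {
      warnings <- c(warnings, sprintf("case %d unreadable: %s", i, conditionMessage(b)))
      next
    }
    if (!quiet) inform(sprintf("evaluating %s", b$case_id))
    ce <- tryCatch(evaluate_case(b, config), error = function(e) e)
    if (inherits(ce, "error")) {
      warnings <- c(warnings, sprintf("case %s failed: %s", b$case_id,
                                      conditionMessage(ce)))
      next
    }
    if (length(ce$warnings)) {
      warnings <- c(warnings, sprintf("%s: %s", ce$case_id, ce$warnings))
    }
    evals[[length(evals) + 1]] <- ce
  }
  if (!length(evals)) abort("Every case failed to evaluate.")

  cases <- purrr::map_dfr(evals, "metrics")
  components <- purrr::map_dfr(evals, "components")
  stats <- cohort_stats(cases)
  grouped <- grouped_metrics(cases, config)
  rho <- volume_correlation(cases$gt_volume_cm3, cases$detected_volume_cm3,
                            method = config$correlation)
  cat_gt <- category_table(dplyr::filter(components, .data$side == "gt"))
  cat_det_rows <- dplyr::filter(components, .data$side == "detection")
  cat_det <- if (nrow(cat_det_rows)) category_table(cat_det_rows) else NULL
  sweep <- threshold_sweep(components, config$sweep_thresholds)
  half_brain <- half_brain_differences(components)
  histograms <- axis_histograms(components, config$bin_width_mm)
  vol_int <- if (any(grepl("^id_", names(components)))) {
    volume_intensity_table(components)
  } else NULL

  structure(
    list(config = config, cases = cases, cohort_stats = stats,
         grouped_stats = grouped, volume_correlation = rho,
         components = components, category_gt = cat_gt,
         category_detection = cat_det, sweep = sweep,
         half_brain = half_brain, histograms = histograms,
         volume_intensity = vol_int, warnings = warnings,
         case_evals = evals),
    class = "lesion_eval"
  )
}

cohort_bundles <- function(x) {
  if (inherits(x, "phantom_cohort")) return(purrr::map(x, "bundle"))
  if (inherits(x, "phantom_case")) return(list(x$bundle))
  if (inherits(x, "case_bundle")) return(list(x))
  if (is.character(x) && length(x) == 1L) {
    man <- read_manifest(x)
    return(purrr::map(seq_len(nrow(man)), function(i) {
      force(i); function() read_case(man[i, ])
    }))
  }
  if (is.list(x)) return(x)
  abort("Cannot interpret `x` as a cohort.")
}

#' @export
print.lesion_eval <- function(x, ...) {
  cat(sprintf("<lesion_eval> %d case(s), %d component record(s)\n",
              nrow(x$cases), nrow(x$components)))
  cat("\nWhole-volume metrics:\n")
  print(as.data.frame(x$cohort_stats[, c("metric", "mean", "sd", "median",
                                         "q25", "q75", "min", "max")]),
        digits = 3, row.names = FALSE)
  if (!is.na(x$volume_correlation)) {
    cat(sprintf("\nGT vs detected volume correlation (%s): %.3f\n",
                x$config$correlation, x$volume_correlation))
  }
  cat("\nGT component categories:\n")
  print(as.data.frame(x$category_gt), digits = 3, row.names = FALSE)
  if (!is.null(x$category_detection)) {
    cat("\nDetection component categories:\n")
    print(as.data.frame(x$category_detection), digits = 3, row.names = FALSE)
  }
  if (length(x$warnings)) {
    cat(sprintf("\n%d warning(s); see $warnings\n", length(x$warnings)))
  }
  invisible(x)
}

#' Render an evaluation report to files
#'
#' Writes every table of a cohort evaluation as delimited text plus one
#' machine-readable JSON file.  Text tables are human-oriented: metrics are
#' rounded to two decimals and percentages to one, matching how component
#' results tables are printed; the JSON keeps full precision and
#' round-trips through [read_report()].
#'
#' @param eval A `"lesion_eval"`.
#' @param dir Output directory (created if needed).
#' @param plots Also write the standard figures as PDFs.
#' @return Invisibly, the paths written.
#' @export
render_report <- function(eval, dir, plots = FALSE) {
  stopifnot(inherits(eval, "lesion_eval"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  put <- function(df, name, round2 = character(), round1 = character()) {
    if (is.null(df)) return()
    df <- as.data.frame(df)
    for (col in intersect(round2, names(df))) df[[col]] <- round(df[[col]], 2)
    for (col in intersect(round1, names(df))) df[[col]] <- round(df[[col]], 1)
    p <- file.path(dir, paste0(name, ".tsv"))
    readr::write_tsv(df, p)
    paths[[length(paths) + 1]] <<- p
  }
  metric_cols <- c("dsc", "sensitivity", "precision", "mean", "sd", "median",
                   "q25", "q75", "min", "max")
  pct_cols <- c("pct_components", "pct_volume", "pct_difference")
  put(eval$cases, "cases", round2 = metric_cols)
  put(eval$cohort_stats, "cohort_stats", round2 = metric_cols)
  put(eval$grouped_stats, "grouped_stats", round2 = metric_cols)
  put(eval$category_gt, "category_gt", round1 = pct_cols)
  put(eval$category_detection, "category_detection", round1 = pct_cols)
  put(eval$components, "components", round2 = "dsc")
  put(eval$sweep, "sweep", round1 = pct_cols)
  put(eval$half_brain, "half_brain", round1 = pct_cols)
  put(eval$histograms, "histograms")
  put(eval$volume_intensity, "volume_intensity", round1 = character())
  write_config(eval$config, file.path(dir, "config.txt"))
  if (length(eval$warnings)) {
    writeLines(eval$warnings, file.path(dir, "warnings.txt"))
  }

  json_path <- file.path(dir, "report.json")
  payload <- list(
    config = unclass(eval$config),
    cases = eval$cases,
    cohort_stats = eval$cohort_stats,
    grouped_stats = eval$grouped_stats,
    volume_correlation = eval$volume_correlation,
    components = eval$components,
    category_gt = eval$category_gt,
    category_detection = eval$category_detection,
    sweep = eval$sweep,
    half_brain = eval$half_brain,
    histograms = eval$histograms,
    volume_intensity = eval$volume_intensity,
    warnings = eval$warnings
  )
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                       na = "null", null = "null")
  paths <- c(paths, json_path)

  if (plots) {
    for (type in c("sweep", "offsets", "volume_intensity", "volumes")) {
      p <- tryCatch(autoplot(eval, type = type), error = function(e) NULL)
      if (!is.null(p)) {
        f <- file.path(dir, paste0("plot_", type, ".pdf"))
        ggplot2::ggsave(f, p, width = 7, height = 5)
        paths <- c(paths, f)
      }
    }
  }
  invisible(unlist(paths))
}

#' @rdname render_report
#' @param path Path to a `report.json` written by `render_report()`.
#' @return `read_report()` returns the report tables as a named list of
#'   tibbles (plus config and scalars).
#' @export
read_report <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  tables <- c("cases", "cohort_stats", "grouped_stats", "components",
              "category_gt", "category_detection", "sweep", "half_brain",
              "histograms", "volume_intensity")
  for (t in intersect(tables, names(raw))) {
    if (!is.null(raw[[t]]) && is.data.frame(raw[[t]])) {
      raw[[t]] <- as_tibble(raw[[t]])
    }
  }
  raw
}
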