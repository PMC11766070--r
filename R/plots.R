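#' Plot a cohort evaluation
#'
#' `autoplot()` dispatches to the standard figures of the framework:
#'
#' * `"sweep"` — component counts (and volume share) surviving each Dice
#'   threshold, per side.
#' * `"offsets"` — component centroid scatter in the axial plane, coloured
#'   by category.
#' * `"volume_intensity"` — component volume versus intensity difference per
#'   modality, coloured by category.
#' * `"volumes"` — per-case ground-truth versus detected volume.
#'
#' @param object A `"lesion_eval"`.
#' @param type One of `"sweep"`, `"offsets"`, `"volume_intensity"`,
#'   `"volumes"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.lesion_eval <- function(object, type = c("sweep", "offsets",
                                                  "volume_intensity",
                                                  "volumes"), ...) {
  type <- match.arg(type)
  switch(type,
    sweep = plot_sweep(object$sweep),
    offsets = plot_offsets(object$components),
    volume_intensity = plot_volume_intensity(object$components),
    volumes = plot_volumes(object$cases)
  )
}

#' @rdname autoplot.lesion_eval
#' @param sweep A [threshold_sweep()] tibble.
#' @export
plot_sweep <- function(sweep) {
  ggplot2::ggplot(sweep, ggplot2::aes(x = .data$threshold,
                                      y = .data$n_components,
                                      colour = .data$side)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1.2) +
    ggplot2::labs(x = "Dice threshold", y = "components at or above threshold",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.lesion_eval
#' @param components Component records with offsets (see
#'   [evaluate_cohort()]).
#' @export
plot_offsets <- function(components) {
  ggplot2::ggplot(components,
                  ggplot2::aes(x = .data$offset_x_mm, y = .data$offset_y_mm,
                               colour = .data$category,
                               size = .data$volume_mm3)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::scale_size_area(max_size = 4, guide = "none") +
    ggplot2::facet_wrap(~side) +
    ggplot2::geom_hline(yintercept = 0, linetype = 3) +
    ggplot2::geom_vline(xintercept = 0, linetype = 3) +
    ggplot2::labs(x = "X offset (mm, left +)", y = "Y offset (mm, front +)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.lesion_eval
#' @export
plot_volume_intensity <- function(components) {
  id_cols <- grep("^id_", names(components), value = TRUE)
  if (!length(id_cols)) abort("No intensity columns to plot.")
  long <- tidyr::pivot_longer(components, dplyr::all_of(id_cols),
                              names_to = "modality", names_prefix = "id_",
                              values_to = "id")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$volume_mm3, y = .data$id,
                                     colour = .data$category)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~modality) +
    ggplot2::labs(x = "component volume (mm^3, log scale)",
                  y = "intensity difference (%)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.lesion_eval
#' @param cases Per-case metrics tibble.
#' @export
plot_volumes <- function(cases) {
  ggplot2::ggplot(cases, ggplot2::aes(x = .data$gt_volume_cm3,
                                      y = .data$detected_volume_cm3)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 3) +
    ggplot2::geom_point() +
    ggplot2::labs(x = expression("ground-truth volume" ~ (cm^3)),
                  y = expression("detected volume" ~ (cm^3))) +
    ggplot2::theme_minimal()
}
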