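#' Healthy-VOI intensity statistics
#'
#' Mean intensity of a modality image over the healthy white-matter volume of
#' interest.  This mean is the reference for every intensity difference of
#' the case, so it must be computed on the same (post-stretch) intensities as
#' the component means.
#'
#' @param voi Non-empty [binary_mask()] of the healthy VOI.
#' @param modality A [voxel_grid()] intensity volume.
#' @param name Modality name carried into the output.
#' @return A one-row tibble `modality`, `voi_mean`, `voi_n_voxels`.  A zero
#'   mean is allowed here but renders downstream intensity differences
#'   undefined.
#' @export
voi_stats <- function(voi, modality, name = "modality") {
  stopifnot(inherits(voi, "binary_mask"), inherits(modality, "voxel_grid"))
  check_same_geometry(voi, modality, "VOI and modality")
  if (n_voxels(voi) == 0L) abort("Healthy VOI is empty.")
  m <- mean(modality$values[voi$values])
  tibble(modality = name, voi_mean = m, voi_n_voxels = n_voxels(voi))
}

#' Intensity difference versus the healthy reference
#'
#' Percent deviation of an abnormal component's mean intensity from the
#' healthy-VOI mean:
#' `ID = 100 * (component_mean - voi_mean) / voi_mean`.
#' Positive IDs are hyperintense relative to healthy white matter, negative
#' hypointense.  The statistic is invariant under a common positive rescaling
#' of the image but *not* under an affine map with offset, which is why the
#' 12-bit stretch must precede it.
#'
#' @param component_mean Numeric vector of component mean intensities.
#' @param voi_mean Healthy-VOI mean intensity (scalar).
#' @return Numeric vector of IDs in percent; `NA` when `voi_mean` is 0.
#' @export
intensity_difference <- function(component_mean, voi_mean) {
  if (length(voi_mean) != 1L) abort("`voi_mean` must be a single value.")
  if (!is.finite(voi_mean) || voi_mean == 0) {
    return(rep(NA_real_, length(component_mean)))
  }
  100 * (component_mean - voi_mean) / voi_mean
}

#' Per-component intensity profile
#'
#' Computes, for every component of a set and every modality, the component's
#' mean intensity and its intensity difference against the case VOI.
#'
#' @param cs A [label_components()] result.
#' @param modalities Named list of [voxel_grid()] intensity volumes.
#' @param voi The case's healthy-VOI [binary_mask()].
#' @return A tibble `label`, then per modality `mean_<mod>` and `id_<mod>`
#'   columns (one row per component).
#' @export
component_intensity <- function(cs, modalities, voi) {
  stopifnot(inherits(cs, "component_set"), is.list(modalities))
  out <- tibble(label = cs$components$label)
  if (length(modalities) == 0L) return(out)
  fg <- cs$labels > 0L
  lab <- cs$labels[fg]
  for (nm in names(modalities)) {
    mod <- modalities[[nm]]
    vs <- voi_stats(voi, mod, name = nm)
    means <- if (cs$n_components > 0L) {
      as.numeric(tapply(mod$values[fg], lab, mean))
    } else numeric()
    out[[paste0("mean_", nm)]] <- means
    out[[paste0("id_", nm)]] <- intensity_difference(means, vs$voi_mean)
  }
  out
}

#' Joint volume-versus-intensity summary
#'
#' Summarises, per component category and modality, the observed intensity
#' differences (range and inter-decile range) and component volumes — the
#' tabular counterpart of a volume-versus-ID density plot.
#'
#' @param records Component records carrying `category`, `volume_mm3` and
#'   `id_<modality>` columns (as assembled by [evaluate_case()]).
#' @param by Extra grouping columns, e.g. `"side"`.
#' @return A tibble keyed by (`by` columns, `category`, `modality`) with
#'   `n`, `id_min`, `id_p10`, `id_median`, `id_p90`, `id_max`,
#'   `volume_min_mm3`, `volume_max_mm3`.
#' @export
volume_intensity_table <- function(records, by = intersect("side", names(records))) {
  stopifnot(is.data.frame(records), nrow(records) > 0L)
  id_cols <- grep("^id_", names(records), value = TRUE)
  if (length(id_cols) == 0L) abort("`records` carries no `id_<modality>` columns.")
  records |>
    tidyr::pivot_longer(dplyr::all_of(id_cols), names_to = "modality",
                        names_prefix = "id_", values_to = "id") |>
    dplyr::filter(!is.na(.data$id)) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(by, "category", "modality")))) |>
    dplyr::summarise(
      n = dplyr::n(),
      id_min = min(.data$id),
      id_p10 = unname(quantile(.data$id, 0.10)),
      id_median = median(.data$id),
      id_p90 = unname(quantile(.data$id, 0.90)),
      id_max = max(.data$id),
      volume_min_mm3 = min(.data$volume_mm3),
      volume_max_mm3 = max(.data$volume_mm3),
      .groups = "drop"
    )
}
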