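#' Cohort template for phantom generation
#'
#' Ranges from which [generate_cohort()] draws each case.  The defaults
#' emulate a multi-pathology validation cohort: a handful of well-separated
#' lesions per case with volumes spanning two decades (2 cm^3 down to 2 cm^3
#' / 50), planned detection quality drawn with roughly half the components
#' Found, a quarter Partially Found and a quarter Missed, FLAIR
#' hyperintense contrast, broad T2 contrast, mildly hypo- to hyperintense
#' T1ce contrast, a small number of micro false-positive detections per
#' case, and modality noise at 2% of the background level.
#'
#' @param n_lesions_range Integer range of lesions per case.
#' @param volume_range_mm3 Lesion volume range, mm^3 (log-uniform draw).
#' @param category_probs Probabilities of planning a lesion as Found,
#'   Partial, or Missed.
#' @param dsc_found_range,dsc_partial_range Planned-Dice draw ranges for
#'   Found and Partial lesions (kept clear of the 0.5 and 0.05 category
#'   boundaries so voxelisation error cannot flip a planned category).
#' @param id_ranges Named list of per-modality intensity-difference draw
#'   ranges, percent.
#' @param n_fp_range Integer range of false-positive components per case.
#' @param fp_volume_range_mm3 False-positive volume range, mm^3.
#' @param noise_frac Noise standard deviation as a fraction of background.
#' @inheritParams phantom_spec
#' @return A list of class `"phantom_template"`.
#' @export
phantom_template <- function(shape = c(72, 72, 72),
                             spacing = c(2.5, 2.5, 2.5),
                             brain_radius_mm = 75,
                             background = 1000,
                             voi_radius_mm = 10,
                             n_lesions_range = c(2, 6),
                             volume_range_mm3 = c(2000, 1e5),
                             category_probs = c(Found = 0.49, Partial = 0.27,
                                                Missed = 0.24),
                             dsc_found_range = c(0.6, 0.95),
                             dsc_partial_range = c(0.15, 0.45),
                             id_ranges = list(flair = c(10, 65),
                                              t2 = c(0, 70),
                                              t1ce = c(-30, 20)),
                             n_fp_range = c(0, 2),
                             fp_volume_range_mm3 = c(100, 500),
                             noise_frac = 0.02) {
  structure(as.list(environment()), class = "phantom_template")
}

#' Generate a reproducible phantom cohort
#'
#' Draws `n_cases` independent phantom cases from a [phantom_template()].
#' Each case gets its own seed derived from the cohort seed, so the whole
#' cohort is bit-reproducible and individual cases can be regenerated in
#' isolation.
#'
#' @param n_cases Number of cases.
#' @param seed Cohort seed.
#' @param template A [phantom_template()].
#' @param perturb With `FALSE`, detections are exact copies of the ground
#'   truth: no planned degradation, no false positives, no noise — the
#'   identity cohort used for end-to-end checks.
#' @return A list of class `"phantom_cohort"`: elements are
#'   `"phantom_case"` objects (see [generate_bundle()]).
#' @export
generate_cohort <- function(n_cases = 24, seed = 1,
                            template = phantom_template(),
                            perturb = TRUE) {
  stopifnot(n_cases >= 1, inherits(template, "phantom_template"))
  case_seeds <- withr::with_seed(seed, sample.int(.Machine$integer.max - 1L, n_cases))
  cases <- purrr::map(seq_len(n_cases), function(i) {
    spec <- withr::with_seed(case_seeds[i], draw_case_spec(template, perturb))
    spec$case_id <- sprintf("phantom_%03d", i)
    spec$seed <- case_seeds[i]
    generate_bundle(spec)
  })
  structure(cases, class = "phantom_cohort")
}

#' @rdname generate_cohort
#' @param cohort A `"phantom_cohort"`.
#' @return `cohort_truth()` returns the stacked truth tables with a
#'   `case_id` column.
#' @export
cohort_truth <- function(cohort) {
  purrr::map_dfr(cohort, function(pc) {
    dplyr::mutate(pc$truth, case_id = pc$spec$case_id, .before = 1)
  })
}

# draw one case spec from a template (runs inside the per-case seed)
draw_case_spec <- function(template, perturb) {
  t <- template
  n_les <- sample(t$n_lesions_range[1]:t$n_lesions_range[2], 1)
  placed <- list()   # (center offset, bound radius)
  max_sp <- max(t$spacing)

  draw_position <- function(bound_mm) {
    max_r <- t$brain_radius_mm - bound_mm - 2 * max_sp
    if (max_r <= 0) return(NULL)
    for (try in 1:200) {
      u <- rnorm(3)
      u <- u / sqrt(sum(u^2))
      pos <- u * max_r * runif(1)^(1 / 3)
      ok <- TRUE
      for (p in placed) {
        if (sqrt(sum((pos - p$pos)^2)) <= bound_mm + p$bound + 2 * max_sp) {
          ok <- FALSE; break
        }
      }
      if (ok) return(pos)
    }
    NULL
  }

  draw_ids <- function() {
    id <- vapply(t$id_ranges, function(r) runif(1, r[1], r[2]), numeric(1))
    setNames(id, names(t$id_ranges))
  }

  lesion_rows <- list()
  for (i in seq_len(n_les)) {
    vol <- exp(runif(1, log(t$volume_range_mm3[1]), log(t$volume_range_mm3[2])))
    bound <- 1.35 * (3 * vol / (4 * pi))^(1 / 3)
    pos <- draw_position(bound)
    if (is.null(pos)) next   # no room left; smaller case
    placed[[length(placed) + 1]] <- list(pos = pos, bound = bound)
    if (perturb) {
      cat_i <- sample(names(t$category_probs), 1, prob = t$category_probs)
      dsc <- switch(cat_i,
        Found = runif(1, t$dsc_found_range[1], t$dsc_found_range[2]),
        Partial = runif(1, t$dsc_partial_range[1], t$dsc_partial_range[2]),
        Missed = NA_real_
      )
      drop <- identical(cat_i, "Missed")
    } else {
      dsc <- NA_real_
      drop <- FALSE
    }
    lesion_rows[[length(lesion_rows) + 1]] <-
      lesion_spec(vol, offset_mm = pos, id = draw_ids(),
                  dsc_target = if (perturb && !drop) dsc else NA_real_,
                  drop = drop)
  }
  if (!length(lesion_rows)) {
    # degenerate template; fall back to one central lesion
    lesion_rows[[1]] <- lesion_spec(t$volume_range_mm3[1], id = draw_ids())
  }
  lesions <- dplyr::bind_rows(lesion_rows)

  fps <- NULL
  if (perturb && t$n_fp_range[2] > 0) {
    n_fp <- sample(t$n_fp_range[1]:t$n_fp_range[2], 1)
    fp_rows <- list()
    for (j in seq_len(n_fp)) {
      vol <- runif(1, t$fp_volume_range_mm3[1], t$fp_volume_range_mm3[2])
      bound <- 1.35 * (3 * vol / (4 * pi))^(1 / 3)
      pos <- draw_position(bound)
      if (is.null(pos)) next
      placed[[length(placed) + 1]] <- list(pos = pos, bound = bound)
      fp_rows[[length(fp_rows) + 1]] <-
        lesion_spec(vol, offset_mm = pos, id = draw_ids())
    }
    if (length(fp_rows)) fps <- dplyr::bind_rows(fp_rows)
  }

  phantom_spec(
    lesions = lesions, false_positives = fps,
    shape = t$shape, spacing = t$spacing,
    brain_radius_mm = t$brain_radius_mm, background = t$background,
    noise_sd = if (perturb) t$noise_frac * t$background else 0,
    voi_radius_mm = t$voi_radius_mm
  )
}

#' Write phantom cases to disk
#'
#' Serialises a phantom case (or cohort) as NIfTI volumes plus a delimited
#' manifest compatible with [read_manifest()], and the truth table as TSV.
#'
#' @param case A `"phantom_case"` from [generate_bundle()].
#' @param dir Output directory (created if needed).
#' @return The manifest row (invisibly for `write_cohort()`, which writes
#'   `manifest.tsv` and `truth.tsv` and returns their directory).
#' @export
write_bundle <- function(case, dir) {
  stopifnot(inherits(case, "phantom_case"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  b <- case$bundle
  id <- b$case_id
  paths <- list(
    gt = file.path(dir, paste0(id, "_gt.nii.gz")),
    detection = file.path(dir, paste0(id, "_detection.nii.gz")),
    brain = file.path(dir, paste0(id, "_brain.nii.gz")),
    voi = file.path(dir, paste0(id, "_voi.nii.gz"))
  )
  write_grid(b$gt, paths$gt)
  write_grid(b$detection, paths$detection)
  write_grid(b$brain, paths$brain)
  write_grid(b$healthy_voi, paths$voi)
  row <- tibble(case_id = id, gt = paths$gt, detection = paths$detection,
                brain = paths$brain, voi = paths$voi)
  for (nm in names(b$modalities)) {
    p <- file.path(dir, paste0(id, "_", nm, ".nii.gz"))
    write_grid(b$modalities[[nm]], p)
    row[[nm]] <- p
  }
  row
}

#' @rdname write_bundle
#' @param cohort A `"phantom_cohort"`.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "phantom_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- purrr::map_dfr(cohort, write_bundle, dir = dir)
  # volumes sit beside the manifest: record portable relative paths
  manifest <- dplyr::mutate(manifest,
                            dplyr::across(-"case_id", basename))
  readr::write_tsv(manifest, file.path(dir, "manifest.tsv"))
  readr::write_tsv(cohort_truth(cohort), file.path(dir, "truth.tsv"))
  invisible(dir)
}
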