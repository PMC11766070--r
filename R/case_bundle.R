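#' Case bundles
#'
#' A case bundle holds every co-registered volume belonging to one
#' examination: the reference ground-truth abnormality mask, the automated
#' detection mask, a whole-brain mask, a healthy white-matter volume of
#' interest (VOI) used as the intensity reference, and one scalar intensity
#' volume per MRI modality (typically FLAIR, T2 and T1ce).
#'
#' @param gt,detection,brain,healthy_voi [binary_mask()] objects sharing one
#'   geometry.
#' @param modalities Named list of [voxel_grid()] intensity volumes.
#' @param case_id Case identifier.
#' @return An object of class `"case_bundle"`.
#' @seealso [validate_bundle()] for the invariant checks.
#' @export
case_bundle <- function(gt, detection, brain, healthy_voi,
                        modalities = list(), case_id = "case") {
  for (m in list(gt, detection, brain, healthy_voi)) {
    stopifnot(inherits(m, "binary_mask"))
  }
  stopifnot(is.list(modalities))
  if (length(modalities) && is.null(names(modalities))) {
    abort("`modalities` must be a named list of voxel grids.")
  }
  structure(
    list(gt = gt, detection = detection, brain = brain,
         healthy_voi = healthy_voi, modalities = modalities,
         case_id = as.character(case_id)),
    class = "case_bundle"
  )
}

#' @export
print.case_bundle <- function(x, ...) {
  cat(sprintf("<case_bundle> %s: %s voxels, modalities: %s\n",
              x$case_id, paste(grid_shape(x$gt), collapse = "x"),
              if (length(x$modalities)) paste(names(x$modalities), collapse = ", ")
              else "none"))
  cat(sprintf("  GT %d voxels | detection %d | brain %d | VOI %d\n",
              n_voxels(x$gt), n_voxels(x$detection),
              n_voxels(x$brain), n_voxels(x$healthy_voi)))
  invisible(x)
}

#' Validate a case bundle
#'
#' Checks the structural invariants every downstream computation relies on:
#' all members share one shape and spacing, the healthy VOI lies inside the
#' brain mask, and the VOI is disjoint from the ground truth (a VOI touching
#' abnormal tissue would bias every intensity difference).
#'
#' Validation is report-only: it never throws, so a pipeline can decide
#' whether to skip or flag a case.
#'
#' @param bundle A [case_bundle()].
#' @return Character vector of violated invariants; empty when valid.
#' @export
validate_bundle <- function(bundle) {
  stopifnot(inherits(bundle, "case_bundle"))
  issues <- character()
  ref <- bundle$gt
  members <- c(list(detection = bundle$detection, brain = bundle$brain,
                    healthy_voi = bundle$healthy_voi), bundle$modalities)
  for (nm in names(members)) {
    g <- members[[nm]]
    if (!identical(dim(g$values), dim(ref$values))) {
      issues <- c(issues, sprintf("`%s` shape (%s) differs from `gt` (%s)",
                                  nm, paste(dim(g$values), collapse = "x"),
                                  paste(dim(ref$values), collapse = "x")))
    } else if (!isTRUE(all.equal(g$spacing, ref$spacing))) {
      issues <- c(issues, sprintf("`%s` voxel spacing differs from `gt`", nm))
    }
  }
  same_geom <- function(a, b) identical(dim(a$values), dim(b$values))
  if (same_geom(bundle$healthy_voi, bundle$brain)) {
    outside <- sum(bundle$healthy_voi$values & !bundle$brain$values)
    if (outside > 0) {
      issues <- c(issues, sprintf(
        "healthy_voi extends outside the brain mask (%d voxels)", outside))
    }
  }
  if (same_geom(bundle$healthy_voi, bundle$gt)) {
    overlap <- sum(bundle$healthy_voi$values & bundle$gt$values)
    if (overlap > 0) {
      issues <- c(issues, sprintf(
        "healthy_voi overlaps the ground truth (%d voxels)", overlap))
    }
  }
  issues
}
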