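#' Phantom case specification
#'
#' A phantom spec fully determines one synthetic case: a spherical "brain" on
#' a regular grid, a list of ellipsoidal lesions with target volume, position
#' (relative to the brain centre), per-modality intensity contrast, and a
#' perturbation plan for the matching detection; plus spurious
#' false-positive components, a background intensity level, additive Gaussian
#' noise for the modality images (masks stay clean), and a seed that fixes
#' all randomness.
#'
#' Lesion rows are built with [lesion_spec()]; intensity contrasts are given
#' as intensity differences in percent versus healthy tissue, the quantity
#' the evaluation recovers.
#'
#' @param lesions Tibble of lesion rows ([lesion_spec()]).
#' @param false_positives Optional tibble of spurious detection components
#'   (same columns; `dsc_target` and `drop` are ignored).
#' @param shape Grid shape (3 integers).
#' @param spacing Voxel spacing, mm.
#' @param brain_radius_mm Brain sphere radius, mm.
#' @param background Healthy-tissue intensity level (arbitrary units).
#' @param noise_sd Standard deviation of additive Gaussian intensity noise.
#' @param voi_radius_mm Radius of the healthy reference VOI sphere, mm.
#' @param case_id Case identifier.
#' @param seed Integer seed fixing all randomness of the bundle.
#' @return An object of class `"phantom_spec"`.
#' @export
phantom_spec <- function(lesions,
                         false_positives = NULL,
                         shape = c(72, 72, 72),
                         spacing = c(2.5, 2.5, 2.5),
                         brain_radius_mm = 75,
                         background = 1000,
                         noise_sd = 0,
                         voi_radius_mm = 10,
                         case_id = "phantom",
                         seed = 1L) {
  stopifnot(is.data.frame(lesions), nrow(lesions) >= 0)
  if (any(lesions$volume_mm3 < prod(spacing))) {
    abort("Every lesion must be at least one voxel in volume.")
  }
  offs <- sqrt(lesions$offset_x_mm^2 + lesions$offset_y_mm^2 + lesions$offset_z_mm^2)
  if (any(offs >= brain_radius_mm)) {
    abort("Lesion centres must lie inside the brain radius.")
  }
  structure(
    list(lesions = lesions, false_positives = false_positives,
         shape = as.integer(shape), spacing = as.numeric(spacing),
         brain_radius_mm = brain_radius_mm, background = background,
         noise_sd = noise_sd, voi_radius_mm = voi_radius_mm,
         case_id = case_id, seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

#' @rdname phantom_spec
#' @param volume_mm3 Target lesion volume, mm^3.
#' @param offset_mm Target centroid offset from the brain centre, mm
#'   (length 3; X left+, Y front+, Z upper+).
#' @param id Named numeric vector of target intensity differences in percent,
#'   one per modality (e.g. `c(flair = 40, t2 = 25, t1ce = -10)`).
#' @param dsc_target Planned per-component Dice of the matching detection:
#'   `NA` leaves the detection identical to the lesion (Dice 1); values in
#'   (0, 1) shrink the detection concentrically until the planned Dice is
#'   met.
#' @param drop Drop the lesion from the detection mask entirely (a planned
#'   Missed ground truth).
#' @param det_shift_mm Optional translation of the detection component, mm.
#' @export
lesion_spec <- function(volume_mm3, offset_mm = c(0, 0, 0),
                        id = c(flair = 40, t2 = 25, t1ce = -10),
                        dsc_target = NA_real_, drop = FALSE,
                        det_shift_mm = c(0, 0, 0)) {
  stopifnot(length(offset_mm) == 3L, length(det_shift_mm) == 3L,
            !is.null(names(id)))
  row <- tibble(
    volume_mm3 = volume_mm3,
    offset_x_mm = offset_mm[1], offset_y_mm = offset_mm[2],
    offset_z_mm = offset_mm[3],
    dsc_target = dsc_target, drop = isTRUE(drop),
    shift_x_mm = det_shift_mm[1], shift_y_mm = det_shift_mm[2],
    shift_z_mm = det_shift_mm[3]
  )
  for (nm in names(id)) row[[paste0("id_", nm)]] <- unname(id[nm])
  row
}

# squared-distance field helper: ellipsoid membership over a bounding box
paint_ellipsoid <- function(arr, center_mm, semi_mm, spacing, value) {
  d <- dim(arr)
  lo <- pmax(1L, floor((center_mm - semi_mm) / spacing) + 1L)
  hi <- pmin(d, ceiling((center_mm + semi_mm) / spacing) + 1L)
  if (any(lo > hi)) return(arr)
  ix <- lo[1]:hi[1]; iy <- lo[2]:hi[2]; iz <- lo[3]:hi[3]
  fx <- (((ix - 1) * spacing[1] - center_mm[1]) / semi_mm[1])^2
  fy <- (((iy - 1) * spacing[2] - center_mm[2]) / semi_mm[2])^2
  fz <- (((iz - 1) * spacing[3] - center_mm[3]) / semi_mm[3])^2
  inside <- outer(outer(fx, fy, `+`), fz, `+`) <= 1
  sub <- arr[ix, iy, iz, drop = FALSE]
  sub[inside] <- value
  arr[ix, iy, iz] <- sub
  arr
}

# semi-axes realising a target ellipsoid volume with mild random anisotropy
draw_semi_axes <- function(volume_mm3) {
  u <- runif(3, 0.75, 1.3)
  u <- u / prod(u)^(1 / 3)
  r <- (3 * volume_mm3 / (4 * pi))^(1 / 3)
  r * u
}

# erosion offset r (<= 0) such that the concentric ellipsoid with semi-axes
# (a+r, b+r, c+r) has Dice `target` against the original (nested overlap:
# DSC = 2 Vd / (Vd + Vg))
solve_erosion <- function(semi, target) {
  stopifnot(target > 0, target < 1)
  vg <- prod(semi)
  f <- function(r) {
    vd <- prod(pmax(semi + r, 0))
    2 * vd / (vd + vg) - target
  }
  uniroot(f, lower = -min(semi) * 0.999999, upper = 0)$root
}

#' Generate a phantom case bundle
#'
#' Realises a [phantom_spec()] on its voxel grid: the ground-truth mask is
#' the union of the voxelised lesions, the detection mask is built per lesion
#' from its perturbation plan (identical copy, concentric shrink to a target
#' Dice, translation, or drop) plus the spurious components, the modality
#' images carry each component's planned intensity difference against the
#' emitted healthy VOI before noise, and the VOI is a sphere placed at
#' maximal clearance from every component.  The same seed always yields a
#' bit-identical bundle.
#'
#' Lesions that merge into a single connected component (or vanish entirely
#' when voxelised) violate the spec's promise of distinct components and
#' raise an error rather than silently changing the truth.
#'
#' @param spec A [phantom_spec()].
#' @return A list of class `"phantom_case"` with elements `bundle` (a
#'   [case_bundle()]), `truth` (one row per planned component: realised
#'   voxel counts, volumes, centroid offsets, per-modality planned ID,
#'   planned Dice and category, engine labels), and `spec`.
#' @export
generate_bundle <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  withr::with_seed(spec$seed, generate_bundle_impl(spec))
}

generate_bundle_impl <- function(spec) {
  d <- spec$shape; sp <- spec$spacing
  center <- (d - 1) / 2 * sp
  xs <- (seq_len(d[1]) - 1) * sp[1]
  ys <- (seq_len(d[2]) - 1) * sp[2]
  zs <- (seq_len(d[3]) - 1) * sp[3]
  dist2 <- outer(outer((xs - center[1])^2, (ys - center[2])^2, `+`),
                 (zs - center[3])^2, `+`)
  brain <- dist2 <= spec$brain_radius_mm^2

  lesions <- spec$lesions
  n_les <- nrow(lesions)
  fps <- spec$false_positives
  n_fp <- if (is.null(fps)) 0L else nrow(fps)
  mod_names <- sub("^id_", "", grep("^id_", names(lesions), value = TRUE))
  if (n_fp > 0) {
    fp_mods <- sub("^id_", "", grep("^id_", names(fps), value = TRUE))
    if (!setequal(fp_mods, mod_names)) {
      abort("False positives must carry the same `id_` modalities as lesions.")
    }
  }

  gt_ids <- array(0L, d)      # which planned lesion owns each GT voxel
  det_ids <- array(0L, d)     # planned component owning each detection voxel
  object_meta <- vector("list", n_les + n_fp)

  for (i in seq_len(n_les)) {
    les <- lesions[i, ]
    semi <- draw_semi_axes(les$volume_mm3)
    c_mm <- center + c(les$offset_x_mm, les$offset_y_mm, les$offset_z_mm)
    before <- sum(gt_ids > 0L)
    gt_ids <- paint_ellipsoid(gt_ids, c_mm, semi, sp, i)
    painted <- sum(gt_ids == i)
    if (painted == 0L) {
      abort(sprintf("Lesion %d voxelises to zero voxels (volume %.1f mm^3).",
                    i, les$volume_mm3))
    }
    if (sum(gt_ids > 0L) - before < painted) {
      abort(sprintf("Lesion %d overlaps an earlier lesion; distinct components required.", i))
    }
    det_semi <- semi
    shifted_c <- c_mm + c(les$shift_x_mm, les$shift_y_mm, les$shift_z_mm)
    if (!isTRUE(les$drop)) {
      if (!is.na(les$dsc_target) && les$dsc_target < 1) {
        det_semi <- semi + solve_erosion(semi, les$dsc_target)
      }
      det_ids <- paint_ellipsoid(det_ids, shifted_c, det_semi, sp, i)
      if (sum(det_ids == i) == 0L) {
        abort(sprintf("Planned detection for lesion %d voxelises to zero voxels.", i))
      }
    }
    object_meta[[i]] <- list(type = "lesion", center_mm = c_mm,
                             bound_mm = max(semi), row = les)
  }

  for (j in seq_len(n_fp)) {
    fp <- fps[j, ]
    semi <- draw_semi_axes(fp$volume_mm3)
    c_mm <- center + c(fp$offset_x_mm, fp$offset_y_mm, fp$offset_z_mm)
    k <- n_les + j
    before <- sum(det_ids > 0L)
    det_ids <- paint_ellipsoid(det_ids, c_mm, semi, sp, k)
    painted <- sum(det_ids == k)
    if (painted == 0L) abort(sprintf("False positive %d voxelises to zero voxels.", j))
    if (sum(det_ids > 0L) - before < painted) {
      abort(sprintf("False positive %d overlaps an earlier detection component.", j))
    }
    if (any(gt_ids[det_ids == k] > 0L)) {
      abort(sprintf("False positive %d overlaps the ground truth.", j))
    }
    object_meta[[k]] <- list(type = "false_positive", center_mm = c_mm,
                             bound_mm = max(semi), row = fp)
  }

  gt <- binary_mask(gt_ids > 0L, sp)
  det <- binary_mask(det_ids > 0L, sp)
  brain_mask <- binary_mask(brain, sp)

  # distinct planned components must stay distinct under 26-connectivity
  gt_cs <- label_components(gt, 26)
  if (gt_cs$n_components != n_les) {
    abort(sprintf("Planned %d distinct lesions but realised %d connected component(s); lesions touch or merge.",
                  n_les, gt_cs$n_components))
  }
  det_cs <- label_components(det, 26)
  n_det_expected <- sum(!lesions$drop) + n_fp
  if (det_cs$n_components != n_det_expected) {
    abort(sprintf("Planned %d distinct detection components but realised %d; components touch or merge.",
                  n_det_expected, det_cs$n_components))
  }

  # healthy VOI: sphere at maximal clearance from every painted object
  voi_center <- place_voi(spec, center, object_meta, dist2)
  voi <- array(FALSE, d)
  voi <- paint_ellipsoid(voi, voi_center, rep(spec$voi_radius_mm, 3), sp, TRUE)
  if (any(voi & (gt_ids > 0L | det_ids > 0L))) {
    abort("Healthy VOI could not be placed disjoint from all components.")
  }
  voi_mask <- binary_mask(voi & brain, sp)
  if (n_voxels(voi_mask) == 0L) abort("Healthy VOI fell outside the brain.")

  # modalities: background inside brain, per-component contrast, then noise
  modalities <- list()
  for (nm in mod_names) {
    vals <- array(0, d)
    vals[brain] <- spec$background
    for (i in seq_len(n_les)) {
      idv <- lesions[[paste0("id_", nm)]][i]
      vals[gt_ids == i] <- spec$background * (1 + idv / 100)
    }
    for (j in seq_len(n_fp)) {
      idv <- fps[[paste0("id_", nm)]][j]
      vals[det_ids == n_les + j] <- spec$background * (1 + idv / 100)
    }
    if (spec$noise_sd > 0) {
      vals <- vals + array(rnorm(prod(d), 0, spec$noise_sd), d)
    }
    modalities[[nm]] <- voxel_grid(vals, sp)
  }

  truth <- phantom_truth(spec, gt_ids, det_ids, gt_cs, det_cs, center,
                         object_meta, mod_names)

  bundle <- case_bundle(gt = gt, detection = det, brain = brain_mask,
                        healthy_voi = voi_mask, modalities = modalities,
                        case_id = spec$case_id)
  structure(list(bundle = bundle, truth = truth, spec = spec),
            class = "phantom_case")
}

# candidate-scan placement of the healthy VOI sphere
place_voi <- function(spec, center, object_meta, dist2) {
  d <- spec$shape; sp <- spec$spacing
  margin <- spec$brain_radius_mm - spec$voi_radius_mm - max(sp)
  cand <- which(dist2 <= margin^2, arr.ind = TRUE)
  stride <- cand[, 1] %% 2L == 0L & cand[, 2] %% 2L == 0L & cand[, 3] %% 2L == 0L
  cand <- cand[stride, , drop = FALSE]
  if (nrow(cand) == 0L) abort("Brain too small to host the healthy VOI.")
  coords <- sweep(cand - 1, 2, sp, `*`)
  clearance <- rep(Inf, nrow(cand))
  for (obj in object_meta) {
    dd <- sqrt((coords[, 1] - obj$center_mm[1])^2 +
               (coords[, 2] - obj$center_mm[2])^2 +
               (coords[, 3] - obj$center_mm[3])^2) - obj$bound_mm
    clearance <- pmin(clearance, dd)
  }
  best <- which.max(clearance)
  if (clearance[best] <= spec$voi_radius_mm + max(sp)) {
    abort("No location clears every component for the healthy VOI.")
  }
  coords[best, ]
}

phantom_truth <- function(spec, gt_ids, det_ids, gt_cs, det_cs, center,
                          object_meta, mod_names) {
  vox <- prod(spec$spacing)
  rows <- purrr::imap_dfr(object_meta, function(obj, k) {
    les <- obj$row
    is_fp <- obj$type == "false_positive"
    own_ids <- if (is_fp) det_ids else gt_ids
    idx <- which(own_ids == k, arr.ind = TRUE)
    centroid <- colMeans(sweep(idx - 1, 2, spec$spacing, `*`))
    planned_dsc <- if (is_fp || isTRUE(les$drop)) 0
                   else if (is.na(les$dsc_target)) 1 else les$dsc_target
    row <- tibble(
      object = k,
      type = obj$type,
      side = if (is_fp) "detection" else "gt",
      target_volume_mm3 = les$volume_mm3,
      n_voxels = nrow(idx),
      volume_mm3 = nrow(idx) * vox,
      target_offset_x_mm = les$offset_x_mm,
      target_offset_y_mm = les$offset_y_mm,
      target_offset_z_mm = les$offset_z_mm,
      offset_x_mm = centroid[1] - center[1],
      offset_y_mm = centroid[2] - center[2],
      offset_z_mm = centroid[3] - center[3],
      dropped = if (is_fp) FALSE else isTRUE(les$drop),
      planned_dsc = planned_dsc,
      planned_category = categorize_dsc(planned_dsc),
      gt_label = if (is_fp) NA_integer_ else
        gt_cs$labels[idx[1, 1], idx[1, 2], idx[1, 3]],
      det_label = {
        dl <- det_ids == k & det_ids > 0L
        if (any(dl)) {
          first <- which(dl)[1]
          det_cs$labels[first]
        } else NA_integer_
      }
    )
    for (nm in mod_names) {
      row[[paste0("planned_id_", nm)]] <- les[[paste0("id_", nm)]]
    }
    row
  })
  rows
}
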