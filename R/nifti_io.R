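#' Read and write volumes as NIfTI
#'
#' All volumes are exchanged as NIfTI-1 files (`.nii` / `.nii.gz`).  Voxel
#' spacing is taken from the header; files carrying an orientation (qform or
#' sform) are reoriented on load so the stored axes run left / anterior /
#' superior ("LAS"), the fixed convention under which signed positional
#' offsets are reported.  Files without any orientation information are
#' assumed to already follow that convention.
#'
#' @param path Path to a NIfTI file containing a 3D volume.
#' @param reorient Reorient to the LAS axis convention when the header allows
#'   it (default `TRUE`).
#' @return `read_grid()` returns a [voxel_grid()]; `read_mask()` a
#'   [binary_mask()].
#' @export
read_grid <- function(path, reorient = TRUE) {
  if (!file.exists(path)) abort(sprintf("NIfTI file not found: %s", path))
  img <- RNifti::readNifti(path)
  if (reorient && !identical(RNifti::orientation(img), "LAS")) {
    hdr <- RNifti::niftiHeader(img)
    if (hdr$qform_code > 0 || hdr$sform_code > 0) {
      RNifti::orientation(img) <- "LAS"
    }
  }
  d <- dim(img)
  if (length(d) == 4L && d[4] == 1L) {
    img <- array(as.array(img), d[1:3])
    d <- d[1:3]
  } else if (length(d) != 3L) {
    abort(sprintf("%s: expected a 3D volume, got %d dimensions.", path, length(d)))
  }
  sp <- RNifti::pixdim(img)[1:3]
  if (any(!is.finite(sp)) || any(sp <= 0)) {
    abort(sprintf("%s: header voxel spacing must be strictly positive.", path))
  }
  voxel_grid(array(as.numeric(img), d), sp)
}

#' @rdname read_grid
#' @param threshold Values strictly greater than this become foreground.  The
#'   default 0.5 tolerates interpolation residue in nominally binary masks.
#' @export
read_mask <- function(path, threshold = 0.5, reorient = TRUE) {
  g <- read_grid(path, reorient = reorient)
  binary_mask(array(g$values > threshold, dim(g$values)), g$spacing)
}

#' @rdname read_grid
#' @param grid A `voxel_grid` or `binary_mask` to serialise.
#' @export
write_grid <- function(grid, path) {
  stopifnot(inherits(grid, "voxel_grid"))
  v <- grid$values
  if (is.logical(v)) v <- array(as.integer(v), dim(v))
  img <- RNifti::asNifti(v)
  RNifti::pixdim(img) <- grid$spacing
  # LAS affine: RNifti expresses xforms in RAS terms, so a leftward first axis
  # carries a negative x column.
  m <- diag(c(-grid$spacing[1], grid$spacing[2], grid$spacing[3], 1))
  RNifti::sform(img) <- structure(m, code = 2L)
  RNifti::qform(img) <- structure(m, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a cohort manifest
#'
#' A manifest is a delimited text file (comma or tab separated, header row)
#' with one row per case and columns `case_id`, `gt`, `detection`, `brain`,
#' `voi`, plus one column per modality (any further columns are treated as
#' modality paths).  Relative paths are resolved against the manifest's
#' directory.
#'
#' @param path Manifest file path.
#' @return A tibble with one row per case and absolute file paths.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) abort(sprintf("Manifest not found: %s", path))
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  man <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  required <- c("case_id", "gt", "detection", "brain", "voi")
  missing <- setdiff(required, names(man))
  if (length(missing)) {
    abort(sprintf("Manifest lacks required columns: %s", paste(missing, collapse = ", ")))
  }
  root <- dirname(normalizePath(path))
  path_cols <- setdiff(names(man), "case_id")
  for (col in path_cols) {
    man[[col]] <- ifelse(grepl("^/", man[[col]]), man[[col]],
                         file.path(root, man[[col]]))
  }
  man
}

#' @rdname read_manifest
#' @param row One manifest row (a single-row data frame).
#' @param reorient Passed on to [read_grid()].
#' @return `read_case()` returns a [case_bundle()].
#' @export
read_case <- function(row, reorient = TRUE) {
  stopifnot(is.data.frame(row), nrow(row) == 1L)
  mod_cols <- setdiff(names(row), c("case_id", "gt", "detection", "brain", "voi"))
  modalities <- lapply(setNames(as.list(row[mod_cols]), mod_cols), function(p) {
    read_grid(p, reorient = reorient)
  })
  case_bundle(
    gt = read_mask(row$gt, reorient = reorient),
    detection = read_mask(row$detection, reorient = reorient),
    brain = read_mask(row$brain, reorient = reorient),
    healthy_voi = read_mask(row$voi, reorient = reorient),
    modalities = modalities,
    case_id = as.character(row$case_id)
  )
}
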