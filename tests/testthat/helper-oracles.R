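# Independent brute-force oracles and small fixture builders.
# The labelling oracle is a plain queue-based flood fill over explicit voxel
# coordinates, sharing no code with the package's scan-order BFS kernel.

oracle_label <- function(arr, connectivity = 26) {
  d <- dim(arr)
  fg <- which(arr)
  fg_coords <- arrayInd(fg, d)
  labels <- array(0L, d)
  lab <- 0L
  for (s in seq_along(fg)) {
    if (labels[fg[s]] != 0L) next
    lab <- lab + 1L
    queue <- s
    labels[fg[s]] <- lab
    while (length(queue)) {
      v <- queue[1]
      queue <- queue[-1]
      dd <- abs(fg_coords - matrix(fg_coords[v, ], nrow(fg_coords), 3, byrow = TRUE))
      adj <- if (connectivity == 6) {
        rowSums(dd) == 1L
      } else {
        apply(dd, 1, max) == 1L
      }
      new <- which(adj & labels[fg] == 0L)
      labels[fg[new]] <- lab
      queue <- c(queue, new)
    }
  }
  labels
}

# exhaustive pairwise intersection counts between two labelled arrays
oracle_overlap <- function(gt_labels, det_labels) {
  edges <- list()
  for (g in setdiff(unique(as.vector(gt_labels)), 0L)) {
    for (dd in setdiff(unique(as.vector(det_labels)), 0L)) {
      shared <- sum(gt_labels == g & det_labels == dd)
      if (shared > 0) {
        edges[[length(edges) + 1]] <- data.frame(
          gt_label = g, det_label = dd, shared_voxels = shared)
      }
    }
  }
  if (!length(edges)) {
    return(data.frame(gt_label = integer(), det_label = integer(),
                      shared_voxels = integer()))
  }
  out <- do.call(rbind, edges)
  out[order(out$gt_label, out$det_label), , drop = FALSE]
}

mask_from_indices <- function(dim, idx, spacing = c(1, 1, 1)) {
  a <- array(FALSE, dim)
  a[idx] <- TRUE
  binary_mask(a, spacing)
}

random_mask <- function(dim, p = 0.3, spacing = c(1, 1, 1)) {
  binary_mask(array(runif(prod(dim)) < p, dim), spacing)
}

# a small, fast phantom template used by most tests
small_template <- function(...) {
  phantom_template(
    shape = c(48, 48, 48), spacing = c(3, 3, 3), brain_radius_mm = 60,
    voi_radius_mm = 9, n_lesions_range = c(2, 4),
    volume_range_mm3 = c(1500, 2e4), fp_volume_range_mm3 = c(150, 500),
    ...
  )
}

small_phantom <- function(seed = 7, dsc_target = 0.7, drop = FALSE,
                          noise_sd = 0, n_extra = 0) {
  les <- lesion_spec(8000, c(15, 10, -6), id = c(flair = 40, t2 = 25, t1ce = -10),
                     dsc_target = dsc_target, drop = drop)
  if (n_extra >= 1) {
    les <- dplyr::bind_rows(
      les,
      lesion_spec(3000, c(-25, -15, 12), id = c(flair = 55, t2 = 60, t1ce = 5),
                  dsc_target = if (is.na(dsc_target)) NA_real_ else 0.3)
    )
  }
  generate_bundle(phantom_spec(
    les, shape = c(48, 48, 48), spacing = c(3, 3, 3), brain_radius_mm = 60,
    voi_radius_mm = 9, noise_sd = noise_sd, seed = seed
  ))
}
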