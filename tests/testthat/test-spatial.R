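test_that("brain centre is the voxel centroid in physical coordinates", {
  # two voxels at 0-based indices 0 and 10 on x, spacing 2 mm -> centre 10 mm
  m <- mask_from_indices(c(12, 3, 3), rbind(c(1, 1, 1), c(11, 1, 1)),
                         spacing = c(2, 1, 1))
  expect_equal(unname(brain_center(m)["x"]), 10)

  single <- mask_from_indices(c(5, 5, 5), cbind(3, 4, 2), spacing = c(1, 2, 3))
  expect_equal(unname(brain_center(single)), c(2, 6, 3))

  # a symmetric blob centred on voxel c has centre at c's coordinate
  a <- array(FALSE, c(7, 7, 7))
  for (i in 1:7) for (j in 1:7) for (k in 1:7) {
    if ((i - 4)^2 + (j - 4)^2 + (k - 4)^2 <= 4) a[i, j, k] <- TRUE
  }
  expect_equal(unname(brain_center(binary_mask(a))), c(3, 3, 3))
  expect_equal(unname(brain_center(binary_mask(a), method = "bbox")), c(3, 3, 3))

  expect_error(brain_center(binary_mask(array(FALSE, c(3, 3, 3)))), "empty")
})

test_that("component offsets are centroid minus centre with oracle agreement", {
  pc <- small_phantom(n_extra = 1)
  b <- pc$bundle
  cs <- label_components(b$gt)
  center <- brain_center(b$brain)
  off <- component_offsets(cs, center)
  # coordinate-averaging oracle per component
  for (lab in off$label) {
    idx <- which(cs$labels == lab, arr.ind = TRUE)
    cent <- colMeans(sweep(idx - 1, 2, cs$spacing, `*`))
    expect_equal(off$offset_x_mm[off$label == lab], cent[1] - center["x"],
                 ignore_attr = TRUE)
    expect_equal(off$offset_y_mm[off$label == lab], cent[2] - center["y"],
                 ignore_attr = TRUE)
    expect_equal(off$offset_z_mm[off$label == lab], cent[3] - center["z"],
                 ignore_attr = TRUE)
  }
  # component centred at the brain centre has offset (0, 0, 0)
  d <- c(9, 9, 9)
  brain <- binary_mask(array(TRUE, d))
  comp <- mask_from_indices(d, cbind(4:6, 5, 5))
  o <- component_offsets(label_components(comp), brain_center(brain))
  expect_equal(unname(unlist(o[1, c("offset_x_mm", "offset_y_mm", "offset_z_mm")])),
               c(0, 0, 0))
})

test_that("translating all masks leaves offsets unchanged", {
  pc <- small_phantom(n_extra = 1)
  b <- pc$bundle
  shift_mask <- function(m, by = c(2, 1, 3)) {
    a <- array(FALSE, dim(m$values))
    d <- dim(a)
    a[(1 + by[1]):d[1], (1 + by[2]):d[2], (1 + by[3]):d[3]] <-
      m$values[1:(d[1] - by[1]), 1:(d[2] - by[2]), 1:(d[3] - by[3])]
    binary_mask(a, m$spacing)
  }
  off_cols <- c("offset_x_mm", "offset_y_mm", "offset_z_mm")
  off1 <- component_offsets(label_components(b$gt), brain_center(b$brain))
  off2 <- component_offsets(label_components(shift_mask(b$gt)),
                            brain_center(shift_mask(b$brain)))
  expect_equal(off1[order(off1$offset_x_mm), off_cols],
               off2[order(off2$offset_x_mm), off_cols],
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("half-brain differences follow the signed-count formula", {
  rec <- tibble::tibble(
    category = "Found",
    offset_x_mm = c(rep(1, 6), rep(-1, 4)),
    offset_y_mm = c(rep(2, 5), rep(-2, 5)),
    offset_z_mm = c(rep(3, 10))
  )
  h <- half_brain_differences(rec)
  expect_equal(h$pct_difference[h$axis == "x"], 100 * (6 - 4) / 10)  # +20
  expect_equal(h$pct_difference[h$axis == "y"], 0)
  expect_equal(h$pct_difference[h$axis == "z"], 100)

  # zero offsets excluded from both halves
  rec0 <- tibble::tibble(category = "Missed",
                         offset_x_mm = c(0, 0, 5),
                         offset_y_mm = c(0, 0, 0),
                         offset_z_mm = c(-1, 1, 0))
  h0 <- half_brain_differences(rec0)
  expect_equal(h0$n_positive[h0$axis == "x"], 1)
  expect_equal(h0$n_negative[h0$axis == "x"], 0)
  expect_equal(h0$pct_difference[h0$axis == "x"], 100)
  expect_true(is.na(h0$pct_difference[h0$axis == "y"]))   # all on the plane
  expect_true(abs(h0$pct_difference[h0$axis == "z"]) <= 100)

  # sign flips when the axis orientation is flipped
  rec_flip <- dplyr::mutate(rec, offset_x_mm = -offset_x_mm)
  hf <- half_brain_differences(rec_flip)
  expect_equal(hf$pct_difference[hf$axis == "x"],
               -h$pct_difference[h$axis == "x"])
})

test_that("axis histograms bin on centres with complete totals", {
  rec <- tibble::tibble(category = "Found",
                        offset_x_mm = 20, offset_y_mm = 0, offset_z_mm = -14.9)
  h <- axis_histograms(rec, bin_width_mm = 10)
  expect_equal(h$bin_center_mm[h$axis == "x"], 20)   # bin [15, 25)
  expect_equal(h$bin_center_mm[h$axis == "y"], 0)
  expect_equal(h$bin_center_mm[h$axis == "z"], -10)  # [-15, -5)

  pc <- small_phantom(n_extra = 1)
  ev <- evaluate_case(pc$bundle)
  hh <- axis_histograms(ev$components, 10)
  totals <- dplyr::count(ev$components, side, category, name = "expected")
  sums <- hh |>
    dplyr::filter(axis == "x") |>
    dplyr::group_by(side, category) |>
    dplyr::summarise(n = sum(n), .groups = "drop")
  joined <- dplyr::left_join(totals, sums, by = c("side", "category"))
  expect_equal(joined$n, joined$expected)

  # symmetric records make a mirror-symmetric histogram
  sym <- tibble::tibble(category = "Found",
                        offset_x_mm = c(-22, 22), offset_y_mm = c(-7, 7),
                        offset_z_mm = c(-31, 31))
  hs <- axis_histograms(sym, 10)
  for (ax in c("x", "y", "z")) {
    sub <- hs[hs$axis == ax, ]
    expect_setequal(sub$bin_center_mm, c(-sub$bin_center_mm))
  }
})

test_that("per-bin category counts sum to the all-component histogram", {
  pc <- small_phantom(n_extra = 1)
  ev <- evaluate_case(pc$bundle)
  by_cat <- axis_histograms(ev$components, 10)
  all_comp <- dplyr::mutate(ev$components, category = "all")
  overall <- axis_histograms(all_comp, 10)
  merged <- by_cat |>
    dplyr::group_by(axis, side, bin_center_mm) |>
    dplyr::summarise(n = sum(n), .groups = "drop") |>
    dplyr::arrange(axis, side, bin_center_mm)
  overall <- dplyr::arrange(
    overall[, c("axis", "side", "bin_center_mm", "n")],
    axis, side, bin_center_mm)
  expect_equal(as.data.frame(merged), as.data.frame(overall))
})
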