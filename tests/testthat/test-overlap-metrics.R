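test_that("confusion counts are exact voxelwise set counts", {
  d <- c(4, 4, 4)
  ten <- mask_from_indices(d, arrayInd(1:10, d))
  expect_equal(as.list(confusion_counts(ten, ten)), list(tp = 10, fp = 0, fn = 0))

  gt3 <- mask_from_indices(d, cbind(1:3, 1, 1))
  det5 <- mask_from_indices(d, cbind(c(1:4, 1), c(3, 3, 3, 3, 4), 3))
  expect_equal(as.list(confusion_counts(gt3, det5)), list(tp = 0, fp = 5, fn = 3))

  gt4 <- mask_from_indices(d, cbind(1:4, 1, 1))
  det6 <- mask_from_indices(d, cbind(c(2, 3, 4, 1, 2, 3), c(1, 1, 1, 2, 2, 2), 1))
  expect_equal(as.list(confusion_counts(gt4, det6)), list(tp = 3, fp = 3, fn = 1))

  expect_error(confusion_counts(gt4, mask_from_indices(c(3, 3, 3), cbind(1, 1, 1))),
               "shape")
})

test_that("case metrics follow the Dice / sensitivity / precision formulas", {
  d <- c(4, 4, 4)
  gt <- mask_from_indices(d, cbind(1:4, 1, 1))
  det <- mask_from_indices(d, cbind(c(2, 3, 4, 1, 2, 3), c(1, 1, 1, 2, 2, 2), 1))
  cm <- case_metrics(confusion_counts(gt, det), gt, det)
  expect_equal(cm$dsc, 0.6)
  expect_equal(cm$sensitivity, 0.75)
  expect_equal(cm$precision, 0.5)

  same <- case_metrics(confusion_counts(gt, gt), gt, gt)
  expect_equal(unlist(same[, c("dsc", "sensitivity", "precision")]),
               c(dsc = 1, sensitivity = 1, precision = 1))

  # zero denominators are undefined, not 0 or 1
  empty <- binary_mask(array(FALSE, d))
  cm0 <- case_metrics(confusion_counts(empty, empty), empty, empty)
  expect_true(all(is.na(unlist(cm0[, c("dsc", "sensitivity", "precision")]))))
})

test_that("Dice is symmetric and harmonically ties precision to sensitivity", {
  withr::with_seed(21, {
    for (i in 1:20) {
      a <- random_mask(c(5, 5, 5), p = runif(1, 0.2, 0.6))
      b <- random_mask(c(5, 5, 5), p = runif(1, 0.2, 0.6))
      mab <- case_metrics(confusion_counts(a, b), a, b)
      mba <- case_metrics(confusion_counts(b, a), b, a)
      expect_equal(mab$dsc, mba$dsc)
      # sensitivity(gt, det) = precision(det, gt)
      expect_equal(mab$sensitivity, mba$precision)
      if (!is.na(mab$precision) && !is.na(mab$sensitivity) &&
          (mab$precision + mab$sensitivity) > 0) {
        expect_equal(mab$dsc, 2 * mab$precision * mab$sensitivity /
                       (mab$precision + mab$sensitivity))
      }
    }
  })
})

test_that("adding pure false positives never increases Dice or precision", {
  withr::with_seed(22, {
    for (i in 1:10) {
      gt <- random_mask(c(5, 5, 5), p = 0.3)
      det <- random_mask(c(5, 5, 5), p = 0.3)
      m0 <- case_metrics(confusion_counts(gt, det), gt, det)
      extra <- det$values | (!gt$values & array(runif(125) < 0.2, dim(det$values)))
      det2 <- binary_mask(extra, det$spacing)
      m1 <- case_metrics(confusion_counts(gt, det2), gt, det2)
      if (!is.na(m0$dsc) && !is.na(m1$dsc)) expect_lte(m1$dsc, m0$dsc)
      if (!is.na(m0$precision) && !is.na(m1$precision)) {
        expect_lte(m1$precision, m0$precision)
      }
    }
  })
})

test_that("nested detections have precision 1 and the nested-Dice form", {
  gt <- mask_from_indices(c(4, 4, 4), cbind(rep(1:4, 2), rep(1:2, each = 4), 1))
  det <- mask_from_indices(c(4, 4, 4), cbind(1:3, 1, 1))
  m <- case_metrics(confusion_counts(gt, det), gt, det)
  expect_equal(m$precision, 1)
  expect_equal(m$dsc, 2 * 3 / (3 + 8))
})

test_that("cohort statistics summarise defined values with interpolated quantiles", {
  single <- tibble::tibble(dsc = 0.8, sensitivity = NA_real_, precision = 0.5)
  s <- cohort_stats(single)
  row <- s[s$metric == "dsc", ]
  expect_equal(row$mean, 0.8)
  expect_equal(row$median, 0.8)
  expect_equal(row$min, 0.8)
  expect_equal(row$max, 0.8)
  expect_equal(row$sd, 0)
  expect_equal(s$n[s$metric == "sensitivity"], 0L)
  expect_equal(s$n_undefined[s$metric == "sensitivity"], 1L)

  four <- tibble::tibble(dsc = c(0.2, 0.4, 0.6, 0.8),
                         sensitivity = c(0, 1, NA, NA),
                         precision = rep(0.5, 4))
  s4 <- cohort_stats(four)
  expect_equal(s4$mean[s4$metric == "dsc"], 0.5)
  expect_equal(s4$median[s4$metric == "dsc"], 0.5)
  # {0, 1} has 25th percentile 0.25 under linear interpolation
  expect_equal(s4$q25[s4$metric == "sensitivity"], 0.25)
  # quantile ordering invariant
  srow <- s4[s4$metric == "dsc", ]
  expect_true(srow$min <= srow$q25 && srow$q25 <= srow$median &&
              srow$median <= srow$q75 && srow$q75 <= srow$max)
})

test_that("volume strata use [0,10), [10,100], (100,Inf) in cm^3", {
  expect_equal(volume_group(5), "<10")
  expect_equal(volume_group(10), "10-100")     # lower edge inclusive
  expect_equal(volume_group(100), "10-100")
  expect_equal(volume_group(100.1), ">100")

  metrics <- tibble::tibble(
    dsc = c(0.5, 0.6, 0.7), sensitivity = c(0.5, 0.6, 0.7),
    precision = c(0.5, 0.6, 0.7),
    gt_volume_cm3 = c(1, 50, 500),
    volume_group = volume_group(c(1, 50, 500))
  )
  g <- grouped_metrics(metrics)
  dsc_rows <- g[g$metric == "dsc", ]
  expect_setequal(dsc_rows$volume_group, c("<10", "10-100", ">100"))
  expect_true(all(dsc_rows$n == 1))
})

test_that("pooled stratified metrics recompute from summed voxel counts", {
  metrics <- tibble::tibble(
    volume_group = c("<10", "<10"),
    tp = c(10, 30), fp = c(5, 5), fn = c(5, 15)
  )
  g <- grouped_metrics(metrics, pooled = TRUE)
  row <- g[g$volume_group == "<10", ]
  expect_equal(row$dsc, 2 * 40 / (2 * 40 + 10 + 20))
  expect_equal(row$sensitivity, 40 / 60)
  expect_equal(row$precision, 40 / 50)
})

test_that("volume correlation matches the product-moment formula", {
  expect_equal(volume_correlation(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(volume_correlation(c(1, 2, 3), c(-1, -2, -3)), -1)
  gt <- c(1, 2, 3); det <- c(2, 4, 7)
  manual <- sum((gt - mean(gt)) * (det - mean(det))) /
    sqrt(sum((gt - mean(gt))^2) * sum((det - mean(det))^2))
  expect_equal(volume_correlation(gt, det), manual)
  expect_true(is.na(volume_correlation(c(1, 1), c(1, 2))))
  expect_true(is.na(volume_correlation(1, 1)))
})
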