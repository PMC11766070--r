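test_that("simple component topologies label as expected", {
  d <- c(4, 4, 4)
  one <- mask_from_indices(d, cbind(2, 2, 2))
  cs <- label_components(one)
  expect_equal(cs$n_components, 1L)
  expect_equal(cs$components$n_voxels, 1L)

  empty <- binary_mask(array(FALSE, d))
  expect_equal(label_components(empty)$n_components, 0L)

  # two voxels sharing only a cube corner: one component under 26, two under 6
  corner <- mask_from_indices(d, rbind(c(1, 1, 1), c(2, 2, 2)))
  expect_equal(label_components(corner, 26)$n_components, 1L)
  expect_equal(label_components(corner, 6)$n_components, 2L)

  expect_error(label_components(one, connectivity = 18), "6 or 26")
})

test_that("labels are deterministic in column-major scan order", {
  d <- c(3, 3, 3)
  m <- mask_from_indices(d, rbind(c(3, 3, 3), c(1, 1, 1)))
  cs <- label_components(m, 6)
  expect_equal(cs$labels[1, 1, 1], 1L)   # first voxel in scan order gets label 1
  expect_equal(cs$labels[3, 3, 3], 2L)
})

test_that("labelling agrees with a brute-force flood-fill oracle", {
  withr::with_seed(31, {
    for (i in 1:40) {
      m <- random_mask(c(4, 4, 4), p = runif(1, 0.2, 0.7))
      for (conn in c(6, 26)) {
        expect_identical(label_components(m, conn)$labels,
                         oracle_label(m$values, conn))
      }
    }
  })
})

test_that("overlap graph edges carry exact shared-voxel counts", {
  d <- c(6, 6, 6)
  gt <- mask_from_indices(d, rbind(c(1, 1, 1), c(6, 6, 6)))
  det <- mask_from_indices(d, rbind(c(3, 3, 3)))
  g <- overlap_graph(label_components(gt), label_components(det))
  expect_equal(nrow(g), 0L)

  # one detection blob covering two separate GT components -> two edges
  gt2 <- mask_from_indices(d, rbind(c(1, 1, 1), c(5, 1, 1)))
  det2 <- mask_from_indices(d, cbind(1:5, 1, 1))
  g2 <- overlap_graph(label_components(gt2), label_components(det2))
  expect_equal(nrow(g2), 2L)
  expect_equal(g2$det_label, c(1L, 1L))
  expect_equal(g2$shared_voxels, c(1L, 1L))

  withr::with_seed(32, {
    for (i in 1:15) {
      a <- random_mask(c(5, 5, 5), p = 0.4)
      b <- random_mask(c(5, 5, 5), p = 0.4)
      acs <- label_components(a); bcs <- label_components(b)
      got <- as.data.frame(overlap_graph(acs, bcs))
      want <- oracle_overlap(acs$labels, bcs$labels)
      rownames(got) <- rownames(want) <- NULL
      expect_equal(got, want)
      # edge weights sum to the whole-volume true-positive count
      expect_equal(sum(got$shared_voxels), confusion_counts(a, b)$tp)
    }
  })
})

test_that("per-component Dice uses the union of overlapping counterparts", {
  d <- c(6, 6, 6)
  # gt component: 8 voxels in a 2x2x2 block
  gt <- mask_from_indices(d, as.matrix(expand.grid(2:3, 2:3, 2:3)))
  # overlapping detection blob of 12 voxels, 6 of them shared; plus a remote
  # blob that overlaps nothing and must not distort the score
  det_idx <- rbind(
    as.matrix(expand.grid(2:3, 2:3, 1:2)),    # 8 voxels, 4 shared (z = 2)
    as.matrix(expand.grid(2:3, 2, 3:4)),      # 4 voxels, 2 shared (z = 3)
    as.matrix(expand.grid(5:6, 5:6, 6))       # remote blob, no overlap
  )
  det <- mask_from_indices(d, det_idx)
  gt_cs <- label_components(gt); det_cs <- label_components(det)
  graph <- overlap_graph(gt_cs, det_cs)
  rec <- component_dsc(gt_cs, graph, det_cs, side = "gt")
  expect_equal(rec$shared_voxels, 6L)
  expect_equal(rec$counterpart_union_voxels, 12L)
  expect_equal(rec$dsc, 0.6)

  # no overlapping counterpart scores 0; identical lone components score 1
  lone <- mask_from_indices(d, cbind(1:4, 6, 6))
  lone_cs <- label_components(lone)
  rec0 <- component_dsc(lone_cs, overlap_graph(lone_cs, det_cs), det_cs, "gt")
  expect_equal(rec0$dsc, 0)
  rec1 <- component_dsc(lone_cs, overlap_graph(lone_cs, lone_cs), lone_cs, "gt")
  expect_equal(rec1$dsc, 1)
})

test_that("category boundaries are inclusive at 0.5 and 0.05", {
  expect_equal(categorize_dsc(c(0.5, 0.05, 0.049, 0.51, 0.499, 0)),
               c("Found", "Partial", "Missed", "Found", "Partial", "Missed"))

  # mask-level check at exactly DSC 0.5: 2 gt voxels, 2 det voxels, 1 shared
  d <- c(4, 4, 4)
  gt <- mask_from_indices(d, rbind(c(1, 1, 1), c(2, 1, 1)))
  det <- mask_from_indices(d, rbind(c(2, 1, 1), c(3, 1, 1)))
  rec <- classify_components(label_components(gt), label_components(det))
  expect_equal(unique(rec$dsc), 0.5)
  expect_equal(unique(rec$category), "Found")
})

test_that("classification is invariant under spatial permutation of components", {
  pc <- small_phantom(n_extra = 1)
  b <- pc$bundle
  flip <- function(m) binary_mask(m$values[dim(m$values)[1]:1, , ], m$spacing)
  rec1 <- classify_components(label_components(b$gt),
                              label_components(b$detection))
  rec2 <- classify_components(label_components(flip(b$gt)),
                              label_components(flip(b$detection)))
  sorted <- function(r) {
    r <- r[order(r$side, r$n_voxels, r$dsc), c("side", "n_voxels", "dsc", "category")]
    rownames(r) <- NULL
    r
  }
  expect_equal(sorted(as.data.frame(rec1)), sorted(as.data.frame(rec2)))
})

test_that("category tables partition components and volume", {
  records <- tibble::tibble(
    side = "gt",
    volume_mm3 = c(100, 50, 30, 20, 10),
    dsc = c(0.9, 0.6, 0.3, 0.02, 0),
    category = categorize_dsc(c(0.9, 0.6, 0.3, 0.02, 0))
  )
  tab <- category_table(records)
  body <- tab[tab$category != "Total", ]
  expect_equal(sum(body$n), 5)
  expect_equal(sum(body$pct_components), 100)
  expect_equal(sum(body$pct_volume), 100)
  expect_equal(body$pct_volume[body$category == "Found"], 100 * 150 / 210)

  all_found <- category_table(dplyr::mutate(records, dsc = 0.9, category = "Found"))
  expect_equal(all_found$pct_components[all_found$category != "Total"],
               c(100, 0, 0))
})

test_that("threshold sweep counts are monotone and match direct filtering", {
  pc <- small_phantom(n_extra = 1)
  ev <- evaluate_case(pc$bundle)
  thr <- seq(0.05, 0.95, by = 0.05)
  sw <- threshold_sweep(ev$components, thr)
  for (s in unique(sw$side)) {
    sub <- sw[sw$side == s, ]
    expect_true(all(diff(sub$n_components) <= 0))
    expect_true(all(diff(sub$volume_mm3) <= 1e-9))
    # filter-and-count oracle
    recs <- ev$components[ev$components$side == s, ]
    for (t in c(0.05, 0.5, 0.95)) {
      expect_equal(sub$n_components[abs(sub$threshold - t) < 1e-9],
                   sum(recs$dsc >= t))
      expect_equal(sub$volume_mm3[abs(sub$threshold - t) < 1e-9],
                   sum(recs$volume_mm3[recs$dsc >= t]))
    }
  }
  # boundary thresholds
  sw1 <- threshold_sweep(ev$components, c(1e-9, 1))
  gt_rec <- ev$components[ev$components$side == "gt", ]
  expect_equal(sw1$n_components[sw1$threshold == 1e-9 & sw1$side == "gt"],
               sum(gt_rec$dsc > 0))
  expect_equal(sw1$n_components[sw1$threshold == 1 & sw1$side == "gt"],
               sum(gt_rec$dsc >= 1))
  expect_error(threshold_sweep(ev$components, c(0.5, 0.2)), "increasing")
})

test_that("GT components without edges contribute no true positives", {
  pc <- small_phantom(drop = TRUE)   # the only lesion is dropped
  b <- pc$bundle
  gt_cs <- label_components(b$gt)
  det_cs <- label_components(b$detection)
  graph <- overlap_graph(gt_cs, det_cs)
  expect_equal(nrow(graph), 0L)
  expect_equal(confusion_counts(b$gt, b$detection)$tp, 0L)
})
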