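test_that("dice and jaccard match worked arithmetic and handle degenerate masks", {
  a <- array(0, c(4, 5, 5)); a[1:2, , ] <- 1          # |A| = 50
  expect_identical(dice(a, a), 1)
  expect_identical(jaccard(a, a), 1)

  # |A| = |B| = 100, |A intersect B| = 50
  a <- array(0, c(4, 10, 10)); a[1, , ] <- 1
  b <- array(0, c(4, 10, 10)); b[1, , 1:5] <- 1; b[2, , 1:5] <- 1
  expect_equal(sum(a), 100); expect_equal(sum(b), 100)
  expect_equal(sum(a * b), 50)
  expect_identical(dice(a, b), 0.5)
  expect_identical(jaccard(a, b), 50 / 150)

  z <- array(0, c(3, 3, 3))
  expect_identical(dice(z, z), 1)
  expect_identical(jaccard(z, z), 1)
  expect_identical(dice(z, a[1:3, 1:3, 1:3]), 0)
  expect_error(dice(a, array(0, c(2, 2, 2))), "grid")
})

test_that("overlap metrics equal naive-loop oracles on random masks", {
  set.seed(101)
  for (rep in 1:25) {
    d <- sample(3:8, 3, replace = TRUE)
    a <- rand_mask(d, runif(1, 0.1, 0.6))
    b <- rand_mask(d, runif(1, 0.1, 0.6))
    expect_identical(dice(a, b), oracle_dice(a, b))
    expect_identical(jaccard(a, b), oracle_jaccard(a, b))
    # algebraic identity J = D / (2 - D)
    expect_equal(jaccard(a, b), dice(a, b) / (2 - dice(a, b)), tolerance = 1e-12)
  }
})

test_that("surface extraction finds exactly the voxels with a background face-neighbor", {
  m <- array(0, c(5, 5, 5)); m[3, 3, 3] <- 1
  expect_equal(surface_voxels(m), matrix(c(3L, 3L, 3L), 1, 3), ignore_attr = TRUE)

  cube <- array(0, c(5, 5, 5)); cube[2:4, 2:4, 2:4] <- 1
  expect_equal(nrow(surface_voxels(cube)), 26)  # all but the center voxel

  expect_equal(nrow(surface_voxels(array(0, c(3, 3, 3)))), 0)

  set.seed(7)
  for (rep in 1:10) {
    blob <- rand_mask(c(6, 6, 6), 0.4)
    got <- surface_voxels(blob)
    want <- oracle_surface(blob)
    expect_equal(got[order(got[, 1], got[, 2], got[, 3]), , drop = FALSE],
                 want[order(want[, 1], want[, 2], want[, 3]), , drop = FALSE],
                 ignore_attr = TRUE)
  }
})

test_that("surface distances match all-pairs oracles under anisotropic spacing", {
  a <- array(0, c(3, 5, 5)); a[2, 3, 1] <- 1
  b <- array(0, c(3, 5, 5)); b[2, 3, 4] <- 1
  expect_equal(hd95(a, b, c(5, 1, 1)), 3)           # 3 columns at 1 mm
  expect_equal(ahd(a, b, c(5, 1, 1)), 3)
  b2 <- array(0, c(3, 5, 5)); b2[2, 3, 3] <- 1
  expect_equal(ahd(a, b2, c(5, 2, 2)), 4)           # 2 columns at 2 mm
  expect_equal(hd95(a, a, c(5, 0.8, 0.8)), 0)
  expect_equal(ahd(a, a, c(5, 0.8, 0.8)), 0)

  spacing <- c(4.5, 0.7, 0.7)
  for (seed in 1:8) {
    a <- rand_blob(c(6, 9, 9), seed)
    b <- rand_blob(c(6, 9, 9), seed + 100)
    expect_equal(hd95(a, b, spacing), oracle_hd95(a, b, spacing), tolerance = 1e-9)
    expect_equal(ahd(a, b, spacing), oracle_ahd(a, b, spacing), tolerance = 1e-9)
    # symmetry and the percentile/maximum ordering
    expect_equal(hd95(a, b, spacing), hd95(b, a, spacing))
    expect_equal(ahd(a, b, spacing), ahd(b, a, spacing))
    expect_lte(hd95(a, b, spacing), hd95(a, b, spacing, percentile = 1))
  }
})

test_that("surface distances are undefined for empty masks", {
  a <- rand_blob(c(4, 6, 6), 1)
  z <- array(0, c(4, 6, 6))
  expect_true(is.na(hd95(a, z, c(5, 1, 1))))
  expect_true(is.na(ahd(z, a, c(5, 1, 1))))
})

test_that("metrics are invariant to simultaneous mirroring of both masks", {
  spacing <- c(5, 0.9, 0.9)
  a <- rand_blob(c(5, 8, 8), 11)
  b <- rand_blob(c(5, 8, 8), 12)
  am <- a[, , 8:1]; bm <- b[, , 8:1]
  expect_identical(dice(a, b), dice(am, bm))
  expect_identical(jaccard(a, b), jaccard(am, bm))
  expect_equal(hd95(a, b, spacing), hd95(am, bm, spacing))
  expect_equal(ahd(a, b, spacing), ahd(am, bm, spacing))
})

test_that("dilating a perfect prediction strictly decreases dice and jaccard", {
  a <- array(0, c(5, 9, 9)); a[2:4, 3:7, 3:7] <- 1
  grown <- array(0, c(5, 9, 9)); grown[2:4, 2:8, 2:8] <- 1
  expect_true(all(a[grown == 0] == 0))  # nested
  expect_lt(dice(grown, a), dice(a, a))
  expect_lt(jaccard(grown, a), jaccard(a, a))
})

test_that("case metrics flag empty-mask ROIs and report per-ROI rows", {
  cs <- tiny_cohort(2)[[1]]
  cm <- case_metrics(cs$labels, cs$labels, "self")
  expect_equal(nrow(cm), 4)
  expect_setequal(cm$roi, c("left_parotid", "right_parotid", "left_tumor", "right_tumor"))
  expect_true(all(cm$dice == 1))
  expect_true(all(cm$hd95_mm == 0))
  expect_true(all(cm$jaccard <= cm$dice))

  empty <- cs$labels
  empty$masks[, , , 3] <- 0
  cm2 <- case_metrics(empty, cs$labels, "miss")
  expect_equal(cm2$flags[cm2$roi == "left_tumor"], "pred_empty")
  expect_true(is.na(cm2$hd95_mm[cm2$roi == "left_tumor"]))
  expect_equal(cm2$dice[cm2$roi == "left_tumor"], 0)
})

test_that("cohort aggregation reproduces means and percentile ranges", {
  one <- data.frame(patient_id = "a", roi = "left_parotid", dice = 0.9,
                    jaccard = 0.8, hd95_mm = 2, ahd_mm = 1, flags = "")
  rep1 <- aggregate_metrics(one)
  s <- rep1$summary
  expect_equal(s$mean[s$metric == "dice"], 0.9)
  expect_equal(s$lo[s$metric == "dice"], 0.9)
  expect_equal(s$hi[s$metric == "dice"], 0.9)

  two <- rbind(one, within(one, { patient_id <- "b"; dice <- 0.8 }))
  s2 <- aggregate_metrics(two)$summary
  expect_equal(s2$mean[s2$metric == "dice"], 0.85)

  set.seed(33)
  vals <- runif(100)
  many <- do.call(rbind, lapply(seq_along(vals), function(i) {
    within(one, { patient_id <- sprintf("p%03d", i); dice <- vals[i] })
  }))
  s3 <- aggregate_metrics(many)$summary
  expect_equal(s3$lo[s3$metric == "dice"], oracle_percentile(vals, 0.025), tolerance = 1e-12)
  expect_equal(s3$hi[s3$metric == "dice"], oracle_percentile(vals, 0.975), tolerance = 1e-12)
  expect_true(s3$lo[s3$metric == "dice"] >= min(vals))
  expect_true(s3$hi[s3$metric == "dice"] <= max(vals))

  # undefined values are excluded with counts
  two$hd95_mm <- NA_real_
  s4 <- aggregate_metrics(two)$summary
  expect_equal(s4$n_undefined[s4$metric == "hd95_mm"], 2)
  expect_true(is.na(s4$mean[s4$metric == "hd95_mm"]))
})
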