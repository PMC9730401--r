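test_that("phantom generation is deterministic under a fixed seed", {
  s <- tiny_grid_spec(seed = 42L)
  a <- generate_phantom(s, "p1")
  b <- generate_phantom(s, "p1")
  expect_identical(a$volume$sequences, b$volume$sequences)
  expect_identical(a$labels$masks, b$labels$masks)
  # a different seed changes the data
  s2 <- tiny_grid_spec(seed = 43L)
  expect_false(identical(generate_phantom(s2, "p1")$volume$sequences,
                         a$volume$sequences))
})

test_that("invalid phantom specs are rejected", {
  expect_error(phantom_spec(grid_shape = c(0, 32, 32)), "positive")
  expect_error(phantom_spec(spacing = c(0.4, 0.8, 0.8)), "thickness")
  expect_error(phantom_spec(laterality = "none", tumor_radius_frac = 0.4),
               "incompatible")
  expect_error(phantom_spec(noise_sd = -1), "noise_sd")
  bad_cp <- default_contrast_profile(); bad_cp[1, 1] <- 2
  expect_error(phantom_spec(contrast_profile = bad_cp), "contrast_profile")
})

test_that("tumor laterality controls which tumor masks have foreground", {
  left_only <- generate_phantom(tiny_grid_spec(seed = 5L, laterality = "left"))
  m <- left_only$labels$masks
  expect_gt(sum(m[, , , "left_tumor"]), 0)
  expect_identical(sum(m[, , , "right_tumor"]), 0)

  none <- generate_phantom(phantom_spec(grid_shape = c(4, 32, 32),
                                        laterality = "none",
                                        tumor_radius_frac = 0, seed = 5L))
  expect_identical(sum(none$labels$masks[, , , 3:4]), 0)
})

test_that("tumors are voxelwise subsets of their gland and sides stay lateralized", {
  for (cs in tiny_cohort(4)) {
    m <- cs$labels$masks
    # brute-force containment: no tumor voxel outside its parotid
    viol <- 0L
    d <- dim(m)
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
      if (m[i, j, k, 3] == 1 && m[i, j, k, 1] == 0) viol <- viol + 1L
      if (m[i, j, k, 4] == 1 && m[i, j, k, 2] == 0) viol <- viol + 1L
    }
    expect_identical(viol, 0L)
    # anatomical-left occupies the high-column half (radiological display)
    w <- d[3]
    left_cols <- which(apply(m[, , , "left_parotid"], 3, sum) > 0)
    right_cols <- which(apply(m[, , , "right_parotid"], 3, sum) > 0)
    expect_true(all(left_cols > w / 2))
    expect_true(all(right_cols <= w / 2))
  }
})

test_that("noise-free phantoms take exactly the contrast-profile intensities", {
  s <- tiny_grid_spec(seed = 9L, noise_sd = 0)
  cs <- generate_phantom(s)
  m <- cs$labels$masks
  parotid_only <- (m[, , , 1] | m[, , , 2]) & !(m[, , , 3] | m[, , , 4])
  tumor <- m[, , , 3] | m[, , , 4]
  bg <- !(m[, , , 1] | m[, , , 2])
  for (sq in c("T1w", "T2w", "T1wC")) {
    img <- cs$volume$sequences[[sq]]
    cp <- s$contrast_profile[sq, ]
    expect_identical(unique(img[bg]), unname(cp[["background"]]))
    expect_identical(unique(img[parotid_only]), unname(cp[["parotid"]]))
    expect_identical(unique(img[tumor]), unname(cp[["tumor"]]))
  }
})

test_that("mirrored geometry reproduces the mirror-with-label-swap of a phantom", {
  s <- phantom_spec(grid_shape = c(4, 32, 32), laterality = "left",
                    noise_sd = 0, rotation_deg = 8, seed = 21L)
  a <- generate_phantom(s)
  w <- dim(a$labels$masks)[3]
  b <- generate_phantom(s, geometry = mirror_geometry(a$ground_truth_params, w))
  flipped <- a$labels$masks[, , w:1, c(2, 1, 4, 3)]
  expect_identical(unname(b$labels$masks), unname(flipped))
})

test_that("cohort generation is deterministic and writes a readable manifest", {
  d1 <- file.path(tempdir(), "coh1"); d2 <- file.path(tempdir(), "coh2")
  on.exit(unlink(c(d1, d2), recursive = TRUE), add = TRUE)
  generate_cohort(3, tiny_grid_spec(), seed = 7L, out_dir = d1)
  generate_cohort(3, tiny_grid_spec(), seed = 7L, out_dir = d2)
  expect_identical(readLines(file.path(d1, "manifest.json")),
                   readLines(file.path(d2, "manifest.json")))
  m <- read_manifest(file.path(d1, "manifest.json"))
  expect_length(m$cases, 3)

  one <- generate_cohort(1, tiny_grid_spec(), seed = 1L,
                         out_dir = file.path(tempdir(), "coh3"))
  on.exit(unlink(file.path(tempdir(), "coh3"), recursive = TRUE), add = TRUE)
  m1 <- read_manifest(file.path(tempdir(), "coh3", "manifest.json"))
  expect_length(m1$cases, 1)
  expect_identical(m1$cases[[1]]$patient_id, "phantom001")
})

test_that("cohort laterality frequencies stay inside exact binomial 99% bounds", {
  cases <- generate_cohort(100, tiny_grid_spec(), seed = 12345L)
  lat <- table(factor(vapply(cases, function(cs) cs$spec$laterality, ""),
                      levels = c("left", "right", "both")))
  probs <- c(left = 0.446, right = 0.491, both = 0.063)
  for (nm in names(probs)) {
    lo <- qbinom(0.005, 100, probs[[nm]])
    hi <- qbinom(0.995, 100, probs[[nm]])
    expect_gte(lat[[nm]], lo)
    expect_lte(lat[[nm]], hi)
  }
})
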