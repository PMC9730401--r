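test_that("configuration contracts are enforced", {
  expect_error(model_config(input_size = 500), "divisible")
  expect_error(model_config(depth = 3, encoder_block_allocation = c(2, 2)),
               "length depth \\+ 1")
  expect_error(model_config(encoder_block_allocation = c(2, 2, 2, 3, 0)),
               "at least one conv block")
  cfg <- model_config()
  expect_equal(sum(cfg$encoder_block_allocation), 12)
  expect_equal(cfg$depth, 4)
  expect_equal(cfg$input_size, 512)
  expect_equal(cfg$base_filters, 64)
})

test_that("the default allocation yields 12 encoder conv blocks and 4 pool stages", {
  # full default layer layout at a reduced width (structure is width-independent)
  cfg <- model_config(base_filters = 4L, input_size = 64L)
  m <- build_model(cfg, seed = 1)
  s <- model_summary(m)
  expect_equal(s$encoder_conv_blocks, 12)
  expect_equal(s$max_pool_stages, 4)
  expect_equal(s$attention_gates, 4)
})

test_that("seeded builds are bit-identical and the output contract holds on small grids", {
  cfg <- tiny_model_config()
  m1 <- build_model(cfg, seed = 9)
  m2 <- build_model(cfg, seed = 9)
  expect_identical(m1$params, m2$params)
  expect_false(identical(build_model(cfg, seed = 10)$params, m1$params))

  x <- array(runif(32 * 32 * 3 * 2), c(32, 32, 3, 2))
  fw <- unet_forward(m1, x, want_masks = TRUE)
  expect_equal(dim(fw$y), c(32, 32, 4, 2))
  expect_true(all(fw$y > 0 & fw$y < 1))
  # independent sigmoids: per-pixel channel sums are not constrained to 1
  sums <- apply(fw$y, c(1, 2, 4), sum)
  expect_true(any(sums > 1))
  # attention masks stay in [0, 1] at every level
  for (mk in fw$masks) {
    expect_true(all(mk >= 0 & mk <= 1))
  }
  # bottleneck spatial size is input_size / 2^depth
  expect_error(unet_forward(m1, array(0, c(30, 30, 3, 1))), "divisible")
  expect_error(unet_forward(m1, array(0, c(32, 32, 2, 1))), "channels")
})

test_that("inference is batch-consistent: duplicated inputs give duplicated outputs", {
  m <- build_model(tiny_model_config(1), seed = 4)
  x1 <- array(runif(32 * 32), c(32, 32, 1, 1))
  xb <- array(0, c(32, 32, 1, 3))
  xb[, , , 1] <- x1; xb[, , , 2] <- x1; xb[, , , 3] <- runif(32 * 32)
  y <- unet_forward(m, xb)$y
  expect_identical(y[, , , 1], y[, , , 2])
  expect_false(identical(y[, , , 1], y[, , , 3]))
})

test_that("the standalone attention gate reproduces a hand-computed toy case", {
  skip_mat <- array(c(0.2, -0.4, 1.5, 0.0), c(2, 2, 1, 1))
  gate_mat <- array(c(0.3, 0.1, -2.0, 0.5), c(2, 2, 1, 1))
  id_k <- array(1, c(1, 1, 1, 1))
  params <- list(Wx = id_k, bx = 0, Wg = id_k, bg = 0, Wp = id_k, bp = 0)
  out <- attention_gate(skip_mat, gate_mat, params)
  manual_mask <- 1 / (1 + exp(-pmax(skip_mat + gate_mat, 0)))
  expect_equal(out$mask, manual_mask, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(out$gated, skip_mat * manual_mask, tolerance = 1e-12,
               ignore_attr = TRUE)

  # saturating the mask projection forces all-ones / all-zeros gating
  ones <- attention_gate(skip_mat, gate_mat,
                         modifyList(params, list(Wp = array(0, c(1, 1, 1, 1)),
                                                 bp = 40)))
  expect_identical(ones$gated, skip_mat)
  zeros <- attention_gate(skip_mat, gate_mat,
                          modifyList(params, list(Wp = array(0, c(1, 1, 1, 1)),
                                                  bp = -40)))
  expect_lt(max(abs(zeros$gated)), 1e-12)
})

test_that("analytic gradients match finite differences on a tiny network", {
  cfg <- model_config(in_channels = 2, out_channels = 3, input_size = 8,
                      depth = 2, base_filters = 2,
                      encoder_block_allocation = c(1, 1, 1))
  m <- build_model(cfg, seed = 7)
  set.seed(21)
  xb <- array(runif(8 * 8 * 2 * 2), c(8, 8, 2, 2))
  tb <- array(rbinom(8 * 8 * 3 * 2, 1, 0.3), c(8, 8, 3, 2))
  fw <- unet_forward(m, xb, train = TRUE, keep = TRUE)
  bk <- unet_backward(m, fw, soft_dice_loss_grad(fw$y, tb, 1))
  lossfn <- function(model) {
    soft_dice_loss(unet_forward(model, xb, train = TRUE)$y, tb, 1)
  }
  check <- c("enc1_b1_W", "bot_b1_g", "dec1_gate_Wg", "dec2_up_b", "out_W")
  for (nm in check) {
    p <- m$params[[nm]]
    idx <- sample(length(p), min(3, length(p)))
    for (i in idx) {
      mp <- m; mp$params[[nm]][i] <- p[i] + 1e-5
      mm <- m; mm$params[[nm]][i] <- p[i] - 1e-5
      fd <- (lossfn(mp) - lossfn(mm)) / 2e-5
      expect_equal(bk$grads[[nm]][i], fd, tolerance = 1e-4)
    }
  }
})

test_that("an untrained zero-bias network is translation-covariant away from borders", {
  m <- build_model(model_config(in_channels = 1, input_size = 64, depth = 2,
                                base_filters = 4,
                                encoder_block_allocation = c(1, 1, 1)),
                   seed = 6)
  blob <- function(ctr_col) {
    x <- array(0, c(64, 64, 1, 1))
    x[29:35, (ctr_col - 3):(ctr_col + 3), 1, 1] <- 1
    x
  }
  y1 <- unet_forward(m, blob(28))$y
  y2 <- unet_forward(m, blob(36))$y  # shifted by 8 columns (multiple of 2^depth)
  shifted <- array(sigmoid(0), dim(y1))
  shifted[, 9:64, , ] <- y1[, 1:56, , ]
  expect_lt(max(abs(y2 - shifted)), 1e-8)
})

test_that("both gate wirings build and agree on shape but differ in parameters", {
  cfg_b <- tiny_model_config()
  cfg_a <- tiny_model_config()
  cfg_a$gate_source <- "adjacent_decoder"
  mb <- build_model(cfg_b, seed = 2)
  ma <- build_model(cfg_a, seed = 2)
  # gate projections take the bottleneck channel count vs the adjacent level's
  expect_equal(dim(mb$params$dec1_gate_Wg)[3], 16)  # bottleneck: 4 * 2^2
  expect_equal(dim(ma$params$dec1_gate_Wg)[3], 8)   # adjacent decoder level
  x <- array(runif(32 * 32 * 3), c(32, 32, 3, 1))
  expect_equal(dim(unet_forward(ma, x)$y), c(32, 32, 4, 1))
})

test_that("checkpoints round-trip through save/load", {
  dir <- tempdir()
  m <- build_model(tiny_model_config(), seed = 15)
  x <- array(runif(32 * 32 * 3), c(32, 32, 3, 1))
  p <- file.path(dir, "ckpt.rds")
  save_model(m, p)
  m2 <- load_model(p)
  expect_identical(unet_forward(m, x)$y, unet_forward(m2, x)$y)
  unlink(p)
})

test_that("case prediction assembles thresholded slices back onto the native grid", {
  cs <- tiny_cohort(2)[[1]]
  m <- build_model(tiny_model_config(), seed = 3)
  pred <- predict_case(m, cs)
  expect_s3_class(pred, "roi_label_volume")
  expect_identical(dim(pred$masks), dim(cs$labels$masks))
  expect_true(all(pred$masks %in% c(0, 1)))
  # threshold 1.0 can never be reached by a sigmoid
  empty <- predict_case(m, cs, threshold = 1.0)
  expect_identical(sum(empty$masks), 0)
})
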