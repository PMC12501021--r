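# Enhancement: adaptive smoothing, Laplacian sharpening, fused output.

test_that("noise-variance estimate matches brute-force local variances and sampling theory", {
  # constant image: zero variance everywhere
  expect_equal(estimate_noise_variance(matrix(7, 16, 16), 3), 0)

  # 3x3 worked example: median of the nine hand-computed window variances
  img <- impulse3()
  expect_equal(estimate_noise_variance(img, 3),
               median(brute_local_var(img, 3)))

  # i.i.d. noise of variance 4 on a flat field is recovered within 15%
  set.seed(11)
  noisy <- matrix(pmin(pmax(100 + rnorm(256 * 256, 0, 2), 0), 255), 256, 256)
  est <- estimate_noise_variance(noisy, 7)
  expect_lt(abs(est - 4) / 4, 0.15)

  expect_error(estimate_noise_variance(matrix(1, 4, 4), 7), "smaller")
  expect_error(estimate_noise_variance(impulse3(), 4), "odd")
})

test_that("adaptive average filter obeys its limiting and convex-combination behaviour", {
  img <- random_rgb(16, 16)
  # zero noise variance: exact identity
  expect_equal(adaptive_average_filter(img, 0, 5), img)
  # constant image is a fixed point for any noise variance
  cst <- matrix(42, 10, 10)
  expect_equal(adaptive_average_filter(cst, 100, 3), cst)
  # worked 3x3 example: center = mu + ((8-2)/8)*(9-1) = 7
  out <- adaptive_average_filter(impulse3(), 2, 3)
  expect_equal(out[2, 2], 7)
  # clamped ratio keeps every output within the local window range
  g <- to_gray(img)
  out2 <- adaptive_average_filter(g, 5000, 3)
  p <- 1L
  mp <- g[c(p:1, 1:nrow(g), nrow(g):(nrow(g) - p + 1)),
          c(p:1, 1:ncol(g), ncol(g):(ncol(g) - p + 1))]
  for (i in seq_len(nrow(g))) for (j in seq_len(ncol(g))) {
    win <- mp[i:(i + 2), j:(j + 2)]
    expect_gte(out2[i, j], min(win) - 1e-9)
    expect_lte(out2[i, j], max(win) + 1e-9)
  }
  expect_error(adaptive_average_filter(img, -1, 3), ">= 0")
})

test_that("Laplacian filter is a linear second-derivative operator", {
  # constant -> zero response
  expect_equal(laplacian_filter(matrix(3, 8, 8)), matrix(0, 8, 8))
  # unit impulse reproduces the kernel, both variants
  imp <- matrix(0, 5, 5); imp[3, 3] <- 1
  r8 <- laplacian_filter(imp, "eight-neighbor")
  expect_equal(r8[2:4, 2:4], matrix(c(1, 1, 1, 1, -8, 1, 1, 1, 1), 3, 3))
  r4 <- laplacian_filter(imp, "four-neighbor")
  expect_equal(r4[2:4, 2:4], matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3, 3))
  # linear ramp: zero response in the interior
  ramp <- matrix(rep(seq(0, 250, length.out = 10), each = 10), 10, 10)
  expect_equal(max(abs(laplacian_filter(ramp)[2:9, 2:9])), 0)
  # linearity on random images
  set.seed(2)
  for (rep in 1:5) {
    x <- matrix(runif(64, 0, 255), 8, 8); y <- matrix(runif(64, 0, 255), 8, 8)
    expect_equal(laplacian_filter(2 * x + 3 * y),
                 2 * laplacian_filter(x) + 3 * laplacian_filter(y),
                 tolerance = 1e-10)
  }
})

test_that("enhancement fuses smoothing and sharpening and clips to range", {
  cst <- matrix(120, 12, 12)
  expect_equal(enhance_image(cst, enhancement_config(noise_var = 0)), cst)
  # 3x3 example: composition of the two per-stage oracles
  img <- impulse3()
  cfg <- enhancement_config(window = 3, noise_var = 2)
  adap <- adaptive_average_filter(img, 2, 3)
  expected <- pmin(pmax(adap + laplacian_filter(adap, "eight-neighbor"), 0), 255)
  expect_equal(enhance_image(img, cfg), expected)
  # clipping contract on random RGB input
  out <- enhance_image(random_rgb(20, 20), enhancement_config())
  expect_true(all(out >= 0 & out <= 255))
})

test_that("hair mask detection finds drawn strokes and respects its contracts", {
  les <- generate_lesion_image(lesion_spec(5), c(96, 96), 21)
  h <- draw_hairs(les$image, hair_spec(n_strokes = 5), 22)
  m <- detect_hair_mask(h$image, hair_removal_config())
  expect_true(all(m %in% c(0, 1)))
  expect_equal(dim(m), dim(h$mask))
  recall <- sum(m * h$mask) / sum(h$mask)
  expect_gte(recall, 0.8)

  # smooth, soft-edged hairless lesion with a fixed threshold above the
  # noise floor: nothing detected
  smooth <- generate_lesion_image(
    lesion_spec(5, irregularity = 0, noise_sd = 2, edge_px = 8), c(96, 96), 31)
  m0 <- detect_hair_mask(smooth$image, hair_removal_config(mask_threshold = 60))
  expect_equal(sum(m0), 0)

  # invariance to a global additive intensity shift (closing residual is
  # shift-invariant); fixed threshold so the comparison is exact
  shifted <- pmin(h$image + 20, 255)
  if (max(h$image) <= 235) {
    cfgf <- hair_removal_config(mask_threshold = 35)
    expect_equal(detect_hair_mask(shifted, cfgf), detect_hair_mask(h$image + 20, cfgf))
  }
  m1 <- detect_hair_mask(h$image, hair_removal_config(mask_threshold = 35))
  m2 <- detect_hair_mask(pmin(h$image + 15, 240), hair_removal_config(mask_threshold = 35))
  # (shift stays in range by construction above)
  expect_equal(m1, m2)

  expect_error(detect_hair_mask(h$image, hair_removal_config(se_length = 201)),
               "exceeds")
})

test_that("inverse-distance inpainting replaces only masked pixels", {
  img <- random_rgb(12, 12)
  empty <- matrix(0, 12, 12)
  expect_equal(inpaint_hair(img, empty), img)

  # constant image stays constant under any proper mask
  cst <- matrix(100, 9, 9)
  mask <- matrix(0, 9, 9); mask[4:6, 4:6] <- 1
  expect_equal(inpaint_hair(cst, mask), cst)

  # 5x5 horizontal ramp, single masked center: hand-computed inverse
  # Euclidean-distance weighted mean of the 8 donors in the 3x3 window
  ramp <- matrix(rep(c(10, 20, 30, 40, 50), each = 5), 5, 5)
  m1 <- matrix(0, 5, 5); m1[3, 3] <- 1
  donors <- expand.grid(dy = -1:1, dx = -1:1)
  donors <- donors[!(donors$dy == 0 & donors$dx == 0), ]
  wgt <- 1 / sqrt(donors$dy^2 + donors$dx^2)
  vals <- ramp[cbind(3 + donors$dy, 3 + donors$dx)]
  expect_equal(inpaint_hair(ramp, m1, hair_removal_config(inpaint_min_neighbors = 8))[3, 3],
               sum(wgt * vals) / sum(wgt))

  # locality: unmasked pixels are bit-identical
  out <- inpaint_hair(img, {m <- matrix(0, 12, 12); m[2:4, 7] <- 1; m})
  keep <- matrix(TRUE, 12, 12); keep[2:4, 7] <- FALSE
  for (k in 1:3) expect_identical(out[, , k][keep], img[, , k][keep])

  expect_error(inpaint_hair(cst, matrix(1, 9, 9)), "donor")
  expect_error(inpaint_hair(cst, matrix(0, 5, 5)), "shape")
})

test_that("the full pipeline is deterministic and changes only what it should", {
  les <- generate_lesion_image(lesion_spec(2), c(80, 80), 5)
  h <- draw_hairs(les$image, hair_spec(n_strokes = 4), 6)
  p1 <- preprocess_pipeline(h$image)
  p2 <- preprocess_pipeline(h$image)
  expect_identical(p1$image, p2$image)   # determinism
  expect_identical(p1$mask, p2$mask)
  # unmasked pixels come from the enhancement stage alone
  keep <- p1$mask == 0
  for (k in 1:3) expect_identical(p1$image[, , k][keep], p1$enhanced[, , k][keep])
  # a hairless constant image passes through unchanged
  cst <- array(90, c(64, 64, 3))
  pc <- preprocess_pipeline(cst, enhancement_config(noise_var = 0),
                            hair_removal_config(mask_threshold = 10))
  expect_equal(pc$image, cst)
})

test_that("raster IO round-trips PNG images", {
  img <- round(random_rgb(16, 20))
  path <- tempfile(fileext = ".png")
  write_image(img, path)
  back <- read_image(path)
  expect_equal(dim(back), dim(img))
  expect_lt(max(abs(back - img)), 1)   # 8-bit quantization only
  mask <- matrix(rbinom(16 * 20, 1, 0.3), 16, 20)
  mpath <- tempfile(fileext = ".png")
  write_mask(mask, mpath)
  expect_equal((to_gray(read_image(mpath)) > 127) * 1, mask)
  unlink(c(path, mpath))
})
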