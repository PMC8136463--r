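test_that("heatmap encoding follows the Gaussian target definition", {
  h <- encode_heatmap(c(10, 10), c(21, 21), sigma_px = 4)
  expect_equal(h[11, 11], 1.0)              # intensity 1 at the point
  expect_equal(h[11, 15], exp(-0.5))        # one SD away along x
  expect_equal(h[15, 11], exp(-0.5))        # one SD away along y
  expect_equal(h[15, 14], exp(-(3^2 + 4^2) / 32))  # at distance 5
  expect_true(all(h <= 1) && all(h > 0))
  expect_equal(encode_heatmap(NULL, c(9, 9)), matrix(0, 9, 9))
  expect_error(encode_heatmap(c(30, 2), c(21, 21)), "outside")
})

test_that("heatmaps are radially symmetric about the encoded point", {
  h <- encode_heatmap(c(10, 10), c(21, 21))
  for (d in list(c(3, 4), c(4, 3), c(-3, 4), c(-4, -3))) {
    expect_equal(h[11 + d[2], 11 + d[1]], h[11 + 4, 11 + 3])
  }
})

test_that("decode inverts encode over a grid of points and shapes", {
  for (shape in list(c(3, 3), c(5, 9), c(17, 17), c(20, 31))) {
    xs <- unique(round(seq(0, shape[2] - 1, length.out = 4)))
    ys <- unique(round(seq(0, shape[1] - 1, length.out = 4)))
    for (x in xs) for (y in ys) {
      expect_equal(decode_heatmap(encode_heatmap(c(x, y), shape)),
                   c(x = x, y = y))
    }
  }
})

test_that("decoding ties break at the smallest row-major index", {
  expect_equal(decode_heatmap(matrix(0.3, 7, 5)), c(x = 0, y = 0))
  m <- matrix(0, 4, 4); m[2, 3] <- m[3, 1] <- 0.9
  expect_equal(decode_heatmap(m), c(x = 2, y = 1))
  expect_null(decode_heatmap(matrix(0, 6, 6)))
})

test_that("center crop pads and crops symmetrically, trailing-heavy", {
  img <- matrix(runif(600 * 800), 600, 800)
  cc <- center_crop(img, 640)
  expect_equal(dim(cc$image), c(640, 640))
  expect_equal(cc$spec$rows$pad_lead, 20)
  expect_equal(cc$spec$rows$pad_trail, 20)
  expect_equal(cc$spec$cols$crop_lead, 80)
  expect_equal(cc$spec$cols$crop_trail, 80)
  expect_equal(apply_crop_spec(c(80, 0), cc$spec), c(0, 20))
  # padded border is zero, interior preserved
  expect_true(all(cc$image[1:20, ] == 0))
  expect_equal(cc$image[21, 1], img[1, 81])

  id <- center_crop(matrix(1:16, 4, 4), 4)
  expect_equal(id$image, matrix(as.numeric(1:16), 4, 4))
  expect_equal(id$spec$row_offset, 0)

  odd <- center_crop(matrix(0, 641, 641), 640)
  expect_equal(odd$spec$rows$crop_lead, 0)
  expect_equal(odd$spec$rows$crop_trail, 1)
})

test_that("crop coordinate map round-trips and cropping is idempotent", {
  img <- matrix(runif(300 * 500), 300, 500)
  cc <- center_crop(img, 256)
  pts <- cbind(x = c(130, 250, 499), y = c(25, 150, 299))
  back <- apply_crop_spec(apply_crop_spec(pts, cc$spec), cc$spec,
                          inverse = TRUE)
  expect_equal(back, pts)
  cc2 <- center_crop(cc$image, 256)
  expect_equal(cc2$image, cc$image)
})

test_that("loss weights zero out exactly the missing keypoints", {
  ann <- keypoint_df(1:4, 1:4)
  expect_equal(unname(loss_weights(ann)), c(1, 1, 1, 1))
  ann$missing[ann$keypoint_name == "pw_epi"] <- TRUE
  w <- loss_weights(ann)
  expect_equal(w[["pw_epi"]], 0)
  expect_equal(sum(w), 3)
  ann$missing[] <- TRUE
  expect_equal(sum(loss_weights(ann)), 0)
})

test_that("pixel to mm conversion honours per-axis spacing", {
  expect_equal(pixels_to_mm(c(10, 20), 0.5, 0.25), c(2.5, 10.0))
  expect_equal(pixels_to_mm(c(7, 3), 1, 1), c(7, 3))
  p <- c(12.5, 31.25)
  expect_equal(mm_to_pixels(pixels_to_mm(p, 0.4, 0.7), 0.4, 0.7), p)
  expect_error(pixels_to_mm(c(1, 1), -0.5, 0.5), "positive")
})

test_that("augmentation identity case returns the input unchanged", {
  img <- matrix(runif(40 * 40), 40, 40)
  kp <- data.frame(x = c(5, 20), y = c(7, 33))
  out <- augment_frame(img, kp, identity_aug_config(), seed = 1)
  expect_equal(out$image, img)
  expect_equal(out$keypoints$x, kp$x)
  expect_equal(out$keypoints$y, kp$y)
  expect_true(all(out$keypoints$valid))
})

test_that("pure translation shifts image and keypoints together", {
  img <- matrix(0, 40, 40); img[15, 11] <- 1
  cfg <- aug_config(rotation_deg = c(0, 0), scale = c(1, 1),
                    translate_frac = c(0.25, 0.25), gamma = c(1, 1),
                    erase_area_frac = c(0, 0))
  out <- augment_frame(img, data.frame(x = 10, y = 14), cfg, seed = 2)
  expect_equal(out$keypoints$x, 20)
  expect_equal(out$keypoints$y, 24)
  expect_equal(out$image[25, 21], 1)   # bright pixel moved with the point
  expect_equal(sum(out$image), 1)
  # keypoint pushed outside the raster is flagged invalid
  out2 <- augment_frame(img, data.frame(x = 35, y = 14), cfg, seed = 2)
  expect_false(out2$keypoints$valid)
})

test_that("gamma and erasure act on intensities as specified", {
  img <- matrix(0.5, 20, 20)
  cfg <- aug_config(rotation_deg = c(0, 0), scale = c(1, 1),
                    translate_frac = c(0, 0), gamma = c(2, 2),
                    erase_area_frac = c(0, 0))
  out <- augment_frame(img, data.frame(x = 1, y = 1), cfg, seed = 1)
  expect_equal(out$image, matrix(0.25, 20, 20))

  cfg2 <- aug_config(rotation_deg = c(0, 0), scale = c(1, 1),
                     translate_frac = c(0, 0), gamma = c(1, 1),
                     erase_area_frac = c(0.1, 0.1))
  out2 <- augment_frame(matrix(1, 30, 30), data.frame(x = 1, y = 1),
                        cfg2, seed = 3)
  n_erased <- sum(out2$image == 0)        # ~10% of 900 px (rounded rect)
  expect_gte(n_erased, 70)
  expect_lte(n_erased, 110)
  expect_true(out2$keypoints$valid)       # erasure never invalidates

  expect_error(aug_config(gamma = c(-1, 2)), "gamma")
})

test_that("augmentation is reproducible for a fixed seed", {
  img <- matrix(runif(50 * 50), 50, 50)
  kp <- data.frame(x = c(10, 30), y = c(12, 44))
  a <- augment_frame(img, kp, aug_config(), seed = 7)
  b <- augment_frame(img, kp, aug_config(), seed = 7)
  c <- augment_frame(img, kp, aug_config(), seed = 8)
  expect_identical(a, b)
  expect_false(identical(a$params, c$params))
})
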