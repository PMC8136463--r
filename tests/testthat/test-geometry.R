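test_that("line frames are orthonormal with the documented orientation", {
  lf <- line_frame(c(0, 0), c(0, 10))
  expect_equal(lf$length_mm, 10)
  expect_equal(lf$unit_along, c(0, 1))
  expect_equal(lf$unit_perp, c(1, 0))    # +90 deg in y-down orientation
  expect_equal(sum(lf$unit_along * lf$unit_perp), 0)

  lf2 <- line_frame(c(0, 0), c(3, 4))
  expect_equal(lf2$length_mm, 5)
  expect_equal(sqrt(sum(lf2$unit_along^2)), 1)

  rev <- line_frame(c(3, 4), c(0, 0))
  expect_equal(rev$unit_along, -lf2$unit_along)
  expect_error(line_frame(c(1, 1), c(1, 1)), "coincide")
})

test_that("deviations project onto the line frame as stated", {
  lf <- line_frame(c(0, 0), c(0, 10))
  d <- decompose_deviation(c(1, 2), c(0, 0), lf)
  expect_equal(d[["transverse_frac"]], 0.20)
  expect_equal(d[["longitudinal_frac"]], 0.10)
  expect_equal(unname(decompose_deviation(c(4, 7), c(4, 7), lf)),
               c(0, 0))
})

test_that("decomposition satisfies Pythagorean closure", {
  set.seed(6)
  for (i in 1:50) {
    s <- runif(2, -50, 50); e <- runif(2, -50, 50)
    if (all(s == e)) next
    lf <- line_frame(s, e)
    obs <- runif(2, -60, 60); cons <- runif(2, -60, 60)
    dec <- decompose_deviation(obs, cons, lf)
    lhs <- lf$length_mm^2 * sum(dec^2)
    rhs <- sum((obs - cons)^2)
    expect_equal(lhs, rhs, tolerance = 1e-9)
  }
})

test_that("decomposition is invariant under similarity transforms", {
  set.seed(8)
  for (i in 1:20) {
    s <- runif(2, 0, 100); e <- runif(2, 0, 100)
    obs <- runif(2, 0, 100); cons <- runif(2, 0, 100)
    base <- decompose_deviation(obs, cons, line_frame(s, e))
    th <- runif(1, 0, 2 * pi); sc <- runif(1, 0.1, 5)
    tr <- runif(2, -30, 30)
    # rotation with the same handedness as the (x, y-down) image plane
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    f <- function(p) as.numeric(sc * R %*% p + tr)
    moved <- decompose_deviation(f(obs), f(cons),
                                 line_frame(f(s), f(e)))
    expect_equal(moved, base, tolerance = 1e-9)
  }
})

test_that("consensus keypoints are robust coordinate-wise medians", {
  ann0 <- do.call(rbind, lapply(1:5, function(e) {
    data.frame(frame_id = "f1", rater_id = sprintf("e%d", e),
               reading_index = 1, keypoint_name = keypoint_names(),
               x_px = c(100, 100, 100, 100),
               y_px = c(50, 73, 167, 189), missing = FALSE,
               stringsAsFactors = FALSE)
  }))
  ck <- consensus_keypoints(ann0, 0.5, 0.5)
  expect_equal(ck$x_mm, rep(50, 4))
  expect_equal(ck$y_mm, c(50, 73, 167, 189) * 0.5)

  # one wild outlier among five leaves the median unchanged
  ann1 <- ann0
  ann1[ann1$rater_id == "e3", c("x_px", "y_px")] <- 9999
  expect_equal(consensus_keypoints(ann1, 0.5, 0.5)$x_mm, rep(50, 4))

  # permutation invariance
  expect_equal(consensus_keypoints(ann0[sample(nrow(ann0)), ], 0.5, 0.5),
               ck)

  # quorum rule
  few <- ann0[ann0$rater_id %in% c("e1", "e2"), ]
  expect_true(all(consensus_keypoints(few, 0.5, 0.5,
                                      min_experts = 3)$missing))
})

test_that("each structure decomposes against its own consensus line", {
  fr <- simple_frame()
  meta <- data.frame(frame_id = fr$frame_id, phase = "ED",
                     pixel_spacing_row_mm = 0.5,
                     pixel_spacing_col_mm = 0.5)
  experts <- do.call(rbind, lapply(1:3, function(e)
    simulate_rater_annotations(fr, rater_model(sprintf("e%d", e)), 1,
                               seed = e)))
  # AI displaced 2 mm along the axis at pw_endo only
  ai <- simulate_ai_annotations(fr, rater_model("ai"), seed = 1)
  i <- ai$keypoint_name == "pw_endo"
  ai$y_px[i] <- ai$y_px[i] + 4          # 2 mm at 0.5 mm/px, vertical axis
  dec <- decompose_annotations(rbind(experts, ai), meta,
                               sprintf("e%d", 1:3))
  ai_rows <- dec[dec$method_id == "ai", ]
  lv <- ai_rows[ai_rows$dimension == "lvid" &
                  ai_rows$keypoint_name == "pw_endo", ]
  expect_equal(lv$transverse_frac, 2 / fr$dims_mm[["lvid"]],
               tolerance = 1e-9)
  pw <- ai_rows[ai_rows$dimension == "pw" &
                  ai_rows$keypoint_name == "pw_endo", ]
  # same 2 mm offset, but normalised by the much shorter PW line
  # (pw_endo starts the PW line, which shares the axis direction)
  expect_equal(pw$transverse_frac, 2 / fr$dims_mm[["pw"]],
               tolerance = 1e-9)
  # every other AI keypoint row is unperturbed
  others <- ai_rows[ai_rows$keypoint_name != "pw_endo", ]
  expect_true(all(abs(others$transverse_frac) < 1e-9))
  expect_true(all(abs(ai_rows$longitudinal_frac) < 1e-9))
})

test_that("isotropic scatter shows no longitudinal excess", {
  set.seed(10)
  lf <- line_frame(c(0, 0), c(0, 47))
  nonsig <- logical(200)
  for (i in 1:200) {
    dec <- t(vapply(1:50, function(j) decompose_deviation(
      rnorm(2, 0, 3), c(0, 0), lf), numeric(2)))
    p <- f_test_sd(dec[, 2], dec[, 1])$p_value
    nonsig[i] <- p >= 0.05
  }
  expect_gte(mean(nonsig), 0.90)
})

test_that("zero-noise raters produce zero component scatter", {
  fr <- simple_frame()
  meta <- data.frame(frame_id = fr$frame_id, phase = "ED",
                     pixel_spacing_row_mm = 0.5,
                     pixel_spacing_col_mm = 0.5)
  ann <- do.call(rbind, lapply(1:4, function(e)
    simulate_rater_annotations(fr, rater_model(sprintf("e%d", e)), 2,
                               seed = e)))
  dec <- decompose_annotations(ann, meta, sprintf("e%d", 1:4))
  ds <- decomposition_summary(dec)$summary
  ok <- ds[ds$available, ]
  expect_true(all(ok$sd_transverse_pct == 0))
  expect_true(all(ok$sd_longitudinal_pct == 0))
})
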