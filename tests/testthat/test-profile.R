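test_that("a straight trace yields evenly spaced anchors with one normal", {
  tr <- membrane_trace(data.frame(x_nm = c(0, 5000), y_nm = c(500, 500)))
  segs <- segment_trace(tr)
  expect_length(segs, 5)
  anchors_x <- vapply(segs, function(s) s$anchor[1], numeric(1))
  expect_equal(anchors_x, c(500, 1500, 2500, 3500, 4500))
  normals <- t(vapply(segs, function(s) s$normal, numeric(2)))
  expect_true(all(abs(normals[, 1]) < 1e-9))
  expect_equal(abs(normals[, 2]), rep(1, 5))
  expect_equal(length(unique(normals[, 2])), 1)  # consistent orientation
})

test_that("a circular trace gives radial outward normals (either traversal)", {
  R <- 2000
  ang <- seq(0, 2 * pi, length.out = 201)[-201]
  mk <- function(a) membrane_trace(
    data.frame(x_nm = 5000 + R * cos(a), y_nm = 5000 + R * sin(a)))
  segs <- segment_trace(mk(ang))
  expect_length(segs, floor(2 * pi * R / 1000))
  for (s in segs) {
    radial <- (s$anchor - c(5000, 5000)) / sqrt(sum((s$anchor - c(5000, 5000))^2))
    cosang <- sum(radial * s$normal)
    expect_gt(cosang, cos(pi / 180))  # within 1 degree of radial, outward
  }
  segs_rev <- segment_trace(mk(rev(ang)))
  n1 <- t(vapply(segs, function(s) s$normal, numeric(2)))
  n2 <- t(vapply(segs_rev, function(s) s$normal, numeric(2)))
  # same outward orientation regardless of traversal direction
  expect_true(all(vapply(seq_len(nrow(n2)), function(i) {
    radial <- segs_rev[[i]]$anchor - c(5000, 5000)
    sum(radial * n2[i, ]) > 0
  }, logical(1))))
  expect_true(all(vapply(seq_len(nrow(n1)), function(i)
    sum((segs[[i]]$anchor - c(5000, 5000)) * n1[i, ]) > 0, logical(1))))
})

test_that("profiles of a constant image are flat at the constant", {
  img <- structure(list(pixels = matrix(3.5, 300, 300), pixel_size_nm = 10,
                        origin_nm = c(0, 0), blur_sigma_nm = 0,
                        n_excluded = 0), class = "rendered_image")
  seg <- straight_segment(anchor = c(1500, 1000))
  pr <- extract_profile(img, seg, offset_min_nm = -400, offset_max_nm = 1400)
  expect_equal(pr$value, rep(3.5, nrow(pr)), tolerance = 1e-9)
})

test_that("a Gaussian ridge appears at its true offset in the profile", {
  img <- ridge_image(ridge_y_nm = 1200, sigma_nm = 30)
  seg <- straight_segment(anchor = c(1500, 1000))
  pr <- extract_profile(img, seg, step_nm = 10, offset_min_nm = -200,
                        offset_max_nm = 800)
  expect_equal(pr$position_nm[which.max(pr$value)], 200, tolerance = 10)
})

test_that("profile is insensitive to thickness when the scene is uniform along the membrane", {
  img <- ridge_image(ridge_y_nm = c(1100, 1900), sigma_nm = 40)
  s1 <- straight_segment(anchor = c(1500, 1000), thickness_nm = 350)
  s2 <- straight_segment(anchor = c(1500, 1000), thickness_nm = 700)
  p1 <- extract_profile(img, s1, offset_min_nm = 0, offset_max_nm = 1200)
  p2 <- extract_profile(img, s2, offset_min_nm = 0, offset_max_nm = 1200)
  rel <- abs(p1$value - p2$value) / max(p1$value)
  expect_lt(max(rel), 0.02)
})

test_that("border fitting is exact on a noiseless two-Gaussian profile", {
  pos <- seq(-500, 2000, 10)
  val <- 2 + 30 * exp(-(pos - 0)^2 / (2 * 60^2)) +
    25 * exp(-(pos - 1000)^2 / (2 * 60^2))
  pr <- structure(data.frame(position_nm = pos, value = val),
                  class = c("line_profile", "data.frame"))
  fit <- fit_borders(pr)
  expect_true(fit$fit_ok)
  expect_equal(fit$inner_nm, 0, tolerance = 1)
  expect_equal(fit$outer_nm, 1000, tolerance = 1)
  expect_equal(fit$thickness_nm, 1000, tolerance = 1.5)
})

test_that("degenerate profiles are rejected with a reason", {
  pos <- seq(-500, 2000, 10)
  set.seed(71)
  flat <- structure(data.frame(position_nm = pos,
                               value = rnorm(length(pos), 5, 0.05)),
                    class = c("line_profile", "data.frame"))
  f1 <- fit_borders(flat)
  expect_false(f1$fit_ok)
  single <- structure(data.frame(
    position_nm = pos, value = 1 + 20 * exp(-(pos - 500)^2 / (2 * 80^2))),
    class = c("line_profile", "data.frame"))
  f2 <- fit_borders(single)
  expect_false(f2$fit_ok)
})

test_that("contiguity filter cuts exactly at 0.70 and flags membrane gaps", {
  segs <- replicate(3, straight_segment(), simplify = FALSE)
  mk_fit <- function(ct) list(inner_nm = 0, outer_nm = 1000,
                              thickness_nm = 1000, fit_ok = TRUE,
                              reason = "ok", params = NULL, contiguity = ct)
  fits <- list(mk_fit(0.69), mk_fit(0.70), mk_fit(0.95))
  expect_equal(apply_contiguity_filter(segs, fits), c(2, 3))
  # all-pass set is identity
  fits2 <- list(mk_fit(1), mk_fit(1), mk_fit(1))
  expect_equal(apply_contiguity_filter(segs, fits2), 1:3)

  # a membrane with a lateral gap over half the segment drops contiguity
  img_full <- ridge_image(c(1200, 2200), sigma_nm = 30, extent = c(3000, 3000))
  img_gap <- img_full
  # remove the inner ridge for x > 1500 nm (half the 700 nm strip and more)
  img_gap$pixels[round(1100 / 10):round(1320 / 10), 150:300] <- 0
  seg <- straight_segment(anchor = c(1500, 1000))
  pr_full <- extract_profile(img_full, seg, offset_min_nm = -300,
                             offset_max_nm = 1700)
  fit <- fit_borders(pr_full)
  expect_true(fit$fit_ok)
  ct_full <- segment_contiguity(img_full, seg, fit)
  ct_gap <- segment_contiguity(img_gap, seg, fit)
  expect_gte(ct_full, 0.95)
  expect_lt(ct_gap, 0.70)
})

test_that("normalization maps borders exactly and scales interior affinely", {
  pos <- seq(-500, 2000, 10)
  val <- exp(-(pos - 400)^2 / (2 * 50^2))
  pr <- structure(data.frame(position_nm = pos, value = val),
                  class = c("line_profile", "data.frame"))
  fit <- list(inner_nm = 0, outer_nm = 800, thickness_nm = 800,
              fit_ok = TRUE, params = NULL, contiguity = 1)
  np <- normalize_profile(pr, fit, mean_thickness_nm = 1000)
  # feature at 400 of an 800-thick calyx lands at 500 on the 1000 axis
  expect_equal(np$position_nm[which.max(np$value)], 500, tolerance = 10)
  # identity when the profile already spans (0, L_bar)
  fit_id <- list(inner_nm = 0, outer_nm = 1000, thickness_nm = 1000,
                 fit_ok = TRUE, params = NULL, contiguity = 1)
  np_id <- normalize_profile(pr, fit_id, mean_thickness_nm = 1000)
  keep <- !is.na(np_id$value)
  expect_equal(np_id$value[keep],
               approx(pos, val, np_id$position_nm[keep])$y,
               tolerance = 1e-9)
  bad <- list(inner_nm = 5, outer_nm = 5, fit_ok = TRUE)
  expect_error(normalize_profile(pr, bad, 1000), "degenerate")
})

test_that("cohort averaging weights calyces, not segments", {
  grid <- seq(-500, 1500, 10)
  mk <- function(v, cid) structure(
    data.frame(position_nm = grid, value = rep(v, length(grid))),
    class = c("normalized_profile", "data.frame"), calyx_id = cid,
    segment_id = paste0(cid, "_s", v), mean_thickness_nm = 1000,
    target = "t")
  same <- list(mk(2, "c1"), mk(2, "c2"))
  avg <- average_profiles(same)
  expect_equal(avg$mean, rep(2, length(grid)))
  expect_equal(avg$sd, rep(0, length(grid)))
  two <- list(mk(1, "c1"), mk(3, "c2"))
  avg2 <- average_profiles(two)
  expect_equal(avg2$mean, rep(2, length(grid)))
  expect_equal(avg2$sd, rep(sqrt(2), length(grid)))
  # unbalanced: calyx c1 contributes 3 segments at 1, c2 one segment at 3
  unb <- list(mk(1, "c1"), mk(1, "c1"), mk(1, "c1"), mk(3, "c2"))
  expect_equal(average_profiles(unb)$mean, rep(2, length(grid)))
})

test_that("peak localization recovers Gaussian means exactly and symmetrically", {
  pos <- seq(0, 1000, 5)
  v1 <- 1 + 10 * exp(-(pos - 420)^2 / (2 * 70^2))
  expect_equal(locate_peaks(pos, v1, 1), 420, tolerance = 0.5)
  v2 <- 10 * exp(-(pos - 300)^2 / (2 * 60^2)) +
    10 * exp(-(pos - 700)^2 / (2 * 60^2))
  pk <- locate_peaks(pos, v2, 2)
  expect_equal(pk, c(300, 700), tolerance = 1)
  expect_equal(mean(pk), 500, tolerance = 1)  # symmetric about the centre
  expect_error(locate_peaks(pos, rep(1, length(pos)), 1), "constant")
})

test_that("compare_peaks validates group structure", {
  expect_error(compare_peaks(list(a = c(1, 2))), "2")
  expect_error(compare_peaks(list(a = c(1, 2), b = 3)), "calyces")
  res <- compare_peaks(list(a = c(100, 110, 105), b = c(500, 505, 498)))
  expect_lt(res$p, 1e-4)
})
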