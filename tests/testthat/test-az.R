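mk_flat_image <- function(val = 0, extent = c(3000, 3000), px = 10)
  structure(list(pixels = matrix(val, extent[2] / px, extent[1] / px),
                 pixel_size_nm = px, origin_nm = c(0, 0),
                 blur_sigma_nm = 0, n_excluded = 0),
            class = "rendered_image")

mk_fit <- function(inner = 100, outer = 1100) list(
  inner_nm = inner, outer_nm = outer, thickness_nm = outer - inner,
  fit_ok = TRUE, reason = "ok", params = NULL, contiguity = 1)

test_that("zero AZ-marker signal labels every segment AZ_free", {
  segs <- list(straight_segment(c(800, 800)), straight_segment(c(1800, 800)))
  segs[[2]]$segment_id <- "fix_seg02"
  fits <- list(mk_fit(), mk_fit())
  lab <- label_regions(mk_flat_image(0), segs, fits, mode = "auto")
  expect_true(all(lab$class == "AZ_free"))
})

test_that("dense AZ-marker signal under a segment labels it AZ_positive", {
  segs <- list(straight_segment(c(500, 800)), straight_segment(c(1500, 800)),
               straight_segment(c(2500, 800)))
  segs[[2]]$segment_id <- "fix_seg02"
  segs[[3]]$segment_id <- "fix_seg03"
  fits <- list(mk_fit(), mk_fit(), mk_fit())
  img <- mk_flat_image(1)
  # strong signal near the inner border (y ~ 800 + 100) under segment 1 only
  img$pixels[85:100, 15:85] <- 50
  lab <- label_regions(img, segs, fits, mode = "auto")
  expect_equal(lab$class, c("AZ_positive", "AZ_free", "AZ_free"))
})

test_that("manual labels round-trip and unknown segments are rejected", {
  segs <- list(straight_segment())
  fits <- list(mk_fit())
  man <- data.frame(segment_id = "fix_seg01", class = "AZ_positive")
  lab <- label_regions(segments = segs, fits = fits, mode = "manual",
                       manual_labels = man)
  expect_equal(lab$class, "AZ_positive")
  expect_equal(lab$basis, "manual")
  bad <- data.frame(segment_id = "nope", class = "AZ_free")
  expect_error(label_regions(segments = segs, fits = fits, mode = "manual",
                             manual_labels = bad), "unknown segment")
})

test_that("stratified profiles split by class and warn on empty classes", {
  grid <- seq(-500, 1500, 10)
  mk_np <- function(v, sid) structure(
    data.frame(position_nm = grid, value = rep(v, length(grid))),
    class = c("normalized_profile", "data.frame"), calyx_id = "c1",
    segment_id = sid, mean_thickness_nm = 1000, target = "t")
  prof <- list(mk_np(1, "s1"), mk_np(3, "s2"))
  labels <- data.frame(segment_id = c("s1", "s2"),
                       class = c("AZ_positive", "AZ_free"))
  st <- stratified_profiles(prof, labels)
  expect_equal(st$AZ_positive$mean[1], 1)
  expect_equal(st$AZ_free$mean[1], 3)
  labels2 <- data.frame(segment_id = c("s1", "s2"), class = "AZ_positive")
  expect_warning(stratified_profiles(prof, labels2), "AZ_free")
})

test_that("colocalization matrix has C(n,2) pairs per triangle and unit diagonal", {
  set.seed(81)
  n_t <- 14
  base <- mk_flat_image(0, extent = c(3000, 2400), px = 20)
  imgs <- lapply(seq_len(n_t), function(i) {
    im <- base; im$pixels[] <- runif(length(im$pixels)); im
  })
  names(imgs) <- paste0("t", seq_len(n_t))
  segs <- list(straight_segment(c(1000, 600)), straight_segment(c(2000, 600)))
  segs[[2]]$segment_id <- "fix_seg02"
  fits <- list(mk_fit(0, 1000), mk_fit(0, 1000))
  labels <- data.frame(segment_id = c("fix_seg01", "fix_seg02"),
                       class = c("AZ_positive", "AZ_free"))
  cm <- colocalization_matrix(imgs, segs, fits, labels, min_pixels = 20)
  expect_equal(length(unique(cm$per_selection$pair)), choose(n_t, 2))
  expect_equal(sum(!is.na(cm$matrix[upper.tri(cm$matrix)])), choose(n_t, 2))
  expect_equal(sum(!is.na(cm$matrix[lower.tri(cm$matrix)])), choose(n_t, 2))
  expect_equal(unname(diag(cm$matrix)), rep(1, n_t))
  expect_true(all(abs(cm$per_selection$r) <= 1, na.rm = TRUE))
})

test_that("a target against its identical copy gives r = 1 in both triangles", {
  im <- mk_flat_image(0, extent = c(3000, 2400), px = 20)
  set.seed(82)
  im$pixels[] <- runif(length(im$pixels))
  imgs <- list(a = im, b = im)
  segs <- list(straight_segment(c(1000, 600)), straight_segment(c(2000, 600)))
  segs[[2]]$segment_id <- "fix_seg02"
  fits <- list(mk_fit(0, 1000), mk_fit(0, 1000))
  labels <- data.frame(segment_id = c("fix_seg01", "fix_seg02"),
                       class = c("AZ_positive", "AZ_free"))
  cm <- colocalization_matrix(imgs, segs, fits, labels, min_pixels = 20)
  expect_equal(cm$matrix["a", "b"], 1, tolerance = 1e-9)
  expect_equal(cm$matrix["b", "a"], 1, tolerance = 1e-9)
})

test_that("independent uniform targets have near-zero mean colocalization", {
  set.seed(83)
  rs <- replicate(20, {
    n <- 4000
    t1 <- points_table(runif(n, 0, 3000), runif(n, 0, 2400),
                       frame = rep(0, n), field = c(3000, 2400))
    t2 <- points_table(runif(n, 0, 3000), runif(n, 0, 2400),
                       frame = rep(0, n), field = c(3000, 2400))
    i1 <- render_2d(t1, 20, 20); i2 <- render_2d(t2, 20, 20)
    poly <- cbind(c(200, 2800, 2800, 200), c(200, 200, 2200, 2200))
    pearson_r(i1, i2, poly)
  })
  expect_lt(abs(mean(rs)), 0.1)
})

test_that("class comparison of per-selection r values uses the t oracle", {
  per <- rbind(
    data.frame(a = "x", b = "y", pair = "x|y", class = "AZ_positive",
               segment_id = paste0("p", 1:3), r = c(0.1, 0.12, 0.11)),
    data.frame(a = "x", b = "y", pair = "x|y", class = "AZ_free",
               segment_id = paste0("f", 1:3), r = c(0.8, 0.82, 0.81)))
  cm <- structure(list(targets = c("x", "y"), matrix = NULL, n = NULL,
                       per_selection = per), class = "coloc_matrix")
  res <- compare_colocalization(cm)
  expect_lt(res$p, 1e-4)
  expect_true(res$significant)
  ref <- t.test(c(0.1, 0.12, 0.11), c(0.8, 0.82, 0.81), var.equal = TRUE)
  expect_equal(res$t, unname(ref$statistic), tolerance = 1e-6)
  # identical classes: p = 1
  per2 <- per; per2$r <- rep(c(0.5, 0.52, 0.51), 2)
  cm2 <- structure(list(targets = c("x", "y"), matrix = NULL, n = NULL,
                        per_selection = per2), class = "coloc_matrix")
  expect_equal(compare_colocalization(cm2)$p, 1, tolerance = 1e-9)
})
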