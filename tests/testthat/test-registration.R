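# direct evaluation of the registration-error definition, kept independent
# of the package implementation
re_oracle <- function(delta) mean(abs(mean(delta) - delta))

test_that("bead extraction recovers well-separated clusters at CLT accuracy", {
  set.seed(101)
  centres <- data.frame(x = c(2000, 7000, 12000), y = c(3000, 9000, 4000))
  n <- 100; s <- 5
  df <- do.call(rbind, lapply(1:3, function(i)
    data.frame(x_nm = rnorm(n, centres$x[i], s),
               y_nm = rnorm(n, centres$y[i], s))))
  tab <- points_table(df$x_nm, df$y_nm, frame = seq_len(3 * n) - 1,
                      field = c(15000, 15000))
  fs <- extract_bead_positions(tab)
  expect_equal(nrow(fs), 3)
  ord <- order(fs$x_nm)
  expect_lt(max(abs(fs$x_nm[ord] - sort(centres$x))), 4 * s / sqrt(n))

  # single localization below m_min yields no bead
  single <- points_table(100, 100, frame = 0)
  expect_error(extract_bead_positions(single, m_min = 10), "no fiducial")

  # a duplicate cluster shifted by 1 nm merges at the default link radius
  df2 <- rbind(df, data.frame(x_nm = df$x_nm + 1, y_nm = df$y_nm))
  tab2 <- points_table(df2$x_nm, df2$y_nm, frame = seq_len(6 * n) - 1,
                       field = c(15000, 15000))
  expect_equal(nrow(extract_bead_positions(tab2)), 3)
})

test_that("mutual-nearest matching gates on distance and pair count", {
  ref <- fiducial_set(data.frame(x_nm = c(0, 5000, 10000, 2000, 8000),
                                 y_nm = c(0, 1000, 3000, 7000, 9000)))
  m0 <- match_fiducials(ref, ref)
  expect_equal(nrow(m0), 5)
  expect_equal(m0$dist_nm, rep(0, 5))
  mov <- fiducial_set(data.frame(x_nm = ref$x_nm + 100, y_nm = ref$y_nm),
                      round_index = 2)
  m1 <- match_fiducials(ref, mov, max_dist_nm = 500)
  expect_equal(nrow(m1), 5)
  # a spurious far-away bead is excluded by the gate
  mov2 <- fiducial_set(rbind(as.data.frame(mov)[, c("x_nm", "y_nm")],
                             data.frame(x_nm = 1e5, y_nm = 1e5)))
  m2 <- match_fiducials(ref, mov2, max_dist_nm = 500)
  expect_equal(nrow(m2), 5)
  # fewer than 3 matches is an error
  tiny_ref <- fiducial_set(data.frame(x_nm = c(0, 5000), y_nm = c(0, 0)))
  tiny_mov <- fiducial_set(data.frame(x_nm = c(0, 5000) + 2000,
                                      y_nm = c(0, 0)))
  expect_error(match_fiducials(tiny_ref, tiny_mov, max_dist_nm = 100),
               "fewer than 3")
})

test_that("shift estimation is the mean displacement with the ref - mov sign", {
  mk_pairs <- function(dx) data.frame(
    ref_id = seq_along(dx), mov_id = seq_along(dx),
    x_ref = 1000 + dx, y_ref = rep(0, length(dx)),
    x_mov = rep(1000, length(dx)), y_mov = rep(0, length(dx)),
    dist_nm = abs(dx))
  expect_equal(estimate_shift(mk_pairs(c(-1, -1, -1)))$dx_nm, -1)
  expect_equal(estimate_shift(mk_pairs(c(-1, -3, -2)))$dx_nm, -2)
})

test_that("shift estimation is translation-equivariant", {
  set.seed(55)
  ref <- fiducial_set(data.frame(x_nm = runif(5, 0, 1e4),
                                 y_nm = runif(5, 0, 1e4)))
  mov <- fiducial_set(data.frame(x_nm = ref$x_nm + 40, y_nm = ref$y_nm - 70))
  s0 <- estimate_shift(match_fiducials(ref, mov))
  mov2 <- mov; mov2$x_nm <- mov2$x_nm + 30; mov2$y_nm <- mov2$y_nm + 10
  s1 <- estimate_shift(match_fiducials(ref, mov2))
  expect_equal(s1$dx_nm, s0$dx_nm - 30, tolerance = 1e-9)
  expect_equal(s1$dy_nm, s0$dy_nm - 10, tolerance = 1e-9)
})

test_that("registration error matches hand-evaluated and random oracles", {
  mk_pairs <- function(dx, dy = rep(0, length(dx))) data.frame(
    x_ref = dx, y_ref = dy, x_mov = rep(0, length(dx)),
    y_mov = rep(0, length(dx)))
  expect_equal(unname(registration_error(mk_pairs(c(-1, -1)))["re_x"]), 0)
  expect_equal(unname(registration_error(mk_pairs(c(-1, -3)))["re_x"]), 1)
  expect_equal(unname(registration_error(mk_pairs(c(0, 2, 4)))["re_x"]),
               4 / 3)
  expect_error(registration_error(mk_pairs(5)), "fewer than 2")
  set.seed(77)
  for (i in 1:100) {
    n <- sample(3:12, 1)
    dx <- rnorm(n, 0, 50); dy <- rnorm(n, 0, 50)
    re <- registration_error(mk_pairs(dx, dy))
    expect_equal(unname(re["re_x"]), re_oracle(dx), tolerance = 1e-9)
    expect_equal(unname(re["re_y"]), re_oracle(dy), tolerance = 1e-9)
  }
})

test_that("registration error is invariant under global translation", {
  set.seed(78)
  p <- data.frame(x_ref = rnorm(6, 0, 100), y_ref = rnorm(6, 0, 100),
                  x_mov = rnorm(6, 0, 100), y_mov = rnorm(6, 0, 100))
  re0 <- registration_error(p)
  p2 <- p; p2$x_mov <- p2$x_mov + 1234; p2$y_ref <- p2$y_ref - 987
  expect_equal(registration_error(p2), re0, tolerance = 1e-9)
})

test_that("apply_shift is exact and invertible", {
  tb <- points_table(c(10, 20), c(30, 40), frame = 0:1)
  s <- list(dx_nm = 5.5, dy_nm = -2.25)
  expect_equal(apply_shift(tb, list(dx_nm = 0, dy_nm = 0))$x_nm, tb$x_nm)
  back <- apply_shift(apply_shift(tb, s),
                      list(dx_nm = -s$dx_nm, dy_nm = -s$dy_nm))
  expect_equal(back$x_nm, tb$x_nm, tolerance = 1e-9)
  expect_equal(back$y_nm, tb$y_nm, tolerance = 1e-9)
})

test_that("registration matrix has the documented triangle layout", {
  beads <- data.frame(x_nm = c(0, 5000, 10000, 2000, 8000),
                      y_nm = c(0, 1000, 3000, 7000, 9000))
  sets <- lapply(1:2, function(r) fiducial_set(beads, round_index = r))
  rep2 <- registration_matrix(sets)
  expect_equal(rep2$matrix, matrix(0, 2, 2, dimnames = list(1:2, 1:2)))
  # 11 rounds: 55 populated cells per triangle
  set.seed(90)
  sets11 <- lapply(1:11, function(r) {
    b <- beads; b$x_nm <- b$x_nm + rnorm(5, 0, 10)
    b$y_nm <- b$y_nm + rnorm(5, 0, 10)
    fiducial_set(b, round_index = r)
  })
  rep11 <- registration_matrix(sets11)
  expect_equal(sum(upper.tri(rep11$matrix) & !is.na(rep11$matrix)), 55)
  expect_equal(sum(lower.tri(rep11$matrix) & !is.na(rep11$matrix)), 55)
  expect_true(all(rep11$matrix >= 0, na.rm = TRUE))
  # symmetric in the pair, per axis
  expect_equal(rep11$re_x, t(rep11$re_x))
  expect_equal(rep11$re_y, t(rep11$re_y))
})

test_that("expected RE under bead jitter follows the folded-normal oracle", {
  # dx_i ~ N(shift, 2 sigma_f^2): E|dx - mean| = sigma_f sqrt(2) sqrt(2/pi)
  # with the (n-1)/n finite-sample factor
  sigma_f <- 10; n <- 5
  expected <- sigma_f * sqrt(2) * sqrt(2 / pi) * sqrt((n - 1) / n)
  set.seed(123)
  res <- replicate(200, {
    base <- data.frame(x_nm = runif(n, 0, 1e4), y_nm = runif(n, 0, 1e4))
    a <- fiducial_set(data.frame(x_nm = base$x_nm + rnorm(n, 0, sigma_f),
                                 y_nm = base$y_nm + rnorm(n, 0, sigma_f)))
    b <- fiducial_set(data.frame(x_nm = base$x_nm + rnorm(n, 0, sigma_f) + 50,
                                 y_nm = base$y_nm + rnorm(n, 0, sigma_f)),
                      round_index = 2)
    registration_error(match_fiducials(a, b))[["re_x"]]
  })
  expect_lt(abs(mean(res) - expected) / expected, 0.15)
})

test_that("registration of generator rounds cancels the true offsets", {
  scene <- tiny_scene(0.2)
  ex <- tiny_experiment(seed = 19, round_offsets = rbind(c(0, 0), c(120, -80)),
                        drift = list(type = "none"), fiducial_jitter_nm = 10)
  ds <- generate_experiment(scene, ex)
  sets <- lapply(ds$rounds, function(r) extract_bead_positions(r$fiducials))
  sh <- estimate_shift(match_fiducials(sets[[1]], sets[[2]]))
  reg <- apply_shift(ds$rounds$SR2$fiducials, sh)
  # post-registration mean fiducial residual below the per-bead jitter
  s1 <- extract_bead_positions(ds$rounds$SR1$fiducials)
  s2 <- extract_bead_positions(reg)
  m <- match_fiducials(s1, s2, max_dist_nm = 200)
  expect_lt(mean(m$dist_nm), ex$fiducial_jitter_nm)
})
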