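test_that("uniform-profile molecule counts follow the Poisson oracle", {
  d <- 150
  scene <- scene_spec(targets = list(
    target_spec("uni", uniform_weight = 1, density_um2 = d)))
  truth <- build_scene(scene, seed = 5)
  A <- pi * (truth$outer_radius_nm^2 - truth$inner_radius_nm^2) / 1e6
  expect_lt(abs(nrow(truth$molecules) - d * A), 4 * sqrt(d * A))
})

test_that("a Gaussian profile at the inner border stays near it", {
  sdu <- 0.03
  scene <- scene_spec(targets = list(
    target_spec("mem", data.frame(mean = 0, sd = sdu, weight = 1),
                density_um2 = 300)))
  truth <- build_scene(scene, seed = 6)
  r <- sqrt((truth$molecules$x_nm - truth$centre_nm[1])^2 +
              (truth$molecules$y_nm - truth$centre_nm[2])^2)
  dist_inner <- abs(r - truth$inner_radius_nm)
  frac <- mean(dist_inner <= 2 * sdu * scene$calyx_thickness_nm)
  expect_gte(frac, 0.90)
})

test_that("az_enrichment = 1 leaves density near AZ patches unchanged", {
  az <- data.frame(angle_rad = c(0.5, 2.5, 4.5), arc_len_nm = 500)
  mk <- function(enr, seed) {
    scene <- scene_spec(az_patches = az, targets = list(
      target_spec("uni", uniform_weight = 1, density_um2 = 300,
                  az_enrichment = enr, az_range_nm = 500)))
    build_scene(scene, seed = seed)
  }
  t1 <- mk(1, 21)
  # area fraction near AZ estimated from an independent unenriched draw
  t_ref <- mk(1, 22)
  n1 <- sum(t1$molecules$az_dist_nm <= 500)
  n2 <- sum(t_ref$molecules$az_dist_nm <= 500)
  pt <- prop.test(c(n1, n2), c(nrow(t1$molecules), nrow(t_ref$molecules)))
  expect_gt(pt$p.value, 0.01)
  # and enrichment = 2 visibly raises that fraction
  t2 <- mk(2, 23)
  expect_gt(mean(t2$molecules$az_dist_nm <= 500),
            1.4 * mean(t1$molecules$az_dist_nm <= 500))
})

test_that("radial histogram matches the analytic profile law (chi-square)", {
  scene <- scene_spec(targets = list(
    target_spec("uni", uniform_weight = 1, density_um2 = 6000)))
  truth <- build_scene(scene, seed = 9)
  u <- truth$molecules$u
  expect_gt(length(u), 5e4)
  h <- hist(u, breaks = seq(0, 1, 0.05), plot = FALSE)
  ct <- chisq.test(h$counts, p = rep(0.05, 20))
  expect_gt(ct$p.value, 0.01)
})

test_that("noise-free single-blink round reproduces molecule positions", {
  scene <- tiny_scene(0.3)
  ex <- tiny_experiment(seed = 4, loss_per_round = 0,
                        round_offsets = matrix(0, 2, 2),
                        drift = list(type = "none"),
                        blinking = list(mean_locs = 1,
                                        sigma_loc_nm = 1e-9))
  truth <- build_scene(scene, seed = ex$seed)
  rr <- simulate_round(truth, 1, ex)
  tab <- rr$tables$WGA
  mol <- truth$molecules[truth$molecules$target == "WGA", ]
  expect_equal(nrow(tab), nrow(mol))
  expect_equal(sort(tab$x_nm), sort(mol$x_nm), tolerance = 1e-6)
})

test_that("per-round localization counts follow the loss model", {
  scene <- tiny_scene(0.5)
  loss <- 0.1; mean_k <- 3
  rounds <- data.frame(round = 1:6, channel = "Ch1", target = "WGA")
  ex <- experiment_spec(rounds, seed = 8, loss_per_round = loss,
                        drift = list(type = "none"),
                        blinking = list(mean_locs = mean_k,
                                        sigma_loc_nm = 7.5))
  truth <- build_scene(scene, seed = ex$seed)
  N <- sum(truth$molecules$target == "WGA")
  for (r in c(1, 4, 6)) {
    tab <- simulate_round(truth, r, ex)$tables$WGA
    expected <- N * (1 - loss)^(r - 1) * mean_k
    # var of sum of k over Bernoulli-retained molecules, CLT bound
    sd_bound <- sqrt(N * ((1 - loss)^(r - 1)) * (mean_k - 1 + mean_k^2))
    expect_lt(abs(nrow(tab) - expected), 4 * sd_bound)
  }
})

test_that("round offsets appear as mean fiducial displacements", {
  scene <- tiny_scene(0.2)
  jit <- 10
  ex <- tiny_experiment(seed = 12,
                        round_offsets = rbind(c(0, 0), c(100, 0)),
                        fiducial_jitter_nm = jit,
                        drift = list(type = "none"))
  truth <- build_scene(scene, seed = ex$seed)
  fid <- place_fiducials(scene, 5, ex$seed)
  r1 <- simulate_round(truth, 1, ex, fid)$fiducials
  r2 <- simulate_round(truth, 2, ex, fid)$fiducials
  n <- nrow(r1)
  dmean <- mean(r2$x_nm) - mean(r1$x_nm)
  expect_lt(abs(dmean - 100), 4 * jit / sqrt(n) * sqrt(2))
})

test_that("generation is deterministic and writes a complete dataset", {
  scene <- tiny_scene(0.2)
  ex <- tiny_experiment(seed = 33)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  ds1 <- generate_experiment(scene, ex, out_dir = d1)
  ds2 <- generate_experiment(scene, ex, out_dir = d2)
  expect_identical(ds1$truth$molecules, ds2$truth$molecules)
  f1 <- sort(list.files(d1)); f2 <- sort(list.files(d2))
  expect_identical(f1, f2)
  for (f in f1)
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  # written dataset reads back
  back <- read_dataset(d1)
  expect_equal(back$round_ids, c(1, 2))
  expect_equal(nrow(back$rounds$SR1$tables$WGA), nrow(ds1$rounds$SR1$tables$WGA))
})

test_that("a 10-round 2-channel design emits 20 target + 10 fiducial tables", {
  targets <- lapply(1:20, function(i)
    target_spec(paste0("t", i), uniform_weight = 1, density_um2 = 2))
  scene <- scene_spec(targets = targets)
  rounds <- data.frame(round = rep(1:10, each = 2),
                       channel = rep(c("Ch1", "Ch2"), 10),
                       target = paste0("t", 1:20))
  ex <- experiment_spec(rounds, seed = 2,
                        blinking = list(mean_locs = 1.2, sigma_loc_nm = 7.5))
  d <- withr::local_tempdir()
  generate_experiment(scene, ex, out_dir = d)
  expect_length(list.files(d, "^round[0-9]+_"), 20)
  expect_length(list.files(d, "^fiducials_"), 10)
})

test_that("duplicate target-round assignments are rejected", {
  rounds <- data.frame(round = c(1, 1), channel = c("Ch1", "Ch2"),
                       target = c("a", "a"))
  expect_error(experiment_spec(rounds), "duplicate target-round")
  rounds2 <- data.frame(round = c(1, 1), channel = c("Ch1", "Ch1"),
                        target = c("a", "b"))
  expect_error(experiment_spec(rounds2), "duplicate round/channel")
})

test_that("the calyx-16 preset generates and validates", {
  preset <- calyx16_preset(seed = 1, density_scale = 0.05)
  expect_length(preset$scene$targets, 16)
  ds <- generate_experiment(preset$scene, preset$exp)
  expect_length(ds$rounds, 10)
  n_tabs <- sum(vapply(ds$rounds, function(r) length(r$tables), integer(1)))
  expect_equal(n_tabs, 16)
  for (r in ds$rounds) expect_s3_class(validate_loc_table(r$fiducials),
                                       "loc_table")
})
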