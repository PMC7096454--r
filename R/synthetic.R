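#' Synthetic calyx scene specification
#'
#' Describes the ground-truth geometry the generator emulates: a presynaptic
#' calyx of Held cross-section modeled as an annulus around a postsynaptic
#' disk, with active-zone (AZ) patches as arcs on the inner (synaptic)
#' membrane, and a set of labeled targets with radial density profiles.
#'
#' Radial profiles are expressed over normalized calyx depth `u`: 0 at the
#' inner synaptic border, 1 at the outer border.  Gaussian components may
#' have means outside `[0, 1]` to represent e.g. postsynaptic contributions
#' (`u < 0`).
#'
#' @param post_radius_nm radius of the postsynaptic disk = inner calyx
#'   border radius (nm).
#' @param calyx_thickness_nm inner-to-outer membrane distance (nm);
#'   default 987.2, the mean thickness of a calyx cross-section cohort.
#' @param membrane_sigma_nm radial spread of membrane-bound labels (nm).
#' @param az_patches data.frame with columns `angle_rad` (arc centre) and
#'   `arc_len_nm` (arc length on the inner membrane); patches must not
#'   overlap.
#' @param targets list of [target_spec()] objects.
#' @param field_extent numeric length 2 (nm); default leaves a 1500 nm
#'   margin around the outer border.
#' @return object of class `scene_spec`.
#' @export
scene_spec <- function(post_radius_nm = 2000,
                       calyx_thickness_nm = 987.2,
                       membrane_sigma_nm = 30,
                       az_patches = NULL,
                       targets = list(),
                       field_extent = NULL) {
  stopifnot(post_radius_nm > 0, calyx_thickness_nm > 0, membrane_sigma_nm > 0)
  if (is.null(az_patches))
    az_patches <- data.frame(angle_rad = numeric(0), arc_len_nm = numeric(0))
  if (nrow(az_patches)) {
    stopifnot(all(az_patches$arc_len_nm > 0))
    # non-overlap on the circle
    half <- (az_patches$arc_len_nm / 2) / post_radius_nm
    a <- sort(az_patches$angle_rad %% (2 * pi))
    o <- order(az_patches$angle_rad %% (2 * pi))
    hh <- half[o]
    if (nrow(az_patches) > 1) {
      gaps <- diff(c(a, a[1] + 2 * pi))
      if (any(gaps < hh + c(hh[-1], hh[1])))
        stop("AZ patches overlap")
    }
  }
  if (is.null(field_extent)) {
    ext <- 2 * (post_radius_nm + calyx_thickness_nm + 1500)
    field_extent <- c(ext, ext)
  }
  nm <- vapply(targets, function(t) t$name, character(1))
  if (anyDuplicated(nm)) stop("duplicate target names in scene")
  structure(list(
    post_radius_nm = post_radius_nm,
    calyx_thickness_nm = calyx_thickness_nm,
    membrane_sigma_nm = membrane_sigma_nm,
    az_patches = az_patches,
    targets = targets,
    field_extent = field_extent
  ), class = "scene_spec")
}

#' Target specification for the synthetic scene
#'
#' @param name target label (e.g. "WGA", "VGlut1").
#' @param components data.frame with columns `mean`, `sd`, `weight`:
#'   Gaussian mixture components of the radial profile over normalized
#'   depth u (0 = inner synaptic border, 1 = outer border).
#' @param uniform_weight weight of a uniform-on-`[0,1]` profile component.
#' @param density_um2 molecules per square micrometre of calyx
#'   cross-section (annulus area).
#' @param az_enrichment multiplicative density factor applied within
#'   `az_range_nm` of an AZ patch (1 = none; < 1 depletes).
#' @param az_range_nm enrichment radius around AZ patches (nm);
#'   default 500.
#' @return object of class `target_spec`.
#' @export
target_spec <- function(name, components = NULL, uniform_weight = 0,
                        density_um2 = 100, az_enrichment = 1,
                        az_range_nm = 500) {
  if (is.null(components))
    components <- data.frame(mean = numeric(0), sd = numeric(0),
                             weight = numeric(0))
  stopifnot(all(components$weight >= 0), uniform_weight >= 0,
            density_um2 >= 0, az_enrichment >= 0, az_range_nm > 0)
  if (sum(components$weight) + uniform_weight <= 0)
    stop("profile weights must sum to > 0")
  structure(list(name = name, components = components,
                 uniform_weight = uniform_weight, density_um2 = density_um2,
                 az_enrichment = az_enrichment, az_range_nm = az_range_nm),
            class = "target_spec")
}

# sample n normalized depths from a target's radial mixture profile
sample_depth <- function(tg, n) {
  if (n == 0) return(numeric(0))
  w <- c(tg$components$weight, tg$uniform_weight)
  w <- w / sum(w)
  comp <- sample.int(length(w), n, replace = TRUE, prob = w)
  u <- numeric(n)
  k <- nrow(tg$components)
  for (ci in seq_len(k)) {
    idx <- comp == ci
    u[idx] <- stats::rnorm(sum(idx), tg$components$mean[ci],
                           tg$components$sd[ci])
  }
  if (tg$uniform_weight > 0) {
    idx <- comp == k + 1
    u[idx] <- stats::runif(sum(idx))
  }
  u
}

# distance (nm) from points (r, theta) to the nearest AZ arc on the inner
# membrane circle of radius R
az_distance <- function(r, theta, az_patches, R) {
  if (!nrow(az_patches)) return(rep(Inf, length(r)))
  d <- rep(Inf, length(r))
  for (p in seq_len(nrow(az_patches))) {
    phi <- az_patches$angle_rad[p]
    alpha <- (az_patches$arc_len_nm[p] / 2) / R
    dth <- ((theta - phi + pi) %% (2 * pi)) - pi
    inside <- abs(dth) <= alpha
    dp <- numeric(length(r))
    dp[inside] <- abs(r[inside] - R)
    if (any(!inside)) {
      # nearest arc endpoint
      ea <- phi + sign(dth[!inside]) * alpha
      ex <- R * cos(ea); ey <- R * sin(ea)
      px <- r[!inside] * cos(theta[!inside])
      py <- r[!inside] * sin(theta[!inside])
      dp[!inside] <- sqrt((px - ex)^2 + (py - ey)^2)
    }
    d <- pmin(d, dp)
  }
  d
}

#' Place ground-truth molecules for a synthetic scene
#'
#' Molecule counts per target are Poisson with mean `density_um2 x annulus
#' area`; depths are drawn from the target's radial mixture profile
#' (inverse-transform via component sampling), azimuths uniformly.  AZ
#' enrichment/depletion is applied by acceptance-rejection thinning against
#' the local enrichment factor, so the realized density within
#' `az_range_nm` of an AZ patch is the base density times `az_enrichment`.
#'
#' @param scene a [scene_spec()].
#' @param seed integer seed (the placement is fully reproducible).
#' @return object of class `ground_truth`: list with `molecules`
#'   (data.frame `target`, `x_nm`, `y_nm`, `u`, `az_dist_nm`), the scene,
#'   the annulus geometry (`centre_nm`, `inner_radius_nm`,
#'   `outer_radius_nm`) and the seed.
#' @export
build_scene <- function(scene, seed = 1L) {
  stopifnot(inherits(scene, "scene_spec"))
  if (!length(scene$targets)) stop("scene has no targets")
  set.seed(as.integer(seed))
  R_in <- scene$post_radius_nm
  th <- scene$calyx_thickness_nm
  R_out <- R_in + th
  centre <- scene$field_extent / 2
  area_um2 <- pi * (R_out^2 - R_in^2) / 1e6
  mols <- vector("list", length(scene$targets))
  for (ti in seq_along(scene$targets)) {
    tg <- scene$targets[[ti]]
    e <- tg$az_enrichment
    e_max <- max(1, e)
    n_cand <- stats::rpois(1, tg$density_um2 * area_um2 * e_max)
    u <- sample_depth(tg, n_cand)
    r <- R_in + u * th
    # depths far below the postsynaptic centre are unphysical; resample
    bad <- which(r <= 1)
    while (length(bad)) {
      u[bad] <- sample_depth(tg, length(bad))
      r[bad] <- R_in + u[bad] * th
      bad <- bad[r[bad] <= 1]
    }
    theta <- stats::runif(n_cand, 0, 2 * pi)
    d_az <- az_distance(r, theta, scene$az_patches, R_in)
    w <- ifelse(d_az <= tg$az_range_nm, e, 1)
    keep <- stats::runif(n_cand) < w / e_max
    mols[[ti]] <- data.frame(
      target = rep(tg$name, sum(keep)),
      x_nm = centre[1] + (r * cos(theta))[keep],
      y_nm = centre[2] + (r * sin(theta))[keep],
      u = u[keep],
      az_dist_nm = d_az[keep],
      stringsAsFactors = FALSE
    )
  }
  structure(list(
    molecules = do.call(rbind, mols),
    scene = scene,
    centre_nm = centre,
    inner_radius_nm = R_in,
    outer_radius_nm = R_out,
    seed = as.integer(seed)
  ), class = "ground_truth")
}

#' Multi-round acquisition specification
#'
#' @param rounds data.frame with columns `round`, `channel`, `target`
#'   assigning each imaged target to a staining round and spectral channel.
#' @param n_fiducials number of immobile fiducial beads (>= 5; ROIs in a
#'   multiplexing experiment must contain at least five beads for reliable
#'   registration).
#' @param round_offsets matrix `n_rounds x 2` of per-round rigid stage
#'   offsets (dx, dy nm); `NULL` draws them uniformly from
#'   `[-offset_range_nm, offset_range_nm]` (round 1 fixed at 0,0).
#' @param offset_range_nm range for generated offsets; default 200.
#' @param fiducial_jitter_nm per-localization bead jitter sd (nm).
#' @param loss_per_round fractional signal loss per staining round
#'   (e.g. 0.027); retention at round r is `(1 - loss)^(r-1)`.
#' @param drift list: `list(type = "linear", velocity_nm_per_frame =
#'   c(vx, vy))` or `list(type = "random_walk", step_sd_nm = s)`; or
#'   `list(type = "none")`.
#' @param blinking list `list(mean_locs = k, sigma_loc_nm = s)`: each
#'   surviving molecule emits `1 + Poisson(k - 1)` localizations in
#'   consecutive frames, each with isotropic Gaussian error of sd `s`.
#' @param n_frames frames per acquisition (default 20000).
#' @param fid_interval_frames a fiducial localization is emitted every
#'   this many frames (default 100).
#' @param seed experiment seed; every stochastic element derives from it.
#' @return object of class `experiment_spec`.
#' @export
experiment_spec <- function(rounds,
                            n_fiducials = 5L,
                            round_offsets = NULL,
                            offset_range_nm = 200,
                            fiducial_jitter_nm = 10,
                            loss_per_round = 0.03,
                            drift = list(type = "linear",
                                         velocity_nm_per_frame = c(0.005, 0)),
                            blinking = list(mean_locs = 3, sigma_loc_nm = 7.5),
                            n_frames = 20000L,
                            fid_interval_frames = 100L,
                            seed = 1L) {
  rounds <- as.data.frame(rounds)
  stopifnot(all(c("round", "channel", "target") %in% names(rounds)))
  if (anyDuplicated(rounds[c("round", "channel")]))
    stop("duplicate round/channel assignment")
  if (anyDuplicated(rounds[c("round", "target")]))
    stop("duplicate target-round assignment")
  if (n_fiducials < 5L)
    warning("fewer than 5 fiducials: registration will be unreliable",
            call. = FALSE)
  stopifnot(loss_per_round >= 0, loss_per_round < 1,
            blinking$sigma_loc_nm > 0, blinking$mean_locs >= 1)
  n_rounds <- max(rounds$round)
  seed <- as.integer(seed)
  if (is.null(round_offsets)) {
    set.seed(seed + 11L)
    round_offsets <- cbind(
      stats::runif(n_rounds, -offset_range_nm, offset_range_nm),
      stats::runif(n_rounds, -offset_range_nm, offset_range_nm)
    )
    round_offsets[1, ] <- 0
  }
  round_offsets <- matrix(round_offsets, ncol = 2)
  stopifnot(nrow(round_offsets) >= n_rounds)
  structure(list(
    rounds = rounds, n_fiducials = as.integer(n_fiducials),
    round_offsets = round_offsets,
    fiducial_jitter_nm = fiducial_jitter_nm,
    loss_per_round = loss_per_round, drift = drift, blinking = blinking,
    n_frames = as.integer(n_frames),
    fid_interval_frames = as.integer(fid_interval_frames),
    seed = seed
  ), class = "experiment_spec")
}

#' Place immobile fiducial beads
#'
#' Beads are scattered uniformly over the field with a 1000 nm margin and
#' a minimum pairwise separation (imaging regions are chosen so that
#' beads are well separated; closely spaced beads would make the
#' cross-round matching ambiguous).  Positions are shared by every round
#' — the beads are immobile by construction.
#'
#' @param scene a [scene_spec()].
#' @param n_fiducials bead count.
#' @param seed integer seed.
#' @param min_sep_nm minimum pairwise bead distance (nm).
#' @return data.frame `bead_id`, `x_nm`, `y_nm`.
#' @export
place_fiducials <- function(scene, n_fiducials = 5L, seed = 1L,
                            min_sep_nm = 2000) {
  set.seed(as.integer(seed) + 23L)
  fe <- scene$field_extent
  xs <- numeric(0); ys <- numeric(0)
  tries <- 0
  while (length(xs) < n_fiducials && tries < 10000) {
    x <- stats::runif(1, 1000, fe[1] - 1000)
    y <- stats::runif(1, 1000, fe[2] - 1000)
    if (!length(xs) || min((xs - x)^2 + (ys - y)^2) >= min_sep_nm^2) {
      xs <- c(xs, x); ys <- c(ys, y)
    }
    tries <- tries + 1
  }
  if (length(xs) < n_fiducials)
    stop("could not place ", n_fiducials, " beads at ", min_sep_nm,
         " nm separation in this field")
  data.frame(bead_id = seq_len(n_fiducials), x_nm = xs, y_nm = ys)
}

# drift displacement (nm) at given frames for one round; random-walk
# trajectories must be generated under the caller's RNG state
drift_trajectory <- function(drift, n_frames) {
  f <- seq_len(n_frames) - 1
  if (is.null(drift) || identical(drift$type, "none")) {
    return(cbind(dx = numeric(n_frames), dy = numeric(n_frames)))
  }
  if (drift$type == "linear") {
    v <- drift$velocity_nm_per_frame
    return(cbind(dx = v[1] * f, dy = v[2] * f))
  }
  if (drift$type == "random_walk") {
    s <- drift$step_sd_nm
    cbind(dx = c(0, cumsum(stats::rnorm(n_frames - 1, 0, s))),
          dy = c(0, cumsum(stats::rnorm(n_frames - 1, 0, s))))
  } else stop("unknown drift type: ", drift$type)
}

#' Simulate one staining round
#'
#' Each ground-truth molecule of the round's targets survives re-staining
#' with probability `(1 - loss_per_round)^(round - 1)`, then emits
#' `1 + Poisson(mean_locs - 1)` localizations placed in consecutive frames
#' starting at a uniform frame, each displaced by the round's rigid offset,
#' the intra-round drift at its frame, and isotropic Gaussian localization
#' noise.  Fiducial beads emit one localization every
#' `fid_interval_frames` frames with jitter `fiducial_jitter_nm`, subject
#' to the same offset and drift.
#'
#' The round is simulated under its own derived seed
#' (`seed + 97 * round`), so any round can be regenerated independently
#' and reproducibly.
#'
#' @param truth a [build_scene()] result.
#' @param round_index staining round to simulate (must appear in
#'   `exp$rounds`).
#' @param exp an [experiment_spec()].
#' @param fiducials bead positions from [place_fiducials()]; generated
#'   from the experiment seed when `NULL`.
#' @return list with `tables` (named list of [loc_table()], one per target),
#'   `fiducials` (a [loc_table()] of bead localizations), `offset_nm`,
#'   and `drift` (the per-frame trajectory actually applied).
#' @export
simulate_round <- function(truth, round_index, exp, fiducials = NULL) {
  stopifnot(inherits(truth, "ground_truth"), inherits(exp, "experiment_spec"))
  sel <- exp$rounds[exp$rounds$round == round_index, , drop = FALSE]
  if (!nrow(sel)) stop("round ", round_index, " not defined in experiment spec")
  if (is.null(fiducials))
    fiducials <- place_fiducials(truth$scene, exp$n_fiducials, exp$seed)
  set.seed(exp$seed + 97L * as.integer(round_index))
  offset <- exp$round_offsets[round_index, ]
  drift <- drift_trajectory(exp$drift, exp$n_frames)
  retain_p <- (1 - exp$loss_per_round)^(round_index - 1)
  sigma <- exp$blinking$sigma_loc_nm
  mean_k <- exp$blinking$mean_locs
  fe <- truth$scene$field_extent

  tables <- list()
  for (i in seq_len(nrow(sel))) {
    tgt <- sel$target[i]
    mol <- truth$molecules[truth$molecules$target == tgt, , drop = FALSE]
    if (!nrow(mol)) stop("target '", tgt, "' absent from ground truth")
    keep <- stats::runif(nrow(mol)) < retain_p
    mol <- mol[keep, , drop = FALSE]
    k <- 1L + stats::rpois(nrow(mol), mean_k - 1)
    start <- floor(stats::runif(nrow(mol), 0, pmax(1, exp$n_frames - k)))
    mi <- rep.int(seq_len(nrow(mol)), k)
    frame <- start[mi] + (sequence(k) - 1)
    n <- length(mi)
    x <- mol$x_nm[mi] + offset[1] + drift[frame + 1, 1] +
      stats::rnorm(n, 0, sigma)
    y <- mol$y_nm[mi] + offset[2] + drift[frame + 1, 2] +
      stats::rnorm(n, 0, sigma)
    tables[[tgt]] <- suppressWarnings(loc_table(
      data.frame(x_nm = x, y_nm = y, z_nm = 0, frame = frame,
                 intensity = stats::rpois(n, 1000)),
      round_index = round_index, channel = sel$channel[i], target = tgt,
      field_extent = fe, n_frames = exp$n_frames
    ))
  }

  ff <- seq(0, exp$n_frames - 1, by = exp$fid_interval_frames)
  bi <- rep(seq_len(nrow(fiducials)), each = length(ff))
  fr <- rep(ff, times = nrow(fiducials))
  nf <- length(bi)
  fx <- fiducials$x_nm[bi] + offset[1] + drift[fr + 1, 1] +
    stats::rnorm(nf, 0, exp$fiducial_jitter_nm)
  fy <- fiducials$y_nm[bi] + offset[2] + drift[fr + 1, 2] +
    stats::rnorm(nf, 0, exp$fiducial_jitter_nm)
  fid_tab <- suppressWarnings(loc_table(
    data.frame(x_nm = fx, y_nm = fy, z_nm = 0, frame = fr,
               intensity = stats::rpois(nf, 5000)),
    round_index = round_index, channel = "fid", target = "fiducial",
    field_extent = fe, n_frames = exp$n_frames
  ))
  list(tables = tables, fiducials = fid_tab, offset_nm = offset,
       drift = drift)
}

#' Generate a complete multi-round synthetic dataset
#'
#' Builds the scene, places fiducials, simulates every round, and (when
#' `out_dir` is given) writes one localization CSV per round x channel, one
#' fiducial CSV per round, the ground-truth molecule table, and a JSON
#' sidecar with the true offsets, geometry and parameters.  Fully
#' reproducible from `exp$seed`.
#'
#' @param scene a [scene_spec()].
#' @param exp an [experiment_spec()].
#' @param out_dir optional output directory.
#' @return object of class `smlm_dataset`: list with `truth`, `fiducials`
#'   (true bead positions), `rounds` (per-round output of
#'   [simulate_round()]), `scene`, `exp`, and `files` when written.
#' @export
generate_experiment <- function(scene, exp, out_dir = NULL) {
  stopifnot(inherits(scene, "scene_spec"), inherits(exp, "experiment_spec"))
  truth <- build_scene(scene, seed = exp$seed)
  fid <- place_fiducials(scene, exp$n_fiducials, exp$seed)
  round_ids <- sort(unique(exp$rounds$round))
  rounds <- lapply(round_ids, function(r)
    simulate_round(truth, r, exp, fiducials = fid))
  names(rounds) <- paste0("SR", round_ids)
  ds <- structure(list(truth = truth, fiducials = fid, rounds = rounds,
                       round_ids = round_ids, scene = scene, exp = exp),
                  class = "smlm_dataset")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    files <- character(0)
    for (r in seq_along(rounds)) {
      rr <- rounds[[r]]
      for (tgt in names(rr$tables)) {
        ch <- attr(rr$tables[[tgt]], "channel")
        f <- file.path(out_dir, sprintf("round%02d_%s_%s.csv",
                                        round_ids[r], ch, gsub("[^A-Za-z0-9]", "_", tgt)))
        write_localizations(rr$tables[[tgt]], f)
        files <- c(files, f)
      }
      f <- file.path(out_dir, sprintf("fiducials_round%02d.csv", round_ids[r]))
      write_localizations(rr$fiducials, f)
      files <- c(files, f)
    }
    gt_file <- file.path(out_dir, "ground_truth_molecules.csv")
    utils::write.csv(truth$molecules, gt_file, row.names = FALSE)
    sidecar <- list(
      seed = exp$seed,
      centre_nm = truth$centre_nm,
      inner_radius_nm = truth$inner_radius_nm,
      outer_radius_nm = truth$outer_radius_nm,
      calyx_thickness_nm = scene$calyx_thickness_nm,
      round_offsets = apply(exp$round_offsets, 1, identity, simplify = FALSE),
      fiducials = fid,
      n_frames = exp$n_frames,
      loss_per_round = exp$loss_per_round,
      sigma_loc_nm = exp$blinking$sigma_loc_nm
    )
    jsonlite::write_json(sidecar, file.path(out_dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "columns")
    ds$files <- c(files, gt_file)
  }
  ds
}

#' @export
print.smlm_dataset <- function(x, ...) {
  cat(sprintf("<smlm_dataset> %d rounds, %d targets, %d ground-truth molecules\n",
              length(x$rounds), length(unique(x$exp$rounds$target)),
              nrow(x$truth$molecules)))
  invisible(x)
}
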