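#' Simulate and analyze a cohort of synthetic calyces
#'
#' Emulates the cohort design of the calyx line-profile analysis: several
#' calyces (each its own synthetic scene with a thickness drawn from the
#' cohort distribution) are imaged, their WGA border profiles fitted and
#' contiguity-filtered, the cohort mean thickness computed from all
#' accepted WGA fits, and every target's profiles normalized onto the
#' average-calyx axis and averaged hierarchically.
#'
#' The membrane trace of each calyx is taken from the generator's true
#' inner-border circle (standing in for the manual WGA tracing step);
#' everything downstream — border fitting, contiguity, normalization,
#' peaks — works only on the rendered images, exactly as for traced real
#' data.
#'
#' @param targets list of [target_spec()]; must include a membrane target
#'   named `wga_target`.
#' @param n_calyces number of calyces in the cohort.
#' @param seed cohort seed; calyx c uses `seed + 1000 * c` internally.
#' @param thickness_mean_nm,thickness_sd_nm cohort thickness distribution
#'   (nm); per-calyx thickness is truncated to `[500, 1700]`.
#' @param post_radius_nm postsynaptic disk radius of each scene.
#' @param az_patches AZ patch table passed to each scene (`NULL` = none).
#' @param wga_target name of the membrane target used for borders.
#' @param profile_thickness_nm lateral profile width (700 for the cohort
#'   profile analysis, 300 for AZ stratification).
#' @param pixel_size_nm,blur_sigma_nm render settings for the profile
#'   images.
#' @param sigma_loc_nm localization precision of the simulated emitters.
#' @param mean_locs mean localizations per molecule.
#' @param contiguity_min contiguity acceptance threshold.
#' @return object of class `calyx_cohort`: list with `calyces` (per-calyx
#'   scene geometry, segments, fits, accepted indices, per-target images),
#'   `mean_thickness_nm` (cohort mean over accepted WGA fits),
#'   `true_thickness_nm` (per-calyx generator truth), `profiles`
#'   (per-target lists of [normalize_profile()] results) and `cohort`
#'   (per-target [average_profiles()] curves).
#' @export
simulate_calyx_cohort <- function(targets,
                                  n_calyces = 9,
                                  seed = 1L,
                                  thickness_mean_nm = 987.2,
                                  thickness_sd_nm = 238.6,
                                  post_radius_nm = 2000,
                                  az_patches = NULL,
                                  wga_target = "WGA",
                                  profile_thickness_nm = 700,
                                  pixel_size_nm = 10,
                                  blur_sigma_nm = 10,
                                  sigma_loc_nm = 7.5,
                                  mean_locs = 3,
                                  contiguity_min = 0.70) {
  tnames <- vapply(targets, function(t) t$name, character(1))
  stopifnot(wga_target %in% tnames)
  calyces <- vector("list", n_calyces)
  for (ci in seq_len(n_calyces)) {
    cseed <- as.integer(seed) + 1000L * ci
    set.seed(cseed)
    th <- min(max(stats::rnorm(1, thickness_mean_nm, thickness_sd_nm),
                  500), 1700)
    scene <- scene_spec(post_radius_nm = post_radius_nm,
                        calyx_thickness_nm = th,
                        az_patches = az_patches, targets = targets)
    # all targets in one acquisition (paired into 2-channel rounds),
    # no loss / offsets / drift: the cohort isolates the profile analysis
    rr <- data.frame(
      round = rep(seq_len(ceiling(length(tnames) / 2)), each = 2)[
        seq_along(tnames)],
      channel = rep(c("Ch1", "Ch2"), length.out = length(tnames)),
      target = tnames, stringsAsFactors = FALSE)
    ex <- experiment_spec(rr, round_offsets = matrix(0, max(rr$round), 2),
                          loss_per_round = 0, drift = list(type = "none"),
                          blinking = list(mean_locs = mean_locs,
                                          sigma_loc_nm = sigma_loc_nm),
                          seed = cseed)
    ds <- generate_experiment(scene, ex)
    tables <- do.call(c, lapply(ds$rounds, function(r) r$tables))
    names(tables) <- sub("^SR[0-9]+\\.", "", names(tables))
    images <- lapply(tables, render_2d, pixel_size_nm = pixel_size_nm,
                     blur_sigma_nm = blur_sigma_nm)
    ang <- seq(0, 2 * pi, length.out = 121)[-121]
    trace <- membrane_trace(
      data.frame(x_nm = ds$truth$centre_nm[1] + post_radius_nm * cos(ang),
                 y_nm = ds$truth$centre_nm[2] + post_radius_nm * sin(ang)),
      calyx_id = sprintf("calyx%02d", ci))
    segs <- segment_trace(trace, thickness_nm = profile_thickness_nm)
    offset_max <- min(2200, th + 900)
    wga_profiles <- lapply(segs, function(s)
      extract_profile(images[[wga_target]], s, offset_max_nm = offset_max))
    fits <- lapply(seq_along(segs), function(i) {
      f <- fit_borders(wga_profiles[[i]])
      if (isTRUE(f$fit_ok))
        f$contiguity <- segment_contiguity(images[[wga_target]],
                                           segs[[i]], f)
      f
    })
    accepted <- apply_contiguity_filter(segs, fits, contiguity_min)
    calyces[[ci]] <- list(calyx_id = trace$calyx_id, truth = ds$truth,
                          true_thickness_nm = th, tables = tables,
                          images = images,
                          segments = segs, wga_profiles = wga_profiles,
                          fits = fits, accepted = accepted,
                          offset_max_nm = offset_max)
  }
  thicknesses <- unlist(lapply(calyces, function(cc)
    vapply(cc$fits[cc$accepted], `[[`, numeric(1), "thickness_nm")))
  if (!length(thicknesses)) stop("no accepted segments in the cohort")
  L_bar <- mean(thicknesses)
  profiles <- stats::setNames(vector("list", length(tnames)), tnames)
  for (tn in tnames) {
    pl <- list()
    for (cc in calyces) {
      for (i in cc$accepted) {
        pr <- if (tn == wga_target) cc$wga_profiles[[i]] else
          extract_profile(cc$images[[tn]], cc$segments[[i]],
                          offset_max_nm = cc$offset_max_nm)
        attr(pr, "target") <- tn
        pl[[length(pl) + 1]] <- normalize_profile(pr, cc$fits[[i]], L_bar)
      }
    }
    profiles[[tn]] <- pl
  }
  cohort <- lapply(profiles, average_profiles)
  structure(list(calyces = calyces, mean_thickness_nm = L_bar,
                 accepted_thicknesses_nm = thicknesses,
                 true_thickness_nm = vapply(calyces, `[[`, numeric(1),
                                            "true_thickness_nm"),
                 profiles = profiles, cohort = cohort,
                 wga_target = wga_target, seed = seed),
            class = "calyx_cohort")
}

#' @export
print.calyx_cohort <- function(x, ...) {
  cat(sprintf(
    "<calyx_cohort> %d calyces, %d accepted segments, mean thickness %.1f nm\n",
    length(x$calyces), length(x$accepted_thicknesses_nm),
    x$mean_thickness_nm))
  invisible(x)
}

#' Per-calyx peak positions for selected targets of a cohort
#'
#' For each calyx, the target's accepted normalized profiles are averaged
#' and the requested number of Gaussian peaks located; the ensemble of
#' per-calyx peak distances to the synaptic membrane (position 0) per
#' target feeds [compare_peaks()].
#'
#' @param cohort a [simulate_calyx_cohort()] result.
#' @param peak_spec named list: target name -> number of peaks; a target
#'   with n peaks contributes n groups named `target` (n = 1) or
#'   `target_p1`, `target_p2`, ... (n > 1).
#' @return named list of per-calyx peak-position vectors (nm), ready for
#'   [compare_peaks()].
#' @export
cohort_peak_positions <- function(cohort, peak_spec) {
  out <- list()
  for (tn in names(peak_spec)) {
    npk <- peak_spec[[tn]]
    prof <- cohort$profiles[[tn]]
    if (is.null(prof)) stop("target not in cohort: ", tn)
    cids <- vapply(prof, function(p) as.character(attr(p, "calyx_id")),
                   character(1))
    peaks <- matrix(NA_real_, nrow = length(unique(cids)), ncol = npk)
    for (k in seq_along(unique(cids))) {
      cid <- unique(cids)[k]
      avg <- average_profiles(prof[cids == cid])
      pk <- tryCatch(locate_peaks(avg$position_nm, avg$mean, n_peaks = npk),
                     error = function(e) rep(NA_real_, npk))
      peaks[k, ] <- pk
    }
    gnames <- if (npk == 1) tn else paste0(tn, "_p", seq_len(npk))
    for (j in seq_len(npk))
      out[[gnames[j]]] <- peaks[, j][!is.na(peaks[, j])]
  }
  out
}

#' Pick the paper-style AZ design: fixed numbers of AZ-positive and
#' AZ-free selections per calyx
#'
#' From auto [label_regions()] output, keeps per calyx the `n_each`
#' segments with the strongest AZ-marker signal as `AZ_positive` and the
#' `n_each` weakest as `AZ_free` (two of each per calyx in the classical
#' design).
#'
#' @param labels [label_regions()] output (auto mode, with `az_signal`).
#' @param calyx_ids calyx of each labeled segment.
#' @param n_each selections per class per calyx.
#' @return relabeled data.frame (rows not selected are dropped).
#' @export
select_az_design <- function(labels, calyx_ids, n_each = 2) {
  stopifnot(nrow(labels) == length(calyx_ids))
  out <- list()
  for (cid in unique(calyx_ids)) {
    d <- labels[calyx_ids == cid & !is.na(labels$az_signal), , drop = FALSE]
    if (nrow(d) < 2 * n_each) next
    d <- d[order(d$az_signal, decreasing = TRUE), ]
    top <- d[seq_len(n_each), ]
    bot <- d[seq(nrow(d) - n_each + 1, nrow(d)), ]
    top$class <- "AZ_positive"; bot$class <- "AZ_free"
    out[[cid]] <- rbind(top, bot)
  }
  do.call(rbind, out)
}

#' AZ-stratified cohort analysis
#'
#' Runs the AZ arm of the calyx analysis on a cohort generated with AZ
#' patches and 300 nm profile thickness: segments are auto-labeled from
#' the AZ-marker image, the paper-style design (two AZ-positive and two
#' AZ-free selections per calyx) selected, per-class stratified cohort
#' profiles computed for every target, and the per-selection Pearson r of
#' requested target pairs compared between classes with the unpaired t
#' test.
#'
#' @param cohort a [simulate_calyx_cohort()] result (generated with
#'   `az_patches` and `profile_thickness_nm = 300`).
#' @param az_marker target name of the AZ marker (default "bassoon").
#' @param coloc_pairs list of 2-element character vectors of target pairs
#'   for the colocalization comparison; `NULL` = all pairs.
#' @param coloc_pixel_nm,coloc_blur_nm render settings for the
#'   colocalization images.
#' @param n_each selections per class per calyx.
#' @return list with `labels`, `stratified` (per target: AZ_positive /
#'   AZ_free cohort curves), `coloc` ([colocalization_matrix()] result)
#'   and `tests` ([compare_colocalization()] output).
#' @export
az_cohort_analysis <- function(cohort, az_marker = "bassoon",
                               coloc_pairs = NULL,
                               coloc_pixel_nm = 20, coloc_blur_nm = 20,
                               n_each = 2) {
  all_segs <- list(); all_fits <- list(); all_cids <- character(0)
  raw_labels <- list()
  for (cc in cohort$calyces) {
    if (!length(cc$accepted)) next
    segs <- cc$segments[cc$accepted]
    fits <- cc$fits[cc$accepted]
    lab <- label_regions(cc$images[[az_marker]], segs, fits, mode = "auto")
    raw_labels[[cc$calyx_id]] <- lab
    all_segs <- c(all_segs, segs)
    all_fits <- c(all_fits, fits)
    all_cids <- c(all_cids, rep(cc$calyx_id, length(segs)))
  }
  labels_all <- do.call(rbind, raw_labels)
  design <- select_az_design(labels_all, all_cids, n_each = n_each)
  # stratified profiles per target
  strat <- list()
  for (tn in names(cohort$profiles)) {
    strat[[tn]] <- suppressWarnings(
      stratified_profiles(cohort$profiles[[tn]], design))
  }
  # colocalization on per-calyx re-renders at the coloc settings
  per_rows <- list()
  tnames <- names(cohort$profiles)
  if (is.null(coloc_pairs))
    coloc_pairs <- utils::combn(tnames, 2, simplify = FALSE)
  for (cc in cohort$calyces) {
    keep <- which(vapply(cc$segments, function(s)
      s$segment_id %in% design$segment_id, logical(1)))
    if (!length(keep)) next
    imgs <- list()
    for (pp in coloc_pairs) for (tn in pp) if (is.null(imgs[[tn]]))
      imgs[[tn]] <- render_2d(cc$tables[[tn]],
                              pixel_size_nm = coloc_pixel_nm,
                              blur_sigma_nm = coloc_blur_nm)
    for (i in keep) {
      seg <- cc$segments[[i]]
      fit <- cc$fits[[i]]
      if (!isTRUE(fit$fit_ok)) next
      cls <- design$class[match(seg$segment_id, design$segment_id)]
      poly <- segment_polygon(seg, fit)
      for (pp in coloc_pairs) {
        r <- tryCatch(pearson_r(imgs[[pp[1]]], imgs[[pp[2]]], poly,
                                min_pixels = 20),
                      error = function(e) NA_real_)
        per_rows[[length(per_rows) + 1]] <- data.frame(
          a = pp[1], b = pp[2], pair = paste(pp, collapse = "|"),
          class = cls, segment_id = seg$segment_id, r = as.numeric(r))
      }
    }
  }
  per <- do.call(rbind, per_rows)
  coloc <- structure(list(targets = tnames,
                          matrix = NULL, n = NULL, per_selection = per),
                     class = "coloc_matrix")
  # fill matrix from per-selection values
  m <- matrix(NA_real_, length(tnames), length(tnames),
              dimnames = list(tnames, tnames))
  diag(m) <- 1
  if (!is.null(per)) {
    agg <- stats::aggregate(r ~ a + b + class, data = per[!is.na(per$r), ],
                            FUN = mean)
    for (i in seq_len(nrow(agg))) {
      ia <- match(agg$a[i], tnames); ib <- match(agg$b[i], tnames)
      if (agg$class[i] == "AZ_positive")
        m[min(ia, ib), max(ia, ib)] <- agg$r[i]
      else m[max(ia, ib), min(ia, ib)] <- agg$r[i]
    }
  }
  coloc$matrix <- m
  tests <- compare_colocalization(coloc)
  list(labels = design, stratified = strat, coloc = coloc, tests = tests)
}
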