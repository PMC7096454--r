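#' Membrane trace
#'
#' Ordered polyline (nm) along the apposed pre-/postsynaptic membranes of
#' one calyx, as drawn on a WGA image.  Traces are input data; automatic
#' membrane segmentation is out of scope.
#'
#' @param vertices data.frame with `x_nm`, `y_nm` (>= 2 rows, consecutive
#'   vertices distinct).
#' @param calyx_id calyx identifier.
#' @param experiment_id experiment identifier.
#' @return object of class `membrane_trace`.
#' @export
membrane_trace <- function(vertices, calyx_id = "calyx1",
                           experiment_id = "exp1") {
  vertices <- as.data.frame(vertices)[c("x_nm", "y_nm")]
  if (nrow(vertices) < 2) stop("a membrane trace needs >= 2 vertices")
  step <- sqrt(diff(vertices$x_nm)^2 + diff(vertices$y_nm)^2)
  if (any(step == 0)) stop("consecutive trace vertices must be distinct")
  structure(list(vertices = vertices, calyx_id = calyx_id,
                 experiment_id = experiment_id),
            class = "membrane_trace")
}

#' Read membrane traces from CSV
#'
#' Expected columns: `calyx_id`, `vertex_index`, `x_nm`, `y_nm` (and
#' optionally `experiment_id`).
#'
#' @param path CSV file.
#' @return named list of [membrane_trace()] objects, one per calyx.
#' @export
read_traces <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("calyx_id", "vertex_index", "x_nm", "y_nm")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("trace file lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (is.null(df$experiment_id)) df$experiment_id <- "exp1"
  out <- lapply(split(df, df$calyx_id), function(d) {
    d <- d[order(d$vertex_index), ]
    membrane_trace(d[c("x_nm", "y_nm")], calyx_id = d$calyx_id[1],
                   experiment_id = d$experiment_id[1])
  })
  out
}

#' Write membrane traces to CSV
#' @param traces list of [membrane_trace()].
#' @param path destination CSV.
#' @return `path`, invisibly.
#' @export
write_traces <- function(traces, path) {
  rows <- lapply(traces, function(tr)
    data.frame(calyx_id = tr$calyx_id,
               vertex_index = seq_len(nrow(tr$vertices)),
               x_nm = tr$vertices$x_nm, y_nm = tr$vertices$y_nm,
               experiment_id = tr$experiment_id))
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

# point and unit tangent at arc length s along a polyline
polyline_point <- function(vertices, s) {
  seg <- sqrt(diff(vertices$x_nm)^2 + diff(vertices$y_nm)^2)
  cs <- c(0, cumsum(seg))
  s <- pmin(pmax(s, 0), cs[length(cs)])
  i <- findInterval(s, cs, rightmost.closed = TRUE)
  i <- pmin(i, length(seg))
  f <- (s - cs[i]) / seg[i]
  tx <- (vertices$x_nm[i + 1] - vertices$x_nm[i]) / seg[i]
  ty <- (vertices$y_nm[i + 1] - vertices$y_nm[i]) / seg[i]
  list(x = vertices$x_nm[i] + f * seg[i] * tx,
       y = vertices$y_nm[i] + f * seg[i] * ty,
       tx = tx, ty = ty)
}

#' Segment a membrane trace into perpendicular profile anchors
#'
#' The trace is interpolated by arc length and split into segments of
#' `spacing_nm` (default 1000 nm = 1 um); each segment is represented by
#' its midpoint anchor and the local tangent rotated by 90 degrees — the
#' direction of the membrane-perpendicular line profile.  A global
#' orientation is chosen by majority vote so that all normals point from
#' the inner (postsynaptic) side outward through the calyx: for a closed
#' trace around the postsynaptic cell this is the direction away from the
#' trace centroid, independent of traversal direction.
#'
#' @param trace a [membrane_trace()].
#' @param spacing_nm segment length (nm).
#' @param thickness_nm lateral averaging width of the profiles that will
#'   be extracted on these segments (700 nm default; 300 nm for the AZ
#'   analysis).
#' @return list of `profile_segment` objects (anchor, unit normal, unit
#'   tangent, thickness, ids).
#' @export
segment_trace <- function(trace, spacing_nm = 1000, thickness_nm = 700) {
  stopifnot(inherits(trace, "membrane_trace"))
  v <- trace$vertices
  total <- sum(sqrt(diff(v$x_nm)^2 + diff(v$y_nm)^2))
  n_seg <- floor(total / spacing_nm)
  if (n_seg < 1) stop("trace arc length shorter than one segment")
  s_mid <- (seq_len(n_seg) - 0.5) * spacing_nm
  eps <- min(spacing_nm / 20, 25)
  p <- polyline_point(v, s_mid)
  p0 <- polyline_point(v, pmax(s_mid - eps, 0))
  p1 <- polyline_point(v, pmin(s_mid + eps, total))
  tx <- p1$x - p0$x; ty <- p1$y - p0$y
  tl <- sqrt(tx^2 + ty^2)
  tx <- tx / tl; ty <- ty / tl
  # candidate normal: tangent rotated +90 (x right, y down)
  nx <- -ty; ny <- tx
  cx <- mean(v$x_nm); cy <- mean(v$y_nm)
  vote <- sum(sign((p$x - cx) * nx + (p$y - cy) * ny))
  if (vote < 0) { nx <- -nx; ny <- -ny }
  lapply(seq_len(n_seg), function(k) structure(list(
    anchor = c(p$x[k], p$y[k]),
    normal = c(nx[k], ny[k]),
    tangent = c(tx[k], ty[k]),
    spacing_nm = spacing_nm,
    thickness_nm = thickness_nm,
    segment_id = sprintf("%s_seg%02d", trace$calyx_id, k),
    calyx_id = trace$calyx_id,
    experiment_id = trace$experiment_id
  ), class = "profile_segment"))
}

#' Extract a membrane-perpendicular line profile from a rendered image
#'
#' Samples the image bilinearly on a rectangular grid: offsets along the
#' segment normal (`offset_min_nm` .. `offset_max_nm`, step `step_nm`;
#' offset 0 at the anchor on the traced membrane) by lateral positions
#' across the segment `thickness_nm`; the profile value at each offset is
#' the mean over the lateral samples — the thick-line profile of the
#' classical ImageJ analysis.  Samples falling outside the image are
#' dropped from the mean and flag the profile as clipped.
#'
#' @param image a `rendered_image`.
#' @param seg a `profile_segment`.
#' @param step_nm sampling step along and across the profile (nm).
#' @param offset_min_nm,offset_max_nm profile extent along the normal;
#'   the defaults reach 500 nm beyond each side of a ~1 um calyx.
#' @return object of class `line_profile`: data.frame `position_nm`,
#'   `value` with segment metadata attributes.
#' @export
extract_profile <- function(image, seg, step_nm = 10,
                            offset_min_nm = -500, offset_max_nm = 2000) {
  stopifnot(inherits(seg, "profile_segment"))
  offs <- seq(offset_min_nm, offset_max_nm, by = step_nm)
  n_lat <- max(3L, round(seg$thickness_nm / step_nm) + 1L)
  lat <- seq(-seg$thickness_nm / 2, seg$thickness_nm / 2,
             length.out = n_lat)
  xs <- outer(offs * seg$normal[1], lat * seg$tangent[1], "+") +
    seg$anchor[1]
  ys <- outer(offs * seg$normal[2], lat * seg$tangent[2], "+") +
    seg$anchor[2]
  v <- matrix(sample_image(image, as.vector(xs), as.vector(ys)),
              nrow = length(offs))
  clipped <- anyNA(v)
  structure(data.frame(position_nm = offs, value = rowMeans(v, na.rm = TRUE)),
            class = c("line_profile", "data.frame"),
            segment = seg, step_nm = step_nm, clipped = clipped,
            target = NA_character_)
}

# Levenberg-Marquardt fit of n Gaussians + constant; robust to the
# exact-fit (zero residual) case.  Parameter layout:
# c0, then (a, m, s) per component.
fit_gaussians_lm <- function(p, v, init, lower, upper) {
  model <- function(par) {
    n_pk <- (length(par) - 1) / 3
    out <- rep(par[1], length(p))
    for (k in seq_len(n_pk)) {
      a <- par[3 * k - 1]; m <- par[3 * k]; s <- par[3 * k + 1]
      out <- out + a * exp(-(p - m)^2 / (2 * s^2))
    }
    out
  }
  rv <- tryCatch(minpack.lm::nls.lm(
    par = init, fn = function(par) v - model(par),
    lower = lower, upper = upper,
    control = minpack.lm::nls.lm.control(maxiter = 300)),
    error = function(e) NULL)
  if (is.null(rv) || !rv$info %in% 1:4) return(NULL)
  list(par = rv$par, resid = rv$fvec)
}

# local maxima of a (lightly median-smoothed) curve, ordered by height
find_local_maxima <- function(pos, val, min_sep_nm = 0) {
  vs <- if (length(val) >= 7) stats::runmed(val, 5) else val
  n <- length(vs)
  cand <- which(vs >= c(vs[1] - 1, vs[-n]) & vs >= c(vs[-1], vs[n] - 1))
  cand <- cand[order(val[cand], decreasing = TRUE)]
  keep <- integer(0)
  for (i in cand) {
    if (!length(keep) || all(abs(pos[i] - pos[keep]) >= min_sep_nm))
      keep <- c(keep, i)
  }
  keep
}

#' Fit the calyx borders on a WGA line profile
#'
#' The two membrane crossings of a WGA profile are modeled as a
#' two-Gaussian-plus-constant curve fitted simultaneously; the fitted
#' means are the inner (smaller offset) and outer border positions.
#' Initialization uses the two highest local maxima separated by at least
#' `min_sep_nm`.  The fit is accepted (`fit_ok`) when it converges, both
#' amplitudes exceed `snr_min` times the residual standard deviation, and
#' the implied thickness lies in `[min_thickness_nm, max_thickness_nm]`.
#'
#' @param wga_profile a [extract_profile()] result on the WGA image.
#' @param min_sep_nm minimal separation of initial peaks (nm).
#' @param min_thickness_nm,max_thickness_nm acceptance gate on the fitted
#'   border distance.
#' @param snr_min amplitude / residual-sd acceptance threshold.
#' @return object of class `border_fit`: list `inner_nm`, `outer_nm`,
#'   `thickness_nm`, `fit_ok`, `reason`, `params` (named coefficients),
#'   `contiguity` (`NA` until [segment_contiguity()] fills it).
#' @export
fit_borders <- function(wga_profile, min_sep_nm = 300,
                        min_thickness_nm = 300, max_thickness_nm = 3000,
                        snr_min = 3) {
  p <- wga_profile$position_nm
  v <- wga_profile$value
  fail <- function(reason) structure(
    list(inner_nm = NA_real_, outer_nm = NA_real_, thickness_nm = NA_real_,
         fit_ok = FALSE, reason = reason, params = NULL,
         contiguity = NA_real_), class = "border_fit")
  if (all(!is.finite(v)) || max(v, na.rm = TRUE) == min(v, na.rm = TRUE))
    return(fail("flat profile"))
  pk <- find_local_maxima(p, v, min_sep_nm)
  # candidate peaks must rise visibly above the profile floor
  pk <- pk[v[pk] >= min(v, na.rm = TRUE) +
             0.1 * (max(v, na.rm = TRUE) - min(v, na.rm = TRUE))]
  if (length(pk) < 2) return(fail("single detectable peak"))
  pk <- pk[1:2]
  c0 <- stats::quantile(v, 0.1, names = FALSE)
  init <- c(c0 = c0, a1 = v[pk[1]] - c0, m1 = p[pk[1]], s1 = 50,
            a2 = v[pk[2]] - c0, m2 = p[pk[2]], s2 = 50)
  fit <- fit_gaussians_lm(
    p, v, init,
    lower = c(-Inf, 0, min(p), 5, 0, min(p), 5),
    upper = c(Inf, Inf, max(p), 500, Inf, max(p), 500))
  if (is.null(fit)) return(fail("fit non-convergence"))
  cf <- fit$par
  sd_res <- stats::sd(fit$resid)
  snr <- if (sd_res > 1e-12) min(cf["a1"], cf["a2"]) / sd_res else Inf
  # both membranes must carry comparable signal: a vanishing second
  # amplitude means only one peak was really present
  balanced <- min(cf["a1"], cf["a2"]) >= 0.05 * max(cf["a1"], cf["a2"])
  inner <- min(cf["m1"], cf["m2"]); outer <- max(cf["m1"], cf["m2"])
  th <- outer - inner
  ok <- snr >= snr_min && balanced && th >= min_thickness_nm &&
    th <= max_thickness_nm
  structure(list(
    inner_nm = unname(inner), outer_nm = unname(outer),
    thickness_nm = unname(th), fit_ok = ok,
    reason = if (ok) "ok" else if (!balanced) "single detectable peak"
    else if (snr < snr_min) "low amplitude SNR"
    else "implausible thickness",
    params = cf, contiguity = NA_real_
  ), class = "border_fit")
}

#' Membrane contiguity of a segment
#'
#' Operationalizes the inclusion criterion "WGA staining clearly
#' discernible at both membranes over at least 70% of the selection": for
#' each lateral position across the segment thickness, single-pixel-wide
#' profiles are sampled and each membrane counts as present when the
#' maximal value within `window_nm` of its fitted border reaches the
#' fitted baseline plus `frac` of that border's fitted amplitude.  The
#' returned contiguity is the fraction of lateral positions where both
#' membranes are present.
#'
#' @param image WGA `rendered_image`.
#' @param seg a `profile_segment`.
#' @param fit the segment's [fit_borders()] result (must be `fit_ok`).
#' @param window_nm search window around each border (nm).
#' @param frac amplitude fraction defining "discernible".
#' @param n_lateral number of lateral sample lines.
#' @return contiguity fraction in `[0, 1]`.
#' @export
segment_contiguity <- function(image, seg, fit, window_nm = 150,
                               frac = 0.25, n_lateral = 21) {
  if (!isTRUE(fit$fit_ok)) return(NA_real_)
  cf <- fit$params
  lat <- seq(-seg$thickness_nm / 2, seg$thickness_nm / 2,
             length.out = n_lateral)
  both <- logical(n_lateral)
  thr1 <- cf["c0"] + frac * cf["a1"]
  thr2 <- cf["c0"] + frac * cf["a2"]
  # match thresholds to borders by position
  if (cf["m1"] > cf["m2"]) { tmp <- thr1; thr1 <- thr2; thr2 <- tmp }
  check <- function(centre, t_off, thr) {
    offs <- seq(centre - window_nm, centre + window_nm, by = 10)
    x <- seg$anchor[1] + offs * seg$normal[1] + t_off * seg$tangent[1]
    y <- seg$anchor[2] + offs * seg$normal[2] + t_off * seg$tangent[2]
    vv <- sample_image(image, x, y)
    isTRUE(max(vv, na.rm = TRUE) >= thr)
  }
  for (i in seq_len(n_lateral)) {
    both[i] <- check(fit$inner_nm, lat[i], thr1) &&
      check(fit$outer_nm, lat[i], thr2)
  }
  mean(both)
}

#' Filter segments on border-fit quality and membrane contiguity
#'
#' Keeps segments whose WGA border fit converged (`fit_ok`) and whose
#' contiguity is at least `threshold` (default 0.70; the boundary is
#' inclusive).
#'
#' @param segments list of `profile_segment`.
#' @param fits matching list of [fit_borders()] results with contiguity
#'   filled in.
#' @param threshold contiguity acceptance threshold.
#' @return integer vector of accepted segment indices.
#' @export
apply_contiguity_filter <- function(segments, fits, threshold = 0.70) {
  stopifnot(length(segments) == length(fits))
  which(vapply(fits, function(f)
    isTRUE(f$fit_ok) && !is.na(f$contiguity) && f$contiguity >= threshold,
    logical(1)))
}

#' Map a line profile onto the average-calyx axis
#'
#' Affine map taking the segment's fitted inner border to 0 and its outer
#' border to `mean_thickness_nm` (the cohort mean thickness, computed
#' from the cohort's WGA fits — not a constant), extended linearly beyond
#' the borders; values are linearly interpolated onto the common cohort
#' grid.
#'
#' @param profile a [extract_profile()] result.
#' @param fit the segment's accepted [fit_borders()].
#' @param mean_thickness_nm cohort mean calyx thickness (nm).
#' @param grid_step_nm cohort grid step; the grid spans
#'   `-500 .. mean_thickness_nm + 500`.
#' @return object of class `normalized_profile`: data.frame
#'   `position_nm`, `value` (NA outside the source profile's mapped
#'   range) with metadata attributes.
#' @export
normalize_profile <- function(profile, fit, mean_thickness_nm,
                              grid_step_nm = 10) {
  if (!isTRUE(fit$fit_ok)) stop("cannot normalize: border fit not accepted")
  if (fit$outer_nm == fit$inner_nm) stop("degenerate border fit")
  grid <- seq(-500, mean_thickness_nm + 500, by = grid_step_nm)
  mapped <- (profile$position_nm - fit$inner_nm) /
    (fit$outer_nm - fit$inner_nm) * mean_thickness_nm
  vals <- stats::approx(mapped, profile$value, xout = grid, rule = 1)$y
  seg <- attr(profile, "segment")
  structure(data.frame(position_nm = grid, value = vals),
            class = c("normalized_profile", "data.frame"),
            segment_id = if (!is.null(seg)) seg$segment_id else NA,
            calyx_id = if (!is.null(seg)) seg$calyx_id else NA,
            mean_thickness_nm = mean_thickness_nm,
            target = attr(profile, "target"))
}

#' Hierarchical cohort average of normalized profiles
#'
#' Profiles are first averaged within each calyx (so calyces with many
#' segments do not dominate), then calyx means are averaged into the
#' cohort curve; the SD is taken across calyx means.
#'
#' @param profiles list of [normalize_profile()] results sharing one grid.
#' @param calyx_ids calyx of each profile; defaults to each profile's
#'   `calyx_id` attribute.
#' @return data.frame `position_nm`, `mean`, `sd`, `n_calyx`.
#' @export
average_profiles <- function(profiles, calyx_ids = NULL) {
  stopifnot(length(profiles) >= 1)
  grid <- profiles[[1]]$position_nm
  for (pr in profiles)
    if (!isTRUE(all.equal(pr$position_nm, grid)))
      stop("normalized profiles are on different grids")
  if (is.null(calyx_ids))
    calyx_ids <- vapply(profiles, function(p)
      as.character(attr(p, "calyx_id")), character(1))
  vals <- vapply(profiles, function(p) p$value, numeric(length(grid)))
  vals <- matrix(vals, nrow = length(grid))
  by_calyx <- lapply(split(seq_along(profiles), calyx_ids), function(ii)
    rowMeans(vals[, ii, drop = FALSE], na.rm = TRUE))
  cm <- matrix(unlist(by_calyx), nrow = length(grid))
  data.frame(
    position_nm = grid,
    mean = rowMeans(cm, na.rm = TRUE),
    sd = apply(cm, 1, stats::sd, na.rm = TRUE),
    n_calyx = length(by_calyx)
  )
}

#' Locate intensity peaks on a profile curve by Gaussian fitting
#'
#' Fits `n_peaks` Gaussians plus a constant to the curve and returns the
#' fitted means, sorted.  Initialization uses the highest local maxima
#' separated by `min_sep_nm`.
#'
#' @param positions,values curve samples (use e.g. the `position_nm` /
#'   `mean` columns of [average_profiles()]).
#' @param n_peaks number of Gaussian components.
#' @param min_sep_nm minimal separation of initial peaks.
#' @return numeric vector of peak positions (nm), increasing.
#' @export
locate_peaks <- function(positions, values, n_peaks = 1, min_sep_nm = 200) {
  ok <- is.finite(values)
  p <- positions[ok]; v <- values[ok]
  if (length(p) < 5 || stats::sd(v) == 0)
    stop("cannot locate peaks on a constant or near-empty curve")
  pk <- find_local_maxima(p, v, min_sep_nm)
  if (length(pk) < n_peaks)
    pk <- c(pk, order(v, decreasing = TRUE))[1:n_peaks]
  pk <- pk[1:n_peaks]
  c0 <- min(v)
  init <- c(c0, as.vector(rbind(v[pk] - c0, p[pk], rep(100, n_peaks))))
  names(init) <- c("c0", as.vector(rbind(paste0("a", 1:n_peaks),
                                         paste0("m", 1:n_peaks),
                                         paste0("s", 1:n_peaks))))
  lower <- c(-Inf, rep(c(0, min(p), 10), n_peaks))
  upper <- c(Inf, rep(c(Inf, max(p), 1000), n_peaks))
  fit <- fit_gaussians_lm(p, v, init, lower, upper)
  if (is.null(fit))
    stop("peak fit did not converge (n_peaks = ", n_peaks, ")")
  sort(unname(fit$par[paste0("m", 1:n_peaks)]))
}

#' Compare per-calyx peak distances across targets
#'
#' One-way ANOVA on per-calyx peak distances to the synaptic membrane
#' (normalized position 0), followed by Bonferroni-corrected pairwise
#' comparisons — the classical test battery for peak-architecture
#' differences between targets.
#'
#' @param peaks_by_target named list: one numeric vector of per-calyx
#'   peak positions (nm) per target (>= 2 targets, >= 2 calyces each).
#' @return an [anova_oneway()] result.
#' @export
compare_peaks <- function(peaks_by_target) {
  stopifnot(length(peaks_by_target) >= 2)
  if (any(lengths(peaks_by_target) < 2))
    stop("need >= 2 calyces per target")
  anova_oneway(peaks_by_target)
}
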