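#' Adjacent-frame nearest-neighbour distances
#'
#' For every localization in frame f, the distance to its nearest
#' neighbour in frame f+1, kept when within `capture_nm`.  Repeated
#' localizations of the same blinking emitter in consecutive frames
#' dominate these pairs, so their distance distribution carries the
#' localization precision.
#'
#' @param table a [loc_table()].
#' @param capture_nm capture radius (nm); default 100.
#' @return numeric vector of distances (nm).
#' @export
nn_adjacent_distances <- function(table, capture_nm = 100) {
  stopifnot(inherits(table, "loc_table"))
  idx <- split(seq_len(nrow(table)), table$frame)
  frames <- as.integer(names(idx))
  nxt <- match(frames + 1L, frames)
  out <- vector("list", length(frames))
  for (k in which(!is.na(nxt))) {
    a <- idx[[k]]; b <- idx[[nxt[k]]]
    d2 <- outer(table$x_nm[a], table$x_nm[b], "-")^2 +
      outer(table$y_nm[a], table$y_nm[b], "-")^2
    dmin <- sqrt(if (length(b) == 1L) d2[, 1] else apply(d2, 1, min))
    out[[k]] <- dmin[dmin <= capture_nm]
  }
  unlist(out)
}

#' Nearest-neighbour localization precision
#'
#' Estimates the localization precision sigma from the adjacent-frame
#' nearest-neighbour distance distribution.  If both localizations of a
#' pair carry isotropic error sigma, their distance is Rayleigh with scale
#' `sqrt(2) * sigma`, density `d/(2 sigma^2) * exp(-d^2/(4 sigma^2))`.
#' The binned distance histogram is fitted by least squares with this
#' Rayleigh plus a linear (area-proportional) background on
#' `[0, capture_nm]` accounting for unrelated neighbours:
#' `p(d) = w * Rayleigh(d; sigma) + (1 - w) * 2 d / capture^2`.
#'
#' @param table a [loc_table()].
#' @param capture_nm capture radius (nm).
#' @param bin_nm histogram bin width (nm).
#' @param min_pairs minimal number of adjacent-frame NN pairs required.
#' @return object of class `precision_estimate`: list `sigma_nm`,
#'   `n_pairs`, `background_weight`, `residual_norm`, `converged`.
#' @export
nn_precision <- function(table, capture_nm = 100, bin_nm = 1,
                         min_pairs = 1000) {
  d <- nn_adjacent_distances(table, capture_nm)
  if (length(d) < min_pairs)
    stop(sprintf("only %d adjacent-frame NN pairs (need >= %d)",
                 length(d), min_pairs))
  # degenerate, essentially zero-spread data: moment estimator
  # (Rayleigh scale sqrt(2) sigma has E[d^2] = 4 sigma^2)
  if (stats::quantile(d, 0.95) < 2 * bin_nm) {
    return(structure(list(sigma_nm = sqrt(mean(d^2) / 4),
                          n_pairs = length(d), background_weight = 0,
                          residual_norm = 0, converged = TRUE),
                     class = "precision_estimate"))
  }
  br <- seq(0, capture_nm, by = bin_nm)
  h <- graphics::hist(d[d <= capture_nm], breaks = br, plot = FALSE)
  counts <- h$counts
  n <- sum(counts)
  lo <- br[-length(br)]; hi <- br[-1]
  ray_mass <- function(sigma) exp(-lo^2 / (4 * sigma^2)) -
    exp(-hi^2 / (4 * sigma^2))
  bg_mass <- (hi^2 - lo^2) / capture_nm^2
  mode0 <- h$mids[which.max(counts)]
  sigma0 <- max(mode0 / sqrt(2), bin_nm / 2)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      counts ~ n * (w * ray_mass(sigma) + (1 - w) * bg_mass),
      start = list(sigma = sigma0, w = 0.9),
      lower = c(bin_nm / 10, 0), upper = c(capture_nm, 1),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )
  if (is.null(fit))
    stop("NN-precision fit did not converge (mode at ", mode0,
         " nm, n = ", n, ")")
  cf <- stats::coef(fit)
  structure(list(
    sigma_nm = unname(cf["sigma"]), n_pairs = length(d),
    background_weight = unname(1 - cf["w"]),
    residual_norm = sqrt(sum(stats::resid(fit)^2)) / n,
    converged = TRUE
  ), class = "precision_estimate")
}

#' @export
print.precision_estimate <- function(x, ...) {
  cat(sprintf("<precision_estimate> sigma = %.2f nm (%d NN pairs, bg %.2f)\n",
              x$sigma_nm, x$n_pairs, x$background_weight))
  invisible(x)
}

# cross-correlation displacement between two equally-sized images:
# returns d (px, c(dx, dy)) such that B is approximately A translated by d,
# with sub-pixel quadratic peak interpolation; attribute "peak_corr" holds
# the normalized correlation peak.
xcorr_shift <- function(A, B) {
  stopifnot(all(dim(A) == dim(B)))
  # mean-subtract so the correlation peak reflects structure, not the DC
  # component, and featureless pairs score low
  A <- A - mean(A); B <- B - mean(B)
  nr <- nrow(A); nc <- ncol(A)
  FA <- stats::fft(A); FB <- stats::fft(B)
  C <- Re(stats::fft(Conj(FA) * FB, inverse = TRUE)) / (nr * nc)
  pk <- which(C == max(C), arr.ind = TRUE)[1, ]
  wrap <- function(i, n) ((i - 1 + n / 2) %% n) - n / 2
  subpix <- function(vals) {
    den <- vals[1] - 2 * vals[2] + vals[3]
    if (abs(den) < 1e-12) 0 else 0.5 * (vals[1] - vals[3]) / den
  }
  im <- pk[1]; jm <- pk[2]
  iw <- function(i) ((i - 1) %% nr) + 1
  jw <- function(j) ((j - 1) %% nc) + 1
  di <- wrap(im, nr) + subpix(c(C[iw(im - 1), jm], C[im, jm],
                                C[iw(im + 1), jm]))
  dj <- wrap(jm, nc) + subpix(c(C[im, jw(jm - 1)], C[im, jm],
                                C[im, jw(jm + 1)]))
  norm <- sqrt(sum(A^2) * sum(B^2))
  structure(c(dx = unname(dj), dy = unname(di)),
            peak_corr = if (norm > 0) max(C) / norm else 0)
}

#' Feature-based intra-round drift correction
#'
#' Frames are grouped into bins of `bin_frames`; each bin is rendered as a
#' count histogram and its displacement relative to the first bin is
#' estimated from the image cross-correlation peak with sub-pixel
#' quadratic interpolation.  Bin displacements are interpolated linearly
#' per frame and subtracted from the coordinates.  Bins whose normalized
#' correlation peak falls below `min_peak` are flagged featureless and
#' bridged by interpolation.
#'
#' @param table a [loc_table()].
#' @param bin_frames frames per bin (n_frames / bin_frames >= 2).
#' @param pixel_size_nm rendering pixel for the correlation images.
#' @param blur_sigma_nm rendering blur (helps the correlation peak).
#' @param min_peak normalized-correlation acceptance threshold.
#' @return list with `table` (corrected [loc_table()]; frame indices and
#'   record count untouched) and `track` (data.frame `frame_centre`,
#'   `dx_nm`, `dy_nm`, `flagged`; first bin is the (0,0) reference).
#' @export
drift_correct <- function(table, bin_frames = 2000, pixel_size_nm = 20,
                          blur_sigma_nm = 20, min_peak = 0.05) {
  stopifnot(inherits(table, "loc_table"))
  n_frames <- attr(table, "n_frames")
  n_bins <- floor(n_frames / bin_frames)
  if (n_bins < 2) stop("n_frames / bin_frames must be >= 2")
  fe <- attr(table, "field_extent")
  window <- c(0, fe[1], 0, fe[2])
  bin_of <- pmin(floor(table$frame / bin_frames) + 1, n_bins)
  imgs <- lapply(seq_len(n_bins), function(b) {
    sel <- bin_of == b
    render_points_2d(table$x_nm[sel], table$y_nm[sel], pixel_size_nm,
                     blur_sigma_nm, window)$pixels
  })
  dx <- dy <- numeric(n_bins)
  flagged <- logical(n_bins)
  for (b in 2:n_bins) {
    s <- xcorr_shift(imgs[[1]], imgs[[b]])
    if (attr(s, "peak_corr") < min_peak) {
      flagged[b] <- TRUE
      dx[b] <- NA; dy[b] <- NA
    } else {
      dx[b] <- s[["dx"]] * pixel_size_nm
      dy[b] <- s[["dy"]] * pixel_size_nm
    }
  }
  centres <- (seq_len(n_bins) - 0.5) * bin_frames
  ok <- !is.na(dx)
  if (sum(ok) >= 2) {
    dx[!ok] <- stats::approx(centres[ok], dx[ok], centres[!ok],
                             rule = 2)$y
    dy[!ok] <- stats::approx(centres[ok], dy[ok], centres[!ok],
                             rule = 2)$y
  } else {
    dx[!ok] <- 0; dy[!ok] <- 0
  }
  fdx <- stats::approx(centres, dx, xout = table$frame, rule = 2)$y
  fdy <- stats::approx(centres, dy, xout = table$frame, rule = 2)$y
  table$x_nm <- table$x_nm - fdx
  table$y_nm <- table$y_nm - fdy
  list(table = table,
       track = data.frame(frame_centre = centres, dx_nm = dx, dy_nm = dy,
                          flagged = flagged))
}

#' Apply an estimated drift track to another table of the same acquisition
#'
#' Subtracts the per-frame linear interpolation of the track (e.g.
#' estimated on the fiducial channel) from a table's coordinates.
#'
#' @param table a [loc_table()].
#' @param track `track` data.frame from [drift_correct()].
#' @return the corrected [loc_table()].
#' @export
apply_drift_track <- function(table, track) {
  stopifnot(inherits(table, "loc_table"))
  table$x_nm <- table$x_nm - stats::approx(track$frame_centre, track$dx_nm,
                                           xout = table$frame, rule = 2)$y
  table$y_nm <- table$y_nm - stats::approx(track$frame_centre, track$dy_nm,
                                           xout = table$frame, rule = 2)$y
  table
}

#' Re-staining efficiency regression
#'
#' Fits an ordinary least-squares line through the per-round signal series
#' normalized to round 1 and reports the fractional loss per imaging round
#' as minus the slope (linear scale, matching a "% loss per round"
#' summary).
#'
#' @param signals per-round signal values (e.g. localization counts of the
#'   re-stained structure); length >= 3.
#' @param rounds round indices; default `1:length(signals)`.
#' @return object of class `efficiency_fit`: list `loss_per_round`
#'   (fraction), `intercept`, `r_squared` (`NA` for a constant series),
#'   `per_round_signal` (data.frame).
#' @export
restaining_efficiency <- function(signals, rounds = seq_along(signals)) {
  if (length(signals) < 3) stop("need >= 3 rounds for the efficiency fit")
  if (signals[1] == 0) stop("zero first-round signal")
  s <- signals / signals[1]
  fit <- stats::lm(s ~ rounds)
  r2 <- if (stats::var(s) == 0) NA_real_ else
    suppressWarnings(summary(fit)$r.squared)
  structure(list(
    loss_per_round = -unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r_squared = r2,
    per_round_signal = data.frame(round = rounds, signal = signals,
                                  normalized = s)
  ), class = "efficiency_fit")
}

#' @export
print.efficiency_fit <- function(x, ...) {
  cat(sprintf("<efficiency_fit> loss %.2f%% per round (r^2 = %s, %d rounds)\n",
              100 * x$loss_per_round,
              ifelse(is.na(x$r_squared), "NA", sprintf("%.3f", x$r_squared)),
              nrow(x$per_round_signal)))
  invisible(x)
}

#' Pearson cross-correlation between two rendered rounds
#'
#' Pixel-wise Pearson correlation of two identically rendered, registered
#' images; the series of round k vs round 1 tracks whether sample
#' structure survives repeated staining/elution.
#'
#' @param img_k,img_1 `rendered_image`s on identical grids.
#' @return Pearson r (scalar).
#' @export
round_cross_correlation <- function(img_k, img_1) {
  if (!all(dim(img_k$pixels) == dim(img_1$pixels)) ||
      img_k$pixel_size_nm != img_1$pixel_size_nm)
    stop("images must share an identical grid")
  a <- as.vector(img_k$pixels); b <- as.vector(img_1$pixels)
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("Pearson correlation undefined for a constant image")
  stats::cor(a, b)
}
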