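#' Area selection of a profile segment clipped to the calyx borders
#'
#' The rectangle spanned by the segment thickness (lateral) and the fitted
#' inner-to-outer border interval (along the normal), optionally padded —
#' the "area selection" form of a thick line profile used for
#' colocalization.
#'
#' @param seg a `profile_segment`.
#' @param fit the segment's accepted [fit_borders()].
#' @param pad_nm padding beyond each border along the normal (nm).
#' @return 4 x 2 matrix of polygon vertices (x_nm, y_nm).
#' @export
segment_polygon <- function(seg, fit, pad_nm = 0) {
  stopifnot(isTRUE(fit$fit_ok))
  o1 <- fit$inner_nm - pad_nm; o2 <- fit$outer_nm + pad_nm
  h <- seg$thickness_nm / 2
  corner <- function(o, t)
    seg$anchor + o * seg$normal + t * seg$tangent
  rbind(corner(o1, -h), corner(o2, -h), corner(o2, h), corner(o1, h))
}

#' Label segments as AZ-positive or AZ-free
#'
#' Manual mode validates and passes labels through.  Auto mode measures
#' the AZ-marker (bassoon) density within `range_nm` of each segment's
#' fitted inner border and labels a segment `AZ_positive` when that
#' density reaches `k` times the median across the calyx's segments —
#' "characterized by dense bassoon signal".
#'
#' @param bassoon AZ-marker `rendered_image` (registered).
#' @param segments list of `profile_segment`.
#' @param fits matching list of accepted [fit_borders()] results.
#' @param mode `"auto"` or `"manual"`.
#' @param manual_labels data.frame `segment_id`, `class` for manual mode
#'   (`class` in `AZ_positive`/`AZ_free`).
#' @param range_nm band half-width around the inner border (nm).
#' @param k density-over-median threshold for auto labeling.
#' @return data.frame `segment_id`, `class`, `basis`, `az_signal`.
#' @export
label_regions <- function(bassoon = NULL, segments, fits,
                          mode = c("auto", "manual"), manual_labels = NULL,
                          range_nm = 200, k = 2) {
  mode <- match.arg(mode)
  ids <- vapply(segments, function(s) s$segment_id, character(1))
  if (mode == "manual") {
    stopifnot(!is.null(manual_labels))
    unknown <- setdiff(manual_labels$segment_id, ids)
    if (length(unknown))
      stop("manual label references unknown segment(s): ",
           paste(unknown, collapse = ", "))
    stopifnot(all(manual_labels$class %in% c("AZ_positive", "AZ_free")))
    out <- manual_labels[c("segment_id", "class")]
    out$basis <- "manual"
    out$az_signal <- NA_real_
    return(out)
  }
  stopifnot(!is.null(bassoon))
  sig <- vapply(seq_along(segments), function(i) {
    seg <- segments[[i]]; fit <- fits[[i]]
    if (!isTRUE(fit$fit_ok)) return(NA_real_)
    offs <- seq(fit$inner_nm - range_nm, fit$inner_nm + range_nm, by = 10)
    lat <- seq(-seg$thickness_nm / 2, seg$thickness_nm / 2, by = 10)
    xs <- outer(offs * seg$normal[1], lat * seg$tangent[1], "+") +
      seg$anchor[1]
    ys <- outer(offs * seg$normal[2], lat * seg$tangent[2], "+") +
      seg$anchor[2]
    mean(sample_image(bassoon, as.vector(xs), as.vector(ys)), na.rm = TRUE)
  }, numeric(1))
  med <- stats::median(sig, na.rm = TRUE)
  cls <- ifelse(is.na(sig), NA_character_,
                ifelse(med > 0 & sig >= k * med, "AZ_positive", "AZ_free"))
  data.frame(segment_id = ids, class = cls, basis = "bassoon-threshold",
             az_signal = sig, stringsAsFactors = FALSE)
}

#' AZ-stratified cohort profiles
#'
#' Splits normalized profiles by their segment's region label and averages
#' each class hierarchically with [average_profiles()].
#'
#' @param profiles list of [normalize_profile()] results.
#' @param labels [label_regions()] output.
#' @return named list with elements `AZ_positive` and `AZ_free` (each an
#'   [average_profiles()] data.frame, or `NULL` with a warning when a
#'   class is empty).
#' @export
stratified_profiles <- function(profiles, labels) {
  seg_ids <- vapply(profiles, function(p)
    as.character(attr(p, "segment_id")), character(1))
  cls <- labels$class[match(seg_ids, labels$segment_id)]
  out <- list()
  for (cl in c("AZ_positive", "AZ_free")) {
    sel <- which(cls == cl)
    if (!length(sel)) {
      warning("no segments in class ", cl, call. = FALSE)
      out[[cl]] <- NULL
    } else {
      out[[cl]] <- average_profiles(profiles[sel])
    }
  }
  out
}

#' Pearson correlation of two images within an area selection
#'
#' Pixel-wise Pearson r over pixels whose centres fall inside the
#' selection polygon.
#'
#' @param img_a,img_b `rendered_image`s on identical grids.
#' @param selection polygon vertices, matrix/data.frame with x, y columns
#'   in nm.
#' @param min_pixels minimal selection size (pixels).
#' @return Pearson r, or `NA` (flagged via attribute `reason`) when a
#'   constant image makes it undefined.
#' @export
pearson_r <- function(img_a, img_b, selection, min_pixels = 100) {
  if (!all(dim(img_a$pixels) == dim(img_b$pixels)) ||
      img_a$pixel_size_nm != img_b$pixel_size_nm)
    stop("images must share an identical grid")
  px <- img_a$pixel_size_nm
  nc <- ncol(img_a$pixels); nr <- nrow(img_a$pixels)
  sel <- as.matrix(selection)[, 1:2]
  # restrict candidate pixels to the polygon bounding box
  jr <- range(sel[, 1]); ir <- range(sel[, 2])
  js <- max(1, floor((jr[1] - img_a$origin_nm[1]) / px)):
    min(nc, ceiling((jr[2] - img_a$origin_nm[1]) / px))
  is <- max(1, floor((ir[1] - img_a$origin_nm[2]) / px)):
    min(nr, ceiling((ir[2] - img_a$origin_nm[2]) / px))
  if (!length(js) || !length(is)) stop("selection outside image")
  cx <- img_a$origin_nm[1] + (js - 0.5) * px
  cy <- img_a$origin_nm[2] + (is - 0.5) * px
  pts <- cbind(rep(cx, each = length(cy)), rep(cy, times = length(cx)))
  inside <- mgcv::in.out(rbind(sel, sel[1, ]), pts)
  if (sum(inside) < min_pixels)
    stop("selection smaller than ", min_pixels, " pixels")
  ii <- rep(is, times = length(js))[inside]
  jj <- rep(js, each = length(is))[inside]
  a <- img_a$pixels[cbind(ii, jj)]
  b <- img_b$pixels[cbind(ii, jj)]
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    return(structure(NA_real_, reason = "constant image in selection"))
  stats::cor(a, b)
}

#' All-pairs colocalization matrix, stratified by AZ class
#'
#' For every target pair and every labeled selection, the Pearson r is
#' computed within the selection, then averaged per class across
#' selections (matching a per-selection error structure rather than
#' pooling pixels).  The matrix stores the AZ-proximal means in the upper
#' triangle and the AZ-free means in the lower triangle; per-selection r
#' values are retained for the class comparison t-tests.
#'
#' @param images named list of per-target `rendered_image`s (identical
#'   grids, registered).
#' @param segments list of `profile_segment`.
#' @param fits matching accepted [fit_borders()] list.
#' @param labels [label_regions()] output.
#' @param min_pixels per-selection minimal pixel count.
#' @return object of class `coloc_matrix`: list with `targets`, `matrix`
#'   (upper = AZ-proximal, lower = AZ-free, diagonal 1), `n` (same layout,
#'   selection counts), and `per_selection` (data.frame `pair`, `class`,
#'   `segment_id`, `r`).
#' @export
colocalization_matrix <- function(images, segments, fits, labels,
                                  min_pixels = 20) {
  targets <- names(images)
  stopifnot(length(targets) >= 2)
  usable <- which(vapply(fits, function(f) isTRUE(f$fit_ok), logical(1)))
  per <- list()
  for (i in usable) {
    seg <- segments[[i]]
    cls <- labels$class[match(seg$segment_id, labels$segment_id)]
    if (is.na(cls)) next
    poly <- segment_polygon(seg, fits[[i]])
    for (a in seq_along(targets)[-length(targets)]) {
      for (b in (a + 1):length(targets)) {
        r <- tryCatch(pearson_r(images[[a]], images[[b]], poly,
                                min_pixels = min_pixels),
                      error = function(e) NA_real_)
        per[[length(per) + 1]] <- data.frame(
          a = targets[a], b = targets[b],
          pair = paste(targets[a], targets[b], sep = "|"),
          class = cls, segment_id = seg$segment_id, r = as.numeric(r))
      }
    }
  }
  per <- do.call(rbind, per)
  n_t <- length(targets)
  m <- matrix(NA_real_, n_t, n_t, dimnames = list(targets, targets))
  nmat <- matrix(0L, n_t, n_t, dimnames = list(targets, targets))
  diag(m) <- 1
  if (!is.null(per)) {
    agg <- stats::aggregate(r ~ a + b + class, data = per, FUN = mean,
                            na.action = stats::na.omit)
    cnt <- stats::aggregate(r ~ a + b + class,
                            data = per[!is.na(per$r), ], FUN = length)
    for (i in seq_len(nrow(agg))) {
      ia <- match(agg$a[i], targets); ib <- match(agg$b[i], targets)
      # upper triangle (row < col) = AZ-proximal, lower = AZ-free
      if (agg$class[i] == "AZ_positive") {
        m[min(ia, ib), max(ia, ib)] <- agg$r[i]
      } else {
        m[max(ia, ib), min(ia, ib)] <- agg$r[i]
      }
    }
    for (i in seq_len(nrow(cnt))) {
      ia <- match(cnt$a[i], targets); ib <- match(cnt$b[i], targets)
      if (cnt$class[i] == "AZ_positive") {
        nmat[min(ia, ib), max(ia, ib)] <- cnt$r[i]
      } else {
        nmat[max(ia, ib), min(ia, ib)] <- cnt$r[i]
      }
    }
  }
  structure(list(targets = targets, matrix = m, n = nmat,
                 per_selection = per),
            class = "coloc_matrix")
}

#' @export
print.coloc_matrix <- function(x, ...) {
  cat(sprintf("<coloc_matrix> %d targets (upper: AZ-proximal, lower: AZ-free)\n",
              length(x$targets)))
  print(round(x$matrix, 2))
  invisible(x)
}

#' Compare per-selection colocalization between AZ classes
#'
#' For each target pair, an unpaired two-tailed Student's t test (pooled
#' variance, via [t_test_unpaired()]) compares the per-selection r values
#' of AZ-proximal vs AZ-free selections.  Bonferroni correction across
#' pairs is off by default (stars are conventionally reported unadjusted)
#' but can be enabled.
#'
#' @param coloc a [colocalization_matrix()] result.
#' @param bonferroni adjust p-values across pairs.
#' @return data.frame `pair`, `mean_az`, `mean_free`, `n_az`, `n_free`,
#'   `t`, `p`, `significant` (p <= 0.05).
#' @export
compare_colocalization <- function(coloc, bonferroni = FALSE) {
  per <- coloc$per_selection
  per <- per[!is.na(per$r), ]
  pairs <- unique(per$pair)
  out <- lapply(pairs, function(pp) {
    d <- per[per$pair == pp, ]
    ra <- d$r[d$class == "AZ_positive"]
    rf <- d$r[d$class == "AZ_free"]
    if (length(ra) < 2 || length(rf) < 2)
      return(data.frame(pair = pp, mean_az = mean(ra), mean_free = mean(rf),
                        n_az = length(ra), n_free = length(rf),
                        t = NA_real_, p = NA_real_))
    tt <- t_test_unpaired(ra, rf)
    data.frame(pair = pp, mean_az = tt$mean_a, mean_free = tt$mean_b,
               n_az = length(ra), n_free = length(rf), t = tt$t, p = tt$p)
  })
  out <- do.call(rbind, out)
  if (bonferroni) out$p <- pmin(1, out$p * nrow(out))
  out$significant <- !is.na(out$p) & out$p <= 0.05
  out
}

#' Export a colocalization matrix (CSV + heatmap + p-value table)
#'
#' @param coloc a [colocalization_matrix()] result.
#' @param csv_path matrix CSV path (upper = AZ-proximal, lower = AZ-free).
#' @param png_path optional heatmap PNG.
#' @param pvals_path optional CSV for [compare_colocalization()] output.
#' @return `csv_path`, invisibly.
#' @export
export_coloc_matrix <- function(coloc, csv_path, png_path = NULL,
                                pvals_path = NULL) {
  utils::write.csv(as.data.frame(coloc$matrix), csv_path, row.names = TRUE)
  if (!is.null(png_path)) {
    grDevices::png(png_path, width = 750, height = 700)
    op <- graphics::par(mar = c(8, 8, 3, 2))
    n <- length(coloc$targets)
    m <- coloc$matrix
    graphics::image(seq_len(n), seq_len(n), t(m[n:1, , drop = FALSE]),
                    zlim = c(-1, 1),
                    col = grDevices::hcl.colors(64, "RdBu", rev = TRUE),
                    axes = FALSE, xlab = "", ylab = "",
                    main = "Pearson r (upper: AZ-proximal, lower: AZ-free)")
    graphics::axis(1, at = seq_len(n), labels = coloc$targets, las = 2)
    graphics::axis(2, at = seq_len(n), labels = rev(coloc$targets), las = 2)
    graphics::par(op)
    grDevices::dev.off()
  }
  if (!is.null(pvals_path))
    utils::write.csv(compare_colocalization(coloc), pvals_path,
                     row.names = FALSE)
  invisible(csv_path)
}
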