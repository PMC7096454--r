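#' Extract fiducial bead positions from a localization table
#'
#' Localizations are linked into spatial clusters by a greedy
#' nearest-centre rule with link radius `r_link_nm` (beads are micrometres
#' apart, so the linkage is unambiguous at the default 500 nm); clusters
#' with at least `m_min` members become beads at the member mean, the
#' natural summary when every frame-bin re-localizes the same immobile
#' bead.
#'
#' @param table fiducial-channel [loc_table()].
#' @param r_link_nm cluster link radius (nm).
#' @param m_min minimal localizations per accepted bead.
#' @return object of class `fiducial_set`: data.frame `bead_id`, `x_nm`,
#'   `y_nm`, `n_locs` with attributes `round_index` and `low_bead_count`
#'   (TRUE when fewer than 5 beads were found).
#' @export
extract_bead_positions <- function(table, r_link_nm = 500, m_min = 10) {
  stopifnot(inherits(table, "loc_table"))
  if (!nrow(table)) stop("empty fiducial table")
  cx <- numeric(0); cy <- numeric(0); cn <- integer(0)
  sx <- numeric(0); sy <- numeric(0)
  assign_id <- integer(nrow(table))
  for (i in seq_len(nrow(table))) {
    x <- table$x_nm[i]; y <- table$y_nm[i]
    if (length(cx)) {
      d2 <- (cx - x)^2 + (cy - y)^2
      j <- which.min(d2)
      if (d2[j] <= r_link_nm^2) {
        sx[j] <- sx[j] + x; sy[j] <- sy[j] + y; cn[j] <- cn[j] + 1L
        cx[j] <- sx[j] / cn[j]; cy[j] <- sy[j] / cn[j]
        assign_id[i] <- j
        next
      }
    }
    cx <- c(cx, x); cy <- c(cy, y); sx <- c(sx, x); sy <- c(sy, y)
    cn <- c(cn, 1L)
    assign_id[i] <- length(cx)
  }
  keep <- which(cn >= m_min)
  if (!length(keep)) stop("no fiducial bead with >= ", m_min, " localizations")
  out <- data.frame(bead_id = seq_along(keep), x_nm = cx[keep],
                    y_nm = cy[keep], n_locs = cn[keep])
  structure(out, class = c("fiducial_set", "data.frame"),
            round_index = attr(table, "round_index"),
            low_bead_count = nrow(out) < 5L)
}

#' Build a fiducial set directly from known bead coordinates
#'
#' @param beads data.frame with `x_nm`, `y_nm` (and optionally `bead_id`).
#' @param round_index staining round the set belongs to.
#' @return a `fiducial_set`.
#' @export
fiducial_set <- function(beads, round_index = 1L) {
  beads <- as.data.frame(beads)
  if (is.null(beads$bead_id)) beads$bead_id <- seq_len(nrow(beads))
  if (is.null(beads$n_locs)) beads$n_locs <- NA_integer_
  structure(beads[c("bead_id", "x_nm", "y_nm", "n_locs")],
            class = c("fiducial_set", "data.frame"),
            round_index = as.integer(round_index),
            low_bead_count = nrow(beads) < 5L)
}

#' Match fiducials between two rounds
#'
#' Mutual-nearest-neighbour pairing: bead i of `ref` and bead j of `mov`
#' are matched when each is the other's nearest neighbour and their
#' distance is at most `max_dist_nm`.  Each bead enters at most one pair.
#'
#' @param ref,mov `fiducial_set`s of the reference and moving round.
#' @param max_dist_nm matching gate (nm); default 1000.
#' @return data.frame with the paired coordinates (`x_ref`, `y_ref`,
#'   `x_mov`, `y_mov`), bead ids and pair distance.
#' @export
match_fiducials <- function(ref, mov, max_dist_nm = 1000) {
  if (!nrow(ref) || !nrow(mov)) stop("empty fiducial set")
  d <- outer(ref$x_nm, mov$x_nm, "-")^2 + outer(ref$y_nm, mov$y_nm, "-")^2
  nn_rm <- apply(d, 1, which.min)   # for each ref bead: nearest mov
  nn_mr <- apply(d, 2, which.min)   # for each mov bead: nearest ref
  pairs <- which(nn_mr[nn_rm] == seq_len(nrow(ref)))
  pairs <- pairs[sqrt(d[cbind(pairs, nn_rm[pairs])]) <= max_dist_nm]
  out <- data.frame(
    ref_id = ref$bead_id[pairs], mov_id = mov$bead_id[nn_rm[pairs]],
    x_ref = ref$x_nm[pairs], y_ref = ref$y_nm[pairs],
    x_mov = mov$x_nm[nn_rm[pairs]], y_mov = mov$y_nm[nn_rm[pairs]]
  )
  out$dist_nm <- sqrt((out$x_ref - out$x_mov)^2 + (out$y_ref - out$y_mov)^2)
  if (nrow(out) < 3)
    stop("fewer than 3 matched fiducials: translation estimate unreliable")
  out
}

#' Estimate the round-pair translation from matched fiducials
#'
#' The per-bead displacements are `dx_i = x_ref,i - x_mov,i` and the shift
#' is their mean, so `ref = mov + shift`: applying the shift maps the
#' moving round into the reference frame.
#'
#' @param pairs output of [match_fiducials()].
#' @return object of class `shift2d`: list `dx_nm`, `dy_nm`, `n_beads`.
#' @export
estimate_shift <- function(pairs) {
  stopifnot(nrow(pairs) >= 1)
  structure(list(
    dx_nm = mean(pairs$x_ref - pairs$x_mov),
    dy_nm = mean(pairs$y_ref - pairs$y_mov),
    n_beads = nrow(pairs)
  ), class = "shift2d")
}

#' @export
print.shift2d <- function(x, ...) {
  cat(sprintf("<shift2d> dx = %.2f nm, dy = %.2f nm (%d beads)\n",
              x$dx_nm, x$dy_nm, x$n_beads))
  invisible(x)
}

#' Registration error between two rounds
#'
#' For per-bead displacements `dx_i` between rounds A and B, the
#' registration error along x is the mean absolute deviation from the mean
#' displacement,
#' `RE_x = (1/n) * sum_i |mean(dx) - dx_i|`,
#' and analogously along y.  The statistic is invariant under any global
#' translation of either round, so it is identical before and after the
#' registration transform is applied.
#'
#' @param pairs output of [match_fiducials()] (>= 2 pairs).
#' @return named numeric `c(re_x, re_y)` in nm.
#' @export
registration_error <- function(pairs) {
  if (nrow(pairs) < 2)
    stop("registration error undefined for fewer than 2 bead pairs")
  dx <- pairs$x_ref - pairs$x_mov
  dy <- pairs$y_ref - pairs$y_mov
  c(re_x = mean(abs(mean(dx) - dx)), re_y = mean(abs(mean(dy) - dy)))
}

#' Apply a translation to a localization table
#'
#' Adds `(dx, dy)` to every record, mapping the table's round into the
#' reference round's frame (`ref = mov + shift`).  The applied shift is
#' recorded in the `applied_shift_nm` attribute.
#'
#' @param table a [loc_table()].
#' @param shift a [estimate_shift()] result (or list with `dx_nm`,
#'   `dy_nm`).
#' @return the shifted [loc_table()].
#' @export
apply_shift <- function(table, shift) {
  stopifnot(inherits(table, "loc_table"))
  table$x_nm <- table$x_nm + shift$dx_nm
  table$y_nm <- table$y_nm + shift$dy_nm
  prev <- attr(table, "applied_shift_nm")
  if (is.null(prev)) prev <- c(0, 0)
  attr(table, "applied_shift_nm") <- prev + c(shift$dx_nm, shift$dy_nm)
  table
}

#' Pairwise registration-error matrix over all rounds
#'
#' For every round pair the fiducials are matched and RE computed; the
#' report stores `RE_x` in the upper triangle and `RE_y` in the lower
#' triangle of one matrix (diagonal 0), the layout used for registration
#' heatmaps.  Pairs with fewer than 3 matches are flagged `NA`, never
#' fabricated.  Shifts of every round relative to the reference round
#' (the first set) are estimated alongside.
#'
#' @param sets list of `fiducial_set`s, one per round (>= 2).
#' @param max_dist_nm matching gate passed to [match_fiducials()].
#' @return object of class `registration_report`: list with `rounds`,
#'   `matrix` (upper = RE_x, lower = RE_y), `re_x`, `re_y` (full symmetric
#'   matrices) and `shifts` (per-round [estimate_shift()] vs round 1).
#' @export
registration_matrix <- function(sets, max_dist_nm = 1000) {
  if (length(sets) < 2) stop("need at least 2 rounds")
  rounds <- vapply(sets, function(s) attr(s, "round_index"), integer(1))
  n <- length(sets)
  re_x <- re_y <- matrix(NA_real_, n, n, dimnames = list(rounds, rounds))
  diag(re_x) <- diag(re_y) <- 0
  for (a in seq_len(n - 1)) {
    for (b in (a + 1):n) {
      re <- tryCatch(registration_error(
        match_fiducials(sets[[a]], sets[[b]], max_dist_nm)),
        error = function(e) c(re_x = NA_real_, re_y = NA_real_))
      re_x[a, b] <- re_x[b, a] <- re[["re_x"]]
      re_y[a, b] <- re_y[b, a] <- re[["re_y"]]
    }
  }
  combo <- re_x
  combo[lower.tri(combo)] <- re_y[lower.tri(re_y)]
  shifts <- vector("list", n)
  shifts[[1]] <- structure(list(dx_nm = 0, dy_nm = 0,
                                n_beads = nrow(sets[[1]])), class = "shift2d")
  for (b in 2:n) {
    shifts[[b]] <- tryCatch(
      estimate_shift(match_fiducials(sets[[1]], sets[[b]], max_dist_nm)),
      error = function(e) NULL)
  }
  names(shifts) <- paste0("SR", rounds)
  structure(list(rounds = rounds, matrix = combo, re_x = re_x, re_y = re_y,
                 shifts = shifts),
            class = "registration_report")
}

#' @export
print.registration_report <- function(x, ...) {
  cat(sprintf("<registration_report> %d rounds; RE range %.1f-%.1f nm\n",
              length(x$rounds),
              min(x$matrix[x$matrix > 0], na.rm = TRUE),
              max(x$matrix, na.rm = TRUE)))
  invisible(x)
}

#' Export a registration report (CSV matrix + heatmap + shift sidecar)
#'
#' @param report a [registration_matrix()] result.
#' @param csv_path path for the matrix CSV (upper triangle = RE_x,
#'   lower = RE_y).
#' @param png_path optional heatmap PNG path.
#' @param json_path optional JSON sidecar with the per-round shifts.
#' @return `csv_path`, invisibly.
#' @export
export_registration_report <- function(report, csv_path, png_path = NULL,
                                       json_path = NULL) {
  m <- report$matrix
  utils::write.csv(as.data.frame(m), csv_path, row.names = TRUE)
  if (!is.null(png_path)) {
    grDevices::png(png_path, width = 700, height = 650)
    op <- graphics::par(mar = c(4, 4, 3, 6))
    n <- nrow(m)
    graphics::image(seq_len(n), seq_len(n), t(m[n:1, , drop = FALSE]),
                    col = grDevices::hcl.colors(64, "viridis"),
                    axes = FALSE, xlab = "staining round",
                    ylab = "staining round",
                    main = "Registration error (upper: x, lower: y) [nm]")
    graphics::axis(1, at = seq_len(n), labels = report$rounds)
    graphics::axis(2, at = seq_len(n), labels = rev(report$rounds))
    for (i in seq_len(n)) for (j in seq_len(n))
      graphics::text(j, n - i + 1, sprintf("%.0f", m[i, j]), cex = 0.7,
                     col = "white")
    graphics::par(op)
    grDevices::dev.off()
  }
  if (!is.null(json_path)) {
    sh <- lapply(report$shifts, function(s)
      if (is.null(s)) NULL else list(dx_nm = s$dx_nm, dy_nm = s$dy_nm,
                                     n_beads = s$n_beads))
    jsonlite::write_json(sh, json_path, auto_unbox = TRUE, digits = NA,
                         null = "null")
  }
  invisible(csv_path)
}
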