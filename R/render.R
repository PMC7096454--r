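#' 2D density rendering of localization tables
#'
#' Bins localizations into a 2D count histogram at `pixel_size_nm` and
#' optionally smooths with an isotropic Gaussian of `blur_sigma_nm`.  Pixel
#' `(i, j)` (row i, column j; x right, y down) covers the half-open square
#' `[xmin + (j-1)*px, xmin + j*px) x [ymin + (i-1)*px, ymin + i*px)`, so
#' localizations exactly on the right/bottom window edge are excluded.
#' With `blur_sigma_nm = 0` the sum of pixels equals the number of rendered
#' localizations; the blur kernel is normalized, so total mass is conserved
#' up to truncation at the window boundary.
#'
#' Defaults (10 nm pixels, 10 nm blur, roughly the localization precision
#' of a good dSTORM acquisition) are a rendering choice; both are
#' configurable everywhere they are used downstream.
#'
#' @param table a [loc_table()].
#' @param pixel_size_nm grid spacing, nm per pixel (> 0).
#' @param blur_sigma_nm Gaussian smoothing sigma in nm (0 = pure histogram).
#' @param window numeric length 4 `c(xmin, xmax, ymin, ymax)` in nm;
#'   defaults to the table's field extent.
#' @return an object of class `rendered_image`: list with `pixels` (matrix,
#'   rows = y), `pixel_size_nm`, `origin_nm` (world coordinate of the
#'   top-left pixel corner), `blur_sigma_nm`, and `n_excluded`, the count of
#'   localizations outside the window.
#' @export
render_2d <- function(table, pixel_size_nm = 10, blur_sigma_nm = 10,
                      window = NULL) {
  stopifnot(inherits(table, "loc_table"))
  if (pixel_size_nm <= 0) stop("pixel_size_nm must be > 0")
  if (is.null(window)) {
    fe <- attr(table, "field_extent")
    window <- c(0, fe[1], 0, fe[2])
  }
  render_points_2d(table$x_nm, table$y_nm, pixel_size_nm, blur_sigma_nm, window)
}

# rendering core on bare coordinate vectors (shared with drift binning)
render_points_2d <- function(x, y, pixel_size_nm, blur_sigma_nm, window) {
  nx <- max(1L, ceiling((window[2] - window[1]) / pixel_size_nm))
  ny <- max(1L, ceiling((window[4] - window[3]) / pixel_size_nm))
  jx <- floor((x - window[1]) / pixel_size_nm) + 1
  iy <- floor((y - window[3]) / pixel_size_nm) + 1
  inside <- jx >= 1 & jx <= nx & iy >= 1 & iy <= ny
  n_excl <- sum(!inside)
  pix <- matrix(0, nrow = ny, ncol = nx)
  if (any(inside)) {
    tb <- table(factor(iy[inside], levels = 1:ny),
                factor(jx[inside], levels = 1:nx))
    pix <- matrix(as.numeric(tb), nrow = ny, ncol = nx)
  }
  if (blur_sigma_nm > 0)
    pix <- gaussian_blur(pix, blur_sigma_nm / pixel_size_nm)
  structure(list(
    pixels = pix, pixel_size_nm = pixel_size_nm,
    origin_nm = c(window[1], window[3]), blur_sigma_nm = blur_sigma_nm,
    n_excluded = n_excl
  ), class = "rendered_image")
}

#' @export
print.rendered_image <- function(x, ...) {
  cat(sprintf("<rendered_image> %d x %d px @ %g nm/px, blur %g nm, mass %.1f\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size_nm,
              x$blur_sigma_nm, sum(x$pixels)))
  invisible(x)
}

# separable Gaussian convolution with zero padding; sigma in pixels.
# kernel truncated at 4 sigma and renormalized, so interior mass is
# conserved to < 1e-4 and boundary losses are pure truncation.
gaussian_blur <- function(m, sigma_px) {
  if (sigma_px <= 0) return(m)
  r <- max(1L, ceiling(4 * sigma_px))
  k <- stats::dnorm(-r:r, sd = sigma_px)
  k <- k / sum(k)
  conv1 <- function(mat) {
    # zero-pad rows, filter each column, crop
    n <- nrow(mat)
    padded <- rbind(matrix(0, r, ncol(mat)), mat, matrix(0, r, ncol(mat)))
    f <- stats::filter(padded, k, sides = 2)
    as.matrix(f[(r + 1):(r + n), , drop = FALSE])
  }
  t(conv1(t(conv1(m))))
}

#' Bilinear sampling of a rendered image at world coordinates
#'
#' Pixel centres sit at `origin + (index - 0.5) * pixel_size`.  Points
#' outside the image return `NA`.
#'
#' @param image a `rendered_image`.
#' @param x_nm,y_nm world coordinates (vectors).
#' @return numeric vector of interpolated values.
#' @export
sample_image <- function(image, x_nm, y_nm) {
  px <- image$pixel_size_nm
  # continuous pixel coordinates: centre of pixel (i,j) is at (j-0.5, i-0.5)
  cx <- (x_nm - image$origin_nm[1]) / px - 0.5
  cy <- (y_nm - image$origin_nm[2]) / px - 0.5
  m <- image$pixels
  nx <- ncol(m); ny <- nrow(m)
  j0 <- floor(cx); i0 <- floor(cy)
  fx <- cx - j0; fy <- cy - i0
  # clamp to valid bilinear support, mark fully-outside points NA
  outside <- cx < -0.5 | cx > nx - 0.5 | cy < -0.5 | cy > ny - 0.5
  j0c <- pmin(pmax(j0, 0), nx - 1); j1c <- pmin(j0c + 1, nx - 1)
  i0c <- pmin(pmax(i0, 0), ny - 1); i1c <- pmin(i0c + 1, ny - 1)
  idx <- function(i, j) m[cbind(i + 1, j + 1)]
  v <- (1 - fx) * (1 - fy) * idx(i0c, j0c) +
    fx * (1 - fy) * idx(i0c, j1c) +
    (1 - fx) * fy * idx(i1c, j0c) +
    fx * fy * idx(i1c, j1c)
  v[outside] <- NA_real_
  v
}

#' Export a rendered image as 32-bit TIFF
#'
#' Single-page 32-bit TIFF.  The TIFF container stores samples on `[0, 1]`,
#' so pixel values are scaled by the image maximum; the scale factor,
#' pixel size, origin and blur are recorded in a JSON sidecar
#' (`<path>.json`) from which [read_image_tiff()] reconstructs the exact
#' density values.
#'
#' @param image a `rendered_image`.
#' @param path destination `.tif` path.
#' @return `path`, invisibly.
#' @export
write_image_tiff <- function(image, path) {
  mx <- max(image$pixels)
  scaled <- if (mx > 0) image$pixels / mx else image$pixels
  tiff::writeTIFF(scaled, path, bits.per.sample = 32L,
                  reduce = FALSE, compression = "none")
  meta <- list(pixel_size_nm = image$pixel_size_nm,
               origin_nm = image$origin_nm,
               blur_sigma_nm = image$blur_sigma_nm,
               value_scale = mx,
               resolution_px_per_cm = 1e7 / image$pixel_size_nm)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a rendered image written by [write_image_tiff()]
#' @param path `.tif` path with its JSON sidecar.
#' @return a `rendered_image`.
#' @export
read_image_tiff <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pix <- tiff::readTIFF(path) * meta$value_scale
  structure(list(pixels = pix, pixel_size_nm = meta$pixel_size_nm,
                 origin_nm = meta$origin_nm,
                 blur_sigma_nm = meta$blur_sigma_nm, n_excluded = NA),
            class = "rendered_image")
}
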