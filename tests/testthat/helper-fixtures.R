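# shared fixture builders; everything is generated in code at test time

su_mem <- 30 / 987.2  # membrane sigma 30 nm in normalized-depth units

wga_spec <- function(density = 400)
  target_spec("WGA", data.frame(mean = c(0, 1), sd = c(su_mem, su_mem),
                                weight = c(0.5, 0.5)), density_um2 = density)

# minimal two-target scene (membrane + uniform interior)
tiny_scene <- function(density_scale = 1) {
  scene_spec(targets = list(
    wga_spec(400 * density_scale),
    target_spec("VGlut1", uniform_weight = 1,
                density_um2 = 150 * density_scale)
  ))
}

# two-round experiment over the tiny scene
tiny_experiment <- function(seed = 3, ...) {
  rounds <- data.frame(round = c(1, 2), channel = c("Ch1", "Ch1"),
                       target = c("WGA", "VGlut1"))
  experiment_spec(rounds, seed = seed, ...)
}

# loc_table with explicit coordinates, one frame each
points_table <- function(x, y, frame = seq_along(x) - 1,
                         field = c(10000, 10000), n_frames = NULL) {
  if (is.null(n_frames)) n_frames <- max(frame) + 1L
  loc_table(data.frame(x_nm = x, y_nm = y, z_nm = 0, frame = frame,
                       intensity = 1),
            field_extent = field, n_frames = n_frames)
}

# synthetic image with horizontal Gaussian ridges at given y positions
ridge_image <- function(ridge_y_nm, sigma_nm = 30, amp = 100,
                        extent = c(3000, 3000), px = 10) {
  ny <- extent[2] / px; nx <- extent[1] / px
  yc <- (seq_len(ny) - 0.5) * px
  col <- rep(0, ny)
  for (ry in ridge_y_nm) col <- col + amp * exp(-(yc - ry)^2 / (2 * sigma_nm^2))
  structure(list(pixels = matrix(col, nrow = ny, ncol = nx),
                 pixel_size_nm = px, origin_nm = c(0, 0),
                 blur_sigma_nm = 0, n_excluded = 0),
            class = "rendered_image")
}

# straight horizontal segment with normal pointing +y (downward in image)
straight_segment <- function(anchor = c(1500, 1000), thickness_nm = 700) {
  structure(list(anchor = anchor, normal = c(0, 1), tangent = c(1, 0),
                 spacing_nm = 1000, thickness_nm = thickness_nm,
                 segment_id = "fix_seg01", calyx_id = "fix",
                 experiment_id = "exp1"),
            class = "profile_segment")
}
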