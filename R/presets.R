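#' The "calyx-16" preset: 16 targets over 10 staining rounds
#'
#' A ready-made scene + experiment emulating a multiplexed dSTORM run on a
#' calyx of Held cross-section: membrane label (WGA) on both borders, AZ
#' marker (bassoon) concentrated at active-zone patches, a postsynaptic
#' marker (homer) just inside the postsynaptic cell, synaptic-vesicle
#' markers (VGlut1, synaptophysin) filling the presynaptic space with
#' VGlut1 and MyoVa enriched x2 within 500 nm of AZs, cytoskeletal targets
#' (F-actin with peaks near both membranes and AZ-proximal depletion,
#' beta-II-spectrin similar, alpha-tubulin peaked in the calyx interior),
#' and organelle/other markers with interior profiles.  Ten rounds carry
#' one or two channels each, for 16 target tables plus 10 fiducial tables.
#'
#' @param seed experiment seed.
#' @param density_scale multiplier on all molecular densities (1 = preset
#'   default; lower it for quick smoke runs).
#' @param ... overrides passed to [experiment_spec()].
#' @return list with elements `scene` ([scene_spec()]) and `exp`
#'   ([experiment_spec()]).
#' @export
calyx16_preset <- function(seed = 1L, density_scale = 1, ...) {
  gauss <- function(m, s, w = 1) data.frame(mean = m, sd = s, weight = w)
  ds <- function(d) d * density_scale
  # membrane sigma 30 nm over ~987 nm thickness -> sd ~ 0.0304 in u
  su <- 30 / 987.2
  targets <- list(
    target_spec("WGA", gauss(c(0, 1), c(su, su), c(0.5, 0.5)),
                density_um2 = ds(400)),
    target_spec("bassoon", gauss(0.03, 0.05), density_um2 = ds(60),
                az_enrichment = 8, az_range_nm = 150),
    target_spec("homer", gauss(-0.05, 0.04), density_um2 = ds(80)),
    target_spec("VGlut1", uniform_weight = 1, density_um2 = ds(200),
                az_enrichment = 2, az_range_nm = 500),
    target_spec("F-actin", gauss(c(0.1, 0.9), c(0.08, 0.08), c(0.5, 0.5)),
                density_um2 = ds(200), az_enrichment = 0.5,
                az_range_nm = 500),
    target_spec("alpha-tubulin", gauss(0.55, 0.15), density_um2 = ds(150)),
    target_spec("MyoVa", uniform_weight = 1, density_um2 = ds(120),
                az_enrichment = 2, az_range_nm = 500),
    target_spec("bII-spectrin", gauss(c(0.12, 0.88), c(0.1, 0.1),
                                      c(0.5, 0.5)), density_um2 = ds(120)),
    target_spec("synaptophysin", uniform_weight = 1, density_um2 = ds(150)),
    target_spec("Rab3a", uniform_weight = 1, density_um2 = ds(100)),
    target_spec("Tom20", gauss(0.5, 0.2), density_um2 = ds(80)),
    target_spec("GM130", gauss(0.4, 0.1), density_um2 = ds(60)),
    target_spec("MAP2", gauss(-0.15, 0.1), density_um2 = ds(80)),
    target_spec("CHC17", uniform_weight = 1, density_um2 = ds(80)),
    target_spec("PDI", gauss(0.6, 0.2), density_um2 = ds(80)),
    target_spec("gamma-actin", gauss(c(0.15, 0.85), c(0.12, 0.12),
                                     c(0.5, 0.5)), density_um2 = ds(100))
  )
  az <- data.frame(
    angle_rad = c(0.3, 1.4, 2.5, 3.6, 4.7, 5.6),
    arc_len_nm = c(400, 350, 450, 400, 350, 400)
  )
  scene <- scene_spec(az_patches = az, targets = targets)
  rounds <- data.frame(
    round = c(1, 1, 2, 2, 3, 3, 4, 4, 5, 5, 6, 6, 7, 8, 9, 10),
    channel = c("Ch1", "Ch2", "Ch1", "Ch2", "Ch1", "Ch2", "Ch1", "Ch2",
                "Ch1", "Ch2", "Ch1", "Ch2", "Ch1", "Ch1", "Ch1", "Ch1"),
    target = c("WGA", "bassoon", "homer", "VGlut1", "F-actin",
               "alpha-tubulin", "MyoVa", "bII-spectrin", "synaptophysin",
               "Rab3a", "Tom20", "GM130", "MAP2", "CHC17", "PDI",
               "gamma-actin"),
    stringsAsFactors = FALSE
  )
  exp <- experiment_spec(rounds, seed = seed, ...)
  list(scene = scene, exp = exp)
}
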