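#' Default run configuration
#'
#' Every pipeline parameter with its documented default.  A configuration
#' is a plain nested list; [read_run_config()] merges a YAML file over
#' these defaults and [write_run_config()] round-trips one to YAML.
#'
#' @param ... named overrides, merged recursively over the defaults
#'   (e.g. `run_config(seed = 7, render = list(pixel_size_nm = 20))`).
#' @return nested configuration list.
#' @export
run_config <- function(...) {
  defaults <- list(
    seed = 1L,
    stages = c("simulate", "register", "qc", "profile", "coloc", "report"),
    dataset_dir = NULL,
    synthetic = list(preset = "calyx16", density_scale = 1,
                     write_dataset = FALSE),
    render = list(pixel_size_nm = 10, blur_sigma_nm = 10),
    registration = list(r_link_nm = 500, m_min = 10, max_dist_nm = 1000),
    qc = list(capture_nm = 100, bin_nm = 1, min_pairs = 1000,
              drift_correct = TRUE, drift_bin_frames = 2000),
    profile = list(spacing_nm = 1000, thickness_nm = 700, step_nm = 10,
                   contiguity_min = 0.70,
                   peak_spec = list("alpha-tubulin" = 1, "F-actin" = 2,
                                    "VGlut1" = 1)),
    coloc = list(pixel_size_nm = 20, blur_sigma_nm = 20,
                 az_marker = "bassoon", bonferroni = FALSE)
  )
  merge_config(defaults, list(...))
}

merge_config <- function(base, over) {
  for (nm in names(over)) {
    if (is.list(base[[nm]]) && is.list(over[[nm]]) &&
        !is.null(names(over[[nm]])))
      base[[nm]] <- merge_config(base[[nm]], over[[nm]])
    else base[[nm]] <- over[[nm]]
  }
  base
}

#' @rdname run_config
#' @param path YAML file.
#' @export
read_run_config <- function(path) {
  over <- yaml::read_yaml(path)
  do.call(run_config, over)
}

#' @rdname run_config
#' @param config configuration list.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Load a written synthetic dataset from disk
#'
#' Reads the localization CSVs and ground-truth sidecar written by
#' [generate_experiment()] back into an `smlm_dataset`-like structure
#' (without the full scene specification).
#'
#' @param dir dataset directory.
#' @return list with `rounds` (tables + fiducials per round),
#'   `round_ids`, and `truth_meta` (the JSON sidecar, when present).
#' @export
read_dataset <- function(dir) {
  fid_files <- sort(list.files(dir, "^fiducials_round[0-9]+\\.csv$",
                               full.names = TRUE))
  if (!length(fid_files)) stop("no fiducial tables found in ", dir)
  round_ids <- as.integer(sub(".*round([0-9]+)\\.csv$", "\\1", fid_files))
  meta <- NULL
  gt <- file.path(dir, "ground_truth.json")
  if (file.exists(gt)) meta <- jsonlite::read_json(gt, simplifyVector = TRUE)
  rounds <- list()
  for (k in seq_along(round_ids)) {
    r <- round_ids[k]
    fid <- read_localizations(fid_files[k], round_index = r,
                              channel = "fid", target = "fiducial")
    tfiles <- list.files(dir, sprintf("^round%02d_.*\\.csv$", r),
                         full.names = TRUE)
    tables <- list()
    for (f in tfiles) {
      parts <- strsplit(sub("\\.csv$", "", basename(f)), "_")[[1]]
      ch <- parts[2]; tgt <- paste(parts[-(1:2)], collapse = "_")
      tables[[tgt]] <- read_localizations(f, round_index = r, channel = ch,
                                          target = tgt)
    }
    rounds[[paste0("SR", r)]] <- list(tables = tables, fiducials = fid)
  }
  list(rounds = rounds, round_ids = round_ids, truth_meta = meta)
}

pipe_log <- function(state, ...) {
  msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                 paste0(...))
  message(msg)
  cat(msg, "\n", file = state$log_file, append = TRUE)
}

run_stage <- function(state, name, fun) {
  pipe_log(state, "stage ", name, ": start")
  t0 <- Sys.time()
  res <- tryCatch(fun(), error = function(e)
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
  pipe_log(state, "stage ", name, sprintf(": done (%.1f s)",
                                          as.numeric(Sys.time() - t0,
                                                     units = "secs")))
  res
}

#' Run the full pipeline
#'
#' Executes the configured stages in order — simulate (or load) the
#' multi-round dataset, register all rounds to round 1 on the fiducials,
#' compute the QC statistics, run the calyx line-profile analysis, the
#' AZ/colocalization analysis, and write the summary report — emitting
#' CSV/PNG/JSON artifacts and a provenance record into `out_dir`.  A
#' stage failure halts the run with the stage name; partial outputs are
#' retained.  The run is deterministic for a fixed `config$seed`.
#'
#' @param config a [run_config()] list.
#' @param out_dir output directory (created).
#' @return invisibly, a list with the in-memory stage results and
#'   `out_dir`.
#' @export
run_pipeline <- function(config = run_config(), out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  state <- new.env()
  state$log_file <- file.path(out_dir, "run.log")
  cat("", file = state$log_file)
  prov <- list(package_version = as.character(utils::packageVersion("smlmplex")),
               started = format(Sys.time()), config = config)
  res <- list(out_dir = out_dir)
  stages <- config$stages

  ## --- simulate / load -------------------------------------------------
  if ("simulate" %in% stages && is.null(config$dataset_dir)) {
    res$dataset <- run_stage(state, "simulate", function() {
      preset <- calyx16_preset(seed = config$seed,
                               density_scale = config$synthetic$density_scale)
      generate_experiment(preset$scene, preset$exp,
                          out_dir = if (isTRUE(config$synthetic$write_dataset))
                            file.path(out_dir, "dataset") else NULL)
    })
    rounds <- res$dataset$rounds
    round_ids <- res$dataset$round_ids
    truth <- res$dataset$truth
  } else {
    res$dataset <- run_stage(state, "load", function()
      read_dataset(config$dataset_dir))
    rounds <- res$dataset$rounds
    round_ids <- res$dataset$round_ids
    truth <- NULL
  }

  ## --- register --------------------------------------------------------
  if ("register" %in% stages) {
    res$registration <- run_stage(state, "register", function() {
      sets <- lapply(rounds, function(r)
        extract_bead_positions(r$fiducials,
                               r_link_nm = config$registration$r_link_nm,
                               m_min = config$registration$m_min))
      rep <- registration_matrix(sets,
                                 max_dist_nm = config$registration$max_dist_nm)
      export_registration_report(
        rep, file.path(out_dir, "registration_matrix.csv"),
        file.path(out_dir, "registration_heatmap.png"),
        file.path(out_dir, "registration_shifts.json"))
      rep
    })
    # map every round into the round-1 frame
    for (k in seq_along(rounds)) {
      sh <- res$registration$shifts[[k]]
      if (is.null(sh)) next
      rounds[[k]]$tables <- lapply(rounds[[k]]$tables, apply_shift, shift = sh)
      rounds[[k]]$fiducials <- apply_shift(rounds[[k]]$fiducials, sh)
    }
  }

  ## --- qc --------------------------------------------------------------
  if ("qc" %in% stages) {
    res$qc <- run_stage(state, "qc", function() {
      qc <- list()
      if (isTRUE(config$qc$drift_correct)) {
        tracks <- list()
        for (k in seq_along(rounds)) {
          dc <- drift_correct(rounds[[k]]$fiducials,
                              bin_frames = config$qc$drift_bin_frames)
          rounds[[k]]$fiducials <<- dc$table
          rounds[[k]]$tables <<- lapply(rounds[[k]]$tables,
                                        apply_drift_track, track = dc$track)
          tracks[[names(rounds)[k]]] <- dc$track
        }
        qc$drift_tracks <- tracks
      }
      prec <- list()
      for (k in seq_along(rounds)) {
        for (tgt in names(rounds[[k]]$tables)) {
          tab <- rounds[[k]]$tables[[tgt]]
          pe <- tryCatch(nn_precision(tab, capture_nm = config$qc$capture_nm,
                                      bin_nm = config$qc$bin_nm,
                                      min_pairs = config$qc$min_pairs),
                         error = function(e) NULL)
          prec[[length(prec) + 1]] <- data.frame(
            round = round_ids[k], channel = attr(tab, "channel"),
            target = tgt,
            sigma_nm = if (is.null(pe)) NA_real_ else pe$sigma_nm,
            n_pairs = if (is.null(pe)) NA_integer_ else pe$n_pairs)
        }
      }
      qc$precision <- do.call(rbind, prec)
      # efficiency: localizations per ground-truth molecule per round
      if (!is.null(truth)) {
        sig <- vapply(seq_along(rounds), function(k) {
          n_loc <- sum(vapply(rounds[[k]]$tables, nrow, numeric(1)))
          tgts <- names(rounds[[k]]$tables)
          n_mol <- sum(truth$molecules$target %in% tgts)
          n_loc / n_mol
        }, numeric(1))
        qc$efficiency <- restaining_efficiency(sig, round_ids)
      }
      # structural cross-correlation: registered fiducial renders vs SR1
      fw <- attr(rounds[[1]]$fiducials, "field_extent")
      win <- c(0, fw[1], 0, fw[2])
      fimg <- lapply(rounds, function(r)
        render_points_2d(r$fiducials$x_nm, r$fiducials$y_nm, 20, 20, win))
      qc$cross_correlation <- data.frame(
        round = round_ids,
        r = vapply(seq_along(fimg), function(k)
          round_cross_correlation(fimg[[k]], fimg[[1]]), numeric(1)))
      utils::write.csv(qc$precision,
                       file.path(out_dir, "qc_precision.csv"),
                       row.names = FALSE)
      utils::write.csv(qc$cross_correlation,
                       file.path(out_dir, "qc_cross_correlation.csv"),
                       row.names = FALSE)
      json <- list(
        precision_mean_nm = mean(qc$precision$sigma_nm, na.rm = TRUE),
        efficiency_loss_per_round = if (!is.null(qc$efficiency))
          qc$efficiency$loss_per_round else NA,
        cross_correlation_min = min(qc$cross_correlation$r))
      jsonlite::write_json(json, file.path(out_dir, "qc_summary.json"),
                           auto_unbox = TRUE, digits = NA)
      qc
    })
  }

  ## --- profile ---------------------------------------------------------
  all_tables <- do.call(c, lapply(rounds, function(r) r$tables))
  names(all_tables) <- sub("^SR[0-9]+\\.", "", names(all_tables))
  if ("profile" %in% stages) {
    res$profile <- run_stage(state, "profile", function() {
      if (is.null(truth))
        stop("profile stage needs a trace: synthetic runs derive it from ",
             "ground truth; supply traces for file datasets")
      pr <- config$profile
      ang <- seq(0, 2 * pi, length.out = 121)[-121]
      trace <- membrane_trace(
        data.frame(x_nm = truth$centre_nm[1] +
                     truth$inner_radius_nm * cos(ang),
                   y_nm = truth$centre_nm[2] +
                     truth$inner_radius_nm * sin(ang)),
        calyx_id = "calyx01")
      segs <- segment_trace(trace, spacing_nm = pr$spacing_nm,
                            thickness_nm = pr$thickness_nm)
      images <- lapply(all_tables, render_2d,
                       pixel_size_nm = config$render$pixel_size_nm,
                       blur_sigma_nm = config$render$blur_sigma_nm)
      wga <- images[["WGA"]]
      if (is.null(wga)) stop("no WGA target in dataset")
      wga_prof <- lapply(segs, extract_profile, image = wga,
                         step_nm = pr$step_nm)
      fits <- lapply(seq_along(segs), function(i) {
        f <- fit_borders(wga_prof[[i]])
        if (isTRUE(f$fit_ok))
          f$contiguity <- segment_contiguity(wga, segs[[i]], f)
        f
      })
      accepted <- apply_contiguity_filter(segs, fits, pr$contiguity_min)
      if (!length(accepted)) stop("no segment passed the contiguity filter")
      L_bar <- mean(vapply(fits[accepted], `[[`, numeric(1), "thickness_nm"))
      norm <- list(); curves <- list()
      for (tn in names(images)) {
        pl <- lapply(accepted, function(i) {
          p <- if (tn == "WGA") wga_prof[[i]] else
            extract_profile(images[[tn]], segs[[i]], step_nm = pr$step_nm)
          attr(p, "target") <- tn
          normalize_profile(p, fits[[i]], L_bar)
        })
        norm[[tn]] <- pl
        curves[[tn]] <- average_profiles(pl)
      }
      peaks <- list()
      for (tn in names(pr$peak_spec)) {
        if (!tn %in% names(curves)) next
        peaks[[tn]] <- tryCatch(
          locate_peaks(curves[[tn]]$position_nm, curves[[tn]]$mean,
                       n_peaks = pr$peak_spec[[tn]]),
          error = function(e) NA_real_)
      }
      # exports: long-format curves + peak table + figure
      long <- do.call(rbind, lapply(names(curves), function(tn)
        cbind(target = tn, curves[[tn]])))
      utils::write.csv(long, file.path(out_dir, "profile_curves.csv"),
                       row.names = FALSE)
      pk_df <- do.call(rbind, lapply(names(peaks), function(tn)
        data.frame(target = tn, peak = seq_along(peaks[[tn]]),
                   position_nm = peaks[[tn]])))
      if (!is.null(pk_df))
        utils::write.csv(pk_df, file.path(out_dir, "profile_peaks.csv"),
                         row.names = FALSE)
      grDevices::png(file.path(out_dir, "profile_curves.png"),
                     width = 900, height = 600)
      sel <- intersect(c("WGA", names(pr$peak_spec)), names(curves))
      cols <- grDevices::hcl.colors(length(sel), "Dark 3")
      ymax <- max(vapply(curves[sel], function(cu)
        max(cu$mean, na.rm = TRUE), numeric(1)))
      graphics::plot(NULL, xlim = range(curves[[1]]$position_nm),
                     ylim = c(0, ymax * 1.05),
                     xlab = "distance to synaptic membrane (nm)",
                     ylab = "mean density", main = "Normalized calyx profiles")
      for (i in seq_along(sel))
        graphics::lines(curves[[sel[i]]]$position_nm, curves[[sel[i]]]$mean,
                        col = cols[i], lwd = 2)
      graphics::legend("topright", legend = sel, col = cols, lwd = 2)
      grDevices::dev.off()
      list(segments = segs, fits = fits, accepted = accepted,
           mean_thickness_nm = L_bar, profiles = norm, curves = curves,
           peaks = peaks, images = images)
    })
  }

  ## --- coloc -----------------------------------------------------------
  if ("coloc" %in% stages && !is.null(res$profile)) {
    res$coloc <- run_stage(state, "coloc", function() {
      cl <- config$coloc
      imgs <- lapply(all_tables, render_2d,
                     pixel_size_nm = cl$pixel_size_nm,
                     blur_sigma_nm = cl$blur_sigma_nm)
      segs <- res$profile$segments
      fits <- res$profile$fits
      acc <- res$profile$accepted
      az_img <- imgs[[cl$az_marker]]
      if (is.null(az_img)) stop("AZ marker '", cl$az_marker,
                                "' not in dataset")
      labels <- label_regions(az_img, segs[acc], fits[acc], mode = "auto")
      cm <- colocalization_matrix(imgs, segs[acc], fits[acc], labels)
      export_coloc_matrix(cm, file.path(out_dir, "coloc_matrix.csv"),
                          file.path(out_dir, "coloc_heatmap.png"),
                          file.path(out_dir, "coloc_tests.csv"))
      strat <- suppressWarnings(stratified_profiles(
        res$profile$profiles[["VGlut1"]], labels))
      list(labels = labels, matrix = cm, stratified_vglut1 = strat)
    })
  }

  ## --- report ----------------------------------------------------------
  if ("report" %in% stages) {
    run_stage(state, "report", function()
      write_report(res, out_dir))
  }
  files <- list.files(out_dir, full.names = TRUE, recursive = TRUE)
  files <- files[!grepl("provenance\\.json$", files)]
  prov$finished <- format(Sys.time())
  prov$outputs <- lapply(stats::setNames(files, basename(files)),
                         function(f) unname(tools::md5sum(f)))
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(res)
}

# markdown summary with one section per executed stage
write_report <- function(res, out_dir) {
  L <- c("# Multiplexed SMLM run summary", "")
  if (!is.null(res$dataset) && inherits(res$dataset, "smlm_dataset")) {
    L <- c(L, sprintf("- dataset: synthetic, %d rounds, %d targets, %d ground-truth molecules",
                      length(res$dataset$rounds),
                      length(unique(res$dataset$exp$rounds$target)),
                      nrow(res$dataset$truth$molecules)), "")
  }
  L <- c(L, "## Registration", "")
  if (!is.null(res$registration)) {
    m <- res$registration$matrix
    L <- c(L, sprintf("RE range %.1f-%.1f nm over %d rounds.",
                      min(m[m > 0], na.rm = TRUE), max(m, na.rm = TRUE),
                      length(res$registration$rounds)),
           "", "![](registration_heatmap.png)",
           "", "Data: `registration_matrix.csv`, `registration_shifts.json`", "")
  } else L <- c(L, "_stage not run_", "")
  L <- c(L, "## Quality control", "")
  if (!is.null(res$qc)) {
    L <- c(L, sprintf("- mean localization precision: %.1f nm",
                      mean(res$qc$precision$sigma_nm, na.rm = TRUE)))
    if (!is.null(res$qc$efficiency))
      L <- c(L, sprintf("- re-staining loss per round: %.1f%% (r² = %.3f)",
                        100 * res$qc$efficiency$loss_per_round,
                        res$qc$efficiency$r_squared))
    L <- c(L, sprintf("- round cross-correlation vs round 1: min %.3f",
                      min(res$qc$cross_correlation$r)),
           "", "Data: `qc_precision.csv`, `qc_cross_correlation.csv`", "")
  } else L <- c(L, "_stage not run_", "")
  L <- c(L, "## Calyx line profiles", "")
  if (!is.null(res$profile)) {
    L <- c(L, sprintf("- accepted segments: %d / %d (contiguity filter)",
                      length(res$profile$accepted),
                      length(res$profile$segments)),
           sprintf("- mean calyx thickness: %.1f nm",
                   res$profile$mean_thickness_nm))
    for (tn in names(res$profile$peaks))
      L <- c(L, sprintf("- %s peak(s): %s nm", tn,
                        paste(sprintf("%.0f", res$profile$peaks[[tn]]),
                              collapse = ", ")))
    L <- c(L, "", "![](profile_curves.png)",
           "", "Data: `profile_curves.csv`, `profile_peaks.csv`", "")
  } else L <- c(L, "_stage not run_", "")
  L <- c(L, "## AZ stratification & colocalization", "")
  if (!is.null(res$coloc)) {
    n_az <- sum(res$coloc$labels$class == "AZ_positive", na.rm = TRUE)
    L <- c(L, sprintf("- AZ-positive segments: %d / %d", n_az,
                      nrow(res$coloc$labels)),
           "", "![](coloc_heatmap.png)",
           "", "Data: `coloc_matrix.csv`, `coloc_tests.csv`", "")
  } else L <- c(L, "_stage not run_", "")
  writeLines(L, file.path(out_dir, "report.md"))
  invisible(file.path(out_dir, "report.md"))
}
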