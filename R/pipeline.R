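# End-to-end orchestration: simulate -> register -> filter -> volume ->
# report, as one reproducible run driven by a single flat config with one
# section per stage.  All randomness flows from one master seed, split into
# per-stage sub-seeds; a run manifest records the config, seeds, per-stage
# record counts and output checksums.

#' Default pipeline configuration
#'
#' A compact demonstration run: a 2-treatment, 1-plot, 3-vine-per-plot
#' scene scanned at the operational settings (270 degrees at 0.5 degree
#' steps, 50 Hz, 0.5 m/s, 10 Hz RTK fixes), filtered with the 64-neighbor
#' SOR rule and measured with a 0.1 m alpha shape.
#'
#' @param seed master seed
#' @return nested list of class `run_config` with sections `scene`,
#'   `sensor`, `trajectory`, `filter`, `alpha`, `nmea`
#' @export
default_config <- function(seed = 1L) {
  cfg <- list(
    seed = as.integer(seed),
    scene = list(treatments = 2, plots_per_treatment = 1, vines_per_plot = 3),
    sensor = list(fov = 270, angular_step = 0.5, scan_rate = 50,
                  range_noise_sd = 0.012),
    trajectory = list(speed = 0.5, gnss_rate = 10, gnss_noise_sd = 0.02),
    filter = list(z0 = NA, k = 64, nsigma = 1, mask_margin = 0.08),
    alpha = list(alpha = 0.1, sweep = NULL, coverage_frac = 0.99),
    nmea = list(origin = c(40.1333, -3.3667, 750)),
    biomass_cv = 0,
    export_scene_ply = FALSE)
  class(cfg) <- "run_config"
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' Unknown keys are rejected; missing sections are an error (every run
#' states its sensor, trajectory, scene, filter and alpha settings
#' explicitly or uses [default_config()] programmatically).
#'
#' @param path YAML file with the sections of [default_config()]
#' @return a validated `run_config`
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  validate_config(raw)
}

#' @rdname read_run_config
#' @param config a config list to validate
#' @export
validate_config <- function(config) {
  need <- c("scene", "sensor", "trajectory", "filter", "alpha")
  for (s in need)
    if (is.null(config[[s]]))
      stop("config validation: missing section '", s, "'")
  base <- default_config(config$seed %||% 1L)
  for (s in c(need, "nmea")) {
    sec <- config[[s]] %||% list()
    unknown <- setdiff(names(sec), switch(s,
      scene = names(formals(scene_spec)),
      sensor = names(formals(sensor_config)),
      trajectory = names(formals(trajectory_spec)),
      filter = c("z0", "k", "nsigma", "mask_margin"),
      alpha = c("alpha", "sweep", "coverage_frac"),
      nmea = c("origin", "utc_start")))
    if (length(unknown))
      stop("config validation: unknown key(s) in section '", s, "': ",
           paste(unknown, collapse = ", "))
    base[[s]] <- utils::modifyList(base[[s]], sec)
  }
  base$biomass_cv <- config$biomass_cv %||% base$biomass_cv
  base$export_scene_ply <- isTRUE(config$export_scene_ply)
  base
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE))
}

#' Run the full pipeline
#'
#' Executes simulate, register, filter, volume and report in order, writing
#' every intermediate artifact plus `volume.json`, `report.json` and
#' `manifest.json` into `out_dir`.  Re-running with the same config and
#' seed reproduces identical outputs.
#'
#' @param config a `run_config` (see [default_config()],
#'   [read_run_config()])
#' @param out_dir output directory (created if needed)
#' @param verbose print per-stage progress
#' @return (invisibly) a list with the scene, records, fit tables, per-batch
#'   volumes and the manifest
#' @export
run_pipeline <- function(config = default_config(), out_dir = tempfile("run"),
                         verbose = FALSE) {
  config <- validate_config(unclass(config))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message(sprintf(...))
  seed <- config$seed

  # --- simulate -------------------------------------------------------
  res <- .stage("simulate", {
    scene <- build_scene(do.call(scene_spec, config$scene),
                         stage_seed(seed, "scene"))
    sensor <- do.call(sensor_config, config$sensor)
    tr_args <- config$trajectory
    tr_args$x_start <- tr_args$x_start %||% 0
    tr_args$x_end <- tr_args$x_end %||% scene$row_length
    traj <- do.call(trajectory_spec, tr_args)
    run <- simulate_scan(scene, sensor, traj, stage_seed(seed, "scan"))
    say("simulate: %d frames x %d beams", max(run$scans$scan_index),
        sensor$n_beams)
    nmea <- generate_nmea(run$poses, traj$gnss_rate, traj$gnss_noise_sd,
                          stage_seed(seed, "nmea"),
                          origin = config$nmea$origin)
    write_scan_log(run$scans, file.path(out_dir, "scans.csv"))
    writeLines(nmea, file.path(out_dir, "fixes.nmea"))
    if (config$export_scene_ply)
      write_scene_ply(scene, file.path(out_dir, "scene.ply"))
    list(scene = scene, sensor = sensor, run = run)
  })
  scene <- res$scene; sensor <- res$sensor

  # --- register (from the files, exercising the io layer) -------------
  cloud <- .stage("register", {
    scans <- read_scan_log(file.path(out_dir, "scans.csv"), sensor)
    fixes <- read_nmea(file.path(out_dir, "fixes.nmea"),
                       origin = config$nmea$origin)
    cl <- georeference(scans, fixes, sensor)
    write_cloud(cl, file.path(out_dir, "cloud.ply"))
    say("register: %d points", nrow(cl))
    cl
  })

  # --- filter + volume per batch --------------------------------------
  fcfg <- config$filter
  z0 <- if (is.na(fcfg$z0))
    scene$spec$cordon_height + 2 * scene$spec$cordon_radius else fcfg$z0
  masks <- structure_masks(scene, fcfg$mask_margin)
  acfg <- config$alpha
  batch_out <- .stage("filter/volume", {
    lapply(seq_len(nrow(scene$batches)), function(b) {
      iv <- c(scene$batches$xmin[b], scene$batches$xmax[b])
      fb <- filter_batch(cloud, iv, z0, masks, fcfg$k, fcfg$nsigma)
      sel <- NULL
      alpha <- acfg$alpha
      if (!is.null(acfg$sweep)) {
        sel <- select_alpha(fb$shoots, acfg$sweep, acfg$coverage_frac,
                            seed = stage_seed(seed, "alpha"))
        alpha <- sel$alpha
      }
      total_cloud <- .as_cloud(rbind(fb$shoots, fb$structures))
      vt <- if (nrow(total_cloud) >= 4)
        alpha_complex(total_cloud, alpha,
                      seed = stage_seed(seed, "alpha"))$volume else 0
      vs <- if (nrow(fb$structures) >= 4)
        alpha_complex(fb$structures, alpha,
                      seed = stage_seed(seed, "alpha"))$volume else 0
      say("batch %d: %d shoot points, V_total %.3e m3", b,
          nrow(fb$shoots), vt)
      list(report = fb$report, alpha = alpha, sweep = sel$sweep,
           n_scans = length(unique(fb$shoots$scan_index)),
           n_points = nrow(fb$shoots),
           volume_total = vt, volume_structures = vs,
           volume_no_structures = volume_without_structures(vt, vs))
    })
  })

  # --- report ---------------------------------------------------------
  out <- .stage("report", {
    truth <- batch_truth(scene)
    volumes <- data.frame(
      n_scans = vapply(batch_out, `[[`, numeric(1), "n_scans"),
      n_points = vapply(batch_out, `[[`, numeric(1), "n_points"),
      volume_total = vapply(batch_out, `[[`, numeric(1), "volume_total"),
      volume_no_structures = vapply(batch_out, `[[`, numeric(1),
                                    "volume_no_structures"))
    biomass <- truth$true_biomass
    if (config$biomass_cv > 0)
      biomass <- with_seed(stage_seed(seed, "stats"),
        biomass * (1 + rnorm(length(biomass), 0, config$biomass_cv)))
    records <- batch_records(truth, volumes, biomass)
    fits <- NULL; aov_tabs <- NULL
    if (nrow(records) >= 3) {
      fits <- do.call(rbind, lapply(
        c("n_scans", "volume_total", "volume_no_structures"),
        function(p) suppressWarnings(fits_by_group(records, p))))
      tab <- fits[, c("variable", "treatment", "estimate", "se", "p_value")]
      names(tab) <- c("Variable", "Treatment", "Estimate", "SE", "p-Value")
      write.csv(tab, file.path(out_dir, "fits_by_treatment.csv"),
                row.names = FALSE)
      if (length(unique(records$treatment)) >= 2 &&
          nrow(records) > length(unique(records$treatment)) + 1) {
        aov_tabs <- lapply(c("n_scans", "volume_total"), function(p) {
          a <- anova_records(records, p)
          data.frame(term = rownames(a), df = a$Df, sum_sq = a$`Sum Sq`,
                     f_value = a$`F value`, p_value = a$`Pr(>F)`)
        })
        names(aov_tabs) <- c("n_scans", "volume_total")
      }
      .plot_records(records, out_dir)
    }
    jsonlite::write_json(
      list(batches = lapply(seq_along(batch_out), function(b)
             c(list(treatment = truth$treatment[b], plot = truth$plot[b]),
               batch_out[[b]][c("alpha", "n_scans", "n_points",
                                "volume_total", "volume_structures",
                                "volume_no_structures")])),
           stage_counts = lapply(batch_out, `[[`, "report")),
      file.path(out_dir, "volume.json"), auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(
      list(records = records, fits = fits, anova = aov_tabs),
      file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA,
      dataframe = "rows")
    list(records = records, fits = fits, anova = aov_tabs)
  })

  manifest <- .stage("manifest", {
    files <- list.files(out_dir, full.names = TRUE)
    files <- files[!basename(files) %in% "manifest.json"]
    man <- list(
      package_version = as.character(packageVersion("vinescan")),
      master_seed = seed,
      stage_seeds = sapply(c("scene", "scan", "nmea", "alpha", "stats"),
                           function(s) stage_seed(seed, s)),
      config = unclass(config),
      counts = list(segments = nrow(scene$segments),
                    batches = nrow(scene$batches),
                    frames = max(res$run$scans$scan_index),
                    cloud_points = nrow(cloud)),
      checksums = as.list(tools::md5sum(files)))
    names(man$checksums) <- basename(files)
    jsonlite::write_json(man, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    man
  })

  invisible(list(scene = scene, cloud = cloud, batches = batch_out,
                 records = out$records, fits = out$fits, anova = out$anova,
                 manifest = manifest, out_dir = out_dir))
}

# scatter plots of biomass against each LiDAR predictor, with the pooled fit
.plot_records <- function(records, out_dir) {
  for (p in c("n_scans", "volume_total", "volume_no_structures")) {
    f <- file.path(out_dir, paste0("biomass_vs_", p, ".png"))
    grDevices::png(f, width = 720, height = 540)
    graphics::plot(records[[p]], records$biomass,
                   xlab = p, ylab = "dry biomass (kg)",
                   pch = 19, col = factor(records$treatment),
                   main = sprintf("biomass vs %s", p))
    if (var(records[[p]]) > 0) {
      ft <- linear_fit(records[[p]], records$biomass)
      graphics::abline(ft$intercept, ft$slope, lty = 2)
      graphics::legend("topleft", bty = "n",
                       legend = sprintf("R2 = %.3f (n = %d)",
                                        ft$r_squared, ft$n))
    }
    grDevices::dev.off()
  }
}
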