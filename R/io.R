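#' Write / read a recording as CSV + JSON sidecar
#'
#' One CSV per IMU location (`t, acc_x..gyr_z`, with a `#`-comment header
#' carrying units and rate), one CSV for the speed series (`t, speed`),
#' and a JSON sidecar for subject, breed and gait segments.
#'
#' @param rec An `imu_recording`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_recording <- function(rec, dir) {
  validate_recording(rec)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  hdr <- sprintf("# units: acc m/s^2, gyr deg/s; rate %d Hz", rec$rate_imu)
  for (loc in names(rec$imu)) {
    path <- file.path(dir, paste0("imu_", loc, ".csv"))
    con <- file(path, "w")
    writeLines(hdr, con)
    write.csv(data.frame(t = rec$t_imu, rec$imu[[loc]], check.names = FALSE),
              con, row.names = FALSE)
    close(con)
  }
  spath <- file.path(dir, "speed.csv")
  con <- file(spath, "w")
  writeLines(sprintf("# units: m/s; rate %d Hz", rec$rate_speed), con)
  write.csv(rec$speed, con, row.names = FALSE)
  close(con)
  jsonlite::write_json(list(subject_id = rec$subject_id, breed = rec$breed,
                            rate_imu = rec$rate_imu, rate_speed = rec$rate_speed,
                            seed = rec$seed,
                            gait_segments = rec$gait_segments),
                       file.path(dir, "recording.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_recording
#' @export
read_recording <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "recording.json"),
                              simplifyVector = TRUE)
  imu <- list()
  for (loc in SENSOR_LOCATIONS) {
    d <- read.csv(file.path(dir, paste0("imu_", loc, ".csv")),
                  comment.char = "#", check.names = FALSE)
    imu[[loc]] <- as.matrix(d[, CHANNELS])
  }
  speed <- read.csv(file.path(dir, "speed.csv"), comment.char = "#")
  t_imu <- read.csv(file.path(dir, paste0("imu_", SENSOR_LOCATIONS[1], ".csv")),
                    comment.char = "#", check.names = FALSE)$t
  structure(list(
    subject_id = meta$subject_id, breed = meta$breed,
    imu = imu, t_imu = t_imu, speed = speed,
    gait_segments = as.data.frame(meta$gait_segments),
    rate_imu = meta$rate_imu, rate_speed = meta$rate_speed,
    units = c(acc = "m/s^2", gyr = "deg/s", speed = "m/s"),
    seed = meta$seed
  ), class = "imu_recording")
}

#' Write a feature matrix to CSV
#'
#' Metadata columns first, then one column per feature named
#' `<feature>_<channel>(<location>)`.
#'
#' @param fm A `feature_matrix`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(fm, path) {
  write.csv(fm, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  fm <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  class(fm) <- c("feature_matrix", "data.frame")
  fm
}

#' Pipeline configuration
#'
#' Bundles every constant of the pipeline: simulator parameters, window
#' size, filter spec, sampling rates, SFFS settings, model families and
#' seeds. All constants are configuration defaults, never hard-coded
#' downstream.
#'
#' @param n_subjects Cohort size.
#' @param breed_mix Named breed counts/proportions.
#' @param segment_duration Per-gait segment length (s).
#' @param window_size Samples per window (even, >= 64).
#' @param filter_order,filter_cutoff Butterworth low-pass spec (cutoff
#'   must stay below the 100 Hz Nyquist frequency).
#' @param sffs_k,sffs_criterion,sffs_cap SFFS settings; the criterion is
#'   the minimum RMSE improvement (m/s) and must be positive.
#' @param families Model families to run.
#' @param feature_sets Feature-set names to run.
#' @param select_set Feature set on which SFFS is demonstrated by
#'   [run_pipeline()] (selection over the 966-column `All` set is
#'   configurable but expensive).
#' @param poly_degree Stride-baseline polynomial degree.
#' @param seed Master seed.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(n_subjects = 3,
                            breed_mix = c(icelandic = 15, fm = 25),
                            segment_duration = 12,
                            window_size = 256,
                            filter_order = 4,
                            filter_cutoff = 30,
                            sffs_k = 5,
                            sffs_criterion = 0.01,
                            sffs_cap = 30,
                            families = c("rf"),
                            feature_sets = c("All", "LH"),
                            select_set = "LH",
                            poly_degree = 2,
                            seed = 1L) {
  cfg <- list(n_subjects = n_subjects, breed_mix = as.list(breed_mix),
              segment_duration = segment_duration, window_size = window_size,
              filter_order = filter_order, filter_cutoff = filter_cutoff,
              rate_imu = IMU_RATE, rate_speed = SPEED_RATE,
              sffs_k = sffs_k, sffs_criterion = sffs_criterion,
              sffs_cap = sffs_cap, families = families,
              feature_sets = feature_sets, select_set = select_set,
              poly_degree = poly_degree, seed = as.integer(seed))
  validate_config(cfg)
}

#' @rdname pipeline_config
#' @param cfg A config list (e.g. parsed from JSON).
#' @export
validate_config <- function(cfg) {
  if (cfg$window_size %% 2 != 0 || cfg$window_size < 64)
    stop("window_size must be even and >= 64")
  if (cfg$filter_cutoff >= cfg$rate_imu / 2)
    stop("filter cutoff must be below the Nyquist frequency")
  if (cfg$sffs_criterion <= 0) stop("SFFS criterion must be positive")
  if (cfg$n_subjects < 2) stop("n_subjects must be >= 2")
  bad_sets <- setdiff(cfg$feature_sets, names(feature_set_defs()))
  if (length(bad_sets) > 0)
    stop("unknown feature set(s): ", paste(bad_sets, collapse = ", "))
  structure(cfg, class = c("pipeline_config", "list"))
}

#' @rdname pipeline_config
#' @param path JSON config path.
#' @export
read_config <- function(path) {
  validate_config(jsonlite::read_json(path, simplifyVector = TRUE))
}

#' @rdname pipeline_config
#' @export
write_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

# MD5 of the serialized config, stamped into every artifact
config_hash <- function(cfg) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(unclass(cfg), tf, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tf))
}

#' Run the full pipeline
#'
#' Executes the stages in order — simulate, preprocess + window,
#' featurise, select, train/evaluate, stride baseline — and writes every
#' artifact (per-subject recording CSVs, feature matrix CSV, selection
#' JSON, grid CSV, baseline JSON, summary JSON) under `out_dir`. Each
#' artifact is stamped with the config hash and master seed; rerunning
#' with the same config reproduces the outputs.
#'
#' @param cfg A [pipeline_config()].
#' @param out_dir Output directory.
#' @param write_recordings Write the (large) per-subject signal CSVs.
#' @return Invisibly, a list with the in-memory results of every stage.
#' @export
run_pipeline <- function(cfg = pipeline_config(), out_dir = tempfile("equispeed_"),
                         write_recordings = FALSE) {
  cfg <- validate_config(cfg)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stamp <- list(config_hash = config_hash(cfg), seed = cfg$seed)
  t0 <- Sys.time()
  log_stage <- function(msg) message(sprintf("[%5.1fs] %s",
                                             as.numeric(Sys.time() - t0, units = "secs"), msg))

  log_stage("simulate")
  cohort <- simulate_cohort(
    n_subjects = cfg$n_subjects,
    breed_mix = unlist(cfg$breed_mix),
    schedule_template = default_schedule(cfg$segment_duration),
    seed = cfg$seed
  )
  if (write_recordings) {
    for (rec in cohort)
      write_recording(rec, file.path(out_dir, "cohort", rec$subject_id))
  }

  log_stage("preprocess + window")
  windows <- cohort_windows(cohort, n = cfg$window_size)

  log_stage("features")
  fm_all <- build_feature_matrix(windows, "All")
  write_feature_matrix(fm_all, file.path(out_dir, "features_All.csv"))

  log_stage(sprintf("select (SFFS on %s)", cfg$select_set))
  fm_sel <- build_feature_matrix(windows, cfg$select_set)
  selection <- sffs_select(fm_sel, k = min(cfg$sffs_k, cfg$n_subjects),
                           criterion = cfg$sffs_criterion,
                           cap = cfg$sffs_cap, seed = cfg$seed)
  jsonlite::write_json(c(stamp, list(
    feature_set = cfg$select_set,
    ordered_features = selection$ordered_features,
    rmse_trajectory = selection$rmse_trajectory,
    baseline_rmse = selection$baseline_rmse,
    flags = selection$flags
  )), file.path(out_dir, "selection.json"), auto_unbox = TRUE, digits = NA)

  log_stage(sprintf("train/evaluate (%d sets x %d families)",
                    length(cfg$feature_sets), length(cfg$families)))
  grid <- run_grid(windows, families = cfg$families, sets = cfg$feature_sets,
                   seed = cfg$seed)
  write.csv(grid$table, file.path(out_dir, "grid.csv"), row.names = FALSE)
  reports <- lapply(grid$reports, function(r) {
    if (inherits(r, "grid_failure")) return(unclass(r))
    c(stamp, list(feature_set = r$feature_set, family = r$family,
                  mae = r$mae, rmse = r$rmse, nrmse = r$nrmse,
                  per_gait = r$per_gait, hyperparameters = r$hyperparameters))
  })
  jsonlite::write_json(reports, file.path(out_dir, "reports.json"),
                       auto_unbox = TRUE, digits = NA)

  log_stage("stride baseline")
  baseline <- stride_baseline(cohort, degree = cfg$poly_degree)
  write.csv(baseline$strides[, c("stride_frequency", "speed", "gait")],
            file.path(out_dir, "stride_scatter.csv"), row.names = FALSE)
  jsonlite::write_json(c(stamp, list(
    degree = baseline$fit$degree, coefficients = baseline$fit$coefficients,
    mae = baseline$fit$mae, rmse = baseline$fit$rmse,
    r_squared = baseline$fit$r_squared, n = baseline$fit$n
  )), file.path(out_dir, "stride_baseline.json"), auto_unbox = TRUE, digits = NA)

  summary <- c(stamp, list(
    n_subjects = cfg$n_subjects,
    n_windows = nrow(windows$meta),
    n_features_All = length(feature_columns(fm_all)),
    grid_cells = length(grid$reports),
    selected = selection$ordered_features,
    stride_rmse = baseline$fit$rmse
  ))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  log_stage("done")
  invisible(list(cohort = cohort, windows = windows, features = fm_all,
                 selection = selection, grid = grid, baseline = baseline,
                 out_dir = out_dir, stamp = stamp))
}
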