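#' Write a cohort of recordings to disk
#'
#' One long-format CSV per recording (`time_s, angle_deg, emg_RF, ...` on
#' the 1000 Hz grid, with the 200 Hz angle sampled-and-held) plus a native
#' 200 Hz angle CSV, a JSON manifest (ids, groups, seeds, true spectral
#' parameters, sampling rates) and a key-value config echo.
#'
#' @param recordings List of `recording` objects.
#' @param dir Output directory (created if absent).
#' @param config Optional [cohort_config()] echoed into `config.yml`.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(recordings, dir, config = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(recordings = list())
  for (rec in recordings) {
    fs_e <- rec$fs_emg
    n <- length(rec$emg[[1L]])
    t_emg <- (seq_len(n) - 1) / fs_e
    hold_idx <- pmin(floor(t_emg * rec$angle$fs) + 1L,
                     length(rec$angle$angle))
    dt <- data.table::data.table(time_s = t_emg,
                                 angle_deg = rec$angle$angle[hold_idx])
    for (m in names(rec$emg)) dt[[paste0("emg_", m)]] <- rec$emg[[m]]
    f_emg <- file.path(dir, paste0(rec$participant_id, ".csv"))
    data.table::fwrite(dt, f_emg)
    f_ang <- file.path(dir, paste0(rec$participant_id, "_angle200.csv"))
    data.table::fwrite(data.table::data.table(time_s = rec$angle$t,
                                              angle_deg = rec$angle$angle),
                       f_ang)
    manifest$recordings[[rec$participant_id]] <- list(
      participant_id = rec$participant_id,
      group = rec$group,
      seed = rec$seed,
      fs_emg = fs_e,
      fs_angle = rec$angle$fs,
      t0_onset_truth = rec$t0_onset_truth,
      emg_file = basename(f_emg),
      angle_file = basename(f_ang),
      muscles = names(rec$emg),
      true_params = lapply(rec$true_params, unclass)
    )
  }
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(config)) {
    flat <- config[!vapply(config, is.list, logical(1))]
    writeLines(paste0(names(flat), ": ",
                      vapply(flat, function(v) paste(v, collapse = ","),
                             character(1))),
               file.path(dir, "config.yml"))
  }
  invisible(dir)
}

#' Read a cohort of recordings from disk
#'
#' Reads the manifest written by [write_cohort()] and validates each file:
#' channels present, uniform timestamps, matching sampling rates.
#'
#' @param dir Directory containing `manifest.json` and per-recording CSVs.
#' @return Named list of `recording` objects.
#' @export
read_recordings <- function(dir) {
  mf_path <- file.path(dir, "manifest.json")
  if (!file.exists(mf_path)) stop("no manifest.json in ", dir)
  manifest <- jsonlite::read_json(mf_path, simplifyVector = FALSE)
  recs <- list()
  for (entry in manifest$recordings) {
    f_emg <- file.path(dir, entry$emg_file)
    f_ang <- file.path(dir, entry$angle_file)
    for (f in c(f_emg, f_ang))
      if (!file.exists(f))
        stop("manifest lists missing file: ", basename(f))
    dt <- data.table::fread(f_emg)
    muscles <- unlist(entry$muscles)
    cols <- paste0("emg_", muscles)
    miss <- setdiff(cols, names(dt))
    if (length(miss))
      stop("missing channel column(s) ", paste(miss, collapse = ", "),
           " in ", basename(f_emg))
    check_uniform_time(dt$time_s, 1 / entry$fs_emg, basename(f_emg))
    ang <- data.table::fread(f_ang)
    check_uniform_time(ang$time_s, 1 / entry$fs_angle, basename(f_ang))
    emg <- lapply(cols, function(cc) dt[[cc]])
    names(emg) <- muscles
    recs[[entry$participant_id]] <- structure(list(
      participant_id = entry$participant_id,
      group = entry$group,
      angle = list(t = ang$time_s, angle = ang$angle_deg,
                   fs = entry$fs_angle),
      emg = emg,
      fs_emg = entry$fs_emg,
      t0_onset_truth = entry$t0_onset_truth,
      true_params = entry$true_params,
      seed = entry$seed
    ), class = "recording")
  }
  recs
}

check_uniform_time <- function(t, dt_expect, fname) {
  dd <- diff(t)
  bad <- which(abs(dd - dt_expect) > dt_expect * 1e-6)
  if (length(bad))
    stop(sprintf("non-uniform timestamps in %s at row %d (gap %.6f s)",
                 fname, bad[1L] + 1L, dd[bad[1L]]))
  invisible(TRUE)
}
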