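#' Trial recording container
#'
#' Synchronized time series for one walking trial: marker positions (m), a
#' CoM channel, platform pitch (degrees) and belt speed (m/s), sampled
#' uniformly. Axis convention: X = mediolateral (+right),
#' Y = anteroposterior (+anterior), Z = vertical (+up).
#'
#' @param data data frame with columns `time_s`, `{M}_X/_Y/_Z` for markers
#'   LHEEL, RHEEL, LTOE, RTOE, LPSIS, RPSIS, C7, COM, plus
#'   `platform_pitch_deg` and `belt_speed_mps`.
#' @param sample_rate_hz sampling rate (Hz).
#' @param arm_condition arm-swing condition label.
#' @param trial_id trial label.
#' @return An object of class `trial_recording`.
#' @export
trial_recording <- function(data, sample_rate_hz, arm_condition = "normal",
                            trial_id = "trial") {
  need <- trial_channels()
  miss <- setdiff(need, names(data))
  if (length(miss) > 0) {
    stop("trial_recording: missing channel(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  dt <- diff(data$time_s)
  if (any(dt <= 0) || max(abs(dt - 1 / sample_rate_hz)) > 1e-6) {
    stop("trial_recording: time base must be strictly increasing at 1/sample_rate",
         call. = FALSE)
  }
  structure(list(data = data, sample_rate_hz = sample_rate_hz,
                 arm_condition = arm_condition, trial_id = trial_id),
            class = "trial_recording")
}

trial_markers <- function() {
  c("LHEEL", "RHEEL", "LTOE", "RTOE", "LPSIS", "RPSIS", "C7", "COM")
}

trial_channels <- function() {
  c("time_s",
    as.vector(t(outer(trial_markers(), c("_X", "_Y", "_Z"), paste0))),
    "platform_pitch_deg", "belt_speed_mps")
}

#' @export
print.trial_recording <- function(x, ...) {
  cat(sprintf("<trial_recording '%s'> %d samples @ %g Hz (%.1f s), arms: %s\n",
              x$trial_id, nrow(x$data), x$sample_rate_hz,
              nrow(x$data) / x$sample_rate_hz, x$arm_condition))
  invisible(x)
}

#' Write a trial recording to tab-delimited text
#'
#' The native on-disk format: `#`-prefixed metadata lines (sample rate, arm
#' condition, trial id) followed by a tab-delimited table with one header
#' row. Values are written with 17 significant digits so the file
#' round-trips doubles exactly.
#'
#' @param rec a [trial_recording()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trial <- function(rec, path) {
  stopifnot(inherits(rec, "trial_recording"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# slopegait trial recording",
               paste0("# sample_rate_hz: ", format(rec$sample_rate_hz, digits = 17)),
               paste0("# arm_condition: ", rec$arm_condition),
               paste0("# trial_id: ", rec$trial_id)), con)
  df <- rec$data
  fmt <- vapply(df, function(col) {
    out <- formatC(col, digits = 17, format = "g")
    out[is.na(col)] <- "NA"
    out
  }, character(nrow(df)))
  writeLines(paste(names(df), collapse = "\t"), con)
  writeLines(apply(fmt, 1, paste, collapse = "\t"), con)
  invisible(path)
}

#' Read a trial recording from tab-delimited text
#'
#' Reads the format written by [write_trial()]. Isolated gaps (runs of
#' missing samples up to `max_gap_s` seconds) in any channel are linearly
#' interpolated with a warning; longer gaps are an error. Positions that
#' look like millimetres (vertical CoM far above any plausible height in
#' metres) are rejected with instructions to convert.
#'
#' @param path input file path.
#' @param max_gap_s longest interpolatable gap (s). Default 0.1.
#' @return A [trial_recording()].
#' @export
read_trial <- function(path, max_gap_s = 0.1) {
  if (!file.exists(path)) stop("read_trial: file not found: ", path, call. = FALSE)
  hdr <- readLines(path, n = 20)
  meta <- grep("^# ", hdr, value = TRUE)
  get_meta <- function(key, default) {
    ln <- grep(paste0("^# ", key, ": "), meta, value = TRUE)
    if (length(ln) == 0) return(default)
    sub(paste0("^# ", key, ": "), "", ln[1])
  }
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                          colClasses = "numeric")
  miss <- setdiff(trial_channels(), names(df))
  if (length(miss) > 0) {
    stop("read_trial: missing mandatory channel(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  fs <- as.numeric(get_meta("sample_rate_hz", NA))
  if (is.na(fs)) {
    fs <- 1 / stats::median(diff(df$time_s))
  }
  dt <- diff(df$time_s)
  if (any(dt <= 0) || max(abs(dt - 1 / fs)) > 1e-6) {
    stop("read_trial: non-uniform time base", call. = FALSE)
  }
  if (max(abs(df$COM_Z), na.rm = TRUE) > 50) {
    stop("read_trial: positions appear to be in millimetres; convert to metres",
         call. = FALSE)
  }
  max_run <- max(1, floor(max_gap_s * fs))
  for (ch in setdiff(names(df), "time_s")) {
    x <- df[[ch]]
    if (anyNA(x)) {
      r <- rle(is.na(x))
      if (any(r$lengths[r$values] > max_run)) {
        stop("read_trial: gap longer than ", max_gap_s, " s in channel ", ch,
             call. = FALSE)
      }
      if (is.na(x[1]) || is.na(x[length(x)])) {
        stop("read_trial: channel ", ch, " starts or ends with missing samples",
             call. = FALSE)
      }
      df[[ch]] <- stats::approx(df$time_s[!is.na(x)], x[!is.na(x)],
                                xout = df$time_s)$y
      warning("read_trial: interpolated ", sum(is.na(x)),
              " missing sample(s) in channel ", ch, call. = FALSE)
    }
  }
  trial_recording(df, sample_rate_hz = fs,
                  arm_condition = get_meta("arm_condition", "normal"),
                  trial_id = get_meta("trial_id", basename(path)))
}

#' Default pipeline configuration
#'
#' Nested list of every tunable pipeline parameter with its default:
#' `terrain` (rolling-hills components), `walker` (generator settings and
#' arm-condition scalings), `filter` (cutoff 10 Hz, net order 4), `events`
#' (detection method and refractory fraction), `analysis` (slope band
#' \[1, 3\] degrees, level-section window \[10, 30\) m, minimum 3 steps per
#' class, flat lead-in 40 m, hills duration), `stats` (alpha 0.05) and
#' `study` (number of subjects and between-subject variation used by
#' [run_pipeline()]).
#'
#' @return A nested list; the same shape is accepted back by
#'   [run_pipeline()] and [read_config()].
#' @export
default_config <- function() {
  list(
    terrain = list(frequencies_hz = c(0.16, 0.21, 0.24, 0.49),
                   amplitudes = c(1, 1, 1, 1),
                   phases_rad = c(0, 0, 0, 0),
                   peak_deg = 3,
                   sample_rate_hz = 100),
    walker = list(step_time_s = 0.51, step_length_m = 0.616,
                  step_width_m = 0.198, dst_fraction = 0.301,
                  trunk_lean_deg = 7.49, noise_sd_m = 0.003,
                  jitter_frac = 0.03,
                  held_scale = 0.92, active_scale = 1.08,
                  held_lean_delta_deg = 1, active_lean_delta_deg = -2),
    filter = list(cutoff_hz = 10, order = 4),
    events = list(method = "velocity", refractory_frac = 0.25),
    analysis = list(slope_band_deg = c(1, 3),
                    level_window_m = c(10, 30),
                    min_steps_per_class = 3,
                    flat_lead_m = 40,
                    hills_duration_s = 150),
    stats = list(alpha = 0.05, contrasts = c("uphill", "downhill")),
    study = list(n_subjects = 15,
                 between_sd = list(step_time_s = 0.03, step_length_m = 0.05,
                                   step_width_m = 0.02, dst_fraction = 0.02,
                                   trunk_lean_deg = 1.5))
  )
}

#' Read a pipeline configuration file
#'
#' Reads a YAML configuration and merges it over [default_config()]
#' block-by-block, so a file only needs to name the keys it changes.
#'
#' @param path YAML file path.
#' @return Full configuration list.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- default_config()
  for (block in names(user)) {
    if (!block %in% names(cfg)) {
      warning("read_config: unknown config block '", block, "' ignored")
      next
    }
    for (key in names(user[[block]])) {
      cfg[[block]][[key]] <- user[[block]][[key]]
    }
  }
  cfg
}
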