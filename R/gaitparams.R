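#' Build a step skeleton from gait events
#'
#' One step per heel strike after the first: the step led by the foot
#' striking at heel strike k spans the half-open sample interval
#' \[previous contralateral heel strike, this heel strike). Refuses to run
#' if the event set fails [check_event_integrity()].
#'
#' @param events a `gait_events` object.
#' @param rec the matching [trial_recording()] (used for bounds checking).
#' @return Data frame with columns `step`, `side`, `start`, `end` (1-based
#'   samples, interval \[`start`, `end`)); the leading heel strike is at
#'   sample `end`.
#' @export
steps_from_events <- function(events, rec = NULL) {
  diag <- check_event_integrity(events)
  empty <- nrow(diag) == 1 && diag$check[1] == "empty"
  if (nrow(diag) > 0 && !empty) {
    stop("steps_from_events: event set fails integrity checks (",
         paste(unique(diag$check), collapse = ", "),
         "); run check_event_integrity() for details", call. = FALSE)
  }
  allhs <- rbind(data.frame(side = rep("L", length(events$hs$L)), idx = events$hs$L),
                 data.frame(side = rep("R", length(events$hs$R)), idx = events$hs$R))
  allhs <- allhs[order(allhs$idx), ]
  m <- nrow(allhs)
  if (m < 2) {
    return(data.frame(step = integer(0), side = character(0),
                      start = integer(0), end = integer(0)))
  }
  data.frame(step = seq_len(m - 1),
             side = allhs$side[-1],
             start = as.integer(allhs$idx[-m]),
             end = as.integer(allhs$idx[-1]))
}

#' Step length from heel positions at heel strike
#'
#' The hypotenuse of the anteroposterior and vertical distances between the
#' two heels at the leading leg's heel strike; the mediolateral separation
#' is excluded by definition.
#'
#' @param lead_heel,trail_heel numeric length-3 positions `c(X, Y, Z)` =
#'   (ML, AP, VT) in metres, both at the leading heel-strike sample.
#' @return Step length in cm.
#' @export
step_length_cm <- function(lead_heel, trail_heel) {
  100 * sqrt((lead_heel[2] - trail_heel[2])^2 + (lead_heel[3] - trail_heel[3])^2)
}

#' Step width from heel positions at heel strike
#'
#' Absolute mediolateral distance between the lateral heel markers at the
#' leading leg's heel strike.
#'
#' @inheritParams step_length_cm
#' @return Step width in cm.
#' @export
step_width_cm <- function(lead_heel, trail_heel) {
  100 * abs(lead_heel[1] - trail_heel[1])
}

#' Mean belt speed over a step
#'
#' @param belt_speed belt-speed channel (m/s).
#' @param start,end step interval, 1-based half-open \[`start`, `end`).
#' @return Mean speed (m/s).
#' @export
step_speed <- function(belt_speed, start, end) {
  if (!(start >= 1 && start < end && end <= length(belt_speed) + 1)) {
    stop("step_speed: empty or out-of-range interval", call. = FALSE)
  }
  mean(belt_speed[start:(end - 1)])
}

#' Inverted-pendulum model from heel-strike geometry
#'
#' The pendulum length is the mean 3D distance from the leading lateral
#' heel marker to the CoM over all heel strikes of the trial; the
#' eigenfrequency is `omega = sqrt(g / l)` with g = 9.81 m/s^2.
#'
#' @param l_m pendulum length (m), > 0.
#' @return List of class `pendulum_model` with `l_m`, `omega` (1/s) and
#'   `g` (9.81 m/s^2).
#' @export
pendulum_model <- function(l_m) {
  if (!is.finite(l_m) || l_m <= 0) {
    stop("pendulum_model: pendulum length must be positive", call. = FALSE)
  }
  g <- 9.81
  structure(list(l_m = l_m, omega = sqrt(g / l_m), g = g),
            class = "pendulum_model")
}

#' @export
print.pendulum_model <- function(x, ...) {
  cat(sprintf("pendulum l = %.3f m, omega0 = %.3f 1/s\n", x$l_m, x$omega))
  invisible(x)
}

#' Estimate the pendulum model from a trial
#'
#' @param rec a [trial_recording()]; heel and CoM channels are low-pass
#'   filtered before measuring.
#' @param events a `gait_events` object for the same trial.
#' @param cutoff_hz,order filter settings.
#' @return A [pendulum_model()].
#' @export
pendulum_length <- function(rec, events, cutoff_hz = 10, order = 4) {
  df <- rec$data
  fs <- rec$sample_rate_hz
  f <- function(ch) lowpass_zero_lag(df[[ch]], fs, cutoff_hz, order)
  com <- cbind(f("COM_X"), f("COM_Y"), f("COM_Z"))
  dists <- c()
  for (s in c("L", "R")) {
    idx <- events$hs[[s]]
    if (length(idx) == 0) next
    heel <- cbind(f(paste0(s, "HEEL_X")), f(paste0(s, "HEEL_Y")),
                  f(paste0(s, "HEEL_Z")))
    dists <- c(dists, sqrt(rowSums((heel[idx, , drop = FALSE] -
                                    com[idx, , drop = FALSE])^2)))
  }
  if (length(dists) == 0) {
    stop("pendulum_length: no heel strikes available", call. = FALSE)
  }
  pendulum_model(mean(dists))
}

#' Extrapolated centre of mass (mediolateral)
#'
#' `xCoM = CoMp + CoMv / omega`: the CoM position extrapolated along its
#' velocity by the inverted-pendulum time constant.
#'
#' @param com_pos_ml mediolateral CoM position (m).
#' @param com_vel_ml mediolateral CoM velocity (m/s).
#' @param model a [pendulum_model()].
#' @return xCoM mediolateral coordinate (m).
#' @export
extrapolated_com <- function(com_pos_ml, com_vel_ml, model) {
  stopifnot(inherits(model, "pendulum_model"))
  com_pos_ml + com_vel_ml / model$omega
}

#' Mediolateral margin of stability
#'
#' Signed distance from the extrapolated centre of mass to the lateral
#' boundary of the base of support (the lateral heel marker) at the leading
#' heel strike. With +ML = rightward, the sign is mirrored between sides so
#' that positive always means the xCoM lies medial to the lateral boundary
#' (stable).
#'
#' @param heel_ml lateral heel marker ML coordinate (m) at heel strike.
#' @param xcom_ml xCoM ML coordinate (m) at the same sample.
#' @param side `"L"` or `"R"`, the leading side.
#' @return Margin of stability in cm; positive = stable.
#' @export
ml_margin_of_stability <- function(heel_ml, xcom_ml, side) {
  if (!side %in% c("L", "R")) {
    stop("ml_margin_of_stability: side must be 'L' or 'R'", call. = FALSE)
  }
  if (side == "R") 100 * (heel_ml - xcom_ml) else 100 * (xcom_ml - heel_ml)
}

#' Sagittal trunk angle
#'
#' Inclination of the PSIS-midpoint-to-C7 line from global vertical in the
#' anteroposterior plane; positive = C7 anterior of the pelvis (forward
#' lean).
#'
#' @param psis_mid,c7 numeric length-3 positions `c(ML, AP, VT)` in metres
#'   at the same sample.
#' @return Trunk angle in degrees.
#' @export
trunk_angle <- function(psis_mid, c7) {
  d_ap <- c7[2] - psis_mid[2]
  d_vt <- c7[3] - psis_mid[3]
  if (d_vt <= 0) {
    stop("trunk_angle: C7 must lie above the PSIS midpoint", call. = FALSE)
  }
  atan2(d_ap, d_vt) * 180 / pi
}

#' Coefficient of variation
#'
#' `100 * sd / |mean|` with the sample (n-1) standard deviation; the
#' step-to-step variability index.
#'
#' @param values numeric vector, length >= 2, with nonzero mean.
#' @return CoV in percent.
#' @export
coefficient_of_variation <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 2) {
    stop("coefficient_of_variation: need at least 2 values", call. = FALSE)
  }
  m <- mean(values)
  if (m == 0) {
    stop("coefficient_of_variation: undefined for zero mean", call. = FALSE)
  }
  100 * stats::sd(values) / abs(m)
}

#' Per-axis trunk-acceleration RMS over step intervals
#'
#' RMS is computed per step interval, then averaged across the supplied
#' steps; used per slope class as an upper-body variability measure.
#'
#' @param accel numeric acceleration series for one axis (m/s^2).
#' @param intervals two-column matrix or data frame of half-open step
#'   intervals (`start`, `end`), 1-based samples.
#' @return Mean per-step RMS (m/s^2); `NA` when no intervals are given.
#' @export
trunk_rms <- function(accel, intervals) {
  if (NROW(intervals) == 0) return(NA_real_)
  vals <- vapply(seq_len(NROW(intervals)), function(i) {
    s <- intervals[i, 1]
    e <- intervals[i, 2]
    sqrt(mean(accel[s:(e - 1)]^2))
  }, numeric(1))
  mean(vals)
}

#' Select level-walking steps
#'
#' Level steps are those whose leading heel strike occurs while the
#' cumulative belt distance lies in the half-open window `window_m` (the
#' middle of the flat lead-in section) and whose interval has identically
#' zero platform pitch.
#'
#' @param rec a [trial_recording()].
#' @param steps step table with `start`/`end` columns (samples).
#' @param window_m distance window in metres, default `c(10, 30)`.
#' @return Logical vector marking level steps; all-`FALSE` with a warning
#'   when the trial has no flat section.
#' @export
select_level_steps <- function(rec, steps, window_m = c(10, 30)) {
  dist <- cumsum(rec$data$belt_speed_mps) / rec$sample_rate_hz
  pitch <- rec$data$platform_pitch_deg
  sel <- vapply(seq_len(nrow(steps)), function(i) {
    hs <- steps$end[i]
    dist[hs] >= window_m[1] && dist[hs] < window_m[2] &&
      all(pitch[steps$start[i]:(steps$end[i] - 1)] == 0)
  }, logical(1))
  if (!any(sel) && nrow(steps) > 0) {
    warning("select_level_steps: no level steps found (trial may lack a flat section)")
  }
  sel
}

# Step time and double-support percentage for one step.
#
# hs_all: sorted data frame (side, idx) of all heel strikes; to_events:
# gait_events$to; k: index of the step's leading heel strike in hs_all.
# DST is defined on the stride starting at this step's leading heel strike:
# DS1 runs from the leading heel strike to the trailing foot's toe-off,
# DS2 from the next contralateral heel strike to the leading foot's
# toe-off; stride time is to the leading foot's next heel strike.
step_time_dst_at <- function(hs_all, to_events, k, fs) {
  t_hs <- hs_all$idx[k]
  time_s <- (t_hs - hs_all$idx[k - 1]) / fs
  if (k + 2 > nrow(hs_all)) {
    return(list(time_s = time_s, dst_pct = NA_real_))
  }
  lead <- hs_all$side[k]
  trail <- if (lead == "L") "R" else "L"
  stride <- hs_all$idx[k + 2] - t_hs
  to_trail <- to_events[[trail]][to_events[[trail]] >= t_hs]
  to_lead <- to_events[[lead]][to_events[[lead]] >= hs_all$idx[k + 1]]
  if (length(to_trail) == 0 || length(to_lead) == 0) {
    return(list(time_s = time_s, dst_pct = NA_real_))
  }
  ds1 <- to_trail[1] - t_hs
  ds2 <- to_lead[1] - hs_all$idx[k + 1]
  list(time_s = time_s, dst_pct = 100 * (ds1 + ds2) / stride)
}

#' Compute the full per-step outcome table for a trial
#'
#' Runs the whole measurement chain on one trial: low-pass filtering,
#' per-step spatiotemporal measures (length, width, time, double-support
#' percentage, speed), the mediolateral margin of stability at each leading
#' heel strike (via the trial-level inverted-pendulum model and the
#' extrapolated CoM), per-step mean trunk angle and per-axis
#' trunk-acceleration RMS, and slope classification of every step
#' (`uphill` / `downhill` / `level` / `excluded`).
#'
#' @param rec a [trial_recording()].
#' @param events a `gait_events` object; computed with default settings
#'   when omitted.
#' @param cutoff_hz,order filter settings applied to marker and CoM
#'   channels.
#' @param slope_band uphill/downhill mean-pitch band (degrees).
#' @param level_window_m level-section distance window (m).
#' @return Data frame (one row per step): `step`, `side`, `start`, `end`,
#'   `time_s`, `length_cm`, `width_cm`, `dst_pct`, `speed_mps`, `mos_cm`,
#'   `trunk_angle_deg`, `rms_ap`, `rms_ml`, `rms_vt`, `mean_pitch_deg`,
#'   `spans_extremum`, `slope_class`. The fitted [pendulum_model()] is
#'   attached as attribute `pendulum`.
#' @export
compute_step_table <- function(rec, events = detect_gait_events(rec),
                               cutoff_hz = 10, order = 4,
                               slope_band = c(1, 3),
                               level_window_m = c(10, 30)) {
  df <- rec$data
  fs <- rec$sample_rate_hz
  f <- function(ch) lowpass_zero_lag(df[[ch]], fs, cutoff_hz, order)

  steps <- steps_from_events(events, rec)
  if (nrow(steps) == 0) return(steps)

  heel <- list(L = cbind(f("LHEEL_X"), f("LHEEL_Y"), f("LHEEL_Z")),
               R = cbind(f("RHEEL_X"), f("RHEEL_Y"), f("RHEEL_Z")))
  com_ml <- f("COM_X")
  com_ml_vel <- derivative(com_ml, fs)
  pend <- pendulum_length(rec, events, cutoff_hz, order)

  psis_ap <- (f("LPSIS_Y") + f("RPSIS_Y")) / 2
  psis_vt <- (f("LPSIS_Z") + f("RPSIS_Z")) / 2
  c7 <- list(ml = f("C7_X"), ap = f("C7_Y"), vt = f("C7_Z"))
  trunk_series <- atan2(c7$ap - psis_ap, c7$vt - psis_vt) * 180 / pi
  acc <- list(ap = derivative(c7$ap, fs, 2),
              ml = derivative(c7$ml, fs, 2),
              vt = derivative(c7$vt, fs, 2))

  pitch <- df$platform_pitch_deg
  extrema <- if (stats::sd(pitch) > 0) locate_extrema(pitch) else integer(0)

  hs_all <- rbind(data.frame(side = rep("L", length(events$hs$L)), idx = events$hs$L),
                  data.frame(side = rep("R", length(events$hs$R)), idx = events$hs$R))
  hs_all <- hs_all[order(hs_all$idx), ]

  n <- nrow(steps)
  out <- steps
  out$time_s <- NA_real_
  out$length_cm <- NA_real_
  out$width_cm <- NA_real_
  out$dst_pct <- NA_real_
  out$speed_mps <- NA_real_
  out$mos_cm <- NA_real_
  out$trunk_angle_deg <- NA_real_
  out$rms_ap <- NA_real_
  out$rms_ml <- NA_real_
  out$rms_vt <- NA_real_
  out$mean_pitch_deg <- NA_real_
  out$spans_extremum <- NA
  out$slope_class <- NA_character_

  for (i in seq_len(n)) {
    lead <- steps$side[i]
    trail <- if (lead == "L") "R" else "L"
    hs_i <- steps$end[i]
    # Foot separation is read at the middle of the initial double-support
    # phase: both feet are planted there, so the separation equals its
    # value at the contact instant, but the filtered trajectories are
    # locally linear (the zero-lag filter rounds the swing-to-stance
    # corner at the contact sample itself).
    to_trail <- events$to[[trail]][events$to[[trail]] >= hs_i]
    geom_i <- if (length(to_trail) > 0) {
      min(nrow(df), hs_i + floor((to_trail[1] - hs_i) / 2))
    } else hs_i
    lead_pos <- heel[[lead]][geom_i, ]
    trail_pos <- heel[[trail]][geom_i, ]
    out$length_cm[i] <- step_length_cm(lead_pos, trail_pos)
    out$width_cm[i] <- step_width_cm(lead_pos, trail_pos)
    td <- step_time_dst_at(hs_all, events$to, i + 1, fs)
    out$time_s[i] <- td$time_s
    out$dst_pct[i] <- td$dst_pct
    out$speed_mps[i] <- step_speed(df$belt_speed_mps, steps$start[i], steps$end[i])
    xcom <- extrapolated_com(com_ml[hs_i], com_ml_vel[hs_i], pend)
    out$mos_cm[i] <- ml_margin_of_stability(heel[[lead]][hs_i, 1], xcom, lead)
    iv <- steps$start[i]:(steps$end[i] - 1)
    out$trunk_angle_deg[i] <- mean(trunk_series[iv])
    out$rms_ap[i] <- sqrt(mean(acc$ap[iv]^2))
    out$rms_ml[i] <- sqrt(mean(acc$ml[iv]^2))
    out$rms_vt[i] <- sqrt(mean(acc$vt[iv]^2))
    cls <- classify_step_slope(steps$start[i], steps$end[i], pitch, extrema,
                               band = slope_band)
    out$mean_pitch_deg[i] <- cls$mean_pitch_deg
    out$spans_extremum[i] <- cls$spans_extremum
    out$slope_class[i] <- cls$class_label
  }

  lvl <- suppressWarnings(select_level_steps(rec, steps, level_window_m))
  out$slope_class[lvl & out$slope_class == "excluded"] <- "level"
  attr(out, "pendulum") <- pend
  out
}

#' Summarise a step table by slope class
#'
#' Per-slope-class condition summary: means and coefficients of variation
#' of the spatiotemporal measures and the margin of stability, mean speed,
#' mean trunk angle, and per-axis trunk-acceleration RMS (mean of per-step
#' RMS). Classes with fewer than `min_steps` contributing steps are
#' omitted.
#'
#' @param steps a step table from [compute_step_table()].
#' @param min_steps minimum steps per class for a summary row. Default 3.
#' @return Data frame with one row per slope class present.
#' @export
summarize_conditions <- function(steps, min_steps = 3) {
  classes <- intersect(c("uphill", "level", "downhill"),
                       unique(steps$slope_class))
  rows <- lapply(classes, function(cl) {
    s <- steps[steps$slope_class == cl, ]
    if (nrow(s) < min_steps) return(NULL)
    data.frame(
      slope_class = cl,
      n_steps = nrow(s),
      speed = mean(s$speed_mps),
      step_length = mean(s$length_cm),
      step_length_cov = coefficient_of_variation(s$length_cm),
      step_width = mean(s$width_cm),
      step_width_cov = coefficient_of_variation(s$width_cm),
      step_time = mean(s$time_s),
      step_time_cov = coefficient_of_variation(s$time_s),
      dst = mean(s$dst_pct, na.rm = TRUE),
      dst_cov = coefficient_of_variation(s$dst_pct),
      mos = mean(s$mos_cm),
      mos_cov = coefficient_of_variation(s$mos_cm),
      trunk_angle = mean(s$trunk_angle_deg),
      rms_ap = mean(s$rms_ap),
      rms_ml = mean(s$rms_ml),
      rms_vt = mean(s$rms_vt)
    )
  })
  do.call(rbind, rows)
}

#' Analyse one trial end to end
#'
#' Convenience wrapper: event detection, step table, condition summary.
#'
#' @param rec a [trial_recording()].
#' @param config pipeline configuration list, see [default_config()].
#' @return List with `events`, `steps` and `summary`.
#' @export
analyze_trial <- function(rec, config = default_config()) {
  events <- detect_gait_events(rec,
                               method = config$events$method,
                               cutoff_hz = config$filter$cutoff_hz,
                               order = config$filter$order,
                               refractory_frac = config$events$refractory_frac)
  steps <- compute_step_table(rec, events,
                              cutoff_hz = config$filter$cutoff_hz,
                              order = config$filter$order,
                              slope_band = config$analysis$slope_band_deg,
                              level_window_m = config$analysis$level_window_m)
  list(events = events, steps = steps,
       summary = summarize_conditions(steps, config$analysis$min_steps_per_class))
}
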