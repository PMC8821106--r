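#' Synthetic walker parameters
#'
#' Parameter set for the kinematic treadmill-walker simulator. Defaults are
#' centred on typical level-walking values for healthy young adults with
#' normal arm swing (step length 61.6 cm, step time 0.51 s, step width
#' 19.8 cm, double support 30.1% of stride, trunk lean 7.49 degrees).
#'
#' @param step_time_s mean step duration (s).
#' @param step_length_m mean step length (m).
#' @param step_width_m mean mediolateral heel separation (m).
#' @param dst_fraction fraction of the stride spent in double support, in
#'   (0, 0.5).
#' @param com_ml_amp_m mediolateral CoM oscillation amplitude (m), at stride
#'   frequency.
#' @param com_vt_amp_m vertical CoM oscillation amplitude (m), at step
#'   frequency.
#' @param trunk_lean_deg mean forward trunk inclination (degrees).
#' @param arm_condition one of `"held"`, `"normal"`, `"active"`; see
#'   [arm_condition_params()].
#' @param noise_sd_m additive i.i.d. Gaussian noise SD on marker channels
#'   (m). Default 3 mm, a typical optical motion-capture noise floor.
#' @param n_steps number of steps to simulate (>= 4).
#' @param seed RNG seed for jitter and noise; identical seeds give
#'   bit-identical trials.
#' @param jitter_frac per-step timing jitter SD as a fraction of
#'   `step_time_s` (0 disables jitter). Default 0.03.
#' @param com_height_m mean CoM height (m).
#' @param trunk_length_m PSIS-midpoint to C7 distance along the trunk (m).
#' @param trunk_osc_amp_m anteroposterior C7 oscillation amplitude (m) at
#'   step frequency; drives trunk-acceleration RMS.
#' @param com_ap_amp_m anteroposterior CoM/pelvis oscillation amplitude (m).
#' @param pelvis_width_m mediolateral PSIS marker separation (m).
#' @param foot_length_m heel-to-toe marker distance (m).
#' @param swing_clearance_m peak vertical heel clearance during swing (m).
#' @param belt_fluct_mps amplitude of the slow belt-speed fluctuation (m/s).
#'
#' @return An object of class `walker_params`.
#' @export
walker_params <- function(step_time_s = 0.51,
                          step_length_m = 0.616,
                          step_width_m = 0.198,
                          dst_fraction = 0.301,
                          com_ml_amp_m = 0.02,
                          com_vt_amp_m = 0.015,
                          trunk_lean_deg = 7.49,
                          arm_condition = "normal",
                          noise_sd_m = 0.003,
                          n_steps = 50,
                          seed = 1,
                          jitter_frac = 0.03,
                          com_height_m = 0.93,
                          trunk_length_m = 0.45,
                          trunk_osc_amp_m = 0.013,
                          com_ap_amp_m = 0.005,
                          pelvis_width_m = 0.16,
                          foot_length_m = 0.15,
                          swing_clearance_m = 0.05,
                          belt_fluct_mps = 0.02) {
  p <- list(step_time_s = step_time_s, step_length_m = step_length_m,
            step_width_m = step_width_m, dst_fraction = dst_fraction,
            com_ml_amp_m = com_ml_amp_m, com_vt_amp_m = com_vt_amp_m,
            trunk_lean_deg = trunk_lean_deg, arm_condition = arm_condition,
            noise_sd_m = noise_sd_m, n_steps = as.integer(n_steps),
            seed = as.integer(seed), jitter_frac = jitter_frac,
            com_height_m = com_height_m, trunk_length_m = trunk_length_m,
            trunk_osc_amp_m = trunk_osc_amp_m, com_ap_amp_m = com_ap_amp_m,
            pelvis_width_m = pelvis_width_m, foot_length_m = foot_length_m,
            swing_clearance_m = swing_clearance_m,
            belt_fluct_mps = belt_fluct_mps)
  lens <- c(p$step_time_s, p$step_length_m, p$step_width_m, p$com_height_m,
            p$trunk_length_m, p$foot_length_m)
  if (any(!is.finite(lens)) || any(lens <= 0)) {
    stop("walker_params: lengths and times must be positive", call. = FALSE)
  }
  if (!(p$dst_fraction > 0 && p$dst_fraction < 0.5)) {
    stop("walker_params: dst_fraction must lie in (0, 0.5)", call. = FALSE)
  }
  if (p$n_steps < 4) {
    stop("walker_params: n_steps must be at least 4", call. = FALSE)
  }
  if (!p$arm_condition %in% c("held", "normal", "active")) {
    stop("walker_params: arm_condition must be held, normal or active",
         call. = FALSE)
  }
  if (p$noise_sd_m < 0 || p$jitter_frac < 0) {
    stop("walker_params: noise_sd_m and jitter_frac must be >= 0", call. = FALSE)
  }
  structure(p, class = "walker_params")
}

#' Apply an arm-swing condition to walker parameters
#'
#' Maps an arm-swing instruction onto the generator parameters it affects.
#' Holding the arms shortens steps (and hence derived speed) and tilts the
#' trunk further forward; active arm swing lengthens both step length and
#' step time (leaving derived speed about unchanged) and straightens the
#' trunk. Trunk AP oscillation scales with arm swing so that
#' trunk-acceleration RMS orders held < normal < active. The scalings are
#' synthetic effect knobs, overridable, but any override must keep the step
#' length ordering held < normal < active.
#'
#' @param base a [walker_params()] object.
#' @param condition `"held"`, `"normal"` or `"active"`.
#' @param held_scale multiplicative step-length scale for `"held"`
#'   (default 0.92, must be < 1).
#' @param active_scale multiplicative step-length and step-time scale for
#'   `"active"` (default 1.08, must be > 1).
#' @param held_lean_delta_deg trunk-lean increase for `"held"` (degrees).
#' @param active_lean_delta_deg trunk-lean change for `"active"` (degrees,
#'   negative = straighter).
#' @return A `walker_params` object for the requested condition.
#' @export
arm_condition_params <- function(base, condition,
                                 held_scale = 0.92,
                                 active_scale = 1.08,
                                 held_lean_delta_deg = 1,
                                 active_lean_delta_deg = -2) {
  stopifnot(inherits(base, "walker_params"))
  if (!is.character(condition) || length(condition) != 1 ||
      !condition %in% c("held", "normal", "active")) {
    stop("arm_condition_params: unknown arm condition ",
         deparse(substitute(condition)), call. = FALSE)
  }
  if (!(held_scale < 1 && active_scale > 1)) {
    stop("arm_condition_params: overrides must keep held < normal < active step length",
         call. = FALSE)
  }
  p <- unclass(base)
  if (condition == "held") {
    p$step_length_m <- p$step_length_m * held_scale
    p$trunk_lean_deg <- p$trunk_lean_deg + held_lean_delta_deg
    p$trunk_osc_amp_m <- p$trunk_osc_amp_m * 0.8
  } else if (condition == "active") {
    p$step_length_m <- p$step_length_m * active_scale
    p$step_time_s <- p$step_time_s * active_scale
    p$trunk_lean_deg <- p$trunk_lean_deg + active_lean_delta_deg
    p$trunk_osc_amp_m <- p$trunk_osc_amp_m * 1.3
  }
  p$arm_condition <- condition
  structure(p, class = "walker_params")
}

# Heel AP/VT trajectory of one foot over the trial.
#
# lands: land times delimiting the foot's cycles (first/last extend beyond
# the trial window); contras: the contralateral heel-strike time inside each
# cycle. During stance the foot translates backward at belt speed v from its
# landing position L/2; after toe-off (half a double-support phase past the
# contralateral strike) it swings forward along a half-cosine profile with a
# half-sine vertical clearance arc, landing again at L/2.
foot_trajectory <- function(tt, lands, contras, v, L, dst_fraction, clearance) {
  k <- length(lands) - 1
  ci <- findInterval(tt, lands)
  ci[ci < 1L] <- 1L
  ci[ci > k] <- k
  land_i <- lands[ci]
  land_n <- lands[ci + 1]
  stride <- land_n - land_i
  to <- contras[ci] + 0.5 * dst_fraction * stride
  x <- numeric(length(tt))
  z <- numeric(length(tt))
  stance <- tt <= to
  x[stance] <- L / 2 - v * (tt[stance] - land_i[stance])
  sw <- !stance
  if (any(sw)) {
    x_to <- L / 2 - v * (to - land_i)
    s <- pmin(pmax((tt - to) / (land_n - to), 0), 1)
    x[sw] <- (x_to + (L / 2 - x_to) * (1 - cos(pi * s)) / 2)[sw]
    z[sw] <- (clearance * sin(pi * s))[sw]
  }
  list(ap = x, vt = z)
}

#' Simulate a treadmill walking trial with known ground truth
#'
#' Generates a kinematic (prescribed-trajectory) treadmill walking trial:
#' lateral heel and toe markers for both feet, PSIS pair, C7, a CoM channel,
#' a belt-speed channel and a platform-pitch channel, sampled at
#' `sample_rate_hz` in a treadmill frame where the feet oscillate about a
#' fixed origin. Axis convention: X = mediolateral (+right),
#' Y = anteroposterior (+anterior), Z = vertical (+up), all in meters.
#'
#' The stance foot translates backward at belt speed; the swing foot
#' advances along a smooth half-cosine profile with a half-sine vertical
#' clearance arc, landing `step_length_m` ahead of the other heel. Per-step
#' timing jitter is Gaussian with SD `jitter_frac * step_time_s`; additive
#' i.i.d. Gaussian noise of SD `noise_sd_m` is applied to the seven physical
#' marker channels (the CoM channel, a model-derived signal, stays clean).
#' Identical seeds yield bit-identical output.
#'
#' @param params a [walker_params()] object.
#' @param terrain optional [terrain_config()]; when given, the platform
#'   pitch channel follows the rolling-hills signal (regenerated at the
#'   trial's rate and duration) once the cumulative belt distance exceeds
#'   `flat_lead_m`, and is zero before. When `NULL` the pitch is zero
#'   throughout.
#' @param flat_lead_m length of the level lead-in section (m of belt
#'   travel) before the terrain starts. Default 0.
#' @param sample_rate_hz sampling rate (Hz), default 100.
#' @param trial_id label stored in the recording.
#'
#' @return A list with components:
#' \describe{
#'   \item{recording}{a `trial_recording`: see [trial_recording()].}
#'   \item{truth}{data frame of per-step ground truth: `step`, `side`,
#'     `hs_time_s`, `to_time_s` (toe-off of the trailing foot), `length_cm`,
#'     `width_cm`, `time_s`, `dst_pct`, plus attributes `trunk_angle_deg`
#'     and `params`.}
#' }
#' @export
simulate_trial <- function(params, terrain = NULL, flat_lead_m = 0,
                           sample_rate_hz = 100, trial_id = "sim") {
  stopifnot(inherits(params, "walker_params"))
  p <- params
  fs <- sample_rate_hz
  T0 <- p$step_time_s
  v <- p$step_length_m / T0
  ns <- p$n_steps
  set.seed(p$seed)
  jit <- if (p$jitter_frac > 0) stats::rnorm(ns, 0, p$jitter_frac * T0) else numeric(ns)
  dt <- pmax(0.5 * T0, pmin(1.5 * T0, T0 + jit))
  hs <- cumsum(dt)                       # heel-strike times, first near T0
  side <- rep(c("L", "R"), length.out = ns)
  dur <- hs[ns] + 0.6 * T0   # ends mid-double-support after the last strike
  n_samp <- floor(dur * fs) + 1L
  tt <- (seq_len(n_samp) - 1) / fs

  hsL <- hs[side == "L"]
  hsR <- hs[side == "R"]
  landsL <- c(hsL[1] - 2 * T0, hsL, hsL[length(hsL)] + 2 * T0)
  landsR <- c(hsR[1] - 2 * T0, hsR, hsR[length(hsR)] + 2 * T0)
  contra_for <- function(lands, other) {
    k <- length(lands) - 1
    out <- numeric(k)
    for (i in seq_len(k)) {
      idx <- findInterval(lands[i + 1] - 1e-9, other)
      cand <- if (idx >= 1) other[idx] else -Inf
      out[i] <- if (cand > lands[i]) cand else (lands[i] + lands[i + 1]) / 2
    }
    out
  }
  contrasL <- contra_for(landsL, landsR)
  contrasR <- contra_for(landsR, landsL)

  fl <- foot_trajectory(tt, landsL, contrasL, v, p$step_length_m,
                        p$dst_fraction, p$swing_clearance_m)
  fr <- foot_trajectory(tt, landsR, contrasR, v, p$step_length_m,
                        p$dst_fraction, p$swing_clearance_m)

  stride_T <- 2 * T0
  com_ml <- p$com_ml_amp_m * sin(2 * pi * (tt - hs[1]) / stride_T)
  com_ap <- p$com_ap_amp_m * sin(2 * pi * tt / T0)
  com_vt <- p$com_height_m + p$com_vt_amp_m * sin(2 * pi * tt / T0)
  pelvis_ap <- com_ap
  lean_rad <- p$trunk_lean_deg * pi / 180
  c7_ap <- pelvis_ap + tan(lean_rad) * p$trunk_length_m +
    p$trunk_osc_amp_m * sin(2 * pi * tt / T0 + pi / 3)
  c7_vt <- p$com_height_m + p$trunk_length_m

  belt <- v + p$belt_fluct_mps * sin(2 * pi * 0.1 * tt)

  pitch <- numeric(n_samp)
  if (!is.null(terrain)) {
    dist <- cumsum(belt) / fs
    i0 <- which(dist >= flat_lead_m)[1]
    if (is.na(i0)) {
      warning("simulate_trial: trial too short to reach the terrain section")
    } else {
      tcfg <- terrain_config(frequencies_hz = terrain$frequencies_hz,
                             amplitudes = terrain$amplitudes,
                             phases_rad = terrain$phases_rad,
                             peak_deg = terrain$peak_deg,
                             duration_s = (n_samp - i0 + 1) / fs,
                             sample_rate_hz = fs)
      tp <- generate_platform_pitch(tcfg)
      pitch[i0:n_samp] <- tp[seq_len(n_samp - i0 + 1)]
    }
  }

  noise <- function() if (p$noise_sd_m > 0) stats::rnorm(n_samp, 0, p$noise_sd_m) else 0
  df <- data.frame(
    time_s = tt,
    LHEEL_X = -p$step_width_m / 2 + noise(),
    LHEEL_Y = fl$ap + noise(),
    LHEEL_Z = fl$vt + noise(),
    RHEEL_X = p$step_width_m / 2 + noise(),
    RHEEL_Y = fr$ap + noise(),
    RHEEL_Z = fr$vt + noise(),
    LTOE_X = -p$step_width_m / 2 + noise(),
    LTOE_Y = fl$ap + p$foot_length_m + noise(),
    LTOE_Z = fl$vt + noise(),
    RTOE_X = p$step_width_m / 2 + noise(),
    RTOE_Y = fr$ap + p$foot_length_m + noise(),
    RTOE_Z = fr$vt + noise(),
    LPSIS_X = -p$pelvis_width_m / 2 + noise(),
    LPSIS_Y = pelvis_ap + noise(),
    LPSIS_Z = p$com_height_m + noise(),
    RPSIS_X = p$pelvis_width_m / 2 + noise(),
    RPSIS_Y = pelvis_ap + noise(),
    RPSIS_Z = p$com_height_m + noise(),
    C7_X = 0 + noise(),
    C7_Y = c7_ap + noise(),
    C7_Z = c7_vt + noise(),
    COM_X = com_ml,
    COM_Y = com_ap,
    COM_Z = com_vt,
    platform_pitch_deg = pitch,
    belt_speed_mps = belt
  )
  rec <- trial_recording(df, sample_rate_hz = fs,
                         arm_condition = p$arm_condition, trial_id = trial_id)

  # ground truth: one step per heel strike after the first
  k <- 2:ns
  to_time <- rep(NA_real_, length(k))
  dst_pct <- rep(NA_real_, length(k))
  for (j in seq_along(k)) {
    i <- k[j]
    if (i <= ns - 1) {
      to_time[j] <- hs[i] + 0.5 * p$dst_fraction * (hs[i + 1] - hs[i - 1])
    }
    if (i <= ns - 2) {
      ds1 <- 0.5 * p$dst_fraction * (hs[i + 1] - hs[i - 1])
      ds2 <- 0.5 * p$dst_fraction * (hs[i + 2] - hs[i])
      dst_pct[j] <- 100 * (ds1 + ds2) / (hs[i + 2] - hs[i])
    }
  }
  truth <- data.frame(
    step = seq_along(k),
    side = side[k],
    hs_time_s = hs[k],
    to_time_s = to_time,
    length_cm = 100 * v * dt[k],
    width_cm = 100 * p$step_width_m,
    time_s = dt[k],
    dst_pct = dst_pct
  )
  attr(truth, "trunk_angle_deg") <- p$trunk_lean_deg
  attr(truth, "params") <- p
  attr(truth, "hs_times_all") <- hs
  attr(truth, "hs_sides_all") <- side

  list(recording = rec, truth = truth)
}
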