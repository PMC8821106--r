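#' Rolling-hills terrain configuration
#'
#' Describes the sagittal platform pitch signal used to emulate a
#' continuously varying mild-slope ("rolling hills") walking surface: a sum
#' of sinusoids whose realized extreme is normalized to `peak_deg`.
#'
#' The default component frequencies are 0.16, 0.21, 0.24 and 0.49 Hz with
#' equal amplitudes and zero phases, giving a deterministic signal whose
#' pitch oscillates within +/- `peak_deg` degrees. Component amplitudes and
#' phases are free parameters of the protocol; set `phase_seed` to draw
#' uniformly random phases for a different (but reproducible) realization.
#'
#' @param frequencies_hz strictly positive, distinct oscillation frequencies
#'   (Hz).
#' @param amplitudes per-component relative amplitudes (dimensionless,
#'   positive); only their ratios matter because the summed signal is
#'   rescaled to `peak_deg`.
#' @param phases_rad per-component phase offsets (radians). Ignored when
#'   `phase_seed` is given.
#' @param peak_deg target maximum absolute pitch (degrees), > 0.
#' @param duration_s signal length (seconds), > 0.
#' @param sample_rate_hz sampling rate (Hz); must be at least twice the
#'   largest component frequency.
#' @param phase_seed optional integer; when given, phases are drawn
#'   uniformly on \[0, 2*pi) from this seed (the global RNG state is left
#'   untouched).
#'
#' @return An object of class `terrain_config`.
#' @seealso [generate_platform_pitch()]
#' @export
#' @examples
#' cfg <- terrain_config(duration_s = 60)
#' pitch <- generate_platform_pitch(cfg)
#' max(abs(pitch))  # == 3 by construction
terrain_config <- function(frequencies_hz = c(0.16, 0.21, 0.24, 0.49),
                           amplitudes = rep(1, length(frequencies_hz)),
                           phases_rad = rep(0, length(frequencies_hz)),
                           peak_deg = 3,
                           duration_s = 600,
                           sample_rate_hz = 100,
                           phase_seed = NULL) {
  if (length(frequencies_hz) == 0) {
    stop("terrain_config: at least one component frequency is required",
         call. = FALSE)
  }
  if (any(!is.finite(frequencies_hz)) || any(frequencies_hz <= 0)) {
    stop("terrain_config: frequencies must be finite and strictly positive",
         call. = FALSE)
  }
  if (anyDuplicated(frequencies_hz) > 0) {
    stop("terrain_config: component frequencies must be distinct",
         call. = FALSE)
  }
  if (length(amplitudes) != length(frequencies_hz) ||
      length(phases_rad) != length(frequencies_hz)) {
    stop("terrain_config: amplitudes and phases must match frequencies in length",
         call. = FALSE)
  }
  if (any(amplitudes <= 0)) {
    stop("terrain_config: amplitudes must be strictly positive", call. = FALSE)
  }
  if (!is.finite(peak_deg) || peak_deg <= 0) {
    stop("terrain_config: peak_deg must be > 0", call. = FALSE)
  }
  if (!is.finite(duration_s) || duration_s <= 0) {
    stop("terrain_config: duration_s must be > 0", call. = FALSE)
  }
  if (sample_rate_hz < 2 * max(frequencies_hz)) {
    stop("terrain_config: sample_rate_hz must be at least twice the highest frequency",
         call. = FALSE)
  }
  if (!is.null(phase_seed)) {
    phases_rad <- with_preserved_rng(phase_seed,
                                     stats::runif(length(frequencies_hz), 0, 2 * pi))
  }
  structure(
    list(frequencies_hz = as.numeric(frequencies_hz),
         amplitudes = as.numeric(amplitudes),
         phases_rad = as.numeric(phases_rad),
         peak_deg = peak_deg,
         duration_s = duration_s,
         sample_rate_hz = sample_rate_hz),
    class = "terrain_config"
  )
}

#' Generate the rolling-hills platform pitch signal
#'
#' Evaluates the sum of sinusoids described by a [terrain_config()] on a
#' uniform time grid and rescales it so the realized extreme over the
#' generated horizon equals `cfg$peak_deg` exactly.
#'
#' @param cfg a [terrain_config()].
#' @return Numeric vector of platform pitch (degrees), one value per sample
#'   (`duration_s * sample_rate_hz` samples), with attribute
#'   `sample_rate_hz`.
#' @export
generate_platform_pitch <- function(cfg) {
  if (!inherits(cfg, "terrain_config")) {
    stop("generate_platform_pitch: cfg must be a terrain_config", call. = FALSE)
  }
  n <- round(cfg$duration_s * cfg$sample_rate_hz)
  t <- (seq_len(n) - 1) / cfg$sample_rate_hz
  raw <- numeric(n)
  for (i in seq_along(cfg$frequencies_hz)) {
    raw <- raw + cfg$amplitudes[i] *
      sin(2 * pi * cfg$frequencies_hz[i] * t + cfg$phases_rad[i])
  }
  m <- max(abs(raw))
  if (m == 0) {
    stop("generate_platform_pitch: degenerate configuration (signal identically zero)",
         call. = FALSE)
  }
  pitch <- raw * (cfg$peak_deg / m)
  attr(pitch, "sample_rate_hz") <- cfg$sample_rate_hz
  pitch
}

#' Locate strict local extrema of a sampled series
#'
#' Finds the sample indices of strict local maxima and minima. A plateau
#' flanked by lower (or higher) values on both sides counts as a single
#' extremum reported at its first sample; monotone and constant series have
#' no extrema.
#'
#' @param x numeric series, length >= 3.
#' @return Sorted integer vector of 1-based extremum sample indices.
#' @export
locate_extrema <- function(x) {
  n <- length(x)
  if (n < 3) {
    stop("locate_extrema: series must have at least 3 samples", call. = FALSE)
  }
  d <- diff(x)
  nz <- which(d != 0)
  if (length(nz) < 2) return(integer(0))
  s <- sign(d[nz])
  chg <- which(s[-1] != s[-length(s)])
  sort(as.integer(nz[chg] + 1L))
}

#' Classify a step interval by mean platform slope
#'
#' Assigns a step to the uphill, downhill or excluded class from the mean
#' platform pitch over its interval. Uphill steps have mean pitch in
#' \[`band[1]`, `band[2]`\] degrees (closed interval), downhill steps the
#' mirrored negative band, and any step whose open interval contains a pitch
#' extremum (a hill peak or trough) is excluded regardless of its mean.
#'
#' @param start,end step interval as 1-based samples, half-open
#'   \[`start`, `end`): samples `start` to `end - 1` belong to the step.
#' @param pitch numeric platform pitch series (degrees).
#' @param extrema extremum sample indices, as from [locate_extrema()];
#'   extrema exactly at `start` or `end` do not exclude the step.
#' @param band positive slope band limits, default `c(1, 3)` degrees.
#' @return A list with `class_label` (`"uphill"`, `"downhill"` or
#'   `"excluded"`), `mean_pitch_deg` and `spans_extremum`.
#' @export
classify_step_slope <- function(start, end, pitch, extrema = locate_extrema(pitch),
                                band = c(1, 3)) {
  if (!(start >= 1 && start < end && end <= length(pitch) + 1)) {
    stop("classify_step_slope: need 1 <= start < end <= length(pitch) + 1",
         call. = FALSE)
  }
  mean_pitch <- mean(pitch[start:(end - 1)])
  spans <- any(extrema > start & extrema < end)
  label <- "excluded"
  if (!spans) {
    if (mean_pitch >= band[1] && mean_pitch <= band[2]) {
      label <- "uphill"
    } else if (mean_pitch <= -band[1] && mean_pitch >= -band[2]) {
      label <- "downhill"
    }
  }
  list(class_label = label,
       mean_pitch_deg = mean_pitch,
       spans_extremum = spans)
}

# Evaluate `expr` under a temporary seed without disturbing the caller's RNG.
with_preserved_rng <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
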