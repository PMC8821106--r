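#' Run the full synthetic study pipeline
#'
#' End-to-end orchestration mirroring the study's analysis chain: for each
#' synthetic subject and arm condition (held, normal, active) a treadmill
#' trial is simulated over a level lead-in followed by rolling-hills
#' terrain; events are detected, the step table and per-slope-class
#' summaries computed, and each outcome variable is analysed with a
#' two-way repeated-measures ANOVA (arms x slope) for each slope contrast
#' (uphill vs level, downhill vs level). Deterministic given `seed`.
#'
#' Between-subject variation is drawn from the `study$between_sd` block of
#' the configuration; per-trial generator seeds derive from `seed` so the
#' whole run is reproducible.
#'
#' @param config configuration list, see [default_config()].
#' @param seed integer seed for the whole run.
#' @param out_dir optional directory; when given, writes `steps.tsv`,
#'   `summary.tsv`, `anova.tsv` and `manifest.json` there.
#' @return Invisibly, a list with `steps`, `summary`, `long` (one row per
#'   subject x slope class x arm condition x variable), `anova` and
#'   `posthoc` tables plus the echoed `config` and `seed`.
#' @export
run_pipeline <- function(config = default_config(), seed = 1, out_dir = NULL) {
  set.seed(seed)
  st <- config$study
  wk <- config$walker
  an <- config$analysis
  n_sub <- st$n_subjects
  if (n_sub < 2) {
    stop("run_pipeline: stats stage requires at least 2 subjects", call. = FALSE)
  }
  arms <- c("held", "normal", "active")
  tcfg <- terrain_config(frequencies_hz = config$terrain$frequencies_hz,
                         amplitudes = config$terrain$amplitudes,
                         phases_rad = config$terrain$phases_rad,
                         peak_deg = config$terrain$peak_deg,
                         duration_s = an$hills_duration_s + 60,
                         sample_rate_hz = config$terrain$sample_rate_hz)

  rnorm_pos <- function(mu, sd, floor_frac = 0.5) {
    max(mu * floor_frac, stats::rnorm(1, mu, sd))
  }
  steps_all <- NULL
  summary_all <- NULL
  for (s in seq_len(n_sub)) {
    base <- walker_params(
      step_time_s = rnorm_pos(wk$step_time_s, st$between_sd$step_time_s),
      step_length_m = rnorm_pos(wk$step_length_m, st$between_sd$step_length_m),
      step_width_m = rnorm_pos(wk$step_width_m, st$between_sd$step_width_m),
      dst_fraction = min(0.45, rnorm_pos(wk$dst_fraction, st$between_sd$dst_fraction)),
      trunk_lean_deg = stats::rnorm(1, wk$trunk_lean_deg, st$between_sd$trunk_lean_deg),
      noise_sd_m = wk$noise_sd_m,
      jitter_frac = wk$jitter_frac,
      n_steps = 10)
    for (arm in arms) {
      p <- arm_condition_params(base, arm,
                                held_scale = wk$held_scale,
                                active_scale = wk$active_scale,
                                held_lean_delta_deg = wk$held_lean_delta_deg,
                                active_lean_delta_deg = wk$active_lean_delta_deg)
      v <- p$step_length_m / p$step_time_s
      dur <- an$flat_lead_m / v + an$hills_duration_s + 5
      p$n_steps <- as.integer(ceiling(dur / p$step_time_s))
      p$seed <- sample.int(.Machine$integer.max - 1L, 1)
      trial_id <- sprintf("S%02d_%s", s, arm)
      message(sprintf("[simulate] %s: %d steps", trial_id, p$n_steps))
      sim <- simulate_trial(p, terrain = tcfg, flat_lead_m = an$flat_lead_m,
                            trial_id = trial_id)
      res <- analyze_trial(sim$recording, config)
      if (is.null(res$summary) || nrow(res$summary) < 3) {
        stop("run_pipeline: trial ", trial_id, " lacks a full set of slope ",
             "classes; increase hills_duration_s", call. = FALSE)
      }
      res$steps$subject <- s
      res$steps$arms <- arm
      res$summary$subject <- s
      res$summary$arms <- arm
      steps_all <- rbind(steps_all, res$steps)
      summary_all <- rbind(summary_all, res$summary)
    }
  }

  vars <- c("speed", "step_length", "step_length_cov", "step_width",
            "step_width_cov", "step_time", "step_time_cov", "dst", "dst_cov",
            "mos", "mos_cov", "trunk_angle", "rms_ap", "rms_ml", "rms_vt")
  long <- stats::reshape(
    summary_all[, c("subject", "arms", "slope_class", vars)],
    direction = "long", varying = vars, v.names = "value",
    timevar = "variable", times = vars,
    idvar = c("subject", "arms", "slope_class"))
  rownames(long) <- NULL
  names(long)[names(long) == "slope_class"] <- "slope"

  anova_all <- NULL
  posthoc_all <- NULL
  for (contrast in config$stats$contrasts) {
    sub <- long[long$slope %in% c(contrast, "level"), ]
    for (v in vars) {
      dd <- sub[sub$variable == v, ]
      fit <- rm_anova_2way(dd, subject = "subject", a = "arms", b = "slope",
                           value = "value", alpha = config$stats$alpha)
      tb <- fit$table
      tb$contrast <- paste0(contrast, "_vs_level")
      tb$variable <- v
      anova_all <- rbind(anova_all, tb)
      ph <- bonferroni_pairwise(dd, factor_col = "arms", other_col = "slope")
      ph$contrast <- paste0(contrast, "_vs_level")
      ph$variable <- v
      posthoc_all <- rbind(posthoc_all, ph)
    }
  }

  out <- list(steps = steps_all, summary = summary_all, long = long,
              anova = anova_all, posthoc = posthoc_all,
              config = config, seed = seed)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    wt <- function(df, f) utils::write.table(
      df, file.path(out_dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
    wt(steps_all, "steps.tsv")
    wt(summary_all, "summary.tsv")
    wt(anova_all, "anova.tsv")
    wt(posthoc_all, "posthoc.tsv")
    jsonlite::write_json(list(seed = seed, n_subjects = n_sub,
                              config = config,
                              created = "slopegait run manifest"),
                         file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(out)
}
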