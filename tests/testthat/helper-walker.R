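# Shared fixtures: small synthetic trials and event-matching utilities.

quick_trial <- function(step_time_s = 0.5, n_steps = 20, noise_sd_m = 0,
                        jitter_frac = 0, seed = 1, ...) {
  simulate_trial(walker_params(step_time_s = step_time_s, n_steps = n_steps,
                               noise_sd_m = noise_sd_m,
                               jitter_frac = jitter_frac, seed = seed, ...))
}

# Compare detected heel strikes against the generator's full event list.
# Returns per-event absolute errors in samples and the count of detected
# events inside the ground-truth time span that match no true event.
match_heel_strikes <- function(sim, events, tol_samples = 1) {
  tr <- sim$truth
  fs <- sim$recording$sample_rate_hz
  hs_all <- attr(tr, "hs_times_all")
  sides <- attr(tr, "hs_sides_all")
  rng <- range(hs_all)
  errs <- c()
  spurious <- 0L
  for (s in c("L", "R")) {
    th <- hs_all[sides == s]
    det <- (events$hs[[s]] - 1) / fs
    errs <- c(errs, vapply(th, function(t) min(abs(det - t)) * fs, numeric(1)))
    inr <- det[det >= rng[1] - 0.51 / fs & det <= rng[2] + 0.51 / fs]
    spurious <- spurious +
      sum(vapply(inr, function(t) min(abs(th - t)) * fs, numeric(1)) >
            tol_samples + 0.001)
  }
  list(errors = errs, spurious = spurious)
}

# Independent explicit-summation oracle for the two-way within-subjects
# sums of squares: every SS computed by direct loops over the design means.
rm_ss_oracle <- function(d) {
  subs <- sort(unique(d$subject))
  A <- sort(unique(d$arms))
  B <- sort(unique(d$slope))
  n <- length(subs); ka <- length(A); kb <- length(B)
  cell <- function(s, a, b) d$value[d$subject == s & d$arms == a & d$slope == b]
  grand <- mean(d$value)
  ms <- sapply(subs, function(s) mean(d$value[d$subject == s]))
  ma <- sapply(A, function(a) mean(d$value[d$arms == a]))
  mb <- sapply(B, function(b) mean(d$value[d$slope == b]))
  ss_a <- 0; ss_b <- 0; ss_ab <- 0; ss_s <- 0; ss_as <- 0; ss_bs <- 0; ss_tot <- 0
  for (a in seq_along(A)) ss_a <- ss_a + n * kb * (ma[a] - grand)^2
  for (b in seq_along(B)) ss_b <- ss_b + n * ka * (mb[b] - grand)^2
  for (a in seq_along(A)) for (b in seq_along(B)) {
    mab <- mean(d$value[d$arms == A[a] & d$slope == B[b]])
    ss_ab <- ss_ab + n * (mab - ma[a] - mb[b] + grand)^2
  }
  for (s in seq_along(subs)) ss_s <- ss_s + ka * kb * (ms[s] - grand)^2
  for (s in seq_along(subs)) for (a in seq_along(A)) {
    msa <- mean(d$value[d$subject == subs[s] & d$arms == A[a]])
    ss_as <- ss_as + kb * (msa - ms[s] - ma[a] + grand)^2
  }
  for (s in seq_along(subs)) for (b in seq_along(B)) {
    msb <- mean(d$value[d$subject == subs[s] & d$slope == B[b]])
    ss_bs <- ss_bs + ka * (msb - ms[s] - mb[b] + grand)^2
  }
  for (i in seq_len(nrow(d))) ss_tot <- ss_tot + (d$value[i] - grand)^2
  list(A = ss_a, B = ss_b, AB = ss_ab,
       AS = ss_as, BS = ss_bs,
       ABS = ss_tot - ss_a - ss_b - ss_ab - ss_s - ss_as - ss_bs)
}

random_rm_fixture <- function(n = 15, effects = FALSE) {
  d <- expand.grid(subject = factor(seq_len(n)),
                   arms = c("held", "normal", "active"),
                   slope = c("hill", "level"))
  d$value <- stats::rnorm(nrow(d)) + rep(stats::rnorm(n), 6)
  if (effects) {
    d$value <- d$value + as.numeric(d$arms) * 0.5 +
      (d$slope == "hill") * 0.8
  }
  d
}
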