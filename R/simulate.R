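#' Generative parameters for one group-by-condition cell
#'
#' A preset plants every behavioral and signal-quality parameter of the
#' simulator for a single group (`adhd`/`tdc`) by condition (`none`,
#' `auditory`, `visual25`, `visual50`) cell, so the pipeline can be validated
#' by parameter recovery.
#'
#' Anticipatory saccades are generated as out-and-back gaze excursions during
#' the delay window; each event contributes exactly two countable saccades
#' (out and return), so events are drawn as Poisson with mean
#' `mgs_anticipatory_mean / 2`. Because any delay-window excursion breaks the
#' hold-the-center criterion, correctness is planted in closed form:
#' `p_correct = exp(-mgs_anticipatory_mean/2) * (1 - p_delay_break) *
#' (1 - p_quadrant_error)`. When `p_correct` is supplied,
#' `p_quadrant_error` is solved from that mapping.
#'
#' Response latency is 80 ms plus a lognormal truncated to the valid response
#' window (85-995 ms), with the log-mean solved numerically so the truncated
#' mean equals `latency_mean_ms`; gain is Normal truncated to `[0.21, 1.6]`
#' with the location solved so the truncated mean equals `gain_mean` (the
#' lower bound keeps the response saccade at or above the 2 deg detection and
#' eccentricity thresholds).
#'
#' @param group,condition cell labels.
#' @param fix_jitter_sd_deg Gaussian fixational jitter SD per eye (deg).
#' @param pf_oncenter_fraction planted fraction of PF trial time spent within
#'   2 deg of center.
#' @param pf_intrusive_mean planted expected number of pipeline-counted
#'   intrusive saccades per 60 s PF trial (excursions are Poisson with half
#'   this mean).
#' @param mgs_anticipatory_mean planted expected anticipatory-saccade count
#'   per MGS trial.
#' @param latency_mean_ms,latency_sd_ms response-latency mean and SD (ms).
#' @param gain_mean,gain_sd response gain (amplitude / 10 deg) mean and SD.
#' @param p_correct planted probability of a correct trial; used to solve
#'   `p_quadrant_error` unless that is given directly.
#' @param p_quadrant_error probability the response lands in a wrong quadrant.
#' @param p_delay_break probability of an additional long delay-period
#'   excursion (adds 2 to the expected anticipatory count when nonzero).
#' @param blink_rate_per_min,blink_dur_ms binocular blink process.
#' @param p_gross_loss probability of a long track-loss episode covering
#'   25-50% of the trial's loss-scope window (drives the exclusion rule).
#' @param accuracy_offset_sd_deg SD of the per-trial constant calibration
#'   offset, per axis.
#' @param participant_sd SD of an optional participant-level additive shift
#'   on latency (ms-scale) and gain (gain-scale, divided by 1000); 0 disables
#'   it so planted cell means are recovered exactly in expectation.
#' @param interpolated `TRUE` when some values were not printed for this cell
#'   and were filled from neighbouring conditions (non-authoritative).
#' @return An object of class `sim_preset`.
#' @export
sim_preset <- function(group, condition,
                       fix_jitter_sd_deg = 0.06,
                       pf_oncenter_fraction = 0.95,
                       pf_intrusive_mean = 10,
                       mgs_anticipatory_mean = 0.5,
                       latency_mean_ms = 330, latency_sd_ms = 170,
                       gain_mean = 0.85, gain_sd = 0.20,
                       p_correct = NULL, p_quadrant_error = NULL,
                       p_delay_break = 0,
                       blink_rate_per_min = 10, blink_dur_ms = 250,
                       p_gross_loss = 0.02,
                       accuracy_offset_sd_deg = 0.35,
                       participant_sd = 0,
                       interpolated = FALSE) {
  stopifnot(pf_oncenter_fraction >= 0, pf_oncenter_fraction <= 1,
            p_delay_break >= 0, p_delay_break <= 1,
            gain_mean > 0, gain_sd >= 0, latency_sd_ms >= 0,
            fix_jitter_sd_deg >= 0, pf_intrusive_mean >= 0,
            mgs_anticipatory_mean >= 0, p_gross_loss >= 0, p_gross_loss <= 1)
  lambda <- mgs_anticipatory_mean / 2
  if (is.null(p_quadrant_error)) {
    if (is.null(p_correct))
      stop("supply either p_correct or p_quadrant_error")
    ceiling_p <- exp(-lambda) * (1 - p_delay_break)
    p_quadrant_error <- 1 - p_correct / ceiling_p
    if (p_quadrant_error < 0 || p_quadrant_error > 1)
      stop(sprintf(
        "p_correct = %.3f is not reachable given the anticipatory mean (max %.3f)",
        p_correct, ceiling_p))
  }
  if (is.null(p_correct))
    p_correct <- exp(-lambda) * (1 - p_delay_break) * (1 - p_quadrant_error)

  lat <- calibrate_truncated_lognormal(latency_mean_ms - 80, latency_sd_ms,
                                       lo = 5, hi = 915)
  gn <- calibrate_truncated_normal(gain_mean, gain_sd, lo = 0.21, hi = 1.6)

  structure(list(
    group = group, condition = condition,
    fix_jitter_sd_deg = fix_jitter_sd_deg,
    pf_oncenter_fraction = pf_oncenter_fraction,
    pf_intrusive_mean = pf_intrusive_mean,
    mgs_anticipatory_mean = mgs_anticipatory_mean,
    latency_mean_ms = latency_mean_ms, latency_sd_ms = latency_sd_ms,
    latency_meanlog = lat$meanlog, latency_sdlog = lat$sdlog,
    latency_lo = lat$lo, latency_hi = lat$hi,
    gain_mean = gain_mean, gain_sd = gain_sd,
    gain_mu = gn$mu, gain_lo = gn$lo, gain_hi = gn$hi,
    p_correct = p_correct, p_quadrant_error = p_quadrant_error,
    p_delay_break = p_delay_break,
    blink_rate_per_min = blink_rate_per_min, blink_dur_ms = blink_dur_ms,
    p_gross_loss = p_gross_loss,
    accuracy_offset_sd_deg = accuracy_offset_sd_deg,
    participant_sd = participant_sd,
    interpolated = interpolated
  ), class = "sim_preset")
}

# location calibration: lognormal truncated to (lo, hi) with target mean/sd
calibrate_truncated_lognormal <- function(mean_excess, sd, lo, hi) {
  stopifnot(mean_excess > lo, mean_excess < hi)
  if (sd == 0)  # degenerate point mass at the mean
    return(list(meanlog = log(mean_excess), sdlog = 0, lo = lo, hi = hi))
  sdlog <- sqrt(log(1 + (sd / mean_excess)^2))
  trunc_mean <- function(mu) {
    zlo <- (log(lo) - mu) / sdlog
    zhi <- (log(hi) - mu) / sdlog
    num <- stats::pnorm(zhi - sdlog) - stats::pnorm(zlo - sdlog)
    den <- stats::pnorm(zhi) - stats::pnorm(zlo)
    exp(mu + sdlog^2 / 2) * num / den
  }
  mu0 <- log(mean_excess) - sdlog^2 / 2
  mu <- stats::uniroot(function(m) trunc_mean(m) - mean_excess,
                       c(mu0 - 2, mu0 + 2))$root
  list(meanlog = mu, sdlog = sdlog, lo = lo, hi = hi)
}

calibrate_truncated_normal <- function(mean, sd, lo, hi) {
  if (sd == 0) return(list(mu = mean, lo = lo, hi = hi))
  trunc_mean <- function(mu) {
    a <- (lo - mu) / sd; b <- (hi - mu) / sd
    mu + sd * (stats::dnorm(a) - stats::dnorm(b)) /
      (stats::pnorm(b) - stats::pnorm(a))
  }
  mu <- stats::uniroot(function(m) trunc_mean(m) - mean,
                       c(mean - 4 * sd, mean + 4 * sd))$root
  list(mu = mu, lo = lo, hi = hi)
}

rtrunc_lnorm <- function(n, meanlog, sdlog, lo, hi) {
  if (sdlog == 0) return(rep(exp(meanlog), n))
  u <- stats::runif(n, stats::plnorm(lo, meanlog, sdlog),
                    stats::plnorm(hi, meanlog, sdlog))
  stats::qlnorm(u, meanlog, sdlog)
}

rtrunc_norm <- function(n, mu, sd, lo, hi) {
  if (sd == 0) return(rep(mu, n))
  u <- stats::runif(n, stats::pnorm(lo, mu, sd), stats::pnorm(hi, mu, sd))
  stats::qnorm(u, mu, sd)
}

#' Simulator presets transcribed from printed group-by-condition means
#'
#' One [sim_preset()] per cell of the 2 (group) x 4 (condition) design, with
#' the behavioral parameters set to the published group/condition means:
#' fixation ratio, intrusive-saccade count, anticipatory-saccade count,
#' response latency (mean and SD), gain (mean and SD) and proportion of
#' correct trials. Latency means for the auditory cells are not printed (that
#' contrast showed no effects) and reuse the no-noise values; those cells are
#' flagged `interpolated`. The ADHD cells get higher blink and gross-loss
#' rates than TDC, mirroring the observed data-loss asymmetry, so the
#' exclusion-rule code paths are exercised.
#'
#' @return named list of 8 `sim_preset` objects, keyed `group_condition`.
#' @export
results_presets <- function() {
  cells <- list(
    # group, cond, fr,  intr,  ant,  lat_m, lat_sd, g_m, g_sd, p_c, interp
    list("adhd", "none",     0.93, 15.35, 0.69, 327.8, 174.5, 0.84, 0.21, 0.49, FALSE),
    list("adhd", "auditory", 0.93, 13.68, 0.70, 327.8, 174.5, 0.81, 0.20, 0.50, TRUE),
    list("adhd", "visual25", 0.90, 12.06, 0.63, 339.5, 178.0, 0.82, 0.19, 0.43, FALSE),
    list("adhd", "visual50", 0.93, 11.92, 0.61, 347.2, 170.5, 0.81, 0.19, 0.47, FALSE),
    list("tdc",  "none",     0.96,  9.46, 0.43, 332.0, 163.0, 0.86, 0.20, 0.61, FALSE),
    list("tdc",  "auditory", 0.97,  9.02, 0.39, 332.0, 163.0, 0.85, 0.21, 0.63, TRUE),
    list("tdc",  "visual25", 0.96,  8.61, 0.34, 320.0, 159.1, 0.86, 0.20, 0.62, FALSE),
    list("tdc",  "visual50", 0.97,  7.05, 0.36, 345.1, 164.4, 0.85, 0.18, 0.62, FALSE)
  )
  out <- lapply(cells, function(c) {
    adhd <- c[[1]] == "adhd"
    sim_preset(group = c[[1]], condition = c[[2]],
               fix_jitter_sd_deg = if (adhd) 0.06 else 0.045,
               pf_oncenter_fraction = c[[3]],
               pf_intrusive_mean = c[[4]],
               mgs_anticipatory_mean = c[[5]],
               latency_mean_ms = c[[6]], latency_sd_ms = c[[7]],
               gain_mean = c[[8]], gain_sd = c[[9]],
               p_correct = c[[10]],
               blink_rate_per_min = if (adhd) 12 else 10,
               blink_dur_ms = if (adhd) 260 else 250,
               p_gross_loss = if (adhd) 0.03 else 0.015,
               interpolated = c[[11]])
  })
  names(out) <- vapply(out, function(p) paste(p$group, p$condition, sep = "_"),
                       character(1))
  out
}

#' Write / read a preset table as YAML
#'
#' @param presets named list of [sim_preset()] objects.
#' @param path YAML file path.
#' @return `read_presets_yaml()` the reconstructed preset list.
#' @export
write_presets_yaml <- function(presets, path) {
  keep <- c("group", "condition", "fix_jitter_sd_deg", "pf_oncenter_fraction",
            "pf_intrusive_mean", "mgs_anticipatory_mean", "latency_mean_ms",
            "latency_sd_ms", "gain_mean", "gain_sd", "p_correct",
            "p_delay_break", "blink_rate_per_min", "blink_dur_ms",
            "p_gross_loss", "accuracy_offset_sd_deg", "participant_sd",
            "interpolated")
  yaml::write_yaml(lapply(presets, function(p) p[keep]), path)
  invisible(path)
}

#' @rdname write_presets_yaml
#' @export
read_presets_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  out <- lapply(raw, function(p) do.call(sim_preset, p))
  names(out) <- vapply(out, function(p) paste(p$group, p$condition, sep = "_"),
                       character(1))
  out
}

# non-overlapping interval placement: k events with durations `durs` inside
# [lo, hi], separated by at least `sep`; drops events that cannot be placed
place_intervals <- function(k, lo, hi, durs, sep = 0.15, tries = 60) {
  while (k > 0) {
    d <- durs[seq_len(k)]
    for (i in seq_len(tries)) {
      starts <- sort(stats::runif(k, lo, hi - max(d)))
      ok <- all(starts + d <= hi) &&
        (k == 1 || all(starts[-1] - (starts[-k] + d[-k]) >= sep))
      if (ok) return(list(starts = starts, durs = d))
    }
    k <- k - 1L
  }
  list(starts = numeric(), durs = numeric())
}

# piecewise-constant gaze path -> per-sample positions
path_at <- function(t, bp_t, bp_x, bp_y) {
  idx <- findInterval(t, bp_t)
  idx[idx < 1L] <- 1L
  list(x = bp_x[idx], y = bp_y[idx])
}

# stamp blink/loss intervals into a validity vector
invalidate <- function(valid, t, starts, durs) {
  for (i in seq_along(starts))
    valid[t >= starts[i] & t < starts[i] + durs[i]] <- FALSE
  valid
}

# shared: render a degree-space path into a binocular recording
render_recording <- function(t, base_x, base_y, preset, geometry,
                             valid, meta) {
  n <- length(t)
  off <- stats::rnorm(2, 0, preset$accuracy_offset_sd_deg)
  eyes <- lapply(1:2, function(e) {
    eoff <- off + stats::rnorm(2, 0, 0.1)
    x <- base_x + eoff[1] + stats::rnorm(n, 0, preset$fix_jitter_sd_deg)
    y <- base_y + eoff[2] + stats::rnorm(n, 0, preset$fix_jitter_sd_deg)
    deg_to_norm(x, y, geometry)
  })
  samples <- data.frame(t = t,
                        x_l = eyes[[1]]$x, y_l = eyes[[1]]$y,
                        x_r = eyes[[2]]$x, y_r = eyes[[2]]$y,
                        valid_l = valid, valid_r = valid)
  do.call(gaze_recording, c(list(samples = samples, geometry = geometry), meta))
}

draw_blinks <- function(preset, duration, forbidden = NULL, scale = 1) {
  nb <- stats::rpois(1, preset$blink_rate_per_min * duration / 60 * scale)
  if (nb == 0) return(list(starts = numeric(), durs = numeric()))
  durs <- preset$blink_dur_ms / 1000 * stats::runif(nb, 0.6, 1.4)
  starts <- stats::runif(nb, 0, duration - durs)
  if (!is.null(forbidden)) {
    for (i in seq_len(nb)) {
      for (try in 1:20) {
        if (starts[i] + durs[i] < forbidden[1] || starts[i] > forbidden[2])
          break
        starts[i] <- stats::runif(1, 0, duration - durs[i])
      }
      if (starts[i] + durs[i] >= forbidden[1] && starts[i] <= forbidden[2])
        starts[i] <- NA  # could not be placed outside the protected epoch
    }
    keep <- !is.na(starts)
    starts <- starts[keep]; durs <- durs[keep]
  }
  list(starts = starts, durs = durs)
}

#' Draw a random MGS trial timeline
#'
#' Samples the variable intervals of the trial schedule: flash onset
#' uniformly 2.0-3.5 s after fixation onset, the go cue uniformly 2.0-3.5 s
#' after flash offset, and the flash direction uniformly over the four
#' diagonals.
#'
#' @return An [mgs_timeline()].
#' @export
draw_mgs_timeline <- function() {
  flash_onset <- stats::runif(1, 2.0, 3.5)
  go <- flash_onset + 0.300 + stats::runif(1, 2.0, 3.5)
  mgs_timeline(flash_onset, go, sample(c(45, 135, 225, 315), 1))
}

#' Simulate one memory-guided-saccade trial
#'
#' Generates a 600 Hz binocular recording for one MGS trial under a preset:
#' the gaze holds center with Gaussian jitter; Poisson-many anticipatory
#' excursions (out at 2.5-6 deg for 150-350 ms, then back) are planted in the
#' delay window; the response saccade jumps to `10 * gain` deg along the
#' flash direction (or, with `p_quadrant_error`, a rotated direction) at
#' go + latency; a corrective saccade lands on the true target shortly after
#' reappearance; blinks and optional gross track-loss episodes invalidate
#' samples in both eyes. Planted saccades are instantaneous plateau jumps --
#' every downstream measure is fixation-based, so velocity profiles are
#' irrelevant.
#'
#' @param preset a [sim_preset()].
#' @param seed optional integer; when given, `set.seed(seed)` is called so
#'   the trial is bit-reproducible.
#' @param geometry a [screen_geometry()].
#' @param participant,trial_index metadata labels.
#' @return list with `recording` (a `gaze_recording`), `timeline` (an
#'   [mgs_timeline()]) and `truth` -- the ground-truth record of every
#'   planted event (anticipatory saccades emitted, quadrant error flag,
#'   latency, gain, planted correctness, blink and loss episodes).
#' @export
simulate_mgs_trial <- function(preset, seed = NULL,
                               geometry = screen_geometry(),
                               participant = NA_character_,
                               trial_index = NA_integer_) {
  if (!is.null(seed)) set.seed(seed)
  rate <- geometry$sampling_rate_hz
  tl <- draw_mgs_timeline()
  go <- tl$go
  flash_onset <- tl$flash_onset
  dir <- tl$flash_direction
  duration <- tl$reappear_off + 0.2
  n <- round(duration * rate)
  t <- (seq_len(n) - 1L) / rate

  # planted delay-window excursions (anticipatory saccades, 2 per event)
  n_pois <- stats::rpois(1, preset$mgs_anticipatory_mean / 2)
  n_break <- stats::rbinom(1, 1, preset$p_delay_break)
  dwells <- c(stats::runif(n_pois, 0.15, 0.35),
              if (n_break) stats::runif(1, 0.5, 1.0))
  k <- n_pois + n_break
  exc <- place_intervals(k, flash_onset + 0.05, go - 0.5, dwells)
  k_placed <- length(exc$starts)
  exc_r <- stats::runif(k_placed, 2.5, 6)
  exc_a <- stats::runif(k_placed, 0, 2 * pi)

  # response
  latency <- 80 + rtrunc_lnorm(1, preset$latency_meanlog,
                               preset$latency_sdlog,
                               preset$latency_lo, preset$latency_hi)
  if (preset$participant_sd > 0)
    latency <- max(85, min(995, latency + stats::rnorm(1, 0, preset$participant_sd)))
  g <- rtrunc_norm(1, preset$gain_mu, preset$gain_sd,
                   preset$gain_lo, preset$gain_hi)
  qerr <- stats::rbinom(1, 1, preset$p_quadrant_error) == 1
  resp_dir <- if (qerr) (dir + sample(c(90, 180, 270), 1)) %% 360 else dir
  resp_t <- go + latency / 1000
  resp_xy <- 10 * g * c(cos(resp_dir * pi / 180), sin(resp_dir * pi / 180))
  corr_t <- tl$reappear + stats::runif(1, 0.15, 0.25)
  corr_xy <- flash_position(tl)
  # a corrective saccade is launched only when the landing error is
  # perceptible (>= 1 deg); tiny errors fall inside the saccadic dead zone
  corrective <- sqrt(sum((corr_xy - resp_xy)^2)) >= 1.0

  # assemble the piecewise-constant path
  bp_t <- 0; bp_x <- 0; bp_y <- 0
  for (i in seq_len(k_placed)) {
    bp_t <- c(bp_t, exc$starts[i], exc$starts[i] + exc$durs[i])
    bp_x <- c(bp_x, exc_r[i] * cos(exc_a[i]), 0)
    bp_y <- c(bp_y, exc_r[i] * sin(exc_a[i]), 0)
  }
  bp_t <- c(bp_t, resp_t, if (corrective) corr_t)
  bp_x <- c(bp_x, resp_xy[1], if (corrective) corr_xy[1])
  bp_y <- c(bp_y, resp_xy[2], if (corrective) corr_xy[2])
  pos <- path_at(t, bp_t, bp_x, bp_y)

  # data loss: blinks (suppressed around the response epoch) + gross episodes
  blinks <- draw_blinks(preset, duration, forbidden = c(go - 0.05, go + 1.05))
  valid <- rep(TRUE, n)
  valid <- invalidate(valid, t, blinks$starts, blinks$durs)
  gross <- stats::rbinom(1, 1, preset$p_gross_loss) == 1
  if (gross) {
    span <- tl$reappear - tl$flash_onset
    len <- stats::runif(1, 0.25, 0.5) * span
    gs <- stats::runif(1, tl$flash_onset, tl$reappear - len)
    valid <- invalidate(valid, t, gs, len)
  }

  rec <- render_recording(t, pos$x, pos$y, preset, geometry, valid,
                          list(participant = participant,
                               group = preset$group, task = "MGS",
                               condition = preset$condition))
  truth <- list(
    n_excursions = k_placed,
    anticipatory_emitted = 2L * k_placed,
    delay_break = n_break == 1,
    quadrant_error = qerr,
    latency_ms = latency,
    gain = g,
    response_direction = resp_dir,
    correct = k_placed == 0 && !qerr,
    gross_loss = gross,
    n_blinks = length(blinks$starts)
  )
  list(recording = rec, timeline = tl, truth = truth,
       trial_index = trial_index)
}

#' Simulate one prolonged-fixation trial
#'
#' 60 s of on-center jittered gaze, interleaved with Poisson-many planted
#' excursions (out at 2.5-6 deg, dwell scaled so that the expected on-center
#' time fraction equals `pf_oncenter_fraction`), plus blinks and optional
#' gross loss. Each excursion produces two countable intrusive saccades, so
#' excursions are Poisson with mean `pf_intrusive_mean / 2`.
#'
#' @inheritParams simulate_mgs_trial
#' @param duration_s trial duration (s).
#' @param n_excursions optional fixed excursion count overriding the Poisson
#'   draw (for constructed fixtures).
#' @return list with `recording` and `truth` (excursions emitted, expected
#'   intrusive count, realized on-center fraction, loss episodes).
#' @export
simulate_pf_trial <- function(preset, seed = NULL,
                              geometry = screen_geometry(), duration_s = 60,
                              participant = NA_character_,
                              trial_index = NA_integer_,
                              n_excursions = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rate <- geometry$sampling_rate_hz
  n <- round(duration_s * rate)
  t <- (seq_len(n) - 1L) / rate

  k <- if (is.null(n_excursions)) stats::rpois(1, preset$pf_intrusive_mean / 2)
       else as.integer(n_excursions)
  mean_dwell <- if (preset$pf_intrusive_mean > 0)
    (1 - preset$pf_oncenter_fraction) * duration_s /
      (preset$pf_intrusive_mean / 2) else 0.5
  dwells <- mean_dwell * stats::runif(k, 0.5, 1.5)
  exc <- place_intervals(k, 1, duration_s - 1, dwells)
  k_placed <- length(exc$starts)
  exc_r <- stats::runif(k_placed, 2.5, 6)
  exc_a <- stats::runif(k_placed, 0, 2 * pi)

  bp_t <- 0; bp_x <- 0; bp_y <- 0
  for (i in seq_len(k_placed)) {
    bp_t <- c(bp_t, exc$starts[i], exc$starts[i] + exc$durs[i])
    bp_x <- c(bp_x, exc_r[i] * cos(exc_a[i]), 0)
    bp_y <- c(bp_y, exc_r[i] * sin(exc_a[i]), 0)
  }
  pos <- path_at(t, bp_t, bp_x, bp_y)

  blinks <- draw_blinks(preset, duration_s)
  valid <- rep(TRUE, n)
  valid <- invalidate(valid, t, blinks$starts, blinks$durs)
  gross <- stats::rbinom(1, 1, preset$p_gross_loss) == 1
  if (gross) {
    len <- stats::runif(1, 0.25, 0.5) * duration_s
    gs <- stats::runif(1, 0, duration_s - len)
    valid <- invalidate(valid, t, gs, len)
  }

  rec <- render_recording(t, pos$x, pos$y, preset, geometry, valid,
                          list(participant = participant,
                               group = preset$group, task = "PF",
                               condition = preset$condition))
  truth <- list(
    n_excursions = k_placed,
    intrusive_emitted = 2L * k_placed,
    oncenter_fraction = 1 - sum(exc$durs) / duration_s,
    gross_loss = gross,
    n_blinks = length(blinks$starts)
  )
  list(recording = rec, truth = truth, trial_index = trial_index)
}

#' Simulate one participant's full session
#'
#' Block order mirrors the study procedure: two MGS tasks, four PF tasks,
#' two final MGS tasks. The four conditions are randomly assigned within
#' each task type so every participant sees each condition once per task
#' type; each MGS task comprises `mgs_trials_per_condition` trials, each PF
#' task one 60 s trial.
#'
#' @param participant participant id label.
#' @param group `"adhd"` or `"tdc"`.
#' @param presets named preset list as from [results_presets()].
#' @param mgs_trials_per_condition MGS trials per condition (study value 30).
#' @param geometry a [screen_geometry()].
#' @param seed optional integer seed.
#' @return list with `participant`, `group`, `blocks` (the condition order)
#'   and `trials`, a list of simulated trial objects each tagged with `task`,
#'   `condition` and `trial_index`.
#' @export
simulate_session <- function(participant, group, presets = results_presets(),
                             mgs_trials_per_condition = 30,
                             geometry = screen_geometry(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  conds <- c("none", "auditory", "visual25", "visual50")
  need <- paste(group, conds, sep = "_")
  missing <- setdiff(need, names(presets))
  if (length(missing))
    stop("preset table is missing cell(s): ", paste(missing, collapse = ", "))
  mgs_order <- sample(conds)
  pf_order <- sample(conds)
  blocks <- data.frame(
    task = c("MGS", "MGS", "PF", "PF", "PF", "PF", "MGS", "MGS"),
    condition = c(mgs_order[1:2], pf_order, mgs_order[3:4])
  )
  trials <- list()
  for (b in seq_len(nrow(blocks))) {
    task <- blocks$task[b]
    cond <- blocks$condition[b]
    preset <- presets[[paste(group, cond, sep = "_")]]
    ntr <- if (task == "MGS") mgs_trials_per_condition else 1L
    for (i in seq_len(ntr)) {
      tr <- if (task == "MGS")
        simulate_mgs_trial(preset, geometry = geometry,
                           participant = participant, trial_index = i)
      else
        simulate_pf_trial(preset, geometry = geometry,
                          participant = participant, trial_index = i)
      tr$task <- task
      tr$condition <- cond
      trials[[length(trials) + 1L]] <- tr
    }
  }
  list(participant = participant, group = group, blocks = blocks,
       trials = trials)
}

#' Simulate a cohort and write session files to disk
#'
#' Writes, per participant, a directory with one gaze TSV per trial, a
#' trial-event JSON (`events.json`) describing every trial's task, condition
#' and timeline, and a `ground_truth.csv` with the planted per-trial
#' parameters. Deterministic under `seed`.
#'
#' @param out_dir output directory (created if needed).
#' @param presets named preset list covering all 2 x 4 cells.
#' @param n_adhd,n_tdc group sizes (study values 52 and 45).
#' @param seed integer seed.
#' @param mgs_trials_per_condition MGS trials per condition.
#' @param geometry a [screen_geometry()].
#' @return invisibly, a data frame indexing the written sessions.
#' @export
simulate_cohort <- function(out_dir, presets = results_presets(),
                            n_adhd = 52, n_tdc = 45, seed = 1,
                            mgs_trials_per_condition = 30,
                            geometry = screen_geometry()) {
  conds <- c("none", "auditory", "visual25", "visual50")
  need <- as.vector(outer(c("adhd", "tdc"), conds, paste, sep = "_"))
  missing <- setdiff(need, names(presets))
  if (length(missing))
    stop("preset table is missing cell(s): ", paste(missing, collapse = ", "))
  set.seed(seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ids <- c(sprintf("adhd%03d", seq_len(n_adhd)),
           sprintf("tdc%03d", seq_len(n_tdc)))
  groups <- rep(c("adhd", "tdc"), c(n_adhd, n_tdc))
  index <- data.frame(participant = ids, group = groups,
                      dir = file.path(out_dir, ids))
  for (p in seq_along(ids)) {
    ses <- simulate_session(ids[p], groups[p], presets,
                            mgs_trials_per_condition, geometry)
    pdir <- index$dir[p]
    dir.create(pdir, showWarnings = FALSE)
    events <- list()
    gt <- list()
    for (j in seq_along(ses$trials)) {
      tr <- ses$trials[[j]]
      fname <- sprintf("trial%03d_%s_%s.tsv", j, tr$task, tr$condition)
      write_gaze_tsv(tr$recording, file.path(pdir, fname))
      ev <- list(task = tr$task, condition = tr$condition,
                 trial_index = tr$trial_index, gaze_file = fname)
      if (tr$task == "MGS")
        ev$timeline <- unclass(tr$timeline)
      events[[j]] <- ev
      gt[[j]] <- data.frame(
        trial = j, task = tr$task, condition = tr$condition,
        correct = if (tr$task == "MGS") tr$truth$correct else NA,
        anticipatory = if (tr$task == "MGS") tr$truth$anticipatory_emitted else NA,
        latency_ms = if (tr$task == "MGS") tr$truth$latency_ms else NA,
        gain = if (tr$task == "MGS") tr$truth$gain else NA,
        intrusive = if (tr$task == "PF") tr$truth$intrusive_emitted else NA,
        gross_loss = tr$truth$gross_loss
      )
    }
    write_session_events(events, file.path(pdir, "events.json"))
    utils::write.csv(do.call(rbind, gt), file.path(pdir, "ground_truth.csv"),
                     row.names = FALSE)
  }
  utils::write.csv(index[c("participant", "group")],
                   file.path(out_dir, "participants.csv"), row.names = FALSE)
  invisible(index)
}
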