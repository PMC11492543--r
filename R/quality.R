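#' Eye coordinates of one eye in degrees
#'
#' Internal helper: extracts one eye's trace from a recording, converted to
#' degrees of visual angle, together with its validity flags.
#' @noRd
eye_trace_deg <- function(rec, eye = c("left", "right")) {
  eye <- match.arg(eye)
  geom <- rec_geometry(rec)
  if (eye == "left") {
    deg <- norm_to_deg(rec$x_l, rec$y_l, geom)
    valid <- rec$valid_l
  } else {
    deg <- norm_to_deg(rec$x_r, rec$y_r, geom)
    valid <- rec$valid_r
  }
  list(t = rec$t, x = deg$x_deg, y = deg$y_deg, valid = valid)
}

undefined_metric <- function(what) {
  warning(what, " is undefined for this input; returning NA", call. = FALSE)
  NA_real_
}

#' Sample-to-sample RMS precision of one eye
#'
#' Root mean square of the angular distances between consecutive valid
#' samples. Pairs that bridge an invalid gap are skipped rather than
#' interpolated, so blinks do not inflate the estimate. Precision is
#' translation invariant: it measures recording noise, not offset.
#'
#' @param rec a `gaze_recording`.
#' @param eye `"left"` or `"right"`.
#' @param window optional `c(t0, t1)` restricting the samples used.
#' @return RMS sample-to-sample distance in degrees; `NA` with a warning when
#'   fewer than two valid samples are available.
#' @export
rms_s2s_precision <- function(rec, eye = c("left", "right"), window = NULL) {
  tr <- eye_trace_deg(rec, eye)
  keep <- rep(TRUE, length(tr$t))
  if (!is.null(window)) keep <- tr$t >= window[1] & tr$t <= window[2]
  ok <- tr$valid & keep
  if (sum(ok) < 2) return(undefined_metric("RMS-S2S precision"))
  n <- length(ok)
  pair <- ok[-n] & ok[-1]                 # consecutive samples, both valid
  if (!any(pair)) return(undefined_metric("RMS-S2S precision"))
  d <- angular_distance(tr$x[-n][pair], tr$y[-n][pair],
                        tr$x[-1][pair], tr$y[-1][pair])
  sqrt(mean(d^2))
}

#' Accuracy offset of one eye against a known target
#'
#' Mean angular distance between the recorded gaze and the true (validation)
#' target position. Computed per target; averaging over the validation points
#' is the caller's job (see [quality_report()]).
#'
#' @param rec a `gaze_recording`.
#' @param target_deg numeric `c(x_deg, y_deg)` of the fixated target.
#' @inheritParams rms_s2s_precision
#' @return mean offset in degrees; `NA` with a warning when no valid sample
#'   is available.
#' @export
accuracy_offset <- function(rec, target_deg, eye = c("left", "right"),
                            window = NULL) {
  tr <- eye_trace_deg(rec, eye)
  keep <- rep(TRUE, length(tr$t))
  if (!is.null(window)) keep <- tr$t >= window[1] & tr$t <= window[2]
  ok <- tr$valid & keep
  if (!any(ok)) return(undefined_metric("accuracy offset"))
  mean(angular_distance(tr$x[ok], tr$y[ok], target_deg[1], target_deg[2]))
}

#' Fraction of invalid samples in a window
#'
#' Data loss is the proportion of invalid eye-tracking samples (blinks,
#' track losses) among all samples of the window, counted at the nominal
#' sampling rate.
#'
#' @inheritParams rms_s2s_precision
#' @param window `c(t0, t1)` in seconds; defaults to the whole recording.
#' @return loss fraction in `[0, 1]`.
#' @export
data_loss_fraction <- function(rec, eye = c("left", "right"), window = NULL) {
  eye <- match.arg(eye)
  valid <- if (eye == "left") rec$valid_l else rec$valid_r
  keep <- rep(TRUE, nrow(rec))
  if (!is.null(window)) keep <- rec$t >= window[1] & rec$t <= window[2]
  if (!any(keep)) stop("window contains no samples")
  mean(!valid[keep])
}

#' Per-eye quality report for one recording
#'
#' One row per eye with the three reporting-guideline metrics: RMS
#' sample-to-sample precision, accuracy (when validation targets are given,
#' the unweighted mean of per-target means), and data-loss fraction. Eyes are
#' never averaged.
#'
#' @param rec a `gaze_recording`.
#' @param validation_targets optional data frame with columns `x_deg`,
#'   `y_deg` and optionally `t0`, `t1` windows, one row per validation point.
#' @return data frame with columns `eye`, `precision_rms_deg`,
#'   `accuracy_deg`, `data_loss_fraction`.
#' @export
quality_report <- function(rec, validation_targets = NULL) {
  rows <- lapply(c("left", "right"), function(eye) {
    acc <- NA_real_
    if (!is.null(validation_targets) && nrow(validation_targets) > 0) {
      per <- vapply(seq_len(nrow(validation_targets)), function(i) {
        tgt <- validation_targets[i, ]
        win <- if (all(c("t0", "t1") %in% names(tgt))) c(tgt$t0, tgt$t1) else NULL
        accuracy_offset(rec, c(tgt$x_deg, tgt$y_deg), eye, win)
      }, numeric(1))
      acc <- mean(per)
    }
    data.frame(eye = eye,
               precision_rms_deg = rms_s2s_precision(rec, eye),
               accuracy_deg = acc,
               data_loss_fraction = data_loss_fraction(rec, eye))
  })
  do.call(rbind, rows)
}

#' Trial-exclusion rule for excessive data loss
#'
#' Trials are excluded when data loss exceeds `max_loss_fraction` in both
#' eyes (the default reading of a "loss from both eyes" rule); the stricter
#' `mode = "either"` excludes when either eye exceeds the threshold. The
#' `scope` names the window over which loss is evaluated: the whole trial for
#' prolonged-fixation trials, flash onset to target reappearance for
#' memory-guided-saccade trials.
#'
#' @param max_loss_fraction threshold in `(0, 1]`.
#' @param scope `"trial"` or `"flash_to_reappear"`.
#' @param mode `"both"` (default) or `"either"`.
#' @return An object of class `exclusion_rule`.
#' @export
exclusion_rule <- function(max_loss_fraction = 0.20,
                           scope = c("trial", "flash_to_reappear"),
                           mode = c("both", "either")) {
  if (!is.finite(max_loss_fraction) || max_loss_fraction <= 0 ||
      max_loss_fraction > 1)
    stop("max_loss_fraction must be in (0, 1]")
  structure(list(max_loss_fraction = max_loss_fraction,
                 scope = match.arg(scope), mode = match.arg(mode)),
            class = "exclusion_rule")
}

#' Loss-evaluation window of a trial under a rule
#'
#' @param rec the trial's `gaze_recording`.
#' @param timeline the trial's [mgs_timeline()] (required for the
#'   `"flash_to_reappear"` scope).
#' @param rule an [exclusion_rule()].
#' @return `c(t0, t1)` in seconds.
#' @export
loss_window <- function(rec, rule, timeline = NULL) {
  if (rule$scope == "flash_to_reappear") {
    if (is.null(timeline))
      stop("flash_to_reappear scope needs the trial timeline")
    c(timeline$flash_onset, timeline$reappear)
  } else {
    range(rec$t)
  }
}

#' Apply the data-loss exclusion rule to a set of trials
#'
#' @param losses data frame with one row per trial and columns `loss_left`,
#'   `loss_right` evaluated over the rule's scope window; any further columns
#'   (trial ids etc.) are carried through.
#' @param rule an [exclusion_rule()].
#' @return list with elements `kept` and `excluded`, both subsets of
#'   `losses`; `excluded` gains a `reason` column carrying both loss values.
#' @export
apply_exclusion <- function(losses, rule = exclusion_rule()) {
  stopifnot(all(c("loss_left", "loss_right") %in% names(losses)))
  over_l <- losses$loss_left > rule$max_loss_fraction
  over_r <- losses$loss_right > rule$max_loss_fraction
  out <- if (rule$mode == "both") over_l & over_r else over_l | over_r
  excluded <- losses[out, , drop = FALSE]
  if (nrow(excluded))
    excluded$reason <- sprintf(
      "data loss %.1f%% (L) / %.1f%% (R) exceeds %.0f%% [%s eyes]",
      100 * excluded$loss_left, 100 * excluded$loss_right,
      100 * rule$max_loss_fraction, rule$mode)
  list(kept = losses[!out, , drop = FALSE], excluded = excluded)
}
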