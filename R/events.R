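#' Fixation-detector parameters
#'
#' Defaults follow the published defaults of the windowed two-means
#' clustering detector family: short invalid gaps are interpolated, cluster
#' transition weights are aggregated over 200 ms moving windows, samples with
#' weight at or below mean + 2 SD form fixation candidates, nearby candidates
#' are merged and very short ones dropped.
#'
#' @param max_interp_gap_ms longest invalid run that is linearly interpolated.
#' @param cluster_window_ms moving-window length for the two-means clustering.
#' @param window_step_ms step between successive windows.
#' @param weight_threshold_sd candidate threshold in SD units above the mean
#'   transition weight.
#' @param merge_max_dist_deg,merge_max_gap_ms fixation-merging limits.
#' @param min_fix_dur_ms minimum fixation duration.
#' @param disp_max_deg,disp_min_dur_ms parameters of the alternative
#'   dispersion (I-DT) backend.
#' @return An object of class `detector_params`.
#' @export
detector_params <- function(max_interp_gap_ms = 100, cluster_window_ms = 200,
                            window_step_ms = 20, weight_threshold_sd = 2.0,
                            merge_max_dist_deg = 0.7, merge_max_gap_ms = 30,
                            min_fix_dur_ms = 40, disp_max_deg = 1.0,
                            disp_min_dur_ms = 100) {
  p <- list(max_interp_gap_ms = max_interp_gap_ms,
            cluster_window_ms = cluster_window_ms,
            window_step_ms = window_step_ms,
            weight_threshold_sd = weight_threshold_sd,
            merge_max_dist_deg = merge_max_dist_deg,
            merge_max_gap_ms = merge_max_gap_ms,
            min_fix_dur_ms = min_fix_dur_ms,
            disp_max_deg = disp_max_deg,
            disp_min_dur_ms = disp_min_dur_ms)
  if (any(!vapply(p, function(v) is.finite(v) && v > 0, logical(1))))
    stop("all detector parameters must be positive and finite")
  structure(p, class = "detector_params")
}

#' Linearly interpolate short invalid gaps
#'
#' Runs of invalid samples shorter than `max_gap_ms` that are flanked by
#' valid samples are filled per eye by linear interpolation over time and
#' flagged in the logical columns `interp_l` / `interp_r`. Longer runs (real
#' blinks, track losses) are left untouched.
#'
#' @param rec a `gaze_recording`.
#' @param max_gap_ms gap threshold in milliseconds.
#' @return The recording with gaps filled and interpolation flags attached.
#' @export
interpolate_gaps <- function(rec, max_gap_ms = 100) {
  out <- rec
  if (is.null(out$interp_l)) out$interp_l <- FALSE
  if (is.null(out$interp_r)) out$interp_r <- FALSE
  for (eye in c("l", "r")) {
    vcol <- paste0("valid_", eye)
    xcol <- paste0("x_", eye); ycol <- paste0("y_", eye)
    icol <- paste0("interp_", eye)
    valid <- out[[vcol]]
    r <- rle(!valid)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in seq_along(r$lengths)) {
      if (!r$values[k]) next
      s <- starts[k]; e <- ends[k]
      if (s == 1L || e == nrow(out)) next            # no flanking sample
      gap_ms <- (out$t[e + 1L] - out$t[s - 1L]) * 1000
      if (gap_ms >= max_gap_ms) next
      idx <- s:e
      f <- (out$t[idx] - out$t[s - 1L]) / (out$t[e + 1L] - out$t[s - 1L])
      out[[xcol]][idx] <- out[[xcol]][s - 1L] +
        f * (out[[xcol]][e + 1L] - out[[xcol]][s - 1L])
      out[[ycol]][idx] <- out[[ycol]][s - 1L] +
        f * (out[[ycol]][e + 1L] - out[[ycol]][s - 1L])
      out[[vcol]][idx] <- TRUE
      out[[icol]][idx] <- TRUE
    }
  }
  out
}

#' Averaged binocular trace in degrees
#'
#' Averages the two eyes when both are valid and falls back on the valid eye
#' otherwise, mirroring detectors that take both eyes as input.
#' @noRd
binocular_trace <- function(rec) {
  l <- eye_trace_deg(rec, "left")
  r <- eye_trace_deg(rec, "right")
  both <- l$valid & r$valid
  x <- ifelse(both, (l$x + r$x) / 2, ifelse(l$valid, l$x, r$x))
  y <- ifelse(both, (l$y + r$y) / 2, ifelse(l$valid, l$y, r$y))
  list(t = rec$t, x = x, y = y, valid = l$valid | r$valid)
}

fixation_df <- function(onset = numeric(), offset = numeric(),
                        x = numeric(), y = numeric(), n = integer()) {
  data.frame(onset = onset, offset = offset, duration = offset - onset,
             x = x, y = y, n = n)
}

#' Detect fixations in a binocular gaze recording
#'
#' The default backend re-implements the windowed two-means clustering
#' pipeline: short invalid gaps are linearly interpolated, the averaged
#' binocular trace is clustered into two means inside each moving window, and
#' every cluster switch distributes weight across the window. Samples whose
#' aggregated weight stays at or below mean + `weight_threshold_sd` SD form
#' fixation candidates; candidates closer than `merge_max_dist_deg` with gaps
#' under `merge_max_gap_ms` are merged and candidates shorter than
#' `min_fix_dur_ms` dropped. Centroids are means of the member samples in
#' degrees. The `"dispersion"` backend is a classic I-DT detector used as an
#' in-repo cross-check.
#'
#' @param rec a `gaze_recording`.
#' @param params a [detector_params()].
#' @param backend `"twomeans"` (default) or `"dispersion"`.
#' @return data frame of fixations: `onset`, `offset`, `duration` (s),
#'   centroid `x`, `y` (deg), member-sample count `n`; time-ordered and
#'   non-overlapping.
#' @export
detect_fixations <- function(rec, params = detector_params(),
                             backend = c("twomeans", "dispersion")) {
  backend <- match.arg(backend)
  rec <- interpolate_gaps(rec, params$max_interp_gap_ms)
  tr <- binocular_trace(rec)
  if (!any(tr$valid)) {
    warning("no valid samples; returning no fixations", call. = FALSE)
    return(fixation_df())
  }
  rate <- rec_geometry(rec)$sampling_rate_hz
  if (backend == "twomeans") {
    win <- max(4L, as.integer(round(params$cluster_window_ms / 1000 * rate)))
    step <- max(1L, as.integer(round(params$window_step_ms / 1000 * rate)))
    if (length(tr$t) < win) {
      # shorter than one window: treat the valid stretch as one candidate run
      candidate <- tr$valid
    } else {
      w <- transition_weights_cpp(tr$x, tr$y, tr$valid, win, step)
      wv <- w[tr$valid & !is.na(w)]
      thr <- mean(wv) + params$weight_threshold_sd * stats::sd(wv)
      if (!is.finite(thr)) thr <- 0
      candidate <- tr$valid & !is.na(w) & w <= thr
    }
  } else {
    return(detect_fixations_idt(tr, params))
  }
  runs_to_fixations(tr, candidate, params)
}

#' Turn a candidate mask into merged, duration-filtered fixations
#' @noRd
runs_to_fixations <- function(tr, candidate, params) {
  candidate[is.na(candidate)] <- FALSE
  r <- rle(candidate)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  if (!length(keep)) return(fixation_df())
  fx <- lapply(keep, function(k) {
    idx <- starts[k]:ends[k]
    c(onset = tr$t[starts[k]], offset = tr$t[ends[k]],
      sx = sum(tr$x[idx]), sy = sum(tr$y[idx]), n = length(idx))
  })
  fx <- as.data.frame(do.call(rbind, fx))
  # merge neighbouring candidates that are close in space and time
  i <- 1L
  while (i < nrow(fx)) {
    gap_ms <- (fx$onset[i + 1L] - fx$offset[i]) * 1000
    d <- angular_distance(fx$sx[i] / fx$n[i], fx$sy[i] / fx$n[i],
                          fx$sx[i + 1L] / fx$n[i + 1L],
                          fx$sy[i + 1L] / fx$n[i + 1L])
    if (gap_ms <= params$merge_max_gap_ms && d <= params$merge_max_dist_deg) {
      fx$offset[i] <- fx$offset[i + 1L]
      fx$sx[i] <- fx$sx[i] + fx$sx[i + 1L]
      fx$sy[i] <- fx$sy[i] + fx$sy[i + 1L]
      fx$n[i] <- fx$n[i] + fx$n[i + 1L]
      fx <- fx[-(i + 1L), , drop = FALSE]
    } else {
      i <- i + 1L
    }
  }
  dur_ok <- (fx$offset - fx$onset) * 1000 >= params$min_fix_dur_ms
  fx <- fx[dur_ok, , drop = FALSE]
  fixation_df(fx$onset, fx$offset, fx$sx / fx$n, fx$sy / fx$n,
              as.integer(fx$n))
}

#' I-DT dispersion backend
#' @noRd
detect_fixations_idt <- function(tr, params) {
  n <- length(tr$t)
  out <- list()
  i <- 1L
  min_dur <- params$disp_min_dur_ms / 1000
  while (i <= n) {
    if (!tr$valid[i]) { i <- i + 1L; next }
    # grow the window while dispersion stays within bounds
    j <- i
    while (j < n && tr$valid[j + 1L]) {
      idx <- i:(j + 1L)
      disp <- (max(tr$x[idx]) - min(tr$x[idx])) +
              (max(tr$y[idx]) - min(tr$y[idx]))
      if (disp > params$disp_max_deg) break
      j <- j + 1L
    }
    if (tr$t[j] - tr$t[i] >= min_dur) {
      idx <- i:j
      out[[length(out) + 1L]] <-
        c(onset = tr$t[i], offset = tr$t[j],
          x = mean(tr$x[idx]), y = mean(tr$y[idx]), n = length(idx))
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  if (!length(out)) return(fixation_df())
  m <- as.data.frame(do.call(rbind, out))
  fixation_df(m$onset, m$offset, m$x, m$y, as.integer(m$n))
}

#' Derive saccades from consecutive fixations
#'
#' Saccades are operationalized as the displacements between consecutive
#' fixation centroids: `n` fixations yield `n - 1` saccades. A saccade's
#' onset is the preceding fixation's offset; amplitude is the angular
#' distance between centroids; direction the `atan2` angle of the
#' displacement in degrees (counter-clockwise from rightward, up positive).
#'
#' @param fixations a fixation data frame from [detect_fixations()].
#' @return data frame of saccades: `onset`, `amplitude`, `direction`,
#'   `x_from`, `y_from`, `x_to`, `y_to`, `landing` (row index of the landing
#'   fixation).
#' @export
derive_saccades <- function(fixations) {
  n <- nrow(fixations)
  if (n < 2)
    return(data.frame(onset = numeric(), amplitude = numeric(),
                      direction = numeric(), x_from = numeric(),
                      y_from = numeric(), x_to = numeric(), y_to = numeric(),
                      landing = integer()))
  i <- seq_len(n - 1L)
  dx <- fixations$x[i + 1L] - fixations$x[i]
  dy <- fixations$y[i + 1L] - fixations$y[i]
  data.frame(onset = fixations$offset[i],
             amplitude = sqrt(dx^2 + dy^2),
             direction = (atan2(dy, dx) * 180 / pi) %% 360,
             x_from = fixations$x[i], y_from = fixations$y[i],
             x_to = fixations$x[i + 1L], y_to = fixations$y[i + 1L],
             landing = i + 1L)
}

#' Write detected events to CSV
#'
#' One file with a `type` column distinguishing fixation rows (onset, offset,
#' duration, centroid) from saccade rows (onset, amplitude, direction).
#'
#' @param fixations,saccades event data frames.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_events_csv <- function(fixations, saccades, path) {
  f <- data.frame(type = "fixation", onset = fixations$onset,
                  offset = fixations$offset, duration = fixations$duration,
                  x_deg = fixations$x, y_deg = fixations$y,
                  amplitude = NA_real_, direction = NA_real_)
  s <- data.frame(type = "saccade", onset = saccades$onset,
                  offset = NA_real_, duration = NA_real_,
                  x_deg = NA_real_, y_deg = NA_real_,
                  amplitude = saccades$amplitude,
                  direction = saccades$direction)
  utils::write.csv(rbind(f, s), path, row.names = FALSE)
  invisible(path)
}
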