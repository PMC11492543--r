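#' Fixation ratio of a prolonged-fixation trial
#'
#' Every fixation is classified as correct when its centroid lies strictly
#' within `threshold_deg` of the central fixation point. The fixation ratio
#' is the summed duration of correct fixations divided by the summed duration
#' of all fixations, so it is scale-free in time.
#'
#' @param fixations fixation data frame from [detect_fixations()].
#' @param center `c(x_deg, y_deg)` of the central fixation point.
#' @param threshold_deg correctness radius (strict `<`).
#' @return fraction in `[0, 1]`; `NA` with a warning when there are no
#'   fixations.
#' @export
fixation_ratio <- function(fixations, center = c(0, 0), threshold_deg = 2) {
  if (nrow(fixations) == 0) return(undefined_metric("fixation ratio"))
  d <- angular_distance(fixations$x, fixations$y, center[1], center[2])
  sum(fixations$duration[d < threshold_deg]) / sum(fixations$duration)
}

#' Count intrusive saccades in a prolonged-fixation trial
#'
#' Saccades with amplitude at or above `amp_threshold_deg` count as
#' intrusive. Saccades made at the start of the trial to bring the gaze onto
#' the central point are excluded: counting begins at the onset of the first
#' fixation lying within `center_threshold_deg` of the center. By default
#' both legs of an excursion (outgoing and return) count, since each is a
#' large saccade; `direction = "outgoing"` counts only saccades that land
#' off-center, i.e. one per excursion.
#'
#' @param saccades saccade data frame from [derive_saccades()].
#' @param fixations the trial's fixations (used to find the first on-center
#'   fixation).
#' @param center `c(x_deg, y_deg)` of the central fixation point.
#' @param amp_threshold_deg intrusiveness amplitude threshold (inclusive
#'   `>=`), complementary at the boundary to the `<` correctness rule.
#' @param center_threshold_deg on-center radius for the start rule.
#' @param direction `"all"` (default) or `"outgoing"`.
#' @return integer count; 0 with a warning when no fixation is ever
#'   on-center.
#' @export
count_intrusive_saccades <- function(saccades, fixations, center = c(0, 0),
                                     amp_threshold_deg = 2,
                                     center_threshold_deg = 2,
                                     direction = c("all", "outgoing")) {
  direction <- match.arg(direction)
  if (nrow(fixations) == 0 || nrow(saccades) == 0) return(0L)
  d <- angular_distance(fixations$x, fixations$y, center[1], center[2])
  on_center <- which(d < center_threshold_deg)
  if (!length(on_center)) {
    warning("gaze never reached the central fixation point; counting 0 ",
            "intrusive saccades", call. = FALSE)
    return(0L)
  }
  t0 <- fixations$onset[on_center[1]]
  big <- saccades$amplitude >= amp_threshold_deg & saccades$onset >= t0
  if (direction == "outgoing") {
    lands_off <- angular_distance(saccades$x_to, saccades$y_to,
                                  center[1], center[2]) >= center_threshold_deg
    big <- big & lands_off
  }
  sum(big)
}

#' Measure one prolonged-fixation trial
#'
#' Convenience wrapper: detects events and returns both PF measures.
#'
#' @param rec the trial's `gaze_recording` (nominal 60 s central fixation).
#' @param params a [detector_params()].
#' @param center central fixation point in degrees.
#' @param backend detector backend, see [detect_fixations()].
#' @return one-row data frame with `fixation_ratio` and `intrusive_saccades`.
#' @export
measure_pf_trial <- function(rec, params = detector_params(),
                             center = c(0, 0),
                             backend = c("twomeans", "dispersion")) {
  fx <- detect_fixations(rec, params, match.arg(backend))
  sc <- derive_saccades(fx)
  data.frame(fixation_ratio = fixation_ratio(fx, center),
             intrusive_saccades = count_intrusive_saccades(sc, fx, center))
}
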