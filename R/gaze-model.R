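#' Screen geometry of the recording setup
#'
#' Physical description of the display and viewing position used to convert
#' normalized screen coordinates into degrees of visual angle. The defaults
#' describe a 23.8-inch 16:9 panel viewed from 63 cm with a 600 Hz tracker.
#'
#' @param width_mm physical display width in millimetres.
#' @param height_mm physical display height in millimetres.
#' @param viewing_distance_mm eye-to-screen distance in millimetres.
#' @param sampling_rate_hz nominal gaze sample rate in Hz.
#' @return An object of class `screen_geometry`.
#' @export
#' @examples
#' geom <- screen_geometry()
#' norm_to_deg(1, 0.5, geom)  # right screen edge, about 22.7 deg
screen_geometry <- function(width_mm = 527.0, height_mm = 296.5,
                            viewing_distance_mm = 630,
                            sampling_rate_hz = 600) {
  vals <- c(width_mm = width_mm, height_mm = height_mm,
            viewing_distance_mm = viewing_distance_mm,
            sampling_rate_hz = sampling_rate_hz)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all screen_geometry fields must be strictly positive and finite")
  structure(as.list(vals), class = "screen_geometry")
}

#' @export
print.screen_geometry <- function(x, ...) {
  cat(sprintf("screen_geometry: %.1f x %.1f mm at %.0f mm, %g Hz\n",
              x$width_mm, x$height_mm, x$viewing_distance_mm,
              x$sampling_rate_hz))
  invisible(x)
}

sample_cols <- c("t", "x_l", "y_l", "x_r", "y_r", "valid_l", "valid_r")

#' Construct a binocular gaze recording
#'
#' Samples live in the vendor's normalized screen coordinate system where the
#' upper-left corner is (0,0) and the lower-right corner is (1,1). Invalid
#' eyes carry `NA` coordinates and a `FALSE` validity flag; consumers must
#' branch on the flag, never on coordinate magnitude.
#'
#' @param samples data frame with columns `t, x_l, y_l, x_r, y_r, valid_l,
#'   valid_r`; timestamps in seconds, strictly increasing.
#' @param geometry a [screen_geometry()].
#' @param participant,group,task,condition recording metadata labels.
#' @return An object of class `gaze_recording`: the sample data frame with
#'   geometry and metadata attached as attributes.
#' @export
gaze_recording <- function(samples, geometry = screen_geometry(),
                           participant = NA_character_, group = NA_character_,
                           task = NA_character_, condition = NA_character_) {
  stopifnot(is.data.frame(samples))
  missing <- setdiff(sample_cols, names(samples))
  if (length(missing))
    stop("gaze samples missing column(s): ", paste(missing, collapse = ", "))
  if (nrow(samples) < 1L) stop("a gaze recording needs at least one sample")
  dt <- diff(samples$t)
  if (length(dt) && any(dt <= 0)) {
    bad <- which(dt <= 0)[1] + 1L
    stop(sprintf("timestamps must be strictly increasing; first violation at row %d", bad))
  }
  samples$valid_l <- as.logical(samples$valid_l)
  samples$valid_r <- as.logical(samples$valid_r)
  # enforce the sentinel convention
  samples$x_l[!samples$valid_l] <- NA_real_
  samples$y_l[!samples$valid_l] <- NA_real_
  samples$x_r[!samples$valid_r] <- NA_real_
  samples$y_r[!samples$valid_r] <- NA_real_
  if (any(!is.finite(samples$x_l[samples$valid_l])) ||
      any(!is.finite(samples$y_l[samples$valid_l])) ||
      any(!is.finite(samples$x_r[samples$valid_r])) ||
      any(!is.finite(samples$y_r[samples$valid_r])))
    stop("valid samples must carry finite coordinates")
  structure(samples,
            geometry = geometry,
            meta = list(participant = participant, group = group,
                        task = task, condition = condition),
            class = c("gaze_recording", "data.frame"))
}

#' Geometry and metadata accessors
#' @param rec a `gaze_recording`.
#' @return `rec_geometry()` the attached [screen_geometry()]; `rec_meta()` the
#'   metadata list.
#' @export
rec_geometry <- function(rec) attr(rec, "geometry")

#' @rdname rec_geometry
#' @export
rec_meta <- function(rec) attr(rec, "meta")

#' Convert normalized screen coordinates to degrees of visual angle
#'
#' Per-axis tangent conversion about the screen center: a point at normalized
#' `(0.5, 0.5)` maps to `(0, 0)` degrees. The normalized y axis grows
#' downward (screen convention); the degree y axis is flipped so that up is
#' positive.
#'
#' @param x,y normalized coordinates (vectors of equal length).
#' @param geometry a [screen_geometry()].
#' @return data frame with columns `x_deg`, `y_deg`.
#' @export
norm_to_deg <- function(x, y, geometry = screen_geometry()) {
  d <- geometry$viewing_distance_mm
  data.frame(
    x_deg = atan((x - 0.5) * geometry$width_mm / d) * 180 / pi,
    y_deg = atan((0.5 - y) * geometry$height_mm / d) * 180 / pi
  )
}

#' @rdname norm_to_deg
#' @param x_deg,y_deg positions in degrees of visual angle.
#' @export
deg_to_norm <- function(x_deg, y_deg, geometry = screen_geometry()) {
  d <- geometry$viewing_distance_mm
  data.frame(
    x = tan(x_deg * pi / 180) * d / geometry$width_mm + 0.5,
    y = 0.5 - tan(y_deg * pi / 180) * d / geometry$height_mm
  )
}

#' Angular distance between gaze positions
#'
#' Planar Euclidean distance in the per-axis degree plane, the standard
#' small-angle treatment in eye-tracking analysis. Vectorized over points.
#'
#' @param x1,y1,x2,y2 coordinates in degrees of visual angle.
#' @return distance(s) in degrees.
#' @export
#' @examples
#' angular_distance(0, 0, 3, 4)  # 5
angular_distance <- function(x1, y1, x2, y2) {
  sqrt((x1 - x2)^2 + (y1 - y2)^2)
}

#' Read and write gaze sample TSV files
#'
#' The on-disk format is a UTF-8 tab-separated table with header
#' `t x_l y_l x_r y_r valid_l valid_r`, one sample per row; coordinates are
#' written with 6 decimal places and invalid eyes as `NA`. Extra columns are
#' tolerated on read and ignored.
#'
#' @param path file path.
#' @param geometry a [screen_geometry()] attached to the returned recording.
#' @param ... metadata passed on to [gaze_recording()].
#' @return `read_gaze_tsv()` a `gaze_recording`; `write_gaze_tsv()` the path,
#'   invisibly.
#' @export
read_gaze_tsv <- function(path, geometry = screen_geometry(), ...) {
  if (!file.exists(path)) stop("no such gaze file: ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  missing <- setdiff(sample_cols, names(df))
  if (length(missing))
    stop(sprintf("gaze file %s is missing required column(s): %s",
                 path, paste(missing, collapse = ", ")))
  df <- df[sample_cols]
  for (col in c("t", "x_l", "y_l", "x_r", "y_r"))
    df[[col]] <- as.numeric(df[[col]])
  if (any(!is.finite(df$t)))
    stop(sprintf("gaze file %s: non-finite timestamp at row %d",
                 path, which(!is.finite(df$t))[1]))
  gaze_recording(df, geometry, ...)
}

#' @rdname read_gaze_tsv
#' @param rec a `gaze_recording` to write.
#' @export
write_gaze_tsv <- function(rec, path) {
  df <- as.data.frame(rec)[sample_cols]
  for (col in c("x_l", "y_l", "x_r", "y_r")) df[[col]] <- round(df[[col]], 6)
  df$valid_l <- as.integer(df$valid_l)
  df$valid_r <- as.integer(df$valid_r)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read and write per-session trial-event files
#'
#' A session's trial schedule is stored as JSON: a list of trials, each with
#' `task` ("PF" or "MGS"), `condition` ("none", "auditory", "visual25" or
#' "visual50"), `trial_index`, the gaze file name, and for MGS trials the
#' timeline timestamps plus flash direction.
#'
#' @param trials list of trial descriptors (see Details).
#' @param path file path of the JSON document.
#' @return `read_session_events()` the list of trial descriptors;
#'   `write_session_events()` the path, invisibly.
#' @export
write_session_events <- function(trials, path) {
  jsonlite::write_json(trials, path, auto_unbox = TRUE, digits = 8,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_session_events
#' @export
read_session_events <- function(path) {
  if (!file.exists(path)) stop("no such trial-event file: ", path)
  jsonlite::read_json(path, simplifyVector = FALSE)
}

#' Read a screen-geometry block from a YAML config file
#'
#' Expects a top-level `geometry:` mapping with the physical fields of
#' [screen_geometry()]; absent fields fall back to the defaults.
#'
#' @param path YAML file path.
#' @return A [screen_geometry()].
#' @export
read_geometry_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  g <- cfg$geometry
  if (is.null(g)) stop("config file has no `geometry:` block: ", path)
  defaults <- formals(screen_geometry)
  args <- lapply(names(defaults), function(nm) {
    if (!is.null(g[[nm]])) g[[nm]] else eval(defaults[[nm]])
  })
  names(args) <- names(defaults)
  do.call(screen_geometry, args)
}
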