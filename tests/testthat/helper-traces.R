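# Fixture builders: recordings constructed from degree-space traces.

default_geom <- screen_geometry()

# recording from degree coordinates; both eyes identical unless jitter given
rec_from_deg <- function(x_deg, y_deg, valid = TRUE, rate = 600,
                         geom = default_geom, jitter = 0) {
  n <- length(x_deg)
  stopifnot(length(y_deg) == n)
  valid <- rep_len(valid, n)
  t <- (seq_len(n) - 1L) / rate
  mk_eye <- function() {
    deg_to_norm(x_deg + rnorm(n, 0, jitter), y_deg + rnorm(n, 0, jitter),
                geom)
  }
  l <- mk_eye(); r <- mk_eye()
  gaze_recording(data.frame(t = t, x_l = l$x, y_l = l$y,
                            x_r = r$x, y_r = r$y,
                            valid_l = valid, valid_r = valid), geom)
}

# plateau trace: positions held for dur_s each, instantaneous jumps between
plateau_rec <- function(positions, dur_s = 1, rate = 600, jitter = 0,
                        geom = default_geom) {
  n_per <- round(dur_s * rate)
  x <- rep(vapply(positions, `[`, numeric(1), 1), each = n_per)
  y <- rep(vapply(positions, `[`, numeric(1), 2), each = n_per)
  rec_from_deg(x, y, rate = rate, geom = geom, jitter = jitter)
}

# hand-built fixation / saccade tables for unit-level measure tests
fix_table <- function(onset, offset, x, y) {
  data.frame(onset = onset, offset = offset, duration = offset - onset,
             x = x, y = y, n = NA_integer_)
}
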