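tl45 <- mgs_timeline(flash_onset = 2.5, go = 5.3, flash_direction = 45)

test_that("timeline construction enforces the trial schedule", {
  expect_equal(tl45$flash_offset, 2.8)
  expect_equal(tl45$reappear, 6.3)
  expect_equal(tl45$reappear_off, 7.3)
  expect_equal(flash_position(tl45), 10 * c(cos(pi / 4), sin(pi / 4)))
  expect_error(mgs_timeline(2.5, 2.6, 45), "ordered")     # go inside flash
  expect_error(mgs_timeline(2.5, 5.3, 90), "flash_direction")
})

test_that("quadrants follow sign patterns; axis points match none", {
  expect_equal(quadrant_of(3, 3), 45)
  expect_equal(quadrant_of(-3, 3), 135)
  expect_equal(quadrant_of(-3, -3), 225)
  expect_equal(quadrant_of(3, -3), 315)
  expect_true(is.na(quadrant_of(0, 3)))
  expect_true(is.na(quadrant_of(3, 0)))
  expect_true(is.na(quadrant_of(0, 0)))
  # off-origin center
  expect_equal(quadrant_of(2, 2, center = c(1, 1)), 45)
})

sacc_at <- function(onset, amplitude, x_to = 7, y_to = 7) {
  n <- length(onset)
  data.frame(onset = onset, amplitude = amplitude,
             direction = rep_len(45, n), x_from = rep_len(0, n),
             y_from = rep_len(0, n), x_to = rep_len(x_to, n),
             y_to = rep_len(y_to, n), landing = rep_len(NA_integer_, n))
}

test_that("anticipatory window is [flash_onset, go + 80 ms), amplitude-gated", {
  expect_equal(count_anticipatory_saccades(sacc_at(numeric(0), numeric(0)),
                                           tl45), 0)
  # inside the window
  expect_equal(count_anticipatory_saccades(sacc_at(tl45$go + 0.05, 3), tl45), 1)
  # at go + 100 ms: outside
  expect_equal(count_anticipatory_saccades(sacc_at(tl45$go + 0.10, 3), tl45), 0)
  # before flash onset: not analyzed
  expect_equal(count_anticipatory_saccades(sacc_at(1.0, 5), tl45), 0)
  # amplitude below 2 deg never counts
  expect_equal(count_anticipatory_saccades(sacc_at(3.0, 1.9), tl45), 0)
  expect_equal(count_anticipatory_saccades(sacc_at(3.0, 2.0), tl45), 1)
})

test_that("response saccade is the first large saccade in the response window", {
  s <- rbind(sacc_at(tl45$go + 0.2, 8), sacc_at(tl45$go + 0.4, 8))
  r <- find_response_saccade(s, tl45)
  expect_equal(r$onset, tl45$go + 0.2)
  # amplitude gate: only a small drift in the window
  expect_null(find_response_saccade(sacc_at(tl45$go + 0.3, 1), tl45))
  # boundaries: 80 ms inclusive, 1000 ms inclusive, just outside excluded
  expect_false(is.null(find_response_saccade(sacc_at(tl45$go + 0.08, 5), tl45)))
  expect_false(is.null(find_response_saccade(sacc_at(tl45$go + 1.0, 5), tl45)))
  expect_null(find_response_saccade(sacc_at(tl45$go + 1.2, 5), tl45))
})

hold_fix <- function() {
  # one fixation covering fixation period through the delay, on center
  fix_table(onset = 0, offset = tl45$go + 0.3 - 1e-3, x = 0, y = 0)
}

test_that("a compliant trial is classified correct with latency and gain", {
  land <- fix_table(onset = tl45$go + 0.32, offset = tl45$reappear_off,
                    x = 9.5 * cos(pi / 4), y = 9.5 * sin(pi / 4))
  fx <- rbind(hold_fix(), land)
  sc <- derive_saccades(fx)
  v <- classify_mgs_trial(fx, sc, tl45)
  expect_true(v$correct)
  expect_equal(v$failed, character(0))
  expect_equal(latency_ms(v), (tl45$go + 0.3 - 1e-3 - tl45$go) * 1000,
               tolerance = 1e-6)
  expect_equal(gain(v), 0.95, tolerance = 1e-9)
})

test_that("each criterion is detected and all failures are reported", {
  land <- fix_table(onset = tl45$go + 0.32, offset = tl45$reappear_off,
                    x = 9.5 * cos(pi / 4), y = 9.5 * sin(pi / 4))

  # (ii): a delay-period fixation at 3 deg from center
  fx <- rbind(fix_table(onset = 0, offset = 3.5, x = 0, y = 0),
              fix_table(onset = 3.6, offset = tl45$go + 0.3 - 1e-3, x = 3, y = 0),
              land)
  v <- classify_mgs_trial(fx, derive_saccades(fx), tl45)
  expect_false(v$correct)
  expect_equal(v$failed, "ii")
  expect_error(latency_ms(v), "correct")
  expect_error(gain(v), "correct")

  # (iii): response too late (go + 1.2 s)
  late <- fix_table(onset = tl45$go + 1.25, offset = tl45$reappear_off,
                    x = 7, y = 7)
  fx <- rbind(fix_table(onset = 0, offset = tl45$go + 1.2, x = 0, y = 0), late)
  v <- classify_mgs_trial(fx, derive_saccades(fx), tl45)
  expect_true("iii" %in% v$failed)

  # (iv): a >2 deg saccade whose landing is still within 2 deg of center
  nearc <- fix_table(onset = tl45$go + 0.32, offset = tl45$reappear_off,
                     x = 1.2, y = 1.2)
  fx <- rbind(fix_table(onset = 0, offset = tl45$go + 0.3, x = -0.8, y = -0.8),
              nearc)
  v <- classify_mgs_trial(fx, derive_saccades(fx), tl45)
  expect_true("iv" %in% v$failed)

  # (v): landing in the wrong quadrant
  wrong <- fix_table(onset = tl45$go + 0.32, offset = tl45$reappear_off,
                     x = -7, y = 7)
  fx <- rbind(hold_fix(), wrong)
  v <- classify_mgs_trial(fx, derive_saccades(fx), tl45)
  expect_false(v$correct)
  expect_equal(v$failed, "v")

  # (i): no fixation overlapping the delay window at all
  fx <- fix_table(onset = tl45$go + 0.5, offset = tl45$reappear_off,
                  x = 7, y = 7)
  v <- classify_mgs_trial(fx, derive_saccades(fx), tl45)
  expect_true("i" %in% v$failed)
})

test_that("removing a violating fixation can only shrink the failed set", {
  land <- fix_table(onset = tl45$go + 0.32, offset = tl45$reappear_off,
                    x = 7, y = 7)
  bad <- fix_table(onset = 3.6, offset = 4.4, x = 4, y = 0)
  fx_bad <- rbind(fix_table(onset = 0, offset = 3.5, x = 0, y = 0), bad,
                  fix_table(onset = 4.5, offset = tl45$go + 0.3 - 1e-3,
                            x = 0, y = 0), land)
  fx_ok <- fx_bad[-2, ]
  v_bad <- classify_mgs_trial(fx_bad, derive_saccades(fx_bad), tl45)
  v_ok <- classify_mgs_trial(fx_ok, derive_saccades(fx_ok), tl45)
  expect_true(all(v_ok$failed %in% v_bad$failed))
  expect_true("ii" %in% v_bad$failed)
  expect_true(v_ok$correct)
})

test_that("events after reappearance offset change neither counts nor verdict", {
  land <- fix_table(onset = tl45$go + 0.32, offset = tl45$reappear_off,
                    x = 7, y = 7)
  fx <- rbind(hold_fix(), land)
  v0 <- classify_mgs_trial(fx, derive_saccades(fx), tl45)
  a0 <- count_anticipatory_saccades(derive_saccades(fx), tl45)
  fx_more <- rbind(fx, fix_table(onset = tl45$reappear_off + 0.1,
                                 offset = tl45$reappear_off + 1,
                                 x = -6, y = -6))
  v1 <- classify_mgs_trial(fx_more, derive_saccades(fx_more), tl45)
  expect_equal(v1$correct, v0$correct)
  expect_equal(v1$failed, v0$failed)
  expect_equal(count_anticipatory_saccades(derive_saccades(fx_more), tl45), a0)
})

test_that("the alternative flash-offset anchoring is available", {
  # gaze leaves for the target 0.5 s after FLASH offset: correct under the
  # alternative reading, a delay break (hence incorrect) under the default
  # go-cue reading
  land <- fix_table(onset = tl45$flash_offset + 0.5,
                    offset = tl45$reappear_off, x = 7, y = 7)
  fx <- rbind(fix_table(onset = 0, offset = tl45$flash_offset + 0.49,
                        x = 0, y = 0), land)
  sc <- derive_saccades(fx)
  v_go <- classify_mgs_trial(fx, sc, tl45, target_offset = "go")
  v_fl <- classify_mgs_trial(fx, sc, tl45, target_offset = "flash_offset")
  expect_false(v_go$correct)
  expect_true(v_fl$correct)
  # saccade onset is the hold fixation's offset, 490 ms after flash offset
  expect_equal(latency_ms(v_fl), 490, tolerance = 1e-6)
})

test_that("proportion correct counts verdicts", {
  mk <- function(ok) structure(list(correct = ok), class = "trial_verdict")
  expect_equal(proportion_correct(list(mk(TRUE), mk(TRUE))), 1.0)
  expect_equal(proportion_correct(c(rep(TRUE, 15), rep(FALSE, 15))), 0.5)
  expect_warning(v <- proportion_correct(logical(0)), "undefined")
  expect_true(is.na(v))
})

test_that("latency and gain exist iff the verdict is correct, over simulator output", {
  pr <- sim_preset("x", "none", p_correct = 0.5)
  set.seed(8)
  for (i in 1:20) {
    tr <- simulate_mgs_trial(pr)
    fx <- detect_fixations(tr$recording)
    sc <- derive_saccades(fx)
    v <- classify_mgs_trial(fx, sc, tr$timeline)
    expect_equal(!is.null(v$latency_ms), v$correct)
    expect_equal(!is.null(v$gain), v$correct)
  }
})
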