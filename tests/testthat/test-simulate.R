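test_that("preset construction solves the correctness mapping and rejects impossible cells", {
  pr <- sim_preset("adhd", "none", mgs_anticipatory_mean = 0.69,
                   p_correct = 0.49)
  expect_equal(exp(-0.69 / 2) * (1 - pr$p_quadrant_error), 0.49,
               tolerance = 1e-12)
  # a planted proportion above the anticipatory ceiling is unreachable
  expect_error(sim_preset("x", "none", mgs_anticipatory_mean = 3,
                          p_correct = 0.5), "not reachable")
  expect_error(sim_preset("x", "none"), "p_correct or p_quadrant_error")
})

test_that("latency and gain calibrations hit their targets after truncation", {
  pr <- results_presets()[["adhd_visual50"]]
  set.seed(1)
  lat <- 80 + noisegaze:::rtrunc_lnorm(2e5, pr$latency_meanlog,
                                       pr$latency_sdlog, pr$latency_lo,
                                       pr$latency_hi)
  expect_equal(mean(lat), 347.2, tolerance = 2)
  expect_true(all(lat >= 85 & lat <= 995))
  g <- noisegaze:::rtrunc_norm(2e5, pr$gain_mu, pr$gain_sd, pr$gain_lo,
                               pr$gain_hi)
  expect_equal(mean(g), 0.81, tolerance = 0.005)
  expect_true(all(g >= 0.21 & g <= 1.6))
})

test_that("the preset table covers all eight cells and survives YAML round-trip", {
  pre <- results_presets()
  expect_length(pre, 8)
  expect_setequal(names(pre),
                  as.vector(outer(c("adhd", "tdc"),
                                  c("none", "auditory", "visual25", "visual50"),
                                  paste, sep = "_")))
  # the auditory latency cells are flagged as filled-in
  expect_true(pre$adhd_auditory$interpolated)
  expect_false(pre$adhd_none$interpolated)

  path <- withr::local_tempfile(fileext = ".yaml")
  write_presets_yaml(pre, path)
  back <- read_presets_yaml(path)
  expect_equal(back$adhd_none$p_quadrant_error, pre$adhd_none$p_quadrant_error,
               tolerance = 1e-9)
  expect_equal(back$tdc_visual50$latency_meanlog,
               pre$tdc_visual50$latency_meanlog, tolerance = 1e-9)
})

test_that("timeline draws respect the printed interval bounds", {
  set.seed(123)
  for (i in 1:1000) {
    tl <- draw_mgs_timeline()
    expect_true(tl$flash_onset - tl$fix_onset >= 2.0)
    expect_true(tl$flash_onset - tl$fix_onset <= 3.5)
    delay <- tl$go - tl$flash_offset
    expect_true(delay >= 2.0 && delay <= 3.5)
    expect_equal(tl$flash_offset - tl$flash_onset, 0.300)
    expect_equal(tl$reappear - tl$go, 1.000)
    expect_equal(tl$reappear_off - tl$reappear, 1.000)
    expect_true(tl$flash_direction %in% c(45, 135, 225, 315))
  }
})

test_that("simulation is deterministic under a seed, with no hidden state", {
  pr <- results_presets()[["adhd_none"]]
  a <- simulate_mgs_trial(pr, seed = 77)
  b <- simulate_mgs_trial(pr, seed = 77)
  expect_identical(a$recording$x_l, b$recording$x_l)
  expect_identical(a$truth, b$truth)
  expect_identical(unclass(a$timeline), unclass(b$timeline))

  # interleaving other draws between seeded runs changes nothing
  set.seed(5); p1 <- simulate_pf_trial(pr, duration_s = 5)
  runif(1000)
  set.seed(5); p2 <- simulate_pf_trial(pr, duration_s = 5)
  expect_identical(p1$recording$x_r, p2$recording$x_r)
})

test_that("a noiseless constructed trial reproduces its parameters end-to-end", {
  pr <- sim_preset("x", "none", fix_jitter_sd_deg = 0,
                   mgs_anticipatory_mean = 0, p_quadrant_error = 0,
                   gain_mean = 1.0, gain_sd = 0,
                   latency_mean_ms = 300, latency_sd_ms = 0,
                   blink_rate_per_min = 0, p_gross_loss = 0,
                   accuracy_offset_sd_deg = 0)
  set.seed(31)
  for (i in 1:5) {
    tr <- simulate_mgs_trial(pr)
    m <- measure_mgs_trial(tr$recording, tr$timeline)
    expect_true(m$correct)
    expect_equal(m$latency_ms, 300, tolerance = 1000 / 600)  # one sample
    expect_equal(m$gain, 1.00, tolerance = 0.01)
    expect_equal(m$anticipatory_count, 0)
  }
})

test_that("planted anticipatory events are counted exactly on clean trials", {
  pr <- sim_preset("x", "none", mgs_anticipatory_mean = 2,
                   p_quadrant_error = 0, blink_rate_per_min = 0,
                   p_gross_loss = 0)
  set.seed(55)
  mism <- 0L
  for (i in 1:60) {
    tr <- simulate_mgs_trial(pr)
    m <- measure_mgs_trial(tr$recording, tr$timeline)
    if (m$anticipatory_count != tr$truth$anticipatory_emitted)
      mism <- mism + 1L
    # the pipeline never counts more than was planted on blink-free trials
    expect_lte(m$anticipatory_count, tr$truth$anticipatory_emitted)
  }
  expect_lte(mism, 2)   # rare placement-edge misses only
})

test_that("a session has the study's block structure", {
  pre <- results_presets()
  set.seed(9)
  ses <- simulate_session("p1", "adhd", pre, mgs_trials_per_condition = 2)
  expect_equal(ses$blocks$task, c("MGS", "MGS", "PF", "PF", "PF", "PF",
                                  "MGS", "MGS"))
  # each task type sees all four conditions
  expect_setequal(ses$blocks$condition[ses$blocks$task == "MGS"],
                  c("none", "auditory", "visual25", "visual50"))
  expect_setequal(ses$blocks$condition[ses$blocks$task == "PF"],
                  c("none", "auditory", "visual25", "visual50"))
  tasks <- vapply(ses$trials, `[[`, character(1), "task")
  conds <- vapply(ses$trials, `[[`, character(1), "condition")
  expect_equal(sum(tasks == "PF"), 4)
  expect_equal(as.integer(table(conds[tasks == "MGS"])), rep(2L, 4))

  expect_error(simulate_session("p1", "adhd", pre[-1],
                                mgs_trials_per_condition = 1),
               "missing cell")
})

test_that("cohort simulation writes one directory per participant, deterministically", {
  pre <- results_presets()
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  idx <- simulate_cohort(d1, pre, n_adhd = 2, n_tdc = 1, seed = 42,
                         mgs_trials_per_condition = 1)
  expect_equal(nrow(idx), 3)
  expect_true(all(dir.exists(idx$dir)))
  p1 <- idx$dir[1]
  expect_true(file.exists(file.path(p1, "events.json")))
  ev <- read_session_events(file.path(p1, "events.json"))
  expect_length(ev, 4 + 4)   # 4 MGS (1 per condition) + 4 PF
  gt <- read.csv(file.path(p1, "ground_truth.csv"))
  expect_equal(nrow(gt), 8)

  simulate_cohort(d2, pre, n_adhd = 2, n_tdc = 1, seed = 42,
                  mgs_trials_per_condition = 1)
  f1 <- list.files(p1, pattern = "tsv$")[1]
  expect_identical(readLines(file.path(d1, "adhd001", f1)),
                   readLines(file.path(d2, "adhd001", f1)))
})
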