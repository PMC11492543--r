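test_that("elementwise transforms match their definitions and guard domains", {
  expect_equal(transform_values(0, "log1p"), 0)
  expect_equal(transform_values(c(0, 1, 9), "sqrt"), c(0, 1, 3))
  expect_equal(transform_values(0.81, "sqrt"), 0.9)
  expect_equal(transform_values(exp(2), "log"), 2)
  expect_error(transform_values(c(1, 0), "log", measure = "latency_ms"),
               "latency_ms")
  expect_error(transform_values(-1, "log1p"), "non-negative")
  expect_error(transform_values(-1, "sqrt"), "non-negative")
})

test_that("rank-based inverse normal uses Blom offsets and handles ties", {
  # symmetric 5-value set: antisymmetric output summing to zero, and the
  # quantile-function oracle reproduces each value
  v <- c(-2, -1, 0, 1, 2)
  z <- transform_values(v, "rank_inverse_normal")
  expect_equal(sum(z), 0, tolerance = 1e-12)
  expect_equal(z, -rev(z))
  expect_equal(z, qnorm(((1:5) - 3 / 8) / (5 + 1 / 4)))

  # ties share mean rank
  z2 <- transform_values(c(1, 1, 5), "rank_inverse_normal")
  expect_equal(z2[1], z2[2])
  expect_equal(z2[1], qnorm((1.5 - 3 / 8) / (3 + 1 / 4)))

  # strict monotonicity preserves order
  set.seed(1)
  x <- rexp(50)
  expect_equal(order(transform_values(x, "rank_inverse_normal")), order(x))
})

make_table <- function(n_per_group = 8, conds = c("none", "auditory"),
                       n_trials = 6, group_eff = 0, cond_eff = 0,
                       participant_sd = 0.5, sigma = 1, base = 5) {
  rows <- list()
  for (g in c("adhd", "tdc")) {
    for (p in seq_len(n_per_group)) {
      id <- paste0(g, p)
      b <- rnorm(1, 0, participant_sd)
      for (cn in conds) {
        mu <- base + b + (g == "adhd") * group_eff +
          (cn != "none") * cond_eff
        rows[[length(rows) + 1L]] <- data.frame(
          participant = id, group = g, task = "MGS", condition = cn,
          measure = "m", trial = seq_len(n_trials),
          value = rnorm(n_trials, mu, sigma))
      }
    }
  }
  do.call(rbind, rows)
}

test_that("condition summaries aggregate trials to participants with t CIs", {
  tab <- data.frame(participant = rep(c("a", "b"), each = 2),
                    group = "adhd", task = "MGS", condition = "none",
                    measure = "gain", trial = c(1, 2, 1, 2),
                    value = c(0.7, 0.9, 1.0, 1.0))
  s <- condition_summary(tab)
  expect_equal(nrow(s), 1)
  expect_equal(s$mean, 0.9)        # participant means 0.8 and 1.0
  expect_equal(s$n, 2)
  half <- qt(0.975, 1) * sd(c(0.8, 1.0)) / sqrt(2)
  expect_equal(s$ci_hi - s$mean, half)

  # identical values: zero SD, zero CI width
  tab2 <- transform(tab, value = 0.5)
  s2 <- condition_summary(tab2)
  expect_equal(s2$sd, 0)
  expect_equal(s2$ci_hi, s2$ci_lo)

  # invariant to row order and trial relabeling
  tab3 <- tab[sample(nrow(tab)), ]
  tab3$trial <- rev(tab3$trial)
  expect_equal(condition_summary(tab3)$mean, s$mean)
})

test_that("model report degrees of freedom match the design", {
  set.seed(10)
  tab <- make_table(conds = c("none", "visual25", "visual50"))
  fit <- fit_group_condition_model(tab, "m",
                                   conditions = c("none", "visual25",
                                                  "visual50"),
                                   transform = "identity", pairwise = TRUE)
  an <- fit$anova
  expect_equal(an$NumDF[an$effect == "group"], 1)
  expect_equal(an$NumDF[an$effect == "condition"], 2)
  expect_equal(an$NumDF[an$effect == "condition:group"], 2)
  expect_false(fit$singular)
  # 6 cells -> 15 Bonferroni-adjusted pairwise contrasts
  expect_equal(nrow(fit$emmeans), 15)
  expect_error(fit_group_condition_model(tab[tab$group == "adhd", ], "m",
                                         transform = "identity"),
               "2 participants")
})

test_that("a planted group effect is detected and noise correctly not flagged", {
  set.seed(2024)
  hits_group <- 0; false_noise <- 0
  n_cohorts <- 60
  for (i in seq_len(n_cohorts)) {
    tab <- make_table(n_per_group = 10, group_eff = 0.8, cond_eff = 0,
                      participant_sd = 0.4, sigma = 1, n_trials = 8)
    an <- fit_group_condition_model(tab, "m", transform = "identity",
                                    pairwise = FALSE)$anova
    if (an$p[an$effect == "group"] < 0.05) hits_group <- hits_group + 1
    if (an$p[an$effect == "condition"] < 0.05) false_noise <- false_noise + 1
  }
  expect_gte(hits_group / n_cohorts, 0.9)
  expect_lte(false_noise / n_cohorts, 0.15)
})

test_that("permuting group labels destroys a planted group effect", {
  set.seed(99)
  tab <- make_table(n_per_group = 10, group_eff = 1.2, participant_sd = 0.3)
  p_true <- fit_group_condition_model(tab, "m", transform = "identity",
                                      pairwise = FALSE)$anova
  p_true <- p_true$p[p_true$effect == "group"]
  expect_lt(p_true, 0.05)
  p_perm <- vapply(1:11, function(i) {
    ids <- unique(tab$participant)
    relab <- setNames(sample(rep(c("adhd", "tdc"), length.out = length(ids))),
                      ids)
    tab$group <- relab[tab$participant]
    an <- fit_group_condition_model(tab, "m", transform = "identity",
                                    pairwise = FALSE)$anova
    an$p[an$effect == "group"]
  }, numeric(1))
  expect_gt(median(p_perm), 0.05)
})

test_that("model reports can be written to CSV", {
  set.seed(4)
  tab <- make_table()
  fit <- fit_group_condition_model(tab, "m", transform = "identity",
                                   pairwise = FALSE)
  path <- withr::local_tempfile(fileext = ".csv")
  write_model_report_csv(list(m.auditory = fit), path)
  out <- read.csv(path)
  expect_true(all(c("effect", "F", "p", "model", "singular") %in% names(out)))
  expect_equal(nrow(out), 3)
})
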