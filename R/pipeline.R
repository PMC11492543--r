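#' Simulate and measure one MGS group-by-condition cell
#'
#' The parameter-recovery harness: simulates `n_participants` participants by
#' `n_trials` MGS trials under one preset, screens each trial against the
#' data-loss exclusion rule over the flash-to-reappearance window, runs the
#' event pipeline on every kept trial and returns trial-level measures next
#' to the planted ground truth.
#'
#' @param preset a [sim_preset()].
#' @param n_participants,n_trials cell size (study values 52 x 30).
#' @param geometry a [screen_geometry()].
#' @param params a [detector_params()].
#' @param rule an [exclusion_rule()]; defaults to >20% both-eye loss over
#'   the flash-to-reappearance window.
#' @return data frame with one row per simulated trial: pipeline measures
#'   (`anticipatory_count`, `correct`, `latency_ms`, `gain`), planted truth
#'   (`true_*`), per-eye losses and a `kept` flag (measures are `NA` for
#'   excluded trials).
#' @export
measure_mgs_cell <- function(preset, n_participants, n_trials = 30,
                             geometry = screen_geometry(),
                             params = detector_params(),
                             rule = exclusion_rule(scope = "flash_to_reappear")) {
  rows <- vector("list", n_participants * n_trials)
  k <- 0L
  for (p in seq_len(n_participants)) {
    for (i in seq_len(n_trials)) {
      tr <- simulate_mgs_trial(preset, geometry = geometry,
                               participant = sprintf("p%03d", p),
                               trial_index = i)
      win <- loss_window(tr$recording, rule, tr$timeline)
      ll <- data_loss_fraction(tr$recording, "left", win)
      lr <- data_loss_fraction(tr$recording, "right", win)
      kept <- nrow(apply_exclusion(
        data.frame(loss_left = ll, loss_right = lr), rule)$kept) == 1L
      m <- if (kept) measure_mgs_trial(tr$recording, tr$timeline, params)
           else data.frame(anticipatory_count = NA_integer_, correct = NA,
                           latency_ms = NA_real_, gain = NA_real_,
                           failed_criteria = NA_character_)
      k <- k + 1L
      rows[[k]] <- cbind(
        data.frame(participant = sprintf("p%03d", p), trial = i,
                   kept = kept, loss_left = ll, loss_right = lr),
        m,
        data.frame(true_anticipatory = tr$truth$anticipatory_emitted,
                   true_correct = tr$truth$correct,
                   true_latency_ms = tr$truth$latency_ms,
                   true_gain = tr$truth$gain,
                   true_gross_loss = tr$truth$gross_loss))
    }
  }
  do.call(rbind, rows)
}

#' Simulate and measure a set of PF trials under one preset
#'
#' @param preset a [sim_preset()].
#' @param n_trials number of 60 s PF trials (one per participant in the
#'   study design, so 52 for the ADHD group).
#' @param geometry a [screen_geometry()].
#' @param params a [detector_params()].
#' @param rule an [exclusion_rule()] with whole-trial scope.
#' @param duration_s trial duration.
#' @return data frame with one row per trial: `fixation_ratio`,
#'   `intrusive_saccades`, planted truth and the `kept` flag.
#' @export
measure_pf_cell <- function(preset, n_trials = 52,
                            geometry = screen_geometry(),
                            params = detector_params(),
                            rule = exclusion_rule(scope = "trial"),
                            duration_s = 60) {
  rows <- vector("list", n_trials)
  for (i in seq_len(n_trials)) {
    tr <- simulate_pf_trial(preset, geometry = geometry,
                            participant = sprintf("p%03d", i),
                            trial_index = 1L, duration_s = duration_s)
    ll <- data_loss_fraction(tr$recording, "left")
    lr <- data_loss_fraction(tr$recording, "right")
    kept <- nrow(apply_exclusion(
      data.frame(loss_left = ll, loss_right = lr), rule)$kept) == 1L
    m <- if (kept) measure_pf_trial(tr$recording, params)
         else data.frame(fixation_ratio = NA_real_,
                         intrusive_saccades = NA_integer_)
    rows[[i]] <- cbind(
      data.frame(participant = sprintf("p%03d", i), kept = kept,
                 loss_left = ll, loss_right = lr),
      m,
      data.frame(true_intrusive = tr$truth$intrusive_emitted,
                 true_oncenter_fraction = tr$truth$oncenter_fraction,
                 true_gross_loss = tr$truth$gross_loss))
  }
  do.call(rbind, rows)
}

#' Long-format measure rows for one simulated session
#'
#' Screens every trial with the task-appropriate exclusion rule (whole-trial
#' loss for PF, flash-to-reappearance loss for MGS), measures the kept
#' trials, and returns the long measure table together with an exclusion log
#' that reconciles exactly (`input trials = kept + excluded`).
#'
#' @param session result of [simulate_session()].
#' @param params a [detector_params()].
#' @param max_loss_fraction exclusion threshold.
#' @return list with `table` (long measure rows), `exclusions` (one row per
#'   excluded trial with both losses and reason) and `n_trials`.
#' @export
session_measures <- function(session, params = detector_params(),
                             max_loss_fraction = 0.20) {
  pf_rule <- exclusion_rule(max_loss_fraction, scope = "trial")
  mgs_rule <- exclusion_rule(max_loss_fraction, scope = "flash_to_reappear")
  tab <- list(); excl <- list()
  for (j in seq_along(session$trials)) {
    tr <- session$trials[[j]]
    rule <- if (tr$task == "MGS") mgs_rule else pf_rule
    win <- loss_window(tr$recording, rule,
                       if (tr$task == "MGS") tr$timeline else NULL)
    ll <- data_loss_fraction(tr$recording, "left", win)
    lr <- data_loss_fraction(tr$recording, "right", win)
    ex <- apply_exclusion(data.frame(loss_left = ll, loss_right = lr), rule)
    base <- data.frame(participant = session$participant,
                       group = session$group, task = tr$task,
                       condition = tr$condition, trial = j)
    if (nrow(ex$excluded)) {
      excl[[length(excl) + 1L]] <- cbind(base, ex$excluded)
      next
    }
    if (tr$task == "MGS") {
      m <- measure_mgs_trial(tr$recording, tr$timeline, params)
      vals <- c(anticipatory_count = m$anticipatory_count,
                correct = as.numeric(m$correct),
                latency_ms = m$latency_ms, gain = m$gain)
    } else {
      m <- measure_pf_trial(tr$recording, params)
      vals <- c(fixation_ratio = m$fixation_ratio,
                intrusive_saccades = m$intrusive_saccades)
    }
    vals <- vals[!is.na(vals)]
    if (length(vals))
      tab[[length(tab) + 1L]] <-
        cbind(base[rep(1, length(vals)), ],
              data.frame(measure = names(vals), value = unname(vals)))
  }
  table <- if (length(tab)) do.call(rbind, tab) else NULL
  if (!is.null(table)) rownames(table) <- NULL
  list(table = table,
       exclusions = if (length(excl)) do.call(rbind, excl) else NULL,
       n_trials = length(session$trials))
}

#' End-to-end run configuration
#'
#' Bundles every tunable of the pipeline into one serializable object that
#' is archived (as YAML) beside the run's outputs.
#'
#' @param n_adhd,n_tdc simulated group sizes.
#' @param mgs_trials_per_condition MGS trials per condition per participant.
#' @param seed integer seed driving all randomness of the run.
#' @param out_dir output directory.
#' @param geometry a [screen_geometry()].
#' @param detector a [detector_params()].
#' @param max_loss_fraction trial-exclusion threshold.
#' @param presets preset list (defaults to [results_presets()]).
#' @return An object of class `run_config`.
#' @export
run_config <- function(n_adhd = 5, n_tdc = 5, mgs_trials_per_condition = 30,
                       seed = 1, out_dir = tempfile("noisegaze_run"),
                       geometry = screen_geometry(),
                       detector = detector_params(),
                       max_loss_fraction = 0.20,
                       presets = results_presets()) {
  structure(list(n_adhd = n_adhd, n_tdc = n_tdc,
                 mgs_trials_per_condition = mgs_trials_per_condition,
                 seed = seed, out_dir = out_dir, geometry = geometry,
                 detector = detector, max_loss_fraction = max_loss_fraction,
                 presets = presets),
            class = "run_config")
}

#' Run the full pipeline: simulate, detect, screen, measure, summarize
#'
#' Simulates a cohort under the configured presets, measures every kept
#' trial, writes the long measure table, the exclusion log (which reconciles
#' exactly against the simulated trial count), per-cell summaries, mixed-
#' model reports for the auditory and visual condition subsets of each
#' measure, and the archived configuration. Deterministic under
#' `config$seed`.
#'
#' @param config a [run_config()].
#' @param fit_models whether to fit the mixed-model stage (needs at least
#'   2 participants per group).
#' @return list with `measures`, `exclusions`, `summary`, `models` and
#'   `out_dir`, invisibly.
#' @export
run_end_to_end <- function(config = run_config(), fit_models = TRUE) {
  set.seed(config$seed)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  ids <- c(sprintf("adhd%03d", seq_len(config$n_adhd)),
           sprintf("tdc%03d", seq_len(config$n_tdc)))
  groups <- rep(c("adhd", "tdc"), c(config$n_adhd, config$n_tdc))
  tabs <- list(); excls <- list(); total_trials <- 0L
  for (p in seq_along(ids)) {
    ses <- simulate_session(ids[p], groups[p], config$presets,
                            config$mgs_trials_per_condition, config$geometry)
    sm <- session_measures(ses, config$detector, config$max_loss_fraction)
    total_trials <- total_trials + sm$n_trials
    if (!is.null(sm$table)) tabs[[length(tabs) + 1L]] <- sm$table
    if (!is.null(sm$exclusions)) excls[[length(excls) + 1L]] <- sm$exclusions
  }
  measures <- do.call(rbind, tabs)
  exclusions <- if (length(excls)) do.call(rbind, excls) else
    data.frame()
  n_excluded <- if (nrow(exclusions)) nrow(exclusions) else 0L
  n_kept_trials <- length(unique(paste(measures$participant, measures$trial)))
  message(sprintf("trials: %d simulated = %d kept + %d excluded",
                  total_trials, n_kept_trials, n_excluded))
  stopifnot(total_trials == n_kept_trials + n_excluded)

  summary <- condition_summary(measures)
  models <- list()
  if (fit_models && config$n_adhd >= 2 && config$n_tdc >= 2) {
    subsets <- list(auditory = c("none", "auditory"),
                    visual = c("none", "visual25", "visual50"))
    for (meas in setdiff(unique(measures$measure), "correct")) {
      for (sub in names(subsets)) {
        nm <- paste(meas, sub, sep = ".")
        models[[nm]] <- tryCatch(
          fit_group_condition_model(measures, meas, subsets[[sub]]),
          error = function(e) {
            message("model ", nm, " skipped: ", conditionMessage(e))
            NULL
          })
      }
    }
    models <- Filter(Negate(is.null), models)
  }

  utils::write.csv(measures, file.path(config$out_dir, "measures.csv"),
                   row.names = FALSE)
  utils::write.csv(exclusions, file.path(config$out_dir, "exclusions.csv"),
                   row.names = FALSE)
  utils::write.csv(summary, file.path(config$out_dir, "summary.csv"),
                   row.names = FALSE)
  if (length(models))
    write_model_report_csv(models, file.path(config$out_dir, "models.csv"))
  cfg <- config
  cfg$presets <- NULL
  yaml::write_yaml(lapply(unclass(cfg), function(v)
    if (inherits(v, c("screen_geometry", "detector_params"))) unclass(v) else v),
    file.path(config$out_dir, "config.yaml"))
  write_presets_yaml(config$presets,
                     file.path(config$out_dir, "presets.yaml"))
  invisible(list(measures = measures, exclusions = exclusions,
                 summary = summary, models = models,
                 out_dir = config$out_dir))
}
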