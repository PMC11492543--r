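#' Variable transformations toward normality
#'
#' The measure-specific transforms applied before model fitting:
#' `rank_inverse_normal` maps ranks `r` of `n` values (ties sharing mean
#' rank) to normal quantiles at `(r - 3/8) / (n + 1/4)` (Blom offsets);
#' `rank` uses plain mid-ranks; `log1p` is `log(x + 1)` for count measures
#' where zero is common; `log` and `sqrt` are elementwise. All transforms are
#' strictly monotone on their domains, so cell rank order is preserved.
#'
#' @param values numeric vector.
#' @param kind one of `"rank_inverse_normal"`, `"rank"`, `"log1p"`, `"log"`,
#'   `"sqrt"`, `"identity"`.
#' @param measure optional measure name used in domain-violation errors.
#' @return transformed numeric vector.
#' @export
transform_values <- function(values,
                             kind = c("rank_inverse_normal", "rank", "log1p",
                                      "log", "sqrt", "identity"),
                             measure = NULL) {
  kind <- match.arg(kind)
  lbl <- if (is.null(measure)) "values" else measure
  switch(kind,
    rank_inverse_normal = {
      ok <- !is.na(values)
      out <- rep(NA_real_, length(values))
      r <- rank(values[ok], ties.method = "average")
      out[ok] <- stats::qnorm((r - 3 / 8) / (sum(ok) + 1 / 4))
      out
    },
    rank = {
      ok <- !is.na(values)
      out <- rep(NA_real_, length(values))
      out[ok] <- rank(values[ok], ties.method = "average")
      out
    },
    log1p = {
      if (any(values < 0, na.rm = TRUE))
        stop("log1p transform needs non-negative values: ", lbl)
      log1p(values)
    },
    log = {
      if (any(values <= 0, na.rm = TRUE))
        stop("log transform needs strictly positive values: ", lbl)
      log(values)
    },
    sqrt = {
      if (any(values < 0, na.rm = TRUE))
        stop("sqrt transform needs non-negative values: ", lbl)
      sqrt(values)
    },
    identity = values
  )
}

#' Default measure-to-transform mapping
#'
#' Rank-based inverse normal for the two PF measures, `log(x + 1)` for
#' anticipatory counts (zero-inflated), `log` for latency, square root for
#' gain.
#'
#' @return named character vector: measure -> transform kind.
#' @export
default_transforms <- function() {
  c(fixation_ratio = "rank_inverse_normal",
    intrusive_saccades = "rank_inverse_normal",
    anticipatory_count = "log1p",
    latency_ms = "log",
    gain = "sqrt",
    correct = "identity")
}

#' Per-cell descriptive summaries with 95% confidence intervals
#'
#' Two-stage aggregation on the untransformed scale: trials are first
#' averaged within participant, then cells (group x condition x measure,
#' optionally by task) are summarized over participant means with a
#' t-based 95% CI, matching figure-style participant-level error bars.
#' Empty cells are simply absent; single-participant cells report an `NA` CI.
#'
#' @param table long-format measure table with columns `participant`,
#'   `group`, `task`, `condition`, `measure`, `value`.
#' @return data frame with one row per cell: `mean`, `sd`, `n`, `ci_lo`,
#'   `ci_hi`.
#' @export
condition_summary <- function(table) {
  stopifnot(all(c("participant", "group", "condition", "measure", "value")
                %in% names(table)))
  if (!"task" %in% names(table)) table$task <- NA_character_
  pm <- stats::aggregate(value ~ participant + group + task + condition + measure,
                         data = table, FUN = mean, na.rm = TRUE)
  cells <- split(pm, list(pm$group, pm$task, pm$condition, pm$measure),
                 drop = TRUE)
  rows <- lapply(cells, function(cell) {
    v <- cell$value[!is.na(cell$value)]
    n <- length(v)
    m <- mean(v)
    s <- if (n > 1) stats::sd(v) else NA_real_
    half <- if (n > 1) stats::qt(0.975, n - 1) * s / sqrt(n) else NA_real_
    data.frame(group = cell$group[1], task = cell$task[1],
               condition = cell$condition[1], measure = cell$measure[1],
               mean = m, sd = s, n = n,
               ci_lo = m - half, ci_hi = m + half)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$measure, out$group, out$condition), ]
}

#' Group-by-condition mixed-model report for one measure
#'
#' Fits the study's model contract: transformed value ~ noise condition x
#' group with a random intercept per participant, treatment coding with the
#' no-noise condition as reference, a type III ANOVA with Satterthwaite
#' degrees of freedom, and Bonferroni-adjusted pairwise contrasts of the
#' estimated marginal means. The auditory contrast (2 conditions) and the
#' visual contrast (3 conditions sharing the no-noise cell) are fit as
#' separate models by passing the matching `conditions` subset.
#'
#' @param table long-format measure table (see [condition_summary()]).
#' @param measure measure name to model.
#' @param conditions condition subset to analyze; first element is the
#'   reference level.
#' @param transform transform kind (see [transform_values()]); defaults to
#'   the measure's entry in [default_transforms()].
#' @param pairwise whether to compute Bonferroni pairwise cell contrasts.
#' @return list with `anova` (effect, F, NumDF, DenDF, p), `emmeans`
#'   (contrast table or `NULL`), `singular` flag and the fitted `model`.
#' @export
fit_group_condition_model <- function(table, measure,
                                      conditions = c("none", "auditory"),
                                      transform = NULL, pairwise = TRUE) {
  d <- table[table$measure == measure & table$condition %in% conditions, ]
  d <- d[!is.na(d$value), ]
  if (is.null(transform)) {
    tf <- default_transforms()
    transform <- if (measure %in% names(tf)) tf[[measure]] else "identity"
  }
  d$value_t <- transform_values(d$value, transform, measure)
  d$condition <- factor(d$condition, levels = conditions)
  d$group <- factor(d$group)
  d$participant <- factor(d$participant)
  if (nlevels(d$group) < 2 || any(table(d$group[!duplicated(d$participant)]) < 2))
    stop("need at least 2 participants per group to fit the model")
  m <- lmerTest::lmer(value_t ~ condition * group + (1 | participant),
                      data = d)
  singular <- lme4::isSingular(m)
  a <- stats::anova(m, type = 3)
  an <- data.frame(effect = rownames(a),
                   NumDF = a$NumDF, DenDF = a$DenDF,
                   F = a$`F value`, p = a$`Pr(>F)`)
  contrasts <- NULL
  if (pairwise) {
    em <- emmeans::emmeans(m, ~ condition * group)
    contrasts <- as.data.frame(emmeans::contrast(em, method = "pairwise",
                                                 adjust = "bonferroni"))
  }
  list(anova = an, emmeans = contrasts, singular = singular, model = m,
       transform = transform, conditions = conditions)
}

#' Write a set of model reports to CSV
#'
#' @param reports named list of results from [fit_group_condition_model()].
#' @param path output CSV path (ANOVA tables, stacked, with a `model` column).
#' @return the path, invisibly.
#' @export
write_model_report_csv <- function(reports, path) {
  rows <- lapply(names(reports), function(nm) {
    a <- reports[[nm]]$anova
    a$model <- nm
    a$singular <- reports[[nm]]$singular
    a
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
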