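.trial_columns <- c("participant_id", "instruction", "difficulty",
                    "session", "trial", "stimulus", "pre_rating",
                    "type1_response", "post_rating", "rt_pre", "rt_answer",
                    "rt_post")

#' Read and validate a trial-level CSV
#'
#' The schema is one row per trial with columns (exactly):
#' `participant_id, instruction, difficulty, session, trial, stimulus,
#' pre_rating, type1_response, post_rating, rt_pre, rt_answer, rt_post`.
#' Empty fields encode missing responses; a missing response time makes
#' the corresponding response count as missing downstream. Enumerations
#' and rating ranges are enforced with row-numbered diagnostics. A derived
#' logical `correct` column (response equals stimulus match status) is
#' added.
#'
#' @param path path to a CSV file.
#' @return a validated trial data frame.
#' @export
read_trials <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"))
  miss <- setdiff(.trial_columns, names(df))
  if (length(miss) > 0) {
    stop("trial CSV is missing column(s): ", paste(miss, collapse = ", "))
  }
  df <- df[.trial_columns]
  validate_trials(df)
}

#' @rdname read_trials
#' @param trials a trial data frame.
#' @export
validate_trials <- function(trials) {
  check_enum <- function(col, levels) {
    v <- trials[[col]]
    bad <- which(!is.na(v) & !(v %in% levels))
    if (length(bad) > 0) {
      stop(sprintf("column '%s': invalid value '%s' at row %d (allowed: %s)",
                   col, v[bad[1]], bad[1], paste(levels, collapse = ", ")))
    }
  }
  check_range <- function(col, lo, hi) {
    v <- suppressWarnings(as.numeric(trials[[col]]))
    bad <- which(!is.na(trials[[col]]) &
                 (is.na(v) | v < lo | v > hi | v != round(v)))
    if (length(bad) > 0) {
      stop(sprintf("column '%s': value '%s' at row %d outside %d..%d",
                   col, trials[[col]][bad[1]], bad[1], lo, hi))
    }
    as.integer(v)
  }
  check_enum("instruction", c("bet", "confidence"))
  check_enum("difficulty", c("easy", "hard"))
  check_enum("stimulus", c("match", "nonmatch"))
  check_enum("type1_response", c("match", "nonmatch"))
  trials$pre_rating <- check_range("pre_rating", 1, 2)
  trials$post_rating <- check_range("post_rating", 1, 5)
  trials$session <- check_range("session", 1, 1000)
  trials$trial <- check_range("trial", 1, 10000)
  for (col in c("rt_pre", "rt_answer", "rt_post")) {
    v <- suppressWarnings(as.numeric(trials[[col]]))
    bad <- which(!is.na(trials[[col]]) & (is.na(v) | v < 0))
    if (length(bad) > 0) {
      stop(sprintf("column '%s': invalid response time '%s' at row %d",
                   col, trials[[col]][bad[1]], bad[1]))
    }
    trials[[col]] <- v
  }
  trials$participant_id <- as.character(trials$participant_id)
  trials$correct <- ifelse(is.na(trials$type1_response), NA,
                           trials$type1_response == trials$stimulus)
  trials
}

#' Write a trial table to CSV
#'
#' Writes the 12 schema columns (dropping derived columns); missing values
#' become empty fields. `write_trials` then `read_trials` round-trips.
#'
#' @param trials a trial data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  miss <- setdiff(.trial_columns, names(trials))
  if (length(miss) > 0) {
    stop("trials is missing column(s): ", paste(miss, collapse = ", "))
  }
  utils::write.csv(trials[.trial_columns], path, row.names = FALSE,
                   na = "")
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Orchestrates the complete analysis on a trial table (read from
#' `trials`, or simulated when a `sim_config` is given): exclusions,
#' participant summaries, two-way mixed ANOVAs (accuracy, d', total score,
#' mean pre- and post-rating), the paired t test of post-rating by
#' pre-rating level (with the JZS Bayes factor), Levene's test on the mean
#' pre-rating per difficulty with Holm correction, and hierarchical
#' Bayesian M-ratio fits for the requested phases with effect summaries
#' under the HDI/pd decision rule.
#'
#' When `out_dir` is given, writes `exclusion_report.csv`,
#' `participant_summary.csv`, `behavioral_tests.csv`, `effect_summaries.csv`
#' and `.json`, and `manifest.json` (resolved configuration, seed and
#' package version; no timestamps, so identical runs produce identical
#' bundles).
#'
#' @param trials a trial data frame, a path to a trial CSV, or a
#'   `sim_config` (the cohort is then simulated first).
#' @param out_dir optional output directory (created if needed).
#' @param phases which rating phases to model: subset of
#'   `c("pre", "post")`.
#' @param chains,iterations,burnin MCMC settings for
#'   [fit_hierarchical_mratio].
#' @param seed integer seed controlling the hierarchical fits (and the
#'   simulation if `trials` is a config without its own seed).
#' @param alpha significance level recorded for the frequentist tests.
#' @param hdi_mass,pd_threshold decision-rule settings for
#'   [summarize_effects].
#' @return (invisibly) a list with elements `trials`, `exclusions`,
#'   `summary`, `anova`, `paired_t`, `levene`, `fits`, `effects`,
#'   `manifest`.
#' @export
run_pipeline <- function(trials, out_dir = NULL,
                         phases = c("pre", "post"), chains = 3,
                         iterations = 10000, burnin = 1000, seed,
                         alpha = 0.05, hdi_mass = 0.95,
                         pd_threshold = 0.95) {
  if (missing(seed)) stop("seed is required")
  phases <- match.arg(phases, several.ok = TRUE)
  input_desc <- "data.frame"
  if (inherits(trials, "sim_config")) {
    input_desc <- "simulated"
    trials <- simulate_task_data(trials)$trials
  } else if (is.character(trials)) {
    input_desc <- trials
    trials <- read_trials(trials)
  } else {
    trials <- validate_trials(trials)
  }

  excl <- apply_exclusions(trials)
  kept <- excl$trials
  summ <- summarize_participants(kept)

  anova_vars <- c(accuracy = "accuracy", d_prime = "d_prime",
                  total_score = "total_score",
                  pre_rating = "mean_pre_rating",
                  post_rating = "mean_post_rating")
  anova_rows <- lapply(names(anova_vars), function(v) {
    d <- data.frame(participant_id = summ$participant_id,
                    instruction = summ$instruction,
                    difficulty = summ$difficulty,
                    value = summ[[anova_vars[[v]]]])
    res <- mixed_anova(d)
    cbind(variable = v, res)
  })
  anova_tab <- do.call(rbind, anova_rows)

  # post-rating averaged within each pre-rating level, per participant
  pt <- NULL
  by_level <- stats::aggregate(post_rating ~ participant_id + pre_rating,
                               data = kept, FUN = mean)
  wide <- stats::reshape(by_level, idvar = "participant_id",
                         timevar = "pre_rating", direction = "wide")
  both <- stats::complete.cases(wide)
  if (sum(both) >= 3) {
    pt <- paired_t_with_bf(wide$post_rating.1[both],
                           wide$post_rating.2[both])
    pt <- cbind(test = "post_rating_by_pre_level_low_minus_high", pt)
  }

  lev <- levene_holm(data.frame(participant_id = summ$participant_id,
                                instruction = summ$instruction,
                                difficulty = summ$difficulty,
                                value = summ$mean_pre_rating))

  fits <- list()
  effects <- list()
  for (ph in phases) {
    cells <- prepare_mratio_cells(kept, ph)
    fit <- fit_hierarchical_mratio(cells, chains = chains,
                                   iterations = iterations,
                                   burnin = burnin,
                                   seed = seed + match(ph, c("pre", "post")))
    eff <- summarize_effects(fit, hdi_mass = hdi_mass,
                             pd_threshold = pd_threshold)
    fits[[ph]] <- fit
    effects[[ph]] <- cbind(phase = ph, eff)
  }
  effects_tab <- do.call(rbind, effects)
  rownames(effects_tab) <- NULL

  manifest <- list(
    package = "mratio",
    version = as.character(utils::packageVersion("mratio")),
    input = input_desc, seed = seed, phases = phases,
    mcmc = list(chains = chains, iterations = iterations, burnin = burnin),
    alpha = alpha, hdi_mass = hdi_mass, pd_threshold = pd_threshold,
    n_participants_in = length(unique(trials$participant_id)),
    n_participants_kept = length(unique(kept$participant_id)),
    decisions = c(
      "edge correction: Hautus 1/(2K) for point estimates, raw counts in likelihoods",
      "fixed-response exclusion rule applied to the pre-rating",
      "confidence-group score emulation: high belief -> high-risk bet",
      "Levene centering: group mean",
      "Holm correction applied to the Levene difficulty pair only"))

  result <- list(trials = trials, exclusions = excl$report, summary = summ,
                 anova = anova_tab, paired_t = pt, levene = lev,
                 fits = fits, effects = effects_tab, manifest = manifest)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(excl$report,
                     file.path(out_dir, "exclusion_report.csv"),
                     row.names = FALSE)
    utils::write.csv(summ, file.path(out_dir, "participant_summary.csv"),
                     row.names = FALSE)
    tests <- anova_tab
    tests$test <- paste("mixed_anova", tests$variable, tests$effect,
                        sep = ":")
    behav <- data.frame(test = tests$test, statistic = tests$statistic,
                        df1 = tests$df1, df2 = tests$df2,
                        p_value = tests$p_value, effect_size = tests$ges,
                        bf10 = NA_real_, adjusted_p = NA_real_)
    if (!is.null(pt)) {
      behav <- rbind(behav, data.frame(
        test = pt$test, statistic = pt$statistic, df1 = pt$df, df2 = NA,
        p_value = pt$p_value, effect_size = pt$cohens_d, bf10 = pt$bf10,
        adjusted_p = NA_real_))
    }
    behav <- rbind(behav, data.frame(
      test = paste0("levene_pre_rating:", lev$difficulty),
      statistic = lev$statistic, df1 = lev$df1, df2 = lev$df2,
      p_value = lev$p_value, effect_size = NA_real_, bf10 = NA_real_,
      adjusted_p = lev$adjusted_p))
    utils::write.csv(behav, file.path(out_dir, "behavioral_tests.csv"),
                     row.names = FALSE)
    utils::write.csv(effects_tab,
                     file.path(out_dir, "effect_summaries.csv"),
                     row.names = FALSE)
    jsonlite::write_json(effects_tab,
                         file.path(out_dir, "effect_summaries.json"),
                         dataframe = "rows", digits = NA, pretty = TRUE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(result)
}
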