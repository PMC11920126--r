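#' Apply trial- and participant-level exclusion rules
#'
#' Trials are dropped when any of the three responses (pre-rating, match
#' answer, post-rating) is missing or has a response time below 100 ms (a
#' missing RT counts as a missing response). A participant is then dropped
#' entirely when, within either difficulty condition, (a) all of their
#' valid trials share one identical pre-rating value, or (b) they have
#' fewer than `min_valid` (default 18) valid trials.
#'
#' The operation is idempotent: applying it to its own output changes
#' nothing.
#'
#' @param trials a trial data frame ([read_trials] schema).
#' @param min_valid minimum valid trials required per difficulty.
#' @param rt_floor fastest plausible response time in milliseconds.
#' @return a list with `trials` (valid trials of retained participants) and
#'   `report` (one row per participant: valid-trial counts, the rules that
#'   fired, and whether the participant was excluded).
#' @export
apply_exclusions <- function(trials, min_valid = 18, rt_floor = 100) {
  if (nrow(trials) == 0) {
    return(list(trials = trials,
                report = data.frame(participant_id = character(0))))
  }
  valid <- !is.na(trials$pre_rating) & !is.na(trials$type1_response) &
    !is.na(trials$post_rating) &
    !is.na(trials$rt_pre) & trials$rt_pre >= rt_floor &
    !is.na(trials$rt_answer) & trials$rt_answer >= rt_floor &
    !is.na(trials$rt_post) & trials$rt_post >= rt_floor
  kept_trials <- trials[valid, , drop = FALSE]

  ids <- unique(trials$participant_id)
  rep_rows <- lapply(ids, function(id) {
    sub_all <- trials[trials$participant_id == id, , drop = FALSE]
    sub <- kept_trials[kept_trials$participant_id == id, , drop = FALSE]
    counts <- c(easy = sum(sub$difficulty == "easy"),
                hard = sum(sub$difficulty == "hard"))
    fixed <- vapply(c("easy", "hard"), function(d) {
      v <- sub$pre_rating[sub$difficulty == d]
      length(v) > 0 && length(unique(v)) == 1
    }, logical(1))
    too_few <- counts < min_valid
    reasons <- c(
      if (any(too_few)) paste0("fewer than ", min_valid, " valid trials (",
                               paste(names(counts)[too_few],
                                     collapse = ", "), ")"),
      if (any(fixed)) paste0("identical pre-rating across all valid trials (",
                             paste(names(fixed)[fixed], collapse = ", "),
                             ")"))
    data.frame(participant_id = id,
               instruction = sub_all$instruction[1],
               n_trials = nrow(sub_all),
               n_excluded_trials = nrow(sub_all) - nrow(sub),
               n_valid_easy = unname(counts["easy"]),
               n_valid_hard = unname(counts["hard"]),
               excluded = any(too_few) || any(fixed),
               reason = if (length(reasons)) paste(reasons,
                                                   collapse = "; ") else "",
               stringsAsFactors = FALSE)
  })
  report <- do.call(rbind, rep_rows)
  keep_ids <- report$participant_id[!report$excluded]
  out <- kept_trials[kept_trials$participant_id %in% keep_ids, ,
                     drop = FALSE]
  rownames(out) <- NULL
  list(trials = out, report = report)
}

#' Trial score under the betting rule
#'
#' High-risk bets earn 2 points when correct and lose 1 when incorrect;
#' low-risk bets earn 1 point when correct and nothing when incorrect. For
#' the confidence group the score is emulated by mapping the high belief
#' level to the high-risk bet.
#'
#' @param pre_rating integer vector, 1 = low / 2 = high.
#' @param correct logical vector.
#' @return integer vector of points.
#' @examples
#' compute_trial_score(c(2, 2, 1, 1), c(TRUE, FALSE, TRUE, FALSE))
#' @export
compute_trial_score <- function(pre_rating, correct) {
  if (length(pre_rating) != length(correct)) {
    stop("pre_rating and correct must have equal length")
  }
  if (anyNA(pre_rating) || anyNA(correct)) {
    stop("pre_rating and correct must not be missing; apply exclusions ",
         "first")
  }
  if (!all(pre_rating %in% c(1, 2))) stop("pre_rating must be 1 (low) or ",
                                          "2 (high)")
  high <- pre_rating == 2
  as.integer(ifelse(high, ifelse(correct, 2L, -1L),
                    ifelse(correct, 1L, 0L)))
}

#' Participant-level behavioral summaries
#'
#' One row per participant and difficulty: number of valid trials,
#' accuracy, type-1 d' (edge-corrected, via [compute_type1_sdt] on the
#' stimulus x response margins), total betting score, and mean pre- and
#' post-ratings. Exclusions are assumed to have been applied.
#'
#' @param trials a trial data frame of valid trials.
#' @return a data frame of class `participant_summary`.
#' @export
summarize_participants <- function(trials) {
  key <- interaction(trials$participant_id, trials$difficulty, drop = TRUE)
  rows <- lapply(split(trials, key), function(g) {
    correct <- g$type1_response == g$stimulus
    arr <- array(0, dim = c(2, 2, 2))
    si <- ifelse(g$stimulus == "match", 2L, 1L)
    ri <- ifelse(g$type1_response == "match", 2L, 1L)
    for (i in seq_along(si)) arr[si[i], ri[i], 1] <- arr[si[i], ri[i], 1] + 1
    t1 <- compute_type1_sdt(rating_counts(arr), correction = "hautus")
    data.frame(participant_id = g$participant_id[1],
               instruction = g$instruction[1],
               difficulty = g$difficulty[1],
               n_valid_trials = nrow(g),
               accuracy = mean(correct),
               d_prime = t1$d_prime,
               criterion = t1$criterion,
               total_score = sum(compute_trial_score(g$pre_rating, correct)),
               mean_pre_rating = mean(g$pre_rating),
               mean_post_rating = mean(g$post_rating),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$participant_id, out$difficulty), ]
}

#' Two-way mixed ANOVA with generalized eta squared
#'
#' Classical mixed-design decomposition for one between-participant factor
#' (instruction) and one within-participant factor (difficulty): the
#' instruction effect is tested against the between-participant error and
#' the difficulty and interaction effects against the participant x
#' difficulty error (fit via `stats::aov` with an `Error(participant)`
#' stratum). Generalized eta squared follows the Olejnik-Algina formula
#' with all participant-variance sums of squares in the denominator:
#' `SS_effect / (SS_effect + SS_between_error + SS_within_error)`.
#'
#' @param data a data frame with columns `participant_id`, `instruction`,
#'   `difficulty`, `value` (one value per participant x difficulty).
#' @return a data frame with one row per effect (`instruction`,
#'   `difficulty`, `interaction`): `statistic` (F), `df1`, `df2`,
#'   `p_value`, `ges`.
#' @export
mixed_anova <- function(data) {
  req <- c("participant_id", "instruction", "difficulty", "value")
  if (!all(req %in% names(data))) {
    stop("data must have columns ", paste(req, collapse = ", "))
  }
  tab <- table(data$participant_id, data$difficulty)
  bad <- rownames(tab)[rowSums(tab == 1) != ncol(tab)]
  if (length(bad) > 0) {
    stop("unbalanced within-participant design: participant(s) ",
         paste(bad, collapse = ", "), " lack one value per difficulty")
  }
  if (min(table(unique(data[c("participant_id",
                              "instruction")])$instruction)) < 2) {
    stop("need at least 2 participants per instruction group")
  }
  d <- data.frame(id = factor(data$participant_id),
                  instruction = factor(data$instruction),
                  difficulty = factor(data$difficulty),
                  value = data$value)
  fit <- stats::aov(value ~ instruction * difficulty + Error(id), data = d)
  s_between <- summary(fit)[["Error: id"]][[1]]
  s_within <- summary(fit)[["Error: Within"]][[1]]
  get_row <- function(s, name) {
    i <- match(name, trimws(rownames(s)))
    c(ss = s[i, "Sum Sq"], df = s[i, "Df"], f = s[i, "F value"],
      p = s[i, "Pr(>F)"])
  }
  inst <- get_row(s_between, "instruction")
  diff_ <- get_row(s_within, "difficulty")
  inter <- get_row(s_within, "instruction:difficulty")
  err_b <- get_row(s_between, "Residuals")
  err_w <- get_row(s_within, "Residuals")
  ges <- function(ss) {
    denom <- ss + err_b[["ss"]] + err_w[["ss"]]
    if (denom == 0) 0 else ss / denom
  }
  out <- data.frame(
    effect = c("instruction", "difficulty", "interaction"),
    statistic = c(inst[["f"]], diff_[["f"]], inter[["f"]]),
    df1 = c(inst[["df"]], diff_[["df"]], inter[["df"]]),
    df2 = c(err_b[["df"]], err_w[["df"]], err_w[["df"]]),
    p_value = c(inst[["p"]], diff_[["p"]], inter[["p"]]),
    ges = c(ges(inst[["ss"]]), ges(diff_[["ss"]]), ges(inter[["ss"]])),
    stringsAsFactors = FALSE)
  # degenerate inputs (zero effect variance) give 0/0 in aov; report F = 0
  ss_scale <- sum(d$value^2) + 1e-300
  zero_ss <- c(inst[["ss"]], diff_[["ss"]], inter[["ss"]]) <
    1e-12 * ss_scale
  out$statistic[zero_ss] <- 0
  out$p_value[zero_ss] <- 1
  out$ges[zero_ss] <- 0
  out
}

#' Jeffreys-Zellner-Siow Bayes factor for a one-sample / paired t statistic
#'
#' Default Bayes factor BF10 for the paired t test, with a Cauchy prior of
#' scale `rscale` on the standardized effect size, computed by
#' one-dimensional numerical integration of the JZS marginal likelihood
#' (with the integrand evaluated on the log scale for stability).
#'
#' @param t observed t statistic.
#' @param n number of pairs.
#' @param rscale Cauchy prior scale; default `sqrt(2)/2`.
#' @return BF10 (evidence for a non-zero effect over the point null).
#' @export
bf10_jzs <- function(t, n, rscale = sqrt(2) / 2) {
  stopifnot(n >= 2, is.finite(t))
  nu <- n - 1
  log_null <- -(nu + 1) / 2 * log1p(t^2 / nu)
  log_f <- function(g) {
    -0.5 * log1p(n * g) -
      (nu + 1) / 2 * log1p(t^2 / ((1 + n * g) * nu)) +
      0.5 * log(rscale^2 / (2 * pi)) - 1.5 * log(g) - rscale^2 / (2 * g)
  }
  # locate the integrand peak to rescale before quadrature
  opt <- stats::optimize(function(lg) log_f(exp(lg)) + lg,
                         interval = c(-15, 15), maximum = TRUE)
  m <- opt$objective
  h <- function(lg) exp(log_f(exp(lg)) + lg - m)  # integrand in log-g
  int <- stats::integrate(h, -60, 60, rel.tol = 1e-10,
                          subdivisions = 500L)$value
  exp(m + log(int) - log_null)
}

#' Paired t test with effect size and JZS Bayes factor
#'
#' Paired t statistic with `n - 1` degrees of freedom, Cohen's d for paired
#' data (`mean(diff) / sd(diff)`), and the default-prior Bayes factor BF10
#' from [bf10_jzs].
#'
#' @param x,y paired numeric vectors (e.g. per-participant mean post-rating
#'   at the low and high pre-rating level).
#' @param rscale Cauchy prior scale for the Bayes factor.
#' @return a one-row data frame: `statistic` (t), `df`, `p_value`,
#'   `cohens_d`, `bf10`.
#' @export
paired_t_with_bf <- function(x, y, rscale = sqrt(2) / 2) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 pairs")
  diffs <- x - y
  if (stats::sd(diffs) == 0) {
    stop("zero-variance differences: paired t test undefined")
  }
  tt <- stats::t.test(x, y, paired = TRUE)
  data.frame(statistic = unname(tt$statistic), df = unname(tt$parameter),
             p_value = tt$p.value,
             cohens_d = mean(diffs) / stats::sd(diffs),
             bf10 = bf10_jzs(unname(tt$statistic), length(x), rscale),
             stringsAsFactors = FALSE)
}

#' Levene's test per difficulty with Holm correction
#'
#' Tests whether the between-participant variance of a participant-level
#' value (typically the mean pre-rating) differs across instruction groups,
#' separately within each difficulty condition, using Levene's original
#' test (absolute deviations from the group mean; via
#' `car::leveneTest(center = mean)`), followed by a Holm step-down
#' adjustment across the difficulty-level tests.
#'
#' @param data a data frame with columns `participant_id`, `instruction`,
#'   `difficulty`, `value` (one row per participant x difficulty).
#' @return a data frame with one row per difficulty: `statistic` (F),
#'   `df1`, `df2`, `p_value`, `adjusted_p`.
#' @export
levene_holm <- function(data) {
  req <- c("instruction", "difficulty", "value")
  if (!all(req %in% names(data))) {
    stop("data must have columns ", paste(req, collapse = ", "))
  }
  diffs <- sort(unique(data$difficulty))
  rows <- lapply(diffs, function(dl) {
    sub <- data[data$difficulty == dl, ]
    if (min(table(sub$instruction)) < 2) {
      stop("need at least 2 participants per instruction group (",
           dl, ")")
    }
    dev <- abs(sub$value - stats::ave(sub$value, sub$instruction))
    if (all(dev == 0)) {
      stop("degenerate data in difficulty '", dl,
           "': all values identical within groups")
    }
    lt <- car::leveneTest(sub$value, factor(sub$instruction),
                          center = mean)
    data.frame(difficulty = dl, statistic = lt[1, "F value"],
               df1 = lt[1, "Df"], df2 = lt[2, "Df"],
               p_value = lt[1, "Pr(>F)"], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$adjusted_p <- stats::p.adjust(out$p_value, method = "holm")
  out
}
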