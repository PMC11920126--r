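#' Calibrate d' to a target accuracy
#'
#' Returns the type-1 sensitivity at which an observer with the given
#' criterion reaches the target expected accuracy with equal match /
#' nonmatch base rates. For an unbiased criterion (0) this is the closed
#' form `2 * qnorm(accuracy)`.
#'
#' @param target_accuracy expected proportion correct, in (0.5, 1).
#' @param criterion type-1 criterion, default 0.
#' @return d' in z units.
#' @examples
#' calibrate_dprime(0.70)  # about 1.049
#' @export
calibrate_dprime <- function(target_accuracy, criterion = 0) {
  if (!is.numeric(target_accuracy) || target_accuracy <= 0.5 ||
      target_accuracy >= 1) {
    stop("target_accuracy must be in (0.5, 1): no positive-d' solution ",
         "exists at or below chance")
  }
  acc <- function(dp) {
    0.5 * (1 - stats::pnorm(criterion - dp / 2)) +
      0.5 * stats::pnorm(criterion + dp / 2)
  }
  stats::uniroot(function(dp) acc(dp) - target_accuracy,
                 interval = c(1e-8, 15), tol = 1e-10)$root
}

# ---- metacognitive-noise calibration -------------------------------------
#
# Generative metacognitive sample, single parameter theta:
#   theta >= 0:  y = x + theta * N(0, 1)          (noise-loss regime)
#   theta <  0:  y = x + |theta| * z, z ~ N(mu_s, 1)  (super-optimal regime:
#                an independent second stimulus sample adds information)
# The rating is a threshold on y on the side of the type-1 response. The
# mapping theta -> asymptotic MLE-fitted M-ratio is computed by numerical
# integration + the package's own fitter on expected proportions, then
# inverted on a memoized monotone grid.

# P(response region, y below t | stimulus mean mu1), by 1-D integration
# over the decision variable x.
.joint_resp_y <- function(t, mu1, lower_x, upper_x, shift, s) {
  if (s == 0) {
    # y = x + shift exactly
    hi <- min(upper_x, t - shift)
    if (hi <= lower_x) return(0)
    return(stats::pnorm(hi, mean = mu1) - stats::pnorm(lower_x, mean = mu1))
  }
  f <- function(x) {
    stats::dnorm(x, mean = mu1) * stats::pnorm((t - x - shift) / s)
  }
  stats::integrate(f, lower_x, upper_x, rel.tol = 1e-9,
                   stop.on.error = FALSE)$value
}

# Expected response-conditional probability table (2 x 2 x K, joint with
# response) for the generative observer.
.asymptotic_table <- function(d_prime, criterion, theta, thresholds) {
  K <- length(thresholds) + 1
  s <- abs(theta)
  arr <- array(0, dim = c(2, 2, K))
  for (i in 1:2) {
    mu1 <- (if (i == 1) -1 else 1) * d_prime / 2
    shift <- if (theta < 0) s * mu1 else 0
    # match response (x > criterion): rating k <=> w = y - criterion in
    # (a_{k-1}, a_k), a_0 = -Inf, a_K = Inf
    edges <- c(-Inf, thresholds, Inf) + criterion
    cum <- vapply(edges, function(t)
      if (is.infinite(t) && t > 0) {
        1 - stats::pnorm(criterion, mean = mu1)
      } else if (is.infinite(t)) 0 else {
        .joint_resp_y(t, mu1, criterion, Inf, shift, s)
      }, numeric(1))
    arr[i, 2, ] <- pmax(diff(cum), 0)
    # nonmatch response (x < criterion): w = criterion - y, so rating k
    # has mass G(c - a_k) - G(c - a_{k-1}) with G(t) = P(x < c, y >= t)
    edges_nm <- criterion - c(-Inf, thresholds, Inf)  # descending in y
    cum_nm <- vapply(edges_nm, function(t)
      if (is.infinite(t) && t > 0) 0 else if (is.infinite(t)) {
        stats::pnorm(criterion, mean = mu1)
      } else {
        stats::pnorm(criterion, mean = mu1) -
          .joint_resp_y(t, mu1, -Inf, criterion, shift, s)
      }, numeric(1))
    arr[i, 1, ] <- pmax(diff(cum_nm), 0)
  }
  arr
}

# Asymptotic MLE M-ratio of the generative observer at a given theta.
.mratio_at_theta <- function(theta, d_prime, criterion, thresholds) {
  arr <- .asymptotic_table(d_prime, criterion, theta, thresholds)
  fit <- .fit_meta_d_core(arr * 1e4, d_prime, criterion)
  fit$m_ratio
}

.calibration_cache <- new.env(parent = emptyenv())

# Monotone grid of (theta, m_ratio) for one observer geometry, memoized.
.calibration_grid <- function(d_prime, criterion, thresholds) {
  key <- paste(round(c(d_prime, criterion, thresholds), 6), collapse = "_")
  if (!is.null(.calibration_cache[[key]])) return(.calibration_cache[[key]])
  thetas <- c(seq(-2, -0.25, by = 0.25), seq(0, 1.5, by = 0.125),
              seq(1.75, 3, by = 0.25), 3.5, 4, 5, 6, 8)
  m <- vapply(thetas, .mratio_at_theta, numeric(1),
              d_prime = d_prime, criterion = criterion,
              thresholds = thresholds)
  # enforce strict monotonicity for interpolation (m decreases with theta)
  grid <- list(theta = thetas, m = cummin(m - 1e-9 * seq_along(m)))
  .calibration_cache[[key]] <- grid
  grid
}

# Solve theta so the asymptotic fitted M-ratio equals the target. Returns
# list(theta, m) where m is the attained M-ratio (equal to m_target unless
# clamped at the edge of the calibratable range).
.solve_meta_theta <- function(m_target, d_prime, criterion, thresholds,
                              warn_super = TRUE) {
  grid <- .calibration_grid(d_prime, criterion, thresholds)
  if (m_target > 1 && warn_super) {
    warning(sprintf("M-ratio target %.3f > 1: super-optimal regime",
                    m_target))
  }
  if (m_target > max(grid$m)) {
    warning(sprintf(
      "requested M-ratio %.3f exceeds the calibratable super-optimal range (max %.3f); clamping",
      m_target, max(grid$m)))
    return(list(theta = grid$theta[which.max(grid$m)], m = max(grid$m)))
  }
  if (m_target < min(grid$m)) {
    return(list(theta = max(grid$theta), m = min(grid$m)))
  }
  list(theta = stats::approx(rev(grid$m), rev(grid$theta), xout = m_target,
                             ties = "ordered")$y,
       m = m_target)
}

#' Simulate rating counts for a single generative observer
#'
#' Draws trials from the generative SDT observer used by the task
#' simulator: type-1 evidence `x ~ N(+/- d'/2, 1)`, response by criterion,
#' metacognitive evidence `y` obtained from `x` with the noise (or
#' super-optimal) parameter solved so the observer's asymptotic fitted
#' M-ratio equals `m_ratio`, and the rating assigned by thresholding `y` on
#' the side of the response. With `m_ratio = 1` the rating thresholds the
#' same evidence as the decision (the ideal metacognitive observer).
#'
#' @param n_trials number of trials.
#' @param d_prime,criterion type-1 parameters.
#' @param m_ratio target metacognitive efficiency.
#' @param thresholds positive ascending rating thresholds (length `K - 1`)
#'   on the decision-aligned metacognitive evidence.
#' @param p_match probability of a match (signal) trial.
#' @param seed integer seed (required).
#' @return a [rating_counts] object with `K = length(thresholds) + 1`.
#' @examples
#' cnt <- simulate_rating_counts(2000, d_prime = 1, m_ratio = 1, seed = 1)
#' fit_meta_d_mle(cnt)$m_ratio  # close to 1
#' @export
simulate_rating_counts <- function(n_trials, d_prime, criterion = 0,
                                   m_ratio = 1, thresholds = 0.5,
                                   p_match = 0.5, seed) {
  if (missing(seed)) stop("seed is required")
  set.seed(as.integer(seed))
  theta <- .solve_meta_theta(m_ratio, d_prime, criterion, thresholds)$theta
  sim <- .simulate_trials_core(n_trials, d_prime, criterion, theta,
                               thresholds, p_match)
  K <- length(thresholds) + 1
  arr <- array(0, dim = c(2, 2, K))
  for (r in seq_len(n_trials)) {
    arr[sim$stim[r], sim$resp[r], sim$rating[r]] <-
      arr[sim$stim[r], sim$resp[r], sim$rating[r]] + 1
  }
  rating_counts(arr)
}

# Vectorized trial core: stim/resp as 1 (nonmatch) / 2 (match), rating 1..K.
.simulate_trials_core <- function(n, d_prime, criterion, theta, thresholds,
                                  p_match) {
  stim <- 1L + (stats::runif(n) < p_match)
  mu1 <- (2 * stim - 3) * d_prime / 2
  x <- stats::rnorm(n, mean = mu1, sd = 1)
  resp <- 1L + (x > criterion)
  s <- abs(theta)
  y <- if (theta >= 0) {
    x + s * stats::rnorm(n)
  } else {
    x + s * stats::rnorm(n, mean = mu1, sd = 1)
  }
  w <- ifelse(resp == 2L, y - criterion, criterion - y)
  rating <- 1L + findInterval(w, thresholds)
  list(stim = stim, resp = resp, rating = rating, x = x, correct =
         (stim == resp))
}

#' Simulation configuration for the delayed match-to-sample task
#'
#' Builds the parameter set for [simulate_task_data]. Defaults emulate the
#' study design being modeled: two instruction groups (bet N = 104,
#' confidence N = 100), 6 sessions of 12 trials with difficulty blocked in
#' session halves and the block order counterbalanced by participant
#' parity, d' calibrated so expected accuracy is 0.70 (easy) and 0.60
#' (hard), a binary prospective pre-rating and a 5-point retrospective
#' post-rating, and log M-ratio following the two-way mixed linear model
#' of [fit_hierarchical_mratio] per phase (confidence and hard coded
#' positive). Default effects: pre phase `mu = log(0.65)`,
#' `beta_I = -0.4` (efficiency higher under betting), others 0; post phase
#' `mu = log(0.8)`, `beta_I = -0.15`, `beta_D = -0.25`, interaction 0;
#' `sigma_u = 0.15`, `sigma_e = 0.1` in both phases, with participant
#' intercepts correlated `phase_cor = 0.5` across phases (pre-to-post
#' carry-over).
#'
#' @param n_bet,n_confidence participants per instruction group.
#' @param sessions,trials_per_session task structure (6 x 12).
#' @param accuracy_easy,accuracy_hard target accuracies used to calibrate
#'   the per-difficulty d'.
#' @param criterion type-1 criterion.
#' @param pre,post named lists of log-M-ratio model coefficients
#'   (`mu`, `beta_I`, `beta_D`, `beta_ID`, `sigma_u`, `sigma_e`).
#' @param pre_thresholds,post_thresholds rating thresholds on the
#'   decision-aligned metacognitive evidence (lengths 1 and 4).
#' @param phase_cor correlation of participant random intercepts across
#'   the pre and post phases, in `[0, 1]`.
#' @param p_match probability of a match trial.
#' @param lapse_rate per-trial probability of a missing or too-fast
#'   response (injected for exclusion testing).
#' @param dropout_rate probability that a participant is a chronic lapser
#'   whose per-trial lapse probability is `dropout_lapse` instead of
#'   `lapse_rate`; such participants often fall below the 18-valid-trial
#'   exclusion bound, emulating the participant-level exclusions seen in
#'   online cohorts.
#' @param dropout_lapse per-trial lapse probability of chronic lapsers.
#' @param rt_meanlog,rt_sdlog log-normal response-time parameters
#'   (milliseconds; defaults give a median near 800 ms).
#' @param seed integer seed; mandatory, stored in the config.
#' @return a `sim_config` list.
#' @export
simulation_config <- function(n_bet = 104, n_confidence = 100,
                              sessions = 6, trials_per_session = 12,
                              accuracy_easy = 0.70, accuracy_hard = 0.60,
                              criterion = 0,
                              pre = list(mu = log(0.65), beta_I = -0.4,
                                         beta_D = 0, beta_ID = 0,
                                         sigma_u = 0.15, sigma_e = 0.1),
                              post = list(mu = log(0.8), beta_I = -0.15,
                                          beta_D = -0.25, beta_ID = 0,
                                          sigma_u = 0.15, sigma_e = 0.1),
                              pre_thresholds = 0.5,
                              post_thresholds = c(0.2, 0.6, 1.1, 1.7),
                              phase_cor = 0.5, p_match = 0.5,
                              lapse_rate = 0.03, dropout_rate = 0.05,
                              dropout_lapse = 0.5,
                              rt_meanlog = log(800), rt_sdlog = 0.4,
                              seed) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory in a ",
                                           "simulation config")
  for (ph in list(pre, post)) {
    if (ph$sigma_u < 0 || ph$sigma_e < 0) stop("sigma must be non-negative")
  }
  if (p_match < 0 || p_match > 1 || lapse_rate < 0 || lapse_rate > 1) {
    stop("probabilities must be in [0, 1]")
  }
  d_easy <- calibrate_dprime(accuracy_easy, criterion)
  d_hard <- calibrate_dprime(accuracy_hard, criterion)
  if (d_easy <= 0 || d_hard <= 0) stop("d' per difficulty must be positive")
  structure(list(
    n_bet = n_bet, n_confidence = n_confidence, sessions = sessions,
    trials_per_session = trials_per_session,
    d_prime = c(easy = d_easy, hard = d_hard), criterion = criterion,
    pre = pre, post = post, pre_thresholds = pre_thresholds,
    post_thresholds = post_thresholds, phase_cor = phase_cor,
    p_match = p_match, lapse_rate = lapse_rate,
    dropout_rate = dropout_rate, dropout_lapse = dropout_lapse,
    rt_meanlog = rt_meanlog, rt_sdlog = rt_sdlog,
    seed = as.integer(seed)), class = "sim_config")
}

#' Simulate a full task dataset
#'
#' Generates trial-level data for a cohort under a [simulation_config]:
#' stimulus labels drawn with `p_match`, type-1 evidence and responses from
#' the SDT observer at the per-difficulty d', prospective binary
#' pre-ratings and retrospective 5-point post-ratings from metacognitive
#' evidence whose noise is solved per participant and cell so the
#' asymptotic fitted M-ratio equals the participant's true
#' `exp(log M-ratio)` target, log-normal response times, and lapse trials
#' (missing or sub-100-ms responses) injected at `lapse_rate`. Difficulty
#' is blocked into session halves with order alternating by participant
#' index parity.
#'
#' The same config (including its seed) always regenerates a byte-identical
#' dataset.
#'
#' @param config a `sim_config` from [simulation_config].
#' @return a list with `trials` (trial data frame in the [read_trials]
#'   schema plus the derived `correct` column) and `truth` (a list with
#'   `participants` -- per participant x difficulty true d', criterion and
#'   pre/post M-ratio targets -- and the generating `coefficients` and
#'   `config`).
#' @export
simulate_task_data <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n_total <- config$n_bet + config$n_confidence
  instruction <- rep(c("bet", "confidence"),
                     c(config$n_bet, config$n_confidence))
  ids <- sprintf("P%03d", seq_len(n_total))
  xD <- c(easy = -0.5, hard = 0.5)
  n_per_diff <- config$sessions * config$trials_per_session / 2

  trials_list <- vector("list", n_total)
  truth_list <- vector("list", n_total)
  for (s in seq_len(n_total)) {
    xI <- if (instruction[s] == "confidence") 0.5 else -0.5
    # correlated participant intercepts across phases
    z1 <- stats::rnorm(1)
    z2 <- stats::rnorm(1)
    u_pre <- config$pre$sigma_u * z1
    u_post <- config$post$sigma_u *
      (config$phase_cor * z1 + sqrt(1 - config$phase_cor^2) * z2)
    per_diff <- lapply(c("easy", "hard"), function(diff_lab) {
      dp <- config$d_prime[[diff_lab]]
      lam <- function(ph, u) {
        ph$mu + ph$beta_I * xI + ph$beta_D * xD[[diff_lab]] +
          ph$beta_ID * xI * xD[[diff_lab]] + u +
          ph$sigma_e * stats::rnorm(1)
      }
      sol_pre <- .solve_meta_theta(exp(lam(config$pre, u_pre)), dp,
                                   config$criterion, config$pre_thresholds,
                                   warn_super = FALSE)
      sol_post <- .solve_meta_theta(exp(lam(config$post, u_post)), dp,
                                    config$criterion,
                                    config$post_thresholds,
                                    warn_super = FALSE)
      m_pre <- sol_pre$m
      m_post <- sol_post$m
      th_pre <- sol_pre$theta
      th_post <- sol_post$theta
      n <- n_per_diff
      stim <- 1L + (stats::runif(n) < config$p_match)
      mu1 <- (2 * stim - 3) * dp / 2
      x <- stats::rnorm(n, mean = mu1)
      resp <- 1L + (x > config$criterion)
      mk_y <- function(theta) {
        if (theta >= 0) x + theta * stats::rnorm(n)
        else x + (-theta) * stats::rnorm(n, mean = mu1)
      }
      y_pre <- mk_y(th_pre)
      y_post <- mk_y(th_post)
      w_pre <- ifelse(resp == 2L, y_pre - config$criterion,
                      config$criterion - y_pre)
      w_post <- ifelse(resp == 2L, y_post - config$criterion,
                       config$criterion - y_post)
      list(difficulty = diff_lab, m_pre = m_pre, m_post = m_post,
           theta_pre = th_pre, theta_post = th_post,
           stim = stim, resp = resp,
           pre_rating = 1L + findInterval(w_pre, config$pre_thresholds),
           post_rating = 1L + findInterval(w_post, config$post_thresholds))
    })
    # difficulty block order counterbalanced by participant parity
    order_labs <- if (s %% 2 == 1) c("easy", "hard") else c("hard", "easy")
    blocks <- per_diff[match(order_labs, c("easy", "hard"))]
    n <- 2 * n_per_diff
    df <- data.frame(
      participant_id = ids[s], instruction = instruction[s],
      difficulty = rep(order_labs, each = n_per_diff),
      session = rep(seq_len(config$sessions),
                    each = config$trials_per_session),
      trial = rep(seq_len(config$trials_per_session), config$sessions),
      stimulus = c("nonmatch", "match")[c(blocks[[1]]$stim,
                                          blocks[[2]]$stim)],
      pre_rating = c(blocks[[1]]$pre_rating, blocks[[2]]$pre_rating),
      type1_response = c("nonmatch", "match")[c(blocks[[1]]$resp,
                                                blocks[[2]]$resp)],
      post_rating = c(blocks[[1]]$post_rating, blocks[[2]]$post_rating),
      rt_pre = stats::rlnorm(n, config$rt_meanlog, config$rt_sdlog),
      rt_answer = stats::rlnorm(n, config$rt_meanlog, config$rt_sdlog),
      rt_post = stats::rlnorm(n, config$rt_meanlog, config$rt_sdlog),
      stringsAsFactors = FALSE)
    # lapse injection: a missing response or an implausibly fast RT;
    # chronic lapsers emulate participants destined for exclusion
    lapse_p <- if (stats::runif(1) < config$dropout_rate) {
      config$dropout_lapse
    } else {
      config$lapse_rate
    }
    lapse <- stats::runif(n) < lapse_p
    if (any(lapse)) {
      which_phase <- sample(1:3, sum(lapse), replace = TRUE)
      fast <- stats::runif(sum(lapse)) < 0.5
      fast_rt <- stats::runif(sum(lapse), 0, 99)
      idx <- which(lapse)
      for (j in seq_along(idx)) {
        cols <- switch(which_phase[j],
                       c("pre_rating", "rt_pre"),
                       c("type1_response", "rt_answer"),
                       c("post_rating", "rt_post"))
        if (fast[j]) {
          df[idx[j], cols[2]] <- fast_rt[j]
        } else {
          df[idx[j], cols[1]] <- NA
          df[idx[j], cols[2]] <- NA
        }
      }
    }
    df$correct <- !is.na(df$type1_response) &
      df$type1_response == df$stimulus
    df$correct[is.na(df$type1_response)] <- NA
    trials_list[[s]] <- df
    truth_list[[s]] <- data.frame(
      participant_id = ids[s], instruction = instruction[s],
      difficulty = c("easy", "hard"),
      true_d_prime = unname(config$d_prime),
      true_criterion = config$criterion,
      true_m_pre = vapply(per_diff, `[[`, numeric(1), "m_pre"),
      true_m_post = vapply(per_diff, `[[`, numeric(1), "m_post"),
      theta_pre = vapply(per_diff, `[[`, numeric(1), "theta_pre"),
      theta_post = vapply(per_diff, `[[`, numeric(1), "theta_post"),
      stringsAsFactors = FALSE)
  }
  trials <- do.call(rbind, trials_list)
  rownames(trials) <- NULL
  list(trials = trials,
       truth = list(participants = do.call(rbind, truth_list),
                    coefficients = list(pre = config$pre,
                                        post = config$post),
                    config = config))
}
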