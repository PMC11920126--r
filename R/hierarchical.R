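#' Assemble per-cell data for the hierarchical M-ratio model
#'
#' Builds the cell table consumed by [fit_hierarchical_mratio] from
#' trial-level data: one row per participant x difficulty with the phase's
#' rating counts and the per-cell type-1 point estimates (edge-corrected
#' d' and criterion).
#'
#' With few trials per cell the raw per-cell d' is noisy (at 36 trials its
#' sampling SD is comparable to a low d' itself), and cells whose estimate
#' lands near or below zero distort the fitted log M-ratio, biasing the
#' group model. `stabilize_type1 = TRUE` (default) therefore shrinks each
#' cell's d' and criterion toward its instruction x difficulty group mean
#' with empirical-Bayes weights (delta-method sampling variance against the
#' estimated between-participant variance), which leaves group contrasts
#' intact while suppressing the small-sample noise.
#'
#' @param trials a trial data frame with exclusions already applied.
#' @param phase `"pre"` (binary rating) or `"post"` (5-point rating).
#' @param stabilize_type1 shrink per-cell type-1 estimates toward their
#'   instruction x difficulty group mean (default `TRUE`).
#' @return a data frame with columns `participant_id`, `instruction`,
#'   `difficulty`, `d_prime`, `criterion`, and list-column `counts`.
#' @export
prepare_mratio_cells <- function(trials, phase = c("pre", "post"),
                                 stabilize_type1 = TRUE) {
  phase <- match.arg(phase)
  cells <- tabulate_rating_counts(trials, phase)
  t1 <- lapply(cells$counts, compute_type1_sdt, correction = "hautus")
  cells$d_prime <- vapply(t1, `[[`, numeric(1), "d_prime")
  cells$criterion <- vapply(t1, `[[`, numeric(1), "criterion")
  # delta-method sampling variances of z(HR) and z(FAR)
  var_z <- function(p, n) p * (1 - p) / (n * stats::dnorm(stats::qnorm(p))^2)
  vh <- mapply(function(f) var_z(f$hit_rate, f$n_match), t1)
  vf <- mapply(function(f) var_z(f$fa_rate, f$n_nonmatch), t1)
  v_d <- vh + vf
  v_c <- (vh + vf) / 4
  if (stabilize_type1) {
    grp <- interaction(cells$instruction, cells$difficulty, drop = TRUE)
    shrink <- function(x, v) {
      est <- x
      cell_v <- v
      grp_v <- rep(0, length(x))
      for (g in levels(grp)) {
        i <- which(grp == g)
        if (length(i) < 3) next
        m <- mean(x[i])
        tau2 <- max(stats::var(x[i]) - mean(v[i]), 0)
        w <- tau2 / (tau2 + v[i])
        est[i] <- m + w * (x[i] - m)
        # residual cell-level EB variance; the group-mean estimation
        # error is coherent across the group's cells and is carried
        # separately so contrasts see it
        cell_v[i] <- w * v[i]
        grp_v[i] <- mean(v[i]) / length(i)
      }
      list(est = est, sd = sqrt(cell_v), group_sd = sqrt(grp_v))
    }
    sd_ <- shrink(cells$d_prime, v_d)
    sc_ <- shrink(cells$criterion, v_c)
    cells$d_prime <- sd_$est
    cells$criterion <- sc_$est
    cells$d_prime_sd <- sd_$sd
    cells$criterion_sd <- sc_$sd
    cells$d_prime_group_sd <- sd_$group_sd
    cells$criterion_group_sd <- sc_$group_sd
  } else {
    cells$d_prime_sd <- sqrt(v_d)
    cells$criterion_sd <- sqrt(v_c)
    cells$d_prime_group_sd <- 0
    cells$criterion_group_sd <- 0
  }
  cells
}

#' Hierarchical Bayesian estimation of M-ratio (two-way mixed design)
#'
#' Samples the joint posterior of a hierarchical model of log M-ratio
#' `lambda` with one between-participant factor (instruction: bet vs
#' confidence) and one within-participant factor (difficulty: easy vs
#' hard). Per participant `s` and difficulty cell `c`:
#'
#' \deqn{\lambda_{s,c} = \mu + \beta_I x_I(s) + \beta_D x_D(c) +
#'   \beta_{ID} x_I x_D + u_s + \epsilon_{s,c}}
#'
#' with effect coding `x_I, x_D \in \{-0.5, +0.5\}` (confidence and hard
#' coded positive), participant random intercepts `u_s ~ N(0, sigma_u^2)`
#' and cell-level noise `eps ~ N(0, sigma_e^2)`. Observed rating counts
#' follow the response-conditional type-2 multinomial likelihood (see
#' [type2_probabilities]) at `meta-d' = exp(lambda) * d'`, with the type-1
#' parameters fixed at their per-cell point estimates and per-participant
#' ordered type-2 criteria. Priors: `mu, beta ~ N(0,1)`;
#' `sigma_u, sigma_e ~ Half-Normal(1)`; criterion increments
#' `~ Half-Normal(1)`.
#'
#' Sampling uses an adaptive Metropolis-within-Gibbs scheme implemented in
#' C++ (proposal scales adapt during burn-in only). All randomness flows
#' from `seed`, which is mandatory: a fixed seed with fixed data yields
#' bit-identical draws.
#'
#' @param cells a cell table from [prepare_mratio_cells], or any data frame
#'   with columns `participant_id`, `instruction` (`"bet"`/`"confidence"`),
#'   `difficulty` (`"easy"`/`"hard"`), list-column `counts` of
#'   [rating_counts], and optionally `d_prime`/`criterion` (computed from
#'   the counts when absent). Every participant must contribute exactly one
#'   cell per difficulty, with the same instruction in both.
#' @param chains number of chains (default 3).
#' @param iterations total MCMC iterations per chain, including burn-in
#'   (default 10000).
#' @param burnin burn-in iterations discarded per chain (default 1000).
#' @param seed integer seed (required).
#' @return an object of class `mratio_fit`: list with `draws` (an
#'   iterations x chains x parameters array for `mu`, `b_instruction`,
#'   `b_difficulty`, `b_interaction`, `sigma_u`, `sigma_e`), `cells`
#'   (participant/cell metadata with posterior-mean log M-ratio per cell),
#'   `K`, and the MCMC settings.
#' @export
fit_hierarchical_mratio <- function(cells, chains = 3, iterations = 10000,
                                    burnin = 1000, seed = NULL) {
  if (is.null(seed)) {
    stop("seed is required: hierarchical fits must be reproducible")
  }
  if (iterations <= burnin) stop("iterations must exceed burnin")
  if (!all(c("participant_id", "instruction", "difficulty", "counts") %in%
           names(cells))) {
    stop("cells must have participant_id, instruction, difficulty, counts")
  }
  if (!all(cells$instruction %in% c("bet", "confidence"))) {
    stop("instruction must be 'bet' or 'confidence'")
  }
  if (!all(cells$difficulty %in% c("easy", "hard"))) {
    stop("difficulty must be 'easy' or 'hard'")
  }
  if (!("d_prime" %in% names(cells))) {
    t1 <- lapply(cells$counts, compute_type1_sdt, correction = "hautus")
    cells$d_prime <- vapply(t1, `[[`, numeric(1), "d_prime")
    cells$criterion <- vapply(t1, `[[`, numeric(1), "criterion")
  }

  ids <- unique(cells$participant_id)
  S <- length(ids)
  for (id in ids) {
    rows <- cells[cells$participant_id == id, ]
    if (nrow(rows) != 2 || !setequal(rows$difficulty, c("easy", "hard"))) {
      stop("participant ", id, " must contribute exactly one easy and one ",
           "hard cell")
    }
    if (length(unique(rows$instruction)) != 1) {
      stop("participant ", id, " has inconsistent instruction labels")
    }
  }
  instr <- vapply(ids, function(id)
    cells$instruction[cells$participant_id == id][1], character(1))
  if (length(unique(instr)) < 2 || any(table(instr) < 2)) {
    stop("need at least 2 participants per instruction group (both ",
         "'bet' and 'confidence')")
  }

  K <- dim(cells$counts[[1]])[3]
  has_sd <- all(c("d_prime_sd", "criterion_sd") %in% names(cells))
  has_group_sd <- all(c("d_prime_group_sd", "criterion_group_sd") %in%
                      names(cells))
  counts_vec <- numeric(S * 2 * 2 * 2 * K)
  dprime <- numeric(S * 2)
  crit <- numeric(S * 2)
  dprime_sd <- numeric(S * 2)
  crit_sd <- numeric(S * 2)
  gd_sd_cell <- numeric(S * 2)
  gc_sd_cell <- numeric(S * 2)
  for (s in seq_len(S)) {
    for (ci in 1:2) {
      diff_lab <- c("easy", "hard")[ci]
      row <- which(cells$participant_id == ids[s] &
                   cells$difficulty == diff_lab)
      arr <- unclass(cells$counts[[row]])
      if (dim(arr)[3] != K) stop("inconsistent K across cells")
      dp <- cells$d_prime[row]
      if (!is.finite(dp)) {
        stop("non-finite type-1 d' in cell (participant ", ids[s],
             ", ", diff_lab, ")")
      }
      dprime[(s - 1) * 2 + ci] <- dp
      crit[(s - 1) * 2 + ci] <- cells$criterion[row]
      if (has_sd) {
        dprime_sd[(s - 1) * 2 + ci] <- cells$d_prime_sd[row]
        crit_sd[(s - 1) * 2 + ci] <- cells$criterion_sd[row]
      }
      if (has_group_sd) {
        gd_sd_cell[(s - 1) * 2 + ci] <- cells$d_prime_group_sd[row]
        gc_sd_cell[(s - 1) * 2 + ci] <- cells$criterion_group_sd[row]
      }
      # layout: [cell][stim][j], j<K nonmatch-response, j>=K match-response
      for (i in 1:2) {
        base <- (((s - 1) * 2 + ci - 1) * 2 + (i - 1)) * 2 * K
        counts_vec[base + seq_len(K)] <- arr[i, 1, ]
        counts_vec[base + K + seq_len(K)] <- arr[i, 2, ]
      }
    }
  }
  xI <- ifelse(instr == "confidence", 0.5, -0.5)
  xD <- c(-0.5, 0.5)  # easy, hard
  # instruction x difficulty group per cell (0-based for the sampler) and
  # the shared type-1 offset SD of each group
  grp_cell <- (rep(ifelse(instr == "confidence", 1L, 0L), each = 2)) * 2L +
    rep(c(0L, 1L), S)
  gd_sd <- numeric(4)
  gc_sd <- numeric(4)
  for (g in 0:3) {
    i <- which(grp_cell == g)
    if (length(i) > 0) {
      gd_sd[g + 1] <- gd_sd_cell[i[1]]
      gc_sd[g + 1] <- gc_sd_cell[i[1]]
    }
  }

  set.seed(as.integer(seed) %% .Machine$integer.max)
  chain_seeds <- sample.int(2^31 - 2, chains)
  n_keep <- iterations - burnin
  draws <- array(NA_real_, dim = c(n_keep, chains, 6))
  lambda_mean <- matrix(0, nrow = S * 2, ncol = chains)
  for (ch in seq_len(chains)) {
    set.seed(chain_seeds[ch])
    init <- list(mu = stats::rnorm(1, 0, 0.3),
                 b1 = stats::rnorm(1, 0, 0.2),
                 b2 = stats::rnorm(1, 0, 0.2),
                 b3 = stats::rnorm(1, 0, 0.2),
                 lsu = log(0.5) + stats::rnorm(1, 0, 0.2),
                 lse = log(0.5) + stats::rnorm(1, 0, 0.2),
                 ld0 = log(0.5))
    res <- .mratio_sampler_cpp(counts_vec, dprime, crit, dprime_sd,
                               crit_sd, grp_cell, gd_sd, gc_sd, xI, xD,
                               S, K, as.integer(iterations),
                               as.integer(burnin), init)
    draws[, ch, ] <- res$draws
    lambda_mean[, ch] <- res$lambda_mean
  }
  dimnames(draws) <- list(NULL, paste0("chain", seq_len(chains)),
                          c("mu", "b_instruction", "b_difficulty",
                            "b_interaction", "sigma_u", "sigma_e"))
  cell_info <- data.frame(
    participant_id = rep(ids, each = 2),
    instruction = rep(instr, each = 2),
    difficulty = rep(c("easy", "hard"), S),
    d_prime = dprime, criterion = crit,
    log_mratio_mean = rowMeans(lambda_mean),
    stringsAsFactors = FALSE)
  structure(list(draws = draws, cells = cell_info, K = K,
                 chains = chains, iterations = iterations, burnin = burnin,
                 seed = seed),
            class = "mratio_fit")
}

#' @export
print.mratio_fit <- function(x, ...) {
  cat(sprintf(
    "Hierarchical M-ratio fit: %d participants, K = %d, %d chains x %d iterations (%d burn-in)\n",
    nrow(x$cells) / 2, x$K, x$chains, x$iterations, x$burnin))
  print(summarize_effects(x), ...)
  invisible(x)
}

#' Posterior effect summaries with the HDI/pd decision rule
#'
#' For each fixed effect of a hierarchical M-ratio fit, reports the
#' pooled-chain posterior median, the 95% (by default) highest-density
#' interval, the probability of direction, the rank-normalized split R-hat
#' and the tail effective sample size. The decision column applies the
#' preregistered-style rule: `"effect"` iff the HDI excludes 0 AND
#' pd exceeds `pd_threshold`; otherwise `"no-effect"`. Fits with any
#' R-hat at or above 1.01 are still summarized but flagged as
#' non-converged.
#'
#' @param fit an `mratio_fit` object (needs at least 2 chains).
#' @param hdi_mass HDI probability mass (default 0.95).
#' @param pd_threshold pd cut-off for the decision rule (default 0.95).
#' @param include_mean also include a row for the grand mean `mu`
#'   (default `FALSE`; its decision column is `NA` since the rule targets
#'   design effects).
#' @return a data frame with one row per effect: `effect`, `median`,
#'   `hdi_low`, `hdi_high`, `pd`, `rhat`, `ess_tail`, `decision`,
#'   `converged`.
#' @export
summarize_effects <- function(fit, hdi_mass = 0.95, pd_threshold = 0.95,
                              include_mean = FALSE) {
  stopifnot(inherits(fit, "mratio_fit"))
  if (dim(fit$draws)[2] < 2) stop("need draws from at least 2 chains")
  pars <- c(instruction = "b_instruction", difficulty = "b_difficulty",
            interaction = "b_interaction")
  if (include_mean) pars <- c(mean = "mu", pars)
  rows <- lapply(names(pars), function(nm) {
    mat <- fit$draws[, , pars[[nm]]]
    pooled <- as.vector(mat)
    hdi <- compute_hdi(pooled, hdi_mass)
    pd <- compute_pd(pooled)
    rh <- rhat_rank(mat)
    et <- ess_tail(mat)
    decision <- if (nm == "mean") NA_character_ else {
      if ((hdi[1] > 0 || hdi[2] < 0) && pd > pd_threshold) "effect"
      else "no-effect"
    }
    data.frame(effect = nm, median = stats::median(pooled),
               hdi_low = unname(hdi[1]), hdi_high = unname(hdi[2]),
               pd = pd, rhat = rh, ess_tail = et, decision = decision,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$converged <- all(out$rhat < 1.01)
  out
}
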