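# Independent oracles used across the test files. Each is deliberately
# implemented by a different route than the package code it checks.

# Exhaustive grid-search meta-d' optimum for binary (K = 2) rating counts.
# For K = 2 the response-conditional likelihood separates: given meta-d',
# the nonmatch-response cells depend only on the low-side criterion and the
# match-response cells only on the high-side criterion, so each side can be
# scanned independently.
grid_search_meta_d <- function(counts, d_prime, criterion,
                               meta_d_grid = seq(-3, 3, by = 0.01),
                               offset_grid = seq(0.01, 4, by = 0.01)) {
  arr <- unclass(counts)
  best_ll <- -Inf
  best_md <- NA_real_
  for (md in meta_d_grid) {
    cpr <- criterion * md / d_prime
    ll <- 0
    for (side in 1:2) {  # 1 = nonmatch response, 2 = match response
      t2c <- if (side == 1) cpr - offset_grid else cpr + offset_grid
      ll_side <- rep(0, length(offset_grid))
      for (i in 1:2) {
        mu <- (if (i == 1) -1 else 1) * md / 2
        if (side == 1) {
          denom <- pnorm(cpr, mean = mu)
          p1 <- (denom - pnorm(t2c, mean = mu)) / denom  # rating 1
          p2 <- pnorm(t2c, mean = mu) / denom            # rating 2
        } else {
          denom <- 1 - pnorm(cpr, mean = mu)
          p1 <- (pnorm(t2c, mean = mu) - pnorm(cpr, mean = mu)) / denom
          p2 <- (1 - pnorm(t2c, mean = mu)) / denom
        }
        p1 <- pmax(p1, 1e-12)
        p2 <- pmax(p2, 1e-12)
        ll_side <- ll_side + arr[i, side, 1] * log(p1) +
          arr[i, side, 2] * log(p2)
      }
      ll <- ll + max(ll_side)
    }
    if (ll > best_ll + 1e-12 ||
        (abs(ll - best_ll) <= 1e-12 && abs(md) < abs(best_md))) {
      best_ll <- ll
      best_md <- md
    }
  }
  list(meta_d = best_md, log_lik = best_ll)
}

# Hand sums-of-squares decomposition of the balanced two-way mixed design
# (one between factor, one within factor), written directly from the
# classical formulas.
ss_mixed_anova_oracle <- function(df) {
  # df: participant_id, instruction, difficulty, value; balanced groups
  Y <- mean(df$value)
  subj <- split(df$value, df$participant_id)
  subj_mean <- vapply(subj, mean, numeric(1))
  subj_grp <- vapply(split(df$instruction, df$participant_id),
                     function(x) x[1], character(1))
  k <- 2  # within levels
  grp_means <- tapply(df$value, df$instruction, mean)
  grp_n <- table(subj_grp)  # participants per group
  diff_means <- tapply(df$value, df$difficulty, mean)
  cell_means <- tapply(df$value, list(df$instruction, df$difficulty), mean)
  n_per_diff <- tapply(df$value, df$difficulty, length)

  ss_between_subj <- k * sum((subj_mean - Y)^2)
  ss_instruction <- k * sum(grp_n * (grp_means[names(grp_n)] - Y)^2)
  ss_subj_within_grp <- ss_between_subj - ss_instruction
  ss_difficulty <- sum(n_per_diff * (diff_means - Y)^2)
  ss_cells <- sum(outer(grp_n, c(1, 1)) *
                  (cell_means[names(grp_n), ] - Y)^2)
  ss_interaction <- ss_cells - ss_instruction - ss_difficulty
  ss_total <- sum((df$value - Y)^2)
  ss_error_within <- ss_total - ss_between_subj - ss_difficulty -
    ss_interaction
  n_subj <- length(subj_mean)
  df_err_b <- n_subj - 2
  df_err_w <- n_subj - 2
  list(
    F_instruction = (ss_instruction / 1) / (ss_subj_within_grp / df_err_b),
    F_difficulty = (ss_difficulty / 1) / (ss_error_within / df_err_w),
    F_interaction = (ss_interaction / 1) / (ss_error_within / df_err_w),
    ges_instruction = ss_instruction /
      (ss_instruction + ss_subj_within_grp + ss_error_within),
    ges_difficulty = ss_difficulty /
      (ss_difficulty + ss_subj_within_grp + ss_error_within),
    ges_interaction = ss_interaction /
      (ss_interaction + ss_subj_within_grp + ss_error_within))
}

# High-resolution Simpson quadrature of the JZS Bayes-factor integral on
# the substitution g = u / (1 - u), u in (0, 1).
jzs_quadrature_oracle <- function(t, n, rscale = sqrt(2) / 2,
                                  n_points = 200001) {
  nu <- n - 1
  u <- seq(1e-9, 1 - 1e-9, length.out = n_points)
  g <- u / (1 - u)
  jac <- 1 / (1 - u)^2
  f <- (1 + n * g)^(-0.5) *
    (1 + t^2 / ((1 + n * g) * nu))^(-(nu + 1) / 2) *
    rscale / sqrt(2 * pi) * g^(-1.5) * exp(-rscale^2 / (2 * g)) * jac
  h <- u[2] - u[1]
  w <- rep(c(4, 2), length.out = n_points - 2)
  integral <- h / 3 * (f[1] + sum(w * f[2:(n_points - 1)]) + f[n_points])
  integral / (1 + t^2 / nu)^(-(nu + 1) / 2)
}

# Small trial-table builder for exclusion fixtures: one participant block
# with full control over validity of individual trials.
make_participant_trials <- function(id, instruction = "bet",
                                    n_per_diff = 36, pre = NULL,
                                    response = NULL, post = NULL,
                                    rt = 800) {
  n <- 2 * n_per_diff
  set.seed(nchar(id) + utf8ToInt(substr(id, 1, 1)))
  df <- data.frame(
    participant_id = id, instruction = instruction,
    difficulty = rep(c("easy", "hard"), each = n_per_diff),
    session = rep(1:6, each = n / 6), trial = rep(1:(n / 6), 6),
    stimulus = rep(c("match", "nonmatch"), n / 2),
    pre_rating = if (is.null(pre)) rep(c(1L, 2L), n / 2) else pre,
    type1_response = if (is.null(response)) {
      rep(c("match", "nonmatch"), n / 2)
    } else response,
    post_rating = if (is.null(post)) rep(c(1L, 3L, 5L), length.out = n)
                  else post,
    rt_pre = rt, rt_answer = rt, rt_post = rt,
    stringsAsFactors = FALSE)
  df
}
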