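test_that("betting scores follow the payoff rule", {
  expect_identical(compute_trial_score(c(2, 2, 1, 1),
                                       c(TRUE, FALSE, TRUE, FALSE)),
                   c(2L, -1L, 1L, 0L))
  expect_error(compute_trial_score(c(2, NA), c(TRUE, TRUE)), "missing")
  expect_error(compute_trial_score(3, TRUE), "1 \\(low\\) or")
})

test_that("trial and participant exclusions follow the study rules", {
  clean <- make_participant_trials("A")
  # one fast pre-rating trial is dropped but the participant is kept
  fast <- make_participant_trials("B")
  fast$rt_pre[3] <- 50
  # all-identical pre-ratings in the easy condition
  fixed <- make_participant_trials("C")
  fixed$pre_rating[fixed$difficulty == "easy"] <- 2L
  # 20 missing answers in the hard condition -> 16 valid < 18
  sparse <- make_participant_trials("D")
  idx <- which(sparse$difficulty == "hard")[1:20]
  sparse$type1_response[idx] <- NA
  sparse$rt_answer[idx] <- NA

  res <- apply_exclusions(rbind(clean, fast, fixed, sparse))
  rep <- res$report
  expect_equal(sort(unique(res$trials$participant_id)), c("A", "B"))
  expect_false(rep$excluded[rep$participant_id == "A"])
  expect_equal(rep$n_excluded_trials[rep$participant_id == "B"], 1)
  expect_match(rep$reason[rep$participant_id == "C"],
               "identical pre-rating")
  expect_match(rep$reason[rep$participant_id == "C"], "easy")
  expect_match(rep$reason[rep$participant_id == "D"], "fewer than 18")
  expect_equal(rep$n_valid_hard[rep$participant_id == "D"], 16)

  # three-participant fixture: clean / fixed-easy / sparse-hard
  res3 <- apply_exclusions(rbind(clean, fixed, sparse))
  expect_equal(unique(res3$trials$participant_id), "A")
  expect_equal(sum(res3$report$excluded), 2)
})

test_that("exclusion is idempotent", {
  sim <- simulate_task_data(simulation_config(
    n_bet = 8, n_confidence = 8, lapse_rate = 0.1, dropout_rate = 0.3,
    seed = 61))
  once <- apply_exclusions(sim$trials)
  twice <- apply_exclusions(once$trials)
  expect_identical(once$trials, twice$trials)
  expect_true(any(once$report$excluded))  # dropouts present at this rate
})

test_that("participant summaries agree with their building blocks", {
  tr <- make_participant_trials("A", n_per_diff = 36)
  # force a known accuracy: 27 correct of 36 in easy
  easy <- which(tr$difficulty == "easy")
  tr$type1_response[easy] <- tr$stimulus[easy]
  tr$type1_response[easy[1:9]] <-
    ifelse(tr$stimulus[easy[1:9]] == "match", "nonmatch", "match")
  s <- summarize_participants(tr)
  expect_equal(s$accuracy[s$difficulty == "easy"], 27 / 36)
  expect_equal(s$n_valid_trials, c(36, 36))

  # d' equals compute_type1_sdt on the same margins
  arr <- array(0, dim = c(2, 2, 2))
  sub <- tr[tr$difficulty == "easy", ]
  for (i in seq_len(nrow(sub))) {
    si <- if (sub$stimulus[i] == "match") 2 else 1
    ri <- if (sub$type1_response[i] == "match") 2 else 1
    arr[si, ri, 1] <- arr[si, ri, 1] + 1
  }
  t1 <- compute_type1_sdt(rating_counts(arr))
  expect_equal(s$d_prime[s$difficulty == "easy"], t1$d_prime)

  # score conservation: total equals the sum of per-trial scores
  correct <- sub$type1_response == sub$stimulus
  expect_equal(s$total_score[s$difficulty == "easy"],
               sum(compute_trial_score(sub$pre_rating, correct)))
})

test_that("mixed ANOVA matches the sums-of-squares oracle exactly", {
  toy <- data.frame(
    participant_id = rep(c("p1", "p2", "p3", "p4"), each = 2),
    instruction = rep(c("bet", "bet", "confidence", "confidence"),
                      each = 2),
    difficulty = rep(c("easy", "hard"), 4),
    value = c(1.0, 2.0, 1.5, 2.1, 0.8, 2.6, 1.2, 2.9))
  res <- mixed_anova(toy)
  oracle <- ss_mixed_anova_oracle(toy)
  expect_equal(res$statistic[res$effect == "instruction"],
               oracle$F_instruction, tolerance = 1e-10)
  expect_equal(res$statistic[res$effect == "difficulty"],
               oracle$F_difficulty, tolerance = 1e-10)
  expect_equal(res$statistic[res$effect == "interaction"],
               oracle$F_interaction, tolerance = 1e-10)
  expect_equal(res$ges[res$effect == "instruction"],
               oracle$ges_instruction, tolerance = 1e-10)
  expect_equal(res$ges[res$effect == "difficulty"],
               oracle$ges_difficulty, tolerance = 1e-10)
  expect_equal(res$ges[res$effect == "interaction"],
               oracle$ges_interaction, tolerance = 1e-10)
})

test_that("mixed ANOVA handles degenerate and structured inputs", {
  const <- data.frame(
    participant_id = rep(paste0("p", 1:6), each = 2),
    instruction = rep(c("bet", "confidence"), each = 6),
    difficulty = rep(c("easy", "hard"), 6), value = 5)
  res <- mixed_anova(const)
  expect_equal(res$statistic, c(0, 0, 0))

  # a pure within effect: difficulty adds +1 for every participant
  set.seed(9)
  base <- rep(rnorm(8, sd = 1e-3), each = 2)
  wd <- data.frame(
    participant_id = rep(paste0("p", 1:8), each = 2),
    instruction = rep(c("bet", "confidence"), each = 8),
    difficulty = rep(c("easy", "hard"), 8),
    value = base + rep(c(0, 1), 8) + rnorm(16, sd = 1e-4))
  res_wd <- mixed_anova(wd)
  expect_gt(res_wd$statistic[res_wd$effect == "difficulty"], 1e4)
  expect_lt(res_wd$p_value[res_wd$effect == "difficulty"], 1e-10)
  expect_gt(res_wd$p_value[res_wd$effect == "instruction"], 0.05)

  bad <- const[-2, ]
  expect_error(mixed_anova(bad), "p1")
})

test_that("generalized eta squared stays within [0, 1]", {
  set.seed(33)
  for (i in 1:10) {
    d <- data.frame(
      participant_id = rep(paste0("p", 1:10), each = 2),
      instruction = rep(c("bet", "confidence"), each = 10),
      difficulty = rep(c("easy", "hard"), 10),
      value = rnorm(20, sd = runif(1, 0.1, 3)))
    res <- mixed_anova(d)
    expect_true(all(res$ges >= 0 & res$ges <= 1))
  }
})

test_that("permuted group labels give null-like instruction tests", {
  set.seed(40)
  n <- 20
  base <- rnorm(n)
  p_vals <- replicate(200, {
    labs <- sample(rep(c("bet", "confidence"), each = n / 2))
    d <- data.frame(
      participant_id = rep(paste0("p", 1:n), each = 2),
      instruction = rep(labs, each = 2),
      difficulty = rep(c("easy", "hard"), n),
      value = rep(base, each = 2) + rnorm(2 * n, sd = 0.5))
    mixed_anova(d)$p_value[1]
  })
  expect_gt(mean(p_vals < 0.05), 0.005)
  expect_lt(mean(p_vals < 0.05), 0.12)
})

test_that("JZS Bayes factor matches a quadrature oracle", {
  # fixed 10-pair dataset
  x <- c(5.1, 4.8, 6.0, 5.5, 4.9, 5.7, 5.2, 6.1, 5.0, 5.4)
  y <- c(4.6, 4.9, 5.1, 5.0, 4.4, 5.3, 4.8, 5.6, 4.9, 4.8)
  res <- paired_t_with_bf(x, y)
  t_stat <- res$statistic
  expect_equal(res$df, 9)
  expect_equal(res$cohens_d, mean(x - y) / sd(x - y), tolerance = 1e-12)
  oracle <- jzs_quadrature_oracle(t_stat, 10)
  expect_equal(res$bf10, oracle, tolerance = 1e-6)

  # anchors frozen from an independent implementation (pingouin
  # bayesfactor_ttest): t = 2.24, n = 80 pairs
  expect_equal(bf10_jzs(2.24, 80, rscale = 1), 0.9762771, tolerance = 1e-4)
  expect_equal(bf10_jzs(2.24, 80), 1.2986364, tolerance = 1e-3)
})

test_that("paired t test flags degenerate inputs and decisive effects", {
  x <- rnorm(10)
  expect_error(paired_t_with_bf(x, x), "zero-variance")
  expect_error(paired_t_with_bf(x[1:2], x[1:2] + 1), "at least 3")
  set.seed(5)
  a <- rnorm(20)
  res <- paired_t_with_bf(a + 1 + rnorm(20, sd = 1e-6), a)
  expect_gt(abs(res$statistic), 1e4)
  expect_gt(res$bf10, 3)
  # identical-mean data: BF favors the null
  set.seed(6)
  b <- rnorm(30)
  res0 <- paired_t_with_bf(b + rnorm(30, sd = 0.2), b + rnorm(30, sd = 0.2))
  expect_lt(res0$bf10, 1)
})

test_that("Levene tests detect variance differences with Holm control", {
  set.seed(51)
  n <- 100
  d <- data.frame(
    participant_id = rep(paste0("p", 1:(2 * n)), 2),
    instruction = rep(rep(c("bet", "confidence"), each = n), 2),
    difficulty = rep(c("easy", "hard"), each = 2 * n),
    value = c(rnorm(n, sd = 1), rnorm(n, sd = 4),
              rnorm(n, sd = 1), rnorm(n, sd = 4)))
  res <- levene_holm(d)
  expect_equal(nrow(res), 2)
  expect_true(all(res$adjusted_p < 0.05))
  expect_true(all(res$adjusted_p >= res$p_value))
  # Holm arithmetic on the function's own raw p values
  expect_equal(res$adjusted_p,
               pmin(1, cummax(sort(res$p_value) * c(2, 1)))[
                 rank(res$p_value)])
  expect_error(levene_holm(data.frame(
    participant_id = 1:4, instruction = rep(c("bet", "confidence"), 2),
    difficulty = "easy", value = 1)), "degenerate")
})
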