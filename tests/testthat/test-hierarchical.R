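# small simulated cohorts for the hierarchical model tests
sim_cells <- function(n_per_group, seed, phase = "pre", ...) {
  cfg <- simulation_config(n_bet = n_per_group, n_confidence = n_per_group,
                           lapse_rate = 0, dropout_rate = 0, seed = seed,
                           ...)
  sim <- simulate_task_data(cfg)
  prepare_mratio_cells(sim$trials, phase)
}

test_that("the reproducibility contract is enforced and honored", {
  cells <- sim_cells(3, seed = 71)
  expect_error(fit_hierarchical_mratio(cells, iterations = 200,
                                       burnin = 50), "seed")
  f1 <- fit_hierarchical_mratio(cells, chains = 2, iterations = 300,
                                burnin = 100, seed = 5)
  f2 <- fit_hierarchical_mratio(cells, chains = 2, iterations = 300,
                                burnin = 100, seed = 5)
  expect_identical(f1$draws, f2$draws)
  f3 <- fit_hierarchical_mratio(cells, chains = 2, iterations = 300,
                                burnin = 100, seed = 6)
  expect_false(identical(f1$draws, f3$draws))
})

test_that("cell validation catches malformed designs", {
  cells <- sim_cells(3, seed = 72)
  expect_error(fit_hierarchical_mratio(cells[-1, ], iterations = 200,
                                       burnin = 50, seed = 1),
               "exactly one easy and one hard")
  bad <- cells
  bad$instruction[1] <- "confidence"
  expect_error(fit_hierarchical_mratio(bad, iterations = 200, burnin = 50,
                                       seed = 1), "inconsistent")
  two <- cells[cells$instruction == "bet", ]
  expect_error(fit_hierarchical_mratio(two, iterations = 200, burnin = 50,
                                       seed = 1), "2 participants per")
  nf <- cells
  nf$d_prime[3] <- NaN
  expect_error(fit_hierarchical_mratio(nf, iterations = 200, burnin = 50,
                                       seed = 1), "non-finite")
})

test_that("with no data the effect posteriors reproduce their priors", {
  K <- 2
  empty <- rating_counts(array(0, dim = c(2, 2, K)))
  cells <- data.frame(
    participant_id = rep(paste0("p", 1:4), each = 2),
    instruction = rep(c("bet", "confidence"), each = 4),
    difficulty = rep(c("easy", "hard"), 4),
    d_prime = 1, criterion = 0, stringsAsFactors = FALSE)
  cells$counts <- I(replicate(8, empty, simplify = FALSE))
  fit <- fit_hierarchical_mratio(cells, chains = 3, iterations = 4000,
                                 burnin = 500, seed = 9)
  draws <- fit$draws
  for (p in c("mu", "b_instruction", "b_difficulty", "b_interaction")) {
    expect_lt(abs(mean(draws[, , p])), 0.08)
    expect_lt(abs(sd(draws[, , p]) - 1), 0.08)
  }
  # half-normal(1) prior: mean sqrt(2/pi) ~ 0.798
  expect_lt(abs(mean(draws[, , "sigma_u"]) - sqrt(2 / pi)), 0.08)
})

test_that("swapping instruction labels flips the instruction effect", {
  cells <- sim_cells(10, seed = 73)
  fit1 <- fit_hierarchical_mratio(cells, chains = 3, iterations = 1200,
                                  burnin = 400, seed = 21)
  swapped <- cells
  swapped$instruction <- ifelse(cells$instruction == "bet", "confidence",
                                "bet")
  fit2 <- fit_hierarchical_mratio(swapped, chains = 3, iterations = 1200,
                                  burnin = 400, seed = 21)
  m1 <- median(fit1$draws[, , "b_instruction"])
  m2 <- median(fit2$draws[, , "b_instruction"])
  expect_lt(abs(m1 + m2), 0.12)
  # grand mean is invariant to the label swap
  expect_lt(abs(median(fit1$draws[, , "mu"]) -
                median(fit2$draws[, , "mu"])), 0.12)
})

test_that("identical duplicated participants leave no between-participant variance", {
  cfg <- simulation_config(n_bet = 2, n_confidence = 2, lapse_rate = 0,
                           dropout_rate = 0, seed = 74)
  sim <- simulate_task_data(cfg)
  cells1 <- prepare_mratio_cells(sim$trials, "pre", stabilize_type1 = FALSE)
  # duplicate each of the 4 participants 5 times with identical counts
  reps <- do.call(rbind, lapply(1:5, function(k) {
    c2 <- cells1
    c2$participant_id <- paste0(c2$participant_id, "_", k)
    c2
  }))
  fit <- fit_hierarchical_mratio(reps, chains = 3, iterations = 1500,
                                 burnin = 500, seed = 31)
  # sigma_u concentrates near the low end of its prior
  expect_lt(median(fit$draws[, , "sigma_u"]), 0.3)
})

test_that("the sampler agrees with JAGS on the same model and data", {
  # both samplers run with type-1 parameters fixed, so drop the
  # uncertainty columns that would switch ours to sampled type-1
  cells <- sim_cells(6, seed = 75)
  cells <- cells[setdiff(names(cells),
                         c("d_prime_sd", "criterion_sd",
                           "d_prime_group_sd", "criterion_group_sd"))]
  model_string <- "
  model {
    mu ~ dnorm(0, 1)
    bI ~ dnorm(0, 1)
    bD ~ dnorm(0, 1)
    bID ~ dnorm(0, 1)
    sigma_u ~ dnorm(0, 1) T(0,)
    sigma_e ~ dnorm(0, 1) T(0,)
    tau_u <- pow(sigma_u, -2)
    tau_e <- pow(sigma_e, -2)
    for (s in 1:S) {
      u[s] ~ dnorm(0, tau_u)
      for (c in 1:2) {
        dlow[s,c] ~ dnorm(0, 1) T(0.0001,)
        dhigh[s,c] ~ dnorm(0, 1) T(0.0001,)
        e[s,c] ~ dnorm(0, tau_e)
        lambda[s,c] <- mu + bI*xI[s] + bD*xD[c] + bID*xI[s]*xD[c] +
                       u[s] + e[s,c]
        metad[s,c] <- exp(lambda[s,c]) * dprime[s,c]
        cpr[s,c] <- crit[s,c] * exp(lambda[s,c])
        tl[s,c] <- cpr[s,c] - dlow[s,c]
        th[s,c] <- cpr[s,c] + dhigh[s,c]
        for (i in 1:2) {
          m2[s,c,i] <- (2*i - 3) * metad[s,c] / 2
          pc[s,c,i] <- phi(cpr[s,c] - m2[s,c,i])
          q1[s,c,i] <- max(pc[s,c,i] - phi(tl[s,c] - m2[s,c,i]), 1e-10)
          q2[s,c,i] <- max(phi(tl[s,c] - m2[s,c,i]), 1e-10)
          q3[s,c,i] <- max(phi(th[s,c] - m2[s,c,i]) - pc[s,c,i], 1e-10)
          q4[s,c,i] <- max(1 - phi(th[s,c] - m2[s,c,i]), 1e-10)
          r_nm[s,c,i] ~ dbin(q1[s,c,i] / (q1[s,c,i] + q2[s,c,i]),
                             n_nm[s,c,i])
          r_m[s,c,i] ~ dbin(q3[s,c,i] / (q3[s,c,i] + q4[s,c,i]),
                            n_m[s,c,i])
        }
      }
    }
  }"
  ids <- unique(cells$participant_id)
  S <- length(ids)
  r_nm <- n_nm <- r_m <- n_m <- array(0, dim = c(S, 2, 2))
  dprime <- crit <- matrix(0, S, 2)
  for (s in seq_len(S)) for (ci in 1:2) {
    row <- which(cells$participant_id == ids[s] &
                 cells$difficulty == c("easy", "hard")[ci])
    arr <- unclass(cells$counts[[row]])
    for (i in 1:2) {
      r_nm[s, ci, i] <- arr[i, 1, 1]
      n_nm[s, ci, i] <- sum(arr[i, 1, ])
      r_m[s, ci, i] <- arr[i, 2, 1]
      n_m[s, ci, i] <- sum(arr[i, 2, ])
    }
    dprime[s, ci] <- cells$d_prime[row]
    crit[s, ci] <- cells$criterion[row]
  }
  xI <- ifelse(cells$instruction[match(ids, cells$participant_id)] ==
               "confidence", 0.5, -0.5)
  jm <- rjags::jags.model(
    textConnection(model_string),
    data = list(r_nm = r_nm, n_nm = n_nm, r_m = r_m, n_m = n_m,
                dprime = dprime, crit = crit, xI = xI,
                xD = c(-0.5, 0.5), S = S),
    inits = list(.RNG.name = "base::Mersenne-Twister", .RNG.seed = 777),
    n.chains = 1, n.adapt = 500, quiet = TRUE)
  jsamp <- rjags::coda.samples(jm, c("mu", "bI", "bD", "bID"),
                               n.iter = 4000)[[1]]
  fit <- fit_hierarchical_mratio(cells, chains = 3, iterations = 2500,
                                 burnin = 700, seed = 41)
  pairs <- c(mu = "mu", bI = "b_instruction", bD = "b_difficulty",
             bID = "b_interaction")
  for (nm in names(pairs)) {
    expect_lt(abs(median(fit$draws[, , pairs[[nm]]]) -
                  median(jsamp[, nm])), 0.15)
    expect_lt(abs(sd(fit$draws[, , pairs[[nm]]]) - sd(jsamp[, nm])) /
                sd(jsamp[, nm]), 0.35)
  }
})

test_that("posterior recovers cell-level log M-ratio with strong data", {
  cfg <- simulation_config(
    n_bet = 4, n_confidence = 4, sessions = 6, trials_per_session = 500,
    lapse_rate = 0, dropout_rate = 0,
    pre = list(mu = log(0.7), beta_I = 0, beta_D = 0, beta_ID = 0,
               sigma_u = 0, sigma_e = 0),
    seed = 76)
  sim <- simulate_task_data(cfg)
  cells <- prepare_mratio_cells(sim$trials, "pre")
  fit <- fit_hierarchical_mratio(cells, chains = 3, iterations = 2000,
                                 burnin = 500, seed = 51)
  expect_lt(abs(median(fit$draws[, , "mu"]) - log(0.7)), 0.17)
  # per-cell posterior-mean log M-ratio also tracks the truth
  expect_lt(abs(mean(fit$cells$log_mratio_mean) - log(0.7)), 0.17)
})
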