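test_that("type-1 estimates match the closed-form z-difference", {
  arr <- array(0, dim = c(2, 2, 2))
  arr[2, 2, 1] <- 69; arr[2, 1, 1] <- 31   # match trials
  arr[1, 2, 1] <- 31; arr[1, 1, 1] <- 69   # nonmatch trials
  fit <- compute_type1_sdt(rating_counts(arr), correction = "none")
  expect_equal(fit$hit_rate, 0.69)
  expect_equal(fit$fa_rate, 0.31)
  expect_equal(fit$d_prime, qnorm(0.69) - qnorm(0.31), tolerance = 1e-12)
  expect_equal(fit$criterion, -0.5 * (qnorm(0.69) + qnorm(0.31)),
               tolerance = 1e-12)
  # equal hit and false-alarm rates cancel exactly
  arr2 <- array(c(28, 28, 12, 12, 6, 6, 14, 14), dim = c(2, 2, 2))
  fit2 <- compute_type1_sdt(rating_counts(arr2), correction = "none")
  expect_equal(fit2$d_prime, 0, tolerance = 1e-12)
})

test_that("edge correction keeps perfect performance finite", {
  arr <- array(0, dim = c(2, 2, 2))
  arr[2, 2, 1] <- 10   # all match trials answered match
  arr[1, 1, 1] <- 10   # all nonmatch answered nonmatch
  fit <- compute_type1_sdt(rating_counts(arr))
  expect_true(is.finite(fit$d_prime) && fit$d_prime > 0)
  # Hautus 1/(2K) per cell adds 0.5 per response margin
  expect_equal(fit$hit_rate, 10.5 / 11, tolerance = 1e-12)
  expect_error(compute_type1_sdt(rating_counts(arr), correction = "none"),
               "0 or 1")
})

test_that("type-1 estimates ignore rating labels", {
  set.seed(3)
  arr <- array(rpois(20, 8), dim = c(2, 2, 5))
  perm <- arr[, , c(4, 1, 5, 3, 2)]
  f1 <- compute_type1_sdt(rating_counts(arr))
  f2 <- compute_type1_sdt(rating_counts(perm))
  expect_equal(f1$d_prime, f2$d_prime)
  expect_equal(f1$criterion, f2$criterion)
})

test_that("empty stimulus classes are reported by name", {
  arr <- array(0, dim = c(2, 2, 2))
  arr[2, 2, 1] <- 5
  expect_error(compute_type1_sdt(rating_counts(arr)), "nonmatch")
  arr2 <- array(0, dim = c(2, 2, 2))
  arr2[1, 1, 1] <- 5
  expect_error(compute_type1_sdt(rating_counts(arr2)), "'match'")
})

test_that("type-2 probabilities normalize and lose information at meta-d' 0", {
  set.seed(14)
  for (i in 1:10) {
    K <- sample(2:6, 1)
    md <- runif(1, -2, 2)
    crit <- runif(1, -0.5, 0.5)
    cpr <- crit * md / 1.2
    t2c <- c(cpr - rev(cumsum(runif(K - 1, 0.05, 0.8))),
             cpr + cumsum(runif(K - 1, 0.05, 0.8)))
    p <- type2_probabilities(md, 1.2, crit, t2c, K)
    expect_equal(as.vector(apply(p, c(1, 2), sum)), rep(1, 4),
                 tolerance = 1e-9)
  }
  # zero meta-d': rating distribution identical for the two stimulus
  # classes within each response (no accuracy information)
  p0 <- type2_probabilities(0, 1, 0.3, c(-0.9, -0.4, 0.4, 0.9), K = 3)
  expect_equal(p0[1, , ], p0[2, , ], tolerance = 1e-12)
})

test_that("type-2 probabilities match direct numerical integration", {
  # meta-d' = d' = 1, c = 0, symmetric criteria at +/- 0.5
  p <- type2_probabilities(1, 1, 0, c(-0.5, 0.5), K = 2)
  for (i in 1:2) {
    mu <- c(-0.5, 0.5)[i]
    for (r in 1:2) {
      bounds <- if (r == 1) list(c(-0.5, 0), c(-Inf, -0.5)) else
        list(c(0, 0.5), c(0.5, Inf))
      denom <- integrate(dnorm, if (r == 1) -Inf else 0,
                         if (r == 1) 0 else Inf, mean = mu)$value
      for (k in 1:2) {
        num <- integrate(dnorm, bounds[[k]][1], bounds[[k]][2],
                         mean = mu)$value
        expect_equal(p[i, r, k], num / denom, tolerance = 1e-6)
      }
    }
  }
})

test_that("criterion ordering violations identify the offending pair", {
  expect_error(type2_probabilities(1, 1, 0, c(0.5, -0.5), K = 2),
               "ordering violated")
  expect_error(type2_probabilities(1, 1, 0, c(-0.2, -0.4, 0.1, 0.5), K = 3),
               "positions")
})

test_that("meta-d' MLE agrees with the grid-search oracle", {
  # a fixed 2x2x2 example table
  arr <- array(0, dim = c(2, 2, 2))
  arr[1, 1, ] <- c(20, 10); arr[1, 2, ] <- c(8, 12)
  arr[2, 1, ] <- c(9, 6);   arr[2, 2, ] <- c(11, 24)
  cnt <- rating_counts(arr)
  fit <- fit_meta_d_mle(cnt)
  oracle <- grid_search_meta_d(cnt, fit$d_prime, fit$criterion)
  expect_lt(abs(fit$meta_d - oracle$meta_d), 0.02)
  expect_true(fit$converged)
  expect_equal(fit$m_ratio, fit$meta_d / fit$d_prime, tolerance = 1e-12)

  # a handful of random tables
  set.seed(21)
  for (i in 1:5) {
    arr <- array(rpois(8, lambda = sample(5:25, 8, replace = TRUE)),
                 dim = c(2, 2, 2))
    arr[arr == 0] <- 1
    cnt <- rating_counts(arr)
    fit <- fit_meta_d_mle(cnt)
    oracle <- grid_search_meta_d(cnt, fit$d_prime, fit$criterion)
    expect_lt(abs(fit$meta_d - oracle$meta_d), 0.02)
  }
})

test_that("accuracy-independent ratings yield meta-d' near zero", {
  set.seed(8)
  n <- 4000
  stim <- 1L + (runif(n) < 0.5)
  x <- rnorm(n, mean = (2 * stim - 3) * 0.5)
  resp <- 1L + (x > 0)
  rating <- sample(1:2, n, replace = TRUE)  # pure noise ratings
  arr <- array(0, dim = c(2, 2, 2))
  for (t in seq_len(n)) arr[stim[t], resp[t], rating[t]] <-
      arr[stim[t], resp[t], rating[t]] + 1
  fit <- fit_meta_d_mle(rating_counts(arr))
  expect_lt(abs(fit$meta_d), 0.12)
})

test_that("rating counts round-trip through CSV", {
  set.seed(4)
  arr <- array(rpois(20, 6), dim = c(2, 2, 5))
  cnt <- rating_counts(arr)
  path <- withr::local_tempfile(fileext = ".csv")
  write_rating_counts(cnt, path)
  back <- read_rating_counts(path)
  expect_equal(unclass(back), unclass(cnt), ignore_attr = TRUE)
})

test_that("rating_counts enforces its invariants", {
  expect_error(rating_counts(array(-1, dim = c(2, 2, 2))), "non-negative")
  expect_error(rating_counts(array(1.5, dim = c(2, 2, 2))), "integer")
  expect_error(rating_counts(array(1, dim = c(2, 2, 1))), "K must be >= 2")
  df <- data.frame(stimulus = "match", response = "match", rating = 3,
                   count = 2)
  expect_equal(sum(rating_counts(df, K = 5)), 2)
})
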