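#' Type-1 signal detection estimates
#'
#' Computes d' and the decision criterion c from the stimulus x response
#' margins of a rating count table. With the "match" class as signal, the
#' hit rate is P(respond match | match stimulus) and the false-alarm rate is
#' P(respond match | nonmatch stimulus), so that
#' `d' = z(HR) - z(FAR)` and `c = -0.5 * (z(HR) + z(FAR))`.
#'
#' The default edge correction (`"hautus"`) adds `1/(2K)` to every cell of
#' the count table before forming the rates, which keeps the normal
#' quantiles finite for perfect or empty response cells. `"none"` uses the
#' raw proportions (finite only when neither rate is 0 or 1).
#'
#' @param counts a [rating_counts] object (or a plain `2 x 2 x K` array).
#' @param correction `"hautus"` (default) or `"none"`.
#' @return an object of class `type1_fit`: a list with elements `d_prime`,
#'   `criterion`, `hit_rate`, `fa_rate`, `n_match`, `n_nonmatch`.
#' @examples
#' counts <- rating_counts(array(c(35, 15, 5, 10, 15, 35, 10, 20),
#'                               dim = c(2, 2, 2)))
#' compute_type1_sdt(counts)
#' @export
compute_type1_sdt <- function(counts, correction = c("hautus", "none")) {
  correction <- match.arg(correction)
  arr <- unclass(counts)
  K <- dim(arr)[3]
  n_stim <- apply(arr, 1, sum)
  if (n_stim[1] <= 0) stop("no trials in stimulus class 'nonmatch'")
  if (n_stim[2] <= 0) stop("no trials in stimulus class 'match'")
  if (correction == "hautus") arr <- arr + 1 / (2 * K)
  # margins over ratings: [stimulus, response]
  m <- apply(arr, c(1, 2), sum)
  hit_rate <- m[2, 2] / sum(m[2, ])
  fa_rate <- m[1, 2] / sum(m[1, ])
  if (correction == "none" &&
      any(c(hit_rate, fa_rate) %in% c(0, 1))) {
    stop("hit or false-alarm rate is 0 or 1; use correction = 'hautus'")
  }
  zh <- stats::qnorm(hit_rate)
  zf <- stats::qnorm(fa_rate)
  structure(list(d_prime = zh - zf,
                 criterion = -0.5 * (zh + zf),
                 hit_rate = hit_rate,
                 fa_rate = fa_rate,
                 n_match = unname(n_stim[2]),
                 n_nonmatch = unname(n_stim[1])),
            class = "type1_fit")
}

#' @export
print.type1_fit <- function(x, ...) {
  cat(sprintf("Type-1 SDT fit: d' = %.3f, c = %.3f (HR = %.3f, FAR = %.3f)\n",
              x$d_prime, x$criterion, x$hit_rate, x$fa_rate))
  invisible(x)
}

# Full ascending type-2 criterion vector from the scaled type-1 criterion
# c' and positive outward increments (first K-1 below c', last K-1 above).
.t2c_from_increments <- function(cprime, inc_low, inc_high) {
  c(rev(cprime - cumsum(inc_low)), cprime + cumsum(inc_high))
}

#' Response-conditional type-2 rating probabilities
#'
#' Evaluates the response-conditional Gaussian type-2 model: evidence for
#' the metacognitive observer is normal with means `-meta_d/2` (nonmatch
#' stimulus) and `+meta_d/2` (match stimulus) and unit variance; the type-1
#' decision axis is partitioned at the scaled criterion
#' `c' = criterion * meta_d / d_prime`, and each response region is further
#' partitioned by `K - 1` ordered type-2 criteria per side. Rating
#' probabilities are the truncated-normal masses of those segments,
#' conditional on the response region.
#'
#' @param meta_d type-2 sensitivity, in d' (z) units.
#' @param d_prime,criterion type-1 sensitivity and criterion (fixed).
#' @param type2_criteria ascending numeric vector of length `2 * (K - 1)`:
#'   the `K - 1` criteria below `c'` followed by the `K - 1` criteria above
#'   `c'`.
#' @param K number of rating levels.
#' @return a `2 x 2 x K` array `P(rating = k | stimulus, response)`; each
#'   `(stimulus, response)` row sums to 1.
#' @examples
#' p <- type2_probabilities(1, 1, 0, c(-0.5, 0.5), K = 2)
#' apply(p, c(1, 2), sum)  # all 1
#' @export
type2_probabilities <- function(meta_d, d_prime, criterion, type2_criteria,
                                K) {
  if (d_prime == 0) stop("d_prime must be non-zero")
  if (length(type2_criteria) != 2 * (K - 1)) {
    stop("type2_criteria must have length 2*(K-1) = ", 2 * (K - 1))
  }
  cprime <- criterion * meta_d / d_prime
  tc <- c(type2_criteria[seq_len(K - 1)], cprime,
          type2_criteria[K - 1 + seq_len(K - 1)])
  bad <- which(diff(tc) < 0)
  if (length(bad) > 0) {
    stop(sprintf(
      "type-2 criterion ordering violated between positions %d (%.4f) and %d (%.4f) around c' = %.4f",
      bad[1], tc[bad[1]], bad[1] + 1, tc[bad[1] + 1], cprime))
  }
  out <- array(NA_real_, dim = c(2, 2, K),
               dimnames = list(stimulus = c("nonmatch", "match"),
                               response = c("nonmatch", "match"),
                               rating = as.character(seq_len(K))))
  lo <- tc[seq_len(K - 1)]
  hi <- tc[K - 1 + 1 + seq_len(K - 1)]
  for (i in 1:2) {
    mu <- (if (i == 1) -1 else 1) * meta_d / 2
    # nonmatch response: region (-Inf, c'], ratings increase away from c'
    b_nm <- c(-Inf, lo, cprime)
    seg_nm <- diff(stats::pnorm(b_nm, mean = mu))
    denom_nm <- stats::pnorm(cprime, mean = mu)
    out[i, 1, ] <- rev(seg_nm) / max(denom_nm, 1e-300)
    # match response: region [c', Inf), ratings increase away from c'
    b_m <- c(cprime, hi, Inf)
    seg_m <- diff(stats::pnorm(b_m, mean = mu))
    denom_m <- 1 - stats::pnorm(cprime, mean = mu)
    out[i, 2, ] <- seg_m / max(denom_m, 1e-300)
  }
  out
}

# Negative log-likelihood of response-conditional rating counts.
# counts may be non-integer (used for asymptotic calibration).
.meta_d_negll <- function(par, counts, d_prime, criterion, K) {
  meta_d <- par[1]
  inc <- exp(par[-1])
  cprime <- criterion * meta_d / d_prime
  tcrit <- .t2c_from_increments(cprime, inc[seq_len(K - 1)],
                                inc[K - 1 + seq_len(K - 1)])
  p <- type2_probabilities(meta_d, d_prime, criterion, tcrit, K)
  p <- pmax(p, 1e-12)
  -sum(counts * log(p))
}

#' Single-subject maximum-likelihood meta-d' fit
#'
#' Fits meta-d' and the type-2 criteria by maximizing the multinomial
#' likelihood of the observed rating counts conditional on stimulus and
#' response, with the type-1 parameters (d', c) fixed at their edge-corrected
#' point estimates. The criteria are parameterized as log-scale outward
#' increments from the scaled criterion c', which enforces the ordering
#' constraint; the optimizer is bounded quasi-Newton (`L-BFGS-B`) started
#' from three initial meta-d' values, with ties broken by highest likelihood
#' and then smallest `|meta-d'|`.
#'
#' @param counts a [rating_counts] object.
#' @param meta_d_bounds search interval for meta-d', default `c(-5, 5)`.
#' @return an object of class `meta_d_fit`: list with `meta_d`, `m_ratio`
#'   (`meta_d / d_prime`), `type2_criteria` (ascending, length `2(K-1)`),
#'   `d_prime`, `criterion`, `log_likelihood`, `converged`.
#' @examples
#' counts <- rating_counts(array(c(20, 9, 8, 11, 10, 6, 12, 24),
#'                               dim = c(2, 2, 2)))
#' fit_meta_d_mle(counts)
#' @export
fit_meta_d_mle <- function(counts, meta_d_bounds = c(-5, 5)) {
  t1 <- compute_type1_sdt(counts, correction = "hautus")
  .fit_meta_d_core(unclass(counts), t1$d_prime, t1$criterion, meta_d_bounds)
}

# Core fitter on a plain (possibly non-integer) 2 x 2 x K count array with
# type-1 parameters supplied by the caller.
.fit_meta_d_core <- function(arr, d_prime, criterion, meta_d_bounds = c(-5, 5)) {
  K <- dim(arr)[3]
  if (!is.finite(d_prime) || d_prime == 0) {
    stop("type-1 d' must be finite and non-zero for a meta-d' fit")
  }
  n_inc <- 2 * (K - 1)
  starts <- unique(pmin(pmax(c(0.5, 1, 1.5) * d_prime,
                             meta_d_bounds[1] + 1e-3),
                        meta_d_bounds[2] - 1e-3))
  best <- NULL
  any_conv <- FALSE
  for (s in starts) {
    par0 <- c(s, rep(log(0.5), n_inc))
    opt <- try(stats::optim(
      par0, .meta_d_negll, method = "L-BFGS-B",
      lower = c(meta_d_bounds[1], rep(log(1e-4), n_inc)),
      upper = c(meta_d_bounds[2], rep(log(20), n_inc)),
      counts = arr, d_prime = d_prime, criterion = criterion, K = K,
      control = list(maxit = 500)), silent = TRUE)
    if (inherits(opt, "try-error")) next
    conv <- opt$convergence == 0
    any_conv <- any_conv || conv
    if (is.null(best) ||
        opt$value < best$value - 1e-6 ||
        (abs(opt$value - best$value) <= 1e-6 &&
         abs(opt$par[1]) < abs(best$par[1]))) {
      best <- opt
      best$converged <- conv
    }
  }
  if (is.null(best)) stop("meta-d' optimization failed from all starts")
  meta_d <- best$par[1]
  inc <- exp(best$par[-1])
  cprime <- criterion * meta_d / d_prime
  structure(list(
    meta_d = meta_d,
    m_ratio = meta_d / d_prime,
    type2_criteria = .t2c_from_increments(cprime, inc[seq_len(K - 1)],
                                          inc[K - 1 + seq_len(K - 1)]),
    d_prime = d_prime,
    criterion = criterion,
    log_likelihood = -best$value,
    converged = best$converged
  ), class = "meta_d_fit")
}

#' @export
print.meta_d_fit <- function(x, ...) {
  cat(sprintf(
    "meta-d' fit: meta-d' = %.3f, d' = %.3f, M-ratio = %.3f (logL = %.2f%s)\n",
    x$meta_d, x$d_prime, x$m_ratio, x$log_likelihood,
    if (x$converged) "" else ", NOT converged"))
  invisible(x)
}
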