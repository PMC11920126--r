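#' Highest-density interval of a sample
#'
#' Shortest contiguous interval containing `ceiling(mass * n)` of the sorted
#' draws. For unimodal posteriors this approximates the highest posterior
#' density interval.
#'
#' @param draws numeric vector of at least 100 draws.
#' @param mass interval probability mass, in (0, 1); default 0.95.
#' @return named numeric vector `c(lower, upper)`.
#' @examples
#' compute_hdi(rnorm(10000))
#' @export
compute_hdi <- function(draws, mass = 0.95) {
  if (!is.numeric(mass) || length(mass) != 1 || mass <= 0 || mass >= 1) {
    stop("mass must be a single number in (0, 1)")
  }
  draws <- draws[is.finite(draws)]
  n <- length(draws)
  if (n < 100) stop("need at least 100 draws for an HDI")
  x <- sort(draws)
  w <- ceiling(mass * n)
  if (w >= n) return(c(lower = x[1], upper = x[n]))
  widths <- x[w:n] - x[seq_len(n - w + 1)]
  i <- which.min(widths)
  c(lower = x[i], upper = x[i + w - 1])
}

#' Probability of direction
#'
#' The posterior probability that an effect is strictly of its dominant
#' sign: the larger of the fraction of draws above zero and below zero,
#' with draws exactly at zero split evenly. Always in `[0.5, 1]`.
#'
#' @param draws numeric vector of at least 100 draws.
#' @return a single number in `[0.5, 1]`.
#' @examples
#' compute_pd(rnorm(10000, mean = 1))  # about 0.84
#' @export
compute_pd <- function(draws) {
  draws <- draws[is.finite(draws)]
  n <- length(draws)
  if (n == 0) stop("empty draws vector")
  if (n < 100) stop("need at least 100 draws for pd")
  p_pos <- (sum(draws > 0) + 0.5 * sum(draws == 0)) / n
  max(p_pos, 1 - p_pos)
}

# ---- Convergence diagnostics (Vehtari et al. style) ----------------------

# Split each column (chain) in half -> matrix with 2x the chains.
.split_chains <- function(x) {
  n <- nrow(x)
  h <- floor(n / 2)
  cbind(x[seq_len(h), , drop = FALSE],
        x[(n - h + 1):n, , drop = FALSE])
}

# Rank-normalize the pooled draws, preserving the chain layout.
.rank_normalize <- function(x) {
  r <- rank(as.vector(x), ties.method = "average")
  z <- stats::qnorm((r - 3 / 8) / (length(r) + 1 / 4))
  matrix(z, nrow = nrow(x), ncol = ncol(x))
}

# Classic split-Rhat on a (possibly transformed) iterations x chains matrix.
.rhat_basic <- function(x) {
  x <- .split_chains(x)
  n <- nrow(x)
  m <- ncol(x)
  if (n < 2) return(NA_real_)
  means <- colMeans(x)
  vars <- apply(x, 2, stats::var)
  B <- n * stats::var(means)
  W <- mean(vars)
  if (W == 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Rank-normalized split R-hat
#'
#' Potential scale reduction factor computed on rank-normalized split
#' chains; the reported value is the maximum of the bulk statistic and the
#' statistic of the draws folded around their median (which is sensitive to
#' scale differences between chains). Values near 1 indicate convergence;
#' values at or above 1.01 are flagged downstream.
#'
#' @param x an iterations x chains numeric matrix of draws.
#' @return a single R-hat value.
#' @export
rhat_rank <- function(x) {
  x <- as.matrix(x)
  bulk <- .rhat_basic(.rank_normalize(x))
  folded <- .rhat_basic(.rank_normalize(abs(x - stats::median(x))))
  max(bulk, folded)
}

# Effective sample size of an iterations x chains matrix via chain
# autocorrelations combined with Geyer's initial monotone positive sequence.
.ess_basic <- function(x) {
  x <- .split_chains(as.matrix(x))
  n <- nrow(x)
  m <- ncol(x)
  if (n < 4) return(NA_real_)
  chain_var <- apply(x, 2, stats::var)
  W <- mean(chain_var)
  B_n <- stats::var(colMeans(x))       # B/n
  var_plus <- (n - 1) / n * W + B_n
  if (var_plus == 0) return(n * m)
  # per-chain autocovariances (biased, as in the split-ESS definition)
  max_lag <- n - 1
  acov <- sapply(seq_len(m), function(j) {
    a <- stats::acf(x[, j], lag.max = max_lag, type = "covariance",
                    plot = FALSE, demean = TRUE)$acf[, 1, 1]
    a * (n - 1) / n
  })
  mean_acov <- rowMeans(acov)
  rho <- 1 - (W - mean_acov) / var_plus   # rho[1] is lag 0 (= 1-ish)
  # Geyer paired sums over lags (1,2), (3,4), ...
  rho_t <- rho[-1]
  n_pairs <- floor(length(rho_t) / 2)
  if (n_pairs == 0) return(n * m)
  p <- rho_t[2 * seq_len(n_pairs) - 1] + rho_t[2 * seq_len(n_pairs)]
  # initial positive sequence
  k_max <- 0
  for (k in seq_len(n_pairs)) {
    if (p[k] > 0) k_max <- k else break
  }
  if (k_max == 0) return(n * m)
  p <- p[seq_len(k_max)]
  # initial monotone sequence
  p <- cummin(p)
  tau <- 1 + 2 * sum(p)
  max(n * m / tau, 1)
}

#' Tail effective sample size
#'
#' Minimum of the effective sample sizes of the 5% and 95% quantile
#' indicator functions, computed on split chains: a measure of how reliably
#' the tails (and hence HDI endpoints) are estimated.
#'
#' @param x an iterations x chains numeric matrix of draws.
#' @return a single ESS value.
#' @export
ess_tail <- function(x) {
  x <- as.matrix(x)
  q <- stats::quantile(as.vector(x), c(0.05, 0.95), names = FALSE)
  min(.ess_basic((x <= q[1]) * 1), .ess_basic((x <= q[2]) * 1))
}
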