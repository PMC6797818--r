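#' MCMC run configuration
#'
#' Defaults mirror the analysis protocol: 4 chains of 4,000 iterations
#' each, the first half used for warmup/adaptation. Test suites run
#' reduced chains with fixed seeds.
#'
#' @param chains Number of chains (>= 2 for convergence diagnostics).
#' @param iterations Total iterations per chain, warmup included.
#' @param warmup Warmup iterations per chain (default `iterations / 2`).
#' @param seed Integer RNG seed; chain c uses `seed + c - 1`.
#' @return An `mcmc_config` list.
#' @export
mcmc_config <- function(chains = 4, iterations = 4000,
                        warmup = floor(iterations / 2), seed = 1) {
  stopifnot(chains >= 1, iterations > warmup, warmup >= 0)
  structure(list(chains = as.integer(chains),
                 iterations = as.integer(iterations),
                 warmup = as.integer(warmup),
                 seed = as.integer(seed)),
            class = "mcmc_config")
}

new_posterior <- function(draws, model, data_info = list()) {
  # draws: [post-warmup iteration, chain, parameter] array, named parameters
  stopifnot(length(dim(draws)) == 3L, !is.null(dimnames(draws)[[3]]))
  structure(list(draws = draws, model = model, data_info = data_info),
            class = "mcmc_posterior")
}

#' Extract posterior draws for one parameter
#'
#' @param posterior An `mcmc_posterior`.
#' @param parameter Parameter name.
#' @param by_chain If `TRUE`, return an iterations x chains matrix;
#'   otherwise a flat vector over all chains.
#' @return Numeric vector or matrix of draws.
#' @export
posterior_draws <- function(posterior, parameter, by_chain = FALSE) {
  pars <- dimnames(posterior$draws)[[3]]
  if (!parameter %in% pars)
    stop("unknown parameter: ", parameter)
  m <- posterior$draws[, , parameter, drop = TRUE]
  m <- matrix(m, nrow = dim(posterior$draws)[1])
  if (by_chain) m else as.vector(m)
}

#' @export
print.mcmc_posterior <- function(x, ...) {
  d <- dim(x$draws)
  cat(sprintf("<mcmc_posterior: %s; %d draws x %d chains x %d parameters>\n",
              x$model, d[1], d[2], d[3]))
  invisible(x)
}

#' Summarise a posterior
#'
#' @param object An `mcmc_posterior`.
#' @param parameters Parameters to summarise (default all).
#' @param ... Unused.
#' @return Data frame with mean, sd, central 95% interval, r-hat and
#'   effective sample size per parameter.
#' @export
summary.mcmc_posterior <- function(object, parameters = NULL, ...) {
  pars <- dimnames(object$draws)[[3]]
  if (!is.null(parameters)) pars <- intersect(parameters, pars)
  out <- lapply(pars, function(p) {
    m <- posterior_draws(object, p, by_chain = TRUE)
    v <- as.vector(m)
    data.frame(parameter = p, mean = mean(v), sd = stats::sd(v),
               q2.5 = unname(stats::quantile(v, 0.025)),
               q97.5 = unname(stats::quantile(v, 0.975)),
               rhat = split_rhat(m), ess = ess_basic(m),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Split R-hat convergence diagnostic
#'
#' The potential scale reduction factor computed on split chains: each
#' chain is halved, and R-hat is the square root of the ratio of the
#' pooled-variance estimate to the mean within-chain variance. Values near
#' 1 indicate convergence.
#'
#' @param chains An iterations x chains matrix of draws for one parameter.
#' @return The split R-hat (scalar). `NA` if the draws are constant.
#' @export
split_rhat <- function(chains) {
  stopifnot(is.matrix(chains), ncol(chains) >= 1)
  n <- nrow(chains)
  half <- floor(n / 2)
  if (half < 2) stop("too few iterations for split R-hat")
  sub <- cbind(chains[seq_len(half), , drop = FALSE],
               chains[(n - half + 1):n, , drop = FALSE])
  m <- ncol(sub)
  if (m < 2) stop("split R-hat requires at least 2 (split) chains")
  means <- colMeans(sub)
  vars <- apply(sub, 2, stats::var)
  W <- mean(vars)
  B <- half * stats::var(means)
  if (W == 0) return(NA_real_)
  var_plus <- (half - 1) / half * W + B / half
  sqrt(var_plus / W)
}

#' Effective sample size
#'
#' Autocorrelation-based effective sample size across split chains, using
#' the initial-positive-sequence truncation of the summed autocorrelation.
#'
#' @param chains An iterations x chains matrix of draws for one parameter.
#' @return Estimated effective sample size.
#' @export
ess_basic <- function(chains) {
  stopifnot(is.matrix(chains))
  n <- nrow(chains)
  m <- ncol(chains)
  N <- n * m
  means <- colMeans(chains)
  vars <- apply(chains, 2, stats::var)
  W <- mean(vars)
  B <- if (m > 1) n * stats::var(means) else 0
  var_plus <- (n - 1) / n * W + if (m > 1) B / n else 0
  if (var_plus == 0) return(NA_real_)
  max_lag <- min(n - 1L, 1000L)
  # mean within-chain autocovariance at each lag
  acov <- matrix(0, nrow = max_lag + 1L, ncol = m)
  for (c in seq_len(m)) {
    a <- stats::acf(chains[, c], lag.max = max_lag, type = "covariance",
                    plot = FALSE, demean = TRUE)
    acov[, c] <- a$acf[, 1, 1]
  }
  mean_acov <- rowMeans(acov)
  rho <- 1 - (W - mean_acov) / var_plus
  # initial positive sequence: stop when a pair sum goes non-positive
  s <- 0
  t <- 1L
  while (t + 1L <= length(rho) - 1L) {
    pair <- rho[t + 1L] + rho[t + 2L]
    if (is.na(pair) || pair <= 0) break
    s <- s + pair
    t <- t + 2L
  }
  ess <- N / (1 + 2 * s)
  min(ess, N)
}

#' Convergence report for a posterior
#'
#' Computes split R-hat and effective sample size for every parameter and
#' flags the fit as converged if all R-hat values fall below the threshold.
#'
#' @param posterior An `mcmc_posterior`.
#' @param threshold R-hat pass threshold (default 1.01).
#' @return A `convergence_report`: data frame of per-parameter diagnostics
#'   plus attributes `pass` and `threshold`.
#' @export
check_convergence <- function(posterior, threshold = 1.01) {
  stopifnot(inherits(posterior, "mcmc_posterior"))
  if (dim(posterior$draws)[2] < 2)
    stop("convergence diagnostics require at least 2 chains")
  pars <- dimnames(posterior$draws)[[3]]
  rep <- do.call(rbind, lapply(pars, function(p) {
    m <- posterior_draws(posterior, p, by_chain = TRUE)
    data.frame(parameter = p, rhat = split_rhat(m), ess = ess_basic(m),
               stringsAsFactors = FALSE)
  }))
  rownames(rep) <- NULL
  pass <- all(is.na(rep$rhat) | rep$rhat < threshold)
  structure(rep, pass = pass, threshold = threshold,
            class = c("convergence_report", "data.frame"))
}

#' @export
print.convergence_report <- function(x, ...) {
  cat(sprintf("Convergence: %s (threshold %.3f)\n",
              if (attr(x, "pass")) "PASS" else "FAIL", attr(x, "threshold")))
  worst <- x[order(-x$rhat), , drop = FALSE]
  print.data.frame(utils::head(worst, 10), row.names = FALSE, digits = 4)
  invisible(x)
}

# inverse-gamma draw for a variance with flat-positive prior on the sd:
# p(sigma) ~ 1  =>  p(sigma^2) ~ (sigma^2)^(-1/2); conditional on a sum of
# squares SS over k terms is InvGamma((k - 1)/2, SS/2), proper for k >= 2.
draw_var_flat_sd <- function(k, ss) {
  if (k < 2) stop("flat-positive sd prior needs >= 2 contributing terms")
  1 / stats::rgamma(1, shape = (k - 1) / 2, rate = ss / 2)
}

# draw from N(mean, sd) truncated to (0, Inf)
rtnorm_pos <- function(mean, sd) {
  lo <- stats::pnorm(0, mean, sd)
  if (lo >= 1 - 1e-12) return(abs(stats::rnorm(1, 0, sd)) * 1e-8 + 1e-12)
  stats::qnorm(stats::runif(1, lo, 1), mean, sd)
}

# random-walk Metropolis step on an unconstrained scalar; returns the new
# value and whether the proposal was accepted
rw_step <- function(cur, logpost, scale) {
  prop <- cur + stats::rnorm(1, 0, scale)
  lp_cur <- logpost(cur)
  lp_prop <- logpost(prop)
  if (is.finite(lp_prop) && log(stats::runif(1)) < lp_prop - lp_cur)
    list(value = prop, accepted = TRUE)
  else
    list(value = cur, accepted = FALSE)
}

# Robbins-Monro style scale adaptation toward a target acceptance rate
adapt_scale <- function(scale, accepted, iter, target = 0.44) {
  step <- min(0.1, 1 / sqrt(iter))
  if (accepted) scale * exp(step * (1 - target)) else scale * exp(-step * target)
}
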