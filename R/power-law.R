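#' Specification of the two-level hierarchical power-law model
#'
#' Similarity decay over response position or lag is modelled as
#' \deqn{y = a_s x^{b_s} + \epsilon,\quad \epsilon \sim N(0, \sigma)}
#' with subject-level parameters drawn from group-level distributions
#' \eqn{a_s \sim N(\bar a_g, \tau_{a,g})}, \eqn{b_s \sim N(\bar b_g,
#' \tau_{b,g})}. Group-level priors: \eqn{\bar a \sim N(0.2, 0.5)},
#' \eqn{\bar b \sim N(0, 0.5)}, scales half-Cauchy(0, 5). Because x is a
#' positive integer, \eqn{f(1) = a} exactly: `a` is the curve's starting
#' point and `b` its growth/decay rate.
#'
#' @param x_var Which x variable the records carry: `"position"` or
#'   `"lag"`.
#' @param data_mode `"raw"` fits the raw records with subject-level
#'   parameters (default); `"subject_mean"` first aggregates to
#'   per-subject-per-x means.
#' @param prior_a_mean,prior_a_sd Group-level prior on \eqn{\bar a}.
#' @param prior_b_mean,prior_b_sd Group-level prior on \eqn{\bar b}.
#' @param scale_prior_scale Half-Cauchy scale for \eqn{\tau} parameters.
#' @return A `power_law_spec`.
#' @export
power_law_spec <- function(x_var = c("position", "lag"),
                           data_mode = c("raw", "subject_mean"),
                           prior_a_mean = 0.2, prior_a_sd = 0.5,
                           prior_b_mean = 0, prior_b_sd = 0.5,
                           scale_prior_scale = 5) {
  structure(list(x_var = match.arg(x_var),
                 data_mode = match.arg(data_mode),
                 prior_a_mean = prior_a_mean, prior_a_sd = prior_a_sd,
                 prior_b_mean = prior_b_mean, prior_b_sd = prior_b_sd,
                 scale_prior_scale = scale_prior_scale),
            class = "power_law_spec")
}

#' Fit the hierarchical power-law model
#'
#' Metropolis-within-Gibbs sampler. Subject-level `a` and the group means
#' are conditionally conjugate (the model is linear in `a` given `b`);
#' subject-level `b` and the group scales use adaptive random-walk
#' Metropolis steps tuned during warmup; the observation variance is
#' conjugate under a flat-positive prior on sigma. Since x takes only a
#' handful of integer values, the likelihood is evaluated from per-subject
#' sufficient statistics, making the sampler fast.
#'
#' @param records Data frame with columns `subject_id`, `group`, `score`
#'   and the x column named by `spec$x_var`.
#' @param spec A [power_law_spec()].
#' @param mcmc An [mcmc_config()].
#' @return An `mcmc_posterior` (model `"power_law"`) with group parameters
#'   `a_bar[g]`, `b_bar[g]`, `tau_a[g]`, `tau_b[g]`, observation `sigma`,
#'   and subject-level `a[s]`, `b[s]`; convergence report in
#'   `$convergence`.
#' @export
fit_power_law <- function(records, spec = power_law_spec(),
                          mcmc = mcmc_config()) {
  stopifnot(inherits(spec, "power_law_spec"), inherits(mcmc, "mcmc_config"))
  xcol <- spec$x_var
  if (!xcol %in% names(records)) stop("records lack an x column: ", xcol)
  x <- as.integer(records[[xcol]])
  if (any(x < 1)) stop("x values must be positive integers")
  if (length(unique(x)) < 2) stop("need >= 2 distinct x levels")
  y <- records$score

  if (spec$data_mode == "subject_mean") {
    agg <- stats::aggregate(list(score = y),
                            by = list(subject_id = records$subject_id,
                                      group = records$group, xval = x),
                            FUN = mean)
    records <- data.frame(subject_id = agg$subject_id, group = agg$group,
                          score = agg$score, stringsAsFactors = FALSE)
    x <- agg$xval
    y <- records$score
  }

  subj <- factor(records$subject_id)
  J <- nlevels(subj)
  js <- as.integer(subj)
  grp_of_subj <- vapply(levels(subj), function(s)
    as.character(records$group[match(s, records$subject_id)]), character(1))
  groups <- sort(unique(grp_of_subj))
  gs <- match(grp_of_subj, groups)      # group index per subject
  G <- length(groups)

  ux <- sort(unique(x))
  U <- length(ux)
  xi <- match(x, ux)
  lux <- log(ux)
  # per-subject sufficient statistics over x levels
  n_su <- matrix(0, J, U); S_su <- matrix(0, J, U)
  for (i in seq_along(y)) {
    n_su[js[i], xi[i]] <- n_su[js[i], xi[i]] + 1
    S_su[js[i], xi[i]] <- S_su[js[i], xi[i]] + y[i]
  }
  Q_s <- rowsum(y^2, js)[, 1]
  n <- length(y)

  pa_m <- spec$prior_a_mean; pa_v <- spec$prior_a_sd^2
  pb_m <- spec$prior_b_mean; pb_v <- spec$prior_b_sd^2
  hc <- spec$scale_prior_scale
  log_half_cauchy <- function(tau) {
    if (tau <= 0) return(-Inf)
    -log1p((tau / hc)^2)
  }

  par_names <- c(paste0("a_bar[", groups, "]"), paste0("b_bar[", groups, "]"),
                 paste0("tau_a[", groups, "]"), paste0("tau_b[", groups, "]"),
                 "sigma",
                 paste0("a[", levels(subj), "]"),
                 paste0("b[", levels(subj), "]"))
  keep <- mcmc$iterations - mcmc$warmup
  draws <- array(NA_real_, dim = c(keep, mcmc$chains, length(par_names)),
                 dimnames = list(NULL, NULL, par_names))

  for (chain in seq_len(mcmc$chains)) {
    set.seed(mcmc$seed + chain - 1L)
    # initial values: a from mean at smallest x, b jittered around 0
    a_s <- vapply(seq_len(J), function(s) {
      if (n_su[s, 1] > 0) S_su[s, 1] / n_su[s, 1] else mean(y)
    }, numeric(1)) + stats::rnorm(J, 0, 0.02)
    b_s <- stats::rnorm(J, 0, 0.05)
    a_bar <- tapply(a_s, gs, mean) + stats::rnorm(G, 0, 0.02)
    b_bar <- stats::rnorm(G, 0, 0.05)
    tau_a <- rep(0.1, G); tau_b <- rep(0.1, G)
    sig2 <- stats::var(y)
    b_scale <- rep(0.1, J)
    tau_scale <- matrix(0.5, G, 2)
    shift_scale <- matrix(0.05, G, 2)   # columns: a, b

    for (it in seq_len(mcmc$iterations)) {
      for (s in seq_len(J)) {
        g <- gs[s]
        ns <- n_su[s, ]; Ss <- S_su[s, ]
        # b_s | rest: random-walk Metropolis on sufficient statistics
        a_cur <- a_s[s]
        logpost_b <- function(b) {
          gx <- exp(b * lux)
          ll <- -(Q_s[s] - 2 * a_cur * sum(gx * Ss) +
                    a_cur^2 * sum(ns * gx^2)) / (2 * sig2)
          ll - (b - b_bar[g])^2 / (2 * tau_b[g]^2)
        }
        st <- rw_step(b_s[s], logpost_b, b_scale[s])
        b_s[s] <- st$value
        if (it <= mcmc$warmup)
          b_scale[s] <- adapt_scale(b_scale[s], st$accepted, it)
        # a_s | rest: conjugate normal (linear in a)
        gx <- exp(b_s[s] * lux)
        prec <- sum(ns * gx^2) / sig2 + 1 / tau_a[g]^2
        mu_a <- (sum(gx * Ss) / sig2 + a_bar[g] / tau_a[g]^2) / prec
        a_s[s] <- stats::rnorm(1, mu_a, sqrt(1 / prec))
      }
      # group means | rest: conjugate normal
      for (g in seq_len(G)) {
        idx <- which(gs == g); Jg <- length(idx)
        prec <- Jg / tau_a[g]^2 + 1 / pa_v
        a_bar[g] <- stats::rnorm(1, (sum(a_s[idx]) / tau_a[g]^2 +
                                       pa_m / pa_v) / prec, sqrt(1 / prec))
        prec <- Jg / tau_b[g]^2 + 1 / pb_v
        b_bar[g] <- stats::rnorm(1, (sum(b_s[idx]) / tau_b[g]^2 +
                                       pb_m / pb_v) / prec, sqrt(1 / prec))
        # group scales | rest: Metropolis on log tau, half-Cauchy prior
        for (which_tau in 1:2) {
          cur <- if (which_tau == 1) tau_a[g] else tau_b[g]
          vals <- if (which_tau == 1) a_s[idx] - a_bar[g]
                  else b_s[idx] - b_bar[g]
          logpost_ltau <- function(lt) {
            tau <- exp(lt)
            -Jg * lt - sum(vals^2) / (2 * tau^2) +
              log_half_cauchy(tau) + lt    # + lt: Jacobian of log transform
          }
          st <- rw_step(log(cur), logpost_ltau, tau_scale[g, which_tau])
          newv <- exp(st$value)
          if (which_tau == 1) tau_a[g] <- newv else tau_b[g] <- newv
          if (it <= mcmc$warmup)
            tau_scale[g, which_tau] <-
              adapt_scale(tau_scale[g, which_tau], st$accepted, it)
        }
      }
      # joint translation moves: shift a group's mean and all its subject
      # parameters together. These leave the subject-deviation prior terms
      # unchanged and decouple the group mean from the scale funnel.
      for (g in seq_len(G)) {
        idx <- which(gs == g)
        # shift in b
        delta <- stats::rnorm(1, 0, shift_scale[g, 2])
        dll <- (b_bar[g] - pb_m)^2 / (2 * pb_v) -
          (b_bar[g] + delta - pb_m)^2 / (2 * pb_v)
        for (s in idx) {
          g0 <- exp(b_s[s] * lux); g1 <- exp((b_s[s] + delta) * lux)
          dll <- dll -
            (-2 * a_s[s] * sum(g1 * S_su[s, ]) +
               a_s[s]^2 * sum(n_su[s, ] * g1^2)) / (2 * sig2) +
            (-2 * a_s[s] * sum(g0 * S_su[s, ]) +
               a_s[s]^2 * sum(n_su[s, ] * g0^2)) / (2 * sig2)
        }
        acc <- is.finite(dll) && log(stats::runif(1)) < dll
        if (acc) { b_bar[g] <- b_bar[g] + delta; b_s[idx] <- b_s[idx] + delta }
        if (it <= mcmc$warmup)
          shift_scale[g, 2] <- adapt_scale(shift_scale[g, 2], acc, it)
        # shift in a (likelihood is quadratic in the shift)
        delta <- stats::rnorm(1, 0, shift_scale[g, 1])
        dll <- (a_bar[g] - pa_m)^2 / (2 * pa_v) -
          (a_bar[g] + delta - pa_m)^2 / (2 * pa_v)
        for (s in idx) {
          gx <- exp(b_s[s] * lux)
          a0 <- a_s[s]; a1 <- a_s[s] + delta
          dll <- dll -
            (-2 * a1 * sum(gx * S_su[s, ]) +
               a1^2 * sum(n_su[s, ] * gx^2)) / (2 * sig2) +
            (-2 * a0 * sum(gx * S_su[s, ]) +
               a0^2 * sum(n_su[s, ] * gx^2)) / (2 * sig2)
        }
        acc <- is.finite(dll) && log(stats::runif(1)) < dll
        if (acc) { a_bar[g] <- a_bar[g] + delta; a_s[idx] <- a_s[idx] + delta }
        if (it <= mcmc$warmup)
          shift_scale[g, 1] <- adapt_scale(shift_scale[g, 1], acc, it)
      }
      # observation variance | rest
      gx_all <- exp(outer(b_s, lux))          # J x U
      ss <- sum(Q_s) + sum(a_s^2 * rowSums(n_su * gx_all^2)) -
        2 * sum(a_s * rowSums(gx_all * S_su))
      sig2 <- draw_var_flat_sd(n, max(ss, 1e-12))
      if (it > mcmc$warmup)
        draws[it - mcmc$warmup, chain, ] <-
          c(a_bar, b_bar, tau_a, tau_b, sqrt(sig2), a_s, b_s)
    }
  }

  post <- new_posterior(draws, model = "power_law",
                        data_info = list(n = n, n_subjects = J,
                                         groups = groups, x_var = xcol,
                                         data_mode = spec$data_mode))
  post$convergence <- check_convergence(post)
  if (!attr(post$convergence, "pass"))
    warning("power-law fit did not reach the R-hat threshold; ",
            "inspect $convergence")
  post
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Posterior difference distribution between groups
#'
#' For each posterior draw, subtracts the CO group-level parameter from the
#' HP one (HP minus CO), yielding a difference distribution summarised by
#' its mean, the proportion of draws above zero, and the central 95%
#' interval.
#'
#' @param posterior A power-law `mcmc_posterior` containing both groups.
#' @param parameter `"a"` or `"b"` (the group-level mean of that
#'   parameter).
#' @return A `difference_summary` list: `parameter`, `mean`,
#'   `prop_above_zero`, `q2.5`, `q97.5`, and the raw `draws`.
#' @export
difference_distribution <- function(posterior, parameter = c("a", "b")) {
  parameter <- match.arg(parameter)
  pn <- paste0(parameter, "_bar")
  pars <- dimnames(posterior$draws)[[3]]
  hp_name <- paste0(pn, "[HP]"); co_name <- paste0(pn, "[CO]")
  if (!all(c(hp_name, co_name) %in% pars))
    stop("posterior does not contain both CO and HP group parameters")
  d <- posterior_draws(posterior, hp_name) - posterior_draws(posterior, co_name)
  ci <- unname(stats::quantile(d, c(0.025, 0.975)))
  # ties at exactly zero (possible only in degenerate posteriors) count as
  # half, so a perfectly symmetric null yields exactly 0.5
  structure(list(parameter = parameter, mean = mean(d),
                 prop_above_zero = mean(d > 0) + 0.5 * mean(d == 0),
                 q2.5 = ci[1], q97.5 = ci[2], draws = d),
            class = "difference_summary")
}

#' @export
print.difference_summary <- function(x, ...) {
  cat(sprintf(
    "HP - CO difference in %s: mean %.4f, P(>0) = %.2f, 95%% CI [%.4f, %.4f]\n",
    x$parameter, x$mean, x$prop_above_zero, x$q2.5, x$q97.5))
  invisible(x)
}

#' Posterior-mean power curve
#'
#' Evaluates \eqn{\bar a_g x^{\bar b_g}} at the posterior means, with a
#' pointwise central 95% band from the draws.
#'
#' @param posterior A power-law `mcmc_posterior`.
#' @param group Group label.
#' @param x Vector of x values.
#' @return Data frame with `x`, `fit`, `lower`, `upper`.
#' @export
power_curve <- function(posterior, group, x) {
  a <- posterior_draws(posterior, paste0("a_bar[", group, "]"))
  b <- posterior_draws(posterior, paste0("b_bar[", group, "]"))
  fit <- mean(a) * x^mean(b)
  qs <- vapply(x, function(xx) {
    f <- a * xx^b
    stats::quantile(f, c(0.025, 0.975))
  }, numeric(2))
  data.frame(x = x, fit = fit, lower = qs[1, ], upper = qs[2, ])
}

#' Pointwise predictive information criterion
#'
#' Generic model comparison between a fitted power-law posterior and a
#' null fit (for example one where both groups share parameters): the sum
#' over observations of the log of the posterior-mean likelihood, penalised
#' by the effective number of parameters (WAIC-style). Offered as a
#' utility; no reference value is asserted for it.
#'
#' @param posterior A power-law `mcmc_posterior`.
#' @param records The records the model was fitted to.
#' @param spec The [power_law_spec()] used.
#' @return List with `elpd`, `p_eff`, `waic`.
#' @export
powerlaw_waic <- function(posterior, records, spec = power_law_spec()) {
  x <- as.numeric(records[[spec$x_var]])
  y <- records$score
  subj <- paste0("a[", records$subject_id, "]")
  subj_b <- paste0("b[", records$subject_id, "]")
  sig <- posterior_draws(posterior, "sigma")
  ndraw <- length(sig)
  lpd <- 0; p_eff <- 0
  for (i in seq_along(y)) {
    a <- posterior_draws(posterior, subj[i])
    b <- posterior_draws(posterior, subj_b[i])
    ll <- stats::dnorm(y[i], a * x[i]^b, sig, log = TRUE)
    lpd <- lpd + (max(ll) + log(mean(exp(ll - max(ll)))))
    p_eff <- p_eff + stats::var(ll)
  }
  list(elpd = lpd - p_eff, p_eff = p_eff, waic = -2 * (lpd - p_eff))
}
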