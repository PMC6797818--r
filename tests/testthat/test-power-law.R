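test_that("power-law preconditions", {
  recs <- generate_power_law_records(0.25, -0.2, 0.05, 3, 5, seed = 1,
                                     n_per_cell = 4)
  expect_error(fit_power_law(recs[, setdiff(names(recs), "position")],
                             mcmc = test_mcmc()), "x column")
  one_x <- recs[recs$position == 1, ]
  expect_error(fit_power_law(one_x, mcmc = test_mcmc()), "2 distinct x")
})

test_that("parameter recovery on simulated decay data", {
  recs <- rbind(
    generate_power_law_records(0.25, -0.20, 0.05, 8, 5, seed = 5,
                               group = "CO", n_per_cell = 15),
    generate_power_law_records(0.25, -0.12, 0.05, 4, 5, seed = 6,
                               group = "HP", n_per_cell = 15))
  fit <- suppressWarnings(
    fit_power_law(recs, power_law_spec(), test_mcmc(seed = 2,
                                                    iterations = 600)))
  expect_lt(abs(mean(posterior_draws(fit, "a_bar[CO]")) - 0.25), 0.03)
  expect_lt(abs(mean(posterior_draws(fit, "b_bar[CO]")) - (-0.20)), 0.05)
  expect_lt(abs(mean(posterior_draws(fit, "a_bar[HP]")) - 0.25), 0.03)
  expect_lt(abs(mean(posterior_draws(fit, "b_bar[HP]")) - (-0.12)), 0.05)
  d <- difference_distribution(fit, "b")
  expect_gt(d$prop_above_zero, 0.8)
  # f(1) = a holds exactly for every draw
  a <- posterior_draws(fit, "a_bar[CO]")
  b <- posterior_draws(fit, "b_bar[CO]")
  expect_identical(a * 1^b, a)
})

test_that("b = 0 simulation yields a flat fit with a near the sample mean", {
  recs <- generate_power_law_records(0.25, 0, 0.05, 5, 5, seed = 9,
                                     n_per_cell = 20)
  fit <- suppressWarnings(
    fit_power_law(recs, power_law_spec(), test_mcmc(seed = 4)))
  expect_lt(abs(mean(posterior_draws(fit, "b_bar[CO]"))), 0.02)
  expect_lt(abs(mean(posterior_draws(fit, "a_bar[CO]")) - mean(recs$score)),
            0.02)
})

test_that("near-noiseless single subject: posterior curve passes through data", {
  recs <- generate_power_law_records(0.3, -0.15, 0.001, 1, 5, seed = 3,
                                     n_per_cell = 10)
  fit <- suppressWarnings(
    fit_power_law(recs, power_law_spec(), test_mcmc(seed = 6,
                                                    iterations = 600)))
  # with a single subject the group mean is only weakly identified; the
  # subject-level posterior mean curve is what must pass through the data
  a <- mean(posterior_draws(fit, "a[CO01]"))
  b <- mean(posterior_draws(fit, "b[CO01]"))
  truth <- 0.3 * (1:5)^(-0.15)
  expect_true(all(abs(a * (1:5)^b - truth) < 0.01))
})

test_that("identical simulated groups: difference centred near zero", {
  recs <- rbind(
    generate_power_law_records(0.25, -0.2, 0.05, 6, 5, seed = 11,
                               group = "CO", n_per_cell = 10),
    generate_power_law_records(0.25, -0.2, 0.05, 6, 5, seed = 12,
                               group = "HP", n_per_cell = 10))
  fit <- suppressWarnings(
    fit_power_law(recs, power_law_spec(), test_mcmc(seed = 8)))
  da <- difference_distribution(fit, "a")
  expect_lt(abs(da$mean), 0.02)
  expect_lt(da$q2.5, 0); expect_gt(da$q97.5, 0)
})

test_that("subject_mean data mode aggregates before fitting", {
  recs <- generate_power_law_records(0.25, -0.2, 0.05, 4, 5, seed = 13,
                                     n_per_cell = 10)
  fit <- suppressWarnings(
    fit_power_law(recs, power_law_spec(data_mode = "subject_mean"),
                  test_mcmc(seed = 9)))
  expect_equal(fit$data_info$n, 4 * 5)  # one point per subject x position
  expect_lt(abs(mean(posterior_draws(fit, "a_bar[CO]")) - 0.25), 0.05)
})

test_that("interval coverage across seeded recovery simulations", {
  # reduced scale to keep runtime bounded: 20 seeds, small n, short chains;
  # the loose >= 85% coverage bound is for the ~95% central interval of b
  hits <- 0L
  for (s in 1:20) {
    recs <- generate_power_law_records(0.25, -0.2, 0.05, 4, 5,
                                       seed = 100 + s, n_per_cell = 8)
    fit <- suppressWarnings(
      fit_power_law(recs, power_law_spec(),
                    mcmc_config(chains = 2, iterations = 400,
                                seed = 200 + s)))
    ci <- quantile(posterior_draws(fit, "b_bar[CO]"), c(0.025, 0.975))
    if (ci[1] <= -0.2 && -0.2 <= ci[2]) hits <- hits + 1L
  }
  expect_gte(hits, 17L)
})

test_that("waic utility returns finite comparable numbers", {
  recs <- generate_power_law_records(0.25, -0.2, 0.05, 3, 4, seed = 15,
                                     n_per_cell = 5)
  fit <- suppressWarnings(
    fit_power_law(recs, power_law_spec(), test_mcmc(seed = 10,
                                                    iterations = 300)))
  w <- powerlaw_waic(fit, recs)
  expect_true(is.finite(w$waic))
  expect_gt(w$p_eff, 0)
})
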