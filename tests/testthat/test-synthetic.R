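test_that("fixture spaces are deterministic unit vectors", {
  s1 <- make_fixture_space(fixture_words(20), dims = 16, seed = 1)
  s2 <- make_fixture_space(fixture_words(20), dims = 16, seed = 1)
  expect_identical(unclass(s1)[, ], unclass(s2)[, ])
  s3 <- make_fixture_space(fixture_words(20), dims = 16, seed = 2)
  expect_false(isTRUE(all.equal(unclass(s1)[, ], unclass(s3)[, ])))
  norms <- sqrt(rowSums(unclass(s1)^2))
  expect_true(all(abs(norms - 1) < 1e-12))
})

test_that("power-law record generator obeys its contract", {
  # noiseless: scores exactly a * x^b
  recs <- generate_power_law_records(0.25, -0.2, 0, 2, 5, seed = 1,
                                     n_per_cell = 3)
  expect_equal(recs$score, 0.25 * recs$position^(-0.2), tolerance = 1e-12)
  # b = 0: all expected scores equal a
  recs0 <- generate_power_law_records(0.4, 0, 0, 2, 4, seed = 1,
                                      n_per_cell = 2)
  expect_true(all(recs0$score == 0.4))
  # CLT check: large-n sample mean at each x within 3 SE of a * x^b
  big <- generate_power_law_records(0.25, -0.2, 0.05, 20, 5, seed = 2,
                                    n_per_cell = 40)
  for (x in 1:5) {
    s <- big$score[big$position == x]
    se <- 0.05 / sqrt(length(s))
    expect_lt(abs(mean(s) - 0.25 * x^(-0.2)), 3 * se)
  }
})

test_that("simulate_search: greedy limit, degenerate restriction, no repeats", {
  sp <- make_fixture_space(c("target", fixture_words(30)), dims = 20, seed = 4)
  cands <- fixture_words(30)
  tv <- embedding_vector(sp, "target")
  sims <- vapply(cands, function(w) cosine(tv, embedding_vector(sp, w)),
                 numeric(1))

  # sharpness -> Inf with lambda == 1: deterministic descending-similarity order
  cfg <- search_sim_config(dims = 20, n_candidates = 30, sharpness = Inf,
                           lambda_gamma = 1, lambda_min = 1,
                           max_responses = 10)
  out <- simulate_search("target", cands, sp, cfg, seed = 1)
  expect_identical(out, cands[order(-sims)][1:10])

  # impossible range limit: empty trial
  cfg2 <- search_sim_config(dims = 20, n_candidates = 30, range_limit = 1.0,
                            max_responses = 10)
  expect_length(simulate_search("target", cands, sp, cfg2, seed = 1), 0L)

  # no candidate reported twice
  cfg3 <- search_sim_config(dims = 20, n_candidates = 30, max_responses = 30,
                            range_limit = -1)
  out3 <- simulate_search("target", cands, sp, cfg3, seed = 2)
  expect_equal(anyDuplicated(out3), 0L)
})

test_that("range restriction raises mean target-similarity (Monte Carlo)", {
  sp <- make_fixture_space(c("t", sprintf("c%02d", 1:40)), dims = 50, seed = 6)
  cands <- sprintf("c%02d", 1:40)
  tv <- embedding_vector(sp, "t")
  sims <- vapply(cands, function(w) cosine(tv, embedding_vector(sp, w)),
                 numeric(1))
  co_cfg <- search_sim_config(n_candidates = 40, range_limit = -1,
                              max_responses = 8)
  hp_cfg <- search_sim_config(n_candidates = 40, range_limit = 0.1,
                              max_responses = 8)
  mean_sim <- function(cfg, seed_base) {
    vals <- c()
    for (i in 1:50) {
      out <- simulate_search("t", cands, sp, cfg, seed = seed_base + i)
      vals <- c(vals, sims[out])
    }
    mean(vals)
  }
  expect_gt(mean_sim(hp_cfg, 1000), mean_sim(co_cfg, 2000))
})

test_that("expected target-similarity declines across positions (lambda = 1)", {
  sp <- make_fixture_space(c("t", sprintf("c%02d", 1:40)), dims = 50, seed = 8)
  cands <- sprintf("c%02d", 1:40)
  tv <- embedding_vector(sp, "t")
  sims <- vapply(cands, function(w) cosine(tv, embedding_vector(sp, w)),
                 numeric(1))
  cfg <- search_sim_config(n_candidates = 40, lambda_gamma = 1,
                           lambda_min = 1, sharpness = 8, max_responses = 6)
  bypos <- matrix(NA_real_, 300, 6)
  for (i in 1:300) {
    out <- simulate_search("t", cands, sp, cfg, seed = 3000 + i)
    bypos[i, seq_along(out)] <- sims[out]
  }
  m <- colMeans(bypos, na.rm = TRUE)
  expect_true(all(diff(m) < 0.005))  # non-increasing up to Monte-Carlo noise
})

test_that("generate_cohort is deterministic and mirrors the study design", {
  cfg <- cohort_config(n_hp = 2, n_co = 3, n_targets = 4,
                       co_config = search_sim_config(max_responses = 6,
                                                     n_candidates = 20),
                       hp_config = search_sim_config(max_responses = 4,
                                                     n_candidates = 20,
                                                     range_limit = 0.2))
  coh <- generate_cohort(cfg, seed = 7)
  expect_s3_class(coh$trials, "trial_table")
  expect_s3_class(coh$space, "embedding_space")
  expect_equal(length(unique(coh$trials$subject_id)), 5L)
  expect_setequal(unique(coh$trials$group), c("HP", "CO"))
  expect_lte(max(coh$trials$position[coh$trials$group == "CO"]), 6L)

  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_cohort(coh, d1)
  write_cohort(generate_cohort(cfg, seed = 7), d2)
  expect_identical(readLines(file.path(d1, "trials.tsv")),
                   readLines(file.path(d2, "trials.tsv")))
  expect_identical(readLines(file.path(d1, "embeddings.txt")),
                   readLines(file.path(d2, "embeddings.txt")))
  # written cohort round-trips through the transcript reader
  back <- read_trials(file.path(d1, "trials.tsv"))
  expect_equal(nrow(back), nrow(coh$trials))
  sp <- load_embeddings(file.path(d1, "embeddings.txt"))
  expect_equal(nrow(sp), nrow(coh$space))
})

test_that("default cohort counts follow the study design", {
  cfg <- cohort_config()
  expect_equal(cfg$n_hp, 5L)
  expect_equal(cfg$n_co, 15L)
  expect_equal(cfg$n_targets, 35L)
  expect_equal(cfg$hp_config$range_limit, 0.2)
  expect_equal(cfg$co_config$range_limit, -1)
})
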