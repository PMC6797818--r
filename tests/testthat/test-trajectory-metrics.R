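test_that("target_feature_similarity averages word cosines and tracks OOV", {
  sp <- make_cosine_space("book", c("something", "read"), c(0.3614, 0.5758))
  res <- target_feature_similarity("book", c("something", "read"), sp)
  expect_equal(res$score, mean(c(0.3614, 0.5758)), tolerance = 1e-12)
  expect_equal(res$n_scored_words, 2L)

  # single token: score equals that token's cosine exactly
  res1 <- target_feature_similarity("book", "read", sp)
  expect_equal(res1$score, 0.5758, tolerance = 1e-12)

  # OOV tokens skipped and counted; all-OOV is a missing marker
  res2 <- target_feature_similarity("book", c("read", "unicorn"), sp)
  expect_equal(res2$n_scored_words, 1L)
  expect_equal(res2$n_oov, 1L)
  expect_null(target_feature_similarity("book", "unicorn", sp))
  expect_null(target_feature_similarity("book", character(), sp))

  # OOV target is fatal
  expect_error(target_feature_similarity("dragon", "read", sp),
               "out of vocabulary")
})

test_that("feature_feature_similarity matches a brute-force pairwise oracle", {
  sp <- make_fixture_space(fixture_words(6), dims = 12, seed = 3)
  w <- fixture_words(6)
  pairwise_oracle <- function(t1, t2) {
    acc <- c()
    for (u in t1) for (v in t2)
      acc <- c(acc, cosine(embedding_vector(sp, u), embedding_vector(sp, v)))
    mean(acc)
  }
  f1 <- w[1:2]; f2 <- w[3:5]
  expect_equal(feature_feature_similarity(f1, f2, sp),
               pairwise_oracle(f1, f2), tolerance = 1e-12)
  expect_equal(feature_feature_similarity(w[1], w[2:3], sp),
               pairwise_oracle(w[1], w[2:3]), tolerance = 1e-12)
  # symmetry + identity
  expect_equal(feature_feature_similarity(f1, f2, sp),
               feature_feature_similarity(f2, f1, sp), tolerance = 1e-12)
  expect_equal(feature_feature_similarity(w[1], w[1], sp), 1, tolerance = 1e-12)
  # missing side -> missing marker
  expect_null(feature_feature_similarity(character(), f2, sp))
  expect_null(feature_feature_similarity("unicorn", f2, sp))
})

test_that("aggregation scores stay within word-level cosine bounds", {
  sp <- make_fixture_space(fixture_words(8), dims = 10, seed = 5)
  w <- fixture_words(8)
  tv <- embedding_vector(sp, w[1])
  toks <- w[2:5]
  cs <- vapply(toks, function(x) cosine(tv, embedding_vector(sp, x)),
               numeric(1))
  res <- target_feature_similarity(w[1], toks, sp)
  expect_gte(res$score, min(cs))
  expect_lte(res$score, max(cs))
})

test_that("build_position_records honours the position cap", {
  sp <- make_fixture_space(c("book", fixture_words(7)), dims = 8, seed = 1)
  tr <- as_trial_table(data.frame(
    subject_id = "CO01", group = "CO", target_word = "book",
    position = 1:7, feature_text = fixture_words(7),
    stringsAsFactors = FALSE))
  prep <- prepare_trials(tr)
  expect_equal(nrow(build_position_records(prep, sp, max_position = 5)), 5L)
  expect_equal(nrow(build_position_records(prep, sp, max_position = Inf)), 7L)
  r3 <- build_position_records(prep[prep$position <= 3, ], sp, 5)
  expect_equal(nrow(r3), 3L)
  recs <- build_position_records(prep, sp, max_position = 5)
  expect_true(all(recs$position <= 5))
  expect_true(all(recs$n_scored_words >= 1))
  expect_true(all(abs(recs$score) <= 1))
})

test_that("build_lag_records counts match the combinatorial formula", {
  lag_count_oracle <- function(n, max_lag = 4) {
    total <- 0
    for (l in seq_len(max_lag)) if (n - l >= 1) total <- total + (n - l)
    total
  }
  for (n in c(1, 2, 3, 5, 8)) {
    sp <- make_fixture_space(c("book", fixture_words(n)), dims = 8, seed = n)
    tr <- as_trial_table(data.frame(
      subject_id = "CO01", group = "CO", target_word = "book",
      position = seq_len(n), feature_text = fixture_words(n),
      stringsAsFactors = FALSE))
    recs <- build_lag_records(prepare_trials(tr), sp)
    expect_equal(nrow(recs), lag_count_oracle(n))
    if (nrow(recs) > 0) {
      expect_true(all(recs$lag == recs$to_position - recs$from_position))
      expect_true(all(recs$lag >= 1 & recs$lag <= 4))
    }
  }
})

test_that("group_summary matches a streaming-moments oracle", {
  set.seed(11)
  recs <- data.frame(group = rep(c("CO", "HP"), each = 50),
                     score = runif(100, -0.2, 0.8))
  gs <- group_summary(recs)
  # independent oracle: Welford streaming moments
  welford <- function(x) {
    m <- 0; m2 <- 0; k <- 0
    for (xi in x) {
      k <- k + 1; d <- xi - m; m <- m + d / k; m2 <- m2 + d * (xi - m)
    }
    c(mean = m, sd = sqrt(m2 / (k - 1)))
  }
  for (g in c("CO", "HP")) {
    o <- welford(recs$score[recs$group == g])
    expect_equal(gs$mean[gs$group == g], unname(o["mean"]), tolerance = 1e-12)
    expect_equal(gs$sd[gs$group == g], unname(o["sd"]), tolerance = 1e-12)
  }
  recs$score <- 0.5
  gs2 <- group_summary(recs)
  expect_equal(gs2$sd, c(0, 0))
  expect_error(group_summary(recs[0, ]), "no records")
})

test_that("records round-trip through tidy CSV", {
  sp <- make_fixture_space(c("book", fixture_words(4)), dims = 8, seed = 2)
  tr <- tiny_trials()
  tr$feature_text <- rep(fixture_words(4), 2)
  prep <- prepare_trials(as_trial_table(tr))
  recs <- build_position_records(prep, sp, max_position = Inf)
  f <- withr::local_tempfile(fileext = ".csv")
  write_records(recs, f)
  back <- utils::read.csv(f, stringsAsFactors = FALSE)
  expect_equal(back$score, recs$score, tolerance = 1e-12)
  expect_equal(back$position, recs$position)
})
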