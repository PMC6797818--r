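# Fixtures are constructed in code; nothing is read from disk except files
# the tests themselves write to tempdir().

# 2-D space in which cosine(target, w_i) equals the requested value exactly:
# target = (1, 0), word = (c, sqrt(1 - c^2)).
make_cosine_space <- function(target, words, cosines) {
  stopifnot(length(words) == length(cosines), all(abs(cosines) <= 1))
  mat <- rbind(c(1, 0),
               cbind(cosines, sqrt(1 - cosines^2)))
  rownames(mat) <- c(target, words)
  semsearch:::new_embedding_space(mat, lowercase = TRUE)
}

# small transcript table used across prep/metric tests
tiny_trials <- function() {
  as_trial_table(data.frame(
    subject_id = rep(c("HP01", "CO01"), each = 4),
    group = rep(c("HP", "CO"), each = 4),
    target_word = "book",
    position = rep(1:4, 2),
    feature_text = rep(c("something you read", "made of paper",
                         "tells a story", "found in a library"), 2),
    stringsAsFactors = FALSE))
}

# deterministic word list for fixture spaces
fixture_words <- function(n) sprintf("word%03d", seq_len(n))

# reduced MCMC protocol for unit tests (acceptance tests use 4 x 500)
test_mcmc <- function(seed = 1, chains = 2, iterations = 400)
  mcmc_config(chains = chains, iterations = iterations, seed = seed)

# hand-built power-law posterior with known draws, for exact-value tests
fake_powerlaw_posterior <- function(a_hp, a_co, b_hp = NULL, b_co = NULL) {
  n <- length(a_hp)
  if (is.null(b_hp)) b_hp <- rep(0, n)
  if (is.null(b_co)) b_co <- rep(0, n)
  arr <- array(NA_real_, dim = c(n, 1, 4),
               dimnames = list(NULL, NULL,
                               c("a_bar[CO]", "a_bar[HP]",
                                 "b_bar[CO]", "b_bar[HP]")))
  arr[, 1, "a_bar[CO]"] <- a_co
  arr[, 1, "a_bar[HP]"] <- a_hp
  arr[, 1, "b_bar[CO]"] <- b_co
  arr[, 1, "b_bar[HP]"] <- b_hp
  semsearch:::new_posterior(arr, model = "power_law")
}
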