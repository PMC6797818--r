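#' Target-to-feature similarity
#'
#' A multi-word feature is scored as the arithmetic mean of the cosine
#' similarity between the target word's vector and each content word of
#' the feature. Feature words missing from the vocabulary are skipped and
#' counted; if no word is scorable the result is a missing marker (`NULL`).
#' A target word missing from the vocabulary is fatal for the trial — the
#' target anchors every score, a missing modifier word does not.
#'
#' @param target Target word string.
#' @param tokens Character vector of filtered content words of one feature.
#' @param space An `embedding_space`.
#' @return A list with `score`, `n_scored_words`, `n_oov`; or `NULL` if no
#'   token is scorable.
#' @export
target_feature_similarity <- function(target, tokens, space) {
  tv <- embedding_vector(space, target)
  if (is.null(tv))
    stop("target word out of vocabulary: ", target)
  if (length(tokens) == 0L) return(NULL)
  present <- in_vocabulary(space, tokens)
  scorable <- tokens[present]
  if (length(scorable) == 0L) return(NULL)
  scores <- vapply(scorable,
                   function(w) cosine(tv, embedding_vector(space, w)),
                   numeric(1))
  list(score = mean(scores),
       n_scored_words = length(scorable),
       n_oov = sum(!present))
}

#' Feature-to-feature similarity
#'
#' The similarity of two multi-word features is the mean over all word-pair
#' cosines, one word drawn from each feature, restricted to in-vocabulary
#' words. The score never references the target vector. Returns `NULL` if
#' either side has no scorable word.
#'
#' @param tokens1,tokens2 Filtered content-word vectors of the two features.
#' @param space An `embedding_space`.
#' @return Mean pairwise cosine, or `NULL`.
#' @export
feature_feature_similarity <- function(tokens1, tokens2, space) {
  t1 <- tokens1[in_vocabulary(space, tokens1)]
  t2 <- tokens2[in_vocabulary(space, tokens2)]
  if (length(t1) == 0L || length(t2) == 0L) return(NULL)
  total <- 0
  for (u in t1) {
    uv <- embedding_vector(space, u)
    for (w in t2) total <- total + cosine(uv, embedding_vector(space, w))
  }
  total / (length(t1) * length(t2))
}

#' Build target-similarity records by response position
#'
#' One record per (trial, position) with a scorable feature. The
#' position-decay analysis caps at the first five responses, which puts the
#' two groups on comparable footing; the overall group-shift analysis uses
#' every position (`max_position = Inf`).
#'
#' @param trials A prepared `trial_table` (see [prepare_trials()]).
#' @param space An `embedding_space`.
#' @param max_position Cap on response position (default 5; `Inf` = no cap).
#' @return Data frame with columns `subject_id`, `group`, `target_word`,
#'   `position`, `score`, `n_scored_words`.
#' @export
build_position_records <- function(trials, space, max_position = 5) {
  stopifnot(!is.null(trials$tokens))
  keep <- trials$position <= max_position
  rows <- trials[keep, , drop = FALSE]
  out <- vector("list", nrow(rows))
  n_oov <- 0L
  for (i in seq_len(nrow(rows))) {
    res <- target_feature_similarity(rows$target_word[i], rows$tokens[[i]],
                                     space)
    if (is.null(res)) next
    n_oov <- n_oov + res$n_oov
    out[[i]] <- data.frame(subject_id = rows$subject_id[i],
                           group = rows$group[i],
                           target_word = rows$target_word[i],
                           position = rows$position[i],
                           score = res$score,
                           n_scored_words = res$n_scored_words,
                           stringsAsFactors = FALSE)
  }
  if (n_oov > 0L)
    message("skipped ", n_oov, " out-of-vocabulary feature word(s)")
  recs <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(recs))
    recs <- data.frame(subject_id = character(), group = character(),
                       target_word = character(), position = integer(),
                       score = numeric(), n_scored_words = integer())
  rownames(recs) <- NULL
  recs
}

#' Build feature-to-feature similarity records by lag
#'
#' For each trial, one record per ordered pair of positions `(i, i + lag)`
#' with `lag` in `1..max_lag`: adjacent features have lag 1, features
#' separated by one intervening feature lag 2, and so forth.
#'
#' @param trials A prepared `trial_table`.
#' @param space An `embedding_space`.
#' @param max_lag Maximum lag (default 4).
#' @return Data frame with columns `subject_id`, `group`, `target_word`,
#'   `lag`, `from_position`, `to_position`, `score`.
#' @export
build_lag_records <- function(trials, space, max_lag = 4) {
  stopifnot(!is.null(trials$tokens))
  out <- list()
  for (tr in split_trials(trials)) {
    feats <- tr$features
    n <- nrow(feats)
    if (n < 2L) next
    for (lag in seq_len(min(max_lag, n - 1L))) {
      for (i in seq_len(n - lag)) {
        s <- feature_feature_similarity(feats$tokens[[i]],
                                        feats$tokens[[i + lag]], space)
        if (is.null(s)) next
        out[[length(out) + 1L]] <-
          data.frame(subject_id = tr$subject_id, group = tr$group,
                     target_word = tr$target_word, lag = lag,
                     from_position = feats$position[i],
                     to_position = feats$position[i + lag],
                     score = s, stringsAsFactors = FALSE)
      }
    }
  }
  recs <- do.call(rbind, out)
  if (is.null(recs))
    recs <- data.frame(subject_id = character(), group = character(),
                       target_word = character(), lag = integer(),
                       from_position = integer(), to_position = integer(),
                       score = numeric())
  rownames(recs) <- NULL
  recs
}

#' Descriptive per-group summary of similarity records
#'
#' Plain arithmetic mean and standard deviation of `score` per group.
#'
#' @param records A record data frame with `group` and `score` columns.
#' @return Data frame with `group`, `n`, `mean`, `sd`.
#' @export
group_summary <- function(records) {
  if (nrow(records) == 0L) stop("no records to summarise")
  groups <- sort(unique(records$group))
  out <- data.frame(group = groups,
                    n = NA_integer_, mean = NA_real_, sd = NA_real_)
  for (i in seq_along(groups)) {
    s <- records$score[records$group == groups[i]]
    if (length(s) == 0L) stop("empty group: ", groups[i])
    out$n[i] <- length(s)
    out$mean[i] <- mean(s)
    out$sd[i] <- stats::sd(s)
  }
  out
}

#' Write records to a tidy CSV
#'
#' One row per record; the `tokens` list-column, if present, is dropped.
#'
#' @param records Record data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path) {
  records$tokens <- NULL
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}
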