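#' Exclusion word lists for content-word filtering
#'
#' The scoring scheme keeps content words and drops function words. The
#' grammatical classes excluded are: articles, coordinating conjunctions,
#' personal pronouns, possessive pronouns/determiners, and all inflections
#' of the auxiliaries be/do/have. The `"extended"` profile (default)
#' additionally drops common prepositions and modal auxiliaries, which is
#' what reproduces the worked scoring examples (e.g. "in", "can" and
#' "either" unscored while "like" and "often" are scored); the
#' `"strict_paper"` profile keeps only the five named classes.
#'
#' @param profile `"extended"` (default) or `"strict_paper"`.
#' @param extra Additional words to exclude.
#' @return Character vector of lowercase words to exclude.
#' @export
exclusion_words <- function(profile = c("extended", "strict_paper"),
                            extra = character()) {
  profile <- match.arg(profile)
  articles <- c("a", "an", "the")
  coord_conj <- c("and", "but", "or", "nor", "for", "so", "yet")
  pers_pron <- c("i", "you", "he", "she", "it", "we", "they",
                 "me", "him", "her", "us", "them")
  poss_pron <- c("my", "your", "his", "her", "its", "our", "their",
                 "mine", "yours", "hers", "ours", "theirs")
  aux <- c("be", "am", "is", "are", "was", "were", "been", "being",
           "do", "does", "did", "doing", "done",
           "have", "has", "had", "having")
  base <- c(articles, coord_conj, pers_pron, poss_pron, aux)
  if (profile == "extended") {
    preps <- c("in", "on", "at", "of", "to", "from", "with", "by",
               "about", "as", "into", "over", "under", "between",
               "through", "during", "without", "within", "upon")
    modals <- c("can", "could", "will", "would", "shall", "should",
                "may", "might", "must", "either", "neither")
    base <- c(base, preps, modals)
  }
  unique(c(base, tolower(extra)))
}

#' Tokenize a raw feature string
#'
#' Splits on whitespace, strips punctuation from token edges, lowercases
#' per policy, and never returns empty strings.
#'
#' @param text A single feature string.
#' @param lowercase Lowercase tokens (default `TRUE`).
#' @return Character vector of tokens (possibly empty).
#' @export
tokenize <- function(text, lowercase = TRUE) {
  stopifnot(length(text) == 1L)
  if (is.na(text)) return(character())
  toks <- strsplit(trimws(text), "[[:space:]]+")[[1]]
  toks <- gsub("^[[:punct:]]+|[[:punct:]]+$", "", toks)
  toks <- toks[nzchar(toks)]
  if (lowercase) toks <- tolower(toks)
  toks
}

#' Filter a token list down to content words
#'
#' Removes every token found in the exclusion list, preserving order.
#' Filtering is idempotent and never reorders tokens.
#'
#' @param tokens Character vector of normalised tokens.
#' @param exclusions Character vector from [exclusion_words()].
#' @return The content-word subset, in original order.
#' @export
filter_content_words <- function(tokens, exclusions = exclusion_words()) {
  tokens[!(tokens %in% exclusions)]
}

#' Read a transcript table of feature-generation trials
#'
#' Expects a TSV (or CSV) with header columns `subject_id`, `group`,
#' `target_word`, `position`, `feature_text`. Rows are grouped into trial
#' records; within each trial, positions must be contiguous from 1.
#'
#' @param path Path to the table.
#' @param sep Field separator, `"\t"` (default) or `","`.
#' @return A data frame of class `trial_table` with one row per feature,
#'   ordered by subject, target and position.
#' @export
read_trials <- function(path, sep = "\t") {
  if (!file.exists(path)) stop("transcript file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          stringsAsFactors = FALSE, comment.char = "",
                          fileEncoding = "UTF-8")
  as_trial_table(df)
}

#' Validate a raw transcript data frame
#'
#' @param df Data frame with the transcript schema.
#' @return The validated, ordered `trial_table`.
#' @export
as_trial_table <- function(df) {
  need <- c("subject_id", "group", "target_word", "position", "feature_text")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L)
    stop("transcript table is missing column(s): ", paste(miss, collapse = ", "))
  bad_group <- setdiff(unique(df$group), c("CO", "HP"))
  if (length(bad_group) > 0L)
    stop("unknown group label(s): ", paste(bad_group, collapse = ", "))
  df$position <- as.integer(df$position)
  key <- interaction(df$subject_id, df$target_word, drop = TRUE)
  dup <- duplicated(data.frame(key, df$position))
  if (any(dup))
    stop(sprintf("duplicate (subject, target, position): %s/%s position %d",
                 df$subject_id[dup][1L], df$target_word[dup][1L],
                 df$position[dup][1L]))
  for (k in levels(key)) {
    pos <- sort(df$position[key == k])
    if (!identical(pos, seq_along(pos)))
      stop("positions not contiguous from 1 in trial ", k)
  }
  # one group per subject
  for (s in unique(df$subject_id)) {
    g <- unique(df$group[df$subject_id == s])
    if (length(g) > 1L)
      stop("subject ", s, " appears under more than one group label")
  }
  df <- df[order(df$subject_id, df$target_word, df$position), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("trial_table", "data.frame")
  df
}

#' Prepare trials: tokenize and content-filter every feature
#'
#' Adds a `tokens` list-column of filtered content words and an
#' `all_excluded` flag for features whose every token was excluded. Such
#' features are kept (positions are the x-axis of the decay analyses and
#' must not silently shift); downstream scoring skips them.
#'
#' @param trials A `trial_table`.
#' @param exclusions Exclusion word vector, see [exclusion_words()].
#' @param lowercase Lowercase tokens (default `TRUE`).
#' @return The `trial_table` with `tokens` and `all_excluded` columns.
#' @export
prepare_trials <- function(trials, exclusions = exclusion_words(),
                           lowercase = TRUE) {
  stopifnot(inherits(trials, "trial_table") || is.data.frame(trials))
  raw_tokens <- lapply(trials$feature_text, tokenize, lowercase = lowercase)
  trials$tokens <- lapply(raw_tokens, filter_content_words,
                          exclusions = exclusions)
  trials$all_excluded <- lengths(raw_tokens) > 0L & lengths(trials$tokens) == 0L
  n_flag <- sum(trials$all_excluded)
  if (n_flag > 0L)
    message(n_flag, " feature(s) had all tokens excluded; kept with empty ",
            "token lists")
  class(trials) <- c("trial_table", "data.frame")
  trials
}

#' Split a trial table into per-trial records
#'
#' @param trials A prepared `trial_table`.
#' @return A list of trial records, each with `subject_id`, `group`,
#'   `target_word` and the ordered per-position data frame.
#' @export
split_trials <- function(trials) {
  key <- interaction(trials$subject_id, trials$target_word, drop = TRUE)
  lapply(split(seq_len(nrow(trials)), key), function(idx) {
    rows <- trials[idx, , drop = FALSE]
    rows <- rows[order(rows$position), , drop = FALSE]
    list(subject_id = rows$subject_id[1L],
         group = rows$group[1L],
         target_word = rows$target_word[1L],
         features = rows)
  })
}
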