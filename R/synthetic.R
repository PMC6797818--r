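#' Deterministic fixture embedding space
#'
#' Seeded random unit vectors for a fixed word list; the same seed yields a
#' bit-identical space. Used throughout the test suite so that no embedding
#' download is ever required.
#'
#' @param words Character vector of words.
#' @param dims Vector dimension (>= 2).
#' @param seed Integer seed.
#' @return An `embedding_space`.
#' @export
make_fixture_space <- function(words, dims = 16, seed = 1) {
  stopifnot(dims >= 2, length(words) >= 1)
  words <- tolower(words)
  if (anyDuplicated(words)) stop("duplicate words in fixture word list")
  set.seed(seed)
  mat <- matrix(stats::rnorm(length(words) * dims), nrow = length(words))
  mat <- mat / sqrt(rowSums(mat^2))
  rownames(mat) <- words
  new_embedding_space(mat, lowercase = TRUE)
}

#' Generate power-law decay records with known parameters
#'
#' Scores follow `a * x^b` plus Gaussian noise. Each subject contributes
#' `n_per_cell` records at each x in `1..x_max`, mirroring a design of one
#' observation per target word (default 35 words). Generating parameters
#' are attached as attributes for recovery tests.
#'
#' @param a,b Power-law parameters (a > 0).
#' @param noise_sd Observation noise standard deviation.
#' @param n_subjects Number of subjects.
#' @param x_max Largest x (>= 2).
#' @param seed Integer seed.
#' @param n_per_cell Records per subject per x (default 35).
#' @param group Group label attached to every record.
#' @param x_name Name of the x column (default `"position"`).
#' @param subject_prefix Prefix for generated subject identifiers.
#' @return Record data frame with attributes `truth` (list of generating
#'   parameters).
#' @export
generate_power_law_records <- function(a, b, noise_sd, n_subjects, x_max,
                                       seed = 1, n_per_cell = 35,
                                       group = "CO", x_name = "position",
                                       subject_prefix = group) {
  stopifnot(a > 0, x_max >= 2, n_subjects >= 1, noise_sd >= 0)
  set.seed(seed)
  x <- rep(rep(seq_len(x_max), each = n_per_cell), n_subjects)
  subj <- rep(sprintf("%s%02d", subject_prefix, seq_len(n_subjects)),
              each = x_max * n_per_cell)
  score <- a * x^b + stats::rnorm(length(x), 0, noise_sd)
  out <- data.frame(subject_id = subj, group = group, score = score,
                    stringsAsFactors = FALSE)
  out[[x_name]] <- x
  out$target_word <- sprintf("w%02d", rep_len(seq_len(n_per_cell), nrow(out)))
  attr(out, "truth") <- list(a = a, b = b, noise_sd = noise_sd)
  out
}

#' Generate two-group records from the mixed-effects generative model
#'
#' Draws scores from `exp(mu + beta * I(HP) + s + w + e)` (lognormal
#' family) or its identity-scale analogue, with known variance components,
#' for mixed-model parameter-recovery tests.
#'
#' @param beta_group Group shift on the linear (log) scale.
#' @param mu Intercept on the linear scale (default `log(0.2)`, a typical
#'   cosine similarity level).
#' @param sigma_s,sigma_w,sigma_e Subject, word and residual SDs.
#' @param n_hp,n_co Subjects per group.
#' @param n_words Number of target words.
#' @param n_rep Records per subject x word.
#' @param family `"lognormal"` or `"normal"`.
#' @param seed Integer seed.
#' @return Record data frame with a `truth` attribute.
#' @export
generate_group_records <- function(beta_group, mu = log(0.2),
                                   sigma_s = 0.05, sigma_w = 0.05,
                                   sigma_e = 0.5,
                                   n_hp = 5, n_co = 15, n_words = 35,
                                   n_rep = 5,
                                   family = c("lognormal", "normal"),
                                   seed = 1) {
  family <- match.arg(family)
  set.seed(seed)
  subjects <- c(sprintf("HP%02d", seq_len(n_hp)),
                sprintf("CO%02d", seq_len(n_co)))
  grp <- c(rep("HP", n_hp), rep("CO", n_co))
  s_eff <- stats::rnorm(length(subjects), 0, sigma_s)
  w_eff <- stats::rnorm(n_words, 0, sigma_w)
  words <- sprintf("w%02d", seq_len(n_words))
  idx <- expand.grid(s = seq_along(subjects), w = seq_len(n_words),
                     r = seq_len(n_rep))
  lin <- mu + beta_group * (grp[idx$s] == "HP") + s_eff[idx$s] +
    w_eff[idx$w] + stats::rnorm(nrow(idx), 0, sigma_e)
  score <- if (family == "lognormal") exp(lin) else lin
  out <- data.frame(subject_id = subjects[idx$s], group = grp[idx$s],
                    target_word = words[idx$w],
                    position = idx$r, score = score,
                    stringsAsFactors = FALSE)
  attr(out, "truth") <- list(beta_group = beta_group, mu = mu,
                             sigma_s = sigma_s, sigma_w = sigma_w,
                             sigma_e = sigma_e, family = family)
  out
}

#' Configuration of the compound-retrieval-cue search simulator
#'
#' The simulator formalises a verbal model of semantic memory search: a
#' retrieval cue probes a semantic space, activating candidate feature
#' concepts in proportion to their proximity, and the winning concept is
#' reported and folded back into the cue. Step t uses the compound cue
#' `c_t = lambda_t * v_target + (1 - lambda_t) * v_prev` (normalised;
#' `c_1 = v_target`). The default weight schedule
#' `lambda_t = max(lambda_min, gamma^(t-1))` makes the target become
#' progressively less influential while never vanishing from the cue.
#' The hippocampal-damage analogue is a range limit: candidates whose
#' similarity to the target falls below `range_limit` are ineligible,
#' restricting how far search can roam from the target. All functional
#' choices here are this package's formalisation; the simulator is a data
#' generator and hypothesis demonstrator, not a fitted cognitive model.
#'
#' @param dims Embedding dimension.
#' @param n_candidates Candidate feature concepts per target.
#' @param target_spread Noise scale controlling how widely candidates
#'   scatter around the target vector (larger = farther).
#' @param lambda_gamma,lambda_min Cue weight schedule parameters.
#' @param sharpness Exponent converting cue-candidate similarity into
#'   retrieval support (`Inf` = greedy).
#' @param range_limit Minimum cosine(candidate, target) for eligibility
#'   (-1 disables the restriction).
#' @param max_responses Stop after this many responses.
#' @param stop_prob Per-step termination probability after each response.
#' @return A `search_sim_config`.
#' @export
search_sim_config <- function(dims = 50, n_candidates = 60,
                              target_spread = 5,
                              lambda_gamma = 0.8, lambda_min = 0.3,
                              sharpness = 8, range_limit = -1,
                              max_responses = 20, stop_prob = 0) {
  stopifnot(dims >= 2, n_candidates >= max_responses,
            lambda_gamma >= 0, lambda_gamma <= 1,
            lambda_min >= 0, lambda_min <= 1,
            sharpness > 0, stop_prob >= 0, stop_prob < 1)
  structure(list(dims = dims, n_candidates = n_candidates,
                 target_spread = target_spread,
                 lambda_gamma = lambda_gamma, lambda_min = lambda_min,
                 sharpness = sharpness, range_limit = range_limit,
                 max_responses = max_responses, stop_prob = stop_prob),
            class = "search_sim_config")
}

cue_weight <- function(t, cfg) max(cfg$lambda_min, cfg$lambda_gamma^(t - 1))

normalize_vec <- function(v) {
  nv <- sqrt(sum(v^2))
  if (nv == 0) stop("cannot normalise a zero vector")
  v / nv
}

#' Simulate one memory-search trial
#'
#' Runs the compound-retrieval-cue search over a candidate set already
#' present in `space` (candidate words must be supplied). At each step the
#' eligible, not-yet-reported candidate with support proportional to
#' `max(cos(cue, cand), 0)^sharpness` is sampled (without replacement);
#' with `sharpness = Inf` selection is greedy. A trial ends at the stop
#' rule or when no eligible candidate remains (a valid short trial).
#'
#' @param target Target word (must be in `space`).
#' @param candidates Character vector of candidate words in `space`.
#' @param space An `embedding_space`.
#' @param cfg A [search_sim_config()].
#' @param seed Optional integer seed (set before the trial if given).
#' @return Character vector of reported candidate words, in order.
#' @export
simulate_search <- function(target, candidates, space, cfg, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tv <- embedding_vector(space, target)
  if (is.null(tv)) stop("target word out of vocabulary: ", target)
  cand_mat <- t(vapply(candidates, function(w) {
    v <- embedding_vector(space, w)
    if (is.null(v)) stop("candidate out of vocabulary: ", w)
    normalize_vec(v)
  }, numeric(attr(space, "dims"))))
  tvn <- normalize_vec(tv)
  target_sim <- as.vector(cand_mat %*% tvn)
  eligible <- target_sim >= cfg$range_limit
  reported <- logical(length(candidates))
  out <- character(0)
  prev <- NULL
  for (t in seq_len(cfg$max_responses)) {
    lam <- cue_weight(t, cfg)
    cue <- if (is.null(prev)) tvn else {
      normalize_vec(lam * tvn + (1 - lam) * prev)
    }
    avail <- which(eligible & !reported)
    if (length(avail) == 0L) break
    support <- pmax(as.vector(cand_mat[avail, , drop = FALSE] %*% cue), 0)
    pick <- if (is.infinite(cfg$sharpness)) {
      avail[which.max(support)]
    } else {
      w <- support^cfg$sharpness
      if (sum(w) <= 0) w <- rep(1, length(avail))
      if (length(avail) == 1L) avail else sample(avail, 1L, prob = w)
    }
    reported[pick] <- TRUE
    out <- c(out, candidates[pick])
    prev <- cand_mat[pick, ]
    if (cfg$stop_prob > 0 && stats::runif(1) < cfg$stop_prob) break
  }
  out
}

#' Configuration of a full synthetic cohort
#'
#' Defaults mirror the study design: 5 hippocampal-patient (HP) and 15
#' comparison (CO) subjects, 35 target words. The HP group's simulator has
#' a range restriction and a shorter response budget (patients produced
#' roughly half as many features); the CO group is unrestricted.
#'
#' @param n_hp,n_co Subjects per group.
#' @param n_targets Number of target words.
#' @param co_config,hp_config Per-group [search_sim_config()].
#' @param max_extra_words Multi-word features carry the chosen candidate
#'   word plus 0..`max_extra_words` sampled neighbour words.
#' @return A `cohort_config`.
#' @export
cohort_config <- function(n_hp = 5, n_co = 15, n_targets = 35,
                          co_config = search_sim_config(range_limit = -1,
                                                        max_responses = 20),
                          hp_config = search_sim_config(range_limit = 0.2,
                                                        max_responses = 10),
                          max_extra_words = 2) {
  stopifnot(n_hp >= 1, n_co >= 1, n_targets >= 1,
            co_config$dims == hp_config$dims)
  structure(list(n_hp = n_hp, n_co = n_co, n_targets = n_targets,
                 co_config = co_config, hp_config = hp_config,
                 max_extra_words = max_extra_words),
            class = "cohort_config")
}

#' Generate a full synthetic cohort
#'
#' Builds an embedding space holding target words, per-target candidate
#' feature words (scattered around each target vector with the configured
#' spread) and neighbour words; then simulates every subject x target
#' trial with the group's simulator, realising each feature as the chosen
#' candidate word plus 0-2 neighbour words so the multi-word scoring path
#' is exercised end to end.
#'
#' @param cfg A [cohort_config()].
#' @param seed Integer seed; the same seed reproduces the cohort exactly.
#' @return List with `trials` (a `trial_table` in the transcript schema),
#'   `space` (the fixture `embedding_space`) and `truth` (configs and
#'   seeds).
#' @export
generate_cohort <- function(cfg = cohort_config(), seed = 1) {
  stopifnot(inherits(cfg, "cohort_config"))
  set.seed(seed)
  dims <- cfg$co_config$dims
  n_cand <- max(cfg$co_config$n_candidates, cfg$hp_config$n_candidates)

  targets <- sprintf("target%02d", seq_len(cfg$n_targets))
  tmat <- matrix(stats::rnorm(cfg$n_targets * dims), nrow = cfg$n_targets)
  tmat <- tmat / sqrt(rowSums(tmat^2))

  # candidates scattered around each target; neighbours scattered around
  # each candidate (closer in, so they plausibly share the feature's sense)
  words <- targets
  vecs <- tmat
  cand_words <- vector("list", cfg$n_targets)
  nbr_words <- vector("list", cfg$n_targets)
  spread <- cfg$co_config$target_spread
  for (k in seq_len(cfg$n_targets)) {
    cw <- sprintf("t%02dcand%03d", k, seq_len(n_cand))
    cmat <- tmat[rep(k, n_cand), ] +
      spread * matrix(stats::rnorm(n_cand * dims), nrow = n_cand) / sqrt(dims)
    cmat <- cmat / sqrt(rowSums(cmat^2))
    nw <- sprintf("t%02dnbr%03d", k, seq_len(n_cand))
    nmat <- cmat + 0.3 * spread *
      matrix(stats::rnorm(n_cand * dims), nrow = n_cand) / sqrt(dims)
    nmat <- nmat / sqrt(rowSums(nmat^2))
    words <- c(words, cw, nw)
    vecs <- rbind(vecs, cmat, nmat)
    cand_words[[k]] <- cw
    nbr_words[[k]] <- nw
  }
  rownames(vecs) <- words
  space <- new_embedding_space(vecs, lowercase = TRUE)

  subjects <- c(sprintf("HP%02d", seq_len(cfg$n_hp)),
                sprintf("CO%02d", seq_len(cfg$n_co)))
  grp <- c(rep("HP", cfg$n_hp), rep("CO", cfg$n_co))
  rows <- list()
  for (i in seq_along(subjects)) {
    gcfg <- if (grp[i] == "HP") cfg$hp_config else cfg$co_config
    for (k in seq_len(cfg$n_targets)) {
      picks <- simulate_search(targets[k], cand_words[[k]], space, gcfg)
      if (length(picks) == 0L) next
      for (p in seq_along(picks)) {
        n_extra <- sample(0:cfg$max_extra_words, 1L)
        extra <- if (n_extra > 0) {
          ci <- match(picks[p], cand_words[[k]])
          # neighbours of the chosen candidate, same index block
          nbr_pool <- nbr_words[[k]][unique(c(ci, sample(n_cand, n_extra)))]
          utils::head(nbr_pool, n_extra)
        } else character(0)
        rows[[length(rows) + 1L]] <-
          data.frame(subject_id = subjects[i], group = grp[i],
                     target_word = targets[k], position = p,
                     feature_text = paste(c(picks[p], extra), collapse = " "),
                     stringsAsFactors = FALSE)
      }
    }
  }
  trials <- as_trial_table(do.call(rbind, rows))
  truth <- list(seed = seed,
                n_hp = cfg$n_hp, n_co = cfg$n_co, n_targets = cfg$n_targets,
                co_config = unclass(cfg$co_config),
                hp_config = unclass(cfg$hp_config))
  list(trials = trials, space = space, truth = truth)
}

#' Write a synthetic cohort to disk
#'
#' Serialises the transcript TSV (exact schema read by [read_trials()]),
#' the embedding text file and the truth metadata JSON.
#'
#' @param cohort Result of [generate_cohort()].
#' @param out_dir Output directory (created if absent).
#' @return Named list of written paths, invisibly.
#' @export
write_cohort <- function(cohort, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(trials = file.path(out_dir, "trials.tsv"),
                embeddings = file.path(out_dir, "embeddings.txt"),
                truth = file.path(out_dir, "truth.json"))
  df <- as.data.frame(cohort$trials)
  df <- df[, c("subject_id", "group", "target_word", "position",
               "feature_text")]
  utils::write.table(df, paths$trials, sep = "\t", row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  write_embeddings(cohort$space, paths$embeddings)
  jsonlite::write_json(cohort$truth, paths$truth, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}
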