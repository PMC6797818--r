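#' Analysis configuration
#'
#' A flat-key configuration, readable from YAML via [read_config()].
#' Toggles select which of the four analyses run: the overall group-shift
#' mixed model (all positions, lognormal), the position power law (first
#' five responses), the lag analyses (mixed model with normal response and
#' lag power law), and the leave-one-out robustness loop.
#'
#' @param embeddings_path Path to the embedding text file.
#' @param transcripts_path Path to the transcript TSV.
#' @param out_dir Output directory.
#' @param embeddings_dims Expected embedding dimension (optional).
#' @param embeddings_lowercase Case policy for the space.
#' @param exclusion_profile `"extended"` or `"strict_paper"`.
#' @param extra_exclusions Additional exclusion words.
#' @param max_position Position cap for the position power law (default 5).
#' @param max_lag Lag cap (default 4).
#' @param lognormal_policy Non-positive score policy for the lognormal
#'   family.
#' @param powerlaw_data_mode `"raw"` or `"subject_mean"`.
#' @param mcmc_chains,mcmc_iterations,mcmc_warmup,mcmc_seed MCMC protocol.
#' @param overall_shift,position_powerlaw,lag_powerlaw,leave_one_out
#'   Analysis toggles.
#' @return An `analysis_config`.
#' @export
analysis_config <- function(embeddings_path = NULL, transcripts_path = NULL,
                            out_dir = "semsearch-out",
                            embeddings_dims = NULL,
                            embeddings_lowercase = TRUE,
                            exclusion_profile = "extended",
                            extra_exclusions = character(),
                            max_position = 5, max_lag = 4,
                            lognormal_policy = "shift_epsilon",
                            powerlaw_data_mode = "raw",
                            mcmc_chains = 4, mcmc_iterations = 4000,
                            mcmc_warmup = floor(mcmc_iterations / 2),
                            mcmc_seed = 1,
                            overall_shift = TRUE, position_powerlaw = TRUE,
                            lag_powerlaw = TRUE, leave_one_out = FALSE) {
  structure(as.list(environment()), class = "analysis_config")
}

#' Read an analysis configuration from YAML
#'
#' Keys use dotted sections flattened with underscores or nested maps,
#' e.g. `embeddings: {path: ..., dims: 300}`.
#'
#' @param path YAML file path.
#' @return An `analysis_config`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  flat <- list()
  grab <- function(section, key, new) {
    val <- raw[[section]][[key]]
    if (!is.null(val)) flat[[new]] <<- val
  }
  grab("embeddings", "path", "embeddings_path")
  grab("embeddings", "dims", "embeddings_dims")
  grab("embeddings", "lowercase", "embeddings_lowercase")
  grab("prep", "exclusion_profile", "exclusion_profile")
  grab("prep", "extra_exclusions", "extra_exclusions")
  grab("model", "lognormal_policy", "lognormal_policy")
  grab("model", "powerlaw_data_mode", "powerlaw_data_mode")
  grab("mcmc", "chains", "mcmc_chains")
  grab("mcmc", "iterations", "mcmc_iterations")
  grab("mcmc", "warmup", "mcmc_warmup")
  grab("mcmc", "seed", "mcmc_seed")
  for (k in c("transcripts_path", "out_dir", "max_position", "max_lag",
              "overall_shift", "position_powerlaw", "lag_powerlaw",
              "leave_one_out"))
    if (!is.null(raw[[k]])) flat[[k]] <- raw[[k]]
  do.call(analysis_config, flat)
}

summarise_fit <- function(post, parameters = NULL) {
  s <- summary(post, parameters = parameters)
  conv <- post$convergence
  list(summary = s,
       convergence = list(pass = attr(conv, "pass"),
                          threshold = attr(conv, "threshold"),
                          max_rhat = max(conv$rhat, na.rm = TRUE),
                          min_ess = min(conv$ess, na.rm = TRUE)))
}

diff_to_list <- function(d) {
  list(parameter = d$parameter, mean = d$mean,
       prop_above_zero = d$prop_above_zero, q2.5 = d$q2.5, q97.5 = d$q97.5)
}

#' Run the full analysis pipeline
#'
#' Sequences: load embeddings, read and prepare transcripts, build
#' similarity records, then the enabled Bayesian analyses. Writes tidy
#' record CSVs, posterior draw CSVs, and a JSON report with posterior
#' summaries, difference distributions, convergence diagnostics and a
#' provenance block; the same config and seed reproduce the same report.
#'
#' @param config An [analysis_config()].
#' @param space Optionally, an already-loaded `embedding_space` (otherwise
#'   loaded from `config$embeddings_path`).
#' @param trials Optionally, an already-loaded `trial_table`.
#' @return The `analysis_report` list, invisibly written to
#'   `out_dir/report.json`.
#' @export
run_pipeline <- function(config, space = NULL, trials = NULL) {
  stopifnot(inherits(config, "analysis_config"))
  t0 <- Sys.time()
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    message("[", name, "] ...")
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  if (is.null(space))
    space <- stage("embeddings",
                   load_embeddings(config$embeddings_path,
                                   expected_dims = config$embeddings_dims,
                                   lowercase = config$embeddings_lowercase))
  if (is.null(trials))
    trials <- stage("transcripts", read_trials(config$transcripts_path))
  excl <- exclusion_words(config$exclusion_profile,
                          extra = config$extra_exclusions)
  trials <- stage("prep", prepare_trials(trials, exclusions = excl))

  mcmc <- mcmc_config(chains = config$mcmc_chains,
                      iterations = config$mcmc_iterations,
                      warmup = config$mcmc_warmup, seed = config$mcmc_seed)

  pos_all <- stage("score-positions-all",
                   build_position_records(trials, space, max_position = Inf))
  pos_cap <- pos_all[pos_all$position <= config$max_position, , drop = FALSE]
  lag_recs <- stage("score-lags",
                    build_lag_records(trials, space, max_lag = config$max_lag))
  write_records(pos_all, file.path(config$out_dir, "position_records.csv"))
  write_records(lag_recs, file.path(config$out_dir, "lag_records.csv"))

  report <- list(
    descriptives = list(
      overall = group_summary(pos_all),
      first_positions = group_summary(pos_cap),
      lags = if (nrow(lag_recs) > 0) group_summary(lag_recs) else NULL),
    provenance = list(package_version = as.character(
                        utils::packageVersion("semsearch")),
                      mcmc = unclass(mcmc),
                      exclusion_profile = config$exclusion_profile,
                      max_position = config$max_position,
                      max_lag = config$max_lag,
                      n_position_records = nrow(pos_all),
                      n_lag_records = nrow(lag_recs)))

  mspec <- mixed_model_spec(response_family = "lognormal",
                            lognormal_policy = config$lognormal_policy)
  if (isTRUE(config$overall_shift)) {
    fit <- stage("overall-shift", fit_mixed_model(pos_all, mspec, mcmc))
    report$overall_shift <- summarise_fit(
      fit, c("mu", "beta_group", "sigma_e", "sigma_s", "sigma_w"))
    save_draws(fit, file.path(config$out_dir, "overall_shift_draws.csv"))
  }
  if (isTRUE(config$position_powerlaw)) {
    pspec <- power_law_spec(x_var = "position",
                            data_mode = config$powerlaw_data_mode)
    fit <- stage("position-powerlaw", fit_power_law(pos_cap, pspec, mcmc))
    report$position_powerlaw <- summarise_fit(
      fit, grep("_bar|sigma", dimnames(fit$draws)[[3]], value = TRUE))
    report$position_powerlaw$difference_a <-
      diff_to_list(difference_distribution(fit, "a"))
    report$position_powerlaw$difference_b <-
      diff_to_list(difference_distribution(fit, "b"))
    save_draws(fit, file.path(config$out_dir, "position_powerlaw_draws.csv"))
  }
  if (isTRUE(config$lag_powerlaw) && nrow(lag_recs) > 0) {
    fit <- stage("lag-mixed",
                 fit_mixed_model(lag_recs,
                                 mixed_model_spec(response_family = "normal"),
                                 mcmc))
    report$lag_shift <- summarise_fit(
      fit, c("mu", "beta_group", "sigma_e", "sigma_s", "sigma_w"))
    lspec <- power_law_spec(x_var = "lag",
                            data_mode = config$powerlaw_data_mode)
    fit <- stage("lag-powerlaw", fit_power_law(lag_recs, lspec, mcmc))
    report$lag_powerlaw <- summarise_fit(
      fit, grep("_bar|sigma", dimnames(fit$draws)[[3]], value = TRUE))
    report$lag_powerlaw$difference_a <-
      diff_to_list(difference_distribution(fit, "a"))
    report$lag_powerlaw$difference_b <-
      diff_to_list(difference_distribution(fit, "b"))
    save_draws(fit, file.path(config$out_dir, "lag_powerlaw_draws.csv"))
  }
  if (isTRUE(config$leave_one_out)) {
    report$leave_one_out <- stage(
      "leave-one-out",
      leave_one_out_by_subject(pos_all, group = "HP", spec = mspec,
                               mcmc = mcmc))
  }

  report$provenance$elapsed_sec <-
    as.numeric(difftime(Sys.time(), t0, units = "secs"))
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows", force = TRUE)
  invisible(report)
}

#' Save posterior draws as tidy CSV
#'
#' One row per (chain, iteration), one column per parameter.
#'
#' @param posterior An `mcmc_posterior`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
save_draws <- function(posterior, path) {
  d <- posterior$draws
  niter <- dim(d)[1]; nchain <- dim(d)[2]
  flat <- do.call(rbind, lapply(seq_len(nchain), function(c)
    d[, c, , drop = TRUE]))
  out <- data.frame(chain = rep(seq_len(nchain), each = niter),
                    iteration = rep(seq_len(niter), nchain))
  out <- cbind(out, as.data.frame(flat))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Plot trajectory curves with fitted power functions
#'
#' Writes one figure per analysis: per-group mean scores at each x with
#' the posterior-mean power curve and a pointwise 95% band.
#'
#' @param records Record data frame (`position` or `lag` x column).
#' @param posterior The matching power-law `mcmc_posterior`.
#' @param x_var `"position"` or `"lag"`.
#' @param path Output file (PDF or PNG by extension).
#' @return `path`, invisibly.
#' @export
plot_trajectories <- function(records, posterior, x_var = "position", path) {
  x <- records[[x_var]]
  groups <- sort(unique(records$group))
  xs <- sort(unique(x))
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") grDevices::png(path, width = 800, height = 600)
  else grDevices::pdf(path, width = 7, height = 5)
  on.exit(grDevices::dev.off())
  cols <- c(CO = "#1b6ca8", HP = "#c0392b")
  graphics::plot(NULL, xlim = range(xs), ylim = range(records$score),
                 xlab = x_var, ylab = "cosine similarity",
                 main = paste("similarity by", x_var))
  xfine <- seq(min(xs), max(xs), length.out = 50)
  for (g in groups) {
    mg <- tapply(records$score[records$group == g], x[records$group == g],
                 mean)
    curve_df <- power_curve(posterior, g, xfine)
    graphics::polygon(c(xfine, rev(xfine)),
                      c(curve_df$lower, rev(curve_df$upper)),
                      col = grDevices::adjustcolor(cols[[g]], alpha.f = 0.15),
                      border = NA)
    graphics::lines(xfine, curve_df$fit, col = cols[[g]], lwd = 2)
    graphics::points(as.numeric(names(mg)), mg, col = cols[[g]], pch = 19)
  }
  graphics::legend("topright", legend = groups, col = cols[groups], lwd = 2)
  invisible(path)
}
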