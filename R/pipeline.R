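# End-to-end pipeline: simulate (or load) behavior and epochs, fit the
# serial-bias regression, decode past information from residualized signals,
# estimate the past-present interaction, run group cluster statistics and
# the neuro-behavioral correlation, and write tidy outputs plus a manifest.
# With a fixed config the outputs are byte-identical across runs.

#' Default pipeline configuration
#'
#' Desk-scale settings for a full synthetic run of the experiment-1
#' analysis circle.  Any element can be overridden via `modifyList()` or a
#' YAML config file.
#'
#' @return A named list.
#' @export
default_config <- function() {
  list(experiment = 1L,
       seed = 1L,
       n_subjects = 8L,
       n_trials_per_block = 40L,
       n_blocks = 2L,
       truth = list(axis_angle = 180),
       n_channels = 16L,
       sfreq = 100,
       epoch_window = c(-100, 400),
       window_ms = 50,
       smooth_ms = 50,
       n_perm = 500L,
       cluster_alpha = 0.05,
       predictors = c("current_stimulus", "current_start", "previous_report"),
       residualize = c("current_stimulus", "current_start"),
       past = "previous_report",
       present = "current_stimulus")
}

#' Load a pipeline configuration from YAML
#'
#' Missing fields fall back to [default_config()].
#'
#' @param path YAML file path.
#' @return A config list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  out <- utils::modifyList(default_config(), cfg)
  if (is.null(out$seed)) stop("config must set an integer `seed`")
  out
}

#' Run the full serial-dependence analysis pipeline on synthetic data
#'
#' Simulates behavior and epoched neural data from the configured ground
#' truth, fits the serial-bias regression, decodes the past predictor from
#' residualized signals, estimates the past-present interaction, applies
#' the sign-flip cluster permutation test, and correlates the
#' cluster-averaged neural interaction with the behavioral bias across
#' subjects.  Writes tidy CSV/JSON outputs and a manifest into `out_dir`.
#'
#' @param config a config list (see [default_config()]) or a YAML path.
#' @param out_dir output directory (created if needed).
#' @return Invisibly, a list with the in-memory results.
#' @export
run_pipeline <- function(config = default_config(), out_dir) {
  if (is.character(config)) config <- read_run_config(config)
  cfg <- utils::modifyList(default_config(), config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  truth <- do.call(ground_truth, cfg$truth)
  seed <- as.integer(cfg$seed)

  trials <- simulate_behavior_exp1(n_subjects = cfg$n_subjects,
                                   n_trials_per_block = cfg$n_trials_per_block,
                                   n_blocks = cfg$n_blocks,
                                   truth = truth, seed = derive_seed(seed, 0L))
  fit <- fit_serial_regression(trials, predictors = cfg$predictors)

  subjects <- sort(unique(trials$subject))
  decode_rows <- list(); inter_rows <- list()
  inter_mat <- NULL
  for (s in subjects) {
    tr_s <- trials[trials$subject == s, , drop = FALSE]
    ep <- simulate_neural(tr_s, truth, n_channels = cfg$n_channels,
                          sfreq = cfg$sfreq, epoch_window = cfg$epoch_window,
                          present = cfg$present, past = cfg$past,
                          seed = derive_seed(seed, 100L + s))
    dec <- decode_timecourse(ep, tr_s, cfg$past, window_ms = cfg$window_ms,
                             residualize = cfg$residualize)
    itc <- interaction_timecourse(ep, tr_s, predictors = cfg$predictors,
                                  past = cfg$past, present = cfg$present,
                                  smooth_ms = cfg$smooth_ms)
    decode_rows[[s]] <- data.frame(subject = s, predictor = cfg$past,
                                   time_ms = dec$time_ms, beta = dec$beta)
    inter_rows[[s]] <- data.frame(subject = s,
                                  pair = paste(cfg$past, cfg$present,
                                               sep = ":"),
                                  time_ms = itc$time_ms,
                                  cosine = itc$cosine)
    inter_mat <- rbind(inter_mat, itc$cosine)
  }
  times <- decode_rows[[1]]$time_ms
  perm <- sign_permutation_test(inter_mat, n_perm = cfg$n_perm,
                                seed = derive_seed(seed, 999L),
                                times = times)
  clus <- cluster_correction(perm, cluster_alpha = cfg$cluster_alpha)

  windows <- significant_windows(clus)
  nb <- NULL
  behav <- fit$coefficients[, cfg$past]
  if (length(windows)) {
    sel <- Reduce(`|`, lapply(windows, function(w)
      times >= w[1] - 1e-9 & times <= w[2] + 1e-9))
    neural <- rowMeans(inter_mat[, sel, drop = FALSE])
    nb <- tryCatch(across_subject_correlation(behav, neural),
                   error = function(e) NULL)
  }

  # tidy outputs
  coef_df <- data.frame(subject = rep(subjects,
                                      times = length(cfg$predictors)),
                        predictor = rep(cfg$predictors,
                                        each = length(subjects)),
                        beta = as.vector(fit$coefficients))
  utils::write.csv(coef_df, file.path(out_dir, "coefficients.csv"),
                   row.names = FALSE)
  utils::write.csv(do.call(rbind, decode_rows),
                   file.path(out_dir, "decoding.csv"), row.names = FALSE)
  utils::write.csv(do.call(rbind, inter_rows),
                   file.path(out_dir, "interaction.csv"), row.names = FALSE)
  jsonlite::write_json(list(threshold = clus$threshold,
                            n_perm = clus$n_perm,
                            clusters = clus$clusters),
                       file.path(out_dir, "clusters.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    if (is.null(nb)) list(note = "no significant clusters; correlation skipped")
    else list(mode = nb$mode, r = nb$r, p = nb$p, df = nb$df),
    file.path(out_dir, "neurobehav.json"), auto_unbox = TRUE, digits = NA)

  outputs <- c("coefficients.csv", "decoding.csv", "interaction.csv",
               "clusters.json", "neurobehav.json")
  manifest <- list(config = cfg,
                   package_version = as.character(utils::packageVersion("serialdep")),
                   outputs = as.list(stats::setNames(
                     unname(tools::md5sum(file.path(out_dir, outputs))),
                     outputs)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(trials = trials, fit = fit, permutation = perm,
                 clusters = clus, neurobehav = nb,
                 interaction = inter_mat, times = times))
}

# ---- command-line interface -------------------------------------------------

parse_cli_args <- function(args) {
  out <- list(); i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (startsWith(a, "--")) {
      key <- sub("^--", "", a)
      if (i + 1L <= length(args) && !startsWith(args[i + 1L], "--")) {
        out[[key]] <- args[i + 1L]; i <- i + 2L
      } else { out[[key]] <- TRUE; i <- i + 1L }
    } else i <- i + 1L
  }
  out
}

#' Command-line entry point
#'
#' Dispatches the subcommands of the `serialdep` command-line tool
#' (installed under `inst/cli/serialdep.R`): `simulate-behavior`,
#' `fit-behavior`, `run`.  The `run` subcommand executes the full pipeline
#' from a YAML config; the others are thin wrappers over the corresponding
#' functions operating on CSV files.
#'
#' @param args character vector of command-line arguments.
#' @return Exit status, invisibly.
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) {
    cat("usage: serialdep <simulate-behavior|fit-behavior|run> [--options]\n")
    return(invisible(1L))
  }
  cmd <- args[1]
  opt <- parse_cli_args(args[-1])
  seed <- as.integer(opt$seed %||% 1L)
  switch(cmd,
    "simulate-behavior" = {
      exp <- as.integer(opt$exp %||% 1L)
      tr <- if (exp == 1L)
        simulate_behavior_exp1(n_subjects = as.integer(opt$subjects %||% 1L),
                               n_trials_per_block = as.integer(opt$trials %||% 50L),
                               n_blocks = as.integer(opt$blocks %||% 2L),
                               seed = seed)
      else
        simulate_behavior_exp2(n_subjects = as.integer(opt$subjects %||% 1L),
                               n_trials = as.integer(opt$trials %||% 100L),
                               seed = seed)
      write_trials(tr, opt$out %||% "trials.csv")
    },
    "fit-behavior" = {
      tr <- read_trials(opt$trials %||% "trials.csv")
      exp <- attr(tr, "experiment")
      if (exp == 1L) {
        fit <- fit_serial_regression(tr)
        utils::write.csv(fit$group, opt$out %||% "serial_fit.csv",
                         row.names = FALSE)
      } else {
        cmp <- compare_choice_models(tr, seed = seed)
        jsonlite::write_json(list(table = cmp$table,
                                  selected = cmp$selected),
                             opt$out %||% "model_comparison.json",
                             auto_unbox = TRUE, digits = NA)
      }
    },
    "run" = {
      cfg <- if (!is.null(opt$config)) read_run_config(opt$config)
             else default_config()
      if (!is.null(opt$seed)) cfg$seed <- seed
      run_pipeline(cfg, opt$out %||% "serialdep_out")
    },
    stop("unknown subcommand: ", cmd))
  invisible(0L)
}
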