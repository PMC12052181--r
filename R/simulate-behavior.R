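#' Simulate the spatial reproduction task (single-item delayed response)
#'
#' Generates per-trial behavior with a known linear report model: per
#' coordinate, the report equals a weighted sum of the current stimulus, the
#' random start position of the response cursor, and the report of the
#' previous trial, plus Gaussian noise.  Stimulus and start locations are
#' sampled independently and uniformly over the disk.  The first trial of
#' each block has no previous report (lagged fields `NA`, `valid_serial`
#' FALSE) and is generated without the serial term.
#'
#' @param n_subjects number of simulated subjects.
#' @param n_trials_per_block trials per block (>= 2).
#' @param n_blocks blocks per subject.
#' @param truth a [ground_truth()]; uses `exp1_coefs` and `exp1_noise_sd`.
#' @param geometry a [disk_geometry()].
#' @param seed integer seed; fixed seed gives an identical table.
#' @return A `trial_table` with columns `subject`, `block`, `trial`,
#'   `current_stimulus_x/_y`, `current_start_x/_y`, `current_report_x/_y`,
#'   `previous_report_x/_y`, `valid_serial`.
#' @export
simulate_behavior_exp1 <- function(n_subjects = 1, n_trials_per_block = 50,
                                   n_blocks = 32, truth = ground_truth(),
                                   geometry = disk_geometry(), seed = NULL) {
  stopifnot(inherits(truth, "ground_truth"), n_trials_per_block >= 2,
            n_subjects >= 1, n_blocks >= 1)
  b <- truth$exp1_coefs
  out <- vector("list", n_subjects)
  for (s in seq_len(n_subjects)) {
    sub_seed <- if (is.null(seed)) NULL else derive_seed(seed, s - 1L)
    out[[s]] <- with_seed(sub_seed, {
      n <- n_trials_per_block * n_blocks
      stim <- sample_disk_locations(n, geometry)
      start <- sample_disk_locations(n, geometry)
      noise <- matrix(rnorm(2 * n, sd = truth$exp1_noise_sd), n, 2)
      block <- rep(seq_len(n_blocks), each = n_trials_per_block)
      # linear recurrence r_t = base_t + b3 * r_{t-1} within each block
      base_xy <- b["current_stimulus"] * stim +
        b["current_start"] * start + noise
      rep_xy <- matrix(NA_real_, n, 2)
      for (bl in seq_len(n_blocks)) {
        idx <- which(block == bl)
        for (ax in 1:2)
          rep_xy[idx, ax] <- as.numeric(
            stats::filter(base_xy[idx, ax], b["previous_report"],
                          method = "recursive"))
      }
      data.frame(subject = s, block = block,
                 trial = sequence(rep(n_trials_per_block, n_blocks)),
                 current_stimulus_x = stim[, 1], current_stimulus_y = stim[, 2],
                 current_start_x = start[, 1], current_start_y = start[, 2],
                 current_report_x = rep_xy[, 1], current_report_y = rep_xy[, 2])
    })
  }
  df <- do.call(rbind, out)
  df <- add_serial_lags(df, experiment = 1L)
  new_trial_table(df, experiment = 1L, geometry = geometry)
}

#' Simulate the two-item probe-comparison task
#'
#' Each trial presents two memory dots (one later retro-cued as target) and
#' two response probes, all sampled uniformly over the disk (coincident
#' probes are resampled).  A latent decision value is formed from the planted
#' coefficients applied to the signed distance differences of the six
#' candidate locations (current target/non-target, previous target/
#' non-target, previous chosen/unchosen probes) plus Gaussian noise; the
#' binary choice is its sign.  Reaction times follow a shifted lognormal
#' whose log-mean decreases with the absolute latent evidence, so harder
#' trials (probes nearly equidistant from the target) are slower.
#'
#' The latent model is driven by raw distance differences; the Monte-Carlo
#' demeaning of probe-geometry bias is an analysis-side transform applied by
#' [compare_choice_models()], mirroring how a real observer responds to the
#' actual probe distances.
#'
#' @param n_subjects number of simulated subjects.
#' @param n_trials trials per subject (split over `n_blocks` blocks).
#' @param truth a [ground_truth()]; uses `exp2_*` and `rt_*` fields.
#' @param geometry a [disk_geometry()].
#' @param n_blocks blocks per subject; default 5.
#' @param seed integer seed.
#' @return A `trial_table` with stimulus/probe coordinates, `choice`
#'   (1/2), `rt` (s), `accuracy` (0/1), lagged `previous_*` location pairs
#'   and `valid_serial`.
#' @export
simulate_behavior_exp2 <- function(n_subjects = 1, n_trials = 500,
                                   truth = ground_truth(),
                                   geometry = disk_geometry(),
                                   n_blocks = 5, seed = NULL) {
  stopifnot(inherits(truth, "ground_truth"), n_trials >= 2, n_blocks >= 1,
            n_trials %% n_blocks == 0)
  cf <- truth$exp2_coefs
  out <- vector("list", n_subjects)
  for (s in seq_len(n_subjects)) {
    sub_seed <- if (is.null(seed)) NULL else derive_seed(seed, s - 1L)
    out[[s]] <- with_seed(sub_seed, {
      n <- n_trials
      tgt <- sample_disk_locations(n, geometry)
      ntg <- sample_disk_locations(n, geometry)
      p1 <- sample_disk_locations(n, geometry)
      p2 <- sample_disk_locations(n, geometry)
      # resample coincident probe pairs (degenerate comparison)
      bad <- which(rowSums((p1 - p2)^2) < 1e-10)
      while (length(bad)) {
        p2[bad, ] <- sample_disk_locations(length(bad), geometry)
        bad <- bad[rowSums((p1[bad, , drop = FALSE] -
                            p2[bad, , drop = FALSE])^2) < 1e-10]
      }
      block <- rep(seq_len(n_blocks), each = n / n_blocks)
      eps <- rnorm(n, sd = truth$exp2_noise_sd)
      choice <- integer(n); rt <- numeric(n); acc <- integer(n)
      prev_chosen <- prev_unchosen <- c(NA_real_, NA_real_)
      dl_t <- delta_l(tgt, p1, p2)
      dl_n <- delta_l(ntg, p1, p2)
      for (i in seq_len(n)) {
        latent <- truth$exp2_intercept +
          cf["current_target"] * dl_t[i] +
          cf["current_nontarget"] * dl_n[i] + eps[i]
        if (i > 1 && block[i] == block[i - 1]) {
          latent <- latent +
            cf["previous_target"] * delta_l(tgt[i - 1, ], p1[i, ], p2[i, ]) +
            cf["previous_nontarget"] * delta_l(ntg[i - 1, ], p1[i, ], p2[i, ]) +
            cf["previous_chosen"] * delta_l(prev_chosen, p1[i, ], p2[i, ]) +
            cf["previous_unchosen"] * delta_l(prev_unchosen, p1[i, ], p2[i, ])
        }
        choice[i] <- if (latent < 0) 1L else 2L
        rt[i] <- truth$rt_shift +
          rlnorm(1, meanlog = log(truth$rt_mu) -
                   truth$rt_sensitivity * abs(latent),
                 sdlog = truth$rt_sdlog)
        acc[i] <- as.integer((dl_t[i] < 0) == (choice[i] == 1L))
        prev_chosen <- if (choice[i] == 1L) p1[i, ] else p2[i, ]
        prev_unchosen <- if (choice[i] == 1L) p2[i, ] else p1[i, ]
      }
      data.frame(subject = s, block = block,
                 trial = sequence(rep(n / n_blocks, n_blocks)),
                 current_target_x = tgt[, 1], current_target_y = tgt[, 2],
                 current_nontarget_x = ntg[, 1], current_nontarget_y = ntg[, 2],
                 probe1_x = p1[, 1], probe1_y = p1[, 2],
                 probe2_x = p2[, 1], probe2_y = p2[, 2],
                 choice = choice, rt = rt, accuracy = acc)
    })
  }
  df <- do.call(rbind, out)
  df <- add_serial_lags(df, experiment = 2L)
  new_trial_table(df, experiment = 2L, geometry = geometry)
}
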