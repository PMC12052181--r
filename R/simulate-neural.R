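#' Simulate epoched multichannel data with planted location axes
#'
#' Builds a trials x channels x time array in which the present-trial and
#' past-trial 2-D locations are encoded on unit-norm channel weight vectors
#' ("representational axes") inside stage-specific time-gain windows, with
#' additive Gaussian channel noise.  The past-location axes are rotated by
#' `truth$axis_angle` relative to the present-location axes within channel
#' space (0 deg: aligned, 90 deg: orthogonal, 180 deg: flipped), so the
#' past-present interaction estimated downstream has a known ground truth of
#' `cos(axis_angle)`.
#'
#' Construction: four orthonormal channel directions `e1..e4` are drawn from
#' the seed; the present X/Y axes are `e1`, `e2` and the past X/Y axes are
#' `cos(a) e1 + sin(a) e3` and `cos(a) e2 + sin(a) e4`.  This requires
#' `n_channels >= 4`.
#'
#' @param trials a `trial_table` providing the location columns.
#' @param truth a [ground_truth()]; uses `axis_angle`, `gain_present`,
#'   `gain_past`, `neural_noise_sd`, `neural_noise_ar`.
#' @param n_channels number of channels (>= 4).
#' @param sfreq sampling rate, Hz.
#' @param epoch_window length-2 vector, epoch start/end in ms.
#' @param present,past location names of the present- and past-trial
#'   predictors carried by the signal.  Rows with missing past locations
#'   (first trial of a block) carry no past signal.
#' @param trial_gain optional per-trial multiplier on the past-axis gain
#'   (length = trials); default 1 for every trial.
#' @param trial_axis_angle optional per-trial past-axis angle in degrees
#'   (length = trials), overriding `truth$axis_angle` trial by trial; the
#'   aligned component of trial i's past signal then carries gain
#'   `trial_gain[i] * cos(trial_axis_angle[i])`.  Used to plant per-trial
#'   modulation of the past-present interaction.
#' @param stage stage label stored in the array.
#' @param channel_positions optional channels x 3 sensor positions.
#' @param seed integer seed; fixed seed gives an identical array.
#' @return An [epoch_array()].
#' @export
simulate_neural <- function(trials, truth = ground_truth(), n_channels = 32,
                            sfreq = 100, epoch_window = c(-200, 600),
                            present = "current_stimulus",
                            past = "previous_report",
                            trial_gain = NULL, trial_axis_angle = NULL,
                            stage = "encoding",
                            channel_positions = NULL, seed = NULL) {
  stopifnot(inherits(truth, "ground_truth"), sfreq > 0,
            length(epoch_window) == 2L, epoch_window[1] < epoch_window[2])
  if (n_channels < 4)
    stop("n_channels must be >= 4 to realize an arbitrary past-present angle")
  n <- nrow(trials)
  pres <- loc_matrix(trials, present)
  pastm <- loc_matrix(trials, past)
  if (is.null(trial_gain)) trial_gain <- rep(1, n)
  stopifnot(length(trial_gain) == n)
  dt <- 1000 / sfreq
  times <- seq(epoch_window[1], epoch_window[2], by = dt)
  nt <- length(times)
  a <- if (is.null(trial_axis_angle)) rep(truth$axis_angle, n)
       else { stopifnot(length(trial_axis_angle) == n); trial_axis_angle }
  a <- a * pi / 180
  arr <- with_seed(seed, {
    e <- qr.Q(qr(matrix(rnorm(n_channels * 4L), n_channels, 4L)))
    w_pres_x <- e[, 1]; w_pres_y <- e[, 2]
    w_past_x <- cos(a[1]) * e[, 1] + sin(a[1]) * e[, 3]
    w_past_y <- cos(a[1]) * e[, 2] + sin(a[1]) * e[, 4]
    gp <- truth$gain_present$amp *
      as.numeric(times >= truth$gain_present$window[1] &
                 times <= truth$gain_present$window[2])
    gq <- truth$gain_past$amp *
      as.numeric(times >= truth$gain_past$window[1] &
                 times <= truth$gain_past$window[2])
    A_pres <- pres[, 1, drop = FALSE] %*% t(w_pres_x) +
      pres[, 2, drop = FALSE] %*% t(w_pres_y)
    past_x <- ifelse(is.na(pastm[, 1]), 0, pastm[, 1]) * trial_gain
    past_y <- ifelse(is.na(pastm[, 2]), 0, pastm[, 2]) * trial_gain
    # per-trial past axes: cos(a_i) along the present axes, sin(a_i) along
    # the orthogonal complement directions e3/e4
    A_past <- (past_x * cos(a)) %*% t(e[, 1]) + (past_x * sin(a)) %*% t(e[, 3]) +
      (past_y * cos(a)) %*% t(e[, 2]) + (past_y * sin(a)) %*% t(e[, 4])
    arr <- array(rnorm(n * n_channels * nt, sd = truth$neural_noise_sd),
                 dim = c(n, n_channels, nt))
    if (truth$neural_noise_ar > 0) {
      rho <- truth$neural_noise_ar
      for (t in 2:nt)
        arr[, , t] <- rho * arr[, , t - 1] + sqrt(1 - rho^2) * arr[, , t]
    }
    for (t in seq_len(nt)) {
      if (gp[t] != 0) arr[, , t] <- arr[, , t] + gp[t] * A_pres
      if (gq[t] != 0) arr[, , t] <- arr[, , t] + gq[t] * A_past
    }
    attr(arr, "axes") <- list(present_x = w_pres_x, present_y = w_pres_y,
                              past_x = w_past_x, past_y = w_past_y,
                              gain_present = gp, gain_past = gq)
    arr
  })
  axes <- attr(arr, "axes"); attr(arr, "axes") <- NULL
  ep <- epoch_array(arr, times, sfreq, stage = stage,
                    channel_positions = channel_positions)
  ep$planted_axes <- axes
  ep
}
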