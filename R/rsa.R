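# Trial-wise representational similarity decoding of continuous 2-D
# locations: per time point, the condensed neural dissimilarity vector
# (cosine distance between spatiotemporal channel patterns) is regressed on
# the condensed location dissimilarity vector; the slope is the
# representation strength.

# Unordered trial pairs in fixed lexicographic order (i < j), matching the
# layout of both location and neural condensed RDMs.
condensed_pairs <- function(n) {
  stopifnot(n >= 2)
  i <- rep(seq_len(n - 1L), times = (n - 1L):1L)
  j <- unlist(lapply(seq_len(n - 1L), function(k) (k + 1L):n))
  cbind(i = i, j = j)
}

condensed_index <- function(i, j, n) {
  stopifnot(all(i < j), all(j <= n))
  unname((i - 1L) * n - i * (i - 1L) / 2 + (j - i))
}

#' Condensed location dissimilarity vector
#'
#' Absolute pairwise differences of a per-trial 1-D coordinate, one value per
#' unordered trial pair in fixed lexicographic order (pair (i, j), i < j).
#'
#' @param values_1d numeric vector, one coordinate per trial.
#' @return Numeric vector of length `n (n - 1) / 2` of class `condensed_rdm`
#'   with attribute `n_trials`.
#' @examples
#' location_rdm(c(0, 3, 7))  # pairs (1,2) (1,3) (2,3): 3 7 4
#' @export
location_rdm <- function(values_1d) {
  n <- length(values_1d)
  if (n < 2) stop("need at least 2 trials")
  bad <- which(!is.finite(values_1d))
  if (length(bad))
    stop("non-finite coordinate at trial ", bad[1])
  v <- as.vector(stats::dist(values_1d))
  structure(v, n_trials = n, class = "condensed_rdm")
}

# Sample indices of the spatiotemporal window centred at t_center.
window_idx <- function(times, t_center, window_ms) {
  k <- which(abs(times - t_center) < 1e-6)
  if (length(k) != 1L) stop("t_center (", t_center, " ms) not on the time grid")
  half <- window_ms / 2
  idx <- which(times >= t_center - half - 1e-9 &
               times <= t_center + half + 1e-9)
  if (!length(idx)) stop("empty pattern window")
  idx
}

#' Spatiotemporal pattern vector for one trial
#'
#' Flattens the channels x samples block of one trial inside a window
#' centred at `t_center` (default 50 ms wide).  Edge windows are truncated,
#' never zero-padded.
#'
#' @param epochs an [epoch_array()].
#' @param trial trial index.
#' @param t_center window centre (ms, on the epoch time grid).
#' @param window_ms window width in ms.
#' @return Numeric vector of length channels x samples-in-window.
#' @export
pattern_vector <- function(epochs, trial, t_center, window_ms = 50) {
  stopifnot(inherits(epochs, "epoch_array"))
  idx <- window_idx(epochs$times, t_center, window_ms)
  as.vector(epochs$data[trial, , idx])
}

# All trials' pattern vectors as an n x (channels * samples) matrix.
pattern_matrix <- function(epochs, t_center, window_ms = 50) {
  idx <- window_idx(epochs$times, t_center, window_ms)
  d <- epochs$data[, , idx, drop = FALSE]
  dim(d) <- c(dim(d)[1], dim(d)[2] * dim(d)[3])
  d
}

#' Condensed neural dissimilarity vector (cosine distance)
#'
#' One minus the cosine similarity between the spatiotemporal pattern
#' vectors of every trial pair, in the same fixed pair order as
#' [location_rdm()].  Values lie in `[0, 2]`.
#'
#' @inheritParams pattern_vector
#' @return A `condensed_rdm` vector.
#' @export
neural_rdm <- function(epochs, t_center, window_ms = 50) {
  X <- pattern_matrix(epochs, t_center, window_ms)
  nrm <- sqrt(rowSums(X^2))
  bad <- which(nrm == 0)
  if (length(bad))
    stop("zero-norm pattern at trial ", bad[1])
  Xn <- X / nrm
  S <- tcrossprod(Xn)
  # lower.tri in column-major order == lexicographic (i < j) pair order
  v <- 1 - S[lower.tri(S)]
  structure(v, n_trials = nrow(X), class = "condensed_rdm")
}

#' Reduce channels to principal components
#'
#' Fits PCA on the concatenated (trials x time) x channels matrix of the
#' stage (channels as features, mean-centred per channel) and keeps the
#' smallest number of leading components whose cumulative explained variance
#' reaches `var_target`.  Intended per subject, per stage.
#'
#' @param epochs an [epoch_array()].
#' @param var_target cumulative explained-variance target in (0, 1];
#'   default 0.99.
#' @return An [epoch_array()] in component space, with attributes
#'   `n_components` and `explained_variance` on the returned object.
#' @export
pca_reduce <- function(epochs, var_target = 0.99) {
  stopifnot(inherits(epochs, "epoch_array"))
  if (!(is.numeric(var_target) && var_target > 0 && var_target <= 1))
    stop("`var_target` must lie in (0, 1]")
  d <- dim(epochs$data)
  if (d[2] < 2) stop("need at least 2 channels")
  # trials*time rows, channels columns
  X <- matrix(aperm(epochs$data, c(1, 3, 2)), d[1] * d[3], d[2])
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  cum <- cumsum(ev) / sum(ev)
  k <- which(cum >= var_target - 1e-12)[1]
  scores <- sweep(X, 2, pc$center) %*% pc$rotation[, seq_len(k), drop = FALSE]
  arr <- aperm(array(scores, dim = c(d[1], d[3], k)), c(1, 3, 2))
  out <- epoch_array(arr, epochs$times, epochs$sfreq, epochs$stage)
  out$n_components <- k
  out$explained_variance <- cum[k]
  out
}

#' Representation strength: slope of neural on location dissimilarity
#'
#' Ordinary least-squares slope (with intercept) of the condensed neural RDM
#' on the condensed location RDM.
#'
#' @param neural,location `condensed_rdm` vectors of equal length.
#' @return The slope (numeric scalar).
#' @export
decode_strength <- function(neural, location) {
  if (length(neural) != length(location))
    stop("condensed RDMs have different lengths")
  vl <- stats::var(location)
  if (vl == 0) stop("zero-variance location RDM")
  stats::cov(as.numeric(neural), as.numeric(location)) / vl
}

#' Time-resolved RSA decoding of a 2-D location
#'
#' For each time point, computes the neural cosine RDM from the 50 ms
#' spatiotemporal pattern window and regresses it on the location RDM of
#' each coordinate axis; the two slopes are averaged into the representation
#' strength.  Trials with missing predictor values (e.g., the first trial of
#' each block for lagged predictors) are dropped together with their epochs.
#'
#' @param epochs an [epoch_array()] aligned to `trials` (same trial count
#'   and order).
#' @param trials a `trial_table`.
#' @param predictor location name to decode (must have `_x` / `_y` columns).
#' @param window_ms pattern window width, ms.
#' @param residualize optional character vector of current-trial location
#'   names to regress out of the signal first (see
#'   [residualize_current()]).
#' @return An object of class `decoding_timecourse`: a data.frame with
#'   columns `time_ms`, `beta`, `beta_x`, `beta_y` and attributes
#'   `predictor` and `window_ms`.
#' @export
decode_timecourse <- function(epochs, trials, predictor, window_ms = 50,
                              residualize = NULL) {
  stopifnot(inherits(epochs, "epoch_array"))
  if (nrow(trials) != dim(epochs$data)[1])
    stop("trial table and epochs disagree on trial count")
  if (!is.null(residualize))
    epochs <- residualize_current(epochs, trials, residualize)
  locs <- loc_matrix(trials, predictor)
  keep <- stats::complete.cases(locs)
  if (sum(keep) < 3) stop("fewer than 3 trials with predictor values")
  locs <- locs[keep, , drop = FALSE]
  ep <- epochs_subset(epochs, keep)
  rdm_x <- location_rdm(locs[, 1])
  rdm_y <- location_rdm(locs[, 2])
  times <- ep$times
  bx <- by_ <- numeric(length(times))
  for (ti in seq_along(times)) {
    nr <- neural_rdm(ep, times[ti], window_ms)
    bx[ti] <- decode_strength(nr, rdm_x)
    by_[ti] <- decode_strength(nr, rdm_y)
  }
  structure(data.frame(time_ms = times, beta = (bx + by_) / 2,
                       beta_x = bx, beta_y = by_),
            predictor = predictor, window_ms = window_ms,
            n_trials = sum(keep),
            class = c("decoding_timecourse", "data.frame"))
}

#' @export
plot.decoding_timecourse <- function(x, ...) {
  graphics::plot(x$time_ms, x$beta, type = "l",
                 xlab = "time (ms)", ylab = "representation strength (beta)",
                 main = paste("RSA decoding:", attr(x, "predictor")), ...)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}

#' Regress current-trial locations out of the signal
#'
#' Per channel (or component) and per time point, fits an OLS of the signal
#' on the X and Y coordinates of every listed current-trial location (with
#' intercept) and returns the residual signal.  Used before decoding past-
#' trial information so that the dominant current-trial response does not
#' leak into lagged decoding.
#'
#' @param epochs an [epoch_array()].
#' @param trials aligned `trial_table`.
#' @param current_predictors character vector of location names to remove.
#' @return An [epoch_array()] of residuals.
#' @export
residualize_current <- function(epochs, trials, current_predictors) {
  stopifnot(inherits(epochs, "epoch_array"), length(current_predictors) >= 1)
  n <- dim(epochs$data)[1]
  D <- cbind(1, do.call(cbind, lapply(current_predictors,
                                      function(p) loc_matrix(trials, p))))
  colnames(D) <- c("(Intercept)",
                   unlist(lapply(current_predictors, loc_cols)))
  if (anyNA(D)) stop("missing values in current predictors")
  qrD <- qr(D)
  if (qrD$rank < ncol(D)) {
    bad <- colnames(D)[qrD$pivot[(qrD$rank + 1):ncol(D)]]
    stop("singular design; collinear predictors: ",
         paste(bad, collapse = ", "))
  }
  out <- epochs$data
  for (ti in seq_len(dim(out)[3])) {
    Y <- out[, , ti]
    if (is.null(dim(Y))) Y <- matrix(Y, nrow = n)
    out[, , ti] <- Y - D %*% qr.coef(qrD, Y)
  }
  res <- epochs
  res$data <- out
  res
}
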