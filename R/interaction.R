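# Representational axes: per time point, each channel's signal is regressed
# on the predictor location coordinates; the vector of per-channel
# coefficients for one predictor is that predictor's representational axis.
# The past-present interaction is the cosine of the angle between the past
# and present axes, computed per coordinate axis and averaged.

#' Estimate representational axes by per-channel encoding regressions
#'
#' For each time point and coordinate axis (X/Y), fits a multivariate-output
#' OLS of all channels on the listed predictor coordinates (with intercept).
#' The per-channel coefficient vector of each predictor is its
#' representational axis at that time.
#'
#' @param epochs an [epoch_array()].
#' @param trials aligned `trial_table`.
#' @param predictors ordered character vector of location names entering the
#'   regression jointly.
#' @return An object of class `axis_set`: arrays `W_x`, `W_y` of dimension
#'   time x predictor x channel, plus `times` and `predictors`.  Trials with
#'   missing predictor values are dropped (their count is recorded).
#' @export
encoding_axes <- function(epochs, trials, predictors) {
  stopifnot(inherits(epochs, "epoch_array"), length(predictors) >= 1)
  n_all <- dim(epochs$data)[1]
  if (nrow(trials) != n_all)
    stop("trial table and epochs disagree on trial count")
  locs <- lapply(predictors, function(p) loc_matrix(trials, p))
  keep <- Reduce(`&`, lapply(locs, stats::complete.cases))
  n <- sum(keep)
  if (n < length(predictors) + 2)
    stop("need more trials than predictors + 1")
  ep <- epochs_subset(epochs, keep)
  d <- dim(ep$data)
  W <- list()
  for (ax in 1:2) {
    D <- cbind(1, do.call(cbind, lapply(locs, function(L) L[keep, ax])))
    colnames(D) <- c("(Intercept)", predictors)
    qrD <- qr(D)
    if (qrD$rank < ncol(D)) {
      bad <- colnames(D)[qrD$pivot[(qrD$rank + 1):ncol(D)]]
      stop("singular design; collinear predictors: ",
           paste(bad, collapse = ", "))
    }
    Wax <- array(NA_real_, dim = c(d[3], length(predictors), d[2]),
                 dimnames = list(NULL, predictors, NULL))
    for (ti in seq_len(d[3])) {
      B <- qr.coef(qrD, ep$data[, , ti])
      Wax[ti, , ] <- B[-1, , drop = FALSE]
    }
    W[[ax]] <- Wax
  }
  structure(list(W_x = W[[1]], W_y = W[[2]], times = ep$times,
                 predictors = predictors, n_trials = n,
                 n_dropped = n_all - n),
            class = "axis_set")
}

#' Cosine similarity between two representational axes
#'
#' `dot(a, b) / (|a| |b|)`: +1 for aligned axes, -1 for flipped, 0 for
#' orthogonal (non-interfering) axes.
#'
#' @param axis_a,axis_b numeric weight vectors of equal length, nonzero.
#' @return Cosine similarity in `[-1, 1]`.
#' @export
axis_alignment <- function(axis_a, axis_b) {
  stopifnot(length(axis_a) == length(axis_b))
  na <- sqrt(sum(axis_a^2)); nb <- sqrt(sum(axis_b^2))
  if (na == 0 || nb == 0) stop("zero axis vector: angle undefined")
  sum(axis_a * axis_b) / (na * nb)
}

# Centred boxcar smoothing over time, truncated at the edges.
smooth_boxcar <- function(x, times, smooth_ms) {
  if (is.null(smooth_ms) || smooth_ms <= 0) return(x)
  half <- smooth_ms / 2
  vapply(seq_along(times), function(i) {
    mean(x[times >= times[i] - half - 1e-9 & times <= times[i] + half + 1e-9])
  }, numeric(1))
}

#' Past-present interaction time course
#'
#' Fits the encoding regression of [encoding_axes()] and, at each time
#' point, computes the cosine similarity between the past predictor's axis
#' and the present predictor's axis, separately for the X and Y coordinate
#' fits; the two cosines are averaged and the resulting series is smoothed
#' with a centred 50 ms boxcar (edges truncated).  Positive values mean the
#' past reactivation is aligned with the present representation (attractive
#' interaction), negative values flipped (repulsive).
#'
#' @inheritParams encoding_axes
#' @param past,present predictor names (must be among `predictors`).
#' @param smooth_ms boxcar width in ms; 0 disables smoothing.
#' @return An object of class `interaction_timecourse`: data.frame with
#'   `time_ms`, `cosine` (smoothed), `cosine_raw`, `cosine_x`, `cosine_y`.
#' @export
interaction_timecourse <- function(epochs, trials, predictors, past,
                                   present, smooth_ms = 50) {
  stopifnot(past %in% predictors, present %in% predictors)
  axes <- encoding_axes(epochs, trials, predictors)
  nt <- length(axes$times)
  cx <- cy <- numeric(nt)
  for (ti in seq_len(nt)) {
    cx[ti] <- axis_alignment(axes$W_x[ti, past, ], axes$W_x[ti, present, ])
    cy[ti] <- axis_alignment(axes$W_y[ti, past, ], axes$W_y[ti, present, ])
  }
  raw <- (cx + cy) / 2
  sm <- smooth_boxcar(raw, axes$times, smooth_ms)
  structure(data.frame(time_ms = axes$times, cosine = sm,
                       cosine_raw = raw, cosine_x = cx, cosine_y = cy),
            past = past, present = present, smooth_ms = smooth_ms,
            class = c("interaction_timecourse", "data.frame"))
}

#' @export
plot.interaction_timecourse <- function(x, ...) {
  graphics::plot(x$time_ms, x$cosine, type = "l", ylim = c(-1, 1),
                 xlab = "time (ms)", ylab = "past-present interaction (cosine)",
                 main = paste(attr(x, "past"), "vs", attr(x, "present")), ...)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}

#' Leave-one-out trial-level past-present interaction
#'
#' For each trial i, the interaction time course is recomputed with trial i
#' left out, and the trial-level value is the full-sample interaction minus
#' the leave-one-out interaction: trials that pull the alignment up receive
#' positive values.  Each trial's series is boxcar-smoothed; averaging the
#' values inside externally supplied significant-cluster windows gives the
#' per-trial neural effect used in neuro-behavioral coupling.
#'
#' @inheritParams interaction_timecourse
#' @param method `"naive"` refits the regression from scratch for every
#'   left-out trial (the reference path); `"downdate"` uses a rank-one
#'   Sherman-Morrison update of the normal equations and matches the naive
#'   path to near machine precision.
#' @return An object of class `trial_interaction`: a trials x time matrix of
#'   smoothed leave-one-out values with attributes `times`, `trial_rows`
#'   (row indices of `trials` used) and `full` (the full-sample raw
#'   interaction series).
#' @export
trial_level_interaction <- function(epochs, trials, predictors, past,
                                    present, smooth_ms = 50,
                                    method = c("naive", "downdate")) {
  method <- match.arg(method)
  stopifnot(past %in% predictors, present %in% predictors)
  n_all <- dim(epochs$data)[1]
  locs <- lapply(predictors, function(p) loc_matrix(trials, p))
  keep <- Reduce(`&`, lapply(locs, stats::complete.cases))
  rows <- which(keep)
  n <- length(rows)
  if (n < length(predictors) + 2)
    stop("need at least predictors + 2 trials")
  ep <- epochs_subset(epochs, keep)
  d <- dim(ep$data)
  nt <- d[3]
  ip <- which(predictors == past) + 1L
  iq <- which(predictors == present) + 1L
  D <- list()
  for (ax in 1:2)
    D[[ax]] <- cbind(1, do.call(cbind, lapply(locs, function(L) L[keep, ax])))
  cosine_pair <- function(B) {
    a <- B[ip, ]; b <- B[iq, ]
    sum(a * b) / (sqrt(sum(a^2)) * sqrt(sum(b^2)))
  }
  full <- numeric(nt)
  vals <- matrix(0, n, nt)
  for (ax in 1:2) {
    Dax <- D[[ax]]
    G <- solve(crossprod(Dax))
    for (ti in seq_len(nt)) {
      Y <- ep$data[, , ti]
      if (is.null(dim(Y))) Y <- matrix(Y, nrow = n)
      DtY <- crossprod(Dax, Y)
      B <- G %*% DtY
      c_all <- cosine_pair(B)
      full[ti] <- full[ti] + c_all / 2
      for (i in seq_len(n)) {
        if (method == "naive") {
          Bi <- qr.coef(qr(Dax[-i, , drop = FALSE]), Y[-i, , drop = FALSE])
        } else {
          di <- Dax[i, ]
          Gd <- G %*% di
          Gi <- G + (Gd %*% t(Gd)) / (1 - sum(di * Gd))
          Bi <- Gi %*% (DtY - di %*% t(Y[i, ]))
        }
        vals[i, ti] <- vals[i, ti] + (c_all - cosine_pair(Bi)) / 2
      }
    }
  }
  for (i in seq_len(n))
    vals[i, ] <- smooth_boxcar(vals[i, ], ep$times, smooth_ms)
  structure(vals, times = ep$times, trial_rows = rows,
            full = full, past = past, present = present, method = method,
            class = "trial_interaction")
}

#' Average a trial-level interaction inside cluster windows
#'
#' @param trial_values a `trial_interaction` matrix.
#' @param windows list of length-2 numeric vectors `(start_ms, end_ms)`;
#'   typically the significant clusters of a [cluster_correction()] result.
#' @return Numeric vector, one averaged value per trial.
#' @export
average_in_windows <- function(trial_values, windows) {
  times <- attr(trial_values, "times")
  if (is.null(times)) stop("`trial_values` must be a trial_interaction")
  if (!length(windows)) stop("no cluster windows supplied")
  sel <- Reduce(`|`, lapply(windows, function(w)
    times >= w[1] - 1e-9 & times <= w[2] + 1e-9))
  if (!any(sel)) stop("cluster windows do not overlap the time grid")
  rowMeans(unclass(trial_values)[, sel, drop = FALSE])
}
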