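#' Signed distance difference between a reference and two probes
#'
#' The decision variable of the probe-comparison task: Euclidean distance
#' from the reference location to probe 1 minus the distance to probe 2.
#' Negative values mean the reference lies closer to probe 1.
#'
#' @param reference,probe1,probe2 2-D coordinates; either length-2 vectors or
#'   `n x 2` matrices (recycled row-wise as needed).
#' @return Numeric vector of signed distance differences (degrees).
#' @examples
#' delta_l(c(0, 0), c(0, 3), c(0, -3))  # 0: equidistant
#' delta_l(c(1, 1), c(1, 1), c(4, 1))   # -3: reference sits on probe 1
#' @export
delta_l <- function(reference, probe1, probe2) {
  as_mat <- function(p) {
    if (is.null(dim(p))) matrix(p, ncol = 2, byrow = TRUE) else as.matrix(p)
  }
  r <- as_mat(reference); p1 <- as_mat(probe1); p2 <- as_mat(probe2)
  n <- max(nrow(r), nrow(p1), nrow(p2))
  rec <- function(m) if (nrow(m) == n) m else m[rep(seq_len(nrow(m)), length.out = n), , drop = FALSE]
  r <- rec(r); p1 <- rec(p1); p2 <- rec(p2)
  if (!all(is.finite(r), is.finite(p1), is.finite(p2)))
    stop("delta_l: non-finite coordinates")
  d1 <- sqrt(rowSums((r - p1)^2))
  d2 <- sqrt(rowSums((r - p2)^2))
  d1 - d2
}

#' Monte-Carlo demeaning of the distance-difference variable
#'
#' Probe geometry alone biases the raw distance difference: for a random
#' location in the disk, the expected `delta_l` is generally nonzero (a probe
#' near the centre is on average closer).  The offset is estimated by Monte
#' Carlo -- averaging `delta_l` over uniformly sampled disk locations -- and
#' subtracted, yielding the demeaned decision variable.  The default uses
#' 10,000 draws.
#'
#' @param probe1,probe2 length-2 probe coordinates (must be distinct).
#' @param geometry a [disk_geometry()].
#' @param n_samples Monte-Carlo draws (>= 1); default 10000.
#' @param seed optional integer seed.
#' @return A list of class `delta_l_demean` with `offset` (the Monte-Carlo
#'   mean), `mc_se` (its standard error) and `transform(loc)`, a function
#'   returning the demeaned distance difference for new reference locations.
#' @export
demean_delta_l <- function(probe1, probe2, geometry = disk_geometry(),
                           n_samples = 10000, seed = NULL) {
  if (!is.numeric(n_samples) || n_samples < 1)
    stop("`n_samples` must be >= 1")
  if (isTRUE(all(abs(as.numeric(probe1) - as.numeric(probe2)) < 1e-12)))
    stop("probes must be distinct")
  pts <- sample_disk_locations(n_samples, geometry, seed = seed)
  dl <- delta_l(pts, probe1, probe2)
  offset <- mean(dl)
  structure(list(offset = offset,
                 mc_se = stats::sd(dl) / sqrt(n_samples),
                 n_samples = n_samples,
                 transform = function(loc) delta_l(loc, probe1, probe2) - offset),
            class = "delta_l_demean")
}

# Vectorised probe-geometry offsets for many probe pairs at once, sharing the
# Monte-Carlo point sample within chunks for speed.  Equivalent in
# expectation to per-pair demean_delta_l().
demean_offsets <- function(probe1, probe2, geometry = disk_geometry(),
                           n_samples = 10000, seed = NULL, chunk = 256L) {
  p1 <- as.matrix(probe1); p2 <- as.matrix(probe2)
  n <- nrow(p1)
  out <- numeric(n)
  with_seed(seed, {
    for (start in seq(1L, n, by = chunk)) {
      idx <- start:min(start + chunk - 1L, n)
      pts <- sample_disk_locations(n_samples, geometry)
      # distances: n_samples x |idx|
      d1 <- sqrt(outer(pts[, 1], p1[idx, 1], "-")^2 +
                 outer(pts[, 2], p1[idx, 2], "-")^2)
      d2 <- sqrt(outer(pts[, 1], p2[idx, 1], "-")^2 +
                 outer(pts[, 2], p2[idx, 2], "-")^2)
      out[idx] <- colMeans(d1 - d2)
    }
  })
  out
}

#' Weighted choice: binary report graded by reaction time
#'
#' Converts a binary probe choice into a continuous decision variable in
#' `[-1, 1]`: the choice is coded -1 (probe 1) or +1 (probe 2) and multiplied
#' by `1 - RT_rescaled`, where the reaction time is min-max rescaled to
#' `[0, 1]`.  Fast confident choices map near the bounds, slow choices toward
#' zero.
#'
#' @param choice integer vector in `{1, 2}`.
#' @param rt reaction times, seconds.
#' @param rt_min,rt_max rescaling bounds; default the range of `rt` (the
#'   per-subject convention).  Out-of-range values are clipped when bounds
#'   are supplied externally.
#' @return Numeric vector in `[-1, 1]`.
#' @examples
#' weighted_choice(c(1, 2), c(0.4, 1.2), rt_min = 0.4, rt_max = 1.2)
#' @export
weighted_choice <- function(choice, rt, rt_min = min(rt), rt_max = max(rt)) {
  stopifnot(all(choice %in% c(1L, 2L)), all(rt > 0))
  if (rt_max <= rt_min)
    stop("degenerate RT scale: rt_min must be < rt_max")
  rts <- pmin(pmax(rt, rt_min), rt_max)
  rt_rescaled <- (rts - rt_min) / (rt_max - rt_min)
  code <- ifelse(choice == 1L, -1, 1)
  code * (1 - rt_rescaled)
}

#' Fit the trial-wise serial-bias regression
#'
#' Ordinary least squares of the current report on the current stimulus, the
#' response start position and the previous trial's report, fitted per
#' subject and separately for the X and Y coordinates; the two per-axis
#' coefficients are averaged to give each predictor's coefficient.  A
#' positive previous-report coefficient is an attractive serial bias.  Group
#' inference is a two-sided one-sample t-test across subjects with Cohen's d.
#'
#' @param trials a `trial_table` (or data.frame) with `<name>_x` / `<name>_y`
#'   columns for the response and every predictor, plus `subject` and
#'   `valid_serial`.
#' @param predictors character vector of predictor location names.
#' @param response location name of the response; default `"current_report"`.
#' @param intercept include an intercept (default TRUE; absorbs any constant
#'   response bias).
#' @return An object of class `serial_fit` with per-subject averaged
#'   coefficients (`coefficients`, subjects x predictors), per-axis
#'   coefficients, per-subject standard errors and a `group` table of
#'   one-sample t-tests.
#' @examples
#' tr <- simulate_behavior_exp1(n_subjects = 2, n_trials_per_block = 50,
#'                              n_blocks = 2, seed = 1)
#' fit <- fit_serial_regression(tr)
#' coef(fit)
#' @export
fit_serial_regression <- function(trials,
                                  predictors = c("current_stimulus",
                                                 "current_start",
                                                 "previous_report"),
                                  response = "current_report",
                                  intercept = TRUE) {
  df <- as.data.frame(trials)
  keep <- df$valid_serial &
    stats::complete.cases(df[, unlist(lapply(c(predictors, response), loc_cols))])
  df <- df[keep, , drop = FALSE]
  subjects <- sort(unique(df$subject))
  p <- length(predictors)
  bx <- by_ <- se_x <- se_y <- matrix(NA_real_, length(subjects), p,
                                      dimnames = list(subjects, predictors))
  for (si in seq_along(subjects)) {
    d <- df[df$subject == subjects[si], , drop = FALSE]
    if (nrow(d) < p + 1 + as.integer(intercept))
      stop("subject ", subjects[si], ": fewer valid serial trials (", nrow(d),
           ") than parameters")
    for (ax in c("x", "y")) {
      X <- sapply(predictors, function(nm) d[[paste0(nm, "_", ax)]])
      X <- cbind(X)
      if (intercept) X <- cbind(`(Intercept)` = 1, X)
      qrX <- qr(X)
      if (qrX$rank < ncol(X)) {
        bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
        stop("singular design for subject ", subjects[si],
             "; collinear predictors: ", paste(bad, collapse = ", "))
      }
      y <- d[[paste0(response, "_", ax)]]
      fit <- lm.fit(X, y)
      cf <- fit$coefficients[predictors]
      dfree <- nrow(X) - ncol(X)
      rss <- sum(fit$residuals^2)
      XtXinv <- chol2inv(qr.R(qrX))
      se <- sqrt(diag(XtXinv) * rss / max(dfree, 1))
      names(se) <- colnames(X)
      if (ax == "x") { bx[si, ] <- cf; se_x[si, ] <- se[predictors] }
      else { by_[si, ] <- cf; se_y[si, ] <- se[predictors] }
    }
  }
  bavg <- (bx + by_) / 2
  group <- do.call(rbind, lapply(seq_len(p), function(j) {
    gt <- if (nrow(bavg) >= 2) unclass(group_test(bavg[, j]))
    else list(mean = bavg[1, j], t = NA_real_, df = 0, p = NA_real_,
              cohens_d = NA_real_, n = 1L)
    cbind(predictor = predictors[j], as.data.frame(gt))
  }))
  group <- group[, c("predictor", "mean", "t", "df", "p", "cohens_d")]
  rownames(group) <- NULL
  structure(list(coefficients = bavg, coefficients_x = bx,
                 coefficients_y = by_, se_x = se_x, se_y = se_y,
                 group = group, predictors = predictors,
                 response = response, intercept = intercept,
                 n_trials_used = nrow(df)),
            class = "serial_fit")
}

#' @export
coef.serial_fit <- function(object, ...) {
  stats::setNames(object$group$mean, object$group$predictor)
}

#' @export
print.serial_fit <- function(x, digits = 4, ...) {
  cat(sprintf("<serial_fit> %d subjects, %d trials; response: %s\n",
              nrow(x$coefficients), x$n_trials_used, x$response))
  print(format(x$group, digits = digits), row.names = FALSE)
  invisible(x)
}

#' @export
summary.serial_fit <- function(object, ...) {
  object$group
}
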