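# Neuro-behavioral coupling: across-subject Pearson correlation of a
# behavioral bias coefficient with the cluster-averaged neural interaction,
# and the within-subject trial-level regression of reciprocal reaction time
# on the leave-one-out neural effect.

#' One-sample group test across subjects
#'
#' Two-sided one-sample t-test of per-subject values against zero, with
#' Cohen's d (mean / SD).  Degenerate inputs are guarded: all values zero
#' gives `t = 0, p = 1`; identical nonzero values give an infinite t and
#' `p = 0`.
#'
#' @param values numeric vector, one value per subject (>= 2).
#' @return A list of class `group_test` with `mean`, `t`, `df`, `p`,
#'   `cohens_d`, `n`.
#' @export
group_test <- function(values) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 2) stop("need at least 2 subjects")
  m <- mean(values); s <- stats::sd(values)
  df <- n - 1
  if (s == 0) {
    if (m == 0) {
      t <- 0; p <- 1; d <- 0
    } else {
      t <- sign(m) * Inf; p <- 0; d <- sign(m) * Inf
    }
  } else {
    t <- m / (s / sqrt(n))
    p <- 2 * stats::pt(-abs(t), df)
    d <- m / s
  }
  structure(list(mean = m, t = t, df = df, p = p, cohens_d = d, n = n),
            class = "group_test")
}

#' @export
print.group_test <- function(x, digits = 4, ...) {
  cat(sprintf("one-sample t-test: mean = %.*g, t(%d) = %.*g, p = %.*g, d = %.*g\n",
              digits, x$mean, x$df, digits, x$t, digits, x$p, digits,
              x$cohens_d))
  invisible(x)
}

#' Across-subject neuro-behavioral correlation
#'
#' Pearson correlation between a per-subject behavioral effect (e.g., the
#' previous-report regression coefficient) and a per-subject neural effect
#' (the past-present interaction averaged within externally supplied
#' significant clusters).
#'
#' @param behav_effect,neural_effect numeric vectors, one value per subject
#'   (>= 3 subjects).
#' @return An object of class `neurobehav_result` with `mode
#'   = "across_subject"`, `r`, `p`, `df`, `n`.
#' @export
across_subject_correlation <- function(behav_effect, neural_effect) {
  stopifnot(length(behav_effect) == length(neural_effect))
  ok <- is.finite(behav_effect) & is.finite(neural_effect)
  b <- behav_effect[ok]; ne <- neural_effect[ok]
  if (length(b) < 3) stop("need at least 3 subjects")
  if (stats::sd(b) == 0 || stats::sd(ne) == 0)
    stop("zero variance in behavioral or neural effect")
  ct <- stats::cor.test(b, ne, method = "pearson")
  structure(list(mode = "across_subject", r = unname(ct$estimate),
                 p = ct$p.value, df = unname(ct$parameter), n = length(b)),
            class = "neurobehav_result")
}

#' Within-subject trial-level neuro-behavioral regression
#'
#' Per subject, fits an OLS (with intercept) of the reciprocal reaction time
#' `1 / rt` on the per-trial neural effect (the trial-level leave-one-out
#' interaction averaged over supplied cluster windows); the per-subject
#' slopes are tested against zero at the group level.  A positive group
#' slope means stronger past-present interaction predicts faster responses.
#'
#' @param trial_neural list (one element per subject) of per-trial neural
#'   scalars, or a single numeric vector for one subject.
#' @param rt matching list/vector of reaction times in seconds (> 0).
#' @param min_trials subjects with fewer valid trials are excluded with a
#'   warning (default 10).
#' @return An object of class `neurobehav_result` with `mode =
#'   "within_subject"`, per-subject `beta1`, and the group t-test.
#' @export
within_subject_neurobehav <- function(trial_neural, rt, min_trials = 10) {
  if (!is.list(trial_neural)) trial_neural <- list(trial_neural)
  if (!is.list(rt)) rt <- list(rt)
  stopifnot(length(trial_neural) == length(rt))
  betas <- rep(NA_real_, length(trial_neural))
  for (s in seq_along(trial_neural)) {
    x <- trial_neural[[s]]; r <- rt[[s]]
    stopifnot(length(x) == length(r))
    ok <- is.finite(x) & is.finite(r) & r > 0
    if (sum(ok) < min_trials) {
      warning("subject ", s, " excluded: only ", sum(ok), " valid trials")
      next
    }
    fit <- stats::lm.fit(cbind(1, x[ok]), 1 / r[ok])
    betas[s] <- fit$coefficients[2]
  }
  used <- which(!is.na(betas))
  grp <- group_test(betas[used])
  structure(list(mode = "within_subject", beta1 = betas,
                 subjects_used = used, group = grp),
            class = "neurobehav_result")
}

#' @export
print.neurobehav_result <- function(x, digits = 4, ...) {
  if (x$mode == "across_subject") {
    cat(sprintf("<neurobehav_result> across-subject Pearson r(%d) = %.*g, p = %.*g\n",
                x$df, digits, x$r, digits, x$p))
  } else {
    cat(sprintf("<neurobehav_result> within-subject: %d subjects, group beta1 = %.*g\n",
                length(x$subjects_used), digits, x$group$mean))
    print(x$group)
  }
  invisible(x)
}
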