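#' Ground-truth parameters for the synthetic generators
#'
#' Bundles every planted quantity the synthetic behavioral and neural
#' generators use, so that recovery tests can compare estimates against a
#' single authoritative object.
#'
#' The default behavioral coefficients are of the magnitude observed in real
#' spatial-reproduction data (stimulus coefficient near 1, start-position and
#' previous-report coefficients two orders of magnitude smaller); the report
#' noise, the choice noise and the reaction-time model are generator choices
#' documented in the methods vignette, not empirical values.
#'
#' @param exp1_coefs named numeric: planted coefficients of the reproduction
#'   report on `current_stimulus`, `current_start` and `previous_report`
#'   (dimensionless, applied per coordinate).
#' @param exp1_noise_sd report noise SD in degrees, per coordinate.
#' @param exp2_coefs named numeric: planted weighted-choice coefficients for
#'   the six candidate locations (`current_target`, `current_nontarget`,
#'   `previous_target`, `previous_nontarget`, `previous_chosen`,
#'   `previous_unchosen`), applied to the demeaned distance differences.
#' @param exp2_intercept latent choice intercept.
#' @param exp2_noise_sd SD of the latent choice noise.
#' @param rt_shift,rt_mu,rt_sensitivity,rt_sdlog shifted-lognormal RT model:
#'   `rt = rt_shift + exp(N(log(rt_mu) - rt_sensitivity * |latent|, rt_sdlog))`
#'   so that stronger evidence gives faster responses.
#' @param axis_angle degrees in `[0, 180]` between the planted past-trial and
#'   present-trial representational axes in channel space.
#' @param gain_present,gain_past lists with `window` (ms, length 2) and `amp`:
#'   boxcar time-gain profile of the present- and past-location signals.
#' @param neural_noise_sd SD of the additive channel noise (signal units).
#' @param neural_noise_ar AR(1) coefficient of the channel noise over time;
#'   0 (the default) gives i.i.d. noise.
#' @return An object of class `ground_truth`.
#' @export
ground_truth <- function(exp1_coefs = c(current_stimulus = 0.92,
                                        current_start = 0.008,
                                        previous_report = 0.005),
                         exp1_noise_sd = 0.5,
                         exp2_coefs = c(current_target = 0.13,
                                        current_nontarget = -0.0052,
                                        previous_target = 0,
                                        previous_nontarget = 0,
                                        previous_chosen = 0.0039,
                                        previous_unchosen = -0.0038),
                         exp2_intercept = 0,
                         exp2_noise_sd = 0.15,
                         rt_shift = 0.3, rt_mu = 1.7,
                         rt_sensitivity = 0.4, rt_sdlog = 0.3,
                         axis_angle = 180,
                         gain_present = list(window = c(100, 400), amp = 1),
                         gain_past = list(window = c(150, 350), amp = 1),
                         neural_noise_sd = 0.5,
                         neural_noise_ar = 0) {
  need1 <- c("current_stimulus", "current_start", "previous_report")
  if (!all(need1 %in% names(exp1_coefs)))
    stop("`exp1_coefs` must name ", paste(need1, collapse = ", "))
  need2 <- c("current_target", "current_nontarget", "previous_target",
             "previous_nontarget", "previous_chosen", "previous_unchosen")
  if (!all(need2 %in% names(exp2_coefs)))
    stop("`exp2_coefs` must name all six candidate locations")
  stopifnot(all(is.finite(exp1_coefs)), all(is.finite(exp2_coefs)),
            exp1_noise_sd >= 0, exp2_noise_sd >= 0,
            axis_angle >= 0, axis_angle <= 180,
            neural_noise_sd >= 0,
            neural_noise_ar >= 0, neural_noise_ar < 1,
            rt_shift >= 0, rt_mu > 0, rt_sdlog >= 0)
  structure(list(exp1_coefs = exp1_coefs[need1],
                 exp1_noise_sd = exp1_noise_sd,
                 exp2_coefs = exp2_coefs[need2],
                 exp2_intercept = exp2_intercept,
                 exp2_noise_sd = exp2_noise_sd,
                 rt_shift = rt_shift, rt_mu = rt_mu,
                 rt_sensitivity = rt_sensitivity, rt_sdlog = rt_sdlog,
                 axis_angle = axis_angle,
                 gain_present = gain_present, gain_past = gain_past,
                 neural_noise_sd = neural_noise_sd,
                 neural_noise_ar = neural_noise_ar),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("<ground_truth>\n")
  cat("  exp1 coefs:",
      paste(sprintf("%s=%g", names(x$exp1_coefs), x$exp1_coefs),
            collapse = ", "),
      sprintf(" (noise sd %g deg)\n", x$exp1_noise_sd))
  cat("  exp2 coefs:",
      paste(sprintf("%s=%g", names(x$exp2_coefs), x$exp2_coefs),
            collapse = ", "), "\n")
  cat(sprintf("  axis angle: %g deg, neural noise sd %g\n",
              x$axis_angle, x$neural_noise_sd))
  invisible(x)
}
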