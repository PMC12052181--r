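# Candidate-factor model comparison for the probe-comparison task: linear
# mixed models of the RT-weighted choice on demeaned distance differences,
# compared by AIC against the base model (current target only).

#' The six candidate choice factors
#'
#' Location names whose demeaned distance differences may drive the weighted
#' choice: the two current stimuli, the two previous stimuli, and the two
#' previous choice options.
#' @export
CHOICE_FACTORS <- c("current_target", "current_nontarget",
                    "previous_target", "previous_nontarget",
                    "previous_chosen", "previous_unchosen")

# Attach weighted_choice and dld_<factor> columns to an exp-2 trial table.
prepare_choice_data <- function(trials, factors = CHOICE_FACTORS,
                                demean_n = 10000, seed = NULL,
                                rt_rescale = c("subject", "experiment")) {
  rt_rescale <- match.arg(rt_rescale)
  df <- as.data.frame(trials)
  if (rt_rescale == "subject") {
    wc <- numeric(nrow(df))
    for (s in unique(df$subject)) {
      i <- df$subject == s
      wc[i] <- weighted_choice(df$choice[i], df$rt[i])
    }
    df$weighted_choice <- wc
  } else {
    df$weighted_choice <- weighted_choice(df$choice, df$rt)
  }
  p1 <- loc_matrix(df, "probe1"); p2 <- loc_matrix(df, "probe2")
  offs <- demean_offsets(p1, p2, geometry = attr(trials, "geometry") %||%
                           disk_geometry(),
                         n_samples = demean_n, seed = seed)
  for (f in factors) {
    ref <- loc_matrix(df, f)
    dl <- rep(NA_real_, nrow(df))
    ok <- stats::complete.cases(ref)
    dl[ok] <- delta_l(ref[ok, , drop = FALSE],
                      p1[ok, , drop = FALSE], p2[ok, , drop = FALSE]) - offs[ok]
    df[[paste0("dld_", f)]] <- dl
  }
  df
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Compare candidate choice models by AIC
#'
#' Fits linear mixed models of the RT-weighted choice on the demeaned
#' distance differences of candidate location sets, with per-subject random
#' effects on every coefficient, and compares them by AIC against the base
#' model (current target only).  Candidates are either supplied explicitly
#' or built by forward stepwise selection: starting from the base model, the
#' factor giving the largest AIC drop is added until no factor lowers the
#' AIC (ties broken by factor list order).  Models are fitted by maximum
#' likelihood (not REML) so that AICs are comparable across fixed-effects
#' structures.
#'
#' @param trials an experiment-2 `trial_table`.
#' @param candidates optional list of character vectors of factor names
#'   (each a candidate fixed-effects set); `NULL` builds them stepwise.
#' @param factors pool of candidate factors for stepwise selection.
#' @param demean_n Monte-Carlo draws for probe-geometry demeaning.
#' @param seed integer seed for the demeaning draws.
#' @param rt_rescale RT rescaling scope for the weighted choice.
#' @param engine `"lmm"` (default): `lme4::lmer` with per-subject
#'   uncorrelated random slopes on every coefficient; `"ols"`: pooled
#'   fixed-effects fit, retained for likelihood-nesting diagnostics.
#' @return An object of class `choice_model_comparison` with the AIC `table`
#'   (one row per candidate, `delta_aic` relative to the base model), the
#'   `selected` factor set, per-subject coefficients of the selected model
#'   and the group t-test table.
#' @export
compare_choice_models <- function(trials, candidates = NULL,
                                  factors = CHOICE_FACTORS,
                                  demean_n = 10000, seed = NULL,
                                  rt_rescale = c("subject", "experiment"),
                                  engine = c("lmm", "ols")) {
  engine <- match.arg(engine)
  rt_rescale <- match.arg(rt_rescale)
  base <- "current_target"
  stopifnot(base %in% factors)
  df <- prepare_choice_data(trials, factors = factors, demean_n = demean_n,
                            seed = seed, rt_rescale = rt_rescale)
  df <- df[stats::complete.cases(df[, paste0("dld_", factors)]), , drop = FALSE]

  fit_one <- function(set) {
    terms <- paste0("dld_", set)
    if (engine == "ols") {
      fml <- stats::as.formula(paste("weighted_choice ~",
                                     paste(terms, collapse = " + ")))
      fit <- stats::lm(fml, data = df)
      return(list(fit = fit, aic = AIC(fit), logLik = as.numeric(logLik(fit)),
                  fallback = FALSE))
    }
    fml <- stats::as.formula(paste(
      "weighted_choice ~", paste(terms, collapse = " + "),
      "+ (1 +", paste(terms, collapse = " + "), "|| subject)"))
    ctrl <- lme4::lmerControl(calc.derivs = FALSE,
                              check.conv.singular = "ignore")
    fit <- tryCatch(
      suppressMessages(lme4::lmer(fml, data = df, REML = FALSE,
                                  control = ctrl)),
      error = function(e) NULL)
    if (is.null(fit)) {
      warning("mixed model with factors {", paste(set, collapse = ", "),
              "} did not converge; falling back to random intercepts only")
      fml2 <- stats::as.formula(paste(
        "weighted_choice ~", paste(terms, collapse = " + "),
        "+ (1 | subject)"))
      fit <- lme4::lmer(fml2, data = df, REML = FALSE, control = ctrl)
      return(list(fit = fit, aic = AIC(fit), logLik = as.numeric(logLik(fit)),
                  fallback = TRUE))
    }
    list(fit = fit, aic = AIC(fit), logLik = as.numeric(logLik(fit)),
         fallback = FALSE)
  }

  fitted <- list()
  key <- function(set) paste(sort(set), collapse = "+")
  get_fit <- function(set) {
    k <- key(set)
    if (is.null(fitted[[k]])) fitted[[k]] <<- c(fit_one(set), list(set = set))
    fitted[[k]]
  }

  if (is.null(candidates)) {
    current <- base
    repeat {
      cur <- get_fit(current)
      pool <- setdiff(factors, current)
      if (!length(pool)) break
      aics <- vapply(pool, function(f) get_fit(c(current, f))$aic, numeric(1))
      best <- which.min(aics)  # ties: first in factor order
      if (aics[best] < cur$aic) current <- c(current, pool[best]) else break
    }
  } else {
    if (!any(vapply(candidates, function(s) setequal(s, base), logical(1))))
      candidates <- c(list(base), candidates)
    for (set in candidates) get_fit(set)
  }

  tab <- do.call(rbind, lapply(fitted, function(fo)
    data.frame(factors = paste(fo$set, collapse = "+"),
               n_factors = length(fo$set),
               aic = fo$aic, logLik = fo$logLik,
               fallback = fo$fallback, stringsAsFactors = FALSE)))
  rownames(tab) <- NULL
  base_aic <- tab$aic[tab$factors == base]
  tab$delta_aic <- tab$aic - base_aic
  tab <- tab[order(tab$n_factors, tab$factors), , drop = FALSE]
  sel_row <- which.min(tab$aic)
  selected <- strsplit(tab$factors[sel_row], "+", fixed = TRUE)[[1]]

  sel_fit <- fitted[[key(selected)]]
  subj_coefs <- NULL; group <- NULL
  if (engine == "lmm") {
    cc <- stats::coef(sel_fit$fit)$subject
    keep <- paste0("dld_", selected)
    subj_coefs <- as.matrix(cc[, keep, drop = FALSE])
    colnames(subj_coefs) <- selected
    group <- do.call(rbind, lapply(selected, function(f)
      cbind(predictor = f,
            as.data.frame(unclass(group_test(subj_coefs[, f]))))))
    group <- group[, c("predictor", "mean", "t", "df", "p", "cohens_d")]
    rownames(group) <- NULL
  }
  structure(list(table = tab, selected = selected,
                 selected_aic = tab$aic[sel_row],
                 delta_aic_selected = tab$delta_aic[sel_row],
                 subject_coefficients = subj_coefs, group = group,
                 engine = engine, model = sel_fit$fit,
                 n_trials_used = nrow(df)),
            class = "choice_model_comparison")
}

#' @export
print.choice_model_comparison <- function(x, digits = 4, ...) {
  cat(sprintf("<choice_model_comparison> %d candidates (%s engine), %d trials\n",
              nrow(x$table), x$engine, x$n_trials_used))
  print(format(x$table[, c("factors", "aic", "delta_aic", "fallback")],
               digits = digits), row.names = FALSE)
  cat("selected:", paste(x$selected, collapse = " + "),
      sprintf("(delta AIC %.2f)\n", x$delta_aic_selected))
  if (!is.null(x$group)) print(format(x$group, digits = digits),
                               row.names = FALSE)
  invisible(x)
}
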