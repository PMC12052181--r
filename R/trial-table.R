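# Trial tables are plain data.frames (class "trial_table" first) with one row
# per trial, 2-D locations stored as <name>_x / <name>_y column pairs, and a
# `valid_serial` flag that is FALSE exactly on the first trial of each block
# (no previous trial exists within the recording block).

TRIALS_FORMAT_VERSION <- "serialdep-trials-v1"

loc_cols <- function(name) paste0(name, c("_x", "_y"))

# Extract an n x 2 matrix of a named location from a trial table.
loc_matrix <- function(trials, name) {
  cols <- loc_cols(name)
  missing <- setdiff(cols, names(trials))
  if (length(missing))
    stop("trial table lacks location columns: ", paste(missing, collapse = ", "))
  as.matrix(trials[, cols, drop = FALSE])
}

new_trial_table <- function(df, experiment, geometry) {
  structure(df,
            class = c("trial_table", "data.frame"),
            experiment = experiment,
            geometry = geometry)
}

#' @export
print.trial_table <- function(x, ...) {
  cat(sprintf("<trial_table> experiment %s: %d trials, %d subjects\n",
              attr(x, "experiment"), nrow(x), length(unique(x$subject))))
  print(utils::head(as.data.frame(x), 4))
  if (nrow(x) > 4) cat("...\n")
  invisible(x)
}

# Recompute lag-1 columns within subject x block.  `pairs` maps lagged column
# prefix -> current-trial source prefix (or function of the row for
# chosen/unchosen).  Returns the table with previous_* columns and
# valid_serial set.
add_serial_lags <- function(df, experiment) {
  ord <- order(df$subject, df$block, df$trial)
  stopifnot(identical(ord, seq_len(nrow(df))))
  grp <- interaction(df$subject, df$block, drop = TRUE)
  first <- !duplicated(grp)
  lag1 <- function(v) { out <- c(NA, v[-length(v)]); out[first] <- NA; out }
  if (experiment == 1L) {
    for (cl in loc_cols("current_report"))
      df[[sub("current_report", "previous_report", cl)]] <- lag1(df[[cl]])
  } else {
    # previous target / non-target, and previous probes partitioned by the
    # previous trial's choice
    for (ax in c("_x", "_y")) {
      df[[paste0("previous_target", ax)]] <- lag1(df[[paste0("current_target", ax)]])
      df[[paste0("previous_nontarget", ax)]] <- lag1(df[[paste0("current_nontarget", ax)]])
      chosen <- ifelse(df$choice == 1L, df[[paste0("probe1", ax)]],
                       df[[paste0("probe2", ax)]])
      unchosen <- ifelse(df$choice == 1L, df[[paste0("probe2", ax)]],
                         df[[paste0("probe1", ax)]])
      df[[paste0("previous_chosen", ax)]] <- lag1(chosen)
      df[[paste0("previous_unchosen", ax)]] <- lag1(unchosen)
    }
  }
  df$valid_serial <- !first
  df
}
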