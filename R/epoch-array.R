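#' Epoched neural data container
#'
#' A trials x channels x time array with its time axis (ms relative to the
#' stage event), sampling rate, stage label and optional channel metadata.
#'
#' @param data numeric array, trials x channels x time.
#' @param times numeric vector of time points (ms), strictly increasing with
#'   uniform spacing `1000 / sfreq`.
#' @param sfreq sampling rate in Hz.
#' @param stage stage label (e.g., "encoding", "delay", "decision").
#' @param channel_positions optional channels x 3 matrix of sensor positions.
#' @param channel_groups optional character vector, one label per channel.
#' @return An object of class `epoch_array`.
#' @export
epoch_array <- function(data, times, sfreq, stage = "encoding",
                        channel_positions = NULL, channel_groups = NULL) {
  stopifnot(is.array(data), length(dim(data)) == 3L,
            length(times) == dim(data)[3], sfreq > 0)
  if (length(times) > 1) {
    dt <- diff(times)
    if (any(dt <= 0)) stop("`times` must be strictly increasing")
    if (any(abs(dt - 1000 / sfreq) > 1e-6))
      stop("`times` spacing inconsistent with sfreq (expected ",
           1000 / sfreq, " ms)")
  }
  if (!is.null(channel_positions)) {
    channel_positions <- as.matrix(channel_positions)
    stopifnot(nrow(channel_positions) == dim(data)[2],
              ncol(channel_positions) == 3L)
  }
  if (!is.null(channel_groups))
    stopifnot(length(channel_groups) == dim(data)[2])
  structure(list(data = data, times = as.numeric(times), sfreq = sfreq,
                 stage = stage, channel_positions = channel_positions,
                 channel_groups = channel_groups),
            class = "epoch_array")
}

#' @export
print.epoch_array <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoch_array> stage '%s': %d trials x %d channels x %d times (%g-%g ms @ %g Hz)\n",
              x$stage, d[1], d[2], d[3], x$times[1], x$times[length(x$times)],
              x$sfreq))
  invisible(x)
}

#' @export
dim.epoch_array <- function(x) dim(x$data)

# Subset trials of an epoch array.
epochs_subset <- function(epochs, idx) {
  epoch_array(epochs$data[idx, , , drop = FALSE], epochs$times, epochs$sfreq,
              epochs$stage, epochs$channel_positions, epochs$channel_groups)
}

# Subset channels of an epoch array (view semantics: metadata subset along).
epochs_select_channels <- function(epochs, ch) {
  epoch_array(epochs$data[, ch, , drop = FALSE], epochs$times, epochs$sfreq,
              epochs$stage,
              if (!is.null(epochs$channel_positions))
                epochs$channel_positions[ch, , drop = FALSE],
              if (!is.null(epochs$channel_groups)) epochs$channel_groups[ch])
}
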