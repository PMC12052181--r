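# File formats.  Trial tables travel as CSV with a versioned comment header.
# Epoch arrays travel as a self-describing directory: meta.json (dimensions,
# time axis, sampling rate, channel metadata) plus data.bin, the raw array as
# little-endian float64 in R's native column-major order.  Both round-trip
# losslessly.

#' Write / read a trial table as versioned CSV
#'
#' The first line is a comment carrying the format version; lagged
#' (`previous_*`) columns are recomputed from the block structure on read
#' and cross-checked against stored values when present.
#'
#' @param trials a `trial_table`.
#' @param path file path.
#' @return `write_trials` returns `path` invisibly; `read_trials` returns a
#'   `trial_table`.
#' @export
write_trials <- function(trials, path) {
  stopifnot(inherits(trials, "trial_table"))
  geom <- attr(trials, "geometry") %||% disk_geometry()
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# %s experiment=%d diameter=%g",
                     TRIALS_FORMAT_VERSION, attr(trials, "experiment"),
                     geom$diameter), con)
  utils::write.csv(as.data.frame(trials), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  header <- readLines(path, n = 1L)
  if (!startsWith(header, paste0("# ", TRIALS_FORMAT_VERSION)))
    stop("not a ", TRIALS_FORMAT_VERSION, " file: ", path)
  fields <- strsplit(sub("^# \\S+ ", "", header), " ")[[1]]
  kv <- strsplit(fields, "=")
  meta <- stats::setNames(vapply(kv, `[`, character(1), 2),
                          vapply(kv, `[`, character(1), 1))
  experiment <- as.integer(meta[["experiment"]])
  geom <- disk_geometry(diameter = as.numeric(meta[["diameter"]]))
  df <- utils::read.csv(path, comment.char = "#")
  required <- c("subject", "block", "trial")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("schema mismatch: missing columns ", paste(missing, collapse = ", "))
  # validate presented locations against the disk
  presented <- intersect(c("current_stimulus", "current_start",
                           "current_target", "current_nontarget",
                           "probe1", "probe2"),
                         unique(sub("_[xy]$", "",
                                    grep("_[xy]$", names(df), value = TRUE))))
  for (p in presented) {
    xy <- loc_matrix(df, p)
    bad <- which(!in_disk(xy, geom))
    if (length(bad))
      stop("location '", p, "' outside the disk at row ", bad[1])
  }
  if ("rt" %in% names(df) && any(df$rt <= 0))
    stop("non-positive reaction time at row ", which(df$rt <= 0)[1])
  stored <- df[, grep("^previous_|^valid_serial$", names(df)),
               drop = FALSE]
  df2 <- add_serial_lags(df[, !(names(df) %in% names(stored)), drop = FALSE],
                         experiment = experiment)
  if (ncol(stored)) {
    for (cl in setdiff(names(stored), "valid_serial")) {
      a <- stored[[cl]]; b <- df2[[cl]]
      same <- (is.na(a) & is.na(b)) |
        (!is.na(a) & !is.na(b) & abs(a - b) < 1e-9)
      if (!all(same))
        stop("stored lagged column '", cl,
             "' disagrees with recomputed lags at row ", which(!same)[1])
    }
  }
  new_trial_table(df2, experiment = experiment, geometry = geom)
}

#' Write / read an epoch array
#'
#' `path` is created as a directory holding `meta.json` (dimensions, time
#' axis, sampling rate, stage and channel metadata) and `data.bin`, the
#' array as little-endian float64 in column-major order.  The round trip is
#' byte-exact.
#'
#' @param epochs an [epoch_array()].
#' @param path directory path to create (or read).
#' @return `write_epochs` returns `path` invisibly; `read_epochs` returns an
#'   [epoch_array()].
#' @export
write_epochs <- function(epochs, path) {
  stopifnot(inherits(epochs, "epoch_array"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  meta <- list(format = "serialdep-epochs-v1",
               dim = dim(epochs$data),
               times = epochs$times,
               sfreq = epochs$sfreq,
               stage = epochs$stage)
  if (!is.null(epochs$channel_positions))
    meta$channel_positions <- unname(epochs$channel_positions)
  if (!is.null(epochs$channel_groups))
    meta$channel_groups <- epochs$channel_groups
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  con <- file(file.path(path, "data.bin"), "wb")
  on.exit(close(con))
  writeBin(as.vector(epochs$data), con, size = 8, endian = "little")
  invisible(path)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(path) {
  meta_path <- file.path(path, "meta.json")
  bin_path <- file.path(path, "data.bin")
  if (!file.exists(meta_path) || !file.exists(bin_path))
    stop("missing dataset: expected meta.json and data.bin under ", path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  if (!identical(meta$format, "serialdep-epochs-v1"))
    stop("unrecognised epochs format in ", meta_path)
  d <- as.integer(meta$dim)
  con <- file(bin_path, "rb")
  on.exit(close(con))
  v <- readBin(con, what = "double", n = prod(d), size = 8,
               endian = "little")
  if (length(v) != prod(d)) stop("data.bin shorter than declared dimensions")
  cp <- if (!is.null(meta$channel_positions)) {
    m <- meta$channel_positions
    if (is.matrix(m)) m else do.call(rbind, lapply(m, as.numeric))
  } else NULL
  epoch_array(array(v, dim = d), as.numeric(meta$times), meta$sfreq,
              stage = meta$stage, channel_positions = cp,
              channel_groups = meta$channel_groups)
}

#' Split sensors into anterior and posterior groups by Y position
#'
#' Sensors with positive Y (in the 3-D sensor frame, Y pointing anterior)
#' form the anterior group; sensors with negative Y the posterior group.
#' Sensors exactly at `y == 0` are assigned to the posterior group (tie
#' rule) with a message.
#'
#' @param channel_positions channels x 3 numeric matrix of sensor positions.
#' @return An object of class `sensor_groups`: list with integer index
#'   vectors `anterior`, `posterior` and `provenance = "y_sign_split"`.
#' @export
split_sensors <- function(channel_positions) {
  if (is.null(channel_positions))
    stop("channel positions unavailable; supply explicit channel_groups labels")
  pos <- as.matrix(channel_positions)
  stopifnot(ncol(pos) == 3)
  y <- pos[, 2]
  anterior <- which(y > 0)
  posterior <- which(y <= 0)
  if (any(y == 0))
    message(sum(y == 0), " sensor(s) at y == 0 assigned to posterior (tie rule)")
  if (!length(posterior) || !length(anterior))
    warning("degenerate split: one sensor group is empty")
  structure(list(anterior = anterior, posterior = posterior,
                 provenance = "y_sign_split"),
            class = "sensor_groups")
}

#' @export
print.sensor_groups <- function(x, ...) {
  cat(sprintf("<sensor_groups> anterior: %d, posterior: %d (%s)\n",
              length(x$anterior), length(x$posterior), x$provenance))
  invisible(x)
}
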