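# Group-level inference for effect time series: sign-flip permutation null,
# pointwise p-values, cluster-based correction over time, and an optional
# cross-region (spatial) correction pooling permuted cluster masses.

#' Sign-flip permutation test of a group effect time series
#'
#' Builds the group null by randomly negating each subject's entire effect
#' series with probability 1/2 (whole-series flips preserve temporal
#' autocorrelation) and averaging across subjects.  Two-sided pointwise
#' p-values compare the absolute observed group mean against the absolute
#' null means with add-one smoothing, `p = (1 + count) / (1 + n_perm)`.
#'
#' @param subject_series subjects x time numeric matrix.
#' @param n_perm number of permutations; the desk-scale default is 1000
#'   (increase to 1e5 for publication-grade tails).
#' @param seed integer seed.
#' @param times optional time axis (ms) carried into cluster results.
#' @return An object of class `sign_permutation` with `observed` (group
#'   mean), `p` (pointwise), `null` (n_perm x time matrix of null means),
#'   `times`, `n_perm` and `seed`.
#' @export
sign_permutation_test <- function(subject_series, n_perm = 1000, seed = NULL,
                                  times = NULL) {
  x <- as.matrix(subject_series)
  ns <- nrow(x)
  if (ns < 2) stop("need at least 2 subjects")
  if (n_perm < 100)
    warning("n_perm < 100: permutation p-values will have unstable tails")
  if (is.null(times)) times <- seq_len(ncol(x))
  stopifnot(length(times) == ncol(x))
  obs <- colMeans(x)
  null <- with_seed(seed, {
    flips <- matrix(sample(c(-1, 1), n_perm * ns, replace = TRUE),
                    n_perm, ns)
    (flips %*% x) / ns
  })
  # tolerance so that the identity flip pattern always counts as a tie
  # (flips %*% x and colMeans can differ in the last ulp)
  thr <- matrix(abs(obs) - 1e-12 * (abs(obs) + 1), n_perm, ncol(x),
                byrow = TRUE)
  p <- (1 + colSums(abs(null) >= thr)) / (1 + n_perm)
  structure(list(observed = obs, p = p, null = null,
                 times = as.numeric(times), n_perm = n_perm, seed = seed,
                 n_subjects = ns),
            class = "sign_permutation")
}

#' @export
print.sign_permutation <- function(x, ...) {
  cat(sprintf("<sign_permutation> %d subjects x %d time points, %d permutations; min p = %.4g\n",
              x$n_subjects, length(x$observed), x$n_perm, min(x$p)))
  invisible(x)
}

# Contiguous suprathreshold runs split by sign of the mean; returns a list
# of integer index vectors.
find_clusters <- function(p, means, alpha) {
  supra <- p < alpha
  out <- list()
  i <- 1L
  n <- length(p)
  while (i <= n) {
    if (supra[i]) {
      s <- sign(means[i])
      j <- i
      while (j < n && supra[j + 1L] && sign(means[j + 1L]) == s) j <- j + 1L
      out[[length(out) + 1L]] <- i:j
      i <- j + 1L
    } else i <- i + 1L
  }
  out
}

max_cluster_mass <- function(p, means, alpha) {
  cl <- find_clusters(p, means, alpha)
  if (!length(cl)) return(0)
  max(vapply(cl, function(idx) abs(sum(means[idx])), numeric(1)))
}

# Pointwise permutation p-values of every permutation against the whole null
# ensemble (per time point): p[k, t] = #{j : |null[j,t]| >= |null[k,t]|} / n.
perm_pointwise_p <- function(null_abs) {
  n <- nrow(null_abs)
  apply(null_abs, 2, function(v) (n - rank(v, ties.method = "min") + 1) / n)
}

#' Cluster-based correction over time
#'
#' Clusters are maximal contiguous runs of time points with pointwise
#' `p < cluster_alpha`, split by the sign of the group mean; a cluster's
#' mass is the signed sum of group means inside it.  The corrected p-value
#' of each cluster is the fraction of permutations whose maximal absolute
#' cluster mass (clusters formed identically on the permuted data) meets or
#' exceeds the observed absolute mass, with add-one smoothing.
#'
#' @param perm a [sign_permutation_test()] result.
#' @param cluster_alpha cluster-forming threshold on the pointwise p-value;
#'   default 0.05.
#' @return An object of class `cluster_result` with a `clusters` data.frame
#'   (`start_ms`, `end_ms`, `mass`, `p_corrected`, sorted by onset), the
#'   pointwise p-values, and the permutation distribution of maximal
#'   absolute cluster masses (`null_max_mass`) used for correction.
#' @export
cluster_correction <- function(perm, cluster_alpha = 0.05) {
  stopifnot(inherits(perm, "sign_permutation"))
  null_abs <- abs(perm$null)
  pp <- perm_pointwise_p(null_abs)
  null_max <- vapply(seq_len(perm$n_perm), function(k)
    max_cluster_mass(pp[k, ], perm$null[k, ], cluster_alpha), numeric(1))
  cl <- find_clusters(perm$p, perm$observed, cluster_alpha)
  clusters <- if (length(cl)) {
    df <- do.call(rbind, lapply(cl, function(idx) {
      mass <- sum(perm$observed[idx])
      data.frame(start_ms = perm$times[idx[1]],
                 end_ms = perm$times[idx[length(idx)]],
                 n_points = length(idx), mass = mass,
                 p_corrected = (1 + sum(null_max >= abs(mass))) /
                   (1 + perm$n_perm))
    }))
    df[order(df$start_ms), , drop = FALSE]
  } else {
    data.frame(start_ms = numeric(0), end_ms = numeric(0),
               n_points = integer(0), mass = numeric(0),
               p_corrected = numeric(0))
  }
  rownames(clusters) <- NULL
  structure(list(clusters = clusters, pointwise_p = perm$p,
                 observed = perm$observed, times = perm$times,
                 null_max_mass = null_max, n_perm = perm$n_perm,
                 threshold = cluster_alpha, seed = perm$seed,
                 tail = "two-sided"),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, digits = 4, ...) {
  cat(sprintf("<cluster_result> threshold p < %g, %d permutations, %s\n",
              x$threshold, x$n_perm, x$tail))
  if (nrow(x$clusters)) print(format(x$clusters, digits = digits),
                              row.names = FALSE)
  else cat("  no suprathreshold clusters\n")
  invisible(x)
}

#' Significant cluster windows as a list
#'
#' @param x a `cluster_result`.
#' @param alpha corrected significance level.
#' @return List of `(start_ms, end_ms)` vectors for clusters with
#'   `p_corrected < alpha`.
#' @export
significant_windows <- function(x, alpha = 0.05) {
  stopifnot(inherits(x, "cluster_result"))
  sig <- x$clusters[x$clusters$p_corrected < alpha, , drop = FALSE]
  lapply(seq_len(nrow(sig)), function(i)
    c(sig$start_ms[i], sig$end_ms[i]))
}

#' Cross-region spatial correction of temporal clusters
#'
#' Recomputes each region's cluster p-values against the distribution of
#' the maximal absolute cluster mass pooled across all regions per
#' permutation, controlling the family-wise error over regions as well as
#' time.  All regions must share the permutation count and seed schedule.
#'
#' @param region_results named list of `cluster_result` objects, one per
#'   region.
#' @return The same list with each cluster's `p_corrected` replaced by the
#'   spatially corrected value (and the original kept as
#'   `p_temporal`).
#' @export
spatial_correction <- function(region_results) {
  stopifnot(length(region_results) >= 1,
            all(vapply(region_results, inherits, logical(1),
                       "cluster_result")))
  nps <- vapply(region_results, function(r) r$n_perm, numeric(1))
  if (length(unique(nps)) != 1)
    stop("regions have mismatched permutation counts")
  seeds <- lapply(region_results, function(r) r$seed)
  if (length(unique(vapply(seeds, function(s)
    paste(s, collapse = ","), character(1)))) != 1)
    stop("regions have mismatched permutation seed schedules")
  pooled <- Reduce(pmax, lapply(region_results, function(r) r$null_max_mass))
  n_perm <- nps[1]
  lapply(region_results, function(r) {
    if (nrow(r$clusters)) {
      r$clusters$p_temporal <- r$clusters$p_corrected
      r$clusters$p_corrected <- vapply(r$clusters$mass, function(m)
        (1 + sum(pooled >= abs(m))) / (1 + n_perm), numeric(1))
    }
    r$tail <- "two-sided, spatially corrected"
    r
  })
}
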