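#' Disk geometry of the stimulus space
#'
#' The tasks present stimuli inside a round 2-D area; the default diameter is
#' 15 degrees of visual angle, with Cartesian coordinates centred on the disk
#' (X rightward, Y upward).
#'
#' @param diameter disk diameter in degrees of visual angle.
#' @param center length-2 numeric, disk centre.
#' @return An object of class `disk_geometry` with fields `diameter`,
#'   `radius` and `center`.
#' @examples
#' geom <- disk_geometry()
#' geom$radius  # 7.5
#' @export
disk_geometry <- function(diameter = 15, center = c(0, 0)) {
  stopifnot(is.numeric(diameter), length(diameter) == 1L, diameter > 0,
            is.numeric(center), length(center) == 2L, all(is.finite(center)))
  structure(list(diameter = diameter, radius = diameter / 2,
                 center = as.numeric(center)),
            class = "disk_geometry")
}

#' @export
print.disk_geometry <- function(x, ...) {
  cat(sprintf("<disk_geometry> diameter %g deg, center (%g, %g)\n",
              x$diameter, x$center[1], x$center[2]))
  invisible(x)
}

#' Sample locations uniformly over the disk
#'
#' Area-uniform sampling: the radius is drawn as `R * sqrt(u)` with
#' `u ~ Uniform(0, 1)` and the angle uniformly on `[0, 2*pi)`, so that points
#' are uniform over the disk area rather than over radius.
#'
#' @param n number of points (>= 0).
#' @param geometry a [disk_geometry()].
#' @param seed optional integer seed for reproducibility.
#' @return An `n x 2` numeric matrix with columns `x`, `y`.
#' @examples
#' pts <- sample_disk_locations(1000, disk_geometry(), seed = 1)
#' max(sqrt(rowSums(pts^2)))  # <= 7.5
#' @export
sample_disk_locations <- function(n, geometry = disk_geometry(), seed = NULL) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 0 ||
      n != floor(n))
    stop("`n` must be a single non-negative integer")
  stopifnot(inherits(geometry, "disk_geometry"))
  pts <- with_seed(seed, {
    r <- geometry$radius * sqrt(runif(n))
    theta <- runif(n, 0, 2 * pi)
    cbind(x = geometry$center[1] + r * cos(theta),
          y = geometry$center[2] + r * sin(theta))
  })
  pts
}

# TRUE for rows of `xy` inside the disk (with small tolerance).
in_disk <- function(xy, geometry, tol = 1e-8) {
  dx <- xy[, 1] - geometry$center[1]
  dy <- xy[, 2] - geometry$center[2]
  sqrt(dx^2 + dy^2) <= geometry$radius + tol
}
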