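#' Negative exponential dispersal kernel
#'
#' Converts an inter-patch distance into a probability of functional
#' connection, `p(d) = exp(-k d)`. The decay constant `k` is calibrated from
#' an anchor pair: the probability `p0` of connection at distance `d0`, so
#' `k = -log(p0) / d0`. The package default anchors the kernel at a 10%
#' probability of connection between patches 2 km apart, a parameterization
#' suited to a stingless bee's flight range.
#'
#' @param p0 anchor probability, in (0, 1]. `p0 = 1` gives the degenerate
#'   flat kernel `p(d) = 1`.
#' @param d0 anchor distance in meters, > 0.
#' @return An object of class `dispersal_kernel` with fields `k`, `p0`, `d0`.
#' @examples
#' k <- dispersal_kernel(0.10, 2000)
#' predict(k, c(0, 1000, 2000, 4000))
#' @export
dispersal_kernel <- function(p0 = 0.10, d0 = 2000) {
  if (!is.numeric(p0) || length(p0) != 1L || p0 <= 0 || p0 > 1)
    stop("`p0` must be a probability in (0, 1]")
  if (!is.numeric(d0) || length(d0) != 1L || d0 <= 0)
    stop("`d0` must be a positive distance in meters")
  structure(list(k = -log(p0) / d0, p0 = p0, d0 = d0),
            class = "dispersal_kernel")
}

#' @export
print.dispersal_kernel <- function(x, ...) {
  cat("<dispersal_kernel> p(d) = exp(-", format(x$k, digits = 6),
      " * d), anchored at p(", x$d0, " m) = ", x$p0, "\n", sep = "")
  invisible(x)
}

#' @param object a `dispersal_kernel`.
#' @param distance numeric vector of distances in meters.
#' @param ... unused.
#' @return Probabilities of connection at each distance.
#' @rdname dispersal_kernel
#' @export
predict.dispersal_kernel <- function(object, distance, ...) {
  if (any(distance < 0)) stop("distances must be non-negative")
  exp(-object$k * distance)
}

#' Distance beyond which kernel probabilities are negligible
#'
#' The distance at which `p(d)` falls below `pmin`; used as the default
#' cutoff when enumerating inter-patch distances, since pairs beyond it
#' contribute negligibly to the connectivity index.
#'
#' @param kernel a [dispersal_kernel].
#' @param pmin probability floor (default 1e-4).
#' @return Distance in meters (`Inf` for the flat kernel).
#' @export
kernel_cutoff <- function(kernel, pmin = 1e-4) {
  stopifnot(inherits(kernel, "dispersal_kernel"))
  if (kernel$k == 0) Inf else -log(pmin) / kernel$k
}
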