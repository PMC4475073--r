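#' Define a synthetic landscape scenario
#'
#' A scenario bundles everything needed to generate (reproducibly) a
#' fragmented binary habitat raster and a family of habitat-suitability
#' surfaces whose high-suitability region drifts across time periods,
#' emulating a poleward/inland range shift projected by a species
#' distribution model. All downstream stages of the package can be exercised
#' on these rasters without any external data.
#'
#' @param extent numeric `c(xmin, xmax, ymin, ymax)` in projected meters.
#' @param res pixel size in meters; default 50 m, the resolution at which
#'   connectivity is computed.
#' @param habitat_fraction target proportion of habitat pixels, in \[0, 1\].
#' @param aggregation clumping of habitat in \[0, 1\]: 0 gives salt-and-pepper
#'   fragmentation, 1 gives few large patches (maps to the correlation length
#'   of the underlying Gaussian random field).
#' @param n_periods number of suitability surfaces (time periods).
#' @param drift per-period displacement `c(dx, dy)` of the suitability peak,
#'   meters. Negative `dy` moves the peak south.
#' @param seed integer RNG seed; identical scenarios yield bit-identical
#'   rasters.
#' @return An object of class `synth_scenario`.
#' @export
synth_scenario <- function(extent, res = 50, habitat_fraction = 0.3,
                           aggregation = 0.5, n_periods = 4,
                           drift = c(0, 0), seed = 1L) {
  if (length(extent) != 4L || extent[2] <= extent[1] || extent[4] <= extent[3])
    stop("`extent` must be c(xmin, xmax, ymin, ymax) with positive width and height")
  if (!is.numeric(res) || res <= 0) stop("`res` must be positive")
  if (habitat_fraction < 0 || habitat_fraction > 1)
    stop("`habitat_fraction` must be in [0, 1]")
  if (aggregation < 0 || aggregation > 1)
    stop("`aggregation` must be in [0, 1]")
  nc <- (extent[2] - extent[1]) / res
  nr <- (extent[4] - extent[3]) / res
  if (abs(nc - round(nc)) > 1e-9 || abs(nr - round(nr)) > 1e-9)
    stop("extent must divide into whole pixels at the given resolution")
  structure(
    list(extent = as.numeric(extent), res = as.numeric(res),
         habitat_fraction = habitat_fraction, aggregation = aggregation,
         n_periods = as.integer(n_periods), drift = as.numeric(drift),
         seed = as.integer(seed)),
    class = "synth_scenario"
  )
}

#' @export
print.synth_scenario <- function(x, ...) {
  cat("<synth_scenario> ", diff(x$extent[1:2]) / 1000, " x ",
      diff(x$extent[3:4]) / 1000, " km @ ", x$res, " m, habitat ",
      100 * x$habitat_fraction, "%, aggregation ", x$aggregation,
      ", ", x$n_periods, " period(s), drift (", x$drift[1], ", ",
      x$drift[2], ") m, seed ", x$seed, "\n", sep = "")
  invisible(x)
}

scenario_dims <- function(scn) {
  c(round((scn$extent[4] - scn$extent[3]) / scn$res),
    round((scn$extent[2] - scn$extent[1]) / scn$res))
}

## Periodic Gaussian smoothing via FFT; sigma in pixels.
smooth_field <- function(z, sigma) {
  if (sigma <= 0) return(z)
  nr <- nrow(z); nc <- ncol(z)
  dr <- pmin(0:(nr - 1), nr - 0:(nr - 1))
  dc <- pmin(0:(nc - 1), nc - 0:(nc - 1))
  k <- exp(-outer(dr^2, dc^2, "+") / (2 * sigma^2))
  k <- k / sum(k)
  Re(stats::fft(stats::fft(z) * stats::fft(k), inverse = TRUE)) / (nr * nc)
}

#' Generate the binary habitat raster of a scenario
#'
#' A Gaussian white-noise field is smoothed (correlation length set by
#' `aggregation`) and thresholded at the quantile matching
#' `habitat_fraction`, yielding a binary map whose realized habitat fraction
#' tracks the request closely and whose patch structure ranges from highly
#' fragmented to strongly clumped.
#'
#' @param scenario a [synth_scenario].
#' @return A binary [land_raster] (values 0/1).
#' @export
generate_habitat <- function(scenario) {
  stopifnot(inherits(scenario, "synth_scenario"))
  d <- scenario_dims(scenario)
  f <- scenario$habitat_fraction
  if (f == 0) v <- matrix(0, d[1], d[2])
  else if (f == 1) v <- matrix(1, d[1], d[2])
  else {
    set.seed(scenario$seed)
    z <- matrix(stats::rnorm(d[1] * d[2]), d[1], d[2])
    z <- smooth_field(z, sigma = scenario$aggregation * 12)
    thr <- stats::quantile(z, 1 - f, names = FALSE)
    v <- matrix(as.numeric(z > thr), d[1], d[2])
  }
  land_raster(v, res = scenario$res,
              xmin = scenario$extent[1], ymin = scenario$extent[3])
}

#' Generate the suitability surface of a scenario for one period
#'
#' An anisotropic Gaussian bump (the species' climatic optimum) plus a
#' low-amplitude smooth noise field, clamped to \[0, 1\]. The bump center is
#' translated by `drift` for each successive period; the noise field is
#' shared across periods so that a zero drift yields identical surfaces.
#'
#' @param scenario a [synth_scenario].
#' @param period period index, `1 .. n_periods`.
#' @return A [land_raster] with values in \[0, 1\].
#' @export
generate_suitability <- function(scenario, period) {
  stopifnot(inherits(scenario, "synth_scenario"))
  if (period < 1 || period > scenario$n_periods)
    stop("`period` out of range: must be in 1..", scenario$n_periods)
  d <- scenario_dims(scenario)
  ext <- scenario$extent
  cx <- mean(ext[1:2]) + (period - 1) * scenario$drift[1]
  cy <- mean(ext[3:4]) + (period - 1) * scenario$drift[2]
  sx <- 0.30 * (ext[2] - ext[1])
  sy <- 0.20 * (ext[4] - ext[3])
  x <- ext[1] + (seq_len(d[2]) - 0.5) * scenario$res
  y <- ext[4] - (seq_len(d[1]) - 0.5) * scenario$res
  bump <- exp(-outer((y - cy)^2 / (2 * sy^2), (x - cx)^2 / (2 * sx^2), "+"))
  set.seed(scenario$seed + 1L)
  noise <- smooth_field(matrix(stats::rnorm(d[1] * d[2]), d[1], d[2]), sigma = 6)
  noise <- (noise - min(noise)) / max(1e-12, diff(range(noise)))
  v <- pmin(1, pmax(0, 0.9 * bump + 0.1 * noise))
  land_raster(matrix(v, d[1], d[2]), res = scenario$res,
              xmin = ext[1], ymin = ext[3])
}

#' Write a scenario's rasters plus a provenance sidecar
#'
#' Writes `habitat.asc` and `suitability_<period>.asc` for every period into
#' `dir`, together with `scenario.json` recording the full scenario so a run
#' can be reproduced from the files alone.
#'
#' @param scenario a [synth_scenario].
#' @param dir output directory (created if needed).
#' @param periods character labels, one per period (defaults to `period_1`..).
#' @return Named list of written file paths, invisibly.
#' @export
write_scenario <- function(scenario, dir,
                           periods = paste0("period_", seq_len(scenario$n_periods))) {
  stopifnot(inherits(scenario, "synth_scenario"),
            length(periods) == scenario$n_periods)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(habitat = file.path(dir, "habitat.asc"))
  write_raster(generate_habitat(scenario), paths$habitat)
  for (i in seq_len(scenario$n_periods)) {
    p <- file.path(dir, paste0("suitability_", periods[i], ".asc"))
    write_raster(generate_suitability(scenario, i), p)
    paths[[paste0("suitability_", periods[i])]] <- p
  }
  jsonlite::write_json(unclass(scenario), file.path(dir, "scenario.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
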