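#' Gridded raster with projected-CRS metadata
#'
#' Lightweight single-band raster container used throughout the package.
#' Values are stored as a numeric matrix with row 1 at the *top* (largest y),
#' the usual raster convention. Pixels are square and the CRS is assumed to be
#' projected with units of meters.
#'
#' @param values numeric matrix of cell values (row 1 = northernmost row).
#' @param res pixel size in meters (square pixels).
#' @param xmin,ymin coordinates of the lower-left corner of the grid, meters.
#' @param crs free-text CRS identifier (e.g. an EPSG code); purely metadata.
#' @return An object of class `land_raster`.
#' @export
land_raster <- function(values, res, xmin = 0, ymin = 0, crs = "local-meters") {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (!is.numeric(res) || length(res) != 1L || !is.finite(res) || res <= 0)
    stop("`res` must be a single positive number (meters per pixel)")
  structure(
    list(values = values, res = as.numeric(res),
         xmin = as.numeric(xmin), ymin = as.numeric(ymin), crs = as.character(crs)),
    class = "land_raster"
  )
}

#' @export
print.land_raster <- function(x, ...) {
  d <- dim(x$values)
  cat("<land_raster> ", d[1], " x ", d[2], " pixels @ ", x$res, " m (",
      x$crs, ")\n", sep = "")
  cat("  extent: x [", x$xmin, ", ", x$xmin + d[2] * x$res, "]  y [",
      x$ymin, ", ", x$ymin + d[1] * x$res, "] m\n", sep = "")
  v <- x$values[is.finite(x$values)]
  if (length(v)) cat("  values: [", format(min(v)), ", ", format(max(v)), "]\n", sep = "")
  invisible(x)
}

#' @export
dim.land_raster <- function(x) dim(x$values)

raster_extent <- function(r) {
  d <- dim(r$values)
  c(xmin = r$xmin, xmax = r$xmin + d[2] * r$res,
    ymin = r$ymin, ymax = r$ymin + d[1] * r$res)
}

## cell-center coordinates for every pixel, in raster storage order
## (column-major over the value matrix)
raster_coords <- function(r) {
  d <- dim(r$values)
  row <- rep.int(seq_len(d[1]), d[2])
  col <- rep(seq_len(d[2]), each = d[1])
  list(x = r$xmin + (col - 0.5) * r$res,
       y = r$ymin + (d[1] - row + 0.5) * r$res)
}

same_grid <- function(a, b) {
  identical(dim(a$values), dim(b$values)) &&
    isTRUE(all.equal(a$res, b$res)) &&
    isTRUE(all.equal(a$xmin, b$xmin)) &&
    isTRUE(all.equal(a$ymin, b$ymin))
}

#' Write a raster to disk
#'
#' Two plain formats are supported, chosen by file extension:
#' * `.asc` — ESRI ASCII grid, self-describing text (recommended for fixtures);
#'   the CRS string is stored in a sidecar `<path>.json`.
#' * `.tif` — single-band TIFF via the `tiff` package (8-bit for binary
#'   rasters, 32-bit float otherwise) with georeferencing (origin, resolution,
#'   CRS) in a sidecar `<path>.json`, since plain TIFF carries no geo tags.
#'
#' @param r a [land_raster].
#' @param path output file path ending in `.asc` or `.tif`.
#' @return `path`, invisibly.
#' @export
write_raster <- function(r, path) {
  stopifnot(inherits(r, "land_raster"))
  ext <- tolower(tools::file_ext(path))
  meta <- list(res = r$res, xmin = r$xmin, ymin = r$ymin, crs = r$crs,
               nrow = nrow(r$values), ncol = ncol(r$values))
  if (ext == "asc") {
    d <- dim(r$values)
    hdr <- c(paste("ncols", d[2]), paste("nrows", d[1]),
             paste("xllcorner", format(r$xmin, digits = 15)),
             paste("yllcorner", format(r$ymin, digits = 15)),
             paste("cellsize", format(r$res, digits = 15)),
             "NODATA_value -9999")
    v <- r$values
    v[!is.finite(v)] <- -9999
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(hdr, con)
    utils::write.table(v, con, row.names = FALSE, col.names = FALSE)
    jsonlite::write_json(meta["crs"], paste0(path, ".json"), auto_unbox = TRUE)
  } else if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("writing .tif requires the 'tiff' package; use .asc instead")
    binary <- all(r$values %in% c(0, 1))
    v <- r$values
    storage.mode(v) <- "double"
    tiff::writeTIFF(v, path, bits.per.sample = if (binary) 8L else 32L)
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  } else stop("unsupported raster extension: .", ext)
  invisible(path)
}

#' Read a raster written by [write_raster()]
#'
#' @param path file path ending in `.asc` or `.tif`.
#' @return A [land_raster].
#' @export
read_raster <- function(path) {
  ext <- tolower(tools::file_ext(path))
  side <- paste0(path, ".json")
  if (ext == "asc") {
    lines <- readLines(path, n = 6)
    kv <- strsplit(trimws(lines), "\\s+")
    hdr <- stats::setNames(as.numeric(vapply(kv, `[`, "", 2)),
                           tolower(vapply(kv, `[`, "", 1)))
    v <- as.matrix(utils::read.table(path, skip = 6))
    dimnames(v) <- NULL
    v[v == hdr[["nodata_value"]]] <- NA_real_
    crs <- if (file.exists(side)) jsonlite::read_json(side)$crs else "local-meters"
    land_raster(v, res = hdr[["cellsize"]], xmin = hdr[["xllcorner"]],
                ymin = hdr[["yllcorner"]], crs = crs)
  } else if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("reading .tif requires the 'tiff' package")
    if (!file.exists(side))
      stop("missing georeferencing sidecar: ", side)
    meta <- jsonlite::read_json(side)
    v <- tiff::readTIFF(path)
    if (length(dim(v)) == 3L) v <- v[, , 1]
    land_raster(v, res = meta$res, xmin = meta$xmin, ymin = meta$ymin,
                crs = meta$crs)
  } else stop("unsupported raster extension: .", ext)
}
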