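#' Tessellate an extent into equal-area hexagonal focal landscapes
#'
#' Covers a rectangular extent with a flat-top regular hexagon grid whose
#' cells all have area exactly `cell_area_ha` (default 5,000 ha — a focal
#' landscape several times wider than a short-range pollinator's dispersal).
#' The edge length follows from the area: `s = sqrt(2A / (3 sqrt(3)))`,
#' about 4,387 m for 5,000 ha. Cells whose hexagon is not entirely inside
#' the extent are flagged (`interior = FALSE`) so users may exclude them.
#'
#' @param extent numeric `c(xmin, xmax, ymin, ymax)`, meters.
#' @param cell_area_ha cell area in hectares (> 0).
#' @return An object of class `focal_grid`: a `cells` data.frame
#'   (`id`, axial coordinates `q`, `r`, center `cx`, `cy`, `interior`),
#'   the hexagon edge length `s` (m), the cell area, an adjacency edge list
#'   over edge-sharing cells, and the extent. Per-period local connectivity
#'   values are added by [local_connectivity()].
#' @export
hex_tessellation <- function(extent, cell_area_ha = 5000) {
  if (length(extent) != 4L || extent[2] <= extent[1] || extent[4] <= extent[3])
    stop("`extent` must be c(xmin, xmax, ymin, ymax) with positive area")
  if (cell_area_ha <= 0) stop("`cell_area_ha` must be positive")
  A <- cell_area_ha * 1e4  # m^2
  s <- sqrt(2 * A / (3 * sqrt(3)))
  ext_area_ha <- (extent[2] - extent[1]) * (extent[4] - extent[3]) / 1e4
  if (cell_area_ha > ext_area_ha)
    warning("cell area exceeds the extent; grid degenerates to clipped cell(s)")
  w <- extent[2] - extent[1]; h <- extent[4] - extent[3]
  # centers: cx = xmin + 1.5 s q ; cy = ymin + sqrt(3) s (r + q/2)
  qs <- seq.int(-2L, ceiling((w + s) / (1.5 * s)) + 1L)
  cells <- do.call(rbind, lapply(qs, function(q) {
    cx <- extent[1] + 1.5 * s * q
    hh <- sqrt(3) / 2 * s  # half height of a flat-top hexagon
    rmin <- floor((-hh) / (sqrt(3) * s) - q / 2) - 1L
    rmax <- ceiling((h + hh) / (sqrt(3) * s) - q / 2) + 1L
    r <- seq.int(rmin, rmax)
    data.frame(q = rep(q, length(r)), r = r, cx = rep(cx, length(r)),
               cy = extent[3] + sqrt(3) * s * (r + q / 2))
  }))
  # keep cells whose hexagon bounding box intersects the extent
  hh <- sqrt(3) / 2 * s
  keep <- cells$cx + s > extent[1] & cells$cx - s < extent[2] &
    cells$cy + hh > extent[3] & cells$cy - hh < extent[4]
  cells <- cells[keep, , drop = FALSE]
  # interior = all six vertices strictly inside the extent (a cell merely
  # tangent to the boundary counts as a boundary cell, which guarantees
  # every interior cell has all six neighbors in the grid)
  ang <- seq(0, 2 * pi, length.out = 7)[-7]
  eps <- 1e-6
  vin <- rep(TRUE, nrow(cells))
  for (a in ang) {
    vx <- cells$cx + s * cos(a); vy <- cells$cy + s * sin(a)
    vin <- vin & vx > extent[1] + eps & vx < extent[2] - eps &
      vy > extent[3] + eps & vy < extent[4] - eps
  }
  ord <- order(-cells$cy, cells$cx)  # north-to-south, west-to-east reading order
  cells <- cells[ord, , drop = FALSE]
  cells <- data.frame(id = seq_len(nrow(cells)), cells,
                      interior = vin[ord], row.names = NULL)
  # adjacency between edge-sharing hexagons: axial-coordinate neighbors
  key <- paste(cells$q, cells$r)
  # one representative of each neighbor direction pair
  dirs <- rbind(c(1, 0), c(0, 1), c(1, -1))
  adj <- do.call(rbind, lapply(seq_len(nrow(dirs)), function(d) {
    nb <- match(paste(cells$q + dirs[d, 1], cells$r + dirs[d, 2]), key)
    ok <- !is.na(nb)
    data.frame(i = cells$id[ok], j = cells$id[nb[ok]])
  }))
  # three directions cover each undirected pair once; normalize i < j
  adj <- unique(data.frame(i = pmin(adj$i, adj$j), j = pmax(adj$i, adj$j)))
  adj <- adj[order(adj$i, adj$j), , drop = FALSE]
  structure(list(cells = cells, s = s, cell_area_ha = cell_area_ha,
                 adjacency = adj, extent = as.numeric(extent),
                 values = list(), res = NA_real_),
            class = "focal_grid")
}

#' @export
print.focal_grid <- function(x, ...) {
  cat("<focal_grid> ", nrow(x$cells), " hexagonal cell(s) of ",
      x$cell_area_ha, " ha (edge ", round(x$s), " m), ",
      sum(x$cells$interior), " interior\n", sep = "")
  if (length(x$values))
    cat("  local connectivity computed for: ",
        paste(names(x$values), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Vertex coordinates of one hexagon cell
#'
#' @param grid a [focal_grid].
#' @param id cell id.
#' @return A 6x2 matrix of (x, y) vertex coordinates, counter-clockwise.
#' @export
hex_vertices <- function(grid, id) {
  cell <- grid$cells[grid$cells$id == id, ]
  if (!nrow(cell)) stop("unknown cell id: ", id)
  ang <- seq(0, 2 * pi, length.out = 7)[-7]
  cbind(x = cell$cx + grid$s * cos(ang), y = cell$cy + grid$s * sin(ang))
}

## assign points to hexagon cells by axial-coordinate cube rounding;
## returns the row index into grid$cells (NA if the containing hexagon
## is not part of the grid)
hex_assign <- function(grid, x, y) {
  s <- grid$s
  qf <- (x - grid$extent[1]) / (1.5 * s)
  rf <- (y - grid$extent[3]) / (sqrt(3) * s) - qf / 2
  xq <- qf; zq <- rf; yq <- -xq - zq
  rx <- round(xq); rz <- round(zq); ry <- round(yq)
  dx <- abs(rx - xq); dz <- abs(rz - zq); dy <- abs(ry - yq)
  fix_x <- dx > dz & dx > dy
  fix_z <- !fix_x & dz > dy
  rx[fix_x] <- -ry[fix_x] - rz[fix_x]
  rz[fix_z] <- -rx[fix_z] - ry[fix_z]
  match(paste(rx, rz), paste(grid$cells$q, grid$cells$r))
}
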