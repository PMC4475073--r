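#' Label habitat patches in a binary raster
#'
#' Connected-component labeling of habitat pixels. Neighboring habitat pixels
#' belong to the same patch under the chosen pixel connectivity: with
#' 8-connectivity diagonal neighbors are contiguous (the default — at 50 m
#' resolution diagonally touching forest pixels are functionally one patch),
#' with 4-connectivity only rook neighbors are.
#'
#' @param habitat a binary [land_raster] (values exactly 0/1).
#' @param connectivity 8 (default) or 4.
#' @return An object of class `patch_map`: the integer label matrix
#'   (`0` = non-habitat, patches numbered from 1 in scan order), a patch
#'   `table` (`id`, `pixels`, `area_ha`, `attribute`), and the grid metadata.
#'   Attributes are `NA` until [patch_attributes()] fills them.
#' @export
label_patches <- function(habitat, connectivity = 8) {
  stopifnot(inherits(habitat, "land_raster"))
  if (!all(habitat$values %in% c(0, 1)))
    stop("habitat raster must be strictly binary (0/1)")
  if (!connectivity %in% c(4, 8)) stop("connectivity must be 4 or 8")
  m <- habitat$values == 1
  lab <- label_components(m, connectivity)
  ids <- seq_len(max(lab, 0L))
  px <- tabulate(lab[lab > 0L], nbins = length(ids))
  structure(
    list(labels = lab,
         table = data.frame(id = ids, pixels = px,
                            area_ha = px * habitat$res^2 / 1e4,
                            attribute = rep(NA_real_, length(ids))),
         res = habitat$res, xmin = habitat$xmin, ymin = habitat$ymin,
         crs = habitat$crs, connectivity = connectivity),
    class = "patch_map"
  )
}

#' @export
print.patch_map <- function(x, ...) {
  cat("<patch_map> ", nrow(x$table), " patch(es), ",
      sum(x$table$pixels), " habitat pixel(s) @ ", x$res, " m, ",
      x$connectivity, "-connectivity\n", sep = "")
  if (!all(is.na(x$table$attribute)))
    cat("  suitability-weighted attributes: [",
        format(min(x$table$attribute)), ", ",
        format(max(x$table$attribute)), "]\n", sep = "")
  invisible(x)
}

## Core labeling: connected components of TRUE pixels via an adjacency
## edge list fed to igraph. `restrict` (optional integer matrix) confines
## components to pixels sharing a restrict value (used for per-cell clipping).
label_components <- function(m, connectivity = 8, restrict = NULL) {
  nr <- nrow(m); nc <- ncol(m)
  lab <- matrix(0L, nr, nc)
  on <- which(m)
  if (!length(on)) return(lab)
  cell <- matrix(seq_len(nr * nc), nr, nc)
  shifts <- list(c(1L, 0L), c(0L, 1L))
  if (connectivity == 8) shifts <- c(shifts, list(c(1L, 1L), c(1L, -1L)))
  from <- integer(0); to <- integer(0)
  for (s in shifts) {
    dr <- s[1]; dc <- s[2]  # dr >= 0 by construction, dc in {-1, 0, 1}
    r1 <- seq_len(nr - dr)
    c1 <- if (dc >= 0) seq_len(nc - dc) else seq.int(1 - dc, nc)
    r2 <- r1 + dr; c2 <- c1 + dc
    a <- as.vector(cell[r1, c1, drop = FALSE])
    b <- as.vector(cell[r2, c2, drop = FALSE])
    ok <- m[a] & m[b]
    if (!is.null(restrict)) ok <- ok & restrict[a] == restrict[b]
    from <- c(from, a[ok]); to <- c(to, b[ok])
  }
  vid <- integer(nr * nc)
  vid[on] <- seq_along(on)
  g <- igraph::graph_from_edgelist(cbind(vid[from], vid[to]), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(on) - igraph::vcount(g)))
  memb <- igraph::components(g)$membership
  # renumber so patch 1 is the first encountered in column-major scan order
  first <- !duplicated(memb)
  newid <- integer(max(memb))
  newid[memb[first]] <- seq_len(sum(first))
  lab[on] <- newid[memb]
  lab
}

#' Resample a suitability raster to a target resolution
#'
#' Brings a suitability surface onto the grid on which connectivity is
#' computed (habitat-map resolution, 50 m by default in this package).
#' Nearest-neighbor (default) preserves the original pixel values so that
#' patch attribute sums are not smoothed; bilinear is available as an option
#' and, being a convex combination, also keeps values inside \[0, 1\].
#'
#' @param suit a [land_raster] with values in \[0, 1\].
#' @param target_res target pixel size in meters; ignored if `template` given.
#' @param template optional [land_raster] whose grid (and CRS) to match;
#'   a CRS mismatch is an error.
#' @param method `"nearest"` (default) or `"bilinear"`.
#' @return A [land_raster] on the target grid.
#' @export
resample_suitability <- function(suit, target_res = NULL, template = NULL,
                                 method = c("nearest", "bilinear")) {
  stopifnot(inherits(suit, "land_raster"))
  method <- match.arg(method)
  if (!is.null(template)) {
    if (!identical(suit$crs, template$crs))
      stop("CRS mismatch: suitability is '", suit$crs, "', template is '",
           template$crs, "'")
    target_res <- template$res
  }
  if (is.null(target_res) || target_res <= 0)
    stop("`target_res` must be positive (or supply `template`)")
  ext <- raster_extent(suit)
  nc <- round((ext["xmax"] - ext["xmin"]) / target_res)
  nr <- round((ext["ymax"] - ext["ymin"]) / target_res)
  if (nr < 1 || nc < 1) stop("target resolution coarser than the raster extent")
  # target cell-center coordinates
  tx <- ext["xmin"] + (seq_len(nc) - 0.5) * target_res
  ty <- ext["ymax"] - (seq_len(nr) - 0.5) * target_res
  d <- dim(suit$values)
  if (method == "nearest") {
    sc <- pmin(pmax(ceiling((tx - ext["xmin"]) / suit$res), 1L), d[2])
    sr <- pmin(pmax(ceiling((ext["ymax"] - ty) / suit$res), 1L), d[1])
    out <- suit$values[sr, sc, drop = FALSE]
  } else {
    # fractional source position of each target center (1-based, cell centers)
    fc <- (tx - ext["xmin"]) / suit$res + 0.5
    fr <- (ext["ymax"] - ty) / suit$res + 0.5
    c0 <- pmin(pmax(floor(fc), 1L), d[2]); c1 <- pmin(c0 + 1L, d[2])
    r0 <- pmin(pmax(floor(fr), 1L), d[1]); r1 <- pmin(r0 + 1L, d[1])
    wc <- pmin(pmax(fc - c0, 0), 1); wr <- pmin(pmax(fr - r0, 0), 1)
    v <- suit$values
    out <- outer(1 - wr, 1 - wc) * v[r0, c0, drop = FALSE] +
      outer(1 - wr, wc) * v[r0, c1, drop = FALSE] +
      outer(wr, 1 - wc) * v[r1, c0, drop = FALSE] +
      outer(wr, wc) * v[r1, c1, drop = FALSE]
  }
  dimnames(out) <- NULL
  land_raster(out, res = target_res, xmin = suit$xmin, ymin = suit$ymin,
              crs = suit$crs)
}

#' Compute suitability-weighted patch attributes
#'
#' The attribute of each patch is the sum of the habitat-suitability values
#' of all its pixels — habitat area weighted by quality, so a large patch in
#' a highly suitable region scores highest. The suitability raster must
#' already be on the patch grid (see [resample_suitability()]).
#'
#' @param patches a [patch_map].
#' @param suit a [land_raster] of suitability on the same grid.
#' @return The `patch_map` with its `table$attribute` column filled.
#' @export
patch_attributes <- function(patches, suit) {
  stopifnot(inherits(patches, "patch_map"), inherits(suit, "land_raster"))
  if (!identical(dim(patches$labels), dim(suit$values)))
    stop("suitability grid shape does not match the patch grid; resample first")
  lab <- patches$labels
  a <- rep(0, nrow(patches$table))
  if (any(lab > 0L)) {
    s <- rowsum(as.vector(suit$values[lab > 0L]), group = lab[lab > 0L])
    a[as.integer(rownames(s))] <- s[, 1]
  }
  patches$table$attribute <- a
  patches
}

## Boundary pixels of each patch: habitat pixels with at least one
## rook neighbor outside the patch (or on the grid border). Returns, per
## patch id, a 2-column matrix of cell-center coordinates (meters).
boundary_pixels <- function(patches) {
  lab <- patches$labels
  nr <- nrow(lab); nc <- ncol(lab)
  inner <- matrix(TRUE, nr, nc)
  pad <- function(shift_r, shift_c) {
    out <- matrix(0L, nr, nc)
    rs <- seq_len(nr) + shift_r; cs <- seq_len(nc) + shift_c
    ok_r <- rs >= 1 & rs <= nr; ok_c <- cs >= 1 & cs <= nc
    out[ok_r, ok_c] <- lab[rs[ok_r], cs[ok_c]]
    out
  }
  same <- (pad(1, 0) == lab) & (pad(-1, 0) == lab) &
    (pad(0, 1) == lab) & (pad(0, -1) == lab)
  # grid-border pixels are always boundary
  same[1, ] <- FALSE; same[nr, ] <- FALSE; same[, 1] <- FALSE; same[, nc] <- FALSE
  bnd <- which(lab > 0L & !same)
  row <- (bnd - 1L) %% nr + 1L
  col <- (bnd - 1L) %/% nr + 1L
  x <- patches$xmin + (col - 0.5) * patches$res
  y <- patches$ymin + (nr - row + 0.5) * patches$res
  split.data.frame(cbind(x = x, y = y), lab[bnd])
}

## minimum Euclidean distance between two coordinate matrices;
## the larger set is processed in chunks to bound memory
min_cross_dist <- function(a, b) {
  if (nrow(a) < nrow(b)) { tmp <- a; a <- b; b <- tmp }
  chunk <- max(1L, floor(4e6 / nrow(b)))
  bs <- rowSums(b^2)
  best <- Inf
  for (start in seq.int(1L, nrow(a), by = chunk)) {
    ai <- a[start:min(nrow(a), start + chunk - 1L), , drop = FALSE]
    d2 <- outer(rowSums(ai^2), bs, "+") - 2 * tcrossprod(ai, b)
    best <- min(best, min(d2))
  }
  sqrt(max(0, best))
}

#' Edge-to-edge distances between patches
#'
#' Minimum Euclidean distance between the boundary pixels of every pair of
#' patches, measured center-to-center of the nearest pixels, reported only
#' for pairs within `cutoff`. This is the distance the dispersal kernel is
#' evaluated at.
#'
#' @param patches a [patch_map].
#' @param cutoff maximum distance to report, meters (default `Inf`); in the
#'   pipeline the cutoff is the distance at which the kernel probability
#'   drops below 1e-4 (see [kernel_cutoff()]), beyond which contributions to
#'   the connectivity index are numerically negligible.
#' @return `data.frame(i, j, distance)` with `i < j`; zero rows if fewer than
#'   two patches or no pair within the cutoff.
#' @export
interpatch_distances <- function(patches, cutoff = Inf) {
  stopifnot(inherits(patches, "patch_map"))
  if (cutoff <= 0) stop("`cutoff` must be positive")
  bp <- boundary_pixels(patches)
  ids <- as.integer(names(bp))
  n <- length(ids)
  empty <- data.frame(i = integer(0), j = integer(0), distance = numeric(0))
  if (n < 2) return(empty)
  # bounding boxes for a cheap cutoff prefilter
  bb <- t(vapply(bp, function(m)
    c(range(m[, 1]), range(m[, 2])), numeric(4)))
  res <- vector("list", n * (n - 1) / 2); k <- 0L
  for (u in seq_len(n - 1)) for (v in (u + 1):n) {
    gap_x <- max(0, max(bb[u, 1] - bb[v, 2], bb[v, 1] - bb[u, 2]))
    gap_y <- max(0, max(bb[u, 3] - bb[v, 4], bb[v, 3] - bb[u, 4]))
    if (is.finite(cutoff) && sqrt(gap_x^2 + gap_y^2) > cutoff) next
    d <- min_cross_dist(bp[[u]], bp[[v]])
    if (d <= cutoff) {
      k <- k + 1L
      res[[k]] <- c(ids[u], ids[v], d)
    }
  }
  if (!k) return(empty)
  out <- as.data.frame(do.call(rbind, res[seq_len(k)]))
  names(out) <- c("i", "j", "distance")
  out$i <- as.integer(out$i); out$j <- as.integer(out$j)
  out
}

#' Export the patch table as CSV
#'
#' Columns: `patch_id`, `pixel_count`, `area_ha`, `attribute`.
#' @param patches a [patch_map].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_patch_table <- function(patches, path) {
  tab <- patches$table
  names(tab) <- c("patch_id", "pixel_count", "area_ha", "attribute")
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' Export an inter-patch distance table as a CSV edge list
#'
#' Columns: `id_i`, `id_j`, `distance_m` (Conefor-style connection list).
#' @param distances output of [interpatch_distances()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(distances, path) {
  names(distances) <- c("id_i", "id_j", "distance_m")
  utils::write.csv(distances, path, row.names = FALSE)
  invisible(path)
}
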