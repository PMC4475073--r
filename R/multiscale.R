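#' Local connectivity of each focal landscape (PC numerator)
#'
#' Computes, for one time period, the habitat connectivity *inside* each
#' hexagonal focal landscape. Habitat patches are clipped by the cell edges
#' (each fragment becomes a local graph node), fragment attributes are the
#' summed habitat-suitability of their pixels, link probabilities come from
#' the dispersal kernel applied to edge-to-edge fragment distances, and the
#' stored per-cell value is the *numerator* of the Probability of
#' Connectivity. The numerator (not PC itself) is used because suitability
#' weighting makes the attainable attribute sum differ between equal-area
#' cells, so the unnormalized sum ranks cells by connectivity and
#' suitability jointly.
#'
#' @param grid a [focal_grid].
#' @param patches a [patch_map] of the study-area habitat.
#' @param suit a suitability [land_raster] on the patch grid (values in
#'   \[0, 1\]); see [resample_suitability()].
#' @param kernel a [dispersal_kernel].
#' @param period character label under which to store the values (e.g.
#'   `"current"`, `"2050"`).
#' @return The `focal_grid` with `values[[period]]` set: one PC-numerator
#'   value per cell (0 for cells without habitat).
#' @export
local_connectivity <- function(grid, patches, suit, kernel, period = "current") {
  stopifnot(inherits(grid, "focal_grid"), inherits(patches, "patch_map"),
            inherits(suit, "land_raster"), inherits(kernel, "dispersal_kernel"))
  if (!identical(dim(patches$labels), dim(suit$values)))
    stop("suitability grid shape does not match the patch grid; resample first")
  lab <- patches$labels
  nr <- nrow(lab); nc <- ncol(lab)
  # cell membership of every pixel center
  col <- rep(seq_len(nc), each = nr); row <- rep.int(seq_len(nr), nc)
  px <- patches$xmin + (col - 0.5) * patches$res
  py <- patches$ymin + (nr - row + 0.5) * patches$res
  cellmap <- matrix(hex_assign(grid, px, py), nr, nc)
  if (anyNA(cellmap[lab > 0L]))
    stop("focal grid does not cover all habitat pixels")
  # fragments: connected components confined to one cell
  frag <- label_components(lab > 0L, patches$connectivity, restrict = cellmap)
  vals <- rep(0, nrow(grid$cells))
  nfrag <- max(frag, 0L)
  if (nfrag > 0L) {
    on <- frag > 0L
    attr_frag <- rep(0, nfrag)
    s <- rowsum(as.vector(suit$values[on]), group = frag[on])
    attr_frag[as.integer(rownames(s))] <- s[, 1]
    # cell of each fragment (any pixel; fragments never straddle cells)
    cell_frag <- rep(NA_integer_, nfrag)
    cell_frag[frag[on]] <- cellmap[on]
    # boundary pixels of fragments, for edge-to-edge distances
    fp <- patches; fp$labels <- frag
    bp <- boundary_pixels(fp)
    bp_id <- as.integer(names(bp))
    cutoff <- kernel_cutoff(kernel)
    for (ci in unique(cell_frag)) {
      fids <- which(cell_frag == ci)
      a <- attr_frag[fids]
      if (length(fids) == 1L) { vals[ci] <- a^2; next }
      sub <- match(fids, bp_id)
      links <- NULL
      if (length(fids) >= 2) {
        dmat <- local_pair_distances(bp[sub], cutoff)
        if (nrow(dmat))
          links <- data.frame(i = fids[dmat$i], j = fids[dmat$j],
                              p = predict(kernel, dmat$distance))
      }
      g <- patch_graph(a, links, mode = "probability", ids = fids)
      vals[ci] <- pc_numerator(g)
    }
  }
  grid$values[[period]] <- vals
  grid$res <- patches$res
  # per-cell habitat pixel count (period-independent); clipping loses no pixels
  grid$habitat_pixels <- tabulate(cellmap[lab > 0L], nbins = nrow(grid$cells))
  grid
}

## pairwise min boundary distances within one cell (list of coord matrices)
local_pair_distances <- function(bps, cutoff) {
  n <- length(bps)
  out <- list(); k <- 0L
  for (u in seq_len(n - 1)) for (v in (u + 1):n) {
    d <- min_cross_dist(bps[[u]], bps[[v]])
    if (d <= cutoff) { k <- k + 1L; out[[k]] <- c(u, v, d) }
  }
  if (!k) return(data.frame(i = integer(0), j = integer(0), distance = numeric(0)))
  m <- as.data.frame(do.call(rbind, out))
  names(m) <- c("i", "j", "distance")
  m
}

#' Regional graph over focal landscapes
#'
#' Builds the study-area graph for one period: focal-landscape cells are the
#' nodes, node attributes are the cells' local PC numerators, and links join
#' exactly the edge-sharing hexagons — cells further apart than one hexagon
#' edge (~4.4 km for 5,000-ha cells) are beyond a short-range pollinator's
#' dispersal, so only adjacency links are functional. `A_L` is set to
#' (number of cells) x (cell pixel count), the maximum attainable total
#' attribute, which makes IIC dimensionless and at most 1; the removal
#' importance dIIC is a ratio and invariant to this normalization.
#'
#' @param grid a [focal_grid] with [local_connectivity()] computed.
#' @param period period label present in `grid$values`.
#' @return A binary-mode [patch_graph] whose node ids are the cell ids.
#' @export
regional_graph <- function(grid, period) {
  stopifnot(inherits(grid, "focal_grid"))
  if (!period %in% names(grid$values))
    stop("no local connectivity stored for period '", period,
         "'; run local_connectivity() first")
  cell_px <- grid$cell_area_ha * 1e4 / grid$res^2
  patch_graph(grid$values[[period]],
              links = grid$adjacency,
              A_L = nrow(grid$cells) * cell_px,
              mode = "binary", ids = grid$cells$id)
}

#' Regional importance of each focal landscape (dIIC)
#'
#' For each period, the Integral Index of Connectivity of the whole study
#' area is computed on the regional graph, then each cell is removed in turn
#' and the IIC recomputed; the percent drop is that cell's importance for
#' regional dispersal (see [node_removal_importance()]).
#'
#' @param grid a [focal_grid] with local connectivity stored for the periods.
#' @param periods period labels (default: all stored periods, in order).
#' @return An `importance_table`: data.frame with `cell_id` and one dIIC
#'   (percent) column per period.
#' @export
regional_importance <- function(grid, periods = names(grid$values)) {
  stopifnot(inherits(grid, "focal_grid"), length(periods) >= 1)
  cols <- lapply(periods, function(p) {
    g <- regional_graph(grid, p)
    if (all(g$attributes == 0))
      warning("all cell attributes are zero for period '", p,
              "'; importances are 0")
    imp <- suppressWarnings(node_removal_importance(g, "IIC"))
    imp$importance_pct
  })
  out <- data.frame(cell_id = grid$cells$id,
                    stats::setNames(cols, periods),
                    check.names = FALSE)
  structure(out, periods = periods,
            class = c("importance_table", "data.frame"))
}

#' Export an importance table as long-format CSV
#'
#' Columns: `cell_id`, `period`, `delta_iic_pct`.
#' @param importance an `importance_table` from [regional_importance()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_importance <- function(importance, path) {
  periods <- attr(importance, "periods")
  long <- do.call(rbind, lapply(periods, function(p)
    data.frame(cell_id = importance$cell_id, period = p,
               delta_iic_pct = importance[[p]])))
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' Sensitivity of regional importance to the dispersal distance
#'
#' Re-runs the local-plus-regional analysis with the kernel re-anchored
#' (same anchor probability) at each candidate dispersal distance, and
#' reports the Spearman rank correlation matrix of the per-cell dIIC
#' values across distances. High correlations indicate that the ranking of
#' focal landscapes is robust to the assumed dispersal capability.
#'
#' @param grid a [focal_grid].
#' @param patches a [patch_map].
#' @param suit a suitability [land_raster] on the patch grid.
#' @param distances numeric vector (>= 2) of anchor distances `d0`, meters.
#' @param p0 anchor probability (default 0.10).
#' @return An object of class `dispersal_sensitivity`: the per-cell
#'   importance matrix (cells x distances), the Spearman correlation matrix
#'   `rho`, and the distances. With fewer than 3 cells or constant
#'   importances the correlations are reported as `NA` and flagged.
#' @export
sensitivity_to_dispersal <- function(grid, patches, suit, distances,
                                     p0 = 0.10) {
  stopifnot(length(distances) >= 2)
  ncell <- nrow(grid$cells)
  imp <- vapply(distances, function(d0) {
    k <- dispersal_kernel(p0 = p0, d0 = d0)
    g <- local_connectivity(grid, patches, suit, k, period = ".sens")
    gr <- regional_graph(g, ".sens")
    suppressWarnings(node_removal_importance(gr, "IIC"))$importance_pct
  }, numeric(ncell))
  imp <- matrix(imp, nrow = ncell,
                dimnames = list(grid$cells$id, paste0(distances, "m")))
  degenerate <- nrow(imp) < 3 ||
    any(apply(imp, 2, function(v) stats::sd(v) == 0))
  rho <- if (degenerate) {
    matrix(NA_real_, ncol(imp), ncol(imp),
           dimnames = list(colnames(imp), colnames(imp)))
  } else stats::cor(imp, method = "spearman")
  structure(list(importances = imp, rho = rho,
                 distances = distances, degenerate = degenerate),
            class = "dispersal_sensitivity")
}

#' @export
print.dispersal_sensitivity <- function(x, ...) {
  cat("<dispersal_sensitivity> dIIC across dispersal distances (",
      paste(x$distances, collapse = ", "), " m)\n", sep = "")
  if (x$degenerate)
    cat("  rank correlation undefined (fewer than 3 cells or constant ranks)\n")
  else {
    cat("  Spearman rank correlations:\n")
    print(round(x$rho, 3))
  }
  invisible(x)
}
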