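#' Construct a landscape graph
#'
#' Nodes are habitat patches (or focal-landscape cells) carrying an
#' attribute `a_i` — typically habitat area weighted by summed habitat
#' suitability. Links are either probabilistic (`p_ij` in \[0, 1\], from a
#' dispersal kernel) for the Probability of Connectivity index, or binary
#' (present/absent) for the Integral Index of Connectivity. `A_L` is the
#' landscape "area" in the same units as the attributes, used to normalize
#' the indices; the PC/IIC numerators can be computed without it.
#'
#' @param attributes numeric vector of non-negative node attributes; names
#'   (or `ids`) identify the nodes.
#' @param links `data.frame(i, j, p)` in probability mode, or
#'   `data.frame(i, j)` in binary mode, referring to node ids; `NULL` for a
#'   linkless graph. Links are undirected; self-links are not allowed
#'   (the self-pair `i = j` is handled analytically in the indices).
#' @param A_L landscape area (attribute units); `NA` allowed when only
#'   numerators are needed.
#' @param mode `"probability"` or `"binary"`.
#' @param ids optional node identifiers (default `1..n` or names of
#'   `attributes`).
#' @return An object of class `patch_graph`.
#' @export
patch_graph <- function(attributes, links = NULL, A_L = NA_real_,
                        mode = c("probability", "binary"), ids = NULL) {
  mode <- match.arg(mode)
  if (any(!is.finite(attributes)) || any(attributes < 0))
    stop("node attributes must be finite and non-negative")
  if (is.null(ids)) ids <- if (!is.null(names(attributes))) names(attributes)
    else seq_along(attributes)
  ids <- as.character(ids)
  if (anyDuplicated(ids)) stop("node ids must be unique")
  n <- length(attributes)
  if (is.null(links)) {
    links <- if (mode == "probability")
      data.frame(i = character(0), j = character(0), p = numeric(0))
    else data.frame(i = character(0), j = character(0))
  } else {
    links <- as.data.frame(links)
    links$i <- as.character(links$i); links$j <- as.character(links$j)
    if (!all(c(links$i, links$j) %in% ids))
      stop("links refer to unknown node ids")
    if (any(links$i == links$j)) stop("self-links are not allowed")
    if (mode == "probability") {
      if (!"p" %in% names(links)) stop("probability mode requires a `p` column")
      p <- links$p
      if (any(!is.finite(p)) || any(p < 0)) stop("link probabilities must be in [0, 1]")
      over <- p > 1
      if (any(p[over] > 1 + 1e-9)) stop("link probabilities must be in [0, 1]")
      p[over] <- 1  # clip tiny floating-point overshoot
      links$p <- p
    }
  }
  if (!is.na(A_L) && A_L <= 0) stop("`A_L` must be positive (or NA)")
  structure(list(ids = ids, attributes = as.numeric(attributes),
                 links = links, A_L = as.numeric(A_L), mode = mode),
            class = "patch_graph")
}

#' @export
print.patch_graph <- function(x, ...) {
  cat("<patch_graph> ", length(x$ids), " node(s), ", nrow(x$links),
      " link(s), mode ", x$mode, ", A_L = ", x$A_L, "\n", sep = "")
  invisible(x)
}

#' Build a probability-mode graph from patches, distances and a kernel
#'
#' Convenience constructor: node attributes from the patch table, link
#' probabilities `p_ij = exp(-k d_ij)` from the dispersal kernel applied to
#' the edge-to-edge distances.
#'
#' @param patches a [patch_map] with attributes computed.
#' @param distances output of [interpatch_distances()].
#' @param kernel a [dispersal_kernel].
#' @param A_L landscape area in attribute units (`NA` for numerator-only use).
#' @return A probability-mode [patch_graph].
#' @export
graph_from_patches <- function(patches, distances, kernel, A_L = NA_real_) {
  stopifnot(inherits(patches, "patch_map"), inherits(kernel, "dispersal_kernel"))
  if (all(is.na(patches$table$attribute)))
    stop("patch attributes not set; run patch_attributes() first")
  links <- if (nrow(distances))
    data.frame(i = distances$i, j = distances$j,
               p = predict(kernel, distances$distance))
  else NULL
  patch_graph(patches$table$attribute, links, A_L = A_L,
              mode = "probability", ids = patches$table$id)
}

ig_from <- function(graph, weights = FALSE) {
  g <- igraph::make_empty_graph(n = length(graph$ids), directed = FALSE)
  if (nrow(graph$links)) {
    ii <- match(graph$links$i, graph$ids)
    jj <- match(graph$links$j, graph$ids)
    g <- igraph::add_edges(g, rbind(ii, jj))
    if (weights) igraph::E(g)$weight <- -log(graph$links$p)
  }
  g
}

#' Maximum product-probability path between all node pairs
#'
#' For each ordered pair the probability `p*_ij` of the best path: the
#' maximum over paths of the product of link probabilities (`p*_ii = 1`;
#' 0 for disconnected pairs). Computed as shortest paths on `-log(p)`
#' weights; links with `p = 0` are dropped beforehand.
#'
#' @param graph a probability-mode [patch_graph].
#' @return A symmetric numeric matrix with unit diagonal, dimnames = node ids.
#' @export
max_product_paths <- function(graph) {
  stopifnot(inherits(graph, "patch_graph"))
  if (graph$mode != "probability") stop("requires a probability-mode graph")
  g2 <- graph
  g2$links <- graph$links[graph$links$p > 0, , drop = FALSE]
  ig <- ig_from(g2, weights = TRUE)
  D <- igraph::distances(ig, algorithm = "dijkstra")
  P <- exp(-D)
  dimnames(P) <- list(graph$ids, graph$ids)
  P
}

## number of links on the topological shortest path (Inf if disconnected)
shortest_path_links <- function(graph) {
  ig <- ig_from(graph, weights = FALSE)
  igraph::distances(ig, weights = NA)
}

pc_numerator <- function(graph) {
  a <- graph$attributes
  as.numeric(t(a) %*% max_product_paths(graph) %*% a)
}

iic_numerator <- function(graph) {
  a <- graph$attributes
  W <- 1 / (1 + shortest_path_links(graph))  # 0 for disconnected pairs
  as.numeric(t(a) %*% W %*% a)
}

new_index_result <- function(name, numerator, A_L) {
  structure(list(index_name = name, numerator = numerator,
                 index = if (is.na(A_L)) NA_real_ else numerator / A_L^2,
                 A_L = A_L),
            class = "index_result")
}

#' @export
print.index_result <- function(x, ...) {
  cat("<index_result> ", x$index_name, " = ", format(x$index),
      " (numerator ", format(x$numerator), ", A_L = ", x$A_L, ")\n", sep = "")
  invisible(x)
}

#' Probability of Connectivity (PC)
#'
#' The habitat-availability index
#' \deqn{PC = \frac{\sum_{i=1}^n \sum_{j=1}^n a_i a_j p^*_{ij}}{A_L^2}}
#' over all ordered node pairs including the self-pairs (`p*_ii = 1`), where
#' `p*_ij` is the maximum product-probability path (see
#' [max_product_paths()]). With `numerator_only = TRUE` the unnormalized
#' double sum is returned even when `A_L` is unset — the per-focal-landscape
#' quantity used at the local scale, where suitability weighting makes the
#' attainable attribute sum differ between equal-area landscapes.
#'
#' @param graph a probability-mode [patch_graph].
#' @param numerator_only if `TRUE`, skip the `A_L` normalization.
#' @return An `index_result` with fields `index`, `numerator`.
#' @export
compute_pc <- function(graph, numerator_only = FALSE) {
  stopifnot(inherits(graph, "patch_graph"))
  if (graph$mode != "probability") stop("PC requires a probability-mode graph")
  num <- pc_numerator(graph)
  if (!numerator_only && is.na(graph$A_L))
    stop("`A_L` is unset; supply it or use numerator_only = TRUE")
  new_index_result("PC", num, if (numerator_only) NA_real_ else graph$A_L)
}

#' Integral Index of Connectivity (IIC)
#'
#' The binary counterpart of [compute_pc()]:
#' \deqn{IIC = \frac{\sum_{i=1}^n \sum_{j=1}^n a_i a_j / (1 + nl_{ij})}{A_L^2}}
#' where `nl_ij` is the number of links on the topological shortest path
#' between `i` and `j` (`nl_ii = 0`; the term is 0 for disconnected pairs).
#'
#' @param graph a binary-mode [patch_graph].
#' @param numerator_only if `TRUE`, skip the `A_L` normalization.
#' @return An `index_result`.
#' @export
compute_iic <- function(graph, numerator_only = FALSE) {
  stopifnot(inherits(graph, "patch_graph"))
  if (graph$mode != "binary") stop("IIC requires a binary-mode graph")
  num <- iic_numerator(graph)
  if (!numerator_only && is.na(graph$A_L))
    stop("`A_L` is unset; supply it or use numerator_only = TRUE")
  new_index_result("IIC", num, if (numerator_only) NA_real_ else graph$A_L)
}

drop_node <- function(graph, id) {
  keep <- graph$ids != id
  g2 <- graph
  g2$ids <- graph$ids[keep]
  g2$attributes <- graph$attributes[keep]
  g2$links <- graph$links[graph$links$i != id & graph$links$j != id, ,
                          drop = FALSE]
  g2
}

#' Node-removal importance (dPC / dIIC)
#'
#' The importance of each node is the percent drop in the index when that
#' node (and its links) is removed, the landscape area `A_L` being held
#' fixed across removals:
#' \deqn{\Delta I_k = 100 \, (I - I_{-k}) / I}
#' Because `A_L` cancels in the ratio, the computation uses the numerators
#' and works whether or not `A_L` is set.
#'
#' @param graph a [patch_graph] (mode must match `index`).
#' @param index `"IIC"` or `"PC"`.
#' @return `data.frame(id, importance_pct)` in node order; values in
#'   \[0, 100\]. If the index is zero (all attributes zero), importances are
#'   reported as 0 with a warning.
#' @export
node_removal_importance <- function(graph, index = c("IIC", "PC")) {
  stopifnot(inherits(graph, "patch_graph"))
  index <- match.arg(index)
  numfun <- if (index == "PC") pc_numerator else iic_numerator
  need <- if (index == "PC") "probability" else "binary"
  if (graph$mode != need)
    stop(index, " importance requires a ", need, "-mode graph")
  full <- numfun(graph)
  n <- length(graph$ids)
  if (full == 0) {
    warning("index is zero; node importances undefined, reported as 0")
    return(data.frame(id = graph$ids, importance_pct = rep(0, n)))
  }
  imp <- vapply(graph$ids, function(id) {
    g2 <- drop_node(graph, id)
    100 * (full - numfun(g2)) / full
  }, numeric(1))
  data.frame(id = graph$ids, importance_pct = unname(imp))
}
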