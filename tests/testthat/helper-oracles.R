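# Independent brute-force oracles, deliberately written with different
# algorithms than the production code paths they check.

# queue-based flood fill labeling (production uses graph components)
oracle_label <- function(m, connectivity = 8) {
  nr <- nrow(m); nc <- ncol(m)
  lab <- matrix(0L, nr, nc)
  nxt <- 0L
  nbr <- if (connectivity == 8)
    rbind(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1), c(0, 1),
          c(1, -1), c(1, 0), c(1, 1))
  else rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  for (c0 in seq_len(nc)) for (r0 in seq_len(nr)) {
    if (!m[r0, c0] || lab[r0, c0] > 0L) next
    nxt <- nxt + 1L
    queue <- list(c(r0, c0)); lab[r0, c0] <- nxt
    while (length(queue)) {
      cur <- queue[[1]]; queue <- queue[-1]
      for (k in seq_len(nrow(nbr))) {
        rr <- cur[1] + nbr[k, 1]; cc <- cur[2] + nbr[k, 2]
        if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc &&
            m[rr, cc] && lab[rr, cc] == 0L) {
          lab[rr, cc] <- nxt
          queue[[length(queue) + 1L]] <- c(rr, cc)
        }
      }
    }
  }
  lab
}

# exhaustive simple-path enumeration of max product-probability paths
oracle_pstar <- function(n, links) {
  adj <- replicate(n, list())
  if (nrow(links)) for (k in seq_len(nrow(links))) {
    i <- as.integer(links$i[k]); j <- as.integer(links$j[k]); p <- links$p[k]
    adj[[i]][[length(adj[[i]]) + 1L]] <- c(j, p)
    adj[[j]][[length(adj[[j]]) + 1L]] <- c(i, p)
  }
  P <- diag(n)
  for (src in seq_len(n)) {
    best <- numeric(n)
    dfs <- function(v, visited, prob) {
      if (prob > best[v]) best[v] <<- prob
      for (e in adj[[v]])
        if (!visited[e[1]])
          dfs(e[1], `[<-`(visited, e[1], TRUE), prob * e[2])
    }
    dfs(src, `[<-`(logical(n), src, TRUE), 1)
    P[src, ] <- best
  }
  P
}

oracle_pc_numerator <- function(a, links) {
  P <- oracle_pstar(length(a), links)
  sum(outer(a, a) * P)
}

# breadth-first link counts for every pair, then the IIC double sum
oracle_iic_numerator <- function(a, links) {
  n <- length(a)
  A <- matrix(FALSE, n, n)
  if (nrow(links)) {
    A[cbind(links$i, links$j)] <- TRUE
    A[cbind(links$j, links$i)] <- TRUE
  }
  nl <- matrix(Inf, n, n)
  for (src in seq_len(n)) {
    dist <- rep(Inf, n); dist[src] <- 0
    frontier <- src; d <- 0
    while (length(frontier)) {
      d <- d + 1
      nxt <- which(apply(A[frontier, , drop = FALSE], 2, any) & is.infinite(dist))
      dist[nxt] <- d
      frontier <- nxt
    }
    nl[src, ] <- dist
  }
  sum(outer(a, a) / (1 + nl))
}

# min distance between two patches over *all* pixel pairs (not just boundary)
oracle_patch_distance <- function(lab, id1, id2, res, xmin = 0, ymin = 0) {
  nr <- nrow(lab)
  xy <- function(id) {
    w <- which(lab == id)
    row <- (w - 1L) %% nr + 1L; col <- (w - 1L) %/% nr + 1L
    cbind(xmin + (col - 0.5) * res, ymin + (nr - row + 0.5) * res)
  }
  a <- xy(id1); b <- xy(id2)
  best <- Inf
  for (u in seq_len(nrow(a))) for (v in seq_len(nrow(b)))
    best <- min(best, sqrt(sum((a[u, ] - b[v, ])^2)))
  best
}

# random probability-mode graph on n nodes (integer ids 1..n)
random_graph <- function(n, p_link = 0.4, mode = "probability") {
  pairs <- t(utils::combn(n, 2))
  keep <- stats::runif(nrow(pairs)) < p_link
  links <- if (mode == "probability")
    data.frame(i = pairs[keep, 1], j = pairs[keep, 2],
               p = stats::runif(sum(keep)))
  else data.frame(i = pairs[keep, 1], j = pairs[keep, 2])
  a <- stats::runif(n, 0, 5)
  list(a = a, links = links,
       graph = patch_graph(a, if (nrow(links)) links else NULL,
                           A_L = sum(a) + 1, mode = mode))
}

shoelace_area <- function(v) {
  abs(sum(v[, 1] * c(v[-1, 2], v[1, 2]) - c(v[-1, 1], v[1, 1]) * v[, 2])) / 2
}

tiny_scenario <- function(seed = 1L, n_periods = 1L, drift = c(0, 0),
                          fraction = 0.3, aggregation = 0.4,
                          extent = c(0, 6400, 0, 6400), res = 100) {
  synth_scenario(extent = extent, res = res, habitat_fraction = fraction,
                 aggregation = aggregation, n_periods = n_periods,
                 drift = drift, seed = seed)
}
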