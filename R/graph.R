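#' Weighted network container
#'
#' A symmetric, non-negative weight matrix with zero diagonal. Built from a
#' [build_connectome()] result (choosing which edge weight to analyse) or
#' from any raw matrix.
#'
#' @param w symmetric non-negative matrix, or a `connectome`.
#' @param weight_kind one of `"fiber_number"`, `"mean_fa"`, `"binary"`; for
#'   a raw matrix this is a descriptive tag, for a `connectome` it selects
#'   the matrix (binary = fiber_number > 0).
#' @return an object of class `weighted_network`.
#' @export
weighted_network <- function(w, weight_kind = c("fiber_number", "mean_fa", "binary")) {
  weight_kind <- match.arg(weight_kind)
  if (inherits(w, "connectome")) {
    w <- switch(weight_kind,
                fiber_number = w$fiber_number,
                mean_fa = w$mean_fa,
                binary = (w$fiber_number > 0) * 1)
  }
  w <- as.matrix(w)
  if (nrow(w) != ncol(w)) stop("weight matrix must be square")
  if (any(w < 0)) stop("negative edge weight")
  if (max(abs(w - t(w))) > 1e-12) stop("weight matrix must be symmetric")
  w <- (w + t(w)) / 2
  diag(w) <- 0
  structure(list(w = w, n = nrow(w), weight_kind = weight_kind),
            class = "weighted_network")
}

#' Weight-to-distance conversion
#'
#' Standard weighted-graph convention: `d_ij = 1 / w_ij` for `w_ij > 0`,
#' `Inf` for absent edges, 0 on the diagonal.
#'
#' @param net a `weighted_network`.
#' @return the edge-length matrix.
#' @export
to_distance <- function(net) {
  stopifnot(inherits(net, "weighted_network"))
  d <- ifelse(net$w > 0, 1 / net$w, Inf)
  diag(d) <- 0
  d
}

net_graph <- function(net) {
  g <- igraph::graph_from_adjacency_matrix(net$w, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  igraph::E(g)$length <- 1 / igraph::E(g)$weight
  g
}

shortest_distances <- function(net) {
  if (all(net$w == 0)) {
    d <- matrix(Inf, net$n, net$n); diag(d) <- 0
    return(d)
  }
  g <- net_graph(net)
  igraph::distances(g, weights = igraph::E(g)$length, algorithm = "dijkstra")
}

efficiency_from_distances <- function(d) {
  n <- nrow(d)
  if (n < 2) return(0)
  inv <- 1 / d; diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

#' Core topology metrics of a weighted network
#'
#' Shortest paths are Dijkstra over `d = 1/w` edge lengths. Global
#' efficiency `Eg` is the mean over ordered node pairs of `1/d_ij` (with
#' `1/Inf = 0`); characteristic path length `Lp` is the mean `d_ij` over
#' connected ordered pairs (disconnected pairs excluded and counted); local
#' efficiency `Eloc` is the mean over nodes of the global efficiency of
#' each node's neighbour-induced subgraph; `Cp` is the mean Onnela weighted
#' clustering coefficient (weights normalized by the network maximum;
#' reduces to per-node triangle density for binary networks).
#'
#' @param net a `weighted_network`.
#' @return list with `Eg`, `Eloc`, `Lp`, `Cp`, and
#'   `n_disconnected_pairs` (ordered pairs excluded from `Lp`).
#' @export
network_metrics <- function(net) {
  stopifnot(inherits(net, "weighted_network"))
  n <- net$n
  if (n < 2) stop("network needs at least 2 nodes")
  d <- shortest_distances(net)
  off <- d[row(d) != col(d)]
  eg <- mean(ifelse(is.finite(off), 1 / off, 0))
  connected <- is.finite(off)
  lp <- if (any(connected)) mean(off[connected]) else NA_real_

  eloc <- mean(vapply(seq_len(n), function(i) {
    nb <- which(net$w[i, ] > 0)
    if (length(nb) < 2) return(0)
    sub <- weighted_network(net$w[nb, nb, drop = FALSE], net$weight_kind)
    efficiency_from_distances(shortest_distances(sub))
  }, numeric(1)))

  list(Eg = eg, Eloc = eloc, Lp = lp, Cp = clustering_onnela(net),
       n_disconnected_pairs = sum(!connected))
}

clustering_onnela <- function(net) {
  w <- net$w
  mx <- max(w)
  if (mx == 0) return(0)
  s <- (w / mx)^(1 / 3)
  num <- diag(s %*% s %*% s)
  k <- rowSums(w > 0)
  ci <- ifelse(k >= 2, num / (k * (k - 1)), 0)
  mean(ci)
}

#' Degree-preserving rewired null network
#'
#' Maslov-Sneppen double-edge swaps: `10 * |E|` attempted swaps, each
#' replacing edges (a,b), (c,d) by (a,d), (c,b) when neither self-loops nor
#' multi-edges would result. Edge weights travel with the rewired edges, so
#' both the degree sequence and the weight multiset are preserved exactly.
#' Graphs admitting no legal swap (e.g. complete graphs) are returned
#' unchanged with attribute `unchanged = TRUE`.
#'
#' @param net a `weighted_network` with >= 2 edges.
#' @param seed RNG seed.
#' @return a rewired `weighted_network`.
#' @export
rewire_null <- function(net, seed = NULL) {
  stopifnot(inherits(net, "weighted_network"))
  if (!is.null(seed)) set.seed(seed)
  ut <- which(upper.tri(net$w) & net$w > 0, arr.ind = TRUE)
  ne <- nrow(ut)
  if (ne < 2) stop("rewiring needs at least 2 edges")
  edges <- ut          # ne x 2, i < j
  wts <- net$w[ut]
  adj <- net$w > 0
  n_swapped <- 0L
  for (att in seq_len(10L * ne)) {
    pick <- sample.int(ne, 2L)
    e1 <- edges[pick[1], ]; e2 <- edges[pick[2], ]
    if (stats::runif(1) < 0.5) e2 <- rev(e2)
    a <- e1[1]; b <- e1[2]; c <- e2[1]; d <- e2[2]
    # propose (a,d) and (c,b)
    if (a == d || c == b) next
    if (length(unique(c(a, b, c, d))) < 4) next
    if (adj[a, d] || adj[c, b]) next
    adj[a, b] <- adj[b, a] <- FALSE
    adj[c, d] <- adj[d, c] <- FALSE
    adj[a, d] <- adj[d, a] <- TRUE
    adj[c, b] <- adj[b, c] <- TRUE
    edges[pick[1], ] <- sort(c(a, d))
    edges[pick[2], ] <- sort(c(c, b))
    n_swapped <- n_swapped + 1L
  }
  w <- matrix(0, net$n, net$n)
  w[edges] <- wts
  w <- w + t(w)
  out <- weighted_network(w, net$weight_kind)
  attr(out, "unchanged") <- n_swapped == 0L
  attr(out, "n_swapped") <- n_swapped
  out
}

#' Small-worldness against degree-preserving nulls
#'
#' `gamma = Cp / mean(Cp_null)`, `lambda = Lp / mean(Lp_null)`,
#' `sigma = gamma / lambda`, over `n_null` rewired nulls (seeds
#' `seed + 1 .. seed + n_null`). Disconnected input triggers a warning and
#' the computation runs on the largest connected component.
#'
#' @param net a `weighted_network`.
#' @param n_null number of null networks (default 100).
#' @param seed base RNG seed.
#' @return list with `gamma`, `lambda`, `sigma`, `Cp`, `Lp`, `Cp_null`,
#'   `Lp_null` (null means), `n_null`.
#' @export
small_worldness <- function(net, n_null = 100L, seed = 1L) {
  stopifnot(inherits(net, "weighted_network"))
  comp <- igraph::components(igraph::graph_from_adjacency_matrix(
    (net$w > 0) * 1, mode = "undirected", diag = FALSE))
  if (comp$no > 1) {
    warning("network is disconnected; using the largest connected component")
    keep <- which(comp$membership == which.max(comp$csize))
    net <- weighted_network(net$w[keep, keep, drop = FALSE], net$weight_kind)
  }
  m <- network_metrics(net)
  cp_lp <- function(x) {
    d <- shortest_distances(x)
    off <- d[row(d) != col(d)]
    list(Cp = clustering_onnela(x), Lp = mean(off[is.finite(off)]))
  }
  nulls <- lapply(seq_len(n_null), function(i) {
    nl <- rewire_null(net, seed = seed + i)
    cp_lp(nl)
  })
  cp_null <- mean(vapply(nulls, `[[`, numeric(1), "Cp"))
  lp_null <- mean(vapply(nulls, `[[`, numeric(1), "Lp"))
  if (cp_null == 0 || lp_null == 0) stop("null Cp or Lp is zero; sigma undefined")
  gamma <- m$Cp / cp_null
  lambda <- m$Lp / lp_null
  list(gamma = gamma, lambda = lambda, sigma = gamma / lambda,
       Cp = m$Cp, Lp = m$Lp, Cp_null = cp_null, Lp_null = lp_null,
       n_null = n_null)
}

#' Full per-network metric set
#'
#' Convenience wrapper combining [network_metrics()] and
#' [small_worldness()] into the flat per-subject record used by the cohort
#' layer.
#'
#' @inheritParams small_worldness
#' @return data.frame with one row: Eg, Eloc, Lp, Cp, gamma, lambda, sigma.
#' @export
graph_metrics_set <- function(net, n_null = 100L, seed = 1L) {
  m <- network_metrics(net)
  sw <- small_worldness(net, n_null = n_null, seed = seed)
  data.frame(Eg = m$Eg, Eloc = m$Eloc, Lp = m$Lp, Cp = m$Cp,
             gamma = sw$gamma, lambda = sw$lambda, sigma = sw$sigma)
}
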