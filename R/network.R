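#' Social networks for behavior contagion
#'
#' The population is tied together by one undirected social network shared by
#' all three behavior dimensions. Construction follows the Watts-Strogatz
#' recipe: a regular ring lattice ([build_ring_lattice()]) whose edges are
#' then randomly rewired ([rewire()]), giving high clustering with short
#' average path lengths for small rewiring probabilities.
#'
#' A `social_network` stores the edge list as a two-column integer matrix of
#' 0-based node ids (node ids coincide with agent ids) plus the construction
#' parameters. Rewiring moves edge endpoints but never adds or removes edges,
#' so the edge count is invariant.
#'
#' @name social_network
NULL

new_social_network <- function(n_nodes, edges, mean_degree, rewire_prob) {
  storage.mode(edges) <- "integer"
  dimnames(edges) <- NULL
  structure(
    list(n_nodes = as.integer(n_nodes), edges = edges,
         mean_degree = as.integer(mean_degree),
         rewire_prob = rewire_prob),
    class = "social_network"
  )
}

#' Build a regular ring lattice
#'
#' Node `i` is connected to `i +/- 1, ..., i +/- k/2` (mod n): every node has
#' degree exactly `k` and the graph has `n * k / 2` edges.
#'
#' @param n Number of nodes.
#' @param k Even number of neighbors per node, `0 <= k < n`.
#' @return A `social_network`.
#' @export
build_ring_lattice <- function(n, k) {
  if (length(k) != 1 || k %% 2 != 0 || k < 0) {
    stop("k must be a nonnegative even integer", call. = FALSE)
  }
  if (k >= n) stop("k must be smaller than n", call. = FALSE)
  if (n == 0 || k == 0) {
    return(new_social_network(n, matrix(integer(0), ncol = 2), k, 0))
  }
  i <- rep(seq_len(n) - 1L, each = k / 2)
  off <- rep(seq_len(k / 2), times = n)
  edges <- cbind(i, (i + off) %% n)
  new_social_network(n, edges, k, 0)
}

#' Rewire lattice edges at random
#'
#' Each original lattice edge is independently rewired with probability
#' `beta`: one endpoint is kept and the other is replaced by a uniformly
#' random node that is neither the kept endpoint nor already its neighbor.
#' If no such node exists the edge is left in place. The edge count is
#' preserved and the graph stays simple.
#'
#' @param net A `social_network` (typically a fresh ring lattice).
#' @param beta Rewiring probability in \[0, 1\].
#' @return A rewired `social_network`.
#' @export
rewire <- function(net, beta) {
  stopifnot(inherits(net, "social_network"))
  if (beta < 0 || beta > 1) {
    stop("beta must be a probability in [0, 1]", call. = FALSE)
  }
  n <- net$n_nodes
  edges <- net$edges
  if (beta == 0 || nrow(edges) == 0) {
    net$rewire_prob <- beta
    return(net)
  }
  # adjacency as an environment-free list of integer vectors (0-based ids)
  adj <- vector("list", n)
  for (e in seq_len(nrow(edges))) {
    u <- edges[e, 1]; v <- edges[e, 2]
    adj[[u + 1L]] <- c(adj[[u + 1L]], v)
    adj[[v + 1L]] <- c(adj[[v + 1L]], u)
  }
  do_rewire <- stats::runif(nrow(edges)) < beta
  for (e in which(do_rewire)) {
    keep <- edges[e, 1]; old <- edges[e, 2]
    excluded <- c(keep, adj[[keep + 1L]])
    pool_size <- n - length(unique(excluded))
    if (pool_size <= 0) next
    # draw until the target is admissible; pool is large for sparse graphs
    repeat {
      cand <- sample.int(n, 1L) - 1L
      if (cand != keep && !(cand %in% adj[[keep + 1L]])) break
    }
    edges[e, 2] <- cand
    adj[[keep + 1L]] <- c(setdiff(adj[[keep + 1L]], old), cand)
    adj[[old + 1L]] <- setdiff(adj[[old + 1L]], keep)
    adj[[cand + 1L]] <- c(adj[[cand + 1L]], keep)
  }
  net$edges <- edges
  net$rewire_prob <- beta
  net
}

#' Build a Watts-Strogatz small-world network
#'
#' Convenience wrapper: [build_ring_lattice()] followed by [rewire()].
#'
#' @param n Number of nodes.
#' @param k Even mean degree.
#' @param beta Rewiring probability.
#' @return A `social_network`.
#' @export
build_small_world <- function(n, k = 6, beta = 0.1) {
  rewire(build_ring_lattice(n, k), beta)
}

#' @export
print.social_network <- function(x, ...) {
  cat("Social network: ", x$n_nodes, " nodes, ", nrow(x$edges),
      " edges (k = ", x$mean_degree, ", beta = ", x$rewire_prob, ")\n",
      sep = "")
  invisible(x)
}

node_degrees <- function(net) {
  tabulate(c(net$edges[, 1], net$edges[, 2]) + 1L, nbins = net$n_nodes)
}

#' Count behavior signals received by each agent
#'
#' At the start of each simulated year every living agent sends a positive
#' signal to its neighbors if it is in the healthy state of the behavior
#' (not smoking / healthy diet / physically active) and a negative signal if
#' it is in the unhealthy state. Dead agents send nothing and receive
#' nothing.
#'
#' @param healthy Logical vector over all nodes: is the agent in the healthy
#'   state of this behavior?
#' @param alive Logical vector over all nodes.
#' @param net A `social_network` with `n_nodes == length(healthy)`.
#' @return A list with integer vectors `positive` (m) and `negative` (n),
#'   one entry per node; both zero for dead agents.
#' @export
count_signals <- function(healthy, alive, net) {
  stopifnot(inherits(net, "social_network"),
            length(healthy) == net$n_nodes,
            length(alive) == net$n_nodes)
  n <- net$n_nodes
  pos <- integer(n); neg <- integer(n)
  if (nrow(net$edges) > 0) {
    u <- net$edges[, 1] + 1L
    v <- net$edges[, 2] + 1L
    # a sender contributes only if alive; receivers accumulate per endpoint
    send_pos_u <- alive[u] & healthy[u]
    send_neg_u <- alive[u] & !healthy[u]
    send_pos_v <- alive[v] & healthy[v]
    send_neg_v <- alive[v] & !healthy[v]
    pos <- tabulate(c(v[send_pos_u], u[send_pos_v]), nbins = n)
    neg <- tabulate(c(v[send_neg_u], u[send_neg_v]), nbins = n)
    pos[!alive] <- 0L
    neg[!alive] <- 0L
  }
  list(positive = pos, negative = neg)
}

#' Write / read a network as a plain-text edge list
#'
#' One edge per line, two whitespace-separated 0-based integer node ids —
#' enough to replay a run exactly.
#'
#' @param net A `social_network`.
#' @param path File path.
#' @param n_nodes Node count on read (node ids alone cannot recover isolated
#'   trailing nodes); defaults to `max(id) + 1`.
#' @return `read_edgelist` returns a `social_network`.
#' @export
write_edgelist <- function(net, path) {
  utils::write.table(net$edges, path, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_edgelist
#' @export
read_edgelist <- function(path, n_nodes = NULL) {
  tab <- utils::read.table(path, header = FALSE,
                           colClasses = c("integer", "integer"))
  edges <- as.matrix(tab)
  dimnames(edges) <- NULL
  if (is.null(n_nodes)) n_nodes <- max(edges) + 1L
  deg <- tabulate(c(edges[, 1], edges[, 2]) + 1L, nbins = n_nodes)
  new_social_network(n_nodes, edges, round(mean(deg)), NA_real_)
}
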