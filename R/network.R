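#' Spatially embedded support networks
#'
#' A `spatial_network` is an undirected simple graph whose nodes carry a
#' fixed position on a spatial ring (`spatial_index`, 0-based). The ring
#' position — the node index in the regular lattice prior to rewiring —
#' determines which disasters hit a node; the edges determine whom it may ask
#' for support. Constructors: [ring_lattice()] (regular substrate),
#' [rewire_network()] (Watts-Strogatz rewiring), [powerlaw_network()].
#'
#' @param n number of nodes.
#' @param k even target mean degree: each node is linked to its `k/2` nearest
#'   ring neighbors on each side.
#' @return a `spatial_network`: list with `n`, `edges` (2-column integer
#'   matrix, 1-based node ids, `u < v`), `spatial_index` (integer vector,
#'   node ring positions `0..n-1`), `k`, `beta`, `generator`.
#' @examples
#' net <- ring_lattice(100, 4)
#' mean(network_degrees(net))  # 4
#' @export
ring_lattice <- function(n, k = 4L) {
  n <- as.integer(n); k <- as.integer(k)
  if (k %% 2L != 0L) stop("'k' must be even", call. = FALSE)
  if (n <= k) stop("'n' must exceed 'k'", call. = FALSE)
  u <- rep(seq_len(n), each = k %/% 2L)
  v <- (u - 1L + rep(seq_len(k %/% 2L), n)) %% n + 1L
  edges <- cbind(pmin(u, v), pmax(u, v))
  edges <- edges[order(edges[, 1L], edges[, 2L]), , drop = FALSE]
  new_spatial_network(n, edges, spatial_index = 0:(n - 1L),
                      k = k, beta = 0, generator = "ring")
}

new_spatial_network <- function(n, edges, spatial_index, k, beta, generator) {
  dimnames(edges) <- list(NULL, c("u", "v"))
  structure(list(n = as.integer(n), edges = edges,
                 spatial_index = as.integer(spatial_index),
                 k = k, beta = beta, generator = generator),
            class = "spatial_network")
}

#' Node degrees of a spatial network
#' @param net a `spatial_network`.
#' @return integer vector of degrees, one per node.
#' @export
network_degrees <- function(net) {
  tabulate(c(net$edges[, 1L], net$edges[, 2L]), nbins = net$n)
}

#' Adjacency list of a spatial network
#' @param net a `spatial_network`.
#' @return list of integer vectors; element `i` holds the neighbors of node `i`.
#' @export
adjacency_list <- function(net) {
  adj <- vector("list", net$n)
  for (i in seq_len(net$n)) adj[[i]] <- integer(0)
  for (e in seq_len(nrow(net$edges))) {
    u <- net$edges[e, 1L]; v <- net$edges[e, 2L]
    adj[[u]] <- c(adj[[u]], v)
    adj[[v]] <- c(adj[[v]], u)
  }
  adj
}

#' Watts-Strogatz rewiring of a ring lattice
#'
#' Each edge is independently selected with probability `beta`; a selected
#' edge keeps its first endpoint and has the other reattached to a uniformly
#' chosen node, rejecting self-loops and duplicate edges. Edge count and mean
#' degree are conserved; increasing `beta` increases the spatial heterogeneity
#' of the network.
#'
#' @param net a `spatial_network` (typically from [ring_lattice()]).
#' @param beta rewiring fraction in `[0, 1]`.
#' @return the rewired `spatial_network`.
#' @export
rewire_network <- function(net, beta) {
  stopifnot(inherits(net, "spatial_network"))
  if (beta < 0 || beta > 1) stop("'beta' must be in [0, 1]", call. = FALSE)
  if (beta == 0) {
    net$beta <- 0
    return(net)
  }
  n <- net$n
  edges <- net$edges
  adj <- matrix(FALSE, n, n)
  adj[edges] <- TRUE
  adj[edges[, c(2L, 1L)]] <- TRUE
  sel <- stats::runif(nrow(edges)) < beta
  for (e in which(sel)) {
    u <- edges[e, 1L]; v <- edges[e, 2L]
    if (sum(adj[u, ]) >= n - 1L) next   # u saturated, nothing to rewire to
    repeat {
      w <- sample.int(n, 1L)
      if (w != u && !adj[u, w]) break
    }
    adj[u, v] <- adj[v, u] <- FALSE
    adj[u, w] <- adj[w, u] <- TRUE
    edges[e, ] <- c(min(u, w), max(u, w))
  }
  edges <- edges[order(edges[, 1L], edges[, 2L]), , drop = FALSE]
  new_spatial_network(n, edges, net$spatial_index, net$k, beta,
                      generator = paste0(net$generator, "+rewire"))
}

#' Power-law degree-distribution network
#'
#' Draws a degree sequence from a discrete truncated power law
#' \eqn{P(d) \propto d^{-\gamma}}, rescales it to the requested mean degree,
#' and realizes it as a connected simple graph (Viger-Latapy construction).
#' Ring positions are assigned by a uniform random permutation, embedding the
#' network in the same disaster space as the ring-rewired networks.
#'
#' @param n number of nodes (at least 10).
#' @param mean_degree target mean degree.
#' @param exponent power-law exponent \eqn{\gamma} (default 2.5).
#' @param max_tries resampling attempts for infeasible degree sequences.
#' @return a `spatial_network`.
#' @export
powerlaw_network <- function(n, mean_degree = 4, exponent = 2.5,
                             max_tries = 100L) {
  if (n < 10) stop("'n' must be >= 10", call. = FALSE)
  d_max <- max(3L, as.integer(round(sqrt(n * mean_degree))))
  target_sum <- as.integer(round(n * mean_degree))
  if (target_sum %% 2L == 1L) target_sum <- target_sum + 1L
  for (try in seq_len(max_tries)) {
    base <- sample(seq_len(d_max), n, replace = TRUE,
                   prob = seq_len(d_max)^(-exponent))
    deg <- pmax(1L, pmin(n - 1L, as.integer(round(base * mean_degree / mean(base)))))
    # nudge individual degrees to hit the (even) target sum exactly
    guard <- 0L
    while (sum(deg) != target_sum && guard < 10L * n) {
      i <- sample.int(n, 1L)
      if (sum(deg) < target_sum && deg[i] < n - 1L) deg[i] <- deg[i] + 1L
      else if (sum(deg) > target_sum && deg[i] > 1L) deg[i] <- deg[i] - 1L
      guard <- guard + 1L
    }
    g <- tryCatch(igraph::sample_degseq(deg, method = "vl"),
                  error = function(e) NULL)
    if (!is.null(g)) {
      el <- igraph::as_edgelist(g, names = FALSE)
      edges <- cbind(pmin(el[, 1L], el[, 2L]), pmax(el[, 1L], el[, 2L]))
      edges <- edges[order(edges[, 1L], edges[, 2L]), , drop = FALSE]
      return(new_spatial_network(n, edges, spatial_index = sample(n) - 1L,
                                 k = mean_degree, beta = NA_real_,
                                 generator = "powerlaw"))
    }
  }
  stop("could not realize a power-law degree sequence after ", max_tries,
       " attempts", call. = FALSE)
}

#' Degree-preserving edge randomization
#'
#' Randomizes an edge set by repeated double-edge swaps, preserving every
#' node's degree (in- and out-degree for directed graphs) while destroying
#' all other structure. Swaps that would introduce self-loops or duplicate
#' edges are rejected. Used to build the null ensemble against which
#' flow-network clustering and cycle counts are compared.
#'
#' @param edges 2-column integer matrix; rows are edges (`from`, `to` for
#'   directed input; unordered pairs otherwise).
#' @param directed logical; are the edges directed?
#' @param n_swaps number of attempted swaps (default `10 * nrow(edges)`).
#' @return the randomized edge matrix, with attribute `n_success` giving the
#'   number of accepted swaps. If fewer than `n_swaps / 100` swaps succeed a
#'   warning is issued and the best effort is returned.
#' @export
degree_preserving_shuffle <- function(edges, directed = FALSE,
                                      n_swaps = NULL) {
  edges <- as.matrix(edges)
  m <- nrow(edges)
  if (m < 2L) {
    attr(edges, "n_success") <- 0L
    return(edges)
  }
  if (is.null(n_swaps)) n_swaps <- 10L * m
  n <- max(edges)
  has <- new.env(hash = TRUE, size = 4L * m)
  key <- function(a, b) {
    if (!directed && a > b) paste0(b, "_", a) else paste0(a, "_", b)
  }
  for (e in seq_len(m)) assign(key(edges[e, 1L], edges[e, 2L]), TRUE, has)
  ok_new <- function(a, b) {
    a != b && !exists(key(a, b), envir = has, inherits = FALSE)
  }
  succ <- 0L
  for (s in seq_len(n_swaps)) {
    ij <- sample.int(m, 2L)
    a <- edges[ij[1L], 1L]; b <- edges[ij[1L], 2L]
    c_ <- edges[ij[2L], 1L]; d <- edges[ij[2L], 2L]
    if (!directed && stats::runif(1) < 0.5) { tmp <- c_; c_ <- d; d <- tmp }
    # propose a-d and c-b: preserves all degrees (out/in for directed)
    if (!ok_new(a, d) || !ok_new(c_, b)) next
    rm(list = c(key(a, b), key(c_, d)), envir = has)
    if (exists(key(a, d), has, inherits = FALSE) ||
        exists(key(c_, b), has, inherits = FALSE)) {
      # the two removed edges shared a proposed edge; restore and skip
      assign(key(a, b), TRUE, has); assign(key(c_, d), TRUE, has)
      next
    }
    assign(key(a, d), TRUE, has); assign(key(c_, b), TRUE, has)
    edges[ij[1L], ] <- c(a, d)
    edges[ij[2L], ] <- c(c_, b)
    succ <- succ + 1L
  }
  if (succ < n_swaps / 100) {
    warning("degree-preserving shuffle accepted only ", succ, " of ",
            n_swaps, " attempted swaps", call. = FALSE)
  }
  if (!directed) edges <- cbind(pmin(edges[, 1L], edges[, 2L]),
                                pmax(edges[, 1L], edges[, 2L]))
  dimnames(edges) <- NULL
  attr(edges, "n_success") <- succ
  edges
}

#' @export
print.spatial_network <- function(x, ...) {
  cat(sprintf("Spatial support network: %d nodes, %d edges (%s", x$n,
              nrow(x$edges), x$generator))
  if (!is.na(x$beta)) cat(sprintf(", beta = %g", x$beta))
  cat(")\n")
  cat(sprintf("  mean degree %.2f\n", mean(network_degrees(x))))
  invisible(x)
}

#' Convert a spatial network to an igraph graph
#' @param net a `spatial_network`.
#' @return an undirected `igraph` graph with `n` vertices.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "spatial_network"))
  g <- igraph::graph_from_edgelist(net$edges, directed = FALSE)
  if (igraph::vcount(g) < net$n) {
    g <- igraph::add_vertices(g, net$n - igraph::vcount(g))
  }
  g
}

#' Write a network edge list to CSV + JSON sidecar
#'
#' @param net a `spatial_network`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_network <- function(net, dir) {
  stopifnot(inherits(net, "spatial_network"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(as.data.frame(net$edges), file.path(dir, "edges.csv"),
                   row.names = FALSE)
  meta <- list(n = net$n, k = net$k, beta = net$beta,
               generator = net$generator,
               spatial_index = net$spatial_index)
  jsonlite::write_json(meta, file.path(dir, "network.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}
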