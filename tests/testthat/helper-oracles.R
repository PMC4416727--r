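# Independent oracles used to cross-check the graph metrics, plus small
# fixture builders. Deliberately naive implementations.

# all-pairs shortest paths on an undirected edge list via breadth-first search
bfs_distances <- function(n, edges) {
  adj <- vector("list", n)
  for (i in seq_len(n)) adj[[i]] <- integer(0)
  for (e in seq_len(nrow(edges))) {
    u <- edges[e, 1L]; v <- edges[e, 2L]
    adj[[u]] <- c(adj[[u]], v); adj[[v]] <- c(adj[[v]], u)
  }
  d <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    d[s, s] <- 0
    queue <- s
    while (length(queue)) {
      u <- queue[1]; queue <- queue[-1]
      for (w in adj[[u]]) {
        if (is.infinite(d[s, w])) {
          d[s, w] <- d[s, u] + 1
          queue <- c(queue, w)
        }
      }
    }
  }
  d
}

# mean local clustering by explicit triangle census (0 for degree < 2)
census_clustering <- function(n, edges, vids) {
  adj <- matrix(FALSE, n, n)
  for (e in seq_len(nrow(edges))) {
    adj[edges[e, 1L], edges[e, 2L]] <- TRUE
    adj[edges[e, 2L], edges[e, 1L]] <- TRUE
  }
  cc <- vapply(vids, function(v) {
    nb <- which(adj[v, ])
    k <- length(nb)
    if (k < 2) return(0)
    tri <- 0L
    for (a in seq_len(k - 1)) {
      for (b in (a + 1):k) {
        if (adj[nb[a], nb[b]]) tri <- tri + 1L
      }
    }
    2 * tri / (k * (k - 1))
  }, numeric(1))
  mean(cc)
}

# exhaustive elementary-circuit count of a small digraph: for every vertex
# subset, count Hamiltonian directed cycles of the induced subgraph by
# enumerating permutations anchored at the subset's smallest vertex
bruteforce_cycle_count <- function(n, edges) {
  has <- matrix(FALSE, n, n)
  for (e in seq_len(nrow(edges))) has[edges[e, 1L], edges[e, 2L]] <- TRUE
  count <- 0L
  verts <- seq_len(n)
  for (size in 2:n) {
    combs <- utils::combn(verts, size)
    for (ci in seq_len(ncol(combs))) {
      s <- combs[, ci]
      anchor <- s[1]
      rest <- s[-1]
      perms <- if (length(rest) == 1) matrix(rest, 1, 1) else {
        pm <- NULL
        gen <- function(prefix, left) {
          if (!length(left)) { pm <<- rbind(pm, prefix); return(invisible()) }
          for (x in left) gen(c(prefix, x), setdiff(left, x))
        }
        gen(integer(0), rest)
        pm
      }
      for (pi in seq_len(nrow(perms))) {
        cyc <- c(anchor, perms[pi, ], anchor)
        ok <- TRUE
        for (j in seq_len(length(cyc) - 1)) {
          if (!has[cyc[j], cyc[j + 1]]) { ok <- FALSE; break }
        }
        if (ok) count <- count + 1L
      }
    }
  }
  count
}

random_digraph_edges <- function(n, p) {
  all <- expand.grid(from = seq_len(n), to = seq_len(n))
  all <- all[all$from != all$to, ]
  pick <- all[stats::runif(nrow(all)) < p, , drop = FALSE]
  as.matrix(pick)
}

flow_from_edges <- function(n, edges) {
  gifts <- data.frame(year = rep(1L, nrow(edges)),
                      giver = edges[, 1L], receiver = edges[, 2L],
                      amount = rep(1, nrow(edges)))
  build_flow_network(gifts, n)
}

# disaster field with no events at all (quiet world)
empty_field <- function(x_extent = 100L, t_extent = 50L) {
  f <- generate_disaster_field("none", n_total = 1, m_clusters = 1,
                               x_extent = x_extent, t_extent = t_extent)
  f$occupancy[] <- 0L
  f$events <- f$events[0, , drop = FALSE]
  f
}

# field with prescribed event cells (matrix of year, location rows)
field_with_events <- function(cells, x_extent = 100L, t_extent = 50L) {
  f <- empty_field(x_extent, t_extent)
  if (nrow(cells)) {
    f$occupancy[cbind(cells[, "location"] + 1L, cells[, "year"])] <- 1L
    f$events <- cells
  }
  f
}
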