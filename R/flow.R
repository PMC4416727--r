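#' Build the activated cattle-flow network
#'
#' Condenses a gift log into the directed *activated* network: one edge per
#' ordered (giver, receiver) pair with at least one gift over the run,
#' weighted by the number of gift events. The flow network is the subgraph of
#' the potential support network that disasters actually evoked.
#'
#' @param gifts data frame with columns `year`, `giver`, `receiver`,
#'   `amount` (as produced by [run_simulation()]).
#' @param n node count of the potential network.
#' @param status optional logical vector: alive flags at the horizon.
#' @return an object of class `flow_network`: list with `n`, `edges`
#'   (2-column matrix `giver`, `receiver`), `weight` (gift-event counts) and
#'   `status`.
#' @export
build_flow_network <- function(gifts, n, status = NULL) {
  stopifnot(is.data.frame(gifts), n >= 1)
  if (nrow(gifts) > 0 && (max(gifts$giver, gifts$receiver) > n ||
                          min(gifts$giver, gifts$receiver) < 1)) {
    stop("gift log references nodes outside 1..n", call. = FALSE)
  }
  if (nrow(gifts) == 0) {
    edges <- matrix(integer(0), 0, 2,
                    dimnames = list(NULL, c("giver", "receiver")))
    weight <- integer(0)
  } else {
    key <- paste(gifts$giver, gifts$receiver)
    tab <- table(key)
    parts <- do.call(rbind, strsplit(names(tab), " ", fixed = TRUE))
    edges <- cbind(giver = as.integer(parts[, 1L]),
                   receiver = as.integer(parts[, 2L]))
    weight <- as.integer(tab)
    o <- order(edges[, 1L], edges[, 2L])
    edges <- edges[o, , drop = FALSE]
    weight <- weight[o]
  }
  structure(list(n = as.integer(n), edges = edges, weight = weight,
                 status = status),
            class = "flow_network")
}

#' @export
print.flow_network <- function(x, ...) {
  cat(sprintf("Cattle-flow network: %d nodes, %d directed edges (%d gifts)\n",
              x$n, nrow(x$edges), sum(x$weight)))
  invisible(x)
}

# igraph view of the flow network (directed), all n vertices present
.flow_igraph <- function(flow, directed = TRUE) {
  g <- igraph::make_empty_graph(n = flow$n, directed = directed)
  if (nrow(flow$edges) > 0) {
    g <- igraph::add_edges(g, t(flow$edges))
    if (!directed) g <- igraph::simplify(g)
  }
  g
}

.non_isolated <- function(flow) {
  sort(unique(as.integer(flow$edges)))
}

#' Average shortest-path length of a flow network
#'
#' Mean shortest-path distance over all connected ordered pairs of
#' non-isolated nodes, on the undirected projection. Isolated nodes are
#' ignored; pairs in different components do not contribute. Returns 0 for an
#' edgeless network.
#'
#' @param flow a `flow_network`.
#' @return the average path length.
#' @export
average_path_length <- function(flow) {
  stopifnot(inherits(flow, "flow_network"))
  keep <- .non_isolated(flow)
  if (length(keep) < 2) return(0)
  g <- igraph::induced_subgraph(.flow_igraph(flow, directed = FALSE), keep)
  d <- igraph::distances(g)
  d <- d[upper.tri(d)]
  d <- d[is.finite(d)]
  if (length(d) == 0) return(0)
  mean(d)
}

#' Average degree of a flow network
#'
#' Mean total degree (in-degree plus out-degree) over non-isolated nodes.
#'
#' @param flow a `flow_network`.
#' @return the average degree (0 for an edgeless network).
#' @export
average_degree <- function(flow) {
  stopifnot(inherits(flow, "flow_network"))
  keep <- .non_isolated(flow)
  if (length(keep) == 0) return(0)
  2 * nrow(flow$edges) / length(keep)
}

#' Clustering coefficient of a flow network
#'
#' Mean local clustering coefficient of the undirected projection, averaged
#' over non-isolated nodes. Nodes of degree one have local clustering 0.
#'
#' @param flow a `flow_network`.
#' @return the average local clustering coefficient.
#' @export
clustering_coefficient <- function(flow) {
  stopifnot(inherits(flow, "flow_network"))
  keep <- .non_isolated(flow)
  if (length(keep) == 0) return(0)
  g <- .flow_igraph(flow, directed = FALSE)
  cc <- igraph::transitivity(g, type = "local", vids = keep)
  cc[is.na(cc)] <- 0
  mean(cc)
}

# Johnson-style enumeration of elementary circuits, with a count cap.
# adj: 0-based adjacency list of the directed graph.
.count_simple_cycles <- function(n, edges, max_cycles) {
  if (nrow(edges) == 0) return(list(count = 0L, overflow = FALSE))
  adj <- vector("list", n)
  for (i in seq_len(n)) adj[[i]] <- integer(0)
  for (e in seq_len(nrow(edges))) {
    adj[[edges[e, 1L]]] <- c(adj[[edges[e, 1L]]], edges[e, 2L])
  }
  count <- 0L
  overflow <- FALSE
  blocked <- logical(n)
  blist <- vector("list", n)
  on_stack <- logical(n)

  unblock <- function(v) {
    blocked[v] <<- FALSE
    for (w in blist[[v]]) {
      if (blocked[w]) unblock(w)
    }
    blist[[v]] <<- integer(0)
  }

  s <- 0L
  circuit <- function(v) {
    found <- FALSE
    blocked[v] <<- TRUE
    for (w in adj[[v]]) {
      if (overflow) break
      if (w < s) next  # restrict to the subgraph induced by nodes >= s
      if (w == s) {
        count <<- count + 1L
        if (count >= max_cycles) overflow <<- TRUE
        found <- TRUE
      } else if (!blocked[w]) {
        if (circuit(w)) found <- TRUE
      }
    }
    if (found) {
      unblock(v)
    } else {
      for (w in adj[[v]]) {
        if (w < s) next
        if (!(v %in% blist[[w]])) blist[[w]] <<- c(blist[[w]], v)
      }
    }
    found
  }

  for (start in seq_len(n)) {
    if (overflow) break
    s <- start
    blocked[] <- FALSE
    for (i in seq_len(n)) blist[[i]] <- integer(0)
    circuit(start)
  }
  list(count = count, overflow = overflow)
}

#' Count cycles in a flow network
#'
#' Two notions of "number of cycles" are supported. `"simple_directed"`
#' (the default) enumerates elementary circuits of the directed graph
#' (Johnson's algorithm) and counts them, aborting at `max_cycles` circuits to
#' guard against combinatorial blow-up on dense randomized graphs.
#' `"cyclomatic"` returns the cycle-space dimension
#' \eqn{|E| - |V| + c} of the undirected projection restricted to
#' non-isolated nodes (\eqn{c} = number of connected components).
#'
#' @param flow a `flow_network`.
#' @param method `"simple_directed"` or `"cyclomatic"`.
#' @param max_cycles enumeration cap (default `1e5`).
#' @return the cycle count; if the cap was hit, the count so far with
#'   attribute `overflow = TRUE`.
#' @export
count_cycles <- function(flow, method = c("simple_directed", "cyclomatic"),
                         max_cycles = 1e5) {
  stopifnot(inherits(flow, "flow_network"))
  method <- match.arg(method)
  if (method == "cyclomatic") {
    keep <- .non_isolated(flow)
    if (length(keep) == 0) return(0L)
    g <- igraph::induced_subgraph(.flow_igraph(flow, directed = FALSE), keep)
    return(igraph::ecount(g) - igraph::vcount(g) +
             igraph::components(g)$no)
  }
  res <- .count_simple_cycles(flow$n, flow$edges, max_cycles)
  out <- res$count
  if (res$overflow) attr(out, "overflow") <- TRUE
  out
}

#' Flow-network metrics with degree-preserving null models
#'
#' Computes the observed flow-network metrics (average path length, average
#' degree, clustering coefficient, cycle count) and the ensemble means of
#' clustering and cycle count over `reps` degree-preserving randomizations
#' ([degree_preserving_shuffle()] of the directed edge set, preserving in-
#' and out-degrees).
#'
#' @param flow a `flow_network`.
#' @param reps number of randomized networks (default 100).
#' @param method cycle-count method, see [count_cycles()].
#' @param max_cycles enumeration cap per network.
#' @return a list of class `flow_metrics`: `avg_path_length`, `avg_degree`,
#'   `clustering`, `n_cycles`, `null_clustering`, `null_cycles`.
#' @export
null_model_metrics <- function(flow, reps = 100L,
                               method = c("simple_directed", "cyclomatic"),
                               max_cycles = 1e5) {
  stopifnot(inherits(flow, "flow_network"), reps >= 1)
  method <- match.arg(method)
  null_cc <- numeric(reps)
  null_cyc <- numeric(reps)
  for (r in seq_len(reps)) {
    shuf <- degree_preserving_shuffle(flow$edges, directed = TRUE)
    nf <- structure(list(n = flow$n,
                         edges = cbind(giver = shuf[, 1L],
                                       receiver = shuf[, 2L]),
                         weight = rep(1L, nrow(shuf)), status = NULL),
                    class = "flow_network")
    null_cc[r] <- clustering_coefficient(nf)
    null_cyc[r] <- as.numeric(count_cycles(nf, method, max_cycles))
  }
  structure(list(
    avg_path_length = average_path_length(flow),
    avg_degree = average_degree(flow),
    clustering = clustering_coefficient(flow),
    n_cycles = as.numeric(count_cycles(flow, method, max_cycles)),
    null_clustering = mean(null_cc),
    null_cycles = mean(null_cyc)
  ), class = "flow_metrics")
}

#' @export
print.flow_metrics <- function(x, ...) {
  cat("Flow-network metrics (observed vs degree-preserving null):\n")
  cat(sprintf("  avg path length %.3f, avg degree %.3f\n",
              x$avg_path_length, x$avg_degree))
  cat(sprintf("  clustering %.4f (null %.4f)\n",
              x$clustering, x$null_clustering))
  cat(sprintf("  cycles %.1f (null %.1f)\n", x$n_cycles, x$null_cycles))
  invisible(x)
}

#' Check that every flow edge exists in the potential network
#'
#' @param flow a `flow_network`.
#' @param net the potential `spatial_network`.
#' @return `TRUE` if every activated edge connects nodes adjacent in the
#'   potential network.
#' @export
flow_edges_in_potential <- function(flow, net) {
  stopifnot(inherits(flow, "flow_network"), inherits(net, "spatial_network"))
  if (nrow(flow$edges) == 0) return(TRUE)
  pot <- paste(net$edges[, 1L], net$edges[, 2L])
  und <- paste(pmin(flow$edges[, 1L], flow$edges[, 2L]),
               pmax(flow$edges[, 1L], flow$edges[, 2L]))
  all(und %in% pot)
}

#' Write a flow network edge list to CSV
#'
#' Columns `giver,receiver,weight`.
#'
#' @param flow a `flow_network`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_flow_network <- function(flow, file) {
  stopifnot(inherits(flow, "flow_network"))
  df <- data.frame(giver = flow$edges[, 1L], receiver = flow$edges[, 2L],
                   weight = flow$weight)
  utils::write.csv(df, file, row.names = FALSE)
  invisible(file)
}
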