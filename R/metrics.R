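# Binary graph metrics and degree-preserving null-model normalization.
# Shortest paths, local clustering, and betweenness are computed through
# igraph; the Maslov-Sneppen rewiring and the normalization convention are
# implemented here.

.as_binary_adjacency <- function(adjacency) {
  A <- as.matrix(adjacency) > 0
  diag(A) <- FALSE
  if (!isTRUE(all(A == t(A)))) stop_("adjacency must be symmetric")
  storage.mode(A) <- "integer"
  A
}

.graph_from_adjacency <- function(A) {
  igraph::graph_from_adjacency_matrix(A, mode = "undirected", diag = FALSE)
}

#' Characteristic path length
#'
#' Mean number of steps on shortest paths between node pairs, the global
#' communication-capacity metric of a binary network. Shortest paths are
#' averaged over reachable (finite-distance) unordered pairs; the fraction
#' of unreachable pairs is reported alongside because degree-preserving
#' rewiring can disconnect a network.
#'
#' @param adjacency binary symmetric matrix (any positive entry is an edge).
#' @return Numeric path length with attribute \code{unreachable_fraction}.
#' @examples
#' characteristic_path_length(1 - diag(4))  # complete graph: 1
#' @export
characteristic_path_length <- function(adjacency) {
  A <- .as_binary_adjacency(adjacency)
  if (nrow(A) < 2L) stop_("need at least 2 nodes")
  if (sum(A) == 0L) stop_("graph has no edges: path length undefined")
  D <- igraph::distances(.graph_from_adjacency(A))
  d <- D[upper.tri(D)]
  finite <- is.finite(d)
  out <- mean(d[finite])
  attr(out, "unreachable_fraction") <- mean(!finite)
  out
}

#' Clustering coefficient
#'
#' For each node, the number of connections between its neighbors divided by
#' the number of possible connections between those neighbors (0 for nodes
#' with fewer than two neighbors), averaged across all nodes — the local
#' segregation metric of a binary network.
#'
#' @param adjacency binary symmetric matrix.
#' @return Mean clustering coefficient.
#' @examples
#' clustering_coefficient(matrix(c(0,1,1,1,0,1,1,1,0), 3))  # triangle: 1
#' @export
clustering_coefficient <- function(adjacency) {
  A <- .as_binary_adjacency(adjacency)
  if (nrow(A) < 3L) stop_("need at least 3 nodes")
  ci <- igraph::transitivity(.graph_from_adjacency(A), type = "local",
                             isolates = "zero")
  ci[is.nan(ci)] <- 0   # degree-1 nodes
  mean(ci)
}

#' Null-model configuration
#'
#' @param n_networks number of rewired reference networks (default 1000).
#' @param swaps_per_edge rewiring attempts per edge (default 10; attempts,
#'   not successful swaps, are counted).
#' @param seed integer seed.
#' @return A \code{"null_model_config"} list.
#' @export
null_model_config <- function(n_networks = 1000, swaps_per_edge = 10, seed = 1) {
  stopifnot(is_count(n_networks), is_count(swaps_per_edge))
  structure(list(n_networks = as.integer(n_networks),
                 swaps_per_edge = as.integer(swaps_per_edge),
                 seed = seed),
            class = "null_model_config")
}

#' Degree-preserving rewiring (Maslov-Sneppen)
#'
#' Randomizes a simple undirected graph by repeated double-edge swaps:
#' two edges (a,b), (c,d) are replaced by (a,d), (c,b) unless the swap would
#' create a self-loop or a multi-edge. Every node's degree is preserved
#' exactly. The attempt budget is \code{swaps_per_edge * n_edges} attempts
#' (rejected proposals count against the budget). Deterministic per seed.
#'
#' @param adjacency binary symmetric matrix.
#' @param config a \code{\link{null_model_config}} (its \code{swaps_per_edge}
#'   and \code{seed} are used).
#' @return Rewired binary adjacency matrix.
#' @export
rewire_degree_preserving <- function(adjacency, config = null_model_config()) {
  A <- .as_binary_adjacency(adjacency)
  edges <- which(upper.tri(A) & A == 1L, arr.ind = TRUE)
  m <- nrow(edges)
  if (m < 2L) return(A)
  with_seed(config$seed, .ms_rewire(A, edges, config$swaps_per_edge * m))
}

# Swap loop on a logical adjacency + edge matrix; called inside a seeded
# RNG context.
.ms_rewire <- function(A, edges, n_attempts) {
  m <- nrow(edges)
  e1s <- sample.int(m, n_attempts, replace = TRUE)
  e2s <- sample.int(m, n_attempts, replace = TRUE)
  flips <- sample.int(2L, n_attempts, replace = TRUE) == 1L
  for (t in seq_len(n_attempts)) {
    i <- e1s[t]; j <- e2s[t]
    if (i == j) next
    a <- edges[i, 1]; b <- edges[i, 2]
    c_ <- edges[j, 1]; d <- edges[j, 2]
    if (flips[t]) { tmp <- c_; c_ <- d; d <- tmp }
    # proposed: (a,d) and (c_,b)
    if (a == d || c_ == b) next
    if (A[a, d] == 1L || A[c_, b] == 1L) next
    A[a, b] <- A[b, a] <- 0L
    A[c_, d] <- A[d, c_] <- 0L
    A[a, d] <- A[d, a] <- 1L
    A[c_, b] <- A[b, c_] <- 1L
    edges[i, ] <- c(min(a, d), max(a, d))
    edges[j, ] <- c(min(c_, b), max(c_, b))
  }
  A
}

#' Normalize a metric against a null distribution
#'
#' Normalized value is the ratio of the raw metric to the mean of its values
#' on the rewired reference networks (the conventional small-world-style
#' normalization); the null mean and SD are recorded.
#'
#' @param raw observed metric value.
#' @param nulls numeric vector of metric values on reference networks.
#' @param metric metric name for the record.
#' @param scope scope label (e.g. hemisphere).
#' @return A \code{"metric_result"} list: \code{raw}, \code{null_mean},
#'   \code{null_sd}, \code{normalized}, \code{metric}, \code{scope},
#'   \code{n_nulls}.
#' @export
normalize_metric <- function(raw, nulls, metric = "metric", scope = "whole") {
  stopifnot(is.numeric(raw), length(raw) == 1L, length(nulls) >= 1L)
  mu <- mean(nulls)
  if (mu == 0) stop_("null mean is zero: ratio normalization undefined")
  structure(list(raw = as.numeric(raw), null_mean = mu,
                 null_sd = stats::sd(nulls) %||% 0,
                 normalized = as.numeric(raw) / mu,
                 metric = metric, scope = scope, n_nulls = length(nulls)),
            class = "metric_result")
}

#' @export
print.metric_result <- function(x, ...) {
  cat(sprintf("%s (%s): raw %.4f, null %.4f +/- %.4f (n=%d), normalized %.4f\n",
              x$metric, x$scope, x$raw, x$null_mean,
              ifelse(is.na(x$null_sd), 0, x$null_sd), x$n_nulls, x$normalized))
  invisible(x)
}

#' Normalized path length and clustering of a binary network
#'
#' Computes characteristic path length and clustering coefficient and
#' normalizes each by its mean over an ensemble of degree-preserved rewired
#' reference networks.
#'
#' @param adjacency binary symmetric matrix.
#' @param config a \code{\link{null_model_config}}; reference network
#'   \code{k} is rewired under seed \code{seed + k}.
#' @param scope scope label carried into the results.
#' @return List with \code{"metric_result"} entries \code{path_length} and
#'   \code{clustering}.
#' @export
normalized_graph_metrics <- function(adjacency, config = null_model_config(),
                                     scope = "whole") {
  A <- .as_binary_adjacency(adjacency)
  raw_cpl <- characteristic_path_length(A)
  raw_cc <- clustering_coefficient(A)
  null_cpl <- numeric(config$n_networks)
  null_cc <- numeric(config$n_networks)
  for (k in seq_len(config$n_networks)) {
    cfg_k <- config
    cfg_k$seed <- derive_seed(config$seed, paste0("null", k))
    R <- rewire_degree_preserving(A, cfg_k)
    null_cpl[k] <- as.numeric(characteristic_path_length(R))
    null_cc[k] <- clustering_coefficient(R)
  }
  list(path_length = normalize_metric(as.numeric(raw_cpl), null_cpl,
                                      "characteristic_path_length", scope),
       clustering = normalize_metric(raw_cc, null_cc,
                                     "clustering_coefficient", scope))
}

#' Hub metrics: degree, betweenness, rich-club curve
#'
#' Degree per node; unnormalized shortest-path betweenness per node (paths
#' with equal length split the count evenly); and the rich-club curve
#' \eqn{\phi(k)}, the density of the subgraph restricted to nodes of degree
#' greater than k.
#'
#' @param adjacency binary symmetric matrix.
#' @return List with \code{degree}, \code{betweenness}, and a
#'   \code{rich_club} data.frame (columns \code{k}, \code{n_nodes},
#'   \code{phi}).
#' @export
hub_metrics <- function(adjacency) {
  A <- .as_binary_adjacency(adjacency)
  g <- .graph_from_adjacency(A)
  deg <- colSums(A)
  btw <- igraph::betweenness(g, directed = FALSE, normalized = FALSE)
  ks <- sort(unique(deg))
  ks <- ks[ks < max(deg)]
  rc <- do.call(rbind, lapply(ks, function(k) {
    keep <- which(deg > k)
    phi <- if (length(keep) >= 2L) {
      sub <- A[keep, keep, drop = FALSE]
      sum(sub[upper.tri(sub)]) / (length(keep) * (length(keep) - 1) / 2)
    } else NA_real_
    data.frame(k = k, n_nodes = length(keep), phi = phi)
  }))
  list(degree = deg, betweenness = btw,
       rich_club = rc %||% data.frame(k = integer(), n_nodes = integer(),
                                      phi = numeric()))
}

#' Long-format metric table for a set of species
#'
#' Computes normalized path length and clustering per hemisphere for each
#' connectome and returns the tab-separable long-format table used by the
#' pipeline reports.
#'
#' @param conns list of \code{"connectome"} objects (typically
#'   density-equalized first; see \code{\link{equalize_density}}).
#' @param config a \code{\link{null_model_config}}; per-species seeds are
#'   derived from it.
#' @return Data.frame: species, hemisphere, metric, raw, null_mean, null_sd,
#'   normalized, n_nulls, seed.
#' @export
metric_table <- function(conns, config = null_model_config()) {
  rows <- list()
  for (cn in conns) {
    for (h in c("left", "right")) {
      idx <- hemisphere_indices(cn, h)
      cfg <- config
      cfg$seed <- derive_seed(config$seed, paste0(cn$species, "_", h))
      res <- normalized_graph_metrics(cn$W[idx, idx], cfg, scope = h)
      for (r in res) {
        rows[[length(rows) + 1L]] <- data.frame(
          species = cn$species, hemisphere = h, metric = r$metric,
          raw = r$raw, null_mean = r$null_mean, null_sd = r$null_sd,
          normalized = r$normalized, n_nulls = r$n_nulls, seed = cfg$seed)
      }
    }
  }
  do.call(rbind, rows)
}
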