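# Independent brute-force oracles and small fixture builders used across the
# suite. These stay deliberately naive (closed forms, exhaustive enumeration)
# so they share no code path with the package implementations they check.

# Closed-form OLS with intercept.
ols_oracle <- function(y, x) {
  X <- cbind(1, x)
  XtXi <- solve(t(X) %*% X)
  beta <- drop(XtXi %*% t(X) %*% y)
  res <- y - drop(X %*% beta)
  s2 <- sum(res^2) / (length(y) - 2)
  list(coef = beta, se = sqrt(diag(XtXi) * s2))
}

# All-pairs shortest path lengths by Floyd-Warshall.
bf_distances <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  D[A > 0] <- 1
  diag(D) <- 0
  for (k in 1:n) for (i in 1:n) for (j in 1:n) {
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  }
  D
}

bf_path_length <- function(A) {
  D <- bf_distances(A)
  d <- D[upper.tri(D)]
  mean(d[is.finite(d)])
}

# Per-node neighbor-pair enumeration.
bf_clustering <- function(A) {
  n <- nrow(A)
  mean(vapply(1:n, function(i) {
    nb <- which(A[i, ] > 0)
    k <- length(nb)
    if (k < 2) return(0)
    sub <- A[nb, nb, drop = FALSE]
    sum(sub[upper.tri(sub)] > 0) / (k * (k - 1) / 2)
  }, numeric(1)))
}

# Erdos-Renyi adjacency, guaranteed symmetric zero-diagonal.
random_graph <- function(n, p, seed) {
  set.seed(seed)
  A <- matrix(0L, n, n)
  ut <- which(upper.tri(A))
  A[ut[runif(length(ut)) < p]] <- 1L
  A + t(A)
}

# Small named graphs.
complete_graph <- function(n) {
  A <- matrix(1L, n, n); diag(A) <- 0L; A
}
path_graph <- function(n) {
  A <- matrix(0L, n, n)
  for (i in seq_len(n - 1)) A[i, i + 1] <- A[i + 1, i] <- 1L
  A
}
cycle_graph <- function(n) {
  A <- path_graph(n)
  A[1, n] <- A[n, 1] <- 1L
  A
}
star_graph <- function(n) {   # node 1 is the hub
  A <- matrix(0L, n, n)
  A[1, 2:n] <- A[2:n, 1] <- 1L
  A
}

# Two-hemisphere toy connectome from left/right intrahemispheric weight
# matrices; homolog pairing is L_k <-> R_k. Region centroids sit on two
# parallel AP lines so all connection lengths are positive and distinct.
toy_connectome <- function(WL, WR = WL, ap = 100, species = "toy") {
  n <- nrow(WL)
  regions <- data.frame(
    region = c(paste0("L", 1:n), paste0("R", 1:n)),
    hemisphere = rep(c("left", "right"), each = n),
    x = rep(c(-10, 10), each = n),
    y = rep(seq(1, ap - 1, length.out = n), 2),
    z = 0)
  W <- matrix(0, 2 * n, 2 * n)
  W[1:n, 1:n] <- WL
  W[n + 1:n, n + 1:n] <- WR
  Dm <- as.matrix(dist(regions[, c("x", "y", "z")]))
  L <- ifelse(W > 0, Dm, 0)
  connectome(regions, W, L, ap_extent_mm = ap, species = species,
             homolog = c(n + 1:n, 1:n))
}

# Symmetric intrahemispheric weight matrix from an edge list given as
# rbind(c(i, j, w), ...).
wmat <- function(n, edges) {
  W <- matrix(0, n, n)
  for (r in seq_len(nrow(edges))) {
    W[edges[r, 1], edges[r, 2]] <- W[edges[r, 2], edges[r, 1]] <- edges[r, 3]
  }
  W
}
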