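# Per-species two-hemisphere connectomes: construction from streamline
# endpoint tables, density, density equalization across species, and
# brain-size-normalized connection-length distributions.

#' Construct a connectome object
#'
#' A connectome is a region-by-region weighted graph for one species, with
#' streamline counts (NOS) as connection strength and mean fiber length (mm)
#' per connection. Regions 1..R are left-hemisphere, R+1..2R right-hemisphere
#' for the standard layout; \code{homolog} maps each region to its
#' contralateral spatial homolog.
#'
#' @param regions data.frame with columns \code{region} (unique id),
#'   \code{hemisphere} ("left"/"right"), \code{x}, \code{y}, \code{z}
#'   (centroid, mm).
#' @param W square numeric matrix of connection weights (NOS), symmetric,
#'   zero diagonal.
#' @param L square numeric matrix of connection lengths (mm); must be
#'   positive wherever \code{W > 0}.
#' @param ap_extent_mm anterior-posterior extent of the brain (mm).
#' @param species species identifier.
#' @param homolog integer vector: \code{homolog[i]} is the region index of
#'   the contralateral homolog of region \code{i}.
#' @return An object of class \code{"connectome"}.
#' @export
connectome <- function(regions, W, L, ap_extent_mm, species = "species",
                       homolog = NULL) {
  W <- as.matrix(W); L <- as.matrix(L)
  n <- nrow(regions)
  stopifnot(nrow(W) == n, ncol(W) == n, nrow(L) == n, ncol(L) == n)
  if (anyDuplicated(regions$region)) stop_("region ids must be unique")
  if (!isTRUE(all.equal(W, t(W)))) stop_("weight matrix must be symmetric")
  if (!isTRUE(all.equal(L, t(L)))) stop_("length matrix must be symmetric")
  if (any(diag(W) != 0) || any(diag(L) != 0)) stop_("diagonals must be zero")
  if (any(W < 0)) stop_("weights must be non-negative")
  if (any(L[W > 0] <= 0)) stop_("connection lengths must be positive where W > 0")
  if (is.null(homolog)) {
    homolog <- .default_homolog(regions)
  }
  structure(list(regions = regions, W = W, L = L,
                 ap_extent = ap_extent_mm, species = species,
                 homolog = as.integer(homolog)),
            class = "connectome")
}

# Standard layout pairing: left region k <-> right region with the same
# within-hemisphere position.
.default_homolog <- function(regions) {
  left <- which(regions$hemisphere == "left")
  right <- which(regions$hemisphere == "right")
  if (length(left) != length(right)) return(rep(NA_integer_, nrow(regions)))
  h <- integer(nrow(regions))
  h[left] <- right
  h[right] <- left
  h
}

#' @export
print.connectome <- function(x, ...) {
  nL <- sum(x$regions$hemisphere == "left")
  cat("connectome '", x$species, "': ", nrow(x$regions), " regions (",
      nL, " left), ", sum(x$W > 0) / 2, " connections, AP extent ",
      format(x$ap_extent, digits = 5), " mm\n", sep = "")
  invisible(x)
}

hemisphere_indices <- function(conn, scope = c("left", "right", "whole")) {
  scope <- match.arg(scope)
  switch(scope,
         left = which(conn$regions$hemisphere == "left"),
         right = which(conn$regions$hemisphere == "right"),
         whole = seq_len(nrow(conn$regions)))
}

#' Build a connectome from a streamline endpoint table
#'
#' Connection strength between two regions is the number of streamlines
#' (NOS) with one endpoint in each; connection length is the mean arclength
#' of those streamlines (the average physical distance traveled by the
#' reconstructed fibers). Streamlines with an unassigned endpoint, or with
#' both endpoints in the same region, are dropped and tallied in the discard
#' log.
#'
#' @param streamlines data.frame with columns \code{region_a},
#'   \code{region_b} (region ids, or \code{NA}/\code{"unassigned"}), and
#'   \code{length_mm} (> 0).
#' @param regions region table as for \code{\link{connectome}}.
#' @param ap_extent_mm anterior-posterior extent (mm).
#' @param species species id.
#' @return A \code{"connectome"} with an attached \code{discard_log}
#'   attribute: counts of streamlines dropped as \code{unassigned} or
#'   \code{intra_region}, plus \code{counted}.
#' @examples
#' regs <- data.frame(region = c("A", "B"), hemisphere = "left",
#'                    x = c(0, 10), y = 0, z = 0)
#' st <- data.frame(region_a = "A", region_b = "B", length_mm = c(10, 20, 30))
#' cn <- streamlines_to_connectome(st, regs, ap_extent_mm = 50)
#' @export
streamlines_to_connectome <- function(streamlines, regions, ap_extent_mm,
                                      species = "species") {
  n <- nrow(regions)
  ids <- as.character(regions$region)
  W <- matrix(0, n, n, dimnames = list(ids, ids))
  L <- matrix(0, n, n, dimnames = list(ids, ids))
  discard <- c(unassigned = 0L, intra_region = 0L, counted = 0L)
  if (nrow(streamlines) == 0L) {
    warning("empty streamline table: returning an all-zero connectome")
  } else {
    if (any(streamlines$length_mm <= 0, na.rm = TRUE)) {
      stop_("streamline arclengths must be positive")
    }
    a <- match(as.character(streamlines$region_a), ids)
    b <- match(as.character(streamlines$region_b), ids)
    unass <- is.na(a) | is.na(b)
    intra <- !unass & a == b
    keep <- !unass & !intra
    discard["unassigned"] <- sum(unass)
    discard["intra_region"] <- sum(intra)
    discard["counted"] <- sum(keep)
    if (any(keep)) {
      i <- pmin(a[keep], b[keep]); j <- pmax(a[keep], b[keep])
      key <- (i - 1L) * n + j
      cnt <- tapply(rep(1L, length(key)), key, sum)
      len <- tapply(streamlines$length_mm[keep], key, mean)
      kk <- as.integer(names(cnt))
      ii <- (kk - 1L) %/% n + 1L; jj <- (kk - 1L) %% n + 1L
      W[cbind(ii, jj)] <- cnt; W[cbind(jj, ii)] <- cnt
      L[cbind(ii, jj)] <- len; L[cbind(jj, ii)] <- len
    }
  }
  out <- connectome(regions, W, L, ap_extent_mm, species)
  attr(out, "discard_log") <- discard
  out
}

#' Network density
#'
#' Number of observed connections divided by the number of all possible
#' connections between regions. Hemisphere scopes count only
#' intrahemispheric node pairs (the comparative analyses are
#' intrahemispheric).
#'
#' @param conn a \code{"connectome"}, or a square weight/adjacency matrix.
#' @param scope \code{"left"}, \code{"right"}, or \code{"whole"}.
#' @return Fraction in \eqn{[0, 1]}.
#' @export
network_density <- function(conn, scope = c("left", "right", "whole")) {
  scope <- match.arg(scope)
  W <- if (inherits(conn, "connectome")) {
    idx <- hemisphere_indices(conn, scope)
    conn$W[idx, idx, drop = FALSE]
  } else as.matrix(conn)
  n <- nrow(W)
  if (n < 2L) stop_("density needs at least 2 regions in scope")
  sum(W[upper.tri(W)] > 0) / (n * (n - 1) / 2)
}

#' Equalize network density across a set of connectomes
#'
#' Thresholds each species' connectome down to a common intrahemispheric
#' density so that cross-species differences in connection count cannot
#' drive differences in path length, clustering, or asymmetry. Each
#' hemisphere retains its strongest-NOS connections down to the target edge
#' count; ties at the cutoff are broken by higher weight, then lexicographic
#' node-pair order.
#'
#' @param conns list of \code{"connectome"} objects.
#' @param target \code{"min"} (the minimum hemisphere density across the set,
#'   default) or a fixed fraction in (0, 1].
#' @return List of thresholded connectomes (edge sets nested within the
#'   originals; interhemispheric connections are left untouched).
#' @export
equalize_density <- function(conns, target = "min") {
  stopifnot(is.list(conns), length(conns) >= 1L)
  dens <- vapply(conns, function(cn)
    min(network_density(cn, "left"), network_density(cn, "right")), numeric(1))
  tgt <- if (identical(target, "min")) min(dens) else {
    stopifnot(is.numeric(target), length(target) == 1L, target > 0, target <= 1)
    target
  }
  bad <- which(dens < tgt - 1e-12)
  if (length(bad)) {
    stop_("target density ", format(tgt, digits = 4),
          " exceeds the density of: ",
          paste(vapply(conns[bad], function(cn) cn$species, ""), collapse = ", "))
  }
  lapply(conns, function(cn) {
    for (scope in c("left", "right")) {
      idx <- hemisphere_indices(cn, scope)
      sub <- cn$W[idx, idx, drop = FALSE]
      n <- nrow(sub)
      n_keep <- round(tgt * n * (n - 1) / 2)
      ut <- which(upper.tri(sub) & sub > 0, arr.ind = TRUE)
      if (nrow(ut) > n_keep) {
        w <- sub[ut]
        ord <- order(-w, ut[, 1], ut[, 2])   # strongest first; ties by pair order
        drop_rc <- ut[ord[-seq_len(n_keep)], , drop = FALSE]
        gi <- idx[drop_rc[, 1]]; gj <- idx[drop_rc[, 2]]
        cn$W[cbind(gi, gj)] <- 0; cn$W[cbind(gj, gi)] <- 0
        cn$L[cbind(gi, gj)] <- 0; cn$L[cbind(gj, gi)] <- 0
      }
    }
    cn
  })
}

#' Brain-size-normalized connection-length distribution
#'
#' Splits the connection lengths (one value per connection, not per
#' streamline) into 10 equal bins from 0 mm to the anterior-posterior extent
#' of the brain, so each bin covers 10\% of the AP length and distributions
#' are comparable across brain sizes. Connections longer than the AP extent
#' fall in the longest bin.
#'
#' @param conn a \code{"connectome"} with at least one connection.
#' @param scope which connections to bin (default \code{"whole"}).
#' @return An object of class \code{"length_bins"}: \code{proportions}
#'   (length 10, sums to 1), \code{counts}, \code{bin_width_mm}.
#' @export
length_bin_distribution <- function(conn, scope = c("whole", "left", "right")) {
  scope <- match.arg(scope)
  stopifnot(inherits(conn, "connectome"))
  if (conn$ap_extent <= 0) stop_("anterior-posterior extent must be positive")
  idx <- hemisphere_indices(conn, scope)
  W <- conn$W[idx, idx, drop = FALSE]; L <- conn$L[idx, idx, drop = FALSE]
  lens <- L[upper.tri(L)][W[upper.tri(W)] > 0]
  if (length(lens) == 0L) stop_("connectome has no connections to bin")
  width <- conn$ap_extent / 10
  b <- pmin(floor(lens / width) + 1L, 10L)   # overflow into bin 10
  counts <- tabulate(b, nbins = 10L)
  structure(list(proportions = counts / sum(counts), counts = counts,
                 bin_width_mm = width, n_connections = length(lens)),
            class = "length_bins")
}

#' @export
print.length_bins <- function(x, ...) {
  cat("connection-length bins (width", format(x$bin_width_mm, digits = 5),
      "mm,", x$n_connections, "connections):\n")
  print(round(x$proportions, 4))
  invisible(x)
}

#' Short- versus long-range connection contrast
#'
#' The proportion of connections in the two shortest length bins (0-20\% of
#' the AP extent) against everything longer — the contrast under which the
#' long-range bottleneck is strongest.
#'
#' @param bins a \code{"length_bins"}.
#' @return Named vector \code{c(short = , long = )}.
#' @export
short_long_contrast <- function(bins) {
  stopifnot(inherits(bins, "length_bins"))
  s <- sum(bins$proportions[1:2])
  c(short = s, long = 1 - s)
}

# ---- input/output ----------------------------------------------------------

#' Write a connectome as tab-separated matrices plus a region sidecar
#'
#' Writes \code{<prefix>_weights.tsv}, \code{<prefix>_lengths.tsv} (square
#' matrices with region-id headers) and \code{<prefix>_regions.tsv}
#' (id, hemisphere, x, y, z, homolog, ap_extent_mm).
#'
#' @param conn a \code{"connectome"}.
#' @param prefix output path prefix.
#' @export
write_connectome <- function(conn, prefix) {
  ids <- as.character(conn$regions$region)
  wm <- conn$W; lm <- conn$L
  dimnames(wm) <- dimnames(lm) <- list(ids, ids)
  utils::write.table(wm, paste0(prefix, "_weights.tsv"), sep = "\t", quote = FALSE)
  utils::write.table(lm, paste0(prefix, "_lengths.tsv"), sep = "\t", quote = FALSE)
  side <- cbind(conn$regions, homolog = conn$homolog,
                ap_extent_mm = conn$ap_extent)
  utils::write.table(side, paste0(prefix, "_regions.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(prefix)
}

#' Read a connectome written by \code{\link{write_connectome}}
#'
#' @param prefix path prefix used when writing.
#' @param species species id for the object.
#' @return A \code{"connectome"}.
#' @export
read_connectome <- function(prefix, species = basename(prefix)) {
  W <- as.matrix(utils::read.delim(paste0(prefix, "_weights.tsv"), check.names = FALSE))
  L <- as.matrix(utils::read.delim(paste0(prefix, "_lengths.tsv"), check.names = FALSE))
  dimnames(W) <- dimnames(L) <- NULL
  side <- utils::read.delim(paste0(prefix, "_regions.tsv"))
  connectome(side[, c("region", "hemisphere", "x", "y", "z")], W, L,
             ap_extent_mm = side$ap_extent_mm[1], species = species,
             homolog = side$homolog)
}

#' Write a connectome as a weighted edge list
#'
#' @param conn a \code{"connectome"}.
#' @param file output path; columns i, j, nos, length_mm.
#' @export
write_edge_list <- function(conn, file) {
  ut <- which(upper.tri(conn$W) & conn$W > 0, arr.ind = TRUE)
  d <- data.frame(i = conn$regions$region[ut[, 1]],
                  j = conn$regions$region[ut[, 2]],
                  nos = conn$W[ut], length_mm = conn$L[ut])
  utils::write.table(d, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
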