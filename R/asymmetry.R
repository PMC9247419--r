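# Homotopic connectivity asymmetry: rank-based weight normalization, the
# per-homolog-pair profile comparison, the species-level score, and its
# permutation null against a size trait.

#' Asymmetry configuration
#'
#' @param target_mean,target_sd moments of the normal reference distribution
#'   the weights are resampled to (defaults M = 1, SD = 0.2).
#' @param mode \code{"weighted"} (mean absolute profile difference over
#'   shared connections) or \code{"binary"} (1 - Jaccard overlap of
#'   presence/absence profiles, the supplementary variant).
#' @param n_perm permutation count for the null test (default 1000).
#' @param seed integer seed.
#' @return An \code{"asymmetry_config"} list.
#' @export
asymmetry_config <- function(target_mean = 1, target_sd = 0.2,
                             mode = c("weighted", "binary"),
                             n_perm = 1000, seed = 1) {
  mode <- match.arg(mode)
  stopifnot(target_sd > 0, is_count(n_perm))
  structure(list(target_mean = target_mean, target_sd = target_sd,
                 mode = mode, n_perm = as.integer(n_perm), seed = seed),
            class = "asymmetry_config")
}

#' Resample connection weights to a common normal distribution
#'
#' Within each hemisphere, replaces the intrahemispheric edge weights by a
#' rank-preserving quantile map onto a normal(M, SD) reference: the k-th
#' smallest of m weights maps to the normal quantile at (k - 0.5)/m. After
#' resampling, both hemispheres carry weight distributions with identical
#' moments, so the asymmetry score registers only differences in the ranking
#' and placement of weights, never differences in overall connection
#' strength between species or hemispheres. Ties are broken by edge order
#' (first occurrence gets the smaller quantile); topology is unchanged.
#'
#' @param conn a \code{"connectome"} with at least 2 intrahemispheric edges
#'   per hemisphere.
#' @param config an \code{\link{asymmetry_config}}.
#' @return The connectome with resampled intrahemispheric weights.
#' @export
resample_weights_to_normal <- function(conn, config = asymmetry_config()) {
  stopifnot(inherits(conn, "connectome"))
  for (h in c("left", "right")) {
    idx <- hemisphere_indices(conn, h)
    sub <- conn$W[idx, idx, drop = FALSE]
    ut <- which(upper.tri(sub) & sub > 0, arr.ind = TRUE)
    m <- nrow(ut)
    if (m < 2L) stop_("hemisphere '", h, "' has fewer than 2 edges")
    w <- sub[ut]
    q <- stats::qnorm((seq_len(m) - 0.5) / m,
                      mean = config$target_mean, sd = config$target_sd)
    new_w <- q[rank(w, ties.method = "first")]
    gi <- idx[ut[, 1]]; gj <- idx[ut[, 2]]
    conn$W[cbind(gi, gj)] <- new_w
    conn$W[cbind(gj, gi)] <- new_w
  }
  attr(conn, "weights_resampled") <- TRUE
  conn
}

#' Connectivity asymmetry of one homolog pair
#'
#' Compares the connectivity profile of region A (its connection strengths
#' to the other regions of its hemisphere) with the profile of its
#' contralateral spatial homolog A', indexed over homologous targets.
#' Weighted mode: the mean absolute difference in connection strength over
#' connections present in both profiles (0 means identical, i.e.
#' symmetrical, profiles). Binary mode: 1 minus the Jaccard overlap of the
#' presence/absence profiles.
#'
#' @param profile_a,profile_b numeric weight vectors over homologous
#'   intrahemispheric targets (same length and target order).
#' @param mode \code{"weighted"} or \code{"binary"}.
#' @return Score, or \code{NA} (weighted mode) when the profiles share no
#'   connection — such pairs are excluded from the species mean.
#' @examples
#' pair_asymmetry(c(1.0, 0.5), c(0.8, 0.5))  # (0.2 + 0)/2 = 0.1
#' @export
pair_asymmetry <- function(profile_a, profile_b, mode = c("weighted", "binary")) {
  mode <- match.arg(mode)
  stopifnot(length(profile_a) == length(profile_b))
  pa <- profile_a > 0; pb <- profile_b > 0
  if (mode == "binary") {
    union <- sum(pa | pb)
    if (union == 0L) return(NA_real_)
    return(1 - sum(pa & pb) / union)
  }
  shared <- pa & pb
  if (!any(shared)) return(NA_real_)
  mean(abs(profile_a[shared] - profile_b[shared]))
}

#' Total connectivity asymmetry of a connectome
#'
#' Applies \code{\link{pair_asymmetry}} to every left-right homolog pair of
#' regions and averages the scores over pairs with at least one shared
#' connection, yielding the species-level connectivity-asymmetry score.
#' Unless the weights are already resampled (flagged by
#' \code{\link{resample_weights_to_normal}}), resampling is applied first so
#' scores are comparable across species.
#'
#' @param conn a \code{"connectome"} with homolog pairing.
#' @param config an \code{\link{asymmetry_config}}.
#' @param resample apply weight resampling if not already done (default TRUE).
#' @return An \code{"asymmetry_result"}: \code{pair_scores} (per left
#'   region), \code{n_shared} per pair, \code{species_mean},
#'   \code{n_eligible_pairs}, \code{config}.
#' @export
total_asymmetry <- function(conn, config = asymmetry_config(), resample = TRUE) {
  stopifnot(inherits(conn, "connectome"))
  if (any(is.na(conn$homolog))) stop_("connectome has no homolog pairing")
  if (resample && !isTRUE(attr(conn, "weights_resampled")) &&
      config$mode == "weighted") {
    conn <- resample_weights_to_normal(conn, config)
  }
  left <- hemisphere_indices(conn, "left")
  right <- hemisphere_indices(conn, "right")
  Wl <- conn$W[left, left, drop = FALSE]
  # reorder the right-hemisphere block so row/column r is the homolog of
  # left region r: profiles are then aligned over homologous targets
  rmap <- conn$homolog[left]
  Wr <- conn$W[rmap, rmap, drop = FALSE]
  nL <- length(left)
  scores <- numeric(nL)
  n_shared <- integer(nL)
  for (r in seq_len(nL)) {
    a <- Wl[r, -r]; b <- Wr[r, -r]
    scores[r] <- pair_asymmetry(a, b, config$mode)
    n_shared[r] <- sum(a > 0 & b > 0)
  }
  eligible <- !is.na(scores)
  if (!any(eligible)) stop_("no homolog pair has shared connections")
  structure(list(pair_scores = scores, n_shared = n_shared,
                 species_mean = mean(scores[eligible]),
                 n_eligible_pairs = sum(eligible),
                 species = conn$species, config = config),
            class = "asymmetry_result")
}

#' @export
print.asymmetry_result <- function(x, ...) {
  cat("connectivity asymmetry '", x$species, "': species mean ",
      format(x$species_mean, digits = 5), " over ", x$n_eligible_pairs,
      " homolog pairs (", x$config$mode, " mode)\n", sep = "")
  invisible(x)
}

# Shuffle intrahemispheric edge weights among the existing edges of each
# hemisphere (topology preserved); called inside a seeded RNG context.
.shuffle_weights <- function(conn) {
  for (h in c("left", "right")) {
    idx <- hemisphere_indices(conn, h)
    sub <- conn$W[idx, idx, drop = FALSE]
    ut <- which(upper.tri(sub) & sub > 0, arr.ind = TRUE)
    w <- sub[ut][sample.int(nrow(ut))]
    gi <- idx[ut[, 1]]; gj <- idx[ut[, 2]]
    conn$W[cbind(gi, gj)] <- w
    conn$W[cbind(gj, gi)] <- w
  }
  conn
}

#' Permutation null for the asymmetry-size association
#'
#' Tests whether the cross-species association between connectivity
#' asymmetry and a size trait exceeds what random placement of connection
#' weights produces. Each permutation shuffles the connection weights among
#' the existing edges within each hemisphere of each species (preserving
#' topology), recomputes the species asymmetry scores, and refits the
#' standardized PGLS slope of asymmetry on the trait. The empirical p-value
#' is \eqn{(1 + \#\{null \ge observed\}) / (1 + n_{perm})}.
#'
#' @param conns list of \code{"connectome"} objects (one per species), with
#'   weights already resampled or resampled internally.
#' @param trait named numeric vector (e.g. cerebral volume, cm^3) over the
#'   same species; log10 is applied before z-scoring.
#' @param tree a \code{"phylo"} tree over the species.
#' @param config an \code{\link{asymmetry_config}} (permutation count and
#'   seed).
#' @param log_trait log10-transform the trait before z-scoring (default TRUE).
#' @return List: \code{observed_slope}, \code{null_slopes} (length
#'   \code{n_perm}), \code{p_value}, \code{observed_asymmetry} (per species),
#'   \code{n_perm}, \code{seed}.
#' @export
asymmetry_permutation_test <- function(conns, trait, tree,
                                       config = asymmetry_config(),
                                       log_trait = TRUE) {
  stopifnot(length(conns) >= 3L, length(trait) == length(conns))
  species <- vapply(conns, function(cn) cn$species, "")
  if (is.null(names(trait))) names(trait) <- species
  trait <- trait[species]
  x <- if (log_trait) log10(trait) else trait
  xz <- ztrans(x)

  # resample once; permutations re-shuffle the resampled weights (a shuffle
  # of rank-mapped weights equals the rank map of shuffled weights)
  conns <- lapply(conns, function(cn) {
    if (config$mode == "weighted" && !isTRUE(attr(cn, "weights_resampled"))) {
      resample_weights_to_normal(cn, config)
    } else cn
  })

  obs_asym <- vapply(conns, function(cn)
    total_asymmetry(cn, config, resample = FALSE)$species_mean, numeric(1))
  names(obs_asym) <- species
  obs_fit <- fit_pgls(ztrans(obs_asym), xz, tree)
  observed <- unname(coef(obs_fit)["x"])

  null_slopes <- with_seed(config$seed, {
    vapply(seq_len(config$n_perm), function(p) {
      shuffled <- lapply(conns, .shuffle_weights)
      a <- vapply(shuffled, function(cn)
        total_asymmetry(cn, config, resample = FALSE)$species_mean, numeric(1))
      unname(coef(fit_pgls(ztrans(a), xz, tree))["x"])
    }, numeric(1))
  })
  if (length(null_slopes) != config$n_perm) {
    stop_("only ", length(null_slopes), " of ", config$n_perm,
          " permutations completed")
  }
  list(observed_slope = observed,
       null_slopes = null_slopes,
       p_value = (1 + sum(null_slopes >= observed)) / (1 + config$n_perm),
       observed_asymmetry = obs_asym,
       n_perm = config$n_perm, seed = config$seed)
}
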