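# Synthetic comparative studies with known ground truth: ultrametric trees,
# Brownian traits with configurable allometric exponents, mirrored
# two-hemisphere connectomes with distance decay and controllable
# left-right asymmetry. Defaults emulate the primate study conditions:
# 14 species, cerebral volume 2.6-905 cm^3, generating exponents 0.85
# (surface ~ volume), 1.10 (white ~ gray matter), 0.88 (corpus callosum ~
# surface), density falling from 0.52 in the smallest to 0.34 in the
# largest brain.

#' Simulate a pure-birth ultrametric phylogeny
#'
#' All root-to-tip depths are equal (a time-calibrated tree); branch lengths
#' are in arbitrary time units. Deterministic per seed.
#'
#' @param n_taxa number of species (>= 2).
#' @param birth_rate speciation rate (> 0).
#' @param seed integer seed.
#' @return A \code{"phylo"} tree with tip labels \code{sp01, sp02, ...}.
#' @export
simulate_tree <- function(n_taxa, birth_rate = 1, seed = 1) {
  if (!is_count(n_taxa) || n_taxa < 2) stop_("n_taxa must be an integer >= 2")
  if (!is.numeric(birth_rate) || birth_rate <= 0) stop_("birth_rate must be > 0")
  tr <- with_seed(seed, ape::rphylo(n_taxa, birth = birth_rate, death = 0))
  tr$tip.label <- sprintf("sp%02d", seq_len(n_taxa))
  validate_phylo_tree(tr)
  tr
}

#' Species specification for the synthetic generator
#'
#' Bundles the generating parameters of a synthetic comparative study. The
#' defaults reproduce the study conditions of the primate analyses: 14
#' species spanning the printed cerebral-volume range, allometric exponents
#' at the printed point estimates, a distance-decay length that shrinks
#' relative to brain size as size grows (the long-range bottleneck rule),
#' density falling with size, and hemispheric asymmetry rising with size.
#'
#' @param n_species number of species.
#' @param volume_range_cm3 cerebral-volume endpoints (cm^3); log-uniform span.
#' @param exp_surface_volume generating exponent of surface area on cerebral
#'   volume (log-log slope).
#' @param exp_wm_gm generating exponent of white-matter on gray-matter volume.
#' @param exp_cc_surface generating exponent of corpus-callosum area on
#'   surface area.
#' @param noise_sd_frac SD of the Brownian deviations around each scaling
#'   law, as a fraction of the predictor's cross-species SD (log scale).
#' @param n_regions parcels per hemisphere (25, 50, or 100).
#' @param decay_frac_range decay length d0 as a fraction of the AP extent,
#'   linear in log volume from the smallest (first element) to the largest
#'   species (second element). A decreasing pair is the bottleneck rule ON;
#'   equal values switch size dependence off.
#' @param density_range target intrahemispheric density, linear in log
#'   volume from smallest to largest species.
#' @param asymmetry_range multiplicative weight-perturbation level, linear
#'   in log volume from smallest to largest species.
#' @param mesh_subdivisions icosphere subdivision level for the hemisphere
#'   meshes.
#' @param birth_rate speciation rate of the simulated tree.
#' @param seed master seed; all per-stage seeds derive from it.
#' @return A \code{"species_spec"} list.
#' @export
species_spec <- function(n_species = 14,
                         volume_range_cm3 = c(2.6, 905),
                         exp_surface_volume = 0.85,
                         exp_wm_gm = 1.10,
                         exp_cc_surface = 0.88,
                         noise_sd_frac = 0.05,
                         n_regions = 50,
                         decay_frac_range = c(0.30, 0.12),
                         density_range = c(0.52, 0.34),
                         asymmetry_range = c(0.05, 0.40),
                         mesh_subdivisions = 3,
                         birth_rate = 1,
                         seed = 1) {
  stopifnot(is_count(n_species), n_species >= 2,
            length(volume_range_cm3) == 2L, all(volume_range_cm3 > 0),
            volume_range_cm3[2] > volume_range_cm3[1],
            is.finite(exp_surface_volume), is.finite(exp_wm_gm),
            is.finite(exp_cc_surface), noise_sd_frac >= 0,
            n_regions %in% c(25, 50, 100),
            length(decay_frac_range) == 2L, all(decay_frac_range > 0),
            length(density_range) == 2L, all(density_range > 0),
            all(density_range <= 1),
            length(asymmetry_range) == 2L, all(asymmetry_range >= 0))
  structure(as.list(environment()), class = "species_spec")
}

# Brownian motion realization on a tree: multivariate normal with the shared
# branch-length covariance, root value 0, rate 1.
.bm_on_tree <- function(tree) {
  C <- brownian_covariance(tree)$C
  drop(t(chol(C)) %*% stats::rnorm(nrow(C)))
}

# Rescale v linearly so its range maps onto [lo, hi].
.rescale_range <- function(v, lo, hi) {
  if (diff(range(v)) == 0) return(rep((lo + hi) / 2, length(v)))
  (v - min(v)) / diff(range(v)) * (hi - lo) + lo
}

#' Simulate species traits under Brownian scaling laws
#'
#' log10 cerebral volume evolves by Brownian motion on the tree and is
#' rescaled onto the requested volume range. Each downstream trait follows
#' its scaling law on the log scale plus a Brownian deviation whose
#' cross-species SD is \code{noise_sd_frac} times the predictor's SD:
#' surface area from volume, white-matter volume from gray-matter volume,
#' corpus-callosum area from surface area. Gray-matter volume is a fixed
#' fraction (0.55) of cerebral volume so the white-gray law has a concrete
#' predictor. With \code{residual_model = "iid"} the deviations are drawn
#' independently of the tree instead — the no-phylogenetic-signal endpoint
#' (Pagel's lambda near 0).
#'
#' @param tree a \code{"phylo"} tree.
#' @param spec a \code{\link{species_spec}}.
#' @param seed integer seed (defaults to the spec's).
#' @param residual_model \code{"bm"} (deviations are Brownian on the tree)
#'   or \code{"iid"}.
#' @return Data.frame, one row per species (row names = tip labels):
#'   \code{cerebral_volume_cm3}, \code{gm_volume_cm3}, \code{wm_volume_cm3},
#'   \code{surface_area_cm2}, \code{cc_area_cm2}.
#' @export
simulate_traits <- function(tree, spec = species_spec(), seed = spec$seed,
                            residual_model = c("bm", "iid")) {
  residual_model <- match.arg(residual_model)
  validate_phylo_tree(tree)
  n <- length(tree$tip.label)
  with_seed(derive_seed(seed, "traits"), {
    lv <- .rescale_range(.bm_on_tree(tree),
                         log10(spec$volume_range_cm3[1]),
                         log10(spec$volume_range_cm3[2]))
    dev <- function() {
      d <- if (residual_model == "bm") .bm_on_tree(tree) else stats::rnorm(n)
      if (stats::sd(d) == 0 || spec$noise_sd_frac == 0) return(rep(0, n))
      d / stats::sd(d) * (spec$noise_sd_frac * stats::sd(lv))
    }
    # anchor intercepts to brain-like magnitudes at the smallest species:
    # gray matter 55% of cerebrum; at the minimum volume, surface ~ 11 cm^2,
    # white matter ~ 37% of the cerebrum, 1 cm^2 of CC per 90 cm^2 of surface
    lv0 <- log10(spec$volume_range_cm3[1])
    lgm <- lv + log10(0.55)
    lsurf <- spec$exp_surface_volume * (lv - lv0) + log10(11) + dev()
    lwm <- spec$exp_wm_gm * (lgm - lv0 - log10(0.55)) +
      log10(0.37 * spec$volume_range_cm3[1]) + dev()
    lcc <- spec$exp_cc_surface * (lsurf - log10(11)) + log10(11 / 90) + dev()
    data.frame(cerebral_volume_cm3 = 10^lv,
               gm_volume_cm3 = 10^lgm,
               wm_volume_cm3 = 10^lwm,
               surface_area_cm2 = 10^lsurf,
               cc_area_cm2 = 10^lcc,
               row.names = tree$tip.label)
  })
}

#' Generate a mirrored two-hemisphere synthetic connectome
#'
#' Intrahemispheric edges on the left hemisphere are drawn with an
#' exponential distance rule: connection probability proportional to
#' \eqn{\exp(-d/d_0)} in the centroid distance d, conditioned on hitting the
#' target edge count exactly (the proportionality constant is the order
#' statistic of the scored uniform draws, so achieved density is within one
#' edge of the target). NOS weights are a discretized lognormal. The right
#' hemisphere mirrors the left through the homolog map; with
#' \code{asymmetry_level > 0} its weights are multiplied by
#' \eqn{\exp(a \epsilon)}, \eqn{\epsilon \sim N(0,1)} per edge, so level 0
#' gives an exact mirror. Connection lengths are Euclidean centroid
#' distances (no streamlines exist for synthetic data).
#'
#' @param centroids_left data.frame from \code{\link{region_centroids}} for
#'   the left hemisphere.
#' @param centroids_right same for the right hemisphere (homolog r = region r).
#' @param ap_extent_mm anterior-posterior extent of the brain (mm).
#' @param target_density intrahemispheric density to hit.
#' @param decay_mm distance-decay length d0 (mm).
#' @param asymmetry_level multiplicative log-scale perturbation SD applied to
#'   right-hemisphere weights (0 = exact mirror).
#' @param species species id.
#' @param seed integer seed.
#' @param nos_meanlog,nos_sdlog lognormal weight-law parameters.
#' @return A \code{"connectome"} (regions L1..Ln then R1..Rn, homolog map
#'   linking them).
#' @export
generate_connectome <- function(centroids_left, centroids_right, ap_extent_mm,
                                target_density = 0.4, decay_mm = 20,
                                asymmetry_level = 0, species = "synthetic",
                                seed = 1, nos_meanlog = 3, nos_sdlog = 1) {
  nr <- nrow(centroids_left)
  stopifnot(nrow(centroids_right) == nr, nr >= 3,
            target_density > 0, target_density <= 1, decay_mm > 0,
            asymmetry_level >= 0)
  xyzL <- as.matrix(centroids_left[, c("x", "y", "z")])
  xyzR <- as.matrix(centroids_right[, c("x", "y", "z")])
  dL <- as.matrix(stats::dist(xyzL))
  dR <- as.matrix(stats::dist(xyzR))
  n_pairs <- nr * (nr - 1) / 2
  k <- round(target_density * n_pairs)
  if (k < 1L) stop_("target density ", target_density, " yields no edges; ",
                    "feasible range is [", format(1 / n_pairs, digits = 3), ", 1]")

  with_seed(derive_seed(seed, paste0("conn_", species)), {
    ut <- which(upper.tri(dL), arr.ind = TRUE)
    u <- stats::runif(n_pairs)
    score <- u * exp(dL[ut] / decay_mm)   # edge iff u < c * exp(-d/d0)
    keep <- order(score)[seq_len(k)]
    wL <- pmax(1, round(exp(stats::rnorm(k, nos_meanlog, nos_sdlog))))
    wR <- if (asymmetry_level > 0) {
      pmax(1, round(wL * exp(asymmetry_level * stats::rnorm(k))))
    } else wL

    W <- matrix(0, 2 * nr, 2 * nr)
    L <- matrix(0, 2 * nr, 2 * nr)
    i <- ut[keep, 1]; j <- ut[keep, 2]
    W[cbind(i, j)] <- wL; W[cbind(j, i)] <- wL
    L[cbind(i, j)] <- dL[cbind(i, j)]; L[cbind(j, i)] <- dL[cbind(i, j)]
    ir <- i + nr; jr <- j + nr
    W[cbind(ir, jr)] <- wR; W[cbind(jr, ir)] <- wR
    L[cbind(ir, jr)] <- dR[cbind(i, j)]; L[cbind(jr, ir)] <- dR[cbind(i, j)]

    regions <- data.frame(
      region = c(paste0("L", seq_len(nr)), paste0("R", seq_len(nr))),
      hemisphere = rep(c("left", "right"), each = nr),
      x = c(xyzL[, 1], xyzR[, 1]),
      y = c(xyzL[, 2], xyzR[, 2]),
      z = c(xyzL[, 3], xyzR[, 3]))
    connectome(regions, W, L, ap_extent_mm, species,
               homolog = c(seq_len(nr) + nr, seq_len(nr)))
  })
}

#' Generate a complete synthetic comparative study
#'
#' Runs the full generator: pure-birth tree, Brownian traits, mirrored
#' hemisphere meshes scaled to each species' surface area, random
#' parcellation projected to the right hemisphere, and per-species
#' connectomes whose distance-decay length, density, and asymmetry level
#' follow the spec's size rules. The returned ground-truth record contains
#' every generating parameter and derived per-species value; regenerating
#' with the same spec is bitwise identical.
#'
#' @param spec a \code{\link{species_spec}}.
#' @return A \code{"generated_study"} list: \code{tree}, \code{traits},
#'   \code{meshes} (per species, \code{left}/\code{right}),
#'   \code{parcellations} (per species, \code{left}/\code{right}),
#'   \code{connectomes} (per species), \code{ground_truth}.
#' @export
generate_study <- function(spec = species_spec()) {
  stopifnot(inherits(spec, "species_spec"))
  tree <- simulate_tree(spec$n_species, spec$birth_rate,
                        derive_seed(spec$seed, "tree"))
  traits <- simulate_traits(tree, spec, seed = spec$seed)
  sp_names <- tree$tip.label

  lv <- log10(traits$cerebral_volume_cm3)
  size01 <- if (diff(range(lv)) > 0) (lv - min(lv)) / diff(range(lv)) else rep(0.5, length(lv))
  decay_frac <- spec$decay_frac_range[1] +
    size01 * diff(spec$decay_frac_range)
  density <- spec$density_range[1] + size01 * diff(spec$density_range)
  asym <- spec$asymmetry_range[1] + size01 * diff(spec$asymmetry_range)

  meshes <- list(); parcs <- list(); conns <- list()
  gt_species <- data.frame(species = sp_names, decay_frac = decay_frac,
                           target_density = density, asymmetry_level = asym)
  for (s in seq_along(sp_names)) {
    # per-hemisphere area: half the total cortical surface
    area_h <- traits$surface_area_cm2[s] / 2
    mL <- generate_hemisphere_mesh(area_h, subdivisions = spec$mesh_subdivisions,
                                   side = "left")
    mR <- generate_hemisphere_mesh(area_h, subdivisions = spec$mesh_subdivisions,
                                   side = "right")
    pL <- random_parcellation(mL, spec$n_regions,
                              seed = derive_seed(spec$seed, paste0("parc_", s)))
    pR <- project_contralateral(pL, mL, mR)
    ap <- ap_extent(mL)
    cn <- generate_connectome(region_centroids(mL, pL),
                              region_centroids(mR, pR),
                              ap_extent_mm = ap,
                              target_density = density[s],
                              decay_mm = decay_frac[s] * ap,
                              asymmetry_level = asym[s],
                              species = sp_names[s],
                              seed = derive_seed(spec$seed, paste0("conn_", s)))
    meshes[[sp_names[s]]] <- list(left = mL, right = mR)
    parcs[[sp_names[s]]] <- list(left = pL, right = pR)
    conns[[sp_names[s]]] <- cn
  }
  structure(list(tree = tree, traits = traits, meshes = meshes,
                 parcellations = parcs, connectomes = conns,
                 ground_truth = list(spec = spec, per_species = gt_species)),
            class = "generated_study")
}

#' @export
print.generated_study <- function(x, ...) {
  cat("generated_study:", length(x$tree$tip.label), "species,",
      x$ground_truth$spec$n_regions, "regions/hemisphere, master seed",
      x$ground_truth$spec$seed, "\n")
  invisible(x)
}

#' Write a generated study to a directory
#'
#' Writes the same text formats the pipeline reads: \code{tree.nwk},
#' \code{traits.tsv}, per-species PLY meshes, parcellation tables,
#' connectome matrices, and \code{ground_truth.yaml}.
#'
#' @param study a \code{"generated_study"}.
#' @param dir output directory (created if needed).
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_phylo_tree(study$tree, file.path(dir, "tree.nwk"))
  utils::write.table(cbind(species = rownames(study$traits), study$traits),
                     file.path(dir, "traits.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (sp in names(study$connectomes)) {
    write_ply(study$meshes[[sp]]$left, file.path(dir, paste0(sp, "_left.ply")))
    write_ply(study$meshes[[sp]]$right, file.path(dir, paste0(sp, "_right.ply")))
    write_parcellation(study$parcellations[[sp]]$left,
                       file.path(dir, paste0(sp, "_left_labels.tsv")))
    write_parcellation(study$parcellations[[sp]]$right,
                       file.path(dir, paste0(sp, "_right_labels.tsv")))
    write_connectome(study$connectomes[[sp]], file.path(dir, sp))
  }
  spec <- study$ground_truth$spec
  yaml::write_yaml(lapply(unclass(spec), function(v)
    if (is.numeric(v)) as.numeric(v) else v),
    file.path(dir, "ground_truth.yaml"))
  invisible(dir)
}
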