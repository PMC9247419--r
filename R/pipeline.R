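# End-to-end orchestration: generate (optional) -> parcellate -> build
# connectomes -> equalize density -> network metrics with rewired nulls ->
# asymmetry with permutation null -> PGLS scaling report. All outputs are
# tab-separated tables plus a manifest recording seeds and the config hash.

#' Pipeline configuration
#'
#' Builds and validates the configuration driving
#' \code{\link{run_pipeline}}. Either \code{input_dir} points at a study
#' written by \code{\link{write_study}} (or equivalently formatted data), or
#' the synthetic generator runs first with \code{generator} parameters.
#'
#' @param output_dir directory for all pipeline outputs.
#' @param input_dir optional directory with tree.nwk, traits.tsv and
#'   per-species connectome tables; \code{NULL} runs the generator.
#' @param generator list of \code{\link{species_spec}} arguments for the
#'   synthetic stage (ignored when \code{input_dir} is given).
#' @param n_regions parcellation resolution per hemisphere (25, 50, or 100).
#' @param n_nulls rewired reference networks per connectome.
#' @param swaps_per_edge rewiring attempts per edge.
#' @param n_perm permutations for the asymmetry null test.
#' @param run_permutation run the asymmetry permutation test (it dominates
#'   runtime at full permutation counts).
#' @param equalize_target \code{"min"} or a fixed density fraction.
#' @param seed master seed; every stage derives its stream from it.
#' @param verbose log stage banners to standard error.
#' @return A \code{"pipeline_config"} list.
#' @export
pipeline_config <- function(output_dir,
                            input_dir = NULL,
                            generator = list(),
                            n_regions = 50,
                            n_nulls = 1000,
                            swaps_per_edge = 10,
                            n_perm = 1000,
                            run_permutation = TRUE,
                            equalize_target = "min",
                            seed = 1,
                            verbose = TRUE) {
  if (!n_regions %in% c(25, 50, 100)) {
    stop_("unsupported parcellation resolution: ", n_regions,
          " (supported: 25, 50, 100)")
  }
  stopifnot(is_count(n_nulls), is_count(swaps_per_edge), is_count(n_perm))
  structure(list(output_dir = output_dir, input_dir = input_dir,
                 generator = generator, n_regions = n_regions,
                 n_nulls = n_nulls, swaps_per_edge = swaps_per_edge,
                 n_perm = n_perm, run_permutation = isTRUE(run_permutation),
                 equalize_target = equalize_target,
                 seed = seed, verbose = isTRUE(verbose)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' @param file YAML file whose keys are \code{\link{pipeline_config}}
#'   arguments.
#' @return A \code{"pipeline_config"}.
#' @export
read_pipeline_config <- function(file) {
  vals <- yaml::read_yaml(file)
  do.call(pipeline_config, vals)
}

.log_stage <- function(cfg, ...) {
  if (cfg$verbose) {
    message(format(Sys.time(), "[%Y-%m-%d %H:%M:%S] "), ...)
  }
}

#' PGLS scaling summary over trait pairs
#'
#' log10-transforms both traits of each pair, fits PGLS with ML lambda, and
#' reports the scaling exponent with its confidence interval, adjusted R^2,
#' lambda, p-value, and each trait's cross-species fold range.
#'
#' @param traits data.frame of positive trait values, rows named by species.
#' @param tree a \code{"phylo"} tree over the same species.
#' @param pairs list of \code{c(y, x)} trait-column pairs.
#' @return Data.frame: trait_y, trait_x, b, ci_lo, ci_hi, r2_adj, lambda, p,
#'   n, fold_range_y, fold_range_x.
#' @export
trait_scaling_summary <- function(traits, tree, pairs) {
  stopifnot(is.data.frame(traits), is.list(pairs))
  rows <- lapply(pairs, function(pr) {
    stopifnot(length(pr) == 2L)
    if (!all(pr %in% names(traits))) {
      stop_("missing trait column(s): ",
            paste(setdiff(pr, names(traits)), collapse = ", "))
    }
    yv <- traits[[pr[1]]]; xv <- traits[[pr[2]]]
    if (any(yv <= 0) || any(xv <= 0)) stop_("traits must be positive for log transform")
    d <- data.frame(y = log10(yv), x = log10(xv), row.names = rownames(traits))
    fit <- pgls(y ~ x, data = d, tree = tree)
    data.frame(trait_y = pr[1], trait_x = pr[2],
               b = unname(coef(fit)["x"]),
               ci_lo = fit$ci["x", "lower"], ci_hi = fit$ci["x", "upper"],
               r2_adj = fit$adj.r.squared, lambda = fit$lambda,
               p = unname(fit$p.value["x"]), n = fit$n,
               fold_range_y = max(yv) / min(yv),
               fold_range_x = max(xv) / min(xv))
  })
  do.call(rbind, rows)
}

# Standardized PGLS slope of a per-species metric on log10 cerebral volume.
# A metric that is constant across species carries no association: beta 0,
# p 1 (z-scoring is undefined there).
.metric_beta <- function(values, traits, tree, metric) {
  if (stats::sd(values) == 0) {
    return(data.frame(metric = metric, beta = 0, ci_lo = 0, ci_hi = 0,
                      r2_adj = NA_real_, lambda = NA_real_, p = 1,
                      n = length(values)))
  }
  xz <- ztrans(log10(traits$cerebral_volume_cm3))
  names(xz) <- rownames(traits)
  fit <- fit_pgls(ztrans(values[rownames(traits)]), xz[rownames(traits)], tree)
  data.frame(metric = metric,
             beta = unname(coef(fit)["x"]),
             ci_lo = fit$ci["x", "lower"], ci_hi = fit$ci["x", "upper"],
             r2_adj = fit$adj.r.squared, lambda = fit$lambda,
             p = unname(fit$p.value["x"]), n = fit$n)
}

#' Run the full comparative connectomics pipeline
#'
#' Sequences the analysis stages: synthetic generation (or input loading),
#' density and length-bin analyses on the raw connectomes, density
#' equalization, normalized path length and clustering against rewired
#' nulls, connectivity asymmetry (with optional permutation null), and the
#' PGLS scaling regressions (log-log exponents for traits, standardized
#' betas for network metrics). All tables are written under
#' \code{config$output_dir}; a manifest records the package version, master
#' seed, and config hash. Rerunning with the same config is byte-identical.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @return A \code{"scaling_report"} list: \code{trait_fits},
#'   \code{metric_fits}, \code{species_metrics}, \code{length_bins} (species
#'   x 10 heat table ordered by cerebral volume), \code{permutation}
#'   (or NULL), \code{manifest}.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)

  stage <- function(name, expr) {
    .log_stage(config, "stage: ", name)
    tryCatch(expr, error = function(e) {
      stop_("pipeline stage '", name, "' failed: ", conditionMessage(e))
    })
  }

  study <- stage("generate/load", {
    if (is.null(config$input_dir)) {
      gen_args <- config$generator
      gen_args$n_regions <- config$n_regions
      gen_args$seed <- gen_args$seed %||% derive_seed(config$seed, "generator")
      generate_study(do.call(species_spec, gen_args))
    } else {
      read_study(config$input_dir)
    }
  })
  tree <- study$tree
  traits <- study$traits
  conns <- study$connectomes
  species <- rownames(traits)

  dens_tab <- stage("density", {
    do.call(rbind, lapply(conns, function(cn) data.frame(
      species = cn$species,
      left = network_density(cn, "left"),
      right = network_density(cn, "right"))))
  })

  bins_tab <- stage("length bins", {
    ord <- order(traits$cerebral_volume_cm3)
    m <- t(vapply(conns[species[ord]], function(cn)
      length_bin_distribution(cn)$proportions, numeric(10)))
    colnames(m) <- paste0("bin", 1:10)
    data.frame(species = species[ord], m)
  })

  conns_eq <- stage("equalize density", {
    equalize_density(conns, target = config$equalize_target)
  })

  metrics_tab <- stage("network metrics", {
    metric_table(conns_eq, null_model_config(config$n_nulls,
                                             config$swaps_per_edge,
                                             derive_seed(config$seed, "nulls")))
  })

  acfg <- asymmetry_config(n_perm = config$n_perm,
                           seed = derive_seed(config$seed, "asym"))
  asym_tab <- stage("asymmetry", {
    do.call(rbind, lapply(conns_eq, function(cn) {
      res <- total_asymmetry(cn, acfg)
      data.frame(species = cn$species, asymmetry = res$species_mean,
                 n_eligible_pairs = res$n_eligible_pairs)
    }))
  })

  perm <- if (config$run_permutation) {
    stage("permutation null", {
      tr_vec <- traits$cerebral_volume_cm3
      names(tr_vec) <- species
      asymmetry_permutation_test(conns_eq, tr_vec, tree, acfg)
    })
  } else NULL

  report <- stage("scaling regressions", {
    trait_fits <- trait_scaling_summary(traits, tree, list(
      c("surface_area_cm2", "cerebral_volume_cm3"),
      c("wm_volume_cm3", "gm_volume_cm3"),
      c("surface_area_cm2", "wm_volume_cm3"),
      c("cc_area_cm2", "surface_area_cm2")))

    sm <- data.frame(species = species, row.names = species)
    sm$density <- rowMeans(cbind(dens_tab$left, dens_tab$right))[
      match(species, dens_tab$species)]
    cpl <- metrics_tab[metrics_tab$metric == "characteristic_path_length", ]
    cc <- metrics_tab[metrics_tab$metric == "clustering_coefficient", ]
    sm$path_length <- tapply(cpl$normalized, cpl$species, mean)[species]
    sm$clustering <- tapply(cc$normalized, cc$species, mean)[species]
    sm$asymmetry <- asym_tab$asymmetry[match(species, asym_tab$species)]
    metric_fits <- rbind(
      .metric_beta(stats::setNames(sm$density, species), traits, tree, "density"),
      .metric_beta(stats::setNames(sm$path_length, species), traits, tree,
                   "path_length_normalized"),
      .metric_beta(stats::setNames(sm$clustering, species), traits, tree,
                   "clustering_normalized"),
      .metric_beta(stats::setNames(sm$asymmetry, species), traits, tree,
                   "asymmetry"))
    list(trait_fits = trait_fits, metric_fits = metric_fits, species_metrics = sm)
  })

  manifest <- stage("write outputs", {
    out <- function(name) file.path(config$output_dir, name)
    wt <- function(d, name) utils::write.table(
      d, out(name), sep = "\t", quote = FALSE, row.names = FALSE)
    wt(dens_tab, "density.tsv")
    wt(bins_tab, "length_bins.tsv")
    wt(metrics_tab, "network_metrics.tsv")
    wt(asym_tab, "asymmetry.tsv")
    wt(report$trait_fits, "trait_scaling.tsv")
    wt(report$metric_fits, "metric_scaling.tsv")
    wt(cbind(species = rownames(traits), traits), "traits.tsv")
    write_phylo_tree(tree, out("tree.nwk"))
    if (!is.null(perm)) {
      wt(data.frame(perm_index = seq_along(perm$null_slopes),
                    null_slope = perm$null_slopes), "asymmetry_null.tsv")
      wt(data.frame(observed = perm$observed_slope, p = perm$p_value,
                    n_perm = perm$n_perm, seed = perm$seed),
         "asymmetry_permutation_summary.tsv")
    }
    cfg_file <- out("config.yaml")
    yaml::write_yaml(lapply(unclass(config), function(v) v), cfg_file)
    # hash only the analysis-relevant configuration, so runs into different
    # output directories are recognizably the same analysis
    cfg_hash <- unclass(config)
    cfg_hash$output_dir <- NULL
    cfg_hash$verbose <- NULL
    hash_file <- tempfile()
    yaml::write_yaml(cfg_hash, hash_file)
    mf <- data.frame(
      package_version = as.character(utils::packageVersion("connallom")),
      master_seed = config$seed,
      config_md5 = unname(tools::md5sum(hash_file)),
      n_species = length(species),
      n_regions = config$n_regions,
      n_nulls = config$n_nulls,
      n_perm = if (config$run_permutation) config$n_perm else 0L)
    wt(mf, "manifest.tsv")
    mf
  })

  structure(list(trait_fits = report$trait_fits,
                 metric_fits = report$metric_fits,
                 species_metrics = report$species_metrics,
                 length_bins = bins_tab,
                 density = dens_tab,
                 permutation = perm,
                 manifest = manifest,
                 output_dir = config$output_dir),
            class = "scaling_report")
}

#' @export
print.scaling_report <- function(x, ...) {
  cat("scaling_report (", nrow(x$species_metrics), " species)\n", sep = "")
  cat("\ntrait scaling exponents (log10-log10 PGLS):\n")
  print(x$trait_fits[, c("trait_y", "trait_x", "b", "ci_lo", "ci_hi", "lambda", "p")],
        row.names = FALSE, digits = 4)
  cat("\nnetwork-metric standardized betas vs log10 cerebral volume:\n")
  print(x$metric_fits, row.names = FALSE, digits = 4)
  if (!is.null(x$permutation)) {
    cat("\nasymmetry permutation null: observed slope ",
        format(x$permutation$observed_slope, digits = 4), ", p = ",
        format(x$permutation$p_value, digits = 4), " (",
        x$permutation$n_perm, " permutations)\n", sep = "")
  }
  invisible(x)
}

#' Read a study directory written by \code{\link{write_study}}
#'
#' @param dir directory containing tree.nwk, traits.tsv, and per-species
#'   connectome tables.
#' @return A list with \code{tree}, \code{traits}, \code{connectomes}
#'   (meshes and parcellations are not reloaded; connectome tables carry
#'   everything the analyses need).
#' @export
read_study <- function(dir) {
  tree <- read_phylo_tree(file.path(dir, "tree.nwk"))
  traits <- utils::read.delim(file.path(dir, "traits.tsv"))
  rownames(traits) <- traits$species
  traits$species <- NULL
  conns <- lapply(rownames(traits), function(sp)
    read_connectome(file.path(dir, sp), species = sp))
  names(conns) <- rownames(traits)
  list(tree = tree, traits = traits, connectomes = conns)
}
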