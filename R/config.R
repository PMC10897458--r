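#' Pipeline configuration
#'
#' Builds the configuration driving [cluster_localizations()].  Defaults come
#' from the versioned profile file shipped with the package
#' (`inst/config/profiles.yaml`); any field can be overridden by argument.
#'
#' The fields mirror the pipeline's hyperparameters: the initial clustering
#' model (`eps`/`min_samples` for DBSCAN; `min_cluster_size`, `min_samples`
#' and `cluster_selection_epsilon` for HDBSCAN), `investigate_min_sample`
#' (min_samples of the seed-detection DBSCAN inside the temporal refinement,
#' default 50), `radius_ratio` (multiplier on the SEM of interquartile
#' pairwise distances in the search range, default 1.96),
#' `rough_min_points`/`final_min_points` (size floors before/after
#' refinement) and `filter_mode` (`"strict"`: density AND size, `"lose"`:
#' density OR size, `"none"`: keep all).  All parameters applied after
#' standardization are unitless.
#'
#' @param profile Profile name in the shipped profile file (see
#'   [list_profiles()]), or `NULL` for `"default"`.
#' @param ... Named overrides of individual fields.
#' @param seed Integer seed controlling the pipeline's only stochastic steps
#'   (noise subsampling in the smart density filter and pairwise-distance
#'   subsampling).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(profile = NULL, ..., seed = 1L) {
  cfg <- load_profile(if (is.null(profile)) "default" else profile)
  overrides <- list(...)
  unknown <- setdiff(names(overrides), c(names(cfg), "seed"))
  if (length(unknown))
    stop("unknown configuration field(s): ", paste(unknown, collapse = ", "))
  cfg[names(overrides)] <- overrides
  cfg$seed <- as.integer(seed)
  cfg$filter_mode <- match.arg(cfg$filter_mode, c("strict", "lose", "none"))
  cfg$initial_model <- match.arg(cfg$initial_model,
                                 c("auto", "dbscan", "hdbscan"))
  structure(cfg, class = "pipeline_config")
}

profile_registry <- function() {
  path <- system.file("config", "profiles.yaml", package = "smlmorph")
  if (path == "") path <- file.path("inst", "config", "profiles.yaml")
  yaml::read_yaml(path)
}

#' List shipped configuration profiles
#' @return Character vector of profile names.
#' @export
list_profiles <- function() names(profile_registry()$profiles)

#' Load one named configuration profile
#'
#' Profiles may inherit from each other (`inherits:` field); inheritance is
#' resolved here.  Fixed internal constants of the failsafe, density
#' estimator and refinement are attached alongside the profile fields.
#'
#' @param name Profile name.
#' @return A plain list of configuration fields.
#' @export
load_profile <- function(name) {
  reg <- profile_registry()$profiles
  if (!name %in% names(reg))
    stop("unknown profile '", name, "'; available: ",
         paste(names(reg), collapse = ", "))
  chain <- list()
  cur <- name
  while (!is.null(cur)) {
    chain <- c(list(reg[[cur]]), chain)
    cur <- reg[[cur]]$inherits
  }
  cfg <- list()
  for (layer in chain) cfg[names(layer)] <- layer
  cfg$inherits <- NULL
  # internal constants (configurable via pipeline_config(...))
  defaults <- list(
    density_k = 10L,        # k-NN order of the local density estimator
    noise_sample = 500L,    # noise points sampled by the smart filter
    pdist_max = 500L,       # subsample cap before pairwise distances
    range_stat = "sem",     # spread statistic of the search range: sem | sd
    seed_chain = NULL,      # DBSCAN core count of the seed search (NULL:
                            # investigate_min_sample itself); a seed cluster
                            # must always reach investigate_min_sample
    refine_stride = 1L,     # frames folded into one refinement step
    vote_closure = TRUE,    # transitive (vs single-pass) per-frame vote
    seed_space = "xy",      # metric of the seed scan: xy | xyt
    failsafe_bins = 128L,   # 2D histogram bins of the topological failsafe
    failsafe_sigma = 2,     # Gaussian blur, in bins
    failsafe_percentile = 0.90)
  for (nm in names(defaults)) if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  cfg
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  for (nm in names(x)) cat(sprintf("  %-26s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

pipeline_log <- function(...) {
  if (isTRUE(getOption("smlmorph.verbose", FALSE)))
    message("[smlmorph] ", sprintf(...))
}
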