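# Downstream fingerprint analytics: low-dimensional embedding for
# visualization/grouping, density-based group discovery, feature ranking,
# and geometric quantification (radius/diameter from area).  The embedding
# is a grouping aid; classification-style conclusions should rest on the
# fingerprints themselves wherever possible.

#' Embed fingerprints with UMAP
#'
#' Standardizes the feature columns (z-score; constant columns dropped) and
#' embeds them with a seeded UMAP.  Recipe presets bundle the embedding
#' parameters used for the shipped analysis recipes.
#'
#' @param fingerprints data.frame or matrix of fingerprints (an
#'   `assembly_id` column is carried through, not embedded).
#' @param n_components 2 or 3 output coordinates (default 3).
#' @param n_neighbors,min_dist UMAP locality parameters (defaults 5, 0.1).
#' @param seed Integer seed; fixed seed gives identical coordinates.
#' @param feature_subset Optional character vector restricting the embedded
#'   features (e.g. the circularity family plus `L_s_ratio`/`L_l_ratio`).
#' @param recipe Optional preset overriding the parameters:
#'   `"simulation"` (n_neighbors 5, min_dist 0.1),
#'   `"insulin"` (n_neighbors 10, min_dist 0.1, circularity +
#'   path-straightness subset), `"npc"` (n_neighbors 10, min_dist 0.2).
#' @return Numeric matrix (rows = fingerprints) with `assembly_id` attribute
#'   when present in the input.
#' @export
embed_fingerprints <- function(fingerprints, n_components = 3,
                               n_neighbors = 5, min_dist = 0.1, seed = 42,
                               feature_subset = NULL, recipe = NULL) {
  fp <- as.data.frame(fingerprints)
  ids <- fp$assembly_id
  fp$assembly_id <- NULL
  if (!is.null(recipe)) {
    recipe <- match.arg(recipe, c("simulation", "insulin", "npc"))
    if (recipe == "insulin") {
      n_neighbors <- 10; min_dist <- 0.1
      reg <- fingerprint_registry()
      feature_subset <- c(reg$name[reg$family == "circularity"],
                          "L_s_ratio", "L_l_ratio")
    } else if (recipe == "npc") {
      n_neighbors <- 10; min_dist <- 0.2
    }
  }
  if (!is.null(feature_subset))
    fp <- fp[, intersect(feature_subset, names(fp)), drop = FALSE]
  if (nrow(fp) < n_neighbors + 1)
    stop("need at least n_neighbors + 1 = ", n_neighbors + 1,
         " fingerprints, got ", nrow(fp))
  x <- as.matrix(fp)
  x[!is.finite(x)] <- 0
  keep <- apply(x, 2, function(v) stats::sd(v) > 0)
  x <- scale(x[, keep, drop = FALSE])
  emb <- uwot::umap(x, n_components = n_components,
                    n_neighbors = n_neighbors, min_dist = min_dist,
                    seed = seed, n_threads = 1, n_sgd_threads = 1)
  if (!is.null(ids)) attr(emb, "assembly_id") <- ids
  emb
}

#' Group embedded fingerprints with DBSCAN
#'
#' @param coordinates Embedded coordinates (matrix, 2 or 3 columns).
#' @param eps,min_samples DBSCAN parameters (defaults 0.8, 5).
#' @return Integer group labels (`-1` = unassigned) with a `counts`
#'   attribute (points per group).
#' @export
group_embedded <- function(coordinates, eps = 0.8, min_samples = 5) {
  stopifnot(nrow(coordinates) > 0)
  g <- dbscan_points(as.matrix(coordinates), eps = eps,
                     min_samples = min_samples)
  attr(g, "counts") <- table(g)
  g
}

#' Rank fingerprint features by group-discriminating power
#'
#' Random-forest importance of every feature for separating the given
#' groups, normalized to sum to one and sorted in decreasing order.
#'
#' @param fingerprints data.frame of fingerprints (an `assembly_id` column
#'   is ignored).
#' @param group_labels One group label per row; at least two groups with
#'   at least 5 members each.
#' @param method `"impurity"` (mean decrease in Gini, default) or
#'   `"permutation"` (mean decrease in accuracy).
#' @param seed Integer seed of the forest.
#' @return Named numeric vector of importances, decreasing, summing to 1.
#' @export
rank_features <- function(fingerprints, group_labels,
                          method = c("impurity", "permutation"),
                          seed = 42) {
  method <- match.arg(method)
  fp <- as.data.frame(fingerprints)
  fp$assembly_id <- NULL
  grp <- factor(group_labels)
  tab <- table(grp)
  if (length(tab) < 2) stop("feature ranking needs at least two groups")
  if (any(tab < 5)) stop("every group needs at least 5 members")
  x <- as.matrix(fp)
  x[!is.finite(x)] <- 0
  imp <- run_seeded(seed, function() {
    rf <- randomForest::randomForest(x, grp,
                                     importance = method == "permutation")
    if (method == "impurity")
      randomForest::importance(rf, type = 2)[, 1]
    else
      randomForest::importance(rf, type = 1)[, 1]
  })
  imp <- pmax(imp, 0)
  if (sum(imp) == 0) imp[] <- 1
  sort(imp / sum(imp), decreasing = TRUE)
}

#' Quantify assembly radii from areas
#'
#' Converts each area to the radius of the equivalent circle,
#' `sqrt(A / pi)`, fits the radius distribution with a Gaussian by
#' maximum likelihood (mean and ML standard deviation), and propagates to
#' the diameter: `d = 2 * mu_r`, `sigma_d = sqrt(4 * sigma_r^2) = 2 *
#' sigma_r`.
#'
#' @param areas Positive areas (nm^2).
#' @return Object of class `quantification`: `r` (per-assembly radii),
#'   `mu_r`, `sigma_r`, `diameter`, `sigma_d`, `n`.
#' @export
quantify_radius <- function(areas) {
  if (any(!is.finite(areas)) || any(areas <= 0))
    stop("areas must be positive and finite")
  r <- sqrt(areas / pi)
  mu <- mean(r)
  sigma <- sqrt(mean((r - mu)^2))   # ML estimate
  structure(list(r = r, mu_r = mu, sigma_r = sigma,
                 diameter = 2 * mu, sigma_d = 2 * sigma, n = length(r)),
            class = "quantification")
}

#' @export
print.quantification <- function(x, ...) {
  cat(sprintf("<quantification: d = %.1f +/- %.1f nm (N = %d)>\n",
              x$diameter, x$sigma_d, x$n))
  invisible(x)
}
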