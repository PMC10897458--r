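# The clustering pipeline: standardization, density-driven model choice,
# topological failsafe, frame-iterative temporal refinement with a
# data-derived search range, and the smart density filter.

#' Choose and run the initial clustering model
#'
#' The model is picked from the general density of the field of view: with
#' fewer than 1500 points per standardized area (N divided by the
#' standardized x-range times y-range) DBSCAN is used, otherwise HDBSCAN.
#' The goal of this stage is regions of interest, not final clusters;
#' over-merged regions are dissected later by the temporal refinement.
#'
#' @param std_table Standardized localization table (from [standardize()]).
#' @param config A [pipeline_config()].
#' @return List with `model` (`"dbscan"` or `"hdbscan"`), `density`
#'   (points per standardized area) and `labels` (initial region labels,
#'   `-1` = noise).
#' @export
select_initial_model <- function(std_table, config) {
  if (nrow(std_table) == 0) stop("empty table: nothing to cluster")
  dens <- nrow(std_table) /
    (diff(range(std_table$x)) * diff(range(std_table$y)))
  model <- if (config$initial_model != "auto") config$initial_model
           else if (dens < 1500) "dbscan" else "hdbscan"
  pipeline_log("initial model %s (%.1f points per standardized area)",
               model, dens)
  labels <- if (model == "dbscan") {
    dbscan_points(std_table, eps = config$eps,
                  min_samples = config$min_samples)
  } else {
    hdbscan_points(std_table, min_cluster_size = config$min_cluster_size,
                   min_samples = config$min_samples,
                   cluster_selection_epsilon =
                     config$cluster_selection_epsilon)
  }
  list(model = model, density = dens, labels = labels)
}

hist2d_counts <- function(x, y, bins, xlim, ylim) {
  bx <- seq(xlim[1], xlim[2], length.out = bins + 1)
  by <- seq(ylim[1], ylim[2], length.out = bins + 1)
  ix <- pmin(pmax(findInterval(x, bx, rightmost.closed = TRUE), 1L), bins)
  iy <- pmin(pmax(findInterval(y, by, rightmost.closed = TRUE), 1L), bins)
  counts <- matrix(0, bins, bins)
  tab <- table(ix, iy)
  counts[cbind(as.integer(rownames(tab))[row(tab)],
               as.integer(colnames(tab))[col(tab)])] <- as.vector(tab)
  list(counts = counts, ix = ix, iy = iy,
       xmid = (bx[-1] + bx[-length(bx)]) / 2,
       ymid = (by[-1] + by[-length(by)]) / 2)
}

#' Topological failsafe region recovery
#'
#' Fallback used when the initial clustering returns zero regions: the 2D
#' binned localizations are Gaussian-blurred and the largest connected
#' contour region above the 90th density percentile becomes the single
#' initial region.  Always returns at least one region on non-empty input.
#'
#' @inheritParams select_initial_model
#' @return Integer labels: 1 for points inside the recovered region,
#'   `-1` elsewhere.
#' @export
topological_failsafe <- function(std_table, config) {
  n <- nrow(std_table)
  if (n == 0) stop("empty table")
  bins <- config$failsafe_bins
  h <- hist2d_counts(std_table$x, std_table$y, bins,
                     range(std_table$x), range(std_table$y))
  blur <- EBImage::gblur(h$counts, sigma = config$failsafe_sigma)
  # level enclosing `failsafe_percentile` of the blurred density mass
  v <- sort(as.vector(blur), decreasing = TRUE)
  thr <- v[which(cumsum(v) >= config$failsafe_percentile * sum(v))[1]]
  mask <- blur >= thr
  comp <- EBImage::bwlabel(mask)
  if (max(comp) == 0) return(rep(1L, n))  # flat density: everything one region
  pt_comp <- comp[cbind(h$ix, h$iy)]
  per_comp <- tabulate(pt_comp[pt_comp > 0], nbins = max(comp))
  best <- which.max(per_comp)
  pipeline_log("failsafe recovered region with %d of %d points",
               per_comp[best], n)
  ifelse(pt_comp == best, 1L, -1L)
}

#' Data-derived search range of a region
#'
#' From the pairwise spatial distances of a MinMax-scaled region, the
#' distances inside the interquartile band (order-statistic quartiles,
#' inclusive) give the standard error on the mean, and the search range is
#' `sqrt(radius_ratio * SEM)` -- the square root of the 95\% confidence
#' interval of the SEM at the default `radius_ratio = 1.96`.  Pairwise
#' distances are computed on at most `pdist_max` (default 500) points
#' subsampled in canonical coordinate order; because the SEM shrinks with
#' the number of distances, this cap sets the scale of the search range
#' (see the methods vignette), and profiles tune it per structure type.
#'
#' @param region_points MinMax-scaled region table (columns `x`, `y`).
#' @param config A [pipeline_config()] (fields `radius_ratio`, `pdist_max`).
#' @return List of class `search_range`: `r_search`, `sem`, `n_distances`,
#'   `iqr` (the inclusive band).
#' @export
compute_search_range <- function(region_points, config = pipeline_config()) {
  n <- nrow(region_points)
  if (n < 3) stop("search range needs at least 3 points")
  idx <- seq_len(n)
  if (n > config$pdist_max) {
    # subsample in canonical coordinate order so the draw, and hence the
    # search range, is invariant to row permutations of the input
    canonical <- order(region_points$x, region_points$y)
    idx <- canonical[sample.int(n, config$pdist_max)]
  }
  d <- as.vector(stats::dist(cbind(region_points$x[idx],
                                   region_points$y[idx])))
  q <- stats::quantile(d, c(0.25, 0.75), type = 1, names = FALSE)
  kept <- d[d >= q[1] & d <= q[2]]
  sdv <- stats::sd(kept)
  if (!is.finite(sdv) || sdv <= 1e-9 * mean(kept))
    stop("zero spread: all interquartile distances identical (degenerate region)")
  sem <- if (identical(config$range_stat, "sd")) sdv
         else sdv / sqrt(length(kept))
  structure(list(r_search = sqrt(config$radius_ratio * sem), sem = sem,
                 n_distances = length(d), iqr = q),
            class = "search_range")
}

#' @export
print.search_range <- function(x, ...) {
  cat(sprintf("<search_range: r = %.4f (SEM %.3g over %d IQR distances)>\n",
              x$r_search, x$sem, x$n_distances))
  invisible(x)
}

#' Temporal refinement of one region
#'
#' Dissects a region of interest into the assemblies that grew inside it.
#' The region is MinMax-rescaled; its search range comes from
#' [compute_search_range()].  Frames are processed from lowest to highest;
#' at each step the accumulated label-free points lying farther than
#' `r_search` from every labelled point are scanned by DBSCAN at
#' `eps = r_search` for new aggregation seeds (a seed cluster must reach
#' `investigate_min_sample` members; the scan's core count defaults to the
#' same value and drops to chain connectivity in the fibril profile), then
#' the radius-neighbor growth vote assigns each remaining label-free point
#' within `r_search` of a labelled point the label of its nearest labelled
#' neighbor, transitively within the frame.  Points are never relabelled;
#' whatever is still label-free after the last frame is noise, except that
#' a region in which nothing ever seeded is kept unsplit (the smart
#' density filter decides its fate).
#'
#' @param region Localization table of one region (original coordinates;
#'   needs `t` for refinement, otherwise returned unsplit).
#' @param config A [pipeline_config()].
#' @return List: `labels` (1..k sub-clusters, `-1` noise), `seed_frame`
#'   (frame at which each sub-cluster was seeded), `r_search`.
#' @export
temporal_refinement <- function(region, config = pipeline_config()) {
  n <- nrow(region)
  if (!"t" %in% names(region) || length(unique(region$t)) < 2)
    return(list(labels = rep(1L, n),
                seed_frame = if ("t" %in% names(region)) min(region$t)
                             else NA_integer_,
                r_search = NA_real_))
  mm <- minmax_scale(region, with_t = TRUE)$table
  r <- compute_search_range(mm, config)$r_search
  coords <- cbind(mm$x, mm$y)           # spatial metric: growth linking
  coords3 <- cbind(mm$x, mm$y, mm$t)    # spatiotemporal metric: seeding
  labels <- integer(n)                  # 0 = label-free
  seed_frame <- integer(0)
  frames <- sort(unique(region$t))
  steps <- split(frames, ceiling(seq_along(frames) / config$refine_stride))
  arrived <- rep(FALSE, n)
  for (st in steps) {
    arrived[region$t %in% st] <- TRUE
    pool <- which(arrived & labels == 0L)
    if (!length(pool)) next
    # new aggregation seeds first, detected in (x, y, t): an onset burst is
    # spatiotemporally dense and far from the labelled points, whereas the
    # ongoing growth of an existing assembly is spatially spread per frame
    # and hugs its labelled frontier, so it never forms a competing seed
    if (length(pool) >= config$investigate_min_sample) {
      seed_coords <- if (identical(config$seed_space, "xy")) coords
                     else coords3
      cand <- pool
      labelled <- which(labels > 0L)
      if (length(labelled)) {
        nn3 <- RANN::nn2(seed_coords[labelled, , drop = FALSE],
                         seed_coords[cand, , drop = FALSE], k = 1)
        cand <- cand[nn3$nn.dists[, 1] > r]
      }
      if (length(cand) >= config$investigate_min_sample) {
        db <- dbscan_points(seed_coords[cand, , drop = FALSE], eps = r,
                            min_samples = config$seed_chain %||%
                              config$investigate_min_sample)
        for (cl in seq_len(max(0L, max(db)))) {
          members <- cand[db == cl]
          if (length(members) < config$investigate_min_sample) next
          new_lab <- length(seed_frame) + 1L
          labels[members] <- new_lab
          seed_frame[new_lab] <- st[length(st)]
        }
        pool <- pool[labels[pool] == 0L]
      }
    }
    # then the radius-neighbor growth vote in (x, y)
    labelled <- which(labels > 0L)
    while (length(labelled) && length(pool)) {
      nn <- RANN::nn2(coords[labelled, , drop = FALSE],
                      coords[pool, , drop = FALSE], k = 1)
      take <- nn$nn.dists[, 1] <= r
      if (!any(take)) break
      labels[pool[take]] <- labels[labelled[nn$nn.idx[take, 1]]]
      labelled <- pool[take]       # newly labelled frontier only
      pool <- pool[!take]
      if (!isTRUE(config$vote_closure)) break
    }
  }
  if (!length(seed_frame)) {
    # nothing seeded (search range below the local point spacing): keep the
    # region unsplit; the smart density filter decides its fate
    return(list(labels = rep(1L, n), seed_frame = min(region$t),
                r_search = r))
  }
  labels[labels == 0L] <- -1L
  list(labels = labels, seed_frame = seed_frame, r_search = r)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

knn_density <- function(points, k) {
  n <- nrow(points)
  if (n < 2) return(rep(0, n))
  kk <- min(k + 1L, n)          # +1: self is its own first neighbor
  d <- RANN::nn2(points, k = kk)$nn.dists[, kk]
  (kk - 1L) / (pi * pmax(d, 1e-300)^2)
}

#' Smart density filter
#'
#' Rejects candidate clusters whose density is indistinguishable from
#' background.  The noise density baseline is estimated from (up to) 500
#' randomly sampled initial-noise points: each sampled point's local density
#' is `k / (pi * d_k^2)` with `d_k` its k-th nearest-neighbor distance
#' (k = 10 by default), only densities above their 25th percentile are kept
#' (avoiding underestimation from the empty space around high-density
#' areas), and the baseline is their mean plus one standard deviation.  A
#' candidate survives with `filter_mode = "strict"` iff its mean member
#' density exceeds the baseline AND it has at least `final_min_points`
#' points; with `"lose"` either condition suffices; with `"none"` all pass.
#'
#' @param candidates List of candidate-cluster tables (standardized spatial
#'   coordinates, columns `x`, `y`).
#' @param noise_points Table of initial-noise points on the same scale (may
#'   be empty: the baseline is then 0 and the filter reduces to the size
#'   rule, with a warning under `"strict"`).
#' @param config A [pipeline_config()].
#' @return data.frame with one row per candidate: `n`, `density`,
#'   `passes_density`, `passes_size`, `keep`, plus attribute `baseline`.
#' @export
smart_density_filter <- function(candidates, noise_points,
                                 config = pipeline_config()) {
  stopifnot(length(candidates) >= 1)
  k <- config$density_k
  if (nrow(noise_points) >= 2) {
    take <- seq_len(nrow(noise_points))
    if (length(take) > config$noise_sample) {
      canonical <- order(noise_points$x, noise_points$y)
      take <- canonical[sample.int(length(take), config$noise_sample)]
    }
    dens <- knn_density(cbind(noise_points$x, noise_points$y)[take, ,
                                                              drop = FALSE], k)
    dens <- dens[dens >= stats::quantile(dens, 0.25, names = FALSE)]
    baseline <- mean(dens) + stats::sd(dens)
    if (!is.finite(baseline)) baseline <- mean(dens)
  } else {
    baseline <- 0
    if (config$filter_mode == "strict")
      warning("no noise points to estimate a density baseline; ",
              "the smart filter reduces to the size rule")
  }
  cand_dens <- vapply(candidates, function(cl)
    mean(knn_density(cbind(cl$x, cl$y), k)), 0)
  sizes <- vapply(candidates, nrow, 0L)
  passes_density <- cand_dens > baseline
  passes_size <- sizes >= config$final_min_points
  keep <- switch(config$filter_mode,
                 strict = passes_density & passes_size,
                 lose = passes_density | passes_size,
                 none = rep(TRUE, length(candidates)))
  pipeline_log("smart filter baseline %.3g: %d of %d candidates kept",
               baseline, sum(keep), length(keep))
  structure(data.frame(n = sizes, density = cand_dens,
                       passes_density = passes_density,
                       passes_size = passes_size, keep = keep),
            baseline = baseline)
}

#' Cluster a localization table into individual assemblies
#'
#' The full pipeline: standardize (x, y and, when present, t), pick and run
#' the initial density model, recover a region through the topological
#' failsafe if nothing was found, drop regions below `rough_min_points`,
#' dissect every region by temporal refinement, and apply the smart density
#' filter.  Deterministic given `(table, config)`: the configuration seed
#' drives the only stochastic steps (noise and pairwise-distance
#' subsampling).
#'
#' @param table Localization table (`x`, `y`, optional `t`).
#' @param config A [pipeline_config()]; profiles supply per-recipe defaults.
#' @return Object of class `cluster_result`: `labels` (per-row integer,
#'   `-1` = noise, assemblies numbered from 1), `clusters` (per-assembly
#'   metadata: region, seed frame, size, density, filter verdict), `params`
#'   (model choice, field density, per-region search ranges, density
#'   baseline).
#' @export
cluster_localizations <- function(table, config = pipeline_config()) {
  validate_localizations(table)
  n <- nrow(table)
  if (n == 0)
    return(structure(list(labels = integer(0),
                          clusters = data.frame(), params = list()),
                     class = "cluster_result"))
  run_seeded(config$seed, function() {
    static <- isTRUE(config$static) || !"t" %in% names(table)
    std <- standardize(table, with_t = !static)$table
    if (static) std$t <- NULL   # static mode clusters in 2D
    init <- select_initial_model(std, config)
    labels0 <- init$labels
    used_failsafe <- FALSE
    # rough size filter
    sizes0 <- tabulate(labels0[labels0 > 0L])
    for (rg in which(sizes0 < config$rough_min_points))
      labels0[labels0 == rg] <- -1L
    if (!any(labels0 > 0L)) {
      # no usable region: density-contour failsafe supplies the only one
      labels0 <- topological_failsafe(std, config)
      used_failsafe <- TRUE
    }
    noise_idx <- which(labels0 == -1L)

    final <- rep(-1L, n)
    meta <- list()
    r_search <- c()
    next_id <- 0L
    for (rg in sort(unique(labels0[labels0 > 0L]))) {
      idx <- which(labels0 == rg)
      region <- table[idx, , drop = FALSE]
      ref <- if (static) list(labels = rep(1L, length(idx)),
                              seed_frame = NA_integer_, r_search = NA_real_)
        else tryCatch(temporal_refinement(region, config),
                      error = function(e) list(labels = rep(1L, length(idx)),
                                               seed_frame = NA_integer_,
                                               r_search = NA_real_))
      r_search[as.character(rg)] <- ref$r_search
      for (sub in seq_len(max(0L, max(ref$labels)))) {
        members <- idx[ref$labels == sub]
        if (!length(members)) next
        next_id <- next_id + 1L
        final[members] <- next_id
        meta[[next_id]] <- data.frame(
          cluster = next_id, region = rg,
          seed_frame = if (length(ref$seed_frame) >= sub)
            ref$seed_frame[sub] else NA_integer_,
          n = length(members))
      }
    }
    params <- list(model = init$model, field_density = init$density,
                   used_failsafe = used_failsafe, r_search = r_search,
                   profile_seed = config$seed)
    if (next_id == 0L)
      return(structure(list(labels = final, clusters = data.frame(),
                            params = params), class = "cluster_result"))
    meta <- do.call(rbind, meta)

    candidates <- lapply(seq_len(next_id),
                         function(cl) std[final == cl, , drop = FALSE])
    verdict <- smart_density_filter(candidates, std[noise_idx, , drop = FALSE],
                                    config)
    meta$density <- verdict$density
    meta$keep <- verdict$keep
    params$density_baseline <- attr(verdict, "baseline")
    # drop rejected candidates and renumber survivors
    remap <- integer(next_id)
    remap[meta$cluster[meta$keep]] <- seq_len(sum(meta$keep))
    final <- ifelse(final > 0L & meta$keep[pmax(final, 1L)],
                    remap[pmax(final, 1L)], -1L)
    kept_meta <- meta[meta$keep, , drop = FALSE]
    kept_meta$cluster <- remap[kept_meta$cluster]
    rownames(kept_meta) <- NULL
    structure(list(labels = as.integer(final), clusters = kept_meta,
                   params = params, filter = verdict),
              class = "cluster_result")
  })
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result: %d assemblies, %d/%d points labelled (%s)>\n",
              nrow(x$clusters), sum(x$labels > 0L), length(x$labels),
              x$params$model %||% "?"))
  invisible(x)
}
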