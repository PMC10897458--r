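# Morphological fingerprinting: one named feature vector per assembly,
# built from four families -- circularity (5), symmetry (7), geometric
# interior (3) and graph network (25+) -- plus the point count.  Degenerate
# geometry yields flagged sentinel values instead of exceptions so batch
# fingerprinting never aborts.

REGISTRY_VERSION <- "1.0"

#' Feature registry of the morphology fingerprint
#'
#' Names and families of every feature a fingerprint can contain, in the
#' order they are emitted.  The registry is versioned so features can be
#' added without breaking stored fingerprints.
#'
#' @return data.frame with columns `name`, `family`, `optional`; attribute
#'   `version`.
#' @export
fingerprint_registry <- function() {
  geometric <- c("Area", "density", "max_extent")
  graph <- c("n_nodes", "n_edges", "edge_density", "degree_mean", "degree_sd",
             "degree_max", "degree_min", "n_components",
             "largest_component_frac", "transitivity_global",
             "transitivity_local_mean", "degree_assortativity",
             "mst_total_length", "mst_mean_edge", "mst_sd_edge",
             "mst_max_edge", "mst_leaf_count", "mst_leaf_frac",
             "mst_branch_count", "mst_branch_frac", "mst_degree_max",
             "mst_diameter_length", "mst_diameter_hops",
             "longest_shortest_path", "avg_shortest_path", "graph_radius",
             "L_s_ratio", "L_l_ratio")
  gauss <- c("mu_N", "sig_N", "W_N")
  circularity <- c("isoperimetric_quotient", "contour_aspect_ratio",
                   "radial_cv", "solidity", "equiv_radius_ratio")
  symmetry <- c("quad_ratio", "quad_entropy", "balance_x", "balance_y",
                "extent_balance_x", "extent_balance_y", "diag_correlation")
  reg <- rbind(
    data.frame(name = geometric, family = "geometric", optional = FALSE),
    data.frame(name = graph, family = "graph", optional = FALSE),
    data.frame(name = gauss, family = "graph", optional = TRUE),
    data.frame(name = circularity, family = "circularity", optional = FALSE),
    data.frame(name = symmetry, family = "symmetry", optional = FALSE),
    data.frame(name = "N_points", family = "count", optional = TRUE))
  attr(reg, "version") <- REGISTRY_VERSION
  reg
}

#' Align a structure to its principal axes
#'
#' Centers the point set at its centroid and rotates it so the major
#' principal axis points along the first coordinate axis, with a
#' deterministic sign convention (positive third moment along each axis),
#' giving pose-invariant downstream features.
#'
#' @param points data.frame or matrix with columns `x`, `y`.
#' @return data.frame `x`, `y`; attributes `rotation` (2x2 matrix) and
#'   `minimal` (`TRUE` when < 3 points prevented rotation).
#' @export
normalize_structure <- function(points) {
  p <- as.matrix(as.data.frame(points)[, c("x", "y")])
  p <- sweep(p, 2, colMeans(p))
  if (nrow(p) < 3) {
    out <- data.frame(x = p[, 1], y = p[, 2])
    attr(out, "rotation") <- diag(2)
    attr(out, "minimal") <- TRUE
    return(out)
  }
  ev <- eigen(stats::cov(p), symmetric = TRUE)
  rot <- ev$vectors                      # columns: major, minor axis
  a <- p %*% rot
  for (j in 1:2) {
    m3 <- mean(a[, j]^3)
    if (m3 < 0) { a[, j] <- -a[, j]; rot[, j] <- -rot[, j] }
  }
  out <- data.frame(x = a[, 1], y = a[, 2])
  attr(out, "rotation") <- rot
  attr(out, "minimal") <- FALSE
  out
}

polygon_area <- function(x, y) {
  n <- length(x)
  abs(sum(x * y[c(2:n, 1)] - x[c(2:n, 1)] * y)) / 2
}

tri_area <- function(x, y)
  abs((x[2] - x[1]) * (y[3] - y[1]) - (x[3] - x[1]) * (y[2] - y[1])) / 2

#' Geometric interior features
#'
#' Delaunay-triangulates the structure, fits a lognormal distribution to the
#' triangle edge lengths by log-moment matching, prunes edges beyond the
#' fitted 95\% right tail, and reports the summed area of fully surviving
#' triangles, the mean density `N_points / Area`, and the furthest
#' connected point pair (`max_extent`).  The pruning removes spurious long
#' bridges so the area follows the occupied region rather than the convex
#' hull.  Collinear or too-small input yields zero sentinels with
#' `flags = "degenerate"`.
#'
#' @param points data.frame with `x`, `y` (nm).
#' @return List: `features` (named numeric: Area, density, max_extent),
#'   `radius` (the 95\% edge-length cutoff, used by [graph_features()]),
#'   `flags` (character vector of sentinel markers, empty when clean).
#' @export
geometric_features <- function(points) {
  n <- nrow(points)
  sentinel <- list(features = c(Area = 0, density = 0, max_extent = 0),
                   radius = 0, flags = "degenerate")
  if (n < 3) return(sentinel)
  tm <- tryCatch(interp::tri.mesh(points$x, points$y, duplicate = "remove"),
                 error = function(e) NULL)
  if (is.null(tm)) return(sentinel)
  tri <- interp::triangles(tm)
  if (!nrow(tri)) return(sentinel)
  px <- tm$x; py <- tm$y
  elen <- function(a, b) sqrt((px[a] - px[b])^2 + (py[a] - py[b])^2)
  e1 <- elen(tri[, 1], tri[, 2])
  e2 <- elen(tri[, 2], tri[, 3])
  e3 <- elen(tri[, 1], tri[, 3])
  pos <- c(e1, e2, e3); pos <- pos[pos > 0]
  if (!length(pos)) return(sentinel)
  ml <- mean(log(pos)); sl <- stats::sd(log(pos))
  cutoff <- if (is.finite(sl) && sl > 0) stats::qlnorm(0.95, ml, sl)
            else max(pos)
  keep <- e1 <= cutoff & e2 <= cutoff & e3 <= cutoff
  area <- sum(abs((px[tri[keep, 2]] - px[tri[keep, 1]]) *
                    (py[tri[keep, 3]] - py[tri[keep, 1]]) -
                  (px[tri[keep, 3]] - px[tri[keep, 1]]) *
                    (py[tri[keep, 2]] - py[tri[keep, 1]])) / 2)
  # furthest pair connected through surviving edges
  surv_pts <- unique(as.vector(tri[keep, 1:3]))
  if (length(surv_pts) < 2) surv_pts <- seq_along(px)
  hull_pts <- surv_pts[grDevices::chull(px[surv_pts], py[surv_pts])]
  dmat <- as.matrix(stats::dist(cbind(px[hull_pts], py[hull_pts])))
  extent <- max(dmat)
  if (area <= 0)
    return(list(features = c(Area = 0, density = 0, max_extent = extent),
                radius = cutoff, flags = "zero_area"))
  list(features = c(Area = area, density = n / area, max_extent = extent),
       radius = cutoff, flags = character(0))
}

#' Graph-network features
#'
#' Builds a radius-to-neighbors graph (threshold from the geometric stage's
#' pruned edge-length cutoff) and its minimum spanning tree (edge lengths as
#' weights), and summarizes both: degree and component statistics, global
#' and local clustering, MST edge-length/leaf/branch/depth statistics, the
#' weighted graph diameter (`longest_shortest_path`), and the
#' path-straightness ratios `L_s_ratio` / `L_l_ratio` (shortest-path and
#' MST-path length between the two max-extent endpoints of the largest
#' component, divided by their Euclidean separation).  Structures above
#' `max_points` localizations are subsampled deterministically before the
#' graph is built to bound the all-pairs shortest-path cost.
#'
#' @param points data.frame with `x`, `y`.
#' @param radius Positive distance threshold of the neighbor graph.
#' @param max_points Subsampling cap for the graph stage (default 600).
#' @param gauss_fit Also emit the Gaussian fit (`mu_N`, `sig_N`, `W_N`) to
#'   the per-point local-density histogram.
#' @return List: `features` (named numeric), `flags`.
#' @export
graph_features <- function(points, radius, max_points = 600,
                           gauss_fit = TRUE) {
  flags <- character(0)
  p <- as.data.frame(points)[, c("x", "y")]
  if (nrow(p) > max_points) {
    p <- p[run_seeded(7L, function()
      sort(sample.int(nrow(p), max_points))), , drop = FALSE]
    flags <- c(flags, "subsampled")
  }
  n <- nrow(p)
  if (n < 2 || !is.finite(radius) || radius <= 0) {
    reg <- fingerprint_registry()
    nm <- reg$name[reg$family == "graph"]
    if (!gauss_fit) nm <- setdiff(nm, c("mu_N", "sig_N", "W_N"))
    f <- stats::setNames(rep(0, length(nm)), nm)
    f["n_nodes"] <- n
    return(list(features = f, flags = c(flags, "degenerate")))
  }
  dmat <- as.matrix(stats::dist(p))
  adj <- dmat <= radius
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  igraph::E(g)$weight <- dmat[igraph::as_edgelist(g, names = FALSE)]
  deg <- igraph::degree(g)
  comps <- igraph::components(g)
  big <- which(comps$membership == which.max(comps$csize))
  gs <- igraph::induced_subgraph(g, big)
  mst_big <- igraph::mst(gs, weights = igraph::E(gs)$weight)
  mst_w <- igraph::E(mst_big)$weight
  if (!length(mst_w)) mst_w <- 0
  mst_deg <- igraph::degree(mst_big)
  dists <- igraph::distances(gs, weights = igraph::E(gs)$weight)
  lsp <- max(dists[is.finite(dists)])
  hop_d <- igraph::distances(mst_big, weights = NA)
  ecc <- apply(dists, 1, max)
  # max-extent endpoints of the largest component
  bigxy <- p[big, , drop = FALSE]
  hull <- grDevices::chull(bigxy$x, bigxy$y)
  hd <- as.matrix(stats::dist(bigxy[hull, , drop = FALSE]))
  ij <- which(hd == max(hd), arr.ind = TRUE)[1, ]
  e1 <- hull[ij[1]]; e2 <- hull[ij[2]]
  ext <- max(hd)
  if (ext > 0 && e1 != e2) {
    sp <- dists[e1, e2]
    mp <- igraph::distances(mst_big, v = e1, to = e2,
                            weights = igraph::E(mst_big)$weight)[1, 1]
    L_s <- if (is.finite(sp)) sp / ext else 0
    L_l <- if (is.finite(mp)) mp / ext else 0
  } else { L_s <- L_l <- 0; flags <- c(flags, "point_like") }
  tr_g <- igraph::transitivity(g, type = "global")
  tr_l <- igraph::transitivity(g, type = "localaverage", isolates = "zero")
  assort <- suppressWarnings(igraph::assortativity_degree(g))
  f <- c(
    n_nodes = n,
    n_edges = igraph::ecount(g),
    edge_density = igraph::edge_density(g),
    degree_mean = mean(deg), degree_sd = stats::sd(deg) %||% 0,
    degree_max = max(deg), degree_min = min(deg),
    n_components = comps$no,
    largest_component_frac = max(comps$csize) / n,
    transitivity_global = if (is.finite(tr_g)) tr_g else 0,
    transitivity_local_mean = if (is.finite(tr_l)) tr_l else 0,
    degree_assortativity = if (is.finite(assort)) assort else 0,
    mst_total_length = sum(mst_w),
    mst_mean_edge = mean(mst_w),
    mst_sd_edge = if (length(mst_w) > 1) stats::sd(mst_w) else 0,
    mst_max_edge = max(mst_w),
    mst_leaf_count = sum(mst_deg == 1),
    mst_leaf_frac = mean(mst_deg == 1),
    mst_branch_count = sum(mst_deg >= 3),
    mst_branch_frac = mean(mst_deg >= 3),
    mst_degree_max = max(mst_deg),
    mst_diameter_length = igraph::diameter(mst_big,
                                           weights = igraph::E(mst_big)$weight),
    mst_diameter_hops = max(hop_d[is.finite(hop_d)]),
    longest_shortest_path = lsp,
    avg_shortest_path = mean(dists[is.finite(dists) & dists > 0]) %||% 0,
    graph_radius = min(ecc),
    L_s_ratio = L_s,
    L_l_ratio = L_l)
  f[!is.finite(f)] <- 0
  if (gauss_fit) {
    dens <- knn_density(as.matrix(p), k = min(10L, n - 1L))
    gfit <- fit_density_gaussian(dens)
    f <- c(f, gfit)
  }
  list(features = f, flags = flags)
}

# Gaussian fit (mean, SD, amplitude) to the histogram of per-point local
# densities; falls back to moment estimates when the fit does not converge.
fit_density_gaussian <- function(dens) {
  h <- graphics::hist(dens, breaks = "Sturges", plot = FALSE)
  df <- data.frame(x = h$mids, y = h$counts)
  start <- list(mu = mean(dens), sig = max(stats::sd(dens), 1e-12),
                W = max(h$counts))
  fit <- tryCatch(
    suppressWarnings(
      stats::nls(y ~ W * exp(-(x - mu)^2 / (2 * sig^2)), data = df,
                 start = start,
                 control = stats::nls.control(warnOnly = TRUE))),
    error = function(e) NULL)
  if (!is.null(fit)) {
    cf <- stats::coef(fit)
    out <- c(mu_N = unname(cf["mu"]), sig_N = abs(unname(cf["sig"])),
             W_N = unname(cf["W"]))
    if (all(is.finite(out))) return(out)
  }
  c(mu_N = start$mu, sig_N = start$sig, W_N = start$W)
}

#' Circularity features
#'
#' Bins the structure into a 2D histogram (64 x 64 over the aligned bounding
#' box), Gaussian-blurs the counts (sigma 2 bins), thresholds at the 90th
#' percentile of the blurred density and takes the largest contour of that
#' top-decile region.  Five scale-free scalars follow: the isoperimetric
#' quotient `4*pi*A/P^2`, the contour aspect ratio, the coefficient of
#' variation of the radial contour distances, solidity (contour area over
#' its convex-hull area), and the equivalent-circle radius ratio
#' `sqrt(A/pi) / max radial distance`.  Below 10 points the convex hull of
#' the points serves as a coarse contour (flagged).
#'
#' @param points data.frame with `x`, `y` (aligned coordinates).
#' @param bins,blur_sigma,percentile Histogram constants.
#' @return List: `features` (named numeric), `flags`.
#' @export
circularity_features <- function(points, bins = 64, blur_sigma = 2,
                                 percentile = 0.90) {
  flags <- character(0)
  n <- nrow(points)
  sentinel <- list(features = c(isoperimetric_quotient = 0,
                                contour_aspect_ratio = 0, radial_cv = 0,
                                solidity = 0, equiv_radius_ratio = 0),
                   flags = "degenerate")
  if (n < 3) return(sentinel)
  if (n < 10) {
    hull <- grDevices::chull(points$x, points$y)
    if (length(hull) < 3) return(sentinel)
    cx <- points$x[hull]; cy <- points$y[hull]
    flags <- c(flags, "coarse_contour")
  } else {
    rx <- range(points$x); ry <- range(points$y)
    pad <- c(diff(rx), diff(ry)) * 2 / bins + 1e-9
    h <- hist2d_counts(points$x, points$y, bins,
                       rx + c(-pad[1], pad[1]), ry + c(-pad[2], pad[2]))
    blur <- EBImage::gblur(h$counts, sigma = blur_sigma)
    # density level enclosing `percentile` of the blurred mass, so flat-top
    # structures contour at their outline rather than at sampling speckle
    v <- sort(as.vector(blur), decreasing = TRUE)
    thr <- v[which(cumsum(v) >= percentile * sum(v))[1]]
    cl <- grDevices::contourLines(h$xmid, h$ymid, blur, levels = thr)
    if (!length(cl)) return(sentinel)
    areas <- vapply(cl, function(cc) polygon_area(cc$x, cc$y), 0)
    best <- cl[[which.max(areas)]]
    cx <- best$x; cy <- best$y
  }
  A <- polygon_area(cx, cy)
  if (A <= 0) return(sentinel)
  P <- sum(sqrt(diff(c(cx, cx[1]))^2 + diff(c(cy, cy[1]))^2))
  ctr <- c(mean(cx), mean(cy))
  rad <- sqrt((cx - ctr[1])^2 + (cy - ctr[2])^2)
  ev <- eigen(stats::cov(cbind(cx, cy)), symmetric = TRUE)$values
  hull2 <- grDevices::chull(cx, cy)
  hull_A <- polygon_area(cx[hull2], cy[hull2])
  f <- c(isoperimetric_quotient = 4 * pi * A / P^2,
         contour_aspect_ratio = sqrt(max(ev[1], 0) /
                                       max(ev[2], .Machine$double.eps)),
         radial_cv = stats::sd(rad) / mean(rad),
         solidity = if (hull_A > 0) A / hull_A else 0,
         equiv_radius_ratio = sqrt(A / pi) / max(rad))
  f[!is.finite(f)] <- 0
  list(features = f, flags = flags)
}

#' Symmetry features
#'
#' Seven scalars from quadrant occupancy and extent about the centroid of
#' the aligned structure: the (Laplace-smoothed) max/min quadrant count
#' ratio, normalized quadrant entropy, left/right and up/down count
#' balances, extent balances along both axes, and the diagonal-quadrant
#' correlation `(q1 + q3 - q2 - q4) / N`.  Counts are reflection invariant.
#'
#' @param points data.frame with `x`, `y` (centered coordinates).
#' @return List: `features` (named numeric), `flags`.
#' @export
symmetry_features <- function(points) {
  x <- points$x - mean(points$x)
  y <- points$y - mean(points$y)
  n <- length(x)
  q <- c(sum(x >= 0 & y >= 0), sum(x < 0 & y >= 0),
         sum(x < 0 & y < 0), sum(x >= 0 & y < 0))
  fr <- q / n
  ent <- -sum(ifelse(fr > 0, fr * log(fr), 0)) / log(4)
  ext_bal <- function(v) {
    hi <- max(v); lo <- -min(v)
    if (max(hi, lo) <= 0) return(1)
    max(min(hi, lo), 0) / max(hi, lo)
  }
  f <- c(quad_ratio = (max(q) + 1) / (min(q) + 1),
         quad_entropy = ent,
         balance_x = abs(sum(x >= 0) - sum(x < 0)) / n,
         balance_y = abs(sum(y >= 0) - sum(y < 0)) / n,
         extent_balance_x = ext_bal(x),
         extent_balance_y = ext_bal(y),
         diag_correlation = abs(q[1] + q[3] - q[2] - q[4]) / n)
  list(features = f, flags = character(0))
}

#' Compute the morphology fingerprint of one assembly
#'
#' Aligns the structure to its principal axes, then assembles the full named
#' feature vector: geometric interior (Delaunay area, density, extent),
#' graph network (radius graph + MST statistics, path-straightness ratios,
#' optional local-density Gaussian fit `mu_N`/`sig_N`/`W_N`), circularity
#' (density-contour shape) and symmetry (quadrant occupancy), plus
#' `N_points`.  Works from as few as 4 detections; degenerate geometry is
#' reported through the `flags` attribute, never as silent `NaN`.
#'
#' @param points data.frame with `x`, `y` (and ignored extra columns).
#' @param gauss_fit Include the density-histogram Gaussian fit triplet
#'   (disable for recipes that omit it).
#' @param include_n_points Include the raw localization count (disable when
#'   classifying structures of deliberately matched size).
#' @param max_graph_points Subsampling cap of the graph stage.
#' @return Named numeric vector (>= 40 features with all options on);
#'   attributes `flags`, `registry_version`.
#' @export
compute_fingerprint <- function(points, gauss_fit = TRUE,
                                include_n_points = TRUE,
                                max_graph_points = 600) {
  points <- as.data.frame(points)
  if (nrow(points) < 4)
    stop("fingerprinting needs at least 4 localizations, got ", nrow(points))
  aligned <- normalize_structure(points)
  geo <- geometric_features(aligned)
  gra <- graph_features(aligned, radius = geo$radius,
                        max_points = max_graph_points, gauss_fit = gauss_fit)
  cir <- circularity_features(aligned)
  sym <- symmetry_features(aligned)
  f <- c(geo$features, gra$features, cir$features, sym$features)
  if (include_n_points) f <- c(f, N_points = nrow(points))
  attr(f, "flags") <- unique(c(geo$flags, gra$flags, cir$flags, sym$flags))
  attr(f, "registry_version") <- REGISTRY_VERSION
  f
}

#' Fingerprint every assembly of a clustering result
#'
#' @param table The localization table that was clustered.
#' @param labels Integer assembly labels (`-1` = noise), e.g.
#'   `cluster_result$labels`.
#' @param min_points Assemblies below this size are skipped (default 4).
#' @param ... Passed to [compute_fingerprint()].
#' @return data.frame: one row per assembly, fingerprint features plus
#'   `assembly_id`.
#' @export
fingerprint_assemblies <- function(table, labels, min_points = 4, ...) {
  ids <- sort(unique(labels[labels > 0L]))
  rows <- list()
  for (id in ids) {
    pts <- table[labels == id, , drop = FALSE]
    if (nrow(pts) < min_points) next
    fp <- compute_fingerprint(pts, ...)
    rows[[length(rows) + 1L]] <-
      cbind(data.frame(assembly_id = id), as.data.frame(t(fp)))
  }
  if (!length(rows)) return(data.frame())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
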