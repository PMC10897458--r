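# Density-based clustering engines used by the pipeline.  DBSCAN runs on a
# grid-hashed fixed-radius neighborhood (compiled); HDBSCAN follows the
# standard construction: core distances, minimum spanning tree of the mutual
# reachability graph, single-linkage hierarchy, condensed tree at
# min_cluster_size, excess-of-mass cluster selection with an optional
# cluster_selection_epsilon merge threshold.

as_coord_matrix <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x[, intersect(c("x", "y", "t"),
                                                     names(x)), drop = FALSE])
  storage.mode(x) <- "double"
  x
}

#' DBSCAN clustering
#'
#' Classic density-based clustering: a point is core if its closed
#' `eps`-neighborhood holds at least `min_samples` points (itself included);
#' clusters are the connected components of core points plus their border
#' points.
#'
#' @param x Numeric matrix (2 or 3 columns) or localization data.frame.
#' @param eps Neighborhood radius.
#' @param min_samples Minimum neighborhood size (point itself included).
#' @return Integer labels, `-1` = noise, clusters numbered from 1.
#' @export
dbscan_points <- function(x, eps, min_samples) {
  x <- as_coord_matrix(x)
  if (nrow(x) == 0) return(integer(0))
  stopifnot(eps > 0, min_samples >= 1)
  as.integer(cpp_dbscan(x, eps, as.integer(min_samples)))
}

#' HDBSCAN clustering
#'
#' Hierarchical density-based clustering over all scales: builds the mutual
#' reachability minimum spanning tree from the `min_samples`-NN core
#' distances, condenses the single-linkage hierarchy at `min_cluster_size`,
#' and selects clusters by excess of mass.  With a positive
#' `cluster_selection_epsilon`, splits occurring below that distance are not
#' honoured: a selected cluster born at a smaller distance is replaced by its
#' lowest ancestor born at or above the threshold.
#'
#' @inheritParams dbscan_points
#' @param min_cluster_size Smallest size a condensed cluster may have.
#' @param min_samples Neighborhood size of the core distance (point itself
#'   included); defaults to `min_cluster_size` capped at 10.
#' @param cluster_selection_epsilon Distance threshold below which clusters
#'   are merged (0 disables).
#' @param allow_single_cluster Permit the hierarchy root as a cluster.
#' @return Integer labels, `-1` = noise, clusters numbered from 1.
#' @export
hdbscan_points <- function(x, min_cluster_size = 5, min_samples = NULL,
                           cluster_selection_epsilon = 0,
                           allow_single_cluster = FALSE) {
  x <- as_coord_matrix(x)
  n <- nrow(x)
  if (n == 0) return(integer(0))
  if (is.null(min_samples)) min_samples <- min(min_cluster_size, 10)
  min_cluster_size <- max(2L, as.integer(min_cluster_size))
  if (n <= min_cluster_size || n <= min_samples) return(rep(-1L, n))

  nn <- RANN::nn2(x, k = min(min_samples, n))
  core <- nn$nn.dists[, min(min_samples, n)]
  mst <- cpp_mst_mutual_reach(x, core)
  ord <- order(mst[, 3])
  merges <- cpp_single_linkage(as.integer(mst[ord, 1]),
                               as.integer(mst[ord, 2]), mst[ord, 3], n)
  condensed_labels(merges, n, min_cluster_size, cluster_selection_epsilon,
                   allow_single_cluster)
}

node_size <- function(v, merges, n) ifelse(v <= n, 1, merges[v - n, 4])

leaves_under <- function(v, merges, n) {
  stack <- v
  res <- integer(0)
  while (length(stack)) {
    u <- stack[length(stack)]
    stack <- stack[-length(stack)]
    if (u <= n) res[length(res) + 1L] <- u
    else stack <- c(stack, merges[u - n, 1], merges[u - n, 2])
  }
  res
}

condensed_labels <- function(merges, n, mcs, eps, allow_single_cluster) {
  m <- nrow(merges)
  root <- n + m
  max_cl <- 2L * ceiling(n / mcs) + 2L
  cl_parent <- integer(max_cl)
  cl_birth <- numeric(max_cl)       # lambda at creation
  cl_birth_dist <- numeric(max_cl)  # distance at creation
  cl_stab <- numeric(max_cl)
  cl_kids <- integer(max_cl)        # number of condensed children
  n_cl <- 1L
  cl_parent[1] <- 0L; cl_birth[1] <- 0; cl_birth_dist[1] <- Inf

  pt_cl <- rep(NA_integer_, n)
  pt_lambda <- numeric(n)

  node_stack <- integer(2L * m + 2L); cid_stack <- integer(2L * m + 2L)
  sp <- 1L; node_stack[1] <- root; cid_stack[1] <- 1L
  fall <- function(v, cid, lam) {
    lv <- leaves_under(v, merges, n)
    pt_cl[lv] <<- cid
    pt_lambda[lv] <<- lam
    cl_stab[cid] <<- cl_stab[cid] + length(lv) * (lam - cl_birth[cid])
  }
  while (sp > 0L) {
    v <- node_stack[sp]; cid <- cid_stack[sp]; sp <- sp - 1L
    e <- v - n
    d <- merges[e, 3]
    lam <- 1 / max(d, 1e-12)
    L <- merges[e, 1]; R <- merges[e, 2]
    sL <- node_size(L, merges, n); sR <- node_size(R, merges, n)
    bigL <- sL >= mcs; bigR <- sR >= mcs
    if (bigL && bigR) {
      cl_stab[cid] <- cl_stab[cid] + (sL + sR) * (lam - cl_birth[cid])
      for (child in list(L, R)) {
        n_cl <- n_cl + 1L
        cl_parent[n_cl] <- cid
        cl_birth[n_cl] <- lam
        cl_birth_dist[n_cl] <- d
        cl_kids[cid] <- cl_kids[cid] + 1L
        if (child > n) {
          sp <- sp + 1L; node_stack[sp] <- child; cid_stack[sp] <- n_cl
        } else {
          # a bare leaf can only be a cluster when mcs allows size 1;
          # treat it as an immediate fall of its single point
          pt_cl[child] <- n_cl
          pt_lambda[child] <- lam
        }
      }
    } else if (bigL || bigR) {
      keep <- if (bigL) L else R
      drop <- if (bigL) R else L
      fall(drop, cid, lam)
      if (keep > n) {
        sp <- sp + 1L; node_stack[sp] <- keep; cid_stack[sp] <- cid
      } else fall(keep, cid, lam)
    } else {
      fall(L, cid, lam)
      fall(R, cid, lam)
    }
  }

  # excess-of-mass selection, leaves of the condensed tree upward
  selected <- logical(n_cl)
  subtree_stab <- numeric(n_cl)
  kids_of <- split(seq_len(n_cl)[-1], cl_parent[seq_len(n_cl)[-1]])
  for (cid in rev(seq_len(n_cl))) {
    ch <- kids_of[[as.character(cid)]]
    if (is.null(ch)) {
      selected[cid] <- TRUE
      subtree_stab[cid] <- cl_stab[cid]
    } else if (cl_stab[cid] >= sum(subtree_stab[ch])) {
      selected[cid] <- TRUE
      subtree_stab[cid] <- cl_stab[cid]
    } else {
      subtree_stab[cid] <- sum(subtree_stab[ch])
    }
  }
  if (!allow_single_cluster) selected[1] <- FALSE
  # keep only the highest selected cluster on every root-to-leaf path
  has_sel_anc <- logical(n_cl)
  for (cid in seq_len(n_cl)) {
    p <- cl_parent[cid]
    while (p > 0L) {
      if (selected[p]) { has_sel_anc[cid] <- TRUE; break }
      p <- cl_parent[p]
    }
  }
  selected <- selected & !has_sel_anc

  if (eps > 0) {
    merged <- integer(0)
    for (cid in which(selected)) {
      cur <- cid
      while (cl_parent[cur] > 0L && cl_birth_dist[cur] < eps) {
        nxt <- cl_parent[cur]
        if (nxt == 1L && !allow_single_cluster) break
        cur <- nxt
      }
      merged <- c(merged, cur)
    }
    selected <- logical(n_cl)
    selected[unique(merged)] <- TRUE
    has_sel_anc <- logical(n_cl)
    for (cid in seq_len(n_cl)) {
      p <- cl_parent[cid]
      while (p > 0L) {
        if (selected[p]) { has_sel_anc[cid] <- TRUE; break }
        p <- cl_parent[p]
      }
    }
    selected <- selected & !has_sel_anc
  }

  sel_ids <- which(selected)
  labels <- rep(-1L, n)
  if (length(sel_ids)) {
    lab_of <- integer(n_cl)
    lab_of[sel_ids] <- seq_along(sel_ids)
    # nearest selected ancestor (inclusive) of each condensed cluster
    anc_lab <- integer(n_cl)
    for (cid in seq_len(n_cl)) {
      cur <- cid
      while (cur > 0L && !selected[cur]) cur <- cl_parent[cur]
      anc_lab[cid] <- if (cur > 0L) lab_of[cur] else 0L
    }
    ok <- !is.na(pt_cl)
    labels[ok] <- ifelse(anc_lab[pt_cl[ok]] > 0L, anc_lab[pt_cl[ok]], -1L)
  }
  labels
}
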