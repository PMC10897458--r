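# Shared fixtures and small independent utilities for the test suite.
# Everything is generated in code under fixed seeds; no stored data.

# Three Gaussian blobs plus uniform stragglers; used to pin the density
# clustering engines against independently computed reference labels.
blob_fixture <- function() {
  set.seed(42)
  n <- 25
  pts <- rbind(cbind(rnorm(n, 0, .25), rnorm(n, 0, .25)),
               cbind(rnorm(n, 3, .3), rnorm(n, 3, .3)),
               cbind(rnorm(n, 0, .35), rnorm(n, 4, .35)),
               cbind(runif(15, -1.5, 4.5), runif(15, -1.5, 5.5)))
  colnames(pts) <- c("x", "y")
  pts
}

# Adjusted Rand index, implemented directly from the pair-counting formula
# (independent of any clustering code under test).
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_i <- sum(choose2(rowSums(tab)))
  sum_j <- sum(choose2(colSums(tab)))
  total <- choose2(length(a))
  expected <- sum_i * sum_j / total
  (sum_ij - expected) / ((sum_i + sum_j) / 2 - expected)
}

# A compact single steric-growth assembly (dense enough that the refinement
# has no reason to split it).
single_assembly <- function(seed = 9) {
  simulate_steric(0, 300, origin = c(5000, 5000), seed = seed)
}

# Shared reduced-scale simulation suite for the acceptance checks: built
# once per test run, reused across criteria.  Three movies per morphology
# class at the full per-movie composition.
acceptance_suite <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    seeds <- 1:10
    out <- list()
    for (class in c("isotropic", "steric", "fibril")) {
      nA <- if (class == "fibril") 25 else 10
      runs <- list()
      for (s in seeds) {
        mv <- assemble_movie(movie_spec(stats::setNames(nA, class)),
                             seed = 1000L + s)
        cfg <- pipeline_config(class, seed = s)
        res <- cluster_localizations(mv$points, cfg)
        rep <- evaluate_clustering(
          res$labels, mv$points$assembly_id, mv$points$t,
          stats::setNames(mv$assemblies$frame_start,
                          mv$assemblies$assembly_id))
        runs[[s]] <- list(movie = mv, result = res, report = rep)
      }
      out[[class]] <- runs
    }
    cache <<- out
    out
  }
})
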