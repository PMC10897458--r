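test_that("initial model choice follows the density rule", {
  set.seed(21)
  sparse <- data.frame(x = runif(1000), y = runif(1000))
  cfg <- pipeline_config("default")
  init <- select_initial_model(standardize(sparse)$table, cfg)
  expect_equal(init$model, "dbscan")
  expect_lt(init$density, 1500)

  dense <- data.frame(x = runif(20000), y = runif(20000))
  init2 <- select_initial_model(standardize(dense)$table, cfg)
  expect_gte(init2$density, 1500)       # uniform: area ~ 12 standardized
  expect_equal(init2$model, "hdbscan")  # 1500 is already HDBSCAN (strict <)

  expect_error(select_initial_model(data.frame(x = numeric(0),
                                               y = numeric(0)), cfg),
               "empty")
  # profile override wins over the rule
  cfg2 <- pipeline_config("default", initial_model = "hdbscan")
  expect_equal(select_initial_model(standardize(sparse)$table,
                                    cfg2)$model, "hdbscan")
})

test_that("topological failsafe recovers a dense blob from sparse noise", {
  set.seed(31)
  blob <- data.frame(x = rnorm(2000, 0, 40), y = rnorm(2000, 0, 40))
  noise <- data.frame(x = runif(500, -2000, 2000),
                      y = runif(500, -2000, 2000))
  tab <- standardize(rbind(blob, noise))$table
  cfg <- pipeline_config("default")
  mask <- topological_failsafe(tab, cfg)
  expect_gte(mean(mask[1:2000] == 1), 0.95)   # blob inside the region
  expect_lt(mean(mask[2001:2500] == 1), 0.5)  # most noise outside
  # flat field still yields a nonempty region (totality)
  flat <- standardize(data.frame(x = runif(400), y = runif(400)))$table
  expect_gt(sum(topological_failsafe(flat, cfg) == 1), 0)
})

test_that("search range matches the literal brute-force statistic", {
  # independent oracle: quartiles as order statistics, inclusive band,
  # SEM of the kept distances, sqrt(ratio * SEM)
  oracle <- function(pts, ratio) {
    d <- as.vector(dist(pts))
    q <- quantile(d, c(.25, .75), type = 1, names = FALSE)
    kept <- d[d >= q[1] & d <= q[2]]
    sqrt(ratio * sd(kept) / sqrt(length(kept)))
  }
  corners <- data.frame(x = c(0, 1, 1, 0), y = c(0, 0, 1, 1))
  cfg <- pipeline_config("default")
  sr <- compute_search_range(corners, cfg)
  expect_equal(sr$r_search, oracle(corners, 1.96), tolerance = 1e-12)
  expect_equal(sr$r_search, 0.4137, tolerance = 1e-3)
  expect_equal(sr$n_distances, 6)
  # radius_ratio scales the range by its square root
  cfg1 <- pipeline_config("default", radius_ratio = 1)
  expect_equal(compute_search_range(corners, cfg)$r_search /
                 compute_search_range(corners, cfg1)$r_search,
               sqrt(1.96), tolerance = 1e-12)
  # collinear equally spaced points: positive and below the max distance
  line <- data.frame(x = seq(0, 1, length.out = 100), y = rep(0, 100))
  sr2 <- compute_search_range(line, cfg)
  expect_equal(sr2$r_search, oracle(line, 1.96), tolerance = 1e-12)
  expect_gt(sr2$r_search, 0)
  expect_lt(sr2$r_search, 1)
  # all distances identical -> degenerate
  tri <- data.frame(x = c(0, 1, 0.5), y = c(0, 0, sqrt(3) / 2))
  expect_error(compute_search_range(tri, cfg), "zero spread")
})

test_that("temporal refinement dissects overlapping growth by onset", {
  # two assemblies with interleaved halos, onsets 150 frames apart
  a <- simulate_steric(0, 140, origin = c(0, 0), seed = 41)
  b <- simulate_steric(150, 290, origin = c(5000, 0), seed = 43)
  region <- rbind(cbind(a, assembly_id = 1L), cbind(b, assembly_id = 2L))
  cfg <- pipeline_config("simulation", seed = 1)
  set.seed(1)
  ref <- temporal_refinement(region[, c("x", "y", "t")], cfg)
  expect_gte(max(ref$labels), 2)
  # both assemblies recovered with high purity
  for (gt in 1:2) {
    labs <- ref$labels[region$assembly_id == gt & ref$labels > 0]
    expect_gt(mean(labs == as.integer(names(which.max(table(labs))))), 0.9)
  }
  # label purity the other way: the main sub-cluster of each assembly is
  # not the same one
  main <- sapply(1:2, function(gt) {
    labs <- ref$labels[region$assembly_id == gt & ref$labels > 0]
    as.integer(names(which.max(table(labs))))
  })
  expect_false(main[1] == main[2])
  # static region bypass
  flat <- data.frame(x = rnorm(100), y = rnorm(100))
  expect_equal(temporal_refinement(flat, cfg)$labels, rep(1L, 100))
})

test_that("refinement equals density clustering when nothing splits", {
  # a single assembly growing everywhere at all times: the refinement must
  # return exactly the search-range-connected component of its seed, i.e.
  # the partition a plain density scan at eps = r_search produces
  set.seed(10)
  blob <- data.frame(x = rnorm(2000, 0, 500), y = rnorm(2000, 0, 500),
                     t = sample(0:300, 2000, replace = TRUE))
  cfg <- pipeline_config("simulation", seed = 1)
  mm <- minmax_scale(blob)$table
  set.seed(1)
  r <- compute_search_range(mm, cfg)$r_search
  set.seed(1)
  ref <- temporal_refinement(blob, cfg)
  expect_equal(max(ref$labels), 1)
  db <- dbscan_points(cbind(mm$x, mm$y), eps = r, min_samples = 2)
  comp <- as.integer(names(which.max(table(db[ref$labels == 1]))))
  expect_identical(which(ref$labels == 1), which(db == comp))
})

test_that("smart density filter keeps planted clusters, rejects noise", {
  set.seed(51)
  noise <- data.frame(x = runif(3000, 0, 100), y = runif(3000, 0, 100))
  planted <- data.frame(x = rnorm(300, 50, 1), y = rnorm(300, 50, 1))
  fake <- noise[sample(3000, 200), ]        # relabelled uniform noise
  cfg <- pipeline_config("default", seed = 1)
  set.seed(1)
  verdict <- smart_density_filter(list(planted, fake), noise, cfg)
  expect_true(verdict$keep[1])
  expect_false(verdict$keep[2])
  # mode none passes everything through
  cfg_none <- pipeline_config("default", filter_mode = "none")
  expect_true(all(smart_density_filter(list(planted, fake), noise,
                                       cfg_none)$keep))
  # empty noise under strict warns and falls back to the size rule
  cfg_s <- pipeline_config("default", final_min_points = 10)
  expect_warning(v <- smart_density_filter(list(planted),
                                           noise[0, ], cfg_s),
                 "baseline")
  expect_true(v$keep[1])
})

test_that("full pipeline: one clean assembly yields one full cluster", {
  p <- single_assembly()
  cfg <- pipeline_config("simulation", filter_mode = "none", seed = 1)
  res <- cluster_localizations(p, cfg)
  expect_equal(nrow(res$clusters), 1)
  expect_gte(mean(res$labels == 1), 0.9)
})

test_that("pipeline is scale invariant and determinate", {
  mv <- assemble_movie(movie_spec(c(steric = 3)), seed = 61)
  cfg <- pipeline_config("steric", seed = 5)
  res1 <- cluster_localizations(mv$points, cfg)
  scaled <- mv$points
  scaled$x <- scaled$x * 1000
  scaled$y <- scaled$y * 1000
  res2 <- cluster_localizations(scaled, cfg)
  expect_identical(res1$labels, res2$labels)
  res3 <- cluster_localizations(mv$points, cfg)
  expect_identical(res1$labels, res3$labels)
})

test_that("pipeline is permutation invariant up to label renaming", {
  mv <- assemble_movie(movie_spec(c(steric = 3)), seed = 62)
  cfg <- pipeline_config("steric", seed = 5)
  res1 <- cluster_localizations(mv$points, cfg)
  set.seed(1)
  perm <- sample(nrow(mv$points))
  res2 <- cluster_localizations(mv$points[perm, ], cfg)
  # membership agrees up to renaming; residual disagreement is confined to
  # contested border points of the density scans
  expect_gt(mean((res2$labels == -1L) == (res1$labels[perm] == -1L)), 0.99)
  expect_gt(adjusted_rand(res1$labels[perm], res2$labels), 0.98)
})

test_that("empty input produces an empty result", {
  res <- cluster_localizations(data.frame(x = numeric(0), y = numeric(0)),
                               pipeline_config("default"))
  expect_length(res$labels, 0)
  expect_equal(nrow(res$clusters), 0)
})
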