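test_that("registry meets the family counts", {
  reg <- fingerprint_registry()
  counts <- table(reg$family[!reg$optional])
  expect_gte(counts[["circularity"]], 5)
  expect_gte(counts[["symmetry"]], 7)
  expect_gte(counts[["geometric"]], 3)
  expect_gte(counts[["graph"]], 25)
  expect_gte(nrow(reg), 40)
  expect_true(all(c("Area", "L_s_ratio", "L_l_ratio", "mu_N", "sig_N",
                    "W_N", "longest_shortest_path", "N_points") %in%
                    reg$name))
})

test_that("normalize_structure centres and aligns the major axis", {
  set.seed(71)
  base <- cbind(rnorm(400, 0, 50), rnorm(400, 0, 10))
  th <- 37 * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  rot <- base %*% t(R)
  out <- normalize_structure(data.frame(x = rot[, 1] + 300,
                                        y = rot[, 2] - 100))
  expect_lt(abs(mean(out$x)), 1e-9)
  expect_lt(abs(mean(out$y)), 1e-9)
  # post-alignment covariance is diagonal with the major axis first
  cv <- cov(cbind(out$x, out$y))
  expect_lt(abs(cv[1, 2]) / cv[1, 1], 1e-6)
  expect_gt(cv[1, 1], cv[2, 2])
  # direct eigen-decomposition agrees on the major-axis direction
  ev <- eigen(cov(rot))$vectors[, 1]
  expect_lt(min(sum((ev - attr(out, "rotation")[, 1])^2),
                sum((ev + attr(out, "rotation")[, 1])^2)), 1e-10)
  expect_true(attr(normalize_structure(data.frame(x = 0:1, y = 0:1)),
                   "minimal"))
})

test_that("geometric features: unit square, disc, and pruned bridges", {
  sq <- data.frame(x = c(0, 1, 1, 0), y = c(0, 0, 1, 1))
  g <- geometric_features(sq)
  expect_equal(unname(g$features["Area"]), 1)
  expect_equal(unname(g$features["max_extent"]), sqrt(2))
  # dense disc: Delaunay area within 10% of pi R^2
  set.seed(72)
  th <- runif(3000, 0, 2 * pi); r <- 100 * sqrt(runif(3000))
  disc <- data.frame(x = r * cos(th), y = r * sin(th))
  gd <- geometric_features(disc)
  expect_lt(abs(gd$features[["Area"]] - pi * 100^2) / (pi * 100^2), 0.1)
  # a single bridging point between two discs is pruned away
  d1 <- data.frame(x = rnorm(400, 0, 30), y = rnorm(400, 0, 30))
  d2 <- data.frame(x = rnorm(400, 3000, 30), y = rnorm(400, 0, 30))
  bridged <- rbind(d1, d2, data.frame(x = 1500, y = 0))
  gb <- geometric_features(bridged)
  apart <- geometric_features(d1)$features[["Area"]] +
    geometric_features(d2)$features[["Area"]]
  expect_lt(gb$features[["Area"]], 1.3 * apart)   # not the convex hull
  expect_gt(gb$features[["Area"]], 0.7 * apart)
  # collinear input flags a sentinel instead of failing
  col <- geometric_features(data.frame(x = 1:10, y = rep(2, 10)))
  expect_equal(unname(col$features["Area"]), 0)
  expect_true(length(col$flags) > 0)
})

test_that("graph features on a line and a complete graph", {
  n <- 20; s <- 5
  line <- data.frame(x = s * (0:(n - 1)), y = rep(0, n))
  g <- graph_features(line, radius = s * 1.01, gauss_fit = FALSE)
  f <- g$features
  expect_equal(unname(f["n_components"]), 1)
  expect_equal(unname(f["mst_total_length"]), (n - 1) * s)
  expect_equal(unname(f["longest_shortest_path"]), (n - 1) * s)
  expect_equal(unname(f["mst_leaf_count"]), 2)
  expect_equal(unname(f["L_s_ratio"]), 1)  # straight path
  # radius >= max distance -> single component, full density
  g2 <- graph_features(line, radius = 1000, gauss_fit = FALSE)
  expect_equal(unname(g2$features["n_components"]), 1)
  expect_equal(unname(g2$features["edge_density"]), 1)
})

test_that("fibril vs isotropic path-straightness contrast", {
  fib <- simulate_fibril(0, 420, rate = 1, turn_sd = pi / 8, seed = 73)
  iso <- simulate_isotropic(0, 100, seed = 74)
  fp_f <- compute_fingerprint(fib)
  fp_i <- compute_fingerprint(iso)
  # a fibril's shortest path between its extent endpoints runs along the
  # meandering backbone; an isotropic blob's cuts straight through
  expect_gt(fp_f[["L_s_ratio"]], 1.25 * fp_i[["L_s_ratio"]])
  expect_gt(fp_f[["longest_shortest_path"]] / fp_f[["max_extent"]],
            1.3 * fp_i[["longest_shortest_path"]] / fp_i[["max_extent"]])
  expect_gt(fp_f[["contour_aspect_ratio"]], fp_i[["contour_aspect_ratio"]])
})

test_that("circularity features separate discs from filaments", {
  set.seed(75)
  th <- runif(3000, 0, 2 * pi); r <- 100 * sqrt(runif(3000))
  disc <- data.frame(x = r * cos(th), y = r * sin(th))
  cd <- circularity_features(disc)
  expect_gte(cd$features[["isoperimetric_quotient"]], 0.85)
  thin <- data.frame(x = seq(0, 2000, length.out = 500) +
                       rnorm(500, 0, 10),
                     y = rnorm(500, 0, 15))
  ct <- circularity_features(thin)
  expect_lt(ct$features[["isoperimetric_quotient"]], 0.5)
  expect_gt(ct$features[["contour_aspect_ratio"]], 3)
  # scale-free: doubling the coordinates changes nothing
  cd2 <- circularity_features(disc * 2)
  expect_equal(cd$features, cd2$features, tolerance = 1e-9)
})

test_that("symmetry features: balanced lattices and reflections", {
  lat <- expand.grid(x = seq(-9.5, 9.5, 1), y = seq(-9.5, 9.5, 1))
  s <- symmetry_features(lat)$features
  expect_equal(unname(s["quad_ratio"]), 1)
  expect_equal(unname(s["balance_x"]), 0)
  expect_equal(unname(s["balance_y"]), 0)
  expect_equal(unname(s["diag_correlation"]), 0)
  expect_equal(unname(s["quad_entropy"]), 1)
  set.seed(76)
  cloud <- data.frame(x = rnorm(200), y = rexp(200))
  mirrored <- data.frame(x = -cloud$x, y = cloud$y)
  expect_equal(symmetry_features(cloud)$features,
               symmetry_features(mirrored)$features, tolerance = 1e-12)
})

test_that("compute_fingerprint: size, options, determinism, minimum", {
  set.seed(77)
  pts <- data.frame(x = rnorm(150, 0, 60), y = rnorm(150, 0, 25))
  fp <- compute_fingerprint(pts)
  expect_gte(length(fp), 40)
  expect_true(all(is.finite(fp)))
  expect_identical(fp, compute_fingerprint(pts))
  no_gauss <- compute_fingerprint(pts, gauss_fit = FALSE)
  expect_false(any(c("mu_N", "sig_N", "W_N") %in% names(no_gauss)))
  no_n <- compute_fingerprint(pts, include_n_points = FALSE)
  expect_false("N_points" %in% names(no_n))
  fp4 <- compute_fingerprint(data.frame(x = c(0, 10, 20, 30),
                                        y = c(0, 4, -3, 2)))
  expect_true(all(is.finite(fp4)))
  expect_error(compute_fingerprint(pts[1:3, ]), "at least 4")
})

test_that("fingerprints are invariant to rigid motion", {
  set.seed(78)
  pts <- data.frame(x = rnorm(300, 0, 80), y = rnorm(300, 0, 30))
  th <- 1.1
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  moved <- as.matrix(pts) %*% R
  fp1 <- compute_fingerprint(pts)
  fp2 <- compute_fingerprint(data.frame(x = moved[, 1] + 777,
                                        y = moved[, 2] - 55))
  expect_equal(fp1, fp2, tolerance = 1e-6)
})

test_that("three morphology classes separate by nearest centroid", {
  # 30 fixtures per class near 200 points each; leave-one-out
  # nearest-centroid classification on standardized fingerprints
  make_fix <- function(class, seed) {
    p <- switch(class,
                isotropic = simulate_isotropic(0, 120, seed = seed),
                steric = simulate_steric(0, 60, seed = seed),
                fibril = simulate_fibril(0, 250, rate = 2, seed = seed))
    if (nrow(p) > 200) p <- p[sample(nrow(p), 200), ]
    p
  }
  set.seed(99)
  cls <- rep(c("isotropic", "steric", "fibril"), each = 30)
  fps <- t(sapply(seq_along(cls), function(i)
    compute_fingerprint(make_fix(cls[i], 100 + i),
                        include_n_points = FALSE)))
  x <- scale(fps); x[!is.finite(x)] <- 0
  pred <- sapply(seq_len(nrow(x)), function(i) {
    cents <- sapply(unique(cls), function(cc)
      colMeans(x[cls == cc & seq_len(nrow(x)) != i, , drop = FALSE]))
    unique(cls)[which.min(colSums((cents - x[i, ])^2))]
  })
  f1 <- sapply(unique(cls), function(cc) {
    tp <- sum(pred == cc & cls == cc)
    2 * tp / (2 * tp + sum(pred == cc & cls != cc) +
                sum(pred != cc & cls == cc))
  })
  expect_gt(mean(f1), 0.95)
})

test_that("fingerprints stay class-separable under blinking at 15+ points", {
  set.seed(88)
  classes <- rep(c("fibril", "ellipse"), each = 20)
  fps <- t(sapply(seq_along(classes), function(i) {
    gt <- simulate_sparse_structure(classes[i], 15, seed = 300 + i)
    b <- apply_blinking(gt, seed = 600 + i)
    compute_fingerprint(b, include_n_points = FALSE, gauss_fit = FALSE)
  }))
  x <- scale(fps); x[!is.finite(x)] <- 0
  pred <- sapply(seq_len(nrow(x)), function(i) {
    cents <- sapply(unique(classes), function(cc)
      colMeans(x[classes == cc & seq_len(nrow(x)) != i, , drop = FALSE]))
    unique(classes)[which.min(colSums((cents - x[i, ])^2))]
  })
  expect_gt(mean(pred == classes), 0.85)
})
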