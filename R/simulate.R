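# Ground-truth simulators for spatiotemporal SMLM movies: isotropic
# (spherulite-like) growth, steric-hindrance ("random") growth, branching
# fibrils, sparse nanostructures, fluorophore blinking and two noise models.
# Every generator is a pure function of (parameters, seed).

run_seeded <- function(seed, fn) {
  if (is.null(seed)) return(fn())
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  fn()
}

#' Kernel bandwidth of the isotropic growth law
#'
#' Bandwidth (nm) of the Gaussian KDE from which new localizations of an
#' isotropically growing assembly are drawn.  It starts at 10 nm at growth
#' onset and increases linearly with the growth phase, scaled by the
#' assembly's own end frame:
#' `((frame - frame_start) / (frame_end - frame_start) * frame_end + 1) * 10`.
#'
#' @param frame Current frame.
#' @param frame_start,frame_end Growth onset and termination frames
#'   (`frame_end > frame_start`).
#' @return Bandwidth in nm (strictly positive, non-decreasing in `frame`).
#' @export
growth_bandwidth <- function(frame, frame_start, frame_end) {
  stopifnot(frame_end > frame_start)
  ((frame - frame_start) / (frame_end - frame_start) * frame_end + 1) * 10
}

#' Steric hindrance of a candidate position
#'
#' `sum(exp(-distance^2))` over the distances from a candidate to the current
#' assembly points; non-negative and decreasing in distance.
#'
#' @param distances Numeric vector of distances (working units).
#' @return Scalar hindrance.
#' @export
steric_hindrance <- function(distances) sum(exp(-distances^2))

#' Simulate one isotropically growing assembly
#'
#' Frame-iterative growth: a single seed localization is placed at the origin
#' at `frame_start`; at every subsequent frame a uniform 0--`max_new` new
#' points are drawn from a Gaussian KDE refitted to all current points, with
#' the bandwidth of [growth_bandwidth()].  Sampling from the KDE draws a
#' uniformly chosen existing point plus isotropic Gaussian noise of that
#' bandwidth.  The result is an approximately radially symmetric structure
#' whose extent grows over time and whose density falls off at the rim.
#'
#' @param frame_start,frame_end Growth window (frames).
#' @param origin Length-2 centre (nm).
#' @param max_new Upper bound of the per-frame uniform point count
#'   (default 30).
#' @param seed Optional integer seed.
#' @return data.frame `x`, `y` (nm), `t` (frame).
#' @export
simulate_isotropic <- function(frame_start, frame_end, origin = c(0, 0),
                               max_new = 30, seed = NULL) {
  stopifnot(frame_end > frame_start)
  run_seeded(seed, function() {
    xs <- origin[1]; ys <- origin[2]; ts <- frame_start
    for (f in seq(frame_start + 1, frame_end)) {
      bw <- growth_bandwidth(f, frame_start, frame_end)
      k <- sample.int(max_new + 1L, 1L) - 1L
      if (k == 0L) next
      comp <- sample.int(length(xs), k, replace = TRUE)
      xs <- c(xs, xs[comp] + stats::rnorm(k, 0, bw))
      ys <- c(ys, ys[comp] + stats::rnorm(k, 0, bw))
      ts <- c(ts, rep(f, k))
    }
    data.frame(x = xs, y = ys, t = ts)
  })
}

#' Simulate one steric-hindrance ("random") assembly
#'
#' Monte-Carlo growth biased away from crowded regions: per frame, one
#' candidate is proposed around each of the last `neighbourhood` (default 50)
#' points by a unit Gaussian in working units, each candidate's hindrance is
#' `sum(exp(-d^2))` over its distances to those points, and a Poisson(`rate`)
#' number of lowest-hindrance candidates is accepted.  Working unit:
#' `unit_nm` nanometres per unit (default 100 nm), which gives the structures
#' a biologically plausible micron-scale footprint.
#'
#' @inheritParams simulate_isotropic
#' @param rate Poisson mean of accepted points per frame (default 10).
#' @param neighbourhood Number of most recent points proposals and hindrance
#'   are computed against (default 50).
#' @param unit_nm Size of the working unit in nm (default 100).
#' @return data.frame `x`, `y` (nm), `t` (frame).
#' @export
simulate_steric <- function(frame_start, frame_end, origin = c(0, 0),
                            rate = 10, neighbourhood = 50, unit_nm = 100,
                            seed = NULL) {
  stopifnot(frame_end > frame_start)
  run_seeded(seed, function() {
    px <- 0; py <- 0; ts <- frame_start
    for (f in seq(frame_start + 1, frame_end)) {
      n <- length(px)
      recent <- seq.int(max(1L, n - neighbourhood + 1L), n)
      cx <- px[recent] + stats::rnorm(length(recent))
      cy <- py[recent] + stats::rnorm(length(recent))
      h <- vapply(seq_along(cx), function(i) {
        steric_hindrance(sqrt((cx[i] - px[recent])^2 + (cy[i] - py[recent])^2))
      }, 0)
      k <- min(stats::rpois(1, rate), length(cx))
      if (k == 0L) next
      pick <- order(h)[seq_len(k)]
      px <- c(px, cx[pick]); py <- c(py, cy[pick])
      ts <- c(ts, rep(f, k))
    }
    data.frame(x = origin[1] + px * unit_nm, y = origin[2] + py * unit_nm,
               t = ts)
  })
}

#' Simulate one branching fibril
#'
#' Directed-diffusion growth: the fibril starts in a uniformly random
#' direction; per frame a Poisson(`rate`, default 1) number of points extends
#' a uniformly chosen active tip, each step turning by N(0, `turn_sd`^2)
#' (default pi/4) and advancing N(`step_mean`, `step_sd`^2) nm (defaults
#' 100 and 20).  At every step the fibril branches with probability
#' `branch_prob` (default 0.5\%) up to `max_branches` times (default 3); the
#' branch direction is the current direction +/- `branch_angle` (side by a
#' fair Bernoulli trial) with SD `branch_angle_sd`.
#'
#' @inheritParams simulate_isotropic
#' @param step_mean,step_sd Elongation step length law (nm).
#' @param turn_sd SD of the per-step turn (radians).
#' @param rate Poisson mean of points added per frame.
#' @param branch_prob Per-step branching probability.
#' @param max_branches Maximum number of branch events.
#' @param branch_angle,branch_angle_sd Branch angle offset law (radians).
#' @return data.frame `x`, `y` (nm), `t` (frame); attribute `n_branches`.
#' @export
simulate_fibril <- function(frame_start, frame_end, origin = c(0, 0),
                            step_mean = 100, step_sd = 20, turn_sd = pi / 4,
                            rate = 1, branch_prob = 0.005, max_branches = 3,
                            branch_angle = pi / 4, branch_angle_sd = pi / 16,
                            seed = NULL) {
  stopifnot(frame_end > frame_start)
  run_seeded(seed, function() {
    tip_x <- origin[1]; tip_y <- origin[2]
    tip_dir <- stats::runif(1, 0, 2 * pi)
    xs <- origin[1]; ys <- origin[2]; ts <- frame_start
    n_branches <- 0L
    for (f in seq(frame_start + 1, frame_end)) {
      k <- stats::rpois(1, rate)
      for (i in seq_len(k)) {
        tip <- sample.int(length(tip_x), 1L)
        tip_dir[tip] <- stats::rnorm(1, tip_dir[tip], turn_sd)
        step <- stats::rnorm(1, step_mean, step_sd)
        tip_x[tip] <- tip_x[tip] + step * cos(tip_dir[tip])
        tip_y[tip] <- tip_y[tip] + step * sin(tip_dir[tip])
        xs <- c(xs, tip_x[tip]); ys <- c(ys, tip_y[tip]); ts <- c(ts, f)
      }
      if (n_branches < max_branches && stats::runif(1) < branch_prob) {
        n_branches <- n_branches + 1L
        src <- sample.int(length(tip_x), 1L)
        side <- if (stats::runif(1) < 0.5) 1 else -1
        new_dir <- stats::rnorm(1, tip_dir[src] + side * branch_angle,
                                branch_angle_sd)
        tip_x <- c(tip_x, tip_x[src]); tip_y <- c(tip_y, tip_y[src])
        tip_dir <- c(tip_dir, new_dir)
      }
    }
    out <- data.frame(x = xs, y = ys, t = ts)
    attr(out, "n_branches") <- n_branches
    out
  })
}

#' Simulate one sparse nanostructure
#'
#' Small structures of exactly `n_points` detections inside a 3 x 3 um region
#' of interest, mimicking protein oligomerization data.  `kind = "fibril"`
#' uses the fibril engine with a mean elongation of 20 nm (SD 5 nm), one
#' point per frame from `frame_start`; `kind = "ellipse"` draws x ~ N(0, 10^2)
#' and y ~ N(0, 20^2) nm, applies a uniformly random rotation, and assigns a
#' uniformly random frame to every point (static-modality data).
#'
#' @param kind `"fibril"` or `"ellipse"`.
#' @param n_points Number of detections (>= 2; 4, 8, 15 and 25 are the
#'   standard settings).
#' @param origin Length-2 centre (nm).
#' @param frame_start Onset frame of the fibril variant.
#' @param max_frames Frame range for the random frames of the ellipse
#'   variant.
#' @param seed Optional integer seed.
#' @return data.frame `x`, `y` (nm), `t` (frame).
#' @export
simulate_sparse_structure <- function(kind = c("fibril", "ellipse"),
                                      n_points, origin = c(0, 0),
                                      frame_start = 0, max_frames = 400,
                                      seed = NULL) {
  kind <- match.arg(kind)
  if (n_points < 2) stop("n_points must be >= 2")
  run_seeded(seed, function() {
    if (kind == "fibril") {
      # rate 1/frame and a generous window, truncated to exactly n_points
      pts <- simulate_fibril(frame_start, frame_start + 8L * n_points,
                             origin = origin, step_mean = 20, step_sd = 5,
                             rate = 1)
      while (nrow(pts) < n_points) {
        pts <- simulate_fibril(frame_start, frame_start + 16L * n_points,
                               origin = origin, step_mean = 20, step_sd = 5,
                               rate = 1)
      }
      pts[seq_len(n_points), , drop = FALSE]
    } else {
      x <- stats::rnorm(n_points, 0, 10)
      y <- stats::rnorm(n_points, 0, 20)
      a <- stats::runif(1, 0, 2 * pi)
      data.frame(x = origin[1] + x * cos(a) - y * sin(a),
                 y = origin[2] + x * sin(a) + y * cos(a),
                 t = sample.int(max_frames + 1L, n_points, replace = TRUE) - 1L)
    }
  })
}

#' Replace ground-truth points by blinking detections
#'
#' Emulates fluorophore blinking: every ground-truth localization is replaced
#' by a uniform 1--6 detections, each displaced by a Gaussian localization
#' error whose sigma is drawn per detection from LogNormal(meanlog = 3,
#' sdlog = 0.28) (median ~ 20 nm).  The original points are not kept.
#'
#' @param structure data.frame with `x`, `y` and optionally `t` (nm, frames).
#' @param max_detections Upper bound of the uniform multiplicity (default 6).
#' @param meanlog,sdlog Log-scale parameters of the sigma distribution.
#' @param seed Optional integer seed.
#' @return data.frame of the blinking detections (between `n` and
#'   `max_detections * n` rows).
#' @export
apply_blinking <- function(structure, max_detections = 6, meanlog = 3,
                           sdlog = 0.28, seed = NULL) {
  stopifnot(nrow(structure) > 0)
  run_seeded(seed, function() {
    k <- sample.int(max_detections, nrow(structure), replace = TRUE)
    idx <- rep(seq_len(nrow(structure)), k)
    sig <- stats::rlnorm(length(idx), meanlog, sdlog)
    out <- structure[idx, , drop = FALSE]
    out$x <- out$x + stats::rnorm(length(idx), 0, sig)
    out$y <- out$y + stats::rnorm(length(idx), 0, sig)
    rownames(out) <- NULL
    out
  })
}

#' Append noise localizations to a movie
#'
#' `mode = "uniform"`: noise uniform in x, y and t over the field of view and
#' frame range; the amount is `amount` times the number of signal points
#' (default 0.3).  `mode = "heterogeneous"`: 5--25 noise seeds placed
#' uniformly in the FOV, each contributing 20--50 points Gaussian around the
#' seed (sigma 320 nm), every noise point additionally displaced by a
#' N(20000, 100^2) nm magnitude along a uniformly random direction, wrapped
#' into the FOV; frames are drawn uniformly.  Noise rows carry
#' `assembly_id = -1` and `class = "noise"`; signal rows are never modified.
#'
#' @param movie A `simulated_movie` (from [assemble_movie()]) or a labelled
#'   localization data.frame.
#' @param mode `"uniform"`, `"heterogeneous"` or `"none"`.
#' @param amount Noise-to-signal ratio for uniform mode; 0 disables noise.
#' @param fov,max_frames Field of view (nm) and frame range; taken from the
#'   movie spec when omitted.
#' @param seed Optional integer seed.
#' @return Object of the same kind with noise rows appended.
#' @export
add_noise <- function(movie, mode = c("uniform", "heterogeneous", "none"),
                      amount = 0.3, fov = NULL, max_frames = NULL,
                      seed = NULL) {
  mode <- match.arg(mode)
  is_movie <- inherits(movie, "simulated_movie")
  pts <- if (is_movie) movie$points else movie
  if (is.null(fov)) fov <- if (is_movie) movie$spec$fov else
    c(diff(range(pts$x)), diff(range(pts$y)))
  if (is.null(max_frames)) max_frames <- if (is_movie) movie$spec$max_frames
    else max(pts$t)
  if (mode == "none" || amount == 0 || nrow(pts) == 0) return(movie)
  if (!"assembly_id" %in% names(pts)) pts$assembly_id <- 0L
  if (!"class" %in% names(pts)) pts$class <- "signal"
  noise <- run_seeded(seed, function() {
    if (mode == "uniform") {
      n <- round(amount * sum(pts$assembly_id != -1L))
      data.frame(x = stats::runif(n, 0, fov[1]),
                 y = stats::runif(n, 0, fov[2]),
                 t = sample.int(max_frames + 1L, n, replace = TRUE) - 1L)
    } else {
      n_seeds <- sample(5:25, 1)
      sx <- stats::runif(n_seeds, 0, fov[1])
      sy <- stats::runif(n_seeds, 0, fov[2])
      per <- sample(20:50, n_seeds, replace = TRUE)
      i <- rep(seq_len(n_seeds), per)
      n <- length(i)
      x <- sx[i] + stats::rnorm(n, 0, 320)
      y <- sy[i] + stats::rnorm(n, 0, 320)
      mag <- stats::rnorm(n, 20000, 100)
      dir <- stats::runif(n, 0, 2 * pi)
      data.frame(x = (x + mag * cos(dir)) %% fov[1],
                 y = (y + mag * sin(dir)) %% fov[2],
                 t = sample.int(max_frames + 1L, n, replace = TRUE) - 1L)
    }
  })
  noise$assembly_id <- -1L
  noise$class <- "noise"
  out <- rbind(pts[, c("x", "y", "t", "assembly_id", "class")], noise)
  rownames(out) <- NULL
  if (is_movie) { movie$points <- out; movie } else out
}

#' Movie specification for [assemble_movie()]
#'
#' @param n_assemblies Named integer vector of assemblies per class; names
#'   among `"isotropic"`, `"steric"`, `"fibril"`, `"sparse_fibril"`,
#'   `"sparse_ellipse"`.
#' @param fov Field of view (nm), default 40 x 40 um.
#' @param max_frames Maximum experiment time (default 400 frames).
#' @param start_window Growth starts within the first `start_window` frames
#'   (default 300).
#' @param min_lifetime Minimum aggregation time (default 100 frames);
#'   `start_window + min_lifetime <= max_frames` is required.
#' @param noise_mode,noise_amount Passed to [add_noise()].
#' @param sparse_n_points Detections per sparse structure (sparse classes
#'   only).
#' @return A `movie_spec` list.
#' @export
movie_spec <- function(n_assemblies, fov = c(40000, 40000), max_frames = 400,
                       start_window = 300, min_lifetime = 100,
                       noise_mode = "uniform", noise_amount = 0.3,
                       sparse_n_points = 4) {
  stopifnot(length(n_assemblies) > 0, !is.null(names(n_assemblies)))
  bad <- setdiff(names(n_assemblies),
                 c("isotropic", "steric", "fibril", "sparse_fibril",
                   "sparse_ellipse"))
  if (length(bad)) stop("unknown assembly class(es): ",
                        paste(bad, collapse = ", "))
  if (start_window + min_lifetime > max_frames)
    stop("start_window + min_lifetime must not exceed max_frames")
  structure(list(n_assemblies = n_assemblies, fov = fov,
                 max_frames = max_frames, start_window = start_window,
                 min_lifetime = min_lifetime, noise_mode = noise_mode,
                 noise_amount = noise_amount,
                 sparse_n_points = sparse_n_points),
            class = "movie_spec")
}

#' Assemble a ground-truth-labelled simulated movie
#'
#' Places the requested assemblies at uniformly random origins in the field
#' of view (overlap permitted and expected), draws each assembly's growth
#' onset uniformly within the start window and its end uniformly between
#' onset + minimum lifetime and the experiment end, grows each assembly with
#' its class simulator, and appends noise per the spec.
#'
#' @param spec A [movie_spec()].
#' @param seed Optional integer seed; a fixed seed reproduces the movie
#'   exactly.
#' @return A `simulated_movie`: list with `points` (x, y, t, assembly_id,
#'   class; noise rows have `assembly_id = -1`), `assemblies` (per-assembly
#'   ground truth: origin, onset/end frames, point count, class) and `spec`.
#' @export
assemble_movie <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "movie_spec"))
  run_seeded(seed, function() {
    pts <- list(); meta <- list(); id <- 0L
    for (cls in names(spec$n_assemblies)) {
      for (i in seq_len(spec$n_assemblies[[cls]])) {
        id <- id + 1L
        origin <- c(stats::runif(1, 0, spec$fov[1]),
                    stats::runif(1, 0, spec$fov[2]))
        fs <- sample.int(spec$start_window + 1L, 1L) - 1L
        fe <- fs + spec$min_lifetime +
          sample.int(spec$max_frames - fs - spec$min_lifetime + 1L, 1L) - 1L
        p <- switch(cls,
          isotropic = simulate_isotropic(fs, fe, origin),
          steric = simulate_steric(fs, fe, origin),
          fibril = simulate_fibril(fs, fe, origin),
          sparse_fibril = simulate_sparse_structure(
            "fibril", spec$sparse_n_points, origin, frame_start = fs,
            max_frames = spec$max_frames),
          sparse_ellipse = simulate_sparse_structure(
            "ellipse", spec$sparse_n_points, origin,
            max_frames = spec$max_frames))
        p$assembly_id <- id
        p$class <- cls
        pts[[id]] <- p
        meta[[id]] <- data.frame(assembly_id = id, class = cls,
                                 x0 = origin[1], y0 = origin[2],
                                 frame_start = fs, frame_end = fe,
                                 n_points = nrow(p))
      }
    }
    movie <- structure(list(points = do.call(rbind, pts),
                            assemblies = do.call(rbind, meta), spec = spec),
                       class = "simulated_movie")
    rownames(movie$points) <- NULL
    add_noise(movie, spec$noise_mode, spec$noise_amount)
  })
}

#' @export
print.simulated_movie <- function(x, ...) {
  n_noise <- sum(x$points$assembly_id == -1L)
  cat(sprintf("<simulated_movie: %d assemblies (%s), %d points (%d noise)>\n",
              nrow(x$assemblies),
              paste(unique(x$assemblies$class), collapse = ", "),
              nrow(x$points), n_noise))
  invisible(x)
}

#' Reverse the time axis of a movie
#'
#' Maps `t` to `max(t) - t`, leaving spatial coordinates untouched; supports
#' the degenerative (shrinking) structure experiments.  Ground-truth
#' onset/end frames of a `simulated_movie` are swapped and reflected.
#'
#' @param movie A `simulated_movie` or localization data.frame with `t`.
#' @return Object of the same kind with reversed time.
#' @export
reverse_time <- function(movie) {
  is_movie <- inherits(movie, "simulated_movie")
  pts <- if (is_movie) movie$points else movie
  if (!"t" %in% names(pts)) stop("static table: no time axis to reverse")
  tmax <- max(pts$t)
  pts$t <- tmax - pts$t
  if (!is_movie) return(pts)
  movie$points <- pts
  fs <- movie$assemblies$frame_start
  movie$assemblies$frame_start <- tmax - movie$assemblies$frame_end
  movie$assemblies$frame_end <- tmax - fs
  movie
}

#' Interpolate a morphing sequence between structures
#'
#' Builds `n_interp` intermediate point sets for every consecutive pair of
#' structures by linear interpolation of matched points: both sets are
#' centroid-aligned, the smaller set is padded by resampling, and points are
#' paired greedily by nearest neighbour.  Fraction `j / n_interp` for
#' `j = 1..n_interp`, so the last intermediate of a transition is the next
#' structure exactly.
#'
#' @param structures List (>= 2) of data.frames with `x`, `y`; consecutive
#'   structures should differ in morphology class.
#' @param n_interp Intermediates per transition (default 100).
#' @param seed Optional integer seed (pairs the resampling padding).
#' @return List of `(length(structures) - 1) * n_interp` data.frames.
#' @export
morph_sequence <- function(structures, n_interp = 100, seed = NULL) {
  if (length(structures) < 2)
    stop("morphing needs at least two structures")
  run_seeded(seed, function() {
    out <- vector("list", (length(structures) - 1L) * n_interp)
    k <- 0L
    for (i in seq_len(length(structures) - 1L)) {
      a <- as.matrix(structures[[i]][, c("x", "y")])
      b <- as.matrix(structures[[i + 1L]][, c("x", "y")])
      a <- sweep(a, 2, colMeans(a)); b <- sweep(b, 2, colMeans(b))
      n <- max(nrow(a), nrow(b))
      if (nrow(a) < n) a <- a[c(seq_len(nrow(a)),
                                sample.int(nrow(a), n - nrow(a),
                                           replace = TRUE)), , drop = FALSE]
      if (nrow(b) < n) b <- b[c(seq_len(nrow(b)),
                                sample.int(nrow(b), n - nrow(b),
                                           replace = TRUE)), , drop = FALSE]
      # greedy nearest-neighbour pairing from a to b
      ord <- integer(n); free <- rep(TRUE, n)
      nn <- RANN::nn2(b, a, k = n)
      for (j in seq_len(n)) {
        cand <- nn$nn.idx[j, ]
        ord[j] <- cand[which(free[cand])[1]]
        free[ord[j]] <- FALSE
      }
      bm <- b[ord, , drop = FALSE]
      for (j in seq_len(n_interp)) {
        f <- j / n_interp
        k <- k + 1L
        m <- (1 - f) * a + f * bm
        out[[k]] <- data.frame(x = m[, 1], y = m[, 2])
      }
    }
    out
  })
}
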