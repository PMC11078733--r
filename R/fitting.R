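# Random-search fitting of the inverse-sigmoid fitness parameters against
# observed joint heteroplasmy distributions, scored by a combined mean
# squared error (2D kernel-density MSE plus twice the mean-heteroplasmy
# MSE) with k-nearest-neighbour smoothing over the search space.

# Scott's-rule bandwidth on kde2d's scale (kde2d uses h/4 as the kernel sd)
.kde_bandwidth <- function(v) {
  h <- 4 * stats::sd(v) * length(v)^(-1 / 6)
  max(h, 0.05)
}

.kde_grid <- function(df, n_grid = 50L) {
  h <- c(.kde_bandwidth(df$missense_het), .kde_bandwidth(df$silent_het))
  MASS::kde2d(df$missense_het, df$silent_het, h = h, n = n_grid,
              lims = c(0, 1, 0, 1))$z
}

#' Combined MSE between simulated and observed heteroplasmy distributions
#'
#' For each timepoint the score has two parts: (a) the MSE between 2D
#' kernel density estimates of the joint (missense, silent) heteroplasmy
#' distributions, evaluated on a fixed 50 x 50 grid over the unit square
#' (Gaussian kernel, Scott's-rule bandwidth), and (b) the mean squared
#' error of the mean missense and mean silent heteroplasmy.  Per timepoint
#' the total is (a) + 2 x (b); the returned score is the mean over
#' timepoints.  The score is non-negative, zero for identical inputs, and
#' symmetric in its two arguments.
#'
#' @param sim,obs named lists of data.frames with columns `missense_het`,
#'   `silent_het`; names identify timepoints and must coincide.
#' @param n_grid KDE evaluation grid size per axis.
#' @return scalar combined MSE.
#' @export
combined_mse <- function(sim, obs, n_grid = 50L) {
  tps <- names(obs)
  if (!all(tps %in% names(sim)))
    stop("simulated samples are missing timepoints: ",
         paste(setdiff(tps, names(sim)), collapse = ", "))
  per_tp <- vapply(tps, function(tp) {
    s <- sim[[tp]]; o <- obs[[tp]]
    if (nrow(s) == 0 || nrow(o) == 0)
      stop("empty sample set at timepoint ", tp)
    kde_mse <- mean((.kde_grid(s, n_grid) - .kde_grid(o, n_grid))^2)
    mean_mse <- ((mean(s$missense_het) - mean(o$missense_het))^2 +
                   (mean(s$silent_het) - mean(o$silent_het))^2) / 2
    kde_mse + 2 * mean_mse
  }, numeric(1))
  mean(per_tp)
}

#' Search space for the random-search fit
#'
#' Default ranges: depth d in [0.05, 1] (linear), pitch p in [0.5, 50]
#' (log), location l in [0.2, 1] (linear), molecules per cell M in
#' [100, 10000] (log).  The number of iterations and the neighbourhood
#' size used for smoothing are part of the space definition.
#'
#' @param d,p,l,M two-element numeric ranges (min, max).
#' @param n_iterations random parameter sets drawn (default 20000).
#' @param k_neighbours neighbourhood size for score smoothing (default 50).
#' @return list of class `scilite_search_space`.
#' @export
search_space <- function(d = c(0.05, 1), p = c(0.5, 50), l = c(0.2, 1),
                         M = c(100, 10000), n_iterations = 20000L,
                         k_neighbours = 50L) {
  for (r in list(d = d, p = p, l = l, M = M))
    if (length(r) != 2 || r[1] >= r[2]) stop("ranges must be increasing pairs")
  if (n_iterations < k_neighbours)
    stop("n_iterations must be at least k_neighbours")
  structure(list(d = d, p = p, l = l, M = M,
                 n_iterations = as.integer(n_iterations),
                 k_neighbours = as.integer(k_neighbours)),
            class = "scilite_search_space")
}

# scale parameters to [0,1] per axis (d, l linear; p, M log) for the
# neighbour metric
.scale_params <- function(pts, space) {
  cbind(d = (pts$d - space$d[1]) / diff(space$d),
        p = (log(pts$p) - log(space$p[1])) / diff(log(space$p)),
        l = (pts$l - space$l[1]) / diff(space$l),
        M = (log(pts$M) - log(space$M[1])) / diff(log(space$M)))
}

#' k-nearest-neighbour smoothing of search scores
#'
#' Replaces each point's raw score by the mean raw score of its k nearest
#' neighbours (the point itself included) under a scale-normalized
#' Euclidean metric: each axis is mapped to the unit interval, linearly for
#' d and l and logarithmically for p and M.  Smoothing damps the run-to-run
#' noise of scoring each parameter set with a single stochastic simulation.
#'
#' @param points data.frame with columns `d`, `p`, `l`, `M`.
#' @param scores raw scores, one per point.
#' @param k neighbourhood size (including the point itself); `k = 1`
#'   returns the raw scores.
#' @param space [search_space()] supplying the axis ranges.
#' @return numeric vector of smoothed scores.
#' @export
knn_smooth <- function(points, scores, k, space = search_space()) {
  n <- nrow(points)
  if (k > n) stop("k must not exceed the number of points")
  if (k == 1) return(as.numeric(scores))
  z <- .scale_params(points, space)
  out <- numeric(n)
  block <- 512L
  for (start in seq(1L, n, by = block)) {
    rows <- start:min(start + block - 1L, n)
    # squared distances from this block to all points
    d2 <- outer(rowSums(z[rows, , drop = FALSE]^2), rowSums(z^2), "+") -
      2 * z[rows, , drop = FALSE] %*% t(z)
    for (i in seq_along(rows)) {
      nb <- order(d2[i, ])[seq_len(k)]
      out[rows[i]] <- mean(scores[nb])
    }
  }
  out
}

#' Fit fitness parameters by random search
#'
#' Samples `n_iterations` parameter sets uniformly in the (scaled) search
#' space, runs one simulated time course per set against the observed
#' day-0 cells, scores each against the observed later-timepoint joint
#' heteroplasmy distributions with [combined_mse()], smooths the scores
#' with [knn_smooth()], and returns the parameter set with the minimum
#' smoothed score.
#'
#' @param observed named list of heteroplasmy data.frames; must contain
#'   `day0` (with `total_umis`) plus at least one later timepoint named
#'   like the simulator's collection labels (`day5`, `day10`, ...).
#' @param space [search_space()].
#' @param schedule [default_schedule()] used for every simulation.
#' @param n_cells initial simulated population size per run.
#' @param seed RNG seed governing both the parameter draws and the
#'   per-iteration simulation seeds.
#' @return list of class `scilite_fit` with `iterations` (a `data.table`
#'   of parameters, raw and smoothed scores), `best` (a
#'   [sigmoid_params()]), and the `space`.
#' @export
random_search <- function(observed, space = search_space(),
                          schedule = default_schedule(), n_cells = 2500L,
                          seed = 1L) {
  tps <- setdiff(names(observed), "day0")
  if (!"day0" %in% names(observed) || length(tps) == 0)
    stop("observed must contain day0 plus at least one later timepoint")
  n <- space$n_iterations
  set.seed(seed)
  pts <- data.table::data.table(
    d = stats::runif(n, space$d[1], space$d[2]),
    p = exp(stats::runif(n, log(space$p[1]), log(space$p[2]))),
    l = stats::runif(n, space$l[1], space$l[2]),
    M = exp(stats::runif(n, log(space$M[1]), log(space$M[2]))))
  iter_seeds <- sample.int(.Machine$integer.max - 1L, n)
  n_collect <- max(vapply(observed[tps], nrow, integer(1)))
  obs_tp <- observed[tps]
  raw <- vapply(seq_len(n), function(i) {
    par_i <- sigmoid_params(pts$d[i], pts$p[i], pts$l[i], pts$M[i])
    run <- run_timecourse(observed$day0, par_i, schedule, n_cells = n_cells,
                          n_collect = n_collect, seed = iter_seeds[i])
    combined_mse(run$samples, obs_tp)
  }, numeric(1))
  smoothed <- knn_smooth(pts, raw, space$k_neighbours, space)
  pts[, `:=`(iter = .I, raw_mse = raw, smoothed_mse = smoothed)]
  best_i <- which.min(smoothed)
  structure(list(
    iterations = pts[],
    best = sigmoid_params(pts$d[best_i], pts$p[best_i], pts$l[best_i],
                          pts$M[best_i]),
    best_iter = best_i,
    space = space
  ), class = "scilite_fit")
}

#' @export
print.scilite_fit <- function(x, ...) {
  cat("random-search fit over", nrow(x$iterations), "parameter sets\nbest: ")
  print(x$best)
  invisible(x)
}

#' Replicate simulations at fixed parameters
#'
#' Runs the simulated growth experiment `n_runs` times, each with a
#' different seed, and collects the per-collection-day mean heteroplasmy
#' values, characterizing the run-to-run spread of the model at its fitted
#' parameters.
#'
#' @param params [sigmoid_params()].
#' @param day0 observed day-0 heteroplasmy table.
#' @param n_runs number of replicate runs (default 100).
#' @param schedule [default_schedule()].
#' @param n_cells initial population size per run.
#' @param seed base seed; replicate seeds are drawn from it.
#' @return `data.table` with `run`, `day`, `mean_missense`, `mean_silent`.
#' @export
replicate_runs <- function(params, day0, n_runs = 100L,
                           schedule = default_schedule(), n_cells = 2500L,
                           seed = 1L) {
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1L, n_runs)
  out <- lapply(seq_len(n_runs), function(r) {
    run <- run_timecourse(day0, params, schedule, n_cells = n_cells,
                          seed = seeds[r])
    data.table::rbindlist(lapply(names(run$samples), function(tp)
      data.table::data.table(run = r,
                             day = as.integer(sub("^day", "", tp)),
                             mean_missense = mean(run$samples[[tp]]$missense_het),
                             mean_silent = mean(run$samples[[tp]]$silent_het))))
  })
  data.table::rbindlist(out)
}
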