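# Heteroplasmy-dynamics simulator: a dividing cell population in which a
# cell's relative probability of division is an inverse-sigmoid function of
# its missense heteroplasmy, molecule counts are resampled multinomially at
# each division, and the culture follows an experimental passaging schedule.

#' Inverse-sigmoid fitness parameters
#'
#' The fitness model maps a cell's missense heteroplasmy fraction x to its
#' relative division probability
#' \deqn{y(x) = (1-d)\,\frac{10^{-p(x-l)}}{1+10^{-p(x-l)}} + d,}
#' a decreasing sigmoid from 1 down to the floor `d`.  `d` (depth) sets the
#' relative growth rate of a homoplasmic mutant cell, `l` (location) the
#' heteroplasmy at the inflection point, and `p` (pitch) the sharpness of
#' the transition — together `l` and `p` encode the biochemical threshold
#' beyond which fitness drops off.  `M` is the number of molecules
#' simulated per cell, which sets the precision of the per-cell
#' heteroplasmy estimates.
#'
#' @param d fitness floor in (0, 1]; `d = 1` gives a flat (neutral) model.
#' @param p pitch (> 0), dimensionless.
#' @param l location of the inflection point, a heteroplasmy fraction.
#' @param M molecules simulated per cell (positive integer).
#' @return object of class `scilite_sigmoid`.
#' @export
sigmoid_params <- function(d = 0.31, p = 4.95, l = 0.75, M = 1000L) {
  if (d <= 0 || d > 1) stop("d must be in (0, 1]")
  if (p <= 0) stop("p must be positive")
  if (l < 0 || l > 1) stop("l must be a fraction in [0, 1]")
  if (M < 1) stop("M must be a positive integer")
  structure(list(d = d, p = p, l = l, M = as.integer(round(M))),
            class = "scilite_sigmoid")
}

#' @export
print.scilite_sigmoid <- function(x, ...) {
  cat(sprintf("inverse-sigmoid fitness: d = %.3g, p = %.3g, l = %.3g, M = %d\n",
              x$d, x$p, x$l, x$M))
  invisible(x)
}

#' Relative division probability at a given heteroplasmy
#'
#' @param x missense heteroplasmy fraction(s) in [0, 1].
#' @param params [sigmoid_params()].
#' @return y(x) in [d, 1]; exactly `(1 + d) / 2` at `x = l`.
#' @examples
#' fitness(0.656, sigmoid_params(0.31, 4.95, 0.75))  # ~0.824
#' @export
fitness <- function(x, params) {
  if (any(x < 0 | x > 1)) stop("heteroplasmy x must be in [0, 1]")
  s <- 10^(-params$p * (x - params$l))
  (1 - params$d) * (s / (1 + s)) + params$d
}

#' Expected heteroplasmy after n editing rounds
#'
#' A fully active base editor converts at most half of the molecules per
#' round of mtDNA replication (only the newly synthesized strand templates
#' the edit), so after n rounds the expected heteroplasmy is
#' H = 1 - (1/2)^n: 50% after a single round, approaching 100% over a few
#' rounds.
#'
#' @param n non-negative integer number of replication rounds.
#' @return expected heteroplasmy fraction.
#' @examples
#' editor_heteroplasmy(0:3)  # 0, 0.5, 0.75, 0.875
#' @export
editor_heteroplasmy <- function(n) {
  if (any(n < 0)) stop("n must be non-negative")
  1 - 0.5^n
}

# vectorized multinomial resampling of (missense, silent, wt) molecule
# counts: one multinomial of size draws[i] per row of the fraction matrix
.resample_counts <- function(frac, draws) {
  n <- nrow(frac)
  draws <- pmax(1L, as.integer(round(draws)))
  mis <- stats::rbinom(n, draws, frac[, 1L])
  rem <- draws - mis
  p2 <- ifelse(frac[, 1L] >= 1, 0, frac[, 2L] / (1 - frac[, 1L]))
  p2 <- pmin(pmax(p2, 0), 1)
  sil <- stats::rbinom(n, rem, p2)
  cbind(missense = mis, silent = sil, wt = rem - sil)
}

.pop_frac <- function(counts) counts / rowSums(counts)

#' Simulated cell population
#'
#' @param counts integer matrix with columns `missense`, `silent`, `wt`:
#'   molecule counts per cell.
#' @param weight per-cell draw-count scale in (0, 1] (observed UMIs divided
#'   by the maximum day-0 UMI count).
#' @param day current day index.
#' @return object of class `scilite_population`.
#' @export
sim_population <- function(counts, weight = rep(1, nrow(counts)), day = 0L) {
  stopifnot(is.matrix(counts), ncol(counts) == 3L,
            all(counts >= 0), all(rowSums(counts) >= 1),
            length(weight) == nrow(counts), all(weight > 0 & weight <= 1))
  colnames(counts) <- c("missense", "silent", "wt")
  pop <- structure(list(counts = counts, weight = weight, day = as.integer(day),
                        history = NULL), class = "scilite_population")
  pop$history <- .pop_snapshot(pop)
  pop
}

.pop_snapshot <- function(pop) {
  x <- .pop_frac(pop$counts)
  data.table::data.table(day = pop$day, n_cells = nrow(pop$counts),
                         mean_missense = mean(x[, 1L]),
                         mean_silent = mean(x[, 2L]))
}

#' @export
print.scilite_population <- function(x, ...) {
  cat(sprintf("simulated population: %d cells, day %d, mean missense het %.3f\n",
              nrow(x$counts), x$day, mean(.pop_frac(x$counts)[, 1L])))
  invisible(x)
}

#' Heteroplasmy fractions of a simulated population
#' @param pop a `scilite_population`.
#' @return matrix of per-cell (missense, silent, wt) fractions.
#' @export
heteroplasmy_fractions <- function(pop) .pop_frac(pop$counts)

#' Resample the molecules of every cell
#'
#' Draws each cell's molecule counts anew from a multinomial parameterized
#' by its current heteroplasmy fractions.  The number of draws is
#' `round(M * weight)` (clamped to at least one molecule), so cells whose
#' heteroplasmy was estimated from fewer observed UMIs are simulated with
#' proportionally fewer molecules.  Fractions are then recomputed from the
#' simulated molecules only.
#'
#' @param pop a [sim_population()].
#' @param params [sigmoid_params()] (supplies `M`).
#' @return the population with resampled counts.
#' @export
resample_molecules <- function(pop, params) {
  frac <- .pop_frac(pop$counts)
  pop$counts <- .resample_counts(frac, params$M * pop$weight)
  pop
}

#' Initialize a simulated population from observed day-0 cells
#'
#' Samples `n_cells` cells with replacement from the observed day-0
#' heteroplasmy table; each draw is passed through multinomial molecule
#' resampling so that repeated draws of the same observed cell do not stay
#' numerically identical.  Draw counts are scaled per cell by its observed
#' UMI coverage relative to the maximum day-0 coverage.
#'
#' @param day0 data.frame with columns `missense_het`, `silent_het` and
#'   `total_umis` (a `wt_het` column is derived if absent).
#' @param n_cells number of cells to initialize (default 2500).
#' @param params [sigmoid_params()].
#' @return a `scilite_population` at day 0.
#' @export
init_population <- function(day0, n_cells = 2500L, params = sigmoid_params()) {
  day0 <- as.data.frame(day0)
  if (nrow(day0) == 0) stop("day-0 table is empty")
  idx <- sample.int(nrow(day0), n_cells, replace = TRUE)
  mis <- day0$missense_het[idx]
  sil <- day0$silent_het[idx]
  wt <- if ("wt_het" %in% names(day0)) day0$wt_het[idx] else 1 - mis - sil
  frac <- cbind(mis, sil, pmax(wt, 0))
  frac <- frac / rowSums(frac)
  w <- if ("total_umis" %in% names(day0))
    day0$total_umis[idx] / max(day0$total_umis) else rep(1, n_cells)
  counts <- .resample_counts(frac, params$M * w)
  sim_population(counts, weight = w, day = 0L)
}

#' Advance the population by one day of growth
#'
#' The culture doubles: N daughter cells are drawn with replacement from
#' the N current cells, with selection probability proportional to the
#' inverse-sigmoid fitness of each cell's missense heteroplasmy.  Each
#' daughter's molecules are resampled multinomially; cells that do not
#' divide keep their heteroplasmy unchanged.
#'
#' @param pop a `scilite_population`.
#' @param params [sigmoid_params()].
#' @return the doubled population, day advanced by one.
#' @export
grow_one_day <- function(pop, params) {
  n <- nrow(pop$counts)
  if (n == 0) stop("population is empty")
  x <- .pop_frac(pop$counts)[, 1L]
  w <- fitness(x, params)
  idx <- sample.int(n, n, replace = TRUE, prob = w)
  daughters <- .resample_counts(.pop_frac(pop$counts)[idx, , drop = FALSE],
                                params$M * pop$weight[idx])
  pop$counts <- rbind(pop$counts, daughters)
  pop$weight <- c(pop$weight, pop$weight[idx])
  pop$day <- pop$day + 1L
  pop$history <- rbind(pop$history, .pop_snapshot(pop))
  pop
}

#' Passage the culture
#'
#' Uniform subsample without replacement, emulating a culture split.
#'
#' @param pop a `scilite_population`.
#' @param n_keep number of cells kept (must not exceed the current size).
#' @return the passaged population (same day).
#' @export
passage <- function(pop, n_keep) {
  n <- nrow(pop$counts)
  if (n_keep > n) stop("n_keep exceeds the population size")
  idx <- if (n_keep == n) seq_len(n) else sample.int(n, n_keep)
  pop$counts <- pop$counts[idx, , drop = FALSE]
  pop$weight <- pop$weight[idx]
  pop
}

#' Experimental passaging schedule
#'
#' The default mirrors the time-course protocol: passaging on days 3, 5, 8,
#' 10 and 13, keeping 5000 cells before a 2-day interval and 2500 cells
#' before a 3-day interval, with pseudo-library collections on days 5, 10
#' and 15.  `scale` shrinks every cell count proportionally for reduced
#' problem sizes.
#'
#' @param days total growth days.
#' @param passages named numeric vector: day -> cells kept at that passage.
#' @param collect days on which pseudo-library samples are drawn.
#' @param scale multiplier applied to all cell counts.
#' @return list with `days`, `passages`, `collect`.
#' @export
default_schedule <- function(days = 15L,
                             passages = c(`3` = 5000, `5` = 2500, `8` = 5000,
                                          `10` = 2500, `13` = 5000),
                             collect = c(5L, 10L, 15L),
                             scale = 1) {
  list(days = as.integer(days),
       passages = stats::setNames(pmax(1L, as.integer(round(passages * scale))),
                                  names(passages)),
       collect = as.integer(collect))
}

#' Run the full simulated time course
#'
#' Initializes the population from the day-0 table, then iterates daily
#' growth with passaging applied before the doubling on scheduled days.  On
#' collection days, a pseudo-library of `n_collect` cells is drawn with
#' replacement from the culture, emulating single-cell data collection.
#'
#' @param day0 observed day-0 heteroplasmy table (see [init_population()]).
#' @param params [sigmoid_params()].
#' @param schedule a [default_schedule()].
#' @param n_cells initial population size.
#' @param n_collect cells per collection (default: number of observed day-0
#'   cells).
#' @param seed RNG seed; the run is fully reproducible given the seed.
#' @return list with `population` (final state), `history` (per-day mean
#'   heteroplasmy and size) and `samples` (named list of collection-day
#'   data.tables with `missense_het`, `silent_het`).
#' @export
run_timecourse <- function(day0, params = sigmoid_params(),
                           schedule = default_schedule(),
                           n_cells = 2500L, n_collect = NULL, seed = 1L) {
  set.seed(seed)
  if (is.null(n_collect)) n_collect <- nrow(as.data.frame(day0))
  pop <- init_population(day0, n_cells = n_cells, params = params)
  samples <- list()
  if (schedule$days >= 1) for (day in seq_len(schedule$days)) {
    key <- as.character(day)
    if (key %in% names(schedule$passages))
      pop <- passage(pop, min(schedule$passages[[key]], nrow(pop$counts)))
    pop <- grow_one_day(pop, params)
    if (day %in% schedule$collect) {
      idx <- sample.int(nrow(pop$counts), n_collect, replace = TRUE)
      x <- .pop_frac(pop$counts[idx, , drop = FALSE])
      samples[[paste0("day", day)]] <-
        data.table::data.table(missense_het = x[, 1L], silent_het = x[, 2L])
    }
  }
  list(population = pop, history = pop$history, samples = samples)
}
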