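# Kimura pure-drift distribution of allele frequency: fixation masses at 0
# and 1 plus a continuous interior density expressed as a Gegenbauer-
# polynomial series, parameterized by the initial frequency p0 and the
# drift extent b (b -> 1: no drift, the distribution concentrates at p0;
# b -> 0: complete fixation, point masses q0 and p0 at the boundaries).

# T_i(x) = F(1-i, i+2; 2; x) = P_{i-1}^{(1,1)}(1 - 2x) / i, evaluated via
# the (numerically stable) Jacobi three-term recurrence; |T_i| <= 1 on [0,1]
.kimura_T <- function(imax, x) {
  z <- 1 - 2 * x
  P <- matrix(0, nrow = imax, ncol = length(x))
  P[1L, ] <- 1
  if (imax >= 2) P[2L, ] <- 2 * z
  if (imax >= 3) for (n in 2:(imax - 1)) {
    P[n + 1L, ] <- ((n + 1) * ((2 * n + 1) * z * P[n, ] - n * P[n - 1L, ])) /
      (n * (n + 2))
  }
  sweep(P, 1L, seq_len(imax), "/")
}

# number of series terms needed so the truncated tail is below tol
.kimura_terms <- function(b, tol = 1e-8, max_terms = 400L) {
  i <- seq_len(max_terms)
  bound <- i * (i + 1) * (2 * i + 1) * 0.25 * b^(i * (i + 1) / 2)
  k <- which(bound < tol)
  if (length(k) == 0)
    stop("Kimura series did not reach tolerance ", tol, " within ",
         max_terms, " terms (b = ", b, " is too close to 1)")
  max(min(k), 2L)
}

#' Kimura distribution: interior density and fixation masses
#'
#' `kimura_density()` evaluates the continuous interior density at
#' heteroplasmy values in (0, 1); `kimura_masses()` returns the point
#' masses at 0 (loss) and 1 (fixation).  Together they integrate to one,
#' and the distribution's mean equals `p0` for every `b` (drift preserves
#' the expected allele frequency).
#'
#' @param h heteroplasmy values in (0, 1).
#' @param p0 initial population heteroplasmy in (0, 1).
#' @param b drift extent in (0, 1); under one generation of Wright-Fisher
#'   resampling of M molecules, `b = 1 - 1/M`.
#' @param tol series truncation tolerance (successive-term bound).
#' @return `kimura_density()`: density values; `kimura_masses()`: named
#'   vector `c(f0, f1)`.
#' @export
kimura_density <- function(h, p0, b, tol = 1e-8) {
  .check_kimura_args(p0, b)
  if (any(h <= 0 | h >= 1)) stop("h must lie strictly inside (0, 1)")
  imax <- .kimura_terms(b, tol)
  i <- seq_len(imax)
  q0 <- 1 - p0
  coef <- i * (i + 1) * (2 * i + 1) * p0 * q0 *
    .kimura_T(imax, p0)[, 1L] * b^(i * (i + 1) / 2)
  pmax(colSums(coef * .kimura_T(imax, h)), 0)
}

#' @rdname kimura_density
#' @export
kimura_masses <- function(p0, b, tol = 1e-8) {
  .check_kimura_args(p0, b)
  imax <- .kimura_terms(b, tol)
  i <- seq_len(imax)
  q0 <- 1 - p0
  w <- (2 * i + 1) * p0 * q0 * (-1)^i * b^(i * (i + 1) / 2)
  f1 <- p0 + sum(w * .kimura_T(imax, p0)[, 1L])
  f0 <- q0 + sum(w * .kimura_T(imax, q0)[, 1L])
  c(f0 = max(f0, 0), f1 = max(f1, 0))
}

.check_kimura_args <- function(p0, b) {
  if (p0 <= 0 || p0 >= 1) stop("p0 must be in (0, 1)")
  if (b <= 0 || b >= 1) stop("b must be in (0, 1)")
}

# interior CDF on a fixed grid (trapezoid rule); returns a function-like
# list used by the CDF, sampler and KS machinery
.kimura_cdf_grid <- function(p0, b, n_grid = 2001L) {
  x <- seq(1e-6, 1 - 1e-6, length.out = n_grid)
  d <- kimura_density(x, p0, b)
  m <- kimura_masses(p0, b)
  cum <- c(0, cumsum((d[-1L] + d[-n_grid]) / 2 * diff(x)))
  list(x = x, cdf = m[["f0"]] + cum, f0 = m[["f0"]], f1 = m[["f1"]],
       interior = cum[n_grid])
}

#' Kimura cumulative distribution function
#'
#' @inheritParams kimura_density
#' @param h heteroplasmy values in [0, 1].
#' @return P(H <= h), including the point masses at the boundaries.
#' @export
kimura_cdf <- function(h, p0, b) {
  g <- .kimura_cdf_grid(p0, b)
  out <- stats::approx(g$x, g$cdf, xout = h, rule = 2)$y
  out[h >= 1] <- 1
  out[h <= 0] <- g$f0
  out
}

#' Sample from a Kimura distribution
#'
#' Inverse-CDF sampling on a fine grid, with boundary draws mapped to the
#' point masses at 0 and 1.  With `truncated = TRUE` the sample is drawn
#' conditional on non-loss (h > 0), matching data from which
#' zero-heteroplasmy cells were removed.
#'
#' @inheritParams kimura_density
#' @param n number of draws.
#' @param truncated draw conditional on h > 0.
#' @return numeric vector in [0, 1] (or (0, 1] when truncated).
#' @export
rkimura <- function(n, p0, b, truncated = FALSE) {
  g <- .kimura_cdf_grid(p0, b)
  lo <- if (truncated) g$f0 else 0
  u <- stats::runif(n, lo, 1)
  out <- numeric(n)
  at0 <- u <= g$f0
  at1 <- u >= 1 - g$f1
  mid <- !at0 & !at1
  out[at1] <- 1
  if (any(mid))
    out[mid] <- stats::approx(g$cdf, g$x, xout = u[mid], rule = 2,
                              ties = "ordered")$y
  out
}

# KS sup-distance between the ECDF of data (in (0,1]) and the fitted
# Kimura conditioned on h > 0
.kimura_ks_stat <- function(h, grid) {
  n <- length(h)
  hs <- sort(h)
  denom <- 1 - grid$f0
  Fh <- (stats::approx(grid$x, grid$cdf, xout = hs, rule = 2)$y - grid$f0) /
    denom
  Fh[hs >= 1] <- (grid$f0 + grid$interior - grid$f0) / denom  # left limit at 1
  # left limit: continuous except the mass at 1, where F jumps to 1
  Fh_right <- Fh
  Fh_right[hs >= 1] <- 1
  i <- seq_len(n)
  max(abs(i / n - Fh_right), abs((i - 1) / n - Fh))
}

#' Fit the Kimura drift parameter with fixed initial heteroplasmy
#'
#' Fixes the initial population heteroplasmy `p0` (typically the mean
#' heteroplasmy observed at day 0), removes zero-heteroplasmy cells, and
#' fits the drift parameter `b` to the later-timepoint heteroplasmy values
#' by bounded one-dimensional optimization.  The default objective is the
#' maximum of the likelihood conditioned on non-loss (h > 0), honouring
#' the removal of unedited cells; `objective = "ks"` instead minimizes the
#' Kolmogorov-Smirnov distance between the data and the conditional model
#' CDF.
#'
#' @param h heteroplasmy observations in [0, 1]; zeros are removed here.
#' @param p0 fixed initial heteroplasmy in (0, 1).
#' @param objective `"mle"` or `"ks"`.
#' @param lower,upper optimization bounds for `b`.
#' @return list of class `scilite_kimura_fit`: `p0`, `b`, `logLik`, `D`
#'   (KS distance at the fit), `objective`, `n` (observations used),
#'   `n_zero_removed`.
#' @export
fit_kimura_b <- function(h, p0, objective = c("mle", "ks"),
                         lower = 1e-3, upper = 1 - 1e-6) {
  objective <- match.arg(objective)
  n_zero <- sum(h == 0)
  h <- h[h > 0]
  if (length(h) < 20)
    stop("need at least 20 non-zero observations to fit b")
  if (any(h < 0 | h > 1)) stop("heteroplasmy values must be in [0, 1]")
  # cap b so the series stays within the term budget
  upper <- min(upper, .kimura_b_cap())
  cond_loglik <- function(b) {
    m <- kimura_masses(p0, b)
    interior <- h < 1
    dens <- if (any(interior)) kimura_density(h[interior], p0, b) else numeric(0)
    sum(log(pmax(dens, 1e-300))) + sum(!interior) * log(max(m[["f1"]], 1e-300)) -
      length(h) * log(max(1 - m[["f0"]], 1e-300))
  }
  if (objective == "mle") {
    opt <- stats::optimize(cond_loglik, c(lower, upper), maximum = TRUE,
                           tol = 1e-6)
    b_hat <- opt$maximum
    ll <- opt$objective
  } else {
    ksfun <- function(b) .kimura_ks_stat(h, .kimura_cdf_grid(p0, b))
    opt <- stats::optimize(ksfun, c(lower, upper), tol = 1e-6)
    b_hat <- opt$minimum
    ll <- cond_loglik(b_hat)
  }
  if (b_hat > upper - 1e-4 || b_hat < lower + 1e-4)
    warning("fitted b is at the boundary of its allowed range")
  D <- .kimura_ks_stat(h, .kimura_cdf_grid(p0, b_hat))
  structure(list(p0 = p0, b = b_hat, logLik = ll, D = D,
                 objective = objective, n = length(h),
                 n_zero_removed = n_zero),
            class = "scilite_kimura_fit")
}

# largest b for which the series converges within the term budget
.kimura_b_cap <- function(tol = 1e-8, max_terms = 400L) {
  i <- max_terms
  # solve i(i+1)(2i+1)/4 * b^(i(i+1)/2) = tol for b at the last term
  exp((log(tol) - log(i * (i + 1) * (2 * i + 1) / 4)) / (i * (i + 1) / 2))
}

#' @export
print.scilite_kimura_fit <- function(x, ...) {
  cat(sprintf(
    "Kimura fit (%s): p0 = %.4f (fixed), b = %.4f, logLik = %.2f, D = %.4f\n",
    x$objective, x$p0, x$b, x$logLik, x$D))
  if (!is.null(x$p_value))
    cat(sprintf("Monte-Carlo KS: p = %.3f (num_MC = %d)\n",
                x$p_value, x$num_MC))
  invisible(x)
}

#' Monte-Carlo Kolmogorov-Smirnov test of a Kimura fit
#'
#' Computes the KS sup-distance D between the empirical CDF of the data
#' (zero-heteroplasmy cells removed) and the fitted Kimura conditioned on
#' non-loss, then draws `num_MC` synthetic datasets of the same size from
#' the fitted distribution and reports the fraction whose D exceeds the
#' observed one.  A small p flags data inconsistent with pure drift — the
#' signature used to tell selection from drift.
#'
#' Because `b` is estimated from the same data, each Monte-Carlo replicate
#' is refitted before its D is computed (a parametric bootstrap), which
#' keeps the p-value calibrated; `refit = FALSE` skips the refit and
#' compares every replicate to the original fitted CDF, which is cheaper
#' but conservative.
#'
#' @param h heteroplasmy observations (zeros removed internally).
#' @param fit a [fit_kimura_b()] result.
#' @param num_MC number of Monte-Carlo replicates (default 100).
#' @param seed RNG seed.
#' @param refit refit `b` on every synthetic replicate (default `TRUE`).
#' @return the fit, augmented with `D`, `p_value`, `num_MC`.
#' @export
ks_test_kimura <- function(h, fit, num_MC = 100L, seed = 1L, refit = TRUE) {
  if (num_MC < 1) stop("num_MC must be at least 1")
  h <- h[h > 0]
  grid <- .kimura_cdf_grid(fit$p0, fit$b)
  D_obs <- .kimura_ks_stat(h, grid)
  set.seed(seed)
  n <- length(h)
  D_mc <- vapply(seq_len(num_MC), function(j) {
    sim <- rkimura(n, fit$p0, fit$b, truncated = TRUE)
    if (refit) {
      f_j <- suppressWarnings(fit_kimura_b(sim, fit$p0,
                                           objective = fit$objective))
      .kimura_ks_stat(sim, .kimura_cdf_grid(fit$p0, f_j$b))
    } else {
      .kimura_ks_stat(sim, grid)
    }
  }, numeric(1))
  fit$D <- D_obs
  fit$p_value <- mean(D_mc >= D_obs)
  fit$num_MC <- as.integer(num_MC)
  fit
}
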