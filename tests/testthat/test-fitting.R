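.mk_samples <- function(n, m_mean, s_mean, seed) {
  set.seed(seed)
  data.table::data.table(
    missense_het = pmin(pmax(stats::rnorm(n, m_mean, 0.1), 0), 1),
    silent_het = pmin(pmax(stats::rnorm(n, s_mean, 0.05), 0), 1))
}

test_that("combined MSE is zero for identical samples, symmetric, and grows with shift", {
  a <- list(day5 = .mk_samples(400, 0.5, 0.2, 1))
  expect_equal(combined_mse(a, a), 0)

  shifts <- c(0.05, 0.1, 0.2)
  scores <- vapply(shifts, function(d) {
    b <- list(day5 = data.table::copy(a$day5))
    b$day5[, missense_het := pmin(missense_het + d, 1)]
    combined_mse(b, a)
  }, numeric(1))
  expect_true(all(diff(scores) > 0))       # strictly increasing in the shift
  # the mean-heteroplasmy component contributes ~ delta^2 (2 x delta^2 / 2)
  b <- list(day5 = data.table::copy(a$day5))
  b$day5[, missense_het := missense_het + 0.1]
  delta <- mean(b$day5$missense_het) - mean(a$day5$missense_het)
  expect_gte(combined_mse(b, a), delta^2 * 0.99)
  expect_equal(combined_mse(b, a), combined_mse(a, b))  # symmetry
  expect_error(combined_mse(list(day5 = a$day5[0]), a), "empty")
})

test_that("knn smoothing matches a brute-force all-pairs oracle", {
  set.seed(23)
  n <- 200L
  space <- search_space()
  pts <- data.frame(d = runif(n, 0.05, 1), p = exp(runif(n, log(0.5), log(50))),
                    l = runif(n, 0.2, 1), M = exp(runif(n, log(100), log(1e4))))
  scores <- runif(n)
  for (k in c(1L, 10L, 50L, n)) {
    got <- knn_smooth(pts, scores, k, space)
    z <- scilite:::.scale_params(pts, space)
    dm <- as.matrix(stats::dist(z))
    want <- vapply(seq_len(n), function(i)
      mean(scores[order(dm[i, ])[seq_len(k)]]), numeric(1))
    expect_equal(got, want, tolerance = 1e-12, label = paste("k =", k))
  }
  # degenerate cases
  expect_equal(knn_smooth(pts, rep(2, n), 25, space), rep(2, n))
  expect_equal(knn_smooth(pts, scores, n, space), rep(mean(scores), n))
  expect_equal(knn_smooth(pts, scores, 1, space), scores)
  expect_error(knn_smooth(pts, scores, n + 1, space), "exceed")
})

test_that("random search scores every draw and k = 1 smoothing is a no-op", {
  day0 <- make_edited_population(n_cells = 150, seed = 5)$observed
  sched <- default_schedule(days = 5, passages = c(`3` = 300),
                            collect = 5L, scale = 1)
  obs_run <- run_timecourse(day0, sigmoid_params(0.3, 5, 0.6, 500), sched,
                            n_cells = 150, n_collect = 150, seed = 17)
  observed <- c(list(day0 = day0), obs_run$samples)
  fit <- random_search(observed,
                       search_space(n_iterations = 24L, k_neighbours = 1L),
                       schedule = sched, n_cells = 150, seed = 33)
  expect_equal(nrow(fit$iterations), 24L)
  expect_equal(fit$iterations$raw_mse, fit$iterations$smoothed_mse)
  expect_equal(fit$best_iter, which.min(fit$iterations$smoothed_mse))
  expect_true(all(fit$iterations$raw_mse >= 0))
  # draws respect the space bounds
  expect_true(all(fit$iterations$d >= 0.05 & fit$iterations$d <= 1))
  expect_true(all(fit$iterations$M >= 100 & fit$iterations$M <= 1e4))
  expect_error(random_search(list(day0 = day0),
                             search_space(n_iterations = 24L)),
               "later timepoint")
})

test_that("replicate runs are seed-stable and tighten with population size", {
  day0 <- make_edited_population(n_cells = 150, seed = 5)$observed
  sched <- default_schedule(days = 5, passages = c(`3` = 500), collect = 5L)
  r1 <- replicate_runs(sigmoid_params(), day0, n_runs = 3, schedule = sched,
                       n_cells = 200, seed = 9)
  r2 <- replicate_runs(sigmoid_params(), day0, n_runs = 3, schedule = sched,
                       n_cells = 200, seed = 9)
  expect_identical(r1, r2)
  expect_equal(sort(unique(r1$day)), 5)
  expect_equal(nrow(r1), 3L)

  spread <- vapply(c(100L, 1600L), function(nc) {
    r <- replicate_runs(sigmoid_params(d = 1), day0, n_runs = 15,
                        schedule = sched, n_cells = nc, seed = 41)
    stats::sd(r$mean_missense)
  }, numeric(1))
  expect_gt(spread[1], spread[2])   # SE shrinks as N grows
})
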