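test_that("inverse-sigmoid fitness has the stated shape and landmarks", {
  pars <- sigmoid_params(0.31, 4.95, 0.75)
  # exact inflection value
  expect_equal(fitness(pars$l, pars), (1 + pars$d) / 2)
  # monotone non-increasing, bounded in [d, 1]
  x <- seq(0, 1, by = 0.001)
  y <- fitness(x, pars)
  expect_true(all(diff(y) <= 0))
  expect_true(all(y >= pars$d & y <= 1))
  # a homoplasmic wild-type cell grows at full rate
  expect_equal(fitness(0, pars), 1, tolerance = 1e-3)
  expect_error(fitness(1.2, pars), "\\[0, 1\\]")
  expect_error(sigmoid_params(d = 0), "d must")
  expect_error(sigmoid_params(l = 1.5), "l must")
})

test_that("editing model gives H = 1 - (1/2)^n", {
  expect_equal(editor_heteroplasmy(0), 0)
  expect_equal(editor_heteroplasmy(1), 0.5)
  expect_equal(editor_heteroplasmy(3), 0.875)
  expect_error(editor_heteroplasmy(-1), "non-negative")
})

test_that("multinomial molecule resampling is unbiased with binomial variance", {
  pars <- sigmoid_params(M = 200L)
  pop <- sim_population(matrix(rep(c(120L, 40L, 40L), each = 2000),
                               ncol = 3), day = 0L)
  set.seed(3)
  res <- resample_molecules(pop, pars)
  x <- heteroplasmy_fractions(res)[, 1L]
  expect_equal(mean(x), 0.6, tolerance = 4 / sqrt(2000))  # MC error bound
  expect_equal(stats::var(x), 0.6 * 0.4 / 200, tolerance = 0.08)
  # homoplasmic cells stay homoplasmic
  homo <- sim_population(matrix(c(50L, 0L, 0L), nrow = 1), day = 0L)
  expect_equal(
    unname(heteroplasmy_fractions(resample_molecules(homo, pars))[1, 1]), 1)
})

test_that("initialization bootstraps day-0 cells and breaks duplicate ties", {
  day0 <- make_edited_population(n_cells = 500, seed = 2)$observed
  set.seed(10)
  pop <- init_population(day0, n_cells = 2500, params = sigmoid_params())
  expect_equal(nrow(pop$counts), 2500L)
  # bootstrap + resampling noise: sd of the mean is ~0.008 at this size
  expect_lt(abs(mean(heteroplasmy_fractions(pop)[, 1L]) -
                  mean(day0$missense_het)), 0.03)
  # duplicate draws of one mixed source cell differ after resampling
  one <- day0[which(day0$missense_het > 0.3 & day0$missense_het < 0.7)[1L]]
  set.seed(11)
  twin <- init_population(rbind(one, one), n_cells = 2L,
                          params = sigmoid_params(M = 1000L))
  expect_false(all(twin$counts[1L, ] == twin$counts[2L, ]))
  expect_error(init_population(day0[0], 10), "empty")
  set.seed(12)
  single <- init_population(day0, n_cells = 1L)
  expect_equal(nrow(single$counts), 1L)
})

test_that("daily growth doubles the culture and selection lowers heteroplasmy", {
  day0 <- make_edited_population(n_cells = 400, seed = 6)$observed
  set.seed(20)
  pop <- init_population(day0, n_cells = 1000)
  grown <- grow_one_day(pop, sigmoid_params())
  expect_equal(nrow(grown$counts), 2000L)      # exact doubling
  expect_equal(grown$day, 1L)

  # mutant molecules never arise de novo
  wtpop <- sim_population(matrix(rep(c(0L, 10L, 90L), each = 50), ncol = 3))
  for (i in 1:3) wtpop <- grow_one_day(wtpop, sigmoid_params(M = 100L))
  expect_true(all(wtpop$counts[, 1L] == 0L))

  # with d < 1 the mean missense heteroplasmy decreases in expectation
  deltas <- vapply(1:25, function(s) {
    set.seed(100 + s)
    p <- init_population(day0, n_cells = 800,
                         params = sigmoid_params(0.3, 5, 0.5, 500))
    g <- grow_one_day(p, sigmoid_params(0.3, 5, 0.5, 500))
    mean(heteroplasmy_fractions(g)[, 1L]) -
      mean(heteroplasmy_fractions(p)[, 1L])
  }, numeric(1))
  expect_lt(mean(deltas), 0)
})

test_that("passaging is an unbiased uniform bottleneck", {
  day0 <- make_edited_population(n_cells = 300, seed = 8)$observed
  set.seed(30)
  pop <- init_population(day0, n_cells = 2000)
  expect_equal(passage(pop, 2000)$counts, pop$counts)   # identity
  expect_error(passage(pop, 3000), "exceeds")
  one <- passage(pop, 1)
  expect_equal(nrow(one$counts), 1L)
  deltas <- vapply(1:40, function(s) {
    set.seed(200 + s)
    mean(heteroplasmy_fractions(passage(pop, 200))[, 1L])
  }, numeric(1))
  expect_equal(mean(deltas), mean(heteroplasmy_fractions(pop)[, 1L]),
               tolerance = 0.01)
})

test_that("time course is seed-reproducible and selection drives a monotone decline", {
  day0 <- make_edited_population(n_cells = 400, zero_weight = 0.3, seed = 14)$observed
  sched <- default_schedule(scale = 0.2)
  r1 <- run_timecourse(day0, sigmoid_params(), sched, n_cells = 500, seed = 77)
  r2 <- run_timecourse(day0, sigmoid_params(), sched, n_cells = 500, seed = 77)
  expect_identical(serialize(r1, NULL), serialize(r2, NULL))

  # fitted-parameter dynamics: mean missense heteroplasmy falls across
  # the collection days
  means <- vapply(r1$samples, function(s) mean(s$missense_het), numeric(1))
  expect_equal(names(means), c("day5", "day10", "day15"))
  expect_true(all(diff(means) < 0))

  # no growth days: initial population returned, no samples
  r0 <- run_timecourse(day0, sigmoid_params(),
                       default_schedule(days = 0, passages = numeric(0),
                                        collect = integer(0)),
                       n_cells = 100, seed = 1)
  expect_equal(r0$population$day, 0L)
  expect_length(r0$samples, 0L)
})

test_that("neutral dynamics preserve day-0 marginals (drift only)", {
  day0 <- make_edited_population(n_cells = 400, zero_weight = 0.3, seed = 16)$observed
  sched <- default_schedule(days = 5, passages = c(`3` = 1000), collect = 5L)
  # across seeds the day-5 collection mean is an unbiased estimate of the
  # day-0 mean; per-seed deviations are genuine neutral drift
  runs <- lapply(1:30, function(s)
    run_timecourse(day0, sigmoid_params(d = 1, M = 2000), sched,
                   n_cells = 1000, seed = 500 + s)$samples$day5$missense_het)
  devs <- vapply(runs, mean, numeric(1)) - mean(day0$missense_het)
  se <- stats::sd(devs) / sqrt(length(devs))
  expect_lt(abs(mean(devs)), 3 * se)
  # pooled across seeds, per-seed drift averages out: the unedited-cell
  # fraction and the edited-cell median match day 0
  pooled <- unlist(runs)
  expect_lt(abs(mean(pooled == 0) - mean(day0$missense_het == 0)), 0.05)
  expect_lt(abs(stats::median(pooled[pooled > 0]) -
                  stats::median(day0$missense_het[day0$missense_het > 0])),
            0.05)
})
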