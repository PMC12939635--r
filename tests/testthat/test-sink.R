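crowded_state <- function(n_females, n_males) {
  p <- simulation_params(n_initial_females = n_females,
                         n_initial_males = n_males)
  init_population(p)
}

test_that("deviation decay fires only on strict threshold exceedance", {
  sink <- sink_params(enabled = TRUE, n_crit_individual = 400,
                      n_crit_social = 300)
  st <- crowded_state(200, 200)            # N = 400, not above threshold
  apply_deviation_decay(st, sink)
  expect_true(all(st$deviation[mouseutopia:::living(st)] == 1))

  st <- crowded_state(400, 400)            # N = 800
  apply_deviation_decay(st, sink)
  expect_true(all(st$deviation[mouseutopia:::living(st)] == 0.5))
  apply_deviation_decay(st, sink)          # second consecutive day
  expect_true(all(st$deviation[mouseutopia:::living(st)] == 0.25))

  # disabled sink is a no-op at any density
  st <- crowded_state(400, 400)
  apply_deviation_decay(st, sink_params(enabled = FALSE))
  expect_true(all(st$deviation[mouseutopia:::living(st)] == 1))
})

test_that("a newborn's deviation is the parental mean, within parental bounds", {
  expect_equal(newborn_deviation(1, 1), 1)
  expect_equal(newborn_deviation(0.5, 0.25), 0.375)
  expect_equal(newborn_deviation(0, 1), 0.5)  # can exceed one parent
  expect_error(newborn_deviation(1.2, 0.5), "\\[0, 1\\]")
  set.seed(20)
  m <- runif(500); f <- runif(500)
  child <- newborn_deviation(m, f)
  expect_true(all(child >= pmin(m, f) & child <= pmax(m, f)))
})

test_that("beautiful ones appear only above the social threshold, once per male", {
  # below threshold: no tests, no beautiful ones
  sink <- sink_params(enabled = TRUE, n_crit_social = 1000)
  st <- crowded_state(0, 500)
  set.seed(21)
  assign_beautiful(st, sink, adult_age = 65)
  expect_equal(sum(st$beautiful[1:st$n]), 0L)
  expect_equal(sum(st$beautiful_tested[1:st$n]), 0L)

  # p = 1 above threshold: every adult male converts at his first test
  sink <- sink_params(enabled = TRUE, n_crit_social = 100, p_beautiful = 1)
  st <- crowded_state(0, 500)
  assign_beautiful(st, sink, adult_age = 65)
  expect_equal(sum(st$beautiful[1:st$n]), 500L)

  # binomial rate at p = 0.3 over ~1100 tested males
  sink <- sink_params(enabled = TRUE, n_crit_social = 1000, p_beautiful = 0.3)
  st <- crowded_state(0, 1100)
  set.seed(22)
  assign_beautiful(st, sink, adult_age = 65)
  n_beau <- sum(st$beautiful[1:st$n])
  expect_true(abs(n_beau - 330) < 4 * sqrt(1100 * 0.3 * 0.7))
  expect_equal(sum(st$beautiful_tested[1:st$n]), 1100L)
  # no re-testing: a second pass changes nothing
  before <- st$beautiful[1:st$n]
  assign_beautiful(st, sink, adult_age = 65)
  expect_identical(st$beautiful[1:st$n], before)
})

test_that("beautiful males sire no litters", {
  p <- pair_params(horizon = 80, seed = 23)
  set.seed(p$seed)
  st <- init_population(p)
  st$beautiful[which(st$is_male[1:st$n])] <- TRUE
  for (d in 1:80) step_day(st, p)
  expect_equal(st$cum_births, 0L)
})

test_that("litter abandonment is gated by the social threshold", {
  st <- crowded_state(100, 100)
  # below threshold: never abandons, no RNG consumed
  sink <- sink_params(enabled = TRUE, n_crit_social = 500, p_abandon = 1)
  expect_false(abandonment_check(st, sink, mother = 1L))
  # certain abandonment above it
  sink <- sink_params(enabled = TRUE, n_crit_social = 50, p_abandon = 1)
  expect_true(abandonment_check(st, sink, mother = 1L))
  expect_equal(st$abandoned_today, 1L)
  # binomial rate at p = 0.5
  sink <- sink_params(enabled = TRUE, n_crit_social = 50, p_abandon = 0.5)
  set.seed(24)
  hits <- sum(vapply(1:2000, function(i) abandonment_check(st, sink, 1L),
                     logical(1)))
  expect_true(abs(hits - 1000) < 4 * sqrt(2000 * 0.25))
})

test_that("certain abandonment above a low threshold stops all recruitment", {
  p <- simulation_params(horizon = 150, seed = 25,
                         sink = sink_params(enabled = TRUE,
                                            n_crit_individual = 10000,
                                            n_crit_social = 5, p_abandon = 1))
  r <- run_simulation(p)
  expect_true(all(r$records$births == 0))
  expect_gt(sum(r$records$abandoned_litters), 0)
})

test_that("a disabled sink reproduces the pure growth engine bit-for-bit", {
  # enabled-but-never-triggered consumes no extra RNG, so trajectories match
  p_off <- simulation_params(horizon = 150, seed = 26)
  p_hi <- modify_params(p_off, list(sink = list(enabled = TRUE,
                                                n_crit_individual = 1e6,
                                                n_crit_social = 1e6)))
  a <- run_simulation(p_off)
  b <- run_simulation(p_hi)
  expect_identical(a$records, b$records)
  expect_true(all(a$records$mean_deviation == 1))
  expect_true(all(a$records$n_beautiful == 0))
})

test_that("an individual's deviation never increases under repeated decay", {
  sink <- sink_params(enabled = TRUE, n_crit_individual = 100)
  st <- crowded_state(80, 80)
  prev <- st$deviation[1:st$n]
  for (i in 1:30) {
    apply_deviation_decay(st, sink)
    cur <- st$deviation[1:st$n]
    expect_true(all(cur <= prev + 1e-12))
    expect_true(all(cur >= 0 & cur <= 1))
    prev <- cur
  }
})

test_that("population-mean deviation does not rise on consecutive decay days", {
  p <- preset_params("set1", horizon = 600, seed = 27,
                     sink = list(enabled = TRUE, n_crit_individual = 400,
                                 n_crit_social = 300))
  r <- run_simulation(p)$records
  fire <- r$n_total > 400
  d <- which(fire[-1] & fire[-nrow(r)]) + 1L
  expect_gt(length(d), 10)
  expect_true(all(r$mean_deviation[d] <= r$mean_deviation[d - 1L] + 1e-9))
})
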