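test_that("analytic selection coefficient matches hand evaluations", {
  # identical genotypes are neutral
  expect_equal(analytic_selection_coefficient(805, 162, 805, 162), 0)
  # doubling-time-only term
  expect_equal(
    analytic_selection_coefficient(804.8, 162.3, 804.8, 130.2, M = 5),
    0.1709, tolerance = 1e-3)
  # full FPS1 parameters
  expect_equal(
    analytic_selection_coefficient(804.8, 162.3, 276.6, 130.2, M = 5),
    0.7333, tolerance = 1e-3)
  expect_error(analytic_selection_coefficient(805, 0, 805, 162), "doubling")
  expect_warning(analytic_selection_coefficient(200, 162, 500, 162),
                 "assumption")
})

test_that("doubling and lag terms are exactly additive", {
  set.seed(41)
  for (i in 1:200) {
    l1 <- runif(1, 100, 900)
    l2 <- runif(1, 50, l1)
    t1 <- runif(1, 80, 300)
    t2 <- runif(1, 80, 300)
    M <- sample(1:10, 1)
    expect_identical(
      analytic_selection_coefficient(l1, t1, l2, t2, M),
      analytic_selection_coefficient(l1, t1, l2, t2, M, "doubling") +
        analytic_selection_coefficient(l1, t1, l2, t2, M, "lag"))
  }
})

test_that("lag-term benefit decays with more doublings and slower mutants", {
  lag_term <- function(M, t2) analytic_selection_coefficient(
    804.8, 162.3, 276.6, t2, M, component = "lag")
  expect_true(all(diff(sapply(2:10, lag_term, t2 = 130.2)) < 0))
  expect_true(all(diff(sapply(seq(100, 200, 10), function(t2)
    lag_term(5, t2))) < 0))
})

test_that("neutral competition conserves the frequency ratio", {
  p <- batch_protocol(1e5, 5, 20)
  for (dil in c("whole-cells", "continuous")) {
    fit <- compete_deterministic(growth_law(804.8, 162.3, 99999),
                                 growth_law(804.8, 162.3, 1), p,
                                 dilution = dil)
    expect_equal(max(abs(diff(fit$trajectory$ln_ratio))), 0,
                 tolerance = 1e-9)
  }
})

test_that("a doubly disadvantaged mutant declines monotonically", {
  p <- batch_protocol(1e4, 5, 10)
  # the mutant's longer lag puts it outside the analytic derivation's
  # assumption, which compete_deterministic flags
  expect_warning(
    fit <- compete_deterministic(growth_law(300, 120, 9990),
                                 growth_law(500, 150, 10), p,
                                 dilution = "continuous"),
    "assumption")
  expect_true(all(diff(fit$trajectory$ln_ratio) < 0))
})

test_that("regression recovers an exactly linear log-ratio", {
  d <- data.frame(generations = seq(0, 100, 5),
                  ln_ratio = -10 + 0.5 * seq(0, 100, 5))
  expect_equal(regress_selection_coefficient(d), 0.5)
  expect_error(regress_selection_coefficient(
    data.frame(generations = c(0, 5), ln_ratio = c(0, 1))), "at least 3")
  expect_error(regress_selection_coefficient(
    data.frame(generations = c(0, 5, 10), ln_ratio = c(0, 1, Inf))),
    "extinct")
})

test_that("first-cycle ratio gain matches the analytic coefficient", {
  # with the mutant at frequency 1e-5 the resident sets the cycle end, so
  # the per-generation ln(r) increment equals the closed form
  p <- batch_protocol(1e5, 5, 1)
  for (mut in list(fps1_mutant(), ask10_mutant(), acr3_mutant())) {
    fit <- compete_deterministic(arsenic_wt(), mut, p,
                                 dilution = "continuous")
    inc <- diff(fit$trajectory$ln_ratio) / 5
    expect_equal(inc, analytic_selection_coefficient(
      804.8, 162.3, mut$lag, mut$doubling_time, 5), tolerance = 1e-3)
  }
})

test_that("whole-cell dilution truncates the trajectory at WT extinction", {
  p <- batch_protocol(1e5, 5, 20)
  fit <- compete_deterministic(arsenic_wt(), fps1_mutant(), p)
  expect_identical(fit$extinct, "wt")
  expect_lt(max(fit$trajectory$cycle), 20)
  cont <- compete_deterministic(arsenic_wt(), fps1_mutant(), p,
                                dilution = "continuous")
  expect_true(is.na(cont$extinct))
  expect_identical(max(cont$trajectory$cycle), 20)
  # frozen values from the independent trajectory oracle
  expect_equal(unname(coef(fit)), 0.6539, tolerance = 1e-3)
  expect_equal(unname(coef(cont)), 0.5999, tolerance = 1e-3)
})

test_that("fixation generation reports the first cycle at threshold", {
  p <- batch_protocol(1e5, 5, 20)
  fit <- compete_deterministic(arsenic_wt(), fps1_mutant(), p)
  expect_equal(fixation_generation(fit), 25)
  expect_true(is.na(fixation_generation(
    compete_deterministic(growth_law(804.8, 162.3, 99999),
                          growth_law(804.8, 162.3, 1), p))))
})

test_that("trajectory export writes one row per cycle end plus t = 0", {
  p <- batch_protocol(1e4, 5, 6)
  fit <- compete_deterministic(growth_law(500, 150, 9999),
                               growth_law(400, 140, 1), p,
                               dilution = "continuous")
  path <- tempfile(fileext = ".tsv")
  write_trajectory(fit, path)
  back <- read.table(path, header = TRUE, sep = "\t")
  expect_identical(nrow(back), 7L)
  expect_named(back, c("cycle", "t_end_min", "generations", "ln_ratio",
                       "mutant_frequency"))
  expect_equal(back$ln_ratio, fit$trajectory$ln_ratio)
})
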