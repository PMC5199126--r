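test_that("preprocessing smooths, subtracts background and floors", {
  # constant curve collapses to the epsilon floor
  flat <- growth_curve(seq(0, 200, 20), rep(0.08, 11))
  pre <- preprocess_curve(flat)
  expect_true(all(pre$od == pre$eps))
  # a single aberrant reading is removed by the running median
  od <- rep(0.08, 11)
  od[6] <- 0.8
  spiky <- preprocess_curve(growth_curve(seq(0, 200, 20), od),
                            smoothing_window = 3)
  expect_true(all(spiky$od == spiky$eps))
  expect_error(preprocess_curve(growth_curve(c(0, 20), c(1, 1))), "window")
  # calibration hook is applied to the net signal
  cal <- preprocess_curve(flat, calibration = function(x) 10 * x)
  expect_true(all(cal$od == 10 * pre$eps))
})

test_that("extraction round-trips a noiseless synthetic curve", {
  spec <- synthetic_curve_spec(lag = 276.6, doubling_time = 130.2,
                               noise_sd = 0)
  fc <- extract_fitness_components(generate_growth_curve(spec))
  expect_identical(fc$flag, "ok")
  expect_lt(abs(fc$doubling_h * 60 - 130.2) / 130.2, 0.02)
  expect_lt(abs(fc$lag_h * 60 - 276.6), 20)        # one sampling interval
  expect_lt(abs(fc$efficiency_od - 1), 0.05)
  # the classical tangent estimator agrees on clean data
  fc2 <- extract_fitness_components(generate_growth_curve(spec),
                                    method = "max-slope")
  expect_lt(abs(fc2$doubling_h * 60 - 130.2) / 130.2, 0.05)
  expect_lt(abs(fc2$lag_h * 60 - 276.6), 40)
})

test_that("a lag-free exponential start yields a near-zero lag", {
  spec <- synthetic_curve_spec(lag = 0, doubling_time = 120, noise_sd = 0)
  fc <- extract_fitness_components(generate_growth_curve(spec))
  expect_lt(fc$lag_h * 60, 20)
})

test_that("doubling time is invariant to scaling the curve", {
  spec <- synthetic_curve_spec(lag = 300, doubling_time = 150, noise_sd = 0)
  cu <- generate_growth_curve(spec)
  scaled <- growth_curve(cu$times, cu$od * 2.5, well_id = "scaled")
  a <- extract_fitness_components(cu)
  b <- extract_fitness_components(scaled)
  expect_equal(a$doubling_h, b$doubling_h, tolerance = 0.01)
})

test_that("no-growth curves are flagged, not crashed", {
  flat <- growth_curve(seq(0, 2000, 20), rep(0.08, 101))
  fc <- extract_fitness_components(flat)
  expect_identical(fc$flag, "no_growth")
  expect_true(is.na(fc$doubling_h))
})

test_that("founder normalization follows the orientation conventions", {
  expect_equal(normalize_to_founder(2, c(2, 2, 2), "doubling"), 0)
  expect_equal(normalize_to_founder(2, c(2, 2), "lag"), 0)
  expect_equal(normalize_to_founder(2, c(2, 2), "efficiency"), 0)
  # doubling time halved: log2 drops by 1, relative value +1
  expect_equal(normalize_to_founder(log2(1), log2(2), "doubling"), 1)
  # efficiency doubled: reversed orientation, also +1
  expect_equal(normalize_to_founder(log2(4), log2(2), "efficiency"), 1)
  expect_error(normalize_to_founder(1, numeric(0), "lag"), "founder")
})

test_that("plates are read in wide and long format alike", {
  set.seed(12)
  pl <- generate_plate(list(mutant = synthetic_curve_spec()),
                       n_founder_controls = 2)
  wide_path <- tempfile(fileext = ".tsv")
  write_plate(pl$plate, wide_path)
  wide <- read_plate(wide_path)
  expect_identical(length(wide), 3L)
  long <- do.call(rbind, lapply(wide, function(cu)
    data.frame(well = cu$well_id, time = cu$times, od = cu$od)))
  long_path <- tempfile(fileext = ".csv")
  write.csv(long, long_path, row.names = FALSE)
  back <- read_plate(long_path)
  expect_identical(sort(names(back)), sort(names(wide)))
  expect_equal(back[[1]]$od, wide[[names(back)[1]]]$od)
})

test_that("well components normalize against founder controls", {
  set.seed(13)
  # mutant with half the founder doubling time: relative doubling ~ +1 log2
  pl <- generate_plate(
    list(fast = synthetic_curve_spec(lag = 300, doubling_time = 81)),
    founder_spec = synthetic_curve_spec(lag = 300, doubling_time = 162),
    n_founder_controls = 6)
  curves <- lapply(seq_len(nrow(pl$layout)), function(i)
    growth_curve(pl$plate$time, pl$plate[[pl$layout$well[i]]],
                 well_id = pl$layout$well[i]))
  names(curves) <- pl$layout$well
  out <- fit_growth_curves(curves, founder_wells = pl$founder_wells)
  founder_rows <- out$well_id %in% pl$founder_wells
  expect_lt(max(abs(out$relative_doubling[founder_rows])), 0.1)
  expect_equal(out$relative_doubling[!founder_rows], 1, tolerance = 0.1)
  expect_error(fit_growth_curves(curves, founder_wells = "nonexistent"),
               "founder")
})
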