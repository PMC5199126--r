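test_that("doubling-time effects follow the saturating conversion with cap", {
  expect_equal(effect_on_doubling(0), 0)
  expect_equal(effect_on_doubling(0.25, 162, 126), 32.4)
  expect_equal(effect_on_doubling(1, 162, 126), 36)   # 81 capped
  expect_equal(effect_on_doubling(Inf, 162, 126), 36)
  expect_error(effect_on_doubling(-1), "undefined")
})

test_that("lag effects use the rearranged lag-selection identity", {
  expect_equal(effect_on_lag(0, 130.2), 0)
  # round trip: the produced lag change re-inserted into the lag-only
  # selection formula returns s = s_r * ln 2
  s_r <- 0.8114
  dl <- effect_on_lag(s_r, 130.2, M = 5)
  expect_equal(dl, 528.2, tolerance = 1e-3)
  expect_equal(log(2) * dl / (5 * 130.2), 0.5624, tolerance = 1e-4)
  expect_equal(effect_on_lag(10, 130.2, M = 5, L_wt = 805, L_wt_N = 271),
               534)
  expect_error(effect_on_lag(1, 0), "doubling")
})

test_that("diminishing returns scale with distance to the optimum", {
  expect_equal(apply_diminishing_returns(30, 162, 162, 126), 30)
  expect_equal(apply_diminishing_returns(30, 126, 162, 126), 0)
  expect_equal(apply_diminishing_returns(30, 144, 162, 126), 15)
  expect_error(apply_diminishing_returns(30, 126, 126, 126), "differ")
})

test_that("no mutation ever arises at rate zero", {
  params <- mutation_parameters(base_rate_per_bp = 0)
  carrier <- list(lag = 805, doubling_time = 162)
  set.seed(1)
  expect_true(all(vapply(1:200, function(i)
    is.null(sample_mutation(params, carrier)), logical(1))))
})

test_that("realized affecting and beneficial fractions match y and y*z", {
  params <- mutation_parameters(base_rate_per_bp = 1, genome_size = 1,
                                fraction_affecting = 0.034,
                                fraction_beneficial = 0.13,
                                map_variant = "M2")
  carrier <- list(lag = 805, doubling_time = 162)
  set.seed(8)
  n <- 1e5
  aff <- ben <- logical(n)
  for (i in seq_len(n)) {
    m <- sample_mutation(params, carrier)
    aff[i] <- m$affecting
    ben[i] <- m$affecting && m$beneficial
  }
  se_aff <- sqrt(0.034 * 0.966 / n)
  se_ben <- sqrt(0.034 * 0.13 * (1 - 0.034 * 0.13) / n)
  expect_lt(abs(mean(aff) - 0.034), 3 * se_aff)
  expect_lt(abs(mean(ben) - 0.034 * 0.13), 3 * se_ben)
})

test_that("sampled effect sizes recover the gamma distribution", {
  # invert the s_r bridge to the raw gamma draw; with a small scale the
  # truncation at the stressed-unstressed gap is negligible
  params <- mutation_parameters(base_rate_per_bp = 1, genome_size = 1,
                                fraction_affecting = 1,
                                fraction_beneficial = 1,
                                gamma_scale = 13.3, map_variant = "M1")
  carrier <- list(lag = 805, doubling_time = 162)
  set.seed(9)
  n <- 2e4
  raw <- vapply(seq_len(n), function(i) {
    m <- sample_mutation(params, carrier)
    162 * m$raw_coefficient / (m$raw_coefficient + 1)
  }, numeric(1))
  raw <- raw[is.finite(raw)]
  se <- sd(raw) / sqrt(length(raw))
  expect_lt(abs(mean(raw) - 2 * 13.3), 3 * se)
})

test_that("positive pleiotropy couples the sign of both components", {
  params <- mutation_parameters(base_rate_per_bp = 1, genome_size = 1,
                                fraction_affecting = 1, map_variant = "M2")
  carrier <- list(lag = 500, doubling_time = 145)
  set.seed(10)
  for (i in 1:500) {
    m <- sample_mutation(params, carrier)
    if (m$delta_doubling != 0 && m$delta_lag != 0)
      expect_identical(sign(m$delta_doubling), sign(m$delta_lag))
    if (m$beneficial) {
      expect_lte(m$delta_doubling, 0)
      expect_lte(m$delta_lag, 0)
    }
  }
})

test_that("M1 never touches the lag", {
  params <- mutation_parameters(base_rate_per_bp = 1, genome_size = 1,
                                fraction_affecting = 1, map_variant = "M1")
  set.seed(11)
  dl <- vapply(1:300, function(i)
    sample_mutation(params, list(lag = 500, doubling_time = 145))$delta_lag,
    numeric(1))
  expect_true(all(dl == 0))
})

test_that("phenotypes stay inside the stressed/unstressed bounds", {
  # long mutation-rich runs under every map variant
  p <- batch_protocol(5000, 5, 20)
  for (v in c("M1", "M2", "M3")) {
    params <- mutation_parameters(base_rate_per_bp = 2e-8,
                                  fraction_affecting = 0.17,
                                  fraction_beneficial = 0.65,
                                  map_variant = v)
    run <- run_evolution(genotype_phenotype(805, 162),
                         dfe_mutation_model(params), p,
                         seed = 50 + match(v, c("M1", "M2", "M3")))
    st <- run$final_state
    expect_true(all(st$doubling_time >= 126 - 1e-9 &
                      st$doubling_time <= 162 + 1e-9))
    expect_true(all(st$lag >= 271 - 1e-9 & st$lag <= 805 + 1e-9))
    expect_true(all(run$trajectory$mean_doubling <= 162 + 1e-9))
    expect_true(all(run$trajectory$mean_doubling >= 126 - 1e-9))
  }
})

test_that("targeted channel rates scale with target size and multiplier", {
  targets <- default_locus_targets()
  r1 <- targeted_mutation_rates(targets, 0.33e-9, 1)
  expect_equal(unname(r1["ACR3"]), 3e-7)
  expect_equal(unname(r1["FPS1"]), 200 * 0.33e-9)
  r10 <- targeted_mutation_rates(targets, 0.33e-9, 10)
  expect_equal(r10, 10 * r1)
  t0 <- default_locus_targets(fps1_target = 0)
  expect_equal(unname(targeted_mutation_rates(t0)["FPS1"]), 0)
})

test_that("complete negative epistasis keeps the single fittest allele", {
  expect_equal(combine_targeted_genotype(character()),
               c(lag = 805, doubling_time = 162))
  expect_equal(combine_targeted_genotype("FPS1"),
               c(lag = 276.6, doubling_time = 130.2))
  # FPS1 wins on fitness although ACR3 has the shorter doubling time
  expect_equal(combine_targeted_genotype(c("FPS1", "ACR3")),
               combine_targeted_genotype("FPS1"))
  expect_equal(combine_targeted_genotype(c("ASK10", "ACR3")),
               combine_targeted_genotype("ASK10"))
  expect_error(combine_targeted_genotype("XYZ9"), "unknown allele")
})

test_that("the factorial parameter grid has the documented structure", {
  g <- parameter_grid()
  expect_identical(nrow(g), 750L)
  expect_true(all(g$gamma_shape == 2))
  expect_true(all(g$fraction_affecting <= 1 & g$fraction_beneficial <= 1))
  # contains the empirical point
  hit <- g$rate_multiplier == 1 &
    abs(g$fraction_affecting - 0.034) < 1e-12 &
    abs(g$fraction_beneficial - 0.13) < 1e-12 &
    g$gamma_scale == 33
  expect_identical(sum(hit), 1L)
  pars <- grid_parameters(g[hit, ], map_variant = "M3")
  expect_identical(pars$map_variant, "M3")
  expect_equal(pars$gamma_scale, 33)
})
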