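test_that("one mutation-free lineage doubles exactly M times", {
  p <- batch_protocol(100, 5, 10)
  st <- population_state(100, 805, 162)
  out <- advance_cycle(st, p)
  expect_equal(sum(out$counts), 3200)
  expect_identical(attr(out, "n_events"), 5L)
  expect_equal(attr(out, "t_end"), 805 + 5 * 162)
})

test_that("equal-phenotype lineages stay at their initial ratio", {
  p <- batch_protocol(300, 5, 10)
  st <- population_state(c(200, 100), c(805, 805), c(162, 162))
  out <- advance_cycle(st, p)
  expect_equal(out$counts[1] / out$counts[2], 2)
  expect_equal(sum(out$counts), 300 * 32)
})

test_that("a certain-mutation hook converts every dividing daughter", {
  p <- batch_protocol(8, 1, 1)
  st <- population_state(8, 100, 50)
  hook <- function(n_daughters, carrier, time) {
    data.frame(lag = rep(0, n_daughters),
               doubling_time = rep(carrier$doubling_time, n_daughters))
  }
  out <- advance_cycle(st, p, mutation_hook = hook)
  # after the first division of 8 cells: 8 new singleton lineages
  expect_identical(length(out$counts), 9L)
  expect_equal(out$counts, c(8, rep(1, 8)))
  bad_hook <- function(n_daughters, carrier, time) {
    data.frame(lag = rep(0, n_daughters + 1),
               doubling_time = rep(50, n_daughters + 1))
  }
  expect_error(advance_cycle(st, p, mutation_hook = bad_hook),
               "more mutants than dividing cells")
})

test_that("mid-cycle mutants divide one own doubling time after birth", {
  p <- batch_protocol(4, 2, 1)
  st <- population_state(4, 100, 50)
  born <- numeric()
  hook <- function(n_daughters, carrier, time) {
    born <<- c(born, time)
    data.frame(lag = 0, doubling_time = 10)
  }
  out <- advance_cycle(st, p, mutation_hook = hook)
  # mutant born at the first division (t = 150) divides every 10 min after
  expect_equal(born[1], 150)
  expect_gt(length(out$counts), 1)
})

test_that("bottleneck sampling is exact multivariate hypergeometric", {
  expect_equal(bottleneck_sample(c(70, 30), 100), c(70, 30))
  expect_equal(bottleneck_sample(3.2e6, 1e5), 1e5)
  expect_error(bottleneck_sample(c(10, 20), 100), "smaller")
  set.seed(1)
  out <- replicate(200, bottleneck_sample(c(700, 200, 100), 250))
  expect_true(all(colSums(out) == 250))
  # Monte-Carlo check of the hypergeometric mean at a 50/50 composition
  set.seed(2)
  draws <- replicate(1e4, bottleneck_sample(c(5000, 5000), 1000)[1])
  se <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - 500), 3 * se)
})

test_that("identical seeds give bit-identical competition results", {
  p <- batch_protocol(1e4, 5, 10)
  wt <- genotype_phenotype(804.8, 162.3)
  mut <- genotype_phenotype(276.6, 130.2)
  a <- run_competition_ibm(wt, mut, p, n_replicates = 5, seed = 99)
  b <- run_competition_ibm(wt, mut, p, n_replicates = 5, seed = 99)
  expect_identical(a$frequency, b$frequency)
  expect_identical(a$loss, b$loss)
})

test_that("compiled and reference engines agree exactly without mutation", {
  p <- batch_protocol(1e4, 5, 8)
  founder <- genotype_phenotype(805, 162)
  a <- run_evolution(founder, NULL, p, seed = 5)           # compiled
  b <- run_evolution(founder, NULL, p, seed = 5, engine = "R")
  expect_identical(a$trajectory, b$trajectory)
  # and cycle-level states agree for a mixed population
  st <- population_state(c(900, 100), c(805, 400), c(162, 130))
  fast <- batchevol:::advance_cycle_fast(st, batch_protocol(1000, 5, 1))
  ref <- advance_cycle(st, batch_protocol(1000, 5, 1))
  expect_equal(fast$counts, ref$counts)
  expect_equal(attr(fast, "t_end"), attr(ref, "t_end"))
})

test_that("neutral mutant frequencies behave like a drift martingale", {
  p <- batch_protocol(1000, 5, 10)
  g <- genotype_phenotype(805, 162)
  res <- run_competition_ibm(g, g, p, n_replicates = 400,
                             mutant_count = 100, seed = 7)
  start <- 0.1
  means <- colMeans(res$frequency)
  se <- apply(res$frequency, 2, sd) / sqrt(nrow(res$frequency))
  expect_true(all(abs(means - start) <= 3 * pmax(se, 1e-3)))
})

test_that("stronger mutants are never lost more often", {
  p <- batch_protocol(1e4, 5, 15)
  wt <- genotype_phenotype(804.8, 162.3)
  loss <- sapply(c(150, 140, 130), function(tau) {
    mean(run_competition_ibm(wt, genotype_phenotype(500, tau), p,
                             n_replicates = 300, seed = 31)$loss)
  })
  expect_true(all(diff(loss) <= 0))
})

test_that("conditioned IBM means track the drift-free competition model", {
  # synchronous integer divisions quantize the within-cycle gain, so the
  # stochastic mean cannot match the continuum model pointwise; fixation
  # timing and the direction of travel must still agree
  p <- batch_protocol(1e5, 5, 12)
  det <- compete_deterministic(arsenic_wt(), fps1_mutant(), p,
                               dilution = "continuous")
  ibm <- run_competition_ibm(genotype_phenotype(804.8, 162.3),
                             genotype_phenotype(276.6, 130.2), p,
                             n_replicates = 200, seed = 13)
  expect_identical(sum(ibm$loss), 0L)
  mean_freq <- colMeans(ibm$frequency)
  det_fix <- min(det$trajectory$generations[det$trajectory$mutant_frequency
                                            >= 0.99])
  ibm_fix <- min(ibm$generations[mean_freq >= 0.99])
  expect_lte(abs(ibm_fix - det_fix), 5)  # within one cycle
  expect_true(all(diff(mean_freq) >= -1e-6))
})

test_that("evolution without mutation keeps the founder forever", {
  p <- batch_protocol(1e4, 5, 10)
  run <- run_evolution(genotype_phenotype(805, 162), NULL, p, seed = 1)
  expect_true(is.na(run$founder_extinct_generation))
  expect_true(all(run$trajectory$mean_doubling == 162))
  expect_true(all(run$trajectory$founder_count == 1e4))
})

test_that("a duplication-only targeted model produces only that class", {
  targets <- list(ACR3 = locus_target("ACR3", effect_lag = 630.4,
                                      effect_doubling = 122.8,
                                      duplication_rate = 3e-5))
  p <- batch_protocol(1e4, 5, 15)
  model <- targeted_mutation_model(targets, multiplier = 10)
  run <- run_evolution(genotype_phenotype(805, 162), model, p, seed = 21)
  last <- run$trajectory[nrow(run$trajectory), ]
  expect_gt(last$ACR3, 0)
  expect_equal(last$ACR3 + last$founder, 1e4)
  # per-cycle class counts always partition the bottleneck
  expect_true(all(run$trajectory$ACR3 + run$trajectory$founder == 1e4))
})

test_that("compiled and reference DFE engines agree statistically", {
  # small population and a modest per-daughter rate keep the pure-R
  # reference engine tractable while still producing many mutations
  p <- batch_protocol(500, 5, 6)
  params <- mutation_parameters(base_rate_per_bp = 2e-10,
                                fraction_affecting = 1,
                                fraction_beneficial = 1,
                                map_variant = "M2")
  model <- dfe_mutation_model(params)
  founder <- genotype_phenotype(805, 162)
  fin_cpp <- sapply(1:25, function(i)
    tail(run_evolution(founder, model, p, seed = 100 + i)$trajectory$
           mean_doubling, 1))
  fin_r <- sapply(1:25, function(i)
    tail(run_evolution(founder, model, p, seed = 500 + i,
                       engine = "R")$trajectory$mean_doubling, 1))
  # both engines must show adaptation away from the founder
  expect_lt(mean(fin_cpp), 162)
  expect_lt(mean(fin_r), 162)
  se <- sqrt(var(fin_cpp) / 25 + var(fin_r) / 25)
  expect_lt(abs(mean(fin_cpp) - mean(fin_r)), 4 * max(se, 0.5))
})
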