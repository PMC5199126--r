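#' Recovery fraction of a time-like fitness component
#'
#' Expresses a doubling time or lag as the percentage of the stressed-to-
#' unstressed gap recovered: 0% at the stressed wild-type value, 100% at the
#' unstressed wild-type value (smaller times are better).
#'
#' @param value Component value, minutes.
#' @param stressed_ref Stressed WT reference (0% recovery).
#' @param unstressed_ref Unstressed WT reference (100% recovery).
#' @param cap Clamp the result to [0, 100] (default TRUE).
#' @return Recovery percentage(s).
#' @examples
#' recovery_fraction(144, 162, 126)  # 50
#' @export
recovery_fraction <- function(value, stressed_ref, unstressed_ref,
                              cap = TRUE) {
  if (any(stressed_ref == unstressed_ref))
    stop("stressed and unstressed references must differ")
  r <- 100 * (stressed_ref - value) / (stressed_ref - unstressed_ref)
  if (cap) pmin(pmax(r, 0), 100) else r
}

#' Generations to reach recovery thresholds
#'
#' Fits a monotone non-decreasing function to a recovery trajectory by least
#' squares (isotonic regression) and reports, for each threshold, the first
#' recorded generation at which the fitted curve is at or above it
#' (\code{NA} when never reached). With \code{interpolate = TRUE} the
#' crossing is instead linearly interpolated between the bracketing samples.
#'
#' @param generations Non-decreasing numeric vector of generation counts.
#' @param recovery Recovery percentages at those generations.
#' @param thresholds Recovery thresholds in percent (default 25, 50, 75).
#' @param interpolate Interpolate between samples (default FALSE).
#' @return Named numeric vector, one entry per threshold.
#' @export
generations_to_recovery <- function(generations, recovery,
                                    thresholds = c(25, 50, 75),
                                    interpolate = FALSE) {
  stopifnot(length(generations) == length(recovery),
            length(generations) > 0, !is.unsorted(generations))
  if (length(thresholds) == 0) stop("no thresholds given")
  fit <- if (length(generations) > 1)
    stats::isoreg(generations, recovery)$yf else recovery
  out <- vapply(thresholds, function(thr) {
    hit <- which(fit >= thr)
    if (length(hit) == 0) return(NA_real_)
    i <- hit[1L]
    if (!interpolate || i == 1L) return(generations[i])
    g0 <- generations[i - 1L]
    f0 <- fit[i - 1L]
    g0 + (thr - f0) * (generations[i] - g0) / (fit[i] - f0)
  }, numeric(1))
  names(out) <- paste0("gen_to_", thresholds)
  out
}

#' Per-generation quantile curves across populations
#'
#' Empirical quantiles of recovery across a collection of populations sharing
#' a common generation grid. The default probabilities correspond to the
#' fastest 1, 10, 25, 75, 90 and 99% of populations plus the median.
#'
#' @param trajectories Numeric matrix, one row per population, one column per
#'   generation grid point (>= 2 rows).
#' @param generations Generation grid (defaults to column index).
#' @param probs Quantile probabilities.
#' @return Data frame with \code{generations} and one column per quantile.
#' @export
summarize_quantiles <- function(trajectories,
                                generations = seq_len(ncol(trajectories)),
                                probs = c(0.01, 0.1, 0.25, 0.5, 0.75, 0.9,
                                          0.99)) {
  stopifnot(is.matrix(trajectories), nrow(trajectories) >= 2,
            length(generations) == ncol(trajectories))
  q <- apply(trajectories, 2L, stats::quantile, probs = probs, names = FALSE)
  out <- data.frame(generations, t(q))
  names(out) <- c("generations", paste0("q", probs * 100))
  out
}

#' Parameter sweep across pleiotropy map variants
#'
#' Runs one evolution simulation per mutation-parameter set and map variant
#' (paired seeds across variants, so variant contrasts are matched) and
#' summarizes each run by the generations needed to recover 25/50/75% of the
#' stressed-to-unstressed doubling-time gap and by a "fast scenario" flag
#' (75% recovery within \code{fast_budget} generations).
#'
#' @param grid Data frame from \code{\link{parameter_grid}} (or a subset).
#' @param protocol A \code{\link{batch_protocol}}.
#' @param variants Character vector of map variants to run.
#' @param base Base \code{\link{mutation_parameters}}.
#' @param bounds A \code{\link{phenotype_bounds}}.
#' @param fast_budget Generation budget for the fast-scenario flag
#'   (default 100).
#' @param seed Optional master seed; run seeds are derived per parameter set
#'   so each variant sees the same seed on the same set.
#' @return An object of class \code{"sweep_result"}: a data frame
#'   (\code{set_id}, \code{variant}, \code{gen_to_25/50/75},
#'   \code{final_recovery}, \code{fast}) with the per-run recovery
#'   trajectories in \code{attr(, "trajectories")}.
#' @export
run_sweep <- function(grid, protocol, variants = c("M1", "M2", "M3"),
                      base = mutation_parameters(),
                      bounds = phenotype_bounds(),
                      fast_budget = 100, seed = NULL) {
  stopifnot(is.data.frame(grid), nrow(grid) > 0)
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1)
  founder <- genotype_phenotype(bounds$stressed_lag, bounds$stressed_doubling)
  rows <- list()
  trajs <- list()
  for (i in seq_len(nrow(grid))) {
    run_seed <- (seed + 7919L * i) %% 2147483629L
    for (v in variants) {
      params <- grid_parameters(grid[i, ], base, map_variant = v)
      run <- run_evolution(founder, dfe_mutation_model(params, bounds),
                           protocol, seed = run_seed)
      gens <- c(0, run$trajectory$generations)
      rec <- recovery_fraction(
        c(bounds$stressed_doubling, run$trajectory$mean_doubling),
        bounds$stressed_doubling, bounds$unstressed_doubling)
      gtr <- generations_to_recovery(gens, rec)
      rows[[length(rows) + 1L]] <- data.frame(
        set_id = grid$set_id[i], variant = v,
        gen_to_25 = gtr[[1L]], gen_to_50 = gtr[[2L]], gen_to_75 = gtr[[3L]],
        final_recovery = rec[length(rec)],
        fast = !is.na(gtr[[3L]]) && gtr[[3L]] <= fast_budget)
      trajs[[paste(grid$set_id[i], v, sep = ".")]] <- rec
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "trajectories") <- trajs
  attr(out, "generations") <- c(0, seq_len(protocol$n_cycles) *
                                  protocol$doublings_per_cycle)
  class(out) <- c("sweep_result", class(out))
  out
}

#' @export
summary.sweep_result <- function(object, ...) {
  sp <- split(object, object$variant)
  data.frame(
    variant = names(sp),
    n = vapply(sp, nrow, integer(1)),
    median_gen_to_75 = vapply(sp, function(d)
      stats::median(d$gen_to_75, na.rm = TRUE), numeric(1)),
    n_fast = vapply(sp, function(d) sum(d$fast), integer(1)),
    row.names = NULL)
}

#' Mutation-rate scan of the targeted-locus model
#'
#' Simulates replicate adaptations under the targeted FPS1/ASK10/ACR3 model
#' at several global mutation-rate multipliers and summarizes, per replicate,
#' the founder-extinction generation, the number of distinct allele classes
#' above a frequency threshold at the end, and the dominant allele class
#' (highest summed frequency at the final cycle).
#'
#' @param targets Named list of \code{\link{locus_target}} objects.
#' @param protocol A \code{\link{batch_protocol}}.
#' @param multipliers Rate multipliers (default 1, 3, 5, 10).
#' @param n_replicates Replicates per multiplier (default 25).
#' @param base_rate_per_bp Per-bp per-division rate.
#' @param founder Founder \code{c(lag, doubling_time)}.
#' @param class_threshold Frequency above which a class counts as present at
#'   the end (default 0.05).
#' @param seed Optional master seed.
#' @return An object of class \code{"rate_scan"}: data frame with
#'   \code{multiplier}, \code{replicate}, \code{extinction_generation},
#'   \code{n_classes_gt_threshold}, \code{dominant_class}.
#' @export
run_rate_scan <- function(targets = default_locus_targets(), protocol,
                          multipliers = c(1, 3, 5, 10), n_replicates = 25,
                          base_rate_per_bp = 0.33e-9,
                          founder = c(lag = 805, doubling_time = 162),
                          class_threshold = 0.05, seed = NULL) {
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1)
  founder_gt <- genotype_phenotype(founder[[1L]], founder[[2L]])
  classes <- names(targets)
  rows <- list()
  for (m in multipliers) {
    model <- targeted_mutation_model(targets, base_rate_per_bp,
                                     multiplier = m, founder = founder)
    for (r in seq_len(n_replicates)) {
      run_seed <- (seed + 104729L * match(m, multipliers) + 7919L * r) %%
        2147483629L
      run <- run_evolution(founder_gt, model, protocol, seed = run_seed)
      last <- run$trajectory[nrow(run$trajectory), ]
      cf <- vapply(classes, function(cl) last[[cl]], numeric(1)) /
        protocol$bottleneck
      dominant <- if (all(cf == 0) ||
                      last$founder / protocol$bottleneck > max(cf))
        "founder" else classes[which.max(cf)]
      rows[[length(rows) + 1L]] <- data.frame(
        multiplier = m, replicate = r,
        extinction_generation = run$founder_extinct_generation,
        n_classes_gt_threshold = sum(cf > class_threshold),
        dominant_class = dominant)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("rate_scan", class(out))
  out
}

#' @export
summary.rate_scan <- function(object, ...) {
  sp <- split(object, object$multiplier)
  data.frame(
    multiplier = as.numeric(names(sp)),
    median_extinction_generation = vapply(sp, function(d)
      stats::median(d$extinction_generation, na.rm = TRUE), numeric(1)),
    prop_extinct = vapply(sp, function(d)
      mean(!is.na(d$extinction_generation)), numeric(1)),
    n_winning_classes = vapply(sp, function(d)
      length(unique(d$dominant_class[d$dominant_class != "founder"])),
      numeric(1)),
    fps1_dominant = vapply(sp, function(d)
      mean(d$dominant_class == "FPS1"), numeric(1)),
    row.names = NULL)
}
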