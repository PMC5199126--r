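#' Genotype phenotype for the individual-based model
#'
#' @param lag Lag time in minutes (>= 0).
#' @param doubling_time Doubling time in minutes (> 0).
#' @param mutations Character vector of carried mutation/allele identifiers.
#' @return An object of class \code{"genotype_phenotype"}.
#' @export
genotype_phenotype <- function(lag, doubling_time, mutations = character()) {
  if (lag < 0) stop("'lag' must be >= 0")
  if (doubling_time <= 0) stop("'doubling_time' must be > 0")
  structure(list(lag = lag, doubling_time = doubling_time,
                 mutations = mutations),
            class = "genotype_phenotype")
}

#' Population state of the individual-based model
#'
#' Genotype-structured state: per-lineage integer cell counts with phenotypes.
#' Lineages are "genotypes" in the model's sense: cells created together with
#' identical genotype divide at the same time.
#'
#' @param counts Numeric vector of cell counts (non-negative integers).
#' @param lag,doubling_time Numeric vectors of per-lineage phenotypes.
#' @param mask Integer vector of allele bit-masks (targeted model; 0 = none).
#' @param id Integer lineage identifiers (founder lineages get 1..k).
#' @return An object of class \code{"population_state"}.
#' @export
population_state <- function(counts, lag, doubling_time,
                             mask = integer(length(counts)),
                             id = seq_along(counts)) {
  stopifnot(length(counts) == length(lag),
            length(counts) == length(doubling_time),
            length(counts) == length(mask), all(counts >= 0),
            all(counts == round(counts)), all(doubling_time > 0),
            all(lag >= 0))
  structure(list(counts = as.numeric(counts), lag = as.numeric(lag),
                 doubling_time = as.numeric(doubling_time),
                 mask = as.integer(mask), id = as.integer(id)),
            class = "population_state")
}

#' Advance one batch cycle of the individual-based model (reference engine)
#'
#' Pure-R event loop. All cells of a lineage divide synchronously: the
#' lineage's first division is at \code{lag + doubling_time} after the cycle
#' start and every \code{doubling_time} thereafter; each division doubles the
#' lineage count. After each division event the mutation hook may convert a
#' random number of the just-divided cells into new single-cell lineages
#' whose next division is one own doubling time after their birth (lag
#' applies only at cycle starts). The cycle stops at the first division event
#' at which the total population reaches \code{2^M * N}; simultaneous events
#' are processed in lineage order and the stop condition is checked after
#' each lineage's doubling.
#'
#' The compiled engine used by \code{\link{run_evolution}} and
#' \code{\link{run_competition_ibm}} implements the same event rules; with
#' the hook disabled the two produce identical states.
#'
#' @param state A \code{\link{population_state}} whose counts sum to the
#'   protocol bottleneck.
#' @param protocol A \code{\link{batch_protocol}}.
#' @param mutation_hook \code{NULL}, or a function
#'   \code{function(n_daughters, carrier, time)} returning \code{NULL} or a
#'   data frame with columns \code{lag}, \code{doubling_time} and optionally
#'   \code{mask}, one row per new mutant cell (at most \code{n_daughters}
#'   rows).
#' @return The pre-bottleneck \code{population_state}, with attributes
#'   \code{t_end} (minutes) and \code{n_events}.
#' @export
advance_cycle <- function(state, protocol, mutation_hook = NULL) {
  stopifnot(inherits(state, "population_state"),
            inherits(protocol, "batch_protocol"))
  target <- 2^protocol$doublings_per_cycle * sum(state$counts)
  if (sum(state$counts) <= 0) stop("population is empty")
  counts <- state$counts
  lag <- state$lag
  tau <- state$doubling_time
  mask <- state$mask
  id <- state$id
  next_div <- ifelse(counts > 0, lag + tau, Inf)
  total <- sum(counts)
  n_events <- 0L
  t_end <- 0
  repeat {
    i <- which.min(next_div)  # ties resolved to the lowest index (lineage order)
    t <- next_div[i]
    if (!is.finite(t)) stop("no dividing lineages left before the cycle target")
    n <- counts[i]
    counts[i] <- 2 * n
    total <- total + n
    t_end <- t
    n_events <- n_events + 1L
    next_div[i] <- t + tau[i]
    if (!is.null(mutation_hook)) {
      mut <- mutation_hook(n_daughters = n,
                           carrier = list(lag = lag[i], doubling_time = tau[i],
                                          mask = mask[i]),
                           time = t)
      if (!is.null(mut) && nrow(mut) > 0) {
        k <- nrow(mut)
        if (k > n)
          stop("mutation hook returned more mutants than dividing cells")
        counts[i] <- counts[i] - k
        counts <- c(counts, rep(1, k))
        lag <- c(lag, mut$lag)
        tau <- c(tau, mut$doubling_time)
        mask <- c(mask, if ("mask" %in% names(mut)) mut$mask
                        else rep(0L, k))
        id <- c(id, max(id) + seq_len(k))
        next_div <- c(next_div, t + mut$doubling_time)
      }
    }
    if (total >= target) break
  }
  out <- population_state(counts, lag, tau, mask, id)
  attr(out, "t_end") <- t_end
  attr(out, "n_events") <- n_events
  out
}

# Compiled fast path for the same cycle rules; model 0 = no mutation,
# 1 = gamma-DFE genotype-phenotype map, 2 = targeted locus channels.
advance_cycle_fast <- function(state, protocol, model = 0L, pars = list()) {
  target <- 2^protocol$doublings_per_cycle * sum(state$counts)
  res <- .ibm_advance_cycle_cpp(state$counts, state$lag, state$doubling_time,
                                state$mask, target, as.integer(model), pars)
  k <- length(res$count) - length(state$counts)
  out <- population_state(res$count, res$lag, res$doubling_time, res$mask,
                          id = c(state$id,
                                 if (k > 0) max(state$id) + seq_len(k)))
  attr(out, "t_end") <- res$t_end
  attr(out, "n_events") <- res$n_events
  out
}

#' Bottleneck subsampling of a genotype-structured population
#'
#' Draws exactly \code{N} cells without replacement from the pooled
#' population (multivariate hypergeometric across lineages), by sequential
#' conditional univariate hypergeometric draws. The expected sampled count of
#' each lineage is \code{N * count/total}.
#'
#' @param counts Numeric vector of lineage cell counts.
#' @param N Bottleneck size; must not exceed \code{sum(counts)}.
#' @return Numeric vector of sampled counts, summing to \code{N} exactly.
#' @export
bottleneck_sample <- function(counts, N) {
  total <- sum(counts)
  if (total < N) stop("total population smaller than the bottleneck")
  if (total == N) return(counts)
  out <- numeric(length(counts))
  remaining_total <- total
  remaining_N <- N
  for (i in seq_along(counts)) {
    if (remaining_N == 0) break
    if (i == length(counts)) {
      out[i] <- remaining_N
      break
    }
    out[i] <- stats::rhyper(1, counts[i], remaining_total - counts[i],
                            remaining_N)
    remaining_total <- remaining_total - counts[i]
    remaining_N <- remaining_N - out[i]
  }
  out
}

# drop empty lineages, keeping founder bookkeeping via id
prune_state <- function(state) {
  keep <- state$counts > 0
  population_state(state$counts[keep], state$lag[keep],
                   state$doubling_time[keep], state$mask[keep],
                   state$id[keep])
}

#' Stochastic competition assay between two genotypes
#'
#' Individual-based competition initiated with a single mutant cell in an
#' otherwise uniform founder population, with no further mutation: repeated
#' cycles of synchronous-division growth to \code{2^M N} cells followed by a
#' random bottleneck of \code{N} cells. Genetic drift at the bottleneck can
#' lose the mutant lineage.
#'
#' @param wt,mutant \code{\link{genotype_phenotype}} objects.
#' @param protocol A \code{\link{batch_protocol}}.
#' @param n_replicates Number of independent replicate assays.
#' @param mutant_count Starting mutant cells (default 1).
#' @param seed Optional RNG seed (\code{set.seed} is called when given).
#' @return An object of class \code{"ibm_competition"}: list with
#'   \code{frequency} (replicates x cycles matrix of post-bottleneck mutant
#'   frequencies, cycle 0 first), \code{loss} (logical vector), \code{seed},
#'   and the inputs. Once the mutant is lost its frequency stays 0; once
#'   fixed it stays 1.
#' @examples
#' p <- batch_protocol(1e3, 5, 10)
#' res <- run_competition_ibm(genotype_phenotype(804.8, 162.3),
#'                            genotype_phenotype(276.6, 130.2),
#'                            p, n_replicates = 5, seed = 1)
#' summary(res)
#' @export
run_competition_ibm <- function(wt, mutant, protocol, n_replicates = 25,
                                mutant_count = 1, seed = NULL) {
  stopifnot(inherits(wt, "genotype_phenotype"),
            inherits(mutant, "genotype_phenotype"),
            inherits(protocol, "batch_protocol"))
  if (!is.null(seed)) set.seed(seed)
  N <- protocol$bottleneck
  ncyc <- protocol$n_cycles
  freq <- matrix(NA_real_, n_replicates, ncyc + 1L)
  loss <- logical(n_replicates)
  for (r in seq_len(n_replicates)) {
    counts <- c(N - mutant_count, mutant_count)
    freq[r, 1L] <- counts[2L] / N
    for (cy in seq_len(ncyc)) {
      if (counts[1L] == 0 || counts[2L] == 0) {
        freq[r, cy + 1L] <- freq[r, cy]
        next
      }
      st <- population_state(counts, c(wt$lag, mutant$lag),
                             c(wt$doubling_time, mutant$doubling_time))
      st <- advance_cycle_fast(st, protocol)
      counts <- bottleneck_sample(st$counts, N)
      freq[r, cy + 1L] <- counts[2L] / N
    }
    loss[r] <- freq[r, ncyc + 1L] == 0
  }
  structure(list(frequency = freq,
                 generations = (0:ncyc) * protocol$doublings_per_cycle,
                 loss = loss, wt = wt, mutant = mutant, protocol = protocol,
                 seed = seed),
            class = "ibm_competition")
}

#' @export
print.ibm_competition <- function(x, ...) {
  cat(sprintf(
    "IBM competition: %d replicates, %d cycles; mutant lost in %d (%.0f%%)\n",
    nrow(x$frequency), x$protocol$n_cycles, sum(x$loss),
    100 * mean(x$loss)))
  invisible(x)
}

#' @export
summary.ibm_competition <- function(object, ...) {
  list(n_replicates = nrow(object$frequency),
       n_lost = sum(object$loss),
       loss_fraction = mean(object$loss),
       mean_final_frequency = mean(object$frequency[, ncol(object$frequency)]))
}

#' @export
plot.ibm_competition <- function(x, ...) {
  graphics::matplot(x$generations, t(x$frequency), type = "l", lty = 1,
                    xlab = "generations", ylab = "mutant frequency", ...)
  invisible(x)
}

#' Gamma-DFE mutation model
#'
#' Mutation model for \code{\link{run_evolution}}: per daughter cell a
#' fitness-affecting mutation arises with probability
#' \code{genome_size * base_rate_per_bp * rate_multiplier *
#' fraction_affecting}; its phenotype effect follows the map variant in
#' \code{params} (see \code{\link{sample_mutation}}). Mutations that do not
#' affect fitness leave the phenotype unchanged and are not tracked as
#' separate lineages.
#'
#' @param params A \code{\link{mutation_parameters}} object.
#' @param bounds A \code{\link{phenotype_bounds}} object.
#' @return An object of class \code{"mutation_model"}.
#' @export
dfe_mutation_model <- function(params, bounds = phenotype_bounds()) {
  stopifnot(inherits(params, "mutation_parameters"),
            inherits(bounds, "phenotype_bounds"))
  structure(list(type = "dfe", params = params, bounds = bounds),
            class = "mutation_model")
}

#' Targeted-locus mutation model
#'
#' Mutation model with one channel per beneficial locus: per daughter cell
#' each channel fires with its per-division probability
#' (\code{\link{targeted_mutation_rates}}); a hit adds the allele to the
#' genotype, whose phenotype is the best carried allele's empirical values
#' (complete negative epistasis, \code{\link{combine_targeted_genotype}}).
#'
#' @param targets Named list of \code{\link{locus_target}} objects.
#' @param base_rate_per_bp Per-bp per-division rate (default 0.33e-9).
#' @param multiplier Global rate multiplier.
#' @param founder Founder \code{c(lag, doubling_time)}.
#' @return An object of class \code{"mutation_model"}.
#' @export
targeted_mutation_model <- function(targets = default_locus_targets(),
                                    base_rate_per_bp = 0.33e-9,
                                    multiplier = 1,
                                    founder = c(lag = 805,
                                                doubling_time = 162)) {
  rates <- targeted_mutation_rates(targets, base_rate_per_bp, multiplier)
  structure(list(type = "targeted", targets = targets, rates = rates,
                 founder = founder),
            class = "mutation_model")
}

#' Custom-hook mutation model
#'
#' Wraps a user mutation hook (see \code{\link{advance_cycle}}) so it can be
#' passed to \code{\link{run_evolution}}; runs on the pure-R reference
#' engine.
#'
#' @param hook A function \code{function(n_daughters, carrier, time)}.
#' @return An object of class \code{"mutation_model"}.
#' @export
hook_mutation_model <- function(hook) {
  stopifnot(is.function(hook))
  structure(list(type = "hook", hook = hook), class = "mutation_model")
}

# R-level hook equivalent of the compiled DFE model (used for cross-checks)
dfe_hook <- function(params, bounds, M) {
  p_aff <- min(1, params$genome_size * params$base_rate_per_bp *
                 params$rate_multiplier * params$fraction_affecting)
  function(n_daughters, carrier, time) {
    nm <- stats::rbinom(1, n_daughters, p_aff)
    if (nm == 0) return(NULL)
    res <- vapply(seq_len(nm), function(k) {
      mut <- NULL
      # rejection-free: sample the affecting branch directly
      repeat {
        m <- sample_mutation_affecting(params, carrier, bounds, M)
        if (!is.null(m)) { mut <- m; break }
      }
      c(carrier$lag + mut$delta_lag,
        carrier$doubling_time + mut$delta_doubling)
    }, numeric(2))
    data.frame(lag = res[1L, ], doubling_time = res[2L, ])
  }
}

# the affecting branch of sample_mutation (mutation occurred and affects
# fitness), shared by the R hook path
sample_mutation_affecting <- function(params, carrier, bounds, M) {
  saved <- params
  saved$genome_size <- 1
  saved$base_rate_per_bp <- 1
  saved$rate_multiplier <- 1
  saved$fraction_affecting <- 1
  sample_mutation(saved, carrier, bounds, M)
}

#' Simulate serial-batch experimental evolution
#'
#' Runs a founder population through repeated batch cycles with mutation:
#' each cycle grows by synchronous divisions (with per-division mutation per
#' the model) until the total reaches \code{2^M N}, then a random bottleneck
#' of \code{N} cells founds the next cycle. Per cycle end (post-bottleneck,
#' i.e. every M generations) the population-mean phenotypes, the founder
#' lineage count and, for the targeted model, allele-class counts are
#' recorded.
#'
#' @param founder A \code{\link{genotype_phenotype}} for the starting clone.
#' @param mutation_model A \code{"mutation_model"} (from
#'   \code{\link{dfe_mutation_model}}, \code{\link{targeted_mutation_model}}
#'   or \code{\link{hook_mutation_model}}), or \code{NULL} for no mutation.
#' @param protocol A \code{\link{batch_protocol}}.
#' @param seed Optional RNG seed.
#' @param engine \code{"auto"} (compiled for built-in models), \code{"R"} to
#'   force the reference engine.
#' @return An object of class \code{"evolution_run"}: list with
#'   \code{trajectory} (data frame: \code{cycle}, \code{generations},
#'   \code{mean_doubling}, \code{mean_lag}, \code{founder_count},
#'   \code{n_lineages}, plus allele-class count columns for the targeted
#'   model), \code{founder_extinct_generation} (NA if never), \code{seed}.
#' @export
run_evolution <- function(founder, mutation_model, protocol, seed = NULL,
                          engine = c("auto", "R")) {
  stopifnot(inherits(founder, "genotype_phenotype"),
            inherits(protocol, "batch_protocol"))
  engine <- match.arg(engine)
  if (!is.null(seed)) set.seed(seed)
  N <- protocol$bottleneck
  M <- protocol$doublings_per_cycle
  model_type <- if (is.null(mutation_model)) "none" else mutation_model$type
  classes <- if (model_type == "targeted") names(mutation_model$targets)
             else character()

  use_cpp <- engine == "auto" && model_type %in% c("none", "dfe", "targeted")
  cpp_model <- switch(model_type, none = 0L, dfe = 1L, targeted = 2L, NULL)
  cpp_pars <- switch(
    model_type,
    dfe = {
      p <- mutation_model$params
      b <- mutation_model$bounds
      list(p_affect = min(1, p$genome_size * p$base_rate_per_bp *
                            p$rate_multiplier * p$fraction_affecting),
           z = p$fraction_beneficial, shape = p$gamma_shape,
           scale = p$gamma_scale, T_wt = b$stressed_doubling,
           T_wt_N = b$unstressed_doubling, L_wt = b$stressed_lag,
           L_wt_N = b$unstressed_lag, M = M,
           variant = match(p$map_variant, c("M1", "M2", "M3")))
    },
    targeted = list(p_channel = unname(mutation_model$rates),
                    channel_lag = vapply(mutation_model$targets, `[[`,
                                         numeric(1), "effect_lag"),
                    channel_doubling = vapply(mutation_model$targets, `[[`,
                                              numeric(1), "effect_doubling"),
                    channel_score = vapply(mutation_model$targets, function(tg)
                      analytic_selection_coefficient(
                        mutation_model$founder[[1L]],
                        mutation_model$founder[[2L]],
                        tg$effect_lag, tg$effect_doubling, M),
                      numeric(1))),
    list())
  hook <- switch(model_type,
                 hook = mutation_model$hook,
                 dfe = if (!use_cpp)
                   dfe_hook(mutation_model$params, mutation_model$bounds, M),
                 NULL)

  state <- population_state(N, founder$lag, founder$doubling_time)
  founder_id <- 1L
  rows <- vector("list", protocol$n_cycles)
  founder_gone <- NA_real_
  for (cy in seq_len(protocol$n_cycles)) {
    state <- if (use_cpp)
      advance_cycle_fast(state, protocol, cpp_model, cpp_pars)
    else advance_cycle(state, protocol, mutation_hook = hook)
    state$counts <- bottleneck_sample(state$counts, N)
    state <- prune_state(state)
    fc <- sum(state$counts[state$id == founder_id])
    if (is.na(founder_gone) && fc == 0) founder_gone <- cy * M
    row <- data.frame(
      cycle = cy, generations = cy * M,
      mean_doubling = sum(state$counts * state$doubling_time) / N,
      mean_lag = sum(state$counts * state$lag) / N,
      founder_count = fc, n_lineages = length(state$counts))
    if (model_type == "targeted") {
      cls <- lineage_class(state$mask, mutation_model, M)
      for (cl in c("founder", classes))
        row[[cl]] <- sum(state$counts[cls == cl])
    }
    rows[[cy]] <- row
  }
  structure(list(trajectory = do.call(rbind, rows),
                 founder_extinct_generation = founder_gone,
                 final_state = state, classes = classes,
                 founder = founder, protocol = protocol, seed = seed,
                 model_type = model_type),
            class = "evolution_run")
}

# assign each lineage to the allele class that determines its phenotype
# (the fittest carried allele; "founder" when none)
lineage_class <- function(mask, mutation_model, M = 5) {
  targets <- mutation_model$targets
  nms <- names(targets)
  vapply(mask, function(m) {
    if (m == 0) return("founder")
    carried <- nms[bitwAnd(m, bitwShiftL(1L, seq_along(nms) - 1L)) != 0L]
    carried[best_allele_index(carried, targets, mutation_model$founder, M)]
  }, character(1))
}

#' @export
print.evolution_run <- function(x, ...) {
  d <- x$trajectory
  cat(sprintf("Evolution run (%s model): %d cycles, %d generations\n",
              x$model_type, nrow(d), max(d$generations)))
  cat(sprintf("  final mean doubling %.1f min, mean lag %.1f min, %d lineages\n",
              d$mean_doubling[nrow(d)], d$mean_lag[nrow(d)],
              d$n_lineages[nrow(d)]))
  cat(sprintf("  founder extinct at generation: %s\n",
              format(x$founder_extinct_generation)))
  invisible(x)
}

#' Write per-cycle evolution output as delimited text
#'
#' Long format: one row per cycle and recorded quantity (class counts for the
#' targeted model, mean phenotypes otherwise) plus a summary row.
#'
#' @param run An \code{"evolution_run"}.
#' @param path Output file path.
#' @export
write_evolution <- function(run, path) {
  stopifnot(inherits(run, "evolution_run"))
  utils::write.table(run$trajectory, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
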