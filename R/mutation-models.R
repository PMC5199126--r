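#' Mutation-supply and fitness-effect parameters
#'
#' Parameters of the random genotype-phenotype map used by the evolutionary
#' simulations: the per-bp per-division mutation rate and genome size set the
#' per-daughter mutation probability; a mutation affects fitness with
#' probability \code{fraction_affecting} and, given that, is beneficial with
#' probability \code{fraction_beneficial}; non-neutral effect sizes come from
#' a gamma distribution (shape \code{gamma_shape}, scale \code{gamma_scale}
#' in minutes of doubling time). \code{map_variant} selects the pleiotropy
#' structure: \code{"M1"} affects doubling time only, \code{"M2"} affects
#' doubling time and lag with the same sampled effect and direction (positive
#' pleiotropy), \code{"M3"} affects both with independently sampled effect
#' sizes and directions.
#'
#' @param base_rate_per_bp Mutations per bp per division (default 0.33e-9).
#' @param genome_size Genome size in bp converting the per-bp rate into the
#'   per-division overall rate (default 1.2e7).
#' @param fraction_affecting Probability a mutation affects fitness
#'   (default 0.034).
#' @param fraction_beneficial Probability an affecting mutation is beneficial
#'   (default 0.13).
#' @param gamma_shape Gamma shape of the effect-size distribution (default 2).
#' @param gamma_scale Gamma scale in minutes (default 33, the empirical value;
#'   the grid also uses 13.3, 20, 27.35, 40 and 47).
#' @param map_variant One of \code{"M1"}, \code{"M2"}, \code{"M3"}.
#' @param rate_multiplier Global multiplier on the mutation rate (default 1).
#' @return An object of class \code{"mutation_parameters"}.
#' @export
mutation_parameters <- function(base_rate_per_bp = 0.33e-9,
                                genome_size = 1.2e7,
                                fraction_affecting = 0.034,
                                fraction_beneficial = 0.13,
                                gamma_shape = 2,
                                gamma_scale = 33,
                                map_variant = c("M2", "M1", "M3"),
                                rate_multiplier = 1) {
  map_variant <- match.arg(map_variant)
  stopifnot(base_rate_per_bp >= 0, genome_size > 0,
            fraction_affecting >= 0, fraction_affecting <= 1,
            fraction_beneficial >= 0, fraction_beneficial <= 1,
            gamma_shape > 0, gamma_scale > 0, rate_multiplier >= 0)
  structure(list(base_rate_per_bp = base_rate_per_bp,
                 genome_size = genome_size,
                 fraction_affecting = fraction_affecting,
                 fraction_beneficial = fraction_beneficial,
                 gamma_shape = gamma_shape,
                 gamma_scale = gamma_scale,
                 map_variant = map_variant,
                 rate_multiplier = rate_multiplier),
            class = "mutation_parameters")
}

#' Phenotype bounds of the adaptive walk
#'
#' The stressed wild-type values are the founder phenotype under arsenic
#' stress; the unstressed values are the wild-type phenotype without stress,
#' the asymptote that adapting genotypes approach but cannot exceed
#' (effect capping plus diminishing-returns epistasis keep every phenotype
#' inside these bounds).
#'
#' @param stressed_doubling,stressed_lag Founder (stressed WT) doubling time
#'   and lag, minutes (defaults 162 and 805).
#' @param unstressed_doubling,unstressed_lag Unstressed WT doubling time and
#'   lag, minutes (defaults 126 and 271).
#' @return An object of class \code{"phenotype_bounds"}.
#' @export
phenotype_bounds <- function(stressed_doubling = 162, stressed_lag = 805,
                             unstressed_doubling = 126, unstressed_lag = 271) {
  stopifnot(unstressed_doubling < stressed_doubling,
            unstressed_lag < stressed_lag,
            unstressed_doubling > 0, unstressed_lag >= 0)
  structure(list(stressed_doubling = stressed_doubling,
                 stressed_lag = stressed_lag,
                 unstressed_doubling = unstressed_doubling,
                 unstressed_lag = unstressed_lag),
            class = "phenotype_bounds")
}

#' Mutation effect on doubling time
#'
#' Converts a dimensionless raw selection coefficient \code{s_r} into the
#' doubling-time change of a mutation arising in a stressed wild-type cell:
#' \deqn{\Delta T = T_{wt}\, s_r/(s_r + 1)} truncated at
#' \eqn{T_{wt} - T_{wt,N}} so that no single mutation overshoots the
#' unstressed phenotype. \code{s_r = Inf} yields the truncation cap.
#'
#' @param s_r Raw (per-doubling) selection coefficient, >= 0 for beneficial
#'   conversions.
#' @param T_wt Stressed WT doubling time, minutes (default 162).
#' @param T_wt_N Unstressed WT doubling time, minutes (default 126).
#' @return Doubling-time change in minutes (positive magnitude).
#' @examples
#' effect_on_doubling(0.25)  # 162 * 0.25 / 1.25 = 32.4
#' effect_on_doubling(1)     # 81 truncated to 36
#' @export
effect_on_doubling <- function(s_r, T_wt = 162, T_wt_N = 126) {
  if (any(s_r == -1, na.rm = TRUE)) stop("s_r = -1 is undefined")
  raw <- ifelse(is.infinite(s_r), T_wt, T_wt * s_r / (s_r + 1))
  pmin(raw, T_wt - T_wt_N)
}

#' Mutation effect on lag time
#'
#' The lag-only selection coefficient is
#' \eqn{s = \ln 2\,\Delta\lambda/(M\tau)}; with sampled coefficients defined
#' on the doubling scale (\eqn{s = s_r \ln 2}) the \eqn{\ln 2} factors cancel
#' and the lag change of a mutation with raw coefficient \code{s_r} in a
#' carrier with doubling time \code{doubling_carrier} is
#' \eqn{\Delta\lambda = s_r M \tau}, truncated at \eqn{L_{wt} - L_{wt,N}}.
#'
#' @param s_r Raw selection coefficient (dimensionless).
#' @param doubling_carrier Carrier doubling time, minutes (> 0).
#' @param M Population doublings per cycle.
#' @param L_wt,L_wt_N Stressed and unstressed WT lag, minutes (defaults 805
#'   and 271).
#' @return Lag change in minutes (positive magnitude).
#' @examples
#' effect_on_lag(0.8114, 130.2, M = 5)  # ~528.2
#' @export
effect_on_lag <- function(s_r, doubling_carrier, M = 5,
                          L_wt = 805, L_wt_N = 271) {
  if (any(doubling_carrier <= 0)) stop("carrier doubling time must be > 0")
  pmin(s_r * M * doubling_carrier, L_wt - L_wt_N)
}

#' Diminishing-returns epistasis
#'
#' Scales a mutation's wild-type effect by the carrier's remaining distance
#' to the unstressed optimum:
#' \deqn{\Delta_G = \frac{G - \mathrm{unstressed}}
#'   {\mathrm{stressed} - \mathrm{unstressed}}\,\Delta_{wt}.}
#' A wild-type carrier receives the full effect; a fully adapted carrier
#' gains nothing. Applied component-wise to doubling time and, by analogy,
#' to lag.
#'
#' @param delta_wt Effect in a wild-type carrier, minutes.
#' @param current_value Carrier's current component value, minutes.
#' @param stressed_ref,unstressed_ref Component bounds, minutes.
#' @return The scaled effect in minutes.
#' @export
apply_diminishing_returns <- function(delta_wt, current_value,
                                      stressed_ref, unstressed_ref) {
  if (any(stressed_ref == unstressed_ref))
    stop("stressed and unstressed references must differ")
  delta_wt * (current_value - unstressed_ref) / (stressed_ref - unstressed_ref)
}

#' Sample one potential mutation for a dividing daughter cell
#'
#' Implements the per-daughter mutation chain: a mutation occurs with
#' probability \code{genome_size * base_rate_per_bp * rate_multiplier}; it
#' affects fitness with probability \code{fraction_affecting} (otherwise it
#' is neutral, with zero phenotype deltas); an affecting mutation is
#' beneficial with probability \code{fraction_beneficial}. Effect sizes are
#' sampled as a raw doubling-time change from the gamma distribution,
#' bridged to a dimensionless raw coefficient
#' \eqn{s_r = \Delta T_{raw}/(T_{wt} - \Delta T_{raw})} (infinite when the
#' draw reaches \eqn{T_{wt}}; the downstream truncations absorb it), and
#' converted to phenotype deltas per the map variant with
#' diminishing-returns scaling for beneficial effects and stressed-bound
#' capping for deleterious ones. Deltas are additive changes: the mutant
#' phenotype is \code{carrier + delta}, so beneficial deltas are <= 0.
#'
#' @param params A \code{\link{mutation_parameters}} object.
#' @param carrier List or vector with the carrier's \code{lag} and
#'   \code{doubling_time} (minutes), inside the bounds.
#' @param bounds A \code{\link{phenotype_bounds}} object.
#' @param M Population doublings per cycle (enters the lag conversion).
#' @return \code{NULL} when no mutation occurs, otherwise an object of class
#'   \code{"mutation"} with fields \code{raw_coefficient},
#'   \code{per_generation_s} (\eqn{= s_r \ln 2}), \code{affecting},
#'   \code{beneficial}, \code{delta_doubling}, \code{delta_lag},
#'   \code{locus_class}.
#' @export
sample_mutation <- function(params, carrier, bounds = phenotype_bounds(),
                            M = 5) {
  stopifnot(inherits(params, "mutation_parameters"),
            inherits(bounds, "phenotype_bounds"))
  p_mut <- min(1, params$genome_size * params$base_rate_per_bp *
                 params$rate_multiplier)
  if (stats::runif(1) >= p_mut) return(NULL)
  lag0 <- carrier$lag
  tau0 <- carrier$doubling_time
  neutral <- structure(list(raw_coefficient = 0, per_generation_s = 0,
                            affecting = FALSE, beneficial = FALSE,
                            delta_doubling = 0, delta_lag = 0,
                            locus_class = "generic"),
                       class = "mutation")
  if (stats::runif(1) >= params$fraction_affecting) return(neutral)
  draw_sr <- function() {
    raw <- stats::rgamma(1, shape = params$gamma_shape,
                         scale = params$gamma_scale)
    if (raw >= bounds$stressed_doubling) Inf
    else raw / (bounds$stressed_doubling - raw)
  }
  delta_pair <- function(s_r, beneficial) {
    dT_wt <- effect_on_doubling(s_r, bounds$stressed_doubling,
                                bounds$unstressed_doubling)
    dL_wt <- effect_on_lag(s_r, tau0, M, bounds$stressed_lag,
                           bounds$unstressed_lag)
    if (beneficial) {
      c(-apply_diminishing_returns(dT_wt, tau0, bounds$stressed_doubling,
                                   bounds$unstressed_doubling),
        -apply_diminishing_returns(dL_wt, lag0, bounds$stressed_lag,
                                   bounds$unstressed_lag))
    } else {
      c(min(dT_wt, bounds$stressed_doubling - tau0),
        min(dL_wt, bounds$stressed_lag - lag0))
    }
  }
  if (params$map_variant %in% c("M1", "M2")) {
    beneficial <- stats::runif(1) < params$fraction_beneficial
    s_r <- draw_sr()
    d <- delta_pair(s_r, beneficial)
    delta_doubling <- d[1L]
    delta_lag <- if (params$map_variant == "M2") d[2L] else 0
  } else {
    ben_T <- stats::runif(1) < params$fraction_beneficial
    sr_T <- draw_sr()
    ben_L <- stats::runif(1) < params$fraction_beneficial
    sr_L <- draw_sr()
    delta_doubling <- delta_pair(sr_T, ben_T)[1L]
    delta_lag <- delta_pair(sr_L, ben_L)[2L]
    beneficial <- ben_T
    s_r <- sr_T
  }
  structure(list(raw_coefficient = s_r,
                 per_generation_s = s_r * log(2),
                 affecting = TRUE, beneficial = beneficial,
                 delta_doubling = delta_doubling, delta_lag = delta_lag,
                 locus_class = "generic"),
            class = "mutation")
}

#' Beneficial locus target
#'
#' One mutational channel of the targeted-locus model: either a SNP target
#' (effective beneficial target size in bp, multiplied by the per-bp rate)
#' or a duplication channel with its own per-division rate. The effect is
#' the empirically measured carrier phenotype of the allele.
#'
#' @param gene Locus label (e.g. \code{"FPS1"}).
#' @param effect_lag,effect_doubling Carrier lag and doubling time, minutes.
#' @param snp_target_size Beneficial SNP target size in bp (\code{NULL} for a
#'   duplication channel).
#' @param duplication_rate Duplications per division (\code{NULL} for a SNP
#'   channel).
#' @return An object of class \code{"locus_target"}.
#' @export
locus_target <- function(gene, effect_lag, effect_doubling,
                         snp_target_size = NULL, duplication_rate = NULL) {
  if (is.null(snp_target_size) == is.null(duplication_rate))
    stop("exactly one of 'snp_target_size' and 'duplication_rate' must be set")
  if (!is.null(snp_target_size) && snp_target_size < 0)
    stop("'snp_target_size' must be >= 0")
  if (!is.null(duplication_rate) && duplication_rate < 0)
    stop("'duplication_rate' must be >= 0")
  structure(list(gene = gene, effect_lag = effect_lag,
                 effect_doubling = effect_doubling,
                 snp_target_size = snp_target_size,
                 duplication_rate = duplication_rate),
            class = "locus_target")
}

#' Default arsenic-adaptation locus targets
#'
#' The three beneficial channels of the targeted model: loss-of-function SNPs
#' in FPS1 and ASK10 and duplication of ACR3, with the reconstructed alleles'
#' empirical phenotypes. SNP target sizes are user-configurable effective
#' sizes (defaults 200 bp for FPS1 and 150 bp for ASK10, from
#' gene-length/loss-of-function site-density reasoning); the ACR3 basal
#' duplication rate is 3e-7 per division.
#'
#' @param fps1_target,ask10_target SNP target sizes in bp.
#' @param acr3_duplication_rate Duplications per division.
#' @return A named list of \code{\link{locus_target}} objects.
#' @export
default_locus_targets <- function(fps1_target = 200, ask10_target = 150,
                                  acr3_duplication_rate = 3e-7) {
  list(
    FPS1 = locus_target("FPS1", effect_lag = 276.6, effect_doubling = 130.2,
                        snp_target_size = fps1_target),
    ASK10 = locus_target("ASK10", effect_lag = 503.3, effect_doubling = 134.6,
                         snp_target_size = ask10_target),
    ACR3 = locus_target("ACR3", effect_lag = 630.4, effect_doubling = 122.8,
                        duplication_rate = acr3_duplication_rate))
}

#' Per-division allele-class mutation probabilities
#'
#' SNP channels get \code{snp_target_size * base_rate_per_bp * multiplier};
#' duplication channels get \code{duplication_rate * multiplier}.
#'
#' @param targets A list of \code{\link{locus_target}} objects.
#' @param base_rate_per_bp Per-bp per-division mutation rate.
#' @param multiplier Global rate multiplier (> 0), e.g. 1, 3, 5, 10.
#' @return Named numeric vector of per-division probabilities.
#' @export
targeted_mutation_rates <- function(targets, base_rate_per_bp = 0.33e-9,
                                    multiplier = 1) {
  stopifnot(multiplier > 0)
  vapply(targets, function(tg) {
    stopifnot(inherits(tg, "locus_target"))
    if (!is.null(tg$snp_target_size))
      tg$snp_target_size * base_rate_per_bp * multiplier
    else tg$duplication_rate * multiplier
  }, numeric(1))
}

#' Phenotype of a targeted-model genotype under complete negative epistasis
#'
#' The phenotype of a genotype carrying any set of beneficial alleles is the
#' single best allele's empirical (lag, doubling time) pair; further alleles
#' add nothing. "Best" means fittest against the founder: highest analytic
#' per-generation selection coefficient (which weighs both the doubling-time
#' and the lag gain; see
#' \code{\link{analytic_selection_coefficient}}), ties broken by smaller
#' doubling time then smaller lag. A genotype carrying both the FPS1 and the
#' ACR3 allele therefore has the FPS1 phenotype: ACR3's smaller doubling time
#' does not compensate its much longer lag.
#'
#' @param alleles Character vector of carried allele labels (may be empty).
#' @param targets Named list of \code{\link{locus_target}} objects.
#' @param founder Numeric vector \code{c(lag, doubling_time)} of the founder
#'   (default \code{c(805, 162)}).
#' @param M Population doublings per cycle entering the lag term (default 5).
#' @return Named numeric vector \code{c(lag = , doubling_time = )}.
#' @export
combine_targeted_genotype <- function(alleles, targets = default_locus_targets(),
                                      founder = c(lag = 805,
                                                  doubling_time = 162),
                                      M = 5) {
  if (length(alleles) == 0)
    return(c(lag = unname(founder[1L]), doubling_time = unname(founder[2L])))
  unknown <- setdiff(alleles, names(targets))
  if (length(unknown) > 0)
    stop("unknown allele label(s): ", paste(unknown, collapse = ", "))
  best <- alleles[best_allele_index(alleles, targets, founder, M)]
  c(lag = targets[[best]]$effect_lag,
    doubling_time = targets[[best]]$effect_doubling)
}

# index (within `alleles`) of the fittest allele against the founder
best_allele_index <- function(alleles, targets, founder, M = 5) {
  s <- vapply(targets[alleles], function(tg)
    analytic_selection_coefficient(founder[[1L]], founder[[2L]],
                                   tg$effect_lag, tg$effect_doubling, M),
    numeric(1))
  dt <- vapply(targets[alleles], `[[`, numeric(1), "effect_doubling")
  lg <- vapply(targets[alleles], `[[`, numeric(1), "effect_lag")
  order(-s, dt, lg)[1L]
}

#' Full-factorial mutation-parameter grid
#'
#' Cartesian product of multiplicative perturbations \{1/5, 1/3, 1, 3, 5\} of
#' the base mutation rate, the fraction of fitness-affecting mutations and
#' the fraction of beneficial mutations, crossed with six gamma scales
#' (13.3, 20, 27.35, 33, 40, 47 min): 750 parameter sets, all with shape 2.
#' Probabilities are capped at 1.
#'
#' @param base A \code{\link{mutation_parameters}} object giving the central
#'   values.
#' @return A data frame with one row per parameter set (columns \code{set_id},
#'   \code{rate_multiplier}, \code{fraction_affecting},
#'   \code{fraction_beneficial}, \code{gamma_shape}, \code{gamma_scale}).
#' @export
parameter_grid <- function(base = mutation_parameters()) {
  stopifnot(inherits(base, "mutation_parameters"))
  f <- c(1 / 5, 1 / 3, 1, 3, 5)
  g <- expand.grid(rate_multiplier = f,
                   fraction_affecting = pmin(1, base$fraction_affecting * f),
                   fraction_beneficial = pmin(1, base$fraction_beneficial * f),
                   gamma_scale = c(13.3, 20, 27.35, 33, 40, 47),
                   KEEP.OUT.ATTRS = FALSE)
  data.frame(set_id = seq_len(nrow(g)), g,
             gamma_shape = base$gamma_shape)
}

#' Materialize one grid row as mutation parameters
#'
#' @param row One row of \code{\link{parameter_grid}} output.
#' @param base The base \code{\link{mutation_parameters}}.
#' @param map_variant Pleiotropy map for this run.
#' @return A \code{\link{mutation_parameters}} object.
#' @export
grid_parameters <- function(row, base = mutation_parameters(),
                            map_variant = "M2") {
  mutation_parameters(
    base_rate_per_bp = base$base_rate_per_bp,
    genome_size = base$genome_size,
    fraction_affecting = row$fraction_affecting,
    fraction_beneficial = row$fraction_beneficial,
    gamma_shape = row$gamma_shape,
    gamma_scale = row$gamma_scale,
    map_variant = map_variant,
    rate_multiplier = row$rate_multiplier)
}
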