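#' Analytic selection coefficient from lag and doubling-time differences
#'
#' Closed-form per-generation selection coefficient of a mutant (subscript 2)
#' against a resident (subscript 1) in a batch cycle that ends after the
#' resident's M doublings:
#' \deqn{s = \ln 2\,(\tau_1/\tau_2 - 1 + (\lambda_1 - \lambda_2)/(M \tau_2))}
#' The expression is the exact sum of a doubling-time term
#' \eqn{\ln 2 (\tau_1/\tau_2 - 1)} and a lag term
#' \eqn{\ln 2 (\lambda_1 - \lambda_2)/(M \tau_2)}; the lag contribution
#' shrinks as M or the mutant doubling time grows. The derivation assumes
#' \code{lag_mut <= lag_wt} (the cycle end set by the resident); the formula
#' is still evaluated, with a warning, when that does not hold.
#'
#' @param lag_wt,doubling_wt Resident lag and doubling time (minutes).
#' @param lag_mut,doubling_mut Mutant lag and doubling time (minutes).
#' @param M Population doublings per cycle.
#' @param component \code{"total"} (default), or only the \code{"doubling"}
#'   or \code{"lag"} term.
#' @return Per-generation selection coefficient (dimensionless).
#' @examples
#' analytic_selection_coefficient(804.8, 162.3, 276.6, 130.2, M = 5)
#' @export
analytic_selection_coefficient <- function(lag_wt, doubling_wt,
                                           lag_mut, doubling_mut, M = 5,
                                           component = c("total", "doubling",
                                                         "lag")) {
  component <- match.arg(component)
  if (any(doubling_wt <= 0) || any(doubling_mut <= 0))
    stop("doubling times must be > 0")
  if (any(lag_mut > lag_wt))
    warning("lag_mut > lag_wt: outside the derivation's assumption that the ",
            "resident sets the cycle end; formula evaluated as written")
  doubling_term <- log(2) * (doubling_wt / doubling_mut - 1)
  lag_term <- log(2) * (lag_wt - lag_mut) / (M * doubling_mut)
  switch(component,
         total = doubling_term + lag_term,
         doubling = doubling_term,
         lag = lag_term)
}

#' Deterministic serial-batch competition between two genotypes
#'
#' Simulates a competition assay between a resident (\code{wt}) and a mutant
#' over repeated batch cycles. Each cycle is grown until the total population
#' has completed M doublings (cycle end solved by root finding), the
#' frequency ratio \eqn{r = N_{mut}/N_{wt}} is recorded, and both
#' subpopulations are diluted proportionally back to the bottleneck; lags
#' restart every cycle. The per-generation selection coefficient is the OLS
#' slope of \eqn{\ln r} at cycle ends (including the t = 0 point) against
#' cumulative generations, counted as M per cycle.
#'
#' With the default \code{dilution = "whole-cells"} every transfer rounds
#' each subpopulation to an integer number of cells, reflecting that a
#' bottleneck moves discrete cells: once the losing lineage's expected
#' transfer falls below half a cell it goes extinct and the ratio trajectory
#' (and hence the regression) ends there. \code{dilution = "continuous"}
#' keeps real-valued counts, so both lineages persist indefinitely and all
#' cycles enter the regression.
#'
#' @param wt,mutant \code{\link{growth_law}} objects with their starting
#'   counts; the counts must sum to the protocol's bottleneck.
#' @param protocol A \code{\link{batch_protocol}}.
#' @param dilution Between-cycle dilution rule; see Details.
#' @return An object of class \code{"competition_fit"}: a list with the
#'   per-cycle trajectory (data frame with \code{cycle}, \code{t_end_min},
#'   \code{generations}, \code{ln_ratio}, \code{mutant_frequency}), the
#'   regressed \code{selection_coefficient}, the analytic coefficient, and
#'   the inputs.
#' @examples
#' p <- batch_protocol(1e5, 5, 20)
#' wt <- growth_law(804.8, 162.3, initial_count = 1e5 - 1)
#' mut <- growth_law(276.6, 130.2, initial_count = 1)
#' fit <- compete_deterministic(wt, mut, p)
#' coef(fit)
#' @export
compete_deterministic <- function(wt, mutant, protocol,
                                  dilution = c("whole-cells", "continuous")) {
  stopifnot(inherits(wt, "growth_law"), inherits(mutant, "growth_law"),
            inherits(protocol, "batch_protocol"))
  dilution <- match.arg(dilution)
  N <- protocol$bottleneck
  M <- protocol$doublings_per_cycle
  if (abs(wt$initial_count + mutant$initial_count - N) > 1e-8)
    stop("initial counts must sum to the protocol bottleneck")
  n1 <- wt$initial_count
  n2 <- mutant$initial_count
  cycle <- 0
  rows <- list(data.frame(cycle = 0, t_end_min = 0, generations = 0,
                          ln_ratio = log(n2 / n1),
                          mutant_frequency = n2 / (n1 + n2)))
  extinct <- NA_character_
  for (cy in seq_len(protocol$n_cycles)) {
    laws <- list(growth_law(wt$lag, wt$doubling_time, n1),
                 growth_law(mutant$lag, mutant$doubling_time, n2))
    t_end <- cycle_end_time(laws, protocol)
    n1 <- subpopulation_size(laws[[1]], t_end)
    n2 <- subpopulation_size(laws[[2]], t_end)
    scale <- N / (n1 + n2)
    n1 <- n1 * scale
    n2 <- n2 * scale
    if (dilution == "whole-cells") {
      n1 <- round(n1)
      n2 <- round(n2)
    }
    if (n1 == 0 || n2 == 0) {
      extinct <- if (n1 == 0) "wt" else "mutant"
      break
    }
    rows[[cy + 1L]] <- data.frame(cycle = cy, t_end_min = t_end,
                                  generations = cy * M,
                                  ln_ratio = log(n2 / n1),
                                  mutant_frequency = n2 / (n1 + n2))
  }
  traj <- do.call(rbind, rows)
  fit <- structure(
    list(trajectory = traj,
         selection_coefficient = NA_real_,
         analytic = analytic_selection_coefficient(
           wt$lag, wt$doubling_time, mutant$lag, mutant$doubling_time, M),
         extinct = extinct, wt = wt, mutant = mutant, protocol = protocol,
         dilution = dilution),
    class = "competition_fit")
  # trajectories with fewer than 3 recorded points carry no regression
  fit$selection_coefficient <- tryCatch(regress_selection_coefficient(fit),
                                        error = function(e) NA_real_)
  fit
}

#' Regression-based selection coefficient of a competition trajectory
#'
#' OLS slope of \eqn{\ln r} at cycle ends (including the t = 0 point)
#' against the cumulative generation axis.
#'
#' @param traj A \code{"competition_fit"} object or a data frame with
#'   \code{generations} and \code{ln_ratio} columns.
#' @return Per-generation selection coefficient.
#' @export
regress_selection_coefficient <- function(traj) {
  d <- if (inherits(traj, "competition_fit")) traj$trajectory else traj
  stopifnot(is.data.frame(d), all(c("generations", "ln_ratio") %in% names(d)))
  ok <- is.finite(d$ln_ratio)
  if (!all(ok))
    stop("trajectory contains non-finite ln(ratio): a subpopulation is extinct")
  if (sum(ok) < 3)
    stop("need at least 3 finite ln(ratio) points for the regression")
  unname(stats::coef(stats::lm(ln_ratio ~ generations, data = d))[2L])
}

#' First generation at which the mutant reaches a frequency threshold
#'
#' @param fit A \code{"competition_fit"} object.
#' @param threshold Mutant frequency defining fixation (default 0.99).
#' @return The first cycle-end generation count at which the mutant frequency
#'   is at or above the threshold, or \code{NA} if never reached.
#' @export
fixation_generation <- function(fit, threshold = 0.99) {
  stopifnot(inherits(fit, "competition_fit"))
  d <- fit$trajectory
  hit <- which(d$mutant_frequency >= threshold)
  if (length(hit) == 0) return(NA_real_)
  d$generations[hit[1L]]
}

#' @export
coef.competition_fit <- function(object, ...) {
  c(s = object$selection_coefficient)
}

#' @export
print.competition_fit <- function(x, ...) {
  cat("Deterministic serial-batch competition\n")
  cat(sprintf("  WT:     lag %.1f min, doubling %.1f min\n",
              x$wt$lag, x$wt$doubling_time))
  cat(sprintf("  Mutant: lag %.1f min, doubling %.1f min\n",
              x$mutant$lag, x$mutant$doubling_time))
  cat(sprintf("  %d cycles recorded (%s dilution)\n",
              max(x$trajectory$cycle), x$dilution))
  if (!is.na(x$extinct))
    cat(sprintf("  %s lineage extinct at transfer after cycle %d\n",
                x$extinct, max(x$trajectory$cycle) + 1L))
  cat(sprintf("  selection coefficient (regressed): %.4f per generation\n",
              x$selection_coefficient))
  cat(sprintf("  selection coefficient (analytic):  %.4f per generation\n",
              x$analytic))
  invisible(x)
}

#' @export
summary.competition_fit <- function(object, ...) {
  M <- object$protocol$doublings_per_cycle
  out <- list(
    selection_coefficient = object$selection_coefficient,
    analytic_total = object$analytic,
    analytic_doubling = analytic_selection_coefficient(
      object$wt$lag, object$wt$doubling_time,
      object$mutant$lag, object$mutant$doubling_time, M, "doubling"),
    analytic_lag = analytic_selection_coefficient(
      object$wt$lag, object$wt$doubling_time,
      object$mutant$lag, object$mutant$doubling_time, M, "lag"),
    fixation_generation = fixation_generation(object),
    n_cycles = max(object$trajectory$cycle))
  class(out) <- "summary.competition_fit"
  out
}

#' @export
print.summary.competition_fit <- function(x, ...) {
  cat(sprintf("s (regressed)          : %.4f\n", x$selection_coefficient))
  cat(sprintf("s (analytic)           : %.4f = %.4f (doubling) + %.4f (lag)\n",
              x$analytic_total, x$analytic_doubling, x$analytic_lag))
  cat(sprintf("fixation (>= 99%%) at   : generation %s\n",
              format(x$fixation_generation)))
  cat(sprintf("cycles in trajectory   : %d\n", x$n_cycles))
  invisible(x)
}

#' @export
plot.competition_fit <- function(x, ...) {
  d <- x$trajectory
  plot(d$generations, d$ln_ratio, xlab = "generations",
       ylab = "ln(mutant/WT)", pch = 19, ...)
  graphics::abline(stats::lm(ln_ratio ~ generations, data = d), lty = 2)
  invisible(x)
}

#' @export
as.data.frame.competition_fit <- function(x, ...) x$trajectory

#' Write a competition trajectory to delimited text
#'
#' One row per cycle end plus the t = 0 row, with columns \code{cycle},
#' \code{t_end_min}, \code{generations}, \code{ln_ratio},
#' \code{mutant_frequency}.
#'
#' @param fit A \code{"competition_fit"} object.
#' @param path Output file path.
#' @export
write_trajectory <- function(fit, path) {
  stopifnot(inherits(fit, "competition_fit"))
  utils::write.table(fit$trajectory, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
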