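#' Deterministic growth law of one genotype in a batch cycle
#'
#' A genotype's growth within a batch cycle is fully described by three
#' numbers: no net growth until the lag time has elapsed, then exponential
#' growth with a fixed doubling time.
#'
#' @param lag Lag time in minutes (time to the first cell division), >= 0.
#' @param doubling_time Doubling time in minutes during exponential growth,
#'   > 0.
#' @param initial_count Cell count at the start of the cycle, >= 0.
#' @return An object of class \code{"growth_law"}.
#' @examples
#' wt <- growth_law(lag = 804.8, doubling_time = 162.3, initial_count = 1e5)
#' subpopulation_size(wt, 804.8 + 5 * 162.3)  # 5 doublings
#' @export
growth_law <- function(lag, doubling_time, initial_count = 1) {
  stopifnot(is.numeric(lag), length(lag) == 1L, is.finite(lag),
            is.numeric(doubling_time), length(doubling_time) == 1L,
            is.finite(doubling_time),
            is.numeric(initial_count), length(initial_count) == 1L,
            is.finite(initial_count))
  if (lag < 0) stop("'lag' must be >= 0")
  if (doubling_time <= 0) stop("'doubling_time' must be > 0")
  if (initial_count < 0) stop("'initial_count' must be >= 0")
  structure(list(lag = lag, doubling_time = doubling_time,
                 initial_count = initial_count),
            class = "growth_law")
}

#' @export
print.growth_law <- function(x, ...) {
  cat(sprintf("Growth law: lag %.1f min, doubling time %.1f min, N0 = %g\n",
              x$lag, x$doubling_time, x$initial_count))
  invisible(x)
}

#' Serial-transfer batch protocol
#'
#' Defines the propagation regime: each cycle starts from \code{bottleneck}
#' cells, runs until the total population has doubled
#' \code{doublings_per_cycle} times, and is then subsampled back to the
#' bottleneck to found the next cycle.
#'
#' @param bottleneck Number of cells founding each cycle (N), >= 1.
#' @param doublings_per_cycle Population doublings per cycle (M), >= 1.
#' @param n_cycles Number of batch cycles, >= 1.
#' @return An object of class \code{"batch_protocol"}.
#' @examples
#' batch_protocol(bottleneck = 1e5, doublings_per_cycle = 5, n_cycles = 20)
#' @export
batch_protocol <- function(bottleneck = 1e5, doublings_per_cycle = 5,
                           n_cycles = 20) {
  stopifnot(is.numeric(bottleneck), length(bottleneck) == 1L,
            is.numeric(doublings_per_cycle), length(doublings_per_cycle) == 1L,
            is.numeric(n_cycles), length(n_cycles) == 1L)
  if (bottleneck < 1 || bottleneck != round(bottleneck))
    stop("'bottleneck' must be a positive integer")
  if (doublings_per_cycle < 1 || doublings_per_cycle != round(doublings_per_cycle))
    stop("'doublings_per_cycle' must be a positive integer")
  if (n_cycles < 1 || n_cycles != round(n_cycles))
    stop("'n_cycles' must be a positive integer")
  structure(list(bottleneck = bottleneck,
                 doublings_per_cycle = doublings_per_cycle,
                 n_cycles = n_cycles),
            class = "batch_protocol")
}

#' @export
print.batch_protocol <- function(x, ...) {
  cat(sprintf(
    "Batch protocol: N = %g, M = %d doublings/cycle, %d cycles (%d generations)\n",
    x$bottleneck, x$doublings_per_cycle, x$n_cycles,
    x$doublings_per_cycle * x$n_cycles))
  invisible(x)
}

#' Subpopulation size under a growth law
#'
#' Size at time \code{t} within a cycle: the initial count for
#' \code{t <= lag}, and \code{initial_count * 2^((t - lag)/doubling_time)}
#' afterwards. Continuous at \code{t = lag}.
#'
#' @param law A \code{\link{growth_law}}.
#' @param t Time(s) in minutes since the start of the cycle, >= 0.
#' @return Cell count(s), same length as \code{t}.
#' @export
subpopulation_size <- function(law, t) {
  stopifnot(inherits(law, "growth_law"), is.numeric(t))
  if (any(t < 0)) stop("'t' must be >= 0")
  ifelse(t <= law$lag,
         law$initial_count,
         law$initial_count * 2^((t - law$lag) / law$doubling_time))
}

#' Time at which a batch cycle ends
#'
#' Solves for the unique time \code{t_end} at which the summed sizes of all
#' subpopulations reach \code{2^M} times the total initial count, i.e. the
#' cycle's M population doublings are complete. The total size is monotone
#' non-decreasing in time, so the root is found by Brent's method.
#'
#' @param laws A list of \code{\link{growth_law}} objects (or a single one).
#' @param protocol A \code{\link{batch_protocol}}; only
#'   \code{doublings_per_cycle} is used.
#' @param tol Relative tolerance of the root, as a fraction of the search
#'   interval (default 1e-10).
#' @return The cycle end time in minutes.
#' @examples
#' p <- batch_protocol(1e5, 5, 20)
#' cycle_end_time(growth_law(804.8, 162.3, 1e5), p)  # = 804.8 + 5*162.3
#' @export
cycle_end_time <- function(laws, protocol, tol = 1e-10) {
  if (inherits(laws, "growth_law")) laws <- list(laws)
  stopifnot(all(vapply(laws, inherits, logical(1), "growth_law")),
            inherits(protocol, "batch_protocol"))
  n0 <- vapply(laws, function(l) l$initial_count, numeric(1))
  if (sum(n0) <= 0) stop("all subpopulations are empty")
  target <- 2^protocol$doublings_per_cycle * sum(n0)
  # Bracket from 0: a subpopulation that dominates the mixture can finish the
  # cycle's doublings before a slower genotype's lag has even ended.
  upper <- max(vapply(laws, `[[`, numeric(1), "lag")) +
    2 * protocol$doublings_per_cycle *
      max(vapply(laws, `[[`, numeric(1), "doubling_time"))
  total_at <- function(t) sum(vapply(laws, subpopulation_size, numeric(1), t))
  stats::uniroot(function(t) total_at(t) - target,
                 lower = 0, upper = upper,
                 tol = tol * upper, check.conv = TRUE)$root
}
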