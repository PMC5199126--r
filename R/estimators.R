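#' Fluctuation-assay mutation rate (p0 method)
#'
#' Estimates a per-locus per-division loss-of-function mutation rate from the
#' fraction \eqn{P_0} of parallel cultures with zero resistant colonies:
#' \eqn{\mu = -\ln(P_0)/N}, where \eqn{N} is the number of cell divisions
#' (approximately cells) per culture.
#'
#' @param p_zero Fraction of cultures without resistant colonies, in (0, 1].
#' @param cells_per_culture Cells per culture (>= 1).
#' @return Mutation rate per locus per division.
#' @examples
#' fluctuation_mutation_rate(exp(-1), 1e6)  # 1e-6
#' @export
fluctuation_mutation_rate <- function(p_zero, cells_per_culture) {
  stopifnot(is.numeric(p_zero), length(p_zero) == 1L,
            is.numeric(cells_per_culture), cells_per_culture >= 1)
  if (p_zero <= 0 || p_zero > 1) {
    if (p_zero == 0)
      stop("p_zero = 0: every culture had mutants; the p0 estimator is ",
           "undefined - repeat the assay at a higher dilution")
    stop("'p_zero' must be in (0, 1]")
  }
  -log(p_zero) / cells_per_culture
}

#' Probability of adaptive standing variants after clonal expansion
#'
#' Assuming adaptive mutations during a clonal expansion from a single cell
#' are Poisson distributed, a colony of final size \eqn{n} underwent
#' \eqn{n - 1} divisions, so the expected number of adaptive mutations is
#' \eqn{\lambda =} rate \eqn{\times (n - 1)}. Returns the probability that a
#' single founder population carries one or more standing adaptive variants,
#' and the probability that all of \code{n_populations} independent founder
#' populations do.
#'
#' @param final_population Final clone size (>= 1).
#' @param beneficial_rate_per_division Adaptive mutations per division.
#' @param n_populations Number of independent founder populations.
#' @return Named list with \code{p_single} and \code{p_all}.
#' @examples
#' standing_variant_probability(3e7, 0.0834 / (3e7 - 1), 4)
#' @export
standing_variant_probability <- function(final_population,
                                         beneficial_rate_per_division,
                                         n_populations = 1) {
  stopifnot(final_population >= 1, beneficial_rate_per_division >= 0,
            n_populations >= 1)
  divisions <- final_population - 1
  lambda <- beneficial_rate_per_division * divisions
  p_single <- 1 - exp(-lambda)
  list(p_single = p_single, p_all = p_single^n_populations)
}

#' Confidence filter for variant frequency trajectories
#'
#' Keeps a variant if and only if (i) its read depth exceeds
#' \code{min_depth} (summed across time points by default, or at every kept
#' time point with \code{depth_mode = "per_timepoint"}), (ii) its frequency
#' exceeds \code{min_freq} at no fewer than \code{min_timepoints} time
#' points, and (iii) when a \code{sift} column is present and non-missing,
#' its SIFT score is below \code{sift_cutoff}. All rows of surviving variants
#' are returned. The filter is idempotent and monotone: raising any threshold
#' never enlarges the surviving set.
#'
#' @param table Data frame with columns \code{variant_id}, \code{time_point},
#'   \code{read_depth}, \code{frequency}; optional \code{sift}.
#' @param min_depth Depth gate (strictly greater than; default 100).
#' @param min_freq Frequency gate (strictly greater than; default 0.10).
#' @param min_timepoints Minimum time points above the frequency gate
#'   (default 2).
#' @param sift_cutoff SIFT gate (strictly less than; default 0.05).
#' @param depth_mode \code{"total"} (default) or \code{"per_timepoint"}.
#' @return The filtered table (same columns).
#' @export
filter_variant_trajectories <- function(table, min_depth = 100,
                                        min_freq = 0.10, min_timepoints = 2,
                                        sift_cutoff = 0.05,
                                        depth_mode = c("total",
                                                       "per_timepoint")) {
  depth_mode <- match.arg(depth_mode)
  required <- c("variant_id", "time_point", "read_depth", "frequency")
  missing_cols <- setdiff(required, names(table))
  if (length(missing_cols) > 0)
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  if (nrow(table) == 0) return(table)
  keep_variant <- vapply(split(table, table$variant_id), function(d) {
    depth_ok <- if (depth_mode == "total") sum(d$read_depth) > min_depth
                else all(d$read_depth > min_depth)
    freq_ok <- sum(d$frequency > min_freq) >= min_timepoints
    sift_ok <- if ("sift" %in% names(d) && any(is.finite(d$sift)))
      min(d$sift, na.rm = TRUE) < sift_cutoff else TRUE
    depth_ok && freq_ok && sift_ok
  }, logical(1))
  table[table$variant_id %in% names(keep_variant)[keep_variant], ,
        drop = FALSE]
}

#' Read / write variant trajectory tables
#'
#' Delimited text with header columns \code{variant_id}, \code{time_point},
#' \code{read_depth}, \code{frequency} and optionally \code{effect},
#' \code{sift}.
#'
#' @param path File path.
#' @return \code{read_variant_table}: the table as a data frame.
#' @export
read_variant_table <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  required <- c("variant_id", "time_point", "read_depth", "frequency")
  missing_cols <- setdiff(required, names(d))
  if (length(missing_cols) > 0)
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  d
}

#' @param table A variant trajectory table.
#' @rdname read_variant_table
#' @export
write_variant_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
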