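#' Specification of a synthetic growth curve
#'
#' Ground-truth parameters for a simulated plate-reader well: flat baseline
#' during the lag, then logistic growth from the inoculum density toward the
#' carrying capacity at the given intrinsic doubling time, plus additive
#' Gaussian reading noise. The defaults emulate a 72-h cultivation read every
#' 20 minutes.
#'
#' @param lag Lag time, minutes.
#' @param doubling_time Intrinsic doubling time, minutes.
#' @param carrying_capacity Plateau net density, OD units (default 1).
#' @param baseline Background light scattering, OD units (default 0.08).
#' @param inoculum Starting cell density, OD units (default 1e-3).
#' @param noise_sd Reading noise standard deviation, OD (default 0.003).
#' @param cadence Reading interval, minutes (default 20).
#' @param duration Total cultivation, minutes (default 4320 = 72 h).
#' @return An object of class \code{"synthetic_curve_spec"}.
#' @export
synthetic_curve_spec <- function(lag = 276.6, doubling_time = 130.2,
                                 carrying_capacity = 1, baseline = 0.08,
                                 inoculum = 1e-3, noise_sd = 0.003,
                                 cadence = 20, duration = 4320) {
  stopifnot(lag >= 0, doubling_time > 0, carrying_capacity > 0,
            baseline >= 0, inoculum > 0, noise_sd >= 0, cadence > 0,
            duration > cadence)
  structure(list(lag = lag, doubling_time = doubling_time,
                 carrying_capacity = carrying_capacity, baseline = baseline,
                 inoculum = inoculum, noise_sd = noise_sd, cadence = cadence,
                 duration = duration),
            class = "synthetic_curve_spec")
}

#' Generate a synthetic growth curve
#'
#' @param spec A \code{\link{synthetic_curve_spec}}.
#' @param well_id Well label.
#' @return A \code{\link{growth_curve}}.
#' @examples
#' set.seed(1)
#' generate_growth_curve(synthetic_curve_spec())
#' @export
generate_growth_curve <- function(spec, well_id = "well") {
  stopifnot(inherits(spec, "synthetic_curve_spec"))
  times <- seq(0, spec$duration, by = spec$cadence)
  K <- spec$carrying_capacity
  x0 <- spec$inoculum
  r <- log(2) / spec$doubling_time
  tp <- pmax(times - spec$lag, 0)
  x <- K * x0 * exp(r * tp) / (K + x0 * (exp(r * tp) - 1))
  od <- spec$baseline + x
  if (spec$noise_sd > 0) od <- od + stats::rnorm(length(od), 0, spec$noise_sd)
  growth_curve(times, od, well_id = well_id)
}

#' Generate a synthetic plate with founder controls
#'
#' Builds a wide-format plate table (first column \code{time}, one column per
#' well) containing the requested genotype wells plus founder-control wells
#' at randomized positions, and a companion layout table recording which well
#' holds which genotype.
#'
#' @param genotype_specs Named list of \code{\link{synthetic_curve_spec}}
#'   objects, one entry per non-founder genotype well.
#' @param founder_spec The founder's \code{\link{synthetic_curve_spec}}.
#' @param n_founder_controls Number of founder-control wells (default 4).
#' @return List with \code{plate} (wide data frame), \code{layout} (data
#'   frame \code{well}, \code{genotype}) and \code{founder_wells}.
#' @export
generate_plate <- function(genotype_specs, founder_spec = synthetic_curve_spec(
                             lag = 805, doubling_time = 162),
                           n_founder_controls = 4) {
  stopifnot(length(genotype_specs) >= 1 || n_founder_controls >= 1)
  specs <- c(genotype_specs,
             stats::setNames(rep(list(founder_spec), n_founder_controls),
                             rep("founder", n_founder_controls)))
  pos <- sample(length(specs))  # fixed but randomized positions
  specs <- specs[pos]
  wells <- sprintf("W%02d", seq_along(specs))
  curves <- lapply(seq_along(specs), function(i)
    generate_growth_curve(specs[[i]], well_id = wells[i]))
  plate <- data.frame(time = curves[[1L]]$times)
  for (i in seq_along(curves)) plate[[wells[i]]] <- curves[[i]]$od
  layout <- data.frame(well = wells, genotype = names(specs),
                       stringsAsFactors = FALSE)
  list(plate = plate, layout = layout,
       founder_wells = wells[names(specs) == "founder"])
}

#' Write a synthetic plate to delimited text
#'
#' @param plate The \code{plate} element of \code{\link{generate_plate}}.
#' @param path Output path (tab-separated; readable by
#'   \code{\link{read_plate}}).
#' @export
write_plate <- function(plate, path) {
  utils::write.table(plate, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Generate a synthetic variant trajectory table
#'
#' Emulates population sequencing of known allele-frequency trajectories:
#' per variant and time point the read depth is Poisson with the given mean
#' and the alternate-read count is binomial at the true frequency; the
#' observed frequency is their ratio (0 when depth is 0).
#'
#' @param true_trajectories Data frame with columns \code{variant_id},
#'   \code{time_point}, \code{frequency} (true frequencies in [0, 1]);
#'   optional extra columns (e.g. \code{effect}, \code{sift}) are carried
#'   through.
#' @param mean_depth Mean sequencing depth (default 200).
#' @return A variant trajectory table with \code{read_depth} and observed
#'   \code{frequency}, plus \code{true_frequency}.
#' @export
generate_variant_table <- function(true_trajectories, mean_depth = 200) {
  stopifnot(all(c("variant_id", "time_point", "frequency") %in%
                  names(true_trajectories)),
            all(true_trajectories$frequency >= 0),
            all(true_trajectories$frequency <= 1))
  n <- nrow(true_trajectories)
  depth <- stats::rpois(n, mean_depth)
  alt <- stats::rbinom(n, depth, true_trajectories$frequency)
  out <- true_trajectories
  out$true_frequency <- out$frequency
  out$read_depth <- depth
  out$frequency <- ifelse(depth > 0, alt / depth, 0)
  out
}
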