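#' Growth curve container
#'
#' @param times Sampling times in minutes, strictly increasing.
#' @param od Optical-density readings, same length.
#' @param well_id Well label.
#' @return An object of class \code{"growth_curve"}.
#' @export
growth_curve <- function(times, od, well_id = "well") {
  stopifnot(length(times) == length(od), all(is.finite(od)),
            all(diff(times) > 0))
  structure(list(times = as.numeric(times), od = as.numeric(od),
                 well_id = well_id, preprocessed = FALSE),
            class = "growth_curve")
}

#' @export
print.growth_curve <- function(x, ...) {
  cat(sprintf("Growth curve '%s': %d readings over %.1f h%s\n", x$well_id,
              length(x$times), diff(range(x$times)) / 60,
              if (isTRUE(x$preprocessed)) " (preprocessed)" else ""))
  invisible(x)
}

#' Preprocess a raw growth curve
#'
#' Light running-median smoothing removes single-reading noise spikes, the
#' background light scattering (mean of the first three smoothed readings) is
#' subtracted with a floor at a small positive epsilon, and an optional
#' monotone calibration maps net optical density to population size
#' (default identity).
#'
#' @param curve A \code{\link{growth_curve}}.
#' @param smoothing_window Running-median window in readings (odd; default 5).
#' @param calibration Monotone function OD -> population size (default
#'   identity).
#' @param eps Positive floor applied after background subtraction
#'   (default 1e-3).
#' @return The preprocessed \code{\link{growth_curve}} (od holds the
#'   calibrated net signal).
#' @export
preprocess_curve <- function(curve, smoothing_window = 5,
                             calibration = identity, eps = 1e-3) {
  stopifnot(inherits(curve, "growth_curve"))
  if (length(curve$od) < smoothing_window)
    stop("fewer readings than the smoothing window")
  k <- smoothing_window
  if (k %% 2 == 0) k <- k + 1
  sm <- if (k >= 3) stats::runmed(curve$od, k) else curve$od
  background <- mean(sm[seq_len(min(3L, length(sm)))])
  net <- pmax(sm - background, eps)
  out <- curve
  out$od <- calibration(net)
  out$preprocessed <- TRUE
  out$background <- background
  out$eps <- eps
  out
}

#' Extract lag, doubling time and growth efficiency from a growth curve
#'
#' Two estimators are provided. The default, \code{method = "logistic"},
#' exploits that logistic growth is exactly linear on the logit scale:
#' \eqn{\ln(x/(K - x)) = r t + c}, with the plateau \eqn{K} estimated from
#' the top smoothed readings. The intrinsic rate \eqn{r} is the OLS slope of
#' the logit-transformed signal over the readings between \code{min_signal}
#' and \code{upper_frac} of the plateau, the doubling time is \eqn{\ln 2/r},
#' and the lag is the time at which the fitted line crosses the logit of the
#' inoculum reference level \code{ref_level} (floored at 0). Pooling the
#' whole exponential rise makes this estimator robust to reading noise.
#'
#' \code{method = "max-slope"} is the classical tangent construction: the
#' doubling time is \eqn{\ln 2} over the maximal slope of log size across
#' sliding windows of \code{fit_window} readings (slopes smoothed by a
#' running median before taking the maximum), and the lag is where the
#' max-slope tangent crosses \code{log(ref_level)}. It assumes nothing about
#' the curve's later shape but is considerably noisier.
#'
#' Efficiency is the total gain in population size (final minus initial net
#' signal) under both methods. Curves whose signal never exceeds
#' \code{min_signal} return \code{NA} components with
#' \code{flag = "no_growth"}.
#'
#' @param curve A preprocessed \code{\link{growth_curve}} (raw curves are
#'   preprocessed with defaults first).
#' @param method \code{"logistic"} (default) or \code{"max-slope"}.
#' @param min_signal Minimum net signal entering the fit (default 0.02).
#' @param ref_level Inoculum reference level in net signal units
#'   (default 1e-3); the lag is measured back to this density.
#' @param upper_frac Upper band limit as a fraction of the plateau, logistic
#'   method (default 0.9).
#' @param fit_window Readings per slope window, max-slope method (default 5).
#' @return An object of class \code{"fitness_components"}: one-row data frame
#'   with \code{well_id}, \code{lag_h}, \code{doubling_h},
#'   \code{efficiency_od}, their log2 transforms and a \code{flag} column
#'   (\code{"ok"} or \code{"no_growth"}).
#' @examples
#' spec <- synthetic_curve_spec(lag = 276.6, doubling_time = 130.2,
#'                              noise_sd = 0)
#' fc <- extract_fitness_components(generate_growth_curve(spec))
#' fc$doubling_h * 60  # close to 130.2 min
#' @export
extract_fitness_components <- function(curve,
                                       method = c("logistic", "max-slope"),
                                       min_signal = 0.02, ref_level = 1e-3,
                                       upper_frac = 0.9, fit_window = 5) {
  stopifnot(inherits(curve, "growth_curve"))
  method <- match.arg(method)
  if (!isTRUE(curve$preprocessed)) curve <- preprocess_curve(curve)
  times <- curve$times
  size <- curve$od
  n <- length(size)
  na_row <- function(flag) {
    structure(data.frame(well_id = curve$well_id, lag_h = NA_real_,
                         doubling_h = NA_real_, efficiency_od = NA_real_,
                         log2_lag = NA_real_, log2_doubling = NA_real_,
                         log2_efficiency = NA_real_, flag = flag,
                         stringsAsFactors = FALSE),
              class = c("fitness_components", "data.frame"))
  }
  if (n < max(fit_window, 4L) || sum(size > min_signal) < 4L)
    return(na_row("no_growth"))

  if (method == "logistic") {
    K <- mean(sort(size, decreasing = TRUE)[seq_len(min(9L, n))])
    band <- size > min_signal & size < upper_frac * K & size < K
    if (sum(band) < 4L) return(na_row("no_growth"))
    tx <- times[band]
    yx <- log(size[band] / (K - size[band]))
    slope <- stats::cov(tx, yx) / stats::var(tx)
    if (!is.finite(slope) || slope <= 0) return(na_row("no_growth"))
    intercept <- mean(yx) - slope * mean(tx)
    y0 <- log(ref_level / (K - ref_level))
    lag_min <- max((y0 - intercept) / slope, 0)
  } else {
    y <- log(size)
    usable <- size > min_signal
    slopes <- tc <- yc <- rep(NA_real_, n)
    for (i in seq_len(n - fit_window + 1L)) {
      idx <- i:(i + fit_window - 1L)
      if (!all(usable[idx])) next
      tx <- times[idx]
      slopes[i] <- stats::cov(tx, y[idx]) / stats::var(tx)
      tc[i] <- mean(tx)
      yc[i] <- mean(y[idx])
    }
    ok <- which(is.finite(slopes))
    if (length(ok) == 0) return(na_row("no_growth"))
    sm <- slopes[ok]
    if (length(sm) >= 5L) sm <- stats::runmed(sm, 5L)
    b <- which.max(sm)
    slope <- sm[b]
    if (!is.finite(slope) || slope <= 0) return(na_row("no_growth"))
    lag_min <- max(tc[ok[b]] - (yc[ok[b]] - log(ref_level)) / slope, 0)
  }
  doubling_min <- log(2) / slope
  efficiency <- size[n] - size[1L]
  safe_log2 <- function(x) ifelse(x > 0, log2(x), NA_real_)
  structure(data.frame(
    well_id = curve$well_id,
    lag_h = lag_min / 60, doubling_h = doubling_min / 60,
    efficiency_od = efficiency,
    log2_lag = safe_log2(lag_min / 60),
    log2_doubling = safe_log2(doubling_min / 60),
    log2_efficiency = safe_log2(efficiency),
    flag = "ok", stringsAsFactors = FALSE),
    class = c("fitness_components", "data.frame"))
}

#' Founder-normalized relative fitness component
#'
#' For doubling time and lag the relative measure is
#' mean(founder log2) - experimental log2; for efficiency it is
#' experimental log2 - mean(founder log2). Positive values therefore always
#' indicate adaptation.
#'
#' @param log2_value Experimental log2 estimate(s).
#' @param founder_log2_values Founder-control log2 estimates (>= 1 value).
#' @param component_kind One of \code{"doubling"}, \code{"lag"},
#'   \code{"efficiency"}.
#' @return Relative value(s).
#' @export
normalize_to_founder <- function(log2_value, founder_log2_values,
                                 component_kind = c("doubling", "lag",
                                                    "efficiency")) {
  component_kind <- match.arg(component_kind)
  founder_log2_values <- founder_log2_values[is.finite(founder_log2_values)]
  if (length(founder_log2_values) == 0)
    stop("no founder reference values")
  ref <- mean(founder_log2_values)
  if (component_kind == "efficiency") log2_value - ref else ref - log2_value
}

#' Read a plate growth-curve table
#'
#' Accepts wide format (first column time in minutes, one column per well) or
#' long format (columns \code{well}, \code{time}, \code{od} in any order);
#' the layout and the delimiter (tab or comma) are auto-detected.
#'
#' @param path Delimited-text file path.
#' @return A list of \code{\link{growth_curve}} objects, named by well.
#' @export
read_plate <- function(path) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  d <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE, check.names = FALSE)
  nms <- tolower(names(d))
  if (all(c("well", "time", "od") %in% nms)) {
    names(d) <- nms
    sp <- split(d, d$well)
    return(lapply(sp, function(x) {
      x <- x[order(x$time), ]
      growth_curve(x$time, x$od, well_id = x$well[1L])
    }))
  }
  times <- d[[1L]]
  wells <- names(d)[-1L]
  out <- lapply(wells, function(w) growth_curve(times, d[[w]], well_id = w))
  names(out) <- wells
  out
}

#' Fit fitness components for every well of a plate
#'
#' Preprocesses and extracts components per well; when founder-control wells
#' are identified, the founder-normalized relative components are added
#' (normalization uses the mean founder log2 value per component).
#'
#' @param curves List of \code{\link{growth_curve}} objects (e.g. from
#'   \code{\link{read_plate}}).
#' @param founder_wells Character vector of founder-control well ids
#'   (optional).
#' @param ... Passed to \code{\link{preprocess_curve}} and
#'   \code{\link{extract_fitness_components}}.
#' @return Data frame, one row per well, with absolute, log2 and (when
#'   founders are given) relative components.
#' @export
fit_growth_curves <- function(curves, founder_wells = NULL, ...) {
  args <- list(...)
  pre_args <- args[names(args) %in% c("smoothing_window", "calibration", "eps")]
  ext_args <- args[names(args) %in% c("method", "fit_window", "min_signal",
                                      "ref_level", "upper_frac")]
  rows <- lapply(curves, function(cu) {
    cu <- do.call(preprocess_curve, c(list(cu), pre_args))
    do.call(extract_fitness_components, c(list(cu), ext_args))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(founder_wells)) {
    if (!any(out$well_id %in% founder_wells))
      stop("no founder-control wells found in the plate")
    fo <- out[out$well_id %in% founder_wells, ]
    out$relative_doubling <- normalize_to_founder(out$log2_doubling,
                                                  fo$log2_doubling, "doubling")
    out$relative_lag <- normalize_to_founder(out$log2_lag, fo$log2_lag, "lag")
    out$relative_efficiency <- normalize_to_founder(out$log2_efficiency,
                                                    fo$log2_efficiency,
                                                    "efficiency")
  }
  out
}
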