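# Traveling-wave drift-time -> collision cross-section calibration:
# mass-dependent drift-time correction, reduced-mass/charge normalisation of
# reference CCS values, and a log-log power-law fit.

#' Correct a drift time for the mass-dependent transit delay
#'
#' `t_d' = t_d - c * sqrt(m/z) / 1000`, the standard enhanced-duty-cycle
#' (EDC) correction of T-wave instruments; mass-independent offsets are
#' absorbed by the power-law intercept.
#'
#' @param t_d Measured drift time (ms), > 0.
#' @param mz Ion m/z (Th).
#' @param c EDC delay coefficient (instrument setting).
#' @return Corrected drift time t_d' (ms).
#' @export
correct_drift_time <- function(t_d, mz, c) {
  if (any(t_d <= 0)) stop("t_d must be > 0")
  td_prime <- t_d - c * sqrt(mz) / 1000
  if (any(td_prime <= 0))
    stop("mass-dependent correction exceeds the drift time")
  td_prime
}

# ion-gas reduced mass (Da)
.reduced_mass <- function(mass, gas_mass) mass * gas_mass / (mass + gas_mass)

#' Fit a drift-time -> CCS calibration
#'
#' Normalises each calibrant's reference CCS for charge and reduced mass,
#' `Omega' = Omega_ref / (z * sqrt(1/mu))`, and fits
#' `ln Omega' = ln A + X ln t_d'` by least squares. The validity range is
#' the span of corrected calibrant drift times; unknowns outside it are
#' rejected by [ccs_from_drift()].
#'
#' @param calibrants data.frame with columns `protein`, `z`, `mass` (Da),
#'   `ccs_ref` (A^2), `t_d` (ms).
#' @param gas_mass Drift-gas mass (Da); default N2.
#' @param c EDC delay coefficient used during acquisition.
#' @return Object of class `ccs_calibration`: `c`, `A`, `X`, `r2`,
#'   `range` (min/max t_d'), `gas_mass`, `n`, `residuals`.
#' @export
fit_calibration <- function(calibrants, gas_mass = 28.0134, c = 1.41) {
  need <- c("protein", "z", "mass", "ccs_ref", "t_d")
  if (!all(need %in% names(calibrants)))
    stop("calibrants must have columns ", paste(need, collapse = ", "))
  if (nrow(calibrants) < 3L) stop("need >= 3 calibrant ions")
  k <- ms_constants()
  mz <- (calibrants$mass + calibrants$z * k$proton) / calibrants$z
  tdp <- correct_drift_time(calibrants$t_d, mz, c)
  if (max(tdp) / min(tdp) <= 1.2)
    stop("corrected drift times span less than a 1.2x range; fit is degenerate")
  mu <- .reduced_mass(calibrants$mass, gas_mass)
  omega_prime <- calibrants$ccs_ref / (calibrants$z * sqrt(1 / mu))
  fit <- stats::lm(log(omega_prime) ~ log(tdp))
  X <- unname(stats::coef(fit)[2])
  A <- exp(unname(stats::coef(fit)[1]))
  if (X <= 0) stop("fitted exponent X <= 0; calibrant table is inconsistent")
  lo <- log(omega_prime)
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((lo - mean(lo))^2)
  structure(list(
    c = c, A = A, X = X, r2 = r2,
    range = range(tdp), gas_mass = gas_mass, n = nrow(calibrants),
    residuals = stats::residuals(fit)
  ), class = "ccs_calibration")
}

#' @export
print.ccs_calibration <- function(x, ...) {
  cat(sprintf("<ccs_calibration> Omega' = %.4g * t_d'^%.4f (r2 = %.5f, n = %d)\n",
              x$A, x$X, x$r2, x$n))
  cat(sprintf("  EDC c = %.3g, gas %.4f Da, valid t_d' in [%.3f, %.3f] ms\n",
              x$c, x$gas_mass, x$range[1], x$range[2]))
  invisible(x)
}

#' CCS of an unknown ion from its drift time
#'
#' `Omega = A * t_d'^X * z * sqrt(1/mu)`, inverting the calibration
#' normalisation. The corrected drift time must fall within the calibration
#' range: all reported CCS values must interpolate, never extrapolate, the
#' calibrant curve.
#'
#' @param cal A [fit_calibration()] result.
#' @param t_d Measured drift time (ms).
#' @param z Charge.
#' @param mass Neutral mass (Da).
#' @return CCS in A^2.
#' @export
ccs_from_drift <- function(cal, t_d, z, mass) {
  stopifnot(inherits(cal, "ccs_calibration"))
  k <- ms_constants()
  mz <- (mass + z * k$proton) / z
  tdp <- correct_drift_time(t_d, mz, cal$c)
  out_of_range <- tdp < cal$range[1] | tdp > cal$range[2]
  if (any(out_of_range))
    stop(sprintf(
      "corrected drift time %.4g ms outside the calibration range [%.4g, %.4g]; CCS values must fall within the calibrant curve",
      tdp[out_of_range][1], cal$range[1], cal$range[2]))
  mu <- .reduced_mass(mass, cal$gas_mass)
  cal$A * tdp^cal$X * z * sqrt(1 / mu)
}

#' Shipped calibrant reference table
#'
#' Denatured ubiquitin (+9..+11), myoglobin (+15..+22) and cytochrome c
#' (+11..+18): the 19 charge states of the three protein standards. The
#' reference CCS values are literature-derived (helium, denatured-protein
#' drift-tube measurements) and intended as replaceable defaults; the `t_d`
#' column is absent and must come from the user's (or the simulator's)
#' acquisition.
#'
#' @return data.frame `(protein, z, mass, ccs_ref)`.
#' @export
default_calibrants <- function() {
  path <- system.file("extdata", "calibrants.csv", package = "oligoIMS")
  if (!nzchar(path)) path <- file.path("inst", "extdata", "calibrants.csv")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Average CCS estimates over wave-height replicate calibrations
#'
#' T-wave data are acquired at several wave heights; each yields its own
#' calibration and CCS estimate for an unknown. Estimates are averaged with
#' the sample standard deviation across replicates.
#'
#' @param cals List of [fit_calibration()] results (one per wave height).
#' @param t_d Vector of drift times, one per calibration/replicate.
#' @param z Charge.
#' @param mass Neutral mass (Da).
#' @return List `mean`, `sd`, `values`.
#' @export
ccs_replicate_average <- function(cals, t_d, z, mass) {
  if (length(cals) != length(t_d)) stop("one drift time per calibration required")
  vals <- mapply(function(cal, td) ccs_from_drift(cal, td, z, mass), cals, t_d)
  list(mean = mean(vals), sd = stats::sd(vals), values = vals)
}
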