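# Individual-level two-compartment PK model with zero-order (infusion) input
# and first-order elimination from the central compartment.

#' Individual two-compartment disposition parameters
#'
#' Macro-constant parameterization of the two-compartment model: clearance
#' `cl` (L/h), central volume `vc` (L), intercompartmental clearance `q` (L/h)
#' and peripheral volume `vp` (L). The derived micro-constants are
#' `k10 = cl/vc`, `k12 = q/vc`, `k21 = q/vp`; the two disposition exponents
#' (eigenvalues of the linear system) must be real, distinct and positive,
#' which holds for all strictly positive macro constants except the
#' measure-zero repeated-root case, which is rejected.
#'
#' @param cl Clearance from the central compartment (L/h).
#' @param vc Central volume of distribution (L).
#' @param q Intercompartmental clearance (L/h).
#' @param vp Peripheral volume of distribution (L).
#'
#' @return An object of class `pk_params`.
#' @examples
#' pk_params(cl = 4.95, vc = 21.59, q = 4.78, vp = 202.15)
#' @export
pk_params <- function(cl, vc, q, vp) {
  vals <- c(cl = cl, vc = vc, q = q, vp = vp)
  ld_assert(all(is.finite(vals)) && all(vals > 0),
            "all of cl, vc, q, vp must be finite and strictly positive",
            "pk_invalid_params")
  k10 <- cl / vc; k12 <- q / vc; k21 <- q / vp
  s <- k10 + k12 + k21
  disc <- s^2 - 4 * k10 * k21
  ld_assert(disc > (1e-10 * s)^2,
            "repeated disposition eigenvalues (degenerate parameter set)",
            "pk_repeated_eigenvalues")
  structure(list(cl = cl, vc = vc, q = q, vp = vp), class = "pk_params")
}

#' @export
print.pk_params <- function(x, ...) {
  cat(sprintf("<pk_params> CL=%.4g L/h, Vc=%.4g L, Q=%.4g L/h, Vp=%.4g L\n",
              x$cl, x$vc, x$q, x$vp))
  invisible(x)
}

# Disposition eigenvalues, exposed for diagnostics and terminal-slope work.
pk_eigenvalues <- function(params) {
  k10 <- params$cl / params$vc
  k12 <- params$q / params$vc
  k21 <- params$q / params$vp
  s <- k10 + k12 + k21
  sq <- sqrt(s^2 - 4 * k10 * k21)
  c(lambda1 = (s + sq) / 2, lambda2 = (s - sq) / 2)
}

#' Dose events (zero-order infusions)
#'
#' One row per administration. `amount` is the administered activity per
#' cycle (GBq by convention), infused at constant rate over `duration` hours
#' starting at `start_time` hours. Overlapping infusions are allowed (rates
#' add under linearity).
#'
#' @param amount Administered amounts (>= 0).
#' @param start_time Infusion start times in hours (>= 0).
#' @param duration Infusion durations in hours (> 0; zero-order input requires
#'   a finite rate).
#'
#' @return A tibble of class `dose_regimen` with columns `amount`,
#'   `start_time`, `duration`.
#' @export
dose_regimen <- function(amount, start_time = 0, duration = 0.5) {
  n <- max(length(amount), length(start_time), length(duration))
  amount <- rep_len(amount, n)
  start_time <- rep_len(start_time, n)
  duration <- rep_len(duration, n)
  ld_assert(all(is.finite(amount)) && all(amount >= 0),
            "dose amount must be finite and >= 0", "pk_invalid_dose")
  ld_assert(all(is.finite(start_time)) && all(start_time >= 0),
            "dose start_time must be finite and >= 0", "pk_invalid_dose")
  ld_assert(all(is.finite(duration)) && all(duration > 0),
            "infusion duration must be finite and > 0", "pk_invalid_dose")
  out <- tibble::tibble(amount = amount, start_time = start_time,
                        duration = duration)
  class(out) <- c("dose_regimen", class(out))
  out
}

#' Standard multi-cycle regimen
#'
#' The approved adult regimen is 7.4 GBq per cycle every 8 weeks (1,344 h)
#' for 4 cycles, infused over 30 minutes.
#'
#' @param amount Activity per cycle (GBq).
#' @param n_cycles Number of cycles.
#' @param interval Inter-cycle interval (h).
#' @param duration Infusion duration (h).
#' @export
cycle_regimen <- function(amount = 7.4, n_cycles = 4, interval = 1344,
                          duration = 0.5) {
  dose_regimen(amount = rep(amount, n_cycles),
               start_time = interval * (seq_len(n_cycles) - 1),
               duration = duration)
}

empty_regimen <- function() {
  out <- tibble::tibble(amount = numeric(), start_time = numeric(),
                        duration = numeric())
  class(out) <- c("dose_regimen", class(out))
  out
}

#' Predict the concentration-time profile
#'
#' Closed-form biexponential solution of the two-compartment model with
#' zero-order input, superposed linearly over all dose events. During an
#' infusion the concentration is monotone nondecreasing; after the last
#' infusion ends the profile is a sum of two decaying exponentials.
#'
#' @param params A [pk_params()] object.
#' @param doses A [dose_regimen()] (may have zero rows: all-zero profile).
#' @param times Sampling times in hours, sorted nondecreasing.
#' @param amount_scale Multiplicative conversion from the dose unit (GBq) to
#'   the mass-equivalent unit the concentrations are expressed in. Kinetics
#'   are linear, so this is a single scalar (default 1).
#'
#' @return A tibble of class `conc_profile` with columns `time` and `conc`
#'   (amount/L).
#' @examples
#' p <- pk_params(4.95, 21.59, 4.78, 202.15)
#' predict_concentrations(p, cycle_regimen(n_cycles = 1), times = c(0, 1, 24))
#' @export
predict_concentrations <- function(params, doses, times, amount_scale = 1) {
  stopifnot(inherits(params, "pk_params"))
  if (!inherits(doses, "dose_regimen")) {
    ld_abort("`doses` must be a dose_regimen", "pk_invalid_dose")
  }
  ld_assert(is.numeric(times) && all(is.finite(times)) && all(times >= 0) &&
              !is.unsorted(times),
            "`times` must be finite, nonnegative and sorted", "pk_invalid_times")
  ld_assert(is.numeric(amount_scale) && length(amount_scale) == 1L &&
              is.finite(amount_scale) && amount_scale > 0,
            "`amount_scale` must be a positive scalar", "pk_invalid_dose")
  conc <- cpp_conc_2cmt(params$cl, params$vc, params$q, params$vp,
                        doses$amount * amount_scale, doses$start_time,
                        doses$duration, times)
  # guard against -0 / tiny negative round-off far in the tail
  conc[conc < 0 & conc > -1e-12] <- 0
  out <- tibble::tibble(time = times, conc = conc)
  class(out) <- c("conc_profile", class(out))
  out
}

#' Exposure metrics from a predicted profile
#'
#' `auc_last` is the area under the predicted curve over the supplied grid,
#' by default with the standard linear-up/log-down trapezoid (logarithmic
#' interpolation on declining segments, which is near-exact on exponential
#' decay and keeps sparse clinical schedules accurate); `auc_inf` extrapolates
#' beyond the last point as `C_last / lambda_z`, with the terminal slope
#' `lambda_z` estimated by log-linear regression on the tail of the grid
#' (points after the last infusion ends). `cmax` and `tmax` are read off the
#' grid. For a dense grid extending to effective infinity, `auc_inf`
#' approaches `dose / cl` (linear kinetics).
#'
#' @inheritParams predict_concentrations
#' @param n_tail Number of terminal grid points used for the log-linear
#'   terminal-slope fit.
#' @param auc_method `"lin_log"` (linear-up/log-down, default) or `"linear"`
#'   (plain trapezoid).
#' @return A list of class `exposure_metrics`: `auc_last`, `auc_inf`, `cmax`,
#'   `tmax`, `lambda_z`.
#' @export
exposure_metrics <- function(params, doses, times, amount_scale = 1,
                             n_tail = 5L, auc_method = c("lin_log", "linear")) {
  auc_method <- match.arg(auc_method)
  ld_assert(inherits(doses, "dose_regimen") && nrow(doses) >= 1L,
            "at least one dose event is required", "pk_invalid_dose")
  ld_assert(length(times) >= 3L, "time grid too short", "pk_invalid_times")
  prof <- predict_concentrations(params, doses, times, amount_scale)
  auc_last <- if (auc_method == "linear") {
    trapz(prof$time, prof$conc)
  } else {
    auc_lin_log(prof$time, prof$conc)
  }
  imax <- which.max(prof$conc)
  cmax <- prof$conc[imax]
  tmax <- prof$time[imax]

  end_infusion <- max(doses$start_time + doses$duration)
  tail_idx <- which(prof$time > end_infusion & prof$conc > 0)
  tail_idx <- tail(tail_idx, n_tail)
  ld_assert(length(tail_idx) >= 2L,
            "not enough positive post-infusion points to estimate the terminal slope",
            "pk_flat_terminal")
  tt <- prof$time[tail_idx]
  lc <- log(prof$conc[tail_idx])
  slope <- sum((tt - mean(tt)) * (lc - mean(lc))) / sum((tt - mean(tt))^2)
  ld_assert(is.finite(slope) && slope < 0,
            "flat or rising terminal phase: lambda_z not estimable",
            "pk_flat_terminal")
  lambda_z <- -slope
  c_last <- prof$conc[nrow(prof)]
  structure(list(auc_last = auc_last,
                 auc_inf = auc_last + c_last / lambda_z,
                 cmax = cmax, tmax = tmax, lambda_z = lambda_z),
            class = "exposure_metrics")
}

#' @export
print.exposure_metrics <- function(x, ...) {
  cat(sprintf("<exposure_metrics> AUClast=%.4g, AUCinf=%.4g amount*h/L; Cmax=%.4g at t=%.3g h\n",
              x$auc_last, x$auc_inf, x$cmax, x$tmax))
  invisible(x)
}
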