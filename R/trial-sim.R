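# Monte Carlo engines: activity x CrCL scenario grid, virtual-trial
# sample-size simulation, cohort exceedance summaries, flat-dosing check.

#' Scenario grid of activity and CrCL values
#'
#' Default 8 activities (1-8 GBq) by 30 CrCL values (35-180 mL/min in steps
#' of 5): 240 scenarios, each simulated with 500 virtual subjects over 4
#' treatment cycles.
#'
#' @param activities Per-cycle activities (GBq).
#' @param crcl_values CrCL grid (mL/min).
#' @param n_subjects_per_cell Virtual subjects per cell.
#' @param n_cycles Treatment cycles.
#' @param n_scenarios Declared scenario count; must equal
#'   `length(activities) * length(crcl_values)`.
#' @export
scenario_grid <- function(activities = 1:8, crcl_values = seq(35, 180, by = 5),
                          n_subjects_per_cell = 500, n_cycles = 4,
                          n_scenarios = length(activities) * length(crcl_values)) {
  ld_assert(all(activities > 0) && all(crcl_values > 0) &&
              n_subjects_per_cell > 0 && n_cycles > 0,
            "all grid values must be positive", "trial_invalid_grid")
  ld_assert(length(activities) * length(crcl_values) == n_scenarios,
            "scenario count does not match activities x crcl_values",
            "trial_invalid_grid")
  structure(list(activities = activities, crcl_values = crcl_values,
                 n_subjects_per_cell = n_subjects_per_cell,
                 n_cycles = n_cycles),
            class = "scenario_grid")
}

#' Simulate the scenario grid
#'
#' For every activity x CrCL cell, simulates `n_subjects_per_cell` virtual
#' subjects at fixed covariates: the cumulative dose over `n_cycles` cycles
#' receives one proportional residual draw per subject (negative factors
#' resampled). Reports the cell median cumulative dose and the fraction of
#' subjects exceeding each organ threshold. With `noise = FALSE` the cell
#' median equals the deterministic [cumulative_dose()] and the exceedance is
#' a 0/1 step function of the threshold.
#'
#' @param p A [dosimetry_params()] object.
#' @param grid A [scenario_grid()].
#' @param seed Master seed.
#' @param thresholds Named list of organ thresholds in Gy
#'   (default `list(kidney = c(23, 29), bone_marrow = 2)`).
#' @param adolescent Apply the study shift on the kidney CrCL exponent.
#' @param noise Include residual variability (default `TRUE`).
#' @param residual Residual model (see [generate_dosimetry_dataset()]).
#' @return A tibble: `activity`, `crcl`, `organ`, `median_dose`, `threshold`,
#'   `p_exceed`.
#' @export
simulate_scenario_grid <- function(p, grid, seed = NULL,
                                   thresholds = list(kidney = c(23, 29),
                                                     bone_marrow = 2),
                                   adolescent = FALSE, noise = TRUE,
                                   residual = c("proportional", "lognormal")) {
  stopifnot(inherits(p, "dosimetry_params"), inherits(grid, "scenario_grid"))
  residual <- match.arg(residual)
  if (!is.null(seed)) set.seed(seed)
  cells <- expand.grid(activity = grid$activities, crcl = grid$crcl_values,
                       KEEP.OUT.ATTRS = FALSE)
  n <- grid$n_subjects_per_cell
  out <- vector("list", nrow(cells) * 2L)
  k <- 0L
  for (i in seq_len(nrow(cells))) {
    a <- cells$activity[i]; cc <- cells$crcl[i]
    for (org in c("kidney", "bone_marrow")) {
      cum <- cumulative_dose(p, rep(a, grid$n_cycles), cc, organ = org,
                             adolescent = adolescent,
                             max_cycles = grid$n_cycles)
      doses <- if (noise) {
        b <- if (org == "kidney") p$b1 else p$b2
        cum * residual_factors(n, b, residual)
      } else {
        rep(cum, n)
      }
      thr <- thresholds[[org]]
      k <- k + 1L
      out[[k]] <- tibble::tibble(
        activity = a, crcl = cc, organ = org,
        median_dose = median(doses),
        threshold = thr,
        p_exceed = vapply(thr, function(t) mean(doses > t), numeric(1)))
    }
  }
  dplyr::bind_rows(out[seq_len(k)])
}

#' Truncated CrCL distribution for virtual subjects
#'
#' Truncated normal sampled by inverse CDF. The default emulates the
#' adolescent cohort (median 122.1 mL/min, range 86-160) with the bounds at
#' about +/- 2.5 SD; externally published distribution parameters can be
#' plugged in directly.
#'
#' @param center Location (mL/min).
#' @param spread SD before truncation (mL/min).
#' @param lower,upper Hard truncation bounds (mL/min).
#' @export
crcl_distribution <- function(center = 122, spread = (160 - 86) / 5,
                              lower = 86, upper = 160) {
  ld_assert(lower < upper && spread > 0 && lower > 0,
            "need lower < upper, spread > 0, positive bounds",
            "trial_invalid_distribution")
  structure(list(family = "truncated-normal", center = center,
                 spread = spread, lower = lower, upper = upper),
            class = "crcl_distribution")
}

sample_crcl <- function(dist, n) {
  rtruncnorm(n, dist$center, dist$spread, dist$lower, dist$upper)
}

#' Virtual-trial design
#'
#' @param n_per_trial Subjects per trial (the published simulation used 5 and
#'   10).
#' @param n_trials Number of trials (default 500).
#' @param activity_per_cycle Activity per cycle (GBq, default 7.4).
#' @param n_cycles Treatment cycles (default 4).
#' @export
trial_design <- function(n_per_trial, n_trials = 500, activity_per_cycle = 7.4,
                         n_cycles = 4) {
  ld_assert(n_per_trial > 0 && n_trials > 0 && activity_per_cycle > 0 &&
              n_cycles > 0, "design values must be positive",
            "trial_invalid_design")
  structure(list(n_per_trial = as.integer(n_per_trial),
                 n_trials = as.integer(n_trials),
                 total_pool = as.integer(n_per_trial) * as.integer(n_trials),
                 activity_per_cycle = activity_per_cycle,
                 n_cycles = as.integer(n_cycles)),
            class = "trial_design")
}

#' Simulate virtual trials for sample-size evaluation
#'
#' Samples `total_pool = n_per_trial * n_trials` CrCL values from `dist`,
#' partitions them into sequential trials (equivalent in distribution to
#' independent trials), simulates each subject's cumulative organ dose over
#' `n_cycles` cycles with one proportional residual draw per subject, and
#' computes each trial's median dose (even `n`: mean of the two middle order
#' statistics). Returns the fraction of trials whose median exceeds each
#' threshold together with the trial-median distribution and the distribution
#' of per-trial subject-level exceedance fractions.
#'
#' @param p A [dosimetry_params()] object.
#' @param dist A [crcl_distribution()].
#' @param design A [trial_design()].
#' @param thresholds Thresholds in Gy (default kidney 23 and 29).
#' @param organ Organ to simulate (default `"kidney"`).
#' @param adolescent Apply the kidney study shift (default `FALSE`: the
#'   trial-size simulation used the adult model).
#' @param seed Master seed.
#' @param residual Residual model.
#' @return An object of class `exceedance_result` with elements
#'   `trial_medians` (tibble), `prob` (tibble: `threshold`,
#'   `p_exceed_median`), `subject_exceedance` (tibble: per-threshold median
#'   and 5th/95th percentiles across trials of the within-trial exceedance
#'   fraction) and the design.
#' @export
simulate_virtual_trials <- function(p, dist, design, thresholds = c(23, 29),
                                    organ = c("kidney", "bone_marrow"),
                                    adolescent = FALSE, seed = NULL,
                                    residual = c("proportional", "lognormal")) {
  stopifnot(inherits(p, "dosimetry_params"), inherits(dist, "crcl_distribution"),
            inherits(design, "trial_design"))
  organ <- match.arg(organ)
  residual <- match.arg(residual)
  if (!is.null(seed)) set.seed(seed)

  crcl <- sample_crcl(dist, design$total_pool)
  cum <- cumulative_dose(p, rep(design$activity_per_cycle, design$n_cycles),
                         crcl, organ = organ, adolescent = adolescent,
                         max_cycles = design$n_cycles)
  b <- if (organ == "kidney") p$b1 else p$b2
  doses <- cum * residual_factors(design$total_pool, b, residual)
  trial <- rep(seq_len(design$n_trials), each = design$n_per_trial)
  med <- tapply(doses, trial, median)

  prob <- tibble::tibble(
    threshold = thresholds,
    p_exceed_median = vapply(thresholds, function(t) mean(med > t), numeric(1)))
  subj_exc <- dplyr::bind_rows(lapply(thresholds, function(t) {
    frac <- tapply(doses > t, trial, mean)
    tibble::tibble(threshold = t,
                   median = median(frac),
                   lo = quantile(frac, 0.05, names = FALSE),
                   hi = quantile(frac, 0.95, names = FALSE))
  }))
  structure(list(trial_medians = tibble::tibble(trial = seq_len(design$n_trials),
                                                median_dose = as.numeric(med)),
                 prob = prob, subject_exceedance = subj_exc,
                 organ = organ, design = design),
            class = "exceedance_result")
}

#' @export
print.exceedance_result <- function(x, ...) {
  cat(sprintf("<exceedance_result> %s, %d trials of n=%d\n", x$organ,
              x$design$n_trials, x$design$n_per_trial))
  print(as.data.frame(x$prob), row.names = FALSE)
  invisible(x)
}

#' Cohort threshold-exceedance summaries
#'
#' For each population in `cohort` and each simulated trial (default 500
#' trials of 500 virtual subjects bootstrapped from the cohort covariate
#' table), computes the fraction of subjects whose cumulative dose after
#' `n_cycles` cycles exceeds each organ threshold, and summarizes the
#' trial-level fractions by their median and 5th/95th percentiles.
#'
#' @param p A [dosimetry_params()] object.
#' @param cohort Covariate tibble with columns `population`
#'   (`"adult"` / `"adolescent"`) and `crcl`.
#' @param design A [trial_design()] (default 500 trials of 500 subjects).
#' @param thresholds Named list of organ thresholds
#'   (default `list(kidney = c(23, 29), bone_marrow = 2)`).
#' @param seed Master seed.
#' @param residual Residual model.
#' @return A tibble: `population`, `organ`, `threshold`, `p_median`, `p_lo`,
#'   `p_hi`.
#' @export
exceedance_summary <- function(p, cohort, design = trial_design(500, 500),
                               thresholds = list(kidney = c(23, 29),
                                                 bone_marrow = 2),
                               seed = NULL,
                               residual = c("proportional", "lognormal")) {
  stopifnot(inherits(p, "dosimetry_params"), inherits(design, "trial_design"))
  residual <- match.arg(residual)
  cohort <- tibble::as_tibble(cohort)
  ld_assert(all(c("population", "crcl") %in% names(cohort)),
            "cohort needs columns population and crcl", "trial_invalid_cohort")
  if (!is.null(seed)) set.seed(seed)

  out <- list()
  for (pop in unique(cohort$population)) {
    crcl_pool <- cohort$crcl[cohort$population == pop]
    ntot <- design$total_pool
    crcl <- sample(crcl_pool, ntot, replace = TRUE)
    trial <- rep(seq_len(design$n_trials), each = design$n_per_trial)
    for (org in names(thresholds)) {
      cum <- cumulative_dose(p, rep(design$activity_per_cycle, design$n_cycles),
                             crcl, organ = org,
                             adolescent = pop == "adolescent",
                             max_cycles = design$n_cycles)
      b <- if (org == "kidney") p$b1 else p$b2
      doses <- cum * residual_factors(ntot, b, residual)
      for (t in thresholds[[org]]) {
        frac <- tapply(doses > t, trial, mean)
        out[[length(out) + 1L]] <- tibble::tibble(
          population = pop, organ = org, threshold = t,
          p_median = median(frac),
          p_lo = quantile(frac, 0.05, names = FALSE),
          p_hi = quantile(frac, 0.95, names = FALSE))
      }
    }
  }
  dplyr::bind_rows(out)
}

#' Flat-dosing stratified dose summary
#'
#' Descriptive check that cumulative organ doses are comparable across body
#' weight groups (and populations) under flat dosing: group medians and
#' ranges per weight bin.
#'
#' @param doses Tibble with columns `dose_gy`, `weight` and optionally
#'   `population` and `organ`.
#' @param weight_breaks Bin breaks in kg, or an integer number of quantile
#'   bins (default 4). A single bin reproduces the unstratified summary.
#' @return A tibble of per-stratum summaries: `n`, `median_dose`, `min_dose`,
#'   `max_dose`.
#' @export
flat_dose_summary <- function(doses, weight_breaks = 4) {
  doses <- tibble::as_tibble(doses)
  ld_assert(all(c("dose_gy", "weight") %in% names(doses)),
            "doses needs columns dose_gy and weight", "trial_invalid_cohort")
  if (length(weight_breaks) == 1L) {
    if (weight_breaks == 1) {
      doses$weight_bin <- "all"
    } else {
      bid <- quantile_bins(doses$weight, as.integer(weight_breaks))
      lab <- tapply(doses$weight, bid, function(w) sprintf("%.3g-%.3g kg",
                                                           min(w), max(w)))
      doses$weight_bin <- lab[bid]
    }
  } else {
    doses$weight_bin <- as.character(cut(doses$weight, weight_breaks,
                                         include.lowest = TRUE))
    if (anyNA(doses$weight_bin)) {
      message("flat_dose_summary: records outside the weight breaks dropped")
      doses <- doses[!is.na(doses$weight_bin), ]
    }
  }
  grp <- c("weight_bin", intersect(c("population", "organ"), names(doses)))
  out <- dplyr::summarise(dplyr::group_by(doses, dplyr::across(dplyr::all_of(grp))),
                          n = dplyr::n(),
                          median_dose = median(.data$dose_gy),
                          min_dose = min(.data$dose_gy),
                          max_dose = max(.data$dose_gy),
                          .groups = "drop")
  empty <- out$n == 0
  if (any(empty)) message("flat_dose_summary: empty stratum")
  out
}
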