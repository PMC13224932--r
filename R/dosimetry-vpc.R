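# Visual predictive check for the dosimetry models, binned against each
# covariate (CrCL and activity).

#' Dosimetry VPC summaries
#'
#' Simulates `n_sim` replicates of the observed design under `p` (proportional
#' residual, negative draws resampled) and summarizes, per covariate bin, the
#' 5th/50th/95th percentiles of the simulated bin medians next to the observed
#' bin median — once binned against CrCL and once against activity, per organ.
#' As the residual SD tends to zero the bands collapse onto the model
#' prediction curve.
#'
#' @param p A [dosimetry_params()] object.
#' @param records Dosimetry records (see [fit_dosimetry()]).
#' @param n_sim Number of simulation replicates (default 500).
#' @param bins Number of quantile bins per covariate.
#' @param seed Master seed.
#' @param residual Residual model for the simulation (see
#'   [generate_dosimetry_dataset()]).
#' @return A tibble: `organ`, `covariate`, `bin`, covariate bin median `x`,
#'   `n_obs`, `obs_median`, `sim_lo`, `sim_median`, `sim_hi`, `inside`.
#' @export
dosimetry_vpc <- function(p, records, n_sim = 500, bins = 6, seed = NULL,
                          residual = c("proportional", "lognormal")) {
  stopifnot(inherits(p, "dosimetry_params"))
  residual <- match.arg(residual)
  records <- tibble::as_tibble(records)
  if (!is.null(seed)) set.seed(seed)

  out <- list()
  for (org in c("kidney", "bone_marrow")) {
    rec <- records[records$organ == org, ]
    if (nrow(rec) == 0L) next
    adol <- rec$study == "adolescent"
    pred <- if (org == "kidney") {
      predict_kidney_dose(p, rec$activity_gbq, rec$crcl, adol)
    } else {
      predict_marrow_dose(p, rec$activity_gbq, rec$crcl)
    }
    b <- if (org == "kidney") p$b1 else p$b2
    # n_sim replicate datasets of the same design
    sims <- matrix(residual_factors(nrow(rec) * n_sim, b, residual),
                   nrow = nrow(rec)) * pred

    for (covn in c("crcl", "activity")) {
      x <- if (covn == "crcl") rec$crcl else rec$activity_gbq
      bin_id <- if (length(unique(x)) <= bins) {
        match(x, sort(unique(x)))
      } else {
        quantile_bins(x, bins, min_per_bin = 2L)
      }
      nb <- max(bin_id)
      obs_med <- tapply(rec$dose_gy, bin_id, median)
      sim_med <- apply(sims, 2, function(col) tapply(col, bin_id, median))
      sim_med <- matrix(sim_med, nrow = nb)
      lo <- apply(sim_med, 1, quantile, probs = 0.05)
      hi <- apply(sim_med, 1, quantile, probs = 0.95)
      md <- apply(sim_med, 1, median)
      out[[paste(org, covn)]] <- tibble::tibble(
        organ = org, covariate = covn, bin = seq_len(nb),
        x = as.numeric(tapply(x, bin_id, median)),
        n_obs = as.integer(tabulate(bin_id, nb)),
        obs_median = as.numeric(obs_med),
        sim_lo = lo, sim_median = md, sim_hi = hi,
        inside = obs_med >= lo & obs_med <= hi)
    }
  }
  dplyr::bind_rows(out)
}
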