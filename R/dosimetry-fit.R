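# Maximum-likelihood fitting of the power-law dosimetry models.
#
# Residual model: observed = predicted * (1 + b * eps), eps ~ N(0,1), with the
# factor truncated at zero (an absorbed dose cannot be negative), i.e.
# observed | covariates ~ N(pred, (b * pred)^2) renormalized to [0, Inf).
# The truncation normalizer Phi(1/b) is the same for every record. Kidney and
# bone marrow are fitted independently, each organ with its own proportional
# SD.

organ_nll <- function(y, act, crcl, adol, ref_a, ref_c, study_effect) {
  lr_a <- log(act / ref_a)
  lr_c <- log(crcl / ref_c)
  n <- length(y)
  function(par) {
    # par: log baseline, activity exponent, crcl exponent, [study shift], log b
    base <- exp(par[1])
    expo_c <- par[3] + if (study_effect) par[4] * adol else 0
    b <- exp(par[length(par)])
    pred <- base * exp(par[2] * lr_a + expo_c * lr_c)
    s <- b * pred
    0.5 * n * log(2 * pi) + sum(log(s)) + sum((y - pred)^2 / (2 * s^2)) +
      n * pnorm(1 / b, log.p = TRUE)
  }
}

fit_one_organ <- function(rec, study_effect, ref_a, ref_c) {
  y <- rec$dose_gy
  act <- rec$activity_gbq
  crcl <- rec$crcl
  adol <- as.numeric(rec$study == "adolescent")
  n <- length(y)

  # log-log least squares starting values
  X <- cbind(1, log(act / ref_a), log(crcl / ref_c))
  if (study_effect) X <- cbind(X, adol * log(crcl / ref_c))
  beta0 <- tryCatch(qr.solve(X, log(y)), error = function(e) {
    c(mean(log(y)), rep(0, ncol(X) - 1))
  })
  res0 <- log(y) - X %*% beta0
  par0 <- c(beta0, log(max(sd(as.numeric(res0)), 0.05)))

  nll <- organ_nll(y, act, crcl, adol, ref_a, ref_c, study_effect)
  k <- length(par0)
  lower <- c(par0[1] - 8, rep(-10, k - 2), log(1e-4))
  upper <- c(par0[1] + 8, rep(10, k - 2), log(10))
  fit <- nlminb(par0, nll, lower = lower, upper = upper,
                control = list(iter.max = 500))

  est <- c(exp(fit$par[1]), fit$par[2], fit$par[3],
           if (study_effect) fit$par[4],
           exp(fit$par[length(fit$par)]))
  nll_nat <- function(v) {
    p <- c(log(v[1]), v[2], v[3], if (study_effect) v[4], log(v[length(v)]))
    nll(p)
  }
  H <- suppressWarnings(try(num_hessian(nll_nat, est), silent = TRUE))
  se <- if (inherits(H, "try-error") || anyNA(H)) rep(NA_real_, length(est))
        else se_from_hessian(H)
  list(estimate = est, rse = 100 * se / abs(est),
       neg2ll = 2 * fit$objective, bic = 2 * fit$objective + k * log(n),
       converged = fit$convergence == 0, n = n, k = k)
}

#' Fit the power-law dosimetry models
#'
#' Fits the kidney and bone-marrow power-law models independently by maximum
#' likelihood under proportional Gaussian residual error. With
#' `include_study_effect = TRUE` the kidney CrCL exponent gains an additive
#' shift for adolescent-study records. %RSE from the inverse observed Fisher
#' information; BIC = -2LL + k log(n) per organ.
#'
#' @param records Tibble of dosimetry records: columns `id`, `organ`
#'   (`"kidney"` / `"bone_marrow"`), `dose_gy`, `activity_gbq`, `crcl`,
#'   `study` (`"adult"` / `"adolescent"`). One record per subject per organ.
#' @param include_study_effect Estimate the adolescent shift on the kidney
#'   CrCL exponent (requires both study labels present).
#' @param ref_activity,ref_crcl Reference normalizers.
#'
#' @return An object of class `dosimetry_fit`: `params` (a
#'   [dosimetry_params()] with the estimates), `rse_percent`, `neg2_loglik`
#'   and `bic` (per organ and total), `converged`, `n`.
#' @export
fit_dosimetry <- function(records, include_study_effect = FALSE,
                          ref_activity = 7.4, ref_crcl = 99) {
  records <- tibble::as_tibble(records)
  need <- c("id", "organ", "dose_gy", "activity_gbq", "crcl", "study")
  ld_assert(all(need %in% names(records)),
            paste("records must have columns:", paste(need, collapse = ", ")),
            "dosimetry_invalid_records")
  ld_assert(all(records$organ %in% c("kidney", "bone_marrow")),
            "organ must be 'kidney' or 'bone_marrow'", "dosimetry_invalid_records")
  ld_assert(all(records$dose_gy > 0) && all(records$activity_gbq > 0) &&
              all(records$crcl > 0),
            "doses, activities and CrCL must be > 0", "dosimetry_invalid_records")
  if (include_study_effect) {
    ld_assert(all(c("adult", "adolescent") %in% records$study),
              "study-effect fit requires both study labels present",
              "dosimetry_invalid_records")
  }

  fits <- list()
  for (org in c("kidney", "bone_marrow")) {
    rec <- records[records$organ == org, ]
    ld_assert(nrow(rec) >= 10L,
              sprintf("need >= 10 records for organ '%s'", org),
              "dosimetry_too_few_records")
    ld_assert(length(unique(rec$activity_gbq)) > 1L || length(unique(rec$crcl)) > 1L,
              "both covariates constant: model not identifiable",
              "dosimetry_invalid_records")
    fits[[org]] <- fit_one_organ(rec, include_study_effect && org == "kidney",
                                 ref_activity, ref_crcl)
  }
  kf <- fits$kidney; mf <- fits$bone_marrow
  params <- dosimetry_params(
    a_pop = kf$estimate[1], b_pop = kf$estimate[2], c_pop = kf$estimate[3],
    beta_study = if (include_study_effect) kf$estimate[4] else 0,
    d_pop = mf$estimate[1], e_pop = mf$estimate[2], f_pop = mf$estimate[3],
    b1 = kf$estimate[length(kf$estimate)], b2 = mf$estimate[length(mf$estimate)],
    ref_activity = ref_activity, ref_crcl = ref_crcl)
  kn <- c("a_pop", "b_pop", "c_pop", if (include_study_effect) "beta_study", "b1")
  mn <- c("d_pop", "e_pop", "f_pop", "b2")
  rse <- c(setNames(kf$rse, kn), setNames(mf$rse, mn))
  structure(list(params = params, rse_percent = rse,
                 neg2_loglik = c(kidney = kf$neg2ll, bone_marrow = mf$neg2ll,
                                 total = kf$neg2ll + mf$neg2ll),
                 bic = c(kidney = kf$bic, bone_marrow = mf$bic,
                         total = kf$bic + mf$bic),
                 converged = kf$converged && mf$converged,
                 n = c(kidney = kf$n, bone_marrow = mf$n),
                 include_study_effect = include_study_effect,
                 residual_model = "proportional"),
            class = "dosimetry_fit")
}

#' @export
print.dosimetry_fit <- function(x, ...) {
  cat(sprintf("<dosimetry_fit> %s; -2LL total = %.2f, BIC total = %.2f%s\n",
              if (x$converged) "converged" else "NOT converged",
              x$neg2_loglik["total"], x$bic["total"],
              if (x$include_study_effect) " (with study effect)" else ""))
  print(x$params)
  if (!is.null(x$rse_percent)) {
    cat("%RSE:\n"); print(round(x$rse_percent, 2))
  }
  invisible(x)
}
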