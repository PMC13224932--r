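# Population PK layer: fixed effects, log-normal inter-individual variability
# on CL and Vc, additive residual error.

#' Population PK model
#'
#' Fixed effects `theta` (typical CL, Vc, Q, Vp) with log-normal
#' inter-individual variability (IIV) on CL and optionally Vc:
#' `CL_i = CL * exp(eta_cl)`, `Vc_i = Vc * exp(eta_vc)`, where
#' `(eta_cl, eta_vc)` is bivariate normal with SDs `(omega_cl, omega_vc)` and
#' correlation `rho`. Residual error is additive Gaussian with SD `sigma_add`
#' on the concentration scale (the constant-residual convention); an additive
#' log-scale alternative is available at simulation time.
#'
#' @param theta A [pk_params()] object of population typical values.
#' @param omega_cl SD of the log-scale random effect on CL (>= 0).
#' @param omega_vc SD of the log-scale random effect on Vc (>= 0); `0` removes
#'   IIV on Vc (the adolescent model structure).
#' @param rho Correlation between the CL and Vc random effects; ignored when
#'   `omega_vc = 0`.
#' @param sigma_add Additive residual SD (> 0), concentration units.
#'
#' @return An object of class `poppk_model`.
#' @seealso [poppk_model_adult()], [poppk_model_adolescent()]
#' @export
poppk_model <- function(theta, omega_cl, omega_vc = 0, rho = 0, sigma_add) {
  stopifnot(inherits(theta, "pk_params"))
  ld_assert(omega_cl >= 0 && omega_vc >= 0, "omega SDs must be >= 0",
            "poppk_invalid_model")
  ld_assert(abs(rho) <= 1, "|rho| must be <= 1", "poppk_invalid_model")
  ld_assert(is.finite(sigma_add) && sigma_add > 0, "sigma_add must be > 0",
            "poppk_invalid_model")
  if (omega_vc == 0) rho <- 0
  structure(list(theta = theta, omega_cl = omega_cl, omega_vc = omega_vc,
                 rho = rho, sigma_add = sigma_add),
            class = "poppk_model")
}

#' Published adult population PK model
#'
#' Typical values CL 4.95 L/h, Vc 21.59 L, Q 4.78 L/h, Vp 202.15 L; IIV SDs
#' 0.41 (CL) and 0.52 (Vc) with correlation 0.70; additive residual SD 0.40.
#' @export
poppk_model_adult <- function() {
  poppk_model(pk_params(cl = 4.95, vc = 21.59, q = 4.78, vp = 202.15),
              omega_cl = 0.41, omega_vc = 0.52, rho = 0.70, sigma_add = 0.40)
}

#' Published adolescent population PK model
#'
#' Typical values CL 5.92 L/h, Vc 17.86 L, Q 2.63 L/h, Vp 99.42 L; IIV on CL
#' only (SD 0.14); additive residual SD 0.25.
#' @export
poppk_model_adolescent <- function() {
  poppk_model(pk_params(cl = 5.92, vc = 17.86, q = 2.63, vp = 99.42),
              omega_cl = 0.14, omega_vc = 0, rho = 0, sigma_add = 0.25)
}

#' @export
print.poppk_model <- function(x, ...) {
  cat(sprintf(paste0("<poppk_model> CL=%.4g, Vc=%.4g, Q=%.4g, Vp=%.4g | ",
                     "omega_cl=%.3g, omega_vc=%.3g, rho=%.3g | sigma=%.3g\n"),
              x$theta$cl, x$theta$vc, x$theta$q, x$theta$vp,
              x$omega_cl, x$omega_vc, x$rho, x$sigma_add))
  invisible(x)
}

# Draw (eta_cl, eta_vc) for n subjects.
draw_etas <- function(model, n) {
  z1 <- rnorm(n)
  z2 <- rnorm(n)
  eta_cl <- model$omega_cl * z1
  eta_vc <- model$omega_vc * (model$rho * z1 + sqrt(1 - model$rho^2) * z2)
  cbind(eta_cl = eta_cl, eta_vc = eta_vc)
}

#' Simulate a population PK dataset
#'
#' Draws per-subject random effects, computes each subject's closed-form
#' concentration profile at the skeleton's observation times, and adds
#' residual noise. With the default additive residual model, negative
#' observations are resampled so simulated concentrations are nonnegative.
#'
#' @param model A [poppk_model()].
#' @param skeleton A [pk_dataset()] whose observation rows define the design
#'   (any `conc` values are ignored).
#' @param seed Integer master seed; the same seed reproduces the dataset
#'   bit for bit.
#' @param residual `"additive"` (default) or `"log_additive"` (additive
#'   Gaussian on the log-concentration scale, always positive).
#'
#' @return A `pk_dataset` with simulated `conc`; the generating random effects
#'   are attached as `attr(, "etas")` and the model as `attr(, "model")`.
#' @export
simulate_population <- function(model, skeleton, seed = NULL,
                                residual = c("additive", "log_additive")) {
  stopifnot(inherits(model, "poppk_model"), inherits(skeleton, "pk_dataset"))
  residual <- match.arg(residual)
  if (!is.null(seed)) set.seed(seed)
  ids <- skeleton$subjects$id
  etas <- draw_etas(model, length(ids))
  obs <- skeleton$observations
  conc <- numeric(nrow(obs))
  obs_idx <- split(seq_len(nrow(obs)), factor(obs$id, levels = ids))
  dose_idx <- split(seq_len(nrow(skeleton$doses)),
                    factor(skeleton$doses$id, levels = ids))
  for (i in seq_along(ids)) {
    idx <- obs_idx[[i]]
    dos <- skeleton$doses[dose_idx[[i]], ]
    p_i <- pk_params(cl = model$theta$cl * exp(etas[i, "eta_cl"]),
                     vc = model$theta$vc * exp(etas[i, "eta_vc"]),
                     q = model$theta$q, vp = model$theta$vp)
    pred <- cpp_conc_2cmt(p_i$cl, p_i$vc, p_i$q, p_i$vp,
                          dos$amount * skeleton$amount_scale,
                          dos$start_time, dos$duration,
                          as.numeric(obs$time[idx]))
    if (residual == "additive") {
      y <- pred + model$sigma_add * rnorm(length(idx))
      bad <- which(y < 0)
      while (length(bad) > 0L) {
        y[bad] <- pred[bad] + model$sigma_add * rnorm(length(bad))
        bad <- bad[y[bad] < 0]
      }
    } else {
      y <- exp(log(pmax(pred, 1e-300)) + model$sigma_add * rnorm(length(idx)))
    }
    conc[idx] <- y
  }
  obs$conc <- conc
  out <- pk_dataset(skeleton$subjects, skeleton$doses, obs,
                    amount_scale = skeleton$amount_scale)
  attr(out, "etas") <- tibble::tibble(id = ids, eta_cl = etas[, "eta_cl"],
                                      eta_vc = etas[, "eta_vc"])
  attr(out, "model") <- model
  out
}

#' Laplace-approximation -2 log-likelihood of a model on a dataset
#'
#' The marginal likelihood integrates the per-subject random effects out of
#' the conditional likelihood (additive Gaussian residual truncated at zero,
#' matching the simulator's resampling of negative draws); the integral is
#' approximated by the Laplace method at the conditional mode (numerical
#' log-determinant of the conditional Hessian).
#'
#' @param model A [poppk_model()].
#' @param data A `pk_dataset` with observed concentrations.
#' @return `-2 * log L` (scalar).
#' @export
poppk_neg2ll <- function(model, data) {
  subs <- subject_list(data)
  vc_iiv <- model$omega_vc > 0
  par <- transform_poppk(model, vc_iiv)
  2 * cpp_poppk_nll(par, subs, vc_iiv)
}

# model -> transformed parameter vector used by the compiled objective
transform_poppk <- function(model, vc_iiv) {
  th <- model$theta
  base <- c(log(th$cl), log(th$vc), log(th$q), log(th$vp),
            log(max(model$omega_cl, 1e-8)))
  if (vc_iiv) {
    c(base, log(max(model$omega_vc, 1e-8)), atanh(min(max(model$rho, -0.999), 0.999)),
      log(model$sigma_add))
  } else {
    c(base, log(model$sigma_add))
  }
}

# transformed vector -> poppk_model
untransform_poppk <- function(par, vc_iiv) {
  theta <- pk_params(exp(par[1]), exp(par[2]), exp(par[3]), exp(par[4]))
  if (vc_iiv) {
    poppk_model(theta, omega_cl = exp(par[5]), omega_vc = exp(par[6]),
                rho = tanh(par[7]), sigma_add = exp(par[8]))
  } else {
    poppk_model(theta, omega_cl = exp(par[5]), omega_vc = 0, rho = 0,
                sigma_add = exp(par[6]))
  }
}

#' Empirical Bayes estimates of the individual random effects
#'
#' Returns, per subject, the mode of the conditional distribution of
#' `(eta_cl, eta_vc)` given that subject's data under `model`. With vanishing
#' IIV the estimates shrink to 0 (the prior mode); subjects whose inner
#' optimization fails are reported with `NA` rather than aborting.
#'
#' @inheritParams poppk_neg2ll
#' @return A tibble with columns `id`, `eta_cl`, `eta_vc`.
#' @export
compute_ebes <- function(model, data) {
  stopifnot(inherits(model, "poppk_model"), inherits(data, "pk_dataset"))
  ids <- data$subjects$id
  if (model$omega_cl == 0 && model$omega_vc == 0) {
    return(tibble::tibble(id = ids, eta_cl = 0, eta_vc = 0))
  }
  ld_assert(model$omega_cl > 0,
            "IIV on Vc without IIV on CL is not a supported structure",
            "poppk_invalid_model")
  subs <- subject_list(data)
  vc_iiv <- model$omega_vc > 0
  m <- try(cpp_poppk_ebes(model$theta$cl, model$theta$vc, model$theta$q,
                          model$theta$vp, model$omega_cl, model$omega_vc,
                          model$rho, model$sigma_add, subs, vc_iiv),
           silent = TRUE)
  if (inherits(m, "try-error")) {
    warning("EBE optimization failed; returning NA")
    return(tibble::tibble(id = ids, eta_cl = NA_real_, eta_vc = NA_real_))
  }
  tibble::tibble(id = ids, eta_cl = m[, 1], eta_vc = m[, 2])
}

#' Screen covariates against empirical Bayes estimates
#'
#' Rank (Spearman) correlation between each baseline covariate and each
#' random-effect column, with the correlation-test p-value; pairs with
#' `p < alpha` are flagged as candidate covariate effects. Constant covariates
#' are skipped with a warning. The published models found no covariate effect,
#' so on data generated without covariate dependence the expected flag rate is
#' about `alpha`.
#'
#' @param ebes Tibble from [compute_ebes()] (columns `id`, `eta_cl`,
#'   and `eta_vc` when present).
#' @param covariates Tibble with `id` plus numeric (or two-level) covariate
#'   columns.
#' @param alpha Flagging level (default 0.05).
#' @return A tibble: `effect`, `covariate`, `correlation`, `p_value`, `flagged`.
#' @export
screen_covariates <- function(ebes, covariates, alpha = 0.05) {
  ld_assert(nrow(ebes) >= 6L, "covariate screening requires >= 6 subjects",
            "poppk_too_few_subjects")
  merged <- merge(as.data.frame(ebes), as.data.frame(covariates), by = "id")
  eff_cols <- intersect(c("eta_cl", "eta_vc"), names(ebes))
  cov_cols <- setdiff(names(covariates), "id")
  rows <- list()
  for (cv in cov_cols) {
    x <- merged[[cv]]
    if (is.character(x) || is.factor(x)) x <- as.numeric(factor(x))
    if (length(unique(x[!is.na(x)])) < 2L) {
      warning(sprintf("covariate '%s' is constant; skipped", cv))
      next
    }
    for (ef in eff_cols) {
      y <- merged[[ef]]
      if (sd(y) == 0) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          effect = ef, covariate = cv, correlation = 0, p_value = 1,
          flagged = FALSE)
        next
      }
      ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
      rows[[length(rows) + 1L]] <- tibble::tibble(
        effect = ef, covariate = cv,
        correlation = unname(ct$estimate), p_value = ct$p.value,
        flagged = ct$p.value < alpha)
    }
  }
  if (length(rows) == 0L) {
    return(tibble::tibble(effect = character(), covariate = character(),
                          correlation = numeric(), p_value = numeric(),
                          flagged = logical()))
  }
  dplyr::bind_rows(rows)
}
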