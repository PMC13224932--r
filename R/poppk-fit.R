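# Maximum-likelihood population fitting via the Laplace approximation.

# Naive two-stage starting values: per-subject least-squares curve fits from
# crude moment-based starts, then moments of the individual estimates.
naive_two_stage <- function(data) {
  subs <- subject_list(data)
  logs <- matrix(NA_real_, length(subs), 4)
  resid2 <- c(); nres <- 0L
  for (i in seq_along(subs)) {
    s <- subs[[i]]
    auc <- max(trapz(s$times, s$y), 1e-12)
    total <- sum(s$amt)
    cmax <- max(s$y, 1e-12)
    start <- log(c(cl = max(total / auc, 1e-6),
                   vc = max(s$amt[1] / cmax, 1e-6),
                   q = max(total / auc, 1e-6),
                   vp = 10 * max(s$amt[1] / cmax, 1e-6)))
    ssq <- function(lp) {
      pred <- cpp_conc_2cmt(exp(lp[1]), exp(lp[2]), exp(lp[3]), exp(lp[4]),
                            s$amt, s$start, s$dur, s$times)
      sum((s$y - pred)^2)
    }
    fit <- try(nlminb(start, ssq, lower = start - 7, upper = start + 7),
               silent = TRUE)
    if (!inherits(fit, "try-error") && all(is.finite(fit$par))) {
      logs[i, ] <- fit$par
      resid2 <- c(resid2, fit$objective)
      nres <- nres + length(s$y)
    }
  }
  ok <- complete.cases(logs)
  if (!any(ok)) {
    # fall back to crude pooled guesses
    theta <- pk_params(1, 10, 1, 100)
    return(poppk_model(theta, omega_cl = 0.3, omega_vc = 0.3, rho = 0,
                       sigma_add = max(sd(unlist(lapply(subs, `[[`, "y"))), 1e-3)))
  }
  # medians and MAD-type spreads: individual curve fits can run away on
  # subjects whose late samples sit at the noise floor
  mu <- apply(logs[ok, , drop = FALSE], 2, median)
  sds <- apply(logs[ok, , drop = FALSE], 2,
               function(z) median(abs(z - median(z))) * 1.4826)
  rho0 <- if (sum(ok) >= 3) suppressWarnings(cor(logs[ok, 1], logs[ok, 2],
                                                 method = "spearman")) else 0
  if (!is.finite(rho0)) rho0 <- 0
  sigma0 <- sqrt(max(sum(resid2) / max(nres, 1), 1e-6))
  poppk_model(pk_params(exp(mu[1]), exp(mu[2]), exp(mu[3]), exp(mu[4])),
              omega_cl = min(max(sds[1], 0.05), 1),
              omega_vc = min(max(sds[2], 0.05), 1),
              rho = min(max(rho0, -0.9), 0.9),
              sigma_add = sigma0)
}

#' Fit the population PK model by Laplace-approximation maximum likelihood
#'
#' Maximizes the marginal likelihood of the two-compartment population model,
#' integrating the per-subject random effects out with the Laplace
#' approximation (conditional modes by damped Gauss-Newton, numerical
#' log-determinant of the conditional Hessian). Percent relative standard
#' errors come from the inverse observed Fisher information (numerical Hessian
#' of the negative log-likelihood on the natural scale); %RSE = SE/estimate x 100.
#'
#' @param data A `pk_dataset` with at least 2 subjects and >= 4 observations
#'   per subject.
#' @param init Optional [poppk_model()] of starting values; the default is a
#'   naive two-stage estimate (per-subject curve fits, then moments).
#' @param vc_iiv Logical: estimate IIV on Vc and the CL-Vc correlation (the
#'   adult structure). `FALSE` fixes `omega_vc = 0` (adolescent structure).
#' @param n_restarts Number of optimization starts; starts beyond the first
#'   jitter the initial log-parameters (best final -2LL wins).
#' @param compute_rse Set `FALSE` to skip the (relatively costly) observed
#'   information computation, e.g. inside simulation studies.
#' @param control Passed to [stats::nlminb()].
#'
#' @return An object of class `poppk_fit`: `estimates` (a `poppk_model`),
#'   `rse_percent`, `neg2_loglik`, `converged`, plus bookkeeping fields.
#' @export
fit_poppk <- function(data, init = NULL, vc_iiv = TRUE, n_restarts = 3,
                      compute_rse = TRUE,
                      control = list(iter.max = 400, eval.max = 600)) {
  stopifnot(inherits(data, "pk_dataset"))
  obs_per <- table(data$observations$id)
  ld_assert(n_subjects(data) >= 2L && min(obs_per) >= 4L,
            "fit_poppk needs >= 2 subjects with >= 4 observations each",
            "poppk_too_few_subjects")
  subs <- subject_list(data)
  if (is.null(init)) init <- naive_two_stage(data)
  par0 <- transform_poppk(init, vc_iiv)
  npar <- length(par0)
  lower <- par0 - 6; upper <- par0 + 6
  iw <- if (vc_iiv) c(5, 6) else 5
  lower[iw] <- log(1e-4); upper[iw] <- log(5)
  if (vc_iiv) { lower[7] <- -3; upper[7] <- 3 }
  lower[npar] <- log(1e-9); upper[npar] <- par0[npar] + 6

  obj <- function(p) {
    v <- cpp_poppk_nll(p, subs, vc_iiv)
    if (!is.finite(v)) 1e10 else v
  }

  obj_boxed <- function(p) obj(pmin(pmax(p, lower), upper))
  run_one <- function(p_start) {
    fit <- try(nlminb(p_start, obj, lower = lower, upper = upper,
                      control = control), silent = TRUE)
    if (inherits(fit, "try-error")) return(NULL)
    # on "false convergence" the PORT gradient stalls on a stiff ridge;
    # alternate simplex and quasi-Newton rounds until no further progress
    rounds <- 0L
    while (fit$convergence != 0 && rounds < 3L) {
      nm <- optim(fit$par, obj_boxed, method = "Nelder-Mead",
                  control = list(maxit = 1000, reltol = 1e-12))
      refit <- try(nlminb(pmin(pmax(nm$par, lower), upper), obj,
                          lower = lower, upper = upper, control = control),
                   silent = TRUE)
      if (inherits(refit, "try-error")) break
      improved <- fit$objective - refit$objective
      fit <- refit
      rounds <- rounds + 1L
      if (improved < 1e-4) {
        # stalled at the same value: treat as converged-in-practice
        if (improved >= 0) fit$convergence <- 0L
        break
      }
    }
    fit
  }
  best <- NULL
  for (r in seq_len(max(1L, n_restarts))) {
    p_start <- if (r == 1L) {
      par0
    } else if (r == 2L) {
      # deterministic start at the IIV lower bound: escapes the ridge where
      # inflated random effects absorb a fixed-effect offset
      ps <- par0
      ps[iw] <- lower[iw]
      ps
    } else {
      pmin(pmax(par0 + rnorm(npar, 0, 0.2), lower), upper)
    }
    fit <- run_one(p_start)
    if (is.null(fit)) next
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  if (is.null(best)) {
    return(structure(list(estimates = init, rse_percent = NULL,
                          neg2_loglik = NA_real_, converged = FALSE,
                          vc_iiv = vc_iiv, n_subjects = n_subjects(data),
                          n_obs = nrow(data$observations),
                          residual_scale = "concentration"),
                     class = "poppk_fit"))
  }
  est <- untransform_poppk(best$par, vc_iiv)
  converged <- best$convergence == 0

  rse <- NULL
  if (compute_rse) {
    nat <- if (vc_iiv) {
      c(cl = est$theta$cl, vc = est$theta$vc, q = est$theta$q, vp = est$theta$vp,
        omega_cl = est$omega_cl, omega_vc = est$omega_vc, rho = est$rho,
        sigma_add = est$sigma_add)
    } else {
      c(cl = est$theta$cl, vc = est$theta$vc, q = est$theta$q, vp = est$theta$vp,
        omega_cl = est$omega_cl, sigma_add = est$sigma_add)
    }
    nll_nat <- function(v) {
      m <- try(suppressWarnings(
        if (vc_iiv) {
          poppk_model(pk_params(v[1], v[2], v[3], v[4]), v[5], v[6],
                      min(max(v[7], -0.999), 0.999), v[8])
        } else {
          poppk_model(pk_params(v[1], v[2], v[3], v[4]), v[5], 0, 0, v[6])
        }), silent = TRUE)
      if (inherits(m, "try-error")) return(NA_real_)
      cpp_poppk_nll(transform_poppk(m, vc_iiv), subs, vc_iiv)
    }
    H <- suppressWarnings(try(num_hessian(nll_nat, nat), silent = TRUE))
    se <- if (inherits(H, "try-error") || anyNA(H)) rep(NA_real_, length(nat))
          else se_from_hessian(H)
    rse <- 100 * se / abs(nat)
    names(rse) <- names(nat)
  }

  structure(list(estimates = est, rse_percent = rse,
                 neg2_loglik = 2 * best$objective, converged = converged,
                 vc_iiv = vc_iiv, n_subjects = n_subjects(data),
                 n_obs = nrow(data$observations),
                 residual_scale = "concentration"),
            class = "poppk_fit")
}

#' @export
print.poppk_fit <- function(x, ...) {
  cat(sprintf("<poppk_fit> -2LL = %.3f (%s), %d subjects / %d observations\n",
              x$neg2_loglik, if (x$converged) "converged" else "NOT converged",
              x$n_subjects, x$n_obs))
  e <- x$estimates
  vals <- c(CL = e$theta$cl, Vc = e$theta$vc, Q = e$theta$q, Vp = e$theta$vp,
            omega_cl = e$omega_cl, omega_vc = e$omega_vc, rho = e$rho,
            sigma_add = e$sigma_add)
  print(round(vals, 4))
  if (!is.null(x$rse_percent)) {
    cat("%RSE:\n"); print(round(x$rse_percent, 2))
  }
  cat(sprintf("residual model: additive on the %s scale\n", x$residual_scale))
  invisible(x)
}
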