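# Population layer: simulation, Laplace ML fitting, EBEs, covariate screening.

quick_cohort <- function(n, seed) generate_cohort(cohort_spec("adult", n = n),
                                                  seed = seed)

test_that("degenerate variability reproduces the typical-value prediction", {
  m <- poppk_model(pk_params(4.95, 21.59, 4.78, 202.15),
                   omega_cl = 0, omega_vc = 0, rho = 0, sigma_add = 1e-12)
  d <- generate_pk_dataset(m, quick_cohort(3, 21), seed = 22)
  for (sid in d$subjects$id) {
    obs <- d$observations[d$observations$id == sid, ]
    pred <- predict_concentrations(m$theta, cycle_regimen(), obs$time,
                                   amount_scale = d$amount_scale)$conc
    expect_equal(obs$conc, pred, tolerance = 1e-6)
  }
})

test_that("simulation is reproducible under a fixed seed and varies across seeds", {
  m <- poppk_model_adult()
  coh <- quick_cohort(4, 31)
  d1 <- generate_pk_dataset(m, coh, seed = 32)
  d2 <- generate_pk_dataset(m, coh, seed = 32)
  d3 <- generate_pk_dataset(m, coh, seed = 33)
  expect_identical(d1$observations$conc, d2$observations$conc)
  expect_false(identical(d1$observations$conc, d3$observations$conc))
})

test_that("simulated random effects reproduce the generating IIV variance", {
  m <- poppk_model_adult()
  # variance check needs many subjects, not many samples: one observation each
  coh <- generate_cohort(cohort_spec("adult", n = 10000), seed = 41)
  d <- generate_pk_dataset(m, coh, schedule = c(1), seed = 42)
  etas <- attr(d, "etas")
  v <- var(etas$eta_cl)
  se <- m$omega_cl^2 * sqrt(2 / (nrow(etas) - 1))
  expect_lt(abs(v - 0.41^2), 3 * se)
  # log-normal IIV keeps individual parameters positive
  expect_true(all(m$theta$cl * exp(etas$eta_cl) > 0))
  # correlation close to the generating 0.70
  expect_equal(cor(etas$eta_cl, etas$eta_vc), 0.70, tolerance = 0.05)
})

test_that("noise-free zero-IIV data identify the fixed effects to 0.1%", {
  truth <- pk_params(4.95, 21.59, 4.78, 202.15)
  m0 <- poppk_model(truth, 0, 0, 0, 1e-6)
  d0 <- generate_pk_dataset(m0, quick_cohort(8, 51), seed = 52)
  f <- fit_poppk(d0, n_restarts = 2, compute_rse = FALSE)
  e <- f$estimates$theta
  expect_equal(e$cl, truth$cl, tolerance = 1e-3)
  expect_equal(e$vc, truth$vc, tolerance = 1e-3)
  expect_equal(e$q, truth$q, tolerance = 1e-3)
  expect_equal(e$vp, truth$vp, tolerance = 1e-3)
})

test_that("the marginal likelihood is invariant to subject order", {
  m <- poppk_model_adult()
  d <- generate_pk_dataset(m, quick_cohort(6, 61), seed = 62)
  ll1 <- poppk_neg2ll(m, d)
  perm <- c(4, 2, 6, 1, 5, 3)
  dp <- pk_dataset(d$subjects[perm, ], d$doses, d$observations,
                   amount_scale = d$amount_scale)
  expect_equal(poppk_neg2ll(m, dp), ll1, tolerance = 1e-8)
})

test_that("population fit recovers the adolescent model structure (no Vc IIV)", {
  m <- poppk_model_adolescent()
  coh <- generate_cohort(cohort_spec("adolescent", n = 12), seed = 71)
  d <- generate_pk_dataset(m, coh, seed = 72)
  f <- fit_poppk(d, vc_iiv = FALSE, n_restarts = 1)
  expect_identical(f$estimates$omega_vc, 0)
  expect_true(f$converged)
  expect_equal(f$estimates$theta$cl, 5.92, tolerance = 0.25)
  expect_true(all(is.finite(f$neg2_loglik)))
  # %RSE defined as SE/estimate x 100, nonnegative where reported
  expect_true(all(f$rse_percent[is.finite(f$rse_percent)] >= 0))
})

test_that("fit_poppk rejects undersized datasets", {
  m <- poppk_model_adult()
  d <- generate_pk_dataset(m, quick_cohort(1, 81), seed = 82)
  expect_error(fit_poppk(d), class = "poppk_too_few_subjects")
})

test_that("EBEs recover known individual deviations from dense noise-free data", {
  times <- sort(c(seq(0.25, 168, length.out = 30), seq(200, 1100, length.out = 12)))
  p_i <- pk_params(4.95 * exp(0.3), 21.59 * exp(-0.2), 4.78, 202.15)
  conc <- predict_concentrations(p_i, cycle_regimen(), times,
                                 amount_scale = 1000)$conc
  d <- pk_dataset(tibble::tibble(id = "S1"),
                  tibble::tibble(id = "S1", amount = rep(7.4, 4),
                                 start_time = 1344 * (0:3), duration = 0.5),
                  tibble::tibble(id = "S1", time = times, conc = conc),
                  amount_scale = 1000)
  m <- poppk_model(pk_params(4.95, 21.59, 4.78, 202.15), 0.41, 0.52, 0.7, 1e-6)
  eb <- compute_ebes(m, d)
  expect_equal(eb$eta_cl, 0.3, tolerance = 0.01)
  expect_equal(eb$eta_vc, -0.2, tolerance = 0.01)
})

test_that("EBEs sit at the prior mode for typical-value data and shrink with noise", {
  m <- poppk_model_adult()
  times <- default_sampling_schedule()
  conc <- predict_concentrations(m$theta, cycle_regimen(), times,
                                 amount_scale = 1000)$conc
  d <- pk_dataset(tibble::tibble(id = "S1"),
                  tibble::tibble(id = "S1", amount = rep(7.4, 4),
                                 start_time = 1344 * (0:3), duration = 0.5),
                  tibble::tibble(id = "S1", time = times, conc = conc),
                  amount_scale = 1000)
  eb <- compute_ebes(m, d)
  expect_lt(abs(eb$eta_cl), 1e-3)
  expect_lt(abs(eb$eta_vc), 1e-3)

  # zero IIV: exact shrinkage to zero
  m0 <- poppk_model(m$theta, 0, 0, 0, 0.4)
  eb0 <- compute_ebes(m0, d)
  expect_identical(c(eb0$eta_cl, eb0$eta_vc), c(0, 0))

  # growing residual SD shrinks |EBE| monotonically on fixed data
  dshift <- d
  dshift$observations$conc <- conc * 1.3  # a subject above the typical curve
  mags <- sapply(c(0.2, 1, 5, 25), function(s) {
    mm <- poppk_model(m$theta, 0.41, 0.52, 0.7, s)
    e <- compute_ebes(mm, dshift)
    abs(e$eta_cl) + abs(e$eta_vc)
  })
  expect_true(all(diff(mags) <= 1e-6))
})

test_that("covariate screening flags a perfect association and respects the null", {
  set.seed(91)
  n <- 24
  ebes <- tibble::tibble(id = sprintf("S%02d", 1:n),
                         eta_cl = rnorm(n, 0, 0.4),
                         eta_vc = rnorm(n, 0, 0.5))
  covs <- tibble::tibble(id = ebes$id,
                         weight = rnorm(n, 75, 15),
                         mirror = exp(ebes$eta_cl),
                         flatline = rep(1, n))
  expect_warning(tab <- screen_covariates(ebes, covs), "constant")
  hit <- tab[tab$covariate == "mirror" & tab$effect == "eta_cl", ]
  expect_equal(hit$correlation, 1)
  expect_true(hit$flagged)
  expect_false("flatline" %in% tab$covariate)

  # all-zero effects at the minimum size: nothing flagged
  eb0 <- tibble::tibble(id = sprintf("S%d", 1:6), eta_cl = rep(0, 6),
                        eta_vc = rep(0, 6))
  cv0 <- tibble::tibble(id = eb0$id, age = c(30, 40, 50, 60, 70, 80))
  tab0 <- screen_covariates(eb0, cv0)
  expect_false(any(tab0$flagged))
  expect_error(screen_covariates(eb0[1:4, ], cv0), class = "poppk_too_few_subjects")
})

test_that("the type-I error rate of covariate screening is close to alpha", {
  set.seed(92)
  n <- 24
  flags <- replicate(1000, {
    ebes <- tibble::tibble(id = as.character(1:n), eta_cl = rnorm(n, 0, 0.4))
    covs <- tibble::tibble(id = ebes$id, weight = rnorm(n, 75, 15))
    screen_covariates(ebes, covs)$flagged
  })
  rate <- mean(flags)
  se <- sqrt(0.05 * 0.95 / length(flags))
  expect_lt(abs(rate - 0.05), 4 * se + 0.01)
})

test_that("prediction-corrected VPC is deterministic under a seed and exact in degenerate bins", {
  m <- poppk_model_adult()
  d <- generate_pk_dataset(m, quick_cohort(12, 93), seed = 94)
  v1 <- pc_vpc(m, d, n_sim = 120, seed = 95)
  v2 <- pc_vpc(m, d, n_sim = 120, seed = 95)
  expect_identical(v1, v2)
  # common schedule: all population predictions equal within each time bin,
  # so the correction is the identity and the observed median is the raw one
  raw <- tapply(d$observations$conc, d$observations$time, median)
  expect_equal(v1$obs_median, as.numeric(raw), tolerance = 1e-12)
  expect_true(all(v1$sim_lo <= v1$sim_hi))
})
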