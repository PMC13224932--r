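# Monte Carlo engines: scenario grid, virtual trials, exceedance summaries,
# flat-dosing check.

test_that("the default grid declares exactly 240 scenarios and validates counts", {
  g <- scenario_grid()
  expect_identical(length(g$activities) * length(g$crcl_values), 240L)
  expect_error(scenario_grid(activities = 1:3, crcl_values = c(50, 60),
                             n_scenarios = 240),
               class = "trial_invalid_grid")
  expect_error(scenario_grid(activities = c(-1, 2)), class = "trial_invalid_grid")
})

test_that("without residual noise the cell median is the deterministic dose and exceedance is a step", {
  p <- dosimetry_params_adult()
  g <- scenario_grid(activities = c(3.7, 7.4), crcl_values = c(55, 99),
                     n_subjects_per_cell = 50)
  res <- simulate_scenario_grid(p, g, seed = 201, noise = FALSE,
                                thresholds = list(kidney = c(20, 30),
                                                  bone_marrow = 2))
  kid <- res[res$organ == "kidney" & res$activity == 7.4 & res$crcl == 55, ]
  expect_equal(unique(kid$median_dose), cumulative_dose(p, rep(7.4, 4), 55, "kidney"),
               tolerance = 1e-12)
  # deterministic dose 23.79: exceeds 20, not 30
  expect_identical(kid$p_exceed[kid$threshold == 20], 1)
  expect_identical(kid$p_exceed[kid$threshold == 30], 0)
})

test_that("cell exceedance matches the truncated-normal tail probability", {
  p <- dosimetry_params_adult()
  n <- 4000
  g <- scenario_grid(activities = 7.4, crcl_values = c(55, 99),
                     n_subjects_per_cell = n)
  res <- simulate_scenario_grid(p, g, seed = 202,
                                thresholds = list(kidney = c(23, 29),
                                                  bone_marrow = 2))
  for (cc in c(55, 99)) {
    cum <- cumulative_dose(p, rep(7.4, 4), cc, "kidney")
    for (thr in c(23, 29)) {
      z <- (thr / cum - 1) / p$b1
      p_true <- (1 - pnorm(z)) / pnorm(1 / p$b1)
      got <- res$p_exceed[res$organ == "kidney" & res$crcl == cc &
                            res$threshold == thr]
      se <- sqrt(max(p_true * (1 - p_true), 1e-6) / n)
      expect_lt(abs(got - p_true), 3 * se + 1e-4)
    }
  }
})

test_that("exceedance is nonincreasing in threshold and nondecreasing in activity", {
  p <- dosimetry_params_adult()
  g <- scenario_grid(activities = c(2, 5, 8), crcl_values = c(60, 100),
                     n_subjects_per_cell = 2000)
  res <- simulate_scenario_grid(p, g, seed = 203,
                                thresholds = list(kidney = c(10, 20, 30),
                                                  bone_marrow = c(1, 2)))
  by_cell <- split(res, list(res$activity, res$crcl, res$organ))
  for (cell in by_cell) {
    cell <- cell[order(cell$threshold), ]
    expect_true(all(diff(cell$p_exceed) <= 0))
  }
  kid <- res[res$organ == "kidney" & res$crcl == 60 & res$threshold == 20, ]
  kid <- kid[order(kid$activity), ]
  expect_true(all(diff(kid$p_exceed) >= -0.02))
})

test_that("Monte Carlo cell medians are stable when the cell size doubles", {
  p <- dosimetry_params_adult()
  run <- function(n, seed) {
    g <- scenario_grid(activities = 7.4, crcl_values = 99,
                       n_subjects_per_cell = n)
    r <- simulate_scenario_grid(p, g, seed = seed,
                                thresholds = list(kidney = 29, bone_marrow = 2))
    r$median_dose[r$organ == "kidney"][1]
  }
  m500 <- run(500, 204)
  m1000 <- run(1000, 205)
  cum <- cumulative_dose(p, rep(7.4, 4), 99, "kidney")
  se <- 1.2533 * p$b1 * cum * sqrt(1 / 500 + 1 / 1000)
  expect_lt(abs(m500 - m1000), 3 * se)
})

test_that("trial-median exceedance matches the binomial closed form at a point-mass CrCL", {
  p <- dosimetry_params_adult()
  dist <- crcl_distribution(center = 99, spread = 1e-4,
                            lower = 99 - 1e-3, upper = 99 + 1e-3)
  des <- trial_design(n_per_trial = 5, n_trials = 500)
  thr <- 20
  res <- simulate_virtual_trials(p, dist, des, thresholds = thr, seed = 206)
  cum <- cumulative_dose(p, rep(7.4, 4), 99, "kidney")
  p_subj <- (1 - pnorm((thr / cum - 1) / p$b1)) / pnorm(1 / p$b1)
  p_med <- sum(dbinom(3:5, 5, p_subj))
  se <- sqrt(p_med * (1 - p_med) / 500)
  expect_lt(abs(res$prob$p_exceed_median - p_med), 3 * se)
  # total pool bookkeeping
  expect_identical(des$total_pool, 2500L)
  expect_identical(trial_design(10, 500)$total_pool, 5000L)
})

test_that("trial medians tighten and exceedance drops as the trial grows", {
  p <- dosimetry_params_adult()
  dist <- crcl_distribution()
  r5 <- simulate_virtual_trials(p, dist, trial_design(5, 500),
                                thresholds = c(23, 29), seed = 207)
  r10 <- simulate_virtual_trials(p, dist, trial_design(10, 500),
                                 thresholds = c(23, 29), seed = 207)
  expect_lt(var(r10$trial_medians$median_dose),
            var(r5$trial_medians$median_dose))
  # subject-level exceedance < 0.5 here, so larger trials exceed less often
  expect_lte(r10$prob$p_exceed_median[1], r5$prob$p_exceed_median[1] + 0.02)
  # bounds in the threshold
  rinf <- simulate_virtual_trials(p, dist, trial_design(5, 200),
                                  thresholds = c(1e-9, 1e9), seed = 208)
  expect_identical(rinf$prob$p_exceed_median, c(1, 0))
})

test_that("cohort exceedance summaries are seed-stable with ordered quantiles", {
  p <- dosimetry_params_pooled()
  coh <- generate_pooled_cohort(seed = 209)
  des <- trial_design(n_per_trial = 200, n_trials = 100)
  s1 <- exceedance_summary(p, coh, design = des, seed = 210)
  s2 <- exceedance_summary(p, coh, design = des, seed = 210)
  expect_identical(s1, s2)
  expect_true(all(s1$p_lo <= s1$p_median & s1$p_median <= s1$p_hi))
  expect_true(all(s1$p_median >= 0 & s1$p_median <= 1))
  # zero residual error with all predictions below threshold: probability 0
  p0 <- dosimetry_params(a_pop = 4.3, b_pop = 0.66, c_pop = -0.552,
                         d_pop = 0.246, e_pop = 0.597, f_pop = -1.11,
                         b1 = 1e-9, b2 = 1e-9)
  adults <- coh[coh$population == "adult" & coh$crcl > 70, ]
  s0 <- exceedance_summary(p0, adults, design = trial_design(50, 50),
                           thresholds = list(kidney = 1e6), seed = 211)
  expect_true(all(s0$p_median == 0))
})

test_that("flat-dose summaries behave on degenerate and null inputs", {
  doses <- tibble::tibble(dose_gy = rep(17.2, 40), weight = rep(70, 40),
                          population = rep(c("adult", "adolescent"), 20))
  s <- flat_dose_summary(doses, weight_breaks = 1)
  expect_identical(nrow(s), 2L)
  expect_true(all(s$median_dose == 17.2))

  # single bin reproduces the unstratified summary
  set.seed(212)
  d2 <- tibble::tibble(dose_gy = rlnorm(60, 2.8, 0.4),
                       weight = runif(60, 40, 140))
  s_all <- flat_dose_summary(d2, weight_breaks = 1)
  expect_equal(s_all$median_dose, median(d2$dose_gy))
  expect_identical(s_all$n, 60L)

  # no weight dependence: bin index and bin median are uncorrelated
  set.seed(213)
  pvals <- replicate(200, {
    d <- tibble::tibble(dose_gy = rlnorm(60, 2.8, 0.4),
                        weight = runif(60, 40, 140))
    s <- flat_dose_summary(d, weight_breaks = 5)
    suppressWarnings(cor.test(seq_len(nrow(s)), s$median_dose,
                              method = "spearman")$p.value)
  })
  expect_gte(mean(pvals > 0.05), 0.90)
})
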