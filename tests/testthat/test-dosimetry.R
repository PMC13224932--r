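# Power-law exposure-dosimetry models: prediction, cumulative dose, fitting,
# model comparison, VPC.

test_that("point predictions follow the power law", {
  p <- dosimetry_params_adult()
  # reference point: baselines by construction
  expect_equal(predict_kidney_dose(p, 7.4, 99), 4.3, tolerance = 1e-12)
  expect_equal(predict_marrow_dose(p, 7.4, 99), 0.246, tolerance = 1e-12)
  # scalar power-law evaluations
  expect_equal(predict_kidney_dose(p, 3.7, 99), 4.3 * 0.5^0.66,
               tolerance = 1e-12)
  expect_equal(predict_marrow_dose(p, 7.4, 49.5), 0.246 * 2^1.11,
               tolerance = 1e-12)
  # zero exponents collapse to the baseline
  p0 <- dosimetry_params(a_pop = 4.3, b_pop = 0, c_pop = 0,
                         d_pop = 0.246, e_pop = 0, f_pop = 0,
                         b1 = 0.5, b2 = 0.5)
  expect_equal(predict_kidney_dose(p0, 2.2, 150), 4.3)
  expect_equal(predict_marrow_dose(p0, 2.2, 150), 0.246)
  expect_error(predict_kidney_dose(p, -1, 99), class = "dosimetry_invalid_input")
  expect_error(predict_marrow_dose(p, 7.4, 0), class = "dosimetry_invalid_input")
})

test_that("the pooled model applies the adolescent study shift to the kidney only", {
  p <- dosimetry_params_pooled()
  expect_equal(predict_kidney_dose(p, 7.4, 99, adolescent = FALSE), 4.37,
               tolerance = 1e-12)
  expect_equal(predict_kidney_dose(p, 7.4, 99, adolescent = TRUE), 4.37,
               tolerance = 1e-12)  # reference CrCL: the shift has no leverage
  # opposite CrCL trends: decreasing for adults, increasing for adolescents
  crcl <- c(60, 99, 140)
  adult <- predict_kidney_dose(p, 7.4, crcl, adolescent = FALSE)
  adol <- predict_kidney_dose(p, 7.4, crcl, adolescent = TRUE)
  expect_true(all(diff(adult) < 0))
  expect_true(all(diff(adol) > 0))
  expect_equal(predict_marrow_dose(p, 7.4, 99), 0.24, tolerance = 1e-12)
})

test_that("kidney dose is monotone in activity and scale-equivariant in the normalizers", {
  p <- dosimetry_params_adult()
  act <- c(1, 2, 4, 8)
  expect_true(all(diff(predict_kidney_dose(p, act, 99)) > 0))
  # rescaling ref_activity together with the activities leaves doses unchanged
  p2 <- dosimetry_params(a_pop = p$a_pop, b_pop = p$b_pop, c_pop = p$c_pop,
                         d_pop = p$d_pop, e_pop = p$e_pop, f_pop = p$f_pop,
                         b1 = p$b1, b2 = p$b2,
                         ref_activity = 7.4 * 1000, ref_crcl = 99)
  expect_equal(predict_kidney_dose(p2, act * 1000, 99),
               predict_kidney_dose(p, act, 99), tolerance = 1e-12)
})

test_that("cumulative dose sums per-cycle predictions", {
  p <- dosimetry_params_adult()
  expect_equal(cumulative_dose(p, rep(7.4, 4), 99, "kidney"), 4 * 4.3,
               tolerance = 1e-12)
  expect_equal(cumulative_dose(p, rep(7.4, 4), 55, "kidney"),
               17.2 * (55 / 99)^-0.552, tolerance = 1e-12)
  expect_equal(cumulative_dose(p, 7.4, 99, "kidney"),
               predict_kidney_dose(p, 7.4, 99), tolerance = 1e-12)
  # unequal activities
  expect_equal(cumulative_dose(p, c(7.4, 3.7), 99, "bone_marrow"),
               predict_marrow_dose(p, 7.4, 99) + predict_marrow_dose(p, 3.7, 99),
               tolerance = 1e-12)
  expect_error(cumulative_dose(p, numeric(0), 99, "kidney"),
               class = "dosimetry_invalid_input")
  expect_error(cumulative_dose(p, rep(7.4, 5), 99, "kidney"),
               class = "dosimetry_invalid_input")
})

test_that("noise-free records are recovered exactly", {
  p0 <- dosimetry_params(a_pop = 4.3, b_pop = 0.66, c_pop = -0.552,
                         d_pop = 0.246, e_pop = 0.597, f_pop = -1.11,
                         b1 = 0, b2 = 0)
  coh <- generate_cohort(cohort_spec("adult", n = 47), seed = 101)
  act <- rep(c(3.7, 5.55, 7.4), length.out = 47)
  rec <- generate_dosimetry_dataset(p0, coh, activity = act, seed = 102)
  # b = 0: records equal the model predictions
  kid <- rec[rec$organ == "kidney", ]
  expect_equal(kid$dose_gy, predict_kidney_dose(p0, kid$activity_gbq, kid$crcl),
               tolerance = 1e-12)
  f <- fit_dosimetry(rec)
  expect_equal(f$params$a_pop, 4.3, tolerance = 1e-3)
  expect_equal(f$params$b_pop, 0.66, tolerance = 1e-3)
  expect_equal(f$params$c_pop, -0.552, tolerance = 1e-3)
  expect_equal(f$params$d_pop, 0.246, tolerance = 1e-3)
  expect_equal(f$params$e_pop, 0.597, tolerance = 1e-3)
  expect_equal(f$params$f_pop, -1.11, tolerance = 1e-3)
})

test_that("fit_dosimetry validates its inputs", {
  p <- dosimetry_params_adult()
  coh <- generate_cohort(cohort_spec("adult", n = 4), seed = 103)
  rec <- generate_dosimetry_dataset(p, coh, seed = 104)
  expect_error(fit_dosimetry(rec), class = "dosimetry_too_few_records")
  coh2 <- generate_cohort(cohort_spec("adult", n = 15), seed = 105)
  rec2 <- generate_dosimetry_dataset(p, coh2, seed = 106)
  expect_error(fit_dosimetry(rec2, include_study_effect = TRUE),
               class = "dosimetry_invalid_records")
})

test_that("likelihood at the generating parameters beats perturbed parameters on average", {
  p <- dosimetry_params_adult()
  nll_at <- function(params, rec) {
    kid <- rec[rec$organ == "kidney", ]
    f <- lutadosim:::organ_nll(kid$dose_gy, kid$activity_gbq, kid$crcl,
                               rep(0, nrow(kid)), 7.4, 99, FALSE)
    f(c(log(params$a_pop), params$b_pop, params$c_pop, log(params$b1)))
  }
  worse <- dosimetry_params(a_pop = 4.3 * 1.5, b_pop = 0.66, c_pop = -0.552,
                            d_pop = 0.246, e_pop = 0.597, f_pop = -1.11,
                            b1 = 0.515, b2 = 0.675)
  set.seed(107)
  diffs <- replicate(30, {
    coh <- generate_cohort(cohort_spec("adult", n = 47))
    act <- sample(c(3.7, 5.55, 7.4), 47, replace = TRUE)
    rec <- generate_dosimetry_dataset(p, coh, activity = act)
    nll_at(worse, rec) - nll_at(p, rec)
  })
  expect_gt(mean(diffs), 0)
})

test_that("BIC prefers the simpler kidney model on data without a study effect", {
  pnull <- dosimetry_params(a_pop = 4.37, b_pop = 0.65, c_pop = -0.55,
                            beta_study = 0, d_pop = 0.24, e_pop = 0.52,
                            f_pop = -1.18, b1 = 0.48, b2 = 0.63)
  set.seed(108)
  wins <- replicate(30, {
    coh <- generate_pooled_cohort()
    act <- sample(c(3.7, 5.55, 7.4), nrow(coh), replace = TRUE)
    rec <- generate_dosimetry_dataset(pnull, coh, activity = act)
    f0 <- fit_dosimetry(rec, include_study_effect = FALSE)
    f1 <- fit_dosimetry(rec, include_study_effect = TRUE)
    f0$bic[["kidney"]] < f1$bic[["kidney"]]
  })
  expect_gt(mean(wins), 0.5)
})

test_that("dosimetry VPC is seed-stable and collapses onto the prediction without noise", {
  p <- dosimetry_params_adult()
  coh <- generate_cohort(cohort_spec("adult", n = 47), seed = 109)
  rec <- generate_dosimetry_dataset(p, coh, seed = 110)
  v1 <- dosimetry_vpc(p, rec, n_sim = 150, seed = 111)
  v2 <- dosimetry_vpc(p, rec, n_sim = 150, seed = 111)
  expect_identical(v1, v2)
  expect_setequal(unique(v1$covariate), c("crcl", "activity"))

  ptiny <- dosimetry_params(a_pop = 4.3, b_pop = 0.66, c_pop = -0.552,
                            d_pop = 0.246, e_pop = 0.597, f_pop = -1.11,
                            b1 = 1e-9, b2 = 1e-9)
  rec0 <- generate_dosimetry_dataset(ptiny, coh, seed = 112)
  v0 <- dosimetry_vpc(ptiny, rec0, n_sim = 150, seed = 113)
  expect_lt(max((v0$sim_hi - v0$sim_lo) / v0$sim_median), 1e-7)
})
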