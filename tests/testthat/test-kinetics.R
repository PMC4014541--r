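test_that("dose conversion to micromoles is exact", {
  expect_equal(dose_to_micromol(tracer_dose(3, 147.14)), 3 / 147.14 * 1000,
               tolerance = 1e-12)
  expect_equal(dose_to_micromol(tracer_dose(3, 147.14)), 20.39, tolerance = 1e-3)
  expect_equal(dose_to_micromol(tracer_dose(0.14714, 147.14)), 1, tolerance = 1e-6)
  d1 <- dose_to_micromol(tracer_dose(3, 147.14, isotopic_purity = 0.99))
  expect_equal(d1, 0.99 * dose_to_micromol(tracer_dose(3, 147.14)))
  expect_error(tracer_dose(-1), class = "glnbolus_domain_error")
  expect_error(tracer_dose(3, isotopic_purity = 1.2), class = "glnbolus_domain_error")
})

test_that("observed AUC reproduces simple geometry", {
  expect_equal(auc_observed(enrichment_curve(c(0, 10, 20), c(1, 1, 1))), 20)
  expect_equal(auc_observed(enrichment_curve(c(0, 10, 20), c(2, 1, 1))), 25)
  short <- enrichment_curve(1:3, c(1, 1, 1))
  short$points <- short$points[1, , drop = FALSE]
  expect_error(auc_observed(short), class = "glnbolus_input_error")
})

test_that("trapezoid AUC of a mono-exponential matches the analytic oracle", {
  t <- default_times()
  A <- 2; k <- 0.1
  exact <- expo_integral(A, k, min(t), max(t))
  lin <- auc_observed(mono_exp_curve(A, k, t))
  expect_equal(lin, exact, tolerance = 5e-3)
  expect_gte(lin, exact) # trapezoid overestimates a convex decay
  expect_equal(lin, trap_oracle(function(u) A * exp(-k * u), t),
               tolerance = 1e-12)
  # log-trapezoid is exact for an exponential
  expect_equal(auc_observed(mono_exp_curve(A, k, t), method = "log"), exact,
               tolerance = 1e-10)
})

test_that("log-trapezoid falls back to the linear rule on non-positive segments", {
  cv <- enrichment_curve(c(0, 1, 2, 3), c(1, 0, -0.01, 0.5))
  lin <- auc_observed(cv, "linear")
  expect_equal(auc_observed(cv, "log"), lin)
  flat <- enrichment_curve(c(0, 1, 2), c(1, 1, 1))
  expect_equal(auc_observed(flat, "log"), 2)
})

test_that("tail fit recovers an exact terminal exponential", {
  cv <- mono_exp_curve(2, 0.05, default_times())
  tf <- fit_tail(cv, 10)
  expect_equal(tf$k_per_min, 0.05, tolerance = 1e-10)
  expect_equal(tf$r_squared, 1, tolerance = 1e-8)
  expect_equal(tf$amplitude_ape, 2 * exp(-0.05 * 90), tolerance = 1e-10)
  expect_equal(tf$n_points_used, 10)
})

test_that("tail fit fails cleanly on degenerate tails", {
  flat <- enrichment_curve(seq(1, 12), rep(1, 12))
  expect_error(fit_tail(flat), class = "glnbolus_no_valid_tail")
  rising <- enrichment_curve(seq(1, 12), exp(0.05 * seq(1, 12)))
  expect_error(fit_tail(rising), class = "glnbolus_no_valid_tail")
  expect_error(fit_tail(mono_exp_curve(2, 0.05, 1:12), n_tail = 2),
               class = "glnbolus_input_error")
  few <- flag_below_loq(mono_exp_curve(2, 0.5, 1:12), loq_ape = 0.05)
  expect_error(fit_tail(few, 10), class = "glnbolus_input_error")
  # non-positive points inside the window shrink it with a warning
  y <- 2 * exp(-0.05 * (1:12)); y[11] <- -1e-4
  mixed <- enrichment_curve(1:12, y)
  expect_warning(tf <- fit_tail(mixed, 10), "non-positive")
  expect_equal(tf$n_points_used, 9)
  expect_equal(tf$k_per_min, 0.05, tolerance = 1e-6)
})

test_that("tail k is recovered within 10% under measurement noise", {
  sim <- simulate_single_pool(pool_model_params())
  k_true <- sim$truth$k_per_min
  ks <- vapply(1:20, function(s) {
    noisy <- add_noise(sim$curve, noise_model(0.041, seed = 1000 + s))
    fit_tail(flag_below_loq(noisy, 0.01), 10)$k_per_min
  }, numeric(1))
  expect_true(all(abs(ks / k_true - 1) < 0.10))
})

test_that("tail extrapolation adds amplitude/k and nothing else", {
  cv <- mono_exp_curve(2, 0.05, default_times())
  tf <- fit_tail(cv, 10)
  obs <- auc_observed(cv)
  expect_equal(auc_total(cv, tf, extrapolate = TRUE),
               obs + tf$amplitude_ape / tf$k_per_min)
  expect_identical(auc_total(cv, extrapolate = FALSE), obs)
  # amplitude 0.2% at t_ref with k = 0.05/min -> 4 %*min of tail area
  fake <- structure(list(amplitude_ape = 0.2, k_per_min = 0.05,
                         t_ref_min = 90, n_points_used = 10, r_squared = 1),
                    class = "tail_fit")
  expect_equal(auc_total(cv, fake, extrapolate = TRUE), obs + 4)
})

test_that("extrapolated AUC sits between the analytic bounds", {
  # For APE = A exp(-k t) sampled from t1, the estimate must lie in
  # [A/k - head, A/k + trapezoid excess]; with these dense schedules the
  # excess is far smaller than the head, so the estimate stays below A/k
  # and Ra is an overestimate, never an underestimate.
  schedules <- alternative_schedules()[c("default", "peak_2min", "tail_6min")]
  for (k in c(0.02, 0.05, 0.1)) {
    for (sch in schedules) {
      t <- schedule_times(sch)
      cv <- mono_exp_curve(3, k, t)
      est <- auc_total(cv, extrapolate = TRUE)
      full <- 3 / k
      head_missed <- expo_integral(3, k, 0, min(t))
      expect_gte(est, full - head_missed - 1e-9)
      expect_lte(est, full + 1e-9)
      ra <- ra_single_pool(20, est)
      expect_gte(ra, 20 / (full / 100) - 1e-9)
    }
  }
})

test_that("exogenous glutamine rate follows dose arithmetic and stoichiometry", {
  expect_identical(exogenous_glutamine_rate(infusion_none()), 0)
  expect_equal(exogenous_glutamine_rate(infusion_ala_gln(25)),
               25 / 217.22 * 1000 / 60, tolerance = 1e-12)
  expect_equal(exogenous_glutamine_rate(infusion_ala_gln(25)), 1.918,
               tolerance = 1e-3)
  expect_identical(exogenous_glutamine_rate(infusion_alanine(9)), 0)
  expect_error(infusion_regimen("x", -1), class = "glnbolus_domain_error")
})

test_that("single-pool Ra is Dose/AUC with percent handled", {
  expect_equal(ra_single_pool(20.39, 334.3), 20.39 / 3.343, tolerance = 1e-12)
  expect_equal(ra_single_pool(20.39, 334.3), 6.10, tolerance = 1e-3)
  expect_equal(ra_single_pool(20.39, 2 * 334.3), ra_single_pool(20.39, 334.3) / 2)
  expect_equal(ra_single_pool(2 * 20.39, 334.3), 2 * ra_single_pool(20.39, 334.3))
  expect_error(ra_single_pool(20.39, 0), class = "glnbolus_domain_error")
  expect_error(ra_single_pool(20.39, -3), class = "glnbolus_domain_error")
})

test_that("analyze_curve composes the pipeline and keeps intermediates", {
  sim <- simulate_single_pool(pool_model_params())
  res <- analyze_curve(sim$curve)
  expect_s3_class(res, "kinetics_result")
  expect_equal(res$auc_total, res$auc_observed + res$auc_tail + res$auc_head)
  expect_equal(res$ra, res$dose_umol_per_kg / (res$auc_total / 100))
  expect_equal(res$endo_ra, res$ra) # no infusion declared
  expect_lt(abs(res$ra / sim$truth$ra_true - 1), 0.02)

  with_inf <- analyze_curve(sim$curve, infusion = infusion_ala_gln(25))
  expect_equal(with_inf$endo_ra,
               with_inf$ra - exogenous_glutamine_rate(infusion_ala_gln(25)))
  expect_equal(with_inf$ra, res$ra)
})

test_that("an all-baseline record fails with a staged domain error", {
  s <- data.frame(time_min = c(-5, -1, seq(1, 15)),
                  ratio_tracer = rep(0.011, 17))
  expect_error(analyze_curve(s, config = kinetics_config(extrapolate = FALSE)),
               class = "glnbolus_domain_error")
  err <- tryCatch(analyze_curve(s, config = kinetics_config(extrapolate = FALSE)),
                  error = identity)
  expect_match(conditionMessage(err), "^\\[ra\\]")
})

test_that("dropping tail samples without extrapolation inflates Ra monotonically", {
  sim <- simulate_single_pool(pool_model_params())
  cfg <- kinetics_config(extrapolate = FALSE)
  sch <- alternative_schedules()
  ra <- vapply(c("default", "trunc_60", "trunc_30"), function(nm) {
    analyze_curve(subsample(sim$curve, sch[[nm]]), config = cfg)$ra
  }, numeric(1))
  expect_true(ra[["trunc_30"]] > ra[["trunc_60"]])
  expect_true(ra[["trunc_60"]] > ra[["default"]])
})

test_that("the triangular head option adds exactly the leading triangle", {
  sim <- simulate_single_pool(pool_model_params())
  plain <- analyze_curve(sim$curve)
  headed <- analyze_curve(sim$curve, config = kinetics_config(add_head = TRUE))
  p1 <- sim$curve$points[1, ]
  expect_equal(headed$auc_head, 0.5 * p1$time_min * p1$ape_percent)
  expect_equal(headed$auc_total, plain$auc_total + headed$auc_head)
  expect_lt(headed$ra, plain$ra)
})

test_that("analyze_cohort returns one stable row per subject and visit", {
  co <- simulate_cohort(3, n_visits = 2, seed = 42)
  tab <- analyze_cohort(co$samples)
  expect_equal(nrow(tab), 6)
  expect_equal(names(tab)[1:2], c("subject_id", "visit"))
  expect_true(all(c("auc_observed", "auc_tail", "auc_total", "ra",
                    "exo_rate", "endo_ra") %in% names(tab)))
  # a broken subject is reported, not fatal, under on_error = "na"
  broken <- co$samples[!(co$samples$subject_id == "S01" &
                           co$samples$time_min < 0), ]
  tab2 <- analyze_cohort(broken, on_error = "na")
  expect_equal(sum(tab2$error != ""), 2) # both visits of S01
  expect_true(all(is.finite(tab2$endo_ra[tab2$subject_id != "S01"])))
  expect_error(analyze_cohort(broken, on_error = "stop"),
               class = "glnbolus_config_error")
})
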