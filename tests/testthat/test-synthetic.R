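test_that("single-pool curves follow the closed-form decay on both APE scales", {
  p <- pool_model_params(ra_true = 6.1, q_plasma = 20.7,
                         dose_umol_per_kg = 20.39)
  t <- default_times()
  x0 <- 20.39 / 20.7
  k <- 6.1 / 20.7
  sim_r <- simulate_single_pool(p, ape_method = "ratio")
  expect_equal(sim_r$curve$points$ape_percent, 100 * x0 * exp(-k * t),
               tolerance = 1e-12)
  # mole-fraction output compresses the same ratios through x/(1+x);
  # at t -> 0 it approaches 100 * dose / (q + dose) ~ 49.6%
  sim_m <- simulate_single_pool(p, ape_method = "mole_fraction")
  xx <- x0 * exp(-k * t)
  expect_equal(sim_m$curve$points$ape_percent, 100 * xx / (1 + xx),
               tolerance = 1e-12)
  expect_equal(100 * 20.39 / (20.7 + 20.39), 49.62, tolerance = 1e-2)
  # full-time ratio-scale AUC identity: 100 * dose / Ra
  expect_equal(sim_r$truth$auc_true, 100 * 20.39 / 6.1)
  expect_equal(sim_r$truth$auc_true, 334.3, tolerance = 0.1)
})

test_that("two-pool collapses to the single pool when exchange is zero", {
  p2 <- pool_model_params("two_pool", q_plasma = 20.7, q_tissue = 400,
                          k_exchange = 0)
  p1 <- pool_model_params("one_pool", q_plasma = 20.7)
  s2 <- simulate_two_pool(p2)
  s1 <- simulate_single_pool(p1)
  expect_equal(s2$curve$points$ape_percent, s1$curve$points$ape_percent,
               tolerance = 1e-12)
})

test_that("two-pool closed form matches a numerical ODE oracle", {
  skip_if_not_installed("deSolve")
  p <- pool_model_params("two_pool")
  t <- c(0.5, 1, 2, 5, 10, 20, 40, 60, 90)
  sol <- glnbolus:::.two_pool_solution(p, t)
  ke <- p$ra_true / p$q_plasma
  k12 <- p$k_exchange
  k21 <- p$k_exchange * p$q_plasma / p$q_tissue
  rhs <- function(time, y, parms) {
    list(c(-(ke + k12) * y[1] + k21 * y[2],
           k12 * y[1] - k21 * y[2]))
  }
  ode <- deSolve::lsoda(c(p$dose_umol_per_kg, 0), c(0, t), rhs, NULL,
                        rtol = 1e-11, atol = 1e-12)
  expect_equal(sol$a1, unname(ode[-1, 2]), tolerance = 1e-8)
  expect_equal(sol$a2, unname(ode[-1, 3]), tolerance = 1e-8)
})

test_that("two-pool tracer mass is conserved at all times", {
  p <- pool_model_params("two_pool")
  t <- seq(0.5, 180, by = 0.5)
  sol <- glnbolus:::.two_pool_solution(p, t)
  total <- sol$a1 + sol$a2 + sol$loss
  expect_true(all(abs(total / p$dose_umol_per_kg - 1) < 1e-9))
})

test_that("a large slow pool leaves the early decay single-pool-like but slows the tail", {
  # exchange slow relative to turnover: early decay is indistinguishable
  # from the single pool, and the terminal slope flattens (the slow
  # eigenvalue is much smaller than the single-pool rate constant)
  p2 <- pool_model_params("two_pool", q_plasma = 160, q_tissue = 1e5,
                          k_exchange = 0.002)
  p1 <- pool_model_params("one_pool", q_plasma = 160)
  sim2 <- simulate_two_pool(p2)
  sim1 <- simulate_single_pool(p1)
  early <- sim1$curve$points$time_min <= 5
  expect_equal(sim2$curve$points$ape_percent[early],
               sim1$curve$points$ape_percent[early], tolerance = 0.02)
  expect_lt(abs(sim2$truth$lambda_slow), 0.05 * sim1$truth$k_per_min)
  # the flatter terminal phase emerges beyond the sampling window: far
  # out, the two-pool plasma tracer exceeds the single-pool prediction
  far <- 2000
  a1_two <- glnbolus:::.two_pool_solution(p2, far)$a1
  a1_one <- p1$dose_umol_per_kg * exp(-sim1$truth$k_per_min * far)
  expect_gt(a1_two, a1_one)
})

test_that("the noise model is calibrated, seeded, and degenerate-safe", {
  sim <- simulate_single_pool(pool_model_params())
  expect_identical(add_noise(sim$curve, noise_model(0)), sim$curve)
  n1 <- add_noise(sim$curve, noise_model(0.041, seed = 7))
  n2 <- add_noise(sim$curve, noise_model(0.041, seed = 7))
  expect_identical(n1$points$ape_percent, n2$points$ape_percent)
  expect_false(identical(
    add_noise(sim$curve, noise_model(0.041, seed = 8))$points$ape_percent,
    n1$points$ape_percent))
})

test_that("repeated measurements reproduce the nominal analytical CV", {
  # many independent re-measurements of the same 3-point curve; each
  # draws a fresh run factor and fresh point factors, so the spread per
  # point is the full per-measurement CV
  cv0 <- 0.041
  base <- enrichment_curve(c(1, 2, 3), c(10, 8, 6))
  set.seed(123)
  reps <- vapply(seq_len(4000), function(i) {
    add_noise(base, noise_model(cv0))$points$ape_percent
  }, numeric(3))
  emp <- apply(reps, 1, stats::sd) / rowMeans(reps)
  expect_true(all(abs(emp / cv0 - 1) < 0.05))
})

test_that("cohort simulation emits analyzable records with a faithful truth table", {
  co <- simulate_cohort(5, seed = 3)
  expect_equal(co$truth$ra_true, rep(6.1, 5)) # degenerate sampler
  expect_equal(co$truth$endo_ra_true, co$truth$ra_true)
  expect_equal(unique(co$samples$subject_id), sprintf("S%02d", 1:5))
  # two baselines then 60 post-bolus rows per record
  one <- co$samples[co$samples$subject_id == "S01", ]
  expect_equal(sum(one$time_min < 0), 2)
  expect_equal(sum(one$time_min > 0), 60)
  # infusion bookkeeping: ra_true is total appearance
  co_inf <- simulate_cohort(2, infusion = infusion_ala_gln(25), seed = 4)
  expect_equal(co_inf$truth$endo_ra_true,
               co_inf$truth$ra_true - exogenous_glutamine_rate(infusion_ala_gln(25)))
  # the variation-study design: subjects with replicate visits
  co_var <- simulate_cohort(4, n_visits = 2, seed = 5)
  expect_equal(nrow(co_var$truth), 8)
  expect_equal(as.integer(table(co_var$truth$subject_id)), rep(2L, 4))
})

test_that("cohort CSVs are byte-identical under a fixed seed", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  simulate_cohort(3, seed = 17, n_visits = 2, out_dir = d1)
  simulate_cohort(3, seed = 17, n_visits = 2, out_dir = d2)
  for (f in c("samples.csv", "truth.csv")) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  }
})

test_that("mole-fraction cohort encoding round-trips through compute_ape", {
  for (m in c("ratio", "mole_fraction")) {
    co <- simulate_cohort(1, seed = 9, noise = noise_model(0), ape_method = m)
    cv <- compute_ape(co$samples, ape_method = m)
    sim <- simulate_single_pool(pool_model_params(), ape_method = m)
    expect_equal(cv$points$ape_percent, sim$curve$points$ape_percent,
                 tolerance = 1e-10)
    expect_equal(cv$baseline_ratio, 0.011)
  }
})
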