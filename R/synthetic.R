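#' Ground-truth kinetic parameters for the synthetic generators
#'
#' The single-pool model is the generative inverse of the estimator: a
#' dose mixing instantly into one pool of size `q_plasma` that turns
#' over at `ra_true`. Its defaults describe a typical post-absorptive
#' adult: endogenous Ra 6.1 umol/kg/min and a rapidly-mixing glutamine
#' pool of 160 umol/kg (roughly extracellular water, 0.26 L/kg, at a
#' plasma concentration of ~0.6 mM), giving a peak enrichment near 13%
#' that decays below quantification between 60 and 90 min.
#'
#' The two-pool model adds a slowly exchanging tissue pool (free
#' glutamine in skeletal muscle dominates the whole-body pool) behind a
#' small plasma pool; its defaults are illustrative only: the plasma
#' pool is sized so the bolus transiently doubles plasma glutamine, and
#' the exchange produces a slow tail that stays quantifiable past 60
#' min.
#'
#' @param model `"one_pool"` or `"two_pool"`.
#' @param ra_true Appearance rate into (and irreversible loss from) the
#'   plasma pool, umol/kg/min.
#' @param q_plasma Accessible (plasma) pool size, umol/kg. Defaults:
#'   160 (one_pool), 20.7 (two_pool).
#' @param q_tissue Slow tissue pool size, umol/kg (two_pool; default 500).
#' @param k_exchange Plasma-to-tissue exchange rate constant, 1/min
#'   (two_pool; default 0.25). The reverse rate constant follows from
#'   tracee steady state: `k_exchange * q_plasma / q_tissue`.
#' @param dose_umol_per_kg Tracer dose, umol/kg; default the 3 mg/kg
#'   \[1-13C\]glutamine bolus (~20.39 umol/kg).
#' @return Object of class `pool_model_params`.
#' @export
pool_model_params <- function(model = c("one_pool", "two_pool"),
                              ra_true = 6.1,
                              q_plasma = NULL,
                              q_tissue = NULL,
                              k_exchange = NULL,
                              dose_umol_per_kg = dose_to_micromol(tracer_dose())) {
  model <- match.arg(model)
  if (is.null(q_plasma)) q_plasma <- if (model == "one_pool") 160 else 20.7
  if (model == "two_pool") {
    if (is.null(q_tissue)) q_tissue <- 500
    if (is.null(k_exchange)) k_exchange <- 0.25
    if (q_tissue <= 0 || k_exchange < 0) {
      abort_domain("two_pool needs q_tissue > 0 and k_exchange >= 0")
    }
  }
  if (ra_true <= 0 || q_plasma <= 0 || dose_umol_per_kg <= 0) {
    abort_domain("ra_true, q_plasma and dose_umol_per_kg must be > 0")
  }
  structure(
    list(model = model, ra_true = ra_true, q_plasma = q_plasma,
         q_tissue = q_tissue, k_exchange = k_exchange,
         dose_umol_per_kg = dose_umol_per_kg),
    class = "pool_model_params"
  )
}

.ape_from_ttr <- function(x, ape_method) {
  switch(ape_method,
    ratio = 100 * x,
    mole_fraction = 100 * x / (1 + x)
  )
}

#' Simulate a noiseless single-pool bolus decay curve
#'
#' The tracer amount decays as `dose * exp(-(ra_true / q_plasma) * t)`;
#' the tracer/tracee excess ratio is that amount over `q_plasma`, and
#' the APE reported follows the chosen convention. On the ratio scale
#' the area under APE from 0 to infinity is exactly
#' `100 * dose / ra_true`, which is what makes Ra = Dose / AUC exact.
#'
#' @param params A [pool_model_params()] with `model = "one_pool"`.
#' @param schedule A [sampling_schedule()].
#' @param ape_method APE convention; keep it equal to the one the
#'   analysis uses (see [kinetics_config()]).
#' @param subject_id Label for the curve.
#' @return List with `curve` (an [enrichment_curve()]) and `truth`
#'   (`ra_true`, `k_per_min`, `ape0_percent`, `auc_true` on the ratio
#'   scale).
#' @export
simulate_single_pool <- function(params, schedule = default_schedule(),
                                 ape_method = c("ratio", "mole_fraction"),
                                 subject_id = "sim") {
  stopifnot(inherits(params, "pool_model_params"))
  if (params$model != "one_pool") abort_input("params$model must be 'one_pool'")
  ape_method <- match.arg(ape_method)
  t <- schedule_times(schedule)
  k <- params$ra_true / params$q_plasma
  x <- (params$dose_umol_per_kg / params$q_plasma) * exp(-k * t)
  curve <- enrichment_curve(t, .ape_from_ttr(x, ape_method),
                            subject_id = subject_id,
                            ape_method = ape_method)
  list(
    curve = curve,
    truth = list(ra_true = params$ra_true,
                 k_per_min = k,
                 ape0_percent = 100 * params$dose_umol_per_kg / params$q_plasma,
                 auc_true = 100 * params$dose_umol_per_kg / params$ra_true)
  )
}

# Closed-form tracer state of the two-pool system at times t:
# plasma amount a1, tissue amount a2, cumulative irreversible loss.
.two_pool_solution <- function(params, t) {
  ke <- params$ra_true / params$q_plasma
  k12 <- params$k_exchange
  k21 <- params$k_exchange * params$q_plasma / params$q_tissue
  tr <- -(ke + k12 + k21)
  det <- ke * k21
  disc <- tr^2 - 4 * det
  if (disc <= 0) abort_domain("two-pool parameters give a degenerate eigensystem")
  l1 <- (tr - sqrt(disc)) / 2 # fast
  l2 <- (tr + sqrt(disc)) / 2 # slow
  d <- params$dose_umol_per_kg
  # a1(0) = dose, a2(0) = 0
  c1 <- (l1 + k21) / (l1 - l2)
  c2 <- -(l2 + k21) / (l1 - l2)
  a1 <- d * (c1 * exp(l1 * t) + c2 * exp(l2 * t))
  a2 <- d * k12 * (exp(l1 * t) - exp(l2 * t)) / (l1 - l2)
  loss <- if (l2 == 0) NA_real_ else {
    ke * d * (c1 * (exp(l1 * t) - 1) / l1 + c2 * (exp(l2 * t) - 1) / l2)
  }
  list(a1 = a1, a2 = a2, loss = loss, lambda = c(fast = l1, slow = l2),
       ke = ke, k12 = k12, k21 = k21)
}

#' Simulate a noiseless two-pool bolus decay curve
#'
#' Solves the linear two-compartment tracer system (bolus into a plasma
#' pool with irreversible loss `ra_true` and bidirectional exchange with
#' a tissue pool, both tracee pools at steady state) in closed
#' bi-exponential form, and reports plasma enrichment. With
#' `k_exchange = 0` the output equals [simulate_single_pool()] at the
#' same plasma pool. Because irreversible loss occurs only from plasma,
#' the full-time plasma AUC still satisfies `AUC = 100 * dose /
#' ra_true`: a single-pool analysis of a two-pool curve estimates
#' plasma-pool throughput, and what it misses in a finite study is the
#' slow tail.
#'
#' @inheritParams simulate_single_pool
#' @param params A [pool_model_params()] with `model = "two_pool"`.
#' @return As [simulate_single_pool()]; `truth` additionally carries the
#'   two eigenvalues and exchange rate constants.
#' @export
simulate_two_pool <- function(params, schedule = default_schedule(),
                              ape_method = c("ratio", "mole_fraction"),
                              subject_id = "sim") {
  stopifnot(inherits(params, "pool_model_params"))
  if (params$model != "two_pool") abort_input("params$model must be 'two_pool'")
  ape_method <- match.arg(ape_method)
  t <- schedule_times(schedule)
  sol <- .two_pool_solution(params, t)
  x <- sol$a1 / params$q_plasma
  curve <- enrichment_curve(t, .ape_from_ttr(x, ape_method),
                            subject_id = subject_id,
                            ape_method = ape_method)
  list(
    curve = curve,
    truth = list(ra_true = params$ra_true,
                 lambda_fast = sol$lambda[["fast"]],
                 lambda_slow = sol$lambda[["slow"]],
                 k12_per_min = sol$k12, k21_per_min = sol$k21,
                 ape0_percent = 100 * params$dose_umol_per_kg / params$q_plasma,
                 auc_true = 100 * params$dose_umol_per_kg / params$ra_true)
  )
}

#' Measurement-noise model for simulated enrichment curves
#'
#' Multiplicative lognormal noise with median 1 calibrated to a total
#' per-measurement CV (default 4.1%, the analytical CV of duplicate
#' GC-MS analyses). The variance is split between a run-level factor
#' shared by all points of one curve (calibration state of one
#' analytical run) and independent per-point factors; `run_share` is
#' the run-level share (default 0.8). The split matters: purely
#' independent point noise would almost entirely average out in a
#' 60-point AUC, which is not what duplicate analyses of real curves
#' show — repeated runs move the whole curve together.
#'
#' @param cv_fraction Total per-measurement CV as a fraction (>= 0).
#' @param seed Optional integer; if set, [add_noise()] uses (and then
#'   restores) its own RNG state so results are reproducible without
#'   touching the caller's stream.
#' @param run_share Fraction of the noise variance that is run-level,
#'   in \[0, 1\].
#' @return Object of class `noise_model`.
#' @export
noise_model <- function(cv_fraction = 0.041, seed = NULL, run_share = 0.8) {
  if (cv_fraction < 0) abort_domain("`cv_fraction` must be >= 0")
  if (run_share < 0 || run_share > 1) abort_domain("`run_share` must be in [0, 1]")
  structure(list(cv_fraction = cv_fraction, seed = seed,
                 run_share = run_share),
            class = "noise_model")
}

#' Apply measurement noise to an enrichment curve
#'
#' Each APE value is multiplied by `R * P_i`, where `R` is one lognormal
#' run factor per curve and `P_i` are independent lognormal point
#' factors; all factors have median 1 and their combined variance gives
#' the model's total CV. A zero CV returns the curve unchanged; a fixed
#' seed gives identical output on repeated calls.
#'
#' @param curve An [enrichment_curve()].
#' @param noise A [noise_model()].
#' @return The noisy [enrichment_curve()].
#' @export
add_noise <- function(curve, noise = noise_model()) {
  stopifnot(inherits(curve, "enrichment_curve"),
            inherits(noise, "noise_model"))
  if (noise$cv_fraction == 0) return(curve)
  if (!is.null(noise$seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(noise$seed)
  }
  var_total <- log(1 + noise$cv_fraction^2)
  sd_run <- sqrt(noise$run_share * var_total)
  sd_pt <- sqrt((1 - noise$run_share) * var_total)
  n <- nrow(curve$points)
  run <- exp(stats::rnorm(1L, 0, sd_run))
  pt <- exp(stats::rnorm(n, 0, sd_pt))
  curve$points$ape_percent <- curve$points$ape_percent * run * pt
  curve
}

#' Simulate a cohort of bolus experiments as raw-sample records
#'
#' Draws a true Ra per subject, simulates the corresponding noiseless
#' decay curve, applies fresh measurement noise per visit, and emits the
#' records in the raw-sample CSV dialect the enrichment module reads
#' (baseline rows at the schedule's pre-bolus times with the
#' natural-abundance ratio, post-bolus rows with
#' `baseline_ratio + excess`), together with a ground-truth table.
#'
#' When an infusion is declared, `ra_true` is the total appearance into
#' plasma and the truth table's `endo_ra_true` is `ra_true` minus the
#' infusion's glutamine delivery rate.
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param params A [pool_model_params()] template.
#' @param ra_sampler `NULL` (every subject at `params$ra_true`) or a
#'   `function(n)` drawing `n` true Ra values.
#' @param schedule A [sampling_schedule()].
#' @param noise A [noise_model()].
#' @param infusion An [infusion_regimen()].
#' @param n_visits Visits (repeat studies) per subject; each gets fresh
#'   noise on the same true kinetics.
#' @param seed Integer seed governing every random draw; the same seed
#'   reproduces the output (and any written CSVs) byte for byte.
#' @param baseline_ratio Natural-abundance tracer/tracee ratio of the
#'   baseline samples (default 0.011).
#' @param ape_method APE convention used to encode the ratios.
#' @param out_dir If non-`NULL`, write `samples.csv` and `truth.csv`
#'   there.
#' @return List with `samples` (subject_id, visit, time_min,
#'   ratio_tracer) and `truth` (subject_id, visit, ra_true, exo_rate,
#'   endo_ra_true, q_plasma, dose_umol_per_kg).
#' @export
simulate_cohort <- function(n_subjects, params = pool_model_params(),
                            ra_sampler = NULL,
                            schedule = default_schedule(),
                            noise = noise_model(),
                            infusion = infusion_none(),
                            n_visits = 1L,
                            seed = NULL,
                            baseline_ratio = 0.011,
                            ape_method = c("ratio", "mole_fraction"),
                            out_dir = NULL) {
  stopifnot(n_subjects >= 1L, n_visits >= 1L)
  ape_method <- match.arg(ape_method)
  if (!is.null(seed)) set.seed(seed)
  ra <- if (is.null(ra_sampler)) rep(params$ra_true, n_subjects) else
    ra_sampler(n_subjects)
  stopifnot(length(ra) == n_subjects)
  exo <- exogenous_glutamine_rate(infusion)
  noise_once <- noise_model(noise$cv_fraction, seed = NULL,
                            run_share = noise$run_share)
  bl <- schedule$baseline_times

  samples <- list()
  truth <- list()
  idx <- 0L
  for (i in seq_len(n_subjects)) {
    sid <- sprintf("S%02d", i)
    p_i <- params
    p_i$ra_true <- ra[[i]]
    sim <- if (params$model == "one_pool") {
      simulate_single_pool(p_i, schedule, ape_method, subject_id = sid)
    } else {
      simulate_two_pool(p_i, schedule, ape_method, subject_id = sid)
    }
    for (v in seq_len(n_visits)) {
      noisy <- add_noise(sim$curve, noise_once)
      # Encode APE back into measured ratios so that compute_ape() with the
      # same convention recovers the noisy APE exactly.
      ratio_post <- switch(ape_method,
        ratio = baseline_ratio + noisy$points$ape_percent / 100,
        mole_fraction = mole_fraction_to_ratio(
          ratio_to_mole_fraction(baseline_ratio) +
            noisy$points$ape_percent / 100)
      )
      idx <- idx + 1L
      samples[[idx]] <- data.frame(
        subject_id = sid,
        visit = v,
        time_min = c(bl, noisy$points$time_min),
        ratio_tracer = c(rep(baseline_ratio, length(bl)), ratio_post),
        stringsAsFactors = FALSE
      )
      truth[[idx]] <- data.frame(
        subject_id = sid, visit = v,
        ra_true = ra[[i]], exo_rate = exo,
        endo_ra_true = ra[[i]] - exo,
        q_plasma = params$q_plasma,
        dose_umol_per_kg = params$dose_umol_per_kg,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- list(samples = do.call(rbind, samples),
              truth = do.call(rbind, truth))
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    utils::write.csv(out$samples, file.path(out_dir, "samples.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(out$truth, file.path(out_dir, "truth.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  out
}
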