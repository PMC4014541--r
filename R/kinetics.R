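# Built-in molar masses (g/mol): [1-13C]glutamine, alanyl-glutamine
# (Ala 89.09 + Gln 146.15 - H2O 18.02), alanine. Overridable everywhere.
.molar_mass <- c(gln_1_13c = 147.14, ala_gln = 217.22, alanine = 89.09)

#' Describe the injected tracer bolus
#'
#' @param amount_mg_per_kg Bolus amount in mg per kg body weight (> 0);
#'   default 3 mg/kg, the dose at which enrichment stays quantifiable for
#'   about an hour while plasma glutamine rises only transiently.
#' @param molar_mass_g_per_mol Molar mass of the labeled species; default
#'   147.14 g/mol for \[1-13C\]glutamine.
#' @param isotopic_purity Fraction of the injected material that is the
#'   labeled species, in (0, 1]; default 1.
#' @param tracer_name Label.
#' @return Object of class `tracer_dose`.
#' @export
tracer_dose <- function(amount_mg_per_kg = 3,
                        molar_mass_g_per_mol = .molar_mass[["gln_1_13c"]],
                        isotopic_purity = 1,
                        tracer_name = "[1-13C]glutamine") {
  if (!is.numeric(amount_mg_per_kg) || amount_mg_per_kg <= 0) {
    abort_domain("`amount_mg_per_kg` must be > 0")
  }
  if (!is.numeric(molar_mass_g_per_mol) || molar_mass_g_per_mol <= 0) {
    abort_domain("`molar_mass_g_per_mol` must be > 0")
  }
  if (!is.numeric(isotopic_purity) || isotopic_purity <= 0 ||
      isotopic_purity > 1) {
    abort_domain("`isotopic_purity` must lie in (0, 1]")
  }
  structure(
    list(amount_mg_per_kg = amount_mg_per_kg,
         molar_mass_g_per_mol = molar_mass_g_per_mol,
         isotopic_purity = isotopic_purity,
         tracer_name = tracer_name),
    class = "tracer_dose"
  )
}

#' Tracer dose in micromoles per kilogram
#'
#' @param dose A [tracer_dose()].
#' @return Dose in umol/kg: `amount / molar_mass * 1000 * purity`.
#' @export
#' @examples
#' dose_to_micromol(tracer_dose(3, 147.14)) # ~20.39 umol/kg
dose_to_micromol <- function(dose) {
  stopifnot(inherits(dose, "tracer_dose"))
  dose$amount_mg_per_kg / dose$molar_mass_g_per_mol * 1000 *
    dose$isotopic_purity
}

#' Describe a continuous exogenous infusion
#'
#' The infusion's glutamine delivery rate is subtracted from whole-body
#' Ra to obtain the endogenous rate of appearance. `moles_glutamine_per_
#' mole_compound` carries the stoichiometry: 1 for the alanyl-glutamine
#' dipeptide, 0 for alanine or saline (no glutamine delivered).
#'
#' @param compound Label.
#' @param rate_mg_per_kg_per_h Infusion rate (>= 0), mg/kg/h.
#' @param compound_molar_mass_g_per_mol Molar mass of the infused
#'   compound, g/mol (> 0 unless the rate is 0).
#' @param moles_glutamine_per_mole_compound Stoichiometry (>= 0).
#' @return Object of class `infusion_regimen`.
#' @export
infusion_regimen <- function(compound,
                             rate_mg_per_kg_per_h,
                             compound_molar_mass_g_per_mol = NA_real_,
                             moles_glutamine_per_mole_compound = 0) {
  if (!is.numeric(rate_mg_per_kg_per_h) || rate_mg_per_kg_per_h < 0) {
    abort_domain("`rate_mg_per_kg_per_h` must be >= 0")
  }
  if (moles_glutamine_per_mole_compound < 0) {
    abort_domain("stoichiometry must be >= 0")
  }
  if (rate_mg_per_kg_per_h > 0 && moles_glutamine_per_mole_compound > 0 &&
      (is.na(compound_molar_mass_g_per_mol) ||
         compound_molar_mass_g_per_mol <= 0)) {
    abort_domain("a glutamine-delivering infusion needs a positive molar mass")
  }
  structure(
    list(compound = compound,
         rate_mg_per_kg_per_h = rate_mg_per_kg_per_h,
         compound_molar_mass_g_per_mol = compound_molar_mass_g_per_mol,
         moles_glutamine_per_mole_compound = moles_glutamine_per_mole_compound),
    class = "infusion_regimen"
  )
}

#' @rdname infusion_regimen
#' @export
infusion_none <- function() {
  infusion_regimen("saline", 0, NA_real_, 0)
}

#' @rdname infusion_regimen
#' @param rate_mg_per_kg_per_h Infusion rate; the dipeptide helper
#'   defaults to 25 mg/kg/h, the alanine helper to 9 mg/kg/h.
#' @export
infusion_ala_gln <- function(rate_mg_per_kg_per_h = 25) {
  infusion_regimen("alanyl-glutamine", rate_mg_per_kg_per_h,
                   .molar_mass[["ala_gln"]], 1)
}

#' @rdname infusion_regimen
#' @export
infusion_alanine <- function(rate_mg_per_kg_per_h = 9) {
  infusion_regimen("alanine", rate_mg_per_kg_per_h,
                   .molar_mass[["alanine"]], 0)
}

#' Glutamine delivery rate of an infusion
#'
#' @param infusion An [infusion_regimen()].
#' @return Exogenous glutamine appearance in umol/kg/min:
#'   `rate / molar_mass * 1000 / 60 * stoichiometry`.
#' @export
#' @examples
#' exogenous_glutamine_rate(infusion_ala_gln(25)) # ~1.918 umol/kg/min
exogenous_glutamine_rate <- function(infusion) {
  stopifnot(inherits(infusion, "infusion_regimen"))
  if (infusion$rate_mg_per_kg_per_h == 0 ||
      infusion$moles_glutamine_per_mole_compound == 0) {
    return(0)
  }
  infusion$rate_mg_per_kg_per_h / infusion$compound_molar_mass_g_per_mol *
    1000 / 60 * infusion$moles_glutamine_per_mole_compound
}

#' Analysis configuration for the bolus pipeline
#'
#' @param auc_method Integration rule for the observed span: `"linear"`
#'   trapezoid (default; on the dense default schedule its error is far
#'   below the analytical CV) or `"log"` (log-trapezoid on declining
#'   positive segments, linear fallback elsewhere).
#' @param extrapolate Add the fitted mono-exponential tail area beyond
#'   the last quantifiable sample (default `TRUE`).
#' @param n_tail Number of trailing quantifiable points for the tail fit.
#' @param loq_ape Limit of quantification, APE percent.
#' @param ape_method APE convention shared by the enrichment and
#'   synthetic modules: `"ratio"` (default) or `"mole_fraction"`.
#' @param add_head Add a triangular leading-edge area between t = 0 and
#'   the first sample (default `FALSE`). The estimator is defined without
#'   it — missing the pre-first-sample area is the method's acknowledged,
#'   small overestimation of Ra — so the head is for sensitivity
#'   analyses only.
#' @return A list of class `kinetics_config`.
#' @export
kinetics_config <- function(auc_method = c("linear", "log"),
                            extrapolate = TRUE,
                            n_tail = 10,
                            loq_ape = 0.01,
                            ape_method = c("ratio", "mole_fraction"),
                            add_head = FALSE) {
  structure(
    list(auc_method = match.arg(auc_method),
         extrapolate = isTRUE(extrapolate),
         n_tail = as.integer(n_tail),
         loq_ape = loq_ape,
         ape_method = match.arg(ape_method),
         add_head = isTRUE(add_head)),
    class = "kinetics_config"
  )
}

#' Observed area under the enrichment curve
#'
#' Integrates APE versus time between the first and last sample. All
#' recorded points contribute, including those flagged below the LOQ
#' (clamping them would bias the area upward).
#'
#' @param curve An [enrichment_curve()].
#' @param method `"linear"` trapezoid or `"log"` trapezoid. The log rule
#'   uses `(y1 - y2) * h / log(y1 / y2)` on segments where both
#'   endpoints are positive and unequal, and falls back to the linear
#'   rule otherwise.
#' @return Area in %*min.
#' @export
auc_observed <- function(curve, method = c("linear", "log")) {
  stopifnot(inherits(curve, "enrichment_curve"))
  method <- match.arg(method)
  t <- curve$points$time_min
  y <- curve$points$ape_percent
  if (length(t) < 2L) abort_input("AUC needs at least 2 points")
  h <- diff(t)
  y1 <- y[-length(y)]
  y2 <- y[-1L]
  lin <- h * (y1 + y2) / 2
  if (method == "linear") return(sum(lin))
  loggable <- y1 > 0 & y2 > 0 & y1 != y2
  seg <- lin
  seg[loggable] <- h[loggable] * (y1[loggable] - y2[loggable]) /
    log(y1[loggable] / y2[loggable])
  sum(seg)
}

#' Fit the terminal mono-exponential tail
#'
#' Ordinary least squares of `log(APE)` against time on the last
#' `n_tail` quantifiable points. The terminal rate constant is minus the
#' slope; the amplitude is the fitted APE at the last quantifiable time,
#' so the extrapolated tail area is `amplitude / k`.
#'
#' @param curve An [enrichment_curve()], ideally after [flag_below_loq()].
#' @param n_tail Number of trailing quantifiable points to use (>= 3).
#'   Points with non-positive APE inside the window are dropped with a
#'   warning (the window shrinks).
#' @return Object of class `tail_fit` with `amplitude_ape`, `k_per_min`,
#'   `t_ref_min`, `n_points_used`, `r_squared`.
#' @export
fit_tail <- function(curve, n_tail = 10) {
  stopifnot(inherits(curve, "enrichment_curve"))
  if (n_tail < 3) abort_input("`n_tail` must be >= 3")
  pts <- curve$points[curve$points$quantifiable, , drop = FALSE]
  if (nrow(pts) < n_tail) {
    abort_input(sprintf("need >= %d quantifiable points for the tail fit, got %d",
                        n_tail, nrow(pts)))
  }
  sel <- utils::tail(pts, n_tail)
  if (any(sel$ape_percent <= 0)) {
    warning(sprintf("dropping %d non-positive APE point(s) from the tail window",
                    sum(sel$ape_percent <= 0)), call. = FALSE)
    sel <- sel[sel$ape_percent > 0, , drop = FALSE]
    if (nrow(sel) < 3L) {
      abort_no_valid_tail("fewer than 3 positive points left in the tail window")
    }
  }
  fit <- stats::lm(log(ape_percent) ~ time_min, data = sel)
  slope <- unname(stats::coef(fit)[2L])
  k <- -slope
  if (!is.finite(k) || k <= 0) {
    abort_no_valid_tail(sprintf("terminal slope is not negative (k = %.4g/min)", k))
  }
  t_ref <- max(sel$time_min)
  r2 <- if (stats::var(log(sel$ape_percent)) == 0) NA_real_ else
    suppressWarnings(summary(fit)$r.squared) # noiseless data fit perfectly
  structure(
    list(amplitude_ape = unname(exp(stats::coef(fit)[1L] + slope * t_ref)),
         k_per_min = k,
         t_ref_min = t_ref,
         n_points_used = nrow(sel),
         r_squared = r2),
    class = "tail_fit"
  )
}

#' @export
print.tail_fit <- function(x, ...) {
  cat(sprintf(
    "<tail_fit> k = %.4g/min (t1/2 %.1f min), amplitude %.4g%% at %g min, n = %d, r2 = %.4f\n",
    x$k_per_min, log(2) / x$k_per_min, x$amplitude_ape, x$t_ref_min,
    x$n_points_used, x$r_squared
  ))
  invisible(x)
}

#' Total area under the curve, optionally tail-extrapolated
#'
#' `auc_observed + amplitude/k` when extrapolation is on and the tail
#' fit is valid; the observed area alone otherwise. No leading-edge area
#' before the first sample is added (see [kinetics_config()]).
#'
#' @param curve An [enrichment_curve()].
#' @param tail A [fit_tail()] result, or `NULL` to fit one here when
#'   `extrapolate = TRUE`.
#' @param extrapolate Logical.
#' @param method Passed to [auc_observed()].
#' @param n_tail Used only when a tail must be fitted here.
#' @return Area in %*min.
#' @export
auc_total <- function(curve, tail = NULL, extrapolate = TRUE,
                      method = c("linear", "log"), n_tail = 10) {
  obs <- auc_observed(curve, method = method)
  if (!isTRUE(extrapolate)) return(obs)
  if (is.null(tail)) tail <- fit_tail(curve, n_tail = n_tail)
  stopifnot(inherits(tail, "tail_fit"))
  obs + tail$amplitude_ape / tail$k_per_min
}

#' Whole-body rate of appearance by the single-pool model
#'
#' `Ra = Dose / AUC`, with the APE percent converted to a fraction
#' before division: `Ra = dose_umol_per_kg / (auc_total / 100)`.
#'
#' @param dose_umol_per_kg Tracer dose, umol/kg (> 0).
#' @param auc_total Area under APE (%) versus time (min), > 0.
#' @return Ra in umol/kg/min.
#' @export
#' @examples
#' ra_single_pool(20.39, 334.3) # ~6.10 umol/kg/min
ra_single_pool <- function(dose_umol_per_kg, auc_total) {
  if (!is.numeric(dose_umol_per_kg) || dose_umol_per_kg <= 0) {
    abort_domain("`dose_umol_per_kg` must be > 0")
  }
  if (!is.numeric(auc_total) || is.na(auc_total) || auc_total <= 0) {
    abort_domain("`auc_total` must be > 0")
  }
  dose_umol_per_kg / (auc_total / 100)
}

#' Analyze one bolus experiment end to end
#'
#' Composes the pipeline: raw ratios to APE ([compute_ape()]), LOQ
#' flagging, terminal tail fit, AUC (observed + extrapolated tail), Ra
#' by the single-pool model, and subtraction of the exogenous infusion
#' rate to give the endogenous Ra. All intermediates are kept on the
#' result for audit.
#'
#' @param x Either a data frame of raw samples (see [compute_ape()]) or
#'   an [enrichment_curve()].
#' @param dose A [tracer_dose()].
#' @param infusion An [infusion_regimen()]; default none.
#' @param config A [kinetics_config()].
#' @return Object of class `kinetics_result` with fields `subject_id`,
#'   `auc_observed`, `auc_tail`, `auc_head`, `auc_total`,
#'   `dose_umol_per_kg`, `ra`, `exo_rate`, `endo_ra`, `tail_fit`,
#'   `n_points`, `n_quantifiable`.
#' @export
analyze_curve <- function(x, dose = tracer_dose(),
                          infusion = infusion_none(),
                          config = kinetics_config()) {
  stopifnot(inherits(config, "kinetics_config"))
  curve <- if (inherits(x, "enrichment_curve")) x else {
    with_stage("enrichment", compute_ape(x, ape_method = config$ape_method))
  }
  curve <- with_stage("loq", flag_below_loq(curve, config$loq_ape))

  tail <- NULL
  if (config$extrapolate) {
    tail <- with_stage("tail", fit_tail(curve, n_tail = config$n_tail))
  }
  obs <- with_stage("auc", auc_observed(curve, method = config$auc_method))
  tail_area <- if (config$extrapolate) tail$amplitude_ape / tail$k_per_min else 0
  head_area <- if (config$add_head) {
    0.5 * curve$points$time_min[1L] * curve$points$ape_percent[1L]
  } else 0
  total <- obs + tail_area + head_area

  dose_umol <- dose_to_micromol(dose)
  ra <- with_stage("ra", ra_single_pool(dose_umol, total))
  exo <- exogenous_glutamine_rate(infusion)
  endo <- ra - exo
  if (endo < 0) {
    warning(sprintf(
      "subject %s: endogenous Ra is negative (%.3f umol/kg/min); the declared infusion exceeds the measured whole-body Ra",
      curve$subject_id, endo), call. = FALSE)
  }

  structure(
    list(subject_id = curve$subject_id,
         n_points = nrow(curve$points),
         n_quantifiable = sum(curve$points$quantifiable),
         auc_observed = obs,
         auc_tail = tail_area,
         auc_head = head_area,
         auc_total = total,
         dose_umol_per_kg = dose_umol,
         ra = ra,
         exo_rate = exo,
         endo_ra = endo,
         tail_fit = tail,
         config = config),
    class = "kinetics_result"
  )
}

#' @export
print.kinetics_result <- function(x, ...) {
  cat(sprintf("<kinetics_result> subject %s\n", x$subject_id))
  cat(sprintf("  AUC observed %.2f + tail %.2f + head %.2f = %.2f %%*min\n",
              x$auc_observed, x$auc_tail, x$auc_head, x$auc_total))
  cat(sprintf("  dose %.3f umol/kg -> Ra %.3f, exogenous %.3f, endoRa %.3f umol/kg/min\n",
              x$dose_umol_per_kg, x$ra, x$exo_rate, x$endo_ra))
  invisible(x)
}

#' @export
as.data.frame.kinetics_result <- function(x, ...) {
  data.frame(
    subject_id = x$subject_id,
    n_points = x$n_points,
    n_quantifiable = x$n_quantifiable,
    auc_observed = x$auc_observed,
    auc_tail = x$auc_tail,
    auc_head = x$auc_head,
    auc_total = x$auc_total,
    dose_umol_per_kg = x$dose_umol_per_kg,
    ra = x$ra,
    exo_rate = x$exo_rate,
    endo_ra = x$endo_ra,
    tail_k_per_min = if (is.null(x$tail_fit)) NA_real_ else x$tail_fit$k_per_min,
    tail_r_squared = if (is.null(x$tail_fit)) NA_real_ else x$tail_fit$r_squared,
    stringsAsFactors = FALSE
  )
}

#' Analyze every subject (and visit) in a raw-sample table
#'
#' @param samples Data frame of raw samples with `subject_id`,
#'   `time_min`, `ratio_tracer` and optionally `visit`.
#' @param dose,infusion,config As in [analyze_curve()].
#' @param on_error `"stop"` (default) or `"na"`: on `"na"`, a failing
#'   subject yields a row of NAs plus an `error` message column and the
#'   remaining subjects are still analyzed.
#' @return Data frame, one row per subject (x visit), with the
#'   `kinetics_result` fields as columns. Column names are stable across
#'   runs.
#' @export
analyze_cohort <- function(samples, dose = tracer_dose(),
                           infusion = infusion_none(),
                           config = kinetics_config(),
                           on_error = c("stop", "na")) {
  on_error <- match.arg(on_error)
  if (!"subject_id" %in% names(samples)) {
    abort_input("`samples` needs a `subject_id` column")
  }
  has_visit <- "visit" %in% names(samples)
  key <- if (has_visit) {
    interaction(samples$subject_id, samples$visit, drop = TRUE, lex.order = TRUE)
  } else factor(samples$subject_id, levels = unique(samples$subject_id))
  groups <- split(samples, key)

  rows <- lapply(groups, function(g) {
    err_msg <- ""
    res <- tryCatch(
      as.data.frame(analyze_curve(g, dose = dose, infusion = infusion,
                                  config = config)),
      glnbolus_error = function(e) {
        if (on_error == "stop") stop(e)
        err_msg <<- conditionMessage(e)
        NULL
      }
    )
    if (is.null(res)) {
      res <- data.frame(subject_id = as.character(g$subject_id[[1L]]),
                        n_points = NA_integer_, n_quantifiable = NA_integer_,
                        auc_observed = NA_real_, auc_tail = NA_real_,
                        auc_head = NA_real_, auc_total = NA_real_,
                        dose_umol_per_kg = NA_real_, ra = NA_real_,
                        exo_rate = NA_real_, endo_ra = NA_real_,
                        tail_k_per_min = NA_real_, tail_r_squared = NA_real_,
                        stringsAsFactors = FALSE)
    }
    res$error <- err_msg
    if (has_visit) res$visit <- g$visit[[1L]]
    res
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  front <- c("subject_id", if (has_visit) "visit")
  out[, c(front, setdiff(names(out), front)), drop = FALSE]
}
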