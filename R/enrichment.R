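#' Convert a tracer/tracee ion ratio to an isotopomer mole fraction
#'
#' For a measured labeled/unlabeled ion-intensity ratio `r` (e.g. m/z
#' 432/431 for \[1-13C\]glutamine over unlabeled glutamine), the labeled
#' mole fraction is `r / (1 + r)`. The map is strictly increasing and
#' bounded in `[0, 1)`; [mole_fraction_to_ratio()] is its exact inverse.
#'
#' @param ratio Non-negative numeric vector of labeled/unlabeled ratios.
#' @return Numeric vector of mole fractions in `[0, 1)`.
#' @seealso [compute_ape()]
#' @export
#' @examples
#' ratio_to_mole_fraction(c(0, 1, 0.01))
ratio_to_mole_fraction <- function(ratio) {
  if (!is.numeric(ratio) || anyNA(ratio)) {
    abort_domain("`ratio` must be numeric without NA")
  }
  if (any(ratio < 0)) abort_domain("`ratio` must be >= 0")
  ratio / (1 + ratio)
}

#' @rdname ratio_to_mole_fraction
#' @param mole_fraction Numeric vector in `[0, 1)`.
#' @export
mole_fraction_to_ratio <- function(mole_fraction) {
  if (!is.numeric(mole_fraction) || anyNA(mole_fraction)) {
    abort_domain("`mole_fraction` must be numeric without NA")
  }
  if (any(mole_fraction < 0 | mole_fraction >= 1)) {
    abort_domain("`mole_fraction` must lie in [0, 1)")
  }
  mole_fraction / (1 - mole_fraction)
}

#' Construct an enrichment curve
#'
#' An `enrichment_curve` holds the time-ordered atom-percent-excess (APE)
#' samples of one bolus experiment: the object that is integrated to an
#' AUC by the kinetics functions. Usually produced by [compute_ape()] from
#' raw ion ratios; this constructor accepts pre-computed APE values.
#'
#' @param time_min Strictly increasing post-bolus sampling times (min).
#' @param ape_percent APE values (%), same length as `time_min`. Slightly
#'   negative values (baseline-subtraction noise) are permitted.
#' @param subject_id Opaque subject label.
#' @param baseline_ratio Pre-bolus tracer/tracee ratio the APE was
#'   referenced to, if known.
#' @param ape_method Convention the APE values follow: `"ratio"` for a
#'   tracer/tracee ratio difference x 100 (default), `"mole_fraction"`
#'   for a labeled-mole-fraction difference x 100.
#' @return Object of class `enrichment_curve` with a `points` data frame
#'   (`time_min`, `ape_percent`, `quantifiable`).
#' @export
enrichment_curve <- function(time_min, ape_percent, subject_id = "subject",
                             baseline_ratio = NA_real_,
                             ape_method = c("ratio", "mole_fraction")) {
  ape_method <- match.arg(ape_method)
  if (length(time_min) != length(ape_percent)) {
    abort_input("`time_min` and `ape_percent` must have equal length")
  }
  if (length(time_min) < 3L) {
    abort_input("an enrichment curve needs at least 3 points")
  }
  if (anyNA(time_min) || anyNA(ape_percent)) {
    abort_input("curve points must not contain NA")
  }
  if (any(diff(time_min) <= 0)) {
    abort_input("`time_min` must be strictly increasing")
  }
  structure(
    list(
      points = data.frame(
        time_min = as.numeric(time_min),
        ape_percent = as.numeric(ape_percent),
        quantifiable = TRUE
      ),
      baseline_ratio = baseline_ratio,
      subject_id = as.character(subject_id),
      ape_method = ape_method
    ),
    class = "enrichment_curve"
  )
}

#' @export
print.enrichment_curve <- function(x, ...) {
  p <- x$points
  cat(sprintf(
    "<enrichment_curve> subject %s: %d points over [%g, %g] min (%s APE)\n",
    x$subject_id, nrow(p), min(p$time_min), max(p$time_min), x$ape_method
  ))
  cat(sprintf("  peak APE %.3f%% at %g min; %d quantifiable\n",
              max(p$ape_percent), p$time_min[which.max(p$ape_percent)],
              sum(p$quantifiable)))
  invisible(x)
}

#' Baseline-corrected atom percent excess from raw tracer ratios
#'
#' Converts one subject's raw samples (time and m/z 432/431 ion ratio)
#' into an APE-versus-time curve. Samples with `time_min < 0` are
#' pre-bolus baselines; their mean ratio is the natural-abundance
#' reference that is subtracted from every post-bolus sample.
#'
#' Two APE conventions are supported. The default, `"ratio"`, is the
#' tracer/tracee ratio difference `100 * (r_t - r_baseline)`: the scale on
#' which the single-pool relation Ra = Dose / AUC is exact when the
#' tracee pool is constant. `"mole_fraction"` uses the difference of
#' labeled mole fractions `100 * (r_t/(1+r_t) - r_b/(1+r_b))`; the two
#' agree closely only at low enrichment (see the package vignette).
#'
#' @param samples Data frame with columns `time_min` and `ratio_tracer`
#'   (optionally `subject_id`). At least one baseline (`time_min < 0`)
#'   and three post-bolus samples are required; times must be strictly
#'   increasing.
#' @param ape_method `"ratio"` (default) or `"mole_fraction"`.
#' @param subject_id Label; taken from the data if present.
#' @return An [enrichment_curve()] of the post-bolus samples.
#' @export
#' @examples
#' s <- data.frame(time_min = c(-5, -1, 1, 5, 10),
#'                 ratio_tracer = c(0.011, 0.011, 0.10, 0.06, 0.03))
#' compute_ape(s)
compute_ape <- function(samples, ape_method = c("ratio", "mole_fraction"),
                        subject_id = NULL) {
  ape_method <- match.arg(ape_method)
  if (!is.data.frame(samples) ||
      !all(c("time_min", "ratio_tracer") %in% names(samples))) {
    abort_input("`samples` needs columns `time_min` and `ratio_tracer`")
  }
  if (anyNA(samples$time_min) || anyNA(samples$ratio_tracer)) {
    abort_input("samples must not contain NA")
  }
  if (any(diff(samples$time_min) <= 0)) {
    abort_input("sample times must be strictly increasing")
  }
  if (any(samples$ratio_tracer < 0)) abort_domain("tracer ratios must be >= 0")
  if (is.null(subject_id)) {
    subject_id <- if ("subject_id" %in% names(samples)) {
      as.character(samples$subject_id[[1L]])
    } else "subject"
  }

  pre <- samples$time_min < 0
  if (!any(pre)) {
    abort_config(sprintf("subject %s: no pre-bolus baseline sample (time_min < 0)",
                         subject_id))
  }
  if (sum(pre) == 1L) {
    warning(sprintf("subject %s: only one baseline sample; baseline ratio taken from it",
                    subject_id), call. = FALSE)
  }
  post <- samples[!pre, , drop = FALSE]
  if (nrow(post) < 3L) {
    abort_input(sprintf("subject %s: need >= 3 post-bolus samples, got %d",
                        subject_id, nrow(post)))
  }

  baseline_ratio <- mean(samples$ratio_tracer[pre])
  ape <- switch(ape_method,
    ratio = 100 * (post$ratio_tracer - baseline_ratio),
    mole_fraction = 100 * (ratio_to_mole_fraction(post$ratio_tracer) -
                             ratio_to_mole_fraction(baseline_ratio))
  )
  enrichment_curve(post$time_min, ape,
                   subject_id = subject_id,
                   baseline_ratio = baseline_ratio,
                   ape_method = ape_method)
}

#' Plasma concentration by single-point isotope dilution
#'
#' With a known amount of a fully labeled internal standard (here
#' \[13C5\]glutamine, monitored at m/z 436) added to each sample, the
#' analyte concentration is the analyte/standard ion ratio times the
#' standard's concentration equivalent.
#'
#' @param ratio_is Analyte/internal-standard ion-intensity ratio (> 0,
#'   or 0 if `zero_action = "zero"`).
#' @param is_concentration Concentration equivalent of the added internal
#'   standard (micromolar), > 0.
#' @param zero_action What a zero `ratio_is` means: `"error"` (default)
#'   or `"zero"` (return 0, i.e. analyte below detection).
#' @return Concentration in the units of `is_concentration`.
#' @export
#' @examples
#' concentration_from_is(1.034, 500) # ~517 uM
concentration_from_is <- function(ratio_is, is_concentration,
                                  zero_action = c("error", "zero")) {
  zero_action <- match.arg(zero_action)
  if (!is.numeric(ratio_is) || !is.numeric(is_concentration) ||
      anyNA(ratio_is) || anyNA(is_concentration)) {
    abort_domain("inputs must be numeric without NA")
  }
  if (any(is_concentration <= 0)) {
    abort_domain("`is_concentration` must be > 0")
  }
  if (any(ratio_is < 0)) abort_domain("`ratio_is` must be >= 0")
  if (any(ratio_is == 0) && zero_action == "error") {
    abort_domain("`ratio_is` is 0; pass zero_action = \"zero\" to map it to 0")
  }
  ratio_is * is_concentration
}

#' Flag curve points below the limit of quantification
#'
#' Points with APE below `loq_ape` are marked non-quantifiable: they are
#' excluded from terminal tail fitting ([fit_tail()]) but retained in the
#' record (and in the observed AUC, so that noise around zero is not
#' clamped into a positive bias).
#'
#' @param curve An [enrichment_curve()].
#' @param loq_ape Limit of quantification in APE percent (>= 0). The
#'   default 0.01% reflects that a 3 mg/kg bolus curve falls below
#'   reliable quantification well before the end of a 90-min study.
#' @return The curve with its `quantifiable` column updated.
#' @export
flag_below_loq <- function(curve, loq_ape = 0.01) {
  stopifnot(inherits(curve, "enrichment_curve"))
  if (!is.numeric(loq_ape) || length(loq_ape) != 1L || is.na(loq_ape) ||
      loq_ape < 0) {
    abort_domain("`loq_ape` must be a single number >= 0")
  }
  curve$points$quantifiable <- curve$points$ape_percent >= loq_ape
  curve$loq_ape <- loq_ape
  curve
}
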