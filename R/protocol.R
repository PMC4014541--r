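#' Construct a blood-sampling schedule
#'
#' A schedule is a set of pre-bolus baseline times plus contiguous
#' post-bolus segments, each sampled at a fixed interval. A segment
#' `(start, end, interval)` contributes the times
#' `start + interval, start + 2*interval, ..., end`.
#'
#' @param name Schedule label.
#' @param baseline_times Times (min, < 0) of the pre-bolus samples.
#' @param segments Data frame with columns `start_min`, `end_min`,
#'   `interval_min`; segments must be contiguous (each starts where the
#'   previous ends), non-overlapping, with positive intervals that
#'   divide the segment length.
#' @return Object of class `sampling_schedule`.
#' @seealso [default_schedule()], [schedule_times()]
#' @export
sampling_schedule <- function(name, baseline_times, segments) {
  if (!is.data.frame(segments) ||
      !all(c("start_min", "end_min", "interval_min") %in% names(segments))) {
    abort_input("`segments` needs columns start_min, end_min, interval_min")
  }
  if (length(baseline_times) < 1L || any(baseline_times >= 0)) {
    abort_input("`baseline_times` must all be < 0 (pre-bolus)")
  }
  segments <- segments[, c("start_min", "end_min", "interval_min")]
  if (any(segments$interval_min <= 0)) abort_input("intervals must be > 0")
  if (any(segments$end_min <= segments$start_min)) {
    abort_input("each segment needs end_min > start_min")
  }
  if (nrow(segments) > 1L &&
      any(abs(segments$start_min[-1L] -
                segments$end_min[-nrow(segments)]) > 1e-9)) {
    abort_input("segments must be contiguous and non-overlapping")
  }
  n_steps <- (segments$end_min - segments$start_min) / segments$interval_min
  if (any(abs(n_steps - round(n_steps)) > 1e-9)) {
    abort_input("each interval must divide its segment length")
  }
  structure(
    list(name = as.character(name),
         baseline_times = as.numeric(sort(baseline_times)),
         segments = segments),
    class = "sampling_schedule"
  )
}

#' @export
print.sampling_schedule <- function(x, ...) {
  cat(sprintf("<sampling_schedule> %s: %d baseline + %d post-bolus samples over %g min\n",
              x$name, length(x$baseline_times), length(schedule_times(x)),
              max(x$segments$end_min)))
  for (i in seq_len(nrow(x$segments))) {
    s <- x$segments[i, ]
    cat(sprintf("  (%g, %g] min every %g min\n",
                s$start_min, s$end_min, s$interval_min))
  }
  invisible(x)
}

#' The study's default 90-minute sampling schedule
#'
#' Two pre-bolus baselines, then samples every 30 s up to 10 min, every
#' 1 min up to 30 min, and every 3 min up to 90 min: 60 post-bolus
#' samples (20 + 20 + 20) that resolve both the peak and the tail of the
#' enrichment decay.
#'
#' @return A [sampling_schedule()] named `"default"`.
#' @export
default_schedule <- function() {
  sampling_schedule(
    name = "default",
    baseline_times = c(-5, -1),
    segments = data.frame(
      start_min = c(0, 10, 30),
      end_min = c(10, 30, 90),
      interval_min = c(0.5, 1, 3)
    )
  )
}

#' Post-bolus sampling times of a schedule
#'
#' @param schedule A [sampling_schedule()].
#' @return Increasing numeric vector of post-bolus times (min).
#' @export
schedule_times <- function(schedule) {
  stopifnot(inherits(schedule, "sampling_schedule"))
  unlist(lapply(seq_len(nrow(schedule$segments)), function(i) {
    s <- schedule$segments[i, ]
    n <- round((s$end_min - s$start_min) / s$interval_min)
    s$start_min + s$interval_min * seq_len(n)
  }), use.names = FALSE)
}

#' Restrict a curve to a schedule's sampling times
#'
#' Emulates having sampled a measured (or simulated) curve under an
#' alternative protocol: keeps exactly the points whose times match the
#' schedule's, and errors if any requested time is absent.
#'
#' @param curve An [enrichment_curve()].
#' @param schedule A [sampling_schedule()] whose times must all be
#'   present in the curve (within `tolerance_min`).
#' @param tolerance_min Time-matching tolerance; default `1e-6` min
#'   (schedules address exact grid points).
#' @return The restricted [enrichment_curve()].
#' @export
subsample <- function(curve, schedule, tolerance_min = 1e-6) {
  stopifnot(inherits(curve, "enrichment_curve"),
            inherits(schedule, "sampling_schedule"))
  want <- schedule_times(schedule)
  have <- curve$points$time_min
  idx <- vapply(want, function(w) {
    j <- which(abs(have - w) <= tolerance_min)
    if (length(j) == 0L) NA_integer_ else j[[1L]]
  }, integer(1))
  if (anyNA(idx)) {
    abort_input(sprintf(
      "schedule '%s' requests times absent from the curve: %s",
      schedule$name,
      paste(format(want[is.na(idx)]), collapse = ", ")))
  }
  out <- curve
  out$points <- curve$points[idx, , drop = FALSE]
  rownames(out$points) <- NULL
  out$schedule_name <- schedule$name
  out
}

#' A family of alternative schedules for sensitivity analysis
#'
#' Variations of the default protocol along the axes that matter for a
#' bolus study: peak sampling frequency, tail sampling frequency, and
#' tail duration. All are subsets of the default grid, so measured
#' default-protocol curves can be subsampled to each.
#'
#' @return Named list of [sampling_schedule()]s, the default first.
#' @export
alternative_schedules <- function() {
  seg <- function(start, end, int) {
    data.frame(start_min = start, end_min = end, interval_min = int)
  }
  bl <- c(-5, -1)
  list(
    default = default_schedule(),
    peak_1min = sampling_schedule("peak_1min", bl, seg(c(0, 10, 30), c(10, 30, 90), c(1, 1, 3))),
    peak_2min = sampling_schedule("peak_2min", bl, seg(c(0, 10, 30), c(10, 30, 90), c(2, 2, 3))),
    tail_6min = sampling_schedule("tail_6min", bl, seg(c(0, 10, 30), c(10, 30, 90), c(0.5, 1, 6))),
    trunc_60 = sampling_schedule("trunc_60", bl, seg(c(0, 10, 30), c(10, 30, 60), c(0.5, 1, 3))),
    trunc_30 = sampling_schedule("trunc_30", bl, seg(c(0, 10), c(10, 30), c(0.5, 1)))
  )
}

#' Protocol-sensitivity analysis
#'
#' Recomputes the endogenous Ra of every subject under each candidate
#' schedule (by subsampling the measured curves) and compares each
#' schedule against the reference with a paired t-test.
#'
#' By default the analysis is run without tail extrapolation: the
#' comparison is about what each schedule's observed samples alone
#' yield, and extrapolating would mask the cost of truncating the tail.
#'
#' @param curves List of [enrichment_curve()]s (>= 2 subjects).
#' @param schedules Named list of [sampling_schedule()]s including the
#'   reference.
#' @param dose A [tracer_dose()].
#' @param infusion An [infusion_regimen()].
#' @param config A [kinetics_config()]; default linear AUC without
#'   extrapolation.
#' @param reference Name of the reference schedule (default
#'   `"default"`).
#' @return List of class `protocol_sensitivity`: `endo_ra`, a subject x
#'   schedule data frame; `summary`, one row per schedule with
#'   `mean_endo_ra`, `mean_diff` (vs reference), paired `t` and `p`.
#'   Failing (subject, schedule) cells become `NA` with a warning.
#' @export
protocol_sensitivity <- function(curves, schedules,
                                 dose = tracer_dose(),
                                 infusion = infusion_none(),
                                 config = kinetics_config(extrapolate = FALSE),
                                 reference = "default") {
  if (length(curves) < 2L) abort_input("need curves from >= 2 subjects")
  if (is.null(names(schedules)) || any(names(schedules) == "")) {
    names(schedules) <- vapply(schedules, `[[`, "", "name")
  }
  if (!reference %in% names(schedules)) {
    abort_input(sprintf("reference schedule '%s' not among the schedules", reference))
  }
  subjects <- vapply(curves, `[[`, "", "subject_id")
  if (anyDuplicated(subjects)) subjects <- make.unique(subjects)

  endo <- sapply(schedules, function(sch) {
    vapply(curves, function(cv) {
      tryCatch({
        res <- analyze_curve(subsample(cv, sch), dose = dose,
                             infusion = infusion, config = config)
        res$endo_ra
      }, glnbolus_error = function(e) {
        warning(sprintf("subject %s, schedule %s: %s", cv$subject_id,
                        sch$name, conditionMessage(e)), call. = FALSE)
        NA_real_
      })
    }, numeric(1))
  })
  endo <- as.data.frame(endo)
  rownames(endo) <- subjects

  ref <- endo[[reference]]
  summary <- do.call(rbind, lapply(names(schedules), function(nm) {
    v <- endo[[nm]]
    ok <- stats::complete.cases(v, ref)
    d <- v[ok] - ref[ok]
    if (nm == reference) {
      tt <- list(t = NA_real_, p = NA_real_)
    } else if (sum(ok) >= 2L) {
      pt <- paired_t(ref[ok], v[ok])
      tt <- list(t = pt$t, p = pt$p)
    } else {
      tt <- list(t = NA_real_, p = NA_real_)
    }
    data.frame(schedule = nm, n = sum(ok),
               mean_endo_ra = mean(v, na.rm = TRUE),
               mean_diff = if (nm == reference) 0 else mean(d),
               t = tt$t, p = tt$p, stringsAsFactors = FALSE)
  }))
  rownames(summary) <- NULL
  structure(list(endo_ra = endo, summary = summary, reference = reference),
            class = "protocol_sensitivity")
}

#' @export
print.protocol_sensitivity <- function(x, ...) {
  cat(sprintf("<protocol_sensitivity> %d subjects x %d schedules (reference: %s)\n",
              nrow(x$endo_ra), ncol(x$endo_ra), x$reference))
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Read or write a sampling schedule as a YAML file
#'
#' Schedules serialize to a small structured text file with the name,
#' baseline times and segments; reading back reproduces the schedule
#' exactly.
#'
#' @param path File path.
#' @return `read_schedule()` returns a [sampling_schedule()];
#'   `write_schedule()` returns `path` invisibly.
#' @export
read_schedule <- function(path) {
  y <- yaml::read_yaml(path)
  seg <- do.call(rbind, lapply(y$segments, function(s) {
    data.frame(start_min = as.numeric(s$start_min),
               end_min = as.numeric(s$end_min),
               interval_min = as.numeric(s$interval_min))
  }))
  sampling_schedule(y$name, as.numeric(y$baseline_times), seg)
}

#' @rdname read_schedule
#' @param schedule A [sampling_schedule()].
#' @export
write_schedule <- function(schedule, path) {
  stopifnot(inherits(schedule, "sampling_schedule"))
  y <- list(
    name = schedule$name,
    baseline_times = as.list(schedule$baseline_times),
    segments = lapply(seq_len(nrow(schedule$segments)), function(i) {
      as.list(schedule$segments[i, ])
    })
  )
  yaml::write_yaml(y, path, precision = 15)
  invisible(path)
}
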