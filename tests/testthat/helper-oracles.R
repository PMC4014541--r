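# Independent oracles used across the suite.

# Analytic integral of A * exp(-k t) over [t1, t2].
expo_integral <- function(A, k, t1, t2) {
  A / k * (exp(-k * t1) - exp(-k * t2))
}

# Segment-exact trapezoid sum of an arbitrary function evaluated on a
# time grid: what a trapezoid rule *should* return, computed without the
# package's integration code.
trap_oracle <- function(f, times) {
  y <- f(times)
  sum(diff(times) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

# A mono-exponential enrichment curve on a given time grid.
mono_exp_curve <- function(A, k, times, subject_id = "oracle") {
  enrichment_curve(times, A * exp(-k * times), subject_id = subject_id)
}

default_times <- function() schedule_times(default_schedule())

`%||%` <- function(a, b) if (is.null(a)) b else a
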