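#' Coefficient of variation in percent
#'
#' @param values Numeric vector, length >= 2, with non-zero mean.
#' @return `100 * sd(values) / mean(values)`.
#' @export
#' @examples
#' cv_percent(c(4, 6)) # 28.28%
cv_percent <- function(values) {
  if (!is.numeric(values) || length(values) < 2L || anyNA(values)) {
    abort_input("`values` must be numeric, length >= 2, without NA")
  }
  m <- mean(values)
  if (m == 0) abort_domain("mean of `values` is 0; CV undefined")
  100 * stats::sd(values) / m
}

#' Pooled within-subject coefficient of variation
#'
#' Repeatability of a measurement repeated on several occasions per
#' subject: the root mean square of the per-subject CVs.
#'
#' @param measures Data frame with columns `subject_id` and `value`;
#'   every subject needs >= 2 values.
#' @return Pooled within-subject CV in percent.
#' @export
#' @examples
#' d <- data.frame(subject_id = rep(c("a", "b"), each = 2),
#'                 value = c(4, 6, 5, 5))
#' within_subject_cv(d) # 20%
within_subject_cv <- function(measures) {
  if (!is.data.frame(measures) ||
      !all(c("subject_id", "value") %in% names(measures))) {
    abort_input("`measures` needs columns `subject_id` and `value`")
  }
  per <- split(measures$value, measures$subject_id)
  if (any(lengths(per) < 2L)) {
    abort_input("every subject needs >= 2 values for a within-subject CV")
  }
  cvs <- vapply(per, cv_percent, numeric(1))
  sqrt(mean(cvs^2))
}

#' Paired Student's t-test
#'
#' Two-sided paired t-test of `post` against `pre`. Zero-variance
#' differences (every pair differing by the same amount) cannot be
#' tested; they are returned with `degenerate = TRUE` and a p-value of
#' 1 (all differences zero) or 0 (a constant non-zero shift).
#'
#' @param pre,post Paired numeric vectors of equal length >= 2.
#' @return List with `t`, `df`, `p`, `mean_diff` (post - pre),
#'   `degenerate`.
#' @export
paired_t <- function(pre, post) {
  if (length(pre) != length(post) || length(pre) < 2L) {
    abort_input("`pre` and `post` must have equal length >= 2")
  }
  if (anyNA(pre) || anyNA(post)) abort_input("paired values must not contain NA")
  d <- post - pre
  if (stats::sd(d) == 0) {
    if (mean(d) == 0) {
      return(list(t = 0, df = length(d) - 1L, p = 1, mean_diff = 0,
                  degenerate = TRUE))
    }
    return(list(t = sign(mean(d)) * Inf, df = length(d) - 1L, p = 0,
                mean_diff = mean(d), degenerate = TRUE))
  }
  ht <- stats::t.test(post, pre, paired = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, mean_diff = unname(ht$estimate),
       degenerate = FALSE)
}

# Dunnett two-sided familywise probability P(max_j |T_j| <= q) for the
# multivariate t with the many-to-one correlation structure.
.dunnett_prob <- function(q, corr, df) {
  m <- nrow(corr)
  if (m == 1L) return(1 - 2 * stats::pt(-q, df))
  # Genz-Bretz quasi-Monte-Carlo consumes the R RNG stream; fix it so
  # repeated calls are identical and the caller's stream is untouched.
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(1L)
  as.numeric(mvtnorm::pmvt(lower = rep(-q, m), upper = rep(q, m),
                           df = as.integer(df), corr = corr,
                           algorithm = mvtnorm::GenzBretz(abseps = 1e-6,
                                                          maxpts = 100000L)))
}

#' One-way ANOVA with Dunnett many-to-one comparisons
#'
#' Fits a one-way ANOVA (via [stats::aov()]) and compares every
#' non-control group against the named control with two-sided
#' Dunnett-adjusted p-values. The adjustment uses the multivariate-t
#' distribution of the comparison statistics, whose correlation is
#' `sqrt(n_i * n_j / ((n_i + n_c) * (n_j + n_c)))` (1/2 in the balanced
#' case), integrated exactly for up to three comparisons and by
#' Genz-Bretz quadrature otherwise.
#'
#' @param values Numeric response vector.
#' @param group Group labels, same length as `values`; every group
#'   needs n >= 2.
#' @param control Label of the control group.
#' @return List with `f`, `p_anova`, `df_residual`, `control`, and
#'   `comparisons`, a data frame (`group`, `estimate`, `t`,
#'   `p_unadjusted`, `p_adjusted`).
#' @export
anova_dunnett <- function(values, group, control) {
  if (length(values) != length(group)) {
    abort_input("`values` and `group` must have equal length")
  }
  if (anyNA(values)) abort_input("`values` must not contain NA")
  group <- as.character(group)
  if (!control %in% group) {
    abort_input(sprintf("control label '%s' not present in `group`", control))
  }
  n <- table(group)
  if (length(n) < 2L) abort_input("need >= 2 groups")
  if (any(n < 2L)) abort_input("every group needs n >= 2")

  g <- factor(group, levels = c(control, sort(setdiff(unique(group), control))))
  fit <- stats::aov(values ~ g)
  an <- summary(fit)[[1L]]
  f <- an[["F value"]][1L]
  p_anova <- an[["Pr(>F)"]][1L]
  df_res <- fit$df.residual
  mse <- an[["Mean Sq"]][2L]

  means <- tapply(values, g, mean)
  ns <- tapply(values, g, length)
  others <- levels(g)[-1L]
  nc <- ns[[control]]
  est <- means[others] - means[[control]]
  se <- sqrt(mse * (1 / ns[others] + 1 / nc))
  tstat <- est / se

  lam <- sqrt(ns[others] / (ns[others] + nc))
  corr <- outer(lam, lam)
  diag(corr) <- 1
  p_unadj <- 2 * stats::pt(-abs(tstat), df_res)
  p_adj <- vapply(abs(tstat), function(q) {
    max(0, min(1, 1 - .dunnett_prob(q, corr, df_res)))
  }, numeric(1))

  list(
    f = f, p_anova = p_anova, df_residual = df_res, control = control,
    comparisons = data.frame(
      group = others,
      estimate = unname(est),
      t = unname(tstat),
      p_unadjusted = unname(p_unadj),
      p_adjusted = unname(p_adj),
      stringsAsFactors = FALSE
    )
  )
}
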