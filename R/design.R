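#' Gompertz survivorship function
#'
#' Fraction of an aging cohort still alive at a given age under the Gompertz
#' mortality law, the standard model for adult cohorts of *Drosophila* and
#' many other organisms. The hazard is `a * exp(b * t)`, so survivorship is
#' `S(t) = exp(-(a / b) * (exp(b * t) - 1))`, with `S(0) = 1` and `S`
#' strictly decreasing.
#'
#' @param day Age in days (non-negative, vectorised).
#' @param a Baseline hazard, `> 0` (per day).
#' @param b Rate of exponential hazard increase, `> 0` (per day).
#' @return Survival fraction in `(0, 1]`, same length as `day`.
#' @seealso [calibrate_gompertz()] to obtain `(a, b)` from two survivorship
#'   anchors, [make_design()] which uses it to build a sampling design.
#' @export
#' @examples
#' gompertz_survival(0, 0.001, 0.15)   # 1 by construction
#' gompertz_survival(c(3, 59), 0.0005, 0.148)
gompertz_survival <- function(day, a, b) {
  if (!is.numeric(a) || length(a) != 1L || !is.finite(a) || a <= 0 ||
      !is.numeric(b) || length(b) != 1L || !is.finite(b) || b <= 0) {
    stop("Gompertz parameters 'a' and 'b' must be single positive numbers")
  }
  if (!is.numeric(day) || any(day < 0)) {
    stop("'day' must be non-negative")
  }
  exp(-(a / b) * (exp(b * day) - 1))
}

#' Calibrate Gompertz parameters from two survivorship anchors
#'
#' Solves for `(a, b)` such that the Gompertz curve passes exactly through
#' two observed (day, survival) points. The ratio of cumulative hazards
#' depends on `b` alone, so `b` is found by root-finding and `a` follows in
#' closed form. Defaults reproduce a cohort that is 99.9% alive at day 3 and
#' 1.92% alive at day 59.
#'
#' @param day1,survival1 First (young) anchor.
#' @param day2,survival2 Second (old) anchor; `day2 > day1`,
#'   `survival2 < survival1`.
#' @return Named numeric vector `c(a =, b =)`.
#' @export
#' @examples
#' p <- calibrate_gompertz()
#' gompertz_survival(c(3, 59), p[["a"]], p[["b"]])
calibrate_gompertz <- function(day1 = 3, survival1 = 0.999,
                               day2 = 59, survival2 = 0.0192) {
  stopifnot(day2 > day1, day1 > 0,
            survival1 > survival2, survival2 > 0, survival1 < 1 || survival1 == 1)
  h1 <- -log(survival1)
  h2 <- -log(survival2)
  ratio <- h2 / h1
  f <- function(b) (exp(b * day2) - 1) / (exp(b * day1) - 1) - ratio
  b <- stats::uniroot(f, interval = c(1e-8, 5), tol = 1e-14)$root
  a <- b * h1 / (exp(b * day1) - 1)
  c(a = a, b = b)
}

#' Weibull survivorship function
#'
#' `S(t) = exp(-(t / scale)^shape)`: strictly decreasing with `S(0) = 1`.
#' With `shape > 1` mortality accelerates with age while deaths remain
#' spread over much of the lifespan, the shape an observed fly-cohort
#' Kaplan-Meier curve takes; this makes it the default mortality law for
#' the synthetic design (a Gompertz forced through the same two anchors
#' concentrates nearly all deaths in the last third of the sampled span
#' and understates the day-mortality collinearity real cohorts show).
#'
#' @param day Age in days (non-negative, vectorised).
#' @param shape,scale Weibull parameters, `> 0`.
#' @return Survival fraction in `(0, 1]`.
#' @export
weibull_survival <- function(day, shape, scale) {
  if (!is.numeric(shape) || shape <= 0 || !is.numeric(scale) || scale <= 0) {
    stop("Weibull parameters must be positive")
  }
  if (!is.numeric(day) || any(day < 0)) stop("'day' must be non-negative")
  exp(-(day / scale)^shape)
}

#' Calibrate Weibull parameters from two survivorship anchors
#'
#' Closed-form 2-point fit: the cumulative-hazard ratio fixes `shape`, then
#' `scale` follows. Defaults reproduce 99.9% alive at day 3 and 1.92% at
#' day 59.
#'
#' @inheritParams calibrate_gompertz
#' @return Named numeric vector `c(shape =, scale =)`.
#' @export
#' @examples
#' p <- calibrate_weibull()
#' weibull_survival(c(3, 59), p[["shape"]], p[["scale"]])
calibrate_weibull <- function(day1 = 3, survival1 = 0.999,
                              day2 = 59, survival2 = 0.0192) {
  stopifnot(day2 > day1, day1 > 0, survival1 > survival2, survival2 > 0)
  h1 <- -log(survival1)
  h2 <- -log(survival2)
  shape <- log(h2 / h1) / log(day2 / day1)
  scale <- day1 / h1^(1 / shape)
  c(shape = shape, scale = scale)
}

# Evaluate a survivorship specification at given days: either a function
# day -> fraction, a Gompertz parameter vector c(a=, b=), or a Weibull
# parameter vector c(shape=, scale=).
eval_survival <- function(survival, days) {
  if (is.function(survival)) {
    s <- survival(days)
    if (any(s <= 0 | s > 1)) stop("design error: survival function must return values in (0, 1]")
    return(s)
  }
  nm <- names(survival)
  if (all(c("a", "b") %in% nm)) {
    return(gompertz_survival(days, survival[["a"]], survival[["b"]]))
  }
  if (all(c("shape", "scale") %in% nm)) {
    return(weibull_survival(days, survival[["shape"]], survival[["scale"]]))
  }
  stop("design error: 'survival' must be a function, c(a=, b=) or c(shape=, scale=)")
}

#' Default lifespan sampling days
#'
#' Fifteen sampling days spaced roughly every 4 days from day 3 to day 59,
#' chosen to sample an aging cohort approximately evenly through both
#' chronological and physiological (survivorship) age.
#'
#' @return Integer vector of 15 days.
#' @export
default_sampling_days <- function() {
  c(3L, 6L, 10L, 14L, 17L, 23L, 27L, 31L, 36L, 41L, 45L, 48L, 52L, 55L, 59L)
}

#' Build the replicated lifespan sampling design
#'
#' Creates the per-sample design table: one row per RNA-seq replicate per
#' sampling day, with the cohort survival fraction at each day taken from a
#' Gompertz survivorship curve. The default design has 3 replicates at each
#' of the first 14 sampling points and 6 at the last (48 samples total);
#' because mortality accelerates late in life while sampling days are roughly
#' evenly spaced, day and mortality fraction are strongly but not perfectly
#' correlated — the covariate structure the downstream differential
#' expression analyses assume.
#'
#' @param days Strictly increasing sampling days.
#' @param replicates Integer vector, one entry per sampling day.
#' @param survival Survivorship model: a function `day -> fraction`, a
#'   Gompertz parameter vector `c(a =, b =)` (see [calibrate_gompertz()]),
#'   or a Weibull vector `c(shape =, scale =)` (the default; see
#'   [calibrate_weibull()]).
#' @param batch Optional character vector of batch labels per sample
#'   (recycled), or `NULL`.
#' @return A `data.frame` (sample table) with columns `sample_id`, `day`,
#'   `survival_fraction`, `mortality_fraction`, `sampling_point` (ordered
#'   factor `SP1..SPn`), `replicate`, `batch`.
#' @export
#' @examples
#' design <- make_design()
#' nrow(design)                       # 48
#' nlevels(design$sampling_point)     # 15
make_design <- function(days = default_sampling_days(),
                        replicates = c(rep(3L, length(days) - 1L), 6L),
                        survival = calibrate_weibull(),
                        batch = NULL) {
  if (length(days) != length(replicates)) {
    stop("design error: 'days' and 'replicates' must have the same length")
  }
  if (length(days) < 1L || any(diff(days) <= 0)) {
    stop("design error: 'days' must be non-empty and strictly increasing")
  }
  if (any(replicates < 1L) || any(replicates != round(replicates))) {
    stop("design error: 'replicates' must be positive integers")
  }
  surv <- eval_survival(survival, days)
  sp_levels <- sprintf("SP%d", seq_along(days))
  day_rep <- rep(days, replicates)
  surv_rep <- rep(surv, replicates)
  rep_idx <- unlist(lapply(replicates, seq_len), use.names = FALSE)
  out <- data.frame(
    sample_id = sprintf("d%02d_r%d", day_rep, rep_idx),
    day = as.integer(day_rep),
    survival_fraction = surv_rep,
    mortality_fraction = 1 - surv_rep,
    sampling_point = factor(rep(sp_levels, replicates), levels = sp_levels),
    replicate = as.integer(rep_idx),
    batch = if (is.null(batch)) NA_character_ else as.character(batch),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}
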