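# Experimental-design power analysis: a two-tailed comparison of two
# independent means, parameterized by replicate CV and raw-scale fold
# change, using the exact noncentral-t distribution (small n makes the
# normal approximation too optimistic).

#' Standardized effect size from CV and fold change
#'
#' Converts a raw-scale fold change and replicate coefficient of variation
#' into a Cohen's d. Two conventions are supported:
#' \describe{
#'   \item{`"lognormal"` (default)}{the pipeline's own scale: intensities
#'     are log-normal, so the within-group SD on the log2 scale is
#'     `sqrt(ln(1 + cv^2)) / ln 2` and `d = log2(fc) / sd_log2`.}
#'   \item{`"raw"`}{SD proportional to the mean on the raw scale, with the
#'     pooled mean midway between the groups:
#'     `d = (fc - 1) / (cv * (1 + fc) / 2)`.}
#' }
#' For moderate CV and fold change the two agree closely (at cv = 0.3,
#' fc = 2: d = 2.36 vs 2.22).
#'
#' @param cv fractional coefficient of variation (> 0), e.g. 0.30.
#' @param fold_change raw-scale ratio >= 1 (use the reciprocal for
#'   depletion).
#' @param convention `"lognormal"` or `"raw"`.
#' @return Cohen's d.
#' @export
effect_size_d <- function(cv, fold_change,
                          convention = c("lognormal", "raw")) {
  convention <- match.arg(convention)
  stopifnot(is.numeric(cv), length(cv) == 1L,
            is.numeric(fold_change), length(fold_change) == 1L)
  if (cv <= 0) stop("cv must be > 0")
  if (fold_change < 1)
    stop("fold_change must be >= 1; use the reciprocal for depletion")
  if (convention == "lognormal") {
    log2(fold_change) / (sqrt(log1p(cv^2)) / log(2))
  } else {
    (fold_change - 1) / (cv * (1 + fold_change) / 2)
  }
}

#' Power of the two-sample comparison
#'
#' Exact power of a two-tailed two-independent-means t-test with
#' `n_per_group` replicates per group: noncentrality
#' `lambda = d * sqrt(n/2)`, `df = 2n - 2`, and
#' `power = P(|T'_{df,lambda}| > t_{1-alpha/2,df})` from the noncentral t
#' distribution. At `fold_change = 1` the power equals `alpha` (the size of
#' the test).
#'
#' @param n_per_group integer >= 2, replicates per group.
#' @inheritParams effect_size_d
#' @param alpha two-sided significance level.
#' @return the power, in `(0, 1)`.
#' @examples
#' power_two_sample(6, cv = 0.30, fold_change = 2)  # > 0.90
#' @export
power_two_sample <- function(n_per_group, cv, fold_change, alpha = 0.05,
                             convention = c("lognormal", "raw")) {
  stopifnot(is.numeric(n_per_group), length(n_per_group) == 1L,
            n_per_group == round(n_per_group))
  if (n_per_group < 2) stop("n_per_group must be >= 2")
  stopifnot(alpha > 0, alpha < 1)
  d <- effect_size_d(cv, fold_change, convention)
  df <- 2 * n_per_group - 2
  ncp <- d * sqrt(n_per_group / 2)
  tc <- qt(1 - alpha / 2, df)
  pt(-tc, df, ncp) + pt(tc, df, ncp, lower.tail = FALSE)
}

#' Smallest group size reaching a target power
#'
#' Inverts [power_two_sample()] in `n`: doubling search for an upper bound,
#' then integer bisection. Always terminates since power increases to 1
#' with `n`.
#'
#' @param target_power required power, in `(alpha, 1)`.
#' @inheritParams power_two_sample
#' @return the smallest integer `n >= 2` with
#'   `power_two_sample(n, ...) >= target_power`.
#' @examples
#' min_n_for_power(0.90, cv = 0.30, fold_change = 2)
#' @export
min_n_for_power <- function(target_power, cv, fold_change, alpha = 0.05,
                            convention = c("lognormal", "raw")) {
  convention <- match.arg(convention)
  stopifnot(is.numeric(target_power), length(target_power) == 1L)
  if (target_power <= alpha || target_power >= 1)
    stop("target_power must lie in (alpha, 1)")
  pw <- function(n) power_two_sample(n, cv, fold_change, alpha, convention)
  if (pw(2) >= target_power) return(2L)
  hi <- 2L
  while (pw(hi) < target_power) hi <- hi * 2L
  lo <- hi %/% 2L
  while (hi - lo > 1L) {
    mid <- (hi + lo) %/% 2L
    if (pw(mid) >= target_power) hi <- mid else lo <- mid
  }
  hi
}
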