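# Per-protein statistics of the enrichment pipeline: Welch's t-test,
# population fold-change z-scores, replicate CV, and the joint hit call.

#' Welch's unequal-variance two-sample t-test
#'
#' The per-protein test of the pipeline, on log2 intensities:
#' `t = (mean(x) - mean(y)) / sqrt(var(x)/nx + var(y)/ny)` with sample
#' variances, degrees of freedom by the Welch-Satterthwaite approximation,
#' and a two-sided p-value from the t distribution. `NA`s are dropped.
#'
#' Degenerate inputs are defined, not errors: zero variance in both groups
#' with equal means gives `t = 0, p = 1`; with unequal means it gives
#' `p = 0` and a warning (an infinitely confident difference is a data
#' pathology worth flagging).
#'
#' @param x,y numeric vectors (bait and control log2 intensities), each with
#'   at least 2 non-missing values.
#' @return a list with `t_stat`, `df_welch`, `p_welch` and `diff_log2`
#'   (`mean(x) - mean(y)`).
#' @export
welch_t <- function(x, y) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  if (length(x) < 2L || length(y) < 2L)
    stop("welch_t() needs at least 2 observed values per group")
  nx <- length(x)
  ny <- length(y)
  d <- mean(x) - mean(y)
  vx <- var(x)
  vy <- var(y)
  se2 <- vx / nx + vy / ny
  if (se2 == 0) {
    if (d == 0)
      return(list(t_stat = 0, df_welch = nx + ny - 2, p_welch = 1,
                  diff_log2 = 0))
    warning("zero variance in both groups with unequal means")
    return(list(t_stat = sign(d) * Inf, df_welch = nx + ny - 2, p_welch = 0,
                diff_log2 = d))
  }
  t_stat <- d / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  list(t_stat = t_stat, df_welch = df,
       p_welch = 2 * pt(-abs(t_stat), df), diff_log2 = d)
}

# Vectorized Welch over matrix rows (complete data, post-imputation).
welch_rows <- function(X, Y) {
  nx <- ncol(X)
  ny <- ncol(Y)
  mx <- rowMeans(X)
  my <- rowMeans(Y)
  vx <- rowSums((X - mx)^2) / (nx - 1)
  vy <- rowSums((Y - my)^2) / (ny - 1)
  d <- mx - my
  se2 <- vx / nx + vy / ny
  ok <- se2 > 0
  t_stat <- ifelse(ok, d / sqrt(ifelse(ok, se2, 1)), sign(d) * Inf)
  t_stat[!ok & d == 0] <- 0
  df <- ifelse(ok,
               se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1)),
               nx + ny - 2)
  p <- ifelse(ok, 2 * pt(-abs(t_stat), df), as.numeric(d == 0))
  data.frame(t_stat = t_stat, df_welch = df, p_welch = p, diff_log2 = d)
}

#' Fold-change z-scores over a protein population
#'
#' Standardizes each protein's log2 bait-minus-control difference against
#' the population of differences: `z_i = (d_i - mean(d)) / sd(d)` with the
#' sample SD. A protein's z-score therefore measures how far its fold change
#' sits above the bulk of (mostly unenriched) proteins, and the output has
#' mean 0 and sample SD 1 by construction.
#'
#' @param diffs numeric vector of log2 differences, length >= 3, complete,
#'   not constant.
#' @return the vector of z-scores, in input order.
#' @export
fold_change_zscores <- function(diffs) {
  diffs <- as.numeric(diffs)
  if (length(diffs) < 3L)
    stop("need at least 3 fold changes to standardize")
  if (anyNA(diffs)) stop("fold changes must be complete")
  s <- sd(diffs)
  if (!is.finite(s) || s == 0)
    stop("fold changes are constant; z-scores are undefined")
  (diffs - mean(diffs)) / s
}

#' Percent coefficient of variation of replicate intensities
#'
#' `100 * sd / mean` over the observed (non-missing, non-imputed) raw-scale
#' intensities of one protein in one group; the pipeline's per-protein
#' reproducibility measure.
#'
#' @param raw_values numeric vector of raw-scale intensities; `NA`s dropped.
#' @return percent CV, or `NA` when fewer than 2 values are observed or the
#'   mean is not positive (such proteins are excluded from QC averages).
#' @export
protein_cv_pct <- function(raw_values) {
  v <- raw_values[!is.na(raw_values)]
  if (length(v) < 2L) return(NA_real_)
  m <- mean(v)
  if (m <= 0) return(NA_real_)
  100 * sd(v) / m
}

#' Joint hit call
#'
#' A protein group is a hit when it passes all cutoffs jointly and strictly:
#' `p < alpha`, `z > z_cutoff` and (by default) a positive log2 difference,
#' i.e. enrichment toward the bait. The individual flags are recorded so the
#' contribution of each cutoff stays inspectable.
#'
#' @param table data frame with columns `p_welch`, `z` and `diff_log2`
#'   (`NA`s never pass).
#' @param params a [pipeline_params()] list.
#' @return `table` with logical columns `passed_p`, `passed_z`, `hit`.
#' @export
call_hits <- function(table, params) {
  stopifnot(is.data.frame(table),
            all(c("p_welch", "z", "diff_log2") %in% names(table)))
  passed_p <- !is.na(table$p_welch) & table$p_welch < params$alpha
  passed_z <- !is.na(table$z) & table$z > params$z_cutoff
  sign_ok <- if (isTRUE(params$require_positive_diff))
    !is.na(table$diff_log2) & table$diff_log2 > 0
  else
    rep(TRUE, nrow(table))
  table$passed_p <- passed_p
  table$passed_z <- passed_z
  table$hit <- passed_p & passed_z & sign_ok
  table
}
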