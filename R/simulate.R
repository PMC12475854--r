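# Synthetic LFQ generator: log-normal protein abundances, a minority of
# proteins truly enriched in the bait group, replicate noise expressed as a
# CV, and intensity-dependent (left-censored, MNAR) missingness. Gives every
# pipeline stage a ground truth to be tested against.

#' Convert between log2 replicate SD and fractional CV
#'
#' Log-normal identity: if log2 intensities have replicate SD `s`, the
#' natural-log SD is `s * ln 2` and the raw-scale coefficient of variation
#' is `cv = sqrt(exp((s ln 2)^2) - 1)`. `rep_sd_from_cv()` is the exact
#' inverse.
#'
#' @param rep_sd_log2 replicate SD on the log2 scale (>= 0).
#' @return fractional CV.
#' @export
cv_from_rep_sd <- function(rep_sd_log2) {
  stopifnot(all(rep_sd_log2 >= 0))
  sqrt(expm1((rep_sd_log2 * log(2))^2))
}

#' @rdname cv_from_rep_sd
#' @param cv fractional CV (>= 0).
#' @export
rep_sd_from_cv <- function(cv) {
  stopifnot(all(cv >= 0))
  sqrt(log1p(cv^2)) / log(2)
}

#' Simulation parameters
#'
#' The default scenario is the package's reference validation condition:
#' 5000 proteins, 5% truly enriched at 4-fold (2 on the log2 scale), 6
#' bait vs 6 control replicates, replicate noise equivalent to a 20% CV,
#' and logistic left-censoring placed to lose roughly 10% of cells.
#'
#' @param n_proteins number of protein groups.
#' @param frac_enriched fraction of proteins truly enriched in the bait
#'   group, in `[0, 1]`.
#' @param effect_log2 log2 enrichment added to bait replicates of enriched
#'   proteins; a scalar, or a length-2 range sampled uniformly per protein
#'   (2- to 50-fold enrichment corresponds to about 1 to 5.7).
#' @param n_bait,n_ctrl replicate counts per group.
#' @param baseline_mean,baseline_sd log2 abundance distribution across
#'   proteins.
#' @param rep_sd replicate noise SD on the log2 scale; see
#'   [rep_sd_from_cv()].
#' @param censor_limit log2 intensity at which a cell is missing with
#'   probability 0.5 (logistic mode) or below which it is always missing
#'   (hard mode).
#' @param censor_scale logistic steepness (> 0); smaller is closer to a
#'   hard threshold.
#' @param censor_mode `"logistic"` (default; keeps every protein testable
#'   while making low values stochastically more likely to vanish) or
#'   `"hard"` for worst-case tests.
#' @return a list of class `sim_params`.
#' @export
sim_params <- function(n_proteins = 5000, frac_enriched = 0.05,
                       effect_log2 = 2, n_bait = 6, n_ctrl = 6,
                       baseline_mean = 25, baseline_sd = 2.5,
                       rep_sd = rep_sd_from_cv(0.20),
                       censor_limit = 21.8, censor_scale = 0.5,
                       censor_mode = c("logistic", "hard")) {
  censor_mode <- match.arg(censor_mode)
  stopifnot(n_proteins >= 1, n_bait >= 2, n_ctrl >= 2,
            frac_enriched >= 0, frac_enriched <= 1,
            length(effect_log2) %in% c(1L, 2L), all(effect_log2 >= 0),
            baseline_sd > 0, rep_sd >= 0, censor_scale > 0)
  structure(list(n_proteins = as.integer(n_proteins),
                 frac_enriched = frac_enriched,
                 effect_log2 = effect_log2,
                 n_bait = as.integer(n_bait), n_ctrl = as.integer(n_ctrl),
                 baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                 rep_sd = rep_sd, censor_limit = censor_limit,
                 censor_scale = censor_scale, censor_mode = censor_mode),
            class = "sim_params")
}

#' Simulate an LFQ bait-vs-control experiment with known ground truth
#'
#' Per protein `i`, a log2 baseline `mu_i ~ Normal(baseline_mean,
#' baseline_sd^2)`; the log2 value in sample `j` is `mu_i + effect_i` (bait
#' samples of enriched proteins only) plus `Normal(0, rep_sd^2)` replicate
#' noise; the raw intensity is `2^value`. Each cell then goes missing
#' independently with probability `logistic((censor_limit - value) /
#' censor_scale)` — lower-abundance cells are more likely to vanish, the
#' missing-not-at-random pattern that downshifted imputation assumes.
#' Deterministic given `params` and `seed`.
#'
#' @param params a [sim_params()] list.
#' @param seed integer seed.
#' @return a list with `matrix` (raw-scale [intensity_matrix()]), `design`
#'   (a [group_design()], groups `"bait"` and `"control"`), and `truth`
#'   (class `synthetic_truth`: `protein_ids`, `enriched_ids`, per-protein
#'   `effect_log2`, the `params` echo and `seed`).
#' @export
simulate_lfq <- function(params = sim_params(), seed = 1L) {
  stopifnot(inherits(params, "sim_params"))
  p <- params
  set.seed(as.integer(seed))
  n <- p$n_proteins
  ns <- p$n_bait + p$n_ctrl
  ids <- sprintf("PG%05d", seq_len(n))
  genes <- sprintf("Gene%05d", seq_len(n))
  n_enr <- round(p$frac_enriched * n)
  enriched <- if (n_enr) sort(sample.int(n, n_enr)) else integer(0)
  eff <- numeric(n)
  if (n_enr)
    eff[enriched] <- if (length(p$effect_log2) == 2L)
      runif(n_enr, p$effect_log2[1L], p$effect_log2[2L])
    else p$effect_log2
  mu <- rnorm(n, p$baseline_mean, p$baseline_sd)
  sams <- c(sprintf("bait_%02d", seq_len(p$n_bait)),
            sprintf("ctrl_%02d", seq_len(p$n_ctrl)))
  is_bait <- rep(c(TRUE, FALSE), c(p$n_bait, p$n_ctrl))
  lv <- matrix(mu, n, ns) + outer(eff, as.numeric(is_bait)) +
        matrix(rnorm(n * ns, 0, p$rep_sd), n, ns)
  p_miss <- if (p$censor_mode == "logistic")
    plogis((p$censor_limit - lv) / p$censor_scale)
  else
    (lv < p$censor_limit) * 1
  miss <- matrix(runif(n * ns), n, ns) < p_miss
  raw <- 2^lv
  raw[miss] <- NA_real_
  dimnames(raw) <- list(ids, sams)
  m <- intensity_matrix(raw, gene_symbols = genes, scale = "raw")
  design <- group_design(setNames(ifelse(is_bait, "bait", "control"), sams),
                         bait_group = "bait", control_group = "control")
  truth <- structure(list(protein_ids = ids, enriched_ids = ids[enriched],
                          effect_log2 = setNames(eff, ids),
                          params = p, seed = as.integer(seed)),
                     class = "synthetic_truth")
  list(matrix = m, design = design, truth = truth)
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("<synthetic_truth> %d proteins, %d enriched (seed %d)\n",
              length(x$protein_ids), length(x$enriched_ids), x$seed))
  invisible(x)
}

#' Score a call set against the simulation ground truth
#'
#' @param truth a `synthetic_truth` from [simulate_lfq()].
#' @param calls a `proximity_enrichment` fit or enrichment table over the
#'   same protein universe.
#' @return list with `sensitivity` (`TP / n_enriched`; `NA` when nothing is
#'   enriched), `empirical_fdr` (`FP / max(1, n_hits)`, so an empty call
#'   set scores 0), and the `tp`, `fp`, `fn`, `n_hits` counts.
#' @export
evaluate_calls <- function(truth, calls) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (inherits(calls, "proximity_enrichment")) calls <- calls$table
  stopifnot(is.data.frame(calls),
            all(c("protein_id", "hit") %in% names(calls)))
  if (!setequal(calls$protein_id, truth$protein_ids))
    stop("call table and truth cover different protein universes")
  hit_ids <- calls$protein_id[calls$hit %in% TRUE]
  tp <- length(intersect(hit_ids, truth$enriched_ids))
  fp <- length(setdiff(hit_ids, truth$enriched_ids))
  fn <- length(setdiff(truth$enriched_ids, hit_ids))
  list(sensitivity = if (length(truth$enriched_ids))
         tp / length(truth$enriched_ids) else NA_real_,
       empirical_fdr = fp / max(1, length(hit_ids)),
       tp = tp, fp = fp, fn = fn, n_hits = length(hit_ids))
}
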