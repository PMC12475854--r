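#' Pipeline parameters
#'
#' Every threshold of the enrichment pipeline in one validated list. The
#' defaults are the cultured-cell (n = 3 per group) parameterization:
#' complete observation required in at least one group and imputation with
#' width 0.5 / downshift 1.6. See [pipeline_preset()] for the named presets.
#'
#' @param min_valid_fraction completeness fraction required in at least one
#'   group, in `[0, 1]`.
#' @param impute_width,impute_downshift imputation shape in observed-SD
#'   units; see [impute_left_censored()].
#' @param alpha two-sided significance level for the Welch test (strict:
#'   `p < alpha`).
#' @param z_cutoff fold-change z-score cutoff (strict: `z > z_cutoff`);
#'   1 for the primary call set, 2 for a stricter view.
#' @param cv_qc_limit_pct dataset-level QC bound on the average percent CV
#'   over the hit set.
#' @param require_positive_diff demand enrichment toward the bait
#'   (`diff_log2 > 0`).
#' @param seed integer root seed for the imputation draws.
#' @param impute_mode `"column"` or `"matrix"`; see
#'   [impute_left_censored()].
#' @param z_population which proteins define the z-score mean/SD:
#'   `"filtered"` (all proteins passing the completeness filter; default,
#'   the less selection-biased choice) or `"significant"` (only proteins
#'   with `p < alpha`).
#' @param cv_group samples used for the per-protein CV: `"bait"` (default)
#'   or `"pooled"` (both groups).
#' @return a list of class `pipeline_params`.
#' @export
pipeline_params <- function(min_valid_fraction = 1.0,
                            impute_width = 0.5,
                            impute_downshift = 1.6,
                            alpha = 0.05,
                            z_cutoff = 1,
                            cv_qc_limit_pct = 30,
                            require_positive_diff = TRUE,
                            seed = 1L,
                            impute_mode = c("column", "matrix"),
                            z_population = c("filtered", "significant"),
                            cv_group = c("bait", "pooled")) {
  p <- list(min_valid_fraction = as.numeric(min_valid_fraction),
            impute_width = as.numeric(impute_width),
            impute_downshift = as.numeric(impute_downshift),
            alpha = as.numeric(alpha),
            z_cutoff = as.numeric(z_cutoff),
            cv_qc_limit_pct = as.numeric(cv_qc_limit_pct),
            require_positive_diff = isTRUE(require_positive_diff),
            seed = as.integer(seed),
            impute_mode = match.arg(impute_mode),
            z_population = match.arg(z_population),
            cv_group = match.arg(cv_group))
  stopifnot(p$min_valid_fraction >= 0, p$min_valid_fraction <= 1,
            p$impute_width > 0, p$impute_downshift >= 0,
            p$alpha > 0, p$alpha < 1, p$cv_qc_limit_pct > 0,
            !is.na(p$seed))
  class(p) <- "pipeline_params"
  p
}

#' Named parameter presets
#'
#' Two complete parameterizations of the pipeline: `"n2a"` for small
#' cultured-cell designs (n = 3 per group: completeness 1.0, imputation
#' width 0.5 / downshift 1.6) and `"brain"` for larger tissue designs
#' (completeness 0.75, width 0.4 / downshift 1.7). Both use alpha = 0.05,
#' z > 1, positive-difference requirement and a 30% CV QC bound.
#'
#' @param name `"n2a"` or `"brain"`.
#' @param ... overrides passed on to [pipeline_params()].
#' @return a [pipeline_params()] list.
#' @export
pipeline_preset <- function(name = c("n2a", "brain"), ...) {
  name <- match.arg(name)
  base <- switch(name,
                 n2a   = list(min_valid_fraction = 1.0, impute_width = 0.5,
                              impute_downshift = 1.6),
                 brain = list(min_valid_fraction = 0.75, impute_width = 0.4,
                              impute_downshift = 1.7))
  do.call(pipeline_params, utils::modifyList(base, list(...)))
}

#' @export
print.pipeline_params <- function(x, ...) {
  cat(sprintf(paste0("<pipeline_params> completeness >= %g in one group; ",
                     "impute width %g, downshift %g (%s-wise); p < %g; z > %g; ",
                     "positive diff: %s; CV QC < %g%%; seed %d\n"),
              x$min_valid_fraction, x$impute_width, x$impute_downshift,
              x$impute_mode, x$alpha, x$z_cutoff,
              x$require_positive_diff, x$cv_qc_limit_pct, x$seed))
  invisible(x)
}

#' Fit the proximity-labeling enrichment model
#'
#' The central function of the package. Runs, in order: base-2 log
#' transform, group-completeness filter, left-censored Gaussian imputation
#' (seeded), a per-protein Welch t-test of bait versus control, fold-change
#' z-scores over the filtered population, the joint hit call
#' (`p < alpha`, `z > z_cutoff`, positive difference), and a CV-based QC
#' summary of the hit set. The reported `ratio` is `2^diff_log2`, the
#' geometric-mean bait/control ratio.
#'
#' @param m an [intensity_matrix()] of raw-scale LFQ intensities.
#' @param design a [group_design()] covering all samples of `m`.
#' @param params a [pipeline_params()] list (thresholds, imputation shape,
#'   seed).
#' @return An object of class `proximity_enrichment` with elements:
#'   \describe{
#'     \item{table}{data frame with one row per input protein group:
#'       `protein_id, gene, n_valid_bait, n_valid_ctrl, diff_log2, ratio,
#'       t_stat, df_welch, p_welch, z, cv_bait_pct, passed_filter, passed_p,
#'       passed_z, hit`. Rows failing the completeness filter keep their
#'       valid counts but carry `NA` statistics and `hit = FALSE`.}
#'     \item{qc}{list with `n_tested`, `n_hits`, `average_cv_pct`,
#'       `median_cv_pct` over the hit set, the QC limit and `pass_cv_qc`.}
#'     \item{imputed}{the complete log2-scale matrix of filtered proteins
#'       actually tested.}
#'     \item{params, design, call}{the inputs, echoed.}
#'   }
#' @seealso [hits()], [write_enrichment_table()], [gene_level_overlap()],
#'   [evaluate_calls()]
#' @examples
#' sim <- simulate_lfq(sim_params(n_proteins = 300), seed = 7)
#' fit <- proximity_enrichment(sim$matrix, sim$design)
#' fit
#' head(hits(fit))
#' @export
proximity_enrichment <- function(m, design, params = pipeline_params()) {
  stopifnot(inherits(m, "intensity_matrix"), inherits(design, "group_design"),
            inherits(params, "pipeline_params"))
  cols <- design_columns(m, design)

  lm <- log2_transform(m)
  vb <- rowSums(!is.na(lm$values[, cols$bait, drop = FALSE]))
  vc <- rowSums(!is.na(lm$values[, cols$ctrl, drop = FALSE]))
  keep <- (vb / length(cols$bait) >= params$min_valid_fraction) |
          (vc / length(cols$ctrl) >= params$min_valid_fraction)
  if (!any(keep)) warning("no protein group passed the completeness filter")

  tab <- data.frame(protein_id = protein_ids(m),
                    gene = m$gene_symbols,
                    n_valid_bait = as.integer(vb),
                    n_valid_ctrl = as.integer(vc),
                    diff_log2 = NA_real_, ratio = NA_real_,
                    t_stat = NA_real_, df_welch = NA_real_,
                    p_welch = NA_real_, z = NA_real_,
                    cv_bait_pct = NA_real_,
                    passed_filter = keep,
                    stringsAsFactors = FALSE)
  rownames(tab) <- NULL

  imputed <- NULL
  if (any(keep)) {
    im <- impute_left_censored(lm[keep, ], params$impute_width,
                               params$impute_downshift, params$seed,
                               mode = params$impute_mode)
    w <- welch_rows(im$values[, cols$bait, drop = FALSE],
                    im$values[, cols$ctrl, drop = FALSE])
    tab$diff_log2[keep] <- w$diff_log2
    tab$ratio[keep] <- 2^w$diff_log2
    tab$t_stat[keep] <- w$t_stat
    tab$df_welch[keep] <- w$df_welch
    tab$p_welch[keep] <- w$p_welch

    zpop <- if (params$z_population == "filtered") rep(TRUE, nrow(w))
            else !is.na(w$p_welch) & w$p_welch < params$alpha
    if (sum(zpop) >= 3L && sd(w$diff_log2[zpop]) > 0) {
      z <- rep(NA_real_, nrow(w))
      z[zpop] <- fold_change_zscores(w$diff_log2[zpop])
      tab$z[keep] <- z
    } else {
      warning("z-score population too small or degenerate; z left NA")
    }

    cv_cols <- if (params$cv_group == "bait") cols$bait
               else c(cols$bait, cols$ctrl)
    tab$cv_bait_pct[keep] <- apply(m$values[keep, cv_cols, drop = FALSE],
                                   1L, protein_cv_pct)
    imputed <- im
  }

  tab <- call_hits(tab, params)
  cvh <- tab$cv_bait_pct[tab$hit]
  cvh <- cvh[!is.na(cvh)]
  qc <- list(n_tested = sum(keep),
             n_hits = sum(tab$hit),
             average_cv_pct = if (length(cvh)) mean(cvh) else NA_real_,
             median_cv_pct = if (length(cvh)) median(cvh) else NA_real_,
             cv_qc_limit_pct = params$cv_qc_limit_pct,
             pass_cv_qc = if (length(cvh)) mean(cvh) < params$cv_qc_limit_pct
                          else NA)
  structure(list(table = tab, qc = qc, params = params, design = design,
                 imputed = imputed, n_input = nrow(tab),
                 call = match.call()),
            class = "proximity_enrichment")
}

#' Extract the called hit set
#' @param x a `proximity_enrichment` fit.
#' @param ... unused.
#' @return the rows of the enrichment table flagged as hits.
#' @export
hits <- function(x, ...) UseMethod("hits")

#' @rdname hits
#' @export
hits.proximity_enrichment <- function(x, ...) {
  x$table[x$table$hit, , drop = FALSE]
}

#' @export
as.data.frame.proximity_enrichment <- function(x, ...) x$table

#' @export
print.proximity_enrichment <- function(x, ...) {
  cat("Proximity-labeling enrichment fit\n")
  cat(sprintf("  %d protein groups; %d passed the completeness filter; %d hits\n",
              x$n_input, x$qc$n_tested, x$qc$n_hits))
  cat(sprintf("  cutoffs: p < %g, z > %g%s\n", x$params$alpha,
              x$params$z_cutoff,
              if (x$params$require_positive_diff) ", diff_log2 > 0" else ""))
  if (!is.na(x$qc$average_cv_pct))
    cat(sprintf("  hit-set CV: average %.1f%%, median %.1f%% (QC limit %g%%: %s)\n",
                x$qc$average_cv_pct, x$qc$median_cv_pct,
                x$qc$cv_qc_limit_pct,
                if (isTRUE(x$qc$pass_cv_qc)) "pass" else "FAIL"))
  invisible(x)
}

#' @export
summary.proximity_enrichment <- function(object, n_top = 10L, ...) {
  h <- hits(object)
  h <- h[order(-h$z, h$p_welch), , drop = FALSE]
  structure(list(qc = object$qc, params = object$params,
                 n_input = object$n_input,
                 top = utils::head(h[, c("protein_id", "gene", "diff_log2",
                                         "ratio", "p_welch", "z",
                                         "cv_bait_pct")], n_top)),
            class = "summary.proximity_enrichment")
}

#' @export
print.summary.proximity_enrichment <- function(x, ...) {
  cat(sprintf("Enrichment of %d protein groups: %d tested, %d hits\n",
              x$n_input, x$qc$n_tested, x$qc$n_hits))
  print(x$params)
  if (nrow(x$top)) {
    cat("Top hits by z-score:\n")
    print(format(x$top, digits = 3), row.names = FALSE)
  }
  invisible(x)
}

#' Volcano plot of an enrichment fit
#'
#' log2 bait-minus-control difference against -log10 Welch p-value over the
#' tested proteins, with the called hits highlighted.
#'
#' @param x a `proximity_enrichment` fit.
#' @param ... passed to [plot()].
#' @return `x`, invisibly.
#' @export
plot.proximity_enrichment <- function(x, ...) {
  t <- x$table[x$table$passed_filter, , drop = FALSE]
  if (!nrow(t)) stop("nothing to plot: no protein passed the filter")
  lp <- -log10(pmax(t$p_welch, .Machine$double.xmin))
  plot(t$diff_log2, lp, pch = 16, cex = 0.5,
       col = ifelse(t$hit, "firebrick", "grey60"),
       xlab = "t-test difference (log2 bait - control)",
       ylab = "-log10 Welch p-value", ...)
  abline(h = -log10(x$params$alpha), lty = 2, col = "grey40")
  abline(v = 0, lty = 3, col = "grey40")
  legend("topleft", pch = 16, col = c("firebrick", "grey60"),
         legend = c(sprintf("hit (n=%d)", sum(t$hit)), "tested"),
         bty = "n", cex = 0.8)
  invisible(x)
}

#' Write the one-row QC summary of a fit as TSV
#' @param fit a `proximity_enrichment` fit.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_qc_summary <- function(fit, path) {
  stopifnot(inherits(fit, "proximity_enrichment"))
  df <- as.data.frame(fit$qc)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
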