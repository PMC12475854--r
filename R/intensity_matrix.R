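#' Protein-group by sample intensity matrix
#'
#' In-memory container for label-free quantification (LFQ) intensities:
#' a numeric grid with one row per protein group and one column per sample.
#' Missing cells (not identified / not quantified in that run) are `NA`.
#' The `scale` field records whether values are raw intensities or their
#' base-2 logarithms; downstream stages check it so a matrix is never
#' log-transformed twice or imputed on the raw scale.
#'
#' @param values numeric matrix with protein-group ids as `rownames` and
#'   sample ids as `colnames`; `NA` marks missing cells. On the raw scale
#'   every present value must be finite and strictly positive.
#' @param gene_symbols character vector, one per row; may repeat across
#'   isoform rows and may be empty (`""`) where no symbol is annotated.
#' @param scale `"raw"` or `"log2"`.
#'
#' @return An object of class `intensity_matrix`: a list with elements
#'   `values`, `gene_symbols` and `scale`.
#' @seealso [read_protein_matrix()], [log2_transform()],
#'   [filter_by_completeness()], [impute_left_censored()]
#' @export
intensity_matrix <- function(values, gene_symbols = NULL,
                             scale = c("raw", "log2")) {
  scale <- match.arg(scale)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values)))
    stop("`values` must carry protein-group ids as rownames")
  if (is.null(colnames(values)))
    stop("`values` must carry sample ids as colnames")
  if (anyDuplicated(rownames(values))) {
    dup <- rownames(values)[duplicated(rownames(values))][1L]
    stop("duplicate protein-group id: ", dup)
  }
  if (anyDuplicated(colnames(values))) {
    dup <- colnames(values)[duplicated(colnames(values))][1L]
    stop("duplicate sample id: ", dup)
  }
  if (is.null(gene_symbols)) gene_symbols <- rep("", nrow(values))
  gene_symbols <- as.character(gene_symbols)
  gene_symbols[is.na(gene_symbols)] <- ""
  if (length(gene_symbols) != nrow(values))
    stop("`gene_symbols` must have one entry per protein group")
  present <- values[!is.na(values)]
  if (any(!is.finite(present)))
    stop("present intensities must be finite")
  if (scale == "raw" && any(present <= 0))
    stop("raw-scale intensities must be strictly positive")
  structure(list(values = values, gene_symbols = gene_symbols, scale = scale),
            class = "intensity_matrix")
}

#' @export
dim.intensity_matrix <- function(x) dim(x$values)

#' Protein-group and sample identifiers of an intensity matrix
#' @param m an [intensity_matrix()]
#' @return character vector of row (protein-group) or column (sample) ids.
#' @export
protein_ids <- function(m) {
  stopifnot(inherits(m, "intensity_matrix"))
  rownames(m$values)
}

#' @rdname protein_ids
#' @export
sample_ids <- function(m) {
  stopifnot(inherits(m, "intensity_matrix"))
  colnames(m$values)
}

#' @export
`[.intensity_matrix` <- function(x, i, j) {
  if (missing(i)) i <- seq_len(nrow(x$values))
  if (missing(j)) j <- seq_len(ncol(x$values))
  ri <- if (is.character(i)) match(i, rownames(x$values)) else i
  out <- x
  out$values <- x$values[i, j, drop = FALSE]
  out$gene_symbols <- x$gene_symbols[ri]
  out
}

#' @export
print.intensity_matrix <- function(x, ...) {
  cat(sprintf("<intensity_matrix> %d protein groups x %d samples (%s scale), %.1f%% missing\n",
              nrow(x$values), ncol(x$values), x$scale,
              100 * mean(is.na(x$values))))
  invisible(x)
}

#' Base-2 log transform of an intensity matrix
#'
#' Replaces every present value by its base-2 logarithm; the missing-value
#' mask is unchanged. The pipeline's filtering, imputation and testing all
#' operate on this scale.
#'
#' @param m an [intensity_matrix()] on the raw scale (all present values > 0).
#' @return the matrix on the log2 scale.
#' @export
log2_transform <- function(m) {
  stopifnot(inherits(m, "intensity_matrix"))
  if (m$scale == "log2") stop("matrix is already on the log2 scale")
  v <- m$values
  if (any(v[!is.na(v)] <= 0))
    stop("cannot log2-transform non-positive intensities")
  m$values <- log2(v)
  m$scale <- "log2"
  m
}

#' Sample-to-group design for a two-group comparison
#'
#' Assigns each sample to one of exactly two groups: the bait fusion
#' (e.g. a TurboID-tagged protein of interest) and the spatial-reference
#' control (e.g. a freely diffusing cytosolic ligase). Each group needs at
#' least two samples so that within-group variance is estimable.
#'
#' @param assignments named character vector, sample id -> group label.
#' @param bait_group,control_group the two group labels. If omitted,
#'   `bait_group` defaults to the group of the first sample and
#'   `control_group` to the other label.
#' @return An object of class `group_design`.
#' @export
group_design <- function(assignments, bait_group = NULL, control_group = NULL) {
  if (is.null(names(assignments)) || any(!nzchar(names(assignments))))
    stop("`assignments` must be a named vector (sample id -> group label)")
  if (anyDuplicated(names(assignments)))
    stop("duplicate sample id in design: ",
         names(assignments)[duplicated(names(assignments))][1L])
  assignments <- setNames(as.character(assignments), names(assignments))
  groups <- unique(assignments)
  if (length(groups) != 2L)
    stop("design must contain exactly two group labels, got: ",
         paste(groups, collapse = ", "))
  if (is.null(bait_group)) bait_group <- assignments[[1L]]
  if (is.null(control_group)) control_group <- setdiff(groups, bait_group)
  if (!bait_group %in% groups) stop("bait group '", bait_group, "' not in design")
  if (!control_group %in% groups)
    stop("control group '", control_group, "' not in design")
  if (bait_group == control_group)
    stop("bait and control group must differ")
  for (g in c(bait_group, control_group))
    if (sum(assignments == g) < 2L)
      stop("group '", g, "' has fewer than 2 samples; variance is not estimable")
  structure(list(assignments = assignments, bait_group = bait_group,
                 control_group = control_group),
            class = "group_design")
}

#' @export
print.group_design <- function(x, ...) {
  cat(sprintf("<group_design> bait '%s' (n=%d) vs control '%s' (n=%d)\n",
              x$bait_group, sum(x$assignments == x$bait_group),
              x$control_group, sum(x$assignments == x$control_group)))
  invisible(x)
}

#' Read a two-column sample design table
#'
#' @param path tab-separated file with a header row and two columns:
#'   sample id and group label.
#' @inheritParams group_design
#' @return a [group_design()].
#' @export
read_design <- function(path, bait_group = NULL, control_group = NULL) {
  df <- read.delim(path, header = TRUE, sep = "\t", colClasses = "character",
                   check.names = FALSE)
  if (ncol(df) < 2L) stop("design table needs two columns (sample_id, group)")
  group_design(setNames(df[[2L]], df[[1L]]),
               bait_group = bait_group, control_group = control_group)
}

#' Group-completeness filter
#'
#' Retains a protein group when the fraction of present (quantified) values
#' reaches `min_valid_fraction` in *at least one* of the two groups, i.e.
#' OR semantics: a protein fully observed in the bait group but never in the
#' control group is kept (it is exactly the kind of candidate a
#' bait-over-control design looks for). Row order is preserved.
#'
#' @param m an [intensity_matrix()] (either scale; the mask is what counts).
#' @param design a [group_design()] covering all samples of `m`.
#' @param min_valid_fraction required fraction of present values in a group,
#'   in `[0, 1]` (1 demands complete observation in one group; 0.75 allows
#'   e.g. 9 of 11).
#' @return the filtered matrix. An empty result triggers a warning, not an
#'   error.
#' @export
filter_by_completeness <- function(m, design, min_valid_fraction) {
  stopifnot(inherits(m, "intensity_matrix"), inherits(design, "group_design"))
  stopifnot(is.numeric(min_valid_fraction), length(min_valid_fraction) == 1L,
            min_valid_fraction >= 0, min_valid_fraction <= 1)
  cols <- design_columns(m, design)
  vb <- rowSums(!is.na(m$values[, cols$bait, drop = FALSE]))
  vc <- rowSums(!is.na(m$values[, cols$ctrl, drop = FALSE]))
  keep <- (vb / length(cols$bait) >= min_valid_fraction) |
          (vc / length(cols$ctrl) >= min_valid_fraction)
  if (!any(keep)) warning("no protein group passed the completeness filter")
  m[keep, ]
}

# Map a design onto the matrix columns; errors on uncovered samples.
design_columns <- function(m, design) {
  sams <- sample_ids(m)
  uncovered <- setdiff(sams, names(design$assignments))
  if (length(uncovered))
    stop("design does not cover sample(s): ", paste(uncovered, collapse = ", "))
  grp <- design$assignments[sams]
  bait <- sams[grp == design$bait_group]
  ctrl <- sams[grp == design$control_group]
  if (length(bait) < 2L || length(ctrl) < 2L)
    stop("each group needs at least 2 samples present in the matrix")
  list(bait = bait, ctrl = ctrl)
}
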