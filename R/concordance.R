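#' Gene-level overlap of two enrichment call sets
#'
#' Compares the hit sets of two datasets (e.g. an in vitro cell line and an
#' in vivo tissue) at the gene level: protein-group isoforms are first
#' collapsed to gene symbols via [collapse_to_genes()] (rows without a
#' symbol fall back to their protein-group id), then the shared and unique
#' gene sets are computed. By default symbols are trimmed and upper-cased
#' before matching, since datasets from different species conventions mix
#' capitalizations ("Bin1" vs "BIN1").
#'
#' @param hits_a,hits_b `proximity_enrichment` fits or enrichment-table data
#'   frames (only rows with `hit == TRUE` enter the comparison).
#' @param normalize_case match case-insensitively (default `TRUE`).
#' @param labels length-2 character, names of the two datasets for printing.
#' @return An object of class `concordance`: list with `shared`,
#'   `unique_a`, `unique_b` (character vectors), their counts `n_shared`,
#'   `n_unique_a`, `n_unique_b`, per-dataset gene totals `n_a`, `n_b`, and
#'   `labels`.
#' @export
gene_level_overlap <- function(hits_a, hits_b, normalize_case = TRUE,
                               labels = c("a", "b")) {
  ga <- hit_genes(hits_a, normalize_case)
  gb <- hit_genes(hits_b, normalize_case)
  shared <- intersect(ga, gb)
  structure(list(shared = shared,
                 unique_a = setdiff(ga, gb),
                 unique_b = setdiff(gb, ga),
                 n_shared = length(shared),
                 n_unique_a = length(setdiff(ga, gb)),
                 n_unique_b = length(setdiff(gb, ga)),
                 n_a = length(ga), n_b = length(gb),
                 labels = as.character(labels)),
            class = "concordance")
}

hit_genes <- function(x, normalize_case) {
  if (inherits(x, "proximity_enrichment")) x <- x$table
  stopifnot(is.data.frame(x),
            all(c("protein_id", "hit") %in% names(x)))
  g <- if ("gene" %in% names(x)) x$gene else NULL
  h <- x$hit %in% TRUE
  collapse_to_genes(x$protein_id[h], g[h],
                    normalize_case = normalize_case)$genes
}

#' @export
print.concordance <- function(x, ...) {
  cat(sprintf("Gene-level concordance (%s vs %s)\n", x$labels[1], x$labels[2]))
  cat(sprintf("  %s: %d genes (%d unique)\n", x$labels[1], x$n_a, x$n_unique_a))
  cat(sprintf("  %s: %d genes (%d unique)\n", x$labels[2], x$n_b, x$n_unique_b))
  cat(sprintf("  shared: %d\n", x$n_shared))
  invisible(x)
}

#' Write a concordance result as a long TSV
#'
#' Two columns: `set` (`shared`, `unique_<label a>`, `unique_<label b>`) and
#' `gene`.
#'
#' @param x a `concordance` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_concordance <- function(x, path) {
  stopifnot(inherits(x, "concordance"))
  sets <- list(shared = x$shared, a = x$unique_a, b = x$unique_b)
  names(sets) <- c("shared", paste0("unique_", x$labels[1]),
                   paste0("unique_", x$labels[2]))
  df <- do.call(rbind, lapply(names(sets), function(nm) {
    if (!length(sets[[nm]])) return(NULL)
    data.frame(set = nm, gene = sets[[nm]], stringsAsFactors = FALSE)
  }))
  if (is.null(df))
    df <- data.frame(set = character(0), gene = character(0))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
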