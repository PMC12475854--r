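# File formats: wide protein-group TSV (DIA-NN pg_matrix dialect), the
# enrichment-table TSV, and GMT gene-set collections.

# Column names written by write_enrichment_table, in order.
enrichment_columns <- c("protein_id", "gene", "n_valid_bait", "n_valid_ctrl",
                        "diff_log2", "ratio", "p_welch", "z", "cv_bait_pct",
                        "hit")

norm_name <- function(x) gsub("[^a-z0-9]+", ".", tolower(trimws(x)))

#' Read a wide protein-group intensity matrix
#'
#' Reads a tab-separated protein-group x sample table in the dialect of
#' DIA-NN's `pg_matrix` output: a header row, a leading block of annotation
#' columns, then one numeric column per sample. Annotation columns are
#' auto-detected as the leading run of columns whose names match
#' `annotation_cols` (case- and punctuation-insensitive); everything after is
#' treated as a sample.
#'
#' Blank cells, any token in `missing_codes` and (by default, matching the
#' DIA-NN matrix convention) exact zeros are read as missing.
#'
#' @param path path to the TSV file (UTF-8, `.` decimal point).
#' @param missing_codes character tokens to treat as missing.
#' @param zero_is_missing treat a numeric 0 as missing.
#' @param annotation_cols names recognized as annotation columns; the
#'   defaults cover the DIA-NN pg_matrix header.
#' @param id_col,gene_col override which annotation column supplies the
#'   protein-group id (default: the first annotation column) and the gene
#'   symbol (default: a column named `Genes`, if present).
#' @return an [intensity_matrix()] on the raw scale.
#' @export
read_protein_matrix <- function(path,
                                missing_codes = c("", "NA", "NaN"),
                                zero_is_missing = TRUE,
                                annotation_cols = c("Protein.Group",
                                                    "Protein.Ids",
                                                    "Protein.Names", "Genes",
                                                    "First.Protein.Description",
                                                    "Description"),
                                id_col = NULL, gene_col = NULL) {
  raw <- read.delim(path, header = TRUE, sep = "\t", colClasses = "character",
                    check.names = FALSE, quote = "",
                    na.strings = character(0))
  if (!nrow(raw) || !ncol(raw)) stop("empty matrix file: ", path)
  nn <- norm_name(names(raw))
  is_ann <- nn %in% norm_name(annotation_cols)
  n_ann <- if (is_ann[1L]) rle(is_ann)$lengths[1L] else 0L
  if (n_ann == 0L)
    stop("no recognized annotation column at the left of ", path,
         "; pass `annotation_cols` naming them")
  if (n_ann >= ncol(raw)) stop("no sample columns found in ", path)
  sample_cols <- names(raw)[(n_ann + 1L):ncol(raw)]
  if (anyDuplicated(sample_cols))
    stop("duplicate sample name: ", sample_cols[duplicated(sample_cols)][1L])

  if (is.null(id_col)) id_col <- names(raw)[1L]
  if (!id_col %in% names(raw)) stop("id column '", id_col, "' not found")
  ids <- raw[[id_col]]
  if (anyDuplicated(ids))
    stop("duplicate protein-group id: ", ids[duplicated(ids)][1L])

  if (is.null(gene_col)) {
    gi <- which(nn[seq_len(n_ann)] == "genes")
    gene_col <- if (length(gi)) names(raw)[gi[1L]] else NULL
  }
  genes <- if (is.null(gene_col)) rep("", nrow(raw)) else raw[[gene_col]]

  vm <- matrix(NA_real_, nrow(raw), length(sample_cols),
               dimnames = list(ids, sample_cols))
  for (k in seq_along(sample_cols)) {
    tok <- trimws(raw[[sample_cols[k]]])
    miss <- tok %in% missing_codes
    num <- suppressWarnings(as.numeric(tok))
    bad <- !miss & is.na(num)
    if (any(bad)) {
      i <- which(bad)[1L]
      stop(sprintf("non-numeric value '%s' in column '%s', row %d of %s",
                   tok[i], sample_cols[k], i, path))
    }
    if (zero_is_missing) miss <- miss | (!is.na(num) & num == 0)
    num[miss] <- NA_real_
    vm[, k] <- num
  }
  intensity_matrix(vm, gene_symbols = genes, scale = "raw")
}

#' Write an intensity matrix as a wide TSV
#'
#' Inverse of [read_protein_matrix()]: writes a `Protein.Group` id column, a
#' `Genes` column and one column per sample. Missing cells are written as
#' blanks; present values are written with 17 significant digits so the
#' read/write round trip is exact.
#'
#' @param m an [intensity_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_protein_matrix <- function(m, path) {
  stopifnot(inherits(m, "intensity_matrix"))
  fmt <- function(v) ifelse(is.na(v), "", sprintf("%.17g", v))
  df <- data.frame(Protein.Group = protein_ids(m), Genes = m$gene_symbols,
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- c("Protein.Group", "Genes")
  for (s in sample_ids(m)) df[[s]] <- fmt(m$values[, s])
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read the per-protein enrichment table
#'
#' The on-disk schema is a tab-separated file with the fixed column set
#' `protein_id, gene, n_valid_bait, n_valid_ctrl, diff_log2, ratio, p_welch,
#' z, cv_bait_pct, hit`. Numeric fields are written with 12 significant
#' digits, so a write/read round trip reproduces them to that precision;
#' `hit` is written as `TRUE`/`FALSE` and unavailable values as `NA`.
#'
#' @param table a [proximity_enrichment()] fit or its `$table` data frame
#'   (extra columns such as `t_stat` are allowed and ignored on write).
#' @param path file path.
#' @return `write_enrichment_table()` returns `path` invisibly;
#'   `read_enrichment_table()` returns a data frame with the schema above.
#' @export
write_enrichment_table <- function(table, path) {
  if (inherits(table, "proximity_enrichment")) table <- table$table
  stopifnot(is.data.frame(table))
  missing_cols <- setdiff(enrichment_columns, names(table))
  if (length(missing_cols))
    stop("enrichment table lacks column(s): ", paste(missing_cols, collapse = ", "))
  df <- table[, enrichment_columns, drop = FALSE]
  out <- df
  for (cn in enrichment_columns) {
    v <- df[[cn]]
    out[[cn]] <- if (is.numeric(v)) {
      ifelse(is.na(v), "NA", sprintf("%.12g", v))
    } else if (is.logical(v)) {
      ifelse(is.na(v), "NA", ifelse(v, "TRUE", "FALSE"))
    } else {
      as.character(v)
    }
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_enrichment_table
#' @export
read_enrichment_table <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   colClasses = "character", na.strings = "NA", quote = "")
  missing_cols <- setdiff(enrichment_columns, names(df))
  if (length(missing_cols))
    stop("not an enrichment table (missing ",
         paste(missing_cols, collapse = ", "), "): ", path)
  df$gene[is.na(df$gene)] <- ""
  for (cn in c("n_valid_bait", "n_valid_ctrl"))
    df[[cn]] <- as.integer(df[[cn]])
  for (cn in c("diff_log2", "ratio", "p_welch", "z", "cv_bait_pct"))
    df[[cn]] <- as.numeric(df[[cn]])
  df$hit <- as.logical(df$hit)
  df
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: one term per line with at least three tab-separated fields
#' (name, description, member symbols). Duplicate member symbols within a
#' line are dropped; duplicate term names across lines are an error.
#'
#' @param path path to the GMT file.
#' @return an object of class `gene_set_collection`: a list with element
#'   `terms`, a named list of `list(description, genes)`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  terms <- list()
  for (i in which(keep)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      stop(sprintf("GMT line %d has fewer than 3 tab-separated fields", i))
    name <- f[1L]
    if (name %in% names(terms)) stop("duplicate gene-set name: ", name)
    members <- unique(f[-(1:2)])
    members <- members[nzchar(members)]
    if (!length(members))
      stop(sprintf("GMT line %d ('%s') has no member symbols", i, name))
    terms[[name]] <- list(description = f[2L], genes = members)
  }
  structure(list(terms = terms), class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  sizes <- vapply(x$terms, function(t) length(t$genes), 1L)
  cat(sprintf("<gene_set_collection> %d terms, %d member symbols in total\n",
              length(x$terms), sum(sizes)))
  invisible(x)
}

#' Collapse protein-group isoforms to gene symbols
#'
#' Multiple isoforms of one protein are counted as a single entry: rows
#' sharing a gene symbol collapse to that symbol, and rows with an empty
#' symbol fall back to their protein-group id so no row silently disappears.
#'
#' @param protein_ids,gene_symbols parallel character vectors (one entry per
#'   protein-group row); `gene_symbols` may be `NULL` or contain empty
#'   strings.
#' @param normalize_case compare symbols after trimming and upper-casing
#'   (useful when datasets mix species-style capitalizations).
#' @return a list with `genes` (the distinct entries, in order of first
#'   appearance) and `mapping` (for each entry, the input row indices that
#'   fed it).
#' @export
collapse_to_genes <- function(protein_ids, gene_symbols = NULL,
                              normalize_case = FALSE) {
  protein_ids <- as.character(protein_ids)
  if (is.null(gene_symbols)) gene_symbols <- rep("", length(protein_ids))
  gene_symbols <- as.character(gene_symbols)
  if (length(protein_ids) != length(gene_symbols))
    stop("`protein_ids` and `gene_symbols` must have equal length")
  g <- trimws(gene_symbols)
  g[is.na(g)] <- ""
  key <- ifelse(nzchar(g), g, trimws(protein_ids))
  if (normalize_case) key <- toupper(key)
  mapping <- split(seq_along(key), factor(key, levels = unique(key)))
  list(genes = unique(key), mapping = mapping)
}
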