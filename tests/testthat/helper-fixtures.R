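# Shared fixture builders: everything is generated in code at test time.

# A small raw-scale matrix with a controllable missing mask.
toy_matrix <- function(values = NULL, genes = NULL) {
  if (is.null(values)) {
    values <- matrix(c(100, 110, 90, 10, 12, 11,
                       200, NA, 190, 180, 170, 160),
                     nrow = 2, byrow = TRUE,
                     dimnames = list(c("P1", "P2"),
                                     c("b1", "b2", "b3", "c1", "c2", "c3")))
  }
  intensity_matrix(values, gene_symbols = genes)
}

toy_design <- function(sams = c("b1", "b2", "b3", "c1", "c2", "c3")) {
  group_design(setNames(rep(c("bait", "control"), each = length(sams) / 2),
                        sams),
               bait_group = "bait", control_group = "control")
}

# Write a DIA-NN-style pg_matrix TSV from a cell matrix of character tokens.
write_pg_tsv <- function(rows, header, path = tempfile(fileext = ".tsv")) {
  lines <- c(paste(header, collapse = "\t"),
             vapply(rows, paste, "", collapse = "\t"))
  writeLines(lines, path)
  path
}

write_gmt_lines <- function(lines, path = tempfile(fileext = ".gmt")) {
  writeLines(lines, path)
  path
}

# Minimal enrichment-table data frame for IO and concordance tests.
toy_enrichment_table <- function(protein_id, gene = NULL, hit = TRUE) {
  n <- length(protein_id)
  data.frame(protein_id = protein_id,
             gene = if (is.null(gene)) rep("", n) else gene,
             n_valid_bait = rep(3L, n), n_valid_ctrl = rep(3L, n),
             diff_log2 = seq_len(n) + 0.5, ratio = 2^(seq_len(n) + 0.5),
             p_welch = rep(0.01, n), z = rep(2, n),
             cv_bait_pct = rep(10, n),
             hit = rep_len(hit, n), stringsAsFactors = FALSE)
}
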