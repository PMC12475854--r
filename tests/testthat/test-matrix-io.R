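test_that("reading a complete pg_matrix TSV preserves shape and values", {
  path <- write_pg_tsv(
    header = c("Protein.Group", "Genes", "s1", "s2", "s3"),
    rows = list(c("P1", "GeneA", "100", "110", "120"),
                c("P2", "GeneB", "5", "6", "7")))
  m <- read_protein_matrix(path)
  expect_s3_class(m, "intensity_matrix")
  expect_equal(dim(m), c(2L, 3L))
  expect_equal(protein_ids(m), c("P1", "P2"))
  expect_equal(sample_ids(m), c("s1", "s2", "s3"))
  expect_equal(m$gene_symbols, c("GeneA", "GeneB"))
  expect_false(anyNA(m$values))
  expect_equal(unname(m$values["P2", "s3"]), 7)
})

test_that("missing-value encodings are honoured", {
  path <- write_pg_tsv(
    header = c("Protein.Group", "Genes", "s1", "s2"),
    rows = list(c("P1", "G1", "0", "3"),
                c("P2", "G2", "", "NaN")))
  m <- read_protein_matrix(path, zero_is_missing = TRUE)
  expect_true(is.na(m$values["P1", "s1"]))   # zero
  expect_true(is.na(m$values["P2", "s1"]))   # blank
  expect_true(is.na(m$values["P2", "s2"]))   # listed code
  expect_error(read_protein_matrix(path, zero_is_missing = FALSE),
               "positive")
})

test_that("malformed matrices are rejected with informative errors", {
  dup <- write_pg_tsv(header = c("Protein.Group", "Genes", "s1", "s2"),
                      rows = list(c("P1", "G", "1", "2"),
                                  c("P1", "G", "3", "4")))
  expect_error(read_protein_matrix(dup), "P1")

  dupcol <- write_pg_tsv(header = c("Protein.Group", "Genes", "s1", "s1"),
                         rows = list(c("P1", "G", "1", "2")))
  expect_error(read_protein_matrix(dupcol), "duplicate sample")

  badtok <- write_pg_tsv(header = c("Protein.Group", "Genes", "s1", "s2"),
                         rows = list(c("P1", "G", "1", "2"),
                                     c("P2", "G", "oops", "4")))
  expect_error(read_protein_matrix(badtok), "oops.*s1.*row 2")

  noann <- write_pg_tsv(header = c("weird", "s1"),
                        rows = list(c("P1", "1")))
  expect_error(read_protein_matrix(noann), "annotation")
})

test_that("write/read round trip is the identity on values, mask and order", {
  sim <- simulate_lfq(sim_params(n_proteins = 60, n_bait = 3, n_ctrl = 3),
                      seed = 11)
  path <- tempfile(fileext = ".tsv")
  write_protein_matrix(sim$matrix, path)
  back <- read_protein_matrix(path)
  expect_identical(protein_ids(back), protein_ids(sim$matrix))
  expect_identical(sample_ids(back), sample_ids(sim$matrix))
  expect_identical(back$gene_symbols, sim$matrix$gene_symbols)
  expect_identical(is.na(back$values), is.na(sim$matrix$values))
  expect_equal(back$values, sim$matrix$values)
})

test_that("enrichment table round-trips field by field", {
  tab <- toy_enrichment_table(c("P1", "P2", "P3"), gene = c("A", "B", ""),
                              hit = c(TRUE, FALSE, TRUE))
  tab$p_welch <- c(1 / 3, 0.02131164113, NA)
  path <- tempfile(fileext = ".tsv")
  write_enrichment_table(tab, path)
  back <- read_enrichment_table(path)
  expect_equal(back$protein_id, tab$protein_id)
  expect_equal(back$gene, tab$gene)
  expect_equal(back$hit, tab$hit)
  for (cn in c("n_valid_bait", "n_valid_ctrl", "diff_log2", "ratio",
               "p_welch", "z", "cv_bait_pct"))
    expect_equal(back[[cn]], tab[[cn]], tolerance = 1e-11, label = cn)
  # a non-hit row is present, flagged FALSE
  expect_false(back$hit[back$protein_id == "P2"])
})

test_that("an empty enrichment table writes a header-only file", {
  tab <- toy_enrichment_table(character(0))
  path <- tempfile(fileext = ".tsv")
  write_enrichment_table(tab, path)
  expect_length(readLines(path), 1L)
  expect_equal(nrow(read_enrichment_table(path)), 0L)
})

test_that("GMT parsing deduplicates members and validates structure", {
  p <- write_gmt_lines(c("T1\tdesc\tA\tB\tA", "T2\td2\tC"))
  gs <- read_gmt(p)
  expect_setequal(gs$terms$T1$genes, c("A", "B"))
  expect_length(gs$terms$T1$genes, 2L)

  expect_error(read_gmt(write_gmt_lines(c("T1\td\tA", "T1\td\tB"))),
               "duplicate gene-set name: T1")
  expect_error(read_gmt(write_gmt_lines(c("T1\td\tA", "T2\tonlytwo"))),
               "line 2")
  empty <- read_gmt(write_gmt_lines(character(0)))
  expect_length(empty$terms, 0L)
})

test_that("isoform collapsing maps rows to distinct gene entries", {
  out <- collapse_to_genes(c("Bin1-iso1", "Bin1-iso9", "Amph"),
                           c("Bin1", "Bin1", "Amph"))
  expect_setequal(out$genes, c("Bin1", "Amph"))
  expect_equal(out$mapping$Bin1, c(1L, 2L))

  # all distinct: identity
  ident <- collapse_to_genes(c("a", "b"), c("X", "Y"))
  expect_length(ident$genes, 2L)

  # empty symbol falls back to the protein id
  fb <- collapse_to_genes(c("Q9X", "P2"), c("", "G2"))
  expect_true("Q9X" %in% fb$genes)

  # idempotent and never larger than the input
  again <- collapse_to_genes(out$genes, out$genes)
  expect_identical(sort(again$genes), sort(out$genes))
  expect_lte(length(out$genes), 3L)
})
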