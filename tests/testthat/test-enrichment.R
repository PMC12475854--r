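test_that("log2 transform maps values and preserves the missing mask", {
  m <- toy_matrix(matrix(c(8, 1, NA, 4), 2, 2,
                         dimnames = list(c("P1", "P2"), c("s1", "s2"))))
  lm <- log2_transform(m)
  expect_equal(unname(lm$values["P1", "s1"]), 3)
  expect_equal(unname(lm$values["P2", "s1"]), 0)
  expect_true(is.na(lm$values["P1", "s2"]))
  expect_error(log2_transform(lm), "already")
  bad <- toy_matrix(matrix(c(8, 1, 2, 4), 2, 2,
                           dimnames = list(c("P1", "P2"), c("s1", "s2"))))
  bad$values[1, 1] <- -1  # bypass the constructor on purpose
  expect_error(log2_transform(bad), "non-positive")
})

test_that("completeness filter keeps a protein valid in at least one group", {
  vals <- matrix(2^c(10, 11, 12, NA, NA, NA,     # 3/3 bait, 0/3 ctrl
                     10, NA, 12, 10, NA, 12),    # 2/3 in both
                 nrow = 2, byrow = TRUE,
                 dimnames = list(c("keep", "drop"),
                                 c("b1", "b2", "b3", "c1", "c2", "c3")))
  m <- intensity_matrix(vals)
  f <- filter_by_completeness(m, toy_design(), 1.0)
  expect_equal(protein_ids(f), "keep")

  # 0.75 threshold with unequal groups: 9/11 bait (0.818) vs 1/9 ctrl
  v2 <- matrix(NA_real_, 1, 20,
               dimnames = list("P", c(sprintf("b%02d", 1:11),
                                      sprintf("c%02d", 1:9))))
  v2[1, 1:9] <- 2^10
  v2[1, 12] <- 2^10
  m2 <- intensity_matrix(v2)
  d2 <- group_design(setNames(rep(c("bait", "control"), c(11, 9)),
                              colnames(v2)), "bait", "control")
  expect_equal(nrow(filter_by_completeness(m2, d2, 0.75)$values), 1L)
  expect_warning(filter_by_completeness(m2, d2, 0.95), "no protein group")
})

test_that("imputation draws from the downshifted, narrowed normal", {
  # column with observed mean 25 and sample SD 2; 1e4 missing cells
  n_miss <- 10000
  v <- matrix(c(23, 25, 27, rep(NA_real_, n_miss)), ncol = 1,
              dimnames = list(sprintf("P%05d", seq_len(n_miss + 3)), "s1"))
  m <- structure(list(values = v, gene_symbols = rep("", nrow(v)),
                      scale = "log2"), class = "intensity_matrix")
  out <- impute_left_censored(m, width = 0.5, downshift = 1.6, seed = 42)
  imp <- out$values[is.na(v)]
  expect_false(anyNA(out$values))
  # expected moments: mean 25 - 1.6*2 = 21.8, SD 0.5*2 = 1; 3 SE tolerance
  expect_lt(abs(mean(imp) - 21.8), 3 * 1 / sqrt(n_miss))
  expect_lt(abs(sd(imp) - 1), 3 * 1 / sqrt(2 * n_miss))
  # present values untouched
  expect_equal(unname(out$values[1:3, 1]), c(23, 25, 27))
})

test_that("imputation is deterministic and column-order invariant", {
  sim <- simulate_lfq(sim_params(n_proteins = 200, n_bait = 3, n_ctrl = 3),
                      seed = 5)
  lm <- log2_transform(sim$matrix)
  a <- impute_left_censored(lm, 0.5, 1.6, seed = 7)
  b <- impute_left_censored(lm, 0.5, 1.6, seed = 7)
  expect_identical(a$values, b$values)
  # permuting columns permutes, but does not change, the imputed values
  perm <- rev(sample_ids(lm))
  c <- impute_left_censored(lm[, perm], 0.5, 1.6, seed = 7)
  expect_identical(c$values[, sample_ids(lm)], a$values)
  # a column with < 2 observed values is an error naming the column
  v <- matrix(c(1, NA, NA, 2, 3, 4), 3, 2,
              dimnames = list(paste0("P", 1:3), c("bad", "good")))
  mm <- structure(list(values = v, gene_symbols = rep("", 3), scale = "log2"),
                  class = "intensity_matrix")
  expect_error(impute_left_censored(mm, 0.5, 1.6, 1), "'bad'")
})

test_that("welch_t reproduces hand-derived cases", {
  same <- welch_t(c(3, 4, 5), c(3, 4, 5))
  expect_equal(same$t_stat, 0)
  expect_equal(same$p_welch, 1)
  expect_equal(same$diff_log2, 0)

  w <- welch_t(c(4, 5, 6), c(1, 2, 3))
  expect_equal(w$diff_log2, 3)
  expect_equal(w$t_stat, 3.67423461417477, tolerance = 1e-12)
  expect_equal(w$df_welch, 4, tolerance = 1e-12)
  expect_equal(w$p_welch, 0.0213116411287567, tolerance = 1e-12)

  # unequal variances shrink the Satterthwaite df below nx + ny - 2
  uv <- welch_t(c(10, 10, 10, 10.001), c(0, 1, 2, 3))
  expect_lt(uv$df_welch, 6)

  # degenerate: both variances zero, unequal means
  expect_warning(deg <- welch_t(c(1, 1), c(2, 2)), "zero variance")
  expect_equal(deg$p_welch, 0)
  expect_error(welch_t(1, c(1, 2)), "at least 2")
})

test_that("welch_t matches the stats::t.test reference on random inputs", {
  set.seed(123)
  for (i in 1:1000) {
    nx <- sample(2:8, 1)
    ny <- sample(2:8, 1)
    x <- rnorm(nx, sd = runif(1, 0.5, 3))
    y <- rnorm(ny, 2 * rbinom(1, 1, 0.5), sd = runif(1, 0.5, 3))
    w <- welch_t(x, y)
    ref <- stats::t.test(x, y, var.equal = FALSE)
    expect_equal(w$t_stat, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(w$df_welch, unname(ref$parameter), tolerance = 1e-10)
    expect_equal(w$p_welch, ref$p.value, tolerance = 1e-10)
  }
})

test_that("fold-change z-scores standardize exactly", {
  expect_equal(fold_change_zscores(c(1, 2, 3)), c(-1, 0, 1))
  set.seed(4)
  z <- fold_change_zscores(rnorm(500, 2, 3))
  expect_lt(abs(mean(z)), 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
  expect_error(fold_change_zscores(c(5, 5, 5)), "constant")
  expect_error(fold_change_zscores(c(1, 2)), "at least 3")
})

test_that("percent CV follows 100 * sd / mean on observed values", {
  expect_equal(protein_cv_pct(c(10, 10, 10)), 0)
  expect_equal(protein_cv_pct(c(8, 10, 12)), 20)
  expect_equal(protein_cv_pct(c(1, 100)), 138.620933341521, tolerance = 1e-12)
  expect_true(is.na(protein_cv_pct(c(5, NA))))
})

test_that("hit calling applies all cutoffs jointly and strictly", {
  params <- pipeline_params()
  tab <- data.frame(p_welch = c(0.01, 0.01, 0.05, 0.01),
                    z = c(1.5, 1.5, 1.5, 1.0),
                    diff_log2 = c(2, -2, 2, 2))
  out <- call_hits(tab, params)
  expect_equal(out$hit, c(TRUE, FALSE, FALSE, FALSE))
  # sign requirement can be lifted
  out2 <- call_hits(tab, pipeline_params(require_positive_diff = FALSE))
  expect_equal(out2$hit, c(TRUE, TRUE, FALSE, FALSE))
})

test_that("the fitted object is deterministic and self-consistent", {
  sim <- simulate_lfq(sim_params(n_proteins = 400, n_bait = 3, n_ctrl = 3),
                      seed = 3)
  fit1 <- proximity_enrichment(sim$matrix, sim$design)
  fit2 <- proximity_enrichment(sim$matrix, sim$design)
  expect_identical(fit1$table, fit2$table)

  tab <- fit1$table
  # z-population is standardized
  z <- tab$z[!is.na(tab$z)]
  expect_lt(abs(mean(z)), 1e-10)
  expect_equal(sd(z), 1, tolerance = 1e-10)
  # Welch df bounds
  df <- tab$df_welch[!is.na(tab$df_welch)]
  expect_true(all(df > 1 & df <= 4 + 1e-9))
  # ratio is the unlogged difference
  ok <- !is.na(tab$diff_log2)
  expect_equal(tab$ratio[ok], 2^tab$diff_log2[ok])
  # hit implies every individual flag
  expect_true(all(tab$passed_p[tab$hit] & tab$passed_z[tab$hit] &
                  tab$diff_log2[tab$hit] > 0))
  # QC summary counts agree with the table
  expect_equal(fit1$qc$n_hits, sum(tab$hit))
  expect_equal(fit1$qc$n_tested, sum(tab$passed_filter))
})

test_that("tightening a cutoff never adds hits on a fixed imputed matrix", {
  sim <- simulate_lfq(sim_params(n_proteins = 600, frac_enriched = 0.1),
                      seed = 9)
  n_hits <- function(alpha, z_cutoff) {
    fit <- proximity_enrichment(sim$matrix, sim$design,
                                pipeline_params(alpha = alpha,
                                                z_cutoff = z_cutoff,
                                                seed = 17))
    fit$qc$n_hits
  }
  base <- n_hits(0.05, 1)
  expect_lte(n_hits(0.05, 2), base)
  expect_lte(n_hits(0.01, 1), base)
  expect_lte(n_hits(0.01, 2), min(n_hits(0.05, 2), n_hits(0.01, 1)))
})

test_that("under the null the joint call is rare and p-values are not anticonservative", {
  # no true effects, n = 3 vs 3: the z and sign filters push the hit rate
  # far below alpha, and the Welch stage never exceeds its nominal size
  tot <- 0; n_sig <- 0; n_hit <- 0
  for (s in 1:5) {
    sim <- simulate_lfq(sim_params(n_proteins = 1000, frac_enriched = 0,
                                   n_bait = 3, n_ctrl = 3,
                                   censor_limit = -1000), seed = s)
    fit <- proximity_enrichment(sim$matrix, sim$design)
    p <- fit$table$p_welch
    tot <- tot + sum(!is.na(p))
    n_sig <- n_sig + sum(p < 0.05, na.rm = TRUE)
    n_hit <- n_hit + fit$qc$n_hits
  }
  upper <- 0.05 + 2.5758 * sqrt(0.05 * 0.95 / tot)
  expect_lt(n_sig / tot, upper)
  expect_lt(n_hit / tot, 0.05 / 2)
})
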