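# Over-representation of a hit list against user-supplied gene sets:
# hypergeometric upper tail, Benjamini-Hochberg FDR, fold enrichment.

#' Hypergeometric over-representation p-value
#'
#' Upper-tail probability `P(X >= k)` for
#' `X ~ Hypergeometric(N, K, n)`: drawing `n` hit genes from a background of
#' `N` genes of which `K` belong to the term, the chance of seeing `k` or
#' more term members among the hits. Equivalent to a one-sided Fisher exact
#' test of the 2x2 table. Computed via the log-space-stable distribution
#' function.
#'
#' @param k hits in the term; `n` hits in the background; `K` background
#'   genes in the term; `N` background size.
#' @param n,K,N see `k`.
#' @return the p-value; exactly 1 when `k = 0`.
#' @export
hypergeom_overrep <- function(k, n, K, N) {
  check_counts(k, n, K, N)
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Fold enrichment of a term
#'
#' Effect size of over-representation: the fraction of hit genes in the
#' term divided by the fraction of background genes in the term,
#' `(k/n) / (K/N)`.
#'
#' @inheritParams hypergeom_overrep
#' @return the ratio; `NA` when `n = 0` or `K = 0` (undefined).
#' @export
fold_enrichment <- function(k, n, K, N) {
  check_counts(k, n, K, N)
  if (n == 0 || K == 0) return(NA_real_)
  (k / n) / (K / N)
}

check_counts <- function(k, n, K, N) {
  stopifnot(length(k) == 1L, length(n) == 1L, length(K) == 1L,
            length(N) == 1L)
  if (any(c(k, n, K, N) < 0) || any(c(k, n, K, N) != round(c(k, n, K, N))))
    stop("counts must be non-negative integers")
  if (k > n || n > N || k > K || K > N || k < max(0, n + K - N))
    stop(sprintf("inconsistent counts: k=%d, n=%d, K=%d, N=%d", k, n, K, N))
  invisible(TRUE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up false-discovery-rate adjustment: sort ascending, take
#' `q_(i) = min_{j >= i} p_(j) * m / j` capped at 1, return in input order.
#'
#' @param pvalues numeric vector in `[0, 1]`.
#' @return adjusted values, same length and order.
#' @export
bh_fdr <- function(pvalues) {
  pvalues <- as.numeric(pvalues)
  if (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(pvalues, method = "BH")
}

#' Over-representation analysis of a hit list
#'
#' Tests every term of a [read_gmt()] collection for over-representation of
#' `hits` relative to an explicit user-supplied `background` gene universe.
#' Term membership is intersected with the background first (genes the
#' experiment could never have seen do not count); hits absent from the
#' background are dropped with a warning. One hypergeometric upper-tail
#' p-value per term with `K > 0`, Benjamini-Hochberg FDR across all tested
#' terms, results sorted by p-value.
#'
#' @param hits character vector of hit gene symbols.
#' @param background character vector: the gene universe.
#' @param collection a `gene_set_collection`.
#' @param fdr_cutoff threshold for the `significant` flag (default 0.05).
#' @return data frame with one row per tested term: `term, description, k,
#'   n, K, N, fold_enrichment, p_hyper, fdr_bh, significant`; the number of
#'   dropped hits is in `attr(, "n_hits_dropped")`.
#' @export
run_overrepresentation <- function(hits, background, collection,
                                   fdr_cutoff = 0.05) {
  stopifnot(inherits(collection, "gene_set_collection"))
  background <- unique(as.character(background))
  if (!length(background)) stop("background gene list is empty")
  hits <- unique(as.character(hits))
  outside <- setdiff(hits, background)
  if (length(outside)) {
    warning(length(outside),
            " hit gene(s) absent from the background were dropped")
    hits <- intersect(hits, background)
  }
  N <- length(background)
  n <- length(hits)
  rows <- lapply(names(collection$terms), function(nm) {
    mem <- intersect(collection$terms[[nm]]$genes, background)
    K <- length(mem)
    if (K == 0L) return(NULL)
    k <- length(intersect(hits, mem))
    data.frame(term = nm,
               description = collection$terms[[nm]]$description,
               k = k, n = n, K = K, N = N,
               fold_enrichment = fold_enrichment(k, n, K, N),
               p_hyper = hypergeom_overrep(k, n, K, N),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) {
    res <- data.frame(term = character(0), description = character(0),
                      k = integer(0), n = integer(0), K = integer(0),
                      N = integer(0), fold_enrichment = numeric(0),
                      p_hyper = numeric(0), fdr_bh = numeric(0),
                      significant = logical(0))
    attr(res, "n_hits_dropped") <- length(outside)
    return(res)
  }
  res <- do.call(rbind, rows)
  res$fdr_bh <- bh_fdr(res$p_hyper)
  res <- res[order(res$p_hyper, -res$fold_enrichment, res$term), , drop = FALSE]
  res$significant <- res$fdr_bh < fdr_cutoff
  rownames(res) <- NULL
  attr(res, "n_hits_dropped") <- length(outside)
  res
}
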