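# Term over-representation: one-sided hypergeometric enrichment with BH
# correction, plus a Wallenius noncentral variant that absorbs per-gene
# sampling bias (e.g. transcript length) through a single odds parameter.

#' Upper-tail hypergeometric enrichment p-value
#'
#' P(X >= k) for X ~ Hypergeometric(N, K, n): the probability of observing at
#' least k term genes in a study set of size n drawn from a population of N
#' genes of which K carry the term.
#'
#' @param k study genes carrying the term.
#' @param K population genes carrying the term.
#' @param n study-set size.
#' @param N population size.
#' @return one-sided p-value.
#' @export
hypergeom_test <- function(k, K, n, N) {
  if (k < 0 || K < 0 || n < 0 || N < 1 || k > min(K, n) || K > N || n > N)
    stop_config("inconsistent counts: need 0 <= k <= min(K, n), K,n <= N")
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

# Wallenius noncentral hypergeometric pmf by its integral representation.
# m1 term genes (odds omega), m2 others (odds 1), n drawn, x term hits.
dwallenius <- function(x, m1, m2, n, omega) {
  if (x < max(0, n - m2) || x > min(n, m1)) return(0)
  d <- omega * (m1 - x) + (m2 - (n - x))
  if (d <= 0) return(if (x == m1 && n - x == m2) 1 else 0)
  f <- function(t) {
    res <- rep(1, length(t))
    if (x > 0) res <- res * (1 - t^(omega / d))^x
    if (n - x > 0) res <- res * (1 - t^(1 / d))^(n - x)
    res
  }
  int <- integrate(f, 0, 1, rel.tol = 1e-12, abs.tol = 1e-14,
                   subdivisions = 500L)$value
  exp(lchoose(m1, x) + lchoose(m2, n - x)) * int
}

#' Length-bias-aware enrichment p-value (Wallenius)
#'
#' Upper-tail probability under the Wallenius noncentral hypergeometric
#' distribution, in which term genes are drawn with odds equal to the mean
#' weight of term genes divided by the mean weight of non-term genes. Equal
#' weights reduce exactly to [hypergeom_test()]; rescaling all weights leaves
#' the p-value unchanged.
#'
#' @inheritParams hypergeom_test
#' @param w_term,w_other positive weight vectors (or pre-averaged scalars)
#'   for term and non-term population genes.
#' @return one-sided p-value.
#' @export
weighted_enrichment <- function(k, K, n, N, w_term, w_other) {
  if (any(c(w_term, w_other) <= 0))
    stop_config("gene weights must be positive")
  if (k < 0 || k > min(K, n) || K > N || n > N)
    stop_config("inconsistent counts: need 0 <= k <= min(K, n), K,n <= N")
  omega <- mean(w_term) / mean(w_other)
  xs <- k:min(K, n)
  p <- sum(vapply(xs, dwallenius, 0, m1 = K, m2 = N - K, n = n,
                  omega = omega))
  min(1, max(0, p))
}

#' Enrichment of a study gene set across a term catalogue
#'
#' Tests every term with genes in the population for over-representation in
#' the study set ([hypergeom_test()], or [weighted_enrichment()] when
#' per-gene weights are supplied), BH-adjusts across all tested terms, and
#' flags terms with q < alpha. Terms with no population genes are skipped.
#'
#' @param study character vector of study gene ids (must be a subset of
#'   `population`).
#' @param population character vector of background gene ids.
#' @param terms data.frame: term_id, term_name, gene_id (one row per
#'   term-gene assignment).
#' @param alpha significance threshold on q (default 0.05).
#' @param weights optional named positive vector of per-gene weights (e.g.
#'   transcript lengths) switching the test to the Wallenius variant.
#' @return data.frame: term_id, term_name, k, K, n, N, p_value, q_value,
#'   significant — ordered by p-value.
#' @export
enrich_all <- function(study, population, terms, alpha = 0.05,
                       weights = NULL) {
  study <- unique(study)
  population <- unique(population)
  bad <- setdiff(study, population)
  if (length(bad))
    stop_config("study genes absent from population: %s",
                paste(bad, collapse = ", "))
  stopifnot(all(c("term_id", "term_name", "gene_id") %in% names(terms)))
  terms <- terms[terms$gene_id %in% population, , drop = FALSE]
  if (nrow(terms) == 0L)
    return(data.frame(term_id = character(), term_name = character(),
                      k = integer(), K = integer(), n = integer(),
                      N = integer(), p_value = numeric(), q_value = numeric(),
                      significant = logical(), stringsAsFactors = FALSE))
  n <- length(study)
  N <- length(population)
  by_term <- split(terms$gene_id, terms$term_id)
  name_of <- terms$term_name[match(names(by_term), terms$term_id)]
  rows <- lapply(seq_along(by_term), function(i) {
    genes <- unique(by_term[[i]])
    K <- length(genes)
    k <- length(intersect(genes, study))
    p <- if (is.null(weights)) {
      hypergeom_test(k, K, n, N)
    } else {
      w_term <- weights[genes]
      w_other <- weights[setdiff(population, genes)]
      if (any(is.na(c(w_term, w_other))))
        stop_config("weights must cover every population gene")
      weighted_enrichment(k, K, n, N, w_term, w_other)
    }
    data.frame(term_id = names(by_term)[i], term_name = name_of[i],
               k = k, K = K, n = n, N = N, p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_value <- bh_adjust(out$p_value)
  out$significant <- out$q_value < alpha
  out <- out[order(out$p_value, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
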