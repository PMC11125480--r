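#' Hypergeometric upper-tail probability
#'
#' `P(X >= k)` where `X` counts annotated genes in a random draw of `n`
#' genes from a population of `N` genes of which `K` are annotated — the
#' over-representation p-value of a term.
#'
#' @param N Population size.
#' @param K Number of annotated genes in the population.
#' @param n Number of selected genes.
#' @param k Observed overlap between selection and annotation.
#' @return Upper-tail probability in (0, 1].
#' @export
hypergeom_upper_tail <- function(N, K, n, k) {
  stopifnot(length(N) == 1, length(K) == 1, length(n) == 1,
            length(k) == 1)
  if (K > N || n > N) stop("K and n must not exceed N")
  if (k < 0 || k > min(n, K))
    stop("k must lie in [0, min(n, K)]; got k=", k, " with n=", n,
         ", K=", K)
  phyper(k - 1, m = K, n = N - K, k = n, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment, capped at 1, returned in the input order.
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0, 1] and be non-missing")
  p.adjust(pvalues, method = "BH")
}

#' Term enrichment of a gene selection
#'
#' One-sided hypergeometric over-representation test of each term's gene
#' set in `selected` against `population`, with BH FDR across all tested
#' terms. Term sets are intersected with the population before testing and
#' terms with no population gene are dropped. The recommended population is
#' the detected-gene background ([detected_genes()]), not the whole
#' annotation.
#'
#' @param selected Character vector of selected gene_ids (subset of
#'   `population`).
#' @param population Character vector of background gene_ids.
#' @param terms Named list of character vectors (term -> gene set), e.g.
#'   from [read_gmt()].
#' @return data.frame sorted by p-value with columns term_id, k_overlap,
#'   n_selected, K_annotated, N_population, pvalue, fdr.
#' @export
enrich <- function(selected, population, terms) {
  selected <- unique(selected); population <- unique(population)
  out_of_pop <- setdiff(selected, population)
  if (length(out_of_pop))
    stop("selected genes absent from population: ",
         paste(out_of_pop, collapse = ", "))
  if (is.null(names(terms))) stop("terms must be a named list")
  N <- length(population)
  n <- length(selected)
  rows <- lapply(names(terms), function(tm) {
    g <- intersect(unique(terms[[tm]]), population)
    K <- length(g)
    if (K == 0) return(NULL)
    k <- length(intersect(g, selected))
    data.frame(term_id = tm, k_overlap = k, n_selected = n,
               K_annotated = K, N_population = N,
               pvalue = hypergeom_upper_tail(N, K, n, k),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0)
    return(data.frame(term_id = character(0), k_overlap = integer(0),
                      n_selected = integer(0), K_annotated = integer(0),
                      N_population = integer(0), pvalue = numeric(0),
                      fdr = numeric(0)))
  out <- do.call(rbind, rows)
  out$fdr <- bh_adjust(out$pvalue)
  out <- out[order(out$pvalue, out$term_id), ]
  rownames(out) <- NULL
  out
}
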