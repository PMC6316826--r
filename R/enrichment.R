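#' Hypergeometric term enrichment
#'
#' For every annotation term, tests over-representation of the gene set
#' against the background universe with the one-sided upper-tail
#' hypergeometric probability
#' \deqn{p = \sum_{k \ge x} C(K,k)\, C(N-K, n-k) / C(N,n)}
#' where N is the background size, K the term's annotated genes, n the
#' gene-set size and x the observed overlap. Benjamini-Hochberg
#' adjustment is applied across the tested terms. Terms with zero
#' overlap are reported with their (trivial) upper-tail value.
#'
#' @param geneSet character vector of genes (must be a subset of the
#'   background).
#' @param termMap data.frame with columns \code{gene_id},
#'   \code{term_id}, \code{description} (see [readTermMap]).
#' @param background character vector of universe genes.
#' @return data.frame with columns term_id, description, overlap, K, n,
#'   N, p, p_adj, sorted by p.
#' @examples
#' tm <- data.frame(gene_id = paste0("g", 1:5), term_id = "T1",
#'                  description = "toy term")
#' hypergeomEnrich(paste0("g", 1:4), tm, paste0("g", 1:10))
#' @importFrom stats phyper p.adjust
#' @export
hypergeomEnrich <- function(geneSet, termMap, background) {
  background <- unique(background)
  if (length(background) == 0L) stop("background universe is empty")
  geneSet <- unique(geneSet)
  if (!all(geneSet %in% background))
    stop("gene set contains genes outside the background universe")
  tm <- termMap[termMap$gene_id %in% background, , drop = FALSE]
  N <- length(background)
  n <- length(geneSet)
  terms <- unique(tm$term_id)
  rows <- lapply(terms, function(t) {
    genes <- unique(tm$gene_id[tm$term_id == t])
    K <- length(genes)
    x <- length(intersect(genes, geneSet))
    data.frame(term_id = t,
               description = tm$description[tm$term_id == t][1],
               overlap = x, K = K, n = n, N = N,
               p = phyper(x - 1, K, N - K, n, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(term_id = character(0), description = character(0),
                      overlap = integer(0), K = integer(0), n = integer(0),
                      N = integer(0), p = numeric(0), p_adj = numeric(0),
                      stringsAsFactors = FALSE))
  out$p_adj <- p.adjust(out$p, method = "BH")
  out <- out[order(out$p, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Between-species subfamily proportion comparison
#'
#' For each subfamily, builds the 2x2 table (in-subfamily vs rest,
#' species A vs B) and applies Fisher's exact test (two-sided,
#' summing hypergeometric probabilities of tables as extreme or less
#' probable), with Benjamini-Hochberg adjustment across subfamilies.
#' The test is symmetric in the two species.
#'
#' @param countsA,countsB named numeric vectors of per-subfamily counts
#'   (names must match).
#' @param totalA,totalB family totals per species.
#' @param alpha significance threshold on the adjusted p-value.
#' @return data.frame with columns subfamily, n_a, n_b, prop_a, prop_b,
#'   p, p_adj, significant.
#' @examples
#' compareProportions(c(XII = 102), 511, c(XII = 61), 515)
#' @importFrom stats fisher.test p.adjust
#' @export
compareProportions <- function(countsA, totalA, countsB, totalB,
                               alpha = 0.05) {
  if (totalA <= 0 || totalB <= 0) stop("species totals must be positive")
  if (any(countsA > totalA) || any(countsB > totalB))
    stop("counts exceed totals")
  sf <- names(countsA)
  if (!identical(sort(sf), sort(names(countsB))))
    stop("subfamily names differ between species")
  p <- vapply(sf, function(s) {
    tab <- matrix(c(countsA[[s]], totalA - countsA[[s]],
                    countsB[[s]], totalB - countsB[[s]]), nrow = 2)
    fisher.test(tab)$p.value
  }, numeric(1))
  out <- data.frame(subfamily = sf,
                    n_a = as.numeric(countsA[sf]),
                    n_b = as.numeric(countsB[sf]),
                    prop_a = as.numeric(countsA[sf]) / totalA,
                    prop_b = as.numeric(countsB[sf]) / totalB,
                    p = unname(p),
                    p_adj = p.adjust(unname(p), method = "BH"),
                    stringsAsFactors = FALSE)
  out$significant <- out$p_adj < alpha
  rownames(out) <- NULL
  out
}

#' Cross-species subfamily proportion ratios
#'
#' Ratio of subfamily percentage shares between two species (e.g. how
#' many times larger a subfamily's share is in one lineage than
#' another). A zero denominator yields \code{NA} as the undefined
#' marker; a zero numerator yields 0.
#'
#' @param pctA,pctB named numeric vectors of subfamily percentages
#'   (names must match).
#' @return data.frame with columns subfamily, pct_a, pct_b, ratio.
#' @examples
#' ratioReport(c("XI-1" = 25.2), c("XI-1" = 13.1))
#' @export
ratioReport <- function(pctA, pctB) {
  sf <- names(pctA)
  if (!identical(sort(sf), sort(names(pctB))))
    stop("subfamily names differ between species")
  b <- as.numeric(pctB[sf])
  ratio <- ifelse(b == 0, NA_real_, as.numeric(pctA[sf]) / b)
  data.frame(subfamily = sf, pct_a = as.numeric(pctA[sf]), pct_b = b,
             ratio = ratio, row.names = NULL, stringsAsFactors = FALSE)
}
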