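#' Log-transform an expression matrix
#'
#' \code{log10(x + offset)} with a pseudo-count so zero FPKM values map
#' to zero; the transform is strictly order-preserving.
#'
#' @param mat non-negative numeric matrix (genes by samples).
#' @param offset pseudo-count (default 1).
#' @return transformed matrix of the same shape.
#' @examples
#' logTransform(matrix(c(0, 99), 1))
#' @export
logTransform <- function(mat, offset = 1) {
  if (any(mat < 0)) stop("expression values must be non-negative")
  log10(mat + offset)
}

# run code under a local RNG state, restoring the caller's afterwards
.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

# renumber cluster labels by descending mean expression so labels are
# stable under gene reordering and restarts
.renumberByMean <- function(labels, mat) {
  means <- vapply(split(rowMeans(mat), labels), mean, numeric(1))
  ord <- names(sort(means, decreasing = TRUE))
  out <- match(as.character(labels), ord)
  names(out) <- rownames(mat)
  out
}

#' k-means expression groups
#'
#' Deterministic given the seed: the best of \code{nRestarts} runs by
#' within-cluster sum of squares is kept, and groups are renumbered by
#' descending mean expression (group 1 = highest).
#'
#' @param logMat log-transformed matrix (genes by samples).
#' @param k number of groups.
#' @param seed RNG seed (the caller's RNG state is restored).
#' @param nRestarts number of random restarts.
#' @return named integer vector of group labels per gene.
#' @importFrom stats kmeans
#' @export
kmeansGroups <- function(logMat, k = 2L, seed = 17L, nRestarts = 25L) {
  if (k < 1L) stop("k must be >= 1")
  if (k > nrow(logMat)) stop("k exceeds the number of genes")
  if (k == 1L)
    return(setNames(rep(1L, nrow(logMat)), rownames(logMat)))
  fit <- .withSeed(seed, kmeans(logMat, centers = k, nstart = nRestarts,
                                iter.max = 100L))
  .renumberByMean(fit$cluster, logMat)
}

#' Hierarchical expression groups
#'
#' Cuts a hierarchical clustering tree into exactly \code{nGroups}
#' groups, renumbered by descending mean expression; the partition is
#' invariant to the gene order of the input.
#'
#' @param logMat log-transformed matrix (genes by samples).
#' @param nGroups number of groups.
#' @param linkage linkage method passed to \code{hclust}.
#' @param distMethod distance passed to \code{dist}.
#' @return named integer vector of group labels per gene.
#' @importFrom stats hclust cutree dist
#' @export
hierarchicalGroups <- function(logMat, nGroups = 4L, linkage = "complete",
                               distMethod = "euclidean") {
  if (nGroups > nrow(logMat)) stop("nGroups exceeds the number of genes")
  # order rows deterministically so the partition ignores input order
  ord <- order(rownames(logMat))
  m <- logMat[ord, , drop = FALSE]
  cl <- cutree(hclust(dist(m, method = distMethod), method = linkage),
               k = nGroups)
  .renumberByMean(cl, m)[rownames(logMat)]
}

#' Differential-expression filter with contrast intersection
#'
#' A gene is kept when it passes |log2FC| > \code{lfcMin} and
#' FDR < \code{fdrMax} in every required contrast (e.g. both pathogen
#' strains) or, with \code{requireAll = FALSE}, in at least one.
#'
#' @param records data.frame with columns \code{gene_id},
#'   \code{contrast_id}, \code{log2fc}, \code{fdr}.
#' @param config a [PipelineConfig-class] supplying the cutoffs.
#' @param requireAll require the gene to pass in every contrast listed
#'   in \code{contrasts}.
#' @param contrasts contrasts that must be passed; defaults to every
#'   contrast present in \code{records}.
#' @return sorted character vector of significant gene ids.
#' @export
filterDE <- function(records, config = pipelineConfig(),
                     requireAll = TRUE, contrasts = NULL) {
  if (nrow(records) == 0L) return(character(0))
  if (is.null(contrasts)) contrasts <- unique(records$contrast_id)
  pass <- records[abs(records$log2fc) > config@deLfcMin &
                  records$fdr < config@deFdrMax &
                  records$contrast_id %in% contrasts, , drop = FALSE]
  if (nrow(pass) == 0L) return(character(0))
  hits <- table(unique(pass[, c("gene_id", "contrast_id")])$gene_id)
  need <- if (requireAll) length(contrasts) else 1L
  sort(names(hits)[hits >= need])
}
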