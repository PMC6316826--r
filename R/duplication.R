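#' Chromosome-ordered gene index
#'
#' Ranks every annotated gene (family members and all neighbours alike)
#' along its sequence by genomic start, so that intervening-gene counts
#' between family members are meaningful. Scaffolds are indexed
#' separately from chromosomes, each sequence independently.
#'
#' @param gms a [GeneModelSet-class] holding all annotated genes.
#' @return data.frame with columns \code{gene_id}, \code{chromosome},
#'   \code{start}, \code{end}, \code{is_scaffold} and dense 0-based
#'   \code{rank} within each sequence.
#' @export
orderGenes <- function(gms) {
  g <- geneRanges(gms)
  if (anyDuplicated(g$gene_id))
    stop("duplicate gene_id: ", g$gene_id[duplicated(g$gene_id)][1])
  df <- data.frame(gene_id = g$gene_id,
                   chromosome = as.character(seqnames(g)),
                   start = start(g), end = end(g),
                   is_scaffold = g$is_scaffold,
                   stringsAsFactors = FALSE)
  df <- df[order(df$chromosome, df$start, df$gene_id), , drop = FALSE]
  df$rank <- unlist(lapply(split(seq_len(nrow(df)), df$chromosome)[
    unique(df$chromosome)], function(idx) seq_along(idx) - 1L),
    use.names = FALSE)
  rownames(df) <- NULL
  df
}

# union-find over 1..n
.ufFind <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}

#' Detect tandem-duplication sets
#'
#' Two family genes are tandem neighbours when they belong to the same
#' subfamily on the same sequence, are separated by at most
#' \code{tandemMaxIntervening} annotated genes, and their gap distance
#' (closer ends of the two gene spans; 0 when overlapping) is at most
#' \code{tandemMaxDistance}. Connected components of the neighbour graph
#' with two or more members form tandem sets; chained merging is allowed,
#' so end members of a set may exceed the pairwise window.
#'
#' @param assignments data.frame with \code{gene_id}, \code{subfamily}.
#' @param index data.frame from [orderGenes] over all annotated genes.
#' @param config a [PipelineConfig-class].
#' @return data.frame with one row per member gene: \code{set_id},
#'   \code{subfamily}, \code{chromosome}, \code{gene_id}, ordered by
#'   genomic start within each set; empty when no set is found.
#' @export
findTandemSets <- function(assignments, index, config = pipelineConfig()) {
  fam <- merge(assignments[, c("gene_id", "subfamily")], index,
               by = "gene_id")
  empty <- data.frame(set_id = character(0), subfamily = character(0),
                      chromosome = character(0), gene_id = character(0),
                      stringsAsFactors = FALSE)
  if (nrow(fam) == 0L) return(empty)
  fam <- fam[order(fam$chromosome, fam$rank), , drop = FALSE]
  sets <- list()
  for (key in unique(paste(fam$chromosome, fam$subfamily, sep = "\r"))) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
    grp <- fam[fam$chromosome == parts[1] & fam$subfamily == parts[2], ,
               drop = FALSE]
    k <- nrow(grp)
    if (k < 2L) next
    parent <- seq_len(k)
    for (i in seq_len(k - 1L)) {
      for (j in (i + 1L):k) {
        if (grp$rank[j] - grp$rank[i] - 1L > config@tandemMaxIntervening)
          break  # ranks sorted; later j only farther
        gap <- max(0L, grp$start[j] - grp$end[i])
        if (gap <= config@tandemMaxDistance) {
          ri <- .ufFind(parent, i); rj <- .ufFind(parent, j)
          if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
        }
      }
    }
    roots <- vapply(seq_len(k), function(i) .ufFind(parent, i), integer(1))
    for (r in unique(roots)) {
      members <- which(roots == r)
      if (length(members) >= 2L)
        sets[[length(sets) + 1L]] <-
          data.frame(subfamily = parts[2], chromosome = parts[1],
                     gene_id = grp$gene_id[members],
                     start = grp$start[members], stringsAsFactors = FALSE)
    }
  }
  if (length(sets) == 0L) return(empty)
  # deterministic set ids: by chromosome then first member start
  firsts <- vapply(sets, function(s) min(s$start), numeric(1))
  chrs <- vapply(sets, function(s) s$chromosome[1], character(1))
  ord <- order(chrs, firsts)
  out <- do.call(rbind, lapply(seq_along(ord), function(i) {
    s <- sets[[ord[i]]]
    s <- s[order(s$start), , drop = FALSE]
    data.frame(set_id = sprintf("TD%03d", i), subfamily = s$subfamily,
               chromosome = s$chromosome, gene_id = s$gene_id,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Summarize tandem duplication per subfamily
#'
#' Per-subfamily set and gene counts, totals, the share of sets and genes
#' falling in the expanded subfamilies (XI-1/XI-2/XI-3 and XII), and the
#' fraction of each subfamily's members that are tandem duplicates.
#'
#' @param sets data.frame from [findTandemSets].
#' @param assignments data.frame with \code{gene_id}, \code{subfamily}
#'   (the family universe, for per-subfamily tandem fractions).
#' @return list with \code{table} (per-subfamily n_genes/n_sets and
#'   tandem fraction), \code{total_sets}, \code{total_genes},
#'   \code{xi_xii_set_share} and \code{xi_xii_gene_share} (percentages,
#'   one decimal; 0 when no sets exist).
#' @export
summarizeTandem <- function(sets, assignments = NULL) {
  if (nrow(sets) == 0L)
    return(list(table = data.frame(subfamily = character(0),
                                   n_genes = integer(0),
                                   n_sets = integer(0),
                                   tandem_fraction = numeric(0),
                                   stringsAsFactors = FALSE),
                total_sets = 0L, total_genes = 0L,
                xi_xii_set_share = 0, xi_xii_gene_share = 0))
  perSet <- unique(sets[, c("set_id", "subfamily")])
  nSets <- table(perSet$subfamily)
  nGenes <- table(sets$subfamily)
  sf <- sort(unique(sets$subfamily))
  tab <- data.frame(subfamily = sf,
                    n_genes = as.integer(nGenes[sf]),
                    n_sets = as.integer(nSets[sf]),
                    stringsAsFactors = FALSE)
  if (!is.null(assignments)) {
    famSize <- table(assignments$subfamily)
    tab$tandem_fraction <- round(tab$n_genes /
                                   as.integer(famSize[tab$subfamily]), 3)
  }
  shares <- tandemShares(setNames(tab$n_genes, tab$subfamily),
                         setNames(tab$n_sets, tab$subfamily))
  list(table = tab,
       total_sets = sum(tab$n_sets), total_genes = sum(tab$n_genes),
       xi_xii_set_share = shares$set_share,
       xi_xii_gene_share = shares$gene_share)
}

#' Share of tandem duplication in the expanded subfamilies
#'
#' From per-subfamily tandem gene and set counts, computes the percentage
#' of all tandem sets and of all tandem-duplicated genes that fall in the
#' expanded subfamilies XI (XI-1, XI-2, XI-3) and XII.
#'
#' @param nGenes,nSets named numeric vectors of per-subfamily tandem
#'   gene and set counts.
#' @param expanded the subfamily labels counted as expanded.
#' @return list with \code{set_share} and \code{gene_share}
#'   (percentages rounded to one decimal) and the totals.
#' @examples
#' tandemShares(c("XI-1" = 31, "XII" = 31, "VIII-2" = 10, II = 5, III = 2),
#'              c("XI-1" = 11, "XII" = 8, "VIII-2" = 4, II = 2, III = 1))
#' @export
tandemShares <- function(nGenes, nSets,
                         expanded = c("XI-1", "XI-2", "XI-3", "XII")) {
  totG <- sum(nGenes); totS <- sum(nSets)
  eg <- sum(nGenes[names(nGenes) %in% expanded])
  es <- sum(nSets[names(nSets) %in% expanded])
  list(set_share = if (totS > 0) .round1(100 * es / totS) else 0,
       gene_share = if (totG > 0) .round1(100 * eg / totG) else 0,
       total_sets = totS, total_genes = totG)
}

#' Scaffold placement summary
#'
#' Counts family genes located on scaffolds versus chromosomes and the
#' scaffold percentage (one decimal).
#'
#' @param nScaffold number of family genes on scaffolds.
#' @param total total family size.
#' @return list with \code{n}, \code{total}, \code{pct}.
#' @export
scaffoldShare <- function(nScaffold, total) {
  list(n = nScaffold, total = total,
       pct = .round1(100 * nScaffold / total))
}
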