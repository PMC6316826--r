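#' @importFrom Biostrings DNAString DNAStringSet reverseComplement
#'   matchPattern subseq
NULL

.IUPAC <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
            "B", "D", "H", "V", "N")

#' Read a cis-element catalog
#'
#' TSV with header columns \code{element_id, motif, category}. Motifs
#' must be non-empty IUPAC nucleotide strings.
#'
#' @param path path to the catalog TSV; defaults to the synthetic
#'   catalog shipped with the package (element names follow the field's
#'   conventional cis-element ids; the motif strings are synthetic
#'   placeholders, not database definitions).
#' @return data.frame with columns element_id, motif, category.
#' @export
readCisCatalog <- function(path = system.file("extdata",
                                              "cis_catalog_synthetic.tsv",
                                              package = "rlkfam")) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("element_id", "motif", "category")
  if (!all(need %in% names(df)))
    stop("catalog missing columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  df$motif <- toupper(df$motif)
  ok <- vapply(strsplit(df$motif, ""), function(ch)
    length(ch) > 0L && all(ch %in% .IUPAC), logical(1))
  if (!all(ok))
    stop("invalid IUPAC motif in catalog: ", df$element_id[!ok][1])
  df[need]
}

#' Extract promoter sequences
#'
#' The promoter is the window of \code{length} bp upstream of the start
#' codon (the first CDS base in transcription orientation): for a plus
#' strand gene with start codon at position s, genomic
#' \code{[s-length, s-1]}; for a minus strand gene with start codon at
#' position e, genomic \code{(e, e+length]} reverse-complemented.
#' Windows are truncated (and flagged) at contig edges. Genes without a
#' CDS are skipped with a warning.
#'
#' @param genome a \code{DNAStringSet} of genome sequences.
#' @param gms a [GeneModelSet-class].
#' @param length promoter window length in bp.
#' @return a \code{DNAStringSet} named by gene id, with metadata columns
#'   \code{truncated}, \code{window_start}, \code{window_end}.
#' @export
extractPromoters <- function(genome, gms, length = 1500L) {
  g <- geneRanges(gms)
  seqs <- character(0); ids <- character(0)
  trunc <- logical(0); ws <- integer(0); we <- integer(0)
  for (i in seq_along(geneIds(gms))) {
    cd <- cdsList(gms)[[i]]
    if (base::length(cd) == 0L) {
      warning("gene ", g$gene_id[i], " has no CDS; skipped")
      next
    }
    chr <- as.character(seqnames(g)[i])
    chrSeq <- genome[[chr]]
    chrLen <- base::length(chrSeq)
    minus <- as.character(strand(g)[i]) == "-"
    if (minus) {
      scodon <- max(end(cd))
      from <- scodon + 1L
      to <- min(chrLen, scodon + length)
      if (from > to) next
      s <- as.character(reverseComplement(subseq(chrSeq, from, to)))
      tr <- to < scodon + length
    } else {
      scodon <- min(start(cd))
      from <- max(1L, scodon - length)
      to <- scodon - 1L
      if (from > to) next
      s <- as.character(subseq(chrSeq, from, to))
      tr <- from > scodon - length
    }
    seqs <- c(seqs, s); ids <- c(ids, g$gene_id[i])
    trunc <- c(trunc, tr); ws <- c(ws, from); we <- c(we, to)
  }
  out <- DNAStringSet(seqs)
  names(out) <- ids
  mcols(out) <- DataFrame(truncated = trunc, window_start = ws,
                          window_end = we)
  out
}

#' Scan promoters for IUPAC cis-element motifs
#'
#' Reports every IUPAC-compatible occurrence of every catalog motif on
#' both strands of every promoter; overlapping occurrences are all
#' reported. Offsets are 0-based positions in the promoter sequence (for
#' minus-strand matches, the position of the occurrence of the motif's
#' reverse complement).
#'
#' @param promoters a named \code{DNAStringSet} (see [extractPromoters]).
#' @param catalog data.frame from [readCisCatalog].
#' @return data.frame with columns \code{gene_id}, \code{element_id},
#'   \code{offset}, \code{strand}.
#' @export
scanMotifs <- function(promoters, catalog) {
  rows <- list()
  for (e in seq_len(nrow(catalog))) {
    fwd <- DNAString(catalog$motif[e])
    rev <- reverseComplement(fwd)
    for (i in seq_along(promoters)) {
      subj <- promoters[[i]]
      mF <- matchPattern(fwd, subj, fixed = "subject")
      mR <- matchPattern(rev, subj, fixed = "subject")
      if (length(mF))
        rows[[length(rows) + 1L]] <- data.frame(
          gene_id = names(promoters)[i],
          element_id = catalog$element_id[e],
          offset = start(mF) - 1L, strand = "+",
          stringsAsFactors = FALSE)
      if (length(mR))
        rows[[length(rows) + 1L]] <- data.frame(
          gene_id = names(promoters)[i],
          element_id = catalog$element_id[e],
          offset = start(mR) - 1L, strand = "-",
          stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(gene_id = character(0), element_id = character(0),
                      offset = integer(0), strand = character(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out <- out[order(out$gene_id, out$element_id, out$offset, out$strand), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-category promoter element presence
#'
#' A gene counts once toward a category when at least one element of
#' that category matches its promoter, regardless of how many elements
#' or occurrences.
#'
#' @param matches data.frame from [scanMotifs].
#' @param catalog data.frame from [readCisCatalog].
#' @param universe character vector of genes forming the denominator.
#' @return list with \code{table} (data.frame category, n_genes, pct)
#'   and \code{presence} (logical gene-by-category matrix over the
#'   universe).
#' @export
categorizePresence <- function(matches, catalog, universe) {
  cats <- unique(catalog$category)
  pres <- matrix(FALSE, nrow = length(universe), ncol = length(cats),
                 dimnames = list(universe, cats))
  if (nrow(matches)) {
    mcat <- catalog$category[match(matches$element_id,
                                   catalog$element_id)]
    keep <- matches$gene_id %in% universe & !is.na(mcat)
    pres[cbind(matches$gene_id[keep], mcat[keep])] <- TRUE
  }
  n <- colSums(pres)
  list(table = data.frame(category = cats, n_genes = as.integer(n),
                          pct = .round1(100 * n / length(universe)),
                          row.names = NULL, stringsAsFactors = FALSE),
       presence = pres)
}

#' Per-subfamily cis-element over-representation
#'
#' For every (subfamily, category) pair, tests whether promoters of the
#' subfamily's members carry the category more often than the family
#' background with a one-sided hypergeometric (upper-tail) test;
#' Benjamini-Hochberg adjustment is applied across all tested pairs.
#'
#' @param presence logical gene-by-category matrix (the background
#'   universe is its row set).
#' @param assignments data.frame with \code{gene_id}, \code{subfamily}.
#' @param alpha significance threshold on the adjusted p-value.
#' @return data.frame with columns subfamily, category, n, k, K, N, p,
#'   p_adj, significant; subfamilies with no member in the universe are
#'   skipped.
#' @importFrom stats phyper p.adjust
#' @export
subfamilyCisEnrichment <- function(presence, assignments, alpha = 0.05) {
  genes <- rownames(presence)
  sf <- assignments$subfamily[match(genes, assignments$gene_id)]
  N <- length(genes)
  rows <- list()
  for (s in sort(unique(sf[!is.na(sf)]))) {
    inS <- which(sf == s)
    n <- length(inS)
    if (n == 0L) next
    for (cat in colnames(presence)) {
      K <- sum(presence[, cat])
      x <- sum(presence[inS, cat])
      p <- phyper(x - 1, K, N - K, n, lower.tail = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        subfamily = s, category = cat, n = n, k = x, K = K, N = N,
        p = p, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(subfamily = character(0), category = character(0),
                      n = integer(0), k = integer(0), K = integer(0),
                      N = integer(0), p = numeric(0), p_adj = numeric(0),
                      significant = logical(0), stringsAsFactors = FALSE))
  out$p_adj <- p.adjust(out$p, method = "BH")
  out$significant <- out$p_adj < alpha
  rownames(out) <- NULL
  out
}
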