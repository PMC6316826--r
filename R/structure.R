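#' Map a protein-coordinate interval onto the genome
#'
#' Residues \code{p..q} occupy coding nucleotides \code{3p-2..3q} of the
#' spliced CDS. The nucleotide run is split at CDS segment boundaries and
#' projected onto the genome; on the minus strand the CDS is walked in
#' transcription (3' to 5' genomic) order. Returned intervals are sorted
#' by genomic start.
#'
#' @param gms a [GeneModelSet-class].
#' @param geneId one gene id in \code{gms}.
#' @param proteinStart,proteinEnd 1-based inclusive residue interval;
#'   must lie within the translated CDS length.
#' @return an \code{IRanges} of genomic intervals (1-based inclusive).
#' @examples
#' sim <- simulateStudy(seed = 1, nGenes = 30, nFamily = 10)
#' gid <- geneIds(models(sim))[1]
#' mapProteinToGenome(models(sim), gid, 1, 10)
#' @export
mapProteinToGenome <- function(gms, geneId, proteinStart, proteinEnd) {
  m <- gms[geneId]
  cd <- cdsList(m)[[1]]
  if (length(cd) == 0L) stop("gene ", geneId, " has no CDS")
  minus <- as.character(strand(geneRanges(m))[1]) == "-"
  if (minus) cd <- cd[order(-start(cd))]
  w <- width(cd)
  protLen <- sum(w) %/% 3L
  if (proteinStart < 1L || proteinEnd > protLen || proteinStart > proteinEnd)
    stop("protein interval ", proteinStart, "-", proteinEnd,
         " outside translated length ", protLen)
  ntFrom <- 3L * proteinStart - 2L
  ntTo <- 3L * proteinEnd
  offs <- cumsum(c(0L, w[-length(w)]))  # CDS nt preceding each segment
  res <- IRanges()
  for (i in seq_along(w)) {
    segFrom <- offs[i] + 1L
    segTo <- offs[i] + w[i]
    lo <- max(ntFrom, segFrom)
    hi <- min(ntTo, segTo)
    if (lo > hi) next
    if (minus) {
      gHi <- end(cd)[i] - (lo - segFrom)
      gLo <- end(cd)[i] - (hi - segFrom)
      res <- c(res, IRanges(gLo, gHi))
    } else {
      gLo <- start(cd)[i] + (lo - segFrom)
      gHi <- start(cd)[i] + (hi - segFrom)
      res <- c(res, IRanges(gLo, gHi))
    }
  }
  sort(res)
}

#' Count introns inside a domain's genomic projection
#'
#' The mapped genomic intervals of a domain are separated only by
#' introns, so the number of intron boundaries strictly inside the domain
#' equals the number of disjoint genomic intervals minus one.
#'
#' @param genomicIntervals \code{IRanges} from [mapProteinToGenome].
#' @return integer intron count (0 for a single-exon domain).
#' @export
countIntronsInRegion <- function(genomicIntervals) {
  n <- length(reduce(genomicIntervals))
  if (n == 0L) return(0L)
  n - 1L
}

#' Assign the kinase-domain structure group
#'
#' Genes whose KD lies on an integral exon form Group A; a KD split by
#' one intron gives Group B; three or more KD-bearing exons give Group C
#' (counts above six, beyond the commonly observed range, are accepted).
#' Genes with no mapped KD are unassigned.
#'
#' @param kdExonCount number of genomic intervals the KD maps to.
#' @return \code{"A"}, \code{"B"}, \code{"C"} or \code{"unassigned"}.
#' @export
assignStructureGroup <- function(kdExonCount) {
  vapply(kdExonCount, function(k) {
    if (is.na(k) || k == 0L) "unassigned"
    else if (k == 1L) "A"
    else if (k == 2L) "B"
    else "C"
  }, character(1))
}

#' Exon-intron structure profiles for family genes
#'
#' For every gene with domain spans, projects the KD and the ECD (the
#' region N-terminal of the first TM segment) onto the genome and counts
#' the introns in each, then assigns the structure group.
#'
#' @param gms a [GeneModelSet-class].
#' @param domains data.frame with columns
#'   \code{protein_id, class, start, end} in protein coordinates
#'   (\code{class} in \code{lrr}, \code{tm}, \code{kd}); protein ids must
#'   be gene ids or translated through \code{proteinToGene}.
#' @param proteinToGene optional named character vector mapping protein
#'   ids to gene ids (defaults to identity).
#' @return data.frame with columns \code{gene_id}, \code{n_exons},
#'   \code{kd_exon_count}, \code{introns_in_kd}, \code{introns_in_ecd},
#'   \code{group}.
#' @export
structureProfiles <- function(gms, domains, proteinToGene = NULL) {
  prot <- unique(domains$protein_id)
  gene <- if (is.null(proteinToGene)) prot else unname(proteinToGene[prot])
  keep <- gene %in% geneIds(gms)
  prot <- prot[keep]; gene <- gene[keep]
  rows <- lapply(seq_along(prot), function(i) {
    d <- domains[domains$protein_id == prot[i], , drop = FALSE]
    nEx <- length(exonList(gms[gene[i]])[[1]])
    kd <- d[d$class == "kd", , drop = FALSE]
    kdN <- 0L
    if (nrow(kd)) {
      kdM <- .mergeSpans(IRanges(kd$start, kd$end))
      kdIv <- IRanges()
      for (j in seq_along(kdM))
        kdIv <- c(kdIv, mapProteinToGenome(gms, gene[i],
                                           start(kdM)[j], end(kdM)[j]))
      kdN <- length(reduce(kdIv))
    }
    tm <- d[d$class == "tm", , drop = FALSE]
    ecdIntrons <- NA_integer_
    if (nrow(tm)) {
      ecdEnd <- min(tm$start) - 1L
      if (ecdEnd >= 1L) {
        iv <- mapProteinToGenome(gms, gene[i], 1L, ecdEnd)
        ecdIntrons <- countIntronsInRegion(iv)
      } else ecdIntrons <- 0L
    }
    data.frame(gene_id = gene[i], n_exons = nEx, kd_exon_count = kdN,
               introns_in_kd = max(kdN - 1L, 0L),
               introns_in_ecd = ecdIntrons,
               group = assignStructureGroup(kdN),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(gene_id = character(0), n_exons = integer(0),
                      kd_exon_count = integer(0), introns_in_kd = integer(0),
                      introns_in_ecd = integer(0), group = character(0),
                      stringsAsFactors = FALSE)
  out
}

#' Flag intronless retrogene candidates
#'
#' An intronless (single-exon) family gene whose subfamily contains at
#' least one member with two or more introns is flagged as a candidate
#' retrogene: the multi-intron subfamily mate is the witness that the
#' gene's close homologues carry introns it has lost.
#'
#' @param profiles data.frame from [structureProfiles].
#' @param assignments data.frame with \code{gene_id} and
#'   \code{subfamily}.
#' @return character vector of flagged gene ids (sorted).
#' @export
detectIntronless <- function(profiles, assignments) {
  sf <- assignments$subfamily[match(profiles$gene_id,
                                    assignments$gene_id)]
  introns <- profiles$n_exons - 1L
  flagged <- character(0)
  for (s in unique(sf[!is.na(sf)])) {
    idx <- which(sf == s)
    if (any(introns[idx] >= 2L)) {
      z <- idx[profiles$n_exons[idx] == 1L]
      flagged <- c(flagged, profiles$gene_id[z])
    }
  }
  sort(flagged)
}

#' Per-subfamily intron-count summary
#'
#' Mean and standard deviation of intron counts in the ECD and KD per
#' subfamily (the per-subfamily structure summary).
#'
#' @param profiles data.frame from [structureProfiles].
#' @param assignments data.frame with \code{gene_id}, \code{subfamily}.
#' @return data.frame with per-subfamily means and standard deviations.
#' @export
summarizeStructure <- function(profiles, assignments) {
  sf <- assignments$subfamily[match(profiles$gene_id,
                                    assignments$gene_id)]
  keep <- !is.na(sf)
  p <- profiles[keep, , drop = FALSE]; sf <- sf[keep]
  out <- do.call(rbind, lapply(split(seq_len(nrow(p)), sf), function(idx) {
    data.frame(subfamily = sf[idx[1]], n = length(idx),
               kd_introns_mean = mean(p$introns_in_kd[idx]),
               kd_introns_sd = if (length(idx) > 1)
                 stats::sd(p$introns_in_kd[idx]) else NA_real_,
               ecd_introns_mean = mean(p$introns_in_ecd[idx], na.rm = TRUE),
               ecd_introns_sd = if (length(idx) > 1)
                 stats::sd(p$introns_in_ecd[idx], na.rm = TRUE) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
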