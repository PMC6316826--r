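#' @import methods
#' @import S4Vectors
#' @import IRanges
#' @import GenomicRanges
NULL

# round half away from zero, as printed tables conventionally do
# (base round() rounds half to even: 81.25 -> 81.2, not the printed 81.3)
.round1 <- function(x) sign(x) * floor(abs(x) * 10 + 0.5) / 10

# The 21 canonical LRR-RLK subfamily labels (kinase-domain phylogeny
# nomenclature with the VI/VII/VIII/XI sub-splits).
.SUBFAMILY_LABELS <- c(
  "I", "II", "III", "IV", "V", "VI-1", "VI-2", "VII-1", "VII-2",
  "VIII-1", "VIII-2", "IX", "X", "XI-1", "XI-2", "XI-3", "XII",
  "XIII-1", "XIII-2", "XIV", "XV"
)

#' PipelineConfig: every numeric threshold of the pipeline in one place
#'
#' Holds the analysis thresholds used throughout the pipeline: evidence
#' E-value cutoffs, the similarity identity floor, the promoter window,
#' the tandem-duplication adjacency window, differential-expression
#' cutoffs, clustering group counts and the canonical subfamily label set.
#'
#' @slot hmmEvalueMax maximum E-value for a profile-HMM domain hit.
#' @slot simEvalueMax maximum E-value for a similarity-search hit.
#' @slot simIdentityMin minimum percent identity (strict >) for a
#'   similarity-search hit.
#' @slot promoterLength promoter window upstream of the start codon, bp.
#' @slot tandemMaxIntervening maximum number of intervening genes between
#'   two tandem neighbours.
#' @slot tandemMaxDistance maximum gap distance between two tandem
#'   neighbours, bp.
#' @slot deLfcMin minimum |log2 fold change| for a DE call (strict >).
#' @slot deFdrMax maximum FDR for a DE call (strict <).
#' @slot hclustGroups number of hierarchical-clustering groups.
#' @slot kmeansK number of k-means groups.
#' @slot logOffset pseudo-count added before log10 transformation.
#' @slot subfamilyLabels the 21 subfamily labels.
#' @slot chromPattern regular expression recognising chromosome (as
#'   opposed to scaffold) sequence names.
#' @export
setClass("PipelineConfig", representation(
  hmmEvalueMax = "numeric",
  simEvalueMax = "numeric",
  simIdentityMin = "numeric",
  promoterLength = "integer",
  tandemMaxIntervening = "integer",
  tandemMaxDistance = "integer",
  deLfcMin = "numeric",
  deFdrMax = "numeric",
  hclustGroups = "integer",
  kmeansK = "integer",
  logOffset = "numeric",
  subfamilyLabels = "character",
  chromPattern = "character"
))

setValidity("PipelineConfig", function(object) {
  msgs <- character(0)
  thr <- c(
    hmmEvalueMax = object@hmmEvalueMax,
    simEvalueMax = object@simEvalueMax,
    simIdentityMin = object@simIdentityMin,
    promoterLength = object@promoterLength,
    tandemMaxDistance = object@tandemMaxDistance,
    deLfcMin = object@deLfcMin,
    deFdrMax = object@deFdrMax,
    hclustGroups = object@hclustGroups,
    kmeansK = object@kmeansK,
    logOffset = object@logOffset
  )
  if (any(!is.finite(thr)) || any(thr <= 0))
    msgs <- c(msgs, "all thresholds must be finite and strictly positive")
  if (object@tandemMaxIntervening < 0)
    msgs <- c(msgs, "tandemMaxIntervening must be non-negative")
  if (length(object@subfamilyLabels) != 21L ||
      anyDuplicated(object@subfamilyLabels))
    msgs <- c(msgs, "subfamilyLabels must be 21 distinct labels")
  if (length(msgs)) msgs else TRUE
})

#' Construct a PipelineConfig
#'
#' Defaults are the study conditions of the pipeline: HMM hits kept at
#' E-value <= 1e-10, similarity hits at E-value <= 1e-5 and identity
#' > 50 percent, 1.5 kb promoters, tandem neighbours separated by at most
#' 10 intervening genes within 200 kb, DE calls at |log2FC| > 1 and
#' FDR < 0.05, 4 hierarchical groups, k-means with k = 2, and a
#' pseudo-count of 1 before log10 transformation.
#'
#' @param hmmEvalueMax,simEvalueMax,simIdentityMin evidence thresholds.
#' @param promoterLength promoter window in bp.
#' @param tandemMaxIntervening,tandemMaxDistance tandem adjacency window.
#' @param deLfcMin,deFdrMax differential-expression cutoffs.
#' @param hclustGroups,kmeansK clustering group counts.
#' @param logOffset pseudo-count for the log10 transform.
#' @param subfamilyLabels the subfamily label set (21 labels).
#' @param chromPattern regex matched against sequence names; non-matching
#'   names are flagged as scaffolds.
#' @return A [PipelineConfig-class] object.
#' @examples
#' cfg <- pipelineConfig()
#' cfg
#' @export
pipelineConfig <- function(hmmEvalueMax = 1e-10,
                           simEvalueMax = 1e-5,
                           simIdentityMin = 50.0,
                           promoterLength = 1500L,
                           tandemMaxIntervening = 10L,
                           tandemMaxDistance = 200000L,
                           deLfcMin = 1.0,
                           deFdrMax = 0.05,
                           hclustGroups = 4L,
                           kmeansK = 2L,
                           logOffset = 1.0,
                           subfamilyLabels = .SUBFAMILY_LABELS,
                           chromPattern = "^(A|D)?[0-9]+$") {
  new("PipelineConfig",
      hmmEvalueMax = hmmEvalueMax,
      simEvalueMax = simEvalueMax,
      simIdentityMin = simIdentityMin,
      promoterLength = as.integer(promoterLength),
      tandemMaxIntervening = as.integer(tandemMaxIntervening),
      tandemMaxDistance = as.integer(tandemMaxDistance),
      deLfcMin = deLfcMin,
      deFdrMax = deFdrMax,
      hclustGroups = as.integer(hclustGroups),
      kmeansK = as.integer(kmeansK),
      logOffset = logOffset,
      subfamilyLabels = subfamilyLabels,
      chromPattern = chromPattern)
}

#' The 21 canonical LRR-RLK subfamily labels
#'
#' @return Character vector of the 21 labels (I through XV with the
#'   VI, VII, VIII and XI sub-splits).
#' @examples
#' subfamilyLabels()
#' @export
subfamilyLabels <- function() .SUBFAMILY_LABELS

setMethod("show", "PipelineConfig", function(object) {
  cat("PipelineConfig\n")
  cat("  HMM E-value <=", format(object@hmmEvalueMax), "\n")
  cat("  similarity E-value <=", format(object@simEvalueMax),
      ", identity >", object@simIdentityMin, "%\n")
  cat("  promoter:", object@promoterLength, "bp upstream of start codon\n")
  cat("  tandem: <=", object@tandemMaxIntervening, "intervening genes, <=",
      object@tandemMaxDistance, "bp\n")
  cat("  DE: |log2FC| >", object@deLfcMin, ", FDR <", object@deFdrMax, "\n")
  cat("  clustering: hclust", object@hclustGroups, "groups, k-means k =",
      object@kmeansK, "\n")
  cat("  ", length(object@subfamilyLabels), " subfamily labels\n", sep = "")
})

#' GeneModelSet: gene models from a genome annotation
#'
#' Container for the gene models of one annotated genome: one genomic
#' range per gene plus per-gene exon and CDS structures (1-based
#' inclusive coordinates throughout, matching GFF3). One representative
#' transcript per gene.
#'
#' @slot genes a \code{GRanges}, one range per gene, with metadata
#'   columns \code{gene_id}, \code{transcript_id} and \code{is_scaffold}.
#' @slot exons a \code{GRangesList} (parallel to \code{genes}) of exon
#'   ranges sorted by genomic start.
#' @slot cds a \code{GRangesList} (parallel to \code{genes}) of CDS
#'   segments sorted by genomic start, with metadata column \code{phase}.
#' @export
setClass("GeneModelSet", representation(
  genes = "GRanges",
  exons = "GRangesList",
  cds = "GRangesList"
))

setValidity("GeneModelSet", function(object) {
  msgs <- character(0)
  n <- length(object@genes)
  ids <- object@genes$gene_id
  if (is.null(ids) || anyDuplicated(ids))
    msgs <- c(msgs, "genes must carry unique gene_id metadata")
  if (length(object@exons) != n || length(object@cds) != n)
    msgs <- c(msgs, "exons and cds must be parallel to genes")
  for (i in seq_len(n)) {
    ex <- object@exons[[i]]
    cd <- object@cds[[i]]
    id <- ids[i]
    if (length(ex) == 0L) {
      msgs <- c(msgs, paste0(id, ": no exons")); next
    }
    s <- start(ex); e <- end(ex)
    if (is.unsorted(s, strictly = FALSE) ||
        (length(ex) > 1L && any(s[-1] <= e[-length(e)])))
      msgs <- c(msgs, paste0(id, ": exons must be sorted and non-overlapping"))
    if (min(s) < start(object@genes[i]) || max(e) > end(object@genes[i]))
      msgs <- c(msgs, paste0(id, ": gene span must cover all exons"))
    if (length(cd)) {
      # every CDS base must fall inside the exon union
      cov <- reduce(c(IRanges(s, e), IRanges(start(cd), end(cd))))
      if (sum(width(cov)) != sum(width(reduce(IRanges(s, e)))))
        msgs <- c(msgs, paste0(id, ": CDS outside exon union"))
      ph <- cd$phase
      if (is.null(ph)) ph <- rep(0L, length(cd))
      first <- if (as.character(strand(object@genes[i])) == "-")
        which.max(end(cd)) else which.min(start(cd))
      if ((sum(width(cd)) - ph[first]) %% 3L != 0L)
        msgs <- c(msgs, paste0(id, ": CDS length not divisible by 3 ",
                               "after phase adjustment"))
    }
    if (length(msgs) > 20L) break
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a GeneModelSet
#'
#' @param genes \code{GRanges} with \code{gene_id} (and optionally
#'   \code{transcript_id}) metadata.
#' @param exons,cds \code{GRangesList}s parallel to \code{genes}.
#' @param chromPattern regex recognising chromosome names; used to set
#'   the \code{is_scaffold} flag.
#' @return A [GeneModelSet-class].
#' @export
GeneModelSet <- function(genes, exons, cds,
                         chromPattern = "^(A|D)?[0-9]+$") {
  if (is.null(genes$is_scaffold))
    genes$is_scaffold <- !grepl(chromPattern, as.character(seqnames(genes)))
  names(exons) <- genes$gene_id
  names(cds) <- genes$gene_id
  new("GeneModelSet", genes = genes, exons = exons, cds = cds)
}

#' @describeIn GeneModelSet number of genes
#' @param x a GeneModelSet
#' @export
setMethod("length", "GeneModelSet", function(x) length(x@genes))

#' Accessors for GeneModelSet
#'
#' \code{geneIds} returns the gene identifiers; \code{geneRanges} the
#' per-gene \code{GRanges}; \code{exonList} and \code{cdsList} the
#' per-gene exon/CDS \code{GRangesList}s.
#'
#' @param x a [GeneModelSet-class].
#' @return See details.
#' @name GeneModelSet-accessors
NULL

#' @rdname GeneModelSet-accessors
#' @export
geneIds <- function(x) x@genes$gene_id

#' @rdname GeneModelSet-accessors
#' @export
geneRanges <- function(x) x@genes

#' @rdname GeneModelSet-accessors
#' @export
exonList <- function(x) x@exons

#' @rdname GeneModelSet-accessors
#' @export
cdsList <- function(x) x@cds

#' @describeIn GeneModelSet subset by index or gene id
#' @param i index or character vector of gene ids
#' @param j,drop,... ignored
#' @export
setMethod("[", "GeneModelSet", function(x, i, j, ..., drop = TRUE) {
  if (is.character(i)) i <- match(i, geneIds(x))
  if (anyNA(i)) stop("unknown gene id")
  new("GeneModelSet", genes = x@genes[i], exons = x@exons[i], cds = x@cds[i])
})

setMethod("show", "GeneModelSet", function(object) {
  cat("GeneModelSet with", length(object), "genes on",
      length(unique(as.character(seqnames(object@genes)))), "sequences\n")
  nsc <- sum(object@genes$is_scaffold)
  if (nsc) cat("  ", nsc, " gene(s) on scaffolds\n", sep = "")
})
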