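#' @importFrom utils read.delim write.table read.table
#' @importFrom Biostrings readDNAStringSet readAAStringSet writeXStringSet
#' @importFrom ape read.tree write.tree
#' @importFrom rtracklayer import
NULL

#' Read gene models from a GFF3 annotation
#'
#' Parses gene/mRNA/exon/CDS features and assembles one [GeneModelSet-class]
#' with one representative transcript per gene (the one with the longest
#' total CDS; ties broken lexicographically by transcript id).
#' Coordinates are kept 1-based inclusive as in the file.
#'
#' @param path path to a GFF3 file.
#' @param chromPattern regex recognising chromosome names; other sequence
#'   names are flagged as scaffolds.
#' @return A [GeneModelSet-class]; empty input yields an empty set.
#' @examples
#' sim <- simulateStudy(seed = 1, nGenes = 30, nFamily = 10)
#' gff <- file.path(tempdir(), "ex.gff3")
#' writeGff3(models(sim), gff)
#' gms <- readGff3(gff)
#' length(gms)
#' @export
readGff3 <- function(path, chromPattern = "^(A|D)?[0-9]+$") {
  # pre-validation pass so malformed intervals are reported with their line
  lines <- readLines(path)
  body <- which(!startsWith(lines, "#") & nzchar(lines))
  for (ln in body) {
    f <- strsplit(lines[ln], "\t", fixed = TRUE)[[1]]
    if (length(f) < 9L)
      stop("GFF3 line ", ln, ": expected 9 tab-separated columns")
    s <- suppressWarnings(as.numeric(f[4])); e <- suppressWarnings(as.numeric(f[5]))
    if (is.na(s) || is.na(e) || s > e)
      stop("GFF3 line ", ln, ": malformed interval ", f[4], "-", f[5])
  }
  if (length(body) == 0L)
    return(GeneModelSet(GRanges(gene_id = character(0),
                                transcript_id = character(0)),
                        GRangesList(), GRangesList(),
                        chromPattern = chromPattern))
  gr <- rtracklayer::import(path, format = "gff3")
  genes <- gr[gr$type == "gene"]
  if (length(genes) == 0L)
    return(GeneModelSet(GRanges(gene_id = character(0),
                                transcript_id = character(0)),
                        GRangesList(), GRangesList(),
                        chromPattern = chromPattern))
  mrna <- gr[gr$type == "mRNA"]
  exon <- gr[gr$type == "exon"]
  cds <- gr[gr$type == "CDS"]
  exonParent <- vapply(exon$Parent, `[`, character(1), 1L)
  cdsParent <- vapply(cds$Parent, `[`, character(1), 1L)
  mrnaParent <- vapply(mrna$Parent, `[`, character(1), 1L)
  exonByTx <- split(seq_along(exon), exonParent)
  cdsByTx <- split(seq_along(cds), cdsParent)
  txByGene <- split(mrna$ID, mrnaParent)
  cdsWidth <- width(cds)

  keepTx <- character(length(genes))
  exIdx <- vector("list", length(genes))
  cdIdx <- vector("list", length(genes))
  for (i in seq_along(genes)) {
    gid <- genes$ID[i]
    txs <- txByGene[[gid]]
    if (is.null(txs))
      stop("gene ", gid, " has no mRNA feature")
    # representative transcript: longest total CDS, ties lexicographic
    cdsLen <- vapply(txs, function(tx)
      sum(cdsWidth[cdsByTx[[tx]]]), numeric(1))
    tx <- txs[order(-cdsLen, txs)][1L]
    ei <- exonByTx[[tx]]; ci <- cdsByTx[[tx]]
    ei <- ei[order(start(exon)[ei])]
    ci <- ci[order(start(cds)[ci])]
    if (length(ci)) {
      exR <- IRanges(start(exon)[ei], end(exon)[ei])
      cov <- reduce(c(exR, IRanges(start(cds)[ci], end(cds)[ci])))
      if (sum(width(cov)) != sum(width(reduce(exR))))
        stop("gene ", gid, ": CDS outside exon union")
    }
    exIdx[[i]] <- ei
    cdIdx[[i]] <- if (is.null(ci)) integer(0) else ci
    keepTx[i] <- tx
  }
  g <- granges(genes)
  g$gene_id <- genes$ID
  g$transcript_id <- keepTx
  exFlat <- granges(exon)[unlist(exIdx)]
  geneFac <- function(idx) factor(rep(genes$ID, lengths(idx)),
                                  levels = genes$ID)
  exGrl <- split(exFlat, geneFac(exIdx))
  cdFlat <- granges(cds)[unlist(cdIdx)]
  cdFlat$phase <- cds$phase[unlist(cdIdx)]
  cdGrl <- split(cdFlat, geneFac(cdIdx))
  GeneModelSet(g, exGrl, cdGrl, chromPattern = chromPattern)
}

#' Write a GeneModelSet as GFF3
#'
#' Emits gene/mRNA/exon/CDS features with deterministic formatting so
#' identical inputs produce byte-identical files.
#'
#' @param gms a [GeneModelSet-class].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeGff3 <- function(gms, path) {
  out <- c("##gff-version 3")
  g <- geneRanges(gms)
  for (i in seq_len(length(gms))) {
    chr <- as.character(seqnames(g)[i])
    std <- as.character(strand(g)[i])
    if (std == "*") std <- "+"
    gid <- g$gene_id[i]
    tid <- if (!is.null(g$transcript_id)) g$transcript_id[i] else
      paste0(gid, ".t1")
    out <- c(out,
      paste(chr, "rlkfam", "gene", start(g)[i], end(g)[i], ".", std, ".",
            paste0("ID=", gid), sep = "\t"),
      paste(chr, "rlkfam", "mRNA", start(g)[i], end(g)[i], ".", std, ".",
            paste0("ID=", tid, ";Parent=", gid), sep = "\t"))
    ex <- exonList(gms)[[i]]
    for (j in seq_along(ex))
      out <- c(out, paste(chr, "rlkfam", "exon", start(ex)[j], end(ex)[j],
                          ".", std, ".", paste0("Parent=", tid), sep = "\t"))
    cd <- cdsList(gms)[[i]]
    ph <- cd$phase
    if (is.null(ph)) ph <- rep(0L, length(cd))
    for (j in seq_along(cd))
      out <- c(out, paste(chr, "rlkfam", "CDS", start(cd)[j], end(cd)[j],
                          ".", std, ph[j], paste0("Parent=", tid),
                          sep = "\t"))
  }
  writeLines(out, path)
  invisible(path)
}

.DOMAIN_HIT_COLS <- c("protein_id", "family_id", "evidence", "e_value",
                      "ali_start", "ali_end", "identity_pct")

.emptyHits <- function() {
  data.frame(protein_id = character(0), family_id = character(0),
             evidence = character(0), e_value = numeric(0),
             ali_start = integer(0), ali_end = integer(0),
             identity_pct = numeric(0), stringsAsFactors = FALSE)
}

.checkHits <- function(df, what) {
  bad <- which(!is.finite(df$e_value))
  if (length(bad))
    stop(what, ": non-numeric or non-finite E-value at row ", bad[1])
  bad <- which(df$ali_start > df$ali_end)
  if (length(bad))
    stop(what, ": alignment start > end at row ", bad[1])
  df
}

#' Read a domain-hit table (HMM evidence)
#'
#' Two dialects are supported. \code{"tsv"} expects a header with columns
#' \code{protein_id, family_id, e_value, ali_start, ali_end}.
#' \code{"domtblout"} parses the HMMER3 per-domain tabular output (hmmsearch
#' with Pfam profiles as queries): the target name is the protein, the
#' query accession (version stripped) the Pfam family, the independent
#' per-domain E-value is used, and alignment coordinates come from the
#' "ali from/to" columns.
#'
#' @param path path to the table.
#' @param dialect \code{"tsv"} or \code{"domtblout"}.
#' @return data.frame of domain hits with \code{evidence = "hmm"}.
#' @export
readDomainTable <- function(path, dialect = c("tsv", "domtblout")) {
  dialect <- match.arg(dialect)
  if (dialect == "tsv") {
    df <- read.delim(path, stringsAsFactors = FALSE,
                     colClasses = "character")
    if (nrow(df) == 0L) return(.emptyHits())
    need <- c("protein_id", "family_id", "e_value", "ali_start", "ali_end")
    if (!all(need %in% names(df)))
      stop("domain table missing columns: ",
           paste(setdiff(need, names(df)), collapse = ", "))
    ev <- suppressWarnings(as.numeric(df$e_value))
    out <- data.frame(protein_id = df$protein_id, family_id = df$family_id,
                      evidence = "hmm", e_value = ev,
                      ali_start = as.integer(df$ali_start),
                      ali_end = as.integer(df$ali_end),
                      identity_pct = NA_real_, stringsAsFactors = FALSE)
    return(.checkHits(out, "domain table"))
  }
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(lines) == 0L) return(.emptyHits())
  fields <- strsplit(trimws(lines), "[[:space:]]+")
  nf <- vapply(fields, length, integer(1))
  if (any(nf < 22L))
    stop("domtblout: fewer than 22 columns at row ", which(nf < 22L)[1])
  getcol <- function(k) vapply(fields, `[`, character(1), k)
  fam <- getcol(5L)
  noacc <- fam == "-"
  fam[noacc] <- getcol(4L)[noacc]
  fam <- sub("\\.[0-9]+$", "", fam)
  ev <- suppressWarnings(as.numeric(getcol(13L)))
  out <- data.frame(protein_id = getcol(1L), family_id = fam,
                    evidence = "hmm", e_value = ev,
                    ali_start = as.integer(getcol(18L)),
                    ali_end = as.integer(getcol(19L)),
                    identity_pct = NA_real_, stringsAsFactors = FALSE)
  .checkHits(out, "domtblout")
}

#' Read a 12-column blast-tabular similarity table
#'
#' Standard tabular dialect (query, subject, identity, length, mismatches,
#' gapopens, qstart, qend, sstart, send, evalue, bitscore), no header.
#' The query is taken as the candidate protein; its alignment coordinates
#' populate \code{ali_start}/\code{ali_end}. No filtering is applied here.
#'
#' @param path path to the table.
#' @return data.frame of hits with \code{evidence = "similarity"} and
#'   \code{identity_pct} populated.
#' @export
readSimilarityTable <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(.emptyHits())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- vapply(fields, length, integer(1))
  if (any(nf != 12L))
    stop("similarity table: expected 12 columns, found ", nf[nf != 12L][1],
         " at row ", which(nf != 12L)[1])
  getcol <- function(k) vapply(fields, `[`, character(1), k)
  out <- data.frame(protein_id = getcol(1L), family_id = getcol(2L),
                    evidence = "similarity",
                    e_value = suppressWarnings(as.numeric(getcol(11L))),
                    ali_start = as.integer(getcol(7L)),
                    ali_end = as.integer(getcol(8L)),
                    identity_pct = as.numeric(getcol(3L)),
                    stringsAsFactors = FALSE)
  .checkHits(out, "similarity table")
}

#' Read a transmembrane-segment table
#'
#' Expects a header with columns \code{protein_id, start, end}; a protein
#' may appear on zero or more rows (zero segments = absent).
#'
#' @param path path to the table.
#' @param predictor label recorded in the \code{predictor} column
#'   (\code{"predictor_a"} or \code{"predictor_b"}).
#' @return data.frame with columns protein_id, predictor, start, end.
#' @export
readTmTable <- function(path, predictor = c("predictor_a", "predictor_b")) {
  predictor <- match.arg(predictor)
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L)
    return(data.frame(protein_id = character(0), predictor = character(0),
                      start = integer(0), end = integer(0),
                      stringsAsFactors = FALSE))
  if (any(df$start > df$end))
    stop("TM table: segment start > end at row ", which(df$start > df$end)[1])
  data.frame(protein_id = df$protein_id, predictor = predictor,
             start = as.integer(df$start), end = as.integer(df$end),
             stringsAsFactors = FALSE)
}

#' Read a Newick tree
#'
#' @param path path to a Newick file.
#' @return an \code{ape} \code{phylo} object.
#' @export
readNewick <- function(path) ape::read.tree(path)

#' Read sequences from FASTA
#'
#' @param path path to a FASTA file.
#' @param type \code{"DNA"} or \code{"AA"}.
#' @return a \code{DNAStringSet} or \code{AAStringSet}.
#' @export
readFasta <- function(path, type = c("DNA", "AA")) {
  type <- match.arg(type)
  if (type == "DNA") readDNAStringSet(path) else readAAStringSet(path)
}

#' Read a gene-by-sample numeric matrix from TSV
#'
#' First column holds the gene id (must be unique); remaining columns are
#' numeric samples.
#'
#' @param path path to the TSV.
#' @return numeric matrix with gene ids as rownames.
#' @export
readMatrixTsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (anyDuplicated(df[[1]]))
    stop("duplicate gene ids in matrix: ",
         df[[1]][duplicated(df[[1]])][1])
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' Write a gene-by-sample matrix as TSV
#'
#' @param m numeric matrix with rownames.
#' @param path output path.
#' @param idCol name for the gene-id column.
#' @return \code{path}, invisibly.
#' @export
writeMatrixTsv <- function(m, path, idCol = "gene_id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- idCol
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# deterministic TSV writer used by the report stage
.writeTsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a differential-expression statistics table
#'
#' Expects a header with columns
#' \code{gene_id, contrast_id, log2fc, fdr}.
#'
#' @param path path to the TSV.
#' @return data.frame with those columns.
#' @export
readDeTable <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "contrast_id", "log2fc", "fdr")
  if (!all(need %in% names(df)))
    stop("DE table missing columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  if (nrow(df) && (any(df$fdr < 0) || any(df$fdr > 1)))
    stop("DE table: FDR outside [0,1]")
  df[need]
}

#' Read a gene-to-term annotation map
#'
#' Expects a header with columns \code{gene_id, term_id, description}.
#'
#' @param path path to the TSV.
#' @return data.frame with those columns.
#' @export
readTermMap <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "term_id", "description")
  if (!all(need %in% names(df)))
    stop("term map missing columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  df[need]
}
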