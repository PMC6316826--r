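# Shared fixtures and independent oracles for the test suite.
# Simulated studies are cached per parameter set so multiple test files
# can reuse them without regenerating.

.simCache <- new.env(parent = emptyenv())

# sample() with a scalar x draws from 1:x; resample never does
resample <- function(x, n = 1) x[sample.int(length(x), n)]

cachedSim <- function(seed = 101, nGenes = 80, nFamily = 20, ...) {
  key <- paste(seed, nGenes, nFamily, ..., sep = "_")
  if (is.null(.simCache[[key]]))
    .simCache[[key]] <- simulateStudy(seed = seed, nGenes = nGenes,
                                      nFamily = nFamily, ...)
  .simCache[[key]]
}

# run the identification stage of a simulated study, returning the
# result table plus the planted truth
identifyFromSim <- function(sim, config = pipelineConfig()) {
  tm <- rbind(sim@tmA, sim@tmB)
  cand <- buildCandidateSet(sim@kdHits, sim@lrrHits, sim@simHits, config)
  tmc <- callTm(tm, universe = unique(c(cand$protein_id, tm$protein_id,
                                        sim@domains$protein_id)))
  arch <- architectureTable(sim@domains, tm)
  res <- identifyLrrRlks(cand, arch, tmc,
                         universe = unique(c(sim@kdHits$protein_id,
                                             sim@lrrHits$protein_id,
                                             sim@simHits$protein_id)))
  m <- manifest(sim)
  list(result = res, candidates = cand,
       truth = m$genes$gene_id[m$genes$is_family])
}

familyAssignments <- function(sim) {
  m <- manifest(sim)
  fam <- m$genes[m$genes$is_family, , drop = FALSE]
  data.frame(gene_id = fam$gene_id, subfamily = fam$subfamily,
             stringsAsFactors = FALSE)
}

# build a one-gene GeneModelSet from exon coordinates (CDS = exons)
makeGeneModel <- function(exonStarts, exonEnds, strand = "+",
                          chrom = "A1", geneId = "g1") {
  g <- GenomicRanges::GRanges(chrom,
                              IRanges::IRanges(min(exonStarts),
                                               max(exonEnds)),
                              strand = strand)
  g$gene_id <- geneId
  g$transcript_id <- paste0(geneId, ".t1")
  ex <- GenomicRanges::GRanges(chrom,
                               IRanges::IRanges(exonStarts, exonEnds),
                               strand = strand)
  cd <- ex
  cd$phase <- 0L
  GeneModelSet(g, GenomicRanges::GRangesList(list(ex)),
               GenomicRanges::GRangesList(list(cd)))
}

# random gene model with CDS length divisible by 3, for mapping oracles
randomGeneModel <- function(nExons = NULL, strand = NULL) {
  if (is.null(nExons)) nExons <- sample(1:6, 1)
  if (is.null(strand)) strand <- sample(c("+", "-"), 1)
  widths <- sample(9:120, nExons, replace = TRUE)
  excess <- sum(widths) %% 3L
  widths[nExons] <- widths[nExons] - excess
  gaps <- if (nExons > 1) sample(50:400, nExons - 1, replace = TRUE)
          else integer(0)
  starts <- cumsum(c(sample(1000:5000, 1), widths[-nExons] + gaps))
  ends <- starts + widths - 1L
  makeGeneModel(starts, ends, strand = strand)
}

# per-base brute-force oracle for protein-to-genome interval mapping
oracleMapProtein <- function(gms, geneId, p, q) {
  cd <- cdsList(gms[geneId])[[1]]
  minus <- as.character(GenomicRanges::strand(geneRanges(gms[geneId]))[1]) == "-"
  ord <- if (minus) order(-IRanges::start(cd)) else order(IRanges::start(cd))
  positions <- unlist(lapply(ord, function(i) {
    if (minus) seq(IRanges::end(cd)[i], IRanges::start(cd)[i])
    else seq(IRanges::start(cd)[i], IRanges::end(cd)[i])
  }))
  nt <- sort(positions[(3 * p - 2):(3 * q)])
  brk <- c(0, which(diff(nt) > 1), length(nt))
  IRanges::IRanges(nt[brk[-length(brk)] + 1], nt[brk[-1]])
}

# brute-force tandem detector: all-pairs graph + connected components
oracleTandem <- function(assignments, index, config = pipelineConfig()) {
  fam <- merge(assignments, index, by = "gene_id")
  n <- nrow(fam)
  if (n < 2) return(list())
  edges <- matrix(integer(0), ncol = 2)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (fam$chromosome[i] != fam$chromosome[j]) next
    if (fam$subfamily[i] != fam$subfamily[j]) next
    if (abs(fam$rank[i] - fam$rank[j]) - 1 > config@tandemMaxIntervening)
      next
    lo <- if (fam$start[i] <= fam$start[j]) i else j
    hi <- if (lo == i) j else i
    gap <- max(0, fam$start[hi] - fam$end[lo])
    if (gap <= config@tandemMaxDistance)
      edges <- rbind(edges, c(i, j))
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (nrow(edges))
    g <- igraph::add_edges(g, t(edges))
  comp <- igraph::components(g)$membership
  out <- split(fam$gene_id, comp)
  out <- out[vapply(out, length, integer(1)) >= 2]
  unname(lapply(out, sort))
}

# random chromosome index + subfamily assignment for tandem oracles
randomChromIndex <- function(nGenes = 200, nFamily = 40) {
  starts <- cumsum(sample(c(2000:60000), nGenes, replace = TRUE))
  ends <- starts + sample(1000:6000, nGenes, replace = TRUE)
  ids <- sprintf("t%03d", seq_len(nGenes))
  index <- data.frame(gene_id = ids, chromosome = "A1", start = starts,
                      end = ends, is_scaffold = FALSE,
                      rank = seq_len(nGenes) - 1L,
                      stringsAsFactors = FALSE)
  famIdx <- sort(sample(nGenes, nFamily))
  assignments <- data.frame(
    gene_id = ids[famIdx],
    subfamily = sample(c("XI-1", "XII", "VIII-2", "III", "IX"),
                       nFamily, replace = TRUE),
    stringsAsFactors = FALSE)
  list(index = index, assignments = assignments)
}

# tandem sets as a canonical partition (list of sorted member vectors)
setsAsPartition <- function(sets) {
  if (nrow(sets) == 0) return(list())
  out <- lapply(split(sets$gene_id, sets$set_id), sort)
  unname(out[order(vapply(out, `[`, character(1), 1))])
}

canonicalPartition <- function(lst) {
  unname(lst[order(vapply(lst, `[`, character(1), 1))])
}

# naive IUPAC sliding-window motif scanner (oracle for scanMotifs)
.IUPAC_SETS <- list(A = "A", C = "C", G = "G", T = "T",
                    R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                    W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                    B = c("C", "G", "T"), D = c("A", "G", "T"),
                    H = c("A", "C", "T"), V = c("A", "C", "G"),
                    N = c("A", "C", "G", "T"))

naiveScan <- function(seqStr, motif) {
  s <- strsplit(seqStr, "")[[1]]
  m <- strsplit(motif, "")[[1]]
  w <- length(m)
  hits <- integer(0)
  if (length(s) >= w)
    for (off in 0:(length(s) - w)) {
      ok <- TRUE
      for (k in seq_len(w))
        if (!(s[off + k] %in% .IUPAC_SETS[[m[k]]])) { ok <- FALSE; break }
      if (ok) hits <- c(hits, off)
    }
  hits
}

revcompStr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# exhaustive hypergeometric upper-tail oracle by subset enumeration
oracleHyper <- function(N, K, n, x) {
  subs <- utils::combn(N, n)
  inTerm <- seq_len(K)
  hits <- apply(subs, 2, function(s) sum(s %in% inTerm))
  mean(hits >= x)
}

# exhaustive two-sided Fisher oracle: sum of table probabilities as
# extreme or less probable than the observed table
oracleFisher <- function(a, b, c, d) {
  K <- a + b; N <- a + b + c + d; n <- a + c
  kk <- max(0, n - (N - K)):min(K, n)
  pr <- stats::dhyper(kk, K, N - K, n)
  pObs <- stats::dhyper(a, K, N - K, n)
  sum(pr[pr <= pObs * (1 + 1e-7)])
}
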