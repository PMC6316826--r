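#' @importFrom Biostrings AAStringSet
#' @importFrom stats runif setNames
NULL

#' SimulatedStudy: a synthetic gene-family study with ground truth
#'
#' Holds every input the pipeline consumes — genome, annotation,
#' proteins, the three evidence streams, two TM tables, confirmed domain
#' spans, a reference-anchored tree, promoter catalog, expression
#' matrices and DE statistics — together with the ground-truth manifest
#' that determines the expected output of every stage at zero noise.
#'
#' @slot genome \code{DNAStringSet} of chromosome/scaffold sequences.
#' @slot models the [GeneModelSet-class] annotation.
#' @slot proteins \code{AAStringSet} of representative proteins.
#' @slot kdHits,lrrHits,simHits evidence tables.
#' @slot tmA,tmB per-predictor transmembrane segment tables.
#' @slot domains confirmed domain-span table (protein coordinates).
#' @slot tree \code{phylo} with reference anchors among the tips.
#' @slot anchors anchor table (leaf_id, subfamily).
#' @slot catalog cis-element catalog used for motif planting.
#' @slot fiberFpkm,stressFpkm expression matrices (FPKM).
#' @slot deTable differential-expression statistics table.
#' @slot termMap synthetic gene-to-term annotation map with one term
#'   planted to be enriched in the family.
#' @slot manifest named list of planted truths.
#' @export
setClass("SimulatedStudy", representation(
  genome = "DNAStringSet", models = "GeneModelSet",
  proteins = "AAStringSet",
  kdHits = "data.frame", lrrHits = "data.frame", simHits = "data.frame",
  tmA = "data.frame", tmB = "data.frame", domains = "data.frame",
  tree = "ANY", anchors = "data.frame", catalog = "data.frame",
  fiberFpkm = "matrix", stressFpkm = "matrix", deTable = "data.frame",
  termMap = "data.frame", manifest = "list"
))

setMethod("show", "SimulatedStudy", function(object) {
  m <- object@manifest
  cat("SimulatedStudy (seed ", m$seed, ")\n", sep = "")
  cat("  ", nrow(m$genes), " genes (", sum(m$genes$is_family),
      " family) on ", length(object@genome), " sequences\n", sep = "")
  cat("  ", length(m$arrays), " planted tandem arrays, ",
      sum(m$genes$is_retro), " retrogenes, ",
      nrow(m$motifPlan), " planted motif occurrences\n", sep = "")
})

#' @rdname SimulatedStudy-class
#' @param x a SimulatedStudy
#' @export
models <- function(x) x@models

#' @rdname SimulatedStudy-class
#' @export
manifest <- function(x) x@manifest

# fixed codon per amino acid: synthetic back-translation
.CODON <- c(A = "GCT", R = "CGT", N = "AAT", D = "GAT", C = "TGT",
            Q = "CAA", E = "GAA", G = "GGT", H = "CAT", I = "ATT",
            L = "CTT", K = "AAA", M = "ATG", F = "TTT", P = "CCT",
            S = "TCT", T = "ACT", W = "TGG", Y = "TAT", V = "GTT")

.randProtein <- function(len) {
  paste0("M", paste(sample(names(.CODON), len - 1L, replace = TRUE),
                    collapse = ""))
}

.backTranslate <- function(prot) {
  paste(.CODON[strsplit(prot, "")[[1]]], collapse = "")
}

.randDna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# kinase-domain structure group of each subfamily (exon-intron convention)
.KD_GROUP <- c("VII-1" = "A", "VII-2" = "A", "XV" = "A",
               "III" = "B", "IV" = "B", "IX" = "B", "X" = "B",
               "XI-1" = "B", "XI-2" = "B", "XI-3" = "B", "XII" = "B",
               "I" = "C", "II" = "C", "V" = "C", "VI-1" = "C",
               "VI-2" = "C", "VIII-1" = "C", "VIII-2" = "C",
               "XIII-1" = "C", "XIII-2" = "C", "XIV" = "C")

# per-gene layout: protein architecture + exon cuts (codon boundaries)
.planGene <- function(isFamily, subfamily = NA, retro = FALSE) {
  if (!isFamily) {
    protLen <- sample(200:500, 1L)
    nCuts <- sample(0:4, 1L)
    cuts <- if (nCuts && protLen > 10L)
      sort(sample(seq_len(protLen - 1L), min(nCuts, protLen - 1L)))
    else integer(0)
    return(list(protLen = protLen, cuts = cuts, arch = NULL))
  }
  ecdLen <- sample(250:420, 1L)
  tmLen <- 23L
  linker <- 15L
  kdLen <- 260L
  kdStart <- ecdLen + tmLen + linker + 1L
  kdEnd <- kdStart + kdLen - 1L
  protLen <- kdEnd + 15L
  nLrr <- sample(2:4, 1L)
  lrrStarts <- sort(sample(seq(30L, ecdLen - 40L, by = 30L), nLrr))
  arch <- list(
    lrr = IRanges(lrrStarts, lrrStarts + 23L),
    tm = IRanges(ecdLen + 1L, ecdLen + tmLen),
    kd = IRanges(kdStart, kdEnd))
  if (retro)
    return(list(protLen = protLen, cuts = integer(0), arch = arch))
  grp <- .KD_GROUP[[subfamily]]
  kdExons <- switch(grp, A = 1L, B = 2L, C = sample(3:5, 1L))
  kdCuts <- if (kdExons > 1L)
    sort(sample(seq(kdStart + 10L, kdEnd - 10L), kdExons - 1L))
  else integer(0)
  ecdIntrons <- if (grp == "C") sample(3:4, 1L) else sample(2:3, 1L)
  ecdCuts <- sort(sample(seq(20L, ecdLen - 20L, by = 7L), ecdIntrons))
  list(protLen = protLen, cuts = sort(c(ecdCuts, kdCuts)), arch = arch)
}

# build the ordered gene plan of one sequence
# each element: list(type, subfamily, retro, bigGapBefore)
.bgGene <- function() list(type = "bg", subfamily = NA, retro = FALSE,
                           bigGapBefore = FALSE)
.famGene <- function(sf, retro = FALSE, bigGap = FALSE)
  list(type = "fam", subfamily = sf, retro = retro, bigGapBefore = bigGap)

#' Simulate a complete gene-family study
#'
#' Generates a deterministic synthetic study: an annotated genome with
#' planted family genes (LRR-TM-KD architectures honouring the
#' subfamily exon-intron conventions), decoys for every rejection
#' route, tandem arrays inside the detection window plus negative pairs
#' just outside it, intronless retrogene copies, the three evidence
#' streams, two TM predictor tables, a reference-anchored phylogeny,
#' motif-planted promoters, and expression matrices with planted
#' clusters and DE genes. The manifest records every planted truth.
#'
#' @param seed RNG seed; identical seeds give byte-identical outputs.
#' @param nGenes total annotated genes (family plus background).
#' @param nFamily number of planted family genes.
#' @param nRetro number of intronless retrogene copies (among
#'   \code{nFamily}).
#' @param fnRate per-family-gene probability that its kinase-domain
#'   evidence is missed in both the HMM and similarity streams.
#' @param fpRate per-background-gene probability of spurious passing
#'   evidence rows (filtered downstream by TM/architecture).
#' @param tmDisagreeRate per-family-gene probability that predictor A
#'   misses the TM segment (predictor B still reports it, exercising
#'   the either-predictor consensus).
#' @param treeMisplacement fraction of family tips placed into a wrong
#'   subfamily clade.
#' @param config a [PipelineConfig-class].
#' @param catalog cis-element catalog (see [readCisCatalog]).
#' @return a [SimulatedStudy-class].
#' @examples
#' sim <- simulateStudy(seed = 1, nGenes = 40, nFamily = 12)
#' sim
#' @export
simulateStudy <- function(seed = 17L, nGenes = 300L, nFamily = 60L,
                          nRetro = 2L, fnRate = 0, fpRate = 0,
                          tmDisagreeRate = 0, treeMisplacement = 0,
                          config = pipelineConfig(),
                          catalog = readCisCatalog()) {
  stopifnot(nFamily <= nGenes, nFamily >= 6L)
  .withSeed(seed, .simulateStudyImpl(seed, nGenes, nFamily, nRetro,
                                     fnRate, fpRate, tmDisagreeRate,
                                     treeMisplacement, config, catalog))
}

.simulateStudyImpl <- function(seed, nGenes, nFamily, nRetro, fnRate,
                               fpRate, tmDisagreeRate, treeMisplacement,
                               config, catalog) {
  subfams <- c("III", "VII-1", "VIII-2", "IX", "XI-1", "XII", "XIV", "XV")
  big <- nFamily >= 40L

  # --- planted structures -------------------------------------------------
  if (big) {
    arrays <- list(list(sf = "XI-1", chrom = "A1", size = 3L),
                   list(sf = "VIII-2", chrom = "A1", size = 2L),
                   list(sf = "XII", chrom = "A2", size = 4L),
                   list(sf = "III", chrom = "A2", size = 2L))
    farPair <- list(sf = "IX", chrom = "A1")        # >10 intervening genes
    distPair <- list(sf = "XIV", chrom = "A2")      # >200 kb gap
  } else {
    arrays <- list(list(sf = "XI-1", chrom = "A1", size = 2L),
                   list(sf = "XII", chrom = "A2", size = 2L))
    farPair <- NULL
    distPair <- NULL
  }
  nPlanted <- sum(vapply(arrays, `[[`, integer(1), "size")) +
    (if (is.null(farPair)) 0L else 2L) +
    (if (is.null(distPair)) 0L else 2L)
  nSingle <- nFamily - nPlanted
  stopifnot(nSingle >= 2L)

  # subfamilies with a planted structure on a chromosome must not get
  # singletons on that same chromosome (keeps the manifest the exact truth)
  blockOn <- list(A1 = character(0), A2 = character(0),
                  scaffold_1 = character(0))
  for (a in arrays) blockOn[[a$chrom]] <- c(blockOn[[a$chrom]], a$sf)
  if (!is.null(farPair))
    blockOn[[farPair$chrom]] <- c(blockOn[[farPair$chrom]], farPair$sf)
  if (!is.null(distPair))
    blockOn[[distPair$chrom]] <- c(blockOn[[distPair$chrom]], distPair$sf)

  # singleton subfamilies cycle; retro copies drawn from the singletons
  singleSf <- rep(subfams, length.out = nSingle)
  retroIdx <- if (nRetro > 0L) seq_len(min(nRetro, nSingle)) else integer(0)

  # --- per-sequence gene plans -------------------------------------------
  chroms <- c("A1", "A2", "scaffold_1")
  nScaffold <- max(2L, round(0.06 * nGenes))
  plans <- list(A1 = list(), A2 = list(), scaffold_1 = list())
  # last plan position of each subfamily per sequence, to keep unplanned
  # same-subfamily neighbours outside the tandem window
  lastPos <- list(A1 = list(), A2 = list(), scaffold_1 = list())
  pad <- function(chrom, k) {
    for (z in seq_len(k))
      plans[[chrom]][[length(plans[[chrom]]) + 1L]] <<- .bgGene()
  }
  addFam <- function(chrom, sf, retro = FALSE, bigGap = FALSE) {
    plans[[chrom]][[length(plans[[chrom]]) + 1L]] <<-
      .famGene(sf, retro, bigGap)
    lastPos[[chrom]][[sf]] <<- length(plans[[chrom]])
  }
  sep <- config@tandemMaxIntervening + 1L

  pad("A1", 2L); pad("A2", 2L); pad("scaffold_1", 1L)
  for (a in arrays) {
    pad(a$chrom, 1L)
    for (z in seq_len(a$size)) addFam(a$chrom, a$sf)
    pad(a$chrom, 1L)
  }
  if (!is.null(farPair)) {
    pad(farPair$chrom, 1L)
    addFam(farPair$chrom, farPair$sf)
    pad(farPair$chrom, sep + 1L)   # 12 intervening genes
    addFam(farPair$chrom, farPair$sf)
    pad(farPair$chrom, 1L)
  }
  if (!is.null(distPair)) {
    pad(distPair$chrom, 1L)
    addFam(distPair$chrom, distPair$sf)
    addFam(distPair$chrom, distPair$sf, bigGap = TRUE)  # adjacent, >200 kb
    pad(distPair$chrom, 1L)
  }
  # singletons round-robin over the three sequences, 2 background genes
  # after each so same-subfamily singletons never fall inside the window
  seqCycle <- c("A1", "A2", "scaffold_1")
  ci <- 0L
  for (i in seq_len(nSingle)) {
    sf <- singleSf[i]
    repeat {
      ci <- ci + 1L
      chrom <- seqCycle[((ci - 1L) %% 3L) + 1L]
      if (!(sf %in% blockOn[[chrom]])) break
    }
    # keep same-subfamily genes on one sequence outside the window
    prev <- lastPos[[chrom]][[sf]]
    if (!is.null(prev)) {
      intervening <- length(plans[[chrom]]) - prev
      if (intervening <= config@tandemMaxIntervening)
        pad(chrom, config@tandemMaxIntervening + 1L - intervening)
    }
    addFam(chrom, sf, retro = i %in% retroIdx)
    pad(chrom, 2L)
  }
  # distribute the remaining background genes
  used <- sum(vapply(plans, length, integer(1)))
  remaining <- nGenes - used
  if (remaining < 0L)
    stop("nGenes too small for the planted structures (need >= ",
         used, ")")
  scafDeficit <- max(0L, nScaffold - length(plans$scaffold_1))
  pad("scaffold_1", min(remaining, scafDeficit))
  remaining <- remaining - min(remaining, scafDeficit)
  pad("A1", remaining %/% 2L)
  pad("A2", remaining - remaining %/% 2L)

  # --- materialise gene models and sequences -----------------------------
  promLen <- config@promoterLength
  nTot <- sum(vapply(plans, length, integer(1)))
  gChr <- character(nTot); gStartV <- integer(nTot); gEndV <- integer(nTot)
  gStrand <- character(nTot); gIdV <- character(nTot)
  exChr <- list(); exS <- list(); exE <- list(); exStr <- list()
  exGene <- list()
  protSeqs <- character(0); protIds <- character(0)
  chromSeqs <- list()
  archList <- list()
  manifestGenes <- vector("list", nTot)
  gi <- 0L
  for (chrom in chroms) {
    plan <- plans[[chrom]]
    cursor <- promLen + sample(2000:4000, 1L)
    lastEnd <- 0L
    for (g in plan) {
      gi <- gi + 1L
      gid <- sprintf("Gs%03d", gi)
      layout <- .planGene(g$type == "fam", g$subfamily, g$retro)
      prot <- .randProtein(layout$protLen)
      cdsLenNt <- 3L * layout$protLen
      cutsNt <- layout$cuts * 3L
      segLens <- diff(c(0L, cutsNt, cdsLenNt))
      intronLens <- if (length(segLens) > 1L)
        sample(120:400, length(segLens) - 1L, replace = TRUE) else integer(0)
      strandCh <- sample(c("+", "-"), 1L)
      if (g$bigGapBefore)
        cursor <- cursor + config@tandemMaxDistance + 50000L
      gStart <- cursor
      # genomic exon layout (exons coincide with CDS segments here); on
      # the minus strand the first coding segment occupies the highest
      # coordinates, so the genomic order of segment lengths is reversed
      glens <- if (strandCh == "-") rev(segLens) else segLens
      exStarts <- integer(0); exEnds <- integer(0)
      pos <- gStart
      for (k in seq_along(glens)) {
        exStarts <- c(exStarts, pos)
        exEnds <- c(exEnds, pos + glens[k] - 1L)
        pos <- pos + glens[k] +
          (if (k < length(glens)) intronLens[k] else 0L)
      }
      gEnd <- exEnds[length(exEnds)]
      lastEnd <- gEnd
      cursor <- gEnd + promLen + sample(2200:7000, 1L)

      gChr[gi] <- chrom; gStartV[gi] <- gStart; gEndV[gi] <- gEnd
      gStrand[gi] <- strandCh; gIdV[gi] <- gid
      exChr[[gi]] <- rep(chrom, length(exStarts))
      exS[[gi]] <- exStarts; exE[[gi]] <- exEnds
      exStr[[gi]] <- rep(strandCh, length(exStarts))
      exGene[[gi]] <- rep(gid, length(exStarts))
      protIds <- c(protIds, gid)
      protSeqs <- c(protSeqs, prot)
      if (!is.null(layout$arch)) archList[[gid]] <- layout$arch
      manifestGenes[[gi]] <- data.frame(
        gene_id = gid, chromosome = chrom, start = gStart, end = gEnd,
        strand = strandCh, is_family = g$type == "fam",
        subfamily = ifelse(g$type == "fam", g$subfamily, NA_character_),
        is_retro = g$retro, n_exons = length(segLens),
        protein_length = layout$protLen, stringsAsFactors = FALSE)
    }
    chromSeqs[[chrom]] <- .randDna(lastEnd + promLen + 2000L)
  }
  genome <- DNAStringSet(unlist(chromSeqs))
  names(genome) <- chroms
  genesGr <- GRanges(gChr, IRanges(gStartV, gEndV), strand = gStrand)
  genesGr$gene_id <- gIdV
  genesGr$transcript_id <- paste0(gIdV, ".t1")
  exAll <- GRanges(unlist(exChr), IRanges(unlist(exS), unlist(exE)),
                   strand = unlist(exStr))
  geneFac <- factor(unlist(exGene), levels = gIdV)
  exGrl <- split(exAll, geneFac)
  cdAll <- exAll
  cdAll$phase <- 0L
  cdGrl <- split(cdAll, geneFac)
  gms <- GeneModelSet(genesGr, exGrl, cdGrl,
                      chromPattern = config@chromPattern)
  proteins <- AAStringSet(setNames(protSeqs, protIds))
  mg <- do.call(rbind, manifestGenes)

  # --- decoys -------------------------------------------------------------
  bgIds <- mg$gene_id[!mg$is_family]
  decoyClasses <- c("weak_evalue", "kd_only", "lrr_only", "no_tm",
                    "bad_order")
  decoys <- data.frame(protein_id = sample(bgIds, length(decoyClasses)),
                       class = decoyClasses, stringsAsFactors = FALSE)

  # --- evidence streams ---------------------------------------------------
  ev <- .simulateEvidence(mg, archList, decoys, fnRate, fpRate,
                          tmDisagreeRate, config)

  # --- tree and anchors ---------------------------------------------------
  tr <- .simulateTree(mg, subfams, treeMisplacement)

  # --- promoters: motif planting ------------------------------------------
  pm <- .plantPromoters(genome, gms, mg, catalog, config)
  genome <- pm$genome

  # --- expression ----------------------------------------------------------
  expr <- .simulateExpression(mg, config)

  # --- functional annotation ----------------------------------------------
  trm <- .simulateTerms(mg)

  man <- list(seed = seed, genes = mg, decoys = decoys,
              arrays = lapply(seq_along(arrays), function(i) {
                a <- arrays[[i]]
                members <- mg$gene_id[mg$is_family &
                                        mg$subfamily == a$sf &
                                        mg$chromosome == a$chrom]
                list(sf = a$sf, chrom = a$chrom, members = members)
              }),
              negatives = list(farPair = farPair, distPair = distPair),
              retro = mg$gene_id[mg$is_retro],
              misplaced = tr$misplaced,
              motifPlan = pm$plan,
              enriched = pm$enriched,
              fiberCluster = expr$fiberCluster,
              stressCluster = expr$stressCluster,
              deTrue = expr$deTrue,
              deOneContrast = expr$deOneContrast,
              enrichedTerm = trm$enriched,
              rates = c(fn = fnRate, fp = fpRate,
                        tm_disagree = tmDisagreeRate,
                        misplacement = treeMisplacement))

  new("SimulatedStudy", genome = genome, models = gms,
      proteins = proteins,
      kdHits = ev$kd, lrrHits = ev$lrr, simHits = ev$sim,
      tmA = ev$tmA, tmB = ev$tmB, domains = ev$domains,
      tree = tr$tree, anchors = tr$anchors, catalog = catalog,
      fiberFpkm = expr$fiber, stressFpkm = expr$stress,
      deTable = expr$de, termMap = trm$map, manifest = man)
}

.simulateEvidence <- function(mg, archList, decoys, fnRate, fpRate,
                              tmDisagreeRate, config) {
  kd <- list(); lrr <- list(); sim <- list()
  tmA <- list(); tmB <- list(); dom <- list()
  lrrFams <- c("PF13855", "PF00560", "PF08263", "PF13516")
  addHit <- function(store, pid, fam, evd, eval, s, e, ident = NA_real_) {
    store[[length(store) + 1L]] <- data.frame(
      protein_id = pid, family_id = fam, evidence = evd,
      e_value = as.numeric(eval), ali_start = as.integer(s),
      ali_end = as.integer(e), identity_pct = ident,
      stringsAsFactors = FALSE)
    store
  }
  famIds <- mg$gene_id[mg$is_family]
  dropKd <- famIds[runif(length(famIds)) < fnRate]
  tmMissA <- famIds[runif(length(famIds)) < tmDisagreeRate]
  for (pid in famIds) {
    a <- archList[[pid]]
    eKd <- 10^-runif(1, 20, 60)
    if (!(pid %in% dropKd)) {
      kd <- addHit(kd, pid, "PF00069", "hmm", eKd,
                   start(a$kd), end(a$kd))
      sim <- addHit(sim, pid, "AT_LRRRLK_ref", "similarity",
                    10^-runif(1, 30, 80),
                    1, mg$protein_length[mg$gene_id == pid],
                    round(runif(1, 55, 90), 1))
    }
    for (j in seq_along(a$lrr))
      lrr <- addHit(lrr, pid, sample(lrrFams, 1L),
                    "hmm", 10^-runif(1, 12, 30),
                    start(a$lrr)[j], end(a$lrr)[j])
    if (!(pid %in% tmMissA))
      tmA[[length(tmA) + 1L]] <- data.frame(
        protein_id = pid, predictor = "predictor_a",
        start = start(a$tm), end = end(a$tm), stringsAsFactors = FALSE)
    tmB[[length(tmB) + 1L]] <- data.frame(
      protein_id = pid, predictor = "predictor_b",
      start = start(a$tm), end = end(a$tm), stringsAsFactors = FALSE)
    for (cls in c("lrr", "tm", "kd")) {
      r <- a[[cls]]
      for (j in seq_along(r))
        dom[[length(dom) + 1L]] <- data.frame(
          protein_id = pid, class = cls, start = start(r)[j],
          end = end(r)[j], stringsAsFactors = FALSE)
    }
  }
  # decoys exercise each rejection route
  for (i in seq_len(nrow(decoys))) {
    pid <- decoys$protein_id[i]
    plen <- mg$protein_length[mg$gene_id == pid]
    cls <- decoys$class[i]
    if (cls == "weak_evalue") {
      kd <- addHit(kd, pid, "PF00069", "hmm", 1e-8, 50, 250)
      lrr <- addHit(lrr, pid, "PF13855", "hmm", 1e-8, 10, 40)
      sim <- addHit(sim, pid, "AT_LRRRLK_ref", "similarity", 1e-20,
                    1, plen, 45.0)
    } else if (cls == "kd_only") {
      kd <- addHit(kd, pid, "PF00069", "hmm", 1e-30, 50, 250)
    } else if (cls == "lrr_only") {
      lrr <- addHit(lrr, pid, "PF13855", "hmm", 1e-20, 10, 40)
    } else if (cls == "no_tm") {
      kd <- addHit(kd, pid, "PF00069", "hmm", 1e-30,
                   plen - 150L, plen - 20L)
      lrr <- addHit(lrr, pid, "PF13855", "hmm", 1e-20, 10, 40)
      dom[[length(dom) + 1L]] <- data.frame(
        protein_id = pid, class = "lrr", start = 10L, end = 40L,
        stringsAsFactors = FALSE)
      dom[[length(dom) + 1L]] <- data.frame(
        protein_id = pid, class = "kd", start = plen - 150L,
        end = plen - 20L, stringsAsFactors = FALSE)
    } else if (cls == "bad_order") {
      # KD-TM-LRR: reversed architecture
      kd <- addHit(kd, pid, "PF00069", "hmm", 1e-30, 10, 150)
      lrr <- addHit(lrr, pid, "PF13855", "hmm", 1e-20,
                    plen - 60L, plen - 30L)
      dom[[length(dom) + 1L]] <- data.frame(
        protein_id = pid, class = "kd", start = 10L, end = 150L,
        stringsAsFactors = FALSE)
      dom[[length(dom) + 1L]] <- data.frame(
        protein_id = pid, class = "lrr", start = plen - 60L,
        end = plen - 30L, stringsAsFactors = FALSE)
      tmA[[length(tmA) + 1L]] <- data.frame(
        protein_id = pid, predictor = "predictor_a",
        start = 170L, end = 192L, stringsAsFactors = FALSE)
      dom[[length(dom) + 1L]] <- data.frame(
        protein_id = pid, class = "tm", start = 170L, end = 192L,
        stringsAsFactors = FALSE)
    }
  }
  bind <- function(x, empty = .emptyHits()) {
    if (length(x)) do.call(rbind, x) else empty
  }
  emptyTm <- data.frame(protein_id = character(0), predictor = character(0),
                        start = integer(0), end = integer(0),
                        stringsAsFactors = FALSE)
  emptyDom <- data.frame(protein_id = character(0), class = character(0),
                         start = integer(0), end = integer(0),
                         stringsAsFactors = FALSE)
  list(kd = bind(kd), lrr = bind(lrr), sim = bind(sim),
       tmA = bind(tmA, emptyTm), tmB = bind(tmB, emptyTm),
       domains = bind(dom, emptyDom))
}

# synthetic GO/KEGG-style annotation: one kinase-signalling term covers
# the family (planted enrichment), noise terms cover random gene subsets
.simulateTerms <- function(mg) {
  famIds <- mg$gene_id[mg$is_family]
  allIds <- mg$gene_id
  rows <- list(data.frame(
    gene_id = c(famIds, sample(setdiff(allIds, famIds),
                               max(2L, round(0.05 * length(allIds))))),
    term_id = "T:0001", description = "protein kinase signalling",
    stringsAsFactors = FALSE))
  for (k in 2:6)
    rows[[k]] <- data.frame(
      gene_id = sample(allIds, round(0.25 * length(allIds))),
      term_id = sprintf("T:%04d", k),
      description = paste("background process", k),
      stringsAsFactors = FALSE)
  list(map = do.call(rbind, rows), enriched = "T:0001")
}

.newickLabel <- function(x) gsub("[ ():;,]", "_", x)

# caterpillar newick over a label vector with random branch lengths
.caterpillar <- function(labels, blRange = c(0.02, 0.2)) {
  bl <- function() sprintf("%.4f", runif(1, blRange[1], blRange[2]))
  if (length(labels) == 1L)
    return(paste0(.newickLabel(labels), ":", bl()))
  s <- paste0("(", .newickLabel(labels[1]), ":", bl(), ",",
              .newickLabel(labels[2]), ":", bl(), ")")
  for (lb in labels[-(1:2)])
    s <- paste0("(", s, ":", bl(), ",", .newickLabel(lb), ":", bl(), ")")
  paste0(s, ":", bl())
}

.simulateTree <- function(mg, subfams, misplacement) {
  famIds <- mg$gene_id[mg$is_family]
  trueSf <- mg$subfamily[mg$is_family]
  placedSf <- trueSf
  mis <- runif(length(famIds)) < misplacement
  for (i in which(mis))
    placedSf[i] <- sample(setdiff(subfams, trueSf[i]), 1L)
  anchors <- do.call(rbind, lapply(subfams, function(sf) {
    data.frame(leaf_id = paste0("AT_", sf, "_", 1:2), subfamily = sf,
               stringsAsFactors = FALSE)
  }))
  cladeStrs <- vapply(subfams, function(sf) {
    members <- c(anchors$leaf_id[anchors$subfamily == sf],
                 famIds[placedSf == sf])
    .caterpillar(sample(members))
  }, character(1))
  # backbone over clades
  s <- paste0("(", cladeStrs[1], ",", cladeStrs[2], ")")
  for (k in seq_along(cladeStrs)[-(1:2)])
    s <- paste0("(", s, ":1.0,", cladeStrs[k], ")")
  tree <- ape::read.tree(text = paste0(s, ";"))
  misplaced <- data.frame(gene_id = famIds[mis],
                          true_subfamily = trueSf[mis],
                          placed_subfamily = placedSf[mis],
                          stringsAsFactors = FALSE)
  list(tree = tree, anchors = anchors, misplaced = misplaced,
       placed = setNames(placedSf, famIds))
}

# instantiate IUPAC degeneracies with concrete bases
.IUPAC_EXPAND <- list(A = "A", C = "C", G = "G", T = "T",
                      R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                      W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                      B = c("C", "G", "T"), D = c("A", "G", "T"),
                      H = c("A", "C", "T"), V = c("A", "C", "G"),
                      N = c("A", "C", "G", "T"))

.instantiateMotif <- function(motif) {
  paste(vapply(strsplit(motif, "")[[1]], function(ch) {
    sample(.IUPAC_EXPAND[[ch]], 1L)
  }, character(1)), collapse = "")
}

# IUPAC motif -> zero-width regex counting overlapping occurrences
.IUPAC_RE <- c(A = "A", C = "C", G = "G", T = "T", R = "[AG]",
               Y = "[CT]", S = "[CG]", W = "[AT]", K = "[GT]",
               M = "[AC]", B = "[CGT]", D = "[AGT]", H = "[ACT]",
               V = "[ACG]", N = "[ACGT]")

.motifRegex <- function(motif) {
  paste0("(?=", paste(.IUPAC_RE[strsplit(motif, "")[[1]]],
                      collapse = ""), ")")
}

# total occurrences of any catalog motif on either strand of seqStr
.makeCatalogCounter <- function(catalog) {
  rc <- vapply(catalog$motif, function(m)
    as.character(reverseComplement(DNAString(m))), character(1))
  res <- vapply(c(catalog$motif, rc), .motifRegex, character(1))
  function(seqStr) {
    total <- 0L
    for (re in res) {
      g <- gregexpr(re, seqStr, perl = TRUE)[[1]]
      if (g[1] != -1L) total <- total + length(g)
    }
    total
  }
}

.plantPromoters <- function(genome, gms, mg, catalog, config) {
  promLen <- config@promoterLength
  famIds <- mg$gene_id[mg$is_family]
  enrichedSf <- "XI-1"
  enrichedCat <- grep("pathogen|wound", unique(catalog$category),
                      value = TRUE)[1]
  if (is.na(enrichedCat)) enrichedCat <- unique(catalog$category)[1]
  otherCats <- setdiff(unique(catalog$category), enrichedCat)
  plan <- list()
  countMatches <- .makeCatalogCounter(catalog)
  gstr <- as.character(genome)
  names(gstr) <- names(genome)
  g <- geneRanges(gms)
  for (pid in famIds) {
    i <- match(pid, g$gene_id)
    cd <- cdsList(gms)[[i]]
    chr <- as.character(seqnames(g)[i])
    minus <- as.character(strand(g)[i]) == "-"
    if (minus) {
      scodon <- max(end(cd)); from <- scodon + 1L; to <- scodon + promLen
    } else {
      scodon <- min(start(cd)); from <- scodon - promLen; to <- scodon - 1L
    }
    sf <- mg$subfamily[mg$gene_id == pid]
    # choose the elements planted in this promoter
    chosen <- character(0)
    if (sf == enrichedSf) {
      cands <- catalog$element_id[catalog$category == enrichedCat]
      chosen <- c(chosen, cands[1])
    } else if (runif(1) < 0.15) {
      cands <- catalog$element_id[catalog$category == enrichedCat]
      chosen <- c(chosen, cands[1])
    }
    nOther <- sample(0:2, 1L)
    if (nOther > 0L && length(otherCats)) {
      cats <- sample(otherCats, min(nOther, length(otherCats)))
      for (cc in cats)
        chosen <- c(chosen, sample(catalog$element_id[
          catalog$category == cc], 1L))
    }
    # motif-free background window, then plant at spaced offsets
    maxW <- max(nchar(catalog$motif))
    for (try in seq_len(300L)) {
      bgSeq <- .randDna(promLen)
      if (countMatches(bgSeq) > 0L) next
      pSeq <- strsplit(bgSeq, "")[[1]]
      if (length(chosen)) {
        slots <- seq(1L, promLen - maxW, by = 2L * maxW + 6L)
        offs <- sort(sample(slots, length(chosen)))
        strands <- sample(c("+", "-"), length(chosen), replace = TRUE)
        for (k in seq_along(chosen)) {
          mot <- catalog$motif[catalog$element_id == chosen[k]]
          inst <- .instantiateMotif(mot)
          if (strands[k] == "-")
            inst <- as.character(reverseComplement(DNAString(inst)))
          pSeq[offs[k]:(offs[k] + nchar(inst) - 1L)] <-
            strsplit(inst, "")[[1]]
        }
      }
      pStr <- paste(pSeq, collapse = "")
      # verify: exactly the planted occurrences, nothing else
      if (countMatches(pStr) != length(chosen)) next
      # write the promoter content into the genome (promoter coordinates
      # read 5'->3' on the coding strand)
      gSeq <- if (minus)
        as.character(reverseComplement(DNAString(pStr))) else pStr
      substr(gstr[chr], from, to) <- gSeq
      if (length(chosen))
        plan[[length(plan) + 1L]] <- data.frame(
          gene_id = pid, element_id = chosen,
          offset = offs - 1L, strand = strands,
          stringsAsFactors = FALSE)
      break
    }
  }
  newGenome <- DNAStringSet(gstr)
  names(newGenome) <- names(genome)
  planDf <- if (length(plan)) do.call(rbind, plan) else
    data.frame(gene_id = character(0), element_id = character(0),
               offset = integer(0), strand = character(0),
               stringsAsFactors = FALSE)
  list(genome = newGenome, plan = planDf,
       enriched = list(subfamily = enrichedSf, category = enrichedCat))
}

.simulateExpression <- function(mg, config) {
  famIds <- mg$gene_id[mg$is_family]
  n <- length(famIds)
  # fiber development: two well-separated k-means clusters
  fiberSamples <- c("dpa5", "dpa10", "dpa20", "dpa25")
  nHigh <- max(3L, round(0.15 * n))
  highIdx <- sample(n, nHigh)
  fiber <- matrix(runif(n * 4L, 0, 2), n, 4L,
                  dimnames = list(famIds, fiberSamples))
  fiber[highIdx, ] <- matrix(rep(c(400, 600, 150, 80), each = nHigh),
                             nHigh) * runif(nHigh * 4L, 0.8, 1.25)
  fiberCluster <- setNames(rep(2L, n), famIds)
  fiberCluster[highIdx] <- 1L   # group 1 = highest mean expression
  # abiotic stress: four separated hierarchical groups
  stressSamples <- paste0(rep(c("cold", "heat", "peg", "salt"), each = 4L),
                          "_", rep(c(1, 3, 6, 12), times = 4L), "h")
  lev <- c(0.5, 8, 80, 800)
  stressCluster <- setNames(rep(seq_len(4L), length.out = n)[sample(n)],
                            famIds)
  stress <- matrix(0, n, 16L, dimnames = list(famIds, stressSamples))
  for (i in seq_len(n))
    stress[i, ] <- lev[stressCluster[i]] * runif(16L, 0.85, 1.18)
  # renumber planted groups by descending mean so labels align with the
  # clustering convention (group 1 = highest expression)
  stressCluster <- 5L - stressCluster
  stressCluster <- setNames(as.integer(stressCluster), famIds)
  # differential expression under two pathogen strains
  nDe <- max(4L, round(0.12 * n))
  deTrue <- sort(sample(famIds, nDe))
  rest <- setdiff(famIds, deTrue)
  deOne <- sort(sample(rest, min(3L, length(rest))))
  rows <- list()
  for (ct in c("V991", "D07038")) {
    lfc <- runif(n, -0.8, 0.8)
    fdr <- runif(n, 0.1, 0.9)
    names(lfc) <- names(fdr) <- famIds
    sign <- sample(c(-1, 1), nDe, replace = TRUE)
    lfc[deTrue] <- sign * runif(nDe, 1.4, 4)
    fdr[deTrue] <- runif(nDe, 1e-6, 0.01)
    if (ct == "V991" && length(deOne)) {
      lfc[deOne] <- runif(length(deOne), 1.5, 3)
      fdr[deOne] <- runif(length(deOne), 1e-4, 0.01)
    }
    rows[[ct]] <- data.frame(gene_id = famIds, contrast_id = ct,
                             log2fc = unname(lfc), fdr = unname(fdr),
                             stringsAsFactors = FALSE)
  }
  list(fiber = fiber, stress = stress,
       fiberCluster = fiberCluster, stressCluster = stressCluster,
       deTrue = deTrue, deOneContrast = deOne,
       de = do.call(rbind, rows))
}

#' Write a simulated study to a directory of standard-format files
#'
#' Emits the genome FASTA, protein FASTA, GFF3 annotation, evidence
#' tables (HMM TSVs, 12-column similarity table, two TM tables,
#' confirmed domain spans), Newick tree with anchor table, cis-element
#' catalog, expression matrices, DE statistics, and the manifest as TSV
#' sections. Identical studies produce byte-identical directories.
#'
#' @param sim a [SimulatedStudy-class].
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeSimulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  writeXStringSet(sim@genome, p("genome.fa"))
  writeXStringSet(sim@proteins, p("proteins.fa"))
  writeGff3(sim@models, p("annotation.gff3"))
  .writeTsv(sim@kdHits[c("protein_id", "family_id", "e_value",
                         "ali_start", "ali_end")], p("kd_hits.tsv"))
  .writeTsv(sim@lrrHits[c("protein_id", "family_id", "e_value",
                          "ali_start", "ali_end")], p("lrr_hits.tsv"))
  # similarity hits in the 12-column tabular dialect, no header
  s <- sim@simHits
  simLines <- sprintf("%s\t%s\t%.1f\t%d\t0\t0\t%d\t%d\t1\t%d\t%g\t100",
                      s$protein_id, s$family_id, s$identity_pct,
                      s$ali_end - s$ali_start + 1L, s$ali_start, s$ali_end,
                      s$ali_end - s$ali_start + 1L, s$e_value)
  writeLines(simLines, p("sim_hits.tsv"))
  .writeTsv(sim@tmA[c("protein_id", "start", "end")], p("tm_a.tsv"))
  .writeTsv(sim@tmB[c("protein_id", "start", "end")], p("tm_b.tsv"))
  .writeTsv(sim@domains, p("domains.tsv"))
  ape::write.tree(sim@tree, p("tree.nwk"))
  .writeTsv(sim@anchors, p("anchors.tsv"))
  .writeTsv(sim@catalog, p("catalog.tsv"))
  writeMatrixTsv(sim@fiberFpkm, p("fiber_fpkm.tsv"))
  writeMatrixTsv(sim@stressFpkm, p("stress_fpkm.tsv"))
  .writeTsv(sim@deTable, p("de_stats.tsv"))
  .writeTsv(sim@termMap, p("term_map.tsv"))
  m <- sim@manifest
  .writeTsv(m$genes, p("manifest_genes.tsv"))
  .writeTsv(m$decoys, p("manifest_decoys.tsv"))
  .writeTsv(m$motifPlan, p("manifest_motifs.tsv"))
  arrTab <- do.call(rbind, lapply(seq_along(m$arrays), function(i) {
    a <- m$arrays[[i]]
    data.frame(array_id = sprintf("ARR%02d", i), subfamily = a$sf,
               chromosome = a$chrom,
               members = paste(a$members, collapse = ","),
               stringsAsFactors = FALSE)
  }))
  if (is.null(arrTab))
    arrTab <- data.frame(array_id = character(0), subfamily = character(0),
                         chromosome = character(0), members = character(0))
  .writeTsv(arrTab, p("manifest_arrays.tsv"))
  .writeTsv(data.frame(gene_id = m$retro, stringsAsFactors = FALSE),
            p("manifest_retro.tsv"))
  .writeTsv(data.frame(gene_id = names(m$fiberCluster),
                       fiber_cluster = unname(m$fiberCluster),
                       stress_cluster = unname(
                         m$stressCluster[names(m$fiberCluster)]),
                       stringsAsFactors = FALSE),
            p("manifest_expression.tsv"))
  .writeTsv(data.frame(gene_id = m$deTrue, stringsAsFactors = FALSE),
            p("manifest_de.tsv"))
  invisible(dir)
}
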