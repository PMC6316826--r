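#' Run the full gene-family analysis pipeline on a study directory
#'
#' Orchestrates the stages in dependency order over a directory of
#' standard-format inputs (the layout written by [writeSimulation]):
#' identification from the three evidence streams, subfamily
#' classification from the anchored tree, exon-intron structure
#' profiling with retrogene flagging, tandem-duplication detection,
#' promoter cis-element analysis, and expression clustering with the DE
#' filter. Report tables are written as TSV; identical inputs and
#' configuration produce byte-identical reports.
#'
#' @param inputDir directory holding the study inputs.
#' @param outDir directory for the report tables (created if needed).
#' @param config a [PipelineConfig-class].
#' @param skip character vector of stages to skip (any of
#'   \code{"structure"}, \code{"tandem"}, \code{"promoter"},
#'   \code{"enrichment"}, \code{"expression"}).
#' @return (invisibly) a list: per-stage result objects plus
#'   \code{counts}, a named vector reconciling gene counts across
#'   stages, and the config snapshot.
#' @export
runPipeline <- function(inputDir, outDir, config = pipelineConfig(),
                        skip = character(0)) {
  need <- c("annotation.gff3", "genome.fa", "kd_hits.tsv", "lrr_hits.tsv",
            "sim_hits.tsv", "tm_a.tsv", "tm_b.tsv", "domains.tsv",
            "tree.nwk", "anchors.tsv")
  missing <- need[!file.exists(file.path(inputDir, need))]
  if (length(missing))
    stop("missing pipeline inputs: ", paste(missing, collapse = ", "))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  o <- function(f) file.path(outDir, f)
  i <- function(f) file.path(inputDir, f)

  gms <- readGff3(i("annotation.gff3"), chromPattern = config@chromPattern)
  kd <- readDomainTable(i("kd_hits.tsv"))
  lrr <- readDomainTable(i("lrr_hits.tsv"))
  simh <- readSimilarityTable(i("sim_hits.tsv"))
  tm <- rbind(readTmTable(i("tm_a.tsv"), "predictor_a"),
              readTmTable(i("tm_b.tsv"), "predictor_b"))
  domains <- read.delim(i("domains.tsv"), stringsAsFactors = FALSE)

  # identification
  cand <- buildCandidateSet(kd, lrr, simh, config)
  tmCalls <- callTm(tm, universe = unique(c(cand$protein_id,
                                            tm$protein_id,
                                            domains$protein_id)))
  arch <- architectureTable(domains, tm)
  ident <- identifyLrrRlks(cand, arch, tmCalls,
                           universe = unique(c(kd$protein_id,
                                               lrr$protein_id,
                                               simh$protein_id)))
  .writeTsv(ident, o("identification.tsv"))
  famIds <- ident$protein_id[ident$is_lrr_rlk]

  # classification
  tree <- readNewick(i("tree.nwk"))
  anchors <- read.delim(i("anchors.tsv"), stringsAsFactors = FALSE)
  assign <- assignSubfamilies(tree, anchors, config = config)
  assign <- assign[assign$is_anchor | assign$gene_id %in% famIds, ,
                   drop = FALSE]
  assign$species[!assign$is_anchor] <- "simulated"
  .writeTsv(assign, o("assignments.tsv"))
  famAssign <- assign[!assign$is_anchor, , drop = FALSE]
  .writeTsv(tabulateSubfamilies(assign, config = config),
            o("subfamily_table.tsv"))

  res <- list(identification = ident, assignments = assign)

  if (!("structure" %in% skip)) {
    prof <- structureProfiles(gms, domains[domains$protein_id %in%
                                             famIds, , drop = FALSE])
    retro <- detectIntronless(prof, famAssign)
    .writeTsv(prof, o("structure_profiles.tsv"))
    .writeTsv(summarizeStructure(prof, famAssign),
              o("structure_summary.tsv"))
    .writeTsv(data.frame(gene_id = retro), o("retrogenes.tsv"))
    res$profiles <- prof
    res$retrogenes <- retro
  }

  if (!("tandem" %in% skip)) {
    index <- orderGenes(gms)
    sets <- findTandemSets(famAssign, index, config)
    .writeTsv(sets, o("tandem_sets.tsv"))
    tsum <- summarizeTandem(sets, famAssign)
    .writeTsv(tsum$table, o("tandem_summary.tsv"))
    res$tandem <- sets
    res$tandemSummary <- tsum
  }

  if (!("promoter" %in% skip) && file.exists(i("catalog.tsv"))) {
    catalog <- readCisCatalog(i("catalog.tsv"))
    genome <- readFasta(i("genome.fa"))
    prom <- extractPromoters(genome, gms[intersect(geneIds(gms), famIds)],
                             length = config@promoterLength)
    matches <- scanMotifs(prom, catalog)
    pres <- categorizePresence(matches, catalog, universe = names(prom))
    .writeTsv(matches, o("motif_matches.tsv"))
    .writeTsv(pres$table, o("promoter_categories.tsv"))
    cisEnr <- subfamilyCisEnrichment(pres$presence, famAssign)
    .writeTsv(cisEnr, o("promoter_enrichment.tsv"))
    res$promoter <- list(matches = matches, presence = pres,
                         enrichment = cisEnr)
  }

  if (!("enrichment" %in% skip) && file.exists(i("term_map.tsv"))) {
    termMap <- readTermMap(i("term_map.tsv"))
    enr <- hypergeomEnrich(famIds, termMap, background = geneIds(gms))
    .writeTsv(enr, o("term_enrichment.tsv"))
    res$enrichment <- enr
  }

  if (!("expression" %in% skip) && file.exists(i("fiber_fpkm.tsv"))) {
    fiber <- readMatrixTsv(i("fiber_fpkm.tsv"))
    km <- kmeansGroups(logTransform(fiber, config@logOffset),
                       k = config@kmeansK)
    out <- data.frame(gene_id = names(km), kmeans_group = unname(km),
                      stringsAsFactors = FALSE)
    if (file.exists(i("stress_fpkm.tsv"))) {
      stress <- readMatrixTsv(i("stress_fpkm.tsv"))
      hc <- hierarchicalGroups(logTransform(stress, config@logOffset),
                               nGroups = config@hclustGroups)
      out$hclust_group <- unname(hc[out$gene_id])
    }
    .writeTsv(out, o("expression_groups.tsv"))
    res$expression <- out
    if (file.exists(i("de_stats.tsv"))) {
      de <- filterDE(readDeTable(i("de_stats.tsv")), config)
      .writeTsv(data.frame(gene_id = de), o("de_genes.tsv"))
      res$deGenes <- de
    }
  }

  counts <- c(annotated = length(gms),
              candidates = nrow(cand),
              identified = length(famIds),
              classified = nrow(famAssign))
  res$counts <- counts
  res$config <- config
  .writeTsv(data.frame(stage = names(counts), n = unname(counts)),
            o("run_report.tsv"))
  invisible(res)
}
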