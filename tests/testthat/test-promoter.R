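test_that("promoter windows: upstream arithmetic, edges, minus strand", {
  genome <- Biostrings::DNAStringSet(c(
    A1 = paste(rep("ACGT", 1000), collapse = "")))
  gms <- makeGeneModel(2001, 2300)
  p <- extractPromoters(genome, gms, length = 1500)
  expect_equal(unname(as.character(p)[1]),
               as.character(Biostrings::subseq(genome[[1]], 501, 2000)))
  expect_false(S4Vectors::mcols(p)$truncated[1])

  # start codon at 800: truncated window 1-799
  gms2 <- makeGeneModel(800, 1099)
  p2 <- extractPromoters(genome, gms2, length = 1500)
  expect_equal(Biostrings::width(p2)[1], 799L)
  expect_true(S4Vectors::mcols(p2)$truncated[1])

  # minus strand: reverse complement of the 3'-adjacent window
  gms3 <- makeGeneModel(501, 800, strand = "-")
  p3 <- extractPromoters(genome, gms3, length = 1500)
  expect_equal(unname(as.character(p3)[1]),
               revcompStr(as.character(
                 Biostrings::subseq(genome[[1]], 801, 2300))))
})

test_that("motif scanner finds exact IUPAC occurrences on both strands", {
  cat0 <- data.frame(element_id = character(0), motif = character(0),
                     category = character(0))
  prom <- Biostrings::DNAStringSet(c(g1 = "CCTATACC"))
  expect_equal(nrow(scanMotifs(prom, cat0)), 0)

  cat1 <- data.frame(element_id = "TATA", motif = "TATA",
                     category = "core", stringsAsFactors = FALSE)
  m <- scanMotifs(prom, cat1)
  # TATA is its own reverse complement: the occurrence at offset 2 is
  # reported on both strands
  expect_equal(m$offset[m$strand == "+"], 2L)
  expect_equal(m$offset[m$strand == "-"], 2L)

  # degenerate positions and overlapping occurrences all reported
  cat2 <- data.frame(element_id = "E", motif = "WAW", category = "x",
                     stringsAsFactors = FALSE)
  m2 <- scanMotifs(Biostrings::DNAStringSet(c(g1 = "AAAAA")), cat2)
  expect_equal(sort(m2$offset[m2$strand == "+"]), 0:2)
})

test_that("scanner equals the naive sliding-window oracle on long input", {
  set.seed(5)
  seqStr <- paste(sample(c("A", "C", "G", "T"), 10000, replace = TRUE),
                  collapse = "")
  prom <- Biostrings::DNAStringSet(c(g = seqStr))
  motifs <- c("TACGTGGC", "CAAGNNTATC", "TGAGTCAY", "WAW", "ACGT")
  for (mot in motifs) {
    catalog <- data.frame(element_id = "E", motif = mot, category = "x",
                          stringsAsFactors = FALSE)
    got <- scanMotifs(prom, catalog)
    expect_equal(sort(got$offset[got$strand == "+"]),
                 sort(naiveScan(seqStr, mot)), info = mot)
    expect_equal(sort(got$offset[got$strand == "-"]),
                 sort(naiveScan(seqStr, revcompStr(mot))), info = mot)
  }
})

test_that("reverse-complement symmetry mirrors match offsets", {
  set.seed(11)
  seqStr <- paste(sample(c("A", "C", "G", "T"), 3000, replace = TRUE),
                  collapse = "")
  mot <- "TGAGTCAY"
  catalog <- data.frame(element_id = "E", motif = mot, category = "x",
                        stringsAsFactors = FALSE)
  fwd <- scanMotifs(Biostrings::DNAStringSet(c(g = seqStr)), catalog)
  catRc <- data.frame(element_id = "E", motif = revcompStr(mot),
                      category = "x", stringsAsFactors = FALSE)
  rev <- scanMotifs(Biostrings::DNAStringSet(c(g = revcompStr(seqStr))),
                    catRc)
  L <- nchar(seqStr); w <- nchar(mot)
  expect_equal(sort(L - w - fwd$offset[fwd$strand == "+"]),
               sort(rev$offset[rev$strand == "+"]))
})

test_that("planted promoter occurrences are recovered exactly", {
  sim <- cachedSim(101, 80, 20)
  m <- manifest(sim)
  famIds <- m$genes$gene_id[m$genes$is_family]
  prom <- extractPromoters(sim@genome, models(sim)[famIds], length = 1500)
  got <- scanMotifs(prom, sim@catalog)
  want <- m$motifPlan
  keyG <- function(d) paste(d$gene_id, d$element_id, d$offset, d$strand)
  expect_setequal(keyG(got), keyG(want))
})

test_that("category presence counts genes once and bounds percentages", {
  catalog <- data.frame(element_id = c("ABRE", "ABRE3a", "LTR"),
                        motif = c("TACGTGGC", "GCAACGTGTC", "CCGAAATC"),
                        category = c("ABA response", "ABA response",
                                     "cold response"),
                        stringsAsFactors = FALSE)
  matches <- data.frame(gene_id = c("g1", "g1"),
                        element_id = c("ABRE", "ABRE3a"),
                        offset = c(0L, 100L), strand = "+",
                        stringsAsFactors = FALSE)
  out <- categorizePresence(matches, catalog, universe = c("g1", "g2"))
  aba <- out$table[out$table$category == "ABA response", ]
  expect_equal(aba$n_genes, 1L)   # presence, not occurrence count
  expect_equal(aba$pct, 50.0)
  expect_true(all(out$table$pct <= 100))
  # no matches: zero everywhere
  none <- categorizePresence(matches[0, ], catalog, c("g1", "g2"))
  expect_true(all(none$table$n_genes == 0))
})

test_that("per-subfamily cis enrichment: null gives p 1, planted pair
           ranks first", {
  pres <- matrix(TRUE, nrow = 10, ncol = 1,
                 dimnames = list(paste0("g", 1:10), "cat"))
  asn <- data.frame(gene_id = paste0("g", 1:10),
                    subfamily = rep(c("XII", "XI-1"), each = 5))
  enr <- subfamilyCisEnrichment(pres, asn)
  expect_true(all(enr$p == 1))

  # frozen hypergeometric example: C(5,4)/C(10,4) = 5/210
  pres2 <- matrix(c(rep(TRUE, 5), rep(FALSE, 5)), ncol = 1,
                  dimnames = list(paste0("g", 1:10), "cat"))
  asn2 <- data.frame(gene_id = paste0("g", 1:10),
                     subfamily = c(rep("XII", 4), rep("XI-1", 6)))
  enr2 <- subfamilyCisEnrichment(pres2, asn2)
  pXII <- enr2$p[enr2$subfamily == "XII"]
  expect_equal(pXII, 5 / 210, tolerance = 1e-12)
  expect_equal(pXII, oracleHyper(10, 5, 4, 4), tolerance = 1e-12)

  sim <- cachedSim(101, 80, 20)
  m <- manifest(sim)
  famIds <- m$genes$gene_id[m$genes$is_family]
  prom <- extractPromoters(sim@genome, models(sim)[famIds], length = 1500)
  pres3 <- categorizePresence(scanMotifs(prom, sim@catalog), sim@catalog,
                              famIds)$presence
  enr3 <- subfamilyCisEnrichment(pres3, familyAssignments(sim))
  top <- enr3[which.min(enr3$p_adj), ]
  expect_equal(top$subfamily, m$enriched$subfamily)
  expect_equal(top$category, m$enriched$category)
})
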