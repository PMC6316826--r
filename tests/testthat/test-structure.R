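test_that("protein interval maps onto a single-CDS gene by 3p arithmetic", {
  gms <- makeGeneModel(1001, 1300)
  iv <- mapProteinToGenome(gms, "g1", 1, 10)
  expect_equal(as.data.frame(iv)[, 1:2], data.frame(start = 1001, end = 1030))
  expect_error(mapProteinToGenome(gms, "g1", 1, 101), "outside")
})

test_that("mapping splits at CDS boundaries (frozen two-segment case)", {
  gms <- makeGeneModel(c(1001, 2001), c(1100, 2200))
  iv <- mapProteinToGenome(gms, "g1", 30, 40)
  expect_equal(IRanges::start(iv), c(1088, 2001))
  expect_equal(IRanges::end(iv), c(1100, 2020))
  expect_equal(as.data.frame(oracleMapProtein(gms, "g1", 30, 40))[, 1:2],
               as.data.frame(iv)[, 1:2])
})

test_that("mapping equals the per-base oracle on random models", {
  set.seed(42)
  for (rep in 1:25) {
    gms <- randomGeneModel()
    protLen <- sum(IRanges::width(cdsList(gms)[[1]])) %/% 3
    p <- sample(protLen, 1)
    q <- resample(p:protLen)
    iv <- mapProteinToGenome(gms, "g1", p, q)
    orc <- oracleMapProtein(gms, "g1", p, q)
    expect_equal(as.data.frame(iv)[, 1:2], as.data.frame(orc)[, 1:2],
                 info = paste("rep", rep))
    # round trip: mapped nucleotides total 3*(q-p+1)
    expect_equal(sum(IRanges::width(iv)), 3 * (q - p + 1))
  }
})

test_that("strand symmetry: a mirrored gene maps to mirrored intervals", {
  set.seed(7)
  for (rep in 1:5) {
    gms <- randomGeneModel(strand = "+")
    ex <- exonList(gms)[[1]]
    L <- max(IRanges::end(ex)) + 1000L
    # mirror the exon layout around the sequence and flip the strand
    mi <- makeGeneModel(sort(L - IRanges::end(ex)),
                        sort(L - IRanges::start(ex)), strand = "-")
    protLen <- sum(IRanges::width(ex)) %/% 3
    p <- sample(protLen, 1); q <- resample(p:protLen)
    fwd <- mapProteinToGenome(gms, "g1", p, q)
    revv <- mapProteinToGenome(mi, "g1", p, q)
    expect_equal(sort(L - IRanges::end(fwd)), IRanges::start(revv))
    expect_equal(sort(L - IRanges::start(fwd)), IRanges::end(revv))
  }
})

test_that("intron counting and structure groups follow the KD convention", {
  expect_equal(countIntronsInRegion(IRanges::IRanges(100, 400)), 0L)
  expect_equal(countIntronsInRegion(IRanges::IRanges(c(100, 600),
                                                     c(400, 900))), 1L)
  gms <- makeGeneModel(c(1, 301, 601, 901), c(150, 450, 750, 1050))
  protLen <- sum(IRanges::width(cdsList(gms)[[1]])) %/% 3
  iv <- mapProteinToGenome(gms, "g1", 1, protLen)
  expect_equal(countIntronsInRegion(iv), 3L)

  expect_equal(assignStructureGroup(c(1, 2, 4, 0)),
               c("A", "B", "C", "unassigned"))
})

test_that("structure profiles recover planted groups and retrogenes", {
  sim <- cachedSim(101, 80, 20)
  m <- manifest(sim)
  famIds <- m$genes$gene_id[m$genes$is_family]
  prof <- structureProfiles(models(sim),
                            sim@domains[sim@domains$protein_id %in%
                                          famIds, ])
  asn <- familyAssignments(sim)
  # groups partition all profiled genes
  expect_setequal(prof$gene_id, famIds)
  expect_true(all(prof$group %in% c("A", "B", "C", "unassigned")))
  # invariant: introns_in_kd = kd_exon_count - 1
  withKd <- prof[prof$kd_exon_count >= 1, ]
  expect_equal(withKd$introns_in_kd, withKd$kd_exon_count - 1L)
  # retrogene copies are single-exon, hence group A by construction
  expect_equal(sort(detectIntronless(prof, asn)), sort(m$retro))
})

test_that("intronless flag requires a multi-intron subfamily witness", {
  prof <- data.frame(gene_id = c("a", "b", "c", "d"),
                     n_exons = c(4, 5, 1, 6),
                     kd_exon_count = 2, introns_in_kd = 1,
                     introns_in_ecd = 1, group = "B",
                     stringsAsFactors = FALSE)
  asn <- data.frame(gene_id = c("a", "b", "c", "d"), subfamily = "XII")
  expect_equal(detectIntronless(prof, asn), "c")
  # no witness: a subfamily of all-intronless genes flags nothing
  prof$n_exons <- 1
  expect_equal(detectIntronless(prof, asn), character(0))
})
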