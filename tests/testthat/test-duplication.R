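cfg <- pipelineConfig()

test_that("gene ordering produces dense per-sequence ranks", {
  sim <- cachedSim(101, 80, 20)
  idx <- orderGenes(models(sim))
  for (ch in unique(idx$chromosome)) {
    r <- idx$rank[idx$chromosome == ch]
    expect_equal(sort(r), seq_along(r) - 1L)
    expect_false(is.unsorted(idx$start[idx$chromosome == ch][order(r)]))
  }
  # shuffled input order yields identical ranks
  shuffled <- models(sim)[sample(length(models(sim)))]
  idx2 <- orderGenes(shuffled)
  idx2 <- idx2[match(idx$gene_id, idx2$gene_id), ]
  expect_equal(idx$rank, idx2$rank)
})

test_that("tandem adjacency rule: distance and intervening-gene windows", {
  idx <- data.frame(gene_id = c("x", "y"), chromosome = "A1",
                    start = c(10000, 60000), end = c(15000, 66000),
                    is_scaffold = FALSE, rank = 0:1,
                    stringsAsFactors = FALSE)
  asn <- data.frame(gene_id = c("x", "y"), subfamily = "XII")
  sets <- findTandemSets(asn, idx, cfg)
  expect_equal(sort(sets$gene_id), c("x", "y"))
  # same pair 250 kb apart: no set
  idx$start[2] <- idx$end[1] + 250001
  idx$end[2] <- idx$start[2] + 5000
  expect_equal(nrow(findTandemSets(asn, idx, cfg)), 0)
  # different subfamilies never pair
  idx$start[2] <- 60000; idx$end[2] <- 66000
  asn$subfamily <- c("XII", "XI-1")
  expect_equal(nrow(findTandemSets(asn, idx, cfg)), 0)
})

test_that("chained components merge beyond the pairwise window", {
  # A-B and B-C are within 150 kb, A-C is 300 kb apart: one set {A,B,C}
  idx <- data.frame(gene_id = c("A", "i1", "i2", "B", "i3", "i4", "i5",
                                "C"),
                    chromosome = "A1",
                    start = c(0, 30, 60, 150, 180, 210, 240, 300) * 1000 + 1,
                    end = c(5, 35, 65, 155, 185, 215, 245, 305) * 1000,
                    is_scaffold = FALSE, rank = 0:7,
                    stringsAsFactors = FALSE)
  asn <- data.frame(gene_id = c("A", "B", "C"), subfamily = "XI-1")
  sets <- findTandemSets(asn, idx, cfg)
  expect_equal(length(unique(sets$set_id)), 1)
  expect_equal(sets$gene_id, c("A", "B", "C"))  # ordered by start
})

test_that("detector equals the brute-force pair graph on random input", {
  skip_if_not_installed("igraph")
  set.seed(2024)
  for (rep in 1:10) {
    rc <- randomChromIndex(nGenes = 120, nFamily = 30)
    got <- setsAsPartition(findTandemSets(rc$assignments, rc$index, cfg))
    want <- canonicalPartition(oracleTandem(rc$assignments, rc$index, cfg))
    expect_equal(got, want, info = paste("rep", rep))
  }
})

test_that("widening either window never loses tandem genes", {
  set.seed(99)
  rc <- randomChromIndex(nGenes = 150, nFamily = 40)
  base <- findTandemSets(rc$assignments, rc$index, cfg)
  wider <- findTandemSets(rc$assignments, rc$index,
                          pipelineConfig(tandemMaxDistance = 400000,
                                         tandemMaxIntervening = 20))
  expect_true(all(base$gene_id %in% wider$gene_id))
  # every gene belongs to at most one set
  expect_false(anyDuplicated(base$gene_id) > 0)
})

test_that("planted arrays are recovered exactly; negatives stay out", {
  sim <- cachedSim(202, 300, 60)
  m <- manifest(sim)
  sets <- findTandemSets(familyAssignments(sim), orderGenes(models(sim)),
                         cfg)
  planted <- canonicalPartition(lapply(m$arrays, function(a)
    sort(a$members)))
  expect_equal(setsAsPartition(sets), planted)
})

test_that("expanded-subfamily shares reproduce the printed arithmetic", {
  tc <- gossypiumTandemCounts()
  ga <- tc[tc$species == "G_arboreum", ]
  sh <- tandemShares(setNames(ga$n_genes, ga$subfamily),
                     setNames(ga$n_sets, ga$subfamily))
  expect_equal(sh$set_share, 73.1)
  expect_equal(sh$gene_share, 78.5)
  expect_equal(sh$total_sets, 26)
  expect_equal(sh$total_genes, 79)
  # no sets: all shares zero, empty table
  z <- summarizeTandem(data.frame(set_id = character(0),
                                  subfamily = character(0),
                                  chromosome = character(0),
                                  gene_id = character(0)))
  expect_equal(z$xi_xii_set_share, 0)
  expect_equal(nrow(z$table), 0)
})

test_that("summary table counts genes and sets per subfamily", {
  sim <- cachedSim(202, 300, 60)
  sets <- findTandemSets(familyAssignments(sim), orderGenes(models(sim)),
                         cfg)
  sm <- summarizeTandem(sets, familyAssignments(sim))
  expect_equal(sm$total_genes, nrow(sets))
  expect_equal(sm$total_sets, length(unique(sets$set_id)))
  expect_true(all(sm$table$tandem_fraction <= 1))
})
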