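test_that("hypergeometric enrichment matches exhaustive enumeration", {
  tm <- data.frame(gene_id = paste0("g", 1:5), term_id = "T1",
                   description = "toy", stringsAsFactors = FALSE)
  bg <- paste0("g", 1:10)
  # frozen case N=10, K=5, n=4, x=4: p = C(5,4)/C(10,4) = 5/210
  out <- hypergeomEnrich(paste0("g", 1:4), tm, bg)
  expect_equal(out$p, 5 / 210, tolerance = 1e-12)
  expect_equal(out$p, oracleHyper(10, 5, 4, 4), tolerance = 1e-12)
  # gene set = background: overlap is certain, p = 1 for every term
  expect_true(all(hypergeomEnrich(bg, tm, bg)$p == 1))
  expect_error(hypergeomEnrich("g1", tm, character(0)), "empty")
  expect_error(hypergeomEnrich("zz", tm, bg), "outside")
})

test_that("enrichment p equals the subset-enumeration oracle for N <= 12", {
  set.seed(8)
  for (rep in 1:12) {
    N <- sample(5:12, 1)
    K <- sample(1:(N - 1), 1)
    n <- sample(1:(N - 1), 1)
    bg <- paste0("g", seq_len(N))
    tm <- data.frame(gene_id = bg[seq_len(K)], term_id = "T",
                     description = "d", stringsAsFactors = FALSE)
    gs <- sample(bg, n)
    p <- hypergeomEnrich(gs, tm, bg)$p
    x <- sum(gs %in% bg[seq_len(K)])
    expect_equal(p, oracleHyper(N, K, n, x), tolerance = 1e-12)
  }
})

test_that("BH adjustment is monotone and never below the raw p", {
  set.seed(4)
  bg <- paste0("g", 1:40)
  tm <- do.call(rbind, lapply(1:8, function(k)
    data.frame(gene_id = sample(bg, sample(5:20, 1)),
               term_id = paste0("T", k), description = "d",
               stringsAsFactors = FALSE)))
  out <- hypergeomEnrich(sample(bg, 12), tm, bg)
  expect_true(all(out$p_adj >= out$p))
  expect_false(is.unsorted(out$p_adj))   # table is sorted by raw p
})

test_that("planted enriched term attains the smallest adjusted p", {
  set.seed(12)
  bg <- paste0("g", 1:60)
  hit <- bg[1:12]
  tm <- rbind(
    data.frame(gene_id = hit, term_id = "T_hit", description = "planted",
               stringsAsFactors = FALSE),
    do.call(rbind, lapply(1:6, function(k)
      data.frame(gene_id = sample(bg, 15), term_id = paste0("T", k),
                 description = "noise", stringsAsFactors = FALSE))))
  out <- hypergeomEnrich(hit, tm, bg)
  expect_equal(out$term_id[1], "T_hit")
})

test_that("proportion comparison: exact test, symmetry, printed cases", {
  eq <- compareProportions(c(I = 5), 100, c(I = 5), 100)
  expect_equal(eq$p, 1.0)
  # subfamily I: 41/213 vs 4/298 is overwhelmingly significant
  p1 <- compareProportions(c(I = 41), 213, c(I = 4), 298)
  expect_true(p1$significant)
  expect_equal(p1$p, oracleFisher(41, 213 - 41, 4, 298 - 4),
               tolerance = 1e-8)
  # subfamily XII: 102/511 vs 61/515 is significant at 0.05
  p2 <- compareProportions(c(XII = 102), 511, c(XII = 61), 515)
  expect_true(p2$significant)
  expect_equal(p2$p, oracleFisher(102, 511 - 102, 61, 515 - 61),
               tolerance = 1e-8)
  # swapping the two species leaves the p-value unchanged
  p2swap <- compareProportions(c(XII = 61), 515, c(XII = 102), 511)
  expect_equal(p2$p, p2swap$p)
  expect_error(compareProportions(c(I = 1), 0, c(I = 1), 10), "positive")
})

test_that("proportion ratios handle equal, zero and undefined cases", {
  r <- ratioReport(c("XI-1" = 25.2), c("XI-1" = 13.1))
  expect_equal(r$ratio, 25.2 / 13.1, tolerance = 1e-12)
  expect_gt(r$ratio, 1.9)
  expect_equal(ratioReport(c(a = 5), c(a = 5))$ratio, 1.0)
  expect_equal(ratioReport(c(a = 0), c(a = 5))$ratio, 0.0)
  expect_true(is.na(ratioReport(c(a = 5), c(a = 0))$ratio))
})
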