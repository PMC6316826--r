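cfg <- pipelineConfig()

hit <- function(pid, fam, e, s = 1L, e2 = 100L, ident = NA_real_,
                ev = "hmm") {
  data.frame(protein_id = pid, family_id = fam, evidence = ev,
             e_value = e, ali_start = s, ali_end = e2,
             identity_pct = ident, stringsAsFactors = FALSE)
}

test_that("candidate set requires both HMM domains or a similarity hit", {
  kd <- hit("p1", "PF00069", 1e-12)
  # KD alone is not enough
  expect_equal(nrow(buildCandidateSet(kd, kd[0, ], NULL, cfg)), 0)
  # KD + LRR at threshold qualifies via the HMM route
  lrr <- hit("p1", "PF13855", 1e-11)
  cand <- buildCandidateSet(kd, lrr, NULL, cfg)
  expect_equal(cand$route, "hmm_both")
  # similarity route: E-value and identity both required
  sim <- hit("p2", "ATref", 1e-20, ident = 62.5, ev = "similarity")
  cand <- buildCandidateSet(kd, lrr, sim, cfg)
  expect_setequal(cand$protein_id, c("p1", "p2"))
  expect_equal(cand$route[cand$protein_id == "p2"], "similarity")
  # identity exactly at the floor is excluded (strict >)
  simLow <- hit("p3", "ATref", 1e-20, ident = 50.0, ev = "similarity")
  expect_false("p3" %in%
    buildCandidateSet(kd, lrr, rbind(sim, simLow), cfg)$protein_id)
  # both routes at once
  simBoth <- hit("p1", "ATref", 1e-20, ident = 80, ev = "similarity")
  expect_equal(buildCandidateSet(kd, lrr, simBoth, cfg)$route, "both")
})

test_that("TM consensus: either predictor suffices, union is retained", {
  seg <- function(pid, pred, s, e)
    data.frame(protein_id = pid, predictor = pred, start = s, end = e,
               stringsAsFactors = FALSE)
  tm <- rbind(seg("p1", "predictor_a", 100, 122),
              seg("p2", "predictor_a", 50, 70),
              seg("p2", "predictor_b", 60, 85))
  calls <- callTm(tm, universe = c("p1", "p2", "p3"))
  expect_equal(calls$has_tm, c(TRUE, TRUE, FALSE))
  # overlapping segments from the two predictors merge into one union span
  expect_equal(calls$n_segments[calls$protein_id == "p2"], 1L)
  expect_equal(as.data.frame(tmSpans(tm, "p2")),
               as.data.frame(IRanges::IRanges(50, 85)))
})

test_that("architecture order check uses midpoints after merging", {
  ok <- validateArchitecture(IRanges::IRanges(50, 400),
                             IRanges::IRanges(420, 442),
                             IRanges::IRanges(480, 760))
  expect_true(ok$ordered_ok)
  bad <- validateArchitecture(IRanges::IRanges(340, 600),
                              IRanges::IRanges(300, 322),
                              IRanges::IRanges(10, 280))
  expect_false(bad$ordered_ok)
  # overlapping LRR spans merge to 50-500 (midpoint 275) before the check
  merged <- validateArchitecture(IRanges::IRanges(c(50, 150), c(400, 500)),
                                 IRanges::IRanges(520, 542),
                                 IRanges::IRanges(560, 800))
  expect_true(merged$ordered_ok)
  expect_length(merged$lrr, 1)
  # a missing class can never be in order
  expect_false(validateArchitecture(IRanges::IRanges(),
                                    IRanges::IRanges(520, 542),
                                    IRanges::IRanges(560, 800))$ordered_ok)
})

test_that("zero-noise synthetic study is recovered perfectly with routes", {
  sim <- cachedSim(101, 80, 20)
  out <- identifyFromSim(sim)
  called <- out$result$protein_id[out$result$is_lrr_rlk]
  expect_setequal(called, out$truth)
  # every identified protein has a route; identified within candidates
  expect_false(anyNA(out$result$route[out$result$is_lrr_rlk]))
  expect_lte(length(called), nrow(out$candidates))
  # decoys fail with their designed reasons
  dec <- manifest(sim)$decoys
  got <- out$result[match(dec$protein_id, out$result$protein_id), ]
  expect_false(any(got$is_lrr_rlk))
  reasonOf <- function(cls) got$rejection_reason[dec$class == cls]
  expect_equal(reasonOf("no_tm"), "no_tm")
  expect_equal(reasonOf("bad_order"), "bad_order")
  expect_equal(reasonOf("weak_evalue"), "not_candidate")
  expect_equal(reasonOf("kd_only"), "not_candidate")
  expect_equal(reasonOf("lrr_only"), "not_candidate")
})

test_that("relaxing thresholds never shrinks the candidate set", {
  sim <- cachedSim(101, 80, 20)
  strict <- buildCandidateSet(sim@kdHits, sim@lrrHits, sim@simHits, cfg)
  relaxed <- buildCandidateSet(
    sim@kdHits, sim@lrrHits, sim@simHits,
    pipelineConfig(hmmEvalueMax = 1e-6, simEvalueMax = 1e-3,
                   simIdentityMin = 40))
  expect_true(all(strict$protein_id %in% relaxed$protein_id))
  # the weak-e-value decoy enters once thresholds are relaxed
  weak <- manifest(sim)$decoys$protein_id[
    manifest(sim)$decoys$class == "weak_evalue"]
  expect_false(weak %in% strict$protein_id)
  expect_true(weak %in% relaxed$protein_id)
})

test_that("either-predictor rule keeps all family genes when one
           predictor always misses", {
  sim <- cachedSim(77, 60, 14, tmDisagreeRate = 1)
  expect_equal(nrow(sim@tmA[sim@tmA$protein_id %in%
                              manifest(sim)$genes$gene_id[
                                manifest(sim)$genes$is_family], ]), 0)
  out <- identifyFromSim(sim)
  expect_setequal(out$result$protein_id[out$result$is_lrr_rlk], out$truth)
})
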