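#' Build the candidate set from the three evidence streams
#'
#' A protein is a candidate when it has both a kinase-domain (KD) HMM hit
#' and a leucine-rich-repeat (LRR) HMM hit at E-value <= the HMM cutoff,
#' or a similarity hit at E-value <= the similarity cutoff with identity
#' strictly above the identity floor. The union of the two branches is
#' kept, with the route recorded.
#'
#' @param kdHits,lrrHits data.frames of HMM hits (see [readDomainTable]).
#' @param simHits data.frame of similarity hits
#'   (see [readSimilarityTable]).
#' @param config a [PipelineConfig-class].
#' @return data.frame with columns \code{protein_id} and \code{route}
#'   (\code{hmm_both}, \code{similarity}, or \code{both}).
#' @examples
#' kd <- data.frame(protein_id = "p1", family_id = "PF00069",
#'                  evidence = "hmm", e_value = 1e-12,
#'                  ali_start = 400L, ali_end = 660L, identity_pct = NA)
#' lrr <- transform(kd, family_id = "PF13855", ali_start = 40L,
#'                  ali_end = 300L, e_value = 1e-11)
#' buildCandidateSet(kd, lrr, NULL, pipelineConfig())
#' @export
buildCandidateSet <- function(kdHits, lrrHits, simHits, config) {
  thr <- config@hmmEvalueMax
  kdOk <- unique(kdHits$protein_id[kdHits$e_value <= thr])
  lrrOk <- unique(lrrHits$protein_id[lrrHits$e_value <= thr])
  hmmBoth <- intersect(kdOk, lrrOk)
  simOk <- character(0)
  if (!is.null(simHits) && nrow(simHits))
    simOk <- unique(simHits$protein_id[
      simHits$e_value <= config@simEvalueMax &
      !is.na(simHits$identity_pct) &
      simHits$identity_pct > config@simIdentityMin])
  ids <- sort(union(hmmBoth, simOk))
  route <- ifelse(ids %in% hmmBoth & ids %in% simOk, "both",
                  ifelse(ids %in% hmmBoth, "hmm_both", "similarity"))
  data.frame(protein_id = ids, route = route, stringsAsFactors = FALSE)
}

#' Consensus transmembrane call across two predictors
#'
#' A protein is called transmembrane-positive when either predictor
#' reports at least one segment. Segments from both predictors are
#' retained (union) for downstream architecture checks.
#'
#' @param tmSegments data.frame with columns
#'   \code{protein_id, predictor, start, end} (rows from both predictors;
#'   see [readTmTable]).
#' @param universe optional character vector of protein ids to report on;
#'   defaults to the proteins present in \code{tmSegments}.
#' @return data.frame with columns \code{protein_id}, \code{has_tm} and
#'   \code{n_segments} (count of merged union segments).
#' @export
callTm <- function(tmSegments, universe = NULL) {
  if (is.null(universe)) universe <- unique(tmSegments$protein_id)
  universe <- sort(unique(universe))
  nseg <- vapply(universe, function(p) {
    seg <- tmSegments[tmSegments$protein_id == p, , drop = FALSE]
    if (nrow(seg) == 0L) return(0L)
    length(reduce(IRanges(seg$start, seg$end)))
  }, integer(1))
  data.frame(protein_id = universe, has_tm = nseg > 0L,
             n_segments = unname(nseg), stringsAsFactors = FALSE)
}

#' Merged union of TM segments for one protein
#'
#' @param tmSegments data.frame as in [callTm].
#' @param proteinId one protein id.
#' @return an \code{IRanges} of merged segments (may be empty).
#' @export
tmSpans <- function(tmSegments, proteinId) {
  seg <- tmSegments[tmSegments$protein_id == proteinId, , drop = FALSE]
  reduce(IRanges(seg$start, seg$end))
}

# merge overlapping same-class spans; spans given as IRanges
.mergeSpans <- function(spans) reduce(spans)

#' Validate the LRR-TM-KD domain architecture of one protein
#'
#' Overlapping same-class spans are merged first. The architecture is in
#' the canonical receptor-kinase order when the largest LRR-span midpoint
#' lies N-terminal of the smallest TM midpoint, which in turn lies
#' N-terminal of the smallest KD midpoint (LRR-TM-KD from N- to
#' C-terminus).
#'
#' @param lrrSpans,tmSpans,kdSpans \code{IRanges} of protein-coordinate
#'   spans (confirmed domain spans; HMM alignment coordinates when no
#'   confirmation table is available).
#' @return list with elements \code{lrr}, \code{tm}, \code{kd} (merged
#'   spans) and \code{ordered_ok} (logical; \code{FALSE} whenever any of
#'   the three classes is absent).
#' @examples
#' validateArchitecture(IRanges::IRanges(50, 400),
#'                      IRanges::IRanges(420, 442),
#'                      IRanges::IRanges(480, 760))$ordered_ok
#' @export
validateArchitecture <- function(lrrSpans, tmSpans, kdSpans) {
  lrr <- .mergeSpans(lrrSpans)
  tm <- .mergeSpans(tmSpans)
  kd <- .mergeSpans(kdSpans)
  ok <- FALSE
  if (length(lrr) && length(tm) && length(kd)) {
    mid <- function(r) (start(r) + end(r)) / 2
    ok <- max(mid(lrr)) < min(mid(tm)) && min(mid(tm)) < min(mid(kd))
  }
  list(lrr = lrr, tm = tm, kd = kd, ordered_ok = ok)
}

#' Build per-protein domain architectures
#'
#' Combines a confirmed domain-span table with the merged TM segments and
#' computes the order flag for every protein present in either input.
#'
#' @param domains data.frame with columns
#'   \code{protein_id, class, start, end}, where \code{class} is
#'   \code{"lrr"} or \code{"kd"} (protein coordinates).
#' @param tmSegments data.frame as in [callTm].
#' @return named list of architectures (see [validateArchitecture]),
#'   keyed by protein id.
#' @export
architectureTable <- function(domains, tmSegments) {
  ids <- sort(union(unique(domains$protein_id),
                    unique(tmSegments$protein_id)))
  out <- lapply(ids, function(p) {
    d <- domains[domains$protein_id == p, , drop = FALSE]
    lrr <- d[d$class == "lrr", , drop = FALSE]
    kd <- d[d$class == "kd", , drop = FALSE]
    validateArchitecture(IRanges(lrr$start, lrr$end),
                         tmSpans(tmSegments, p),
                         IRanges(kd$start, kd$end))
  })
  names(out) <- ids
  out
}

#' Final LRR-RLK identification
#'
#' A protein is called an LRR-RLK when it is a candidate, carries at
#' least one LRR span and one KD span, is transmembrane-positive under
#' the either-predictor consensus, and its domains lie in LRR-TM-KD
#' order. The first failing check is recorded as the rejection reason, in
#' the order \code{not_candidate}, \code{no_lrr}, \code{no_kd},
#' \code{no_tm}, \code{bad_order}.
#'
#' @param candidates data.frame from [buildCandidateSet].
#' @param architectures named list from [architectureTable].
#' @param tmCalls data.frame from [callTm].
#' @param universe optional additional protein ids to report on (e.g.
#'   every protein with any evidence row); defaults to the ids present
#'   in the three inputs.
#' @return data.frame with columns \code{protein_id}, \code{is_lrr_rlk},
#'   \code{route}, \code{rejection_reason}.
#' @export
identifyLrrRlks <- function(candidates, architectures, tmCalls,
                            universe = NULL) {
  ids <- sort(unique(c(candidates$protein_id, names(architectures),
                       tmCalls$protein_id, universe)))
  route <- candidates$route[match(ids, candidates$protein_id)]
  hasTm <- tmCalls$has_tm[match(ids, tmCalls$protein_id)]
  hasTm[is.na(hasTm)] <- FALSE
  reason <- character(length(ids))
  for (i in seq_along(ids)) {
    p <- ids[i]
    arch <- architectures[[p]]
    reason[i] <- if (!(p %in% candidates$protein_id)) "not_candidate"
      else if (is.null(arch) || length(arch$lrr) == 0L) "no_lrr"
      else if (length(arch$kd) == 0L) "no_kd"
      else if (!hasTm[i]) "no_tm"
      else if (!arch$ordered_ok) "bad_order"
      else "none"
  }
  data.frame(protein_id = ids, is_lrr_rlk = reason == "none",
             route = ifelse(is.na(route), NA_character_, route),
             rejection_reason = reason, stringsAsFactors = FALSE)
}
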