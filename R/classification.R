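#' @importFrom ape is.rooted cophenetic.phylo Ntip
#' @importFrom phangorn midpoint Ancestors Descendants
NULL

#' Assign subfamilies from a reference-anchored phylogeny
#'
#' Reference leaves (anchors) carry known subfamily labels. Every
#' non-anchor leaf is labelled by walking from the leaf toward the root
#' to the smallest clade containing at least one anchor and taking the
#' majority anchor label in that clade. Ties are broken by the smallest
#' patristic distance to an anchor carrying a tied label; residual ties
#' are flagged ambiguous and receive the lexicographically first tied
#' label. Unrooted trees are midpoint-rooted first.
#'
#' @param tree an \code{ape} \code{phylo} object.
#' @param anchors data.frame with columns \code{leaf_id} and
#'   \code{subfamily}; every \code{leaf_id} must be a tree tip.
#' @param species optional named character vector mapping gene ids to a
#'   species label (recorded in the output).
#' @param config a [PipelineConfig-class]; anchor labels must come from
#'   its subfamily label set.
#' @return data.frame with columns \code{gene_id}, \code{species},
#'   \code{subfamily}, \code{ambiguous}, \code{support} (majority share
#'   among anchors in the deciding clade) and \code{is_anchor}.
#' @examples
#' tr <- ape::read.tree(text = "((q1:1,atA:1):1,(atB:1,q2:1):1);")
#' anc <- data.frame(leaf_id = c("atA", "atB"),
#'                   subfamily = c("XII", "XI-1"))
#' assignSubfamilies(tr, anc)
#' @export
assignSubfamilies <- function(tree, anchors, species = NULL,
                              config = pipelineConfig()) {
  tips <- tree$tip.label
  if (nrow(anchors) == 0L || !any(anchors$leaf_id %in% tips))
    stop("tree contains no anchor leaves")
  if (!all(anchors$leaf_id %in% tips))
    stop("anchor leaves absent from tree: ",
         paste(setdiff(anchors$leaf_id, tips), collapse = ", "))
  if (anyNA(anchors$subfamily) ||
      !all(anchors$subfamily %in% config@subfamilyLabels))
    stop("anchor subfamily labels must be among the configured labels")
  if (!is.rooted(tree)) tree <- phangorn::midpoint(tree)

  anchorLab <- anchors$subfamily[match(tips, anchors$leaf_id)]
  isAnchor <- !is.na(anchorLab)
  ntip <- length(tips)
  dmat <- NULL  # patristic distances, computed lazily on first tie

  # tip sets of every node, and the ancestor walk per tip
  desc <- phangorn::Descendants(tree, seq_len(ntip + tree$Nnode), "tips")
  anc <- phangorn::Ancestors(tree, seq_len(ntip), "all")

  lab <- anchorLab
  ambiguous <- rep(FALSE, ntip)
  support <- rep(1.0, ntip)
  for (i in seq_len(ntip)) {
    if (isAnchor[i]) next
    deciding <- NULL
    for (node in anc[[i]]) {
      cladeTips <- desc[[node]]
      if (any(isAnchor[cladeTips])) { deciding <- cladeTips; break }
    }
    if (is.null(deciding)) stop("no anchored clade found for ", tips[i])
    aIdx <- deciding[isAnchor[deciding]]
    counts <- table(anchorLab[aIdx])
    top <- names(counts)[counts == max(counts)]
    support[i] <- max(counts) / length(aIdx)
    if (length(top) == 1L) {
      lab[i] <- top
    } else {
      if (is.null(dmat)) dmat <- cophenetic.phylo(tree)
      # nearest anchor among the tied labels
      dTied <- vapply(top, function(lb) {
        min(dmat[tips[i], tips[aIdx[anchorLab[aIdx] == lb]]])
      }, numeric(1))
      best <- top[dTied == min(dTied)]
      if (length(best) > 1L) {
        ambiguous[i] <- TRUE
        best <- sort(best)[1L]
      }
      lab[i] <- best[1L]
    }
  }
  sp <- if (is.null(species)) NA_character_ else
    unname(species[tips])
  data.frame(gene_id = tips, species = sp, subfamily = lab,
             ambiguous = ambiguous, support = support,
             is_anchor = isAnchor, stringsAsFactors = FALSE)
}

#' Compare subfamily assignments from two tree topologies
#'
#' Measures how stable the clade membership is between two phylogenies
#' of the same leaves (e.g. a maximum-likelihood and a neighbour-joining
#' tree): the fraction of leaves receiving the same label under both.
#'
#' @param assignA,assignB data.frames from [assignSubfamilies] over the
#'   same leaf set.
#' @return list with \code{overall} (fraction identical) and
#'   \code{per_subfamily} (data.frame of per-label agreement, computed
#'   over the leaves carrying that label in \code{assignA}).
#' @export
compareTopologies <- function(assignA, assignB) {
  if (!setequal(assignA$gene_id, assignB$gene_id))
    stop("assignments cover different leaf sets")
  b <- assignB$subfamily[match(assignA$gene_id, assignB$gene_id)]
  same <- assignA$subfamily == b
  per <- vapply(split(same, assignA$subfamily), mean, numeric(1))
  list(overall = mean(same),
       per_subfamily = data.frame(subfamily = names(per),
                                  stability = unname(per),
                                  stringsAsFactors = FALSE))
}

#' Per-subfamily percentages from member counts
#'
#' @param counts named numeric vector of per-subfamily member counts for
#'   one species.
#' @param total total family size for the species (defaults to
#'   \code{sum(counts)}).
#' @return data.frame with columns \code{subfamily}, \code{n},
#'   \code{pct} (percentage rounded to one decimal).
#' @examples
#' subfamilyPercentages(c("XI-1" = 75, "XII" = 49), total = 298)
#' @export
subfamilyPercentages <- function(counts, total = sum(counts)) {
  data.frame(subfamily = names(counts), n = as.numeric(counts),
             pct = .round1(100 * as.numeric(counts) / total),
             stringsAsFactors = FALSE)
}

#' Tabulate subfamily composition per species
#'
#' Counts family members per subfamily and species and computes the
#' percentage of each species' family total.
#'
#' @param assignments data.frame from [assignSubfamilies] (anchors are
#'   excluded unless \code{includeAnchors = TRUE}); must carry a
#'   \code{species} column.
#' @param totals optional named vector of family totals per species;
#'   defaults to the per-species assignment counts.
#' @param config a [PipelineConfig-class] supplying the label order.
#' @param includeAnchors count anchor leaves too.
#' @return data.frame with columns \code{species}, \code{subfamily},
#'   \code{n}, \code{pct}; empty input yields an empty table.
#' @export
tabulateSubfamilies <- function(assignments, totals = NULL,
                                config = pipelineConfig(),
                                includeAnchors = FALSE) {
  a <- assignments
  if (!includeAnchors && "is_anchor" %in% names(a))
    a <- a[!a$is_anchor, , drop = FALSE]
  if (nrow(a) == 0L)
    return(data.frame(species = character(0), subfamily = character(0),
                      n = numeric(0), pct = numeric(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, lapply(split(a, a$species), function(sa) {
    cnt <- table(factor(sa$subfamily, levels = config@subfamilyLabels))
    tot <- if (is.null(totals)) nrow(sa) else totals[[sa$species[1]]]
    cbind(species = sa$species[1],
          subfamilyPercentages(setNames(as.numeric(cnt), names(cnt)),
                               total = tot))
  }))
  rownames(out) <- NULL
  out
}
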