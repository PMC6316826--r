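#' Published cotton LRR-RLK study tables
#'
#' Accessors for the per-subfamily member counts, per-subfamily tandem
#' duplication counts and family sizes reported for the four
#' \emph{Gossypium} species and \emph{A. thaliana}, shipped as plain
#' TSV. These are the raw counts from which the package's worked
#' examples recompute percentage compositions, expansion ratios,
#' tandem-duplication shares and scaffold placement rates.
#'
#' @return \code{gossypiumSubfamilyCounts}: data.frame of per-subfamily
#'   member counts per species. \code{gossypiumTandemCounts}: data.frame
#'   of per-subfamily tandem gene/set counts per species.
#'   \code{gossypiumFamilySizes}: data.frame of identified family sizes
#'   and scaffold-located counts per species.
#' @examples
#' counts <- gossypiumSubfamilyCounts()
#' subfamilyPercentages(setNames(counts$G_arboreum, counts$subfamily))
#' @name gossypium-tables
NULL

#' @rdname gossypium-tables
#' @export
gossypiumSubfamilyCounts <- function() {
  read.delim(system.file("extdata", "gossypium_subfamily_counts.tsv",
                         package = "rlkfam"),
             stringsAsFactors = FALSE, check.names = FALSE)
}

#' @rdname gossypium-tables
#' @export
gossypiumTandemCounts <- function() {
  read.delim(system.file("extdata", "gossypium_tandem_counts.tsv",
                         package = "rlkfam"),
             stringsAsFactors = FALSE, check.names = FALSE)
}

#' @rdname gossypium-tables
#' @export
gossypiumFamilySizes <- function() {
  read.delim(system.file("extdata", "gossypium_family_sizes.tsv",
                         package = "rlkfam"),
             stringsAsFactors = FALSE, check.names = FALSE)
}
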