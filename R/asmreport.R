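#' Nxx assembly statistic
#'
#' Sorts lengths in decreasing order and returns the length at which the
#' cumulative sum first reaches x% of the total ("first-reach" convention,
#' `>=`). `total_override` lets the Nxx of a full assembly be computed from a
#' subset of its sequences (e.g. scaffold N50 of an assembly from its
#' chromosome-scale scaffolds alone).
#'
#' @param lengths numeric vector of positive sequence lengths in bp.
#' @param x percentage in (0, 100); 50 gives N50, 90 gives N90.
#' @param total_override optional total assembly size in bp to use instead of
#'   `sum(lengths)`.
#' @return the Nxx length in bp.
#' @export
nxx <- function(lengths, x = 50, total_override = NULL) {
  if (!length(lengths)) stop("empty length set")
  if (any(lengths <= 0)) stop("lengths must be positive")
  if (x <= 0 || x >= 100) stop("x must lie in (0, 100)")
  total <- if (is.null(total_override)) sum(lengths) else total_override
  target <- x / 100 * total
  sorted <- sort(lengths, decreasing = TRUE)
  cum <- cumsum(sorted)
  if (target > cum[length(cum)])
    stop("x% of total exceeds the summed lengths provided")
  sorted[which(cum >= target)[1]]
}

#' Chromosome anchoring (mounting) ratio
#'
#' Percentage of the assembly placed into chromosome-scale sequences:
#' `100 * sum(chrom_lengths) / assembly_total`, rounded to one decimal.
#'
#' @param chrom_lengths lengths of the chromosome-scale sequences (bp).
#' @param assembly_total total assembly size (bp).
#' @return percentage, one decimal.
#' @export
anchoring_ratio <- function(chrom_lengths, assembly_total) {
  if (assembly_total <= 0) stop("assembly total must be positive")
  s <- sum(chrom_lengths)
  if (s > assembly_total)
    stop("chromosome lengths exceed the assembly total")
  round(100 * s / assembly_total, 1)
}

#' BUSCO completeness summary percentage
#'
#' `100 * complete / total`, one decimal. If single-copy and duplicated
#' counts are both supplied and disagree with the complete count, a warning
#' is raised and the complete count is used.
#'
#' @param counts named numeric vector or list with `complete` and `total`,
#'   optionally `single` and `duplicated`.
#' @return percentage complete, one decimal.
#' @export
busco_summary <- function(counts) {
  counts <- as.list(counts)
  if (is.null(counts$complete) || is.null(counts$total))
    stop("counts must include 'complete' and 'total'")
  if (counts$total <= 0) stop("total must be positive")
  if (!is.null(counts$single) && !is.null(counts$duplicated) &&
      counts$single + counts$duplicated != counts$complete)
    warning("single + duplicated != complete; using the complete count")
  round(100 * counts$complete / counts$total, 1)
}

#' Composition percentages over a common denominator
#'
#' `100 * part / denominator` per label, rounded to two decimals — the form
#' used for repeat-class and functional-annotation summary tables. Subtotal
#' lines (e.g. all LTR classes together) should be summed *before* calling,
#' so rounding happens once per reported line.
#'
#' @param parts named nonnegative numeric vector (bp or counts).
#' @param denominator positive total (bp or count).
#' @return named numeric vector of percentages, two decimals.
#' @export
composition_percentages <- function(parts, denominator) {
  if (denominator <= 0) stop("denominator must be positive")
  if (any(parts < 0)) stop("parts must be nonnegative")
  round(100 * parts / denominator, 2)
}

#' Published assembly-report tables bundled with the package
#'
#' Summary tables of the published chromosome-level *Prunus tenella*
#' assembly (Genome Warehouse accession GWHCBGA00000000), shipped as
#' plain-text TSVs: chromosome-scale scaffold lengths, assembly totals,
#' BUSCO counts, transposable-element class lengths, and functional
#' annotation counts. These are the desk-scale inputs for the report
#' arithmetic ([nxx()], [anchoring_ratio()], [busco_summary()],
#' [composition_percentages()]).
#'
#' @return named list of data.frames: `chromosomes`, `totals`, `busco`,
#'   `te_classes`, `annotation`.
#' @export
ptenella_assembly_data <- function() {
  dir <- system.file("extdata", package = "popgenscan")
  rd <- function(f) utils::read.table(file.path(dir, f), header = TRUE,
                                      sep = "\t", quote = "",
                                      stringsAsFactors = FALSE)
  list(chromosomes = rd("ptenella_chromosome_lengths.tsv"),
       totals = rd("ptenella_assembly_totals.tsv"),
       busco = rd("ptenella_busco.tsv"),
       te_classes = rd("ptenella_te_classes.tsv"),
       annotation = rd("ptenella_annotation_counts.tsv"))
}
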