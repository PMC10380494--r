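#' SNP quality filtering
#'
#' Applies the standard resequencing SNP filters in a fixed, documented order
#' so that each removed variant is attributed to the *first* rule it fails:
#' biallelic -> missingness -> minor-allele frequency -> Hardy-Weinberg exact
#' test. Retained variants are biallelic, have missing fraction
#' `<= missing_max`, pooled-cohort MAF strictly `> maf_min`, and HWE exact
#' p-value `>= hwe_alpha` (variants departing HWE at `p < hwe_alpha` are
#' removed; set `hwe_keep_low = TRUE` for the literal keep-low reading).
#'
#' @param gm a [geno_matrix()].
#' @param maf_min minor-allele-frequency threshold (pooled over all samples,
#'   non-missing genotypes only); retained variants satisfy MAF > `maf_min`.
#' @param missing_max maximum tolerated fraction of missing genotypes.
#' @param hwe_alpha HWE exact-test significance level.
#' @param biallelic_only drop multiallelic records first (flagged on read).
#' @param hwe_keep_low if `TRUE`, invert the HWE rule and *keep only* variants
#'   with p < `hwe_alpha` (non-standard; provided because study write-ups are
#'   sometimes worded this way).
#' @return list with elements `gm` (filtered [geno_matrix()]) and `report`
#'   (a `filter_report`).
#' @export
filter_variants <- function(gm, maf_min = 0.05, missing_max = 0.10,
                            hwe_alpha = 0.001, biallelic_only = TRUE,
                            hwe_keep_low = FALSE) {
  for (th in c(maf_min, missing_max, hwe_alpha))
    if (th < 0 || th > 1) stop("filter thresholds must lie in [0, 1]")
  nv <- n_variants(gm)
  fail <- rep(NA_character_, nv)   # first failed rule, NA = retained

  bial <- is_biallelic(gm)
  if (biallelic_only) fail[!bial] <- "non_biallelic"

  miss_frac <- colMeans(is.na(gm$geno))
  idx <- is.na(fail) & miss_frac > missing_max
  fail[idx] <- "missingness"

  n_ok <- colSums(!is.na(gm$geno))
  p_alt <- colSums(gm$geno, na.rm = TRUE) / (2 * pmax(n_ok, 1L))
  maf <- pmin(p_alt, 1 - p_alt)
  idx <- is.na(fail) & (n_ok == 0L | maf <= maf_min)
  fail[idx] <- "maf"

  todo <- which(is.na(fail))
  if (length(todo)) {
    hwe_p <- vapply(todo, function(k) {
      g <- gm$geno[, k]
      hwe_exact_test(sum(g == 0L, na.rm = TRUE), sum(g == 1L, na.rm = TRUE),
                     sum(g == 2L, na.rm = TRUE))
    }, numeric(1))
    bad <- if (hwe_keep_low) hwe_p >= hwe_alpha else hwe_p < hwe_alpha
    fail[todo[bad]] <- "hwe"
  }

  keep <- is.na(fail)
  report <- structure(list(
    n_input = nv,
    removed = c(non_biallelic = sum(fail == "non_biallelic", na.rm = TRUE),
                missingness = sum(fail == "missingness", na.rm = TRUE),
                maf = sum(fail == "maf", na.rm = TRUE),
                hwe = sum(fail == "hwe", na.rm = TRUE)),
    n_retained = sum(keep),
    thresholds = list(maf_min = maf_min, missing_max = missing_max,
                      hwe_alpha = hwe_alpha, biallelic_only = biallelic_only,
                      hwe_keep_low = hwe_keep_low)),
    class = "filter_report")
  list(gm = subset_variants(gm, keep), report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("filter_report: %d variants in, %d retained\n", x$n_input,
              x$n_retained))
  for (r in names(x$removed))
    cat(sprintf("  removed by %-14s %d\n", paste0(r, ":"), x$removed[[r]]))
  invisible(x)
}

#' @export
as.data.frame.filter_report <- function(x, ...) {
  data.frame(rule = c(names(x$removed), "retained"),
             n = c(unname(x$removed), x$n_retained))
}

#' Write a filter report as TSV
#' @param report a `filter_report` from [filter_variants()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_filter_report <- function(report, path) {
  utils::write.table(as.data.frame(report), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
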