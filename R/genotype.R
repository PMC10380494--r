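#' Diploid genotype matrix
#'
#' The central container of the package: diploid genotype codes for a set of
#' samples at a set of biallelic (or flagged multiallelic) SNPs. Codes count
#' alternate-allele copies: 0 (hom ref), 1 (het), 2 (hom alt), `NA` (missing).
#' When the matrix comes from one of the simulators the two phased haplotypes
#' are carried along; their per-entry sum always equals the genotype code.
#'
#' @param geno integer matrix, samples x variants, entries in \{0, 1, 2, NA\}.
#' @param chrom character vector of chromosome identifiers, one per variant.
#' @param pos integer vector of 1-based positions (VCF convention), strictly
#'   increasing within each chromosome.
#' @param ref,alt reference and alternate allele strings per variant. A
#'   comma-separated `alt` marks a multiallelic record, which is retained but
#'   flagged so that downstream filtering can attribute its removal.
#' @param samples character vector of sample identifiers (row names).
#' @param hap optional list of two 0/1 matrices (`h1`, `h2`) with the same
#'   shape as `geno`; required to sum to `geno` wherever `geno` is non-missing.
#' @param chrom_lengths optional named integer vector giving the physical
#'   length of each chromosome; used by windowing code. Defaults to the
#'   largest observed position per chromosome.
#'
#' @return An object of class `geno_matrix`.
#' @export
geno_matrix <- function(geno, chrom, pos, ref, alt, samples = rownames(geno),
                        hap = NULL, chrom_lengths = NULL) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  nv <- ncol(geno)
  if (is.null(samples)) samples <- paste0("S", seq_len(nrow(geno)))
  stopifnot(length(chrom) == nv, length(pos) == nv,
            length(ref) == nv, length(alt) == nv,
            length(samples) == nrow(geno))
  pos <- as.integer(pos)
  chrom <- as.character(chrom)
  bad <- geno[!is.na(geno)]
  if (length(bad) && !all(bad %in% 0:2))
    stop("genotype codes must be 0, 1, 2 or NA")
  for (ch in unique(chrom)) {
    p <- pos[chrom == ch]
    if (is.unsorted(p, strictly = TRUE))
      stop("positions must be strictly increasing within chromosome ", ch)
  }
  if (!is.null(hap)) {
    stopifnot(is.list(hap), length(hap) == 2)
    h1 <- hap[[1]]; h2 <- hap[[2]]
    storage.mode(h1) <- "integer"; storage.mode(h2) <- "integer"
    if (!identical(dim(h1), dim(geno)) || !identical(dim(h2), dim(geno)))
      stop("haplotype matrices must match the genotype matrix shape")
    s <- h1 + h2
    ok <- is.na(geno) | (s == geno)
    if (!all(ok, na.rm = TRUE))
      stop("phased haplotypes must sum to the genotype code at every called entry")
    hap <- list(h1 = h1, h2 = h2)
  }
  if (is.null(chrom_lengths)) {
    chrom_lengths <- vapply(split(pos, chrom), max, integer(1))
  } else {
    nm <- names(chrom_lengths)
    chrom_lengths <- as.integer(chrom_lengths)
    names(chrom_lengths) <- nm
  }
  rownames(geno) <- samples
  structure(list(geno = geno, chrom = chrom, pos = pos, ref = as.character(ref),
                 alt = as.character(alt), samples = as.character(samples),
                 hap = hap, chrom_lengths = chrom_lengths),
            class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("geno_matrix: %d samples x %d variants on %d chromosome(s)%s\n",
              n_samples(x), n_variants(x), length(unique(x$chrom)),
              if (is_phased(x)) " [phased]" else ""))
  miss <- mean(is.na(x$geno))
  cat(sprintf("  missingness %.2f%%; chrom: %s\n", 100 * miss,
              paste(utils::head(unique(x$chrom), 5), collapse = ", ")))
  invisible(x)
}

#' Number of samples / variants in a genotype matrix
#' @param gm a [geno_matrix()].
#' @return integer count.
#' @export
n_samples <- function(gm) nrow(gm$geno)

#' @rdname n_samples
#' @export
n_variants <- function(gm) ncol(gm$geno)

#' Does the matrix carry phased haplotypes?
#' @param gm a [geno_matrix()].
#' @return logical.
#' @export
is_phased <- function(gm) !is.null(gm$hap)

#' Is each variant biallelic?
#'
#' A variant is flagged multiallelic when its ALT field holds more than one
#' allele (comma-separated); such records are retained on read and removed by
#' [filter_variants()].
#' @param gm a [geno_matrix()].
#' @return logical vector, one per variant.
#' @export
is_biallelic <- function(gm) !grepl(",", gm$alt, fixed = TRUE)

#' Subset a genotype matrix by variant index or by sample id
#'
#' @param gm a [geno_matrix()].
#' @param idx integer or logical index over variants.
#' @return a new `geno_matrix`.
#' @export
subset_variants <- function(gm, idx) {
  geno_matrix(gm$geno[, idx, drop = FALSE], gm$chrom[idx], gm$pos[idx],
              gm$ref[idx], gm$alt[idx], gm$samples,
              hap = if (is_phased(gm))
                list(gm$hap$h1[, idx, drop = FALSE], gm$hap$h2[, idx, drop = FALSE]),
              chrom_lengths = gm$chrom_lengths)
}

#' @rdname subset_variants
#' @param ids character vector of sample identifiers (order preserved).
#' @export
subset_samples <- function(gm, ids) {
  miss <- setdiff(ids, gm$samples)
  if (length(miss))
    stop("unknown sample id(s): ", paste(miss, collapse = ", "))
  i <- match(ids, gm$samples)
  geno_matrix(gm$geno[i, , drop = FALSE], gm$chrom, gm$pos, gm$ref, gm$alt,
              gm$samples[i],
              hap = if (is_phased(gm))
                list(gm$hap$h1[i, , drop = FALSE], gm$hap$h2[i, , drop = FALSE]),
              chrom_lengths = gm$chrom_lengths)
}
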