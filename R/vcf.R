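#' Read a diploid GT-only VCF into a genotype matrix
#'
#' Parses a (plain-text) VCF 4.x file whose records carry diploid `GT` calls
#' and transcribes it into a [geno_matrix()]. Only the GT subfield is used.
#' Multiallelic records are kept but flagged (see [is_biallelic()]) so that
#' [filter_variants()] can attribute their removal rather than dropping them
#' silently. `./.` (or `.|.`) becomes a missing code. When *every* genotype in
#' the file is phased (`|` separator) the haplotypes are retained; any
#' unphased call drops phase for the whole matrix.
#'
#' @param path path to an uncompressed VCF file.
#' @param missing_policy how to treat half-calls such as `0/.`: `"missing"`
#'   (default) codes them missing; `"error"` raises an error.
#' @return a [geno_matrix()].
#' @export
read_vcf <- function(path, missing_policy = c("missing", "error")) {
  missing_policy <- match.arg(missing_policy)
  lines <- readLines(path)
  if (!length(lines)) stop("empty VCF file: ", path)
  hdr_i <- grep("^#CHROM\t", lines)
  if (!length(hdr_i)) stop("no #CHROM header line in ", path)
  hdr <- strsplit(lines[hdr_i[1]], "\t", fixed = TRUE)[[1]]
  if (length(hdr) < 10) stop("VCF has no sample columns: ", path)
  samples <- hdr[-(1:9)]
  body_i <- seq.int(hdr_i[1] + 1L, length(lines))
  body_i <- body_i[body_i <= length(lines) & !startsWith(lines[body_i], "#") &
                     nzchar(lines[body_i])]
  if (!length(body_i)) stop("VCF contains a header but no records: ", path)

  nv <- length(body_i)
  ns <- length(samples)
  chrom <- character(nv); pos <- integer(nv)
  ref <- character(nv); alt <- character(nv)
  geno <- matrix(NA_integer_, ns, nv)
  h1 <- matrix(NA_integer_, ns, nv); h2 <- matrix(NA_integer_, ns, nv)
  all_phased <- TRUE

  for (k in seq_len(nv)) {
    ln <- body_i[k]
    f <- strsplit(lines[ln], "\t", fixed = TRUE)[[1]]
    if (length(f) != length(hdr))
      stop("line ", ln, ": expected ", length(hdr), " fields, found ", length(f))
    chrom[k] <- f[1]
    pos[k] <- suppressWarnings(as.integer(f[2]))
    if (is.na(pos[k])) stop("line ", ln, ": POS is not an integer")
    ref[k] <- f[4]; alt[k] <- f[5]
    fmt <- strsplit(f[9], ":", fixed = TRUE)[[1]]
    gt_i <- match("GT", fmt)
    if (is.na(gt_i)) stop("line ", ln, ": FORMAT has no GT field")
    for (s in seq_len(ns)) {
      gt <- strsplit(f[9 + s], ":", fixed = TRUE)[[1]][gt_i]
      if (is.na(gt) || !nzchar(gt))
        stop("line ", ln, ": malformed GT field for sample ", samples[s])
      phased <- grepl("|", gt, fixed = TRUE)
      al <- strsplit(gt, "[/|]")[[1]]
      if (length(al) == 1L)
        stop("line ", ln, ": non-diploid GT '", gt, "' for sample ", samples[s])
      if (length(al) != 2L)
        stop("line ", ln, ": non-diploid GT '", gt, "' for sample ", samples[s])
      if (!all(al %in% c(".", "0", "1", "2", "3")))
        stop("line ", ln, ": malformed GT '", gt, "' for sample ", samples[s])
      if (any(al == ".")) {
        if (!all(al == ".") && missing_policy == "error")
          stop("line ", ln, ": half-called GT '", gt, "' for sample ", samples[s])
        # geno stays NA
      } else {
        a <- as.integer(al)
        # alt-allele dosage; any non-ref allele counts (multiallelics are
        # flagged for removal downstream, codes still land in 0..2)
        geno[s, k] <- sum(a > 0L)
        if (phased) { h1[s, k] <- as.integer(a[1] > 0L); h2[s, k] <- as.integer(a[2] > 0L) }
      }
      if (!phased) all_phased <- FALSE
    }
  }
  hap <- if (all_phased) list(h1, h2) else NULL
  geno_matrix(geno, chrom, pos, ref, alt, samples, hap = hap)
}

#' Write a genotype matrix as a VCF 4.2 file
#'
#' Emits a minimal GT-only VCF. Phased matrices are written with `|`
#' separators (haplotype order preserved); unphased matrices use `/` with the
#' conventional 0/0, 0/1, 1/1 coding. [read_vcf()] round-trips the result.
#'
#' @param gm a [geno_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path) {
  if (n_samples(gm) == 0L || n_variants(gm) == 0L)
    stop("refusing to write an empty cohort")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=popgenscan",
               paste0("##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">"),
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", gm$samples), collapse = "\t")), con)
  phased <- is_phased(gm)
  gt_chr <- if (phased) {
    m <- matrix(".|.", n_samples(gm), n_variants(gm))
    ok <- !is.na(gm$geno)
    m[ok] <- paste0(gm$hap$h1[ok], "|", gm$hap$h2[ok])
    m
  } else {
    m <- matrix("./.", n_samples(gm), n_variants(gm))
    m[!is.na(gm$geno) & gm$geno == 0L] <- "0/0"
    m[!is.na(gm$geno) & gm$geno == 1L] <- "0/1"
    m[!is.na(gm$geno) & gm$geno == 2L] <- "1/1"
    m
  }
  for (k in seq_len(n_variants(gm))) {
    writeLines(paste(c(gm$chrom[k], gm$pos[k], ".", gm$ref[k], gm$alt[k], ".",
                       "PASS", ".", "GT", gt_chr[, k]), collapse = "\t"), con)
  }
  invisible(path)
}
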