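make_vcf <- function(lines, path = tempfile(fileext = ".vcf")) {
  writeLines(lines, path)
  path
}

vcf_header <- function(samples) {
  c("##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
}

test_that("read_vcf transcribes records, missing calls and multiallelic flags", {
  p <- make_vcf(c(vcf_header(c("s1", "s2")),
                  "chr1\t100\t.\tA\tT\t.\tPASS\t.\tGT\t0/0\t0/1",
                  "chr1\t200\t.\tG\tC\t.\tPASS\t.\tGT\t1/1\t./.",
                  "chr1\t300\t.\tA\tT,G\t.\tPASS\t.\tGT\t0/1\t1/2"))
  gm <- read_vcf(p)
  expect_equal(n_samples(gm), 2L)
  expect_equal(n_variants(gm), 3L)
  expect_equal(gm$geno[, 1], c(s1 = 0L, s2 = 1L))
  expect_equal(gm$geno["s2", 2], c(s2 = NA_integer_))
  expect_equal(gm$pos, c(100L, 200L, 300L))
  expect_equal(is_biallelic(gm), c(TRUE, TRUE, FALSE))
  expect_false(is_phased(gm))
})

test_that("read_vcf keeps phase when (and only when) every call is phased", {
  p <- make_vcf(c(vcf_header("s1"),
                  "chr1\t10\t.\tA\tT\t.\t.\t.\tGT\t1|0",
                  "chr1\t20\t.\tA\tT\t.\t.\t.\tGT\t0|1"))
  gm <- read_vcf(p)
  expect_true(is_phased(gm))
  expect_equal(unname(gm$hap$h1[1, ]), c(1L, 0L))
  p2 <- make_vcf(c(vcf_header("s1"),
                   "chr1\t10\t.\tA\tT\t.\t.\t.\tGT\t1|0",
                   "chr1\t20\t.\tA\tT\t.\t.\t.\tGT\t0/1"))
  expect_false(is_phased(read_vcf(p2)))
})

test_that("read_vcf errors name the offending line", {
  expect_error(read_vcf(make_vcf(character(0))), "empty")
  expect_error(read_vcf(make_vcf(vcf_header("s1"))), "no records")
  p <- make_vcf(c(vcf_header("s1"), "chr1\t10\t.\tA\tT\t.\t.\t.\tGT\t0/1/1"))
  expect_error(read_vcf(p), "line 4.*non-diploid")
  p <- make_vcf(c(vcf_header("s1"), "chr1\t10\t.\tA\tT\t.\t.\t.\tGT\tx/y"))
  expect_error(read_vcf(p), "line 4.*malformed")
  p <- make_vcf(c(vcf_header("s1"), "chr1\t10\t.\tA\tT\t.\t.\t.\tDP\t13"))
  expect_error(read_vcf(p), "line 4.*no GT")
})

test_that("write_vcf / read_vcf round-trips genotypes, positions, alleles and phase", {
  co <- simulate_structured_cohort(cohort_design(n_snps = 80, n_per_pop = 4,
                                                 seed = 42))
  path <- tempfile(fileext = ".vcf")
  write_vcf(co$gm, path)
  back <- read_vcf(path)
  expect_identical(unname(back$geno), unname(co$gm$geno))
  expect_identical(back$pos, co$gm$pos)
  expect_identical(back$ref, co$gm$ref)
  expect_identical(back$alt, co$gm$alt)
  expect_identical(back$samples, co$gm$samples)
  expect_identical(unname(back$hap$h1), unname(co$gm$hap$h1))
})

test_that("an independent VCF parser (VariantAnnotation) reads our output identically", {
  co <- simulate_structured_cohort(cohort_design(n_snps = 40, n_per_pop = 3,
                                                 seed = 9))
  path <- tempfile(fileext = ".vcf")
  write_vcf(co$gm, path)
  v <- suppressWarnings(VariantAnnotation::readVcf(path))
  gt <- VariantAnnotation::geno(v)$GT
  dose <- matrix(vapply(strsplit(gt, "[|/]"),
                        function(a) sum(a == "1"), integer(1)),
                 nrow(gt), ncol(gt))
  expect_equal(unname(t(dose)), unname(co$gm$geno))
  expect_equal(unname(BiocGenerics::start(SummarizedExperiment::rowRanges(v))),
               co$gm$pos)
})

test_that("population map reading validates structure and duplicates", {
  p <- tempfile(fileext = ".tsv")
  writeLines(c("sample\tpopulation\tregion", "a\tP1\tR1", "b\tP1\tR1",
               "c\tP2\tR2"), p)
  pm <- read_population_map(p)
  expect_s3_class(pm, "pop_map")
  expect_equal(nrow(pm), 3L)
  writeLines(c("sample\tpopulation\tregion", "a\tP1\tR1", "a\tP2\tR2"), p)
  expect_error(read_population_map(p), "duplicated sample")
  # population mapped to two regions is inconsistent
  expect_error(pop_map(data.frame(sample = c("a", "b"),
                                  population = c("P1", "P1"),
                                  region = c("R1", "R2"))),
               "more than one region")
})

test_that("a map emulating the eight-population three-region design loads cleanly", {
  pops <- c(paste0("Yumin_", 1:3), paste0("Tuoli_", 1:4), "Tacheng_1")
  regions <- c(rep("Yumin", 3), rep("Tuoli", 4), "Tacheng")
  df <- data.frame(sample = paste0("s", 1:8), population = pops,
                   region = regions)
  p <- tempfile(fileext = ".tsv")
  utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
  pm <- read_population_map(p)
  expect_equal(length(unique(pm$population)), 8L)
  expect_equal(length(unique(pm$region)), 3L)
})

test_that("hwe_exact_test matches its closed cases and the enumeration oracle", {
  expect_equal(hwe_exact_test(5, 0, 0), 1)        # monomorphic
  expect_equal(hwe_exact_test(0, 0, 7), 1)
  expect_equal(hwe_exact_test(10, 21, 15), hwe_exact_test(15, 21, 10)) # symmetry
  # frozen from the enumeration oracle (41 ref / 51 alt allele copies)
  expect_equal(hwe_exact_test(10, 21, 15), 0.764547805033763, tolerance = 1e-12)
  expect_error(hwe_exact_test(0, 0, 0), "at least one")
  expect_error(hwe_exact_test(-1, 2, 0), "nonnegative")
  for (tab in list(c(3, 5, 2), c(0, 15, 0), c(12, 1, 9), c(6, 6, 6))) {
    expect_equal(hwe_exact_test(tab[1], tab[2], tab[3]),
                 oracle_hwe(tab[1], tab[2], tab[3]), tolerance = 1e-12)
  }
})

test_that("filter_variants attributes removals in rule order on a hand-built fixture", {
  n <- 15L
  v_tri <- c(rep(0L, 10), rep(1L, 5))                   # triallelic (alt T,G)
  v_miss <- c(rep(NA_integer_, 2), rep(1L, 8), rep(0L, 5))  # 2/15 missing
  v_rare <- c(1L, rep(0L, 14))                          # MAF 1/30 <= 0.05
  v_het <- rep(1L, n)                                   # HWE p = 2.1e-4
  v_ok1 <- c(rep(0L, 4), rep(1L, 8), rep(2L, 3))        # HWE p = 1
  v_ok2 <- c(rep(0L, 7), rep(1L, 6), rep(2L, 2))        # HWE p = 1
  gm <- toy_gm(list(v_tri, v_miss, v_rare, v_het, v_ok1, v_ok2),
               alt = c("T,G", "T", "T", "T", "T", "T"))
  out <- filter_variants(gm)
  expect_equal(n_variants(out$gm), 2L)
  expect_equal(out$gm$pos, c(500L, 600L))
  expect_equal(unname(out$report$removed),
               c(1L, 1L, 1L, 1L))
  expect_equal(out$report$n_input,
               sum(out$report$removed) + out$report$n_retained)
})

test_that("monomorphic input is removed entirely under the MAF rule", {
  gm <- toy_gm(list(rep(0L, 8), rep(2L, 8)))
  out <- filter_variants(gm)
  expect_equal(n_variants(out$gm), 0L)
  expect_equal(unname(out$report$removed["maf"]), 2L)
})

test_that("filtering is idempotent and retained variants satisfy all bounds", {
  co <- simulate_structured_cohort(cohort_design(n_snps = 2000, n_per_pop = 10,
                                                 seed = 5))
  # add some missingness so the rule is exercised
  set.seed(5)
  g <- co$gm$geno
  g[sample(length(g), length(g) %/% 50)] <- NA_integer_
  gm <- geno_matrix(g, co$gm$chrom, co$gm$pos, co$gm$ref, co$gm$alt,
                    co$gm$samples, chrom_lengths = co$gm$chrom_lengths)
  out <- filter_variants(gm)
  again <- filter_variants(out$gm)
  expect_equal(n_variants(again$gm), n_variants(out$gm))
  expect_equal(sum(again$report$removed), 0L)
  # every retained variant satisfies the documented regime
  st <- locus_allele_stats(out$gm, out$gm$samples)
  maf <- pmin(st$p_alt, 1 - st$p_alt)
  expect_true(all(maf > 0.05))
  expect_true(all(colMeans(is.na(out$gm$geno)) <= 0.10))
  hp <- vapply(seq_len(n_variants(out$gm)), function(k)
    hwe_exact_test(st$n_hom_ref[k], st$n_het[k], st$n_hom_alt[k]), numeric(1))
  expect_true(all(hp >= 0.001))
})

test_that("filter thresholds are validated and the keep-low flag inverts HWE", {
  gm <- toy_gm(list(c(rep(0L, 4), rep(1L, 8), rep(2L, 3))))
  expect_error(filter_variants(gm, maf_min = -0.1), "thresholds")
  v_het <- rep(1L, 15)
  gm2 <- toy_gm(list(v_het, c(rep(0L, 4), rep(1L, 8), rep(2L, 3))))
  inv <- filter_variants(gm2, hwe_keep_low = TRUE)
  expect_equal(gm2$pos[1], inv$gm$pos)  # only the HWE-departing variant kept
})
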