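phased_gm <- function(h1, h2, pos = NULL, chrom_len = NULL) {
  n <- ncol(h1)
  if (is.null(pos)) pos <- seq_len(n) * 100L
  if (is.null(chrom_len)) chrom_len <- max(pos)
  geno_matrix(h1 + h2, rep("chr1", n), pos, rep("A", n), rep("T", n),
              paste0("s", seq_len(nrow(h1))), hap = list(h1, h2),
              chrom_lengths = c(chr1 = chrom_len))
}

test_that("r2 hits its closed cases under both methods", {
  set.seed(3)
  h <- matrix(rbinom(20, 1, 0.5), 10, 2)
  # identical sites -> 1
  gm2 <- phased_gm(cbind(h[, 1], h[, 1]), cbind(h[, 2], h[, 2]))
  expect_equal(ld_r2(gm2, 1, 2, "haplotype"), 1)
  expect_equal(ld_r2(gm2, 1, 2, "genotype"), 1)
  # the four haplotypes 00/01/10/11 equally frequent -> 0
  h1 <- rbind(c(0L, 0L), c(1L, 0L))
  h2 <- rbind(c(0L, 1L), c(1L, 1L))
  gm3 <- phased_gm(h1, h2)
  expect_equal(ld_r2(gm3, 1, 2, "haplotype"), 0)
  # monomorphic site errors
  gm4 <- phased_gm(matrix(0L, 5, 2), matrix(0L, 5, 2))
  expect_error(ld_r2(gm4, 1, 2, "haplotype"), "monomorphic")
  expect_error(ld_r2(gm4, 1, 2, "genotype"), "monomorphic")
})

test_that("haplotype r2 equals a hand-tally oracle on a 10-sample toy", {
  set.seed(14)
  h1 <- matrix(rbinom(20, 1, 0.5), 10, 2)
  h2 <- matrix(rbinom(20, 1, 0.5), 10, 2)
  gm <- phased_gm(h1, h2)
  # oracle: tabulate the 20 haplotypes directly
  hapA <- c(h1[, 1], h2[, 1]); hapB <- c(h1[, 2], h2[, 2])
  p11 <- mean(hapA == 1 & hapB == 1)
  pA <- mean(hapA); pB <- mean(hapB)
  D <- p11 - pA * pB
  expect_equal(ld_r2(gm, 1, 2, "haplotype"),
               D^2 / (pA * (1 - pA) * pB * (1 - pB)))
  # the two measures agree reasonably but are not the same statistic
  expect_gte(ld_r2(gm, 1, 2, "genotype"), 0)
})

test_that("junction score with two SNPs per side is the mean of the four pair r2s", {
  set.seed(5)
  h1 <- matrix(rbinom(80, 1, 0.5), 20, 4)
  h2 <- matrix(rbinom(80, 1, 0.5), 20, 4)
  gm <- phased_gm(h1, h2, pos = c(900L, 950L, 1050L, 1100L), chrom_len = 2000L)
  sc <- junction_scenario("chr1", breakpoint = 1000, flank = 200,
                          chrom_length = 2000)
  got <- junction_ld_score(gm, sc, "current", max_pair_distance = 2000)
  pairs <- expand.grid(a = 1:2, b = 3:4)
  manual <- mean(mapply(function(a, b) ld_r2(gm, a, b, "haplotype"),
                        pairs$a, pairs$b))
  expect_equal(got$mean_r2, manual)
  expect_equal(got$n_pairs, 4L)
})

test_that("scores are invariant under sample permutation and allele swap", {
  haps <- simulate_linked_haplotypes(20, chrom_length = 400000,
                                     snp_density = 5e-4, seed = 31)
  sc <- junction_scenario("chr1", 200000, 100000, 400000)
  s0 <- junction_ld_score(haps, sc, "current")
  perm <- subset_samples(haps, sample(haps$samples))
  expect_equal(junction_ld_score(perm, sc, "current"), s0)
  flip <- geno_matrix(2L - haps$geno, haps$chrom, haps$pos, haps$alt,
                      haps$ref, haps$samples,
                      hap = list(1L - haps$hap$h1, 1L - haps$hap$h2),
                      chrom_lengths = haps$chrom_lengths)
  expect_equal(junction_ld_score(flip, sc, "current")$mean_r2, s0$mean_r2)
})

test_that("LD decays with distance in the founder-mosaic simulator", {
  haps <- simulate_linked_haplotypes(40, chrom_length = 600000,
                                     snp_density = 1e-3, recomb_rate = 1e-5,
                                     seed = 8)
  r2 <- popgenscan:::ld_r2_matrix(haps, seq_len(n_variants(haps)),
                                  seq_len(n_variants(haps)))
  d <- abs(outer(haps$pos, haps$pos, "-"))
  near <- r2[d > 0 & d <= 10000]
  far <- r2[d >= 200000 & d <= 300000]
  expect_gt(mean(near, na.rm = TRUE), mean(far, na.rm = TRUE))
  # monotone decay over distance bins (rank correlation)
  bins <- cut(d[upper.tri(d)], c(0, 2e4, 5e4, 1e5, 2e5, 3e5, 6e5))
  mean_by_bin <- tapply(r2[upper.tri(r2)], bins, mean, na.rm = TRUE)
  expect_lt(suppressWarnings(cor(seq_along(mean_by_bin), mean_by_bin,
                                 method = "spearman")), 0)
})

test_that("the true connection mode wins and label equivariance holds", {
  haps <- simulate_linked_haplotypes(50, chrom_length = 1200000,
                                     snp_density = 1e-3, seed = 100)
  cur <- make_junction_scenario(haps, 600000, 500000, "current")
  expect_equal(validate_junction(cur$gm, cur$scenario)$chosen, "current")
  alt <- make_junction_scenario(haps, 600000, 500000, "alternative")
  expect_equal(validate_junction(alt$gm, alt$scenario)$chosen, "alternative")
  # reversing the truth reverses the decision on the same haplotypes
  expect_error(make_junction_scenario(haps, 100000, 500000, "current"),
               "flank")
})

test_that("LD-free data scores the two modes equally and ties are undecided", {
  set.seed(60)
  L <- 300; n <- 40
  p <- runif(L, 0.2, 0.8)
  g <- vapply(p, function(pp) rbinom(n, 2L, pp), integer(n))
  gm <- geno_matrix(g, rep("chr1", L), sort(sample.int(1200000, L)),
                    rep("A", L), rep("T", L), paste0("s", 1:n),
                    chrom_lengths = c(chr1 = 1200000))
  sc <- junction_scenario("chr1", 600000, 500000, 1200000)
  s1 <- junction_ld_score(gm, sc, "current")$mean_r2
  s2 <- junction_ld_score(gm, sc, "alternative")$mean_r2
  expect_lt(abs(s1 - s2), 0.005)   # both near the 1/(2n) sampling floor
})

test_that("exactly tied scores are called undecided", {
  # two identical B-side columns: reversal permutes them onto each other, so
  # with an uncapped pair distance both modes score identically
  set.seed(2)
  a1 <- rbinom(30, 1, 0.5); a2 <- rbinom(30, 1, 0.5); b <- rbinom(30, 1, 0.5)
  h1 <- cbind(a1, a2, b, b); h2 <- cbind(rev(a1), rev(a2), rev(b), rev(b))
  gm <- phased_gm(h1, h2, pos = c(800L, 900L, 1100L, 1200L), chrom_len = 2000L)
  # flank = half the chromosome, so both modes see the same B-side SNP set
  sc <- junction_scenario("chr1", 1000, 1000, 2000)
  dec <- validate_junction(gm, sc, max_pair_distance = 2000)
  expect_equal(dec$chosen, "undecided")
  expect_equal(dec$ratio, 1)
})
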