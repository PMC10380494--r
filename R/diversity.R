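#' Per-locus allele statistics for a sample subset
#'
#' Shared counting kernel for every diversity index: per locus, the
#' alternate-allele frequency, the number of distinct alleles observed, the
#' genotype counts and the number of non-missing samples within the subset.
#'
#' @param gm a [geno_matrix()].
#' @param samples character vector of sample ids (non-empty subset of
#'   `gm$samples`).
#' @return data.frame with one row per locus: `chrom`, `pos`, `n` (non-missing
#'   samples), `p_alt`, `n_hom_ref`, `n_het`, `n_hom_alt`, `n_alleles`,
#'   `usable` (FALSE when every genotype is missing).
#' @export
locus_allele_stats <- function(gm, samples) {
  if (!length(samples)) stop("sample subset is empty")
  g <- subset_samples(gm, samples)$geno
  n <- colSums(!is.na(g))
  n_hom_ref <- colSums(g == 0L, na.rm = TRUE)
  n_het <- colSums(g == 1L, na.rm = TRUE)
  n_hom_alt <- colSums(g == 2L, na.rm = TRUE)
  p_alt <- ifelse(n > 0, colSums(g, na.rm = TRUE) / (2 * n), NA_real_)
  n_alleles <- ifelse(n == 0, NA_integer_,
                      (p_alt > 0) + (p_alt < 1))
  data.frame(chrom = gm$chrom, pos = gm$pos, n = n, p_alt = p_alt,
             n_hom_ref = n_hom_ref, n_het = n_het, n_hom_alt = n_hom_alt,
             n_alleles = as.integer(n_alleles), usable = n > 0)
}

#' Per-population genetic-diversity indices
#'
#' For each population the classical biallelic-SNP summary indices, each a
#' mean over usable loci:
#' * `Ho` — observed heterozygosity, the fraction of heterozygous calls;
#' * `He` — expected heterozygosity \eqn{1 - p^2 - q^2};
#' * `Nei` — Nei's unbiased gene diversity \eqn{2n/(2n-1) \cdot He} with `n`
#'   the non-missing sample count at the locus;
#' * `Shannon` — Shannon-Wiener index \eqn{-\sum_a p_a \ln p_a} (natural log,
#'   maximum \eqn{\ln 2} for biallelic loci);
#' * `allele_number` — observed distinct alleles (1 or 2).
#' Loci monomorphic within the population still count toward the means
#' (indices 0, allele number 1); loci with no called genotype are skipped.
#'
#' @param gm a filtered [geno_matrix()].
#' @param pmap a [pop_map()] covering every sample of `gm`.
#' @return data.frame, one row per population: `population`, `region`,
#'   `n_samples`, `n_loci`, `Ho`, `He`, `Nei`, `Shannon`, `allele_number`.
#' @export
population_diversity <- function(gm, pmap) {
  check_map_covers(gm, pmap)
  pops <- unique(pmap$population)
  rows <- lapply(pops, function(pop) {
    ids <- intersect(samples_of(pmap, pop), gm$samples)
    if (length(ids) < 2) stop("population ", pop, " has fewer than 2 samples")
    st <- locus_allele_stats(gm, ids)
    st <- st[st$usable, , drop = FALSE]
    p <- st$p_alt; q <- 1 - p
    he <- 1 - p^2 - q^2
    nei <- (2 * st$n) / (2 * st$n - 1) * he
    sh <- ifelse(p %in% c(0, 1), 0, -(p * log(p) + q * log(q)))
    data.frame(population = pop,
               region = pmap$region[match(pop, pmap$population)],
               n_samples = length(ids), n_loci = nrow(st),
               Ho = mean(st$n_het / st$n),
               He = mean(he), Nei = mean(nei), Shannon = mean(sh),
               allele_number = mean(st$n_alleles))
  })
  do.call(rbind, rows)
}

#' Sliding-window nucleotide diversity
#'
#' Windowed per-site pi for one population: within each window the sum over
#' SNPs of the unbiased per-site heterozygosity
#' \eqn{2\hat p(1-\hat p)\,2n/(2n-1)} (equal to the mean pairwise difference
#' among the \eqn{2n} sampled sequences), divided by the *window span* in bp.
#' Windows with fewer than `min_snps` callable SNPs get `NA`. Terminal
#' partial windows are emitted with `partial = TRUE`.
#'
#' @param gm a [geno_matrix()].
#' @param pmap a [pop_map()].
#' @param population population label to analyse.
#' @param window,step window size and step in bp (defaults 100 kb / 10 kb).
#' @param min_snps minimum callable SNPs for a window value.
#' @return a [window_track()] with statistic `"pi"`.
#' @export
windowed_pi <- function(gm, pmap, population, window = 100000L,
                        step = 10000L, min_snps = 10L) {
  check_map_covers(gm, pmap)
  ids <- intersect(samples_of(pmap, population), gm$samples)
  st <- locus_allele_stats(gm, ids)
  contrib <- ifelse(st$usable & st$n >= 1,
                    2 * st$p_alt * (1 - st$p_alt) * (2 * st$n) / (2 * st$n - 1),
                    0)
  grid <- make_windows(gm$chrom_lengths, window, step)
  ws <- window_sums(gm$chrom, gm$pos, contrib, st$usable, grid)
  value <- ifelse(ws$n < min_snps, NA_real_, ws$sum / (grid$end - grid$start))
  window_track(cbind(grid[c("chrom", "start", "end")],
                     data.frame(n_snps = ws$n, value = value,
                                partial = grid$partial)),
               stat = "pi", populations = population,
               window = window, step = step, min_snps = min_snps)
}
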