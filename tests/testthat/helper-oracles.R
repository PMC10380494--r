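# Independent brute-force oracles. These are deliberately written as direct
# transcriptions of definitions (log-factorials, pairwise tallies, scalar
# formula evaluation) and share no code with the package implementations
# they check.

# exact HWE p-value by direct enumeration of the conditional distribution
# P(n_het | n, allele counts) via log-factorials
oracle_hwe <- function(n_hom_ref, n_het, n_hom_alt) {
  n <- n_hom_ref + n_het + n_hom_alt
  na <- 2 * n_hom_ref + n_het
  nb <- 2 * n_hom_alt + n_het
  if (na == 0 || nb == 0) return(1)
  hets <- seq(min(na, nb) %% 2, min(na, nb), by = 2)
  logp <- vapply(hets, function(h) {
    hr <- (na - h) / 2; ha <- (nb - h) / 2
    lfactorial(n) - lfactorial(hr) - lfactorial(h) - lfactorial(ha) +
      h * log(2) + lfactorial(na) + lfactorial(nb) - lfactorial(2 * n)
  }, numeric(1))
  pr <- exp(logp - max(logp))
  pr <- pr / sum(pr)
  p_obs <- pr[hets == n_het]
  min(1, sum(pr[pr <= p_obs * (1 + 1e-9)]))
}

# mean pairwise difference per site over all haplotype pairs, summed over
# SNPs, divided by span; requires a fully called phased matrix
oracle_pi_pairwise <- function(gm, ids, span) {
  g <- subset_samples(gm, ids)
  H <- rbind(g$hap$h1, g$hap$h2)
  m <- nrow(H)
  tot <- 0
  for (i in seq_len(m - 1)) for (j in seq((i + 1), m))
    tot <- tot + sum(H[i, ] != H[j, ])
  tot / choose(m, 2) / span
}

# scalar transcription of the Weir & Cockerham (1984) two-population
# components for one site
oracle_wc_site <- function(n1, p1, h1, n2, p2, h2) {
  r <- 2
  nbar <- (n1 + n2) / 2
  nc <- (n1 + n2 - (n1^2 + n2^2) / (n1 + n2)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (n1 + n2)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (n1 + n2)
  a <- (nbar / nc) * (s2 - (1 / (nbar - 1)) *
                        (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
  b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
                                ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  c(a = a, b = b, c = cc)
}

# Hudson (Bhatia et al. 2013) ratio-of-sums Fst from per-population allele
# frequencies and haploid sample sizes
oracle_hudson_fst <- function(p1, p2, n1, n2) {
  m1 <- 2 * n1; m2 <- 2 * n2
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (m1 - 1) - p2 * (1 - p2) / (m2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  sum(num) / sum(den)
}

# order-statistic quantile with linear interpolation (R type 7), coded from
# the definition rather than via stats::quantile
oracle_quantile7 <- function(x, p) {
  x <- sort(x)
  h <- (length(x) - 1) * p + 1
  lo <- floor(h)
  x[lo] + (h - lo) * (x[min(lo + 1, length(x))] - x[lo])
}

# small hand-buildable genotype matrix; columns given as a list of per-variant
# genotype vectors
toy_gm <- function(cols, pos = NULL, chrom = "chr1", alt = NULL) {
  g <- do.call(cbind, cols)
  nv <- ncol(g)
  if (is.null(pos)) pos <- seq_len(nv) * 100L
  if (is.null(alt)) alt <- rep("T", nv)
  geno_matrix(g, rep(chrom, nv), pos, rep("A", nv), alt,
              samples = paste0("s", seq_len(nrow(g))))
}
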