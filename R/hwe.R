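#' Exact test of Hardy-Weinberg equilibrium
#'
#' Two-sided exact conditional test on the heterozygote count: conditioning on
#' the observed allele counts, the p-value sums the probabilities of all
#' heterozygote counts whose conditional probability does not exceed that of
#' the observed table. This is the standard genotyping-QC formulation used by
#' SNP pipelines (not the mid-p variant). Probabilities are computed with the
#' usual two-step recurrence over heterozygote counts of the same parity as
#' the minor-allele count.
#'
#' A relative tolerance of `1e-9` is used when comparing table probabilities,
#' so tables tied with the observed one (e.g. mirror-symmetric counts) are
#' always included regardless of floating-point evaluation order.
#'
#' @param n_hom_ref,n_het,n_hom_alt nonnegative genotype counts (hom ref,
#'   het, hom alt). At least one individual in total.
#' @return the exact p-value in \[0, 1\]. `1` when one allele is absent
#'   (single possible table).
#' @export
hwe_exact_test <- function(n_hom_ref, n_het, n_hom_alt) {
  counts <- c(n_hom_ref, n_het, n_hom_alt)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("genotype counts must be nonnegative integers")
  n <- sum(counts)
  if (n == 0L) stop("at least one individual is required")
  na <- 2 * n_hom_ref + n_het   # ref allele copies
  nb <- 2 * n_hom_alt + n_het   # alt allele copies
  if (na == 0L || nb == 0L) return(1)

  rare <- min(na, nb)
  hets <- seq.int(rare %% 2L, rare, by = 2L)    # feasible het counts
  # unnormalized probabilities by recurrence from the largest het count:
  # P(h-2)/P(h) = h*(h-1) / (4*(nAA(h-2... ) worked as forward ratio below
  np <- length(hets)
  pr <- numeric(np)
  pr[np] <- 1
  if (np > 1) {
    for (i in seq.int(np, 2L)) {
      h <- hets[i]
      hom_r <- (na - h) / 2   # hom-ref count at this het count
      hom_a <- (nb - h) / 2
      # ratio P(h-2)/P(h)
      pr[i - 1L] <- pr[i] * h * (h - 1) / (4 * (hom_r + 1) * (hom_a + 1))
    }
  }
  pr <- pr / sum(pr)
  p_obs <- pr[match(n_het, hets)]
  if (is.na(p_obs)) stop("heterozygote count inconsistent with allele counts")
  min(1, sum(pr[pr <= p_obs * (1 + 1e-9)]))
}
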