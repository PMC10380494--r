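#' Per-site Weir-Cockerham Fst variance components
#'
#' Computes the Weir & Cockerham (1984) variance components per SNP for two
#' (or, internally, more) groups of samples: `a` (among-population), `b`
#' (among individuals within populations) and `c` (within individuals). The
#' per-site estimator is theta = a/(a+b+c); genome-wide and windowed values
#' aggregate as a ratio of sums. Sites where either group has fewer than two
#' non-missing genotypes are flagged unusable and never enter sums.
#'
#' @param gm a [geno_matrix()].
#' @param popA,popB disjoint character vectors of sample ids.
#' @return an `fst_components` data.frame: `chrom`, `pos`, `a`, `b`, `c`,
#'   `theta` (per-site ratio, NA when a+b+c = 0) and `usable`.
#' @export
fst_site_components <- function(gm, popA, popB) {
  if (length(intersect(popA, popB)))
    stop("sample subsets overlap: ", paste(intersect(popA, popB), collapse = ", "))
  comp <- wc_components(list(locus_allele_stats(gm, popA),
                             locus_allele_stats(gm, popB)))
  out <- data.frame(chrom = gm$chrom, pos = gm$pos, a = comp$a, b = comp$b,
                    c = comp$c, theta = comp$theta, usable = comp$usable)
  class(out) <- c("fst_components", "data.frame")
  out
}

# Weir & Cockerham (1984) components for r >= 2 groups, vectorized over
# sites. stats_list: per group, the locus_allele_stats() frame.
wc_components <- function(stats_list) {
  r <- length(stats_list)
  n <- vapply(stats_list, function(s) s$n, numeric(nrow(stats_list[[1]])))
  p <- vapply(stats_list, function(s) s$p_alt, numeric(nrow(stats_list[[1]])))
  h <- vapply(stats_list, function(s) ifelse(s$n > 0, s$n_het / s$n, NA_real_),
              numeric(nrow(stats_list[[1]])))
  if (is.null(dim(n))) { n <- rbind(n); p <- rbind(p); h <- rbind(h) }
  usable <- rowSums(n >= 2) == r
  nbar <- rowMeans(n)
  sum_n <- rowSums(n)
  nc <- (sum_n - rowSums(n^2) / sum_n) / (r - 1)
  pbar <- rowSums(n * p) / sum_n
  s2 <- rowSums(n * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- rowSums(n * h) / sum_n
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - ((r - 1) / r) * s2 - ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  a[!usable] <- NA_real_; b[!usable] <- NA_real_; cc[!usable] <- NA_real_
  den <- a + b + cc
  theta <- ifelse(usable & den > 0, a / den, NA_real_)
  list(a = a, b = b, c = cc, theta = theta, usable = usable)
}

#' Windowed Fst from per-site components
#'
#' Ratio-of-sums aggregation: each window's value is
#' \eqn{\sum a / \sum (a+b+c)} over its usable SNPs; windows with fewer than
#' `min_snps` usable SNPs get `NA`. Small negative values are reported as
#' computed (never clamped).
#'
#' @param components an `fst_components` frame from [fst_site_components()].
#' @param chrom_lengths named lengths of the chromosomes (defaults to the
#'   largest SNP position per chromosome).
#' @param window,step,min_snps windowing parameters (defaults 100 kb / 10 kb
#'   / 10).
#' @return a [window_track()] with statistic `"fst"`.
#' @export
fst_windowed <- function(components, window = 100000L, step = 10000L,
                         min_snps = 10L, chrom_lengths = NULL) {
  if (is.null(chrom_lengths))
    chrom_lengths <- vapply(split(components$pos, components$chrom), max,
                            numeric(1))
  grid <- make_windows(chrom_lengths, window, step)
  ok <- components$usable & !is.na(components$a)
  num <- ifelse(ok, components$a, 0)
  den <- ifelse(ok, components$a + components$b + components$c, 0)
  ws_num <- window_sums(components$chrom, components$pos, num, ok, grid)
  ws_den <- window_sums(components$chrom, components$pos, den, ok, grid)
  value <- ifelse(ws_num$n >= min_snps & ws_den$sum > 0,
                  ws_num$sum / ws_den$sum, NA_real_)
  window_track(cbind(grid[c("chrom", "start", "end")],
                     data.frame(n_snps = ws_num$n, value = value,
                                partial = grid$partial)),
               stat = "fst", populations = NA_character_,
               window = window, step = step, min_snps = min_snps)
}

#' Genome-wide pairwise Fst matrix
#'
#' All pairwise Weir-Cockerham Fst values between populations (or regions),
#' each the genome-wide ratio of sums over usable SNPs. The matrix is
#' symmetric with a zero diagonal; small negative estimates are kept.
#'
#' @param gm a [geno_matrix()].
#' @param pmap a [pop_map()].
#' @param level `"population"` or `"region"`.
#' @return symmetric numeric matrix with group labels as dimnames.
#' @export
pairwise_fst <- function(gm, pmap, level = c("population", "region")) {
  level <- match.arg(level)
  check_map_covers(gm, pmap)
  groups <- unique(pmap[[level]])
  if (length(groups) < 2) stop("need at least 2 groups at level ", level)
  sizes <- vapply(groups, function(g)
    length(intersect(samples_of(pmap, g, level), gm$samples)), integer(1))
  if (any(sizes < 2))
    stop("group(s) with fewer than 2 samples: ",
         paste(groups[sizes < 2], collapse = ", "))
  m <- matrix(0, length(groups), length(groups),
              dimnames = list(groups, groups))
  for (i in seq_along(groups)) for (j in seq_len(i - 1L)) {
    comp <- fst_site_components(gm,
                                intersect(samples_of(pmap, groups[i], level), gm$samples),
                                intersect(samples_of(pmap, groups[j], level), gm$samples))
    ok <- comp$usable & !is.na(comp$a)
    m[i, j] <- m[j, i] <-
      sum(comp$a[ok]) / sum((comp$a + comp$b + comp$c)[ok])
  }
  m
}
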