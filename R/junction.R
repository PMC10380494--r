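#' Pairwise linkage disequilibrium r-squared
#'
#' LD between two SNPs, either from phased haplotypes
#' (\eqn{r^2 = D^2/(p_i q_i p_j q_j)} with D the haplotype-frequency
#' covariance) or as the genotype-composite measure, the squared Pearson
#' correlation of genotype dosages (Rogers-Huff style). `method = "auto"`
#' uses haplotypes when the matrix is phased.
#'
#' @param gm a [geno_matrix()].
#' @param site_i,site_j variant indices (columns of `gm`).
#' @param method `"auto"`, `"haplotype"` or `"genotype"`.
#' @return r-squared in \[0, 1\].
#' @export
ld_r2 <- function(gm, site_i, site_j, method = c("auto", "haplotype", "genotype")) {
  method <- match.arg(method)
  if (method == "auto") method <- if (is_phased(gm)) "haplotype" else "genotype"
  if (method == "haplotype") {
    if (!is_phased(gm)) stop("matrix is not phased; use method = 'genotype'")
    keep <- !is.na(gm$geno[, site_i]) & !is.na(gm$geno[, site_j])
    if (sum(keep) < 2) stop("fewer than 2 samples called at both sites")
    hi <- c(gm$hap$h1[keep, site_i], gm$hap$h2[keep, site_i])
    hj <- c(gm$hap$h1[keep, site_j], gm$hap$h2[keep, site_j])
    pi <- mean(hi); pj <- mean(hj)
    if (pi %in% c(0, 1) || pj %in% c(0, 1))
      stop("monomorphic site: r-squared undefined")
    D <- mean(hi * hj) - pi * pj
    D^2 / (pi * (1 - pi) * pj * (1 - pj))
  } else {
    gi <- gm$geno[, site_i]; gj <- gm$geno[, site_j]
    keep <- !is.na(gi) & !is.na(gj)
    if (sum(keep) < 2) stop("fewer than 2 samples called at both sites")
    if (stats::sd(gi[keep]) == 0 || stats::sd(gj[keep]) == 0)
      stop("monomorphic site: r-squared undefined")
    stats::cor(gi[keep], gj[keep])^2
  }
}

#' Describe a two-contig junction and its two connection modes
#'
#' A chromosome assembled from two contigs joined at `breakpoint` admits two
#' connection modes: `"current"` (the B-side contig as assembled) and
#' `"alternative"` (the B-side contig reversed before joining). The
#' alternative mode remaps every B-side position `p > breakpoint` to
#' `breakpoint + (chrom_length - p) + 1`, i.e. the distal end of the
#' chromosome becomes adjacent to the junction.
#'
#' @param chrom chromosome identifier.
#' @param breakpoint 1-based position of the contig join.
#' @param flank flank length in bp scored on each side (default 500 kb).
#' @param chrom_length total chromosome length in bp.
#' @return a `junction_scenario` list.
#' @export
junction_scenario <- function(chrom, breakpoint, flank = 500000L, chrom_length) {
  breakpoint <- as.numeric(breakpoint); flank <- as.numeric(flank)
  chrom_length <- as.numeric(chrom_length)
  if (breakpoint < flank || chrom_length - breakpoint < flank)
    stop("breakpoint must be at least one flank length from both chromosome ends")
  structure(list(chrom = chrom, breakpoint = breakpoint, flank = flank,
                 chrom_length = chrom_length,
                 modes = c("current", "alternative")),
            class = "junction_scenario")
}

# position remapping of the B side under a connection mode
remap_positions <- function(scenario, pos, mode) {
  b <- pos > scenario$breakpoint
  out <- as.numeric(pos)
  if (mode == "alternative")
    out[b] <- scenario$breakpoint + (scenario$chrom_length - pos[b]) + 1
  else if (mode != "current")
    stop("unknown connection mode: ", mode)
  out
}

# r^2 matrix between two column sets, NA where undefined
ld_r2_matrix <- function(gm, idx_a, idx_b) {
  if (is_phased(gm) && !anyNA(gm$geno)) {
    H <- rbind(gm$hap$h1, gm$hap$h2)
    ha <- H[, idx_a, drop = FALSE]; hb <- H[, idx_b, drop = FALSE]
    m <- nrow(H)
    pa <- colMeans(ha); pb <- colMeans(hb)
    p11 <- crossprod(ha, hb) / m
    D <- p11 - outer(pa, pb)
    den <- outer(pa * (1 - pa), pb * (1 - pb))
    r2 <- D^2 / den
    r2[den == 0] <- NA_real_
    r2
  } else {
    r2 <- suppressWarnings(
      stats::cor(gm$geno[, idx_a, drop = FALSE], gm$geno[, idx_b, drop = FALSE],
                 use = "pairwise.complete.obs"))^2
    r2
  }
}

#' Mean cross-junction LD under one connection mode
#'
#' Scores a connection mode by the unweighted mean r-squared over all SNP
#' pairs with one SNP in the flank upstream of the breakpoint and one in the
#' flank downstream of it *under that mode's coordinates*, with inter-SNP
#' distance at most `max_pair_distance`. The better-supported mode places
#' truly nearby (high-LD) SNPs across the junction.
#'
#' @param gm a [geno_matrix()].
#' @param scenario a [junction_scenario()].
#' @param mode `"current"` or `"alternative"`.
#' @param max_pair_distance pair distance cap in bp (default: the flank).
#' @param method LD method, see [ld_r2()].
#' @return list with `mean_r2` and `n_pairs`.
#' @export
junction_ld_score <- function(gm, scenario, mode,
                              max_pair_distance = scenario$flank,
                              method = c("auto", "haplotype", "genotype")) {
  method <- match.arg(method)
  on_chrom <- gm$chrom == scenario$chrom
  pos <- remap_positions(scenario, gm$pos, mode)
  a_idx <- which(on_chrom & pos > scenario$breakpoint - scenario$flank &
                   pos <= scenario$breakpoint)
  b_idx <- which(on_chrom & pos > scenario$breakpoint &
                   pos <= scenario$breakpoint + scenario$flank)
  if (!length(a_idx) || !length(b_idx))
    stop("no usable cross-junction SNP pairs under mode ", mode)
  gm2 <- gm
  if (method == "genotype") gm2$hap <- NULL
  r2 <- ld_r2_matrix(gm2, a_idx, b_idx)
  dist <- abs(outer(pos[a_idx], pos[b_idx], "-"))
  use <- dist <= max_pair_distance & !is.na(r2)
  if (!any(use)) stop("no usable cross-junction SNP pairs under mode ", mode)
  list(mean_r2 = mean(r2[use]), n_pairs = sum(use))
}

#' Choose the better-supported connection mode by cross-junction LD
#'
#' Scores both connection modes with [junction_ld_score()] and picks the one
#' with the higher mean r-squared; relative score differences below `tol`
#' yield `"undecided"`.
#'
#' @param gm a [geno_matrix()].
#' @param scenario a [junction_scenario()].
#' @param max_pair_distance pair distance cap in bp (default: the flank).
#' @param method LD method, see [ld_r2()].
#' @param tol relative tie tolerance (default 1e-6).
#' @return a `junction_decision`: list with `scores` (named per mode),
#'   `n_pairs`, `chosen`, `ratio` (score current / score alternative).
#' @export
validate_junction <- function(gm, scenario,
                              max_pair_distance = scenario$flank,
                              method = c("auto", "haplotype", "genotype"),
                              tol = 1e-6) {
  method <- match.arg(method)
  sc <- lapply(scenario$modes, function(m)
    junction_ld_score(gm, scenario, m, max_pair_distance, method))
  scores <- vapply(sc, `[[`, numeric(1), "mean_r2")
  n_pairs <- vapply(sc, `[[`, numeric(1), "n_pairs")
  names(scores) <- names(n_pairs) <- scenario$modes
  rel <- abs(diff(scores)) / max(abs(scores))
  chosen <- if (is.finite(rel) && rel < tol) "undecided"
            else scenario$modes[which.max(scores)]
  structure(list(scores = scores, n_pairs = n_pairs, chosen = chosen,
                 ratio = scores[["current"]] / scores[["alternative"]]),
            class = "junction_decision")
}

#' @export
print.junction_decision <- function(x, ...) {
  cat(sprintf("junction_decision: chosen mode '%s'\n", x$chosen))
  for (m in names(x$scores))
    cat(sprintf("  %-12s mean r2 = %.5f over %d pairs\n", m, x$scores[[m]],
                x$n_pairs[[m]]))
  invisible(x)
}
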