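#' Cohort design for the hierarchical Balding-Nichols simulator
#'
#' Describes a multi-region sampling design: regions, subpopulations per
#' region, diploid samples per subpopulation, and the two structure
#' parameters of the hierarchical Balding-Nichols model (expected Fst between
#' regions and between subpopulations within a region). Defaults emulate a
#' three-county, eight-population wild-almond survey: 3 + 4 + 1
#' subpopulations with 15-18 samples each, strong between-region
#' differentiation and weak within-region differentiation.
#'
#' @param regions named integer vector: subpopulations per region.
#' @param n_per_pop diploid samples per subpopulation (recycled across the
#'   populations in order).
#' @param f_region expected region-level Fst (default 0.25).
#' @param f_local expected within-region, between-population Fst
#'   (default 0.07).
#' @param n_snps number of SNPs.
#' @param chrom_length chromosome length in bp (single simulated chromosome).
#' @param p_anc_range range of the uniform ancestral allele-frequency
#'   distribution (default \[0.05, 0.95\], keeping most sites past a 5% MAF
#'   filter).
#' @param seed RNG seed.
#' @return a `cohort_design` list.
#' @export
cohort_design <- function(regions = c(Yumin = 3L, Tuoli = 4L, Tacheng = 1L),
                          n_per_pop = c(15L, 16L, 17L, 18L),
                          f_region = 0.25, f_local = 0.07,
                          n_snps = 20000L, chrom_length = 10000000L,
                          p_anc_range = c(0.05, 0.95), seed = 1L) {
  if (f_region <= 0 || f_region >= 1 || f_local <= 0 || f_local >= 1)
    stop("F values must lie strictly between 0 and 1")
  n_pops <- sum(regions)
  sizes <- rep_len(n_per_pop, n_pops)
  if (any(sizes < 2)) stop("sample sizes must be >= 2")
  structure(list(regions = regions, n_per_pop = sizes, f_region = f_region,
                 f_local = f_local, n_snps = as.integer(n_snps),
                 chrom_length = as.integer(chrom_length),
                 p_anc_range = p_anc_range, seed = as.integer(seed)),
            class = "cohort_design")
}

# Balding-Nichols draw: Beta with mean p and variance F p (1-p)
rbn <- function(p, f) {
  x <- stats::rbeta(length(p), p * (1 - f) / f, (1 - p) * (1 - f) / f)
  pmin(pmax(x, 1e-9), 1 - 1e-9)
}

#' Simulate a structured cohort under the hierarchical Balding-Nichols model
#'
#' Ancestral frequencies are uniform on the design's range; each region draws
#' its frequency from a Beta with mean p and variance `f_region * p(1-p)`;
#' each subpopulation draws around its region value with `f_local`; diploid
#' genotypes are two independent Bernoulli haplotypes per sample (so
#' populations are internally in Hardy-Weinberg proportions and phase is
#' carried). Deterministic given the design (including its seed). The model
#' generates no linkage disequilibrium by construction; LD testing uses
#' [simulate_linked_haplotypes()].
#'
#' @param design a [cohort_design()].
#' @return list with `gm` (phased [geno_matrix()]), `pmap` ([pop_map()]) and
#'   `truth` (generating parameters, per-population frequencies, injected
#'   sweep windows — empty here).
#' @export
simulate_structured_cohort <- function(design) {
  stopifnot(inherits(design, "cohort_design"))
  set.seed(design$seed)
  L <- design$n_snps
  pos <- sort(sample.int(design$chrom_length, L))
  p_anc <- stats::runif(L, design$p_anc_range[1], design$p_anc_range[2])

  pops <- character(0); pop_region <- character(0)
  for (rg in names(design$regions))
    for (k in seq_len(design$regions[[rg]])) {
      pops <- c(pops, paste0(rg, "_", k)); pop_region <- c(pop_region, rg)
    }
  p_region <- lapply(names(design$regions), function(rg) rbn(p_anc, design$f_region))
  names(p_region) <- names(design$regions)
  p_pop <- lapply(seq_along(pops), function(i)
    rbn(p_region[[pop_region[i]]], design$f_local))
  names(p_pop) <- pops

  n_tot <- sum(design$n_per_pop)
  h1 <- matrix(0L, n_tot, L); h2 <- matrix(0L, n_tot, L)
  samples <- character(n_tot); s_pop <- character(n_tot)
  row <- 0L
  for (i in seq_along(pops)) {
    for (s in seq_len(design$n_per_pop[i])) {
      row <- row + 1L
      h1[row, ] <- stats::rbinom(L, 1L, p_pop[[i]])
      h2[row, ] <- stats::rbinom(L, 1L, p_pop[[i]])
      samples[row] <- sprintf("%s_s%02d", pops[i], s)
      s_pop[row] <- pops[i]
    }
  }
  rownames(h1) <- samples
  gm <- geno_matrix(h1 + h2, rep("chr1", L), pos,
                    ref = rep("A", L), alt = rep("T", L), samples = samples,
                    hap = list(h1, h2),
                    chrom_lengths = c(chr1 = design$chrom_length))
  pmap <- pop_map(data.frame(sample = samples, population = s_pop,
                             region = pop_region[match(s_pop, pops)]))
  truth <- list(design = design, pop_freqs = do.call(rbind, p_pop),
                sweep_windows = data.frame(chrom = character(0),
                                           start = integer(0), end = integer(0),
                                           target = character(0),
                                           strength = numeric(0)),
                true_mode = NA_character_)
  list(gm = gm, pmap = pmap, truth = truth)
}

#' Inject sweep-like signals into a simulated cohort
#'
#' Within the listed windows the target population's allele frequencies are
#' pushed toward the nearest fixation point
#' (`p' = p + s(1-p)` when `p >= 0.5`, `p' = p(1-s)` otherwise) and that
#' population's genotypes at those SNPs are redrawn, raising local Fst and
#' depressing local pi in the target population. `strength = 0` returns the
#' input unchanged. Genotypes outside the windows are untouched.
#'
#' @param cohort list from [simulate_structured_cohort()] (`gm`, `pmap`,
#'   `truth`).
#' @param windows data.frame with `chrom`, `start`, `end` (0-based half-open,
#'   non-overlapping).
#' @param target_pop population label whose frequencies are shifted.
#' @param strength frequency-shift parameter in \[0, 1\].
#' @param seed optional seed for the redraw (default: continue the current
#'   RNG stream).
#' @return the cohort with modified `gm` and updated `truth$sweep_windows`.
#' @export
inject_sweep_signal <- function(cohort, windows, target_pop, strength,
                                seed = NULL) {
  stopifnot(strength >= 0, strength <= 1)
  if (strength == 0) return(cohort)
  if (!is.null(seed)) set.seed(seed)
  w <- windows[order(windows$chrom, windows$start), , drop = FALSE]
  if (nrow(w) > 1) {
    same <- w$chrom[-1] == w$chrom[-nrow(w)]
    if (any(same & w$start[-1] < w$end[-nrow(w)]))
      stop("injected windows overlap")
  }
  gm <- cohort$gm
  ids <- samples_of(cohort$pmap, target_pop)
  rows <- match(ids, gm$samples)
  pop_i <- match(target_pop, rownames(cohort$truth$pop_freqs))
  if (is.na(pop_i)) stop("unknown target population: ", target_pop)
  in_win <- rep(FALSE, n_variants(gm))
  for (k in seq_len(nrow(w)))
    in_win <- in_win | (gm$chrom == w$chrom[k] & (gm$pos - 1L) >= w$start[k] &
                          (gm$pos - 1L) < w$end[k])
  snps <- which(in_win)
  p <- cohort$truth$pop_freqs[pop_i, snps]
  p_new <- ifelse(p >= 0.5, p + strength * (1 - p), p * (1 - strength))
  for (j in seq_along(snps)) {
    a1 <- stats::rbinom(length(rows), 1L, p_new[j])
    a2 <- stats::rbinom(length(rows), 1L, p_new[j])
    gm$hap$h1[rows, snps[j]] <- a1
    gm$hap$h2[rows, snps[j]] <- a2
    gm$geno[rows, snps[j]] <- a1 + a2
  }
  cohort$gm <- gm
  cohort$truth$pop_freqs[pop_i, snps] <- p_new
  cohort$truth$sweep_windows <- rbind(
    cohort$truth$sweep_windows,
    data.frame(chrom = w$chrom, start = w$start, end = w$end,
               target = target_pop, strength = strength))
  cohort
}

#' Simulate phased haplotypes with distance-decaying LD
#'
#' A founder-mosaic model: `founder_count` founder haplotypes are drawn
#' site-wise (frequencies uniform on \[0.1, 0.9\]); each sample haplotype
#' copies a founder and switches to a random founder at crossover points laid
#' down as a Poisson process of rate `recomb_rate` per bp. Two sites at
#' distance d share a founder block with probability `exp(-recomb_rate * d)`,
#' so expected r-squared decays with distance at scale `1/recomb_rate`
#' toward the founder-pool baseline.
#'
#' @param n_samples diploid sample count.
#' @param chrom_length chromosome length in bp.
#' @param snp_density SNPs per bp (default 5e-4, one per 2 kb).
#' @param founder_count founder haplotypes (>= 2; default 20).
#' @param recomb_rate crossovers per bp per copied haplotype (default 1e-5,
#'   i.e. 100 kb decay scale).
#' @param seed RNG seed.
#' @return a phased [geno_matrix()] on chromosome `"chr1"`.
#' @export
simulate_linked_haplotypes <- function(n_samples, chrom_length = 2000000L,
                                       snp_density = 5e-4, founder_count = 20L,
                                       recomb_rate = 1e-5, seed = 1L) {
  if (founder_count < 2) stop("founder_count must be >= 2")
  set.seed(seed)
  L <- max(2L, round(chrom_length * snp_density))
  pos <- sort(sample.int(chrom_length, L))
  founders <- matrix(stats::rbinom(founder_count * L, 1L,
                                   rep(stats::runif(L, 0.1, 0.9),
                                       each = founder_count)),
                     founder_count, L)
  n_hap <- 2L * n_samples
  haps <- matrix(0L, n_hap, L)
  for (hh in seq_len(n_hap)) {
    n_x <- stats::rpois(1, recomb_rate * chrom_length)
    bp <- sort(stats::runif(n_x, 0, chrom_length))
    block <- findInterval(pos, bp) + 1L
    donors <- sample.int(founder_count, n_x + 1L, replace = TRUE)
    haps[hh, ] <- founders[cbind(donors[block], seq_len(L))]
  }
  h1 <- haps[seq_len(n_samples) * 2L - 1L, , drop = FALSE]
  h2 <- haps[seq_len(n_samples) * 2L, , drop = FALSE]
  samples <- sprintf("S%03d", seq_len(n_samples))
  rownames(h1) <- samples
  geno_matrix(h1 + h2, rep("chr1", L), pos, ref = rep("A", L),
              alt = rep("T", L), samples = samples, hap = list(h1, h2),
              chrom_lengths = c(chr1 = as.integer(chrom_length)))
}

#' Build an observed assembly around a junction with a known true mode
#'
#' Takes a contiguously simulated chromosome (the biological truth), a
#' breakpoint and a flank, and returns the matrix *as observed in the
#' assembly under test*: identical to the truth when `true_mode` is
#' `"current"`, or with the B-side contig's coordinates reversed when
#' `true_mode` is `"alternative"` (so the assembly under test joined the
#' contig backwards and the alternative connection mode is the correct one).
#'
#' @param haps a phased [geno_matrix()] from [simulate_linked_haplotypes()].
#' @param breakpoint 1-based junction position.
#' @param flank flank length in bp.
#' @param true_mode `"current"` or `"alternative"`.
#' @return list with `gm` (observed matrix), `scenario`
#'   ([junction_scenario()]) and `truth` (list with `true_mode`).
#' @export
make_junction_scenario <- function(haps, breakpoint, flank = 500000L,
                                   true_mode = c("current", "alternative")) {
  true_mode <- match.arg(true_mode)
  chrom <- haps$chrom[1]
  chrom_length <- haps$chrom_lengths[[chrom]]
  scenario <- junction_scenario(chrom, breakpoint, flank, chrom_length)
  gm <- haps
  if (true_mode == "alternative") {
    new_pos <- remap_positions(scenario, haps$pos, "alternative")
    o <- order(new_pos)
    gm <- geno_matrix(haps$geno[, o, drop = FALSE], haps$chrom[o],
                      as.integer(new_pos[o]), haps$ref[o], haps$alt[o],
                      haps$samples,
                      hap = list(haps$hap$h1[, o, drop = FALSE],
                                 haps$hap$h2[, o, drop = FALSE]),
                      chrom_lengths = haps$chrom_lengths)
  }
  list(gm = gm, scenario = scenario, truth = list(true_mode = true_mode))
}

#' Write a simulated cohort to disk (VCF + population map)
#'
#' @param gm a [geno_matrix()].
#' @param pmap a [pop_map()].
#' @param dir output directory (created if needed).
#' @return named character vector with paths `vcf` and `popmap`, invisibly.
#' @export
write_cohort <- function(gm, pmap, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  vcf <- file.path(dir, "cohort.vcf")
  tsv <- file.path(dir, "popmap.tsv")
  write_vcf(gm, vcf)
  write_population_map(pmap, tsv)
  invisible(c(vcf = vcf, popmap = tsv))
}
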