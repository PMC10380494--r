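#' Sliding-window track
#'
#' Windowed statistics (pi, Fst, log2 pi-ratio) are carried as a
#' `window_track`: a data.frame with columns `chrom`, `start`, `end` (0-based
#' half-open, BED convention), `n_snps`, `value` and `partial` (terminal
#' windows shorter than the nominal size; these are emitted but excluded from
#' downstream quantile computations). Track metadata (statistic name,
#' population labels, window, step, min_snps) is kept in attributes.
#'
#' @param df data.frame with the columns above.
#' @param stat statistic name (e.g. `"pi"`, `"fst"`, `"log2_pi_ratio"`).
#' @param populations character vector of population labels involved.
#' @param window,step,min_snps the windowing parameters used.
#' @return the classed track.
#' @export
window_track <- function(df, stat, populations, window, step, min_snps) {
  need <- c("chrom", "start", "end", "n_snps", "value", "partial")
  stopifnot(all(need %in% names(df)))
  structure(as.data.frame(df)[need], stat = stat, populations = populations,
            window = window, step = step, min_snps = min_snps,
            class = c("window_track", "data.frame"))
}

# window grid for one set of chromosome lengths; start every `step` bp while
# the window start lies inside the chromosome
make_windows <- function(chrom_lengths, window, step) {
  stopifnot(window >= step, step > 0)
  out <- lapply(names(chrom_lengths), function(ch) {
    len <- chrom_lengths[[ch]]
    starts <- seq.int(0L, max(0L, len - 1L), by = step)
    ends <- pmin(starts + window, len)
    data.frame(chrom = ch, start = starts, end = ends,
               partial = (ends - starts) < window)
  })
  do.call(rbind, out)
}

# sum per-SNP contributions into windows. pos is 1-based; a SNP falls in
# [start, end) via its 0-based coordinate pos-1. Returns list(n, sum).
window_sums <- function(chrom, pos, contrib, counted, grid) {
  n <- integer(nrow(grid)); s <- numeric(nrow(grid))
  for (ch in unique(grid$chrom)) {
    wi <- which(grid$chrom == ch)
    vi <- which(chrom == ch)
    p0 <- pos[vi] - 1L
    o <- order(p0)
    p0 <- p0[o]
    cv <- cumsum(c(0, contrib[vi][o]))
    cn <- cumsum(c(0L, as.integer(counted[vi][o])))
    lo <- findInterval(grid$start[wi] - 0.5, p0)
    hi <- findInterval(grid$end[wi] - 0.5, p0)
    n[wi] <- cn[hi + 1L] - cn[lo + 1L]
    s[wi] <- cv[hi + 1L] - cv[lo + 1L]
  }
  list(n = n, sum = s)
}

# grids must agree exactly for track arithmetic
check_same_grid <- function(a, b) {
  if (!identical(a[c("chrom", "start", "end", "partial")],
                 b[c("chrom", "start", "end", "partial")]))
    stop("window tracks are on different grids")
  invisible(TRUE)
}

#' Write a window track as BED4+ TSV
#'
#' Columns: chrom, start, end, n_snps, value, partial. Missing values are
#' written as `NA`.
#' @param track a [window_track()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_window_track <- function(track, path) {
  utils::write.table(track, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
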