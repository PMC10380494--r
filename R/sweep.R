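#' Log2 pi-ratio track between two populations
#'
#' `log2((piA + eps)/(piB + eps))` per window, on the shared grid of the two
#' input tracks. Positive values mean higher diversity in A (so a diversity
#' *deficit* in B, the hallmark of a sweep in B); negative values the
#' converse. `NA` wherever either input is `NA`.
#'
#' @param piA,piB pi [window_track()]s on identical grids.
#' @param pseudocount per-site pseudo-diversity added to both numerator and
#'   denominator to keep zero-diversity windows finite (default `1e-6`,
#'   i.e. one mismatch per Mb — well below any polymorphic window's pi).
#' @return a [window_track()] with statistic `"log2_pi_ratio"`; the
#'   `populations` attribute is `c(popA, popB)`.
#' @export
pi_ratio_track <- function(piA, piB, pseudocount = 1e-6) {
  check_same_grid(piA, piB)
  value <- log2((piA$value + pseudocount) / (piB$value + pseudocount))
  value[is.na(piA$value) | is.na(piB$value)] <- NA_real_
  window_track(cbind(piA[c("chrom", "start", "end")],
                     data.frame(n_snps = pmin(piA$n_snps, piB$n_snps),
                                value = value, partial = piA$partial)),
               stat = "log2_pi_ratio",
               populations = c(attr(piA, "populations"),
                               attr(piB, "populations")),
               window = attr(piA, "window"), step = attr(piA, "step"),
               min_snps = attr(piA, "min_snps"))
}

#' Joint Fst / pi-ratio selective-sweep scan
#'
#' Flags candidate selected windows as the intersection of the top-`q` tail
#' of windowed Fst with the extreme tails of the log2 pi-ratio distribution.
#' Thresholds are empirical quantiles (linear interpolation) of the usable
#' (non-missing, non-partial) windows: Fst at `1-q`; the ratio split across
#' two tails at `q/2` and `1-q/2` (one tail per population), or a single tail
#' when `tails` is `"lower"`/`"upper"`. The selection test is `>=` for Fst
#' and strict `>`/`<` for tail exceedance, so tie behaviour is reproducible.
#' The selected-in population of a candidate is the low-diversity side of its
#' ratio.
#'
#' @param fst an Fst [window_track()].
#' @param ratio a log2 pi-ratio [window_track()] on the same grid, with its
#'   `populations` attribute naming `c(popA, popB)`.
#' @param q total tail mass for each statistic (default 0.05).
#' @param tails `"both"` (default, q/2 per side), `"lower"` or `"upper"`.
#' @return a `sweep_result`: list with `fst_threshold`, `ratio_lo`,
#'   `ratio_hi`, `candidates` (data.frame chrom/start/end/fst/ratio/
#'   direction), `counts` (named per direction), `n_usable`, `q`, `tails`,
#'   `populations`.
#' @export
sweep_scan <- function(fst, ratio, q = 0.05, tails = c("both", "lower", "upper")) {
  tails <- match.arg(tails)
  check_same_grid(as.data.frame(fst), as.data.frame(ratio))
  if (q <= 0 || q >= 1) stop("q must lie in (0, 1)")
  pops <- attr(ratio, "populations")
  if (length(pops) != 2 || anyNA(pops))
    pops <- c("A", "B")
  usable <- !is.na(fst$value) & !is.na(ratio$value) & !fst$partial
  if (sum(usable) < 20)
    stop("need at least 20 usable windows, have ", sum(usable))
  fv <- fst$value[usable]; rv <- ratio$value[usable]
  fst_thr <- stats::quantile(fv, 1 - q, names = FALSE, type = 7)
  if (tails == "both") {
    lo <- stats::quantile(rv, q / 2, names = FALSE, type = 7)
    hi <- stats::quantile(rv, 1 - q / 2, names = FALSE, type = 7)
  } else if (tails == "lower") {
    lo <- stats::quantile(rv, q, names = FALSE, type = 7); hi <- Inf
  } else {
    lo <- -Inf; hi <- stats::quantile(rv, 1 - q, names = FALSE, type = 7)
  }
  in_fst <- usable & fst$value >= fst_thr
  in_lo <- usable & ratio$value < lo
  in_hi <- usable & ratio$value > hi
  cand <- in_fst & (in_lo | in_hi)
  # high ratio = pi deficit in B; low ratio = deficit in A
  direction <- ifelse(in_hi, pops[2], pops[1])[cand]
  candidates <- data.frame(chrom = fst$chrom[cand], start = fst$start[cand],
                           end = fst$end[cand], fst = fst$value[cand],
                           ratio = ratio$value[cand],
                           direction = direction)
  counts <- c(sum(direction == pops[1]), sum(direction == pops[2]))
  names(counts) <- pops
  structure(list(fst_threshold = fst_thr, ratio_lo = lo, ratio_hi = hi,
                 candidates = candidates, counts = counts,
                 n_usable = sum(usable), q = q, tails = tails,
                 populations = pops,
                 window = attr(fst, "window"), step = attr(fst, "step")),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("sweep_result: %d candidate window(s) of %d usable (q = %g)\n",
              nrow(x$candidates), x$n_usable, x$q))
  cat(sprintf("  Fst >= %.4f; log2 pi-ratio tails (%.4f, %.4f)\n",
              x$fst_threshold, x$ratio_lo, x$ratio_hi))
  for (p in names(x$counts))
    cat(sprintf("  selected in %-12s %d\n", paste0(p, ":"), x$counts[[p]]))
  invisible(x)
}

#' Count candidate windows selected in one population
#'
#' @param result a `sweep_result` from [sweep_scan()].
#' @param direction one of the two population labels of the scan.
#' @return integer count.
#' @export
count_selected <- function(result, direction) {
  if (!direction %in% result$populations)
    stop("unknown direction label '", direction, "'; expected one of: ",
         paste(result$populations, collapse = ", "))
  sum(result$candidates$direction == direction)
}

#' Write a sweep result (candidates BED + JSON summary)
#'
#' @param result a `sweep_result`.
#' @param prefix output path prefix; writes `<prefix>_candidates.tsv` and
#'   `<prefix>_summary.json`.
#' @return character vector of the two paths, invisibly.
#' @export
write_sweep_result <- function(result, prefix) {
  bed <- paste0(prefix, "_candidates.tsv")
  js <- paste0(prefix, "_summary.json")
  utils::write.table(result$candidates, bed, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(list(fst_threshold = result$fst_threshold,
                            ratio_lo = result$ratio_lo,
                            ratio_hi = result$ratio_hi,
                            counts = as.list(result$counts),
                            n_usable = result$n_usable, q = result$q,
                            tails = result$tails,
                            populations = result$populations),
                       js, auto_unbox = TRUE, digits = NA)
  invisible(c(bed, js))
}
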