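#' Read a sample-to-population-to-region map
#'
#' The cohort design maps every sample to a subpopulation and every
#' subpopulation to a geographic region (e.g. eight subpopulations across
#' three counties). The file is a TSV with header columns `sample`,
#' `population`, `region`.
#'
#' @param path TSV path.
#' @return a `pop_map`: a data.frame with columns sample/population/region.
#' @export
read_population_map <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = "character", quote = "")
  pop_map(df)
}

#' Construct / validate a population map
#'
#' @param df data.frame with character columns `sample`, `population`,
#'   `region`.
#' @return the validated map, classed `pop_map`.
#' @export
pop_map <- function(df) {
  need <- c("sample", "population", "region")
  if (!all(need %in% names(df)))
    stop("population map needs columns: ", paste(need, collapse = ", "))
  df <- as.data.frame(df)[need]
  dup <- df$sample[duplicated(df$sample)]
  if (length(dup))
    stop("duplicated sample id(s) in population map: ",
         paste(unique(dup), collapse = ", "))
  reg_per_pop <- tapply(df$region, df$population, function(r) length(unique(r)))
  if (any(reg_per_pop > 1))
    stop("population(s) mapped to more than one region: ",
         paste(names(reg_per_pop)[reg_per_pop > 1], collapse = ", "))
  class(df) <- c("pop_map", "data.frame")
  df
}

#' @export
print.pop_map <- function(x, ...) {
  cat(sprintf("pop_map: %d samples, %d populations, %d regions\n",
              nrow(x), length(unique(x$population)), length(unique(x$region))))
  invisible(x)
}

#' Write a population map as TSV
#' @param pmap a [pop_map()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_population_map <- function(pmap, path) {
  utils::write.table(pmap, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# samples of one population / region, checked against a genotype matrix
samples_of <- function(pmap, label, level = c("population", "region")) {
  level <- match.arg(level)
  hit <- pmap$sample[pmap[[level]] == label]
  if (!length(hit)) stop("unknown ", level, " label: ", label)
  hit
}

# every sample of gm must appear exactly once in the map
check_map_covers <- function(gm, pmap) {
  missing <- setdiff(gm$samples, pmap$sample)
  if (length(missing))
    stop("sample(s) absent from population map: ",
         paste(missing, collapse = ", "))
  invisible(TRUE)
}
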