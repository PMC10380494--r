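.config_defaults <- function() {
  list(
    input = NULL,         # list(vcf =, popmap =)
    simulation = NULL,    # cohort_design() arguments
    filter = list(maf_min = 0.05, missing_max = 0.10, hwe_alpha = 0.001,
                  biallelic_only = TRUE),
    window = 100000L, step = 10000L, min_snps = 10L,
    sweep_q = 0.05,
    compare = list(level = "region", groups = NULL),
    junction = NULL,      # list(chrom =, breakpoint =, flank =)
    out_dir = "popgenscan_run", seed = 1L, log_level = "info")
}

# overlay user values on defaults, rejecting unknown keys at each level
.merge_config <- function(defaults, user, path = "") {
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ",
         paste0(sub("^\\.", "", paste0(path, ".", unknown)), collapse = ", "))
  for (k in names(user)) {
    if (is.list(defaults[[k]]) && is.list(user[[k]]) &&
        !is.null(names(defaults[[k]])) && k %in% c("filter", "compare"))
      defaults[k] <- list(.merge_config(defaults[[k]], user[[k]],
                                        paste0(path, ".", k)))
    else defaults[k] <- list(user[[k]])   # keeps explicit NULLs in place
  }
  defaults
}

#' Load / write a pipeline run configuration
#'
#' The configuration is a single JSON file. Every omitted key takes its
#' documented default (filters 0.05/0.10/0.001; windows 100 kb / 10 kb / 10
#' SNPs; sweep q 0.05); unknown keys are rejected by name. Exactly one of
#' `input` (paths `vcf`, `popmap`) or `simulation` ([cohort_design()]
#' arguments) must be supplied.
#'
#' @param path JSON config path.
#' @return a `run_config` list.
#' @export
load_config <- function(path) {
  user <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- .merge_config(.config_defaults(), user)
  if (is.null(cfg$input) == is.null(cfg$simulation))
    stop("config must supply exactly one of 'input' or 'simulation'")
  structure(cfg, class = "run_config")
}

#' @rdname load_config
#' @param config a `run_config`.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

.log_stage <- function(con, stage, msg) {
  line <- sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"), stage, msg)
  message(line)
  if (!is.null(con)) writeLines(line, con)
}

#' Run the full scan pipeline
#'
#' Fixed stage order: input (read or simulate) -> SNP filtering ->
#' diversity -> Fst -> sweep scan -> optional junction validation. Every
#' output is a plain-text TSV/JSON file under `config$out_dir`, and a
#' manifest (`manifest.json`) records inputs, parameters, seed, package
#' version and every file written, so a rerun with the same config and seed
#' reproduces the outputs byte for byte. A stage failure aborts the run with
#' the failing stage named.
#'
#' @param config a `run_config` from [load_config()], or a list coercible to
#'   one.
#' @return the manifest, invisibly.
#' @export
run_scan <- function(config) {
  if (!inherits(config, "run_config"))
    config <- structure(.merge_config(.config_defaults(), config),
                        class = "run_config")
  if (is.null(config$input) == is.null(config$simulation))
    stop("config must supply exactly one of 'input' or 'simulation'")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file(file.path(config$out_dir, "run.log"), "w")
  on.exit(close(logf))
  outputs <- character(0)
  stages <- character(0)
  emit <- function(name, writer) {
    p <- file.path(config$out_dir, name)
    writer(p)
    outputs <<- c(outputs, name)
    p
  }
  run_stage <- function(stage, expr) {
    .log_stage(logf, stage, "start")
    r <- tryCatch(expr, error = function(e)
      stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE))
    stages <<- c(stages, stage)
    r
  }

  # -- input ---------------------------------------------------------------
  cohort <- run_stage("input", {
    if (!is.null(config$simulation)) {
      args <- config$simulation
      if (!is.null(args$regions)) args$regions <- unlist(args$regions)
      if (is.null(args$seed)) args$seed <- config$seed
      simulate_structured_cohort(do.call(cohort_design, args))
    } else {
      list(gm = read_vcf(config$input$vcf),
           pmap = read_population_map(config$input$popmap), truth = NULL)
    }
  })

  # -- filter --------------------------------------------------------------
  flt <- run_stage("filter", {
    f <- do.call(filter_variants, c(list(gm = cohort$gm), config$filter))
    emit("filter_report.tsv", function(p) write_filter_report(f$report, p))
    f
  })
  gm <- flt$gm; pmap <- cohort$pmap

  # -- diversity -----------------------------------------------------------
  comparison <- run_stage("diversity", {
    div <- population_diversity(gm, pmap)
    emit("diversity.tsv", function(p)
      utils::write.table(div, p, sep = "\t", quote = FALSE, row.names = FALSE))
    level <- config$compare$level
    groups <- config$compare$groups
    if (is.null(groups)) {
      tab <- sort(table(pmap[[level]]), decreasing = TRUE)
      groups <- names(tab)[1:2]
    }
    gmap <- pop_map(data.frame(sample = pmap$sample,
                               population = pmap[[level]],
                               region = pmap$region))
    piA <- windowed_pi(gm, gmap, groups[1], config$window, config$step,
                       config$min_snps)
    piB <- windowed_pi(gm, gmap, groups[2], config$window, config$step,
                       config$min_snps)
    emit(paste0("pi_", groups[1], ".tsv"), function(p) write_window_track(piA, p))
    emit(paste0("pi_", groups[2], ".tsv"), function(p) write_window_track(piB, p))
    list(level = level, groups = groups, gmap = gmap, piA = piA, piB = piB)
  })

  # -- fst -----------------------------------------------------------------
  fst_tr <- run_stage("fst", {
    for (lv in c("population", "region")) {
      if (length(unique(pmap[[lv]])) >= 2) {
        m <- pairwise_fst(gm, pmap, lv)
        emit(paste0("fst_", lv, ".tsv"), function(p)
          utils::write.table(m, p, sep = "\t", quote = FALSE))
      }
    }
    comp <- fst_site_components(
      gm,
      intersect(samples_of(pmap, comparison$groups[1], comparison$level), gm$samples),
      intersect(samples_of(pmap, comparison$groups[2], comparison$level), gm$samples))
    tr <- fst_windowed(comp, config$window, config$step, config$min_snps,
                       chrom_lengths = gm$chrom_lengths)
    emit("fst_windows.tsv", function(p) write_window_track(tr, p))
    tr
  })

  # -- sweep ---------------------------------------------------------------
  sweep <- run_stage("sweep", {
    ratio <- pi_ratio_track(comparison$piA, comparison$piB)
    res <- sweep_scan(fst_tr, ratio, q = config$sweep_q)
    write_sweep_result(res, file.path(config$out_dir, "sweep"))
    outputs <- c(outputs, "sweep_candidates.tsv", "sweep_summary.json")
    res
  })

  # -- junction (optional) -------------------------------------------------
  junction <- NULL
  if (!is.null(config$junction)) {
    junction <- run_stage("junction", {
      sc <- junction_scenario(config$junction$chrom, config$junction$breakpoint,
                              config$junction$flank %||% 500000L,
                              gm$chrom_lengths[[config$junction$chrom]])
      dec <- validate_junction(gm, sc)
      emit("junction_decision.json", function(p)
        jsonlite::write_json(list(scores = as.list(dec$scores),
                                  n_pairs = as.list(dec$n_pairs),
                                  chosen = dec$chosen, ratio = dec$ratio),
                             p, auto_unbox = TRUE, digits = NA))
      dec
    })
  }

  manifest <- list(
    package = "popgenscan",
    version = as.character(utils::packageVersion("popgenscan")),
    seed = config$seed,
    parameters = unclass(config),
    comparison = list(level = comparison$level, groups = comparison$groups),
    stages = stages,
    outputs = sort(unique(outputs)),
    sweep = list(fst_threshold = sweep$fst_threshold,
                 counts = as.list(sweep$counts)),
    junction_chosen = if (!is.null(junction)) junction$chosen else NULL)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  .log_stage(logf, "done", paste(length(stages), "stages complete"))
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
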