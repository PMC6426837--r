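# End-to-end orchestration: load (or simulate) -> filter -> pairwise
# statistics -> ordination -> classification -> resurrection test, with a
# provenance record in every output.

#' Build a pipeline configuration
#'
#' Exactly one of `input` or `scenario` must be given.
#'
#' @param input `NULL`, or `list(path, format, taxon_map_path)` for
#'   [load_dataset()].
#' @param scenario `NULL`, or a [sim_scenario()] to generate the input.
#' @param filter `NULL` to skip locus filtering, or a list with any of
#'   `repavg`, `callrate`, `skip` for [filter_snp_chain()].
#' @param tloc,min_n Fixed-difference parameters.
#' @param sexual_refs Taxa used as sexual references for classification
#'   (`NULL` skips classification).
#' @param theta,min_loci Hybridogen-call parameters.
#' @param resurrection `NULL`, or `list(pureP, founder1, founder2, tau)`.
#' @param k Ordination axes used for intermediacy summaries.
#' @param seed Integer seed (drives the secondaries draw and, if simulating
#'   without an explicit scenario seed, the simulation).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL, scenario = NULL, filter = list(),
                            tloc = 0, min_n = 1, sexual_refs = NULL,
                            theta = 0.9, min_loci = 10, resurrection = NULL,
                            k = 2, seed = 1L) {
  if (is.null(input) == is.null(scenario))
    stop("give exactly one of `input` or `scenario`")
  if (!is.null(input) && !file.exists(input$path))
    stop("input file does not exist: ", input$path)
  structure(list(input = input, scenario = scenario, filter = filter,
                 tloc = tloc, min_n = min_n, sexual_refs = sexual_refs,
                 theta = theta, min_loci = min_loci,
                 resurrection = resurrection, k = k, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' @param config A `pipeline_config`.
#' @return List of class `pipeline_report`: `dataset` (filtered),
#'   `filter_report`, `missingness`, `stats` (a `pairwise_taxon_stats`),
#'   `ordination`, `classification`, `resurrection`, `truth` (simulated
#'   input only) and `provenance`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  truth <- NULL
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  loaded <- stage("load", {
    if (!is.null(config$scenario)) {
      sim <- simulate_dataset(config$scenario)
      list(ds = sim$dataset, truth = sim$truth)
    } else {
      list(ds = load_dataset(config$input$path, config$input$format,
                             config$input$taxon_map_path),
           truth = NULL)
    }
  })
  ds <- loaded$ds
  truth <- loaded$truth
  if (!is.null(config$filter)) {
    f <- config$filter
    ds <- stage("filter", filter_snp_chain(
      ds,
      repavg = if (is.null(f$repavg)) 0.99 else f$repavg,
      callrate = if (is.null(f$callrate)) 0.95 else f$callrate,
      seed = config$seed,
      skip = if (is.null(f$skip)) character(0) else f$skip))
  }
  miss <- stage("missingness", missingness_summary(ds))
  stats <- stage("stats", pairwise_taxon_stats(ds, tloc = config$tloc,
                                               min_n = config$min_n))
  ord <- stage("ordination", ordinate(ds))
  classification <- NULL
  if (!is.null(config$sexual_refs))
    classification <- stage("classify", classify_individuals(
      ds, config$sexual_refs, theta = config$theta, tloc = config$tloc,
      min_loci = config$min_loci, min_n = config$min_n))
  resurrection <- NULL
  if (!is.null(config$resurrection)) {
    r <- config$resurrection
    resurrection <- stage("resurrection-test", resurrection_test(
      ds, r$pureP, r$founder1, r$founder2,
      tau = if (is.null(r$tau)) 0 else r$tau,
      tloc = config$tloc, min_n = config$min_n))
  }
  provenance <- list(package = "hemiclone",
                     version = as.character(utils::packageVersion("hemiclone")),
                     seed = config$seed,
                     config = config[setdiff(names(config), "scenario")],
                     scenario_seed = if (!is.null(config$scenario))
                       config$scenario$seed else NULL)
  structure(list(dataset = ds, filter_report = filter_report(ds),
                 missingness = miss, stats = stats, ordination = ord,
                 classification = classification, resurrection = resurrection,
                 truth = truth, provenance = provenance),
            class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("pipeline report (seed ", x$provenance$seed, ")\n", sep = "")
  print(x$dataset)
  if (length(x$filter_report)) {
    cat("filter chain:\n")
    for (st in x$filter_report)
      cat(sprintf("  %-16s %d -> %d loci (-%d)\n", st$step, st$loci_in,
                  st$loci_out, st$loci_removed))
  }
  print(x$stats)
  if (!is.null(x$resurrection)) print(x$resurrection)
  invisible(x)
}

#' Write a pipeline report bundle to a directory
#'
#' Emits `stats.tsv`, `ordination.tsv`, `classification.tsv` (if present),
#' `resurrection.json` (if present), `filter_report.json`, `missingness.tsv`
#' and `provenance.json`.
#'
#' @param report A `pipeline_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_pipeline_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_pairwise_stats(report$stats, file.path(dir, "stats.tsv"))
  write_ordination(report$ordination, file.path(dir, "ordination.tsv"),
                   taxon_of = individual_taxa(report$dataset))
  utils::write.table(report$missingness, file.path(dir, "missingness.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_filter_report(report$dataset, file.path(dir, "filter_report.json"))
  if (!is.null(report$classification))
    utils::write.table(report$classification,
                       file.path(dir, "classification.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(report$resurrection))
    write_resurrection_verdict(report$resurrection,
                               file.path(dir, "resurrection.json"))
  jsonlite::write_json(report$provenance, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  invisible(dir)
}
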