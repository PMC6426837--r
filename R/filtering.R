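# Locus-filtering chain for reduced-representation SNP data:
# reproducibility -> call rate -> secondaries -> monomorphic loci.
# Each step appends to a filter report carried on the dataset, so the
# full provenance of a filtered matrix can be reconstructed and audited.

#' Filter report of a dataset
#'
#' @param ds A `geno_dataset`.
#' @return List of filter steps (possibly empty), each with the step name,
#'   parameters, locus counts in/removed/out and the removed locus IDs.
#' @export
filter_report <- function(ds) {
  rep <- attr(ds, "filter_report")
  if (is.null(rep)) list() else rep
}

append_filter_step <- function(ds_out, ds_in, step, params) {
  removed <- setdiff(locus_ids(ds_in), locus_ids(ds_out))
  rec <- list(step = step, params = params,
              loci_in = n_loci(ds_in), loci_removed = length(removed),
              loci_out = n_loci(ds_out), removed_ids = removed)
  attr(ds_out, "filter_report") <- c(filter_report(ds_in), list(rec))
  ds_out
}

#' Write a filter report as JSON
#' @param ds A filtered `geno_dataset`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_filter_report <- function(ds, path) {
  jsonlite::write_json(filter_report(ds), path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Filter loci on scoring reproducibility
#'
#' Retains loci whose technical-replicate reproducibility (`rep_avg`) is at
#' least `threshold` (inclusive).
#'
#' @param ds A `geno_dataset` whose loci carry `rep_avg` metadata.
#' @param threshold Minimum reproducibility in \[0, 1\] (default 0.99).
#' @return Filtered `geno_dataset` with the filter report updated.
#' @export
filter_reproducibility <- function(ds, threshold = 0.99) {
  stopifnot(threshold >= 0, threshold <= 1)
  ra <- ds$loci$rep_avg
  if (is.null(ra) || anyNA(ra))
    stop("reproducibility metadata (rep_avg) is absent for some loci; ",
         "skip this step explicitly if the data carry no replicate scores")
  keep <- ra >= threshold
  out <- subset_dataset(ds, loci = keep)
  append_filter_step(out, ds, "reproducibility", list(threshold = threshold))
}

#' Filter loci on call rate
#'
#' Retains loci whose fraction of non-missing calls is at least
#' `min_callrate` (inclusive), i.e. removes loci with strictly more than
#' `1 - min_callrate` missing values.
#'
#' @param ds A `geno_dataset`.
#' @param min_callrate Minimum call rate in \[0, 1\] (default 0.95).
#' @return Filtered `geno_dataset` with the filter report updated.
#' @export
filter_callrate <- function(ds, min_callrate = 0.95) {
  stopifnot(min_callrate >= 0, min_callrate <= 1)
  cr <- colMeans(!missing_calls(ds))
  out <- subset_dataset(ds, loci = cr >= min_callrate)
  append_filter_step(out, ds, "callrate", list(min_callrate = min_callrate))
}

#' Thin secondary SNPs to one per sequenced tag
#'
#' Multiple SNPs called on the same restriction-site tag are tightly linked;
#' this keeps exactly one locus per `tag_id`, chosen uniformly at random and
#' reproducibly under `seed`. Loci on unique tags are untouched.
#'
#' @param ds A `geno_dataset` whose loci carry non-empty `tag_id`.
#' @param seed Integer seed recorded in the report.
#' @return Filtered `geno_dataset` with the filter report updated.
#' @export
filter_secondaries <- function(ds, seed = 1L) {
  tags <- ds$loci$tag_id
  if (is.null(tags) || any(is.na(tags) | tags == ""))
    stop("secondaries filtering requires a non-empty tag_id for every locus")
  keep <- with_seed(seed, {
    idx <- split(seq_len(n_loci(ds)), tags)
    sort(vapply(idx, function(v) if (length(v) == 1L) v else v[sample.int(length(v), 1L)],
                integer(1)))
  })
  out <- subset_dataset(ds, loci = unname(keep))
  append_filter_step(out, ds, "secondaries", list(seed = seed))
}

#' Drop monomorphic loci
#'
#' Removes loci at which all non-missing calls carry a single allele, and
#' loci with no data at all — both arise routinely after subsetting a
#' dataset to fewer individuals or taxa.
#'
#' @param ds A `geno_dataset`.
#' @return Filtered `geno_dataset` with the filter report updated.
#' @export
drop_monomorphic <- function(ds) {
  poly <- vapply(seq_len(n_loci(ds)), function(j) {
    al <- c(ds$a1[, j], ds$a2[, j])
    length(unique(al[!is.na(al)])) >= 2L
  }, logical(1))
  out <- subset_dataset(ds, loci = poly)
  append_filter_step(out, ds, "monomorphic", list())
}

#' Run the standard SNP filter chain
#'
#' Applies, in order: reproducibility, call rate, secondaries,
#' monomorphic-locus removal. Any step can be skipped by name.
#'
#' @param ds A `geno_dataset`.
#' @param repavg Reproducibility threshold (default 0.99).
#' @param callrate Minimum call rate (default 0.95).
#' @param seed Seed for the secondaries draw.
#' @param skip Character vector of step names to skip, among
#'   `"reproducibility"`, `"callrate"`, `"secondaries"`, `"monomorphic"`.
#' @return Filtered `geno_dataset`; inspect [filter_report()] for the audit
#'   trail.
#' @export
filter_snp_chain <- function(ds, repavg = 0.99, callrate = 0.95, seed = 1L,
                             skip = character(0)) {
  if (!"reproducibility" %in% skip) ds <- filter_reproducibility(ds, repavg)
  if (!"callrate" %in% skip) ds <- filter_callrate(ds, callrate)
  if (!"secondaries" %in% skip) ds <- filter_secondaries(ds, seed)
  if (!"monomorphic" %in% skip) ds <- drop_monomorphic(ds)
  ds
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  expr
}
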