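# Per-taxon allele profiles and the pairwise statistics used to detect
# ghost genomes: observed heterozygosity, absolute fixed differences,
# Euclidean genetic distance, and Nei's (1972) standard distance.

#' Per-taxon allele profile
#'
#' Observed allele counts and frequencies per locus, computed over
#' non-missing calls only. The profile is the substrate for every
#' fixed-difference and distance computation.
#'
#' @param ds A `geno_dataset`.
#' @param taxon A taxon label present in the dataset's taxon map, or `NULL`
#'   when `individuals` is given.
#' @param individuals Optional explicit individual IDs (overrides `taxon`).
#' @return An `allele_profile`: list with `taxon`, `counts` (loci x allele
#'   codes), `freq` (row-normalised counts; `NaN` rows where a locus has no
#'   data), `n` (non-missing individuals per locus) and `loci`.
#' @export
allele_profile <- function(ds, taxon = NULL, individuals = NULL) {
  if (is.null(individuals)) {
    if (is.null(taxon)) stop("give either `taxon` or `individuals`")
    tx <- individual_taxa(ds)
    if (!taxon %in% tx) stop("unknown taxon: ", taxon)
    individuals <- individual_ids(ds)[!is.na(tx) & tx == taxon]
  }
  ii <- resolve_selector(individuals, individual_ids(ds), "individual")
  if (!length(ii)) stop("no individuals selected")
  a1 <- ds$a1[ii, , drop = FALSE]; a2 <- ds$a2[ii, , drop = FALSE]
  K <- max(vapply(ds$alleles, length, integer(1)))
  counts <- matrix(0, n_loci(ds), K,
                   dimnames = list(locus_ids(ds), paste0("allele", 0:(K - 1L))))
  for (k in 0:(K - 1L))
    counts[, k + 1L] <- colSums(a1 == k, na.rm = TRUE) + colSums(a2 == k, na.rm = TRUE)
  tot <- rowSums(counts)
  freq <- counts / tot       # NaN where a locus has no data in this taxon
  structure(list(taxon = if (is.null(taxon)) NA_character_ else taxon,
                 counts = counts, freq = freq, n = tot / 2,
                 loci = locus_ids(ds)),
            class = "allele_profile")
}

#' @export
print.allele_profile <- function(x, ...) {
  cat("allele_profile for taxon", x$taxon, "-", length(x$loci), "loci;",
      sum(x$n == 0), "loci with no data\n")
  invisible(x)
}

#' Observed heterozygosity of a taxon
#'
#' Per-locus heterozygote fraction (heterozygous calls / non-missing calls),
#' averaged without weighting over loci that carry at least one non-missing
#' call. Unisexual hybrid lineages show strongly elevated values relative to
#' their sexual relatives because they are heterozygous at every locus that
#' diagnoses their two parental species.
#'
#' @param ds A `geno_dataset`.
#' @param taxon Taxon label.
#' @return List of class `heterozygosity_result` with `taxon`, `Ho`,
#'   `per_locus`, `n_individuals`, `n_loci_used`. `Ho` is `NA` (with a
#'   warning) when every call of the taxon is missing.
#' @export
observed_heterozygosity <- function(ds, taxon) {
  tx <- individual_taxa(ds)
  if (!taxon %in% tx) stop("unknown taxon: ", taxon)
  ii <- which(!is.na(tx) & tx == taxon)
  het <- ds$a1[ii, , drop = FALSE] != ds$a2[ii, , drop = FALSE]
  n_call <- colSums(!is.na(het))
  h <- colSums(het, na.rm = TRUE) / n_call
  used <- n_call > 0
  Ho <- if (any(used)) mean(h[used]) else {
    warning("taxon ", taxon, ": all calls missing; H_O undefined")
    NA_real_
  }
  structure(list(taxon = taxon, Ho = Ho, per_locus = h,
                 n_individuals = length(ii), n_loci_used = sum(used)),
            class = "heterozygosity_result")
}

#' @export
print.heterozygosity_result <- function(x, ...) {
  cat(sprintf("H_O(%s) = %.4f  [%d individuals, %d loci]\n",
              x$taxon, x$Ho, x$n_individuals, x$n_loci_used))
  invisible(x)
}

#' Absolute fixed differences between two taxa
#'
#' A locus enters the comparison when both taxa have at least `min_n`
#' non-missing calls there. With `tloc = 0` the locus counts as an absolute
#' fixed difference when the two taxa's observed allele sets are disjoint;
#' with `tloc > 0`, when every allele shared between the taxa has frequency
#' at most `tloc` in at least one of them.
#'
#' @param ds A `geno_dataset` (or pass two `allele_profile`s via
#'   `profileA`/`profileB`).
#' @param taxonA,taxonB Taxon labels.
#' @param tloc Tolerance frequency for a shared allele, in \[0, 0.5).
#' @param min_n Minimum non-missing calls per taxon for a locus to be
#'   compared (default 1).
#' @param profileA,profileB Optional precomputed profiles.
#' @return List of class `fixed_diff` with `taxa`, `n_loci_compared`,
#'   `fixed_diff_count`, `fixed_diff_loci`, `tloc`, `min_n`.
#' @export
fixed_difference_count <- function(ds = NULL, taxonA = NULL, taxonB = NULL,
                                   tloc = 0, min_n = 1,
                                   profileA = NULL, profileB = NULL) {
  stopifnot(tloc >= 0, tloc < 0.5, min_n >= 1)
  if (is.null(profileA)) profileA <- allele_profile(ds, taxonA)
  if (is.null(profileB)) profileB <- allele_profile(ds, taxonB)
  compared <- profileA$n >= min_n & profileB$n >= min_n
  fA <- profileA$freq; fB <- profileB$freq
  shared <- !is.na(fA) & !is.na(fB) & fA > 0 & fB > 0
  blocked <- shared & fA > tloc & fB > tloc   # shared allele above tolerance in both
  fixed <- compared & rowSums(blocked) == 0
  structure(list(taxa = c(profileA$taxon, profileB$taxon),
                 n_loci_compared = sum(compared),
                 fixed_diff_count = sum(fixed),
                 fixed_diff_loci = profileA$loci[fixed],
                 tloc = tloc, min_n = min_n),
            class = "fixed_diff")
}

#' @export
print.fixed_diff <- function(x, ...) {
  cat(sprintf("%s vs %s: %d absolute fixed differences / %d loci compared (tloc = %g)\n",
              x$taxa[1], x$taxa[2], x$fixed_diff_count, x$n_loci_compared, x$tloc))
  invisible(x)
}

shared_data_loci <- function(profileA, profileB) {
  w <- which(profileA$n >= 1 & profileB$n >= 1)
  if (!length(w))
    stop("taxa ", profileA$taxon, " and ", profileB$taxon,
         " share no loci with data")
  w
}

#' Euclidean genetic distance between two allele profiles
#'
#' Root sum over shared-data loci of the squared difference in the
#' reference-allele frequency (allele code 0). Unscaled by default, so the
#' magnitude grows with the number of loci compared; `normalize = TRUE`
#' divides by the square root of that number.
#'
#' @param profileA,profileB `allele_profile`s over the same loci.
#' @param normalize Divide by `sqrt(n_loci_compared)`?
#' @return Non-negative scalar.
#' @export
euclidean_distance <- function(profileA, profileB, normalize = FALSE) {
  w <- shared_data_loci(profileA, profileB)
  d2 <- sum((profileA$freq[w, 1L] - profileB$freq[w, 1L])^2)
  if (normalize) sqrt(d2 / length(w)) else sqrt(d2)
}

#' Nei's (1972) standard genetic distance
#'
#' With per-locus sums `jx = sum(p^2)`, `jy = sum(q^2)`, `jxy = sum(p q)`
#' averaged over shared-data loci into `Jx`, `Jy`, `Jxy`, the distance is
#' `D = -ln(Jxy / sqrt(Jx * Jy))`. Fully disjoint profiles give `Jxy = 0`
#' and `D = Inf`.
#'
#' @param profileA,profileB `allele_profile`s over the same loci.
#' @return Non-negative scalar, possibly `Inf`.
#' @export
nei_distance <- function(profileA, profileB) {
  w <- shared_data_loci(profileA, profileB)
  fA <- profileA$freq[w, , drop = FALSE]; fB <- profileB$freq[w, , drop = FALSE]
  Jx <- mean(rowSums(fA^2)); Jy <- mean(rowSums(fB^2)); Jxy <- mean(rowSums(fA * fB))
  if (Jxy == 0) return(Inf)
  max(-log(Jxy / sqrt(Jx * Jy)), 0)
}

#' Pairwise taxon statistics table
#'
#' Computes, for every pair of taxa, the absolute fixed-difference count,
#' the number of loci compared, and the Euclidean (optionally Nei) genetic
#' distance, plus per-taxon observed heterozygosity — a compact summary of
#' the genomic evidence separating sexual species, hemi-clonal lineages and
#' candidate ghost remnants.
#'
#' @param ds A `geno_dataset` with a taxon map.
#' @param taxa_order Optional ordering/subset of taxa.
#' @param tloc,min_n Passed to [fixed_difference_count()].
#' @param nei Also compute Nei distances?
#' @return List of class `pairwise_taxon_stats` with `taxa`, `Ho` (named
#'   vector), square matrices `fixed_diff`, `n_loci_compared`, `euclidean`
#'   (and `nei`), a `fixed_diff_loci` list, and the parameters used.
#' @export
pairwise_taxon_stats <- function(ds, taxa_order = NULL, tloc = 0, min_n = 1,
                                 nei = TRUE) {
  tset <- if (is.null(taxa_order)) taxa(ds) else taxa_order
  if (length(tset) < 2) stop("need at least two taxa")
  profs <- lapply(tset, function(t) allele_profile(ds, t))
  names(profs) <- tset
  k <- length(tset)
  fd <- nlc <- eu <- nd <- matrix(0, k, k, dimnames = list(tset, tset))
  fd_loci <- list()
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    f <- fixed_difference_count(tloc = tloc, min_n = min_n,
                                profileA = profs[[i]], profileB = profs[[j]])
    fd[i, j] <- fd[j, i] <- f$fixed_diff_count
    nlc[i, j] <- nlc[j, i] <- f$n_loci_compared
    eu[i, j] <- eu[j, i] <- euclidean_distance(profs[[i]], profs[[j]])
    if (nei) nd[i, j] <- nd[j, i] <- nei_distance(profs[[i]], profs[[j]])
    fd_loci[[paste(tset[i], tset[j], sep = " vs ")]] <- f$fixed_diff_loci
  }
  Ho <- vapply(tset, function(t) observed_heterozygosity(ds, t)$Ho, numeric(1))
  structure(list(taxa = tset, Ho = Ho, fixed_diff = fd, n_loci_compared = nlc,
                 euclidean = eu, nei = if (nei) nd else NULL,
                 fixed_diff_loci = fd_loci, tloc = tloc, min_n = min_n),
            class = "pairwise_taxon_stats")
}

#' @export
print.pairwise_taxon_stats <- function(x, digits = 2, ...) {
  k <- length(x$taxa)
  m <- matrix("", k, k, dimnames = list(x$taxa, x$taxa))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i > j) m[i, j] <- format(x$fixed_diff[i, j])
    if (i < j) m[i, j] <- format(round(x$euclidean[i, j], digits))
    if (i == j) m[i, j] <- "-"
  }
  cat("Observed heterozygosity:\n")
  print(round(x$Ho, 3))
  cat("\nLower triangle: absolute fixed differences (tloc =", x$tloc,
      "); upper: Euclidean distance\n")
  print(m, quote = FALSE)
  invisible(x)
}

#' Export a pairwise statistics table as TSV
#'
#' Writes the per-taxon heterozygosity block and the combined matrix
#' (fixed differences below the diagonal, Euclidean distances above).
#'
#' @param stats A `pairwise_taxon_stats`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pairwise_stats <- function(stats, path) {
  k <- length(stats$taxa)
  m <- matrix("", k, k, dimnames = list(stats$taxa, stats$taxa))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i > j) m[i, j] <- format(stats$fixed_diff[i, j])
    if (i < j) m[i, j] <- format(signif(stats$euclidean[i, j], 6))
  }
  con <- file(path, "w"); on.exit(close(con))
  writeLines(paste0("# pairwise taxon statistics (tloc = ", stats$tloc,
                    ", min_n = ", stats$min_n, ")"), con)
  writeLines(paste("taxon", "Ho", sep = "\t"), con)
  writeLines(paste(stats$taxa, signif(stats$Ho, 6), sep = "\t"), con)
  writeLines("", con)
  writeLines(paste(c("", colnames(m)), collapse = "\t"), con)
  for (i in seq_len(k))
    writeLines(paste(c(rownames(m)[i], m[i, ]), collapse = "\t"), con)
  invisible(path)
}
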