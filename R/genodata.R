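# Core genotype container: individuals x loci diploid calls stored as two
# integer allele-code matrices (a1 <= a2, both NA when the call is missing).
# Allele codes are per-locus, assigned in first-seen order; original symbols
# are retained in `alleles` for reporting. Phase is never stored or used.

#' Construct a genotype dataset
#'
#' `geno_dataset()` builds the container used by every downstream analysis:
#' a matrix of unordered diploid allele-code pairs, per-locus metadata, the
#' per-locus allele symbol registry, and an individual-to-taxon map.
#'
#' @param a1,a2 Integer matrices (individuals x loci) holding the two allele
#'   codes of each call, `NA` in both for a missing call. Codes are 0-based
#'   per locus; pairs are unordered and are normalised so that `a1 <= a2`.
#'   Row names are individual IDs, column names locus IDs.
#' @param loci Data frame of locus metadata with at least `locus_id`;
#'   optionally `tag_id` (sequenced-tag/clone identifier used by secondaries
#'   filtering) and `rep_avg` (scoring reproducibility in \[0, 1\]).
#' @param alleles List (one element per locus) of character vectors giving
#'   the allele symbols; code `k` refers to `alleles[[locus]][k + 1]`. If
#'   `NULL`, symbols `"0"`, `"1"`, ... are registered from the observed codes
#'   (minimum two alleles per locus, the biallelic SNP convention).
#' @param taxon_map Data frame with columns `individual_id`, `taxon` and
#'   optionally `site`, covering a subset of individuals. Untagged
#'   individuals are allowed but excluded from per-taxon statistics.
#'
#' @return An object of class `geno_dataset`.
#' @export
geno_dataset <- function(a1, a2, loci, alleles = NULL, taxon_map = NULL) {
  a1 <- as.matrix(a1); a2 <- as.matrix(a2)
  storage.mode(a1) <- "integer"; storage.mode(a2) <- "integer"
  if (!identical(dim(a1), dim(a2)))
    stop("allele matrices `a1` and `a2` must have identical dimensions")
  if (is.null(rownames(a1)))
    rownames(a1) <- rownames(a2) <- paste0("ind", seq_len(nrow(a1)))
  loci <- as.data.frame(loci, stringsAsFactors = FALSE)
  if (is.null(loci$locus_id)) stop("`loci` must contain a `locus_id` column")
  loci$locus_id <- as.character(loci$locus_id)
  if (ncol(a1) != nrow(loci))
    stop("number of locus metadata rows must equal the number of call columns")
  colnames(a1) <- colnames(a2) <- loci$locus_id
  if (anyDuplicated(rownames(a1)))
    stop("duplicate individual IDs: ",
         paste(unique(rownames(a1)[duplicated(rownames(a1))]), collapse = ", "))
  if (anyDuplicated(loci$locus_id))
    stop("duplicate locus IDs: ",
         paste(unique(loci$locus_id[duplicated(loci$locus_id)]), collapse = ", "))
  if (!is.null(loci$rep_avg)) {
    bad <- !is.na(loci$rep_avg) & (loci$rep_avg < 0 | loci$rep_avg > 1)
    if (any(bad)) stop("`rep_avg` must lie in [0, 1]")
  }
  ## unordered-pair normalisation and half-missing coercion
  half <- xor(is.na(a1), is.na(a2))
  if (any(half)) { a1[half] <- NA_integer_; a2[half] <- NA_integer_ }
  swap <- !is.na(a1) & a1 > a2
  if (any(swap)) { tmp <- a1[swap]; a1[swap] <- a2[swap]; a2[swap] <- tmp }

  if (is.null(alleles)) {
    alleles <- lapply(seq_len(ncol(a1)), function(j) {
      mx <- suppressWarnings(max(c(a1[, j], a2[, j], 1L), na.rm = TRUE))
      as.character(0:mx)
    })
  }
  if (length(alleles) != nrow(loci))
    stop("`alleles` must have one element per locus")
  names(alleles) <- loci$locus_id
  for (j in seq_len(ncol(a1))) {
    k <- length(alleles[[j]])
    obs <- c(a1[, j], a2[, j])
    if (any(!is.na(obs) & (obs < 0L | obs >= k)))
      stop("locus ", loci$locus_id[j], ": call uses an unregistered allele code")
  }

  if (!is.null(taxon_map)) {
    taxon_map <- as.data.frame(taxon_map, stringsAsFactors = FALSE)
    if (!all(c("individual_id", "taxon") %in% names(taxon_map)))
      stop("`taxon_map` needs columns `individual_id` and `taxon`")
    if (is.null(taxon_map$site)) taxon_map$site <- NA_character_
    taxon_map <- taxon_map[, c("individual_id", "taxon", "site")]
    unknown <- setdiff(taxon_map$individual_id, rownames(a1))
    if (length(unknown)) {
      warning("taxon map references unknown individuals (dropped): ",
              paste(unknown, collapse = ", "))
      taxon_map <- taxon_map[taxon_map$individual_id %in% rownames(a1), ]
    }
    if (anyDuplicated(taxon_map$individual_id))
      stop("taxon map lists an individual more than once")
  }

  structure(list(a1 = a1, a2 = a2, loci = loci, alleles = alleles,
                 taxon_map = taxon_map),
            class = "geno_dataset")
}

#' @export
print.geno_dataset <- function(x, ...) {
  cat("geno_dataset:", nrow(x$a1), "individuals x", ncol(x$a1), "loci\n")
  miss <- mean(is.na(x$a1))
  cat(sprintf("  missing calls: %.2f%%\n", 100 * miss))
  if (!is.null(x$taxon_map)) {
    tb <- table(x$taxon_map$taxon)
    cat("  taxa:", paste(sprintf("%s (%d)", names(tb), tb), collapse = ", "), "\n")
  } else cat("  no taxon map\n")
  invisible(x)
}

#' Number of individuals / loci in a dataset
#' @param ds A `geno_dataset`.
#' @return Integer count.
#' @export
n_individuals <- function(ds) nrow(ds$a1)

#' @rdname n_individuals
#' @export
n_loci <- function(ds) ncol(ds$a1)

#' Individual and locus identifiers
#' @param ds A `geno_dataset`.
#' @return Character vector of IDs.
#' @export
individual_ids <- function(ds) rownames(ds$a1)

#' @rdname individual_ids
#' @export
locus_ids <- function(ds) ds$loci$locus_id

#' Taxon label of every individual
#'
#' @param ds A `geno_dataset`.
#' @return Named character vector over all individuals; `NA` for individuals
#'   absent from the taxon map.
#' @export
individual_taxa <- function(ds) {
  out <- setNames(rep(NA_character_, n_individuals(ds)), individual_ids(ds))
  if (!is.null(ds$taxon_map))
    out[ds$taxon_map$individual_id] <- ds$taxon_map$taxon
  out
}

#' Taxa present in a dataset
#' @param ds A `geno_dataset`.
#' @return Character vector of distinct taxon labels, in first appearance order.
#' @export
taxa <- function(ds) {
  if (is.null(ds$taxon_map)) character(0) else unique(ds$taxon_map$taxon)
}

#' Logical matrix of missing calls
#' @param ds A `geno_dataset`.
#' @return Logical individuals x loci matrix, `TRUE` where the call is missing.
#' @export
missing_calls <- function(ds) is.na(ds$a1)

#' Logical matrix of heterozygous calls
#' @param ds A `geno_dataset`.
#' @return Logical individuals x loci matrix; `NA` where the call is missing.
#' @export
het_calls <- function(ds) ds$a1 != ds$a2

#' Subset a genotype dataset
#'
#' Order-preserving selection of individuals and/or loci; locus metadata,
#' allele registries and the taxon map are carried through. Selectors may be
#' character IDs, integer indices or logical masks.
#'
#' @param ds A `geno_dataset`.
#' @param individuals,loci Optional selectors; `NULL` keeps everything.
#' @return A `geno_dataset`.
#' @export
subset_dataset <- function(ds, individuals = NULL, loci = NULL) {
  ii <- resolve_selector(individuals, individual_ids(ds), "individual")
  jj <- resolve_selector(loci, locus_ids(ds), "locus")
  tm <- ds$taxon_map
  if (!is.null(tm))
    tm <- tm[tm$individual_id %in% individual_ids(ds)[ii], , drop = FALSE]
  geno_dataset(ds$a1[ii, jj, drop = FALSE], ds$a2[ii, jj, drop = FALSE],
               ds$loci[jj, , drop = FALSE], ds$alleles[jj],
               if (!is.null(tm) && nrow(tm)) tm else NULL)
}

resolve_selector <- function(sel, ids, what) {
  if (is.null(sel)) return(seq_along(ids))
  if (is.logical(sel)) {
    if (length(sel) != length(ids)) stop("logical ", what, " selector has wrong length")
    return(which(sel))
  }
  if (is.numeric(sel)) {
    if (any(sel < 1 | sel > length(ids))) stop(what, " index out of range")
    return(as.integer(sel))
  }
  idx <- match(sel, ids)
  if (anyNA(idx))
    stop("unknown ", what, " ID(s): ", paste(sel[is.na(idx)], collapse = ", "))
  idx
}

#' Select all individuals belonging to given taxa
#'
#' @param ds A `geno_dataset`.
#' @param taxon Character vector of taxon labels.
#' @return A `geno_dataset` restricted to those individuals.
#' @export
subset_taxon <- function(ds, taxon) {
  if (is.null(ds$taxon_map)) stop("dataset has no taxon map")
  unknown <- setdiff(taxon, ds$taxon_map$taxon)
  if (length(unknown)) stop("unknown taxon: ", paste(unknown, collapse = ", "))
  keep <- ds$taxon_map$individual_id[ds$taxon_map$taxon %in% taxon]
  subset_dataset(ds, individuals = keep)
}

#' Missing-data summary
#'
#' Overall fraction of missing calls and, optionally, the fraction within
#' each taxon (computed over that taxon's individuals only). Taxa with no
#' individuals yield `NA`.
#'
#' @param ds A `geno_dataset`.
#' @param by_taxon Also report per-taxon fractions?
#' @return A data frame with columns `taxon` (label or `"overall"`),
#'   `n_individuals`, `n_missing` and `fraction_missing`.
#' @export
missingness_summary <- function(ds, by_taxon = TRUE) {
  if (n_individuals(ds) == 0L || n_loci(ds) == 0L) stop("dataset is empty")
  m <- missing_calls(ds)
  out <- data.frame(taxon = "overall", n_individuals = nrow(m),
                    n_missing = sum(m), fraction_missing = mean(m),
                    stringsAsFactors = FALSE)
  if (by_taxon && !is.null(ds$taxon_map)) {
    tx <- individual_taxa(ds)
    for (t in taxa(ds)) {
      rows <- which(!is.na(tx) & tx == t)
      mt <- m[rows, , drop = FALSE]
      out <- rbind(out, data.frame(
        taxon = t, n_individuals = length(rows), n_missing = sum(mt),
        fraction_missing = if (length(rows)) mean(mt) else NA_real_,
        stringsAsFactors = FALSE))
    }
  }
  out
}

#' Reference-allele dosage matrix
#'
#' Per-call count (0/1/2) of each locus' reference allele (code 0, the first
#' registered allele). Loci with more than two registered alleles are
#' expanded into one dosage column per allele, so allozyme genotypes
#' contribute comparably to biallelic SNPs. Missing calls give `NA`.
#'
#' @param ds A `geno_dataset`.
#' @return Numeric matrix, individuals x dosage columns, with an attribute
#'   `locus` mapping each column back to its locus index.
#' @export
dosage_matrix <- function(ds) {
  nal <- vapply(ds$alleles, length, integer(1))
  cols <- vector("list", n_loci(ds))
  locus_of <- vector("list", n_loci(ds))
  for (j in seq_len(n_loci(ds))) {
    if (nal[j] <= 2L) {
      cols[[j]] <- (ds$a1[, j] == 0L) + (ds$a2[, j] == 0L)
      locus_of[[j]] <- j
    } else {
      cols[[j]] <- vapply(0:(nal[j] - 1L), function(k)
        (ds$a1[, j] == k) + (ds$a2[, j] == k), numeric(n_individuals(ds)))
      locus_of[[j]] <- rep(j, nal[j])
    }
  }
  out <- do.call(cbind, cols)
  rownames(out) <- individual_ids(ds)
  attr(out, "locus") <- unlist(locus_of)
  out
}
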