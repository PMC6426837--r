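# Readers and writers. Three dialects are supported:
#   vcf          - VCF 4.x biallelic SNP records, GT field only (via vcfR)
#   dart_csv     - DArT-style wide SNP table, one-row dosage coding or
#                  two-row per-allele presence coding
#   allozyme_csv - individuals x loci table of letter genotypes ("ab";
#                  a single letter is a homozygote)
# plus a three-column taxon map TSV (individual_id, taxon, site).

#' Load a genotype dataset from disk
#'
#' @param path Path to the genotype file.
#' @param format One of `"vcf"`, `"dart_csv"`, `"allozyme_csv"`.
#' @param taxon_map_path Optional path to a taxon map TSV with header
#'   `individual_id`, `taxon`, `site`; individuals named there but absent
#'   from the genotype file trigger a warning, not an error.
#' @return A `geno_dataset`.
#' @export
load_dataset <- function(path, format = c("vcf", "dart_csv", "allozyme_csv"),
                         taxon_map_path = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  ds <- switch(format,
               vcf = read_vcf_dataset(path),
               dart_csv = read_dart_csv(path),
               allozyme_csv = read_allozyme_csv(path))
  if (!is.null(taxon_map_path)) {
    tm <- read_taxon_map(taxon_map_path)
    ds <- geno_dataset(ds$a1, ds$a2, ds$loci, ds$alleles, tm)
  }
  ds
}

#' Read a taxon map TSV
#'
#' @param path Tab-delimited file with one header row and columns
#'   `individual_id`, `taxon` and optionally `site`.
#' @return Data frame with those columns.
#' @export
read_taxon_map <- function(path) {
  tm <- utils::read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  if (!all(c("individual_id", "taxon") %in% names(tm)))
    stop("taxon map must have columns `individual_id` and `taxon`: ", path)
  if (is.null(tm$site)) tm$site <- NA_character_
  tm[, c("individual_id", "taxon", "site")]
}

#' Write a dataset's taxon map as TSV
#' @param ds A `geno_dataset` with a taxon map.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_taxon_map <- function(ds, path) {
  if (is.null(ds$taxon_map)) stop("dataset has no taxon map")
  utils::write.table(ds$taxon_map, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

## ---- VCF ----

read_vcf_dataset <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  ids <- fix$ID
  ids[is.na(ids) | ids == "."] <- paste0(fix$CHROM, "_", fix$POS)[is.na(ids) | ids == "."]
  samples <- colnames(gt)
  n <- length(samples); L <- nrow(gt)
  a1 <- matrix(NA_integer_, n, L, dimnames = list(samples, ids))
  a2 <- a1
  for (j in seq_len(L)) {
    g <- gsub("|", "/", gt[j, ], fixed = TRUE)
    parts <- strsplit(g, "/", fixed = TRUE)
    np <- lengths(parts)
    called <- !is.na(g) & g != "."
    if (any(np[called] != 2L))
      stop("VCF record ", ids[j], ": ploidy != 2 is not supported")
    for (i in which(called)) {
      al <- parts[[i]]
      if (any(al == ".")) next   # half-missing -> missing
      a1[i, j] <- as.integer(al[1]); a2[i, j] <- as.integer(al[2])
    }
  }
  alleles <- lapply(seq_len(L), function(j) {
    alt <- fix$ALT[j]
    alt <- if (is.na(alt) || alt == ".") character(0) else strsplit(alt, ",", fixed = TRUE)[[1]]
    c(fix$REF[j], alt)
  })
  loci <- data.frame(locus_id = ids, tag_id = NA_character_, rep_avg = NA_real_,
                     chrom = fix$CHROM, pos = suppressWarnings(as.integer(fix$POS)),
                     stringsAsFactors = FALSE)
  geno_dataset(a1, a2, loci, alleles)
}

#' Write a biallelic dataset as VCF 4.2 (GT field only)
#'
#' Loci must be biallelic. Chromosome/position metadata are used when
#' present, otherwise placeholder coordinates are emitted.
#'
#' @param ds A `geno_dataset`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(ds, path) {
  nal <- vapply(ds$alleles, length, integer(1))
  if (any(nal != 2L)) stop("write_vcf requires biallelic loci")
  chrom <- if (!is.null(ds$loci$chrom)) ds$loci$chrom else rep("1", n_loci(ds))
  pos <- if (!is.null(ds$loci$pos) && !anyNA(ds$loci$pos)) ds$loci$pos else seq_len(n_loci(ds))
  ref <- vapply(ds$alleles, `[`, character(1), 1L)
  alt <- vapply(ds$alleles, `[`, character(1), 2L)
  ok <- grepl("^[ACGT]$", ref) & grepl("^[ACGT]$", alt)
  ref[!ok] <- "A"; alt[!ok] <- "T"   # symbolic alleles: emit placeholder bases
  gt <- matrix("./.", n_loci(ds), n_individuals(ds))
  called <- t(!missing_calls(ds))
  gt[called] <- paste0(t(ds$a1), "/", t(ds$a2))[called]
  header <- c("##fileformat=VCFv4.2",
              "##source=hemiclone",
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", individual_ids(ds)), collapse = "\t"))
  body <- paste(chrom, pos, locus_ids(ds), ref, alt, ".", "PASS", ".", "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

## ---- DArT-style CSV ----

#' @describeIn load_dataset Read a DArT-style wide CSV directly. The one-row
#'   dialect has columns `locus_id`, `tag_id`, `rep_avg` then one column per
#'   individual holding the alternate-allele dosage (`0` = 0/0, `1` = 0/1,
#'   `2` = 1/1, `-` or empty = missing). The two-row dialect has an extra
#'   leading `allele_id` column and two rows per locus scoring presence
#'   (`1`/`0`) of the reference and alternate allele respectively; `(1,1)`
#'   is a heterozygote and `(0,0)` or `-` is missing. The dialect is
#'   detected from the header.
#' @export
read_dart_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                        colClasses = "character")
  if ("allele_id" %in% names(df)) read_dart_tworow(df, path) else read_dart_onerow(df, path)
}

dart_meta_cols <- c("locus_id", "tag_id", "rep_avg")

read_dart_onerow <- function(df, path) {
  if (!all(dart_meta_cols %in% names(df)))
    stop("dart_csv needs columns ", paste(dart_meta_cols, collapse = ", "), ": ", path)
  samples <- setdiff(names(df), dart_meta_cols)
  if (!length(samples)) stop("no individual columns in ", path)
  g <- as.matrix(df[, samples, drop = FALSE])
  g[g %in% c("-", "", "NA")] <- NA
  bad <- !is.na(g) & !(g %in% c("0", "1", "2"))
  if (any(bad)) {
    w <- which(bad, arr.ind = TRUE)[1, ]
    stop(sprintf("%s line %d: invalid dosage '%s' for individual %s",
                 path, w[1] + 1L, g[bad][1], samples[w[2]]))
  }
  dos <- matrix(as.integer(g), nrow(g), ncol(g))
  a1 <- t(ifelse(dos >= 1L, ifelse(dos == 2L, 1L, 0L), 0L))
  a2 <- t(ifelse(dos >= 1L, 1L, 0L))
  a1[t(is.na(dos))] <- NA_integer_; a2[t(is.na(dos))] <- NA_integer_
  rownames(a1) <- rownames(a2) <- samples
  loci <- data.frame(locus_id = df$locus_id, tag_id = df$tag_id,
                     rep_avg = as.numeric(df$rep_avg), stringsAsFactors = FALSE)
  if (any(is.na(loci$tag_id) | loci$tag_id == ""))
    stop("dart_csv requires a non-empty tag_id for every locus: ", path)
  geno_dataset(a1, a2, loci, alleles = rep(list(c("0", "1")), nrow(loci)))
}

read_dart_tworow <- function(df, path) {
  need <- c("allele_id", dart_meta_cols)
  if (!all(need %in% names(df)))
    stop("two-row dart_csv needs columns ", paste(need, collapse = ", "), ": ", path)
  if (nrow(df) %% 2L != 0L)
    stop("two-row dart_csv must have an even number of rows: ", path)
  ref_rows <- seq(1L, nrow(df), by = 2L)
  alt_rows <- ref_rows + 1L
  if (any(df$locus_id[ref_rows] != df$locus_id[alt_rows]))
    stop("two-row dart_csv: consecutive rows must share locus_id: ", path)
  samples <- setdiff(names(df), need)
  pres <- as.matrix(df[, samples, drop = FALSE])
  pres[pres %in% c("-", "", "NA")] <- NA
  bad <- !is.na(pres) & !(pres %in% c("0", "1"))
  if (any(bad)) {
    w <- which(bad, arr.ind = TRUE)[1, ]
    stop(sprintf("%s line %d: invalid presence score '%s'", path, w[1] + 1L, pres[bad][1]))
  }
  p <- matrix(as.integer(pres), nrow(pres), ncol(pres))
  pr <- p[ref_rows, , drop = FALSE]; pa <- p[alt_rows, , drop = FALSE]
  miss <- is.na(pr) | is.na(pa) | (pr == 0L & pa == 0L)
  a1 <- t(ifelse(pr == 1L, 0L, 1L))
  a2 <- t(ifelse(pa == 1L, 1L, 0L))
  a1[t(miss)] <- NA_integer_; a2[t(miss)] <- NA_integer_
  rownames(a1) <- rownames(a2) <- samples
  loci <- data.frame(locus_id = df$locus_id[ref_rows], tag_id = df$tag_id[ref_rows],
                     rep_avg = as.numeric(df$rep_avg[ref_rows]), stringsAsFactors = FALSE)
  if (any(is.na(loci$tag_id) | loci$tag_id == ""))
    stop("dart_csv requires a non-empty tag_id for every locus: ", path)
  geno_dataset(a1, a2, loci, alleles = rep(list(c("0", "1")), nrow(loci)))
}

#' Write a biallelic dataset as one-row DArT-style CSV
#' @param ds A `geno_dataset` with biallelic loci and tag metadata.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dart_csv <- function(ds, path) {
  nal <- vapply(ds$alleles, length, integer(1))
  if (any(nal != 2L)) stop("write_dart_csv requires biallelic loci")
  dos <- ds$a1 + ds$a2        # alternate-allele dosage (codes 0/1)
  cells <- t(dos)
  out <- matrix(as.character(cells), nrow(cells), ncol(cells))
  out[is.na(cells)] <- "-"
  tag <- ds$loci$tag_id
  if (is.null(tag) || any(is.na(tag) | tag == "")) tag <- locus_ids(ds)
  rep_avg <- if (is.null(ds$loci$rep_avg)) rep(1, n_loci(ds)) else ds$loci$rep_avg
  rep_avg[is.na(rep_avg)] <- 1
  df <- data.frame(locus_id = locus_ids(ds), tag_id = tag, rep_avg = rep_avg,
                   stringsAsFactors = FALSE, check.names = FALSE)
  df <- cbind(df, as.data.frame(out, stringsAsFactors = FALSE) |>
                stats::setNames(individual_ids(ds)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

## ---- allozyme CSV ----

#' @describeIn load_dataset Read an allozyme genotype CSV directly: first
#'   column `individual_id`, one column per locus, genotypes as letter pairs
#'   (`"ab"`), a single letter for homozygotes, and `-`/empty for missing.
#'   Allele letters are integer-coded per locus in first-seen order.
#' @export
read_allozyme_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                        colClasses = "character")
  if (names(df)[1] != "individual_id")
    stop("allozyme_csv must start with an `individual_id` column: ", path)
  ids <- df$individual_id
  locus_names <- names(df)[-1]
  if (!length(locus_names)) stop("no locus columns in ", path)
  n <- length(ids); L <- length(locus_names)
  a1 <- matrix(NA_integer_, n, L, dimnames = list(ids, locus_names))
  a2 <- a1
  alleles <- vector("list", L)
  for (j in seq_len(L)) {
    g <- df[[j + 1L]]
    g[g %in% c("-", "", "NA")] <- NA
    seen <- character(0)
    for (i in seq_len(n)) {
      if (is.na(g[i])) next
      ch <- strsplit(g[i], "")[[1]]
      if (!length(ch) %in% 1:2 || !all(grepl("^[A-Za-z]$", ch)))
        stop(sprintf("%s line %d: malformed genotype '%s' at locus %s",
                     path, i + 1L, g[i], locus_names[j]))
      if (length(ch) == 1L) ch <- c(ch, ch)
      for (a in unique(ch)) if (!a %in% seen) seen <- c(seen, a)
      a1[i, j] <- match(ch[1], seen) - 1L
      a2[i, j] <- match(ch[2], seen) - 1L
    }
    alleles[[j]] <- if (length(seen)) seen else c("a", "b")
  }
  loci <- data.frame(locus_id = locus_names, tag_id = NA_character_,
                     rep_avg = NA_real_, stringsAsFactors = FALSE)
  geno_dataset(a1, a2, loci, alleles)
}

#' Write a dataset as allozyme-style CSV (letter genotypes)
#' @param ds A `geno_dataset` whose allele symbols are single letters.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_allozyme_csv <- function(ds, path) {
  sym <- function(j, code) ds$alleles[[j]][code + 1L]
  cells <- matrix("-", n_individuals(ds), n_loci(ds))
  for (j in seq_len(n_loci(ds))) {
    ok <- !is.na(ds$a1[, j])
    s1 <- sym(j, ds$a1[ok, j]); s2 <- sym(j, ds$a2[ok, j])
    cells[ok, j] <- ifelse(s1 == s2, s1, paste0(s1, s2))
  }
  df <- data.frame(individual_id = individual_ids(ds), cells,
                   stringsAsFactors = FALSE, check.names = FALSE)
  names(df) <- c("individual_id", locus_ids(ds))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
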