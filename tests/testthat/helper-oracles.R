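# Shared fixtures and independent brute-force oracles. The oracles use only
# elementary loops over calls, never the package's vectorised code paths.

# Build a dataset from a character matrix of calls like "0/1"; "." or NA is
# missing. Allele codes are taken literally.
toy_dataset <- function(calls, taxon = NULL, tag_id = NULL, rep_avg = NULL,
                        alleles = NULL) {
  calls <- as.matrix(calls)
  n <- nrow(calls); L <- ncol(calls)
  if (is.null(rownames(calls))) rownames(calls) <- paste0("ind", seq_len(n))
  if (is.null(colnames(calls))) colnames(calls) <- paste0("loc", seq_len(L))
  a1 <- a2 <- matrix(NA_integer_, n, L, dimnames = dimnames(calls))
  for (i in seq_len(n)) for (j in seq_len(L)) {
    g <- calls[i, j]
    if (is.na(g) || g == ".") next
    al <- as.integer(strsplit(g, "/", fixed = TRUE)[[1]])
    a1[i, j] <- al[1]; a2[i, j] <- al[2]
  }
  loci <- data.frame(locus_id = colnames(calls),
                     tag_id = if (is.null(tag_id)) colnames(calls) else tag_id,
                     rep_avg = if (is.null(rep_avg)) 1 else rep_avg,
                     stringsAsFactors = FALSE)
  tm <- if (!is.null(taxon))
    data.frame(individual_id = rownames(calls), taxon = taxon,
               site = NA_character_, stringsAsFactors = FALSE)
  geno_dataset(a1, a2, loci, alleles, tm)
}

# Random biallelic dataset with two taxa and random missingness.
random_dataset <- function(n = 10, L = 50, miss = 0.1, taxa_labels = c("A", "B")) {
  a1 <- matrix(sample(0:1, n * L, replace = TRUE), n, L)
  a2 <- matrix(sample(0:1, n * L, replace = TRUE), n, L)
  drop <- matrix(runif(n * L) < miss, n, L)
  a1[drop] <- NA_integer_; a2[drop] <- NA_integer_
  rownames(a1) <- rownames(a2) <- paste0("ind", seq_len(n))
  loci <- data.frame(locus_id = paste0("loc", seq_len(L)),
                     tag_id = paste0("tag", seq_len(L)),
                     rep_avg = 1, stringsAsFactors = FALSE)
  tm <- data.frame(individual_id = rownames(a1),
                   taxon = rep(taxa_labels, length.out = n),
                   site = NA_character_, stringsAsFactors = FALSE)
  geno_dataset(a1, a2, loci, taxon_map = tm)
}

taxon_rows <- function(ds, taxon) {
  tx <- individual_taxa(ds)
  which(!is.na(tx) & tx == taxon)
}

oracle_missing_fraction <- function(ds, taxon = NULL) {
  rows <- if (is.null(taxon)) seq_len(n_individuals(ds)) else taxon_rows(ds, taxon)
  n_miss <- 0L; n_tot <- 0L
  for (i in rows) for (j in seq_len(n_loci(ds))) {
    n_tot <- n_tot + 1L
    if (is.na(ds$a1[i, j])) n_miss <- n_miss + 1L
  }
  n_miss / n_tot
}

oracle_Ho <- function(ds, taxon) {
  rows <- taxon_rows(ds, taxon)
  hs <- c()
  for (j in seq_len(n_loci(ds))) {
    het <- 0L; called <- 0L
    for (i in rows) {
      if (is.na(ds$a1[i, j])) next
      called <- called + 1L
      if (ds$a1[i, j] != ds$a2[i, j]) het <- het + 1L
    }
    if (called > 0) hs <- c(hs, het / called)
  }
  mean(hs)
}

# per-locus observed allele sets and frequencies of a taxon
oracle_locus_profile <- function(ds, taxon, j) {
  rows <- taxon_rows(ds, taxon)
  al <- c()
  for (i in rows) if (!is.na(ds$a1[i, j])) al <- c(al, ds$a1[i, j], ds$a2[i, j])
  if (!length(al)) return(NULL)
  tb <- table(al)
  list(set = as.integer(names(tb)), freq = as.numeric(tb) / length(al),
       n = length(al) / 2)
}

oracle_fixed_diff <- function(ds, taxonA, taxonB, tloc = 0, min_n = 1) {
  count <- 0L; compared <- 0L; loci <- character(0)
  for (j in seq_len(n_loci(ds))) {
    pa <- oracle_locus_profile(ds, taxonA, j)
    pb <- oracle_locus_profile(ds, taxonB, j)
    if (is.null(pa) || is.null(pb) || pa$n < min_n || pb$n < min_n) next
    compared <- compared + 1L
    fixed <- TRUE
    for (a in intersect(pa$set, pb$set)) {
      fa <- pa$freq[match(a, pa$set)]; fb <- pb$freq[match(a, pb$set)]
      if (fa > tloc && fb > tloc) { fixed <- FALSE; break }
    }
    if (fixed) { count <- count + 1L; loci <- c(loci, locus_ids(ds)[j]) }
  }
  list(count = count, compared = compared, loci = loci)
}

oracle_euclid <- function(ds, taxonA, taxonB) {
  d2 <- 0
  for (j in seq_len(n_loci(ds))) {
    pa <- oracle_locus_profile(ds, taxonA, j)
    pb <- oracle_locus_profile(ds, taxonB, j)
    if (is.null(pa) || is.null(pb)) next
    fa <- if (0L %in% pa$set) pa$freq[match(0L, pa$set)] else 0
    fb <- if (0L %in% pb$set) pb$freq[match(0L, pb$set)] else 0
    d2 <- d2 + (fa - fb)^2
  }
  sqrt(d2)
}

oracle_nei <- function(ds, taxonA, taxonB) {
  jx <- jy <- jxy <- c()
  for (j in seq_len(n_loci(ds))) {
    pa <- oracle_locus_profile(ds, taxonA, j)
    pb <- oracle_locus_profile(ds, taxonB, j)
    if (is.null(pa) || is.null(pb)) next
    all_alleles <- union(pa$set, pb$set)
    fa <- fb <- setNames(rep(0, length(all_alleles)), all_alleles)
    fa[as.character(pa$set)] <- pa$freq
    fb[as.character(pb$set)] <- pb$freq
    jx <- c(jx, sum(fa^2)); jy <- c(jy, sum(fb^2)); jxy <- c(jxy, sum(fa * fb))
  }
  Jxy <- mean(jxy)
  if (Jxy == 0) return(Inf)
  -log(Jxy / sqrt(mean(jx) * mean(jy)))
}

# pairwise dosage distance with pairwise-complete rescaling (biallelic only)
oracle_dist_matrix <- function(ds) {
  n <- n_individuals(ds); L <- n_loci(ds)
  dos <- matrix(NA_real_, n, L)
  for (i in seq_len(n)) for (j in seq_len(L))
    if (!is.na(ds$a1[i, j]))
      dos[i, j] <- (ds$a1[i, j] == 0L) + (ds$a2[i, j] == 0L)
  D <- matrix(0, n, n)
  for (i in seq_len(n)) for (k in seq_len(n)) {
    if (i == k) next
    ss <- 0; m <- 0L
    for (j in seq_len(L)) {
      if (is.na(dos[i, j]) || is.na(dos[k, j])) next
      m <- m + 1L; ss <- ss + (dos[i, j] - dos[k, j])^2
    }
    D[i, k] <- sqrt(ss / m * L)
  }
  dimnames(D) <- list(individual_ids(ds), individual_ids(ds))
  D
}

# least-squares Procrustes residual after centring, optimal rotation and
# scaling (configurations are compared up to similarity transform)
procrustes_resid <- function(X, Y) {
  X <- scale(as.matrix(X), scale = FALSE)
  Y <- scale(as.matrix(Y), scale = FALSE)
  k <- max(ncol(X), ncol(Y))
  if (ncol(X) < k) X <- cbind(X, matrix(0, nrow(X), k - ncol(X)))
  if (ncol(Y) < k) Y <- cbind(Y, matrix(0, nrow(Y), k - ncol(Y)))
  s <- svd(t(Y) %*% X)
  R <- s$v %*% t(s$u)
  sc <- sum(s$d) / sum(X^2)
  sqrt(sum((sc * X %*% R - Y)^2) / sum(Y^2))
}
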