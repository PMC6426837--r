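# Principal co-ordinates analysis of individual genotypes, and a
# quantitative statistic for the classical expectation that F1 hybrids
# (and hence hybridogens) sit half-way between their parental taxa on the
# ordination plot.

#' Pairwise genotype distance matrix
#'
#' Euclidean distance on reference-allele dosage (0/1/2 per biallelic locus;
#' multi-allelic loci expand to one dosage column per allele). For each pair
#' of individuals, squared differences are averaged over mutually
#' non-missing columns and multiplied by the total column count, so pairs
#' with heavy but random missingness remain comparable to fully genotyped
#' pairs in expectation.
#'
#' @param ds A `geno_dataset` with at least two individuals.
#' @return Symmetric numeric matrix with zero diagonal.
#' @export
genotype_distance_matrix <- function(ds) {
  if (n_individuals(ds) < 2) stop("need at least two individuals")
  X <- dosage_matrix(ds)
  M <- (!is.na(X)) * 1
  X0 <- X; X0[is.na(X)] <- 0
  S <- X0^2
  sumsq <- S %*% t(M) + M %*% t(S) - 2 * X0 %*% t(X0)
  C <- M %*% t(M)
  if (any(C == 0 & upper.tri(C)))  {
    w <- which(C == 0 & upper.tri(C), arr.ind = TRUE)[1, ]
    stop("individuals ", rownames(X)[w[1]], " and ", rownames(X)[w[2]],
         " share no genotyped loci")
  }
  D <- sqrt(pmax(sumsq / C * ncol(X), 0))
  diag(D) <- 0
  dimnames(D) <- list(rownames(X), rownames(X))
  (D + t(D)) / 2
}

#' Principal co-ordinates analysis
#'
#' Gower double-centering of `-D^2 / 2` followed by eigendecomposition.
#' Coordinates are eigenvectors scaled by the square root of their
#' eigenvalues; axes with non-positive eigenvalues are dropped (with a
#' warning recording the largest negative magnitude when it exceeds
#' numerical noise).
#'
#' @param D Square symmetric distance matrix with zero diagonal and
#'   non-negative entries.
#' @param metric Free-text descriptor of the distance used (stored only).
#' @return Object of class `pcoa_ordination`: `coordinates` (individuals x
#'   axes), `eigenvalues`, `percent_var`, `negative_eigenvalues`, `metric`.
#' @export
pcoa <- function(D, metric = "euclidean-dosage") {
  D <- as.matrix(D)
  if (nrow(D) != ncol(D) || max(abs(D - t(D))) > 1e-8)
    stop("distance matrix must be square and symmetric")
  if (any(D < 0)) stop("distance matrix has negative entries")
  if (any(abs(diag(D)) > 1e-12)) stop("distance matrix must have zero diagonal")
  n <- nrow(D)
  A <- -0.5 * D^2
  J <- diag(n) - matrix(1 / n, n, n)
  B <- J %*% A %*% J
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  tol <- 1e-8 * max(abs(e$values), 1e-12)
  neg <- e$values[e$values < -tol]
  if (length(neg))
    warning(sprintf("dropping %d negative-eigenvalue axes (largest magnitude %.3g)",
                    length(neg), max(abs(neg))))
  keep <- which(e$values > tol)
  coords <- e$vectors[, keep, drop = FALSE] %*% diag(sqrt(e$values[keep]), length(keep))
  rownames(coords) <- rownames(D)
  colnames(coords) <- paste0("PCo", seq_along(keep))
  structure(list(coordinates = coords, eigenvalues = e$values[keep],
                 percent_var = 100 * e$values[keep] / sum(e$values[keep]),
                 negative_eigenvalues = abs(neg), metric = metric),
            class = "pcoa_ordination")
}

#' @export
print.pcoa_ordination <- function(x, ...) {
  cat("PCoA (", x$metric, "): ", nrow(x$coordinates), " individuals, ",
      ncol(x$coordinates), " axes\n", sep = "")
  k <- min(4, length(x$percent_var))
  cat("  % variance:", paste(sprintf("%.1f", x$percent_var[1:k]), collapse = ", "),
      if (length(x$percent_var) > k) "..." else "", "\n")
  invisible(x)
}

#' Ordinate a genotype dataset
#'
#' Convenience wrapper: [genotype_distance_matrix()] then [pcoa()].
#'
#' @param ds A `geno_dataset`.
#' @return A `pcoa_ordination`.
#' @export
ordinate <- function(ds) pcoa(genotype_distance_matrix(ds))

#' Write ordination coordinates as TSV
#'
#' @param ord A `pcoa_ordination`.
#' @param path Output path.
#' @param taxon_of Optional named vector of taxon labels, added as a column.
#' @return `path`, invisibly.
#' @export
write_ordination <- function(ord, path, taxon_of = NULL) {
  df <- data.frame(individual_id = rownames(ord$coordinates),
                   ord$coordinates, check.names = FALSE)
  if (!is.null(taxon_of)) df$taxon <- unname(taxon_of[df$individual_id])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Intermediacy of a putative hybrid taxon on an ordination
#'
#' Quantifies the "half-way" expectation for F1 hybrids: with taxon
#' centroids `h`, `a`, `b` in the first `k` ordination axes, reports the
#' projection fraction `t = ((h - a) . (b - a)) / ||b - a||^2` (0.5 for a
#' perfectly intermediate hybrid, 0 at parent A, 1 at parent B) and the
#' scaled midpoint displacement `D_mid = ||h - (a + b)/2|| / ||a - b||`.
#'
#' @param ord A `pcoa_ordination`.
#' @param taxon_of Named character vector mapping individual IDs to taxon
#'   labels (e.g. `individual_taxa(ds)`).
#' @param hybrid,parentA,parentB Taxon labels.
#' @param k Number of leading axes to use (default 2).
#' @return Object of class `intermediacy_result` with `t`, `D_mid`, `k`
#'   and the three centroids.
#' @export
intermediacy <- function(ord, taxon_of, hybrid, parentA, parentB, k = 2) {
  stopifnot(k >= 1)
  k <- min(k, ncol(ord$coordinates))
  centroid <- function(lbl) {
    ids <- names(taxon_of)[!is.na(taxon_of) & taxon_of == lbl]
    ids <- intersect(ids, rownames(ord$coordinates))
    if (!length(ids)) stop("taxon not present in ordination: ", lbl)
    colMeans(ord$coordinates[ids, seq_len(k), drop = FALSE])
  }
  h <- centroid(hybrid); a <- centroid(parentA); b <- centroid(parentB)
  ab <- b - a
  denom <- sum(ab^2)
  if (denom == 0) stop("parent centroids coincide; intermediacy undefined")
  t_frac <- sum((h - a) * ab) / denom
  D_mid <- sqrt(sum((h - (a + b) / 2)^2)) / sqrt(denom)
  structure(list(hybrid = hybrid, parents = c(parentA, parentB),
                 t = t_frac, D_mid = D_mid, k = k,
                 centroids = rbind(hybrid = h, parentA = a, parentB = b)),
            class = "intermediacy_result")
}

#' @export
print.intermediacy_result <- function(x, ...) {
  cat(sprintf("intermediacy of %s between %s and %s (first %d axes):\n",
              x$hybrid, x$parents[1], x$parents[2], x$k))
  cat(sprintf("  projection fraction t = %.3f (0.5 = exactly half-way)\n", x$t))
  cat(sprintf("  midpoint displacement D_mid = %.3f\n", x$D_mid))
  invisible(x)
}
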