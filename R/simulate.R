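# Forward simulator of a sexual/unisexual species complex with known truth.
# It reproduces the statistical structure the inference assumes: divergent
# sexual species (Balding-Nichols frequencies around a shared ancestor, plus
# forced diagnostic loci), hemi-clonal hybridogen lineages that transmit one
# haploid genome unchanged while re-acquiring the other from a sexual host
# each generation, optional resurrection crosses between two lineages
# carrying the same ghost genome, drifted remnant populations of the ghost
# species, and a two-layer missingness regime (per-taxon locus dropout, as
# caused by restriction-site mutations, plus random per-call missingness).

#' Define a simulation scenario
#'
#' The default scenario mirrors a carp-gudgeon-style complex: three sexual
#' species (HA, HB and the "ghost" HX, the latter sampled only as a drifted
#' remnant population) and the three hybridogen lineages HAxHB (HB genome
#' clonal, HA host), HAxHX and HBxHX (HX genome clonal), 20 individuals per
#' taxon at 4,000 biallelic loci. The default divergence `Fst = 0.85` makes
#' within-species frequencies mostly extreme, which is what reduced-
#' representation SNP panels of long-separated congeners look like: it
#' yields sexual-species observed heterozygosity of a few percent versus
#' 0.2-0.4 for hybridogens, and several hundred absolute fixed differences
#' per sexual species pair. The remnant drifts from the founding HX gene
#' pool with F_drift = 0.05; the remnant taxon suffers 30% per-locus dropout
#' on top of 1% random per-call missingness, emulating restriction-site loss
#' in a diverged genome.
#'
#' @param species Sexual species labels; the last is the ghost species by
#'   convention of the other defaults.
#' @param L Number of biallelic loci.
#' @param Fst Balding-Nichols divergence of each species from the shared
#'   ancestral frequencies, in (0, 1).
#' @param n_diagnostic Number of loci forced to a (1, 0) frequency pair for
#'   each unordered species pair (disjoint sets across pairs).
#' @param sexual_n Named vector: sample size of each sexual species sampled
#'   directly (the ghost species is normally omitted here and represented by
#'   `remnant`).
#' @param lineages List of hybridogen lineage specs:
#'   `list(label, host, clonal, maternal, n)`.
#' @param remnant `NULL` or `list(species, F_drift, n, label)`.
#' @param resurrection `NULL` or `list(lineage1, lineage2, n, label)` — a
#'   cross between two lineages whose clonal genomes come from the same
#'   ghost species.
#' @param n_founder_clones Number of distinct founding clonal haplotypes per
#'   lineage (individuals are assigned one uniformly).
#' @param dropout Named per-taxon locus-dropout probabilities (delta).
#' @param call_missing Random per-call missingness probability (epsilon).
#' @param error_rate Per-call symmetric allele-flip genotyping error.
#' @param seed Mandatory integer seed; every draw is reproducible under it.
#' @return List of class `sim_scenario`.
#' @export
sim_scenario <- function(species = c("HA", "HB", "HX"),
                         L = 4000,
                         Fst = 0.85,
                         n_diagnostic = 40,
                         sexual_n = c(HA = 20, HB = 20),
                         lineages = list(
                           list(label = "HAxHB", host = "HA", clonal = "HB",
                                maternal = "HB", n = 20),
                           list(label = "HAxHX", host = "HA", clonal = "HX",
                                maternal = "HX", n = 20),
                           list(label = "HBxHX", host = "HB", clonal = "HX",
                                maternal = "HX", n = 20)),
                         remnant = list(species = "HX", F_drift = 0.05,
                                        n = 20, label = "HX"),
                         resurrection = NULL,
                         n_founder_clones = 1,
                         dropout = c(HX = 0.30),
                         call_missing = 0.01,
                         error_rate = 0,
                         seed) {
  if (missing(seed)) stop("a seed is mandatory for a simulation scenario")
  stopifnot(Fst > 0, Fst < 1, L >= 1, n_diagnostic >= 0,
            call_missing >= 0, call_missing <= 1,
            error_rate >= 0, error_rate <= 1,
            all(dropout >= 0), all(dropout <= 1),
            n_founder_clones >= 1)
  for (ln in lineages) {
    if (!all(c(ln$host, ln$clonal) %in% species))
      stop("lineage ", ln$label, " references an unknown species")
  }
  if (!is.null(remnant) && !remnant$species %in% species)
    stop("remnant species not in the species list")
  n_pairs <- choose(length(species), 2)
  if (n_diagnostic * n_pairs > L)
    stop("forced diagnostic loci exceed the number of loci")
  structure(list(species = species, L = as.integer(L), Fst = Fst,
                 n_diagnostic = as.integer(n_diagnostic), sexual_n = sexual_n,
                 lineages = lineages, remnant = remnant,
                 resurrection = resurrection,
                 n_founder_clones = as.integer(n_founder_clones),
                 dropout = dropout, call_missing = call_missing,
                 error_rate = error_rate, seed = as.integer(seed)),
            class = "sim_scenario")
}

#' Ancestral and per-species allele frequencies
#'
#' Ancestral frequencies are Uniform(0.05, 0.95); each species' frequencies
#' are Balding-Nichols draws `Beta(p (1 - F) / F, (1 - p)(1 - F) / F)`
#' around them. For each unordered species pair, `n_diagnostic` loci are
#' then forced to frequencies (1, 0) so the pair is fixed-different there;
#' the forced sets are disjoint across pairs. Frequencies refer to the
#' alternate allele (code 1).
#'
#' @param scenario A `sim_scenario` (only its frequency-model fields are
#'   used). The draw happens inside the scenario's seed when called from
#'   [simulate_dataset()]; called directly it uses the current RNG state.
#' @return List with `ancestral` (length-L vector), `species` (L x
#'   n_species matrix) and `diagnostic` (data frame: locus index, pair).
#' @export
simulate_ancestral_frequencies <- function(scenario) {
  L <- scenario$L; sp <- scenario$species; F <- scenario$Fst
  p_anc <- stats::runif(L, 0.05, 0.95)
  freq <- vapply(sp, function(s)
    stats::rbeta(L, p_anc * (1 - F) / F, (1 - p_anc) * (1 - F) / F),
    numeric(L))
  rownames(freq) <- paste0("L", seq_len(L))
  diag_df <- data.frame(locus = integer(0), speciesA = character(0),
                        speciesB = character(0), stringsAsFactors = FALSE)
  if (scenario$n_diagnostic > 0 && length(sp) >= 2) {
    pairs <- utils::combn(sp, 2)
    pool <- sample.int(L, scenario$n_diagnostic * ncol(pairs))
    for (k in seq_len(ncol(pairs))) {
      loc <- pool[(k - 1) * scenario$n_diagnostic + seq_len(scenario$n_diagnostic)]
      freq[loc, pairs[1, k]] <- 1
      freq[loc, pairs[2, k]] <- 0
      diag_df <- rbind(diag_df, data.frame(locus = loc, speciesA = pairs[1, k],
                                           speciesB = pairs[2, k],
                                           stringsAsFactors = FALSE))
    }
  }
  list(ancestral = p_anc, species = freq, diagnostic = diag_df)
}

# Hardy-Weinberg diploid sample: two independent Bernoulli(p) gametes per
# locus. Returns unordered a1/a2 code matrices (n x L).
hw_sample <- function(p, n) {
  L <- length(p)
  g1 <- matrix(stats::rbinom(n * L, 1L, rep(p, each = n)), n, L)
  g2 <- matrix(stats::rbinom(n * L, 1L, rep(p, each = n)), n, L)
  list(a1 = pmin(g1, g2), a2 = pmax(g1, g2))
}

#' Sample a sexual population under Hardy-Weinberg proportions
#'
#' @param freqs Per-locus alternate-allele frequencies of the species.
#' @param n Sample size.
#' @param species Species label (becomes taxon, truth class `"sexual"` and
#'   maternal clade).
#' @param prefix Individual-ID prefix.
#' @return List with `a1`, `a2` (n x L code matrices) and `truth` rows.
#' @export
sample_sexual_population <- function(freqs, n, species, prefix = species) {
  g <- hw_sample(freqs, n)
  ids <- sprintf("%s_%02d", prefix, seq_len(n))
  rownames(g$a1) <- rownames(g$a2) <- ids
  truth <- data.frame(individual_id = ids, class = "sexual", taxon = species,
                      origin = species, clonal_hap_id = NA_character_,
                      maternal_clade = species, stringsAsFactors = FALSE)
  c(g, list(truth = truth))
}

#' Found and sample a hybridogen lineage
#'
#' One (or a few) clonal haploid genome(s) are drawn once from the clonal
#' species' frequencies at founding. Every sampled individual, in every
#' generation, is that clonal haplotype paired with a freshly drawn host
#' gamete — the host species is a genetic parent but never a grandparent,
#' so the number of elapsed generations leaves the genotype distribution
#' unchanged and the clonal haplotype identical.
#'
#' @param clonal_freqs,host_freqs Per-locus alternate-allele frequencies of
#'   the clonal-genome species and the sexual host.
#' @param n Sample size.
#' @param label Lineage label (taxon).
#' @param maternal Maternal mtDNA clade label for the lineage.
#' @param generations Generations since founding (no genetic effect; kept to
#'   make the hemi-clonal invariance explicit and testable).
#' @param n_clones Number of founding clonal haplotypes.
#' @return List with `a1`, `a2`, `truth`, `clonal_haps` (n_clones x L, codes)
#'   and `clone_of` (clone index per individual).
#' @export
found_hybridogen_lineage <- function(clonal_freqs, host_freqs, n, label,
                                     maternal, generations = 1, n_clones = 1) {
  stopifnot(n >= 1, generations >= 1)
  L <- length(clonal_freqs)
  haps <- matrix(stats::rbinom(n_clones * L, 1L, rep(clonal_freqs, each = n_clones)),
                 n_clones, L)
  clone_of <- sample.int(n_clones, n, replace = TRUE)
  ## host gametes are redrawn every generation; only the last matters
  for (g in seq_len(generations))
    host <- matrix(stats::rbinom(n * L, 1L, rep(host_freqs, each = n)), n, L)
  hap_mat <- haps[clone_of, , drop = FALSE]
  ids <- sprintf("%s_%02d", label, seq_len(n))
  a1 <- pmin(hap_mat, host); a2 <- pmax(hap_mat, host)
  rownames(a1) <- rownames(a2) <- ids
  truth <- data.frame(individual_id = ids, class = "hybridogen", taxon = label,
                      origin = label,
                      clonal_hap_id = sprintf("%s_clone%d", label, clone_of),
                      maternal_clade = maternal, stringsAsFactors = FALSE)
  list(a1 = a1, a2 = a2, truth = truth, clonal_haps = haps, clone_of = clone_of)
}

#' Simulate a first-generation hybrid population
#'
#' Each offspring is one fresh gamete from each parental species — the
#' classical F1 expectation against which hybridogen lineages are compared
#' (a hybridogen lineage differs in that its clonal side is a single
#' founding haplotype rather than a fresh draw).
#'
#' @param freqsA,freqsB Per-locus alternate-allele frequencies of the two
#'   parental species.
#' @param n Number of offspring.
#' @param label Taxon label.
#' @param maternal Maternal clade label.
#' @return List with `a1`, `a2` and `truth` rows (class `"f1"`).
#' @export
simulate_f1_cross <- function(freqsA, freqsB, n, label = "F1",
                              maternal = NA_character_) {
  stopifnot(length(freqsA) == length(freqsB), n >= 1)
  L <- length(freqsA)
  gA <- matrix(stats::rbinom(n * L, 1L, rep(freqsA, each = n)), n, L)
  gB <- matrix(stats::rbinom(n * L, 1L, rep(freqsB, each = n)), n, L)
  ids <- sprintf("%s_%02d", label, seq_len(n))
  a1 <- pmin(gA, gB); a2 <- pmax(gA, gB)
  rownames(a1) <- rownames(a2) <- ids
  truth <- data.frame(individual_id = ids, class = "f1", taxon = label,
                      origin = label, clonal_hap_id = NA_character_,
                      maternal_clade = maternal, stringsAsFactors = FALSE)
  list(a1 = a1, a2 = a2, truth = truth)
}

#' Resurrection cross between two hemi-clonal lineages
#'
#' Offspring of a mating between two hybridogen lineages that both carry the
#' ghost species' genome: each offspring is clonal haplotype 1 plus clonal
#' haplotype 2, so (absent genotyping error) all offspring are genetically
#' identical and share at least one allele with each founding lineage at
#' every locus.
#'
#' @param hap1,hap2 Clonal haplotypes (0/1 code vectors) of the two founder
#'   lineages.
#' @param n Number of offspring.
#' @param label Taxon label for the resurrected population.
#' @param maternal Maternal clade label (the ghost species).
#' @return List with `a1`, `a2` and `truth` rows (class `"resurrected"`).
#' @export
simulate_resurrection_cross <- function(hap1, hap2, n, label = "HXres",
                                        maternal = "HX") {
  stopifnot(length(hap1) == length(hap2), n >= 1)
  a1 <- matrix(pmin(hap1, hap2), n, length(hap1), byrow = TRUE)
  a2 <- matrix(pmax(hap1, hap2), n, length(hap1), byrow = TRUE)
  ids <- sprintf("%s_%02d", label, seq_len(n))
  rownames(a1) <- rownames(a2) <- ids
  truth <- data.frame(individual_id = ids, class = "resurrected", taxon = label,
                      origin = label, clonal_hap_id = NA_character_,
                      maternal_clade = maternal, stringsAsFactors = FALSE)
  list(a1 = a1, a2 = a2, truth = truth)
}

#' Drifted remnant population of the ghost species
#'
#' Population frequencies drift from the founding ghost frequencies under a
#' Balding-Nichols model with coefficient `F_drift`, then individuals are
#' sampled under Hardy-Weinberg proportions.
#'
#' @param ghost_freqs Founding per-locus frequencies of the ghost species.
#' @param F_drift Drift coefficient in (0, 1).
#' @param n Sample size.
#' @param label Taxon label.
#' @param species Ghost species label (maternal clade and origin).
#' @return List with `a1`, `a2`, `truth` (class `"remnant"`) and `freqs`
#'   (the drifted frequencies).
#' @export
simulate_remnant_population <- function(ghost_freqs, F_drift, n, label = "HX",
                                        species = "HX") {
  stopifnot(F_drift > 0, F_drift < 1)
  a <- ghost_freqs * (1 - F_drift) / F_drift
  b <- (1 - ghost_freqs) * (1 - F_drift) / F_drift
  drifted <- ifelse(ghost_freqs <= 0, 0,
                    ifelse(ghost_freqs >= 1, 1, stats::rbeta(length(ghost_freqs), a, b)))
  g <- hw_sample(drifted, n)
  ids <- sprintf("%s_%02d", label, seq_len(n))
  rownames(g$a1) <- rownames(g$a2) <- ids
  truth <- data.frame(individual_id = ids, class = "remnant", taxon = label,
                      origin = species, clonal_hap_id = NA_character_,
                      maternal_clade = species, stringsAsFactors = FALSE)
  c(g, list(truth = truth, freqs = drifted))
}

#' Degrade a dataset with missingness and genotyping error
#'
#' Three layers, applied in order and reproducible under `seed`:
#' per-taxon locus dropout (a locus goes missing for *all* individuals of a
#' taxon with probability `delta`, emulating restriction-site loss), random
#' per-call missingness with probability `epsilon`, and symmetric allele-flip
#' genotyping error with probability `error_rate` per call (one of the two
#' gene copies is flipped; biallelic loci only).
#'
#' @param ds A `geno_dataset`.
#' @param dropout Named vector of per-taxon dropout probabilities.
#' @param epsilon Per-call missingness probability.
#' @param error_rate Per-call allele-flip probability.
#' @param seed Integer seed.
#' @return The degraded `geno_dataset`.
#' @export
apply_missingness_and_error <- function(ds, dropout = numeric(0), epsilon = 0,
                                        error_rate = 0, seed = 1L) {
  stopifnot(epsilon >= 0, epsilon <= 1, error_rate >= 0, error_rate <= 1)
  a1 <- ds$a1; a2 <- ds$a2
  with_seed(seed, {
    if (length(dropout)) {
      tx <- individual_taxa(ds)
      for (t in names(dropout)) {
        if (dropout[[t]] <= 0) next
        rows <- which(!is.na(tx) & tx == t)
        if (!length(rows)) next
        drop_loci <- which(stats::runif(n_loci(ds)) < dropout[[t]])
        a1[rows, drop_loci] <- NA_integer_
        a2[rows, drop_loci] <- NA_integer_
      }
    }
    if (epsilon > 0) {
      miss <- matrix(stats::runif(length(a1)) < epsilon, nrow(a1))
      a1[miss] <- NA_integer_; a2[miss] <- NA_integer_
    }
    if (error_rate > 0) {
      flip <- matrix(stats::runif(length(a1)) < error_rate, nrow(a1)) & !is.na(a1)
      which_copy <- matrix(stats::runif(length(a1)) < 0.5, nrow(a1))
      f1 <- flip & which_copy; f2 <- flip & !which_copy
      a1[f1] <- 1L - a1[f1]; a2[f2] <- 1L - a2[f2]
    }
  })
  geno_dataset(a1, a2, ds$loci, ds$alleles, ds$taxon_map)
}

#' Simulate a full sexual/unisexual dataset with truth
#'
#' Drives the whole generator under the scenario's seed: ancestral and
#' species frequencies, sexual samples, hybridogen lineages, the optional
#' resurrection cross and remnant population, assembly into one
#' `geno_dataset` with taxon map, then the missingness/error layers.
#'
#' @param scenario A `sim_scenario`.
#' @return List with `dataset` (a `geno_dataset`), `truth` (one row per
#'   individual: class, taxon, origin, clonal haplotype ID, maternal clade),
#'   `freqs` (the frequency model), `clonal_haps` (per lineage) and
#'   `scenario`.
#' @export
simulate_dataset <- function(scenario) {
  stopifnot(inherits(scenario, "sim_scenario"))
  with_seed(scenario$seed, {
    fr <- simulate_ancestral_frequencies(scenario)
    parts <- list()
    for (s in names(scenario$sexual_n))
      parts[[s]] <- sample_sexual_population(fr$species[, s],
                                             scenario$sexual_n[[s]], s)
    clonal_haps <- list()
    for (ln in scenario$lineages) {
      sim <- found_hybridogen_lineage(fr$species[, ln$clonal],
                                      fr$species[, ln$host],
                                      ln$n, ln$label, ln$maternal,
                                      n_clones = scenario$n_founder_clones)
      clonal_haps[[ln$label]] <- sim$clonal_haps
      parts[[ln$label]] <- sim
    }
    if (!is.null(scenario$resurrection)) {
      rs <- scenario$resurrection
      for (l in c(rs$lineage1, rs$lineage2))
        if (is.null(clonal_haps[[l]]))
          stop("resurrection references unknown lineage: ", l)
      ghost_of <- function(lbl) {
        ln <- Filter(function(x) x$label == lbl, scenario$lineages)[[1]]
        ln$clonal
      }
      if (ghost_of(rs$lineage1) != ghost_of(rs$lineage2))
        stop("resurrection cross requires both lineages to carry the same ghost genome")
      parts[[rs$label]] <- simulate_resurrection_cross(
        clonal_haps[[rs$lineage1]][1, ], clonal_haps[[rs$lineage2]][1, ],
        rs$n, rs$label, maternal = ghost_of(rs$lineage1))
    }
    if (!is.null(scenario$remnant)) {
      rm_ <- scenario$remnant
      parts[[rm_$label]] <- simulate_remnant_population(
        fr$species[, rm_$species], rm_$F_drift, rm_$n, rm_$label, rm_$species)
    }
    a1 <- do.call(rbind, lapply(parts, `[[`, "a1"))
    a2 <- do.call(rbind, lapply(parts, `[[`, "a2"))
    truth <- do.call(rbind, lapply(parts, `[[`, "truth"))
    rownames(truth) <- NULL
    loci <- data.frame(locus_id = paste0("L", seq_len(scenario$L)),
                       tag_id = paste0("tag", seq_len(scenario$L)),
                       rep_avg = 1, stringsAsFactors = FALSE)
    tm <- data.frame(individual_id = truth$individual_id, taxon = truth$taxon,
                     site = NA_character_, stringsAsFactors = FALSE)
    ds <- geno_dataset(a1, a2, loci,
                       alleles = rep(list(c("0", "1")), scenario$L),
                       taxon_map = tm)
    ds <- apply_missingness_and_error(ds, scenario$dropout,
                                      scenario$call_missing,
                                      scenario$error_rate,
                                      seed = scenario$seed + 1L)
    list(dataset = ds, truth = truth, freqs = fr, clonal_haps = clonal_haps,
         scenario = scenario)
  })
}

#' Write simulator truth as TSV
#' @param truth Truth data frame from [simulate_dataset()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth_table <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}
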