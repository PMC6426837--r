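test_that("diagnostic panels contain exactly the fixed-different loci", {
  same <- toy_dataset(rbind(c("0/0", "0/1"), c("0/0", "0/1")), taxon = c("A", "B"))
  expect_warning(panel <- diagnostic_loci(same, "A", "B"), "no diagnostic loci")
  expect_equal(length(panel$loci), 0L)

  ds <- toy_dataset(rbind(c("0/0", "0/0", "0/1"),
                          c("1/1", "1/1", "0/0")), taxon = c("A", "B"))
  panel <- diagnostic_loci(ds, "A", "B")
  expect_equal(panel$loci, c("loc1", "loc2"))
  expect_equal(unname(panel$sideA[, 1]), c(TRUE, TRUE))    # A fixed for code 0
  expect_equal(unname(panel$sideB[, 2]), c(TRUE, TRUE))    # B fixed for code 1

  sim <- simulate_dataset(sim_scenario(L = 400, n_diagnostic = 40,
                                       sexual_n = c(HA = 30, HX = 30),
                                       species = c("HA", "HX"),
                                       lineages = list(), remnant = NULL,
                                       dropout = numeric(0), call_missing = 0,
                                       seed = 8))
  panel <- diagnostic_loci(sim$dataset, "HA", "HX")
  forced <- paste0("L", sim$freqs$diagnostic$locus)
  expect_true(all(forced %in% panel$loci))
})

test_that("hybridogen scores separate fixed heterozygotes from parentals", {
  calls <- rbind(rep("0/0", 12),            # pure A-side individual
                 rep("0/1", 12),            # fixed heterozygote
                 c(rep("0/1", 11), "."),
                 rep("1/1", 12))
  rownames(calls) <- c("pureA", "hyb", "hybmiss", "pureB")
  ds <- toy_dataset(calls, taxon = c("A", "H", "H", "B"))
  ## make A and B reference-fixed opposite at all loci by adding ref individuals
  refs <- rbind(matrix("0/0", 3, 12), matrix("1/1", 3, 12))
  rownames(refs) <- paste0("r", 1:6)
  all_calls <- rbind(calls, refs)
  ds <- toy_dataset(all_calls, taxon = c("A", "H", "H", "B", rep("A", 3), rep("B", 3)))
  panel <- diagnostic_loci(ds, "A", "B")
  expect_equal(length(panel$loci), 12L)

  sA <- hybridogen_score(ds, "pureA", panel)
  expect_equal(sA$f_het, 0)
  expect_equal(sA$class, "sexual-like")

  sH <- hybridogen_score(ds, "hyb", panel)
  expect_equal(sH$f_het, 1)
  expect_equal(sH$class, "F1-hybridogen-like")

  sM <- hybridogen_score(ds, "hybmiss", panel, min_loci = 12)
  expect_equal(sM$n_panel_loci_used, 11L)
  expect_equal(sM$class, "ambiguous")
  expect_error(hybridogen_score(ds, "nobody", panel), "unknown individual")
})

test_that("hybridogen calls tolerate genotyping error; sexual parents score low", {
  ## 2% per-call allele flips; tloc = 0.05 keeps error singletons from
  ## eroding the panel. Scores are pooled over individuals and replicates.
  hyb <- sex <- c()
  for (r in 1:20) {
    sc <- sim_scenario(L = 1000, Fst = 0.2, n_diagnostic = 300, remnant = NULL,
                       sexual_n = c(HA = 15, HX = 15), species = c("HA", "HX"),
                       lineages = list(list(label = "HAxHX", host = "HA",
                                            clonal = "HX", maternal = "HX",
                                            n = 10)),
                       dropout = numeric(0), call_missing = 0,
                       error_rate = 0.02, seed = 900 + r)
    sim <- simulate_dataset(sc)
    panel <- diagnostic_loci(sim$dataset, "HA", "HX", tloc = 0.05)
    scores <- sapply(sim$truth$individual_id, function(id)
      hybridogen_score(sim$dataset, id, panel)$f_het)
    hyb <- c(hyb, scores[sim$truth$taxon == "HAxHX"])
    sex <- c(sex, scores[sim$truth$taxon %in% c("HA", "HX")])
  }
  expect_gte(mean(hyb >= 0.95), 0.99)
  expect_true(all(sex < 0.1))
})

test_that("classification is self-consistent on reference-only data", {
  sim <- simulate_dataset(sim_scenario(L = 300, lineages = list(), remnant = NULL,
                                       sexual_n = c(HA = 12, HB = 12, HX = 12),
                                       dropout = numeric(0), seed = 19))
  cl <- classify_individuals(sim$dataset, c("HA", "HB", "HX"))
  expect_true(all(cl$class == "sexual"))
  expect_equal(cl$assignment, sim$truth$taxon)
})

test_that("a mixed six-taxon dataset is recovered from truth at high accuracy", {
  sim <- simulate_dataset(sim_scenario(L = 1000, seed = 23))
  cl <- classify_individuals(sim$dataset, c("HA", "HB", "HX"))
  want <- ifelse(sim$truth$class == "hybridogen",
                 paste(substr(sim$truth$taxon, 1, 2), "x",
                       substr(sim$truth$taxon, 4, 5)),
                 sim$truth$origin)
  expect_gte(mean(cl$assignment == want), 0.98)
})

test_that("resurrected individuals classify as sexual-like members of the ghost cluster", {
  sc <- sim_scenario(L = 800, remnant = list(species = "HX", F_drift = 0.05,
                                             n = 10, label = "HX"),
                     resurrection = list(lineage1 = "HAxHX", lineage2 = "HBxHX",
                                         n = 8, label = "HXres"),
                     seed = 29)
  sim <- simulate_dataset(sc)
  cl <- classify_individuals(sim$dataset, c("HA", "HB", "HX"))
  res <- cl[sim$truth$class == "resurrected", ]
  expect_true(all(res$class == "sexual"))
  expect_true(all(res$assignment == "HX"))
})

test_that("resurrection test verdicts follow the fixed-difference counts", {
  ## P constructed from the two founder haplotypes -> counts (0, 0)
  h1 <- c(0, 1, 0, 1, 1); h2 <- c(1, 1, 0, 0, 1)
  mk_lineage <- function(h, label, n = 4) {
    host <- matrix(rbinom(n * 5, 1, 0.5), n, 5)
    hm <- matrix(h, n, 5, byrow = TRUE)
    a1 <- pmin(hm, host); a2 <- pmax(hm, host)
    rownames(a1) <- rownames(a2) <- paste0(label, seq_len(n))
    list(a1 = a1, a2 = a2, label = label)
  }
  set.seed(40)
  f1 <- mk_lineage(h1, "f1_"); f2 <- mk_lineage(h2, "f2_")
  off <- simulate_resurrection_cross(h1, h2, n = 3, label = "P")
  a1 <- rbind(f1$a1, f2$a1, off$a1); a2 <- rbind(f1$a2, f2$a2, off$a2)
  tm <- data.frame(individual_id = rownames(a1),
                   taxon = c(rep("F1", 4), rep("F2", 4), rep("P", 3)))
  ds <- geno_dataset(a1, a2, data.frame(locus_id = paste0("l", 1:5)),
                     taxon_map = tm)
  rt <- resurrection_test(ds, "P", "F1", "F2")
  expect_equal(rt$verdict, "resurrection-consistent")
  expect_equal(unname(rt$fixed_diff_counts), c(0L, 0L))
  expect_equal(unname(rt$shared_allele_fraction), c(1, 1))

  ## force one locus disjoint from both founders -> pure-remnant at tau = 0
  a1p <- a1; a2p <- a2
  a1p[9:11, 3] <- 1L; a2p[9:11, 3] <- 1L   # P becomes 1/1
  a1p[1:8, 3] <- 0L; a2p[1:8, 3] <- 0L     # founders 0/0
  ds2 <- geno_dataset(a1p, a2p, ds$loci, taxon_map = tm)
  rt2 <- resurrection_test(ds2, "P", "F1", "F2")
  expect_equal(unname(rt2$fixed_diff_counts), c(1L, 1L))
  expect_equal(rt2$verdict, "pure-remnant")
  ## but resurrection-consistent at tau = 1
  expect_equal(resurrection_test(ds2, "P", "F1", "F2", tau = 1)$verdict,
               "resurrection-consistent")
  expect_error(resurrection_test(ds2, "P", "P", "F2"), "must differ")
})

test_that("offspring of founder gametes never show fixed differences: exhaustive check", {
  ## enumerate every offspring genotype configuration over L loci; for each,
  ## take founder clonal haplotypes equal to the offspring's two gene copies
  set.seed(41)
  for (L in c(2, 6)) {
    configs <- as.matrix(expand.grid(rep(list(0:2), L)))
    host <- matrix(rbinom(2 * L, 1, 0.5), 2, L)
    for (r in seq_len(nrow(configs))) {
      g <- configs[r, ]
      h1 <- ifelse(g >= 1, 1L, 0L)   # first gene copy
      h2 <- ifelse(g == 2, 1L, 0L)   # second gene copy
      h1m <- matrix(h1, 2, L, byrow = TRUE)
      h2m <- matrix(h2, 2, L, byrow = TRUE)
      a1 <- rbind(pmin(h1m, host), pmin(h2m, host), pmin(h1, h2))
      a2 <- rbind(pmax(h1m, host), pmax(h2m, host), pmax(h1, h2))
      rownames(a1) <- rownames(a2) <- paste0("i", 1:5)
      ds <- geno_dataset(a1, a2, data.frame(locus_id = paste0("l", seq_len(L))),
                         taxon_map = data.frame(
                           individual_id = rownames(a1),
                           taxon = c("F1", "F1", "F2", "F2", "P")))
      rt <- resurrection_test(ds, "P", "F1", "F2")
      expect_equal(unname(rt$fixed_diff_counts), c(0L, 0L))
      ## agreement with the brute-force enumerator
      expect_equal(oracle_fixed_diff(ds, "P", "F1")$count, 0L)
      expect_equal(oracle_fixed_diff(ds, "P", "F2")$count, 0L)
    }
  }
})

test_that("verdicts are invariant to allele relabeling and individual order", {
  sim <- simulate_dataset(sim_scenario(L = 400, remnant = list(species = "HX",
                                                               F_drift = 0.1,
                                                               n = 7, label = "HX"),
                                       seed = 31))
  ds <- sim$dataset
  rt <- resurrection_test(ds, "HX", "HAxHX", "HBxHX")
  perm <- sample(n_individuals(ds))
  rt_perm <- resurrection_test(subset_dataset(ds, individuals = perm),
                               "HX", "HAxHX", "HBxHX")
  expect_equal(rt_perm$verdict, rt$verdict)
  expect_equal(rt_perm$fixed_diff_counts, rt$fixed_diff_counts)

  flip <- seq(1, n_loci(ds), by = 2)
  a1 <- ds$a1; a2 <- ds$a2
  a1[, flip] <- 1L - ds$a2[, flip]; a2[, flip] <- 1L - ds$a1[, flip]
  relab <- geno_dataset(a1, a2, ds$loci, taxon_map = ds$taxon_map)
  rt_rel <- resurrection_test(relab, "HX", "HAxHX", "HBxHX")
  expect_equal(rt_rel$verdict, rt$verdict)
  expect_equal(rt_rel$fixed_diff_counts, rt$fixed_diff_counts)
})

test_that("remnant-call power rises with drift and with locus count", {
  power_at <- function(F_drift, L, reps = 25) {
    hits <- 0
    for (r in 1:reps) {
      sim <- simulate_dataset(sim_scenario(
        L = L, remnant = list(species = "HX", F_drift = F_drift, n = 7,
                              label = "HX"), seed = 5000 + r))
      rt <- resurrection_test(sim$dataset, "HX", "HAxHX", "HBxHX")
      hits <- hits + (rt$verdict == "pure-remnant")
    }
    hits / reps
  }
  p_drift <- c(power_at(0.002, 1000), power_at(0.02, 1000), power_at(0.2, 1000))
  expect_true(all(diff(p_drift) >= 0))
  expect_gt(p_drift[3], p_drift[1])
  p_loci <- c(power_at(0.02, 250), power_at(0.02, 1000), power_at(0.02, 4000))
  expect_true(all(diff(p_loci) >= 0))
  expect_gt(p_loci[3], p_loci[1])
})
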