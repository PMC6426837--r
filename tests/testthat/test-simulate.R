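test_that("Balding-Nichols frequencies obey the variance identity and the F -> 0 limit", {
  set.seed(30)
  sc <- sim_scenario(L = 10000, Fst = 0.2, n_diagnostic = 0, seed = 1)
  fr <- simulate_ancestral_frequencies(sc)
  for (s in sc$species) {
    obs <- mean((fr$species[, s] - fr$ancestral)^2)
    expected <- mean(0.2 * fr$ancestral * (1 - fr$ancestral))
    expect_equal(obs, expected, tolerance = 0.1)
  }

  sc0 <- sim_scenario(L = 2000, Fst = 1e-6, n_diagnostic = 0, seed = 1)
  fr0 <- simulate_ancestral_frequencies(sc0)
  expect_lt(max(abs(fr0$species - fr0$ancestral)), 1e-2)

  expect_error(sim_scenario(Fst = 0, seed = 1), "Fst")
  expect_error(sim_scenario(Fst = 1, seed = 1), "Fst")
})

test_that("forced diagnostic loci are set to (1, 0) frequency pairs, disjointly per pair", {
  set.seed(31)
  sc <- sim_scenario(L = 500, n_diagnostic = 40, seed = 1)
  fr <- simulate_ancestral_frequencies(sc)
  expect_equal(nrow(fr$diagnostic), 40 * 3)
  expect_false(anyDuplicated(fr$diagnostic$locus) > 0)
  for (k in seq_len(nrow(fr$diagnostic))) {
    row <- fr$diagnostic[k, ]
    expect_equal(fr$species[row$locus, row$speciesA], 1)
    expect_equal(fr$species[row$locus, row$speciesB], 0)
  }
  ax <- fr$diagnostic[fr$diagnostic$speciesA == "HA" & fr$diagnostic$speciesB == "HX", ]
  expect_equal(nrow(ax), 40)
})

test_that("Hardy-Weinberg sampling matches binomial expectations", {
  set.seed(32)
  fixed <- sample_sexual_population(rep(0, 10), n = 6, species = "S")
  expect_true(all(fixed$a1 == 0) && all(fixed$a2 == 0))

  half <- sample_sexual_population(rep(0.5, 3), n = 1000, species = "S")
  het_frac <- mean(half$a1 != half$a2)
  expect_lt(abs(het_frac - 0.5), 3 * sqrt(0.25 / 3000))
  expect_true(all(half$truth$class == "sexual"))
  expect_true(all(half$truth$maternal_clade == "S"))
})

test_that("the clonal haplotype is transmitted unchanged across generations", {
  set.seed(33)
  pc <- runif(300); ph <- runif(300)
  l1 <- found_hybridogen_lineage(pc, ph, n = 12, label = "LIN", maternal = "X",
                                 generations = 1)
  l50 <- found_hybridogen_lineage(pc, ph, n = 12, label = "LIN", maternal = "X",
                                  generations = 50)
  for (l in list(l1, l50)) {
    hap <- l$clonal_haps[1, ]
    ## every individual carries the clone allele at every locus
    carries <- l$a1 == matrix(hap, 12, 300, byrow = TRUE) |
               l$a2 == matrix(hap, 12, 300, byrow = TRUE)
    expect_true(all(carries))
    expect_equal(unique(l$truth$clonal_hap_id), "LIN_clone1")
  }
  ## the clone is recoverable from offspring wherever the host side differs:
  ## at heterozygous calls, exactly one allele is the clone allele
  hap <- l50$clonal_haps[1, ]
  het <- l50$a1 != l50$a2
  expect_true(all((matrix(hap, 12, 300, byrow = TRUE) == l50$a1 |
                   matrix(hap, 12, 300, byrow = TRUE) == l50$a2)[het]))
})

test_that("hybridogens are fixed heterozygous at parental diagnostic loci and share alleles with their host", {
  for (r in 1:10) {
    sim <- simulate_dataset(sim_scenario(L = 300, n_diagnostic = 20,
                                         remnant = NULL,
                                         sexual_n = c(HA = 10, HB = 10, HX = 10),
                                         dropout = numeric(0), call_missing = 0,
                                         seed = 600 + r))
    fr <- sim$freqs
    ds <- sim$dataset
    ax <- fr$diagnostic[fr$diagnostic$speciesA == "HA" &
                        fr$diagnostic$speciesB == "HX", "locus"]
    lin <- subset_taxon(ds, "HAxHX")
    expect_true(all(lin$a1[, ax] != lin$a2[, ax]))   # f_het = 1 absent error
    ## no absolute fixed differences between a lineage and its host taxon
    expect_equal(fixed_difference_count(ds, "HAxHX", "HA")$fixed_diff_count, 0L)
    expect_equal(fixed_difference_count(ds, "HBxHX", "HB")$fixed_diff_count, 0L)
    expect_equal(fixed_difference_count(ds, "HAxHB", "HA")$fixed_diff_count, 0L)
  }
})

test_that("resurrection offspring are the two clonal haplotypes combined", {
  set.seed(34)
  h1 <- rbinom(200, 1, 0.5); h2 <- rbinom(200, 1, 0.5)
  rs <- simulate_resurrection_cross(h1, h2, n = 8)
  expect_equal(mean(rs$a1[1, ] != rs$a2[1, ]), mean(h1 != h2))
  expect_true(all(rs$a1 == rs$a1[rep(1, 8), ]))      # all offspring identical
  expect_true(all(rs$a1 == pmin(h1, h2)[col(rs$a1)] |
                  rs$a2 == pmax(h1, h2)[col(rs$a2)]))
  ## offspring share >= 1 allele with each donor haplotype at every locus
  expect_true(all(rs$a1[1, ] == h1 | rs$a2[1, ] == h1))
  expect_true(all(rs$a1[1, ] == h2 | rs$a2[1, ] == h2))
})

test_that("a resurrection cross in a full scenario passes the resurrection test", {
  sc <- sim_scenario(L = 600, remnant = NULL,
                     resurrection = list(lineage1 = "HAxHX", lineage2 = "HBxHX",
                                         n = 8, label = "HXres"),
                     seed = 77)
  sim <- simulate_dataset(sc)
  expect_true("HXres" %in% taxa(sim$dataset))
  rt <- resurrection_test(sim$dataset, "HXres", "HAxHX", "HBxHX", tau = 0)
  expect_equal(rt$verdict, "resurrection-consistent")
  expect_equal(unname(rt$fixed_diff_counts), c(0L, 0L))

  bad <- sim_scenario(L = 300, remnant = NULL,
                      resurrection = list(lineage1 = "HAxHB", lineage2 = "HAxHX",
                                          n = 4, label = "bad"), seed = 1)
  expect_error(simulate_dataset(bad), "same ghost genome")
})

test_that("remnant populations drift as configured", {
  set.seed(35)
  p <- runif(500, 0.05, 0.95)
  ## near-zero drift: frequencies essentially unchanged
  r0 <- simulate_remnant_population(p, F_drift = 1e-6, n = 10)
  expect_lt(max(abs(r0$freqs - p)), 0.01)
  expect_true(all(r0$truth$class == "remnant"))

  ## drifted H_O stays in the sexual range for extreme founding frequencies
  sim <- simulate_dataset(sim_scenario(L = 1000, seed = 42))
  Ho_rem <- observed_heterozygosity(sim$dataset, "HX")$Ho
  Ho_lin <- observed_heterozygosity(sim$dataset, "HBxHX")$Ho
  expect_lt(Ho_rem, 0.1)
  expect_gt(Ho_lin, 2 * Ho_rem)
})

test_that("missingness and error layers behave as specified", {
  set.seed(36)
  ds <- random_dataset(30, 400, miss = 0, taxa_labels = c("HX", "OTH"))
  ## identity when all rates are zero
  clean <- apply_missingness_and_error(ds, numeric(0), 0, 0, seed = 2)
  expect_identical(clean$a1, ds$a1)

  deg <- apply_missingness_and_error(ds, c(HX = 0.24), 0.01, 0, seed = 3)
  ms <- missingness_summary(deg)
  hx_frac <- ms$fraction_missing[ms$taxon == "HX"]
  expect_equal(hx_frac, 0.24 + 0.76 * 0.01, tolerance = 0.15)
  expect_equal(ms$fraction_missing[ms$taxon == "overall"],
               oracle_missing_fraction(deg))
  ## reproducible under seed
  deg2 <- apply_missingness_and_error(ds, c(HX = 0.24), 0.01, 0, seed = 3)
  expect_identical(deg$a1, deg2$a1)

  ## allele-flip error changes ~error_rate of calls, never creates missing
  err <- apply_missingness_and_error(ds, numeric(0), 0, 0.05, seed = 4)
  expect_equal(sum(missing_calls(err)), 0L)
  changed <- mean(err$a1 != ds$a1 | err$a2 != ds$a2)
  expect_equal(changed, 0.05, tolerance = 0.15)
})

test_that("the default six-taxon scenario assembles deterministically", {
  sc <- sim_scenario(L = 200, seed = 99)
  sim1 <- simulate_dataset(sc)
  sim2 <- simulate_dataset(sc)
  expect_identical(sim1$dataset$a1, sim2$dataset$a1)
  expect_identical(sim1$truth, sim2$truth)
  expect_setequal(taxa(sim1$dataset),
                  c("HA", "HB", "HX", "HAxHB", "HAxHX", "HBxHX"))
  expect_equal(nrow(sim1$truth), 120)
  expect_equal(sort(unique(sim1$truth$class)),
               c("hybridogen", "remnant", "sexual"))
  ## maternal clades follow the lineage spec exactly
  expect_true(all(sim1$truth$maternal_clade[sim1$truth$taxon == "HAxHX"] == "HX"))
  expect_true(all(sim1$truth$maternal_clade[sim1$truth$taxon == "HAxHB"] == "HB"))

  expect_error(sim_scenario(lineages = list(list(label = "bad", host = "ZZ",
                                                 clonal = "HX", maternal = "HX",
                                                 n = 2)), seed = 1),
               "unknown species")
  f <- tempfile(fileext = ".tsv")
  write_truth_table(sim1$truth, f)
  expect_equal(nrow(read.delim(f)), 120)
})
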