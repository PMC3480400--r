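stat_richness <- function(g, ids) allelic_richness(allele_counts(g, ids))

test_that("degenerate units: full-size subsample and constant statistics", {
  sim <- small_sim(k = 1, n_loci = 8, n_per_pop = 8, seed = 3,
                   missing_rate = 0)
  ids <- sim$genotypes$id
  out <- bootstrap_statistic(sim$genotypes, ids, stat_richness,
                             n_trees = 8, B = 500, seed = 1)
  expect_equal(unname(out["mean"]), stat_richness(sim$genotypes, ids))
  expect_equal(unname(out["sd"]), 0)
  expect_equal(unname(out["n_replicates"]), 1)

  out_const <- bootstrap_statistic(sim$genotypes, ids[1:5],
                                   function(g, i) 42, n_trees = 3, B = 50,
                                   seed = 2)
  expect_equal(unname(out_const["mean"]), 42)
  expect_error(bootstrap_statistic(sim$genotypes, ids[1:3], stat_richness,
                                   n_trees = 8), "fewer than n_trees")
})

test_that("compiled kernel agrees with the plain-R statistic path", {
  sim <- small_sim(k = 2, n_loci = 10, n_per_pop = 15, seed = 7,
                   missing_rate = 0.05)
  ids <- sim$genotypes$id[1:20]
  units <- tibble::tibble(unit = "u1", id = ids)
  B <- 40
  tab <- units_bootstrap(sim$genotypes, units, n_trees = 6, B = B, seed = 5)

  # same subsample indices as units_bootstrap draws internally
  idx <- divgrid:::draw_subsamples(length(ids), 6, B,
                                   divgrid:::unit_seed(5, "u1"))
  r_means <- rowMeans(vapply(seq_len(nrow(idx)), function(b) {
    sub <- ids[idx[b, ]]
    sp <- allele_counts(sim$genotypes, sub)
    c(allelic_richness(sp), shannon_index(sp), nei_gene_diversity(sp),
      observed_heterozygosity(sim$genotypes, sub))
  }, numeric(4)))
  expect_equal(tab$allelic_richness, r_means[1])
  expect_equal(tab$shannon, r_means[2])
  expect_equal(tab$nei_diversity, r_means[3])
  expect_equal(tab$obs_heterozygosity, r_means[4])
})

test_that("bootstrap richness is unbiased against the rarefaction closed form", {
  sim <- small_sim(k = 1, n_loci = 12, n_per_pop = 40, seed = 19,
                   missing_rate = 0)
  ids <- sim$genotypes$id
  B <- 1000
  out <- bootstrap_statistic(sim$genotypes, ids, stat_richness,
                             n_trees = 8, B = B, seed = 4)
  expected <- as.numeric(
    rarefaction_expected_alleles(allele_counts(sim$genotypes, ids), 16))
  se <- out["sd"] / sqrt(B)
  expect_lt(abs(out["mean"] - expected), 3 * se + 0.02)
})

test_that("grid bootstrap is deterministic and independent of unit order", {
  sim <- small_sim(k = 2, n_loci = 8, n_per_pop = 25, seed = 29)
  g <- grid_spec(10, extent = c(-85, -40, -25, 15))
  fc <- filter_cells(replicate_samples(sim$passports, g, 1), 8)
  t1 <- gridwide_bootstrap(fc$assignment, sim$genotypes, n_trees = 8,
                           B = 50, seed = 77)
  t2 <- gridwide_bootstrap(fc$assignment, sim$genotypes, n_trees = 8,
                           B = 50, seed = 77)
  expect_identical(t1, t2)

  rev_asn <- fc$assignment[rev(seq_len(nrow(fc$assignment))), ]
  t3 <- gridwide_bootstrap(rev_asn, sim$genotypes, n_trees = 8, B = 50,
                           seed = 77)
  t3 <- t3[match(t1$unit, t3$unit), ]
  expect_equal(as.data.frame(t3), as.data.frame(t1))
})

test_that("correction removes sampling-intensity bias within one population", {
  # two cells sampling the SAME gene pool at very different intensity:
  # uncorrected richness differs strongly, corrected means agree
  sim <- small_sim(k = 1, n_loci = 12, n_per_pop = 70, seed = 41,
                   missing_rate = 0)
  ids <- sim$genotypes$id
  units <- tibble::tibble(
    unit = rep(c("sparse", "dense"), c(8, 62)),
    id = c(ids[1:8], ids[9:70]))
  direct <- units_direct(sim$genotypes, units)
  boot <- units_bootstrap(sim$genotypes, units, n_trees = 8, B = 1000,
                          seed = 6)
  gap_direct <- abs(diff(direct$allelic_richness))
  gap_boot <- abs(diff(boot$allelic_richness))
  expect_gt(gap_direct, 1)       # census richness grows with sample size
  expect_lt(gap_boot, 0.25)      # corrected values are comparable
  expect_lt(gap_boot, gap_direct / 4)
})

test_that("validation regression is exact on analytic input and converges in B", {
  sim <- small_sim(k = 3, n_loci = 10, n_per_pop = 30, seed = 43,
                   missing_rate = 0)
  g <- grid_spec(10, extent = c(-85, -40, -25, 15))
  fc <- filter_cells(replicate_samples(sim$passports, g, 1), 8)
  units <- tibble::tibble(unit = as.character(fc$assignment$cell),
                          id = fc$assignment$id)
  unit_ids <- split(units$id, units$unit)
  keys <- names(unit_ids)[vapply(unit_ids, length, integer(1)) >= 8]

  analytic <- tibble::tibble(
    unit = keys,
    allelic_richness = vapply(keys, function(u) {
      as.numeric(rarefaction_expected_alleles(
        allele_counts(sim$genotypes, unit_ids[[u]]), 16))
    }, numeric(1)))
  v <- validate_against_rarefaction(analytic, sim$genotypes, units, g = 16)
  expect_equal(unname(v["slope"]), 1)
  expect_equal(unname(v["pearson_r"]), 1)

  # Monte-Carlo error shrinks as B grows (deterministic given the seed)
  rs <- vapply(c(10, 100, 1000), function(B) {
    tab <- units_bootstrap(sim$genotypes, units, n_trees = 8, B = B,
                           seed = 13)
    unname(validate_against_rarefaction(tab, sim$genotypes,
                                        units, 16)["pearson_r"])
  }, numeric(1))
  expect_true(all(diff(abs(rs - 1)) < 0))
  expect_gt(rs[3], 0.99)
})
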