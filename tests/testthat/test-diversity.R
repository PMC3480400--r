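test_that("allele counting excludes missing pairs and sums gene copies", {
  g1 <- geno_tbl(a = list(L1 = c(152, 158)))
  sp1 <- allele_counts(g1)
  expect_equal(sp1$count, c(1L, 1L))
  expect_equal(sum(sp1$count), 2)

  g2 <- geno_tbl(a = list(L1 = c(152, 152)), b = list(L1 = c(152, 158)))
  sp2 <- allele_counts(g2)
  expect_equal(sp2$count[sp2$allele == 152], 3L)
  expect_equal(sp2$count[sp2$allele == 158], 1L)

  g3 <- geno_tbl(a = list(L1 = c(152, 152), L2 = c(10, 12)),
                 b = list(L1 = c(NA, NA), L2 = c(10, 10)))
  sp3 <- allele_counts(g3)
  expect_equal(sum(sp3$count[sp3$locus == "L1"]), 2)  # b's missing pair absent
  expect_equal(sum(sp3$count[sp3$locus == "L2"]), 4)
})

test_that("closed-form identities of the diversity statistics hold", {
  mono <- geno_tbl(a = list(L1 = c(1, 1), L2 = c(5, 5)),
                   b = list(L1 = c(1, 1), L2 = c(5, 5)))
  spm <- allele_counts(mono)
  expect_equal(allelic_richness(spm), 1.0)
  expect_equal(nei_gene_diversity(spm), 0.0)
  expect_equal(shannon_index(spm), 0.0)
  expect_equal(observed_heterozygosity(mono), 0.0)

  # two loci with 3 and 5 alleles -> richness 4
  g35 <- geno_tbl(a = list(L1 = c(1, 2), L2 = c(1, 2)),
                  b = list(L1 = c(3, 3), L2 = c(3, 4)),
                  c = list(L1 = c(1, 1), L2 = c(5, 5)))
  expect_equal(allelic_richness(allele_counts(g35)), 4.0)

  # 0.5/0.5 -> H = 0.5, Shannon = ln 2; four equifrequent -> 0.75, ln 4
  half <- tibble::tibble(locus = "L1", allele = c(1L, 2L), count = c(8L, 8L))
  expect_equal(nei_gene_diversity(half), 0.5)
  expect_equal(shannon_index(half), log(2))
  quarter <- tibble::tibble(locus = "L1", allele = 1:4, count = rep(4L, 4))
  expect_equal(nei_gene_diversity(quarter), 0.75)
  expect_equal(shannon_index(quarter), log(4))

  allhet <- geno_tbl(a = list(L1 = c(1, 2)), b = list(L1 = c(3, 4)))
  expect_equal(observed_heterozygosity(allhet), 1.0)
})

test_that("observed heterozygosity matches HWE expectation in simulation", {
  n <- 10000
  draws <- withr::with_seed(31, matrix(sample(c(1L, 2L), 2 * n, TRUE), n))
  g <- tibble::tibble(id = paste0("i", 1:n),
                      L1_1 = draws[, 1], L1_2 = draws[, 2])
  expect_equal(observed_heterozygosity(g), 0.5, tolerance = 0.015 / 0.5)
})

test_that("richness equals brute-force distinct-allele counting", {
  sim <- small_sim(k = 2, n_loci = 8, n_per_pop = 15, seed = 13)
  sp <- allele_counts(sim$genotypes)
  brute <- mean(vapply(split(sp$allele, sp$locus),
                       function(a) length(unique(a)), numeric(1)))
  expect_equal(allelic_richness(sp), brute)
})

test_that("rarefaction closed form matches its boundary cases and monotonicity", {
  # census sample: expectation equals the exact allele count
  sp <- tibble::tibble(locus = "L1", allele = 1:3, count = c(4L, 5L, 7L))
  expect_equal(as.numeric(rarefaction_expected_alleles(sp, 16)), 3)

  sp2 <- tibble::tibble(locus = "L1", allele = 1:2, count = c(1L, 15L))
  expect_equal(as.numeric(rarefaction_expected_alleles(sp2, 16)), 2)

  # {8, 8}, g = 2: 2 * (1 - C(8,2)/C(16,2)) = 23/15
  sp3 <- tibble::tibble(locus = "L1", allele = 1:2, count = c(8L, 8L))
  expect_equal(as.numeric(rarefaction_expected_alleles(sp3, 2)),
               2 * (1 - choose(8, 2) / choose(16, 2)))

  # monotone non-decreasing in g
  vals <- vapply(1:16, function(g) {
    as.numeric(rarefaction_expected_alleles(sp3, g))
  }, numeric(1))
  expect_true(all(diff(vals) >= -1e-12))

  # loci below g are excluded and flagged
  sp4 <- dplyr::bind_rows(sp3, tibble::tibble(locus = "L2", allele = 1L,
                                              count = 4L))
  r <- rarefaction_expected_alleles(sp4, 16)
  expect_identical(attr(r, "excluded_loci"), "L2")
  expect_error(rarefaction_expected_alleles(sp4, 0), "g must be")
})

test_that("private alleles are exactly the single-unit alleles", {
  same <- tidyr::expand_grid(unit = c("A", "B", "C"),
                             tibble::tibble(locus = "L1", allele = 1:3,
                                            count = 2L))
  pa <- private_alleles(same)
  expect_equal(pa$private_alleles, rep(0, 3))

  # one unique allele in A over 4 loci -> 1/4
  spA <- dplyr::bind_rows(
    tidyr::expand_grid(unit = c("A", "B"),
                       tibble::tibble(locus = paste0("L", 1:4), allele = 1L,
                                      count = 3L)),
    tibble::tibble(unit = "A", locus = "L1", allele = 999L, count = 1L))
  pa2 <- private_alleles(spA)
  expect_equal(pa2$private_alleles[pa2$unit == "A"], 1 / 4)
  expect_equal(pa2$private_alleles[pa2$unit == "B"], 0)

  # random 3-group spectra agree with a brute-force set-difference count
  sim <- small_sim(k = 3, n_loci = 6, n_per_pop = 10, seed = 17)
  ids <- split(sim$truth$id, sim$truth$pop)
  sp <- purrr::imap_dfr(ids, function(ii, p) {
    tibble::tibble(unit = p, allele_counts(sim$genotypes, ii))
  })
  pa3 <- private_alleles(sp)
  for (u in unique(sp$unit)) {
    mine <- sp[sp$unit == u, ]
    other <- sp[sp$unit != u, ]
    brute <- mean(vapply(split(mine, mine$locus), function(d) {
      sum(!paste(d$locus, d$allele) %in%
            paste(other$locus, other$allele))
    }, numeric(1)))
    expect_equal(pa3$private_alleles[pa3$unit == u], brute)
  }
})

test_that("locally common alleles honor occupancy and frequency thresholds", {
  # 4 cells; allele 9 in exactly 1 cell at frequency 0.10
  base <- tidyr::expand_grid(unit = c("c1", "c2", "c3", "c4"),
                             tibble::tibble(locus = "L1", allele = 1:2,
                                            count = 9L))
  sp <- dplyr::bind_rows(base, tibble::tibble(unit = "c1", locus = "L1",
                                              allele = 9L, count = 2L))
  lc <- locally_common_alleles(sp, occupancy_max_frac = 0.25)
  expect_equal(lc$locally_common[lc$unit == "c1"], 1)  # 25% <= 25%, 0.1 >= 0.05
  expect_equal(lc$locally_common[lc$unit == "c2"], 0)  # ubiquitous alleles

  # allele present everywhere is counted nowhere
  lc_all <- locally_common_alleles(base, occupancy_max_frac = 0.25)
  expect_true(all(lc_all$locally_common == 0))

  # cluster mode: frequency exactly 5% fails the strict comparison
  cl <- dplyr::bind_rows(
    tidyr::expand_grid(unit = paste0("k", 1:10),
                       tibble::tibble(locus = "L1", allele = 1:2,
                                      count = 19L)),
    tibble::tibble(unit = c("k1", "k2"), locus = "L1", allele = 9L,
                   count = 2L))
  # k1: counts 19,19,2 -> freq(9) = 2/40 = 0.05 exactly
  lc_cl <- locally_common_alleles(cl, occupancy_max_units = 2, strict = TRUE)
  expect_equal(lc_cl$locally_common[lc_cl$unit == "k1"], 0)
  lc_cl2 <- locally_common_alleles(cl, occupancy_max_units = 2,
                                   strict = FALSE)
  expect_equal(lc_cl2$locally_common[lc_cl2$unit == "k1"], 1)

  expect_warning(
    locally_common_alleles(sp[sp$unit == "c1", ], occupancy_max_frac = 0.25),
    "single unit")
  expect_error(locally_common_alleles(sp), "exactly one")
})

test_that("statistics are invariant to allele relabeling and individual order", {
  sim <- small_sim(k = 2, n_loci = 10, n_per_pop = 12, seed = 23)
  g <- sim$genotypes
  base <- diversity_summary(g)

  shuffled <- g[withr::with_seed(1, sample(nrow(g))), ]
  expect_equal(diversity_summary(shuffled)[-1], base[-1])

  relab <- g
  for (nm in setdiff(names(relab), "id")) {
    relab[[nm]] <- relab[[nm]] * 7L + 3L  # injective relabeling
  }
  expect_equal(diversity_summary(relab)[-1], base[-1])

  # entropy/diversity bounds: H <= 1 - 1/k with equality iff uniform
  sp <- allele_counts(g)
  for (d in split(sp, sp$locus)) {
    k <- nrow(d)
    H <- 1 - sum((d$count / sum(d$count))^2)
    expect_lte(H, 1 - 1 / k + 1e-12)
    if (length(unique(d$count)) == 1) expect_equal(H, 1 - 1 / k)
  }
  expect_gte(shannon_index(sp), 0)
})
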