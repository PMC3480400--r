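test_that("allele matrix encodes dosages and normalizes per locus", {
  g <- geno_tbl(a = list(L1 = c(152, 152), L2 = c(1, 2)),
                b = list(L1 = c(152, 158), L2 = c(2, 2)))
  X <- build_allele_matrix(g)
  expect_equal(X["a", "L1.152"], 1)
  expect_equal(X["b", "L1.152"], 0.5)
  expect_equal(X["b", "L1.158"], 0.5)
  meta <- attr(X, "meta")
  for (loc in unique(meta$locus)) {
    expect_equal(unname(rowSums(X[, meta$locus == loc, drop = FALSE])),
                 c(1, 1))
  }

  # missing loci are imputed with column means
  g2 <- geno_tbl(a = list(L1 = c(1, 1)), b = list(L1 = c(1, 2)),
                 c = list(L1 = c(NA, NA)))
  X2 <- build_allele_matrix(g2)
  expect_equal(unname(X2["c", ]), unname(colMeans(X2[c("a", "b"), ])))
})

test_that("BIC scan recovers planted cluster counts", {
  sim <- small_sim(k = 3, n_loci = 20, n_per_pop = 25, seed = 37, F = 0.3)
  X <- build_allele_matrix(sim$genotypes)
  scan <- kmeans_bic_scan(X, k_range = 1:8, seed = 2)
  expect_equal(scan$chosen_k, 3)
  truthpop <- sim$truth$pop[match(rownames(X), sim$truth$id)]
  expect_gt(mclust::adjustedRandIndex(scan_labels(scan, 3), truthpop), 0.9)

  # duplicating every row leaves the chosen k unchanged
  g2 <- dplyr::bind_rows(sim$genotypes,
                         dplyr::mutate(sim$genotypes,
                                       id = paste0(id, "_dup")))
  scan2 <- kmeans_bic_scan(build_allele_matrix(g2), k_range = 1:8, seed = 2)
  expect_equal(scan2$chosen_k, 3)

  # k = 1 BIC matches the closed form n*log(WSS/n) + log(n)
  scores <- scan$scores
  n <- nrow(scores)
  bic1 <- n * log(sum(scale(scores, scale = FALSE)^2) / n) + log(n)
  expect_equal(scan$curve$bic[scan$curve$k == 1], bic1)

  expect_error(scan_labels(scan, 99), "not scanned")
})

test_that("DAPC posteriors are calibrated, row-stochastic and symmetric", {
  # well-separated clusters -> near-certain membership
  sim <- small_sim(k = 2, n_loci = 25, n_per_pop = 30, seed = 53, F = 0.3)
  X <- build_allele_matrix(sim$genotypes)
  truthpop <- sim$truth$pop[match(rownames(X), sim$truth$id)]
  dap <- dapc_membership(X, truthpop)
  expect_true(all(abs(rowSums(dap$membership) - 1) < 1e-9))
  own <- dap$membership[cbind(seq_along(truthpop), truthpop)]
  expect_gt(mean(own > 0.99), 0.95)

  # points exactly midway between two mirror-image clusters sit at 0.5/0.5
  # (one midpoint labelled into each cluster keeps the training symmetric)
  base <- withr::with_seed(5, matrix(rnorm(40 * 4), 40, 4))
  Xs <- rbind(base + 10, -(base + 10), 0, 0)  # exact mirror symmetry
  rownames(Xs) <- paste0("i", seq_len(nrow(Xs)))
  lab <- rep(c(1, 2, 1, 2), c(40, 40, 1, 1))
  dap2 <- dapc_membership(Xs, lab, n_pcs = 4)
  expect_equal(unname(dap2$membership[81, ]), c(0.5, 0.5), tolerance = 1e-6)
  expect_equal(unname(dap2$membership[82, ]), c(0.5, 0.5), tolerance = 1e-6)

  expect_error(dapc_membership(X, c(1, rep(2, nrow(X) - 1))),
               "at least 2 members")
})

test_that("cluster spectra respect the inclusive membership threshold", {
  g <- geno_tbl(a = list(L1 = c(1, 1)), b = list(L1 = c(1, 2)),
                c = list(L1 = c(2, 2)), d = list(L1 = c(2, 2)))
  M <- rbind(c(1, 0), c(0.7, 0.3), c(0.3, 0.7), c(0.45, 0.55))
  dimnames(M) <- list(g$id, c("A", "B"))
  sp <- cluster_spectra(g, M, min_membership = 0.7)
  members <- attr(sp, "members")
  expect_setequal(members$A, c("a", "b"))  # 0.7 retained (inclusive)
  expect_setequal(members$B, "c")          # 0.55 dropped
  # no filtering when all memberships are certain
  M2 <- rbind(c(1, 0), c(1, 0), c(0, 1), c(0, 1))
  dimnames(M2) <- list(g$id, c("A", "B"))
  sp2 <- cluster_spectra(g, M2, min_membership = 0.7)
  expect_equal(lengths(attr(sp2, "members")), c(A = 2L, B = 2L))

  # bootstrap sample-size rule: n_trees = smallest retained cluster
  sim <- small_sim(k = 2, n_loci = 8, n_per_pop = c(12, 20), seed = 59)
  truthpop <- sim$truth$pop[match(sim$genotypes$id, sim$truth$id)]
  M3 <- cbind(as.numeric(truthpop == 1), as.numeric(truthpop == 2))
  dimnames(M3) <- list(sim$genotypes$id, c("p1", "p2"))
  cd <- cluster_diversity(sim$genotypes, M3, B = 20, seed = 1)
  expect_equal(attr(cd, "config")$n_trees, 12)
})

test_that("Nei 1972 distance matches hand computation and is symmetric", {
  spAB <- dplyr::bind_rows(
    tibble::tibble(unit = "A", locus = "L1", allele = 1L, count = 4L),
    tibble::tibble(unit = "B", locus = "L1", allele = 1:2, count = c(2L, 2L)))
  D <- nei_distance_matrix(spAB)
  expect_equal(D["A", "B"], -log(0.5 / sqrt(1 * 0.5)))
  expect_equal(D["A", "B"], 0.34657359, tolerance = 1e-6)
  expect_equal(D["A", "A"], 0)

  # identical spectra -> 0
  spSame <- tidyr::expand_grid(unit = c("A", "B"),
                               tibble::tibble(locus = "L1", allele = 1:3,
                                              count = c(2L, 3L, 5L)))
  expect_equal(max(abs(nei_distance_matrix(spSame))), 0)

  # symmetric on random spectra
  sim <- small_sim(k = 3, n_loci = 6, n_per_pop = 10, seed = 61)
  ids <- split(sim$truth$id, sim$truth$pop)
  sp <- purrr::imap_dfr(ids, function(ii, p) {
    tibble::tibble(unit = p, allele_counts(sim$genotypes, ii))
  })
  Dr <- nei_distance_matrix(sp)
  expect_equal(Dr, t(Dr))
  expect_true(all(Dr >= 0))

  # disjoint allele sets -> infinite distance with a warning
  spDis <- dplyr::bind_rows(
    tibble::tibble(unit = "A", locus = "L1", allele = 1L, count = 2L),
    tibble::tibble(unit = "B", locus = "L1", allele = 2L, count = 2L))
  expect_warning(Dd <- nei_distance_matrix(spDis), "disjoint")
  expect_equal(Dd["A", "B"], Inf)
})

test_that("complete linkage follows hand agglomeration and exports Newick", {
  D <- matrix(c(0, 1, 5, 1, 0, 5, 5, 5, 0), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- complete_linkage_tree(D)
  expect_equal(tr$hclust$height, c(1, 5))
  first <- tr$hclust$merge[1, ]
  expect_setequal(abs(first), c(1, 2))  # a and b merge first
  phy <- ape::read.tree(text = tr$newick)
  expect_setequal(phy$tip.label, c("a", "b", "c"))

  # ultrametric input is represented exactly
  Du <- matrix(4, 4, 4,
               dimnames = list(letters[1:4], letters[1:4]))
  Du[1, 2] <- Du[2, 1] <- 1
  Du[3, 4] <- Du[4, 3] <- 2
  diag(Du) <- 0
  tru <- complete_linkage_tree(Du)
  expect_equal(tru$cophenetic_r, 1)
  expect_true(all(diff(tru$hclust$height) >= 0))
})

test_that("Mantel test matches vegan and the exhaustive permutation null", {
  sim <- small_sim(k = 2, n_loci = 10, n_per_pop = 10, seed = 67)
  Dg <- geo_distance_matrix(sim$passports)
  Dn <- nei_individual_distance(sim$genotypes)

  # self-comparison: r = 1 and the smallest attainable p
  self <- mantel_test(Dg, Dg + 0, n_perm = 199, seed = 1)
  expect_equal(self$r, 1)
  expect_equal(self$p_value, 1 / 200)

  mt <- mantel_test(Dg, Dn, n_perm = 999, seed = 5)
  vg <- vegan::mantel(as.dist(Dg), as.dist(Dn), permutations = 999)
  expect_equal(mt$r, unname(vg$statistic))
  expect_lt(abs(mt$p_value - vg$signif), 0.05)

  # n = 5: Monte-Carlo p converges to the exhaustive 5!-permutation null
  D1 <- as.matrix(dist(withr::with_seed(8, matrix(rnorm(10), 5))))
  D2 <- as.matrix(dist(withr::with_seed(9, matrix(rnorm(10), 5))))
  ut <- upper.tri(D1)
  P <- perms_of(5)
  r_all <- apply(P, 1, function(p) cor(D1[ut], D2[p, p][ut]))
  r_obs <- cor(D1[ut], D2[ut])
  p_exact <- mean(r_all >= r_obs - 1e-12)
  mc <- mantel_test(D1, D2, n_perm = 19999, seed = 3)
  expect_lt(abs(mc$p_value - p_exact), 0.02)

  expect_error(mantel_test(matrix(1, 4, 4), Dg[1:4, 1:4]), "constant")
})
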