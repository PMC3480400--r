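# Genetic cluster discovery and characterization: k-means on PCA scores with
# a BIC scan, DAPC-style membership probabilities, Nei (1972) distances,
# complete-linkage dendrogram and Mantel tests.

#' Individuals-by-alleles dosage matrix
#'
#' One column per observed allele; a homozygote contributes 1 to its allele's
#' column, a heterozygote 0.5 to each of its two columns, so non-missing rows
#' sum to 1 within each locus. Missing genotypes are imputed with the column
#' means of the non-missing individuals (the usual PCA-ready encoding).
#'
#' @param genotypes Genotype tibble (at least 2 individuals).
#' @return Numeric matrix (rownames = ids) with a `meta` attribute: tibble
#'   `locus`, `allele` describing the columns.
#' @export
build_allele_matrix <- function(genotypes) {
  validate_genotypes(genotypes)
  stopifnot(nrow(genotypes) >= 2)
  enc <- encode_genotypes(genotypes)
  n <- nrow(enc$a1)
  X <- matrix(0, n, enc$n_codes)
  add_half <- function(codes) {
    ok <- which(codes > 0)
    X[cbind(ok, codes[ok])] <<- X[cbind(ok, codes[ok])] + 0.5
  }
  for (j in seq_along(enc$loci)) {
    add_half(enc$a1[, j])
    add_half(enc$a2[, j])
  }
  # mean-impute missing loci per individual
  for (j in seq_along(enc$loci)) {
    miss <- enc$a1[, j] == 0
    if (any(miss)) {
      cols <- which(enc$loc_of_code == j)
      mu <- colMeans(X[!miss, cols, drop = FALSE])
      X[miss, cols] <- rep(mu, each = sum(miss))
    }
  }
  rownames(X) <- enc$ids
  colnames(X) <- paste0(enc$loci[enc$loc_of_code], ".", enc$code_allele)
  attr(X, "meta") <- tibble::tibble(locus = enc$loci[enc$loc_of_code],
                                    allele = enc$code_allele)
  X
}

# PCA scores of a centered allele matrix. n_pcs = "auto" keeps the smallest
# number of axes explaining >= var_target of the variance; "kaiser" keeps
# the axes with above-average eigenvalue. Zero-variance columns (monomorphic
# loci) are dropped first.
pca_scores <- function(X, n_pcs = "auto", var_target = 0.95) {
  Xc <- scale(X, center = TRUE, scale = FALSE)
  keep <- apply(Xc, 2, function(v) any(v != 0))
  if (!all(keep)) {
    message("dropping ", sum(!keep), " zero-variance column(s) before PCA")
    Xc <- Xc[, keep, drop = FALSE]
  }
  if (!ncol(Xc)) stop("rank-0 matrix: no variable columns", call. = FALSE)
  sv <- svd(Xc)
  pos <- sv$d > max(sv$d) * 1e-10
  varexp <- sv$d[pos]^2 / sum(sv$d[pos]^2)
  if (identical(n_pcs, "auto")) {
    n_pcs <- which(cumsum(varexp) >= var_target)[1]
  } else if (identical(n_pcs, "kaiser")) {
    n_pcs <- max(1L, sum(varexp > mean(varexp)))
  }
  n_pcs <- min(n_pcs, sum(pos))
  scores <- sv$u[, seq_len(n_pcs), drop = FALSE] %*%
    diag(sv$d[seq_len(n_pcs)], n_pcs)
  rownames(scores) <- rownames(X)
  list(scores = scores, n_pcs = n_pcs, var_explained = varexp)
}

#' k-means cluster scan with BIC
#'
#' Runs k-means (best of `n_starts` starts) on retained PCA scores of the
#' allele matrix for each `k` and scores solutions with
#' \eqn{BIC(k) = n \ln(WSS_k / n) + k \ln n}. The suggested number of
#' clusters is the elbow of the curve, read as the first flattening (the
#' smallest k whose next improvement falls below 5% of the curve range); the
#' final choice remains with the user.
#'
#' @param X Allele matrix from [build_allele_matrix()].
#' @param k_range Integer vector of cluster counts to scan.
#' @param n_pcs Number of PCA axes to keep; `"kaiser"` (default) retains
#'   axes with above-average eigenvalue — keeping the weak tail of
#'   noise axes blurs the BIC elbow — while `"auto"` uses the smallest
#'   number explaining 95% of variance.
#' @param n_starts Random starts per k (default 30).
#' @param seed Integer seed.
#' @return A `divgrid_bic` object: BIC curve, suggested `chosen_k`, cluster
#'   labels per scanned k, and the retained scores.
#' @export
kmeans_bic_scan <- function(X, k_range = 1:15, n_pcs = "kaiser",
                            n_starts = 30, seed = 1) {
  p <- pca_scores(X, n_pcs)
  n <- nrow(p$scores)
  k_range <- sort(unique(as.integer(k_range)))
  k_range <- k_range[k_range >= 1 & k_range < n]
  labels <- matrix(NA_integer_, n, length(k_range),
                   dimnames = list(rownames(X), paste0("k", k_range)))
  bic <- withr::with_seed(seed, vapply(seq_along(k_range), function(i) {
    k <- k_range[i]
    if (k == 1) {
      wss <- sum(scale(p$scores, scale = FALSE)^2)
      labels[, i] <<- 1L
    } else {
      km <- kmeans(p$scores, centers = k, nstart = n_starts, iter.max = 50)
      wss <- km$tot.withinss
      labels[, i] <<- km$cluster
    }
    n * log(wss / n) + k * log(n)
  }, numeric(1)))
  # Suggested k = the elbow, read as the first flattening: the smallest k
  # whose next BIC improvement drops below 5% of the curve's range (or is an
  # increase). Robust both to curves that keep drifting down in a noisy
  # plateau and to curves that turn back up; the final choice of k remains
  # with the user.
  improvement <- -diff(bic)
  flat <- which(improvement < 0.05 * diff(range(bic)))
  chosen_k <- if (length(flat)) k_range[flat[1]] else k_range[length(k_range)]
  structure(list(curve = tibble::tibble(k = k_range, bic = bic),
                 chosen_k = chosen_k, labels = labels,
                 n_pcs = p$n_pcs, scores = p$scores),
            class = "divgrid_bic")
}

#' Cluster labels from a BIC scan
#'
#' @param scan A `divgrid_bic` object.
#' @param k Number of clusters (default the scan's suggestion).
#' @return Integer vector of cluster labels, named by individual.
#' @export
scan_labels <- function(scan, k = scan$chosen_k) {
  col <- match(paste0("k", k), colnames(scan$labels))
  if (is.na(col)) stop("k = ", k, " was not scanned", call. = FALSE)
  setNames(scan$labels[, col], rownames(scan$labels))
}

#' @export
print.divgrid_bic <- function(x, ...) {
  cat("k-means BIC scan over k = ", min(x$curve$k), "..", max(x$curve$k),
      " on ", x$n_pcs, " PCs; suggested k = ", x$chosen_k, "\n", sep = "")
  invisible(x)
}

#' DAPC-style membership probabilities
#'
#' Discriminant analysis of principal components: linear discriminant
#' analysis on retained PCA scores of the allele matrix, for given cluster
#' labels. Memberships are the Gaussian posterior probabilities under the
#' shared within-group covariance with uniform priors; rows sum to 1 and the
#' assigned cluster is the row argmax.
#'
#' @inheritParams kmeans_bic_scan
#' @param labels Cluster labels (integer or factor), one per individual; every
#'   cluster needs at least 2 members.
#' @param n_da Number of discriminant axes to retain for scores (default
#'   `k - 1`).
#' @return A `divgrid_dapc` object: `membership` (row-stochastic matrix),
#'   `assigned` (argmax labels), discriminant `scores`, `n_pcs`.
#' @export
dapc_membership <- function(X, labels, n_pcs = "auto", n_da = NULL) {
  labels <- as.factor(labels)
  if (any(table(labels) < 2)) {
    stop("every cluster needs at least 2 members", call. = FALSE)
  }
  k <- nlevels(labels)
  if (is.null(n_da)) n_da <- k - 1
  stopifnot(n_da >= 1, n_da <= k - 1)
  p <- pca_scores(X, n_pcs)
  fit <- suppressWarnings(
    MASS::lda(p$scores, grouping = labels, prior = rep(1 / k, k)))
  pred <- stats::predict(fit, p$scores)
  membership <- pred$posterior
  rownames(membership) <- rownames(X)
  structure(list(membership = membership,
                 assigned = setNames(
                   levels(labels)[max.col(membership)], rownames(X)),
                 scores = pred$x[, seq_len(min(n_da, ncol(pred$x))),
                                 drop = FALSE],
                 labels = labels, n_pcs = p$n_pcs, n_da = n_da),
            class = "divgrid_dapc")
}

#' @export
print.divgrid_dapc <- function(x, ...) {
  cat("DAPC membership: ", nrow(x$membership), " individuals x ",
      ncol(x$membership), " clusters (", x$n_pcs, " PCs)\n", sep = "")
  cat(sprintf("  %.1f%% of individuals with max membership > 0.7\n",
              100 * mean(apply(x$membership, 1, max) > 0.7)))
  invisible(x)
}

#' Per-cluster allele spectra of confidently assigned individuals
#'
#' Restricts each cluster to members whose membership probability for it is
#' at least `min_membership` (inclusive), then stacks per-cluster allele
#' counts into a `spectra_by_unit` tibble usable by [private_alleles()],
#' [locally_common_alleles()] and [nei_distance_matrix()].
#'
#' @param genotypes Genotype tibble.
#' @param dapc A `divgrid_dapc` object (or a row-stochastic membership
#'   matrix with individuals as rownames).
#' @param min_membership Membership threshold (default 0.7).
#' @return Tibble `unit`, `locus`, `allele`, `count`; the `members` attribute
#'   maps clusters to retained ids.
#' @export
cluster_spectra <- function(genotypes, dapc, min_membership = 0.7) {
  M <- if (inherits(dapc, "divgrid_dapc")) dapc$membership else dapc
  assigned <- colnames(M)[max.col(M)]
  keep <- M[cbind(seq_len(nrow(M)), max.col(M))] >= min_membership
  members <- split(rownames(M)[keep], assigned[keep])
  empty <- setdiff(colnames(M), names(members))
  if (length(empty)) {
    warning("cluster(s) emptied by the membership threshold: ",
            paste(empty, collapse = ", "))
  }
  out <- purrr::imap_dfr(members, function(ids, cl) {
    sp <- allele_counts(genotypes, ids)
    tibble::tibble(unit = cl, sp)
  })
  attr(out, "members") <- members
  out
}

#' Bootstrap-corrected diversity per cluster
#'
#' Cluster-level analogue of [gridwide_bootstrap()]: statistics averaged over
#' `B` subsamples of `n_trees` individuals per cluster. By default `n_trees`
#' is the size of the smallest retained cluster, locally common alleles use
#' the cluster convention (allele in at most 2 clusters, frequency strictly
#' above 5%).
#'
#' @inheritParams cluster_spectra
#' @param n_trees Subsample size; `"auto"` (default) uses the smallest
#'   retained cluster size.
#' @param B,seed Bootstrap replicates and master seed.
#' @export
cluster_diversity <- function(genotypes, dapc, min_membership = 0.7,
                              n_trees = "auto", B = 1000, seed = 1) {
  sp <- cluster_spectra(genotypes, dapc, min_membership)
  members <- attr(sp, "members")
  units <- purrr::imap_dfr(members, function(ids, cl) {
    tibble::tibble(unit = cl, id = ids)
  })
  if (identical(n_trees, "auto")) {
    n_trees <- min(vapply(members, length, integer(1)))
  }
  units_bootstrap(genotypes, units, n_trees = n_trees, B = B, seed = seed,
                  occupancy_max_units = 2, freq_min = 0.05, strict = TRUE)
}

#' Nei (1972) standard genetic distance between units
#'
#' \eqn{D = -\ln\left(J_{xy} / \sqrt{J_x J_y}\right)} with the J statistics
#' pooled over loci: \eqn{J_{xy} = \sum_L \sum_i x_i y_i} etc., computed on
#' allele frequencies per locus. Loci are restricted pairwise to those with
#' data in both units. D is non-negative and zero for identical spectra; it
#' is not guaranteed to satisfy the triangle inequality. Disjoint allele sets
#' give `Inf` with a warning.
#'
#' @param spectra_by_unit Tibble `unit`, `locus`, `allele`, `count`.
#' @return Symmetric distance matrix with units as dimnames.
#' @export
nei_distance_matrix <- function(spectra_by_unit) {
  units <- spectra_units(spectra_by_unit)
  if (length(units) < 2) stop("need at least 2 units with data", call. = FALSE)
  freqs <- dplyr::mutate(
    dplyr::group_by(spectra_by_unit, .data$unit, .data$locus),
    freq = .data$count / sum(.data$count))
  freqs <- dplyr::ungroup(freqs)
  fl <- split(freqs, freqs$unit)
  D <- matrix(0, length(units), length(units), dimnames = list(units, units))
  for (i in seq_along(units)) {
    for (j in seq_len(i - 1)) {
      a <- fl[[units[i]]]
      b <- fl[[units[j]]]
      shared_loci <- intersect(unique(a$locus), unique(b$locus))
      a <- a[a$locus %in% shared_loci, ]
      b <- b[b$locus %in% shared_loci, ]
      m <- dplyr::full_join(a[c("locus", "allele", "freq")],
                            b[c("locus", "allele", "freq")],
                            by = c("locus", "allele"),
                            suffix = c("_x", "_y"))
      x <- tidyr::replace_na(m$freq_x, 0)
      y <- tidyr::replace_na(m$freq_y, 0)
      jxy <- sum(x * y)
      d <- if (jxy == 0) Inf else -log(jxy / sqrt(sum(x^2) * sum(y^2)))
      D[i, j] <- D[j, i] <- max(d, 0)
    }
  }
  if (any(is.infinite(D))) {
    warning("disjoint allele sets between some units: infinite Nei distance")
  }
  D
}

#' Nei distance between individuals
#'
#' Each individual treated as a two-copy population, with the same pooled
#' Nei (1972) formula evaluated on the dosage encoding of
#' [build_allele_matrix()] (mean-imputed for missing loci). Used for
#' individual-level isolation-by-distance tests.
#'
#' @param genotypes Genotype tibble.
#' @return Symmetric distance matrix (ids as dimnames).
#' @export
nei_individual_distance <- function(genotypes) {
  F <- build_allele_matrix(genotypes)
  J <- tcrossprod(F)
  d <- diag(J)
  R <- J / sqrt(outer(d, d))
  D <- -log(pmin(pmax(R, 1e-12), 1))
  diag(D) <- 0
  D
}

#' Pairwise geographic distance
#'
#' Planar Euclidean distance in decimal degrees, consistent with the grid
#' module's distance convention; `great_circle = TRUE` switches to
#' great-circle kilometers.
#'
#' @param passports Tibble with `id`, `lon`, `lat`.
#' @param great_circle Use haversine kilometers instead of degrees.
#' @return Symmetric distance matrix (ids as dimnames).
#' @export
geo_distance_matrix <- function(passports, great_circle = FALSE) {
  if (great_circle) {
    n <- nrow(passports)
    rad <- pi / 180
    lat <- passports$lat * rad
    lon <- passports$lon * rad
    D <- matrix(0, n, n)
    for (i in seq_len(n)) {
      dlat <- lat - lat[i]
      dlon <- lon - lon[i]
      a <- sin(dlat / 2)^2 + cos(lat[i]) * cos(lat) * sin(dlon / 2)^2
      D[i, ] <- 2 * 6371 * asin(pmin(1, sqrt(a)))
    }
  } else {
    D <- as.matrix(dist(cbind(passports$lon, passports$lat)))
  }
  dimnames(D) <- list(passports$id, passports$id)
  D
}

#' Complete-linkage dendrogram with cophenetic correlation
#'
#' Farthest-neighbour agglomeration of a distance matrix (ties resolved by
#' the standard lowest-index convention of [stats::hclust()]), with the
#' Pearson correlation between the input and cophenetic distances as a
#' goodness-of-representation diagnostic, and a Newick export of the tree.
#'
#' @param D Symmetric distance matrix or `dist`.
#' @return A `cluster_tree` object: `hclust`, `newick` string,
#'   `cophenetic_r` (NA for fewer than 3 tips... n >= 3 required).
#' @export
complete_linkage_tree <- function(D) {
  d <- as.dist(D)
  if (attr(d, "Size") < 3) stop("need at least 3 units", call. = FALSE)
  hc <- hclust(d, method = "complete")
  structure(list(hclust = hc,
                 newick = ape::write.tree(ape::as.phylo(hc)),
                 cophenetic_r = cor(d, cophenetic(hc))),
            class = "cluster_tree")
}

#' @export
print.cluster_tree <- function(x, ...) {
  cat("complete-linkage tree, ", length(x$hclust$order), " tips, ",
      "cophenetic r = ", format(x$cophenetic_r, digits = 3), "\n", sep = "")
  invisible(x)
}

#' Mantel test
#'
#' Pearson correlation between the upper triangles of two distance matrices,
#' with significance from random simultaneous row/column permutations of the
#' second matrix: one-sided
#' \eqn{p = (1 + \#\{r_{perm} \ge r_{obs}\}) / (1 + n_{perm})}.
#'
#' @param D1,D2 Symmetric distance matrices (or `dist`) over the same
#'   entities in the same order; at least 4 entities.
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed.
#' @return A `mantel` object: `r`, `p_value`, `n_perm`, `perm_r`.
#' @export
mantel_test <- function(D1, D2, n_perm = 999, seed = 1) {
  D1 <- as.matrix(D1)
  D2 <- as.matrix(D2)
  n <- nrow(D1)
  stopifnot(n >= 4, all(dim(D2) == n))
  ut <- upper.tri(D1)
  v1 <- D1[ut]
  if (sd(v1) == 0 || sd(D2[ut]) == 0) {
    stop("constant distance matrix: Mantel r undefined", call. = FALSE)
  }
  r_obs <- cor(v1, D2[ut])
  perm_r <- withr::with_seed(seed, vapply(seq_len(n_perm), function(b) {
    p <- sample.int(n)
    cor(v1, D2[p, p][ut])
  }, numeric(1)))
  structure(list(r = r_obs,
                 p_value = (1 + sum(perm_r >= r_obs)) / (1 + n_perm),
                 n_perm = n_perm, perm_r = perm_r),
            class = "divgrid_mantel")
}

#' @export
print.divgrid_mantel <- function(x, ...) {
  cat(sprintf("Mantel test: r = %.4f, p = %.4g (%d permutations)\n",
              x$r, x$p_value, x$n_perm))
  invisible(x)
}
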