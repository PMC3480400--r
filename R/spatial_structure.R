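# Spatial PCA: Delaunay connection network, Moran's I, the eigen-
# decomposition splitting genetic variation into global (positive-eigenvalue,
# cline/patch) and local (negative-eigenvalue, neighbour-dissimilarity)
# structures, permutation tests, and the score-surface raster.

#' Row-normalized Delaunay spatial weights
#'
#' Builds the Delaunay triangulation of the sampling locations (via deldir)
#' and returns the binary adjacency, row-normalized so each row sums to 1.
#' Exactly duplicated coordinates are jittered by at most 1e-6 degrees with a
#' fixed seed (and a message) so the triangulation is defined.
#'
#' @param coords Matrix or data frame with columns `lon`, `lat` (at least 3
#'   non-collinear points).
#' @param normalize Row-normalize the binary adjacency (default TRUE).
#' @return A `spatial_weights` object: `W` (n x n matrix), `coords`.
#' @export
delaunay_weights <- function(coords, normalize = TRUE) {
  coords <- as.data.frame(coords)
  if (!all(c("lon", "lat") %in% names(coords))) {
    names(coords)[1:2] <- c("lon", "lat")
  }
  n <- nrow(coords)
  if (n < 3) stop("need at least 3 points for a Delaunay graph", call. = FALSE)
  xy <- coords[c("lon", "lat")]
  dup <- duplicated(xy)
  if (any(dup)) {
    message("jittering ", sum(dup), " duplicated coordinate(s) by <= 1e-6 deg")
    xy[dup, ] <- xy[dup, ] + withr::with_seed(
      7L, matrix(runif(2 * sum(dup), -1e-6, 1e-6), ncol = 2))
  }
  tri <- deldir::deldir(xy$lon, xy$lat)
  W <- matrix(0, n, n)
  W[cbind(tri$delsgs$ind1, tri$delsgs$ind2)] <- 1
  W[cbind(tri$delsgs$ind2, tri$delsgs$ind1)] <- 1
  diag(W) <- 0
  if (any(rowSums(W) == 0)) {
    stop("isolated vertex in the connection network (collinear input?)",
         call. = FALSE)
  }
  if (normalize) W <- W / rowSums(W)
  structure(list(W = W, coords = tibble::as_tibble(coords)),
            class = "spatial_weights")
}

#' @export
print.spatial_weights <- function(x, ...) {
  cat("spatial_weights: ", nrow(x$W), " vertices, ",
      sum(x$W > 0) / 2, " undirected edges\n", sep = "")
  invisible(x)
}

#' Moran's I spatial autocorrelation
#'
#' \eqn{I = \frac{n}{\sum_{ij} w_{ij}} \frac{\sum_{ij} w_{ij} z_i z_j}
#' {\sum_i z_i^2}} with `z` the centered values. Positive for smooth spatial
#' gradients, negative for neighbor dissimilarity; the permutation-null
#' expectation is \eqn{-1/(n-1)}.
#'
#' @param values Non-constant numeric vector.
#' @param weights A `spatial_weights` object or plain weight matrix.
#' @export
morans_I <- function(values, weights) {
  W <- if (inherits(weights, "spatial_weights")) weights$W else weights
  n <- length(values)
  stopifnot(nrow(W) == n)
  z <- values - mean(values)
  if (all(z == 0)) stop("constant values: Moran's I undefined", call. = FALSE)
  (n / sum(W)) * sum(W * outer(z, z)) / sum(z^2)
}

# Signed eigenvalues of C = t(X) %*% S %*% X / n without forming the p x p
# matrix when the dual n x n route is cheaper. S must be symmetric.
spca_eigenvalues <- function(X, S) {
  n <- nrow(X)
  if (ncol(X) <= n) {
    M <- crossprod(X, S %*% X) / n
    eigen((M + t(M)) / 2, symmetric = TRUE, only.values = TRUE)$values
  } else {
    G <- tcrossprod(X)
    eg <- eigen(G, symmetric = TRUE)
    pos <- eg$values > max(eg$values, 0) * 1e-12
    G12 <- eg$vectors[, pos, drop = FALSE] %*%
      (sqrt(eg$values[pos]) * t(eg$vectors[, pos, drop = FALSE]))
    K <- G12 %*% S %*% G12 / n
    eigen((K + t(K)) / 2, symmetric = TRUE, only.values = TRUE)$values
  }
}

#' Spatial PCA decomposition
#'
#' Eigen-decomposition of \eqn{C = X^T \tilde{W} X / n} where `X` is the
#' column-centered allele matrix and \eqn{\tilde W = (W + W^T)/2} the
#' symmetrized connection-network weights. Each axis score `s = Xv`
#' satisfies the identity \eqn{\lambda = \mathrm{var}(s) \cdot I(s)}:
#' positive eigenvalues capture global structure (high variance and positive
#' spatial autocorrelation), negative eigenvalues local structure.
#'
#' @param X Allele matrix ([build_allele_matrix()]); centered internally.
#' @param weights A `spatial_weights` object (row-normalized).
#' @param n_axes Number of axes to keep from each tail (default 5).
#' @return A `divgrid_spca` object: `eigenvalues` (all, descending), `scores`
#'   and `loadings` for the retained leading/trailing axes, per-axis
#'   `decomposition` tibble (variance, Moran's I), and the trace of C.
#' @export
spca_decompose <- function(X, weights, n_axes = 5) {
  W <- if (inherits(weights, "spatial_weights")) weights$W else weights
  n <- nrow(X)
  stopifnot(nrow(W) == n)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  if (all(Xc == 0)) stop("rank-0 matrix", call. = FALSE)
  S <- (W + t(W)) / 2
  M <- crossprod(Xc, S %*% Xc) / n
  eg <- eigen((M + t(M)) / 2, symmetric = TRUE)
  lam <- eg$values
  keep <- unique(c(seq_len(min(n_axes, length(lam))),
                   seq.int(length(lam), by = -1,
                           length.out = min(n_axes, length(lam)))))
  keep <- sort(keep)
  V <- eg$vectors[, keep, drop = FALSE]
  scores <- Xc %*% V
  axis_var <- colSums(scores^2) / n
  axis_I <- vapply(seq_along(keep), function(j) {
    s <- scores[, j]
    (n / sum(S)) * sum(S * outer(s, s)) / sum(s^2)
  }, numeric(1))
  colnames(scores) <- paste0("axis", keep)
  structure(list(
    eigenvalues = lam,
    axes = keep,
    scores = scores,
    loadings = V,
    decomposition = tibble::tibble(axis = keep, eigenvalue = lam[keep],
                                   variance = axis_var, moran_I = axis_I),
    trace = sum(diag(M))),
    class = "divgrid_spca")
}

#' @export
print.divgrid_spca <- function(x, ...) {
  lam <- x$eigenvalues
  cat("sPCA: ", sum(lam > 0), " positive (global) and ", sum(lam < 0),
      " negative (local) eigenvalues\n", sep = "")
  cat("  leading global eigenvalue ", format(max(lam), digits = 4),
      ", leading local ", format(min(lam), digits = 4), "\n", sep = "")
  invisible(x)
}

#' Permutation test for global and local spatial structure
#'
#' Test statistics are the total positive (global) and absolute negative
#' (local) eigenvalue mass of the sPCA decomposition; the null distribution
#' is generated by randomly permuting the individuals' locations (rows of the
#' allele matrix relative to the weight matrix). One-sided p-values as in
#' [mantel_test()].
#'
#' @inheritParams spca_decompose
#' @param n_perm Number of permutations (at least 99; default 999).
#' @param seed Integer seed.
#' @return Named numeric: `p_global`, `p_local`, plus the observed statistics.
#' @export
global_local_test <- function(X, weights, n_perm = 999, seed = 1) {
  stopifnot(n_perm >= 99)
  W <- if (inherits(weights, "spatial_weights")) weights$W else weights
  Xc <- scale(X, center = TRUE, scale = FALSE)
  S <- (W + t(W)) / 2
  n <- nrow(Xc)
  stat <- function(lam) c(g = sum(lam[lam > 0]), l = sum(-lam[lam < 0]))
  obs <- stat(spca_eigenvalues(Xc, S))
  perms <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      p <- sample.int(n)
      stat(spca_eigenvalues(Xc[p, , drop = FALSE], S))
    }, numeric(2))
  })
  c(p_global = (1 + sum(perms["g", ] >= obs["g"])) / (1 + n_perm),
    p_local = (1 + sum(perms["l", ] >= obs["l"])) / (1 + n_perm),
    stat_global = unname(obs["g"]), stat_local = unname(obs["l"]))
}

#' Raster of neighborhood-averaged sPCA scores
#'
#' Assigns to each grid cell the mean score of all individuals lying within
#' `diameter / 2` of the cell center (the cell-centered counterpart of the
#' tree-centered replication used for diversity surfaces); cells with no
#' individual in range are nodata.
#'
#' @param scores Numeric vector of per-individual scores (e.g. first global
#'   sPCA axis).
#' @param coords Tibble/data frame with `lon`, `lat` aligned with `scores`.
#' @param grid A [grid_spec()].
#' @param diameter Neighborhood diameter in degrees (default 1).
#' @param statistic Name stored in the raster (default "spca_axis1").
#' @return A `div_raster` object.
#' @export
spca_score_raster <- function(scores, coords, grid, diameter = 1,
                              statistic = "spca_axis1") {
  stopifnot(length(scores) == nrow(coords))
  pass <- tibble::tibble(id = as.character(seq_along(scores)),
                         lon = coords$lon, lat = coords$lat)
  asn <- replicate_samples(pass, grid, diameter)
  asn$value <- scores[as.integer(asn$id)]
  cells <- dplyr::summarise(dplyr::group_by(asn, .data$cell, .data$col,
                                            .data$row),
                            value = mean(.data$value), .groups = "drop")
  diversity_raster(cells, grid, "value", statistic_name = statistic)
}
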