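# Synthetic georeferenced SSR datasets with known truth.
#
# Population allele frequencies follow a Balding-Nichols-style Dirichlet
# drift model extended to multi-allelic loci: ancestral frequencies are
# symmetric Dirichlet(1) draws and each population drifts as
# Dirichlet(p_anc * (1 - F) / F), so F near 0 reproduces the ancestral pool
# and large F (bottleneck) drives loci toward fixation. Individuals are
# placed around refugium centers, genotypes are diploid HWE draws, and an
# optional distance-decaying admixture of the population gene pools creates
# isolation by distance.

rdirichlet1 <- function(alpha) {
  x <- stats::rgamma(length(alpha), shape = alpha)
  if (sum(x) == 0) x[sample.int(length(alpha), 1)] <- 1
  x / sum(x)
}

#' Simulation configuration
#'
#' @param k_pops Number of populations (default 10).
#' @param n_loci Number of SSR loci (default 96).
#' @param alleles_range Range of allele counts per locus, drawn uniformly
#'   (default 8..16).
#' @param F Drift parameter per population (scalar recycled; default 0.2;
#'   use ~0.8 for bottlenecked lineages).
#' @param centers k x 2 matrix (lon, lat) of refugium centers; default a
#'   deterministic spread over an equatorial Amazon-like box
#'   (-80..-45 lon, -20..10 lat).
#' @param spatial_sd Per-population spatial standard deviation in degrees
#'   (scalar recycled; default 0.8).
#' @param n_per_pop Individuals per population (scalar recycled; default 50).
#' @param missing_rate Probability a genotype pair is missing (default 0.02).
#' @param ibd_mixing Admixture decay length in degrees; 0 disables admixture
#'   (each individual draws only from its own population).
#' @param admix_frac Fraction of each individual's gene pool drawn from the
#'   distance-decaying mixture of all populations when `ibd_mixing > 0`
#'   (default 0.3); the remainder always comes from the individual's own
#'   population.
#' @param seed Integer seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(k_pops = 10, n_loci = 96, alleles_range = c(8, 16),
                       F = 0.2, centers = NULL, spatial_sd = 0.8,
                       n_per_pop = 50, missing_rate = 0.02, ibd_mixing = 0,
                       admix_frac = 0.3, seed = 1) {
  stopifnot(k_pops >= 1, n_loci >= 1, missing_rate >= 0, missing_rate <= 1,
            all(F >= 0), all(F <= 1))
  if (is.null(centers)) {
    centers <- default_centers(k_pops)
  }
  centers <- matrix(as.numeric(centers), ncol = 2)
  stopifnot(nrow(centers) == k_pops)
  structure(list(k_pops = k_pops, n_loci = n_loci,
                 alleles_range = alleles_range,
                 F = rep_len(F, k_pops), centers = centers,
                 spatial_sd = rep_len(spatial_sd, k_pops),
                 n_per_pop = rep_len(n_per_pop, k_pops),
                 missing_rate = missing_rate, ibd_mixing = ibd_mixing,
                 admix_frac = admix_frac, seed = seed),
            class = "sim_config")
}

# Deterministic center layout inside the study box, spaced so neighbouring
# populations overlap only through their tails.
default_centers <- function(k) {
  base <- cbind(
    lon = c(-70, -79, -53, -60, -50, -76, -63, -73, -74.5, -75),
    lat = c(-9, 7, 4, -3, -14, -2.5, -11, -4, -5.5, -2))
  if (k <= nrow(base)) return(base[seq_len(k), , drop = FALSE])
  extra <- cbind(lon = runif(k - nrow(base), -80, -45),
                 lat = runif(k - nrow(base), -20, 10))
  rbind(base, extra)
}

#' Simulate population allele frequencies
#'
#' Balding-Nichols Dirichlet drift per locus and population (see the module
#' notes). Deterministic given `config$seed`.
#'
#' @param config A [sim_config()].
#' @return List with `ancestral` (list over loci of frequency vectors),
#'   `pops` (list over loci of k x n_alleles frequency matrices) and
#'   `alleles` (list over loci of integer allele labels, fragment-size
#'   style).
#' @export
simulate_frequencies <- function(config) {
  withr::with_seed(config$seed, {
    n_all <- sample(seq(config$alleles_range[1], config$alleles_range[2]),
                    config$n_loci, replace = TRUE)
    alleles <- lapply(n_all, function(k) 100L + 2L * seq_len(k))
    ancestral <- lapply(n_all, function(k) rdirichlet1(rep(1, k)))
    pops <- lapply(seq_len(config$n_loci), function(l) {
      p <- ancestral[[l]]
      t(vapply(seq_len(config$k_pops), function(j) {
        Fj <- config$F[j]
        if (Fj < 1e-9) return(p)
        if (Fj > 1 - 1e-9) {
          out <- numeric(length(p))
          out[sample.int(length(p), 1, prob = p)] <- 1
          return(out)
        }
        rdirichlet1(p * (1 - Fj) / Fj)
      }, numeric(length(p))))
    })
    list(ancestral = ancestral, pops = pops, alleles = alleles)
  })
}

#' Simulate georeferenced diploid individuals
#'
#' Coordinates are bivariate normal around each population's center. With
#' `ibd_mixing > 0` a fraction `admix_frac` of each individual's gene pool is
#' a mixture of all population pools with weights decaying exponentially in
#' the distance from the individual to each center (decay length `ibd_mixing`
#' degrees) — nearby foreign pools leak in, distant ones do not — which
#' produces isolation by distance while keeping every individual's majority
#' ancestry in its own population; with `ibd_mixing = 0`, copies come from
#' the own population only. Genotypes are HWE draws; missing pairs are masked
#' at `missing_rate`.
#'
#' @param frequencies Output of [simulate_frequencies()].
#' @param config The same [sim_config()].
#' @return List with `genotypes` (genotype tibble), `passports` (`id`,
#'   `lon`, `lat`) and `truth` (`id`, `pop`, coordinates, admixture
#'   proportions `adx_*`; per-population frequencies in the `frequencies`
#'   attribute).
#' @export
simulate_individuals <- function(frequencies, config) {
  k <- config$k_pops
  withr::with_seed(config$seed + 1L, {
    pop <- rep(seq_len(k), config$n_per_pop)
    n <- length(pop)
    ord <- sample.int(n)  # shuffle so row order carries no signal
    pop <- pop[ord]
    lon <- config$centers[pop, 1] + rnorm(n, 0, config$spatial_sd[pop])
    lat <- config$centers[pop, 2] + rnorm(n, 0, config$spatial_sd[pop])
    ids <- sprintf("ind%04d", seq_len(n))
    own <- matrix(0, n, k)
    own[cbind(seq_len(n), pop)] <- 1
    if (config$ibd_mixing > 0) {
      d <- sqrt(outer(lon, config$centers[, 1], "-")^2 +
                  outer(lat, config$centers[, 2], "-")^2)
      Wd <- exp(-d / config$ibd_mixing)
      Wd <- Wd / rowSums(Wd)
      Wmix <- (1 - config$admix_frac) * own + config$admix_frac * Wd
    } else {
      Wmix <- own
    }
    geno <- tibble::tibble(id = ids)
    for (l in seq_len(config$n_loci)) {
      P <- Wmix %*% frequencies$pops[[l]]     # per-individual mixture freqs
      cp <- t(apply(P, 1, cumsum))
      draw <- function() {
        u <- runif(n) * cp[, ncol(cp)]
        as.integer(rowSums(cp < u) + 1L)
      }
      a1 <- frequencies$alleles[[l]][draw()]
      a2 <- frequencies$alleles[[l]][draw()]
      if (config$missing_rate > 0) {
        miss <- runif(n) < config$missing_rate
        a1[miss] <- NA_integer_
        a2[miss] <- NA_integer_
      }
      geno[[sprintf("L%02d_1", l)]] <- a1
      geno[[sprintf("L%02d_2", l)]] <- a2
    }
    truth <- tibble::tibble(id = ids, pop = pop, lon = lon, lat = lat)
    adx <- tibble::as_tibble(as.data.frame(Wmix))
    names(adx) <- sprintf("adx_%d", seq_len(k))
    truth <- dplyr::bind_cols(truth, adx)
    attr(truth, "frequencies") <- frequencies
    list(genotypes = geno,
         passports = tibble::tibble(id = ids, lon = lon, lat = lat),
         truth = truth)
  })
}

#' Cacao-like benchmark scenario
#'
#' A full synthetic dataset with the shape of the continental cacao SSR
#' study: 939 individuals, 96 loci, 10 spatially clumped populations in an
#' equatorial box, two bottlenecked lineages (drift F = 0.8) at the range
#' margins, a high-sampling hotspot region in the north-west where four
#' populations co-occur and collecting density is an order of magnitude
#' above the rest of the range, mild distance-decaying admixture, and 2%
#' missing calls.
#'
#' @param seed Integer seed.
#' @param n_individuals Total sample size (default 939).
#' @param n_loci Number of loci (default 96).
#' @return As [simulate_individuals()], plus a `config` element; the truth
#'   table's `bottleneck` attribute names the two low-diversity populations.
#' @export
cacao_like_scenario <- function(seed = 42, n_individuals = 939,
                                n_loci = 96) {
  k <- 10
  F <- rep(0.2, k)
  F[c(2, 3)] <- 0.8                      # bottlenecked margin lineages
  # sampling-density multiplier: the four populations overlapping the
  # north-west hotspot region are each sampled 2.5x as densely, so the
  # region's collecting density is ~10x that of a single-population area
  w <- rep(1, k)
  w[c(6, 8, 9, 10)] <- 2.5
  n_per_pop <- diff(round(cumsum(c(0, w)) / sum(w) * n_individuals))
  cfg <- sim_config(k_pops = k, n_loci = n_loci, F = F,
                    spatial_sd = 0.8, n_per_pop = n_per_pop,
                    missing_rate = 0.02, ibd_mixing = 1, seed = seed)
  freqs <- simulate_frequencies(cfg)
  out <- simulate_individuals(freqs, cfg)
  attr(out$truth, "bottleneck") <- c(2L, 3L)
  out$config <- cfg
  out
}
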