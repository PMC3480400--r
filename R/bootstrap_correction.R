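# Sample-bias correction by repeated subsampling.
#
# Per-unit statistics are averaged over B subsamples of a fixed number of
# trees drawn WITHOUT replacement (repeated rarefaction at the individual
# level: 8 trees = 16 gene copies), so that units holding different numbers
# of individuals are compared at a common sample size. The approach
# reproduces the closed-form rarefaction expectation for allelic richness
# and extends the correction to any statistic.

# Integer-code representation of a genotype table: per locus, observed
# alleles get consecutive global codes so locus-partitioned counting is a
# single array pass. Missing pairs are code 0 in both slots.
encode_genotypes <- function(genotypes) {
  validate_genotypes(genotypes)
  loci <- genotype_loci(genotypes)
  n <- nrow(genotypes)
  L <- length(loci)
  a1 <- matrix(0L, n, L)
  a2 <- matrix(0L, n, L)
  loc_of_code <- integer(0)
  code_allele <- integer(0)
  offset <- 0L
  for (j in seq_len(L)) {
    v1 <- genotypes[[paste0(loci[j], "_1")]]
    v2 <- genotypes[[paste0(loci[j], "_2")]]
    lev <- sort(unique(c(v1, v2)))
    k <- length(lev)
    c1 <- match(v1, lev)
    c2 <- match(v2, lev)
    a1[, j] <- ifelse(is.na(c1), 0L, c1 + offset)
    a2[, j] <- ifelse(is.na(c2), 0L, c2 + offset)
    loc_of_code <- c(loc_of_code, rep(j, k))
    code_allele <- c(code_allele, lev)
    offset <- offset + k
  }
  list(a1 = a1, a2 = a2, ids = genotypes$id, loci = loci,
       loc_of_code = loc_of_code, code_allele = code_allele,
       n_codes = offset)
}

# Deterministic positive-integer seed for a unit, derived from the master
# seed and the unit key, so per-unit results do not depend on iteration
# order.
unit_seed <- function(seed, key) {
  h <- as.double(seed %% 2147483647L)
  for (ch in utf8ToInt(paste0("u", key))) {
    h <- (h * 31 + ch) %% 2147483647
  }
  as.integer(h) + 1L
}

draw_subsamples <- function(n, n_trees, B, seed) {
  if (n == n_trees) {
    return(matrix(seq_len(n), nrow = 1))
  }
  withr::with_seed(seed, {
    t(vapply(seq_len(B), function(b) sort(sample.int(n, n_trees)),
             integer(n_trees)))
  })
}

#' Bootstrap-corrected statistic for one unit
#'
#' Draws `B` subsamples of `n_trees` distinct individuals (without
#' replacement) from the unit and returns the mean and standard deviation of
#' `stat_fn` over them. When the unit holds exactly `n_trees` individuals the
#' single possible subsample is evaluated once (sd 0).
#'
#' @param genotypes Genotype tibble.
#' @param ids Individuals in the unit (must number at least `n_trees`).
#' @param stat_fn Function of `(genotypes, ids)` returning one number, e.g.
#'   `function(g, i) allelic_richness(allele_counts(g, i))`.
#' @param n_trees Subsample size in individuals (default 8 = 16 gene copies).
#' @param B Number of subsamples (default 1000).
#' @param seed Integer seed; results are reproducible given the seed.
#' @return Named numeric: `mean`, `sd`, `n_replicates`.
#' @export
bootstrap_statistic <- function(genotypes, ids, stat_fn, n_trees = 8,
                                B = 1000, seed = 1) {
  stopifnot(n_trees >= 1, B >= 1)
  if (length(ids) < n_trees) {
    stop("unit has ", length(ids), " individuals; fewer than n_trees = ",
         n_trees, call. = FALSE)
  }
  idx <- draw_subsamples(length(ids), n_trees, B, seed)
  vals <- apply(idx, 1, function(i) stat_fn(genotypes, ids[i]))
  c(mean = mean(vals), sd = if (nrow(idx) > 1) sd(vals) else 0,
    n_replicates = nrow(idx))
}

boot_stat_names <- c("allelic_richness", "shannon", "nei_diversity",
                     "obs_heterozygosity", "locally_common",
                     "private_alleles")

# Occupancy indicators per global allele code, computed once from the FULL
# (non-subsampled) unit spectra: occupancy is a global property of the map,
# only the within-unit frequency criterion is re-evaluated inside each
# subsample.
occupancy_vectors <- function(enc, unit_ids, occupancy_max_units) {
  n_units_of_code <- integer(enc$n_codes)
  for (ids in unit_ids) {
    rows <- match(ids, enc$ids)
    codes <- unique(c(enc$a1[rows, ], enc$a2[rows, ]))
    codes <- codes[codes > 0]
    n_units_of_code[codes] <- n_units_of_code[codes] + 1L
  }
  list(occ_lc = n_units_of_code > 0 &
         n_units_of_code <= occupancy_max_units + 1e-9,
       occ_priv = n_units_of_code == 1L)
}

#' Bootstrap-corrected diversity table over units
#'
#' Computes, for every unit (grid cell or cluster) with at least `n_trees`
#' individuals, the bootstrap mean and standard deviation of allelic
#' richness, Shannon index, Nei gene diversity, observed heterozygosity,
#' locally common alleles and private alleles. Units below the threshold are
#' skipped and listed in the `skipped_units` attribute. Per-unit RNG streams
#' are derived from `seed` and the unit key, so results are independent of
#' unit order. The hot loop runs in compiled code.
#'
#' @param genotypes Genotype tibble.
#' @param units Tibble with columns `unit` and `id`: membership of
#'   individuals in units (an individual may appear in many units).
#' @param n_trees Subsample size in individuals (default 8).
#' @param B Replicates (default 1000).
#' @param seed Master seed.
#' @param occupancy_max_frac,occupancy_max_units Occupancy criterion for
#'   locally common alleles (defaults to 25% of units, the grid convention);
#'   see [locally_common_alleles()].
#' @param freq_min,strict Frequency criterion for locally common alleles.
#' @return Tibble: one row per retained unit with `unit`, `n_individuals`,
#'   and `<stat>` / `<stat>_sd` columns.
#' @export
units_bootstrap <- function(genotypes, units, n_trees = 8, B = 1000,
                            seed = 1, occupancy_max_frac = 0.25,
                            occupancy_max_units = NULL, freq_min = 0.05,
                            strict = FALSE) {
  stopifnot(all(c("unit", "id") %in% names(units)))
  enc <- encode_genotypes(genotypes)
  # ids sorted within unit so results do not depend on assignment row order
  unit_ids <- lapply(split(units$id, units$unit), sort)
  keep <- vapply(unit_ids, length, integer(1)) >= n_trees
  skipped <- names(unit_ids)[!keep]
  unit_ids <- unit_ids[keep]
  if (!length(unit_ids)) stop("no unit reaches n_trees = ", n_trees,
                              call. = FALSE)
  if (is.null(occupancy_max_units)) {
    occupancy_max_units <- occupancy_max_frac * length(unit_ids)
  }
  occ <- occupancy_vectors(enc, unit_ids, occupancy_max_units)
  rows <- purrr::imap(unit_ids, function(ids, key) {
    ridx <- match(ids, enc$ids)
    idx <- draw_subsamples(length(ids), n_trees, B, unit_seed(seed, key))
    sub <- matrix(ridx[idx], nrow = nrow(idx))
    st <- boot_stats_kernel(enc$a1, enc$a2, sub, enc$loc_of_code,
                            occ$occ_lc, occ$occ_priv, freq_min, strict)
    mu <- colMeans(st)
    sdv <- if (nrow(st) > 1) apply(st, 2, sd) else rep(0, ncol(st))
    tibble::tibble(unit = key, n_individuals = length(ids),
                   !!!setNames(as.list(mu), boot_stat_names),
                   !!!setNames(as.list(sdv), paste0(boot_stat_names, "_sd")))
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "skipped_units") <- skipped
  attr(out, "config") <- list(n_trees = n_trees, B = B, seed = seed,
                              occupancy_max_units = occupancy_max_units,
                              freq_min = freq_min, strict = strict)
  out
}

#' Bootstrap-corrected diversity table over grid cells
#'
#' [units_bootstrap()] applied to a (filtered) neighborhood assignment; cell
#' keys are restored to `cell`, `col`, `row` columns.
#'
#' @param assignment Filtered assignment tibble (`cell`, `col`, `row`, `id`),
#'   normally `filter_cells(...)$assignment` with `min_trees = n_trees`.
#' @inheritParams units_bootstrap
#' @export
gridwide_bootstrap <- function(assignment, genotypes, n_trees = 8, B = 1000,
                               seed = 1, occupancy_max_frac = 0.25,
                               freq_min = 0.05) {
  units <- tibble::tibble(unit = as.character(assignment$cell),
                          id = assignment$id)
  out <- units_bootstrap(genotypes, units, n_trees = n_trees, B = B,
                         seed = seed, occupancy_max_frac = occupancy_max_frac,
                         freq_min = freq_min, strict = FALSE)
  key <- dplyr::distinct(assignment[c("cell", "col", "row")])
  key$unit <- as.character(key$cell)
  out <- dplyr::left_join(out, key, by = "unit")
  dplyr::relocate(out, "cell", "col", "row")
}

#' Per-cell direct (uncorrected) diversity table
#'
#' The same statistic set evaluated once on each unit's full sample, i.e.
#' without sample-size correction — the contrast partner for the corrected
#' surface.
#'
#' @inheritParams units_bootstrap
#' @export
units_direct <- function(genotypes, units, occupancy_max_frac = 0.25,
                         occupancy_max_units = NULL,
                         freq_min = 0.05, strict = FALSE) {
  stopifnot(all(c("unit", "id") %in% names(units)))
  enc <- encode_genotypes(genotypes)
  unit_ids <- lapply(split(units$id, units$unit), sort)
  if (is.null(occupancy_max_units)) {
    occupancy_max_units <- occupancy_max_frac * length(unit_ids)
  }
  occ <- occupancy_vectors(enc, unit_ids, occupancy_max_units)
  rows <- purrr::imap(unit_ids, function(ids, key) {
    sub <- matrix(match(ids, enc$ids), nrow = 1)
    st <- boot_stats_kernel(enc$a1, enc$a2, sub, enc$loc_of_code,
                            occ$occ_lc, occ$occ_priv, freq_min, strict)
    tibble::tibble(unit = key, n_individuals = length(ids),
                   !!!setNames(as.list(st[1, ]), boot_stat_names))
  })
  dplyr::bind_rows(rows)
}

#' Validate bootstrap richness against the rarefaction closed form
#'
#' Regresses per-unit bootstrap-mean allelic richness on the analytic
#' rarefaction expectation at `g` gene copies (ordinary least squares, with
#' intercept) and reports the slope and Pearson correlation. Values near 1
#' for both confirm that the subsampling correction reproduces the
#' rarefaction standard.
#'
#' @param cell_table Output of [gridwide_bootstrap()] / [units_bootstrap()].
#' @param genotypes Genotype tibble.
#' @param units Tibble `unit`, `id` matching `cell_table$unit`.
#' @param g Gene copies to rarefy to (default 16 = 8 trees).
#' @return Named numeric: `slope`, `pearson_r`, `n_units`.
#' @export
validate_against_rarefaction <- function(cell_table, genotypes, units,
                                         g = 16) {
  stopifnot(nrow(cell_table) >= 3)
  unit_ids <- split(units$id, units$unit)
  expected <- vapply(cell_table$unit, function(u) {
    as.numeric(rarefaction_expected_alleles(
      allele_counts(genotypes, unit_ids[[u]]), g))
  }, numeric(1))
  observed <- cell_table$allelic_richness
  if (var(expected) == 0 || var(observed) == 0) {
    stop("zero variance; regression undefined", call. = FALSE)
  }
  fit <- stats::lm(observed ~ expected)
  c(slope = unname(stats::coef(fit)[2]),
    pearson_r = cor(observed, expected),
    n_units = length(observed))
}
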