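# Per-sample SSR diversity statistics.
#
# All statistics operate on an allele-count spectrum: a tibble with columns
# `locus`, `allele`, `count` giving gene-copy counts over the non-missing
# calls of a set of individuals (2 copies per individual per locus). Loci
# with no data in the sample are simply absent from the spectrum and are
# skipped by the per-locus means rather than imputed as zero.

#' Allele-count spectrum of a set of individuals
#'
#' @param genotypes Genotype tibble.
#' @param ids Individuals to include (default: all).
#' @return Tibble `locus`, `allele`, `count`, sorted; the `loci` attribute
#'   lists every locus of the table, `empty_loci` those with no non-missing
#'   call in the sample.
#' @export
allele_counts <- function(genotypes, ids = genotypes$id) {
  stopifnot(all(ids %in% genotypes$id))
  loci <- genotype_loci(genotypes)
  g <- genotypes[match(ids, genotypes$id), , drop = FALSE]
  long <- tidyr::pivot_longer(g, -"id",
                              names_to = c("locus", "slot"),
                              names_pattern = "(.*)_([12])$",
                              values_to = "allele")
  long <- long[!is.na(long$allele), , drop = FALSE]
  out <- dplyr::count(long, .data$locus, .data$allele, name = "count")
  out <- dplyr::arrange(out, .data$locus, .data$allele)
  attr(out, "loci") <- loci
  attr(out, "empty_loci") <- setdiff(loci, unique(out$locus))
  out
}

per_locus_mean <- function(spectrum, f) {
  if (!nrow(spectrum)) stop("all loci empty: no allele data", call. = FALSE)
  vals <- vapply(split(spectrum$count, spectrum$locus), f, numeric(1))
  mean(vals)
}

#' Mean allelic richness per locus
#'
#' Arithmetic mean, over loci with data, of the number of distinct alleles.
#' Sample-size dependent; compare across samples only after rarefaction or
#' bootstrap correction to a common number of gene copies.
#'
#' @param spectrum An allele-count spectrum from [allele_counts()].
#' @export
allelic_richness <- function(spectrum) per_locus_mean(spectrum, length)

#' Mean Nei gene diversity (expected heterozygosity) per locus
#'
#' Plug-in estimator \eqn{H = 1 - \sum_i \hat p_i^2} per locus, averaged over
#' loci with data. No small-sample correction is applied: sample-size bias is
#' handled by bootstrap subsampling to a common size.
#'
#' @inheritParams allelic_richness
#' @export
nei_gene_diversity <- function(spectrum) {
  per_locus_mean(spectrum, function(cnt) 1 - sum((cnt / sum(cnt))^2))
}

#' Mean Shannon information index per locus
#'
#' \eqn{-\sum_i \hat p_i \ln \hat p_i} per locus (natural log), averaged over
#' loci with data.
#'
#' @inheritParams allelic_richness
#' @export
shannon_index <- function(spectrum) {
  per_locus_mean(spectrum, function(cnt) {
    p <- cnt / sum(cnt)
    -sum(p * log(p))
  })
}

#' Mean observed heterozygosity per locus
#'
#' Per locus, the fraction of individuals with two distinct alleles among
#' those with a non-missing call; averaged over loci with at least one call.
#'
#' @inheritParams allele_counts
#' @export
observed_heterozygosity <- function(genotypes, ids = genotypes$id) {
  loci <- genotype_loci(genotypes)
  g <- genotypes[match(ids, genotypes$id), , drop = FALSE]
  vals <- vapply(loci, function(loc) {
    a1 <- g[[paste0(loc, "_1")]]
    a2 <- g[[paste0(loc, "_2")]]
    ok <- !is.na(a1)
    if (!any(ok)) return(NA_real_)
    mean(a1[ok] != a2[ok])
  }, numeric(1))
  if (all(is.na(vals))) stop("all loci empty: no genotype calls", call. = FALSE)
  mean(vals, na.rm = TRUE)
}

#' Closed-form rarefaction expectation of allelic richness
#'
#' Expected number of distinct alleles in a random subsample of `g` gene
#' copies drawn without replacement from a locus with copy counts
#' \eqn{N_1, \dots, N_k} (total \eqn{N}):
#' \deqn{E = \sum_i \left[1 - \binom{N - N_i}{g} / \binom{N}{g}\right].}
#' Loci with fewer than `g` copies are excluded (and reported via the
#' `excluded_loci` attribute); the mean is over included loci.
#'
#' @inheritParams allelic_richness
#' @param g Number of gene copies to rarefy to (e.g. 16 for 8 trees).
#' @export
rarefaction_expected_alleles <- function(spectrum, g) {
  if (g < 1) stop("g must be >= 1", call. = FALSE)
  by_locus <- split(spectrum$count, spectrum$locus)
  N <- vapply(by_locus, sum, numeric(1))
  keep <- N >= g
  if (!any(keep)) stop("no locus has at least g = ", g, " gene copies",
                       call. = FALSE)
  vals <- vapply(by_locus[keep], function(cnt) {
    N <- sum(cnt)
    sum(1 - exp(lchoose(N - cnt, g) - lchoose(N, g)))
  }, numeric(1))
  out <- mean(vals)
  attr(out, "excluded_loci") <- names(by_locus)[!keep]
  out
}

spectra_units <- function(spectra_by_unit) {
  stopifnot(all(c("unit", "locus", "allele", "count") %in%
                  names(spectra_by_unit)))
  unique(spectra_by_unit$unit)
}

#' Private alleles per unit
#'
#' An allele is private to a unit when its count is positive there and zero
#' in every other unit. Returns, per unit, the mean over that unit's
#' non-empty loci of the number of private alleles.
#'
#' @param spectra_by_unit Tibble `unit`, `locus`, `allele`, `count` (stack of
#'   per-unit spectra; see [allele_counts()]).
#' @return Tibble `unit`, `private_alleles`.
#' @export
private_alleles <- function(spectra_by_unit) {
  units <- spectra_units(spectra_by_unit)
  if (length(units) < 2) stop("need at least 2 units", call. = FALSE)
  occ <- dplyr::summarise(
    dplyr::group_by(spectra_by_unit, .data$locus, .data$allele),
    n_units = dplyr::n_distinct(.data$unit[.data$count > 0]), .groups = "drop")
  x <- dplyr::left_join(spectra_by_unit, occ, by = c("locus", "allele"))
  per_locus <- dplyr::summarise(
    dplyr::group_by(x, .data$unit, .data$locus),
    n_priv = sum(.data$count > 0 & .data$n_units == 1), .groups = "drop")
  out <- dplyr::summarise(dplyr::group_by(per_locus, .data$unit),
                          private_alleles = mean(.data$n_priv),
                          .groups = "drop")
  out[match(units, out$unit), , drop = FALSE]
}

#' Locally common alleles per unit
#'
#' An allele counts as locally common for unit U when it is geographically
#' restricted — present in at most `occupancy_max_frac` of all units (grid
#' mode) or in at most `occupancy_max_units` units (cluster mode) — and
#' frequent within U: frequency `>= freq_min` in grid mode (`strict = FALSE`)
#' or `> freq_min` in cluster mode (`strict = TRUE`). Returns per unit the
#' mean over non-empty loci of the number of qualifying alleles.
#'
#' @inheritParams private_alleles
#' @param occupancy_max_frac Maximum fraction of units an allele may occupy
#'   (inclusive); give exactly one of this and `occupancy_max_units`.
#' @param occupancy_max_units Maximum number of units an allele may occupy
#'   (inclusive).
#' @param freq_min Within-unit frequency threshold (default 0.05).
#' @param strict Use a strict `>` frequency comparison (cluster convention)
#'   instead of the inclusive `>=` (grid convention).
#' @return Tibble `unit`, `locally_common`.
#' @export
locally_common_alleles <- function(spectra_by_unit,
                                   occupancy_max_frac = NULL,
                                   occupancy_max_units = NULL,
                                   freq_min = 0.05, strict = FALSE) {
  if (is.null(occupancy_max_frac) == is.null(occupancy_max_units)) {
    stop("give exactly one of occupancy_max_frac / occupancy_max_units",
         call. = FALSE)
  }
  units <- spectra_units(spectra_by_unit)
  if (length(units) == 1) {
    warning("single unit: every present allele trivially passes occupancy")
  }
  max_units <- if (!is.null(occupancy_max_units)) occupancy_max_units else
    occupancy_max_frac * length(units)
  occ <- dplyr::summarise(
    dplyr::group_by(spectra_by_unit, .data$locus, .data$allele),
    n_units = dplyr::n_distinct(.data$unit[.data$count > 0]), .groups = "drop")
  x <- dplyr::left_join(spectra_by_unit, occ, by = c("locus", "allele"))
  x <- dplyr::mutate(dplyr::group_by(x, .data$unit, .data$locus),
                     freq = .data$count / sum(.data$count))
  freq_ok <- if (strict) x$freq > freq_min else x$freq >= freq_min
  x$hit <- x$count > 0 & x$n_units <= max_units + 1e-9 & freq_ok
  per_locus <- dplyr::summarise(x, n_lc = sum(.data$hit), .groups = "drop")
  out <- dplyr::summarise(dplyr::group_by(per_locus, .data$unit),
                          locally_common = mean(.data$n_lc), .groups = "drop")
  out[match(units, out$unit), , drop = FALSE]
}

#' All diversity statistics of one sample
#'
#' Convenience wrapper returning the full per-sample statistic set as a
#' one-row tibble.
#'
#' @inheritParams allele_counts
#' @export
diversity_summary <- function(genotypes, ids = genotypes$id) {
  sp <- allele_counts(genotypes, ids)
  tibble::tibble(
    n_individuals = length(ids),
    allelic_richness = allelic_richness(sp),
    shannon = shannon_index(sp),
    nei_diversity = nei_gene_diversity(sp),
    obs_heterozygosity = observed_heterozygosity(genotypes, ids))
}
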