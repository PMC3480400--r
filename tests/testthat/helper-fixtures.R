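# Shared fixtures and independent oracles, built in code.

# tiny genotype tibble from a list: geno_tbl(A = list(L1 = c(152, 158), ...))
geno_tbl <- function(...) {
  inds <- list(...)
  loci <- names(inds[[1]])
  out <- tibble::tibble(id = names(inds) %||% paste0("i", seq_along(inds)))
  if (is.null(names(inds))) names(inds) <- out$id
  for (loc in loci) {
    out[[paste0(loc, "_1")]] <-
      vapply(inds, function(x) as.integer(x[[loc]][1]), integer(1))
    out[[paste0(loc, "_2")]] <-
      vapply(inds, function(x) as.integer(x[[loc]][2]), integer(1))
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# all permutations of 1..n (oracle for exhaustive permutation nulls)
perms_of <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- perms_of(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, matrix(setdiff(seq_len(n), i)[sub], nrow(sub)))
  }))
}

# brute-force neighborhood oracle: every cell center of a wide block scanned
# for euclidean degree distance <= diameter / 2
brute_neighborhood <- function(lon, lat, grid, diameter) {
  cs <- grid$cell_size
  r <- diameter / 2
  span <- ceiling(r / cs) + 2
  own <- cell_of(lon, lat, grid)
  cand <- expand.grid(col = own$col + (-span:span),
                      row = own$row + (-span:span))
  ctr_lon <- -180 + (cand$col + 0.5) * cs
  ctr_lat <- -90 + (cand$row + 0.5) * cs
  keep <- (ctr_lon - lon)^2 + (ctr_lat - lat)^2 <= r^2 + 1e-12
  df <- cand[keep, ]
  df[order(df$col, df$row), ]
}

# mean distinct alleles over all g-copy subsets, by exhaustive enumeration
enum_rarefaction <- function(counts, g) {
  copies <- rep(seq_along(counts), counts)
  subs <- utils::combn(length(copies), g)
  mean(apply(subs, 2, function(i) length(unique(copies[i]))))
}

# small spatially-clumped synthetic dataset for pipeline tests
small_sim <- function(k = 3, n_loci = 12, n_per_pop = 20, seed = 11,
                      missing_rate = 0.02, ibd_mixing = 0, F = 0.2,
                      spatial_sd = 0.4) {
  cfg <- sim_config(k_pops = k, n_loci = n_loci, F = F,
                    spatial_sd = spatial_sd, n_per_pop = n_per_pop,
                    missing_rate = missing_rate, ibd_mixing = ibd_mixing,
                    seed = seed)
  sim <- simulate_individuals(simulate_frequencies(cfg), cfg)
  sim$config <- cfg
  sim
}
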