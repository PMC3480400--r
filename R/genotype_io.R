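# Genotype and passport input, validation and cleaning.
#
# A genotype table is an ordinary tibble: one `id` column (character, unique)
# followed by two integer columns per SSR locus named `<locus>_1` and
# `<locus>_2` holding allele labels (fragment sizes). A missing genotype is a
# whole missing pair: both slots NA. Heterozygote (a,b) is equivalent to
# (b,a); allele order within the pair carries no information.

#' Locus names of a genotype table
#'
#' @param genotypes A genotype tibble (`id` column plus `<locus>_1`/`<locus>_2`
#'   column pairs).
#' @return Character vector of locus names, in column order.
#' @export
genotype_loci <- function(genotypes) {
  nm <- setdiff(names(genotypes), "id")
  a1 <- grepl("_1$", nm)
  loci <- sub("_1$", "", nm[a1])
  expect <- as.vector(rbind(paste0(loci, "_1"), paste0(loci, "_2")))
  if (!identical(nm, expect)) {
    stop("genotype columns must come as `<locus>_1`,`<locus>_2` pairs after `id`",
         call. = FALSE)
  }
  loci
}

validate_genotypes <- function(genotypes) {
  stopifnot(is.data.frame(genotypes), names(genotypes)[1] == "id")
  if (anyDuplicated(genotypes$id)) {
    stop("duplicate individual id(s): ",
         paste(unique(genotypes$id[duplicated(genotypes$id)]), collapse = ", "),
         call. = FALSE)
  }
  loci <- genotype_loci(genotypes)
  for (loc in loci) {
    m1 <- is.na(genotypes[[paste0(loc, "_1")]])
    m2 <- is.na(genotypes[[paste0(loc, "_2")]])
    if (any(m1 != m2)) {
      stop("half-missing genotype at locus ", loc,
           "; a missing call must blank the whole pair", call. = FALSE)
    }
  }
  invisible(genotypes)
}

#' Read a diploid SSR genotype table
#'
#' Reads either a plain wide CSV (header `id` then `<locus>_1`,`<locus>_2`
#' pairs) or a GenAlEx-style export (two numeric header rows, then a header
#' row with sample, population and one name per locus spanning two columns).
#' Allele tokens matching `missing_codes`, and any token that does not parse
#' as an integer, become missing; a missing call always blanks the whole
#' allele pair.
#'
#' @param path Path to the CSV file.
#' @param dialect `"wide"` (default) or `"genalex"`.
#' @param missing_codes Sentinel allele codes treated as missing data.
#' @return A genotype tibble.
#' @export
read_genotype_table <- function(path, dialect = c("wide", "genalex"),
                                missing_codes = c(0L, -9L)) {
  dialect <- match.arg(dialect)
  stopifnot(file.exists(path))
  if (dialect == "wide") {
    check_ragged_csv(path)
    raw <- readr::read_csv(path, col_types = readr::cols(
      id = readr::col_character(), .default = readr::col_character()))
    loci <- genotype_loci(raw)
    out <- raw["id"]
  } else {
    lines <- readLines(path)
    if (length(lines) < 4) stop("GenAlEx file too short", call. = FALSE)
    hdr <- strsplit(lines[3], ",")[[1]]
    loci <- hdr[seq(3, length(hdr), by = 2)]
    loci <- loci[nzchar(loci)]
    body <- utils::read.csv(text = lines[-(1:3)], header = FALSE,
                            colClasses = "character")
    if (ncol(body) < 2 + 2 * length(loci)) {
      stop("ragged GenAlEx body: expected ", 2 + 2 * length(loci),
           " columns", call. = FALSE)
    }
    raw <- tibble::tibble(id = body[[1]])
    for (j in seq_along(loci)) {
      raw[[paste0(loci[j], "_1")]] <- body[[2 * j + 1]]
      raw[[paste0(loci[j], "_2")]] <- body[[2 * j + 2]]
    }
    out <- raw["id"]
  }
  for (loc in loci) {
    v1 <- parse_allele(raw[[paste0(loc, "_1")]], missing_codes)
    v2 <- parse_allele(raw[[paste0(loc, "_2")]], missing_codes)
    miss <- is.na(v1) | is.na(v2)
    v1[miss] <- NA_integer_
    v2[miss] <- NA_integer_
    out[[paste0(loc, "_1")]] <- v1
    out[[paste0(loc, "_2")]] <- v2
  }
  validate_genotypes(out)
  out
}

parse_allele <- function(x, missing_codes) {
  v <- suppressWarnings(as.integer(trimws(x)))
  v[v %in% missing_codes] <- NA_integer_
  v
}

check_ragged_csv <- function(path) {
  n_fields <- readr::count_fields(path, tokenizer = readr::tokenizer_csv())
  ncol_expected <- n_fields[1]
  bad <- which(n_fields != ncol_expected)
  if (length(bad)) {
    stop("ragged row ", bad[1], " in ", path, ": ", n_fields[bad[1]],
         " fields, expected ", ncol_expected, call. = FALSE)
  }
  invisible(TRUE)
}

#' Write a genotype table as wide CSV
#'
#' Inverse of [read_genotype_table()] for the `"wide"` dialect; missing pairs
#' are written with the first configured sentinel code.
#'
#' @inheritParams genotype_loci
#' @param path Output path.
#' @param missing_code Sentinel written for missing calls (default 0).
#' @export
write_genotype_table <- function(genotypes, path, missing_code = 0L) {
  validate_genotypes(genotypes)
  out <- genotypes
  for (nm in setdiff(names(out), "id")) {
    v <- out[[nm]]
    v[is.na(v)] <- missing_code
    out[[nm]] <- v
  }
  readr::write_csv(out, path)
  invisible(path)
}

#' Read a passport table
#'
#' @param path CSV with columns `id`, `lon`, `lat` and optional numeric
#'   covariate columns (e.g. bioclim values).
#' @return Tibble with `id` (character), `lon`, `lat` and any covariates.
#' @export
read_passports <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    id = readr::col_character(), .default = readr::col_double()))
}

#' Reverse-jackknife outlier detection
#'
#' Flags extreme values of a numeric vector by the reverse jackknife
#' procedure of Chapman (2005), as implemented in DIVA-GIS. On the sorted
#' unique values \eqn{x_{(1)} \le \dots \le x_{(n)}}, each consecutive gap is
#' weighted by its distance from the mean,
#' \deqn{y_i = (x_{(i+1)} - x_{(i)}) \cdot (\bar{x} - x_{(i)})}
#' for gaps below the mean (and symmetrically \eqn{(x_{(i+1)} - x_{(i)})
#' (x_{(i+1)} - \bar{x})} above it), then standardized as
#' \eqn{z_i = y_i / \sqrt{\sum (y_i - \bar{y})^2 / (n-1)}}. A gap with
#' \eqn{z_i > 0.95\sqrt{n} + 0.2} separates a tail of outliers: all values at
#' or beyond the gap on the far side of the median are flagged. The procedure
#' is deterministic and applied from both tails.
#'
#' @param values Numeric vector (finite values; NAs are never flagged).
#' @return Integer vector of flagged indices into `values` (possibly empty).
#' @export
reverse_jackknife_outliers <- function(values) {
  ok <- which(is.finite(values))
  if (length(ok) < 3) {
    warning("fewer than 3 finite values; no outlier flagging performed")
    return(integer(0))
  }
  d <- unique(values[ok])
  n <- length(d)
  if (n < 2 || diff(range(d)) == 0) return(integer(0))
  x <- sort(d)
  mx <- mean(d)
  gaps_below <- x[-n] < mx
  y <- ifelse(gaps_below,
              (x[-1] - x[-n]) * (mx - x[-n]),
              (x[-1] - x[-n]) * (x[-1] - mx))
  s <- sqrt(sum((y - mean(y))^2) / (n - 1))
  if (s == 0) return(integer(0))
  z <- y / s
  crit <- 0.95 * sqrt(n) + 0.2
  big <- which(z > crit)
  if (!length(big)) return(integer(0))
  med <- median(x)
  flagged <- logical(length(values))
  for (i in big) {
    # gap between x[i] and x[i+1]; flag the tail on the far side of the median
    if (x[i] < med) flagged[values <= x[i]] <- TRUE
    if (x[i + 1] > med) flagged[values >= x[i + 1]] <- TRUE
  }
  flagged[!is.finite(values)] <- FALSE
  which(flagged)
}

#' Clean a georeferenced genotype dataset
#'
#' Drops individuals without coordinates, then flags covariate outliers per
#' column with [reverse_jackknife_outliers()] and drops individuals flagged in
#' any column (single pass over the union by default; `iterative = TRUE`
#' repeats flagging on the retained set until no new flags appear).
#'
#' @param genotypes Genotype tibble.
#' @param passports Passport tibble (`id`, `lon`, `lat`, covariates).
#' @param covariate_cols Character vector of passport columns to screen for
#'   outliers; default all numeric columns besides `lon`/`lat`.
#' @param iterative Repeat outlier flagging until stable (default FALSE).
#' @return List with elements `genotypes`, `passports` (both restricted to
#'   retained individuals) and `report` (counts and removed ids with reasons).
#' @export
clean_dataset <- function(genotypes, passports, covariate_cols = NULL,
                          iterative = FALSE) {
  validate_genotypes(genotypes)
  ids <- intersect(genotypes$id, passports$id)
  if (!length(ids)) stop("no shared ids between genotypes and passports",
                         call. = FALSE)
  pp <- dplyr::semi_join(passports, tibble::tibble(id = ids), by = "id")
  n_input <- nrow(pp)
  miss <- !is.finite(pp$lon) | !is.finite(pp$lat)
  removed_coords <- pp$id[miss]
  pp <- pp[!miss, , drop = FALSE]
  if (is.null(covariate_cols)) {
    covariate_cols <- names(pp)[vapply(pp, is.numeric, logical(1))]
    covariate_cols <- setdiff(covariate_cols, c("lon", "lat"))
  }
  removed_outliers <- character(0)
  repeat {
    flagged <- unique(unlist(lapply(covariate_cols, function(cl) {
      pp$id[reverse_jackknife_outliers(pp[[cl]])]
    })))
    removed_outliers <- c(removed_outliers, flagged)
    pp <- pp[!pp$id %in% flagged, , drop = FALSE]
    if (!iterative || !length(flagged)) break
  }
  report <- list(
    n_input = n_input,
    n_retained = nrow(pp),
    n_removed_missing_coords = length(removed_coords),
    n_removed_outliers = length(removed_outliers),
    removed_ids = tibble::tibble(
      id = c(removed_coords, removed_outliers),
      reason = rep(c("missing_coords", "covariate_outlier"),
                   c(length(removed_coords), length(removed_outliers)))))
  class(report) <- "cleaning_report"
  list(genotypes = dplyr::semi_join(genotypes, pp["id"], by = "id"),
       passports = pp,
       report = report)
}

#' @export
print.cleaning_report <- function(x, ...) {
  cat("Cleaning report: ", x$n_input, " individuals in, ",
      x$n_retained, " retained\n",
      "  removed for missing coordinates: ", x$n_removed_missing_coords, "\n",
      "  removed as covariate outliers:   ", x$n_removed_outliers, "\n",
      sep = "")
  invisible(x)
}
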