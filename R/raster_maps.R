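# Grid-aligned raster map products and ESRI ASCII grid text I/O.
#
# A div_raster stores a value matrix in map orientation (row 1 = northernmost
# row, per the ESRI ASCII standard), aligned to the global 10-arcminute cell
# lattice, with -9999 as the nodata value.

new_div_raster <- function(values, xll, yll, cell_size, statistic,
                           nodata = -9999) {
  structure(list(values = values, xll = xll, yll = yll,
                 cell_size = cell_size, nodata = nodata,
                 statistic = statistic),
            class = "div_raster")
}

#' @export
print.div_raster <- function(x, ...) {
  cat("div_raster '", x$statistic, "': ", nrow(x$values), " rows x ",
      ncol(x$values), " cols, cell ", format(x$cell_size), " deg, ",
      sum(!is.na(x$values)), " data cells\n", sep = "")
  invisible(x)
}

# (col, row) global indices -> matrix over the minimal covering subgrid
cells_to_matrix <- function(col, row, value, grid) {
  c0 <- min(col); c1 <- max(col)
  r0 <- min(row); r1 <- max(row)
  m <- matrix(NA_real_, nrow = r1 - r0 + 1, ncol = c1 - c0 + 1)
  # matrix row 1 is the NORTH row: global row r maps to matrix row r1 - r + 1
  m[cbind(r1 - row + 1, col - c0 + 1)] <- value
  list(values = m,
       xll = grid$origin[1] + c0 * grid$cell_size,
       yll = grid$origin[2] + r0 * grid$cell_size)
}

#' Raster of a per-cell statistic
#'
#' Places a column of a per-cell table onto the minimal grid-aligned raster
#' covering the cells; unfilled cells are nodata.
#'
#' @param cell_table Tibble with `col`, `row` (global cell indices) and the
#'   statistic column, e.g. from [gridwide_bootstrap()].
#' @param grid The [grid_spec()] the indices refer to.
#' @param statistic Name of the column to rasterize.
#' @param statistic_name Name stored in the raster (defaults to `statistic`).
#' @return A `div_raster`.
#' @export
diversity_raster <- function(cell_table, grid, statistic,
                             statistic_name = statistic) {
  stopifnot(statistic %in% names(cell_table),
            all(c("col", "row") %in% names(cell_table)))
  ext <- grid$extent
  cs <- grid$cell_size
  bad <- cell_table$col < round((ext[1] + 180) / cs) |
    cell_table$col >= round((ext[2] + 180) / cs) |
    cell_table$row < round((ext[3] + 90) / cs) |
    cell_table$row >= round((ext[4] + 90) / cs)
  if (any(bad)) stop("cell index outside grid extent", call. = FALSE)
  m <- cells_to_matrix(cell_table$col, cell_table$row,
                       cell_table[[statistic]], grid)
  new_div_raster(m$values, m$xll, m$yll, cs, statistic_name)
}

#' Tidy view of a raster
#'
#' @param x A `div_raster`.
#' @param ... Unused.
#' @return Tibble `lon`, `lat` (cell centers), `value` for data cells.
#' @export
tidy.div_raster <- function(x, ...) {
  nr <- nrow(x$values); nc <- ncol(x$values)
  idx <- which(!is.na(x$values), arr.ind = TRUE)
  tibble::tibble(
    lon = x$xll + (idx[, "col"] - 0.5) * x$cell_size,
    lat = x$yll + (nr - idx[, "row"] + 0.5) * x$cell_size,
    value = x$values[idx])
}

#' Per-cluster membership rasters
#'
#' For each cluster, each cell takes the HIGHEST membership value among the
#' individuals within `diameter / 2` of the cell center whose membership for
#' that cluster is at least `threshold`; cells with no qualifying individual
#' are nodata.
#'
#' @param dapc A `divgrid_dapc` object or row-stochastic membership matrix.
#' @param coords Tibble with `lon`, `lat` aligned with the membership rows.
#' @param grid A [grid_spec()].
#' @param diameter Neighborhood diameter in degrees (default 1).
#' @param threshold Minimum membership considered (default 0.7, inclusive).
#' @return Named list of `div_raster`, one per cluster.
#' @export
cluster_membership_raster <- function(dapc, coords, grid, diameter = 1,
                                      threshold = 0.7) {
  M <- if (inherits(dapc, "divgrid_dapc")) dapc$membership else dapc
  stopifnot(nrow(M) == nrow(coords))
  pass <- tibble::tibble(id = as.character(seq_len(nrow(M))),
                         lon = coords$lon, lat = coords$lat)
  asn <- replicate_samples(pass, grid, diameter)
  ridx <- as.integer(asn$id)
  out <- lapply(seq_len(ncol(M)), function(k) {
    v <- M[ridx, k]
    keep <- v >= threshold
    if (!any(keep)) return(NULL)
    sub <- asn[keep, ]
    sub$value <- v[keep]
    cells <- dplyr::summarise(
      dplyr::group_by(sub, .data$cell, .data$col, .data$row),
      value = max(.data$value), .groups = "drop")
    diversity_raster(cells, grid, "value",
                     statistic_name = paste0("membership_",
                                             colnames(M)[k] %||% k))
  })
  names(out) <- colnames(M) %||% paste0("cluster", seq_len(ncol(M)))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Cluster-richness raster
#'
#' Counts, per cell, how many clusters have data (non-nodata membership) in
#' that cell; cells covered by no cluster are nodata. Rasters must share the
#' cell lattice but may cover different subextents.
#'
#' @param membership_rasters List of `div_raster` from
#'   [cluster_membership_raster()] (NULL entries, from empty clusters, are
#'   ignored).
#' @return A `div_raster` named "cluster_richness".
#' @export
cluster_richness_raster <- function(membership_rasters) {
  rs <- Filter(Negate(is.null), membership_rasters)
  if (!length(rs)) stop("no cluster raster with data", call. = FALSE)
  cs <- rs[[1]]$cell_size
  if (any(abs(vapply(rs, `[[`, numeric(1), "cell_size") - cs) > 1e-12)) {
    stop("rasters disagree on cell size", call. = FALSE)
  }
  cells <- dplyr::bind_rows(lapply(rs, function(r) {
    td <- tidy(r)
    tibble::tibble(col = as.integer(floor((td$lon + 180) / cs)),
                   row = as.integer(floor((td$lat + 90) / cs)))
  }))
  counts <- dplyr::count(cells, .data$col, .data$row, name = "value")
  m <- cells_to_matrix(counts$col, counts$row, counts$value,
                       list(origin = c(-180, -90), cell_size = cs))
  new_div_raster(m$values, m$xll, m$yll, cs, "cluster_richness")
}

#' Write a raster as an ESRI ASCII grid
#'
#' Plain-text interchange format: 6-line header (ncols, nrows, xllcorner,
#' yllcorner, cellsize, NODATA_value) followed by the value matrix,
#' north-to-south, 6 significant digits.
#'
#' @param raster A `div_raster`.
#' @param path Output path (conventionally `.asc`).
#' @export
write_esri_ascii <- function(raster, path) {
  v <- raster$values
  v[is.na(v)] <- raster$nodata
  hdr <- c(paste("ncols", ncol(v)),
           paste("nrows", nrow(v)),
           paste("xllcorner", format(raster$xll, digits = 12)),
           paste("yllcorner", format(raster$yll, digits = 12)),
           paste("cellsize", format(raster$cell_size, digits = 12)),
           paste("NODATA_value", raster$nodata))
  body <- apply(v, 1, function(r) paste(signif(r, 6), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path Path to an `.asc` file.
#' @param statistic Statistic name to attach (default the file name).
#' @return A `div_raster`.
#' @export
read_esri_ascii <- function(path, statistic = basename(path)) {
  lines <- readLines(path)
  hdr <- strsplit(tolower(lines[1:6]), "\\s+")
  val <- setNames(as.numeric(vapply(hdr, `[`, "", 2)),
                  vapply(hdr, `[`, "", 1))
  m <- do.call(rbind, lapply(lines[-(1:6)], function(l) {
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])
  }))
  stopifnot(nrow(m) == val["nrows"], ncol(m) == val["ncols"])
  m[m == val["nodata_value"]] <- NA_real_
  new_div_raster(m, unname(val["xllcorner"]), unname(val["yllcorner"]),
                 unname(val["cellsize"]), statistic,
                 nodata = unname(val["nodata_value"]))
}

#' Plot a raster surface
#'
#' @param object A `div_raster`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.div_raster <- function(object, ...) {
  td <- tidy(object)
  ggplot2::ggplot(td, ggplot2::aes(.data$lon, .data$lat,
                                   fill = .data$value)) +
    ggplot2::geom_tile(width = object$cell_size, height = object$cell_size) +
    ggplot2::scale_fill_viridis_c(name = object$statistic) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "longitude (deg)", y = "latitude (deg)") +
    ggplot2::theme_minimal()
}
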