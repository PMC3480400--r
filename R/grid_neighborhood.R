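# Analysis grid and circular-neighborhood replication.
#
# The grid is aligned to the global origin (-180, -90) so that cell indices
# are reproducible across datasets: cell (col, row) spans the half-open
# rectangle [origin + col*cs, origin + (col+1)*cs) in each axis. Distances are
# planar Euclidean in decimal degrees: the analysis is designed for
# equatorial study regions where a degree of longitude and latitude are
# comparable (~111 km).

#' Define an analysis grid
#'
#' @param cell_minutes Cell size in arcminutes (default 10, i.e. 1/6 degree).
#' @param extent Bounding box `c(xmin, xmax, ymin, ymax)` in decimal degrees;
#'   snapped outward to cell boundaries relative to the (-180, -90) origin.
#' @return A `grid_spec` object.
#' @export
grid_spec <- function(cell_minutes = 10, extent = c(-180, 180, -90, 90)) {
  stopifnot(cell_minutes > 0, length(extent) == 4,
            extent[1] < extent[2], extent[3] < extent[4])
  cs <- cell_minutes / 60
  xmin <- -180 + floor((extent[1] + 180) / cs) * cs
  ymin <- -90 + floor((extent[3] + 90) / cs) * cs
  xmax <- -180 + ceiling((extent[2] + 180) / cs) * cs
  ymax <- -90 + ceiling((extent[4] + 90) / cs) * cs
  structure(list(cell_size = cs, origin = c(-180, -90),
                 extent = c(xmin, xmax, ymin, ymax),
                 ncol_global = as.integer(round(360 / cs))),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat("grid_spec: ", format(x$cell_size * 60), "' cells, extent [",
      paste(format(x$extent), collapse = ", "), "]\n", sep = "")
  invisible(x)
}

cell_key <- function(col, row, grid) as.integer(col + row * grid$ncol_global)

#' Grid cell containing a point
#'
#' Cells follow the half-open convention: a point on a cell boundary belongs
#' to the cell to its north/east.
#'
#' @param lon,lat Coordinate vectors in decimal degrees.
#' @param grid A [grid_spec()].
#' @return Tibble with `cell` (integer key), `col`, `row` (0-based global
#'   indices) per input point.
#' @export
cell_of <- function(lon, lat, grid) {
  cs <- grid$cell_size
  ext <- grid$extent
  bad <- lon < ext[1] | lon >= ext[2] | lat < ext[3] | lat >= ext[4] |
    !is.finite(lon) | !is.finite(lat)
  if (any(bad)) {
    i <- which(bad)[1]
    stop(sprintf("point (%g, %g) outside grid extent [%g, %g) x [%g, %g)",
                 lon[i], lat[i], ext[1], ext[2], ext[3], ext[4]),
         call. = FALSE)
  }
  col <- as.integer(floor((lon + 180) / cs))
  row <- as.integer(floor((lat + 90) / cs))
  tibble::tibble(cell = cell_key(col, row, grid), col = col, row = row)
}

cell_center <- function(col, row, grid) {
  cs <- grid$cell_size
  list(lon = -180 + (col + 0.5) * cs, lat = -90 + (row + 0.5) * cs)
}

#' Grid cells in the circular neighborhood of a point
#'
#' Returns every cell whose center lies within `diameter / 2` (planar degree
#' distance, inclusive) of the point, clipped to the grid extent. The point's
#' own cell is always part of the result.
#'
#' @param lon,lat A single point.
#' @inheritParams cell_of
#' @param diameter Neighborhood diameter in degrees (default 1).
#' @return Tibble with `cell`, `col`, `row`.
#' @export
neighborhood_cells <- function(lon, lat, grid, diameter = 1) {
  stopifnot(length(lon) == 1, length(lat) == 1, diameter > 0)
  cs <- grid$cell_size
  ext <- grid$extent
  r <- diameter / 2
  cols <- seq(floor((lon - r + 180) / cs - 0.5),
              ceiling((lon + r + 180) / cs - 0.5))
  rows <- seq(floor((lat - r + 90) / cs - 0.5),
              ceiling((lat + r + 90) / cs - 0.5))
  cand <- expand.grid(col = cols, row = rows)
  ctr <- cell_center(cand$col, cand$row, grid)
  keep <- (ctr$lon - lon)^2 + (ctr$lat - lat)^2 <= r^2 + 1e-12
  keep <- keep &
    ctr$lon > ext[1] & ctr$lon < ext[2] & ctr$lat > ext[3] & ctr$lat < ext[4]
  own <- cell_of(lon, lat, grid)
  out <- tibble::tibble(col = as.integer(cand$col[keep]),
                        row = as.integer(cand$row[keep]))
  out <- dplyr::distinct(dplyr::bind_rows(out, own[c("col", "row")]))
  out$cell <- cell_key(out$col, out$row, grid)
  dplyr::arrange(out[c("cell", "col", "row")], .data$cell)
}

#' Replicate individuals into their neighborhood cells
#'
#' Implements the circular-neighborhood replication: each individual is
#' placed (once) in every grid cell of its neighborhood, so sparse
#' collections are smoothed into contiguous map coverage.
#'
#' @param passports Tibble with `id`, `lon`, `lat` (cleaned).
#' @inheritParams neighborhood_cells
#' @return A neighborhood assignment: tibble with `cell`, `col`, `row`, `id`.
#' @export
replicate_samples <- function(passports, grid, diameter = 1) {
  stopifnot(all(c("id", "lon", "lat") %in% names(passports)))
  cell_of(passports$lon, passports$lat, grid)  # errors if any point outside
  out <- purrr::pmap_dfr(
    passports[c("id", "lon", "lat")],
    function(id, lon, lat) {
      nb <- neighborhood_cells(lon, lat, grid, diameter)
      nb$id <- id
      nb
    })
  dplyr::arrange(out, .data$cell, .data$id)
}

#' Filter neighborhood cells by minimum sample size
#'
#' Discards cells holding fewer individuals than `min_trees`. With
#' `min_trees = "auto"` the threshold is the median of the per-cell counts,
#' the rule used to standardize the bootstrap sample size.
#'
#' @param assignment Tibble from [replicate_samples()].
#' @param min_trees Integer threshold, or `"auto"` for the median per-cell
#'   count.
#' @return List with `assignment` (filtered), `stats` (retention counts) and
#'   `min_trees` (the threshold actually applied).
#' @export
filter_cells <- function(assignment, min_trees = "auto") {
  counts <- dplyr::count(assignment, .data$cell, name = "n")
  if (identical(min_trees, "auto")) {
    min_trees <- as.integer(floor(median(counts$n)))
  }
  stopifnot(is.numeric(min_trees), min_trees >= 1)
  keep <- counts$cell[counts$n >= min_trees]
  out <- assignment[assignment$cell %in% keep, , drop = FALSE]
  stats <- tibble::tibble(
    n_cells_before = nrow(counts), n_cells_after = length(keep),
    n_placements_before = nrow(assignment), n_placements_after = nrow(out),
    threshold_trees = as.integer(min_trees))
  list(assignment = out, stats = stats, min_trees = as.integer(min_trees))
}
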