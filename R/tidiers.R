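# broom-style tidiers and ggplot2 autoplot methods for fitted objects.

#' @export
tidy.divgrid_bic <- function(x, ...) x$curve

#' @export
glance.divgrid_bic <- function(x, ...) {
  tibble::tibble(chosen_k = x$chosen_k, n_pcs = x$n_pcs,
                 min_bic_k = x$curve$k[which.min(x$curve$bic)])
}

#' @export
autoplot.divgrid_bic <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(.data$k, .data$bic)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$chosen_k, linetype = 2) +
    ggplot2::labs(x = "number of clusters k", y = "BIC",
                  subtitle = paste("suggested k =", object$chosen_k)) +
    ggplot2::theme_minimal()
}

#' @export
tidy.divgrid_dapc <- function(x, ...) {
  m <- tibble::as_tibble(as.data.frame(x$membership))
  names(m) <- paste0("p_", colnames(x$membership))
  dplyr::bind_cols(tibble::tibble(id = rownames(x$membership),
                                  assigned = unname(x$assigned),
                                  max_membership = apply(x$membership, 1,
                                                         max)),
                   m)
}

#' @export
glance.divgrid_dapc <- function(x, ...) {
  tibble::tibble(k = ncol(x$membership), n = nrow(x$membership),
                 n_pcs = x$n_pcs,
                 frac_confident = mean(apply(x$membership, 1, max) > 0.7))
}

#' @export
autoplot.divgrid_dapc <- function(object, ...) {
  td <- tidy(object)
  long <- tidyr::pivot_longer(td, dplyr::starts_with("p_"),
                              names_to = "cluster", values_to = "membership")
  ggplot2::ggplot(long, ggplot2::aes(.data$id, .data$membership,
                                     fill = .data$cluster)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::facet_grid(~assigned, scales = "free_x", space = "free_x") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank()) +
    ggplot2::labs(x = NULL, y = "membership probability")
}

#' @export
tidy.divgrid_spca <- function(x, ...) x$decomposition

#' @export
glance.divgrid_spca <- function(x, ...) {
  lam <- x$eigenvalues
  tibble::tibble(n_positive = sum(lam > 0), n_negative = sum(lam < 0),
                 lambda_max = max(lam), lambda_min = min(lam),
                 trace = x$trace)
}

#' @export
autoplot.divgrid_spca <- function(object, ...) {
  df <- tibble::tibble(rank = seq_along(object$eigenvalues),
                       eigenvalue = object$eigenvalues)
  ggplot2::ggplot(df, ggplot2::aes(.data$rank, .data$eigenvalue,
                                   fill = .data$eigenvalue > 0)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::labs(x = "axis rank", y = "eigenvalue (var x Moran's I)") +
    ggplot2::theme_minimal()
}

#' @export
tidy.divgrid_mantel <- function(x, ...) {
  tibble::tibble(statistic = x$r, p_value = x$p_value, n_perm = x$n_perm)
}

#' @export
autoplot.divgrid_mantel <- function(object, ...) {
  df <- tibble::tibble(perm_r = object$perm_r)
  ggplot2::ggplot(df, ggplot2::aes(.data$perm_r)) +
    ggplot2::geom_histogram(bins = 40) +
    ggplot2::geom_vline(xintercept = object$r, colour = "red") +
    ggplot2::labs(x = "permutation Mantel r",
                  subtitle = sprintf("observed r = %.3f, p = %.4g",
                                     object$r, object$p_value)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.cluster_tree <- function(object, ...) {
  # base-graphics dendrograms do not compose with ggplot; draw segments
  hc <- object$hclust
  dend <- stats::as.dendrogram(hc)
  xy <- dendro_segments(dend)
  ggplot2::ggplot(xy) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$x0, y = .data$y0,
                                       xend = .data$x1, yend = .data$y1)) +
    ggplot2::scale_x_continuous(breaks = seq_along(hc$order),
                                labels = hc$labels[hc$order]) +
    ggplot2::labs(x = NULL, y = "Nei distance (complete linkage)",
                  subtitle = sprintf("cophenetic r = %.3f",
                                     object$cophenetic_r)) +
    ggplot2::theme_minimal()
}

# flatten a dendrogram into plottable segments
dendro_segments <- function(dend) {
  segs <- list()
  walk <- function(node) {
    if (is.leaf(node)) {
      return(c(x = attr(node, "midpoint") %||% 0, h = 0))
    }
    h <- attr(node, "height")
    kids <- lapply(seq_along(node), function(i) walk(node[[i]]))
    xs <- vapply(kids, `[[`, numeric(1), "x")
    hs <- vapply(kids, `[[`, numeric(1), "h")
    for (i in seq_along(kids)) {
      segs[[length(segs) + 1]] <<- c(xs[i], hs[i], xs[i], h)  # riser
    }
    segs[[length(segs) + 1]] <<- c(min(xs), h, max(xs), h)    # bar
    c(x = mean(range(xs)), h = h)
  }
  # leaf x positions: order along the dendrogram
  leaf_i <- 0
  assign_x <- function(node) {
    if (is.leaf(node)) {
      leaf_i <<- leaf_i + 1
      attr(node, "midpoint") <- leaf_i
      return(node)
    }
    for (i in seq_along(node)) node[[i]] <- assign_x(node[[i]])
    node
  }
  dend <- assign_x(dend)
  walk(dend)
  m <- do.call(rbind, segs)
  tibble::tibble(x0 = m[, 1], y0 = m[, 2], x1 = m[, 3], y1 = m[, 4])
}
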