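#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a simulation run
#'
#' Returns the sampled metrics series: one row per sampled month with the
#' number of live camps, total population, Simpson diversity of full status
#' vectors, and (progressive runs) per-feature mean trait complexity.
#'
#' @param x an `hg_sim`.
#' @param ... unused.
#' @return A tibble.
#' @export
tidy.hg_sim <- function(x, ...) x$metrics

#' One-row summary of a simulation run
#'
#' @param x an `hg_sim`.
#' @param ... unused.
#' @return tibble with final counts, diversity, complexity and the mobility
#'   triple (NA when no qualifying moves occurred).
#' @export
glance.hg_sim <- function(x, ...) {
  m <- x$metrics
  cc <- grep("^mean_complexity_", names(m), value = TRUE)
  mob <- tryCatch(mobility_stats(x), error = function(e)
    tibble::tibble(moves_per_year = NA_real_, km_per_move = NA_real_,
                   km_per_year = NA_real_))
  tibble::tibble(
    months = x$state$t,
    n_agents = nrow(x$final_agents),
    total_population = sum(x$final_agents$population),
    simpson = utils::tail(m$simpson, 1),
    mean_complexity = utils::tail(rowMeans(m[cc]), 1),
    moves_per_year = mob$moves_per_year,
    km_per_move = mob$km_per_move,
    km_per_year = mob$km_per_year,
    extinct = x$extinct)
}

#' Plot the metrics series of a run
#'
#' Facetted time series of camp count, total population, Simpson diversity
#' and mean trait complexity.
#'
#' @param object an `hg_sim`.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.hg_sim <- function(object, ...) {
  m <- object$metrics
  cc <- grep("^mean_complexity_", names(m), value = TRUE)
  df <- tibble::tibble(
    t = rep(m$t, 4),
    series = rep(c("camps", "total population", "Simpson diversity",
                   "mean complexity"), each = nrow(m)),
    value = c(m$n_agents, m$total_population, m$simpson, rowMeans(m[cc])))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t / 12, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~series, scales = "free_y") +
    ggplot2::labs(x = "years", y = NULL)
}

#' Plot a suitability landscape slice
#'
#' @param object a [landscape()].
#' @param slice slice index.
#' @param ... unused.
#' @return A ggplot raster of suitability (impassable cells dark).
#' @export
autoplot.suitability_landscape <- function(object, slice = 1, ...) {
  g <- object$suitability[[slice]]
  df <- expand.grid(
    x = object$origin[1] + (seq_len(nrow(g)) - 0.5) * object$cell_size,
    y = object$origin[2] + (seq_len(ncol(g)) - 0.5) * object$cell_size)
  df$suitability <- as.vector(g)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y,
                                   fill = .data$suitability)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "km", y = "km")
}

#' Plot a cluster cell map
#'
#' @param cmap label matrix from [cluster_cell_map()].
#' @param L the matching [landscape()].
#' @return A ggplot raster of cluster labels.
#' @export
plot_cluster_map <- function(cmap, L) {
  df <- expand.grid(
    x = L$origin[1] + (seq_len(nrow(cmap)) - 0.5) * L$cell_size,
    y = L$origin[2] + (seq_len(ncol(cmap)) - 0.5) * L$cell_size)
  df$label <- factor(as.vector(cmap))
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$label)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "km", y = "km", fill = "cluster")
}
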