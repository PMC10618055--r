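#' Simpson's diversity of cultural statuses
#'
#' One minus the probability that two camps drawn at random (with
#' replacement) share the same full status vector across all features:
#' `1 - sum_k p_k^2` over the frequencies `p_k` of distinct status vectors.
#' Camps weight equally.  With `per_feature = TRUE` the per-feature
#' diversities are averaged instead (the laxer reading, for sensitivity
#' checks).
#'
#' @param agents tibble with status columns `s_1..s_c` (or a bare matrix /
#'   data frame of status vectors, camps in rows).
#' @param per_feature average per-feature diversities instead of using joint
#'   vector identity.
#' @return diversity in `[0, 1 - 1/n]`.
#' @export
simpson_diversity <- function(agents, per_feature = FALSE) {
  S <- as_status(agents)
  if (nrow(S) == 0)
    stop("Simpson diversity is undefined for zero agents", call. = FALSE)
  one <- function(keys) {
    p <- tabulate(match(keys, unique(keys))) / length(keys)
    1 - sum(p^2)
  }
  if (per_feature)
    mean(apply(S, 2, one))
  else
    one(apply(S, 1, paste, collapse = "\r"))
}

as_status <- function(agents) {
  if (is.matrix(agents)) return(agents)
  sc <- status_cols(agents)
  if (length(sc)) as.matrix(agents[sc]) else as.matrix(agents)
}

#' Mean trait complexity
#'
#' Unweighted mean trait value across camps for each progressive feature
#' (the complexity analogue: how many variants a typical camp holds).
#'
#' @inheritParams simpson_diversity
#' @param mode guard: complexity is meaningful for progressive features only.
#' @return named numeric vector, one mean per feature.
#' @export
mean_complexity <- function(agents, mode = "progressive") {
  if (!identical(mode, "progressive"))
    stop("mean trait complexity is defined for progressive features only",
         call. = FALSE)
  S <- as_status(agents)
  if (nrow(S) == 0)
    stop("mean complexity is undefined for zero agents", call. = FALSE)
  stats::setNames(colMeans(S), colnames(S))
}

#' Correlation between number of camps and mean complexity
#'
#' Pearson correlation (with the standard t-test p-value) between the number
#' of live camps and the mean trait complexity (averaged over features)
#' across sampled time points of a metrics series.
#'
#' @param series metrics tibble with `n_agents` and `mean_complexity_*`
#'   columns (as produced by [hg_run()]), or vectors via `n_agents` +
#'   `complexity`.
#' @return one-row tibble `estimate`, `p.value`, `n`.
#' @export
population_complexity_correlation <- function(series) {
  cc <- grep("^mean_complexity_", names(series), value = TRUE)
  if (length(cc) == 0)
    stop("series has no mean_complexity_* columns (progressive runs only)",
         call. = FALSE)
  x <- series$n_agents
  y <- rowMeans(series[cc])
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3)
    stop("need at least 3 time points for a correlation", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for a constant series", call. = FALSE)
  ct <- stats::cor.test(x, y)
  tibble::tibble(estimate = unname(ct$estimate), p.value = ct$p.value,
                 n = length(x))
}
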