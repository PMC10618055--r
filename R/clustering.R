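#' Mobility clusters over a static-landscape window
#'
#' Pools the sampled positions of all camps inside a time window that lies
#' within one landscape slice, clusters the pooled point cloud by density
#' ([hg_hdbscan()]), and assigns each camp the majority label among its own
#' pooled points (ties favour a cluster over noise, then the lowest label).
#'
#' @param traj trajectory tibble (`t`, `id`, `x`, `y`, ...) as logged by
#'   [hg_run()].
#' @param window numeric `c(t1, t2)`, months.
#' @param min_cluster_size smallest cluster, in pooled points; default about
#'   five camps' worth of samples.
#' @param max_points subsample cap on the pooled cloud (deterministic,
#'   evenly strided).
#' @return tibble `id`, `mobility_label` (`-1` = noise).
#' @export
mobility_clusters <- function(traj, window = range(traj$t),
                              min_cluster_size = NULL, max_points = 2000) {
  pool <- traj[traj$t >= window[1] & traj$t <= window[2], ]
  if (nrow(pool) == 0)
    stop("no trajectory samples in the window", call. = FALSE)
  if (nrow(pool) > max_points)
    pool <- pool[unique(round(seq(1, nrow(pool), length.out = max_points))), ]
  n_agents <- length(unique(pool$id))
  if (is.null(min_cluster_size))
    min_cluster_size <- max(5, round(5 * nrow(pool) / n_agents))
  # one cohesive occupied region is a legitimate mobility cluster
  labs <- hg_hdbscan(cbind(pool$x, pool$y), min_cluster_size,
                     allow_single_cluster = TRUE)
  per_agent <- vapply(split(labs, pool$id), function(l) {
    tab <- sort(table(l), decreasing = TRUE)
    top <- as.integer(names(tab[tab == tab[1]]))
    if (any(top >= 0)) min(top[top >= 0]) else -1L
  }, integer(1))
  tibble::tibble(id = as.integer(names(per_agent)),
                 mobility_label = unname(per_agent))
}

#' Are two cultural statuses close?
#'
#' Non-progressive: exact vector equality.  Progressive: Euclidean distance
#' between the status vectors at most `epsilon`.
#'
#' @param s_a,s_b integer status vectors of equal length.
#' @param mode `"progressive"` or `"non-progressive"`.
#' @param epsilon closeness radius in trait units (progressive).
#' @return logical.
#' @export
status_close <- function(s_a, s_b, mode = "progressive", epsilon = 2) {
  stopifnot(length(s_a) == length(s_b))
  if (mode == "non-progressive") all(s_a == s_b)
  else sqrt(sum((s_a - s_b)^2)) <= epsilon
}

#' Time-averaged cultural connectivity matrix
#'
#' For every pair of camps, the fraction of sampled window steps at which
#' both were alive and close in status ([status_close()]).  Pairs never
#' co-alive get 0 and are flagged in the `support` attribute (the count of
#' co-alive samples).
#'
#' @inheritParams mobility_clusters
#' @param mode,epsilon see [status_close()].
#' @return symmetric matrix in `[0, 1]` with agent-id dimnames and
#'   attributes `support` (co-alive sample counts) and `window`.
#' @export
cultural_connectivity <- function(traj, window = range(traj$t),
                                  mode = "progressive", epsilon = 2) {
  pool <- traj[traj$t >= window[1] & traj$t <= window[2], ]
  if (nrow(pool) == 0)
    stop("no trajectory samples in the window", call. = FALSE)
  ids <- sort(unique(pool$id))
  n <- length(ids)
  num <- matrix(0, n, n); den <- matrix(0, n, n)
  sc <- status_cols(pool)
  for (tt in unique(pool$t)) {
    snap <- pool[pool$t == tt, ]
    idx <- match(snap$id, ids)
    S <- as.matrix(snap[sc])
    close <- if (mode == "non-progressive") {
      key <- apply(S, 1, paste, collapse = "\r")
      outer(key, key, "==")
    } else {
      as.matrix(stats::dist(S)) <= epsilon
    }
    den[idx, idx] <- den[idx, idx] + 1
    num[idx, idx] <- num[idx, idx] + close
  }
  C <- ifelse(den > 0, num / pmax(den, 1), 0)
  dimnames(C) <- list(ids, ids)
  structure(C, support = den, window = window)
}

#' Cultural clusters from the connectivity matrix
#'
#' Binarises the time-averaged connectivity at `threshold` and labels the
#' connected components of the resulting graph; every camp (including
#' singletons) gets a label.
#'
#' @param C matrix from [cultural_connectivity()].
#' @param threshold binarisation level in `(0, 1]`.
#' @return tibble `id`, `cultural_label`.
#' @export
cultural_clusters <- function(C, threshold = 0.5) {
  stopifnot(threshold > 0, threshold <= 1)
  adj <- (C >= threshold) * 1
  diag(adj) <- 0
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  tibble::tibble(id = as.integer(rownames(C)),
                 cultural_label = as.integer(comp))
}

#' Map clusters onto landscape cells
#'
#' Assigns to each grid cell the cluster whose member camps' sampled
#' positions fell into it most often within the window; ties go to the
#' lowest label, unvisited cells stay `NA`, noise camps are skipped.
#'
#' @inheritParams mobility_clusters
#' @param labels tibble `id` + one label column (e.g. from
#'   [cultural_clusters()] or [mobility_clusters()]).
#' @param L the [landscape()] defining the grid.
#' @return integer matrix (grid shape) of labels, `NA` where unassigned.
#' @export
cluster_cell_map <- function(traj, labels, L, window = range(traj$t)) {
  lab_col <- setdiff(names(labels), "id")[1]
  pool <- traj[traj$t >= window[1] & traj$t <= window[2], ]
  pool$label <- labels[[lab_col]][match(pool$id, labels$id)]
  pool <- pool[!is.na(pool$label) & pool$label >= 0, ]
  dims <- dim(L$suitability[[1]])
  cmap <- matrix(NA_integer_, dims[1], dims[2])
  if (nrow(pool) == 0) return(cmap)
  i <- floor((pool$x - L$origin[1]) / L$cell_size) + 1
  j <- floor((pool$y - L$origin[2]) / L$cell_size) + 1
  ok <- i >= 1 & i <= dims[1] & j >= 1 & j <= dims[2]
  counts <- dplyr::count(
    tibble::tibble(i = i[ok], j = j[ok], label = pool$label[ok]),
    .data$i, .data$j, .data$label)
  counts <- counts[order(counts$i, counts$j, -counts$n, counts$label), ]
  first <- !duplicated(counts[c("i", "j")])
  cmap[cbind(counts$i[first], counts$j[first])] <-
    as.integer(counts$label[first])
  cmap
}

#' Cross-tabulate two cluster labelings
#'
#' The contingency table behind an alluvial diagram: camp counts per pair of
#' labels (noise kept as its own row/column), plus, as an attribute, how
#' many distinct B-clusters each A-cluster contains.
#'
#' @param labels_a,labels_b tibbles `id` + one label column each, same camps.
#' @return tibble `label_a`, `label_b`, `n` with attribute `b_per_a`.
#' @export
cluster_overlap <- function(labels_a, labels_b) {
  ca <- setdiff(names(labels_a), "id")[1]
  cb <- setdiff(names(labels_b), "id")[1]
  j <- dplyr::inner_join(
    tibble::tibble(id = labels_a$id, label_a = labels_a[[ca]]),
    tibble::tibble(id = labels_b$id, label_b = labels_b[[cb]]),
    by = "id")
  tab <- dplyr::count(j, .data$label_a, .data$label_b)
  bpa <- dplyr::summarise(
    dplyr::group_by(tab[tab$label_a >= 0 & tab$label_b >= 0, ], .data$label_a),
    n_b = dplyr::n_distinct(.data$label_b), .groups = "drop")
  structure(tab, b_per_a = bpa)
}
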