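# Hierarchical density-based clustering (HDBSCAN-style), self-contained:
# core distances -> mutual reachability -> single-linkage hierarchy ->
# condensed tree with min_cluster_size -> excess-of-mass cluster selection.

#' Hierarchical density-based clustering
#'
#' Clusters a 2-D point cloud by density: points are connected through the
#' single-linkage hierarchy of mutual-reachability distances
#' (`max(core_i, core_j, d_ij)`, with the core distance the distance to the
#' `min_samples`-th nearest neighbour), the hierarchy is condensed so that
#' components smaller than `min_cluster_size` fall out as noise, and the
#' flat clustering maximising total stability (excess of mass) is returned.
#' The root component is never selected, so fewer than `min_cluster_size`
#' points — or a cloud with no density split — yields only noise.
#'
#' @param x two-column matrix (or data frame) of point coordinates.
#' @param min_cluster_size smallest cluster worth reporting, points.
#' @param min_samples neighbourhood size for the core distance (defaults to
#'   `min_cluster_size`).
#' @param allow_single_cluster let the root component be selected, so one
#'   cohesive cloud yields one cluster instead of noise (off by default, as
#'   in reference implementations).
#' @return integer vector of labels, `-1` for noise, clusters numbered from 1.
#' @export
hg_hdbscan <- function(x, min_cluster_size = 5,
                       min_samples = min_cluster_size,
                       allow_single_cluster = FALSE) {
  x <- as.matrix(x)
  n <- nrow(x)
  labels <- rep(-1L, n)
  if (n < 2 * min_cluster_size) {
    # no split into two clusters of min size is possible; root is excluded
    if (n < min_cluster_size) return(labels)
  }
  d <- as.matrix(stats::dist(x))
  k <- min(min_samples, n)
  core <- apply(d, 1, function(r) sort(r, partial = k)[k])
  mr <- pmax(d, outer(core, core, pmax))
  hc <- stats::hclust(stats::as.dist(mr), method = "single")

  # leaf sets per merge node
  members <- vector("list", n - 1)
  for (m in seq_len(n - 1)) {
    a <- hc$merge[m, 1]; b <- hc$merge[m, 2]
    members[[m]] <- c(if (a < 0) -a else members[[a]],
                      if (b < 0) -b else members[[b]])
  }
  node_size <- function(v) if (v < 0) 1L else length(members[[v]])
  lam <- 1 / pmax(hc$height, 1e-12)

  # condensed tree: walk merges top-down; clusters persist until they split
  # into two children of at least min_cluster_size
  cl_parent <- integer(0); cl_birth <- numeric(0); cl_node <- integer(0)
  cl_stab <- numeric(0)
  new_cluster <- function(parent, birth, node) {
    cl_parent[length(cl_parent) + 1] <<- parent
    cl_birth[length(cl_birth) + 1] <<- birth
    cl_node[length(cl_node) + 1] <<- node
    cl_stab[length(cl_stab) + 1] <<- 0
    length(cl_parent)
  }
  root <- new_cluster(0L, 0, n - 1L)
  stack <- list(list(node = n - 1L, cl = root))
  while (length(stack)) {
    fr <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    node <- fr$node; cl <- fr$cl
    l <- lam[node]
    ch <- hc$merge[node, ]
    sz <- c(node_size(ch[1]), node_size(ch[2]))
    big <- sz >= min_cluster_size
    if (all(big)) {
      # true split: cluster cl dies here, two children are born
      cl_stab[cl] <- cl_stab[cl] + sum(sz) * (l - cl_birth[cl])
      for (j in 1:2) {
        child <- new_cluster(cl, l, ch[j])
        if (ch[j] > 0) stack[[length(stack) + 1]] <-
            list(node = ch[j], cl = child)
      }
    } else if (any(big)) {
      # the small side falls out as noise; the cluster continues
      small <- which(!big); keep <- which(big)
      cl_stab[cl] <- cl_stab[cl] + sz[small] * (l - cl_birth[cl])
      if (ch[keep] > 0) stack[[length(stack) + 1]] <-
          list(node = ch[keep], cl = cl)
    } else {
      # everything falls out; the cluster ends
      cl_stab[cl] <- cl_stab[cl] + sum(sz) * (l - cl_birth[cl])
    }
  }

  n_cl <- length(cl_parent)
  if (n_cl <= 1 && !allow_single_cluster) return(labels)

  # excess-of-mass selection, children before parents (ids increase downward)
  subtree <- cl_stab
  choose_self <- rep(TRUE, n_cl)
  for (cid in n_cl:1) {
    kids <- which(cl_parent == cid)
    root_blocked <- cid == root && !allow_single_cluster
    if (length(kids)) {
      kid_sum <- sum(subtree[kids])
      if (root_blocked || kid_sum > cl_stab[cid]) {
        choose_self[cid] <- FALSE
        subtree[cid] <- kid_sum
      }
    } else if (root_blocked) choose_self[cid] <- FALSE
  }
  # top-down: selected = first choose_self cluster on the root path
  selected <- logical(n_cl)
  blocked <- logical(n_cl)
  for (cid in seq_len(n_cl)) {
    par <- cl_parent[cid]
    if (par > 0 && (blocked[par] || selected[par])) {
      blocked[cid] <- TRUE
      next
    }
    if (choose_self[cid]) selected[cid] <- TRUE
  }
  sel <- which(selected)
  for (j in seq_along(sel))
    labels[members[[cl_node[sel[j]]]]] <- j
  labels
}
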