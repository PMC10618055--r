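test_that("density clustering separates blobs, rejects sparse noise, survives duplication", {
  set.seed(4)
  blob_a <- cbind(rnorm(300, 0, 10), rnorm(300, 0, 10))
  blob_b <- cbind(rnorm(300, 200, 10), rnorm(300, 0, 10))
  lab <- hg_hdbscan(rbind(blob_a, blob_b), min_cluster_size = 30)
  expect_equal(length(setdiff(unique(lab), -1L)), 2)
  # the two blobs land in different clusters, nearly perfectly
  la <- lab[1:300][lab[1:300] > 0]
  lb <- lab[301:600][lab[301:600] > 0]
  expect_equal(length(unique(la)), 1)
  expect_equal(length(unique(lb)), 1)
  expect_false(unique(la) == unique(lb))
  expect_gt(length(la), 250)
  expect_gt(length(lb), 250)

  # sparse uniform scatter with too few points for any dense split: all noise
  sparse <- cbind(runif(60, 0, 2000), runif(60, 0, 2000))
  expect_true(all(hg_hdbscan(sparse, min_cluster_size = 40) == -1L))

  # duplicating every point with doubled min size leaves the partition intact
  X <- rbind(blob_a, blob_b)
  lab2 <- hg_hdbscan(rbind(X, X), min_cluster_size = 60)
  agree <- table(lab, lab2[seq_len(nrow(X))])
  # labels may swap names; require a one-to-one dominant mapping
  expect_equal(sum(apply(agree, 1, max)), nrow(X))
})

test_that("mobility clusters assign agents by majority over pooled points", {
  # two camps oscillating inside separate blobs over a window
  set.seed(6)
  mk_traj <- function(id, cx) tibble::tibble(
    t = seq(0, 990, by = 30), id = id,
    x = cx + rnorm(34, 0, 5), y = 50 + rnorm(34, 0, 5))
  traj <- dplyr::bind_rows(
    lapply(1:6, function(i) mk_traj(i, 0)),
    lapply(7:12, function(i) mk_traj(i, 300)))
  lab <- mobility_clusters(traj, min_cluster_size = 30)
  expect_equal(nrow(lab), 12)
  expect_equal(length(unique(lab$mobility_label[1:6])), 1)
  expect_equal(length(unique(lab$mobility_label[7:12])), 1)
  expect_false(lab$mobility_label[1] == lab$mobility_label[7])
})

test_that("status closeness: exact equality vs epsilon ball", {
  expect_true(status_close(c(3L, 1L, 0L), c(3L, 1L, 0L), "non-progressive"))
  expect_true(status_close(c(3L, 1L, 0L), c(3L, 1L, 0L), "progressive"))
  expect_true(status_close(c(3L, 1L, 0L), c(3L, 2L, 0L), "progressive", 2))
  expect_false(status_close(c(3L, 1L, 0L), c(3L, 2L, 0L), "non-progressive"))
  expect_false(status_close(c(0L, 0L), c(3L, 0L), "progressive", 2))
})

test_that("time-averaged connectivity counts co-alive close fractions", {
  # pair 1-2 always close; pair 1-3 close half the time; 4 never co-alive
  snap <- function(t, ids, s1) tibble::tibble(
    t = t, id = ids, x = 0, y = 0, population = 30, s_1 = s1)
  traj <- dplyr::bind_rows(
    snap(0, 1:3, c(0L, 0L, 0L)),
    snap(10, 1:3, c(0L, 0L, 5L)),
    snap(20, 1:3, c(1L, 1L, 1L)),
    snap(30, 1:3, c(1L, 1L, 9L)),
    snap(40, 4L, 0L))
  C <- cultural_connectivity(traj, window = c(0, 40), mode = "progressive",
                             epsilon = 1)
  expect_equal(C["1", "2"], 1)
  expect_equal(C["1", "3"], 0.5)
  expect_equal(C["1", "4"], 0)
  expect_equal(attr(C, "support")[1, 4], 0)
  expect_equal(C, t(C), ignore_attr = TRUE)
})

test_that("cultural clusters are connected components of the thresholded graph", {
  ids <- as.character(1:4)
  C <- matrix(0, 4, 4, dimnames = list(ids, ids))
  diag(C) <- 1
  C[1, 2] <- C[2, 1] <- 0.8   # a-b
  C[2, 3] <- C[3, 2] <- 0.6   # b-c
  C[1, 3] <- C[3, 1] <- 0.2   # a-c weak: still one component via b
  lab <- cultural_clusters(C, threshold = 0.5)
  expect_equal(lab$cultural_label[1], lab$cultural_label[2])
  expect_equal(lab$cultural_label[2], lab$cultural_label[3])
  expect_false(lab$cultural_label[4] == lab$cultural_label[1])

  # threshold 1 is strict: 0.99 closeness leaves singletons
  C2 <- matrix(0.99, 2, 2, dimnames = list(1:2, 1:2)); diag(C2) <- 1
  lab2 <- cultural_clusters(C2, threshold = 1)
  expect_equal(length(unique(lab2$cultural_label)), 2)
})

test_that("cluster cell maps take the modal cluster per cell with low-label ties", {
  L <- flat_landscape(0.5, nx = 4, ny = 1, cell = 10)
  traj <- tibble::tibble(
    t = rep(c(0, 10, 20, 30, 40), each = 2),
    id = rep(1:2, 5),
    x = c(5, 15, 5, 15, 5, 15, 15, 5, 15, 5),
    y = 5, population = 30, s_1 = 0L)
  labels <- tibble::tibble(id = 1:2, cultural_label = c(1L, 3L))
  cmap <- cluster_cell_map(traj, labels, L, window = c(0, 40))
  # cell 1 visited 3x by cluster 1, 2x by cluster 3
  expect_equal(cmap[1, 1], 1L)
  expect_equal(cmap[2, 1], 3L)
  expect_true(is.na(cmap[3, 1]))  # unvisited
  # tie in a fresh cell goes to the lowest label
  traj2 <- dplyr::bind_rows(traj, tibble::tibble(
    t = c(50, 60), id = 1:2, x = 35, y = 5, population = 30, s_1 = 0L))
  cmap2 <- cluster_cell_map(traj2, labels, L, window = c(0, 60))
  expect_equal(cmap2[4, 1], 1L)
})

test_that("cluster overlap tabulates pairs, keeps noise, counts B-per-A", {
  a <- tibble::tibble(id = 1:6, mobility_label = c(1L, 1L, 1L, 2L, 2L, -1L))
  b <- tibble::tibble(id = 1:6, cultural_label = c(1L, 1L, 2L, 3L, 3L, 4L))
  tab <- cluster_overlap(a, b)
  expect_equal(tab$n[tab$label_a == 1 & tab$label_b == 1], 2)
  expect_equal(tab$n[tab$label_a == 1 & tab$label_b == 2], 1)
  expect_equal(tab$n[tab$label_a == -1 & tab$label_b == 4], 1)
  bpa <- attr(tab, "b_per_a")
  expect_equal(bpa$n_b[bpa$label_a == 1], 2)  # mobility cluster 1 spans 2
  expect_equal(bpa$n_b[bpa$label_a == 2], 1)

  ident <- cluster_overlap(a, dplyr::rename(a, lab = mobility_label))
  expect_true(all(ident$label_a == ident$label_b))
})

test_that("connectivity is stable under stride thinning for constant statuses", {
  snap <- function(t) tibble::tibble(t = t, id = 1:3, x = 0, y = 0,
                                     population = 30,
                                     s_1 = c(0L, 0L, 4L))
  traj <- dplyr::bind_rows(lapply(seq(0, 90, by = 10), snap))
  C_all <- cultural_connectivity(traj, mode = "progressive", epsilon = 1)
  C_thin <- cultural_connectivity(traj[traj$t %% 20 == 0, ],
                                  mode = "progressive", epsilon = 1)
  expect_equal(C_all, C_thin, ignore_attr = TRUE)
})
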