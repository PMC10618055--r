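test_that("the banded network applies the radii and rates with inclusive boundaries", {
  # collinear camps at 0, 10, 30, 100 km; r1 = 20, r2 = 50
  ag <- mk_agents(c(0, 10, 30, 100), c(0, 0, 0, 0))
  A <- build_network(ag, r1 = 20, r2 = 50, phi_1 = 0.02, phi_2 = 0.002)
  expect_equal(A[1, 2], 0.02)
  expect_equal(A[1, 3], 0.002)
  expect_equal(A[2, 3], 0.02)   # d = 20 exactly: inclusive short range
  expect_equal(A[1, 4], 0)
  expect_equal(A[2, 4], 0)
  expect_equal(A[3, 4], 0)      # d = 70 > r2
  expect_equal(A, t(A))
  expect_equal(diag(A), rep(0, 4), ignore_attr = TRUE)

  expect_equal(dim(build_network(mk_agents(0, 0))), c(1, 1))
  expect_error(build_network(ag, r1 = 50, r2 = 20), "r1 < r2")

  # permuting agents permutes but does not change the weighted edge set
  p <- c(3, 1, 4, 2)
  Ap <- build_network(ag[p, ], r1 = 20, r2 = 50, phi_1 = 0.02, phi_2 = 0.002)
  expect_equal(Ap, A[p, p], ignore_attr = TRUE)
})

test_that("network construction matches a brute-force oracle on random configurations", {
  set.seed(9)
  for (rep in 1:3) {
    n <- sample(50:200, 1)
    ag <- mk_agents(runif(n, 0, 300), runif(n, 0, 300))
    A <- build_network(ag, 20, 50, 0.1, 0.01)
    B <- matrix(0, n, n)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == j) next
      d <- sqrt((ag$x[i] - ag$x[j])^2 + (ag$y[i] - ag$y[j])^2)
      B[i, j] <- if (d <= 20) 0.1 else if (d <= 50) 0.01 else 0
    }
    expect_equal(unname(A), B)
  }
})

test_that("event-rate catalogue: floor rule, difference rule, identical statuses", {
  cp <- culture_params(mode = "progressive", c_features = 3, gamma_i = 0.001,
                       lambda_i = 0.02, phi_1 = 0.02, phi_2 = 0.002)
  # isolated progressive agent at the floor: only innovation, total 3 gamma
  lone <- mk_agents(0, 0, status = matrix(0L, 1, 3))
  cat1 <- event_rate_catalogue(lone, matrix(0, 1, 1), cp)
  expect_true(all(cat1$kind == "innovation"))
  expect_equal(sum(cat1$rate), 3 * 0.001)

  # adoption rate = phi1 * (trait difference); only uphill
  pair <- mk_agents(c(0, 5), c(0, 0),
                    status = rbind(c(2L, 0L, 0L), c(5L, 0L, 0L)))
  A <- build_network(pair, 20, 50, 0.02, 0.002)
  cat2 <- event_rate_catalogue(pair, A, cp)
  ad <- cat2[cat2$kind == "adoption", ]
  expect_equal(nrow(ad), 1)
  expect_equal(ad$id, 1L)
  expect_equal(ad$feature, 1L)
  expect_equal(ad$rate, 0.02 * 3)

  # non-progressive identical pair: no copying, only 2 c gamma switching
  cpn <- culture_params(mode = "non-progressive", c_features = 2,
                        gamma_i = 1e-3, Q = 4, phi_1 = 0.02, phi_2 = 0.002)
  same <- mk_agents(c(0, 5), c(0, 0), status = rbind(c(1L, 2L), c(1L, 2L)))
  An <- build_network(same, 20, 50, 0.02, 0.002)
  cat3 <- event_rate_catalogue(same, An, cpn)
  expect_true(all(cat3$kind == "switch"))
  expect_equal(sum(cat3$rate), 2 * 2 * 1e-3)
})

test_that("apply_event enforces bounds, gradual change, and staleness", {
  cp <- culture_params(mode = "progressive", c_features = 2)
  ag <- mk_agents(c(0, 5), c(0, 0), status = rbind(c(1L, 0L), c(5L, 0L)))
  ev <- tibble::tibble(kind = "loss", id = 1L, feature = 1L, old = 1L,
                       new = 0L)
  out <- apply_event(ag, ev, cp)
  expect_equal(out$s_1[1], 0L)

  # adoption increments by exactly 1 even when the source is far ahead
  ev2 <- tibble::tibble(kind = "adoption", id = 1L, feature = 1L, old = 1L,
                        new = 2L, source_id = 2L)
  expect_equal(apply_event(ag, ev2, cp)$s_1[1], 2L)

  stale <- tibble::tibble(kind = "loss", id = 1L, feature = 1L, old = 3L,
                          new = 2L)
  expect_error(apply_event(ag, stale, cp), "stale")

  cpn <- culture_params(mode = "non-progressive", c_features = 2, Q = 4)
  bad <- tibble::tibble(kind = "switch", id = 1L, feature = 1L, old = 1L,
                        new = 4L)
  expect_error(apply_event(ag, bad, cpn), "Q-1")
})

test_that("non-progressive switches always change state and stay in range", {
  cp <- culture_params(mode = "non-progressive", c_features = 1,
                       gamma_i = 0.5, Q = 4, phi_1 = 0, phi_2 = 0)
  ag <- mk_agents(0, 0, status = matrix(2L, 1, 1))
  set.seed(21)
  res <- gillespie_window(ag, matrix(0, 1, 1), cp, t0 = 0, dt = 50)
  ev <- res$events
  expect_gt(nrow(ev), 5)
  expect_true(all(ev$new != ev$old))
  expect_true(all(ev$new %in% 0:3))
  expect_true(all(ev$kind == "switch"))
})

test_that("adoption-only dynamics converge to the initial maximum without exceeding it", {
  # 5 camps on a line, gamma = lambda = 0: pure adoption
  cp <- culture_params(mode = "progressive", c_features = 1, gamma_i = 0,
                       lambda_i = 0, phi_1 = 0.5, phi_2 = 0.05)
  ag <- mk_agents(seq(0, 60, by = 15), rep(0, 5),
                  status = matrix(c(0L, 3L, 1L, 0L, 2L), 5, 1))
  A <- build_network(ag, 20, 50, 0.5, 0.05)
  set.seed(8)
  t0 <- 0
  for (w in 1:400) {
    res <- gillespie_window(ag, A, cp, t0 = t0, dt = 1)
    ag <- res$agents
    expect_lte(max(ag$s_1), 3L)
    t0 <- t0 + 1
    if (all(ag$s_1 == 3L)) break
  }
  expect_true(all(ag$s_1 == 3L))
})

test_that("non-progressive copying reaches consensus on a connected network", {
  cp <- culture_params(mode = "non-progressive", c_features = 1, gamma_i = 0,
                       Q = 4, phi_1 = 0.5, phi_2 = 0.05)
  set.seed(12)
  consensus <- 0
  for (rep in 1:10) {
    ag <- mk_agents(seq(0, 40, by = 10), rep(0, 5),
                    status = matrix(sample(0:3, 5, TRUE), 5, 1))
    A <- build_network(ag, 20, 50, 0.5, 0.05)
    for (w in 1:600) {
      ag <- gillespie_window(ag, A, cp, t0 = w, dt = 1)$agents
      if (length(unique(ag$s_1)) == 1) break
    }
    if (length(unique(ag$s_1)) == 1) consensus <- consensus + 1
  }
  expect_gte(consensus, 9)
})

test_that("replaying the event log reproduces the final state exactly", {
  cp <- culture_params(mode = "progressive", c_features = 3, gamma_i = 0.01,
                       lambda_i = 0.05, phi_1 = 0.3, phi_2 = 0.05)
  set.seed(33)
  ag0 <- mk_agents(c(0, 10, 25, 40, 70), rep(0, 5),
                   status = matrix(sample(0:4, 15, TRUE), 5, 3))
  A <- build_network(ag0, 20, 50, 0.3, 0.05)
  ag <- ag0
  events <- list()
  for (w in 1:50) {
    res <- gillespie_window(ag, A, cp, t0 = w - 1, dt = 1)
    ag <- res$agents
    events[[w]] <- res$events
  }
  log <- dplyr::bind_rows(events)
  expect_gt(nrow(log), 10)
  replayed <- replay_events(ag0, log, cp)
  expect_equal(replayed, ag)
})
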