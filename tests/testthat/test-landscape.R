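test_that("landscape construction validates values, shapes and slice coverage", {
  g <- matrix(0.5, 4, 4)
  sb2 <- data.frame(t_start_bp = c(120000, 80000), t_end_bp = c(80000, 0))
  L <- landscape(list(g, g * 0.2), sb2, cell_size = 50)
  expect_s3_class(L, "suitability_landscape")
  expect_length(L$suitability, 2)

  bad <- g; bad[2, 2] <- 1.3
  expect_error(landscape(list(bad), data.frame(t_start_bp = 1, t_end_bp = 0)),
               "\\[0, 1\\]")
  gap <- data.frame(t_start_bp = c(120000, 70000), t_end_bp = c(80000, 0))
  expect_error(landscape(list(g, g), gap, cell_size = 50), "contiguous")
  expect_error(landscape(list(g), sb2, cell_size = 50), "one slice interval")
  expect_error(
    landscape(list(g), data.frame(t_start_bp = 1, t_end_bp = 0),
              friction = matrix(0, 3, 3)),
    "friction")
})

test_that("ESRI ASCII round trip preserves grids, georeference and slices", {
  dir <- withr::local_tempdir()
  L <- synth_landscape(nx = 12, ny = 9, cell_size = 5, n_slices = 2,
                       smoothness = 15, bp_start = 2000, bp_end = 0, seed = 7)
  idx <- write_landscape(L, dir = dir)
  L2 <- read_landscape(idx, dir = dir)
  for (s in 1:2)
    expect_equal(L2$suitability[[s]], L$suitability[[s]], tolerance = 1e-8)
  expect_equal(L2$slice_bp$t_start_bp, L$slice_bp$t_start_bp)
  expect_equal(L2$cell_size, L$cell_size)

  # out-of-range cells are rejected at load
  f <- file.path(dir, "bad.asc")
  writeLines(c("ncols 2", "nrows 1", "xllcorner 0", "yllcorner 0",
               "cellsize 1", "NODATA_value -9999", "0.2 1.3"), f)
  ti <- data.frame(slice_file = "bad.asc", t_start_bp = 1, t_end_bp = 0)
  expect_error(read_landscape(ti, dir = dir), "format error")
})

test_that("suitability interpolation: cell centres, bilinear midpoint, mask", {
  g <- matrix(c(0.2, 0.6), 2, 1)  # centres at x = 0.5, 1.5
  L <- landscape(list(g), data.frame(t_start_bp = 1, t_end_bp = 0),
                 cell_size = 1)
  expect_equal(suitability_at(L, 0.5, 0.5, 0.5), 0.2)
  expect_equal(suitability_at(L, 1.5, 0.5, 0.5), 0.6)
  expect_equal(suitability_at(L, 1.0, 0.5, 0.5), 0.4)  # midpoint
  expect_equal(suitability_at(L, 50, 50, 0.5), 0)      # outside domain
  expect_error(suitability_at(L, 0.5, 0.5, 5), "horizon")
})

test_that("suitability is piecewise stationary: continuous within a slice, jumps at boundaries", {
  L <- synth_landscape(nx = 10, ny = 10, cell_size = 10, n_slices = 2,
                       smoothness = 20, bp_start = 1000, bp_end = 0, seed = 1)
  x <- 55; y <- 55
  expect_equal(suitability_at(L, x, y, 900), suitability_at(L, x, y, 501))
  expect_false(isTRUE(all.equal(suitability_at(L, x, y, 501),
                                suitability_at(L, x, y, 499))))
})

test_that("potential gradient: flat field zero, linear field exact, maxima stationary", {
  lp <- landscape_params(env_weight = 2)
  Lf <- flat_landscape(0.7)
  expect_equal(potential_gradient(Lf, lp, 95, 95, 500), cbind(0, 0))

  # s increasing linearly in x with slope g: grad V = (-w_env * g, 0)
  slope <- 0.004
  g <- matrix(rep(slope * ((1:20) - 0.5) * 10, 20), 20, 20)
  Ll <- landscape(list(g), data.frame(t_start_bp = 1, t_end_bp = 0),
                  cell_size = 10)
  gr <- potential_gradient(Ll, lp, 95, 95, 0.5)
  expect_equal(gr[1, 1], -2 * slope, tolerance = 1e-10)
  expect_equal(gr[1, 2], 0)

  # near-zero gradient at the argmax of a smooth field
  Ls <- synth_landscape(nx = 50, ny = 50, cell_size = 5, n_slices = 1,
                        smoothness = 60, bp_start = 1, bp_end = 0, seed = 5)
  m <- which(Ls$suitability[[1]] == max(Ls$suitability[[1]]),
             arr.ind = TRUE)[1, ]
  gm <- potential_gradient(Ls, lp, (m[1] - 0.5) * 5, (m[2] - 0.5) * 5, 0.5)
  expect_lt(sqrt(sum(gm^2)), 2e-3 * lp$env_weight)
})

test_that("noise scale follows friction linearly, floors, and vanishes at barriers", {
  lp <- landscape_params(sigma0 = 0.4)
  Lf <- flat_landscape(0.5)
  expect_equal(sigma_at(Lf, lp, 95, 95), 0.4)
  fr <- matrix(0, 20, 20); fr[5, ] <- 1; fr[6, ] <- 0.5
  Lb <- flat_landscape(0.5, friction = fr)
  expect_lte(sigma_at(Lb, lp, 45, 95), 4e-7)      # friction 1, in cell 5
  expect_equal(sigma_at(Lb, lp, 55, 95), 0.2)     # friction 0.5
  expect_equal(sigma_at(Lb, lp, 500, 95), 0)      # outside domain
})

test_that("carrying capacity is the disc-integrated suitability, linear in kappa", {
  lp <- landscape_params(kappa = 0.05)
  L0 <- flat_landscape(0)
  expect_equal(carrying_capacity(L0, lp, 100, 100, 500, r1 = 20), 0)

  # fine grid so the disc integral is accurate: K ~ kappa * pi * r1^2
  L1 <- flat_landscape(1, nx = 60, ny = 60, cell = 2)
  K <- carrying_capacity(L1, lp, 60, 60, 500, r1 = 20)
  expect_equal(K, 0.05 * pi * 400, tolerance = 0.05)

  lp2 <- landscape_params(kappa = 0.1)
  expect_equal(carrying_capacity(L1, lp2, 60, 60, 500, r1 = 20), 2 * K,
               tolerance = 1e-10)

  # monotone under pointwise increase of suitability
  Ls <- synth_landscape(nx = 20, ny = 20, cell_size = 10, n_slices = 1,
                        smoothness = 30, bp_start = 1, bp_end = 0, seed = 2)
  g2 <- pmin(Ls$suitability[[1]] + 0.2, 1)
  Lup <- landscape(list(g2), data.frame(t_start_bp = 1, t_end_bp = 0),
                   cell_size = 10)
  expect_gte(carrying_capacity(Lup, lp, 100, 100, 0.5, 20),
             carrying_capacity(Ls, lp, 100, 100, 0.5, 20))
})

test_that("equilibrium sampling is proportional to suitability and seeded", {
  g <- matrix(c(0.9, 0.1, 0, 0), 2, 2)
  L <- landscape(list(g), data.frame(t_start_bp = 1, t_end_bp = 0),
                 cell_size = 1)
  pts <- sample_equilibrium(L, 0.5, 10000, seed = 11)
  frac_first <- mean(pts$x < 1 & pts$y < 1)
  expect_equal(frac_first, 0.9, tolerance = 0.012)
  expect_true(all(pts$y < 1))  # zero-suitability cells never sampled

  pts2 <- sample_equilibrium(L, 0.5, 10000, seed = 11)
  expect_identical(pts, pts2)

  L0 <- flat_landscape(0)
  expect_error(sample_equilibrium(L0, 500, 5), "zero")
})

test_that("synthetic landscapes are deterministic, barrier-aware, and smoothness-controlled", {
  a <- synth_landscape(nx = 30, ny = 30, n_slices = 2, seed = 9)
  b <- synth_landscape(nx = 30, ny = 30, n_slices = 2, seed = 9)
  expect_equal(a$suitability, b$suitability)
  expect_false(isTRUE(all.equal(a$suitability[[1]], a$suitability[[2]])))

  bar <- synth_landscape(nx = 30, ny = 30, cell_size = 5, n_slices = 1,
                         barrier = list(orientation = "v", at = 75,
                                        width = 5), seed = 3)
  expect_true(all(bar$friction[15, ] == 1))
  expect_true(all(bar$suitability[[1]][15, ] == 0))

  # longer correlation length -> higher lag correlation (variogram proxy)
  lagcor <- function(L, lag) {
    g <- L$suitability[[1]]
    stats::cor(as.vector(g[1:(nrow(g) - lag), ]),
               as.vector(g[(1 + lag):nrow(g), ]))
  }
  smooth <- synth_landscape(nx = 80, ny = 80, cell_size = 5,
                            smoothness = 100, n_slices = 1, seed = 4)
  rough <- synth_landscape(nx = 80, ny = 80, cell_size = 5,
                           smoothness = 10, n_slices = 1, seed = 4)
  expect_gt(lagcor(smooth, 4), lagcor(rough, 4))
})
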