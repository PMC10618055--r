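small_cfg <- function(seed = 1, horizon = 60, N0 = 25, mode = "progressive",
                      ...) {
  L <- synth_landscape(nx = 30, ny = 30, cell_size = 10, n_slices = 2,
                       smoothness = 60, bp_start = 100, bp_end = 0, seed = 99)
  hg_config(L, horizon = horizon, N0 = N0, seed = seed, mode = mode,
            lparams = landscape_params(env_weight = 100,
                                       kappa = 90 / (pi * 400)),
            metrics_stride = 12, traj_stride = 12, ...)
}

test_that("initialisation follows the stated rules and is seed-deterministic", {
  cfg <- small_cfg(N0 = 40)
  st <- hg_init(cfg)
  ag <- hg_agents(st)
  expect_equal(nrow(ag), 40)
  expect_true(all(ag[paste0("s_", 1:3)] == 0))  # progressive floor
  expect_true(all(ag$population >= 18 & ag$population <= 60))
  expect_true(all(suitability_at(cfg$landscape, ag$x, ag$y,
                                 cfg$bp_start) > 0))

  st2 <- hg_init(cfg)
  expect_identical(hg_agents(st2), ag)

  cfgn <- small_cfg(N0 = 40, mode = "non-progressive")
  agn <- hg_agents(hg_init(cfgn))
  S <- as.matrix(agn[paste0("s_", 1:3)])
  expect_true(all(S >= 0 & S <= 15))
  expect_gt(length(unique(as.vector(S))), 1)  # random, not constant
})

test_that("a step with zero rates and zero noise changes only the clock", {
  L <- flat_landscape(0.5, nx = 30, ny = 30, cell = 10, bp_start = 100)
  cfg <- hg_config(
    L, horizon = 10, N0 = 8, seed = 2,
    lparams = landscape_params(sigma0 = 1e-12, kappa = 1e-9),
    mparams = mobility_params(a_att = 1e-12,
                              a_rep = 1e-12),
    dparams = demography_params(rho_g = 0, rho_d = 0),
    cparams = culture_params(gamma_i = 0, lambda_i = 0, phi_1 = 0,
                             phi_2 = 0),
    metrics_stride = 1, traj_stride = 1)
  st0 <- hg_init(cfg)
  st1 <- hg_step(st0, cfg)
  expect_equal(st1$t, st0$t + 1)
  expect_equal(st1$pos, st0$pos, tolerance = 1e-9)
  expect_equal(st1$D, st0$D)
  expect_equal(st1$S, st0$S)
  expect_equal(st1$ids, st0$ids)
})

test_that("runs are fully reproducible and checkpoints resume bit-exactly", {
  cfg <- small_cfg(horizon = 48)
  sim_a <- hg_run(cfg)
  sim_b <- hg_run(cfg)
  expect_identical(sim_a$final_agents, sim_b$final_agents)
  expect_identical(sim_a$metrics, sim_b$metrics)
  expect_identical(sim_a$events_culture, sim_b$events_culture)

  half <- hg_run(small_cfg(horizon = 24))
  resumed <- hg_run(cfg, resume_from = half$state)
  expect_equal(resumed$final_agents, sim_a$final_agents)
  expect_equal(resumed$state$t, sim_a$state$t)
  expect_identical(resumed$state$S, sim_a$state$S)
  expect_equal(resumed$state$D, sim_a$state$D)
})

test_that("horizon 0 yields only the initial state; slices refresh on schedule", {
  cfg <- small_cfg(horizon = 0)
  sim <- hg_run(cfg)
  expect_equal(nrow(sim$metrics), 1)
  expect_equal(sim$metrics$t, 0)
  expect_equal(nrow(sim$final_agents), cfg$N0)

  # two slices over 100 years: the slice index advances past the boundary
  cfg2 <- small_cfg(horizon = 660)
  sim2 <- hg_run(cfg2)
  expect_equal(sim2$state$slice, 2)
})

test_that("toggling culture off leaves the mobility draws untouched (stream isolation)", {
  cfg_on <- small_cfg(horizon = 36)
  cfg_off <- small_cfg(horizon = 36, culture_on = FALSE)
  sim_on <- hg_run(cfg_on)
  sim_off <- hg_run(cfg_off)
  # same camps, same positions: culture has its own RNG stream
  expect_equal(sim_on$trajectory$x, sim_off$trajectory$x)
  expect_equal(sim_on$trajectory$y, sim_off$trajectory$y)
  expect_true(all(sim_off$events_culture$t == 0 |
                    nrow(sim_off$events_culture) == 0))
})

test_that("the population ledger reconciles growth and extinctions exactly", {
  cfg <- small_cfg(horizon = 120)
  sim <- hg_run(cfg)
  initial_total <- sum(hg_agents(hg_init(cfg))$population)
  final_total <- sum(sim$final_agents$population)
  expect_equal(initial_total + sim$cum_growth - sim$cum_extinct, final_total,
               tolerance = 1e-8)
  # fission/fusion events in the log conserve people by construction
  dem <- sim$events_demography
  ext <- dem[dem$kind == "extinction", ]
  expect_equal(sum(ext$population), sim$cum_extinct, tolerance = 1e-8)
})

test_that("total extinction terminates the run gracefully", {
  # barely habitable landscape: every camp declines and dies
  L <- flat_landscape(0.01, nx = 50, ny = 50, cell = 10, bp_start = 10000)
  cfg <- hg_config(L, horizon = 60000, N0 = 2, seed = 3,
                   lparams = landscape_params(kappa = 1e-4),
                   dparams = demography_params(rho_d = 0.05),
                   metrics_stride = 1200, traj_stride = 1200)
  sim <- hg_run(cfg)
  expect_true(sim$extinct)
  expect_equal(nrow(sim$final_agents), 0)
  expect_lt(sim$state$t, 60000)
})

test_that("tidy, glance and autoplot expose the run in standard forms", {
  sim <- hg_run(small_cfg(horizon = 36))
  td <- tidy(sim)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("t", "n_agents", "simpson") %in% names(td)))
  gl <- glance(sim)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$months, 36)
  p <- autoplot(sim)
  expect_s3_class(p, "ggplot")
})
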