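#' Compare simulated mobility with ethnographic reference values
#'
#' Puts the run's mobility triple (residential moves per year, mean km per
#' move, total km per year) side by side with published reference ranges for
#' Central African hunter-gatherers: Aka 8 moves/yr of ~7 km (~60 km/yr) and
#' Mbuti 5-11 moves/yr of 5-8 km (~57 km/yr).
#'
#' @param x an `hg_sim` run, or a one-row tibble from [mobility_stats()].
#' @return tibble `group`, `moves_per_year_min/max`, `km_per_move_min/max`,
#'   `km_per_year`.
#' @export
mobility_comparison <- function(x) {
  if (inherits(x, "hg_sim")) x <- mobility_stats(x)
  if (nrow(x) == 0) stop("empty mobility statistics", call. = FALSE)
  tibble::tibble(
    group = c("Aka", "Mbuti", "model"),
    moves_per_year_min = c(8, 5, x$moves_per_year),
    moves_per_year_max = c(8, 11, x$moves_per_year),
    km_per_move_min = c(7, 5, x$km_per_move),
    km_per_move_max = c(7, 8, x$km_per_move),
    km_per_year = c(60, 57, x$km_per_year))
}

#' Reduced-scale study configuration
#'
#' The desk-scale conditions used throughout the validation experiments:
#' a 100 x 100 synthetic landscape of 5 km cells (500 x 500 km) with 10
#' slices over the horizon, 150 starting camps, 2000 simulated years, and
#' progressive culture at the high innovation rate.  The landscape is fixed
#' across run seeds (like a shared palaeo-landscape stack) unless
#' `landscape_seed` is changed.  `env_weight` and `kappa` are calibrated so
#' that drift competes with the 0.4 noise scale and fission-fusion turnover
#' stays active at mid-range suitabilities (see the methods vignette).
#'
#' @param seed run seed.
#' @param phi adoption-rate pair `c(phi_1, phi_2)`.
#' @param mode cultural mode.
#' @param gamma_i,lambda_i innovation/loss rates, month^-1.
#' @param horizon months (2000 years by default).
#' @param N0 starting camps.
#' @param burn_in months of dynamics on the frozen initial landscape before
#'   logging starts (lets demography and culture equilibrate away from the
#'   arbitrary initial condition).
#' @param landscape optional pre-built [landscape()] (must cover the
#'   horizon); default a fresh synthetic one.
#' @param landscape_seed seed of the default synthetic landscape.
#' @param ... passed on to [hg_config()].
#' @return An [hg_config()].
#' @export
reduced_config <- function(seed = 1, phi = c(0.05, 0.005),
                           mode = "progressive", gamma_i = 1e-4,
                           lambda_i = 0.02, horizon = 24000, N0 = 150,
                           burn_in = 2400, landscape = NULL,
                           landscape_seed = 2026, ...) {
  if (is.null(landscape))
    landscape <- synth_landscape(nx = 100, ny = 100, cell_size = 5,
                                 n_slices = 10, smoothness = 50,
                                 bp_start = horizon / 12, bp_end = 0,
                                 seed = landscape_seed)
  hg_config(
    landscape = landscape, horizon = horizon, N0 = N0, seed = seed,
    mode = mode,
    lparams = landscape_params(env_weight = 250, kappa = 90 / (pi * 20^2)),
    cparams = culture_params(mode = mode, gamma_i = gamma_i,
                             lambda_i = lambda_i, phi_1 = phi[1],
                             phi_2 = phi[2]),
    metrics_stride = 120, traj_stride = 120, burn_in = burn_in, ...)
}

#' The three adoption-rate conditions
#'
#' Low, medium and high adoption pairs `(phi_1, phi_2)` spanning the studied
#' ranges: (0.02, 0.002), (0.05, 0.005), (0.1, 0.01).
#'
#' @return tibble `condition`, `phi_1`, `phi_2`.
#' @export
adoption_conditions <- function() {
  tibble::tibble(condition = c("low", "medium", "high"),
                 phi_1 = c(0.02, 0.05, 0.1),
                 phi_2 = c(0.002, 0.005, 0.01))
}

#' Population-complexity correlations across adoption conditions
#'
#' Runs the reduced-scale progressive model under the low/medium/high
#' adoption conditions for several seeds and computes, per run, the Pearson
#' correlation between the number of camps and the mean trait complexity
#' over the sampled series.
#'
#' @param seeds integer vector of run seeds.
#' @param ... passed to [reduced_config()] (e.g. `horizon`, `N0`).
#' @return tibble `condition`, `phi_1`, `phi_2`, `seed`, `estimate`,
#'   `p.value`, `n`.
#' @export
adoption_correlation_experiment <- function(seeds = 1:5, ...) {
  conds <- adoption_conditions()
  purrr::pmap_dfr(conds, function(condition, phi_1, phi_2) {
    purrr::map_dfr(seeds, function(s) {
      sim <- hg_run(reduced_config(seed = s, phi = c(phi_1, phi_2), ...))
      dplyr::bind_cols(
        tibble::tibble(condition = condition, phi_1 = phi_1, phi_2 = phi_2,
                       seed = s),
        population_complexity_correlation(sim$metrics))
    })
  })
}

#' Parameter sweep
#'
#' Runs all combinations of a parameter grid and seeds at reduced scale and
#' returns a long results table.  Recognised grid columns: `phi_1`, `phi_2`,
#' `gamma_i`, `lambda_i`, `mode`, `h_fus`, `h_fis`; others are passed to
#' [reduced_config()].
#'
#' @param grid data frame of parameter combinations.
#' @param seeds integer vector of run seeds.
#' @param ... shared arguments for [reduced_config()].
#' @return tibble: the grid row, `seed`, `n_agents_final`,
#'   `mean_n_agents`, `simpson_final`, `mean_simpson`, `complexity_final`,
#'   `mean_complexity`, `error` (NA unless the run failed).
#' @export
hg_sweep <- function(grid, seeds = 1, ...) {
  grid <- tibble::as_tibble(grid)
  purrr::map_dfr(seq_len(nrow(grid)), function(r) {
    row <- grid[r, ]
    purrr::map_dfr(seeds, function(s) {
      out <- dplyr::bind_cols(row, tibble::tibble(seed = s))
      res <- tryCatch({
        args <- list(seed = s, ...)
        if (!is.null(row$phi_1)) args$phi <- c(row$phi_1, row$phi_2)
        for (nm in c("gamma_i", "lambda_i", "mode"))
          if (nm %in% names(row)) args[[nm]] <- row[[nm]]
        if (any(c("h_fus", "h_fis") %in% names(row))) {
          dp <- demography_params(
            h_fus = if ("h_fus" %in% names(row)) row$h_fus else 18,
            h_fis = if ("h_fis" %in% names(row)) row$h_fis else 60)
          args$dparams <- dp
        }
        sim <- hg_run(do.call(reduced_config, args))
        m <- sim$metrics
        cc <- grep("^mean_complexity_", names(m), value = TRUE)
        cx <- rowMeans(m[cc])
        tibble::tibble(
          n_agents_final = utils::tail(m$n_agents, 1),
          mean_n_agents = mean(m$n_agents),
          simpson_final = utils::tail(m$simpson, 1),
          mean_simpson = mean(m$simpson, na.rm = TRUE),
          complexity_final = utils::tail(cx, 1),
          mean_complexity = mean(cx, na.rm = TRUE),
          error = NA_character_)
      }, error = function(e) tibble::tibble(error = conditionMessage(e)))
      dplyr::bind_cols(out, res)
    })
  })
}

#' Landscape-fragmentation experiment
#'
#' Compares the number of mobility clusters on a one-patch versus a
#' two-patch landscape of identical total suitability (two patches of scale
#' `radius / sqrt(2)` carry the same integrated suitability as one of scale
#' `radius`).  Mobility-only runs (culture off).
#'
#' @param seeds run seeds.
#' @param horizon months.
#' @param N0 starting camps.
#' @param radius one-patch Gaussian scale, km.
#' @return tibble `landscape`, `seed`, `n_clusters`.
#' @export
fragmentation_experiment <- function(seeds = 1:5, horizon = 24000, N0 = 150,
                                     radius = 90) {
  bp <- horizon / 12
  one <- patch_landscape(centers = list(c(250, 250)), radius = radius,
                         bp_start = bp, bp_end = 0)
  two <- patch_landscape(centers = list(c(150, 250), c(350, 250)),
                         radius = radius / sqrt(2), bp_start = bp, bp_end = 0)
  run_count <- function(L, s) {
    cfg <- reduced_config(seed = s, horizon = horizon, N0 = N0,
                          landscape = L, culture_on = FALSE)
    sim <- hg_run(cfg)
    lab <- mobility_clusters(sim$trajectory)
    length(setdiff(unique(lab$mobility_label), -1L))
  }
  purrr::map_dfr(seeds, function(s) tibble::tibble(
    landscape = c("one-patch", "two-patch"), seed = s,
    n_clusters = c(run_count(one, s), run_count(two, s))))
}

#' Isolation experiment
#'
#' A large source patch and a small peripheral patch joined by a habitable
#' corridor ridge run with progressive culture; at `t_switch` an impassable
#' barrier strip severs the corridor.  The strip width sets the surviving
#' contact: wider than the long-range radius `r2` it cuts all interaction
#' (full isolation — the effective inflow is zero and any loss rate exceeds
#' it); wider than `r1` but narrower than `r2` it leaves only
#' `phi_2`-mediated long-range adoption across the gap.  Reports the small
#' patch's mean trait complexity just before the switch and at the end:
#' a fully isolated small patch (below the critical mass where innovation
#' and internal re-adoption outrun loss) stagnates and decays relative to
#' the still-growing source, while `phi_2` contact with `lambda_i <= phi_2`
#' keeps it tracking the source.
#'
#' @param lambda_i loss rate, month^-1.
#' @param phi_2 long-range adoption rate, month^-1 (`phi_1` is fixed at 0.1).
#' @param barrier_width width of the inserted strip, km; > `r2` = 50 for
#'   full isolation, in `(r1, r2)` for long-range-only contact.
#' @param seed run seed.
#' @param t_switch barrier insertion time, months.
#' @param horizon total months.
#' @param N0 starting camps.
#' @return one-row tibble with per-patch complexity before/after, the
#'   small patch's retention ratio, and its complexity relative to the
#'   source before/after.
#' @export
isolation_experiment <- function(lambda_i = 0.01, phi_2 = 0.002,
                                 barrier_width = 60, seed = 1,
                                 t_switch = 12000, horizon = 24000,
                                 N0 = 150) {
  bp <- horizon / 12
  # a dumbbell: two patches joined by a habitable corridor ridge, so camps
  # migrate freely while open
  centers <- list(c(210, 250), c(310, 250), c(260, 250))
  radii <- c(55, 30, 25)
  mk_land <- function(barrier = NULL) {
    Ls <- patch_landscape(centers = centers[1:2], radius = radii[1:2],
                          peak = 0.95, bp_start = bp, bp_end = 0,
                          barrier = barrier)
    ridge <- patch_landscape(centers = centers[3], radius = radii[3],
                             peak = 0.95, bp_start = bp, bp_end = 0,
                             barrier = barrier)
    g <- pmax(Ls$suitability[[1]], ridge$suitability[[1]])
    if (!is.null(Ls$friction)) g[Ls$friction == 1] <- 0
    landscape(list(g), Ls$slice_bp[c("t_start_bp", "t_end_bp")],
              origin = Ls$origin, cell_size = Ls$cell_size,
              friction = Ls$friction)
  }
  open <- mk_land()
  closed <- mk_land(barrier = list(orientation = "v", at = 260,
                                   width = barrier_width))
  mk <- function(L, hor) reduced_config(
    seed = seed, phi = c(0.1, phi_2), lambda_i = lambda_i, horizon = hor,
    N0 = N0, landscape = L)
  phase1 <- hg_run(mk(open, t_switch))
  phase2 <- hg_run(mk(closed, horizon), resume_from = phase1$state)
  patch_cx <- function(agents) {
    sc <- status_cols(agents)
    small <- agents$x > 280
    c(small = if (any(small)) mean(as.matrix(agents[small, sc])) else NA_real_,
      large = if (any(!small)) mean(as.matrix(agents[!small, sc])) else NA_real_,
      n_small = sum(small))
  }
  pre <- patch_cx(phase1$final_agents)
  post <- patch_cx(phase2$final_agents)
  tibble::tibble(
    lambda_i = lambda_i, phi_2 = phi_2, barrier_width = barrier_width,
    seed = seed,
    small_pre = pre[["small"]], small_post = post[["small"]],
    large_pre = pre[["large"]], large_post = post[["large"]],
    n_small_pre = pre[["n_small"]], n_small_post = post[["n_small"]],
    retention = post[["small"]] / pre[["small"]],
    rel_pre = pre[["small"]] / pre[["large"]],
    rel_post = post[["small"]] / post[["large"]])
}
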