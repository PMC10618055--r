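#' Simulation configuration
#'
#' Bundles the landscape, the parameter groups and the run settings of one
#' simulation.  Defaults follow the reference parameterisation: 300 starting
#' camps, foraging/short-range radius 20 km, long-range radius 50 km,
#' fusion/fission thresholds 18/60 people, growth = decline = 0.001,
#' noise scale 0.4, a one-month step.
#'
#' @param landscape a [landscape()].
#' @param horizon simulated months.
#' @param N0 starting number of camps.
#' @param seed integer; the run is fully deterministic given `(config, seed)`.
#' @param mode cultural mode, `"progressive"` or `"non-progressive"`.
#' @param lparams,mparams,dparams,cparams parameter groups (see
#'   [landscape_params()], [mobility_params()], [demography_params()],
#'   [culture_params()]).
#' @param r1,r2 short/long-range interaction radii, km.
#' @param bp_start years BP at month 0 (default: the landscape's first slice
#'   start); the internal clock is months since start, mapped to BP by
#'   `bp = bp_start - t / 12`.
#' @param metrics_stride months between metrics samples.
#' @param traj_stride months between trajectory samples.
#' @param move_log `"summary"` (count + total distance) or `"full"`
#'   (every move event).
#' @param culture_on logical; disable to run mobility/demography only
#'   (cultural RNG draws are unaffected either way, thanks to per-substep
#'   RNG streams).
#' @param burn_in months of dynamics on the frozen initial landscape before
#'   logging starts (lets statuses and the network equilibrate).
#' @return A list of class `hg_config`.
#' @export
hg_config <- function(landscape, horizon, N0 = 300, seed = 1,
                      mode = c("progressive", "non-progressive"),
                      lparams = landscape_params(),
                      mparams = mobility_params(),
                      dparams = demography_params(),
                      cparams = culture_params(mode = mode),
                      r1 = 20, r2 = 50, bp_start = NULL,
                      metrics_stride = 1200, traj_stride = 120,
                      move_log = c("summary", "full"), culture_on = TRUE,
                      burn_in = 0) {
  mode <- match.arg(mode)
  move_log <- match.arg(move_log)
  stopifnot(inherits(landscape, "suitability_landscape"), horizon >= 0,
            N0 >= 1, r1 > 0, r1 < r2)
  if (!identical(cparams$mode, mode))
    stop("`cparams$mode` disagrees with `mode`", call. = FALSE)
  if (is.null(bp_start)) bp_start <- max(landscape$slice_bp$t_start_bp)
  if (bp_start - horizon / 12 < min(landscape$slice_bp$t_end_bp) - 1e-9)
    stop("horizon extends past the landscape's covered time range",
         call. = FALSE)
  structure(list(landscape = landscape, horizon = horizon, N0 = as.integer(N0),
                 seed = as.integer(seed), mode = mode, lparams = lparams,
                 mparams = mparams, dparams = dparams, cparams = cparams,
                 r1 = r1, r2 = r2, bp_start = bp_start,
                 metrics_stride = metrics_stride, traj_stride = traj_stride,
                 move_log = move_log, culture_on = culture_on,
                 burn_in = burn_in),
            class = "hg_config")
}

#' Initialise the system state
#'
#' Camps are placed by sampling the equilibrium distribution of the initial
#' suitability landscape; populations are drawn uniformly between the fusion
#' and fission thresholds; statuses start at the floor (all zero) in
#' progressive mode and uniformly at random over `{0..Q-1}^c` in
#' non-progressive mode.
#'
#' @param config an [hg_config()].
#' @return A `hg_state` list (time, agent matrices, RNG streams).
#' @export
hg_init <- function(config) {
  L <- config$landscape
  streams <- make_streams(config$seed)
  n <- config$N0
  cf <- config$cparams$c_features
  st <- with_stream(streams, "init", {
    eq <- sample_equilibrium(L, config$bp_start, n)
    D <- stats::runif(n, config$dparams$h_fus, config$dparams$h_fis)
    S <- if (config$mode == "progressive") matrix(0L, n, cf)
         else matrix(sample(0:(config$cparams$Q - 1), n * cf, replace = TRUE),
                     n, cf)
    list(pos = cbind(eq$x, eq$y), D = D, S = S)
  })
  structure(list(t = 0, ids = seq_len(n), pos = st$pos, D = st$D, S = st$S,
                 next_id = n + 1L, slice = slice_index(L, config$bp_start),
                 agent_months = 0, cum_growth = 0, streams = streams,
                 extinct = FALSE),
            class = "hg_state")
}

#' Agents tibble from a state
#' @param state an `hg_state`.
#' @return tibble `id`, `x`, `y`, `population`, `s_1..s_c`.
#' @export
hg_agents <- function(state) {
  agents_tbl(state$ids, state$pos, state$D, state$S)
}

new_logs <- function(config) {
  cf <- config$cparams$c_features
  e <- new.env(parent = emptyenv())
  e$moves <- if (config$move_log == "full")
    grower(7, c("t", "id", "distance", "from_x", "from_y", "to_x", "to_y"))
  e$n_moves <- 0; e$sum_dist <- 0
  e$culture <- grower(7, c("t", "kind", "id", "feature", "old", "new",
                           "source_id"))
  e$demo <- grower(5, c("t", "kind", "id", "target_id", "population"))
  e$metrics <- grower(4 + cf, c("t", "n_agents", "total_population",
                                "simpson",
                                paste0("mean_complexity_", seq_len(cf))))
  e$traj <- grower(5 + cf, c("t", "id", "x", "y", "population",
                             paste0("s_", seq_len(cf))))
  e
}

log_metrics <- function(st, config, logs) {
  n <- length(st$ids)
  simp <- if (n > 0) simpson_diversity(st$S) else NA_real_
  mc <- if (n == 0) rep(NA_real_, ncol(st$S))
        else if (config$mode == "progressive") colMeans(st$S)
        else rep(NA_real_, ncol(st$S))
  grow_add(logs$metrics, c(st$t, n, sum(st$D), simp, mc))
}

log_traj <- function(st, logs) {
  if (length(st$ids) == 0) return(invisible())
  grow_add(logs$traj, cbind(st$t, st$ids, st$pos[, 1], st$pos[, 2], st$D,
                            st$S))
}

# one month of the coupled dynamics; substep order is part of the API:
# slice refresh -> move -> network -> culture -> demography -> fission ->
# fusion.  `logs = NULL` runs silently (burn-in); `bp_override` freezes time.
hg_step_core <- function(st, config, logs = NULL, bp_override = NULL) {
  n <- length(st$ids)
  if (n == 0) { st$extinct <- TRUE; return(st) }
  L <- config$landscape
  dt <- config$mparams$dt
  bp <- if (is.null(bp_override)) config$bp_start - st$t / 12 else bp_override
  st$slice <- slice_index(L, bp)

  old_pos <- st$pos
  st$pos <- with_stream(st$streams, "mobility",
    em_core(st$pos, st$ids, L, config$lparams, config$mparams, bp))
  if (!is.null(logs)) {
    dd <- sqrt(rowSums((st$pos - old_pos)^2))
    sel <- which(dd >= config$mparams$move_threshold)
    if (length(sel)) {
      logs$n_moves <- logs$n_moves + length(sel)
      logs$sum_dist <- logs$sum_dist + sum(dd[sel])
      if (!is.null(logs$moves))
        grow_add(logs$moves, cbind(st$t, st$ids[sel], dd[sel],
                                   old_pos[sel, 1], old_pos[sel, 2],
                                   st$pos[sel, 1], st$pos[sel, 2]))
    }
  }

  if (config$culture_on) {
    A <- if (n > 1)
      net_core(st$pos, config$r1, config$r2, config$cparams$phi_1,
               config$cparams$phi_2)
    else matrix(0, 1, 1)
    res <- with_stream(st$streams, "culture",
      gillespie_core(st$S, A, config$cparams, st$t, dt))
    st$S <- res$S
    if (!is.null(logs) && res$events$n > 0) {
      m <- res$events$mat[seq_len(res$events$n), , drop = FALSE]
      m[, 3] <- st$ids[m[, 3]]
      m[, 7] <- st$ids[m[, 7]]
      grow_add(logs$culture, m)
    }
  }

  Kg <- k_grid(L, config$lparams, st$slice, config$dparams$r_f)
  K <- cpp_bilinear(Kg, L$origin[1], L$origin[2], L$cell_size,
                    st$pos[, 1], st$pos[, 2])
  Lp <- local_pop_core(st$pos, st$D, config$dparams$r_f)
  Dn <- pop_update_core(st$D, Lp, K, config$dparams$rho_g,
                        config$dparams$rho_d, dt)
  st$cum_growth <- st$cum_growth + sum(Dn - st$D)
  st$D <- Dn

  fs <- fission_core(st$ids, st$pos, st$D, st$S, config$dparams$h_fis,
                     st$next_id)
  if (!is.null(logs) && !is.null(fs$events))
    grow_add(logs$demo, cbind(st$t, 1, fs$events[, 1], fs$events[, 2],
                              fs$events[, 3]))
  fu <- fusion_core(fs$ids, fs$pos, fs$D, fs$S, config$dparams$h_fus,
                    config$r2, config$mode == "progressive")
  if (!is.null(logs) && !is.null(fu$events)) {
    cum_ext <- sum(fu$events[fu$events[, 1] == 2, 4])
    st$cum_extinct <- (st$cum_extinct %||% 0) + cum_ext
    grow_add(logs$demo, cbind(st$t, fu$events[, 1] + 1, fu$events[, 2],
                              fu$events[, 3], fu$events[, 4]))
  } else if (!is.null(fu$events)) {
    st$cum_extinct <- (st$cum_extinct %||% 0) +
      sum(fu$events[fu$events[, 1] == 2, 4])
  }
  st$ids <- fu$ids; st$pos <- fu$pos; st$D <- fu$D; st$S <- fu$S
  st$next_id <- fs$next_id

  st$t <- st$t + dt
  st$agent_months <- st$agent_months + length(st$ids) * dt
  if (length(st$ids) == 0) st$extinct <- TRUE
  st
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Advance the simulation by one step
#'
#' Executes the fixed substep order for one month: landscape-slice refresh,
#' Euler-Maruyama move, interaction-network rebuild, Gillespie cultural
#' window, carrying-capacity population update, fission, then fusion.
#'
#' @param state an `hg_state` from [hg_init()].
#' @param config the matching [hg_config()].
#' @return updated `hg_state`.
#' @export
hg_step <- function(state, config) {
  if (state$t >= config$horizon)
    stop("state already at the configured horizon", call. = FALSE)
  hg_step_core(state, config)
}

# serialisable checkpoint of a state (RNG streams frozen as vectors)
state_snapshot <- function(st) {
  st$streams <- streams_to_list(st$streams)
  st
}

state_restore <- function(snap) {
  snap$streams <- streams_from_list(snap$streams)
  snap
}

#' Run a simulation
#'
#' Runs the monthly loop to the configured horizon (or to extinction),
#' logging trajectory samples, residential moves, cultural and demographic
#' events and the metrics series.  Runs are byte-reproducible given
#' `(config, seed)`; `resume_from` continues from a checkpointed state
#' (e.g. `sim$state` of an earlier run, possibly under a modified landscape).
#'
#' @param config an [hg_config()].
#' @param resume_from optional `hg_state` checkpoint to continue from.
#' @return An `hg_sim` object: list with `metrics`, `trajectory`, `moves`,
#'   `move_summary`, `events_culture`, `events_demography`, `final_agents`,
#'   `state` (checkpoint), `agent_months`, `extinct`, `config`.
#' @export
hg_run <- function(config, resume_from = NULL) {
  st <- if (is.null(resume_from)) hg_init(config)
        else state_restore(resume_from)
  logs <- new_logs(config)
  if (is.null(resume_from) && config$burn_in > 0) {
    for (k in seq_len(ceiling(config$burn_in / config$mparams$dt))) {
      st <- hg_step_core(st, config, logs = NULL,
                         bp_override = config$bp_start)
      if (st$extinct) break
    }
    st$t <- 0
    st$agent_months <- 0
    st$cum_growth <- 0
    st$cum_extinct <- 0
  }
  log_metrics(st, config, logs)
  log_traj(st, logs)
  while (st$t < config$horizon && !st$extinct) {
    st <- hg_step_core(st, config, logs)
    if (st$t %% config$metrics_stride == 0) log_metrics(st, config, logs)
    if (st$t %% config$traj_stride == 0) log_traj(st, logs)
  }
  ev_c <- grow_collect(logs$culture)
  ev_c$kind <- kind_labels[ev_c$kind]
  ev_c$id <- as.integer(ev_c$id)
  ev_c$feature <- as.integer(ev_c$feature)
  ev_c$source_id <- as.integer(ev_c$source_id)
  ev_d <- grow_collect(logs$demo)
  ev_d$kind <- c("fission", "fusion", "extinction")[ev_d$kind]
  ev_d$id <- as.integer(ev_d$id)
  ev_d$target_id <- as.integer(ev_d$target_id)
  structure(list(
    config = config,
    metrics = grow_collect(logs$metrics),
    trajectory = grow_collect(logs$traj),
    moves = if (!is.null(logs$moves)) grow_collect(logs$moves),
    move_summary = list(n_moves = logs$n_moves, sum_dist = logs$sum_dist),
    events_culture = ev_c,
    events_demography = ev_d,
    final_agents = hg_agents(st),
    state = state_snapshot(st),
    agent_months = st$agent_months,
    cum_growth = st$cum_growth,
    cum_extinct = st$cum_extinct %||% 0,
    extinct = st$extinct), class = "hg_sim")
}

#' @export
print.hg_sim <- function(x, ...) {
  cat(sprintf(
    "<hg_sim> %s, %d months, %d camps (%.0f people)%s\n",
    x$config$mode, as.integer(x$state$t), nrow(x$final_agents),
    sum(x$final_agents$population),
    if (x$extinct) " [extinct]" else ""))
  cat(sprintf("  moves: %d (%.1f km mean); cultural events: %d; demographic events: %d\n",
              as.integer(x$move_summary$n_moves),
              if (x$move_summary$n_moves > 0)
                x$move_summary$sum_dist / x$move_summary$n_moves else NA,
              nrow(x$events_culture), nrow(x$events_demography)))
  invisible(x)
}

#' @rdname mobility_stats
#' @export
mobility_stats.hg_sim <- function(x, ...) {
  mobility_stats_core(x$move_summary$n_moves, x$move_summary$sum_dist,
                      x$agent_months)
}
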