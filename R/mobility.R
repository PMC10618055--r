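#' Mobility parameters
#'
#' Parameters of the residential-mobility SDE: a Morse-like pair potential
#' `W(d) = a_rep exp(-d / l_rep) - a_att exp(-d / l_att)` (repulsive core,
#' weak attractive tail, truncated at `attraction_cutoff`), the integration
#' step, and the displacement threshold that counts as a residential move.
#' The default strengths put the zero crossing of the pair force at
#' `d_rep = 10` km, the minimum separation camps try to maintain so their
#' foraging areas do not overlap.
#'
#' @param d_rep repulsion core distance (zero crossing of the pair force), km.
#' @param a_rep,l_rep repulsion strength and decay length (km).
#' @param a_att,l_att attraction strength and decay length (km).
#' @param attraction_cutoff interaction truncation distance, km (the
#'   long-range interaction radius by default).
#' @param f_max cap on the pair-force magnitude, km/month (controls the
#'   coincident-position limit after fission).
#' @param dt integration step, months.
#' @param move_threshold displacement counted as a residential move, km.
#' @return A list of class `mobility_params`.
#' @export
mobility_params <- function(d_rep = 10, l_rep = d_rep / 2, a_att = 0.5,
                            l_att = 20,
                            a_rep = l_rep * (a_att / l_att) *
                              exp(d_rep / l_rep - d_rep / l_att),
                            attraction_cutoff = 50, f_max = 10, dt = 1,
                            move_threshold = 2) {
  stopifnot(d_rep >= 0, a_rep > 0, l_rep > 0, a_att >= 0, l_att > 0,
            attraction_cutoff >= l_att, f_max > 0, dt > 0, move_threshold > 0)
  structure(list(d_rep = d_rep, a_rep = a_rep, l_rep = l_rep, a_att = a_att,
                 l_att = l_att, attraction_cutoff = attraction_cutoff,
                 f_max = f_max, dt = dt, move_threshold = move_threshold),
            class = "mobility_params")
}

#' Pairwise interaction forces between camps
#'
#' Force on each camp from the truncated Morse-like pair potential; positive
#' along the separation vector means repulsion.  Forces obey Newton's third
#' law pair by pair.  Coincident camps (e.g. fresh fission twins) are pushed
#' apart along a deterministic direction derived from the id pair, with the
#' magnitude capped at `f_max`.
#'
#' @param agents tibble with columns `id`, `x`, `y`.
#' @param params a [mobility_params()].
#' @return tibble `id`, `fx`, `fy` (km/month).
#' @export
interaction_force <- function(agents, params = mobility_params()) {
  check_agents(agents)
  f <- force_core(cbind(agents$x, agents$y), as.integer(agents$id), params)
  tibble::tibble(id = agents$id, fx = f[, 1], fy = f[, 2])
}

force_core <- function(pos, ids, params) {
  if (nrow(pos) < 2) return(matrix(0, nrow(pos), 2))
  cpp_pair_forces(pos, ids, params$a_rep, params$l_rep, params$a_att,
                  params$l_att, params$attraction_cutoff, params$f_max)
}

#' Analytic potential stub
#'
#' Wraps an analytic potential gradient (and optional noise scale) in the
#' interface [em_step()] expects from a landscape, for integrator tests and
#' idealised experiments (e.g. an Ornstein-Uhlenbeck benchmark on
#' `V = k |x|^2 / 2`).
#'
#' @param grad function(x, y) returning the n x 2 matrix of `grad V`.
#' @param sigma noise scale: a constant or a function(x, y).
#' @return object usable as the landscape argument of [em_step()].
#' @export
potential_stub <- function(grad, sigma = 0) {
  structure(list(grad = grad,
                 sigma = if (is.function(sigma)) sigma
                         else function(x, y) rep(sigma, length(x))),
            class = "potential_stub")
}

# landscape-facing evaluation used by the integrator
sde_fields <- function(L, lparams, pos, t_bp) {
  if (inherits(L, "potential_stub")) {
    list(gradV = L$grad(pos[, 1], pos[, 2]),
         sigma = L$sigma(pos[, 1], pos[, 2]),
         reject = function(p) rep(FALSE, nrow(p)))
  } else {
    list(gradV = potential_gradient(L, lparams, pos[, 1], pos[, 2], t_bp),
         sigma = sigma_at(L, lparams, pos[, 1], pos[, 2]),
         reject = function(p) friction_at(L, p[, 1], p[, 2]) >= 1)
  }
}

#' One Euler-Maruyama step of the mobility SDE
#'
#' Moves every camp by `dX = (-grad V - grad U) dt + sigma(X) sqrt(dt) xi`
#' with `xi` standard bivariate normal.  Proposed positions that land outside
#' the domain or in impassable (friction 1) cells are rejected: the camp
#' stays in place for that step.
#'
#' @param agents tibble with `id`, `x`, `y` (other columns pass through).
#' @param L a [landscape()] or [potential_stub()].
#' @param t_bp time, years BP (ignored for stubs).
#' @param lparams a [landscape_params()].
#' @param mparams a [mobility_params()].
#' @param interactions logical; include pair forces?
#' @return `agents` with updated `x`, `y`.
#' @export
em_step <- function(agents, L, t_bp = NULL, lparams = landscape_params(),
                    mparams = mobility_params(), interactions = TRUE) {
  check_agents(agents)
  pos <- em_core(cbind(agents$x, agents$y), as.integer(agents$id), L,
                 lparams, mparams, t_bp, interactions)
  agents$x <- pos[, 1]
  agents$y <- pos[, 2]
  agents
}

em_core <- function(pos, ids, L, lparams, mparams, t_bp, interactions = TRUE) {
  n <- nrow(pos)
  fl <- sde_fields(L, lparams, pos, t_bp)
  drift <- -fl$gradV
  if (interactions && n > 1)
    drift <- drift + force_core(pos, ids, mparams)
  dt <- mparams$dt
  prop <- pos + drift * dt +
    fl$sigma * sqrt(dt) * matrix(stats::rnorm(2 * n), n, 2)
  bad <- fl$reject(prop)
  if (any(bad)) prop[bad, ] <- pos[bad, , drop = FALSE]
  prop
}

#' Integrate the mobility SDE over many steps
#'
#' Runs [em_step()] repeatedly on a fixed landscape/potential, optionally
#' recording positions at a stride.  Used for integrator benchmarks and
#' standalone mobility experiments.
#'
#' @inheritParams em_step
#' @param n_steps number of steps.
#' @param record_stride record positions every this many steps (0 = none).
#' @return list with `agents` (final) and `trajectory` (tibble
#'   `step`, `id`, `x`, `y`; empty when not recorded).
#' @export
integrate_sde <- function(agents, L, n_steps, t_bp = NULL,
                          lparams = landscape_params(),
                          mparams = mobility_params(), interactions = TRUE,
                          record_stride = 0) {
  check_agents(agents)
  pos <- cbind(agents$x, agents$y)
  ids <- as.integer(agents$id)
  rec <- if (record_stride > 0)
    grower(4, c("step", "id", "x", "y")) else NULL
  for (s in seq_len(n_steps)) {
    pos <- em_core(pos, ids, L, lparams, mparams, t_bp, interactions)
    if (!is.null(rec) && s %% record_stride == 0)
      grow_add(rec, cbind(s, ids, pos[, 1], pos[, 2]))
  }
  agents$x <- pos[, 1]
  agents$y <- pos[, 2]
  list(agents = agents,
       trajectory = if (is.null(rec))
         tibble::tibble(step = numeric(), id = numeric(),
                        x = numeric(), y = numeric())
       else grow_collect(rec))
}

#' Residential moves between two snapshots
#'
#' One move event per camp whose step displacement is at least
#' `move_threshold` (camps relocate every step, but only displacements of at
#' least the threshold — 2 km by default — count as residential moves).
#'
#' @param before,after agents tibbles with the same ids.
#' @param t time stamp, months.
#' @param move_threshold km.
#' @return tibble `id`, `t`, `distance`, `from_x`, `from_y`, `to_x`, `to_y`.
#' @export
record_moves <- function(before, after, t, move_threshold = 2) {
  stopifnot(identical(as.integer(before$id), as.integer(after$id)))
  d <- sqrt((after$x - before$x)^2 + (after$y - before$y)^2)
  sel <- which(d >= move_threshold)
  tibble::tibble(id = before$id[sel], t = rep(t, length(sel)),
                 distance = d[sel],
                 from_x = before$x[sel], from_y = before$y[sel],
                 to_x = after$x[sel], to_y = after$y[sel])
}

#' Mobility statistics
#'
#' The per-camp mobility triple: residential moves per year, mean distance
#' per move (km), and total distance per year (km), weighting camps by the
#' time they were alive (`agent_months`).
#'
#' @param x a tibble of move events (needs a `distance` column) or an
#'   `hg_sim` run object.
#' @param ... passed to methods.
#' @return one-row tibble `moves_per_year`, `km_per_move`, `km_per_year`,
#'   `n_moves`, `agent_months`.
#' @export
mobility_stats <- function(x, ...) UseMethod("mobility_stats")

#' @rdname mobility_stats
#' @param agent_months total camp-months observed.
#' @export
mobility_stats.data.frame <- function(x, agent_months, ...) {
  stopifnot(agent_months >= 12)
  if (nrow(x) == 0)
    stop("no qualifying moves: mobility statistics are undefined",
         call. = FALSE)
  mobility_stats_core(nrow(x), sum(x$distance), agent_months)
}

mobility_stats_core <- function(n_moves, sum_dist, agent_months) {
  if (n_moves == 0)
    stop("no qualifying moves: mobility statistics are undefined",
         call. = FALSE)
  mpy <- n_moves * 12 / agent_months
  kpm <- sum_dist / n_moves
  tibble::tibble(moves_per_year = mpy, km_per_move = kpm,
                 km_per_year = mpy * kpm, n_moves = n_moves,
                 agent_months = agent_months)
}
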