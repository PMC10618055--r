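#' Demography parameters
#'
#' Camp populations grow or decline deterministically against the local
#' carrying capacity; camps split above the fission threshold and merge (or
#' go extinct) below the fusion threshold.  Defaults follow the ethnographic
#' calibration: viable camps of 18-60 people, growth/decline rates of 0.001
#' per month.
#'
#' @param rho_g,rho_d exponential growth / decline rate, month^-1.
#' @param h_fus fusion threshold (minimum viable camp), people.
#' @param h_fis fission threshold (maximum camp size), people.
#' @param r_f foraging radius, km.
#' @return A list of class `demography_params`.
#' @export
demography_params <- function(rho_g = 0.001, rho_d = 0.001, h_fus = 18,
                              h_fis = 60, r_f = 20) {
  stopifnot(rho_g >= 0, rho_d >= 0, h_fus > 0, h_fis > h_fus, r_f > 0)
  structure(list(rho_g = rho_g, rho_d = rho_d, h_fus = h_fus, h_fis = h_fis,
                 r_f = r_f), class = "demography_params")
}

# area of intersection of two discs of radius r at centre distance d,
# as a fraction of one disc's area; 0 at d >= 2r
lens_fraction <- function(d, r) {
  out <- numeric(length(d))
  inside <- d < 2 * r
  dd <- d[inside]
  lens <- 2 * r^2 * acos(dd / (2 * r)) - (dd / 2) * sqrt(4 * r^2 - dd^2)
  out[inside] <- lens / (pi * r^2)
  out
}

#' Local population around each camp
#'
#' Each camp contributes its own members fully; other camps contribute in
#' proportion to the overlap of the two foraging discs of radius `r_f`:
#' `L_a = D_a + sum_b D_b * lens(|x_a - x_b|, r_f) / (pi r_f^2)`.
#' Camps at distance `>= 2 r_f` (tangent or disjoint discs) contribute
#' nothing.
#'
#' @param agents tibble with `id`, `x`, `y`, `population`.
#' @param r_f foraging radius, km.
#' @return tibble `id`, `local_population`.
#' @export
local_population <- function(agents, r_f = 20) {
  stopifnot(r_f > 0)
  check_agents(agents)
  L <- local_pop_core(cbind(agents$x, agents$y), agents$population, r_f)
  tibble::tibble(id = agents$id, local_population = L)
}

local_pop_core <- function(pos, D, r_f) {
  cpp_local_pop(pos, D, r_f)
}

#' Deterministic population update
#'
#' While the local population is strictly below the local carrying capacity
#' the camp grows exponentially at `rho_g`; otherwise (including the tie) it
#' declines at `rho_d`: `D' = D exp(+-rho dt)`.
#'
#' @param agents tibble with `population`.
#' @param K carrying capacity per camp, people.
#' @param params a [demography_params()].
#' @param dt step, months.
#' @param local optional precomputed local populations (defaults to
#'   [local_population()] at `params$r_f`).
#' @return `agents` with updated `population`.
#' @export
update_populations <- function(agents, K, params = demography_params(),
                               dt = 1,
                               local = local_population(agents,
                                 params$r_f)$local_population) {
  stopifnot(dt > 0, length(K) == nrow(agents))
  agents$population <- pop_update_core(agents$population, local, K,
                                       params$rho_g, params$rho_d, dt)
  agents
}

pop_update_core <- function(D, L, K, rho_g, rho_d, dt) {
  D * exp(ifelse(L < K, rho_g, -rho_d) * dt)
}

# --- matrix-level cores shared with the engine ------------------------------

# split every camp with D > h_fis; parent keeps its id, child gets a fresh
# one; returns events matrix (parent id, child id, child population)
fission_core <- function(ids, pos, D, S, h_fis, next_id) {
  split <- which(D > h_fis)
  if (length(split) == 0)
    return(list(ids = ids, pos = pos, D = D, S = S, next_id = next_id,
                events = NULL))
  new_ids <- as.integer(next_id + seq_along(split) - 1L)
  D[split] <- D[split] / 2
  list(ids = c(ids, new_ids),
       pos = rbind(pos, pos[split, , drop = FALSE]),
       D = c(D, D[split]),
       S = rbind(S, S[split, , drop = FALSE]),
       next_id = as.integer(next_id + length(split)),
       events = cbind(ids[split], new_ids, D[split]))
}

# merge camps below h_fus into the nearest live camp within r2 (ascending
# population order, ties by id); extinct if none in range; returns events
# matrix (kind 1=fusion 2=extinction, id, target id or NA, population)
fusion_core <- function(ids, pos, D, S, h_fus, r2, progressive) {
  cand <- ids[D < h_fus]
  cand <- cand[order(D[match(cand, ids)], cand)]
  ev <- NULL
  for (a in cand) {
    i <- match(a, ids)
    if (is.na(i) || D[i] >= h_fus) next
    d <- sqrt((pos[, 1] - pos[i, 1])^2 + (pos[, 2] - pos[i, 2])^2)
    d[i] <- Inf
    ok <- which(d <= r2)
    if (length(ok) == 0) {
      ev <- rbind(ev, c(2, a, NA, D[i]))
    } else {
      j <- ok[order(d[ok], ids[ok])][1]
      D[j] <- D[j] + D[i]
      if (progressive && ncol(S) > 0)
        S[j, ] <- pmax(S[j, ], S[i, ])
      ev <- rbind(ev, c(1, a, ids[j], D[i]))
    }
    ids <- ids[-i]; pos <- pos[-i, , drop = FALSE]
    D <- D[-i]; S <- S[-i, , drop = FALSE]
  }
  list(ids = ids, pos = pos, D = D, S = S, events = ev)
}

#' Camp fission
#'
#' Every camp whose population strictly exceeds `h_fis` splits into two camps
#' at the same position with the same cultural status, each holding half the
#' population.  One child keeps the parent id (trajectory continuity), the
#' other gets a fresh id.  Total population is conserved exactly.
#'
#' @param agents tibble with `id`, `x`, `y`, `population`, status columns.
#' @param h_fis fission threshold, people.
#' @param next_id first fresh id to allocate (default one past the max).
#' @return list with `agents`, `next_id`, and `events`
#'   (tibble `id`, `child_id`, `population`).
#' @export
apply_fission <- function(agents, h_fis = 60,
                          next_id = max(agents$id) + 1L) {
  am <- agents_mat(agents)
  res <- fission_core(am$ids, am$pos, am$D, am$S, h_fis,
                      as.integer(next_id))
  ev <- if (is.null(res$events))
    tibble::tibble(id = integer(), child_id = integer(),
                   population = numeric())
  else tibble::tibble(id = as.integer(res$events[, 1]),
                      child_id = as.integer(res$events[, 2]),
                      population = res$events[, 3])
  list(agents = agents_tbl(res$ids, res$pos, res$D, res$S),
       next_id = res$next_id, events = ev)
}

#' Camp fusion and extinction
#'
#' Camps whose population falls strictly below `h_fus` are processed in
#' ascending-population order.  Each merges into the nearest other live camp
#' within the long-range radius `r2` (ties broken by lower id): the absorber
#' gains the population, and in progressive mode its trait vector becomes the
#' per-feature maximum of the two (the merged camp instantly knows every
#' variant known to either).  In non-progressive mode the absorber's status
#' is unchanged.  With no camp in range the small camp goes extinct and its
#' people leave the system.
#'
#' @param agents tibble with `id`, `x`, `y`, `population`, status columns.
#' @param h_fus fusion threshold, people.
#' @param r2 long-range interaction radius, km.
#' @param mode `"progressive"` or `"non-progressive"`.
#' @return list with `agents` and `events` (tibble `kind` in
#'   fusion/extinction, `id`, `target_id`, `population`).
#' @export
apply_fusion <- function(agents, h_fus = 18, r2 = 50,
                         mode = c("progressive", "non-progressive")) {
  mode <- match.arg(mode)
  am <- agents_mat(agents)
  res <- fusion_core(am$ids, am$pos, am$D, am$S, h_fus, r2,
                     mode == "progressive")
  ev <- if (is.null(res$events))
    tibble::tibble(kind = character(), id = integer(),
                   target_id = integer(), population = numeric())
  else tibble::tibble(kind = c("fusion", "extinction")[res$events[, 1]],
                      id = as.integer(res$events[, 2]),
                      target_id = as.integer(res$events[, 3]),
                      population = res$events[, 4])
  list(agents = agents_tbl(res$ids, res$pos, res$D, res$S), events = ev)
}
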