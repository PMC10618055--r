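#' Cultural-dynamics parameters
#'
#' Camps carry `c_features` integer-valued cultural features.  Progressive
#' features count accumulated variants (unbounded above, floor 0): they
#' change by innovation (rate `gamma_i`), loss (`lambda_i`, zero at the
#' floor) and biased adoption from more knowledgeable neighbours.
#' Non-progressive features are unordered labels in `{0..Q-1}`: they change
#' by spontaneous switches (`gamma_i`) and neutral copying of neighbours.
#' Adoption/copy rates are mediated by the interaction network weights
#' (`phi_1` within the short radius, `phi_2` within the long radius).
#'
#' Defaults use the high-innovation setting of the headline analyses
#' (progressive `gamma_i` 1e-4, loss 0.02) and the medium adoption pair
#' (0.05, 0.005); all rates are per month.
#'
#' @param mode `"progressive"` or `"non-progressive"`.
#' @param c_features number of cultural features.
#' @param gamma_i innovation (progressive) or spontaneous-switch
#'   (non-progressive) rate per camp-feature, month^-1; recycled to
#'   `c_features`.
#' @param lambda_i loss rate (progressive), month^-1; recycled.
#' @param phi_1,phi_2 short/long-range adoption rates, month^-1.
#' @param Q number of trait values (non-progressive).
#' @param adoption_kernel `"linear"` (rate proportional to the trait
#'   difference) or `"indicator"` (any higher neighbour counts equally).
#' @return A list of class `culture_params`.
#' @export
culture_params <- function(mode = c("progressive", "non-progressive"),
                           c_features = 3,
                           gamma_i = if (mode[1] == "progressive") 1e-4 else 1e-3,
                           lambda_i = 0.02, phi_1 = 0.05, phi_2 = 0.005,
                           Q = 16, adoption_kernel = c("linear", "indicator")) {
  mode <- match.arg(mode)
  adoption_kernel <- match.arg(adoption_kernel)
  gamma_i <- rep_len(gamma_i, c_features)
  lambda_i <- rep_len(lambda_i, c_features)
  stopifnot(all(gamma_i >= 0), all(lambda_i >= 0), phi_1 >= 0, phi_2 >= 0,
            phi_2 <= phi_1, c_features >= 1)
  if (mode == "non-progressive") stopifnot(Q >= 2)
  structure(list(mode = mode, c_features = c_features, gamma_i = gamma_i,
                 lambda_i = lambda_i, phi_1 = phi_1, phi_2 = phi_2, Q = Q,
                 adoption_kernel = adoption_kernel),
            class = "culture_params")
}

#' Distance-banded interaction network
#'
#' Weighted adjacency between camps: weight `phi_1` at Euclidean distance
#' `<= r1`, `phi_2` at `r1 < d <= r2` (both boundaries inclusive), 0 beyond.
#' Symmetric, zero diagonal.
#'
#' @param agents tibble with `id`, `x`, `y`.
#' @param r1,r2 short/long-range interaction radii, km (`r1 < r2`).
#' @param phi_1,phi_2 interaction rates.
#' @return weighted adjacency matrix with agent ids as dimnames.
#' @export
build_network <- function(agents, r1 = 20, r2 = 50, phi_1 = 0.05,
                          phi_2 = 0.005) {
  check_agents(agents)
  if (r1 <= 0 || r1 >= r2)
    stop("interaction radii must satisfy 0 < r1 < r2", call. = FALSE)
  stopifnot(phi_2 <= phi_1)
  A <- net_core(cbind(agents$x, agents$y), r1, r2, phi_1, phi_2)
  dimnames(A) <- list(agents$id, agents$id)
  A
}

net_core <- function(pos, r1, r2, phi_1, phi_2) {
  cpp_band_network(pos, r1, r2, phi_1, phi_2)
}

# rate matrices (n x c) for the three/two event channels
rate_mats <- function(S, A, cp) {
  n <- nrow(S); cf <- ncol(S)
  first <- matrix(cp$gamma_i, n, cf, byrow = TRUE)
  if (cp$mode == "progressive") {
    loss <- matrix(cp$lambda_i, n, cf, byrow = TRUE) * (S > 0)
    sec <- matrix(0, n, cf)
    for (i in seq_len(cf)) sec[, i] <- adopt_col(S, A, cp, i)
    list(first = first, loss = loss, sec = sec)
  } else {
    sec <- matrix(0, n, cf)
    for (i in seq_len(cf)) sec[, i] <- copy_col(S, A, i)
    list(first = first, loss = matrix(0, n, cf), sec = sec)
  }
}

# adoption rate column for feature i: sum_b A_ab * kernel(S_bi - S_ai)
adopt_col <- function(S, A, cp, i) {
  cpp_adopt_col(A, S[, i], cp$adoption_kernel == "linear")
}

copy_col <- function(S, A, i) {
  cpp_copy_col(A, S[, i])
}

#' Event-rate catalogue
#'
#' All possible cultural events and their current rates: per camp and
#' feature, innovation and (above the floor) loss in progressive mode, or
#' spontaneous switch in non-progressive mode, plus network-mediated
#' adoption/copy rates summed over neighbours.
#'
#' @param agents tibble with `id` and status columns `s_1..s_c`.
#' @param A adjacency from [build_network()] (same agent order).
#' @param params a [culture_params()].
#' @return tibble `kind`, `id`, `feature`, `rate` (zero-rate rows dropped).
#' @export
event_rate_catalogue <- function(agents, A, params) {
  S <- agents_mat(agents)$S
  rm_ <- rate_mats(S, A, params)
  first_kind <- if (params$mode == "progressive") "innovation" else "switch"
  sec_kind <- if (params$mode == "progressive") "adoption" else "copy"
  cf <- ncol(S)
  out <- dplyr::bind_rows(
    tibble::tibble(kind = first_kind,
                   id = rep(agents$id, cf),
                   feature = rep(seq_len(cf), each = nrow(S)),
                   rate = as.vector(rm_$first)),
    tibble::tibble(kind = "loss", id = rep(agents$id, cf),
                   feature = rep(seq_len(cf), each = nrow(S)),
                   rate = as.vector(rm_$loss)),
    tibble::tibble(kind = sec_kind, id = rep(agents$id, cf),
                   feature = rep(seq_len(cf), each = nrow(S)),
                   rate = as.vector(rm_$sec)))
  out[out$rate > 0, ]
}

# core Gillespie loop on integer status matrix S; A fixed within the window.
# Returns updated S and an event matrix (t, kind, idx, feature, old, new, src).
# kind codes: 1 innovation, 2 loss, 3 adoption, 4 switch, 5 copy.
gillespie_core <- function(S, A, cp, t0, dt) {
  n <- nrow(S); cf <- ncol(S)
  ev <- grower(7, c("t", "kind", "idx", "feature", "old", "new", "src"))
  if (n == 0) return(list(S = S, events = ev))
  rm_ <- rate_mats(S, A, cp)
  progressive <- cp$mode == "progressive"
  t_cum <- 0
  repeat {
    tot_first <- sum(rm_$first); tot_loss <- sum(rm_$loss)
    tot_sec <- sum(rm_$sec)
    lambda_tot <- tot_first + tot_loss + tot_sec
    if (lambda_tot <= 0) break
    t_cum <- t_cum + stats::rexp(1, lambda_tot)
    if (t_cum >= dt) break
    u <- stats::runif(1, 0, lambda_tot)
    if (u < tot_first) {
      cell <- sample.int(n * cf, 1, prob = as.vector(rm_$first))
      a <- (cell - 1) %% n + 1; i <- (cell - 1) %/% n + 1
      old <- S[a, i]
      if (progressive) {
        S[a, i] <- old + 1L
        grow_add(ev, c(t0 + t_cum, 1, a, i, old, S[a, i], NA))
      } else {
        new <- sample((0:(cp$Q - 1))[-(old + 1)], 1)
        S[a, i] <- as.integer(new)
        grow_add(ev, c(t0 + t_cum, 4, a, i, old, new, NA))
      }
    } else if (u < tot_first + tot_loss) {
      cell <- sample.int(n * cf, 1, prob = as.vector(rm_$loss))
      a <- (cell - 1) %% n + 1; i <- (cell - 1) %/% n + 1
      old <- S[a, i]
      S[a, i] <- old - 1L
      grow_add(ev, c(t0 + t_cum, 2, a, i, old, S[a, i], NA))
    } else {
      cell <- sample.int(n * cf, 1, prob = as.vector(rm_$sec))
      a <- (cell - 1) %% n + 1; i <- (cell - 1) %/% n + 1
      old <- S[a, i]
      if (progressive) {
        w <- A[a, ] * if (cp$adoption_kernel == "linear")
          pmax(S[, i] - old, 0) else (S[, i] > old) * 1
        b <- sample.int(n, 1, prob = w)
        S[a, i] <- old + 1L  # gradual: one variant per adoption event
        grow_add(ev, c(t0 + t_cum, 3, a, i, old, S[a, i], b))
      } else {
        w <- A[a, ] * (S[, i] != old)
        b <- sample.int(n, 1, prob = w)
        S[a, i] <- S[b, i]
        grow_add(ev, c(t0 + t_cum, 5, a, i, old, S[a, i], b))
      }
    }
    # refresh the channels the event touched (rates are state-dependent)
    if (progressive) {
      rm_$loss[a, i] <- cp$lambda_i[i] * (S[a, i] > 0)
      rm_$sec[, i] <- adopt_col(S, A, cp, i)
    } else {
      rm_$sec[, i] <- copy_col(S, A, i)
    }
  }
  list(S = S, events = ev)
}

kind_labels <- c("innovation", "loss", "adoption", "switch", "copy")

#' Run the event-driven cultural dynamics over one time window
#'
#' Standard Gillespie simulation of the event catalogue with the interaction
#' network frozen for the window (the operator-splitting coupling with the
#' monthly mobility step): exponential waiting times from the total rate,
#' events drawn proportionally to their rates, and the catalogue refreshed
#' after every executed event.
#'
#' @param agents tibble with `id` and status columns.
#' @param A adjacency from [build_network()] (same agent order).
#' @param params a [culture_params()].
#' @param t0 window start, months.
#' @param dt window length, months.
#' @return list with `agents` (updated statuses) and `events` (tibble `t`,
#'   `kind`, `id`, `feature`, `old`, `new`, `source_id`).
#' @export
gillespie_window <- function(agents, A, params, t0 = 0, dt = 1) {
  am <- agents_mat(agents)
  res <- gillespie_core(am$S, A, params, t0, dt)
  sc <- status_cols(agents)
  agents[sc] <- as.data.frame(res$S)
  list(agents = agents, events = decode_events(res$events, agents$id))
}

decode_events <- function(ev_grower, ids) {
  m <- grow_collect(ev_grower)
  tibble::tibble(t = m$t, kind = kind_labels[m$kind],
                 id = ids[m$idx], feature = as.integer(m$feature),
                 old = as.integer(m$old), new = as.integer(m$new),
                 source_id = ids[as.integer(m$src)])
}

#' Apply a single cultural event
#'
#' Applies one logged event to the agents, validating it against the current
#' state (a mismatch means the event is stale).  Progressive values stay
#' `>= 0` and unbounded above; non-progressive values stay in `{0..Q-1}`.
#'
#' @param agents tibble with `id` and status columns.
#' @param event one-row tibble with `kind`, `id`, `feature`, `old`, `new`.
#' @param params a [culture_params()].
#' @return updated agents tibble.
#' @export
apply_event <- function(agents, event, params) {
  i <- match(event$id, agents$id)
  if (is.na(i)) stop("stale event: agent not present", call. = FALSE)
  col <- paste0("s_", event$feature)
  cur <- agents[[col]][i]
  if (cur != event$old)
    stop(sprintf("stale event: agent %s feature %d is %d, event expects %d",
                 event$id, event$feature, cur, event$old), call. = FALSE)
  new <- as.integer(event$new)
  if (new < 0) stop("invalid event: negative trait value", call. = FALSE)
  if (params$mode == "non-progressive" && new >= params$Q)
    stop("invalid event: trait value outside {0..Q-1}", call. = FALSE)
  agents[[col]][i] <- new
  agents
}

#' Replay an event log
#'
#' Applies a cultural event log in time order to an initial agent state;
#' by construction of the event system, replaying the log reproduces the
#' final statuses exactly.
#'
#' @param agents initial agents tibble.
#' @param events event tibble as returned by [gillespie_window()].
#' @param params a [culture_params()].
#' @return agents tibble with final statuses.
#' @export
replay_events <- function(agents, events, params) {
  if (nrow(events) == 0) return(agents)
  events <- events[order(events$t), ]
  for (k in seq_len(nrow(events)))
    agents <- apply_event(agents, events[k, ], params)
  agents
}
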