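#' Social interaction and integration parameters
#'
#' Pairwise interactions derive from the double-exponential potential
#' `U(d) = Cr * exp(-d/lr) - Ca * exp(-d/la)`; the force is its negative
#' gradient, repulsive at short range (`Cr/lr > Ca/la`) and attractive at
#' intermediate range (`lr < la`). Each agent responds to at most `k` nearest
#' neighbours within its interaction range. Defaults are the reference
#' parameter set (Cr = 1.1, Ca = 1, lr = 1, la = 7.5, k = 25, m = 1, eta = 1,
#' gamma = 0.01, tau = 1).
#'
#' @param Cr,Ca repulsion and attraction strengths.
#' @param lr,la repulsion and attraction length scales (`lr < la`).
#' @param k maximum number of neighbours an agent responds to.
#' @param m agent mass.
#' @param eta damping coefficient of the autonomous force.
#' @param gamma magnitude of the per-step navigational noise (>= 0).
#' @param tau integration time step.
#' @param n_sub number of semi-implicit Euler sub-steps per `tau`.
#' @return an object of class `social_params`.
#' @export
social_params <- function(Cr = 1.1, Ca = 1, lr = 1, la = 7.5, k = 25,
                          m = 1, eta = 1, gamma = 0.01, tau = 1, n_sub = 10) {
  stopifnot(Cr > 0, Ca > 0, lr > 0, la > 0, k >= 0, m > 0, eta > 0,
            gamma >= 0, tau > 0, n_sub >= 1)
  if (lr >= la)
    stop("repulsion must be shorter-ranged than attraction (lr < la)")
  if (Cr / lr <= Ca / la)
    stop("force at zero distance must be repulsive (Cr/lr > Ca/la)")
  structure(list(Cr = Cr, Ca = Ca, lr = lr, la = la, k = as.integer(k),
                 m = m, eta = eta, gamma = gamma, tau = tau,
                 n_sub = as.integer(n_sub)),
            class = "social_params")
}

#' @export
print.social_params <- function(x, ...) {
  cat(sprintf(
    "<social_params> Cr=%g Ca=%g lr=%g la=%g k=%d m=%g eta=%g gamma=%g tau=%g (C=%.3g, l=%.3g)\n",
    x$Cr, x$Ca, x$lr, x$la, x$k, x$m, x$eta, x$gamma, x$tau,
    x$Cr / x$Ca, x$lr / x$la))
  invisible(x)
}

#' Heritable behavioural traits
#'
#' Per-agent phenotype: baseline speed parameter `psi0`, environmental
#' sensitivity `psi1` (the preferred-speed parameter is
#' `Psi_i = psi0 - psi1 * S(x_i)`), and maximum interaction range `lmax`,
#' capped at `lmax_cap` (default 30).
#'
#' @param psi0,psi1,lmax numeric vectors, recycled to a common length.
#' @param lmax_cap upper bound enforced on `lmax`.
#' @return an object of class `trait_set`: a data frame with columns `psi0`,
#'   `psi1`, `lmax` and attribute `lmax_cap`.
#' @export
trait_set <- function(psi0, psi1, lmax, lmax_cap = 30) {
  n <- max(length(psi0), length(psi1), length(lmax))
  df <- data.frame(psi0 = rep_len(as.numeric(psi0), n),
                   psi1 = rep_len(as.numeric(psi1), n),
                   lmax = rep_len(as.numeric(lmax), n))
  stopifnot(all(is.finite(as.matrix(df))), all(df$lmax >= 0),
            all(df$lmax <= lmax_cap))
  attr(df, "lmax_cap") <- lmax_cap
  class(df) <- c("trait_set", "data.frame")
  df
}

#' Positions and velocities of the agent population
#'
#' @param positions n x 2 matrix of torus coordinates (wrapped on input).
#' @param velocities n x 2 matrix of velocities.
#' @param geometry a [torus_geometry()].
#' @return an object of class `agent_state`.
#' @export
agent_state <- function(positions, velocities, geometry) {
  positions <- as.matrix(positions)
  velocities <- as.matrix(velocities)
  stopifnot(ncol(positions) == 2, ncol(velocities) == 2,
            nrow(positions) == nrow(velocities),
            all(is.finite(positions)), all(is.finite(velocities)),
            inherits(geometry, "torus_geometry"))
  structure(list(positions = torus_wrap(positions, geometry),
                 velocities = velocities, geometry = geometry),
            class = "agent_state")
}

#' @export
print.agent_state <- function(x, ...) {
  cat("<agent_state>", nrow(x$positions), "agents on a torus of edge",
      x$geometry$edge_length, "\n")
  invisible(x)
}

#' Random initial agent state
#'
#' Positions uniform on the torus; speeds uniform in `[0, speed_max]` with
#' uniform headings. Uses the current RNG state.
#'
#' @param n number of agents.
#' @param geometry a [torus_geometry()].
#' @param speed_max maximum initial speed (default 0.1).
#' @return an [agent_state()].
#' @export
init_agent_state <- function(n, geometry, speed_max = 0.1) {
  L <- geometry$edge_length
  pos <- matrix(runif(2 * n, 0, L), ncol = 2)
  sp <- runif(n, 0, speed_max)
  th <- runif(n, 0, 2 * pi)
  agent_state(pos, cbind(sp * cos(th), sp * sin(th)), geometry)
}

#' Per-agent neighbour sets
#'
#' For each agent, the indices of up to `k` nearest other agents at
#' minimum-image distance at most that agent's `lmax`, ordered by distance
#' (ties broken by index). An agent is never its own neighbour.
#'
#' @param state an [agent_state()].
#' @param traits a [trait_set()] (per-agent `lmax`).
#' @param params a [social_params()] (neighbour count `k`).
#' @return list of integer vectors, one per agent.
#' @export
neighbor_sets <- function(state, traits, params) {
  cpp_neighbor_sets(state$positions, rep_len(traits$lmax, nrow(state$positions)),
                    params$k, state$geometry$edge_length)
}

#' Social force on every agent
#'
#' Negative gradient of the pairwise double-exponential potential summed over
#' each agent's neighbour set:
#' `F_i = sum_j [ (Cr/lr) e^(-d/lr) - (Ca/la) e^(-d/la) ] * rhat_ij`,
#' with `rhat_ij` the unit vector from neighbour j towards agent i (positive
#' coefficient = repulsion). Coincident pairs contribute zero.
#'
#' @inheritParams neighbor_sets
#' @return n x 2 matrix of force vectors.
#' @export
social_force <- function(state, traits, params) {
  cpp_social_forces(state$positions,
                    rep_len(traits$lmax, nrow(state$positions)),
                    params$k, state$geometry$edge_length,
                    params$Cr, params$Ca, params$lr, params$la)
}

#' Preferred-speed parameter
#'
#' The environmental response `Psi_i = psi0 - psi1 * S`, which may be negative
#' (station-keeping regime).
#'
#' @param traits a [trait_set()] or a list with `psi0`, `psi1`.
#' @param S resource value(s) at the agent position(s).
#' @return numeric vector of `Psi` values.
#' @export
response_speed_param <- function(traits, S) {
  traits$psi0 - traits$psi1 * S
}

#' Autonomous (self-propulsion) force
#'
#' `F_a = (Psi - eta * |v|^2) * v / |v|`: acceleration along the current
#' heading towards the preferred speed `sqrt(Psi/eta)` for `Psi > 0`,
#' deceleration for `Psi <= 0`. Zero when the speed is below the numerical
#' threshold `1e-8` (heading undefined).
#'
#' @param psi preferred-speed parameter `Psi` (scalar).
#' @param velocity numeric 2-vector.
#' @param params a [social_params()] (uses `eta`).
#' @return numeric 2-vector.
#' @export
autonomous_force <- function(psi, velocity, params) {
  sp <- sqrt(sum(velocity^2))
  if (sp < 1e-8) return(c(0, 0))
  (psi - params$eta * sp^2) * velocity / sp
}

#' Advance the agent population
#'
#' Advances `n_steps` time steps of length `tau`. Within each step the social
#' force and the local resource value are evaluated once at the step start and
#' held frozen; velocity and position are integrated by semi-implicit Euler
#' with `n_sub` sub-steps (the autonomous force tracks the evolving velocity);
#' a noise vector of exact magnitude `gamma` with uniform heading is then
#' added to each velocity, and positions are wrapped onto the torus. All
#' agents update synchronously. The resource peaks advance once per step
#' (drift, diffusion, relocation, and depletion when enabled), after the
#' agents.
#'
#' @param state an [agent_state()].
#' @param traits a [trait_set()].
#' @param params a [social_params()].
#' @param field a [resource_field()] or `NULL` for a uniform resource-free
#'   environment.
#' @param n_steps number of time steps to advance.
#' @param record_every record a trajectory snapshot every this many steps
#'   (0 = none).
#' @param count_radius if > 0, record per-step counts of agents within this
#'   distance of the `count_peak`-th peak centre.
#' @param count_peak 1-based peak index for the arrival count.
#' @param move_peaks logical; advance the peak dynamics each step.
#' @return an object of class `sim_result`: list with the final `state`, the
#'   updated `field`, per-agent `fitness` (mean experienced resource), `S_last`,
#'   per-step `counts` (if requested), and a `trajectory` data frame with
#'   columns (t, agent_id, x, y, vx, vy, S, psi) plus `peak_track` (if
#'   recorded).
#' @export
step <- function(state, traits, params, field = NULL, n_steps = 1,
                 record_every = 0, count_radius = 0, count_peak = 1,
                 move_peaks = TRUE) {
  n <- nrow(state$positions)
  L <- state$geometry$edge_length
  if (is.null(field))
    field <- resource_field(list(), geometry = state$geometry,
                            relocation_timescale = Inf)
  stopifnot(identical(L, field$geometry$edge_length))
  pm <- peaks_matrix(field)
  res <- cpp_simulate(state$positions, state$velocities,
                      rep_len(traits$psi0, n), rep_len(traits$psi1, n),
                      rep_len(traits$lmax, n),
                      params$Cr, params$Ca, params$lr, params$la, params$k,
                      params$m, params$eta, params$gamma, params$tau,
                      params$n_sub,
                      pm, peaks_amp_init(field),
                      L, field$drift, field$diffusion_sd,
                      field$relocation_timescale, field$depletion_rate,
                      move_peaks && nrow(pm) > 0,
                      as.integer(n_steps), as.integer(record_every),
                      count_radius, as.integer(count_peak) - 1L)
  out <- list(
    state = agent_state(res$positions, res$velocities, state$geometry),
    field = if (nrow(pm)) set_peaks_matrix(field, res$peaks) else field,
    fitness = res$fitness,
    S_last = res$S_last,
    counts = if (count_radius > 0 && nrow(pm)) as.integer(res$counts) else NULL,
    n_steps = n_steps)
  if (record_every > 0) {
    nr <- length(res$rec_t)
    traj <- data.frame(
      t = rep(res$rec_t, each = n),
      agent_id = rep(seq_len(n), nr),
      x = as.vector(t(res$rec_x)), y = as.vector(t(res$rec_y)),
      vx = as.vector(t(res$rec_vx)), vy = as.vector(t(res$rec_vy)),
      S = as.vector(t(res$rec_S)))
    traj$psi <- rep_len(traits$psi0, n)[traj$agent_id] -
      rep_len(traits$psi1, n)[traj$agent_id] * traj$S
    out$trajectory <- traj
    if (nrow(pm)) {
      pk <- as.data.frame(res$rec_peaks)
      names(pk) <- c("t", "x", "y", "amplitude")
      pk$peak <- rep_len(seq_len(nrow(pm)), nrow(pk))
      out$peak_track <- pk
    }
  }
  class(out) <- "sim_result"
  out
}

#' @export
print.sim_result <- function(x, ...) {
  cat("<sim_result>", nrow(x$state$positions), "agents,", x$n_steps,
      "steps; mean fitness", signif(mean(x$fitness), 4), "\n")
  invisible(x)
}

#' Social interaction graph and groups
#'
#' Two agents are connected if at least one has the other in its neighbour
#' set; a group is a connected component of this undirected graph.
#'
#' @inheritParams neighbor_sets
#' @return list with `graph` (an igraph object), `membership` (1-based
#'   component label per agent), and `sizes` (component sizes).
#' @export
interaction_graph <- function(state, traits, params) {
  nb <- neighbor_sets(state, traits, params)
  n <- length(nb)
  edges <- do.call(rbind, lapply(seq_len(n), function(i) {
    if (length(nb[[i]])) cbind(i, nb[[i]]) else NULL
  }))
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (!is.null(edges)) {
    und <- unique(t(apply(edges, 1, sort)))
    g <- igraph::add_edges(g, t(und))
  }
  comp <- igraph::components(g)
  list(graph = g, membership = as.integer(comp$membership),
       sizes = as.integer(comp$csize))
}
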