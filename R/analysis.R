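#' Mean distance to the n nearest neighbours
#'
#' The collective-state order parameter: for every agent, the mean
#' minimum-image distance to its `n_neighbors` nearest others (irrespective of
#' interaction ranges), averaged over all agents.
#'
#' @param state an [agent_state()] or an n x 2 position matrix (then supply
#'   `geometry`).
#' @param n_neighbors number of nearest neighbours (default 10).
#' @param geometry required when `state` is a bare matrix.
#' @return scalar, non-negative.
#' @export
mean_dist_knn <- function(state, n_neighbors = 10, geometry = NULL) {
  if (inherits(state, "agent_state")) {
    pos <- state$positions
    geometry <- state$geometry
  } else pos <- as.matrix(state)
  if (nrow(pos) <= n_neighbors)
    stop("need more agents than n_neighbors")
  cpp_mean_dist_knn(pos, geometry$edge_length, as.integer(n_neighbors))
}

#' Mean social potential energy
#'
#' Mean over agents of the pairwise potential
#' `Cr e^(-d/lr) - Ca e^(-d/la)` summed over each agent's neighbour set.
#'
#' @inheritParams neighbor_sets
#' @return scalar.
#' @export
potential_energy <- function(state, traits, params) {
  cpp_potential_energy(state$positions,
                       rep_len(traits$lmax, nrow(state$positions)),
                       params$k, state$geometry$edge_length,
                       params$Cr, params$Ca, params$lr, params$la)
}

#' Classify agents into collective-state regimes
#'
#' Labels by the instantaneous preferred-speed parameter: station-keeping for
#' `Psi <= t1`, cohesive for `t1 < Psi <= t2`, dispersed for `Psi > t2`
#' (defaults `t1 = 0`, `t2 = 2.95`; boundary values go to the lower regime).
#'
#' @param psi numeric vector of per-agent `Psi` values.
#' @param thresholds length-2 increasing numeric vector.
#' @return factor with levels `station-keeping`, `cohesive`, `dispersed`.
#' @export
classify_state <- function(psi, thresholds = c(0, 2.95)) {
  stopifnot(length(thresholds) == 2, thresholds[1] < thresholds[2])
  lab <- ifelse(psi <= thresholds[1], "station-keeping",
                ifelse(psi <= thresholds[2], "cohesive", "dispersed"))
  factor(lab, levels = c("station-keeping", "cohesive", "dispersed"))
}

#' Hysteresis sweep of the collective-state order parameter
#'
#' Implements the two-branch protocol in a uniform (resource-free)
#' environment: all agents share the control value `Psi` (imposed as
#' `psi0 = Psi`, `psi1 = 0`). Starting from `psi_start`, the population
#' equilibrates for `equilibration_steps`, `<d10NN>` is measured, and `Psi`
#' is stepped towards `psi_end`; the procedure then reverses back to
#' `psi_start`. Agent state carries over between consecutive `Psi` values
#' within a replicate, which is what produces the hysteresis.
#'
#' @param n_agents population size.
#' @param params a [social_params()].
#' @param psi_start,psi_end,psi_step sweep grid (default 4 to -1 by 0.2).
#' @param equilibration_steps steps before each measurement (default 5000).
#' @param replicates independent replicate populations (default 50).
#' @param lmax shared interaction range (default 30).
#' @param edge_length torus edge (default 346, the reference domain).
#' @param seed optional integer seed.
#' @param n_neighbors neighbours entering the order parameter (default 10).
#' @return object of class `sweep_result`: data frame with columns
#'   `direction` (`"down"`/`"up"`), `psi`, `replicate`, `d10nn`.
#' @export
hysteresis_sweep <- function(n_agents = 500, params = social_params(),
                             psi_start = 4, psi_end = -1, psi_step = 0.2,
                             equilibration_steps = 5000, replicates = 50,
                             lmax = 30, edge_length = 346, seed = NULL,
                             n_neighbors = 10) {
  if (!is.null(seed)) set.seed(seed)
  geo <- torus_geometry(edge_length)
  down <- seq(psi_start, psi_end, by = -abs(psi_step))
  up <- rev(down)
  out <- vector("list", replicates)
  for (r in seq_len(replicates)) {
    state <- init_agent_state(n_agents, geo)
    res_d <- numeric(length(down))
    res_u <- numeric(length(up))
    for (i in seq_along(down)) {
      tr <- trait_set(down[i], 0, lmax)
      state <- step(state, tr, params, NULL,
                    n_steps = equilibration_steps)$state
      res_d[i] <- mean_dist_knn(state, n_neighbors)
    }
    for (i in seq_along(up)) {
      tr <- trait_set(up[i], 0, lmax)
      state <- step(state, tr, params, NULL,
                    n_steps = equilibration_steps)$state
      res_u[i] <- mean_dist_knn(state, n_neighbors)
    }
    out[[r]] <- rbind(
      data.frame(direction = "down", psi = down, replicate = r, d10nn = res_d),
      data.frame(direction = "up", psi = up, replicate = r, d10nn = res_u))
  }
  res <- do.call(rbind, out)
  class(res) <- c("sweep_result", "data.frame")
  res
}

#' Summarise a sweep over replicates
#'
#' @param sweep a `sweep_result` from [hysteresis_sweep()].
#' @return data frame with per-(direction, psi) mean, standard error, and the
#'   2-standard-error band half-width over replicates.
#' @export
summarize_sweep <- function(sweep) {
  agg <- aggregate(d10nn ~ direction + psi, data = sweep,
                   FUN = function(x) c(mean = mean(x),
                                       se = sd(x) / sqrt(length(x))))
  out <- data.frame(direction = agg$direction, psi = agg$psi,
                    d10nn = agg$d10nn[, "mean"], se = agg$d10nn[, "se"])
  out$band2se <- 2 * out$se
  out[order(out$direction, out$psi), ]
}

#' Locate the abrupt transitions of a hysteresis sweep
#'
#' For each branch, finds the pair of consecutive grid values with the
#' largest change of the replicate-mean order parameter in the branch's
#' direction (largest drop on the decreasing branch, largest rise on the
#' increasing branch) and reports the midpoint of that pair.
#'
#' @param sweep a `sweep_result`.
#' @return list with `down` and `up`: each a list with `psi` (transition
#'   location), `delta` (signed change), and the bracketing grid values.
#' @export
transition_points <- function(sweep) {
  s <- summarize_sweep(sweep)
  branch <- function(dir) {
    b <- s[s$direction == dir, ]
    b <- b[order(b$psi, decreasing = (dir == "down")), ]
    d <- diff(b$d10nn)
    i <- if (dir == "down") which.min(d) else which.max(d)
    list(psi = mean(b$psi[c(i, i + 1)]), delta = d[i],
         from = b$psi[i], to = b$psi[i + 1])
  }
  list(down = branch("down"), up = branch("up"))
}

#' Order-parameter surface over a social parameter and psi0
#'
#' Simulates separate populations in a uniform environment for each
#' combination of one social parameter (`Ca`, `k`, or `la`) and `psi0`
#' (with `psi1 = 0`), recording `<d10NN>` after `steps` of equilibration.
#'
#' @param sweep_param one of `"Ca"`, `"k"`, `"la"`.
#' @param sweep_values values of the social parameter.
#' @param psi0_values grid of baseline speed values.
#' @param n_agents population size.
#' @param params base [social_params()].
#' @param steps equilibration steps per cell.
#' @param replicates replicates per cell.
#' @param lmax shared interaction range.
#' @param edge_length torus edge (default 346).
#' @param seed optional integer seed.
#' @return data frame with columns `param`, `value`, `psi0`, `replicate`,
#'   `d10nn`.
#' @export
phase_sweep <- function(sweep_param = c("Ca", "k", "la"), sweep_values,
                        psi0_values, n_agents = 500,
                        params = social_params(), steps = 2000,
                        replicates = 1, lmax = 30, edge_length = 346,
                        seed = NULL) {
  sweep_param <- match.arg(sweep_param)
  if (!is.null(seed)) set.seed(seed)
  geo <- torus_geometry(edge_length)
  grid <- expand.grid(value = sweep_values, psi0 = psi0_values,
                      replicate = seq_len(replicates))
  grid$d10nn <- NA_real_
  for (i in seq_len(nrow(grid))) {
    p <- params
    p[[sweep_param]] <- if (sweep_param == "k") as.integer(grid$value[i])
                        else grid$value[i]
    state <- init_agent_state(n_agents, geo)
    tr <- trait_set(grid$psi0[i], 0, lmax)
    state <- step(state, tr, p, NULL, n_steps = steps)$state
    grid$d10nn[i] <- mean_dist_knn(state)
  }
  data.frame(param = sweep_param, grid)
}

#' Empirical cohesive-dispersed boundary from a phase sweep
#'
#' For each value of the swept social parameter, the boundary is located at
#' the midpoint of the psi0 step with the steepest increase of the
#' replicate-mean `<d10NN>` along the psi0 axis.
#'
#' @param sweep output of [phase_sweep()].
#' @return data frame with columns `param`, `value`, `psi0_boundary`.
#' @export
phase_boundary <- function(sweep) {
  agg <- aggregate(d10nn ~ value + psi0, data = sweep, FUN = mean)
  out <- lapply(split(agg, agg$value), function(b) {
    b <- b[order(b$psi0), ]
    d <- diff(b$d10nn)
    i <- which.max(d)
    data.frame(value = b$value[1], psi0_boundary = mean(b$psi0[c(i, i + 1)]))
  })
  res <- do.call(rbind, out)
  res <- data.frame(param = sweep$param[1], res)
  rownames(res) <- NULL
  res
}

#' Kullback-Leibler divergence between resource and agent density
#'
#' Bins agents into annuli about the designated peak centre, integrates the
#' peak's radial resource profile over the same annuli, normalizes both to
#' probability distributions (additive regularization `eps` on each bin), and
#' returns `KL(resource || agents)` in nats. The divergence falls towards
#' zero as the agent density concentrates like the resource distribution.
#'
#' @param state an [agent_state()].
#' @param field a [resource_field()] with at least one peak.
#' @param peak 1-based index of the designated peak.
#' @param n_bins number of annuli (default 30).
#' @param r_max outer radius (default 3 decay lengths).
#' @param eps additive regularization per bin (default 1e-9).
#' @return scalar divergence in nats, >= 0.
#' @export
kl_divergence_to_resource <- function(state, field, peak = 1, n_bins = 30,
                                      r_max = NULL, eps = 1e-9) {
  stopifnot(length(field$peaks) >= peak, n_bins >= 1)
  pk <- field$peaks[[peak]]
  if (is.null(r_max)) r_max <- 3 * pk$decay_length
  breaks <- seq(0, r_max, length.out = n_bins + 1)
  ctr <- matrix(pk$centroid, nrow(state$positions), 2, byrow = TRUE)
  r <- torus_distance(state$positions, ctr, state$geometry)
  counts <- as.numeric(table(cut(r, breaks, include.lowest = TRUE)))
  if (sum(counts) == 0) stop("no agents within r_max of the peak centre")
  l1 <- pk$decay_length
  # integral of amp * exp(-r^2/l1^2) over an annulus, up to the constant factor
  q <- exp(-breaks[-length(breaks)]^2 / l1^2) - exp(-breaks[-1]^2 / l1^2)
  if (sum(q) == 0) stop("resource distribution has zero mass over the annuli")
  p_agents <- (counts + eps) / sum(counts + eps)
  q_res <- (q + eps) / sum(q + eps)
  sum(q_res * log(q_res / p_agents))
}

#' Arrival curve at a resource peak
#'
#' Wraps per-step counts of agents within one decay length of a peak centre
#' and fits two candidate accumulation models by least squares: a linear
#' model `kappa_a * t + c` (constant arrival rate) and an exponential model
#' `kappa_s1 + exp(kappa_s2 * t)` (self-reinforcing arrival). Models are
#' compared by AIC under Gaussian errors.
#'
#' @param counts non-negative integer vector of per-step counts.
#' @param times time stamps (default `seq_along(counts)`).
#' @return object of class `arrival_curve`: list with `counts`, `times`,
#'   `linear` (kappa_a, intercept, rss, aic), `exponential` (kappa_s1,
#'   kappa_s2, rss, aic; `NULL` if the fit fails), `preferred`
#'   (`"linear"`/`"exponential"`), `degenerate` flag.
#' @export
arrival_curve <- function(counts, times = seq_along(counts)) {
  stopifnot(length(counts) == length(times), length(counts) >= 2,
            all(counts >= 0))
  out <- list(counts = as.numeric(counts), times = as.numeric(times))
  out$degenerate <- length(unique(counts)) == 1
  n <- length(counts)
  aic_ls <- function(rss, k) n * log(rss / n) + 2 * k
  fit_lin <- lm(counts ~ times)
  rss_lin <- sum(residuals(fit_lin)^2)
  out$linear <- list(kappa_a = unname(coef(fit_lin)[2]),
                     intercept = unname(coef(fit_lin)[1]),
                     rss = rss_lin, aic = aic_ls(max(rss_lin, 1e-12), 2))
  out$exponential <- NULL
  if (!out$degenerate) {
    rng <- max(counts) - min(counts)
    k2_0 <- log(rng + 1) / max(times)
    fit_exp <- tryCatch(
      minpack.lm::nlsLM(counts ~ k1 + exp(k2 * times),
                        start = list(k1 = min(counts), k2 = k2_0),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit_exp)) {
      rss_exp <- sum(residuals(fit_exp)^2)
      cf <- coef(fit_exp)
      out$exponential <- list(kappa_s1 = unname(cf["k1"]),
                              kappa_s2 = unname(cf["k2"]),
                              rss = rss_exp,
                              aic = aic_ls(max(rss_exp, 1e-12), 2))
    }
  }
  out$preferred <- if (out$degenerate || is.null(out$exponential)) {
    if (out$degenerate) NA_character_ else "linear"
  } else if (out$exponential$aic < out$linear$aic) "exponential" else "linear"
  class(out) <- "arrival_curve"
  out
}

#' @export
print.arrival_curve <- function(x, ...) {
  cat("<arrival_curve>", length(x$counts), "time points; preferred model:",
      if (is.na(x$preferred)) "none (degenerate)" else x$preferred, "\n")
  if (!is.null(x$linear))
    cat(sprintf("  linear:      kappa_a = %.4g (AIC %.1f)\n",
                x$linear$kappa_a, x$linear$aic))
  if (!is.null(x$exponential))
    cat(sprintf("  exponential: kappa_s1 = %.4g, kappa_s2 = %.4g (AIC %.1f)\n",
                x$exponential$kappa_s1, x$exponential$kappa_s2,
                x$exponential$aic))
  invisible(x)
}

#' Resource-tracking run with arrival and divergence outputs
#'
#' Places a population with the given traits uniformly at random in a
#' single-peak environment and simulates it, returning the per-step arrival
#' counts (agents within one decay length of the current peak centre) and the
#' KL divergence between the resource distribution and the agent density
#' (about the current peak centre) at each recorded snapshot. The default
#' peak drifts slowly and diffuses (drift 0.06, per-step sd 0.5), the regime
#' in which collective tracking operates: the resource core wanders through
#' the station-keeping shell that forms around it, so agents accumulate at
#' high resource values. Set `drift = c(0, 0)`, `diffusion_sd = 0` for a
#' frozen peak.
#'
#' @param traits a [trait_set()] (single row recycled over the population).
#' @param n_agents population size.
#' @param n_steps simulation length.
#' @param params a [social_params()].
#' @param amplitude,decay_length peak parameters.
#' @param drift,diffusion_sd peak motion per step.
#' @param edge_length torus edge (default 346).
#' @param record_every snapshot interval for the divergence series.
#' @param seed optional integer seed.
#' @return list with `counts` (data frame t, count), `kl` (data frame t,
#'   kl), `arrival` (an [arrival_curve()]), the final `state` and `field`.
#' @export
track_run <- function(traits, n_agents = 200, n_steps = 2000,
                      params = social_params(), amplitude = 10,
                      decay_length = 20, drift = c(0.06, 0),
                      diffusion_sd = 0.5, edge_length = 346,
                      record_every = 100, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  geo <- torus_geometry(edge_length)
  static <- all(drift == 0) && diffusion_sd == 0
  fld <- resource_field(
    list(resource_peak(c(edge_length / 2, edge_length / 2), amplitude,
                       decay_length)),
    drift = drift, diffusion_sd = diffusion_sd,
    relocation_timescale = Inf, geometry = geo)
  state <- init_agent_state(n_agents, geo)
  tr <- trait_set(rep_len(traits$psi0, n_agents),
                  rep_len(traits$psi1, n_agents),
                  rep_len(traits$lmax, n_agents))
  sim <- step(state, tr, params, fld, n_steps = n_steps,
              record_every = record_every, count_radius = decay_length,
              count_peak = 1, move_peaks = !static)
  snaps <- split(sim$trajectory, sim$trajectory$t)
  pkt <- sim$peak_track
  kl <- mapply(function(s, tt) {
    st <- agent_state(cbind(s$x, s$y), cbind(s$vx, s$vy), geo)
    f <- sim$field
    f$peaks[[1]]$centroid <- as.numeric(pkt[pkt$t == tt, c("x", "y")])
    kl_divergence_to_resource(st, f)
  }, snaps, as.integer(names(snaps)))
  list(counts = data.frame(t = seq_len(n_steps), count = sim$counts),
       kl = data.frame(t = as.integer(names(snaps)), kl = unname(kl)),
       arrival = arrival_curve(sim$counts),
       state = sim$state, field = sim$field)
}

# circular mean of positions on the torus, per coordinate
torus_centroid <- function(pos, L) {
  th <- 2 * pi * pos / L
  ang <- atan2(colMeans(sin(th)), colMeans(cos(th)))
  (ang %% (2 * pi)) * L / (2 * pi)
}

#' Group-to-peak size matching
#'
#' For each resource peak, finds at every recorded snapshot the group
#' (connected component of the interaction graph) whose centroid is nearest
#' the peak centre, and averages that group's size over the window. Paired
#' with the integrated peak mass.
#'
#' @param sim a `sim_result` from [step()] with a recorded trajectory and
#'   `peak_track`.
#' @param traits,params the trait set and social parameters used in the run
#'   (needed to rebuild interaction graphs).
#' @param window length-2 time range over which to average (default: last
#'   half of the recorded snapshots).
#' @return data frame with columns `peak`, `peak_mass`, `group_size` (time
#'   mean), `n_snapshots`.
#' @export
group_peak_matching <- function(sim, traits, params, window = NULL) {
  stopifnot(!is.null(sim$trajectory), !is.null(sim$peak_track))
  geo <- sim$state$geometry
  L <- geo$edge_length
  ts <- sort(unique(sim$trajectory$t))
  if (is.null(window)) window <- c(ts[ceiling(length(ts) / 2)], max(ts))
  ts <- ts[ts >= window[1] & ts <= window[2]]
  n <- nrow(sim$state$positions)
  lmax <- rep_len(traits$lmax, n)
  masses <- vapply(sim$field$peaks, peak_mass, numeric(1))
  npk <- length(masses)
  acc <- matrix(0, length(ts), npk)
  for (si in seq_along(ts)) {
    s <- sim$trajectory[sim$trajectory$t == ts[si], ]
    pos <- cbind(s$x, s$y)[order(s$agent_id), , drop = FALSE]
    memb <- cpp_components(pos, lmax, params$k, L)
    sizes <- tabulate(memb)
    cents <- t(vapply(seq_along(sizes), function(gid)
      torus_centroid(pos[memb == gid, , drop = FALSE], L), numeric(2)))
    pk <- sim$peak_track[sim$peak_track$t == ts[si], ]
    for (p in seq_len(npk)) {
      ctr <- as.numeric(pk[pk$peak == p, c("x", "y")])
      d <- torus_distance(cents, matrix(ctr, nrow(cents), 2, byrow = TRUE), geo)
      acc[si, p] <- sizes[which.min(d)]
    }
  }
  data.frame(peak = seq_len(npk), peak_mass = masses,
             group_size = colMeans(acc), n_snapshots = length(ts))
}
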