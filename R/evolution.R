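#' Configuration of the generational evolutionary loop
#'
#' Each generation, `n_agents` individuals are placed uniformly at random in
#' the environment with small random velocities, move for
#' `steps_per_generation` time steps, and are scored by the mean resource
#' value they experienced. Offspring parentage is drawn with probability
#' proportional to relative fitness; each offspring inherits its parent's
#' traits perturbed by independent Gaussian mutations. In the asocial control
#' `lmax` is held fixed at `lmax_asocial` (between the repulsion and
#' attraction length scales, so agents repel but never attract).
#'
#' @param n_agents population size N (>= 2).
#' @param generations number of generations G.
#' @param steps_per_generation lifetime length in time steps (default 1500,
#'   matching the default peak relocation timescale).
#' @param mutation_sd named numeric vector with entries `psi0`, `psi1`,
#'   `lmax`: mutation standard deviations.
#' @param lmax_cap upper bound on `lmax` (default 30).
#' @param psi_bounds length-2 numeric: bounds applied to `psi0` and `psi1`
#'   under mutation (default `c(0, Inf)`).
#' @param asocial logical; fix `lmax` at `lmax_asocial`.
#' @param lmax_asocial fixed interaction range in asocial mode (default 2).
#' @param init_psi0,init_psi1,init_lmax length-2 ranges for the uniform
#'   initial trait draws.
#' @param speed_max maximum initial speed at the start of each generation.
#' @param reset_environment logical; redraw peak positions each generation
#'   (default `FALSE`: the environment carries over).
#' @return an object of class `evolution_config`.
#' @export
evolution_config <- function(n_agents = 500, generations = 100,
                             steps_per_generation = 1500,
                             mutation_sd = c(psi0 = 0.05, psi1 = 0.05, lmax = 0.5),
                             lmax_cap = 30, psi_bounds = c(0, Inf),
                             asocial = FALSE, lmax_asocial = 2,
                             init_psi0 = c(0, 1), init_psi1 = c(0, 1),
                             init_lmax = c(0, 30), speed_max = 0.1,
                             reset_environment = FALSE) {
  stopifnot(n_agents >= 2, generations >= 1, steps_per_generation >= 1,
            all(mutation_sd >= 0),
            all(c("psi0", "psi1", "lmax") %in% names(mutation_sd)),
            lmax_cap > 0, length(psi_bounds) == 2,
            psi_bounds[1] <= psi_bounds[2])
  structure(list(n_agents = as.integer(n_agents),
                 generations = as.integer(generations),
                 steps_per_generation = as.integer(steps_per_generation),
                 mutation_sd = mutation_sd, lmax_cap = lmax_cap,
                 psi_bounds = psi_bounds, asocial = asocial,
                 lmax_asocial = lmax_asocial,
                 init_psi0 = init_psi0, init_psi1 = init_psi1,
                 init_lmax = init_lmax, speed_max = speed_max,
                 reset_environment = reset_environment),
            class = "evolution_config")
}

#' Mean experienced resource over a lifetime
#'
#' Fitness is the arithmetic mean of the resource values an individual
#' experienced over its generation.
#'
#' @param S_samples numeric vector of per-step resource values.
#' @return scalar mean.
#' @export
lifetime_fitness <- function(S_samples) {
  if (!length(S_samples)) stop("empty trajectory: no resource samples")
  mean(S_samples)
}

#' Fitness-proportional parent selection
#'
#' Draws one parent per offspring, i.i.d., with probability proportional to
#' relative fitness. When every fitness is zero, parents are drawn uniformly.
#'
#' @param fitnesses non-negative numeric vector.
#' @param n_offspring number of offspring (default: population size).
#' @return integer vector of parent indices.
#' @export
select_and_reproduce <- function(fitnesses, n_offspring = length(fitnesses)) {
  if (any(fitnesses < 0)) stop("fitnesses must be non-negative")
  if (sum(fitnesses) == 0)
    return(sample.int(length(fitnesses), n_offspring, replace = TRUE))
  sample.int(length(fitnesses), n_offspring, replace = TRUE, prob = fitnesses)
}

#' Mutate offspring traits
#'
#' Each trait is perturbed by an independent Gaussian with its configured
#' standard deviation; `lmax` is clipped to `[0, lmax_cap]` and `psi0`,
#' `psi1` to `psi_bounds`. In asocial mode `lmax` stays fixed at
#' `lmax_asocial`.
#'
#' @param traits a [trait_set()] of parent traits.
#' @param config an [evolution_config()].
#' @return mutated [trait_set()].
#' @export
mutate_traits <- function(traits, config) {
  n <- nrow(traits)
  sd <- config$mutation_sd
  clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)
  psi0 <- clip(traits$psi0 + rnorm(n, 0, sd[["psi0"]]),
               config$psi_bounds[1], config$psi_bounds[2])
  psi1 <- clip(traits$psi1 + rnorm(n, 0, sd[["psi1"]]),
               config$psi_bounds[1], config$psi_bounds[2])
  lmax <- if (config$asocial) rep(config$lmax_asocial, n)
          else clip(traits$lmax + rnorm(n, 0, sd[["lmax"]]), 0, config$lmax_cap)
  trait_set(psi0, psi1, lmax, lmax_cap = config$lmax_cap)
}

# uniform initial trait draws per the config
init_traits <- function(config) {
  n <- config$n_agents
  lmax <- if (config$asocial) rep(config$lmax_asocial, n)
          else runif(n, config$init_lmax[1], min(config$init_lmax[2], config$lmax_cap))
  trait_set(runif(n, config$init_psi0[1], config$init_psi0[2]),
            runif(n, config$init_psi1[1], config$init_psi1[2]),
            lmax, lmax_cap = config$lmax_cap)
}

#' Run the evolutionary loop
#'
#' Simulates `generations` generations: random placement, a lifetime of
#' motion in the (persistent) resource environment, fitness scoring,
#' fitness-proportional reproduction and mutation. Uses the current RNG state;
#' call `set.seed()` (or pass `seed`) for reproducibility.
#'
#' @param config an [evolution_config()].
#' @param params a [social_params()].
#' @param field a [resource_field()]; if `NULL`, a fresh default two-peak
#'   field is drawn on the reference 346-lr torus.
#' @param seed optional integer seed.
#' @param traits optional initial [trait_set()] (default: uniform draws per
#'   the config; enables resuming a run from its final traits).
#' @param lineages optional integer lineage label per agent; offspring inherit
#'   their parent's label and per-generation lineage frequencies are recorded.
#' @param record_traits logical; keep the full per-generation trait matrices.
#' @param log_every emit a progress line (generation, mean fitness, trait
#'   means) every this many generations; 0 silences logging.
#' @return object of class `evolution_result`: list with `records` (one row
#'   per generation: trait and fitness summaries), `traits` (final
#'   generation), `trait_history` (optional list of trait data frames),
#'   `lineage_freq` (optional), `field` (final environment state), `config`.
#' @export
run_evolution <- function(config, params = social_params(), field = NULL,
                          seed = NULL, traits = NULL, lineages = NULL,
                          record_traits = FALSE, log_every = 0) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(field)) {
    field <- make_resource_field(geometry = torus_geometry())
  }
  field0 <- field
  if (is.null(traits)) traits <- init_traits(config)
  stopifnot(nrow(traits) == config$n_agents)
  if (!is.null(lineages)) stopifnot(length(lineages) == config$n_agents)

  recs <- vector("list", config$generations)
  hist <- if (record_traits) vector("list", config$generations) else NULL
  lin <- if (!is.null(lineages)) vector("list", config$generations) else NULL

  for (g in seq_len(config$generations)) {
    if (config$reset_environment) {
      field <- field0
      m <- peaks_matrix(field)
      if (nrow(m)) {
        m[, 1:2] <- runif(2 * nrow(m), 0, field$geometry$edge_length)
        field <- set_peaks_matrix(field, m)
      }
    }
    state <- init_agent_state(config$n_agents, field$geometry,
                              config$speed_max)
    sim <- step(state, traits, params, field,
                n_steps = config$steps_per_generation)
    field <- sim$field
    fit <- sim$fitness
    mf <- mean(fit)
    recs[[g]] <- data.frame(
      generation = g,
      mean_fitness = mf,
      cv_fitness = if (mf > 0) sd(fit) / mf else NA_real_,
      mean_psi0 = mean(traits$psi0), sd_psi0 = sd(traits$psi0),
      mean_psi1 = mean(traits$psi1), sd_psi1 = sd(traits$psi1),
      mean_lmax = mean(traits$lmax), sd_lmax = sd(traits$lmax))
    if (log_every > 0 && g %% log_every == 0)
      message(sprintf(
        "generation %d: fitness %.3g, psi0 %.3g, psi1 %.3g, lmax %.3g",
        g, mf, mean(traits$psi0), mean(traits$psi1), mean(traits$lmax)))
    if (record_traits) hist[[g]] <- as.data.frame(traits)
    if (!is.null(lineages))
      lin[[g]] <- data.frame(generation = g,
                             lineage = sort(unique(lineages)),
                             freq = as.vector(
                               table(factor(lineages,
                                            sort(unique(lineages)))) /
                                 config$n_agents))
    parents <- select_and_reproduce(fit)
    traits <- mutate_traits(traits[parents, , drop = FALSE], config)
    class(traits) <- c("trait_set", "data.frame")
    attr(traits, "lmax_cap") <- config$lmax_cap
    if (!is.null(lineages)) lineages <- lineages[parents]
  }
  out <- list(records = do.call(rbind, recs), traits = traits,
              trait_history = hist,
              lineage_freq = if (!is.null(lin)) do.call(rbind, lin) else NULL,
              lineages = lineages, field = field, config = config)
  class(out) <- "evolution_result"
  out
}

#' @export
print.evolution_result <- function(x, ...) {
  r <- x$records[nrow(x$records), ]
  cat(sprintf(
    "<evolution_result> %d generations, N=%d%s\n final: mean fitness %.3g, psi0 %.3g, psi1 %.3g, lmax %.3g\n",
    x$config$generations, x$config$n_agents,
    if (x$config$asocial) " (asocial control)" else "",
    r$mean_fitness, r$mean_psi0, r$mean_psi1, r$mean_lmax))
  invisible(x)
}

#' Invasion experiment
#'
#' Seeds `n_invaders` individuals carrying `invader_traits` into a resident
#' population with `resident_traits`, labels the two lineages, and runs the
#' evolutionary loop with lineage labels inherited by offspring.
#'
#' @param resident_traits,invader_traits single-row [trait_set()]s (or lists
#'   with `psi0`, `psi1`, `lmax`).
#' @param n_invaders number of initial invaders (1 <= n_invaders < N).
#' @param config an [evolution_config()] (its `asocial` flag applies to
#'   mutation of `lmax`; use `asocial = FALSE` to let the social trait
#'   evolve).
#' @inheritParams run_evolution
#' @return data frame with columns `generation` and `invader_freq`, plus the
#'   full `evolution_result` as attribute `"result"`.
#' @export
invasion_experiment <- function(resident_traits, invader_traits, n_invaders,
                                config, params = social_params(), field = NULL,
                                seed = NULL) {
  n <- config$n_agents
  stopifnot(n_invaders >= 1, n_invaders < n)
  traits <- trait_set(
    c(rep(resident_traits$psi0[1], n - n_invaders),
      rep(invader_traits$psi0[1], n_invaders)),
    c(rep(resident_traits$psi1[1], n - n_invaders),
      rep(invader_traits$psi1[1], n_invaders)),
    c(rep(resident_traits$lmax[1], n - n_invaders),
      rep(invader_traits$lmax[1], n_invaders)),
    lmax_cap = config$lmax_cap)
  lineages <- c(rep(0L, n - n_invaders), rep(1L, n_invaders))
  res <- run_evolution(config, params, field, seed = seed, traits = traits,
                       lineages = lineages)
  lf <- res$lineage_freq
  inv <- lf[lf$lineage == 1L, c("generation", "freq")]
  missing_gen <- setdiff(seq_len(config$generations), inv$generation)
  if (length(missing_gen))
    inv <- rbind(inv, data.frame(generation = missing_gen, freq = 0))
  inv <- inv[order(inv$generation), ]
  names(inv) <- c("generation", "invader_freq")
  rownames(inv) <- NULL
  attr(inv, "result") <- res
  inv
}

#' Torus edge length holding a reference number density
#'
#' Optional helper for density-matched scaling: the edge that keeps
#' `n_agents / edge^2` equal to that of `reference_n` agents on a
#' `reference_edge` torus. Protocol defaults use the fixed reference domain
#' instead; this helper supports sensitivity analyses of density-dependent
#' observables.
#'
#' @param n_agents population size of the scaled run.
#' @param reference_n,reference_edge the reference population and edge.
#' @return edge length.
#' @export
scaled_edge_length <- function(n_agents, reference_n = 500,
                               reference_edge = 346) {
  reference_edge * sqrt(n_agents / reference_n)
}

#' Checkpoint and resume an evolutionary run
#'
#' `save_checkpoint()` writes the state needed to continue a run — final
#' traits, environment state, the full RNG state, and the configuration — to
#' an RDS file. `resume_evolution()` restores the RNG state and continues
#' for a further block of generations, erroring if the stored configuration
#' disagrees with the one supplied.
#'
#' @param result an `evolution_result` from [run_evolution()].
#' @param path file path for the checkpoint.
#' @return `save_checkpoint()` returns `path` invisibly.
#' @export
save_checkpoint <- function(result, path) {
  stopifnot(inherits(result, "evolution_result"))
  rng <- get(".Random.seed", envir = globalenv())
  saveRDS(list(traits = result$traits, field = result$field,
               lineages = result$lineages, rng = rng,
               config = result$config), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @param config an [evolution_config()]; must match the checkpointed one
#'   except for `generations`.
#' @param params a [social_params()].
#' @param generations number of further generations to run.
#' @return `resume_evolution()` returns an `evolution_result` for the
#'   continued block.
#' @export
resume_evolution <- function(path, config, params = social_params(),
                             generations = config$generations) {
  ck <- readRDS(path)
  same <- function(f) identical(ck$config[[f]], config[[f]])
  fields <- c("n_agents", "steps_per_generation", "mutation_sd", "lmax_cap",
              "asocial", "lmax_asocial")
  bad <- fields[!vapply(fields, same, logical(1))]
  if (length(bad))
    stop("checkpoint/config mismatch in: ", paste(bad, collapse = ", "))
  assign(".Random.seed", ck$rng, envir = globalenv())
  cfg <- config
  cfg$generations <- as.integer(generations)
  run_evolution(cfg, params, ck$field, traits = ck$traits,
                lineages = ck$lineages)
}
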