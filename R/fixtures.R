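#' Catalogue of deterministic test scenarios
#'
#' Named, fully self-describing configurations used throughout the test
#' suite; replaying a scenario from its seed reproduces its outputs exactly
#' (bit-for-bit when the navigational noise is zero).
#'
#' @return character vector of scenario names.
#' @export
scenario_catalog <- function() {
  c("two_agent_balance", "single_peak_esst", "asocial_control",
    "perturbed_low_psi0", "perturbed_high_psi0")
}

# ESSt-like trait means: psi0 = 3, psi1 = 2.45, lmax = 29
esst_traits <- function(n = 1) trait_set(rep(3, n), 2.45, 29)

#' Build a named scenario
#'
#' * `two_agent_balance`: two noise-free agents at the pair force-balance
#'   separation; they remain at fixed separation.
#' * `single_peak_esst`: a population with ESSt-like trait means
#'   (psi0 = 3, psi1 = 2.45, lmax = 29) tracking a single slowly-moving
#'   peak.
#' * `asocial_control`: the same population with `lmax = 2` (repulsion only).
#' * `perturbed_low_psi0` / `perturbed_high_psi0`: ESSt-like populations with
#'   the baseline speed shifted to mean 0.4 / 8.8; both track a moving peak
#'   poorly relative to the ESSt scenario.
#'
#' @param name a name from [scenario_catalog()].
#' @param overrides named list of fields to override (`n_agents`, `n_steps`,
#'   `seed`, `params`, `traits`, ...); overrides are re-validated.
#' @return object of class `scenario`: list with fields `name`, `n_agents`,
#'   `n_steps`, `seed`, `params`, `traits`, and `checks`
#'   (named list of predicate functions applied to the replayed run).
#' @export
make_scenario <- function(name, overrides = list()) {
  if (!name %in% scenario_catalog())
    stop("unknown scenario: ", name)
  base <- switch(
    name,
    two_agent_balance = {
      p <- social_params(gamma = 0)
      list(n_agents = 2L, n_steps = 50L, seed = 1L,
           params = p, traits = trait_set(0, 0, 30),
           edge_length = 50,
           init = function(geo) {
             d <- pair_balance_distance(p)
             agent_state(rbind(c(25, 25), c(25 + d, 25)),
                         matrix(0, 2, 2), geo)
           },
           checks = list(
             separation_constant = function(run) {
               d0 <- pair_balance_distance(p)
               d1 <- torus_distance(run$state$positions[1, ],
                                    run$state$positions[2, ],
                                    run$state$geometry)
               abs(d1 - d0) < 1e-6
             }))
    },
    single_peak_esst = list(
      n_agents = 150L, n_steps = 1200L, seed = 1L,
      params = social_params(), traits = esst_traits(),
      edge_length = 346, init = NULL,
      checks = list(
        accumulates_on_peak = function(run)
          mean(tail(run$counts, 200)) > mean(head(run$counts, 200)))),
    asocial_control = list(
      n_agents = 150L, n_steps = 1200L, seed = 1L,
      params = social_params(), traits = trait_set(3, 2.45, 2),
      edge_length = 346, init = NULL,
      checks = list(
        some_accumulation = function(run)
          mean(tail(run$counts, 200)) >= mean(head(run$counts, 200)))),
    perturbed_low_psi0 = list(
      n_agents = 150L, n_steps = 1200L, seed = 1L,
      params = social_params(), traits = trait_set(0.4, 2.45, 29),
      edge_length = 346, init = NULL, checks = list()),
    perturbed_high_psi0 = list(
      n_agents = 150L, n_steps = 1200L, seed = 1L,
      params = social_params(), traits = trait_set(8.8, 2.45, 29),
      edge_length = 346, init = NULL, checks = list()))
  sc <- modifyList(base, overrides)
  sc$name <- name
  stopifnot(sc$n_agents >= 1, sc$n_steps >= 1,
            inherits(sc$params, "social_params"),
            inherits(sc$traits, "trait_set"))
  class(sc) <- "scenario"
  sc
}

#' Replay a scenario
#'
#' Runs the scenario from its seed and evaluates its embedded checks.
#'
#' @param scenario a [make_scenario()] object.
#' @return list with the run outputs (fields depend on the scenario: `state`,
#'   `counts`, `kl`, ...) plus `checks`, a named logical vector.
#' @export
run_scenario <- function(scenario) {
  set.seed(scenario$seed)
  run <- if (scenario$name == "two_agent_balance") {
    geo <- torus_geometry(scenario$edge_length)
    state <- scenario$init(geo)
    sim <- step(state, scenario$traits, scenario$params, NULL,
                n_steps = scenario$n_steps)
    list(state = sim$state)
  } else {
    tk <- track_run(scenario$traits, n_agents = scenario$n_agents,
                    n_steps = scenario$n_steps, params = scenario$params,
                    edge_length = scenario$edge_length)
    list(state = tk$state, counts = tk$counts$count, kl = tk$kl,
         arrival = tk$arrival, field = tk$field)
  }
  run$checks <- vapply(scenario$checks, function(f) isTRUE(f(run)), logical(1))
  run
}

#' Pair force-balance separation
#'
#' The distance at which the pairwise repulsion and attraction cancel:
#' the root of `(Cr/lr) e^(-d/lr) = (Ca/la) e^(-d/la)`, in closed form
#' `log((Cr * la) / (Ca * lr)) / (1/lr - 1/la)`.
#'
#' @param params a [social_params()].
#' @return scalar distance.
#' @export
pair_balance_distance <- function(params) {
  log((params$Cr / params$lr) / (params$Ca / params$la)) /
    (1 / params$lr - 1 / params$la)
}

#' Synthetic arrival-count series
#'
#' Generates counts from a linear (`kappa_a * t + intercept`) or exponential
#' (`kappa_s1 + exp(kappa_s2 * t)`) accumulation model plus i.i.d. Gaussian
#' noise, floored at zero and rounded to integers. Supports fit-recovery
#' tests for [arrival_curve()].
#'
#' @param model `"linear"` or `"exponential"`.
#' @param n_times series length (>= 2).
#' @param kappa_a,intercept linear-model parameters.
#' @param kappa_s1,kappa_s2 exponential-model parameters.
#' @param noise_sd Gaussian noise standard deviation (0 = exact curve).
#' @param round_counts floor at 0 and round to integers (default `TRUE`;
#'   disable for exact-curve recovery tests).
#' @return data frame with columns `t`, `count`.
#' @export
synth_counts <- function(model = c("linear", "exponential"), n_times,
                         kappa_a = 0.5, intercept = 0,
                         kappa_s1 = 5, kappa_s2 = 0.01,
                         noise_sd = 0, round_counts = TRUE) {
  model <- match.arg(model)
  stopifnot(n_times >= 2)
  t <- seq_len(n_times)
  mu <- if (model == "linear") kappa_a * t + intercept
        else kappa_s1 + exp(kappa_s2 * t)
  y <- mu + rnorm(n_times, 0, noise_sd)
  if (round_counts) y <- round(pmax(y, 0))
  data.frame(t = t, count = y)
}
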