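geo <- torus_geometry(100)
p0 <- social_params()

test_that("mean distance to 10 nearest neighbours matches brute force", {
  for (seed in 1:50) {
    n <- 15
    pos <- random_config(n, 100, seed)
    st <- agent_state(pos, matrix(0, n, 2), geo)
    expect_equal(mean_dist_knn(st), bf_mean_dist_knn(pos, 100, 10))
  }
  # coincident agents: zero
  st0 <- agent_state(matrix(5, 12, 2), matrix(0, 12, 2), geo)
  expect_equal(mean_dist_knn(st0), 0)
  # homogeneity: doubling all separations doubles the order parameter
  pos <- random_config(15, 20, 3)
  st1 <- agent_state(pos, matrix(0, 15, 2), geo)
  st2 <- agent_state(2 * pos, matrix(0, 15, 2), geo)
  expect_equal(mean_dist_knn(st2), 2 * mean_dist_knn(st1))
  expect_error(mean_dist_knn(agent_state(matrix(1, 5, 2), matrix(0, 5, 2),
                                         geo)),
               "more agents")
})

test_that("potential energy evaluates the pair potential over neighbour sets", {
  # isolated pair at the balance distance: closed-form value, both agents
  dstar <- pair_balance_distance(p0)
  st <- agent_state(rbind(c(50, 50), c(50 + dstar, 50)), matrix(0, 2, 2), geo)
  expect_equal(potential_energy(st, trait_set(0, 0, 30), p0),
               pair_potential(dstar, p0))
  # out of range: zero
  expect_equal(potential_energy(st, trait_set(0, 0, 1), p0), 0)
  # contact-packed cluster (separations well below the potential's zero
  # crossing, so the repulsive core dominates) has higher potential than the
  # same agents dispersed beyond every interaction range
  packed <- agent_state(50 + random_config(20, 0.05, 8), matrix(0, 20, 2),
                        geo)
  spread <- agent_state(random_config(20, 95, 8), matrix(0, 20, 2), geo)
  tr <- trait_set(0, 0, 30)
  expect_gt(potential_energy(packed, tr, p0), 0)
  expect_gt(potential_energy(packed, tr, p0),
            potential_energy(spread, tr, p0))
})

test_that("state classification partitions the line at the two thresholds", {
  psi <- c(-0.5, 0, 1.0, 2.95, 3.0)
  got <- classify_state(psi)
  expect_equal(as.character(got),
               c("station-keeping", "station-keeping", "cohesive",
                 "cohesive", "dispersed"))
  # custom thresholds move the boundaries
  expect_equal(as.character(classify_state(1.5, c(1, 2))), "cohesive")
  expect_equal(as.character(classify_state(0.5, c(1, 2))), "station-keeping")
})

test_that("KL divergence matches direct summation and is zero at equality", {
  set.seed(12)
  fld <- resource_field(list(resource_peak(c(50, 50), 10, 10)),
                        drift = c(0, 0), relocation_timescale = Inf,
                        geometry = geo)
  pos <- matrix(runif(160, 30, 70), ncol = 2)
  st <- agent_state(pos, matrix(0, 80, 2), geo)
  got <- kl_divergence_to_resource(st, fld, n_bins = 10, r_max = 30)
  # direct summation oracle on the same binning
  breaks <- seq(0, 30, length.out = 11)
  r <- torus_distance(pos, matrix(c(50, 50), 80, 2, byrow = TRUE), geo)
  counts <- as.numeric(table(cut(r, breaks, include.lowest = TRUE)))
  q <- exp(-breaks[-11]^2 / 100) - exp(-breaks[-1]^2 / 100)
  expect_equal(got, bf_kl(q, counts))
  expect_gte(got, 0)
  # agents distributed exactly like the resource in every bin -> ~0
  # (construct counts proportional to the annulus-integrated resource)
  nb <- round(1000 * q / sum(q))
  rads <- unlist(mapply(function(lo, hi, k) {
    if (k == 0) return(numeric(0))
    mid <- (lo + hi) / 2
    rep(mid, k)
  }, breaks[-11], breaks[-1], nb))
  posq <- cbind(50 + rads, 50)
  stq <- agent_state(posq, matrix(0, length(rads), 2), geo)
  expect_lt(kl_divergence_to_resource(stq, fld, n_bins = 10, r_max = 30),
            1e-3)
  # all agents in one annulus while the resource spans many: strictly positive
  st1 <- agent_state(matrix(c(rep(52, 30), rep(50, 30)), ncol = 2),
                     matrix(0, 30, 2), geo)
  expect_gt(kl_divergence_to_resource(st1, fld, n_bins = 10, r_max = 30), 0.1)
  # no agents near the peak: error
  stfar <- agent_state(matrix(5, 3, 2), matrix(0, 3, 2), geo)
  expect_error(kl_divergence_to_resource(stfar, fld, n_bins = 10, r_max = 20),
               "no agents")
})

test_that("arrival fits recover noise-free synthetic parameters within 1%", {
  lin <- synth_counts("linear", 200, kappa_a = 0.5, intercept = 2,
                      round_counts = FALSE)
  fl <- arrival_curve(lin$count, lin$t)
  expect_equal(fl$linear$kappa_a, 0.5, tolerance = 1e-6)
  expect_equal(fl$preferred, "linear")
  ex <- synth_counts("exponential", 300, kappa_s1 = 5, kappa_s2 = 0.01,
                     round_counts = FALSE)
  fe <- arrival_curve(ex$count, ex$t)
  expect_equal(fe$exponential$kappa_s1, 5, tolerance = 0.01)
  expect_equal(fe$exponential$kappa_s2, 0.01, tolerance = 0.01)
  expect_equal(fe$preferred, "exponential")
  # degenerate: constant counts flagged, not an error
  fd <- arrival_curve(rep(3, 50))
  expect_true(fd$degenerate)
  expect_true(is.na(fd$preferred))
  # all-zero counts
  f0 <- arrival_curve(rep(0, 50))
  expect_true(f0$degenerate)
})

test_that("model selection recovers the generating model on noisy series", {
  set.seed(55)
  n_rep <- 20
  hits_lin <- hits_exp <- logical(n_rep)
  for (i in seq_len(n_rep)) {
    lin <- synth_counts("linear", 150, kappa_a = 0.4, intercept = 3,
                        noise_sd = 1.5)
    hits_lin[i] <- arrival_curve(lin$count, lin$t)$preferred == "linear"
    ex <- synth_counts("exponential", 400, kappa_s1 = 5, kappa_s2 = 0.012,
                       noise_sd = 1.5)
    hits_exp[i] <- arrival_curve(ex$count, ex$t)$preferred == "exponential"
  }
  expect_gte(mean(hits_lin), 0.95)
  expect_gte(mean(hits_exp), 0.95)
})

test_that("a single-value sweep grid yields identical branches", {
  set.seed(6)
  sw <- hysteresis_sweep(n_agents = 30, psi_start = 2, psi_end = 2,
                         psi_step = 0.2, equilibration_steps = 50,
                         replicates = 2, edge_length = 60)
  s <- summarize_sweep(sw)
  expect_equal(nrow(s), 2)
  # both branches measured (the up branch re-equilibrates from the down
  # branch's end state, so values differ stochastically but exist)
  expect_true(all(c("down", "up") %in% s$direction))
  expect_true(all(is.finite(s$d10nn)))
})

test_that("a k = 0 population stays at the uniform ideal-gas density", {
  # no social interactions: <d10NN> matches uniform random points and is
  # insensitive to psi0
  set.seed(14)
  pk0 <- social_params(k = 0)
  L <- 60
  vals <- vapply(c(0.5, 3), function(psi0) {
    st <- init_agent_state(60, torus_geometry(L))
    st <- step(st, trait_set(psi0, 0, 30), pk0, NULL, n_steps = 300)$state
    mean_dist_knn(st)
  }, numeric(1))
  ref <- mean(replicate(40, {
    mean_dist_knn(agent_state(random_config(60, L, sample.int(1e6, 1)),
                              matrix(0, 60, 2), torus_geometry(L)))
  }))
  expect_equal(vals[1], ref, tolerance = 0.15)
  expect_equal(vals[2], ref, tolerance = 0.15)
})

test_that("group-peak matching pairs each peak with its nearest group", {
  # two well-separated static peaks; plant two clusters by hand
  set.seed(19)
  L <- 200
  g <- torus_geometry(L)
  fld <- resource_field(list(resource_peak(c(50, 100), 10, 15),
                             resource_peak(c(150, 100), 5, 15)),
                        drift = c(0, 0), diffusion_sd = 0,
                        relocation_timescale = Inf, geometry = g)
  n1 <- 40; n2 <- 20
  pos <- rbind(cbind(runif(n1, 45, 55), runif(n1, 95, 105)),
               cbind(runif(n2, 145, 155), runif(n2, 95, 105)))
  tr <- trait_set(rep(1, n1 + n2), 2.45, 29)
  st <- agent_state(pos, matrix(0, n1 + n2, 2), g)
  sim <- step(st, tr, social_params(), fld, n_steps = 60, record_every = 10,
              move_peaks = FALSE)
  m <- group_peak_matching(sim, tr, social_params())
  expect_equal(nrow(m), 2)
  expect_gt(m$peak_mass[1], m$peak_mass[2])
  expect_gt(m$group_size[1], m$group_size[2])
  expect_equal(m$group_size[1], n1, tolerance = 0.2)
})

test_that("stronger attraction shifts the cohesive-dispersed boundary upward", {
  sw <- phase_sweep("Ca", sweep_values = c(0.7, 2), psi0_values = c(1.5, 2.5, 3.5),
                    n_agents = 60, steps = 600, edge_length = 150, seed = 44)
  agg <- aggregate(d10nn ~ value + psi0, sw, mean)
  # at the intermediate baseline speed, stronger attraction keeps the
  # population cohesive (lower <d10NN>)
  mid <- agg[agg$psi0 == 2.5, ]
  expect_lt(mid$d10nn[mid$value == 2], mid$d10nn[mid$value == 0.7])
  b <- phase_boundary(sw)
  expect_equal(nrow(b), 2)
  expect_true(all(b$psi0_boundary >= 1.5 & b$psi0_boundary <= 3.5))
  # boundary at stronger attraction sits at or above the weak-attraction one
  expect_gte(b$psi0_boundary[b$value == 2], b$psi0_boundary[b$value == 0.7])
})
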