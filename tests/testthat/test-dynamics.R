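p0 <- social_params()   # Cr=1.1, Ca=1, lr=1, la=7.5, k=25
geo <- torus_geometry(346)

test_that("parameter invariants are enforced", {
  expect_error(social_params(lr = 8, la = 7.5), "lr < la")
  expect_error(social_params(Cr = 0.1, la = 7.5), "repulsive")
  expect_error(trait_set(1, 1, 31), "lmax")
  expect_silent(trait_set(1, 1, 31, lmax_cap = 50))
})

test_that("neighbour sets match the brute-force all-pairs oracle", {
  for (seed in 1:50) {
    n <- 30
    pos <- random_config(n, 60, seed)
    lmax <- rep(c(30, 8, 2), length.out = n)
    st <- agent_state(pos, matrix(0, n, 2), torus_geometry(60))
    got <- neighbor_sets(st, trait_set(0, 0, lmax), p0)
    want <- bf_neighbors(pos, 60, lmax, p0$k)
    expect_equal(got, lapply(want, as.integer))
  }
})

test_that("neighbour rules: self-exclusion, lmax cutoff, k cap", {
  # two agents in range: each is the other's sole neighbour
  st <- agent_state(rbind(c(10, 10), c(13, 10)), matrix(0, 2, 2), geo)
  nb <- neighbor_sets(st, trait_set(0, 0, 30), p0)
  expect_equal(nb, list(2L, 1L))
  # all others beyond lmax: empty (asocial isolation)
  nb2 <- neighbor_sets(st, trait_set(0, 0, 2), p0)
  expect_equal(lengths(nb2), c(0L, 0L))
  # 30 clustered agents, k = 25: exactly the 25 nearest
  pos <- random_config(30, 15, 99)
  st3 <- agent_state(pos, matrix(0, 30, 2), torus_geometry(60))
  nb3 <- neighbor_sets(st3, trait_set(0, 0, 30), p0)
  expect_true(all(lengths(nb3) == 25))
  expect_equal(nb3, lapply(bf_neighbors(pos, 60, rep(30, 30), 25), as.integer))
})

test_that("social force matches the potential gradient to 1e-6", {
  ds <- seq(0.1, 29, length.out = 40)
  for (d in ds) {
    st <- agent_state(rbind(c(50, 50), c(50 + d, 50)), matrix(0, 2, 2), geo)
    f <- social_force(st, trait_set(0, 0, 30), p0)
    # force on agent 1 is along -x (towards or away from agent 2)
    expect_equal(f[1, 2], 0)
    expect_equal(f[1, 1], -bf_radial_force(d, p0) * 1, tolerance = 1e-6)
  }
})

test_that("pair force is equal and opposite, and flips sign at the balance distance", {
  dstar <- pair_balance_distance(p0)
  expect_equal(dstar, log(8.25) / (1 - 1 / 7.5))
  for (d in c(0.5, dstar - 0.1, dstar + 0.1, 6)) {
    st <- agent_state(rbind(c(50, 50), c(50 + d, 50)), matrix(0, 2, 2), geo)
    f <- social_force(st, trait_set(0, 0, 30), p0)
    expect_equal(f[1, ], -f[2, ])
    # repulsive (agent 1 pushed towards -x) below dstar, attractive above
    expect_equal(sign(f[1, 1]), if (d < dstar) -1 else 1)
  }
  # near-contact repulsion approaches Cr/lr - Ca/la
  st0 <- agent_state(rbind(c(50, 50), c(50 + 1e-6, 50)), matrix(0, 2, 2), geo)
  f0 <- social_force(st0, trait_set(0, 0, 30), p0)
  expect_equal(abs(f0[1, 1]), 1.1 / 1 - 1 / 7.5, tolerance = 1e-5)
  # no neighbours: zero force
  stfar <- agent_state(rbind(c(0, 0), c(173, 173)), matrix(0, 2, 2), geo)
  expect_equal(social_force(stfar, trait_set(0, 0, 2), p0),
               matrix(0, 2, 2))
})

test_that("preferred-speed parameter is psi0 - psi1 * S", {
  expect_equal(response_speed_param(list(psi0 = 3, psi1 = 2.54), 0), 3)
  expect_equal(response_speed_param(list(psi0 = 3, psi1 = 2.45), 10), -21.5)
  expect_equal(response_speed_param(list(psi0 = 5, psi1 = 0), 100), 5)
})

test_that("autonomous force accelerates towards the preferred speed", {
  expect_equal(autonomous_force(3, c(1, 0), p0), c(2, 0))
  # at the fixed point eta|v|^2 = Psi the force vanishes
  expect_equal(autonomous_force(4, c(2, 0), p0), c(0, 0))
  # Psi < 0: force antiparallel to v
  f <- autonomous_force(-1, c(0.3, 0.4), p0)
  expect_lt(sum(f * c(0.3, 0.4)), 0)
  # undefined heading at rest: zero
  expect_equal(autonomous_force(3, c(0, 0), p0), c(0, 0))
})

test_that("isolated agent speed relaxes to the fixed point of the speed ODE", {
  skip_if_not_installed("deSolve")
  pq <- social_params(gamma = 0)
  for (psi in c(0.5, 2, 4)) {
    st <- agent_state(matrix(50, 1, 2), matrix(c(0.05, 0), 1, 2), geo)
    out <- step(st, trait_set(psi, 0, 30), pq, NULL, n_steps = 100)
    got <- sqrt(sum(out$state$velocities^2))
    ode <- deSolve::ode(c(v = 0.05), seq(0, 100, 1),
                        function(t, y, par) list(psi - pq$eta * y^2))
    expect_equal(got, unname(ode[nrow(ode), "v"]), tolerance = 1e-3)
    expect_equal(got, sqrt(psi), tolerance = 1e-3)
  }
})

test_that("station-keeping: speed decays to zero iff Psi <= 0", {
  pq <- social_params(gamma = 0)
  for (psi in c(-1, -0.25, 0)) {
    st <- agent_state(matrix(50, 1, 2), matrix(c(1, 0), 1, 2), geo)
    sp <- numeric(5)
    for (i in 1:5) {
      st <- step(st, trait_set(psi, 0, 30), pq, NULL, n_steps = 40)$state
      sp[i] <- sqrt(sum(st$velocities^2))
    }
    expect_true(all(diff(sp) <= 0))
    # strictly negative Psi decays fast; at Psi = 0 the cubic damping decays
    # algebraically (v ~ 1/sqrt(2t)) but still towards zero
    expect_lt(sp[5], if (psi < 0) 0.02 else 1 / sqrt(2 * 200) * 1.1)
  }
  for (psi in c(0.1, 1)) {
    st <- agent_state(matrix(50, 1, 2), matrix(c(1, 0), 1, 2), geo)
    st <- step(st, trait_set(psi, 0, 30), pq, NULL, n_steps = 400)$state
    expect_equal(sqrt(sum(st$velocities^2)), sqrt(psi), tolerance = 1e-3)
  }
})

test_that("navigational noise has exact magnitude gamma", {
  pg <- social_params(gamma = 0.01)
  st <- agent_state(matrix(50, 1, 2), matrix(0, 1, 2), geo)
  set.seed(1)
  out <- step(st, trait_set(0, 0, 30), pg, NULL, n_steps = 1)
  expect_equal(sqrt(sum(out$state$velocities^2)), 0.01)
})

test_that("trajectories are deterministic given a seed and torus-equivariant", {
  n <- 40
  L <- 80
  g <- torus_geometry(L)
  pos <- random_config(n, L, 123)
  vel <- matrix(rnorm(2 * n, 0, 0.1), ncol = 2)
  tr <- trait_set(2, 0, 30)
  run <- function(positions, seed) {
    set.seed(seed)
    step(agent_state(positions, vel, g), tr, p0, NULL, n_steps = 30)$state
  }
  a <- run(pos, 5)
  b <- run(pos, 5)
  expect_identical(a$positions, b$positions)
  expect_identical(a$velocities, b$velocities)
  shift <- c(31.7, 55.2)
  c2 <- run(torus_wrap(sweep(pos, 2, shift, "+"), g), 5)
  expect_equal(c2$positions,
               torus_wrap(sweep(a$positions, 2, shift, "+"), g),
               tolerance = 1e-9)
  expect_equal(c2$velocities, a$velocities, tolerance = 1e-9)
})

test_that("interaction graph links i and j if either influences the other", {
  # chain: each within lmax of the next only -> one group
  pos <- cbind(seq(10, 10 + 9 * 4, by = 4), rep(50, 10))
  st <- agent_state(pos, matrix(0, 10, 2), geo)
  ig <- interaction_graph(st, trait_set(0, 0, 5), p0)
  expect_equal(length(ig$sizes), 1)
  expect_equal(ig$sizes, 10L)
  # all isolated -> N singleton groups
  ig2 <- interaction_graph(st, trait_set(0, 0, 2), p0)
  expect_equal(length(ig2$sizes), 10)
  # asymmetric influence still creates the edge: k = 1, three agents in a
  # line; the middle agent's single slot is taken by its closer neighbour,
  # but the far agent still counts the middle one
  p1 <- social_params(k = 1)
  pos3 <- rbind(c(50, 50), c(51, 50), c(53, 50))
  st3 <- agent_state(pos3, matrix(0, 3, 2), geo)
  nb <- neighbor_sets(st3, trait_set(0, 0, 30), p1)
  expect_equal(nb[[3]], 2L)   # 3 counts 2
  expect_equal(nb[[2]], 1L)   # but 2 is saturated by 1
  ig3 <- interaction_graph(st3, trait_set(0, 0, 30), p1)
  expect_equal(length(ig3$sizes), 1)
})

test_that("stepping reports the offending agent on numerical blow-up", {
  st <- agent_state(matrix(50, 1, 2), matrix(c(1e200, 0), 1, 2), geo)
  expect_error(step(st, trait_set(1e300, 0, 30), social_params(gamma = 0),
                    NULL, n_steps = 5),
               "agent 1")
})
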