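test_that("WCA potential and force follow the truncated Lennard-Jones form", {
  rc <- 2^(1 / 6)
  expect_equal(wca_potential(1), 1)         # U(sigma) = epsilon
  expect_equal(wca_potential(rc), 0)        # zero at the minimum
  expect_equal(wca_potential(2), 0)         # zero beyond
  expect_equal(wca_force(c(rc, 0, 0)), c(0, 0, 0))
  expect_equal(wca_force(c(5, 0, 0)), c(0, 0, 0))
  f <- wca_force(c(0.99 * rc, 0, 0))
  expect_gt(f[1], 0)                        # repulsive, along +r_vec
  expect_equal(f[2:3], c(0, 0))
  # analytic magnitude at r = sigma: 24 epsilon / sigma
  expect_equal(wca_force(c(1, 0, 0))[1], 24)
  expect_warning(f0 <- wca_force(c(1e-4, 0, 0)), "clamped")
  expect_true(all(is.finite(f0)))
})

test_that("simulation parameters keep the bond rest length tied to sigma", {
  cfg <- sim_config(sigma = 2)
  expect_equal(cfg$bond_rest, 3)
  expect_error(sim_config(t_max = 1, record_every = 100, dt = 0.01),
               "fit window")
})

test_that("the recorded trace starts at the static entanglement of the input structure", {
  f <- make_fixture("cut_hopf_dimer", n_vertices = 30)
  d <- fixture_as_dimer(f)
  g0 <- gaussian_entanglement(d)
  cfg <- sim_config(t_max = 5, record_every = 20, dt = 0.001, n_traj = 2,
                    seed = 4)
  tr <- run_unbinding(d, cfg)
  expect_lt(abs(tr$g_prime_mean[1] - g0), 1e-9)
  expect_equal(tr$g_prime_sem[1], 0)  # identical initial condition
  expect_true(all(diff(tr$times) > 0))
})

test_that("pre-separated chains stay unentangled", {
  a <- ca_chain(helix_chain(20))
  b <- ca_chain(helix_chain(20, origin = c(500, 0, 0)))
  d <- dimer_structure(a, b)
  cfg <- sim_config(t_max = 10, record_every = 40, dt = 0.001, n_traj = 3,
                    seed = 8)
  tr <- run_unbinding(d, cfg)
  expect_true(all(abs(tr$g_prime_mean) < 0.05))
})

test_that("bonds hold their rest length under the chosen stiffness and step", {
  f <- make_fixture("cut_hopf_dimer", n_vertices = 30)
  d <- fixture_as_dimer(f)
  cfg <- sim_config(t_max = 25, record_every = 100, dt = 0.001, n_traj = 1,
                    seed = 5)
  tr <- run_unbinding(d, cfg)
  xa <- tr$final_coords[1:tr$n_beads_a, ]
  xb <- tr$final_coords[(tr$n_beads_a + 1):nrow(tr$final_coords), ]
  bl <- c(sqrt(rowSums(diff(xa)^2)), sqrt(rowSums(diff(xb)^2)))
  expect_true(all(abs(bl - cfg$bond_rest) / cfg$bond_rest < 0.2))
})

test_that("with interactions off each bead diffuses freely at the imposed temperature", {
  a <- ca_chain(helix_chain(15))
  b <- ca_chain(helix_chain(15, origin = c(50, 0, 0)))
  d <- dimer_structure(a, b)
  cfg <- sim_config(t_max = 10, record_every = 40, dt = 0.001,
                    n_traj = 100, seed = 21)
  tr <- run_unbinding(d, cfg, interactions = FALSE)
  # MSD = 6 (kT/gamma) t for overdamped free diffusion
  late <- tr$times >= 4
  rel <- tr$msd[late] / (6 * tr$times[late]) - 1
  expect_true(all(abs(rel) < 0.05))
})

test_that("exponential decay fit recovers planted parameters within bootstrap errors", {
  set.seed(77)
  times <- seq(0, 6000, by = 10)
  a_true <- -1.5
  tau_true <- 900
  signal <- a_true * exp(-times / tau_true)
  g_traj <- sapply(1:50, function(i) signal + rnorm(length(times), sd = 0.05))
  tr <- structure(list(times = times,
                       g_prime_mean = rowMeans(g_traj),
                       g_prime_sem = apply(g_traj, 1, sd) / sqrt(50),
                       g_traj = g_traj),
                  class = "entanglement_trace")
  fit <- fit_decay(tr, skip = 100, n_boot = 200)
  expect_lt(abs(fit$g_star - a_true), 3 * fit$g_star_err)
  expect_lt(abs(fit$tau - tau_true), 3 * fit$tau_err)
  expect_equal(fit$fit_start_index, 101L)
})

test_that("a flat zero trace is rejected rather than fitted", {
  times <- seq(0, 2000, by = 10)
  g_traj <- matrix(0, length(times), 5)
  tr <- structure(list(times = times, g_prime_mean = rep(0, length(times)),
                       g_prime_sem = rep(0, length(times)), g_traj = g_traj),
                  class = "entanglement_trace")
  expect_error(fit_decay(tr, skip = 10), "converge")
  expect_error(fit_decay(tr, skip = length(times)), "too short")
})

test_that("ensemble traces from two master seeds agree within errors", {
  f <- make_fixture("cut_hopf_dimer", n_vertices = 25)
  d <- fixture_as_dimer(f)
  run <- function(seed) {
    run_unbinding(d, sim_config(t_max = 60, record_every = 250, dt = 0.001,
                                n_traj = 15, seed = seed))
  }
  t1 <- run(100)
  t2 <- run(3100)
  comb <- sqrt(t1$g_prime_sem^2 + t2$g_prime_sem^2)
  diff_ok <- abs(t1$g_prime_mean - t2$g_prime_mean) <= pmax(3 * comb, 1e-9)
  expect_true(all(diff_ok))
})

test_that("the disentanglement time grows with chain length", {
  run_tau <- function(n_per_chain, t_max) {
    f <- make_fixture("cut_hopf_dimer", n_vertices = n_per_chain)
    d <- fixture_as_dimer(f)
    cfg <- sim_config(t_max = t_max, record_every = 250, dt = 0.001,
                      n_traj = 6, seed = 42)
    fit_decay(run_unbinding(d, cfg), skip = 100, n_boot = 100)
  }
  fit_small <- run_tau(50, 400)
  fit_large <- run_tau(200, 1200)
  # one-sided comparison at ~95% confidence from the bootstrap spreads
  gap <- fit_large$tau - fit_small$tau
  expect_gt(gap, 1.645 * sqrt(fit_small$tau_err^2 + fit_large$tau_err^2))
})
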