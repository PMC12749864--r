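# Statistical-mechanics checks of the Brownian integrator.  All runs use
# fixed seeds, so every assertion is deterministic.

test_that("a harmonic restraint equilibrates to variance kT/k", {
  flat <- channel_potential()
  cfg <- sim_config(n_ions = 1, n_steps = 1e6, save_stride = 50, seed = 42)
  ws <- simulate_umbrella_window(cfg, flat, umbrella_spec(10, 5))
  burn <- ws$z[-(1:1000)]
  expect_equal(mean(burn), 10, tolerance = 0.02)
  expect_equal(var(burn), kT310 / 5, tolerance = 0.05)
  # equipartition at k = 1 kcal/mol/A^2: var = kT/k = 0.616 A^2
  cfg1 <- sim_config(n_ions = 1, n_steps = 2e6, save_stride = 100,
                     diffusion = 0.3, seed = 42)
  ws1 <- simulate_umbrella_window(cfg1, flat, umbrella_spec(10, 1))
  expect_equal(var(ws1$z[-(1:1000)]), 0.616, tolerance = 0.05)
})

test_that("identical seeds give identical trajectories", {
  pot <- default_channel_potential()
  cfg <- sim_config(n_ions = 3, n_steps = 5000, save_stride = 10, seed = 7)
  t1 <- simulate_langevin(cfg, pot)
  t2 <- simulate_langevin(cfg, pot)
  expect_identical(t1$coords, t2$coords)
  expect_identical(t1$exit_log, t2$exit_log)
  t3 <- simulate_langevin(sim_config(n_ions = 3, n_steps = 5000,
                                     save_stride = 10, seed = 8), pot)
  expect_false(identical(t1$coords, t3$coords))
})

test_that("zero temperature gives gradient descent into the nearest minimum", {
  pot <- channel_potential(
    wells = data.frame(label = "C", center = 9, depth = 2, width = 1.5))
  cfg <- sim_config(n_ions = 1, temperature = 0, n_steps = 5e4,
                    save_stride = 1000, seed = 1)
  tr <- simulate_langevin(cfg, pot, init = matrix(c(0, 0, 11), 1))
  zend <- axial_coords(tr)[dim(tr$coords)[1], 1]
  expect_equal(unname(zend), 9, tolerance = 1e-3)
})

test_that("long unbiased runs reproduce the Boltzmann distribution", {
  pot <- channel_potential(
    wells = data.frame(label = "W", center = 6, depth = 1.2, width = 1.5))
  cfg <- sim_config(n_ions = 1, n_steps = 4e6, save_stride = 10,
                    diffusion = 0.3, box = c(30, 30, 12), z_bottom = 0,
                    pore_region = c(0, 12), bottom_wall = "reflect", seed = 3)
  tr <- simulate_langevin(cfg, pot, init = matrix(c(0, 0, 6), 1))
  h <- hist(axial_coords(tr), breaks = seq(0, 12, 0.4), plot = FALSE)
  keep <- h$counts >= 500
  Fh <- -kT310 * log(h$counts / sum(h$counts))
  d <- (Fh - single_ion_energy(pot, h$mids))[keep]
  d <- d - mean(d)
  expect_gt(sum(keep), 10)
  expect_lt(sqrt(mean(d^2)), 0.2)
})

test_that("a negative field drives ions inward and reversing it reverses the drift", {
  norep <- list(prefactor = 0, eps_r = 1, screening = 7.9)
  for (s in 1:3) {
    cfg <- sim_config(n_ions = 3, n_steps = 2e5, save_stride = 100, seed = s)
    init <- cbind(0, 0, c(10, 20, 30))
    drift <- sapply(c(-0.0577, 0.0577), function(f) {
      pot <- channel_potential(field = f, field_range = c(0, 40),
                               repulsion = norep)
      zu <- axial_coords(simulate_langevin(cfg, pot, init = init),
                         unwrapped = TRUE)
      mean(zu[nrow(zu), ] - zu[1, ])
    })
    expect_lt(drift[1], 0)
    expect_lt(drift[1], drift[2])
  }
})

test_that("umbrella windows obey the Gaussian closed forms", {
  flat <- channel_potential()
  cfg <- sim_config(n_ions = 1, n_steps = 1e5, save_stride = 20, seed = 9)
  # flat potential: mean at the center, variance kT/k
  ws <- simulate_umbrella_window(cfg, flat, umbrella_spec(10, 5))
  z <- ws$z[-(1:500)]
  expect_equal(mean(z), 10, tolerance = 0.005)
  expect_equal(var(z), kT310 / 5, tolerance = 0.05)
  # very stiff restraint pins the ion (stiffness demands a tiny timestep)
  wstiff <- simulate_umbrella_window(
    sim_config(n_ions = 1, n_steps = 2e4, save_stride = 10,
               timestep = 5e-5, seed = 9),
    flat, umbrella_spec(10, 1000))
  expect_true(all(abs(wstiff$z - 10) < 0.1))
  # linear potential of slope s shifts the mean by -s/k
  slope <- channel_potential(field = -0.2, field_range = c(0, 40))
  # U = +0.2 * z for a +1 charge, so slope s = +0.2
  wsl <- simulate_umbrella_window(cfg, slope, umbrella_spec(10, 5))
  expect_equal(mean(wsl$z[-(1:500)]), 10 - 0.2 / 5, tolerance = 0.002)
})

test_that("oversized steps abort with advice instead of silently diverging", {
  pot <- channel_potential(
    barriers = data.frame(label = "wall", center = 10, height = 1e4, width = 1))
  cfg <- sim_config(n_ions = 1, n_steps = 1000, save_stride = 10, seed = 2)
  expect_error(simulate_langevin(cfg, pot, init = matrix(c(0, 0, 9.5), 1)),
               "reduce the timestep")
})

test_that("pore fixtures have the stated analytic geometry", {
  cyl <- make_pore_fixture("cylinder", ring_radius = 5, vdw = 1.7)
  rfun <- attr(cyl, "analytic_radius")
  expect_equal(rfun(c(0, 7, 20)), rep(3.3, 3))
  hg <- make_pore_fixture("hourglass", ring_radius = 5, waist_radius = 3,
                          vdw = 1.7)
  expect_equal(attr(hg, "analytic_radius")(attr(hg, "waist_z")), 1.3)
  expect_error(make_pore_fixture("cylinder", ring_radius = 1, vdw = 1.7),
               "ring_radius > vdw")
})

test_that("hydration fixtures place oxygens at the exact requested distance", {
  for (case in list(c(6, 2.4), c(3, 3.1), c(13, 2.8))) {
    fx <- make_hydration_fixture(case[1], case[2])
    d <- sqrt(rowSums(fx$xyz^2))
    expect_equal(d, rep(case[2], case[1]), tolerance = 1e-9)
  }
  expect_equal(nrow(make_hydration_fixture(0, 2)$xyz), 0)
})
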