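test_that("axis unwrapping undoes wrap jumps and leaves clean series alone", {
  # ion stepping +1 A per frame across the top of a 60 A box
  z <- seq(-8, 60, by = 1)
  zw <- ((z + 10) %% 60) - 10          # wrapped into [-10, 50)
  tr <- traj_from_z(matrix(zw, ncol = 1))
  un <- unwrap_axis(tr)$z_unwrapped[, 1]
  expect_true(all(diff(un) > 0))
  expect_equal(diff(range(un)), diff(range(z)))
  # no jumps -> identity
  tr2 <- traj_from_z(matrix(seq(0, 20, length.out = 40), ncol = 1))
  expect_equal(unwrap_axis(tr2)$z_unwrapped[, 1], tr2$coords[, 1, 3])
  # random walks with wrapping match the generator's internal record
  pot <- channel_potential()
  cfg <- sim_config(n_ions = 4, n_steps = 5e4, save_stride = 10, seed = 13)
  sim <- simulate_langevin(cfg, pot)
  expect_equal(unwrap_axis(sim)$z_unwrapped, sim$z_unwrapped,
               tolerance = 1e-12)
})

test_that("scripted passages are counted exactly once", {
  # monotone descent 45 -> -10: one inward event
  tr <- traj_from_z(matrix(seq(45, -10, by = -1), ncol = 1))
  ev <- detect_permeations(tr, z_top = 40, z_bottom = -5)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$direction, "inward")
  expect_true(ev$t_exit > ev$t_enter)
  # oscillation inside the pore: no events
  osc <- traj_from_z(matrix(25 + 5 * sin(seq(0, 20 * pi, length.out = 400)),
                            ncol = 1))
  expect_equal(nrow(detect_permeations(osc)), 0L)
  # dithering across one boundary must not double-count
  dith <- traj_from_z(matrix(c(45, 30, 45, 30, -8, 30, 45), ncol = 1),
                      box = c(30, 30, 200))
  ev2 <- detect_permeations(dith)
  expect_equal(as.vector(table(ev2$direction)[c("inward", "outward")]),
               c(1L, 1L))
  expect_error(detect_permeations(tr, z_top = -5, z_bottom = 40), "exceed")
})

test_that("detector matches the brute-force oracle on random walks", {
  set.seed(101)
  n_match <- 0
  for (rep in 1:20) {
    nf <- 400; np <- 5
    z <- apply(matrix(rnorm(nf * np, sd = 4), nf, np), 2, cumsum) +
      matrix(rep(runif(np, -10, 50), each = nf), nf, np)
    z <- ((z + 10) %% 60) - 10   # wrap into the box
    tr <- traj_from_z(z)
    got <- detect_permeations(tr)
    want <- oracle_permeation(z, tr$times_ns, 40, -5, 60)
    expect_equal(nrow(got), nrow(want))
    if (nrow(got)) {
      expect_equal(got$ion_id, want$ion_id)
      expect_equal(got$t_exit, want$t_exit)
      expect_equal(got$t_enter, want$t_enter)
      expect_equal(got$direction, want$direction)
    }
    n_match <- n_match + 1
  }
  expect_equal(n_match, 20)
})

test_that("event bookkeeping balances the simulator's raw-exit log", {
  pot <- default_channel_potential(field = field_from_potential(-100, 40))
  for (s in c(5, 17)) {
    cfg <- sim_config(n_ions = 6, n_steps = 4e6, save_stride = 20, seed = s)
    tr <- simulate_langevin(cfg, pot)
    ev <- detect_permeations(tr)
    z <- axial_coords(tr)
    final_below <- sum(apply(z, 2, function(zz) {
      b <- zz[zz > 40 | zz < -5]
      length(b) > 0 && tail(b, 1) < -5
    }))
    start_below <- sum(z[1, ] < -5)
    expect_equal(sum(ev$direction == "inward") - sum(ev$direction == "outward"),
                 raw_exit_count(tr) + final_below - start_below)
  }
})

test_that("site occupancy matches a direct per-frame range check", {
  pot <- default_channel_potential()
  cfg <- sim_config(n_ions = 5, n_steps = 1e5, save_stride = 50, seed = 23)
  tr <- simulate_langevin(cfg, pot)
  occ <- site_occupancy(tr)
  z <- axial_coords(tr)
  for (s in default_sites()) {
    inside <- z >= s$z_range[1] & z < s$z_range[2]
    for (f in c(1, 50, nrow(z))) {
      expect_identical(occ$occupants[[s$label]][[f]], which(inside[f, ]))
    }
    expect_equal(occupancy_fraction(occ)[[s$label]],
                 mean(rowSums(inside) > 0))
  }
  # a parked ion occupies its site every frame
  parked <- traj_from_z(matrix(9, nrow = 20, ncol = 1))
  po <- site_occupancy(parked)
  expect_true(all(vapply(po$occupants$C, length, integer(1)) == 1))
  expect_true(all(lengths(po$occupants$A) == 0))
  expect_error(site_occupancy(tr, list(site_definition("X", c(0, 10)),
                                       site_definition("Y", c(5, 15)))),
               "overlap")
})

test_that("cooperativity scores hand-built hand-off scenarios correctly", {
  # ion 1 sits in C and leaves at frame 6 (event); ion 2 moves B -> C
  z <- cbind(c(45, 30, 9, 9, 9, -8, -8, -8, -8, -8),
             c(41, 19, 19, 19, 19, 19, 9, 9, 9, 9))
  tr <- traj_from_z(z, box = c(30, 30, 200))
  ev <- detect_permeations(tr)
  expect_equal(nrow(ev[ev$direction == "inward", ]), 1L)
  occ <- site_occupancy(tr)
  cf <- cooperativity_fraction(occ, ev, window = 3)
  expect_equal(as.numeric(cf), 1.0)
  # no hand-off: B stays put
  z2 <- cbind(c(45, 30, 9, 9, 9, -8, -8, -8, -8, -8),
              c(41, 19, 19, 19, 19, 19, 19, 19, 19, 19))
  tr2 <- traj_from_z(z2, box = c(30, 30, 200))
  cf2 <- cooperativity_fraction(site_occupancy(tr2),
                                detect_permeations(tr2), window = 3)
  expect_equal(as.numeric(cf2), 0.0)
  # no events -> flagged undefined, not zero
  cf3 <- cooperativity_fraction(occ, detect_permeations(traj_from_z(
    matrix(25, 10, 1))), window = 1)
  expect_true(is.na(cf3))
  expect_true(attr(cf3, "undefined"))
})

test_that("cooperativity matches direct enumeration on randomized occupancies", {
  set.seed(7)
  for (rep in 1:5) {
    nf <- 120
    # two ions wandering among sites with occasional passages
    z <- cbind(cumsum(rnorm(nf, -0.4, 3)) + 42,
               cumsum(rnorm(nf, -0.4, 3)) + 30)
    z <- pmax(pmin(z, 49), -9)
    tr <- traj_from_z(z)
    ev <- detect_permeations(tr)
    occ <- site_occupancy(tr)
    got <- cooperativity_fraction(occ, ev, window = 5)
    inw <- ev[ev$direction == "inward", , drop = FALSE]
    if (nrow(inw) == 0) { expect_true(is.na(got)); next }
    # direct enumeration with the documented definition
    hand <- 0
    for (e in seq_len(nrow(inw))) {
      ion <- inw$ion_id[e]
      relf <- NA
      for (f in seq_len(nf))
        if (tr$times_ns[f] <= inw$t_exit[e] && ion %in% occ$occupants$C[[f]])
          relf <- f
      if (is.na(relf)) next
      bprev <- NA
      for (f in seq_len(relf))
        if (length(occ$occupants$B[[f]])) bprev <- occ$occupants$B[[f]][1]
      if (is.na(bprev) || bprev == ion) next
      for (f in seq_len(nf))
        if (abs(tr$times_ns[f] - tr$times_ns[relf]) <= 5 &&
            bprev %in% occ$occupants$C[[f]]) { hand <- hand + 1; break }
    }
    expect_equal(as.numeric(got), hand / nrow(inw))
  }
})

test_that("detected counts feed conductance identically to hand computation", {
  pot <- default_channel_potential(field = field_from_potential(-100, 40))
  counts <- integer(2); durs <- numeric(2)
  for (i in 1:2) {
    cfg <- sim_config(n_ions = 6, n_steps = 2e6, save_stride = 50,
                      seed = 40 + i)
    tr <- simulate_langevin(cfg, pot)
    ev <- detect_permeations(tr)
    counts[i] <- sum(ev$direction == "inward")
    durs[i] <- max(tr$times_ns) - min(tr$times_ns)
  }
  g <- conductance_estimate(counts, durs, -100)
  expect_identical(g$per_run_pS,
                   counts * 1.602176634e-19 / (durs * 1e-9 * 0.1) * 1e12)
  expect_identical(g$mean_pS, mean(g$per_run_pS))
})
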