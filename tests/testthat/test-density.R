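test_that("stationary ions produce unit-integral point densities", {
  # one ion parked at a voxel center
  tr <- traj_from_z(matrix(10.25, nrow = 7, ncol = 1))
  g <- density_grid(tr, voxel_edge = 0.5,
                    bounds = rbind(c(-1, 1), c(-1, 1), c(9, 12)))
  expect_equal(density_integral(g), 1)
  expect_equal(max(g$density), 1 / 0.5^3)
  expect_equal(sum(g$density > 0), 1L)
  # N stationary ions integrate to N
  trN <- traj_from_z(matrix(rep(c(5, 15, 25), each = 4), nrow = 4))
  gN <- density_grid(trN, voxel_edge = 0.5,
                     bounds = rbind(c(-1, 1), c(-1, 1), c(0, 40)))
  expect_equal(density_integral(gN), 3)
  expect_error(density_grid(tr, selection = integer(0)), "empty")
})

test_that("density normalization holds on simulated runs at any stride", {
  pot <- default_channel_potential()
  cfg <- sim_config(n_ions = 5, n_steps = 5e4, save_stride = 25, seed = 77)
  tr <- simulate_langevin(cfg, pot)
  for (stride in c(1, 3)) {
    g <- density_grid(tr, selection = "NA", voxel_edge = 0.5,
                      bounds = rbind(c(-15, 15), c(-15, 15), c(-10, 50)),
                      stride = stride)
    z <- axial_coords(tr)[seq(1, n_frames(tr), by = stride), , drop = FALSE]
    expect_equal(density_integral(g), ncol(z), tolerance = 1e-9)
  }
})

test_that("uniform positions give Poisson-consistent voxel counts", {
  set.seed(19)
  n <- 1e5
  coords <- array(0, c(n, 1, 3))
  coords[, 1, ] <- cbind(runif(n, 0, 8), runif(n, 0, 8), runif(n, 0, 8))
  tr <- trajectory(coords, seq_len(n), "NA", c(30, 30, 60))
  g <- density_grid(tr, voxel_edge = 2, bounds = rbind(c(0, 8), c(0, 8), c(0, 8)))
  counts <- g$density * 2^3 * n
  expect_equal(sum(counts), n)
  p <- stats::chisq.test(as.vector(counts))$p.value
  expect_gt(p, 0.001)
})

test_that("blob segmentation finds the built components and centroids", {
  mk_grid <- function(dens) {
    structure(list(origin = c(0, 0, 0), voxel_edge = 1, density = dens,
                   n_frames = 1, selection = 1), class = "density_grid")
  }
  d <- array(0, c(15, 15, 15))
  for (i in 1:15) for (j in 1:15) for (k in 1:15)
    d[i, j, k] <- 0.02 * exp(-((i - 5)^2 + (j - 8)^2 + (k - 4)^2) / 4)
  g <- mk_grid(d)
  s <- find_binding_sites(g, threshold = 0.005)
  expect_equal(nrow(s), 1L)
  expect_equal(c(s$cx, s$cy, s$cz), c(4.5, 7.5, 3.5), tolerance = 0.3)
  expect_equal(s$peak_density, 0.02)
  # everything below threshold -> empty
  expect_equal(nrow(find_binding_sites(mk_grid(d * 0.1), 0.005)), 0L)
  # two blobs separated by a sub-threshold gap -> exactly two sites
  d2 <- array(0, c(20, 5, 5))
  d2[3:5, 2:4, 2:4] <- 0.01
  d2[12:14, 2:4, 2:4] <- 0.02
  s2 <- find_binding_sites(mk_grid(d2), 0.005)
  expect_equal(nrow(s2), 2L)
  expect_equal(s2$label[1], "S1")          # ranked by peak
  expect_gt(s2$peak_density[1], s2$peak_density[2])
  # traversal-order invariance: permuting via array flips preserves sites
  d3 <- d2[20:1, , , drop = FALSE]
  s3 <- find_binding_sites(mk_grid(d3), 0.005)
  expect_equal(nrow(s3), 2L)
  expect_equal(sort(20 + 1 - (s3$cx + 0.5) - 0.5), sort(s2$cx))
  expect_equal(s3$peak_density, s2$peak_density)
})

test_that("binding-site recovery locates the generator's wells", {
  pot <- default_channel_potential(field = field_from_potential(-100, 40))
  cfg <- sim_config(n_ions = 6, n_steps = 2e6, save_stride = 10, seed = 21)
  tr <- simulate_langevin(cfg, pot)
  grid <- density_grid(tr, selection = "NA", voxel_edge = 0.5,
                       bounds = rbind(c(-6, 6), c(-6, 6), c(0, 40)))
  sites <- find_binding_sites(grid, threshold = 0.005)
  expect_gte(nrow(sites), 3)
  top3 <- sort(sites$cz[1:3])
  ctr <- attr(pot, "well_centers")
  expect_lt(abs(top3[1] - ctr[["C"]]), 1)
  expect_lt(abs(top3[2] - ctr[["B"]]), 1)
  expect_lt(abs(top3[3] - ctr[["A"]]), 1)
  # B-C spacing ~10 A
  expect_equal(top3[2] - top3[1], 10, tolerance = 0.1)
})

test_that("coordination counts match fixtures and the all-pairs oracle", {
  expect_equal(coordination_count(c(0, 0, 0),
                                  make_hydration_fixture(6, 2.4), 3, "O"), 6L)
  expect_equal(coordination_count(c(0, 0, 0),
                                  make_hydration_fixture(6, 3.1), 3, "O"), 0L)
  set.seed(11)
  at <- atom_set(sample(c("O", "C"), 100, replace = TRUE),
                 matrix(runif(300, -5, 5), 100))
  for (cutoff in c(2, 3, 4.5)) {
    expect_equal(coordination_count(c(0.3, -0.2, 0.5), at, cutoff, "O"),
                 oracle_coordination(c(0.3, -0.2, 0.5), at, cutoff, "O"))
  }
  # monotone non-decreasing in the cutoff
  cuts <- seq(0.5, 8, by = 0.25)
  counts <- vapply(cuts, function(cc)
    coordination_count(c(0, 0, 0), at, cc), integer(1))
  expect_true(all(diff(counts) >= 0))
  # batch form averages per-frame counts
  pos <- rbind(c(0, 0, 0), c(10, 10, 10))
  b <- coordination_count(pos, at, 3, "O")
  expect_equal(b$mean, mean(b$per_frame))
  expect_equal(b$per_frame[1], coordination_count(c(0, 0, 0), at, 3, "O"))
})

test_that("RMSD vanishes for self and rigid moves, and matches closed form", {
  set.seed(2)
  ref <- matrix(rnorm(30), 10, 3)
  nf <- 3
  coords <- array(0, c(nf, 10, 3))
  coords[1, , ] <- ref
  coords[2, , ] <- ref + matrix(rep(c(3, -2, 5), each = 10), 10)  # translation
  disp <- ref; disp[4, ] <- disp[4, ] + c(3, 0, 0)                # one atom 3 A
  coords[3, , ] <- disp
  tr <- trajectory(coords, 1:nf, rep("C", 10), c(50, 50, 50))
  r <- rmsd_series(tr, reference = 1)
  expect_equal(r[1], 0)
  expect_equal(r[3], sqrt(9 / 10), tolerance = 1e-9)
  rs <- rmsd_series(tr, reference = 1, superpose = TRUE)
  expect_lt(rs[2], 1e-9)
  expect_error(rmsd_series(tr, reference = matrix(0, 4, 3)), "counts differ")
})
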