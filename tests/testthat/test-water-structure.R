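test_that("occupancy histograms agree with scripted counts", {
  # scripted occupancy sequence 7, 8, 7, 8 inside a 20 A channel
  nf <- 4; n_w <- 8
  z <- matrix(15, nf, n_w)                       # all parked outside
  for (f in 1:nf) {
    k <- c(7, 8, 7, 8)[f]
    z[f, seq_len(k)] <- seq(-9, 9, length.out = k)
  }
  tr <- scripted_water_traj(z, L = 20)
  occ <- occupancy_histogram(tr, bnd_channel())
  s <- occ$summary[occ$summary$monomer == "M1", ]
  expect_equal(s$mean, 7.5)
  expect_equal(s$sd, stats::sd(c(7, 8, 7, 8)))
  h <- occ$histogram
  expect_equal(sum(h$n_frames_at), nf)
  expect_equal(h$n_frames_at[h$occupancy == 7], 2L)

  # empty channel every frame
  occ0 <- occupancy_histogram(scripted_water_traj(matrix(15, 3, 2)), bnd_channel())
  expect_equal(occ0$summary$mean[1], 0)
  expect_equal(occ0$summary$sd[1], 0)
})

test_that("the water dipole is the HOH bisector and rotates equivariantly", {
  topo <- water_topology(1)
  coords <- matrix(0, 5, 3)
  coords[2, ] <- c(0.76, 0.59, 0)
  coords[3, ] <- c(-0.76, 0.59, 0)
  coords[4, 3] <- -10; coords[5, 3] <- 10
  tr <- trajectory(topo, coords)
  expect_equal(water_dipole(tr, 1, 1, 2, 3), c(0, 1, 0), tolerance = 1e-12)

  # both hydrogens along +z
  c2 <- coords
  c2[2, ] <- c(0.3, 0, 0.9); c2[3, ] <- c(-0.3, 0, 0.9)
  tr2 <- trajectory(topo, c2)
  expect_equal(water_dipole(tr2, 1, 1, 2, 3), c(0, 0, 1), tolerance = 1e-12)

  # rotation equivariance
  th <- 0.7
  R <- rbind(c(cos(th), 0, sin(th)), c(0, 1, 0), c(-sin(th), 0, cos(th)))
  c3 <- coords; c3[1:3, ] <- coords[1:3, ] %*% t(R)
  tr3 <- trajectory(topo, c3)
  expect_equal(water_dipole(tr3, 1, 1, 2, 3),
               as.numeric(R %*% water_dipole(tr, 1, 1, 2, 3)),
               tolerance = 1e-12)

  # coincident atoms are an error
  c4 <- coords; c4[2, ] <- 0; c4[3, ] <- 0
  expect_error(water_dipole(trajectory(topo, c4), 1, 1, 2, 3), "degenerate")
})

test_that("order parameters hit their exact aligned and perpendicular limits", {
  al <- make_oriented_waters(200, "aligned+z", seed = 2)
  p <- order_parameters(al$trajectory, al$channel_def)
  expect_true(all(abs(p$P1 - 1) < 1e-10))
  expect_true(all(abs(p$P2 - 1) < 1e-10))

  am <- make_oriented_waters(200, "aligned-z", seed = 2)
  pm <- order_parameters(am$trajectory, am$channel_def)
  expect_true(all(abs(pm$P1 + 1) < 1e-10))
  expect_true(all(abs(pm$P2 - 1) < 1e-10))

  pp <- make_oriented_waters(200, "perpendicular", seed = 2)
  ppr <- order_parameters(pp$trajectory, pp$channel_def)
  expect_true(all(abs(ppr$P1) < 1e-10))
  expect_true(all(abs(ppr$P2 + 0.5) < 1e-10))
})

test_that("isotropic dipoles average to zero order parameters", {
  iso <- make_oriented_waters(1e5, "isotropic", seed = 4)
  p <- order_parameters(iso$trajectory, iso$channel_def, bin_width = 20)
  # one fat bin holding all 1e5 samples
  big <- p[p$n_samples == max(p$n_samples), ][1, ]
  expect_lt(abs(big$P1), 0.01)
  expect_lt(abs(big$P2), 0.01)
})

test_that("order parameters stay in their admissible ranges and flip correctly", {
  for (seed in 1:3) {
    mix <- make_oriented_waters(500, "isotropic", seed = seed)
    p <- order_parameters(mix$trajectory, mix$channel_def)
    expect_true(all(p$P1 >= -1 - 1e-12 & p$P1 <= 1 + 1e-12))
    expect_true(all(p$P2 >= -0.5 - 1e-12 & p$P2 <= 1 + 1e-12))
  }
  # flipping every dipole negates P1 and leaves P2 unchanged
  mix <- make_oriented_waters(300, "bipolar", seed = 6)
  p <- order_parameters(mix$trajectory, mix$channel_def)
  tr2 <- mix$trajectory
  ow <- water_oxygen_indices(tr2)
  for (o in ow) {   # mirror H positions through the oxygen
    for (h in o + 1:2) {
      tr2$coords[1, h, ] <- 2 * tr2$coords[1, o, ] - tr2$coords[1, h, ]
    }
  }
  p2 <- order_parameters(tr2, mix$channel_def)
  expect_equal(p2$P1, -p$P1, tolerance = 1e-10)
  expect_equal(p2$P2, p$P2, tolerance = 1e-10)
})

test_that("the bipolar fixture shows a P1 sign change and P2 minimum at z0", {
  bp <- make_oriented_waters(5000, "bipolar", z0 = 0, seed = 10)
  p <- order_parameters(bp$trajectory, bp$channel_def, bin_width = 1)
  p <- p[order(p$z), ]
  below <- p[p$z < -2, ]; above <- p[p$z > 2, ]
  expect_true(all(below$P1 > 0))
  expect_true(all(above$P1 < 0))
  # sign change bracketed at the configured midplane
  expect_lt(abs(p$z[which.min(abs(p$P1))]), 1.5)
  expect_lt(abs(p$z[which.min(p$P2)]), 1.5)
  expect_lt(min(p$P2), 0)
})

test_that("charge-weighted and geometric dipoles coincide for rigid waters", {
  bp <- make_oriented_waters(100, "bipolar", seed = 11)
  pg <- order_parameters(bp$trajectory, bp$channel_def)
  pc <- order_parameters(bp$trajectory, bp$channel_def,
                         charges = c(-0.834, 0.417, 0.417))
  expect_equal(pc$P1, pg$P1, tolerance = 1e-8)
  expect_equal(pc$P2, pg$P2, tolerance = 1e-8)
})
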