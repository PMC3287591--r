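ring_wall <- function(traj) select_atoms(traj, "resname RNG")

test_that("a regular atom ring has the analytic maximal sphere", {
  tr <- make_cylinder_pore(ring_radius = 5, vdw = 1.5, length = 20,
                           n_rings = 1, atoms_per_ring = 12)
  res <- pore_radius_at(tr, 1, ring_wall(tr), axis_point = c(0, 0, 0),
                        axis = c(0, 0, 1))
  expect_equal(res$radius, 3.5, tolerance = 0.01)
  expect_equal(res$center, c(0, 0, 0), tolerance = 0.05)
  expect_false(res$occluded)

  # an offset starting point converges to the same optimum
  res2 <- pore_radius_at(tr, 1, ring_wall(tr), axis_point = c(1, 0, 0),
                         axis = c(0, 0, 1))
  expect_equal(res2$radius, 3.5, tolerance = 0.01)
  expect_equal(res2$center[1:2], c(0, 0), tolerance = 0.05)
})

test_that("the optimizer matches a dense brute-force grid on random clouds", {
  for (seed in 1:3) {
    set.seed(seed)
    n <- 40
    ang <- runif(n, 0, 2 * pi)
    rad <- runif(n, 3, 6)
    atoms <- cbind(rad * cos(ang), rad * sin(ang), runif(n, -2, 2))
    vdw <- runif(n, 1.2, 1.8)
    topo <- tibble::tibble(name = "C", element = "C", resname = "RNG",
                           resno = seq_len(n), chain = "A", vdw = vdw)
    tr <- trajectory(topo, atoms)
    res <- pore_radius_at(tr, 1, seq_len(n), c(0, 0, 0), c(0, 0, 1),
                          search_radius = 4)
    # brute force on a 0.05 A grid
    g <- seq(-4, 4, by = 0.05)
    best <- -Inf
    for (gx in g) for (gy in g) {
      if (gx * gx + gy * gy > 16) next
      d <- min(sqrt((atoms[, 1] - gx)^2 + (atoms[, 2] - gy)^2 + atoms[, 3]^2) - vdw)
      if (d > best) best <- d
    }
    expect_equal(res$clearance, best, tolerance = 0.05)
    expect_gte(res$clearance, best - 0.05)
  }
})

test_that("a perfect cylinder profiles flat at the analytic radius", {
  tr <- make_cylinder_pore(ring_radius = 5, vdw = 1.5, length = 20,
                           n_rings = 41, atoms_per_ring = 12)
  cd <- bnd_channel()
  prof <- radius_profile(tr, cd, protein_atoms = ring_wall(tr),
                         z_range = c(-8, 8), z_step = 1)
  expect_true(all(abs(prof$r_mean - 3.5) < 0.05))
  expect_true(all(prof$r_sd == 0))
  expect_equal(attr(prof, "min_radius"), min(prof$r_mean))
})

test_that("a tapering pore follows the analytic linear profile", {
  tr <- make_cylinder_pore(ring_radius = 6, vdw = 1.5, length = 20,
                           n_rings = 81, atoms_per_ring = 16, taper_to = 3)
  prof <- radius_profile(tr, bnd_channel(), protein_atoms = ring_wall(tr),
                         z_range = c(-6, 6), z_step = 2)
  analytic <- (6 + (3 - 6) * (prof$z + 10) / 20) - 1.5
  expect_equal(prof$r_mean, analytic, tolerance = 0.08)
  # narrowest point sits at the narrow end of the sampled range
  expect_equal(attr(prof, "min_z"), 6)
})

test_that("frame averaging yields the mean and SD across frames", {
  tr <- make_cylinder_pore(ring_radius = c(4.5, 5.5), vdw = 1.5, length = 20,
                           n_rings = 21, atoms_per_ring = 12)
  prof <- radius_profile(tr, bnd_channel(), protein_atoms = ring_wall(tr),
                         z_range = c(-4, 4), z_step = 2)
  expect_true(all(abs(prof$r_mean - 3.5) < 0.05))
  expect_true(all(abs(prof$r_sd - stats::sd(c(3, 4))) < 0.05))
})

test_that("inflating every vdW radius deflates the pore by the same amount", {
  tr <- make_cylinder_pore(ring_radius = 5, vdw = 1.5, length = 20,
                           n_rings = 11, atoms_per_ring = 12)
  r1 <- pore_radius_at(tr, 1, ring_wall(tr), c(0, 0, 0), c(0, 0, 1))$radius
  tr$topology$vdw[ring_wall(tr)] <- 1.5 + 0.3
  r2 <- pore_radius_at(tr, 1, ring_wall(tr), c(0, 0, 0), c(0, 0, 1))$radius
  expect_equal(r1 - r2, 0.3, tolerance = 0.02)
})

test_that("an occluded plane reports zero radius with a flag", {
  # one fat atom sitting on the axis blocks the pore
  topo <- tibble::tibble(name = "C", element = "C", resname = "RNG",
                         resno = 1L, chain = "A", vdw = 3)
  tr <- trajectory(topo, matrix(c(0, 0, 0), 1, 3))
  res <- pore_radius_at(tr, 1, 1L, c(0, 0, 0), c(0, 0, 1), search_radius = 1)
  expect_true(res$occluded)
  expect_equal(res$radius, 0)
  expect_lt(res$clearance, 0)
})

test_that("the profile is invariant under a rigid rotation of frame and axis", {
  tr <- make_cylinder_pore(ring_radius = 5, vdw = 1.5, length = 20,
                           n_rings = 21, atoms_per_ring = 12)
  base <- pore_radius_at(tr, 1, ring_wall(tr), c(0, 0, 2), c(0, 0, 1))$radius
  th <- 0.6
  R <- rbind(c(1, 0, 0), c(0, cos(th), -sin(th)), c(0, sin(th), cos(th)))
  tr2 <- tr
  tr2$coords[1, , ] <- tr$coords[1, , ] %*% t(R)
  ax2 <- as.numeric(R %*% c(0, 0, 1))
  pt2 <- as.numeric(R %*% c(0, 0, 2))
  rot <- pore_radius_at(tr2, 1, ring_wall(tr2), pt2, ax2)$radius
  expect_equal(rot, base, tolerance = 0.02)
})
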