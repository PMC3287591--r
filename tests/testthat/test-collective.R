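test_that("collective coordinate accumulates axial displacement over L", {
  # one water translating exactly L along +z while inside: n goes 0 -> 1
  L <- 20
  z <- matrix(seq(-9.99, 9.99, length.out = 50), ncol = 1)
  tr <- scripted_water_traj(z, L = L)
  cc <- collective_coordinate(tr, bnd_channel(), L = L)
  expect_equal(cc$n[1], 0)
  expect_equal(utils::tail(cc$n, 1), (9.99 - (-9.99)) / L, tolerance = 1e-10)

  # static frames: n identically zero
  zs <- matrix(rep(c(-3, 0, 3), each = 10), 10, 3)
  ccs <- collective_coordinate(scripted_water_traj(zs), bnd_channel(), L = 20)
  expect_true(all(ccs$n == 0))
})

test_that("multi-water displacements match an independent cumulative oracle", {
  set.seed(31)
  nf <- 60; n_w <- 5; L <- 20
  z <- matrix(runif(n_w, -8, 8), nf, n_w, byrow = TRUE) +
    apply(matrix(rnorm(nf * n_w, 0, 0.4), nf, n_w), 2, cumsum)
  tr <- scripted_water_traj(z, L = L)
  for (rule in c("clipped", "both_frames")) {
    cc <- collective_coordinate(tr, bnd_channel(), L = L, contribution = rule)
    # oracle: direct per-pair loop over waters
    n_or <- 0
    series <- 0
    for (f in 2:nf) {
      dn <- 0
      for (w in seq_len(n_w)) {
        i1 <- z[f - 1, w] >= -10 && z[f - 1, w] < 10
        i2 <- z[f, w] >= -10 && z[f, w] < 10
        if (rule == "both_frames") {
          if (i1 && i2) dn <- dn + (z[f, w] - z[f - 1, w])
        } else {
          if (i1 || i2) {
            c1 <- min(max(z[f - 1, w], -10), 10)
            c2 <- min(max(z[f, w], -10), 10)
            dn <- dn + (c2 - c1)
          }
        }
      }
      n_or <- n_or + dn / L
      series <- c(series, n_or)
    }
    expect_equal(cc$n, series, tolerance = 1e-12)
  }
})

test_that("multi-origin MSD has closed forms for drift and constants", {
  # pure drift n = c t: msd(tau) = c^2 tau^2 from every origin
  ct <- tibble::tibble(time = seq(0, 2000, by = 2), n = 0.003 * seq(0, 2000, by = 2))
  m <- msd_multi_origin(ct, window_length = 100, origin_stride = 100)
  expect_equal(m$msd, (0.003 * m$lag)^2, tolerance = 1e-12)
  # constant series: msd identically zero
  cs <- tibble::tibble(time = seq(0, 2000, by = 2), n = 1.5)
  expect_true(all(msd_multi_origin(cs, 100)$msd == 0))
  # 20 ns at 2 ps with 100-ps non-overlapping windows: exactly 200 origins
  long <- tibble::tibble(time = seq(0, 20000, by = 2), n = 0)
  m200 <- msd_multi_origin(long, window_length = 100, origin_stride = 100)
  expect_equal(unique(m200$n_origins), 200)
  # explicit two-origin average equals the hand-computed mean of the two
  # squared window displacements
  set.seed(8)
  short <- tibble::tibble(time = seq(0, 200, 2), n = cumsum(rnorm(101)))
  m2 <- msd_multi_origin(short, window_length = 100, origin_stride = 100)
  tau50 <- m2$msd[m2$lag == 100]
  by_hand <- mean(c((short$n[51] - short$n[1])^2, (short$n[101] - short$n[51])^2))
  expect_equal(tau50, by_hand, tolerance = 1e-12)
})

test_that("MSD with too few origins or an oversized window errors", {
  s <- tibble::tibble(time = seq(0, 100, 2), n = 0)
  expect_error(msd_multi_origin(s, window_length = 200), "exceeds")
  expect_error(msd_multi_origin(s, window_length = 90, origin_stride = 500),
               "origins")
})

test_that("D_n fitting halves the slope and clamps negative slopes", {
  lag <- seq(0, 100, 2)
  m <- tibble::tibble(monomer = "M1", lag = lag, msd = 2 * 3.0e-3 * lag)
  f <- fit_Dn(m)   # slope in ps^-1; D_n reported in ns^-1
  expect_equal(f$result$D_n, 3.0, tolerance = 1e-10)
  expect_equal(tidy(f)$D_n, f$result$D_n)
  expect_equal(glance(f)$D_n_mean, 3.0, tolerance = 1e-10)

  m0 <- tibble::tibble(monomer = "M1", lag = lag, msd = 0)
  expect_equal(fit_Dn(m0)$result$D_n, 0)

  mneg <- tibble::tibble(monomer = "M1", lag = lag, msd = -2e-3 * lag)
  expect_warning(fneg <- fit_Dn(mneg), "clamped")
  expect_equal(fneg$result$D_n, 0)

  expect_error(fit_Dn(m, fit_range = c(98, 99)), "fewer than 2")
})

test_that("fit_Dn recovers a known random walk within sampling error", {
  set.seed(77)
  D_true <- 2.0                      # ns^-1
  dt <- 2                            # ps
  nt <- 10001                        # 20 ns
  n <- cumsum(c(0, rnorm(nt - 1, 0, sqrt(2 * D_true * 1e-3 * dt))))
  s <- tibble::tibble(time = (0:(nt - 1)) * dt, n = n)
  m <- msd_multi_origin(s, window_length = 100, origin_stride = 100)
  f <- fit_Dn(m)
  expect_equal(unique(m$n_origins), 200)
  expect_lt(abs(f$result$D_n - D_true) / D_true, 0.2)
})

test_that("p_f estimation is symmetric under time reversal", {
  # with an origin at every frame the squared window displacements form the
  # same multiset forwards and backwards up to O(window/span) edge windows,
  # so D_n agrees to well under a percent
  sim <- simulate_single_file(n_monomers = 1, n_frames = 10000, seed = 13)
  cc <- collective_coordinate(sim$trajectory, sim$channel_def)
  fwd <- fit_Dn(msd_multi_origin(cc, 100, origin_stride = 2))$result$D_n
  rev_tr <- trajectory(sim$trajectory$topology,
                       sim$trajectory$coords[n_frames(sim$trajectory):1, , ,
                                             drop = FALSE],
                       frame_interval = sim$trajectory$frame_interval)
  ccr <- collective_coordinate(rev_tr, sim$channel_def)
  bwd <- fit_Dn(msd_multi_origin(ccr, 100, origin_stride = 2))$result$D_n
  expect_equal(bwd, fwd, tolerance = 0.005)
})

test_that("osmotic permeability and the single-fileness ratio compose", {
  expect_equal(osmotic_permeability(0), 0)
  expect_equal(osmotic_permeability(1), 2.99e-14)
  # inversion of the printed tetramer p_f through the same relation
  expect_equal(osmotic_permeability(6.4e-14 / 2.99e-14), 6.4e-14)
  expect_equal(osmotic_permeability(2.14), 6.4e-14, tolerance = 0.002)

  # per-monomer quotients as printed in the summary table
  expect_equal(round(pf_pd_ratio(6.4, 0.7), 1), 9.1)
  expect_equal(round(pf_pd_ratio(8.3, 2.8), 1), 3.0)
  expect_equal(pf_pd_ratio(5, 5), 1)
  expect_warning(r0 <- pf_pd_ratio(1, 0), "NA")
  expect_true(is.na(r0))
})

test_that("membrane-to-single-channel conversion scales with density", {
  # P_f in cm/s against unit density: p_f equals P_f numerically
  expect_equal(single_channel_from_membrane_permeability(1e4, 1), 1)
  # doubling the density halves p_f
  p1 <- single_channel_from_membrane_permeability(57, 8e13)
  p2 <- single_channel_from_membrane_permeability(57, 1.6e14)
  expect_equal(p1 / p2, 2)
  # algebraic inversion of the reported experimental estimate
  dens <- 57e-4 / 0.7e-14
  expect_equal(single_channel_from_membrane_permeability(57, dens), 0.7e-14)
})
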