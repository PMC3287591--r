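# Synthetic single-file channel trajectories with known transport parameters,
# plus geometric fixtures for the pore-radius and orientation estimators.
#
# Kinetics are the concerted continuous-time random walk of a single-file
# water column: the whole file of n_sites waters shifts one site up or down
# at rate K = hop_rate / n_sites per direction (the collective mobility of a
# single file scales inversely with its length), the leading water leaving to
# the reservoir and a reservoir water entering at the trailing site. A
# water-water interchange channel runs on top: every adjacent pair, including
# the two channel-mouth pairs (boundary water <-> reservoir water), exchanges
# identities at rate hop_rate * interchange_prob. Interchanges move two waters
# in opposite directions, so they change the diffusive permeability without
# touching the collective coordinate; the analytic ground truth is
# p_f/p_d = (n_sites + 1) / (1 + interchange_prob * n_sites).
# Kinetics are exact event-driven (Gillespie) and subsampled onto the frame
# grid, so the dynamics do not depend on the frame interval.

.with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Simulate a single-file water channel
#'
#' Event-driven concerted hopping of a tracked single-file water column with
#' reservoirs, embedded in 3D with transverse jitter and a bipolar dipole
#' field (dipoles rotate from +z below the midplane through perpendicular at
#' the midplane to -z above it). For `interchange_prob = 0` the
#' continuous-time random-walk prediction \eqn{p_f/p_d = n_{sites} + 1}
#' holds; `interchange_prob = 1` drives the ratio to 1 (the
#' independent-particle value); in general the expected ratio is
#' \eqn{(N+1)/(1+pN)}.
#'
#' @param n_sites Number of single-file sites (default 7, the typical
#'   aquaporin constriction-region occupancy).
#' @param site_spacing Site spacing in Angstrom (default 2.8, a water-water
#'   hydrogen-bond distance); the channel length is `n_sites * site_spacing`.
#' @param hop_rate Per-water hop attempt rate in ns^-1 (default 25); the
#'   concerted file shift proceeds at `hop_rate / n_sites` per direction, so
#'   the default reproduces a permeation rate constant
#'   \eqn{k_0 = hop\_rate/(N(N+1))} of about 0.45 ns^-1, the scale reported
#'   for aquaporins.
#' @param interchange_prob Probability that a hop attempt into an occupied
#'   position succeeds as an identity swap (default 0 = strict single file).
#' @param n_monomers Number of independent channels laid out on a lateral
#'   grid (default 1).
#' @param n_frames Number of emitted frames.
#' @param frame_interval Frame spacing in ps (default 2).
#' @param n_reservoir Waters parked in each reservoir pool per monomer
#'   (default 8); pools are FIFO, refilled from the opposite pool if drained.
#' @param reservoir_depth Axial depth of the reservoir parking zone, Angstrom.
#' @param jitter Transverse positional jitter SD in Angstrom (default 0.3).
#' @param seed Mandatory RNG seed; echoed in the output.
#' @return A list of class `aq_sfsim`:
#'   `trajectory` (an `aq_trajectory`), `channel_def` (an `aq_channeldef`),
#'   `events` (exact log of completed traversals: `water` = oxygen atom
#'   index, `monomer`, `t_entry`, `t_exit`, `direction`), and `ground_truth`
#'   (list with `n_sites`, `L`, `occupancy`, measured `k0`/`p_d` from the
#'   exact event log, `expected_k0`, `expected_D_n`, `expected_pf_pd`,
#'   `seed`, `config`).
#' @export
simulate_single_file <- function(n_sites = 7, site_spacing = 2.8, hop_rate = 25,
                                 interchange_prob = 0, n_monomers = 1,
                                 n_frames = 1000, frame_interval = 2,
                                 n_reservoir = 8, reservoir_depth = 6,
                                 jitter = 0.3, seed) {
  if (missing(seed)) abort("seed is mandatory")
  stopifnot(n_sites >= 1, site_spacing > 0, hop_rate >= 0,
            interchange_prob >= 0, interchange_prob <= 1, n_monomers >= 1,
            n_frames >= 2, frame_interval > 0)
  .with_seed(seed, {
    L <- n_sites * site_spacing
    z_bot <- -L / 2; z_top <- L / 2
    site_z <- z_bot + (seq_len(n_sites) - 0.5) * site_spacing
    t_frames <- (seq_len(n_frames) - 1) * frame_interval
    T_end <- t_frames[n_frames]
    K <- hop_rate / n_sites / 1000          # concerted shift rate, ps^-1
    ksw <- hop_rate * interchange_prob / 1000   # swap rate per adjacent pair
    n_pairs <- n_sites - 1
    grid <- cbind(rep(0:1, length.out = n_monomers) * 25,
                  (ceiling(seq_len(n_monomers) / 2) - 1) * 25)
    chains <- LETTERS[seq_len(n_monomers)]
    nw_per <- n_sites + 2 * n_reservoir
    nw_tot <- nw_per * n_monomers

    cap <- 4096L
    mv_t <- numeric(cap); mv_pid <- integer(cap); mv_z <- numeric(cap)
    n_mv <- 0L
    rec_move <- function(t, pid, z) {
      n_mv <<- n_mv + 1L
      if (n_mv > length(mv_t)) {
        mv_t <<- c(mv_t, numeric(length(mv_t)))
        mv_pid <<- c(mv_pid, integer(length(mv_pid)))
        mv_z <<- c(mv_z, numeric(length(mv_z)))
      }
      mv_t[n_mv] <<- t; mv_pid[n_mv] <<- pid; mv_z[n_mv] <<- z
    }
    ev_list <- vector("list", n_monomers)
    z0 <- numeric(nw_tot)

    park_z <- function(side) {
      if (side == "top") z_top + 1.5 + runif(1) * reservoir_depth
      else z_bot - 1.5 - runif(1) * reservoir_depth
    }

    for (m in seq_len(n_monomers)) {
      pid0 <- (m - 1L) * nw_per
      pids <- pid0 + seq_len(nw_per)
      occ <- pids[seq_len(n_sites)]                     # file, bottom to top
      bot_pool <- pids[n_sites + seq_len(n_reservoir)]
      top_pool <- pids[n_sites + n_reservoir + seq_len(n_reservoir)]
      entered_from <- integer(pid0 + nw_per)   # 0 unknown, 1 bottom, 2 top
      entry_t <- numeric(pid0 + nw_per)
      z0[occ] <- site_z
      for (p in bot_pool) z0[p] <- park_z("bottom")
      for (p in top_pool) z0[p] <- park_z("top")

      ev_w <- integer(64); ev_en <- numeric(64); ev_ex <- numeric(64)
      ev_dir <- character(64); n_ev <- 0L
      log_exit <- function(p, t, side) {       # side: 1 bottom, 2 top
        if (entered_from[p] != 0L && entered_from[p] != side) {
          n_ev <<- n_ev + 1L
          if (n_ev > length(ev_w)) {
            ev_w <<- c(ev_w, integer(length(ev_w)))
            ev_en <<- c(ev_en, numeric(length(ev_en)))
            ev_ex <<- c(ev_ex, numeric(length(ev_ex)))
            ev_dir <<- c(ev_dir, character(length(ev_dir)))
          }
          ev_w[n_ev] <<- p; ev_en[n_ev] <<- entry_t[p]; ev_ex[n_ev] <<- t
          ev_dir[n_ev] <<- if (side == 2L) "+z" else "-z"
        }
        entered_from[p] <<- 0L
      }
      take_pool <- function(side, t) {   # FIFO
        if (side == 1L) { p <- bot_pool[1]; bot_pool <<- bot_pool[-1] }
        else { p <- top_pool[1]; top_pool <<- top_pool[-1] }
        p
      }
      # keep the reservoirs balanced: recycle the longest-parked water of the
      # fuller pool to the BACK of the other queue (it rests there before any
      # re-insertion, so entry sides stay unambiguous at frame resolution)
      rebalance <- function(t) {
        while (length(top_pool) - length(bot_pool) > 2L) {
          p <- top_pool[1]; top_pool <<- top_pool[-1]
          bot_pool <<- c(bot_pool, p)
          rec_move(t + 1e-9, p, park_z("bottom"))
        }
        while (length(bot_pool) - length(top_pool) > 2L) {
          p <- bot_pool[1]; bot_pool <<- bot_pool[-1]
          top_pool <<- c(top_pool, p)
          rec_move(t + 1e-9, p, park_z("top"))
        }
      }

      # rates: shift up K, shift down K, interior swaps (n_sites-1) * ksw,
      # mouth swaps 2 * ksw
      rate <- 2 * K + (n_pairs + 2) * ksw
      t <- 0
      if (rate > 0) repeat {
        t <- t + rexp(1, rate)
        if (t > T_end) break
        u <- runif(1) * rate
        if (u < K) {                       # shift up (+z)
          out <- occ[n_sites]
          log_exit(out, t, 2L)
          top_pool <- c(top_pool, out)
          rec_move(t, out, park_z("top"))
          newp <- take_pool(1L, t)
          occ <- c(newp, occ[-n_sites])
          entered_from[newp] <- 1L; entry_t[newp] <- t
          for (s in seq_len(n_sites)) rec_move(t, occ[s], site_z[s])
        } else if (u < 2 * K) {            # shift down (-z)
          out <- occ[1]
          log_exit(out, t, 1L)
          bot_pool <- c(bot_pool, out)
          rec_move(t, out, park_z("bottom"))
          newp <- take_pool(2L, t)
          occ <- c(occ[-1], newp)
          entered_from[newp] <- 2L; entry_t[newp] <- t
          for (s in seq_len(n_sites)) rec_move(t, occ[s], site_z[s])
        } else {                           # an interchange
          j <- floor((u - 2 * K) / ksw) + 1   # 1..n_pairs interior, then mouths
          if (j <= n_pairs) {              # swap file neighbours j, j+1
            a <- occ[j]; b <- occ[j + 1L]
            occ[j] <- b; occ[j + 1L] <- a
            rec_move(t, a, site_z[j + 1L]); rec_move(t, b, site_z[j])
          } else if (j == n_pairs + 1L) {  # bottom mouth swap
            out <- occ[1]
            log_exit(out, t, 1L)
            newp <- take_pool(1L, t)
            bot_pool <- c(bot_pool, out)
            rec_move(t, out, park_z("bottom"))
            occ[1] <- newp
            entered_from[newp] <- 1L; entry_t[newp] <- t
            rec_move(t, newp, site_z[1])
          } else {                         # top mouth swap
            out <- occ[n_sites]
            log_exit(out, t, 2L)
            newp <- take_pool(2L, t)
            top_pool <- c(top_pool, out)
            rec_move(t, out, park_z("top"))
            occ[n_sites] <- newp
            entered_from[newp] <- 2L; entry_t[newp] <- t
            rec_move(t, newp, site_z[n_sites])
          }
        }
        rebalance(t)
      }
      ev_list[[m]] <- if (n_ev == 0) {
        tibble::tibble(water = integer(), monomer = character(),
                       t_entry = numeric(), t_exit = numeric(),
                       direction = character())
      } else {
        tibble::tibble(water = ev_w[seq_len(n_ev)], monomer = paste0("M", m),
                       t_entry = ev_en[seq_len(n_ev)],
                       t_exit = ev_ex[seq_len(n_ev)],
                       direction = ev_dir[seq_len(n_ev)])
      }
    }

    # ---- reconstruct frame-sampled z per particle -------------------------
    zmat <- matrix(NA_real_, n_frames, nw_tot)
    mv_t <- mv_t[seq_len(n_mv)]; mv_pid <- mv_pid[seq_len(n_mv)]
    mv_z <- mv_z[seq_len(n_mv)]
    ord <- order(mv_pid, mv_t)
    sp <- split(ord, mv_pid[ord])
    for (p in seq_len(nw_tot)) {
      key <- as.character(p)
      if (!is.null(sp[[key]])) {
        tt <- c(0, mv_t[sp[[key]]]); zz <- c(z0[p], mv_z[sp[[key]]])
      } else { tt <- 0; zz <- z0[p] }
      zmat[, p] <- zz[findInterval(t_frames, tt)]
    }

    # ---- build topology and coordinates -----------------------------------
    # per monomer: 2 boundary atoms then waters (OW, HW1, HW2)
    topo_list <- vector("list", n_monomers)
    for (m in seq_len(n_monomers)) {
      wat_res <- seq_len(nw_per)
      topo_list[[m]] <- tibble::tibble(
        name = c("O", "O", rep(c("OW", "HW1", "HW2"), nw_per)),
        element = c("O", "O", rep(c("O", "H", "H"), nw_per)),
        resname = c("CYS", "GLY", rep("HOH", 3 * nw_per)),
        resno = c(79L, 195L, rep(wat_res + 200L, each = 3)),
        chain = chains[m]
      )
    }
    topo <- dplyr::bind_rows(topo_list)
    n_at_per <- 2 + 3 * nw_per
    coords <- array(NA_real_, c(n_frames, nrow(topo), 3))
    d_oh <- 0.9572; half_ang <- 52.26 * pi / 180
    for (m in seq_len(n_monomers)) {
      off <- (m - 1L) * n_at_per
      cx <- grid[m, 1]; cy <- grid[m, 2]
      coords[, off + 1, ] <- matrix(c(cx, cy, z_bot), n_frames, 3, byrow = TRUE)
      coords[, off + 2, ] <- matrix(c(cx, cy, z_top), n_frames, 3, byrow = TRUE)
      pids <- (m - 1L) * nw_per + seq_len(nw_per)
      base_x <- cx + runif(nw_per, -0.8, 0.8)
      base_y <- cy + runif(nw_per, -0.8, 0.8)
      for (w in seq_len(nw_per)) {
        p <- pids[w]
        zo <- zmat[, p]
        xo <- base_x[w] + rnorm(n_frames, 0, jitter)
        yo <- base_y[w] + rnorm(n_frames, 0, jitter)
        # bipolar dipole field: uz = -z / (L/2), clipped
        uz <- pmin(1, pmax(-1, -zo / (L / 2)))
        phi <- runif(1, 0, 2 * pi)
        ur <- sqrt(pmax(0, 1 - uz^2))
        d <- cbind(ur * cos(phi), ur * sin(phi), uz)
        u <- matrix(c(-sin(phi), cos(phi), 0), n_frames, 3, byrow = TRUE)
        oc <- cbind(xo, yo, zo)
        h1 <- oc + d_oh * (cos(half_ang) * d + sin(half_ang) * u)
        h2 <- oc + d_oh * (cos(half_ang) * d - sin(half_ang) * u)
        ia <- off + 2 + (w - 1L) * 3
        coords[, ia + 1, ] <- oc
        coords[, ia + 2, ] <- h1
        coords[, ia + 3, ] <- h2
      }
    }
    traj <- trajectory(topo, coords, frame_interval = frame_interval)
    cd <- channel_definition(
      monomer = paste0("M", seq_len(n_monomers)),
      top_selector = paste0("name O & resname GLY & resno 195 & chain ", chains),
      bottom_selector = paste0("name O & resname CYS & resno 79 & chain ", chains),
      lateral_cutoff = 8
    )
    events <- dplyr::bind_rows(ev_list)
    events <- dplyr::arrange(events, .data$t_exit)
    if (nrow(events) > 0) {
      mono_of <- (events$water - 1L) %/% nw_per
      wi <- (events$water - 1L) %% nw_per
      events$water <- mono_of * n_at_per + 2L + wi * 3L + 1L
    }
    t_ns <- T_end / 1000
    k0 <- rate_constant(nrow(events), n_monomers, max(t_ns, 1e-12))
    K_ns <- hop_rate / n_sites
    gt <- list(
      n_sites = n_sites, L = L, occupancy = n_sites,
      k0 = k0, p_d = diffusive_permeability(k0),
      expected_k0 = (K_ns + hop_rate * interchange_prob) / (n_sites + 1),
      expected_D_n = K_ns,
      expected_pf_pd = (n_sites + 1) / (1 + interchange_prob * n_sites),
      seed = seed,
      config = list(n_sites = n_sites, site_spacing = site_spacing,
                    hop_rate = hop_rate, interchange_prob = interchange_prob,
                    n_monomers = n_monomers, n_frames = n_frames,
                    frame_interval = frame_interval, n_reservoir = n_reservoir,
                    reservoir_depth = reservoir_depth, jitter = jitter)
    )
    structure(list(trajectory = traj, channel_def = cd, events = events,
                   ground_truth = gt),
              class = "aq_sfsim")
  })
}

#' @export
print.aq_sfsim <- function(x, ...) {
  gt <- x$ground_truth
  cat(sprintf("<aq_sfsim> %d site(s) x %d monomer(s), %d frames; %d logged traversals, k0 = %.3g ns^-1\n",
              gt$n_sites, gt$config$n_monomers, n_frames(x$trajectory),
              nrow(x$events), gt$k0))
  invisible(x)
}

#' Stacked-ring cylinder pore fixture
#'
#' A protein-like fixture of rings of atoms around the z axis whose analytic
#' pore radius is `ring_radius - vdw` at every z (or linearly tapering when
#' `taper_to` is given). Two zero-size boundary marker atoms (resname `BND`)
#' sit on the axis at the channel ends; exclude them from the wall-atom set
#' when profiling (`select_atoms(traj, "resname RNG")`).
#'
#' @param ring_radius Ring radius in Angstrom (scalar, or one per frame).
#' @param vdw Wall atom vdW radius in Angstrom.
#' @param length Channel length in Angstrom (rings span z in +-length/2).
#' @param n_rings Number of rings.
#' @param atoms_per_ring Atoms per ring.
#' @param taper_to If given, the ring radius varies linearly from
#'   `ring_radius` at the bottom to `taper_to` at the top.
#' @return An `aq_trajectory`; ring atoms have resname `RNG`.
#' @export
make_cylinder_pore <- function(ring_radius = 5, vdw = 1.5, length = 20,
                               n_rings = 41, atoms_per_ring = 12,
                               taper_to = NULL) {
  stopifnot(all(ring_radius > vdw), n_rings >= 1, atoms_per_ring >= 3)
  zs <- if (n_rings == 1) 0 else seq(-length / 2, length / 2, length.out = n_rings)
  ang <- (seq_len(atoms_per_ring) - 1) * 2 * pi / atoms_per_ring
  n_frames <- base::length(ring_radius)
  na <- n_rings * atoms_per_ring
  coords <- array(NA_real_, c(n_frames, na + 2, 3))
  for (f in seq_len(n_frames)) {
    r_bot <- ring_radius[f]
    rr <- if (is.null(taper_to)) rep(r_bot, n_rings) else {
      if (n_rings == 1) r_bot else seq(r_bot, taper_to, length.out = n_rings)
    }
    xyz <- do.call(rbind, lapply(seq_len(n_rings), function(i) {
      cbind(rr[i] * cos(ang), rr[i] * sin(ang), zs[i])
    }))
    coords[f, , ] <- rbind(xyz, c(0, 0, -length / 2), c(0, 0, length / 2))
  }
  topo <- tibble::tibble(
    name = c(rep("C", na), "O", "O"),
    element = c(rep("C", na), "O", "O"),
    resname = c(rep("RNG", na), "BND", "BND"),
    resno = c(rep(seq_len(n_rings), each = atoms_per_ring), 1L, 2L),
    chain = "A",
    vdw = c(rep(vdw[1], na), 0.01, 0.01)
  )
  trajectory(topo, coords)
}

#' Oriented-water fixtures for the order-parameter estimator
#'
#' Waters spread along the channel axis with a prescribed dipole field.
#'
#' @param n Number of waters.
#' @param orientation One of `"aligned+z"`, `"aligned-z"`, `"perpendicular"`,
#'   `"isotropic"`, `"bipolar"`.
#' @param z0 Midplane of the bipolar field (Angstrom; default 0 = channel
#'   center).
#' @param length Channel length in Angstrom.
#' @param seed RNG seed (used for positions and random orientations).
#' @return A list: `trajectory` (single frame, waters plus two `BND` axis
#'   markers delimiting the channel) and `channel_def`.
#' @export
make_oriented_waters <- function(n, orientation = c("aligned+z", "aligned-z",
                                                    "perpendicular", "isotropic",
                                                    "bipolar"),
                                 z0 = 0, length = 20, seed = 1) {
  orientation <- match.arg(orientation)
  .with_seed(seed, {
    zb <- -length / 2; zt <- length / 2
    zo <- runif(n, zb + 0.05, zt - 0.05)
    xo <- runif(n, -1, 1); yo <- runif(n, -1, 1)
    phi <- runif(n, 0, 2 * pi)
    d <- switch(orientation,
      "aligned+z" = cbind(0, 0, rep(1, n)),
      "aligned-z" = cbind(0, 0, rep(-1, n)),
      "perpendicular" = cbind(cos(phi), sin(phi), 0),
      "isotropic" = {
        uz <- runif(n, -1, 1); ur <- sqrt(1 - uz^2)
        cbind(ur * cos(phi), ur * sin(phi), uz)
      },
      "bipolar" = {
        uz <- pmin(1, pmax(-1, -(zo - z0) / (length / 4)))
        ur <- sqrt(pmax(0, 1 - uz^2))
        cbind(ur * cos(phi), ur * sin(phi), uz)
      })
    # unit vector perpendicular to d for the H plane
    ref <- cbind(ifelse(abs(d[, 1]) < 0.9, 1, 0), ifelse(abs(d[, 1]) < 0.9, 0, 1), 0)
    u <- cbind(d[, 2] * ref[, 3] - d[, 3] * ref[, 2],
               d[, 3] * ref[, 1] - d[, 1] * ref[, 3],
               d[, 1] * ref[, 2] - d[, 2] * ref[, 1])
    u <- u / sqrt(rowSums(u^2))
    d_oh <- 0.9572; half_ang <- 52.26 * pi / 180
    oc <- cbind(xo, yo, zo)
    h1 <- oc + d_oh * (cos(half_ang) * d + sin(half_ang) * u)
    h2 <- oc + d_oh * (cos(half_ang) * d - sin(half_ang) * u)
    na <- 3 * n + 2
    coords <- matrix(NA_real_, na, 3)
    for (i in seq_len(n)) {
      coords[(i - 1) * 3 + 1, ] <- oc[i, ]
      coords[(i - 1) * 3 + 2, ] <- h1[i, ]
      coords[(i - 1) * 3 + 3, ] <- h2[i, ]
    }
    coords[3 * n + 1, ] <- c(0, 0, zb)
    coords[3 * n + 2, ] <- c(0, 0, zt)
    topo <- tibble::tibble(
      name = c(rep(c("OW", "HW1", "HW2"), n), "O", "O"),
      element = c(rep(c("O", "H", "H"), n), "O", "O"),
      resname = c(rep("HOH", 3 * n), "BND", "BND"),
      resno = c(rep(seq_len(n), each = 3), 1L, 2L),
      chain = "A"
    )
    traj <- trajectory(topo, coords)
    cd <- channel_definition("M1",
                             top_selector = "resname BND & resno 2",
                             bottom_selector = "resname BND & resno 1",
                             lateral_cutoff = 8)
    list(trajectory = traj, channel_def = cd)
  })
}
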