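# Channel geometry: per-monomer axis, constriction region (CR) boundaries,
# channel length and per-frame water membership.

#' Define one or more monomer channels
#'
#' A channel is described by two boundary atoms (one selection each, resolving
#' to exactly one atom) that delimit the constriction region along the channel
#' axis, plus the axis itself and a lateral membership cutoff. The default
#' axis is the membrane normal (z of the simulation cell).
#'
#' @param monomer Character vector of monomer labels (e.g. `c("M1","M2")`).
#' @param top_selector,bottom_selector Selection strings (one per monomer, or
#'   one recycled) resolving to single atoms; `top` is the boundary with the
#'   larger axial coordinate.
#' @param axis Unit 3-vector of the channel axis (recycled across monomers);
#'   normalized internally.
#' @param anchor Optional 3-vector (or list of them) giving a point on the
#'   axis; defaults to the midpoint of the two boundary atoms, recomputed per
#'   frame.
#' @param lateral_cutoff Maximum radial distance (Angstrom) from the axis for a
#'   water to count as inside; default 8.
#' @param fixed_z Optional numeric `c(z_bottom, z_top)`: use this fixed axial
#'   window instead of the instantaneous boundary-atom positions (useful to
#'   reproduce fixed-window occupancy/radius conventions).
#' @return A tibble of class `aq_channeldef`, one row per monomer.
#' @export
channel_definition <- function(monomer, top_selector, bottom_selector,
                               axis = c(0, 0, 1), anchor = NULL,
                               lateral_cutoff = 8, fixed_z = NULL) {
  n <- length(monomer)
  axis <- axis / sqrt(sum(axis^2))
  if (!is.null(fixed_z)) stopifnot(length(fixed_z) == 2, fixed_z[1] < fixed_z[2])
  out <- tibble::tibble(
    monomer = as.character(monomer),
    top_selector = rep_len(top_selector, n),
    bottom_selector = rep_len(bottom_selector, n),
    axis = rep(list(axis), n),
    anchor = if (is.null(anchor)) rep(list(NULL), n) else {
      if (is.numeric(anchor)) rep(list(anchor), n) else anchor
    },
    lateral_cutoff = rep_len(lateral_cutoff, n),
    fixed_z = rep(list(fixed_z), n)
  )
  class(out) <- c("aq_channeldef", class(out))
  out
}

# Resolve boundary atom indices for every monomer; errors if a selector does
# not match exactly one atom.
.resolve_boundaries <- function(traj, channel_def) {
  res <- lapply(seq_len(nrow(channel_def)), function(i) {
    top <- select_atoms(traj, channel_def$top_selector[i])
    bot <- select_atoms(traj, channel_def$bottom_selector[i])
    if (length(top) != 1 || length(bot) != 1) {
      abort(sprintf("monomer %s: boundary selectors must match exactly one atom (matched %d and %d)",
                    channel_def$monomer[i], length(top), length(bot)))
    }
    c(top = top, bottom = bot)
  })
  do.call(rbind, res)
}

# axial coordinate of points relative to the monomer axis; pts is n x 3
.axial <- function(pts, axis) drop(pts %*% axis)

# per-frame axial window [z_bottom, z_top] for each monomer
# returns list(z_bottom, z_top) of n_frames x n_monomers matrices
.channel_windows <- function(traj, channel_def, bounds = NULL) {
  if (is.null(bounds)) bounds <- .resolve_boundaries(traj, channel_def)
  nf <- n_frames(traj)
  nm <- nrow(channel_def)
  zb <- zt <- matrix(NA_real_, nf, nm)
  for (i in seq_len(nm)) {
    ax <- channel_def$axis[[i]]
    if (!is.null(channel_def$fixed_z[[i]])) {
      zb[, i] <- channel_def$fixed_z[[i]][1]
      zt[, i] <- channel_def$fixed_z[[i]][2]
    } else {
      z1 <- .axial(traj$coords[, bounds[i, "top"], , drop = TRUE], ax)
      z2 <- .axial(traj$coords[, bounds[i, "bottom"], , drop = TRUE], ax)
      if (nf == 1) { z1 <- sum(traj$coords[1, bounds[i, "top"], ] * ax)
                     z2 <- sum(traj$coords[1, bounds[i, "bottom"], ] * ax) }
      zb[, i] <- pmin(z1, z2)
      zt[, i] <- pmax(z1, z2)
    }
  }
  list(z_bottom = zb, z_top = zt)
}

#' Constriction-region channel length
#'
#' The channel length L-bar of each monomer is the time-averaged Euclidean
#' distance between its two boundary atoms; the aggregate row is the
#' arithmetic mean and sample SD of the per-monomer means.
#'
#' @param traj An `aq_trajectory`.
#' @param channel_def An `aq_channeldef`.
#' @return A tibble with one row per monomer plus an `"aggregate"` row and
#'   columns `monomer`, `L_mean` (Angstrom), `L_sd`, `n_frames`.
#' @export
channel_length <- function(traj, channel_def) {
  bounds <- .resolve_boundaries(traj, channel_def)
  per <- purrr::map_dfr(seq_len(nrow(channel_def)), function(i) {
    d <- sqrt(rowSums((traj$coords[, bounds[i, "top"], , drop = FALSE] -
                       traj$coords[, bounds[i, "bottom"], , drop = FALSE])^2,
                      dims = 1))
    d <- as.numeric(d)
    tibble::tibble(monomer = channel_def$monomer[i], L_mean = mean(d),
                   L_sd = stats::sd(d), n_frames = length(d))
  })
  agg <- summarize_monomers(per$L_mean)
  dplyr::bind_rows(per, tibble::tibble(monomer = "aggregate", L_mean = agg$mean,
                                       L_sd = agg$sd, n_frames = per$n_frames[1]))
}

#' Waters inside each monomer's constriction region (one frame)
#'
#' A water oxygen is inside monomer m when its axial coordinate lies in
#' `[z_bottom, z_top)` (half-open, so a value exactly at the top boundary is
#' outside) and its radial distance from m's axis is at most the lateral
#' cutoff. A water satisfying this for several monomers is assigned to the one
#' whose axis is nearest.
#'
#' @param traj An `aq_trajectory`.
#' @param frame Frame number.
#' @param channel_def An `aq_channeldef`.
#' @param water_oxygens Integer atom indices of the water oxygens.
#' @return Named list (by monomer) of integer vectors of atom indices.
#' @export
waters_in_channel <- function(traj, frame, channel_def, water_oxygens) {
  memb <- .membership_array(traj, channel_def, water_oxygens,
                            frames = frame)$inside
  out <- lapply(seq_len(nrow(channel_def)),
                function(i) water_oxygens[memb[1, , i]])
  names(out) <- channel_def$monomer
  out
}

# Core membership computation, vectorized over frames.
# Returns list(inside = nf x nw x nm logical array,
#              z = nf x nw x nm axial coordinates,
#              z_bottom, z_top = nf x nm matrices)
.membership_array <- function(traj, channel_def, water_oxygens,
                              frames = seq_len(n_frames(traj)), bounds = NULL) {
  if (is.null(bounds)) bounds <- .resolve_boundaries(traj, channel_def)
  sub <- traj$coords[frames, , , drop = FALSE]
  nf <- length(frames)
  nw <- length(water_oxygens)
  nm <- nrow(channel_def)
  win <- .channel_windows(traj, channel_def, bounds)
  zb <- win$z_bottom[frames, , drop = FALSE]
  zt <- win$z_top[frames, , drop = FALSE]
  inside <- array(FALSE, c(nf, nw, nm))
  zarr <- array(NA_real_, c(nf, nw, nm))
  r2arr <- array(NA_real_, c(nf, nw, nm))
  for (i in seq_len(nm)) {
    ax <- channel_def$axis[[i]]
    w <- sub[, water_oxygens, , drop = FALSE]
    zw <- w[, , 1] * ax[1] + w[, , 2] * ax[2] + w[, , 3] * ax[3]
    zw <- matrix(zw, nf, nw)
    # axis anchor: configured, or per-frame midpoint of the boundary atoms
    if (!is.null(channel_def$anchor[[i]])) {
      anch <- matrix(channel_def$anchor[[i]], nf, 3, byrow = TRUE)
    } else {
      anch <- (sub[, rep(bounds[i, "top"], 1), , drop = TRUE] +
               sub[, rep(bounds[i, "bottom"], 1), , drop = TRUE]) / 2
      anch <- matrix(anch, nf, 3)
    }
    # radial distance from the axis line through anchor along ax
    r2 <- matrix(0, nf, nw)
    proj <- matrix(0, nf, nw)
    for (k in 1:3) proj <- proj + (w[, , k] - anch[, k]) * ax[k]
    for (k in 1:3) r2 <- r2 + (matrix(w[, , k], nf, nw) - anch[, k] - proj * ax[k])^2
    zarr[, , i] <- zw
    r2arr[, , i] <- r2
    inside[, , i] <- (zw >= zb[, i]) & (zw < zt[, i]) &
      (r2 <= channel_def$lateral_cutoff[i]^2)
  }
  # ties: a water inside several monomers goes to the nearest axis
  if (nm > 1) {
    multi <- rowSums(inside, dims = 2) > 1
    if (any(multi)) {
      idx <- which(multi, arr.ind = TRUE)
      for (r in seq_len(nrow(idx))) {
        f <- idx[r, 1]; wv <- idx[r, 2]
        cand <- which(inside[f, wv, ])
        keep <- cand[which.min(r2arr[f, wv, cand])]
        inside[f, wv, ] <- FALSE
        inside[f, wv, keep] <- TRUE
      }
    }
  }
  list(inside = inside, z = zarr, z_bottom = zb, z_top = zt)
}

#' Water oxygen indices of a trajectory
#'
#' Convenience selector for water oxygens (name `OW`, or name `O` in residues
#' `HOH`/`WAT`/`SOL`/`TIP3`).
#' @param traj An `aq_trajectory`.
#' @return Integer atom indices.
#' @export
water_oxygen_indices <- function(traj) {
  topo <- traj$topology
  which(topo$name == "OW" |
          (topo$name == "O" & topo$resname %in% c("HOH", "WAT", "SOL", "TIP3")))
}
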