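# HOLE-style pore radius: at each axial station, the largest sphere centered
# in the perpendicular plane that touches no atom's vdW sphere. The objective
# f(c) = min_i(|c - x_i| - R_i) is maximized over in-plane centers c with a
# deterministic multi-start compass (pattern) search.

# objective at in-plane offset (u, v) around origin o with plane basis (e1, e2)
.pore_objective <- function(uv, o, e1, e2, atoms, radii) {
  c3 <- o + uv[1] * e1 + uv[2] * e2
  d <- sqrt((atoms[, 1] - c3[1])^2 + (atoms[, 2] - c3[2])^2 +
              (atoms[, 3] - c3[3])^2)
  min(d - radii)
}

# deterministic compass search from one start
.compass_max <- function(start, f, step0 = 1, tol = 0.005, max_iter = 400) {
  x <- start
  fx <- f(x)
  step <- step0
  dirs <- rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1),
                c(1, 1), c(1, -1), c(-1, 1), c(-1, -1) ) / c(1, 1, 1, 1, sqrt(2), sqrt(2), sqrt(2), sqrt(2))
  it <- 0
  while (step > tol && it < max_iter) {
    it <- it + 1
    improved <- FALSE
    for (k in seq_len(nrow(dirs))) {
      cand <- x + step * dirs[k, ]
      fc <- f(cand)
      if (fc > fx + 1e-12) { x <- cand; fx <- fc; improved <- TRUE; break }
    }
    if (!improved) step <- step / 2
  }
  list(x = x, value = fx)
}

#' Pore radius at one axial station
#'
#' Maximizes the clearance to the nearest van der Waals surface over sphere
#' centers constrained to the plane through `axis_point` perpendicular to
#' `axis`. A negative optimum means the plane is occluded: the radius is
#' reported as 0 with `occluded = TRUE`.
#'
#' @param traj An `aq_trajectory`.
#' @param frame Frame number.
#' @param protein_atoms Atom indices forming the pore wall.
#' @param axis_point 3-vector on the channel axis (Angstrom).
#' @param axis Unit 3-vector of the channel axis.
#' @param search_radius In-plane search range around `axis_point` (Angstrom).
#' @param starts Optional matrix of in-plane (u, v) start offsets; defaults to
#'   the origin plus a ring of 6 starts at half the search radius.
#' @return A list: `radius` (Angstrom, >= 0), `center` (3-vector), `clearance`
#'   (the unclamped optimum, negative if occluded), `occluded`.
#' @export
pore_radius_at <- function(traj, frame, protein_atoms, axis_point, axis,
                           search_radius = 5, starts = NULL) {
  axis <- axis / sqrt(sum(axis^2))
  m <- frame_coords(traj, frame)[protein_atoms, , drop = FALSE]
  radii <- traj$topology$vdw[protein_atoms]
  # drop atoms too far from the plane to ever matter
  dist_plane <- abs(drop((sweep(m, 2, axis_point) %*% axis)))
  keep <- (dist_plane - radii) <= search_radius + 10
  if (!any(keep)) abort("no atoms within search range of the plane")
  m <- m[keep, , drop = FALSE]; radii <- radii[keep]
  # in-plane orthonormal basis
  ref <- if (abs(axis[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * axis) * axis; e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(axis[2] * e1[3] - axis[3] * e1[2],
          axis[3] * e1[1] - axis[1] * e1[3],
          axis[1] * e1[2] - axis[2] * e1[1])
  f <- function(uv) {
    if (sqrt(sum(uv^2)) > search_radius) return(-Inf)
    .pore_objective(uv, axis_point, e1, e2, m, radii)
  }
  if (is.null(starts)) {
    ang <- (0:5) * pi / 3
    starts <- rbind(c(0, 0), cbind(cos(ang), sin(ang)) * search_radius / 2)
  }
  best <- NULL
  for (s in seq_len(nrow(starts))) {
    res <- .compass_max(starts[s, ], f)
    if (is.null(best) || res$value > best$value) best <- res
  }
  center <- axis_point + best$x[1] * e1 + best$x[2] * e2
  list(radius = max(0, best$value), center = center,
       clearance = best$value, occluded = best$value < 0)
}

#' Pore radius profile along the channel axis
#'
#' Marches along the axis in `z_step` increments over `z_range`, seeding each
#' station's search at the previous station's optimal center, and averages
#' across frames.
#'
#' @param traj An `aq_trajectory`.
#' @param channel_def A single-monomer `aq_channeldef` row (or the monomer to
#'   use via `monomer=`); the profile is computed along its axis, with z
#'   measured from the channel midpoint.
#' @param protein_atoms Atom indices of the pore wall; defaults to all
#'   non-water atoms.
#' @param z_range Numeric `c(zmin, zmax)` relative to the channel midpoint;
#'   defaults to the constriction-region interval of the first frame.
#' @param z_step Axial grid step in Angstrom (default 0.5).
#' @param frame_stride Analyze every `frame_stride`-th frame (default 1).
#' @param search_radius In-plane search range (Angstrom).
#' @param monomer Which monomer row of `channel_def` to use (default first).
#' @return A tibble of class `aq_radiusprofile`: `z`, `r_mean`, `r_sd`,
#'   `n_frames`, `occluded_frac`; attributes `min_radius` and `min_z`.
#' @export
radius_profile <- function(traj, channel_def, protein_atoms = NULL,
                           z_range = NULL, z_step = 0.5, frame_stride = 1,
                           search_radius = 5, monomer = channel_def$monomer[1]) {
  cd <- channel_def[channel_def$monomer == monomer, ]
  stopifnot(nrow(cd) == 1)
  if (is.null(protein_atoms)) {
    w <- water_oxygen_indices(traj)
    wres <- traj$topology$resname %in% c("HOH", "WAT", "SOL", "TIP3")
    protein_atoms <- which(!wres)
  }
  ax <- cd$axis[[1]]
  bounds <- .resolve_boundaries(traj, cd)
  win <- .channel_windows(traj, cd, bounds)
  frames <- seq(1, n_frames(traj), by = frame_stride)
  if (is.null(z_range)) {
    z_range <- c(win$z_bottom[1, 1], win$z_top[1, 1]) -
      (win$z_bottom[1, 1] + win$z_top[1, 1]) / 2
  }
  zgrid <- seq(z_range[1], z_range[2], by = z_step)
  rmat <- matrix(NA_real_, length(frames), length(zgrid))
  occl <- matrix(FALSE, length(frames), length(zgrid))
  for (fi in seq_along(frames)) {
    f <- frames[fi]
    mid <- (win$z_bottom[f, 1] + win$z_top[f, 1]) / 2
    # anchor: configured, or boundary-atom midpoint projected on the axis
    if (!is.null(cd$anchor[[1]])) {
      anch <- cd$anchor[[1]]
    } else {
      anch <- (frame_coords(traj, f)[bounds[1, "top"], ] +
                 frame_coords(traj, f)[bounds[1, "bottom"], ]) / 2
    }
    base <- anch - drop(sum(anch * ax)) * ax   # in-plane part of the anchor
    prev_center <- NULL
    for (zi in seq_along(zgrid)) {
      pt <- base + (mid + zgrid[zi]) * ax
      starts <- if (is.null(prev_center)) NULL else {
        rbind(prev_center, c(0, 0),
              cbind(cos((0:3) * pi / 2), sin((0:3) * pi / 2)) * 0.5 + rep(prev_center, each = 4))
      }
      res <- pore_radius_at(traj, f, protein_atoms, pt, ax,
                            search_radius = search_radius, starts = starts)
      rmat[fi, zi] <- res$radius
      occl[fi, zi] <- res$occluded
      # previous center expressed in (u, v): recompute offset in plane basis
      off <- res$center - pt
      ref <- if (abs(ax[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
      e1 <- ref - sum(ref * ax) * ax; e1 <- e1 / sqrt(sum(e1^2))
      e2 <- c(ax[2] * e1[3] - ax[3] * e1[2], ax[3] * e1[1] - ax[1] * e1[3],
              ax[1] * e1[2] - ax[2] * e1[1])
      prev_center <- c(sum(off * e1), sum(off * e2))
    }
  }
  out <- tibble::tibble(
    z = zgrid,
    r_mean = colMeans(rmat),
    r_sd = if (length(frames) > 1) apply(rmat, 2, stats::sd) else rep(0, length(zgrid)),
    n_frames = length(frames),
    occluded_frac = colMeans(occl)
  )
  class(out) <- c("aq_radiusprofile", class(out))
  attr(out, "min_radius") <- min(out$r_mean)
  attr(out, "min_z") <- out$z[which.min(out$r_mean)]
  out
}
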