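# Channel water occupancy and z-resolved dipole order parameters
# P1(z) = <cos theta>, P2(z) = <(3 cos^2 theta - 1)/2>, where theta is the
# angle between the water dipole and the channel axis.

#' Channel occupancy histogram
#'
#' Counts the waters inside each monomer's constriction region frame by frame.
#'
#' @param traj An `aq_trajectory`.
#' @param channel_def An `aq_channeldef`.
#' @param water_oxygens Water oxygen atom indices.
#' @return A list with `histogram` (tibble: `monomer`, `occupancy`,
#'   `n_frames_at`) and `summary` (tibble: per-monomer and `"aggregate"` rows
#'   of `mean`, `sd`, `n_frames`; the aggregate is the mean and sample SD of
#'   the per-monomer means).
#' @export
occupancy_histogram <- function(traj, channel_def,
                                water_oxygens = water_oxygen_indices(traj)) {
  memb <- .membership_array(traj, channel_def, water_oxygens)
  nm <- nrow(channel_def)
  counts <- vapply(seq_len(nm),
                   function(i) rowSums(matrix(memb$inside[, , i],
                                              n_frames(traj))),
                   numeric(n_frames(traj)))
  counts <- matrix(counts, n_frames(traj), nm)
  hist <- purrr::map_dfr(seq_len(nrow(channel_def)), function(i) {
    tb <- table(counts[, i])
    tibble::tibble(monomer = channel_def$monomer[i],
                   occupancy = as.integer(names(tb)),
                   n_frames_at = as.integer(tb))
  })
  per <- purrr::map_dfr(seq_len(nrow(channel_def)), function(i) {
    tibble::tibble(monomer = channel_def$monomer[i], mean = mean(counts[, i]),
                   sd = stats::sd(counts[, i]), n_frames = nrow(counts))
  })
  agg <- summarize_monomers(per$mean)
  summary <- dplyr::bind_rows(per, tibble::tibble(monomer = "aggregate",
                                                  mean = agg$mean, sd = agg$sd,
                                                  n_frames = nrow(counts)))
  list(histogram = hist, summary = summary)
}

#' Water dipole direction
#'
#' Geometric (HOH-bisector) dipole: the normalized sum of the two O->H bond
#' vectors. With per-atom charges supplied, the charge-weighted molecular
#' dipole \eqn{\sum q_i r_i} is used instead (for TIP3P-like waters the two
#' directions coincide).
#'
#' @param traj An `aq_trajectory`.
#' @param frame Frame number.
#' @param o,h1,h2 Atom indices of the oxygen and the two hydrogens.
#' @param charges Optional numeric length-3 charges `c(qO, qH1, qH2)`.
#' @return Unit 3-vector.
#' @export
water_dipole <- function(traj, frame, o, h1, h2, charges = NULL) {
  m <- frame_coords(traj, frame)
  .dipole_from_coords(m[o, ], m[h1, ], m[h2, ], charges)
}

.dipole_from_coords <- function(ro, rh1, rh2, charges = NULL) {
  d <- if (is.null(charges)) {
    (rh1 - ro) + (rh2 - ro)
  } else {
    charges[1] * ro + charges[2] * rh1 + charges[3] * rh2
  }
  len <- sqrt(sum(d^2))
  if (len < 1e-8) abort("degenerate water geometry: zero dipole")
  d / len
}

# map every water oxygen to its two hydrogens: fast path assumes the two
# atoms following the oxygen in the topology are its hydrogens (the usual
# O, H1, H2 layout); falls back to a per-residue search otherwise
.water_hydrogens <- function(traj, water_oxygens) {
  topo <- traj$topology
  is_h <- toupper(topo$element) == "H"
  n <- nrow(topo)
  o <- water_oxygens
  ok <- (o + 2 <= n) & is_h[o + 1] & is_h[pmin(o + 2, n)] &
    topo$resno[o + 1] == topo$resno[o] & topo$resno[pmin(o + 2, n)] == topo$resno[o] &
    topo$chain[o + 1] == topo$chain[o] & topo$chain[pmin(o + 2, n)] == topo$chain[o]
  if (all(ok)) return(cbind(o + 1L, o + 2L))
  h <- matrix(NA_integer_, length(water_oxygens), 2)
  for (j in seq_along(water_oxygens)) {
    o <- water_oxygens[j]
    cand <- which(is_h & topo$resno == topo$resno[o] & topo$chain == topo$chain[o] &
                    topo$resname == topo$resname[o])
    cand <- cand[cand != o]
    if (length(cand) < 2) {
      abort(sprintf("water oxygen %d: could not locate two hydrogens in its residue", o))
    }
    h[j, ] <- sort(cand)[1:2]
  }
  h
}

#' z-resolved water dipole order parameters
#'
#' Every channel water contributes \eqn{\cos\theta} (dipole dot channel axis)
#' to the axial bin of its oxygen. Per bin, \eqn{P_1} is the mean of
#' \eqn{\cos\theta} and \eqn{P_2} the mean of \eqn{(3\cos^2\theta - 1)/2},
#' pooled over frames and waters; the error bar is the SD of per-frame bin
#' means across frames. The z coordinate is reported relative to the
#' per-frame channel midpoint, so profiles from different monomers align.
#'
#' @param traj An `aq_trajectory`.
#' @param channel_def An `aq_channeldef`.
#' @param bin_width Bin width in Angstrom (default 1).
#' @param water_oxygens Water oxygen atom indices.
#' @param charges Optional `c(qO, qH, qH)` for charge-weighted dipoles.
#' @param per_monomer Keep per-monomer profiles (`TRUE`) or average across
#'   monomers (`FALSE`, default returns both: per-monomer rows plus
#'   `"average"` rows).
#' @return A tibble of class `aq_orientation` with columns `monomer`, `z`
#'   (bin center, Angstrom), `P1`, `P2`, `P1_sd`, `P2_sd`, `n_samples`.
#'   Bins with no samples are absent (missing, not zero).
#' @export
order_parameters <- function(traj, channel_def, bin_width = 1,
                             water_oxygens = water_oxygen_indices(traj),
                             charges = NULL, per_monomer = TRUE) {
  stopifnot(bin_width > 0)
  memb <- .membership_array(traj, channel_def, water_oxygens)
  hyd <- .water_hydrogens(traj, water_oxygens)
  nf <- n_frames(traj)
  nw <- length(water_oxygens)
  # cos(theta) for all frames x waters, per monomer axis
  res <- purrr::map_dfr(seq_len(nrow(channel_def)), function(i) {
    ax <- channel_def$axis[[i]]
    ro <- traj$coords[, water_oxygens, , drop = FALSE]
    rh1 <- traj$coords[, hyd[, 1], , drop = FALSE]
    rh2 <- traj$coords[, hyd[, 2], , drop = FALSE]
    if (is.null(charges)) {
      dx <- (rh1[, , 1] - ro[, , 1]) + (rh2[, , 1] - ro[, , 1])
      dy <- (rh1[, , 2] - ro[, , 2]) + (rh2[, , 2] - ro[, , 2])
      dz <- (rh1[, , 3] - ro[, , 3]) + (rh2[, , 3] - ro[, , 3])
    } else {
      dx <- charges[1] * ro[, , 1] + charges[2] * rh1[, , 1] + charges[3] * rh2[, , 1]
      dy <- charges[1] * ro[, , 2] + charges[2] * rh1[, , 2] + charges[3] * rh2[, , 2]
      dz <- charges[1] * ro[, , 3] + charges[2] * rh1[, , 3] + charges[3] * rh2[, , 3]
    }
    norm <- sqrt(dx^2 + dy^2 + dz^2)
    cost <- (dx * ax[1] + dy * ax[2] + dz * ax[3]) / norm
    cost <- matrix(cost, nf, nw)
    ins <- matrix(memb$inside[, , i], nf, nw)
    zrel <- matrix(memb$z[, , i], nf, nw) -
      (memb$z_bottom[, i] + memb$z_top[, i]) / 2
    keep <- which(ins)
    if (length(keep) == 0) {
      warn(sprintf("monomer %s: no channel waters in any frame", channel_def$monomer[i]))
      return(tibble::tibble(monomer = character(), z = numeric(), P1 = numeric(),
                            P2 = numeric(), P1_sd = numeric(), P2_sd = numeric(),
                            n_samples = integer()))
    }
    fidx <- ((keep - 1) %% nf) + 1
    tibble::tibble(monomer = channel_def$monomer[i], frame = fidx,
                   z = zrel[keep], cost = cost[keep])
  })
  res$bin <- floor(res$z / bin_width)
  per_bin <- res |>
    dplyr::mutate(p2i = (3 * .data$cost^2 - 1) / 2) |>
    dplyr::group_by(.data$monomer, .data$bin)
  frame_means <- res |>
    dplyr::mutate(p2i = (3 * .data$cost^2 - 1) / 2) |>
    dplyr::group_by(.data$monomer, .data$bin, .data$frame) |>
    dplyr::summarise(f1 = mean(.data$cost), f2 = mean(.data$p2i), .groups = "drop") |>
    dplyr::group_by(.data$monomer, .data$bin) |>
    dplyr::summarise(P1_sd = stats::sd(.data$f1), P2_sd = stats::sd(.data$f2),
                     .groups = "drop")
  prof <- per_bin |>
    dplyr::summarise(P1 = mean(.data$cost), P2 = mean(.data$p2i),
                     n_samples = dplyr::n(), .groups = "drop") |>
    dplyr::left_join(frame_means, by = c("monomer", "bin")) |>
    dplyr::mutate(z = (.data$bin + 0.5) * bin_width) |>
    dplyr::select("monomer", "z", "P1", "P2", "P1_sd", "P2_sd", "n_samples") |>
    dplyr::arrange(.data$monomer, .data$z)
  if (!per_monomer || nrow(channel_def) > 1) {
    avg <- prof |>
      dplyr::group_by(.data$z) |>
      dplyr::summarise(P1_sd = if (dplyr::n() > 1) stats::sd(.data$P1) else .data$P1_sd[1],
                       P2_sd = if (dplyr::n() > 1) stats::sd(.data$P2) else .data$P2_sd[1],
                       P1 = mean(.data$P1), P2 = mean(.data$P2),
                       n_samples = sum(.data$n_samples), .groups = "drop") |>
      dplyr::mutate(monomer = "average") |>
      dplyr::select("monomer", "z", "P1", "P2", "P1_sd", "P2_sd", "n_samples")
    prof <- if (per_monomer) dplyr::bind_rows(prof, avg) else avg
  }
  class(prof) <- c("aq_orientation", class(prof))
  prof
}
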