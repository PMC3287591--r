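# Fixtures built in code: tiny topologies, scripted trajectories, and a
# reference channel definition used across the tests.

# topology of n waters (OW/HW1/HW2) plus two boundary marker atoms on the
# axis (resname BND, resno 1 bottom / 2 top)
water_topology <- function(n_waters) {
  tibble::tibble(
    name = c(rep(c("OW", "HW1", "HW2"), n_waters), "O", "O"),
    element = c(rep(c("O", "H", "H"), n_waters), "O", "O"),
    resname = c(rep("HOH", 3 * n_waters), "BND", "BND"),
    resno = c(rep(seq_len(n_waters), each = 3), 1L, 2L),
    chain = "A"
  )
}

# trajectory in which water oxygens follow scripted z paths; hydrogens ride
# 0.5 A above/below their oxygen; boundary atoms fixed at z = +-L/2
scripted_water_traj <- function(z_paths, L = 20, frame_interval = 2,
                                x = NULL) {
  n_w <- ncol(z_paths)
  nf <- nrow(z_paths)
  topo <- water_topology(n_w)
  coords <- array(0, c(nf, nrow(topo), 3))
  for (w in seq_len(n_w)) {
    i <- (w - 1) * 3
    xo <- if (is.null(x)) 0 else x[w]
    coords[, i + 1, 1] <- xo
    coords[, i + 1, 3] <- z_paths[, w]
    coords[, i + 2, 1] <- xo + 0.76; coords[, i + 2, 2] <- 0.59
    coords[, i + 2, 3] <- z_paths[, w]
    coords[, i + 3, 1] <- xo - 0.76; coords[, i + 3, 2] <- 0.59
    coords[, i + 3, 3] <- z_paths[, w]
  }
  coords[, 3 * n_w + 1, 3] <- -L / 2
  coords[, 3 * n_w + 2, 3] <- L / 2
  trajectory(topo, coords, frame_interval = frame_interval)
}

bnd_channel <- function(lateral_cutoff = 8) {
  channel_definition("M1",
                     top_selector = "resname BND & resno 2",
                     bottom_selector = "resname BND & resno 1",
                     lateral_cutoff = lateral_cutoff)
}

# minimal 3-atom single-model PDB text
minimal_pdb_lines <- function() {
  c("ATOM      1  O   GLY A 195       1.000   2.000   3.000  1.00  0.00           O",
    "ATOM      2  OW  HOH A   1       4.000   5.000   6.000  1.00  0.00           O",
    "ATOM      3  CA  ALA B   2       7.000   8.000   9.000  1.00  0.00           C",
    "END")
}
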