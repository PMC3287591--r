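# RMSD / RMSF / average structures with optimal rigid-body superposition.

#' Optimal rigid superposition (Kabsch)
#'
#' Least-squares rotation and translation mapping `mobile` onto `reference`,
#' with the reflection case corrected so the rotation is proper (det = +1).
#'
#' @param mobile,reference `n x 3` coordinate matrices, n >= 3.
#' @return A list: `rotation` (3x3), `translation` (length 3), `rmsd`
#'   (Angstrom), and `transformed` (the superposed mobile coordinates). The
#'   transform is `x %*% t(rotation) + translation`.
#' @export
kabsch_superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  stopifnot(ncol(mobile) == 3, ncol(reference) == 3)
  if (nrow(mobile) != nrow(reference)) abort("point counts differ")
  if (nrow(mobile) < 3) abort("need at least 3 points for superposition")
  cm <- colMeans(mobile); cr <- colMeans(reference)
  A <- sweep(mobile, 2, cm); B <- sweep(reference, 2, cr)
  H <- t(A) %*% B
  sv <- svd(H)
  if (min(sv$d) < 1e-10 && sum(sv$d > 1e-10) < 2) {
    abort("degenerate (collinear or coincident) point set")
  }
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  transformed <- A %*% t(R)
  rmsd <- sqrt(mean(rowSums((transformed - B)^2)))
  list(rotation = R, translation = as.numeric(cr - (cm %*% t(R))),
       rmsd = rmsd, transformed = sweep(transformed, 2, cr, "+"))
}

#' RMSD time series versus a reference frame
#'
#' @param traj An `aq_trajectory`.
#' @param selection Selection string or integer atom indices (e.g. the C-alpha
#'   atoms of one monomer).
#' @param reference Reference frame number (default last frame), or an
#'   `n x 3` coordinate matrix for the selected atoms.
#' @param superpose Superpose each frame onto the reference before the RMSD
#'   (default `TRUE`).
#' @return A tibble: `time` (ps), `rmsd` (Angstrom).
#' @export
rmsd_series <- function(traj, selection, reference = n_frames(traj),
                        superpose = TRUE) {
  idx <- if (is.character(selection)) select_atoms(traj, selection, require_match = TRUE) else selection
  if (length(idx) == 0) abort("empty selection")
  ref <- if (is.matrix(reference)) reference else frame_coords(traj, reference)[idx, , drop = FALSE]
  if (nrow(ref) != length(idx)) abort("reference size does not match selection")
  rmsd <- vapply(seq_len(n_frames(traj)), function(f) {
    m <- frame_coords(traj, f)[idx, , drop = FALSE]
    if (superpose) kabsch_superpose(m, ref)$rmsd
    else sqrt(mean(rowSums((m - ref)^2)))
  }, numeric(1))
  tibble::tibble(time = traj$times, rmsd = rmsd)
}

#' Per-atom RMSF profile
#'
#' Root-mean-square fluctuation of each selected atom about its time-mean
#' position. With `superpose = TRUE` every frame is first superposed onto the
#' running mean structure (one refinement pass: superpose onto the plain mean,
#' recompute the mean, superpose again).
#'
#' @param traj An `aq_trajectory`.
#' @param selection Selection string or atom indices.
#' @param superpose Remove rigid-body motion first (default `TRUE`).
#' @return A tibble: `atom` (index), `resno`, `name`, `rmsf` (Angstrom).
#' @export
rmsf_profile <- function(traj, selection, superpose = TRUE) {
  idx <- if (is.character(selection)) select_atoms(traj, selection, require_match = TRUE) else selection
  if (n_frames(traj) < 2) abort("need at least 2 frames")
  sub <- traj$coords[, idx, , drop = FALSE]
  nf <- dim(sub)[1]
  get_fit <- function(ref) {
    fitted <- array(NA_real_, dim(sub))
    for (f in seq_len(nf)) {
      m <- matrix(sub[f, , ], ncol = 3)
      fitted[f, , ] <- if (superpose) kabsch_superpose(m, ref)$transformed else m
    }
    fitted
  }
  mean_coords <- function(a) apply(a, c(2, 3), mean)
  ref <- mean_coords(sub)
  fitted <- get_fit(ref)
  if (superpose) fitted <- get_fit(mean_coords(fitted))  # one refinement pass
  mu <- mean_coords(fitted)
  dev2 <- (fitted[, , 1] - matrix(mu[, 1], nf, length(idx), byrow = TRUE))^2 +
    (fitted[, , 2] - matrix(mu[, 2], nf, length(idx), byrow = TRUE))^2 +
    (fitted[, , 3] - matrix(mu[, 3], nf, length(idx), byrow = TRUE))^2
  tibble::tibble(atom = idx, resno = traj$topology$resno[idx],
                 name = traj$topology$name[idx],
                 rmsf = sqrt(colMeans(dev2)))
}

#' Trajectory-average structure
#'
#' Arithmetic per-atom mean of the coordinates over a frame window,
#' optionally after superposing each frame onto the first window frame.
#'
#' @param traj An `aq_trajectory`.
#' @param selection Selection string or atom indices (default all atoms).
#' @param window Integer frame numbers to average (default all frames).
#' @param superpose Superpose frames before averaging (default `FALSE`).
#' @return A single-frame `aq_trajectory` of the selected atoms.
#' @export
average_structure <- function(traj, selection = seq_len(n_atoms(traj)),
                              window = seq_len(n_frames(traj)),
                              superpose = FALSE) {
  idx <- if (is.character(selection)) select_atoms(traj, selection, require_match = TRUE) else selection
  if (length(window) == 0) abort("empty frame window")
  if (any(window < 1 | window > n_frames(traj))) abort("window outside trajectory")
  sub <- traj$coords[window, idx, , drop = FALSE]
  if (superpose && length(window) > 1) {
    ref <- matrix(sub[1, , ], ncol = 3)
    for (f in seq_along(window)) {
      sub[f, , ] <- kabsch_superpose(matrix(sub[f, , ], ncol = 3), ref)$transformed
    }
  }
  avg <- apply(sub, c(2, 3), mean)
  trajectory(traj$topology[idx, ], avg, frame_interval = traj$frame_interval)
}
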