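# Trajectory container: topology tibble + frames x atoms x 3 coordinate array.
# Units: Angstrom and picoseconds everywhere.

#' Bondi van der Waals radii
#'
#' Default element-to-radius lookup (Angstrom) used when reading structures.
#' @return A named numeric vector of radii in Angstrom.
#' @export
bondi_radii <- function() {
  c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, F = 1.47, P = 1.80,
    S = 1.80, CL = 1.75, BR = 1.85, I = 1.98, NA. = 2.27, K = 2.75,
    MG = 1.73, ZN = 1.39, FE = 2.05, SE = 1.90)
}

# guess an element symbol from a PDB atom name ("OW" -> "O", "HW1" -> "H",
# "CA" in a protein residue -> "C", "CL" -> "CL")
.guess_element <- function(name) {
  nm <- toupper(trimws(name))
  two <- substr(nm, 1, 2)
  el <- ifelse(two %in% c("CL", "BR", "NA", "MG", "ZN", "FE", "SE"),
               two, substr(nm, 1, 1))
  # leading digits (e.g. "1HW") -> first letter
  digit <- grepl("^[0-9]", el)
  el[digit] <- substr(gsub("^[0-9]+", "", nm[digit]), 1, 1)
  el
}

.vdw_for <- function(element, radii = bondi_radii(), default_radius = 1.5,
                     quiet = FALSE) {
  key <- toupper(element)
  key[key == "NA"] <- "NA."
  r <- unname(radii[key])
  miss <- is.na(r)
  if (any(miss) && !quiet) {
    warn(paste0("Unknown element(s) ", paste(unique(element[miss]), collapse = ", "),
                "; using default vdW radius ", default_radius, " A"))
  }
  r[miss] <- default_radius
  r
}

#' Construct a trajectory object
#'
#' Binds a topology table to an ordered stack of coordinate frames. This is
#' the in-memory representation every analysis function consumes.
#'
#' @param topology A data frame with one row per atom and columns `name`,
#'   `element`, `resname`, `resno`, `chain` and `vdw` (radius in Angstrom).
#'   An `index` column (1-based) is added if absent.
#' @param coords A numeric array of dimension `c(n_frames, n_atoms, 3)`, or a
#'   `n_atoms x 3` matrix for a single frame. Angstrom.
#' @param times Frame times in ps; defaults to `(0:(n_frames-1)) * frame_interval`.
#' @param frame_interval Frame spacing in ps (must be > 0).
#' @return An object of class `aq_trajectory`.
#' @export
trajectory <- function(topology, coords, times = NULL, frame_interval = 1) {
  if (is.matrix(coords)) coords <- array(coords, c(1L, nrow(coords), 3L))
  stopifnot(length(dim(coords)) == 3, dim(coords)[3] == 3)
  topology <- tibble::as_tibble(topology)
  if (!"index" %in% names(topology)) topology$index <- seq_len(nrow(topology))
  if (!"vdw" %in% names(topology)) {
    topology$vdw <- .vdw_for(topology$element, quiet = TRUE)
  }
  if (dim(coords)[2] != nrow(topology)) {
    abort(sprintf("coords has %d atoms but topology has %d rows",
                  dim(coords)[2], nrow(topology)))
  }
  if (frame_interval <= 0) abort("frame_interval must be > 0")
  n_frames <- dim(coords)[1]
  if (is.null(times)) times <- (seq_len(n_frames) - 1) * frame_interval
  if (length(times) != n_frames) abort("times length must equal frame count")
  if (n_frames > 1 && any(diff(times) <= 0)) {
    abort("frame times must be strictly increasing")
  }
  structure(list(topology = topology, coords = coords, times = as.numeric(times),
                 frame_interval = frame_interval),
            class = "aq_trajectory")
}

#' @export
print.aq_trajectory <- function(x, ...) {
  cat(sprintf("<aq_trajectory> %d atoms, %d frames, dt = %g ps, span = %g ps\n",
              n_atoms(x), n_frames(x), x$frame_interval,
              diff(range(x$times))))
  invisible(x)
}

#' @rdname trajectory
#' @param x An `aq_trajectory`.
#' @export
n_frames <- function(x) dim(x$coords)[1]

#' @rdname trajectory
#' @export
n_atoms <- function(x) dim(x$coords)[2]

#' Extract one frame's coordinates
#' @param x An `aq_trajectory`.
#' @param i Frame number (1-based).
#' @return An `n_atoms x 3` matrix.
#' @export
frame_coords <- function(x, i) {
  m <- x$coords[i, , , drop = FALSE]
  dim(m) <- dim(m)[2:3]
  m
}

#' Read a (possibly multi-MODEL) PDB file as a trajectory
#'
#' Each MODEL becomes one frame; a file without MODEL records yields a
#' single-frame trajectory. van der Waals radii are assigned from the Bondi
#' table by element; unknown elements get `default_radius` with a warning.
#'
#' @param path Path to a PDB v3.3 file.
#' @param frame_interval Frame spacing in ps assigned to the frames.
#' @param radii Named element-to-radius table (Angstrom).
#' @param default_radius Radius used for elements missing from `radii`.
#' @return An `aq_trajectory`.
#' @export
read_pdb <- function(path, frame_interval = 1, radii = bondi_radii(),
                     default_radius = 1.5) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  pdb <- tryCatch(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE),
                  error = function(e) abort(paste0("PDB parse error in ", path,
                                                   ": ", conditionMessage(e))))
  at <- pdb$atom
  element <- at$elesy
  bad <- is.na(element) | element == ""
  element[bad] <- .guess_element(at$elety[bad])
  topo <- tibble::tibble(
    index = seq_len(nrow(at)),
    name = at$elety,
    element = element,
    resname = at$resid,
    resno = at$resno,
    chain = ifelse(is.na(at$chain), "", at$chain),
    vdw = .vdw_for(element, radii, default_radius)
  )
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  nf <- nrow(xyz)
  coords <- array(NA_real_, c(nf, nrow(topo), 3L))
  for (k in 1:3) coords[, , k] <- xyz[, seq(k, ncol(xyz), by = 3), drop = FALSE]
  trajectory(topo, coords, frame_interval = frame_interval)
}

#' Write a trajectory as a (multi-MODEL) PDB file
#' @param traj An `aq_trajectory`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(traj, path) {
  nf <- n_frames(traj)
  na <- n_atoms(traj)
  xyz <- matrix(NA_real_, nf, 3L * na)
  for (k in 1:3) xyz[, seq(k, 3L * na, by = 3)] <- traj$coords[, , k]
  topo <- traj$topology
  bio3d::write.pdb(file = path, xyz = xyz, type = rep("ATOM", nrow(topo)),
                   resno = topo$resno, resid = topo$resname,
                   eleno = seq_len(nrow(topo)), elety = topo$name,
                   chain = ifelse(topo$chain == "", " ", topo$chain))
  invisible(path)
}

#' Read a multi-frame XYZ file against a known topology
#'
#' Standard XYZ blocks (atom-count line, comment line, then `element x y z`
#' rows). Frames are timestamped `frame_index * frame_interval`.
#'
#' @param path Path to the XYZ file.
#' @param topology Topology tibble (or `aq_trajectory` whose topology is used);
#'   the per-frame atom count must match its row count.
#' @param frame_interval Frame spacing in ps.
#' @return An `aq_trajectory`.
#' @export
read_xyz_multiframe <- function(path, topology, frame_interval = 1) {
  if (inherits(topology, "aq_trajectory")) topology <- topology$topology
  lines <- readLines(path)
  lines <- lines[!(seq_along(lines) == length(lines) & lines == "")]
  if (length(lines) == 0) abort(paste0("empty XYZ file: ", path))
  na <- nrow(topology)
  block <- na + 2L
  if (length(lines) %% block != 0) {
    abort(sprintf("XYZ file %s: %d lines is not a multiple of %d (atom count %d + 2)",
                  path, length(lines), block, na))
  }
  nf <- length(lines) %/% block
  counts <- suppressWarnings(as.integer(lines[(0:(nf - 1)) * block + 1]))
  if (any(is.na(counts) | counts != na)) {
    abort(sprintf("XYZ file %s: per-frame atom count does not match topology (%d)",
                  path, na))
  }
  body <- lines[-(c(outer(1:2, (0:(nf - 1)) * block, "+")))]
  fields <- strsplit(trimws(body), "[[:space:]]+")
  if (any(lengths(fields) < 4)) abort(paste0("XYZ parse error in ", path))
  m <- matrix(as.numeric(vapply(fields, function(f) f[2:4], character(3))),
              ncol = 3, byrow = TRUE)
  coords <- array(NA_real_, c(nf, na, 3L))
  for (k in 1:3) coords[, , k] <- matrix(m[, k], nrow = nf, byrow = TRUE)
  trajectory(topology, coords, frame_interval = frame_interval)
}

#' Write a trajectory as a multi-frame XYZ file
#' @param traj An `aq_trajectory`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_xyz_multiframe <- function(traj, path) {
  na <- n_atoms(traj)
  el <- traj$topology$element
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(n_frames(traj))) {
    m <- frame_coords(traj, i)
    writeLines(c(as.character(na), sprintf("frame %d t= %.6g ps", i, traj$times[i]),
                 sprintf("%-2s %14.6f %14.6f %14.6f", el, m[, 1], m[, 2], m[, 3])),
               con)
  }
  invisible(path)
}

#' Select atoms with a small query grammar
#'
#' Queries are conjunctions of field tests joined by `&`; each test is
#' `field value1,value2,...` with fields `name`, `element`, `resname`,
#' `resno` and `chain`, e.g. `"name O & resno 195 & chain A"`. A listed value
#' matches by exact (case-sensitive) equality; the result depends only on the
#' topology, never on coordinates.
#'
#' @param x An `aq_trajectory` or topology data frame.
#' @param query Selection string.
#' @param require_match Error if the selection is empty.
#' @return Sorted integer vector of 1-based atom indices.
#' @export
select_atoms <- function(x, query, require_match = FALSE) {
  topo <- if (inherits(x, "aq_trajectory")) x$topology else tibble::as_tibble(x)
  terms <- trimws(strsplit(query, "&", fixed = TRUE)[[1]])
  keep <- rep(TRUE, nrow(topo))
  for (term in terms) {
    parts <- strsplit(term, "[[:space:]]+")[[1]]
    if (length(parts) < 2) abort(paste0("malformed selection term: '", term, "'"))
    field <- parts[1]
    vals <- unlist(strsplit(paste(parts[-1], collapse = ","), ",", fixed = TRUE))
    vals <- vals[vals != ""]
    col <- switch(field,
                  name = topo$name, element = topo$element,
                  resname = topo$resname, chain = topo$chain,
                  resno = topo$resno,
                  abort(paste0("unknown selection field: '", field, "'")))
    keep <- keep & if (field == "resno") col %in% as.integer(vals) else col %in% vals
  }
  idx <- which(keep)
  if (require_match && length(idx) == 0) {
    abort(paste0("selection matched no atoms: '", query, "'"))
  }
  idx
}
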