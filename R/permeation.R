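# Permeation event counting and the diffusive permeability p_d = v_w * k0.

#' Detect complete water permeation events
#'
#' Runs a per-water, per-monomer three-state machine over the frames. A water
#' completes a permeation event only if it enters the constriction region
#' through one axial boundary and later leaves through the opposite one;
#' re-exits through the entry side emit nothing, and waters that vacate
#' laterally are reset to the outside state on the side of their current
#' axial position. Waters already inside the region at the first analyzed
#' frame carry an unknown entry side and can never complete an event (only
#' full lumen traversals count).
#'
#' @param traj An `aq_trajectory`.
#' @param channel_def An `aq_channeldef`.
#' @param water_oxygens Water oxygen atom indices; defaults to
#'   [water_oxygen_indices()].
#' @param burn_in Time (ps) discarded from the start before the state machine
#'   begins. Default 0.
#' @param max_gap Largest tolerated time gap between consecutive frames (ps)
#'   before a warning that events may be missed; default `Inf`.
#' @return A tibble of class `aq_events` with columns `water` (atom index),
#'   `monomer`, `t_entry`, `t_exit` (ps) and `direction` (`"+z"`/`"-z"`),
#'   ordered by exit time. Attributes `t_span_ns` (analyzed time span) and
#'   `n_monomers` are attached for downstream rate computation.
#' @export
detect_events <- function(traj, channel_def, water_oxygens = water_oxygen_indices(traj),
                          burn_in = 0, max_gap = Inf) {
  if (n_frames(traj) < 2) abort("need at least 2 frames to detect events")
  frames <- which(traj$times >= traj$times[1] + burn_in)
  if (length(frames) < 2) abort("burn_in leaves fewer than 2 frames")
  times <- traj$times[frames]
  if (any(diff(times) > max_gap)) {
    warn("frame gap exceeds max_gap; permeation events may be missed")
  }
  memb <- .membership_array(traj, channel_def, water_oxygens, frames = frames)
  nf <- length(frames)
  nw <- length(water_oxygens)
  nm <- nrow(channel_def)

  # states: 0 outside-below, 1 outside-above, 2 inside-from-below,
  #         3 inside-from-above, 4 inside-unknown (initial occupants)
  mid <- (memb$z_bottom + memb$z_top) / 2
  events <- vector("list", 256)
  n_ev <- 0L
  state <- matrix(NA_real_, nw, nm)
  t_entry <- matrix(NA_real_, nw, nm)
  for (i in seq_len(nm)) {
    ins0 <- memb$inside[1, , i]
    z0 <- memb$z[1, , i]
    state[, i] <- ifelse(ins0, 4, ifelse(z0 >= mid[1, i], 1, 0))
  }
  for (f in 2:nf) {
    for (i in seq_len(nm)) {
      ins <- memb$inside[f, , i]
      z <- memb$z[f, , i]
      zb <- memb$z_bottom[f, i]; zt <- memb$z_top[f, i]
      s <- state[, i]
      # outside waters track their current side (they may migrate around the
      # channel or be exchanged between reservoirs without ever entering)
      out_now <- !ins & (s == 0 | s == 1)
      if (any(out_now)) state[out_now, i] <- ifelse(z[out_now] >= mid[f, i], 1, 0)
      enter <- ins & (s == 0 | s == 1)
      if (any(enter)) {
        state[enter & s == 0, i] <- 2
        state[enter & s == 1, i] <- 3
        t_entry[enter, i] <- times[f - 1]
      }
      # exits from inside
      leave <- !ins & (s == 2 | s == 3 | s == 4)
      if (any(leave)) {
        lz <- z[leave]
        in_band <- lz >= zb & lz < zt   # left laterally: reset by z-sign
        above <- lz >= zt | (in_band & lz >= mid[f, i])
        ls <- s[leave]
        # completed traversals
        plus <- ls == 2 & above & !in_band
        minus <- ls == 3 & !above & !in_band
        widx <- which(leave)
        for (j in which(plus | minus)) {
          n_ev <- n_ev + 1L
          if (n_ev > length(events)) events <- c(events, vector("list", length(events)))
          events[[n_ev]] <- list(water = water_oxygens[widx[j]],
                                 monomer = channel_def$monomer[i],
                                 t_entry = t_entry[widx[j], i],
                                 t_exit = times[f],
                                 direction = if (plus[j]) "+z" else "-z")
        }
        state[leave, i] <- ifelse(above, 1, 0)
        t_entry[leave, i] <- NA_real_
      }
    }
  }
  ev <- if (n_ev == 0) {
    tibble::tibble(water = integer(), monomer = character(),
                   t_entry = numeric(), t_exit = numeric(), direction = character())
  } else {
    dplyr::arrange(dplyr::bind_rows(lapply(events[seq_len(n_ev)], tibble::as_tibble)),
                   .data$t_exit, .data$water)
  }
  class(ev) <- c("aq_events", class(ev))
  attr(ev, "t_span_ns") <- (times[nf] - times[1]) / 1000
  attr(ev, "n_monomers") <- nm
  attr(ev, "monomers") <- channel_def$monomer
  ev
}

#' Unidirectional permeation rate constant
#'
#' \eqn{k_0 = N_\pm / (2 n_m t_{sim})}: completed bidirectional events divided
#' by twice the number of monomers times the analyzed time.
#'
#' @param N_pm Total number of completed permeation events (both directions).
#' @param n_monomers Number of channels the count is pooled over.
#' @param t_sim_ns Analyzed simulation time in ns.
#' @return k0 in ns^-1.
#' @examples
#' rate_constant(69, 4, 19)   # ~0.45 ns^-1, printed as 0.5
#' @export
rate_constant <- function(N_pm, n_monomers, t_sim_ns) {
  stopifnot(N_pm >= 0, n_monomers >= 1)
  if (t_sim_ns <= 0) abort("t_sim_ns must be > 0")
  N_pm / (2 * n_monomers * t_sim_ns)
}

#' Diffusive single-channel permeability
#'
#' \eqn{p_d = v_w k_0}, converting the rate from ns^-1 to s^-1.
#'
#' @param k0 Permeation rate constant in ns^-1.
#' @param v_w Volume of one water molecule in cm^3.
#' @return p_d in cm^3 s^-1.
#' @export
diffusive_permeability <- function(k0, v_w = .v_w_default) {
  stopifnot(k0 >= 0)
  v_w * k0 * 1e9
}

#' Summarize permeation events into rates and p_d
#'
#' @param events An `aq_events` tibble from [detect_events()].
#' @param t_sim_ns Analyzed time span in ns; defaults to the span recorded on
#'   `events`.
#' @param n_monomers Number of monomers pooled in the tetramer row; defaults
#'   to the number recorded on `events`.
#' @param v_w Volume of one water molecule in cm^3.
#' @return A tibble with one row per monomer plus a pooled `"tetramer"` row:
#'   `N_plus`, `N_minus`, `N_pm`, `k0` (ns^-1), `p_d` (cm^3 s^-1).
#' @export
permeation_summary <- function(events, t_sim_ns = attr(events, "t_span_ns"),
                               n_monomers = attr(events, "n_monomers"),
                               v_w = .v_w_default) {
  monomers <- attr(events, "monomers") %||% sort(unique(events$monomer))
  per <- purrr::map_dfr(monomers, function(m) {
    e <- events[events$monomer == m, ]
    np <- sum(e$direction == "+z"); nn <- sum(e$direction == "-z")
    k0 <- rate_constant(np + nn, 1, t_sim_ns)
    tibble::tibble(monomer = m, N_plus = np, N_minus = nn, N_pm = np + nn,
                   k0 = k0, p_d = diffusive_permeability(k0, v_w))
  })
  np <- sum(per$N_plus); nn <- sum(per$N_minus)
  k0 <- rate_constant(np + nn, n_monomers, t_sim_ns)
  dplyr::bind_rows(per, tibble::tibble(monomer = "tetramer", N_plus = np,
                                       N_minus = nn, N_pm = np + nn, k0 = k0,
                                       p_d = diffusive_permeability(k0, v_w)))
}

#' Cumulative permeation counts over time
#'
#' Event counts N+, N- and their sum as step functions of time, for
#' cumulative-event plots.
#'
#' @param events An `aq_events` tibble.
#' @return A tibble with columns `time` (ps), `N_plus`, `N_minus`, `N_pm`.
#' @export
cumulative_events <- function(events) {
  ev <- dplyr::arrange(tibble::as_tibble(events), .data$t_exit)
  tibble::tibble(time = ev$t_exit,
                 N_plus = cumsum(ev$direction == "+z"),
                 N_minus = cumsum(ev$direction == "-z"),
                 N_pm = seq_len(nrow(ev)))
}
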