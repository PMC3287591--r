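# Collective diffusion model: the dimensionless collective coordinate n(t),
# its multi-origin MSD, the collective diffusion constant D_n and the osmotic
# permeability p_f = v_w * D_n.

#' Collective water-transport coordinate n(t)
#'
#' For each consecutive frame pair the axial displacements of the channel
#' waters are summed and divided by the channel length L-bar; the cumulative
#' sum is the collective coordinate, with n(0) = 0. An increment of 1
#' corresponds to the net conduction of one water molecule through the
#' channel.
#'
#' Two conventions decide which waters contribute to a frame pair:
#' `"clipped"` (default) counts every water inside the constriction region at
#' either endpoint, with both endpoint positions clipped to the region's
#' axial interval, so the displacement budget of a full traversal is exactly
#' L-bar; `"both_frames"` counts only waters inside at both endpoints, with
#' unclipped displacements.
#'
#' @param traj An `aq_trajectory`.
#' @param channel_def An `aq_channeldef`.
#' @param L Channel length(s) L-bar in Angstrom: one value, one per monomer,
#'   or `NULL` to compute per-monomer time averages via [channel_length()].
#' @param water_oxygens Water oxygen atom indices.
#' @param contribution `"clipped"` or `"both_frames"`.
#' @return A tibble of class `aq_collective` with columns `monomer`, `time`
#'   (ps) and `n`; attribute `L` stores the lengths used.
#' @export
collective_coordinate <- function(traj, channel_def, L = NULL,
                                  water_oxygens = water_oxygen_indices(traj),
                                  contribution = c("clipped", "both_frames")) {
  contribution <- match.arg(contribution)
  if (n_frames(traj) < 2) abort("need at least 2 frames")
  if (is.null(L)) {
    cl <- channel_length(traj, channel_def)
    L <- cl$L_mean[match(channel_def$monomer, cl$monomer)]
  }
  L <- rep_len(L, nrow(channel_def))
  if (any(L <= 0)) abort("channel length L must be > 0")
  memb <- .membership_array(traj, channel_def, water_oxygens)
  nf <- n_frames(traj)
  out <- purrr::map_dfr(seq_len(nrow(channel_def)), function(i) {
    z <- memb$z[, , i, drop = TRUE]
    if (length(water_oxygens) == 1) z <- matrix(z, ncol = 1)
    ins <- memb$inside[, , i, drop = TRUE]
    if (length(water_oxygens) == 1) ins <- matrix(ins, ncol = 1)
    z1 <- z[-nf, , drop = FALSE]; z2 <- z[-1, , drop = FALSE]
    i1 <- ins[-nf, , drop = FALSE]; i2 <- ins[-1, , drop = FALSE]
    if (contribution == "both_frames") {
      contrib <- (z2 - z1) * (i1 & i2)
    } else {
      zb1 <- memb$z_bottom[-nf, i]; zt1 <- memb$z_top[-nf, i]
      zb2 <- memb$z_bottom[-1, i]; zt2 <- memb$z_top[-1, i]
      c1 <- pmin(pmax(z1, zb1), zt1)
      c2 <- pmin(pmax(z2, zb2), zt2)
      contrib <- (c2 - c1) * (i1 | i2)
    }
    dn <- rowSums(contrib) / L[i]
    tibble::tibble(monomer = channel_def$monomer[i], time = traj$times,
                   n = c(0, cumsum(dn)))
  })
  class(out) <- c("aq_collective", class(out))
  attr(out, "L") <- setNames(L, channel_def$monomer)
  out
}

#' Multi-origin mean-square displacement of n(t)
#'
#' \eqn{\langle n^2(\tau)\rangle} averaged over time origins t':
#' mean of \eqn{(n(t'+\tau)-n(t'))^2}. Origins are spaced `origin_stride` ps
#' apart; with stride equal to the window length the windows do not overlap
#' (20 ns analyzed in 100-ps windows gives 200 origins).
#'
#' @param series An `aq_collective` tibble (any number of monomers), or a
#'   tibble with `time` and `n` columns.
#' @param window_length Window length in ps (default 100).
#' @param origin_stride Origin spacing in ps; default `window_length`
#'   (non-overlapping windows).
#' @return A tibble of class `aq_msd` with columns `monomer`, `lag` (ps),
#'   `msd` and `n_origins`.
#' @export
msd_multi_origin <- function(series, window_length = 100,
                             origin_stride = window_length) {
  if (!"monomer" %in% names(series)) series$monomer <- "M1"
  stopifnot(origin_stride > 0, window_length > 0)
  res <- purrr::map_dfr(split(series, series$monomer), function(s) {
    s <- s[order(s$time), ]
    dt <- diff(s$time)
    step <- dt[1]
    if (any(abs(dt - step) > 1e-8 * step)) abort("series must be evenly spaced in time")
    w <- round(window_length / step)
    stride <- max(1L, round(origin_stride / step))
    nt <- nrow(s)
    if (w >= nt) abort("window_length exceeds the series span")
    origins <- seq(1L, nt - w, by = stride)
    if (length(origins) < 2) abort("fewer than 2 time origins; shorten the window or stride")
    lags <- 0:w
    msd <- vapply(lags, function(l) mean((s$n[origins + l] - s$n[origins])^2),
                  numeric(1))
    tibble::tibble(monomer = s$monomer[1], lag = lags * step, msd = msd,
                   n_origins = length(origins))
  })
  class(res) <- c("aq_msd", class(res))
  res
}

#' Fit the collective diffusion constant D_n
#'
#' Least-squares fit of \eqn{\langle n^2 \rangle = 2 D_n \tau} (free
#' intercept) over `fit_range`; the slope halves to D_n. A negative fitted
#' slope is clamped to zero with a warning.
#'
#' @param msd An `aq_msd` tibble (one or several monomers).
#' @param fit_range Lag interval in ps used for the fit; default `c(10, 100)`
#'   to skip the correlated short-time onset.
#' @return An object of class `aq_dnfit`: a list with `result` (tibble of
#'   `monomer`, `D_n` in ns^-1, `slope`, `intercept`, `r_squared`,
#'   `n_points`) and the fit inputs. `tidy()` and `glance()` methods apply.
#' @export
fit_Dn <- function(msd, fit_range = c(10, 100)) {
  if (!"monomer" %in% names(msd)) msd$monomer <- "M1"
  res <- purrr::map_dfr(split(tibble::as_tibble(msd), msd$monomer), function(m) {
    sel <- m$lag >= fit_range[1] & m$lag <= fit_range[2]
    if (sum(sel) < 2) abort("fit_range contains fewer than 2 MSD points")
    fit <- stats::lm(msd ~ lag, data = m[sel, ])
    slope <- unname(coef(fit)[2])          # per ps
    if (slope < 0) {
      warn(sprintf("monomer %s: negative MSD slope clamped to 0", m$monomer[1]))
      slope <- 0
    }
    ss_tot <- sum((m$msd[sel] - mean(m$msd[sel]))^2)
    r2 <- if (ss_tot > 0) 1 - sum(stats::residuals(fit)^2) / ss_tot else NA_real_
    tibble::tibble(monomer = m$monomer[1],
                   D_n = slope / 2 * 1000,  # ns^-1
                   slope = slope, intercept = unname(coef(fit)[1]),
                   r_squared = r2, n_points = sum(sel))
  })
  structure(list(result = res, fit_range = fit_range, msd = msd),
            class = "aq_dnfit")
}

#' @export
print.aq_dnfit <- function(x, ...) {
  cat(sprintf("<aq_dnfit> fit range [%g, %g] ps\n",
              x$fit_range[1], x$fit_range[2]))
  print(x$result)
  invisible(x)
}

#' @rdname fit_Dn
#' @param x An `aq_dnfit` object.
#' @param ... Unused.
#' @export
tidy.aq_dnfit <- function(x, ...) x$result

#' @rdname fit_Dn
#' @export
glance.aq_dnfit <- function(x, ...) {
  s <- summarize_monomers(x$result$D_n)
  tibble::tibble(n_monomers = nrow(x$result), D_n_mean = s$mean, D_n_sd = s$sd,
                 fit_lag_min = x$fit_range[1], fit_lag_max = x$fit_range[2])
}

#' Osmotic single-channel permeability
#'
#' \eqn{p_f = v_w D_n}, converting D_n from ns^-1 to s^-1.
#'
#' @param D_n Collective diffusion constant in ns^-1 (vectorized).
#' @param v_w Volume of one water molecule in cm^3.
#' @return p_f in cm^3 s^-1.
#' @export
osmotic_permeability <- function(D_n, v_w = .v_w_default) {
  stopifnot(all(D_n >= 0))
  v_w * D_n * 1e9
}

#' Single-fileness ratio p_f / p_d
#'
#' For a perfect single file of N waters the continuous-time random-walk
#' model predicts \eqn{p_f/p_d = N + 1}; water-water interchanges push the
#' ratio toward 1.
#'
#' @param p_f,p_d Permeabilities in the same units (vectorized).
#' @return The ratio; `NA` where `p_d` is 0 (undefined).
#' @export
pf_pd_ratio <- function(p_f, p_d) {
  out <- ifelse(p_d > 0, p_f / p_d, NA_real_)
  if (any(p_d <= 0)) warn("p_d is 0 for some entries; ratio reported as NA")
  out
}

#' Single-channel p_f from a membrane permeability
#'
#' Divides a membrane-level osmotic permeability P_f by the channel density
#' (channels per unit area), the conversion used to compare reconstituted
#' liposome measurements with single-channel estimates.
#'
#' @param P_f_um_s Membrane osmotic permeability in micrometer/s.
#' @param density_per_cm2 Channel density in channels per cm^2.
#' @return Single-channel p_f in cm^3 s^-1.
#' @export
single_channel_from_membrane_permeability <- function(P_f_um_s, density_per_cm2) {
  stopifnot(density_per_cm2 > 0)
  (P_f_um_s * 1e-4) / density_per_cm2   # um/s -> cm/s
}
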