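# Orchestration: run all analysis stages over a trajectory + channel
# definition and emit a summary-table report (per-monomer columns and a
# Mean +/- SD aggregate), plus TSV/JSON writers.

#' Mean and sample SD across monomers
#'
#' The aggregate convention used throughout the report tables: arithmetic
#' mean and sample (n-1) standard deviation of the per-monomer values.
#'
#' @param values Numeric vector (one value per monomer).
#' @return A tibble with `mean`, `sd` (NA when fewer than 2 values) and `n`.
#' @examples
#' summarize_monomers(c(8.3, 6.4, 5.1, 5.6))   # 6.4 +/- 1.4
#' @export
summarize_monomers <- function(values) {
  values <- values[!is.na(values)]
  tibble::tibble(mean = mean(values),
                 sd = if (length(values) >= 2) stats::sd(values) else NA_real_,
                 n = length(values))
}

#' Run the full permeability analysis pipeline
#'
#' Executes the enabled stages (channel length, permeation counting,
#' collective diffusion, occupancy, orientation, pore radius) over one
#' trajectory and assembles the per-monomer summary table of p_d, p_f,
#' p_f/p_d, occupancy and channel length. Deterministic given its inputs.
#'
#' @param traj An `aq_trajectory`.
#' @param channel_def An `aq_channeldef`.
#' @param stages Character vector among `"permeation"`, `"collective"`,
#'   `"occupancy"`, `"orientation"`, `"radius"`.
#' @param burn_in Time (ps) discarded before event counting (default 0).
#' @param window_length,origin_stride MSD windowing in ps (defaults 100, 100).
#' @param fit_range D_n fit range in ps (default `c(10, 100)`).
#' @param contribution dz contribution rule, see [collective_coordinate()].
#' @param bin_width Orientation profile bin width (Angstrom).
#' @param radius_args List of extra arguments passed to [radius_profile()].
#' @param v_w Volume of one water molecule in cm^3.
#' @return A list of class `aq_report`: `table` (tidy tibble: `monomer`,
#'   `quantity`, `value`), `wide` (Table-1-style tibble with per-monomer and
#'   `mean`/`sd` columns), and the per-stage results (`events`,
#'   `permeation`, `collective`, `msd`, `dn_fit`, `occupancy`, `orientation`,
#'   `radius`, `channel_length`).
#' @export
run_pipeline <- function(traj, channel_def,
                         stages = c("permeation", "collective", "occupancy"),
                         burn_in = 0, window_length = 100,
                         origin_stride = window_length,
                         fit_range = c(10, 100),
                         contribution = c("clipped", "both_frames"),
                         bin_width = 1, radius_args = list(),
                         v_w = .v_w_default) {
  contribution <- match.arg(contribution)
  out <- list()
  monomers <- channel_def$monomer
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }
  out$channel_length <- run_stage("channel_length", channel_length(traj, channel_def))
  L <- out$channel_length$L_mean[match(monomers, out$channel_length$monomer)]

  if ("permeation" %in% stages) {
    out$events <- run_stage("permeation",
                            detect_events(traj, channel_def, burn_in = burn_in))
    out$permeation <- permeation_summary(out$events, v_w = v_w)
  }
  if ("collective" %in% stages) {
    out$collective <- run_stage("collective",
      collective_coordinate(traj, channel_def, L = L, contribution = contribution))
    out$msd <- run_stage("collective",
      msd_multi_origin(out$collective, window_length, origin_stride))
    out$dn_fit <- run_stage("collective", fit_Dn(out$msd, fit_range))
  }
  if ("occupancy" %in% stages) {
    out$occupancy <- run_stage("occupancy", occupancy_histogram(traj, channel_def))
  }
  if ("orientation" %in% stages) {
    out$orientation <- run_stage("orientation",
      order_parameters(traj, channel_def, bin_width = bin_width))
  }
  if ("radius" %in% stages) {
    out$radius <- run_stage("radius",
      do.call(radius_profile, c(list(traj, channel_def), radius_args)))
  }

  # ---- assemble summary table --------------------------------------------
  rows <- list()
  add <- function(quantity, values) {
    rows[[length(rows) + 1]] <<- tibble::tibble(monomer = monomers,
                                                quantity = quantity,
                                                value = values)
  }
  add("L", L)
  if (!is.null(out$permeation)) {
    pm <- out$permeation[match(monomers, out$permeation$monomer), ]
    add("k0", pm$k0)
    add("p_d", pm$p_d)
  }
  if (!is.null(out$dn_fit)) {
    dn <- out$dn_fit$result
    dnv <- dn$D_n[match(monomers, dn$monomer)]
    add("D_n", dnv)
    add("p_f", osmotic_permeability(dnv, v_w))
  }
  if (!is.null(out$permeation) && !is.null(out$dn_fit)) {
    pf <- osmotic_permeability(out$dn_fit$result$D_n[match(monomers, out$dn_fit$result$monomer)], v_w)
    pd <- out$permeation$p_d[match(monomers, out$permeation$monomer)]
    add("pf_pd", pf_pd_ratio(pf, pd))
  }
  if (!is.null(out$occupancy)) {
    occ <- out$occupancy$summary
    add("occupancy", occ$mean[match(monomers, occ$monomer)])
  }
  table <- dplyr::bind_rows(rows)
  wide <- table |>
    tidyr::pivot_wider(names_from = "monomer", values_from = "value") |>
    dplyr::rowwise() |>
    dplyr::mutate(mean = mean(c(dplyr::c_across(dplyr::all_of(monomers))), na.rm = TRUE),
                  sd = stats::sd(c(dplyr::c_across(dplyr::all_of(monomers))), na.rm = TRUE)) |>
    dplyr::ungroup()
  out$table <- table
  out$wide <- wide
  class(out) <- "aq_report"
  out
}

#' @export
print.aq_report <- function(x, ...) {
  cat("<aq_report>\n")
  w <- x$wide
  # permeabilities in 1e-14 cm^3/s for display, as in the field's tables
  scale_rows <- w$quantity %in% c("p_d", "p_f")
  num <- names(w)[vapply(w, is.numeric, logical(1))]
  w[scale_rows, num] <- w[scale_rows, num] * 1e14
  w$quantity[scale_rows] <- paste0(w$quantity[scale_rows], " (1e-14 cm^3/s)")
  print(as.data.frame(w), digits = 3, row.names = FALSE)
  invisible(x)
}

#' Write report artifacts to a directory
#'
#' Emits `report.json` (full precision, SI units) and `table1.tsv` (the
#' summary table with permeabilities scaled to 1e-14 cm^3 s^-1 and rounded to
#' one decimal, presentation only), plus series TSVs for any stage present
#' (`events.tsv`, `collective.tsv`, `msd.tsv`, `occupancy.tsv`,
#' `orientation.tsv`, `radius.tsv`).
#'
#' @param report An `aq_report`.
#' @param dir Output directory (created if needed).
#' @param seed Optional seed to echo into the provenance block.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir, seed = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  prov <- list(package = "aquaperm",
               version = as.character(utils::packageVersion("aquaperm")),
               seed = seed)
  jsonlite::write_json(list(table = report$table, provenance = prov),
                       file.path(dir, "report.json"), auto_unbox = TRUE,
                       digits = NA)
  w <- report$wide
  scale_rows <- w$quantity %in% c("p_d", "p_f")
  num <- names(w)[vapply(w, is.numeric, logical(1))]
  w[scale_rows, num] <- w[scale_rows, num] * 1e14
  w[num] <- lapply(w[num], round, digits = 1)
  utils::write.table(w, file.path(dir, "table1.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  tsv <- function(obj, name) {
    if (!is.null(obj)) {
      utils::write.table(tibble::as_tibble(obj), file.path(dir, name),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  tsv(report$events, "events.tsv")
  tsv(report$collective, "collective.tsv")
  tsv(report$msd, "msd.tsv")
  tsv(report$occupancy$summary, "occupancy.tsv")
  tsv(report$orientation, "orientation.tsv")
  tsv(report$radius, "radius.tsv")
  invisible(dir)
}

#' Build a channel definition from a YAML config
#'
#' The YAML mirrors the [channel_definition()] arguments: a `monomers` list
#' of `{id, top, bottom}` selector entries plus optional `axis`,
#' `lateral_cutoff` and `fixed_z`.
#'
#' @param path Path to a YAML file.
#' @return An `aq_channeldef`.
#' @export
read_channel_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  mons <- cfg$monomers
  channel_definition(
    monomer = vapply(mons, `[[`, character(1), "id"),
    top_selector = vapply(mons, `[[`, character(1), "top"),
    bottom_selector = vapply(mons, `[[`, character(1), "bottom"),
    axis = if (!is.null(cfg$axis)) as.numeric(cfg$axis) else c(0, 0, 1),
    lateral_cutoff = cfg$lateral_cutoff %||% 8,
    fixed_z = if (!is.null(cfg$fixed_z)) as.numeric(cfg$fixed_z) else NULL
  )
}
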