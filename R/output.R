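# Delimited-text serialization of runs and base-graphics figures.

.write_table <- function(df, file, header_comment) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(paste0("# ", header_comment), con)
  utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Write the tank-level time series of a run
#'
#' Tab-separated columns: time (d), thickness (um), tank particulates
#' and solutes (g/m3), areal live/dead biomass (g/m2). One comment line
#' documents units.
#'
#' @param sim a `biofilm_sim`.
#' @param file output path.
#' @return the path, invisibly.
#' @export
write_timeseries <- function(sim, file) {
  df <- as.data.frame(sim)
  .write_table(df, file,
    "time [d], Lf_um [um], X_t_* [g/m3], S_t_* [g/m3], areal_* [g/m2]")
}

#' Write depth profiles at selected times
#'
#' One tab-separated block per requested time (nearest sample used),
#' stacked with a `time` column: depth, particulate concentrations and
#' volume fractions, solutes, glucose consumption rate.
#'
#' @param sim a `biofilm_sim`.
#' @param times times in days (default: final sample only).
#' @param file output path.
#' @return the path, invisibly.
#' @export
write_profiles <- function(sim, file, times = NULL) {
  if (is.null(times)) times <- max(sim$times)
  blocks <- lapply(times, function(tm) {
    pr <- biofilm_profile(sim, tm)
    cbind(time = sim$times[which.min(abs(sim$times - tm))], pr)
  })
  .write_table(do.call(rbind, blocks), file,
    "time [d], z_um [um, 0 = substratum], X_b_* [g/m3], P_* [-], S_b_* [g/m3], glucose_consumption [g/m3/d]")
}

#' Write a flat machine-readable metrics summary
#'
#' `key<TAB>value` lines, one metric per line, lengths in microns and
#' fractions in percent.
#'
#' @param metrics a `biofilm_metrics` from [steady_state_metrics()].
#' @param file output path.
#' @return the path, invisibly.
#' @export
write_metrics <- function(metrics, file) {
  kv <- c(
    Lf_ss_um = 1e6 * metrics$Lf_ss,
    areal_live_g_m2 = metrics$areal_live,
    areal_dead_g_m2 = metrics$areal_dead,
    mean_live_fraction_pct = metrics$mean_live_fraction,
    percent_live_pct = metrics$percent_live,
    log_reduction_ss = metrics$log_reduction_ss,
    penetration_glucose_um = 1e6 * metrics$penetration_glucose,
    penetration_hp_um = 1e6 * metrics$penetration_hp,
    S_t_glucose_g_m3 = metrics$S_t_ss[1],
    S_t_hp_g_m3 = metrics$S_t_ss[2],
    eradicated = as.numeric(metrics$eradicated))
  writeLines(paste(names(kv), format(kv, digits = 15, trim = TRUE),
                   sep = "\t"), file)
  invisible(file)
}

#' Thickness dynamics of one or more runs
#'
#' Base-graphics overlay of film thickness versus time, one curve per
#' simulation (e.g. the no-dosing / continuous / on-off trio).
#'
#' @param sims a `biofilm_sim` or list of them.
#' @param labels legend labels.
#' @param ... passed to [graphics::matplot()].
#' @return invisibly, the matrix of plotted thicknesses.
#' @export
plot_thickness <- function(sims, labels = NULL, ...) {
  if (inherits(sims, "biofilm_sim")) sims <- list(sims)
  if (is.null(labels)) labels <- paste("run", seq_along(sims))
  tmax <- max(vapply(sims, function(s) max(s$times), numeric(1)))
  tt <- seq(0, tmax, length.out = 400)
  m <- vapply(sims, function(s) {
    v <- stats::approx(s$times, s$Lf, tt, rule = 2)$y
    if (s$eradicated) v[tt > s$t_eradicated] <- 0
    1e6 * v
  }, numeric(length(tt)))
  graphics::matplot(tt, m, type = "l", lty = seq_along(sims), lwd = 2,
                    xlab = "time (d)", ylab = "biofilm thickness (um)", ...)
  graphics::legend("bottomright", legend = labels, lty = seq_along(sims),
                   col = seq_along(sims), lwd = 2, bty = "n")
  invisible(m)
}

#' Solute depth profiles of one or more runs
#'
#' @param sims a `biofilm_sim` or list of them (final-time profiles).
#' @param solute `"glucose"` or `"hp"`.
#' @param labels legend labels.
#' @param ... passed to [graphics::plot()].
#' @return invisibly, list of plotted profiles.
#' @export
plot_solute_profiles <- function(sims, solute = c("glucose", "hp"),
                                 labels = NULL, ...) {
  solute <- match.arg(solute)
  if (inherits(sims, "biofilm_sim")) sims <- list(sims)
  if (is.null(labels)) labels <- paste("run", seq_along(sims))
  col <- if (solute == "glucose") "S_b_glucose" else "S_b_hp"
  prs <- lapply(sims, biofilm_profile)
  xmax <- max(vapply(prs, function(p) max(p$z_um), numeric(1)))
  ymax <- max(vapply(prs, function(p) max(p[[col]]), numeric(1)))
  graphics::plot(NA, xlim = c(0, xmax), ylim = c(0, ymax * 1.05),
                 xlab = "height above substratum (um)",
                 ylab = paste(solute, "concentration (g/m3)"), ...)
  for (i in seq_along(prs))
    graphics::lines(prs[[i]]$z_um, prs[[i]][[col]], lty = i, col = i, lwd = 2)
  graphics::legend("topleft", legend = labels, lty = seq_along(prs),
                   col = seq_along(prs), lwd = 2, bty = "n")
  invisible(prs)
}

#' Live/dead volume fractions and glucose consumption with depth
#'
#' Two stacked panels: particulate volume fractions and the volumetric
#' glucose consumption rate, for one or more final-time profiles.
#'
#' @param sims a `biofilm_sim` or list of them.
#' @param labels legend labels.
#' @return invisibly, the list of profiles.
#' @export
plot_stratification <- function(sims, labels = NULL) {
  if (inherits(sims, "biofilm_sim")) sims <- list(sims)
  if (is.null(labels)) labels <- paste("run", seq_along(sims))
  prs <- lapply(sims, biofilm_profile)
  old <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(old))
  xmax <- max(vapply(prs, function(p) max(p$z_um), numeric(1)))
  ymax <- max(vapply(prs, function(p) max(p$P_live, p$P_dead), numeric(1)))
  graphics::plot(NA, xlim = c(0, xmax), ylim = c(0, ymax * 1.1),
                 xlab = "height above substratum (um)",
                 ylab = "volume fraction")
  for (i in seq_along(prs)) {
    graphics::lines(prs[[i]]$z_um, prs[[i]]$P_live, col = i, lty = 1, lwd = 2)
    graphics::lines(prs[[i]]$z_um, prs[[i]]$P_dead, col = i, lty = 2, lwd = 2)
  }
  graphics::legend("topright", bty = "n", lwd = 2,
                   legend = c(paste(labels, "live"), paste(labels, "dead")),
                   col = rep(seq_along(prs), 2),
                   lty = rep(c(1, 2), each = length(prs)))
  ymax2 <- max(vapply(prs, function(p) max(p$glucose_consumption), numeric(1)))
  graphics::plot(NA, xlim = c(0, xmax), ylim = c(0, ymax2 * 1.1),
                 xlab = "height above substratum (um)",
                 ylab = "glucose consumption (g/m3/d)")
  for (i in seq_along(prs))
    graphics::lines(prs[[i]]$z_um, prs[[i]]$glucose_consumption,
                    col = i, lwd = 2)
  invisible(prs)
}

#' Dose-response curve from a sweep table
#'
#' @param sweep data.frame from [dose_sweep()] (or
#'   [neutralization_sweep()], with `axis = "k_B_D"`).
#' @param axis name of the x column.
#' @param baseline_um optional untreated thickness to mark.
#' @param ... passed to [graphics::plot()].
#' @return invisibly, the sweep.
#' @export
plot_dose_response <- function(sweep, axis = "dose", baseline_um = NULL, ...) {
  graphics::plot(sweep[[axis]], sweep$Lf_um, type = "b", pch = 16,
                 xlab = axis, ylab = "steady-state thickness (um)", ...)
  if (!is.null(baseline_um))
    graphics::abline(h = baseline_um, lty = 3)
  invisible(sweep)
}
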