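# MESF bead calibration and antibody surface density. Quantum MESF beads
# carry known numbers of fluorophores; an ordinary least-squares line of
# MESF count against per-level median bead intensity converts cell MFI to
# absolute fluorophore counts, and dividing by fluorophores per IgG and the
# cell surface area (sphere, pi * d^2) gives molecules per square
# micrometre.

#' Fit an MESF calibration line
#'
#' Aggregates the bead table to one median intensity per distinct MESF
#' level, then fits MESF count as an ordinary least-squares linear function
#' of intensity. The returned `gain` is the slope (fluorophores per
#' intensity unit) and `intercept` the intensity at zero fluorophores, so
#' that `N_fluor = gain * (intensity - intercept)`.
#'
#' @param bead_table data.frame with columns `mesf_count` and `intensity`
#'   (one row per bead), e.g. from [generate_calibration_beads()].
#' @return An `mesf_calibration` with `gain` (> 0), `intercept` (a.u.),
#'   `fit_residual` (residual sum of squares of the per-level fit) and the
#'   per-level medians used.
#' @export
fit_mesf_calibration <- function(bead_table) {
  if (!is.data.frame(bead_table) ||
      !all(c("mesf_count", "intensity") %in% names(bead_table))) {
    stop("`bead_table` must have columns `mesf_count` and `intensity`",
         call. = FALSE)
  }
  levels_mesf <- sort(unique(bead_table$mesf_count))
  if (length(levels_mesf) < 2L) {
    stop("insufficient calibration: need at least 2 distinct MESF levels",
         call. = FALSE)
  }
  med <- vapply(levels_mesf, function(m) {
    median(bead_table$intensity[bead_table$mesf_count == m])
  }, numeric(1))
  fit <- lm(levels_mesf ~ med)
  gain <- unname(coef(fit)[2])
  if (!is.finite(gain) || gain <= 0) {
    stop("calibration gain is not positive; bead response is not usable",
         call. = FALSE)
  }
  structure(list(
    gain = gain,
    intercept = -unname(coef(fit)[1]) / gain,
    fit_residual = sum(fit$residuals^2),
    level_medians = data.frame(mesf_count = levels_mesf, median_intensity = med)
  ), class = "mesf_calibration")
}

#' @export
print.mesf_calibration <- function(x, ...) {
  cat("MESF calibration (fluorophore count vs intensity):\n")
  cat(sprintf("  gain      : %.6g fluorophores per a.u.\n", x$gain))
  cat(sprintf("  intercept : %.6g a.u. at zero fluorophores\n", x$intercept))
  cat(sprintf("  RSS       : %.6g over %d levels\n", x$fit_residual,
              nrow(x$level_medians)))
  invisible(x)
}

#' Antibody surface density from median fluorescence
#'
#' Converts a population MFI to molecules of IgG per square micrometre:
#' `N_fluor = gain * (mfi - intercept)`, `N_IgG = N_fluor / fluors_per_igg`,
#' `density = N_IgG / (pi * d^2)` with the cell modelled as a sphere of the
#' given average diameter (surface area `pi * d^2`).
#'
#' @param mfi median fluorescence intensity of the cell population (a.u.);
#'   must be >= the calibration intercept.
#' @param cal an [fit_mesf_calibration()] result.
#' @param fluors_per_igg fluorophores per IgG; labelled antibodies carry
#'   five to seven, so the default is the midpoint, 6.
#' @param cell_diameter_um average cell diameter (um), > 0.
#' @return A `surface_density` with `density` (molecules/um^2), plus the
#'   inputs used.
#' @export
density_from_fluorescence <- function(mfi, cal, fluors_per_igg = 6,
                                      cell_diameter_um = 10) {
  if (!inherits(cal, "mesf_calibration")) {
    stop("`cal` must be an mesf_calibration object", call. = FALSE)
  }
  check_scalar_number(mfi, "mfi")
  check_scalar_number(fluors_per_igg, "fluors_per_igg", lower = 0,
                      strict_lower = TRUE)
  check_scalar_number(cell_diameter_um, "cell_diameter_um", lower = 0,
                      strict_lower = TRUE)
  if (mfi < cal$intercept) {
    stop("`mfi` is below the calibration intercept (negative signal)",
         call. = FALSE)
  }
  n_fluor <- cal$gain * (mfi - cal$intercept)
  n_igg <- n_fluor / fluors_per_igg
  structure(list(
    density = n_igg / (pi * cell_diameter_um^2),
    n_fluorophores = n_fluor,
    n_igg = n_igg,
    mfi = mfi,
    fluors_per_igg = fluors_per_igg,
    cell_diameter_um = cell_diameter_um
  ), class = "surface_density")
}

#' @export
print.surface_density <- function(x, ...) {
  cat(sprintf(
    "Antibody surface density: %.4g molecules/um^2\n  (%.4g fluorophores -> %.4g IgG on a %.3g-um sphere, %g fluorophores/IgG)\n",
    x$density, x$n_fluorophores, x$n_igg, x$cell_diameter_um,
    x$fluors_per_igg))
  invisible(x)
}
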