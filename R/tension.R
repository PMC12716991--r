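# Young-Laplace analysis of micropipette aspiration. A cell (or GUV) held at
# the tip of a pipette reaches mechanical equilibrium when
#
#   dP_suction = 2 * gamma * (1/R_pipette - 1/R_cell)
#
# so the interface tension is gamma = dP / (2 * (1/R_p - 1/R_c)). All
# arithmetic is done in SI (Pa, m, N/m) and reported in bench units
# (Pa, um, mN/m).

check_aspiration_geometry <- function(R_pipette_um, R_cell_um) {
  if (any(!is.finite(R_pipette_um)) || any(R_pipette_um <= 0)) {
    stop("`R_pipette_um` must be finite and > 0", call. = FALSE)
  }
  if (any(is.na(R_cell_um)) || any(R_cell_um <= R_pipette_um)) {
    stop("invalid aspiration geometry: need R_cell > R_pipette > 0",
         call. = FALSE)
  }
  invisible(NULL)
}

#' Tension from an aspiration measurement (Young-Laplace)
#'
#' `gamma = dP_suction / (2 * (1/R_pipette - 1/R_cell))`, computed in SI and
#' returned in mN/m. Vectorized over its arguments. `R_cell_um = Inf` gives
#' the flat-reference limit `gamma = dP * R_pipette / 2`.
#'
#' @param dP_suction_Pa suction pressure (Pa), >= 0.
#' @param R_pipette_um pipette inner radius (um), > 0.
#' @param R_cell_um cell or vesicle radius (um), > `R_pipette_um` (may be
#'   `Inf`).
#' @return tension (mN/m).
#' @seealso [required_suction()] for the exact algebraic inverse,
#'   [tongue_within_spec()] for the read-out validity flag.
#' @export
tension_from_aspiration <- function(dP_suction_Pa, R_pipette_um, R_cell_um) {
  check_aspiration_geometry(R_pipette_um, R_cell_um)
  if (any(!is.finite(dP_suction_Pa)) || any(dP_suction_Pa < 0)) {
    stop("`dP_suction_Pa` must be finite and >= 0", call. = FALSE)
  }
  curv <- 1 / um_to_m(R_pipette_um) - 1 / um_to_m(R_cell_um)  # 1/m
  si_to_mN_per_m(dP_suction_Pa / (2 * curv))
}

#' Suction pressure required to hold a given tension
#'
#' Exact algebraic inverse of [tension_from_aspiration()]:
#' `dP = 2 * gamma * (1/R_pipette - 1/R_cell)`.
#'
#' @param gamma_mN_per_m target tension (mN/m), >= 0.
#' @inheritParams tension_from_aspiration
#' @return suction pressure (Pa).
#' @export
required_suction <- function(gamma_mN_per_m, R_pipette_um, R_cell_um) {
  check_aspiration_geometry(R_pipette_um, R_cell_um)
  if (any(!is.finite(gamma_mN_per_m)) || any(gamma_mN_per_m < 0)) {
    stop("`gamma_mN_per_m` must be finite and >= 0", call. = FALSE)
  }
  curv <- 1 / um_to_m(R_pipette_um) - 1 / um_to_m(R_cell_um)
  2 * mN_per_m_to_si(gamma_mN_per_m) * curv
}

#' Flag whether the aspirated tongue length validates a reading
#'
#' Pressure is read once the aspirated membrane tongue reaches a length
#' comparable to the pipette radius; a measurement whose recorded tongue
#' length is within `tol` (default 25%) of the pipette radius is considered
#' read at the right moment. The flag never alters the Laplace formula; it
#' only marks which readings meet the acquisition criterion.
#'
#' @param tongue_um aspirated tongue length (um); `NA` gives `NA`.
#' @param R_pipette_um pipette inner radius (um).
#' @param tol relative tolerance around `R_pipette_um`.
#' @return logical vector.
#' @export
tongue_within_spec <- function(tongue_um, R_pipette_um, tol = 0.25) {
  abs(tongue_um - R_pipette_um) <= tol * R_pipette_um
}

#' Summarize tension estimates by group
#'
#' Per-group mean, sample (n-1) standard deviation (`NA` for singleton
#' groups), n, and the fraction of estimates below/above a tension cutoff
#' separating the low-tension (trogocytosis-prone) and high-tension
#' (phagocytosis-prone) regimes.
#'
#' @param gamma_mN_per_m tension estimates (mN/m).
#' @param group group labels, one per estimate (default: one group).
#' @param cutoff_mN_per_m regime cutoff (mN/m); default 1, the boundary
#'   between the low-tension regime (< 1 mN/m) and the high-tension regime.
#' @return data.frame with one row per group: `group`, `n`, `mean_mN_per_m`,
#'   `sd_mN_per_m`, `frac_below_cutoff`, `frac_above_cutoff`.
#' @export
summarize_tensions <- function(gamma_mN_per_m,
                               group = rep("all", length(gamma_mN_per_m)),
                               cutoff_mN_per_m = 1) {
  if (length(gamma_mN_per_m) == 0L) {
    stop("no tension estimates supplied", call. = FALSE)
  }
  if (length(group) != length(gamma_mN_per_m)) {
    stop("`group` must have one label per estimate", call. = FALSE)
  }
  if (any(!is.finite(gamma_mN_per_m)) || any(gamma_mN_per_m < 0)) {
    stop("tension estimates must be finite and >= 0", call. = FALSE)
  }
  split_gamma <- split(gamma_mN_per_m, group)
  out <- do.call(rbind, lapply(names(split_gamma), function(g) {
    v <- split_gamma[[g]]
    data.frame(
      group = g,
      n = length(v),
      mean_mN_per_m = mean(v),
      sd_mN_per_m = if (length(v) > 1L) sd(v) else NA_real_,
      frac_below_cutoff = mean(v < cutoff_mN_per_m),
      frac_above_cutoff = mean(v >= cutoff_mN_per_m)
    )
  }))
  attr(out, "cutoff_mN_per_m") <- cutoff_mN_per_m
  rownames(out) <- NULL
  out
}
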