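# Mechanical scaling model of the macrophage-target interface. Antibody
# engagement of Fc-gamma receptors drives cytoskeleton-generated normal
# stresses on the target membrane; the target's cortical tension resists
# deformation. Balancing the two,
#
#   sigma_normal(rho_AB) * R_min^2  ~  gamma_t * R_min
#
# gives the minimum deformation ("bite") length scale
#
#   R_min ~ gamma_t / sigma_normal(rho_AB),
#
# with sigma_normal = alpha * rho_AB the simplest stress law that scales
# with antibody density. When R_min is small compared to the interface size
# R the macrophage can pinch off bites (trogocytosis); when R_min is
# comparable to or larger than R it can only engulf the whole target
# (phagocytosis). Below an engagement threshold density neither occurs.

#' Mechanical parameters of the macrophage-target interface
#'
#' @param alpha active normal stress per unit antibody density
#'   (Pa per molecule/um^2). Default 0.25, which maps an opsonization
#'   density of ~400 molecules/um^2 to an active stress of ~100 Pa, the
#'   order of magnitude of measured interfacial traction stresses.
#' @param kappa membrane bending stiffness (J). Default 8e-20 J (~20 kT),
#'   a standard phosphatidylcholine bilayer magnitude.
#' @param R_interface macrophage-target interface size (um). Default 1.
#' @param rho_engage minimum antibody density for engagement
#'   (molecules/um^2). Default 100 (~10^2 antibodies per um^2).
#' @param beta dimensionless classification threshold: trogocytosis
#'   requires `R_min < beta * R_interface`. Default 1.
#' @return A `mech_params` list.
#' @export
mech_params <- function(alpha = 0.25, kappa = 8e-20, R_interface = 1,
                        rho_engage = 100, beta = 1) {
  check_scalar_number(alpha, "alpha", lower = 0, strict_lower = TRUE)
  check_scalar_number(kappa, "kappa", lower = 0, strict_lower = TRUE)
  check_scalar_number(R_interface, "R_interface", lower = 0, strict_lower = TRUE)
  check_scalar_number(rho_engage, "rho_engage", lower = 0, strict_lower = TRUE)
  check_scalar_number(beta, "beta", lower = 0, strict_lower = TRUE)
  structure(list(alpha = alpha, kappa = kappa, R_interface = R_interface,
                 rho_engage = rho_engage, beta = beta),
            class = "mech_params")
}

#' Active normal stress at a given antibody density
#'
#' `sigma = alpha * rho_ab`: the interfacial normal stress scales linearly
#' with antibody surface density. Other stress laws can be substituted by
#' passing a function via `law`.
#'
#' @param rho_ab antibody density (molecules/um^2), >= 0; vectorized.
#' @param params a [mech_params()].
#' @param law optional function `rho -> stress (Pa)` overriding the linear
#'   law.
#' @return stress (Pa).
#' @export
normal_stress <- function(rho_ab, params = mech_params(), law = NULL) {
  if (any(!is.finite(rho_ab)) || any(rho_ab < 0)) {
    stop("`rho_ab` must be finite and >= 0", call. = FALSE)
  }
  if (!is.null(law)) return(law(rho_ab))
  params$alpha * rho_ab
}

#' Minimum deformation (bite) length scale
#'
#' `R_min = gamma_t / sigma`, the scale below which tension damps out
#' active deformations. Computed in SI, returned in micrometres.
#'
#' @param gamma_t target cortical tension (mN/m), >= 0; vectorized.
#' @param sigma_Pa active normal stress (Pa), > 0.
#' @return length (um).
#' @export
r_min <- function(gamma_t, sigma_Pa) {
  if (any(!is.finite(gamma_t)) || any(gamma_t < 0)) {
    stop("`gamma_t` must be finite and >= 0", call. = FALSE)
  }
  if (any(!is.finite(sigma_Pa)) || any(sigma_Pa <= 0)) {
    stop("`sigma_Pa` must be > 0 (zero stress implies no engagement)",
         call. = FALSE)
  }
  m_to_um(mN_per_m_to_si(gamma_t) / sigma_Pa)
}

#' Bending-dominated deformation length scale
#'
#' Balancing active stress against membrane bending, `sigma ~ kappa / R^3`,
#' gives `R_bend = (kappa / sigma)^(1/3)`. For physiological tensions and
#' bending stiffnesses this scale is below `R_min`, so smooth
#' tension-limited deformations, not sharp bending-limited ones, set the
#' bite size.
#'
#' @param kappa bending stiffness (J), > 0.
#' @param sigma_Pa active normal stress (Pa), > 0.
#' @return length (um).
#' @export
bending_length <- function(kappa, sigma_Pa) {
  if (any(!is.finite(kappa)) || any(kappa <= 0)) {
    stop("`kappa` must be > 0", call. = FALSE)
  }
  if (any(!is.finite(sigma_Pa)) || any(sigma_Pa <= 0)) {
    stop("`sigma_Pa` must be > 0", call. = FALSE)
  }
  m_to_um((kappa / sigma_Pa)^(1 / 3))
}

#' Predicted critical antibody density at a given tension
#'
#' Solving `R_min(gamma_t, sigma(rho)) = beta * R_interface` for the
#' antibody density under the linear stress law gives
#' `rho_crit_pred = gamma_t / (alpha * beta * R_interface)` (in SI),
#' strictly proportional to the target tension.
#'
#' @param gamma_t target cortical tension (mN/m), >= 0; vectorized.
#' @param params a [mech_params()].
#' @return antibody density (molecules/um^2).
#' @export
critical_density <- function(gamma_t, params = mech_params()) {
  if (any(!is.finite(gamma_t)) || any(gamma_t < 0)) {
    stop("`gamma_t` must be finite and >= 0", call. = FALSE)
  }
  mN_per_m_to_si(gamma_t) /
    (params$alpha * params$beta * um_to_m(params$R_interface))
}

#' Predicted switch tension at a given stress
#'
#' The boundary `R_min = R_interface` corresponds to a target tension
#' `gamma_switch = sigma * R_interface`; targets below it are trogocytosed,
#' above it phagocytosed (at fixed stress).
#'
#' @param sigma_Pa active normal stress (Pa), >= 0; vectorized.
#' @param R_interface_um interface size (um), > 0.
#' @return tension (mN/m).
#' @export
predict_switch_tension <- function(sigma_Pa, R_interface_um = 1) {
  if (any(!is.finite(sigma_Pa)) || any(sigma_Pa < 0)) {
    stop("`sigma_Pa` must be finite and >= 0", call. = FALSE)
  }
  check_scalar_number(R_interface_um, "R_interface_um", lower = 0,
                      strict_lower = TRUE)
  si_to_mN_per_m(sigma_Pa * um_to_m(R_interface_um))
}

#' Classify predicted macrophage behaviour
#'
#' * `no_engagement` if `rho_ab < rho_engage`;
#' * otherwise `trogocytosis` if `R_min < beta * R_interface`;
#' * otherwise `phagocytosis`.
#'
#' @param rho_ab antibody density (molecules/um^2), >= 0; vectorized.
#' @param gamma_t target cortical tension (mN/m), >= 0; vectorized
#'   (recycled against `rho_ab`).
#' @param params a [mech_params()].
#' @return character vector in `{"no_engagement", "trogocytosis",
#'   "phagocytosis"}`.
#' @export
classify_behaviour <- function(rho_ab, gamma_t, params = mech_params()) {
  if (any(!is.finite(rho_ab)) || any(rho_ab < 0)) {
    stop("`rho_ab` must be finite and >= 0", call. = FALSE)
  }
  if (any(!is.finite(gamma_t)) || any(gamma_t < 0)) {
    stop("`gamma_t` must be finite and >= 0", call. = FALSE)
  }
  n <- max(length(rho_ab), length(gamma_t))
  rho_ab <- rep_len(rho_ab, n)
  gamma_t <- rep_len(gamma_t, n)
  out <- rep("phagocytosis", n)
  engaged <- rho_ab >= params$rho_engage
  out[!engaged] <- "no_engagement"
  if (any(engaged)) {
    rmin <- r_min(gamma_t[engaged], normal_stress(rho_ab[engaged], params))
    out[engaged][rmin < params$beta * params$R_interface] <- "trogocytosis"
  }
  out
}

#' Build the behaviour phase diagram
#'
#' Labels every cell of a (antibody density, tension) grid via
#' [classify_behaviour()] and overlays the predicted critical-density
#' boundary `rho_crit_pred(gamma_t)` from [critical_density()]. Log-spaced
#' grids are supported (the grids are only required to be strictly
#' increasing and positive).
#'
#' @param rho_grid antibody densities (molecules/um^2), strictly increasing,
#'   > 0.
#' @param gamma_grid tensions (mN/m), strictly increasing, > 0.
#' @param params a [mech_params()].
#' @return A `phase_diagram` with `rho_grid`, `gamma_grid`, `labels` (a
#'   `length(gamma_grid) x length(rho_grid)` character matrix, rows indexed
#'   by tension) and `boundary` (data.frame `gamma_t`, `rho_crit_pred`).
#' @export
build_phase_diagram <- function(rho_grid = 10^seq(1, 4, length.out = 100),
                                gamma_grid = 10^seq(-3, 1, length.out = 100),
                                params = mech_params()) {
  for (g in list(rho_grid = rho_grid, gamma_grid = gamma_grid)) {
    if (length(g) == 0L) stop("phase-diagram grids must be non-empty",
                              call. = FALSE)
  }
  if (any(rho_grid <= 0) || any(diff(rho_grid) <= 0)) {
    stop("`rho_grid` must be strictly increasing and positive", call. = FALSE)
  }
  if (any(gamma_grid <= 0) || any(diff(gamma_grid) <= 0)) {
    stop("`gamma_grid` must be strictly increasing and positive",
         call. = FALSE)
  }
  grid <- expand.grid(rho = rho_grid, gamma = gamma_grid,
                      KEEP.OUT.ATTRS = FALSE)
  lab <- classify_behaviour(grid$rho, grid$gamma, params)
  labels <- matrix(lab, nrow = length(gamma_grid), ncol = length(rho_grid),
                   byrow = TRUE,
                   dimnames = list(gamma_t = signif(gamma_grid, 6),
                                   rho_ab = signif(rho_grid, 6)))
  structure(list(
    rho_grid = rho_grid,
    gamma_grid = gamma_grid,
    labels = labels,
    boundary = data.frame(gamma_t = gamma_grid,
                          rho_crit_pred = critical_density(gamma_grid, params)),
    params = params
  ), class = "phase_diagram")
}

#' @export
print.phase_diagram <- function(x, ...) {
  tab <- table(factor(x$labels,
                      levels = c("no_engagement", "phagocytosis", "trogocytosis")))
  cat(sprintf("Phase diagram: %d x %d grid (tension x antibody density)\n",
              length(x$gamma_grid), length(x$rho_grid)))
  cat(sprintf("  rho_ab  in [%.3g, %.3g] molecules/um^2\n",
              min(x$rho_grid), max(x$rho_grid)))
  cat(sprintf("  gamma_t in [%.3g, %.3g] mN/m\n",
              min(x$gamma_grid), max(x$gamma_grid)))
  cat("  cells: ", paste(sprintf("%s %d", names(tab), tab), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.phase_diagram <- function(x, ...) {
  data.frame(
    rho_ab = rep(x$rho_grid, times = length(x$gamma_grid)),
    gamma_t = rep(x$gamma_grid, each = length(x$rho_grid)),
    label = as.vector(t(x$labels))
  )
}

#' Plot a phase diagram
#'
#' ggplot2 raster of the behaviour labels on log-log axes with the
#' critical-density boundary overlaid; optional per-condition measurement
#' points.
#'
#' @param x a `phase_diagram`.
#' @param points optional data.frame with columns `rho_ab`, `gamma_t` (and
#'   optionally `condition`) overlaid as measured conditions.
#' @return a ggplot object.
#' @export
plot_phase_diagram <- function(x, points = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_phase_diagram() requires the ggplot2 package", call. = FALSE)
  }
  df <- as.data.frame(x)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = rho_ab, y = gamma_t)) +
    ggplot2::geom_raster(ggplot2::aes(fill = label)) +
    ggplot2::geom_line(data = x$boundary,
                       ggplot2::aes(x = rho_crit_pred, y = gamma_t),
                       linewidth = 0.8) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "antibody density (molecules/µm²)",
                  y = "target tension (mN/m)", fill = "behaviour")
  if (!is.null(points)) {
    p <- p + ggplot2::geom_point(data = points, colour = "black", size = 2)
  }
  p
}
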