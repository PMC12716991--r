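# Sigmoid dose-response analysis. Efficiency as a function of antibody
# surface density x is modelled as
#
#   decreasing:  y = a * (1 - 1/(1 + exp(-(x - rho_crit)/d)))
#   increasing:  y = a /      (1 + exp(-(x - rho_crit)/d))
#
# with plateau a (%), inflection rho_crit (molecules/um^2) and width d
# (molecules/um^2). rho_crit is the critical antibody density separating
# behaviours; in either orientation the fitted curve equals a/2 at
# x = rho_crit. Fitting is Levenberg-Marquardt nonlinear least squares with
# an analytic Jacobian; confidence intervals come from case-resampling
# bootstrap.

#' Evaluate the sigmoid efficiency model
#'
#' @param x antibody density (molecules/um^2).
#' @param a plateau efficiency (%).
#' @param rho_crit inflection density (molecules/um^2).
#' @param d width (molecules/um^2), > 0.
#' @param direction `"decreasing"` (plateau at low density) or
#'   `"increasing"` (plateau at high density).
#' @return efficiency (%).
#' @export
sigmoid_response <- function(x, a, rho_crit, d,
                             direction = c("decreasing", "increasing")) {
  direction <- match.arg(direction)
  p <- plogis((x - rho_crit) / d)
  if (direction == "decreasing") a * (1 - p) else a * p
}

# residuals and Jacobian for nls.lm; par = c(a, rho_crit, d)
sigmoid_resid <- function(par, x, y, sign_dir) {
  p <- plogis((x - par[2]) / par[3])
  m <- if (sign_dir < 0) par[1] * (1 - p) else par[1] * p
  y - m
}

sigmoid_jac <- function(par, x, y, sign_dir) {
  z <- (x - par[2]) / par[3]
  p <- plogis(z)
  q <- p * (1 - p)
  if (sign_dir < 0) {
    cbind(-(1 - p), -par[1] * q / par[3], -par[1] * q * z / par[3])
  } else {
    cbind(-p, par[1] * q / par[3], par[1] * q * z / par[3])
  }
}

as_titration_points <- function(curve) {
  if (!is.data.frame(curve)) stop("`curve` must be a data.frame", call. = FALSE)
  nm <- names(curve)
  x <- if ("density_per_um2" %in% nm) curve$density_per_um2 else curve$x
  y <- if ("efficiency_pct" %in% nm) curve$efficiency_pct else curve$y
  if (is.null(x) || is.null(y)) {
    stop("`curve` needs columns density_per_um2/efficiency_pct (or x/y)",
         call. = FALSE)
  }
  if (any(!is.finite(x)) || any(x <= 0)) {
    stop("antibody densities must be finite and > 0", call. = FALSE)
  }
  if (any(!is.finite(y)) || any(y < 0) || any(y > 100)) {
    stop("efficiencies must lie in [0, 100]", call. = FALSE)
  }
  data.frame(x = x, y = y)
}

#' Fit the sigmoid efficiency model to a titration curve
#'
#' Levenberg-Marquardt least squares with analytic Jacobian. Starting
#' values: `a0 = max(y)`, `rho0 =` the density whose efficiency is nearest
#' `a0/2`, `d0 = (max(x) - min(x))/4`. Box constraints: `a` in (0, 100\],
#' `d > 0`, `rho_crit` in `[0.5 * min(x), 2 * max(x)]`. A fit on constant
#' efficiencies is flagged non-identifiable rather than returned silently.
#'
#' @param curve data.frame with columns `density_per_um2` and
#'   `efficiency_pct` (or `x`/`y`); at least 4 points.
#' @param direction sigmoid orientation, see [sigmoid_response()]. Use
#'   `"increasing"` when efficiency rises with antibody density (e.g. the
#'   rescue of trogocytosis of stiffened cells at high antibody).
#' @param start optional named vector `c(a=, rho_crit=, d=)` overriding the
#'   default initialization.
#' @return A `sigmoid_fit` with elements `a`, `rho_crit`, `d`, `rss`,
#'   `converged`, `identifiable`, `direction`, `n_points`, `message`,
#'   `ci95_rho_crit` (`NA` until [bootstrap_rho_crit()] is run) and `data`.
#' @export
fit_sigmoid <- function(curve, direction = c("decreasing", "increasing"),
                        start = NULL) {
  direction <- match.arg(direction)
  pts <- as_titration_points(curve)
  if (nrow(pts) < 4L) {
    stop("need at least 4 titration points to fit a sigmoid", call. = FALSE)
  }
  sign_dir <- if (direction == "decreasing") -1 else 1
  out <- list(direction = direction, n_points = nrow(pts), data = pts,
              ci95_rho_crit = c(NA_real_, NA_real_))
  if (diff(range(pts$y)) < sqrt(.Machine$double.eps)) {
    out <- c(out, list(a = NA_real_, rho_crit = NA_real_, d = NA_real_,
                       rss = NA_real_, converged = FALSE, identifiable = FALSE,
                       message = "all efficiencies identical: sigmoid not identifiable"))
    return(structure(out, class = "sigmoid_fit"))
  }
  if (is.null(start)) {
    a0 <- min(100, max(pts$y))
    rho0 <- pts$x[which.min(abs(pts$y - a0 / 2))]
    d0 <- diff(range(pts$x)) / 4
    start <- c(a = a0, rho_crit = rho0, d = d0)
  }
  lower <- c(1e-6, 0.5 * min(pts$x), 1e-9)
  upper <- c(100, 2 * max(pts$x), Inf)
  start_c <- pmin(pmax(unname(start[c("a", "rho_crit", "d")]), lower), upper)
  fit <- minpack.lm::nls.lm(
    par = start_c, lower = lower, upper = upper,
    fn = sigmoid_resid, jac = sigmoid_jac,
    x = pts$x, y = pts$y, sign_dir = sign_dir,
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  converged <- fit$info %in% 1:4 && all(is.finite(fit$par))
  out <- c(out, list(
    a = fit$par[1], rho_crit = fit$par[2], d = fit$par[3],
    rss = fit$deviance, converged = converged, identifiable = TRUE,
    message = fit$message, start = setNames(start_c, c("a", "rho_crit", "d"))
  ))
  structure(out, class = "sigmoid_fit")
}

#' @export
print.sigmoid_fit <- function(x, ...) {
  cat(sprintf("Sigmoid fit (%s), %d points:\n", x$direction, x$n_points))
  if (!x$identifiable) {
    cat("  non-identifiable:", x$message, "\n")
    return(invisible(x))
  }
  cat(sprintf("  plateau a  : %.4g %%\n", x$a))
  cat(sprintf("  rho_crit   : %.4g molecules/um^2", x$rho_crit))
  if (all(is.finite(x$ci95_rho_crit))) {
    cat(sprintf("  (95%% CI %.4g-%.4g)", x$ci95_rho_crit[1], x$ci95_rho_crit[2]))
  }
  cat("\n")
  cat(sprintf("  width d    : %.4g molecules/um^2\n", x$d))
  cat(sprintf("  RSS %.4g, converged: %s\n", x$rss, x$converged))
  invisible(x)
}

#' Bootstrap confidence interval for the critical antibody density
#'
#' Case-resampling bootstrap: titration points are resampled with
#' replacement, the sigmoid refit (starting from the base fit's parameters),
#' and the percentile 2.5/97.5 interval of the refitted `rho_crit` values
#' taken. Replicates that fail to converge or are non-identifiable are
#' dropped and counted; more than 50% failures is an error.
#'
#' @param curve titration data (as in [fit_sigmoid()]).
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed integer RNG seed.
#' @param direction sigmoid orientation.
#' @param base_fit optional pre-computed converged [fit_sigmoid()] result.
#' @return list with `interval` (length-2), `rho_boot`, `n_failed`,
#'   `n_boot`, and the updated `fit` (its `ci95_rho_crit` filled in).
#' @export
bootstrap_rho_crit <- function(curve, n_boot = 1000L, seed = 1L,
                               direction = c("decreasing", "increasing"),
                               base_fit = NULL) {
  direction <- match.arg(direction)
  pts <- as_titration_points(curve)
  if (is.null(base_fit)) base_fit <- fit_sigmoid(pts, direction = direction)
  if (!isTRUE(base_fit$converged)) {
    stop("base sigmoid fit did not converge; cannot bootstrap", call. = FALSE)
  }
  check_scalar_number(n_boot, "n_boot", lower = 1)
  n <- nrow(pts)
  sign_dir <- if (direction == "decreasing") -1 else 1
  lower <- c(1e-6, 0.5 * min(pts$x), 1e-9)
  upper <- c(100, 2 * max(pts$x), Inf)
  start <- pmin(pmax(c(base_fit$a, base_fit$rho_crit, base_fit$d), lower), upper)
  rho <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      i <- sample.int(n, n, replace = TRUE)
      if (diff(range(pts$y[i])) < sqrt(.Machine$double.eps)) return(NA_real_)
      f <- minpack.lm::nls.lm(
        par = start, lower = lower, upper = upper,
        fn = sigmoid_resid, jac = sigmoid_jac,
        x = pts$x[i], y = pts$y[i], sign_dir = sign_dir,
        control = minpack.lm::nls.lm.control(maxiter = 200))
      if (f$info %in% 1:4 && all(is.finite(f$par))) f$par[2] else NA_real_
    }, numeric(1))
  })
  n_failed <- sum(is.na(rho))
  if (n_failed > n_boot / 2) {
    stop(sprintf("unstable fit: %d of %d bootstrap replicates failed",
                 n_failed, n_boot), call. = FALSE)
  }
  interval <- unname(quantile(rho, c(0.025, 0.975), na.rm = TRUE, type = 7))
  base_fit$ci95_rho_crit <- interval
  list(interval = interval, rho_boot = rho[!is.na(rho)],
       n_failed = n_failed, n_boot = as.integer(n_boot), fit = base_fit)
}

#' Linear scaling of the critical antibody density with cortical tension
#'
#' The mechanical model predicts that the critical antibody density grows
#' proportionally with target cortical tension. This fits an ordinary
#' least-squares line `rho_crit ~ gamma_t` through per-condition points and
#' computes a case-resampling bootstrap 95% envelope of the fitted line on a
#' tension grid. The reported band is widened, where necessary, to contain
#' the point fit at every grid value.
#'
#' @param points data.frame with columns `gamma_t` (mN/m) and `rho_crit`
#'   (molecules/um^2); at least 3 rows with at least 2 distinct tensions.
#' @param n_boot bootstrap replicates (default 1000); 0 skips the envelope.
#' @param seed integer RNG seed.
#' @param gamma_grid tensions (mN/m) at which the envelope is evaluated;
#'   default a 50-point grid over the data range.
#' @return A `tension_density_fit` with `slope`, `intercept`,
#'   `slope_positive`, `band` (data.frame `gamma_t`, `fit`, `lo`, `hi`),
#'   `n_dropped` (rank-deficient resamples) and the input points.
#' @export
fit_rho_crit_vs_tension <- function(points, n_boot = 1000L, seed = 1L,
                                    gamma_grid = NULL) {
  if (!is.data.frame(points) ||
      !all(c("gamma_t", "rho_crit") %in% names(points))) {
    stop("`points` must have columns `gamma_t` and `rho_crit`", call. = FALSE)
  }
  if (nrow(points) < 3L) {
    stop("need at least 3 (gamma_t, rho_crit) points", call. = FALSE)
  }
  if (length(unique(points$gamma_t)) < 2L) {
    stop("rank-deficient fit: all points share a single tension value",
         call. = FALSE)
  }
  check_scalar_number(n_boot, "n_boot", lower = 0)
  base <- lm(rho_crit ~ gamma_t, data = points)
  slope <- unname(coef(base)[2])
  intercept <- unname(coef(base)[1])
  if (is.null(gamma_grid)) {
    gamma_grid <- seq(min(points$gamma_t), max(points$gamma_t), length.out = 50)
  }
  fit_line <- intercept + slope * gamma_grid
  n <- nrow(points)
  n_dropped <- 0L
  if (n_boot >= 1) {
    lines_boot <- with_seed(seed, {
      vapply(seq_len(n_boot), function(b) {
        i <- sample.int(n, n, replace = TRUE)
        if (length(unique(points$gamma_t[i])) < 2L) return(rep(NA_real_, length(gamma_grid)))
        cf <- coef(lm(rho_crit ~ gamma_t, data = points[i, , drop = FALSE]))
        cf[1] + cf[2] * gamma_grid
      }, numeric(length(gamma_grid)))
    })
    ok <- colSums(is.na(lines_boot)) == 0L
    n_dropped <- sum(!ok)
    lo <- apply(lines_boot[, ok, drop = FALSE], 1, quantile, probs = 0.025,
                type = 7)
    hi <- apply(lines_boot[, ok, drop = FALSE], 1, quantile, probs = 0.975,
                type = 7)
    lo <- pmin(lo, fit_line)
    hi <- pmax(hi, fit_line)
  } else {
    lo <- hi <- fit_line
  }
  structure(list(
    slope = slope, intercept = intercept, slope_positive = slope > 0,
    band = data.frame(gamma_t = gamma_grid, fit = fit_line, lo = lo, hi = hi),
    n_boot = as.integer(n_boot), n_dropped = n_dropped, points = points
  ), class = "tension_density_fit")
}

#' @export
print.tension_density_fit <- function(x, ...) {
  cat("Linear fit rho_crit ~ gamma_t:\n")
  cat(sprintf("  slope     : %.4g (molecules/um^2) per (mN/m)%s\n", x$slope,
              if (x$slope_positive) "  [positive]" else "  [negative]"))
  cat(sprintf("  intercept : %.4g molecules/um^2\n", x$intercept))
  cat(sprintf("  bootstrap : %d replicates (%d dropped), 95%% envelope on %d grid points\n",
              x$n_boot, x$n_dropped, nrow(x$band)))
  invisible(x)
}

#' Pearson correlation between efficiency and tension
#'
#' Standard Pearson correlation with a two-sided p-value, as used to test
#' whether trogocytic efficiency falls with target cortical tension.
#'
#' @param gamma_t tensions (mN/m).
#' @param efficiency efficiencies (%).
#' @return list with `r`, `p_value`, `n`.
#' @export
correlate_efficiency_tension <- function(gamma_t, efficiency) {
  if (length(gamma_t) != length(efficiency) || length(gamma_t) < 3L) {
    stop("need at least 3 paired (gamma_t, efficiency) observations",
         call. = FALSE)
  }
  if (sd(gamma_t) == 0 || sd(efficiency) == 0) {
    stop("correlation undefined: zero variance on one axis", call. = FALSE)
  }
  ct <- cor.test(gamma_t, efficiency, method = "pearson",
                 alternative = "two.sided")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(gamma_t))
}
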