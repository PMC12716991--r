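# Synthetic data generators. Each generator is seeded and deterministic:
# identical configuration + seed yields byte-identical output. They emulate
# the statistical structure of the assays (log-normal fluorescence
# subpopulations, Laplace-law aspiration pressures with Gaussian sensor
# noise, sigmoid titration curves, linear MESF bead responses) so every
# downstream estimator can be exercised and validated without instrument
# data.

#' Default per-subpopulation fluorescence channel parameters
#'
#' Location/scale (log10 arbitrary-fluorescence units) for each of the three
#' channels in each macrophage subpopulation. A channel a subpopulation is
#' positive for sits two decades above the negative/background location, the
#' usual separation of a cleanly gated cytometry positive population:
#'
#' * `phago`: positive on all three channels (macrophage cytosol marker,
#'   target volume marker delivered to the phagolysosome, target surface
#'   antibody);
#' * `trogo`: positive on cytosol and surface-antibody channels, negative on
#'   the volume channel (bites carry membrane but no acidified volume);
#' * `neither`: positive on the cytosol channel only.
#'
#' @param positive_log10 location (log10 a.u.) of positive populations.
#' @param negative_log10 location (log10 a.u.) of negative populations.
#' @param spread_log10 scale (log10 a.u.) of every population.
#' @return Nested list `channel_params[[label]][[channel]] = c(location,
#'   scale)` accepted by [coculture_config()].
#' @export
default_channel_params <- function(positive_log10 = 4, negative_log10 = 2,
                                   spread_log10 = 0.2) {
  pos <- c(positive_log10, spread_log10)
  neg <- c(negative_log10, spread_log10)
  list(
    phago   = list(ch_ctg = pos, ch_rho = pos, ch_af647 = pos),
    trogo   = list(ch_ctg = pos, ch_rho = neg, ch_af647 = pos),
    neither = list(ch_ctg = pos, ch_rho = neg, ch_af647 = neg)
  )
}

#' Configuration for a synthetic macrophage-target coculture
#'
#' Describes a mixture of macrophage subpopulations (`phago`, `trogo`,
#' `neither`) with per-channel log-normal fluorescence distributions, plus a
#' background (unstained) distribution used for control samples.
#'
#' @param n_events number of macrophage events to generate.
#' @param fraction_phago,fraction_trogo,fraction_neither subpopulation
#'   fractions; must sum to 1 within 1e-12.
#' @param channel_params nested list as returned by
#'   [default_channel_params()]; location/scale in log10 a.u., scale > 0.
#' @param background_params `c(location, scale)` (log10 a.u.) of the
#'   negative/unstained population, used on every channel of control events.
#' @param allocation `"exact"` (largest-remainder rounding of the fractions,
#'   so subpopulation counts are deterministic) or `"multinomial"`.
#' @param seed integer RNG seed.
#' @return A `coculture_config` list.
#' @export
coculture_config <- function(n_events = 1e5,
                             fraction_phago = 0.2,
                             fraction_trogo = 0.6,
                             fraction_neither = 0.2,
                             channel_params = default_channel_params(),
                             background_params = c(2, 0.2),
                             allocation = c("exact", "multinomial"),
                             seed = 1L) {
  allocation <- match.arg(allocation)
  cfg <- structure(list(
    n_events = n_events,
    fractions = c(phago = fraction_phago, trogo = fraction_trogo,
                  neither = fraction_neither),
    channel_params = channel_params,
    background_params = background_params,
    allocation = allocation,
    seed = seed
  ), class = "coculture_config")
  validate_coculture_config(cfg)
  cfg
}

validate_coculture_config <- function(cfg) {
  if (!is.numeric(cfg$n_events) || length(cfg$n_events) != 1L ||
      cfg$n_events < 1 || cfg$n_events != round(cfg$n_events)) {
    stop("`n_events` must be a positive integer count", call. = FALSE)
  }
  f <- cfg$fractions
  if (any(f < 0) || any(f > 1) || abs(sum(f) - 1) > 1e-12) {
    stop("subpopulation fractions must lie in [0, 1] and sum to 1 (within 1e-12)",
         call. = FALSE)
  }
  labs <- c("phago", "trogo", "neither")
  chans <- c("ch_ctg", "ch_rho", "ch_af647")
  if (!all(labs %in% names(cfg$channel_params))) {
    stop("`channel_params` must have entries for phago, trogo and neither",
         call. = FALSE)
  }
  for (lab in labs) {
    for (ch in chans) {
      p <- cfg$channel_params[[lab]][[ch]]
      if (is.null(p) || length(p) != 2L || !all(is.finite(p)) || p[2] <= 0) {
        stop(sprintf("channel_params$%s$%s must be c(location, scale) with scale > 0",
                     lab, ch), call. = FALSE)
      }
    }
  }
  bp <- cfg$background_params
  if (length(bp) != 2L || !all(is.finite(bp)) || bp[2] <= 0) {
    stop("`background_params` must be c(location, scale) with scale > 0",
         call. = FALSE)
  }
  invisible(cfg)
}

#' Generate a synthetic coculture event table
#'
#' Draws `n_events` macrophage events from the configured mixture. Each
#' event carries three channel intensities drawn log-normally (base 10) from
#' its subpopulation's location/scale and a ground-truth label. With
#' `allocation = "exact"` (default) subpopulation counts are the
#' largest-remainder rounding of `n_events * fractions`, so label
#' bookkeeping is deterministic; only intensities (and the row shuffle) are
#' random, under the config seed.
#'
#' @param config a [coculture_config()].
#' @return data.frame with columns `event_id`, `ch_ctg`, `ch_rho`,
#'   `ch_af647`, `true_label`.
#' @export
generate_coculture_events <- function(config) {
  validate_coculture_config(config)
  n <- as.integer(config$n_events)
  labs <- c("phago", "trogo", "neither")
  counts <- if (config$allocation == "exact") {
    largest_remainder(n, config$fractions[labs])
  } else {
    with_seed(config$seed + 1L,
              as.integer(stats::rmultinom(1, n, config$fractions[labs])))
  }
  names(counts) <- labs
  chans <- c("ch_ctg", "ch_rho", "ch_af647")
  with_seed(config$seed, {
    cols <- lapply(chans, function(ch) {
      unlist(lapply(labs, function(lab) {
        p <- config$channel_params[[lab]][[ch]]
        10^rnorm(counts[[lab]], mean = p[1], sd = p[2])
      }), use.names = FALSE)
    })
    names(cols) <- chans
    tab <- data.frame(
      event_id = seq_len(n),
      cols,
      true_label = rep(labs, counts),
      stringsAsFactors = FALSE
    )
    # shuffle so subpopulations are interleaved as on an instrument
    tab <- tab[sample.int(n), , drop = FALSE]
    tab$event_id <- seq_len(n)
    rownames(tab) <- NULL
    tab
  })
}

#' Generate a synthetic unstained control event table
#'
#' Control events draw all three channels from the background distribution;
#' their per-channel upper quantiles define gating thresholds via
#' [derive_thresholds()].
#'
#' @param n_events number of control events.
#' @param background_params `c(location, scale)` in log10 a.u.
#' @param seed integer RNG seed.
#' @return data.frame with columns `event_id`, `ch_ctg`, `ch_rho`, `ch_af647`.
#' @export
generate_control_events <- function(n_events = 1e4,
                                    background_params = c(2, 0.2),
                                    seed = 1L) {
  check_scalar_number(n_events, "n_events", lower = 1)
  if (length(background_params) != 2L || background_params[2] <= 0) {
    stop("`background_params` must be c(location, scale) with scale > 0",
         call. = FALSE)
  }
  n <- as.integer(n_events)
  with_seed(seed, {
    data.frame(
      event_id = seq_len(n),
      ch_ctg = 10^rnorm(n, background_params[1], background_params[2]),
      ch_rho = 10^rnorm(n, background_params[1], background_params[2]),
      ch_af647 = 10^rnorm(n, background_params[1], background_params[2])
    )
  })
}

#' Generate synthetic micropipette aspiration measurements
#'
#' Inverts the Young-Laplace law: for a target of tension `true_tension` the
#' noiseless suction pressure is `2 * gamma * (1/R_pipette - 1/R_cell)`
#' (computed in SI), to which Gaussian sensor noise is added.
#'
#' @param true_tension ground-truth tension (mN/m), >= 0.
#' @param pipette_radius pipette inner radius (um), > 0.
#' @param cell_radius cell or vesicle radius (um), > `pipette_radius`.
#' @param pressure_noise_sd Gaussian noise SD on the pressure (Pa).
#' @param n number of measurements.
#' @param seed integer RNG seed.
#' @return data.frame with columns `id`, `dP_suction_Pa`, `R_pipette_um`,
#'   `R_cell_um`.
#' @export
generate_aspiration_series <- function(true_tension, pipette_radius,
                                       cell_radius, pressure_noise_sd = 0,
                                       n = 10L, seed = 1L) {
  check_scalar_number(true_tension, "true_tension", lower = 0)
  check_scalar_number(pipette_radius, "pipette_radius", lower = 0,
                      strict_lower = TRUE)
  check_scalar_number(pressure_noise_sd, "pressure_noise_sd", lower = 0)
  check_scalar_number(n, "n", lower = 1)
  if (!is.numeric(cell_radius) || cell_radius <= pipette_radius) {
    stop("`cell_radius` must exceed `pipette_radius`", call. = FALSE)
  }
  dp0 <- required_suction(true_tension, pipette_radius, cell_radius)
  with_seed(seed, {
    data.frame(
      id = seq_len(as.integer(n)),
      dP_suction_Pa = dp0 + rnorm(as.integer(n), 0, pressure_noise_sd),
      R_pipette_um = pipette_radius,
      R_cell_um = cell_radius
    )
  })
}

#' Configuration for a synthetic antibody titration curve
#'
#' @param a_true plateau efficiency (%), in (0, 100].
#' @param rho_crit_true inflection antibody density (molecules/um^2).
#' @param d_true sigmoid width (molecules/um^2), > 0.
#' @param densities antibody densities sampled (molecules/um^2), > 0.
#' @param noise_sd additive Gaussian noise SD on efficiency (%).
#' @param replicates replicates per density, >= 1.
#' @param direction `"decreasing"` for the plateau-at-low-density form
#'   `a * (1 - 1/(1 + exp(-(x - rho_crit)/d)))`, `"increasing"` for its
#'   mirrored rising form (see [fit_sigmoid()]).
#' @param seed integer RNG seed.
#' @return A `titration_config` list.
#' @export
titration_config <- function(a_true = 80, rho_crit_true = 500, d_true = 100,
                             densities = c(50, 150, 300, 450, 550, 700, 900, 1200),
                             noise_sd = 4, replicates = 3L,
                             direction = c("decreasing", "increasing"),
                             seed = 1L) {
  direction <- match.arg(direction)
  check_scalar_number(a_true, "a_true", lower = 0, upper = 100,
                      strict_lower = TRUE)
  check_scalar_number(rho_crit_true, "rho_crit_true", lower = 0,
                      strict_lower = TRUE)
  if (!is.numeric(d_true) || length(d_true) != 1L || d_true <= 0) {
    stop("`d_true` must be > 0", call. = FALSE)
  }
  if (!is.numeric(densities) || length(densities) < 1L || any(densities <= 0)) {
    stop("`densities` must be strictly positive", call. = FALSE)
  }
  check_scalar_number(noise_sd, "noise_sd", lower = 0)
  check_scalar_number(replicates, "replicates", lower = 1)
  structure(list(
    a_true = a_true, rho_crit_true = rho_crit_true, d_true = d_true,
    densities = densities, noise_sd = noise_sd,
    replicates = as.integer(replicates), direction = direction, seed = seed
  ), class = "titration_config")
}

#' Generate a synthetic titration curve
#'
#' Evaluates the sigmoid efficiency model at the configured antibody
#' densities, adds Gaussian noise, and clips efficiencies to \[0, 100\].
#'
#' @param config a [titration_config()].
#' @return data.frame with columns `density_per_um2`, `efficiency_pct`,
#'   `replicate`.
#' @export
generate_titration <- function(config) {
  if (!inherits(config, "titration_config")) {
    config <- do.call(titration_config, config)
  }
  x <- rep(config$densities, each = config$replicates)
  y0 <- sigmoid_response(x, config$a_true, config$rho_crit_true,
                         config$d_true, direction = config$direction)
  with_seed(config$seed, {
    y <- pmin(100, pmax(0, y0 + rnorm(length(x), 0, config$noise_sd)))
    data.frame(
      density_per_um2 = x,
      efficiency_pct = y,
      replicate = rep(seq_len(config$replicates), times = length(config$densities))
    )
  })
}

#' Generate a synthetic MESF calibration bead table
#'
#' Beads at each MESF level respond linearly: `intensity = gain_bead * MESF *
#' (1 + eps)` with `eps ~ N(0, noise_cv)`. Note the generator's
#' `gain` is intensity per fluorophore; the fitted calibration gain of
#' [fit_mesf_calibration()] is its reciprocal (fluorophores per intensity
#' unit).
#'
#' @param mesf_levels distinct fluorophore counts of the bead populations
#'   (>= 2 levels, all positive).
#' @param gain intensity per fluorophore (a.u.).
#' @param noise_cv coefficient of variation of the multiplicative noise.
#' @param beads_per_level replicate beads measured at each level.
#' @param seed integer RNG seed.
#' @return data.frame with columns `level_id`, `mesf_count`, `intensity`.
#' @export
generate_calibration_beads <- function(mesf_levels, gain = 0.01,
                                       noise_cv = 0, beads_per_level = 50L,
                                       seed = 1L) {
  if (!is.numeric(mesf_levels) || any(mesf_levels <= 0)) {
    stop("`mesf_levels` must be positive fluorophore counts", call. = FALSE)
  }
  if (length(unique(mesf_levels)) < 2L) {
    stop("insufficient calibration: need at least 2 distinct MESF levels",
         call. = FALSE)
  }
  check_scalar_number(gain, "gain", lower = 0, strict_lower = TRUE)
  check_scalar_number(noise_cv, "noise_cv", lower = 0)
  check_scalar_number(beads_per_level, "beads_per_level", lower = 1)
  k <- as.integer(beads_per_level)
  mesf <- rep(mesf_levels, each = k)
  with_seed(seed, {
    data.frame(
      level_id = rep(seq_along(mesf_levels), each = k),
      mesf_count = mesf,
      intensity = gain * mesf * (1 + rnorm(length(mesf), 0, noise_cv))
    )
  })
}
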