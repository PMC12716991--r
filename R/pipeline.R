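# End-to-end orchestration: simulate -> gate -> tension -> density -> fit
# -> mechanics. Stages are pure functions of the configuration and seed;
# outputs are CSV files plus a JSON manifest of parameters and file hashes,
# so an identical configuration and seed reproduces byte-identical outputs.

PIPELINE_STAGES <- c("simulate", "gate", "tension", "density", "fit",
                     "mechanics")

#' Pipeline run configuration
#'
#' @param stages which stages to run, a subset of `simulate`, `gate`,
#'   `tension`, `density`, `fit`, `mechanics` (run in that dependency
#'   order).
#' @param outdir output directory (created if needed).
#' @param seed integer seed propagated (with fixed offsets) to every
#'   stochastic stage.
#' @param coculture a [coculture_config()] for the simulate stage.
#' @param titration a [titration_config()] for the simulate stage.
#' @param aspiration named list of per-group ground-truth settings, each a
#'   list with `true_tension` (mN/m), `pipette_radius`/`cell_radius` (um),
#'   `pressure_noise_sd` (Pa) and `n`.
#' @param beads list with `mesf_levels`, `gain`, `noise_cv`,
#'   `beads_per_level` for the simulate stage.
#' @param gate_quantile control quantile for [derive_thresholds()].
#' @param mesf list with `mfi`, `fluors_per_igg`, `cell_diameter_um` for the
#'   density stage.
#' @param mech a [mech_params()] for the mechanics stage.
#' @param events_file,control_file,aspiration_file,beads_file,titration_file
#'   optional pre-existing CSV inputs used when the corresponding generator
#'   stage is not enabled.
#' @return A `run_config` list.
#' @export
run_config <- function(stages = PIPELINE_STAGES,
                       outdir = tempfile("trogomech-run-"),
                       seed = 1L,
                       coculture = coculture_config(n_events = 2e4, seed = seed),
                       titration = titration_config(seed = seed + 1L),
                       aspiration = list(
                         low_tension = list(true_tension = 0.26,
                                            pipette_radius = 2.5,
                                            cell_radius = 7.5,
                                            pressure_noise_sd = 5, n = 15L),
                         high_tension = list(true_tension = 11.7,
                                             pipette_radius = 2.5,
                                             cell_radius = 7.5,
                                             pressure_noise_sd = 5, n = 12L)),
                       beads = list(mesf_levels = c(1e4, 1e5, 1e6),
                                    gain = 0.01, noise_cv = 0.02,
                                    beads_per_level = 50L),
                       gate_quantile = 0.999,
                       mesf = list(mfi = 1.2e4, fluors_per_igg = 6,
                                   cell_diameter_um = 10),
                       mech = mech_params(),
                       events_file = NULL, control_file = NULL,
                       aspiration_file = NULL, beads_file = NULL,
                       titration_file = NULL) {
  stages <- match.arg(stages, PIPELINE_STAGES, several.ok = TRUE)
  structure(list(
    stages = PIPELINE_STAGES[PIPELINE_STAGES %in% stages],
    outdir = outdir, seed = as.integer(seed),
    coculture = coculture, titration = titration, aspiration = aspiration,
    beads = beads, gate_quantile = gate_quantile, mesf = mesf, mech = mech,
    events_file = events_file, control_file = control_file,
    aspiration_file = aspiration_file, beads_file = beads_file,
    titration_file = titration_file
  ), class = "run_config")
}

need_input <- function(path, stage, what) {
  if (is.null(path) || !file.exists(path)) {
    stop(sprintf(
      "stage `%s` needs %s: enable the `simulate` stage or supply the file",
      stage, what), call. = FALSE)
  }
  path
}

#' Run the analysis pipeline
#'
#' Executes the enabled stages in dependency order, writes every tabular
#' output as CSV under `config$outdir`, and returns (and writes as JSON) a
#' manifest recording the stages run, parameters, seed, headline results and
#' an MD5 hash of every output file. The manifest carries no timestamps, so
#' identical configuration and seed give identical manifests.
#'
#' @param config a [run_config()].
#' @return The manifest, invisibly a list (also written to
#'   `manifest.json`).
#' @export
run_pipeline <- function(config = run_config()) {
  if (!inherits(config, "run_config")) {
    stop("`config` must be a run_config object", call. = FALSE)
  }
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  path <- function(f) file.path(config$outdir, f)
  results <- list()
  outputs <- character()

  if ("simulate" %in% config$stages) {
    events <- generate_coculture_events(config$coculture)
    control <- generate_control_events(
      n_events = 1e4,
      background_params = config$coculture$background_params,
      seed = config$seed + 101L)
    write_table_csv(events, path("events.csv"))
    write_table_csv(control, path("control.csv"))
    asp <- do.call(rbind, lapply(names(config$aspiration), function(g) {
      a <- config$aspiration[[g]]
      tab <- generate_aspiration_series(
        a$true_tension, a$pipette_radius, a$cell_radius,
        a$pressure_noise_sd, a$n,
        seed = config$seed + 200L + match(g, names(config$aspiration)))
      tab$group <- g
      tab
    }))
    write_table_csv(asp, path("aspiration.csv"))
    bead_tab <- generate_calibration_beads(
      config$beads$mesf_levels, config$beads$gain, config$beads$noise_cv,
      config$beads$beads_per_level, seed = config$seed + 301L)
    write_table_csv(bead_tab, path("beads.csv"))
    titr <- generate_titration(config$titration)
    write_table_csv(titr, path("titration.csv"))
    outputs <- c(outputs, path(c("events.csv", "control.csv",
                                 "aspiration.csv", "beads.csv",
                                 "titration.csv")))
    config$events_file <- path("events.csv")
    config$control_file <- path("control.csv")
    config$aspiration_file <- path("aspiration.csv")
    config$beads_file <- path("beads.csv")
    config$titration_file <- path("titration.csv")
    results$simulate <- list(n_events = nrow(events))
  }

  if ("gate" %in% config$stages) {
    events <- read_event_table(need_input(config$events_file, "gate",
                                          "an event table"))
    control <- read_event_table(need_input(config$control_file, "gate",
                                           "a control event table"))
    thr <- derive_thresholds(control, quantile = config$gate_quantile)
    labelled <- classify_events(events, thr)
    eff <- compute_efficiencies(labelled)
    write_table_csv(labelled, path("events_labelled.csv"))
    outputs <- c(outputs, path("events_labelled.csv"))
    results$gate <- list(
      thresholds = unclass(thr)[c("thr_ctg", "thr_rho", "thr_af647")],
      n_macrophage = eff$n_macrophage,
      phagocytic_efficiency = eff$phagocytic_efficiency,
      trogocytic_efficiency = eff$trogocytic_efficiency)
  }

  if ("tension" %in% config$stages) {
    asp <- read_aspiration_table(need_input(config$aspiration_file, "tension",
                                            "an aspiration table"))
    gamma <- tension_from_aspiration(pmax(asp$dP_suction_Pa, 0),
                                     asp$R_pipette_um, asp$R_cell_um)
    grp <- if ("group" %in% names(asp)) asp$group else rep("all", nrow(asp))
    summ <- summarize_tensions(gamma, grp)
    write_table_csv(cbind(asp, gamma_mN_per_m = gamma),
                    path("tension_estimates.csv"))
    write_table_csv(summ, path("tension_summary.csv"))
    outputs <- c(outputs, path(c("tension_estimates.csv",
                                 "tension_summary.csv")))
    results$tension <- summ
  }

  if ("density" %in% config$stages) {
    beads <- read.csv(need_input(config$beads_file, "density",
                                 "a bead calibration table"))
    cal <- fit_mesf_calibration(beads)
    dens <- density_from_fluorescence(config$mesf$mfi, cal,
                                      config$mesf$fluors_per_igg,
                                      config$mesf$cell_diameter_um)
    results$density <- list(gain = cal$gain, intercept = cal$intercept,
                            mfi = config$mesf$mfi,
                            density_per_um2 = dens$density)
  }

  if ("fit" %in% config$stages) {
    titr <- read_titration_table(need_input(config$titration_file, "fit",
                                            "a titration table"))
    direction <- if (!is.null(config$titration$direction)) {
      config$titration$direction
    } else "decreasing"
    boot <- bootstrap_rho_crit(titr, n_boot = 1000L,
                               seed = config$seed + 401L,
                               direction = direction)
    results$fit <- list(a = boot$fit$a, rho_crit = boot$fit$rho_crit,
                        d = boot$fit$d, ci95_rho_crit = boot$interval,
                        converged = boot$fit$converged,
                        n_failed = boot$n_failed)
  }

  if ("mechanics" %in% config$stages) {
    pd <- build_phase_diagram(params = config$mech)
    write_table_csv(as.data.frame(pd), path("phase_diagram.csv"))
    write_table_csv(pd$boundary, path("phase_boundary.csv"))
    outputs <- c(outputs, path(c("phase_diagram.csv", "phase_boundary.csv")))
    results$mechanics <- list(
      grid = c(length(pd$gamma_grid), length(pd$rho_grid)),
      switch_tension_at_100Pa = predict_switch_tension(
        100, config$mech$R_interface))
  }

  manifest <- list(
    package = "trogomech",
    seed = config$seed,
    stages = config$stages,
    parameters = list(gate_quantile = config$gate_quantile,
                      mech = unclass(config$mech),
                      mesf = config$mesf),
    results = results,
    outputs = as.list(setNames(unname(tools::md5sum(outputs)),
                               basename(outputs)))
  )
  jsonlite::write_json(manifest, path("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Render a plain-text report from a pipeline manifest
#'
#' Tabulates the headline results of each completed stage: gating
#' efficiencies, per-group tensions, calibration gain and converted
#' density, the sigmoid fit with its confidence interval, and the
#' phase-diagram placement of the measured condition. Stages missing from
#' the manifest are reported as warnings, not errors.
#'
#' @param manifest a manifest as returned by [run_pipeline()] (or read back
#'   from `manifest.json`).
#' @return character vector of report lines, invisibly; also printed.
#' @export
make_report <- function(manifest) {
  lines <- c("trogomech pipeline report",
             sprintf("seed: %s; stages: %s", manifest$seed,
                     paste(unlist(manifest$stages), collapse = ", ")))
  res <- manifest$results
  if (length(res) == 0L) {
    warning("manifest contains no stage results", call. = FALSE)
    lines <- c(lines, "(no stage results)")
  }
  if (!is.null(res$gate)) {
    lines <- c(lines, sprintf(
      "gating: %s macrophages; phagocytic %.2f%%, trogocytic %.2f%%",
      res$gate$n_macrophage, res$gate$phagocytic_efficiency,
      res$gate$trogocytic_efficiency))
  } else if (length(res) > 0L) {
    warning("no gating results in manifest", call. = FALSE)
  }
  if (!is.null(res$tension)) {
    tn <- as.data.frame(res$tension)
    lines <- c(lines, apply(tn, 1, function(r) sprintf(
      "tension [%s]: mean %.3g mN/m (sd %s, n %s)", r[["group"]],
      as.numeric(r[["mean_mN_per_m"]]), r[["sd_mN_per_m"]], r[["n"]])))
  }
  if (!is.null(res$density)) {
    lines <- c(lines, sprintf(
      "density: gain %.4g fluor/a.u.; MFI %.4g -> %.4g molecules/um^2",
      res$density$gain, res$density$mfi, res$density$density_per_um2))
  }
  if (!is.null(res$fit)) {
    ci <- unlist(res$fit$ci95_rho_crit)
    lines <- c(lines, sprintf(
      "sigmoid: a %.3g%%, rho_crit %.4g (95%% CI %.4g-%.4g), d %.4g",
      res$fit$a, res$fit$rho_crit, ci[1], ci[2], res$fit$d))
    if (!is.null(res$density) && !is.null(res$tension)) {
      tn <- as.data.frame(res$tension)
      mech <- do.call(mech_params, manifest$parameters$mech)
      for (i in seq_len(nrow(tn))) {
        beh <- classify_behaviour(res$density$density_per_um2,
                                  as.numeric(tn$mean_mN_per_m[i]), mech)
        lines <- c(lines, sprintf(
          "phase placement [%s]: rho %.4g at %.3g mN/m -> %s",
          tn$group[i], res$density$density_per_um2,
          as.numeric(tn$mean_mN_per_m[i]), beh))
      }
    }
  }
  cat(paste(lines, collapse = "\n"), "\n")
  invisible(lines)
}
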