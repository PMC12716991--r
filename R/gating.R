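# Three-channel gating of macrophage events. An event is a macrophage if it
# is positive for the cytosol marker (ch_ctg); a macrophage is scored
# phagocytic if additionally positive for the target volume marker (ch_rho,
# acidified phagolysosome) AND the target surface antibody (ch_af647), and
# trogocytic if positive for the surface antibody but NOT the volume marker.
# Positivity is strict (intensity > threshold): a tie does not count as
# signal.

EVENT_CHANNELS <- c("ch_ctg", "ch_rho", "ch_af647")

check_event_table <- function(events, require_labels = FALSE) {
  if (!is.data.frame(events)) stop("event table must be a data.frame",
                                   call. = FALSE)
  missing <- setdiff(EVENT_CHANNELS, names(events))
  if (length(missing)) {
    stop("event table is missing channel(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  for (ch in EVENT_CHANNELS) {
    if (!is.numeric(events[[ch]]) || any(!is.finite(events[[ch]])) ||
        any(events[[ch]] < 0)) {
      stop(sprintf("channel `%s` must be finite and non-negative", ch),
           call. = FALSE)
    }
  }
  if (require_labels && !"label" %in% names(events)) {
    stop("event table has no `label` column; run classify_events() first",
         call. = FALSE)
  }
  invisible(events)
}

#' Derive gating thresholds from a control sample
#'
#' Each channel's threshold is an upper quantile of that channel's intensity
#' distribution in an unstained/background control sample, using the
#' linear-interpolation quantile definition (`stats::quantile()` type 7).
#'
#' @param control_events control event table (non-empty) with columns
#'   `ch_ctg`, `ch_rho`, `ch_af647`.
#' @param quantile background quantile in (0, 1); default 0.999, i.e. a
#'   nominal 0.1% background false-positive rate per channel.
#' @return A `gating_thresholds` object with elements `thr_ctg`, `thr_rho`,
#'   `thr_af647` and a `provenance` string recording the control size and
#'   quantile rule.
#' @export
derive_thresholds <- function(control_events, quantile = 0.999) {
  check_event_table(control_events)
  if (nrow(control_events) == 0L) {
    stop("control event table is empty", call. = FALSE)
  }
  if (!is.numeric(quantile) || length(quantile) != 1L ||
      quantile <= 0 || quantile >= 1) {
    stop("`quantile` must lie strictly between 0 and 1", call. = FALSE)
  }
  thr <- vapply(EVENT_CHANNELS, function(ch) {
    unname(stats::quantile(control_events[[ch]], probs = quantile, type = 7))
  }, numeric(1))
  structure(list(
    thr_ctg = thr[["ch_ctg"]],
    thr_rho = thr[["ch_rho"]],
    thr_af647 = thr[["ch_af647"]],
    provenance = sprintf(
      "per-channel %.4g quantile (linear interpolation, type 7) of a %d-event control sample",
      quantile, nrow(control_events))
  ), class = "gating_thresholds")
}

#' Manually specified gating thresholds
#'
#' @param thr_ctg,thr_rho,thr_af647 per-channel intensity cutoffs (> 0).
#' @param provenance free-text description of where the cutoffs came from.
#' @return A `gating_thresholds` object.
#' @export
gating_thresholds <- function(thr_ctg, thr_rho, thr_af647,
                              provenance = "manual") {
  for (v in c(thr_ctg, thr_rho, thr_af647)) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop("all thresholds must be single positive numbers", call. = FALSE)
    }
  }
  structure(list(thr_ctg = thr_ctg, thr_rho = thr_rho, thr_af647 = thr_af647,
                 provenance = provenance),
            class = "gating_thresholds")
}

#' @export
print.gating_thresholds <- function(x, ...) {
  cat("Gating thresholds (a.u.):\n")
  cat(sprintf("  ch_ctg   (macrophage cytosol) : %.4g\n", x$thr_ctg))
  cat(sprintf("  ch_rho   (target volume)      : %.4g\n", x$thr_rho))
  cat(sprintf("  ch_af647 (target surface IgG) : %.4g\n", x$thr_af647))
  cat("  provenance:", x$provenance, "\n")
  invisible(x)
}

#' Classify events into phagocytosis / trogocytosis / neither
#'
#' Positivity on each channel is strict (`intensity > threshold`). Events
#' negative for the macrophage cytosol marker are flagged non-macrophage
#' (`macrophage = FALSE`, `label = NA`) and are excluded from all efficiency
#' denominators. Among macrophages:
#' * `phago`: positive on all three channels;
#' * `trogo`: positive on cytosol and surface-antibody channels, negative on
#'   the volume channel;
#' * `neither`: any other macrophage event.
#'
#' @param events event table with channel columns.
#' @param thresholds a `gating_thresholds` object.
#' @return The event table with logical columns `macrophage`, `pos_rho`,
#'   `pos_af647` and a character `label` column (`NA` for non-macrophage
#'   events).
#' @export
classify_events <- function(events, thresholds) {
  check_event_table(events)
  if (!inherits(thresholds, "gating_thresholds")) {
    stop("`thresholds` must be a gating_thresholds object", call. = FALSE)
  }
  pos_ctg <- events$ch_ctg > thresholds$thr_ctg
  pos_rho <- events$ch_rho > thresholds$thr_rho
  pos_af647 <- events$ch_af647 > thresholds$thr_af647
  label <- rep(NA_character_, nrow(events))
  label[pos_ctg] <- "neither"
  label[pos_ctg & pos_af647 & pos_rho] <- "phago"
  label[pos_ctg & pos_af647 & !pos_rho] <- "trogo"
  events$macrophage <- pos_ctg
  events$pos_rho <- pos_rho
  events$pos_af647 <- pos_af647
  events$label <- label
  events
}

#' Compute phagocytic and trogocytic efficiencies
#'
#' Efficiency is the percentage of macrophage-marker-positive events carrying
#' each label: `100 * n_phago / n_macrophage` and `100 * n_trogo /
#' n_macrophage`. Requires at least one macrophage event (a zero denominator
#' is an error, not a 0/0).
#'
#' @param labelled event table as returned by [classify_events()].
#' @return An `efficiency_result` with counts and efficiencies (%).
#' @export
compute_efficiencies <- function(labelled) {
  check_event_table(labelled, require_labels = TRUE)
  if (!"macrophage" %in% names(labelled)) {
    stop("event table has no `macrophage` column; run classify_events() first",
         call. = FALSE)
  }
  n_mac <- sum(labelled$macrophage)
  if (n_mac == 0L) {
    stop("no macrophage-marker-positive events: efficiency denominator is zero",
         call. = FALSE)
  }
  n_phago <- sum(labelled$label == "phago", na.rm = TRUE)
  n_trogo <- sum(labelled$label == "trogo", na.rm = TRUE)
  structure(list(
    n_macrophage = n_mac,
    n_phago = n_phago,
    n_trogo = n_trogo,
    phagocytic_efficiency = 100 * n_phago / n_mac,
    trogocytic_efficiency = 100 * n_trogo / n_mac
  ), class = "efficiency_result")
}

#' @export
print.efficiency_result <- function(x, ...) {
  cat(sprintf("Macrophage events: %d\n", x$n_macrophage))
  cat(sprintf("  phagocytosis: %d events, efficiency %.2f%%\n",
              x$n_phago, x$phagocytic_efficiency))
  cat(sprintf("  trogocytosis: %d events, efficiency %.2f%%\n",
              x$n_trogo, x$trogocytic_efficiency))
  invisible(x)
}

#' Gating accuracy against ground-truth labels
#'
#' Convenience check for synthetic data: the fraction of macrophage events
#' whose gated label matches the generator's `true_label`, plus the 3x3
#' confusion matrix.
#'
#' @param labelled classified event table carrying a `true_label` column.
#' @return list with `accuracy` (fraction) and `confusion` (table).
#' @export
gating_accuracy <- function(labelled) {
  check_event_table(labelled, require_labels = TRUE)
  if (!"true_label" %in% names(labelled)) {
    stop("event table has no `true_label` column", call. = FALSE)
  }
  keep <- labelled$macrophage
  lev <- c("phago", "trogo", "neither")
  conf <- table(
    truth = factor(labelled$true_label[keep], levels = lev),
    gated = factor(labelled$label[keep], levels = lev)
  )
  list(accuracy = sum(diag(conf)) / sum(conf), confusion = conf)
}
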