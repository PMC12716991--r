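# Shared fixtures, built in code.

# Hand-built 10-event table: 6 macrophage-marker-positive events of which
# 1 is triple-positive (phagocytosis), 2 are surface-positive/volume-negative
# (trogocytosis) and 3 carry no target signal; 4 events are marker-negative
# and must be excluded from the denominator.
hand_event_table <- function() {
  data.frame(
    event_id = 1:10,
    ch_ctg   = c(1e4, 1e4, 1e4, 1e4, 1e4, 1e4, 10, 10, 10, 10),
    ch_rho   = c(1e4,  10,  10,  10,  10,  10, 1e4, 10, 10, 10),
    ch_af647 = c(1e4, 1e4, 1e4,  10,  10,  10, 1e4, 10, 10, 10)
  )
}

hand_thresholds <- function() gating_thresholds(100, 100, 100)

# Independent truth-table classifier: per-event if/else chain used as the
# oracle for classify_events() on small tables.
oracle_classify <- function(events, thr) {
  vapply(seq_len(nrow(events)), function(i) {
    ctg <- events$ch_ctg[i] > thr$thr_ctg
    rho <- events$ch_rho[i] > thr$thr_rho
    af <- events$ch_af647[i] > thr$thr_af647
    if (!ctg) return(NA_character_)
    if (af && rho) return("phago")
    if (af && !rho) return("trogo")
    "neither"
  }, character(1))
}

# Noiseless titration points for a known decreasing sigmoid.
exact_titration <- function(a = 80, rho = 500, d = 100,
                            x = c(50, 150, 300, 450, 550, 700, 900, 1200)) {
  data.frame(density_per_um2 = x,
             efficiency_pct = sigmoid_response(x, a, rho, d))
}
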