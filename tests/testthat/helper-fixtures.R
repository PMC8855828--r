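# Shared fixtures: tiny grids keep unit tests fast; study-scale cohorts
# are built only where a check needs them.

tiny_config <- function(seed = 1, ...) {
  sim_config(n_patients = 2, n_normative = 8, n_bscans = 12, n_ascans = 64,
             seed = seed, ...)
}

# A single-eye truth row with fixed onset and growth.
fixed_truth <- function(t0 = 20, growth_rate = 0.2, eye = "right",
                        patient_id = "P001") {
  data.frame(patient_id = patient_id, eye = eye,
             variant_a = "null", variant_b = "null",
             t0 = t0, growth_rate = growth_rate,
             age_criterion_true = t0 + 2.5 / growth_rate,
             stringsAsFactors = FALSE)
}

# Uniform geometry for hand-built rows/masks: square-ish pixels, simple
# pitches so expected values are easy to compute by hand.
simple_geometry <- function(n_bscans = 20, n_ascans = 30,
                            px_deg_x = 0.1, px_deg_y = 0.2,
                            ascan_pitch_um = 50, bscan_spacing_um = 120) {
  geometry(n_bscans, n_ascans, px_deg_x, px_deg_y,
           ascan_pitch_um, bscan_spacing_um)
}

# Brute-force nearest-lesion-pixel distance (oracle for the EDT).
brute_force_distance <- function(mask, sx, sy) {
  nr <- nrow(mask); nc <- ncol(mask)
  les <- which(mask, arr.ind = TRUE)
  out <- matrix(Inf, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      d2 <- ((i - les[, 1]) * sy)^2 + ((j - les[, 2]) * sx)^2
      out[i, j] <- sqrt(min(d2))
    }
  }
  out
}

# Build an OS row (um) from a run-length spec: list of c(value, n_pixels).
os_row_from_runs <- function(...) {
  runs <- list(...)
  unlist(lapply(runs, function(r) rep(r[1], r[2])))
}
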