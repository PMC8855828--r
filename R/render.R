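#' Render the en face maps of one visit
#'
#' Generates the six-lamina en face thickness map set of one eye at one
#' age. The EZ lesion is a fovea-centred disc (optionally an ellipse)
#' whose radius grows linearly with time past onset at
#' `growth_rate / sqrt(pi)` mm/y, so that sqrt(lesion area) grows at
#' `growth_rate` mm/y. Inside the lesion the outer segments are absent
#' (OS thickness exactly 0). Outside the lesion, at boundary distance `d`
#' degrees, lamina `l` is perturbed by `deficit_z[l] * exp(-d /
#' deficit_scale_deg[l])` normative SDs (negative = thinning; the RPE rim
#' is thickened; the choroid is unperturbed). Additive Gaussian pixel
#' noise and a zero floor follow.
#'
#' @param truth one row of [simulate_patient_cohort()] output (or any list
#'   with `t0`, `growth_rate`, `patient_id`, `eye`).
#' @param age visit age in years.
#' @param normative a `normative_model` on the same grid.
#' @param config the [sim_config()] used for the cohort.
#' @param noise add pixel noise (`FALSE` gives the deterministic mean
#'   field).
#' @param seed optional integer; when given, output is reproducible
#'   regardless of RNG state.
#' @return an [en_face_maps()] object; `meta` carries identifiers, age and
#'   the true lesion radius (mm).
#' @export
render_visit <- function(truth, age, normative, config, noise = TRUE,
                         seed = NULL) {
  stopifnot(inherits(normative, "normative_model"))
  geom <- normative$geometry
  cfg_geom <- config_geometry(config)
  if (geom$n_bscans != cfg_geom$n_bscans || geom$n_ascans != cfg_geom$n_ascans) {
    stop("normative grid does not match config grid", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)

  fovea_px <- normative$fovea_px
  grids <- deg_grids(geom, fovea_px)
  # elliptical distance: stretch x by eccentricity before converting to mm
  r_deg_eff <- sqrt((grids$x / config$lesion_eccentricity)^2 + grids$y^2)
  r_mm <- r_deg_eff * geom$mm_per_degree

  radius_mm <- max(0, truth$growth_rate * (age - truth$t0) / sqrt(pi))
  lesion <- r_mm <= radius_mm & radius_mm > 0
  d_deg <- pmax(r_mm - radius_mm, 0) / geom$mm_per_degree

  mu <- normative_mean(normative, age)
  lam <- config$lamina
  th <- list()
  for (i in seq_len(nrow(lam))) {
    l <- lam$lamina[i]
    pert <- lam$deficit_z[i] * lam$sd_um[i] *
      exp(-d_deg / lam$deficit_scale_deg[i])
    m <- mu[[l]] + pert
    if (l == "os") m[lesion] <- 0
    if (noise) {
      m <- m + matrix(stats::rnorm(length(m), 0, config$pixel_noise_sd_um[[l]]),
                      nrow(m), ncol(m))
      if (l == "os") m[lesion] <- 0  # absence is exact, not noisy
    }
    th[[l]] <- pmax(m, 0)
  }

  # optic disc ~15.5 deg nasal, 1.5 deg superior to the fovea; nasal is +x
  # for right eyes, -x for left eyes in this frame convention
  nasal_sign <- if (identical(truth$eye, "left")) -1 else 1
  disc_px <- c(fovea_px[1] - 1.5 / geom$px_deg_y,
               fovea_px[2] + nasal_sign * 15.5 / geom$px_deg_x)

  en_face_maps(
    th, geom, fovea_px, disc_px = disc_px,
    meta = list(patient_id = truth$patient_id, eye = truth$eye, age = age,
                lesion_radius_mm = radius_mm)
  )
}

#' Insert simulated flecks into an OS thickness profile
#'
#' Flecks are transient deposits that interrupt the EZ band over short
#' (< 250 um here, typically < 225 um in vivo) stretches without true
#' photoreceptor loss; the B-scan grading procedure forgives such breaks.
#' This inserts `n` zero-thickness runs of length `config$fleck_length_um`
#' into intact (positive-thickness) stretches of the row, placing each so
#' that a contiguous intact run of at least 200 um remains on its
#' fovea-side, which is exactly the condition under which
#' [bscan_discontinuity_length()] must forgive it.
#'
#' @param os_row numeric vector, one B-scan row of the OS map (um).
#' @param config the [sim_config()] (uses `fleck_length_um`).
#' @param pitch_um A-scan pitch (um).
#' @param fovea_col fovea column index within the row.
#' @param n number of flecks to insert (best effort; rows with no
#'   admissible site get fewer).
#' @return the modified row.
#' @export
insert_flecks <- function(os_row, config, pitch_um, fovea_col, n = 1) {
  flen_um <- config$fleck_length_um
  if (flen_um >= 250) stop("fleck_length_um must be < 250 um", call. = FALSE)
  if (flen_um <= 0 || n <= 0) return(os_row)
  flen <- max(1L, round(flen_um / pitch_um))
  guard <- ceiling(200 / pitch_um)  # intact pixels required fovea-side
  if (length(os_row) < flen) stop("row shorter than fleck length", call. = FALSE)

  row <- os_row
  for (k in seq_len(n)) {
    pos <- which(row > 0)
    # admissible start: the fleck fits in intact tissue and >= guard intact
    # pixels separate its fovea-side end from the fovea (or from absence)
    ok <- logical(0)
    for (s in pos) {
      e <- s + flen - 1L
      if (e > length(row) || any(row[s:e] <= 0)) next
      side <- if (e < fovea_col) (e + 1L):min(length(row), floor(fovea_col))
              else if (s > fovea_col) max(1L, ceiling(fovea_col)):(s - 1L)
              else next  # would overlap the fovea
      if (length(side) < guard) next
      # need a contiguous intact run >= guard within the fovea-side stretch
      runs <- rle(row[side] > 0)
      if (any(runs$values & runs$lengths >= guard)) ok <- c(ok, s)
    }
    if (!length(ok)) break
    s <- if (length(ok) == 1) ok else sample(ok, 1)
    row[s:(s + flen - 1L)] <- 0
  }
  row
}
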