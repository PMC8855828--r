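#' Segmented laminae
#'
#' Short codes for the six segmented laminae: inner retina, outer nuclear
#' layer (including Henle's fiber layer), photoreceptor inner segments,
#' photoreceptor outer segments, retinal pigment epithelium, and choroid.
#'
#' @export
EZ_LAMINAE <- c("inner", "onl", "is", "os", "rpe", "cho")

# Per-lamina generator defaults.
#
# base_um / peak_um: normative thickness away from the fovea and the extra
#   foveal-peak amplitude (Gaussian, sd peak_sd_deg); only the ONL has a
#   pronounced foveal peak.
# beta_age_um: normal ageing slope, um per year, centred at age 40.
# sd_um: normative between-subject SD; also the default pixel noise SD so a
#   healthy simulated eye scores z ~ N(0, 1). Values are back-computed from
#   the z <-> um ratios of the printed first-contour deficits.
# deficit_z: signed z-score perturbation amplitude AT the lesion boundary
#   (negative = thinning; RPE shows junctional thickening).
# deficit_scale_deg: exponential decay constant of the perturbation with
#   distance from the EZ-loss boundary (degrees). ONL > IS > OS.
lamina_defaults <- function() {
  data.frame(
    lamina = EZ_LAMINAE,
    base_um = c(150, 60, 25, 25, 30, 250),
    peak_um = c(0, 30, 0, 0, 0, 0),
    peak_sd_deg = c(1, 2, 1, 1, 1, 1),
    beta_age_um = c(-0.05, -0.10, -0.02, -0.02, 0.00, -1.50),
    sd_um = c(15.4, 8.75, 1.95, 3.06, 3.20, 45.0),
    deficit_z = c(-2.37, -3.94, -4.45, -3.40, +0.94, 0),
    deficit_scale_deg = c(1.00, 4.71, 1.50, 0.90, 1.00, 1.00),
    stringsAsFactors = FALSE
  )
}

#' Simulation configuration
#'
#' Assembles and validates the configuration of the synthetic cohort
#' generator. Defaults emulate the acquisition protocol and cohort
#' structure of a longitudinal Stargardt natural-history study: 37 B-scans
#' over a 30 x 15 degree field (B-scan spacing ~120 um), annual visits plus
#' a six-month retest, square-root-linear lesion growth, genotype-additive
#' onset ages, and layer-specific z-score deficits decaying exponentially
#' with distance from the lesion boundary.
#'
#' @param n_patients number of patients (two eyes each).
#' @param n_normative number of healthy eyes in the normative cohort.
#' @param first_age_range range (years) from which each patient's first
#'   visit age is drawn uniformly.
#' @param n_visits number of annual visits (a 6-month retest is appended
#'   after the first visit when `retest = TRUE`).
#' @param visit_spacing_years spacing between annual visits.
#' @param retest append a 6-month retest visit after the first visit.
#' @param n_bscans,n_ascans grid dimensions (rows = B-scans).
#' @param field_deg field of view, degrees, `c(width, height)`.
#' @param bscan_spacing_um distance between adjacent B-scans (um).
#' @param mm_per_degree retinal scaling of the schematic emmetropic eye.
#' @param growth_rate_mean,growth_rate_sdlog log-normal distribution of the
#'   per-eye square-root-area progression rate (mm/y); `growth_rate_mean`
#'   is the arithmetic mean, truncation at 0 is implied by log-normality.
#' @param patient_sd_years,eye_sd_years SD of the patient-level and
#'   eye-within-patient random shifts of the onset age (years).
#' @param lamina per-lamina parameter table; see [lamina_defaults()]
#'   columns. Override individual cells rather than rebuilding.
#' @param rpe_rim_z junctional RPE thickening amplitude (z units);
#'   convenience alias for `lamina["rpe", "deficit_z"]`.
#' @param pixel_noise_sd_um per-lamina additive pixel noise SD (um); `NULL`
#'   uses the normative SD so healthy eyes have unit z variance.
#' @param fleck_length_um length of simulated flecks (transient zero-OS
#'   runs outside the lesion); must be < 250 so the break-forgiveness rule
#'   applies. Flecks are only inserted by [insert_flecks()], never by
#'   [render_visit()].
#' @param lesion_eccentricity horizontal stretch factor of the lesion
#'   (1 = circular disc; > 1 gives an ellipse for robustness tests).
#' @param criterion_sqrt_mm criterion EZ-loss size on the square-root scale
#'   (2.5 mm, i.e. 6.25 mm^2).
#' @param seed integer seed recorded in the config; all generator output is
#'   reproducible from (config, seed).
#' @return a validated list of class `ez_sim_config`.
#' @export
sim_config <- function(n_patients = 20,
                       n_normative = 50,
                       first_age_range = c(15, 45),
                       n_visits = 5,
                       visit_spacing_years = 1,
                       retest = TRUE,
                       n_bscans = 37,
                       n_ascans = 512,
                       field_deg = c(30, 15),
                       bscan_spacing_um = 120,
                       mm_per_degree = 0.289,
                       growth_rate_mean = 0.09,
                       growth_rate_sdlog = 0.5,
                       patient_sd_years = 5,
                       eye_sd_years = 1.5,
                       lamina = lamina_defaults(),
                       rpe_rim_z = NULL,
                       pixel_noise_sd_um = NULL,
                       fleck_length_um = 150,
                       lesion_eccentricity = 1,
                       criterion_sqrt_mm = 2.5,
                       seed = 1L) {
  if (!is.null(rpe_rim_z)) {
    lamina$deficit_z[lamina$lamina == "rpe"] <- rpe_rim_z
  }
  if (is.null(pixel_noise_sd_um)) {
    pixel_noise_sd_um <- stats::setNames(lamina$sd_um, lamina$lamina)
  }
  cfg <- list(
    n_patients = as.integer(n_patients),
    n_normative = as.integer(n_normative),
    first_age_range = as.numeric(first_age_range),
    n_visits = as.integer(n_visits),
    visit_spacing_years = visit_spacing_years,
    retest = isTRUE(retest),
    n_bscans = as.integer(n_bscans),
    n_ascans = as.integer(n_ascans),
    field_deg = as.numeric(field_deg),
    bscan_spacing_um = bscan_spacing_um,
    mm_per_degree = mm_per_degree,
    growth_rate_mean = growth_rate_mean,
    growth_rate_sdlog = growth_rate_sdlog,
    patient_sd_years = patient_sd_years,
    eye_sd_years = eye_sd_years,
    lamina = lamina,
    pixel_noise_sd_um = pixel_noise_sd_um,
    fleck_length_um = fleck_length_um,
    lesion_eccentricity = lesion_eccentricity,
    criterion_sqrt_mm = criterion_sqrt_mm,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  class(cfg) <- "ez_sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(
    cfg$n_bscans >= 3, cfg$n_ascans >= 8,
    all(cfg$field_deg > 0), cfg$bscan_spacing_um > 0,
    cfg$mm_per_degree > 0, cfg$growth_rate_mean > 0,
    cfg$patient_sd_years >= 0, cfg$eye_sd_years >= 0,
    cfg$growth_rate_sdlog >= 0,
    all(cfg$pixel_noise_sd_um >= 0),
    cfg$lesion_eccentricity > 0
  )
  lam <- cfg$lamina
  if (!all(EZ_LAMINAE %in% lam$lamina)) {
    stop("lamina table must cover all six laminae", call. = FALSE)
  }
  if (any(lam$sd_um <= 0)) {
    stop("normative SDs must be strictly positive", call. = FALSE)
  }
  sc <- stats::setNames(lam$deficit_scale_deg, lam$lamina)
  if (!(sc[["onl"]] > sc[["is"]] && sc[["is"]] > sc[["os"]])) {
    stop("deficit_scale_deg must be ordered ONL > IS > OS", call. = FALSE)
  }
  if (cfg$fleck_length_um >= 250) {
    stop("fleck_length_um must be < 250 um (break-forgiveness premise)",
         call. = FALSE)
  }
  invisible(cfg)
}

# Grid geometry derived from a sim config (shared by generator and
# analysis stages). Pixel pitch in degrees and um per axis.
config_geometry <- function(cfg) {
  px_deg_x <- cfg$field_deg[1] / cfg$n_ascans
  px_deg_y <- cfg$field_deg[2] / cfg$n_bscans
  geometry(
    n_bscans = cfg$n_bscans, n_ascans = cfg$n_ascans,
    px_deg_x = px_deg_x, px_deg_y = px_deg_y,
    ascan_pitch_um = px_deg_x * cfg$mm_per_degree * 1000,
    bscan_spacing_um = cfg$bscan_spacing_um,
    mm_per_degree = cfg$mm_per_degree
  )
}

#' Grid geometry descriptor
#'
#' @param n_bscans,n_ascans grid dimensions (rows = B-scans, columns =
#'   A-scans).
#' @param px_deg_x,px_deg_y pixel pitch in degrees along the A-scan (x) and
#'   B-scan (y) axes.
#' @param ascan_pitch_um,bscan_spacing_um physical pixel pitch (um).
#' @param mm_per_degree retinal scaling.
#' @return list of class `ez_geometry`.
#' @export
geometry <- function(n_bscans, n_ascans, px_deg_x, px_deg_y,
                     ascan_pitch_um, bscan_spacing_um,
                     mm_per_degree = 0.289) {
  g <- list(
    n_bscans = as.integer(n_bscans), n_ascans = as.integer(n_ascans),
    px_deg_x = px_deg_x, px_deg_y = px_deg_y,
    ascan_pitch_um = ascan_pitch_um, bscan_spacing_um = bscan_spacing_um,
    mm_per_degree = mm_per_degree
  )
  stopifnot(g$n_bscans >= 1, g$n_ascans >= 1, px_deg_x > 0, px_deg_y > 0,
            ascan_pitch_um > 0, bscan_spacing_um > 0, mm_per_degree > 0)
  class(g) <- "ez_geometry"
  g
}

# Deterministic child seed, kept below 2^31.
derive_seed <- function(seed, i) {
  as.integer((as.double(seed) * 48271 + i * 104729) %% 2147483647)
}
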