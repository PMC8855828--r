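#' Build the normative thickness model
#'
#' Constructs per-lamina normative mean and SD surfaces for A-scan-wise
#' (pointwise) z-score standardization. The mean surface is
#' `mu_l(x, y, age) = base_l(x, y) + beta_l * (age - 40)` where `base_l`
#' is a smooth surface with a foveal peak for the ONL, and the SD surface
#' `sigma_l(x, y)` is strictly positive. In a real study these surfaces
#' would be estimated from a normative cohort; here they are generated
#' from the configuration's lamina parameters, and the synthetic normative
#' cohort drawn from them ([simulate_normative_cohort()]) scores to
#' z ~ N(0, 1) against the model.
#'
#' @param config an [sim_config()] object.
#' @return object of class `normative_model` with elements `base` (named
#'   list of matrices, um at age 40), `beta_age` (named vector, um/y),
#'   `sigma` (named list of matrices, um), `ref_age`, `geometry`,
#'   `fovea_px`.
#' @export
make_normative_model <- function(config) {
  validate_sim_config(config)
  geom <- config_geometry(config)
  fovea_px <- c((geom$n_bscans + 1) / 2, (geom$n_ascans + 1) / 2)
  grids <- deg_grids(geom, fovea_px)
  lam <- config$lamina
  base <- list(); sigma <- list()
  for (i in seq_len(nrow(lam))) {
    l <- lam$lamina[i]
    base[[l]] <- lam$base_um[i] +
      lam$peak_um[i] * exp(-grids$r^2 / (2 * lam$peak_sd_deg[i]^2))
    sigma[[l]] <- matrix(lam$sd_um[i], geom$n_bscans, geom$n_ascans)
  }
  structure(
    list(base = base,
         beta_age = stats::setNames(lam$beta_age_um, lam$lamina),
         sigma = sigma, ref_age = 40,
         geometry = geom, fovea_px = fovea_px),
    class = "normative_model"
  )
}

#' Normative mean surfaces at a given age
#'
#' @param model a `normative_model`.
#' @param age age in years.
#' @return named list of matrices, `mu_l(x, y, age)` in um.
#' @export
normative_mean <- function(model, age) {
  stopifnot(inherits(model, "normative_model"))
  out <- model$base
  for (l in names(out)) {
    out[[l]] <- pmax(out[[l]] + model$beta_age[[l]] * (age - model$ref_age), 0)
  }
  out
}

#' Simulate a normative (healthy) cohort
#'
#' Draws `config$n_normative` healthy eyes: thickness = normative mean at
#' the drawn age plus Gaussian pixel noise with the per-lamina noise SD,
#' clipped at zero.
#'
#' @param config an [sim_config()] object.
#' @param model a `normative_model` (built from `config` if missing).
#' @param ages optional vector of ages (recycled); default uniform 10-80.
#' @return list of [en_face_maps()] objects with `meta$age` set.
#' @export
simulate_normative_cohort <- function(config, model = make_normative_model(config),
                                      ages = NULL) {
  set.seed(derive_seed(config$seed, 7L))
  n <- config$n_normative
  if (is.null(ages)) ages <- stats::runif(n, 10, 80)
  ages <- rep_len(ages, n)
  geom <- model$geometry
  lapply(seq_len(n), function(i) {
    mu <- normative_mean(model, ages[i])
    th <- lapply(stats::setNames(names(mu), names(mu)), function(l) {
      sd <- config$pixel_noise_sd_um[[l]]
      pmax(mu[[l]] + matrix(stats::rnorm(geom$n_bscans * geom$n_ascans, 0, sd),
                            geom$n_bscans, geom$n_ascans), 0)
    })
    en_face_maps(th, geom, model$fovea_px,
                 meta = list(patient_id = sprintf("N%03d", i), eye = "right",
                             age = ages[i]))
  })
}
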