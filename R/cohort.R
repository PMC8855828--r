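#' Variant pool for genotype simulation
#'
#' A pool of ABCA4 variant specifications for the generator. Each variant
#' carries an additive contribution (years) to the age of criterion
#' EZ-loss. The null-class severity (6.88 y) and the p.Gly1961Glu severity
#' (34.63 y) are the published point estimates; the remaining labels are
#' synthetic severities spanning the plausible range (more severe than
#' null through strongly delaying), present so simulated cohorts exercise
#' pooling, shared alleles and LOOCV eligibility.
#'
#' @param labels optional subset of labels to keep.
#' @return data.frame with columns `label`, `severity_years`, `is_null`.
#' @export
default_variant_pool <- function(labels = NULL) {
  pool <- data.frame(
    label = c("null", "p.Gly1961Glu", "c.5461-10T>C", "p.Cys2150Tyr",
              "p.Thr1526Met", "syn.mild.A", "syn.int.B", "syn.int.C"),
    severity_years = c(6.88, 34.63, 7.20, 3.50, 20.00, 28.00, 14.00, 17.50),
    is_null = c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
  if (!is.null(labels)) pool <- pool[pool$label %in% labels, , drop = FALSE]
  validate_variant_pool(pool)
  pool
}

validate_variant_pool <- function(pool) {
  stopifnot(is.data.frame(pool), nrow(pool) >= 1,
            all(c("label", "severity_years", "is_null") %in% names(pool)))
  if (anyDuplicated(pool$label)) stop("variant labels must be unique", call. = FALSE)
  if (!all(is.finite(pool$severity_years))) {
    stop("severities must be finite", call. = FALSE)
  }
  if (!any(pool$is_null)) {
    stop("variant pool must contain at least one null variant", call. = FALSE)
  }
  invisible(pool)
}

#' Simulate patient-level ground truth
#'
#' Draws, per patient, a genotype of two variants from the pool and, per
#' eye, an onset age and a square-root-area growth rate. Onset age is
#' additive in the two allele severities plus patient- and eye-level
#' Gaussian shifts:
#' `t0 = s(v1) + s(v2) + b_patient + e_eye`,
#' `b_patient ~ N(0, patient_sd_years)`, `e_eye ~ N(0, eye_sd_years)`.
#' The growth rate `r` (slope of sqrt(area) in mm/y) is log-normal with
#' arithmetic mean `growth_rate_mean`, hence strictly positive, so the
#' age of criterion EZ-loss is exactly `t0 + criterion_sqrt_mm / r`.
#'
#' @param config an [sim_config()] object.
#' @param pool variant pool data.frame ([default_variant_pool()]).
#' @param genotype_weights optional sampling weights over pool rows.
#' @return data.frame of class `ez_patient_truth`, one row per eye:
#'   `patient_id`, `eye`, `variant_a`, `variant_b`, `t0`, `growth_rate`,
#'   `age_criterion_true`.
#' @export
simulate_patient_cohort <- function(config, pool = default_variant_pool(),
                                    genotype_weights = NULL) {
  validate_sim_config(config)
  validate_variant_pool(pool)
  set.seed(derive_seed(config$seed, 11L))
  n <- config$n_patients
  if (is.null(genotype_weights)) genotype_weights <- rep(1, nrow(pool))
  sev <- stats::setNames(pool$severity_years, pool$label)

  rows <- lapply(seq_len(n), function(i) {
    vs <- sample(pool$label, 2, replace = TRUE, prob = genotype_weights)
    b_pat <- stats::rnorm(1, 0, config$patient_sd_years)
    per_eye <- lapply(c("right", "left"), function(eye) {
      t0 <- sev[[vs[1]]] + sev[[vs[2]]] + b_pat +
        stats::rnorm(1, 0, config$eye_sd_years)
      mlog <- log(config$growth_rate_mean) - config$growth_rate_sdlog^2 / 2
      r <- stats::rlnorm(1, mlog, config$growth_rate_sdlog)
      data.frame(patient_id = sprintf("P%03d", i), eye = eye,
                 variant_a = vs[1], variant_b = vs[2],
                 t0 = t0, growth_rate = r,
                 age_criterion_true = t0 + config$criterion_sqrt_mm / r,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, per_eye)
  })
  truth <- do.call(rbind, rows)
  rownames(truth) <- NULL
  class(truth) <- c("ez_patient_truth", "data.frame")
  truth
}

#' Genotype table of a simulated cohort
#'
#' @param truth output of [simulate_patient_cohort()].
#' @return data.frame with one row per patient: `patient_id`, `variant_a`,
#'   `variant_b`.
#' @export
cohort_genotypes <- function(truth) {
  g <- unique(truth[, c("patient_id", "variant_a", "variant_b")])
  rownames(g) <- NULL
  g
}

#' Visit schedule for a simulated cohort
#'
#' Per patient: a first-visit age drawn uniformly from
#' `first_age_range`, annual visits, and (optionally) a retest 6 months
#' after the first visit — the prospective design the generator emulates.
#' Both eyes share the schedule.
#'
#' @param config an [sim_config()] object.
#' @param truth output of [simulate_patient_cohort()].
#' @param start_after_onset optional range (years); when given, each
#'   patient's first visit age is drawn uniformly that far after the later
#'   of the two eyes' onset ages, so every visit has measurable EZ loss
#'   (the situation the progression models are fit in; eyes without
#'   measurable loss at two visits are excluded from those analyses).
#' @return data.frame: `patient_id`, `visit`, `age`.
#' @export
cohort_schedule <- function(config, truth, start_after_onset = NULL) {
  set.seed(derive_seed(config$seed, 13L))
  pats <- unique(truth$patient_id)
  rows <- lapply(pats, function(p) {
    a0 <- if (is.null(start_after_onset)) {
      stats::runif(1, config$first_age_range[1], config$first_age_range[2])
    } else {
      max(truth$t0[truth$patient_id == p]) +
        stats::runif(1, start_after_onset[1], start_after_onset[2])
    }
    ages <- a0 + (seq_len(config$n_visits) - 1) * config$visit_spacing_years
    if (config$retest) ages <- sort(c(ages, a0 + 0.5))
    data.frame(patient_id = p, visit = seq_along(ages), age = ages,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Simulate a longitudinal EZ-loss area table
#'
#' Model-level generator (no map rendering): for each eye and scheduled
#' visit, sqrt(area) = growth_rate * (age - t0) plus Gaussian noise on the
#' square-root scale, floored at 0; area = sqrt(area)^2. This is the
#' direct counterpart of the progression statistics' sampling model and is
#' used for model-recovery simulations at full cohort scale.
#'
#' @param config an [sim_config()] object.
#' @param truth output of [simulate_patient_cohort()].
#' @param schedule output of [cohort_schedule()]; built if missing.
#' @param residual_sd_mm measurement noise SD on the sqrt-area scale.
#' @return data.frame: `patient_id`, `eye`, `eye_id`, `visit`, `age`,
#'   `time` (years since the eye's first visit), `sqrt_area_mm`,
#'   `area_mm2`.
#' @export
simulate_area_table <- function(config, truth,
                                schedule = cohort_schedule(config, truth),
                                residual_sd_mm = 0.15) {
  set.seed(derive_seed(config$seed, 17L))
  tab <- merge(truth, schedule, by = "patient_id")
  tab <- tab[order(tab$patient_id, tab$eye, tab$age), ]
  s_true <- pmax(tab$growth_rate * (tab$age - tab$t0), 0)
  s_obs <- pmax(s_true + stats::rnorm(nrow(tab), 0, residual_sd_mm), 0)
  out <- data.frame(
    patient_id = tab$patient_id, eye = tab$eye,
    eye_id = paste(tab$patient_id, tab$eye, sep = ":"),
    visit = tab$visit, age = tab$age,
    sqrt_area_mm = s_obs, area_mm2 = s_obs^2,
    stringsAsFactors = FALSE
  )
  first <- stats::ave(out$age, out$eye_id, FUN = min)
  out$time <- out$age - first
  rownames(out) <- NULL
  out
}
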