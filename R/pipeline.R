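#' Pipeline configuration
#'
#' Bundles the simulation sub-configuration with every analysis parameter
#' of the pipeline, each surfacing a study constant as a named key:
#' contour spacing 0.43 degrees, normative range +/- 2 z, criterion size
#' 2.5 mm (sqrt scale, 6.25 mm^2), frame ceiling 16 mm^2, peri-papillary
#' exclusion radius 5 degrees, Box-Cox lambda grid 0-1. Round-trips
#' losslessly through JSON ([write_pipeline_config()]).
#'
#' @param sim an [sim_config()].
#' @param contour_spacing_deg,contour_K,z_threshold contour parameters.
#' @param min_pixels minimum analyzable pixels per band.
#' @param criterion_sqrt_mm,ceiling_mm2 imputation parameters.
#' @param lambda_grid Box-Cox lambda grid.
#' @param disc_radius_deg peri-papillary exclusion radius.
#' @param os_tol_um OS absence tolerance.
#' @param seed pipeline seed (defaults to the simulation seed).
#' @return list of class `ez_pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(),
                            contour_spacing_deg = 0.43,
                            contour_K = 18,
                            z_threshold = 2,
                            min_pixels = 10,
                            criterion_sqrt_mm = 2.5,
                            ceiling_mm2 = 16,
                            lambda_grid = seq(0, 1, by = 0.05),
                            disc_radius_deg = 5,
                            os_tol_um = 0,
                            seed = sim$seed) {
  cfg <- list(sim = sim, contour_spacing_deg = contour_spacing_deg,
              contour_K = as.integer(contour_K), z_threshold = z_threshold,
              min_pixels = as.integer(min_pixels),
              criterion_sqrt_mm = criterion_sqrt_mm,
              ceiling_mm2 = ceiling_mm2, lambda_grid = lambda_grid,
              disc_radius_deg = disc_radius_deg, os_tol_um = os_tol_um,
              seed = as.integer(seed))
  stopifnot(cfg$contour_spacing_deg > 0, cfg$contour_K >= 1,
            cfg$z_threshold > 0, cfg$min_pixels >= 1,
            cfg$criterion_sqrt_mm > 0, cfg$ceiling_mm2 > 0,
            cfg$disc_radius_deg >= 0, cfg$os_tol_um >= 0)
  class(cfg) <- "ez_pipeline_config"
  cfg
}

#' Write / read a pipeline configuration (JSON)
#'
#' @param config an [pipeline_config()].
#' @param path file path.
#' @return `read_pipeline_config()` returns the reconstructed config.
#' @export
write_pipeline_config <- function(config, path) {
  x <- unclass(config)
  x$sim <- unclass(x$sim)
  # named vectors serialize as bare arrays; keep the names via a list
  x$sim$pixel_noise_sd_um <- as.list(x$sim$pixel_noise_sd_um)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  sim <- x$sim
  lam <- as.data.frame(sim$lamina, stringsAsFactors = FALSE)
  cfg_sim <- sim_config(
    n_patients = sim$n_patients, n_normative = sim$n_normative,
    first_age_range = sim$first_age_range, n_visits = sim$n_visits,
    visit_spacing_years = sim$visit_spacing_years, retest = sim$retest,
    n_bscans = sim$n_bscans, n_ascans = sim$n_ascans,
    field_deg = sim$field_deg, bscan_spacing_um = sim$bscan_spacing_um,
    mm_per_degree = sim$mm_per_degree,
    growth_rate_mean = sim$growth_rate_mean,
    growth_rate_sdlog = sim$growth_rate_sdlog,
    patient_sd_years = sim$patient_sd_years,
    eye_sd_years = sim$eye_sd_years, lamina = lam,
    pixel_noise_sd_um = unlist(sim$pixel_noise_sd_um),
    fleck_length_um = sim$fleck_length_um,
    lesion_eccentricity = sim$lesion_eccentricity,
    criterion_sqrt_mm = sim$criterion_sqrt_mm, seed = sim$seed
  )
  pipeline_config(
    sim = cfg_sim, contour_spacing_deg = x$contour_spacing_deg,
    contour_K = x$contour_K, z_threshold = x$z_threshold,
    min_pixels = x$min_pixels, criterion_sqrt_mm = x$criterion_sqrt_mm,
    ceiling_mm2 = x$ceiling_mm2, lambda_grid = x$lambda_grid,
    disc_radius_deg = x$disc_radius_deg, os_tol_um = x$os_tol_um,
    seed = x$seed
  )
}

#' Run the full analysis pipeline
#'
#' Simulate (or load) a cohort, quantify EZ loss per visit, extract
#' contour and ETDRS features, fit the progression models and the
#' additive allele model, and write all tables plus a run manifest under
#' `out_dir`. Stages are deterministic given (config, seed); re-running
#' with the same config reproduces every table.
#'
#' @param config an [pipeline_config()].
#' @param out_dir output directory.
#' @param cohort_dir optional directory of an existing cohort (skips
#'   simulation); must exist when given.
#' @param quiet suppress progress messages.
#' @return invisible list with the in-memory results (`truth`,
#'   `area_table`, `lesions`, `profiles`, `fits`, `severity`, `paths`).
#' @export
run_pipeline <- function(config, out_dir, cohort_dir = NULL, quiet = FALSE) {
  stopifnot(inherits(config, "ez_pipeline_config"))
  t_all <- Sys.time()
  say <- function(...) if (!quiet) message(sprintf(...))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    t0 <- Sys.time()
    r <- tryCatch(expr, error = function(e) {
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE)
    })
    say("stage %-12s %.1fs", name, as.numeric(Sys.time() - t0, units = "secs"))
    r
  }

  sim <- config$sim
  if (is.null(cohort_dir)) {
    normative <- stage("normative", make_normative_model(sim))
    truth <- stage("truth", simulate_patient_cohort(sim))
    schedule <- cohort_schedule(sim, truth)
    visits <- stage("render", {
      vs <- list(); i <- 0L
      for (r in seq_len(nrow(truth))) {
        tr <- truth[r, ]
        sch <- schedule[schedule$patient_id == tr$patient_id, ]
        for (a in sch$age) {
          i <- i + 1L
          vs[[i]] <- render_visit(tr, a, normative, sim,
                                  seed = derive_seed(sim$seed, 1000L + i))
        }
      }
      vs
    })
  } else {
    if (!dir.exists(cohort_dir)) {
      stop("cohort directory not found: ", cohort_dir, call. = FALSE)
    }
    loaded <- stage("load", read_cohort(cohort_dir))
    visits <- loaded$visits
    truth <- loaded$truth
    normative <- make_normative_model(sim)
  }

  lesions <- stage("quantify", {
    rows <- lapply(visits, function(m) {
      rec <- quantify_lesion(m, tol = config$os_tol_um,
                             disc_radius_deg = config$disc_radius_deg)
      data.frame(patient_id = m$meta$patient_id, eye = m$meta$eye,
                 eye_id = paste(m$meta$patient_id, m$meta$eye, sep = ":"),
                 age = m$meta$age, area_mm2 = rec$area_mm2,
                 sqrt_area_mm = sqrt(rec$area_mm2),
                 riemann_area_mm2 = rec$riemann_area_mm2,
                 stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, rows)
    first <- stats::ave(tab$age, tab$eye_id, FUN = min)
    tab$time <- tab$age - first
    tab
  })

  profiles <- stage("contours", {
    extract_contour_profiles(visits, normative, anchor = "first",
                             spacing = config$contour_spacing_deg,
                             K = config$contour_K,
                             min_pixels = config$min_pixels,
                             tol = config$os_tol_um,
                             disc_radius_deg = config$disc_radius_deg)
  })

  etdrs <- stage("etdrs", {
    rows <- lapply(visits, function(m) {
      e <- etdrs_means(m)
      e$patient_id <- m$meta$patient_id; e$eye <- m$meta$eye
      e$age <- m$meta$age
      e
    })
    do.call(rbind, rows)
  })

  fits <- stage("progression", {
    out <- list()
    out$boxcox <- tryCatch(boxcox_profile(lesions, config$lambda_grid),
                           error = function(e) NULL)
    out$sqrt_area <- fit_sqrt_area_mixed(lesions)
    if (nrow(profiles)) {
      first_prof <- profiles[profiles$time == 0, ]
      out$onl_band1 <- tryCatch(
        fit_contour_cross_section(first_prof, "onl", 1),
        error = function(e) NULL)
      nd <- normalization_distances(profiles,
                                    threshold = config$z_threshold)
      out$norm_dist_onl <- tryCatch(
        summarize_normalization_distance(nd, "onl"),
        error = function(e) NULL)
      out$onl_rate_band1 <- tryCatch(
        fit_contour_rate(profiles, "onl", 1),
        error = function(e) NULL)
    }
    out
  })

  severity <- stage("alleles", {
    if (is.null(truth)) NULL else {
      ages <- impute_cohort_ages(lesions,
                                 criterion_sqrt_mm = config$criterion_sqrt_mm,
                                 ceiling_mm2 = config$ceiling_mm2)
      gt <- cohort_genotypes(as.data.frame(truth))
      pool <- default_variant_pool()
      des <- build_allele_design(gt, null_labels = pool$label[pool$is_null])
      list(ages = ages,
           table = tryCatch(fit_additive_model(des, ages),
                            error = function(e) NULL))
    }
  })

  paths <- stage("write", {
    p <- list(
      lesions = file.path(out_dir, "lesions.csv"),
      profiles = file.path(out_dir, "contour_profiles.csv"),
      etdrs = file.path(out_dir, "etdrs.csv"),
      ages = file.path(out_dir, "ages_of_criterion.csv"),
      severities = file.path(out_dir, "allele_severities.csv"),
      manifest = file.path(out_dir, "manifest.json")
    )
    utils::write.csv(lesions, p$lesions, row.names = FALSE)
    if (nrow(profiles)) utils::write.csv(profiles, p$profiles, row.names = FALSE)
    utils::write.csv(etdrs, p$etdrs, row.names = FALSE)
    if (!is.null(severity)) {
      utils::write.csv(severity$ages, p$ages, row.names = FALSE)
      if (!is.null(severity$table)) {
        utils::write.csv(severity$table$severities, p$severities,
                         row.names = FALSE)
      }
    }
    manifest <- list(
      config_hash = rlang::hash(unclass(config)),
      seed = config$seed,
      n_visits = length(visits),
      r_version = as.character(getRversion()),
      package_version = as.character(utils::packageVersion("ezprog")),
      fixed_effects = if (!is.null(fits$sqrt_area)) fits$sqrt_area$fixed else NULL
    )
    jsonlite::write_json(manifest, p$manifest, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
    p
  })
  say("pipeline done in %.1fs", as.numeric(Sys.time() - t_all, units = "secs"))
  invisible(list(truth = truth, area_table = lesions, profiles = profiles,
                 etdrs = etdrs, fits = fits, severity = severity,
                 paths = paths))
}
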