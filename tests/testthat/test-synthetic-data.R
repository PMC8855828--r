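test_that("normative model: age slope and self-standardization behave", {
  cfg <- tiny_config()
  lam0 <- lamina_defaults()
  lam0$beta_age_um <- 0
  cfg0 <- tiny_config(lamina = lam0)
  nm0 <- make_normative_model(cfg0)
  expect_equal(normative_mean(nm0, 20), normative_mean(nm0, 70))

  nm <- make_normative_model(cfg)
  mu40 <- normative_mean(nm, 40)
  m <- en_face_maps(mu40, nm$geometry, nm$fovea_px, meta = list(age = 40))
  z <- zscore_map(m, nm)
  for (l in names(z)) expect_equal(max(abs(z[[l]])), 0)

  # ONL base has a foveal peak
  onl <- nm$base$onl
  fov <- round(nm$fovea_px)
  expect_gt(onl[fov[1], fov[2]], onl[fov[1], 1])
})

test_that("normative model rejects non-positive SDs", {
  lam <- lamina_defaults()
  lam$sd_um[2] <- 0
  expect_error(tiny_config(lamina = lam), "positive")
})

test_that("a simulated normative cohort scores to approximately N(0,1)", {
  cfg <- sim_config(n_patients = 1, n_normative = 50, n_bscans = 12,
                    n_ascans = 64, seed = 42)
  nm <- make_normative_model(cfg)
  cohort <- simulate_normative_cohort(cfg, nm)
  zs <- lapply(cohort, function(m) zscore_map(m, nm)$onl)
  zmat <- do.call(rbind, lapply(zs, as.vector))  # eyes x pixels
  pix_mean <- colMeans(zmat)
  pix_sd <- apply(zmat, 2, sd)
  # grand mean near 0; average per-pixel SD near 1 (single pixels have
  # Monte-Carlo spread ~1/sqrt(50), so the bands apply to the averages)
  expect_lt(abs(mean(pix_mean)), 0.1)
  expect_true(mean(pix_sd) > 0.85 && mean(pix_sd) < 1.15)
})

test_that("onset ages are additive in allele severities", {
  pool <- default_variant_pool(c("null", "p.Gly1961Glu"))
  cfg <- tiny_config(patient_sd_years = 0, eye_sd_years = 0)
  truth <- simulate_patient_cohort(cfg, pool)
  sev <- setNames(pool$severity_years, pool$label)
  expect_equal(truth$t0, unname(sev[truth$variant_a] + sev[truth$variant_b]))
  # the two published worked examples
  expect_equal(unname(sev["null"] + sev["null"]), 13.76)
  expect_equal(unname(sev["p.Gly1961Glu"] + sev["null"]), 41.51)
  # degenerate noise: both eyes identical
  for (p in unique(truth$patient_id)) {
    t0s <- truth$t0[truth$patient_id == p]
    expect_identical(t0s[1], t0s[2])
  }
})

test_that("age of criterion identity holds exactly for every simulated eye", {
  cfg <- sim_config(n_patients = 15, seed = 9)
  truth <- simulate_patient_cohort(cfg)
  expect_true(all(truth$growth_rate > 0))
  expect_equal(truth$age_criterion_true, truth$t0 + 2.5 / truth$growth_rate)
})

test_that("simulate_patient_cohort rejects an empty pool", {
  pool <- default_variant_pool()[0, ]
  expect_error(simulate_patient_cohort(tiny_config(), pool))
})

test_that("cohort simulation is reproducible from (config, seed)", {
  cfg <- tiny_config(seed = 77)
  t1 <- simulate_patient_cohort(cfg)
  t2 <- simulate_patient_cohort(cfg)
  expect_identical(t1, t2)
  nm <- make_normative_model(cfg)
  m1 <- render_visit(t1[1, ], t1$t0[1] + 4, nm, cfg, seed = 5)
  m2 <- render_visit(t1[1, ], t1$t0[1] + 4, nm, cfg, seed = 5)
  expect_identical(m1$thickness, m2$thickness)
  expect_true(all(vapply(m1$thickness, function(x) all(x >= 0), logical(1))))
})

test_that("pre-onset render has no lesion and positive OS", {
  cfg <- tiny_config()
  nm <- make_normative_model(cfg)
  tr <- fixed_truth(t0 = 30, growth_rate = 0.1)
  m <- render_visit(tr, 25, nm, cfg, noise = FALSE)
  expect_false(any(ez_mask_from_os(m)))
  expect_true(all(m$thickness$os > 0))
})

test_that("noise-free render reproduces the configured first-band deficit", {
  cfg <- sim_config(n_patients = 1, seed = 3)
  nm <- make_normative_model(cfg)
  tr <- fixed_truth(t0 = 20, growth_rate = 0.2)
  m <- render_visit(tr, 30, nm, cfg, noise = FALSE)
  rec <- quantify_lesion(m)
  d <- boundary_distance_map(rec$mask, m$geometry)
  z <- zscore_map(m, nm)
  bm <- contour_band_means(z, m$thickness, d, rec$analyzable)
  onl1 <- bm$mean_z[bm$lamina == "onl" & bm$band == 1]
  # configured decay evaluated at the first contour line: -3.94*exp(-0.43/4.71)
  expect_equal(onl1, -3.60, tolerance = 0.03)
  # RPE rim is thickened, choroid untouched
  expect_gt(bm$mean_z[bm$lamina == "rpe" & bm$band == 1], 0.3)
  expect_equal(bm$mean_z[bm$lamina == "cho" & bm$band == 1], 0)
})

test_that("rendered disc lesion area matches the analytic disc", {
  cfg <- sim_config(n_patients = 1, seed = 3)
  nm <- make_normative_model(cfg)
  # choose growth/age for radius 1.5 mm: r_mm = rate*(age-t0)/sqrt(pi)
  rate <- 0.2; dt <- 1.5 * sqrt(pi) / rate
  tr <- fixed_truth(t0 = 20, growth_rate = rate)
  m <- render_visit(tr, 20 + dt, nm, cfg, noise = FALSE)
  area <- lesion_area(ez_mask_from_os(m), m$geometry)
  expect_equal(area, pi * 1.5^2, tolerance = 0.03)
})

test_that("sqrt(area) of a noise-free growing lesion is linear in age", {
  cfg <- sim_config(n_patients = 1, seed = 3)
  nm <- make_normative_model(cfg)
  tr <- fixed_truth(t0 = 20, growth_rate = 0.15)
  ages <- c(26, 30, 34, 38)
  s <- vapply(ages, function(a) {
    sqrt(lesion_area(ez_mask_from_os(render_visit(tr, a, nm, cfg,
                                                  noise = FALSE)),
                     config_geometry(cfg)))
  }, numeric(1))
  fit <- lm(s ~ ages)
  expect_gt(summary(fit)$r.squared, 0.999)
  expect_equal(unname(coef(fit)[2]), 0.15, tolerance = 0.02)
})

test_that("elliptical lesions are supported", {
  cfg <- sim_config(n_patients = 1, seed = 3, lesion_eccentricity = 2)
  nm <- make_normative_model(cfg)
  tr <- fixed_truth(t0 = 20, growth_rate = 0.2)
  m <- render_visit(tr, 30, nm, cfg, noise = FALSE)
  mask <- ez_mask_from_os(m)
  # horizontal extent about twice the vertical extent
  wx <- diff(range(which(apply(mask, 2, any)))) * m$geometry$px_deg_x
  wy <- diff(range(which(apply(mask, 1, any)))) * m$geometry$px_deg_y
  expect_equal(wx / wy, 2, tolerance = 0.25)
})

test_that("insert_flecks honours its contract", {
  cfg <- sim_config(n_patients = 1, seed = 3)
  geom <- config_geometry(cfg)
  pitch <- geom$ascan_pitch_um
  row <- rep(25, 400)
  fovea <- 200

  cfg0 <- sim_config(n_patients = 1, seed = 3, fleck_length_um = 0)
  expect_identical(insert_flecks(row, cfg0, pitch, fovea), row)
  expect_error(sim_config(fleck_length_um = 250), "250")

  set.seed(1)
  out <- insert_flecks(row, cfg, pitch, fovea, n = 2)
  runs <- rle(out == 0)
  zero_runs <- runs$lengths[runs$values]
  expect_true(length(zero_runs) >= 1)
  expect_true(all(zero_runs * pitch < 250))
  # every fleck is forgiven: discontinuity length unchanged (still 0)
  expect_equal(bscan_discontinuity_length(out, pitch, fovea), 0)
})

test_that("a forgiven fleck leaves the measured discontinuity unchanged", {
  cfg <- sim_config(n_patients = 1, seed = 3)
  nm <- make_normative_model(cfg)
  tr <- fixed_truth(t0 = 20, growth_rate = 0.2)
  m <- render_visit(tr, 30, nm, cfg, noise = FALSE)
  g <- m$geometry
  k <- round(m$fovea_px[1])  # central B-scan crosses the lesion
  row0 <- m$thickness$os[k, ]
  x0 <- bscan_discontinuity_length(row0, g$ascan_pitch_um, m$fovea_px[2])
  expect_gt(x0, 0)
  set.seed(4)
  row1 <- insert_flecks(row0, cfg, g$ascan_pitch_um, m$fovea_px[2], n = 1)
  expect_false(identical(row0, row1))
  x1 <- bscan_discontinuity_length(row1, g$ascan_pitch_um, m$fovea_px[2])
  expect_equal(x1, x0)
})

test_that("model-level area table matches the generative model", {
  cfg <- sim_config(n_patients = 8, seed = 21)
  truth <- simulate_patient_cohort(cfg)
  sch <- cohort_schedule(cfg, truth, start_after_onset = c(3, 8))
  tab <- simulate_area_table(cfg, truth, sch, residual_sd_mm = 0)
  # noise-free: sqrt(area) = rate * (age - t0) exactly
  merged <- merge(tab, truth, by = c("patient_id", "eye"))
  expect_equal(merged$sqrt_area_mm,
               pmax(merged$growth_rate * (merged$age - merged$t0), 0),
               tolerance = 1e-12)
  expect_true(all(tab$time >= 0))
})
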