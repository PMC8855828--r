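test_that("age of criterion imputation solves the fitted line", {
  r <- impute_age_of_criterion(c(10, 15), c(2.0^2, 3.0^2))
  expect_equal(r$slope, 0.2)
  expect_equal(r$age_criterion, 12.5)
  expect_false(r$ceiling_rule_applied)
  expect_equal(r$reason, "ok")

  # visits bracketing the criterion symmetrically
  r2 <- impute_age_of_criterion(c(20, 22), c(2.4^2, 2.6^2))
  expect_equal(r2$age_criterion, 21.0)

  # extrapolation beyond the last visit
  r3 <- impute_age_of_criterion(c(10, 12, 14), c(0.5^2, 0.7^2, 0.9^2))
  expect_equal(r3$slope, 0.1, tolerance = 1e-9)
  expect_equal(r3$age_criterion, 10 + (2.5 - 0.5) / 0.1, tolerance = 1e-9)
})

test_that("imputation applies the frame-ceiling rule and reason codes", {
  # third visit exceeds 16 mm^2: slope from the first two visits only
  ages <- c(10, 12, 14); areas <- c(1.0, 2.25, 17)
  r <- impute_age_of_criterion(ages, areas)
  expect_true(r$ceiling_rule_applied)
  expect_equal(r$n_visits_used, 2)
  slope12 <- (1.5 - 1.0) / 2
  expect_equal(r$slope, slope12)
  expect_equal(r$age_criterion, 10 + (2.5 - 1.0) / slope12)

  expect_equal(impute_age_of_criterion(10, 4)$reason, "too_few_visits")
  expect_equal(impute_age_of_criterion(c(10, 12), c(4, 0))$reason,
               "too_few_visits")  # only one measurable visit
  r4 <- impute_age_of_criterion(c(10, 12), c(4, 3))
  expect_equal(r4$reason, "nonpositive_slope")
  expect_true(is.na(r4$age_criterion))
})

test_that("imputation is invariant to visit ordering", {
  set.seed(6)
  ages <- c(11, 13, 15, 17, 18.5)
  areas <- (0.15 * (ages - 5) + rnorm(5, 0, 0.1))^2
  a <- impute_age_of_criterion(ages, areas)
  perm <- sample(5)
  b <- impute_age_of_criterion(ages[perm], areas[perm])
  expect_equal(a, b)
})

test_that("imputation recovers generator truth from noisy visits", {
  set.seed(40)
  t0 <- 8.76; r <- 0.5  # t_crit = 8.76 + 2.5/0.5 = 13.76
  errs <- replicate(50, {
    ages <- seq(t0 + 2, by = 1.5, length.out = 5)
    s <- pmax(r * (ages - t0) + rnorm(5, 0, 0.1), 0)
    impute_age_of_criterion(ages, s^2)$age_criterion - 13.76
  })
  expect_lt(median(abs(errs)), 1.0)
})

test_that("allele design matrix counts copies and pools nulls", {
  g <- data.frame(patient_id = c("A", "B", "C"),
                  variant_a = c("v1", "c.768G>T", "null"),
                  variant_b = c("v1", "p.Gly1961Glu", "p.Gly1961Glu"))
  des <- build_allele_design(g, null_labels = c("null", "c.768G>T"))
  X <- des$design
  expect_equal(nrow(X), 6)  # 2 eyes per patient
  expect_equal(unname(X[des$patient_id == "A", "v1"]), c(2L, 2L))
  expect_equal(unname(X[des$patient_id == "B", "null"]), c(1L, 1L))
  expect_equal(unname(X[des$patient_id == "B", "p.Gly1961Glu"]), c(1L, 1L))
  # column sums are twice the per-patient allele counts (2 eyes)
  expect_equal(unname(colSums(X)[c("null", "p.Gly1961Glu", "v1")]),
               c(4L, 4L, 4L))
  expect_error(build_allele_design(
    data.frame(patient_id = "X", variant_a = "v", variant_b = NA)),
    "2 variants")
})

test_that("additive model is exact on noise-free additive data", {
  cfg <- sim_config(n_patients = 30, seed = 61, patient_sd_years = 0,
                    eye_sd_years = 0)
  truth <- simulate_patient_cohort(cfg)
  gt <- cohort_genotypes(truth)
  pool <- default_variant_pool()
  des <- build_allele_design(gt, null_labels = pool$label[pool$is_null])
  ages <- data.frame(patient_id = truth$patient_id, eye = truth$eye,
                     eye_id = paste(truth$patient_id, truth$eye, sep = ":"),
                     age_criterion = truth$t0)
  fit <- fit_additive_model(des, ages)
  sev <- setNames(pool$severity_years, pool$label)
  est <- setNames(fit$severities$severity_years, fit$severities$variant)
  for (v in names(est)) {
    expect_equal(unname(est[v]), unname(sev[v]), tolerance = 1e-6)
  }
  expect_gt(fit$marginal_r2, 0.999)
})

test_that("published worked examples: genotype predictions are plain sums", {
  pub <- published_severities()
  expect_equal(predict_age(c("null", "null"), pub), 13.76)
  expect_equal(predict_age(c("p.Gly1961Glu", "null"), pub), 41.51)
  expect_equal(predict_age(c("z1", "z2"),
                           data.frame(variant = c("z1", "z2", "null"),
                                      severity_years = c(0, 0, 5))), 0)
  expect_error(predict_age(c("nope", "null"), pub), "unknown")
})

test_that("severity estimates are equivariant under a constant shift", {
  cfg <- sim_config(n_patients = 25, seed = 63, patient_sd_years = 2,
                    eye_sd_years = 1)
  truth <- simulate_patient_cohort(cfg)
  gt <- cohort_genotypes(truth)
  pool <- default_variant_pool()
  des <- build_allele_design(gt, null_labels = pool$label[pool$is_null])
  ages <- data.frame(patient_id = truth$patient_id,
                     eye_id = paste(truth$patient_id, truth$eye, sep = ":"),
                     age_criterion = truth$t0)
  f1 <- fit_additive_model(des, ages)
  ages2 <- ages; ages2$age_criterion <- ages2$age_criterion + 2 * 3.5
  f2 <- fit_additive_model(des, ages2)  # +3.5 y per allele
  expect_equal(f2$severities$severity_years,
               f1$severities$severity_years + 3.5, tolerance = 1e-6)
})

test_that("variants without carriers are dropped and reported", {
  g <- data.frame(patient_id = c("A", "B", "C", "D"),
                  variant_a = c("null", "null", "v1", "null"),
                  variant_b = c("null", "v1", "v1", "v1"))
  des <- build_allele_design(g)
  ages <- data.frame(patient_id = rep(c("A", "B", "C", "D"), each = 2),
                     eye_id = des$eye_id,
                     age_criterion = c(14, 14, 25, 25, 36, 36, 25, 25))
  # drop every eye of C: v1 still carried by B and D -> estimable;
  # drop B and D too and v1 has no carriers left
  ages$age_criterion[ages$patient_id == "C"] <- NA
  f <- fit_additive_model(des, ages)
  expect_true("v1" %in% f$severities$variant)
  ages$age_criterion[ages$patient_id %in% c("B", "D")] <- NA
  f2 <- fit_additive_model(des, ages)
  expect_true("v1" %in% f2$dropped)
  expect_false("v1" %in% f2$severities$variant)
})

test_that("patient-wise LOOCV: perfect on noise-free data, honest on noise", {
  cfg <- sim_config(n_patients = 24, seed = 65, patient_sd_years = 0,
                    eye_sd_years = 0)
  pool <- default_variant_pool(c("null", "p.Gly1961Glu", "syn.int.B"))
  truth <- simulate_patient_cohort(cfg, pool)
  gt <- cohort_genotypes(truth)
  ages <- data.frame(patient_id = truth$patient_id,
                     eye_id = paste(truth$patient_id, truth$eye, sep = ":"),
                     age_criterion = truth$t0)
  cv <- loocv_additive(gt, ages)
  expect_equal(cv$cv_r2, 1, tolerance = 1e-6)
  expect_gte(cv$n_eligible, 3)

  # pure-noise ages carry no genotype signal
  set.seed(66)
  ages_noise <- ages
  ages_noise$age_criterion <- rnorm(nrow(ages), 25, 8)
  cv2 <- loocv_additive(gt, ages_noise)
  expect_lt(cv2$cv_r2, 0.1)
})

test_that("external comparison is shift-invariant and detects agreement", {
  sev <- data.frame(variant = c("null", "a", "b", "c", "d"),
                    severity_years = c(6.88, 10, 20, 30, 40))
  self <- compare_external(sev, sev)
  expect_equal(self$r2, 1, tolerance = 1e-12)
  shifted <- sev; shifted$severity_years <- shifted$severity_years + 100
  expect_equal(compare_external(sev, shifted)$r2, 1, tolerance = 1e-12)

  # permuted severities destroy the association on average
  set.seed(9)
  r2s <- replicate(30, {
    perm <- sev
    perm$severity_years <- sample(perm$severity_years)
    compare_external(sev, perm)$r2
  })
  expect_lt(mean(r2s), 0.5)

  ord <- data.frame(variant = c("a", "b", "c", "d"),
                    category = c("mild", "mild", "severe", "severe"))
  oc <- compare_external(sev, ord)
  expect_equal(unname(oc$medians["mild"]), mean(c(10, 20)) - 6.88,
               tolerance = 10)  # median of two = midpoint
  expect_true(oc$medians["severe"] > oc$medians["mild"])
})

test_that("between-eye agreement of imputed ages is high at small eye SD", {
  # visits bracket the criterion size (the study's situation: baseline
  # sqrt-area ~3.3 mm, i.e. past criterion), so imputation interpolates
  # and rates are fairly homogeneous; strong extrapolation (slow
  # progressors far from criterion) degrades the agreement, see vignette
  cfg <- sim_config(n_patients = 30, seed = 71, patient_sd_years = 6,
                    eye_sd_years = 0.5, growth_rate_sdlog = 0.1)
  truth <- simulate_patient_cohort(cfg)
  sch <- cohort_schedule(cfg, truth, start_after_onset = c(22, 28))
  tab <- simulate_area_table(cfg, truth, sch, residual_sd_mm = 0.05)
  ages <- impute_cohort_ages(tab)
  w <- reshape(ages[ages$reason == "ok", c("patient_id", "eye", "age_criterion")],
               idvar = "patient_id", timevar = "eye", direction = "wide")
  w <- w[complete.cases(w), ]
  r2 <- cor(w$age_criterion.right, w$age_criterion.left)^2
  expect_gt(r2, 0.9)
})
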