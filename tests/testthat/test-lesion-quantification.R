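make_maps_with_os <- function(os, geom = NULL, fovea_px = NULL,
                              disc_px = NULL, valid = NULL) {
  if (is.null(geom)) {
    geom <- simple_geometry(n_bscans = nrow(os), n_ascans = ncol(os))
  }
  if (is.null(fovea_px)) fovea_px <- c(nrow(os) / 2, ncol(os) / 2)
  en_face_maps(list(os = os), geom, fovea_px, disc_px = disc_px,
               valid = valid)
}

test_that("ez_mask_from_os is the exact zero set of valid pixels", {
  os <- matrix(25, 20, 30)
  m <- make_maps_with_os(os)
  expect_false(any(ez_mask_from_os(m)))

  os2 <- os; os2[5:14, 11:20] <- 0
  m2 <- make_maps_with_os(os2)
  mask <- ez_mask_from_os(m2)
  expect_equal(sum(mask), 100)
  expect_true(all(which(mask) %in% which(os2 == 0)))

  # invalid pixels never enter the mask
  valid <- matrix(TRUE, 20, 30); valid[5, ] <- FALSE
  m3 <- make_maps_with_os(os2, valid = valid)
  expect_equal(sum(ez_mask_from_os(m3)), 90)

  expect_error(ez_mask_from_os(en_face_maps(list(onl = os),
                                            m$geometry, c(10, 15))),
               "OS")
})

test_that("peri-papillary exclusion equals the brute-force 5-degree set", {
  os <- matrix(0, 20, 30)  # everything lesion, so removals are visible
  geom <- simple_geometry()
  # disc far outside: nothing removed
  m_far <- make_maps_with_os(os, geom, disc_px = c(10, 15 + 20 / geom$px_deg_x))
  ex <- apply_exclusions(ez_mask_from_os(m_far), m_far)
  expect_true(all(ex$analyzable))

  # disc at the frame edge
  disc <- c(10, 29)
  m_edge <- make_maps_with_os(os, geom, disc_px = disc)
  ex2 <- apply_exclusions(ez_mask_from_os(m_edge), m_edge)
  brute <- matrix(TRUE, 20, 30)
  for (i in 1:20) for (j in 1:30) {
    d <- sqrt(((i - disc[1]) * geom$px_deg_y)^2 +
                ((j - disc[2]) * geom$px_deg_x)^2)
    brute[i, j] <- d > 5
  }
  expect_identical(ex2$analyzable, brute)
  expect_true(all(!ex2$mask[!brute]))

  # all-invalid map: nothing analyzable
  m_inv <- make_maps_with_os(matrix(1, 20, 30), geom,
                             valid = matrix(FALSE, 20, 30))
  ex3 <- apply_exclusions(ez_mask_from_os(m_inv), m_inv)
  expect_false(any(ex3$analyzable))
})

test_that("lesion_area is pixel count times pixel area", {
  g <- geometry(10, 20, 0.1, 0.2, ascan_pitch_um = 56,
                bscan_spacing_um = 120)
  mask <- matrix(FALSE, 10, 20)
  expect_equal(lesion_area(mask, g), 0)
  mask[1:5, 1:20] <- TRUE
  expect_equal(lesion_area(mask, g), 100 * 120 * 56 / 1e6)
  expect_equal(lesion_area(mask, g), 0.672)
})

test_that("riemann_area equals the printed formula and the summation oracle", {
  expect_equal(riemann_area(c(0, 0, 0), 120), 0)
  expect_equal(riemann_area(c(1000, 2000, 1000), 120), 0.48)
  expect_error(riemann_area(c(-1, 5), 120), "non-negative")

  set.seed(11)
  for (i in 1:25) {
    x <- runif(sample(3:40, 1), 0, 5000)
    dx <- runif(1, 50, 250)
    oracle <- 0
    for (v in x) oracle <- oracle + v * dx
    expect_equal(riemann_area(x, dx), oracle / 1e6, tolerance = 1e-9)
  }

  # linear and monotone in each X_k
  x <- c(500, 1500, 800)
  a0 <- riemann_area(x, 120)
  expect_equal(riemann_area(2 * x, 120), 2 * a0)
  x2 <- x; x2[2] <- x2[2] + 100
  expect_gt(riemann_area(x2, 120), a0)
})

test_that("B-scan discontinuity scan applies the break-forgiveness rules", {
  pitch <- 50  # um per pixel: lengths in pixels x 50
  fovea <- 50.5

  # fully intact row
  expect_equal(bscan_discontinuity_length(rep(20, 100), pitch, fovea), 0)

  # single central absent run of 2000 um (40 px)
  row <- os_row_from_runs(c(20, 30), c(0, 40), c(20, 30))
  expect_equal(bscan_discontinuity_length(row, pitch, fovea), 2000)

  # central 2000 um gap + peripheral 200 um breaks with 300 um intact
  # runs fovea-side: breaks forgiven, X_k unchanged
  row2 <- os_row_from_runs(c(20, 6), c(0, 4), c(20, 6), c(0, 40),
                           c(20, 6), c(0, 4), c(20, 6))
  # 6+4+6+40+6+4+6 = 72 px; fovea at centre of the 40-px gap
  fov2 <- 6 + 4 + 6 + 20.5
  expect_equal(bscan_discontinuity_length(row2, pitch, fov2), 2000)

  # same but the intact run fovea-side is only 150 um (< 200): not
  # forgiven, discontinuity starts at the peripheral break
  row3 <- os_row_from_runs(c(20, 10), c(0, 4), c(20, 3), c(0, 40), c(20, 20))
  fov3 <- 10 + 4 + 3 + 20.5
  expect_equal(bscan_discontinuity_length(row3, pitch, fov3),
               (4 + 3 + 40) * 50)
})

test_that("forgiveness edge cases use the strict/inclusive bounds", {
  pitch <- 50
  # break exactly 250 um (5 px) is NOT forgiven
  row <- os_row_from_runs(c(20, 10), c(0, 5), c(20, 10), c(0, 40), c(20, 20))
  fov <- 10 + 5 + 10 + 20.5
  expect_equal(bscan_discontinuity_length(row, pitch, fov), (5 + 10 + 40) * 50)

  # break 240 um with intact run exactly 200 um (4 px at 50 um): forgiven
  pitch2 <- 60  # 4 px x 60 = 240 um break; intact 4 px x 60 = 240 >= 200
  row2 <- os_row_from_runs(c(20, 10), c(0, 4), c(20, 10), c(0, 30), c(20, 20))
  fov2 <- 10 + 4 + 10 + 15.5
  expect_equal(bscan_discontinuity_length(row2, pitch2, fov2), 30 * 60)
  # shrink the intact run to under 200 um: no longer forgiven
  pitch3 <- 50  # intact 3 px x 50 = 150 um < 200
  row3 <- os_row_from_runs(c(20, 10), c(0, 4), c(20, 3), c(0, 30), c(20, 20))
  fov3 <- 10 + 4 + 3 + 15.5
  expect_equal(bscan_discontinuity_length(row3, pitch3, fov3),
               (4 + 3 + 30) * 50)

  # row with no EZ anywhere returns the full analyzable width
  expect_equal(bscan_discontinuity_length(rep(0, 60), 50, 30), 60 * 50)
})

test_that("break forgiveness never increases X_k", {
  set.seed(23)
  pitch <- 50; n <- 120; fovea <- 60.5
  for (rep in 1:40) {
    row <- ifelse(runif(n) < 0.75, 20, 0)
    forgiving <- bscan_discontinuity_length(row, pitch, fovea)
    strict <- bscan_discontinuity_length(row, pitch, fovea, forgive_um = 0)
    expect_gte(strict, forgiving)
  }
})

test_that("map-threshold and Riemann areas agree on convex lesions", {
  cfg <- sim_config(n_patients = 1, seed = 3)
  nm <- make_normative_model(cfg)
  tr <- fixed_truth(t0 = 20, growth_rate = 0.2)
  for (age in c(26, 31, 36)) {
    m <- render_visit(tr, age, nm, cfg, noise = FALSE)
    rec <- quantify_lesion(m)
    # one pixel-column quantum per B-scan row of the boundary
    rows_hit <- sum(rec$per_bscan_um > 0)
    quantum <- rows_hit * m$geometry$ascan_pitch_um *
      m$geometry$bscan_spacing_um / 1e6
    expect_lt(abs(rec$area_mm2 - rec$riemann_area_mm2), quantum + 1e-9)
  }
})

test_that("mask-based quantification recovers the generator lesion exactly", {
  cfg <- tiny_config()
  nm <- make_normative_model(cfg)
  tr <- fixed_truth(t0 = 20, growth_rate = 0.25)
  m <- render_visit(tr, 28, nm, cfg, noise = FALSE)
  # generator truth: pixels with elliptical-radius <= radius_mm
  g <- m$geometry
  grids_x <- outer(rep(1, g$n_bscans),
                   (seq_len(g$n_ascans) - m$fovea_px[2]) * g$px_deg_x)
  grids_y <- outer((seq_len(g$n_bscans) - m$fovea_px[1]) * g$px_deg_y,
                   rep(1, g$n_ascans))
  r_mm <- sqrt(grids_x^2 + grids_y^2) * g$mm_per_degree
  truth_mask <- r_mm <= m$meta$lesion_radius_mm
  expect_identical(ez_mask_from_os(m), truth_mask)
})
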