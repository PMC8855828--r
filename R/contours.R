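#' Pointwise z-score maps
#'
#' Standardizes each lamina's thickness map against the normative model in
#' an A-scan-wise (per-pixel) manner:
#' `z_l(x, y) = (t_l(x, y) - mu_l(x, y, age)) / sigma_l(x, y)`.
#' Invalid pixels are NA.
#'
#' @param maps an [en_face_maps()].
#' @param normative a `normative_model` on the same grid.
#' @param age age in years (defaults to `maps$meta$age`).
#' @return named list of z-score matrices.
#' @export
zscore_map <- function(maps, normative, age = maps$meta$age) {
  stopifnot(inherits(maps, "en_face_maps"),
            inherits(normative, "normative_model"))
  g <- maps$geometry; ng <- normative$geometry
  if (g$n_bscans != ng$n_bscans || g$n_ascans != ng$n_ascans) {
    stop("map grid does not match normative grid", call. = FALSE)
  }
  if (is.null(age)) stop("age required for z standardization", call. = FALSE)
  mu <- normative_mean(normative, age)
  out <- list()
  for (l in names(maps$thickness)) {
    if (is.null(mu[[l]])) next
    z <- (maps$thickness[[l]] - mu[[l]]) / normative$sigma[[l]]
    z[!maps$valid] <- NA_real_
    out[[l]] <- z
  }
  out
}

#' Contour-band means outside the lesion
#'
#' Collects analyzable non-lesion pixels into disjoint annular bands of
#' boundary distance centred on multiples of the contour spacing (band `k`
#' covers `((k - 0.5) s, (k + 0.5) s]` with `s = 0.43` degrees, a Goldmann
#' III stimulus diameter) and returns per-band, per-lamina mean z-score
#' and mean thickness. Bands with fewer than `min_pixels` analyzable
#' pixels are reported missing rather than noisy.
#'
#' @param zmaps named list of z matrices ([zscore_map()]).
#' @param ummaps named list of thickness matrices (um).
#' @param dist boundary-distance matrix (degrees,
#'   [boundary_distance_map()]).
#' @param analyzable logical matrix of analyzable pixels.
#' @param spacing contour spacing in degrees.
#' @param K number of bands.
#' @param min_pixels minimum analyzable pixels per band.
#' @return data.frame: `band`, `distance_deg`, `lamina`, `mean_z`,
#'   `mean_um`, `n_pixels`.
#' @export
contour_band_means <- function(zmaps, ummaps, dist, analyzable,
                               spacing = 0.43, K = 18, min_pixels = 10) {
  stopifnot(K >= 1, spacing > 0)
  outside <- analyzable & dist > 0
  breaks <- (seq_len(K + 1) - 0.5) * spacing
  band <- findInterval(dist[outside], breaks, left.open = TRUE)
  band[band < 1L | band > K] <- NA_integer_
  rows <- list()
  for (l in names(zmaps)) {
    zv <- zmaps[[l]][outside]
    uv <- ummaps[[l]][outside]
    for (k in seq_len(K)) {
      sel <- which(band == k & !is.na(zv))
      n <- length(sel)
      rows[[length(rows) + 1L]] <- data.frame(
        band = k, distance_deg = k * spacing, lamina = l,
        mean_z = if (n >= min_pixels) mean(zv[sel]) else NA_real_,
        mean_um = if (n >= min_pixels) mean(uv[sel]) else NA_real_,
        n_pixels = n, stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Distance to thickness normalization
#'
#' The smallest contour distance at which a lamina's band-mean z-score
#' lies within the normative range (|z| <= threshold, default 2).
#' Returns NA (censored) when the profile never normalizes within the
#' available bands.
#'
#' @param profile data.frame from [contour_band_means()].
#' @param lamina lamina code.
#' @param threshold normative range half-width in z units.
#' @return list: `distance_deg` (NA if censored), `censored` (logical).
#' @export
distance_to_normalization <- function(profile, lamina, threshold = 2) {
  p <- profile[profile$lamina == lamina & !is.na(profile$mean_z), , drop = FALSE]
  if (!nrow(p)) stop("no non-missing bands for lamina ", lamina, call. = FALSE)
  p <- p[order(p$distance_deg), , drop = FALSE]
  ok <- abs(p$mean_z) <= threshold
  if (!any(ok)) return(list(distance_deg = NA_real_, censored = TRUE))
  list(distance_deg = p$distance_deg[which(ok)[1]], censored = FALSE)
}

#' ETDRS-grid subfield means
#'
#' Mean thickness (um) of each lamina within the nine standard ETDRS
#' subfields: central disc (1 mm diameter), inner ring (1-3 mm) and outer
#' ring (3-6 mm), the rings split into superior / nasal / inferior /
#' temporal quadrants on the 45-degree diagonals. The nasal direction is
#' taken toward the optic disc when `disc_px` is available (falling back
#' to +x). Invalid pixels are excluded.
#'
#' @param maps an [en_face_maps()].
#' @param mm_per_degree retinal scaling (defaults to the map geometry's).
#' @return data.frame: `lamina`, `subfield`, `mean_um`, `n_pixels`.
#' @export
etdrs_means <- function(maps, mm_per_degree = maps$geometry$mm_per_degree) {
  stopifnot(inherits(maps, "en_face_maps"))
  g <- maps$geometry
  grids <- deg_grids(g, maps$fovea_px)
  x_mm <- grids$x * mm_per_degree
  y_mm <- grids$y * mm_per_degree
  r_mm <- sqrt(x_mm^2 + y_mm^2)

  nasal_sign <- 1
  if (!is.null(maps$disc_px) && maps$disc_px[2] < maps$fovea_px[2]) nasal_sign <- -1
  xn <- x_mm * nasal_sign  # +xn = nasal

  ring <- ifelse(r_mm <= 0.5, "central",
          ifelse(r_mm <= 1.5, "inner",
          ifelse(r_mm <= 3.0, "outer", NA)))
  horiz <- abs(xn) >= abs(y_mm)   # ties to the horizontal quadrants
  quad <- ifelse(horiz & xn >= 0, "nasal",
          ifelse(horiz, "temporal",
          ifelse(y_mm < 0, "superior", "inferior")))  # row 1 = superior
  subfield <- ifelse(ring == "central", "central",
                     ifelse(is.na(ring), NA, paste(ring, quad, sep = "_")))

  fields <- c("central",
              paste("inner", c("superior", "nasal", "inferior", "temporal"),
                    sep = "_"),
              paste("outer", c("superior", "nasal", "inferior", "temporal"),
                    sep = "_"))
  rows <- list()
  for (l in names(maps$thickness)) {
    v <- maps$thickness[[l]]
    v[!maps$valid] <- NA_real_
    for (f in fields) {
      sel <- which(subfield == f & !is.na(v))
      rows[[length(rows) + 1L]] <- data.frame(
        lamina = l, subfield = f,
        mean_um = if (length(sel)) mean(v[sel]) else NA_real_,
        n_pixels = length(sel), stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Extract contour profiles for a set of visits
#'
#' Pipeline helper: for each visit map set, quantifies the lesion,
#' computes z-scores and boundary distances, and returns tidy band means.
#' For longitudinal rate analyses the bands can be anchored to the
#' first-visit boundary of each eye (`anchor = "first"`), as the rate
#' models require; `anchor = "visit"` uses each visit's own boundary
#' (cross-sectional convention).
#'
#' @param visits list of [en_face_maps()] (one or more eyes/visits; eyes
#'   identified by `meta$patient_id` / `meta$eye`).
#' @param normative a `normative_model`.
#' @param anchor `"visit"` or `"first"`.
#' @param spacing,K,min_pixels band parameters ([contour_band_means()]).
#' @param tol,disc_radius_deg lesion parameters ([quantify_lesion()]).
#' @return data.frame with identifier columns (`patient_id`, `eye`,
#'   `eye_id`, `age`, `time`, `area_mm2`, `sqrt_area_mm`) plus the band
#'   columns of [contour_band_means()]. Visits with no lesion are dropped
#'   (their count is in `attr(, "n_no_lesion")`).
#' @export
extract_contour_profiles <- function(visits, normative, anchor = c("visit", "first"),
                                     spacing = 0.43, K = 18, min_pixels = 10,
                                     tol = 0, disc_radius_deg = 5) {
  anchor <- match.arg(anchor)
  ids <- vapply(visits, function(m) {
    paste(m$meta$patient_id, m$meta$eye, sep = ":")
  }, character(1))
  ages <- vapply(visits, function(m) m$meta$age, numeric(1))
  n_no_lesion <- 0L
  anchor_dist <- list()  # per eye, first-visit distance map

  rows <- list()
  for (i in order(ids, ages)) {
    m <- visits[[i]]
    rec <- quantify_lesion(m, tol = tol, disc_radius_deg = disc_radius_deg)
    dist <- tryCatch(boundary_distance_map(rec$mask, m$geometry),
                     ezprog_no_lesion = function(e) NULL)
    key <- ids[i]
    if (anchor == "first") {
      if (is.null(anchor_dist[[key]]) && !is.null(dist)) {
        anchor_dist[[key]] <- dist
      }
      dist <- anchor_dist[[key]]
    }
    if (is.null(dist)) { n_no_lesion <- n_no_lesion + 1L; next }
    z <- zscore_map(m, normative)
    bands <- contour_band_means(z, m$thickness, dist, rec$analyzable,
                                spacing = spacing, K = K,
                                min_pixels = min_pixels)
    bands$patient_id <- m$meta$patient_id
    bands$eye <- m$meta$eye
    bands$eye_id <- key
    bands$age <- ages[i]
    bands$area_mm2 <- rec$area_mm2
    bands$sqrt_area_mm <- sqrt(rec$area_mm2)
    rows[[length(rows) + 1L]] <- bands
  }
  if (!length(rows)) {
    out <- data.frame()
  } else {
    out <- do.call(rbind, rows)
    first <- stats::ave(out$age, out$eye_id, FUN = min)
    out$time <- out$age - first
    rownames(out) <- NULL
  }
  attr(out, "n_no_lesion") <- n_no_lesion
  out
}
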