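#' En face map set
#'
#' Container for the per-visit en face thickness maps of one eye: one
#' matrix (um) per lamina on a common grid, plus geometry, fovea/disc
#' pixel coordinates, a validity mask (FALSE where vignetting or other
#' artifacts preclude analysis) and visit metadata.
#'
#' @param thickness named list of numeric matrices (um), names a subset of
#'   [EZ_LAMINAE]; all dimensions `n_bscans x n_ascans`.
#' @param geometry an [geometry()] object.
#' @param fovea_px fovea position, `c(row, col)` (may be fractional).
#' @param disc_px optic-disc position, `c(row, col)`; may lie outside the
#'   frame (the usual case for a fovea-centred 30x15 degree field).
#' @param valid logical matrix; `NULL` means all pixels valid.
#' @param meta list of visit metadata (`patient_id`, `eye`, `age`, ...).
#' @return object of class `en_face_maps`.
#' @export
en_face_maps <- function(thickness, geometry, fovea_px, disc_px = NULL,
                         valid = NULL, meta = list()) {
  stopifnot(is.list(thickness), length(thickness) >= 1,
            inherits(geometry, "ez_geometry"))
  dims <- c(geometry$n_bscans, geometry$n_ascans)
  for (nm in names(thickness)) {
    m <- thickness[[nm]]
    if (!is.matrix(m) || !all(dim(m) == dims)) {
      stop(sprintf("lamina '%s' has wrong shape (expected %d x %d)",
                   nm, dims[1], dims[2]), call. = FALSE)
    }
  }
  if (is.null(valid)) valid <- matrix(TRUE, dims[1], dims[2])
  stopifnot(is.logical(valid), all(dim(valid) == dims))
  if (fovea_px[1] < 1 || fovea_px[1] > dims[1] ||
      fovea_px[2] < 1 || fovea_px[2] > dims[2]) {
    stop("fovea_px must lie inside the grid", call. = FALSE)
  }
  neg <- vapply(names(thickness), function(nm) {
    any(thickness[[nm]][valid] < 0, na.rm = TRUE)
  }, logical(1))
  if (any(neg)) {
    stop("negative thickness on valid pixels: ",
         paste(names(thickness)[neg], collapse = ", "), call. = FALSE)
  }
  structure(
    list(thickness = thickness, geometry = geometry,
         fovea_px = as.numeric(fovea_px),
         disc_px = if (is.null(disc_px)) NULL else as.numeric(disc_px),
         valid = valid, meta = meta),
    class = "en_face_maps"
  )
}

#' @export
print.en_face_maps <- function(x, ...) {
  g <- x$geometry
  cat(sprintf("<en_face_maps> %d x %d px (%.1f x %.1f deg), laminae: %s\n",
              g$n_bscans, g$n_ascans,
              g$n_ascans * g$px_deg_x, g$n_bscans * g$px_deg_y,
              paste(names(x$thickness), collapse = ", ")))
  if (!is.null(x$meta$patient_id)) {
    cat(sprintf("  patient %s, eye %s, age %.2f y\n", x$meta$patient_id,
                x$meta$eye %||% "?", x$meta$age %||% NA_real_))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Pixel-centre coordinate grids in degrees relative to the fovea.
# Returns list(x, y, r) of matrices; x along A-scans, y along B-scans.
deg_grids <- function(geometry, fovea_px) {
  rows <- seq_len(geometry$n_bscans)
  cols <- seq_len(geometry$n_ascans)
  x <- outer(rep(1, geometry$n_bscans),
             (cols - fovea_px[2]) * geometry$px_deg_x)
  y <- outer((rows - fovea_px[1]) * geometry$px_deg_y,
             rep(1, geometry$n_ascans))
  list(x = x, y = y, r = sqrt(x^2 + y^2))
}
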