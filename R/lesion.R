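#' EZ-loss mask from the OS thickness map
#'
#' EZ loss is defined by the complete absence of photoreceptor outer
#' segments: a pixel is lesion iff its OS thickness is `<= tol` (default
#' exactly 0; a small positive tolerance accommodates real exports with
#' sub-micron noise) and the pixel is valid.
#'
#' @param maps an [en_face_maps()] with an `os` lamina.
#' @param tol absence tolerance in um (default 0).
#' @return logical matrix.
#' @export
ez_mask_from_os <- function(maps, tol = 0) {
  stopifnot(inherits(maps, "en_face_maps"))
  os <- maps$thickness[["os"]]
  if (is.null(os)) stop("OS lamina missing from map set", call. = FALSE)
  os <= tol & maps$valid
}

#' Apply region exclusions to a mask
#'
#' Removes from analysis the peri-papillary region (pixels within
#' `disc_radius_deg` of the optic disc) and pixels flagged invalid.
#' Excluded pixels are missing data: they are neither lesion nor intact.
#'
#' @param mask logical matrix (e.g. from [ez_mask_from_os()]).
#' @param maps the [en_face_maps()] supplying disc position and validity.
#' @param disc_radius_deg exclusion radius around the disc (degrees).
#' @return list with `mask` (lesion mask restricted to analyzable pixels)
#'   and `analyzable` (logical matrix of pixels usable for analysis).
#' @export
apply_exclusions <- function(mask, maps, disc_radius_deg = 5) {
  stopifnot(inherits(maps, "en_face_maps"))
  g <- maps$geometry
  analyzable <- maps$valid
  if (!is.null(maps$disc_px)) {
    rows <- seq_len(g$n_bscans); cols <- seq_len(g$n_ascans)
    dx <- outer(rep(1, g$n_bscans), (cols - maps$disc_px[2]) * g$px_deg_x)
    dy <- outer((rows - maps$disc_px[1]) * g$px_deg_y, rep(1, g$n_ascans))
    analyzable <- analyzable & (dx^2 + dy^2 > disc_radius_deg^2)
  }
  list(mask = mask & analyzable, analyzable = analyzable)
}

#' Lesion area from a pixel mask
#'
#' Area = pixel count x pixel area, where one pixel covers the B-scan
#' spacing times the A-scan pitch.
#'
#' @param mask logical matrix.
#' @param geom an [geometry()] object.
#' @return area in mm^2.
#' @export
lesion_area <- function(mask, geom) {
  stopifnot(inherits(geom, "ez_geometry"))
  px_area_um2 <- geom$bscan_spacing_um * geom$ascan_pitch_um
  sum(mask, na.rm = TRUE) * px_area_um2 / 1e6
}

#' Central EZ-band discontinuity length of one B-scan
#'
#' Implements the manual grading rule: starting at each peripheral edge of
#' the scan and moving toward the fovea, the start of the discontinuity is
#' the first EZ-absent pixel, except that an absent run shorter than
#' `forgive_um` (strictly; default 250 um) is forgiven — attributed to a
#' fleck, not to EZ loss — when a contiguous EZ-present run of at least
#' `intact_um` (default 200 um) lies on its fovea side. `X_k` is the span
#' between the left-side and right-side discontinuity starts; 0 when
#' neither side has a (non-forgiven) discontinuity. If only one side has
#' one, the span runs from that start to the fovea-most absent pixel on
#' that side.
#'
#' Pixels excluded from analysis (`analyzable` FALSE) are missing data:
#' they neither start a discontinuity nor contribute to run lengths.
#'
#' @param os_row numeric vector, OS thickness along one B-scan (um).
#' @param pitch_um A-scan pitch (um).
#' @param fovea_col fovea column (may be fractional).
#' @param analyzable optional logical vector; FALSE = excluded.
#' @param tol absence tolerance (um).
#' @param forgive_um,intact_um break-forgiveness parameters (um).
#' @return discontinuity length `X_k` in um.
#' @export
bscan_discontinuity_length <- function(os_row, pitch_um, fovea_col,
                                       analyzable = NULL, tol = 0,
                                       forgive_um = 250, intact_um = 200) {
  n <- length(os_row)
  stopifnot(n >= 1, fovea_col >= 1, fovea_col <= n)
  if (is.null(analyzable)) analyzable <- rep(TRUE, n)
  absent <- os_row <= tol & analyzable
  present <- os_row > tol & analyzable

  # per-side scan over column indices ordered periphery -> fovea
  scan_side <- function(idx) {
    if (!length(idx)) return(NA_integer_)
    runs <- rle(absent[idx])
    pos <- 1L
    for (j in seq_along(runs$lengths)) {
      len <- runs$lengths[j]
      if (runs$values[j]) {
        run_cols <- idx[pos:(pos + len - 1L)]
        # length counts only analyzable pixels of the run
        run_um <- sum(analyzable[run_cols]) * pitch_um
        fovea_side <- if (pos + len <= length(idx)) idx[(pos + len):length(idx)] else integer(0)
        forgiven <- run_um < forgive_um &&
          has_intact_run(present[fovea_side], intact_um, pitch_um)
        if (!forgiven) return(run_cols[1])
      }
      pos <- pos + len
    }
    NA_integer_
  }

  left_idx <- seq_len(floor(fovea_col))                  # periphery -> fovea
  right_idx <- rev(seq.int(ceiling(fovea_col), n))       # periphery -> fovea
  lstart <- scan_side(left_idx)
  rstart <- scan_side(right_idx)

  if (is.na(lstart) && is.na(rstart)) return(0)
  if (is.na(rstart)) {
    # gap confined to the left side: span to its fovea-most absent pixel
    inner <- max(which(absent & seq_len(n) >= lstart &
                         seq_len(n) <= floor(fovea_col)))
    return(sum(analyzable[lstart:inner]) * pitch_um)
  }
  if (is.na(lstart)) {
    inner <- min(which(absent & seq_len(n) <= rstart &
                         seq_len(n) >= ceiling(fovea_col)))
    return(sum(analyzable[inner:rstart]) * pitch_um)
  }
  sum(analyzable[lstart:rstart]) * pitch_um
}

# TRUE when a logical vector (ordered toward the fovea) contains a
# contiguous TRUE run of at least `intact_um`.
has_intact_run <- function(present_side, intact_um, pitch_um) {
  if (!length(present_side)) return(FALSE)
  runs <- rle(present_side)
  any(runs$values & runs$lengths * pitch_um >= intact_um)
}

#' EZ-loss area from per-B-scan discontinuity lengths (Riemann sum)
#'
#' `Area = sum_k X_k * DeltaX`, converted from um^2 to mm^2, where `X_k`
#' is the central EZ-band discontinuity length of B-scan `k` and `DeltaX`
#' the distance between B-scans.
#'
#' @param lengths_um numeric vector of `X_k` (um), one per B-scan.
#' @param dx_um B-scan spacing (um).
#' @return area in mm^2.
#' @export
riemann_area <- function(lengths_um, dx_um) {
  stopifnot(dx_um > 0)
  if (any(lengths_um < 0, na.rm = TRUE)) {
    stop("discontinuity lengths must be non-negative", call. = FALSE)
  }
  sum(lengths_um, na.rm = TRUE) * dx_um / 1e6
}

#' Quantify EZ loss for one visit
#'
#' Convenience wrapper running both quantification routes on a map set:
#' the map-threshold route (mask + pixel-count area) and the B-scan-wise
#' Riemann-sum route with break forgiveness.
#'
#' @param maps an [en_face_maps()].
#' @param tol OS absence tolerance (um).
#' @param disc_radius_deg peri-papillary exclusion radius.
#' @return list of class `lesion_record`: `mask`, `analyzable`,
#'   `area_mm2` (map route), `per_bscan_um`, `riemann_area_mm2`.
#' @export
quantify_lesion <- function(maps, tol = 0, disc_radius_deg = 5) {
  raw <- ez_mask_from_os(maps, tol = tol)
  ex <- apply_exclusions(raw, maps, disc_radius_deg = disc_radius_deg)
  g <- maps$geometry
  os <- maps$thickness[["os"]]
  lengths <- vapply(seq_len(g$n_bscans), function(k) {
    bscan_discontinuity_length(os[k, ], g$ascan_pitch_um, maps$fovea_px[2],
                               analyzable = ex$analyzable[k, ], tol = tol)
  }, numeric(1))
  structure(
    list(mask = ex$mask, analyzable = ex$analyzable,
         area_mm2 = lesion_area(ex$mask, g),
         per_bscan_um = lengths,
         riemann_area_mm2 = riemann_area(lengths, g$bscan_spacing_um),
         meta = maps$meta),
    class = "lesion_record"
  )
}
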