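# Exact 1-D squared-distance transform (lower envelope of parabolas),
# sample spacing `s`. `f` holds squared-distance offsets (Inf = no site).
dt1d_sq <- function(f, s) {
  n <- length(f)
  fin <- which(is.finite(f))
  if (!length(fin)) return(f)
  x <- (seq_len(n) - 1) * s
  v <- integer(n); zl <- numeric(n); zr <- numeric(n)
  k <- 1L
  v[1] <- fin[1]; zl[1] <- -Inf; zr[1] <- Inf
  if (length(fin) > 1) {
    for (q in fin[-1]) {
      repeat {
        p <- v[k]
        s_int <- ((f[q] + x[q]^2) - (f[p] + x[p]^2)) / (2 * (x[q] - x[p]))
        if (s_int <= zl[k]) {
          k <- k - 1L
          if (k == 0L) break
        } else break
      }
      if (k == 0L) {
        k <- 1L; v[1] <- q; zl[1] <- -Inf; zr[1] <- Inf
      } else {
        k <- k + 1L; v[k] <- q
        zl[k] <- s_int; zr[k - 1L] <- s_int; zr[k] <- Inf
      }
    }
  }
  out <- numeric(n); ki <- 1L
  for (q in seq_len(n)) {
    while (zr[ki] < x[q]) ki <- ki + 1L
    p <- v[ki]
    out[q] <- (x[q] - x[p])^2 + f[p]
  }
  out
}

# Exact anisotropic Euclidean distance transform: distance from every
# pixel to the nearest TRUE pixel of `mask`, with per-axis pixel pitch
# (sy rows, sx columns), via the separable parabolic-envelope algorithm.
edt_aniso <- function(mask, sx, sy) {
  nr <- nrow(mask); nc <- ncol(mask)
  g <- matrix(Inf, nr, nc)
  g[mask] <- 0
  for (j in seq_len(nc)) g[, j] <- dt1d_sq(g[, j], sy)
  for (i in seq_len(nr)) g[i, ] <- dt1d_sq(g[i, ], sx)
  sqrt(g)
}

#' Distance to the EZ-loss boundary
#'
#' For every pixel, the Euclidean distance (degrees) to the nearest lesion
#' pixel, computed with an exact distance transform that honours the
#' strongly anisotropic pixel pitch of en face OCT grids (B-scan spacing
#' much larger than the A-scan pitch). Lesion pixels have distance 0;
#' with multifocal lesions the distance is to the nearest pixel of any
#' component.
#'
#' @param mask logical lesion mask.
#' @param geom an [geometry()] object.
#' @return numeric matrix of distances in degrees.
#' @section No lesion: an empty mask raises a condition of class
#'   `ezprog_no_lesion`; callers that iterate over eyes catch it and skip
#'   the contour stage for that visit.
#' @export
boundary_distance_map <- function(mask, geom) {
  stopifnot(inherits(geom, "ez_geometry"),
            all(dim(mask) == c(geom$n_bscans, geom$n_ascans)))
  if (!any(mask)) {
    stop(structure(
      class = c("ezprog_no_lesion", "error", "condition"),
      list(message = "empty lesion mask: no EZ loss to measure from",
           call = sys.call(-1))
    ))
  }
  edt_aniso(mask, geom$px_deg_x, geom$px_deg_y)
}
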