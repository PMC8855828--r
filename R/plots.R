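#' Plot square-root-area progression
#'
#' Spaghetti plot of sqrt-transformed EZ-loss area over time per eye with
#' the mixed-model population trend overlaid.
#'
#' @param table longitudinal table (`time`, `sqrt_area_mm`, `eye_id`).
#' @param fit optional `ez_mixed_fit` from [fit_sqrt_area_mixed()].
#' @return a ggplot object.
#' @export
plot_progression <- function(table, fit = NULL) {
  p <- ggplot2::ggplot(table, ggplot2::aes(x = .data$time,
                                           y = .data$sqrt_area_mm,
                                           group = .data$eye_id)) +
    ggplot2::geom_line(alpha = 0.3) +
    ggplot2::labs(x = "time since first visit (y)",
                  y = expression(sqrt("EZ-loss area") ~ "(mm)"))
  if (!is.null(fit)) {
    icpt <- fixed_est(fit, "(Intercept)")
    slope <- fixed_est(fit, "time")
    p <- p + ggplot2::geom_abline(intercept = icpt, slope = slope,
                                  colour = "red", linetype = "dashed")
  }
  p + ggplot2::theme_minimal()
}

#' Plot Box-Cox profile likelihood
#'
#' @param bc an `ez_boxcox` from [boxcox_profile()].
#' @return a ggplot object.
#' @export
plot_boxcox <- function(bc) {
  d <- data.frame(lambda = bc$lambda, loglik = bc$loglik)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$lambda, y = .data$loglik)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = bc$lambda_opt, linetype = "dashed",
                        colour = "red") +
    ggplot2::labs(x = expression(lambda), y = "profile log-likelihood") +
    ggplot2::theme_minimal()
}

#' Plot contour profiles
#'
#' Per-eye layer z-score as a function of distance from the EZ-loss
#' boundary, one panel per lamina, with the normative band marked.
#'
#' @param profiles output of [extract_contour_profiles()] (first-visit
#'   rows are selected).
#' @param threshold normative range half-width (z units).
#' @return a ggplot object.
#' @export
plot_contour_profiles <- function(profiles, threshold = 2) {
  d <- profiles[profiles$time == 0 & !is.na(profiles$mean_z), ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$distance_deg, y = .data$mean_z,
                                  group = .data$eye_id)) +
    ggplot2::geom_line(alpha = 0.3) +
    ggplot2::geom_hline(yintercept = c(-threshold, threshold),
                        linetype = "dashed", colour = "red") +
    ggplot2::facet_wrap(~lamina, scales = "free_y") +
    ggplot2::labs(x = "distance to EZ-loss boundary (deg)",
                  y = "layer thickness (z)") +
    ggplot2::theme_minimal()
}

#' Plot thinning rate by contour distance
#'
#' Dot-and-interval plot of fitted thinning rates (fixed slope, 95% CI)
#' across contour bands for one lamina.
#'
#' @param profiles longitudinal profiles anchored at the first-visit
#'   boundary.
#' @param lamina lamina code.
#' @param bands band indices to fit.
#' @return a ggplot object.
#' @export
plot_rate_by_distance <- function(profiles, lamina, bands = c(1, 3, 6, 12, 18)) {
  rows <- lapply(bands, function(k) {
    f <- tryCatch(fit_contour_rate(profiles, lamina, k),
                  error = function(e) NULL)
    if (is.null(f)) return(NULL)
    i <- term_index(f, "time")
    data.frame(band = k, distance_deg = unique(
                 profiles$distance_deg[profiles$band == k]),
               rate = f$fixed$estimate[i], lo = f$fixed$ci_lo[i],
               hi = f$fixed$ci_hi[i])
  })
  d <- do.call(rbind, rows)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$distance_deg, y = .data$rate)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$lo, ymax = .data$hi)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "distance to first-visit EZ-loss boundary (deg)",
                  y = "rate of change (z/y)") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
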