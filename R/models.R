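#' @importFrom stats as.formula coef logLik lm pnorm qnorm qt sd var vcov
NULL

# Fit a linear mixed model via lmerTest (Satterthwaite inference), falling
# back to OLS with normal-approximation inference when the mixed fit is
# degenerate (e.g. zero residual variance in noise-free data makes lme4
# error). Returns an `ez_mixed_fit`.
fit_lmm <- function(formula, data, REML = TRUE, level = 0.95) {
  a2 <- (1 - level) / 2
  fit <- tryCatch(
    suppressMessages(suppressWarnings(
      lmerTest::lmer(formula, data = data, REML = REML,
                     control = lme4::lmerControl(
                       check.conv.singular = "ignore",
                       check.conv.grad = "ignore",
                       check.conv.hess = "ignore"))
    )),
    error = function(e) NULL
  )
  if (!is.null(fit)) {
    ct <- tryCatch(coef(summary(fit)), error = function(e) NULL)
    if (!is.null(ct) && all(is.finite(ct[, "Std. Error"]))) {
      df <- ct[, "df"]; est <- ct[, "Estimate"]; se <- ct[, "Std. Error"]
      inference <- "satterthwaite"
      if (any(!is.finite(df))) { df[!is.finite(df)] <- Inf; inference <- "normal" }
      tcrit <- qt(1 - a2, df)
      fixed <- data.frame(
        term = rownames(ct), estimate = est, se = se, df = df,
        ci_lo = est - tcrit * se, ci_hi = est + tcrit * se,
        p = ct[, "Pr(>|t|)"], stringsAsFactors = FALSE
      )
      vc <- as.data.frame(lme4::VarCorr(fit))
      varcomp <- stats::setNames(vc$vcov, paste0(
        vc$grp, ifelse(is.na(vc$var1), "", paste0(".", vc$var1)),
        ifelse(is.na(vc$var2), "", paste0(":", vc$var2))))
      return(new_mixed_fit(fixed, varcomp, as.numeric(logLik(fit)),
                           nrow(data), data, fit,
                           method = if (REML) "REML" else "ML",
                           inference = inference))
    }
  }
  # OLS fallback (degenerate variance structure)
  lhs_rhs <- strip_bars(formula)
  ols <- lm(lhs_rhs, data = data)
  sm <- suppressWarnings(summary(ols))
  ct <- coef(sm)
  est <- ct[, 1]; se <- ct[, 2]
  zcrit <- qnorm(1 - a2)
  pz <- 2 * pnorm(-abs(est / ifelse(se > 0, se, Inf)))
  fixed <- data.frame(
    term = rownames(ct), estimate = est, se = se, df = Inf,
    ci_lo = est - zcrit * se, ci_hi = est + zcrit * se,
    p = pz, stringsAsFactors = FALSE
  )
  varcomp <- c(Residual = sm$sigma^2)
  new_mixed_fit(fixed, varcomp, as.numeric(logLik(ols)), nrow(data),
                data, ols, method = "ols", inference = "normal")
}

# Fixed-effects-only counterpart of a mixed formula (drop (...|g) terms).
strip_bars <- function(formula) {
  rhs <- attr(stats::terms(formula), "term.labels")
  rhs <- rhs[!grepl("\\|", rhs)]
  icpt <- attr(stats::terms(formula), "intercept")
  lhs <- deparse(formula[[2]])
  rhs_str <- paste(c(if (!icpt) "0", rhs), collapse = " + ")
  if (rhs_str == "") rhs_str <- "1"
  as.formula(paste(lhs, "~", rhs_str))
}

new_mixed_fit <- function(fixed, varcomp, loglik, n_obs, data, model,
                          method, inference) {
  rownames(fixed) <- NULL
  n_eyes <- if ("eye_id" %in% names(data)) length(unique(data$eye_id)) else NA_integer_
  n_pat <- if ("patient_id" %in% names(data)) length(unique(data$patient_id)) else NA_integer_
  structure(
    list(fixed = fixed, varcomp = varcomp, loglik = loglik,
         n_obs = n_obs, n_eyes = n_eyes, n_patients = n_pat,
         method = method, inference = inference, model = model),
    class = "ez_mixed_fit"
  )
}

#' @export
print.ez_mixed_fit <- function(x, ...) {
  cat(sprintf("<ez_mixed_fit> %s fit (%s inference), n = %d obs / %s eyes / %s patients\n",
              x$method, x$inference, x$n_obs,
              ifelse(is.na(x$n_eyes), "?", x$n_eyes),
              ifelse(is.na(x$n_patients), "?", x$n_patients)))
  print(x$fixed, digits = 4)
  cat("variance components:\n"); print(round(x$varcomp, 6))
  invisible(x)
}

#' Fixed-effect accessors
#'
#' @param fit an `ez_mixed_fit`.
#' @param term term name or index.
#' @return `fixed_est()`: the estimate; `fixed_ci()`: `c(lower, upper)` of
#'   the 95% CI; `term_index()`: the row index of the term.
#' @export
fixed_est <- function(fit, term = 1) fit$fixed$estimate[term_index(fit, term)]

#' @rdname fixed_est
#' @export
fixed_ci <- function(fit, term = 1) {
  i <- term_index(fit, term)
  c(fit$fixed$ci_lo[i], fit$fixed$ci_hi[i])
}

#' @rdname fixed_est
#' @export
term_index <- function(fit, term) {
  if (is.numeric(term)) return(term)
  match(term, fit$fixed$term)
}

#' Box-Cox profile likelihood over a lambda grid
#'
#' For each lambda, transforms the EZ-loss area with
#' `y = (area^lambda - 1) / lambda` (`log(area)` at lambda = 0), fits the
#' random-intercept-and-slope mixed model `y ~ time` with eye nested in
#' patient by maximum likelihood, and records the profile log-likelihood
#' including the Box-Cox Jacobian term `(lambda - 1) * sum(log(area))`,
#' which makes log-likelihoods comparable across lambdas. The optimum is
#' the argmax. Zero-area visits (transform undefined) are excluded and
#' counted.
#'
#' @param table longitudinal table with `area_mm2`, `time`, `patient_id`,
#'   `eye_id` ([simulate_area_table()] format).
#' @param lambdas lambda grid (default 0 to 1 in steps of 0.05).
#' @return list of class `ez_boxcox`: `lambda`, `loglik`, `lambda_opt`,
#'   `n_dropped_zero`.
#' @export
boxcox_profile <- function(table, lambdas = seq(0, 1, by = 0.05)) {
  stopifnot(all(c("area_mm2", "time", "patient_id", "eye_id") %in% names(table)))
  keep <- table$area_mm2 > 0
  n_dropped <- sum(!keep)
  tab <- table[keep, , drop = FALSE]
  if (!nrow(tab)) stop("no positive-area visits for Box-Cox profiling", call. = FALSE)
  jac <- sum(log(tab$area_mm2))
  ll <- vapply(lambdas, function(lam) {
    tab$y <- if (lam == 0) log(tab$area_mm2) else (tab$area_mm2^lam - 1) / lam
    fit <- fit_lmm(y ~ time + (1 + time | patient_id) + (1 + time | eye_id),
                   tab, REML = FALSE)
    fit$loglik + (lam - 1) * jac
  }, numeric(1))
  structure(
    list(lambda = lambdas, loglik = ll,
         lambda_opt = lambdas[which.max(ll)], n_dropped_zero = n_dropped),
    class = "ez_boxcox"
  )
}

#' Square-root-area progression model
#'
#' Fits `sqrt_area ~ 1 + time` with random intercepts and slopes for
#' patient and for eye nested in patient. The fixed intercept is the
#' population square-root-transformed EZ-loss area at the first visit;
#' the fixed slope is the annual progression rate (mm/y).
#'
#' @param table longitudinal table with `sqrt_area_mm`, `time`,
#'   `patient_id`, `eye_id`. Zero-area visits are included (sqrt = 0).
#' @param REML use REML (default) or ML.
#' @return an `ez_mixed_fit`.
#' @export
fit_sqrt_area_mixed <- function(table, REML = TRUE) {
  stopifnot(all(c("sqrt_area_mm", "time", "patient_id", "eye_id") %in% names(table)))
  if (length(unique(table$time)) < 2) {
    stop("degenerate design: all visit times equal", call. = FALSE)
  }
  fit_lmm(sqrt_area_mm ~ time + (1 + time | patient_id) + (1 + time | eye_id),
          table, REML = REML)
}

#' Cross-sectional contour deficit model
#'
#' For one lamina and one contour band at the first visit, fits the
#' intercept-only mixed model `mean_z ~ 1` with a patient random
#' intercept (eyes are the residual level: one band value per eye). The
#' fixed intercept is the population deficit at that band. Feeding
#' `response = "mean_um"` gives the same model on the micron scale.
#'
#' @param profiles first-visit profiles ([extract_contour_profiles()]
#'   rows, or any data.frame with `patient_id`, `eye_id`, the response,
#'   `lamina`, `band`).
#' @param lamina lamina code.
#' @param band band index k (distance k x spacing).
#' @param response `"mean_z"` or `"mean_um"`.
#' @return an `ez_mixed_fit`.
#' @export
fit_contour_cross_section <- function(profiles, lamina, band,
                                      response = "mean_z") {
  d <- profiles[profiles$lamina == lamina & profiles$band == band &
                  !is.na(profiles[[response]]), , drop = FALSE]
  if (nrow(d) < 2) stop("fewer than 2 eyes with non-missing band values", call. = FALSE)
  d$y <- d[[response]]
  fit_lmm(y ~ 1 + (1 | patient_id), d, REML = TRUE)
}

#' Longitudinal contour thinning-rate model
#'
#' For one lamina and one contour band, fits `value ~ 1 + time` with
#' random intercepts and slopes for patient and eye nested in patient.
#' The fixed slope is the thinning rate (z/y, or um/y when
#' `response = "mean_um"`). The caller must supply profiles whose bands
#' are anchored to the first-visit boundary
#' (`extract_contour_profiles(..., anchor = "first")`), matching the
#' definition of change at a fixed retinal location.
#'
#' @inheritParams fit_contour_cross_section
#' @return an `ez_mixed_fit`.
#' @export
fit_contour_rate <- function(profiles, lamina, band, response = "mean_z") {
  d <- profiles[profiles$lamina == lamina & profiles$band == band &
                  !is.na(profiles[[response]]), , drop = FALSE]
  if (length(unique(d$time)) < 2) {
    stop("insufficient longitudinal depth for a rate model", call. = FALSE)
  }
  d$y <- d[[response]]
  fit_lmm(y ~ time + (1 + time | patient_id) + (1 + time | eye_id),
          d, REML = TRUE)
}

#' Average distance to thickness normalization
#'
#' Summarizes per-eye first-visit distances to normalization for one
#' lamina with the intercept-only mixed model `distance ~ 1` with a
#' patient random intercept. Censored eyes (never normalizing within the
#' measured bands) are excluded and counted.
#'
#' @param distances data.frame with `patient_id`, `eye_id`,
#'   `distance_deg` (NA = censored), `lamina`.
#' @param lamina lamina code.
#' @return an `ez_mixed_fit` with `n_censored` attached.
#' @export
summarize_normalization_distance <- function(distances, lamina) {
  d <- distances[distances$lamina == lamina, , drop = FALSE]
  cens <- sum(is.na(d$distance_deg))
  d <- d[!is.na(d$distance_deg), , drop = FALSE]
  if (nrow(d) < 2) stop("fewer than 2 non-censored eyes", call. = FALSE)
  d$y <- d$distance_deg
  fit <- fit_lmm(y ~ 1 + (1 | patient_id), d, REML = TRUE)
  fit$n_censored <- cens
  fit
}

#' Per-eye distances to normalization at the first visit
#'
#' @param profiles output of [extract_contour_profiles()].
#' @param laminae lamina codes to summarize.
#' @param threshold normative range half-width (z units).
#' @return data.frame: `patient_id`, `eye_id`, `lamina`, `distance_deg`
#'   (NA = censored).
#' @export
normalization_distances <- function(profiles, laminae = EZ_LAMINAE,
                                    threshold = 2) {
  first <- profiles[profiles$time == 0, , drop = FALSE]
  eyes <- unique(first[, c("patient_id", "eye_id")])
  rows <- list()
  for (i in seq_len(nrow(eyes))) {
    p <- first[first$eye_id == eyes$eye_id[i], , drop = FALSE]
    for (l in intersect(laminae, unique(p$lamina))) {
      dn <- tryCatch(distance_to_normalization(p, l, threshold),
                     error = function(e) list(distance_deg = NA_real_,
                                              censored = TRUE))
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = eyes$patient_id[i], eye_id = eyes$eye_id[i],
        lamina = l, distance_deg = dn$distance_deg,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
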