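#' Impute the age of criterion EZ-loss for one eye
#'
#' Fits an ordinary least-squares line to the square-root-transformed
#' EZ-loss areas of one eye over age and solves for the age at which the
#' fitted line reaches the criterion size (2.5 mm on the square-root
#' scale, i.e. 6.25 mm^2), extrapolating in either direction. When any
#' visit exceeds the frame-ceiling area (16 mm^2, lesions reaching the
#' limits of the 30 x 15 degree frame), the line is determined from the
#' first two visits only and the record is flagged. Requires at least two
#' visits with measurable (positive) area; a non-positive slope yields a
#' missing age with a reason code.
#'
#' @param ages visit ages (years).
#' @param areas_mm2 EZ-loss areas (mm^2), same length.
#' @param criterion_sqrt_mm criterion on the sqrt scale (default 2.5).
#' @param ceiling_mm2 frame-ceiling area (default 16).
#' @return one-row data.frame: `age_criterion`, `slope` (mm/y on the sqrt
#'   scale), `intercept`, `n_visits_used`, `ceiling_rule_applied`,
#'   `reason` (`"ok"`, `"too_few_visits"`, `"nonpositive_slope"`).
#' @export
impute_age_of_criterion <- function(ages, areas_mm2,
                                    criterion_sqrt_mm = 2.5,
                                    ceiling_mm2 = 16) {
  stopifnot(length(ages) == length(areas_mm2))
  ord <- order(ages)
  ages <- ages[ord]; areas_mm2 <- areas_mm2[ord]
  measurable <- is.finite(areas_mm2) & areas_mm2 > 0 & is.finite(ages)
  res <- function(age, slope, icpt, n, ceiling, reason) {
    data.frame(age_criterion = age, slope = slope, intercept = icpt,
               n_visits_used = n, ceiling_rule_applied = ceiling,
               reason = reason, stringsAsFactors = FALSE)
  }
  if (sum(measurable) < 2) {
    return(res(NA_real_, NA_real_, NA_real_, sum(measurable), FALSE,
               "too_few_visits"))
  }
  a <- ages[measurable]; y <- sqrt(areas_mm2[measurable])
  ceiling_rule <- any(areas_mm2[measurable] > ceiling_mm2)
  if (ceiling_rule) { a <- a[1:2]; y <- y[1:2] }
  if (length(unique(a)) < 2) {
    return(res(NA_real_, NA_real_, NA_real_, length(a), ceiling_rule,
               "too_few_visits"))
  }
  fit <- lm(y ~ a)
  icpt <- unname(coef(fit)[1]); slope <- unname(coef(fit)[2])
  if (!is.finite(slope) || slope <= 0) {
    return(res(NA_real_, slope, icpt, length(a), ceiling_rule,
               "nonpositive_slope"))
  }
  res((criterion_sqrt_mm - icpt) / slope, slope, icpt, length(a),
      ceiling_rule, "ok")
}

#' Impute ages of criterion EZ-loss for a cohort
#'
#' @param table longitudinal table with `patient_id`, `eye`, `eye_id`,
#'   `age`, `area_mm2`.
#' @inheritParams impute_age_of_criterion
#' @return data.frame, one row per eye, with identifiers plus the columns
#'   of [impute_age_of_criterion()].
#' @export
impute_cohort_ages <- function(table, criterion_sqrt_mm = 2.5,
                               ceiling_mm2 = 16) {
  eyes <- unique(table[, c("patient_id", "eye", "eye_id")])
  rows <- lapply(seq_len(nrow(eyes)), function(i) {
    d <- table[table$eye_id == eyes$eye_id[i], ]
    cbind(eyes[i, , drop = FALSE],
          impute_age_of_criterion(d$age, d$area_mm2, criterion_sqrt_mm,
                                  ceiling_mm2))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Additive allele design matrix
#'
#' Builds the allele-count design of the additive severity model: one row
#' per eye (patient rows duplicated per eye), one column per distinct
#' variant, entries = copies carried (0/1/2), no intercept. All
#' null-class (protein-truncating or functionally equivalent) variants are
#' pooled into a single `null` column, matching the single null severity
#' the model reports.
#'
#' @param genotypes data.frame with `patient_id`, `variant_a`,
#'   `variant_b` (exactly two variants per patient; others are rejected).
#' @param null_labels character vector of variant labels to pool as null.
#' @param eyes eye labels replicated per patient.
#' @return list: `design` (matrix, rownames `patient:eye`), `patient_id`,
#'   `eye_id` (row identifiers), `variants` (column labels).
#' @export
build_allele_design <- function(genotypes, null_labels = "null",
                                eyes = c("right", "left")) {
  stopifnot(nrow(genotypes) >= 1,
            all(c("patient_id", "variant_a", "variant_b") %in% names(genotypes)))
  if (anyDuplicated(genotypes$patient_id)) {
    stop("one genotype row per patient required", call. = FALSE)
  }
  bad <- !stats::complete.cases(genotypes[, c("variant_a", "variant_b")])
  if (any(bad)) {
    stop("patients without exactly 2 variants: ",
         paste(genotypes$patient_id[bad], collapse = ", "), call. = FALSE)
  }
  pool_null <- function(v) ifelse(v %in% null_labels, "null", v)
  va <- pool_null(genotypes$variant_a)
  vb <- pool_null(genotypes$variant_b)
  variants <- sort(unique(c(va, vb)))
  np <- nrow(genotypes)
  X1 <- matrix(0L, np, length(variants), dimnames = list(genotypes$patient_id, variants))
  for (i in seq_len(np)) {
    X1[i, va[i]] <- X1[i, va[i]] + 1L
    X1[i, vb[i]] <- X1[i, vb[i]] + 1L
  }
  X <- X1[rep(seq_len(np), each = length(eyes)), , drop = FALSE]
  patient_id <- rep(genotypes$patient_id, each = length(eyes))
  eye <- rep(eyes, times = np)
  eye_id <- paste(patient_id, eye, sep = ":")
  rownames(X) <- eye_id
  list(design = X, patient_id = patient_id, eye = eye, eye_id = eye_id,
       variants = variants)
}

#' Fit the additive allele-severity model
#'
#' Mixed model `age_criterion = X s + b_patient + e_eye` where `X` is the
#' allele-count design (no intercept), `b_patient` a patient random
#' intercept and the eye the residual level. Each severity `s_v` is the
#' absolute additive contribution (years) of one allele `v` to the age of
#' criterion EZ-loss, so a genotype prediction is the plain sum of its two
#' severities. Variants with no carriers among the non-missing responses
#' (or aliased columns) are dropped and reported, never silently imputed.
#' Marginal R^2 = Var(X s) / (Var(X s) + Var(patient) + Var(residual)).
#'
#' @param design output of [build_allele_design()].
#' @param ages data.frame with `eye_id` and `age_criterion`
#'   ([impute_cohort_ages()] format); eyes with missing ages are dropped.
#' @return list of class `ez_severity_table`: `severities` (data.frame
#'   `variant`, `severity_years`, `se`, `ci_lo`, `ci_hi`, `n_alleles`),
#'   `marginal_r2`, `varcomp`, `dropped`, `fit` (`ez_mixed_fit`),
#'   `n_eyes`, `n_patients`.
#' @export
fit_additive_model <- function(design, ages) {
  stopifnot(all(c("eye_id", "age_criterion") %in% names(ages)))
  idx <- match(design$eye_id, ages$eye_id)
  y <- ages$age_criterion[idx]
  keep <- !is.na(y)
  X <- design$design[keep, , drop = FALSE]
  d <- data.frame(y = y[keep], patient_id = design$patient_id[keep],
                  eye_id = design$eye_id[keep], stringsAsFactors = FALSE)

  counts <- colSums(X)
  dropped <- colnames(X)[counts == 0]
  X <- X[, counts > 0, drop = FALSE]
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    dropped <- c(dropped, aliased)
    X <- X[, setdiff(colnames(X), aliased), drop = FALSE]
  }
  vars <- colnames(X)
  safe <- paste0("v", seq_along(vars))
  dd <- cbind(d, as.data.frame(X) |> stats::setNames(safe))
  form <- as.formula(paste("y ~ 0 +", paste(safe, collapse = " + "),
                           "+ (1 | patient_id)"))
  fit <- fit_lmm(form, dd, REML = TRUE)
  fx <- fit$fixed
  sev <- data.frame(
    variant = vars,
    severity_years = fx$estimate[match(safe, fx$term)],
    se = fx$se[match(safe, fx$term)],
    ci_lo = fx$ci_lo[match(safe, fx$term)],
    ci_hi = fx$ci_hi[match(safe, fx$term)],
    n_alleles = colSums(X), stringsAsFactors = FALSE
  )
  rownames(sev) <- NULL
  pred <- as.numeric(X %*% sev$severity_years)
  var_fix <- stats::var(pred)
  var_pat <- sum(fit$varcomp[grepl("^patient_id", names(fit$varcomp))])
  var_res <- unname(fit$varcomp[["Residual"]])
  marg_r2 <- var_fix / (var_fix + var_pat + var_res)
  structure(
    list(severities = sev, marginal_r2 = marg_r2,
         varcomp = c(patient = var_pat, residual = var_res),
         dropped = dropped, fit = fit,
         n_eyes = nrow(dd), n_patients = length(unique(dd$patient_id))),
    class = "ez_severity_table"
  )
}

#' @export
print.ez_severity_table <- function(x, ...) {
  cat(sprintf("<ez_severity_table> %d variants, %d eyes / %d patients, marginal R2 = %.3f\n",
              nrow(x$severities), x$n_eyes, x$n_patients, x$marginal_r2))
  print(x$severities, digits = 4)
  if (length(x$dropped)) cat("dropped (inestimable):",
                             paste(x$dropped, collapse = ", "), "\n")
  invisible(x)
}

#' Predict the age of criterion EZ-loss from a genotype
#'
#' The additive model's prediction is the plain sum of the two allele
#' severities.
#'
#' @param genotype character vector of two variant labels.
#' @param table an `ez_severity_table`, or a data.frame with `variant` and
#'   `severity_years` columns (e.g. the published table from
#'   [published_severities()]).
#' @param null_labels labels mapped onto the pooled `null` class.
#' @return predicted age (years).
#' @export
predict_age <- function(genotype, table, null_labels = "null") {
  stopifnot(length(genotype) == 2)
  sev <- if (inherits(table, "ez_severity_table")) table$severities else table
  g <- ifelse(genotype %in% null_labels, "null", genotype)
  i <- match(g, sev$variant)
  if (any(is.na(i))) {
    stop("unknown variant(s): ", paste(genotype[is.na(i)], collapse = ", "),
         call. = FALSE)
  }
  sum(sev$severity_years[i])
}

#' Published allele-severity estimates
#'
#' The per-allele contributions (years) to the age of criterion EZ-loss
#' printed in the source study's worked examples: the pooled null class
#' (6.88 y) and p.Gly1961Glu (34.63 y). The study's full 31-variant table
#' is not reproduced here.
#'
#' @return data.frame with `variant`, `severity_years`, `is_null`.
#' @export
published_severities <- function() {
  path <- system.file("extdata", "abca4_severity_published.csv",
                      package = "ezprog", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Patient-wise leave-one-out cross-validation of the additive model
#'
#' Restricts the cohort to patients whose two variants (after null
#' pooling) each occur in at least one other patient, then iteratively
#' refits the additive model on n - 1 patients and predicts the held-out
#' patient's eye ages as the sum of the two refitted severities. Folds in
#' which a held-out variant becomes inestimable in the training set are
#' skipped and counted. The cross-validated R^2 is
#' `1 - SSE_pred / sum((y - mean(y))^2)` with the mean taken over the
#' eligible eyes' observed ages.
#'
#' @param genotypes genotype data.frame (`patient_id`, `variant_a`,
#'   `variant_b`).
#' @param ages imputed ages ([impute_cohort_ages()] format).
#' @param null_labels labels pooled as null.
#' @return list: `cv_r2`, `n_eligible`, `n_folds_used`,
#'   `n_folds_skipped`, `predictions` (data.frame `eye_id`, `observed`,
#'   `predicted`).
#' @export
loocv_additive <- function(genotypes, ages, null_labels = "null") {
  pool_null <- function(v) ifelse(v %in% null_labels, "null", v)
  g <- genotypes
  g$va <- pool_null(g$variant_a); g$vb <- pool_null(g$variant_b)
  # variant -> patients carrying it
  carriers <- function(v) unique(g$patient_id[g$va == v | g$vb == v])
  eligible <- vapply(seq_len(nrow(g)), function(i) {
    length(setdiff(carriers(g$va[i]), g$patient_id[i])) >= 1 &&
      length(setdiff(carriers(g$vb[i]), g$patient_id[i])) >= 1
  }, logical(1))
  gs <- g[eligible, , drop = FALSE]
  if (nrow(gs) < 3) stop("fewer than 3 LOOCV-eligible patients", call. = FALSE)

  obs <- ages[!is.na(ages$age_criterion) &
                ages$patient_id %in% gs$patient_id, , drop = FALSE]
  preds <- list(); skipped <- 0L
  for (p in gs$patient_id) {
    train_g <- genotypes[genotypes$patient_id %in% setdiff(gs$patient_id, p), ,
                         drop = FALSE]
    des <- build_allele_design(train_g, null_labels = null_labels)
    fit <- tryCatch(fit_additive_model(des, ages), error = function(e) NULL)
    held <- gs[gs$patient_id == p, ]
    want <- pool_null(c(held$variant_a, held$variant_b))
    if (is.null(fit) || !all(want %in% fit$severities$variant)) {
      skipped <- skipped + 1L
      next
    }
    yhat <- predict_age(c(held$variant_a, held$variant_b), fit,
                        null_labels = null_labels)
    o <- obs[obs$patient_id == p, , drop = FALSE]
    if (!nrow(o)) next
    preds[[p]] <- data.frame(eye_id = o$eye_id, observed = o$age_criterion,
                             predicted = yhat, stringsAsFactors = FALSE)
  }
  pr <- do.call(rbind, preds)
  rownames(pr) <- NULL
  sse <- sum((pr$observed - pr$predicted)^2)
  sst <- sum((pr$observed - mean(obs$age_criterion))^2)
  list(cv_r2 = 1 - sse / sst, n_eligible = nrow(gs),
       n_folds_used = nrow(gs) - skipped, n_folds_skipped = skipped,
       predictions = pr)
}

#' Compare severities with an external classification
#'
#' Interval-scaled external severities are compared on the delay-of-
#' disease-initiation scale (severity minus the null severity, which is
#' invariant to a constant shift of either scale): the model's delays are
#' regressed on the external delays over the shared variants and the R^2
#' returned. An ordinal external scale (factor/character) instead yields
#' per-category medians of the model's delays.
#'
#' @param table an `ez_severity_table` or severity data.frame.
#' @param external data.frame with `variant` and either numeric
#'   `severity_years` (interval scale) or `category` (ordinal scale).
#' @return for interval scales: list `r2`, `n_shared`, `merged`; for
#'   ordinal: list `medians`, `n_shared`, `merged`.
#' @export
compare_external <- function(table, external) {
  sev <- if (inherits(table, "ez_severity_table")) table$severities else table
  if (!"null" %in% sev$variant) stop("model table lacks a null severity", call. = FALSE)
  s_null <- sev$severity_years[sev$variant == "null"]
  own <- data.frame(variant = sev$variant,
                    delay = sev$severity_years - s_null,
                    stringsAsFactors = FALSE)
  merged <- merge(own, external, by = "variant")
  if (nrow(merged) < 3) stop("fewer than 3 shared variants", call. = FALSE)
  if ("severity_years" %in% names(external)) {
    ext_null <- if ("null" %in% merged$variant) {
      merged$severity_years[merged$variant == "null"]
    } else 0
    merged$ext_delay <- merged$severity_years - ext_null
    fit <- lm(delay ~ ext_delay, data = merged)
    list(r2 = suppressWarnings(summary(fit))$r.squared,
         n_shared = nrow(merged), merged = merged)
  } else if ("category" %in% names(external)) {
    med <- tapply(merged$delay, merged$category, stats::median)
    list(medians = med, n_shared = nrow(merged), merged = merged)
  } else {
    stop("external table needs 'severity_years' or 'category'", call. = FALSE)
  }
}
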