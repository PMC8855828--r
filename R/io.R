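#' Write a simulated cohort to a directory tree
#'
#' Layout: one directory per eye (`P001_right/`), one per visit
#' (`visit_01/`) containing a TSV matrix per lamina plus `meta.json`
#' (identifiers, age, fovea/disc pixel coordinates, pixel pitch); at the
#' top level `genotypes.csv`, `truth.csv` and `config.json` (seed
#' included).
#'
#' @param visits list of [en_face_maps()].
#' @param dir output directory (created).
#' @param truth optional [simulate_patient_cohort()] table.
#' @param config optional [sim_config()].
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(visits, dir, truth = NULL, config = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  counters <- new.env()
  for (m in visits) {
    eye_key <- paste0(m$meta$patient_id, "_", m$meta$eye)
    k <- (get0(eye_key, envir = counters, ifnotfound = 0L)) + 1L
    assign(eye_key, k, envir = counters)
    vdir <- file.path(dir, eye_key, sprintf("visit_%02d", k))
    dir.create(vdir, recursive = TRUE, showWarnings = FALSE)
    for (l in names(m$thickness)) {
      utils::write.table(m$thickness[[l]], file.path(vdir, paste0(l, ".tsv")),
                         sep = "\t", row.names = FALSE, col.names = FALSE)
    }
    utils::write.table(m$valid * 1L, file.path(vdir, "valid.tsv"),
                       sep = "\t", row.names = FALSE, col.names = FALSE)
    g <- m$geometry
    meta <- list(
      patient_id = m$meta$patient_id, eye = m$meta$eye, age = m$meta$age,
      fovea_px = m$fovea_px, disc_px = m$disc_px,
      n_bscans = g$n_bscans, n_ascans = g$n_ascans,
      px_deg_x = g$px_deg_x, px_deg_y = g$px_deg_y,
      ascan_pitch_um = g$ascan_pitch_um,
      bscan_spacing_um = g$bscan_spacing_um,
      mm_per_degree = g$mm_per_degree
    )
    jsonlite::write_json(meta, file.path(vdir, "meta.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  if (!is.null(truth)) {
    utils::write.csv(cohort_genotypes(truth), file.path(dir, "genotypes.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(truth), file.path(dir, "truth.csv"),
                     row.names = FALSE)
  }
  if (!is.null(config)) {
    cfg <- unclass(config)
    jsonlite::write_json(cfg, file.path(dir, "config.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "columns")
  }
  invisible(dir)
}

#' Read a cohort directory
#'
#' @param dir directory written by [write_cohort()] (or user exports in
#'   the same layout).
#' @return list with `visits` (list of [en_face_maps()]), `genotypes`,
#'   `truth` (NULL when absent).
#' @export
read_cohort <- function(dir) {
  if (!dir.exists(dir)) stop("cohort directory not found: ", dir, call. = FALSE)
  visits <- list()
  eye_dirs <- list.dirs(dir, recursive = FALSE)
  for (ed in eye_dirs) {
    for (vd in list.dirs(ed, recursive = FALSE)) {
      meta <- jsonlite::read_json(file.path(vd, "meta.json"),
                                  simplifyVector = TRUE)
      g <- geometry(meta$n_bscans, meta$n_ascans, meta$px_deg_x,
                    meta$px_deg_y, meta$ascan_pitch_um,
                    meta$bscan_spacing_um, meta$mm_per_degree)
      lam_files <- list.files(vd, pattern = "\\.tsv$")
      lam_files <- setdiff(lam_files, "valid.tsv")
      th <- lapply(lam_files, function(f) {
        as.matrix(utils::read.table(file.path(vd, f), sep = "\t"))
      })
      names(th) <- sub("\\.tsv$", "", lam_files)
      th <- lapply(th, function(m) { dimnames(m) <- NULL; m })
      vfile <- file.path(vd, "valid.tsv")
      valid <- if (file.exists(vfile)) {
        m <- as.matrix(utils::read.table(vfile, sep = "\t")) == 1
        dimnames(m) <- NULL
        m
      } else NULL
      visits[[length(visits) + 1L]] <- en_face_maps(
        th, g, unlist(meta$fovea_px), disc_px = unlist(meta$disc_px),
        valid = valid,
        meta = list(patient_id = meta$patient_id, eye = meta$eye,
                    age = meta$age)
      )
    }
  }
  read_opt <- function(f) {
    p <- file.path(dir, f)
    if (file.exists(p)) utils::read.csv(p, stringsAsFactors = FALSE) else NULL
  }
  list(visits = visits, genotypes = read_opt("genotypes.csv"),
       truth = read_opt("truth.csv"))
}

#' Validate a cohort directory
#'
#' Checks grid consistency across visits, metadata completeness,
#' non-negative and within-eye increasing visit ages, lamina matrix
#' shapes, and genotype-table integrity. Issues are collected, not
#' thrown; `ok` is FALSE when any error-level issue is present.
#'
#' @param dir cohort directory.
#' @return list: `ok`, `issues` (data.frame `level`, `where`, `message`),
#'   `n_visits`.
#' @export
validate_cohort <- function(dir) {
  issues <- list()
  note <- function(level, where, msg) {
    issues[[length(issues) + 1L]] <<- data.frame(
      level = level, where = where, message = msg, stringsAsFactors = FALSE)
  }
  if (!dir.exists(dir)) {
    return(list(ok = FALSE, n_visits = 0L,
                issues = data.frame(level = "error", where = dir,
                                    message = "directory not found")))
  }
  ref_dims <- NULL
  ages <- list()
  n_visits <- 0L
  for (ed in list.dirs(dir, recursive = FALSE)) {
    for (vd in list.dirs(ed, recursive = FALSE)) {
      n_visits <- n_visits + 1L
      where <- sub(paste0("^", dir, "/?"), "", vd)
      mfile <- file.path(vd, "meta.json")
      if (!file.exists(mfile)) { note("error", where, "meta.json missing"); next }
      meta <- tryCatch(jsonlite::read_json(mfile, simplifyVector = TRUE),
                       error = function(e) NULL)
      if (is.null(meta)) { note("error", where, "meta.json unreadable"); next }
      for (k in c("patient_id", "eye", "age", "fovea_px", "n_bscans",
                  "n_ascans", "bscan_spacing_um")) {
        if (is.null(meta[[k]])) note("error", where, paste0("meta field missing: ", k))
      }
      if (!is.null(meta$age) && meta$age < 0) {
        note("error", where, sprintf("negative visit age (%s %s): %.2f",
                                     meta$patient_id, meta$eye, meta$age))
      }
      dims <- c(meta$n_bscans, meta$n_ascans)
      if (is.null(ref_dims)) ref_dims <- dims
      else if (!all(dims == ref_dims)) note("error", where, "grid differs across visits")
      for (f in setdiff(list.files(vd, pattern = "\\.tsv$"), "valid.tsv")) {
        m <- tryCatch(as.matrix(utils::read.table(file.path(vd, f), sep = "\t")),
                      error = function(e) NULL)
        if (is.null(m) || !all(dim(m) == dims)) {
          note("error", where, paste0("lamina matrix has wrong shape: ", f))
        }
      }
      key <- paste(meta$patient_id, meta$eye, sep = ":")
      ages[[key]] <- c(ages[[key]], meta$age %||% NA_real_)
    }
  }
  for (key in names(ages)) {
    a <- ages[[key]]
    if (anyNA(a)) next
    if (is.unsorted(a, strictly = FALSE)) {
      note("warning", key, "visit ages not sorted in directory order")
    }
    if (anyDuplicated(a)) note("warning", key, "duplicate visit ages")
  }
  gfile <- file.path(dir, "genotypes.csv")
  if (file.exists(gfile)) {
    gt <- utils::read.csv(gfile, stringsAsFactors = FALSE)
    if (!all(c("patient_id", "variant_a", "variant_b") %in% names(gt))) {
      note("error", "genotypes.csv", "missing required columns")
    } else if (anyDuplicated(gt$patient_id)) {
      note("error", "genotypes.csv", "duplicate patient rows")
    }
  }
  issues <- if (length(issues)) do.call(rbind, issues) else
    data.frame(level = character(), where = character(), message = character())
  list(ok = !any(issues$level == "error"), issues = issues,
       n_visits = n_visits)
}
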