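# table writers: TSVs carry 6 significant digits; full-precision copies go
# to JSON sidecars where the pipeline needs them

write_tsv6 <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- signif(out[[j]], 6)
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write a simulated cohort to disk
#'
#' Writes per-scan TAC tables (TSV: frame_start, frame_end, cerebellum and
#' one column per region, kBq/ml) under \code{dir/tacs/}, a scan manifest
#' (JSON), a covariate table (TSV, long format) and the ground-truth table
#' (TSV) for recovery testing. Activity values are rounded to 6
#' significant digits on write.
#'
#' @param cohort A \code{\link{simulate_cohort}} result.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "pet_cohort"))
  dir.create(file.path(dir, "tacs"), recursive = TRUE, showWarnings = FALSE)
  for (id in names(cohort$tacs)) {
    write_tsv6(cohort$tacs[[id]], file.path(dir, "tacs", paste0(id, ".tsv")))
  }
  write_tsv6(cohort$truth, file.path(dir, "truth.tsv"))
  write_tsv6(covariate_table(cohort), file.path(dir, "covariates.tsv"))
  manifest <- list(
    n_subjects = cohort$config$n_subjects,
    seed = cohort$config$seed,
    conditions = names(cohort$config$conditions),
    regions = cohort$config$regions$region,
    noise_scale = cohort$config$noise_scale,
    scans = cohort$scans)
  jsonlite::write_json(manifest, file.path(dir, "cohort_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Long covariate table of a cohort
#'
#' @param cohort A \code{pet_cohort}.
#' @return Data frame: subject, session, condition, measure, time_min,
#'   value.
#' @export
covariate_table <- function(cohort) {
  rows <- list()
  for (key in names(cohort$covariates)) {
    cv <- cohort$covariates[[key]]
    ses <- as.integer(sub(".*_ses", "", key))
    add <- function(measure, time, value) {
      data.frame(subject = cv$subject, session = ses,
                 condition = cv$condition, measure = measure,
                 time_min = time, value = value, stringsAsFactors = FALSE)
    }
    if (!is.null(cv$mp_plasma)) {
      rows[[length(rows) + 1L]] <- add("mp_ng_ml", cv$mp_plasma$time_min,
                                       cv$mp_plasma$conc_ng_ml)
    }
    for (k in c("tnfa", "il6", "il8")) {
      rows[[length(rows) + 1L]] <- add(paste0(k, "_pg_ml"),
                                       cv$cytokines$time_min,
                                       cv$cytokines[[k]])
    }
    rows[[length(rows) + 1L]] <- add("poms_fatigue",
                                     cv$poms_fatigue$time_min,
                                     cv$poms_fatigue$score)
  }
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Read the TAC tables of a written cohort
#'
#' @param dir Directory previously produced by \code{\link{write_cohort}}
#'   (or \code{\link{run_pipeline}}).
#' @return List with \code{scans} (data frame) and \code{tacs} (named list
#'   of TAC tables).
#' @export
read_cohort_tacs <- function(dir) {
  mpath <- file.path(dir, "cohort_manifest.json")
  if (!file.exists(mpath)) stop("no cohort_manifest.json in ", dir)
  manifest <- jsonlite::read_json(mpath, simplifyVector = TRUE)
  scans <- as.data.frame(manifest$scans, stringsAsFactors = FALSE)
  tacs <- lapply(scans$scan_id, function(id) {
    read_tsv(file.path(dir, "tacs", paste0(id, ".tsv")))
  })
  names(tacs) <- scans$scan_id
  list(scans = scans, tacs = tacs)
}

#' Write a 3D/4D array as NIfTI with a JSON sidecar
#'
#' @param arr Numeric array.
#' @param path Output path ending in \code{.nii} or \code{.nii.gz}.
#' @param voxel_size_mm Voxel edge lengths, mm.
#' @param sidecar Optional list written as \code{<path>.json} (frame
#'   schedule, fit settings, software version...).
#' @return The path, invisibly.
#' @export
write_nifti_map <- function(arr, path, voxel_size_mm = c(2.1, 2.1, 2.4),
                            sidecar = NULL) {
  img <- RNifti::asNifti(arr, pixdim = voxel_size_mm)
  RNifti::writeNifti(img, path)
  if (!is.null(sidecar)) {
    jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  invisible(path)
}
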