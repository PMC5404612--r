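#' Fit SRTM to every scan of a cohort
#'
#' For each scan's TAC table, reconstructs a fine-grid reference curve from
#' the measured cerebellum TAC (\code{\link{tac_to_fine}}) and fits the
#' SRTM to every region column, returning a long BP table. Deterministic:
#' no RNG is touched.
#'
#' @param scans Data frame with columns \code{scan_id}, \code{subject},
#'   \code{session}, \code{scan_type}, \code{condition} (as in
#'   \code{pet_cohort$scans}).
#' @param tacs Named list of TAC tables (frame_start, frame_end,
#'   cerebellum, regions...), keyed by \code{scan_id}.
#' @param k2a_grid Candidate k2a values.
#' @param refine Refinement mode passed to \code{\link{fit_srtm}}.
#' @return Long BP data frame: subject, session, scan_type, condition,
#'   region, bp, r1, k2, k2a, rss, boundary_flag.
#' @export
fit_cohort_bp <- function(scans, tacs, k2a_grid = default_k2a_grid(),
                          refine = "optimize") {
  rows <- list()
  for (i in seq_len(nrow(scans))) {
    id <- scans$scan_id[i]
    tab <- tacs[[id]]
    if (is.null(tab)) stop("missing TAC table for scan ", id)
    schedule <- frame_schedule_from_times(tab$frame_start, tab$frame_end)
    ref_fine <- tac_to_fine(tab$cerebellum, schedule)
    basis <- srtm_basis(ref_fine, schedule, k2a_grid)
    regions <- setdiff(names(tab), c("frame_start", "frame_end",
                                     "cerebellum"))
    for (reg in regions) {
      fit <- fit_srtm(tab[[reg]], basis = basis, refine = refine)
      rows[[length(rows) + 1L]] <- data.frame(
        subject = scans$subject[i], session = scans$session[i],
        scan_type = scans$scan_type[i], condition = scans$condition[i],
        region = reg, bp = fit$bp_nd, r1 = fit$R1, k2 = fit$k2,
        k2a = fit$k2a, rss = fit$rss,
        boundary_flag = fit$boundary_flag, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Run the full occupancy pipeline
#'
#' Orchestrates simulate (or load) -> SRTM fit -> delta-BP -> group
#' statistics -> report as one reproducible run. In \code{"simulate"} mode
#' a synthetic cohort is generated from \code{cohort}; in \code{"analyze"}
#' mode TAC tables are read from \code{input_dir} and the RNG is never
#' touched. Outputs are written to \code{outdir}: per-scan TAC tables
#' (simulate mode), \code{bp_table.tsv}, \code{dbp_table.tsv},
#' \code{table1.tsv}, \code{test_retest.json}, full-precision
#' \code{bp_table.json}, a run log, and \code{run_manifest.json} recording
#' the seed, configuration hash and per-file checksums. With
#' \code{voxel = TRUE} a digital phantom is rendered per scan of the first
#' subject... (see Details).
#'
#' @details The voxel path renders each scan of the cohort onto the
#' phantom with per-voxel noise, fits voxelwise BP maps, forms per-subject
#' delta-BP maps per condition, contrasts conditions with a paired
#' voxelwise t-test, and writes the (1-p) map, display mask and direction
#' image as NIfTI with a JSON sidecar, plus per-region
#' percent-significant-voxel summaries. It is off by default (it is the
#' expensive stage).
#'
#' @param config A list (or path to a YAML file) with entries:
#'   \code{mode} ("simulate" or "analyze"); \code{cohort} (arguments for
#'   \code{\link{cohort_config}}) or \code{input_dir}; optional
#'   \code{seed} (overrides the cohort seed), \code{voxel} (logical),
#'   \code{voxel_noise_scale}, \code{k2a_grid} (list: n, min, max),
#'   \code{refine}.
#' @param outdir Output directory.
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with \code{bp_table}, \code{dbp_table},
#'   \code{table1}, \code{test_retest}, \code{cohort} (simulate mode),
#'   \code{voxel} (when enabled) and \code{outdir}.
#' @export
run_pipeline <- function(config, outdir, quiet = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$mode) ||
      !config$mode %in% c("simulate", "analyze")) {
    stop("config$mode must be 'simulate' or 'analyze'")
  }
  if (config$mode == "simulate" && is.null(config$cohort)) {
    stop("simulate mode needs config$cohort")
  }
  if (config$mode == "analyze" && is.null(config$input_dir)) {
    stop("analyze mode needs config$input_dir")
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(outdir, "run_log.txt")
  log_lines <- character(0)
  say <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, line)
    if (!quiet) message(line)
  }
  k2a_grid <- if (!is.null(config$k2a_grid)) {
    default_k2a_grid(config$k2a_grid$n %||% 128,
                     c(config$k2a_grid$min %||% 0.006,
                       config$k2a_grid$max %||% 0.6))
  } else default_k2a_grid()
  refine <- config$refine %||% "optimize"

  cohort <- NULL
  if (config$mode == "simulate") {
    cc_args <- config$cohort
    if (!is.null(cc_args$regions) && !is.data.frame(cc_args$regions)) {
      # YAML configs carry the region table as a list of records
      cc_args$regions <- do.call(rbind, lapply(cc_args$regions, function(r)
        data.frame(region = r$region, bp0 = r$bp0,
                   volume_ml = r$volume_ml %||% NA_real_,
                   stringsAsFactors = FALSE)))
    }
    if (!is.null(config$seed)) cc_args$seed <- config$seed
    cc <- do.call(cohort_config, cc_args)
    say("stage simulate: n=%d seed=%d conditions=%s", cc$n_subjects,
        cc$seed, paste(names(cc$conditions), collapse = ","))
    cohort <- simulate_cohort(cc)
    # round to the written 6-significant-digit representation before
    # fitting, so analyze mode on the exported tables reproduces this run
    # exactly
    for (id in names(cohort$tacs)) {
      for (j in seq_along(cohort$tacs[[id]])) {
        cohort$tacs[[id]][[j]] <- signif(cohort$tacs[[id]][[j]], 6)
      }
    }
    write_cohort(cohort, outdir)
    scans <- cohort$scans; tacs <- cohort$tacs
  } else {
    say("stage load: %s", config$input_dir)
    inp <- read_cohort_tacs(config$input_dir)
    scans <- inp$scans; tacs <- inp$tacs
  }

  say("stage fit: %d scans, %d-point k2a grid, refine=%s",
      nrow(scans), length(k2a_grid), refine)
  bp_table <- fit_cohort_bp(scans, tacs, k2a_grid = k2a_grid,
                            refine = refine)
  write_tsv6(bp_table, file.path(outdir, "bp_table.tsv"))
  jsonlite::write_json(bp_table, file.path(outdir, "bp_table.json"),
                       digits = NA, dataframe = "columns")

  say("stage delta_bp")
  dbp <- delta_bp_table(bp_table)
  write_tsv6(dbp, file.path(outdir, "dbp_table.tsv"))

  say("stage group_stats")
  volumes <- NULL
  if (!is.null(cohort)) {
    volumes <- stats::setNames(cohort$config$regions$volume_ml,
                               cohort$config$regions$region)
  }
  tab1 <- build_table1(dbp, volumes = volumes)
  write_tsv6(tab1, file.path(outdir, "table1.tsv"))

  trr <- NULL
  if (length(unique(bp_table$session[bp_table$scan_type == "baseline"])) >= 2) {
    trr <- test_retest_report(bp_table)
    jsonlite::write_json(trr, file.path(outdir, "test_retest.json"),
                         digits = NA, dataframe = "columns", pretty = TRUE)
  }

  vox <- NULL
  if (isTRUE(config$voxel)) {
    say("stage voxel: rendering phantom cohort")
    vox <- .voxel_stage(scans, tacs, config, outdir, k2a_grid)
  }

  files <- list.files(outdir, recursive = TRUE, full.names = TRUE)
  files <- setdiff(files, log_path)
  sums <- tools::md5sum(files)
  cfg_json <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                               force = TRUE)
  cfg_tmp <- tempfile(); writeLines(cfg_json, cfg_tmp)
  manifest <- list(
    package = "occupet",
    version = as.character(utils::packageVersion("occupet")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    mode = config$mode,
    seed = if (!is.null(config$seed)) config$seed
           else if (!is.null(cohort)) cohort$config$seed else NA,
    config_md5 = unname(tools::md5sum(cfg_tmp)),
    config = config,
    checksums = as.list(stats::setNames(unname(sums),
                                        substring(files,
                                                  nchar(outdir) + 2L))))
  unlink(cfg_tmp)
  jsonlite::write_json(manifest, file.path(outdir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("stage report: wrote %d files", length(files) + 2L)
  writeLines(log_lines, log_path)
  invisible(list(bp_table = bp_table, dbp_table = dbp, table1 = tab1,
                 test_retest = trr, cohort = cohort, voxel = vox,
                 outdir = outdir))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Parameter-recovery run: simulate a cohort and recover condition means
#'
#' The canonical validation loop of the simulator/fitter pair: draw
#' subject-level true delta-BP values from configured condition cells
#' (recentred so the sample mean of the truths equals the population mean),
#' generate baseline and post-challenge TACs with noise, fit the SRTM to
#' every scan, and return the estimated mean delta-BP per condition
#' alongside the configured truth.
#'
#' @param conditions Condition cells as in \code{\link{cohort_config}}.
#' @param region Region name (single-region cohort).
#' @param bp0 Baseline binding potential of the region.
#' @param n_subjects Cohort size.
#' @param seed Root seed.
#' @param noise_scale TAC noise level (default 0.1).
#' @param recenter Recentre the sampled truths (default TRUE).
#' @return Data frame with columns \code{condition}, \code{true_mean},
#'   \code{estimated_mean}, \code{n}.
#' @export
recover_dbp_means <- function(conditions, region = "striatum", bp0 = 2.5,
                              n_subjects = 8, seed = 0,
                              noise_scale = 0.1, recenter = TRUE) {
  cfg <- cohort_config(
    n_subjects = n_subjects, seed = seed,
    regions = data.frame(region = region, bp0 = bp0, volume_ml = NA_real_,
                         stringsAsFactors = FALSE),
    conditions = conditions, recenter = recenter,
    noise_scale = noise_scale)
  coh <- simulate_cohort(cfg)
  bp <- fit_cohort_bp(coh$scans, coh$tacs)
  dbp <- delta_bp_table(bp)
  est <- stats::aggregate(delta_bp ~ condition, dbp, mean)
  data.frame(
    condition = est$condition,
    true_mean = vapply(est$condition,
                       function(cn) conditions[[cn]]$mean, numeric(1)),
    estimated_mean = est$delta_bp,
    n = as.integer(n_subjects),
    row.names = NULL, stringsAsFactors = FALSE)
}

# voxel stage: phantom-rendered per-scan images, voxelwise BP and delta-BP
# maps, paired contrast between the first two conditions
.voxel_stage <- function(scans, tacs, config, outdir, k2a_grid) {
  phantom <- make_phantom()
  vns <- config$voxel_noise_scale %||% 1.0
  vseed <- (config$seed %||% 1L) + 7000L
  subjects <- unique(scans$subject)
  conds <- unique(scans$condition)
  # map the cohort's region columns onto phantom regions: a single-region
  # cohort fills all striatal labels with that TAC
  fill_tacs <- function(tab) {
    regions <- setdiff(names(tab), c("frame_start", "frame_end"))
    out <- list(cerebellum = tab$cerebellum)
    striatal <- setdiff(names(phantom$label_map),
                        c("background", "cerebellum"))
    for (lab in striatal) {
      base <- sub("_[lr]$", "", lab)
      src <- if (lab %in% regions) lab
             else if (base %in% regions) base
             else if ("striatum" %in% regions) "striatum"
             else regions[regions != "cerebellum"][1]
      out[[lab]] <- tab[[src]]
    }
    out
  }
  dbp_maps <- list()
  i <- 0L
  for (subj in subjects) {
    for (cn in conds) {
      sel <- scans$subject == subj & scans$condition == cn
      if (sum(sel) != 2L) next
      ids <- scans$scan_id[sel]
      types <- scans$scan_type[sel]
      maps <- list()
      for (k in seq_along(ids)) {
        i <- i + 1L
        tab <- tacs[[ids[k]]]
        schedule <- frame_schedule_from_times(tab$frame_start,
                                              tab$frame_end)
        img <- render_dynamic_image(phantom, fill_tacs(tab), schedule,
                                    voxel_noise_scale = vns,
                                    seed = vseed + i)
        ref_fine <- tac_to_fine(extract_roi_tac(img, phantom, "cerebellum"),
                                schedule)
        maps[[types[k]]] <- fit_voxelwise(img, ref_fine, phantom,
                                          labels = "striatum",
                                          k2a_grid = k2a_grid)
      }
      d <- 100 * (1 - maps$post$bp / maps$baseline$bp)
      d[!(maps$post$valid & maps$baseline$valid)] <- NA_real_
      dbp_maps[[cn]][[subj]] <- d
    }
  }
  out <- list(phantom = phantom, dbp_maps = dbp_maps)
  if (length(conds) >= 2 &&
      length(dbp_maps[[conds[1]]]) == length(dbp_maps[[conds[2]]]) &&
      length(dbp_maps[[conds[1]]]) >= 2) {
    sig <- voxelwise_contrast(dbp_maps[[conds[1]]], dbp_maps[[conds[2]]])
    out$significance <- sig
    out$percent_significant <- vapply(
      c("putamen", "caudate", "ventral_striatum"),
      function(r) percent_significant_voxels(sig, phantom, r), numeric(1))
    sidecar <- list(frame_schedule = "see cohort tacs",
                    display_threshold = sig$display_threshold,
                    contrast = conds[1:2],
                    k2a_grid = range(k2a_grid))
    write_nifti_map(sig$one_minus_p,
                    file.path(outdir, "significance_1mp.nii.gz"),
                    phantom$voxel_size_mm, sidecar = sidecar)
    write_nifti_map(array(as.integer(sig$displayed), dim(sig$displayed)),
                    file.path(outdir, "significance_display.nii.gz"),
                    phantom$voxel_size_mm)
    write_nifti_map(sig$direction,
                    file.path(outdir, "significance_direction.nii.gz"),
                    phantom$voxel_size_mm)
  }
  out
}
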