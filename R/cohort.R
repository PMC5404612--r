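#' Cohort simulation configuration
#'
#' Assembles and validates the configuration of a synthetic crossover
#' cohort: subjects scanned at baseline and after a dopamine-releasing
#' challenge under one or more pre-treatment conditions, on a shared frame
#' schedule, with condition-specific true percent reductions in binding
#' potential (delta-BP).
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param seed Root RNG seed; all per-subject and per-scan randomness is
#'   derived from it deterministically.
#' @param frame_spec Binning specification for
#'   \code{\link{make_frame_schedule}}; default the 33-frame, 120-min
#'   protocol.
#' @param regions Data frame with columns \code{region}, \code{bp0}
#'   (baseline binding potential) and \code{volume_ml}; default
#'   \code{\link{default_regions}()}.
#' @param conditions Named list, one entry per pre-treatment condition
#'   (names from \code{"MP+LPS"}, \code{"MP+PBO"}, \code{"LPS"}), each a
#'   list with \code{mean} and \code{sd} of the true subject-level delta-BP
#'   in percent.
#' @param recenter Logical; when TRUE the sampled subject-level true
#'   delta-BP values are shifted so their sample mean equals the configured
#'   population mean exactly (used for parameter-recovery runs).
#' @param noise_scale TAC noise magnitude (see
#'   \code{\link{simulate_target_tac}}); default 0.1.
#' @param ref_params List of reference-curve parameters passed to
#'   \code{\link{simulate_reference_tac}}.
#' @param fine_dt Fine-grid step, minutes.
#' @param r1_mean,r1_sd,k2_mean,k2_sd Between-subject distribution of the
#'   delivery ratio R1 and efflux rate k2 (1/min).
#' @param bp0_cv Between-subject coefficient of variation of baseline BP
#'   (log-normal); default 0.1.
#' @return An object of class \code{cohort_config} (a validated list).
#' @export
cohort_config <- function(n_subjects = 8, seed = 1,
                          frame_spec = default_frame_spec(),
                          regions = default_regions(),
                          conditions = list(
                            "MP+LPS" = list(mean = 17.1, sd = 3.6),
                            "MP+PBO" = list(mean = 8.8, sd = 3.6)),
                          recenter = FALSE,
                          noise_scale = 0.1,
                          ref_params = list(peak_time = 4, peak_amp = 30,
                                            washout_halflife = 25),
                          fine_dt = 0.05,
                          r1_mean = 1.0, r1_sd = 0.05,
                          k2_mean = 0.3, k2_sd = 0.03,
                          bp0_cv = 0.1) {
  if (n_subjects < 1) stop("n_subjects must be >= 1")
  if (!all(c("region", "bp0", "volume_ml") %in% names(regions))) {
    stop("'regions' needs columns region, bp0, volume_ml")
  }
  if (any(regions$bp0 <= 0)) stop("baseline BP must be positive")
  known <- c("MP+LPS", "MP+PBO", "LPS")
  if (is.null(names(conditions)) || !all(names(conditions) %in% known)) {
    stop("condition names must be among: ", paste(known, collapse = ", "))
  }
  for (cnd in conditions) {
    if (!is.finite(cnd$mean) || !is.finite(cnd$sd) || cnd$sd < 0) {
      stop("each condition needs a finite mean and non-negative sd")
    }
  }
  if (noise_scale < 0) stop("noise_scale must be non-negative")
  structure(
    list(n_subjects = as.integer(n_subjects), seed = as.integer(seed),
         frame_spec = frame_spec, regions = regions, conditions = conditions,
         recenter = isTRUE(recenter), noise_scale = noise_scale,
         ref_params = ref_params, fine_dt = fine_dt,
         r1_mean = r1_mean, r1_sd = r1_sd, k2_mean = k2_mean, k2_sd = k2_sd,
         bp0_cv = bp0_cv),
    class = "cohort_config"
  )
}

#' Default striatal region table
#'
#' Region names, baseline binding potentials typical for raclopride, and
#' ROI volumes matching the study template (striatum 42.6 ml, putamen
#' 21.9 ml, caudate 20.7 ml, ventral striatum 2.9 ml).
#'
#' @return Data frame with columns \code{region}, \code{bp0},
#'   \code{volume_ml}.
#' @export
default_regions <- function() {
  data.frame(
    region = c("striatum", "caudate", "putamen", "ventral_striatum"),
    bp0 = c(2.5, 2.4, 2.8, 2.2),
    volume_ml = c(42.6, 20.7, 21.9, 2.9),
    stringsAsFactors = FALSE
  )
}

# per-frame noise standard deviation: count-statistics surrogate for a
# short-lived isotope — variance ~ C * exp(lambda * t_mid) / frame duration
tac_noise_sd <- function(cbar, schedule, noise_scale,
                         decay_lambda = log(2) / 20.4) {
  noise_scale * sqrt(pmax(cbar, 0) * exp(decay_lambda * schedule$mid) /
                       schedule$dur)
}

#' Simulate a noisy target-region TAC from SRTM ground truth
#'
#' Frame-averages the SRTM forward model driven by a fine-grid reference
#' curve, then adds zero-mean Gaussian noise whose per-frame variance is
#' proportional to \code{noise_scale^2 * C * exp(lambda * t_mid) / dt}
#' (lambda = ln2/20.4 per min, carbon-11): later and shorter frames are
#' noisier, mimicking decaying count statistics.
#'
#' @param truth List or data.frame row with \code{R1}, \code{k2},
#'   \code{bp_nd} (all positive; \code{bp_nd >= 0}).
#' @param ref_fine A \code{fine_tac} covering the schedule span.
#' @param schedule A \code{frame_schedule}.
#' @param noise_scale Non-negative noise magnitude; 0 gives the exact
#'   frame-averaged forward model.
#' @param seed Optional integer seed for the noise draw.
#' @param label Label for the returned \code{tac}.
#' @return A \code{\link{tac}}.
#' @export
simulate_target_tac <- function(truth, ref_fine, schedule, noise_scale = 0,
                                seed = NULL, label = NA_character_) {
  stopifnot(truth$R1 > 0, truth$k2 > 0, truth$bp_nd >= 0, noise_scale >= 0)
  if (max(schedule$end) > max(ref_fine$t) + 1e-9) {
    stop("schedule extends past the support of the reference curve")
  }
  y <- srtm_forward(ref_fine, schedule, truth$R1, truth$k2, truth$bp_nd)
  if (noise_scale > 0) {
    if (!is.null(seed)) set.seed(seed)
    y <- y + stats::rnorm(schedule$n,
                          sd = tac_noise_sd(y, schedule, noise_scale))
  }
  tac(schedule, y, label = label)
}

# draw integer sub-seeds deterministically from a root seed
.derive_seeds <- function(root, n) {
  set.seed(root)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Simulate a full crossover cohort
#'
#' Generates, for each subject and each configured pre-treatment condition,
#' a session of two scans — a baseline scan and a post-challenge scan in
#' which every region's generating BP is reduced by the subject's true
#' delta-BP percent for that condition — plus blood/behaviour covariates
#' and a ground-truth record. Session order is a balanced crossover:
#' exactly \code{floor(n/2)} subjects receive the first-listed condition in
#' session 1. All randomness derives from \code{config$seed}.
#'
#' @param config A \code{\link{cohort_config}}.
#' @return An object of class \code{pet_cohort}: list with \code{config},
#'   \code{schedule}, \code{ref_fine} (the generating reference curve),
#'   \code{truth} (data frame: subject, condition, session, true_dbp, R1,
#'   k2, and per-region baseline bp0 columns), \code{scans} (data frame:
#'   scan_id, subject, session, scan_type, condition, order), \code{tacs}
#'   (named list of per-scan TAC tables: frame_start, frame_end, cerebellum
#'   and one column per region, kBq/ml) and \code{covariates}.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  schedule <- make_frame_schedule(config$frame_spec)
  ref <- do.call(simulate_reference_tac,
                 c(config$ref_params,
                   list(t_max = max(schedule$end), fine_dt = config$fine_dt)))
  n <- config$n_subjects
  conds <- names(config$conditions)
  subjects <- sprintf("sub%02d", seq_len(n))

  seeds <- .derive_seeds(config$seed, 4L + n)
  # session order: balanced crossover over the configured conditions
  set.seed(seeds[1])
  first <- sample(seq_len(n), floor(n / 2))
  order_mat <- t(vapply(seq_len(n), function(i) {
    if (length(conds) == 1L) return(conds)
    if (i %in% first) conds else rev(conds)
  }, character(length(conds))))
  if (length(conds) == 1L) order_mat <- matrix(conds, nrow = n)

  # subject-level truths
  set.seed(seeds[2])
  bp0 <- outer(exp(stats::rnorm(n, 0, config$bp0_cv) - config$bp0_cv^2 / 2),
               config$regions$bp0)
  colnames(bp0) <- config$regions$region
  R1 <- pmax(stats::rnorm(n, config$r1_mean, config$r1_sd), 0.3)
  k2 <- pmax(stats::rnorm(n, config$k2_mean, config$k2_sd), 0.05)
  dbp <- vapply(conds, function(cn) {
    cc <- config$conditions[[cn]]
    d <- stats::rnorm(n, cc$mean, cc$sd)
    if (config$recenter) d <- d - mean(d) + cc$mean
    d
  }, numeric(n))
  dbp <- matrix(dbp, nrow = n, dimnames = list(NULL, conds))

  truth <- do.call(rbind, lapply(seq_len(n), function(i) {
    data.frame(subject = subjects[i], condition = conds,
               session = match(conds, order_mat[i, ]),
               true_dbp = dbp[i, conds], R1 = R1[i], k2 = k2[i],
               as.list(stats::setNames(bp0[i, ], colnames(bp0))),
               row.names = NULL, stringsAsFactors = FALSE)
  }))

  scans <- list(); tacs <- list(); covariates <- list()
  scan_seeds <- .derive_seeds(seeds[3], n * length(conds) * 32L)
  cov_seeds <- .derive_seeds(seeds[4], n * length(conds))
  si <- 0L; ci <- 0L
  for (i in seq_len(n)) {
    for (s in seq_along(conds)) {
      cond <- order_mat[i, s]
      for (scan_type in c("baseline", "post")) {
        si <- si + 1L
        scan_id <- sprintf("%s_ses%d_%s", subjects[i], s, scan_type)
        fac <- if (scan_type == "post") 1 - dbp[i, cond] / 100 else 1
        tab <- data.frame(frame_start = schedule$start,
                          frame_end = schedule$end)
        tab$cerebellum <- simulate_target_tac(
          list(R1 = 1, k2 = k2[i], bp_nd = 0), ref, schedule,
          config$noise_scale, seed = scan_seeds[si * 16L - 15L])$activity
        for (r in seq_len(nrow(config$regions))) {
          reg <- config$regions$region[r]
          tab[[reg]] <- simulate_target_tac(
            list(R1 = R1[i], k2 = k2[i], bp_nd = bp0[i, reg] * fac),
            ref, schedule, config$noise_scale,
            seed = scan_seeds[si * 16L - 15L + r])$activity
        }
        scans[[scan_id]] <- data.frame(
          scan_id = scan_id, subject = subjects[i], session = s,
          scan_type = scan_type, condition = cond, stringsAsFactors = FALSE)
        tacs[[scan_id]] <- tab
      }
      ci <- ci + 1L
      covariates[[sprintf("%s_ses%d", subjects[i], s)]] <- simulate_covariates(
        subjects[i], cond, seed = cov_seeds[ci])
    }
  }
  structure(
    list(config = config, schedule = schedule, ref_fine = ref,
         truth = truth, scans = do.call(rbind, c(scans, make.row.names = FALSE)),
         tacs = tacs, covariates = covariates),
    class = "pet_cohort"
  )
}

#' @export
print.pet_cohort <- function(x, ...) {
  cat(sprintf("<pet_cohort: %d subjects, %d scans, conditions: %s>\n",
              x$config$n_subjects, nrow(x$scans),
              paste(names(x$config$conditions), collapse = ", ")))
  invisible(x)
}

#' Simulate blood and behaviour covariates for one session
#'
#' Generates the session covariates of the study template, independent of
#' the subject's true delta-BP (a null-correlation regime): plasma
#' methylphenidate at 30/90/150 min post-drug (absent for the LPS-alone
#' arm), plasma TNF-alpha / IL-6 / IL-8 at 0/60/90/120/180/240 min after
#' pre-treatment (elevated only under LPS, with TNF-alpha peaking before
#' IL-6), and POMS fatigue scores (integers 0-4) at 0/60/210 min.
#'
#' @param subject Subject identifier (recorded, not used numerically).
#' @param condition One of \code{"MP+LPS"}, \code{"MP+PBO"}, \code{"LPS"}.
#' @param seed Integer seed.
#' @return List with \code{mp_plasma} (data frame time_min, conc_ng_ml, or
#'   NULL), \code{cytokines} (data frame time_min, tnfa, il6, il8 in
#'   pg/ml) and \code{poms_fatigue} (data frame time_min, score).
#' @export
simulate_covariates <- function(subject, condition, seed = 1) {
  known <- c("MP+LPS", "MP+PBO", "LPS")
  if (!condition %in% known) stop("unknown condition: ", condition)
  set.seed(seed)
  has_mp <- condition %in% c("MP+LPS", "MP+PBO")
  has_lps <- condition %in% c("MP+LPS", "LPS")

  mp <- NULL
  if (has_mp) {
    mp_mean <- if (condition == "MP+LPS") stats::rnorm(1, 12.7, 7.4)
               else stats::rnorm(1, 11.7, 5.2)
    mp_mean <- max(mp_mean, 0.5)
    mp <- data.frame(time_min = c(30, 90, 150),
                     conc_ng_ml = pmax(mp_mean *
                       exp(stats::rnorm(3, 0, 0.15)), 0))
  }

  ct <- c(0, 60, 90, 120, 180, 240)
  base <- c(tnfa = 1, il6 = 1.5, il8 = 8)
  # gamma-variate bump: TNF-alpha peaks earliest, then IL-6, then IL-8
  bump <- function(t, peak_t, amp, shape = 3) {
    ifelse(t <= 0, 0, amp * (t / peak_t)^shape * exp(shape * (1 - t / peak_t)))
  }
  cyt <- data.frame(time_min = ct)
  amps <- c(tnfa = 120, il6 = 60, il8 = 90) *
    exp(stats::rnorm(3, 0, 0.25))
  peaks <- c(tnfa = 90, il6 = 150, il8 = 180)
  for (k in names(base)) {
    lev <- base[[k]] * exp(stats::rnorm(length(ct), 0, 0.1))
    if (has_lps) lev <- lev + bump(ct, peaks[[k]], amps[[k]])
    cyt[[k]] <- lev
  }

  pt <- c(0, 60, 210)
  base_score <- sample(0:1, 1)
  delta <- if (condition == "LPS") sample(1:2, 1)
           else sample(c(0L, 0L, 0L, 1L), 1)
  score <- pmin(pmax(c(base_score, base_score + delta,
                       base_score + ifelse(delta > 0, delta - sample(0:1, 1),
                                           0)), 0L), 4L)
  poms <- data.frame(time_min = pt, score = as.integer(score))

  list(subject = subject, condition = condition,
       mp_plasma = mp, cytokines = cyt, poms_fatigue = poms)
}
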