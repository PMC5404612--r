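#' Paired two-tailed t-test
#'
#' Student's paired t-test on two subject-matched vectors (typically
#' delta-BP under two pre-treatment conditions). Wraps
#' \code{stats::t.test(..., paired = TRUE)}; zero-variance differences are
#' returned as a flagged degenerate result rather than an error.
#'
#' @param delta_a,delta_b Subject-matched numeric vectors, length >= 2.
#' @return List with \code{t}, \code{p} (two-sided), \code{mean_diff},
#'   \code{df}, \code{n} and \code{degenerate}.
#' @export
paired_ttest <- function(delta_a, delta_b) {
  n <- length(delta_a)
  if (length(delta_b) != n) stop("length mismatch")
  if (n < 2) stop("need at least 2 pairs")
  d <- delta_a - delta_b
  if (any(!is.finite(d))) stop("differences must be finite")
  if (stats::sd(d) == 0) {
    return(list(t = NA_real_, p = NA_real_, mean_diff = mean(d),
                df = n - 1, n = n, degenerate = TRUE))
  }
  ht <- stats::t.test(delta_a, delta_b, paired = TRUE)
  list(t = unname(ht$statistic), p = ht$p.value, mean_diff = mean(d),
       df = unname(ht$parameter), n = n, degenerate = FALSE)
}

#' Bonferroni-adjusted significance threshold
#'
#' @param alpha Family-wise error rate, in (0, 1).
#' @param m Number of independent comparisons, >= 1.
#' @return \code{alpha / m}.
#' @examples
#' bonferroni_threshold(0.05, 6)  # 0.008333...
#' @export
bonferroni_threshold <- function(alpha, m) {
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 1) stop("alpha in (0,1)")
  if (!is.finite(m) || m < 1) stop("m must be >= 1")
  alpha / m
}

#' Pearson correlation screen
#'
#' Sample correlation with the usual t-based two-sided p-value, used to
#' screen covariates (plasma drug level, cytokines, fatigue scores)
#' against delta-BP. Wraps \code{stats::cor.test}.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return List with \code{r}, \code{p}, \code{n} and \code{degenerate}
#'   (TRUE when either vector has zero variance; then r and p are NA).
#' @export
pearson_screen <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("length mismatch")
  if (n < 3) stop("need n >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(r = NA_real_, p = NA_real_, n = n, degenerate = TRUE))
  }
  ht <- stats::cor.test(x, y)
  list(r = unname(ht$estimate), p = ht$p.value, n = n, degenerate = FALSE)
}

#' Voxelwise paired contrast between two conditions
#'
#' Applies a paired two-tailed t-test across subjects at every valid voxel
#' of two sets of subject-aligned delta-BP maps and returns a significance
#' image coded as (1 - p), a display mask thresholded at
#' \code{(1 - p) > display_threshold}, and a direction image (sign of the
#' mean paired difference), so voxels with a > b and a < b remain
#' distinguishable.
#'
#' @param dbp_maps_a,dbp_maps_b Lists of 3D arrays (one per subject, same
#'   subject order, same grid). NA voxels are treated as invalid.
#' @param valid_mask Optional logical 3D array restricting the analysis.
#' @param display_threshold Display cut on (1 - p); default 0.90.
#' @return An object of class \code{significance_map}: list with
#'   \code{one_minus_p}, \code{displayed} (logical), \code{direction}
#'   (-1/0/+1), \code{valid} (voxels tested) and \code{n_subjects}.
#' @export
voxelwise_contrast <- function(dbp_maps_a, dbp_maps_b, valid_mask = NULL,
                               display_threshold = 0.90) {
  n <- length(dbp_maps_a)
  if (length(dbp_maps_b) != n) stop("subject count mismatch across conditions")
  if (n < 2) stop("need >= 2 subjects")
  dims <- dim(dbp_maps_a[[1]])
  A <- vapply(dbp_maps_a, function(m) as.vector(m), numeric(prod(dims)))
  B <- vapply(dbp_maps_b, function(m) as.vector(m), numeric(prod(dims)))
  D <- A - B
  valid <- rowSums(is.na(D)) == 0
  if (!is.null(valid_mask)) valid <- valid & as.vector(valid_mask)
  m <- rowMeans(D)
  s <- sqrt(pmax(rowSums((D - m)^2), 0) / (n - 1))
  tstat <- m / (s / sqrt(n))
  p <- 2 * stats::pt(-abs(tstat), df = n - 1)
  zero_var <- s == 0
  valid <- valid & !zero_var & is.finite(p)
  omp <- rep(NA_real_, prod(dims))
  omp[valid] <- 1 - p[valid]
  displayed <- !is.na(omp) & omp > display_threshold
  dir <- integer(prod(dims))
  dir[valid] <- sign(m[valid])
  structure(list(one_minus_p = array(omp, dims),
                 displayed = array(displayed, dims),
                 direction = array(dir, dims),
                 valid = array(valid, dims),
                 n_subjects = n,
                 display_threshold = display_threshold),
            class = "significance_map")
}

#' @export
print.significance_map <- function(x, ...) {
  cat(sprintf(
    "<significance_map: %d voxels tested, %d displayed at (1-p) > %.2f>\n",
    sum(x$valid), sum(x$displayed), x$display_threshold))
  invisible(x)
}

#' Percentage of significant voxels within a region
#'
#' 100 times the number of displayed voxels inside the region divided by
#' the number of valid (tested) voxels inside the region; voxels excluded
#' as invalid count in neither numerator nor denominator.
#'
#' @param sig_map A \code{\link{voxelwise_contrast}} result.
#' @param phantom The phantom defining the region.
#' @param region Region name or label code(s).
#' @return Percent (scalar); NA if the region holds no valid voxels.
#' @export
percent_significant_voxels <- function(sig_map, phantom, region) {
  codes <- .resolve_labels(phantom, region)
  in_reg <- phantom$labels %in% codes
  if (!any(in_reg)) stop("empty region")
  n_valid <- sum(in_reg & sig_map$valid)
  if (n_valid == 0) return(NA_real_)
  100 * sum(in_reg & sig_map$displayed) / n_valid
}

#' Region-level condition summary table
#'
#' Builds the canonical occupancy report: one row per region (pooled
#' striatum; putamen, caudate and ventral striatum each pooled and
#' left/right), with mean (SD) delta-BP per condition, the paired
#' two-tailed p-value contrasting the two challenge conditions, and ROI
#' volume. Arms without a within-subject pair (e.g. a 2-subject
#' LPS-alone arm) are summarised descriptively only.
#'
#' @param dbp_table Data frame with columns \code{subject},
#'   \code{condition}, \code{region}, \code{delta_bp} (as produced by
#'   \code{\link{delta_bp_table}}).
#' @param volumes Optional named vector of region volumes (ml) to include.
#' @param regions Row order; defaults to the 10-row layout
#'   striatum; putamen (pooled, L, R); caudate (pooled, L, R); ventral
#'   striatum (pooled, L, R). Regions absent from the table are dropped.
#' @param contrast Character pair naming the two conditions to test
#'   (default \code{c("MP+LPS", "MP+PBO")}).
#' @return Data frame, one row per region, deterministic in the input row
#'   order.
#' @export
build_table1 <- function(dbp_table, volumes = NULL,
                         regions = c("striatum",
                                     "putamen", "putamen_l", "putamen_r",
                                     "caudate", "caudate_l", "caudate_r",
                                     "ventral_striatum",
                                     "ventral_striatum_l",
                                     "ventral_striatum_r"),
                         contrast = c("MP+LPS", "MP+PBO")) {
  need <- c("subject", "condition", "region", "delta_bp")
  if (!all(need %in% names(dbp_table))) {
    stop("dbp_table needs columns: ", paste(need, collapse = ", "))
  }
  dbp_table <- dbp_table[order(dbp_table$subject, dbp_table$condition), ]
  regions <- intersect(regions, unique(dbp_table$region))
  conds <- unique(dbp_table$condition)
  rows <- lapply(regions, function(reg) {
    d <- dbp_table[dbp_table$region == reg, ]
    row <- list(region = reg,
                volume_ml = if (!is.null(volumes) && reg %in% names(volumes))
                  volumes[[reg]] else NA_real_)
    for (cn in conds) {
      v <- d$delta_bp[d$condition == cn]
      tag <- gsub("[^A-Za-z]+", "_", tolower(cn))
      row[[paste0("mean_", tag)]] <- if (length(v)) mean(v) else NA_real_
      row[[paste0("sd_", tag)]] <- if (length(v) > 1) stats::sd(v) else NA_real_
      row[[paste0("n_", tag)]] <- length(v)
    }
    row$p_paired <- NA_real_
    row$incomplete <- FALSE
    if (all(contrast %in% conds)) {
      a <- d[d$condition == contrast[1], ]
      b <- d[d$condition == contrast[2], ]
      common <- intersect(a$subject, b$subject)
      if (length(common) >= 2) {
        tt <- paired_ttest(a$delta_bp[match(common, a$subject)],
                           b$delta_bp[match(common, b$subject)])
        row$p_paired <- tt$p
      } else {
        row$incomplete <- TRUE
      }
    }
    as.data.frame(row, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
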