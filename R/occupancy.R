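#' Percent change in binding potential
#'
#' The occupancy statistic: percent reduction of binding potential from the
#' baseline to the post-challenge scan,
#' \deqn{\Delta BP = 100 (BP_{base} - BP_{post}) / BP_{base}.}
#' Positive values mean BP fell (dopamine elevation displacing the tracer);
#' negative values mean it rose. Vectorised.
#'
#' @param bp_baseline,bp_post Binding potentials (unitless).
#' @param fractional Return the fraction instead of percent (default FALSE).
#' @return Numeric vector; NA (with a warning) where \code{bp_baseline} is 0.
#' @examples
#' delta_bp(2.5, 2.0)   # 20
#' @export
delta_bp <- function(bp_baseline, bp_post, fractional = FALSE) {
  out <- (bp_baseline - bp_post) / bp_baseline
  bad <- is.finite(bp_baseline) & bp_baseline == 0
  if (any(bad)) {
    warning("delta_bp undefined where baseline BP is 0; returning NA")
    out[bad] <- NA_real_
  }
  if (fractional) out else 100 * out
}

#' Intra-subject test-retest percent variability
#'
#' Mean over subjects of the absolute difference between two repeat
#' measurements expressed as a percentage of their two-scan mean:
#' \code{mean(100 * |bp1 - bp2| / ((bp1 + bp2)/2))}. Symmetric in the two
#' scans.
#'
#' @param bp_scan1,bp_scan2 Paired vectors of positive BP values.
#' @return Percent variability (scalar).
#' @export
test_retest_variability <- function(bp_scan1, bp_scan2) {
  if (length(bp_scan1) != length(bp_scan2)) stop("length mismatch")
  if (length(bp_scan1) < 1) stop("need at least one pair")
  if (any(bp_scan1 <= 0) || any(bp_scan2 <= 0)) {
    stop("BP values must be positive")
  }
  mean(100 * abs(bp_scan1 - bp_scan2) / ((bp_scan1 + bp_scan2) / 2))
}

#' Intraclass correlation of repeated baseline measurements
#'
#' One-way random-effects, single-measure ICC (ICC(1,1)) from the ANOVA
#' variance decomposition of a subjects-by-scans matrix:
#' \deqn{ICC = (MS_B - MS_W) / (MS_B + (k-1) MS_W),}
#' where MS_B and MS_W are the between- and within-subject mean squares and
#' k the number of repeats. The two baseline scans are treated as unordered
#' replicates. \code{type = "ICC2"} gives the two-way random-effects
#' ICC(2,1) for comparison.
#'
#' @param bp_matrix Numeric matrix, subjects in rows, repeated scans in
#'   columns (>= 2 rows and >= 2 columns).
#' @param type \code{"ICC1"} (default) or \code{"ICC2"}.
#' @return ICC value (<= 1); NA with a warning if total variance is zero.
#' @export
icc_baseline <- function(bp_matrix, type = c("ICC1", "ICC2")) {
  type <- match.arg(type)
  bp_matrix <- as.matrix(bp_matrix)
  n <- nrow(bp_matrix); k <- ncol(bp_matrix)
  if (n < 2 || k < 2) stop("need >= 2 subjects and >= 2 scans")
  if (any(!is.finite(bp_matrix))) stop("BP matrix must be finite")
  gm <- mean(bp_matrix)
  if (sum((bp_matrix - gm)^2) == 0) {
    warning("zero total variance; ICC undefined")
    return(NA_real_)
  }
  row_m <- rowMeans(bp_matrix)
  col_m <- colMeans(bp_matrix)
  msb <- k * sum((row_m - gm)^2) / (n - 1)
  msw <- sum((bp_matrix - row_m)^2) / (n * (k - 1))
  if (type == "ICC1") {
    return((msb - msw) / (msb + (k - 1) * msw))
  }
  msc <- n * sum((col_m - gm)^2) / (k - 1)
  mse <- sum((sweep(sweep(bp_matrix, 1, row_m), 2, col_m) + gm)^2) /
    ((n - 1) * (k - 1))
  (msb - mse) / (msb + (k - 1) * mse + k * (msc - mse) / n)
}

#' Wilcoxon signed-rank test for paired measurements
#'
#' Two-sided signed-rank test of the paired differences. Zero differences
#' are dropped. For n <= 25 retained pairs without rank ties the p-value
#' comes from the exact null distribution of the rank sum
#' (\code{stats::psignrank}); otherwise a normal approximation with
#' continuity and tie corrections is used. If every difference is zero the
#' p-value is 1 by convention and the result is flagged.
#'
#' @param bp_scan1,bp_scan2 Paired numeric vectors.
#' @return List with \code{p} (two-sided), \code{statistic} (V, the sum of
#'   ranks of positive differences), \code{n_used}, \code{exact} and
#'   \code{all_zero}.
#' @export
wilcoxon_signed_rank <- function(bp_scan1, bp_scan2) {
  if (length(bp_scan1) != length(bp_scan2)) stop("length mismatch")
  d <- bp_scan1 - bp_scan2
  if (any(!is.finite(d))) stop("differences must be finite")
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    return(list(p = 1, statistic = NA_real_, n_used = 0L, exact = TRUE,
                all_zero = TRUE))
  }
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  ties <- any(duplicated(r))
  if (n <= 25 && !ties) {
    # exact: P(V <= v) + P(V >= v), capped at 1
    p <- 2 * min(stats::psignrank(V, n),
                 stats::psignrank(V - 1, n, lower.tail = FALSE))
    p <- min(p, 1)
    exact <- TRUE
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- (V - mu - sign(V - mu) * 0.5) / sqrt(sig2)
    p <- 2 * stats::pnorm(-abs(z))
    exact <- FALSE
  }
  list(p = p, statistic = V, n_used = n, exact = exact, all_zero = FALSE)
}

#' Per-subject delta-BP table from a long BP table
#'
#' Pairs each session's baseline and post scans and computes the percent
#' change in BP per subject, condition and region.
#'
#' @param bp_table Long data frame with columns \code{subject},
#'   \code{session}, \code{scan_type} (\code{"baseline"}/\code{"post"}),
#'   \code{condition}, \code{region}, \code{bp}.
#' @return Data frame with columns \code{subject}, \code{condition},
#'   \code{region}, \code{bp_baseline}, \code{bp_post}, \code{delta_bp}.
#' @export
delta_bp_table <- function(bp_table) {
  need <- c("subject", "session", "scan_type", "condition", "region", "bp")
  if (!all(need %in% names(bp_table))) {
    stop("bp_table needs columns: ", paste(need, collapse = ", "))
  }
  base <- bp_table[bp_table$scan_type == "baseline", ]
  post <- bp_table[bp_table$scan_type == "post", ]
  key <- function(d) paste(d$subject, d$session, d$region, sep = "\r")
  m <- match(key(post), key(base))
  if (any(is.na(m))) stop("post scans without a matching baseline scan")
  out <- data.frame(
    subject = post$subject, condition = post$condition,
    region = post$region, bp_baseline = base$bp[m], bp_post = post$bp,
    stringsAsFactors = FALSE)
  out$delta_bp <- delta_bp(out$bp_baseline, out$bp_post)
  out[order(out$subject, out$condition, out$region), , drop = FALSE]
}

#' Test-retest report across repeated baseline scans
#'
#' For each region with two baseline scans per subject, computes the
#' intraclass correlation, the Wilcoxon signed-rank p-value and the mean
#' intra-subject percent variability.
#'
#' @param bp_table Long BP table as in \code{\link{delta_bp_table}};
#'   subjects must have baseline scans in two sessions.
#' @return Data frame with columns \code{region}, \code{icc},
#'   \code{wilcoxon_p}, \code{mean_abs_percent_var}, \code{n}.
#' @export
test_retest_report <- function(bp_table) {
  base <- bp_table[bp_table$scan_type == "baseline", ]
  out <- list()
  for (reg in unique(base$region)) {
    b <- base[base$region == reg, ]
    wide <- stats::reshape(b[, c("subject", "session", "bp")],
                           idvar = "subject", timevar = "session",
                           direction = "wide")
    m <- as.matrix(wide[, -1, drop = FALSE])
    if (ncol(m) < 2 || any(is.na(m))) next
    w <- wilcoxon_signed_rank(m[, 1], m[, 2])
    out[[reg]] <- data.frame(
      region = reg,
      icc = if (nrow(m) >= 2) icc_baseline(m) else NA_real_,
      wilcoxon_p = w$p,
      mean_abs_percent_var = test_retest_variability(m[, 1], m[, 2]),
      n = nrow(m), stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}
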