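#' Voxelwise SRTM fitting of a dynamic image
#'
#' Fits the simplified reference tissue model at every voxel inside the
#' mask and returns parametric maps. The grid stage is fully vectorised:
#' for each candidate k2a the two-parameter weighted linear subproblem is
#' solved for all voxels at once; the winning k2a per voxel is then refined
#' by parabolic interpolation of the RSS profile in log-k2a (default) or a
#' per-voxel golden-section search. Voxels whose fit is non-finite, whose
#' winning k2a sits on the search-grid boundary, or whose BP falls outside
#' \code{bp_clamp} are marked invalid.
#'
#' @param image A \code{dynamic_image}.
#' @param ref_fine Fine-grid reference curve (\code{fine_tac}).
#' @param mask Logical 3D array, or a \code{label_phantom} (then
#'   \code{labels} selects the fitted regions; default all striatal
#'   sub-regions).
#' @param labels Regions to fit when \code{mask} is a phantom.
#' @param k2a_grid Candidate k2a values (1/min).
#' @param weights Per-frame weights; default
#'   \code{compute_weights(schedule)}.
#' @param refine \code{"interp"} (default), \code{"optimize"} or
#'   \code{"none"}.
#' @param bp_clamp Valid BP range; default \code{c(-0.9, 10)}.
#' @return An object of class \code{bp_map}: list of 3D arrays \code{bp},
#'   \code{r1}, \code{k2a} (NA outside mask or where invalid), the logical
#'   \code{valid} mask, the \code{mask} fitted, and fit metadata.
#' @export
fit_voxelwise <- function(image, ref_fine, mask, labels = c("striatum"),
                          k2a_grid = default_k2a_grid(), weights = NULL,
                          refine = c("interp", "optimize", "none"),
                          bp_clamp = c(-0.9, 10)) {
  refine <- match.arg(refine)
  schedule <- image$schedule
  dims <- dim(image$data)[1:3]
  if (inherits(mask, "label_phantom")) {
    if (!all(dim(mask$labels) == dims)) stop("image and mask grids differ")
    codes <- .resolve_labels(mask, labels)
    mask_arr <- array(mask$labels %in% codes, dim = dims)
  } else {
    mask_arr <- mask
    if (!all(dim(mask_arr) == dims)) stop("image and mask grids differ")
  }
  idx <- which(mask_arr)
  if (!length(idx)) stop("empty mask")
  nf <- schedule$n
  nvox <- prod(dims)
  Y <- vapply(seq_len(nf), function(f) image$data[idx + (f - 1L) * nvox],
              numeric(length(idx)))
  Y <- matrix(Y, nrow = length(idx))

  basis <- srtm_basis(ref_fine, schedule, k2a_grid)
  grid <- basis$k2a_grid
  J <- length(grid)
  if (is.null(weights)) weights <- compute_weights(schedule)
  w <- weights / sum(weights)

  refF <- basis$refF
  a11 <- sum(w * refF^2)
  a12 <- colSums(w * refF * basis$B)
  a22 <- colSums(w * basis$B^2)
  det <- a11 * a22 - a12^2
  b1 <- as.vector(Y %*% (w * refF))           # V
  B2 <- Y %*% (w * basis$B)                   # V x J
  syy <- as.vector(Y^2 %*% w)
  ok <- det > .Machine$double.eps * a11 * a22
  # closed-form coefficients for all voxels x grid nodes
  R1m <- (outer(b1, a22) - sweep(B2, 2, a12, `*`)) / rep(det, each = length(idx))
  TH2 <- (sweep(B2, 2, a11, `*`) - outer(b1, a12)) / rep(det, each = length(idx))
  RSS <- syy - R1m * b1 - TH2 * B2
  RSS[, !ok] <- Inf
  jbest <- max.col(-RSS, ties.method = "first")
  V <- length(idx)
  pick <- cbind(seq_len(V), jbest)

  k2a_v <- grid[jbest]
  R1_v <- R1m[pick]
  th2_v <- TH2[pick]
  boundary <- jbest == 1L | jbest == J

  if (refine != "none" && J >= 3) {
    interior <- which(!boundary)
    for (v in interior) {
      j <- jbest[v]
      lx <- log(grid[(j - 1L):(j + 1L)])
      ly <- RSS[v, (j - 1L):(j + 1L)]
      k_new <- k2a_v[v]
      if (refine == "interp") {
        d1 <- (ly[2] - ly[1]) / (lx[2] - lx[1])
        d2 <- (ly[3] - ly[2]) / (lx[3] - lx[2])
        curv <- (d2 - d1) / (lx[3] - lx[1])
        if (is.finite(curv) && curv > 0) {
          k_new <- exp(min(max(0.5 * (lx[1] + lx[2]) - d1 / (2 * curv),
                               lx[1]), lx[3]))
        }
      } else {
        f <- function(lk) {
          b <- exp_convolve(ref_fine, exp(lk), schedule)
          .srtm_solve(Y[v, ], refF, b, w)$rss
        }
        k_new <- exp(stats::optimize(f, interval = c(lx[1], lx[3]),
                                     tol = 1e-7)$minimum)
      }
      if (k_new != k2a_v[v]) {
        b <- exp_convolve(ref_fine, k_new, schedule)
        s <- .srtm_solve(Y[v, ], refF, b, w)
        if (is.finite(s$rss)) {
          k2a_v[v] <- k_new; R1_v[v] <- s$R1; th2_v[v] <- s$theta2
        }
      }
    }
  }

  k2_v <- th2_v + R1_v * k2a_v
  bp_v <- k2_v / k2a_v - 1
  valid <- is.finite(bp_v) & !boundary &
    bp_v > bp_clamp[1] & bp_v < bp_clamp[2]

  mk <- function(vals) {
    a <- array(NA_real_, dim = dims)
    a[idx[valid]] <- vals[valid]
    a
  }
  valid_arr <- array(FALSE, dim = dims)
  valid_arr[idx[valid]] <- TRUE
  structure(list(bp = mk(bp_v), r1 = mk(R1_v), k2a = mk(k2a_v),
                 valid = valid_arr, mask = mask_arr,
                 k2a_grid = grid, bp_clamp = bp_clamp, refine = refine,
                 n_fit = V, n_valid = sum(valid)),
            class = "bp_map")
}

#' @export
print.bp_map <- function(x, ...) {
  cat(sprintf("<bp_map: %d voxels fitted, %d valid, BP range [%.3g, %.3g]>\n",
              x$n_fit, x$n_valid, min(x$bp, na.rm = TRUE),
              max(x$bp, na.rm = TRUE)))
  invisible(x)
}

#' Per-region summary of a parametric BP map
#'
#' @param map A \code{bp_map}.
#' @param phantom The phantom defining the regions.
#' @param labels Region names to summarise.
#' @return Data frame with region, n_valid and mean BP over valid voxels.
#' @export
summarize_bp_map <- function(map, phantom,
                             labels = c("caudate", "putamen",
                                        "ventral_striatum")) {
  rows <- lapply(labels, function(l) {
    codes <- .resolve_labels(phantom, l)
    idx <- which(phantom$labels %in% codes & map$valid)
    data.frame(region = l, n_valid = length(idx),
               mean_bp = if (length(idx)) mean(map$bp[idx]) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
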