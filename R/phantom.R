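#' Label codes of the digital striatum phantom
#'
#' @return Named integer vector mapping region names to label values
#'   (0 = background).
#' @export
phantom_labels <- function() {
  c(background = 0L, caudate_l = 1L, caudate_r = 2L, putamen_l = 3L,
    putamen_r = 4L, ventral_striatum_l = 5L, ventral_striatum_r = 6L,
    cerebellum = 7L)
}

#' Default phantom region volume targets (ml)
#'
#' Bilateral striatal sub-region volumes match the study template (putamen
#' 10.7/11.3, caudate 10.2/10.5, ventral striatum 1.4/1.5 ml). The
#' cerebellum blob is a synthetic stand-in reference region (no template
#' volume exists for it); 40 ml keeps it desk-scale.
#'
#' @return Named numeric vector of volumes in ml.
#' @export
default_phantom_volumes <- function() {
  c(caudate_l = 10.2, caudate_r = 10.5, putamen_l = 10.7, putamen_r = 11.3,
    ventral_striatum_l = 1.4, ventral_striatum_r = 1.5, cerebellum = 40)
}

# ellipsoid geometry: centre offsets from the volume centre (mm) and
# semi-axis shape ratios, chosen so the default regions neither overlap nor
# leave the default 64 x 64 x 32 field of view
.phantom_geometry <- function() {
  list(
    caudate_l          = list(centre = c(-11, 18, 12), ratio = c(0.8, 2.2, 1.4)),
    caudate_r          = list(centre = c( 11, 18, 12), ratio = c(0.8, 2.2, 1.4)),
    putamen_l          = list(centre = c(-28, -2,  4), ratio = c(0.9, 2.4, 1.35)),
    putamen_r          = list(centre = c( 28, -2,  4), ratio = c(0.9, 2.4, 1.35)),
    ventral_striatum_l = list(centre = c( -9, 30, -10), ratio = c(1, 1.3, 1)),
    ventral_striatum_r = list(centre = c(  9, 30, -10), ratio = c(1, 1.3, 1)),
    cerebellum         = list(centre = c(  0, -36, -18), ratio = c(2.2, 1.3, 1))
  )
}

#' Build the digital striatum phantom
#'
#' Places bilateral ellipsoidal caudate, putamen and ventral-striatum
#' regions plus a cerebellar reference blob in an integer label volume.
#' Each region's ellipsoid is scaled by bisection until its voxel count
#' times the voxel volume matches the target volume within 10%.
#'
#' @param dims Integer grid dimensions (default \code{c(64, 64, 32)}).
#' @param voxel_size_mm Voxel edge lengths in mm (default
#'   \code{c(2.1, 2.1, 2.4)}).
#' @param region_volumes Named vector of target volumes in ml (default
#'   \code{\link{default_phantom_volumes}()}).
#' @return An object of class \code{label_phantom}: list with
#'   \code{labels} (integer 3D array), \code{voxel_size_mm},
#'   \code{label_map}, and \code{volumes_ml} (achieved volumes).
#' @export
make_phantom <- function(dims = c(64, 64, 32),
                         voxel_size_mm = c(2.1, 2.1, 2.4),
                         region_volumes = default_phantom_volumes()) {
  stopifnot(length(dims) == 3, all(dims >= 8), all(voxel_size_mm > 0))
  geom <- .phantom_geometry()
  if (!all(names(region_volumes) %in% names(geom))) {
    stop("unknown region in volume targets")
  }
  vox_ml <- prod(voxel_size_mm) / 1000
  # world coordinates of voxel centres, origin at the volume centre
  ax <- lapply(1:3, function(d) {
    (seq_len(dims[d]) - 0.5 - dims[d] / 2) * voxel_size_mm[d]
  })
  labels <- array(0L, dim = dims)
  lm <- phantom_labels()
  achieved <- numeric(0)
  for (reg in names(region_volumes)) {
    target <- region_volumes[[reg]]
    g <- geom[[reg]]
    base <- (target * 1000 / (4 / 3 * pi * prod(g$ratio)))^(1 / 3)
    count_at <- function(scale) {
      semi <- g$ratio * base * scale
      ix <- which(abs(ax[[1]] - g$centre[1]) <= semi[1])
      iy <- which(abs(ax[[2]] - g$centre[2]) <= semi[2])
      iz <- which(abs(ax[[3]] - g$centre[3]) <= semi[3])
      if (!length(ix) || !length(iy) || !length(iz)) return(NULL)
      dx2 <- ((ax[[1]][ix] - g$centre[1]) / semi[1])^2
      dy2 <- ((ax[[2]][iy] - g$centre[2]) / semi[2])^2
      dz2 <- ((ax[[3]][iz] - g$centre[3]) / semi[3])^2
      inside <- outer(outer(dx2, dy2, `+`), dz2, `+`) <= 1
      list(ix = ix, iy = iy, iz = iz, inside = inside,
           n = sum(inside), semi = semi)
    }
    lo <- 0.7; hi <- 1.4; sol <- NULL
    for (it in 1:40) {
      mid <- (lo + hi) / 2
      sol <- count_at(mid)
      n <- if (is.null(sol)) 0 else sol$n
      if (n * vox_ml < target) lo <- mid else hi <- mid
      if (n > 0 && abs(n * vox_ml - target) / target < 0.02) break
    }
    if (is.null(sol) || sol$n == 0 ||
        abs(sol$n * vox_ml - target) / target > 0.10) {
      stop("cannot realise volume target for region ", reg,
           " within 10% on this grid")
    }
    ext <- abs(g$centre) + sol$semi
    half <- dims * voxel_size_mm / 2
    if (any(ext > half)) stop("region ", reg, " does not fit in the volume")
    sub <- labels[sol$ix, sol$iy, sol$iz]
    if (any(sub[sol$inside] != 0L)) stop("region ", reg,
                                         " overlaps an existing region")
    sub[sol$inside] <- lm[[reg]]
    labels[sol$ix, sol$iy, sol$iz] <- sub
    achieved[reg] <- sol$n * vox_ml
  }
  structure(list(labels = labels, voxel_size_mm = voxel_size_mm,
                 label_map = lm[c("background", names(region_volumes))],
                 volumes_ml = achieved),
            class = "label_phantom")
}

#' @export
print.label_phantom <- function(x, ...) {
  cat(sprintf("<label_phantom: %s voxels of %s mm, %d regions>\n",
              paste(dim(x$labels), collapse = "x"),
              paste(x$voxel_size_mm, collapse = "x"),
              length(x$volumes_ml)))
  print(round(x$volumes_ml, 2))
  invisible(x)
}

# resolve region names / label codes / label sets to an integer code vector
.resolve_labels <- function(phantom, labels) {
  if (is.character(labels)) {
    grouped <- list(
      caudate = c("caudate_l", "caudate_r"),
      putamen = c("putamen_l", "putamen_r"),
      ventral_striatum = c("ventral_striatum_l", "ventral_striatum_r"),
      striatum = c("caudate_l", "caudate_r", "putamen_l", "putamen_r",
                   "ventral_striatum_l", "ventral_striatum_r"))
    nm <- unlist(lapply(labels, function(l) {
      if (l %in% names(grouped)) grouped[[l]] else l
    }), use.names = FALSE)
    unknown <- setdiff(nm, names(phantom$label_map))
    if (length(unknown)) stop("unknown region(s): ",
                              paste(unknown, collapse = ", "))
    codes <- unname(phantom$label_map[nm])
  } else {
    codes <- as.integer(labels)
    if (!all(codes %in% phantom$label_map)) stop("unknown label code")
  }
  codes
}

#' Render a dynamic 4D image from per-region TACs
#'
#' Fills each labelled voxel's time course with its region's TAC plus
#' independent per-voxel Gaussian noise under the same duration- and
#' decay-dependent variance law as the cohort simulator; background voxels
#' are zero.
#'
#' @param phantom A \code{\link{make_phantom}} result.
#' @param region_tacs Named list mapping every non-background phantom
#'   region to its frame-averaged activity vector (or \code{tac}).
#' @param schedule A \code{frame_schedule} (may be omitted when any entry
#'   of \code{region_tacs} is a \code{tac}).
#' @param voxel_noise_scale Noise magnitude per voxel (default 0: noise
#'   free).
#' @param seed Integer seed for the voxel noise.
#' @return An object of class \code{dynamic_image}: list with \code{data}
#'   (4D array x,y,z,frame in kBq/ml), \code{schedule} and
#'   \code{voxel_size_mm}.
#' @export
render_dynamic_image <- function(phantom, region_tacs, schedule = NULL,
                                 voxel_noise_scale = 0, seed = 1) {
  if (is.null(schedule)) {
    for (v in region_tacs) if (inherits(v, "tac")) { schedule <- v$schedule; break }
  }
  stopifnot(inherits(schedule, "frame_schedule"))
  regions <- setdiff(names(phantom$label_map), "background")
  missing <- setdiff(regions, names(region_tacs))
  if (length(missing)) stop("missing TAC for region(s): ",
                            paste(missing, collapse = ", "))
  nf <- schedule$n
  dims <- dim(phantom$labels)
  img <- array(0, dim = c(dims, nf))
  set.seed(seed)
  nvox <- prod(dims)
  for (reg in regions) {
    y <- region_tacs[[reg]]
    if (inherits(y, "tac")) y <- y$activity
    if (length(y) != nf) stop("TAC for ", reg, " has wrong frame count")
    idx <- which(phantom$labels == phantom$label_map[[reg]])
    if (!length(idx)) next
    vals <- matrix(rep(y, each = length(idx)), nrow = length(idx))
    if (voxel_noise_scale > 0) {
      sds <- tac_noise_sd(y, schedule, voxel_noise_scale)
      vals <- vals + matrix(stats::rnorm(length(idx) * nf,
                                         sd = rep(sds, each = length(idx))),
                            nrow = length(idx))
    }
    for (f in seq_len(nf)) img[idx + (f - 1L) * nvox] <- vals[, f]
  }
  structure(list(data = img, schedule = schedule,
                 voxel_size_mm = phantom$voxel_size_mm),
            class = "dynamic_image")
}

#' @export
print.dynamic_image <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<dynamic_image: %s, %d frames>\n",
              paste(d[1:3], collapse = "x"), d[4]))
  invisible(x)
}

#' Extract a pooled ROI time-activity curve
#'
#' Unweighted mean over all voxels carrying the requested label(s), per
#' frame. Label sets (e.g. \code{"striatum"}, or
#' \code{c("putamen_l", "putamen_r")}) are pooled voxelwise, not averaged
#' region-wise, so larger sub-regions contribute proportionally more.
#'
#' @param image A \code{dynamic_image}.
#' @param phantom The \code{label_phantom} on the same grid.
#' @param labels Region name(s) (including the pooled names
#'   \code{"striatum"}, \code{"caudate"}, \code{"putamen"},
#'   \code{"ventral_striatum"}) or integer label code(s).
#' @return A \code{\link{tac}}.
#' @export
extract_roi_tac <- function(image, phantom, labels) {
  if (!all(dim(image$data)[1:3] == dim(phantom$labels))) {
    stop("image and phantom grids differ")
  }
  codes <- .resolve_labels(phantom, labels)
  idx <- which(phantom$labels %in% codes)
  if (!length(idx)) stop("empty label selection")
  nf <- image$schedule$n
  nvox <- prod(dim(phantom$labels))
  y <- vapply(seq_len(nf),
              function(f) mean(image$data[idx + (f - 1L) * nvox]),
              numeric(1))
  tac(image$schedule, y,
      label = paste(as.character(labels), collapse = "+"))
}
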