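#' Simulate a reference-region (cerebellum) time-activity curve
#'
#' Generates a noise-free cerebellar TAC on a regular fine time grid as a
#' bi-exponential (linear combination of a fast rise and a slow washout),
#' the standard gamma-variate-like shape of raclopride kinetics in tissue
#' devoid of specific binding:
#' \deqn{C_r(t) = A' (e^{-\lambda_w t} - e^{-\lambda_r t})}
#' with \eqn{\lambda_w = \ln 2 / t_{1/2,washout}} and the rise rate
#' \eqn{\lambda_r} solved so the curve peaks at \code{peak_time}; \eqn{A'}
#' normalises the maximum to \code{peak_amp}. The curve is zero at t = 0,
#' rises to its peak, then decays.
#'
#' @param peak_time Time of maximum, minutes (default 4).
#' @param peak_amp Peak activity concentration, kBq/ml (default 30). A value
#'   of 0 yields an all-zero curve; negative values are an error.
#' @param washout_halflife Half-life of the terminal washout, minutes
#'   (default 25).
#' @param t_max Support of the curve, minutes (default 120).
#' @param fine_dt Fine-grid step, minutes (default 0.05).
#' @return An object of class \code{fine_tac}: list with \code{t} (regular
#'   grid \code{seq(0, t_max, fine_dt)}), \code{y} (kBq/ml) and \code{dt}.
#' @examples
#' ref <- simulate_reference_tac()
#' ref$t[which.max(ref$y)]   # ~4 min
#' @export
simulate_reference_tac <- function(peak_time = 4, peak_amp = 30,
                                   washout_halflife = 25,
                                   t_max = 120, fine_dt = 0.05) {
  if (!is.finite(fine_dt) || fine_dt <= 0) stop("fine_dt must be positive")
  if (!is.finite(peak_amp) || peak_amp < 0) stop("peak_amp must be non-negative")
  if (!is.finite(peak_time) || peak_time <= 0) stop("peak_time must be positive")
  if (!is.finite(washout_halflife) || washout_halflife <= 0) {
    stop("washout_halflife must be positive")
  }
  t <- seq(0, t_max, by = fine_dt)
  if (peak_amp == 0) {
    return(structure(list(t = t, y = rep(0, length(t)), dt = fine_dt),
                     class = "fine_tac"))
  }
  lw <- log(2) / washout_halflife
  # peak of exp(-lw t) - exp(-lr t) sits at log(lr/lw)/(lr - lw); solve for lr
  f <- function(lr) log(lr / lw) / (lr - lw) - peak_time
  lr <- stats::uniroot(f, lower = lw * (1 + 1e-8), upper = 1e4,
                       tol = 1e-12)$root
  y <- exp(-lw * t) - exp(-lr * t)
  ymax <- exp(-lw * peak_time) - exp(-lr * peak_time)
  y <- y * (peak_amp / ymax)
  structure(list(t = t, y = y, dt = fine_dt), class = "fine_tac")
}

#' @export
print.fine_tac <- function(x, ...) {
  cat(sprintf("<fine_tac: %d samples, dt = %g min, span 0-%g min>\n",
              length(x$t), x$dt, max(x$t)))
  invisible(x)
}

#' Construct a fine-grid curve from raw samples
#'
#' @param t Regular time grid (minutes), starting at 0.
#' @param y Activity values (kBq/ml), same length as \code{t}.
#' @return A \code{fine_tac}.
#' @export
fine_tac <- function(t, y) {
  stopifnot(length(t) == length(y), length(t) >= 2)
  dt <- diff(t)
  if (any(abs(dt - dt[1]) > 1e-9)) stop("fine grid must be regular")
  structure(list(t = t, y = y, dt = dt[1]), class = "fine_tac")
}
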