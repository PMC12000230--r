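#' Baroreflex logistic parameters
#'
#' Parameter set for the four-parameter decreasing logistic used throughout
#' the package to describe the arterial baroreflex relation between diastolic
#' blood pressure (DBP) and renal sympathetic nerve activity (RSNA):
#'
#' \deqn{RSNA(DBP) = bottom + \frac{top - bottom}{1 + \exp((DBP - bp50)/w)}}
#'
#' The curve is strictly decreasing in DBP whenever `top > bottom` and
#' `slope_width > 0`. The same parameterization serves two roles: in the
#' synthetic-recording generator the output is a firing rate in spikes/s as a
#' function of absolute DBP (mmHg); in [baro_curve()] fits the output is RSNA
#' as percent of baseline as a function of the DBP *change* from baseline.
#' Units are therefore context-dependent and documented at each use site.
#'
#' @param top Plateau value at low pressure (spikes/s or percent). Must exceed
#'   `bottom`.
#' @param bottom Floor value at high pressure (same units as `top`, >= 0).
#' @param bp50 Pressure of half-maximal output (mmHg; absolute DBP or DBP
#'   change depending on context).
#' @param slope_width Logistic width parameter (mmHg, > 0). Smaller values
#'   give a steeper reflex.
#'
#' @return An object of class `"baro_params"` (a named list).
#' @seealso [baro_logistic()] to evaluate the curve, [baro_curve()] to fit it.
#' @export
#' @examples
#' bp <- baro_params(top = 100, bottom = 0, bp50 = 25, slope_width = 1.5)
#' baro_logistic(bp, c(0, 25, 50))
baro_params <- function(top, bottom, bp50, slope_width) {
  stopifnot(is.numeric(top), is.numeric(bottom), is.numeric(bp50),
            is.numeric(slope_width), length(top) == 1L, length(bottom) == 1L,
            length(bp50) == 1L, length(slope_width) == 1L)
  if (!(top > bottom)) stop("'top' must exceed 'bottom'")
  if (bottom < 0) stop("'bottom' must be >= 0")
  if (slope_width <= 0) stop("'slope_width' must be > 0")
  structure(list(top = top, bottom = bottom, bp50 = bp50,
                 slope_width = slope_width),
            class = "baro_params")
}

#' Evaluate the baroreflex logistic
#'
#' @param params A [baro_params()] object.
#' @param dbp Numeric vector of pressures (mmHg) at which to evaluate.
#' @return Numeric vector, same length as `dbp`; strictly decreasing in `dbp`.
#' @export
baro_logistic <- function(params, dbp) {
  stopifnot(inherits(params, "baro_params"), is.numeric(dbp))
  params$bottom + (params$top - params$bottom) /
    (1 + exp((dbp - params$bp50) / params$slope_width))
}

#' @export
print.baro_params <- function(x, ...) {
  cat("Baroreflex logistic parameters\n")
  cat(sprintf("  top: %.3f  bottom: %.3f  bp50: %.2f mmHg  slope width: %.2f mmHg\n",
              x$top, x$bottom, x$bp50, x$slope_width))
  invisible(x)
}
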