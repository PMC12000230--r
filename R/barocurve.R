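#' Fit a baroreflex function curve from a phenylephrine ramp
#'
#' Builds the open-loop baroreflex curve relating the diastolic pressure
#' rise during a graded phenylephrine infusion to renal sympathetic nerve
#' activity as percent of baseline. Per-beat DBP changes from baseline are
#' sorted into contiguous half-open 2-mmHg bins from 0 to the maximum
#' change, the mean RSNA% of each bin is computed, and a four-parameter
#' decreasing logistic
#' \deqn{RSNA\%(\Delta DBP) = bottom + \frac{top - bottom}{1 + \exp((\Delta DBP - bp50)/w)}}
#' is fitted to the bin means by least squares (Levenberg-Marquardt,
#' [minpack.lm::nlsLM()]) with the width constrained positive so the fitted
#' curve is monotone non-increasing. If the fit fails to converge or comes
#' back non-monotone (top below bottom), the curve falls back to a monotone
#' (antitonic) regression of the bin means with linear interpolation, and
#' the fallback is flagged in the diagnostics.
#'
#' Beats with negative DBP change are excluded; at least 3 nonempty bins are
#' required.
#'
#' @param delta_dbp Numeric, per-beat DBP change from baseline (mmHg,
#'   positive = pressure rise).
#' @param percent Numeric, per-beat RSNA as percent of baseline, same
#'   length.
#' @param bin_width Bin width in mmHg (default 2, the conventional choice).
#' @return An object of class `"baro_curve"`: list with `bins` (data.frame
#'   `lo`, `hi`, `mid`, `mean_percent`, `n`), `params` (a [baro_params()] in
#'   percent vs Delta-DBP units, or `NULL` for the interpolation fallback),
#'   `diagnostics` (`method`, `converged`, `rms`, `n_bins`, `n_beats`),
#'   `range` (fitted Delta-DBP domain) and `call`.
#' @seealso [predict.baro_curve()], [predict_rsna_change()],
#'   [predicted_vs_observed()].
#' @export
#' @examples
#' set.seed(1)
#' d <- runif(400, 0, 30)
#' p <- 5 + 95 / (1 + exp((d - 14) / 3)) + rnorm(400, 0, 4)
#' fit <- baro_curve(d, p)
#' coef(fit)
#' predict_rsna_change(fit, 10)
baro_curve <- function(delta_dbp, percent, bin_width = 2) {
  cl <- match.call()
  stopifnot(length(delta_dbp) == length(percent), bin_width > 0)
  ok <- is.finite(delta_dbp) & is.finite(percent) & delta_dbp >= 0
  d <- delta_dbp[ok]
  p <- percent[ok]
  if (!length(d)) stop("no beats with non-negative DBP change")

  lo <- bin_width * floor(d / bin_width)
  bins <- stats::aggregate(p, by = list(lo = lo), FUN = mean)
  nb <- as.data.frame(table(lo), stringsAsFactors = FALSE)
  bins$n <- nb$Freq[match(bins$lo, as.numeric(nb$lo))]
  bins <- data.frame(lo = bins$lo, hi = bins$lo + bin_width,
                     mid = bins$lo + bin_width / 2,
                     mean_percent = bins$x, n = bins$n)
  bins <- bins[order(bins$lo), , drop = FALSE]
  rownames(bins) <- NULL
  if (nrow(bins) < 3)
    stop("fewer than 3 nonempty bins; cannot fit a baroreflex curve")

  x <- bins$mid
  y <- bins$mean_percent
  w_n <- bins$n
  rng <- range(x)

  # occupancy-weighted least squares: bin means from 1-2 beats carry large
  # Poisson noise and would otherwise dominate the fit
  solid <- if (any(w_n >= 5)) w_n >= 5 else rep(TRUE, length(w_n))
  top0 <- max(y[solid])
  bot0 <- max(min(y[solid]), 0)
  half <- (top0 + bot0) / 2
  bp0 <- x[solid][which.min(abs(y[solid] - half))]
  # multi-start Levenberg-Marquardt: the weighted SSE surface has wide
  # shallow local minima; keep the best of several width/midpoint starts
  starts <- expand.grid(w = unique(pmax(c(bin_width / 2, 1.5, 3,
                                          diff(rng) / 8), 1e-2)),
                        bp50 = unique(c(bp0, mean(rng))))
  fit <- NULL
  best_sse <- Inf
  for (si in seq_len(nrow(starts))) {
    f <- tryCatch(
      minpack.lm::nlsLM(y ~ bottom + (top - bottom) / (1 + exp((x - bp50) / w)),
                        start = list(top = top0, bottom = bot0,
                                     bp50 = starts$bp50[si],
                                     w = starts$w[si]),
                        weights = w_n,
                        lower = c(top = -Inf, bottom = 0, bp50 = -Inf,
                                  w = 1e-3),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(f)) {
      sse <- sum(w_n * stats::residuals(f)^2)
      if (sse < best_sse) {
        best_sse <- sse
        fit <- f
      }
    }
  }

  params <- NULL
  fitfun <- NULL
  converged <- FALSE
  if (!is.null(fit)) {
    co <- stats::coef(fit)
    if (co[["top"]] > co[["bottom"]] && co[["w"]] > 0) {
      params <- baro_params(top = co[["top"]], bottom = co[["bottom"]],
                            bp50 = co[["bp50"]], slope_width = co[["w"]])
      fitfun <- function(z) baro_logistic(params, z)
      converged <- TRUE
    }
  }
  if (!converged) {
    # antitonic bin means with linear interpolation between bin centres
    iso <- stats::isoreg(x, -y)
    yy <- -iso$yf[order(iso$ord %||% seq_along(x))]
    fitfun <- stats::approxfun(x, yy, rule = 2)
  }

  fitted_bins <- fitfun(x)
  structure(list(bins = bins, params = params,
                 diagnostics = list(
                   method = if (converged) "logistic" else "interpolation",
                   converged = converged,
                   rms = sqrt(mean((y - fitted_bins)^2)),
                   n_bins = nrow(bins), n_beats = length(d)),
                 range = rng, fitfun = fitfun, call = cl),
            class = "baro_curve")
}

#' @export
print.baro_curve <- function(x, ...) {
  cat("Baroreflex function curve (", x$diagnostics$method, " fit)\n", sep = "")
  if (!is.null(x$params)) {
    cat(sprintf("  top %.1f%%  bottom %.1f%%  bp50 %.2f mmHg  width %.2f mmHg\n",
                x$params$top, x$params$bottom, x$params$bp50,
                x$params$slope_width))
  }
  cat(sprintf("  %d bins (%d beats), residual RMS %.2f%%\n",
              x$diagnostics$n_bins, x$diagnostics$n_beats, x$diagnostics$rms))
  invisible(x)
}

#' @export
summary.baro_curve <- function(object, ...) {
  print(object)
  cat("\nBin means:\n")
  print(object$bins, digits = 4)
  invisible(object)
}

#' @export
coef.baro_curve <- function(object, ...) {
  if (is.null(object$params))
    return(c(top = NA_real_, bottom = NA_real_, bp50 = NA_real_,
             slope_width = NA_real_))
  unlist(object$params)
}

#' @export
fitted.baro_curve <- function(object, ...) object$fitfun(object$bins$mid)

#' @export
residuals.baro_curve <- function(object, ...)
  object$bins$mean_percent - fitted(object)

#' Evaluate a fitted baroreflex curve
#'
#' Returns the fitted RSNA level (percent of baseline) at the requested DBP
#' changes. Values beyond the fitted range are clamped to the boundary of
#' the curve with a warning.
#'
#' @param object A [baro_curve()].
#' @param delta_dbp Numeric DBP changes (mmHg, >= 0).
#' @param ... Unused.
#' @return Numeric vector of fitted percent levels.
#' @export
predict.baro_curve <- function(object, delta_dbp, ...) {
  stopifnot(is.numeric(delta_dbp), all(delta_dbp >= 0))
  out_of_range <- delta_dbp > object$range[2]
  if (any(out_of_range))
    warning("delta_dbp beyond the fitted range; clamped to the last bin")
  z <- pmin(pmax(delta_dbp, object$range[1]), object$range[2])
  object$fitfun(z)
}

#' Predicted reflex-mediated RSNA change for a pressure rise
#'
#' Evaluates the fitted curve at `delta_dbp` and returns the predicted
#' percent *change* in RSNA relative to no pressure change (negative values
#' = reflex inhibition). This is the quantity compared with the observed
#' pump-induced change in [predicted_vs_observed()].
#'
#' @param curve A [baro_curve()].
#' @param delta_dbp DBP rise in mmHg (>= 0).
#' @param mode `"fit"` (default) evaluates the fitted curve; `"bins"` looks
#'   the level up directly in the binned means (step function over the
#'   2-mmHg bins, clamped at the range ends).
#' @return Numeric predicted percent change (0 at `delta_dbp = 0`).
#' @export
predict_rsna_change <- function(curve, delta_dbp, mode = c("fit", "bins")) {
  mode <- match.arg(mode)
  stopifnot(inherits(curve, "baro_curve"))
  if (mode == "fit") {
    at0 <- suppressWarnings(stats::predict(curve, 0))
    stats::predict(curve, delta_dbp) - at0
  } else {
    stopifnot(all(delta_dbp >= 0))
    b <- curve$bins
    if (any(delta_dbp > b$hi[nrow(b)]))
      warning("delta_dbp beyond the fitted range; clamped to the last bin")
    idx <- pmax(pmin(findInterval(delta_dbp, b$lo), nrow(b)), 1L)
    b$mean_percent[idx] - b$mean_percent[1L]
  }
}

#' @export
plot.baro_curve <- function(x, ...) {
  graphics::plot(x$bins$mid, x$bins$mean_percent,
                 xlab = expression(Delta * "DBP (mmHg)"),
                 ylab = "RSNA (% of baseline)",
                 pch = 16, ...)
  z <- seq(x$range[1], x$range[2], length.out = 200)
  graphics::lines(z, x$fitfun(z), col = "firebrick", lwd = 2)
  invisible(x)
}

#' Paired comparison of predicted and observed RSNA changes
#'
#' Per-subject comparison of the pump-induced RSNA change observed at a pump
#' level against the change predicted by each subject's baroreflex curve at
#' the equivalent pressure rise. A paired two-tailed t-test is run on the
#' per-subject differences (observed minus predicted); a significant excess
#' of the observed inhibition indicates RSNA suppression beyond the arterial
#' baroreflex (decoupling).
#'
#' @param predicted,observed Numeric vectors of percent changes, one entry
#'   per subject (equal length, n >= 3).
#' @return Object of class `"rsna_comparison"`: list with `n`, `mean_diff`,
#'   `sem_diff`, `t`, `df`, `p`, and mean +/- SEM of both arms.
#' @export
predicted_vs_observed <- function(predicted, observed) {
  if (length(predicted) != length(observed))
    stop("predicted and observed must be paired (equal lengths)")
  if (length(predicted) < 3)
    stop("need at least 3 paired subjects")
  d <- observed - predicted
  sem <- function(v) stats::sd(v) / sqrt(length(v))
  if (stats::sd(d) == 0) {
    t <- if (mean(d) == 0) 0 else Inf * sign(mean(d))
    p <- if (mean(d) == 0) 1 else 0
    df <- length(d) - 1
  } else {
    tt <- stats::t.test(observed, predicted, paired = TRUE)
    t <- unname(tt$statistic); df <- unname(tt$parameter); p <- tt$p.value
  }
  structure(list(n = length(d), mean_diff = mean(d), sem_diff = sem(d),
                 t = t, df = df, p = p,
                 mean_observed = mean(observed), sem_observed = sem(observed),
                 mean_predicted = mean(predicted),
                 sem_predicted = sem(predicted)),
            class = "rsna_comparison")
}

#' @export
print.rsna_comparison <- function(x, ...) {
  cat("Observed vs baroreflex-predicted RSNA change\n")
  cat(sprintf("  observed : %6.2f +/- %.2f %%\n", x$mean_observed,
              x$sem_observed))
  cat(sprintf("  predicted: %6.2f +/- %.2f %%\n", x$mean_predicted,
              x$sem_predicted))
  cat(sprintf("  paired t(%g) = %.3f, p = %.4g (n = %d)\n",
              x$df, x$t, x$p, x$n))
  invisible(x)
}

#' Stage-wise relation between two variables (e.g. PP and RSNA%)
#'
#' Returns the paired trajectory of two stage-wise (or pooled
#' subject-by-stage) vectors together with their Pearson correlation and
#' two-tailed p-value. Used both for the pulse-pressure vs RSNA trajectory
#' across pump levels and for the pooled correlation of RSNA change with the
#' renal resistive index.
#'
#' @param x,y Numeric vectors, equal length >= 3.
#' @param labels Optional point labels (e.g. stage names).
#' @return List with `trajectory` (data.frame `label`, `x`, `y`), `r`, `p`,
#'   `n`. Errors if either vector has zero variance.
#' @export
rsna_pp_relation <- function(x, y, labels = NULL) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3) stop("need at least 3 stages/points")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance; correlation undefined")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(trajectory = data.frame(
    label = labels %||% as.character(seq_along(x)), x = x, y = y),
    r = unname(ct$estimate), p = ct$p.value, n = length(x))
}
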