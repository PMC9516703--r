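#' Fit a Gaussian well or peak to a melt-derived trace
#'
#' Fits `value(T) = offset -/+ amplitude * exp(-(T - center)^2 / (2 sigma^2))`
#' by nonlinear least squares with a deterministic initialisation (center at
#' the extremum, amplitude from the data range, sigma a quarter of the
#' temperature span). The `well` orientation (minus sign) models the free
#' energy dG(T), whose minimum `dg_min = offset - amplitude` is the
#' thermodynamic-stability metric; the `peak` orientation models the
#' fractional beta-sheet content.
#'
#' Width is reported as the full width at half maximum
#' (`fwhm = 2 sqrt(2 ln 2) sigma ~= 2.3548 sigma`) and area as the
#' closed-form Gaussian integral `amplitude * sigma * sqrt(2 pi)`.
#'
#' @param temperatures Temperature vector (deg C), >= 6 points.
#' @param values Trace values (kJ/mol for dG, unitless for fractions).
#' @param orientation `"well"` (minimum, dG) or `"peak"` (maximum,
#'   fraction).
#' @return An object of class `landscape_fit` with fields `amplitude`,
#'   `center` (deg C), `sigma` (deg C), `offset`, `dg_min` (well only, `NA`
#'   for peaks), `fwhm`, `area`, `rss`, `fitted`, `residuals`,
#'   `deviation_flag` (initialised `FALSE`; see [detect_deviation()]),
#'   `deviation_onset`, `degenerate` and `orientation`.
#' @examples
#' tt <- seq(25, 97, 2)
#' dg <- -8 * exp(-(tt - 72)^2 / (2 * 6^2))
#' fit_gaussian_landscape(tt, dg, "well")$dg_min  # -8
#' @export
fit_gaussian_landscape <- function(temperatures, values,
                                   orientation = c("well", "peak")) {
  orientation <- match.arg(orientation)
  tt <- as.numeric(temperatures)
  vv <- as.numeric(values)
  stopifnot(length(tt) == length(vv))
  if (length(tt) < 6L)
    stop("need at least 6 points for a 4-parameter Gaussian fit",
         call. = FALSE)
  sgn <- if (orientation == "well") -1 else 1
  rng <- max(vv) - min(vv)
  center0 <- tt[if (orientation == "well") which.min(vv) else which.max(vv)]
  sigma0 <- diff(range(tt)) / 4
  offset0 <- if (orientation == "well") max(vv) else min(vv)
  p0 <- c(offset = offset0, amplitude = max(rng, 1e-12), center = center0,
          sigma = sigma0)
  model <- function(p) p[1] + sgn * p[2] * exp(-(tt - p[3])^2 / (2 * p[4]^2))
  fit <- tryCatch(
    minpack.lm::nls.lm(par = p0, fn = function(p) vv - model(p),
                       lower = c(-Inf, 0, min(tt) - 50, 0.1),
                       upper = c(Inf, Inf, max(tt) + 50, diff(range(tt)) * 2),
                       control = minpack.lm::nls.lm.control(maxiter = 300)),
    error = function(e)
      stop(sprintf("Gaussian fit failed to converge (init: offset %.3g, amplitude %.3g, center %.3g, sigma %.3g): %s",
                   offset0, rng, center0, sigma0, conditionMessage(e)),
           call. = FALSE))
  p <- fit$par
  degenerate <- rng == 0 || p[2] < 1e-9 * rng
  if (degenerate)
    warning("fitted amplitude is negligible relative to the data range; trace is effectively flat",
            call. = FALSE)
  if (p[3] < min(tt) || p[3] > max(tt))
    warning(sprintf("fitted center %.1f degC lies outside the data range [%.1f, %.1f]; extrapolated extremum",
                    p[3], min(tt), max(tt)), call. = FALSE)
  fitted <- model(p)
  structure(
    list(amplitude = unname(p[2]), center = unname(p[3]),
         sigma = unname(p[4]), offset = unname(p[1]),
         dg_min = if (orientation == "well") unname(p[1] - p[2]) else NA_real_,
         fwhm = unname(2 * sqrt(2 * log(2)) * p[4]),
         area = unname(p[2] * p[4] * sqrt(2 * pi)),
         rss = sum((vv - fitted)^2),
         temperatures = tt, values = vv, fitted = fitted,
         residuals = vv - fitted,
         deviation_flag = FALSE, deviation_onset = NA_real_,
         degenerate = degenerate, orientation = orientation),
    class = "landscape_fit")
}

#' @export
print.landscape_fit <- function(x, ...) {
  cat(sprintf("<landscape_fit> %s: center %.1f degC, sigma %.2f degC, amplitude %.3g, offset %.3g\n",
              x$orientation, x$center, x$sigma, x$amplitude, x$offset))
  if (x$orientation == "well")
    cat(sprintf("  dg_min %.3g kJ/mol, fwhm %.2f degC, area %.3g, rss %.3g\n",
                x$dg_min, x$fwhm, x$area, x$rss))
  if (x$deviation_flag)
    cat(sprintf("  deviates from Gaussian behaviour above %.1f degC\n",
                x$deviation_onset))
  invisible(x)
}

#' Flag deviation from Gaussian behaviour at high temperature
#'
#' Extra sigmoidal structure above the Gaussian envelope at high temperature
#' signals enhanced aggregation propensity. The flag is raised when either
#' (a) a run of at least `run_length` consecutive points in the upper
#' temperature quartile has same-signed standardized residuals exceeding
#' `z_threshold` in magnitude (onset recorded as the first such
#' temperature), or (b) a reference residual sum of squares is supplied and
#' the fit's RSS exceeds `rss_ratio` times it. Residuals are standardized by
#' the residual standard deviation of the points *outside* the upper
#' quartile, so the deviation region does not inflate its own yardstick.
#'
#' @param fit A converged `landscape_fit`.
#' @param reference_rss Optional RSS of a reference (e.g. fresh-sample) fit.
#' @param z_threshold Standardized-residual threshold (default 2).
#' @param run_length Minimum consecutive-point run (default 3); a single
#'   outlier never raises the flag.
#' @param rss_ratio RSS ratio threshold versus the reference (default 2).
#' @return The `landscape_fit` with `deviation_flag` and `deviation_onset`
#'   updated.
#' @export
detect_deviation <- function(fit, reference_rss = NULL, z_threshold = 2,
                             run_length = 3, rss_ratio = 2) {
  stopifnot(inherits(fit, "landscape_fit"))
  tt <- fit$temperatures
  res <- fit$residuals
  q3 <- stats::quantile(tt, 0.75, names = FALSE)
  upper <- tt >= q3
  sd_low <- stats::sd(res[!upper])
  if (!is.finite(sd_low) || sd_low == 0) sd_low <- stats::sd(res)
  # numerically exact fits have no residual scale to standardize against
  sd_floor <- 1e-8 * max(diff(range(fit$values)), .Machine$double.eps)
  sd_low <- max(sd_low, sd_floor)
  z <- res / sd_low
  flag <- FALSE
  onset <- NA_real_
  idx <- which(upper)
  if (length(idx) >= run_length) {
    hot <- abs(z[idx]) > z_threshold
    sgn <- sign(z[idx])
    run <- 0L
    for (j in seq_along(idx)) {
      extend <- hot[j] && (j == 1L || run == 0L || sgn[j] == sgn[j - 1L])
      run <- if (extend) run + 1L else if (hot[j]) 1L else 0L
      if (run >= run_length) {
        flag <- TRUE
        onset <- tt[idx[j - run_length + 1L]]
        break
      }
    }
  }
  if (!flag && !is.null(reference_rss) && fit$rss > rss_ratio * reference_rss) {
    flag <- TRUE
    onset <- if (any(upper)) min(tt[upper]) else NA_real_
  }
  fit$deviation_flag <- flag
  fit$deviation_onset <- onset
  fit
}

#' Compare fresh and stored landscape fits
#'
#' Percentage changes of the stability metrics of a stored sample relative
#' to its fresh counterpart: `100 * (stored - fresh) / |fresh|` for the
#' width (FWHM) and area. For `dg_min` the change is reported on the
#' *magnitude* — a more negative stored minimum (deeper well, greater
#' thermodynamic stability) gives a positive percentage:
#' `100 * (|stored| - |fresh|) / |fresh|`.
#'
#' @param fresh,stored Converged `landscape_fit` objects of the same
#'   orientation.
#' @param sample_id Optional label for the pair.
#' @return An object of class `stability_comparison` with fields
#'   `sample_id`, `pct_change_dg_min`, `pct_change_width`,
#'   `pct_change_area` (unrounded) and the rounded-to-integer values used in
#'   report tables (`pct_change_dg_min_int`, ...).
#' @examples
#' tt <- seq(25, 97, 2)
#' f <- fit_gaussian_landscape(tt, -8.3 * exp(-(tt - 72)^2 / 72), "well")
#' s <- fit_gaussian_landscape(tt, -9.5 * exp(-(tt - 73)^2 / 72), "well")
#' round(compare_fresh_stored(f, s)$pct_change_dg_min)  # 14
#' @export
compare_fresh_stored <- function(fresh, stored, sample_id = "") {
  stopifnot(inherits(fresh, "landscape_fit"),
            inherits(stored, "landscape_fit"))
  if (!identical(fresh$orientation, stored$orientation))
    stop("fresh and stored fits have different orientations", call. = FALSE)
  pct <- function(s, f) 100 * (s - f) / abs(f)
  dg <- if (fresh$orientation == "well")
    pct(abs(stored$dg_min), abs(fresh$dg_min)) else NA_real_
  w <- pct(stored$fwhm, fresh$fwhm)
  a <- pct(stored$area, fresh$area)
  structure(list(sample_id = sample_id,
                 pct_change_dg_min = dg, pct_change_width = w,
                 pct_change_area = a,
                 pct_change_dg_min_int = round(dg),
                 pct_change_width_int = round(w),
                 pct_change_area_int = round(a)),
            class = "stability_comparison")
}

#' @export
print.stability_comparison <- function(x, ...) {
  cat(sprintf("<stability_comparison> %s: dG_min %+d%%, width %+d%%, area %+d%% (stored vs fresh)\n",
              x$sample_id, x$pct_change_dg_min_int, x$pct_change_width_int,
              x$pct_change_area_int))
  invisible(x)
}

#' Free-energy landscape of a full melt analysis
#'
#' Builds the full-range free-energy trace `dG(T) = -RT ln(f/(1-f))` from
#' the *global* folded fraction of an [analyze_melt()] result (clipped
#' points excluded) and fits the inverted-Gaussian well with
#' [fit_gaussian_landscape()], optionally running [detect_deviation()].
#'
#' @param melt A `melt_thermo` object from [analyze_melt()].
#' @param flag_deviation Run the deviation detector on the fit (default
#'   TRUE).
#' @param ... Passed on to [detect_deviation()].
#' @return A `landscape_fit` (well orientation).
#' @export
landscape_from_melt <- function(melt, flag_deviation = TRUE, ...) {
  stopifnot(inherits(melt, "melt_thermo"))
  fr <- melt$fraction
  keep <- !fr$clipped
  dg <- free_energy(equilibrium_constant(fr$f[keep]),
                    fr$temperatures[keep])
  fit <- fit_gaussian_landscape(fr$temperatures[keep], dg, "well")
  if (flag_deviation) fit <- detect_deviation(fit, ...)
  fit
}

#' Rank formulations by predicted thermodynamic stability
#'
#' Deterministic total order over samples: formulations whose free-energy
#' landscape stays Gaussian (no deviation flag) rank above flagged ones;
#' within each group a more negative `dg_min` ranks first; ties break by the
#' higher final-transition melting temperature, then lexicographically by
#' sample id.
#'
#' @param samples Named list; each element a list with fields `landscape` (a
#'   `landscape_fit`, well orientation) and optionally `transitions` (list
#'   of `transition_thermo`, used for the Tm tie-break). Names are the
#'   sample ids.
#' @return A data.frame ordered from most to least stable with columns
#'   `rank`, `sample_id`, `dg_min`, `deviation`, `tm_final`.
#' @export
rank_stability <- function(samples) {
  if (length(samples) < 2L)
    stop("need at least 2 samples to rank", call. = FALSE)
  ids <- names(samples)
  if (is.null(ids) || any(ids == ""))
    stop("samples must be a named list", call. = FALSE)
  rows <- lapply(ids, function(id) {
    s <- samples[[id]]
    tm_final <- if (!is.null(s$transitions) && length(s$transitions)) {
      tms <- vapply(s$transitions, function(tr)
        if (is.null(tr)) NA_real_ else tr$tm, numeric(1))
      if (all(is.na(tms))) -Inf else max(tms, na.rm = TRUE)
    } else -Inf
    data.frame(sample_id = id, dg_min = s$landscape$dg_min,
               deviation = isTRUE(s$landscape$deviation_flag),
               tm_final = tm_final, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  ord <- order(df$deviation, df$dg_min, -df$tm_final, df$sample_id)
  df <- df[ord, , drop = FALSE]
  df <- cbind(rank = seq_len(nrow(df)), df)
  rownames(df) <- NULL
  df
}
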