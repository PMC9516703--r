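#' @keywords internal
"_PACKAGE"

# Gas constant, J/mol/K
.R_GAS <- 8.314
# Fraction clip bound keeping ln(K) finite
.F_EPS <- 1e-6

#' Fractional beta-sheet content from a CD melt trace
#'
#' Normalises the CD signal `y` between two anchors: `y0`, the
#' minimum-magnitude signal (fraction 0), and `ymax`, the strongest signal
#' (the maximum of the negative beta-sheet band, fraction 1):
#' `f = (y - y0) / (ymax - y0)`. The result is clipped to
#' `[1e-6, 1 - 1e-6]` so that downstream logarithms stay finite; clipped
#' points are flagged and excluded from transition-window fits.
#'
#' When the anchors are omitted they are selected automatically from the
#' trace: `y0` as the signal of smallest magnitude and `ymax` as the signal
#' of largest magnitude.
#'
#' @param trace An `mre_trace` (from [extract_trace()]) or anything with
#'   `temperatures` and `mre` fields.
#' @param y0 Signal value mapped to fraction 0. Default: auto-selected.
#' @param ymax Signal value mapped to fraction 1. Default: auto-selected.
#' @return An object of class `folded_fraction` with fields `temperatures`,
#'   `f` (clipped), `f_raw` (unclipped), `clipped` (logical), `y0`, `ymax`.
#' @examples
#' tr <- list(temperatures = c(25, 50, 75), mre = c(-3000, -6000, -7000))
#' folded_fraction(tr, y0 = -3000, ymax = -7000)$f  # 0, 0.75, 1 (clipped)
#' @export
folded_fraction <- function(trace, y0 = NULL, ymax = NULL) {
  y <- trace$mre
  tt <- trace$temperatures
  stopifnot(length(y) == length(tt), length(y) >= 2L)
  if (is.null(y0)) y0 <- y[which.min(abs(y))]
  if (is.null(ymax)) ymax <- y[which.max(abs(y))]
  if (y0 == ymax)
    stop("degenerate normalization: y0 equals ymax", call. = FALSE)
  f_raw <- (y - y0) / (ymax - y0)
  f <- pmin(pmax(f_raw, .F_EPS), 1 - .F_EPS)
  structure(list(temperatures = tt, f = f, f_raw = f_raw,
                 clipped = f_raw < .F_EPS | f_raw > 1 - .F_EPS,
                 y0 = y0, ymax = ymax),
            class = "folded_fraction")
}

#' Two-state equilibrium constant from a population fraction
#'
#' Under a two-state model with fraction `f` of molecules in the final
#' ensemble, `K = f / (1 - f)`. Vectorised.
#'
#' @param f Fraction in (0, 1) (use clipped values from
#'   [folded_fraction()]).
#' @return Equilibrium constant(s), unitless.
#' @export
equilibrium_constant <- function(f) {
  if (any(f <= 0 | f >= 1))
    stop("f must lie strictly inside (0, 1); clip first", call. = FALSE)
  f / (1 - f)
}

#' Gibbs free energy of a transition
#'
#' `dG = -R T ln K` with `R = 8.314` J/mol/K and `T` in kelvin
#' (`t_celsius + 273.15`); returned in kJ/mol. Vectorised over both
#' arguments.
#'
#' @param K Equilibrium constant(s), > 0.
#' @param t_celsius Temperature(s) in deg C.
#' @return Free energy in kJ/mol.
#' @examples
#' free_energy(3, 25)  # -2.723 kJ/mol
#' @export
free_energy <- function(K, t_celsius) {
  if (any(K <= 0)) stop("K must be > 0", call. = FALSE)
  -.R_GAS * (t_celsius + 273.15) * log(K) / 1000
}

# Sum-of-logistics model value: baseline c0 plus k logistic steps.
.logistic_sum <- function(tt, pars) {
  k <- (length(pars) - 1L) / 3L
  y <- rep(pars[1L], length(tt))
  for (i in seq_len(k)) {
    a <- pars[1L + 3L * (i - 1L) + 1L]
    m <- pars[1L + 3L * (i - 1L) + 2L]
    s <- pars[1L + 3L * (i - 1L) + 3L]
    y <- y + a / (1 + exp(-(tt - m) / s))
  }
  y
}

# Deterministic multi-start NLS fit of a k-component logistic sum.
# Returns list(pars, rss, centers) or NULL if nothing converged.
.fit_logistic_sum <- function(tt, ff, k) {
  span <- diff(range(tt))
  grid <- stats::quantile(tt, c(0.15, 0.3, 0.5, 0.7, 0.85), names = FALSE)
  starts <- utils::combn(grid, k, simplify = FALSE)
  amp0 <- (max(ff) - min(ff))
  best <- NULL
  lower <- c(-Inf, rep(c(-Inf, min(tt), 0.3), k))
  upper <- c(Inf, rep(c(Inf, max(tt), span / 2), k))
  for (st in starts) {
    p0 <- c(min(ff), as.vector(rbind(amp0 / k, sort(st), span / 20)))
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = p0,
        fn = function(p) ff - .logistic_sum(tt, p),
        lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss)
      best <- list(pars = fit$par, rss = rss)
  }
  if (is.null(best)) return(NULL)
  k_idx <- 1L + 3L * (seq_len(k) - 1L) + 2L
  a_idx <- 1L + 3L * (seq_len(k) - 1L) + 1L
  ord <- order(best$pars[k_idx])
  best$centers <- best$pars[k_idx][ord]
  best$amplitudes <- best$pars[a_idx][ord]
  best
}

# Small-sample-corrected AIC for a least-squares fit.
.aicc <- function(rss, n, n_par) {
  p <- n_par + 1  # + residual variance
  if (n - p - 1 <= 0) return(Inf)
  n * log(max(rss, 1e-300) / n) + 2 * p + 2 * p * (p + 1) / (n - p - 1)
}

#' Segment a melt curve into sigmoidal transition regions
#'
#' Fits sums of `k = 1..max_regions` logistic components to the fractional
#' beta-sheet content versus temperature by nonlinear least squares, using a
#' fixed deterministic grid of starting centers (no randomness), and selects
#' `k` by the small-sample-corrected Akaike criterion (AICc). The trace is
#' then split at the midpoints between adjacent fitted centers, and within
#' each region the fraction is renormalised region-wise so that the local
#' fraction runs 0 to 1 across that transition: the contributions of the
#' *other* fitted components (and the fitted baseline) are subtracted and
#' the isolated signal is divided by the component's own fitted amplitude.
#' Anchoring on the fitted asymptotes rather than on the raw local extrema
#' avoids the truncation bias that overlapping transitions would otherwise
#' impose on each region's endpoints. The
#' equilibrium constant `K = f/(1-f)` and free energy `dG = -RT ln K` are
#' evaluated per point within each region.
#'
#' Two identifiability guards keep the selection honest. Candidate
#' component counts whose best fit contains a degenerate component — an
#' amplitude below 2 % of the data range, or two centers closer than
#' `min_separation` — are discarded: such components are not resolvable
#' transitions. And the RSS entering the AICc is floored at a resolution
#' of 0.1 % of the data range per point, so that fits already at
#' instrument-level precision are not "improved" by extra components.
#'
#' @param fraction A `folded_fraction` object with at least 12 temperature
#'   points.
#' @param max_regions Maximum number of logistic components to consider
#'   (default 3).
#' @param min_separation Minimum resolvable distance between transition
#'   centers, deg C (default 5).
#' @return A list of class `sigmoidal_regions`; each element is a
#'   `sigmoidal_region` with fields `t_lo`, `t_hi`, `region_index`,
#'   `temperatures`, `f_local` (clipped local fraction), `K`, `dG` (kJ/mol),
#'   `clipped`, `center` (fitted logistic center, deg C) and `increasing`.
#'   The list carries attributes `k` (selected component count), `aicc`
#'   (per candidate `k`) and `rss`.
#' @export
segment_transitions <- function(fraction, max_regions = 3,
                                min_separation = 5) {
  stopifnot(inherits(fraction, "folded_fraction"))
  tt <- fraction$temperatures
  ff <- fraction$f_raw
  n <- length(tt)
  if (n < 12L)
    stop("need at least 12 temperature points to segment", call. = FALSE)
  rng <- diff(range(ff))
  rss_floor <- (1e-3 * rng)^2 * n
  fits <- vector("list", max_regions)
  aiccs <- rep(NA_real_, max_regions)
  for (k in seq_len(max_regions)) {
    n_par <- 3L * k + 1L
    if (n <= n_par + 2L) {
      message(sprintf("k = %d skipped: %d points for %d parameters", k, n,
                      n_par))
      next
    }
    fits[[k]] <- .fit_logistic_sum(tt, ff, k)
    if (is.null(fits[[k]])) next
    degenerate <- any(abs(fits[[k]]$amplitudes) < 0.02 * rng) ||
      (k > 1L && any(diff(fits[[k]]$centers) < min_separation))
    if (degenerate) next
    aiccs[k] <- .aicc(max(fits[[k]]$rss, rss_floor), n, n_par)
  }
  if (all(is.na(aiccs)))
    stop("logistic segmentation failed to converge for every component count",
         call. = FALSE)
  k_best <- which.min(aiccs)
  best <- fits[[k_best]]
  centers <- best$centers
  comp <- function(tt, i) {
    a <- best$amplitudes[i]
    # locate this component's (m, s) in the parameter vector
    k_idx <- 1L + 3L * (seq_len(k_best) - 1L) + 2L
    m_all <- best$pars[k_idx]
    j <- order(m_all)[i]
    m <- best$pars[1L + 3L * (j - 1L) + 2L]
    s <- best$pars[1L + 3L * (j - 1L) + 3L]
    a / (1 + exp(-(tt - m) / s))
  }
  cuts <- c(min(tt) - 1, (centers[-1] + centers[-length(centers)]) / 2,
            max(tt) + 1)
  regions <- vector("list", k_best)
  for (i in seq_len(k_best)) {
    sel <- tt > cuts[i] & tt <= cuts[i + 1]
    rt <- tt[sel]
    # isolate this transition: subtract baseline and the other components
    others <- rep(best$pars[1L], length(rt))
    for (j in seq_len(k_best)) if (j != i) others <- others + comp(rt, j)
    a_i <- best$amplitudes[i]
    if (abs(a_i) == 0)
      stop(sprintf("region %d has zero fitted amplitude; cannot renormalize",
                   i), call. = FALSE)
    # anchors: extrema of the isolated signal over the full grid (the
    # region-wise y0 and ymax, free of the other transitions)
    others_all <- rep(best$pars[1L], length(tt))
    for (j in seq_len(k_best)) if (j != i) others_all <- others_all +
      comp(tt, j)
    g_all <- ff - others_all
    increasing <- a_i > 0
    lo <- if (increasing) min(g_all) else max(g_all)
    hi <- if (increasing) max(g_all) else min(g_all)
    f_loc_raw <- (ff[sel] - others - lo) / (hi - lo)
    f_loc <- pmin(pmax(f_loc_raw, .F_EPS), 1 - .F_EPS)
    clipped <- f_loc_raw < .F_EPS | f_loc_raw > 1 - .F_EPS
    K <- equilibrium_constant(f_loc)
    regions[[i]] <- structure(
      list(t_lo = min(rt), t_hi = max(rt), region_index = i,
           temperatures = rt, f_local = f_loc, K = K,
           dG = free_energy(K, rt), clipped = clipped,
           center = centers[i], increasing = increasing),
      class = "sigmoidal_region")
  }
  structure(regions, class = "sigmoidal_regions", k = k_best, aicc = aiccs,
            rss = fits[[k_best]]$rss)
}

#' @export
print.sigmoidal_regions <- function(x, ...) {
  cat(sprintf("<sigmoidal_regions> %d region(s) selected by AICc\n",
              attr(x, "k")))
  for (r in x)
    cat(sprintf("  region %d: %.1f-%.1f degC, center %.1f degC\n",
                r$region_index, r$t_lo, r$t_hi, r$center))
  invisible(x)
}

#' Transition thermodynamics from the linear free-energy window
#'
#' Within the transition window `|dG| < dg_window` kJ/mol (default 5), the
#' two-state free energy is linear in temperature; ordinary least squares of
#' `dG` (kJ/mol) on `T` (deg C) gives the melting temperature as the
#' zero-crossing of the fitted line (where the initial and final ensembles
#' are equally populated) and the entropy as minus the slope.
#'
#' Two enthalpy conventions are returned. The primary value uses the
#' Celsius-axis product `dH = Tm_degC * dS / 1000` (kJ/mol), the convention
#' under which reported melt tables are internally consistent
#' (`Tm x dS = dH`); the thermodynamically standard Kelvin product
#' `dH_kelvin = (Tm + 273.15) * dS / 1000` is stored alongside. See the
#' package vignette for the rationale.
#'
#' Points at the fraction clip bound are excluded before windowing, and the
#' window is the *contiguous* run of in-band points around the zero
#' crossing: with instrument noise, baseline fractions occasionally wander
#' into `|dG| < 5` far from the transition, and admitting them flattens the
#' fitted slope.
#'
#' @param region A `sigmoidal_region` from [segment_transitions()], or any
#'   list with `temperatures`, `dG` and optionally `clipped` fields.
#' @param dg_window Half-width of the free-energy window in kJ/mol.
#' @return An object of class `transition_thermo` with fields `tm` (deg C),
#'   `dH` (kJ/mol, Celsius-axis convention), `dH_kelvin` (kJ/mol), `dS`
#'   (J/K/mol), `slope` (kJ/mol/degC), `intercept` (kJ/mol), `r_squared`,
#'   `window` (temperature range used), `n_points` and `cooperative`
#'   (FALSE when the fitted slope is non-negative).
#' @examples
#' tt <- seq(60, 80, 2)
#' reg <- list(temperatures = tt, dG = -(tt - 70))  # slope -1 kJ/mol/degC
#' ft <- fit_transition(reg)
#' c(ft$tm, ft$dS, ft$dH)  # 70, 1000, 70
#' @export
fit_transition <- function(region, dg_window = 5) {
  tt <- region$temperatures
  dg <- region$dG
  keep <- abs(dg) < dg_window
  if (!is.null(region$clipped)) keep <- keep & !region$clipped
  if (any(keep)) {
    # contiguous in-band run around the smallest |dG| (the transition
    # region proper); noise-driven baseline excursions into the band are
    # not part of the transition
    anchor <- which(keep)[which.min(abs(dg[keep]))]
    lo <- anchor
    while (lo > 1L && keep[lo - 1L]) lo <- lo - 1L
    hi <- anchor
    while (hi < length(keep) && keep[hi + 1L]) hi <- hi + 1L
    keep <- rep(FALSE, length(keep))
    keep[lo:hi] <- TRUE
  }
  if (sum(keep) < 3L)
    stop(sprintf("only %d points with |dG| < %.3g kJ/mol; need >= 3",
                 sum(keep), dg_window), call. = FALSE)
  tw <- tt[keep]
  gw <- dg[keep]
  fit <- stats::lm(gw ~ tw)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  if (slope >= 0)
    warning("non-cooperative transition: fitted dG slope is non-negative",
            call. = FALSE)
  tm <- -intercept / slope
  dS <- -slope * 1000                    # J/K/mol
  res <- structure(
    list(tm = tm, dH = tm * dS / 1000, dH_kelvin = (tm + 273.15) * dS / 1000,
         dS = dS, slope = slope, intercept = intercept,
         r_squared = suppressWarnings(summary(fit)$r.squared),
         window = range(tw), n_points = length(tw),
         cooperative = slope < 0),
    class = "transition_thermo")
  res
}

#' @export
print.transition_thermo <- function(x, ...) {
  cat(sprintf("<transition_thermo> Tm %.1f degC, dH %.3g kJ/mol, dS %.3g J/K/mol (n = %d, R2 = %.4f)\n",
              x$tm, x$dH, x$dS, x$n_points, x$r_squared))
  invisible(x)
}

#' Full melt-curve thermodynamic analysis
#'
#' Convenience wrapper chaining [folded_fraction()],
#' [segment_transitions()] and [fit_transition()]: converts a
#' single-wavelength melt trace to fractional beta-sheet content, segments
#' it into sigmoidal transitions, and fits the two-state thermodynamics of
#' each.
#'
#' @inheritParams folded_fraction
#' @inheritParams segment_transitions
#' @inheritParams fit_transition
#' @return A list of class `melt_thermo` with elements `fraction`
#'   (`folded_fraction`), `regions` (`sigmoidal_regions`) and `transitions`
#'   (list of `transition_thermo`, one per region; `NULL` where the window
#'   had too few points).
#' @export
analyze_melt <- function(trace, y0 = NULL, ymax = NULL, max_regions = 3,
                         dg_window = 5) {
  fr <- folded_fraction(trace, y0 = y0, ymax = ymax)
  regs <- segment_transitions(fr, max_regions = max_regions)
  trans <- lapply(regs, function(r)
    tryCatch(fit_transition(r, dg_window = dg_window),
             error = function(e) NULL))
  structure(list(fraction = fr, regions = regs, transitions = trans),
            class = "melt_thermo")
}

#' Tabulate melt thermodynamics
#'
#' Flattens a [analyze_melt()] result into one row per transition with the
#' columns of a conventional melt table: Tm (deg C), dH (kJ/mol), dS
#' (J/K/mol).
#'
#' @param x A `melt_thermo` object.
#' @param ... Unused.
#' @return A data.frame with columns `region`, `tm`, `dH`, `dS`,
#'   `r_squared`, `n_points`.
#' @export
as.data.frame.melt_thermo <- function(x, ...) {
  rows <- lapply(seq_along(x$transitions), function(i) {
    tr <- x$transitions[[i]]
    if (is.null(tr)) return(NULL)
    data.frame(region = i, tm = tr$tm, dH = tr$dH, dS = tr$dS,
               r_squared = tr$r_squared, n_points = tr$n_points)
  })
  do.call(rbind, rows)
}
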