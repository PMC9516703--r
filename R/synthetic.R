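# Run expr with a private, seeded RNG stream, restoring global state after.
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Specification of a synthetic CD melt curve
#'
#' Describes a multi-transition melt with known ground truth. Each
#' transition is a two-state van't Hoff step: the population of the final
#' ensemble is `f_i(T) = 1 / (1 + exp[(dH_i / R) (1/T_K - 1/Tm_i,K)])`,
#' which equals 1/2 at `Tm_i` and sharpens with the van't Hoff enthalpy
#' `dH_i`. The signal is
#' `y(T) = baseline + sum_i sign_i * amplitude_i * f_i(T) + noise`.
#' Opposite-sign amplitudes on successive transitions emulate the observed
#' deepening-then-loss of the beta-sheet band (the band first gains depth,
#' then structure is lost at higher temperature).
#'
#' The defaults emulate the study conditions of an IgG4 melt in a
#' concentrated choline chloride formulation: acquisition from 25 to 97
#' deg C at 2 deg C intervals; a baseline of -3000 deg cm^2 dmol^-1 and a
#' band deepening of 4000 followed by a partial recovery of 3000 (the
#' observed initial MRE and the 3000-4500 absolute MRE change); two
#' cooperative transitions at 69.2 and 82.9 deg C whose van't Hoff
#' enthalpies, 370 and 590 kJ/mol, are the Kelvin products `Tm_K x dS` of
#' the measured transition entropies (1080 and 1650 J/K/mol); noise-free
#' unless requested.
#'
#' @param transitions List of transitions, each a list/vector with fields
#'   `tm` (deg C), `dh_vanthoff` (kJ/mol, > 0), `amplitude` (deg cm^2
#'   dmol^-1) and `sign` (+1 or -1). Must be ordered by increasing `tm`.
#' @param baseline Baseline signal, deg cm^2 dmol^-1.
#' @param temperature_grid Strictly increasing acquisition grid (deg C).
#' @param noise_sigma Homoscedastic Gaussian noise SD, same units as the
#'   signal, >= 0.
#' @param seed Integer RNG seed for the noise stream.
#' @return An object of class `melt_spec`.
#' @export
melt_spec <- function(transitions = list(
                        list(tm = 69.2, dh_vanthoff = 370, amplitude = 4000,
                             sign = -1),
                        list(tm = 82.9, dh_vanthoff = 590, amplitude = 3000,
                             sign = +1)),
                      baseline = -3000,
                      temperature_grid = seq(25, 97, by = 2),
                      noise_sigma = 0, seed = 1L) {
  stopifnot(length(transitions) >= 1L)
  tms <- vapply(transitions, function(x) x$tm, numeric(1))
  dhs <- vapply(transitions, function(x) x$dh_vanthoff, numeric(1))
  if (is.unsorted(tms, strictly = TRUE))
    stop("transitions must be ordered by strictly increasing tm",
         call. = FALSE)
  if (any(dhs <= 0))
    stop("dh_vanthoff must be > 0 for every transition", call. = FALSE)
  if (any(diff(temperature_grid) <= 0))
    stop("temperature_grid must be strictly increasing", call. = FALSE)
  if (noise_sigma < 0) stop("noise_sigma must be >= 0", call. = FALSE)
  structure(list(transitions = transitions, baseline = baseline,
                 temperature_grid = temperature_grid,
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "melt_spec")
}

#' Two-state van't Hoff population of the final ensemble
#'
#' `f(T) = 1 / (1 + exp[(dH / R)(1/T_K - 1/Tm_K)])`: 0 well below the
#' transition, 1/2 at `tm`, 1 well above.
#'
#' @param t_celsius Temperature(s), deg C.
#' @param tm Transition midpoint, deg C.
#' @param dh_vanthoff van't Hoff enthalpy, kJ/mol.
#' @return Population fraction(s) in (0, 1).
#' @export
vanthoff_fraction <- function(t_celsius, tm, dh_vanthoff) {
  tk <- t_celsius + 273.15
  tmk <- tm + 273.15
  1 / (1 + exp(dh_vanthoff * 1000 / .R_GAS * (1 / tk - 1 / tmk)))
}

#' Generate a synthetic CD melt curve with known thermodynamics
#'
#' Evaluates the multi-transition van't Hoff signal described by a
#' [melt_spec()] on its temperature grid, adds seeded Gaussian noise, and
#' returns both a single-wavelength [cd_spectrum_series()] (at 218 nm, in
#' MRE units) and the ground truth for parameter-recovery tests. The same
#' spec and seed always produce bit-identical output.
#'
#' @param spec A `melt_spec`.
#' @param meta A [sample_meta()] to attach (default a generic synthetic
#'   sample).
#' @param wavelength Wavelength label for the single-column grid (nm).
#' @return A list of class `synthetic_melt` with elements `series`
#'   (`cd_spectrum_series`, MRE units), `trace` (`mre_trace`), `clean`
#'   (noise-free signal vector) and `truth` (the spec).
#' @export
generate_melt <- function(spec, meta = sample_meta("synthetic"),
                          wavelength = 218) {
  stopifnot(inherits(spec, "melt_spec"))
  tt <- spec$temperature_grid
  y <- rep(spec$baseline, length(tt))
  for (tr in spec$transitions)
    y <- y + tr$sign * tr$amplitude *
      vanthoff_fraction(tt, tr$tm, tr$dh_vanthoff)
  clean <- y
  if (spec$noise_sigma > 0)
    y <- y + .with_seed(spec$seed,
                        stats::rnorm(length(tt), 0, spec$noise_sigma))
  series <- cd_spectrum_series(tt, wavelength, matrix(y, ncol = 1), meta,
                               units = "deg.cm2.dmol-1")
  structure(list(series = series,
                 trace = extract_trace(series, wavelength),
                 clean = clean, truth = spec),
            class = "synthetic_melt")
}

#' Specification of a toy solvated-bead trajectory
#'
#' Describes a periodic orthorhombic box holding a rigid bead-cluster
#' solute at the box center and point-particle solvent species (cation,
#' anion, water, one bead per molecule) placed independently in every
#' frame: uniformly throughout the box, except that within a spherical
#' shell `[r1, r2]` (measured as minimum distance to any solute bead) each
#' species' acceptance probability is multiplied by its enrichment factor
#' (> 1 enriches the shell, < 1 depletes it, 1 is an ideal uniform
#' solution). This gives a solvation structure with known preferential
#' interaction behaviour while conserving particle counts across frames.
#'
#' @param n_frames Number of frames.
#' @param box Edge lengths (Angstrom), length 3 (or scalar, cubed).
#' @param solute Bead coordinates (n x 3 matrix, Angstrom); default an
#'   8-bead cube of edge 6 A. Recentred on the box center.
#' @param species_counts Named counts for `cation`, `anion`, `water`.
#' @param shell_bias Named enrichment factors (> 0) per species; species
#'   not listed default to 1 (uniform).
#' @param shell Shell `c(r1, r2)` in Angstrom, `r1 < r2 <` half the
#'   smallest box edge.
#' @param seed Integer RNG seed.
#' @return An object of class `trajectory_spec`.
#' @export
trajectory_spec <- function(n_frames = 20,
                            box = c(60, 60, 60),
                            solute = NULL,
                            species_counts = c(cation = 150, anion = 150,
                                               water = 700),
                            shell_bias = c(cation = 1, anion = 1, water = 1),
                            shell = c(4, 9),
                            seed = 1L) {
  if (length(box) == 1L) box <- rep(box, 3L)
  stopifnot(length(box) == 3L, all(box > 0), n_frames >= 1L)
  if (is.null(solute)) {
    e <- 3  # half-edge of the default 6 A bead cube
    solute <- as.matrix(expand.grid(x = c(-e, e), y = c(-e, e),
                                    z = c(-e, e)))
  }
  solute <- as.matrix(solute)
  stopifnot(ncol(solute) == 3L)
  if (any(species_counts < 0))
    stop("species counts must be >= 0", call. = FALSE)
  bias <- c(cation = 1, anion = 1, water = 1)
  bias[names(shell_bias)] <- shell_bias
  if (any(bias <= 0)) stop("enrichment factors must be > 0", call. = FALSE)
  if (!(shell[1] < shell[2] && shell[2] < min(box) / 2))
    stop("shell must satisfy r1 < r2 < half the smallest box edge",
         call. = FALSE)
  structure(list(n_frames = as.integer(n_frames), box = box,
                 solute = solute, species_counts = species_counts,
                 shell_bias = bias, shell = shell, seed = as.integer(seed)),
            class = "trajectory_spec")
}

# Minimum-image distance from each row of x (n x 3) to the nearest solute
# bead. Straightforward per-bead loop; shared by the generator and oracle.
.min_dist_to_solute <- function(x, solute, box) {
  d2 <- rep(Inf, nrow(x))
  for (i in seq_len(nrow(solute))) {
    dx <- sweep(x, 2, solute[i, ])
    dx <- dx - sweep(round(sweep(dx, 2, box, "/")), 2, box, "*")
    d2 <- pmin(d2, rowSums(dx^2))
  }
  sqrt(d2)
}

#' Generate a toy trajectory with known solvation structure
#'
#' Realises a [trajectory_spec()] as a [frame_set()]: solute beads fixed at
#' the box center, solvent beads independently re-placed each frame by
#' rejection sampling against the shell enrichment weights. Identical specs
#' and seeds give bit-identical frames.
#'
#' @param spec A `trajectory_spec`.
#' @return A `frame_set` whose attribute `"truth"` holds the spec.
#' @export
generate_trajectory <- function(spec) {
  stopifnot(inherits(spec, "trajectory_spec"))
  box <- spec$box
  center <- box / 2
  solute <- sweep(spec$solute, 2, colMeans(spec$solute)) +
    matrix(center, nrow(spec$solute), 3, byrow = TRUE)
  counts <- spec$species_counts
  sp_names <- names(counts)
  n_solv <- sum(counts)
  species <- c(rep("solute", nrow(solute)),
               rep(sp_names, times = counts))
  molecule <- c(rep(1L, nrow(solute)), seq_len(n_solv) + 1L)
  frames <- .with_seed(spec$seed, {
    lapply(seq_len(spec$n_frames), function(fr) {
      coords <- matrix(NA_real_, n_solv, 3)
      row <- 1L
      for (sp in sp_names) {
        need <- counts[[sp]]
        w <- spec$shell_bias[[sp]]
        wmax <- max(w, 1)
        got <- 0L
        while (got < need) {
          m <- max(64L, ceiling((need - got) * 1.6))
          cand <- cbind(stats::runif(m, 0, box[1]),
                        stats::runif(m, 0, box[2]),
                        stats::runif(m, 0, box[3]))
          d <- .min_dist_to_solute(cand, solute, box)
          inshell <- d >= spec$shell[1] & d <= spec$shell[2]
          p <- ifelse(inshell, w, 1) / wmax
          keep <- which(stats::runif(m) < p)
          if (length(keep)) {
            take <- keep[seq_len(min(length(keep), need - got))]
            coords[row + got + seq_along(take) - 1L, ] <- cand[take, ,
                                                               drop = FALSE]
            got <- got + length(take)
          }
        }
        row <- row + need
      }
      rbind(solute, coords)
    })
  })
  fs <- frame_set(frames, species = species, molecule = molecule, box = box)
  attr(fs, "truth") <- spec
  fs
}

#' Direct-count preferential interaction oracle
#'
#' Ground-truth preferential interaction coefficient computed per frame by
#' plain direct counting:
#' `G_s = n_s(<=R) - (N_s^bulk / N_w^bulk) * n_w(<=R)`, where `n(<=R)`
#' counts molecules whose minimum distance to the solute is at most `R` and
#' the bulk counts are the molecules beyond `R`. Written as a deliberately
#' simple reference loop, independent of the vectorised
#' [gamma_species()] pipeline it validates.
#'
#' @param frames A `frame_set` containing `solute` and `water` species.
#' @param species Species to count (e.g. `"cation"`).
#' @param cutoff_r Cutoff radius R, Angstrom.
#' @return Numeric vector of per-frame coefficients.
#' @export
gamma_direct_count <- function(frames, species, cutoff_r = 12) {
  stopifnot(inherits(frames, "frame_set"))
  sol_idx <- which(frames$species == "solute")
  out <- numeric(length(frames$frames))
  for (f in seq_along(frames$frames)) {
    xyz <- frames$frames[[f]]
    count <- function(sp) {
      idx <- which(frames$species == sp)
      mols <- unique(frames$molecule[idx])
      inside <- 0L
      for (m in mols) {
        at <- idx[frames$molecule[idx] == m]
        d <- .min_dist_to_solute(xyz[at, , drop = FALSE],
                                 xyz[sol_idx, , drop = FALSE], frames$box)
        if (min(d) <= cutoff_r) inside <- inside + 1L
      }
      c(inside = inside, total = length(mols))
    }
    s <- count(species)
    w <- count("water")
    s_bulk <- s[["total"]] - s[["inside"]]
    w_bulk <- w[["total"]] - w[["inside"]]
    if (w_bulk == 0L)
      stop("no water beyond the cutoff; box too small for this R",
           call. = FALSE)
    out[f] <- s[["inside"]] - (s_bulk / w_bulk) * w[["inside"]]
  }
  out
}
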