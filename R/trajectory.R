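#' Multi-frame coordinate container
#'
#' Holds a set of frames (one coordinate matrix per frame, Angstrom) over a
#' fixed atom roster with per-atom species labels (`solute`, `cation`,
#' `anion`, `water`, or other) and molecule ids, a periodic orthorhombic
#' box, and optional named atom-index selections (e.g. `Fab1`, `Fab2`,
#' `Fc`).
#'
#' @param frames List of `n_atoms x 3` numeric matrices, identical
#'   dimensions in every frame.
#' @param species Character vector, one label per atom.
#' @param molecule Integer vector, one molecule id per atom.
#' @param box Periodic edge lengths (Angstrom), length 3 (or scalar,
#'   cubed), all > 0.
#' @param selections Named list of atom index vectors.
#' @return An object of class `frame_set`.
#' @export
frame_set <- function(frames, species, molecule, box,
                      selections = list()) {
  stopifnot(is.list(frames), length(frames) >= 1L)
  if (length(box) == 1L) box <- rep(box, 3L)
  if (length(box) != 3L || any(box <= 0))
    stop("box must be 3 positive edge lengths", call. = FALSE)
  n <- nrow(frames[[1]])
  ok <- vapply(frames, function(f) is.matrix(f) && nrow(f) == n &&
                 ncol(f) == 3L, logical(1))
  if (!all(ok))
    stop("all frames must be n_atoms x 3 matrices with a consistent atom count",
         call. = FALSE)
  if (length(species) != n || length(molecule) != n)
    stop("species and molecule labels must have one entry per atom",
         call. = FALSE)
  for (nm in names(selections))
    if (any(selections[[nm]] < 1L | selections[[nm]] > n))
      stop(sprintf("selection '%s' indexes outside 1..%d", nm, n),
           call. = FALSE)
  frames <- lapply(frames, function(f) {
    dimnames(f) <- NULL
    f
  })
  structure(list(frames = frames, species = as.character(species),
                 molecule = as.integer(molecule), box = as.numeric(box),
                 selections = selections),
            class = "frame_set")
}

#' @export
print.frame_set <- function(x, ...) {
  tab <- table(x$species)
  cat(sprintf("<frame_set> %d frames, %d atoms, box %.4g x %.4g x %.4g A\n",
              length(x$frames), length(x$species), x$box[1], x$box[2],
              x$box[3]))
  cat("  species:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
  invisible(x)
}

# Periodic minimum-image displacement of points x (n x 3) from point p.
.mic <- function(x, p, box) {
  dx <- sweep(x, 2, p)
  dx - sweep(round(sweep(dx, 2, box, "/")), 2, box, "*")
}

#' Per-molecule minimum distances to the solute
#'
#' For every molecule of a species in one frame, the minimum over all
#' (molecule atom, solute atom) pairs of the periodic minimum-image
#' distance. This any-atom molecular distance is the counting unit of the
#' minimum-distance distribution function and of the preferential
#' interaction coefficient.
#'
#' @param frames A `frame_set`.
#' @param frame Frame index.
#' @param species Species label to measure (must be present).
#' @param solute_species Label of the solute atoms (default `"solute"`).
#' @return Named numeric vector of distances (Angstrom), one per molecule,
#'   named by molecule id.
#' @export
min_distances <- function(frames, frame = 1L, species,
                          solute_species = "solute") {
  stopifnot(inherits(frames, "frame_set"))
  sol <- which(frames$species == solute_species)
  idx <- which(frames$species == species)
  if (length(sol) == 0L)
    stop("no solute atoms in the frame set", call. = FALSE)
  if (length(idx) == 0L)
    stop(sprintf("species '%s' not present", species), call. = FALSE)
  xyz <- frames$frames[[frame]]
  x <- xyz[idx, , drop = FALSE]
  d2 <- rep(Inf, length(idx))
  for (i in sol) {
    dx <- .mic(x, xyz[i, ], frames$box)
    d2 <- pmin(d2, rowSums(dx * dx))
  }
  d <- sqrt(d2)
  mol <- frames$molecule[idx]
  out <- tapply(d, mol, min)
  stats::setNames(as.numeric(out), names(out))
}

#' Minimum-distance distribution function
#'
#' Histograms the per-molecule minimum distances of a species to the solute
#' over all frames and normalises each distance shell by the count expected
#' from uniform placement at the species' bulk density. Shell volumes in
#' minimum-distance space (which follow the solute's shape, not simple
#' spheres) are estimated by a fixed-seed Monte Carlo volume integration;
#' the bulk density is taken from the outer 25 % of `r_max`. A
#' `normalized_density` of 1 is ideal-solution behaviour; a short-range
#' peak above 1 indicates accumulation at the protein surface.
#'
#' @param frames A `frame_set`.
#' @param species Species label.
#' @param bin_width Histogram bin width (Angstrom).
#' @param r_max Histogram range (Angstrom); must not exceed half the
#'   smallest box edge.
#' @param mc_points Monte Carlo sample size for shell volumes.
#' @return An object of class `mddf_result` with fields `bin_edges`,
#'   `bin_mid`, `counts` (summed over frames), `normalized_density`,
#'   `bulk_density` (molecules / A^3), `n_frames`, `n_molecules`,
#'   `species`, `empty` (TRUE when the species has no molecules; densities
#'   are then `NA`).
#' @export
mddf <- function(frames, species, bin_width = 0.2, r_max = 20,
                 mc_points = 2e5) {
  stopifnot(inherits(frames, "frame_set"))
  if (r_max > min(frames$box) / 2)
    stop("r_max exceeds half the smallest box edge", call. = FALSE)
  edges <- seq(0, r_max, by = bin_width)
  if (edges[length(edges)] < r_max) edges <- c(edges, r_max)
  nb <- length(edges) - 1L
  n_frames <- length(frames$frames)
  idx <- which(frames$species == species)
  if (length(idx) == 0L) {
    return(structure(list(bin_edges = edges,
                          bin_mid = (edges[-1] + edges[-length(edges)]) / 2,
                          counts = rep(0, nb),
                          normalized_density = rep(NA_real_, nb),
                          bulk_density = NA_real_, n_frames = n_frames,
                          n_molecules = 0L, species = species,
                          empty = TRUE),
                     class = "mddf_result"))
  }
  counts <- rep(0, nb)
  n_outer <- 0
  for (f in seq_len(n_frames)) {
    d <- min_distances(frames, f, species)
    counts <- counts + tabulate(findInterval(d, edges, left.open = TRUE,
                                             rightmost.closed = TRUE),
                                nbins = nb)
    n_outer <- n_outer + sum(d >= 0.75 * r_max & d <= r_max)
  }
  # Monte Carlo estimate of shell volumes in min-distance space (fixed
  # internal seed: mddf stays deterministic and leaves the global RNG
  # untouched).
  sol <- which(frames$species == "solute")
  xyz <- frames$frames[[1]]
  vols <- .with_seed(20201L, {
    m <- as.integer(mc_points)
    pts <- cbind(stats::runif(m, 0, frames$box[1]),
                 stats::runif(m, 0, frames$box[2]),
                 stats::runif(m, 0, frames$box[3]))
    d2 <- rep(Inf, m)
    for (i in sol) {
      dx <- .mic(pts, xyz[i, ], frames$box)
      d2 <- pmin(d2, rowSums(dx * dx))
    }
    dmc <- sqrt(d2)
    vbox <- prod(frames$box)
    shell_counts <- tabulate(findInterval(dmc, edges, left.open = TRUE,
                                          rightmost.closed = TRUE),
                             nbins = nb)
    list(shell = shell_counts / m * vbox,
         outer = sum(dmc >= 0.75 * r_max & dmc <= r_max) / m * vbox)
  })
  bulk_density <- (n_outer / n_frames) / vols$outer
  expected <- bulk_density * vols$shell * n_frames
  nd <- ifelse(expected > 0, counts / expected, NA_real_)
  structure(list(bin_edges = edges,
                 bin_mid = (edges[-1] + edges[-length(edges)]) / 2,
                 counts = counts, normalized_density = nd,
                 bulk_density = bulk_density, n_frames = n_frames,
                 n_molecules = length(unique(frames$molecule[idx])),
                 species = species, empty = FALSE),
            class = "mddf_result")
}

#' @export
print.mddf_result <- function(x, ...) {
  cat(sprintf("<mddf_result> %s: %d molecules x %d frames, %d bins to %.4g A\n",
              x$species, x$n_molecules, x$n_frames, length(x$counts),
              max(x$bin_edges)))
  if (x$empty) cat("  (no molecules of this species; densities undefined)\n")
  invisible(x)
}

#' Preferential interaction coefficient of one species
#'
#' For each frame, `G_s = n_s(<=R) - (N_s^bulk / N_w^bulk) * n_w(<=R)`:
#' the excess count of species molecules within cutoff `R` of the solute
#' over the count expected from the bulk species-to-water ratio (molecules
#' beyond `R`). Positive values indicate preferential accumulation at the
#' protein surface, negative values preferential exclusion. The standard
#' error is estimated by block averaging over contiguous frame blocks.
#'
#' @param frames A `frame_set` containing water as the reference species.
#' @param species Species label (e.g. `"cation"`).
#' @param cutoff_r Cutoff radius R (Angstrom), default 12.
#' @param n_blocks Number of blocks for the SE estimate (default 5).
#' @return An object of class `preferential_interaction` with fields
#'   `gamma` (frame average), `se`, `per_frame`, `cutoff_r`, `species`,
#'   `n_frames`.
#' @export
gamma_species <- function(frames, species, cutoff_r = 12, n_blocks = 5) {
  stopifnot(inherits(frames, "frame_set"))
  if (!any(frames$species == "water"))
    stop("water must be present as the reference species", call. = FALSE)
  n_frames <- length(frames$frames)
  per_frame <- numeric(n_frames)
  for (f in seq_len(n_frames)) {
    ds <- min_distances(frames, f, species)
    dw <- min_distances(frames, f, "water")
    s_in <- sum(ds <= cutoff_r)
    w_in <- sum(dw <= cutoff_r)
    s_bulk <- length(ds) - s_in
    w_bulk <- length(dw) - w_in
    if (w_bulk == 0L)
      stop("no water molecules beyond the cutoff; box too small for this R",
           call. = FALSE)
    per_frame[f] <- s_in - (s_bulk / w_bulk) * w_in
  }
  nb <- max(1L, min(n_blocks, n_frames))
  blocks <- split(per_frame, cut(seq_len(n_frames), nb, labels = FALSE))
  bm <- vapply(blocks, mean, numeric(1))
  se <- if (length(bm) > 1L) stats::sd(bm) / sqrt(length(bm)) else NA_real_
  structure(list(gamma = mean(per_frame), se = se, per_frame = per_frame,
                 cutoff_r = cutoff_r, species = species,
                 n_frames = n_frames),
            class = "preferential_interaction")
}

#' @export
print.preferential_interaction <- function(x, ...) {
  cat(sprintf("<preferential_interaction> %s: Gamma = %.3f +/- %.3f (R = %.3g A, %d frames)\n",
              x$species, x$gamma, x$se, x$cutoff_r, x$n_frames))
  invisible(x)
}

#' Combine cation and anion coefficients (indistinguishable-ion approach)
#'
#' For an ionic co-solute the cation and anion coefficients are computed
#' separately and then combined into a single co-solute coefficient. The
#' default form is `Gamma_23 = (Gamma_plus + Gamma_minus) / 2 - Z2 / 2`,
#' where `Z2` is the protein net charge in elementary units; the plain sum
#' and plain mean are selectable alternatives (the charge-corrected mean is
#' a documented convention choice, see the vignette). All forms are
#' symmetric in the two ions.
#'
#' @param gamma_plus,gamma_minus Cation and anion coefficients (numbers or
#'   `preferential_interaction` objects).
#' @param z2 Protein net charge, elementary charge units.
#' @param form `"mean_charge"` (default), `"mean"` or `"sum"`.
#' @return The combined coefficient (numeric scalar).
#' @examples
#' combine_ion_gammas(20, 4, z2 = 22)  # 1
#' @export
combine_ion_gammas <- function(gamma_plus, gamma_minus, z2 = 0,
                               form = c("mean_charge", "mean", "sum")) {
  form <- match.arg(form)
  gp <- if (inherits(gamma_plus, "preferential_interaction"))
    gamma_plus$gamma else gamma_plus
  gm <- if (inherits(gamma_minus, "preferential_interaction"))
    gamma_minus$gamma else gamma_minus
  if (!is.finite(gp) || !is.finite(gm) || !is.finite(z2))
    stop("inputs must be finite", call. = FALSE)
  switch(form,
         mean_charge = (gp + gm) / 2 - z2 / 2,
         mean = (gp + gm) / 2,
         sum = gp + gm)
}

# Kabsch rotation aligning centred mobile X onto centred reference Y:
# returns R with X %*% R ~= Y in the least-squares sense.
.kabsch <- function(X, Y) {
  C <- crossprod(X, Y)
  sv <- svd(C)
  d <- sign(det(sv$u %*% t(sv$v)))
  sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
}

#' Superposition RMSD over frames
#'
#' Optimal rigid-body superposition (least-squares rotation plus
#' translation, Kabsch algorithm) of each frame's selection onto the
#' reference frame before computing the root-mean-square deviation, so the
#' result measures internal deformation only and is invariant under any
#' proper rigid transform of a frame.
#'
#' @param frames A `frame_set`.
#' @param selection Atom indices (or the name of a stored selection); >= 3
#'   atoms.
#' @param reference_frame Reference frame index (default 1).
#' @return Numeric vector of per-frame RMSD values (Angstrom).
#' @export
superpose_rmsd <- function(frames, selection = NULL, reference_frame = 1L) {
  sel <- .resolve_selection(frames, selection)
  if (length(sel) < 3L)
    stop("superposition needs at least 3 atoms", call. = FALSE)
  ref <- frames$frames[[reference_frame]][sel, , drop = FALSE]
  refc <- sweep(ref, 2, colMeans(ref))
  vapply(frames$frames, function(xyz) {
    mob <- xyz[sel, , drop = FALSE]
    mobc <- sweep(mob, 2, colMeans(mob))
    fit <- mobc %*% .kabsch(mobc, refc)
    sqrt(mean(rowSums((fit - refc)^2)))
  }, numeric(1))
}

#' Per-atom RMSF after superposition
#'
#' Root-mean-square fluctuation of each selected atom about its mean
#' position, after superposing every frame onto the reference frame.
#'
#' @inheritParams superpose_rmsd
#' @return Numeric vector, one RMSF (Angstrom) per selected atom.
#' @export
rmsf <- function(frames, selection = NULL, reference_frame = 1L) {
  sel <- .resolve_selection(frames, selection)
  if (length(sel) < 3L)
    stop("superposition needs at least 3 atoms", call. = FALSE)
  if (length(frames$frames) < 2L)
    stop("RMSF needs at least 2 frames", call. = FALSE)
  ref <- frames$frames[[reference_frame]][sel, , drop = FALSE]
  refc <- sweep(ref, 2, colMeans(ref))
  fitted <- lapply(frames$frames, function(xyz) {
    mob <- xyz[sel, , drop = FALSE]
    mobc <- sweep(mob, 2, colMeans(mob))
    mobc %*% .kabsch(mobc, refc)
  })
  arr <- simplify2array(fitted)           # atoms x 3 x frames
  mean_xyz <- apply(arr, c(1, 2), mean)
  dev2 <- apply(arr, 3, function(m) rowSums((m - mean_xyz)^2))
  sqrt(rowMeans(as.matrix(dev2)))
}

.resolve_selection <- function(frames, selection) {
  stopifnot(inherits(frames, "frame_set"))
  if (is.null(selection))
    return(seq_along(frames$species))
  if (is.character(selection)) {
    if (!selection %in% names(frames$selections))
      stop(sprintf("no selection named '%s'", selection), call. = FALSE)
    return(frames$selections[[selection]])
  }
  as.integer(selection)
}

#' Antibody domain distances and Y/lambda conformer call
#'
#' Computes per-frame center-of-mass distances between the two Fab arms and
#' the Fc stem (selections `Fab1`, `Fab2`, `Fc`, equal atom masses) and
#' classifies the global conformation: a frame is lambda-like when the
#' closer Fab sits within `alpha` times the Fab-Fab distance of the Fc
#' (`min(d_Fab1-Fc, d_Fab2-Fc) < alpha * d_Fab1-Fab2`, i.e. a collapsed
#' Fab-Fc interface); the trajectory is called `lambda` when at least
#' `lambda_frac` of frames are lambda-like, `Y` when at most `y_frac` are,
#' and `ambiguous` in between.
#'
#' @param frames A `frame_set` with `Fab1`, `Fab2` and `Fc` selections.
#' @param alpha Fab-Fc proximity ratio threshold (default 0.75).
#' @param lambda_frac,y_frac Frame-fraction thresholds (defaults 0.6 and
#'   0.4).
#' @return An object of class `conformer_call` with fields `fab1_fab2`,
#'   `fab1_fc`, `fab2_fc` (mean distances, Angstrom), `per_frame_labels`,
#'   `lambda_fraction` and `label`.
#' @export
domain_distances <- function(frames, alpha = 0.75, lambda_frac = 0.6,
                             y_frac = 0.4) {
  stopifnot(inherits(frames, "frame_set"))
  need <- c("Fab1", "Fab2", "Fc")
  miss <- setdiff(need, names(frames$selections))
  if (length(miss))
    stop(sprintf("missing selection(s): %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  com <- function(xyz, sel) colMeans(xyz[sel, , drop = FALSE])
  n <- length(frames$frames)
  d12 <- d1c <- d2c <- numeric(n)
  for (f in seq_len(n)) {
    xyz <- frames$frames[[f]]
    c1 <- com(xyz, frames$selections$Fab1)
    c2 <- com(xyz, frames$selections$Fab2)
    cc <- com(xyz, frames$selections$Fc)
    d12[f] <- sqrt(sum((c1 - c2)^2))
    d1c[f] <- sqrt(sum((c1 - cc)^2))
    d2c[f] <- sqrt(sum((c2 - cc)^2))
  }
  lam <- pmin(d1c, d2c) < alpha * d12
  frac <- mean(lam)
  label <- if (frac >= lambda_frac) "lambda" else if (frac <= y_frac) "Y"
    else "ambiguous"
  structure(list(fab1_fab2 = mean(d12), fab1_fc = mean(d1c),
                 fab2_fc = mean(d2c),
                 per_frame_labels = ifelse(lam, "lambda", "Y"),
                 lambda_fraction = frac, label = label),
            class = "conformer_call")
}

#' @export
print.conformer_call <- function(x, ...) {
  cat(sprintf("<conformer_call> %s (%.0f%% lambda-like frames); Fab-Fab %.2f A, Fab-Fc %.2f / %.2f A\n",
              x$label, 100 * x$lambda_fraction, x$fab1_fab2, x$fab1_fc,
              x$fab2_fc))
  invisible(x)
}
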