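#' Sample metadata for a CD melt experiment
#'
#' Bundles the formulation and instrument parameters needed to convert raw
#' ellipticity (mdeg) into mean residue ellipticity (MRE) and to interpret a
#' melt series: protein concentration, cuvette path length, mean residue
#' weight, the co-solute content of the solvent, and whether the sample was
#' measured fresh or after storage. Optional fields carry orthogonal
#' characterisation values (pH, ionic strength, zeta potential, hydrodynamic
#' diameter) that are consumed as annotations only.
#'
#' @param sample_id Character label for the sample.
#' @param solvent_label Description of the solvent, e.g. `"water"` or
#'   `"10 wt% [Cho]Cl"`.
#' @param cosolute_wt_percent Co-solute mass fraction in percent, in
#'   `[0, 100]`.
#' @param protein_conc Protein concentration in mg/mL, strictly positive.
#' @param path_length Cuvette path length in cm, strictly positive.
#' @param mean_residue_weight Mean residue weight in g/mol, strictly
#'   positive (protein molar mass divided by the number of residues).
#' @param storage_state Either `"fresh"` or `"stored"`.
#' @param ph Optional pH.
#' @param ionic_strength Optional ionic strength in mol/L.
#' @param zeta_potential Optional zeta potential in mV.
#' @param hydrodynamic_diameter Optional hydrodynamic diameter in nm.
#'
#' @return An object of class `sample_meta`.
#' @examples
#' meta <- sample_meta("igg4_water", "water", 0,
#'                     protein_conc = 0.4, path_length = 0.1,
#'                     mean_residue_weight = 110)
#' @export
sample_meta <- function(sample_id, solvent_label = "water",
                        cosolute_wt_percent = 0,
                        protein_conc = 0.4, path_length = 0.1,
                        mean_residue_weight = 110,
                        storage_state = c("fresh", "stored"),
                        ph = NULL, ionic_strength = NULL,
                        zeta_potential = NULL,
                        hydrodynamic_diameter = NULL) {
  storage_state <- match.arg(storage_state)
  stopifnot(is.character(sample_id), length(sample_id) == 1L)
  if (!is.numeric(protein_conc) || protein_conc <= 0)
    stop("protein_conc must be > 0 (mg/mL)", call. = FALSE)
  if (!is.numeric(path_length) || path_length <= 0)
    stop("path_length must be > 0 (cm)", call. = FALSE)
  if (!is.numeric(mean_residue_weight) || mean_residue_weight <= 0)
    stop("mean_residue_weight must be > 0 (g/mol)", call. = FALSE)
  if (!is.numeric(cosolute_wt_percent) ||
      cosolute_wt_percent < 0 || cosolute_wt_percent > 100)
    stop("cosolute_wt_percent must lie in [0, 100]", call. = FALSE)
  structure(
    list(sample_id = sample_id, solvent_label = solvent_label,
         cosolute_wt_percent = cosolute_wt_percent,
         protein_conc = protein_conc, path_length = path_length,
         mean_residue_weight = mean_residue_weight,
         storage_state = storage_state, ph = ph,
         ionic_strength = ionic_strength,
         zeta_potential = zeta_potential,
         hydrodynamic_diameter = hydrodynamic_diameter),
    class = "sample_meta")
}

#' @export
print.sample_meta <- function(x, ...) {
  cat(sprintf("<sample_meta> %s (%s, %s)\n", x$sample_id, x$solvent_label,
              x$storage_state))
  cat(sprintf("  conc %.3g mg/mL, path %.3g cm, MRW %.4g g/mol, cosolute %.3g wt%%\n",
              x$protein_conc, x$path_length, x$mean_residue_weight,
              x$cosolute_wt_percent))
  invisible(x)
}

#' Construct a CD melt series
#'
#' A `cd_spectrum_series` holds a complete temperature-by-wavelength grid of
#' CD signal (raw ellipticity in mdeg, or MRE in deg cm^2 dmol^-1 after
#' [compute_mre()]), with the sample metadata attached. Gaps in the grid are
#' rejected: every (temperature, wavelength) cell must be present.
#'
#' @param temperatures Strictly increasing vector of temperatures (deg C),
#'   each within `[0, 110]`.
#' @param wavelengths Strictly increasing vector of wavelengths (nm), each
#'   within `[150, 350]`.
#' @param ellipticity Numeric matrix, `length(temperatures)` rows by
#'   `length(wavelengths)` columns, no missing cells.
#' @param meta A [sample_meta()] object.
#' @param units Signal units; `"mdeg"` for raw ellipticity or
#'   `"deg.cm2.dmol-1"` after MRE conversion.
#'
#' @return An object of class `cd_spectrum_series`.
#' @export
cd_spectrum_series <- function(temperatures, wavelengths, ellipticity, meta,
                               units = c("mdeg", "deg.cm2.dmol-1")) {
  units <- match.arg(units)
  temperatures <- as.numeric(temperatures)
  wavelengths <- as.numeric(wavelengths)
  ellipticity <- as.matrix(ellipticity)
  if (!inherits(meta, "sample_meta"))
    stop("meta must be a sample_meta object", call. = FALSE)
  if (any(diff(temperatures) <= 0))
    stop("temperatures must be strictly increasing", call. = FALSE)
  if (any(diff(wavelengths) <= 0))
    stop("wavelengths must be strictly increasing", call. = FALSE)
  if (any(temperatures < 0 | temperatures > 110))
    stop("temperatures must lie within [0, 110] degC", call. = FALSE)
  if (any(wavelengths < 150 | wavelengths > 350))
    stop("wavelengths must lie within [150, 350] nm", call. = FALSE)
  if (nrow(ellipticity) != length(temperatures) ||
      ncol(ellipticity) != length(wavelengths))
    stop("ellipticity matrix dimensions do not match the axis vectors",
         call. = FALSE)
  if (anyNA(ellipticity))
    stop("grid has missing cells; every (temperature, wavelength) pair is required",
         call. = FALSE)
  dimnames(ellipticity) <- list(NULL, NULL)
  structure(list(temperatures = temperatures, wavelengths = wavelengths,
                 ellipticity = ellipticity, meta = meta, units = units),
            class = "cd_spectrum_series")
}

#' @export
print.cd_spectrum_series <- function(x, ...) {
  cat(sprintf("<cd_spectrum_series> %s: %d temperatures (%.4g-%.4g degC) x %d wavelengths (%.4g-%.4g nm), units %s\n",
              x$meta$sample_id, length(x$temperatures), min(x$temperatures),
              max(x$temperatures), length(x$wavelengths), min(x$wavelengths),
              max(x$wavelengths), x$units))
  invisible(x)
}

# Sniff comma vs tab from the header line; dot decimal separator only.
.sniff_sep <- function(path) {
  header <- readLines(path, n = 1L)
  if (length(header) == 0L)
    stop(sprintf("'%s': empty file (offending line 1)", path), call. = FALSE)
  if (grepl("\t", header)) "\t" else ","
}

#' Read a delimited CD melt table
#'
#' Reads a CSV/TSV melt table in either of two layouts and returns a
#' validated [cd_spectrum_series()]. In the *wide* layout the first column is
#' temperature and every other column is one wavelength (numeric column
#' headers). In the *long* layout three columns named `temperature`,
#' `wavelength` and `ellipticity` (any order, case-insensitive) give one cell
#' per row. Layout is auto-detected from the header unless forced. Rows are
#' sorted by temperature and columns by wavelength; duplicate cells and gaps
#' in the grid are errors.
#'
#' @param path Path to the delimited table. Separator (comma or tab) is
#'   sniffed from the header; a header row is mandatory.
#' @param meta A [sample_meta()] to attach.
#' @param layout `"auto"` (default), `"wide"` or `"long"`.
#' @param units Units of the stored signal (default raw mdeg).
#'
#' @return A `cd_spectrum_series`.
#' @seealso [write_cd_table()] for the inverse.
#' @export
read_cd_table <- function(path, meta, layout = c("auto", "wide", "long"),
                          units = c("mdeg", "deg.cm2.dmol-1")) {
  layout <- match.arg(layout)
  units <- match.arg(units)
  sep <- .sniff_sep(path)
  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                      stringsAsFactors = FALSE),
    error = function(e)
      stop(sprintf("'%s': unparseable table (%s)", path, conditionMessage(e)),
           call. = FALSE))
  if (ncol(df) < 2L)
    stop(sprintf("'%s': need at least two columns (offending line 1)", path),
         call. = FALSE)
  nm <- tolower(names(df))
  long_names <- c("temperature", "wavelength", "ellipticity")
  is_long <- all(long_names %in% nm)
  if (layout == "auto")
    layout <- if (is_long) "long" else "wide"
  if (layout == "long" && !is_long)
    stop(sprintf("'%s': long layout requires columns temperature, wavelength, ellipticity",
                 path), call. = FALSE)

  if (layout == "long") {
    tt <- as.numeric(df[[which(nm == "temperature")[1]]])
    ww <- as.numeric(df[[which(nm == "wavelength")[1]]])
    yy <- as.numeric(df[[which(nm == "ellipticity")[1]]])
    bad <- which(!is.finite(tt) | !is.finite(ww))[1]
    if (!is.na(bad))
      stop(sprintf("'%s': non-numeric temperature/wavelength (offending line %d)",
                   path, bad + 1L), call. = FALSE)
    if (anyDuplicated(cbind(tt, ww)))
      stop(sprintf("'%s': duplicate (temperature, wavelength) cells", path),
           call. = FALSE)
    temps <- sort(unique(tt))
    waves <- sort(unique(ww))
    mat <- matrix(NA_real_, length(temps), length(waves))
    mat[cbind(match(tt, temps), match(ww, waves))] <- yy
    if (anyNA(mat))
      stop(sprintf("'%s': grid has missing cells (not a complete temperature x wavelength grid)",
                   path), call. = FALSE)
  } else {
    waves_raw <- names(df)[-1]
    waves_num <- suppressWarnings(as.numeric(waves_raw))
    if (anyNA(waves_num))
      stop(sprintf("'%s': wide layout requires numeric wavelength headers; first offending header '%s' (offending line 1)",
                   path, waves_raw[which(is.na(waves_num))[1]]), call. = FALSE)
    tt <- suppressWarnings(as.numeric(df[[1]]))
    bad <- which(!is.finite(tt))[1]
    if (!is.na(bad))
      stop(sprintf("'%s': non-numeric temperature (offending line %d)", path,
                   bad + 1L), call. = FALSE)
    if (anyDuplicated(tt))
      stop(sprintf("'%s': duplicate temperature rows", path), call. = FALSE)
    if (anyDuplicated(waves_num))
      stop(sprintf("'%s': duplicate wavelength columns", path), call. = FALSE)
    ot <- order(tt)
    ow <- order(waves_num)
    mat <- as.matrix(df[ot, -1, drop = FALSE])[, ow, drop = FALSE]
    storage.mode(mat) <- "double"
    if (anyNA(mat))
      stop(sprintf("'%s': grid has missing cells", path), call. = FALSE)
    temps <- tt[ot]
    waves <- waves_num[ow]
  }
  cd_spectrum_series(temps, waves, mat, meta, units = units)
}

#' Write a CD melt series as a wide CSV
#'
#' Writes the grid in the wide layout accepted by [read_cd_table()]
#' (temperature column followed by one column per wavelength). Values are
#' written with full double precision so a read round-trip reproduces the
#' series.
#'
#' @param series A `cd_spectrum_series`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cd_table <- function(series, path) {
  stopifnot(inherits(series, "cd_spectrum_series"))
  df <- data.frame(temperature = series$temperatures,
                   series$ellipticity, check.names = FALSE)
  names(df) <- c("temperature", format(series$wavelengths, trim = TRUE,
                                       digits = 15))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Convert raw ellipticity to mean residue ellipticity
#'
#' Applies the standard conversion
#' `MRE = theta_mdeg * MRW / (10 * l_cm * c_mg_per_mL)` cell-wise, where
#' `MRW` is the mean residue weight (g/mol), `l` the path length (cm) and
#' `c` the protein concentration (mg/mL). The result carries units
#' deg cm^2 dmol^-1 and is linear in the input signal.
#'
#' @param series A `cd_spectrum_series` in mdeg.
#' @return A `cd_spectrum_series` with `units = "deg.cm2.dmol-1"`.
#' @examples
#' meta <- sample_meta("ex", protein_conc = 0.4, path_length = 0.1,
#'                     mean_residue_weight = 110)
#' s <- cd_spectrum_series(c(25, 27), c(216, 218),
#'                         matrix(-10, 2, 2), meta)
#' compute_mre(s)$ellipticity[1, 1]  # -2750
#' @export
compute_mre <- function(series) {
  stopifnot(inherits(series, "cd_spectrum_series"))
  m <- series$meta
  if (m$protein_conc <= 0 || m$path_length <= 0 || m$mean_residue_weight <= 0)
    stop("protein_conc, path_length and mean_residue_weight must all be > 0",
         call. = FALSE)
  if (identical(series$units, "deg.cm2.dmol-1"))
    stop("series is already in MRE units", call. = FALSE)
  scale <- m$mean_residue_weight / (10 * m$path_length * m$protein_conc)
  cd_spectrum_series(series$temperatures, series$wavelengths,
                     series$ellipticity * scale, m,
                     units = "deg.cm2.dmol-1")
}

#' Extract a single-wavelength melt trace
#'
#' Pulls the column at the grid wavelength nearest the request (exact match
#' preferred; ties at equal distance break toward the lower wavelength). The
#' beta-sheet band near 218 nm is the conventional choice for IgG melts.
#'
#' @param series A `cd_spectrum_series` (raw or MRE units).
#' @param wavelength Requested wavelength in nm; must lie within the grid
#'   range.
#' @return An object of class `mre_trace` with fields `temperatures`, `mre`,
#'   `wavelength` (the grid wavelength actually used), `requested_wavelength`
#'   and `meta`.
#' @export
extract_trace <- function(series, wavelength = 218) {
  stopifnot(inherits(series, "cd_spectrum_series"))
  w <- series$wavelengths
  if (wavelength < min(w) || wavelength > max(w))
    stop(sprintf("wavelength %.4g nm outside grid range [%.4g, %.4g]",
                 wavelength, min(w), max(w)), call. = FALSE)
  d <- abs(w - wavelength)
  # ties break toward the lower wavelength: which.min takes the first minimum
  j <- which.min(d)
  if (d[j] > 0)
    message(sprintf("no exact %.4g nm column; using nearest grid wavelength %.4g nm",
                    wavelength, w[j]))
  structure(list(temperatures = series$temperatures,
                 mre = series$ellipticity[, j],
                 wavelength = w[j], requested_wavelength = wavelength,
                 units = series$units, meta = series$meta),
            class = "mre_trace")
}

#' @export
print.mre_trace <- function(x, ...) {
  cat(sprintf("<mre_trace> %s at %.4g nm: %d points, %.4g-%.4g degC\n",
              x$meta$sample_id, x$wavelength, length(x$temperatures),
              min(x$temperatures), max(x$temperatures)))
  invisible(x)
}

#' Molarity of a co-solute from its weight percent
#'
#' For a solution of density `density` g/mL containing `wt_percent` percent
#' co-solute by mass, the molar concentration is
#' `c = 10 * wt_percent * density / molar_mass` mol/L. For a fully
#' dissociated 1:1 electrolyte (such as choline chloride) the nominal ionic
#' strength equals this molarity. The default density of 1.00 g/mL is an
#' idealisation; pass the measured solution density when available.
#'
#' @param wt_percent Co-solute mass percent, `0 <= wt_percent < 100`.
#' @param molar_mass Co-solute molar mass in g/mol (choline chloride:
#'   139.62).
#' @param density Solution density in g/mL, default 1.00.
#' @return Molarity in mol/L.
#' @examples
#' ionic_strength_from_wt(30, 139.62)  # 2.15 M
#' ionic_strength_from_wt(50, 139.62)  # 3.58 M
#' @export
ionic_strength_from_wt <- function(wt_percent, molar_mass, density = 1.00) {
  if (any(wt_percent < 0) || any(wt_percent >= 100))
    stop("wt_percent must satisfy 0 <= wt_percent < 100", call. = FALSE)
  if (molar_mass <= 0) stop("molar_mass must be > 0", call. = FALSE)
  if (density <= 0) stop("density must be > 0", call. = FALSE)
  10 * wt_percent * density / molar_mass
}
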