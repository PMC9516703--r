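# Shared fixtures, built in code at test time.

toy_meta <- function(...) {
  sample_meta("toy", "water", 0, protein_conc = 0.4, path_length = 0.1,
              mean_residue_weight = 110, ...)
}

# 3 temperatures x 4 wavelengths toy grid with distinct cell values
toy_grid <- function() {
  list(temperatures = c(25, 27, 29),
       wavelengths = c(216, 218, 220, 222),
       ellipticity = matrix(seq(-12, -1), nrow = 3, byrow = TRUE))
}

toy_series <- function() {
  g <- toy_grid()
  cd_spectrum_series(g$temperatures, g$wavelengths, g$ellipticity,
                     toy_meta())
}

write_wide_csv <- function(g, path) {
  df <- data.frame(temperature = g$temperatures, g$ellipticity,
                   check.names = FALSE)
  names(df) <- c("temperature", g$wavelengths)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

write_long_csv <- function(g, path) {
  df <- expand.grid(wavelength = g$wavelengths,
                    temperature = g$temperatures)
  df$ellipticity <- as.vector(t(g$ellipticity))
  # shuffle rows deterministically: reader must sort
  df <- df[rev(seq_len(nrow(df))), c("temperature", "wavelength",
                                     "ellipticity")]
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

# single-bead-species frame set with atoms at given coordinates
manual_frames <- function(coords_list, species, box,
                          molecule = NULL, selections = list()) {
  if (is.null(molecule)) {
    molecule <- seq_along(species)
    molecule[species == "solute"] <- molecule[species == "solute"][1]
  }
  frame_set(coords_list, species = species, molecule = molecule, box = box,
            selections = selections)
}

# brute-force periodic distance via explicit enumeration of 27 images
brute_min_image_dist <- function(a, b, box) {
  best <- Inf
  for (ix in -1:1) for (iy in -1:1) for (iz in -1:1) {
    shift <- c(ix, iy, iz) * box
    best <- min(best, sqrt(sum((a - (b + shift))^2)))
  }
  best
}

# independent grid-search oracle for the optimal split of a two-sigmoid
# curve: for each candidate split temperature, fit one logistic per side
# and return the split minimising the total RSS
grid_search_split <- function(tt, ff, candidates) {
  fit_one <- function(t, f) {
    st <- list(c0 = min(f), a = diff(range(f)), m = mean(range(t)),
               s = diff(range(t)) / 10)
    fit <- try(minpack.lm::nlsLM(
      f ~ c0 + a / (1 + exp(-(t - m) / s)), start = st,
      control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
    if (inherits(fit, "try-error")) return(Inf)
    sum(residuals(fit)^2)
  }
  rss <- vapply(candidates, function(sp) {
    l <- tt <= sp
    if (sum(l) < 5 || sum(!l) < 5) return(Inf)
    fit_one(tt[l], ff[l]) + fit_one(tt[!l], ff[!l])
  }, numeric(1))
  # RSS is flat for splits falling between the same pair of grid points:
  # report the middle of the optimal plateau
  median(candidates[rss <= min(rss) + 1e-8 * (1 + min(rss))])
}
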