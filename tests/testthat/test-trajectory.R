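test_that("per-molecule minimum distances honour construction and the periodic boundary", {
  box <- 50
  solute <- matrix(c(25, 25, 25), 1, 3)
  # one water exactly 5 A from the solute bead
  w1 <- matrix(c(30, 25, 25), 1, 3)
  fs <- manual_frames(list(rbind(solute, w1)), c("solute", "water"), box)
  expect_equal(unname(min_distances(fs, 1, "water")), 5)
  # across the periodic boundary: direct distance large, image distance small
  w2 <- matrix(c(48, 25, 25), 1, 3)
  sol2 <- matrix(c(2, 25, 25), 1, 3)
  fs2 <- manual_frames(list(rbind(sol2, w2)), c("solute", "water"), box)
  got <- unname(min_distances(fs2, 1, "water"))
  expect_equal(got, brute_min_image_dist(c(2, 25, 25), c(48, 25, 25),
                                         c(box, box, box)))
  expect_equal(got, 4)
  # random configurations against the 27-image brute force
  set.seed(3)
  for (i in 1:20) {
    a <- runif(3, 0, box); b <- runif(3, 0, box)
    fsr <- manual_frames(list(rbind(matrix(a, 1), matrix(b, 1))),
                         c("solute", "water"), box)
    expect_equal(unname(min_distances(fsr, 1, "water")),
                 brute_min_image_dist(a, b, rep(box, 3)), tolerance = 1e-12)
  }
  # overlap gives zero
  fs0 <- manual_frames(list(rbind(solute, solute)), c("solute", "water"),
                       box)
  expect_equal(unname(min_distances(fs0, 1, "water")), 0)
  expect_error(min_distances(fs, 1, "anion"), "not present")
})

test_that("minimum-distance distributions normalise to ideal-solution density", {
  uni <- generate_trajectory(trajectory_spec(n_frames = 12, seed = 21))
  m <- mddf(uni, "water", bin_width = 1, r_max = 20)
  # beyond the solute's own radius the density must hover around 1
  far <- m$bin_mid > 8
  expect_lt(max(abs(m$normalized_density[far] - 1), na.rm = TRUE), 0.35)
  expect_lt(abs(mean(m$normalized_density[far], na.rm = TRUE) - 1), 0.05)
  # the histogram counts every molecule that falls inside r_max
  d_all <- unlist(lapply(seq_len(12), function(f)
    min_distances(uni, f, "water")))
  expect_equal(sum(m$counts), sum(d_all <= 20))
  # shell-enriched trajectory shows ~2x density inside the shell
  enr <- generate_trajectory(trajectory_spec(
    n_frames = 12, seed = 22, shell_bias = c(water = 2), shell = c(4, 9)))
  m2 <- mddf(enr, "water", bin_width = 1, r_max = 20)
  inside <- m2$bin_mid > 4.5 & m2$bin_mid < 8.5
  expect_gt(mean(m2$normalized_density[inside]), 1.6)
  expect_lt(mean(m2$normalized_density[inside]), 2.4)
  # absent species: zero counts, flagged, no crash
  m3 <- mddf(uni, "other")
  expect_true(m3$empty)
  expect_true(all(m3$counts == 0))
  expect_true(all(is.na(m3$normalized_density)))
  expect_error(mddf(uni, "water", r_max = 40), "half the smallest box")
})

test_that("gamma matches the direct-counting oracle exactly, frame by frame", {
  for (bias in c(0.5, 2)) {
    fs <- generate_trajectory(trajectory_spec(
      n_frames = 8, seed = 31 + bias * 10,
      shell_bias = c(cation = bias)))
    g <- gamma_species(fs, "cation", cutoff_r = 12)
    expect_equal(g$per_frame, gamma_direct_count(fs, "cation", 12))
    ga <- gamma_species(fs, "anion", cutoff_r = 12)
    expect_equal(ga$per_frame, gamma_direct_count(fs, "anion", 12))
  }
  # a cutoff inside the solute still yields a well-defined (zero-ish) value
  fs <- generate_trajectory(trajectory_spec(n_frames = 3, seed = 37))
  g0 <- gamma_species(fs, "cation", cutoff_r = 1)
  expect_true(is.finite(g0$gamma))
  # a cutoff reaching past the farthest box corner leaves no bulk water
  expect_error(gamma_species(fs, "cation", cutoff_r = 52.5),
               "beyond the cutoff")
})

test_that("gamma increases monotonically with shell enrichment", {
  gs <- vapply(c(0.5, 1, 2, 4), function(fac) {
    fs <- generate_trajectory(trajectory_spec(
      n_frames = 12, seed = 41, shell_bias = c(cation = fac)))
    gamma_species(fs, "cation")$gamma
  }, numeric(1))
  expect_true(all(diff(gs) > 0))
})

test_that("ion combination is symmetric with a charge-corrected default", {
  expect_equal(combine_ion_gammas(0, 0, 0), 0)
  expect_equal(combine_ion_gammas(0, 0, 0, form = "mean"), 0)
  expect_equal(combine_ion_gammas(0, 0, 0, form = "sum"), 0)
  expect_equal(combine_ion_gammas(20, 4, z2 = 22), 1)
  expect_equal(combine_ion_gammas(20, 4, z2 = 22),
               combine_ion_gammas(4, 20, z2 = 22))
  expect_equal(combine_ion_gammas(20, 4, z2 = 22, form = "mean"), 12)
  expect_equal(combine_ion_gammas(20, 4, z2 = 22, form = "sum"), 24)
  expect_error(combine_ion_gammas(Inf, 0, 0), "finite")
})

test_that("superposition RMSD is invariant under proper rigid transforms", {
  set.seed(8)
  X <- matrix(rnorm(150), 50, 3) * 4
  Y <- X + matrix(rnorm(150), 50, 3) * 0.3   # deformed copy
  rot_z <- function(th) matrix(c(cos(th), -sin(th), 0,
                                 sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  fs <- manual_frames(list(X, Y), rep("solute", 50), 500,
                      molecule = rep(1L, 50))
  base <- superpose_rmsd(fs)[2]
  # transform the mobile frame rigidly: RMSD unchanged to < 1e-8 A
  for (th in c(0.3, 1.2, 2.9)) {
    Yt <- Y %*% rot_z(th) + matrix(c(10, -7, 3), 50, 3, byrow = TRUE)
    fst <- manual_frames(list(X, Yt), rep("solute", 50), 500,
                         molecule = rep(1L, 50))
    expect_lt(abs(superpose_rmsd(fst)[2] - base), 1e-8)
  }
  # identical frame: zero
  fs0 <- manual_frames(list(X, X), rep("solute", 50), 500,
                       molecule = rep(1L, 50))
  expect_equal(superpose_rmsd(fs0)[2], 0, tolerance = 1e-12)
  # one atom displaced by 1 A in a 100-atom rigid body: ~0.1 A
  set.seed(9)
  Z <- matrix(rnorm(300), 100, 3) * 5
  Z2 <- Z; Z2[1, ] <- Z2[1, ] + c(1, 0, 0)
  fs1 <- manual_frames(list(Z, Z2), rep("solute", 100), 500,
                       molecule = rep(1L, 100))
  expect_lt(abs(superpose_rmsd(fs1)[2] - 0.1), 0.01)  # fit correction
  expect_error(superpose_rmsd(fs1, selection = 1:2), "at least 3")
})

test_that("superposition agrees with an independent reference implementation", {
  set.seed(10)
  X <- matrix(rnorm(90), 30, 3) * 3
  Y <- X + matrix(rnorm(90), 30, 3) * 0.5
  fs <- manual_frames(list(X, Y), rep("solute", 30), 500,
                      molecule = rep(1L, 30))
  ours <- superpose_rmsd(fs)[2]
  fitted <- suppressWarnings(
    bio3d::fit.xyz(fixed = as.vector(t(X)),
                   mobile = matrix(as.vector(t(Y)), nrow = 1)))
  ref <- bio3d::rmsd(as.vector(t(X)), fitted)
  # bio3d rounds fitted coordinates to PDB precision; agree to ~1e-3
  expect_equal(ours, ref, tolerance = 1e-3)
})

test_that("RMSF isolates the fluctuating atom", {
  set.seed(12)
  base <- matrix(rnorm(60), 20, 3) * 4
  frames <- lapply(1:30, function(i) {
    f <- base
    f[5, ] <- f[5, ] + rnorm(3, 0, 1.5)   # one mobile atom
    f
  })
  fs <- manual_frames(frames, rep("solute", 20), 500,
                      molecule = rep(1L, 20))
  r <- rmsf(fs)
  expect_identical(which.max(r), 5L)
  expect_gt(r[5], 5 * median(r[-5]))
})

test_that("conformer calls follow the Fab-Fc proximity rule", {
  blob <- function(center) matrix(rep(center, 4), 4, 3, byrow = TRUE)
  mk_frame <- function(fab1, fab2, fc) rbind(blob(fab1), blob(fab2),
                                             blob(fc))
  sels <- list(Fab1 = 1:4, Fab2 = 5:8, Fc = 9:12)
  sp12 <- rep("solute", 12)
  # equilateral triangle: min Fab-Fc = Fab-Fab > 0.75 * Fab-Fab -> Y
  eq <- mk_frame(c(0, 0, 0), c(40, 0, 0), c(20, 20 * sqrt(3), 0))
  fsY <- manual_frames(list(eq), sp12, 300, selections = sels)
  expect_identical(domain_distances(fsY)$label, "Y")
  # one Fab at half the Fab-Fab distance from Fc -> lambda
  lam <- mk_frame(c(0, 0, 0), c(40, 0, 0), c(10, 17.3, 0))
  fsL <- manual_frames(list(lam), sp12, 300, selections = sels)
  expect_identical(domain_distances(fsL)$label, "lambda")
  # half the frames each way -> ambiguous
  fsA <- manual_frames(list(eq, lam), sp12, 300, selections = sels)
  call <- domain_distances(fsA)
  expect_identical(call$label, "ambiguous")
  expect_equal(call$lambda_fraction, 0.5)
  # missing selection is a contract error
  fsM <- manual_frames(list(eq), sp12, 300,
                       selections = sels[c("Fab1", "Fc")])
  expect_error(domain_distances(fsM), "Fab2")
})

test_that("multi-model PDB frames load through the species map", {
  # two-model PDB with one solute residue and two waters
  p <- tempfile(fileext = ".pdb")
  fmt <- function(serial, name, resid, resno, x, y, z)
    sprintf("ATOM  %5d %-4s %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00",
            serial, name, resid, resno, x, y, z)
  writeLines(c(
    "MODEL        1",
    fmt(1, "C1", "PRO", 1, 10, 10, 10),
    fmt(2, "O", "WAT", 2, 15, 10, 10),
    fmt(3, "O", "WAT", 3, 20, 10, 10),
    "ENDMDL",
    "MODEL        2",
    fmt(1, "C1", "PRO", 1, 10, 10, 10),
    fmt(2, "O", "WAT", 2, 16, 10, 10),
    fmt(3, "O", "WAT", 3, 21, 10, 10),
    "ENDMDL",
    "END"), p)
  fs <- read_frames_pdb(p, c(PRO = "solute", WAT = "water"), box = 40)
  expect_length(fs$frames, 2)
  expect_identical(fs$species, c("solute", "water", "water"))
  d <- min_distances(fs, 2, "water")
  expect_equal(unname(d), c(6, 11))
})
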