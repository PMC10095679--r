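# toy_systems: analytic potentials, planted-mode ensembles, molecular
# fixtures, trajectory I/O

test_that("double well has the constructed minima, barrier and gradient", {
  dw <- make_double_well(5, 1)
  expect_equal(dw$energy(c(-1, 1)), c(0, 0))
  expect_equal(dw$energy(0), 5)
  expect_error(make_double_well(-1, 1), "barrier_height")
  expect_error(make_double_well(5, 0), "well_separation")
  set.seed(3)
  for (spec in list(dw, make_double_well(3, 0.7),
                    make_multiwell_2d(c(0.5, 1.5),
                                      rbind(c(-2, 0), c(2, 1)), 0.6))) {
    probes <- matrix(stats::runif(10 * spec$dimension, -1.8, 1.8),
                     ncol = spec$dimension)
    expect_lt(check_gradient(spec, probes), 1e-5)
  }
})

test_that("double-well reference PMF matches a quadrature-normalised density", {
  kt <- 0.596
  dw <- make_double_well(3, 1, kT = kt)
  # oracle: normalise the Boltzmann density numerically, evaluate
  # -kT ln p at the barrier top and at a minimum
  z <- stats::integrate(function(x) dw$energy(x) * 0 + exp(-dw$energy(x) / kt),
                        -Inf, Inf, rel.tol = 1e-12)$value
  oracle <- function(x) -kt * log(exp(-dw$energy(x) / kt) / z)
  expect_equal(dw$reference_pmf(0) - dw$reference_pmf(1),
               oracle(0) - oracle(1), tolerance = 1e-9)
  # pointwise PMF difference equals the bare energy difference
  expect_equal(oracle(0) - oracle(1), 3, tolerance = 1e-9)
})

test_that("2D multiwell is symmetric, warns on overlap, correct at centres", {
  ctr <- rbind(c(-2, 0), c(2, 0))
  mw <- make_multiwell_2d(c(1, 1), ctr, width = 0.3)
  p <- rbind(c(-1.3, 0.4), c(1.3, 0.4))
  v <- mw$energy(p)
  expect_equal(v[1], v[2], tolerance = 1e-12)   # swap symmetry
  # energy at a centre: -depth + wall term (+ negligible cross-well term)
  wall <- mw$params$wall_height * (sum(ctr[2, ]^2) / mw$params$wall_r0^2)^2
  expect_equal(mw$energy(ctr[2, , drop = FALSE]), -1 + wall, tolerance = 1e-6)
  expect_warning(make_multiwell_2d(c(1, 1), rbind(c(0, 0), c(0.1, 0)), 0.5),
                 "closer than")
  expect_error(make_multiwell_2d(c(1), rbind(c(0, 0)), 0.5), "2 wells")
})

test_that("planted-mode generator obeys its construction and determinism", {
  u <- random_modes(5, 1, seed = 2)
  spec <- planted_mode_spec(u, amplitudes = 0.8, autocorrelation = 0,
                            noise_sigma = 0, seed = 10)
  tr <- generate_planted_trajectory(5, 200, spec)
  cv <- build_covariance(tr, align = FALSE)
  ev <- eigen(cv$matrix, symmetric = TRUE, only.values = TRUE)$values
  expect_lt(ev[2] / ev[1], 1e-10)               # rank 1 without noise
  tr2 <- generate_planted_trajectory(5, 200, spec)
  expect_identical(tr$coords, tr2$coords)       # bitwise determinism
  expect_error(generate_planted_trajectory(5, 5, spec), "n_frames")
  expect_error(planted_mode_spec(cbind(u, u), c(1, 1)), "orthonormal")
  bad <- planted_mode_spec(u[, 0, drop = FALSE], numeric(0), noise_sigma = 0)
  expect_error(generate_planted_trajectory(5, 100, bad), "degenerate")
})

test_that("planted leading eigenvalue matches the population value and converges", {
  u <- random_modes(10, 1, seed = 5)
  spec <- planted_mode_spec(u, amplitudes = 1.0, autocorrelation = 0,
                            noise_sigma = 0.1, seed = 42)
  # population covariance s^2 u u' + sigma^2 I: leading eigenvalue 1.01
  tr <- generate_planted_trajectory(10, 20000, spec)
  lam1 <- eigen(build_covariance(tr, align = FALSE)$matrix,
                symmetric = TRUE, only.values = TRUE)$values[1]
  expect_lt(abs(lam1 - 1.01) / 1.01, 0.05)
  # error shrinks with ensemble size
  err_at <- function(n) {
    trn <- generate_planted_trajectory(10, n, spec)
    abs(eigen(build_covariance(trn, align = FALSE)$matrix,
              symmetric = TRUE, only.values = TRUE)$values[1] - 1.01)
  }
  expect_lt(err_at(20000), err_at(500))
})

test_that("hbond fixture reproduces the stated frame-0 geometry exactly", {
  for (cfg in list(c(3.0, 180), c(3.4, 150), c(2.8, 120), c(3.5, 120))) {
    f <- make_hbond_fixture(cfg[1], cfg[2])
    fr <- frame_coords(f$trajectory, 1)
    d <- sqrt(sum((fr[3, ] - fr[1, ])^2))
    u <- fr[1, ] - fr[2, ]; v <- fr[3, ] - fr[2, ]
    ang <- acos(sum(u * v) / sqrt(sum(u^2) * sum(v^2))) * 180 / pi
    expect_lt(abs(d - cfg[1]), 1e-9)
    expect_lt(abs(ang - cfg[2]), 1e-9)
  }
  expect_error(make_hbond_fixture(3.0, 0), "angle")
  expect_error(make_hbond_fixture(3.0, 190), "angle")
  expect_error(make_hbond_fixture(-1, 120), "distance")
})

test_that("jittered fixture occupancy equals a brute-force per-frame recount", {
  f <- make_hbond_fixture(3.4, 150, n_frames = 1000, jitter = 0.05, seed = 7)
  rec <- detect_hbond_series(f$trajectory, 1, 2, 3)
  oracle <- brute_hbond_occupancy(f$trajectory, 1, 2, 3)
  expect_equal(occupancy(rec), round(oracle, 1))
  expect_gt(occupancy(rec), 0)
  expect_lt(occupancy(rec), 100)
})

test_that("ring and ion fixtures carry their stated geometry", {
  rf <- make_ring_fixture(3.8)
  rec <- group_centroid_distance_series(rf$trajectory, 1:6, 7:12)
  expect_equal(rec$distance_series[1], 3.8, tolerance = 1e-12)
  ion <- make_ion_fixture(1.9, 4.6, p1 = 0.5, n_frames = 2000, seed = 3)
  d <- rc_distance_series(ion$trajectory, 1, 2)
  ds <- probability_distribution(d, bin_width = 0.1)
  top2 <- sort(ds$peak_positions[1:2])
  expect_lt(abs(top2[1] - 1.9), 0.1)
  expect_lt(abs(top2[2] - 4.6), 0.1)
})

test_that("PDB and XYZ round trips preserve labels and coordinates", {
  set.seed(8)
  coords <- array(rnorm(3 * 5 * 3, sd = 4), c(3, 5, 3))
  labels <- data.frame(name = c("CA", "CB", "OD1", "MG", "N"),
                       resid = c(1L, 1L, 2L, 3L, 4L),
                       resname = c("ALA", "ALA", "ASP", "MG", "GLY"),
                       element = c("C", "C", "O", "MG", "N"),
                       stringsAsFactors = FALSE)
  tr <- trajectory(coords, labels, timestep = 2)
  pdb <- tempfile(fileext = ".pdb"); xyz <- tempfile(fileext = ".xyz")
  write_trajectory(tr, pdb, "pdb")
  write_trajectory(tr, xyz, "xyz")
  rp <- read_trajectory(pdb)
  rx <- read_trajectory(xyz)
  expect_identical(rp$labels$name, labels$name)
  expect_identical(rp$labels$element, labels$element)
  expect_identical(rp$labels$resid, labels$resid)
  expect_lt(max(abs(rp$coords - coords)), 1e-3 + 1e-12)
  expect_lt(max(abs(rx$coords - coords)), 1e-6 + 1e-12)
  expect_equal(rx$timestep, 2)                  # parsed from XYZ comments
})

test_that("PDB reader infers elements and reports ragged frames", {
  lines <- c(
    "MODEL        1",
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00",
    "ATOM      2  OD1 ASP A   2       1.000   0.000   0.000  1.00  0.00",
    "ATOM      3 MG   MG  A   3       2.000   0.000   0.000  1.00  0.00",
    "ATOM      4  N   GLY A   4       3.000   0.000   0.000  1.00  0.00",
    "ENDMDL")
  p <- tempfile(fileext = ".pdb")
  writeLines(lines, p)
  tr <- read_trajectory(p)
  expect_identical(tr$labels$element, c("C", "O", "MG", "N"))
  writeLines(c(lines, "MODEL        2", lines[2:3], "ENDMDL"), p)
  expect_error(read_trajectory(p), "ragged")
  # ragged XYZ names the offending frame too
  x <- tempfile(fileext = ".xyz")
  writeLines(c("2", "frame=1", "C 0 0 0", "C 1 0 0",
               "2", "frame=2", "C 0 0 0"), x)
  expect_error(read_trajectory(x), "frame 2")
})

test_that("infer_element handles names with digits and two-letter species", {
  expect_identical(infer_element(c("1HB", "HG21", "CA", "CD2", "CL", "ZN",
                                   "O2'")),
                   c("H", "H", "C", "C", "CL", "ZN", "O"))
})
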