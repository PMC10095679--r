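# structure_metrics: superposition, RMSD/RMSF/Rg, distances, distributions

rot_z <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
}

test_that("Kabsch superposition handles identity and rigid motions", {
  set.seed(11)
  ref <- matrix(rnorm(15, sd = 3), 5, 3)
  k <- kabsch_superpose(ref, ref)
  expect_lt(k$rmsd, 1e-12)
  expect_equal(k$rotation, diag(3), tolerance = 1e-9)
  mob <- sweep(ref %*% rot_z(37), 2, c(4, -1, 2), "+")
  k2 <- kabsch_superpose(mob, ref)
  expect_lt(k2$rmsd, 1e-9)
  expect_equal(det(k2$rotation), 1, tolerance = 1e-9)
  fitted <- sweep(mob %*% k2$rotation, 2, k2$translation, "+")
  expect_equal(fitted, ref, tolerance = 1e-9)
  expect_error(kabsch_superpose(ref[1:2, ], ref[1:2, ]), "degenerate")
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch_superpose(line, line + 1), "degenerate")
})

test_that("Kabsch RMSD matches the quaternion-search oracle", {
  set.seed(12)
  ref <- matrix(rnorm(15, sd = 3), 5, 3)
  mob <- ref
  mob[3, ] <- mob[3, ] + c(1, 0, 0)           # one particle displaced 1 A
  mob <- sweep(mob %*% rot_z(25), 2, c(1, 2, 3), "+")
  expect_equal(kabsch_superpose(mob, ref)$rmsd,
               quaternion_rmsd_oracle(mob, ref), tolerance = 1e-6)
  # a harder, fully random deformation
  mob2 <- ref + matrix(rnorm(15, sd = 0.4), 5, 3)
  expect_equal(kabsch_superpose(mob2, ref)$rmsd,
               quaternion_rmsd_oracle(mob2, ref), tolerance = 1e-6)
})

test_that("rmsd_series is zero for rigid motion and matches per-frame fits", {
  set.seed(13)
  base <- matrix(rnorm(24, sd = 3), 8, 3)
  coords <- array(0, c(4, 8, 3))
  for (f in 1:4)
    coords[f, , ] <- sweep(base %*% rot_z(20 * f), 2, c(f, 0, -f), "+")
  tr <- trajectory(coords)
  expect_lt(max(rmsd_series(tr, 1)), 1e-9)
  coords2 <- coords + array(rnorm(length(coords), sd = 0.3), dim(coords))
  tr2 <- trajectory(coords2)
  rs <- rmsd_series(tr2, 1)
  oracle <- vapply(1:4, function(f)
    kabsch_superpose(matrix(coords2[f, , ], ncol = 3),
                     matrix(coords2[1, , ], ncol = 3))$rmsd, 0)
  expect_equal(rs, oracle)
})

test_that("RMSF reproduces closed-form fluctuation patterns", {
  # static ensemble
  coords <- array(rep(matrix(rnorm(15), 5, 3), each = 6), c(6, 5, 3))
  for (f in 1:6) coords[f, , ] <- coords[1, , ]
  expect_equal(rmsf(trajectory(coords))$rmsf, rep(0, 5))
  # one particle oscillating +/- d along x, rest fixed, no alignment
  d <- 0.7
  coords2 <- array(0, c(10, 4, 3))
  coords2[, , 1] <- matrix(rep(c(0, 3, 6, 9), each = 10), ncol = 4)
  coords2[, 2, 1] <- 3 + d * rep(c(1, -1), 5)
  coords2[, , 2] <- matrix(rep(c(0, 1, 0, 1), each = 10), ncol = 4)
  pr <- rmsf(trajectory(coords2), align = FALSE)
  expect_equal(pr$rmsf, c(0, d, 0, 0), tolerance = 1e-12)
  expect_error(rmsf(trajectory(coords2[1, , , drop = FALSE])), "2 frames")
})

test_that("planted-ensemble RMSF matches the generator-side oracle", {
  u <- random_modes(6, 2, seed = 21)
  spec <- planted_mode_spec(u, c(1.2, 0.5), autocorrelation = 0,
                            noise_sigma = 0, seed = 22)
  tr <- generate_planted_trajectory(6, 500, spec)
  amps <- attr(tr, "mode_amplitudes")
  # oracle: fluctuations reconstructed from the recorded amplitudes
  disp <- amps %*% t(u)                        # frames x 3N
  disp <- sweep(disp, 2, colMeans(disp))
  per_coord <- colMeans(disp^2)
  oracle <- sqrt(per_coord[c(TRUE, FALSE, FALSE)] +
                 per_coord[c(FALSE, TRUE, FALSE)] +
                 per_coord[c(FALSE, FALSE, TRUE)])
  expect_equal(rmsf(tr, align = FALSE)$rmsf, oracle, tolerance = 1e-10)
})

test_that("delta RMSF is an elementwise, antisymmetric difference", {
  u <- random_modes(6, 1, seed = 31)
  a <- rmsf(generate_planted_trajectory(
    6, 300, planted_mode_spec(u, 1.0, 0, 0.05, seed = 32)), align = FALSE)
  b <- rmsf(generate_planted_trajectory(
    6, 300, planted_mode_spec(u, 0.4, 0, 0.05, seed = 33)), align = FALSE)
  expect_equal(delta_rmsf(a, a), rep(0, 6))
  expect_equal(delta_rmsf(a, b), -delta_rmsf(b, a))
  b2 <- a; b2$rmsf <- a$rmsf + 0.5
  expect_equal(delta_rmsf(b2, a), rep(0.5, 6))
  bad <- a; bad$rmsf <- a$rmsf[1:3]
  expect_error(delta_rmsf(a, bad), "length")
})

test_that("radius of gyration matches closed forms and a direct oracle", {
  coords <- array(0, c(1, 3, 3))               # all coincident
  expect_equal(radius_of_gyration(trajectory(coords)), 0)
  two <- array(0, c(1, 2, 3)); two[1, 2, 3] <- 2 * 1.7
  lab <- data.frame(name = c("C1", "C2"), resid = 1:2, resname = "UNK",
                    element = "C")
  expect_equal(radius_of_gyration(trajectory(two, lab)), 1.7)
  set.seed(14)
  coords3 <- array(rnorm(20 * 3, sd = 5), c(1, 20, 3))
  tr <- trajectory(coords3)
  m <- tr$masses
  fr <- frame_coords(tr, 1)
  com <- colSums(fr * m) / sum(m)
  oracle <- sqrt(sum(m * rowSums(sweep(fr, 2, com)^2)) / sum(m))
  expect_equal(radius_of_gyration(tr), oracle, tolerance = 1e-10)
})

test_that("RMSD and Rg are invariant under global rigid motion", {
  set.seed(15)
  coords <- array(rnorm(5 * 8 * 3, sd = 3), c(5, 8, 3))
  tr <- trajectory(coords)
  tr2 <- apply_rigid(tr, angle = 1.1, axis = c(1, 2, 0.5))
  expect_equal(rmsd_series(tr, 1), rmsd_series(tr2, 1), tolerance = 1e-9)
  expect_equal(radius_of_gyration(tr), radius_of_gyration(tr2),
               tolerance = 1e-9)
  # RMSF scale equivariance
  tr3 <- tr; tr3$coords <- 2.5 * tr$coords
  expect_equal(rmsf(tr3)$rmsf, 2.5 * rmsf(tr)$rmsf, tolerance = 1e-9)
})

test_that("distance series and label lookup behave per definition", {
  coords <- array(0, c(2, 3, 3))
  coords[, 2, 1] <- 3; coords[, 2, 2] <- 4
  lab <- data.frame(name = c("CA", "CA", "CB"), resid = c(32L, 61L, 61L),
                    resname = "ALA", element = "C")
  tr <- trajectory(coords, lab)
  expect_equal(rc_distance_series(tr, 1, 2), c(5, 5))   # 3-4-5 triangle
  expect_equal(rc_distance_series(tr, 1, 3), c(0, 0))
  expect_equal(rc_from_selection_pair(tr, 32, "CA", 61, "CA"), c(5, 5))
  expect_error(rc_from_selection_pair(tr, 99, "CA", 61, "CA"),
               "residue 99")
  expect_error(rc_distance_series(tr, 1, 7), "out of range")
})

test_that("probability distributions find the planted peaks", {
  set.seed(16)
  g <- rnorm(1e5, 2.08, 0.05)
  ds <- probability_distribution(g, bin_width = 0.02)
  expect_lt(abs(ds$peak_positions[1] - 2.08), 0.02 + 1e-12)
  tz <- sum((ds$density[-1] + ds$density[-length(ds$density)]) / 2 *
              diff(ds$centers))
  expect_equal(tz, 1, tolerance = 1e-9)
  expect_lte(length(ds$peak_positions), length(ds$density))
  bim <- c(rnorm(5e4, 2, 0.1), rnorm(5e4, 4, 0.1))
  db <- probability_distribution(bim, bin_width = 0.05, smooth = TRUE)
  top2 <- sort(db$peak_positions[1:2])
  expect_lt(abs(top2[1] - 2), 0.05 + 1e-12)
  expect_lt(abs(top2[2] - 4), 0.05 + 1e-12)
  cst <- probability_distribution(rep(3.2, 50), bin_width = 0.1)
  expect_identical(cst$peak_positions, 3.2)
  expect_error(probability_distribution(rnorm(5)), ">= 10")
})

test_that("the selection mini-language resolves compound predicates", {
  lab <- data.frame(name = c("CA", "CB", "H", "CA", "OW"),
                    resid = c(30L, 30L, 30L, 41L, 99L),
                    resname = c("ALA", "ALA", "ALA", "GLY", "HOH"),
                    element = c("C", "C", "H", "C", "O"))
  tr <- trajectory(array(0, c(1, 5, 3)), lab)
  expect_identical(select_atoms(tr, "name CA"), c(1L, 4L))
  expect_identical(select_atoms(tr, "protein and not element H"),
                   c(1L, 2L, 4L))
  expect_identical(select_atoms(tr, "resid 30-40"), 1:3)
  expect_identical(select_atoms(tr, "resid 30-40 and name CA"), 1L)
  expect_identical(select_atoms(tr, "name CA,CB or element O"),
                   c(1L, 2L, 4L, 5L))
  expect_error(select_atoms(tr, "name XX"), "zero particles")
  expect_error(select_atoms(tr, "banana 3"), "unknown keyword")
})
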