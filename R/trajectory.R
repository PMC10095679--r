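# The trajectory container shared by every analysis module: a dense
# frames x particles x 3 coordinate array (Angstrom) plus per-particle
# labels and masses and the inter-frame timestep (ps).

.STANDARD_MASSES <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                      S = 32.06, P = 30.974, MG = 24.305, NA. = 22.98977,
                      CL = 35.45, FE = 55.845, ZN = 65.38, K = 39.0983,
                      CA. = 40.078, BR = 79.904, F = 18.998)

#' Standard atomic mass for an element symbol
#'
#' Unknown elements fall back to the mass of carbon (12.011 amu) with a
#' warning.  `"NA."` and `"CA."` address sodium and calcium, avoiding the
#' clash with R's `NA` and the ubiquitous alpha-carbon atom name.
#'
#' @param element character vector of element symbols.
#' @return numeric vector of masses in amu.
#' @export
element_mass <- function(element) {
  key <- toupper(element)
  key[key == "NA"] <- "NA."
  m <- .STANDARD_MASSES[key]
  if (anyNA(m)) {
    warning("unknown element(s) ", paste(unique(element[is.na(m)]), collapse = ", "),
            ": using 12.011 amu")
    m[is.na(m)] <- 12.011
  }
  unname(m)
}

#' Construct a trajectory ensemble
#'
#' @param coords numeric array `frames x particles x 3`, Angstrom.
#' @param labels data.frame with columns `name`, `resid`, `resname`,
#'   `element` (one row per particle); generated defaults if `NULL`.
#' @param masses numeric vector, amu; derived from `labels$element` if `NULL`.
#' @param timestep time between stored frames, ps.
#' @param box optional periodic box lengths (carried, never applied).
#' @return object of class `trajectory`.
#' @export
trajectory <- function(coords, labels = NULL, masses = NULL, timestep = 1,
                       box = NULL) {
  if (length(dim(coords)) != 3L || dim(coords)[3L] != 3L)
    stop("coords must be a frames x particles x 3 array")
  n_frames <- dim(coords)[1L]; n_part <- dim(coords)[2L]
  if (n_frames < 1L) stop("need at least one frame")
  if (is.null(labels)) {
    labels <- data.frame(name = paste0("C", seq_len(n_part)),
                         resid = seq_len(n_part),
                         resname = "UNK",
                         element = "C", stringsAsFactors = FALSE)
  }
  if (nrow(labels) != n_part) stop("label count must equal particle count")
  if (is.null(masses)) masses <- element_mass(labels$element)
  if (length(masses) != n_part) stop("mass count must equal particle count")
  if (any(masses <= 0)) stop("all masses must be > 0")
  structure(list(coords = coords, labels = labels, masses = masses,
                 timestep = timestep, box = box),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  d <- dim(x$coords)
  cat(sprintf("<trajectory> %d frames, %d particles, dt=%g ps\n",
              d[1L], d[2L], x$timestep))
  invisible(x)
}

#' Number of frames / particles in a trajectory
#' @param traj `trajectory`.
#' @return integer count.
#' @export
n_frames <- function(traj) dim(traj$coords)[1L]

#' @rdname n_frames
#' @export
n_particles <- function(traj) dim(traj$coords)[2L]

#' Coordinates of one frame
#' @param traj `trajectory`.
#' @param i frame index.
#' @return `particles x 3` matrix.
#' @export
frame_coords <- function(traj, i) {
  matrix(traj$coords[i, , ], ncol = 3L)
}

# Deterministic protein-like backbone: points on a gentle helix with
# roughly C-alpha spacing (3.8 A between consecutive particles).
.helix_mean_structure <- function(n_particles) {
  i <- seq_len(n_particles) - 1
  r <- 8; theta <- 0.45; pitch <- 1.6
  cbind(r * cos(i * theta), r * sin(i * theta), pitch * i)
}

#' Planted collective-mode specification
#'
#' Ground truth for PCA / cross-correlation validation: a trajectory is
#' generated as `x_t = mean + sum_m a_m(t) u_m + eps_t`, where the mode
#' amplitudes `a_m(t)` follow stationary AR(1) processes with the stated
#' standard deviations and `eps_t` is isotropic Gaussian noise.  The
#' population covariance is then exactly
#' `sum_m s_m^2 u_m u_m^T + noise_sigma^2 I`.
#'
#' @param mode_vectors `3N x M` matrix of orthonormal displacement modes.
#' @param amplitudes per-mode stationary standard deviations, Angstrom (> 0).
#' @param autocorrelation per-mode AR(1) coefficient in `[0, 1)`, recycled.
#' @param noise_sigma isotropic per-coordinate noise, Angstrom (>= 0).
#' @param seed integer seed making the generated ensemble reproducible.
#' @return object of class `planted_mode_spec`.
#' @export
planted_mode_spec <- function(mode_vectors, amplitudes, autocorrelation = 0.9,
                              noise_sigma = 0.1, seed = 1L) {
  mode_vectors <- as.matrix(mode_vectors)
  m <- ncol(mode_vectors)
  if (length(amplitudes) != m) stop("one amplitude per mode required")
  if (any(amplitudes <= 0)) stop("amplitudes must be > 0")
  autocorrelation <- rep_len(autocorrelation, m)
  if (any(autocorrelation < 0 | autocorrelation >= 1))
    stop("autocorrelation must lie in [0, 1)")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  if (m > 0L) {
    gram <- crossprod(mode_vectors)
    if (max(abs(gram - diag(m))) > 1e-10)
      stop("mode vectors must be orthonormal (tolerance 1e-10)")
  }
  structure(list(mode_vectors = mode_vectors, amplitudes = amplitudes,
                 autocorrelation = autocorrelation,
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "planted_mode_spec")
}

#' Random orthonormal displacement modes
#'
#' @param n_particles number of particles.
#' @param n_modes number of modes.
#' @param seed integer seed.
#' @return `3*n_particles x n_modes` orthonormal matrix.
#' @export
random_modes <- function(n_particles, n_modes, seed = 1L) {
  set.seed(seed)
  qr.Q(qr(matrix(rnorm(3 * n_particles * n_modes), ncol = n_modes)))
}

#' Generate a trajectory with planted collective modes
#'
#' @param n_particles number of particles (mean structure is a helix with
#'   C-alpha-like spacing).
#' @param n_frames number of frames (>= 10).
#' @param spec `planted_mode_spec`.
#' @param timestep frame spacing, ps.
#' @return `trajectory`; attribute `"mode_amplitudes"` records the realised
#'   per-frame mode amplitudes (frames x modes) as a generator-side oracle.
#' @export
generate_planted_trajectory <- function(n_particles, n_frames, spec,
                                        timestep = 1) {
  stopifnot(inherits(spec, "planted_mode_spec"))
  if (n_frames < 10L) stop("n_frames must be >= 10")
  if (nrow(spec$mode_vectors) != 3L * n_particles)
    stop("mode_vectors rows must equal 3 * n_particles")
  m <- ncol(spec$mode_vectors)
  if (m == 0L && spec$noise_sigma == 0)
    stop("degenerate ensemble: zero modes and zero noise")
  set.seed(spec$seed)
  amps <- matrix(0, n_frames, max(m, 1L))
  if (m > 0L) {
    for (j in seq_len(m)) {
      s <- spec$amplitudes[j]; phi <- spec$autocorrelation[j]
      a <- numeric(n_frames)
      a[1L] <- rnorm(1L, 0, s)
      innov_sd <- s * sqrt(1 - phi^2)
      eta <- rnorm(n_frames - 1L)
      for (t in seq_len(n_frames - 1L)) a[t + 1L] <- phi * a[t] + innov_sd * eta[t]
      amps[, j] <- a
    }
  }
  mean_flat <- as.vector(t(.helix_mean_structure(n_particles)))  # x1,y1,z1,...
  # mode vectors are stored with the same x1,y1,z1,... coordinate order
  disp <- if (m > 0L) amps[, seq_len(m), drop = FALSE] %*% t(spec$mode_vectors)
          else matrix(0, n_frames, 3L * n_particles)
  if (spec$noise_sigma > 0)
    disp <- disp + matrix(rnorm(length(disp), 0, spec$noise_sigma), nrow = n_frames)
  flat <- sweep(disp, 2L, mean_flat, "+")
  coords <- array(0, c(n_frames, n_particles, 3L))
  for (d in 1:3) coords[, , d] <- flat[, seq(d, 3L * n_particles, by = 3L)]
  labels <- data.frame(name = "CA", resid = seq_len(n_particles),
                       resname = "ALA", element = "C",
                       stringsAsFactors = FALSE)
  out <- trajectory(coords, labels, timestep = timestep)
  attr(out, "mode_amplitudes") <- amps[, seq_len(m), drop = FALSE]
  attr(out, "mean_structure") <- .helix_mean_structure(n_particles)
  out
}
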