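# Essential-dynamics PCA and dynamic cross-correlation maps.  The 3N x 3N
# positional covariance is built from frames least-squares aligned to the
# iteratively refined mean (1/n normalisation, coordinate order
# x1,y1,z1,x2,...); its symmetric eigendecomposition gives the collective
# modes; the DCCM is the normalised displacement-vector correlation
# C_ij = <dr_i . dr_j> / sqrt(<dr_i^2><dr_j^2>).

#' Positional covariance matrix of an aligned ensemble
#'
#' @param traj `trajectory` with >= 2 frames.
#' @param selection integer particle indices (default: all).
#' @param align superpose frames onto the iterative mean first (disable for
#'   ensembles that are already free of rigid-body motion).
#' @return object of class `covariance_matrix`: `matrix` (3N x 3N,
#'   Angstrom^2, 1/n normalisation), `mean_structure` (N x 3), `selection`,
#'   `n_frames`.
#' @export
build_covariance <- function(traj, selection = NULL, align = TRUE) {
  stopifnot(inherits(traj, "trajectory"))
  if (n_frames(traj) < 2L) stop("covariance needs at least 2 frames")
  if (is.null(selection)) selection <- seq_len(n_particles(traj))
  if (length(selection) < 2L) stop("selection must hold >= 2 particles")
  if (align) {
    al <- .align_to_mean(traj, selection)
    arr <- al$aligned; mu <- al$mean
  } else {
    arr <- traj$coords[, selection, , drop = FALSE]
    mu <- apply(arr, c(2L, 3L), mean)
  }
  nf <- dim(arr)[1L]; np <- dim(arr)[2L]
  q <- matrix(0, nf, 3L * np)
  for (d in 1:3) q[, seq(d, 3L * np, by = 3L)] <- arr[, , d]
  q <- sweep(q, 2L, colMeans(q))
  cv <- crossprod(q) / nf
  cv <- (cv + t(cv)) / 2
  structure(list(matrix = cv, mean_structure = mu,
                 selection = selection, n_frames = nf),
            class = "covariance_matrix")
}

#' Eigendecomposition of a positional covariance
#'
#' Symmetric eigendecomposition with eigenvalues sorted descending.  Sign
#' convention: each eigenvector's largest-magnitude component (first such
#' component on ties) is made positive, so modes are deterministic.
#'
#' @param cov `covariance_matrix`, or a plain symmetric matrix.
#' @return object of class `eigen_decomposition`: `values` (Angstrom^2),
#'   `vectors` (orthonormal columns, coordinate order x1,y1,z1,...),
#'   `mean_structure` (may be `NULL` for plain input).
#' @export
diagonalize <- function(cov) {
  mean_structure <- NULL
  if (inherits(cov, "covariance_matrix")) {
    m <- cov$matrix; mean_structure <- cov$mean_structure
  } else m <- as.matrix(cov)
  if (max(abs(m - t(m))) > 1e-8 * max(abs(m), 1))
    stop("covariance matrix is not symmetric")
  e <- eigen((m + t(m)) / 2, symmetric = TRUE)
  vec <- e$vectors
  for (j in seq_len(ncol(vec))) {
    i <- which.max(abs(vec[, j]))
    if (vec[i, j] < 0) vec[, j] <- -vec[, j]
  }
  structure(list(values = e$values, vectors = vec,
                 mean_structure = mean_structure),
            class = "eigen_decomposition")
}

#' Cumulative variance fraction of the leading modes
#'
#' @param eig `eigen_decomposition`.
#' @param n_modes number of leading modes.
#' @return fraction in `[0, 1]`: `sum(lambda[1:n]) / sum(lambda)`.
#' @export
variance_fraction <- function(eig, n_modes) {
  stopifnot(inherits(eig, "eigen_decomposition"))
  nv <- length(eig$values)
  if (n_modes < 1L || n_modes > nv) stop("n_modes out of range")
  vals <- pmax(eig$values, 0)
  sum(vals[seq_len(n_modes)]) / sum(vals)
}

#' Per-particle displacement vectors of one mode
#'
#' @param eig `eigen_decomposition`.
#' @param mode_index mode number (1 = largest eigenvalue).
#' @param scale multiplier applied to the unit eigenvector.
#' @return `N x 3` matrix of displacement vectors, Angstrom.
#' @export
mode_displacements <- function(eig, mode_index, scale = 1) {
  stopifnot(inherits(eig, "eigen_decomposition"))
  nv <- length(eig$values)
  if (mode_index < 1L || mode_index > nv) stop("mode_index out of range")
  matrix(scale * eig$vectors[, mode_index], ncol = 3L, byrow = TRUE)
}

#' Export a mode as a two-model PDB for porcupine rendering
#'
#' Writes the mean structure (MODEL 1) and the mean plus the scaled mode
#' displacement (MODEL 2); arrow tools draw vectors between the paired
#' atoms.
#'
#' @param eig `eigen_decomposition` carrying a `mean_structure`.
#' @param mode_index mode number.
#' @param path output PDB path.
#' @param scale displacement multiplier.
#' @param labels optional label data.frame for the written atoms.
#' @return `path`, invisibly.
#' @export
export_porcupine <- function(eig, mode_index, path, scale = 10,
                             labels = NULL) {
  if (is.null(eig$mean_structure))
    stop("eigendecomposition carries no mean structure")
  mu <- eig$mean_structure
  disp <- mode_displacements(eig, mode_index, scale)
  coords <- array(0, c(2L, nrow(mu), 3L))
  coords[1L, , ] <- mu
  coords[2L, , ] <- mu + disp
  if (is.null(labels))
    labels <- data.frame(name = "CA", resid = seq_len(nrow(mu)),
                         resname = "ALA", element = "C",
                         stringsAsFactors = FALSE)
  write_trajectory(trajectory(coords, labels), path, "pdb")
}

#' Dynamic cross-correlation map
#'
#' For aligned displacements about the mean, `C_ij` is the time-averaged
#' dot product of the displacement vectors of particles i and j normalised
#' by the fluctuation magnitudes, so `C_ij` lies in `[-1, 1]` with +1 for
#' identical and -1 for mirrored motion.  Particles with zero variance get
#' zero rows/columns (diagonal 1) and are flagged in the
#' `"zero_variance"` attribute.
#'
#' @param traj `trajectory` with >= 2 frames.
#' @param selection integer particle indices (default: all).
#' @param align superpose frames onto the iterative mean first.
#' @return object of class `dccm_matrix`: `matrix` (N x N), `selection`.
#' @export
dccm <- function(traj, selection = NULL, align = TRUE) {
  stopifnot(inherits(traj, "trajectory"))
  if (n_frames(traj) < 2L) stop("DCCM needs at least 2 frames")
  if (is.null(selection)) selection <- seq_len(n_particles(traj))
  if (align) {
    al <- .align_to_mean(traj, selection)
    arr <- al$aligned; mu <- al$mean
  } else {
    arr <- traj$coords[, selection, , drop = FALSE]
    mu <- apply(arr, c(2L, 3L), mean)
  }
  np <- length(selection)
  s <- matrix(0, np, np)
  for (d in 1:3) {
    dd <- sweep(arr[, , d, drop = TRUE], 2L, mu[, d])
    dd <- matrix(dd, ncol = np)
    s <- s + crossprod(dd)
  }
  v <- diag(s)
  zero <- v <= 1e-300
  denom <- sqrt(pmax(v, 1e-300))
  cm <- s / outer(denom, denom)
  if (any(zero)) {
    cm[zero, ] <- 0; cm[, zero] <- 0
  }
  diag(cm) <- 1
  cm[cm > 1] <- 1; cm[cm < -1] <- -1
  out <- structure(list(matrix = cm, selection = selection),
                   class = "dccm_matrix")
  attr(out, "zero_variance") <- which(zero)
  out
}

#' @export
print.dccm_matrix <- function(x, ...) {
  cat(sprintf("<dccm_matrix> %d x %d, range [%.3f, %.3f]\n",
              nrow(x$matrix), ncol(x$matrix), min(x$matrix), max(x$matrix)))
  invisible(x)
}
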