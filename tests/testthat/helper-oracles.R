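# Independent oracles used to freeze expected values.  Each is a direct,
# definition-level implementation kept deliberately separate from the code
# paths it checks.

# per-bin Boltzmann reference PMF by adaptive quadrature (1D), min-shifted
ref_pmf_binned <- function(spec, edges, kt) {
  nb <- length(edges) - 1L
  ref <- vapply(seq_len(nb), function(i) {
    z <- stats::integrate(function(x) exp(-spec$energy(x) / kt),
                          edges[i], edges[i + 1L], rel.tol = 1e-10)$value
    -kt * log(z / (edges[i + 1L] - edges[i]))
  }, 0)
  ref - min(ref)
}

# minimum RMSD over rotations by random-quaternion search plus Nelder-Mead
# polish on the axis-angle parameterisation (no SVD involved)
quaternion_rmsd_oracle <- function(mobile, reference, weights = NULL,
                                   n_grid = 20000L, seed = 99L) {
  n <- nrow(mobile)
  w <- if (is.null(weights)) rep(1 / n, n) else weights / sum(weights)
  m <- sweep(mobile, 2, colSums(mobile * w))
  r <- sweep(reference, 2, colSums(reference * w))
  rotmat <- function(v) {           # axis-angle (Rodrigues), v in R^3
    th <- sqrt(sum(v^2))
    if (th < 1e-12) return(diag(3))
    k <- v / th
    kx <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
    diag(3) + sin(th) * kx + (1 - cos(th)) * (kx %*% kx)
  }
  score <- function(v) sum(w * rowSums((m %*% rotmat(v) - r)^2))
  set.seed(seed)
  best <- c(0, 0, 0); bs <- score(best)
  for (i in seq_len(n_grid)) {
    q <- rnorm(4); q <- q / sqrt(sum(q^2))
    th <- 2 * acos(min(max(abs(q[1]), -1), 1))
    sn <- sqrt(max(1 - q[1]^2, 1e-300))
    v <- th * q[2:4] / sn
    s <- score(v)
    if (s < bs) { bs <- s; best <- v }
  }
  op <- stats::optim(best, score, method = "Nelder-Mead",
                     control = list(reltol = 1e-15, maxit = 5000))
  sqrt(op$value)
}

# 3N x 3N covariance by explicit double loop (1/n normalisation)
brute_covariance <- function(flat) {
  n <- nrow(flat); p <- ncol(flat)
  mu <- colMeans(flat)
  cv <- matrix(0, p, p)
  for (i in seq_len(p)) for (j in seq_len(p))
    cv[i, j] <- mean((flat[, i] - mu[i]) * (flat[, j] - mu[j]))
  cv
}

# flatten a trajectory selection into frames x 3N (x1,y1,z1,...)
flatten_coords <- function(traj, selection = seq_len(n_particles(traj))) {
  arr <- traj$coords[, selection, , drop = FALSE]
  np <- length(selection)
  q <- matrix(0, dim(arr)[1L], 3L * np)
  for (d in 1:3) q[, seq(d, 3L * np, by = 3L)] <- arr[, , d]
  q
}

# build a trajectory straight from a frames x particles x 3 array
make_traj <- function(coords, ...) trajectory(coords, ...)

# random rigid motion applied to every frame
apply_rigid <- function(traj, angle = 0.7, axis = c(0, 0, 1),
                        shift = c(1, -2, 3)) {
  axis <- axis / sqrt(sum(axis^2))
  kx <- matrix(c(0, axis[3], -axis[2], -axis[3], 0, axis[1],
                 axis[2], -axis[1], 0), 3, 3)
  rot <- diag(3) + sin(angle) * kx + (1 - cos(angle)) * (kx %*% kx)
  out <- traj
  for (f in seq_len(n_frames(traj)))
    out$coords[f, , ] <- sweep(frame_coords(traj, f) %*% rot, 2, shift, "+")
  out
}

# brute-force hydrogen-bond occupancy: per-frame recount with inline formulas
brute_hbond_occupancy <- function(traj, d_idx, h_idx, a_idx,
                                  dmax = 3.5, amin = 120) {
  hits <- 0L
  for (f in seq_len(n_frames(traj))) {
    fr <- frame_coords(traj, f)
    dvec <- fr[a_idx, ] - fr[d_idx, ]
    dda <- sqrt(sum(dvec^2))
    u <- fr[d_idx, ] - fr[h_idx, ]; v <- fr[a_idx, ] - fr[h_idx, ]
    ang <- acos(min(max(sum(u * v) / sqrt(sum(u^2) * sum(v^2)), -1), 1)) * 180 / pi
    if (dda < dmax && ang > amin) hits <- hits + 1L
  }
  100 * hits / n_frames(traj)
}
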