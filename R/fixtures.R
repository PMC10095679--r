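# Small molecular fixtures with exactly controlled geometry: the ground
# truth for hydrogen-bond, salt-bridge, ring-stacking and ion-coordination
# detection.  Frame 0 reproduces the stated geometry to machine precision;
# later frames add isotropic Gaussian jitter.

#' Construct a molecular fixture
#'
#' @param trajectory `trajectory` object.
#' @param hbonds list of integer triplets `c(donor, hydrogen, acceptor)`
#'   (1-based particle indices).
#' @param charged_pairs list of integer pairs.
#' @param ring_groups list of integer index vectors (>= 3 members each).
#' @param ion_indices integer vector of ion particle indices.
#' @return object of class `molecular_fixture`.
#' @export
molecular_fixture <- function(trajectory, hbonds = list(),
                              charged_pairs = list(), ring_groups = list(),
                              ion_indices = integer()) {
  stopifnot(inherits(trajectory, "trajectory"))
  np <- n_particles(trajectory)
  idx <- c(unlist(hbonds), unlist(charged_pairs), unlist(ring_groups),
           ion_indices)
  if (length(idx) && (any(idx < 1L) || any(idx > np)))
    stop("fixture indices out of range for the trajectory")
  if (any(vapply(hbonds, length, 1L) != 3L))
    stop("each hbond entry must be a (donor, hydrogen, acceptor) triplet")
  if (any(vapply(ring_groups, length, 1L) < 3L))
    stop("each ring group needs >= 3 members")
  structure(list(trajectory = trajectory, hbonds = hbonds,
                 charged_pairs = charged_pairs, ring_groups = ring_groups,
                 ion_indices = as.integer(ion_indices)),
            class = "molecular_fixture")
}

.jittered_frames <- function(frame0, n_frames, jitter) {
  np <- nrow(frame0)
  coords <- array(0, c(n_frames, np, 3L))
  coords[1L, , ] <- frame0
  if (n_frames > 1L) {
    for (f in 2:n_frames)
      coords[f, , ] <- frame0 + matrix(rnorm(np * 3L, 0, jitter), np, 3L)
  }
  coords
}

#' Donor-H-acceptor hydrogen-bond fixture
#'
#' Three particles: donor N at the origin, hydrogen 1.0 Angstrom away along
#' +x, and acceptor O placed in the xy-plane so that frame 0 has exactly the
#' requested acceptor-donor distance and acceptor-H-donor angle (the angle
#' at the hydrogen).  Frames after the first add Gaussian jitter of the
#' stated width to every coordinate.
#'
#' @param distance acceptor-donor distance, Angstrom (> 0).
#' @param angle acceptor-H-donor angle, degrees, in (0, 180].
#' @param n_frames number of frames.
#' @param jitter per-coordinate Gaussian jitter, Angstrom.
#' @param seed integer seed.
#' @return `molecular_fixture` with one hbond triplet.
#' @export
make_hbond_fixture <- function(distance, angle, n_frames = 1L, jitter = 0,
                               seed = 1L) {
  if (distance <= 0) stop("distance must be > 0")
  if (angle <= 0 || angle > 180) stop("angle must lie in (0, 180]")
  if (n_frames < 1L) stop("n_frames must be >= 1")
  alpha <- angle * pi / 180
  # law of cosines in the D-H-A triangle with |DH| = 1:
  # |DA|^2 = 1 + t^2 - 2 t cos(alpha), t = |HA|
  disc <- cos(alpha)^2 - 1 + distance^2
  if (disc < 0) stop("no acceptor position realises this distance/angle pair")
  t <- cos(alpha) + sqrt(disc)
  if (t <= 0) stop("no acceptor position realises this distance/angle pair")
  donor <- c(0, 0, 0)
  hydrogen <- c(1, 0, 0)
  acceptor <- hydrogen + t * c(-cos(alpha), sin(alpha), 0)
  # Snap the frame-0 geometry so the values recomputed from the stored
  # coordinates land on the criterion-safe side of floating-point rounding:
  # the recomputed distance is >= the request and the recomputed angle is
  # <= the request.  A fixture built exactly at a strict threshold
  # ("< 3.5 A", "> 120 deg") then never satisfies it, independent of ulps.
  meas <- function(a) {
    d <- sqrt(sum((a - donor)^2))
    hd <- donor - hydrogen; ha <- a - hydrogen
    cs <- sum(hd * ha) / (sqrt(sum(hd^2)) * sqrt(sum(ha^2)))
    c(d, acos(min(max(cs, -1), 1)) * 180 / pi)
  }
  for (i in 1:20) {
    m <- meas(acceptor)
    if (m[1L] < distance) { acceptor <- acceptor * (1 + 2^-51); next }
    if (m[2L] > angle) {
      # rotate the acceptor about the donor (distance-preserving) by a tiny
      # step in whichever in-plane direction reduces the angle at H
      rot <- function(a, e) {
        cs <- cos(e); sn <- sin(e)
        c(cs * a[1L] - sn * a[2L], sn * a[1L] + cs * a[2L], a[3L])
      }
      step <- 2^-44
      acceptor <- if (meas(rot(acceptor, step))[2L] < m[2L])
        rot(acceptor, step) else rot(acceptor, -step)
      next
    }
    break
  }
  frame0 <- rbind(donor, hydrogen, acceptor)
  set.seed(seed)
  coords <- .jittered_frames(frame0, n_frames, jitter)
  labels <- data.frame(name = c("N", "H", "O"), resid = c(1L, 1L, 2L),
                       resname = c("DON", "DON", "ACC"),
                       element = c("N", "H", "O"), stringsAsFactors = FALSE)
  molecular_fixture(trajectory(coords, labels),
                    hbonds = list(c(1L, 2L, 3L)))
}

#' Stacked aromatic-ring fixture
#'
#' Two parallel regular hexagons of C atoms (ring radius 1.39 Angstrom,
#' benzene-like), stacked along z with the requested centroid separation.
#'
#' @param separation centroid-centroid distance, Angstrom.
#' @param n_frames number of frames.
#' @param jitter Gaussian jitter for frames after the first, Angstrom.
#' @param seed integer seed.
#' @return `molecular_fixture` with two ring groups.
#' @export
make_ring_fixture <- function(separation, n_frames = 1L, jitter = 0,
                              seed = 1L) {
  if (separation <= 0) stop("separation must be > 0")
  ang <- 2 * pi * (0:5) / 6
  hex <- cbind(1.39 * cos(ang), 1.39 * sin(ang), 0)
  frame0 <- rbind(hex, sweep(hex, 2L, c(0, 0, separation), "+"))
  set.seed(seed)
  coords <- .jittered_frames(frame0, n_frames, jitter)
  labels <- data.frame(name = paste0("C", rep(1:6, 2)),
                       resid = rep(c(1L, 2L), each = 6L),
                       resname = rep(c("PHE", "GUA"), each = 6L),
                       element = "C", stringsAsFactors = FALSE)
  molecular_fixture(trajectory(coords, labels),
                    ring_groups = list(1:6, 7:12))
}

#' Bimodal ion-coordination fixture
#'
#' An ion and a coordinating oxygen whose separation alternates between two
#' states (e.g. bound at 1.9 Angstrom, unbound at 4.6 Angstrom) with the
#' stated probability of the first state; optional Gaussian spread about
#' each state distance.
#'
#' @param d1,d2 the two state distances, Angstrom.
#' @param p1 probability of state 1 per frame.
#' @param n_frames number of frames (>= 10).
#' @param spread Gaussian width about each state distance, Angstrom.
#' @param seed integer seed.
#' @return `molecular_fixture` with `ion_indices = 1` and one charged pair.
#' @export
make_ion_fixture <- function(d1 = 1.9, d2 = 4.6, p1 = 0.5, n_frames = 1000L,
                             spread = 0.05, seed = 1L) {
  if (n_frames < 10L) stop("n_frames must be >= 10")
  if (p1 < 0 || p1 > 1) stop("p1 must lie in [0, 1]")
  set.seed(seed)
  state <- stats::runif(n_frames) < p1
  d <- ifelse(state, d1, d2) + rnorm(n_frames, 0, spread)
  coords <- array(0, c(n_frames, 2L, 3L))
  coords[, 2L, 1L] <- d
  labels <- data.frame(name = c("MG", "OG1"), resid = c(1L, 2L),
                       resname = c("MG", "SER"), element = c("MG", "O"),
                       stringsAsFactors = FALSE)
  out <- molecular_fixture(trajectory(coords, labels),
                           charged_pairs = list(c(1L, 2L)),
                           ion_indices = 1L)
  attr(out, "states") <- state
  out
}
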