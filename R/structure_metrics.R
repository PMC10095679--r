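# Rigid-body superposition and per-frame / per-particle descriptors:
# best-fit RMSD series, RMSF about the iteratively aligned mean structure,
# delta-RMSF profiles, radius of gyration, reaction-coordinate distance
# series and peak-reporting probability distributions.

.AMINO3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
             "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
             "TYR", "VAL", "HID", "HIE", "HIP")

#' Resolve an atom selection
#'
#' Either pass filters directly (`name=`, `element=`, `resid=`, `resname=`,
#' `exclude_element=`) or a selection expression string, e.g.
#' `"name CA"`, `"protein and not element H"`, `"resid 30-40"`.  The
#' expression grammar supports `and`, `or`, `not`, parentheses, and the
#' primaries `name`, `element`, `resname`, `resid` (single values,
#' comma-lists, or `a-b` ranges) plus the keyword `protein` (standard
#' amino-acid residue names) and `all`.
#'
#' @param traj `trajectory`.
#' @param expr selection expression string (optional).
#' @param name,element,resname character filters (optional).
#' @param resid integer vector of residue ids (optional).
#' @param exclude_element drop these elements (optional).
#' @return sorted integer vector of particle indices (1-based); error if
#'   empty.
#' @export
select_atoms <- function(traj, expr = NULL, name = NULL, element = NULL,
                         resname = NULL, resid = NULL,
                         exclude_element = NULL) {
  stopifnot(inherits(traj, "trajectory"))
  lab <- traj$labels
  keep <- rep(TRUE, nrow(lab))
  if (!is.null(expr)) keep <- keep & .parse_selection(expr, lab)
  if (!is.null(name)) keep <- keep & lab$name %in% name
  if (!is.null(element)) keep <- keep & toupper(lab$element) %in% toupper(element)
  if (!is.null(resname)) keep <- keep & lab$resname %in% resname
  if (!is.null(resid)) keep <- keep & lab$resid %in% resid
  if (!is.null(exclude_element))
    keep <- keep & !(toupper(lab$element) %in% toupper(exclude_element))
  idx <- which(keep)
  if (!length(idx)) stop("selection resolves to zero particles")
  sort(unique(idx))
}

# tiny recursive-descent parser for the selection mini-language
.parse_selection <- function(expr, lab) {
  toks <- regmatches(expr, gregexpr("\\(|\\)|[^()[:space:]]+", expr))[[1L]]
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else ""
  advance <- function() { t <- toks[pos]; pos <<- pos + 1L; t }
  parse_or <- function() {
    v <- parse_and()
    while (tolower(peek()) == "or") { advance(); v <- v | parse_and() }
    v
  }
  parse_and <- function() {
    v <- parse_not()
    while (tolower(peek()) == "and") { advance(); v <- v & parse_not() }
    v
  }
  parse_not <- function() {
    if (tolower(peek()) == "not") { advance(); return(!parse_not()) }
    parse_primary()
  }
  value_list <- function() {
    vals <- character(0)
    while (pos <= length(toks) &&
           !tolower(peek()) %in% c("and", "or", "not") &&
           !peek() %in% c("(", ")")) {
      vals <- c(vals, strsplit(advance(), ",")[[1L]])
      if (length(vals) && pos <= length(toks) &&
          !grepl(",", toks[pos - 1L])) break
    }
    if (!length(vals)) stop("selection: expected value(s)")
    vals
  }
  parse_primary <- function() {
    t <- tolower(peek())
    if (t == "(") {
      advance(); v <- parse_or()
      if (peek() != ")") stop("selection: unbalanced parentheses")
      advance(); return(v)
    }
    advance()
    switch(t,
      protein = lab$resname %in% .AMINO3,
      all = rep(TRUE, nrow(lab)),
      name = lab$name %in% value_list(),
      element = toupper(lab$element) %in% toupper(value_list()),
      resname = lab$resname %in% value_list(),
      resid = {
        vals <- value_list()
        ids <- unlist(lapply(vals, function(v) {
          if (grepl("^-?[0-9]+--?[0-9]+$", v) || grepl("^[0-9]+-[0-9]+$", v)) {
            ab <- as.integer(strsplit(v, "-")[[1L]])
            seq.int(ab[1L], ab[2L])
          } else as.integer(v)
        }))
        lab$resid %in% ids
      },
      stop("selection: unknown keyword '", t, "'")
    )
  }
  v <- parse_or()
  if (pos <= length(toks)) stop("selection: trailing tokens")
  v
}

#' Weighted Kabsch superposition
#'
#' Finds the proper rotation (determinant +1; reflections excluded) and
#' translation minimising the weighted squared deviation between `mobile`
#' and `reference`, via SVD of the weighted covariance of the centred
#' coordinate sets.
#'
#' @param mobile,reference `particles x 3` matrices.
#' @param weights optional non-negative weights (e.g. masses).
#' @return list with `rotation` (3x3; apply as `mobile %*% rotation`),
#'   `translation` (length 3), and `rmsd` (Angstrom, weighted, post-fit).
#'   `mobile %*% rotation + translation` superposes onto `reference`.
#' @export
kabsch_superpose <- function(mobile, reference, weights = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (!all(dim(mobile) == dim(reference)) || ncol(mobile) != 3L)
    stop("mobile and reference must be equal-shaped particles x 3 matrices")
  n <- nrow(mobile)
  if (n < 3L) stop("degenerate fit: need >= 3 particles")
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n || any(weights < 0) || sum(weights) == 0)
    stop("invalid weights")
  w <- weights / sum(weights)
  cm <- colSums(mobile * w); cr <- colSums(reference * w)
  m <- sweep(mobile, 2L, cm); r <- sweep(reference, 2L, cr)
  h <- t(m) %*% (r * w)
  sv <- svd(h)
  if (sv$d[2L] < 1e-12 * max(sv$d[1L], 1e-300))
    stop("degenerate fit: rank-deficient (collinear) configuration")
  d <- sign(det(sv$u %*% t(sv$v)))
  rot <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  fitted <- m %*% rot
  rmsd <- sqrt(sum(w * rowSums((fitted - r)^2)))
  list(rotation = rot, translation = as.numeric(cr - cm %*% rot), rmsd = rmsd)
}

#' Best-fit RMSD per frame
#'
#' Each frame's selected particles are superposed onto the reference by
#' [kabsch_superpose()] (same selection for fit and measurement) and the
#' post-fit RMSD is reported.
#'
#' @param traj `trajectory`.
#' @param reference_frame frame index used as reference, or a
#'   `particles x 3` matrix covering the selection.
#' @param selection integer particle indices (default: all).
#' @param weights optional per-particle weights over the selection.
#' @return numeric vector, Angstrom per frame.
#' @export
rmsd_series <- function(traj, reference_frame = 1L, selection = NULL,
                        weights = NULL) {
  stopifnot(inherits(traj, "trajectory"))
  if (is.null(selection)) selection <- seq_len(n_particles(traj))
  ref <- if (is.matrix(reference_frame)) reference_frame
         else frame_coords(traj, reference_frame)[selection, , drop = FALSE]
  if (nrow(ref) != length(selection))
    stop("reference does not cover the selection")
  vapply(seq_len(n_frames(traj)), function(f)
    kabsch_superpose(frame_coords(traj, f)[selection, , drop = FALSE],
                     ref, weights)$rmsd, 0)
}

# Align all frames of a selection to the iteratively refined mean structure
# (`passes` rounds; frame 1 seeds the first reference).  Returns the
# aligned frames x n_sel x 3 array and the final mean.
.align_to_mean <- function(traj, selection, passes = 2L) {
  nf <- n_frames(traj)
  sub <- traj$coords[, selection, , drop = FALSE]
  ref <- matrix(sub[1L, , ], ncol = 3L)
  aligned <- array(0, dim(sub))
  for (p in seq_len(passes)) {
    for (f in seq_len(nf)) {
      fr <- matrix(sub[f, , ], ncol = 3L)
      k <- kabsch_superpose(fr, ref)
      aligned[f, , ] <- sweep(fr %*% k$rotation, 2L, k$translation, "+")
    }
    ref <- apply(aligned, c(2L, 3L), mean)
  }
  list(aligned = aligned, mean = ref)
}

#' Root-mean-square fluctuation profile
#'
#' Per-particle `sqrt(<|r_t - <r>|^2>)` about the mean structure.  With
#' `align = TRUE` (default) frames are first superposed onto the
#' iteratively refined mean (2 passes), the standard essential-dynamics
#' convention.
#'
#' @param traj `trajectory` with >= 2 frames.
#' @param selection integer particle indices (default: all).
#' @param align superpose frames before measuring.
#' @return object of class `rmsf_profile`: `rmsf` (Angstrom per selected
#'   particle), `selection`, `reference_kind`.
#' @export
rmsf <- function(traj, selection = NULL, align = TRUE) {
  stopifnot(inherits(traj, "trajectory"))
  if (n_frames(traj) < 2L) stop("RMSF needs at least 2 frames")
  if (is.null(selection)) selection <- seq_len(n_particles(traj))
  if (align) {
    al <- .align_to_mean(traj, selection)
    arr <- al$aligned; mu <- al$mean
  } else {
    arr <- traj$coords[, selection, , drop = FALSE]
    mu <- apply(arr, c(2L, 3L), mean)
  }
  dev2 <- 0
  for (d in 1:3) dev2 <- dev2 + sweep(arr[, , d, drop = TRUE], 2L, mu[, d])^2
  structure(list(rmsf = sqrt(colMeans(matrix(dev2, nrow = dim(arr)[1L]))),
                 selection = selection,
                 reference_kind = if (align) "mean" else "mean-unaligned"),
            class = "rmsf_profile")
}

#' Difference of two RMSF profiles
#'
#' `delta = a - b` elementwise (e.g. mutant minus wild type).
#'
#' @param a,b `rmsf_profile` objects over selections of equal length.
#' @return numeric vector, Angstrom per particle.
#' @export
delta_rmsf <- function(a, b) {
  stopifnot(inherits(a, "rmsf_profile"), inherits(b, "rmsf_profile"))
  if (length(a$rmsf) != length(b$rmsf))
    stop("RMSF profiles have different lengths")
  a$rmsf - b$rmsf
}

#' Radius of gyration per frame
#'
#' `sqrt(sum_i m_i |r_i - r_com|^2 / sum_i m_i)`; `mass_weighted = FALSE`
#' sets all masses to 1.
#'
#' @param traj `trajectory`.
#' @param selection integer particle indices (default: all).
#' @param mass_weighted logical.
#' @return numeric vector, Angstrom per frame.
#' @export
radius_of_gyration <- function(traj, selection = NULL, mass_weighted = TRUE) {
  stopifnot(inherits(traj, "trajectory"))
  if (is.null(selection)) selection <- seq_len(n_particles(traj))
  m <- if (mass_weighted) traj$masses[selection] else rep(1, length(selection))
  w <- m / sum(m)
  vapply(seq_len(n_frames(traj)), function(f) {
    fr <- frame_coords(traj, f)[selection, , drop = FALSE]
    com <- colSums(fr * w)
    sqrt(sum(w * rowSums(sweep(fr, 2L, com)^2)))
  }, 0)
}

#' Inter-particle distance series
#'
#' Euclidean distance between two particles in every frame (no periodic
#' imaging).
#'
#' @param traj `trajectory`.
#' @param particle_i,particle_j particle indices (1-based).
#' @return numeric vector, Angstrom per frame.
#' @export
rc_distance_series <- function(traj, particle_i, particle_j) {
  stopifnot(inherits(traj, "trajectory"))
  np <- n_particles(traj)
  if (any(c(particle_i, particle_j) < 1L) || any(c(particle_i, particle_j) > np))
    stop("particle index out of range")
  d <- traj$coords[, particle_i, , drop = TRUE] -
       traj$coords[, particle_j, , drop = TRUE]
  if (is.null(dim(d))) d <- matrix(d, ncol = 3L)
  sqrt(rowSums(d^2))
}

#' Distance series between labelled atoms of two residues
#'
#' Looks up one atom per (residue id, atom name) pair, e.g. the C-alpha of
#' residue 32 versus the C-alpha of residue 61.
#'
#' @param traj `trajectory`.
#' @param residue_a,residue_b residue ids.
#' @param atom_name_a,atom_name_b atom names.
#' @return numeric vector, Angstrom per frame.
#' @export
rc_from_selection_pair <- function(traj, residue_a, atom_name_a,
                                   residue_b, atom_name_b) {
  lookup <- function(resid, nm) {
    i <- which(traj$labels$resid == resid & traj$labels$name == nm)
    if (length(i) != 1L)
      stop(sprintf("atom '%s' of residue %s resolves to %d particles",
                   nm, resid, length(i)))
    i
  }
  rc_distance_series(traj, lookup(residue_a, atom_name_a),
                     lookup(residue_b, atom_name_b))
}

#' Unit-area probability distribution with peak report
#'
#' Histogram density normalised so that its trapezoidal integral over the
#' bin centres is exactly 1.  Peaks are interior local maxima (plateaus
#' resolve to the leftmost bin, boundary bins qualify against their single
#' neighbour), reported at bin centres and sorted by height descending.
#' With `smooth = TRUE` a 3-bin moving average is applied before peak
#' detection (the reported density is unsmoothed).
#'
#' @param series numeric samples (>= 10 unless constant).
#' @param bin_width bin width in the units of `series`.
#' @param smooth logical.
#' @return object of class `distribution_summary`: `bin_edges`, `centers`,
#'   `density`, `peak_positions`, `peak_heights`.
#' @export
probability_distribution <- function(series, bin_width = 0.05,
                                     smooth = FALSE) {
  series <- as.numeric(series)
  if (stats::sd(series) == 0) {
    ctr <- series[1L]
    edges <- c(ctr - bin_width / 2, ctr + bin_width / 2)
    return(structure(list(bin_edges = edges, centers = ctr,
                          density = 1 / bin_width,
                          peak_positions = ctr,
                          peak_heights = 1 / bin_width),
                     class = "distribution_summary"))
  }
  if (length(series) < 10L) stop("need >= 10 samples")
  lo <- floor(min(series) / bin_width) * bin_width
  hi <- ceiling(max(series) / bin_width) * bin_width
  if (hi <= lo) hi <- lo + bin_width
  edges <- seq(lo, hi + bin_width / 2, by = bin_width)
  counts <- tabulate(findInterval(series, edges, rightmost.closed = TRUE),
                     length(edges) - 1L)
  dens <- counts / (sum(counts) * bin_width)
  centers <- (head(edges, -1L) + tail(edges, -1L)) / 2
  # renormalise so the trapezoid rule over centres integrates to exactly 1
  if (length(centers) > 1L) {
    tz <- sum((dens[-1L] + dens[-length(dens)]) / 2 * diff(centers))
    if (tz > 0) dens <- dens / tz
  }
  prof <- dens
  if (smooth && length(prof) >= 3L)
    prof <- stats::filter(prof, rep(1 / 3, 3L), sides = 2L) |>
      (\(z) { z[is.na(z)] <- dens[is.na(z)]; as.numeric(z) })()
  peaks <- integer(0)
  nb <- length(prof)
  i <- 1L
  while (i <= nb) {
    j <- i
    while (j < nb && prof[j + 1L] == prof[i]) j <- j + 1L
    left_ok <- i == 1L || prof[i - 1L] < prof[i]
    right_ok <- j == nb || prof[j + 1L] < prof[i]
    if (left_ok && right_ok && prof[i] > 0) peaks <- c(peaks, i)
    i <- j + 1L
  }
  ordp <- peaks[order(-prof[peaks], centers[peaks])]
  structure(list(bin_edges = edges, centers = centers, density = dens,
                 peak_positions = centers[ordp],
                 peak_heights = dens[ordp]),
            class = "distribution_summary")
}

#' @export
print.distribution_summary <- function(x, ...) {
  cat(sprintf("<distribution_summary> %d bins, %d peak(s) at %s\n",
              length(x$density), length(x$peak_positions),
              paste(signif(x$peak_positions, 4), collapse = ", ")))
  invisible(x)
}
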