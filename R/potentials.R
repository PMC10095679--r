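# Analytic toy potentials with known Boltzmann ground truth.  A
# potential_spec couples an energy surface V (kcal/mol) over 1-2 coordinates
# (Angstrom) with its analytic gradient and the exact pointwise potential of
# mean force -kT ln p_Boltzmann, so that enhanced-sampling and reweighting
# code can be validated against closed-form references.

#' Construct a potential specification
#'
#' Low-level constructor. `energy` and `gradient` must accept an
#' `n x dimension` matrix of coordinates and return a length-`n` vector
#' (energies, kcal/mol) and an `n x dimension` matrix (gradient,
#' kcal/mol/Angstrom) respectively.
#'
#' @param dimension 1 or 2.
#' @param energy vectorised energy function.
#' @param gradient vectorised gradient function.
#' @param params named list of constants (well positions, depths, ...).
#' @param reference_pmf function mapping coordinates (and `kT`) to
#'   `-kT * ln p_Boltzmann`; exact up to the quadrature of the partition
#'   function.
#' @param kind internal tag selecting the compiled integrator path
#'   (`"double_well"`, `"multiwell_2d"`, or `"custom"`).
#' @return object of class `potential_spec`.
#' @export
potential_spec <- function(dimension, energy, gradient, params = list(),
                           reference_pmf = NULL, kind = "custom") {
  stopifnot(dimension %in% c(1L, 2L), is.function(energy), is.function(gradient))
  structure(list(dimension = as.integer(dimension), energy = energy,
                 gradient = gradient, params = params,
                 reference_pmf = reference_pmf, kind = kind),
            class = "potential_spec")
}

#' @export
print.potential_spec <- function(x, ...) {
  cat(sprintf("<potential_spec> kind=%s dimension=%d\n", x$kind, x$dimension))
  if (length(x$params)) {
    scal <- vapply(x$params, function(p) is.numeric(p) && length(p) == 1, TRUE)
    cat("  params:", paste(names(x$params)[scal],
                           signif(unlist(x$params[scal]), 4),
                           sep = "=", collapse = " "), "\n")
  }
  invisible(x)
}

.as_coord_matrix <- function(x, dimension) {
  if (is.null(dim(x))) {
    if (dimension == 1L) x <- matrix(x, ncol = 1L)
    else x <- matrix(x, ncol = dimension, byrow = TRUE)
  }
  stopifnot(ncol(x) == dimension)
  x
}

#' Symmetric quartic double-well potential
#'
#' `V(x) = h * ((x/a)^2 - 1)^2`: minima of zero energy at `x = +/- a`
#' (the wells are `2a` apart in curvature centres) and a barrier of height
#' `h` at `x = 0`.  The associated `reference_pmf` is the exact
#' `-kT ln p_Boltzmann` with the partition function evaluated by adaptive
#' quadrature.
#'
#' @param barrier_height barrier height `h` in kcal/mol (> 0).
#' @param well_separation half-distance `a` between the minima, Angstrom (> 0).
#' @param kT thermal energy used for the stored reference PMF, kcal/mol.
#' @return `potential_spec` with params `h`, `a`, `kT`, `start`.
#' @examples
#' dw <- make_double_well(6, 1)
#' dw$energy(c(-1, 0, 1)) # 0, 6, 0
#' @export
make_double_well <- function(barrier_height, well_separation, kT = 0.596161) {
  if (!is.numeric(barrier_height) || barrier_height <= 0)
    stop("barrier_height must be > 0")
  if (!is.numeric(well_separation) || well_separation <= 0)
    stop("well_separation must be > 0")
  if (!is.numeric(kT) || kT <= 0) stop("kT must be > 0")
  h <- barrier_height; a <- well_separation
  energy <- function(x) {
    x <- .as_coord_matrix(x, 1L)[, 1L]
    h * ((x / a)^2 - 1)^2
  }
  gradient <- function(x) {
    x <- .as_coord_matrix(x, 1L)[, 1L]
    matrix(4 * h * x * ((x / a)^2 - 1) / a^2, ncol = 1L)
  }
  # Z at construction-time kT; PMF(x) = V(x) + kT ln Z (absolute density scale)
  zfun <- function(kt) {
    stats::integrate(function(x) exp(-energy(x) / kt), -Inf, Inf,
                     rel.tol = 1e-10)$value
  }
  z0 <- zfun(kT)
  reference_pmf <- function(x, kt = kT) {
    z <- if (identical(kt, kT)) z0 else zfun(kt)
    energy(x) + kt * log(z)
  }
  potential_spec(1L, energy, gradient,
                 params = list(h = h, a = a, kT = kT, start = a),
                 reference_pmf = reference_pmf, kind = "double_well")
}

#' Two-dimensional multi-well potential
#'
#' A sum of inverted Gaussians (one per well) plus a confining quartic wall:
#' `V(r) = -sum_i d_i exp(-|r - c_i|^2 / (2 w^2)) + h_w (|r|^2 / r0^2)^2`.
#' The gradient is analytic.  `reference_pmf` evaluates
#' `-kT ln p_Boltzmann` with the 2D partition function computed by grid
#' quadrature on demand.
#'
#' @param depths numeric vector of well depths, kcal/mol (length >= 2).
#' @param centers matrix `n_wells x 2` of well centres, Angstrom.
#' @param width common Gaussian width `w`, Angstrom.
#' @param wall_height quartic wall prefactor, kcal/mol.
#' @return `potential_spec` of dimension 2.
#' @export
make_multiwell_2d <- function(depths, centers, width, wall_height = 20) {
  centers <- .as_coord_matrix(centers, 2L)
  n_wells <- nrow(centers)
  if (n_wells < 2) stop("need at least 2 wells")
  if (length(depths) != n_wells) stop("length(depths) must equal nrow(centers)")
  if (width <= 0) stop("width must be > 0")
  dd <- as.matrix(stats::dist(centers))
  if (any(dd[upper.tri(dd)] < width))
    warning("well centres closer than `width`: wells will merge")
  r0 <- max(sqrt(rowSums(centers^2))) + 3 * width
  energy <- function(x) {
    x <- .as_coord_matrix(x, 2L)
    v <- wall_height * ((x[, 1L]^2 + x[, 2L]^2) / r0^2)^2
    for (i in seq_len(n_wells)) {
      d2 <- (x[, 1L] - centers[i, 1L])^2 + (x[, 2L] - centers[i, 2L])^2
      v <- v - depths[i] * exp(-d2 / (2 * width^2))
    }
    v
  }
  gradient <- function(x) {
    x <- .as_coord_matrix(x, 2L)
    r2 <- x[, 1L]^2 + x[, 2L]^2
    g <- 4 * wall_height * r2 / r0^4 * x
    for (i in seq_len(n_wells)) {
      dx <- x[, 1L] - centers[i, 1L]; dy <- x[, 2L] - centers[i, 2L]
      e <- depths[i] * exp(-(dx^2 + dy^2) / (2 * width^2)) / width^2
      g[, 1L] <- g[, 1L] + e * dx
      g[, 2L] <- g[, 2L] + e * dy
    }
    g
  }
  zcache <- new.env(parent = emptyenv())
  zfun <- function(kt) {
    key <- format(kt, digits = 12)
    if (!is.null(zcache[[key]])) return(zcache[[key]])
    lim <- r0 + 2 * width
    gx <- seq(-lim, lim, length.out = 401L)
    gg <- as.matrix(expand.grid(gx, gx))
    z <- sum(exp(-energy(gg) / kt)) * diff(gx[1:2])^2
    zcache[[key]] <- z
    z
  }
  reference_pmf <- function(x, kt) energy(x) + kt * log(zfun(kt))
  potential_spec(2L, energy, gradient,
                 params = list(depths = depths, centers = centers,
                               width = width, wall_height = wall_height,
                               wall_r0 = r0, start = centers[1L, ]),
                 reference_pmf = reference_pmf, kind = "multiwell_2d")
}

#' Check a potential's gradient against central differences
#'
#' @param spec `potential_spec`.
#' @param points matrix of probe coordinates.
#' @param h finite-difference step.
#' @return maximum relative error across probe points and components.
#' @export
check_gradient <- function(spec, points, h = 1e-5) {
  points <- .as_coord_matrix(points, spec$dimension)
  g <- spec$gradient(points)
  num <- g
  for (d in seq_len(spec$dimension)) {
    p1 <- points; p1[, d] <- p1[, d] + h
    p2 <- points; p2[, d] <- p2[, d] - h
    num[, d] <- (spec$energy(p1) - spec$energy(p2)) / (2 * h)
  }
  scale <- pmax(abs(g), abs(num), 1e-8)
  max(abs(g - num) / scale)
}
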