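# Gaussian-accelerated dynamics on toy potentials.  A conventional Langevin
# run supplies the potential-energy statistics (Vmax, Vmin, Vavg, sigma_V);
# the boost parameters (E, k0, k) are derived from them once and frozen; the
# boosted run samples V* = V + dV with dV = k/2 (E - V)^2 below the
# threshold E, recording dV per frame for reweighting.

#' Potential-energy statistics from a conventional run
#'
#' @param v numeric vector of sampled potential energies, kcal/mol.
#' @return object of class `potential_stats` with fields `v_max`, `v_min`,
#'   `v_avg`, `sigma_v`, `n_samples`.
#' @export
potential_stats <- function(v) {
  v <- as.numeric(v)
  if (length(v) < 2L) stop("need at least 2 potential-energy samples")
  structure(list(v_max = max(v), v_min = min(v), v_avg = mean(v),
                 sigma_v = stats::sd(v), n_samples = length(v)),
            class = "potential_stats")
}

#' @export
print.potential_stats <- function(x, ...) {
  cat(sprintf("<potential_stats> n=%d Vmin=%.4g Vavg=%.4g Vmax=%.4g sigmaV=%.4g\n",
              x$n_samples, x$v_min, x$v_avg, x$v_max, x$sigma_v))
  invisible(x)
}

.validate_stats <- function(stats) {
  stopifnot(inherits(stats, "potential_stats"))
  if (!(stats$v_min <= stats$v_avg && stats$v_avg <= stats$v_max))
    stop("invalid potential statistics: require v_min <= v_avg <= v_max")
  if (stats$v_max == stats$v_min)
    stop("degenerate potential statistics: v_max == v_min")
  if (stats$sigma_v <= 0) stop("sigma_v must be > 0")
  invisible(stats)
}

#' Derive GaMD boost parameters from potential statistics
#'
#' With `E` at the lower bound (`E = Vmax`):
#' `k0 = min(1, (sigma0/sigma_V) * (Vmax - Vmin)/(Vmax - Vavg))`.
#' With `E` at the upper bound (`E = Vmin + 1/k`):
#' `k0 = (1 - sigma0/sigma_V) * (Vmax - Vmin)/(Vavg - Vmin)`; if that k0
#' falls outside (0, 1] the construction falls back to the lower bound with
#' a warning.  In both cases `k = k0 / (Vmax - Vmin)` and the threshold
#' satisfies `Vmax <= E <= Vmin + 1/k`.  `sigma0 = 0` gives `k0 = 0`: the
#' boost vanishes identically and the dynamics reduce to conventional MD.
#'
#' @param stats `potential_stats` from a conventional run.
#' @param sigma0 user ceiling on the boost standard deviation, kcal/mol (>= 0).
#' @param bound_mode `"lower"` or `"upper"`.
#' @return object of class `boost_params` with fields `sigma0`,
#'   `bound_mode`, `k0`, `k`, `threshold_e`, `stats`.
#' @export
compute_boost_params <- function(stats, sigma0, bound_mode = c("lower", "upper")) {
  .validate_stats(stats)
  bound_mode <- match.arg(bound_mode)
  if (sigma0 < 0) stop("sigma0 must be >= 0")
  vmax <- stats$v_max; vmin <- stats$v_min; vavg <- stats$v_avg
  sv <- stats$sigma_v
  if (bound_mode == "upper") {
    k0 <- (1 - sigma0 / sv) * (vmax - vmin) / (vavg - vmin)
    if (!is.finite(k0) || k0 <= 0 || k0 > 1) {
      warning(sprintf(
        "upper-bound k0 = %.4g outside (0, 1]; falling back to lower bound", k0))
      bound_mode <- "lower"
    }
  }
  if (bound_mode == "lower") {
    k0 <- if (vmax == vavg) 1 else
      min(1, (sigma0 / sv) * (vmax - vmin) / (vmax - vavg))
  }
  k <- k0 / (vmax - vmin)
  e <- if (bound_mode == "lower") vmax else vmin + 1 / k
  if (k0 > 0) {
    upper <- vmin + 1 / k
    tol <- 1e-9 * max(abs(vmax), abs(vmin), vmax - vmin)
    if (e < vmax - tol || e > upper + tol)
      stop("threshold E violates Vmax <= E <= Vmin + 1/k")
  }
  structure(list(sigma0 = sigma0, bound_mode = bound_mode, k0 = k0, k = k,
                 threshold_e = e, stats = stats),
            class = "boost_params")
}

#' @export
print.boost_params <- function(x, ...) {
  cat(sprintf("<boost_params> mode=%s sigma0=%.4g k0=%.6g k=%.6g E=%.6g\n",
              x$bound_mode, x$sigma0, x$k0, x$k, x$threshold_e))
  invisible(x)
}

#' Harmonic boost energy
#'
#' `dV = 0` for `V >= E` and `dV = k/2 (E - V)^2` for `V < E`; the modified
#' potential is `V* = V + dV`.
#'
#' @param v potential energy (vectorised), kcal/mol.
#' @param params `boost_params`.
#' @return boost energy dV >= 0, kcal/mol.
#' @export
boost_energy <- function(v, params) {
  stopifnot(inherits(params, "boost_params"))
  0.5 * params$k * pmax(params$threshold_e - v, 0)^2
}

#' Stable default timestep for a potential
#'
#' Probes the stiffest curvature of the energy surface on a coarse grid
#' around the start point and returns `dt = 0.25 / omega_max` (about 1/25
#' of the fastest oscillation period), which keeps velocity-Verlet energy
#' drift at zero friction below 1e-3 kcal/mol per 1000 steps on the
#' built-in potentials.
#'
#' @param potential `potential_spec`.
#' @param mass particle mass, amu.
#' @return timestep in ps.
#' @export
default_dt <- function(potential, mass = 1) {
  dim <- potential$dimension
  start <- potential$params$start
  if (is.null(start)) start <- rep(0, dim)
  span <- max(abs(unlist(potential$params[c("a", "wall_r0")])), 2)
  probes <- as.matrix(expand.grid(rep(list(seq(-span, span, length.out = 15L)),
                                      dim)))
  h <- 1e-4
  kmax <- 0
  for (d in seq_len(dim)) {
    p1 <- probes; p1[, d] <- p1[, d] + h
    p2 <- probes; p2[, d] <- p2[, d] - h
    curv <- (potential$energy(p1) - 2 * potential$energy(probes) +
               potential$energy(p2)) / h^2
    kmax <- max(kmax, max(abs(curv)))
  }
  omega <- sqrt(max(kmax, 1e-6) * .KCAL_PER_AMU_A2_PS2 / mass)
  0.25 / omega
}

# Pure-R BAOAB integrator, RNG-stream compatible with the compiled path:
# one Maxwell draw per coordinate at start, one Gaussian per coordinate per
# step in the O sub-step.
.langevin_core_r <- function(potential, x0, mass, temperature, friction, dt,
                             n_steps, stride, boost_e, boost_k, boosted) {
  dim <- potential$dimension
  kt <- kT(temperature)
  c1 <- exp(-friction * dt)
  c2 <- sqrt(kt * .KCAL_PER_AMU_A2_PS2 / mass * (1 - c1^2))
  vsd <- sqrt(kt * .KCAL_PER_AMU_A2_PS2 / mass)
  x <- as.numeric(x0)
  v <- vsd * rnorm(dim)
  eval_state <- function(x) {
    V <- potential$energy(matrix(x, 1L))
    g <- as.numeric(potential$gradient(matrix(x, 1L)))
    dV <- 0; scale <- 1
    if (boosted && V < boost_e) {
      dV <- 0.5 * boost_k * (boost_e - V)^2
      scale <- 1 - boost_k * (boost_e - V)
    }
    list(V = V, dV = dV, F = -g * scale)
  }
  st <- eval_state(x)
  n_store <- n_steps %/% stride
  coords <- matrix(0, n_store, dim)
  vser <- numeric(n_store); dvser <- numeric(n_store)
  stored <- 0L; diverged <- 0L
  acc <- .KCAL_PER_AMU_A2_PS2 / mass
  for (step in seq_len(n_steps)) {
    v <- v + 0.5 * dt * st$F * acc
    x <- x + 0.5 * dt * v
    v <- c1 * v + c2 * rnorm(dim)
    x <- x + 0.5 * dt * v
    st <- eval_state(x)
    v <- v + 0.5 * dt * st$F * acc
    if (!is.finite(st$V) || abs(st$V) > 1e8) { diverged <- step; break }
    if (step %% stride == 0L && stored < n_store) {
      stored <- stored + 1L
      coords[stored, ] <- x
      vser[stored] <- st$V
      dvser[stored] <- st$dV
    }
  }
  list(coords = coords, v = vser, dv = dvser, stored = stored,
       diverged = diverged)
}

.run_langevin <- function(potential, temperature, friction, dt, n_steps,
                          stride, seed, mass, x0, boost_e, boost_k, boosted,
                          use_compiled = TRUE) {
  if (is.null(dt)) dt <- default_dt(potential, mass)
  if (is.null(x0)) {
    x0 <- potential$params$start
    if (is.null(x0)) x0 <- rep(0, potential$dimension)
  }
  set.seed(seed)
  kind <- match(potential$kind, c("double_well", "multiwell_2d"))
  if (use_compiled && !is.na(kind)) {
    p <- potential$params
    params <- if (kind == 1L) c(p$h, p$a) else
      c(nrow(p$centers), p$width, p$wall_height, p$wall_r0,
        p$depths, p$centers[, 1L], p$centers[, 2L])
    res <- .langevin_core_cpp(kind, params, as.numeric(x0), mass, temperature,
                              friction, dt, as.integer(n_steps),
                              as.integer(stride), boost_e, boost_k, boosted)
  } else {
    res <- .langevin_core_r(potential, x0, mass, temperature, friction, dt,
                            n_steps, stride, boost_e, boost_k, boosted)
  }
  if (res$diverged > 0L)
    stop(sprintf(paste0("energy diverged (|V| > 1e8) at step %d: ",
                        "reduce dt (current %.3g ps) or check the potential"),
                 res$diverged, dt))
  res$dt <- dt
  res
}

#' Conventional Langevin sampling of a toy potential
#'
#' BAOAB Langevin integration at the stated temperature with Maxwell-
#' distributed initial velocities.  The returned potential statistics are
#' computed over stored frames after discarding the burn-in fraction; they
#' parameterise [compute_boost_params()].
#'
#' @param potential `potential_spec`.
#' @param temperature Kelvin.
#' @param friction Langevin collision frequency, ps^-1 (default 2.0).
#' @param dt timestep, ps; `NULL` picks [default_dt()].
#' @param n_steps number of integration steps.
#' @param stride store every `stride`-th step.
#' @param seed integer seed (all randomness flows from it).
#' @param mass particle mass, amu.
#' @param x0 start coordinates; defaults to the potential's `start` param.
#' @param burn_in fraction of stored frames excluded from the statistics.
#' @param use_compiled use the compiled integrator when the potential family
#'   supports it (pure-R fallback otherwise, and always for custom
#'   potentials).
#' @return list with `coords` (stored frames x dimension matrix), `v_series`
#'   (kcal/mol), `stats` (`potential_stats`), `dt`, `stride`, `seed`.
#' @export
run_cmd <- function(potential, temperature = 300, friction = 2.0, dt = NULL,
                    n_steps = 100000L, stride = 10L, seed = 1L, mass = 1,
                    x0 = NULL, burn_in = 0.1, use_compiled = TRUE) {
  stopifnot(inherits(potential, "potential_spec"))
  if (temperature <= 0) stop("temperature must be > 0")
  if (!is.null(dt) && dt <= 0) stop("dt must be > 0")
  if (n_steps < stride) stop("n_steps must be >= stride")
  res <- .run_langevin(potential, temperature, friction, dt, n_steps, stride,
                       seed, mass, x0, 0, 0, FALSE, use_compiled)
  keep <- seq.int(floor(burn_in * res$stored) + 1L, res$stored)
  list(coords = res$coords, v_series = res$v,
       stats = potential_stats(res$v[keep]), dt = res$dt, stride = stride,
       seed = seed, temperature = temperature)
}

#' Gaussian-accelerated Langevin sampling
#'
#' Integrates on the modified surface `V* = V + dV` (forces scaled by
#' `1 - k (E - V)` wherever `V < E`) and records per-frame `V` and `dV`
#' for free-energy reweighting.
#'
#' @inheritParams run_cmd
#' @param params `boost_params` from [compute_boost_params()].
#' @return object of class `boosted_trajectory`: `coords`, `v_series`,
#'   `dv_series`, `params`, `temperature`, `seed`, `dt`, `stride`.
#' @export
run_gamd <- function(potential, params, temperature = 300, friction = 2.0,
                     dt = NULL, n_steps = 100000L, stride = 10L, seed = 1L,
                     mass = 1, x0 = NULL, use_compiled = TRUE) {
  stopifnot(inherits(potential, "potential_spec"),
            inherits(params, "boost_params"))
  if (n_steps < stride) stop("n_steps must be >= stride")
  res <- .run_langevin(potential, temperature, friction, dt, n_steps, stride,
                       seed, mass, x0, params$threshold_e, params$k,
                       params$k0 > 0, use_compiled)
  structure(list(coords = res$coords, v_series = res$v, dv_series = res$dv,
                 params = params, temperature = temperature, seed = seed,
                 dt = res$dt, stride = stride),
            class = "boosted_trajectory")
}

#' @export
print.boosted_trajectory <- function(x, ...) {
  cat(sprintf("<boosted_trajectory> %d frames, <dV>=%.3g kcal/mol (E=%.4g, k=%.4g)\n",
              nrow(x$coords), mean(x$dv_series), x$params$threshold_e,
              x$params$k))
  invisible(x)
}

#' Count barrier crossings in a 1D coordinate series
#'
#' Transitions between the two wells of a double-well coordinate are
#' counted with hysteresis: a crossing is registered each time the series,
#' having last visited one core region (`x <= -threshold` or
#' `x >= threshold`), reaches the opposite core.  Recrossing noise near the
#' barrier top is thereby excluded.
#'
#' @param x numeric coordinate series.
#' @param threshold half-width of the core regions, Angstrom.
#' @return integer number of well-to-well transitions.
#' @export
barrier_crossings <- function(x, threshold = 0.5) {
  state <- sign(x) * (abs(x) >= threshold)
  state <- state[state != 0]
  if (!length(state)) return(0L)
  sum(diff(state) != 0)
}
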