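# Energetic reweighting of boosted ensembles.  The biased density over the
# reaction coordinate(s) is corrected per bin either by the exponential
# average of exp(dV/kT) or by a second-order cumulant expansion
# exp[(<dV> + Var(dV)/(2 kT)) / kT]; the potential of mean force is
# -kT ln p, min-shifted to zero over visited bins.

#' Reweight a boosted ensemble into a potential of mean force
#'
#' @param rc_samples per-frame reaction-coordinate values: a numeric vector
#'   (1D) or a 2-column matrix (2D).
#' @param dv_series per-frame boost energy dV, kcal/mol (same length);
#'   `NULL` is treated as all-zero (no boost).
#' @param bin_edges numeric vector of bin edges (1D) or a list of two such
#'   vectors (2D); `NULL` builds a default grid over the sample range
#'   (100 bins in 1D, 50 x 50 in 2D).
#' @param kT thermal energy, kcal/mol.
#' @param method `"cumulant2"` (default), `"exp_avg"`, or `"none"`.
#'   Under `"cumulant2"`, bins holding fewer than 2 frames take the
#'   first-order (mean-only) correction and are flagged in
#'   `first_order_bins`.
#' @param rc_names axis labels.
#' @return object of class `pmf_grid`: `rc_names`, `bin_edges`, `centers`,
#'   `pmf` (vector in 1D, matrix in 2D; min over visited bins is 0; empty
#'   bins carry `empty_value = max(pmf) + kT`), `counts`, `method`, `kT`,
#'   `empty_value`, `first_order_bins`, `n_frames_used`.
#' @export
reweight_pmf <- function(rc_samples, dv_series = NULL, bin_edges = NULL,
                         kT = 0.596161,
                         method = c("cumulant2", "exp_avg", "none"),
                         rc_names = NULL) {
  method <- match.arg(method)
  rc <- if (is.null(dim(rc_samples))) matrix(rc_samples, ncol = 1L)
        else as.matrix(rc_samples)
  ndim <- ncol(rc)
  if (!ndim %in% 1:2) stop("reaction coordinates must be 1- or 2-dimensional")
  n <- nrow(rc)
  if (is.null(dv_series)) dv_series <- numeric(n)
  if (length(dv_series) != n)
    stop("rc_samples and dv_series must have equal length")
  if (is.null(rc_names))
    rc_names <- paste0("RC", seq_len(ndim))
  if (is.null(bin_edges)) {
    nb <- if (ndim == 1L) 100L else 50L
    bin_edges <- lapply(seq_len(ndim), function(d) {
      r <- range(rc[, d]); pad <- 1e-9 * max(diff(r), 1)
      seq(r[1L] - pad, r[2L] + pad, length.out = nb + 1L)
    })
  }
  if (!is.list(bin_edges)) bin_edges <- list(bin_edges)
  if (length(bin_edges) != ndim) stop("one bin_edges vector per RC required")
  nb <- vapply(bin_edges, function(e) length(e) - 1L, 1L)
  idx <- matrix(0L, n, ndim)
  for (d in seq_len(ndim)) {
    idx[, d] <- findInterval(rc[, d], bin_edges[[d]], rightmost.closed = TRUE)
    idx[idx[, d] < 1L | idx[, d] > nb[d], d] <- NA_integer_
  }
  inside <- !rowSums(is.na(idx))
  if (!any(inside)) stop("no frames fall inside the binning grid")
  lin <- idx[inside, 1L]
  if (ndim == 2L) lin <- lin + (idx[inside, 2L] - 1L) * nb[1L]
  dv <- dv_series[inside]
  n_bins <- prod(nb)
  counts <- tabulate(lin, n_bins)
  visited <- counts > 0L
  p <- counts / sum(counts)
  first_order <- integer()
  if (method != "none" && any(dv != 0)) {
    # subtract the global max of dV/kT before exponentiating (cancels in
    # the min-shift) to keep the exponential average finite
    if (method == "exp_avg") {
      shift <- max(dv) / kT
      ew <- vapply(split(exp(dv / kT - shift), lin), mean, 0)
      w <- rep(0, n_bins)
      w[as.integer(names(ew))] <- ew
      p <- p * w
    } else {
      mu <- vapply(split(dv, lin), mean, 0)
      v2 <- vapply(split(dv, lin), function(z)
        if (length(z) >= 2L) stats::var(z) else NA_real_, 0)
      bins <- as.integer(names(mu))
      first_order <- bins[is.na(v2)]
      v2[is.na(v2)] <- 0
      lw <- (mu + v2 / (2 * kT)) / kT
      lw <- lw - max(lw)
      w <- rep(0, n_bins)
      w[bins] <- exp(lw)
      p <- p * w
    }
  } else if (method != "none") {
    method <- "none"
  }
  pmf <- rep(NA_real_, n_bins)
  pmf[visited & p > 0] <- -kT * log(p[visited & p > 0])
  pmf <- pmf - min(pmf, na.rm = TRUE)
  empty_value <- max(pmf, na.rm = TRUE) + kT
  pmf[is.na(pmf)] <- empty_value
  centers <- lapply(bin_edges, function(e) (head(e, -1L) + tail(e, -1L)) / 2)
  if (ndim == 2L) {
    pmf <- matrix(pmf, nb[1L], nb[2L])
    counts <- matrix(counts, nb[1L], nb[2L])
  }
  structure(list(rc_names = rc_names, bin_edges = bin_edges,
                 centers = centers, pmf = pmf, counts = counts,
                 method = method, kT = kT, empty_value = empty_value,
                 first_order_bins = first_order,
                 n_frames_used = sum(counts)),
            class = "pmf_grid")
}

#' @export
print.pmf_grid <- function(x, ...) {
  nb <- vapply(x$bin_edges, function(e) length(e) - 1L, 1L)
  cat(sprintf("<pmf_grid> %s over %s (%s bins), method=%s, kT=%.4g\n",
              paste(x$rc_names, collapse = " x "),
              sprintf("%d frames", x$n_frames_used),
              paste(nb, collapse = " x "), x$method, x$kT))
  invisible(x)
}

.neighbour_offsets <- function(nb) {
  if (length(nb) == 1L) list(-1L, 1L)
  else list(-1L, 1L, -nb[1L], nb[1L])  # 4-neighbourhood on the linear index
}

#' Detect free-energy basins in a PMF grid
#'
#' Basins are found by a watershed/persistence flood: visited bins are
#' processed in order of increasing PMF and merged into growing
#' catchments (4-neighbourhood in 2D); when two catchments meet, the
#' shallower one dies and its depth is the PMF of the meeting saddle minus
#' its own minimum.  The surviving global catchment's depth is the visited
#' PMF range.  Basins shallower than `min_depth` are discarded; the
#' `max_basins` deepest survivors are labelled `EB1, EB2, ...` by ascending
#' PMF at the basin minimum.
#'
#' @param pmf `pmf_grid`.
#' @param max_basins maximum number of basins returned.
#' @param min_depth minimum escape depth, kcal/mol.
#' @return data.frame with columns `label`, `bin` (linear index), per-axis
#'   bin centre columns (named by `rc_names`), `pmf`, `depth`; zero rows if
#'   nothing passes the filter.
#' @export
detect_basins <- function(pmf, max_basins = 10L, min_depth = 0.5) {
  stopifnot(inherits(pmf, "pmf_grid"))
  nb <- vapply(pmf$bin_edges, function(e) length(e) - 1L, 1L)
  vals <- as.vector(pmf$pmf)
  visited <- as.vector(pmf$counts) > 0L
  ord <- order(vals, seq_along(vals))
  ord <- ord[visited[ord]]
  comp <- integer(length(vals))            # 0 = untouched
  comp_min <- numeric(0); comp_minbin <- integer(0); comp_depth <- numeric(0)
  parent <- integer(0)
  find_root <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  col_of <- function(b) if (length(nb) == 2L) ((b - 1L) %/% nb[1L]) + 1L else 1L
  row_of <- function(b) if (length(nb) == 2L) ((b - 1L) %% nb[1L]) + 1L else b
  for (b in ord) {
    roots <- integer(0)
    r <- row_of(b); cc <- col_of(b)
    nbrs <- integer(0)
    if (r > 1L) nbrs <- c(nbrs, b - 1L)
    if (r < nb[1L]) nbrs <- c(nbrs, b + 1L)
    if (length(nb) == 2L) {
      if (cc > 1L) nbrs <- c(nbrs, b - nb[1L])
      if (cc < nb[2L]) nbrs <- c(nbrs, b + nb[1L])
    }
    for (nbx in nbrs)
      if (comp[nbx] > 0L) roots <- c(roots, find_root(comp[nbx]))
    roots <- unique(roots)
    if (!length(roots)) {
      k <- length(parent) + 1L
      parent[k] <- k; comp_min[k] <- vals[b]; comp_minbin[k] <- b
      comp_depth[k] <- NA_real_
      comp[b] <- k
    } else {
      keep <- roots[which.min(comp_min[roots])]
      comp[b] <- keep
      for (rt in setdiff(roots, keep)) {
        comp_depth[rt] <- vals[b] - comp_min[rt]   # dies at this saddle
        parent[rt] <- keep
      }
    }
  }
  if (!length(parent)) return(.empty_basin_table(pmf))
  alive <- which(parent == seq_along(parent))
  vmaxv <- max(vals[visited])
  comp_depth[alive] <- vmaxv - comp_min[alive]
  keep <- which(comp_depth >= min_depth & comp_depth > 0)
  if (!length(keep)) return(.empty_basin_table(pmf))
  keep <- keep[order(-comp_depth[keep])]
  keep <- head(keep, max_basins)
  keep <- keep[order(comp_min[keep])]
  bins <- comp_minbin[keep]
  out <- data.frame(label = paste0("EB", seq_along(keep)), bin = bins,
                    stringsAsFactors = FALSE)
  for (d in seq_along(nb)) {
    bi <- if (d == 1L) row_of(bins) else col_of(bins)
    out[[pmf$rc_names[d]]] <- pmf$centers[[d]][bi]
  }
  out$pmf <- comp_min[keep]
  out$depth <- comp_depth[keep]
  out
}

.empty_basin_table <- function(pmf) {
  out <- data.frame(label = character(), bin = integer(),
                    stringsAsFactors = FALSE)
  for (nm in pmf$rc_names) out[[nm]] <- numeric()
  out$pmf <- numeric(); out$depth <- numeric()
  out
}

#' Tabulate a PMF grid for export
#'
#' @param pmf `pmf_grid`.
#' @return data.frame of bin centres, PMF and counts (long format in 2D).
#' @export
pmf_table <- function(pmf) {
  stopifnot(inherits(pmf, "pmf_grid"))
  if (length(pmf$bin_edges) == 1L) {
    df <- data.frame(pmf$centers[[1L]], as.vector(pmf$pmf),
                     as.vector(pmf$counts))
    names(df) <- c(pmf$rc_names[1L], "pmf", "count")
  } else {
    g <- expand.grid(pmf$centers[[1L]], pmf$centers[[2L]])
    df <- data.frame(g[, 1L], g[, 2L], as.vector(pmf$pmf),
                     as.vector(pmf$counts))
    names(df) <- c(pmf$rc_names, "pmf", "count")
  }
  df
}
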