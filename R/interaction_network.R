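# Geometric interaction detection with persistence statistics.  A hydrogen
# bond exists in a frame iff the acceptor-donor distance is strictly below
# the cutoff AND the acceptor-H-donor angle (the angle at the hydrogen) is
# strictly above the threshold; occupancy is the percentage of frames in
# which an interaction's criteria hold.

#' Hydrogen-bond geometric criteria
#'
#' Defaults: acceptor-donor distance < 3.5 Angstrom and acceptor-H-donor
#' angle > 120 degrees, both strict.  The angle is measured at the
#' hydrogen, between the H->donor and H->acceptor vectors.
#'
#' @param max_da_distance distance cutoff, Angstrom (> 0).
#' @param min_angle_at_h angle threshold, degrees, in (0, 180].
#' @return object of class `hbond_criteria`.
#' @export
hbond_criteria <- function(max_da_distance = 3.5, min_angle_at_h = 120) {
  if (max_da_distance <= 0) stop("max_da_distance must be > 0")
  if (min_angle_at_h <= 0 || min_angle_at_h > 180)
    stop("min_angle_at_h must lie in (0, 180]")
  structure(list(max_da_distance = max_da_distance,
                 min_angle_at_h = min_angle_at_h),
            class = "hbond_criteria")
}

.interaction_record <- function(kind, members, distance_series,
                                angle_series = NULL, present = NULL,
                                criteria = NULL) {
  occ <- if (is.null(present)) NA_real_ else 100 * mean(present)
  structure(list(kind = kind, members = members,
                 distance_series = distance_series,
                 angle_series = angle_series, present = present,
                 occupancy = occ, criteria = criteria),
            class = "interaction_record")
}

#' @export
print.interaction_record <- function(x, ...) {
  cat(sprintf("<interaction_record> %s [%s] mean d=%.3f A%s\n",
              x$kind, paste(x$members, collapse = ","),
              mean(x$distance_series),
              if (is.na(x$occupancy)) "" else
                sprintf(", occupancy %.1f%%", x$occupancy)))
  invisible(x)
}

#' Per-frame hydrogen-bond detection
#'
#' @param traj `trajectory`.
#' @param donor,hydrogen,acceptor distinct particle indices (1-based).
#' @param criteria `hbond_criteria`.
#' @return `interaction_record` of kind `"hbond"` with `distance_series`
#'   (donor-acceptor, Angstrom), `angle_series` (degrees at the hydrogen),
#'   the per-frame boolean `present`, and `occupancy` (percent).
#' @export
detect_hbond_series <- function(traj, donor, hydrogen, acceptor,
                                criteria = hbond_criteria()) {
  stopifnot(inherits(traj, "trajectory"), inherits(criteria, "hbond_criteria"))
  idx <- c(donor, hydrogen, acceptor)
  if (anyDuplicated(idx)) stop("donor, hydrogen, acceptor must be distinct")
  np <- n_particles(traj)
  if (any(idx < 1L) || any(idx > np)) stop("particle index out of range")
  dh0 <- sqrt(sum((frame_coords(traj, 1L)[donor, ] -
                   frame_coords(traj, 1L)[hydrogen, ])^2))
  if (dh0 >= 1.5)
    warning(sprintf("donor-hydrogen distance %.2f A in frame 1: is the index order (donor, hydrogen, acceptor)?", dh0))
  d_series <- rc_distance_series(traj, donor, acceptor)
  hd <- traj$coords[, donor, , drop = TRUE] - traj$coords[, hydrogen, , drop = TRUE]
  ha <- traj$coords[, acceptor, , drop = TRUE] - traj$coords[, hydrogen, , drop = TRUE]
  if (is.null(dim(hd))) { hd <- matrix(hd, ncol = 3L); ha <- matrix(ha, ncol = 3L) }
  cosang <- rowSums(hd * ha) /
    pmax(sqrt(rowSums(hd^2)) * sqrt(rowSums(ha^2)), 1e-300)
  ang <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
  present <- (d_series < criteria$max_da_distance) &
             (ang > criteria$min_angle_at_h)
  .interaction_record("hbond", c(donor, hydrogen, acceptor), d_series,
                      angle_series = ang, present = present,
                      criteria = criteria)
}

#' Occupancy of an interaction record
#'
#' Percentage of frames in which the interaction's criteria hold, reported
#' to 0.1 percent.
#'
#' @param record `interaction_record` with a per-frame boolean series.
#' @return percentage in `[0, 100]`, rounded to one decimal.
#' @export
occupancy <- function(record) {
  stopifnot(inherits(record, "interaction_record"))
  if (is.null(record$present) || !length(record$present))
    stop("record carries no per-frame boolean series")
  round(100 * mean(record$present), 1L)
}

#' Atom-pair distance series (salt bridge / ion coordination)
#'
#' Delegates the per-frame distances to [rc_distance_series()] (same code
#' path, bitwise-identical values).  The `present` flag applies the strict
#' distance cutoff; the default 5.5 Angstrom is a common salt-bridge
#' criterion.
#'
#' @param traj `trajectory`.
#' @param i,j particle indices.
#' @param kind record label: `"salt_bridge"`, `"ion_coord"`, ...
#' @param cutoff formation cutoff, Angstrom.
#' @return `interaction_record`.
#' @export
atom_pair_distance_series <- function(traj, i, j, kind = "salt_bridge",
                                      cutoff = 5.5) {
  if (i == j) stop("indices must differ")
  d <- rc_distance_series(traj, i, j)
  .interaction_record(kind, c(i, j), d, present = d < cutoff,
                      criteria = list(cutoff = cutoff))
}

#' Group-centroid distance series (pi-pi stacking, long-range
#' electrostatic proxies)
#'
#' Per-frame distance between the (optionally mass-weighted) centroids of
#' two disjoint atom groups, e.g. two aromatic ring centres.
#'
#' @param traj `trajectory`.
#' @param group_a,group_b disjoint non-empty integer index vectors.
#' @param mass_weighted use particle masses as centroid weights.
#' @param kind record label (default `"group_ei"`; use `"pi_pi"` for rings).
#' @return `interaction_record` (no occupancy criterion).
#' @export
group_centroid_distance_series <- function(traj, group_a, group_b,
                                           mass_weighted = TRUE,
                                           kind = "group_ei") {
  stopifnot(inherits(traj, "trajectory"))
  if (!length(group_a) || !length(group_b)) stop("groups must be non-empty")
  if (length(intersect(group_a, group_b))) stop("groups must be disjoint")
  np <- n_particles(traj)
  if (any(c(group_a, group_b) < 1L) || any(c(group_a, group_b) > np))
    stop("particle index out of range")
  cen <- function(grp) {
    w <- if (mass_weighted) traj$masses[grp] else rep(1, length(grp))
    w <- w / sum(w)
    sub <- traj$coords[, grp, , drop = FALSE]
    out <- matrix(0, n_frames(traj), 3L)
    for (d in 1:3) out[, d] <- matrix(sub[, , d], ncol = length(grp)) %*% w
    out
  }
  d <- sqrt(rowSums((cen(group_a) - cen(group_b))^2))
  .interaction_record(kind, list(group_a = group_a, group_b = group_b), d)
}

#' Batch interaction table from a manifest
#'
#' The manifest is a data.frame (or TSV path) with columns `kind` and
#' `members`.  `members` holds 1-based particle indices: `"d,h,a"` for
#' hydrogen bonds, `"i,j"` for pair kinds (`salt_bridge`, `ion_coord`), and
#' `"a1,a2,... | b1,b2,..."` for group kinds (`pi_pi`, `group_ei`).
#' Unresolvable entries are reported in a single warning (and in the
#' `"failures"` attribute); the remaining entries are still computed.
#'
#' @param traj `trajectory`.
#' @param manifest data.frame or TSV file path.
#' @param criteria `hbond_criteria` used for hbond rows.
#' @param pair_cutoff formation cutoff for pair kinds, Angstrom.
#' @param bin_width bin width for the reported distribution peaks.
#' @return data.frame with columns `kind`, `members`, `occupancy`,
#'   `mean_distance`, `peaks`; attribute `"records"` holds the full
#'   `interaction_record` list in manifest order.
#' @export
interaction_table <- function(traj, manifest, criteria = hbond_criteria(),
                              pair_cutoff = 5.5, bin_width = 0.05) {
  if (is.character(manifest))
    manifest <- read.delim(manifest, stringsAsFactors = FALSE)
  stopifnot(is.data.frame(manifest))
  if (!nrow(manifest)) {
    out <- data.frame(kind = character(), members = character(),
                      occupancy = numeric(), mean_distance = numeric(),
                      peaks = character(), stringsAsFactors = FALSE)
    attr(out, "records") <- list()
    return(out)
  }
  if (!all(c("kind", "members") %in% names(manifest)))
    stop("manifest needs columns 'kind' and 'members'")
  parse_idx <- function(s) as.integer(strsplit(gsub(" ", "", s), ",")[[1L]])
  rows <- vector("list", nrow(manifest))
  records <- vector("list", nrow(manifest))
  failures <- character(0)
  for (r in seq_len(nrow(manifest))) {
    kind <- manifest$kind[r]; mem <- manifest$members[r]
    rec <- tryCatch({
      switch(kind,
        hbond = {
          idx <- parse_idx(mem)
          if (length(idx) != 3L) stop("hbond needs 3 indices")
          detect_hbond_series(traj, idx[1L], idx[2L], idx[3L], criteria)
        },
        salt_bridge = ,
        ion_coord = {
          idx <- parse_idx(mem)
          if (length(idx) != 2L) stop("pair kinds need 2 indices")
          atom_pair_distance_series(traj, idx[1L], idx[2L], kind, pair_cutoff)
        },
        pi_pi = ,
        group_ei = {
          gg <- strsplit(mem, "|", fixed = TRUE)[[1L]]
          if (length(gg) != 2L) stop("group kinds need 'a,... | b,...'")
          group_centroid_distance_series(traj, parse_idx(gg[1L]),
                                         parse_idx(gg[2L]), kind = kind)
        },
        stop("unknown interaction kind '", kind, "'")
      )
    }, error = function(e) e)
    if (inherits(rec, "error")) {
      failures <- c(failures,
                    sprintf("row %d (%s %s): %s", r, kind, mem,
                            conditionMessage(rec)))
      next
    }
    records[[r]] <- rec
    ds <- rec$distance_series
    pk <- if (length(ds) >= 10L && stats::sd(ds) > 0)
      probability_distribution(ds, bin_width)$peak_positions else mean(ds)
    rows[[r]] <- data.frame(kind = kind, members = mem,
                            occupancy = if (is.na(rec$occupancy)) NA_real_
                                        else round(rec$occupancy, 1L),
                            mean_distance = mean(ds),
                            peaks = paste(signif(pk, 6), collapse = ";"),
                            stringsAsFactors = FALSE)
  }
  if (length(failures))
    warning("unresolvable manifest entries:\n  ",
            paste(failures, collapse = "\n  "))
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(out))
    out <- data.frame(kind = character(), members = character(),
                      occupancy = numeric(), mean_distance = numeric(),
                      peaks = character(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "records") <- records
  attr(out, "failures") <- failures
  out
}
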