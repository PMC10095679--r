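# Multi-model PDB and XYZ trajectory input/output.  The PDB dialect is the
# minimal robust v3.3 subset: only ATOM/HETATM/MODEL/ENDMDL/TER records are
# consumed, occupancy/B-factor are written as 1.00/0.00, serial numbers are
# 1-based, and frames are delimited by MODEL/ENDMDL.  Coordinates survive a
# write -> read round trip to 1e-3 A (PDB fixed width) / 1e-6 A (XYZ).

.TWO_LETTER_ELEMENTS <- c("MG", "CL", "BR", "FE", "ZN", "NA", "MN", "CU", "SE")

#' Infer an element symbol from a PDB atom name
#'
#' Leading digits and primes are stripped; a two-character prefix matching a
#' common biomolecular two-letter element (MG, CL, BR, FE, ZN, NA, MN, CU,
#' SE) is used only when the whole stripped name equals it, so "CA" and "CD"
#' atom names stay carbon.  Otherwise the first letter is the element.
#'
#' @param name character vector of atom names.
#' @return character vector of element symbols.
#' @export
infer_element <- function(name) {
  vapply(name, function(nm) {
    s <- toupper(gsub("[0-9' ]", "", nm))
    if (s %in% .TWO_LETTER_ELEMENTS) return(s)
    if (nchar(s) == 0L) return("C")
    substr(s, 1L, 1L)
  }, character(1L), USE.NAMES = FALSE)
}

.pdb_atom_line <- function(serial, name, resname, resid, xyz, element) {
  nm <- if (nchar(name) < 4L) sprintf(" %-3s", name) else substr(name, 1L, 4L)
  sprintf("ATOM  %5d %s %-3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial %% 100000L, nm, substr(resname, 1L, 3L), resid %% 10000L,
          xyz[1L], xyz[2L], xyz[3L], 1, 0, substr(element, 1L, 2L))
}

#' Write a trajectory
#'
#' @param traj `trajectory`.
#' @param path output file path.
#' @param format `"pdb"` (multi-model) or `"xyz"`.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path, format = c("pdb", "xyz")) {
  format <- match.arg(format)
  stopifnot(inherits(traj, "trajectory"))
  nf <- n_frames(traj); np <- n_particles(traj); lab <- traj$labels
  con <- file(path, "w"); on.exit(close(con))
  if (format == "pdb") {
    for (f in seq_len(nf)) {
      writeLines(sprintf("MODEL     %4d", f), con)
      fr <- frame_coords(traj, f)
      lines <- vapply(seq_len(np), function(i)
        .pdb_atom_line(i, lab$name[i], lab$resname[i], lab$resid[i],
                       fr[i, ], lab$element[i]), character(1L))
      writeLines(lines, con)
      writeLines(c("TER", "ENDMDL"), con)
    }
    writeLines("END", con)
  } else {
    for (f in seq_len(nf)) {
      writeLines(as.character(np), con)
      writeLines(sprintf("frame=%d time=%.6f ps", f,
                         (f - 1) * traj$timestep), con)
      fr <- frame_coords(traj, f)
      writeLines(sprintf("%-4s %14.6f %14.6f %14.6f",
                         lab$name, fr[, 1L], fr[, 2L], fr[, 3L]), con)
    }
  }
  invisible(path)
}

#' Read a trajectory
#'
#' @param path input file path.
#' @param format `"pdb"` or `"xyz"`; guessed from the extension if missing.
#' @param timestep default frame spacing (ps) when the file carries none.
#' @return `trajectory`.
#' @export
read_trajectory <- function(path, format = NULL, timestep = 1) {
  if (is.null(format)) {
    format <- if (grepl("\\.xyz$", path, ignore.case = TRUE)) "xyz" else "pdb"
  }
  format <- match.arg(format, c("pdb", "xyz"))
  if (format == "pdb") .read_pdb(path, timestep) else .read_xyz(path, timestep)
}

.read_pdb <- function(path, timestep) {
  lines <- readLines(path)
  rec <- substr(lines, 1L, 6L)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  is_model <- startsWith(rec, "MODEL")
  is_end <- startsWith(rec, "ENDMDL")
  # frame id per atom line: cumulative MODEL count (0 if no MODEL records)
  frame_of <- cumsum(is_model)
  if (!any(is_model)) frame_of <- frame_of + 1L
  atom_lines <- lines[is_atom]
  if (!length(atom_lines)) stop("no ATOM/HETATM records in ", path)
  frame_id <- frame_of[is_atom]
  frame_id <- match(frame_id, sort(unique(frame_id)))
  nf <- max(frame_id)
  counts <- tabulate(frame_id, nf)
  if (length(unique(counts)) != 1L)
    stop(sprintf("ragged PDB frames: frame %d has %d atoms, expected %d",
                 which(counts != counts[1L])[1L],
                 counts[counts != counts[1L]][1L], counts[1L]))
  np <- counts[1L]
  x <- as.numeric(substr(atom_lines, 31L, 38L))
  y <- as.numeric(substr(atom_lines, 39L, 46L))
  z <- as.numeric(substr(atom_lines, 47L, 54L))
  if (anyNA(c(x, y, z))) stop("unparseable coordinates in ", path)
  first <- frame_id == 1L
  name <- trimws(substr(atom_lines[first], 13L, 16L))
  resname <- trimws(substr(atom_lines[first], 18L, 20L))
  resid <- suppressWarnings(as.integer(trimws(substr(atom_lines[first], 23L, 26L))))
  resid[is.na(resid)] <- seq_len(np)[is.na(resid)]
  element <- trimws(substr(atom_lines[first], 77L, 78L))
  blank <- is.na(element) | element == ""
  element[blank] <- infer_element(name[blank])
  coords <- array(0, c(nf, np, 3L))
  ord <- order(frame_id)
  coords[, , 1L] <- matrix(x[ord], nf, np, byrow = TRUE)
  coords[, , 2L] <- matrix(y[ord], nf, np, byrow = TRUE)
  coords[, , 3L] <- matrix(z[ord], nf, np, byrow = TRUE)
  labels <- data.frame(name = name, resid = resid, resname = resname,
                       element = element, stringsAsFactors = FALSE)
  trajectory(coords, labels, timestep = timestep)
}

.read_xyz <- function(path, timestep) {
  lines <- readLines(path)
  pos <- 1L; frames <- list(); names <- NULL; times <- numeric()
  while (pos <= length(lines)) {
    if (!nzchar(trimws(lines[pos]))) { pos <- pos + 1L; next }
    np <- suppressWarnings(as.integer(trimws(lines[pos])))
    if (is.na(np)) stop("XYZ format error at line ", pos, ": expected atom count")
    comment <- if (pos + 1L <= length(lines)) lines[pos + 1L] else ""
    tm <- regmatches(comment, regexec("time=([0-9eE.+-]+)", comment))[[1L]]
    if (length(tm) == 2L) times <- c(times, as.numeric(tm[2L]))
    block <- lines[(pos + 2L):(pos + 1L + np)]
    if (length(block) < np || anyNA(block))
      stop(sprintf("ragged XYZ frame %d: expected %d atom lines",
                   length(frames) + 1L, np))
    parts <- strsplit(trimws(block), "[[:space:]]+")
    bad <- vapply(parts, length, 1L) < 4L
    if (any(bad))
      stop(sprintf("ragged XYZ frame %d: malformed atom line", length(frames) + 1L))
    nm <- vapply(parts, `[[`, "", 1L)
    xyz <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3L)))
    if (is.null(names)) names <- nm
    else if (length(nm) != length(names))
      stop(sprintf("ragged XYZ frame %d: atom count changed", length(frames) + 1L))
    frames[[length(frames) + 1L]] <- xyz
    pos <- pos + 2L + np
  }
  if (!length(frames)) stop("no frames in ", path)
  nf <- length(frames); np <- length(names)
  coords <- array(0, c(nf, np, 3L))
  for (f in seq_len(nf)) coords[f, , ] <- frames[[f]]
  dt <- if (length(times) >= 2L) times[2L] - times[1L] else timestep
  labels <- data.frame(name = names, resid = seq_len(np), resname = "UNK",
                       element = infer_element(names),
                       stringsAsFactors = FALSE)
  trajectory(coords, labels, timestep = dt)
}
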