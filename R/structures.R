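# Atomic masses (amu) for the elements that occur in protein-ligand work;
# anything else falls back to 12.0 with a warning.
.element_masses <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                     S = 32.06, P = 30.974, F = 18.998, CL = 35.45)

element_mass <- function(element) {
  el <- toupper(trimws(element))
  m <- .element_masses[el]
  if (anyNA(m)) {
    warning(sprintf("unknown element(s) %s: using mass 12.0",
                    paste(unique(el[is.na(m)]), collapse = ", ")))
    m[is.na(m)] <- 12.0
  }
  unname(m)
}

#' Construct a structure frame
#'
#' One coordinate snapshot: an atom table plus Cartesian coordinates in
#' Angstrom. Masses are assigned from the element symbol (H/C/N/O/S/P/F/Cl;
#' unknown elements get 12.0 amu with a warning).
#'
#' @param atoms `data.frame` with columns `serial` (unique integers), `name`,
#'   `element`, `resname`, `resid`, `chain`.
#' @param coords Numeric matrix, one row per atom, columns x/y/z in Angstrom.
#' @return An object of class `"structure_frame"` with a `masses` vector.
#' @export
structure_frame <- function(atoms, coords) {
  stopifnot(is.data.frame(atoms))
  need <- c("serial", "name", "element", "resname", "resid", "chain")
  if (!all(need %in% names(atoms)))
    stop("atoms needs columns: ", paste(need, collapse = ", "))
  coords <- as.matrix(coords)
  if (is.null(dim(coords)) || ncol(coords) != 3L)
    stop("coords must be an n x 3 matrix (Angstrom)")
  if (nrow(coords) != nrow(atoms))
    stop("coords and atoms must describe the same number of atoms")
  if (anyDuplicated(atoms$serial)) stop("atom serials must be unique")
  if (any(!is.finite(coords))) stop("coordinates must be finite")
  dimnames(coords) <- list(NULL, c("x", "y", "z"))
  structure(list(atoms = atoms, coords = coords,
                 masses = element_mass(atoms$element)),
            class = "structure_frame")
}

#' @export
print.structure_frame <- function(x, ...) {
  cat(sprintf("<structure_frame> %d atoms, %d residue(s)\n",
              nrow(x$atoms), length(unique(paste(x$atoms$chain, x$atoms$resid)))))
  invisible(x)
}

#' Read a structure frame from a PDB file
#'
#' Parses ATOM/HETATM records (fixed-column PDB v3.3 layout, delegated to the
#' bio3d reader). Alternate locations other than '' or 'A' are skipped; the
#' element is taken from columns 77-78 when present, else inferred from the
#' atom name.
#'
#' @param path PDB file path.
#' @return A [structure_frame()].
#' @export
read_pdb <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                  error = function(e) stop(sprintf("PDB parse error in %s: %s",
                                                   path, conditionMessage(e))))
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0L) stop(sprintf("no ATOM/HETATM records in %s", path))
  keep <- is.na(at$alt) | at$alt %in% c("", "A")
  at <- at[keep, , drop = FALSE]
  elem <- at$elesy
  no_el <- is.na(elem) | !nzchar(trimws(elem))
  if (any(no_el))  # fall back to the first letter of the atom name
    elem[no_el] <- substr(gsub("[^A-Za-z].*$", "", trimws(at$elety[no_el])), 1L, 1L)
  atoms <- data.frame(serial = at$eleno, name = trimws(at$elety),
                      element = toupper(trimws(elem)), resname = trimws(at$resid),
                      resid = at$resno,
                      chain = ifelse(is.na(at$chain), "", at$chain))
  structure_frame(atoms, cbind(at$x, at$y, at$z))
}

#' Write a structure frame as a PDB file
#'
#' Emits fixed-column ATOM records (occupancy 1.00, B-factor 0.00).
#'
#' @param frame A [structure_frame()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(frame, path) {
  stopifnot(inherits(frame, "structure_frame"))
  a <- frame$atoms
  lines <- sprintf(
    "ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    a$serial, substr(a$name, 1, 4), substr(a$resname, 1, 3),
    ifelse(nzchar(a$chain), substr(a$chain, 1, 1), "A"), a$resid,
    frame$coords[, 1], frame$coords[, 2], frame$coords[, 3], 1, 0,
    substr(a$element, 1, 2))
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Construct a trajectory
#'
#' @param frames List of [structure_frame()]s with identical atom tables.
#' @param times Frame times in ps, strictly increasing; defaults to
#'   `0, 1, 2, ...`.
#' @return An object of class `"trajectory"`.
#' @export
trajectory <- function(frames, times = NULL) {
  if (!is.list(frames) || length(frames) < 1L)
    stop("need at least one frame")
  if (!all(vapply(frames, inherits, logical(1), "structure_frame")))
    stop("all frames must be structure_frame objects")
  a1 <- frames[[1]]$atoms
  for (i in seq_along(frames))
    if (!identical(frames[[i]]$atoms, a1))
      stop(sprintf("frame %d atom table differs from frame 1", i))
  if (is.null(times)) times <- seq_along(frames) - 1
  times <- as.numeric(times)
  if (length(times) != length(frames) || any(diff(times) <= 0))
    stop("times must match frame count and be strictly increasing")
  structure(list(frames = frames, times = times), class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d frames x %d atoms, t = %g-%g ps\n",
              length(x$frames), nrow(x$frames[[1]]$atoms),
              min(x$times), max(x$times)))
  invisible(x)
}

#' Read a multi-frame XYZ trajectory
#'
#' Standard XYZ layout per frame: an atom-count line, a comment line, then
#' `element x y z` rows. Frame times default to 0, 1, 2, ... ps unless the
#' comment line encodes `t=<ps>`.
#'
#' @param path XYZ file path.
#' @return A [trajectory()] (atom names `X1, X2, ...`, resname `XYZ`).
#' @export
read_xyz_trajectory <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  frames <- list(); times <- numeric(0); i <- 1L; n_atoms0 <- NA_integer_
  while (i <= length(lines) && nzchar(trimws(lines[i]))) {
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n) || n < 1L)
      stop(sprintf("XYZ format error at line %d: expected atom count", i))
    if (is.na(n_atoms0)) n_atoms0 <- n
    if (n != n_atoms0)
      stop(sprintf("XYZ format error at line %d: atom count %d differs from first frame (%d)",
                   i, n, n_atoms0))
    if (i + 1L + n > length(lines))
      stop(sprintf("XYZ format error: truncated frame starting at line %d", i))
    comment <- lines[i + 1L]
    tm <- regmatches(comment, regexec("t\\s*=\\s*([0-9.eE+-]+)", comment))[[1]]
    times <- c(times, if (length(tm) == 2L) as.numeric(tm[2]) else NA_real_)
    rows <- strsplit(trimws(lines[i + 1L + seq_len(n)]), "\\s+")
    if (any(lengths(rows) < 4L))
      stop(sprintf("XYZ format error: short atom row near line %d", i + 2L))
    el <- vapply(rows, `[`, character(1), 1L)
    xyz <- cbind(as.numeric(vapply(rows, `[`, character(1), 2L)),
                 as.numeric(vapply(rows, `[`, character(1), 3L)),
                 as.numeric(vapply(rows, `[`, character(1), 4L)))
    atoms <- data.frame(serial = seq_len(n), name = paste0("X", seq_len(n)),
                        element = toupper(el), resname = "XYZ", resid = 1L,
                        chain = "A")
    frames[[length(frames) + 1L]] <- structure_frame(atoms, xyz)
    i <- i + 2L + n
  }
  if (length(frames) == 0L) stop(sprintf("no frames in %s", path))
  if (anyNA(times)) times <- seq_along(frames) - 1
  trajectory(frames, times)
}

#' Write a trajectory as multi-frame XYZ
#'
#' @param traj A [trajectory()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_xyz_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"))
  n <- nrow(traj$frames[[1]]$atoms)
  out <- unlist(lapply(seq_along(traj$frames), function(k) {
    f <- traj$frames[[k]]
    c(as.character(n), sprintf("frame %d t=%.17g", k - 1L, traj$times[k]),
      sprintf("%-2s %.17g %.17g %.17g", f$atoms$element,
              f$coords[, 1], f$coords[, 2], f$coords[, 3]))
  }))
  writeLines(out, path)
  invisible(path)
}
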