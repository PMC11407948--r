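# Resolve a selection (NULL = all atoms, integer indices, or atom names)
# against a frame's atom table.
resolve_selection <- function(frame, selection) {
  n <- nrow(frame$atoms)
  if (is.null(selection)) return(seq_len(n))
  if (is.character(selection)) {
    idx <- match(selection, frame$atoms$name)
    if (anyNA(idx))
      stop("atoms not found in selection: ",
           paste(selection[is.na(idx)], collapse = ", "))
    return(idx)
  }
  idx <- as.integer(selection)
  if (length(idx) == 0L || any(idx < 1L) || any(idx > n))
    stop("selection indices out of range")
  idx
}

#' Optimal superposition RMSD (Kabsch algorithm)
#'
#' Finds the proper rotation (det = +1) and translation that minimise the
#' (optionally weighted) squared deviation of `mobile` from `reference`, then
#' returns the root-mean-square deviation after superposition:
#' \deqn{RMSD = \sqrt{\sum_i w_i \, \|R p_i + t - q_i\|^2 / \sum_i w_i}.}
#' The solution uses the SVD of the weighted cross-covariance matrix with the
#' standard sign correction that excludes reflections.
#'
#' @param reference,mobile Numeric n x 3 coordinate matrices (Angstrom),
#'   equal atom counts, n >= 3.
#' @param weights Optional per-atom weights (e.g. masses); default uniform.
#' @return List with `rmsd` (Angstrom), `rotation` (3 x 3), `translation`
#'   (length 3; aligned = mobile %*% t(rotation) + translation).
#' @examples
#' ref <- matrix(rnorm(30), ncol = 3)
#' rot <- cbind(c(0, 1, 0), c(-1, 0, 0), c(0, 0, 1))  # 90 deg about z
#' mob <- ref %*% t(rot) + matrix(c(5, 0, 0), 10, 3, byrow = TRUE)
#' kabsch_rmsd(ref, mob)$rmsd  # ~0
#' @export
kabsch_rmsd <- function(reference, mobile, weights = NULL) {
  P <- as.matrix(mobile); Q <- as.matrix(reference)
  if (ncol(P) != 3L || ncol(Q) != 3L) stop("coordinates must be n x 3")
  if (nrow(P) != nrow(Q))
    stop(sprintf("atom count mismatch: reference %d vs mobile %d", nrow(Q), nrow(P)))
  if (nrow(P) < 3L) stop("need >= 3 atoms for a unique superposition")
  w <- if (is.null(weights)) rep(1, nrow(P)) else as.numeric(weights)
  if (length(w) != nrow(P) || any(w < 0) || sum(w) == 0)
    stop("weights must be non-negative with positive sum, one per atom")
  w <- w / sum(w)
  cen_p <- colSums(P * w); cen_q <- colSums(Q * w)
  Pc <- sweep(P, 2L, cen_p); Qc <- sweep(Q, 2L, cen_q)
  C <- t(Qc * w) %*% Pc              # cross-covariance, ref x mobile
  sv <- svd(C)
  d <- sign(det(sv$u %*% t(sv$v)))
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  aligned <- Pc %*% t(R)
  rmsd <- sqrt(sum(w * rowSums((aligned - Qc)^2)))
  list(rmsd = rmsd, rotation = R, translation = as.numeric(cen_q - R %*% cen_p))
}

#' Per-frame RMSD against a reference frame
#'
#' Computes [kabsch_rmsd()] of every frame against `reference_frame` over the
#' selected atoms; the standard convergence diagnostic for a simulation.
#'
#' @param traj A [trajectory()].
#' @param reference_frame Index of the reference frame (default 1).
#' @param selection `NULL` (all atoms), integer indices, or atom names.
#' @param mass_weighted Weight by atomic masses (default `FALSE`).
#' @return Numeric vector, one RMSD (Angstrom) per frame.
#' @export
rmsd_series <- function(traj, reference_frame = 1L, selection = NULL,
                        mass_weighted = FALSE) {
  stopifnot(inherits(traj, "trajectory"))
  idx <- resolve_selection(traj$frames[[1]], selection)
  if (length(idx) == 0L) stop("empty selection")
  ref <- traj$frames[[reference_frame]]$coords[idx, , drop = FALSE]
  w <- if (mass_weighted) traj$frames[[1]]$masses[idx] else NULL
  if (length(idx) < 3L)
    stop("selection must contain >= 3 atoms for superposition")
  vapply(traj$frames, function(f)
    kabsch_rmsd(ref, f$coords[idx, , drop = FALSE], weights = w)$rmsd,
    numeric(1))
}

#' Radius of gyration
#'
#' Mass-weighted root-mean-square distance of the selected atoms from their
#' centre of mass:
#' \deqn{R_g = \sqrt{\sum_i m_i \|r_i - r_{com}\|^2 / \sum_i m_i}.}
#' This is the standard compactness measure computed by simulation packages.
#' `rg_def = "max"` instead returns the literal maximum distance of any
#' selected atom from the centre of mass, for comparison with analyses that
#' describe Rg that way.
#'
#' @param frame A [structure_frame()].
#' @param selection `NULL`, indices, or atom names.
#' @param rg_def `"rms"` (default) or `"max"`.
#' @return Radius of gyration in Angstrom.
#' @export
radius_of_gyration <- function(frame, selection = NULL, rg_def = c("rms", "max")) {
  stopifnot(inherits(frame, "structure_frame"))
  rg_def <- match.arg(rg_def)
  idx <- resolve_selection(frame, selection)
  m <- frame$masses[idx]
  if (sum(m) <= 0) stop("zero total mass in selection")
  r <- frame$coords[idx, , drop = FALSE]
  com <- colSums(r * m) / sum(m)
  d2 <- rowSums(sweep(r, 2L, com)^2)
  if (rg_def == "rms") sqrt(sum(m * d2) / sum(m)) else sqrt(max(d2))
}

#' Per-atom root-mean-square fluctuation
#'
#' For each selected atom, the RMS deviation of its position from its
#' time-average position over the trajectory:
#' \deqn{RMSF_i = \sqrt{\langle \|r_i(t) - \bar r_i\|^2 \rangle_t.}}
#' With `align = TRUE` (default) every frame is first superposed onto frame 1
#' over the selection by [kabsch_rmsd()], so rigid-body motion does not count
#' as fluctuation.
#'
#' @param traj A [trajectory()] with >= 2 frames.
#' @param selection `NULL`, indices, or atom names (>= 3 atoms when aligning).
#' @param align Remove rigid-body motion first (default `TRUE`).
#' @return Numeric vector of per-atom RMSF (Angstrom), one per selected atom.
#' @export
rmsf <- function(traj, selection = NULL, align = TRUE) {
  stopifnot(inherits(traj, "trajectory"))
  if (length(traj$frames) < 2L) stop("RMSF needs >= 2 frames")
  idx <- resolve_selection(traj$frames[[1]], selection)
  coords <- lapply(traj$frames, function(f) f$coords[idx, , drop = FALSE])
  if (align) {
    if (length(idx) < 3L) stop("alignment needs >= 3 atoms in the selection")
    ref <- coords[[1]]
    coords <- lapply(coords, function(X) {
      k <- kabsch_rmsd(ref, X)
      X %*% t(k$rotation) + matrix(k$translation, nrow(X), 3L, byrow = TRUE)
    })
  }
  arr <- simplify2array(coords)                      # atoms x 3 x frames
  mean_pos <- apply(arr, c(1L, 2L), mean)
  dev2 <- sweep(arr, c(1L, 2L), mean_pos)^2
  sqrt(apply(dev2, 1L, function(a) mean(colSums(matrix(a, nrow = 3L)))))
}

#' Angle at a vertex between three points
#'
#' The angle at `b` between rays `b -> a` and `b -> c`, in degrees in
#' \[0, 180\], computed from the normalised dot product with clamping against
#' rounding just outside \[-1, 1\].
#'
#' @param a,b,c Numeric length-3 coordinates (Angstrom).
#' @return Angle in degrees.
#' @examples
#' angle(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0))  # 90
#' @export
angle <- function(a, b, c) {
  u <- as.numeric(a) - as.numeric(b)
  v <- as.numeric(c) - as.numeric(b)
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("zero-length ray: vertex coincides with an endpoint")
  cosang <- sum(u * v) / (nu * nv)
  acos(min(1, max(-1, cosang))) * 180 / pi
}

#' Angle time series for an atom triplet over a trajectory
#'
#' Tracks a rotatable (three-atom) angle across frames; values are in
#' \[0, 180\] degrees with no circular wrapping (torsion ranges of bound
#' small molecules are narrow, so min/max on raw values is meaningful).
#'
#' @param traj A [trajectory()].
#' @param triplet Length-3 selection (indices or atom names) giving the two
#'   ray endpoints around the central vertex atom, in order a, b, c.
#' @param label Optional angle label for reports.
#' @return An object of class `"angle_series"`: list with `triplet`, `label`,
#'   per-frame `values` (degrees), `range_min`, `range_max`, and
#'   `width = range_max - range_min`.
#' @export
angle_series <- function(traj, triplet, label = "") {
  stopifnot(inherits(traj, "trajectory"))
  idx <- resolve_selection(traj$frames[[1]], triplet)
  if (length(idx) != 3L) stop("triplet must select exactly 3 atoms")
  vals <- vapply(traj$frames, function(f)
    angle(f$coords[idx[1], ], f$coords[idx[2], ], f$coords[idx[3], ]),
    numeric(1))
  structure(list(triplet = idx, label = label, values = vals,
                 range_min = min(vals), range_max = max(vals),
                 width = max(vals) - min(vals)),
            class = "angle_series")
}

# Round half away from zero to integer degrees (printed torsion summaries
# use this convention: mean of {22, 16, 20} -> 19).
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Summary statistics for a set of rotatable-angle series
#'
#' Per angle: the observed range \[min, max\] and its width (degrees). Per
#' molecule: the arithmetic mean of the widths, rounded half-away-from-zero
#' to the nearest integer degree — the "average variation" statistic used in
#' torsion-flexibility tables.
#'
#' @param series_list List of [angle_series()] objects (or lists with
#'   `range_min`/`range_max`, e.g. built from printed ranges).
#' @return List with `per_angle` (`data.frame`: label, range_min, range_max,
#'   width), `mean_width_raw`, and `mean_width` (integer degrees).
#' @examples
#' rng <- function(lo, hi) list(label = "", range_min = lo, range_max = hi,
#'                              width = hi - lo)
#' angle_stats(list(rng(105, 127), rng(117, 133), rng(108, 128)))$mean_width  # 19
#' @export
angle_stats <- function(series_list) {
  stopifnot(is.list(series_list), length(series_list) > 0)
  per <- do.call(rbind, lapply(series_list, function(s) {
    data.frame(label = if (is.null(s$label)) "" else s$label,
               range_min = s$range_min, range_max = s$range_max,
               width = s$range_max - s$range_min)
  }))
  mw <- mean(per$width)
  list(per_angle = per, mean_width_raw = mw,
       mean_width = round_half_away(mw))
}
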