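#' Hydrogen-bond geometry for a donor-hydrogen-acceptor triple
#'
#' Computes the covalent donor-hydrogen distance d(X-H), the hydrogen-bond
#' distance d(H...Y), the heavy-atom distance d(X...Y) (Angstrom) and the
#' X-H...Y angle at the hydrogen (degrees). Because all four quantities come
#' from one coordinate set they satisfy the law of cosines
#' d(X...Y)^2 = d(X-H)^2 + d(H...Y)^2 - 2 d(X-H) d(H...Y) cos(angle)
#' by construction.
#'
#' @param frame A [structure_frame()].
#' @param donor,hydrogen,acceptor Three distinct atom references (indices or
#'   atom names) for X, H, Y.
#' @return An object of class `"hbond_geometry"`: list with atom indices and
#'   `d_xh`, `d_hy`, `d_xy` (Angstrom), `angle_xhy` (degrees).
#' @export
hbond_geometry <- function(frame, donor, hydrogen, acceptor) {
  stopifnot(inherits(frame, "structure_frame"))
  idx <- c(resolve_selection(frame, donor), resolve_selection(frame, hydrogen),
           resolve_selection(frame, acceptor))
  if (length(idx) != 3L || anyDuplicated(idx))
    stop("donor, hydrogen, acceptor must be three distinct atoms")
  x <- frame$coords[idx[1], ]; h <- frame$coords[idx[2], ]; y <- frame$coords[idx[3], ]
  d_xh <- sqrt(sum((x - h)^2)); d_hy <- sqrt(sum((h - y)^2))
  d_xy <- sqrt(sum((x - y)^2))
  if (d_xh == 0 || d_hy == 0 || d_xy == 0) stop("coincident atoms")
  structure(list(donor = idx[1], hydrogen = idx[2], acceptor = idx[3],
                 d_xh = d_xh, d_hy = d_hy, d_xy = d_xy,
                 angle_xhy = angle(x, h, y)),
            class = "hbond_geometry")
}

#' @export
print.hbond_geometry <- function(x, ...) {
  cat(sprintf("<hbond> d(X-H)=%.2f d(H...Y)=%.2f d(X...Y)=%.2f A, angle %.1f deg\n",
              x$d_xh, x$d_hy, x$d_xy, x$angle_xhy))
  invisible(x)
}

#' Scan a frame for hydrogen bonds by geometric criteria
#'
#' Evaluates every donor(X-H) x acceptor(Y) pair and keeps those with
#' d(X...Y) <= `d_xy_max` and angle X-H...Y >= `angle_min`. The defaults
#' (3.5 Angstrom, 110 degrees) are deliberately inclusive: docking-derived
#' protein-ligand hydrogen bonds are commonly reported with X-H...Y angles
#' below the classical 120-degree cutoff.
#'
#' @param frame A [structure_frame()].
#' @param donors List of length-2 vectors `c(donor, hydrogen)` (indices or
#'   names): each donor with its attached hydrogen.
#' @param acceptors Vector of acceptor atom references.
#' @param d_xy_max Heavy-atom distance cutoff, Angstrom.
#' @param angle_min Angle cutoff at the hydrogen, degrees.
#' @return List of [hbond_geometry()] hits sorted by `d_hy` ascending.
#' @export
hbond_scan <- function(frame, donors, acceptors, d_xy_max = 3.5, angle_min = 110) {
  stopifnot(inherits(frame, "structure_frame"), is.list(donors))
  acc_idx <- resolve_selection(frame, acceptors)
  hits <- list()
  for (dh in donors) {
    d_idx <- resolve_selection(frame, dh[[1]])
    h_idx <- resolve_selection(frame, dh[[2]])
    for (a_idx in acc_idx) {
      if (a_idx == d_idx || a_idx == h_idx) next
      g <- hbond_geometry(frame, d_idx, h_idx, a_idx)
      if (g$d_xy <= d_xy_max && g$angle_xhy >= angle_min)
        hits[[length(hits) + 1L]] <- g
    }
  }
  hits[order(vapply(hits, function(g) g$d_hy, numeric(1)))]
}
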