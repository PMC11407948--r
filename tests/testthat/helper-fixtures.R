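# Shared in-code fixtures for the test suite.

# A Gaussian-band emission spectrum on an integer grid.
gauss_spectrum <- function(center = 340, sigma = 25, peak = 1000,
                           grid = 300:500, kind = "emission", ...) {
  spectrum(grid, peak * exp(-(grid - center)^2 / (2 * sigma^2)), kind = kind, ...)
}

# A small noiseless emission titration with known truth.
toy_titration <- function(ka = 4.15e4, n = 0.91, ...) {
  simulate_titration(titration_config(ka = ka, n = n, ...))
}

# Minimal hand-written PDB text: three atoms plus an altloc-B duplicate.
tiny_pdb_text <- function() c(
  "ATOM      1  N   ALA A   1      11.104   6.134  -6.504  1.00  0.00           N",
  "ATOM      2  CA  ALA A   1      11.639   6.071  -5.147  1.00  0.00           C",
  "ATOM      3  O  AALA A   1      12.685   6.862  -4.954  1.00  0.00           O",
  "ATOM      4  O  BALA A   1      99.000  99.000  99.000  1.00  0.00           O",
  "END")

write_tiny_pdb <- function(path = tempfile(fileext = ".pdb")) {
  writeLines(tiny_pdb_text(), path)
  path
}

# A frame built directly from coordinates (all carbons unless given).
frame_from_coords <- function(coords, elements = NULL, names = NULL) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (is.null(elements)) elements <- rep("C", n)
  if (is.null(names)) names <- paste0("X", seq_len(n))
  structure_frame(
    data.frame(serial = seq_len(n), name = names, element = elements,
               resname = "TOY", resid = 1L, chain = "A"),
    coords)
}

# Trajectory from a list of coordinate matrices.
traj_from_coords <- function(coord_list, ...) {
  trajectory(lapply(coord_list, frame_from_coords, ...))
}

# Independent superposition oracle: coarse grid over Euler angles followed by
# Nelder-Mead refinement of the post-rotation RMSD (translation removed by
# centering). Slow but implementation-independent.
grid_refine_rmsd <- function(reference, mobile) {
  P <- scale(mobile, scale = FALSE); Q <- scale(reference, scale = FALSE)
  rot <- function(ang) {
    ca <- cos(ang); sa <- sin(ang)
    rz1 <- rbind(c(ca[1], -sa[1], 0), c(sa[1], ca[1], 0), c(0, 0, 1))
    ry <- rbind(c(ca[2], 0, sa[2]), c(0, 1, 0), c(-sa[2], 0, ca[2]))
    rz2 <- rbind(c(ca[3], -sa[3], 0), c(sa[3], ca[3], 0), c(0, 0, 1))
    rz1 %*% ry %*% rz2
  }
  obj <- function(ang) sqrt(mean(rowSums((P %*% t(rot(ang)) - Q)^2)))
  grid <- expand.grid(a = seq(0, 2 * pi, length.out = 13),
                      b = seq(0, pi, length.out = 7),
                      c = seq(0, 2 * pi, length.out = 13))
  vals <- apply(grid, 1L, obj)
  best <- as.numeric(grid[which.min(vals), ])
  stats::optim(best, obj, control = list(reltol = 1e-14, maxit = 5000))$value
}

# Random proper rotation matrix (via QR with det fix).
random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}
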