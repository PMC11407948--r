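test_that("kabsch_rmsd is zero under rigid transforms and symmetric", {
  set.seed(31)
  ref <- matrix(rnorm(30, sd = 5), ncol = 3)
  expect_equal(kabsch_rmsd(ref, ref)$rmsd, 0, tolerance = 1e-12)
  for (k in 1:20) {
    R <- random_rotation()
    t <- rnorm(3, sd = 10)
    mob <- ref %*% t(R) + matrix(t, nrow(ref), 3, byrow = TRUE)
    expect_lt(kabsch_rmsd(ref, mob)$rmsd, 1e-9)
  }
  # symmetry of the minimised deviation
  mob <- ref + matrix(rnorm(30, sd = 0.5), ncol = 3)
  expect_equal(kabsch_rmsd(ref, mob)$rmsd, kabsch_rmsd(mob, ref)$rmsd,
               tolerance = 1e-9)
  expect_error(kabsch_rmsd(ref, mob[1:5, ]), "mismatch")
  expect_error(kabsch_rmsd(ref[1:2, ], mob[1:2, ]), ">= 3 atoms")
})

test_that("kabsch_rmsd returns the transform that aligns mobile onto reference", {
  set.seed(32)
  ref <- matrix(rnorm(24, sd = 4), ncol = 3)
  mob <- ref %*% t(random_rotation()) + matrix(c(3, -2, 7), 8, 3, byrow = TRUE)
  k <- kabsch_rmsd(ref, mob)
  expect_equal(det(k$rotation), 1, tolerance = 1e-9)
  aligned <- mob %*% t(k$rotation) + matrix(k$translation, 8, 3, byrow = TRUE)
  expect_equal(unname(aligned), unname(ref), tolerance = 1e-9)
})

test_that("kabsch_rmsd matches a grid+refine oracle and bio3d on a bent square", {
  square <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))
  bent <- square; bent[3, 3] <- 1   # one corner lifted 1 A
  ours <- kabsch_rmsd(square, bent)$rmsd
  expect_equal(ours, grid_refine_rmsd(square, bent), tolerance = 1e-6)
  expect_equal(ours,
               bio3d::rmsd(as.vector(t(square)), as.vector(t(bent)), fit = TRUE),
               tolerance = 1e-3)  # bio3d rounds to 3 decimals
})

test_that("rmsd_series tracks conformational (not rigid) change", {
  base <- matrix(rnorm(30, sd = 5), ncol = 3)
  static <- traj_from_coords(list(base, base, base))
  expect_equal(rmsd_series(static), rep(0, 3), tolerance = 1e-12)
  expect_equal(rmsd_series(trajectory(list(frame_from_coords(base)))), 0,
               tolerance = 1e-12)

  # rigid drift only: superposition removes it
  drift <- make_toy_trajectory(toy_trajectory_config(n_atoms = 8, n_frames = 5,
                                                     rigid_drift = 2, seed = 4,
                                                     torsion = list(center = 120,
                                                                    amplitude = 0,
                                                                    period = 4)))
  expect_lt(max(rmsd_series(drift)), 1e-9)

  # uniform expansion: internal deformation grows monotonically
  expanding <- traj_from_coords(lapply(0:4, function(t) base * (1 + 0.02 * t)))
  rs <- rmsd_series(expanding)
  expect_true(all(diff(rs) > -1e-12))
  expect_gt(rs[5], rs[2])
  expect_error(rmsd_series(static, selection = integer(0)), "selection")
})

test_that("radius_of_gyration matches closed forms and is rigid-invariant", {
  one <- frame_from_coords(matrix(c(3, 4, 5), 1))
  expect_equal(radius_of_gyration(one), 0)

  two <- frame_from_coords(rbind(c(0, 0, 0), c(2, 0, 0)))  # equal masses
  expect_equal(radius_of_gyration(two), 1.0, tolerance = 1e-12)
  expect_equal(radius_of_gyration(two, rg_def = "max"), 1.0, tolerance = 1e-12)

  # mass weighting: C at origin, O at 2 A
  co <- frame_from_coords(rbind(c(0, 0, 0), c(2, 0, 0)), elements = c("C", "O"))
  m <- c(12.011, 15.999)
  com <- 2 * m[2] / sum(m)
  expect_equal(radius_of_gyration(co),
               sqrt((m[1] * com^2 + m[2] * (2 - com)^2) / sum(m)),
               tolerance = 1e-12)
  expect_equal(radius_of_gyration(co, rg_def = "max"), com, tolerance = 1e-12)

  set.seed(33)
  cloud <- frame_from_coords(matrix(rnorm(60), ncol = 3))
  rg <- radius_of_gyration(cloud)
  moved <- frame_from_coords(sweep(cloud$coords, 2, c(10, 10, 10), "+") %*%
                               t(random_rotation()))
  expect_equal(radius_of_gyration(moved), rg, tolerance = 1e-9)
})

test_that("rmsf matches closed forms and ignores rigid motion when aligned", {
  base <- matrix(rnorm(30, sd = 5), ncol = 3)
  static <- traj_from_coords(list(base, base, base))
  expect_equal(rmsf(static, align = FALSE), rep(0, 10), tolerance = 1e-12)
  expect_error(rmsf(trajectory(list(frame_from_coords(base)))), ">= 2 frames")

  # one atom oscillating +/- 1 A about its mean with equal dwell -> RMSF 1
  up <- base; up[1, 1] <- base[1, 1] + 1
  dn <- base; dn[1, 1] <- base[1, 1] - 1
  osc <- traj_from_coords(list(up, dn, up, dn))
  f <- rmsf(osc, align = FALSE)
  expect_equal(f[1], 1.0, tolerance = 1e-12)
  expect_equal(f[-1], rep(0, 9), tolerance = 1e-12)

  # rigid-body-only motion vanishes under alignment
  rigid <- traj_from_coords(lapply(1:4, function(t)
    base %*% t(random_rotation()) + matrix(rnorm(3, sd = 5), 10, 3, byrow = TRUE)))
  expect_lt(max(rmsf(rigid, align = TRUE)), 1e-9)
})

test_that("angle matches closed forms and an atan2 oracle", {
  expect_equal(angle(c(1, 0, 0), c(0, 0, 0), c(-1, 0, 0)), 180)
  expect_equal(angle(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0)), 90)
  expect_equal(angle(c(1, 0, 0), c(0, 0, 0), c(1, 1, 0)), 45, tolerance = 1e-12)
  expect_error(angle(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0)), "zero-length")

  cross <- function(u, v) c(u[2] * v[3] - u[3] * v[2],
                            u[3] * v[1] - u[1] * v[3],
                            u[1] * v[2] - u[2] * v[1])
  set.seed(34)
  for (k in 1:1000) {
    a <- rnorm(3); b <- rnorm(3); c <- rnorm(3)
    u <- a - b; v <- c - b
    oracle <- atan2(sqrt(sum(cross(u, v)^2)), sum(u * v)) * 180 / pi
    expect_equal(angle(a, b, c), oracle, tolerance = 1e-9)
  }
})

test_that("angle_series and angle_stats summarise torsion variation", {
  traj <- make_toy_trajectory(toy_trajectory_config(n_atoms = 4, n_frames = 20,
                                                    seed = 5))
  s <- angle_series(traj, c("T1", "T2", "T3"))
  expect_equal(s$values, attr(traj, "truth")$torsion_values, tolerance = 1e-9)
  expect_equal(s$range_min, 115, tolerance = 1e-9)
  expect_equal(s$range_max, 125, tolerance = 1e-9)
  expect_equal(s$width, 10, tolerance = 1e-9)

  st <- angle_stats(list(s))
  expect_equal(st$mean_width, 10)

  # constant angle -> zero width
  flat <- make_toy_trajectory(toy_trajectory_config(
    n_atoms = 4, n_frames = 5, seed = 5,
    torsion = list(center = 100, amplitude = 0, period = 4)))
  expect_equal(angle_series(flat, c("T1", "T2", "T3"))$width, 0, tolerance = 1e-9)
})

test_that("angle_stats mean is the unrounded mean, rounded half away from zero", {
  rng <- function(lo, hi) list(label = "", range_min = lo, range_max = hi)
  st <- angle_stats(list(rng(0, 22), rng(0, 16), rng(0, 20)))
  expect_equal(st$mean_width_raw, mean(c(22, 16, 20)))
  expect_equal(st$mean_width, 19)
  expect_equal(angle_stats(list(rng(0, 10), rng(0, 12)))$mean_width, 11)
  expect_equal(angle_stats(list(rng(0, 1), rng(0, 2)))$mean_width, 2)  # 1.5 -> 2
  expect_equal(angle_stats(list(rng(0, 0)))$mean_width, 0)
})
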