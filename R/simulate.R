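# Run expr with the RNG seeded to `seed`, restoring the caller's RNG state
# afterwards so generators are pure functions of (config, seed).
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_old) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Configuration for synthetic titration series
#'
#' Collects the generative parameters for [simulate_titration()] and friends.
#' The defaults reproduce the study conditions of a serum-albumin titration:
#' protein at 10.8 umol/L, ligand added to molar ratios
#' 0, 0.74, 1.48, 2.22, 2.96, 3.7, tryptophan emission band centred at
#' 340 nm.
#'
#' @param ka Binding constant, L/mol, > 0.
#' @param n Number of binding sites (Hill-type exponent), > 0.
#' @param f0_peak Peak intensity of the ligand-free spectrum, a.u., > 0.
#' @param band_center,band_sigma Gaussian emission band centre / width, nm.
#' @param protein_conc Protein concentration, mol/L.
#' @param molar_ratios Ligand:protein molar ratios, non-decreasing, first 0.
#' @param ife Optional inner-filter absorbances: list with vectors `a1`, `a2`
#'   (one per addition); the generator then attenuates the observed signal by
#'   `exp(-(a1 + a2)/2)` and attaches the absorbances to the series.
#' @param noise_sigma_rel Relative s.d. of multiplicative Gaussian noise,
#'   applied i.i.d. per wavelength (0 = noiseless).
#' @param seed Integer RNG seed.
#' @return An object of class `"titration_config"`.
#' @export
titration_config <- function(ka, n, f0_peak = 1000, band_center = 340,
                             band_sigma = 25, protein_conc = 10.8e-6,
                             molar_ratios = c(0, 0.74, 1.48, 2.22, 2.96, 3.7),
                             ife = NULL, noise_sigma_rel = 0, seed = 1L) {
  if (ka <= 0) stop("ka must be > 0")
  if (n <= 0) stop("n must be > 0")
  if (f0_peak <= 0) stop("f0_peak must be > 0")
  if (molar_ratios[1] != 0 || any(diff(molar_ratios) < 0))
    stop("molar_ratios must be non-decreasing and start at 0")
  if (!is.null(ife) &&
      (length(ife$a1) != length(molar_ratios) ||
       length(ife$a2) != length(molar_ratios)))
    stop("ife$a1/a2 need one absorbance per addition")
  if (noise_sigma_rel < 0) stop("noise_sigma_rel must be >= 0")
  structure(list(ka = ka, n = n, f0_peak = f0_peak, band_center = band_center,
                 band_sigma = band_sigma, protein_conc = protein_conc,
                 molar_ratios = molar_ratios, ife = ife,
                 noise_sigma_rel = noise_sigma_rel, seed = as.integer(seed)),
            class = "titration_config")
}

gaussian_band <- function(grid, center, sigma, peak)
  peak * exp(-(grid - center)^2 / (2 * sigma^2))

apply_noise <- function(y, sigma_rel)
  if (sigma_rel > 0) pmax(0, y * (1 + stats::rnorm(length(y), 0, sigma_rel))) else y

#' Simulate an emission titration with known binding ground truth
#'
#' Inverts the double-log quenching equation into the generative model
#' \deqn{F([Q]) = F_0 / (1 + K_a [Q]^n), \quad [Q] = ratio \cdot [P],}
#' so the simulated peak intensities are exactly log-linear in
#' \eqn{\lg [Q]} and [fit_double_log()] recovers (Ka, n) to machine precision
#' in the noiseless case. Each addition's spectrum is a Gaussian emission
#' band scaled so its peak equals \eqn{F}. With `config$ife` set, the
#' observed intensities are attenuated by `exp(-(a1 + a2)/2)` (which
#' [correct_inner_filter()] undoes exactly); multiplicative noise is applied
#' per wavelength after attenuation.
#'
#' The ground truth is attached as `attr(series, "truth")`: a list with
#' `ka`, `n`, `Q`, and the per-addition true peak intensities `f_true`.
#'
#' @param config A [titration_config()].
#' @return A [titration_series()] of kind `"emission"`.
#' @examples
#' s <- simulate_titration(titration_config(ka = 4.15e4, n = 0.91))
#' fit_double_log(quench_points(s))
#' @export
simulate_titration <- function(config) {
  stopifnot(inherits(config, "titration_config"))
  grid <- seq(300, 500, by = 1)
  q <- config$molar_ratios * config$protein_conc
  f_true <- config$f0_peak / (1 + config$ka * q^config$n)
  with_seed(config$seed, {
    spectra <- lapply(seq_along(q), function(i) {
      y <- gaussian_band(grid, config$band_center, config$band_sigma, f_true[i])
      if (!is.null(config$ife))
        y <- y * exp(-(config$ife$a1[i] + config$ife$a2[i]) / 2)
      spectrum(grid, apply_noise(y, config$noise_sigma_rel), kind = "emission",
               excitation = 280, label = sprintf("ratio_%g", config$molar_ratios[i]))
    })
    series <- titration_series(config$protein_conc, q, spectra,
                               ife_absorbances = config$ife)
    attr(series, "truth") <- list(ka = config$ka, n = config$n, q = q,
                                  f_true = f_true)
    series
  })
}

#' Simulate a synchronous-fluorescence titration with a fixed endpoint RSFQ
#'
#' Produces a synchronous-kind series whose endpoint quenching ratio
#' ([rsfq()] of the last vs first addition) equals `max_quench_fraction` by
#' construction; intermediate additions follow the saturable binding model,
#' with the bound fraction \eqn{\theta = 1 - 1/(1 + K_a [Q]^n)} rescaled so
#' the final addition reaches the requested endpoint. The band centre
#' defaults to 340 nm for \eqn{\Delta\lambda} = 60 nm (tryptophan) and
#' 300 nm for 15 nm (tyrosine).
#'
#' @param config A [titration_config()] (its `band_center` is ignored unless
#'   `delta_lambda` is non-standard).
#' @param delta_lambda Wavelength offset, nm (15 or 60 in practice).
#' @param max_quench_fraction Endpoint RSFQ, in \[0, 1).
#' @return A [titration_series()] of kind `"synchronous"` with
#'   `attr(series, "truth")` carrying the per-addition quench fractions.
#' @export
simulate_synchronous <- function(config, delta_lambda, max_quench_fraction) {
  stopifnot(inherits(config, "titration_config"))
  if (max_quench_fraction < 0 || max_quench_fraction >= 1)
    stop("max_quench_fraction must be in [0, 1)")
  center <- if (delta_lambda == 60) 340 else if (delta_lambda == 15) 300
            else config$band_center
  grid <- seq(300, 500, by = 1)
  q <- config$molar_ratios * config$protein_conc
  theta <- 1 - 1 / (1 + config$ka * q^config$n)
  scale <- if (max(theta) > 0) theta / max(theta) else theta
  quench <- max_quench_fraction * scale
  f_peak <- config$f0_peak * (1 - quench)
  with_seed(config$seed, {
    spectra <- lapply(seq_along(q), function(i)
      spectrum(grid,
               apply_noise(gaussian_band(grid, center, config$band_sigma, f_peak[i]),
                           config$noise_sigma_rel),
               kind = "synchronous", excitation = 280, delta_lambda = delta_lambda,
               label = sprintf("ratio_%g", config$molar_ratios[i])))
    series <- titration_series(config$protein_conc, q, spectra)
    attr(series, "truth") <- list(quench = quench, f_peak = f_peak)
    series
  })
}

#' Simulate a UV-absorbance titration with a fixed endpoint change
#'
#' Produces an absorbance series (grid 200-300 nm, band at 278 nm for the
#' aromatic protein absorption) whose endpoint [delta_percent()] at the
#' tracked peak equals `total_delta_percent`, the intensity change and the
#' blue shift of the peak position both linear in addition index.
#'
#' @param config A [titration_config()]; its `f0_peak` is the baseline peak
#'   absorbance (a.u.).
#' @param total_delta_percent Endpoint percent change of the peak absorbance
#'   (> -100; positive = hyperchromic).
#' @param blue_shift_nm Total shift of the band centre toward shorter
#'   wavelengths across the series, nm.
#' @return A [titration_series()] of kind `"absorbance"`.
#' @export
simulate_uv <- function(config, total_delta_percent, blue_shift_nm = 0) {
  stopifnot(inherits(config, "titration_config"))
  if (total_delta_percent <= -100) stop("total_delta_percent must be > -100")
  grid <- seq(200, 300, by = 1)
  q <- config$molar_ratios * config$protein_conc
  m <- length(q)
  frac <- if (m > 1) (seq_len(m) - 1) / (m - 1) else 0
  peaks <- config$f0_peak * (1 + total_delta_percent / 100 * frac)
  centers <- 278 - blue_shift_nm * frac
  with_seed(config$seed, {
    spectra <- lapply(seq_len(m), function(i)
      spectrum(grid,
               apply_noise(gaussian_band(grid, centers[i], 12, peaks[i]),
                           config$noise_sigma_rel),
               kind = "absorbance",
               label = sprintf("ratio_%g", config$molar_ratios[i])))
    series <- titration_series(config$protein_conc, q, spectra)
    attr(series, "truth") <- list(peaks = peaks, centers = centers)
    series
  })
}

#' Simulate a site-marker competition series
#'
#' A saturable displacement model: at marker:protein ratio \eqn{r},
#' \deqn{F_2 = F_1 \left(1 - d_{max} \frac{r}{r + r_{1/2}}\right),}
#' so displacement tends to \eqn{100 (1 - d_{max})} percent as the marker
#' saturates (warfarin-like competition), and `dmax = 0` yields the flat
#' 100 percent curve of a non-competing marker (ibuprofen-like).
#'
#' @param f1 Fluorescence without marker, a.u., > 0.
#' @param marker_ratios Marker:protein concentration ratios, >= 0.
#' @param dmax Maximal displaced fraction, in \[0, 1).
#' @param half_sat_ratio Ratio at half-saturation, > 0.
#' @param protein_conc Protein concentration, mol/L.
#' @return `data.frame` with columns `marker_conc`, `F1`, `F2` suitable for
#'   [displacement_curve()].
#' @export
simulate_competition <- function(f1, marker_ratios, dmax, half_sat_ratio,
                                 protein_conc = 10.8e-6) {
  if (f1 <= 0) stop("f1 must be > 0")
  if (dmax < 0 || dmax >= 1) stop("dmax must be in [0, 1)")
  if (half_sat_ratio <= 0) stop("half_sat_ratio must be > 0")
  r <- as.numeric(marker_ratios)
  data.frame(marker_conc = r * protein_conc, F1 = f1,
             F2 = f1 * (1 - dmax * r / (r + half_sat_ratio)))
}

#' Configuration for toy trajectories with planted geometry
#'
#' @param n_atoms Number of background atoms (carbon, random positions in a
#'   10 Angstrom box).
#' @param n_frames Number of frames, >= 2.
#' @param rigid_drift Rigid translation applied cumulatively per frame,
#'   Angstrom (along x).
#' @param torsion List `(center, amplitude, period)`: the planted three-atom
#'   angle oscillates as `center + amplitude * sin(2 pi t / period)` degrees.
#' @param planted_hbonds List of length-3 vectors `c(d_xh, d_hy, angle_deg)`;
#'   each is realised exactly as an X-H...Y triple in every frame.
#' @param jitter_sigma Per-coordinate Gaussian jitter s.d., Angstrom.
#' @param seed Integer RNG seed.
#' @return An object of class `"toy_trajectory_config"`.
#' @export
toy_trajectory_config <- function(n_atoms = 12, n_frames = 50, rigid_drift = 0,
                                  torsion = list(center = 120, amplitude = 5,
                                                 period = 20),
                                  planted_hbonds = list(), jitter_sigma = 0,
                                  seed = 1L) {
  if (n_frames < 2L) stop("n_frames must be >= 2")
  if (torsion$amplitude < 0) stop("torsion amplitude must be >= 0")
  if (jitter_sigma < 0) stop("jitter_sigma must be >= 0")
  structure(list(n_atoms = n_atoms, n_frames = n_frames,
                 rigid_drift = rigid_drift, torsion = torsion,
                 planted_hbonds = planted_hbonds,
                 jitter_sigma = jitter_sigma, seed = as.integer(seed)),
            class = "toy_trajectory_config")
}

#' Build a toy trajectory with exactly known descriptors
#'
#' Constructs a deterministic trajectory for exercising the descriptor
#' pipeline: a jittered cloud of background atoms, an explicit three-atom
#' subunit (`T1`, `T2`, `T3`) whose angle at `T2` follows the configured
#' sinusoid exactly (before jitter), planted donor-hydrogen-acceptor triples
#' (`Dk`, `Hk`, `Ak`) realised at the requested geometry in every frame, and
#' an optional cumulative rigid drift. Ground truth (atom roles, per-frame
#' torsion values) is attached as `attr(traj, "truth")`.
#'
#' @param config A [toy_trajectory_config()].
#' @return A [trajectory()].
#' @export
make_toy_trajectory <- function(config) {
  stopifnot(inherits(config, "toy_trajectory_config"))
  with_seed(config$seed, {
    base <- matrix(stats::runif(config$n_atoms * 3, 0, 10), ncol = 3)
    tor <- config$torsion
    t_idx <- config$n_atoms + 1:3
    hb_rows <- lapply(seq_along(config$planted_hbonds), function(k) {
      p <- config$planted_hbonds[[k]]
      a <- p[3] * pi / 180
      x <- c(-15, 12 * k, 0)
      h <- x + c(p[1], 0, 0)
      y <- h + p[2] * c(-cos(a), sin(a), 0)   # angle X-H...Y = p[3] exactly
      rbind(x, h, y)
    })
    n_hb <- length(config$planted_hbonds)
    theta <- tor$center + tor$amplitude * sin(2 * pi * (seq_len(config$n_frames) - 1) /
                                              tor$period)
    atoms <- data.frame(
      serial = seq_len(config$n_atoms + 3L + 3L * n_hb),
      name = c(paste0("B", seq_len(config$n_atoms)), "T1", "T2", "T3",
               if (n_hb) as.vector(vapply(seq_len(n_hb), function(k)
                 paste0(c("D", "H", "A"), k), character(3)))),
      element = c(rep("C", config$n_atoms), rep("C", 3L),
                  rep(c("O", "H", "O"), n_hb)),
      resname = "TOY", resid = 1L, chain = "A")
    frames <- lapply(seq_len(config$n_frames), function(t) {
      th <- theta[t] * pi / 180
      t2 <- c(20, 0, 0)
      tri <- rbind(t2 + c(1.5, 0, 0), t2, t2 + 1.5 * c(cos(th), sin(th), 0))
      co <- rbind(base, tri, do.call(rbind, hb_rows))
      co <- co + matrix(c(config$rigid_drift * (t - 1), 0, 0),
                        nrow(co), 3L, byrow = TRUE)
      if (config$jitter_sigma > 0)
        co <- co + matrix(stats::rnorm(length(co), 0, config$jitter_sigma),
                          nrow(co), 3L)
      structure_frame(atoms, co)
    })
    traj <- trajectory(frames, seq_len(config$n_frames) - 1)
    attr(traj, "truth") <- list(
      torsion_triplet = t_idx, torsion_values = theta,
      hbond_triples = if (n_hb) lapply(seq_len(n_hb), function(k)
        config$n_atoms + 3L + 3L * (k - 1L) + 1:3) else list())
    traj
  })
}
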