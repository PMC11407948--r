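#' Inner-filter-effect correction
#'
#' Corrects observed fluorescence for primary and secondary inner-filter
#' attenuation: \deqn{F_{cor} = F_{obs} \cdot e^{(A_1 + A_2)/2}} where
#' \eqn{A_1} is the absorbance at the excitation wavelength and \eqn{A_2} at
#' the emission wavelength. Vectorised; monotone increasing in `a1 + a2`.
#'
#' @param f_obs Observed fluorescence intensity, a.u., >= 0.
#' @param a1 Absorbance at the excitation wavelength, >= 0.
#' @param a2 Absorbance at the emission wavelength, >= 0.
#' @return Corrected intensity, same length as `f_obs`.
#' @examples
#' correct_inner_filter(100, 0.1, 0.1)  # 100 * exp(0.1) = 110.5171
#' @export
correct_inner_filter <- function(f_obs, a1, a2) {
  if (any(!is.finite(a1)) || any(!is.finite(a2)) || any(a1 < 0) || any(a2 < 0))
    stop("absorbances a1, a2 must be finite and >= 0")
  if (any(f_obs < 0)) stop("f_obs must be >= 0")
  f_obs * exp((a1 + a2) / 2)
}

#' Signed percent change from a baseline
#'
#' \eqn{\Delta(\%) = (x - x_0)/x_0 \times 100}. Positive values mean a
#' hyperchromic/enhancement effect, negative values quenching.
#'
#' @param baseline Baseline value (\eqn{A_0} or \eqn{F_0}), > 0.
#' @param value Observed value (\eqn{A} or \eqn{F}).
#' @return Signed percent change.
#' @export
delta_percent <- function(baseline, value) {
  if (any(!is.finite(baseline)) || any(baseline <= 0))
    stop("baseline must be finite and > 0")
  (value - baseline) / baseline * 100
}

#' Extract quenching points from an emission titration series
#'
#' For each addition, reads the peak intensity within `peak_window` (the
#' tryptophan emission region by default). `F0` is the peak of the
#' ligand-free baseline spectrum; `F` the peak after each addition. With
#' `apply_ife = TRUE` both are corrected with [correct_inner_filter()] using
#' the series' attached absorbance pairs. The zero-ligand point itself is
#' excluded from the returned table (its log-transform is undefined in the
#' double-log fit).
#'
#' @param series Emission-kind [titration_series()] whose first addition has
#'   `[Q] = 0`.
#' @param peak_window `c(lo, hi)` nm window for [peak_find()].
#' @param apply_ife Apply inner-filter correction (requires
#'   `series$ife_absorbances`).
#' @return `data.frame` with columns `Q` (mol/L), `F0`, `F` (a.u.), one row
#'   per non-zero addition. Points with `F >= F0` (no quenching) are retained
#'   with a warning.
#' @export
quench_points <- function(series, peak_window = c(320, 360), apply_ife = FALSE) {
  stopifnot(inherits(series, "titration_series"))
  if (series$spectra[[1]]$kind != "emission")
    stop("quench_points requires an emission-kind series")
  if (series$ligand_concs[1] != 0)
    stop("first addition must be the ligand-free baseline ([Q] = 0)")
  if (apply_ife && is.null(series$ife_absorbances))
    stop("apply_ife = TRUE but the series carries no ife_absorbances")
  peaks <- vapply(series$spectra,
                  function(s) peak_find(s, peak_window)$i_max, numeric(1))
  if (apply_ife)
    peaks <- correct_inner_filter(peaks, series$ife_absorbances$a1,
                                  series$ife_absorbances$a2)
  f0 <- peaks[1]
  keep <- series$ligand_concs > 0
  out <- data.frame(Q = series$ligand_concs[keep], F0 = rep(f0, sum(keep)),
                    F = peaks[keep])
  if (any(out$F >= out$F0))
    warning(sprintf("%d point(s) show F >= F0 (no quenching); retained",
                    sum(out$F >= out$F0)))
  out
}

#' Double-logarithmic binding fit (Ka, n)
#'
#' Fits the double-log (Hill-type) quenching equation
#' \deqn{\lg\frac{F_0 - F}{F} = \lg K_a + n \lg [Q]}
#' by ordinary least squares of \eqn{y = \lg((F_0-F)/F)} on
#' \eqn{x = \lg[Q]} (base-10 logarithms). The slope estimates the number of
#' binding sites \eqn{n}; the binding constant is \eqn{K_a = 10^{intercept}}
#' in L/mol. Points violating \eqn{0 < F < F_0} or \eqn{[Q] > 0} cannot be
#' transformed and are dropped with a message; no weighting is applied.
#'
#' @param points `data.frame` with columns `Q`, `F0`, `F`, e.g. from
#'   [quench_points()].
#' @return An object of class `"binding_fit"`: list with `Ka` (L/mol), `n`,
#'   `slope`, `intercept`, `r_squared`, `points_used`, `points_dropped`, and
#'   per-point `residuals` on the log scale.
#' @examples
#' # noiseless points from F = F0 / (1 + Ka * Q^n) are exactly log-linear
#' Q <- c(0.74, 1.48, 2.22, 2.96, 3.7) * 10.8e-6
#' F <- 1000 / (1 + 4.15e4 * Q^0.91)
#' fit_double_log(data.frame(Q = Q, F0 = 1000, F = F))
#' @export
fit_double_log <- function(points) {
  stopifnot(is.data.frame(points), all(c("Q", "F0", "F") %in% names(points)))
  usable <- points$Q > 0 & points$F > 0 & points$F < points$F0
  dropped <- sum(!usable)
  if (dropped > 0)
    message(sprintf("fit_double_log: dropped %d point(s) violating 0 < F < F0, Q > 0",
                    dropped))
  pts <- points[usable, , drop = FALSE]
  if (nrow(pts) < 2L) {
    if (all(points$F == points$F0))
      stop("no quenching signal: all F equal F0")
    stop(sprintf("need >= 2 usable points for the double-log fit, have %d",
                 nrow(pts)))
  }
  x <- log10(pts$Q)
  y <- log10((pts$F0 - pts$F) / pts$F)
  fit <- stats::lm(y ~ x)
  co <- stats::coef(fit)
  ss_tot <- sum((y - mean(y))^2)
  # computed directly: summary.lm warns on exact fits, which are the normal
  # case for noiseless generated data
  r2 <- if (ss_tot == 0) 1 else 1 - sum(stats::residuals(fit)^2) / ss_tot
  structure(
    list(slope = unname(co[2]), intercept = unname(co[1]),
         Ka = 10^unname(co[1]), n = unname(co[2]),
         r_squared = r2, points_used = nrow(pts), points_dropped = dropped,
         residuals = unname(stats::residuals(fit))),
    class = "binding_fit")
}

#' @export
print.binding_fit <- function(x, ...) {
  cat(sprintf("<binding_fit> Ka = %.4g L/mol, n = %.3f, r^2 = %.5f (%d points, %d dropped)\n",
              x$Ka, x$n, x$r_squared, x$points_used, x$points_dropped))
  invisible(x)
}

#' Ratio of synchronous fluorescence quenching (RSFQ)
#'
#' \deqn{R_{SFQ} = 1 - F/F_0} computed at fixed \eqn{\Delta\lambda};
#' reported as a percent in summaries (multiply by 100). A value > 0 means
#' quenching; `F > F0` yields a negative value with a warning (enhancement).
#'
#' @param f0 Intensity before ligand addition, > 0.
#' @param f Intensity after addition, >= 0.
#' @return Fraction quenched, in \[0, 1\] whenever `0 <= f <= f0`.
#' @export
rsfq <- function(f0, f) {
  if (any(!is.finite(f0)) || any(f0 <= 0)) stop("F0 must be finite and > 0")
  if (any(f < 0)) stop("F must be >= 0")
  if (any(f > f0))
    warning("F > F0: negative RSFQ indicates enhancement, not quenching")
  1 - f / f0
}

#' Site-marker displacement curve
#'
#' For a competitive displacement experiment, computes
#' \eqn{Displacement = 100 \cdot F_2/F_1} at each marker dose, where
#' \eqn{F_1} is the protein-ligand fluorescence without the site marker and
#' \eqn{F_2} with it, plotted against the marker:protein concentration ratio.
#' Input order is preserved.
#'
#' @param points `data.frame` with columns `marker_conc` (mol/L), `F1`, `F2`.
#' @param protein_conc Protein concentration, mol/L, > 0.
#' @return `data.frame` with `ratio` (marker_conc/protein_conc) and
#'   `displacement` (percent).
#' @export
displacement_curve <- function(points, protein_conc) {
  stopifnot(is.data.frame(points),
            all(c("marker_conc", "F1", "F2") %in% names(points)))
  if (any(points$F1 <= 0)) stop("all F1 must be > 0")
  if (length(protein_conc) != 1L || protein_conc <= 0)
    stop("protein_conc must be a single positive number")
  data.frame(ratio = points$marker_conc / protein_conc,
             displacement = 100 * points$F2 / points$F1)
}

#' Assign the binding site from two marker displacement curves
#'
#' Warfarin marks Sudlow site I (subdomain IIA) and ibuprofen Sudlow site II
#' (subdomain IIIA). A ligand occupies a site when that marker's endpoint
#' displacement drops below `100 - threshold` percent while the other
#' marker's does not; if both (neither) drop the label is `"both"`
#' (`"neither"`).
#'
#' @param warfarin_curve,ibuprofen_curve `data.frame`s from
#'   [displacement_curve()], nonempty.
#' @param threshold Percent drop of the endpoint displacement counted as
#'   competition (default 10).
#' @return One of `"Sudlow I"`, `"Sudlow II"`, `"both"`, `"neither"`.
#' @export
site_assignment <- function(warfarin_curve, ibuprofen_curve, threshold = 10) {
  stopifnot(nrow(warfarin_curve) > 0, nrow(ibuprofen_curve) > 0)
  w_end <- warfarin_curve$displacement[nrow(warfarin_curve)]
  i_end <- ibuprofen_curve$displacement[nrow(ibuprofen_curve)]
  w_drop <- w_end < (100 - threshold)
  i_drop <- i_end < (100 - threshold)
  if (w_drop && !i_drop) "Sudlow I"
  else if (i_drop && !w_drop) "Sudlow II"
  else if (w_drop && i_drop) "both"
  else "neither"
}
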