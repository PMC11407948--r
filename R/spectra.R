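#' Construct a single spectrum
#'
#' A spectrum is one instrument scan: a strictly increasing wavelength grid
#' (nm) with one intensity per grid point (arbitrary units). Three kinds are
#' supported: steady-state `"emission"` scans, `"absorbance"` (UV-vis) scans,
#' and `"synchronous"` scans acquired at a constant excitation-emission offset
#' \eqn{\Delta\lambda}, which is required for that kind (15 nm probes tyrosine,
#' 60 nm tryptophan environments in serum albumin).
#'
#' @param wavelengths Numeric vector, nm, strictly increasing, length >= 2.
#' @param intensities Numeric vector, a.u., same length, all >= 0. Negative
#'   values are rejected rather than clipped so instrument or parsing problems
#'   surface immediately.
#' @param kind One of `"emission"`, `"absorbance"`, `"synchronous"`.
#' @param excitation Optional excitation wavelength (nm).
#' @param delta_lambda Offset \eqn{\Delta\lambda} (nm); required iff
#'   `kind = "synchronous"`.
#' @param label Free-text label.
#' @return An object of class `"spectrum"`.
#' @examples
#' sp <- spectrum(300:500, dnorm(300:500, 340, 25), kind = "emission")
#' peak_find(sp, c(320, 360))
#' @export
spectrum <- function(wavelengths, intensities,
                     kind = c("emission", "absorbance", "synchronous"),
                     excitation = NULL, delta_lambda = NULL, label = "") {
  kind <- match.arg(kind)
  wavelengths <- as.numeric(wavelengths)
  intensities <- as.numeric(intensities)
  if (length(wavelengths) < 2L || length(wavelengths) != length(intensities))
    stop("wavelengths and intensities must have equal length >= 2")
  if (any(!is.finite(wavelengths)) || any(!is.finite(intensities)))
    stop("non-finite values in spectrum")
  if (any(diff(wavelengths) <= 0))
    stop("wavelengths must be strictly increasing")
  if (any(intensities < 0))
    stop("negative intensities are rejected, not clipped")
  if (kind == "synchronous" && is.null(delta_lambda))
    stop("delta_lambda is required for synchronous spectra")
  structure(
    list(wavelengths = wavelengths, intensities = intensities, kind = kind,
         excitation = if (is.null(excitation)) NA_real_ else as.numeric(excitation),
         delta_lambda = if (is.null(delta_lambda)) NA_real_ else as.numeric(delta_lambda),
         label = as.character(label)),
    class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum> kind=%s, %d points, %g-%g nm%s%s\n",
              x$kind, length(x$wavelengths),
              min(x$wavelengths), max(x$wavelengths),
              if (is.finite(x$delta_lambda)) sprintf(", dl=%g nm", x$delta_lambda) else "",
              if (nzchar(x$label)) paste0(", '", x$label, "'") else ""))
  invisible(x)
}

#' Construct a titration series
#'
#' An ordered set of spectra recorded over successive ligand additions to a
#' fixed protein solution. The first addition is the ligand-free baseline
#' (`ligand_concs[1] == 0`); all spectra must share one wavelength grid and
#' kind (no resampling is performed, since intensities are always read at
#' fixed grid positions).
#'
#' @param protein_conc Protein concentration, mol/L, > 0.
#' @param ligand_concs Total ligand concentration \eqn{[Q]} per addition,
#'   mol/L; non-negative, non-decreasing, first element 0.
#' @param spectra List of [spectrum()] objects, one per addition.
#' @param ife_absorbances Optional inner-filter absorbance pairs: a list with
#'   numeric vectors `a1` (absorbance at the excitation wavelength) and `a2`
#'   (at the emission wavelength), one value per addition.
#' @return An object of class `"titration_series"` with computed
#'   `molar_ratios = ligand_concs / protein_conc`.
#' @export
titration_series <- function(protein_conc, ligand_concs, spectra,
                             ife_absorbances = NULL) {
  protein_conc <- as.numeric(protein_conc)
  ligand_concs <- as.numeric(ligand_concs)
  if (length(protein_conc) != 1L || !is.finite(protein_conc) || protein_conc <= 0)
    stop("protein_conc must be a single positive number")
  if (length(ligand_concs) == 0L || ligand_concs[1] != 0)
    stop("first ligand concentration must be 0 (ligand-free baseline)")
  if (any(ligand_concs < 0) || any(diff(ligand_concs) < 0))
    stop("ligand_concs must be non-negative and non-decreasing")
  if (!is.list(spectra) || length(spectra) == 0L)
    stop("spectra must be a non-empty list of spectrum objects")
  if (length(spectra) != length(ligand_concs))
    stop(sprintf("got %d spectra for %d ligand concentrations",
                 length(spectra), length(ligand_concs)))
  if (!all(vapply(spectra, inherits, logical(1), "spectrum")))
    stop("all elements of spectra must be spectrum objects")
  grid <- spectra[[1]]$wavelengths
  kind <- spectra[[1]]$kind
  for (i in seq_along(spectra)) {
    if (!identical(spectra[[i]]$kind, kind))
      stop("all spectra in a series must share one kind")
    if (length(spectra[[i]]$wavelengths) != length(grid) ||
        any(spectra[[i]]$wavelengths != grid))
      stop("all spectra in a series must share one wavelength grid")
  }
  if (!is.null(ife_absorbances)) {
    a1 <- as.numeric(ife_absorbances$a1)
    a2 <- as.numeric(ife_absorbances$a2)
    if (length(a1) != length(spectra) || length(a2) != length(spectra))
      stop("ife_absorbances$a1 and $a2 need one value per addition")
    if (any(a1 < 0) || any(a2 < 0)) stop("absorbances must be >= 0")
    ife_absorbances <- list(a1 = a1, a2 = a2)
  }
  structure(
    list(protein_conc = protein_conc, ligand_concs = ligand_concs,
         molar_ratios = ligand_concs / protein_conc,
         spectra = spectra, ife_absorbances = ife_absorbances),
    class = "titration_series")
}

#' @export
print.titration_series <- function(x, ...) {
  cat(sprintf("<titration_series> %s, %d additions, ratios %s, [P]=%g mol/L%s\n",
              x$spectra[[1]]$kind, length(x$spectra),
              paste(signif(x$molar_ratios, 3), collapse = ", "),
              x$protein_conc,
              if (is.null(x$ife_absorbances)) "" else ", IFE absorbances attached"))
  invisible(x)
}

#' Locate the peak of a spectrum inside a wavelength window
#'
#' Returns the grid point of maximal intensity within `window`. Ties are
#' broken toward the smaller wavelength so the result is deterministic; the
#' result is invariant under positive rescaling of intensities and shifts
#' rigidly with the grid.
#'
#' @param sp A [spectrum()].
#' @param window Numeric `c(lo, hi)` in nm; must overlap the grid.
#' @return List with `lambda_max` (nm) and `i_max` (a.u.).
#' @examples
#' sp <- spectrum(300:500, exp(-((300:500) - 340)^2 / 800), "emission")
#' peak_find(sp, c(320, 360))$lambda_max  # 340
#' @export
peak_find <- function(sp, window) {
  stopifnot(inherits(sp, "spectrum"))
  window <- as.numeric(window)
  if (length(window) != 2L || window[1] > window[2])
    stop("window must be c(lo, hi) with lo <= hi")
  in_win <- sp$wavelengths >= window[1] & sp$wavelengths <= window[2]
  if (!any(in_win))
    stop(sprintf("window [%g, %g] nm contains no grid points (grid %g-%g nm)",
                 window[1], window[2], min(sp$wavelengths), max(sp$wavelengths)))
  wl <- sp$wavelengths[in_win]
  iy <- sp$intensities[in_win]
  k <- which.max(iy)  # first maximum = smallest wavelength on an increasing grid
  list(lambda_max = wl[k], i_max = iy[k])
}
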