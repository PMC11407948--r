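# Titration CSV dialect: '#key = value' comment header lines, then one
# header row and the numeric body, comma-separated, UTF-8, '.' decimal.
# Column 1 is the wavelength grid; each further column is one addition, in
# addition order. Numbers are written with %.17g so a read/write round trip
# is exact well below the 1e-12 relative contract.

fmt_num <- function(x) sprintf("%.17g", x)

#' Write a titration series to a self-describing CSV file
#'
#' @param series A [titration_series()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [read_titration_csv()]
#' @export
write_titration_csv <- function(series, path) {
  stopifnot(inherits(series, "titration_series"))
  sp1 <- series$spectra[[1]]
  hdr <- c(
    sprintf("#kind = %s", sp1$kind),
    sprintf("#protein_conc = %s", fmt_num(series$protein_conc)),
    sprintf("#ligand_concs = %s", paste(fmt_num(series$ligand_concs), collapse = ",")))
  if (is.finite(sp1$excitation))
    hdr <- c(hdr, sprintf("#excitation = %s", fmt_num(sp1$excitation)))
  if (sp1$kind == "synchronous")
    hdr <- c(hdr, sprintf("#delta_lambda = %s", fmt_num(sp1$delta_lambda)))
  if (!is.null(series$ife_absorbances)) {
    hdr <- c(hdr,
      sprintf("#ife_a1 = %s", paste(fmt_num(series$ife_absorbances$a1), collapse = ",")),
      sprintf("#ife_a2 = %s", paste(fmt_num(series$ife_absorbances$a2), collapse = ",")))
  }
  labels <- vapply(series$spectra, function(s) s$label, character(1))
  if (any(nzchar(labels)))
    hdr <- c(hdr, sprintf("#labels = %s", paste(labels, collapse = ",")))
  n_add <- length(series$spectra)
  body <- cbind(series$spectra[[1]]$wavelengths,
                do.call(cbind, lapply(series$spectra, function(s) s$intensities)))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines(paste(c("wavelength", sprintf("add_%d", seq_len(n_add) - 1L)),
                   collapse = ","), con)
  writeLines(apply(body, 1L, function(r) paste(fmt_num(r), collapse = ",")), con)
  invisible(path)
}

#' Read a titration series from CSV
#'
#' Parses the dialect written by [write_titration_csv()]: `#key = value`
#' header lines declaring `kind`, `protein_conc`, `ligand_concs` (and
#' `delta_lambda` for synchronous series), then a wavelength column plus one
#' intensity column per addition. Column order defines addition order.
#'
#' @param path Input file path.
#' @return A validated [titration_series()].
#' @export
read_titration_csv <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  is_meta <- startsWith(lines, "#")
  meta <- list()
  for (ln in lines[is_meta]) {
    m <- regmatches(ln, regexec("^#\\s*([A-Za-z0-9_]+)\\s*=\\s*(.*)$", ln))[[1]]
    if (length(m) == 3L) meta[[m[2]]] <- trimws(m[3])
  }
  for (key in c("kind", "protein_conc", "ligand_concs"))
    if (is.null(meta[[key]]))
      stop(sprintf("titration CSV format error: missing header key '%s'", key))
  if (identical(meta$kind, "synchronous") && is.null(meta$delta_lambda))
    stop("titration CSV format error: missing header key 'delta_lambda' for synchronous series")

  body_lines <- lines[!is_meta]
  body_lines <- body_lines[nzchar(trimws(body_lines))]
  if (length(body_lines) < 3L) stop("titration CSV format error: no data rows")
  col_names <- strsplit(body_lines[1], ",", fixed = TRUE)[[1]]
  n_col <- length(col_names)
  rows <- strsplit(body_lines[-1], ",", fixed = TRUE)
  widths <- lengths(rows)
  if (any(widths != n_col))
    stop(sprintf("titration CSV format error: ragged row %d (%d fields, expected %d)",
                 which(widths != n_col)[1] + 1L, widths[widths != n_col][1], n_col))
  num <- matrix(suppressWarnings(as.numeric(unlist(rows))),
                ncol = n_col, byrow = TRUE)
  if (any(is.na(num)))
    stop(sprintf("titration CSV format error: non-numeric field in row %d",
                 which(apply(num, 1L, anyNA))[1] + 1L))

  wl <- num[, 1L]
  if (any(diff(wl) <= 0)) stop("wavelengths must be strictly increasing")
  parse_vec <- function(s) as.numeric(strsplit(s, ",", fixed = TRUE)[[1]])
  ligand_concs <- parse_vec(meta$ligand_concs)
  if (ncol(num) - 1L != length(ligand_concs))
    stop(sprintf("titration CSV format error: %d intensity columns for %d ligand_concs",
                 ncol(num) - 1L, length(ligand_concs)))
  labels <- if (!is.null(meta$labels))
    strsplit(meta$labels, ",", fixed = TRUE)[[1]] else rep("", ncol(num) - 1L)
  dl <- if (is.null(meta$delta_lambda)) NULL else as.numeric(meta$delta_lambda)
  exc <- if (is.null(meta$excitation)) NULL else as.numeric(meta$excitation)
  spectra <- lapply(seq_len(ncol(num) - 1L), function(i)
    spectrum(wl, num[, i + 1L], kind = meta$kind, excitation = exc,
             delta_lambda = dl,
             label = if (i <= length(labels)) labels[i] else ""))
  ife <- NULL
  if (!is.null(meta$ife_a1) && !is.null(meta$ife_a2))
    ife <- list(a1 = parse_vec(meta$ife_a1), a2 = parse_vec(meta$ife_a2))
  titration_series(as.numeric(meta$protein_conc), ligand_concs, spectra,
                   ife_absorbances = ife)
}
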