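#' Component-energy ledger for a docked complex
#'
#' Holds the total energies of the complex, free ligand and free receptor
#' (kJ/mol), from which the binding energy
#' \deqn{E_{binding} = E_{complex} - E_{ligand} - E_{receptor}}
#' is derived, plus optional electrostatic and van der Waals interaction
#' components.
#'
#' @param e_complex,e_ligand,e_receptor Component energies, kJ/mol.
#' @param e_electrostatic,e_vdw Optional interaction components, kJ/mol.
#' @return An object of class `"energy_ledger"` with derived `e_binding`.
#' @export
energy_ledger <- function(e_complex, e_ligand, e_receptor,
                          e_electrostatic = NULL, e_vdw = NULL) {
  for (v in list(e_complex, e_ligand, e_receptor))
    if (length(v) != 1L || !is.finite(v))
      stop("e_complex, e_ligand, e_receptor must each be a single finite number")
  structure(list(e_complex = e_complex, e_ligand = e_ligand,
                 e_receptor = e_receptor,
                 e_binding = e_complex - e_ligand - e_receptor,
                 e_electrostatic = if (is.null(e_electrostatic)) NA_real_ else e_electrostatic,
                 e_vdw = if (is.null(e_vdw)) NA_real_ else e_vdw),
            class = "energy_ledger")
}

#' Binding energy from a component ledger
#'
#' @param ledger An [energy_ledger()].
#' @return \eqn{E_{complex} - E_{ligand} - E_{receptor}} in kJ/mol.
#' @examples
#' binding_energy(energy_ledger(-1000, -500, -314.8))  # -185.2
#' @export
binding_energy <- function(ledger) {
  stopifnot(inherits(ledger, "energy_ledger"))
  ledger$e_complex - ledger$e_ligand - ledger$e_receptor
}

#' Which interaction component dominates binding
#'
#' The dominant component is the one with the algebraically lower (more
#' stabilising, i.e. more negative) energy.
#'
#' @param e_electrostatic,e_vdw Interaction energies, kJ/mol, finite.
#' @return `"electrostatic"`, `"van der Waals"`, or `"tie"`.
#' @export
interaction_dominance <- function(e_electrostatic, e_vdw) {
  if (!is.finite(e_electrostatic) || !is.finite(e_vdw))
    stop("both energies must be finite")
  if (e_electrostatic < e_vdw) "electrostatic"
  else if (e_vdw < e_electrostatic) "van der Waals"
  else "tie"
}

#' Frontier-orbital energies
#'
#' @param e_homo,e_lumo HOMO and LUMO energies in atomic units (Hartree).
#' @return An object of class `"orbital_energies"` with derived
#'   `gap = e_lumo - e_homo` (the excitation gap \eqn{\Delta E_{L-H}}).
#' @export
orbital_energies <- function(e_homo, e_lumo) {
  if (!is.finite(e_homo) || !is.finite(e_lumo))
    stop("orbital energies must be finite")
  structure(list(e_homo = e_homo, e_lumo = e_lumo, gap = e_lumo - e_homo),
            class = "orbital_energies")
}

#' HOMO-LUMO gap
#'
#' \eqn{\Delta E_{L-H} = E_{LUMO} - E_{HOMO}}: the energy required to promote
#' an electron from the highest occupied to the lowest unoccupied molecular
#' orbital; a small gap marks a more excitable, more reactive molecule.
#'
#' @param orbitals An [orbital_energies()].
#' @return Gap in atomic units.
#' @examples
#' homo_lumo_gap(orbital_energies(-0.234, -0.177))  # 0.057
#' @export
homo_lumo_gap <- function(orbitals) {
  stopifnot(inherits(orbitals, "orbital_energies"))
  orbitals$e_lumo - orbitals$e_homo
}

#' Read / write energy ledgers and orbital energies as JSON
#'
#' The JSON object for an energy ledger uses keys `e_complex`, `e_ligand`,
#' `e_receptor` and optionally `e_electrostatic`, `e_vdw`; orbital energies
#' use `e_homo`, `e_lumo`. One object per file (or a named map of objects,
#' in which case a named list is returned).
#'
#' @param path JSON file path.
#' @return The parsed object(s).
#' @name energy_json
#' @export
read_energy_ledger <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  build <- function(o) {
    if (!is.list(o)) stop("energy ledger JSON missing 'e_complex'")
    for (k in c("e_complex", "e_ligand", "e_receptor"))
      if (is.null(o[[k]])) stop(sprintf("energy ledger JSON missing '%s'", k))
    energy_ledger(o$e_complex, o$e_ligand, o$e_receptor,
                  o$e_electrostatic, o$e_vdw)
  }
  if (!is.null(obj$e_complex)) build(obj) else lapply(obj, build)
}

#' @rdname energy_json
#' @export
read_orbital_energies <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  build <- function(o) {
    if (!is.list(o) || is.null(o$e_homo) || is.null(o$e_lumo))
      stop("orbital JSON needs 'e_homo' and 'e_lumo'")
    orbital_energies(o$e_homo, o$e_lumo)
  }
  if (!is.null(obj$e_homo)) build(obj) else lapply(obj, build)
}

#' @rdname energy_json
#' @param x An [energy_ledger()] or [orbital_energies()] (or named list of
#'   them).
#' @export
write_energy_json <- function(x, path) {
  strip <- function(o) Filter(function(v) !is.na(v), unclass(o))
  out <- if (inherits(x, "energy_ledger") || inherits(x, "orbital_energies"))
    strip(x) else lapply(x, strip)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
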