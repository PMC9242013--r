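# Core domain containers: molecular structures, QM single-point /
# frequency records, and reaction records grouping species per level of
# theory. Plain S3 lists with validating constructors, in the style of
# the lightweight record classes used across the field's R packages.

#' Create a molecular structure
#'
#' A `qc_structure` holds an ordered atom list (element symbols plus
#' Cartesian coordinates in Angstrom), a pipeline role, a net charge and
#' a free-text label. Atom order is significant and preserved by all IO.
#'
#' @param elements character vector of element symbols
#' @param coords numeric matrix, n x 3, Cartesian coordinates (Angstrom)
#' @param role one of `"MA"`, `"nucleophile"`, `"TS"`, `"product"`,
#'   or `"unknown"`
#' @param net_charge integer net molecular charge (elementary charges)
#' @param label free-text identifier (XYZ comment line)
#' @return object of class `qc_structure`
#' @export
qc_structure <- function(elements, coords, role = "unknown",
                         net_charge = 0L, label = "") {
  coords <- as.matrix(coords)
  if (length(elements) < 1L) stop("structure needs at least one atom")
  if (!is.numeric(coords) || ncol(coords) != 3L ||
      nrow(coords) != length(elements)) {
    stop("coords must be a numeric n x 3 matrix matching elements")
  }
  if (!all(is.finite(coords))) stop("coordinates must be finite")
  role <- match.arg(role, c("MA", "nucleophile", "TS", "product", "unknown"))
  # validates symbols against the periodic-table subset we parameterize
  atomic_mass(elements)
  dimnames(coords) <- list(NULL, c("x", "y", "z"))
  structure(list(elements = as.character(elements), coords = coords,
                 role = role, net_charge = as.integer(net_charge),
                 label = as.character(label)[1]),
            class = "qc_structure")
}

#' @export
print.qc_structure <- function(x, ...) {
  cat(sprintf("<qc_structure> %d atoms, role=%s, charge=%+d, label='%s'\n",
              n_atoms(x), x$role, x$net_charge, x$label))
  invisible(x)
}

#' Number of atoms in a structure
#' @param s a `qc_structure`
#' @return integer atom count
#' @export
n_atoms <- function(s) length(s$elements)

#' Create a quantum-chemistry record
#'
#' Bundles a structure with the electronic energy, an optional
#' solvent-corrected single-point energy, harmonic frequencies (negative
#' values encode imaginary modes) and optional Mulliken charges, all at a
#' named level of theory. Units are fixed at ingestion: Hartree, Angstrom,
#' cm^-1, elementary charges.
#'
#' @param structure a `qc_structure`
#' @param level level of theory string (e.g. `"AM1"`, `"PM6"`, `"DFT"`)
#' @param e_elec electronic energy, Hartree
#' @param e_spe optional solvent single-point energy, Hartree
#' @param frequencies harmonic wavenumbers, cm^-1, signed
#' @param mulliken optional per-atom partial charges (e)
#' @param temperature K (metadata; thermochemistry takes its own T)
#' @param standard_state `"1 atm"` or a concentration string
#' @return object of class `qm_record`
#' @export
qm_record <- function(structure, level, e_elec, e_spe = NA_real_,
                      frequencies = numeric(0), mulliken = NULL,
                      temperature = 298.15, standard_state = "1 atm") {
  stopifnot(inherits(structure, "qc_structure"))
  if (!is.finite(e_elec)) stop("e_elec must be a finite Hartree energy")
  if (!is.null(mulliken) && length(mulliken) != n_atoms(structure)) {
    stop("mulliken length must equal atom count")
  }
  structure(list(structure = structure, level = as.character(level)[1],
                 e_elec = e_elec, e_spe = e_spe,
                 frequencies = as.numeric(frequencies),
                 mulliken = mulliken,
                 temperature = temperature,
                 standard_state = standard_state),
            class = "qm_record")
}

#' @export
print.qm_record <- function(x, ...) {
  cat(sprintf(
    "<qm_record> %s/%s: %d atoms, E=%.6f Eh%s, %d modes (%d imaginary)\n",
    x$level, x$structure$role, n_atoms(x$structure), x$e_elec,
    if (is.finite(x$e_spe)) sprintf(", SPE=%.6f Eh", x$e_spe) else "",
    length(x$frequencies), sum(x$frequencies < 0)))
  invisible(x)
}

#' Number of imaginary modes in a record
#' @param rec a `qm_record`
#' @return integer count of negative wavenumbers
#' @export
n_imaginary <- function(rec) sum(rec$frequencies < 0)

#' Check the imaginary-frequency invariant for a record's role
#'
#' A transition-state record must carry exactly one imaginary mode; a
#' minimum (MA, nucleophile, product) must carry none. Violations stop
#' with an informative error so they surface before thermochemistry.
#'
#' @param rec a `qm_record`
#' @param role optional role override (defaults to the structure's role)
#' @return `rec`, invisibly
#' @export
check_role_frequencies <- function(rec, role = rec$structure$role) {
  n_im <- n_imaginary(rec)
  if (role == "TS" && n_im != 1L) {
    stop(sprintf("TS record '%s' has %d imaginary modes (expected exactly 1)",
                 rec$structure$label, n_im), call. = FALSE)
  }
  if (role %in% c("MA", "nucleophile", "product") && n_im != 0L) {
    stop(sprintf("minimum record '%s' (role %s) has %d imaginary modes",
                 rec$structure$label, role, n_im), call. = FALSE)
  }
  invisible(rec)
}

#' Attach a solvent single-point energy to an optimized record
#'
#' Copies the single-point record's electronic energy into `opt$e_spe`;
#' geometry, frequencies and the gas-phase energy are untouched. The two
#' records must describe the same species (same element sequence).
#'
#' @param opt `qm_record` from the geometry optimization / frequency job
#' @param spe `qm_record` from the solvent single-point job
#' @return `opt` with `e_spe` populated
#' @export
merge_spe <- function(opt, spe) {
  stopifnot(inherits(opt, "qm_record"), inherits(spe, "qm_record"))
  if (!identical(opt$structure$elements, spe$structure$elements)) {
    stop("species mismatch: element sequences differ between opt and spe records",
         call. = FALSE)
  }
  opt$e_spe <- spe$e_elec
  opt
}

#' Composite electronic energy of a record (Hartree)
#'
#' The solvent single-point energy when present, else the gas-phase
#' electronic energy. This is the `E` entering quasiharmonic free energies.
#'
#' @param rec a `qm_record`
#' @return energy in Hartree
#' @export
composite_energy <- function(rec) {
  if (is.finite(rec$e_spe)) rec$e_spe else rec$e_elec
}

#' Create a reaction record
#'
#' Groups the Michael acceptor (MA), nucleophile and transition state of
#' one reaction, each possibly at several levels of theory, together with
#' the key-atom map and a train/test/literature split tag.
#'
#' `key_atoms` is a named list of 1-based atom indices into the TS
#' structure: `nu_c` (nucleophile carbon), `beta_c` (the MA beta-carbon
#' attacked in the conjugate addition), `carbonyl_o`, `core` (the enone
#' core atoms) and `attach` (first atom of each R-group substituent).
#' The `(nu_c, beta_c)` pair defines the forming C-C bond. On disk the
#' manifest stores these 0-based; [load_manifest()] converts.
#'
#' @param reaction_id unique string id
#' @param records nested list: `records[[level]][[role]]` is a `qm_record`
#'   with role in `"MA"`, `"nucleophile"`, `"TS"`
#' @param key_atoms named list of indices, see Details
#' @param split_tag one of `"train"`, `"test"`, `"literature"`,
#'   `"unassigned"`
#' @return object of class `reaction_record`
#' @export
reaction_record <- function(reaction_id, records, key_atoms,
                            split_tag = "unassigned") {
  split_tag <- match.arg(split_tag,
                         c("train", "test", "literature", "unassigned"))
  needed <- c("nu_c", "beta_c", "carbonyl_o", "core", "attach")
  if (!all(needed %in% names(key_atoms))) {
    stop("key_atoms must name: ", paste(needed, collapse = ", "))
  }
  for (lev in names(records)) {
    for (role in names(records[[lev]])) {
      rec <- records[[lev]][[role]]
      stopifnot(inherits(rec, "qm_record"))
      n <- n_atoms(rec$structure)
      idx <- unlist(key_atoms[c("nu_c", "beta_c", "carbonyl_o", "core")])
      if (role == "TS" && (any(idx < 1L) || any(idx > n))) {
        stop(sprintf("reaction %s: key-atom index out of range for %s/%s (n=%d)",
                     reaction_id, lev, role, n), call. = FALSE)
      }
    }
  }
  structure(list(reaction_id = as.character(reaction_id),
                 records = records, key_atoms = key_atoms,
                 split_tag = split_tag),
            class = "reaction_record")
}

#' @export
print.reaction_record <- function(x, ...) {
  cat(sprintf("<reaction_record> %s [%s]: levels %s\n", x$reaction_id,
              x$split_tag, paste(names(x$records), collapse = ", ")))
  invisible(x)
}

#' Fetch a species record from a reaction
#' @param reaction a `reaction_record`
#' @param level level-of-theory string
#' @param role `"MA"`, `"nucleophile"` or `"TS"`
#' @return the `qm_record`
#' @export
get_record <- function(reaction, level, role) {
  rec <- reaction$records[[level]][[role]]
  if (is.null(rec)) {
    stop(sprintf("reaction %s: no %s record at level %s",
                 reaction$reaction_id, role, level), call. = FALSE)
  }
  rec
}
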