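#' Atom-table representation of a macromolecular structure
#'
#' A structure is a tibble with one row per atom and the columns listed below.
#' All geometric operations in the package consume and produce this shape, so
#' results chain naturally with dplyr verbs.
#'
#' Columns:
#' \describe{
#'   \item{chain}{author chain identifier (character)}
#'   \item{resid}{author residue number (integer)}
#'   \item{resname}{3-letter residue / ligand code}
#'   \item{atom}{atom label, e.g. `"CA"`, `"C15'"`}
#'   \item{element}{element symbol, e.g. `"C"`}
#'   \item{x, y, z}{coordinates in angstroms}
#'   \item{b}{isotropic B-factor, angstrom^2 (>= 0)}
#'   \item{occ}{occupancy in \[0, 1\]}
#'   \item{alt}{alternate-location tag, `""` when none}
#'   \item{is_polymer}{TRUE for polymer (ATOM) records}
#'   \item{is_water}{TRUE for water residues}
#' }
#'
#' @param df data frame carrying at least `chain`, `resid`, `resname`, `atom`,
#'   `element`, `x`, `y`, `z`; missing `b`, `occ`, `alt`, `is_polymer`,
#'   `is_water` columns are filled with defaults (B = 0, occupancy 1, no
#'   alt-loc, polymer inferred from standard amino-acid codes, water from
#'   HOH/WAT/DOD).
#' @param assembly_id optional label recording which biological unit / dimer
#'   the table represents (kept as an attribute and propagated by
#'   [select_dimer()]).
#'
#' @return A tibble of class `caro_structure`.
#' @examples
#' s <- caro_structure(tibble::tibble(
#'   chain = "A", resid = 1L, resname = "GLY", atom = c("N", "CA", "C"),
#'   element = c("N", "C", "C"), x = c(0, 1.45, 2.4), y = 0, z = 0
#' ))
#' n_atoms(s)
#' @export
caro_structure <- function(df, assembly_id = NA_character_) {
  df <- as_tibble(df)
  req <- c("chain", "resid", "resname", "atom", "element", "x", "y", "z")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0) {
    abort(paste0("structure table missing column(s): ", paste(miss, collapse = ", ")))
  }
  if (nrow(df) == 0) abort("empty model: structure has no atoms")
  if (!"b" %in% names(df)) df$b <- 0
  if (!"occ" %in% names(df)) df$occ <- 1
  if (!"alt" %in% names(df)) df$alt <- ""
  if (!"is_polymer" %in% names(df)) df$is_polymer <- df$resname %in% aa3_codes()
  if (!"is_water" %in% names(df)) df$is_water <- df$resname %in% c("HOH", "WAT", "DOD")
  df$resid <- as.integer(df$resid)
  df$alt[is.na(df$alt)] <- ""
  bad <- !is.finite(df$x) | !is.finite(df$y) | !is.finite(df$z)
  if (any(bad)) abort("non-finite coordinates in structure table")
  if (any(df$b < 0, na.rm = TRUE)) abort("negative B-factor in structure table")
  if (any(df$occ < 0 | df$occ > 1, na.rm = TRUE)) abort("occupancy outside [0, 1]")
  bad_el <- !df$element %in% names(vdw_radii_full())
  if (any(bad_el)) {
    abort(paste0("unrecognised element symbol(s): ",
                 paste(unique(df$element[bad_el]), collapse = ", ")))
  }
  df <- df[, c(req[1:4], "element", "x", "y", "z", "b", "occ", "alt",
               "is_polymer", "is_water")]
  attr(df, "assembly_id") <- assembly_id
  class(df) <- c("caro_structure", class(df))
  df
}

#' @rdname caro_structure
#' @param x object to coerce / query.
#' @export
as_caro_structure <- function(x) {
  if (inherits(x, "caro_structure")) x else caro_structure(x)
}

#' @rdname caro_structure
#' @export
is_caro_structure <- function(x) inherits(x, "caro_structure")

#' @rdname caro_structure
#' @export
n_atoms <- function(x) nrow(x)

#' @export
print.caro_structure <- function(x, ...) {
  ch <- unique(x$chain)
  cat(sprintf("<caro_structure> %d atoms, %d chain(s): %s\n",
              nrow(x), length(ch), paste(ch, collapse = ", ")))
  NextMethod()
}

# 3-column coordinate matrix for a (subset of an) atom table
atom_xyz <- function(df) {
  cbind(x = df$x, y = df$y, z = df$z)
}

# standard 20 amino acids
aa3_codes <- function() {
  c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
    "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL")
}

aa3_to_1 <- function(codes) {
  map <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
           GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
           MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
           TYR = "Y", VAL = "V")
  out <- unname(map[codes])
  out[is.na(out)] <- "X"
  out
}

# Bondi-type van der Waals radii (angstrom); the 4 contact elements are the
# documented set, others included so SASA never silently mis-sizes an atom.
vdw_radii_full <- function() {
  c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20, P = 1.80,
    F = 1.47, CL = 1.75, BR = 1.85, I = 1.98, "NA" = 2.27, MG = 1.73,
    K = 2.75, CA = 2.31, ZN = 1.39, FE = 2.05, SE = 1.90)
}

#' One-letter sequence of a protein chain
#'
#' Reads the polymer residues of one chain off an atom table in residue-number
#' order and returns the one-letter amino-acid string (unknown residues map
#' to `X`).
#'
#' @param structure a [caro_structure] atom table.
#' @param chain chain identifier.
#' @return list with `sequence` (string) and `resid` (integer vector giving
#'   the author residue number of each letter).
#' @export
chain_sequence <- function(structure, chain) {
  structure <- as_caro_structure(structure)
  sub <- structure[structure$chain == chain & structure$is_polymer &
                     structure$atom == "CA", ]
  if (nrow(sub) == 0) abort(paste0("chain ", chain, " has no CA atoms"))
  sub <- sub[order(sub$resid), ]
  sub <- sub[!duplicated(sub$resid), ]
  list(sequence = paste(aa3_to_1(sub$resname), collapse = ""),
       resid = sub$resid)
}

# apply a rigid transform (3x3 rotation R then translation t) to an atom table
transform_structure <- function(structure, R, t = c(0, 0, 0)) {
  xyz <- atom_xyz(structure) %*% t(R)
  structure$x <- xyz[, 1] + t[1]
  structure$y <- xyz[, 2] + t[2]
  structure$z <- xyz[, 3] + t[3]
  structure
}
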