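#' Carotenoid ligand templates
#'
#' A template names the heavy atoms of a carotenoid chemotype, its bond list
#' with formal bond orders, the ordered conjugated polyene path, the end-ring
#' atom sets, and named torsion quadruples (the end-ring torsions used for
#' s-cis/s-trans classification). Formal bond orders drive the single/double
#' classification in [bla()]; crystallographic bond lengths are the
#' measurement, never the classifier.
#'
#' Built-in templates:
#' * `axt_template()` — astaxanthin (C40H52O4): two keto-hydroxy beta-end
#'   rings, nine conjugated chain C=C plus the ring C5=C6 / C5'=C6' doubles.
#' * `mxt_template()` — mytiloxanthin (C40H54O4): one beta- and one
#'   (primed) kappa-end ring, a C7-C8 triple bond (order 3), a C6' keto and a
#'   C8' enolic hydroxy on the chain. Atom numbering follows the standard
#'   carotenoid scheme with primes; the template is a reconstruction from that
#'   scheme, not a copy of any deposition dictionary, so accession-based runs
#'   may supply their own via `carotenoid_template()`.
#'
#' @param code short ligand identifier (matched against `resname`).
#' @param atoms character vector of heavy-atom names.
#' @param bonds data frame with columns `a1`, `a2`, `order` (1, 2 or 3).
#' @param polyene_path ordered atom names of the conjugated chain.
#' @param end_rings named list of atom-name sets (e.g. `beta`, `beta_prime`,
#'   `kappa`); sets must be pairwise disjoint.
#' @param torsions named list of length-4 atom-name vectors.
#'
#' @return object of class `carotenoid_template`.
#' @export
carotenoid_template <- function(code, atoms, bonds, polyene_path,
                                end_rings = list(), torsions = list()) {
  bonds <- as_tibble(bonds)
  stopifnot(all(c("a1", "a2", "order") %in% names(bonds)))
  unknown <- setdiff(c(bonds$a1, bonds$a2, polyene_path, unlist(end_rings),
                       unlist(torsions)), atoms)
  if (length(unknown) > 0) {
    abort(paste0("template ", code, " references undeclared atom(s): ",
                 paste(unique(unknown), collapse = ", ")))
  }
  if (length(end_rings) > 1) {
    for (i in seq_along(end_rings)) for (j in seq_along(end_rings)) {
      if (i < j && length(intersect(end_rings[[i]], end_rings[[j]])) > 0) {
        abort("end-ring atom sets must be disjoint")
      }
    }
  }
  # polyene path bonds must exist and alternate 1/2 (a single order-3 bond,
  # as in mytiloxanthin C7-C8, is allowed in place of a double)
  po <- path_bond_orders(bonds, polyene_path)
  if (anyNA(po)) {
    abort(paste0("template ", code, ": polyene path bond missing from bond list"))
  }
  structure(
    list(code = code, atoms = atoms, bonds = bonds,
         polyene_path = polyene_path, end_rings = end_rings,
         torsions = torsions),
    class = "carotenoid_template"
  )
}

#' @export
print.carotenoid_template <- function(x, ...) {
  cat(sprintf("<carotenoid_template> %s: %d atoms, %d bonds, polyene path %d atoms\n",
              x$code, length(x$atoms), nrow(x$bonds), length(x$polyene_path)))
  invisible(x)
}

# bond orders along consecutive path pairs; NA where no bond declared
path_bond_orders <- function(bonds, path) {
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  tab <- setNames(bonds$order, key(bonds$a1, bonds$a2))
  n <- length(path)
  unname(tab[key(path[-n], path[-1])])
}

prime <- function(x) paste0(x, "'")

# shared chain topology: C6..C15 then primed side mirrored, methyls C19/C20
carotenoid_chain_bonds <- function(first_order = 2L) {
  ch <- tibble(
    a1 = c("C6", "C7", "C8", "C9", "C10", "C11", "C12", "C13", "C14", "C15"),
    a2 = c("C7", "C8", "C9", "C10", "C11", "C12", "C13", "C14", "C15", "C15'"),
    order = c(1L, first_order, 1L, 2L, 1L, 2L, 1L, 2L, 1L, 2L)
  )
  chp <- tibble(
    a1 = c("C15'", "C14'", "C13'", "C12'", "C11'", "C10'", "C9'", "C8'", "C7'"),
    a2 = c("C14'", "C13'", "C12'", "C11'", "C10'", "C9'", "C8'", "C7'", "C6'"),
    order = c(1L, 2L, 1L, 2L, 1L, 2L, 1L, 2L, 1L)
  )
  me <- tibble(a1 = c("C9", "C13", "C9'", "C13'"),
               a2 = c("C19", "C20", "C19'", "C20'"),
               order = 1L)
  bind_rows(ch, chp, me)
}

carotenoid_polyene_path <- function() {
  c("C6", "C7", "C8", "C9", "C10", "C11", "C12", "C13", "C14", "C15",
    "C15'", "C14'", "C13'", "C12'", "C11'", "C10'", "C9'", "C8'", "C7'", "C6'")
}

beta_ring_bonds <- function(p = identity, keto = TRUE) {
  b <- tibble(
    a1 = p(c("C1", "C2", "C3", "C4", "C5", "C6", "C1", "C1", "C5", "C3")),
    a2 = p(c("C2", "C3", "C4", "C5", "C6", "C1", "C16", "C17", "C18", "O3")),
    order = c(1L, 1L, 1L, 1L, 2L, 1L, 1L, 1L, 1L, 1L)
  )
  if (keto) b <- bind_rows(b, tibble(a1 = p("C4"), a2 = p("O4"), order = 2L))
  b
}

beta_ring_atoms <- function(p = identity, keto = TRUE) {
  a <- p(c("C1", "C2", "C3", "C4", "C5", "C16", "C17", "C18", "O3"))
  if (keto) a <- c(a, p("O4"))
  a
}

#' @rdname carotenoid_template
#' @export
axt_template <- function() {
  pr <- prime
  chain_atoms <- c(carotenoid_polyene_path(), "C19", "C20", "C19'", "C20'")
  atoms <- unique(c(beta_ring_atoms(), beta_ring_atoms(pr), chain_atoms))
  bonds <- bind_rows(beta_ring_bonds(),
                     beta_ring_bonds(function(x) pr(x)),
                     carotenoid_chain_bonds(first_order = 2L))
  carotenoid_template(
    code = "AXT", atoms = atoms, bonds = bonds,
    polyene_path = carotenoid_polyene_path(),
    end_rings = list(beta = beta_ring_atoms(),
                     beta_prime = beta_ring_atoms(pr)),
    torsions = list("C5-C6-C7-C8" = c("C5", "C6", "C7", "C8"),
                    "C5'-C6'-C7'-C8'" = c("C5'", "C6'", "C7'", "C8'"))
  )
}

#' @rdname carotenoid_template
#' @export
mxt_template <- function() {
  pr <- prime
  # kappa end (primed): cyclopentane C1'-C5', gem-dimethyl on C1', methyl C18',
  # C3' hydroxyl; chain-side C6' keto oxygen and C8' enolic hydroxyl
  kappa_bonds <- tibble(
    a1 = pr(c("C1", "C2", "C3", "C4", "C5", "C1", "C1", "C5", "C3", "C6", "C8")),
    a2 = c(pr(c("C2", "C3", "C4", "C5", "C1")), pr("C16"), pr("C17"),
           pr("C18"), pr("O3"), pr("O6"), pr("O8")),
    order = c(1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L, 2L, 1L)
  )
  kappa_atoms <- c(pr(c("C1", "C2", "C3", "C4", "C5", "C16", "C17", "C18",
                        "O3", "O6", "O8")))
  chain_atoms <- c(carotenoid_polyene_path(), "C19", "C20", "C19'", "C20'")
  atoms <- unique(c(beta_ring_atoms(keto = FALSE), kappa_atoms, chain_atoms))
  bonds <- bind_rows(beta_ring_bonds(keto = FALSE), kappa_bonds,
                     carotenoid_chain_bonds(first_order = 3L))
  carotenoid_template(
    code = "MXT", atoms = atoms, bonds = bonds,
    polyene_path = carotenoid_polyene_path(),
    end_rings = list(beta = beta_ring_atoms(keto = FALSE),
                     kappa = kappa_atoms),
    torsions = list("C5-C6-C7-C8" = c("C5", "C6", "C7", "C8"),
                    "C5'-C6'-C7'-C8'" = c("C5'", "C6'", "C7'", "C8'"))
  )
}

#' @rdname carotenoid_template
#' @export
builtin_templates <- function() {
  list(AXT = axt_template(), MXT = mxt_template())
}
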