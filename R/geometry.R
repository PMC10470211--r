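#' Extract the conjugated polyene path of a ligand
#'
#' Resolves the template's ordered polyene path on the ligand's coordinates
#' and attaches the formal bond order of each consecutive pair.
#'
#' @param ligand a `caro_ligand` as returned by [match_ligands()] or
#'   [make_polyene()].
#' @return list with `atoms` (atom tibble in path order) and `orders`
#'   (integer vector, one per consecutive bond).
#' @export
extract_polyene <- function(ligand) {
  stopifnot(inherits(ligand, "caro_ligand"))
  path <- ligand$template$polyene_path
  idx <- match(path, ligand$atoms$atom)
  if (anyNA(idx)) {
    abort(paste0("polyene path atom(s) missing from ligand ", ligand$code, ": ",
                 paste(path[is.na(idx)], collapse = ", ")))
  }
  list(atoms = ligand$atoms[idx, ],
       orders = path_bond_orders(ligand$template$bonds, path))
}

#' Bond length alternation of a conjugated path
#'
#' BLA is the mean formal single-bond length minus the mean formal
#' double-bond length along the conjugated path; a lower BLA goes with a more
#' delocalised pi system and a lower excitation energy. Bond class comes from
#' the template's formal orders -- the observed lengths are the measurement,
#' never the classifier -- and triple bonds (order 3) are excluded from both
#' means. Half scopes split the path at its central bond; with an odd number
#' of path bonds the central bond belongs to neither half.
#'
#' @param path list from [extract_polyene()], or an atom tibble (then supply
#'   `orders`).
#' @param orders integer bond orders, length `nrow(atoms) - 1`.
#' @param scope `"full"`, `"beta_side"` (start of the path) or
#'   `"beta_prime_side"` (end of the path).
#' @param ligand_id label stored in the result.
#' @return object of class `bla_result` with `ligand`, `mean_single`,
#'   `mean_double`, `bla` (angstrom), `n_single`, `n_double`.
#' @export
bla <- function(path, orders = NULL,
                scope = c("full", "beta_side", "beta_prime_side"),
                ligand_id = NULL) {
  scope <- match.arg(scope)
  if (is.list(path) && !is.data.frame(path) && !is.null(path$atoms)) {
    orders <- path$orders
    if (is.null(ligand_id)) ligand_id <- unique(path$atoms$resname)[1]
    path <- path$atoms
  }
  xyz <- atom_xyz(path)
  nb <- nrow(xyz) - 1
  if (length(orders) != nb) abort("orders must have one entry per consecutive bond")
  lens <- sqrt(rowSums((xyz[-1, , drop = FALSE] - xyz[-(nb + 1), , drop = FALSE])^2))
  idx <- switch(scope,
    full = seq_len(nb),
    beta_side = seq_len(floor(nb / 2)),
    beta_prime_side = seq(nb - floor(nb / 2) + 1, nb)
  )
  s <- lens[idx][orders[idx] == 1]
  d <- lens[idx][orders[idx] == 2]
  if (length(s) == 0 || length(d) == 0) {
    abort(paste0("scope '", scope, "' lacks single or double bonds"))
  }
  structure(list(ligand = ligand_id %||% "path", scope = scope,
                 mean_single = mean(s), mean_double = mean(d),
                 bla = mean(s) - mean(d),
                 n_single = length(s), n_double = length(d)),
            class = "bla_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.bla_result <- function(x, ...) {
  cat(sprintf("<bla> %s (%s): %.4f A (%d single %.4f / %d double %.4f)\n",
              x$ligand, x$scope, x$bla, x$n_single, x$mean_single,
              x$n_double, x$mean_double))
  invisible(x)
}

#' Signed dihedral angle of four points
#'
#' IUPAC sign convention (positive clockwise looking from atom 2 to atom 3),
#' range (-180, 180]; mirroring the coordinates negates the angle.
#'
#' @param p1,p2,p3,p4 numeric 3-vectors (angstrom).
#' @return signed angle in degrees.
#' @export
dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  if (sqrt(sum(n1^2)) < 1e-10 || sqrt(sum(n2^2)) < 1e-10) {
    abort("undefined torsion: three consecutive points are collinear")
  }
  b2u <- b2 / sqrt(sum(b2^2))
  ang <- atan2(sum(cross3(n1, n2) * b2u), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# dihedral over four rows of an atom tibble
dihedral_atoms <- function(df) {
  xyz <- atom_xyz(df)
  dihedral(xyz[1, ], xyz[2, ], xyz[3, ], xyz[4, ])
}

#' Named torsion of a ligand
#'
#' Evaluates one of the template's named torsion quadruples on the ligand
#' coordinates.
#'
#' @inheritParams extract_polyene
#' @param name torsion name as declared in the template.
#' @return object of class `torsion_result` (`name`, `atoms`, `angle`).
#' @export
ligand_torsion <- function(ligand, name) {
  stopifnot(inherits(ligand, "caro_ligand"))
  quad <- ligand$template$torsions[[name]]
  if (is.null(quad)) abort(paste0("torsion '", name, "' not defined in template"))
  idx <- match(quad, ligand$atoms$atom)
  if (anyNA(idx)) {
    abort(paste0("torsion atom(s) missing: ", paste(quad[is.na(idx)], collapse = ", ")))
  }
  structure(list(name = name, atoms = quad,
                 angle = dihedral_atoms(ligand$atoms[idx, ])),
            class = "torsion_result")
}

#' End-ring conformation about a chain-ring single bond
#'
#' Classifies the named end-ring torsion as s-cis or s-trans: s-trans iff
#' |angle| > 90 degrees (the 90-degree boundary goes to s-cis). Bound
#' astaxanthin's rings near 165-171 degrees classify s-trans; free
#' astaxanthin near -40 degrees classifies s-cis.
#'
#' @inheritParams ligand_torsion
#' @param ring_torsion_name torsion name, e.g. `"C5-C6-C7-C8"`.
#' @return object of class `ring_conformation` (`ring`, `torsion`, `klass`).
#' @export
ring_conformation <- function(ligand, ring_torsion_name) {
  tor <- ligand_torsion(ligand, ring_torsion_name)
  structure(list(ring = ring_torsion_name, torsion = tor,
                 klass = if (abs(tor$angle) > 90) "s-trans" else "s-cis"),
            class = "ring_conformation")
}

#' @export
print.ring_conformation <- function(x, ...) {
  cat(sprintf("<ring_conformation> %s: %.1f deg -> %s\n",
              x$ring, x$torsion$angle, x$klass))
  invisible(x)
}

#' Least-squares plane through a point set
#'
#' Total-least-squares plane minimising the sum of squared point-plane
#' distances (smallest principal direction of the centred scatter). The
#' normal's sign is fixed toward positive z (ties broken toward positive x,
#' then y) so results are reproducible.
#'
#' @param points n x 3 matrix, n >= 3.
#' @return list with `normal` (unit 3-vector), `centroid`,
#'   `rms_out_of_plane` (angstrom).
#' @export
fit_plane <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 3) abort("need at least 3 points to fit a plane")
  ctr <- colMeans(points)
  X <- sweep(points, 2, ctr)
  S <- crossprod(X)
  ev <- eigen(S, symmetric = TRUE)
  if (ev$values[2] < 1e-12 * max(ev$values[1], 1)) {
    abort("degenerate plane fit: points are collinear")
  }
  n <- ev$vectors[, 3]
  if (n[3] < 0 || (n[3] == 0 && (n[1] < 0 || (n[1] == 0 && n[2] < 0)))) n <- -n
  list(normal = n, centroid = ctr,
       rms_out_of_plane = sqrt(mean((X %*% n)^2)))
}

#' Plane-pair geometry of two bound carotenoids
#'
#' Fits a least-squares plane through each polyene path, and reports the
#' acute interplanar angle, the minimum distance over inter-ligand polyene
#' heavy-atom pairs (chain atoms only, end rings excluded), and the signed
#' crossing dihedral over a named quadruple spanning the two ligands (first
#' two atom names resolved in `carA`, last two in `carB`).
#'
#' @param carA,carB `caro_ligand` objects.
#' @param crossing length-4 character vector of atom names, e.g.
#'   `c("C9", "C15", "C15", "C9")`.
#' @return object of class `plane_pair_geometry` with `interplanar_angle`
#'   (degrees, 0-90), `min_distance` (angstrom), `crossing_dihedral`
#'   (signed degrees), and `axis_angle`/`axis_klass` slots filled by
#'   [pseudo_twofold_axes()] (NA here).
#' @export
pair_geometry <- function(carA, carB, crossing = NULL) {
  pa <- extract_polyene(carA); pb <- extract_polyene(carB)
  fa <- fit_plane(atom_xyz(pa$atoms)); fb <- fit_plane(atom_xyz(pb$atoms))
  ca <- abs(sum(fa$normal * fb$normal))
  interplanar <- acos(max(-1, min(1, ca))) * 180 / pi
  xa <- atom_xyz(pa$atoms); xb <- atom_xyz(pb$atoms)
  d2 <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * xa %*% t(xb)
  min_d <- sqrt(max(0, min(d2)))
  cd <- NA_real_
  if (!is.null(crossing)) {
    stopifnot(length(crossing) == 4)
    ia <- match(crossing[1:2], carA$atoms$atom)
    ib <- match(crossing[3:4], carB$atoms$atom)
    if (anyNA(ia) || anyNA(ib)) {
      abort("crossing quadruple atom(s) not found in the two ligands")
    }
    cd <- dihedral_atoms(bind_rows(carA$atoms[ia, ], carB$atoms[ib, ]))
  }
  structure(list(interplanar_angle = interplanar, min_distance = min_d,
                 crossing_dihedral = cd,
                 axis_angle = NA_real_, axis_klass = NA_character_),
            class = "plane_pair_geometry")
}

#' @export
print.plane_pair_geometry <- function(x, ...) {
  cat(sprintf(
    "<plane_pair> interplanar %.1f deg, min distance %.2f A, crossing %s, axes %s\n",
    x$interplanar_angle, x$min_distance,
    if (is.na(x$crossing_dihedral)) "-" else sprintf("%.1f deg", x$crossing_dihedral),
    if (is.na(x$axis_klass)) "-" else
      sprintf("%.1f deg (%s)", x$axis_angle, x$axis_klass)))
  invisible(x)
}

#' Pseudo-twofold axis relation of a carotenoid pair and its dimer
#'
#' The dimer axis is the rotation axis of the alpha-to-beta chain
#' superposition (a near-180-degree rotation for a pseudo-symmetric dimer).
#' The carotenoid-pair axis is the rotation axis of the best proper rigid map
#' of one polyene onto the other, trying both the forward and the reversed
#' atom order and keeping the lower-RMSD mapping. The acute angle between
#' the two axes classifies the relation: coincident (< 30 deg),
#' perpendicular (> 60 deg), otherwise oblique.
#'
#' @param dimer atom table with the two protein chains.
#' @param carA,carB `caro_ligand` objects.
#' @param chains optional length-2 chain ids (default: the two polymer
#'   chains in file order).
#' @return `plane_pair_geometry`-style list with `axis_angle`, `axis_klass`,
#'   plus `dimer_axis`, `pair_axis`, and the two rotation angles.
#' @export
pseudo_twofold_axes <- function(dimer, carA, carB, chains = NULL) {
  dimer <- as_caro_structure(dimer)
  if (is.null(chains)) chains <- unique(dimer$chain[dimer$is_polymer])
  if (length(chains) != 2) abort("dimer must have exactly two protein chains")
  fit <- superpose_chains(dimer, chains[1], chains[2], trim_sigma = NULL)
  if (fit$rotation_angle < 120) {
    warn(sprintf("no meaningful twofold: alpha->beta rotation is %.1f deg",
                 fit$rotation_angle))
  }
  xa <- atom_xyz(extract_polyene(carA)$atoms)
  xb <- atom_xyz(extract_polyene(carB)$atoms)
  fwd <- kabsch(xb, xa)
  rev_ <- kabsch(xb[rev(seq_len(nrow(xb))), ], xa)
  pf <- if (rev_$rmsd < fwd$rmsd) rev_ else fwd
  ang <- acos(max(-1, min(1, abs(sum(fit$rotation_axis * pf$rotation_axis))))) *
    180 / pi
  klass <- if (ang < 30) "coincident" else if (ang > 60) "perpendicular" else "oblique"
  list(axis_angle = ang, axis_klass = klass,
       dimer_axis = fit$rotation_axis, dimer_rotation = fit$rotation_angle,
       pair_axis = pf$rotation_axis, pair_rotation = pf$rotation_angle,
       pair_rmsd = pf$rmsd)
}
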