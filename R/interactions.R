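#' Protein residues in contact with a ligand
#'
#' A residue is in the contact shell when any of its heavy atoms lies within
#' `cutoff` of any ligand heavy atom (minimum-atom-distance criterion over
#' all ligand heavy atoms). Only polymer residues count; waters, glycans and
#' the partner carotenoid are never listed.
#'
#' @param structure atom table containing the ligand.
#' @param ligand `caro_ligand`.
#' @param cutoff distance cutoff in angstrom (default 4.0, the conventional
#'   shell used when describing a binding site).
#' @return tibble of class `contact_shell`, one row per residue
#'   (`chain`, `resid`, `resname`, `min_distance`), sorted by chain then
#'   residue number; cutoff and ligand id kept as attributes.
#' @export
contact_residues <- function(structure, ligand, cutoff = 4.0) {
  structure <- as_caro_structure(structure)
  stopifnot(inherits(ligand, "caro_ligand"), cutoff > 0)
  lig <- ligand_rows(structure, ligand)
  if (nrow(lig) == 0) abort("ligand not found in structure")
  prot <- structure[structure$is_polymer & !structure$is_water, ]
  if (nrow(prot) == 0) {
    out <- tibble(chain = character(), resid = integer(),
                  resname = character(), min_distance = double())
  } else {
    d <- min_dist_to_set(atom_xyz(prot), atom_xyz(lig))
    prot$min_distance <- d
    out <- prot |>
      group_by(.data$chain, .data$resid, .data$resname) |>
      summarise(min_distance = min(.data$min_distance), .groups = "drop") |>
      filter(.data$min_distance <= cutoff) |>
      arrange(.data$chain, .data$resid)
  }
  attr(out, "cutoff") <- cutoff
  attr(out, "ligand") <- ligand$code
  class(out) <- c("contact_shell", class(out))
  out
}

# per-row minimum distance from each point in X to the set Y
min_dist_to_set <- function(X, Y) {
  d2 <- outer(rowSums(X^2), rowSums(Y^2), "+") - 2 * X %*% t(Y)
  sqrt(pmax(0, apply(d2, 1, min)))
}

# rows of the structure belonging to this ligand residue
ligand_rows <- function(structure, ligand) {
  structure[structure$chain == ligand$chain & structure$resid == ligand$resid &
              structure$resname == ligand$resname, ]
}

#' Hydrogen bonds involving a ligand
#'
#' Heavy-atom criterion (the model carries no hydrogens): candidate
#' donors/acceptors are N and O atoms, a bond is any inter-residue N/O-N/O
#' pair at distance <= `d_max`. With `require_geometry`, the
#' antecedent-donor-acceptor angle (antecedent = nearest covalently bound
#' heavy atom) must be >= 90 degrees on at least one side, a proxy that
#' discards head-on clashes without hydrogen positions. Each pair is
#' reported once; hydroxyl-hydroxyl pairs are donor/acceptor-ambiguous and
#' are reported with the ligand atom first.
#'
#' @param structure atom table.
#' @param ligand `caro_ligand`.
#' @param d_max heavy-atom distance cutoff (default 3.5 angstrom).
#' @param require_geometry apply the angular proxy filter.
#' @param include_waters include water oxygens as partners (default FALSE).
#' @return tibble of class `hbond_list`: ligand atom, partner
#'   chain/resid/resname/atom, `distance`, `klass`
#'   (`"protein-ligand"` or `"ligand-internal"`).
#' @export
hydrogen_bonds <- function(structure, ligand, d_max = 3.5,
                           require_geometry = FALSE, include_waters = FALSE) {
  structure <- as_caro_structure(structure)
  lig <- ligand_rows(structure, ligand)
  if (nrow(lig) == 0) abort("ligand not found in structure")
  ligno <- lig[lig$element %in% c("N", "O"), ]
  partners <- structure[structure$element %in% c("N", "O"), ]
  if (!include_waters) partners <- partners[!partners$is_water, ]
  self <- partners$chain == ligand$chain & partners$resid == ligand$resid &
    partners$resname == ligand$resname
  prot <- partners[partners$is_polymer & !self, ]
  res <- list()
  if (nrow(ligno) > 0 && nrow(prot) > 0) {
    res$pl <- hbond_pairs(ligno, prot, d_max, "protein-ligand")
  }
  if (nrow(ligno) > 1) {
    internal <- hbond_pairs(ligno, ligno, d_max, "ligand-internal")
    if (nrow(internal) > 0) {
      # unordered dedup and drop covalent/self pairs
      key <- paste(pmin(internal$atom, internal$partner_atom),
                   pmax(internal$atom, internal$partner_atom))
      internal <- internal[!duplicated(key) & internal$distance > 2.2, ]
    }
    res$li <- internal
  }
  out <- bind_rows(res)
  if (nrow(out) == 0) {
    out <- tibble(atom = character(), lx = double(), ly = double(),
                  lz = double(), partner_chain = character(),
                  partner_resid = integer(), partner_resname = character(),
                  partner_atom = character(), px = double(), py = double(),
                  pz = double(), distance = double(), klass = character())
  }
  if (nrow(out) > 0 && require_geometry) {
    heavy <- structure
    keep <- map_lgl(seq_len(nrow(out)), function(i) {
      a <- out[i, ]
      don <- c(a$lx, a$ly, a$lz); acc <- c(a$px, a$py, a$pz)
      ok_side <- function(center, other, chain, resid) {
        ante <- antecedent_atom(heavy, chain, resid, center)
        is.null(ante) || angle_deg(ante, center, other) >= 90
      }
      ok_side(don, acc, ligand$chain, ligand$resid) ||
        ok_side(acc, don, a$partner_chain, a$partner_resid)
    })
    out <- out[keep, ]
  }
  out <- out[, c("atom", "partner_chain", "partner_resid", "partner_resname",
                 "partner_atom", "distance", "klass")]
  out <- arrange(out, .data$klass, .data$partner_chain, .data$partner_resid,
                 .data$distance)
  attr(out, "d_max") <- d_max
  attr(out, "ligand") <- ligand$code
  class(out) <- c("hbond_list", class(out))
  out
}

hbond_pairs <- function(lig, part, d_max, klass) {
  xa <- atom_xyz(lig); xb <- atom_xyz(part)
  d2 <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * xa %*% t(xb)
  hit <- which(d2 <= d_max^2, arr.ind = TRUE)
  if (length(hit) == 0) return(tibble())
  tibble(
    atom = lig$atom[hit[, 1]],
    lx = lig$x[hit[, 1]], ly = lig$y[hit[, 1]], lz = lig$z[hit[, 1]],
    partner_chain = part$chain[hit[, 2]], partner_resid = part$resid[hit[, 2]],
    partner_resname = part$resname[hit[, 2]], partner_atom = part$atom[hit[, 2]],
    px = part$x[hit[, 2]], py = part$y[hit[, 2]], pz = part$z[hit[, 2]],
    distance = sqrt(pmax(0, d2[hit])), klass = klass
  ) |> filter(.data$distance > 1e-6)
}

# nearest covalently bound heavy atom (< 1.8 A) within the same residue
antecedent_atom <- function(structure, chain, resid, pos) {
  res <- structure[structure$chain == chain & structure$resid == resid, ]
  if (nrow(res) < 2) return(NULL)
  d <- sqrt((res$x - pos[1])^2 + (res$y - pos[2])^2 + (res$z - pos[3])^2)
  cand <- which(d > 1e-6 & d < 1.8)
  if (length(cand) == 0) return(NULL)
  i <- cand[which.min(d[cand])]
  c(res$x[i], res$y[i], res$z[i])
}

angle_deg <- function(a, center, b) {
  u <- a - center; v <- b - center
  acos(max(-1, min(1, sum(u * v) / sqrt(sum(u^2) * sum(v^2))))) * 180 / pi
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Per-atom SASA by deterministic sphere sampling: each atom's solvent
#' sphere (vdW radius + probe) carries a fixed Fibonacci point lattice and
#' the accessible area is the exposed-point fraction times the sphere area.
#' No randomness is involved, so areas are exactly reproducible.
#'
#' @param structure atom table (any subset; waters included if present).
#' @param probe probe radius in angstrom (default 1.4, a water molecule).
#' @param n_points lattice points per atom (default 960).
#' @return the input tibble with an added `sasa` column (angstrom^2).
#' @export
sasa <- function(structure, probe = 1.4, n_points = 960) {
  structure <- as_caro_structure(structure)
  radii <- vdw_radii_full()
  r <- radii[structure$element]
  if (anyNA(r)) {
    abort(paste0("no van der Waals radius for element(s): ",
                 paste(unique(structure$element[is.na(r)]), collapse = ", ")))
  }
  r <- unname(r) + probe
  pts <- fibonacci_sphere(n_points)
  xyz <- atom_xyz(structure)
  n <- nrow(xyz)
  area <- numeric(n)
  # neighbour search via squared distances; spheres of atom i and j can
  # occlude each other only within r_i + r_j
  d2 <- outer(rowSums(xyz^2), rowSums(xyz^2), "+") - 2 * xyz %*% t(xyz)
  for (i in seq_len(n)) {
    nb <- which(d2[i, ] < (r[i] + r)^2 & seq_len(n) != i)
    sp <- sweep(pts * r[i], 2, xyz[i, ], "+")
    exposed <- rep(TRUE, n_points)
    for (j in nb) {
      dj2 <- (sp[, 1] - xyz[j, 1])^2 + (sp[, 2] - xyz[j, 2])^2 +
        (sp[, 3] - xyz[j, 3])^2
      exposed <- exposed & dj2 > r[j]^2
      if (!any(exposed)) break
    }
    area[i] <- mean(exposed) * 4 * pi * r[i]^2
  }
  structure$sasa <- area
  structure
}

# deterministic, RNG-free spherical Fibonacci lattice of unit vectors
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  z <- 1 - 2 * i / n
  rho <- sqrt(pmax(0, 1 - z^2))
  cbind(rho * cos(phi), rho * sin(phi), z)
}

#' Partition of a ligand's accessible surface across binding partners
#'
#' For each partner entity X (protein chains by chain id; every other
#' non-water residue, e.g. the partner carotenoid or a glycan, under its own
#' `resname` key), the buried fraction is
#' (SASA(ligand alone) - SASA(ligand beside X alone)) / SASA(ligand alone),
#' evaluated over ligand atoms only. `fraction_exposed` is the ligand's SASA
#' in the full (water-free) complex over its isolated SASA. Pairwise buried
#' fractions can double-count regions occluded by several partners at once,
#' so they need not sum to 1 - exposed exactly; the discrepancy is reported
#' as `overlap`.
#'
#' @inheritParams sasa
#' @param ligand `caro_ligand`.
#' @return object of class `sasa_partition`: `ligand`, `total_isolated`
#'   (angstrom^2), `fraction_by_chain` (named list), `fraction_exposed`,
#'   `overlap`.
#' @export
sasa_partition <- function(structure, ligand, probe = 1.4, n_points = 960) {
  structure <- as_caro_structure(structure)
  lig <- ligand_rows(structure, ligand)
  if (nrow(lig) == 0) abort("ligand not found in structure")
  lig_key <- paste(structure$chain, structure$resid, structure$resname) %in%
    paste(ligand$chain, ligand$resid, ligand$resname)
  rest <- structure[!lig_key & !structure$is_water, ]
  iso <- sum(sasa(lig, probe, n_points)$sasa)
  if (iso <= 0) abort("ligand has zero isolated SASA")
  entity <- ifelse(rest$is_polymer, rest$chain, rest$resname)
  lig_in <- function(env) {
    comb <- caro_structure(bind_rows(lig, env))
    sum(sasa(comb, probe, n_points)$sasa[seq_len(nrow(lig))])
  }
  fracs <- map(split(rest, entity), function(env) (iso - lig_in(env)) / iso)
  exposed <- lig_in(rest) / iso
  structure(list(ligand = ligand$code, total_isolated = iso,
                 fraction_by_chain = fracs, fraction_exposed = exposed,
                 overlap = sum(unlist(fracs)) + exposed - 1),
            class = "sasa_partition")
}

#' @export
print.sasa_partition <- function(x, ...) {
  cat(sprintf("<sasa_partition> %s: isolated %.1f A^2, exposed %.1f%%\n",
              x$ligand, x$total_isolated, 100 * x$fraction_exposed))
  for (k in names(x$fraction_by_chain)) {
    cat(sprintf("  buried by %-4s %5.1f%%\n", k, 100 * x$fraction_by_chain[[k]]))
  }
  invisible(x)
}

#' Fragment B-factor statistics of a ligand
#'
#' Unweighted mean and standard deviation of the isotropic B-factors over a
#' template-defined fragment (an end-ring atom set). A high end-ring mean B
#' relative to the other flags a loosely held ring.
#'
#' @param ligand `caro_ligand`.
#' @param fragment_name name of an `end_rings` entry in the template.
#' @return object of class `fragment_bstats`: `fragment`, `n_atoms`,
#'   `mean_b`, `sd_b` (angstrom^2).
#' @export
fragment_bfactor <- function(ligand, fragment_name) {
  stopifnot(inherits(ligand, "caro_ligand"))
  frag <- ligand$template$end_rings[[fragment_name]]
  if (is.null(frag)) {
    abort(paste0("fragment '", fragment_name, "' not defined in template ",
                 ligand$code))
  }
  rows <- ligand$atoms[ligand$atoms$atom %in% frag, ]
  if (nrow(rows) == 0) abort("fragment atoms absent from ligand")
  structure(list(fragment = fragment_name, n_atoms = nrow(rows),
                 mean_b = mean(rows$b),
                 sd_b = if (nrow(rows) > 1) sd(rows$b) else 0),
            class = "fragment_bstats")
}
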