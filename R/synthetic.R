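#' Parameters for a synthetic carotenoprotein complex
#'
#' Bundles the generator knobs with the ground-truth descriptor values they
#' imply, so recovery tests can compare pipeline output against construction.
#'
#' @param n_polyene_atoms atoms in the conjugated path (>= 6).
#' @param single_len,double_len formal single/double bond lengths, angstrom.
#' @param end_ring_torsions length-2 vector of end-ring torsions, degrees.
#' @param inter_polyene_offset separation of the two parallel polyene
#'   planes, angstrom (7 mimics the carotenoid pair in a carotenoprotein
#'   dimer interface).
#' @param shell data frame of pseudo-residues to place around the first
#'   polyene: columns `resname` (default SER), `distance` (target
#'   minimum-atom distance, angstrom) and `target_atom` (path atom name;
#'   default spread along the path). Each entry is placed twice, mirrored
#'   through the polyene plane, one copy per chain -- a symmetric two-chain
#'   shell.
#' @param relation `"translate"` (second polyene is a pure translate of the
#'   first; plane distance is exactly the offset) or `"c2_x"` (second
#'   polyene is the 180-degree rotation of the first about the x axis, the
#'   relation found between carotenoid pairs).
#' @param n_filler far-away filler residues per chain (keeps chains
#'   superposable).
#' @param seed integer seed for the optional coordinate jitter.
#' @param jitter_sd gaussian coordinate noise, angstrom (0 = exact).
#' @return list of class `synthetic_complex_spec` with a `truth` element
#'   (implied `bla`, `torsions`, `min_distance`, `interplanar_angle`,
#'   contact-shell and hydrogen-bond expectations).
#' @export
synthetic_complex_spec <- function(n_polyene_atoms = 20,
                                   single_len = 1.45, double_len = 1.35,
                                   end_ring_torsions = c(170, 170),
                                   inter_polyene_offset = 7,
                                   shell = default_shell(),
                                   relation = c("translate", "c2_x"),
                                   n_filler = 4, seed = 1, jitter_sd = 0) {
  relation <- match.arg(relation)
  if (single_len <= 0 || double_len <= 0) abort("bond lengths must be positive")
  if (n_polyene_atoms < 6) abort("need at least 6 polyene atoms")
  if (!is.null(shell) && any(shell$distance < 1)) {
    abort("steric impossibility: shell distance below 1 angstrom")
  }
  spec <- list(
    n_polyene_atoms = n_polyene_atoms, single_len = single_len,
    double_len = double_len, end_ring_torsions = end_ring_torsions,
    inter_polyene_offset = inter_polyene_offset, shell = shell,
    relation = relation, n_filler = n_filler, seed = seed,
    jitter_sd = jitter_sd
  )
  spec$truth <- list(
    bla = single_len - double_len,
    torsions = end_ring_torsions,
    min_distance = if (relation == "translate") inter_polyene_offset else NA,
    interplanar_angle = 0
  )
  class(spec) <- "synthetic_complex_spec"
  spec
}

#' @rdname synthetic_complex_spec
#' @export
default_shell <- function() {
  tibble(resname = c("SER", "SER", "SER", "SER"),
         distance = c(2.8, 3.4, 3.9, 4.5),
         target_atom = NA_character_)
}

with_seed <- function(seed, code) {
  if (!is.null(seed) && !is.na(seed)) {
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

# place atom D given A, B, C, the C-D bond length, the B-C-D angle (deg) and
# the A-B-C-D dihedral (deg); inverse of dihedral() up to numerics
place_atom <- function(A, B, C, length, angle, dihedral) {
  th <- angle * pi / 180; ph <- dihedral * pi / 180
  bc <- C - B; bc <- bc / sqrt(sum(bc^2))
  ab <- B - A
  n <- cross3(ab, bc); n <- n / sqrt(sum(n^2))
  m <- cross3(n, bc)
  C + length * (-cos(th) * bc + sin(th) * (cos(ph) * m + sin(ph) * n))
}

#' Generate a synthetic polyene ligand with known geometry
#'
#' Builds a planar zig-zag conjugated chain with exactly alternating formal
#' single/double bond lengths (120-degree bond angles), two 2-carbon
#' end-ring stubs rotated out of plane to the requested torsions, and a
#' hydroxyl oxygen on each stub (so hydrogen-bond code paths see ligand
#' oxygens). Entirely deterministic unless `jitter_sd > 0`.
#'
#' @param spec a [synthetic_complex_spec] (or nothing, for the defaults).
#' @param chain,resid placement of the ligand residue.
#' @return list with `ligand` (a `caro_ligand` with an on-the-fly template)
#'   and `truth` (`bla`, `torsions`, per-bond lengths and orders).
#' @export
make_polyene <- function(spec = synthetic_complex_spec(), chain = "P",
                         resid = 501L) {
  n <- spec$n_polyene_atoms
  nb <- n - 1
  orders <- rep(c(1L, 2L), length.out = nb)
  lens <- ifelse(orders == 1L, spec$single_len, spec$double_len)
  pos <- matrix(0, n, 3)
  for (i in seq_len(nb)) {
    a <- if (i %% 2 == 1) 30 else -30
    pos[i + 1, ] <- pos[i, ] +
      lens[i] * c(cos(a * pi / 180), sin(a * pi / 180), 0)
  }
  path_names <- paste0("C", seq_len(n))
  # end-ring stubs: R11-R12(-O1) off the first path atom, R21-R22(-O2) off
  # the last; stub 2nd atom set by the requested ring torsion
  t1 <- spec$end_ring_torsions[1]; t2 <- spec$end_ring_torsions[2]
  r11 <- place_atom(pos[3, ], pos[2, ], pos[1, ], 1.50, 120, 180)
  r12 <- place_atom(pos[2, ], pos[1, ], r11, 1.50, 115, t1)
  o1 <- place_atom(pos[1, ], r11, r12, 1.43, 110, 60)
  r21 <- place_atom(pos[n - 2, ], pos[n - 1, ], pos[n, ], 1.50, 120, 180)
  r22 <- place_atom(pos[n - 1, ], pos[n, ], r21, 1.50, 115, t2)
  o2 <- place_atom(pos[n, ], r21, r22, 1.43, 110, 60)
  xyz <- rbind(pos, r11, r12, o1, r21, r22, o2)
  dimnames(xyz) <- NULL
  names_all <- c(path_names, "R11", "R12", "O1", "R21", "R22", "O2")
  elements <- c(rep("C", n), "C", "C", "O", "C", "C", "O")
  if (spec$jitter_sd > 0) {
    xyz <- with_seed(spec$seed,
                     xyz + matrix(stats::rnorm(length(xyz), 0, spec$jitter_sd),
                                  ncol = 3))
  }
  ctr <- colMeans(xyz[seq_len(n), , drop = FALSE])
  xyz <- sweep(xyz, 2, ctr)
  atoms <- tibble(
    chain = chain, resid = as.integer(resid), resname = "SYN",
    atom = names_all, element = elements,
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    b = 30, occ = 1, alt = "", is_polymer = FALSE, is_water = FALSE
  )
  bonds <- bind_rows(
    tibble(a1 = path_names[-n], a2 = path_names[-1], order = orders),
    tibble(a1 = c("C1", "R11", "R12", path_names[n], "R21", "R22"),
           a2 = c("R11", "R12", "O1", "R21", "R22", "O2"),
           order = 1L)
  )
  template <- carotenoid_template(
    code = "SYN", atoms = names_all, bonds = bonds,
    polyene_path = path_names,
    end_rings = list(ring1 = c("R11", "R12", "O1"),
                     ring2 = c("R21", "R22", "O2")),
    torsions = list(
      ring1 = c("R12", "R11", "C1", "C2"),
      ring2 = c("R22", "R21", path_names[n], path_names[n - 1])
    )
  )
  ligand <- new_caro_ligand(atoms, template)
  list(ligand = ligand,
       truth = list(bla = spec$single_len - spec$double_len,
                    torsions = c(ring1 = t1, ring2 = t2),
                    orders = orders, lengths = lens))
}

#' Generate a two-chain synthetic complex around a polyene pair
#'
#' Places two copies of the synthetic polyene in parallel planes separated
#' by `inter_polyene_offset`, surrounds the first with the shell
#' pseudo-residues -- each placed once per chain, mirrored through the
#' polyene plane, so the two chains bury the ligand identically -- and adds
#' far-away filler residues. Ground truth for every downstream descriptor is
#' returned alongside.
#'
#' @inheritParams make_polyene
#' @return list with `structure` (atom table), `ligandA`, `ligandB`
#'   (`caro_ligand`s) and `truth` (adds the expected contact shell,
#'   hydrogen-bond partners and the SASA chain-symmetry statement to the
#'   polyene truth).
#' @export
make_complex <- function(spec = synthetic_complex_spec()) {
  d <- spec$inter_polyene_offset
  polA <- make_polyene(spec, chain = "P", resid = 501L)
  ligA <- polA$ligand
  atomsA <- ligA$atoms
  atomsA$z <- atomsA$z - d / 2
  atomsB <- polA$ligand$atoms
  if (spec$relation == "c2_x") {
    atomsB$y <- -atomsB$y; atomsB$z <- -atomsB$z
  }
  atomsB$z <- atomsB$z + d / 2
  atomsB$resid <- 502L
  shell_rows <- list(); truth_contacts <- list(); truth_hbonds <- list()
  if (!is.null(spec$shell) && nrow(spec$shell) > 0) {
    n_sh <- nrow(spec$shell)
    path_names <- ligA$template$polyene_path
    targets <- spec$shell$target_atom
    if (all(is.na(targets))) {
      targets <- path_names[round(seq(2, length(path_names) - 1,
                                      length.out = n_sh))]
    }
    for (k in seq_len(n_sh)) {
      p <- unlist(atomsA[match(targets[k], atomsA$atom), c("x", "y", "z")])
      dk <- spec$shell$distance[k]
      rn <- spec$shell$resname[k]
      shell_rows[[length(shell_rows) + 1]] <-
        pseudo_residue(rn, k, "A", p, c(0, 0, -1), dk)
      shell_rows[[length(shell_rows) + 1]] <-
        pseudo_residue(rn, k, "B", p, c(0, 0, 1), dk)
      for (ch in c("A", "B")) {
        truth_contacts[[length(truth_contacts) + 1]] <-
          tibble(chain = ch, resid = k, resname = rn, min_distance = dk)
      }
      tgt_el <- atomsA$element[match(targets[k], atomsA$atom)]
      if (tgt_el %in% c("N", "O") && dk <= 3.5) {
        truth_hbonds[[length(truth_hbonds) + 1]] <-
          tibble(atom = targets[k], chain = c("A", "B"), resid = k,
                 distance = dk)
      }
    }
  }
  filler_rows <- list()
  if (spec$n_filler > 0) {
    x0 <- max(atomsA$x) + 10
    for (k in seq_len(spec$n_filler)) {
      base <- c(x0 + 4 * k, 2 * (k %% 3), -d / 2)
      filler_rows[[length(filler_rows) + 1]] <-
        pseudo_residue("ALA", 100 + k, "A", base, c(0, 0, -1), 5)
      filler_rows[[length(filler_rows) + 1]] <-
        pseudo_residue("ALA", 100 + k, "B", base, c(0, 0, 1), 5)
    }
  }
  prot <- bind_rows(c(shell_rows, filler_rows))
  st <- caro_structure(bind_rows(prot, atomsA, atomsB))
  ligA$atoms <- atomsA
  ligB <- ligA; ligB$atoms <- atomsB; ligB$resid <- 502L
  truth <- polA$truth
  truth$min_distance <- if (spec$relation == "translate") d else
    min_dist_to_set(atom_xyz(atomsA[match(ligA$template$polyene_path,
                                          atomsA$atom), ]),
                    atom_xyz(atomsB[match(ligA$template$polyene_path,
                                          atomsB$atom), ])) |> min()
  truth$interplanar_angle <- 0
  truth$contact_shell <- bind_rows(truth_contacts)
  truth$hbonds <- bind_rows(truth_hbonds)
  truth$sasa_chains_equal <- c("A", "B")
  list(structure = st, ligandA = ligA, ligandB = ligB, truth = truth)
}

# pseudo-residue with real amino-acid atom naming; the probe atom (OG for
# SER, CB otherwise) sits exactly at distance `d` from point `p` along `u`,
# the rest of the residue strictly further away
pseudo_residue <- function(resname, resid, chain, p, u, d) {
  u <- u / sqrt(sum(u^2))
  t <- if (abs(u[1]) < 0.9) cross3(u, c(1, 0, 0)) else cross3(u, c(0, 1, 0))
  t <- t / sqrt(sum(t^2))
  probe <- p + d * u
  cb <- probe + 1.43 * u
  ca <- cb + 1.52 * u + 0.3 * t
  nn <- ca + 1.2 * u - 1.0 * t
  cc <- ca + 1.2 * u + 1.0 * t
  oo <- cc + 1.0 * u + 0.6 * t
  if (resname == "SER") {
    nm <- c("N", "CA", "C", "O", "CB", "OG")
    el <- c("N", "C", "C", "O", "C", "O")
    xyz <- rbind(nn, ca, cc, oo, cb, probe)
  } else {
    nm <- c("N", "CA", "C", "O", "CB")
    el <- c("N", "C", "C", "O", "C")
    xyz <- rbind(nn, ca, cc, oo, probe)
  }
  dimnames(xyz) <- NULL
  tibble(chain = chain, resid = as.integer(resid), resname = resname,
         atom = nm, element = el, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
         b = 20, occ = 1, alt = "", is_polymer = TRUE, is_water = FALSE)
}

#' Generate an exactly C2-symmetric synthetic dimer
#'
#' Chain A is a seeded smooth pseudo-protein trace (GLY backbone); chain B
#' is its exact 180-degree rotation about the chosen axis. The two polyenes
#' are related by a 180-degree rotation about the x axis, so the
#' carotenoid-pair pseudo-twofold axis is x: choosing `dimer_axis = "x"`
#' makes the dimer and pair axes coincident, `"z"` makes them
#' perpendicular.
#'
#' @param n_res residues per chain.
#' @param dimer_axis `"x"` or `"z"`.
#' @param spec polyene parameters ([synthetic_complex_spec]).
#' @param seed seed for the backbone trace.
#' @return list with `structure`, `ligandA`, `ligandB`, `truth`
#'   (`dimer_axis`, `pair_axis`, expected `axis_klass`).
#' @export
make_c2_dimer <- function(n_res = 15, dimer_axis = c("x", "z"),
                          spec = synthetic_complex_spec(), seed = 7) {
  dimer_axis <- match.arg(dimer_axis)
  d <- spec$inter_polyene_offset
  pol <- make_polyene(spec, chain = "P", resid = 501L)
  atomsA <- pol$ligand$atoms
  atomsA$z <- atomsA$z - d / 2
  atomsB <- pol$ligand$atoms
  atomsB$y <- -atomsB$y; atomsB$z <- -atomsB$z    # C2 about x
  atomsB$z <- atomsB$z + d / 2
  atomsB$resid <- 502L
  ca <- with_seed(seed, {
    tseq <- seq(0, 3 * pi, length.out = n_res)
    cbind(6 * cos(tseq) + stats::rnorm(n_res, 0, 0.4),
          10 + 3 * sin(tseq) + stats::rnorm(n_res, 0, 0.4),
          2 * tseq + stats::rnorm(n_res, 0, 0.4))
  })
  chainA <- map(seq_len(n_res), function(i) {
    tibble(chain = "A", resid = i, resname = "GLY",
           atom = c("N", "CA", "C", "O"), element = c("N", "C", "C", "O"),
           x = ca[i, 1] + c(-1.2, 0, 1.2, 1.8),
           y = ca[i, 2] + c(0.3, 0, 0.3, 1.2),
           z = ca[i, 3] + c(0, 0, 0, 0.4),
           b = 20, occ = 1, alt = "", is_polymer = TRUE, is_water = FALSE)
  }) |> bind_rows()
  R <- if (dimer_axis == "x") {
    diag(c(1, -1, -1))
  } else {
    diag(c(-1, -1, 1))
  }
  chainB <- chainA
  xyz <- atom_xyz(chainA) %*% t(R)
  chainB$x <- xyz[, 1]; chainB$y <- xyz[, 2]; chainB$z <- xyz[, 3]
  chainB$chain <- "B"
  st <- caro_structure(bind_rows(chainA, chainB, atomsA, atomsB))
  ligA <- pol$ligand; ligA$atoms <- atomsA
  ligB <- pol$ligand; ligB$atoms <- atomsB; ligB$resid <- 502L
  list(structure = st, ligandA = ligA, ligandB = ligB,
       truth = list(dimer_axis = if (dimer_axis == "x") c(1, 0, 0) else c(0, 0, 1),
                    pair_axis = c(1, 0, 0),
                    axis_klass = if (dimer_axis == "x") "coincident" else
                      "perpendicular"))
}

#' Generate a protein sequence with planted motifs
#'
#' Random background over an alphabet free of Asn, Cys and Thr, with
#' N-x-T sequons (x != P) and cysteines planted at the requested positions,
#' so motif scans must recover exactly the plants.
#'
#' @param length sequence length.
#' @param sequon_positions 1-based start positions of planted N-x-T
#'   triplets.
#' @param cys_positions 1-based cysteine positions.
#' @param cleavage signal cleavage position or NA.
#' @param seed RNG seed.
#' @return list with `record` (a [protein_record]) and `truth`.
#' @export
make_sequence <- function(length = 120, sequon_positions = integer(0),
                          cys_positions = integer(0), cleavage = NA,
                          seed = 1) {
  claimed <- c(unlist(map(sequon_positions, function(p) p:(p + 2))),
               cys_positions)
  if (anyDuplicated(claimed) > 0) abort("overlapping planted motifs")
  if (any(claimed > length | claimed < 1)) abort("planted motif outside sequence")
  bg <- strsplit("ADEFGHIKLMQRSVWY", "")[[1]]   # no N, C, T, P
  s <- with_seed(seed, {
    s <- sample(bg, length, replace = TRUE)
    for (p in sequon_positions) {
      s[p] <- "N"; s[p + 1] <- sample(bg, 1); s[p + 2] <- "T"
    }
    s
  })
  s[cys_positions] <- "C"
  rec <- protein_record("synthetic", paste(s, collapse = ""),
                        signal_cleavage = cleavage)
  list(record = rec,
       truth = list(sequon_positions = sort(sequon_positions),
                    cys_positions = sort(cys_positions),
                    mature_length = if (is.na(cleavage)) NA else
                      length - cleavage))
}

#' Generate a synthetic absorption spectrum
#'
#' Sum of Gaussians on a 1 nm grid plus seeded gaussian noise.
#'
#' @param centers peak centres, nm.
#' @param widths gaussian sigmas, nm (recycled).
#' @param amplitudes peak amplitudes (recycled).
#' @param noise_sd gaussian noise SD.
#' @param seed RNG seed.
#' @param grid wavelength grid (default 350-750 nm, 1 nm).
#' @return list with `spectrum` (a [caro_spectrum]) and `truth` (`centers`).
#' @export
make_spectrum <- function(centers, widths = 25, amplitudes = 1,
                          noise_sd = 0, seed = 1, grid = 350:750) {
  if (any(centers < min(grid) | centers > max(grid))) {
    abort("peak centres must lie within the wavelength grid")
  }
  widths <- rep_len(widths, length(centers))
  amplitudes <- rep_len(amplitudes, length(centers))
  ab <- rep(0, length(grid))
  for (k in seq_along(centers)) {
    ab <- ab + amplitudes[k] * exp(-(grid - centers[k])^2 / (2 * widths[k]^2))
  }
  if (noise_sd > 0) {
    ab <- ab + with_seed(seed, stats::rnorm(length(grid), 0, noise_sd))
  }
  list(spectrum = caro_spectrum(grid, pmax(ab, 0), label = "synthetic"),
       truth = list(centers = centers))
}
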