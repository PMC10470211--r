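#' Full structural characterisation of a carotenoprotein heterodimer
#'
#' Runs the whole descriptor pipeline on a deposited structure: read the
#' asymmetric unit, keep the lowest-mean-B heterodimer, match the carotenoid
#' ligands, and compute for each ligand the polyene BLA, end-ring
#' conformations, fragment B-statistics, 4-angstrom contact shell,
#' hydrogen bonds and SASA partition, plus the pair geometry (crossing
#' dihedral, plane separation) and the pseudo-twofold axis relation, and the
#' alpha/beta chain superposition. This is the accession-based analysis: it
#' needs the deposited mmCIF files (see [fetch_structure()]), which are not
#' bundled with the package.
#'
#' @param path mmCIF/PDB file of the complex.
#' @param templates ligand templates to match (default built-in AXT + MXT).
#' @param crossing crossing-dihedral quadruple: two atom names in the first
#'   ligand, two in the second.
#' @param reference_dimer optional second structure (path) to superpose the
#'   dimer onto (e.g. a homolog), reported as `dimer_vs_reference`.
#' @return list of tidy results: `dimer_chains`, `ligands`, per-ligand
#'   descriptor tibbles, `pair`, `axes`, `chain_superposition`, and
#'   optionally `dimer_vs_reference`.
#' @export
bcp_structure_report <- function(path, templates = builtin_templates(),
                                 crossing = c("C9", "C15", "C15", "C9"),
                                 reference_dimer = NULL) {
  st <- read_structure(path)
  dimer <- select_dimer(st, mode = "lowest_mean_b")
  chains <- unique(dimer$chain[dimer$is_polymer])
  ligs <- match_ligands(dimer, templates)
  if (length(ligs) < 1) abort("no template-matched ligand in the selected dimer")
  per_ligand <- map(ligs, function(lg) {
    pe <- extract_polyene(lg)
    rings <- map(names(lg$template$torsions),
                 function(nm) tidy(ring_conformation(lg, nm))) |> bind_rows()
    frags <- map(names(lg$template$end_rings),
                 function(nm) tidy(fragment_bfactor(lg, nm))) |> bind_rows()
    list(code = lg$code,
         bla = tidy(bla(pe, ligand_id = lg$code)),
         rings = rings,
         fragments = frags,
         contacts = contact_residues(dimer, lg, cutoff = 4.0),
         hbonds = hydrogen_bonds(dimer, lg, d_max = 3.5),
         sasa = sasa_partition(dimer, lg))
  })
  out <- list(dimer_chains = chains,
              ligands = map_chr(ligs, "code"),
              per_ligand = setNames(per_ligand, map_chr(ligs, "code")))
  if (length(ligs) >= 2) {
    out$pair <- tidy(pair_geometry(ligs[[1]], ligs[[2]], crossing = crossing))
    out$axes <- pseudo_twofold_axes(dimer, ligs[[1]], ligs[[2]],
                                    chains = chains)
  }
  if (length(chains) == 2) {
    out$chain_superposition <-
      tidy(superpose_chains(dimer, chains[1], chains[2]))
  }
  if (!is.null(reference_dimer)) {
    ref <- read_structure(reference_dimer)
    ref_dimer <- tryCatch(select_dimer(ref, mode = "lowest_mean_b"),
                          error = function(e) ref)
    out$dimer_vs_reference <- tidy(superpose_dimers(dimer, ref_dimer))
  }
  out
}
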