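#' Read a macromolecular structure into an atom table
#'
#' Parses a PDB or PDBx/mmCIF file (via bio3d) into the package's atom-table
#' representation. Alternate locations are resolved by keeping the
#' highest-occupancy conformer of each atom (ties broken by file order), so
#' downstream analyses see a single-conformer model. Waters are retained but
#' flagged (`is_water`) and excluded from contact/H-bond/SASA analyses by
#' default.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"mmcif"` or `"pdb"`.
#' @param resolve_altloc keep only the best conformer per atom (default TRUE).
#' @return a [caro_structure] tibble.
#' @export
read_structure <- function(path, format = c("auto", "mmcif", "pdb"),
                           resolve_altloc = TRUE) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (format == "auto") {
    format <- if (grepl("\\.cif(\\.gz)?$", path, ignore.case = TRUE))
      "mmcif" else "pdb"
  }
  raw <- tryCatch(
    if (format == "mmcif") {
      suppressWarnings(bio3d::read.cif(path, verbose = FALSE, rm.alt = FALSE))
    } else {
      suppressWarnings(bio3d::read.pdb(path, verbose = FALSE, rm.alt = FALSE))
    },
    error = function(e) {
      abort(paste0("cannot parse ", path, " as ", format, ": ",
                   conditionMessage(e)))
    }
  )
  at <- raw$atom
  if (is.null(at) || nrow(at) == 0) abort(paste0("empty model in ", path))
  strip <- function(x) gsub("^[\"']|[\"']$", "", x)
  df <- tibble(
    chain = as.character(at$chain),
    resid = as.integer(at$resno),
    resname = strip(as.character(at$resid)),
    atom = strip(as.character(at$elety)),
    element = toupper(strip(as.character(at$elesy))),
    x = at$x, y = at$y, z = at$z,
    b = ifelse(is.na(at$b), 0, at$b),
    occ = ifelse(is.na(at$o), 1, at$o),
    alt = ifelse(is.na(at$alt), "", as.character(at$alt)),
    is_polymer = at$type == "ATOM"
  )
  df$element[df$element == "" | is.na(df$element)] <-
    guess_element(df$atom[df$element == "" | is.na(df$element)])
  df$is_water <- df$resname %in% c("HOH", "WAT", "DOD")
  # bio3d's cif reader drops alt-loc ids; recover them from the raw file so
  # the highest-occupancy rule can be applied
  if (format == "mmcif" && all(df$alt == "") && any(df$occ < 1)) {
    df$alt <- cif_altloc_column(path, nrow(df))
  }
  if (resolve_altloc) df <- resolve_altlocs(df)
  caro_structure(df)
}

guess_element <- function(atom_names) {
  two <- toupper(substr(atom_names, 1, 2))
  one <- toupper(substr(gsub("^[0-9]", "", atom_names), 1, 1))
  ifelse(two %in% c("CL", "BR", "NA", "MG", "ZN", "FE", "SE"), two, one)
}

cif_altloc_column <- function(path, n_expected) {
  lines <- readLines(path, warn = FALSE)
  rec <- grep("^(ATOM|HETATM)\\s", lines, value = TRUE)
  if (length(rec) != n_expected) return(rep("", n_expected))
  alt <- vapply(strsplit(rec, "\\s+"), function(f) f[5], character(1))
  ifelse(alt %in% c(".", "?"), "", alt)
}

# keep the highest-occupancy conformer per (chain, resid, resname, atom);
# ties resolved by file order
resolve_altlocs <- function(df) {
  df$.ord <- seq_len(nrow(df))
  df <- df |>
    group_by(.data$chain, .data$resid, .data$resname, .data$atom) |>
    arrange(dplyr::desc(.data$occ), .data$.ord, .by_group = TRUE) |>
    slice(1) |>
    ungroup() |>
    arrange(.data$.ord)
  df$.ord <- NULL
  df
}

#' Write an atom table as PDBx/mmCIF
#'
#' Emits a minimal, valid `atom_site` loop (label and author fields filled
#' identically) that round-trips through [read_structure()]. Coordinates are
#' written at 3 decimals, B-factors at 2 -- matching deposited precision.
#'
#' @param structure atom table.
#' @param path output file.
#' @param data_name CIF data block name.
#' @return `path`, invisibly.
#' @export
write_structure <- function(structure, path, data_name = "generated") {
  structure <- as_caro_structure(structure)
  q <- function(x) ifelse(grepl("'", x), paste0('"', x, '"'), x)
  rec <- sprintf(
    "%s %d %s %s %s %s %s 1 %d ? %.3f %.3f %.3f %.2f %.2f %d %s %s %s 1",
    ifelse(structure$is_polymer, "ATOM", "HETATM"),
    seq_len(nrow(structure)), structure$element, q(structure$atom),
    ifelse(structure$alt == "", ".", structure$alt),
    structure$resname, structure$chain, structure$resid,
    structure$x, structure$y, structure$z, structure$occ, structure$b,
    structure$resid, structure$resname, structure$chain, q(structure$atom)
  )
  hdr <- c(
    paste0("data_", data_name), "#", "loop_",
    paste0("_atom_site.", c(
      "group_PDB", "id", "type_symbol", "label_atom_id", "label_alt_id",
      "label_comp_id", "label_asym_id", "label_entity_id", "label_seq_id",
      "pdbx_PDB_ins_code", "Cartn_x", "Cartn_y", "Cartn_z", "occupancy",
      "B_iso_or_equiv", "auth_seq_id", "auth_comp_id", "auth_asym_id",
      "auth_atom_id", "pdbx_PDB_model_num"))
  )
  writeLines(c(hdr, rec, "#"), path)
  invisible(path)
}

#' Restrict a multi-copy crystal structure to one heterodimer
#'
#' Protein chains are grouped into dimers by ligand sharing: each large
#' non-water heteroresidue (>= `min_ligand_atoms` atoms) links the chains it
#' touches within 4.5 angstrom, and connected components of that
#' chain-ligand graph are the candidate dimers. `lowest_mean_b` keeps the
#' dimer whose protein atoms have the smallest mean B-factor (crystal papers
#' describe the best-ordered copy); `by_chain_ids` keeps the named chains.
#' Small heterogroups (glycans, ions) and waters riding on the kept chains
#' are retained.
#'
#' @param structure atom table for the full asymmetric unit.
#' @param mode `"lowest_mean_b"` or `"by_chain_ids"`.
#' @param chains chain ids, for `mode = "by_chain_ids"`.
#' @param min_ligand_atoms heavy-atom threshold for a linking ligand.
#' @return a [caro_structure] restricted to one dimer (assembly id records
#'   the chains kept).
#' @export
select_dimer <- function(structure, mode = c("lowest_mean_b", "by_chain_ids"),
                         chains = NULL, min_ligand_atoms = 20) {
  structure <- as_caro_structure(structure)
  mode <- match.arg(mode)
  prot_chains <- unique(structure$chain[structure$is_polymer])
  if (mode == "by_chain_ids") {
    if (is.null(chains)) abort("chains must be given for mode 'by_chain_ids'")
    keep <- chains
  } else {
    groups <- dimer_groups(structure, prot_chains, min_ligand_atoms)
    if (length(groups) == 0) {
      abort(paste0("no dimer found among chains: ",
                   paste(prot_chains, collapse = ", ")))
    }
    mean_b <- map_dbl(groups, function(ch) {
      mean(structure$b[structure$is_polymer & structure$chain %in% ch])
    })
    keep <- groups[[which.min(mean_b)]]
  }
  keep_poly <- structure$is_polymer & structure$chain %in% keep
  # heterogroups assigned to the kept dimer: any atom within 4.5 A of it
  het <- structure[!structure$is_polymer, ]
  het_keep <- rep(FALSE, nrow(structure))
  if (nrow(het) > 0 && any(keep_poly)) {
    d <- min_dist_to_set(atom_xyz(het), atom_xyz(structure[keep_poly, ]))
    het$near <- d <= 4.5
    near_res <- unique(paste(het$chain, het$resid, het$resname)[het$near])
    het_keep <- !structure$is_polymer &
      paste(structure$chain, structure$resid, structure$resname) %in% near_res
  }
  out <- structure[keep_poly | het_keep, ]
  attr(out, "assembly_id") <- paste(sort(keep), collapse = "")
  out
}

dimer_groups <- function(structure, prot_chains, min_ligand_atoms) {
  het <- structure[!structure$is_polymer & !structure$is_water, ]
  if (nrow(het) == 0) {
    # no linking ligands: fall back to pairing chains by inter-chain contact
    lig_res <- list()
  } else {
    het_res <- split(het, paste(het$chain, het$resid, het$resname))
    lig_res <- keep(het_res, function(r) nrow(r) >= min_ligand_atoms)
  }
  pairs <- list()
  touch <- function(sub) {
    prot <- structure[structure$is_polymer, ]
    d <- min_dist_to_set(atom_xyz(prot), atom_xyz(sub))
    sort(unique(prot$chain[d <= 4.5]))
  }
  if (length(lig_res) > 0) {
    pairs <- map(lig_res, touch)
  } else if (length(prot_chains) == 2) {
    pairs <- list(prot_chains)
  }
  pairs <- keep(pairs, function(p) length(p) >= 2)
  if (length(pairs) == 0 && length(prot_chains) == 2) pairs <- list(prot_chains)
  # union-find over chains sharing a ligand
  parent <- setNames(prot_chains, prot_chains)
  find <- function(x) { while (parent[[x]] != x) x <- parent[[x]]; x }
  for (p in pairs) for (ch in p[-1]) parent[[find(ch)]] <- find(p[1])
  roots <- vapply(prot_chains, find, character(1))
  comps <- split(prot_chains, roots)
  unname(keep(comps, function(ch) length(ch) == 2))
}

#' Serialize an analysis result to JSON or TSV
#'
#' Results with a [generics::tidy()] method are flattened to their tidy
#' tibble; plain lists are written as-is. Field order is deterministic and
#' floating-point values are fixed at 4 decimals, so identical inputs give
#' byte-identical files.
#'
#' @param report any analysis result from this package.
#' @param path output file.
#' @param format `"json"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, format = c("json", "tsv")) {
  format <- match.arg(format)
  round4 <- function(x) {
    if (is.double(x)) round(x, 4)
    else if (is.list(x)) lapply(x, round4)
    else x
  }
  tidied <- tryCatch(generics::tidy(report), error = function(e) NULL)
  ok <- tryCatch({
    if (format == "json") {
      obj <- if (is.data.frame(report) || inherits(report, "tbl_df")) {
        as.list(as_tibble(report))
      } else if (is.list(report)) {
        unclass(report)
      } else if (!is.null(tidied)) as.list(tidied) else report
      jsonlite::write_json(round4(obj), path, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
    } else {
      df <- if (is.data.frame(report)) report else tidied
      if (is.null(df)) abort("result has no tabular form for TSV output")
      df <- as.data.frame(lapply(df, function(x) {
        if (is.double(x)) sprintf("%.4f", x) else x
      }))
      utils::write.table(df, path, sep = "\t", quote = FALSE,
                         row.names = FALSE)
    }
    TRUE
  }, error = function(e) {
    abort(paste0("cannot write report to ", path, ": ", conditionMessage(e)))
  })
  invisible(path)
}

#' Identify carotenoid ligands by template matching
#'
#' A heteroresidue matches a template when at least `min_coverage` of the
#' template's heavy-atom names are present in the residue. Residues matched
#' by two templates raise an ambiguity error; unmatched heteroresidues with
#' at least 6 atoms are recorded in the `unmatched` attribute.
#'
#' @param structure atom table.
#' @param templates list of [carotenoid_template] objects (default the
#'   built-in AXT + MXT pair).
#' @param min_coverage fraction of template atoms that must be present.
#' @return list of `caro_ligand` objects (fields `code`, `chain`, `resid`,
#'   `resname`, `atoms`, `template`).
#' @export
match_ligands <- function(structure, templates = builtin_templates(),
                          min_coverage = 0.9) {
  structure <- as_caro_structure(structure)
  het <- structure[!structure$is_polymer & !structure$is_water, ]
  if (nrow(het) == 0) return(structure(list(), unmatched = character(0)))
  res_list <- split(het, paste(het$chain, het$resid, het$resname))
  out <- list()
  unmatched <- character(0)
  for (key in names(res_list)) {
    r <- res_list[[key]]
    hits <- keep(templates, function(tp) {
      mean(tp$atoms %in% r$atom) >= min_coverage
    })
    if (length(hits) > 1) {
      abort(paste0("residue ", key, " matches several templates: ",
                   paste(map_chr(hits, "code"), collapse = ", ")))
    }
    if (length(hits) == 1) {
      out[[length(out) + 1]] <- new_caro_ligand(r, hits[[1]])
    } else if (nrow(r) >= 6) {
      unmatched <- c(unmatched, key)
    }
  }
  structure(out, unmatched = unmatched)
}

new_caro_ligand <- function(rows, template) {
  path <- template$polyene_path
  present <- path %in% rows$atom
  if (!all(present)) {
    abort(paste0("ligand ", unique(rows$resname), " ", unique(rows$resid),
                 " is missing polyene path atom(s): ",
                 paste(path[!present], collapse = ", ")))
  }
  structure(list(code = template$code, chain = rows$chain[1],
                 resid = rows$resid[1], resname = rows$resname[1],
                 atoms = as_tibble(rows[, !(names(rows) %in% ".ord")]),
                 template = template),
            class = "caro_ligand")
}

#' @export
print.caro_ligand <- function(x, ...) {
  cat(sprintf("<caro_ligand> %s %s/%d: %d atoms (template %s)\n",
              x$resname, x$chain, x$resid, nrow(x$atoms), x$code))
  invisible(x)
}

#' Download a deposited structure (mmCIF) from the PDB
#'
#' Convenience fetcher for accession-based analyses; requires network
#' access. Files land in `dir` and are reused when already present.
#'
#' @param id 4-character PDB id.
#' @param dir download directory.
#' @return path to the mmCIF file.
#' @export
fetch_structure <- function(id, dir = file.path(tempdir(), "pdb_cache")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dest <- file.path(dir, paste0(tolower(id), ".cif"))
  if (file.exists(dest)) return(dest)
  url <- paste0("https://files.rcsb.org/download/", toupper(id), ".cif")
  ok <- tryCatch(
    utils::download.file(url, dest, quiet = TRUE, mode = "wb") == 0,
    error = function(e) FALSE, warning = function(w) FALSE
  )
  if (!ok || !file.exists(dest) || file.size(dest) == 0) {
    unlink(dest)
    abort(paste0("could not download ", id,
                 " (no network access or PDB unreachable)"))
  }
  dest
}
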