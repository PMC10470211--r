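#' Protein sequence record with signal-peptide bookkeeping
#'
#' @param id record identifier.
#' @param sequence amino-acid string (20-letter alphabet; `X` allowed as
#'   wildcard, as in Edman degradation reads).
#' @param signal_cleavage position after which the mature chain starts
#'   (e.g. 16 for cleavage between residues 16 and 17), or `NA`.
#' @return object of class `protein_record`.
#' @export
protein_record <- function(id, sequence, signal_cleavage = NA_integer_) {
  sequence <- toupper(sequence)
  bad <- setdiff(strsplit(sequence, "")[[1]],
                 strsplit("ACDEFGHIKLMNPQRSTVWYX", "")[[1]])
  if (length(bad) > 0) {
    abort(paste0("invalid residue letter(s): ", paste(unique(bad), collapse = ", ")))
  }
  if (!is.na(signal_cleavage) &&
      (signal_cleavage <= 0 || signal_cleavage >= nchar(sequence))) {
    abort("signal_cleavage must lie strictly inside the sequence")
  }
  structure(list(id = id, sequence = sequence,
                 signal_cleavage = as.integer(signal_cleavage)),
            class = "protein_record")
}

#' @export
print.protein_record <- function(x, ...) {
  cat(sprintf("<protein_record> %s: %d aa%s\n", x$id, nchar(x$sequence),
              if (is.na(x$signal_cleavage)) "" else
                sprintf(", signal cleavage after %d", x$signal_cleavage)))
  invisible(x)
}

#' Read protein records from a FASTA file
#'
#' @param path FASTA file.
#' @return list of [protein_record] objects.
#' @export
read_fasta_records <- function(path) {
  ss <- Biostrings::readAAStringSet(path)
  map(seq_along(ss), function(i) {
    protein_record(names(ss)[i], as.character(ss[[i]]))
  })
}

#' Scan for N-glycosylation sequons
#'
#' Finds all Asn-x-Thr (or Asn-x-Ser/Thr) motifs with x != Pro. Positions
#' are 1-based on the supplied sequence; when the record carries a signal
#' cleavage position, the mature-numbering position is reported too
#' (NA for sequons inside the signal peptide).
#'
#' @param record a [protein_record] or plain sequence string.
#' @param pattern `"NxT"` (default, the stricter motif) or `"NxST"`.
#' @return tibble with `position`, `triplet`, `position_mature`.
#' @export
scan_sequons <- function(record, pattern = c("NxT", "NxST")) {
  pattern <- match.arg(pattern)
  if (is.character(record)) record <- protein_record("seq", record)
  s <- record$sequence
  rx <- if (pattern == "NxT") "N[^P](?=T)" else "N[^P](?=[ST])"
  m <- gregexpr(rx, s, perl = TRUE)[[1]]
  pos <- if (m[1] == -1) integer(0) else as.integer(m)
  out <- tibble(
    position = pos,
    triplet = if (length(pos) == 0) character(0) else
      substring(s, pos, pos + 2)
  )
  cl <- record$signal_cleavage
  out$position_mature <- if (is.na(cl)) NA_integer_ else {
    pm <- out$position - cl
    pm[pm <= 0] <- NA_integer_
    as.integer(pm)
  }
  out
}

#' Mature chain after signal-peptide cleavage
#'
#' @param record a [protein_record] with `signal_cleavage` set.
#' @return the mature amino-acid string.
#' @export
mature_sequence <- function(record) {
  stopifnot(inherits(record, "protein_record"))
  if (is.na(record$signal_cleavage)) {
    abort("signal_cleavage is not set for this record")
  }
  substring(record$sequence, record$signal_cleavage + 1)
}

#' Check an Edman N-terminal read against a mature chain
#'
#' Edman degradation reads carry `X` at positions the chemistry could not
#' call; the read matches when every non-X position equals the mature
#' chain's prefix.
#'
#' @param mature mature-chain amino-acid string.
#' @param nterm N-terminal read, `X` as wildcard.
#' @return TRUE/FALSE.
#' @export
edman_prefix_match <- function(mature, nterm) {
  if (nchar(nterm) > nchar(mature)) return(FALSE)
  a <- strsplit(toupper(nterm), "")[[1]]
  b <- strsplit(toupper(substr(mature, 1, nchar(nterm))), "")[[1]]
  all(a == "X" | a == b)
}

#' Cysteine positions and profile classification
#'
#' Reports the cysteine positions of the mature sequence and, when a pattern
#' table is given, an advisory profile label. The shipped default table is a
#' reconstruction of the published ependymin-family profiles (classified by
#' the number of conserved cysteines): it assigns `profile-1` to 4-cysteine,
#' `profile-2` to 6-cysteine and `profile-3` to 5-cysteine mature chains,
#' and `"unclassified"` otherwise. Labels are advisory; counts and
#' positions are always exact.
#'
#' @param record a [protein_record] (mature numbering is used when
#'   `signal_cleavage` is set) or plain mature-sequence string.
#' @param pattern_table data frame with columns `profile` and `n_cys`;
#'   row order never affects the result.
#' @return object of class `cysteine_profile`: `positions`, `count`,
#'   `profile_label`.
#' @export
cysteine_profile <- function(record, pattern_table = default_cysteine_profiles()) {
  if (is.character(record)) record <- protein_record("seq", record)
  s <- if (!is.na(record$signal_cleavage)) mature_sequence(record) else
    record$sequence
  pos <- which(strsplit(s, "")[[1]] == "C")
  label <- "unclassified"
  if (!is.null(pattern_table)) {
    pt <- as_tibble(pattern_table)[order(as_tibble(pattern_table)$profile), ]
    hit <- pt$profile[pt$n_cys == length(pos)]
    if (length(hit) == 1) label <- hit
  }
  structure(list(positions = pos, count = length(pos), profile_label = label),
            class = "cysteine_profile")
}

#' @rdname cysteine_profile
#' @export
default_cysteine_profiles <- function() {
  tibble(profile = c("profile-1", "profile-2", "profile-3"),
         n_cys = c(4L, 6L, 5L))
}

# monoisotopic masses (IUPAC/CODATA), pinned; electron mass for adduct charge
monoisotopic_masses <- function() {
  c(C = 12.0, H = 1.0078250319, N = 14.0030740052, O = 15.9949146221,
    S = 31.97207069, P = 30.97376151, Na = 22.98976928, K = 38.9637064864,
    Cl = 34.968852682)
}

#' Monoisotopic exact mass of a molecular formula
#'
#' Sums pinned monoisotopic atomic masses; charged adducts are
#' electron-corrected (`[M+H]+` adds one hydrogen atom and removes one
#' electron; `[M+Na]+` likewise with sodium). For C40H52O4 (astaxanthin)
#' this gives the [M+H]+ ion at m/z 597.394, matching high-resolution LC-MS
#' assignment of the pigment.
#'
#' @param formula molecular formula string, e.g. `"C40H52O4"`.
#' @param adduct `"M"` (neutral), `"[M+H]+"` or `"[M+Na]+"`.
#' @return object of class `mass_result`: `formula` (named count vector),
#'   `adduct`, `mz` (Da).
#' @export
exact_mass <- function(formula, adduct = c("M", "[M+H]+", "[M+Na]+")) {
  adduct <- match.arg(adduct)
  counts <- parse_formula(formula)
  masses <- monoisotopic_masses()
  unknown <- setdiff(names(counts), names(masses))
  if (length(unknown) > 0) {
    abort(paste0("unknown element(s) in formula: ", paste(unknown, collapse = ", ")))
  }
  m <- sum(masses[names(counts)] * counts)
  e <- 0.00054858
  mz <- switch(adduct,
    "M" = m,
    "[M+H]+" = m + masses[["H"]] - e,
    "[M+Na]+" = m + masses[["Na"]] - e
  )
  structure(list(formula = counts, adduct = adduct, mz = mz),
            class = "mass_result")
}

parse_formula <- function(formula) {
  if (!grepl("^([A-Z][a-z]?[0-9]*)+$", formula)) {
    abort(paste0("cannot parse formula: ", formula))
  }
  m <- gregexpr("[A-Z][a-z]?[0-9]*", formula)[[1]]
  toks <- regmatches(formula, list(m))[[1]]
  el <- gsub("[0-9]", "", toks)
  ct <- as.integer(ifelse(gsub("[A-Za-z]", "", toks) == "", "1",
                          gsub("[A-Za-z]", "", toks)))
  tapply(ct, el, sum)[unique(el)]
}

#' @export
print.mass_result <- function(x, ...) {
  cat(sprintf("<mass> %s %s: m/z %.4f\n",
              paste0(names(x$formula), x$formula, collapse = ""),
              x$adduct, x$mz))
  invisible(x)
}
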