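#' Global pairwise sequence alignment with identity
#'
#' Needleman-Wunsch global alignment with affine gaps (BLOSUM62, gap open 10,
#' extend 0.5 by default, via Biostrings). Identity is the fraction of
#' identical columns over aligned columns, excluding terminal gap columns --
#' the conventional way percent identity between two homologs is reported.
#'
#' @param seqA,seqB amino-acid strings.
#' @param substitution_table substitution matrix name or matrix (default
#'   `"BLOSUM62"`).
#' @param gap_open,gap_extend affine gap penalties.
#' @return list with `alignedA`, `alignedB` (gapped strings), `identity`
#'   (fraction), `n_identical`, `n_columns` (identity denominator).
#' @export
align_sequences <- function(seqA, seqB, substitution_table = "BLOSUM62",
                            gap_open = 10, gap_extend = 0.5) {
  for (s in c(seqA, seqB)) {
    if (!nzchar(s)) abort("empty sequence")
    bad <- setdiff(strsplit(s, "")[[1]], strsplit("ACDEFGHIKLMNPQRSTVWYX", "")[[1]])
    if (length(bad) > 0) {
      abort(paste0("invalid residue letter(s): ", paste(unique(bad), collapse = ", ")))
    }
  }
  if (is.character(substitution_table)) {
    e <- new.env()
    utils::data(list = substitution_table, package = "Biostrings", envir = e)
    substitution_table <- get(substitution_table, envir = e)
  }
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(seqA), Biostrings::AAString(seqB),
    substitutionMatrix = substitution_table,
    gapOpening = gap_open, gapExtension = gap_extend, type = "global"
  )
  a <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  b <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  ng <- which(a != "-" & b != "-")
  if (length(ng) == 0) abort("alignment has no aligned columns")
  core <- seq(min(ng), max(ng))  # drop terminal gap columns
  ident <- sum(a[core] == b[core] & a[core] != "-" & b[core] != "-")
  list(alignedA = paste(a, collapse = ""), alignedB = paste(b, collapse = ""),
       identity = ident / length(core), n_identical = ident,
       n_columns = length(core))
}

#' Least-squares rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimising the RMSD between two
#' matched coordinate sets; a reflection is never returned (the smallest
#' singular direction is negated when the raw SVD solution is improper).
#'
#' @param coordsA,coordsB n x 3 matrices of matched coordinates; B is
#'   superposed onto A (the returned transform maps B coordinates onto A).
#' @return object of class `superposition_result`: `n_matched`, `rmsd`,
#'   `rotation` (3 x 3, det +1), `translation`, `rotation_angle` (degrees),
#'   `rotation_axis` (unit 3-vector), `trimmed` (empty here; filled by
#'   [superpose_chains()]).
#' @export
kabsch <- function(coordsA, coordsB) {
  coordsA <- as.matrix(coordsA); coordsB <- as.matrix(coordsB)
  if (nrow(coordsA) != nrow(coordsB)) abort("coordinate sets differ in length")
  n <- nrow(coordsA)
  if (n < 3) abort("need at least 3 matched points")
  ca <- colMeans(coordsA); cb <- colMeans(coordsB)
  A <- sweep(coordsA, 2, ca); B <- sweep(coordsB, 2, cb)
  if (qr(A)$rank < 2 || qr(B)$rank < 2) abort("degenerate (collinear) point set")
  H <- t(B) %*% A
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  moved <- B %*% t(R)
  rmsd <- sqrt(mean(rowSums((moved - A)^2)))
  tr <- ca - as.numeric(R %*% cb)
  new_superposition(n, rmsd, R, tr, trimmed = integer(0))
}

new_superposition <- function(n, rmsd, R, tr, trimmed) {
  aa <- rotation_angle_axis(R)
  structure(list(n_matched = n, rmsd = rmsd, rotation = R, translation = tr,
                 rotation_angle = aa$angle, rotation_axis = aa$axis,
                 trimmed = trimmed),
            class = "superposition_result")
}

#' @export
print.superposition_result <- function(x, ...) {
  cat(sprintf("<superposition> rmsd %.3f A over %d pairs (rotation %.1f deg, %d trimmed)\n",
              x$rmsd, x$n_matched, x$rotation_angle, length(x$trimmed)))
  invisible(x)
}

# angle (deg) and unit axis of a proper rotation matrix; robust near 0/180 deg
rotation_angle_axis <- function(R) {
  ct <- (sum(diag(R)) - 1) / 2
  ct <- max(-1, min(1, ct))
  angle <- acos(ct) * 180 / pi
  ev <- eigen(R)
  i <- which.min(abs(ev$values - 1))
  axis <- Re(ev$vectors[, i])
  axis <- axis / sqrt(sum(axis^2))
  # orient by the skew-symmetric part when it is informative
  sk <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
  if (sqrt(sum(sk^2)) > 1e-8 && sum(sk * axis) < 0) axis <- -axis
  list(angle = angle, axis = axis)
}

# rotation matrix about unit axis by angle (degrees)
rotation_about <- function(axis, angle_deg) {
  u <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Sequence-guided superposition of two protein chains
#'
#' Aligns the chain sequences ([align_sequences()]), takes the C-alpha pairs
#' of aligned columns, fits a Kabsch superposition, then iteratively trims
#' pairs deviating more than `trim_sigma` times the current RMSD and refits
#' until stable (or `max_iter`).
#'
#' @param structureA atom table holding `chainA`; data-frame-first so the
#'   call pipes.
#' @param chainA,chainB chain identifiers.
#' @param structureB atom table holding `chainB` (defaults to `structureA`).
#' @param trim_sigma deviation multiplier for outlier trimming; `NULL` or
#'   `Inf` disables trimming.
#' @param max_iter maximum refit iterations.
#' @inherit kabsch return
#' @export
superpose_chains <- function(structureA, chainA, chainB,
                             structureB = structureA,
                             trim_sigma = 2, max_iter = 10) {
  structureA <- as_caro_structure(structureA)
  structureB <- as_caro_structure(structureB)
  pa <- matched_ca_pairs(structureA, chainA, structureB, chainB)
  superpose_matched(pa$A, pa$B, trim_sigma, max_iter)
}

# CA coordinate pairs for aligned, non-gap columns of two chains
matched_ca_pairs <- function(structureA, chainA, structureB, chainB) {
  sa <- chain_sequence(structureA, chainA)
  sb <- chain_sequence(structureB, chainB)
  al <- align_sequences(sa$sequence, sb$sequence)
  a <- strsplit(al$alignedA, "")[[1]]
  b <- strsplit(al$alignedB, "")[[1]]
  ia <- cumsum(a != "-"); ib <- cumsum(b != "-")
  both <- which(a != "-" & b != "-")
  ra <- sa$resid[ia[both]]; rb <- sb$resid[ib[both]]
  caA <- structureA[structureA$chain == chainA & structureA$atom == "CA" &
                      structureA$is_polymer, ]
  caA <- caA[order(caA$resid), ]; caA <- caA[!duplicated(caA$resid), ]
  caB <- structureB[structureB$chain == chainB & structureB$atom == "CA" &
                      structureB$is_polymer, ]
  caB <- caB[order(caB$resid), ]; caB <- caB[!duplicated(caB$resid), ]
  list(A = atom_xyz(caA[match(ra, caA$resid), ]),
       B = atom_xyz(caB[match(rb, caB$resid), ]))
}

superpose_matched <- function(A, B, trim_sigma, max_iter) {
  keep <- seq_len(nrow(A))
  fit <- kabsch(A, B)
  if (is.null(trim_sigma) || !is.finite(trim_sigma)) return(fit)
  for (it in seq_len(max_iter)) {
    if (fit$rmsd < 1e-8) break      # already exact: nothing left to trim
    moved <- sweep(B[keep, , drop = FALSE] %*% t(fit$rotation), 2,
                   fit$translation, "+")
    dev <- sqrt(rowSums((moved - A[keep, , drop = FALSE])^2))
    bad <- dev > trim_sigma * fit$rmsd
    if (!any(bad) || sum(!bad) < 3) break
    keep <- keep[!bad]
    fit <- kabsch(A[keep, , drop = FALSE], B[keep, , drop = FALSE])
  }
  fit$trimmed <- setdiff(seq_len(nrow(A)), keep)
  fit
}

#' Superpose two dimers as single rigid bodies
#'
#' Chains are paired across the two dimers by the pairing (of the two
#' possible ones) that minimises the final RMSD; per-chain sequence
#' alignments supply the C-alpha matches and one rigid transform is fitted
#' over all matched pairs jointly.
#'
#' @param dimerA,dimerB atom tables with exactly two protein chains each.
#' @inheritParams superpose_chains
#' @inherit kabsch return
#' @export
superpose_dimers <- function(dimerA, dimerB, trim_sigma = 2, max_iter = 10) {
  dimerA <- as_caro_structure(dimerA); dimerB <- as_caro_structure(dimerB)
  cha <- unique(dimerA$chain[dimerA$is_polymer])
  chb <- unique(dimerB$chain[dimerB$is_polymer])
  if (length(cha) != 2 || length(chb) != 2) {
    abort("each dimer must contain exactly two protein chains")
  }
  pairings <- list(cbind(cha, chb), cbind(cha, rev(chb)))
  fits <- map(pairings, function(p) {
    m1 <- matched_ca_pairs(dimerA, p[1, 1], dimerB, p[1, 2])
    m2 <- matched_ca_pairs(dimerA, p[2, 1], dimerB, p[2, 2])
    superpose_matched(rbind(m1$A, m2$A), rbind(m1$B, m2$B),
                      trim_sigma, max_iter)
  })
  fits[[which.min(map_dbl(fits, "rmsd"))]]
}
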