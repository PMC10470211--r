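# Independent oracles and fixture builders used across the suite.
# Every oracle here is a second, separate route to the quantity it checks:
# none of them call the package functions they validate.

# dihedral via the projection (praxeolitic) formula: both flanking bonds are
# projected onto the plane perpendicular to the central bond and the signed
# in-plane angle taken with atan2 -- no normal-vector cross products shared
# with the implementation route
oracle_dihedral <- function(p1, p2, p3, p4) {
  cr <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                         a[3] * b[1] - a[1] * b[3],
                         a[1] * b[2] - a[2] * b[1])
  b0 <- p1 - p2
  b1 <- p3 - p2; b1 <- b1 / sqrt(sum(b1^2))
  b2 <- p4 - p3
  v <- b0 - sum(b0 * b1) * b1
  w <- b2 - sum(b2 * b1) * b1
  atan2(sum(cr(b1, v) * w), sum(v * w)) * 180 / pi
}

# quaternion (Horn) absolute-orientation method: eigenvector of the 4x4 key
# matrix; entirely independent of the SVD route
oracle_quaternion_fit <- function(A, B) {
  ca <- colMeans(A); cb <- colMeans(B)
  X <- sweep(B, 2, cb); Y <- sweep(A, 2, ca)
  S <- t(X) %*% Y
  K <- matrix(0, 4, 4)
  K[1, 1] <- S[1, 1] + S[2, 2] + S[3, 3]
  K[1, 2] <- K[2, 1] <- S[2, 3] - S[3, 2]
  K[1, 3] <- K[3, 1] <- S[3, 1] - S[1, 3]
  K[1, 4] <- K[4, 1] <- S[1, 2] - S[2, 1]
  K[2, 2] <- S[1, 1] - S[2, 2] - S[3, 3]
  K[2, 3] <- K[3, 2] <- S[1, 2] + S[2, 1]
  K[2, 4] <- K[4, 2] <- S[1, 3] + S[3, 1]
  K[3, 3] <- -S[1, 1] + S[2, 2] - S[3, 3]
  K[3, 4] <- K[4, 3] <- S[2, 3] + S[3, 2]
  K[4, 4] <- -S[1, 1] - S[2, 2] + S[3, 3]
  q <- eigen(K, symmetric = TRUE)$vectors[, 1]
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
  moved <- X %*% t(R)
  sqrt(mean(rowSums((moved - Y)^2)))
}

# plane fit by direct eigen-decomposition of the centred scatter matrix
oracle_plane <- function(P) {
  ctr <- colMeans(P)
  X <- sweep(P, 2, ctr)
  ev <- eigen(crossprod(X), symmetric = TRUE)
  n <- ev$vectors[, 3]
  list(normal = n, rms = sqrt(mean((X %*% n)^2)))
}

random_rotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

rigid_move_structure <- function(st, R, t) {
  xyz <- cbind(st$x, st$y, st$z) %*% t(R)
  st$x <- xyz[, 1] + t[1]; st$y <- xyz[, 2] + t[2]; st$z <- xyz[, 3] + t[3]
  st
}

rigid_move_ligand <- function(lig, R, t) {
  lig$atoms <- rigid_move_structure(lig$atoms, R, t)
  lig
}

# four-heterodimer assembly with controlled per-dimer mean B, in the shape
# of a crystal asymmetric unit: copies of the synthetic complex shifted
# apart, chains relabelled, carotenoid pair shared at each dimer interface
make_assembly <- function(mean_b_offsets = c(30, 20, 40, 50)) {
  base <- make_complex()
  chains <- list(c("A", "B"), c("C", "D"), c("E", "F"), c("G", "H"))
  lig_chains <- c("P", "Q", "R", "S")
  parts <- lapply(seq_along(mean_b_offsets), function(i) {
    st <- base$structure
    st$x <- st$x + 60 * (i - 1)
    st$b <- mean_b_offsets[i] + (st$b - mean(st$b[st$is_polymer]))
    st$chain[st$chain == "A"] <- chains[[i]][1]
    st$chain[st$chain == "B"] <- chains[[i]][2]
    st$chain[st$chain == "P"] <- lig_chains[i]
    st
  })
  st <- caro_structure(dplyr::bind_rows(parts))
  list(structure = st, chains = chains, lig_chains = lig_chains,
       base = base)
}

# AXT-shaped heteroresidue: every template atom name present, coordinates
# from the synthetic polyene stretched over the template's path, ring atoms
# clustered at the path ends; B-factors settable per end ring
fake_axt_residue <- function(chain = "X", resid = 601L,
                             b_beta = 31, b_beta_prime = 56, b_chain = 40) {
  tp <- axt_template()
  pol <- make_polyene(synthetic_complex_spec(n_polyene_atoms =
                                               length(tp$polyene_path)))
  path_xyz <- pol$ligand$atoms[match(pol$ligand$template$polyene_path,
                                     pol$ligand$atoms$atom), c("x", "y", "z")]
  atoms <- tp$atoms
  xyz <- matrix(NA_real_, length(atoms), 3)
  rownames(xyz) <- atoms
  xyz[tp$polyene_path, ] <- as.matrix(path_xyz)
  ends <- list(beta = as.matrix(path_xyz)[1, ],
               beta_prime = as.matrix(path_xyz)[nrow(path_xyz), ])
  set.seed(42)
  for (ring in names(tp$end_rings)) {
    for (a in tp$end_rings[[ring]]) {
      xyz[a, ] <- ends[[ring]] + rnorm(3, 0, 1.2)
    }
  }
  rest <- atoms[is.na(xyz[, 1])]
  for (a in rest) xyz[a, ] <- rnorm(3, 0, 4)
  b <- rep(b_chain, length(atoms))
  b[atoms %in% tp$end_rings$beta] <- b_beta
  b[atoms %in% tp$end_rings$beta_prime] <- b_beta_prime
  df <- tibble::tibble(
    chain = chain, resid = as.integer(resid), resname = "AXT",
    atom = atoms, element = substr(atoms, 1, 1),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    b = b, occ = 1, alt = "", is_polymer = FALSE, is_water = FALSE
  )
  df
}
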