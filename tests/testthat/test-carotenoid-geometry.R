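test_that("extract_polyene returns path atoms in order with bond orders", {
  pol <- make_polyene(synthetic_complex_spec(n_polyene_atoms = 22))
  pe <- extract_polyene(pol$ligand)
  expect_equal(nrow(pe$atoms), 22)
  expect_length(pe$orders, 21)
  expect_equal(pe$atoms$atom, paste0("C", 1:22))
  # deleting a path atom is an error naming it
  broken <- pol$ligand
  broken$atoms <- broken$atoms[broken$atoms$atom != "C5", ]
  expect_error(extract_polyene(broken), "C5")
})

test_that("bla reproduces constructed alternation and a brute-force oracle", {
  # equal lengths -> zero
  eq <- make_polyene(synthetic_complex_spec(single_len = 1.40,
                                            double_len = 1.40))
  expect_equal(bla(extract_polyene(eq$ligand))$bla, 0, tolerance = 1e-9)
  # alternating 1.45/1.35 -> 0.10
  pol <- make_polyene()
  b <- bla(extract_polyene(pol$ligand))
  expect_equal(b$bla, 0.10, tolerance = 1e-9)
  expect_equal(b$bla, b$mean_single - b$mean_double, tolerance = 1e-12)
  # randomized lengths: compare with an independently coded mean difference
  set.seed(17)
  n <- 14
  xyz <- matrix(0, n, 3)
  lens <- runif(n - 1, 1.30, 1.50)
  for (i in seq_len(n - 1)) {
    a <- if (i %% 2 == 1) 0.5 else -0.5
    xyz[i + 1, ] <- xyz[i, ] + lens[i] * c(cos(a), sin(a), 0)
  }
  orders <- rep(c(1L, 2L), length.out = n - 1)
  df <- tibble::tibble(chain = "P", resid = 1L, resname = "SYN",
                       atom = paste0("C", 1:n), element = "C",
                       x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
  got <- bla(df, orders = orders)
  expect_equal(got$bla, mean(lens[orders == 1]) - mean(lens[orders == 2]),
               tolerance = 1e-12)
  expect_equal(got$n_single, sum(orders == 1))
})

test_that("half-path bla scopes split at the central bond and exclude it when odd", {
  pol <- make_polyene()          # 20 atoms, 19 bonds: central bond 10 excluded
  pe <- extract_polyene(pol$ligand)
  left <- bla(pe, scope = "beta_side")
  right <- bla(pe, scope = "beta_prime_side")
  expect_equal(left$n_single + left$n_double, 9)
  expect_equal(right$n_single + right$n_double, 9)
  full <- bla(pe)
  expect_equal(full$n_single + full$n_double, 19)
  # full-path bla lies between the two half values (here all equal)
  expect_gte(full$bla, min(left$bla, right$bla) - 1e-12)
  expect_lte(full$bla, max(left$bla, right$bla) + 1e-12)
  # triple bond excluded from both means
  orders3 <- pe$orders; orders3[2] <- 3L
  b3 <- bla(pe$atoms, orders = orders3)
  expect_equal(b3$n_single + b3$n_double, 18)
})

test_that("dihedral follows the sign convention and matches the atan2 oracle", {
  expect_equal(dihedral(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, 1, 0)), 0)
  expect_equal(dihedral(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, -1, 0)), 180)
  set.seed(11)
  for (i in 1:1000) {
    p <- matrix(rnorm(12, sd = 2), 4, 3)
    got <- tryCatch(dihedral(p[1, ], p[2, ], p[3, ], p[4, ]),
                    error = function(e) NA)
    if (is.na(got)) next
    expect_equal(got, oracle_dihedral(p[1, ], p[2, ], p[3, ], p[4, ]),
                 tolerance = 1e-9)
    # mirroring negates the angle (except at the 0/180 symmetry points)
    m <- p; m[, 3] <- -m[, 3]
    mir <- dihedral(m[1, ], m[2, ], m[3, ], m[4, ])
    if (abs(abs(got) - 180) > 1e-9 && abs(got) > 1e-9) {
      expect_equal(mir, -got, tolerance = 1e-9)
    }
  }
  expect_error(dihedral(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 1, 0)),
               "collinear")
})

test_that("end-ring conformation classifies by the 90-degree rule", {
  # torsions chosen to mirror reported free (s-cis) and bound (s-trans) rings
  cases <- list(list(t = -39.9, k = "s-cis"), list(t = 170.6, k = "s-trans"),
                list(t = 164.4, k = "s-trans"), list(t = 90.0, k = "s-cis"),
                list(t = -40.0, k = "s-cis"))
  for (cs in cases) {
    pol <- make_polyene(synthetic_complex_spec(end_ring_torsions = c(cs$t, 100)))
    rc <- ring_conformation(pol$ligand, "ring1")
    expect_equal(rc$torsion$angle, cs$t, tolerance = 1e-6)
    expect_equal(rc$klass, cs$k)
  }
})

test_that("fit_plane matches an eigen-decomposition oracle and handles degeneracy", {
  # coplanar points -> zero residual, z-plane -> normal (0,0,1)
  flat <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1), 0)
  f <- fit_plane(flat)
  expect_equal(f$rms_out_of_plane, 0, tolerance = 1e-12)
  expect_equal(f$normal, c(0, 0, 1))
  set.seed(5)
  for (i in 1:20) {
    P <- matrix(rnorm(30), 10, 3)
    got <- fit_plane(P)
    orc <- oracle_plane(P)
    expect_equal(abs(sum(got$normal * orc$normal)), 1, tolerance = 1e-9)
    expect_equal(got$rms_out_of_plane, orc$rms, tolerance = 1e-9)
  }
  line <- cbind(1:5, 2 * (1:5), -1 * (1:5))
  expect_error(fit_plane(line), "collinear")
})

test_that("pair geometry recovers constructed plane separation and crossing dihedral", {
  cx <- make_complex(synthetic_complex_spec(inter_polyene_offset = 7.0))
  pg <- pair_geometry(cx$ligandA, cx$ligandB,
                      crossing = c("C5", "C10", "C10", "C5"))
  expect_equal(pg$interplanar_angle, 0, tolerance = 1e-6)
  expect_equal(pg$min_distance, 7.0, tolerance = 1e-9)
  # crossing dihedral equals a direct dihedral over the same four atoms
  getp <- function(lig, nm) unlist(lig$atoms[match(nm, lig$atoms$atom),
                                             c("x", "y", "z")])
  expect_equal(pg$crossing_dihedral,
               dihedral(getp(cx$ligandA, "C5"), getp(cx$ligandA, "C10"),
                        getp(cx$ligandB, "C10"), getp(cx$ligandB, "C5")),
               tolerance = 1e-9)
  expect_error(pair_geometry(cx$ligandA, cx$ligandB,
                             crossing = c("C5", "C10", "C10", "Z9")),
               "not found")
})

test_that("pseudo-twofold axes classify coincident and perpendicular constructions", {
  co <- make_c2_dimer(dimer_axis = "x")
  ax <- pseudo_twofold_axes(co$structure, co$ligandA, co$ligandB)
  expect_lt(ax$axis_angle, 1)
  expect_equal(ax$axis_klass, "coincident")
  expect_equal(ax$dimer_rotation, 180, tolerance = 1e-6)
  pe <- make_c2_dimer(dimer_axis = "z")
  ax2 <- pseudo_twofold_axes(pe$structure, pe$ligandA, pe$ligandB)
  expect_gt(ax2$axis_angle, 89)
  expect_equal(ax2$axis_klass, "perpendicular")
})

test_that("geometric descriptors are invariant under rigid motion", {
  cx <- make_complex()
  pe0 <- extract_polyene(cx$ligandA)
  b0 <- bla(pe0)$bla
  t0 <- ligand_torsion(cx$ligandA, "ring1")$angle
  pg0 <- pair_geometry(cx$ligandA, cx$ligandB,
                       crossing = c("C5", "C10", "C10", "C5"))
  set.seed(99)
  for (i in 1:100) {
    R <- random_rotation(); t <- rnorm(3, sd = 20)
    la <- rigid_move_ligand(cx$ligandA, R, t)
    lb <- rigid_move_ligand(cx$ligandB, R, t)
    expect_equal(bla(extract_polyene(la))$bla, b0, tolerance = 1e-6)
    expect_equal(ligand_torsion(la, "ring1")$angle, t0, tolerance = 1e-6)
    pg <- pair_geometry(la, lb, crossing = c("C5", "C10", "C10", "C5"))
    # acos amplifies coordinate round-off near exactly parallel planes
    expect_equal(pg$interplanar_angle, pg0$interplanar_angle, tolerance = 1e-4)
    expect_equal(pg$min_distance, pg0$min_distance, tolerance = 1e-6)
    expect_equal(pg$crossing_dihedral, pg0$crossing_dihedral, tolerance = 1e-6)
  }
})
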