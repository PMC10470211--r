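test_that("contact shell applies exact cutoff semantics and sorts output", {
  sh <- tibble::tibble(resname = c("SER", "SER"), distance = c(3.9, 4.1),
                       target_atom = c("C5", "C15"))
  cx <- make_complex(synthetic_complex_spec(shell = sh))
  cs <- contact_residues(cx$structure, cx$ligandA, cutoff = 4.0)
  expect_equal(unique(cs$resid), 1)            # the 4.1 A residue excluded
  expect_equal(cs$min_distance, c(3.9, 3.9), tolerance = 1e-9)
  expect_equal(cs$chain, c("A", "B"))
  # an isolated ligand has an empty shell
  lone <- make_complex(synthetic_complex_spec(shell = NULL, n_filler = 2))
  expect_equal(nrow(contact_residues(lone$structure, lone$ligandA)), 0)
  ghost <- cx$ligandA
  ghost$resid <- 999L
  expect_error(contact_residues(cx$structure, ghost), "not found")
})

test_that("contact shells grow monotonically with the cutoff", {
  cx <- make_complex()
  keys <- function(cs) paste(cs$chain, cs$resid)
  prev <- character(0)
  for (cut in c(3.0, 3.6, 4.0, 4.6, 6.0)) {
    cur <- keys(contact_residues(cx$structure, cx$ligandA, cutoff = cut))
    expect_true(all(prev %in% cur))
    prev <- cur
  }
})

test_that("hydrogen bonds require N/O pairs within the distance cutoff", {
  # a serine OG placed 2.8 A from the ligand's ring hydroxyl oxygen
  sh <- tibble::tibble(resname = c("SER", "SER"), distance = c(2.8, 3.0),
                       target_atom = c("O1", "C10"))
  cx <- make_complex(synthetic_complex_spec(shell = sh))
  hb <- hydrogen_bonds(cx$structure, cx$ligandA)
  pl <- hb[hb$klass == "protein-ligand", ]
  expect_true(all(pl$atom == "O1"))            # carbon target never bonds
  expect_true(all(pl$partner_atom == "OG"))
  expect_equal(sort(pl$partner_chain), c("A", "B"))
  expect_equal(pl$distance, c(2.8, 2.8), tolerance = 1e-9)
  # same geometry beyond the cutoff disappears
  sh5 <- tibble::tibble(resname = "SER", distance = 5.0, target_atom = "O1")
  cx5 <- make_complex(synthetic_complex_spec(shell = sh5))
  hb5 <- hydrogen_bonds(cx5$structure, cx5$ligandA)
  expect_equal(nrow(hb5[hb5$klass == "protein-ligand", ]), 0)
  # geometry filter keeps the well-formed contact
  hbg <- hydrogen_bonds(cx$structure, cx$ligandA, require_geometry = TRUE)
  expect_true(any(hbg$klass == "protein-ligand"))
})

test_that("sasa reproduces the isolated-sphere closed form for several elements", {
  for (el in c("C", "N", "O", "S")) {
    r <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80)[[el]]
    st <- caro_structure(tibble::tibble(
      chain = "X", resid = 1L, resname = "LIG", atom = el, element = el,
      x = 0, y = 0, z = 0, is_polymer = FALSE))
    got <- sasa(st)$sasa
    expect_equal(got, 4 * pi * (r + 1.4)^2, tolerance = 0.005)
  }
  expect_error(sasa(caro_structure(tibble::tibble(
    chain = "X", resid = 1L, resname = "LIG", atom = "XX", element = "ZZ",
    x = 0, y = 0, z = 0, is_polymer = FALSE))))
})

test_that("two coincident atoms each lose half their sphere", {
  st <- caro_structure(tibble::tibble(
    chain = "X", resid = 1L, resname = "LIG", atom = c("C1", "C2"),
    element = "C", x = c(0, 1e-9), y = 0, z = 0, is_polymer = FALSE))
  a <- sasa(st)$sasa
  iso <- 4 * pi * 3.10^2
  expect_equal(a[1] / iso, 0.5, tolerance = 0.01)
  expect_equal(a[2] / iso, 0.5, tolerance = 0.01)
})

test_that("sasa agrees with a high-density quadrature oracle on a random cluster", {
  set.seed(23)
  n <- 20
  st <- caro_structure(tibble::tibble(
    chain = "X", resid = 1L, resname = "LIG", atom = paste0("C", 1:n),
    element = sample(c("C", "N", "O"), n, replace = TRUE),
    x = rnorm(n, sd = 2.5), y = rnorm(n, sd = 2.5), z = rnorm(n, sd = 2.5),
    is_polymer = FALSE))
  coarse <- sum(sasa(st, n_points = 960)$sasa)
  fine <- sum(sasa(st, n_points = 10000)$sasa)
  expect_equal(coarse, fine, tolerance = 0.02)
})

test_that("sasa partition: isolation, symmetry, and bounds", {
  lone <- make_complex(synthetic_complex_spec(shell = NULL, n_filler = 0))
  # drop the partner carotenoid: truly isolated ligand
  solo <- caro_structure(lone$ligandA$atoms)
  sp0 <- sasa_partition(solo, lone$ligandA)
  expect_equal(sp0$fraction_exposed, 1, tolerance = 1e-9)
  expect_length(sp0$fraction_by_chain, 0)
  # mirrored two-chain shell buries the ligand equally from both sides
  cx <- make_complex()
  sp <- sasa_partition(cx$structure, cx$ligandA)
  fr <- sp$fraction_by_chain
  expect_equal(fr$A, fr$B, tolerance = 0.01)
  expect_true(all(unlist(fr) >= 0 & unlist(fr) <= 1))
  expect_lte(sp$fraction_exposed, 1 + 1e-9)
  # burial in the full complex never exceeds the isolated surface
  expect_gte(sp$total_isolated * (1 - sp$fraction_exposed), 0)
})

test_that("fragment B-factor statistics are plain unweighted moments", {
  res <- fake_axt_residue(b_beta = 31, b_beta_prime = 56)
  st <- caro_structure(res)
  lig <- match_ligands(st, templates = list(AXT = axt_template()))[[1]]
  fb <- fragment_bfactor(lig, "beta")
  fb2 <- fragment_bfactor(lig, "beta_prime")
  expect_equal(fb$mean_b, 31)
  expect_equal(fb$sd_b, 0)
  expect_equal(fb2$mean_b, 56)
  expect_equal(fb$n_atoms, length(axt_template()$end_rings$beta))
  expect_error(fragment_bfactor(lig, "kappa"), "not defined")
  # two-point formula
  two <- lig
  two$template$end_rings$pair <- c("C6", "C7")
  two$atoms$b[two$atoms$atom %in% c("C6", "C7")] <- c(10, 30)
  fbp <- fragment_bfactor(two, "pair")
  expect_equal(fbp$mean_b, 20)
  expect_equal(fbp$sd_b, sd(c(10, 30)))
})
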