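test_that("synthetic structures round-trip through mmCIF", {
  cx <- make_complex()
  f <- withr::local_tempfile(fileext = ".cif")
  write_structure(cx$structure, f)
  rt <- read_structure(f)
  expect_equal(nrow(rt), nrow(cx$structure))
  expect_equal(length(unique(rt$chain[rt$is_polymer])), 2)
  expect_lt(max(abs(rt$x - cx$structure$x)), 1e-3)
  expect_lt(max(abs(rt$y - cx$structure$y)), 1e-3)
  expect_lt(max(abs(rt$z - cx$structure$z)), 1e-3)
  expect_equal(rt$b, round(cx$structure$b, 2))
  expect_equal(rt$atom, cx$structure$atom)
  expect_equal(rt$is_polymer, cx$structure$is_polymer)
})

test_that("writing the same structure twice is byte-identical", {
  cx <- make_complex()
  f1 <- withr::local_tempfile(fileext = ".cif")
  f2 <- withr::local_tempfile(fileext = ".cif")
  write_structure(cx$structure, f1)
  write_structure(cx$structure, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("alt-locs resolve to the highest-occupancy conformer, ties by file order", {
  cx <- make_complex()
  st <- cx$structure
  dup <- st[1, ]
  dup$occ <- 0.6; dup$alt <- "A"
  dup2 <- dup; dup2$occ <- 0.4; dup2$alt <- "B"; dup2$x <- dup2$x + 2
  st2 <- caro_structure(dplyr::bind_rows(dup, dup2, st[-1, ]))
  f <- withr::local_tempfile(fileext = ".cif")
  write_structure(st2, f)
  rt <- read_structure(f)
  expect_equal(nrow(rt), nrow(st))      # one conformer kept
  kept <- rt[rt$chain == dup$chain & rt$resid == dup$resid &
               rt$atom == dup$atom, ]
  expect_equal(kept$occ, 0.6)
  # tie: first in file wins
  dup3 <- dup2; dup3$occ <- 0.6
  st3 <- caro_structure(dplyr::bind_rows(dup, dup3, st[-1, ]))
  write_structure(st3, f)
  rt3 <- read_structure(f)
  kept3 <- rt3[rt3$chain == dup$chain & rt3$resid == dup$resid &
                 rt3$atom == dup$atom, ]
  expect_equal(kept3$x, round(unname(dup$x), 3))
})

test_that("unparseable and empty inputs raise format errors", {
  f <- withr::local_tempfile(fileext = ".cif")
  writeLines(c("data_x", "loop_", "_atom_site.id", "garbage here"), f)
  expect_error(read_structure(f))
  expect_error(read_structure("no/such/file.cif"), "not found")
  expect_error(caro_structure(tibble::tibble(chain = character(),
                                             resid = integer(),
                                             resname = character(),
                                             atom = character(),
                                             element = character(),
                                             x = double(), y = double(),
                                             z = double())),
               "empty model")
})

test_that("select_dimer picks the lowest-mean-B dimer from a 4-copy assembly", {
  asm <- make_assembly(mean_b_offsets = c(30, 20, 40, 50))
  d <- select_dimer(asm$structure, mode = "lowest_mean_b")
  expect_setequal(unique(d$chain[d$is_polymer]), c("C", "D"))
  # the selected dimer keeps its two carotenoids
  expect_equal(length(unique(d$resid[d$resname == "SYN"])), 2)
})

test_that("select_dimer is invariant to chain order in the table", {
  asm <- make_assembly(mean_b_offsets = c(35, 45, 25, 55))
  st <- asm$structure
  st_rev <- st[order(st$chain, decreasing = TRUE), ]
  d1 <- select_dimer(st, mode = "lowest_mean_b")
  d2 <- select_dimer(caro_structure(st_rev), mode = "lowest_mean_b")
  expect_setequal(unique(d1$chain[d1$is_polymer]),
                  unique(d2$chain[d2$is_polymer]))
  expect_setequal(unique(d1$chain[d1$is_polymer]), c("E", "F"))
})

test_that("select_dimer on a single-dimer input is the identity on chains", {
  cx <- make_complex()
  d <- select_dimer(cx$structure, mode = "lowest_mean_b")
  expect_setequal(unique(d$chain[d$is_polymer]), c("A", "B"))
  expect_equal(sum(d$is_polymer), sum(cx$structure$is_polymer))
})

test_that("match_ligands applies the 90% atom-coverage rule and flags ambiguity", {
  res <- fake_axt_residue()
  prot <- make_complex()$structure
  st <- caro_structure(dplyr::bind_rows(prot[prot$is_polymer, ], res))
  hits <- match_ligands(st, templates = list(AXT = axt_template()))
  expect_length(hits, 1)
  expect_equal(hits[[1]]$code, "AXT")
  # removing 30% of atoms drops the residue below threshold
  n_drop <- ceiling(0.3 * nrow(res))
  res_part <- res[-seq(nrow(res), by = -1, length.out = n_drop), ]
  st2 <- caro_structure(dplyr::bind_rows(prot[prot$is_polymer, ], res_part))
  hits2 <- match_ligands(st2, templates = list(AXT = axt_template()))
  expect_length(hits2, 0)
  expect_true(length(attr(hits2, "unmatched")) == 1)
  # two identical templates -> ambiguity
  expect_error(
    match_ligands(st, templates = list(A = axt_template(), B = axt_template())),
    "several templates"
  )
})

test_that("write_report emits deterministic JSON and TSV", {
  b <- bla(extract_polyene(make_polyene()$ligand))
  f1 <- withr::local_tempfile(fileext = ".json")
  f2 <- withr::local_tempfile(fileext = ".json")
  write_report(tidy(b), f1)
  write_report(tidy(b), f2)
  expect_identical(readLines(f1), readLines(f2))
  parsed <- jsonlite::read_json(f1)
  expect_setequal(names(parsed),
                  c("ligand", "scope", "mean_single", "mean_double", "bla",
                    "n_single", "n_double"))
  expect_equal(parsed$bla[[1]], 0.1, tolerance = 1e-9)
  # empty contact shell is valid empty JSON
  far <- make_complex(synthetic_complex_spec(shell = NULL, n_filler = 2))
  cs <- contact_residues(far$structure, far$ligandA)
  f3 <- withr::local_tempfile(fileext = ".json")
  write_report(cs, f3)
  expect_true(all(lengths(jsonlite::read_json(f3)) == 0))
  ftsv <- withr::local_tempfile(fileext = ".tsv")
  write_report(tidy(b), ftsv, format = "tsv")
  expect_equal(nrow(utils::read.delim(ftsv)), 1)
})
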