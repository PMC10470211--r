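rotation_37z <- function() {
  th <- 37 * pi / 180
  matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3,
         byrow = TRUE)
}

test_that("kabsch recovers identity and constructed rotations exactly", {
  set.seed(2)
  A <- matrix(rnorm(60, sd = 5), 20, 3)
  same <- kabsch(A, A)
  expect_equal(same$rmsd, 0, tolerance = 1e-9)
  expect_equal(same$rotation, diag(3), tolerance = 1e-9)
  R <- rotation_37z()
  B <- A %*% t(R) + matrix(rep(c(3, -2, 8), each = 20), 20, 3)
  fit <- kabsch(A, B)
  expect_equal(fit$rmsd, 0, tolerance = 1e-9)
  expect_equal(fit$rotation_angle, 37, tolerance = 1e-6)
  expect_equal(abs(fit$rotation_axis[3]), 1, tolerance = 1e-9)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
  expect_error(kabsch(cbind(1:5, 0, 0), cbind(1:5, 0, 0)), "degenerate")
})

test_that("kabsch agrees with an independent quaternion oracle on 1000 point sets", {
  set.seed(41)
  for (i in 1:1000) {
    n <- sample(4:50, 1)
    A <- matrix(rnorm(3 * n, sd = 3), n, 3)
    B <- matrix(rnorm(3 * n, sd = 3), n, 3)
    expect_equal(kabsch(A, B)$rmsd, oracle_quaternion_fit(A, B),
                 tolerance = 1e-9)
  }
})

test_that("superposition RMSD is symmetric and rotation-invariant", {
  set.seed(13)
  A <- matrix(rnorm(90, sd = 4), 30, 3)
  B <- A + matrix(rnorm(90, sd = 0.5), 30, 3)
  expect_equal(kabsch(A, B)$rmsd, kabsch(B, A)$rmsd, tolerance = 1e-9)
  for (i in 1:10) {
    R <- random_rotation()
    expect_equal(kabsch(A %*% t(R), B)$rmsd, kabsch(A, B)$rmsd,
                 tolerance = 1e-9)
  }
})

test_that("sequence alignment identity counts identical core columns", {
  expect_equal(align_sequences("ACDEFG", "ACDEFG")$identity, 1.0)
  expect_equal(align_sequences("ACDEFG", "ACDEYG")$identity, 5 / 6)
  expect_error(align_sequences("ACDEFG", "ACDEZG"), "invalid residue")
  expect_error(align_sequences("", "ACD"), "empty")
})

test_that("chain superposition trims a displaced residue and reports the rest", {
  cd <- make_c2_dimer()
  st <- cd$structure
  # chain vs itself
  self <- superpose_chains(st, "A", "A")
  expect_equal(self$rmsd, 0, tolerance = 1e-9)
  expect_equal(self$n_matched, 15)
  # copy of chain A as chain "C" with one residue displaced 10 A
  cpy <- st[st$chain == "A", ]
  cpy$chain <- "C"
  cpy$x[cpy$resid == 7] <- cpy$x[cpy$resid == 7] + 10
  st2 <- caro_structure(dplyr::bind_rows(st, cpy))
  fit <- superpose_chains(st2, "A", "C", trim_sigma = 2)
  expect_equal(length(fit$trimmed), 1)
  expect_equal(fit$n_matched, 14)
  expect_equal(fit$rmsd, 0, tolerance = 1e-6)
  # without trimming the displaced residue dominates the rmsd
  raw <- superpose_chains(st2, "A", "C", trim_sigma = NULL)
  expect_gt(raw$rmsd, 1)
})

test_that("dimer superposition recovers a rigid transform over both chains", {
  cd <- make_c2_dimer()
  dimA <- cd$structure[cd$structure$is_polymer, ]
  self <- superpose_dimers(dimA, dimA)
  expect_equal(self$rmsd, 0, tolerance = 1e-9)
  set.seed(8)
  R <- random_rotation(); tr <- rnorm(3, sd = 10)
  dimB <- rigid_move_structure(dimA, R, tr)
  # swap chain labels so the pairing search has to work
  dimB$chain <- ifelse(dimB$chain == "A", "B", "A")
  fit <- superpose_dimers(caro_structure(dimA), caro_structure(dimB))
  expect_equal(fit$rmsd, 0, tolerance = 1e-6)
  expect_equal(fit$n_matched, 2 * 15)
  # recovered rotation undoes the applied one
  expect_equal(fit$rotation %*% R, diag(3), tolerance = 1e-6)
})

test_that("trimming never increases the rmsd across iterations", {
  set.seed(19)
  A <- matrix(rnorm(120, sd = 6), 40, 3)
  noise <- matrix(rnorm(120, sd = 0.3), 40, 3)
  noise[c(5, 17), ] <- noise[c(5, 17), ] + 8
  B <- A + noise
  rms_no_trim <- kabsch(A, B)$rmsd
  trimmed <- carotenostruct:::superpose_matched(A, B, trim_sigma = 2,
                                                max_iter = 10)
  expect_lte(trimmed$rmsd, rms_no_trim + 1e-12)
  expect_gte(length(trimmed$trimmed), 2)
})

test_that("the recovered axis of a synthetic C2 dimer matches construction", {
  for (ax in c("x", "z")) {
    cd <- make_c2_dimer(dimer_axis = ax)
    fit <- superpose_chains(cd$structure, "A", "B", trim_sigma = NULL)
    expect_equal(fit$rotation_angle, 180, tolerance = 1e-6)
    cosang <- abs(sum(fit$rotation_axis * cd$truth$dimer_axis))
    expect_equal(acos(min(1, cosang)) * 180 / pi, 0, tolerance = 1)
  }
})
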