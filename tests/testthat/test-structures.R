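test_that("read_subunit parses chains, flags the N-terminus, filters", {
  path <- toy_pdb_file(toy_pdb_lines)
  su <- read_subunit(path, "A")
  expect_s3_class(su, "subunit_model")
  expect_equal(su$resno, 1:3)
  expect_equal(su$resid, c("ALA", "LYS", "GLY"))
  expect_equal(su$xyz[1, ], c(1.458, 0, 0))
  expect_equal(su$xyz[3, ], c(7.5, 3.2, 2.1))
  expect_equal(su$is_n_terminus, c(TRUE, FALSE, FALSE))

  # missing chain errors and names the available ones
  expect_error(read_subunit(path, "C"), "A, B")

  # residue without C-alpha is skipped with a warning
  lines <- c(toy_pdb_lines[1:6],
             "ATOM     99  N   GLY A   5       9.000   9.000   9.000  1.00  0.00",
             toy_pdb_lines[7:10])
  expect_warning(su2 <- read_subunit(toy_pdb_file(lines), "A"), "5")
  expect_equal(length(su2$resno), 3)
})

test_that("superposition recovers transforms and matches bio3d", {
  set.seed(21)
  path <- toy_pdb_file(toy_pdb_lines)
  su <- read_subunit(path, "A")
  # self-fit is exact
  fit <- superpose(su, su)
  expect_equal(fit$rmsd, 0, tolerance = 1e-9)

  # fit onto a rotated copy recovers the rotation
  for (i in 1:10) {
    rt <- random_rt()
    moved <- apply_transform(su, rt)
    fit <- superpose(su, moved)
    expect_lt(fit$rmsd, 1e-9)
    expect_lt(max(abs(quat_to_mat(fit$transform$q) - quat_to_mat(rt$q))), 1e-6)
  }

  # noisy 4-point toy: Kabsch result equals bio3d's least-squares fit and is
  # no worse than any rotation from a quaternion grid (optimality)
  P <- matrix(rnorm(12), 4, 3)
  Q <- matrix(rnorm(12), 4, 3)
  a <- subunit_model("A", 1:4, rep("GLY", 4), P)
  b <- subunit_model("A", 1:4, rep("GLY", 4), Q)
  fit <- superpose(a, b)
  ref <- suppressWarnings(
    bio3d::fit.xyz(fixed = as.numeric(t(Q)), mobile = as.numeric(t(P))))
  rmsd_bio3d <- sqrt(mean(rowSums((matrix(ref, ncol = 3, byrow = TRUE) - Q)^2)))
  expect_equal(fit$rmsd, rmsd_bio3d, tolerance = 1e-6)
  grid_best <- Inf
  Pc <- sweep(P, 2, colMeans(P)); Qc <- sweep(Q, 2, colMeans(Q))
  for (i in 1:2000) {
    q <- rnorm(4); q <- q / sqrt(sum(q^2))
    r <- sqrt(mean(rowSums((Pc %*% t(quat_to_mat(q)) - Qc)^2)))
    grid_best <- min(grid_best, r)
  }
  expect_lte(fit$rmsd, grid_best + 1e-12)

  # invariance to pre-rotation of either input
  pre <- apply_transform(a, random_rt())
  expect_equal(superpose(pre, b)$rmsd, fit$rmsd, tolerance = 1e-6)
})

test_that("complex_rmsd is symmetric and matches closed forms", {
  fixed <- make_subunit(20, "globule", seed = 5, chain_id = "A")
  mobile <- make_subunit(12, "globule", seed = 6, chain_id = "B")
  ref <- complex_model(fixed, mobile)
  expect_equal(suppressMessages(complex_rmsd(ref, ref)), 0, tolerance = 1e-9)

  # pure 2 A translation of the mobile subunit: closed-form RMSD
  moved <- complex_model(fixed,
                         apply_transform(mobile, rigid_transform(t = c(2, 0, 0))))
  n_f <- 20; n_m <- 12
  expect_equal(suppressMessages(complex_rmsd(moved, ref)),
               sqrt(n_m * 4 / (n_f + n_m)), tolerance = 1e-6)

  # symmetry under argument swap
  expect_equal(suppressMessages(complex_rmsd(moved, ref)),
               suppressMessages(complex_rmsd(ref, moved)), tolerance = 1e-9)

  # residue numbering mismatch is reported
  bad <- mobile; bad$resno <- bad$resno + 100L
  expect_error(suppressMessages(complex_rmsd(complex_model(fixed, bad), ref)))
})

test_that("multi-model PDB output round-trips at coordinate precision", {
  fixed <- make_subunit(10, "globule", seed = 5, chain_id = "A")
  mobile <- make_subunit(8, "globule", seed = 6, chain_id = "B")
  models <- lapply(1:4, function(i) {
    set.seed(i)
    complex_model(fixed, apply_transform(mobile, random_rt()))
  })
  path <- tempfile(fileext = ".pdb")
  write_models(models, path)
  txt <- readLines(path)
  expect_equal(sum(grepl("^MODEL", txt)), 4)
  expect_equal(sum(grepl("^ENDMDL", txt)), 4)

  back <- read_models(path, fixed_chain = "A")
  expect_equal(length(back), 4)
  for (i in 1:4) {
    expect_lt(max(abs(back[[i]]$fixed$xyz - models[[i]]$fixed$xyz)), 5e-4)
    expect_lt(max(abs(back[[i]]$mobile[[1]]$xyz - models[[i]]$mobile[[1]]$xyz)),
              5e-4)
  }
})
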