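test_that("square-well energy is zero in the well and quadratic outside", {
  expect_equal(squarewell_energy(15, 20, 30), 0)
  expect_equal(squarewell_energy(25, 24, 30), 30)
  expect_equal(squarewell_energy(24, 24, 30), 0)  # inclusive boundary
  # continuity at the bound
  eps <- 1e-8
  expect_lt(squarewell_energy(20 + eps, 20, 30), 1e-12)
  # matches direct evaluation on random inputs
  set.seed(41)
  d <- runif(200, 1, 50); b <- runif(200, 5, 30); k <- runif(200, 1, 30)
  expect_equal(squarewell_energy(d, b[1], k[1]),
               ifelse(d <= b[1], 0, k[1] * (d - b[1])^2), tolerance = 1e-9)
  for (i in 1:50) {
    expect_equal(squarewell_energy(d[i], b[i], k[i]),
                 if (d[i] <= b[i]) 0 else k[i] * (d[i] - b[i])^2,
                 tolerance = 1e-9)
  }
})

test_that("ensemble effective distance is the inverse-sixth average", {
  expect_equal(ensemble_effective_distance(10), 10)
  expect_equal(ensemble_effective_distance(c(10, 10)), 10)
  expect_equal(ensemble_effective_distance(c(20, 40)),
               mean(c(20, 40)^-6)^(-1 / 6), tolerance = 1e-12)
  expect_equal(round(ensemble_effective_distance(c(20, 40)), 2), 22.39)
  expect_error(ensemble_effective_distance(c(10, -1)), "positive")
  set.seed(42)
  for (i in 1:50) {
    d <- runif(sample(1:6, 1), 2, 80)
    d_eff <- ensemble_effective_distance(d)
    # brute-force re-evaluation
    expect_equal(d_eff, (sum(d^-6) / length(d))^(-1 / 6), tolerance = 1e-9)
    # never exceeds min * N^(1/6)
    expect_lte(d_eff, min(d) * length(d)^(1 / 6) + 1e-9)
    # adding a conformer at least as close as the closest one cannot raise
    # d_eff (and so never raises the ambiguous restraint energy)
    extra <- runif(1, 1, min(d))
    expect_lte(ensemble_effective_distance(c(d, extra)), d_eff + 1e-9)
  }
})

test_that("ambiguous restraint energy honours ensembles and chain swaps", {
  # one far conformer is forgiven when another satisfies the bound
  res <- ambiguous_cxms_energy(c(15, 80), bound = 20, k = 30)
  expect_equal(res$energy, 0)
  expect_lt(res$effective_distance, 20)
  # single conformer in violation: k * delta^2
  res1 <- ambiguous_cxms_energy(30, bound = 20, k = 30)
  expect_equal(res1$energy, 3000)
  # chain-swapped assignment can satisfy the restraint on its own
  res2 <- ambiguous_cxms_energy(50, bound = 20, k = 30, swap_distances = 12)
  expect_equal(res2$energy, 0)
  expect_equal(res2$effective_distance,
               mean(c(50, 12)^-6)^(-1 / 6), tolerance = 1e-12)
})

test_that("repulsion penalizes only inter-subunit clashes", {
  a <- matrix(c(0, 0, 0), 1)
  b <- matrix(c(100, 0, 0), 1)
  expect_equal(repulsion_energy(a, b), 0)
  expect_equal(repulsion_energy(a, matrix(c(1, 0, 0), 1)), 10 * 9)
  # overlapping conformers of an ensemble are not penalized anywhere in the
  # total: only fixed-mobile pairs enter
  fixed <- make_subunit(10, "globule", seed = 1, chain_id = "A")
  far <- apply_transform(make_subunit(8, "globule", seed = 2, chain_id = "B"),
                         rigid_transform(t = c(80, 0, 0)))
  cm <- complex_model(fixed, list(far, far))  # two superposed conformers
  eb <- energy_breakdown(cm, make_record(n_bs3 = 2, res_a = 3, res_b = 5))
  expect_equal(eb$repulsion, 0)
})

test_that("C2 symmetry energy is zero for true dimers and found by closed form", {
  su <- make_subunit(15, "globule", seed = 7, chain_id = "A")
  # exact two-fold image
  axis <- c(0.3, 1, 0.2) / sqrt(sum(c(0.3, 1, 0.2)^2))
  rt <- rt_axis_angle(axis, pi, center = c(12, 0, 3))
  img <- apply_transform(su, rt)
  expect_equal(as.numeric(c2_symmetry_energy(su, img)), 0, tolerance = 1e-4)

  # a shift perpendicular to the two-fold axis is still an exact C2 image
  # (about a parallel displaced axis); a screw shift along the axis is not,
  # and its penalty grows monotonically
  perp <- c(1, 0, 0) - sum(c(1, 0, 0) * axis) * axis
  perp <- perp / sqrt(sum(perp^2))
  shifted_perp <- apply_transform(img, rigid_transform(t = 3 * perp))
  expect_equal(as.numeric(c2_symmetry_energy(su, shifted_perp)), 0,
               tolerance = 1e-4)
  e_prev <- 1e-4
  for (off in c(0.5, 1, 2, 4)) {
    shifted <- apply_transform(img, rigid_transform(t = off * axis))
    e <- as.numeric(c2_symmetry_energy(su, shifted))
    expect_gt(e, e_prev)
    e_prev <- e
  }

  # asymmetric pair: closed-form best axis beats/matches a dense grid search
  set.seed(8)
  other <- apply_transform(make_subunit(15, "globule", seed = 9, chain_id = "B"),
                           rigid_transform(t = c(20, 5, 0)))
  e_closed <- attr(c2_symmetry_energy(su, other), "rmsd")
  A <- su$xyz; B <- other$xyz
  P <- sweep(A, 2, colMeans(A)); Q <- sweep(B, 2, colMeans(B))
  dc <- colMeans(B) - colMeans(A)
  best <- Inf
  for (i in 1:20000) {
    u <- rnorm(3); u <- u / sqrt(sum(u^2))
    val <- sum((P + Q)^2) - 4 * sum((P %*% u) * (Q %*% u)) +
      nrow(P) * sum(u * dc)^2
    best <- min(best, sqrt(max(0, val) / nrow(P)))
  }
  expect_lte(e_closed, best + 1e-9)
  expect_equal(e_closed, best, tolerance = 1e-3)

  expect_error(c2_symmetry_energy(su, img, homodimer = FALSE), "homodimer")
})

test_that("total energy is invariant under global rigid motion", {
  sys <- small_system(seed = 2)
  cm <- planted_complex(sys)
  base <- energy_breakdown(cm, sys$links)
  set.seed(51)
  for (i in 1:5) {
    moved <- apply_transform(cm, random_rt())
    eb <- energy_breakdown(moved, sys$links)
    expect_equal(eb$total, base$total, tolerance = 1e-6)
  }
  expect_equal(base$total, base$cxms + base$repulsion + base$symmetry)
})
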