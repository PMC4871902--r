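one_atom_model <- function(at, fixed) {
  mob <- subunit_model("B", 1:3, rep("GLY", 3),
                       rbind(at, at + c(3.8, 0, 0), at + c(7.6, 0, 0)))
  complex_model(fixed, mob)
}

test_that("probability maps peak at the deposited atoms and conserve mass", {
  fixed <- make_subunit(10, "globule", seed = 1, chain_id = "A")
  at <- c(30, 0, 0)
  pm <- probability_map(one_atom_model(at, fixed), spacing = 1, sigma = 2)
  # overlapping kernels of the three-atom chain peak at the middle atom
  idx <- which(pm$grid == 1, arr.ind = TRUE)[1, ]
  cell <- pm$origin + (idx - 1) * pm$spacing
  expect_lt(sqrt(sum((cell - (at + c(3.8, 0, 0)))^2)), 1.8)

  # two disjoint poses give two equal-height lobes
  m1 <- one_atom_model(c(30, 0, 0), fixed)
  m2 <- one_atom_model(c(-30, 0, 0), fixed)
  pm2 <- probability_map(list(m1, m2), spacing = 1, sigma = 2)
  half <- dim(pm2$grid)[1] %/% 2
  expect_equal(max(pm2$grid[1:half, , ]), max(pm2$grid[(half + 1):dim(pm2$grid)[1], , ]),
               tolerance = 1e-6)

  # quadrature: unnormalized integral = n_atoms * n_models * kernel mass
  expect_equal(pm$raw_sum * pm$spacing^3,
               pm$n_atoms * (2 * pi * pm$sigma^2)^(3 / 2),
               tolerance = 0.01)

  # equivariance: rigidly moving all models moves the map with them
  rt <- rt_axis_angle(c(0, 0, 1), pi / 2)
  pm_rot <- probability_map(apply_transform(one_atom_model(at, fixed), rt),
                            spacing = 1, sigma = 2)
  idx_r <- which(pm_rot$grid == 1, arr.ind = TRUE)[1, ]
  cell_r <- pm_rot$origin + (idx_r - 1) * pm_rot$spacing
  expect_lt(sqrt(sum((cell_r -
                        transform_xyz(matrix(at + c(3.8, 0, 0), 1), rt))^2)),
            1.8)
})

test_that("CCP4 export round-trips the grid", {
  fixed <- make_subunit(10, "globule", seed = 1, chain_id = "A")
  pm <- probability_map(one_atom_model(c(20, 5, -3), fixed), spacing = 2)
  path <- tempfile(fileext = ".ccp4")
  write_map_ccp4(pm, path)
  con <- file(path, "rb")
  hdr <- readBin(con, "integer", 10, size = 4, endian = "little")
  expect_equal(hdr[1:3], dim(pm$grid))
  expect_equal(hdr[4], 2)  # mode 2, float32
  seek(con, 1024)
  vals <- readBin(con, "numeric", prod(dim(pm$grid)), size = 4,
                  endian = "little")
  close(con)
  expect_equal(max(vals), 1, tolerance = 1e-6)
  expect_equal(vals, as.numeric(pm$grid), tolerance = 1e-6)
  expect_equal(file.size(path), 1024 + 4 * prod(dim(pm$grid)))
})

test_that("spherical projection matches direct trigonometry", {
  # a fixed subunit whose long axis defines z
  fixed <- subunit_model("A", 1:9, rep("GLY", 9),
                         cbind(seq(-16, 16, by = 4), rnorm(9, 0, 0.3),
                               rnorm(9, 0, 0.3)))
  place_at <- function(v) {
    mob <- subunit_model("B", 1:3, rep("GLY", 3),
                         rbind(v, v + c(0, 0.1, 0), v - c(0, 0.1, 0)))
    complex_model(fixed, mob)
  }
  com_f <- colMeans(fixed$xyz)
  # along the principal (long) axis: theta = 0 or 180
  p1 <- spherical_projection(place_at(com_f + c(40, 0, 0)))
  expect_true(abs(p1$theta) < 5 || abs(p1$theta - 180) < 5)
  # perpendicular to it: theta = 90
  p2 <- spherical_projection(place_at(com_f + c(0, 40, 0)))
  expect_equal(p2$theta, 90, tolerance = 5)
  expect_equal(p2$r, 40, tolerance = 0.1)

  # random poses agree with direct evaluation in the same frame
  set.seed(61)
  for (i in 1:5) {
    v <- rnorm(3, 0, 30)
    pr <- spherical_projection(place_at(com_f + v))
    expect_equal(pr$r, sqrt(sum(v^2)), tolerance = 1e-6)
    expect_equal(pr$theta, acos(pr$z / pr$r) * 180 / pi, tolerance = 1e-9)
    expect_equal(pr$phi, atan2(pr$y, pr$x) * 180 / pi, tolerance = 1e-9)
    expect_true(pr$theta >= 0 && pr$theta <= 180)
    expect_true(pr$phi > -180 && pr$phi <= 180)
  }
})

test_that("clustering separates planted pose groups and is order-stable", {
  set.seed(71)
  centers <- rbind(c(30, 0, 0), c(-5, 35, 10))
  xyz <- do.call(rbind, lapply(1:2, function(k) {
    sweep(matrix(rnorm(3 * 12, 0, 2), ncol = 3), 2, centers[k, ], "+")
  }))
  proj <- tibble::tibble(model = seq_len(24), conformer = 1,
                         x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
  cl <- cluster_models(proj, eps = 8, min_pts = 3)
  expect_equal(length(unique(cl$cluster)), 2)
  expect_equal(length(unique(cl$cluster[1:12])), 1)
  expect_equal(length(unique(cl$cluster[13:24])), 1)
  expect_true(all(cl$cluster > 0))

  # a single tight group forms one cluster
  one <- cluster_models(proj[1:12, ], eps = 8, min_pts = 3)
  expect_equal(unique(one$cluster), 1)

  # permutation stability (up to label renaming)
  perm <- sample(24)
  cl_p <- cluster_models(proj[perm, ], eps = 8, min_pts = 3)
  expect_equal(length(unique(cl_p$cluster)), 2)
  agree <- table(cl$cluster[perm], cl_p$cluster)
  expect_equal(sum(agree > 0), 2)  # one-to-one label correspondence
})

test_that("clusters are assigned the restraints their members satisfy", {
  fixed <- make_subunit(100, "helix", seed = 3, chain_id = "A")
  mobile <- make_subunit(10, "helix", seed = 4, chain_id = "B")
  sys <- plant_poses_and_links(fixed, mobile, k_poses = 2, links_per_pose = 3,
                               linker = "BS2G", seed = 1)
  # duplicate the true complex a few times so each pose forms a cluster
  models <- replicate(4, planted_complex(sys), simplify = FALSE)
  proj <- cluster_models(spherical_projection(models), eps = 8, min_pts = 3)
  expect_equal(length(setdiff(unique(proj$cluster), 0)), 2)
  tab <- cluster_restraint_table(models, sys$links, proj)
  tab <- tab[tab$cluster > 0, ]
  # together the clusters account for every restraint, each for its own pose
  labs <- sprintf("%s%d-%s%d", sys$links$chain_a, sys$links$res_a,
                  sys$links$chain_b, sys$links$res_b)
  covered <- unlist(strsplit(tab$restraints_satisfied, ","))
  expect_setequal(covered, labs)
  per_pose <- split(labs, sys$links$pose)
  expect_true(all(vapply(tab$restraints_satisfied, function(s) {
    got <- strsplit(s, ",")[[1]]
    any(vapply(per_pose, function(pp) setequal(got, pp), logical(1)))
  }, logical(1))))
})
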