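#' Atomic probability map of the mobile subunit
#'
#' Deposits a spherical Gaussian kernel (sd `sigma`, truncated at 4 sigma)
#' at every selected C-alpha atom of every mobile conformer across the
#' accepted models (equal model weights, with a hook for user weights), on a
#' regular grid; the map is normalized so its maximum is 1, and is plotted or
#' exported at fraction-of-maximum thresholds. Fixed subunits must already
#' share a frame (they do for models from one [run_batch()]).
#'
#' @param models list of `complex_model`s (or a `refine_batch`).
#' @param spacing grid spacing, A (default 2).
#' @param sigma kernel standard deviation, A (default 2).
#' @param weights optional per-model weights (default equal).
#' @return object of class `probability_map`: `origin`, `spacing`, `grid`
#'   (3-D array, max 1), plus the unnormalized sum/max and kernel bookkeeping.
#' @export
probability_map <- function(models, spacing = 2, sigma = 2, weights = NULL) {
  if (inherits(models, "refine_batch")) models <- models$models
  if (inherits(models, "complex_model")) models <- list(models)
  stopifnot(length(models) >= 1)
  pts <- do.call(rbind, lapply(models, function(m) {
    do.call(rbind, lapply(m$mobile, ca_xyz))
  }))
  if (is.null(pts) || nrow(pts) == 0) stop("empty atom selection")
  if (is.null(weights)) weights <- rep(1, length(models))
  stopifnot(length(weights) == length(models))
  n_per <- vapply(models, function(m) sum(vapply(m$mobile, function(s)
    nrow(s$xyz), integer(1))), integer(1))
  w_atom <- rep(weights, times = n_per)

  cut <- 4 * sigma
  lo <- apply(pts, 2, min) - cut
  hi <- apply(pts, 2, max) + cut
  dims <- pmax(2L, as.integer(ceiling((hi - lo) / spacing)) + 1L)
  grid <- array(0, dims)
  ax <- lapply(1:3, function(d) lo[d] + (seq_len(dims[d]) - 1) * spacing)
  for (i in seq_len(nrow(pts))) {
    p <- pts[i, ]
    idx <- lapply(1:3, function(d) {
      which(abs(ax[[d]] - p[d]) <= cut)
    })
    dx <- ax[[1]][idx[[1]]] - p[1]
    dy <- ax[[2]][idx[[2]]] - p[2]
    dz <- ax[[3]][idx[[3]]] - p[3]
    g <- outer(outer(exp(-dx^2 / (2 * sigma^2)), exp(-dy^2 / (2 * sigma^2))),
               exp(-dz^2 / (2 * sigma^2)))
    grid[idx[[1]], idx[[2]], idx[[3]]] <-
      grid[idx[[1]], idx[[2]], idx[[3]]] + w_atom[i] * g
  }
  raw_sum <- sum(grid); raw_max <- max(grid)
  structure(list(origin = lo, spacing = spacing, grid = grid / raw_max,
                 raw_sum = raw_sum, raw_max = raw_max, sigma = sigma,
                 n_models = length(models), n_atoms = nrow(pts)),
            class = "probability_map")
}

#' @export
print.probability_map <- function(x, ...) {
  d <- dim(x$grid)
  cat(sprintf("<probability_map> %dx%dx%d grid, spacing %.1f A, %d atoms from %d models\n",
              d[1], d[2], d[3], x$spacing, x$n_atoms, x$n_models))
  invisible(x)
}

#' Export a probability map in CCP4/MRC volume format
#'
#' Minimal mode-2 (32-bit float) CCP4 map with an orthogonal unit cell of
#' the grid's physical size and the map origin stored in the MRC origin
#' fields, readable by standard molecular-graphics software.
#'
#' @param map a [probability_map()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_map_ccp4 <- function(map, path) {
  g <- map$grid
  d <- dim(g)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(d)                         # NC NR NS
  wi(2)                         # MODE 2: float32
  wi(c(0, 0, 0))                # NCSTART NRSTART NSSTART
  wi(d)                         # MX MY MZ
  wf(d * map$spacing)           # CELLA
  wf(c(90, 90, 90))             # CELLB
  wi(c(1, 2, 3))                # MAPC MAPR MAPS
  wf(c(min(g), max(g), mean(g)))
  wi(1)                         # ISPG
  wi(0)                         # NSYMBT
  wi(rep(0, 25))                # EXTRA
  wf(map$origin)                # ORIGIN x y z
  writeChar("MAP ", con, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # little-endian stamp
  wf(stats::sd(as.numeric(g)))  # RMS
  wi(0)                         # NLABL
  writeBin(raw(800), con)       # empty labels
  wf(as.numeric(g))             # x fastest, then y, then z (column order)
  invisible(path)
}

principal_frame <- function(xyz) {
  com <- colMeans(xyz)
  cen <- sweep(xyz, 2, com)
  e <- eigen(crossprod(cen) / nrow(cen), symmetric = TRUE)
  V <- e$vectors  # columns ordered by decreasing variance
  for (d in 1:2) {
    m3 <- sum((cen %*% V[, d])^3)
    if (m3 < 0 || (abs(m3) < 1e-9 && V[which.max(abs(V[, d])), d] < 0)) {
      V[, d] <- -V[, d]
    }
  }
  V[, 3] <- c(V[2, 1] * V[3, 2] - V[3, 1] * V[2, 2],
              V[3, 1] * V[1, 2] - V[1, 1] * V[3, 2],
              V[1, 1] * V[2, 2] - V[2, 1] * V[1, 2])
  list(com = com, V = V)
}

#' Spherical-coordinate projection of mobile conformer positions
#'
#' Expresses the center of mass of every mobile conformer in the fixed
#' subunit's principal-axis frame (axes by decreasing C-alpha variance,
#' signs fixed by the third moment, right-handed; z = first principal axis)
#' as spherical coordinates: polar angle theta in `[0, 180]` from +z,
#' azimuth phi in `(-180, 180]`, radius r in Angstrom. This is the
#' low-dimensional view in which distinct binding modes appear as distinct
#' clusters.
#'
#' @param models list of `complex_model`s (or a `refine_batch`) with fixed
#'   subunits in a shared frame.
#' @return tibble of class `spherical_projection`: model, conformer, x, y, z
#'   (frame coordinates), r, theta, phi.
#' @export
spherical_projection <- function(models) {
  if (inherits(models, "refine_batch")) models <- models$models
  if (inherits(models, "complex_model")) models <- list(models)
  fr <- principal_frame(models[[1]]$fixed$xyz)
  out <- purrr::map_dfr(seq_along(models), function(mi) {
    purrr::map_dfr(seq_along(models[[mi]]$mobile), function(ci) {
      com <- colMeans(models[[mi]]$mobile[[ci]]$xyz)
      v <- as.numeric(crossprod(fr$V, com - fr$com))  # frame: z first axis
      x <- v[2]; y <- v[3]; z <- v[1]
      r <- sqrt(sum(v^2))
      tibble::tibble(model = mi, conformer = ci, x = x, y = y, z = z, r = r,
                     theta = acos(max(-1, min(1, z / r))) * 180 / pi,
                     phi = atan2(y, x) * 180 / pi)
    })
  })
  class(out) <- c("spherical_projection", class(out))
  out
}

dbscan_points <- function(X, eps, min_pts) {
  # standard DBSCAN; n is small (conformer positions), so the O(n^2)
  # neighbour query is fine
  n <- nrow(X)
  d2 <- cross_dist2(X, X)
  nb <- lapply(seq_len(n), function(i) which(d2[i, ] <= eps^2))
  core <- vapply(nb, length, integer(1)) >= min_pts
  labels <- rep(0L, n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L || !core[i]) next
    cl <- cl + 1L
    labels[i] <- cl
    frontier <- nb[[i]]
    while (length(frontier) > 0) {
      j <- frontier[1]; frontier <- frontier[-1]
      if (labels[j] == 0L) {
        labels[j] <- cl
        if (core[j]) frontier <- c(frontier, nb[[j]][labels[nb[[j]]] == 0L])
      }
    }
  }
  labels
}

#' Cluster conformer positions
#'
#' Density-based (DBSCAN) clustering of mobile-conformer center-of-mass
#' positions; distinct binding modes separate into distinct clusters, noise
#' conformers get cluster 0. Labels are invariant to model order up to
#' cluster renumbering.
#'
#' @param projection a [spherical_projection()] tibble (or any tibble with
#'   x, y, z columns).
#' @param eps DBSCAN neighbourhood radius, A (default 8).
#' @param min_pts minimum neighbours for a core point (default 3).
#' @return the input with a `cluster` integer column added.
#' @export
cluster_models <- function(projection, eps = 8, min_pts = 3) {
  stopifnot(all(c("x", "y", "z") %in% names(projection)))
  X <- as.matrix(projection[, c("x", "y", "z")])
  projection$cluster <- dbscan_points(X, eps, min_pts)
  projection
}

#' Which restraints does each conformer cluster account for?
#'
#' Reproduces the cluster-to-cross-link assignment: a cluster accounts for a
#' restraint when at least one member conformer places the cross-linked pair
#' within its bound (single-conformer C-alpha distance).
#'
#' @param models list of `complex_model`s (or a `refine_batch`).
#' @param restraints cross-link tibble.
#' @param clustered output of [cluster_models()] for these models.
#' @return tibble: cluster, n_members, restraints_satisfied (comma-joined
#'   `res_a-res_b` labels).
#' @export
cluster_restraint_table <- function(models, restraints, clustered) {
  if (inherits(models, "refine_batch")) models <- models$models
  bounds <- effective_bound(restraints)
  lab <- sprintf("%s%d-%s%d", restraints$chain_a, restraints$res_a,
                 restraints$chain_b, restraints$res_b)
  sat <- purrr::map_dfr(seq_len(nrow(clustered)), function(i) {
    m <- models[[clustered$model[i]]]
    ci <- clustered$conformer[i]
    ok <- vapply(seq_len(nrow(restraints)), function(r) {
      d <- restraint_distances(m, restraints[r, ])
      min(c(d$direct[ci], d$swapped[ci])) <= bounds[r]
    }, logical(1))
    tibble::tibble(cluster = clustered$cluster[i], restraint = list(which(ok)))
  })
  dplyr::summarise(
    dplyr::group_by(sat, .data$cluster),
    n_members = dplyr::n(),
    restraints_satisfied = paste(lab[sort(unique(unlist(.data$restraint)))],
                                 collapse = ","),
    .groups = "drop")
}
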