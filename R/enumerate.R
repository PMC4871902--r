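eligible_residues <- function(su, chemistry) {
  if (chemistry == "amine") {
    which(su$resid == "LYS" | su$is_n_terminus)
  } else {
    which(su$resid %in% c("GLU", "ASP"))
  }
}

#' Enumerate theoretical cross-links of a complex
#'
#' Lists every inter-subunit residue pair eligible for the linker's
#' chemistry (lysines and the N-terminus for amine linkers, Glu/Asp for
#' carboxylate) whose distance is within the cutoff, in either straight-line
#' (`euclidean`) or solvent-accessible surface distance (`sasd`) mode. The
#' SASD is the shortest path between the two residues that stays outside
#' the protein volume — the physically meaningful span of a cross-linker —
#' and is never shorter than the chord.
#'
#' @param complex a `complex_model` (first mobile conformer is used).
#' @param linker linker name (`"BS3"`, `"BS2G"`, `"PDH"`).
#' @param mode `"euclidean"` or `"sasd"`.
#' @param cutoff distance cutoff, A (default: the linker's residue-residue bound).
#' @param spacing SASD grid spacing, A (default 1).
#' @param probe solvent probe radius, A (default 1.4).
#' @param atom_radius heavy-atom radius used for the occupancy test, A (default 1.7).
#' @return tibble: res_a, res_b, kind_a, kind_b, euclidean and (in sasd mode)
#'   sasd distances; only pairs within the cutoff in the requested mode.
#' @export
enumerate_theoretical <- function(complex, linker = "BS3",
                                  mode = c("euclidean", "sasd"),
                                  cutoff = NULL, spacing = 1,
                                  probe = 1.4, atom_radius = 1.7) {
  mode <- match.arg(mode)
  reg <- linker_registry()
  li <- reg[reg$name == linker, ]
  if (nrow(li) == 0) stop("unknown linker: ", linker)
  if (is.null(cutoff)) cutoff <- li$bound_res_res
  fixed <- complex$fixed; mobile <- complex$mobile[[1]]
  ia <- eligible_residues(fixed, li$chemistry)
  jb <- eligible_residues(mobile, li$chemistry)
  if (length(ia) == 0 || length(jb) == 0) {
    warning("no eligible residues for ", linker)
    return(tibble::tibble(res_a = integer(), res_b = integer(),
                          kind_a = character(), kind_b = character(),
                          euclidean = numeric()))
  }
  kind_of <- function(su, i) {
    if (li$chemistry == "amine") {
      if (su$is_n_terminus[i] && su$resid[i] != "LYS") "n_terminus" else "lysine"
    } else if (su$resid[i] == "GLU") "glutamate" else "aspartate"
  }
  grid <- NULL
  pairs <- tidyr::expand_grid(i = ia, j = jb)
  eu <- sqrt(rowSums((fixed$xyz[pairs$i, , drop = FALSE] -
                      mobile$xyz[pairs$j, , drop = FALSE])^2))
  out <- tibble::tibble(
    res_a = fixed$resno[pairs$i], res_b = mobile$resno[pairs$j],
    kind_a = vapply(pairs$i, function(i) kind_of(fixed, i), character(1)),
    kind_b = vapply(pairs$j, function(j) kind_of(mobile, j), character(1)),
    euclidean = eu)
  if (mode == "euclidean") {
    return(out[out$euclidean <= cutoff, , drop = FALSE])
  }
  grid <- sasd_grid(rbind(fixed$xyz, mobile$xyz), spacing, probe, atom_radius)
  out$sasd <- NA_real_
  for (i in unique(pairs$i)) {
    sel <- which(pairs$i == i)
    # skip sources whose every target is already beyond any plausible path
    out$sasd[sel] <- sasd_distances(grid, fixed$xyz[i, ],
                                    mobile$xyz[pairs$j[sel], , drop = FALSE])
  }
  out[!is.na(out$sasd) & out$sasd <= cutoff, , drop = FALSE]
}

sasd_grid <- function(atoms, spacing = 1, probe = 1.4, atom_radius = 1.7,
                      cover = NULL) {
  # occupancy grid: a cell is solvent-accessible when its centre is farther
  # than probe + atom_radius from every atom; `cover` lists extra points the
  # grid must span (query endpoints)
  excl <- probe + atom_radius
  ext <- rbind(atoms, cover)
  lo <- apply(ext, 2, min) - excl - 3 * spacing
  hi <- apply(ext, 2, max) + excl + 3 * spacing
  dims <- as.integer(ceiling((hi - lo) / spacing)) + 1L
  ax <- lapply(1:3, function(d) lo[d] + (seq_len(dims[d]) - 1) * spacing)
  open <- array(TRUE, dims)
  r2 <- excl^2
  span <- ceiling(excl / spacing)
  for (i in seq_len(nrow(atoms))) {
    p <- atoms[i, ]
    ci <- lapply(1:3, function(d) {
      j <- round((p[d] - lo[d]) / spacing) + 1
      max(1, j - span):min(dims[d], j + span)
    })
    dx2 <- (ax[[1]][ci[[1]]] - p[1])^2
    dy2 <- (ax[[2]][ci[[2]]] - p[2])^2
    dz2 <- (ax[[3]][ci[[3]]] - p[3])^2
    blocked <- outer(outer(dx2, dy2, "+"), dz2, "+") < r2
    open[ci[[1]], ci[[2]], ci[[3]]] <- open[ci[[1]], ci[[2]], ci[[3]]] & !blocked
  }
  list(open = open, lo = lo, spacing = spacing, dims = dims, ax = ax)
}

nearest_open_cell <- function(grid, p, max_shells = 8) {
  # nearest solvent-accessible cell to point p (searched in growing boxes)
  j <- pmin(pmax(round((p - grid$lo) / grid$spacing) + 1, 1), grid$dims)
  for (s in 0:max_shells) {
    rng <- lapply(1:3, function(d) max(1, j[d] - s):min(grid$dims[d], j[d] + s))
    sub <- grid$open[rng[[1]], rng[[2]], rng[[3]], drop = FALSE]
    if (any(sub)) {
      idx <- which(sub, arr.ind = TRUE)
      cells <- cbind(rng[[1]][idx[, 1]], rng[[2]][idx[, 2]], rng[[3]][idx[, 3]])
      pos <- sweep((cells - 1) * grid$spacing, 2, grid$lo, "+")
      d2 <- rowSums(sweep(pos, 2, p)^2)
      k <- which.min(d2)
      return(list(cell = cells[k, ], dist = sqrt(d2[k])))
    }
  }
  NULL
}

grid_bfs <- function(grid, start_cell) {
  # 6-connected BFS over open cells; returns step counts (Inf = unreachable)
  dims <- grid$dims
  n <- prod(dims)
  steps <- rep(Inf, n)
  open <- as.logical(grid$open)
  id <- function(c3) (c3[3] - 1) * dims[1] * dims[2] + (c3[2] - 1) * dims[1] + c3[1]
  s0 <- id(start_cell)
  if (!open[s0]) return(array(steps, dims))
  steps[s0] <- 0
  frontier <- s0
  nxy <- dims[1] * dims[2]
  # precompute coordinates lazily via modular arithmetic for boundary checks
  lev <- 0
  while (length(frontier) > 0) {
    lev <- lev + 1
    x <- (frontier - 1) %% dims[1] + 1
    y <- ((frontier - 1) %/% dims[1]) %% dims[2] + 1
    z <- (frontier - 1) %/% nxy + 1
    nbrs <- c(frontier[x > 1] - 1, frontier[x < dims[1]] + 1,
              frontier[y > 1] - dims[1], frontier[y < dims[2]] + dims[1],
              frontier[z > 1] - nxy, frontier[z < dims[3]] + nxy)
    nbrs <- unique(nbrs[open[nbrs] & !is.finite(steps[nbrs])])
    steps[nbrs] <- lev
    frontier <- nbrs
  }
  array(steps, dims)
}

sasd_distances <- function(grid, from, to_matrix) {
  src <- nearest_open_cell(grid, from)
  if (is.null(src)) return(rep(Inf, nrow(to_matrix)))
  steps <- grid_bfs(grid, src$cell)
  vapply(seq_len(nrow(to_matrix)), function(k) {
    dst <- nearest_open_cell(grid, to_matrix[k, ])
    if (is.null(dst)) return(Inf)
    st <- steps[dst$cell[1], dst$cell[2], dst$cell[3]]
    if (!is.finite(st)) return(Inf)
    src$dist + st * grid$spacing + dst$dist
  }, numeric(1))
}

#' Solvent-accessible surface distance between two points
#'
#' Shortest 6-connected grid path through solvent-accessible space between
#' two positions, plus the straight segments attaching each endpoint to its
#' nearest accessible cell. Always at least the Euclidean distance.
#'
#' @param atoms n x 3 matrix of atom positions defining the excluded volume.
#' @param a,b endpoint coordinates (length-3).
#' @param spacing,probe,atom_radius grid parameters as in
#'   [enumerate_theoretical()].
#' @return distance in Angstrom (Inf when an endpoint is buried).
#' @export
sasd_distance <- function(atoms, a, b, spacing = 1, probe = 1.4,
                          atom_radius = 1.7) {
  grid <- sasd_grid(as.matrix(atoms), spacing, probe, atom_radius,
                    cover = rbind(a, b))
  sasd_distances(grid, a, matrix(b, nrow = 1))
}
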