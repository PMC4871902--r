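#' Generate a synthetic rigid subunit
#'
#' Builds a C-alpha trace with ideal 3.8 A virtual bonds, either as an
#' alpha-helix (deterministic) or a compact self-avoiding random walk
#' ("globule"), with designated lysines and the first residue flagged as
#' N-terminus. Deterministic per seed.
#'
#' @param n_residues number of residues (>= 5).
#' @param shape `"helix"` or `"globule"`.
#' @param lysine_positions residue numbers carrying lysines (default: every
#'   fifth residue starting at 3).
#' @param seed integer seed (globule shape draws from the RNG).
#' @param chain_id chain identifier (default "A").
#' @return a [subunit_model()].
#' @export
make_subunit <- function(n_residues, shape = c("helix", "globule"),
                         lysine_positions = NULL, seed = 1, chain_id = "A") {
  shape <- match.arg(shape)
  stopifnot(n_residues >= 5)
  if (is.null(lysine_positions)) {
    lysine_positions <- seq(3, n_residues, by = 5)
  }
  set.seed(seed)
  if (shape == "helix") {
    rise <- 1.5
    turn <- 100 * pi / 180
    radius <- sqrt(3.8^2 - rise^2) / (2 * sin(turn / 2))
    i <- seq_len(n_residues) - 1
    xyz <- cbind(radius * cos(i * turn), radius * sin(i * turn), rise * i)
  } else {
    xyz <- globule_walk(n_residues)
  }
  resid <- rep("ALA", n_residues)
  resid[lysine_positions] <- "LYS"
  subunit_model(chain_id, seq_len(n_residues), resid, xyz)
}

globule_walk <- function(n, step = 3.8, min_sep = 3.5, max_tries = 2000) {
  for (attempt in seq_len(max_tries)) {
    xyz <- matrix(0, n, 3)
    ok <- TRUE
    for (i in 2:n) {
      placed <- FALSE
      for (k in 1:60) {
        dir <- stats::rnorm(3)
        # bias the walk back towards the centroid for compactness
        dir <- dir / sqrt(sum(dir^2)) +
          0.35 * (colMeans(xyz[1:(i - 1), , drop = FALSE]) - xyz[i - 1, ]) /
          max(1, sqrt(sum((colMeans(xyz[1:(i - 1), , drop = FALSE]) -
                             xyz[i - 1, ])^2)))
        dir <- dir / sqrt(sum(dir^2))
        cand <- xyz[i - 1, ] + step * dir
        if (i <= 2 || all(rowSums(sweep(xyz[1:(i - 2), , drop = FALSE], 2,
                                        cand)^2) >= min_sep^2)) {
          xyz[i, ] <- cand
          placed <- TRUE
          break
        }
      }
      if (!placed) { ok <- FALSE; break }
    }
    if (ok) return(xyz)
  }
  stop("could not build a self-avoiding chain at the requested density")
}

contact_pose <- function(fixed, mobile, direction, rotation,
                         min_gap = 4.5, max_gap = 8) {
  # slide the rotated mobile subunit along `direction` towards the fixed
  # subunit until just outside clash range
  M0 <- transform_xyz(mobile$xyz, rotation)
  M0 <- sweep(M0, 2, colMeans(M0))
  comf <- colMeans(fixed$xyz)
  r_hi <- bounding_radius(fixed$xyz) + bounding_radius(mobile$xyz) + 5
  for (r in seq(r_hi, 2, by = -0.5)) {
    M <- sweep(M0, 2, comf + r * direction, "+")
    mind <- sqrt(min(cross_dist2(fixed$xyz, M)))
    if (mind < min_gap) break
    if (mind <= max_gap) {
      t <- comf + r * direction - as.numeric(quat_to_mat(rotation$q) %*%
                                               colMeans(mobile$xyz))
      return(rigid_transform(rotation$q, t))
    }
  }
  NULL
}

c2_pose <- function(fixed, mobile, min_gap = 4.5, max_gap = 8) {
  # a two-fold image of the fixed subunit: rotate 180 degrees about an axis
  # displaced from the centre of mass, then check the contact gap
  u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
  v <- stats::rnorm(3); v <- v - sum(v * u) * u; v <- v / sqrt(sum(v^2))
  comf <- colMeans(fixed$xyz)
  for (s in seq(2, bounding_radius(fixed$xyz) + 10, by = 0.25)) {
    rt <- rt_axis_angle(u, pi, center = comf + s * v)
    M <- transform_xyz(mobile$xyz, rt)
    mind <- sqrt(min(cross_dist2(fixed$xyz, M)))
    if (mind >= min_gap && mind <= max_gap) return(rt)
    if (mind > max_gap) return(NULL)  # gap only grows with s
  }
  NULL
}

#' Plant binding poses and a consistent cross-link set
#'
#' Generates `k_poses` clash-free poses of the mobile subunit against the
#' fixed subunit and, for each pose, samples lysine-lysine cross-links whose
#' C-alpha distance in that pose is within `bound - margin`. With
#' `exclusive = TRUE` every link additionally violates its bound by at least
#' `excl_margin` in every other pose, so the full link set cannot be
#' satisfied by fewer than `k_poses` conformers; both properties are
#' verified at generation. In homodimer mode the mobile subunit is a copy of
#' the fixed one, each pose is an exact two-fold image (zero C2 energy), and
#' records allow chain-swapped satisfaction.
#'
#' @param fixed,mobile `subunit_model` objects (mobile ignored in homodimer
#'   mode, where a chain-B copy of `fixed` is used).
#' @param k_poses number of planted poses (>= 1).
#' @param links_per_pose cross-links sampled per pose (default 4).
#' @param linker `"BS3"` or `"BS2G"`.
#' @param exclusive enforce mutual exclusivity between poses (default: when
#'   `k_poses > 1`).
#' @param seed integer seed.
#' @param margin satisfiability margin below the bound, A (default 2).
#' @param excl_margin exclusivity margin above the bound, A (default 10).
#' @param homodimer generate a C2-symmetric homodimer system.
#' @param max_tries pose-set retries before giving up (default 400).
#' @return list of class `planted_system`: `fixed`, `mobile`, `true_poses`
#'   (list of [rigid_transform()]), `links` (cross-link tibble), `params`.
#' @export
plant_poses_and_links <- function(fixed, mobile = NULL, k_poses = 1,
                                  links_per_pose = 4, linker = "BS3",
                                  exclusive = k_poses > 1, seed = 1,
                                  margin = 2, excl_margin = 10,
                                  homodimer = FALSE, max_tries = 400) {
  stopifnot(k_poses >= 1, links_per_pose >= 1)
  reg <- linker_registry()
  bound <- reg$bound_res_res[reg$name == linker]
  if (length(bound) == 0 || reg$chemistry[reg$name == linker] != "amine") {
    stop("planted systems use amine linkers (BS3 or BS2G)")
  }
  if (homodimer) {
    mobile <- fixed
    mobile$chain_id <- "B"
  }
  stopifnot(!is.null(mobile))
  lys_f <- which(fixed$resid == "LYS")
  lys_m <- which(mobile$resid == "LYS")
  if (length(lys_f) == 0 || length(lys_m) == 0) stop("no lysines to link")
  set.seed(seed)

  for (try in seq_len(max_tries)) {
    poses <- vector("list", k_poses)
    bad <- FALSE
    for (p in seq_len(k_poses)) {
      pose <- NULL
      for (k in 1:40) {
        pose <- if (homodimer) {
          c2_pose(fixed, mobile)
        } else {
          u <- stats::rnorm(3)
          contact_pose(fixed, mobile, u / sqrt(sum(u^2)), rt_random_rotation())
        }
        if (!is.null(pose)) break
      }
      if (is.null(pose)) { bad <- TRUE; break }
      poses[[p]] <- pose
    }
    if (bad) next

    # lysine-lysine distance tables per pose
    D <- lapply(poses, function(rt) {
      M <- transform_xyz(mobile$xyz, rt)
      sqrt(cross_dist2(fixed$xyz[lys_f, , drop = FALSE],
                       M[lys_m, , drop = FALSE]))
    })
    picked <- list()
    ok <- TRUE
    for (p in seq_len(k_poses)) {
      cand <- which(D[[p]] <= bound - margin, arr.ind = TRUE)
      if (exclusive && k_poses > 1 && nrow(cand) > 0) {
        keep <- vapply(seq_len(nrow(cand)), function(i) {
          all(vapply(setdiff(seq_len(k_poses), p), function(q) {
            D[[q]][cand[i, 1], cand[i, 2]] >= bound + excl_margin
          }, logical(1)))
        }, logical(1))
        cand <- cand[keep, , drop = FALSE]
      }
      if (nrow(cand) < links_per_pose) { ok <- FALSE; break }
      # spread links over distinct anchor residues on both subunits so the
      # pose is caged (affinely independent restraints), preferring the
      # more informative near-bound pairs
      d_cand <- D[[p]][cand]
      ord <- order(-d_cand + stats::runif(length(d_cand), 0, 4))
      sel <- matrix(0L, 0, 2)
      for (pass in 1:2) {
        for (i in ord) {
          if (nrow(sel) >= links_per_pose) break
          dup_m <- cand[i, 2] %in% sel[, 2]
          dup_f <- cand[i, 1] %in% sel[, 1]
          if (pass == 1 && (dup_m || dup_f)) next
          if (any(sel[, 1] == cand[i, 1] & sel[, 2] == cand[i, 2])) next
          sel <- rbind(sel, cand[i, , drop = FALSE])
        }
      }
      picked[[p]] <- sel
    }
    if (!ok) next

    if (exclusive && k_poses > 1) {
      # certificate that no single conformer can cover two poses: for each
      # pose pair there must be one link from each whose fixed anchors are
      # farther apart than 2*bound plus the rigid mobile-anchor separation
      # (triangle inequality then forbids satisfying both at once)
      certified <- TRUE
      for (p in seq_len(k_poses - 1)) for (q in (p + 1):k_poses) {
        found <- FALSE
        for (i in seq_len(nrow(picked[[p]]))) for (j in seq_len(nrow(picked[[q]]))) {
          fsep <- sqrt(sum((fixed$xyz[lys_f[picked[[p]][i, 1]], ] -
                              fixed$xyz[lys_f[picked[[q]][j, 1]], ])^2))
          msep <- sqrt(sum((mobile$xyz[lys_m[picked[[p]][i, 2]], ] -
                              mobile$xyz[lys_m[picked[[q]][j, 2]], ])^2))
          if (fsep > 2 * bound + msep + 1) { found <- TRUE; break }
        }
        if (!found) { certified <- FALSE; break }
      }
      if (!certified) next
    }

    links <- purrr::map_dfr(seq_len(k_poses), function(p) {
      tibble::tibble(
        chain_a = fixed$chain_id,
        res_a = fixed$resno[lys_f[picked[[p]][, 1]]],
        kind_a = "lysine",
        chain_b = mobile$chain_id,
        res_b = mobile$resno[lys_m[picked[[p]][, 2]]],
        kind_b = "lysine",
        n_bs2g = if (linker == "BS2G") 2L else 0L,
        n_bs3 = if (linker == "BS3") 2L else 0L,
        n_pdh = 0L, total = 2L, best_evalue = 1e-12,
        pose = p)
    })
    links <- links[!duplicated(links[, c("res_a", "res_b")]), , drop = FALSE]
    links$swap_allowed <- homodimer
    sys <- structure(list(fixed = fixed, mobile = mobile, true_poses = poses,
                          links = links,
                          params = list(linker = linker, bound = bound,
                                        margin = margin,
                                        excl_margin = excl_margin,
                                        exclusive = exclusive, seed = seed,
                                        homodimer = homodimer)),
                     class = "planted_system")
    verify_planted(sys)
    return(sys)
  }
  stop("could not plant ", k_poses, " mutually exclusive pose(s) after ",
       max_tries, " tries")
}

verify_planted <- function(sys) {
  bound <- sys$params$bound
  for (li in seq_len(nrow(sys$links))) {
    rec <- sys$links[li, ]
    d <- vapply(sys$true_poses, function(rt) {
      M <- transform_xyz(sys$mobile$xyz, rt)
      a <- sys$fixed$xyz[match(rec$res_a, sys$fixed$resno), ]
      sqrt(sum((a - M[match(rec$res_b, sys$mobile$resno), ])^2))
    }, numeric(1))
    if (!any(d <= bound - sys$params$margin)) {
      stop("planted link not satisfied by any pose")
    }
    if (sys$params$exclusive && length(d) > 1) {
      if (sum(d <= bound + sys$params$excl_margin) > 1) {
        stop("planted link not exclusive to its pose")
      }
    }
  }
  invisible(sys)
}

#' @export
print.planted_system <- function(x, ...) {
  cat(sprintf("<planted_system> %d pose(s), %d links (%s, bound %.0f A)%s\n",
              length(x$true_poses), nrow(x$links), x$params$linker,
              x$params$bound, if (x$params$homodimer) ", C2 homodimer" else ""))
  invisible(x)
}

#' True-pose complex model of a planted system
#'
#' @param sys a [plant_poses_and_links()] result.
#' @return a `complex_model` with one conformer per planted pose.
#' @export
planted_complex <- function(sys) {
  complex_model(sys$fixed,
                lapply(sys$true_poses, function(rt) {
                  apply_transform(sys$mobile, rt)
                }))
}
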