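#' Square-well distance restraint energy
#'
#' Zero inside the bound (inclusive), quadratic penalty `k * (d - bound)^2`
#' beyond it. This is the pseudo-energy used for every CXMS restraint.
#'
#' @param distance C-alpha distance(s), Angstrom.
#' @param bound upper bound, Angstrom.
#' @param k force constant, kcal/(mol A^2).
#' @return energy in kcal/mol (vectorized over `distance`).
#' @export
squarewell_energy <- function(distance, bound, k) {
  stopifnot(all(distance > 0), bound > 0, k >= 0)
  k * pmax(0, distance - bound)^2
}

#' Ensemble-averaged effective distance
#'
#' The inverse-sixth-power average `(mean(d_i^-6))^(-1/6)` over the
#' conformers of an ensemble. Its steep distance dependence biases the
#' average towards the conformer with the shortest distance, so a restraint
#' is satisfiable whenever one conformer is close enough: the effective
#' distance never exceeds `min(d) * N^(1/6)`.
#'
#' @param distances positive distances, one per conformer (Angstrom).
#' @return effective distance, Angstrom.
#' @export
ensemble_effective_distance <- function(distances) {
  if (length(distances) < 1 || any(!is.finite(distances)) || any(distances <= 0)) {
    stop("distances must be positive and finite")
  }
  mean(distances^-6)^(-1 / 6)
}

#' Ambiguous ensemble-averaged restraint energy
#'
#' Applies the square-well penalty to the inverse-sixth ensemble average of
#' the restraint's C-alpha distance over all conformers. For homodimer
#' records with `swap_allowed`, both chain assignments (A:i-B:j and A:j-B:i)
#' enter the average, so either may satisfy the restraint.
#'
#' @param distances distances per conformer, Angstrom.
#' @param bound upper bound, Angstrom.
#' @param k force constant, kcal/(mol A^2).
#' @param swap_distances optional distances of the chain-swapped assignment.
#' @return list with `energy` (kcal/mol), `effective_distance` and
#'   `violation` (Angstrom).
#' @export
ambiguous_cxms_energy <- function(distances, bound, k, swap_distances = NULL) {
  d_eff <- ensemble_effective_distance(c(distances, swap_distances))
  list(energy = squarewell_energy(d_eff, bound, k),
       effective_distance = d_eff,
       violation = max(0, d_eff - bound))
}

cross_dist2 <- function(A, B) {
  # squared distances between rows of A (n x 3) and rows of B (m x 3)
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  d2
}

#' Inter-subunit soft-sphere repulsion
#'
#' Soft-sphere clash penalty `sum k_rep * (r_clash - d)^2` over C-alpha pairs
#' between the fixed and the mobile subunit closer than `r_clash`. Pairs of
#' mobile conformers within an ensemble are never penalized: conformers are
#' alternative states of the same subunit and may overlap.
#'
#' @param fixed,mobile `subunit_model` objects or n x 3 coordinate matrices.
#' @param r_clash clash distance, Angstrom (default 4).
#' @param k_rep force constant, kcal/(mol A^2) (default 10).
#' @return energy in kcal/mol.
#' @export
repulsion_energy <- function(fixed, mobile, r_clash = 4, k_rep = 10) {
  F <- if (inherits(fixed, "subunit_model")) fixed$xyz else as.matrix(fixed)
  M <- if (inherits(mobile, "subunit_model")) mobile$xyz else as.matrix(mobile)
  d2 <- cross_dist2(F, M)
  close <- d2 < r_clash^2
  if (!any(close)) return(0)
  sum(k_rep * (r_clash - sqrt(d2[close]))^2)
}

best_twofold_axis <- function(A, B) {
  # closed-form best C2 operation mapping A onto B (atoms paired by row).
  # A true two-fold S(x) = R_u(pi)(x - c) + c can realize any translation
  # perpendicular to its axis u (by shifting the axis) but none along it,
  # so with centered coordinates p, q and centroid offset dc the residual is
  #   sum |p_i + q_i|^2 - u' (4 M - n dc dc') u,  M = sum (p q' + q p') / 2,
  # minimized by the leading eigenvector of (4 M - n dc dc').
  ca <- colMeans(A); cb <- colMeans(B)
  P <- sweep(A, 2, ca); Q <- sweep(B, 2, cb)
  dc <- cb - ca
  M <- (crossprod(P, Q) + crossprod(Q, P)) / 2
  e <- eigen(4 * M - nrow(A) * tcrossprod(dc), symmetric = TRUE)
  u <- e$vectors[, 1]
  msd <- max(0, (sum((P + Q)^2) - e$values[1]) / nrow(A))
  list(axis = u, rmsd = sqrt(msd), center = (ca + cb) / 2)
}

#' C2 non-crystallographic symmetry energy
#'
#' For a homodimer pair, the penalty is proportional to the RMSD between
#' subunit B and the image of subunit A under the best-fit two-fold
#' operation (axis by closed form, translation optimized); it is exactly
#' zero for a perfectly C2-symmetric pair. Atoms are paired by residue
#' number.
#'
#' @param a,b `subunit_model` objects or n x 3 C-alpha matrices (paired rows).
#' @param k_sym force constant, kcal/(mol A) (default 10).
#' @param homodimer set FALSE to signal heterodimer mode (an error: the C2
#'   term is only defined for two copies of the same protein).
#' @return energy in kcal/mol, with attribute `rmsd`.
#' @export
c2_symmetry_energy <- function(a, b, k_sym = 10, homodimer = TRUE) {
  if (!homodimer) stop("C2 symmetry energy is only defined in homodimer mode")
  A <- if (inherits(a, "subunit_model")) a$xyz else as.matrix(a)
  B <- if (inherits(b, "subunit_model")) b$xyz else as.matrix(b)
  if (inherits(a, "subunit_model") && inherits(b, "subunit_model")) {
    common <- intersect(a$resno, b$resno)
    A <- A[match(common, a$resno), , drop = FALSE]
    B <- B[match(common, b$resno), , drop = FALSE]
  }
  stopifnot(nrow(A) == nrow(B))
  fit <- best_twofold_axis(A, B)
  structure(k_sym * fit$rmsd, rmsd = fit$rmsd)
}

#' Full energy breakdown of an ensemble state
#'
#' Evaluates the CXMS (ambiguous, ensemble-averaged), inter-subunit
#' repulsion, and optional C2 symmetry terms for a complex model against a
#' set of restraints.
#'
#' @param model a `complex_model`.
#' @param restraints cross-link tibble (see [load_crosslink_table()]).
#' @param k CXMS force constant, kcal/(mol A^2).
#' @param r_clash,k_rep repulsion parameters.
#' @param homodimer apply the C2 term between the fixed subunit and each
#'   conformer.
#' @param k_sym C2 force constant.
#' @return list of class `energy_breakdown`: `cxms`, `repulsion`, `symmetry`,
#'   `total` (kcal/mol) and `per_restraint` tibble.
#' @export
energy_breakdown <- function(model, restraints, k = 30, r_clash = 4,
                             k_rep = 10, homodimer = FALSE, k_sym = 10) {
  bounds <- effective_bound(restraints)
  per <- purrr::map_dfr(seq_len(nrow(restraints)), function(i) {
    d <- restraint_distances(model, restraints[i, ])
    res <- ambiguous_cxms_energy(d$direct, bounds[i], k, d$swapped)
    tibble::tibble(restraint = i, effective_distance = res$effective_distance,
                   violation = res$violation, energy = res$energy)
  })
  rep_e <- sum(vapply(model$mobile, function(su) {
    repulsion_energy(model$fixed, su, r_clash, k_rep)
  }, numeric(1)))
  sym_e <- if (homodimer) {
    sum(vapply(model$mobile, function(su) {
      as.numeric(c2_symmetry_energy(model$fixed, su, k_sym))
    }, numeric(1)))
  } else 0
  structure(list(cxms = sum(per$energy), repulsion = rep_e, symmetry = sym_e,
                 total = sum(per$energy) + rep_e + sym_e, per_restraint = per),
            class = "energy_breakdown")
}

restraint_distances <- function(model, record) {
  ia <- match(record$res_a, model$fixed$resno)
  if (is.na(ia)) stop(sprintf("residue %d not in fixed subunit", record$res_a))
  a <- model$fixed$xyz[ia, ]
  direct <- vapply(model$mobile, function(su) {
    jb <- match(record$res_b, su$resno)
    if (is.na(jb)) stop(sprintf("residue %d not in mobile subunit", record$res_b))
    sqrt(sum((a - su$xyz[jb, ])^2))
  }, numeric(1))
  swapped <- NULL
  if ("swap_allowed" %in% names(record) && isTRUE(record$swap_allowed)) {
    ib <- match(record$res_b, model$fixed$resno)
    if (!is.na(ib)) {
      b <- model$fixed$xyz[ib, ]
      swapped <- vapply(model$mobile, function(su) {
        ja <- match(record$res_a, su$resno)
        if (is.na(ja)) return(NA_real_)
        sqrt(sum((b - su$xyz[ja, ])^2))
      }, numeric(1))
      swapped <- swapped[!is.na(swapped)]
      if (length(swapped) == 0) swapped <- NULL
    }
  }
  list(direct = direct, swapped = swapped)
}

#' @export
print.energy_breakdown <- function(x, ...) {
  cat(sprintf("<energy_breakdown> total %.3f kcal/mol (cxms %.3f, repulsion %.3f, symmetry %.3f)\n",
              x$total, x$cxms, x$repulsion, x$symmetry))
  invisible(x)
}
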