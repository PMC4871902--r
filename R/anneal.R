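kB <- 0.0019872041  # kcal/(mol K)

#' Simulated-annealing schedule
#'
#' Temperature ladder, force-constant ramp and move-size policy for one
#' rigid-body refinement run. Temperature cools geometrically from `t_start`
#' to `t_end` while the CXMS force constant ramps from `k_start` to `k_end`
#' and the Monte-Carlo move sizes shrink geometrically; a final
#' zero-temperature quench polishes residual violations.
#'
#' @param t_start,t_end bath temperature, K (defaults 3000 and 298).
#' @param n_stages number of annealing stages (default 50).
#' @param k_start,k_end CXMS force constant ramp, kcal/(mol A^2) (1 to 30).
#' @param steps_per_stage Monte-Carlo steps per stage per conformer (default 200).
#' @param trans_start,trans_end translation move sigma, A (5 to 0.2).
#' @param rot_start,rot_end rotation move sigma, degrees (30 to 1).
#' @param quench_steps downhill-only polishing steps per conformer (default 300).
#' @return list of class `anneal_schedule` with per-stage vectors.
#' @export
anneal_schedule <- function(t_start = 3000, t_end = 298, n_stages = 50,
                            k_start = 1, k_end = 30, steps_per_stage = 200,
                            trans_start = 5, trans_end = 0.2,
                            rot_start = 30, rot_end = 1,
                            quench_steps = 300) {
  stopifnot(t_start > t_end, t_end > 0, n_stages >= 2, k_start <= k_end)
  g <- function(a, b) a * (b / a)^((seq_len(n_stages) - 1) / (n_stages - 1))
  structure(list(
    temperature = g(t_start, t_end),
    k = g(k_start, k_end),
    trans_sigma = g(trans_start, trans_end),
    rot_sigma = g(rot_start, rot_end) * pi / 180,
    steps_per_stage = steps_per_stage,
    quench_steps = quench_steps
  ), class = "anneal_schedule")
}

bounding_radius <- function(xyz) {
  com <- colMeans(xyz)
  sqrt(max(rowSums(sweep(xyz, 2, com)^2)))
}

#' Random initial pose for the mobile subunit
#'
#' Draws a uniform (Haar) random orientation and places the mobile subunit's
#' center of mass uniformly on a shell around the fixed subunit at
#' `R_fixed + R_mobile + margin`, guaranteeing a clash-free start away from
#' the fixed subunit. Uses the current RNG state.
#'
#' @param mobile,fixed `subunit_model` objects.
#' @param margin shell clearance beyond the bounding radii, A (default 5).
#' @return a [rigid_transform()] taking the mobile subunit to its start pose.
#' @export
random_initial_pose <- function(mobile, fixed, margin = 5) {
  rot <- rt_random_rotation()
  u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
  r <- bounding_radius(fixed$xyz) + bounding_radius(mobile$xyz) + margin
  target <- colMeans(fixed$xyz) + r * u
  com_rot <- as.numeric(quat_to_mat(rot$q) %*% colMeans(mobile$xyz))
  rigid_transform(rot$q, target - com_rot)
}

prep_restraints <- function(fixed, mobile, restraints) {
  bounds <- effective_bound(restraints)
  ia <- match(restraints$res_a, fixed$resno)
  jb <- match(restraints$res_b, mobile$resno)
  if (any(is.na(ia)) || any(is.na(jb))) {
    stop("restraint residues not resolvable: ",
         paste(c(restraints$res_a[is.na(ia)], restraints$res_b[is.na(jb)]),
               collapse = ", "))
  }
  swap <- if ("swap_allowed" %in% names(restraints)) {
    restraints$swap_allowed
  } else rep(FALSE, nrow(restraints))
  ib <- match(restraints$res_b, fixed$resno)
  ja <- match(restraints$res_a, mobile$resno)
  swap <- swap & !is.na(ib) & !is.na(ja)
  list(bounds = bounds,
       Fa = fixed$xyz[ia, , drop = FALSE],
       jb = jb,
       swap = swap,
       Fb = fixed$xyz[ifelse(is.na(ib), 1L, ib), , drop = FALSE],
       ja = ifelse(is.na(ja), 1L, ja),
       m_per_conf = 1L + as.integer(swap))
}

# inverse-sixth contributions of one conformer's coordinates to each restraint
d6_column <- function(X, rp) {
  d2 <- rowSums((rp$Fa - X[rp$jb, , drop = FALSE])^2)
  col <- d2^-3
  if (any(rp$swap)) {
    s <- rp$swap
    d2s <- rowSums((rp$Fb[s, , drop = FALSE] - X[rp$ja[s], , drop = FALSE])^2)
    col[s] <- col[s] + d2s^-3
  }
  col
}

cxms_violations <- function(S, m_total, bounds) {
  d_eff <- (S / m_total)^(-1 / 6)
  pmax(0, d_eff - bounds)
}

c2_energy_xyz <- function(F, X, k_sym) {
  as.numeric(c2_symmetry_energy(F, X, k_sym))
}

#' One rigid-body simulated-annealing run
#'
#' Metropolis Monte-Carlo refinement of `n_conformers` rigid copies of the
#' mobile subunit against ambiguous ensemble-averaged CXMS restraints, with
#' inter-subunit soft-sphere repulsion (conformer-conformer contacts are not
#' penalized) and an optional C2 symmetry term per conformer. Per stage the
#' bath temperature, the CXMS force constant, and the move sizes follow the
#' schedule; a downhill-only quench finishes the run. Uses the current RNG
#' state; seed upstream for reproducibility.
#'
#' @param fixed,mobile `subunit_model` objects; `mobile` is replicated.
#' @param restraints cross-link tibble.
#' @param schedule an [anneal_schedule()].
#' @param n_conformers ensemble size N (default 1).
#' @param homodimer apply the C2 term between fixed subunit and each conformer.
#' @param r_clash,k_rep,k_sym energy parameters.
#' @param margin initial-placement shell clearance, A.
#' @return a `complex_model`; `provenance` carries final violations, energies
#'   and the per-stage trace (temperature, k, energy, acceptance ratio).
#' @export
anneal <- function(fixed, mobile, restraints, schedule = anneal_schedule(),
                   n_conformers = 1, homodimer = FALSE,
                   r_clash = 4, k_rep = 10, k_sym = 10, margin = 5) {
  stopifnot(nrow(restraints) >= 1)
  rp <- prep_restraints(fixed, mobile, restraints)
  F <- fixed$xyz
  N <- n_conformers
  m_total <- rp$m_per_conf * N  # values per restraint in the average: (1 or 2) * N

  X <- vector("list", N)
  C6 <- matrix(0, nrow(restraints), N)
  rep_e <- numeric(N)
  sym_e <- numeric(N)
  for (c in seq_len(N)) {
    rt0 <- random_initial_pose(mobile, fixed, margin)
    X[[c]] <- transform_xyz(mobile$xyz, rt0)
    C6[, c] <- d6_column(X[[c]], rp)
    rep_e[c] <- repulsion_energy(F, X[[c]], r_clash, k_rep)
    sym_e[c] <- if (homodimer) c2_energy_xyz(F, X[[c]], k_sym) else 0
  }
  S <- rowSums(C6)

  n_stages <- length(schedule$temperature)
  trace <- vector("list", n_stages)
  for (s in seq_len(n_stages)) {
    temp <- schedule$temperature[s]; kk <- schedule$k[s]
    st <- schedule$trans_sigma[s]; sr <- schedule$rot_sigma[s]
    beta <- 1 / (kB * temp)
    viol <- cxms_violations(S, m_total, rp$bounds)
    e_cxms <- kk * sum(viol^2)
    acc <- 0L; tot <- 0L
    for (step in seq_len(schedule$steps_per_stage)) {
      for (c in seq_len(N)) {
        tot <- tot + 1L
        Xc <- X[[c]]
        axis <- stats::rnorm(3); axis <- axis / sqrt(sum(axis^2))
        ang <- stats::rnorm(1, 0, sr)
        qs <- c(cos(ang / 2), sin(ang / 2) * axis)
        Rs <- quat_to_mat(qs)
        com <- colMeans(Xc)
        Xn <- sweep(sweep(Xc, 2, com) %*% t(Rs), 2,
                    com + stats::rnorm(3, 0, st), "+")
        col_n <- d6_column(Xn, rp)
        S_n <- S - C6[, c] + col_n
        e_cxms_n <- kk * sum(cxms_violations(S_n, m_total, rp$bounds)^2)
        rep_n <- repulsion_energy(F, Xn, r_clash, k_rep)
        sym_n <- if (homodimer) c2_energy_xyz(F, Xn, k_sym) else 0
        dE <- (e_cxms_n - e_cxms) + (rep_n - rep_e[c]) + (sym_n - sym_e[c])
        if (!is.finite(dE)) stop("non-finite energy change during annealing")
        if (dE <= 0 || stats::runif(1) < exp(-beta * dE)) {
          X[[c]] <- Xn; C6[, c] <- col_n; S <- S_n
          e_cxms <- e_cxms_n; rep_e[c] <- rep_n; sym_e[c] <- sym_n
          acc <- acc + 1L
        }
      }
    }
    trace[[s]] <- c(stage = s, temperature = temp, k = kk,
                    e_cxms = e_cxms, e_rep = sum(rep_e), e_sym = sum(sym_e),
                    acceptance = acc / tot)
  }

  # zero-temperature quench at the final force constant and move sizes
  kk <- schedule$k[n_stages]
  st <- schedule$trans_sigma[n_stages]; sr <- schedule$rot_sigma[n_stages]
  e_cxms <- kk * sum(cxms_violations(S, m_total, rp$bounds)^2)
  for (step in seq_len(schedule$quench_steps)) {
    for (c in seq_len(N)) {
      Xc <- X[[c]]
      axis <- stats::rnorm(3); axis <- axis / sqrt(sum(axis^2))
      ang <- stats::rnorm(1, 0, sr)
      qs <- c(cos(ang / 2), sin(ang / 2) * axis)
      com <- colMeans(Xc)
      Xn <- sweep(sweep(Xc, 2, com) %*% t(quat_to_mat(qs)), 2,
                  com + stats::rnorm(3, 0, st), "+")
      col_n <- d6_column(Xn, rp)
      S_n <- S - C6[, c] + col_n
      e_cxms_n <- kk * sum(cxms_violations(S_n, m_total, rp$bounds)^2)
      rep_n <- repulsion_energy(F, Xn, r_clash, k_rep)
      sym_n <- if (homodimer) c2_energy_xyz(F, Xn, k_sym) else 0
      dE <- (e_cxms_n - e_cxms) + (rep_n - rep_e[c]) + (sym_n - sym_e[c])
      if (dE < 0) {
        X[[c]] <- Xn; C6[, c] <- col_n; S <- S_n
        e_cxms <- e_cxms_n; rep_e[c] <- rep_n; sym_e[c] <- sym_n
      }
    }
  }

  viol <- cxms_violations(S, m_total, rp$bounds)
  conformers <- lapply(X, function(Xc) {
    su <- mobile
    su$xyz <- Xc
    if (!is.null(su$backbone)) {
      fitted <- kabsch(mobile$xyz, Xc)
      b <- as.matrix(su$backbone[, c("x", "y", "z")]) %*% t(fitted$R)
      b <- sweep(b, 2, fitted$t, "+")
      su$backbone$x <- b[, 1]; su$backbone$y <- b[, 2]; su$backbone$z <- b[, 3]
    }
    su
  })
  trace_df <- tibble::as_tibble(do.call(rbind, trace))
  complex_model(fixed, conformers, provenance = list(
    violations = viol,
    effective_distances = (S / m_total)^(-1 / 6),
    bounds = rp$bounds,
    e_cxms = kk * sum(viol^2),
    e_rep = sum(rep_e),
    e_sym = sum(sym_e),
    trace = trace_df
  ))
}

#' Repeated refinement runs with model selection
#'
#' Repeats [anneal()] `n_runs` times from independent random starting poses
#' (per-run seed = `seed + run index`, so the batch is reproducible and
#' independent of run order) and keeps the models with no restraint
#' violation beyond `viol_tol` and no steric clash beyond `clash_tol`.
#'
#' @param fixed,mobile `subunit_model` objects.
#' @param restraints cross-link tibble.
#' @param n_runs number of independent runs (default 512).
#' @param n_conformers ensemble size N.
#' @param seed integer; per-run seeds are `seed + 1 .. seed + n_runs`.
#' @param schedule an [anneal_schedule()].
#' @param viol_tol violation tolerance for "no violations", A (default 0.1).
#' @param clash_tol repulsion-energy tolerance, kcal/mol (default 1).
#' @param homodimer,r_clash,k_rep,k_sym,margin passed to [anneal()].
#' @return list of class `refine_batch`: `models` (accepted `complex_model`s),
#'   `report` (one row per run), and the selection settings.
#' @export
run_batch <- function(fixed, mobile, restraints, n_runs = 512,
                      n_conformers = 1, seed = 1,
                      schedule = anneal_schedule(), viol_tol = 0.1,
                      clash_tol = 1, homodimer = FALSE,
                      r_clash = 4, k_rep = 10, k_sym = 10, margin = 5) {
  stopifnot(n_runs >= 1, n_conformers >= 1)
  runs <- lapply(seq_len(n_runs), function(i) {
    set.seed(seed + i)
    m <- anneal(fixed, mobile, restraints, schedule, n_conformers,
                homodimer = homodimer, r_clash = r_clash, k_rep = k_rep,
                k_sym = k_sym, margin = margin)
    m$provenance$run <- i
    m$provenance$seed <- seed + i
    m
  })
  report <- purrr::map_dfr(runs, function(m) {
    p <- m$provenance
    tibble::tibble(run = p$run, seed = p$seed,
                   max_violation = max(p$violations),
                   mean_violation = mean(p$violations),
                   n_satisfied = sum(p$violations <= viol_tol),
                   e_rep = p$e_rep, e_sym = p$e_sym,
                   accepted = max(p$violations) <= viol_tol & p$e_rep <= clash_tol)
  })
  models <- runs[report$accepted]
  if (length(models) == 0) {
    warning(sprintf(
      "no accepted models in %d runs; max-violation range %.2f-%.2f A (see report)",
      n_runs, min(report$max_violation), max(report$max_violation)))
  }
  structure(list(models = models, report = report, viol_tol = viol_tol,
                 clash_tol = clash_tol, n_conformers = n_conformers,
                 n_restraints = nrow(restraints), seed = seed),
            class = "refine_batch")
}

#' @export
print.refine_batch <- function(x, ...) {
  cat(sprintf("<refine_batch> %d/%d runs accepted (N = %d, %d restraints)\n",
              length(x$models), nrow(x$report), x$n_conformers, x$n_restraints))
  invisible(x)
}
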