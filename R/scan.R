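batch_violation_stats <- function(batch, viol_tol) {
  # per-model mean-over-restraints violation; falls back to the best
  # (lowest-violation) models when no model passed selection
  models <- batch$models
  fallback <- length(models) == 0
  if (fallback) {
    ord <- order(batch$report$mean_violation)
    idx <- ord[seq_len(min(10, length(ord)))]
    stats_mean <- batch$report$mean_violation[idx]
    best_sat <- max(batch$report$n_satisfied[idx])
  } else {
    per_model <- vapply(models, function(m) mean(m$provenance$violations),
                        numeric(1))
    stats_mean <- per_model
    best_sat <- max(vapply(models, function(m) {
      sum(m$provenance$violations <= viol_tol)
    }, integer(1)))
  }
  list(average_violation = mean(stats_mean), n_satisfied = best_sat,
       n_accepted = length(models))
}

#' Scan the ensemble size N
#'
#' Runs [run_batch()] for each ensemble size from 1 to `n_max` and reports,
#' per N, the average restraint violation (mean over restraints within a
#' model, then over accepted models; the ten lowest-violation models are
#' used when none is accepted), the number of satisfied restraints in the
#' best model, and the accepted-model count. The chosen ensemble size is the
#' smallest N at which every restraint is satisfied — the minimal ensemble
#' collectively accounting for the cross-links.
#'
#' @param fixed,mobile `subunit_model` objects.
#' @param restraints cross-link tibble.
#' @param n_max largest ensemble size to try.
#' @param n_runs runs per N (default 64).
#' @param seed base seed; N-specific batches use `seed + 1000 * N`.
#' @param schedule an [anneal_schedule()].
#' @param viol_tol,clash_tol,homodimer,... passed to [run_batch()].
#' @return list of class `ensemble_scan`: `per_n` tibble, `chosen_n` (NA when
#'   no N in range satisfies all restraints), and the batches.
#' @export
scan_ensemble_size <- function(fixed, mobile, restraints, n_max,
                               n_runs = 64, seed = 1,
                               schedule = anneal_schedule(),
                               viol_tol = 0.1, clash_tol = 1,
                               homodimer = FALSE, ...) {
  stopifnot(n_max >= 1)
  batches <- lapply(seq_len(n_max), function(N) {
    run_batch(fixed, mobile, restraints, n_runs = n_runs, n_conformers = N,
              seed = seed + 1000L * N, schedule = schedule,
              viol_tol = viol_tol, clash_tol = clash_tol,
              homodimer = homodimer, ...)
  })
  per_n <- purrr::map_dfr(seq_len(n_max), function(N) {
    st <- batch_violation_stats(batches[[N]], viol_tol)
    tibble::tibble(n_conformers = N,
                   average_violation = st$average_violation,
                   n_satisfied = st$n_satisfied,
                   n_accepted = st$n_accepted)
  })
  full <- which(per_n$n_satisfied == nrow(restraints) & per_n$n_accepted > 0)
  chosen <- if (length(full) > 0) min(full) else NA_integer_
  structure(list(per_n = per_n, chosen_n = chosen, batches = batches,
                 n_restraints = nrow(restraints)),
            class = "ensemble_scan")
}

#' @export
print.ensemble_scan <- function(x, ...) {
  cat(sprintf("<ensemble_scan> %d restraints; chosen N = %s\n",
              x$n_restraints,
              if (is.na(x$chosen_n)) "none in range" else x$chosen_n))
  print(x$per_n)
  invisible(x)
}

#' Flag non-contributing conformers (over-fitting diagnostic)
#'
#' A conformer is non-contributing in a model when removing it still leaves
#' every restraint's ensemble-averaged effective distance within its bound:
#' the extra conformer merely scatters around without accounting for any
#' cross-link. Also reports the positional spread of each conformer slot
#' (mean pairwise C-alpha RMSD across models, fixed frames already shared).
#'
#' @param models list of accepted `complex_model`s (N >= 2), e.g. from
#'   [run_batch()].
#' @param restraints cross-link tibble.
#' @param viol_tol violation tolerance, A.
#' @return list with `per_conformer` tibble (model, conformer, contributing)
#'   and `slot_spread` tibble (conformer, rmsd_spread).
#' @export
detect_overfitting <- function(models, restraints, viol_tol = 0.1) {
  if (inherits(models, "refine_batch")) models <- models$models
  if (inherits(models, "complex_model")) models <- list(models)
  stopifnot(length(models) >= 1)
  N <- length(models[[1]]$mobile)
  bounds <- effective_bound(restraints)
  per <- purrr::map_dfr(seq_along(models), function(mi) {
    m <- models[[mi]]
    dists <- lapply(seq_len(nrow(restraints)), function(i) {
      d <- restraint_distances(m, restraints[i, ])
      matrix(c(d$direct, d$swapped), ncol = N, byrow = TRUE)
    })
    contributing <- vapply(seq_len(N), function(c) {
      if (N == 1) return(TRUE)
      ok <- vapply(seq_along(dists), function(i) {
        rest <- as.numeric(dists[[i]][, -c, drop = FALSE])
        ensemble_effective_distance(rest) <= bounds[i] + viol_tol
      }, logical(1))
      !all(ok)  # removing conformer c breaks at least one restraint
    }, logical(1))
    tibble::tibble(model = mi, conformer = seq_len(N),
                   contributing = contributing)
  })
  spread <- purrr::map_dfr(seq_len(N), function(c) {
    coords <- lapply(models, function(m) m$mobile[[c]]$xyz)
    if (length(coords) < 2) {
      return(tibble::tibble(conformer = c, rmsd_spread = 0))
    }
    pairs <- utils::combn(length(coords), 2)
    rms <- apply(pairs, 2, function(p) {
      sqrt(mean(rowSums((coords[[p[1]]] - coords[[p[2]]])^2)))
    })
    tibble::tibble(conformer = c, rmsd_spread = mean(rms))
  })
  list(per_conformer = per, slot_spread = spread)
}

#' Jackknife back-calculation of held-out cross-links
#'
#' Leave-one-out cross-validation of a restraint set: for each cross-link,
#' the complex is refined against the remaining links and the held-out
#' C-alpha (effective) distance is measured over the accepted models. A
#' held-out distance within its bound means the link is redundantly encoded
#' by the others; a violated one marks a link carrying unique structural
#' information.
#'
#' @param fixed,mobile `subunit_model` objects.
#' @param restraints cross-link tibble with at least 2 rows.
#' @param n_runs runs per fold (default 32).
#' @param seed base seed; fold f uses `seed + 100 * f`.
#' @param schedule,n_conformers,... passed to [run_batch()].
#' @return tibble: one row per restraint with the held-out distance
#'   distribution (mean, sd), its bound, the satisfied fraction of accepted
#'   models, and a `failed` flag for folds with no accepted model.
#' @export
jackknife_backcalc <- function(fixed, mobile, restraints, n_runs = 32,
                               seed = 1, schedule = anneal_schedule(),
                               n_conformers = 1, ...) {
  stopifnot(nrow(restraints) >= 2)
  bounds <- effective_bound(restraints)
  purrr::map_dfr(seq_len(nrow(restraints)), function(f) {
    batch <- tryCatch(
      suppressWarnings(
        run_batch(fixed, mobile, restraints[-f, , drop = FALSE],
                  n_runs = n_runs, n_conformers = n_conformers,
                  seed = seed + 100L * f, schedule = schedule, ...)),
      error = function(e) NULL)
    if (is.null(batch) || length(batch$models) == 0) {
      return(tibble::tibble(restraint = f, bound = bounds[f],
                            mean_distance = NA_real_, sd_distance = NA_real_,
                            satisfied_fraction = NA_real_, n_models = 0L,
                            failed = TRUE))
    }
    held <- vapply(batch$models, function(m) {
      d <- restraint_distances(m, restraints[f, ])
      ensemble_effective_distance(c(d$direct, d$swapped))
    }, numeric(1))
    tibble::tibble(restraint = f, bound = bounds[f],
                   mean_distance = mean(held), sd_distance = stats::sd(held),
                   satisfied_fraction = mean(held <= bounds[f]),
                   n_models = length(held), failed = FALSE)
  })
}
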