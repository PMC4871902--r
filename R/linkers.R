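#' Cross-linker registry
#'
#' Maximum C-alpha to C-alpha spans (fully extended linker plus side chains)
#' for the three supported reagents. BS3 and BS2G are amine-reactive (lysine
#' side chains and the protein N-terminus); PDH is carboxylate-reactive
#' (glutamate/aspartate side chains), with no distinct N-terminal bound.
#'
#' @return tibble with columns `name`, `chemistry`, `bound_res_res`,
#'   `bound_nterm_res` (Angstrom).
#' @export
linker_registry <- function() {
  tibble::tibble(
    name = c("BS3", "BS2G", "PDH"),
    chemistry = c("amine", "amine", "carboxylate"),
    bound_res_res = c(24, 20, 22),
    bound_nterm_res = c(19, 15, NA_real_)
  )
}

amine_kinds <- c("lysine", "n_terminus")
acidic_kinds <- c("glutamate", "aspartate")
known_kinds <- c(amine_kinds, acidic_kinds)

#' Effective distance bound for cross-link records
#'
#' The C-alpha upper bound enforced in refinement. For amine cross-links the
#' tighter BS2G bound applies whenever the link was observed with BS2G
#' (alone or together with BS3); the BS3 bound applies to BS3-only links.
#' Links involving a protein N-terminus use the shorter N-terminal bounds
#' (15 A BS2G, 19 A BS3). PDH links between acidic residues are bounded at
#' 22 A.
#'
#' @param records cross-link tibble (see [load_crosslink_table()]).
#' @return numeric vector of upper bounds in Angstrom.
#' @export
effective_bound <- function(records) {
  vapply(seq_len(nrow(records)), function(i) {
    r <- records[i, ]
    kinds <- c(r$kind_a, r$kind_b)
    if (!all(kinds %in% known_kinds)) {
      stop(sprintf("row %d: unknown residue kind '%s'", i,
                   setdiff(kinds, known_kinds)[1]))
    }
    amine_n <- r$n_bs2g + r$n_bs3
    if (r$n_pdh > 0) {
      if (amine_n > 0) stop(sprintf("row %d: mixed amine/carboxylate linkers", i))
      if (!all(kinds %in% acidic_kinds)) {
        stop(sprintf("row %d: PDH links acidic residues, got %s-%s",
                     i, r$kind_a, r$kind_b))
      }
      return(22)
    }
    if (amine_n == 0) stop(sprintf("row %d: no linker observations", i))
    if (!all(kinds %in% amine_kinds)) {
      stop(sprintf("row %d: BS3/BS2G link amine residues, got %s-%s",
                   i, r$kind_a, r$kind_b))
    }
    nterm <- any(kinds == "n_terminus")
    if (r$n_bs2g > 0) { if (nterm) 15 else 20 } else { if (nterm) 19 else 24 }
  }, numeric(1))
}

xl_cols <- c("chain_a", "res_a", "kind_a", "chain_b", "res_b", "kind_b",
             "n_bs2g", "n_bs3", "n_pdh", "total", "best_evalue")

#' Load a cross-link table
#'
#' Reads the tab-separated cross-link dialect with columns
#' `chain_a, res_a, kind_a, chain_b, res_b, kind_b, n_bs2g, n_bs3, n_pdh,
#' total, best_evalue`; extra columns (e.g. a reference distance or cluster
#' remark) are carried through. Residue kinds are one of `lysine`,
#' `n_terminus`, `glutamate`, `aspartate`.
#'
#' @param path TSV file.
#' @return tibble of cross-link records, one per row.
#' @export
load_crosslink_table <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (nrow(tab) == 0) return(tab)
  missing <- setdiff(xl_cols, names(tab))
  if (length(missing) > 0) {
    stop("cross-link table lacks columns: ", paste(missing, collapse = ", "))
  }
  bad_kind <- which(!(tab$kind_a %in% known_kinds & tab$kind_b %in% known_kinds))
  if (length(bad_kind) > 0) {
    stop(sprintf("row %d: unknown residue kind '%s'", bad_kind[1],
                 setdiff(c(tab$kind_a[bad_kind], tab$kind_b[bad_kind]),
                         known_kinds)[1]))
  }
  counts <- as.matrix(tab[, c("n_bs2g", "n_bs3", "n_pdh", "total")])
  if (any(counts < 0)) {
    stop(sprintf("row %d: negative spectral count", which(rowSums(counts < 0) > 0)[1]))
  }
  bad_total <- which(tab$n_pdh == 0 & tab$total != tab$n_bs2g + tab$n_bs3)
  if (length(bad_total) > 0) {
    stop(sprintf("row %d: total != n_bs2g + n_bs3", bad_total[1]))
  }
  if (any(tab$best_evalue <= 0 | tab$best_evalue >= 1)) {
    stop("best_evalue must lie in (0, 1)")
  }
  # chains that carry the same protein on both sides are chemically
  # indistinguishable in the experiment: allow chain-swapped satisfaction
  tab$swap_allowed <- tab$chain_a == tab$chain_b
  tab
}

#' Peptide-level identification filter
#'
#' Keeps cross-links supported by at least `min_spectra` spectra whose best
#' E-value is below `best_e_max`. The spectrum-level FDR and E-value cutoffs
#' are applied upstream by the search engine and arrive pre-filtered in the
#' table.
#'
#' @param records cross-link tibble.
#' @param min_spectra minimum spectral count (default 2).
#' @param best_e_max exclusive best E-value threshold (default 1e-8).
#' @return filtered tibble.
#' @export
filter_identifications <- function(records, min_spectra = 2, best_e_max = 1e-8) {
  stopifnot(min_spectra > 0, best_e_max > 0)
  dplyr::filter(records, .data$total >= min_spectra,
                .data$best_evalue < best_e_max)
}

resolve_ca <- function(cm, chain, resno) {
  subs <- c(list(cm$fixed), cm$mobile)
  for (su in subs) {
    if (su$chain_id == chain) {
      i <- match(resno, su$resno)
      if (!is.na(i)) return(su$xyz[i, ])
    }
  }
  NULL
}

#' Classify cross-link compatibility against a reference structure
#'
#' For each record, the C-alpha to C-alpha distance in the reference complex
#' is compared with the record's effective linker bound; a record is
#' compatible when `distance <= bound` (bounds are maxima, so the boundary is
#' inclusive). Distances may instead be supplied directly (e.g. distances
#' printed for a published structure).
#'
#' @param records cross-link tibble.
#' @param reference optional `complex_model` to measure distances in.
#' @param distances optional numeric vector of precomputed distances (Angstrom),
#'   used when `reference` is NULL.
#' @return the records with columns `distance`, `upper_bound`, `resolved`,
#'   `compatible` added. Unresolvable residues are flagged, not dropped.
#' @export
classify_compatibility <- function(records, reference = NULL, distances = NULL) {
  bound <- effective_bound(records)
  if (is.null(distances)) {
    stopifnot(!is.null(reference))
    distances <- vapply(seq_len(nrow(records)), function(i) {
      a <- resolve_ca(reference, records$chain_a[i], records$res_a[i])
      b <- resolve_ca(reference, records$chain_b[i], records$res_b[i])
      if (is.null(a) || is.null(b)) return(NA_real_)
      sqrt(sum((a - b)^2))
    }, numeric(1))
  }
  dplyr::mutate(records,
                distance = distances,
                upper_bound = bound,
                resolved = !is.na(distances),
                compatible = !is.na(distances) & distances <= bound)
}

#' Isotope-mixing model for intermolecular assignment
#'
#' In a 1:1 mix of light (14N) and heavy (15N) labelled protein, cross-linked
#' peptides from *inter*molecular contacts assort randomly over isotope
#' channels (LL:LH:HL:HH = 1:1:1:1), while *intra*molecular links occupy only
#' the pure channels (LL:HH = 1:1). The intensity ratio of a mixed channel to
#' its matching pure channel is therefore a monotone function of the
#' intermolecular fraction f of that cross-link.
#'
#' @param mix_fraction_light proportion of light protein in the mix (default 0.5).
#' @param ratio_threshold assignment threshold on the mixed/pure ratio (default 0.14).
#' @return list of class `isotope_mix_model`.
#' @export
isotope_mix_model <- function(mix_fraction_light = 0.5, ratio_threshold = 0.14) {
  stopifnot(mix_fraction_light > 0, mix_fraction_light < 1, ratio_threshold >= 0)
  structure(list(mix_fraction_light = mix_fraction_light,
                 ratio_threshold = ratio_threshold),
            class = "isotope_mix_model")
}

#' Mixed/pure channel intensity ratio from the intermolecular fraction
#'
#' With light fraction p, a cross-link that is intermolecular with fraction f
#' has light-heavy intensity f*p*(1-p) and light-light intensity
#' f*p^2 + (1-f)*p, giving ratio r = f*(1-p) / (f*p + 1 - f).
#'
#' @param fraction intermolecular fraction f in `[0, 1]`.
#' @param mix an [isotope_mix_model()].
#' @return the mixed/pure intensity ratio.
#' @export
fraction_to_ratio <- function(fraction, mix = isotope_mix_model()) {
  stopifnot(all(fraction >= 0), all(fraction <= 1))
  p <- mix$mix_fraction_light
  fraction * (1 - p) / (fraction * p + 1 - fraction)
}

#' Intermolecular fraction from the mixed/pure channel intensity ratio
#'
#' Inverse of [fraction_to_ratio()]: f = r / ((1-p) * (1+r)) for p = 1/2;
#' the general closed form is derived from the same channel model.
#'
#' @param ratio observed mixed/pure intensity ratio (>= 0).
#' @param mix an [isotope_mix_model()].
#' @return intermolecular fraction in `[0, 1]`.
#' @export
isotope_ratio_to_fraction <- function(ratio, mix = isotope_mix_model()) {
  stopifnot(all(ratio >= 0))
  p <- mix$mix_fraction_light
  rmax <- (1 - p) / p
  if (any(ratio > rmax + 1e-12)) {
    stop(sprintf("ratio %.3f exceeds the maximum %.3f achievable at f = 1",
                 max(ratio), rmax))
  }
  # r (f p + 1 - f) = f (1 - p)  solves to  f = r / ((1 - p)(1 + r))
  f <- ratio / ((1 - p) * (1 + ratio))
  pmin(1, f)
}

#' Path to the packaged cross-link table of the three study complexes
#'
#' Tab-separated transcription of the published intermolecular cross-link
#' table for CDK9/Cyclin-T1 (3 links), EIN/HPr (13 links) and the ubiquitin
#' homodimer (7 links), including spectral counts per linker, best E-values,
#' and, where available, the C-alpha distances in the known stereospecific
#' complex structure (`ca_dist_ref`) and conformational-cluster remarks.
#'
#' @return file path.
#' @export
example_crosslink_table <- function() {
  system.file("extdata", "study_crosslinks.tsv", package = "xlensemble",
              mustWork = TRUE)
}
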