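test_that("effective bounds follow linker chemistry and observations", {
  # lysine-lysine: BS2G bound wins whenever BS2G was observed
  expect_equal(effective_bound(make_record(n_bs2g = 5, n_bs3 = 10)), 20)
  expect_equal(effective_bound(make_record(n_bs2g = 5)), 20)
  expect_equal(effective_bound(make_record(n_bs3 = 10)), 24)
  # N-terminal bounds are shorter
  expect_equal(effective_bound(make_record(kind_a = "n_terminus", n_bs2g = 2)), 15)
  expect_equal(effective_bound(make_record(kind_b = "n_terminus", n_bs3 = 2)), 19)
  # PDH on acidic pairs
  expect_equal(effective_bound(make_record(kind_a = "glutamate",
                                           kind_b = "aspartate", n_pdh = 3)), 22)
  # chemistry mismatches are errors
  expect_error(effective_bound(make_record(n_pdh = 3)), "acidic")
  expect_error(effective_bound(make_record(kind_a = "glutamate", n_bs3 = 1)),
               "amine")
  expect_error(effective_bound(make_record(kind_a = "selenocysteine", n_bs3 = 1)),
               "unknown")

  reg <- linker_registry()
  expect_equal(reg$bound_res_res, c(24, 20, 22))
  expect_equal(reg$bound_nterm_res, c(19, 15, NA))
})

test_that("the packaged cross-link table loads and filters correctly", {
  tab <- load_crosslink_table(example_crosslink_table())
  expect_equal(nrow(tab), 23)
  expect_equal(sum(tab$chain_a == "CyclinT1"), 3)
  expect_equal(sum(tab$chain_a == "EIN"), 13)
  expect_equal(sum(tab$chain_a == "Ub"), 7)
  # homodimer rows allow chain-swapped satisfaction
  expect_true(all(tab$swap_allowed[tab$chain_a == "Ub"]))
  expect_false(any(tab$swap_allowed[tab$chain_a != "Ub"]))

  # empty table loads as empty
  empty <- tempfile(fileext = ".tsv")
  writeLines(paste(c("chain_a", "res_a", "kind_a", "chain_b", "res_b", "kind_b",
                     "n_bs2g", "n_bs3", "n_pdh", "total", "best_evalue"),
                   collapse = "\t"), empty)
  expect_equal(nrow(load_crosslink_table(empty)), 0)

  # negative counts are rejected with the row number
  bad <- tempfile(fileext = ".tsv")
  readr::write_tsv(make_record(n_bs3 = -1), bad)
  expect_error(load_crosslink_table(bad), "row 1")

  # peptide-level filter: spectral count and best E-value rules
  recs <- dplyr::bind_rows(
    make_record(n_bs3 = 28, e = 1.7e-10),   # kept
    make_record(n_bs3 = 1, e = 1e-12),      # removed: single spectrum
    make_record(n_bs3 = 5, e = 1e-6))       # removed: weak E-value
  kept <- filter_identifications(recs)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$total, 28)
})

test_that("compatibility classification uses inclusive bounds and survives rigid moves", {
  # synthetic pair at exactly the bound is compatible
  rec <- make_record(n_bs3 = 2)
  at_bound <- classify_compatibility(rec, distances = 24)
  expect_true(at_bound$compatible)
  expect_false(classify_compatibility(rec, distances = 24.001)$compatible)

  # distance measured in a reference complex, invariant to rigid motion
  fixed <- make_subunit(10, "globule", seed = 1, chain_id = "A")
  mobile <- make_subunit(8, "globule", seed = 2, chain_id = "B")
  mobile <- apply_transform(mobile, rigid_transform(t = c(15, 0, 0)))
  cm <- complex_model(fixed, mobile)
  rec <- make_record(n_bs3 = 2, res_a = 3, res_b = 5)
  base <- classify_compatibility(rec, cm)
  set.seed(31)
  for (i in 1:5) {
    moved <- apply_transform(cm, random_rt())
    expect_equal(classify_compatibility(rec, moved)$distance, base$distance,
                 tolerance = 1e-6)
  }
  # unresolvable residues are flagged, not dropped
  ghost <- make_record(n_bs3 = 2, res_a = 99, res_b = 5)
  out <- classify_compatibility(dplyr::bind_rows(rec, ghost), cm)
  expect_equal(out$resolved, c(TRUE, FALSE))
  expect_equal(nrow(out), 2)
})

test_that("isotope-mixing fraction and ratio are exact mutual inverses", {
  mix <- isotope_mix_model()
  # boundary identities of the channel model
  expect_equal(fraction_to_ratio(0, mix), 0)
  expect_equal(fraction_to_ratio(1, mix), 1)
  # the published assignment threshold corresponds to ~25% intermolecular
  expect_equal(isotope_ratio_to_fraction(0.14, mix), 0.14 / (0.5 * 1.14),
               tolerance = 1e-12)
  # inverse property and strict monotonicity on a grid
  f <- seq(0, 1, by = 0.01)
  r <- fraction_to_ratio(f, mix)
  expect_true(all(diff(r) > 0))
  expect_equal(isotope_ratio_to_fraction(r, mix), f, tolerance = 1e-10)
  # unreachable ratios are rejected
  expect_error(isotope_ratio_to_fraction(1.5, mix), "maximum")
  # asymmetric mixes keep the inverse property
  mix2 <- isotope_mix_model(mix_fraction_light = 0.3)
  r2 <- fraction_to_ratio(f, mix2)
  expect_equal(isotope_ratio_to_fraction(r2, mix2), f, tolerance = 1e-10)
})
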