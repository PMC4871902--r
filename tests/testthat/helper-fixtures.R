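# shared builders for desk-scale test systems

toy_pdb_file <- function(lines) {
  path <- tempfile(fileext = ".pdb")
  writeLines(lines, path)
  path
}

# hand-written three-residue chain A plus two-residue chain B
toy_pdb_lines <- c(
  "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00",
  "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00",
  "ATOM      3  C   ALA A   1       2.009   1.420   0.000  1.00  0.00",
  "ATOM      4  O   ALA A   1       1.251   2.390   0.000  1.00  0.00",
  "ATOM      5  CA  LYS A   2       4.000   2.000   1.000  1.00  0.00",
  "ATOM      6  CA  GLY A   3       7.500   3.200   2.100  1.00  0.00",
  "ATOM      7  CA  ALA B  10      20.000   0.000   0.000  1.00  0.00",
  "ATOM      8  CA  LYS B  11      23.800   0.000   0.000  1.00  0.00",
  "ATOM      9  CA  GLY B  12      27.600   0.000   0.000  1.00  0.00",
  "END")

random_rt <- function() {
  rot <- rt_random_rotation()
  rigid_transform(rot$q, stats::rnorm(3, 0, 10))
}

# schedule kept light for unit tests; the refiner's defaults are heavier
light_schedule <- function() {
  anneal_schedule(n_stages = 20, steps_per_stage = 50, quench_steps = 100)
}

scan_schedule <- function() {
  anneal_schedule(n_stages = 30, steps_per_stage = 80, quench_steps = 150)
}

small_system <- function(k_poses = 1, links_per_pose = 4, seed = 1,
                         homodimer = FALSE) {
  fixed <- make_subunit(40, "globule", seed = 3, chain_id = "A")
  mobile <- make_subunit(20, "helix", seed = 4, chain_id = "B")
  plant_poses_and_links(fixed, if (homodimer) NULL else mobile,
                        k_poses = k_poses, links_per_pose = links_per_pose,
                        seed = seed, homodimer = homodimer)
}

make_record <- function(kind_a = "lysine", kind_b = "lysine", n_bs2g = 0,
                        n_bs3 = 0, n_pdh = 0, e = 1e-10, chain_a = "A",
                        chain_b = "B", res_a = 1, res_b = 2) {
  tibble::tibble(chain_a = chain_a, res_a = res_a, kind_a = kind_a,
                 chain_b = chain_b, res_b = res_b, kind_b = kind_b,
                 n_bs2g = n_bs2g, n_bs3 = n_bs3, n_pdh = n_pdh,
                 total = n_bs2g + n_bs3 + n_pdh, best_evalue = e)
}
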