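two_bead_topo <- function(sep) {
  b <- data.frame(id = 0:1, charge = 0, radius = 2, mass = 72,
                  molecule = c("receptor", "ligand"),
                  domain = c("N", "ligand"),
                  x = c(0, sep), y = 0, z = 0)
  bead_topology(b, box_side = 100)
}

test_that("contact counting is inclusive at the cutoff and excludes intra pairs", {
  t5 <- two_bead_topo(5.0)
  expect_equal(count_contacts(coords(t5), t5, cutoff = 5.5), 1L)
  t56 <- two_bead_topo(5.6)
  expect_equal(count_contacts(coords(t56), t56, cutoff = 5.5), 0L)
  t55 <- two_bead_topo(5.5)
  expect_equal(count_contacts(coords(t55), t55, cutoff = 5.5), 1L)
  expect_error(count_contacts(coords(t5), t5, cutoff = 0), "cutoff")
})

test_that("contact counts match the brute-force oracle on random frames", {
  topo <- small_system(box = 40)
  is_lig <- topo$beads$molecule == "ligand"
  set.seed(77)
  for (i in 1:20) {
    xyz <- matrix(runif(3 * nrow(topo$beads), 0, 40), ncol = 3)
    expect_equal(count_contacts(xyz, topo, 5.5, box_side = 40),
                 brute_contacts(xyz, is_lig, 5.5, 40))
  }
  # symmetry under swapping molecule labels
  swapped <- topo
  swapped$beads$molecule <- ifelse(is_lig, "receptor", "ligand")
  xyz <- matrix(runif(3 * nrow(topo$beads), 0, 40), ncol = 3)
  expect_equal(count_contacts(xyz, topo, 5.5, 40),
               count_contacts(xyz, swapped, 5.5, 40))
  # monotone non-increasing as the cutoff shrinks
  cts <- vapply(c(8, 5.5, 4, 2), function(cc) {
    count_contacts(xyz, topo, cc, 40)
  }, numeric(1))
  expect_true(all(diff(cts) <= 0))
})

test_that("centre-of-mass distance handles weights exactly", {
  expect_equal(com_distance(coords(two_bead_topo(40)), two_bead_topo(40)),
               40)
  # multi-bead toy with unequal masses, hand-computed
  b <- data.frame(id = 0:3, charge = 0, radius = 2,
                  mass = c(10, 30, 20, 20),
                  molecule = c("receptor", "receptor", "ligand", "ligand"),
                  domain = c("N", "N", "ligand", "ligand"),
                  x = c(0, 4, 10, 14), y = c(0, 0, 3, 3), z = 0)
  topo <- bead_topology(b, box_side = 100)
  rec_com <- c((10 * 0 + 30 * 4) / 40, 0, 0)
  lig_com <- c(12, 3, 0)
  expect_equal(com_distance(coords(topo), topo),
               sqrt(sum((rec_com - lig_com)^2)), tolerance = 1e-12)
  # translation invariance
  expect_equal(com_distance(sweep(coords(topo), 2, c(7, -2, 5), "+"), topo),
               com_distance(coords(topo), topo), tolerance = 1e-12)
})

test_that("RMSD is zero on identity, rigid-motion invariant, and matches bio3d", {
  pose <- make_reference_pose(build_receptor(), build_ligand())
  xyz <- pose$coordinates
  expect_equal(rmsd_to_reference(xyz, pose), 0, tolerance = 1e-9)
  th <- 1.1
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  moved <- sweep(xyz %*% R, 2, c(12, -7, 3), "+")
  expect_equal(rmsd_to_reference(moved, pose), 0, tolerance = 1e-9)
  # independent Kabsch implementation: bio3d fit on all beads
  topo <- pose$topology
  set.seed(55)
  for (i in 1:5) {
    frame <- xyz + matrix(rnorm(length(xyz), sd = 3), ncol = 3)
    ours <- rmsd_to_reference(frame, pose, align_set = topo$beads$id,
                              score_set = topo$beads$id)
    theirs <- bio3d::rmsd(as.vector(t(xyz)), as.vector(t(frame)),
                          fit = TRUE)
    expect_equal(ours, theirs, tolerance = 1e-3)
  }
  # collinear alignment set is rejected
  lin <- two_bead_topo(5)
  expect_error(rmsd_to_reference(coords(lin), coords(lin), lin,
                                 align_set = 0:1),
               "alignment error")
})

test_that("radius of gyration matches the direct formula", {
  b1 <- data.frame(id = 0L, charge = 0, radius = 2, mass = 72,
                   molecule = "receptor", domain = "N", x = 3, y = 1, z = 2)
  t1 <- bead_topology(b1, box_side = 50)
  expect_equal(radius_of_gyration(coords(t1), t1), 0)
  b2 <- data.frame(id = 0:1, charge = 0, radius = 2, mass = 1,
                   molecule = "receptor", domain = "N",
                   x = c(-1, 1), y = 0, z = 0)
  t2 <- bead_topology(b2, box_side = 50)
  expect_equal(radius_of_gyration(coords(t2), t2), 1, tolerance = 1e-12)
  # 5-bead toy with unequal masses against the direct formula
  b5 <- data.frame(id = 0:4, charge = 0, radius = 2,
                   mass = c(1, 2, 3, 4, 5), molecule = "receptor",
                   domain = "N", x = c(0, 1, 2, 3, 4),
                   y = c(0, 1, 0, -1, 0), z = c(1, 0, 0, 0, -1))
  t5 <- bead_topology(b5, box_side = 50)
  xyz <- coords(t5)
  w <- b5$mass
  cm <- colSums(xyz * w) / sum(w)
  expect_equal(radius_of_gyration(xyz, t5),
               sqrt(sum(w * rowSums(sweep(xyz, 2, cm)^2)) / sum(w)),
               tolerance = 1e-12)
  expect_error(radius_of_gyration(xyz, t5, selection = "ligand"), "empty")
})

test_that("approach distribution conserves counts and localises a fixed ligand", {
  # neutral system + zero noise: no forces, ligand frozen across frames
  rec <- build_receptor(10, linker_spec(3), net_charge = 0)
  lig <- build_ligand(6, net_charge = 0)
  topo <- assemble_system(rec, lig, box_side = 80)
  cfg <- simulation_config(ionic_strength = 0, box_side = 80,
                           min_placement_distance = 30, t_max = 3,
                           dt = 0.01, stride = 100, seed = 61,
                           bind_mode = "none", noise_scale = 0)
  inter0 <- interaction_model(ionic_strength = 0,
                              excluded_volume_strength = 0)
  tr <- simulate_trial(topo, cfg, inter0)
  ref_small <- list(topology = topo,
                    coordinates = autoimage_recenter(get_frame(tr, 1),
                                                     topo, 80),
                    contact_count = 50L)
  class(ref_small) <- "reference_pose"
  ad <- approach_distribution(list(tr), ref_small, grid_spacing = 5,
                              selector = function(rmsd, com) rep(TRUE,
                                                                 length(rmsd)))
  expect_equal(sum(ad$counts$count), length(tr$times))
  expect_equal(nrow(ad$counts), 1L)  # frozen ligand: one occupied voxel
  expect_error(
    approach_distribution(list(tr), ref_small,
                          selector = function(r, c) rep(FALSE, length(r))),
    "empty selection")
})
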