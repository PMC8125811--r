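test_that("random ligand placement honours the minimum distance and the seed", {
  topo <- small_system(box = 150)
  cfg <- simulation_config(seed = 11, box_side = 150,
                           min_placement_distance = 40)
  is_lig <- topo$beads$molecule == "ligand"
  rec <- coords(topo)[!is_lig, , drop = FALSE]
  rec <- sweep(rec, 2, colMeans(rec)) + 75
  for (s in 1:20) {
    set.seed(s)
    lig <- place_ligand_random(topo, cfg, receptor_xyz = rec)
    dmin <- min(vapply(seq_len(nrow(lig)), function(j) {
      d <- sweep(rec, 2, lig[j, ])
      d <- d - 150 * round(d / 150)
      sqrt(min(rowSums(d^2)))
    }, numeric(1)))
    expect_gte(dmin, 40)
  }
  set.seed(99); a <- place_ligand_random(topo, cfg, receptor_xyz = rec)
  set.seed(99); b <- place_ligand_random(topo, cfg, receptor_xyz = rec)
  expect_identical(a, b)
})

test_that("accepted placements are uniform over the admissible region", {
  # symmetric system (single-bead receptor at the box centre) so octant
  # occupancies of the ligand position should be equal
  topo <- pair_topology(box = 150)
  cfg <- simulation_config(seed = 1, box_side = 150,
                           min_placement_distance = 40)
  rec <- matrix(75, 1, 3)
  set.seed(314)
  pos <- t(replicate(2000, place_ligand_random(topo, cfg,
                                               receptor_xyz = rec)[1, ]))
  oct <- paste(pos[, 1] > 75, pos[, 2] > 75, pos[, 3] > 75)
  p <- chisq.test(table(oct))$p.value
  expect_gt(p, 0.001)
})

test_that("free ligand diffusion reproduces the Einstein relation", {
  topo <- pair_topology()
  inter <- interaction_model(ionic_strength = 0,
                             excluded_volume_strength = 0)
  cfg <- simulation_config(ionic_strength = 0, dt = 0.01, t_max = 1500,
                           stride = 10, seed = 7, bind_mode = "none")
  tr <- simulate_trial(topo, cfg, inter, d_override = fixed_receptor)
  xyz <- tr$frames[, 4:6]
  lags <- 1:20
  msd <- vapply(lags, function(L) {
    d <- xyz[-(1:L), , drop = FALSE] -
      xyz[seq_len(nrow(xyz) - L), , drop = FALSE]
    mean(rowSums(d^2))
  }, numeric(1))
  slope <- coef(lm(msd ~ I(lags * 0.1)))[2]
  expect_equal(unname(slope), 6 * 10, tolerance = 0.1)
})

test_that("identical seeds give bit-identical trajectories", {
  topo <- small_system()
  inter <- interaction_model(ionic_strength = 0.15, native_well_depth = 8)
  cfg <- simulation_config(ionic_strength = 0.15, box_side = 80,
                           min_placement_distance = 30, t_max = 20,
                           stride = 10, seed = 5, bind_mode = "none")
  a <- simulate_trial(topo, cfg, inter)
  b <- simulate_trial(topo, cfg, inter)
  expect_identical(a$frames, b$frames)
  expect_identical(a$contacts, b$contacts)
})

test_that("zero-noise descent is monotone in distance and energy", {
  topo <- pair_topology()
  inter <- interaction_model(ionic_strength = 0,
                             excluded_volume_strength = 0,
                             native_well_depth = 5, native_well_width = 20)
  cfg <- simulation_config(ionic_strength = 0, t_max = 100, stride = 10,
                           seed = 1, bind_mode = "none", noise_scale = 0,
                           min_placement_distance = 30)
  st <- matrix(c(75, 75, 75, 115, 75, 75), 2, 3, byrow = TRUE)
  tr <- simulate_trial(topo, cfg, inter, start_coords = st,
                       d_override = list(receptor = list(dt = 0, dr = 0)))
  expect_true(all(diff(tr$com_distance) <= 1e-9))
  expect_true(all(diff(tr$energies) <= 1e-9))
})

test_that("too-large time steps raise a stability error", {
  topo <- pair_topology()
  inter <- interaction_model(ionic_strength = 0)
  cfg <- simulation_config(ionic_strength = 0, dt = 1, t_max = 10,
                           seed = 1, bind_mode = "none")
  expect_error(
    simulate_trial(topo, cfg, inter,
                   d_override = list(ligand = list(dt = 100))),
    "stability")
})

test_that("the simulator's contact series matches the observables module", {
  topo <- small_system()
  inter <- interaction_model(ionic_strength = 0, native_well_depth = 10)
  cfg <- simulation_config(ionic_strength = 0, box_side = 80,
                           min_placement_distance = 30, t_max = 50,
                           stride = 25, seed = 21, bind_mode = "none")
  tr <- simulate_trial(topo, cfg, inter)
  obs <- compute_observables(tr)
  expect_equal(obs$contacts, tr$contacts)
  expect_equal(obs$com_distance, tr$com_distance, tolerance = 1e-9)
})

test_that("Boltzmann point sampler reproduces closed-form statistics", {
  kBT <- thermal_energy(300)
  # harmonic well: covariance = (kBT/k) I
  k <- 1
  pts <- sample_pmf_2d(function(x, y) 0.5 * k * (x^2 + y^2), 1e5,
                       seed = 12, domain = list(x = c(-4, 4), y = c(-4, 4)))
  S <- cov(pts)
  expect_equal(S[1, 1], kBT / k, tolerance = 0.05)
  expect_equal(S[2, 2], kBT / k, tolerance = 0.05)
  expect_lt(abs(S[1, 2]), 0.05 * kBT / k)
  # flat energy: uniform marginals
  flat <- sample_pmf_2d(function(x, y) 0 * x, 5000, seed = 3,
                        domain = list(x = c(0, 1), y = c(0, 1)))
  expect_gt(ks.test(flat[, 1], "punif")$p.value, 0.001)
  expect_error(sample_pmf_2d(function(x, y) -Inf + 0 * x, 10),
               "bounded")
})

test_that("mixture sampler hits requested moments and degenerate weights", {
  x <- sample_rg_mixture(1, 18.0, 0.5, 1e4, seed = 8)
  expect_equal(mean(x), 18.0, tolerance = 0.02)
  y <- sample_rg_mixture(c(1, 0), c(15, 18), c(0.1, 0.1), 500, seed = 2)
  expect_true(all(abs(y - 15) < 1))
  expect_error(sample_rg_mixture(c(0.6, 0.6), c(1, 2), c(1, 1), 10),
               "sum to 1")
})
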