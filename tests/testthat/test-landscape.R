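test_that("projection keeps one point per frame with correct provenance", {
  topo <- small_system(box = 80)
  pose <- make_reference_pose(build_receptor(), build_ligand())
  # the reference pose as the sole frame projects to (0, d_ref)
  ref_topo <- pose$topology
  tr_ref <- structure(list(
    times = 0, frames = matrix(as.vector(t(pose$coordinates)), 1),
    topology = ref_topo, box_side = ref_topo$box_side,
    fpt = NA, censored = TRUE), class = "bd_trajectory")
  pr <- project_trajectories(tr_ref, pose)
  expect_equal(nrow(pr), 1)
  expect_equal(pr$rmsd, 0, tolerance = 1e-9)
  expect_equal(pr$com_distance,
               com_distance(pose$coordinates, ref_topo), tolerance = 1e-9)
  # point count equals total frame count, values match per-frame recompute
  inter <- interaction_model(ionic_strength = 0.15)
  cfg <- simulation_config(ionic_strength = 0.15, box_side = 80,
                           min_placement_distance = 30, t_max = 2,
                           stride = 100, seed = 19, bind_mode = "none")
  trs <- list(simulate_trial(topo, cfg, inter),
              simulate_trial(topo, modifyList(cfg, list(seed = 20)), inter))
  pose_small <- list(topology = topo,
                     coordinates = autoimage_recenter(get_frame(trs[[1]], 1),
                                                      topo, 80),
                     contact_count = 50L)
  class(pose_small) <- "reference_pose"
  pr2 <- project_trajectories(trs, pose_small)
  expect_equal(nrow(pr2), sum(vapply(trs, function(t) length(t$times), 1)))
  f2 <- autoimage_recenter(get_frame(trs[[2]], 3), topo, 80)
  expect_equal(pr2$rmsd[pr2$trial == 2 & pr2$frame == 3],
               rmsd_to_reference(f2, pose_small, topo), tolerance = 1e-9)
})

test_that("KDE integrates to one and finds generative modes", {
  set.seed(5)
  cloud <- cbind(rnorm(5000, 10, 1), rnorm(5000, 40, 2))
  kd <- density_kde(cloud)
  dx <- diff(kd$x[1:2]); dy <- diff(kd$y[1:2])
  expect_equal(sum(kd$density) * dx * dy, 1, tolerance = 0.01)
  peak <- which(kd$density == max(kd$density), arr.ind = TRUE)
  expect_equal(kd$x[peak[1]], 10, tolerance = 0.1)
  expect_equal(kd$y[peak[2]], 40, tolerance = 0.05)
  # bimodal cloud: modes within one bandwidth of the true means
  two <- rbind(cbind(rnorm(4000, 5, 0.5), rnorm(4000, 5, 0.5)),
               cbind(rnorm(4000, 12, 0.5), rnorm(4000, 12, 0.5)))
  kd2 <- density_kde(two)
  hx <- sd(two[, 1]) * nrow(two)^(-1 / 6)
  pk <- which(kd2$density == max(kd2$density), arr.ind = TRUE)
  expect_true(min(abs(kd2$x[pk[1]] - c(5, 12))) < hx)
  expect_error(density_kde(cbind(rep(1, 10), rep(2, 10))), "bandwidth")
})

test_that("Boltzmann inversion satisfies its defining identities", {
  rho <- matrix(c(1, 2, exp(1), 4), 2, 2)
  dens <- list(x = 1:2, y = 1:2, density = rho)
  pmf <- boltzmann_invert(dens, temperature = 300)
  kBT <- thermal_energy(300)
  # cell at rho_min has zero energy; all energies <= 0
  expect_equal(pmf$energy[1, 1], 0)
  expect_true(all(pmf$energy <= 1e-12, na.rm = TRUE))
  # cell with rho = e * rho_min sits exactly at -kB*T
  expect_equal(pmf$energy[1, 2], -kBT, tolerance = 1e-12)
  expect_equal(-kBT, -0.596, tolerance = 0.001)
  # scale invariance of rho/rho_min
  pmf2 <- boltzmann_invert(list(x = 1:2, y = 1:2, density = 7 * rho), 300)
  expect_equal(pmf2$energy, pmf$energy, tolerance = 1e-12)
  # minimum energy where density is maximal
  expect_equal(which.min(pmf$energy), which.max(rho))
  expect_error(boltzmann_invert(list(x = 1, y = 1,
                                     density = matrix(0, 2, 2))),
               "all-zero")
})

test_that("a Boltzmann-sampled harmonic well is recovered up to a constant", {
  kspr <- 1
  pts <- sample_pmf_2d(function(x, y) 0.5 * kspr * (x^2 + y^2), 1e5,
                       temperature = 300, seed = 9,
                       domain = list(x = c(-4, 4), y = c(-4, 4)))
  pmf <- boltzmann_invert(density_kde(pts), 300)
  kBT <- thermal_energy(300)
  xg <- outer(pmf$x, rep(1, length(pmf$y)))
  yg <- outer(rep(1, length(pmf$x)), pmf$y)
  true_e <- 0.5 * kspr * (xg^2 + yg^2)
  basin <- true_e <= 2 * kBT & !is.na(pmf$energy)
  fit <- summary(lm(as.vector(pmf$energy[basin]) ~
                      as.vector(true_e[basin])))
  expect_gt(fit$r.squared, 0.95)
})

test_that("native-event counting responds only to trials entering the box", {
  proj <- data.frame(
    trial = c(1, 1, 2, 2, 3),
    rmsd = c(50, 4, 50, 45, 11),
    com_distance = c(80, 6, 70, 60, 9),
    contacts = 0)
  expect_equal(count_native_events(proj, 10, 10), 1)      # only trial 1
  expect_equal(count_native_events(proj, 12, 10), 2)      # trial 3 joins
  # monotone non-decreasing in both cuts
  grid <- expand.grid(rc = c(5, 10, 20, 60), dc = c(5, 10, 20, 90))
  counts <- mapply(function(rc, dc) count_native_events(proj, rc, dc),
                   grid$rc, grid$dc)
  m <- matrix(counts, 4, 4)
  expect_true(all(apply(m, 2, function(v) all(diff(v) >= 0))))
  expect_true(all(apply(m, 1, function(v) all(diff(v) >= 0))))
  expect_error(count_native_events(proj, 0, 10), "> 0")
})

test_that("loosely-bound flags are inclusive and PMF-verified", {
  proj <- data.frame(trial = 1, frame = 1:4, time = 1:4,
                     rmsd = c(30, 10, 5, 50),
                     com_distance = c(60, 20, 8, 90),
                     contacts = c(0, 50, 80, 49))
  out <- loosely_bound_mask(proj, threshold = 50)
  expect_equal(out$loosely_bound, c(FALSE, TRUE, TRUE, FALSE))
  # flag fraction equals a direct recount
  expect_equal(mean(out$loosely_bound), mean(proj$contacts >= 50))
  # with a PMF whose low-(rmsd, dist) corner is favourable, flagged points
  # are verified to be at negative energy
  gx <- seq(0, 100, length.out = 50)
  dens <- outer(gx, gx, function(a, b) exp(-(a + b) / 30))
  pmf <- boltzmann_invert(list(x = gx, y = gx, density = dens), 300)
  out2 <- loosely_bound_mask(proj, 50, pmf = pmf)
  expect_equal(attr(out2, "n_flagged"), 2)
  expect_equal(attr(out2, "frac_favorable"), 1)
  expect_error(loosely_bound_mask(data.frame(rmsd = 1)), "alignment")
})

test_that("mixture decomposition recovers planted components and picks k by BIC", {
  x2 <- sample_rg_mixture(c(0.5, 0.5), c(15.2, 18.0), c(0.6, 0.6), 1e4,
                          seed = 2)
  fit2 <- fit_rg_mixture(x2)
  expect_equal(fit2$n_components, 2)
  expect_equal(fit2$means, c(15.2, 18.0), tolerance = 0.2 / 15)
  expect_equal(sum(fit2$weights), 1, tolerance = 1e-9)
  x1 <- sample_rg_mixture(1, 17, 0.5, 5000, seed = 3)
  expect_equal(fit_rg_mixture(x1)$n_components, 1)
  x3 <- sample_rg_mixture(c(0.4, 0.25, 0.35), c(15.2, 17.0, 18.0),
                          c(0.5, 0.5, 0.5), 1e4, seed = 4)
  fit3 <- fit_rg_mixture(x3)
  expect_equal(fit3$n_components, 3)
  expect_error(fit_rg_mixture(rnorm(10)), "at least 50")
})

test_that("pre-binding RG window arithmetic follows the first passage", {
  topo <- small_system(box = 80)
  inter <- interaction_model(ionic_strength = 0)
  cfg <- simulation_config(ionic_strength = 0, box_side = 80,
                           min_placement_distance = 30, t_max = 5,
                           stride = 100, seed = 31, bind_mode = "none")
  tr <- simulate_trial(topo, cfg, inter)     # 6 frames at times 0..5
  tr$fpt <- 3; tr$censored <- FALSE
  rgs <- pre_binding_rg_series(list(tr))
  expect_length(rgs, 3)                      # frames at t = 0, 1, 2
  # censored trial contributes every frame
  trc <- tr; trc$fpt <- NA; trc$censored <- TRUE
  expect_length(pre_binding_rg_series(list(trc)), 6)
  # values equal the per-frame recompute
  direct <- vapply(1:3, function(f) {
    radius_of_gyration(get_frame(tr, f), topo, "receptor")
  }, numeric(1))
  expect_equal(rgs, direct, tolerance = 1e-12)
  # binding at frame 0 is excluded with a warning
  tr0 <- tr; tr0$fpt <- 0
  expect_warning(pre_binding_rg_series(list(tr0)), "first frame")
})
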