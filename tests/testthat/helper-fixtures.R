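# shared fixtures: all built in code, no data files

# two single-bead molecules in a periodic box; the workhorse for rate-oracle
# runs (receptor pinned, ligand diffusing with a prescribed D)
pair_topology <- function(qr = 0, ql = 0, radius = 2, box = 150) {
  rb <- data.frame(id = 0L, charge = qr, radius = radius, mass = 72,
                   molecule = "receptor", domain = "N",
                   x = 0, y = 0, z = 0)
  lb <- data.frame(id = 1L, charge = ql, radius = radius, mass = 72,
                   molecule = "ligand", domain = "ligand",
                   x = 60, y = 0, z = 0)
  bead_topology(rbind(rb, lb), box_side = box)
}

fixed_receptor <- list(receptor = list(dt = 0, dr = 0),
                       ligand = list(dt = 10, dr = 0))

# run n_trials absorbing-sphere FPT trials and return the times (NA censored)
oracle_fpts <- function(topology, inter, n_trials, seed_base,
                        ionic_strength = 0, t_max = 30000, R = 10,
                        dt = 0.01) {
  vapply(seq_len(n_trials), function(i) {
    cfg <- simulation_config(
      ionic_strength = ionic_strength, dt = dt, t_max = t_max,
      stride = 100, seed = seed_base + i, bind_mode = "com",
      bind_threshold = R, record_frames = FALSE)
    tr <- simulate_trial(topology, cfg, inter, d_override = fixed_receptor)
    if (tr$censored) NA_real_ else tr$fpt
  }, numeric(1))
}

# small multi-bead system for fast trajectory-level tests
small_system <- function(box = 80) {
  rec <- build_receptor(10, linker_spec(3), net_charge = -6)
  lig <- build_ligand(6, net_charge = 3)
  assemble_system(rec, lig, box_side = box)
}

# brute-force O(n^2) minimum-image contact count
brute_contacts <- function(xyz, is_ligand, cutoff, box) {
  ri <- which(!is_ligand)
  li <- which(is_ligand)
  cnt <- 0L
  for (i in ri) for (j in li) {
    d <- xyz[i, ] - xyz[j, ]
    if (!is.na(box) && is.finite(box)) d <- d - box * round(d / box)
    if (sum(d^2) <= cutoff^2) cnt <- cnt + 1L
  }
  cnt
}
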