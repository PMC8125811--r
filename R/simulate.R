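#' Simulation configuration
#'
#' Study conditions for one synthetic Brownian-dynamics trial. Defaults
#' mirror the emulated campaign: a 150 Angstrom cubic box, 2 microsecond
#' (2000 ns) horizon, random ligand placement at least 40 Angstrom from the
#' receptor, and bound-state detection at >= 50 inter-molecular contacts
#' within 5.5 Angstrom.
#'
#' @param ionic_strength mol/L (>= 0).
#' @param temperature K.
#' @param box_side Cubic box side, Angstrom.
#' @param dt Integration time step, ns.
#' @param t_max Trial horizon, ns.
#' @param stride Steps per emitted frame.
#' @param seed Integer RNG seed for the trial.
#' @param min_placement_distance Minimum initial inter-molecular bead-bead
#'   distance, Angstrom (must be < `box_side`/2).
#' @param linker_regime `"WT"` or `"labile"`.
#' @param bind_mode Bound-state criterion: `"contacts"` (count >=
#'   `bind_threshold`), `"com"` (centre-of-mass distance <=
#'   `bind_threshold`, an absorbing sphere), or `"none"`.
#' @param bind_threshold Contact count or absorbing radius (Angstrom).
#' @param contact_cutoff Contact distance cutoff, Angstrom.
#' @param stop_on_bind Terminate the trial at first passage.
#' @param record_frames Keep coordinates (otherwise only per-frame scalar
#'   series are retained).
#' @param noise_scale Multiplier on the thermal noise (0 gives deterministic
#'   steepest-descent dynamics for testing).
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(ionic_strength = 0.15, temperature = 300,
                              box_side = 150, dt = 0.01, t_max = 2000,
                              stride = 100, seed = 1,
                              min_placement_distance = 40,
                              linker_regime = c("WT", "labile"),
                              bind_mode = c("contacts", "com", "none"),
                              bind_threshold = 50, contact_cutoff = 5.5,
                              stop_on_bind = TRUE, record_frames = TRUE,
                              noise_scale = 1) {
  linker_regime <- match.arg(linker_regime)
  bind_mode <- match.arg(bind_mode)
  if (ionic_strength < 0) stop("`ionic_strength` must be >= 0")
  if (dt <= 0 || dt > t_max) stop("need 0 < dt <= t_max")
  if (stride < 1) stop("`stride` must be >= 1")
  if (min_placement_distance >= box_side / 2) {
    stop("`min_placement_distance` must be < box_side/2")
  }
  structure(as.list(environment()), class = "simulation_config")
}

#' @export
print.simulation_config <- function(x, ...) {
  cat(sprintf(paste0("simulation_config: I = %g M, box %g A, dt %g ns, ",
                     "t_max %g ns, stride %d, seed %d\n"),
              x$ionic_strength, x$box_side, x$dt, x$t_max,
              as.integer(x$stride), as.integer(x$seed)))
  cat(sprintf("  bind: %s >= %g (cutoff %g A), placement >= %g A, regime %s\n",
              x$bind_mode, x$bind_threshold, x$contact_cutoff,
              x$min_placement_distance, x$linker_regime))
  invisible(x)
}

# random rotation matrix from a uniform quaternion (consumes 4 normals)
random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

#' Randomly place the ligand around the receptor
#'
#' Draws a uniform random position and orientation for the ligand inside the
#' periodic box, rejecting poses whose minimum-image minimum bead-bead
#' distance to the receptor falls below `config$min_placement_distance`.
#' Consumes the current RNG stream, so results are deterministic under
#' `set.seed()`.
#'
#' @param topology Full system `bead_topology` (receptor + ligand).
#' @param config A [simulation_config()].
#' @param receptor_xyz Receptor coordinates to place against (defaults to
#'   the build coordinates centred in the box).
#' @param max_attempts Rejection-sampling budget before failing.
#' @return N_ligand x 3 matrix of ligand coordinates.
#' @export
place_ligand_random <- function(topology, config, receptor_xyz = NULL,
                                max_attempts = 10000) {
  box <- config$box_side
  b <- topology$beads
  is_lig <- b$molecule == "ligand"
  lig0 <- coords(topology)[is_lig, , drop = FALSE]
  lig0 <- sweep(lig0, 2, colMeans(lig0))
  if (is.null(receptor_xyz)) {
    receptor_xyz <- coords(topology)[!is_lig, , drop = FALSE]
    receptor_xyz <- sweep(receptor_xyz, 2, colMeans(receptor_xyz))
    receptor_xyz <- receptor_xyz + box / 2
  }
  dmin2 <- config$min_placement_distance^2
  for (attempt in seq_len(max_attempts)) {
    pos <- stats::runif(3, 0, box)
    rot <- random_rotation()
    lig <- lig0 %*% t(rot)
    lig <- sweep(lig, 2, pos, "+")
    ok <- TRUE
    for (d in 1:3) {
      dd <- outer(receptor_xyz[, d], lig[, d], "-")
      dd <- dd - box * round(dd / box)
      if (d == 1) acc <- dd^2 else acc <- acc + dd^2
    }
    if (min(acc) >= dmin2) return(lig)
  }
  stop("placement error: no admissible ligand pose found within ",
       max_attempts, " attempts")
}

# body decomposition: rigid receptor domains N and C, one body per linker
# bead, ligand as one rigid body. Returns 0-based body index per bead plus
# per-body diffusion coefficients. Tethered linker beads carry the drag of
# the backbone segment they stand for, not that of a free Stokes sphere of
# bead radius: their effective hydrodynamic radius is `tether_radius`
# (which also keeps the Euler-Maruyama step stable at the default dt).
body_plan <- function(topology, temperature, d_override = NULL,
                      tether_radius = 35) {
  b <- topology$beads
  n <- nrow(b)
  body <- integer(n)
  next_id <- 0L
  for (dom in c("N", "C")) {
    sel <- b$molecule == "receptor" & b$domain == dom
    if (any(sel)) {
      body[sel] <- next_id
      next_id <- next_id + 1L
    }
  }
  sel <- b$molecule == "receptor" & b$domain == "linker"
  if (any(sel)) {
    idx <- which(sel)
    body[idx] <- next_id + seq_along(idx) - 1L
    next_id <- next_id + length(idx)
  }
  other_rec <- b$molecule == "receptor" & !(b$domain %in% c("N", "C", "linker"))
  if (any(other_rec)) {
    body[other_rec] <- next_id
    next_id <- next_id + 1L
  }
  lig <- b$molecule == "ligand"
  body[lig] <- next_id
  nb <- next_id + 1L

  xyz <- coords(topology)
  body_dt <- numeric(nb)
  body_dr <- numeric(nb)
  for (k in seq_len(nb) - 1L) {
    mem <- which(body == k)
    cm <- colMeans(xyz[mem, , drop = FALSE])
    rg <- sqrt(mean(rowSums(sweep(xyz[mem, , drop = FALSE], 2, cm)^2)))
    r_eff <- if (length(mem) == 1 && b$domain[mem] == "linker") {
      max(b$radius[mem], tether_radius)
    } else {
      max(mean(b$radius[mem]),
          sqrt(5 / 3) * rg + mean(b$radius[mem]) / 2)
    }
    body_dt[k + 1L] <- stokes_einstein_dt(r_eff, temperature)
    body_dr[k + 1L] <- stokes_einstein_dr(r_eff, temperature)
  }
  mol_of_body <- vapply(seq_len(nb) - 1L, function(k) {
    b$molecule[which(body == k)[1]]
  }, character(1))
  if (!is.null(d_override)) {
    for (mol in names(d_override)) {
      sel <- which(mol_of_body == mol)
      ov <- d_override[[mol]]
      if (!is.null(ov[["dt"]])) body_dt[sel] <- ov[["dt"]]
      if (!is.null(ov[["dr"]])) body_dr[sel] <- ov[["dr"]]
    }
  }
  list(body = body, body_dt = body_dt, body_dr = body_dr)
}

#' Run one Brownian-dynamics trial
#'
#' Euler-Maruyama overdamped dynamics: the receptor's N and C domains and
#' the ligand move as rigid bodies (translation + rotation, Stokes-Einstein
#' diffusion coefficients on an effective radius), linker beads are
#' propagated individually under their bonded forces. Inter-molecular forces
#' are Debye-Hueckel electrostatics plus WCA excluded volume; an optional
#' native-site Gaussian well creates a fully-bound basin. Seeded and
#' bit-reproducible.
#'
#' @param topology Full system `bead_topology`.
#' @param config A [simulation_config()]; `config$seed` seeds the trial.
#' @param interaction An [interaction_model()]; its `ionic_strength`/`temperature`
#'   should match the config (the interaction object wins).
#' @param start_coords Optional N x 3 starting coordinates; by default the
#'   receptor is centred in the box and the ligand placed by
#'   [place_ligand_random()].
#' @param d_override Optional named list (per molecule,
#'   e.g. `list(receptor = list(dt = 0, dr = 0))`) overriding diffusion
#'   coefficients; receptor `dt = dr = 0` pins it in place.
#' @return A `bd_trajectory`: list with `times` (ns), `frames` (frames x 3N
#'   coordinate matrix, or `NULL` when `record_frames = FALSE`), per-frame
#'   `contacts`, `com_distance`, `energies`, the first passage time `fpt`
#'   (ns, `NA` when censored), `censored`, `topology` and `box_side`.
#' @export
simulate_trial <- function(topology, config, interaction,
                           start_coords = NULL, d_override = NULL) {
  validate_topology(topology)
  stopifnot(inherits(config, "simulation_config"),
            inherits(interaction, "bk_interaction"))
  box <- config$box_side
  set.seed(config$seed)
  plan <- body_plan(topology, interaction$temperature, d_override)
  b <- topology$beads
  if (is.null(start_coords)) {
    xyz <- coords(topology)
    is_lig <- b$molecule == "ligand"
    rec <- xyz[!is_lig, , drop = FALSE]
    rec <- sweep(rec, 2, colMeans(rec)) + box / 2
    lig <- place_ligand_random(topology, config, receptor_xyz = rec)
    start_coords <- matrix(0, nrow(xyz), 3)
    start_coords[!is_lig, ] <- rec
    start_coords[is_lig, ] <- lig
  }
  # thermal-noise step must stay below the smallest bead radius
  max_d <- max(plan$body_dt)
  if (max_d > 0 && sqrt(2 * max_d * config$dt) > min(b$radius)) {
    stop("stability error: rms displacement per step exceeds the smallest ",
         "bead radius; reduce dt")
  }
  site <- which(b$molecule == "receptor" & b$domain %in% c("N", "C")) - 1L
  if (length(site) == 0) site <- which(b$molecule == "receptor") - 1L

  kappa <- if (is.finite(interaction$debye_length)) {
    1 / interaction$debye_length
  } else 0
  n_steps <- ceiling(config$t_max / config$dt)
  bind_mode <- match(config$bind_mode, c("none", "contacts", "com")) - 1L
  check_every <- if (bind_mode == 2L) 1L else as.integer(config$stride)

  res <- bd_run_cpp(
    start_coords, b$charge, b$radius, b$mass,
    plan$body, as.integer(b$molecule == "ligand"),
    plan$body_dt, plan$body_dr,
    as.matrix(topology$bonds[, c("i", "j"), drop = FALSE]),
    topology$bonds$r0, topology$bonds$k,
    as.matrix(topology$angles[, c("i", "j", "k"), drop = FALSE]),
    topology$angles$theta0, topology$angles$kang,
    as.integer(site), box, interaction$kBT, interaction$bjerrum_length,
    kappa, interaction$excluded_volume_strength,
    interaction$native_well_depth, interaction$native_well_width,
    interaction$cutoff, config$dt, 0, as.integer(n_steps),
    as.integer(config$stride), bind_mode, config$bind_threshold,
    config$contact_cutoff, check_every, config$noise_scale,
    isTRUE(config$stop_on_bind), isTRUE(config$record_frames))

  nf <- res$n_frames
  structure(list(
    times = res$times[seq_len(nf)],
    frames = if (isTRUE(config$record_frames)) {
      res$frames[seq_len(nf), , drop = FALSE]
    } else NULL,
    contacts = res$contacts[seq_len(nf)],
    com_distance = res$com_distance[seq_len(nf)],
    energies = res$energies[seq_len(nf)],
    fpt = res$fpt, censored = !isTRUE(res$bound),
    topology = topology, box_side = box, config = config
  ), class = "bd_trajectory")
}

#' @export
print.bd_trajectory <- function(x, ...) {
  cat(sprintf("bd_trajectory: %d frames over %.4g ns, %d beads, box %g A\n",
              length(x$times), max(x$times), nrow(x$topology$beads),
              x$box_side))
  cat(sprintf("  first passage: %s\n",
              if (x$censored) "censored" else sprintf("%.4g ns", x$fpt)))
  invisible(x)
}

#' Extract one frame of a trajectory as an N x 3 coordinate matrix
#'
#' @param trajectory A `bd_trajectory` with recorded frames.
#' @param i Frame index (1-based).
#' @return N x 3 coordinate matrix in Angstrom.
#' @export
get_frame <- function(trajectory, i) {
  if (is.null(trajectory$frames)) stop("trajectory has no recorded frames")
  matrix(trajectory$frames[i, ], ncol = 3, byrow = TRUE)
}

#' Draw points from a 2D Boltzmann distribution
#'
#' Rejection sampler: points on `domain` are accepted with probability
#' `exp(-(E - Emin)/kBT)`, giving a sample distributed proportional to
#' `exp(-E/kBT)`. Used as a fixture generator for testing Boltzmann
#' inversion.
#'
#' @param energy_fn Function of (x, y) (vectorised) returning energy in
#'   kcal/mol; must be bounded below on the domain.
#' @param n Number of points.
#' @param temperature K.
#' @param seed Integer seed.
#' @param domain List with `x = c(lo, hi)`, `y = c(lo, hi)`.
#' @return n x 2 matrix of points.
#' @export
sample_pmf_2d <- function(energy_fn, n, temperature = 300, seed = 1,
                          domain = list(x = c(-5, 5), y = c(-5, 5))) {
  set.seed(seed)
  kBT <- thermal_energy(temperature)
  gx <- seq(domain$x[1], domain$x[2], length.out = 101)
  gy <- seq(domain$y[1], domain$y[2], length.out = 101)
  e_grid <- outer(gx, gy, energy_fn)
  if (!all(is.finite(e_grid)) || min(e_grid) == -Inf) {
    stop("energy function must be finite (bounded below) on the domain")
  }
  emin <- min(e_grid)
  out <- matrix(numeric(0), 0, 2)
  guard <- 0
  while (nrow(out) < n && guard < 10000) {
    m <- max(2000, 2 * (n - nrow(out)))
    px <- stats::runif(m, domain$x[1], domain$x[2])
    py <- stats::runif(m, domain$y[1], domain$y[2])
    e <- energy_fn(px, py)
    keep <- stats::runif(m) < exp(-(e - emin) / kBT)
    out <- rbind(out, cbind(px[keep], py[keep]))
    guard <- guard + 1
  }
  if (nrow(out) < n) stop("rejection sampling failed to reach n points")
  out[seq_len(n), , drop = FALSE]
}

#' Draw a radius-of-gyration sample from a Gaussian mixture
#'
#' Direct i.i.d. sampler used to unit-test the mixture decomposition of
#' receptor RG ensembles (compact / intermediate / extended states).
#'
#' @param weights Non-negative component weights summing to 1.
#' @param means,sds Component means and standard deviations in Angstrom.
#' @param n Sample size.
#' @param seed Integer seed.
#' @return Numeric vector of n draws.
#' @export
sample_rg_mixture <- function(weights, means, sds, n, seed = 1) {
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-8) {
    stop("`weights` must be non-negative and sum to 1")
  }
  stopifnot(length(weights) == length(means), length(means) == length(sds))
  set.seed(seed)
  comp <- sample.int(length(weights), n, replace = TRUE, prob = weights)
  stats::rnorm(n, means[comp], sds[comp])
}
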