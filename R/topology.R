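#' Linker flexibility specification
#'
#' Describes the bead chain joining the receptor's two rigid domains. Two
#' regimes are distinguished: `"WT"`, a stiff (helix-like) linker that holds
#' the two domains in their channel-forming arrangement, and `"labile"`, a
#' near-free chain that lets the domains splay.
#'
#' @param n_beads Number of linker beads (>= 2).
#' @param bend_stiffness Harmonic angle stiffness in kcal/mol/rad^2. Defaults:
#'   10 for `"WT"`, 0.5 for `"labile"`.
#' @param rest_angle Rest angle in radians for the linker angle terms, or
#'   `NULL` to adopt the as-built arc geometry (zero initial strain).
#' @param regime_tag `"WT"` or `"labile"`.
#' @return An object of class `linker_spec`.
#' @export
linker_spec <- function(n_beads = 5, bend_stiffness = NULL, rest_angle = NULL,
                        regime_tag = c("WT", "labile")) {
  regime_tag <- match.arg(regime_tag)
  if (is.null(bend_stiffness)) {
    bend_stiffness <- if (regime_tag == "WT") 10 else 0.5
  }
  if (!is.numeric(n_beads) || n_beads < 2 || n_beads != round(n_beads)) {
    stop("`n_beads` must be an integer >= 2")
  }
  if (bend_stiffness < 0) stop("`bend_stiffness` must be >= 0")
  structure(list(n_beads = as.integer(n_beads),
                 bend_stiffness = bend_stiffness,
                 rest_angle = rest_angle,
                 regime_tag = regime_tag),
            class = "linker_spec")
}

#' @export
print.linker_spec <- function(x, ...) {
  cat(sprintf("linker_spec: %d beads, regime %s, bend stiffness %.3g kcal/mol/rad^2\n",
              x$n_beads, x$regime_tag, x$bend_stiffness))
  invisible(x)
}

bead_frame <- function(charge, radius, mass, molecule, domain, xyz) {
  data.frame(id = seq_len(nrow(xyz)) - 1L,
             charge = charge, radius = radius, mass = mass,
             molecule = molecule, domain = domain,
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             stringsAsFactors = FALSE)
}

#' Bead topology container
#'
#' Bundles the static description of a bead-model system: the bead table
#' (charge, radius, mass, molecule/domain labels and build coordinates),
#' harmonic bonds, harmonic angles and the periodic box side.
#'
#' @param beads Data frame with columns `id` (0-based, unique), `charge` (e),
#'   `radius` (Angstrom, > 0), `mass` (amu, > 0), `molecule`
#'   (`"receptor"`/`"ligand"`), `domain` (`"N"`, `"C"`, `"linker"`,
#'   `"ligand"`), `x`, `y`, `z` (Angstrom).
#' @param bonds Data frame with columns `i`, `j` (bead ids), `r0` (Angstrom),
#'   `k` (kcal/mol/A^2); may have zero rows.
#' @param angles Data frame with columns `i`, `j`, `k` (bead ids), `theta0`
#'   (radians), `kang` (kcal/mol/rad^2); may have zero rows.
#' @param box_side Cubic box side in Angstrom (> 0), or `NA` for a fragment.
#' @return An object of class `bead_topology`.
#' @export
bead_topology <- function(beads, bonds = NULL, angles = NULL, box_side = NA) {
  empty_bonds <- data.frame(i = integer(), j = integer(),
                            r0 = numeric(), k = numeric())
  empty_angles <- data.frame(i = integer(), j = integer(), k = integer(),
                             theta0 = numeric(), kang = numeric())
  if (is.null(bonds)) bonds <- empty_bonds
  if (is.null(angles)) angles <- empty_angles
  topo <- structure(list(beads = beads, bonds = bonds, angles = angles,
                         box_side = box_side),
                    class = "bead_topology")
  validate_topology(topo)
  topo
}

validate_topology <- function(topo) {
  b <- topo$beads
  req <- c("id", "charge", "radius", "mass", "molecule", "domain",
           "x", "y", "z")
  if (!all(req %in% names(b))) stop("bead table missing required columns")
  if (anyDuplicated(b$id)) stop("bead ids must be unique")
  if (any(b$radius <= 0)) stop("bead radii must be > 0")
  if (any(b$mass <= 0)) stop("bead masses must be > 0")
  if (!all(b$molecule %in% c("receptor", "ligand"))) {
    stop("molecule labels must be 'receptor' or 'ligand'")
  }
  ids <- b$id
  if (nrow(topo$bonds) > 0 &&
      !all(c(topo$bonds$i, topo$bonds$j) %in% ids)) {
    stop("bond references a non-existent bead id")
  }
  if (nrow(topo$angles) > 0 &&
      !all(c(topo$angles$i, topo$angles$j, topo$angles$k) %in% ids)) {
    stop("angle references a non-existent bead id")
  }
  if (!is.na(topo$box_side) && topo$box_side <= 0) {
    stop("box_side must be > 0")
  }
  invisible(topo)
}

#' @export
print.bead_topology <- function(x, ...) {
  b <- x$beads
  cat(sprintf("bead_topology: %d beads (%d receptor, %d ligand), %d bonds, %d angles\n",
              nrow(b), sum(b$molecule == "receptor"),
              sum(b$molecule == "ligand"), nrow(x$bonds), nrow(x$angles)))
  cat(sprintf("  net charge %+.2f e, box side %s A\n", sum(b$charge),
              ifelse(is.na(x$box_side), "<fragment>",
                     format(x$box_side))))
  invisible(x)
}

#' Extract bead coordinates as an N x 3 matrix
#'
#' @param topology A `bead_topology`.
#' @return Numeric matrix of build coordinates in Angstrom.
#' @export
coords <- function(topology) {
  as.matrix(topology$beads[, c("x", "y", "z")])
}

# Ring scaffold for one rigid domain: stacked rings of beads about the x axis.
# Returns an n x 3 coordinate matrix. Ring radius/spacing shape the binding
# channel the two domains enclose.
domain_rings <- function(n_beads, x_positions, ring_radius, beads_per_ring) {
  xyz <- matrix(0, n_beads, 3)
  idx <- 1L
  for (ri in seq_along(x_positions)) {
    n_here <- min(beads_per_ring, n_beads - (ri - 1L) * beads_per_ring)
    if (n_here <= 0) break
    # stagger alternate rings for tighter packing
    phi0 <- (ri %% 2) * pi / beads_per_ring
    ang <- phi0 + 2 * pi * (seq_len(n_here) - 1) / beads_per_ring
    xyz[idx:(idx + n_here - 1L), ] <-
      cbind(x_positions[ri], ring_radius * sin(ang), ring_radius * cos(ang))
    idx <- idx + n_here
  }
  xyz
}

# Circular arc joining two anchor points, bulging toward +z, with total arc
# length (n+1)*spacing. Returns n interior points evenly spaced along it.
arc_points <- function(p_from, p_to, n, spacing) {
  chord <- sqrt(sum((p_to - p_from)^2))
  len <- (n + 1) * spacing
  t <- seq_len(n) / (n + 1)
  if (len <= chord + 1e-9) { # nearly straight: interpolate
    return(t(vapply(t, function(u) p_from + u * (p_to - p_from),
                    numeric(3))))
  }
  # solve R*theta = len, 2R sin(theta/2) = chord for theta in (0, 2*pi)
  f <- function(theta) sin(theta / 2) / theta - chord / (2 * len)
  theta <- stats::uniroot(f, c(1e-8, 2 * pi - 1e-8), tol = 1e-12)$root
  R <- len / theta
  h <- sqrt(max(0, R^2 - (chord / 2)^2))
  u <- (p_to - p_from) / chord
  zhat <- c(0, 0, 1)
  w <- zhat - sum(zhat * u) * u
  if (sqrt(sum(w^2)) < 1e-9) w <- c(1, 0, 0) - sum(c(1, 0, 0) * u) * u
  w <- w / sqrt(sum(w^2))
  mid <- (p_from + p_to) / 2
  beta <- atan2(h, chord / 2)
  if (theta <= pi) {           # shallow arc: centre on the far side of w
    yc <- -h
    a0 <- pi - beta
  } else {                     # loop: centre on the bulge side
    yc <- h
    a0 <- -pi + beta
  }
  ang <- a0 - t * theta
  lx <- R * cos(ang)           # local chord-direction coordinate
  ly <- yc + R * sin(ang)      # local bulge-direction coordinate
  t(vapply(seq_len(n), function(i) mid + lx[i] * u + ly[i] * w, numeric(3)))
}

#' Build the synthetic two-domain receptor
#'
#' Constructs a rigid-domain receptor: each domain is a half-channel of bead
#' rings stacked along the x axis, the two domains facing each other across a
#' short gap so that together they enclose a cylindrical binding channel
#' (emulating a two-lobed protein wrapping a helical target). The domains are
#' joined by a linker chain arched over the channel, with harmonic bonds and
#' angle terms whose stiffness comes from the linker regime.
#'
#' @param n_domain_beads Beads per domain (>= 3).
#' @param linker A [linker_spec()].
#' @param net_charge Total receptor charge in e, spread uniformly over
#'   domain beads unless `groove_charge_fraction > 0`.
#' @param bead_radius,bead_mass Per-bead radius (Angstrom) and mass (amu).
#' @param ring_radius Channel radius in Angstrom (default 5).
#' @param ring_spacing Ring spacing along the channel axis (default 3.5).
#' @param beads_per_ring Beads per ring (default 5).
#' @param groove_charge_fraction Fraction of `net_charge` carried by the
#'   channel-lining (innermost-ring) beads, emulating a charge-focused
#'   binding groove; 0 spreads the charge uniformly.
#' @return A `bead_topology` fragment (box side `NA`).
#' @export
build_receptor <- function(n_domain_beads = 40, linker = linker_spec(),
                           net_charge = -16, bead_radius = 2.3,
                           bead_mass = 72, ring_radius = 5,
                           ring_spacing = 3.5, beads_per_ring = 5,
                           groove_charge_fraction = 0) {
  if (!is.numeric(n_domain_beads) || n_domain_beads < 3 ||
      n_domain_beads != round(n_domain_beads)) {
    stop("`n_domain_beads` must be an integer >= 3")
  }
  if (!inherits(linker, "linker_spec")) stop("`linker` must be a linker_spec")
  if (groove_charge_fraction < 0 || groove_charge_fraction > 1) {
    stop("`groove_charge_fraction` must be in [0, 1]")
  }
  n_dom <- as.integer(n_domain_beads)
  n_rings <- ceiling(n_dom / beads_per_ring)
  half_gap <- ring_spacing / 2
  x_c <- half_gap + (seq_len(n_rings) - 1) * ring_spacing
  xyz_C <- domain_rings(n_dom, x_c, ring_radius, beads_per_ring)
  xyz_N <- xyz_C
  xyz_N[, 1] <- -xyz_N[, 1]

  # linker anchors: topmost bead (max z) of each innermost ring
  iN <- which.max(ifelse(abs(xyz_N[, 1]) < half_gap + ring_spacing / 2 + 1e-9,
                         xyz_N[, 3], -Inf))
  iC <- which.max(ifelse(abs(xyz_C[, 1]) < half_gap + ring_spacing / 2 + 1e-9,
                         xyz_C[, 3], -Inf))
  nl <- linker$n_beads
  bond_rest <- 3.5
  xyz_L <- arc_points(xyz_N[iN, ], xyz_C[iC, ], nl, bond_rest)

  xyz <- rbind(xyz_N, xyz_C, xyz_L)
  n_tot <- nrow(xyz)
  domain <- c(rep("N", n_dom), rep("C", n_dom), rep("linker", nl))

  charge <- numeric(n_tot)
  if (groove_charge_fraction > 0) {
    inner <- which(domain != "linker" & abs(xyz[, 1]) < ring_spacing)
    if (length(inner) == 0) inner <- seq_len(2 * n_dom)
    charge[inner] <- net_charge * groove_charge_fraction / length(inner)
    rest <- setdiff(which(domain != "linker"), inner)
    charge[rest] <- net_charge * (1 - groove_charge_fraction) / length(rest)
  } else {
    charge[domain != "linker"] <- net_charge / (2 * n_dom)
  }

  beads <- bead_frame(charge, bead_radius, bead_mass, "receptor", domain, xyz)

  # bonds along the linker chain, anchored into both domains
  chain <- c(iN - 1L, 2L * n_dom + seq_len(nl) - 1L, n_dom + iC - 1L)
  seg <- cbind(chain[-length(chain)], chain[-1])
  r0 <- sqrt(rowSums((xyz[seg[, 1] + 1L, , drop = FALSE] -
                        xyz[seg[, 2] + 1L, , drop = FALSE])^2))
  bonds <- data.frame(i = seg[, 1], j = seg[, 2], r0 = r0, k = 0.5)

  # angle terms over consecutive chain triples
  tri <- cbind(chain[seq_len(length(chain) - 2)],
               chain[seq_len(length(chain) - 2) + 1],
               chain[seq_len(length(chain) - 2) + 2])
  theta0 <- if (!is.null(linker$rest_angle)) {
    rep(linker$rest_angle, nrow(tri))
  } else {
    apply(tri, 1, function(t3) {
      v1 <- xyz[t3[1] + 1L, ] - xyz[t3[2] + 1L, ]
      v2 <- xyz[t3[3] + 1L, ] - xyz[t3[2] + 1L, ]
      acos(pmin(1, pmax(-1, sum(v1 * v2) /
                          sqrt(sum(v1^2) * sum(v2^2)))))
    })
  }
  angles <- data.frame(i = tri[, 1], j = tri[, 2], k = tri[, 3],
                       theta0 = theta0, kang = linker$bend_stiffness)
  bead_topology(beads, bonds, angles, box_side = NA)
}

#' Build the synthetic rod ligand
#'
#' A rigid, uniformly charged, collinear bead rod standing in for a short
#' helical peptide (helical rise per bead, default 1.5 Angstrom).
#'
#' @param n_beads Number of beads (>= 2).
#' @param net_charge Total ligand charge in e, spread uniformly.
#' @param spacing Bond rest length between consecutive beads (Angstrom).
#' @param bead_radius,bead_mass Per-bead radius (Angstrom) and mass (amu).
#' @return A `bead_topology` fragment (box side `NA`).
#' @export
build_ligand <- function(n_beads = 25, net_charge = 5, spacing = 1.5,
                         bead_radius = 2.3, bead_mass = 72) {
  if (!is.numeric(n_beads) || n_beads < 2 || n_beads != round(n_beads)) {
    stop("`n_beads` must be an integer >= 2")
  }
  n <- as.integer(n_beads)
  x <- (seq_len(n) - (n + 1) / 2) * spacing
  xyz <- cbind(x, 0, 0)
  beads <- bead_frame(net_charge / n, bead_radius, bead_mass,
                      "ligand", "ligand", xyz)
  bonds <- data.frame(i = seq_len(n - 1) - 1L, j = seq_len(n - 1),
                      r0 = spacing, k = 50)
  bead_topology(beads, bonds, angles = NULL, box_side = NA)
}

#' Assemble receptor and ligand fragments into one periodic system
#'
#' Concatenates the two fragments (receptor first), re-indexing ligand bead
#' ids and bond references, with the ligand placed at its built (docked)
#' coordinates along the receptor channel axis.
#'
#' @param receptor,ligand `bead_topology` fragments from [build_receptor()]
#'   and [build_ligand()].
#' @param box_side Cubic box side in Angstrom (default 150).
#' @return A complete `bead_topology`.
#' @export
assemble_system <- function(receptor, ligand, box_side = 150) {
  stopifnot(inherits(receptor, "bead_topology"),
            inherits(ligand, "bead_topology"))
  off <- nrow(receptor$beads)
  lb <- ligand$beads
  lb$id <- lb$id + off
  beads <- rbind(receptor$beads, lb)
  lbonds <- ligand$bonds
  if (nrow(lbonds) > 0) {
    lbonds$i <- lbonds$i + off
    lbonds$j <- lbonds$j + off
  }
  langles <- ligand$angles
  if (nrow(langles) > 0) {
    langles$i <- langles$i + off
    langles$j <- langles$j + off
    langles$k <- langles$k + off
  }
  bead_topology(beads, rbind(receptor$bonds, lbonds),
                rbind(receptor$angles, langles), box_side = box_side)
}

#' Construct the reference (fully-bound) pose
#'
#' Docks the ligand rod into the receptor's inter-domain channel and verifies
#' that the pose satisfies the bound-state contact definition. A small line
#' search over axial offsets picks the placement maximising the contact
#' count; construction fails if the target cannot be reached.
#'
#' @param receptor,ligand `bead_topology` fragments.
#' @param target_contacts Minimum inter-molecular contact count the pose must
#'   satisfy (>= 50; the bound-state definition).
#' @param cutoff Contact cutoff in Angstrom (default 5.5).
#' @param box_side Box side for the assembled system (default 150).
#' @return An object of class `reference_pose`: a list with `topology` (the
#'   assembled system), `coordinates` (N x 3 matrix of the bound complex) and
#'   `contact_count`.
#' @export
make_reference_pose <- function(receptor, ligand, target_contacts = 50,
                                cutoff = 5.5, box_side = 150) {
  if (target_contacts < 50) {
    stop("`target_contacts` must be >= 50 (the bound-state definition)")
  }
  topo <- assemble_system(receptor, ligand, box_side = box_side)
  xyz <- coords(topo)
  is_lig <- topo$beads$molecule == "ligand"
  best <- list(count = -1L, xyz = xyz)
  for (dx in seq(-5, 5, by = 0.5)) {
    trial <- xyz
    trial[is_lig, 1] <- trial[is_lig, 1] + dx
    cnt <- contact_count_xyz(trial, is_lig, cutoff, box_side)
    if (cnt > best$count) best <- list(count = cnt, xyz = trial)
  }
  if (best$count < target_contacts) {
    stop(sprintf(paste0("reference-pose construction failed: best contact ",
                        "count %d < target %d (geometry cannot support the ",
                        "bound-state definition)"),
                 best$count, target_contacts))
  }
  structure(list(topology = topo, coordinates = best$xyz,
                 contact_count = as.integer(best$count)),
            class = "reference_pose")
}

#' @export
print.reference_pose <- function(x, ...) {
  cat(sprintf("reference_pose: %d beads, %d contacts at 5.5 A\n",
              nrow(x$coordinates), x$contact_count))
  invisible(x)
}

# raw inter-molecular contact count on a coordinate matrix (minimum image)
contact_count_xyz <- function(xyz, is_ligand, cutoff, box_side) {
  rx <- xyz[!is_ligand, , drop = FALSE]
  lx <- xyz[is_ligand, , drop = FALSE]
  cnt <- 0L
  for (d in 1:3) {
    dd <- outer(rx[, d], lx[, d], "-")
    if (!is.na(box_side) && is.finite(box_side)) {
      dd <- dd - box_side * round(dd / box_side)
    }
    if (d == 1) acc <- dd^2 else acc <- acc + dd^2
  }
  sum(acc <= cutoff^2)
}

#' Serialize a topology to JSON
#'
#' @param topology A `bead_topology`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_topology_json <- function(topology, path) {
  validate_topology(topology)
  obj <- list(beads = topology$beads, bonds = topology$bonds,
              angles = topology$angles, box_side = topology$box_side)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       na = "null")
  invisible(path)
}

#' Read a topology from JSON
#'
#' @param path Path to a file written by [write_topology_json()].
#' @return A `bead_topology`.
#' @export
read_topology_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  box <- obj$box_side
  if (is.null(box)) box <- NA
  bead_topology(as.data.frame(obj$beads), as.data.frame(obj$bonds),
                as.data.frame(obj$angles), box_side = box)
}
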