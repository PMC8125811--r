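#' Per-frame observable series
#'
#' @param times Frame times in ns (strictly increasing).
#' @param values Per-frame scalar values (same length as `times`).
#' @param label Short label (e.g. `"contacts"`, `"com_distance"`).
#' @return An object of class `observable_series` (a data frame with
#'   columns `time` and `value`).
#' @export
observable_series <- function(times, values, label = "observable") {
  if (length(times) != length(values)) {
    stop("`times` and `values` must have equal length")
  }
  if (length(times) > 1 && any(diff(times) <= 0)) {
    stop("`times` must be strictly increasing")
  }
  structure(data.frame(time = times, value = values),
            class = c("observable_series", "data.frame"), label = label)
}

#' Count inter-molecular bead contacts in a frame
#'
#' One contact is any (receptor bead, ligand bead) pair within `cutoff`
#' (minimum-image distance); intra-molecular pairs are excluded and pairs
#' are counted once.
#'
#' @param frame N x 3 coordinate matrix (ideally recentred).
#' @param topology The system `bead_topology`.
#' @param cutoff Contact cutoff in Angstrom (default 5.5).
#' @param box_side Box side for minimum imaging (defaults to the topology's;
#'   `NA`/`Inf` disables imaging).
#' @return Integer contact count.
#' @export
count_contacts <- function(frame, topology, cutoff = 5.5, box_side = NULL) {
  if (cutoff <= 0) stop("`cutoff` must be > 0")
  if (is.null(box_side)) box_side <- topology$box_side
  contact_count_xyz(frame, topology$beads$molecule == "ligand",
                    cutoff, box_side)
}

weighted_com <- function(xyz, w) {
  if (sum(w) <= 0) stop("zero total mass in selection")
  colSums(xyz * w) / sum(w)
}

#' Receptor-ligand centre-of-mass distance
#'
#' Euclidean distance between the mass-weighted centroids of the two
#' molecules (frames are assumed recentred so no imaging is applied).
#'
#' @inheritParams count_contacts
#' @param mass_weighted Use bead masses as weights (default) or plain
#'   centroids.
#' @return Distance in Angstrom.
#' @export
com_distance <- function(frame, topology, mass_weighted = TRUE) {
  b <- topology$beads
  is_lig <- b$molecule == "ligand"
  w <- if (mass_weighted) b$mass else rep(1, nrow(b))
  cr <- weighted_com(frame[!is_lig, , drop = FALSE], w[!is_lig])
  cl <- weighted_com(frame[is_lig, , drop = FALSE], w[is_lig])
  sqrt(sum((cr - cl)^2))
}

# Kabsch: optimal rotation + translation superposing P (mobile) onto Q
# (target); returns the transform applied to arbitrary points.
kabsch_transform <- function(P, Q) {
  cp <- colMeans(P)
  cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp)
  Qc <- sweep(Q, 2, cq)
  if (qr(Pc)$rank < 2) {
    stop("alignment error: need at least 3 non-collinear alignment beads")
  }
  H <- t(Pc) %*% Qc
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  list(rotate = R, centre_from = cp, centre_to = cq)
}

apply_transform <- function(xyz, tr) {
  sweep(sweep(xyz, 2, tr$centre_from) %*% t(tr$rotate), 2, tr$centre_to, "+")
}

#' RMSD of a frame to the reference bound pose
#'
#' Superposes the frame onto the reference by the Kabsch algorithm over
#' `align_set` (default: all receptor beads), then reports the unweighted
#' root-mean-square deviation over `score_set` (default: all complex beads,
#' so unbound ligand placement dominates the value).
#'
#' @param frame N x 3 coordinate matrix.
#' @param reference A `reference_pose` (or an N x 3 coordinate matrix).
#' @param topology The system `bead_topology` (taken from the reference if
#'   omitted).
#' @param align_set,score_set 0-based bead id vectors; defaults as above.
#' @return RMSD in Angstrom.
#' @export
rmsd_to_reference <- function(frame, reference, topology = NULL,
                              align_set = NULL, score_set = NULL) {
  if (inherits(reference, "reference_pose")) {
    if (is.null(topology)) topology <- reference$topology
    ref_xyz <- reference$coordinates
  } else {
    ref_xyz <- reference
  }
  if (is.null(topology)) stop("`topology` required")
  b <- topology$beads
  if (is.null(align_set)) align_set <- b$id[b$molecule == "receptor"]
  if (is.null(score_set)) score_set <- b$id
  ai <- match(align_set, b$id)
  si <- match(score_set, b$id)
  if (length(ai) < 3) {
    stop("alignment error: need at least 3 non-collinear alignment beads")
  }
  tr <- kabsch_transform(frame[ai, , drop = FALSE],
                         ref_xyz[ai, , drop = FALSE])
  moved <- apply_transform(frame[si, , drop = FALSE], tr)
  sqrt(mean(rowSums((moved - ref_xyz[si, , drop = FALSE])^2)))
}

#' Radius of gyration of a bead selection
#'
#' Mass-weighted RMS distance of the selected beads from their weighted
#' centroid.
#'
#' @param frame N x 3 coordinate matrix.
#' @param topology The system `bead_topology`.
#' @param selection `"receptor"`, `"ligand"`, or a 0-based bead id vector.
#' @param mass_weighted Mass-weight both centroid and spread (default).
#' @return RG in Angstrom.
#' @export
radius_of_gyration <- function(frame, topology, selection = "receptor",
                               mass_weighted = TRUE) {
  b <- topology$beads
  idx <- if (is.character(selection)) {
    which(b$molecule == selection)
  } else {
    match(selection, b$id)
  }
  if (length(idx) == 0) stop("empty selection")
  w <- if (mass_weighted) b$mass[idx] else rep(1, length(idx))
  xyz <- frame[idx, , drop = FALSE]
  cm <- weighted_com(xyz, w)
  sqrt(sum(w * rowSums(sweep(xyz, 2, cm)^2)) / sum(w))
}

#' Compute the standard per-frame observables of a trajectory
#'
#' Recentres each frame, then evaluates contacts, centre-of-mass distance,
#' receptor radius of gyration and (when a reference is supplied) RMSD to
#' the reference pose.
#'
#' @param trajectory A `bd_trajectory` with recorded frames.
#' @param reference Optional `reference_pose` for the RMSD column.
#' @param cutoff Contact cutoff in Angstrom.
#' @param recenter Re-image frames before measuring (default TRUE).
#' @return A data frame with columns `time`, `contacts`, `com_distance`,
#'   `rg_receptor` and optionally `rmsd`.
#' @export
compute_observables <- function(trajectory, reference = NULL, cutoff = 5.5,
                                recenter = TRUE) {
  if (is.null(trajectory$frames)) stop("trajectory has no recorded frames")
  topo <- trajectory$topology
  nf <- length(trajectory$times)
  res <- data.frame(time = trajectory$times, contacts = NA_integer_,
                    com_distance = NA_real_, rg_receptor = NA_real_)
  if (!is.null(reference)) res$rmsd <- NA_real_
  for (f in seq_len(nf)) {
    xyz <- matrix(trajectory$frames[f, ], ncol = 3, byrow = TRUE)
    if (recenter) xyz <- autoimage_recenter(xyz, topo, trajectory$box_side)
    res$contacts[f] <- count_contacts(xyz, topo, cutoff,
                                      trajectory$box_side)
    res$com_distance[f] <- com_distance(xyz, topo)
    res$rg_receptor[f] <- radius_of_gyration(xyz, topo, "receptor")
    if (!is.null(reference)) {
      res$rmsd[f] <- rmsd_to_reference(xyz, reference, topo)
    }
  }
  res
}

# mass-weighted principal axes of a selection, with a fixed sign convention
# (largest-magnitude component of each axis positive, right-handed set)
principal_axes <- function(xyz, w) {
  cm <- weighted_com(xyz, w)
  xc <- sweep(xyz, 2, cm)
  C <- t(xc * w) %*% xc / sum(w)
  ev <- eigen(C, symmetric = TRUE)
  V <- ev$vectors
  for (k in 1:3) {
    j <- which.max(abs(V[, k]))
    if (V[j, k] < 0) V[, k] <- -V[, k]
  }
  if (det(V) < 0) V[, 3] <- -V[, 3]
  list(centre = cm, axes = V)
}

#' Spatial distribution of the ligand about the receptor
#'
#' For the frames picked by the selector (by default the bottleneck bands:
#' RMSD within 25-40 Angstrom and centre-of-mass distance within 60-100
#' Angstrom), the ligand centre of mass is expressed in the receptor's
#' principal-axes body frame and binned on a regular 3D grid.
#'
#' @param trajectories A list of `bd_trajectory` objects with frames.
#' @param reference A `reference_pose` (needed for the RMSD selector).
#' @param grid_spacing Voxel edge in Angstrom.
#' @param rmsd_band,dist_band Numeric length-2 selection bands in Angstrom.
#' @param selector Optional `function(rmsd, com_distance)` returning a
#'   logical frame mask, overriding the bands.
#' @return A list with `counts` (data frame `ix, iy, iz, count` of occupied
#'   voxels, 0-based indices), `grid_spacing`, `origin` and `n_selected`;
#'   voxel counts sum to the number of selected frames.
#' @export
approach_distribution <- function(trajectories, reference,
                                  grid_spacing = 5,
                                  rmsd_band = c(25, 40),
                                  dist_band = c(60, 100),
                                  selector = NULL) {
  if (grid_spacing <= 0) stop("`grid_spacing` must be > 0")
  if (inherits(trajectories, "bd_trajectory")) {
    trajectories <- list(trajectories)
  }
  if (is.null(selector)) {
    selector <- function(rmsd, com) {
      rmsd >= rmsd_band[1] & rmsd <= rmsd_band[2] &
        com >= dist_band[1] & com <= dist_band[2]
    }
  }
  pts <- matrix(numeric(0), 0, 3)
  for (traj in trajectories) {
    topo <- traj$topology
    b <- topo$beads
    is_lig <- b$molecule == "ligand"
    obs <- compute_observables(traj, reference)
    keep <- which(selector(obs$rmsd, obs$com_distance))
    for (f in keep) {
      xyz <- autoimage_recenter(
        matrix(traj$frames[f, ], ncol = 3, byrow = TRUE), topo,
        traj$box_side)
      pa <- principal_axes(xyz[!is_lig, , drop = FALSE], b$mass[!is_lig])
      lig_com <- weighted_com(xyz[is_lig, , drop = FALSE], b$mass[is_lig])
      pts <- rbind(pts, as.numeric(t(pa$axes) %*% (lig_com - pa$centre)))
    }
  }
  if (nrow(pts) == 0) stop("empty selection: no frames matched the selector")
  origin <- floor(apply(pts, 2, min) / grid_spacing) * grid_spacing
  idx <- floor(sweep(pts, 2, origin) / grid_spacing)
  key <- paste(idx[, 1], idx[, 2], idx[, 3])
  tab <- table(key)
  parts <- do.call(rbind, strsplit(names(tab), " "))
  counts <- data.frame(ix = as.integer(parts[, 1]),
                       iy = as.integer(parts[, 2]),
                       iz = as.integer(parts[, 3]),
                       count = as.integer(tab))
  list(counts = counts, grid_spacing = grid_spacing, origin = origin,
       n_selected = nrow(pts))
}
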