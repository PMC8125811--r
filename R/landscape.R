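#' Project trajectories onto (RMSD, COM distance)
#'
#' One point per frame per trajectory, with trial and frame provenance.
#'
#' @param trajectories A `bd_trajectory` or list of them (frames recorded).
#' @param reference A `reference_pose`.
#' @param recenter Re-image frames before measuring.
#' @return Data frame with columns `trial`, `frame`, `time`, `rmsd`,
#'   `com_distance`, `contacts`.
#' @export
project_trajectories <- function(trajectories, reference, recenter = TRUE) {
  if (inherits(trajectories, "bd_trajectory")) {
    trajectories <- list(trajectories)
  }
  out <- vector("list", length(trajectories))
  for (tr in seq_along(trajectories)) {
    obs <- compute_observables(trajectories[[tr]], reference,
                               recenter = recenter)
    out[[tr]] <- data.frame(trial = tr, frame = seq_len(nrow(obs)),
                            time = obs$time, rmsd = obs$rmsd,
                            com_distance = obs$com_distance,
                            contacts = obs$contacts)
  }
  do.call(rbind, out)
}

#' Gaussian-kernel density of projected points on a regular grid
#'
#' 2D KDE with Scott's-rule bandwidths (sd * n^(-1/6) per axis, times
#' `bandwidth_scale`), evaluated on a regular grid spanning the data range
#' padded by one bandwidth. The gridded density integrates to ~1.
#'
#' @param points Two-column matrix or data frame (x = RMSD, y = COM
#'   distance), >= 2 distinct points.
#' @param grid_size Cells per axis (default 100).
#' @param bandwidth_scale Scalar multiplier on the Scott bandwidths.
#' @return A list with `x`, `y` (cell-centre grids) and `density` (matrix,
#'   x indexing rows).
#' @export
density_kde <- function(points, grid_size = 100, bandwidth_scale = 1) {
  pts <- as.matrix(points[, 1:2])
  if (nrow(unique(pts)) < 2) {
    stop("bandwidth error: need at least 2 distinct points")
  }
  n <- nrow(pts)
  sdx <- stats::sd(pts[, 1])
  sdy <- stats::sd(pts[, 2])
  if (sdx == 0 || sdy == 0) {
    stop("bandwidth error: degenerate point cloud along one axis")
  }
  hx <- bandwidth_scale * sdx * n^(-1 / 6)
  hy <- bandwidth_scale * sdy * n^(-1 / 6)
  lims <- c(min(pts[, 1]) - hx, max(pts[, 1]) + hx,
            min(pts[, 2]) - hy, max(pts[, 2]) + hy)
  # MASS::kde2d's h is 4x the kernel sd
  k <- MASS::kde2d(pts[, 1], pts[, 2], h = c(4 * hx, 4 * hy),
                   n = grid_size, lims = lims)
  list(x = k$x, y = k$y, density = k$z)
}

#' Boltzmann inversion of a density grid into a free-energy surface
#'
#' E_PMF = -kB*T*ln(rho/rho_min) over cells with positive density, where
#' rho_min is the minimum density among cells above a floor of 1e-12 of the
#' maximum (cells below the floor are masked as `NA`). The surface is <= 0
#' with equality where rho = rho_min, and is invariant to rescaling rho.
#'
#' @param density A list from [density_kde()] (or any list with `x`, `y`,
#'   `density`).
#' @param temperature K.
#' @param floor_fraction Relative density floor defining rho_min's support.
#' @return An object of class `pmf_grid`: `x`, `y`, `density`, `energy`
#'   (kcal/mol), `rho_min`, `temperature`.
#' @export
boltzmann_invert <- function(density, temperature = 300,
                             floor_fraction = 1e-12) {
  rho <- density$density
  if (any(rho < 0)) stop("density must be non-negative")
  if (all(rho <= 0)) stop("all-zero density cannot be inverted")
  floor_val <- floor_fraction * max(rho)
  rho_min <- min(rho[rho > floor_val])
  kBT <- thermal_energy(temperature)
  energy <- matrix(NA_real_, nrow(rho), ncol(rho))
  pos <- rho > floor_val
  energy[pos] <- -kBT * log(rho[pos] / rho_min)
  structure(list(x = density$x, y = density$y, density = rho,
                 energy = energy, rho_min = rho_min,
                 temperature = temperature),
            class = "pmf_grid")
}

#' @export
print.pmf_grid <- function(x, ...) {
  cat(sprintf("pmf_grid: %d x %d cells, E in [%.3g, %.3g] kcal/mol at %g K\n",
              nrow(x$energy), ncol(x$energy),
              min(x$energy, na.rm = TRUE), max(x$energy, na.rm = TRUE),
              x$temperature))
  invisible(x)
}

#' Interpolate a PMF surface at points
#'
#' Nearest-cell lookup of the Boltzmann-inverted energy.
#'
#' @param pmf A `pmf_grid`.
#' @param x,y Point coordinates.
#' @return Energy values in kcal/mol (`NA` outside sampled support).
#' @export
pmf_lookup <- function(pmf, x, y) {
  ix <- pmin(pmax(findInterval(x, pmf$x - diff(pmf$x[1:2]) / 2), 1),
             length(pmf$x))
  iy <- pmin(pmax(findInterval(y, pmf$y - diff(pmf$y[1:2]) / 2), 1),
             length(pmf$y))
  pmf$energy[cbind(ix, iy)]
}

#' Count trials that reach the native-bound region
#'
#' A trial is counted when its projection enters the box
#' [0, rmsd_cut] x [0, dist_cut] near the origin of the (RMSD, COM
#' distance) plane at least once.
#'
#' @param projection Data frame from [project_trajectories()].
#' @param rmsd_cut,dist_cut Box cuts in Angstrom (> 0; defaults 10).
#' @return Integer count of native-binding trials.
#' @export
count_native_events <- function(projection, rmsd_cut = 10, dist_cut = 10) {
  if (rmsd_cut <= 0 || dist_cut <= 0) stop("cuts must be > 0")
  hit <- projection$rmsd <= rmsd_cut & projection$com_distance <= dist_cut
  length(unique(projection$trial[hit]))
}

#' Flag loosely-bound frames and verify thermodynamic favourability
#'
#' Flags projected points whose contact count meets the bound-state
#' threshold, and (when a PMF is supplied) summarises whether the flagged
#' points sit at negative free energy in the fitted landscape.
#'
#' @param projection Data frame from [project_trajectories()] (its
#'   `contacts` column must be frame-aligned with the points).
#' @param threshold Contact threshold (default 50, inclusive).
#' @param pmf Optional `pmf_grid` on the same (RMSD, COM distance) axes.
#' @return The projection with a logical `loosely_bound` column; when `pmf`
#'   is given, attributes `frac_favorable` (fraction of flagged points with
#'   E_PMF < 0) and `n_flagged`.
#' @export
loosely_bound_mask <- function(projection, threshold = 50, pmf = NULL) {
  if (is.null(projection$contacts)) {
    stop("alignment error: projection lacks a frame-aligned contact column")
  }
  projection$loosely_bound <- projection$contacts >= threshold
  if (!is.null(pmf)) {
    flagged <- projection[projection$loosely_bound, ]
    if (nrow(flagged) > 0) {
      e <- pmf_lookup(pmf, flagged$rmsd, flagged$com_distance)
      attr(projection, "frac_favorable") <- mean(e < 0, na.rm = TRUE)
    } else {
      attr(projection, "frac_favorable") <- NA_real_
    }
    attr(projection, "n_flagged") <- sum(projection$loosely_bound)
  }
  projection
}

#' Gaussian-mixture decomposition of a radius-of-gyration sample
#'
#' Fits unequal-variance Gaussian mixtures by EM for each candidate
#' component count and selects the best by BIC (via mclust). Peaks are
#' reported sorted ascending.
#'
#' @param rg_sample Numeric vector of RG values (>= 50).
#' @param k_candidates Component counts to try (default 1:3).
#' @return An object of class `mixture_fit`: `n_components`, `weights`,
#'   `means`, `sds` (sorted by mean), `bic` (selected model's BIC) and
#'   `bic_table`.
#' @export
fit_rg_mixture <- function(rg_sample, k_candidates = 1:3) {
  rg_sample <- rg_sample[!is.na(rg_sample)]
  if (length(rg_sample) < 50) stop("need a sample of at least 50 RG values")
  # Mclust evaluates `mclustBIC` in the calling frame; bind it locally so
  # the package need not be attached
  mclustBIC <- mclust::mclustBIC
  fit <- tryCatch(
    mclust::Mclust(rg_sample, G = k_candidates, modelNames = "V",
                   verbose = FALSE),
    error = function(e) NULL)
  if (is.null(fit)) stop("estimation error: EM failed to converge")
  ord <- order(fit$parameters$mean)
  structure(list(
    n_components = fit$G,
    weights = unname(fit$parameters$pro[ord]),
    means = unname(fit$parameters$mean[ord]),
    sds = sqrt(unname(fit$parameters$variance$sigmasq))[
      if (length(fit$parameters$variance$sigmasq) > 1) ord else 1],
    bic = unname(fit$bic),
    bic_table = fit$BIC
  ), class = "mixture_fit")
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf("mixture_fit: %d component(s), BIC %.1f\n",
              x$n_components, x$bic))
  for (k in seq_len(x$n_components)) {
    cat(sprintf("  mean %.2f A, sd %.2f A, weight %.3f\n",
                x$means[k], x$sds[k], x$weights[k]))
  }
  invisible(x)
}

#' Receptor RG sample over the pre-binding window
#'
#' Collects the receptor radius of gyration over all frames strictly before
#' each trial's first passage (censored trials contribute every frame);
#' trials that bind at the first frame are excluded with a warning.
#'
#' @param trajectories A `bd_trajectory` or list of them (frames recorded).
#' @param fpts Numeric vector of first passage times per trial (ns; `NA`
#'   for censored). Defaults to each trajectory's own `fpt`.
#' @return Numeric vector of RG values (Angstrom).
#' @export
pre_binding_rg_series <- function(trajectories, fpts = NULL) {
  if (inherits(trajectories, "bd_trajectory")) {
    trajectories <- list(trajectories)
  }
  if (is.null(fpts)) {
    fpts <- vapply(trajectories, function(t) {
      if (isTRUE(t$censored) || is.na(t$fpt)) NA_real_ else t$fpt
    }, numeric(1))
  }
  out <- numeric(0)
  for (tr in seq_along(trajectories)) {
    traj <- trajectories[[tr]]
    keep <- if (is.na(fpts[tr])) {
      seq_along(traj$times)
    } else {
      which(traj$times < fpts[tr])
    }
    if (length(keep) == 0) {
      warning("trial ", tr, " bound at the first frame; excluded")
      next
    }
    topo <- traj$topology
    for (f in keep) {
      xyz <- matrix(traj$frames[f, ], ncol = 3, byrow = TRUE)
      out <- c(out, radius_of_gyration(xyz, topo, "receptor"))
    }
  }
  out
}
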