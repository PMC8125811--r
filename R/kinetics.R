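#' Per-trial first-passage-time sample
#'
#' @param times First passage times in ns (one per trial; `NA` for censored
#'   trials).
#' @param censored Logical censoring flags (default: `is.na(times)`).
#' @param t_max Trial horizon in ns.
#' @return An object of class `fpt_sample`.
#' @export
fpt_sample <- function(times, censored = NULL, t_max = 2000) {
  if (is.null(censored)) censored <- is.na(times)
  if (length(censored) != length(times)) {
    stop("`censored` must match `times` in length")
  }
  ok <- !censored
  if (any(ok & (is.na(times) | times <= 0 | times > t_max + 1e-9))) {
    stop("uncensored times must lie in (0, t_max]")
  }
  structure(list(times = times, censored = censored, t_max = t_max,
                 n_trials = length(times)),
            class = "fpt_sample")
}

#' @export
print.fpt_sample <- function(x, ...) {
  nc <- sum(x$censored)
  cat(sprintf("fpt_sample: %d trials (%d censored), t_max %g ns\n",
              x$n_trials, nc, x$t_max))
  if (nc < x$n_trials) {
    cat(sprintf("  mean uncensored FPT %.4g ns\n",
                mean(x$times[!x$censored])))
  }
  invisible(x)
}

#' First passage time to the bound state from a contact series
#'
#' The bound state is reached at the first frame whose contact count meets
#' or exceeds `threshold` ("50 or more" is inclusive); a trial that never
#' reaches it is censored.
#'
#' @param contact_series An [observable_series()] of contact counts (or a
#'   data frame with `time` and `value` columns).
#' @param threshold Bound-state contact threshold (default 50).
#' @return A list with `fpt` (ns, `NA` if censored) and `censored`.
#' @export
detect_binding <- function(contact_series, threshold = 50) {
  if (is.null(contact_series) || nrow(contact_series) == 0) {
    stop("empty contact series")
  }
  hit <- which(contact_series$value >= threshold)
  if (length(hit) == 0) {
    list(fpt = NA_real_, censored = TRUE)
  } else {
    list(fpt = contact_series$time[hit[1]], censored = FALSE)
  }
}

#' Convert a coarse-grained-clock time to the all-atom clock
#'
#' The coarse-grained model's effective dynamics run faster than atomistic
#' dynamics; times are multiplied by `factor` (default 4) to compare with
#' experiment.
#'
#' @param fpt Time(s) in ns on the CG clock (>= 0).
#' @param factor Time-scale factor (default 4).
#' @return Time(s) in ns on the all-atom clock.
#' @export
apply_timescale <- function(fpt, factor = 4) {
  if (factor < 0) stop("`factor` must be >= 0")
  if (any(fpt < 0, na.rm = TRUE)) stop("`fpt` must be >= 0")
  fpt * factor
}

#' Bootstrap the mean first passage time
#'
#' Resamples the uncensored times with replacement (`n_boot` resamples of
#' the original size) and returns the mean of bootstrap means together with
#' their standard deviation.
#'
#' @param sample An [fpt_sample()].
#' @param n_boot Number of bootstrap resamples (default 1000).
#' @param seed Integer seed.
#' @return A list with `mean` (ns), `sd` (ns, dispersion of bootstrap
#'   means), `se_analytic` (ns, sd(times)/sqrt(n)), `boot_means` and
#'   `n_used`.
#' @export
bootstrap_mean_fpt <- function(sample, n_boot = 1000, seed = 1) {
  stopifnot(inherits(sample, "fpt_sample"))
  times <- sample$times[!sample$censored]
  if (length(times) == 0) {
    stop("estimation error: all trials censored, no first passage times")
  }
  set.seed(seed)
  n <- length(times)
  boot_means <- vapply(seq_len(n_boot), function(i) {
    mean(times[sample.int(n, n, replace = TRUE)])
  }, numeric(1))
  list(mean = mean(boot_means), sd = stats::sd(boot_means),
       se_analytic = stats::sd(times) / sqrt(n),
       boot_means = boot_means, n_used = n)
}

#' Association rate from the mean first passage time
#'
#' ka = 1 / (Tfp * c) with c = 1 / (NA * Vbox) the concentration equivalent
#' to one molecule in the simulation box.
#'
#' @param mean_tfp Mean first passage time in ns (all-atom clock).
#' @param box_volume Box volume in litres (default 3.375e-21, a 150
#'   Angstrom cube).
#' @return Association rate in 1/M/s.
#' @examples
#' ka_from_mean_fpt(2326.98) / 1e8 # about 8.73
#' @export
ka_from_mean_fpt <- function(mean_tfp, box_volume = 3.375e-21) {
  if (any(mean_tfp <= 0) || box_volume <= 0) {
    stop("`mean_tfp` and `box_volume` must be > 0")
  }
  conc <- 1 / (bk_constants$avogadro * box_volume)  # mol/L
  1 / (mean_tfp * 1e-9 * conc)
}

#' Full rate estimate from an FPT sample
#'
#' Bootstraps the mean first passage time, converts it to the all-atom
#' clock and applies the one-molecule-per-box concentration to obtain the
#' association rate with a propagated uncertainty. Censored trials are
#' excluded from the mean (their count is reported, plus a sensitivity
#' estimate treating censored times as `t_max`, which bounds the bias).
#'
#' @param sample An [fpt_sample()] on the CG clock.
#' @param box_volume Box volume in litres.
#' @param timescale_factor CG-to-all-atom clock factor (default 4; use 1
#'   for data already on the target clock).
#' @param n_boot,seed Bootstrap settings.
#' @return An object of class `rate_estimate` with `mean_tfp` (ns,
#'   all-atom), `tfp_sd`, `tfp_se`, `ka`, `ka_sd` (1/M/s), `concentration`
#'   (M), `n_trials`, `n_censored` and `ka_censored_sensitivity`.
#' @export
rate_estimate <- function(sample, box_volume = 3.375e-21,
                          timescale_factor = 4, n_boot = 1000, seed = 1) {
  bs <- bootstrap_mean_fpt(sample, n_boot = n_boot, seed = seed)
  mean_aa <- apply_timescale(bs$mean, timescale_factor)
  sd_aa <- bs$sd * timescale_factor
  ka <- ka_from_mean_fpt(mean_aa, box_volume)
  ka_sd <- ka * sd_aa / mean_aa  # delta method on 1/T
  sens <- {
    t_all <- ifelse(sample$censored, sample$t_max, sample$times)
    ka_from_mean_fpt(apply_timescale(mean(t_all), timescale_factor),
                     box_volume)
  }
  structure(list(
    mean_tfp = mean_aa, tfp_sd = sd_aa,
    tfp_se = bs$se_analytic * timescale_factor,
    ka = ka, ka_sd = ka_sd,
    box_volume = box_volume,
    concentration = 1 / (bk_constants$avogadro * box_volume),
    timescale_factor = timescale_factor,
    n_trials = sample$n_trials, n_censored = sum(sample$censored),
    ka_censored_sensitivity = sens
  ), class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf("rate_estimate: Tfp = %.2f +/- %.2f ns (all-atom clock, x%g)\n",
              x$mean_tfp, x$tfp_sd, x$timescale_factor))
  cat(sprintf("  ka = %.3g +/- %.2g /M/s  (%d trials, %d censored)\n",
              x$ka, x$ka_sd, x$n_trials, x$n_censored))
  invisible(x)
}

#' Exponential fit of a first-passage-time distribution
#'
#' Maximum-likelihood fit of A*exp(-tau*x): for an exponential distribution
#' the MLE is tau = 1/mean; A is the implied density amplitude at x = 0.
#' Reports the Kolmogorov-Smirnov distance to the fitted distribution as a
#' convergence/goodness statistic.
#'
#' @param fpts Numeric vector of uncensored first passage times (>= 10
#'   values), ns.
#' @return An object of class `exponential_fit` with `amplitude`, `rate`
#'   (1/ns), `ks_statistic` and `ks_p`.
#' @export
fit_exponential <- function(fpts) {
  fpts <- fpts[!is.na(fpts)]
  if (length(fpts) < 10) {
    stop("estimation error: need at least 10 uncensored times")
  }
  if (stats::sd(fpts) == 0) {
    warning("degenerate fit: all times identical")
  }
  tau <- 1 / mean(fpts)
  ks <- suppressWarnings(stats::ks.test(fpts, "pexp", rate = tau))
  structure(list(amplitude = tau, rate = tau,
                 ks_statistic = unname(ks$statistic), ks_p = ks$p.value),
            class = "exponential_fit")
}

#' @export
print.exponential_fit <- function(x, ...) {
  cat(sprintf("exponential_fit: tau = %.4g /ns (mean %.4g ns), KS D = %.3f\n",
              x$rate, 1 / x$rate, x$ks_statistic))
  invisible(x)
}

#' Welch's t-test between two first-passage-time samples
#'
#' Applied to the per-trial uncensored times (not to bootstrap means, which
#' would inflate significance).
#'
#' @param sample_a,sample_b [fpt_sample()] objects (>= 2 uncensored times
#'   each).
#' @return A list with `statistic`, `p_value`, `df` and the two means.
#' @export
compare_conditions <- function(sample_a, sample_b) {
  a <- sample_a$times[!sample_a$censored]
  b <- sample_b$times[!sample_b$censored]
  if (length(a) < 2 || length(b) < 2) {
    stop("need at least 2 uncensored times per sample")
  }
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (isTRUE(all.equal(mean(a), mean(b)))) {
      return(list(statistic = 0, p_value = 1, df = NA_real_,
                  mean_a = mean(a), mean_b = mean(b)))
    }
    stop("test error: both samples have zero variance")
  }
  tt <- stats::t.test(a, b, var.equal = FALSE)
  list(statistic = unname(tt$statistic), p_value = tt$p.value,
       df = unname(tt$parameter), mean_a = mean(a), mean_b = mean(b))
}
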