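#' Absolute labeling efficiency from construct counts
#'
#' The defining ratio of the assay: among constructs carrying a detected
#' reference label, the fraction that also carries a detected target label,
#' `n_ref_target / (n_ref + n_ref_target)`. It is independent of the
#' reference binder's own labeling efficiency.
#'
#' @param n_ref Number of constructs with only the reference labeled.
#' @param n_ref_target Number of constructs with both labeled.
#' @return Labeling efficiency in \[0, 1\].
#' @export
labeling_efficiency <- function(n_ref, n_ref_target) {
  if (n_ref < 0 || n_ref_target < 0) stop("labeling_efficiency: counts must be >= 0")
  if (n_ref + n_ref_target == 0) stop("labeling_efficiency: both counts are zero")
  n_ref_target / (n_ref + n_ref_target)
}

#' Fit configuration
#'
#' Controls the Monte-Carlo least-squares grid search shared by the
#' labeling-efficiency and dimer-fraction fits. The objective is a noisy
#' one-dimensional function of the mixture proportion, so a global grid
#' scan with common random numbers across candidates (the same seeds per
#' realization index) is used: it keeps the residual curve smooth and the
#' argmin deterministic given the seed.
#'
#' @param grid_step Candidate grid step for the fitted proportion
#'   (default 0.01).
#' @param n_realizations Simulated realizations averaged per candidate
#'   (default 20).
#' @param d_max_nm Upper distance limit of the least-squares comparison
#'   (default 500 nm); the far tail carries density information only,
#'   which is already matched by construction.
#' @param seed Base seed; realization i uses seed + i.
#' @param refine Parabolic refinement of the argmin from its two grid
#'   neighbors (default off, so the returned estimate is exactly the grid
#'   argmin of the reported residual curve).
#' @return A `fit_config` list.
#' @export
fit_config <- function(grid_step = 0.01, n_realizations = 20L, d_max_nm = 500,
                       seed = 1L, refine = FALSE) {
  if (grid_step <= 0 || grid_step > 0.5) stop("fit_config: grid_step must be in (0, 0.5]")
  if (n_realizations < 1) stop("fit_config: n_realizations must be >= 1")
  if (d_max_nm <= 0) stop("fit_config: d_max_nm must be > 0")
  structure(list(grid_step = grid_step, n_realizations = as.integer(n_realizations),
                 d_max_nm = d_max_nm, seed = as.integer(seed), refine = refine),
            class = "fit_config")
}

# Mean simulated histogram density over realizations; simulate_fn(seed)
# must return a distance vector (possibly length 0).
.mean_sim_density <- function(simulate_fn, bin_edges, n_realizations, seed) {
  nb <- length(bin_edges) - 1L
  acc <- rep(0, nb)
  for (i in seq_len(n_realizations)) {
    d <- simulate_fn(seed + i)
    h <- histogram_nnd(d, bin_edges)
    acc <- acc + h$density
  }
  acc / n_realizations
}

.fit_bins <- function(bin_edges, d_max_nm) which(bin_edges[-1] <= d_max_nm)

# Vertex of the parabola through the grid argmin and its two neighbors
# (uniform spacing h): x* = x2 + h/2 * (y1 - y3) / (y1 - 2*y2 + y3).
.parabolic_refine <- function(grid, rss, i) {
  if (i == 1 || i == length(grid)) return(grid[i])
  y <- rss[(i - 1):(i + 1)]
  denom <- y[1] - 2 * y[2] + y[3]
  if (denom <= 0) return(grid[i])
  h <- grid[i] - grid[i - 1]
  grid[i] + 0.5 * h * (y[1] - y[3]) / denom
}

#' Fit labeling efficiency to a cross-NND histogram
#'
#' Scans candidate labeling efficiencies on a grid in `[0, LE_max]` with
#' `LE_max = min(1, rho_target_obs / rho_ref_obs)`. Each candidate LE fixes
#' the mixture by density matching — the simulated total density in each
#' channel equals the experimentally observed one:
#' `rho_dimer = LE * rho_ref_obs`, `rho_ref_mono = rho_ref_obs - rho_dimer`,
#' `rho_target_mono = rho_target_obs - rho_dimer`. For each candidate,
#' `n_realizations` two-channel CSR fields are simulated, the mean
#' cross-NND density histogram is computed on the experimental bins, and
#' the candidate minimizing the sum of squared per-bin density differences
#' (over bins up to `d_max_nm`) is returned together with the full
#' residual curve.
#'
#' @param exp_hist Experimental cross-NND histogram ([histogram_nnd()]),
#'   reference channel against target channel.
#' @param rho_ref_obs,rho_target_obs Observed molecule densities (um^-2)
#'   in the reference and target channel; both > 0.
#' @param d_off Dimer distance in nm (binder geometry).
#' @param uncertainty Per-axis positional sigma in nm.
#' @param roi The `roi` the data were analyzed in (simulations run in the
#'   same geometry so edge effects match).
#' @param config A [fit_config()].
#' @return An `le_fit` list: `labeling_efficiency`, `p_ref`,
#'   `p_ref_target`, `residual_curve` (data.frame `le`, `rss`),
#'   `best_residual`, `le_max`, `n_realizations_used`, `seed`.
#' @export
fit_labeling_efficiency <- function(exp_hist, rho_ref_obs, rho_target_obs,
                                    d_off = 15, uncertainty = 5, roi,
                                    config = fit_config()) {
  stopifnot(inherits(exp_hist, "nnd_histogram"), inherits(config, "fit_config"))
  if (rho_ref_obs <= 0 || rho_target_obs <= 0) {
    stop("fit_labeling_efficiency: observed densities must be > 0")
  }
  if (exp_hist$n_points == 0) stop("fit_labeling_efficiency: empty experimental histogram")
  if (!inherits(roi, "roi") || roi_area(roi) <= 0) {
    stop("fit_labeling_efficiency: valid ROI with positive area required")
  }
  le_max <- min(1, rho_target_obs / rho_ref_obs)
  grid <- seq(0, le_max, by = config$grid_step)
  if (length(grid) < 2) stop("fit_labeling_efficiency: degenerate candidate grid")
  sel <- .fit_bins(exp_hist$bin_edges, config$d_max_nm)
  if (length(sel) == 0) stop("fit_labeling_efficiency: no histogram bins below d_max_nm")
  exp_d <- exp_hist$density[sel]

  rss <- vapply(grid, function(le) {
    rho_d <- le * rho_ref_obs
    p <- sim_params(roi, rho_ref_mono = rho_ref_obs - rho_d,
                    rho_target_mono = rho_target_obs - rho_d,
                    rho_dimer = rho_d, d_off = d_off, uncertainty = uncertainty)
    sim_d <- .mean_sim_density(function(s) {
      f <- simulate_two_channel_field(p, seed = s)
      if (sum(f$target$detected) == 0 || sum(f$reference$detected) == 0) {
        return(numeric(0))
      }
      cross_nnd(f$reference, f$target)
    }, exp_hist$bin_edges, config$n_realizations, config$seed)
    sum((sim_d[sel] - exp_d)^2)
  }, numeric(1))

  i <- which.min(rss)
  est <- if (config$refine) .parabolic_refine(grid, rss, i) else grid[i]
  est <- min(max(est, 0), le_max)
  structure(list(labeling_efficiency = est,
                 p_ref = 1 - est, p_ref_target = est,
                 residual_curve = data.frame(le = grid, rss = rss),
                 best_residual = rss[i], le_max = le_max,
                 n_realizations_used = config$n_realizations,
                 seed = config$seed,
                 d_off = d_off, uncertainty = uncertainty,
                 rho_ref_obs = rho_ref_obs, rho_target_obs = rho_target_obs),
            class = "le_fit")
}

#' @export
print.le_fit <- function(x, ...) {
  cat(sprintf("<le_fit: labeling efficiency %.3f (grid max %.3f, rss %.3g, %d realizations)>\n",
              x$labeling_efficiency, x$le_max, x$best_residual, x$n_realizations_used))
  invisible(x)
}

#' Fit the dimer fraction to a self-NND histogram
#'
#' Scans candidate dimer fractions f (fraction of molecules residing in
#' dimers, `f = 2*rho_dimer / (rho_mono + 2*rho_dimer)`) on a grid in
#' \[0, 1\]. Each candidate fixes the ground-truth densities through the
#' observed-density constraint
#' `(rho_mono + 2*rho_dimer) * labeling_efficiency = rho_obs`:
#' the total molecule density is `rho_tot = rho_obs / labeling_efficiency`,
#' with `rho_dimer = f * rho_tot / 2` (entities) and
#' `rho_mono = (1 - f) * rho_tot`. Single-channel fields are simulated with
#' detection thinning at `labeling_efficiency`, mean self-NND histograms
#' are compared to the experimental one, and the least-squares candidate is
#' returned. Running with `labeling_efficiency = 1` yields the "apparent"
#' (uncorrected) dimer fraction.
#'
#' @param exp_hist Experimental self-NND histogram.
#' @param rho_obs Observed molecule density (um^-2, > 0).
#' @param labeling_efficiency Measured labeling efficiency in (0, 1\]; 1
#'   gives the apparent fit.
#' @param d_off Dimer distance in nm.
#' @param uncertainty Per-axis positional sigma in nm.
#' @param roi The `roi`.
#' @param config A [fit_config()].
#' @return A `dimer_fit` list: `dimer_fraction` (molecule convention),
#'   `dimer_fraction_entities`, `rho_mono`, `rho_dimer`, `apparent` flag,
#'   `residual_curve`, `best_residual`, `seed`, plus the inputs needed by
#'   [correct_dimer_fraction()].
#' @export
fit_dimer_fraction <- function(exp_hist, rho_obs, labeling_efficiency = 1,
                               d_off = 15, uncertainty = 5, roi,
                               config = fit_config()) {
  stopifnot(inherits(exp_hist, "nnd_histogram"), inherits(config, "fit_config"))
  if (rho_obs <= 0) stop("fit_dimer_fraction: observed density must be > 0")
  if (labeling_efficiency <= 0 || labeling_efficiency > 1) {
    stop("fit_dimer_fraction: labeling_efficiency must be in (0, 1]")
  }
  if (!inherits(roi, "roi") || roi_area(roi) <= 0) {
    stop("fit_dimer_fraction: valid ROI with positive area required")
  }
  rho_tot <- rho_obs / labeling_efficiency
  grid <- seq(0, 1, by = config$grid_step)
  sel <- .fit_bins(exp_hist$bin_edges, config$d_max_nm)
  if (length(sel) == 0) stop("fit_dimer_fraction: no histogram bins below d_max_nm")
  exp_d <- exp_hist$density[sel]

  rss <- vapply(grid, function(f) {
    rho_dimer <- f * rho_tot / 2
    rho_mono <- (1 - f) * rho_tot
    p <- sim_params(roi, rho_ref_mono = rho_mono, rho_dimer = rho_dimer,
                    d_off = d_off, uncertainty = uncertainty,
                    labeling_efficiency = labeling_efficiency)
    sim_d <- .mean_sim_density(function(s) {
      field <- simulate_single_channel_field(p, seed = s)
      if (sum(field$detected) < 2) return(numeric(0))
      self_nnd(field)
    }, exp_hist$bin_edges, config$n_realizations, config$seed)
    sum((sim_d[sel] - exp_d)^2)
  }, numeric(1))

  i <- which.min(rss)
  f_hat <- if (config$refine) .parabolic_refine(grid, rss, i) else grid[i]
  f_hat <- min(max(f_hat, 0), 1)
  rho_dimer <- f_hat * rho_tot / 2
  rho_mono <- (1 - f_hat) * rho_tot
  structure(list(dimer_fraction = f_hat,
                 dimer_fraction_entities = if (rho_mono + rho_dimer > 0)
                   rho_dimer / (rho_mono + rho_dimer) else 0,
                 rho_mono = rho_mono, rho_dimer = rho_dimer,
                 apparent = labeling_efficiency == 1,
                 labeling_efficiency = labeling_efficiency,
                 residual_curve = data.frame(f = grid, rss = rss),
                 best_residual = rss[i], seed = config$seed,
                 rho_obs = rho_obs, d_off = d_off, uncertainty = uncertainty,
                 exp_hist = exp_hist, roi = roi, config = config),
            class = "dimer_fit")
}

#' @export
print.dimer_fit <- function(x, ...) {
  cat(sprintf("<dimer_fit (%s): dimer fraction %.3f at LE %.2f (rss %.3g)>\n",
              if (x$apparent) "apparent" else "corrected",
              x$dimer_fraction, x$labeling_efficiency, x$best_residual))
  invisible(x)
}

#' Labeling-efficiency-corrected dimer fraction
#'
#' Re-runs [fit_dimer_fraction()] on the same histogram and configuration,
#' replacing the apparent fit's full-labeling assumption with the measured
#' labeling efficiency. Thinning removes dimer partners independently, so
#' the apparent fraction underestimates the true one; the corrected
#' estimate is (within noise) independent of the binder's labeling
#' efficiency.
#'
#' @param apparent_fit A `dimer_fit` with `apparent = TRUE`.
#' @param labeling_efficiency Measured labeling efficiency in (0, 1\].
#' @return A corrected `dimer_fit` with the apparent one attached as
#'   `$apparent_fit`.
#' @export
correct_dimer_fraction <- function(apparent_fit, labeling_efficiency) {
  stopifnot(inherits(apparent_fit, "dimer_fit"))
  if (!apparent_fit$apparent) {
    stop("correct_dimer_fraction: fit is not flagged apparent")
  }
  corrected <- fit_dimer_fraction(
    exp_hist = apparent_fit$exp_hist, rho_obs = apparent_fit$rho_obs,
    labeling_efficiency = labeling_efficiency, d_off = apparent_fit$d_off,
    uncertainty = apparent_fit$uncertainty, roi = apparent_fit$roi,
    config = apparent_fit$config)
  corrected$apparent_fit <- apparent_fit
  corrected
}

#' Serialize a fit result as JSON
#'
#' Writes all parameters, the candidate grid, the residual curve and the
#' seed, so any fit can be reproduced exactly.
#'
#' @param fit An `le_fit` or `dimer_fit`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  x <- unclass(fit)
  x$exp_hist <- NULL; x$roi <- NULL; x$apparent_fit <- NULL
  x$config <- if (!is.null(fit$config)) unclass(fit$config) else NULL
  x$type <- if (inherits(fit, "le_fit")) "labeling_efficiency" else "dimer_fraction"
  jsonlite::write_json(x, path, digits = NA, auto_unbox = TRUE, dataframe = "columns")
  invisible(path)
}
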