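#' Synthetic-fixture configuration
#'
#' Parameters for generating DNA-PAINT-like synthetic data with known
#' ground truth: molecule positions from the CSR monomer/dimer forward
#' model, and per-molecule clouds of localizations with realistic
#' precisions. Binding kinetics and photophysics are not modeled — the
#' downstream analysis consumes only positions and precisions.
#'
#' @param sim A [sim_params()] describing the molecule populations.
#' @param mean_locs_per_molecule Mean localizations per molecule; counts
#'   are Poisson, truncated to >= 1 so every ground-truth molecule is in
#'   principle detectable (detection failures are modeled exclusively by
#'   [thin_by_detection()], keeping the two effects separable).
#' @param loc_precision_nm Either a scalar precision or `c(mean, sd)` of a
#'   lognormal from which per-localization precisions are drawn (default
#'   mean 4 nm, sd 1 nm — typical for high-quality DNA-PAINT).
#' @param n_frames Acquisition length in frames.
#' @param seed RNG seed.
#' @return A `fixture_config` list.
#' @export
fixture_config <- function(sim, mean_locs_per_molecule = 20,
                           loc_precision_nm = c(4, 1), n_frames = 10000L,
                           seed = 1L) {
  stopifnot(inherits(sim, "sim_params"))
  if (mean_locs_per_molecule <= 0) {
    stop("fixture_config: mean_locs_per_molecule must be > 0")
  }
  if (n_frames < 1) stop("fixture_config: n_frames must be >= 1")
  if (!length(loc_precision_nm) %in% c(1, 2) || any(loc_precision_nm < 0)) {
    stop("fixture_config: loc_precision_nm must be a scalar or c(mean, sd) >= 0")
  }
  structure(list(sim = sim, mean_locs_per_molecule = mean_locs_per_molecule,
                 loc_precision_nm = loc_precision_nm,
                 n_frames = as.integer(n_frames), seed = as.integer(seed)),
            class = "fixture_config")
}

#' Generate a ground-truth two-channel molecule field
#'
#' Delegates to [simulate_two_channel_field()] and attaches a truth record
#' with per-molecule population tags, dimer pairings and the true labeling
#' efficiency implied by the densities,
#' `LE = rho_dimer / (rho_ref_mono + rho_dimer)`.
#'
#' @param config A [fixture_config()].
#' @return A list `reference`, `target` (point fields) and `truth`
#'   (list with `true_le`, densities and the seed).
#' @export
generate_ground_truth <- function(config) {
  stopifnot(inherits(config, "fixture_config"))
  s <- config$sim
  fields <- simulate_two_channel_field(s, seed = config$seed)
  denom <- s$rho_ref_mono + s$rho_dimer
  list(reference = fields$reference, target = fields$target,
       truth = list(true_le = if (denom > 0) s$rho_dimer / denom else 0,
                    rho_ref_mono = s$rho_ref_mono,
                    rho_target_mono = s$rho_target_mono,
                    rho_dimer = s$rho_dimer, d_off = s$d_off,
                    uncertainty = s$uncertainty, seed = config$seed))
}

.draw_precisions <- function(n, spec) {
  if (length(spec) == 1) return(rep(spec[1], n))
  m <- spec[1]; s <- spec[2]
  if (s == 0) return(rep(m, n))
  sdlog2 <- log(1 + (s / m)^2)
  stats::rlnorm(n, meanlog = log(m) - sdlog2 / 2, sdlog = sqrt(sdlog2))
}

#' Generate a localization table around molecule positions
#'
#' Emulates the clouds of localizations that repeated imager binding
#' produces around each docking site: per molecule a truncated-Poisson
#' (>= 1) number of localizations, each offset by per-axis Gaussian noise
#' with sigma equal to its own drawn precision; precisions come from the
#' configured lognormal, frames are uniform over the acquisition.
#'
#' @param field A `point_field` (all points are used, detected or not;
#'   apply [thin_by_detection()] first to emulate incomplete labeling).
#' @param config A [fixture_config()].
#' @param seed Seed for this table; defaults to `config$seed + 1`.
#' @return A [localization_table()] plus attribute `molecule_index`
#'   mapping each localization to its row in `field`.
#' @export
generate_localizations <- function(field, config, seed = config$seed + 1L) {
  stopifnot(inherits(field, "point_field"), inherits(config, "fixture_config"))
  xy <- detected_points(field)
  n_mol <- nrow(xy)
  withr::with_seed(seed, {
    lam <- config$mean_locs_per_molecule
    counts <- stats::rpois(n_mol, lam)
    counts[counts == 0] <- 1L  # truncated: every molecule observable
    idx <- rep(seq_len(n_mol), counts)
    n_loc <- length(idx)
    lpx <- .draw_precisions(n_loc, config$loc_precision_nm)
    lpy <- .draw_precisions(n_loc, config$loc_precision_nm)
    tab <- localization_table(
      frame = sample.int(config$n_frames, n_loc, replace = TRUE) - 1L,
      x = xy[idx, 1] + stats::rnorm(n_loc, 0, lpx),
      y = xy[idx, 2] + stats::rnorm(n_loc, 0, lpy),
      photons = stats::rexp(n_loc, 1 / 3000),
      lpx = pmax(lpx, 1e-6), lpy = pmax(lpy, 1e-6),
      channel_label = attr(field, "channel"))
    attr(tab, "molecule_index") <- idx
    tab
  })
}

#' Write a complete fixture to disk
#'
#' Emits per-channel localization tables (CSV or Picasso-style HDF5) and a
#' truth JSON, so every pipeline stage can be exercised from files.
#'
#' @param config A [fixture_config()].
#' @param dir Output directory (created if needed).
#' @param format `"csv"` or `"hdf5"`.
#' @return Invisible list of written paths.
#' @export
write_fixture <- function(config, dir, format = c("csv", "hdf5")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gt <- generate_ground_truth(config)
  ext <- if (format == "csv") "csv" else "hdf5"
  paths <- list(
    reference = file.path(dir, paste0("reference_locs.", ext)),
    target = file.path(dir, paste0("target_locs.", ext)),
    truth = file.path(dir, "truth.json"))
  ref_locs <- generate_localizations(gt$reference, config, seed = config$seed + 1L)
  tgt_locs <- generate_localizations(gt$target, config, seed = config$seed + 2L)
  write_localizations(ref_locs, paths$reference, format = format)
  write_localizations(tgt_locs, paths$target, format = format)
  jsonlite::write_json(c(gt$truth, list(n_reference = nrow(gt$reference),
                                        n_target = nrow(gt$target))),
                       paths$truth, digits = NA, auto_unbox = TRUE)
  invisible(paths)
}
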