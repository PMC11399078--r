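#' Simulation parameters for CSR monomer/dimer mixtures
#'
#' The forward model behind every fit: molecules are placed with complete
#' spatial randomness (CSR, homogeneous Poisson process) inside the ROI.
#' Dimers are pairs of molecules separated laterally by the characteristic
#' offset `d_off` (set by the binder/linkage geometry); every molecule
#' position is additionally jittered by an isotropic Gaussian `uncertainty`
#' summarizing labeling and localization errors.
#'
#' @param roi An `roi`.
#' @param rho_ref_mono Reference-monomer density (um^-2).
#' @param rho_target_mono Target-monomer density (um^-2).
#' @param rho_dimer Dimer density in dimer entities per um^2 (each entity
#'   contributes two molecules).
#' @param d_off Expected dimer distance in nm (>= 0).
#' @param uncertainty Per-axis positional sigma in nm (>= 0).
#' @param labeling_efficiency Detection fraction in \[0, 1\]; used only by
#'   the single-channel oligomer model.
#' @param n_realizations Number of independent realizations (>= 1).
#' @param seed Base RNG seed.
#' @return A `sim_params` list.
#' @export
sim_params <- function(roi, rho_ref_mono = 0, rho_target_mono = 0, rho_dimer = 0,
                       d_off = 15, uncertainty = 5, labeling_efficiency = 1,
                       n_realizations = 1L, seed = 1L) {
  stopifnot(inherits(roi, "roi"))
  if (rho_ref_mono < 0 || rho_target_mono < 0 || rho_dimer < 0) {
    stop("sim_params: densities must be >= 0")
  }
  if (d_off < 0) stop("sim_params: d_off must be >= 0")
  if (uncertainty < 0) stop("sim_params: uncertainty must be >= 0")
  if (labeling_efficiency < 0 || labeling_efficiency > 1) {
    stop("sim_params: labeling_efficiency must be in [0, 1]")
  }
  if (n_realizations < 1) stop("sim_params: n_realizations must be >= 1")
  structure(list(roi = roi, rho_ref_mono = rho_ref_mono,
                 rho_target_mono = rho_target_mono, rho_dimer = rho_dimer,
                 d_off = d_off, uncertainty = uncertainty,
                 labeling_efficiency = labeling_efficiency,
                 n_realizations = as.integer(n_realizations),
                 seed = as.integer(seed)),
            class = "sim_params")
}

.point_field <- function(x, y, population, pair_id, channel, roi,
                         detected = NULL) {
  n <- length(x)
  out <- data.frame(x = as.numeric(x), y = as.numeric(y),
                    population = population,
                    pair_id = as.integer(pair_id),
                    detected = if (is.null(detected)) rep(TRUE, n) else detected)
  attr(out, "channel") <- channel
  attr(out, "roi") <- roi
  class(out) <- c("point_field", "data.frame")
  out
}

#' @export
print.point_field <- function(x, ...) {
  cat(sprintf("<point_field '%s': %d points (%d detected), %d dimer partners>\n",
              attr(x, "channel"), nrow(x), sum(x$detected),
              sum(x$population == "dimer_partner")))
  invisible(x)
}

#' Simulate a CSR monomer field
#'
#' Point count drawn as Poisson(density x area); positions independent
#' uniform over the ROI. Draws from the current RNG stream (callers seed).
#'
#' @param density Monomer density (um^-2, >= 0).
#' @param roi An `roi`.
#' @param channel Channel tag attached to the field.
#' @return A `point_field`.
#' @export
simulate_monomers <- function(density, roi, channel = "single") {
  stopifnot(density >= 0, inherits(roi, "roi"))
  n <- stats::rpois(1, density * roi_area(roi))
  p <- roi_runif(roi, n)
  .point_field(p$x, p$y, population = rep("monomer", n),
               pair_id = rep(NA_integer_, n), channel = channel, roi = roi)
}

#' Simulate a CSR dimer field
#'
#' Dimer centers are CSR inside the ROI; the two partners of each dimer
#' are placed symmetrically at +/- d_off/2 from the center along an
#' orientation drawn uniformly on \[0, 2*pi), so the partner separation is
#' exactly `d_off` before positional uncertainty is applied. Partner
#' points may fall slightly outside the ROI and are retained, so edge
#' behavior matches experimental data analyzed in the same ROI.
#'
#' @param density Dimer-entity density (um^-2, >= 0).
#' @param d_off Dimer distance in nm (>= 0).
#' @param roi An `roi`.
#' @param channels Length-2 character: channel tags for partners A and B.
#' @return A list of two `point_field`s, `a` and `b`, with matching
#'   `pair_id`.
#' @export
simulate_dimers <- function(density, d_off, roi, channels = c("reference", "target")) {
  stopifnot(density >= 0, d_off >= 0, inherits(roi, "roi"))
  n <- stats::rpois(1, density * roi_area(roi))
  ctr <- roi_runif(roi, n)
  theta <- stats::runif(n, 0, 2 * pi)
  dx <- cos(theta) * d_off / 2
  dy <- sin(theta) * d_off / 2
  pid <- seq_len(n)
  pop <- rep("dimer_partner", n)
  list(a = .point_field(ctr$x + dx, ctr$y + dy, pop, pid, channels[1], roi),
       b = .point_field(ctr$x - dx, ctr$y - dy, pop, pid, channels[2], roi))
}

#' Apply positional uncertainty to a point field
#'
#' Each point is displaced independently by isotropic Gaussian noise with
#' per-axis standard deviation `sigma`; `sigma = 0` is the identity.
#'
#' @param field A `point_field`.
#' @param sigma Per-axis standard deviation in nm (>= 0).
#' @return The jittered `point_field`.
#' @export
apply_uncertainty <- function(field, sigma) {
  stopifnot(inherits(field, "point_field"), sigma >= 0)
  if (sigma == 0 || nrow(field) == 0) return(field)
  field$x <- field$x + stats::rnorm(nrow(field), 0, sigma)
  field$y <- field$y + stats::rnorm(nrow(field), 0, sigma)
  field
}

#' Thin a point field by the detection probability
#'
#' Models incomplete labeling: each point is kept independently with
#' probability `fraction`; the `detected` flag is updated and pairing
#' information is preserved for the kept points.
#'
#' @param field A `point_field`.
#' @param fraction Detection probability in \[0, 1\].
#' @return The field with updated `detected` flags.
#' @export
thin_by_detection <- function(field, fraction) {
  stopifnot(inherits(field, "point_field"))
  if (fraction < 0 || fraction > 1) stop("thin_by_detection: fraction must be in [0, 1]")
  if (nrow(field) == 0) return(field)
  field$detected <- field$detected & (stats::runif(nrow(field)) < fraction)
  field
}

#' Detected coordinates of a point field
#'
#' @param field A `point_field`.
#' @return A two-column matrix (x, y in nm) of the detected points.
#' @export
detected_points <- function(field) {
  stopifnot(inherits(field, "point_field"))
  cbind(x = field$x[field$detected], y = field$y[field$detected])
}

.rbind_fields <- function(a, b, channel, roi) {
  # pair ids of b are shifted past those of a to stay unique
  shift <- if (any(!is.na(a$pair_id))) max(a$pair_id, na.rm = TRUE) else 0L
  b$pair_id <- b$pair_id + shift
  out <- rbind(as.data.frame(a), as.data.frame(b))
  .point_field(out$x, out$y, out$population, out$pair_id, channel, roi,
               detected = out$detected)
}

#' Simulate a two-channel reference/target field
#'
#' The cross-channel mixture behind labeling-efficiency fitting: the
#' reference channel is reference monomers plus dimer partner A, the
#' target channel is target monomers plus dimer partner B; positional
#' uncertainty is applied to every point. Expected channel densities are
#' `rho_ref_mono + rho_dimer` and `rho_target_mono + rho_dimer`. No
#' detection thinning is applied here: incomplete labeling enters through
#' the mixture proportions.
#'
#' @param params A [sim_params()].
#' @param seed Optional seed; if `NULL`, draws from the current RNG stream.
#' @return List with `point_field`s `reference` and `target`.
#' @export
simulate_two_channel_field <- function(params, seed = NULL) {
  stopifnot(inherits(params, "sim_params"))
  run <- function() {
    mono_ref <- simulate_monomers(params$rho_ref_mono, params$roi, "reference")
    mono_tgt <- simulate_monomers(params$rho_target_mono, params$roi, "target")
    dim <- simulate_dimers(params$rho_dimer, params$d_off, params$roi)
    ref <- .rbind_fields(mono_ref, dim$a, "reference", params$roi)
    tgt <- .rbind_fields(mono_tgt, dim$b, "target", params$roi)
    list(reference = apply_uncertainty(ref, params$uncertainty),
         target = apply_uncertainty(tgt, params$uncertainty))
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Simulate a single-channel monomer/dimer field with detection thinning
#'
#' The forward model for oligomerization analysis of one protein species:
#' monomers at `rho_ref_mono` plus both partners of dimers at `rho_dimer`
#' (entities), positional uncertainty applied, then detection thinning at
#' `labeling_efficiency`. The expected detected density is
#' `(rho_ref_mono + 2 * rho_dimer) * labeling_efficiency`.
#'
#' @param params A [sim_params()]; `rho_ref_mono` is the monomer density and
#'   `rho_target_mono` is ignored.
#' @param seed Optional seed; if `NULL`, draws from the current RNG stream.
#' @return A single `point_field` with `detected` flags set.
#' @export
simulate_single_channel_field <- function(params, seed = NULL) {
  stopifnot(inherits(params, "sim_params"))
  run <- function() {
    mono <- simulate_monomers(params$rho_ref_mono, params$roi, "single")
    dim <- simulate_dimers(params$rho_dimer, params$d_off, params$roi,
                           channels = c("single", "single"))
    field <- .rbind_fields(.rbind_fields(mono, dim$a, "single", params$roi),
                           dim$b, "single", params$roi)
    # partners of one dimer must share a pair id: undo the shift of .rbind
    n_dim <- sum(dim$a$population == "dimer_partner")
    if (n_dim > 0) {
      is_b <- seq_len(nrow(field)) > (nrow(mono) + n_dim)
      field$pair_id[is_b] <- field$pair_id[is_b] - n_dim
    }
    field <- apply_uncertainty(field, params$uncertainty)
    thin_by_detection(field, params$labeling_efficiency)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
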