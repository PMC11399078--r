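.as_xy <- function(p) {
  if (inherits(p, "point_field")) return(detected_points(p))
  if (inherits(p, "molecule_set")) return(cbind(x = p$xc, y = p$yc))
  if (is.data.frame(p)) return(cbind(x = p$x, y = p$y))
  m <- as.matrix(p)
  stopifnot(ncol(m) == 2)
  m
}

#' Cross nearest-neighbor distances
#'
#' For each reference point, the Euclidean distance to the closest target
#' point. This is the core colocalization statistic: with incomplete
#' labeling the cross-NND distribution is a mixture of a short-distance
#' dimer mode (around `d_off`, broadened by uncertainty) and a long CSR
#' background mode. Note that `cross_nnd(ref, target)` is not symmetric in
#' its arguments.
#'
#' Exact KD-tree search (FNN) is used; results match exhaustive all-pairs
#' computation.
#'
#' @param ref,target Point sets: two-column matrices, `point_field`s
#'   (detected points only) or `molecule_set`s. Coordinates in nm.
#' @return Numeric vector of distances (nm), one per reference point.
#' @export
cross_nnd <- function(ref, target) {
  r <- .as_xy(ref); t <- .as_xy(target)
  if (nrow(t) == 0) stop("cross_nnd: target point set is empty; no neighbor defined")
  if (nrow(r) == 0) return(numeric(0))
  FNN::get.knnx(t, r, k = 1L)$nn.dist[, 1]
}

#' Self nearest-neighbor distances
#'
#' For each point, the distance to its nearest other point in the same set
#' (self excluded). Used by the single-channel oligomerization analysis.
#'
#' @param points A point set (matrix, `point_field` or `molecule_set`).
#' @return Numeric vector of distances (nm), one per point.
#' @export
self_nnd <- function(points) {
  p <- .as_xy(points)
  if (nrow(p) < 2) stop("self_nnd: need at least 2 points")
  FNN::get.knnx(p, p, k = 2L)$nn.dist[, 2]
}

#' Density-normalized nearest-neighbor-distance histogram
#'
#' Bins distances into a probability-density histogram. Distances at or
#' beyond the last edge are accumulated into a recorded overflow mass so
#' that in-bin mass plus overflow equals 1; with bins covering the full
#' range, `sum(density * diff(bin_edges)) == 1`.
#'
#' @param distances Non-negative distances in nm.
#' @param bin_edges Strictly increasing bin edges in nm (default 10 nm bins
#'   from 0 to 1000 nm).
#' @param keep_distances Retain the raw distances in the result.
#' @return An `nnd_histogram` list: `bin_edges`, `density` (1/nm),
#'   `counts`, `n_points`, `overflow_mass`, optionally `raw_distances`.
#' @export
histogram_nnd <- function(distances, bin_edges = seq(0, 1000, by = 10),
                          keep_distances = FALSE) {
  if (any(diff(bin_edges) <= 0)) stop("histogram_nnd: bin_edges must be strictly increasing")
  if (length(distances) > 0 && any(distances < 0)) {
    stop("histogram_nnd: distances must be >= 0")
  }
  nb <- length(bin_edges) - 1L
  widths <- diff(bin_edges)
  n <- length(distances)
  if (n == 0) {
    h <- list(bin_edges = bin_edges, density = rep(0, nb), counts = rep(0L, nb),
              n_points = 0L, overflow_mass = 0)
  } else {
    idx <- findInterval(distances, bin_edges, left.open = FALSE)
    counts <- tabulate(idx[idx >= 1 & idx <= nb], nbins = nb)
    n_over <- sum(idx > nb) + sum(idx < 1)  # idx < 1: below first edge
    h <- list(bin_edges = bin_edges, density = counts / (n * widths),
              counts = counts, n_points = n, overflow_mass = n_over / n)
  }
  if (keep_distances) h$raw_distances <- distances
  structure(h, class = "nnd_histogram")
}

#' @export
print.nnd_histogram <- function(x, ...) {
  cat(sprintf("<nnd_histogram: %d distances, %d bins [%g, %g] nm, overflow %.3f>\n",
              x$n_points, length(x$density), min(x$bin_edges), max(x$bin_edges),
              x$overflow_mass))
  invisible(x)
}

#' Write an NND histogram as JSON
#'
#' @param hist An `nnd_histogram`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_nnd_histogram <- function(hist, path) {
  stopifnot(inherits(hist, "nnd_histogram"))
  jsonlite::write_json(
    list(bin_edges_nm = hist$bin_edges, density_per_nm = hist$density,
         counts = hist$counts, n_points = hist$n_points,
         overflow_mass = hist$overflow_mass),
    path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
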