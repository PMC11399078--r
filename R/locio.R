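#' Localization table constructor
#'
#' A localization table holds per-localization records for one imaging
#' channel: acquisition frame, position (nm), photon count and per-axis
#' localization precision (nm). Input files are assumed drift-corrected and
#' channel-aligned upstream.
#'
#' @param frame Integer frame indices (>= 0).
#' @param x,y Positions in nm.
#' @param photons Photon counts (>= 0).
#' @param lpx,lpy Localization precisions in nm (strictly positive).
#' @param channel_label Free-text channel identifier.
#' @return A `localization_table` (a data.frame with attribute
#'   `channel_label`).
#' @export
localization_table <- function(frame = integer(0), x = numeric(0), y = numeric(0),
                               photons = numeric(0), lpx = numeric(0),
                               lpy = numeric(0), channel_label = "") {
  n <- length(x)
  stopifnot(length(y) == n, length(frame) == n, length(photons) == n,
            length(lpx) == n, length(lpy) == n)
  if (n > 0) {
    if (any(!is.finite(x)) || any(!is.finite(y))) {
      stop("localization_table: coordinates must be finite")
    }
    if (any(lpx <= 0) || any(lpy <= 0)) {
      stop("localization_table: localization precisions must be strictly positive")
    }
  }
  out <- data.frame(frame = as.integer(frame), x = as.numeric(x), y = as.numeric(y),
                    photons = as.numeric(photons), lpx = as.numeric(lpx),
                    lpy = as.numeric(lpy))
  attr(out, "channel_label") <- channel_label
  class(out) <- c("localization_table", "data.frame")
  out
}

.loc_fields <- c("frame", "x", "y", "photons", "lpx", "lpy")

#' Read a localization table
#'
#' Reads Picasso-style HDF5 (a compound dataset named `"locs"`, coordinates
#' and precisions in camera pixels) or CSV localization files. Coordinates
#' and precisions are converted to nm on read; a pixel value `v` becomes
#' `v * pixel_size_nm`. CSV files may declare their unit in a leading
#' comment line `# units: nm` (or `px`); without a declaration camera
#' pixels are assumed, matching the HDF5 convention.
#'
#' @param path Input file.
#' @param format `"auto"` (by extension), `"hdf5"` or `"csv"`.
#' @param pixel_size_nm Camera pixel size in nm (e.g. 130 for a typical
#'   sCMOS TIRF setup). Must be positive. Ignored for CSV files already
#'   declared in nm.
#' @param channel_label Channel identifier attached to the result.
#' @return A [localization_table()].
#' @export
read_localizations <- function(path, format = c("auto", "hdf5", "csv"),
                               pixel_size_nm = 130, channel_label = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("read_localizations: file not found: ", path)
  if (!is.numeric(pixel_size_nm) || length(pixel_size_nm) != 1 || pixel_size_nm <= 0) {
    stop("read_localizations: pixel_size_nm must be a positive scalar")
  }
  if (format == "auto") {
    format <- if (grepl("\\.(hdf5|h5|hdf)$", path, ignore.case = TRUE)) "hdf5" else "csv"
  }
  if (format == "hdf5") {
    df <- tryCatch(rhdf5::h5read(path, "locs"),
                   error = function(e) stop("read_localizations: no 'locs' dataset in ", path))
    df <- as.data.frame(lapply(df, as.vector))
    units_px <- TRUE
  } else {
    first <- readLines(path, n = 1L)
    units_px <- TRUE
    if (startsWith(first, "#")) {
      if (grepl("units?\\s*:?\\s*nm", first, ignore.case = TRUE)) units_px <- FALSE
    }
    df <- utils::read.csv(path, comment.char = "#")
  }
  missing <- setdiff(.loc_fields, names(df))
  if (length(missing) > 0) {
    stop("read_localizations: missing required field(s): ", paste(missing, collapse = ", "))
  }
  s <- if (units_px) pixel_size_nm else 1
  localization_table(frame = df$frame, x = df$x * s, y = df$y * s,
                     photons = df$photons, lpx = df$lpx * s, lpy = df$lpy * s,
                     channel_label = channel_label %||% basename(path))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a localization table
#'
#' CSV output is written in nm with a `# units: nm` comment line, so a
#' round-trip through [read_localizations()] is lossless. HDF5 output uses
#' the Picasso layout: a compound `"locs"` dataset in camera pixels plus a
#' YAML sidecar (`<file>.yaml`) recording the pixel size.
#'
#' @param locs A [localization_table()].
#' @param path Output file.
#' @param format `"auto"`, `"hdf5"` or `"csv"`.
#' @param pixel_size_nm Pixel size used to convert nm back to camera pixels
#'   for HDF5 output.
#' @return `path`, invisibly.
#' @export
write_localizations <- function(locs, path, format = c("auto", "hdf5", "csv"),
                                pixel_size_nm = 130) {
  stopifnot(inherits(locs, "localization_table"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(hdf5|h5|hdf)$", path, ignore.case = TRUE)) "hdf5" else "csv"
  }
  if (format == "csv") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("# units: nm (x, y, lpx, lpy)", con)
    utils::write.csv(as.data.frame(locs)[, .loc_fields], con, row.names = FALSE)
  } else {
    if (file.exists(path)) file.remove(path)
    df <- as.data.frame(locs)[, .loc_fields]
    for (col in c("x", "y", "lpx", "lpy")) df[[col]] <- df[[col]] / pixel_size_nm
    rhdf5::h5createFile(path)
    rhdf5::h5write(df, path, "locs")
    rhdf5::H5close()
    yaml::write_yaml(
      list(pixel_size_nm = pixel_size_nm,
           channel_label = attr(locs, "channel_label") %||% "",
           generated_by = "paintquant"),
      paste0(tools::file_path_sans_ext(path), ".yaml"))
  }
  invisible(path)
}

# Exact fixed-radius neighborhoods via k-NN with k-doubling: escalate k
# until the k-th neighbor of every point lies beyond `radius` (or k = n).
# Returns a list of integer neighbor index vectors (self excluded).
.radius_neighbors <- function(xy, radius) {
  n <- nrow(xy)
  if (n == 1) return(list(integer(0)))
  k <- min(n - 1, 32L)
  repeat {
    nn <- FNN::get.knnx(xy, xy, k = k + 1L)  # +1: self comes back first
    need_more <- nn$nn.dist[, k + 1L] <= radius
    if (!any(need_more) || k >= n - 1L) break
    k <- min(n - 1L, k * 2L)
  }
  idx <- nn$nn.index; d <- nn$nn.dist
  lapply(seq_len(n), function(i) {
    j <- idx[i, d[i, ] <= radius]
    j[j != i]
  })
}

#' Cluster localizations into molecule candidates
#'
#' Groups circular clouds of localizations around local maxima of the
#' neighbor count, the standard strategy for identifying individual
#' molecules in DNA-PAINT data. For every localization the number of
#' neighbors within `radius` is computed; a localization is a cluster seed
#' if its count is maximal among its neighbors (ties broken by the lowest
#' row index). Cluster members are all localizations within `radius` of a
#' seed, each assigned to its nearest seed. Clusters with fewer than
#' `min_locs` members are dissolved into noise.
#'
#' With `frame_spread_check = TRUE`, clusters whose localization frames are
#' concentrated in a short stretch of the acquisition (inter-quartile frame
#' range below `frame_spread_min_fraction` of the total frame range) are
#' discarded; transient sticking artifacts produce such bursts, whereas
#' genuine DNA-PAINT docking sites are revisited throughout the movie.
#'
#' @param locs A [localization_table()].
#' @param radius Cluster radius in nm (> 0). A sensible default is about 3x
#'   the mean localization precision.
#' @param min_locs Minimum localizations per cluster (>= 1).
#' @param frame_spread_check Enable the temporal artifact filter
#'   (default off).
#' @param frame_spread_min_fraction Minimum IQR of member frames as a
#'   fraction of the acquisition length (default 0.2).
#' @return Integer vector of per-localization cluster ids (0-based, dense),
#'   with -1 marking noise.
#' @export
cluster_localizations <- function(locs, radius, min_locs = 10L,
                                  frame_spread_check = FALSE,
                                  frame_spread_min_fraction = 0.2) {
  stopifnot(inherits(locs, "localization_table"))
  if (!is.numeric(radius) || radius <= 0) stop("cluster_localizations: radius must be > 0")
  if (min_locs < 1) stop("cluster_localizations: min_locs must be >= 1")
  n <- nrow(locs)
  if (n == 0) return(integer(0))
  xy <- cbind(locs$x, locs$y)
  nbrs <- .radius_neighbors(xy, radius)
  counts <- lengths(nbrs) + 1L  # neighbor count including self

  # seed rule: count strictly greater than every neighbor's; ties broken by
  # lexicographic (x, y) order so the result is invariant to row order
  # (exact coordinate duplicates fall back to row index)
  lex_before <- function(i, j) {
    locs$x[i] < locs$x[j] |
      (locs$x[i] == locs$x[j] & (locs$y[i] < locs$y[j] |
                                   (locs$y[i] == locs$y[j] & i < j)))
  }
  is_seed <- vapply(seq_len(n), function(i) {
    j <- nbrs[[i]]
    if (length(j) == 0) return(TRUE)
    all(counts[i] > counts[j] | (counts[i] == counts[j] & lex_before(i, j)))
  }, logical(1))
  seeds <- which(is_seed)
  assignment <- rep(-1L, n)
  if (length(seeds) == 0) return(assignment)

  near <- FNN::get.knnx(xy[seeds, , drop = FALSE], xy, k = 1L)
  within <- near$nn.dist[, 1] <= radius
  assignment[within] <- near$nn.index[within, 1] - 1L

  # dissolve clusters below the membership threshold
  tab <- tabulate(assignment[assignment >= 0] + 1L, nbins = length(seeds))
  small <- which(tab < min_locs) - 1L
  assignment[assignment %in% small] <- -1L

  if (frame_spread_check && any(assignment >= 0)) {
    total_span <- max(locs$frame) - min(locs$frame) + 1L
    for (cl in unique(assignment[assignment >= 0])) {
      fr <- locs$frame[assignment == cl]
      if (stats::IQR(fr) < frame_spread_min_fraction * total_span) {
        assignment[assignment == cl] <- -1L
      }
    }
  }

  # dense relabeling 0..n_clusters-1 in order of first appearance
  keep <- assignment >= 0
  if (any(keep)) {
    assignment[keep] <- match(assignment[keep], unique(assignment[keep])) - 1L
  }
  assignment
}

#' Precision-weighted cluster center
#'
#' Center of a localization cloud computed as the weighted mean with
#' squared inverse localization precisions as weights:
#' `xc = sum(x_i / lpx_i^2) / sum(1 / lpx_i^2)` (and analogously for y).
#' The center uncertainty is the standard error of the weighted mean per
#' axis, `sqrt(1 / sum(w))`, combined over x and y as their root mean
#' square.
#'
#' @param cluster_locs A non-empty [localization_table()] subset (one
#'   cluster).
#' @return Named numeric vector `c(xc, yc, center_uncertainty)` in nm.
#' @export
weighted_center <- function(cluster_locs) {
  if (nrow(cluster_locs) == 0) stop("weighted_center: empty cluster")
  if (any(cluster_locs$lpx <= 0) || any(cluster_locs$lpy <= 0)) {
    stop("weighted_center: non-positive localization precision")
  }
  wx <- 1 / cluster_locs$lpx^2
  wy <- 1 / cluster_locs$lpy^2
  xc <- sum(cluster_locs$x * wx) / sum(wx)
  yc <- sum(cluster_locs$y * wy) / sum(wy)
  sx <- sqrt(1 / sum(wx))
  sy <- sqrt(1 / sum(wy))
  c(xc = xc, yc = yc, center_uncertainty = sqrt((sx^2 + sy^2) / 2))
}

#' Molecule set constructor
#'
#' @param xc,yc Molecule center positions (nm).
#' @param n_locs Localization count per molecule.
#' @param center_uncertainty Standard error of each center (nm).
#' @param roi The `roi` the set lives in.
#' @return A `molecule_set` data.frame with columns `molecule_id`, `xc`,
#'   `yc`, `n_locs`, `center_uncertainty` and attribute `roi`.
#' @export
molecule_set <- function(xc = numeric(0), yc = numeric(0),
                         n_locs = integer(0), center_uncertainty = numeric(0),
                         roi = NULL) {
  n <- length(xc)
  stopifnot(length(yc) == n, length(n_locs) == n, length(center_uncertainty) == n)
  out <- data.frame(molecule_id = seq_len(n) - 1L, xc = as.numeric(xc),
                    yc = as.numeric(yc), n_locs = as.integer(n_locs),
                    center_uncertainty = as.numeric(center_uncertainty))
  attr(out, "roi") <- roi
  class(out) <- c("molecule_set", "data.frame")
  out
}

#' Build a molecule set from a cluster assignment
#'
#' One molecule per cluster via [weighted_center()]; molecules whose center
#' falls outside `roi` are dropped and ids renumbered densely from 0.
#'
#' @param locs A [localization_table()].
#' @param assignment Cluster ids from [cluster_localizations()] on `locs`.
#' @param roi An `roi`; defaults to the bounding rectangle of the centers.
#' @return A [molecule_set()].
#' @export
molecules_from_clusters <- function(locs, assignment, roi = NULL) {
  stopifnot(inherits(locs, "localization_table"), length(assignment) == nrow(locs))
  ids <- sort(unique(assignment[assignment >= 0]))
  if (length(ids) == 0) return(molecule_set(roi = roi))
  centers <- vapply(ids, function(cl) {
    sub <- locs[assignment == cl, , drop = FALSE]
    c(weighted_center(sub), n = nrow(sub))
  }, numeric(4))
  xc <- centers["xc", ]; yc <- centers["yc", ]
  if (is.null(roi)) roi <- roi_from_points(xc, yc)
  keep <- roi_contains(roi, xc, yc)
  molecule_set(xc = xc[keep], yc = yc[keep],
               n_locs = centers["n", keep],
               center_uncertainty = centers["center_uncertainty", keep],
               roi = roi)
}

#' Molecule density within the ROI
#'
#' The binder-specificity readout: number of detected molecules per unit
#' cell area.
#'
#' @param mols A [molecule_set()] with a valid `roi` attribute.
#' @return Density in molecules per um^2.
#' @export
binder_density <- function(mols) {
  stopifnot(inherits(mols, "molecule_set"))
  roi <- attr(mols, "roi")
  if (is.null(roi)) stop("binder_density: molecule set has no ROI")
  nrow(mols) / roi_area(roi)
}

#' Write a molecule set as CSV
#'
#' Columns: `molecule_id,xc_nm,yc_nm,n_locs,center_uncertainty_nm`.
#'
#' @param mols A [molecule_set()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_molecules <- function(mols, path) {
  stopifnot(inherits(mols, "molecule_set"))
  df <- data.frame(molecule_id = mols$molecule_id, xc_nm = mols$xc, yc_nm = mols$yc,
                   n_locs = mols$n_locs, center_uncertainty_nm = mols$center_uncertainty)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a molecule set from CSV
#'
#' @param path CSV written by [write_molecules()] (or pre-clustered
#'   molecule centers with the same columns).
#' @param roi Optional `roi`; defaults to the bounding rectangle.
#' @return A [molecule_set()].
#' @export
read_molecules <- function(path, roi = NULL) {
  if (!file.exists(path)) stop("read_molecules: file not found: ", path)
  df <- utils::read.csv(path, comment.char = "#")
  need <- c("xc_nm", "yc_nm")
  if (!all(need %in% names(df))) {
    stop("read_molecules: missing required column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "))
  }
  n <- nrow(df)
  if (is.null(roi) && n >= 2) roi <- roi_from_points(df$xc_nm, df$yc_nm)
  molecule_set(xc = df$xc_nm, yc = df$yc_nm,
               n_locs = df$n_locs %||% rep(1L, n),
               center_uncertainty = df$center_uncertainty_nm %||% rep(0, n),
               roi = roi)
}

#' @export
print.molecule_set <- function(x, ...) {
  roi <- attr(x, "roi")
  cat(sprintf("<molecule_set: %d molecules%s>\n", nrow(x),
              if (!is.null(roi)) sprintf(", %.1f um^2 ROI, %.2f um^-2",
                                         roi_area(roi), binder_density(x)) else ""))
  invisible(x)
}
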