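#' Per-cell group estimates
#'
#' Container for per-cell fractions (labeling efficiencies or dimer
#' fractions) of one experimental group, e.g. one binder or conjugation
#' strategy.
#'
#' @param label Group label.
#' @param values Per-cell estimates, fractions in \[0, 1\].
#' @return A `group_estimates` list with `label`, `values`, `n`.
#' @export
group_estimates <- function(label, values) {
  values <- as.numeric(values)
  if (any(!is.finite(values))) stop("group_estimates: non-finite value")
  if (any(values < 0 | values > 1)) {
    stop("group_estimates: values must be fractions in [0, 1]")
  }
  structure(list(label = label, values = values, n = length(values)),
            class = "group_estimates")
}

#' Percentile bootstrap confidence interval of the mean
#'
#' @param values Numeric sample (n >= 2).
#' @param n_boot Number of bootstrap resamples (default 10000).
#' @param level Confidence level in (0, 1) (default 0.95).
#' @param seed RNG seed; results are deterministic given the seed.
#' @return Named numeric vector `c(low, high)`.
#' @export
bootstrap_ci <- function(values, n_boot = 10000L, level = 0.95, seed = 1L) {
  if (inherits(values, "group_estimates")) values <- values$values
  n <- length(values)
  if (n < 2) stop("bootstrap_ci: need at least 2 values")
  if (level <= 0 || level >= 1) stop("bootstrap_ci: level must be in (0, 1)")
  means <- withr::with_seed(seed, {
    idx <- matrix(sample.int(n, n_boot * n, replace = TRUE), nrow = n_boot)
    rowMeans(matrix(values[idx], nrow = n_boot))
  })
  q <- stats::quantile(means, c((1 - level) / 2, 1 - (1 - level) / 2), names = FALSE)
  c(low = q[1], high = q[2])
}

#' Two-sided bootstrap ratio test
#'
#' Tests whether two groups of per-cell fractions share a mean, via
#' bootstrap resampling of the ratio of group means. Each group is
#' resampled independently with replacement (`n_boot` times, resampling
#' unit = cell).
#'
#' Three constructions of the two-sided p-value are offered:
#' `"studentized"` (default) is a bootstrap-t test of the log ratio — each
#' resample's centered log ratio is divided by its own delta-method
#' standard error and compared to the observed studentized statistic,
#' `p = Pr(|t*| >= |t_obs|)`. Studentization keeps the type-I error close
#' to nominal even at the small per-group n typical of per-cell analyses
#' (the test suite verifies calibration at n = 7), where the plain
#' percentile forms over-reject. `"ratio"` is the percentile construction
#' `2 * min(Pr[ratio <= 1], Pr[ratio >= 1])`, and `"log_ratio"` the
#' basic-bootstrap pivot `Pr(|t* - t| >= |t|)`. All three use a +1
#' continuity correction in numerator and denominator (so p is never 0)
#' and are capped at 1; all are deterministic given the seed, invariant
#' to common rescaling of both groups, and symmetric under swapping the
#' groups (the resampling indices are drawn in a canonical group order).
#'
#' @param group_a,group_b [group_estimates()] objects (or plain numeric
#'   vectors), both with n >= 2 and positive means.
#' @param n_boot Number of bootstrap resamples (default 10000).
#' @param seed RNG seed.
#' @param pivot `"studentized"` (default), `"ratio"` or `"log_ratio"`.
#' @return A `ratio_test` list: `ratio_of_means`, `p_value`, `n_boot`,
#'   `seed`, `pivot`.
#' @export
bootstrap_ratio_test <- function(group_a, group_b, n_boot = 10000L, seed = 1L,
                                 pivot = c("studentized", "ratio", "log_ratio")) {
  pivot <- match.arg(pivot)
  a <- if (inherits(group_a, "group_estimates")) group_a$values else as.numeric(group_a)
  b <- if (inherits(group_b, "group_estimates")) group_b$values else as.numeric(group_b)
  if (length(a) < 2 || length(b) < 2) {
    stop("bootstrap_ratio_test: both groups need n >= 2")
  }
  if (mean(a) <= 0 || mean(b) <= 0) {
    stop("bootstrap_ratio_test: group means must be > 0 (ratio undefined)")
  }

  # draw resampling indices in a canonical (scale-free, content-based)
  # group order so that swapping the arguments provably preserves p
  key <- function(x) {
    paste(length(x), paste(format(x / mean(c(a, b)), digits = 7), collapse = ","))
  }
  a_first <- key(a) <= key(b)
  draws <- withr::with_seed(seed, {
    n1 <- if (a_first) length(a) else length(b)
    n2 <- if (a_first) length(b) else length(a)
    list(i1 = matrix(sample.int(n1, n_boot * n1, replace = TRUE), nrow = n_boot),
         i2 = matrix(sample.int(n2, n_boot * n2, replace = TRUE), nrow = n_boot))
  })
  idx_a <- if (a_first) draws$i1 else draws$i2
  idx_b <- if (a_first) draws$i2 else draws$i1

  boot_stats <- function(x, idx) {
    n <- ncol(idx)
    m1 <- rowMeans(matrix(x[idx], nrow = nrow(idx)))
    m2 <- rowMeans(matrix(x[idx]^2, nrow = nrow(idx)))
    list(mean = m1, var = pmax(m2 - m1^2, 0) * n / (n - 1))
  }
  sa <- boot_stats(a, idx_a)
  sb <- boot_stats(b, idx_b)
  obs <- mean(a) / mean(b)

  if (pivot == "studentized") {
    se_log <- function(mx, vx, nx, my, vy, ny) {
      sqrt(vx / (nx * mx^2) + vy / (ny * my^2))
    }
    se_obs <- se_log(mean(a), stats::var(a), length(a),
                     mean(b), stats::var(b), length(b))
    if (se_obs == 0) {
      # both groups constant: degenerate, decide on the point ratio
      p <- if (obs == 1) 1 else 1 / (n_boot + 1)
    } else {
      t_obs <- log(obs) / se_obs
      se_star <- se_log(sa$mean, sa$var, length(a), sb$mean, sb$var, length(b))
      ok <- is.finite(se_star) & se_star > 0 & sa$mean > 0 & sb$mean > 0
      t_star <- (log(sa$mean[ok] / sb$mean[ok]) - log(obs)) / se_star[ok]
      p <- min(1, (sum(abs(t_star) >= abs(t_obs)) + 1) / (length(t_star) + 1))
    }
  } else if (pivot == "ratio") {
    ratios <- sa$mean / sb$mean
    p_low <- (sum(ratios <= 1) + 1) / (n_boot + 1)
    p_high <- (sum(ratios >= 1) + 1) / (n_boot + 1)
    p <- min(1, 2 * min(p_low, p_high))
  } else {
    ratios <- sa$mean / sb$mean
    t_obs <- log(obs)
    delta <- log(ratios[ratios > 0]) - t_obs
    p <- min(1, (sum(abs(delta) >= abs(t_obs)) + 1) / (length(delta) + 1))
  }
  structure(list(ratio_of_means = obs, p_value = p, n_boot = as.integer(n_boot),
                 seed = as.integer(seed), pivot = pivot,
                 label_a = if (inherits(group_a, "group_estimates")) group_a$label else "A",
                 label_b = if (inherits(group_b, "group_estimates")) group_b$label else "B"),
            class = "ratio_test")
}

#' @export
print.ratio_test <- function(x, ...) {
  stars <- if (x$p_value < 0.001) "***" else if (x$p_value < 0.01) "**"
           else if (x$p_value < 0.05) "*" else "n.s."
  cat(sprintf("<ratio_test %s/%s: ratio of means %.3f, p = %.4g (%s; %d resamples)>\n",
              x$label_a, x$label_b, x$ratio_of_means, x$p_value, stars, x$n_boot))
  invisible(x)
}
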