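#' Randomly perturb the class thresholds
#'
#' Each threshold `b_r` is replaced by an independent uniform draw from
#' `[b_r (1 - delta), b_r (1 + delta)]`. The perturbation ranges must
#' not allow thresholds to cross or to leave `(0, 1)`; this is checked
#' before any draw.
#'
#' @param profile A [class_profile()].
#' @param delta Relative half-width of the perturbation (e.g. `0.10`
#'   for +/-10 percent).
#' @return A new [class_profile()] with perturbed thresholds.
#' @export
perturb_profile <- function(profile, delta) {
  check_delta(profile, delta)
  b <- profile$thresholds
  class_profile(profile$labels,
                stats::runif(length(b), b * (1 - delta), b * (1 + delta)))
}

check_delta <- function(profile, delta) {
  stopifnot(inherits(profile, "class_profile"))
  if (!is.numeric(delta) || length(delta) != 1L || delta < 0)
    stop("delta must be a single non-negative number")
  b <- profile$thresholds
  if (b[1L] * (1 - delta) <= 0 || b[length(b)] * (1 + delta) >= 1)
    stop("delta = ", delta, " pushes a threshold outside (0, 1)")
  if (length(b) > 1L) {
    hi <- b[-length(b)] * (1 + delta)
    lo <- b[-1L] * (1 - delta)
    if (any(hi >= lo))
      stop("delta = ", delta, " lets adjacent thresholds cross ",
           "(ranges overlap)")
  }
  invisible(TRUE)
}

# Viable-set membership per class for fixed bounds under thresholds
# (vectorized over draws): returns a draws x alternatives matrix of
# set codes "M|B"-style strings are avoided -- classes are encoded as a
# bit mask (class r contributes 2^(r-1)).
viable_mask <- function(s1, s2, b_mat, tol = 1e-9) {
  n_draw <- nrow(b_mat)
  L <- ncol(b_mat) + 1L
  mask <- matrix(0L, n_draw, length(s1))
  for (r in seq_len(L)) {
    lo <- if (r == 1L) NULL else b_mat[, r - 1L]
    hi <- if (r == L) NULL else b_mat[, r]
    member <- matrix(TRUE, n_draw, length(s1))
    if (!is.null(lo))
      member <- member & outer(lo, s2, function(l, s) s > l + tol)
    if (!is.null(hi))
      member <- member & outer(hi, s1, function(h, s) s <= h + tol)
    mask <- mask + member * 2L^(r - 1L)
  }
  mask
}

set_to_mask <- function(viable_sets, labels) {
  vapply(viable_sets, function(s)
    sum(2L^(match(s, labels) - 1L)), numeric(1))
}

mask_to_top <- function(mask, L) {
  # most preferred class present in the mask
  top <- integer(length(mask))
  for (r in seq_len(L)) top[bitwAnd(as.integer(mask), 2L^(r - 1L)) > 0L] <- r
  top
}

#' Monte Carlo sensitivity of class assignments to the thresholds
#'
#' The global-value bounds `[s1, s2]` of each alternative are held fixed
#' (the thresholds do not enter the bounding LPs); only the class
#' thresholds are redrawn `n_draws` times within +/-`delta` and the
#' viable class sets recomputed. An alternative is stable in a draw when
#' its perturbed viable set equals its nominal one (default metric), or
#' when its recommended class is unchanged (`metric = "recommended"`).
#' Group aggregates are reported separately for the nominally
#' singly-classified and the nominally multiply-classified alternatives.
#'
#' @param bounds data.frame with columns `alternative`, `s1`, `s2` (for
#'   instance a [classify_all()] result, [huol_reference_bounds()], or
#'   [read_bounds()] output).
#' @param profile The nominal [class_profile()].
#' @param delta Relative half-width of the threshold perturbation.
#' @param n_draws Number of Monte Carlo draws (>= 1).
#' @param seed RNG seed; runs with the same seed are bit-identical.
#' @param metric `"viable"` (set equality) or `"recommended"`.
#' @param tol Band-edge tolerance, as in [assign_classes()].
#' @return Object of class `"sensitivity_report"`: list with `n_draws`,
#'   `delta`, `seed`, `metric`, `per_alternative` (data.frame:
#'   alternative, nominal viable set, n_classes, stability) and the
#'   group means `group_stability_single`, `group_stability_multi`
#'   (NA when a group is empty).
#' @export
run_sensitivity <- function(bounds, profile, delta = 0.10,
                            n_draws = 10000L, seed = 1L,
                            metric = c("viable", "recommended"),
                            tol = 1e-9) {
  metric <- match.arg(metric)
  stopifnot(inherits(profile, "class_profile"))
  if (!all(c("alternative", "s1", "s2") %in% names(bounds)))
    stop("bounds must have columns alternative, s1, s2")
  if (n_draws < 1L) stop("n_draws must be at least 1")
  check_delta(profile, delta)
  s1 <- bounds$s1; s2 <- bounds$s2
  labels <- profile$labels
  L <- length(labels)
  nominal_sets <- lapply(seq_along(s1), function(j)
    assign_classes(s1[j], s2[j], profile, tol = tol))
  nominal_mask <- set_to_mask(nominal_sets, labels)
  set.seed(seed)
  b <- profile$thresholds
  b_mat <- vapply(seq_along(b), function(r)
    stats::runif(n_draws, b[r] * (1 - delta), b[r] * (1 + delta)),
    numeric(n_draws))
  b_mat <- matrix(b_mat, nrow = n_draws)
  mask <- viable_mask(s1, s2, b_mat, tol = tol)
  if (metric == "viable") {
    stable <- sweep(mask, 2L, nominal_mask, `==`)
  } else {
    top_nom <- mask_to_top(nominal_mask, L)
    stable <- matrix(mask_to_top(mask, L) == rep(top_nom, each = n_draws),
                     n_draws, length(s1))
  }
  stability <- colMeans(stable)
  n_classes <- lengths(nominal_sets)
  single <- n_classes == 1L
  per_alt <- data.frame(
    alternative = bounds$alternative,
    nominal = vapply(nominal_sets, function(s)
      paste(rev(s), collapse = "|"), character(1)),
    n_classes = n_classes,
    stability = stability,
    stringsAsFactors = FALSE)
  structure(list(n_draws = as.integer(n_draws), delta = delta,
                 seed = seed, metric = metric,
                 per_alternative = per_alt,
                 group_stability_single =
                   if (any(single)) mean(stability[single]) else NA_real_,
                 group_stability_multi =
                   if (any(!single)) mean(stability[!single]) else NA_real_),
            class = "sensitivity_report")
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat(sprintf("threshold sensitivity: %d draws, delta = %.0f%%, seed = %s, metric = %s\n",
              x$n_draws, 100 * x$delta, format(x$seed), x$metric))
  cat(sprintf("  singly classified group:   %s\n",
              if (is.na(x$group_stability_single)) "none" else
                sprintf("%.2f%% stable", 100 * x$group_stability_single)))
  cat(sprintf("  multiply classified group: %s\n",
              if (is.na(x$group_stability_multi)) "none" else
                sprintf("%.2f%% stable", 100 * x$group_stability_multi)))
  invisible(x)
}

#' Write a sensitivity report to CSV
#'
#' Per-alternative nominal set and stability, followed by comment-line
#' footers carrying the group aggregates and run parameters.
#'
#' @param report A [run_sensitivity()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sensitivity <- function(report, path) {
  utils::write.csv(report$per_alternative, path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  footer <- c(
    sprintf("# group_stability_single,%s",
            format(report$group_stability_single, digits = 10)),
    sprintf("# group_stability_multi,%s",
            format(report$group_stability_multi, digits = 10)),
    sprintf("# n_draws,%d", report$n_draws),
    sprintf("# delta,%g", report$delta),
    sprintf("# seed,%s", format(report$seed)),
    sprintf("# metric,%s", report$metric))
  cat(footer, file = path, sep = "\n", append = TRUE)
  invisible(path)
}
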