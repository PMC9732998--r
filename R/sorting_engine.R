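#' Bound an alternative's global value over the weight space
#'
#' Solves the two linear programs min/max of `sum(k_i * v_i)` over the
#' current weight space, returning the interval `[s1, s2]` of global
#' values the alternative can take while the weights remain compatible
#' with everything the decision maker has stated.
#'
#' @param values The alternative's marginal values in `[0, 1]`. A named
#'   vector is matched to the space's criteria by name; an unnamed one
#'   is taken to be in ranking order already.
#' @param space A feasible [weight_space()].
#' @return Named numeric vector `c(s1 = , s2 = )`.
#' @examples
#' ws <- weight_space(c("a", "b", "c"), epsilon = 0)
#' solve_bounds(c(a = 0.6, b = 0.2, c = 1.0), ws)   # 0.4, 0.6
#' @export
solve_bounds <- function(values, space) {
  stopifnot(inherits(space, "weight_space"))
  if (!is.null(names(values))) {
    if (!setequal(names(values), space$ranking))
      stop("value names do not match the space's criteria")
    values <- values[space$ranking]
  }
  if (length(values) != space$n)
    stop("expected ", space$n, " marginal values, got ", length(values))
  if (any(values < -1e-9 | values > 1 + 1e-9))
    stop("marginal values must lie in [0, 1]")
  lo <- ws_lp(space, as.numeric(values), maximize = FALSE)
  hi <- ws_lp(space, as.numeric(values), maximize = TRUE)
  if (!lo$feasible || !hi$feasible) stop_infeasible()
  c(s1 = lo$value, s2 = hi$value)
}

#' Viable classes for a global-value interval
#'
#' Returns every class whose band intersects the closed interval
#' `[s1, s2]`. Bands are lower-open/upper-closed (the lowest is closed
#' at 0), so a bound falling exactly on a threshold belongs to the lower
#' band. A small tolerance absorbs solver noise before the band
#' comparison, so an `s` value within `tol` of a threshold is treated as
#' sitting on it.
#'
#' @param s1,s2 Minimum and maximum global value, `0 <= s1 <= s2 <= 1`.
#' @param profile A [class_profile()].
#' @param tol Numerical tolerance applied at band edges.
#' @return Character vector of viable labels, least preferred first
#'   (a subset of `profile$labels` in profile order).
#' @examples
#' prof <- class_profile()
#' assign_classes(0.2099, 0.4586, prof)   # "M" "B"
#' assign_classes(0.9050, 0.9372, prof)   # "W"
#' @export
assign_classes <- function(s1, s2, profile, tol = 1e-9) {
  stopifnot(inherits(profile, "class_profile"))
  if (!(s1 >= -tol && s2 <= 1 + tol && s1 <= s2 + tol))
    stop("need 0 <= s1 <= s2 <= 1 (got ", s1, ", ", s2, ")")
  lo <- c(0, profile$thresholds)
  hi <- c(profile$thresholds, 1)
  L <- length(profile$labels)
  keep <- logical(L)
  for (r in seq_len(L)) {
    # band r = (lo_r, hi_r], with band 1 closed at 0
    reaches_low <- if (r == 1L) TRUE else s2 > lo[r] + tol
    reaches_high <- s1 <= hi[r] + tol
    keep[r] <- reaches_low && reaches_high
  }
  profile$labels[keep]
}

#' Recommended class from a viable set
#'
#' Items spanning several viable classes are monitored at the cadence of
#' the most critical (most preferred) class in the set, the conservative
#' reading for inventory control.
#'
#' @param viable Nonempty character vector of class labels.
#' @param profile A [class_profile()].
#' @return A single class label.
#' @export
recommend_class <- function(viable, profile) {
  stopifnot(inherits(profile, "class_profile"), length(viable) >= 1L)
  idx <- match(viable, profile$labels)
  if (anyNA(idx)) stop("unknown class label(s): ",
                       paste(viable[is.na(idx)], collapse = ", "))
  profile$labels[max(idx)]
}

#' Classify every alternative over the current weight space
#'
#' Runs [solve_bounds()] for each row of the value matrix and maps the
#' resulting intervals to viable and recommended classes.
#'
#' @param values A [compute_value_matrix()] result (or any numeric
#'   matrix of marginal values with criteria as named columns).
#' @param space A feasible [weight_space()].
#' @param profile A [class_profile()].
#' @param tol Band-edge tolerance passed to [assign_classes()].
#' @return A data.frame of class `"classification_result"` with columns
#'   `alternative`, `s1`, `s2`, `viable` (labels joined by `"|"`, most
#'   critical first), `n_classes`, `recommended`; the number of singly
#'   classified alternatives is attached as attribute `"n_single"`.
#' @export
classify_all <- function(values, space, profile, tol = 1e-9) {
  v <- unclass(values)
  stopifnot(is.matrix(v), inherits(space, "weight_space"))
  alts <- rownames(v)
  if (is.null(alts)) alts <- as.character(seq_len(nrow(v)))
  res <- data.frame(alternative = alts, s1 = NA_real_, s2 = NA_real_,
                    viable = NA_character_, n_classes = NA_integer_,
                    recommended = NA_character_,
                    stringsAsFactors = FALSE)
  for (j in seq_len(nrow(v))) {
    b <- solve_bounds(v[j, ], space)
    vc <- assign_classes(b["s1"], b["s2"], profile, tol = tol)
    res$s1[j] <- b["s1"]; res$s2[j] <- b["s2"]
    res$viable[j] <- paste(rev(vc), collapse = "|")
    res$n_classes[j] <- length(vc)
    res$recommended[j] <- recommend_class(vc, profile)
  }
  attr(res, "n_single") <- sum(res$n_classes == 1L)
  class(res) <- c("classification_result", "data.frame")
  res
}

#' Summarize a classification
#'
#' @param results A [classify_all()] result (or a data.frame with
#'   columns `alternative`, `viable`, `n_classes`, `recommended`).
#' @param profile A [class_profile()] giving the label order.
#' @return A list with counts of singly/multiply classified items, per-
#'   class counts by recommendation and by viable-set involvement, and
#'   the ids whose viable set includes the most critical class.
#' @export
count_summary <- function(results, profile = class_profile()) {
  labs <- profile$labels
  top <- labs[length(labs)]
  if (nrow(results) == 0L) {
    z <- setNames(integer(length(labs)), labs)
    return(list(n = 0L, n_single = 0L, n_multi = 0L,
                by_recommended = z, by_viable = z,
                top_class_items = character(0)))
  }
  sets <- strsplit(results$viable, "|", fixed = TRUE)
  by_viable <- vapply(labs, function(l)
    sum(vapply(sets, function(s) l %in% s, logical(1))), integer(1))
  by_rec <- vapply(labs, function(l)
    sum(results$recommended == l), integer(1))
  involves_top <- vapply(sets, function(s) top %in% s, logical(1))
  list(n = nrow(results),
       n_single = sum(results$n_classes == 1L),
       n_multi = sum(results$n_classes > 1L),
       by_recommended = by_rec,
       by_viable = by_viable,
       top_class_items = results$alternative[involves_top])
}

#' Write a classification report to CSV
#'
#' Columns: `alternative, s1, s2, viable_classes, recommended` with
#' viable classes joined by `"|"`.
#'
#' @param results A [classify_all()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_classification <- function(results, path) {
  df <- data.frame(alternative = results$alternative,
                   s1 = results$s1, s2 = results$s2,
                   viable_classes = results$viable,
                   recommended = results$recommended,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read per-alternative bounds from CSV
#'
#' Accepts either a classification report written by
#' [write_classification()] or any CSV with columns `alternative`,
#' `s1`, `s2`.
#'
#' @param path Path to the CSV file.
#' @return data.frame with columns `alternative`, `s1`, `s2`.
#' @export
read_bounds <- function(path) {
  if (!file.exists(path)) stop("bounds file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  need <- c("alternative", "s1", "s2")
  if (!all(need %in% names(df)))
    stop(path, " must have columns: ", paste(need, collapse = ", "))
  df[need]
}
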