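#' Define an evaluation criterion
#'
#' A criterion couples a column of the consequence matrix with the
#' information needed to turn raw performances into 0-1 marginal values:
#' the optimization direction and, optionally, declared worst/best levels
#' in natural units. Built scales (ordinal ratings such as criticality
#' 1-3) restrict the admissible raw values to their declared levels.
#'
#' @param name Character identifier, matching the column name in the
#'   consequence matrix CSV.
#' @param direction `"maximize"` (more is preferred) or `"minimize"`.
#' @param scale_kind `"natural"` (measured quantity) or `"built"`
#'   (constructed ordinal scale).
#' @param worst_level,best_level Optional raw levels mapped to marginal
#'   value 0 and 1. When omitted, the observed column range is used. If
#'   both are given they must differ, and `best_level > worst_level`
#'   exactly when `direction = "maximize"`.
#' @param levels For built scales, the admissible ordinal levels
#'   (default `1:3`).
#' @return An object of class `"criterion"`.
#' @examples
#' criterion("cost", "minimize")
#' criterion("criticality", "maximize", "built", worst_level = 1,
#'           best_level = 3)
#' @export
criterion <- function(name,
                      direction = c("maximize", "minimize"),
                      scale_kind = c("natural", "built"),
                      worst_level = NULL, best_level = NULL,
                      levels = if (match.arg(scale_kind) == "built") 1:3) {
  direction <- match.arg(direction)
  scale_kind <- match.arg(scale_kind)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.null(worst_level) && !is.null(best_level)) {
    if (worst_level == best_level)
      stop("criterion '", name, "': worst_level and best_level must differ")
    if ((best_level > worst_level) != (direction == "maximize"))
      stop("criterion '", name, "': declared levels contradict direction '",
           direction, "'")
  }
  structure(list(name = name, direction = direction,
                 scale_kind = scale_kind,
                 worst_level = worst_level, best_level = best_level,
                 levels = if (scale_kind == "built") levels),
            class = "criterion")
}

#' @export
print.criterion <- function(x, ...) {
  cat(sprintf("criterion '%s' (%s, %s scale)\n", x$name, x$direction,
              x$scale_kind))
  invisible(x)
}

#' Read a criteria configuration file
#'
#' The file is a CSV with columns `name`, `direction` (`max`/`min` or the
#' full words), `scale` (`natural`/`built`) and optional `worst`, `best`
#' columns holding declared levels (empty/NA means observed range).
#'
#' @param path Path to the CSV file.
#' @return A list of [criterion()] objects.
#' @export
read_criteria_config <- function(path) {
  if (!file.exists(path)) stop("criteria config not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "direction", "scale")
  if (!all(need %in% names(df)))
    stop("criteria config ", path, " must have columns: ",
         paste(need, collapse = ", "))
  dir_full <- ifelse(grepl("^max", df$direction), "maximize", "minimize")
  lapply(seq_len(nrow(df)), function(i) {
    w <- if ("worst" %in% names(df) && !is.na(df$worst[i])) df$worst[i]
    b <- if ("best" %in% names(df) && !is.na(df$best[i])) df$best[i]
    criterion(df$name[i], dir_full[i], df$scale[i],
              worst_level = w, best_level = b)
  })
}

criteria_names <- function(criteria) {
  vapply(criteria, function(cr) cr$name, character(1))
}

#' Construct a consequence matrix
#'
#' Raw performances of alternatives on criteria, in natural units
#' (currency, units/month, days, ordinal levels, cubic metres).
#'
#' @param performance Numeric matrix or data.frame, one row per
#'   alternative, columns named and ordered as `criteria`.
#' @param criteria List of [criterion()] objects.
#' @param alternatives Character ids, unique, one per row (defaults to
#'   row names).
#' @return Object of class `"consequence_matrix"`: a list with elements
#'   `alternatives`, `criteria` and the numeric `performance` matrix.
#' @export
consequence_matrix <- function(performance, criteria,
                               alternatives = rownames(performance)) {
  perf <- as.matrix(performance)
  storage.mode(perf) <- "double"
  nms <- criteria_names(criteria)
  if (is.null(alternatives))
    stop("alternative identifiers are required")
  alternatives <- as.character(alternatives)
  if (nrow(perf) < 2L || length(criteria) < 2L)
    stop("need at least 2 alternatives and 2 criteria")
  if (anyDuplicated(alternatives)) {
    dup <- unique(alternatives[duplicated(alternatives)])
    stop("duplicated alternative id(s): ", paste(dup, collapse = "; "))
  }
  if (is.null(colnames(perf))) colnames(perf) <- nms
  if (!setequal(colnames(perf), nms) || ncol(perf) != length(nms))
    stop("performance columns (", paste(colnames(perf), collapse = ", "),
         ") do not match criteria (", paste(nms, collapse = ", "), ")")
  perf <- perf[, nms, drop = FALSE]  # criteria config order wins
  if (any(!is.finite(perf))) {
    bad <- which(!is.finite(perf), arr.ind = TRUE)[1L, ]
    stop("non-finite performance for alternative '",
         alternatives[bad[1L]], "', criterion '", nms[bad[2L]], "'")
  }
  for (cr in criteria) {
    if (cr$scale_kind == "built") {
      x <- perf[, cr$name]
      off <- which(!x %in% cr$levels)
      if (length(off))
        stop("alternative '", alternatives[off[1L]], "', criterion '",
             cr$name, "': value ", x[off[1L]],
             " is not an admissible level (",
             paste(cr$levels, collapse = ", "), ")")
    }
  }
  rownames(perf) <- alternatives
  structure(list(alternatives = alternatives, criteria = criteria,
                 performance = perf),
            class = "consequence_matrix")
}

#' @export
print.consequence_matrix <- function(x, ...) {
  cat(sprintf("consequence matrix: %d alternatives x %d criteria (%s)\n",
              length(x$alternatives), length(x$criteria),
              paste(criteria_names(x$criteria), collapse = ", ")))
  invisible(x)
}

#' Load a consequence matrix from CSV
#'
#' The CSV must have a header whose first column holds the alternative
#' id and one numeric column per configured criterion. Column order in
#' the file is irrelevant; the criteria configuration order is imposed.
#'
#' @param path Path to the CSV file.
#' @param criteria List of [criterion()] objects.
#' @return A [consequence_matrix()].
#' @export
load_consequence_matrix <- function(path, criteria) {
  if (!file.exists(path)) stop("consequence matrix file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                        fileEncoding = "UTF-8")
  if (ncol(df) < 2L) stop(path, ": expected an id column plus criteria")
  nms <- criteria_names(criteria)
  missing_cols <- setdiff(nms, names(df)[-1L])
  if (length(missing_cols))
    stop(path, ": missing criterion column(s): ",
         paste(missing_cols, collapse = ", "))
  extra <- setdiff(names(df)[-1L], nms)
  if (length(extra))
    stop(path, ": unexpected column(s): ", paste(extra, collapse = ", "))
  ids <- as.character(df[[1L]])
  for (nm in nms) {
    if (!is.numeric(df[[nm]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[nm]]))))[1L]
      stop(path, ": non-numeric value in column '", nm, "', row ",
           if (is.na(bad)) "?" else bad, " ('", ids[bad], "')")
    }
  }
  consequence_matrix(as.matrix(df[nms]), criteria, alternatives = ids)
}

#' Write a consequence matrix to CSV
#'
#' @param cm A [consequence_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_consequence_matrix <- function(cm, path) {
  df <- data.frame(alternative = cm$alternatives, cm$performance,
                   check.names = FALSE, row.names = NULL)
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Compute the marginal value matrix
#'
#' Applies the linear marginal value function of each criterion: raw
#' performances are mapped onto 0-1 so that 1 is always the preferred
#' end. For maximized criteria `v = (x - worst)/(best - worst)`; for
#' minimized criteria the same formula with `worst` the largest raw
#' value, so the mapping is decreasing in `x`. Levels default to the
#' observed column range; declared levels override it, and values beyond
#' declared levels are clipped into `[0, 1]`.
#'
#' @param cm A [consequence_matrix()].
#' @param tol Tolerance for the degenerate-range check.
#' @return Object of class `"value_matrix"`: numeric matrix of marginal
#'   values in `[0, 1]`, alternatives x criteria, with the criteria list
#'   attached as attribute `"criteria"`.
#' @export
compute_value_matrix <- function(cm, tol = 1e-12) {
  stopifnot(inherits(cm, "consequence_matrix"))
  perf <- cm$performance
  v <- perf
  for (cr in cm$criteria) {
    x <- perf[, cr$name]
    declared <- !is.null(cr$worst_level) && !is.null(cr$best_level)
    if (declared) {
      worst <- cr$worst_level; best <- cr$best_level
    } else if (cr$direction == "maximize") {
      worst <- min(x); best <- max(x)
    } else {
      worst <- max(x); best <- min(x)
    }
    if (abs(best - worst) <= tol)
      stop("criterion '", cr$name, "' is degenerate (all performances ",
           "equal and no declared levels); drop it or declare ",
           "worst/best levels")
    vi <- (x - worst) / (best - worst)
    v[, cr$name] <- pmin(1, pmax(0, vi))
  }
  structure(v, class = c("value_matrix", "matrix"), criteria = cm$criteria)
}

#' Invert a marginal value back to natural units
#'
#' Used to render elicitation questions: which raw performance on this
#' criterion has marginal value `lambda`?
#'
#' @param cm A [consequence_matrix()].
#' @param name Criterion name.
#' @param lambda Marginal value in `[0, 1]`.
#' @return The raw performance whose marginal value is `lambda`.
#' @export
raw_level_at <- function(cm, name, lambda) {
  stopifnot(inherits(cm, "consequence_matrix"), lambda >= 0, lambda <= 1)
  cr <- cm$criteria[[match(name, criteria_names(cm$criteria))]]
  if (is.null(cr)) stop("unknown criterion: ", name)
  x <- cm$performance[, cr$name]
  declared <- !is.null(cr$worst_level) && !is.null(cr$best_level)
  if (declared) {
    worst <- cr$worst_level; best <- cr$best_level
  } else if (cr$direction == "maximize") {
    worst <- min(x); best <- max(x)
  } else {
    worst <- max(x); best <- min(x)
  }
  worst + lambda * (best - worst)
}

#' Define an ordered class profile
#'
#' Classes partition the 0-1 global-value scale into ordered bands. With
#' labels `(M, B, W)` (least to most preferred) and thresholds
#' `(b1, b2)`, the bands are `M: [0, b1]`, `B: (b1, b2]`, `W: (b2, 1]`;
#' a value falling exactly on a threshold belongs to the lower band.
#'
#' @param labels Class labels ordered from least to most preferred.
#' @param thresholds Strictly increasing cut levels inside `(0, 1)`,
#'   one fewer than labels.
#' @return Object of class `"class_profile"`.
#' @examples
#' class_profile()                      # M / B / W with cuts 0.4, 0.7
#' class_profile(c("C", "B", "A"), c(0.5, 0.8))
#' @export
class_profile <- function(labels = c("M", "B", "W"),
                          thresholds = c(0.4, 0.7)) {
  labels <- as.character(labels)
  thresholds <- as.numeric(thresholds)
  if (length(labels) < 2L) stop("need at least two classes")
  if (anyDuplicated(labels)) stop("class labels must be unique")
  if (length(thresholds) != length(labels) - 1L)
    stop("need exactly ", length(labels) - 1L, " thresholds for ",
         length(labels), " classes")
  if (any(thresholds <= 0) || any(thresholds >= 1))
    stop("thresholds must lie strictly inside (0, 1)")
  if (is.unsorted(thresholds, strictly = TRUE))
    stop("thresholds must be strictly increasing")
  structure(list(labels = labels, thresholds = thresholds),
            class = "class_profile")
}

#' @export
print.class_profile <- function(x, ...) {
  lo <- c(0, x$thresholds); hi <- c(x$thresholds, 1)
  L <- length(x$labels)
  for (r in rev(seq_len(L)))
    cat(sprintf("  %s: %s%.4g, %.4g]\n", x$labels[r],
                if (r == 1L) "[" else "(", lo[r], hi[r]))
  invisible(x)
}

#' Read a class profile from a YAML file
#'
#' Expects keys `labels` (least to most preferred) and `thresholds`.
#'
#' @param path Path to the YAML file.
#' @return A [class_profile()].
#' @export
read_class_profile <- function(path) {
  if (!file.exists(path)) stop("class profile file not found: ", path)
  y <- yaml::read_yaml(path)
  class_profile(y$labels, y$thresholds)
}
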