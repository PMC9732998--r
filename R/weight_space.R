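#' Initial weight space from a criteria ranking
#'
#' The weight space is the polytope of criteria scaling constants
#' `k` compatible with the preference information gathered so far. The
#' base system holds the normalization `sum(k) = 1`, non-negativity, and
#' the strict ranking `k[r1] >= k[r2] + epsilon >= ...` for the given
#' importance order, where `epsilon` is a small constant making strict
#' inequalities tractable in a linear program. Tradeoff constraints from
#' paired comparisons are added with [add_constraint()].
#'
#' @param ranking Criterion names (or indices), most important first.
#' @param epsilon Strictness constant, `0 <= epsilon < 1/(2 n^2)`;
#'   `epsilon = 0` gives the weak ordering used by the exact vertex
#'   oracle.
#' @return Object of class `"weight_space"`.
#' @examples
#' weight_space(c("demand", "criticality", "lead_time", "cost", "volume"))
#' @export
weight_space <- function(ranking, epsilon = 1e-6) {
  if (is.numeric(ranking)) ranking <- as.character(ranking)
  ranking <- as.character(ranking)
  n <- length(ranking)
  if (n < 1L || anyDuplicated(ranking))
    stop("ranking must be a permutation of distinct criterion names")
  if (!is.numeric(epsilon) || length(epsilon) != 1L || epsilon < 0 ||
      epsilon >= 1 / (2 * n^2))
    stop("epsilon must satisfy 0 <= epsilon < 1/(2 n^2) = ",
         format(1 / (2 * n^2)), " for n = ", n)
  structure(list(ranking = ranking, n = n, epsilon = epsilon,
                 constraints = list()),
            class = "weight_space")
}

#' @export
print.weight_space <- function(x, ...) {
  cat(sprintf("weight space on %d criteria: %s (epsilon = %g, %d tradeoff %s)\n",
              x$n, paste(x$ranking, collapse = " > "), x$epsilon,
              length(x$constraints),
              if (length(x$constraints) == 1L) "constraint" else "constraints"))
  invisible(x)
}

#' Build a tradeoff constraint
#'
#' A paired comparison between two hypothetical outcomes -- criterion at
#' ranking position `upper` at the raw level whose marginal value is
#' `level`, versus criterion at position `lower` at its best level --
#' pins the weight ratio: preferring the upper option encodes
#' `level * k_upper >= k_lower + epsilon`, preferring the lower encodes
#' `level * k_upper + epsilon <= k_lower`, and indifference encodes the
#' exact equality `level * k_upper = k_lower`.
#'
#' @param upper,lower Ranking positions with `upper < lower`.
#' @param level Marginal value `lambda` strictly inside `(0, 1)`
#'   (`1` would duplicate the ordering constraint, `0` is vacuous).
#' @param relation `"prefer_upper"`, `"prefer_lower"` or `"indifferent"`.
#' @return Object of class `"tradeoff_constraint"`.
#' @export
tradeoff_constraint <- function(upper, lower, level,
                                relation = c("prefer_upper", "prefer_lower",
                                             "indifferent")) {
  relation <- match.arg(relation)
  upper <- as.integer(upper); lower <- as.integer(lower)
  if (upper >= lower)
    stop("'upper' must come before 'lower' in the ranking")
  if (!is.numeric(level) || level <= 0 || level >= 1)
    stop("level must lie strictly inside (0, 1)")
  structure(list(upper = upper, lower = lower, level = level,
                 relation = relation),
            class = "tradeoff_constraint")
}

#' Add a tradeoff constraint to a weight space
#'
#' Non-destructive: returns a new space with the constraint appended,
#' so an answer that turns out inconsistent can be rolled back by
#' keeping the previous space. Feasibility is checked separately with
#' [is_feasible()].
#'
#' @param space A [weight_space()].
#' @param constraint A [tradeoff_constraint()].
#' @return A new `"weight_space"`.
#' @export
add_constraint <- function(space, constraint) {
  stopifnot(inherits(space, "weight_space"),
            inherits(constraint, "tradeoff_constraint"))
  if (constraint$lower > space$n)
    stop("constraint refers to ranking position ", constraint$lower,
         " but the space has only ", space$n, " criteria")
  space$constraints <- c(space$constraints, list(constraint))
  space
}

# Assemble the linear system in *ranking order* variables.
# Rows are returned in boot::simplex's >= / = split; all rhs >= 0.
ws_system <- function(space) {
  n <- space$n
  eps <- space$epsilon
  ord <- matrix(0, n - 1L, n)
  if (n > 1L) {
    for (r in seq_len(n - 1L)) {
      ord[r, r] <- 1; ord[r, r + 1L] <- -1
    }
  }
  A_ge <- ord
  b_ge <- rep(eps, nrow(ord))
  A_eq <- matrix(1, 1L, n)
  b_eq <- 1
  for (tc in space$constraints) {
    row <- numeric(n)
    if (tc$relation == "prefer_upper") {
      # level * k_u >= k_l + eps
      row[tc$upper] <- tc$level; row[tc$lower] <- -1
      A_ge <- rbind(A_ge, row); b_ge <- c(b_ge, eps)
    } else if (tc$relation == "prefer_lower") {
      # k_l >= level * k_u + eps
      row[tc$upper] <- -tc$level; row[tc$lower] <- 1
      A_ge <- rbind(A_ge, row); b_ge <- c(b_ge, eps)
    } else {
      # level * k_u = k_l
      row[tc$upper] <- tc$level; row[tc$lower] <- -1
      A_eq <- rbind(A_eq, row); b_eq <- c(b_eq, 0)
    }
  }
  list(A_ge = A_ge, b_ge = b_ge, A_eq = A_eq, b_eq = b_eq)
}

# Optimize objective (in ranking-order variables) over the space.
# boot::simplex mis-handles problems given only A2/A3 constraints, so a
# never-binding A1 row (sum k <= 2) is always supplied.
ws_lp <- function(space, objective, maximize) {
  sys <- ws_system(space)
  n <- space$n
  res <- boot::simplex(a = objective,
                       A1 = matrix(1, 1L, n), b1 = 2,
                       A2 = sys$A_ge, b2 = sys$b_ge,
                       A3 = sys$A_eq, b3 = sys$b_eq,
                       maxi = maximize,
                       n.iter = 50L * (n + nrow(sys$A_ge) + nrow(sys$A_eq)))
  if (res$solved == -1L)
    return(list(feasible = FALSE, value = NA_real_, solution = NULL))
  if (res$solved != 1L)
    stop("LP did not converge over the weight space")
  list(feasible = TRUE, value = unname(res$value),
       solution = unname(res$soln[seq_len(n)]))
}

stop_infeasible <- function() {
  stop(errorCondition(
    "weight space is infeasible; retract the latest constraint",
    class = c("fitsort_infeasible", "error", "condition")))
}

#' Is the weight space non-empty?
#'
#' Solves a zero-objective linear program over the full constraint
#' system; an empty space signals that the decision maker's answers are
#' mutually inconsistent and the latest one should be retracted.
#'
#' @param space A [weight_space()].
#' @return `TRUE` or `FALSE`.
#' @export
is_feasible <- function(space) {
  stopifnot(inherits(space, "weight_space"))
  ws_lp(space, rep(0, space$n), maximize = FALSE)$feasible
}

#' Extreme points of an ordering-only weight space
#'
#' With only the ranking constraints and the strictness constant treated
#' as zero, the weight space is the order simplex, whose extreme points
#' are the prefix-uniform vectors: for `m = 1..n`, weight `1/m` on the
#' `m` top-ranked criteria and 0 elsewhere. Any linear objective attains
#' its minimum and maximum over the space at one of these vertices,
#' which makes them an exact oracle for the LP bounds.
#'
#' @param space A [weight_space()] with no tradeoff constraints and
#'   `n <= 10`.
#' @return Numeric matrix, one vertex per row, columns in ranking order
#'   (named by criterion).
#' @export
enumerate_vertices <- function(space) {
  stopifnot(inherits(space, "weight_space"))
  if (length(space$constraints) > 0L)
    stop("vertex enumeration is only valid for ordering-only spaces")
  n <- space$n
  if (n > 10L) stop("vertex enumeration limited to n <= 10")
  v <- matrix(0, n, n, dimnames = list(NULL, space$ranking))
  for (m in seq_len(n)) v[m, seq_len(m)] <- 1 / m
  v
}

#' Per-criterion weight ranges over the current space
#'
#' Minimizes and maximizes each scaling constant over the weight space
#' (2n auxiliary linear programs), the numeric analogue of the weight
#' interval chart a decision-support front end would display.
#'
#' @param space A feasible [weight_space()].
#' @return data.frame with columns `criterion`, `min`, `max` in ranking
#'   order.
#' @export
weight_ranges <- function(space) {
  stopifnot(inherits(space, "weight_space"))
  n <- space$n
  lo <- hi <- numeric(n)
  for (i in seq_len(n)) {
    e <- numeric(n); e[i] <- 1
    a <- ws_lp(space, e, maximize = FALSE)
    b <- ws_lp(space, e, maximize = TRUE)
    if (!a$feasible || !b$feasible) stop_infeasible()
    lo[i] <- a$value; hi[i] <- b$value
  }
  data.frame(criterion = space$ranking, min = lo, max = hi,
             stringsAsFactors = FALSE)
}

#' Read recorded tradeoff constraints
#'
#' CSV with columns `upper`, `lower`, `level`, `relation`, enabling the
#' replay of a recorded elicitation session.
#'
#' @param path Path to the CSV file.
#' @return List of [tradeoff_constraint()] objects.
#' @export
read_constraints <- function(path) {
  if (!file.exists(path)) stop("constraint file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("upper", "lower", "level", "relation")
  if (!all(need %in% names(df)))
    stop(path, " must have columns: ", paste(need, collapse = ", "))
  lapply(seq_len(nrow(df)), function(i)
    tradeoff_constraint(df$upper[i], df$lower[i], df$level[i],
                        df$relation[i]))
}

#' Write tradeoff constraints to CSV
#'
#' @param constraints List of [tradeoff_constraint()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_constraints <- function(constraints, path) {
  df <- data.frame(
    upper = vapply(constraints, `[[`, integer(1), "upper"),
    lower = vapply(constraints, `[[`, integer(1), "lower"),
    level = vapply(constraints, `[[`, numeric(1), "level"),
    relation = vapply(constraints, `[[`, character(1), "relation"))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
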