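#' Configuration for synthetic hospital-inventory problems
#'
#' Describes the distributional shape of each criterion column so that
#' generated consequence matrices resemble hospital inventory data:
#' right-skewed positive unit costs (log-normal), heavy-tailed monthly
#' demand counts (negative binomial), small-integer lead times, ordinal
#' 1-3 criticality, and storage volumes spanning about two orders of
#' magnitude (log-uniform).
#'
#' @param n_alternatives Number of items (>= 2).
#' @param seed RNG seed making the generated problem reproducible.
#' @param cost_meanlog,cost_sdlog Log-normal parameters of unit cost.
#' @param demand_mu,demand_size Negative-binomial mean and dispersion of
#'   monthly demand (shifted by +1 so demand is at least 1).
#' @param lead_range Integer range of lead times in days.
#' @param criticality_prob Probabilities of criticality levels 1, 2, 3
#'   (must sum to 1).
#' @param volume_range Range of item volumes in m3 (sampled log-
#'   uniformly).
#' @return Object of class `"synthetic_config"`.
#' @export
synthetic_config <- function(n_alternatives = 48L, seed = 1L,
                             cost_meanlog = 3, cost_sdlog = 2,
                             demand_mu = 3000, demand_size = 0.4,
                             lead_range = c(2L, 60L),
                             criticality_prob = c(0.2, 0.4, 0.4),
                             volume_range = c(1e-4, 7e-2)) {
  if (n_alternatives < 2L) stop("need at least 2 alternatives")
  if (abs(sum(criticality_prob) - 1) > 1e-12)
    stop("criticality probabilities must sum to 1")
  if (any(criticality_prob < 0)) stop("criticality probabilities must be >= 0")
  structure(list(n_alternatives = as.integer(n_alternatives),
                 seed = as.integer(seed),
                 cost_meanlog = cost_meanlog, cost_sdlog = cost_sdlog,
                 demand_mu = demand_mu, demand_size = demand_size,
                 lead_range = as.integer(lead_range),
                 criticality_prob = criticality_prob,
                 volume_range = volume_range),
            class = "synthetic_config")
}

#' Generate a synthetic consequence matrix
#'
#' Draws a seeded, reproducible hospital-like problem with the five
#' standard criteria (cost, demand, lead time, criticality, volume). A
#' column that comes out constant (which would make its value function
#' degenerate) is redrawn up to `max_retries` times; failure to obtain a
#' non-degenerate column is an error.
#'
#' @param config A [synthetic_config()].
#' @param max_retries Redraws allowed per degenerate column.
#' @return A [consequence_matrix()] with the same criteria semantics as
#'   [huol_fixture()].
#' @export
generate_problem <- function(config, max_retries = 10L) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  n <- config$n_alternatives
  draw <- list(
    cost = function() round(stats::rlnorm(n, config$cost_meanlog,
                                          config$cost_sdlog), 2),
    demand = function() stats::rnbinom(n, size = config$demand_size,
                                       mu = config$demand_mu) + 1,
    lead_time = function() sample(seq(config$lead_range[1L],
                                      config$lead_range[2L]), n,
                                  replace = TRUE),
    criticality = function() sample(1:3, n, replace = TRUE,
                                    prob = config$criticality_prob),
    volume = function() exp(stats::runif(n, log(config$volume_range[1L]),
                                         log(config$volume_range[2L]))))
  cols <- lapply(names(draw), function(nm) {
    x <- draw[[nm]]()
    tries <- 0L
    while (length(unique(x)) < 2L && tries < max_retries) {
      x <- draw[[nm]]()
      tries <- tries + 1L
    }
    if (length(unique(x)) < 2L)
      stop("column '", nm, "' is constant after ", max_retries,
           " redraws; widen its distribution")
    x
  })
  perf <- do.call(cbind, cols)
  colnames(perf) <- names(draw)
  rownames(perf) <- sprintf("item_%02d", seq_len(n))
  criteria <- list(
    criterion("cost", "minimize"),
    criterion("demand", "maximize"),
    criterion("lead_time", "minimize"),
    criterion("criticality", "maximize", "built", worst_level = 1,
              best_level = 3),
    criterion("volume", "minimize"))
  consequence_matrix(perf[, criteria_names(criteria)], criteria)
}

#' A consistent additive-model decision maker
#'
#' Holds a hidden true weight vector used as ground truth in recovery
#' tests: the simulated decision maker answers every tradeoff question
#' by evaluating both hypothetical outcomes under the additive model at
#' the true weights.
#'
#' @param true_weights Named numeric vector, strictly decreasing,
#'   positive, summing to 1; names are the criterion names in ranking
#'   order (most important first).
#' @param tolerance Indifference tolerance `tau >= 0`: value differences
#'   of at most `tau` are answered as indifference.
#' @return Object of class `"simulated_dm"`.
#' @examples
#' simulated_dm(c(demand = 0.4, criticality = 0.3, lead_time = 0.15,
#'                cost = 0.1, volume = 0.05))
#' @export
simulated_dm <- function(true_weights, tolerance = 0) {
  w <- as.numeric(true_weights)
  if (is.null(names(true_weights)))
    stop("true_weights must be named by criterion, ranking order first")
  if (any(w <= 0)) stop("true weights must be strictly positive")
  if (abs(sum(w) - 1) > 1e-9) stop("true weights must sum to 1")
  if (is.unsorted(rev(w), strictly = TRUE))
    stop("true weights must be strictly decreasing in ranking order")
  if (tolerance < 0) stop("tolerance must be >= 0")
  structure(list(true_weights = setNames(w, names(true_weights)),
                 tolerance = tolerance),
            class = "simulated_dm")
}

#' Simulated decision maker's answer to a tradeoff question
#'
#' Option A is worth `lambda * k_i` and option B `k_j` under the true
#' weights; the sign of the difference (outside the indifference
#' tolerance) decides the answer.
#'
#' @param dm A [simulated_dm()].
#' @param question An [generate_question()] result (fields `upper`,
#'   `lower` as ranking positions and `level`).
#' @return `"a"`, `"b"` or `"i"`.
#' @export
simulate_dm_answer <- function(dm, question) {
  stopifnot(inherits(dm, "simulated_dm"))
  k <- dm$true_weights
  d <- question$level * k[question$upper] - k[question$lower]
  if (abs(d) <= dm$tolerance) "i" else if (d > 0) "a" else "b"
}

#' True classification under the hidden weights
#'
#' Evaluates every alternative's global value at the simulated decision
#' maker's true weights and bands it with the profile's boundary
#' convention; the oracle that an elicitation run must remain consistent
#' with.
#'
#' @param values A [compute_value_matrix()] result (columns named by
#'   criterion).
#' @param dm A [simulated_dm()] whose weight names match the value
#'   columns.
#' @param profile A [class_profile()].
#' @return A data.frame with columns `alternative`, `global_value`,
#'   `class`.
#' @export
true_classification <- function(values, dm, profile) {
  stopifnot(inherits(dm, "simulated_dm"))
  v <- unclass(values)
  w <- dm$true_weights
  if (!setequal(names(w), colnames(v)))
    stop("decision maker weights do not match the value-matrix criteria")
  g <- as.numeric(v[, names(w), drop = FALSE] %*% w)
  labs <- vapply(g, function(x)
    assign_classes(x, x, profile)[1L], character(1))
  data.frame(alternative = rownames(v) %||% as.character(seq_along(g)),
             global_value = g, class = labs, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
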