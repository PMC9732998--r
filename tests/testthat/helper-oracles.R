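# Independent oracles and small builders used across the test files.

# Exact bounds of sum(k * v) over the ordering-only weight space with a
# zero strictness constant: extremes of the prefix means of v taken in
# ranking order.
prefix_average_bounds <- function(v) {
  pm <- cumsum(v) / seq_along(v)
  c(s1 = min(pm), s2 = max(pm))
}

# Standard five hospital criteria (matching the bundled dataset).
hospital_criteria <- function() {
  list(criterion("cost", "minimize"),
       criterion("demand", "maximize"),
       criterion("lead_time", "minimize"),
       criterion("criticality", "maximize", "built", worst_level = 1,
                 best_level = 3),
       criterion("volume", "minimize"))
}

tiny_matrix <- function() {
  criteria <- list(criterion("gain", "maximize"),
                   criterion("loss", "minimize"))
  consequence_matrix(
    matrix(c(10, 20, 30, 5, 2, 8), ncol = 2,
           dimnames = list(c("x", "y", "z"), c("gain", "loss"))),
    criteria)
}

# Closed-form stability of a fixed [s1, s2] interval under independent
# uniform threshold draws, for a three-class profile. Conditions on the
# second threshold are one-sided given the first, so the probability is
# the 1D integral over b1 of a piecewise-linear integrand; midpoint
# quadrature on a fine grid evaluates it to ~1e-5.
stability_closed_form <- function(s1, s2, profile, delta,
                                  n_grid = 100000L) {
  stopifnot(length(profile$thresholds) == 2L)
  b <- profile$thresholds
  lo1 <- b[1] * (1 - delta); hi1 <- b[1] * (1 + delta)
  lo2 <- b[2] * (1 - delta); hi2 <- b[2] * (1 + delta)
  nominal <- assign_classes(s1, s2, profile)
  inM <- "M" %in% nominal; inB <- "B" %in% nominal; inW <- "W" %in% nominal
  punif_ge <- function(x, lo, hi) min(1, max(0, (hi - x) / (hi - lo)))
  b1_grid <- lo1 + (seq_len(n_grid) - 0.5) * (hi1 - lo1) / n_grid
  f <- vapply(b1_grid, function(b1) {
    if ((s1 <= b1) != inM) return(0)
    # membership of B is (s2 > b1) & (s1 <= b2); of W is (s2 > b2)
    p_b2_ge_s1 <- punif_ge(s1, lo2, hi2)   # P(b2 >= s1)
    p_b2_ge_s2 <- punif_ge(s2, lo2, hi2)   # P(b2 >= s2), i.e. W absent
    pB <- if (inB) {
      if (s2 > b1) p_b2_ge_s1 else 0
    } else {
      if (s2 > b1) 1 - p_b2_ge_s1 else 1
    }
    pW <- if (inW) 1 - p_b2_ge_s2 else p_b2_ge_s2
    # B and W conditions are both one-sided in b2: intersect intervals
    if (inB && inW) {
      if (s2 <= b1) return(0)
      # need b2 >= s1 and b2 < s2
      lo_cut <- max(lo2, s1); hi_cut <- min(hi2, s2)
      return(max(0, hi_cut - lo_cut) / (hi2 - lo2))
    }
    if (inB && !inW) {
      if (s2 <= b1) return(0)
      # need b2 >= s1 and b2 >= s2  => b2 >= max(s1, s2) = s2
      return(p_b2_ge_s2)
    }
    if (!inB && inW) {
      # need (b2 < s1 or s2 <= b1) and b2 < s2
      if (s2 <= b1) return(1 - p_b2_ge_s2)
      lo_cut <- lo2; hi_cut <- min(hi2, s1, s2)
      return(max(0, hi_cut - lo_cut) / (hi2 - lo2))
    }
    # neither B nor W: need (b2 < s1 or s2 <= b1) and b2 >= s2
    if (s2 <= b1) return(p_b2_ge_s2)
    # b2 < s1 and b2 >= s2 is empty unless s2 <= b2 < s1 (impossible,
    # s1 <= s2)
    0
  }, numeric(1))
  mean(f)
}

standard_ranking <- c("demand", "criticality", "lead_time", "cost",
                      "volume")

viable_vec <- function(viable) strsplit(viable, "|", fixed = TRUE)
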