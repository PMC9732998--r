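#' Start an elicitation state
#'
#' Bookkeeping for the flexible elicitation loop: for every ranked pair
#' of criteria `(i, j)` (i more important), the open interval of tradeoff
#' levels `lambda` where the decision maker's preference is still
#' undetermined, initially `(0, 1)`. Questions bisect these intervals;
#' pairs are visited round-robin, adjacent pairs first, then by
#' increasing rank distance.
#'
#' @param space A [weight_space()].
#' @param resolution Stop refining a pair once its undetermined interval
#'   is narrower than this (also the elicitation's stopping resolution).
#' @return Object of class `"elicitation_state"`.
#' @export
elicitation_state <- function(space, resolution = 0.05) {
  stopifnot(inherits(space, "weight_space"), resolution > 0,
            resolution < 1)
  n <- space$n
  pairs <- expand.grid(upper = seq_len(n), lower = seq_len(n))
  pairs <- pairs[pairs$upper < pairs$lower, , drop = FALSE]
  pairs <- pairs[order(pairs$lower - pairs$upper, pairs$upper), ,
                 drop = FALSE]
  rownames(pairs) <- NULL
  pairs$lo <- 0; pairs$hi <- 1; pairs$active <- TRUE
  structure(list(space = space, pairs = pairs, last = 0L,
                 resolution = resolution),
            class = "elicitation_state")
}

pair_open <- function(state) {
  state$pairs$active & (state$pairs$hi - state$pairs$lo >= state$resolution)
}

#' Generate the next paired-comparison question
#'
#' Picks the next pair (round-robin after the last one asked) whose
#' undetermined interval is still wider than the resolution and asks its
#' midpoint: "criterion i at the raw level worth `lambda`, everything
#' else at worst -- or criterion j at best, everything else at worst?".
#' Option A's global value is `lambda * k_i` and option B's is `k_j` for
#' every weight vector, so the answer is exactly a tradeoff statement.
#'
#' @param state An [elicitation_state()].
#' @param cm Optional [consequence_matrix()]; when given, the question
#'   carries a natural-unit rendering of both hypothetical outcomes.
#' @return An object of class `"elicitation_question"` (fields `upper`,
#'   `lower`, `level`, `pair`, `display`), or `NULL` when every pair is
#'   resolved below the resolution (elicitation exhausted).
#' @export
generate_question <- function(state, cm = NULL) {
  stopifnot(inherits(state, "elicitation_state"))
  open <- which(pair_open(state))
  if (!length(open)) return(NULL)
  nxt <- open[open > state$last]
  row <- if (length(nxt)) nxt[1L] else open[1L]
  p <- state$pairs[row, ]
  lambda <- (p$lo + p$hi) / 2
  ranking <- state$space$ranking
  display <- sprintf(
    "A: %s at %.0f%% of its value range, all else at worst  vs  B: %s at best, all else at worst",
    ranking[p$upper], 100 * lambda, ranking[p$lower])
  if (!is.null(cm)) {
    display <- sprintf(
      "A: %s = %.4g (worth %.0f%%), all else at worst  vs  B: %s = %.4g (best), all else at worst",
      ranking[p$upper], raw_level_at(cm, ranking[p$upper], lambda),
      100 * lambda,
      ranking[p$lower], raw_level_at(cm, ranking[p$lower], 1))
  }
  structure(list(upper = p$upper, lower = p$lower, level = lambda,
                 pair = row, display = display),
            class = "elicitation_question")
}

#' @export
print.elicitation_question <- function(x, ...) {
  cat(x$display, "\n")
  invisible(x)
}

#' Translate an answer into a tradeoff constraint
#'
#' `prefer_A` (the partial outcome on the more important criterion)
#' bounds the weight ratio from above; `prefer_B` bounds it from below;
#' `indifferent` pins it; `skip` carries no information.
#'
#' @param question An [generate_question()] result.
#' @param answer One of `"a"`, `"b"`, `"i"`, `"s"` (or the long forms
#'   `"prefer_A"`, `"prefer_B"`, `"indifferent"`, `"skip"`).
#' @return A [tradeoff_constraint()], or `NULL` for a skip.
#' @export
constraint_from_answer <- function(question, answer) {
  a <- normalize_answer(answer)
  switch(a,
         a = tradeoff_constraint(question$upper, question$lower,
                                 question$level, "prefer_upper"),
         b = tradeoff_constraint(question$upper, question$lower,
                                 question$level, "prefer_lower"),
         i = tradeoff_constraint(question$upper, question$lower,
                                 question$level, "indifferent"),
         s = NULL,
         stop("cannot build a constraint from answer '", answer, "'"))
}

normalize_answer <- function(answer) {
  key <- c(a = "a", prefer_a = "a", b = "b", prefer_b = "b",
           i = "i", indifferent = "i", s = "s", skip = "s",
           q = "q", quit = "q")
  a <- unname(key[tolower(as.character(answer))])
  if (is.na(a)) stop("unrecognized answer: '", answer, "'")
  a
}

# Shrink (or retire) the asked pair's undetermined interval.
update_state <- function(state, question, answer, retire = FALSE) {
  row <- question$pair
  if (retire) {
    state$pairs$active[row] <- FALSE
  } else {
    switch(answer,
           a = { state$pairs$hi[row] <- question$level },
           b = { state$pairs$lo[row] <- question$level },
           i = { state$pairs$active[row] <- FALSE },
           s = { state$pairs$active[row] <- FALSE })
  }
  state$last <- row
  state
}

#' Answer source: replay a recorded session
#'
#' @param answers A data.frame (or CSV path) with columns `cycle`,
#'   `upper`, `lower`, `level`, `answer` as written by
#'   [write_trace()]-compatible tooling. Answers are consumed in order;
#'   each question asked must match the recorded `upper`/`lower`/`level`
#'   (within `tol`) or the replay stops with an error. When the record
#'   is exhausted the source quits.
#' @param tol Tolerance for matching the recorded level.
#' @return A function usable as `answer_source` in [run_elicitation()].
#' @export
recorded_answers <- function(answers, tol = 1e-8) {
  if (is.character(answers)) {
    if (!file.exists(answers)) stop("answer file not found: ", answers)
    answers <- utils::read.csv(answers, stringsAsFactors = FALSE)
  }
  need <- c("upper", "lower", "level", "answer")
  if (!all(need %in% names(answers)))
    stop("recorded answers need columns: ", paste(need, collapse = ", "))
  k <- 0L
  function(question) {
    k <<- k + 1L
    if (k > nrow(answers)) return("q")
    rec <- answers[k, ]
    if (rec$upper != question$upper || rec$lower != question$lower ||
        abs(rec$level - question$level) > tol)
      stop("recorded answer ", k, " is for pair (", rec$upper, ",",
           rec$lower, ") at level ", rec$level,
           " but the question asked (", question$upper, ",",
           question$lower, ") at ", question$level)
    rec$answer
  }
}

#' Answer source: a simulated decision maker
#'
#' @param dm A [simulated_dm()].
#' @return A function usable as `answer_source` in [run_elicitation()].
#' @export
simulated_answers <- function(dm) {
  stopifnot(inherits(dm, "simulated_dm"))
  function(question) simulate_dm_answer(dm, question)
}

#' Answer source: interactive terminal prompts
#'
#' Displays both hypothetical outcomes and reads `a`, `b`, `i`
#' (indifferent), `s` (skip) or `q` (quit) from the console.
#'
#' @return A function usable as `answer_source` in [run_elicitation()].
#' @export
interactive_answers <- function() {
  function(question) {
    cat(question$display, "\n")
    repeat {
      ans <- tolower(trimws(readline("prefer [a/b], indifferent [i], skip [s], quit [q]? ")))
      if (ans %in% c("a", "b", "i", "s", "q")) return(ans)
      cat("please answer a, b, i, s or q\n")
    }
  }
}

#' Run the flexible elicitation loop
#'
#' Cycle 0 classifies all alternatives with only the ranking
#' constraints. Each subsequent cycle asks one paired-comparison
#' question, converts the answer into a weight-space constraint,
#' re-solves the two bounding LPs per alternative and records a trace
#' row. The loop stops when every alternative is singly classified, the
#' answer source quits, the question generator is exhausted, or
#' `max_cycles` is reached. An answer that would empty the weight space
#' is rejected with a warning (decision-maker inconsistency) and its
#' pair retired.
#'
#' @param cm A [consequence_matrix()].
#' @param profile A [class_profile()].
#' @param ranking Criterion names, most important first.
#' @param answer_source Function of one argument (the question)
#'   returning `"a"`, `"b"`, `"i"`, `"s"` or `"q"`; see
#'   [recorded_answers()], [simulated_answers()],
#'   [interactive_answers()].
#' @param epsilon Strictness constant of the weight space.
#' @param resolution Pair-interval resolution; see
#'   [elicitation_state()].
#' @param max_cycles Maximum number of questions.
#' @return Object of class `"elicitation_run"`: list with `trace`
#'   (data.frame: cycle, upper, lower, level, answer, accepted,
#'   n_classified), `results` (final [classify_all()] output), `space`
#'   (final weight space), `partial` (`TRUE` if the source quit before
#'   any other stop condition).
#' @export
run_elicitation <- function(cm, profile, ranking, answer_source,
                            epsilon = 1e-6, resolution = 0.05,
                            max_cycles = 100L) {
  stopifnot(inherits(cm, "consequence_matrix"),
            inherits(profile, "class_profile"), is.function(answer_source))
  if (!setequal(ranking, criteria_names(cm$criteria)))
    stop("ranking must be a permutation of the matrix criteria")
  values <- compute_value_matrix(cm)
  space <- weight_space(ranking, epsilon)
  state <- elicitation_state(space, resolution)
  results <- classify_all(values, space, profile)
  n_alt <- nrow(results)
  trace <- data.frame(cycle = 0L, upper = NA_integer_,
                      lower = NA_integer_, level = NA_real_,
                      answer = NA_character_, accepted = NA,
                      n_classified = attr(results, "n_single"),
                      stringsAsFactors = FALSE)
  partial <- FALSE
  cycle <- 0L
  while (cycle < max_cycles && attr(results, "n_single") < n_alt) {
    q <- generate_question(state, cm)
    if (is.null(q)) break
    ans <- normalize_answer(answer_source(q))
    if (ans == "q") { partial <- TRUE; break }
    cycle <- cycle + 1L
    accepted <- TRUE
    if (ans == "s") {
      state <- update_state(state, q, ans)
    } else {
      tc <- constraint_from_answer(q, ans)
      cand <- add_constraint(state$space, tc)
      if (!is_feasible(cand)) {
        warning("answer '", ans, "' to pair (", q$upper, ",", q$lower,
                ") at level ", signif(q$level, 4),
                " is inconsistent with earlier answers; rejected",
                call. = FALSE)
        accepted <- FALSE
        state <- update_state(state, q, ans, retire = TRUE)
      } else {
        state$space <- cand
        state <- update_state(state, q, ans)
        results <- classify_all(values, state$space, profile)
      }
    }
    trace <- rbind(trace, data.frame(
      cycle = cycle, upper = q$upper, lower = q$lower, level = q$level,
      answer = ans, accepted = accepted,
      n_classified = attr(results, "n_single"),
      stringsAsFactors = FALSE))
  }
  structure(list(trace = trace, results = results, space = state$space,
                 partial = partial),
            class = "elicitation_run")
}

#' @export
print.elicitation_run <- function(x, ...) {
  n <- nrow(x$results)
  cat(sprintf("elicitation run: %d cycles, %d/%d alternatives singly classified%s\n",
              max(x$trace$cycle), attr(x$results, "n_single"), n,
              if (x$partial) " (partial: decision maker quit)" else ""))
  invisible(x)
}

#' Write an elicitation trace to CSV
#'
#' The compact three-column form (`cycle`, `answer`, `n_classified`)
#' summarising each interaction, as a session log a facilitator would
#' keep.
#'
#' @param run An [run_elicitation()] result (or its `trace`).
#' @param path Output path.
#' @param full Also keep the question columns (`upper`, `lower`,
#'   `level`, `accepted`), making the file replayable with
#'   [recorded_answers()].
#' @return `path`, invisibly.
#' @export
write_trace <- function(run, path, full = FALSE) {
  trace <- if (inherits(run, "elicitation_run")) run$trace else run
  df <- if (full) trace else trace[c("cycle", "answer", "n_classified")]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
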