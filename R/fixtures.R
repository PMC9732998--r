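#' Bundled hospital inventory dataset (HUOL, 48 items)
#'
#' The consequence matrix of 48 medicines and medical-hospital materials
#' from a Brazilian university hospital, evaluated on five criteria:
#' unit cost (R$, minimized), monthly demand (units, maximized), lead
#' time (days, minimized), criticality (built 1-3 ordinal scale,
#' maximized) and storage volume (m3, minimized). Also returns the class
#' profile agreed with the inventory manager (three monitoring classes
#' M < B < W with cuts 0.4 and 0.7) and the criteria ranking elicited
#' from him (demand first, volume last).
#'
#' @return A list with elements `matrix` (a [consequence_matrix()]),
#'   `profile` (a [class_profile()]) and `ranking` (character vector of
#'   criterion names, most important first).
#' @examples
#' fx <- huol_fixture()
#' fx$ranking
#' @export
huol_fixture <- function() {
  path <- system.file("extdata", "huol_consequence_matrix.csv",
                      package = "fitsort", mustWork = TRUE)
  crit_path <- system.file("extdata", "huol_criteria.csv",
                           package = "fitsort", mustWork = TRUE)
  criteria <- read_criteria_config(crit_path)
  list(matrix = load_consequence_matrix(path, criteria),
       profile = class_profile(c("M", "B", "W"), c(0.4, 0.7)),
       ranking = c("demand", "criticality", "lead_time", "cost", "volume"))
}

#' Published per-item global-value bounds for the HUOL dataset
#'
#' The minimum and maximum global values (s1, s2) and viable class sets
#' reported for the 48 HUOL items at the end of the original elicitation
#' (34 singly classified, 14 between two classes). The elicitation
#' session that produced these bounds is not replayable, so they are
#' shipped verbatim as fixed inputs for the class-assignment and
#' threshold-sensitivity stages, not as recomputation targets.
#'
#' @return A data.frame with columns `alternative`, `s1`, `s2` and
#'   `classes` (viable classes joined by `"|"`, most critical first).
#' @examples
#' rb <- huol_reference_bounds()
#' table(rb$classes)
#' @export
huol_reference_bounds <- function() {
  path <- system.file("extdata", "huol_reference_bounds.csv",
                      package = "fitsort", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}
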