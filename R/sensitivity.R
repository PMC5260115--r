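#' Expert-weighting scenario
#'
#' A scenario assigns each expert a non-negative influence weight. Weights
#' given as percentages (e.g. 40/30/30 or 33.33 each) are normalized to sum
#' exactly to 1.
#'
#' @param name Scenario label.
#' @param weights Named non-negative numeric vector, one entry per expert.
#' @return An object of class `scenario`.
#' @export
scenario <- function(name, weights) {
  stopifnot(is.character(name), length(name) == 1L,
            is.numeric(weights), !is.null(names(weights)),
            all(weights >= 0), sum(weights) > 0)
  structure(list(name = name, weights = weights / sum(weights)),
            class = "scenario")
}

#' Aggregate per-expert scores under a weighting scenario
#'
#' The joint score of each alternative is the scenario-weighted mean of the
#' per-expert scores (global AHP scores or TOPSIS closeness coefficients —
#' the one level at which experts carrying their own criterion weights are
#' commensurable).
#'
#' @param per_expert_scores Experts x alternatives numeric matrix with
#'   dimnames.
#' @param scn A [scenario] covering exactly those experts.
#' @return List of class `scenario_result` with `scenario`, `scores` (named
#'   vector per alternative) and `ranking` (from [rank_alternatives()]).
#' @export
apply_scenario <- function(per_expert_scores, scn) {
  stopifnot(is.matrix(per_expert_scores), inherits(scn, "scenario"))
  experts <- rownames(per_expert_scores)
  if (!setequal(experts, names(scn$weights))) {
    stop("scenario '", scn$name, "' experts [",
         paste(names(scn$weights), collapse = ","),
         "] do not match the score grid [", paste(experts, collapse = ","), "]")
  }
  w <- scn$weights[experts]
  agg <- as.vector(t(per_expert_scores) %*% w)
  scores <- stats::setNames(agg, colnames(per_expert_scores))
  structure(list(scenario = scn$name, scores = scores,
                 ranking = rank_alternatives(scores)),
            class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, digits = 4, ...) {
  cat("Scenario '", x$scenario, "': ",
      paste(sprintf("%s=%.*f", names(x$scores), digits, x$scores),
            collapse = " "), "\n", sep = "")
  cat("  ranking: ", paste(x$ranking$alternative, collapse = " > "), "\n", sep = "")
  invisible(x)
}

#' Scenario suite over both decision methods
#'
#' Applies every scenario to the per-expert score grids of each method and
#' returns one long table of aggregate scores and ranks.
#'
#' @param method_scores Named list of experts x alternatives matrices, one
#'   per method (e.g. `list(AHP = ..., TOPSIS = ...)`).
#' @param scenarios List of [scenario] objects (or named list of weight
#'   vectors, converted on the fly).
#' @return Data frame with columns `scenario`, `method`, `alternative`,
#'   `score`, `rank`.
#' @export
scenario_suite <- function(method_scores, scenarios) {
  stopifnot(is.list(method_scores), !is.null(names(method_scores)),
            is.list(scenarios), length(scenarios) >= 1L)
  scenarios <- lapply(seq_along(scenarios), function(i) {
    s <- scenarios[[i]]
    if (inherits(s, "scenario")) s else scenario(names(scenarios)[i], s)
  })
  rows <- list()
  for (scn in scenarios) {
    for (meth in names(method_scores)) {
      res <- apply_scenario(method_scores[[meth]], scn)
      rows[[length(rows) + 1L]] <- data.frame(
        scenario = scn$name, method = meth,
        alternative = res$ranking$alternative,
        score = res$ranking$score, rank = res$ranking$rank,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Compare two rankings
#'
#' Summarizes the agreement between two orderings of the same alternatives:
#' the relation (`"identical"`, `"first-choice-agrees"` or `"discordant"`)
#' and the number of unordered pairs ranked the same way.
#'
#' @param a,b Character vectors: alternatives in rank order (best first).
#' @return List with `relation`, `pairs_agreeing`, `pairs_total`.
#' @export
compare_rankings <- function(a, b) {
  stopifnot(is.character(a), is.character(b), setequal(a, b),
            !anyDuplicated(a), !anyDuplicated(b))
  m <- length(a)
  pos_a <- stats::setNames(seq_len(m), a)
  pos_b <- stats::setNames(seq_len(m), b)
  agree <- 0L
  total <- 0L
  items <- sort(a)
  for (i in seq_len(m)) for (j in seq_len(m)) {
    if (i >= j) next
    total <- total + 1L
    same <- sign(pos_a[items[i]] - pos_a[items[j]]) ==
      sign(pos_b[items[i]] - pos_b[items[j]])
    if (same) agree <- agree + 1L
  }
  relation <- if (identical(a, b)) "identical"
  else if (a[1] == b[1]) "first-choice-agrees"
  else "discordant"
  list(relation = relation, pairs_agreeing = agree, pairs_total = total)
}
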