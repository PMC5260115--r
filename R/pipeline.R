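#' Run the full decision pipeline
#'
#' Ties the stages together: criterion weighting by Buckley fuzzy AHP,
#' consistency checking, hierarchical synthesis of global AHP scores,
#' per-expert fuzzy TOPSIS, and the expert-weighting scenario suite. The
#' defaults reproduce the packaged study's conventions with no flags: fixed
#' ideals, the study-form separation distance, scale-maximum normalization,
#' consensus judgment matrices for the AHP synthesis, and each expert's own
#' pairwise matrices (falling back to the consensus set for experts who
#' carry only ratings) for the TOPSIS criterion weights.
#'
#' @param input An [expert_panel], a path to an interchange JSON file, or
#'   `"fixture:study"` for the packaged study.
#' @param method `"both"`, `"ahp"` or `"topsis"`.
#' @param weight_source For TOPSIS criterion weights: `"per-expert"`
#'   (default; an expert without pairwise matrices uses the consensus or the
#'   arithmetic-mean aggregate of the other experts) or `"consensus"` for everyone.
#' @param ideals_mode,variant,divisor_rule Stage options passed through to
#'   [ideal_solutions()], [separation_distance()] and [normalize_ratings()].
#' @param local_defuzz Defuzzification for AHP local alternative weights,
#'   see [local_alternative_weights()].
#' @param scenarios Named list of expert weight vectors; defaults to the
#'   panel's own scenarios, if any.
#' @param cr_defuzz Defuzzification rule for [consistency_ratio()].
#' @param warn_inconsistent Emit a warning when any judgment matrix has
#'   CR > 0.1 (the conventional gate).
#' @return An object of class `decision_report`: a list with `hierarchy`,
#'   `weights` (per weight source), `consistency` (data frame of CR values),
#'   `ahp` (locals, global scores, ranking), `topsis` (per-expert stage
#'   results and closeness table), `scenario_table`, and `config`.
#' @examples
#' rep <- run_pipeline("fixture:study")
#' rep$ahp$ranking
#' rep$topsis$closeness
#' @export
run_pipeline <- function(input = "fixture:study",
                         method = c("both", "ahp", "topsis"),
                         weight_source = c("per-expert", "consensus"),
                         ideals_mode = c("fixed", "extremal"),
                         variant = c("study", "vertex"),
                         divisor_rule = c("scale-max", "extremal"),
                         local_defuzz = c("centroid", "sum_normalized"),
                         scenarios = NULL,
                         cr_defuzz = c("centroid", "modal", "geometric"),
                         warn_inconsistent = TRUE) {
  method <- match.arg(method)
  weight_source <- match.arg(weight_source)
  ideals_mode <- match.arg(ideals_mode)
  variant <- match.arg(variant)
  divisor_rule <- match.arg(divisor_rule)
  local_defuzz <- match.arg(local_defuzz)
  cr_defuzz <- match.arg(cr_defuzz)

  panel <- resolve_panel_input(input)
  h <- panel$hierarchy
  if (is.null(scenarios)) scenarios <- panel$scenarios

  # --- which experts carry pairwise sets / ratings -------------------------
  has_pw <- vapply(panel$experts, function(e) !is.null(e$pairwise), logical(1))
  has_rt <- vapply(panel$experts, function(e) !is.null(e$ratings), logical(1))
  rating_experts <- names(panel$experts)[has_rt]

  # the consensus pairwise set: an expert literally named "consensus",
  # otherwise the arithmetic-mean aggregate of all experts that have one
  consensus_pw <- if (!is.null(panel$experts$consensus$pairwise)) {
    panel$experts$consensus$pairwise
  } else if (any(has_pw)) {
    aggregate_pairwise_sets(lapply(panel$experts[has_pw], `[[`, "pairwise"))
  } else {
    stop("no expert carries pairwise comparison matrices")
  }

  # --- consistency across every matrix of every pairwise set --------------
  consistency <- consistency_table(panel, consensus_pw, cr_defuzz)
  if (warn_inconsistent && any(consistency$consistency_ratio > 0.1)) {
    bad <- consistency[consistency$consistency_ratio > 0.1, ]
    warning("weak consistency (CR > 0.1) in ", nrow(bad), " matrix(es), e.g. ",
            bad$source[1], "/", bad$group[1], " CR = ",
            sprintf("%.3f", bad$consistency_ratio[1]), call. = FALSE)
  }

  weights <- list(consensus = criterion_weights(consensus_pw, h))
  for (id in names(panel$experts)[has_pw]) {
    if (id != "consensus") {
      weights[[id]] <- criterion_weights(panel$experts[[id]]$pairwise, h)
    }
  }

  report <- list(hierarchy = h, weights = weights, consistency = consistency,
                 config = list(method = method, weight_source = weight_source,
                               ideals_mode = ideals_mode, variant = variant,
                               divisor_rule = divisor_rule,
                               local_defuzz = local_defuzz,
                               cr_defuzz = cr_defuzz))
  class(report) <- "decision_report"

  # --- AHP branch ----------------------------------------------------------
  ahp_expert_scores <- NULL
  if (method %in% c("both", "ahp")) {
    ahp_per_expert <- list()
    for (id in union("consensus", names(panel$experts))) {
      pw <- if (identical(id, "consensus")) consensus_pw
      else if (has_pw[[id]]) panel$experts[[id]]$pairwise
      else consensus_pw
      cw <- if (identical(id, "consensus")) weights$consensus
      else weights[[id]] %||% weights$consensus
      alt_ms <- pw[paste0("alts:", sub_criteria(h))]
      names(alt_ms) <- sub_criteria(h)
      if (any(vapply(alt_ms, is.null, logical(1)))) {
        stop("pairwise set for '", id, "' is missing alternatives matrices")
      }
      locals <- local_alternative_weights(alt_ms, defuzz = local_defuzz)
      scores <- synthesize_global_scores(cw$main, cw$subs, locals)
      ahp_per_expert[[id]] <- list(locals = locals, scores = scores,
                                   ranking = rank_alternatives(scores))
    }
    report$ahp <- c(ahp_per_expert$consensus,
                    list(per_expert = ahp_per_expert))
    score_ids <- setdiff(union(rating_experts, names(panel$experts)), "consensus")
    ahp_expert_scores <- do.call(rbind, lapply(score_ids, function(id) {
      (ahp_per_expert[[id]] %||% ahp_per_expert$consensus)$scores
    }))
    rownames(ahp_expert_scores) <- score_ids
  }

  # --- TOPSIS branch -------------------------------------------------------
  topsis_expert_scores <- NULL
  if (method %in% c("both", "topsis")) {
    if (!any(has_rt)) stop("TOPSIS requested but no expert carries ratings")
    topsis_per_expert <- list()
    for (id in rating_experts) {
      cw <- if (weight_source == "consensus") weights$consensus
      else weights[[id]] %||% weights$consensus
      topsis_per_expert[[id]] <- topsis_stage(
        panel$experts[[id]]$ratings, cw, h = h,
        divisor_rule = divisor_rule, ideals_mode = ideals_mode,
        variant = variant, expert = id)
    }
    cc_grid <- do.call(rbind, lapply(topsis_per_expert, function(ts) {
      cc <- ts$closeness
      stats::setNames(cc$cc, cc$alternative)[h$alternatives]
    }))
    rownames(cc_grid) <- rating_experts
    report$topsis <- list(per_expert = topsis_per_expert,
                          closeness = cc_grid,
                          ranking = rank_alternatives(colMeans(cc_grid)))
    topsis_expert_scores <- cc_grid
  }

  # --- scenario suite ------------------------------------------------------
  if (!is.null(scenarios) && length(scenarios)) {
    method_scores <- list()
    if (!is.null(ahp_expert_scores)) method_scores$AHP <- ahp_expert_scores
    if (!is.null(topsis_expert_scores)) method_scores$TOPSIS <- topsis_expert_scores
    # scenarios name only the rating experts in the packaged study; restrict
    method_scores <- lapply(method_scores, function(g) {
      keep <- intersect(rownames(g), names(scenarios[[1]]))
      g[keep, , drop = FALSE]
    })
    report$scenario_table <- scenario_suite(method_scores, scenarios)
  }
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a

resolve_panel_input <- function(input) {
  if (inherits(input, "expert_panel")) return(input)
  if (inherits(input, "study_fixture")) return(input$panel)
  if (is.character(input) && length(input) == 1L) {
    if (identical(input, "fixture:study")) return(load_study_fixture()$panel)
    if (file.exists(input)) return(read_panel_json(input))
    stop("input '", input, "' is neither an existing file nor 'fixture:study'")
  }
  stop("unsupported input; give an expert_panel, a JSON path or 'fixture:study'")
}

# arithmetic-mean aggregation applied matrix-by-matrix across experts' pairwise sets
aggregate_pairwise_sets <- function(sets) {
  groups <- names(sets[[1]])
  out <- lapply(groups, function(g) {
    aggregate_experts(lapply(sets, `[[`, g))
  })
  stats::setNames(out, groups)
}

consistency_table <- function(panel, consensus_pw, cr_defuzz) {
  rows <- list()
  add <- function(src, pw) {
    for (g in names(pw)) {
      rep <- consistency_ratio(pw[[g]], defuzz = cr_defuzz)
      rows[[length(rows) + 1L]] <<- data.frame(
        source = src, group = g, n = rep$n, lambda_max = rep$lambda_max,
        consistency_ratio = rep$consistency_ratio,
        acceptable = rep$acceptable, stringsAsFactors = FALSE)
    }
  }
  add("consensus", consensus_pw)
  for (id in names(panel$experts)) {
    if (id != "consensus" && !is.null(panel$experts[[id]]$pairwise)) {
      add(id, panel$experts[[id]]$pairwise)
    }
  }
  do.call(rbind, rows)
}

#' @export
print.decision_report <- function(x, digits = 3, ...) {
  cat("Decision report\n")
  cat("  goal: ", x$hierarchy$goal, "\n", sep = "")
  if (!is.null(x$ahp)) {
    cat("  AHP global scores (consensus): ",
        paste(sprintf("%s=%.*f", names(x$ahp$scores), digits, x$ahp$scores),
              collapse = " "), "\n", sep = "")
    cat("  AHP ranking: ", paste(x$ahp$ranking$alternative, collapse = " > "),
        "\n", sep = "")
  }
  if (!is.null(x$topsis)) {
    cat("  TOPSIS closeness by expert:\n")
    print(round(x$topsis$closeness, digits))
  }
  if (!is.null(x$scenario_table)) {
    firsts <- x$scenario_table[x$scenario_table$rank == 1, ]
    cat("  scenario winners: ",
        paste(unique(paste0(firsts$method, ":", firsts$alternative)),
              collapse = ", "), "\n", sep = "")
  }
  if (any(!x$consistency$acceptable)) {
    cat("  note: ", sum(!x$consistency$acceptable),
        " judgment matrix(es) exceed CR 0.1\n", sep = "")
  }
  invisible(x)
}

#' Write a decision report to disk
#'
#' Emits CSV tables (criterion weights, consistency ratios, AHP locals and
#' global scores, per-expert normalized/weighted TOPSIS matrices, separation
#' tables with closeness coefficients, scenario suite) plus a
#' machine-readable `summary.json` and a `run_metadata.json` recording the
#' configuration, so a run can be reproduced exactly.
#'
#' @param report A `decision_report` from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @param digits Display rounding for the CSV tables; stored JSON values are
#'   kept at full precision.
#' @return Invisibly, the vector of files written.
#' @export
write_report <- function(report, dir, digits = 4) {
  stopifnot(inherits(report, "decision_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  put <- function(df, name) {
    path <- file.path(dir, name)
    utils::write.csv(df, path, row.names = FALSE)
    files <<- c(files, path)
  }
  h <- report$hierarchy
  subs <- sub_criteria(h)
  parents <- parent_criteria(h)

  wrows <- do.call(rbind, lapply(names(report$weights), function(src) {
    cw <- report$weights[[src]]
    data.frame(source = src, criterion = subs, main = parents[subs],
               main_weight = round(cw$main[parents[subs]], digits),
               sub_weight = round(unlist(unname(cw$subs))[subs], digits),
               product = round(cw$product[subs], digits),
               stringsAsFactors = FALSE)
  }))
  put(wrows, "criterion_weights.csv")
  put(transform(report$consistency,
                lambda_max = round(lambda_max, digits),
                consistency_ratio = round(consistency_ratio, digits)),
      "consistency.csv")

  if (!is.null(report$ahp)) {
    loc <- as.data.frame(round(report$ahp$locals, digits))
    loc <- cbind(alternative = rownames(report$ahp$locals), loc,
                 global_score = round(report$ahp$scores, digits))
    put(loc, "ahp_synthesis.csv")
  }
  if (!is.null(report$topsis)) {
    for (id in names(report$topsis$per_expert)) {
      ts <- report$topsis$per_expert[[id]]
      put(tfn_grid_df(ts$normalized$values, digits),
          paste0("topsis_normalized_", id, ".csv"))
      put(tfn_grid_df(ts$weighted$values, digits),
          paste0("topsis_weighted_", id, ".csv"))
      sep <- cbind(
        data.frame(alternative = rownames(ts$measures$D_positive)),
        round(ts$measures$D_positive, digits),
        S_positive = round(ts$measures$S_positive, digits),
        round(ts$measures$D_negative, digits),
        S_negative = round(ts$measures$S_negative, digits))
      names(sep) <- c("alternative",
                      paste0("Dpos_", colnames(ts$measures$D_positive)),
                      "S_positive",
                      paste0("Dneg_", colnames(ts$measures$D_negative)),
                      "S_negative")
      cc <- ts$closeness
      sep$cc <- round(cc$cc[match(sep$alternative, cc$alternative)], digits)
      put(sep, paste0("topsis_separations_", id, ".csv"))
    }
  }
  if (!is.null(report$scenario_table)) {
    st <- report$scenario_table
    st$score <- round(st$score, digits)
    put(st, "scenario_suite.csv")
  }

  summary <- list(
    goal = h$goal,
    ahp_scores = if (!is.null(report$ahp)) as.list(report$ahp$scores),
    ahp_ranking = if (!is.null(report$ahp)) report$ahp$ranking$alternative,
    topsis_closeness = if (!is.null(report$topsis)) {
      ccg <- report$topsis$closeness
      stats::setNames(lapply(seq_len(nrow(ccg)), function(i) as.list(ccg[i, ])),
                      rownames(ccg))
    },
    scenario_winners = if (!is.null(report$scenario_table)) {
      w <- report$scenario_table[report$scenario_table$rank == 1, ]
      lapply(split(w$alternative, paste(w$scenario, w$method, sep = "/")),
             unique)
    })
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(report$config, file.path(dir, "run_metadata.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(files, file.path(dir, c("summary.json", "run_metadata.json"))))
}

# flatten an alternatives x criteria x 3 array to a printable data frame
tfn_grid_df <- function(vals, digits = 4) {
  alts <- dimnames(vals)[[1]]
  crits <- dimnames(vals)[[2]]
  out <- data.frame(alternative = alts, stringsAsFactors = FALSE)
  for (cc in crits) {
    out[[cc]] <- vapply(alts, function(a) {
      paste0("(", paste(round(vals[a, cc, ], digits), collapse = ","), ")")
    }, character(1))
  }
  out
}
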