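#' Load the packaged anesthesia-method study
#'
#' Returns the complete multi-criteria study shipped with the package: the
#' selection of an anesthesia method for circumcision surgery by a panel of
#' three pediatric surgeons. The decision hierarchy has four main criteria —
#' convenience (C1), reliability (C2), duration (C3) and psychology (C4) —
#' with two sub-criteria each (C11..C42), over three alternatives: general
#' anesthesia without penile block (A1), with penile block (A2), and local
#' anesthesia (A3).
#'
#' The fixture carries the consensus pairwise-comparison matrices of the
#' expert group, Expert 3's individual pairwise matrices, each expert's
#' linguistic alternative ratings, and the four expert-weighting scenarios
#' of the sensitivity analysis. All judgments are stored as linguistic codes
#' in the package's JSON interchange format and decoded on load. Expert 2's
#' rating of A1 under C32 was transcribed from an ambiguous "V" in the
#' source table and is encoded as "VG" (the unique prefix match on the
#' rating scale); see the fixture metadata.
#'
#' The study's published result tables (hierarchy weights, local alternative
#' weights, global scores, Expert 3's separation sums and closeness
#' coefficients) are included under `$published` so that analyses can be
#' checked against — or started from — the printed values.
#'
#' @return An object of class `study_fixture`: list with elements
#'   `panel` (an [expert_panel] whose experts are `consensus`, `E1`, `E2`,
#'   `E3`), `hierarchy`, `scenarios` (named list of percentage weight
#'   vectors) and `published` (named numeric tables).
#' @examples
#' fx <- load_study_fixture()
#' fx$hierarchy
#' pcm_entry(fx$panel$experts$consensus$pairwise$main, "C1", "C2")
#' @export
load_study_fixture <- function() {
  path <- system.file("extdata", "study_fixture.json", package = "fuzzymcda",
                      mustWork = TRUE)
  panel <- read_panel_json(path)
  pub <- panel$metadata$published
  published <- list(
    main_weights = unlist(pub$main_weights),
    sub_weights = unlist(pub$sub_weights),
    local_weights = do.call(rbind, lapply(pub$local_weights, unlist)),
    global_scores = unlist(pub$global_scores),
    expert3_sub_weights = unlist(pub$expert3_sub_weights),
    expert3_main_weights = unlist(pub$expert3_main_weights),
    expert3_S_positive = unlist(pub$expert3_S_positive),
    expert3_S_negative = unlist(pub$expert3_S_negative),
    expert3_closeness = unlist(pub$expert3_closeness)
  )
  structure(list(panel = panel, hierarchy = panel$hierarchy,
                 scenarios = panel$scenarios, published = published),
            class = "study_fixture")
}

#' @export
print.study_fixture <- function(x, ...) {
  cat("Packaged study: anesthesia-method selection for circumcision surgery\n")
  print(x$panel)
  invisible(x)
}
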