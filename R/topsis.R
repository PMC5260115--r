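#' Fuzzy decision matrix from linguistic ratings
#'
#' Decodes an alternatives x criteria grid of rating codes into triangular
#' fuzzy numbers on the rating scale.
#'
#' @param ratings Character matrix (alternatives in rows, criteria in
#'   columns) of rating codes.
#' @param scale Decoding [linguistic_scale]; defaults to the four-term
#'   performance scale.
#' @param expert Optional expert id carried for error messages and reports.
#' @return An object of class `rating_panel`: list with `alternatives`,
#'   `criteria`, `values` (alternatives x criteria x 3 array) and `expert`.
#' @export
build_decision_matrix <- function(ratings, scale = rating_scale(),
                                  expert = NULL) {
  stopifnot(is.matrix(ratings), is.character(ratings),
            !is.null(rownames(ratings)), !is.null(colnames(ratings)))
  alts <- rownames(ratings)
  crit <- colnames(ratings)
  vals <- array(NA_real_, c(length(alts), length(crit), 3),
                dimnames = list(alts, crit, c("lower", "modal", "upper")))
  for (a in alts) for (cc in crit) {
    v <- tryCatch(scale_lookup(ratings[a, cc], scale), error = function(e) {
      stop("invalid rating", if (!is.null(expert)) paste0(" for expert '", expert, "'"),
           " at alternative '", a, "', criterion '", cc, "': ",
           conditionMessage(e), call. = FALSE)
    })
    vals[a, cc, ] <- unclass(v)
  }
  structure(list(alternatives = alts, criteria = crit, values = vals,
                 expert = expert),
            class = "rating_panel")
}

#' @export
print.rating_panel <- function(x, digits = 3, ...) {
  cat("Fuzzy rating panel",
      if (!is.null(x$expert)) paste0(" (expert: ", x$expert, ")"), ": ",
      length(x$alternatives), " alternatives x ", length(x$criteria),
      " criteria\n", sep = "")
  disp <- matrix("", length(x$alternatives), length(x$criteria),
                 dimnames = list(x$alternatives, x$criteria))
  for (i in seq_along(x$alternatives)) for (j in seq_along(x$criteria)) {
    disp[i, j] <- paste0("(", paste(signif(x$values[i, j, ], digits),
                                    collapse = ","), ")")
  }
  print(disp, quote = FALSE)
  invisible(x)
}

#' Normalize a fuzzy decision matrix
#'
#' Two divisor rules are supported. `"scale-max"` (the default, matching the
#' packaged study) divides every component by the largest upper value of the
#' rating scale (10), leaving all entries in `[0, 1]`. `"extremal"` applies
#' the linear-scale transformation per criterion with fuzzy division; see
#' Details.
#'
#' @details For the extremal rule with per-criterion maxima
#' `x_j* = (l*, m*, u*)` the benefit transformation is the fuzzy division
#' `(l/u*, m/m*, u/l*)`; for a cost criterion with floor `a_j-` (the
#' smallest lower component) it is `(a_j-/u, a_j-/m, a_j-/l)`. Both preserve
#' component ordering. Cost criteria require strictly positive entries.
#'
#' @param panel A `rating_panel` from [build_decision_matrix()].
#' @param divisor_rule `"scale-max"` or `"extremal"`.
#' @param directions Named character vector (`"benefit"`/`"cost"`) per
#'   criterion; only used by the extremal rule. Defaults to all-benefit.
#' @param scale_max Scale maximum for the `"scale-max"` rule (10 for the
#'   built-in rating scale).
#' @return A `rating_panel` with normalized values.
#' @export
normalize_ratings <- function(panel, divisor_rule = c("scale-max", "extremal"),
                              directions = NULL, scale_max = 10) {
  stopifnot(inherits(panel, "rating_panel"))
  divisor_rule <- match.arg(divisor_rule)
  vals <- panel$values
  if (divisor_rule == "scale-max") {
    stopifnot(scale_max > 0)
    vals <- vals / scale_max
  } else {
    if (is.null(directions)) {
      directions <- stats::setNames(rep("benefit", length(panel$criteria)),
                                    panel$criteria)
    }
    for (cc in panel$criteria) {
      x <- vals[, cc, , drop = FALSE]
      if (identical(directions[[cc]], "cost")) {
        if (any(x <= 0)) {
          stop("cost criterion '", cc, "' has a non-positive component; ",
               "cannot divide")
        }
        a_minus <- min(x[, , 1])
        for (a in panel$alternatives) {
          v <- vals[a, cc, ]
          vals[a, cc, ] <- c(a_minus / v[3], a_minus / v[2], a_minus / v[1])
        }
      } else {
        u_star <- max(x[, , 3])
        m_star <- max(x[, , 2])
        l_star <- max(x[, , 1])
        if (u_star <= 0) stop("benefit criterion '", cc, "' has no positive upper component")
        for (a in panel$alternatives) {
          v <- vals[a, cc, ]
          vals[a, cc, ] <- c(v[1] / u_star, v[2] / m_star, v[3] / l_star)
        }
      }
    }
  }
  out <- panel
  out$values <- vals
  out
}

#' Weight a normalized decision matrix by hierarchical criterion weights
#'
#' Multiplies each normalized fuzzy entry by the crisp product of its
#' criterion's main and sub weights,
#' `v_ij = [w_main(parent(j)) * w_sub(j)] * r_ij`.
#'
#' @param panel Normalized `rating_panel`.
#' @param main Named numeric main-criterion weights.
#' @param subs Named list of named numeric sub-criterion weight vectors (as
#'   from [criterion_weights()]).
#' @return An object of class `weighted_matrix`: the panel plus the crisp
#'   per-criterion weights used.
#' @export
apply_weights <- function(panel, main, subs) {
  stopifnot(inherits(panel, "rating_panel"))
  sub_w <- unlist(unname(subs))
  parents <- stats::setNames(rep(names(subs), vapply(subs, length, integer(1))),
                             names(sub_w))
  miss <- setdiff(panel$criteria, names(sub_w))
  if (length(miss)) {
    stop("no weights for criteria: ", paste(miss, collapse = ", "))
  }
  w <- stats::setNames(main[parents[panel$criteria]] * sub_w[panel$criteria],
                       panel$criteria)
  vals <- panel$values
  for (cc in panel$criteria) vals[, cc, ] <- vals[, cc, ] * w[[cc]]
  structure(list(alternatives = panel$alternatives, criteria = panel$criteria,
                 values = vals,
                 weights = stats::setNames(as.numeric(w), panel$criteria),
                 expert = panel$expert),
            class = "weighted_matrix")
}

#' @export
print.weighted_matrix <- function(x, digits = 3, ...) {
  cat("Weighted normalized fuzzy matrix",
      if (!is.null(x$expert)) paste0(" (expert: ", x$expert, ")"), "\n", sep = "")
  cat("criterion weights:", paste(sprintf("%s=%.*f", names(x$weights), digits,
                                          x$weights), collapse = " "), "\n")
  disp <- matrix("", length(x$alternatives), length(x$criteria),
                 dimnames = list(x$alternatives, x$criteria))
  for (i in seq_along(x$alternatives)) for (j in seq_along(x$criteria)) {
    disp[i, j] <- paste0("(", paste(signif(x$values[i, j, ], digits),
                                    collapse = ","), ")")
  }
  print(disp, quote = FALSE)
  invisible(x)
}

#' Fuzzy positive and negative ideal solutions
#'
#' In `"fixed"` mode (the default, matching the packaged study's worked
#' distances) the positive ideal is `(1,1,1)` and the negative ideal
#' `(0,0,0)` on every criterion — the extreme points of the normalized
#' weighted space. In `"extremal"` mode the ideals are the component-wise
#' max/min over alternatives per criterion.
#'
#' @param wm A `weighted_matrix`.
#' @param mode `"fixed"` or `"extremal"`.
#' @return List with `positive` and `negative`: criteria x 3 matrices.
#' @export
ideal_solutions <- function(wm, mode = c("fixed", "extremal")) {
  stopifnot(inherits(wm, "weighted_matrix"))
  mode <- match.arg(mode)
  k <- length(wm$criteria)
  if (mode == "fixed") {
    pos <- matrix(1, k, 3, dimnames = list(wm$criteria, c("lower", "modal", "upper")))
    neg <- matrix(0, k, 3, dimnames = list(wm$criteria, c("lower", "modal", "upper")))
  } else {
    pos <- apply(wm$values, c(2, 3), max)  # criteria x component
    neg <- apply(wm$values, c(2, 3), min)
  }
  list(positive = pos, negative = neg)
}

#' Distance between two triangular fuzzy numbers
#'
#' Two variants: the `"study"` form `(1/3) * sqrt(sum_of_squared_component_
#' differences)` used throughout the packaged study's worked separations,
#' and the standard `"vertex"` form `sqrt(mean_of_squared_differences)`.
#' They differ only by the constant factor `sqrt(3)`:
#' `study = vertex / sqrt(3)`.
#'
#' @param v,ideal [tfn] values (or length-3 numerics).
#' @param variant `"study"` or `"vertex"`.
#' @return Non-negative crisp distance.
#' @examples
#' separation_distance(tfn(0.011, 0.022, 0.033), tfn(1, 1, 1))  # 0.565
#' @export
separation_distance <- function(v, ideal, variant = c("study", "vertex")) {
  variant <- match.arg(variant)
  v <- unclass(as_tfn(v)); ideal <- unclass(as_tfn(ideal))
  ss <- sum((v - ideal)^2)
  switch(variant,
         study = sqrt(ss) / 3,
         vertex = sqrt(ss / 3))
}

#' Separation measures from the ideal solutions
#'
#' Computes the per-criterion distances of each alternative to the positive
#' and negative ideals and their row sums `S_i* = sum_j D_ij*` and
#' `S_i- = sum_j D_ij-`.
#'
#' @param wm A `weighted_matrix`.
#' @param ideals Result of [ideal_solutions()].
#' @param variant Distance variant, see [separation_distance()].
#' @return An object of class `separation_measures`: list with `D_positive`,
#'   `D_negative` (alternatives x criteria), `S_positive`, `S_negative`
#'   (named vectors) and `variant`.
#' @export
separation_measures <- function(wm, ideals = ideal_solutions(wm),
                                variant = c("study", "vertex")) {
  stopifnot(inherits(wm, "weighted_matrix"))
  variant <- match.arg(variant)
  alts <- wm$alternatives; crit <- wm$criteria
  Dp <- Dm <- matrix(NA_real_, length(alts), length(crit),
                     dimnames = list(alts, crit))
  for (a in alts) for (cc in crit) {
    Dp[a, cc] <- separation_distance(wm$values[a, cc, ], ideals$positive[cc, ],
                                     variant = variant)
    Dm[a, cc] <- separation_distance(wm$values[a, cc, ], ideals$negative[cc, ],
                                     variant = variant)
  }
  structure(list(D_positive = Dp, D_negative = Dm,
                 S_positive = rowSums(Dp), S_negative = rowSums(Dm),
                 variant = variant, expert = wm$expert),
            class = "separation_measures")
}

#' @export
print.separation_measures <- function(x, digits = 3, ...) {
  cat("Separation measures (", x$variant, " distance)\n", sep = "")
  print(round(cbind(x$D_positive, `S*` = x$S_positive), digits))
  print(round(cbind(x$D_negative, `S-` = x$S_negative), digits))
  invisible(x)
}

#' Closeness coefficients and TOPSIS ranking
#'
#' `CC_i = S_i- / (S_i* + S_i-)`, in `[0, 1]`; alternatives are ranked by
#' descending closeness.
#'
#' @param measures A `separation_measures` object, or any list carrying
#'   numeric `S_positive` and `S_negative` vectors (so published separation
#'   sums can be fed in directly).
#' @return Data frame with columns `alternative`, `S_positive`, `S_negative`,
#'   `cc`, `rank`, ordered best-first.
#' @export
closeness <- function(measures) {
  Sp <- measures$S_positive; Sm <- measures$S_negative
  stopifnot(is.numeric(Sp), is.numeric(Sm), length(Sp) == length(Sm))
  if (any(Sp + Sm <= 0)) {
    stop("degenerate separation measures: S* + S- must be positive")
  }
  cc <- Sm / (Sp + Sm)
  nm <- names(cc)
  if (is.null(nm)) nm <- paste0("A", seq_along(cc))
  rk <- rank_alternatives(stats::setNames(cc, nm))
  data.frame(alternative = rk$alternative,
             S_positive = unname(Sp[rk$alternative]),
             S_negative = unname(Sm[rk$alternative]),
             cc = rk$score, rank = rk$rank,
             stringsAsFactors = FALSE)
}

#' Run the fuzzy TOPSIS stage for one expert
#'
#' Convenience wrapper: decision matrix, normalization, hierarchical
#' weighting, ideals, separations and closeness in one call.
#'
#' @param ratings Character rating matrix (alternatives x sub-criteria).
#' @param weights Result of [criterion_weights()] (list with `main`, `subs`).
#' @param h A [hierarchy] (for attribute directions under the extremal rule).
#' @param divisor_rule,ideals_mode,variant Stage options; the defaults are
#'   the packaged study's conventions.
#' @param expert Optional expert id.
#' @param scale Rating [linguistic_scale].
#' @return List with the intermediate `panel`, `normalized`, `weighted`,
#'   `ideals`, `measures` objects and the final `closeness` table.
#' @export
topsis_stage <- function(ratings, weights, h = NULL,
                         divisor_rule = "scale-max", ideals_mode = "fixed",
                         variant = "study", expert = NULL,
                         scale = rating_scale()) {
  panel <- build_decision_matrix(ratings, scale = scale, expert = expert)
  directions <- if (!is.null(h)) h$directions
  normalized <- normalize_ratings(panel, divisor_rule = divisor_rule,
                                  directions = directions)
  weighted <- apply_weights(normalized, weights$main, weights$subs)
  ideals <- ideal_solutions(weighted, mode = ideals_mode)
  measures <- separation_measures(weighted, ideals, variant = variant)
  list(panel = panel, normalized = normalized, weighted = weighted,
       ideals = ideals, measures = measures, closeness = closeness(measures))
}
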