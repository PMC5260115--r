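#' Aggregate expert judgment matrices
#'
#' Combines one pairwise comparison matrix per expert into a group matrix by
#' the entry-wise arithmetic mean of the triangular judgments,
#' `C = (C^1 + ... + C^K) / K`.
#'
#' @param matrices List of [pairwise_matrix] objects sharing labels.
#' @return A [pairwise_matrix] with `source = "aggregate"`.
#' @export
aggregate_experts <- function(matrices) {
  stopifnot(is.list(matrices), length(matrices) >= 1L,
            all(vapply(matrices, inherits, logical(1), "pairwise_matrix")))
  labels <- matrices[[1]]$labels
  for (m in matrices) {
    if (!identical(m$labels, labels)) {
      stop("aggregate_experts: all matrices must share the same labels")
    }
  }
  arrs <- lapply(matrices, function(m) m$entries)
  mean_arr <- Reduce(`+`, arrs) / length(arrs)
  pairwise_matrix(mean_arr, labels = labels, source = "aggregate")
}

#' Buckley fuzzy weights from a pairwise comparison matrix
#'
#' Buckley's geometric-mean method: each item's fuzzy geometric mean is the
#' n-th root of its row product of judgments,
#' `r_i = (c_i1 x ... x c_in)^(1/n)`, and its fuzzy weight is
#' `w_i = r_i x (r_1 + ... + r_n)^(-1)` with the fuzzy reciprocal of the sum.
#'
#' @param m A [pairwise_matrix] with strictly positive entries.
#' @return An object of class `fuzzy_weights` with components `labels`,
#'   `geometric_means` and `fuzzy_weights` (each an `n x 3` matrix of TFN
#'   components), and `source`.
#' @examples
#' m <- pairwise_matrix(rbind(c("E", "VI"), c("1/VI", "E")),
#'                      labels = c("C31", "C32"))
#' buckley_weights(m)
#' @export
buckley_weights <- function(m) {
  stopifnot(inherits(m, "pairwise_matrix"))
  if (any(m$entries <= 0)) {
    stop("buckley_weights: all judgment components must be strictly positive")
  }
  n <- length(m$labels)
  r <- t(vapply(seq_len(n), function(i) {
    apply(m$entries[i, , , drop = FALSE], 3, prod)^(1 / n)
  }, numeric(3)))
  colnames(r) <- c("lower", "modal", "upper")
  rownames(r) <- m$labels
  total <- colSums(r)
  inv_total <- rev(1 / total)  # fuzzy reciprocal of the component-wise sum
  w <- sweep(r, 2, inv_total, `*`)
  structure(list(labels = m$labels, geometric_means = r, fuzzy_weights = w,
                 source = m$source),
            class = "fuzzy_weights")
}

#' @export
print.fuzzy_weights <- function(x, digits = 3, ...) {
  cat("Buckley fuzzy weights (source: ", x$source, ")\n", sep = "")
  df <- data.frame(round(x$geometric_means, digits),
                   round(x$fuzzy_weights, digits))
  names(df) <- c("r.lower", "r.modal", "r.upper", "w.lower", "w.modal", "w.upper")
  print(df)
  invisible(x)
}

#' Crisp weights from fuzzy weights
#'
#' Defuzzifies Buckley fuzzy weights into a crisp vector. The default
#' `"sum_normalized"` rule divides each weight's component sum
#' `L_i + M_i + U_i` by the grand total over all items, so the result sums
#' to 1. The `"centroid"` rule returns the unnormalized centroid
#' `(L_i + M_i + U_i) / 3` of each fuzzy weight; this is the convention under
#' which the packaged study's per-alternative local weights were tabulated
#' (those columns do not sum to 1).
#'
#' @param fw A `fuzzy_weights` object from [buckley_weights()].
#' @param defuzz `"sum_normalized"` (default) or `"centroid"`.
#' @return Named numeric vector of crisp weights.
#' @export
crisp_weights <- function(fw, defuzz = c("sum_normalized", "centroid")) {
  stopifnot(inherits(fw, "fuzzy_weights"))
  defuzz <- match.arg(defuzz)
  comp_sums <- rowSums(fw$fuzzy_weights)
  if (all(comp_sums == 0)) stop("crisp_weights: all-zero fuzzy weights")
  w <- switch(defuzz,
              sum_normalized = comp_sums / sum(comp_sums),
              centroid = comp_sums / 3)
  stats::setNames(w, fw$labels)
}

# ---------------------------------------------------------------------------
# Consistency

# Saaty's random consistency index, indexed by matrix dimension
saaty_random_index <- function(n) {
  ri <- c(0, 0, 0.58, 0.90, 1.12, 1.24, 1.32, 1.41, 1.45, 1.49,
          1.51, 1.48, 1.56, 1.57, 1.59)
  if (n < 1 || n > length(ri)) {
    stop("random index undefined for n = ", n)
  }
  ri[n]
}

#' Consistency ratio of a fuzzy pairwise matrix
#'
#' Defuzzifies each judgment to a crisp value, then applies Saaty's
#' principal-eigenvalue test: `CI = (lambda_max - n) / (n - 1)` and
#' `CR = CI / RI(n)` with Saaty's random-index table. `CR <= 0.1` is the
#' conventional acceptability gate; 2 x 2 reciprocal matrices are always
#' perfectly consistent.
#'
#' @param m A [pairwise_matrix] with `n >= 2`.
#' @param defuzz Per-entry defuzzification rule: `"centroid"`
#'   (`(L+M+U)/3`, default), `"modal"` (the middle component), or
#'   `"geometric"` (`(L*M*U)^(1/3)`).
#' @return An object of class `consistency_report`: a list with
#'   `lambda_max`, `consistency_index`, `random_index`, `consistency_ratio`,
#'   `defuzzification_rule`, `n` and `acceptable` (the `CR <= 0.1` gate).
#' @export
consistency_ratio <- function(m, defuzz = c("centroid", "modal", "geometric")) {
  stopifnot(inherits(m, "pairwise_matrix"))
  defuzz <- match.arg(defuzz)
  n <- length(m$labels)
  if (n < 2) stop("consistency_ratio requires n >= 2")
  f <- switch(defuzz,
              centroid = function(v) mean(v),
              modal = function(v) v[2],
              geometric = function(v) prod(v)^(1 / 3))
  crisp <- apply(m$entries, c(1, 2), f)
  lambda_max <- max(Re(eigen(crisp, only.values = TRUE)$values))
  ci <- (lambda_max - n) / (n - 1)
  ri <- saaty_random_index(n)
  cr <- if (ri == 0) 0 else ci / ri
  # guard tiny negative round-off for perfectly consistent matrices
  cr <- max(cr, 0)
  structure(list(lambda_max = lambda_max, consistency_index = max(ci, 0),
                 random_index = ri, consistency_ratio = cr,
                 defuzzification_rule = defuzz, n = n,
                 acceptable = cr <= 0.1),
            class = "consistency_report")
}

#' @export
print.consistency_report <- function(x, ...) {
  cat(sprintf("Consistency: n = %d, lambda_max = %.4f, CI = %.4f, RI = %.2f, CR = %.4f (%s; rule: %s)\n",
              x$n, x$lambda_max, x$consistency_index, x$random_index,
              x$consistency_ratio,
              if (x$acceptable) "acceptable" else "weak consistency",
              x$defuzzification_rule))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Hierarchy-level weighting and synthesis

#' Local alternative weights per sub-criterion
#'
#' Runs Buckley's method on one alternatives matrix per sub-criterion and
#' defuzzifies. The default `"centroid"` rule reproduces the packaged study's
#' published local-weight table, whose columns are unnormalized centroids of
#' the fuzzy weights; `"sum_normalized"` gives column sums of 1 instead.
#'
#' @param alt_matrices Named list of [pairwise_matrix] objects over the
#'   alternatives, one per sub-criterion.
#' @param defuzz Passed to [crisp_weights()].
#' @return Matrix of local weights, alternatives x sub-criteria.
#' @export
local_alternative_weights <- function(alt_matrices,
                                      defuzz = c("centroid", "sum_normalized")) {
  stopifnot(is.list(alt_matrices), length(alt_matrices) >= 1L,
            !is.null(names(alt_matrices)))
  defuzz <- match.arg(defuzz)
  alts <- alt_matrices[[1]]$labels
  out <- matrix(NA_real_, length(alts), length(alt_matrices),
                dimnames = list(alts, names(alt_matrices)))
  for (s in names(alt_matrices)) {
    m <- alt_matrices[[s]]
    if (!identical(m$labels, alts)) {
      stop("alternatives matrix for '", s, "' has mismatched labels")
    }
    out[, s] <- crisp_weights(buckley_weights(m), defuzz = defuzz)
  }
  out
}

#' Synthesize global alternative scores over the hierarchy
#'
#' Combines main-criterion weights, sub-criterion weights and local
#' alternative weights multiplicatively:
#' `score(A) = sum_s w_main(parent(s)) * w_sub(s) * local(A, s)`.
#'
#' @param main Named numeric vector of main-criterion weights.
#' @param subs Named list (one element per main criterion) of named numeric
#'   sub-criterion weight vectors, each summing to 1.
#' @param locals Alternatives x sub-criteria matrix of local weights.
#' @return Named numeric vector of global scores per alternative. Scores need
#'   not sum to 1 when the locals are unnormalized centroids.
#' @export
synthesize_global_scores <- function(main, subs, locals) {
  stopifnot(is.numeric(main), !is.null(names(main)), is.list(subs),
            is.matrix(locals))
  if (!setequal(names(subs), names(main))) {
    stop("subs must have one weight vector per main criterion")
  }
  sub_w <- unlist(unname(subs))
  parents <- stats::setNames(rep(names(subs), vapply(subs, length, integer(1))),
                             names(sub_w))
  if (!setequal(colnames(locals), names(sub_w))) {
    stop("locals columns [", paste(colnames(locals), collapse = ","),
         "] do not match the sub-criteria [",
         paste(names(sub_w), collapse = ","), "]")
  }
  s <- names(sub_w)
  crit_w <- main[parents[s]] * sub_w[s]
  scores <- as.vector(locals[, s, drop = FALSE] %*% crit_w)
  stats::setNames(scores, rownames(locals))
}

#' Rank alternatives by score
#'
#' @param scores Named numeric vector (higher is better).
#' @param tol Scores closer than `tol` are flagged as tied; ties keep input
#'   order.
#' @return Data frame with columns `alternative`, `score`, `rank`, `tied`,
#'   ordered best-first.
#' @export
rank_alternatives <- function(scores, tol = 1e-12) {
  stopifnot(is.numeric(scores), !is.null(names(scores)), all(is.finite(scores)))
  ord <- order(-scores)  # stable: ties keep input order
  out <- data.frame(alternative = names(scores)[ord],
                    score = unname(scores[ord]),
                    rank = seq_along(scores),
                    tied = FALSE,
                    stringsAsFactors = FALSE)
  if (length(scores) > 1) {
    d <- abs(diff(out$score)) <= tol
    out$tied <- c(d, FALSE) | c(FALSE, d)
    # tied entries share the best rank in their run
    for (i in seq_len(nrow(out) - 1)) {
      if (d[i]) out$rank[i + 1] <- out$rank[i]
    }
  }
  out
}

#' Criterion weights for a whole panel or consensus set
#'
#' Convenience wrapper running [buckley_weights()] and [crisp_weights()] on a
#' pairwise set (`main` plus one matrix per main-criterion group) and
#' returning the hierarchy-level weights.
#'
#' @param pairwise Named list of [pairwise_matrix]: element `main` plus one
#'   element per main criterion.
#' @param h A [hierarchy].
#' @return List with `main` (named vector), `subs` (named list of named
#'   vectors) and `product` (named vector over sub-criteria,
#'   `w_main(parent) * w_sub`).
#' @export
criterion_weights <- function(pairwise, h) {
  stopifnot(inherits(h, "hierarchy"), is.list(pairwise))
  need <- c("main", h$main_criteria)
  miss <- setdiff(need, names(pairwise))
  if (length(miss)) stop("missing pairwise matrices: ", paste(miss, collapse = ", "))
  main <- crisp_weights(buckley_weights(pairwise$main))
  subs <- lapply(h$main_criteria, function(g) {
    crisp_weights(buckley_weights(pairwise[[g]]))
  })
  names(subs) <- h$main_criteria
  sub_w <- unlist(unname(subs))
  parents <- parent_criteria(h)
  prod_w <- main[parents[names(sub_w)]] * sub_w
  list(main = main, subs = subs,
       product = stats::setNames(as.numeric(prod_w), names(sub_w)))
}
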