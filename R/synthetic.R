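# Synthetic expert panels with known ground truth.
#
# The generator emulates the statistical structure the analysis assumes:
# reciprocal judgment matrices that are near-consistent with a latent weight
# vector (exactly consistent at zero noise), and ordinal alternative ratings
# on the four-term performance scale, optionally with a dominant alternative.

# total order of importance terms used for step-noise perturbation:
# reciprocals mirror below E, base terms above, ordered by modal value
term_ladder <- function(scale = ahp_scale()) {
  base <- names(scale$terms)
  modal <- vapply(scale$terms, function(t) unclass(t)[2], numeric(1))
  base <- base[order(modal)]
  unit <- base[1]  # the (1,1,1) identity term
  c(rev(paste0("1/", setdiff(base, unit))), unit, setdiff(base, unit))
}

# evaluate a sequence of expressions under a temporary RNG state
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' Generator configuration for synthetic expert panels
#'
#' @param n_main Number of main criteria.
#' @param n_subs Sub-criteria per main criterion (scalar or vector).
#' @param n_alternatives Number of alternatives.
#' @param n_experts Panel size K.
#' @param seed Integer seed; the whole panel is reproducible from it.
#' @param noise_steps Maximum number of positions each upper-triangle
#'   judgment may move along the ordered term ladder (0 = exactly
#'   consistent with the ground truth).
#' @param snap_to_scale Whether judgment ratios are snapped to the nearest
#'   linguistic term. Defaults to `TRUE` when `noise_steps > 0` (step noise
#'   is defined on the term ladder), `FALSE` otherwise.
#' @param dominance Optional alternative label that receives the maximal
#'   rating on every criterion while all others rate strictly lower.
#' @param ground_truth Optional named list of weight vectors per group
#'   (`main`, each main criterion, `alts:<sub>` per sub-criterion); missing
#'   groups are drawn from a flat Dirichlet.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n_main = 4, n_subs = 2, n_alternatives = 3,
                             n_experts = 3, seed = 1, noise_steps = 0,
                             snap_to_scale = noise_steps > 0,
                             dominance = NULL, ground_truth = NULL) {
  stopifnot(n_main >= 1, all(n_subs >= 1), n_alternatives >= 2, n_experts >= 1,
            noise_steps >= 0)
  if (length(n_subs) == 1L) n_subs <- rep(n_subs, n_main)
  stopifnot(length(n_subs) == n_main)
  structure(list(n_main = n_main, n_subs = n_subs,
                 n_alternatives = n_alternatives, n_experts = n_experts,
                 seed = seed, noise_steps = noise_steps,
                 snap_to_scale = isTRUE(snap_to_scale),
                 dominance = dominance, ground_truth = ground_truth),
            class = "generator_config")
}

#' Perfectly consistent pairwise matrix from a weight vector
#'
#' Builds the crisp consistent matrix `a_ij = w_i / w_j` as degenerate
#' triangular numbers; Buckley's method recovers `w` exactly from it and its
#' consistency ratio is 0. With `snap_to_scale` each upper-triangle ratio is
#' replaced by the linguistic term (or reciprocal term) whose modal value is
#' nearest, preserving reciprocity.
#'
#' @param true_weights Positive named numeric vector (normalized internally).
#' @param snap_to_scale Snap ratios to the term ladder?
#' @param scale [linguistic_scale] used for snapping.
#' @param source Provenance tag.
#' @return A [pairwise_matrix].
#' @export
generate_consistent_matrix <- function(true_weights, snap_to_scale = FALSE,
                                       scale = ahp_scale(),
                                       source = "synthetic") {
  stopifnot(is.numeric(true_weights), all(true_weights > 0))
  w <- true_weights / sum(true_weights)
  n <- length(w)
  labels <- names(w)
  if (is.null(labels)) labels <- paste0("item", seq_len(n))
  arr <- array(NA_real_, c(n, n, 3))
  ladder <- term_ladder(scale)
  modal_of <- vapply(ladder, function(tm) unclass(scale_lookup(tm, scale))[2],
                     numeric(1))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    ratio <- w[i] / w[j]
    if (i == j) {
      arr[i, j, ] <- 1
    } else if (i < j) {
      if (snap_to_scale) {
        # nearest modal value; ties (several terms share modal 1) resolve
        # to the identity term E, then to the mildest judgment
        dist <- abs(modal_of - ratio)
        cand <- which(dist == min(dist))
        if (length(cand) > 1L) {
          e_pos <- match("E", ladder)
          cand <- cand[which.min(abs(cand - e_pos))]
        }
        tm <- ladder[cand[1]]
        arr[i, j, ] <- unclass(scale_lookup(tm, scale))
      } else {
        arr[i, j, ] <- ratio
      }
    } else {
      arr[i, j, ] <- rev(1 / arr[j, i, ])
    }
  }
  pairwise_matrix(arr, labels = labels, source = source)
}

#' Perturb a scale-valued pairwise matrix with step noise
#'
#' Moves each upper-triangle judgment uniformly at random by at most
#' `noise_steps` positions along the ordered term ladder (clamped at the
#' ends) and resets the lower triangle to the reciprocals. Deterministic
#' given `seed`; `noise_steps = 0` is the identity.
#'
#' @param m A [pairwise_matrix] whose entries all lie on the scale.
#' @param noise_steps Non-negative integer perturbation magnitude.
#' @param seed Integer seed (or `NULL` to use the current RNG stream).
#' @param scale [linguistic_scale] defining the ladder.
#' @return A [pairwise_matrix].
#' @export
perturb_matrix <- function(m, noise_steps, seed = NULL, scale = ahp_scale()) {
  stopifnot(inherits(m, "pairwise_matrix"), noise_steps >= 0)
  if (noise_steps == 0) return(m)
  codes <- encode_pcm_terms(m, scale)
  ladder <- term_ladder(scale)
  n <- length(m$labels)
  with_seed(seed, {
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i >= j) next
      pos <- match(codes[i, j], ladder)
      if (is.na(pos)) stop("entry (", i, ",", j, ") = '", codes[i, j],
                           "' is not on the term ladder")
      step <- sample.int(2L * noise_steps + 1L, 1L) - noise_steps - 1L
      pos <- min(max(pos + step, 1L), length(ladder))
      codes[i, j] <- ladder[pos]
      codes[j, i] <- flip_code(ladder[pos])
    }
  })
  pairwise_matrix(codes, labels = m$labels, source = m$source, scale = scale)
}

flip_code <- function(code) {
  if (grepl("^1/", code)) sub("^1/", "", code) else if (code == "E") "E"
  else paste0("1/", code)
}

#' Generate a synthetic expert panel
#'
#' Draws shared ground-truth weights for every pairwise group of the
#' hierarchy, builds each expert's judgment matrices as (optionally snapped
#' and step-perturbed) consistent matrices around those weights, and draws
#' linguistic ratings on the performance scale. With `noise_steps = 0` and
#' no snapping, the full AHP pipeline recovers the ground truth exactly.
#'
#' @param config A [generator_config].
#' @return An [expert_panel]; the ground-truth weights and the config are
#'   stored in its `metadata`.
#' @examples
#' panel <- generate_panel(generator_config(seed = 42, dominance = "A2"))
#' @export
generate_panel <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  mains <- paste0("C", seq_len(config$n_main))
  subs <- lapply(seq_len(config$n_main), function(i) {
    paste0("C", i, seq_len(config$n_subs[i]))
  })
  names(subs) <- mains
  alts <- paste0("A", seq_len(config$n_alternatives))
  h <- hierarchy(goal = "synthetic decision problem", main_criteria = mains,
                 sub_criteria = subs, alternatives = alts)
  groups <- c(list(main = mains), subs,
              stats::setNames(rep(list(alts), length(sub_criteria(h))),
                              paste0("alts:", sub_criteria(h))))
  rating_terms <- names(rating_scale()$terms)  # ordered P < F < G < VG
  with_seed(config$seed, {
    truth <- lapply(names(groups), function(g) {
      if (!is.null(config$ground_truth[[g]])) {
        w <- config$ground_truth[[g]]
      } else {
        w <- stats::rgamma(length(groups[[g]]), shape = 3)
      }
      stats::setNames(w / sum(w), groups[[g]])
    })
    names(truth) <- names(groups)
    experts <- list()
    for (k in seq_len(config$n_experts)) {
      pw <- lapply(names(groups), function(g) {
        m <- generate_consistent_matrix(truth[[g]],
                                        snap_to_scale = config$snap_to_scale,
                                        source = paste0("E", k))
        if (config$noise_steps > 0) {
          m <- perturb_matrix(m, config$noise_steps)
        }
        m
      })
      names(pw) <- names(groups)
      r <- matrix(NA_character_, length(alts), length(sub_criteria(h)),
                  dimnames = list(alts, sub_criteria(h)))
      top <- rating_terms[length(rating_terms)]
      for (a in alts) {
        if (!is.null(config$dominance) && a == config$dominance) {
          r[a, ] <- top
        } else if (!is.null(config$dominance)) {
          r[a, ] <- sample(rating_terms[-length(rating_terms)],
                           ncol(r), replace = TRUE)
        } else {
          r[a, ] <- sample(rating_terms, ncol(r), replace = TRUE)
        }
      }
      experts[[paste0("E", k)]] <- list(pairwise = pw, ratings = r)
    }
    expert_panel(h, experts,
                 metadata = list(generator = unclass(config),
                                 ground_truth = truth))
  })
}
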