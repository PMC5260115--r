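#' Decision hierarchy
#'
#' Describes a two-level criteria tree: a goal, main criteria, sub-criteria
#' grouped under their main criterion, and the alternatives to be ranked.
#' Each sub-criterion carries an attribute direction (`"benefit"` or
#' `"cost"`) used by the TOPSIS normalization step.
#'
#' @param goal Goal label.
#' @param main_criteria Character vector of main-criterion labels.
#' @param sub_criteria Named list mapping each main criterion to its ordered
#'   sub-criterion labels.
#' @param alternatives Character vector of alternative labels.
#' @param directions Named character vector (`"benefit"`/`"cost"`) per
#'   sub-criterion; defaults to all-benefit.
#' @return An object of class `hierarchy`.
#' @examples
#' hierarchy("anesthesia method",
#'           main_criteria = c("C1", "C2"),
#'           sub_criteria  = list(C1 = c("C11", "C12"), C2 = c("C21", "C22")),
#'           alternatives  = c("A1", "A2"))
#' @export
hierarchy <- function(goal, main_criteria, sub_criteria, alternatives,
                      directions = NULL) {
  stopifnot(is.character(main_criteria), length(main_criteria) >= 1L,
            is.list(sub_criteria), is.character(alternatives))
  if (!setequal(names(sub_criteria), main_criteria)) {
    stop("sub_criteria must be a named list with one entry per main criterion")
  }
  sub_criteria <- sub_criteria[main_criteria]  # enforce main-criterion order
  subs <- unlist(sub_criteria, use.names = FALSE)
  labs <- c(main_criteria, subs, alternatives)
  if (anyDuplicated(labs)) {
    stop("criterion and alternative labels must be unique; duplicated: ",
         paste(unique(labs[duplicated(labs)]), collapse = ", "))
  }
  if (is.null(directions)) {
    directions <- stats::setNames(rep("benefit", length(subs)), subs)
  }
  if (!setequal(names(directions), subs) ||
      !all(directions %in% c("benefit", "cost"))) {
    stop("directions must name every sub-criterion as 'benefit' or 'cost'")
  }
  structure(list(goal = goal,
                 main_criteria = main_criteria,
                 sub_criteria = sub_criteria,
                 alternatives = alternatives,
                 directions = directions[subs]),
            class = "hierarchy")
}

#' @export
print.hierarchy <- function(x, ...) {
  cat("Decision hierarchy: ", x$goal, "\n", sep = "")
  for (m in x$main_criteria) {
    cat("  ", m, ": ", paste(x$sub_criteria[[m]], collapse = ", "), "\n", sep = "")
  }
  cat("  alternatives: ", paste(x$alternatives, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' All sub-criteria of a hierarchy, in hierarchy order
#' @param h A [hierarchy].
#' @return Character vector of sub-criterion labels.
#' @export
sub_criteria <- function(h) {
  stopifnot(inherits(h, "hierarchy"))
  unlist(h$sub_criteria, use.names = FALSE)
}

#' Parent main criterion of each sub-criterion
#' @param h A [hierarchy].
#' @return Named character vector mapping sub-criterion to its main criterion.
#' @export
parent_criteria <- function(h) {
  stopifnot(inherits(h, "hierarchy"))
  stats::setNames(rep(h$main_criteria, lengths(h$sub_criteria)), sub_criteria(h))
}

# ---------------------------------------------------------------------------
# Pairwise comparison matrices

#' Fuzzy pairwise comparison matrix
#'
#' A square reciprocal matrix of triangular fuzzy judgments over one group of
#' items (main criteria, the sub-criteria of one main criterion, or the
#' alternatives under one sub-criterion). Stored as an `n x n x 3` array whose
#' third dimension holds the (lower, modal, upper) components.
#'
#' @param entries Either an `n x n x 3` numeric array of TFN components or a
#'   square character matrix of linguistic codes (decoded with `scale`).
#' @param labels Item labels (row/column names).
#' @param source Provenance tag, e.g. an expert id, `"consensus"` or
#'   `"aggregate"`.
#' @param scale [linguistic_scale] used to decode character entries.
#' @return An object of class `pairwise_matrix`.
#' @examples
#' pairwise_matrix(rbind(c("E", "VI"), c("1/VI", "E")),
#'                 labels = c("C31", "C32"), source = "consensus")
#' @export
pairwise_matrix <- function(entries, labels = NULL, source = "unspecified",
                            scale = ahp_scale()) {
  if (is.character(entries)) {
    stopifnot(is.matrix(entries), nrow(entries) == ncol(entries))
    n <- nrow(entries)
    if (is.null(labels)) labels <- rownames(entries)
    arr <- array(NA_real_, c(n, n, 3))
    for (i in seq_len(n)) for (j in seq_len(n)) {
      arr[i, j, ] <- unclass(scale_lookup(entries[i, j], scale))
    }
    entries <- arr
  }
  stopifnot(is.array(entries), length(dim(entries)) == 3L,
            dim(entries)[1] == dim(entries)[2], dim(entries)[3] == 3L)
  n <- dim(entries)[1]
  if (is.null(labels)) labels <- paste0("item", seq_len(n))
  stopifnot(length(labels) == n)
  dimnames(entries) <- list(labels, labels, c("lower", "modal", "upper"))
  structure(list(labels = as.character(labels), entries = entries,
                 source = source),
            class = "pairwise_matrix")
}

#' @export
print.pairwise_matrix <- function(x, digits = 3, ...) {
  n <- length(x$labels)
  cat("Fuzzy pairwise comparison matrix (", n, "x", n, ", source: ",
      x$source, ")\n", sep = "")
  disp <- matrix("", n, n, dimnames = list(x$labels, x$labels))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    disp[i, j] <- paste0("(", paste(signif(x$entries[i, j, ], digits),
                                    collapse = ","), ")")
  }
  print(disp, quote = FALSE)
  invisible(x)
}

#' Extract one judgment from a pairwise matrix
#' @param m A [pairwise_matrix].
#' @param i,j Row/column label or index.
#' @return A [tfn].
#' @export
pcm_entry <- function(m, i, j) {
  stopifnot(inherits(m, "pairwise_matrix"))
  v <- m$entries[i, j, ]
  tfn(v[1], v[2], v[3])
}

#' Check the reciprocal structure of a pairwise matrix
#'
#' A well-formed judgment matrix has unit diagonal (the `E` term, (1,1,1))
#' and lower-triangle entries equal to the fuzzy reciprocal of their mirrored
#' upper-triangle judgment.
#'
#' @param m A [pairwise_matrix].
#' @param tol Component tolerance.
#' @return A data frame of violations (zero rows when the matrix is valid)
#'   with columns `row`, `col`, `kind`.
#' @export
validate_reciprocity <- function(m, tol = 1e-9) {
  stopifnot(inherits(m, "pairwise_matrix"))
  n <- length(m$labels)
  bad <- list()
  for (i in seq_len(n)) {
    if (max(abs(m$entries[i, i, ] - 1)) > tol) {
      bad[[length(bad) + 1L]] <- data.frame(
        row = m$labels[i], col = m$labels[i], kind = "diagonal-not-unit")
    }
  }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i >= j) next
    up <- tfn(m$entries[i, j, 1], m$entries[i, j, 2], m$entries[i, j, 3])
    expect <- unclass(tfn_reciprocal(up))
    if (max(abs(m$entries[j, i, ] - expect)) > tol) {
      bad[[length(bad) + 1L]] <- data.frame(
        row = m$labels[j], col = m$labels[i], kind = "not-reciprocal")
    }
  }
  if (length(bad) == 0L) {
    data.frame(row = character(), col = character(), kind = character())
  } else {
    do.call(rbind, bad)
  }
}

#' Read a single pairwise matrix from CSV
#'
#' Expects a header row and first column of item labels, with cells holding
#' linguistic codes (`"VI"`, `"1/HI"`, ...).
#'
#' @param path CSV file path.
#' @param source Provenance tag for the resulting matrix.
#' @param scale Decoding [linguistic_scale].
#' @return A [pairwise_matrix].
#' @export
read_pcm_csv <- function(path, source = basename(path), scale = ahp_scale()) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  labels <- as.character(df[[1]])
  mat <- as.matrix(df[, -1, drop = FALSE])
  if (!identical(colnames(mat), labels)) {
    stop("CSV matrix header must repeat the row labels; got [",
         paste(colnames(mat), collapse = ", "), "] vs [",
         paste(labels, collapse = ", "), "]")
  }
  rownames(mat) <- labels
  pairwise_matrix(mat, labels = labels, source = source, scale = scale)
}

# ---------------------------------------------------------------------------
# Expert panels and JSON interchange

#' Expert panel
#'
#' Bundles a hierarchy with per-expert inputs: pairwise comparison sets
#' (one matrix for the main criteria, one per sub-criterion group, one per
#' sub-criterion over the alternatives) and/or linguistic rating grids.
#' Experts may carry only ratings (their judgment matrices then fall back to
#' a consensus set at analysis time).
#'
#' @param hierarchy A [hierarchy].
#' @param experts Named list; each element is a list with optional fields
#'   `pairwise` (named list: `main`, one per main criterion, and
#'   `alts:<sub>` per sub-criterion) and `ratings` (alternatives x
#'   sub-criteria character matrix of rating codes).
#' @param scenarios Optional named list of expert-weight vectors.
#' @param metadata Optional free-form list.
#' @return An object of class `expert_panel`.
#' @export
expert_panel <- function(hierarchy, experts, scenarios = NULL, metadata = NULL) {
  stopifnot(inherits(hierarchy, "hierarchy"), is.list(experts),
            !is.null(names(experts)))
  subs <- sub_criteria(hierarchy)
  for (id in names(experts)) {
    ex <- experts[[id]]
    if (!is.null(ex$pairwise)) {
      for (nm in names(ex$pairwise)) {
        pm <- ex$pairwise[[nm]]
        stopifnot(inherits(pm, "pairwise_matrix"))
        want <- pcm_group_labels(hierarchy, nm)
        if (!identical(pm$labels, want)) {
          stop("expert '", id, "' matrix '", nm, "': labels [",
               paste(pm$labels, collapse = ","), "] do not match group [",
               paste(want, collapse = ","), "]")
        }
      }
    }
    if (!is.null(ex$ratings)) {
      r <- ex$ratings
      stopifnot(is.matrix(r), is.character(r))
      if (!identical(rownames(r), hierarchy$alternatives) ||
          !identical(colnames(r), subs)) {
        stop("expert '", id, "' ratings must be an alternatives x sub-criteria ",
             "matrix with matching dimnames")
      }
    }
  }
  structure(list(hierarchy = hierarchy, experts = experts,
                 scenarios = scenarios, metadata = metadata),
            class = "expert_panel")
}

# which item labels a named pairwise group refers to
pcm_group_labels <- function(h, name) {
  if (identical(name, "main")) return(h$main_criteria)
  if (name %in% h$main_criteria) return(h$sub_criteria[[name]])
  if (grepl("^alts:", name)) {
    s <- sub("^alts:", "", name)
    if (s %in% sub_criteria(h)) return(h$alternatives)
  }
  stop("unknown pairwise group '", name, "'")
}

#' @export
print.expert_panel <- function(x, ...) {
  cat("Expert panel: ", length(x$experts), " expert(s) [",
      paste(names(x$experts), collapse = ", "), "]\n", sep = "")
  print(x$hierarchy)
  if (!is.null(x$scenarios)) {
    cat("  scenarios: ", paste(names(x$scenarios), collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Write / read an expert panel as interchange JSON
#'
#' The interchange format stores the hierarchy, each expert's pairwise
#' matrices as row-major grids of linguistic codes, ratings as per-alternative
#' code maps, and any scenarios, e.g.
#' `{"hierarchy": {...}, "experts": [{"id": "E3", "pairwise": {"main":
#' [[...]]}, "ratings": {"A1": {"C11": "F", ...}}}], "scenarios": {...}}`.
#' Matrices are re-encoded to codes on write, so a panel whose judgments all
#' lie on the scale round-trips losslessly.
#'
#' @param panel An [expert_panel].
#' @param path JSON file path.
#' @param scale [linguistic_scale] for pairwise codes.
#' @param rating_scale_ [linguistic_scale] for rating codes.
#' @return `read_panel_json()` returns an [expert_panel].
#' @export
write_panel_json <- function(panel, path, scale = ahp_scale(),
                             rating_scale_ = rating_scale()) {
  stopifnot(inherits(panel, "expert_panel"))
  h <- panel$hierarchy
  hobj <- list(goal = h$goal, main_criteria = h$main_criteria,
               sub_criteria = h$sub_criteria, alternatives = h$alternatives,
               directions = as.list(h$directions))
  exobj <- lapply(names(panel$experts), function(id) {
    ex <- panel$experts[[id]]
    out <- list(id = id)
    if (!is.null(ex$pairwise)) {
      out$pairwise <- lapply(ex$pairwise, function(pm) {
        enc <- encode_pcm_terms(pm, scale)
        lapply(seq_len(nrow(enc)), function(i) as.list(enc[i, ]))
      })
    }
    if (!is.null(ex$ratings)) {
      out$ratings <- lapply(rownames(ex$ratings), function(a) {
        as.list(stats::setNames(ex$ratings[a, ], colnames(ex$ratings)))
      })
      names(out$ratings) <- rownames(ex$ratings)
    }
    out
  })
  obj <- list(hierarchy = hobj, experts = exobj)
  if (!is.null(panel$scenarios)) obj$scenarios <- lapply(panel$scenarios, as.list)
  if (!is.null(panel$metadata)) obj$metadata <- panel$metadata
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

# express every entry of a pairwise matrix as a scale code (or "1/X")
encode_pcm_terms <- function(pm, scale = ahp_scale(), tol = 1e-9) {
  n <- length(pm$labels)
  out <- matrix(NA_character_, n, n, dimnames = list(pm$labels, pm$labels))
  codes <- c(names(scale$terms), paste0("1/", names(scale$terms)))
  vals <- lapply(codes, scale_lookup, scale = scale)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    v <- pm$entries[i, j, ]
    hit <- which(vapply(vals, function(tv) max(abs(unclass(tv) - v)) <= tol,
                        logical(1)))
    if (length(hit) == 0L) {
      stop("entry (", pm$labels[i], ",", pm$labels[j],
           ") = (", paste(signif(v, 6), collapse = ","),
           ") is not a term of scale '", scale$name, "'")
    }
    out[i, j] <- codes[hit[1]]
  }
  out
}

#' @rdname write_panel_json
#' @export
read_panel_json <- function(path, scale = ahp_scale(),
                            rating_scale_ = rating_scale()) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  hobj <- obj$hierarchy
  h <- hierarchy(goal = hobj$goal,
                 main_criteria = unlist(hobj$main_criteria),
                 sub_criteria = lapply(hobj$sub_criteria, unlist),
                 alternatives = unlist(hobj$alternatives),
                 directions = unlist(hobj$directions))
  subs <- sub_criteria(h)
  experts <- list()
  for (exobj in obj$experts) {
    ex <- list()
    if (!is.null(exobj$pairwise)) {
      ex$pairwise <- lapply(names(exobj$pairwise), function(nm) {
        rows <- exobj$pairwise[[nm]]
        mat <- do.call(rbind, lapply(rows, unlist))
        labels <- pcm_group_labels(h, nm)
        rownames(mat) <- colnames(mat) <- labels
        pairwise_matrix(mat, labels = labels, source = exobj$id, scale = scale)
      })
      names(ex$pairwise) <- names(exobj$pairwise)
    }
    if (!is.null(exobj$ratings)) {
      r <- matrix(NA_character_, length(h$alternatives), length(subs),
                  dimnames = list(h$alternatives, subs))
      for (a in names(exobj$ratings)) {
        r[a, ] <- unlist(exobj$ratings[[a]])[subs]
      }
      ex$ratings <- r
    }
    experts[[exobj$id]] <- ex
  }
  scenarios <- if (!is.null(obj$scenarios)) {
    lapply(obj$scenarios, function(s) unlist(s))
  }
  expert_panel(h, experts, scenarios = scenarios,
               metadata = obj$metadata)
}
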