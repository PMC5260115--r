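#' Triangular fuzzy numbers
#'
#' A triangular fuzzy number (TFN) is an ordered triple `(lower, modal, upper)`
#' describing a membership function that rises linearly from `lower` to 1 at
#' `modal` and falls back to 0 at `upper`. TFNs are the numeric carrier for
#' the linguistic judgments ("Very Important", "Good", ...) used throughout
#' the AHP and TOPSIS stages.
#'
#' @param lower,modal,upper Numeric components with `lower <= modal <= upper`.
#' @return An object of class `tfn`: a numeric vector of length 3.
#' @examples
#' tfn(5, 7, 9)            # "Very Important" on the weighting scale
#' tfn_reciprocal(tfn(5, 7, 9))
#' @export
tfn <- function(lower, modal, upper) {
  x <- c(lower, modal, upper)
  stopifnot(is.numeric(x), length(x) == 3L, !anyNA(x))
  if (!(x[1] <= x[2] && x[2] <= x[3])) {
    stop("invalid triangular fuzzy number: require lower <= modal <= upper, got (",
         paste(signif(x, 6), collapse = ", "), ")")
  }
  structure(as.numeric(x), class = "tfn")
}

#' @export
print.tfn <- function(x, digits = 4, ...) {
  cat("TFN (", paste(signif(unclass(x), digits), collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' @rdname tfn
#' @param x Object to test or coerce.
#' @export
is_tfn <- function(x) inherits(x, "tfn")

as_tfn <- function(x) {
  if (is_tfn(x)) return(x)
  tfn(x[1], x[2], x[3])
}

#' Triangular fuzzy arithmetic
#'
#' Component-wise operations on TFNs. Addition and scalar scaling are exact;
#' multiplication, reciprocal and roots use the standard component-wise
#' approximation, which is exact for degenerate (crisp) triples and is the
#' convention under which the packaged study's worked values were produced.
#'
#' @param a,b Objects of class [tfn].
#' @return A [tfn].
#' @name tfn-arith
NULL

#' @rdname tfn-arith
#' @export
tfn_add <- function(a, b) {
  a <- as_tfn(a); b <- as_tfn(b)
  tfn(a[1] + b[1], a[2] + b[2], a[3] + b[3])
}

#' @rdname tfn-arith
#' @export
tfn_mul <- function(a, b) {
  a <- as_tfn(a); b <- as_tfn(b)
  if (any(unclass(a) < 0) || any(unclass(b) < 0)) {
    stop("tfn_mul: components must be non-negative")
  }
  tfn(a[1] * b[1], a[2] * b[2], a[3] * b[3])
}

#' @rdname tfn-arith
#' @param k Non-negative crisp multiplier.
#' @export
tfn_scale <- function(a, k) {
  a <- as_tfn(a)
  stopifnot(is.numeric(k), length(k) == 1L, k >= 0)
  tfn(k * a[1], k * a[2], k * a[3])
}

#' @rdname tfn-arith
#' @export
tfn_reciprocal <- function(a) {
  a <- as_tfn(a)
  if (any(unclass(a) <= 0)) {
    stop("tfn_reciprocal: all components must be strictly positive")
  }
  tfn(1 / a[3], 1 / a[2], 1 / a[1])
}

#' @rdname tfn-arith
#' @param n Positive integer root order.
#' @export
tfn_root <- function(a, n) {
  a <- as_tfn(a)
  stopifnot(is.numeric(n), length(n) == 1L, n >= 1)
  if (any(unclass(a) < 0)) stop("tfn_root: components must be non-negative")
  tfn(a[1]^(1 / n), a[2]^(1 / n), a[3]^(1 / n))
}

#' Centroid defuzzification of a TFN
#'
#' @param a A [tfn].
#' @return The crisp centroid `(lower + modal + upper) / 3`.
#' @export
tfn_centroid <- function(a) {
  a <- as_tfn(a)
  mean(unclass(a))
}

# ---------------------------------------------------------------------------
# Linguistic scales

#' Linguistic scales
#'
#' A linguistic scale maps verbal term codes to triangular fuzzy numbers.
#' Two scales are built in, matching the packaged study:
#'
#' * `ahp_scale()` — the six-term importance scale for pairwise comparisons:
#'   E (1,1,1), SI (1,1,3), FI (1,3,5), HI (3,5,7), VI (5,7,9), EI (7,9,9).
#'   It supports reciprocal codes spelled `"1/X"`.
#' * `rating_scale()` — the four-term performance scale for alternative
#'   ratings: P (0,2.5,5), F (2.5,5,7.5), G (5,7.5,10), VG (7,10,10).
#'
#' @param name Scale identifier.
#' @param terms Named list of [tfn] values, one per term code.
#' @param supports_reciprocals Whether `"1/X"` codes are meaningful (they are
#'   for importance judgments, not for performance ratings).
#' @return An object of class `linguistic_scale`.
#' @export
linguistic_scale <- function(name, terms, supports_reciprocals = FALSE) {
  stopifnot(is.character(name), length(name) == 1L,
            is.list(terms), length(terms) >= 1L, !is.null(names(terms)))
  terms <- lapply(terms, as_tfn)
  structure(list(name = name, terms = terms,
                 supports_reciprocals = isTRUE(supports_reciprocals)),
            class = "linguistic_scale")
}

#' @export
print.linguistic_scale <- function(x, ...) {
  cat("Linguistic scale '", x$name, "' (", length(x$terms), " terms",
      if (x$supports_reciprocals) ", reciprocals" else "", ")\n", sep = "")
  for (tm in names(x$terms)) {
    cat("  ", format(tm, width = 4), "(",
        paste(signif(unclass(x$terms[[tm]]), 4), collapse = ", "), ")\n", sep = "")
  }
  invisible(x)
}

#' @rdname linguistic_scale
#' @export
ahp_scale <- function() {
  linguistic_scale("ahp", list(
    E  = tfn(1, 1, 1),
    SI = tfn(1, 1, 3),
    FI = tfn(1, 3, 5),
    HI = tfn(3, 5, 7),
    VI = tfn(5, 7, 9),
    EI = tfn(7, 9, 9)
  ), supports_reciprocals = TRUE)
}

#' @rdname linguistic_scale
#' @export
rating_scale <- function() {
  linguistic_scale("rating", list(
    P  = tfn(0, 2.5, 5),
    F  = tfn(2.5, 5, 7.5),
    G  = tfn(5, 7.5, 10),
    VG = tfn(7, 10, 10)
  ), supports_reciprocals = FALSE)
}

#' Look up a linguistic term on a scale
#'
#' Resolves a term code to its TFN. Reciprocal judgments are spelled with a
#' `"1/"` prefix (e.g. `"1/VI"`) and return the fuzzy reciprocal of the base
#' term, provided the scale supports reciprocals.
#'
#' @param term Character code, possibly prefixed `"1/"`.
#' @param scale A [linguistic_scale].
#' @return A [tfn].
#' @examples
#' scale_lookup("VI", ahp_scale())
#' scale_lookup("1/VI", ahp_scale())
#' @export
scale_lookup <- function(term, scale) {
  stopifnot(inherits(scale, "linguistic_scale"),
            is.character(term), length(term) == 1L)
  base <- term
  recip <- FALSE
  if (grepl("^1/+", term)) {
    if (!scale$supports_reciprocals) {
      stop("scale '", scale$name, "' does not support reciprocal terms: '", term, "'")
    }
    # tolerate doubled slashes ("1//SI") seen in transcribed tables
    base <- sub("^1/+", "", term)
    recip <- TRUE
  }
  v <- scale$terms[[base]]
  if (is.null(v)) {
    stop("unknown linguistic term '", term, "' on scale '", scale$name,
         "' (known: ", paste(names(scale$terms), collapse = ", "), ")")
  }
  if (recip) tfn_reciprocal(v) else v
}

#' Serialize / read a linguistic scale as JSON
#'
#' The on-disk form is `{"name": ..., "supports_reciprocals": ...,
#' "terms": {"VI": [5,7,9], ...}}`. Both built-in scales also ship as
#' packaged JSON under `extdata/`.
#'
#' @param scale A [linguistic_scale].
#' @param path File path.
#' @return `read_scale_json()` returns a [linguistic_scale];
#'   `write_scale_json()` returns `path` invisibly.
#' @export
write_scale_json <- function(scale, path) {
  stopifnot(inherits(scale, "linguistic_scale"))
  obj <- list(name = scale$name,
              supports_reciprocals = scale$supports_reciprocals,
              terms = lapply(scale$terms, unclass))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_scale_json
#' @export
read_scale_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  linguistic_scale(obj$name,
                   lapply(obj$terms, function(v) tfn(v[1], v[2], v[3])),
                   supports_reciprocals = isTRUE(obj$supports_reciprocals))
}
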