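#' Per-attribute distance with heterogeneous dispatch
#'
#' Dispatches on the attribute kind: quantitative values use the
#' range-normalised absolute difference `|v1 - v2| / range_a`, clipped to
#' `[0, 1]` for out-of-range candidates; binary values use the Hamming
#' distance (0 if equal, 1 otherwise); ordinal values are looked up in the
#' attribute's expert distance matrix. When either value is missing the
#' neutral distance 0.5 is returned regardless of kind.
#'
#' @param attr An [attribute_schema()].
#' @param v1,v2 Attribute values (or `NA`/`""` for missing).
#' @param matrices Named list of [ordinal_matrix()] objects; required for
#'   ordinal attributes (a default built from the calcification profile is
#'   used when absent only if `default_matrix = TRUE`).
#' @param range Numeric `c(min, max)` overriding the schema bounds
#'   (e.g. a range frozen from a case-base).
#' @param default_matrix Build a default matrix for an ordinal attribute
#'   with no registered matrix instead of erroring.
#' @return A distance in `[0, 1]`.
#' @export
attr_distance <- function(attr, v1, v2, matrices = NULL, range = NULL,
                          default_matrix = FALSE) {
  stopifnot(inherits(attr, "attribute_schema"))
  if (is_missing_value(v1) || is_missing_value(v2)) return(0.5)
  if (attr$kind == "quantitative") {
    rng <- range %||% attr$range
    if (is.null(rng) || any(is.na(rng)))
      stopf("attribute '%s': no range available for the Euclidean distance", attr$name)
    quant_dist(as.numeric(v1), as.numeric(v2), rng)
  } else if (attr$kind == "binary") {
    check_categorical(attr, c(v1, v2))
    as.numeric(v1 != v2)
  } else {
    m <- matrices[[attr$name]]
    if (is.null(m)) {
      if (!default_matrix)
        stopf("ordinal attribute '%s' has no registered distance matrix", attr$name)
      m <- default_ordinal_matrix(attr$name, attr$categories)
    }
    check_categorical(attr, c(v1, v2))
    unname(m$entries[v1, v2])
  }
}

check_categorical <- function(attr, vals) {
  bad <- setdiff(as.character(vals), attr$categories)
  if (length(bad))
    stopf("attribute '%s': value '%s' not in declared categories",
          attr$name, bad[1])
  invisible(TRUE)
}

quant_dist <- function(v1, v2, rng) {
  width <- rng[2] - rng[1]
  if (width <= 0) return(as.numeric(v1 != v2))  # degenerate range
  min(abs(v1 - v2) / width, 1)
}

#' Weighted heterogeneous dissimilarity between two cases
#'
#' The normalised weighted sum of per-attribute distances over the selected
#' attributes: `sum(w_a * d_a) / sum(w_a)`. All per-attribute distances use
#' the heterogeneous dispatch of [attr_distance()] (missing values count
#' 0.5), so the result lies in `[0, 1]` and is symmetric in the two cases.
#'
#' @param c1,c2 Cases ([new_case()] objects or named attribute lists).
#' @param attrs Attribute names entering the sum (non-empty).
#' @param weights Named non-negative weights; their sum over `attrs` must be
#'   positive.
#' @param schema A [cbr_schema()].
#' @param matrices Named list of [ordinal_matrix()]; defaults are built for
#'   ordinal attributes without one.
#' @param ranges Optional named list of frozen quantitative ranges
#'   overriding the schema bounds.
#' @return Dissimilarity in `[0, 1]`.
#' @export
weighted_dissimilarity <- function(c1, c2, attrs, weights, schema,
                                   matrices = NULL, ranges = NULL) {
  stopifnot(inherits(schema, "cbr_schema"))
  if (length(attrs) == 0L) stopf("attrs must be non-empty")
  unknown <- setdiff(attrs, names(schema$attributes))
  if (length(unknown)) stopf("unknown attribute(s): %s", paste(unknown, collapse = ", "))
  w <- weight_vector(weights, attrs)
  if (sum(w) <= 0) stopf("all weights are zero over the selected attributes")
  mats <- build_matrices(schema, matrices)
  a1 <- case_attrs(c1, schema); a2 <- case_attrs(c2, schema)
  d <- vapply(attrs, function(a) {
    attr_distance(schema$attributes[[a]], a1[[a]], a2[[a]], mats,
                  range = ranges[[a]], default_matrix = TRUE)
  }, numeric(1))
  sum(w * d) / sum(w)
}

# Coerce weights into a named vector aligned with attrs (missing names -> 1).
weight_vector <- function(weights, attrs) {
  if (is.null(weights)) return(stats::setNames(rep(1, length(attrs)), attrs))
  w <- unlist(weights)
  if (is.null(names(w))) {
    if (length(w) != length(attrs))
      stopf("unnamed weights must match the attribute list length")
    names(w) <- attrs
  }
  out <- stats::setNames(rep(1, length(attrs)), attrs)
  out[intersect(attrs, names(w))] <- w[intersect(attrs, names(w))]
  if (any(out < 0)) stopf("weights must be non-negative")
  out
}

#' Similarity from a dissimilarity measure
#'
#' Similarity is the complement of dissimilarity: `sim = 1 - diss`.
#'
#' @param c1,c2 Cases.
#' @param measure A function `(c1, c2, ...)` returning a dissimilarity in
#'   `[0, 1]`, e.g. a closure over [weighted_dissimilarity()].
#' @param ... Passed on to `measure`.
#' @return Similarity in `[0, 1]`.
#' @export
similarity <- function(c1, c2, measure, ...) {
  d <- measure(c1, c2, ...)
  if (is.na(d) || d < 0 || d > 1) stopf("measure returned %s, outside [0, 1]", d)
  1 - d
}

#' Heterogeneous Euclidean-overlap metric (HEOM)
#'
#' The unweighted baseline: square root of the sum over *all* schema
#' attributes of squared per-attribute distances, with the overlap (0/1)
#' metric for qualitative attributes (ordinal grades compared nominally)
#' and the range-normalised difference for quantitative ones. A missing
#' value on either side contributes distance 1. No attribute selection, no
#' weighting.
#'
#' @param c1,c2 Cases.
#' @param schema A [cbr_schema()].
#' @param ranges Optional named list of frozen quantitative ranges.
#' @return Non-negative distance (at most `sqrt(n)` for n attributes).
#' @export
heom_distance <- function(c1, c2, schema, ranges = NULL) {
  stopifnot(inherits(schema, "cbr_schema"))
  a1 <- case_attrs(c1, schema); a2 <- case_attrs(c2, schema)
  ss <- 0
  for (a in names(schema$attributes)) {
    def <- schema$attributes[[a]]
    v1 <- a1[[a]]; v2 <- a2[[a]]
    d <- if (is_missing_value(v1) || is_missing_value(v2)) {
      1
    } else if (def$kind == "quantitative") {
      rng <- ranges[[a]] %||% def$range
      if (is.null(rng) || any(is.na(rng)))
        stopf("attribute '%s': no range available", a)
      quant_dist(as.numeric(v1), as.numeric(v2), rng)
    } else {
      as.numeric(v1 != v2)
    }
    ss <- ss + d^2
  }
  sqrt(ss)
}

#' Generalised weighted heterogeneous dissimilarity (GWHSM)
#'
#' Weighted mean of per-attribute distances with the Euclidean distance for
#' quantitative attributes and the Hamming (exact-match) distance for all
#' categorical ones, ordinal included. Attributes with a missing value in
#' either case are discarded from both numerator and denominator, so
#' missing values play no part in the measure.
#'
#' @param c1,c2 Cases.
#' @param weights Named non-negative weights (default all 1).
#' @param schema A [cbr_schema()].
#' @param attrs Attribute names to use (default: all schema attributes).
#' @param ranges Optional named list of frozen quantitative ranges.
#' @return Dissimilarity in `[0, 1]`; errors when every selected attribute
#'   is missing (no informative attribute).
#' @export
gwhsm_dissimilarity <- function(c1, c2, weights = NULL, schema,
                                attrs = names(schema$attributes),
                                ranges = NULL) {
  stopifnot(inherits(schema, "cbr_schema"))
  if (length(attrs) == 0L) stopf("attrs must be non-empty")
  w <- weight_vector(weights, attrs)
  a1 <- case_attrs(c1, schema); a2 <- case_attrs(c2, schema)
  num <- 0; den <- 0
  for (a in attrs) {
    v1 <- a1[[a]]; v2 <- a2[[a]]
    if (is_missing_value(v1) || is_missing_value(v2)) next
    def <- schema$attributes[[a]]
    d <- if (def$kind == "quantitative") {
      rng <- ranges[[a]] %||% def$range
      if (is.null(rng) || any(is.na(rng)))
        stopf("attribute '%s': no range available", a)
      quant_dist(as.numeric(v1), as.numeric(v2), rng)
    } else {
      as.numeric(v1 != v2)
    }
    num <- num + w[[a]] * d
    den <- den + w[[a]]
  }
  if (den <= 0)
    stopf("no informative attribute: every selected attribute is missing (or zero-weighted) in one of the cases")
  num / den
}

## ---- vectorised internals used by retrieval / evaluation / GA ----------

# Measure context: schema + frozen ranges + complete matrix set.
measure_ctx <- function(cb, matrices = NULL) {
  list(schema = cb$schema, ranges = cb$ranges,
       matrices = build_matrices(cb$schema, matrices))
}

# Eq-5 distance of a scalar candidate value against a whole column.
eq5_vec <- function(def, v, col, rng, mat) {
  n <- length(col)
  if (is_missing_value(v)) return(rep(0.5, n))
  out <- numeric(n)
  miss <- is.na(col)
  out[miss] <- 0.5
  ok <- !miss
  if (!any(ok)) return(out)
  if (def$kind == "quantitative") {
    if (is.null(rng) || any(is.na(rng)))
      stopf("attribute '%s': no range available", def$name)
    width <- rng[2] - rng[1]
    out[ok] <- if (width <= 0) as.numeric(col[ok] != v)
               else pmin(abs(col[ok] - as.numeric(v)) / width, 1)
  } else if (def$kind == "binary") {
    out[ok] <- as.numeric(col[ok] != v)
  } else {
    out[ok] <- unname(mat$entries[as.character(v), col[ok]])
  }
  out
}

# Weighted Eq-2 dissimilarity of one candidate against every row of df.
diss_rows <- function(vals, df, attrs, w, ctx) {
  wsum <- sum(w[attrs])
  if (wsum <= 0) stopf("all weights are zero over the selected attributes")
  acc <- numeric(nrow(df))
  for (a in attrs) {
    def <- ctx$schema$attributes[[a]]
    acc <- acc + w[[a]] * eq5_vec(def, vals[[a]], df[[a]],
                                  ctx$ranges[[a]], ctx$matrices[[a]])
  }
  acc / wsum
}

# HEOM of one candidate against every row of df.
heom_rows <- function(vals, df, ctx) {
  ss <- numeric(nrow(df))
  for (a in names(ctx$schema$attributes)) {
    def <- ctx$schema$attributes[[a]]
    v <- vals[[a]]; col <- df[[a]]
    if (is_missing_value(v)) {
      d <- rep(1, nrow(df))
    } else {
      d <- numeric(nrow(df))
      miss <- is.na(col)
      d[miss] <- 1
      ok <- !miss
      if (any(ok)) {
        if (def$kind == "quantitative") {
          rng <- ctx$ranges[[a]] %||% def$range
          width <- rng[2] - rng[1]
          d[ok] <- if (width <= 0) as.numeric(col[ok] != v)
                   else pmin(abs(col[ok] - as.numeric(v)) / width, 1)
        } else {
          d[ok] <- as.numeric(col[ok] != v)
        }
      }
    }
    ss <- ss + d^2
  }
  sqrt(ss)
}

# GWHSM of one candidate against every row of df; pairs sharing no
# informative attribute get the maximal dissimilarity 1.
gwhsm_rows <- function(vals, df, attrs, w, ctx) {
  num <- numeric(nrow(df)); den <- numeric(nrow(df))
  for (a in attrs) {
    v <- vals[[a]]; col <- df[[a]]
    if (is_missing_value(v)) next
    ok <- !is.na(col)
    if (!any(ok)) next
    def <- ctx$schema$attributes[[a]]
    d <- numeric(sum(ok))
    if (def$kind == "quantitative") {
      rng <- ctx$ranges[[a]] %||% def$range
      width <- rng[2] - rng[1]
      d <- if (width <= 0) as.numeric(col[ok] != v)
           else pmin(abs(col[ok] - as.numeric(v)) / width, 1)
    } else {
      d <- as.numeric(col[ok] != v)
    }
    num[ok] <- num[ok] + w[[a]] * d
    den[ok] <- den[ok] + w[[a]]
  }
  out <- rep(1, nrow(df))
  inf <- den > 0
  out[inf] <- num[inf] / den[inf]
  out
}

# Pairwise per-attribute GWHSM distance arrays over a case-base: for each
# attribute a list(D = n x n distances with 0 where masked, M = n x n
# informative-pair mask). Weight changes then cost only matrix sums, which
# is what makes the GA fitness affordable.
gwhsm_pair_arrays <- function(cb, attrs, ctx) {
  df <- cb$cases
  n <- nrow(df)
  out <- list()
  for (a in attrs) {
    def <- ctx$schema$attributes[[a]]
    col <- df[[a]]
    present <- !is.na(col)
    M <- outer(present, present, `&`)
    if (def$kind == "quantitative") {
      rng <- ctx$ranges[[a]] %||% def$range
      width <- rng[2] - rng[1]
      D <- if (width <= 0) (outer(col, col, `!=`)) * 1
           else pmin(abs(outer(col, col, `-`)) / width, 1)
    } else {
      D <- (outer(col, col, `!=`)) * 1
    }
    D[!M] <- 0
    out[[a]] <- list(D = D, M = M * 1)
  }
  out
}
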