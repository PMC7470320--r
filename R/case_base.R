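#' Build a case, the unit of experience of the CBR system
#'
#' A case bundles the problem description (attribute values), the solution
#' per decision (e.g. the vascular access used) and the procedure outcome.
#' Candidate cases entering the retrieve step carry attributes only.
#'
#' @param id Unique case identifier.
#' @param attributes Named list/vector of attribute values; use `NA` (or omit
#'   the attribute) for missing.
#' @param solution Named list: decision name -> solution label.
#' @param result Named list of outcome fields.
#' @return An object of class `cbr_case`.
#' @export
new_case <- function(id, attributes, solution = list(), result = list()) {
  if (!is.character(id) || length(id) != 1L || !nzchar(id))
    stopf("case id must be a non-empty string")
  structure(list(id = id, attributes = as.list(attributes),
                 solution = as.list(solution), result = as.list(result)),
            class = "cbr_case")
}

#' @export
print.cbr_case <- function(x, ...) {
  cat("<cbr_case> ", x$id, "\n", sep = "")
  if (length(x$solution))
    cat("  solution:", paste(names(x$solution), unlist(x$solution),
                             sep = " = ", collapse = "; "), "\n")
  invisible(x)
}

#' Construct a validated case-base
#'
#' Validates every cell of `cases` against the schema and freezes the
#' quantitative normalisation ranges: the schema bounds when declared,
#' otherwise the min/max observed in these initial cases. The frozen ranges
#' are *not* recomputed after later filtering or retention, which keeps the
#' Euclidean per-attribute distance comparable across retrieval levels and
#' candidate cases; out-of-range values clip the distance at 1.
#'
#' @param schema A [cbr_schema()].
#' @param cases A data frame with columns `case_id`, one column per
#'   attribute, `solution.<decision>` columns and `result.<name>` columns.
#'   Character columns are converted per the schema; empty strings and
#'   `"NA"` become missing.
#' @return An object of class `case_base` with fields `schema`, `cases`
#'   (typed data frame) and `ranges` (frozen per-attribute ranges).
#' @export
case_base <- function(schema, cases) {
  stopifnot(inherits(schema, "cbr_schema"), is.data.frame(cases))
  cases <- as.data.frame(cases, stringsAsFactors = FALSE)
  req <- c("case_id", names(schema$attributes),
           if (length(schema$decisions)) paste0("solution.", names(schema$decisions)),
           if (length(schema$results)) paste0("result.", schema$results))
  unknown <- setdiff(names(cases), req)
  if (length(unknown))
    stopf("unknown column(s) not in schema: %s", paste(unknown, collapse = ", "))
  miss_cols <- setdiff(req, names(cases))
  if (length(miss_cols))
    stopf("missing column(s): %s", paste(miss_cols, collapse = ", "))
  cases <- cases[, req, drop = FALSE]
  if (nrow(cases) < 1L) stopf("a case-base needs at least one case (m >= 1)")

  cases$case_id <- as.character(cases$case_id)
  if (anyDuplicated(cases$case_id))
    stopf("duplicate case ids: %s",
          paste(unique(cases$case_id[duplicated(cases$case_id)]), collapse = ", "))

  errs <- character()
  for (a in names(schema$attributes)) {
    def <- schema$attributes[[a]]
    conv <- convert_column(cases[[a]], def)
    cases[[a]] <- conv$values
    if (length(conv$bad))
      errs <- c(errs, sprintf("case '%s', attribute '%s': invalid value '%s'",
                              cases$case_id[conv$bad], a, conv$raw[conv$bad]))
  }
  for (d in names(schema$decisions)) {
    col <- paste0("solution.", d)
    v <- normalize_missing(as.character(cases[[col]]),
                           missing_code = character())
    bad <- which(!is.na(v) & !(v %in% schema$decisions[[d]]))
    if (length(bad))
      errs <- c(errs, sprintf("case '%s', decision '%s': label '%s' not in vocabulary",
                              cases$case_id[bad], d, v[bad]))
    cases[[col]] <- v
  }
  for (r in schema$results) {
    col <- paste0("result.", r)
    cases[[col]] <- normalize_missing(as.character(cases[[col]]), character())
  }
  if (length(errs)) stopf("case-base validation failed:\n  %s",
                          paste(errs, collapse = "\n  "))
  rownames(cases) <- NULL

  ranges <- frozen_ranges(schema, cases)
  structure(list(schema = schema, cases = cases, ranges = ranges),
            class = "case_base")
}

# Schema range if declared, else observed extrema of the initial case-base.
frozen_ranges <- function(schema, cases) {
  ranges <- list()
  for (a in names(schema$attributes)) {
    def <- schema$attributes[[a]]
    if (def$kind != "quantitative") next
    ranges[[a]] <- if (!is.null(def$range)) {
      def$range
    } else {
      v <- cases[[a]]
      if (all(is.na(v))) c(NA_real_, NA_real_) else range(v, na.rm = TRUE)
    }
  }
  ranges
}

# Convert a raw CSV column to its typed form; returns indices of bad cells.
convert_column <- function(raw, def) {
  raw <- as.character(raw)
  v <- normalize_missing(raw, def$missing_code)
  if (def$kind == "quantitative") {
    num <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & is.na(num))
    if (!is.null(def$range)) {
      out <- which(!is.na(num) & (num < def$range[1] | num > def$range[2]))
      bad <- sort(union(bad, out))
    }
    list(values = num, raw = raw, bad = bad)
  } else {
    bad <- which(!is.na(v) & !(v %in% def$categories))
    list(values = v, raw = raw, bad = bad)
  }
}

normalize_missing <- function(x, missing_code) {
  x[is.na(x) | !nzchar(x) | x == "NA"] <- NA_character_
  if (length(missing_code) && nzchar(missing_code)) x[x == missing_code] <- NA_character_
  x
}

#' Read a case-base from CSV
#'
#' The CSV dialect has a `case_id` first column, then the attribute columns,
#' then `solution.<decision>` and `result.<name>` columns. Empty cells and
#' `"NA"` are read as missing; row order is preserved.
#'
#' @param path CSV file path.
#' @param schema A [cbr_schema()] or the path of a schema config.
#' @return A [case_base()].
#' @export
load_case_base <- function(path, schema) {
  if (is.character(schema)) schema <- load_schema(schema)
  if (!file.exists(path)) stopf("case-base file not found: %s", path)
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  case_base(schema, df)
}

#' Write a case-base to CSV
#'
#' Inverse of [load_case_base()]: missing cells are written as empty
#' strings, ordering and values round-trip exactly.
#'
#' @param cb A [case_base()].
#' @param path Output CSV path.
#' @export
write_case_base <- function(cb, path) {
  stopifnot(inherits(cb, "case_base"))
  utils::write.csv(cb$cases, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Number of cases in a case-base
#' @param cb A [case_base()].
#' @export
n_cases <- function(cb) nrow(cb$cases)

#' @export
print.case_base <- function(x, ...) {
  cat("<case_base> m =", nrow(x$cases), "cases,",
      length(x$schema$attributes), "attributes\n")
  for (d in names(x$schema$decisions)) {
    tab <- table(x$cases[[paste0("solution.", d)]], useNA = "no")
    cat("  ", d, ": ", paste(names(tab), tab, sep = "=", collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

#' Retain (append) a solved case into the case-base
#'
#' Adds one validated case at the end of the case-base; the frozen
#' quantitative ranges are deliberately left unchanged.
#'
#' @param cb A [case_base()].
#' @param case A [new_case()] with attributes, solution(s) and result(s).
#' @return The enlarged case-base (m + 1 cases).
#' @export
retain_case <- function(cb, case) {
  stopifnot(inherits(cb, "case_base"), inherits(case, "cbr_case"))
  if (case$id %in% cb$cases$case_id)
    stopf("case id '%s' already present in the case-base", case$id)
  row <- case_to_row(cb$schema, case)
  validated <- case_base(cb$schema, rbind(cb$cases, row))
  validated$ranges <- cb$ranges   # ranges stay frozen from the initial base
  validated
}

#' Remove a case by id
#' @param cb A [case_base()].
#' @param id Case id to drop.
#' @return The reduced case-base; frozen ranges unchanged.
#' @export
remove_case <- function(cb, id) {
  keep <- cb$cases$case_id != id
  if (all(keep)) stopf("case id '%s' not in the case-base", id)
  if (!any(keep)) stopf("cannot remove the last case (m >= 1 required)")
  cb$cases <- cb$cases[keep, , drop = FALSE]
  rownames(cb$cases) <- NULL
  cb
}

#' Extract one case
#' @param cb A [case_base()].
#' @param id Case id.
#' @return A [new_case()] object.
#' @export
get_case <- function(cb, id) {
  i <- match(id, cb$cases$case_id)
  if (is.na(i)) stopf("case id '%s' not in the case-base", id)
  row <- cb$cases[i, , drop = FALSE]
  attrs <- as.list(row[names(cb$schema$attributes)])
  sol <- if (length(cb$schema$decisions))
    as.list(row[paste0("solution.", names(cb$schema$decisions))]) else list()
  names(sol) <- names(cb$schema$decisions)
  res <- if (length(cb$schema$results))
    as.list(row[paste0("result.", cb$schema$results)]) else list()
  names(res) <- cb$schema$results
  new_case(row$case_id, attrs, sol, res)
}

# One-row data frame in the case-base column layout.
case_to_row <- function(schema, case) {
  unknown <- setdiff(names(case$attributes), names(schema$attributes))
  if (length(unknown))
    stopf("case '%s': unknown attribute(s) %s", case$id,
          paste(unknown, collapse = ", "))
  row <- data.frame(case_id = case$id, stringsAsFactors = FALSE)
  for (a in names(schema$attributes)) {
    v <- case$attributes[[a]]
    row[[a]] <- if (is_missing_value(v)) NA else v
  }
  for (d in names(schema$decisions)) {
    v <- case$solution[[d]]
    row[[paste0("solution.", d)]] <- if (is_missing_value(v)) NA_character_ else as.character(v)
  }
  for (r in schema$results) {
    v <- case$result[[r]]
    row[[paste0("result.", r)]] <- if (is_missing_value(v)) NA_character_ else as.character(v)
  }
  row
}

#' Observed range of a quantitative attribute
#'
#' Extrema over the non-missing values currently in the case-base. This is
#' the quantity frozen at construction time when the schema declares no
#' bounds; a degenerate range (single distinct value) is flagged with a
#' warning.
#'
#' @param cb A [case_base()].
#' @param attr Name of a quantitative attribute.
#' @return Numeric `c(min, max)`.
#' @export
attribute_observed_range <- function(cb, attr) {
  def <- cb$schema$attributes[[attr]]
  if (is.null(def)) stopf("unknown attribute '%s'", attr)
  if (def$kind != "quantitative")
    stopf("attribute '%s' is %s, not quantitative", attr, def$kind)
  v <- cb$cases[[attr]]
  v <- v[!is.na(v)]
  if (!length(v)) stopf("attribute '%s': all values missing", attr)
  r <- range(v)
  if (r[1] == r[2])
    warning(sprintf("attribute '%s': degenerate range (min = max = %g)", attr, r[1]))
  r
}

# Candidate attribute values as a named list over all schema attributes,
# NA where missing. Accepts cbr_case, named list/vector or one-row df.
case_attrs <- function(case, schema) {
  vals <- if (inherits(case, "cbr_case")) case$attributes
          else if (is.data.frame(case)) as.list(case[1, , drop = FALSE])
          else as.list(case)
  out <- stats::setNames(vector("list", length(schema$attributes)),
                         names(schema$attributes))
  for (a in names(schema$attributes)) {
    v <- vals[[a]]
    out[[a]] <- if (is_missing_value(v)) NA else v
  }
  out
}
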