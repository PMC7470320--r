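#' Hierarchical weighted heterogeneous retrieval
#'
#' The hierarchical retrieve over a clinical decision tree. For each level
#' `l = 1..L` of the CDT the dissimilarity between the candidate and the
#' surviving cases is recomputed over the cumulative attribute set of
#' levels `1..l` with the level weights of [level_weights()]; when
#' `m / 2^l > min_cases` (with `m` the size of the *initial* case-base) and
#' `l != L`, only the most similar half of the survivors (rounded up) is
#' kept. The final ranking uses the level-`L` dissimilarity over the last
#' surviving set; the hierarchical similarity is its complement,
#' `1 - diss_L`. The guard means small case-bases are never filtered: the
#' hierarchy then acts purely through attribute accumulation and
#' weighting.
#'
#' Ties — both in the final ranking and at the halving cut — are resolved
#' by `(dissimilarity, case id)` stable order; cases past the cut are
#' dropped even when tied with the last survivor.
#'
#' @param candidate The query case ([new_case()] or named attribute list);
#'   must not be a member of `cb`.
#' @param cb A [case_base()].
#' @param cdt A [clinical_decision_tree()] whose attributes all exist in
#'   the schema.
#' @param matrices Optional named list of [ordinal_matrix()] overrides.
#' @param min_cases Filtering floor: the surviving case-base is never
#'   halved below this size (default 20).
#' @return A `retrieval_result`: `ranked` data frame (`case_id`,
#'   `dissimilarity`, `similarity`, `rank`) over the final survivors, and
#'   `level_trace`, the per-level surviving id sets.
#' @export
h_whsm_retrieve <- function(candidate, cb, cdt, matrices = NULL,
                            min_cases = 20) {
  stopifnot(inherits(cb, "case_base"), inherits(cdt, "clinical_decision_tree"))
  m <- nrow(cb$cases)
  unknown <- setdiff(unlist(cdt$levels), names(cb$schema$attributes))
  if (length(unknown))
    stopf("CDT references unknown attribute(s): %s", paste(unknown, collapse = ", "))
  ctx <- measure_ctx(cb, matrices)
  vals <- case_attrs(candidate, cb$schema)
  cand_id <- if (inherits(candidate, "cbr_case")) candidate$id else NA_character_
  if (!is.na(cand_id) && cand_id %in% cb$cases$case_id)
    stopf("candidate '%s' is already a member of the case-base", cand_id)

  ids <- cb$cases$case_id
  w <- level_weights(cdt)
  surv <- seq_len(m)
  trace <- vector("list", cdt$L)
  diss <- numeric(0)
  for (l in seq_len(cdt$L)) {
    attrs <- attributes_through_level(cdt, l)
    diss <- diss_rows(vals, cb$cases[surv, , drop = FALSE], attrs, w, ctx)
    if (m / 2^l > min_cases && l != cdt$L) {
      ord <- order_by_diss(diss, ids[surv])
      keep <- sort(surv[ord[seq_len(ceiling(length(surv) / 2))]])
      diss <- diss[match(keep, surv)]
      surv <- keep
    }
    trace[[l]] <- list(level = l, size = length(surv), case_ids = ids[surv])
  }
  ord <- order_by_diss(diss, ids[surv])
  ranked <- data.frame(case_id = ids[surv][ord],
                       dissimilarity = diss[ord],
                       similarity = 1 - diss[ord],
                       rank = seq_along(ord),
                       stringsAsFactors = FALSE)
  retrieval_result(cand_id, "H_WHSM", ranked, trace)
}

retrieval_result <- function(candidate_id, measure, ranked, level_trace) {
  structure(list(candidate = candidate_id, measure = measure,
                 ranked = ranked, level_trace = level_trace),
            class = "retrieval_result")
}

#' @export
print.retrieval_result <- function(x, ...) {
  cat("<retrieval_result> measure:", x$measure,
      " candidate:", x$candidate %||% "<anonymous>", "\n")
  if (length(x$level_trace)) {
    sizes <- vapply(x$level_trace, function(t) t$size, numeric(1))
    cat("  survivors per level:", paste(sizes, collapse = " -> "), "\n")
  }
  print(utils::head(x$ranked, 5))
  if (nrow(x$ranked) > 5) cat("  ...", nrow(x$ranked), "cases ranked\n")
  invisible(x)
}

#' Top-k nearest cases
#'
#' The k most similar cases by ascending dissimilarity with the
#' deterministic `(dissimilarity, case id)` tie-break. When fewer than `k`
#' cases survive, the whole set is returned, a warning is raised and the
#' `incomplete` attribute of the result is `TRUE`.
#'
#' @param x A `retrieval_result` or a named numeric vector of
#'   dissimilarities keyed by case id.
#' @param k Number of neighbours (k >= 1).
#' @return Data frame (`case_id`, `dissimilarity`, `rank`) of at most `k`
#'   rows.
#' @export
knn <- function(x, k) {
  if (length(k) != 1L || is.na(k) || k < 1) stopf("k must be >= 1")
  df <- if (inherits(x, "retrieval_result")) {
    x$ranked
  } else {
    v <- unlist(x)
    if (is.null(names(v))) stopf("dissimilarities must be named by case id")
    ord <- order_by_diss(v, names(v))
    data.frame(case_id = names(v)[ord], dissimilarity = unname(v[ord]),
               rank = seq_along(v), stringsAsFactors = FALSE)
  }
  incomplete <- k > nrow(df)
  if (incomplete)
    warning(sprintf("only %d case(s) available for k = %d", nrow(df), k))
  out <- utils::head(df, min(k, nrow(df)))
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "incomplete") <- incomplete
  out
}

#' Retrieve similar cases under a named measure
#'
#' Dispatch over the three similarity measures: `H_WHSM` delegates to the
#' hierarchical [h_whsm_retrieve()] (attribute selection, level weights and
#' progressive case filtering); `HEOM` and `GWHSM` rank the *full*
#' case-base (no case selection) by [heom_distance()] and
#' [gwhsm_dissimilarity()] respectively.
#'
#' @param candidate Query case.
#' @param cb A [case_base()].
#' @param measure `"H_WHSM"`, `"HEOM"` or `"GWHSM"`.
#' @param cdt CDT (required for `H_WHSM`).
#' @param weights Named attribute weights for `GWHSM` (default all 1).
#' @param matrices Optional ordinal matrix overrides (H_WHSM only).
#' @param min_cases Filtering floor for `H_WHSM`.
#' @return A `retrieval_result` with the full ranking.
#' @export
retrieve <- function(candidate, cb,
                     measure = c("H_WHSM", "HEOM", "GWHSM"),
                     cdt = NULL, weights = NULL, matrices = NULL,
                     min_cases = 20) {
  measure <- match.arg(measure)
  stopifnot(inherits(cb, "case_base"))
  if (measure == "H_WHSM") {
    if (is.null(cdt)) stopf("H_WHSM retrieval needs a clinical decision tree")
    return(h_whsm_retrieve(candidate, cb, cdt, matrices, min_cases))
  }
  ctx <- measure_ctx(cb, matrices)
  vals <- case_attrs(candidate, cb$schema)
  ids <- cb$cases$case_id
  diss <- if (measure == "HEOM") {
    heom_rows(vals, cb$cases, ctx)
  } else {
    attrs <- names(cb$schema$attributes)
    gwhsm_rows(vals, cb$cases, attrs, weight_vector(weights, attrs), ctx)
  }
  ord <- order_by_diss(diss, ids)
  ranked <- data.frame(case_id = ids[ord], dissimilarity = diss[ord],
                       similarity = NA_real_, rank = seq_along(ord),
                       stringsAsFactors = FALSE)
  if (measure == "GWHSM") ranked$similarity <- 1 - ranked$dissimilarity
  cand_id <- if (inherits(candidate, "cbr_case")) candidate$id else NA_character_
  retrieval_result(cand_id, measure, ranked, list())
}

#' Serialise a retrieval result to JSON
#'
#' Includes the ranked list and the per-level survivor trace for audit.
#'
#' @param result A `retrieval_result`.
#' @param path Output path.
#' @export
write_retrieval_result <- function(result, path) {
  stopifnot(inherits(result, "retrieval_result"))
  jsonlite::write_json(
    list(candidate = result$candidate, measure = result$measure,
         ranked = result$ranked,
         level_trace = lapply(result$level_trace, function(t)
           list(level = t$level, size = t$size, case_ids = t$case_ids))),
    path, auto_unbox = TRUE, digits = NA, null = "null", na = "null")
  invisible(path)
}
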