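#' Specify a similarity measure for evaluation
#'
#' Bundles a measure name with its configuration so the evaluation designs
#' can dispatch uniformly: `H_WHSM` needs a CDT (and optional ordinal
#' matrix overrides), `GWHSM` takes attribute weights (all 1 when absent,
#' or GA-learned ones), `HEOM` needs nothing.
#'
#' @param measure `"H_WHSM"`, `"HEOM"` or `"GWHSM"`.
#' @param cdt A [clinical_decision_tree()] (H_WHSM only).
#' @param weights Named weights (GWHSM only).
#' @param matrices Ordinal matrix overrides.
#' @param min_cases H_WHSM filtering floor.
#' @return An object of class `measure_spec`.
#' @export
measure_spec <- function(measure = c("H_WHSM", "HEOM", "GWHSM"),
                         cdt = NULL, weights = NULL, matrices = NULL,
                         min_cases = 20) {
  measure <- match.arg(measure)
  if (measure == "H_WHSM" && is.null(cdt))
    stopf("H_WHSM needs a clinical decision tree")
  structure(list(measure = measure, cdt = cdt, weights = weights,
                 matrices = matrices, min_cases = min_cases),
            class = "measure_spec")
}

retrieve_with_spec <- function(candidate, cb, spec) {
  retrieve(candidate, cb, measure = spec$measure, cdt = spec$cdt,
           weights = spec$weights, matrices = spec$matrices,
           min_cases = spec$min_cases)
}

#' Retrieve-based hit at k
#'
#' A candidate counts as correctly classified under the retrieve-based
#' criterion when its confirmed solution appears at least once among the
#' solutions of the k retrieved cases; the criterion is therefore monotone
#' (non-decreasing) in k.
#'
#' @param retrieved_solutions Character vector of the top-k solutions.
#' @param confirmed The confirmed solution label.
#' @return `TRUE`/`FALSE`.
#' @export
retrieve_hit <- function(retrieved_solutions, confirmed) {
  if (!length(retrieved_solutions)) stopf("need at least one retrieved case")
  confirmed %in% retrieved_solutions
}

#' Leave-one-out cross validation of a similarity measure
#'
#' Each case becomes the candidate in turn and is retrieved against the
#' remaining m - 1 cases (the frozen quantitative ranges of the full
#' case-base are kept). Both criteria are computed: the retrieve-based hit
#' (confirmed solution among the k retrieved) and the reuse-based
#' correctness (the weighted vote suggests the confirmed solution). The
#' 1-NN prediction (rank-1 neighbour's solution) feeds the per-solution
#' sensitivity/specificity table and the TPR/FPR summary.
#'
#' @param cb A [case_base()] with >= 2 cases.
#' @param spec A [measure_spec()].
#' @param decision Decision to evaluate.
#' @param k Number of retrieved cases (k < m).
#' @return An `evaluation_report`.
#' @export
loocv <- function(cb, spec, decision, k = 1) {
  stopifnot(inherits(cb, "case_base"), inherits(spec, "measure_spec"))
  m <- nrow(cb$cases)
  if (m < 2L) stopf("LOOCV needs at least two cases")
  if (k >= m) stopf("k must be smaller than the number of cases (m = %d)", m)
  sols <- stats::setNames(solution_column(cb, decision), cb$cases$case_id)
  rows <- lapply(cb$cases$case_id, function(id) {
    rest <- remove_case(cb, id)
    cand <- get_case(cb, id)
    res <- retrieve_with_spec(cand, rest, spec)
    evaluate_one(id, res, sols, sols[[id]], k, decision)
  })
  build_report("loocv", spec$measure, decision, k, do.call(rbind, rows))
}

#' Holdout evaluation: train case-base vs test case-base
#'
#' Every test case is retrieved against the full training case-base. The
#' design matches the generated-versus-real validation: train on the real
#' cases, test on augmented/generated ones. Schemas must be identical.
#'
#' @param train,test [case_base()] objects sharing a schema.
#' @param spec A [measure_spec()].
#' @param decision Decision to evaluate.
#' @param k Number of retrieved cases (k <= m_train).
#' @return An `evaluation_report`.
#' @export
holdout <- function(train, test, spec, decision, k = 1) {
  stopifnot(inherits(train, "case_base"), inherits(test, "case_base"))
  if (!identical(train$schema, test$schema))
    stopf("train and test case-bases must share an identical schema")
  if (k > nrow(train$cases))
    stopf("k must not exceed the training case-base size")
  sols_train <- stats::setNames(solution_column(train, decision),
                                train$cases$case_id)
  sols_test <- stats::setNames(solution_column(test, decision),
                               test$cases$case_id)
  rows <- lapply(test$cases$case_id, function(id) {
    cand <- get_case(test, id)
    cand$id <- paste0("candidate::", id)   # ids may collide across bases
    res <- retrieve_with_spec(cand, train, spec)
    evaluate_one(id, res, sols_train, sols_test[[id]], k, decision)
  })
  build_report("holdout", spec$measure, decision, k, do.call(rbind, rows))
}

# Criteria for one candidate given its full ranking.
evaluate_one <- function(id, res, sols, confirmed, k, decision) {
  top <- suppressWarnings(knn(res, k))
  ret_sols <- unname(unlist(sols)[top$case_id])
  sug <- suggest(top, sols, k = nrow(top), decision = decision)
  data.frame(candidate_id = id,
             confirmed = confirmed,
             predicted = ret_sols[1],
             suggested = sug$suggested,
             retrieve_hit = retrieve_hit(ret_sols, confirmed),
             reuse_correct = identical(sug$suggested, confirmed),
             retrieved_ids = paste(top$case_id, collapse = ";"),
             retrieved_solutions = paste(ret_sols, collapse = ";"),
             stringsAsFactors = FALSE)
}

build_report <- function(design, measure, decision, k, per_case) {
  rownames(per_case) <- NULL
  per_sol <- per_solution_metrics(per_case)
  aggregates <- list(
    retrieve_hit_rate = mean(per_case$retrieve_hit),
    reuse_correct_rate = mean(per_case$reuse_correct),
    tpr = mean(per_case$predicted == per_case$confirmed),
    fpr = macro_fpr(per_case))
  structure(list(design = design, measure = measure, decision = decision,
                 k = k, per_case = per_case, per_solution = per_sol,
                 aggregates = aggregates),
            class = "evaluation_report")
}

# TPR is the micro-averaged 1-NN accuracy; FPR the macro average of
# one-vs-rest false-positive rates over the labels present in the test set.
macro_fpr <- function(per_case) {
  labels <- sort(unique(per_case$confirmed), method = "radix")
  fprs <- vapply(labels, function(s) {
    neg <- per_case$confirmed != s
    if (!any(neg)) return(NA_real_)
    mean(per_case$predicted[neg] == s)
  }, numeric(1))
  mean(fprs, na.rm = TRUE)
}

#' Per-solution sensitivity and specificity (one-vs-rest)
#'
#' For each solution label `s`: sensitivity is the fraction of confirmed-s
#' cases whose 1-NN prediction is `s`; specificity the fraction of
#' confirmed-not-s cases predicted not-s. A quantity whose denominator is
#' empty (e.g. specificity in a single-solution case-base) is reported as
#' `NA`, not zero.
#'
#' @param per_case Data frame with columns `confirmed` and `predicted`.
#' @param labels Labels to tabulate (default: all labels appearing in
#'   either column).
#' @return Data frame (`solution`, `n`, `sensitivity`, `specificity`).
#' @export
per_solution_metrics <- function(per_case, labels = NULL) {
  labels <- labels %||%
    sort(unique(c(per_case$confirmed, per_case$predicted)), method = "radix")
  rows <- lapply(labels, function(s) {
    pos <- per_case$confirmed == s
    neg <- !pos
    data.frame(solution = s, n = sum(pos),
               sensitivity = if (any(pos)) mean(per_case$predicted[pos] == s)
                             else NA_real_,
               specificity = if (any(neg)) mean(per_case$predicted[neg] != s)
                             else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report> ", x$design, " / ", x$measure, " / ",
      x$decision, " (k = ", x$k, ", n = ", nrow(x$per_case), ")\n", sep = "")
  a <- x$aggregates
  cat(sprintf("  retrieve-hit rate : %.3f\n", a$retrieve_hit_rate))
  cat(sprintf("  reuse-correct rate: %.3f\n", a$reuse_correct_rate))
  cat(sprintf("  TPR (1-NN)        : %.3f   FPR (macro): %.3f\n", a$tpr, a$fpr))
  print(x$per_solution)
  invisible(x)
}

#' Write an evaluation report to disk
#'
#' Per-case results as CSV, aggregates plus the per-solution table as JSON.
#'
#' @param report An `evaluation_report`.
#' @param csv_path,json_path Output paths (either may be `NULL` to skip).
#' @export
write_evaluation_report <- function(report, csv_path = NULL,
                                    json_path = NULL) {
  stopifnot(inherits(report, "evaluation_report"))
  if (!is.null(csv_path))
    utils::write.csv(report$per_case, csv_path, row.names = FALSE, na = "")
  if (!is.null(json_path))
    jsonlite::write_json(
      list(design = report$design, measure = report$measure,
           decision = report$decision, k = report$k,
           aggregates = report$aggregates,
           per_solution = report$per_solution),
      json_path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(report)
}
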