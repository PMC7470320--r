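#' Distance- and rank-weighted vote scores
#'
#' The reuse step turns the k retrieved cases into votes for their
#' solutions: each case contributes `(k + 1 - rank) / diss` to its own
#' solution label, so nearer (and better ranked) cases weigh more. An
#' exact-duplicate neighbour has dissimilarity 0; the divisor is clamped
#' below at `eps`, which keeps scores finite while preserving the
#' "more similar, more weight" ordering.
#'
#' @param retrieved Data frame from [knn()] with columns `case_id`,
#'   `dissimilarity`, `rank` (ranks `1..k` without gaps).
#' @param solutions Named character vector/list: case id -> solution label.
#' @param k Number of voters (default: the number of retrieved rows).
#' @param eps Lower clamp for the dissimilarity divisor.
#' @return Named numeric vector of non-negative scores per label.
#' @export
vote_scores <- function(retrieved, solutions, k = nrow(retrieved),
                        eps = 1e-9) {
  if (is.null(retrieved) || nrow(retrieved) == 0L)
    stopf("no retrieved cases to vote with")
  if (!identical(as.integer(retrieved$rank), seq_len(nrow(retrieved))))
    stopf("ranks must be 1..k without gaps")
  if (any(retrieved$dissimilarity < 0)) stopf("dissimilarities must be >= 0")
  if (eps <= 0) stopf("eps must be positive")
  sols <- unlist(solutions)[retrieved$case_id]
  if (any(is.na(sols)))
    stopf("no solution label for case(s): %s",
          paste(retrieved$case_id[is.na(sols)], collapse = ", "))
  contrib <- (k + 1 - retrieved$rank) / pmax(retrieved$dissimilarity, eps)
  scores <- tapply(contrib, factor(sols, levels = sort(unique(sols))), sum)
  stats::setNames(as.numeric(scores), names(scores))
}

#' Suggest a solution from the retrieved cases
#'
#' Applies [vote_scores()] and suggests the argmax label; exact score ties
#' are broken lexicographically (smallest label wins), which keeps the
#' suggestion deterministic and auditable. Scores are also converted to
#' percentages (`100 * score / sum(scores)`) expressing the confidence in
#' each candidate solution.
#'
#' @inheritParams vote_scores
#' @param decision Decision name recorded in the suggestion.
#' @return A `cbr_suggestion`: fields `decision`, `votes`, `suggested`,
#'   `confidence` (percentages summing to 100).
#' @export
suggest <- function(retrieved, solutions, k = nrow(retrieved),
                    decision = "decision", eps = 1e-9) {
  scores <- vote_scores(retrieved, solutions, k, eps)
  lab <- sort(names(scores), method = "radix")
  scores <- scores[lab]                    # lexicographic tie-break
  suggested <- names(scores)[which.max(scores)]
  confidence <- 100 * scores / sum(scores)
  structure(list(decision = decision, votes = scores,
                 suggested = suggested, confidence = confidence),
            class = "cbr_suggestion")
}

#' @export
print.cbr_suggestion <- function(x, ...) {
  cat("<cbr_suggestion> decision:", x$decision, "\n")
  cat("  suggested:", x$suggested, "\n")
  for (s in names(x$confidence))
    cat(sprintf("  %-28s %6.1f%%\n", s, x$confidence[[s]]))
  invisible(x)
}

#' Serialise a suggestion to JSON
#'
#' Machine form of the confidence bar chart shown to the user: the
#' suggested label plus the percentage per candidate solution.
#'
#' @param suggestion A `cbr_suggestion`.
#' @param path Output path.
#' @export
write_suggestion <- function(suggestion, path) {
  stopifnot(inherits(suggestion, "cbr_suggestion"))
  jsonlite::write_json(
    list(decision = suggestion$decision, suggested = suggestion$suggested,
         confidence = as.list(suggestion$confidence)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
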