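#' Clinical decision tree (CDT)
#'
#' An expert-authored hierarchy of decision-relevant attributes: level 1
#' holds the attributes examined first in clinical reasoning (e.g. the
#' ilio-femoral minimal diameters for the vascular-access decision), deeper
#' levels hold progressively less decisive attributes. The tree drives the
#' hierarchical similarity measure in three ways: cumulative attribute
#' selection, level weighting ([level_weights()]) and progressive case
#' filtering ([h_whsm_retrieve()]). It is not a rule engine: no if/then
#' routing is executed.
#'
#' @param decision Decision name the tree supports.
#' @param levels List of character vectors, one per level, each non-empty;
#'   every attribute appears at exactly one level.
#' @param schema Optional [cbr_schema()]; when given, every attribute must
#'   exist in it.
#' @return An object of class `clinical_decision_tree` with height
#'   `L = length(levels)`.
#' @export
clinical_decision_tree <- function(decision, levels, schema = NULL) {
  if (!length(levels)) stopf("a CDT needs at least one level (L >= 1)")
  levels <- lapply(levels, as.character)
  if (any(vapply(levels, length, integer(1)) == 0L))
    stopf("every CDT level must be non-empty")
  all_attrs <- unlist(levels)
  if (anyDuplicated(all_attrs))
    stopf("attribute(s) %s appear at more than one CDT level",
          paste(unique(all_attrs[duplicated(all_attrs)]), collapse = ", "))
  if (!is.null(schema)) {
    unknown <- setdiff(all_attrs, names(schema$attributes))
    if (length(unknown))
      stopf("CDT for '%s' references unknown attribute(s): %s",
            decision, paste(unknown, collapse = ", "))
  }
  structure(list(decision = decision, levels = levels,
                 L = length(levels)),
            class = "clinical_decision_tree")
}

#' @export
print.clinical_decision_tree <- function(x, ...) {
  cat("<clinical_decision_tree> decision:", x$decision, " L =", x$L, "\n")
  for (l in seq_len(x$L))
    cat(sprintf("  level %d: %s\n", l, paste(x$levels[[l]], collapse = ", ")))
  invisible(x)
}

#' Load a CDT from a YAML/JSON config
#'
#' Document keys: `decision` and `levels` (list of attribute-name lists).
#' Trees live in config files rather than code because the underlying
#' clinical rules vary by hospital and physician.
#'
#' @param path Config file path.
#' @param schema Optional [cbr_schema()] to validate attribute names.
#' @return A [clinical_decision_tree()].
#' @export
load_cdt <- function(path, schema = NULL) {
  doc <- read_config(path)
  if (is.null(doc$decision) || is.null(doc$levels))
    stopf("CDT config '%s': needs keys 'decision' and 'levels'", path)
  clinical_decision_tree(doc$decision, doc$levels, schema)
}

#' Default CDTs shipped with the package
#'
#' Reconstructed attribute hierarchies for the two TAVI decisions. The
#' vascular-access tree puts the ilio-femoral minimal diameters at level 1
#' (trans-femoral access is preferred first, so artery calibre is examined
#' first), tortuosity/calcification and previous femoral disease at level
#' 2, and patient build at level 3. The prosthesis tree (joint type + size
#' decision) puts the aortic annulus dimensions and valve area at level 1,
#' access-linked attributes at level 2 and demographics at level 3. Both
#' are config files under `inst/extdata/` and are meant to be overridden
#' per centre.
#'
#' @param decision `"vascular_access"` or `"prosthesis"`.
#' @param schema Schema to validate against (default [tavi_schema()]).
#' @return A [clinical_decision_tree()].
#' @export
tavi_cdt <- function(decision = c("vascular_access", "prosthesis"),
                     schema = tavi_schema()) {
  decision <- match.arg(decision)
  f <- paste0("cdt_", decision, ".yaml")
  load_cdt(system.file("extdata", f, package = "tavicbr"), schema)
}

#' Cumulative attribute selection down to a CDT level
#'
#' All attributes from level 1 through `l`, in deterministic level-major,
#' then declaration, order. The result for `l` is always a superset of the
#' result for `l - 1`.
#'
#' @param cdt A [clinical_decision_tree()].
#' @param l Level index in `1..L`.
#' @return Character vector of attribute names.
#' @export
attributes_through_level <- function(cdt, l) {
  stopifnot(inherits(cdt, "clinical_decision_tree"))
  if (length(l) != 1L || is.na(l) || l < 1 || l > cdt$L)
    stopf("level %s out of range [1, %d]", as.character(l)[1], cdt$L)
  unlist(cdt$levels[seq_len(l)], use.names = FALSE)
}

#' Level weights of a CDT
#'
#' Each attribute is weighted by its level `l_a` in the tree:
#' `w = (L - l_a + 1) / L`. Root attributes get weight 1, the deepest level
#' gets `1/L`, and weights decrease strictly with depth, reflecting the
#' higher importance of attributes examined earlier in clinical reasoning.
#'
#' @param cdt A [clinical_decision_tree()].
#' @return Named numeric vector of weights in `(0, 1]`.
#' @export
level_weights <- function(cdt) {
  stopifnot(inherits(cdt, "clinical_decision_tree"))
  L <- cdt$L
  w <- lapply(seq_len(L), function(l) {
    stats::setNames(rep((L - l + 1) / L, length(cdt$levels[[l]])),
                    cdt$levels[[l]])
  })
  unlist(w)
}
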