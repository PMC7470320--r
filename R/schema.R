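#' Declare a single clinical attribute
#'
#' An attribute is one component of the problem description of a case. Three
#' kinds are supported: `quantitative` (numeric, with bounds that define the
#' normalisation range of the Euclidean per-attribute distance), `ordinal`
#' (ordered categories compared through an expert distance matrix) and
#' `binary` (values restricted to `"yes"`/`"no"`, compared with the Hamming
#' distance).
#'
#' @param name Attribute identifier (must match the case-base CSV header).
#' @param kind One of `"quantitative"`, `"ordinal"`, `"binary"`.
#' @param range Numeric `c(min, max)` for quantitative attributes. Optional:
#'   when absent, the range is frozen from the values observed in the initial
#'   case-base (see [case_base()]).
#' @param categories Ordered character vector of labels for ordinal
#'   attributes (at least two, all distinct).
#' @param missing_code Token denoting a missing value in CSV files. Empty
#'   cells and `"NA"` are always accepted as missing on read.
#' @return An object of class `attribute_schema`.
#' @export
attribute_schema <- function(name,
                             kind = c("quantitative", "ordinal", "binary"),
                             range = NULL, categories = NULL,
                             missing_code = "") {
  kind <- match.arg(kind)
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stopf("attribute name must be a non-empty string")
  if (kind == "quantitative") {
    if (!is.null(range)) {
      range <- as.numeric(range)
      if (length(range) != 2L || any(!is.finite(range)) || range[1] >= range[2])
        stopf("attribute '%s': range must be c(min, max) with min < max", name)
    }
    categories <- NULL
  } else if (kind == "ordinal") {
    if (is.null(categories) || !is.character(categories))
      stopf("attribute '%s': ordinal attributes need character categories (quote labels such as 'No' in YAML)", name)
    if (length(categories) < 2L || anyDuplicated(categories))
      stopf("attribute '%s': needs >= 2 distinct ordered categories", name)
    range <- NULL
  } else {
    categories <- c("yes", "no")
    range <- NULL
  }
  structure(list(name = name, kind = kind, range = range,
                 categories = categories, missing_code = missing_code),
            class = "attribute_schema")
}

#' Assemble a case-base schema
#'
#' Bundles the attribute declarations with the controlled vocabularies of the
#' decisions (each decision maps to its allowed solution labels) and the
#' names of the outcome (result) fields.
#'
#' @param attributes List of [attribute_schema()] objects.
#' @param decisions Named list: decision name -> character vector of allowed
#'   solution labels.
#' @param results Character vector of outcome field names.
#' @return An object of class `cbr_schema`.
#' @export
cbr_schema <- function(attributes, decisions = list(), results = character()) {
  if (length(attributes) == 0L) stopf("schema needs at least one attribute")
  nm <- vapply(attributes, function(a) a$name, character(1))
  if (anyDuplicated(nm)) stopf("duplicate attribute names in schema")
  names(attributes) <- nm
  if (length(decisions)) {
    if (is.null(names(decisions)) || any(!nzchar(names(decisions))))
      stopf("decisions must be a named list")
    for (d in names(decisions)) {
      decisions[[d]] <- as.character(decisions[[d]])
      if (length(decisions[[d]]) < 1L || anyDuplicated(decisions[[d]]))
        stopf("decision '%s': needs distinct solution labels", d)
    }
  }
  structure(list(attributes = attributes, decisions = decisions,
                 results = as.character(results)),
            class = "cbr_schema")
}

#' @export
print.cbr_schema <- function(x, ...) {
  kinds <- vapply(x$attributes, function(a) a$kind, character(1))
  cat("<cbr_schema> ", length(x$attributes), " attributes (",
      sum(kinds == "quantitative"), " quantitative, ",
      sum(kinds == "ordinal"), " ordinal, ",
      sum(kinds == "binary"), " binary), ",
      length(x$decisions), " decision(s), ",
      length(x$results), " result field(s)\n", sep = "")
  invisible(x)
}

#' Load a schema from a YAML or JSON config
#'
#' The document must have keys `attributes` (list of
#' `{name, kind, range|categories}`), `decisions` (map of decision name to
#' label list) and optionally `results`.
#'
#' @param path Path to the config file (`.yaml`/`.yml` or `.json`).
#' @return A [cbr_schema()] object.
#' @export
load_schema <- function(path) {
  doc <- read_config(path)
  if (is.null(doc$attributes)) stopf("schema config '%s': no 'attributes' key", path)
  attrs <- lapply(doc$attributes, function(a) {
    if (!is.null(a$categories) && !is.character(a$categories))
      stopf("attribute '%s': categories parsed as %s; quote labels such as 'No' in YAML",
            a$name %||% "?", class(a$categories)[1])
    attribute_schema(name = a$name, kind = a$kind,
                     range = a$range, categories = a$categories,
                     missing_code = a$missing_code %||% "")
  })
  cbr_schema(attrs,
             decisions = lapply(doc$decisions %||% list(), as.character),
             results = as.character(doc$results %||% character()))
}

#' Default TAVI schema
#'
#' The schema shipped with the package: demographic and anatomical
#' measurements (age, weight, height, body mass index, body surface area,
#' aortic annulus diameter and area, aortic valve area, per-side ilio-femoral
#' minimal diameters), ordinal tortuosity and calcification grades per side,
#' and binary flags (LVOT calcification, previous aneurysm or thrombus),
#' with the two decisions: vascular access (five routes) and prosthesis
#' (joint type + size, four combinations).
#'
#' @return A [cbr_schema()] object.
#' @export
tavi_schema <- function() {
  load_schema(system.file("extdata", "schema_tavi.yaml", package = "tavicbr"))
}

# Dispatch YAML vs JSON on extension.
read_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                        simplifyMatrix = FALSE)
  } else {
    stopf("unsupported config format '%s' (use .yaml or .json)", ext)
  }
}
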