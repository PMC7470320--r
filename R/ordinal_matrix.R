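#' Expert distance matrix for an ordinal attribute
#'
#' Ordinal grades (e.g. calcification severity) do not influence a clinical
#' decision linearly, so the per-attribute distance between two grades is
#' given by a matrix elicited from expert knowledge rather than by the gap
#' between category indices. Entries are unit-interval distances; the matrix
#' must be symmetric with a zero diagonal.
#'
#' @param attribute Attribute name the matrix applies to.
#' @param categories Ordered category labels (row/column order).
#' @param entries Square numeric matrix of distances in `[0, 1]`.
#' @return An object of class `ordinal_matrix` with a dimnamed `entries`
#'   matrix.
#' @export
ordinal_matrix <- function(attribute, categories, entries) {
  categories <- as.character(categories)
  k <- length(categories)
  if (k < 2L || anyDuplicated(categories))
    stopf("ordinal matrix '%s': needs >= 2 distinct categories", attribute)
  entries <- as.matrix(entries)
  if (!is.numeric(entries) || !all(dim(entries) == k))
    stopf("ordinal matrix '%s': entries must be a %dx%d numeric matrix",
          attribute, k, k)
  dimnames(entries) <- list(categories, categories)
  if (any(entries < 0 | entries > 1))
    stopf("ordinal matrix '%s': entries must lie in [0, 1]", attribute)
  if (any(abs(diag(entries)) > 1e-12))
    stopf("ordinal matrix '%s': diagonal must be zero", attribute)
  if (any(abs(entries - t(entries)) > 1e-12))
    stopf("ordinal matrix '%s': matrix must be symmetric", attribute)
  structure(list(attribute = attribute, categories = categories,
                 entries = entries),
            class = "ordinal_matrix")
}

#' @export
print.ordinal_matrix <- function(x, ...) {
  cat("<ordinal_matrix> ", x$attribute, "\n", sep = "")
  print(x$entries)
  invisible(x)
}

#' Expert calcification distance matrix
#'
#' The five-grade matrix used for arterial calcification: grades `No`,
#' `Mild`, `Moderate`, `Heavy`, `Massive`. In decision-making terms an
#' artery with no calcification is quite similar to one with mild
#' calcification (distance 0.15), while `No` vs `Heavy` is almost maximal
#' (0.90); `Heavy` and `Massive` are again close (0.15).
#'
#' @param attribute Attribute name to attach the matrix to.
#' @return An [ordinal_matrix()].
#' @export
calcification_matrix <- function(attribute = "calcification") {
  cats <- c("No", "Mild", "Moderate", "Heavy", "Massive")
  m <- matrix(c(
    0,    0.15, 0.5,  0.90, 1,
    0.15, 0,    0.2,  0.5,  0.7,
    0.5,  0.2,  0,    0.2,  0.5,
    0.90, 0.5,  0.2,  0,    0.15,
    1,    0.7,  0.5,  0.15, 0),
    nrow = 5, byrow = TRUE)
  ordinal_matrix(attribute, cats, m)
}

#' Default distance matrix for an arbitrary ordinal scale
#'
#' Expert matrices are attribute-specific and only the calcification one is
#' fixed; for other ordinal attributes (or other category counts) the
#' default maps the calcification profile onto the requested scale by
#' bilinear interpolation over normalised grade positions, then restores the
#' zero diagonal and symmetry. Any attribute can override this default with
#' its own config matrix.
#'
#' @param attribute Attribute name.
#' @param categories Ordered category labels of the target scale.
#' @return An [ordinal_matrix()].
#' @export
default_ordinal_matrix <- function(attribute, categories) {
  k <- length(categories)
  base <- calcification_matrix()$entries
  if (k == nrow(base)) {
    return(ordinal_matrix(attribute, categories, base))
  }
  # positions of the k grades on the 5-grade index grid [1, 5]
  pos <- seq(1, nrow(base), length.out = k)
  interp <- function(x, y) {
    i0 <- pmin(floor(x), nrow(base) - 1); j0 <- pmin(floor(y), nrow(base) - 1)
    fx <- x - i0; fy <- y - j0
    base[cbind(i0, j0)] * (1 - fx) * (1 - fy) +
      base[cbind(i0 + 1, j0)] * fx * (1 - fy) +
      base[cbind(i0, j0 + 1)] * (1 - fx) * fy +
      base[cbind(i0 + 1, j0 + 1)] * fx * fy
  }
  m <- outer(seq_len(k), seq_len(k), function(i, j) interp(pos[i], pos[j]))
  m <- (m + t(m)) / 2
  diag(m) <- 0
  ordinal_matrix(attribute, categories, pmin(pmax(m, 0), 1))
}

#' Load ordinal distance matrices from a config file
#'
#' The YAML/JSON document is either one matrix object or a list of them;
#' each has keys `attribute`, `categories` and `matrix` (row-major list of
#' rows). Symmetry, zero diagonal and unit-interval bounds are validated on
#' load.
#'
#' @param path Config file path.
#' @return Named list of [ordinal_matrix()] objects keyed by attribute.
#' @export
load_ordinal_matrices <- function(path) {
  doc <- read_config(path)
  if (!is.null(doc$attribute)) doc <- list(doc)
  out <- list()
  for (entry in doc) {
    m <- do.call(rbind, lapply(entry$matrix, as.numeric))
    om <- ordinal_matrix(entry$attribute, as.character(entry$categories), m)
    out[[om$attribute]] <- om
  }
  out
}

# Full matrix set for a schema: user-supplied where given, defaults
# (calcification profile mapped to the category count) elsewhere.
build_matrices <- function(schema, matrices = NULL) {
  out <- list()
  for (def in schema$attributes) {
    if (def$kind != "ordinal") next
    m <- matrices[[def$name]]
    if (is.null(m)) {
      out[[def$name]] <- default_ordinal_matrix(def$name, def$categories)
    } else {
      if (!inherits(m, "ordinal_matrix"))
        stopf("matrix for '%s' is not an ordinal_matrix", def$name)
      if (!identical(m$categories, def$categories))
        stopf("matrix for '%s': categories do not match the schema", def$name)
      out[[def$name]] <- m
    }
  }
  out
}
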