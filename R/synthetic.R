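#' Augmentation settings
#'
#' Controls the label-preserving data augmentation: quantitative attributes
#' are jittered multiplicatively by up to `quantitative_jitter` (default
#' +/- 10%) and clipped to the clinically coherent interval declared in the
#' schema; ordinal attributes move at most one grade (uniform over
#' lower/same/upper by default, clipped at the scale ends); binary
#' attributes, the solution and the result fields are left unchanged.
#' Measurement attributes tied to a solution (e.g. annulus dimensions tied
#' to the prosthesis size through the device Instruction-For-Use ranges)
#' are instead resampled uniformly inside the solution-consistent interval.
#'
#' @param quantitative_jitter Relative jitter bound in `(0, 0.5]`.
#' @param ordinal_shift_probs Probabilities of a -1 / 0 / +1 grade shift.
#' @param solution_consistent_ranges `NULL`, or a list with fields
#'   `decision` and `ranges`: label -> attribute -> `c(min, max)`; see
#'   [default_ifu_ranges()].
#' @param seed Integer seed for [augment_case_base()].
#' @return An object of class `augmentation_spec`.
#' @export
augmentation_spec <- function(quantitative_jitter = 0.10,
                              ordinal_shift_probs = c(1, 1, 1) / 3,
                              solution_consistent_ranges = NULL,
                              seed = 1) {
  if (quantitative_jitter <= 0 || quantitative_jitter > 0.5)
    stopf("quantitative_jitter must lie in (0, 0.5]")
  ordinal_shift_probs <- as.numeric(ordinal_shift_probs)
  if (length(ordinal_shift_probs) != 3L || any(ordinal_shift_probs < 0) ||
      sum(ordinal_shift_probs) <= 0)
    stopf("ordinal_shift_probs must be three non-negative values")
  structure(list(quantitative_jitter = quantitative_jitter,
                 ordinal_shift_probs = ordinal_shift_probs / sum(ordinal_shift_probs),
                 solution_consistent_ranges = solution_consistent_ranges,
                 seed = as.integer(seed)),
            class = "augmentation_spec")
}

#' Device IFU ranges shipped as an editable fixture
#'
#' Solution-consistent measurement intervals keyed by the four prosthesis
#' labels, loaded from `inst/extdata/ifu_ranges.yaml`. The values are a
#' synthetic stand-in for manufacturer Instruction-For-Use tables (which
#' are not redistributable) chosen to be anatomically plausible; edit the
#' YAML file to match the devices in use.
#'
#' @param path Config path (default: the shipped fixture).
#' @return List with fields `decision`, `ranges` (label -> attribute ->
#'   `c(min, max)`).
#' @export
default_ifu_ranges <- function(path = system.file("extdata", "ifu_ranges.yaml",
                                                  package = "tavicbr")) {
  doc <- read_config(path)
  doc$ranges <- lapply(doc$ranges, function(r) lapply(r, as.numeric))
  doc
}

#' Augmentation settings for the TAVI schema
#'
#' [augmentation_spec()] preloaded with the prosthesis IFU ranges so that
#' annulus measurements of generated cases stay consistent with the case's
#' prosthesis solution.
#'
#' @inheritParams augmentation_spec
#' @return An `augmentation_spec`.
#' @export
tavi_augmentation_spec <- function(quantitative_jitter = 0.10, seed = 1) {
  augmentation_spec(quantitative_jitter = quantitative_jitter,
                    solution_consistent_ranges = default_ifu_ranges(),
                    seed = seed)
}

#' Generate one augmented case
#'
#' Perturbs the problem attributes of a case while leaving its solution and
#' result untouched, so the generated case is a plausible new patient with
#' the same confirmed decisions. Draws from the current RNG stream; use
#' [augment_case_base()] for a seeded batch.
#'
#' @param case A [new_case()] with solution/result fields.
#' @param spec An [augmentation_spec()].
#' @param schema The [cbr_schema()] the case conforms to.
#' @param new_id Id of the generated case (default: `"<id>-gen"`).
#' @return A new `cbr_case`.
#' @export
augment_case <- function(case, spec, schema, new_id = paste0(case$id, "-gen")) {
  stopifnot(inherits(case, "cbr_case"), inherits(spec, "augmentation_spec"),
            inherits(schema, "cbr_schema"))
  attrs <- case_attrs(case, schema)
  scr <- spec$solution_consistent_ranges
  tied <- character()
  if (!is.null(scr)) {
    label <- case$solution[[scr$decision]]
    if (is_missing_value(label))
      label <- NULL
    if (!is.null(label)) {
      if (is.null(scr$ranges[[label]]))
        stopf("no solution-consistent range configured for label '%s'", label)
      tied <- names(scr$ranges[[label]])
    }
  }
  for (a in names(schema$attributes)) {
    def <- schema$attributes[[a]]
    v <- attrs[[a]]
    if (is_missing_value(v)) next
    if (a %in% tied) {
      rng <- scr$ranges[[label]][[a]]
      attrs[[a]] <- stats::runif(1, rng[1], rng[2])
    } else if (def$kind == "quantitative") {
      v <- as.numeric(v)
      j <- spec$quantitative_jitter
      v2 <- v * (1 + stats::runif(1, -j, j))
      if (!is.null(def$range)) v2 <- min(max(v2, def$range[1]), def$range[2])
      attrs[[a]] <- v2
    } else if (def$kind == "ordinal") {
      i <- match(v, def$categories)
      shift <- sample(c(-1L, 0L, 1L), 1L, prob = spec$ordinal_shift_probs)
      attrs[[a]] <- def$categories[min(max(i + shift, 1L), length(def$categories))]
    }
    # binary attributes left unchanged
  }
  new_case(new_id, attrs, case$solution, case$result)
}

#' Double a case-base by augmentation
#'
#' Appends one generated case per original (ids suffixed `-gen`), so the
#' result has exactly 2m cases and the per-solution label histogram of the
#' generated half equals that of the originals. Fully deterministic from
#' `spec$seed`.
#'
#' @param cb A [case_base()].
#' @param spec An [augmentation_spec()].
#' @return A [case_base()] of size 2m.
#' @export
augment_case_base <- function(cb, spec) {
  stopifnot(inherits(cb, "case_base"), inherits(spec, "augmentation_spec"))
  with_seed(spec$seed, {
    gen <- lapply(cb$cases$case_id, function(id) {
      case_to_row(cb$schema, augment_case(get_case(cb, id), spec, cb$schema))
    })
    out <- case_base(cb$schema, rbind(cb$cases, do.call(rbind, gen)))
    out$ranges <- cb$ranges
    out
  })
}

#' Synthetic TAVI case-base profile
#'
#' Describes the generator used in place of a real registry extract: joint
#' (vascular access, prosthesis) labels are drawn from mixtures matching
#' clinical practice (trans-femoral routes together above 80%), and every
#' attribute is drawn around a label-conditional centre. In `"separable"`
#' mode the within-label noise is tiny relative to the between-label centre
#' gaps, so a nearest neighbour under the true schema recovers the labels
#' perfectly; in `"noisy"` mode labels overlap and ordinal/binary values
#' can deviate from their class centre.
#'
#' @param mode `"separable"` or `"noisy"`.
#' @param access_mixture Named probabilities over the five access routes.
#' @param prosthesis_mixture Named probabilities over the four prostheses.
#' @return An object of class `synthetic_profile`.
#' @export
tavi_profile <- function(mode = c("separable", "noisy"),
                         access_mixture = c(
                           "right trans-femoral" = 0.45,
                           "left trans-femoral" = 0.38,
                           "left trans-subclavian" = 0.09,
                           "trans-aortic" = 0.04,
                           "trans-apical" = 0.04),
                         prosthesis_mixture = c(
                           "Edwards Sapien XT 23" = 0.30,
                           "Edwards Sapien XT 26" = 0.30,
                           "Medtronic CoreValve 26" = 0.20,
                           "Medtronic CoreValve 29" = 0.20)) {
  mode <- match.arg(mode)
  check_mixture(access_mixture, "access_mixture")
  check_mixture(prosthesis_mixture, "prosthesis_mixture")
  structure(list(schema = tavi_schema(), mode = mode,
                 mixtures = list(vascular_access = access_mixture,
                                 prosthesis = prosthesis_mixture),
                 center_fun = tavi_centers,
                 rel_noise = if (mode == "separable") 0.002 else 0.08,
                 ordinal_flip = if (mode == "separable") 0 else 0.3,
                 binary_flip = if (mode == "separable") 0 else 0.1),
            class = "synthetic_profile")
}

check_mixture <- function(p, what) {
  if (is.null(names(p)) || any(p < 0) || abs(sum(p) - 1) > 1e-8)
    stopf("%s must be named non-negative probabilities summing to 1", what)
  invisible(TRUE)
}

# Label-conditional attribute centres of the TAVI generator: femoral-side
# attributes depend on the access route, annulus/valve measurements on the
# prosthesis, demographics are label-free.
tavi_centers <- function(labels) {
  acc <- labels[["vascular_access"]]
  pro <- labels[["prosthesis"]]
  fem <- switch(acc,
    "right trans-femoral" = list(r = 8.5, l = 6.8, tor = c("No", "Mild"),
                                 cal = c("No", "Mild"), prev = "no"),
    "left trans-femoral" = list(r = 6.8, l = 8.5, tor = c("Mild", "No"),
                                cal = c("Mild", "No"), prev = "no"),
    "left trans-subclavian" = list(r = 5.2, l = 5.2, tor = c("Moderate", "Moderate"),
                                   cal = c("Moderate", "Moderate"), prev = "yes"),
    "trans-aortic" = list(r = 4.6, l = 4.0, tor = c("Severe", "Severe"),
                          cal = c("Heavy", "Heavy"), prev = "yes"),
    "trans-apical" = list(r = 4.0, l = 4.6, tor = c("Severe", "Severe"),
                          cal = c("Massive", "Massive"), prev = "yes"))
  ann <- switch(pro,
    "Edwards Sapien XT 23" = list(d = 19.5, a = 310, va = 0.60, lvot = "no"),
    "Edwards Sapien XT 26" = list(d = 23.5, a = 420, va = 0.75, lvot = "no"),
    "Medtronic CoreValve 26" = list(d = 21.5, a = 360, va = 0.65, lvot = "yes"),
    "Medtronic CoreValve 29" = list(d = 26.0, a = 500, va = 0.80, lvot = "yes"))
  list(age = 81, weight = 74, height = 165,
       body_mass_index = 27, body_surface_area = 1.8,
       aortic_annulus_diameter = ann$d, aortic_annulus_area = ann$a,
       aortic_valve_area = ann$va, lvot_calcification = ann$lvot,
       ilio_femoral_min_diameter_right = fem$r,
       ilio_femoral_min_diameter_left = fem$l,
       tortuosity_right = fem$tor[1], tortuosity_left = fem$tor[2],
       calcification_right = fem$cal[1], calcification_left = fem$cal[2],
       previous_aneurysm_or_thrombus = fem$prev)
}

#' Profile with one planted predictive attribute
#'
#' A minimal generator for weight-recovery studies: a two-label decision
#' whose solution is fully determined by a single quantitative `signal`
#' attribute, plus `n_noise` quantitative attributes of pure uniform noise.
#' A nearest neighbour weighted on `signal` classifies perfectly, while the
#' class centres (0.47 vs 0.53) sit close enough that equally weighted
#' retrieval misclassifies a visible fraction of cases — without that, the
#' noise attributes would be harmless and no weighting scheme could be
#' told apart. Weights concentrated on a noise attribute perform at
#' chance.
#'
#' @param n_noise Number of noise attributes (>= 1).
#' @return A `synthetic_profile`.
#' @export
planted_profile <- function(n_noise = 3) {
  stopifnot(n_noise >= 1)
  noise_names <- paste0("noise_", seq_len(n_noise))
  attrs <- c(list(attribute_schema("signal", "quantitative", range = c(0, 1))),
             lapply(noise_names, attribute_schema, kind = "quantitative",
                    range = c(0, 1)))
  schema <- cbr_schema(attrs,
                       decisions = list(outcome = c("low", "high")),
                       results = character())
  centers <- function(labels) {
    v <- c(signal = if (labels[["outcome"]] == "low") 0.47 else 0.53)
    c(as.list(v), stats::setNames(as.list(rep(NA_real_, n_noise)), noise_names))
  }
  structure(list(schema = schema, mode = "separable",
                 mixtures = list(outcome = c(low = 0.5, high = 0.5)),
                 center_fun = centers,
                 rel_noise = 0.02, ordinal_flip = 0, binary_flip = 0,
                 uniform_attrs = noise_names),
            class = "synthetic_profile")
}

#' Generate a fully synthetic case-base
#'
#' Draws `n` cases from a [tavi_profile()]-style generator: solution labels
#' per decision from the profile mixtures, then attribute values around the
#' label-conditional centres. Quantitative values get relative uniform
#' noise and are clipped to the schema range; attributes listed in
#' `profile$uniform_attrs` are drawn uniformly over their range (pure
#' noise); a centre of `NA` also yields a uniform draw. In `"separable"`
#' mode every realised joint label class is guaranteed at least two
#' members (singletons are reassigned to the most frequent class) so that
#' leave-one-out nearest-neighbour retrieval can succeed by construction.
#'
#' @param n Number of cases (>= 1).
#' @param profile A `synthetic_profile`.
#' @param seed Integer seed; generation is fully deterministic.
#' @return A [case_base()].
#' @export
generate_synthetic_case_base <- function(n, profile = tavi_profile(),
                                         seed = 1) {
  stopifnot(inherits(profile, "synthetic_profile"))
  if (length(n) != 1L || is.na(n) || n < 1) stopf("n must be >= 1")
  n <- as.integer(n)
  schema <- profile$schema
  for (p in profile$mixtures) check_mixture(p, "mixture")
  with_seed(seed, {
    labels <- lapply(profile$mixtures, function(p) {
      sample(names(p), n, replace = TRUE, prob = p)
    })
    if (profile$mode == "separable") labels <- ensure_pairs(labels)
    rows <- lapply(seq_len(n), function(i) {
      li <- lapply(labels, `[[`, i)
      centers <- profile$center_fun(li)
      attrs <- draw_attrs(schema, centers, profile)
      sol <- li[intersect(names(li), names(schema$decisions))]
      res <- synth_results(schema)
      case_to_row(schema, new_case(sprintf("S%03d", i), attrs, sol, res))
    })
    case_base(schema, do.call(rbind, rows))
  })
}

# Reassign singleton joint-label classes to the most frequent class so each
# realised class has >= 2 members (required for separable LOOCV).
ensure_pairs <- function(labels) {
  joint <- do.call(paste, c(labels, sep = "\r"))
  tab <- table(joint)
  if (!any(tab == 1L) || length(tab) == 1L) return(labels)
  major <- names(tab)[which.max(tab)]
  major_parts <- strsplit(major, "\r", fixed = TRUE)[[1]]
  for (i in which(joint %in% names(tab)[tab == 1L])) {
    for (d in seq_along(labels)) labels[[d]][i] <- major_parts[d]
  }
  labels
}

draw_attrs <- function(schema, centers, profile) {
  attrs <- list()
  for (a in names(schema$attributes)) {
    def <- schema$attributes[[a]]
    ctr <- centers[[a]]
    if (def$kind == "quantitative") {
      rng <- def$range %||% c(0, 1)
      if ((!is.null(profile$uniform_attrs) && a %in% profile$uniform_attrs) ||
          is_missing_value(ctr)) {
        attrs[[a]] <- stats::runif(1, rng[1], rng[2])
      } else {
        v <- ctr * (1 + stats::runif(1, -profile$rel_noise, profile$rel_noise))
        attrs[[a]] <- min(max(v, rng[1]), rng[2])
      }
    } else if (def$kind == "ordinal") {
      i <- match(ctr, def$categories)
      if (stats::runif(1) < profile$ordinal_flip) {
        i <- i + sample(c(-1L, 1L), 1L)
        i <- min(max(i, 1L), length(def$categories))
      }
      attrs[[a]] <- def$categories[i]
    } else {
      v <- ctr
      if (stats::runif(1) < profile$binary_flip)
        v <- setdiff(c("yes", "no"), v)[1]
      attrs[[a]] <- v
    }
  }
  attrs
}

synth_results <- function(schema) {
  res <- list()
  for (r in schema$results) {
    res[[r]] <- if (r == "procedure_success") {
      if (stats::runif(1) < 0.95) "yes" else "no"
    } else NA
  }
  res
}
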