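# Fixture builders and independent brute-force oracles. The oracles are
# literal transcriptions of the measure definitions (explicit loops,
# re-sorting at every level) kept deliberately separate from the package's
# vectorised implementation paths.

tiny_schema <- function() {
  cbr_schema(list(
    attribute_schema("diam", "quantitative", range = c(18, 28)),
    attribute_schema("calc", "ordinal",
                     categories = c("No", "Mild", "Moderate", "Heavy", "Massive")),
    attribute_schema("flag", "binary")),
    decisions = list(access = c("A", "B")),
    results = "outcome")
}

tiny_case <- function(id, diam, calc, flag, access = "A", outcome = "ok") {
  new_case(id, list(diam = diam, calc = calc, flag = flag),
           solution = list(access = access), result = list(outcome = outcome))
}

# Build a case_base from a list of cbr_case objects.
mk_cb <- function(schema, cases) {
  rows <- lapply(cases, function(cs) case_to_row(schema, cs))
  case_base(schema, do.call(rbind, rows))
}

# Random mixed-type schema with <= 8 attributes and a two-label decision.
random_schema <- function(n_attrs = sample(2:8, 1)) {
  attrs <- lapply(seq_len(n_attrs), function(i) {
    kind <- sample(c("quantitative", "ordinal", "binary"), 1)
    name <- paste0("a", i)
    if (kind == "quantitative") {
      lo <- runif(1, -50, 50)
      attribute_schema(name, kind, range = c(lo, lo + runif(1, 1, 100)))
    } else if (kind == "ordinal") {
      attribute_schema(name, kind, categories = paste0("g", seq_len(sample(2:5, 1))))
    } else {
      attribute_schema(name, kind)
    }
  })
  cbr_schema(attrs, decisions = list(d = c("X", "Y")), results = character())
}

random_attr_value <- function(def, p_missing = 0.15) {
  if (runif(1) < p_missing) return(NA)
  if (def$kind == "quantitative") runif(1, def$range[1], def$range[2])
  else sample(def$categories, 1)
}

random_case <- function(schema, id, p_missing = 0.15) {
  vals <- lapply(schema$attributes, random_attr_value, p_missing = p_missing)
  new_case(id, vals, solution = list(d = sample(c("X", "Y"), 1)))
}

random_case_base <- function(schema, m, p_missing = 0.1) {
  mk_cb(schema, lapply(seq_len(m), function(i) {
    random_case(schema, sprintf("c%02d", i), p_missing)
  }))
}

random_cdt <- function(schema, L = sample(1:3, 1)) {
  attrs <- sample(names(schema$attributes))
  cut <- sort(sample(seq_len(length(attrs) - 1), min(L - 1, length(attrs) - 1)))
  levels <- unname(split(attrs, cumsum(seq_along(attrs) %in% (cut + 1))))
  clinical_decision_tree("d", levels, schema)
}

## ---- oracles -----------------------------------------------------------

# Literal per-attribute distance dispatch.
oracle_attr_distance <- function(def, v1, v2, rng, mats) {
  if (is.null(v1) || is.null(v2) || is.na(v1) || is.na(v2)) return(0.5)
  if (def$kind == "quantitative") {
    width <- rng[2] - rng[1]
    if (width <= 0) return(if (v1 == v2) 0 else 1)
    min(abs(v1 - v2) / width, 1)
  } else if (def$kind == "binary") {
    if (v1 == v2) 0 else 1
  } else {
    mats[[def$name]]$entries[v1, v2]
  }
}

# Literal weighted-mean dissimilarity.
oracle_eq2 <- function(vals1, vals2, attrs, w, schema, ranges, mats) {
  num <- 0; den <- 0
  for (a in attrs) {
    d <- oracle_attr_distance(schema$attributes[[a]], vals1[[a]], vals2[[a]],
                              ranges[[a]], mats)
    num <- num + w[[a]] * d
    den <- den + w[[a]]
  }
  num / den
}

# Literal hierarchical retrieval: explicit loops, re-sorting at each level.
oracle_hierarchical <- function(cand_vals, cb, cdt, min_cases = 20) {
  mats <- build_matrices(cb$schema)
  m <- nrow(cb$cases)
  L <- cdt$L
  ids <- cb$cases$case_id
  level_of <- function(a) which(vapply(cdt$levels, function(lv) a %in% lv, logical(1)))
  surv <- ids
  trace <- list()
  diss <- NULL
  for (l in seq_len(L)) {
    attrs <- unlist(cdt$levels[seq_len(l)])
    w <- sapply(attrs, function(a) (L - level_of(a) + 1) / L)
    diss <- sapply(surv, function(id) {
      row <- cb$cases[match(id, ids), , drop = FALSE]
      vals2 <- setNames(lapply(attrs, function(a) {
        v <- row[[a]]; if (is.na(v)) NA else v
      }), attrs)
      oracle_eq2(cand_vals, vals2, attrs, w, cb$schema, cb$ranges, mats)
    })
    if (m / 2^l > min_cases && l != L) {
      ord <- order(diss, surv, method = "radix")
      kept <- surv[ord[seq_len(ceiling(length(surv) / 2))]]
      diss <- diss[match(kept, surv)]
      surv <- kept
      ord2 <- order(surv, method = "radix")  # keep set in id order
      surv <- surv[ord2]; diss <- diss[ord2]
    }
    trace[[l]] <- sort(surv, method = "radix")
  }
  list(survivors = sort(surv, method = "radix"),
       diss = setNames(as.numeric(diss), surv), trace = trace)
}

# Case-base of identical duplicate pairs sharing a solution.
duplicate_pair_cb <- function(n_pairs = 4) {
  schema <- tiny_schema()
  cases <- list()
  for (i in seq_len(n_pairs)) {
    acc <- if (i %% 2 == 0) "A" else "B"
    proto <- tiny_case(sprintf("p%da", i), 18 + i, "Mild", "yes", acc)
    twin <- proto; twin$id <- sprintf("p%db", i)
    cases <- c(cases, list(proto, twin))
  }
  mk_cb(schema, cases)
}
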