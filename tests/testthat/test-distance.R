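test_that("per-attribute dispatch covers all kinds, missing values and clipping", {
  schema <- tiny_schema()
  mats <- build_matrices(schema)
  calc <- schema$attributes$calc
  diam <- schema$attributes$diam
  flag <- schema$attributes$flag

  expect_equal(attr_distance(calc, "Mild", "Moderate", mats), 0.2)
  expect_equal(attr_distance(diam, 23, 26), 0.3)
  expect_equal(attr_distance(flag, "yes", "no"), 1)
  # identity
  expect_equal(attr_distance(calc, "Heavy", "Heavy", mats), 0)
  expect_equal(attr_distance(diam, 20, 20), 0)
  # neutral missing-value rule, either side or both
  expect_equal(attr_distance(diam, NA, 26), 0.5)
  expect_equal(attr_distance(calc, "Mild", NA, mats), 0.5)
  expect_equal(attr_distance(flag, NA, NA), 0.5)
  # candidate values beyond the frozen range clip the distance at 1
  expect_equal(attr_distance(diam, 18, 50), 1)
  expect_error(attr_distance(calc, "Mild", "Moderate"), "no registered")
  expect_error(attr_distance(flag, "yes", "maybe"), "not in declared")
})

test_that("weighted dissimilarity is a normalised weighted mean in [0,1]", {
  schema <- tiny_schema()
  c1 <- tiny_case("x", 23, "Mild", "yes")
  c2 <- tiny_case("y", 26, "Moderate", "yes")
  # single attribute reduces to the per-attribute distance, any weight
  expect_equal(weighted_dissimilarity(c1, c2, "diam", c(diam = 7), schema), 0.3)
  # two attributes, weights (1,1), distances (0.3, 0.2) -> 0.25
  expect_equal(
    weighted_dissimilarity(c1, c2, c("diam", "calc"), c(diam = 1, calc = 1), schema),
    0.25)
  expect_equal(weighted_dissimilarity(c1, c1, c("diam", "calc", "flag"),
                                      NULL, schema), 0)
  expect_error(
    weighted_dissimilarity(c1, c2, c("diam", "calc"), c(diam = 0, calc = 0), schema),
    "all weights are zero")
  # sim + diss = 1 exactly
  meas <- function(a, b) weighted_dissimilarity(a, b, c("diam", "calc"),
                                                NULL, schema)
  expect_identical(similarity(c1, c2, meas), 1 - meas(c1, c2))
})

test_that("weighted dissimilarity matches a literal transcription on random cases", {
  set.seed(101)
  mismatch <- 0
  for (i in 1:60) {
    schema <- random_schema()
    mats <- build_matrices(schema)
    ranges <- lapply(schema$attributes, function(a) a$range)
    c1 <- random_case(schema, "u")
    c2 <- random_case(schema, "v")
    attrs <- sample(names(schema$attributes),
                    sample(length(schema$attributes), 1))
    w <- setNames(runif(length(attrs), 0.1, 2), attrs)
    got <- weighted_dissimilarity(c1, c2, attrs, w, schema)
    want <- oracle_eq2(case_attrs(c1, schema), case_attrs(c2, schema),
                       attrs, w, schema, ranges, mats)
    sym <- weighted_dissimilarity(c2, c1, attrs, w, schema)
    if (abs(got - want) > 1e-12 || abs(got - sym) > 1e-12 ||
        got < 0 || got > 1) mismatch <- mismatch + 1
  }
  expect_equal(mismatch, 0)
})

test_that("HEOM sums squared overlap/normalised distances over all attributes", {
  schema <- cbr_schema(list(
    attribute_schema("q", "quantitative", range = c(0, 10)),
    attribute_schema("o", "ordinal", categories = c("a", "b", "c"))))
  c1 <- new_case("x", list(q = 5, o = "a"))
  c2 <- new_case("y", list(q = 5, o = "b"))
  expect_equal(heom_distance(c1, c1, schema), 0)
  # one nominal mismatch, one equal quantitative -> sqrt(1 + 0) = 1
  expect_equal(heom_distance(c1, c2, schema), 1)
  # a missing value contributes distance 1
  c3 <- new_case("z", list(q = NA, o = "a"))
  expect_equal(heom_distance(c1, c3, schema), 1)
  set.seed(11)
  for (i in 1:20) {
    s <- random_schema()
    a <- random_case(s, "a"); b <- random_case(s, "b")
    d1 <- heom_distance(a, b, s); d2 <- heom_distance(b, a, s)
    expect_gte(d1, 0)
    expect_equal(d1, d2)
  }
})

test_that("GWHSM discards missing attributes and uses exact-match ordinal distance", {
  schema <- tiny_schema()
  c1 <- tiny_case("x", 23, "Mild", "yes")
  c2 <- tiny_case("y", 26, "Moderate", "yes")
  expect_equal(gwhsm_dissimilarity(c1, c1, schema = schema), 0)
  # ordinal grades one step apart: Hamming says 1, the expert matrix 0.2
  expect_equal(gwhsm_dissimilarity(c1, c2, schema = schema, attrs = "calc"), 1)
  expect_equal(weighted_dissimilarity(c1, c2, "calc", NULL, schema), 0.2)
  # a missing attribute plays no part: result equals the remaining distance
  c2m <- tiny_case("ym", 26, NA, "yes")
  expect_equal(
    gwhsm_dissimilarity(c1, c2m, schema = schema, attrs = c("diam", "calc")),
    0.3)
  c1m <- tiny_case("xm", NA, NA, NA)
  expect_error(gwhsm_dissimilarity(c1m, c2, schema = schema),
               "no informative attribute")
})

test_that("vectorised row measures agree with the scalar operations", {
  set.seed(21)
  schema <- random_schema(6)
  cb <- random_case_base(schema, 15)
  ctx <- measure_ctx(cb)
  cand <- random_case(schema, "query")
  vals <- case_attrs(cand, schema)
  attrs <- names(schema$attributes)
  w <- setNames(runif(length(attrs), 0.2, 1), attrs)
  d_eq2 <- diss_rows(vals, cb$cases, attrs, w, ctx)
  d_heom <- heom_rows(vals, cb$cases, ctx)
  d_gw <- gwhsm_rows(vals, cb$cases, attrs, w, ctx)
  for (i in seq_len(nrow(cb$cases))) {
    other <- get_case(cb, cb$cases$case_id[i])
    expect_equal(d_eq2[i],
                 weighted_dissimilarity(cand, other, attrs, w, schema,
                                        ranges = cb$ranges),
                 tolerance = 1e-12)
    expect_equal(d_heom[i],
                 heom_distance(cand, other, schema, ranges = cb$ranges),
                 tolerance = 1e-12)
    scalar <- tryCatch(
      gwhsm_dissimilarity(cand, other, w, schema, attrs, ranges = cb$ranges),
      error = function(e) 1)  # uninformative pairs rank at maximal distance
    expect_equal(d_gw[i], scalar, tolerance = 1e-12)
  }
})
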