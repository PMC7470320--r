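test_that("a single-level tree reduces hierarchical retrieval to Eq-2 ranking", {
  set.seed(31)
  schema <- random_schema(5)
  cb <- random_case_base(schema, 12)
  cand <- random_case(schema, "query")
  cdt1 <- clinical_decision_tree("d", list(names(schema$attributes)), schema)
  res <- h_whsm_retrieve(cand, cb, cdt1)
  attrs <- names(schema$attributes)
  w <- setNames(rep(1, length(attrs)), attrs)   # Eq 6 gives weight 1 at L = 1
  ref <- vapply(cb$cases$case_id, function(id) {
    weighted_dissimilarity(cand, get_case(cb, id), attrs, w, schema,
                           ranges = cb$ranges)
  }, numeric(1))
  expect_equal(setNames(res$ranked$dissimilarity, res$ranked$case_id),
               ref[res$ranked$case_id], tolerance = 1e-12)
  expect_identical(res$ranked$case_id,
                   names(ref)[order(ref, names(ref), method = "radix")])
})

test_that("the filtering guard uses the initial case-base size", {
  set.seed(32)
  schema <- random_schema(4)
  cdt <- random_cdt(schema, L = min(3, length(schema$attributes)))
  # m = 16: 16/2 = 8 <= 20, so no level ever filters
  cb16 <- random_case_base(schema, 16)
  res16 <- h_whsm_retrieve(random_case(schema, "q"), cb16, cdt)
  expect_true(all(vapply(res16$level_trace, function(t) t$size, numeric(1)) == 16))
  expect_equal(nrow(res16$ranked), 16)
})

test_that("survivor counts follow the ceil-half convention on a 138-case base", {
  cb <- generate_synthetic_case_base(138, tavi_profile("noisy"), seed = 9)
  cdt <- tavi_cdt("vascular_access")
  cand <- get_case(cb, "S001")
  res <- h_whsm_retrieve(cand, remove_case(cb, "S001"), cdt)
  sizes <- vapply(res$level_trace, function(t) t$size, numeric(1))
  # m = 137: 137/2 > 20 and 137/4 > 20 fire; 69 = ceil(137/2), 35 = ceil(69/2)
  expect_equal(sizes, c(69, 35, 35))
  expect_equal(nrow(res$ranked), 35)
  # nesting CB_l subset of CB_{l-1}
  for (l in 2:length(res$level_trace)) {
    expect_true(all(res$level_trace[[l]]$case_ids %in%
                      res$level_trace[[l - 1]]$case_ids))
  }
})

test_that("hierarchical retrieval matches the brute-force transcription", {
  set.seed(33)
  for (i in 1:12) {
    schema <- random_schema()
    cb <- random_case_base(schema, sample(5:32, 1))
    cdt <- random_cdt(schema, L = sample(1:3, 1))
    cand <- random_case(schema, "query")
    for (mc in c(20, 4)) {   # floor 4 exercises the halving on small bases
      got <- h_whsm_retrieve(cand, cb, cdt, min_cases = mc)
      want <- oracle_hierarchical(case_attrs(cand, schema), cb, cdt, mc)
      expect_identical(sort(got$ranked$case_id, method = "radix"),
                       want$survivors)
      expect_equal(setNames(got$ranked$dissimilarity, got$ranked$case_id),
                   want$diss[got$ranked$case_id], tolerance = 1e-12)
      for (l in seq_along(want$trace)) {
        expect_identical(sort(got$level_trace[[l]]$case_ids, method = "radix"),
                         want$trace[[l]])
      }
    }
  }
})

test_that("retrieval is deterministic, including under ties", {
  schema <- tiny_schema()
  cases <- lapply(1:6, function(i) tiny_case(paste0("t", i), 20, "Mild", "yes"))
  cb <- mk_cb(schema, cases)   # every stored case is identical -> full tie
  cdt <- clinical_decision_tree("access", list("diam", c("calc", "flag")), schema)
  cand <- tiny_case("q", 22, "Moderate", "no")
  r1 <- h_whsm_retrieve(cand, cb, cdt)
  r2 <- h_whsm_retrieve(cand, cb, cdt)
  expect_identical(r1, r2)
  expect_identical(r1$ranked$case_id, paste0("t", 1:6))  # tie-break by id
})

test_that("knn selects top-k with deterministic tie-break and boundary warning", {
  d <- c(B = 0.2, A = 0.1, C = 0.2, D = 0.4)
  expect_identical(knn(d, 1)$case_id, "A")
  # tie at the k-th position: lower case id kept
  expect_identical(knn(d, 2)$case_id, c("A", "B"))
  expect_error(knn(d, 0), "k must be >= 1")
  expect_warning(all4 <- knn(d, 9), "only 4")
  expect_equal(nrow(all4), 4)
  expect_true(attr(all4, "incomplete"))
})

test_that("measure dispatch ranks HEOM/GWHSM over the full base", {
  schema <- tiny_schema()
  cb <- mk_cb(schema, list(
    tiny_case("dup", 23, "Mild", "yes"),
    tiny_case("far", 28, "Massive", "no"),
    tiny_case("mid", 24, "Moderate", "yes")))
  cand <- new_case("q", list(diam = 23, calc = "Mild", flag = "yes"))
  res <- retrieve(cand, cb, "HEOM")
  expect_identical(res$ranked$case_id[1], "dup")
  expect_equal(res$ranked$dissimilarity[1], 0)
  expect_equal(nrow(res$ranked), 3)
  gw <- retrieve(cand, cb, "GWHSM")
  expect_identical(gw$ranked$case_id[1], "dup")
  expect_false(is.unsorted(gw$ranked$dissimilarity))
  expect_error(retrieve(cand, cb, "VDM"), "arg")
  expect_error(retrieve(cand, cb, "H_WHSM"), "needs a clinical decision tree")
})

test_that("weights that silence a noise attribute change the GWHSM ranking", {
  schema <- cbr_schema(list(
    attribute_schema("signal", "quantitative", range = c(0, 1)),
    attribute_schema("noise", "quantitative", range = c(0, 1))))
  cb <- mk_cb(schema, list(
    new_case("good", list(signal = 0.50, noise = 0.95)),
    new_case("bad", list(signal = 0.80, noise = 0.52))))
  cand <- new_case("q", list(signal = 0.51, noise = 0.50))
  uniform <- retrieve(cand, cb, "GWHSM")
  learned <- retrieve(cand, cb, "GWHSM",
                      weights = c(signal = 1, noise = 1e-6))
  expect_identical(uniform$ranked$case_id[1], "bad")
  expect_identical(learned$ranked$case_id[1], "good")
})
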