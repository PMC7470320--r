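heom_spec <- function() measure_spec("HEOM")

test_that("LOOCV on duplicate pairs is perfect under both criteria", {
  cb <- duplicate_pair_cb(4)
  rep <- loocv(cb, heom_spec(), "access", k = 1)
  expect_equal(rep$aggregates$retrieve_hit_rate, 1)
  expect_equal(rep$aggregates$reuse_correct_rate, 1)
  expect_equal(rep$aggregates$tpr, 1)
  expect_equal(rep$aggregates$fpr, 0)
  expect_equal(nrow(rep$per_case), n_cases(cb))
  expect_error(loocv(cb, heom_spec(), "access", k = n_cases(cb)), "k must be")
})

test_that("a single-solution case-base has sensitivity 1 and absent specificity", {
  schema <- tiny_schema()
  cb <- mk_cb(schema, lapply(1:4, function(i) {
    tiny_case(paste0("c", i), 18 + i, "Mild", "yes", access = "A")
  }))
  rep <- loocv(cb, heom_spec(), "access", k = 1)
  row <- rep$per_solution[rep$per_solution$solution == "A", ]
  expect_equal(row$sensitivity, 1)
  expect_true(is.na(row$specificity))
})

test_that("randomly labelled cases score near chance under reuse", {
  set.seed(77)
  schema <- cbr_schema(list(attribute_schema("x", "quantitative", range = c(0, 1)),
                            attribute_schema("y", "quantitative", range = c(0, 1))),
                       decisions = list(d = c("A", "B")))
  cases <- lapply(1:40, function(i) {
    new_case(sprintf("r%02d", i), list(x = runif(1), y = runif(1)),
             solution = list(d = if (i %% 2 == 0) "A" else "B"))
  })
  rep <- loocv(mk_cb(schema, cases), heom_spec(), "d", k = 1)
  expect_gt(rep$aggregates$reuse_correct_rate, 0.25)
  expect_lt(rep$aggregates$reuse_correct_rate, 0.75)
})

test_that("holdout self-match and disjoint-solution boundaries", {
  cb <- generate_synthetic_case_base(20, tavi_profile("noisy"), seed = 12)
  test_cb <- cb
  test_cb$cases$case_id <- paste0("T", test_cb$cases$case_id)
  rep <- holdout(cb, test_cb, heom_spec(), "vascular_access", k = 1)
  expect_equal(rep$aggregates$retrieve_hit_rate, 1)   # exact copies self-match
  expect_equal(rep$aggregates$reuse_correct_rate, 1)

  # no shared solutions between train and test -> reuse cannot be correct
  schema <- tiny_schema()
  train <- mk_cb(schema, lapply(1:3, function(i) {
    tiny_case(paste0("a", i), 18 + i, "Mild", "yes", access = "A")
  }))
  test2 <- mk_cb(schema, lapply(1:3, function(i) {
    tiny_case(paste0("b", i), 18 + i, "Mild", "yes", access = "B")
  }))
  rep2 <- holdout(train, test2, heom_spec(), "access", k = 1)
  expect_equal(rep2$aggregates$reuse_correct_rate, 0)
  expect_equal(rep2$aggregates$retrieve_hit_rate, 0)
})

test_that("augmented holdout approaches a perfect hit rate as jitter shrinks", {
  cb <- generate_synthetic_case_base(24, tavi_profile("separable"), seed = 13)
  spec <- heom_spec()
  # perturbation -> 0 means both the jitter and the ordinal grade shifts
  shift_probs <- list(c(1, 1, 1) / 3, c(0, 1, 0))
  rates <- vapply(seq_along(shift_probs), function(i) {
    j <- c(0.2, 0.01)[i]
    aug <- augment_case_base(cb, augmentation_spec(
      quantitative_jitter = j, ordinal_shift_probs = shift_probs[[i]],
      seed = 5))
    gen <- aug$cases[!aug$cases$case_id %in% cb$cases$case_id, , drop = FALSE]
    test_cb <- case_base(cb$schema, gen)
    holdout(cb, test_cb, spec, "vascular_access", k = 1)$aggregates$retrieve_hit_rate
  }, numeric(1))
  expect_gte(rates[2], rates[1])
  expect_equal(rates[2], 1)
})

test_that("retrieve-based hits are monotone in k", {
  expect_true(retrieve_hit(c("B", "A", "B"), "A"))
  expect_false(retrieve_hit("B", "A"))
  expect_error(retrieve_hit(character(), "A"), "at least one")
  set.seed(41)
  cb <- generate_synthetic_case_base(25, tavi_profile("noisy"), seed = 21)
  prev <- 0
  for (k in 1:5) {
    rep <- loocv(cb, heom_spec(), "vascular_access", k = k)
    expect_gte(rep$aggregates$retrieve_hit_rate, prev)
    # the vote can only choose among retrieved solutions
    expect_lte(rep$aggregates$reuse_correct_rate,
               rep$aggregates$retrieve_hit_rate)
    prev <- rep$aggregates$retrieve_hit_rate
  }
})

test_that("one-vs-rest sensitivity/specificity match hand-computed confusion", {
  # confusion for label s: TP = 3, FN = 1, TN = 5, FP = 1
  per_case <- data.frame(
    confirmed = c(rep("s", 4), rep("t", 6)),
    predicted = c("s", "s", "s", "t", "s", rep("t", 5)),
    stringsAsFactors = FALSE)
  tab <- per_solution_metrics(per_case)
  srow <- tab[tab$solution == "s", ]
  expect_equal(srow$sensitivity, 0.75)
  expect_equal(srow$specificity, 5 / 6)
  # perfect predictions give 1/1 for every present label
  perfect <- data.frame(confirmed = c("a", "b", "b"),
                        predicted = c("a", "b", "b"),
                        stringsAsFactors = FALSE)
  ptab <- per_solution_metrics(perfect)
  expect_true(all(ptab$sensitivity == 1))
  expect_true(all(ptab$specificity == 1))
})

test_that("merging the two trans-femoral sides never lowers sensitivity", {
  # brute force over random small confusion settings: relabelling right/left
  # trans-femoral as one class turns cross-side confusions into hits, so the
  # merged sensitivity is bounded below by the side-exact (pooled) rate
  set.seed(55)
  checked <- 0
  for (i in 1:60) {
    n <- sample(4:10, 1)
    labs <- c("rTF", "lTF", "other")
    per_case <- data.frame(confirmed = sample(labs, n, replace = TRUE),
                           predicted = sample(labs, n, replace = TRUE),
                           stringsAsFactors = FALSE)
    merged <- data.frame(
      confirmed = ifelse(per_case$confirmed %in% c("rTF", "lTF"), "TF",
                         per_case$confirmed),
      predicted = ifelse(per_case$predicted %in% c("rTF", "lTF"), "TF",
                         per_case$predicted),
      stringsAsFactors = FALSE)
    tf <- per_case$confirmed %in% c("rTF", "lTF")
    if (!any(tf)) next
    pooled <- mean(per_case$predicted[tf] == per_case$confirmed[tf])
    merged_tab <- per_solution_metrics(merged)
    expect_gte(merged_tab$sensitivity[merged_tab$solution == "TF"], pooled)
    checked <- checked + 1
  }
  expect_gt(checked, 30)
})
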