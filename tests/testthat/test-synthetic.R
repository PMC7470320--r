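test_that("augmentation perturbs the problem but preserves solution and result", {
  cb <- generate_synthetic_case_base(15, tavi_profile("noisy"), seed = 8)
  spec <- tavi_augmentation_spec(seed = 2)
  aug <- augment_case_base(cb, spec)
  expect_equal(n_cases(aug), 2 * n_cases(cb))
  gen <- aug$cases[seq(n_cases(cb) + 1, n_cases(aug)), , drop = FALSE]
  orig <- cb$cases
  # solutions and results unchanged, per-label histogram exactly doubled
  for (col in c("solution.vascular_access", "solution.prosthesis",
                "result.procedure_success")) {
    expect_identical(gen[[col]], orig[[col]])
  }
  # binary attributes unchanged; ordinal moved at most one grade
  expect_identical(gen$lvot_calcification, orig$lvot_calcification)
  cats <- cb$schema$attributes$calcification_right$categories
  shift <- abs(match(gen$calcification_right, cats) -
                 match(orig$calcification_right, cats))
  expect_true(all(shift <= 1))
  # augmented cases still validate against the schema
  expect_s3_class(case_base(cb$schema, gen), "case_base")
  # determinism: same seed, byte-identical output
  expect_identical(augment_case_base(cb, spec)$cases, aug$cases)
})

test_that("quantitative jitter stays within +/-10% and IFU ranges bind tied attributes", {
  cb <- generate_synthetic_case_base(20, tavi_profile("noisy"), seed = 19)
  ifu <- default_ifu_ranges()
  spec <- tavi_augmentation_spec(seed = 3)
  set.seed(1)
  for (id in cb$cases$case_id[1:10]) {
    case <- get_case(cb, id)
    gen <- augment_case(case, spec, cb$schema)
    expect_identical(gen$id, paste0(id, "-gen"))
    label <- case$solution$prosthesis
    tied <- names(ifu$ranges[[label]])
    for (a in names(cb$schema$attributes)) {
      def <- cb$schema$attributes[[a]]
      if (def$kind != "quantitative") next
      v <- case$attributes[[a]]; v2 <- gen$attributes[[a]]
      if (a %in% tied) {
        rng <- ifu$ranges[[label]][[a]]
        expect_gte(v2, rng[1]); expect_lte(v2, rng[2])
      } else if (v > def$range[1] / 0.9 && v < def$range[2] / 1.1) {
        # clipping cannot bind here, so the raw jitter bound is observable
        expect_lte(abs(v2 - v), 0.10 * abs(v) + 1e-12)
      }
    }
  }
  expect_error(augmentation_spec(quantitative_jitter = 0.6), "jitter")
  # a solution label absent from the consistent-range table is a config error
  bad <- spec
  bad$solution_consistent_ranges$ranges[["Edwards Sapien XT 23"]] <- NULL
  sxt23 <- cb$cases$case_id[cb$cases$solution.prosthesis == "Edwards Sapien XT 23"][1]
  if (!is.na(sxt23)) {
    expect_error(augment_case(get_case(cb, sxt23), bad, cb$schema),
                 "no solution-consistent range")
  }
})

test_that("the generator reproduces the clinical access mixture", {
  cb <- generate_synthetic_case_base(400, tavi_profile("noisy"), seed = 101)
  acc <- cb$cases$solution.vascular_access
  tf <- mean(acc %in% c("right trans-femoral", "left trans-femoral"))
  expect_gt(tf, 0.8)   # trans-femoral routes dominate, as in practice
  expect_equal(sort(unique(acc)),
               sort(intersect(tavi_schema()$decisions$vascular_access, acc)))
  expect_error(generate_synthetic_case_base(0), "n must be")
  expect_error(tavi_profile(access_mixture = c(a = 0.5)), "summing to 1")
  # determinism
  a <- generate_synthetic_case_base(25, tavi_profile("separable"), seed = 6)
  b <- generate_synthetic_case_base(25, tavi_profile("separable"), seed = 6)
  expect_identical(a$cases, b$cases)
})

test_that("separable case-bases give perfect 1-NN retrieval for all measures", {
  cb <- generate_synthetic_case_base(40, tavi_profile("separable"), seed = 23)
  for (decision in c("vascular_access", "prosthesis")) {
    specs <- list(measure_spec("HEOM"),
                  measure_spec("GWHSM"),
                  measure_spec("H_WHSM", cdt = tavi_cdt(decision)))
    for (spec in specs) {
      rep <- loocv(cb, spec, decision, k = 1)
      expect_equal(rep$aggregates$retrieve_hit_rate, 1)
    }
  }
})
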