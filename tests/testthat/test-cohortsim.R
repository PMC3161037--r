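test_that("the published spec carries the printed class-conditional statistics", {
  sp <- published_spec()
  expect_identical(sp$n_negative, 17L)
  expect_identical(sp$n_positive, 18L)
  age_pos <- sp$continuous[sp$continuous$attribute == "age" &
                             sp$continuous$class == "positive", ]
  expect_identical(age_pos$mean, 55.4)
  expect_identical(age_pos$sd, 14.2)
  wbc_pos <- sp$categorical[sp$categorical$attribute == "abnormal_wbc" &
                              sp$categorical$class == "positive" &
                              sp$categorical$category == "abnormal", ]
  expect_equal(wbc_pos$prob, 0.444, tolerance = 1e-12)
  # printed drug columns sum to 1 within rounding (1.001 / 1.002 before
  # renormalisation); the stored vectors are exactly normalised
  drug <- sp$categorical[sp$categorical$attribute == "chemotherapeutic_drug", ]
  for (cl in c("negative", "positive")) {
    expect_equal(sum(drug$prob[drug$class == cl]), 1, tolerance = 1e-12)
  }
  # renormalisation shifts each printed proportion by at most the residual
  carb <- drug[drug$class == "positive" & drug$category == "carboplatin", ]
  expect_lt(abs(carb$prob - 0.278), 0.01)
})

test_that("cohort generation is deterministic and respects class sizes", {
  sp <- published_spec()
  c1 <- generate_cohort(sp, seed = 12)
  c2 <- generate_cohort(sp, seed = 12)
  expect_identical(c2, c1)
  expect_false(identical(generate_cohort(sp, seed = 13), c1))
  counts <- cohort_counts(c1)
  expect_identical(counts$n[counts$rechallenge_status == "negative"], 17L)
  expect_identical(counts$n[counts$rechallenge_status == "positive"], 18L)

  empty <- generate_cohort(cohort_spec(0, 0, continuous = sp$continuous), seed = 1)
  expect_identical(nrow(empty), 0L)

  # physiological support: ages adult, labs strictly positive
  big <- generate_cohort(published_spec(n_negative = 2000, n_positive = 2000),
                         seed = 14)
  expect_true(all(big$age >= 18))
  expect_true(all(big$albumin > 0 & big$rbc > 0 & big$platelet > 0))
  # generated cohorts validate against the default clinical schema
  expect_silent(validate_cohort(c1))
})

test_that("large-sample moments match the generating spec", {
  sp <- published_spec(n_negative = 10000, n_positive = 10000)
  cohort <- generate_cohort(sp, seed = 15)
  for (i in seq_len(nrow(sp$continuous))) {
    row <- sp$continuous[i, ]
    x <- cohort[[row$attribute]][cohort$rechallenge_status == row$class]
    # the generator samples the floor-truncated Gaussian; its population
    # moments follow in closed form from the spec parameters
    pop <- trunc_norm_moments(row$mean, row$sd, generator_floor(row$attribute))
    se <- pop$sd / sqrt(length(x))
    expect_lt(abs(mean(x) - pop$mean), 3 * se)
  }
})

test_that("noise attributes are class-independent", {
  sp <- cohort_spec(4000, 4000, n_noise = 2)
  cohort <- generate_cohort(sp, seed = 16)
  neg <- cohort$noise_01[cohort$rechallenge_status == "negative"]
  pos <- cohort$noise_01[cohort$rechallenge_status == "positive"]
  expect_lt(abs(mean(neg) - mean(pos)), 3 * sqrt(1 / 4000 + 1 / 4000))
  auc <- roc_auc(cohort$noise_02, cohort$rechallenge_status)
  expect_lt(abs(auc - 0.5), 3 * sqrt((4000 + 4000 + 1) / (12 * 4000 * 4000)))
})

test_that("the published model reconstructs the released 8-predictor classifier", {
  m <- published_model()
  expect_length(m$subset, 8)
  expect_equal(m$prior[["negative"]], 17 / 35)
  rit_pos <- m$categorical[m$categorical$attribute == "chemotherapeutic_drug" &
                             m$categorical$class == "positive" &
                             m$categorical$category == "rituximab", ]
  expect_identical(rit_pos$prob, 0)
  # rituximab was never seen among positive-rechallenge cases: with alpha = 0
  # observing it is decisive evidence for negative rechallenge
  rec <- tibble::tibble(chemotherapeutic_drug = "rituximab")
  expect_identical(posterior_negative(m, rec), 1)
})

test_that("fitting on a large simulated cohort recovers the spec parameters", {
  sp <- published_spec(n_negative = 6000, n_positive = 6000)
  cohort <- generate_cohort(sp, seed = 18)
  m <- nb_fit(cohort, subset = published_model()$subset, alpha = 0)
  merged <- dplyr::inner_join(m$continuous, sp$continuous,
                              by = c("attribute", "class"),
                              suffix = c("_fit", "_spec"))
  for (i in seq_len(nrow(merged))) {
    pop <- trunc_norm_moments(merged$mean_spec[i], merged$sd_spec[i],
                              generator_floor(merged$attribute[i]))
    expect_lt(abs(merged$mean_fit[i] - pop$mean), 3 * pop$sd / sqrt(6000))
  }
  mc <- dplyr::inner_join(m$categorical, sp$categorical,
                          by = c("attribute", "class", "category"),
                          suffix = c("_fit", "_spec"))
  expect_true(all(abs(mc$prob_fit - mc$prob_spec) < 0.02))
})

test_that("published model discriminates on cohorts drawn from the published spec", {
  m <- published_model()
  sp <- published_spec()
  aucs <- vapply(1:40, function(s) {
    cohort <- generate_cohort(sp, seed = 100 + s)
    evaluate_model(cohort, m, thresholds = 0.5)$auc
  }, numeric(1))
  expect_gte(mean(aucs > 0.5), 0.95)
})

test_that("cohort specs survive a JSON round trip", {
  sp <- published_spec(n_noise = 2)
  path <- withr::local_tempfile(fileext = ".json")
  write_cohort_spec(sp, path)
  back <- read_cohort_spec(path)
  expect_identical(back$n_negative, sp$n_negative)
  expect_identical(back$n_noise, sp$n_noise)
  expect_equal(back$continuous, sp$continuous, tolerance = 0)
  expect_equal(back$categorical, sp$categorical, tolerance = 0)
  # generation from the round-tripped spec is identical
  expect_identical(generate_cohort(back, seed = 20),
                   generate_cohort(sp, seed = 20))
})

test_that("spec-derived schemas cover exactly the generated columns", {
  sp <- planted_spec(n_per_class = 5, n_noise = 3)
  schema <- spec_schema(sp)
  cohort <- generate_cohort(sp, seed = 21)
  expect_setequal(c(schema$name, "rechallenge_status"), names(cohort))
  expect_silent(validate_cohort(cohort, schema))
})
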