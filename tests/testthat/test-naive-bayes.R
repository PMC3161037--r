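test_that("fitted priors and class-conditional frequencies are empirical", {
  # 17 negative / 18 positive records; 5 carboplatin among the positives
  cohort <- tibble::tibble(
    chemotherapeutic_drug = c(rep("oxaliplatin", 17),
                              rep("carboplatin", 5), rep("rituximab", 13)),
    rechallenge_status = c(rep("negative", 17), rep("positive", 18))
  )
  m <- nb_fit(cohort, "chemotherapeutic_drug", alpha = 0)
  expect_equal(m$prior[["negative"]], 17 / 35)
  p_carb_pos <- m$categorical$prob[m$categorical$class == "positive" &
                                     m$categorical$category == "carboplatin"]
  expect_equal(round(p_carb_pos, 3), 0.278)
  expect_equal(p_carb_pos, 5 / 18)
})

test_that("additive smoothing follows the Laplace closed form", {
  schema <- toy_schema()
  cohort <- tibble::tibble(
    chemotherapeutic_drug = rep("carboplatin", 8),
    rechallenge_status = rep(c("negative", "positive"), each = 4)
  )
  m <- nb_fit(cohort, "chemotherapeutic_drug", schema, alpha = 1)
  k <- 3  # categories in the toy schema
  tab <- m$categorical[m$categorical$class == "negative", ]
  expect_equal(tab$prob[tab$category == "carboplatin"], (4 + 1) / (4 + k))
  expect_equal(tab$prob[tab$category == "rituximab"], 1 / (4 + k))
  expect_equal(sum(tab$prob), 1)
})

test_that("log-likelihood sums per-attribute factors and skips missing values", {
  prior <- c(negative = 0.5, positive = 0.5)
  # empty attribute set: empty product, log-likelihood 0 for both classes
  empty <- nb_model(character(0), prior)
  rec <- tibble::tibble(x = 1)
  expect_identical(nb_log_likelihood(empty, tibble::tibble(a = 1), "negative"), 0)
  expect_identical(nb_log_likelihood(empty, tibble::tibble(a = 1), "positive"), 0)

  # one continuous attribute evaluated at the class mean: Gaussian mode
  m <- nb_model("x", prior,
                continuous = tibble::tibble(
                  attribute = "x", class = c("negative", "positive"),
                  mean = c(2, 5), sd = c(0.5, 0.5)))
  expect_equal(nb_log_likelihood(m, tibble::tibble(x = 2), "negative"),
               log(1 / (0.5 * sqrt(2 * pi))))
  # a record missing every selected attribute contributes nothing
  expect_identical(nb_log_likelihood(m, tibble::tibble(x = NA_real_), "negative"), 0)
})

test_that("posterior matches hand Bayes arithmetic on small models", {
  # identical class-conditionals and equal priors: no information, 0.5
  sym <- nb_model("x", c(negative = 0.5, positive = 0.5),
                  continuous = tibble::tibble(
                    attribute = "x", class = c("negative", "positive"),
                    mean = 1, sd = 2))
  expect_equal(posterior_negative(sym, tibble::tibble(x = 3.7)), 0.5)

  # published carboplatin class-conditionals, priors 17/35 vs 18/35
  m <- carboplatin_model()
  got <- posterior_negative(m, tibble::tibble(drug = "carboplatin"))
  hand <- (17 / 35 * 0.059) / ((17 / 35 * 0.059) + (18 / 35 * 0.278))
  expect_equal(got, hand, tolerance = 1e-9)
  expect_equal(round(hand, 3), 0.167)

  # zero likelihood in one class eliminates it outright
  m0 <- nb_model("flag", c(negative = 0.5, positive = 0.5),
                 categorical = tibble::tibble(
                   attribute = "flag",
                   class = rep(c("negative", "positive"), each = 2),
                   category = rep(c("a", "b"), 2),
                   prob = c(0.4, 0.6, 0, 1)))
  expect_identical(posterior_negative(m0, tibble::tibble(flag = "a")), 1)
})

test_that("posteriors sum to one and log-space agrees with direct products", {
  m <- published_model()
  cohort <- generate_cohort(published_spec(), seed = 42)
  prob <- predict(m, cohort, type = "prob")
  expect_true(all(abs(prob$posterior_negative + prob$posterior_positive - 1) < 1e-12))
  for (i in seq_len(10)) {
    direct <- posterior_direct(m, cohort[i, ])
    expect_equal(prob$posterior_negative[i], direct, tolerance = 1e-9)
  }
})

test_that("records with no usable evidence fall back to the prior with a warning", {
  m <- carboplatin_model()
  rec <- tibble::tibble(drug = NA_character_)
  expect_warning(p <- posterior_negative(m, rec), "no usable evidence")
  expect_equal(p, 17 / 35)
})

test_that("duplicating one class leaves the other class's parameters unchanged", {
  cohort <- random_toy_cohort(60, 8, p_missing = 0)
  m1 <- nb_fit(cohort, c("age", "chemotherapeutic_drug"), toy_schema())
  dup <- dplyr::bind_rows(cohort,
                          cohort[cohort$rechallenge_status == "positive", ])
  m2 <- nb_fit(dup, c("age", "chemotherapeutic_drug"), toy_schema())
  neg1 <- m1$continuous[m1$continuous$class == "negative", ]
  neg2 <- m2$continuous[m2$continuous$class == "negative", ]
  expect_equal(neg2, neg1)
  cat1 <- m1$categorical[m1$categorical$class == "negative", ]
  cat2 <- m2$categorical[m2$categorical$class == "negative", ]
  expect_equal(cat2, cat1)
})

test_that("fit agrees with an independent naive Bayes implementation", {
  skip_if_not_installed("e1071")
  cohort <- random_toy_cohort(80, 21, p_missing = 0)
  m <- nb_fit(cohort, c("age", "albumin", "chemotherapeutic_drug"), toy_schema())
  ref <- e1071::naiveBayes(
    x = data.frame(age = cohort$age, albumin = cohort$albumin,
                   chemotherapeutic_drug = factor(cohort$chemotherapeutic_drug)),
    y = factor(cohort$rechallenge_status), laplace = 0
  )
  for (attr in c("age", "albumin")) {
    ours <- m$continuous[m$continuous$attribute == attr, ]
    expect_equal(ours$mean, unname(ref$tables[[attr]][, 1]))
    expect_equal(ours$sd, unname(ref$tables[[attr]][, 2]))
  }
  # posterior agreement on held-out records
  newdata <- random_toy_cohort(20, 22, p_missing = 0)
  ours <- posterior_negative(m, newdata)
  theirs <- predict(ref, data.frame(
    age = newdata$age, albumin = newdata$albumin,
    chemotherapeutic_drug = factor(newdata$chemotherapeutic_drug,
                                   levels = c("oxaliplatin", "carboplatin",
                                              "rituximab"))
  ), type = "raw")[, "negative"]
  expect_equal(ours, unname(theirs), tolerance = 1e-6)
})

test_that("classification uses the strict-exceedance threshold rule", {
  m <- carboplatin_model()
  fake_scores <- function(p) {
    # single-attribute model whose posterior for category "a" is exactly p
    nb_model("f", c(negative = 0.5, positive = 0.5),
             categorical = tibble::tibble(
               attribute = "f", class = rep(c("negative", "positive"), each = 2),
               category = rep(c("a", "b"), 2),
               prob = c(p, 1 - p, 1 - p, p)))
  }
  rec <- tibble::tibble(f = "a")
  m9 <- fake_scores(0.9)
  expect_identical(predict(m9, rec, threshold = 0.8), "negative")
  m5 <- fake_scores(0.5)
  expect_identical(predict(m5, rec, threshold = 0.5), "positive")  # tie -> positive
  expect_identical(predict(m9, rec, threshold = 0), "negative")
  expect_error(predict(m9, rec, threshold = 1.5), class = "rc_predict_error")
})

test_that("with alpha = 0 an unseen category collapses the posterior", {
  cohort <- tibble::tibble(
    chemotherapeutic_drug = c(rep("oxaliplatin", 10), rep("carboplatin", 10)),
    rechallenge_status = rep(c("negative", "positive"), each = 10)
  )
  m <- nb_fit(cohort, "chemotherapeutic_drug", toy_schema(), alpha = 0)
  rec <- tibble::tibble(chemotherapeutic_drug = "oxaliplatin")
  expect_identical(posterior_negative(m, rec), 1)
})

test_that("models survive a JSON round trip at full precision", {
  m <- published_model()
  path <- withr::local_tempfile(fileext = ".json")
  write_nb_model(m, path)
  m2 <- read_nb_model(path)
  expect_equal(m2$prior, m$prior, tolerance = 0)
  expect_equal(m2$continuous, m$continuous, tolerance = 0)
  expect_equal(m2$categorical, m$categorical, tolerance = 0)

  # property: random fitted models, including zero-probability entries
  for (seed in c(31, 32, 33)) {
    cohort <- random_toy_cohort(25, seed, p_missing = 0.1)
    mf <- nb_fit(cohort, c("age", "abnormal_wbc", "chemotherapeutic_drug"),
                 toy_schema(), alpha = 0)
    write_nb_model(mf, path)
    back <- read_nb_model(path)
    expect_equal(back$continuous, mf$continuous, tolerance = 0)
    expect_equal(back$categorical, mf$categorical, tolerance = 0)
    expect_identical(back$subset, mf$subset)
  }
})

test_that("corrupted or mismatched model files raise versioned errors", {
  path <- withr::local_tempfile(fileext = ".json")
  writeLines("{not valid json", path)
  expect_error(read_nb_model(path), class = "rc_model_io_error")
  jsonlite::write_json(list(version = 99), path, auto_unbox = TRUE)
  expect_error(read_nb_model(path), "version", class = "rc_model_io_error")
})

test_that("degenerate training inputs raise informative fit errors", {
  cohort <- tibble::tibble(age = c(1, 2), rechallenge_status = c("negative", "negative"))
  expect_error(nb_fit(cohort, "age"), class = "rc_fit_error")
  cohort2 <- tibble::tibble(
    age = c(NA, NA, 50, 60),
    rechallenge_status = rep(c("negative", "positive"), each = 2)
  )
  expect_error(nb_fit(cohort2, "age"), "entirely missing", class = "rc_fit_error")
  expect_error(nb_fit(cohort2, character(0)), class = "rc_fit_error")
})
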