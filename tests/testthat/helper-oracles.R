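# Independent oracles and fixture builders shared across tests.

# Exhaustive Mann-Whitney concordance over all (negative, positive) pairs;
# ties count 1/2.  Deliberately O(n^2) and independent of roc_auc().
pairwise_auc <- function(scores, labels) {
  neg <- scores[labels == "negative"]
  pos <- scores[labels == "positive"]
  total <- 0
  for (s_n in neg) {
    total <- total + sum(s_n > pos) + 0.5 * sum(s_n == pos)
  }
  total / (length(neg) * length(pos))
}

# Direct-product posterior (no log space): prior_neg * prod(f_neg) /
# (prior_neg * prod(f_neg) + prior_pos * prod(f_pos)) for a single record.
posterior_direct <- function(model, record) {
  lik <- function(cl) {
    out <- 1
    cont <- model$continuous[model$continuous$class == cl, ]
    for (i in seq_len(nrow(cont))) {
      x <- record[[cont$attribute[i]]]
      if (!is.null(x) && !is.na(x)) {
        out <- out * dnorm(x, cont$mean[i], cont$sd[i])
      }
    }
    cats <- model$categorical[model$categorical$class == cl, ]
    for (nm in unique(cats$attribute)) {
      x <- record[[nm]]
      if (!is.null(x) && !is.na(x)) {
        tab <- cats[cats$attribute == nm, ]
        out <- out * tab$prob[match(x, tab$category)]
      }
    }
    out
  }
  a <- model$prior[["negative"]] * lik("negative")
  b <- model$prior[["positive"]] * lik("positive")
  a / (a + b)
}

# A single-attribute model over the drug variable with the published
# carboplatin class-conditionals, collapsed to carboplatin vs other so the
# probability tables are exact.
carboplatin_model <- function() {
  nb_model(
    subset = "drug",
    prior = c(negative = 17 / 35, positive = 18 / 35),
    categorical = tibble::tibble(
      attribute = "drug",
      class = rep(c("negative", "positive"), each = 2),
      category = rep(c("carboplatin", "other"), 2),
      prob = c(0.059, 0.941, 0.278, 0.722)
    ),
    alpha = 0
  )
}

# Cohort spec with one perfectly separating binary attribute plus
# class-independent standard-normal noise attributes.
planted_spec <- function(n_per_class = 50, n_noise = 20) {
  cohort_spec(
    n_negative = n_per_class, n_positive = n_per_class,
    categorical = tibble::tibble(
      attribute = "planted",
      class = rep(c("negative", "positive"), each = 2),
      category = rep(c("absent", "present"), 2),
      prob = c(0, 1, 1, 0)
    ),
    n_noise = n_noise, seed = 1
  )
}

# Random labelled cohort over a small mixed schema, with missing values,
# for round-trip and property tests.
toy_schema <- function() {
  attribute_schema(tibble::tibble(
    name = c("age", "albumin", "chemotherapeutic_drug", "abnormal_wbc"),
    kind = c("continuous", "continuous", "categorical", "binary"),
    categories = list(NULL, NULL,
                      c("oxaliplatin", "carboplatin", "rituximab"),
                      c("normal", "abnormal")),
    derived_from = list(NULL, NULL, NULL, NULL),
    group = NA_character_
  ))
}

random_toy_cohort <- function(n, seed, p_missing = 0.15) {
  withr::with_seed(seed, {
    maybe_na <- function(x) {
      x[runif(length(x)) < p_missing] <- NA
      x
    }
    tibble::tibble(
      age = maybe_na(round(runif(n, 20, 90), 3)),
      albumin = maybe_na(round(rnorm(n, 34, 5), 3)),
      chemotherapeutic_drug = maybe_na(
        sample(c("oxaliplatin", "carboplatin", "rituximab"), n, replace = TRUE)),
      abnormal_wbc = maybe_na(sample(c("normal", "abnormal"), n, replace = TRUE)),
      rechallenge_status = sample(c("negative", "positive"), n, replace = TRUE)
    )
  })
}

# Closed-form mean/sd of a Gaussian truncated below at `a` (the population
# actually sampled by generate_cohort's physiological-floor resampling).
trunc_norm_moments <- function(mu, sigma, a) {
  alpha <- (a - mu) / sigma
  if (!is.finite(alpha)) return(list(mean = mu, sd = sigma))
  Z <- 1 - pnorm(alpha)
  lambda <- dnorm(alpha) / Z
  list(mean = mu + sigma * lambda,
       sd = sigma * sqrt(1 + alpha * lambda - lambda^2))
}

# Physiological floors used by the generator for the published attributes.
generator_floor <- function(attribute) {
  if (attribute == "age") return(18)
  if (attribute %in% c("albumin", "rbc", "platelet")) return(0)
  -Inf
}
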