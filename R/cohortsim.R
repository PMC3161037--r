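#' Specify a synthetic cohort by its class-conditional distributions
#'
#' A cohort specification gives, for each attribute, its distribution
#' within the negative- and positive-rechallenge classes: Gaussian
#' mean/SD for continuous attributes, a category probability vector for
#' categorical ones.  Optional noise attributes are standard-normal and
#' identical in both classes, so they carry no outcome signal.
#'
#' @param n_negative,n_positive Records to generate per class.
#' @param continuous Tibble with columns `attribute`, `class`, `mean`, `sd`.
#' @param categorical Tibble with columns `attribute`, `class`, `category`,
#'   `prob`; per attribute and class the probabilities must sum to 1.
#' @param n_noise Number of class-independent standard-normal noise
#'   attributes (named `noise_01`, `noise_02`, ...).
#' @param floors Optional named numeric vector of physiological lower
#'   bounds enforced by resampling; by default age is kept at >= 18 years
#'   and laboratory values strictly positive.
#' @param seed Default seed used by [generate_cohort()].
#'
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_negative, n_positive, continuous = NULL,
                        categorical = NULL, n_noise = 0, floors = NULL,
                        seed = 1L) {
  stopifnot(n_negative >= 0, n_positive >= 0, n_noise >= 0)
  empty_cont <- tibble(attribute = character(), class = character(),
                       mean = numeric(), sd = numeric())
  empty_cat <- tibble(attribute = character(), class = character(),
                      category = character(), prob = numeric())
  continuous <- if (is.null(continuous)) empty_cont else as_tibble(continuous)
  categorical <- if (is.null(categorical)) empty_cat else as_tibble(categorical)
  if (nrow(continuous) && any(continuous$sd <= 0)) {
    abort("every sd must be > 0", class = "rc_spec_error")
  }
  if (nrow(categorical)) {
    sums <- dplyr::summarise(
      dplyr::group_by(categorical, .data$attribute, .data$class),
      total = sum(.data$prob), .groups = "drop"
    )
    if (any(abs(sums$total - 1) > 1e-9)) {
      abort("category probability vectors must sum to 1", class = "rc_spec_error")
    }
  }
  structure(
    list(n_negative = as.integer(n_negative),
         n_positive = as.integer(n_positive),
         continuous = continuous, categorical = categorical,
         n_noise = as.integer(n_noise), floors = floors,
         seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

table2_continuous <- function() {
  tibble(
    attribute = rep(c("age", "albumin", "rbc", "platelet"), each = 2),
    class = rep(rc_classes(), 4),
    mean = c(47.7, 55.4, 35.7, 30.9, 4.06, 3.69, 331.41, 324.39),
    sd = c(14.9, 14.2, 4.6, 5.6, 0.58, 0.81, 153.62, 150.86)
  )
}

table2_drug <- function() {
  drugs <- c("oxaliplatin", "carboplatin", "bleomycin", "rituximab",
             "paclitaxel", "docetaxel", "trastuzumab", "cetuximab",
             "gemcitabine")
  tibble(
    attribute = "chemotherapeutic_drug",
    class = rep(rc_classes(), each = length(drugs)),
    category = rep(drugs, 2),
    prob = c(0.294, 0.059, 0.059, 0.235, 0.118, 0.059, 0.118, 0.000, 0.059,
             0.278, 0.278, 0.000, 0.000, 0.167, 0.111, 0.056, 0.056, 0.056)
  )
}

table2_flags <- function() {
  p_abn <- list(
    abnormal_wbc = c(negative = 0.118, positive = 0.444),
    abnormal_alanine_aminotransferase = c(negative = 0.118, positive = 0.278),
    abnormal_alkaline_phosphatase = c(negative = 0.176, positive = 0.556)
  )
  dplyr::bind_rows(lapply(names(p_abn), function(f) {
    tibble(
      attribute = f,
      class = rep(rc_classes(), each = 2),
      category = rep(c("abnormal", "normal"), 2),
      prob = c(p_abn[[f]][["negative"]], 1 - p_abn[[f]][["negative"]],
               p_abn[[f]][["positive"]], 1 - p_abn[[f]][["positive"]])
    )
  }))
}

# the printed drug columns sum to 1.001 (negative) and 1.002 (positive)
# because each entry is a count over 17 or 18 rounded to 3 d.p.; vectors are
# renormalised so probability tables are exact, preserving exact zeros
renormalise_cat <- function(cat_tbl) {
  dplyr::ungroup(dplyr::mutate(
    dplyr::group_by(cat_tbl, .data$attribute, .data$class),
    prob = .data$prob / sum(.data$prob)
  ))
}

#' Published class-conditional statistics of the 8 clinical predictors
#'
#' The descriptive statistics of the clinical predictors in the 35-case
#' testing set: per-class Gaussian mean/SD for age, albumin, red blood
#' cell and platelet levels; per-class proportions for the
#' chemotherapeutic drug and the abnormal WBC / ALT / alkaline-phosphatase
#' flags.  The class composition (17 negative / 18 positive rechallenge)
#' is inferred from the unit fractions in the proportion columns
#' (0.059 = 1/17, 0.056 = 1/18, 0.278 = 5/18) and can be overridden.
#' Drug probability vectors are renormalised from the printed 3-decimal
#' values (column sums 1.001 / 1.002) so they are exact probability
#' distributions; printed zeros stay exactly zero.
#'
#' @param n_negative,n_positive Class sizes (defaults 17 and 18).
#' @param n_noise Additional class-independent noise attributes.
#' @param seed Default generation seed.
#' @return A [cohort_spec()].
#' @export
published_spec <- function(n_negative = 17, n_positive = 18, n_noise = 0,
                           seed = 1L) {
  cohort_spec(
    n_negative = n_negative, n_positive = n_positive,
    continuous = table2_continuous(),
    categorical = renormalise_cat(dplyr::bind_rows(table2_drug(), table2_flags())),
    n_noise = n_noise, seed = seed
  )
}

cont_floor_ok <- function(attribute, x) {
  labs <- c("wbc", "rbc", "platelet", "neutrophil", "lymphocyte", "monocyte",
            "eosinophil", "basophil", "serum_creatinine",
            "alkaline_phosphatase", "alanine_aminotransferase",
            "aspartate_aminotransferase", "albumin")
  if (attribute == "age") return(x >= 18)
  if (attribute %in% labs) return(x > 0)
  rep(TRUE, length(x))
}

#' Generate a synthetic cohort from a specification
#'
#' Draws `n_negative + n_positive` labelled patient records: continuous
#' attributes from their per-class Gaussians (resampled onto physiological
#' support: age >= 18, laboratory values > 0), categorical attributes from
#' their per-class category vectors, and noise attributes identically for
#' both classes.  Generation is fully deterministic for a fixed seed.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed; defaults to the seed stored in the spec.
#' @return A labelled cohort tibble (negative-rechallenge rows first).
#' @export
generate_cohort <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- c(negative = spec$n_negative, positive = spec$n_positive)
  cont_attrs <- unique(spec$continuous$attribute)
  cat_attrs <- unique(spec$categorical$attribute)
  noise_attrs <- if (spec$n_noise > 0) {
    sprintf("noise_%02d", seq_len(spec$n_noise))
  } else character(0)

  with_rng_seed(seed, {
    per_class <- lapply(rc_classes(), function(cl) {
      m <- n[[cl]]
      out <- tibble(.rows = m)
      for (nm in cont_attrs) {
        row <- spec$continuous[spec$continuous$attribute == nm &
                                 spec$continuous$class == cl, ]
        x <- rnorm(m, row$mean, row$sd)
        fl <- if (!is.null(spec$floors) && nm %in% names(spec$floors)) {
          spec$floors[[nm]]
        } else NA_real_
        ok <- if (!is.na(fl)) x >= fl else cont_floor_ok(nm, x)
        while (!all(ok)) {
          x[!ok] <- rnorm(sum(!ok), row$mean, row$sd)
          ok <- if (!is.na(fl)) x >= fl else cont_floor_ok(nm, x)
        }
        out[[nm]] <- x
      }
      for (nm in cat_attrs) {
        tab <- spec$categorical[spec$categorical$attribute == nm &
                                  spec$categorical$class == cl, ]
        out[[nm]] <- if (m > 0) {
          sample(tab$category, m, replace = TRUE, prob = tab$prob)
        } else character(0)
      }
      for (nm in noise_attrs) out[[nm]] <- rnorm(m)
      out[[rc_label_col()]] <- rep(cl, m)
      out
    })
    dplyr::bind_rows(per_class)
  })
}

#' Attribute schema implied by a cohort specification
#'
#' Builds an [attribute_schema()] covering exactly the attributes a
#' [generate_cohort()] call will emit, so synthetic cohorts with custom or
#' noise attributes can be fitted and searched without editing the default
#' schema.
#'
#' @param spec A [cohort_spec()].
#' @return An [attribute_schema()].
#' @export
spec_schema <- function(spec) {
  cont_attrs <- unique(spec$continuous$attribute)
  noise_attrs <- if (spec$n_noise > 0) {
    sprintf("noise_%02d", seq_len(spec$n_noise))
  } else character(0)
  rows <- list()
  for (nm in c(cont_attrs, noise_attrs)) {
    rows[[length(rows) + 1]] <- tibble(
      name = nm, kind = "continuous", categories = list(NULL),
      derived_from = list(NULL), group = "synthetic"
    )
  }
  for (nm in unique(spec$categorical$attribute)) {
    cats <- unique(spec$categorical$category[spec$categorical$attribute == nm])
    rows[[length(rows) + 1]] <- tibble(
      name = nm, kind = if (length(cats) == 2) "binary" else "categorical",
      categories = list(cats), derived_from = list(NULL), group = "synthetic"
    )
  }
  attribute_schema(dplyr::bind_rows(rows))
}

#' The published 8-predictor naive Bayes model
#'
#' Reconstructs the released rechallenge model from its published
#' distribution table: class priors 17/35 (negative) and 18/35 (positive),
#' Gaussian parameters for age, albumin, RBC and platelet levels, and
#' class-conditional proportions for the chemotherapeutic drug and the
#' abnormal WBC / ALT / alkaline-phosphatase flags, with smoothing
#' alpha = 0 (the table's exact zero proportions are preserved, so e.g.
#' a drug never seen among positive-rechallenge cases is decisive
#' evidence for negative rechallenge).  This fixture stands in for the
#' original fitted model, whose training data are not public.
#'
#' @return An [nb_model()] over 8 attributes.
#' @export
published_model <- function() {
  nb_model(
    subset = c("age", "albumin", "rbc", "platelet", "chemotherapeutic_drug",
               "abnormal_wbc", "abnormal_alanine_aminotransferase",
               "abnormal_alkaline_phosphatase"),
    prior = c(negative = 17 / 35, positive = 18 / 35),
    continuous = table2_continuous(),
    categorical = renormalise_cat(dplyr::bind_rows(table2_drug(), table2_flags())),
    alpha = 0
  )
}

#' Read or write a cohort specification as JSON
#'
#' @param spec A [cohort_spec()].
#' @param path File path.
#' @return `write_cohort_spec()` returns `path` invisibly;
#'   `read_cohort_spec()` returns the spec.
#' @export
write_cohort_spec <- function(spec, path) {
  doc <- list(
    n_negative = spec$n_negative, n_positive = spec$n_positive,
    continuous = spec$continuous, categorical = spec$categorical,
    n_noise = spec$n_noise, floors = as.list(spec$floors %||% list()),
    seed = spec$seed
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  invisible(path)
}

#' @rdname write_cohort_spec
#' @export
read_cohort_spec <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  floors <- if (length(doc$floors)) unlist(doc$floors) else NULL
  cohort_spec(
    n_negative = doc$n_negative, n_positive = doc$n_positive,
    continuous = if (length(doc$continuous)) as_tibble(doc$continuous) else NULL,
    categorical = if (length(doc$categorical)) as_tibble(doc$categorical) else NULL,
    n_noise = doc$n_noise %||% 0, floors = floors, seed = doc$seed %||% 1L
  )
}
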