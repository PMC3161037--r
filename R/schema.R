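#' Build an attribute schema
#'
#' A schema declares every attribute a cohort may carry: its name, its kind
#' (`"continuous"`, `"categorical"` or `"binary"`), the allowed category
#' labels for discrete attributes, and — for constructed attributes such as
#' the elderly flag — the raw field(s) it is derived from.  The schema is
#' data, not code: cohorts are validated against it, the naive Bayes
#' classifier reads category lists from it, and users can supply their own
#' (e.g. the exact attribute catalogue of a local ADR registry) via
#' [read_schema()].
#'
#' @param attributes A data frame with columns `name` (character), `kind`
#'   (one of `"continuous"`, `"categorical"`, `"binary"`), `categories`
#'   (list-column of character vectors; `NULL` for continuous attributes) and
#'   optionally `derived_from` (list-column naming source fields) and `group`
#'   (free-text grouping such as "demographics").
#'
#' @return A tibble of class `rc_schema`, one row per attribute.
#' @seealso [default_schema()], [derive_attributes()], [read_cohort()]
#' @export
attribute_schema <- function(attributes) {
  s <- as_tibble(attributes)
  if (!all(c("name", "kind") %in% names(s))) {
    abort("schema needs at least `name` and `kind` columns", class = "rc_schema_error")
  }
  if (!"categories" %in% names(s)) s$categories <- rep(list(NULL), nrow(s))
  if (!"derived_from" %in% names(s)) s$derived_from <- rep(list(NULL), nrow(s))
  if (!"group" %in% names(s)) s$group <- NA_character_
  s <- s[, c("name", "kind", "categories", "derived_from", "group")]
  class(s) <- c("rc_schema", class(s))
  validate_schema(s)
}

#' @rdname attribute_schema
#' @param schema An `rc_schema` object to validate.
#' @export
validate_schema <- function(schema) {
  n <- schema$name
  if (any(is.na(n) | !nzchar(n))) {
    abort("attribute names must be non-empty", class = "rc_schema_error")
  }
  if (anyDuplicated(n)) {
    abort(
      paste0("duplicated attribute name(s): ",
             paste(unique(n[duplicated(n)]), collapse = ", ")),
      class = "rc_schema_error"
    )
  }
  bad_kind <- setdiff(unique(schema$kind), c("continuous", "categorical", "binary"))
  if (length(bad_kind)) {
    abort(paste0("unknown attribute kind: ", paste(bad_kind, collapse = ", ")),
          class = "rc_schema_error")
  }
  for (i in seq_len(nrow(schema))) {
    k <- schema$kind[i]
    cats <- schema$categories[[i]]
    if (k == "continuous" && length(cats)) {
      abort(paste0("continuous attribute `", n[i], "` must not list categories"),
            class = "rc_schema_error")
    }
    if (k != "continuous" && length(cats) < 2) {
      abort(paste0("attribute `", n[i], "` needs at least 2 categories"),
            class = "rc_schema_error")
    }
    if (k == "binary" && length(cats) != 2) {
      abort(paste0("binary attribute `", n[i], "` needs exactly 2 categories"),
            class = "rc_schema_error")
    }
  }
  schema
}

yn <- function() c("no", "yes")

#' Default clinical attribute schema
#'
#' The 53-attribute schema used for rechallenge modelling: patient
#' demographics, medical conditions, medication usage and laboratory
#' parameters, plus the constructed attributes (elderly flag, polypharmacy
#' flag, comorbidity count, abnormal-laboratory flags).  Age appears both as
#' a continuous attribute and as the derived elderly binary; attribute
#' subset selection may pick either or both.  The catalogue is a faithful
#' reconstruction from the published attribute groups; sites with richer
#' registries can extend or replace it since the schema is plain data.
#'
#' @return An [attribute_schema()] with exactly 53 attributes.
#' @export
default_schema <- function() {
  drugs <- c("oxaliplatin", "carboplatin", "bleomycin", "rituximab",
             "paclitaxel", "docetaxel", "trastuzumab", "cetuximab",
             "gemcitabine")
  labs <- c("wbc", "rbc", "platelet", "neutrophil", "lymphocyte", "monocyte",
            "eosinophil", "basophil", "serum_creatinine",
            "alkaline_phosphatase", "alanine_aminotransferase",
            "aspartate_aminotransferase", "albumin")
  flagged <- setdiff(labs, "basophil")
  comorb <- comorbidity_fields()

  row <- function(name, kind, categories = NULL, derived_from = NULL, group) {
    tibble(name = name, kind = kind, categories = list(categories),
           derived_from = list(derived_from), group = group)
  }
  specs <- dplyr::bind_rows(
    row("age", "continuous", group = "demographics"),
    row("elderly", "binary", c("non_elderly", "elderly"), "age", "demographics"),
    row("gender", "binary", c("female", "male"), group = "demographics"),
    row("ethnicity", "categorical", c("chinese", "malay", "indian", "other"),
        group = "demographics"),
    row("weight", "continuous", group = "demographics"),
    row("drug_allergy", "binary", yn(), group = "medical_conditions"),
    row("cancer_type", "categorical",
        c("breast", "lung", "colorectal", "lymphoma", "gynaecological",
          "head_and_neck", "other"), group = "medical_conditions"),
    row("cancer_malignancy", "binary", c("localized", "metastatic"),
        group = "medical_conditions"),
    dplyr::bind_rows(lapply(comorb, function(f)
      row(f, "binary", yn(), group = "medical_conditions"))),
    row("comorbidity_count", "continuous", derived_from = comorb,
        group = "medical_conditions"),
    row("adr_symptoms", "categorical",
        c("rash", "anaphylaxis", "cytopenia", "hepatotoxicity", "other"),
        group = "medical_conditions"),
    row("hospitalization_prior_adr", "binary", yn(), group = "medical_conditions"),
    row("adr_organ_system", "categorical",
        c("skin", "immune", "hematological", "hepatic", "respiratory", "other"),
        group = "medical_conditions"),
    row("adr_onset", "binary", c("immediate", "delayed"),
        group = "medical_conditions"),
    row("number_of_cycles", "continuous", group = "medications"),
    row("number_of_doses", "continuous", group = "medications"),
    row("chemotherapeutic_drug", "categorical", drugs, group = "medications"),
    row("chemotherapeutic_drug_class", "categorical",
        c("platinum", "taxane", "monoclonal_antibody", "cytotoxic_antibiotic",
          "antimetabolite"), group = "medications"),
    row("concurrent_medications", "continuous", group = "medications"),
    row("polypharmacy", "binary", yn(), "concurrent_medications", "medications"),
    row("dose_reduction_on_rechallenge", "binary", yn(), group = "medications"),
    row("rechallenge_on_same_day", "binary", yn(), group = "medications"),
    dplyr::bind_rows(lapply(labs, function(l)
      row(l, "continuous", group = "laboratory"))),
    dplyr::bind_rows(lapply(flagged, function(l)
      row(paste0("abnormal_", l), "binary", c("normal", "abnormal"), l,
          "laboratory")))
  )
  attribute_schema(specs)
}

comorbidity_fields <- function() {
  c("hypertension", "diabetes", "hyperlipidemia", "psoriasis", "gerd",
    "asthma", "other_allergic_disorders")
}

#' Reference intervals for laboratory parameters
#'
#' Per-laboratory low/high bounds used to derive the abnormal-lab binary
#' flags: a value strictly outside \[low, high\] is flagged `"abnormal"`.
#' The defaults are conventional adult reference intervals (haematology in
#' 10^9/L except RBC in 10^12/L, creatinine in umol/L, liver enzymes in U/L,
#' albumin in g/L); laboratories should override them with their own panel
#' ranges via a JSON table read with [read_reference_intervals()].
#'
#' @return A tibble with columns `lab`, `low`, `high`.
#' @export
default_reference_intervals <- function() {
  tibble(
    lab  = c("wbc", "rbc", "platelet", "neutrophil", "lymphocyte", "monocyte",
             "eosinophil", "serum_creatinine", "alkaline_phosphatase",
             "alanine_aminotransferase", "aspartate_aminotransferase",
             "albumin"),
    low  = c(4,   3.8, 150, 2,   1,   0.2, 0.02, 45,  40,  5,  10, 35),
    high = c(10,  5.8, 450, 7.5, 4,   1,   0.5,  110, 130, 40, 45, 50)
  )
}

#' Read or write a schema as JSON
#'
#' @param path File path.
#' @return `read_schema()` returns an [attribute_schema()];
#'   `write_schema()` returns `path` invisibly.
#' @export
read_schema <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  specs <- dplyr::bind_rows(lapply(raw, function(a) {
    tibble(
      name = a$name, kind = a$kind,
      categories = list(if (length(a$categories)) unlist(a$categories) else NULL),
      derived_from = list(if (length(a$derived_from)) unlist(a$derived_from) else NULL),
      group = a$group %||% NA_character_
    )
  }))
  attribute_schema(specs)
}

#' @rdname read_schema
#' @param schema An `rc_schema`.
#' @export
write_schema <- function(schema, path) {
  out <- lapply(seq_len(nrow(schema)), function(i) {
    a <- list(name = schema$name[i], kind = schema$kind[i])
    if (length(schema$categories[[i]])) a$categories <- schema$categories[[i]]
    if (length(schema$derived_from[[i]])) a$derived_from <- schema$derived_from[[i]]
    if (!is.na(schema$group[i])) a$group <- schema$group[i]
    a
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname default_reference_intervals
#' @param path File path of a JSON map `lab -> {low, high}`.
#' @export
read_reference_intervals <- function(path) {
  raw <- jsonlite::fromJSON(path)
  tibble(
    lab = names(raw),
    low = vapply(raw, function(x) as.numeric(x$low), numeric(1),
                 USE.NAMES = FALSE),
    high = vapply(raw, function(x) as.numeric(x$high), numeric(1),
                  USE.NAMES = FALSE)
  )
}

#' @rdname default_reference_intervals
#' @param intervals A tibble with columns `lab`, `low`, `high`.
#' @export
write_reference_intervals <- function(intervals, path) {
  out <- setNames(
    lapply(seq_len(nrow(intervals)),
           function(i) list(low = intervals$low[i], high = intervals$high[i])),
    intervals$lab
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

schema_spec <- function(schema, name) {
  i <- match(name, schema$name)
  if (is.na(i)) {
    abort(paste0("attribute `", name, "` is not in the schema"),
          class = "rc_schema_error")
  }
  list(name = schema$name[i], kind = schema$kind[i],
       categories = schema$categories[[i]],
       derived_from = schema$derived_from[[i]])
}
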