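#' Derive constructed clinical attributes
#'
#' Populates every derived attribute declared in the schema from its raw
#' source fields:
#' \itemize{
#'   \item `elderly`: `"elderly"` when age >= 65 years, `"non_elderly"` below.
#'   \item `polypharmacy`: `"yes"` when the number of concurrent medications
#'     exceeds 5 (the serious-polypharmacy definition), `"no"` otherwise.
#'   \item `comorbidity_count`: number of listed comorbidities present
#'     (hypertension, diabetes, hyperlipidemia, psoriasis, GERD, asthma,
#'     other allergic disorders).
#'   \item `abnormal_<lab>`: `"abnormal"` when the laboratory value lies
#'     strictly outside its reference interval, `"normal"` inside.
#' }
#' Missing source values yield missing derived values.  The operation is
#' idempotent: re-deriving an already-derived cohort changes nothing.
#'
#' @param data A cohort data frame (one row per patient).  Columns must be
#'   schema attributes, plus optionally `rechallenge_status` and split flags.
#' @param schema An [attribute_schema()]; defaults to [default_schema()].
#' @param reference_intervals Per-lab low/high bounds used for the
#'   abnormal-lab flags; defaults to [default_reference_intervals()].
#'
#' @return A tibble with the same rows and all derivable attributes
#'   populated, columns in schema order (label and split flags last).
#' @export
derive_attributes <- function(data, schema = default_schema(),
                              reference_intervals = default_reference_intervals()) {
  data <- as_tibble(data)
  extra <- setdiff(names(data), c(schema$name, rc_label_col(), split_cols()))
  if (length(extra)) {
    abort(paste0("unknown field(s) not in schema: ", paste(extra, collapse = ", ")),
          class = "rc_schema_error")
  }

  num_source <- function(field) {
    x <- data[[field]]
    if (is.null(x)) return(NULL)
    if (is.character(x) || is.factor(x)) {
      x_chr <- as.character(x)
      xn <- suppressWarnings(as.numeric(x_chr))
      if (any(!is.na(x_chr) & is.na(xn))) {
        abort(paste0("non-numeric value in field `", field, "`"),
              class = "rc_parse_error")
      }
      return(xn)
    }
    as.numeric(x)
  }

  derived <- schema[vapply(schema$derived_from, length, integer(1)) > 0, ]
  for (i in seq_len(nrow(derived))) {
    name <- derived$name[i]
    src <- derived$derived_from[[i]]
    if (name == "elderly") {
      age <- num_source("age")
      if (!is.null(age)) {
        data[[name]] <- ifelse(is.na(age), NA_character_,
                               ifelse(age >= 65, "elderly", "non_elderly"))
      }
    } else if (name == "polypharmacy") {
      n_med <- num_source("concurrent_medications")
      if (!is.null(n_med)) {
        data[[name]] <- ifelse(is.na(n_med), NA_character_,
                               ifelse(n_med > 5, "yes", "no"))
      }
    } else if (name == "comorbidity_count") {
      present <- intersect(src, names(data))
      if (length(present)) {
        flags <- vapply(present, function(f) {
          x <- as.character(data[[f]])
          ifelse(is.na(x), NA_real_, as.numeric(x == "yes"))
        }, numeric(nrow(data)))
        flags <- matrix(flags, nrow = nrow(data))
        all_na <- rowSums(!is.na(flags)) == 0
        cnt <- rowSums(flags, na.rm = TRUE)
        cnt[all_na] <- NA_real_
        data[[name]] <- cnt
      }
    } else if (startsWith(name, "abnormal_")) {
      lab <- src[1]
      x <- num_source(lab)
      if (!is.null(x)) {
        j <- match(lab, reference_intervals$lab)
        if (is.na(j)) {
          abort(paste0("no reference interval configured for lab `", lab, "`"),
                class = "rc_config_error")
        }
        lo <- reference_intervals$low[j]
        hi <- reference_intervals$high[j]
        data[[name]] <- ifelse(is.na(x), NA_character_,
                               ifelse(x < lo | x > hi, "abnormal", "normal"))
      }
    }
    # pass-through derived categoricals (drug class, cancer type/malignancy,
    # ADR groupings) are plain raw columns in this representation: nothing to do
  }

  front <- intersect(schema$name, names(data))
  back <- intersect(c(rc_label_col(), split_cols()), names(data))
  data[, c(front, back)]
}

split_cols <- function() c("is_train", "is_test", "is_validation")
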