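#' Read and write cohort CSV files
#'
#' A cohort file is a CSV with a header of schema attribute names plus a
#' `rechallenge_status` column holding the outcome label (`negative` /
#' `positive`, parsed case-insensitively).  Columns may appear in any order;
#' missing values use a configurable token (default `"NA"`).  Every value is
#' validated against the schema on read.
#'
#' @param path File path.
#' @param schema An [attribute_schema()]; defaults to [default_schema()].
#' @param missing Token encoding missing values.
#' @param require_labels When `TRUE` (default) the label column must exist
#'   and every row must carry a label; prediction-time cohorts may pass
#'   `FALSE` to allow unlabelled records.
#'
#' @return `read_cohort()` returns a validated tibble, row order preserved;
#'   `write_cohort()` writes attributes in schema order with the label
#'   column last and returns `path` invisibly.
#' @export
read_cohort <- function(path, schema = default_schema(), missing = "NA",
                        require_labels = TRUE) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         na = missing, progress = FALSE)
  raw <- as_tibble(raw)
  if (rc_label_col() %in% names(raw)) {
    lab <- tolower(raw[[rc_label_col()]])
    bad <- !is.na(lab) & !lab %in% rc_classes()
    if (any(bad)) {
      abort(paste0("invalid rechallenge_status in row(s): ",
                   paste(which(bad), collapse = ", ")),
            class = "rc_validation_error")
    }
    raw[[rc_label_col()]] <- lab
  }
  # type conversion per schema (values arrive as character)
  for (nm in intersect(schema$name, names(raw))) {
    sp <- schema_spec(schema, nm)
    if (sp$kind == "continuous") {
      x <- raw[[nm]]
      xn <- suppressWarnings(as.numeric(x))
      bad <- !is.na(x) & is.na(xn)
      if (any(bad)) {
        abort(paste0("non-numeric value for `", nm, "` in row(s): ",
                     paste(which(bad), collapse = ", ")),
              class = "rc_parse_error")
      }
      raw[[nm]] <- xn
    }
  }
  validate_cohort(raw, schema, require_labels = require_labels)
}

#' @rdname read_cohort
#' @param cohort A validated cohort tibble.
#' @export
write_cohort <- function(cohort, path, schema = default_schema(), missing = "NA") {
  cohort <- validate_cohort(cohort, schema, require_labels = FALSE)
  cols <- c(intersect(schema$name, names(cohort)),
            intersect(rc_label_col(), names(cohort)))
  readr::write_csv(cohort[, cols], path, na = missing, progress = FALSE)
  invisible(path)
}

#' Validate a cohort against a schema
#'
#' Checks that every column is a schema attribute (or the label / split-flag
#' columns), that continuous attributes are numeric, and that every
#' non-missing discrete value belongs to the attribute's category set.
#' Errors name the offending attribute and row numbers.
#'
#' @inheritParams read_cohort
#' @param data A cohort data frame.
#' @return The validated cohort as a tibble (invisibly usable in pipes).
#' @export
validate_cohort <- function(data, schema = default_schema(), require_labels = TRUE) {
  data <- as_tibble(data)
  extra <- setdiff(names(data), c(schema$name, rc_label_col(), split_cols()))
  if (length(extra)) {
    abort(paste0("column(s) not in schema: ", paste(extra, collapse = ", ")),
          class = "rc_schema_error")
  }
  if (require_labels) {
    if (!rc_label_col() %in% names(data)) {
      abort("label column `rechallenge_status` is required",
            class = "rc_validation_error")
    }
    if (anyNA(data[[rc_label_col()]])) {
      abort(paste0("missing rechallenge_status in row(s): ",
                   paste(which(is.na(data[[rc_label_col()]])), collapse = ", ")),
            class = "rc_validation_error")
    }
  }
  if (rc_label_col() %in% names(data)) {
    lab <- data[[rc_label_col()]]
    bad <- !is.na(lab) & !lab %in% rc_classes()
    if (any(bad)) {
      abort(paste0("invalid rechallenge_status in row(s): ",
                   paste(which(bad), collapse = ", ")),
            class = "rc_validation_error")
    }
  }
  for (nm in intersect(schema$name, names(data))) {
    sp <- schema_spec(schema, nm)
    x <- data[[nm]]
    if (sp$kind == "continuous") {
      if (!is.numeric(x)) {
        abort(paste0("continuous attribute `", nm, "` must be numeric"),
              class = "rc_validation_error")
      }
    } else {
      x <- as.character(x)
      bad <- !is.na(x) & !x %in% sp$categories
      if (any(bad)) {
        abort(paste0("value outside category set for `", nm, "` in row(s): ",
                     paste(which(bad), collapse = ", ")),
              class = "rc_validation_error")
      }
      data[[nm]] <- x
    }
  }
  data
}

#' Tag training / testing / validation membership
#'
#' Replicates the overlapping development protocol: from the eligible
#' (non-validation-era) records, `n_train` are sampled without replacement
#' to form the training set, while the testing pool is the *entire* eligible
#' set — training records are also testing records.  Validation-era records
#' are excluded from both and tagged as the independent validation set.
#'
#' @param cohort A cohort tibble.
#' @param n_train Number of records to tag as training.
#' @param seed Integer seed; the same seed always yields the same split.
#' @param validation Optional logical vector (length `nrow(cohort)`) marking
#'   validation-era records, e.g. cases from the most recent year.
#'
#' @return The cohort with logical columns `is_train`, `is_test`,
#'   `is_validation` added.
#' @export
split_cohort <- function(cohort, n_train, seed, validation = NULL) {
  cohort <- as_tibble(cohort)
  n <- nrow(cohort)
  if (is.null(validation)) validation <- rep(FALSE, n)
  stopifnot(is.logical(validation), length(validation) == n)
  eligible <- which(!validation)
  if (n_train > length(eligible)) {
    abort(paste0("n_train (", n_train, ") exceeds the eligible pool (",
                 length(eligible), ")"),
          class = "rc_split_error")
  }
  train_idx <- with_rng_seed(seed, {
    if (n_train > 0) sample(eligible, n_train) else integer(0)
  })
  cohort$is_train <- seq_len(n) %in% train_idx
  cohort$is_test <- !validation
  cohort$is_validation <- validation
  cohort
}

#' Count cohort records by outcome label
#'
#' @param cohort A cohort tibble.
#' @return A tibble with one row per outcome label and an `n` column;
#'   the counts sum to `nrow(cohort)`.
#' @export
cohort_counts <- function(cohort) {
  lab <- cohort[[rc_label_col()]]
  if (is.null(lab)) lab <- rep(NA_character_, nrow(cohort))
  out <- tibble(rechallenge_status = c(rc_classes(), NA_character_))
  out$n <- vapply(seq_len(nrow(out)), function(i) {
    v <- out$rechallenge_status[i]
    if (is.na(v)) sum(is.na(lab)) else sum(!is.na(lab) & lab == v)
  }, integer(1))
  out[out$n > 0 | !is.na(out$rechallenge_status), ]
}

# evaluate `code` under a temporary RNG state seeded with `seed`,
# restoring the caller's stream afterwards
with_rng_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
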