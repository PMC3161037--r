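# GA wrapper attribute selection: chromosomes are bit masks over the
# candidate attributes; the fitness of a mask is the AUC of a naive Bayes
# model fitted on the training records (restricted to the masked
# attributes) and scored on the testing records.

#' AUC fitness of an attribute subset
#'
#' Fits a naive Bayes model on the training records using exactly the given
#' attributes, scores the testing records, and returns the AUC with
#' negative rechallenge as the detection target.  A degenerate fit (e.g. an
#' attribute entirely missing within a class) maps to fitness 0 with a
#' logged message, so one bad chromosome cannot abort a search.
#'
#' @param train,test Labelled cohort tibbles (both classes present).
#' @param subset Non-empty character vector of attribute names.
#' @param schema An [attribute_schema()].
#' @param alpha Smoothing pseudocount forwarded to [nb_fit()].
#' @return AUC in \[0, 1\]; deterministic given its inputs.
#' @export
ga_fitness <- function(train, test, subset, schema = default_schema(), alpha = 0) {
  tryCatch({
    m <- nb_fit(train, subset = subset, schema = schema, alpha = alpha)
    sc <- nb_score_impl(m, test)$posterior
    roc_auc(sc, test[[rc_label_col()]])
  }, error = function(e) {
    inform(paste0("degenerate subset scored 0: ", conditionMessage(e)))
    0
  })
}

#' Roulette-wheel (fitness-proportional) selection
#'
#' Samples one population index with probability proportional to fitness.
#' When every fitness is zero the draw is uniform.
#'
#' @param fitness Non-negative numeric vector of fitness values.
#' @return A single index into `fitness`.
#' @export
roulette_select <- function(fitness) {
  if (any(fitness < 0)) abort("fitness must be non-negative", class = "rc_ga_error")
  if (sum(fitness) == 0) {
    sample.int(length(fitness), 1)
  } else {
    sample.int(length(fitness), 1, prob = fitness)
  }
}

#' Single-point crossover of two attribute masks
#'
#' With probability `rate`, a cut point is drawn uniformly in
#' \[1, L - 1\] and the tails beyond the cut are swapped; otherwise the
#' children are copies of the parents.  Masks of length < 2 are always
#' copied.
#'
#' @param a,b Logical masks of equal length.
#' @param rate Crossover probability.
#' @param cut Optional fixed cut position (tail starts at `cut + 1`);
#'   mainly for deterministic testing.
#' @return A list with elements `a` and `b`, the two children.
#' @export
ga_crossover <- function(a, b, rate, cut = NULL) {
  L <- length(a)
  if (length(b) != L) abort("parent masks differ in length", class = "rc_ga_error")
  if (L < 2 || runif(1) >= rate) return(list(a = a, b = b))
  if (is.null(cut)) cut <- sample.int(L - 1, 1)
  tail_idx <- (cut + 1):L
  tmp <- a[tail_idx]
  a[tail_idx] <- b[tail_idx]
  b[tail_idx] <- tmp
  list(a = a, b = b)
}

#' Bit-flip mutation of an attribute mask
#'
#' Each bit flips independently with probability `rate` (interpreted per
#' bit, so at 5% an average of 0.05 * L attributes toggle).  An empty mask
#' is repaired by switching one uniformly chosen bit on, preserving the
#' at-least-one-attribute invariant.
#'
#' @param mask Logical mask.
#' @param rate Per-bit flip probability.
#' @return The mutated (and repaired) mask.
#' @export
ga_mutate <- function(mask, rate) {
  flip <- runif(length(mask)) < rate
  mask <- xor(mask, flip)
  repair_mask(mask)
}

repair_mask <- function(mask) {
  if (!any(mask)) mask[sample.int(length(mask), 1)] <- TRUE
  mask
}

#' Genetic-algorithm attribute selection
#'
#' Wrapper feature selection: evolves a population of attribute masks whose
#' fitness is the testing-set AUC of a naive Bayes model fitted on the
#' training set.  Each run initialises `population_size` random masks (each
#' bit on with probability 0.5), then iterates for `generations`
#' generations of roulette-wheel parent selection, single-point crossover,
#' per-bit mutation, and full generational replacement with `elitism` best
#' individuals carried over unchanged.  The search is repeated `n_runs`
#' times from different starting populations (seeds `seed`, `seed + 1`,
#' ...) and the best individual across all runs is returned; ties are
#' broken towards fewer selected attributes, then the earlier run.
#'
#' @param train,test Labelled cohort tibbles; the testing pool may overlap
#'   the training records (the development protocol re-scores the full
#'   eligible set).
#' @param attributes Candidate attribute names; defaults to every schema
#'   attribute present in `train`.
#' @param schema An [attribute_schema()].
#' @param population_size Number of masks per generation (default 80).
#' @param generations Number of generations per run (default 100).
#' @param crossover_rate Probability of single-point crossover (default 0.95).
#' @param mutation_rate Per-bit flip probability (default 0.05).
#' @param n_runs Independent restarts (default 5).
#' @param elitism Number of best individuals copied unchanged into the next
#'   generation (default 1; set 0 to disable).
#' @param seed Integer seed; the full result, histories included, is
#'   bit-reproducible for a fixed seed.
#' @param alpha Smoothing pseudocount forwarded to the model fits.
#'
#' @return A `ga_result`: list with `best_subset` (attribute names),
#'   `best_mask`, `best_fitness`, `history` (tibble of per-run, per-
#'   generation best and mean fitness), `run_seeds` and `attributes`.
#' @export
run_ga <- function(train, test, attributes = NULL, schema = default_schema(),
                   population_size = 80, generations = 100,
                   crossover_rate = 0.95, mutation_rate = 0.05,
                   n_runs = 5, elitism = 1, seed = 1, alpha = 0) {
  stopifnot(population_size >= 1, generations >= 1, n_runs >= 1,
            elitism >= 0, elitism < population_size,
            crossover_rate >= 0, crossover_rate <= 1,
            mutation_rate >= 0, mutation_rate <= 1)
  if (is.null(attributes)) {
    attributes <- intersect(default_candidates(schema), names(as_tibble(train)))
  }
  L <- length(attributes)
  if (L == 0) abort("no candidate attributes", class = "rc_ga_error")
  prep <- ga_prepare(train, test, attributes, schema, alpha)
  cache <- new.env(parent = emptyenv())
  fit_mask <- function(mask) {
    key <- paste(which(mask), collapse = ",")
    got <- cache[[key]]
    if (!is.null(got)) return(got)
    val <- ga_fitness_fast(mask, prep)
    cache[[key]] <- val
    val
  }

  seed <- as.integer(seed)
  run_seeds <- seed + seq_len(n_runs) - 1L
  history <- vector("list", n_runs)
  best <- NULL  # list(mask, fitness, run)

  for (r in seq_len(n_runs)) {
    hist_best <- hist_mean <- numeric(generations)
    run_best <- NULL
    with_rng_seed(run_seeds[r], {
      pop <- lapply(seq_len(population_size), function(i) {
        repair_mask(runif(L) < 0.5)
      })
      for (gen in seq_len(generations)) {
        stopifnot(all(vapply(pop, any, logical(1))))  # non-empty-mask invariant
        fit <- vapply(pop, fit_mask, numeric(1))
        hist_best[gen] <- max(fit)
        hist_mean[gen] <- mean(fit)
        gi <- ga_argbest(fit, pop)
        cand <- list(mask = pop[[gi]], fitness = fit[gi])
        if (is.null(run_best) || ga_better(cand, run_best)) run_best <- cand
        if (gen < generations) {
          ord <- order(fit, decreasing = TRUE)
          nxt <- if (elitism > 0) pop[ord[seq_len(elitism)]] else list()
          while (length(nxt) < population_size) {
            pa <- pop[[roulette_select(fit)]]
            pb <- pop[[roulette_select(fit)]]
            kids <- ga_crossover(pa, pb, crossover_rate)
            nxt[[length(nxt) + 1]] <- ga_mutate(kids$a, mutation_rate)
            if (length(nxt) < population_size) {
              nxt[[length(nxt) + 1]] <- ga_mutate(kids$b, mutation_rate)
            }
          }
          pop <- nxt
        }
      }
    })
    history[[r]] <- tibble(run = r, generation = seq_len(generations),
                           best = hist_best, mean = hist_mean)
    run_best$run <- r
    if (is.null(best) || ga_better(run_best, best)) best <- run_best
  }

  structure(
    list(
      best_subset = attributes[best$mask],
      best_mask = best$mask,
      best_fitness = best$fitness,
      best_run = best$run,
      history = dplyr::bind_rows(history),
      run_seeds = run_seeds,
      attributes = attributes,
      config = list(population_size = population_size,
                    generations = generations,
                    crossover_rate = crossover_rate,
                    mutation_rate = mutation_rate,
                    n_runs = n_runs, elitism = elitism, seed = seed,
                    alpha = alpha)
    ),
    class = "ga_result"
  )
}

# strictly better: higher fitness, then fewer selected bits, then earlier run
ga_better <- function(a, b) {
  if (a$fitness != b$fitness) return(a$fitness > b$fitness)
  na <- sum(a$mask); nb <- sum(b$mask)
  if (na != nb) return(na < nb)
  FALSE
}

ga_argbest <- function(fit, pop) {
  i <- which(fit == max(fit))
  if (length(i) == 1) return(i)
  i[which.min(vapply(pop[i], sum, numeric(1)))]
}

default_candidates <- function(schema) schema$name

# ---- fast fitness path -----------------------------------------------------
# Scores test records by the class log-likelihood difference, a strictly
# monotone transform of the posterior (AUC-invariant), avoiding
# exponentiation in the inner loop.

ga_prepare <- function(train, test, attributes, schema, alpha, sd_floor = 1e-6) {
  train <- as_tibble(train)
  test <- as_tibble(test)
  lab_tr <- train[[rc_label_col()]]
  lab_te <- test[[rc_label_col()]]
  if (is.null(lab_tr) || is.null(lab_te)) {
    abort("train and test cohorts must be labelled", class = "rc_ga_error")
  }
  keep_tr <- !is.na(lab_tr); train <- train[keep_tr, ]; lab_tr <- lab_tr[keep_tr]
  keep_te <- !is.na(lab_te); test <- test[keep_te, ]; lab_te <- check_labels(lab_te[keep_te])
  lab_tr <- check_labels(lab_tr)
  if (length(unique(lab_tr)) < 2) {
    abort("both classes must be present in the training set", class = "rc_ga_error")
  }
  attrs <- lapply(attributes, function(nm) {
    sp <- schema_spec(schema, nm)
    if (!nm %in% names(train) || !nm %in% names(test)) {
      abort(paste0("attribute `", nm, "` missing from cohort"), class = "rc_ga_error")
    }
    if (sp$kind == "continuous") {
      list(kind = "c", xtr = as.numeric(train[[nm]]), xte = as.numeric(test[[nm]]))
    } else {
      k <- length(sp$categories)
      list(kind = "d", k = k,
           xtr = match(as.character(train[[nm]]), sp$categories),
           xte = match(as.character(test[[nm]]), sp$categories))
    }
  })
  list(attrs = attrs, neg_tr = lab_tr == "negative",
       is_neg_te = lab_te == "negative", n_te = length(lab_te),
       alpha = alpha, sd_floor = sd_floor)
}

ga_fitness_fast <- function(mask, prep) {
  tryCatch({
    lln <- llp <- numeric(prep$n_te)
    for (j in which(mask)) {
      a <- prep$attrs[[j]]
      if (a$kind == "c") {
        for (neg in c(TRUE, FALSE)) {
          xi <- a$xtr[prep$neg_tr == neg]
          xi <- xi[!is.na(xi)]
          if (length(xi) == 0) stop("continuous attribute empty in a class")
          s <- if (length(xi) > 1) sd(xi) else 0
          term <- dnorm(a$xte, mean(xi), max(s, prep$sd_floor), log = TRUE)
          term[is.na(term)] <- 0
          if (neg) lln <- lln + term else llp <- llp + term
        }
      } else {
        for (neg in c(TRUE, FALSE)) {
          xi <- a$xtr[prep$neg_tr == neg]
          xi <- xi[!is.na(xi)]
          n_obs <- length(xi)
          if (n_obs == 0 && prep$alpha == 0) {
            stop("categorical attribute empty in a class with alpha = 0")
          }
          p <- (tabulate(xi, a$k) + prep$alpha) / (n_obs + prep$alpha * a$k)
          term <- log(p)[a$xte]
          term[is.na(a$xte)] <- 0
          if (neg) lln <- lln + term else llp <- llp + term
        }
      }
    }
    score <- lln - llp
    score[is.infinite(lln) & lln < 0 & is.infinite(llp) & llp < 0] <- 0
    auc_lean(score, prep$is_neg_te)
  }, error = function(e) 0)
}

# trapezoidal ROC area on plain vectors (ties get half credit)
auc_lean <- function(scores, is_target) {
  n_t <- sum(is_target)
  n_f <- sum(!is_target)
  if (n_t == 0 || n_f == 0) stop("AUC undefined: one class missing")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  tgt <- is_target[ord]
  last <- which(c(s[-1] != s[-length(s)], TRUE))
  tpr <- c(0, cumsum(tgt)[last] / n_t)
  fpr <- c(0, cumsum(!tgt)[last] / n_f)
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

#' @export
print.ga_result <- function(x, ...) {
  cat("<ga_result> GA attribute selection\n")
  cat(sprintf("  %d candidate attributes, %d run(s) x %d generation(s), population %d\n",
              length(x$attributes), x$config$n_runs, x$config$generations,
              x$config$population_size))
  cat(sprintf("  best fitness (testing-set AUC): %.4f (run %d)\n",
              x$best_fitness, x$best_run))
  cat("  selected:", paste(x$best_subset, collapse = ", "), "\n")
  invisible(x)
}

#' Per-generation fitness history of a GA search
#'
#' @param x A `ga_result`.
#' @param ... Unused.
#' @return A tibble with columns `run`, `generation`, `best`, `mean`.
#' @method tidy ga_result
#' @export
tidy.ga_result <- function(x, ...) x$history

#' @method glance ga_result
#' @export
glance.ga_result <- function(x, ...) {
  tibble(best_fitness = x$best_fitness,
         n_selected = length(x$best_subset),
         n_candidates = length(x$attributes),
         n_runs = x$config$n_runs,
         best_run = x$best_run)
}

#' Plot GA fitness trajectories
#'
#' @param object A `ga_result`.
#' @param ... Unused.
#' @return A ggplot of best and mean fitness per generation, one panel line
#'   pair per run.
#' @method autoplot ga_result
#' @export
autoplot.ga_result <- function(object, ...) {
  h <- tidyr::pivot_longer(object$history, c("best", "mean"),
                           names_to = "statistic", values_to = "fitness")
  ggplot2::ggplot(h, ggplot2::aes(x = .data$generation, y = .data$fitness,
                                  colour = .data$statistic)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~run, labeller = ggplot2::label_both) +
    ggplot2::labs(y = "testing-set AUC", x = "generation") +
    ggplot2::theme_minimal()
}

#' Write a GA result (with full history) to JSON
#'
#' @param result A `ga_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ga_result <- function(result, path) {
  doc <- list(
    best_subset = result$best_subset,
    best_fitness = result$best_fitness,
    best_run = result$best_run,
    run_seeds = result$run_seeds,
    attributes = result$attributes,
    config = result$config,
    history = result$history
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  invisible(path)
}
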