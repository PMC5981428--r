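#' Outcome fractions of a results table
#'
#' Percentages of trials classified unsuccessful / naturalized / invader,
#' with the mean and standard deviation of the final alien density, overall
#' or within groups. Trials recorded in the unclassifiable gap are excluded
#' from the percentages and reported in `n_gap`.
#'
#' @param results A trial table from [run_design()] / [run_trial()].
#' @param by Optional character vector of grouping columns (e.g.
#'   `"alien_efficiency"`, `"mortality"`).
#' @return A tibble of per-group percentages and abundance summaries.
#' @export
outcome_fractions <- function(results, by = NULL) {
  if (nrow(results) == 0) stop("empty results table", call. = FALSE)
  g <- if (is.null(by)) results else
    dplyr::group_by(results, dplyr::across(dplyr::all_of(by)))
  dplyr::summarise(
    g,
    n = sum(.data$outcome != "gap"),
    n_gap = sum(.data$outcome == "gap"),
    pct_unsuccessful = 100 * mean(.data$outcome[.data$outcome != "gap"] ==
                                    "unsuccessful"),
    pct_naturalized = 100 * mean(.data$outcome[.data$outcome != "gap"] ==
                                   "naturalized"),
    pct_invader = 100 * mean(.data$outcome[.data$outcome != "gap"] ==
                               "invader"),
    abundance_mean = mean(.data$alien_final_density),
    abundance_sd = stats::sd(.data$alien_final_density),
    .groups = "drop"
  )
}

#' Regression-tree variable importance with fivefold cross-validation
#'
#' Fits a binary recursive-partitioning tree of `response` on `predictors`
#' (variance reduction; for a 0/1 response this is equivalent to impurity
#' reduction), prunes it at the complexity value minimising the
#' cross-validated error, and reports each predictor's share of the total
#' split improvement normalised to sum 100%. Predictive power is summarised
#' as the R-squared of pooled held-out predictions over `folds` seeded
#' folds.
#'
#' @param results A trial table (rows with missing predictor values are
#'   dropped).
#' @param response Name of the response column. Character or factor
#'   responses are converted to 0/1 indicator per level against the rest
#'   only if binary; otherwise supply a numeric column.
#' @param predictors Character vector of predictor columns.
#' @param folds Number of cross-validation folds.
#' @param seed Seed controlling fold assignment.
#' @param cp,minsplit Tree-growing controls passed to [rpart::rpart()].
#' @return An `invasion_tree` object with `importance` (tibble),
#'   `r_squared`, and the pruned `model`. `tidy()` returns the importance
#'   table; `glance()` the fit summary.
#' @export
tree_importance <- function(results, response, predictors, folds = 5,
                            seed = 1, cp = 1e-3, minsplit = 20) {
  d <- results[, c(response, predictors)]
  d <- d[stats::complete.cases(d), ]
  y <- d[[response]]
  if (is.character(y) || is.factor(y) || is.logical(y)) {
    lv <- unique(as.character(y))
    if (length(lv) != 2) stop("non-numeric response must be binary",
                              call. = FALSE)
    y <- as.numeric(as.character(y) == sort(lv)[2])
    d[[response]] <- y
  }
  if (stats::var(y) == 0) stop("response is constant", call. = FALSE)
  if (nrow(d) < 50) stop("need at least 50 usable rows", call. = FALSE)

  fm <- stats::reformulate(predictors, response)
  # primary splits only, so importance reflects realised split improvement
  ctl <- rpart::rpart.control(cp = cp, minsplit = minsplit, xval = 0,
                              maxcompete = 0, maxsurrogate = 0,
                              usesurrogate = 0)
  set.seed(seed)
  fold <- sample(rep_len(seq_len(folds), nrow(d)))
  # cross-validated choice of pruning complexity
  full <- rpart::rpart(fm, data = d, method = "anova",
                       control = rpart::rpart.control(cp = cp,
                                                      minsplit = minsplit,
                                                      maxcompete = 0,
                                                      maxsurrogate = 0,
                                                      usesurrogate = 0,
                                                      xval = folds))
  cptab <- full$cptable
  best_cp <- cptab[which.min(cptab[, "xerror"]), "CP"]
  model <- rpart::prune(full, cp = best_cp)

  pred <- numeric(nrow(d))
  for (k in seq_len(folds)) {
    fit_k <- rpart::rpart(fm, data = d[fold != k, ], method = "anova",
                          control = ctl)
    fit_k <- rpart::prune(fit_k, cp = best_cp)
    pred[fold == k] <- stats::predict(fit_k, d[fold == k, ])
  }
  r2 <- 1 - sum((y - pred)^2) / sum((y - mean(y))^2)

  imp <- model$variable.importance
  if (is.null(imp)) imp <- stats::setNames(numeric(0), character(0))
  importance <- tibble::tibble(
    predictor = predictors,
    importance = as.numeric(imp[predictors])
  )
  importance$importance[is.na(importance$importance)] <- 0
  tot <- sum(importance$importance)
  importance$importance <- if (tot > 0) 100 * importance$importance / tot
                           else importance$importance
  importance <- dplyr::arrange(importance, dplyr::desc(.data$importance))

  structure(
    list(model = model, importance = importance, r_squared = r2,
         response = response, n = nrow(d), folds = folds),
    class = "invasion_tree"
  )
}

#' @export
print.invasion_tree <- function(x, ...) {
  cat(sprintf("<invasion_tree> %s ~ %d predictors, n = %d, CV R^2 = %.2f\n",
              x$response, nrow(x$importance), x$n, x$r_squared))
  print(utils::head(x$importance, 5))
  invisible(x)
}

#' @export
tidy.invasion_tree <- function(x, ...) x$importance

#' @export
glance.invasion_tree <- function(x, ...) {
  tibble::tibble(
    response = x$response, n = x$n, folds = x$folds,
    r_squared = x$r_squared,
    n_splits = sum(x$model$frame$var != "<leaf>")
  )
}

interaction_lattice <- function(predictors, max_order = 3) {
  two <- if (length(predictors) >= 2) {
    utils::combn(predictors, 2, simplify = FALSE)
  } else list()
  three <- if (max_order >= 3 && length(predictors) >= 3) {
    utils::combn(predictors, 3, simplify = FALSE)
  } else list()
  list(two = two, three = three)
}

#' Gaussian linear models with AIC-selected interactions
#'
#' Fits Gaussian identity-link linear models of `response` on the given
#' main effects plus every marginality-respecting subset of their two- and
#' three-way interactions (a three-way term is considered only when all of
#' its two-way children are present), and selects the model with the
#' lowest AIC. The search is exhaustive over the interaction lattice, so
#' results are deterministic.
#'
#' @param results A trial table.
#' @param response Name of the (numeric) response column.
#' @param predictors Character vector of main-effect columns (at most 5).
#' @param max_order Highest interaction order searched (2 or 3).
#' @return An `invasion_glm` object with the fitted `model`, its `aic`,
#'   `formula`, and a `candidates` tibble of all models searched. `tidy()`
#'   returns the coefficient table; `glance()` the model summary.
#' @export
fit_effect_glm <- function(results, response, predictors, max_order = 3) {
  stopifnot(length(predictors) >= 1, length(predictors) <= 5)
  d <- results[, c(response, predictors)]
  d <- d[stats::complete.cases(d), ]
  lat <- interaction_lattice(predictors, max_order)
  n2 <- length(lat$two)
  term_label <- function(v) paste(v, collapse = ":")

  candidates <- list()
  for (mask2 in seq_len(2^n2) - 1L) {
    two_in <- lat$two[bitwAnd(mask2, bitwShiftL(1L, seq_len(n2) - 1L)) > 0]
    two_lab <- vapply(two_in, term_label, character(1))
    ok3 <- Filter(function(tr) {
      all(vapply(utils::combn(tr, 2, simplify = FALSE), term_label,
                 character(1)) %in% two_lab)
    }, lat$three)
    n3 <- length(ok3)
    for (mask3 in seq_len(max(1L, 2^n3)) - 1L) {
      three_in <- if (n3 == 0) list() else
        ok3[bitwAnd(mask3, bitwShiftL(1L, seq_len(n3) - 1L)) > 0]
      terms <- c(predictors, two_lab,
                 vapply(three_in, term_label, character(1)))
      candidates[[length(candidates) + 1L]] <- terms
    }
  }

  fits <- lapply(candidates, function(terms) {
    stats::glm(stats::reformulate(terms, response), data = d,
               family = stats::gaussian())
  })
  aics <- vapply(fits, stats::AIC, numeric(1))
  sizes <- lengths(candidates)
  best <- order(aics, sizes)[1]
  model <- fits[[best]]
  if (anyNA(stats::coef(model))) {
    stop("collinear terms in selected model: ",
         paste(names(stats::coef(model))[is.na(stats::coef(model))],
               collapse = ", "),
         call. = FALSE)
  }
  structure(
    list(
      model = model, aic = aics[best],
      formula = stats::formula(model),
      candidates = tibble::tibble(
        terms = vapply(candidates, paste, character(1), collapse = " + "),
        aic = aics
      ),
      response = response, n = nrow(d)
    ),
    class = "invasion_glm"
  )
}

#' @export
print.invasion_glm <- function(x, ...) {
  cat(sprintf("<invasion_glm> %s, AIC = %.1f (best of %d candidates)\n",
              deparse(x$formula), x$aic, nrow(x$candidates)))
  invisible(x)
}

#' @export
tidy.invasion_glm <- function(x, ...) {
  s <- summary(x$model)$coefficients
  tibble::tibble(
    term = rownames(s),
    estimate = s[, "Estimate"],
    std.error = s[, "Std. Error"],
    statistic = s[, "t value"],
    p.value = s[, "Pr(>|t|)"]
  )
}

#' @export
glance.invasion_glm <- function(x, ...) {
  tibble::tibble(
    aic = x$aic, n = x$n,
    df = x$model$df.residual,
    deviance = stats::deviance(x$model),
    n_candidates = nrow(x$candidates)
  )
}
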