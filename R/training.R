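# Retraining the contact-based affinity model: Ki -> free-energy conversion,
# ordinary least squares, AIC stepwise feature selection and repeated k-fold
# cross-validation.  Fitting is delegated to stats::lm / stats::step; the
# stepwise AIC convention is the Gaussian form n*ln(RSS/n) + 2*(p+1).

#' Convert an inhibition constant to a binding free energy
#'
#' `dG = R * T * ln(Ki)`, with Ki in molar units, so sub-molar affinities give
#' negative free energies.
#'
#' @param ki inhibition constant(s) in molar; must be positive.
#' @param temperature absolute temperature in kelvin.
#' @param gas_constant in kcal/(mol K).
#' @return Free energy in kcal/mol.
#' @export
ki_to_dg <- function(ki, temperature = 298.15, gas_constant = 0.0019872) {
  if (any(!is.finite(ki) | ki <= 0))
    stop("ki must be positive and finite")
  gas_constant * temperature * log(ki)
}

#' Assemble a training table
#'
#' One row per complex: an id column, numeric feature columns (electrostatic
#' energy and the ten contact-pair counts by default) and the target free
#' energy `dg` in kcal/mol.
#'
#' @param df data.frame with columns `complex_id`, the features, and `dg`.
#' @param feature_names which columns are features; default all columns other
#'   than `complex_id` and `dg`.
#' @return A `training_table` (a data.frame with a `feature_names` attribute).
#' @export
training_table <- function(df, feature_names = NULL) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (!all(c("complex_id", "dg") %in% names(df)))
    stop("training table needs 'complex_id' and 'dg' columns")
  if (anyDuplicated(df$complex_id))
    stop("complex_ids must be unique")
  if (is.null(feature_names))
    feature_names <- setdiff(names(df), c("complex_id", "dg"))
  vals <- as.matrix(df[, c(feature_names, "dg")])
  if (!is.numeric(vals) || any(!is.finite(vals)))
    stop("features and targets must be numeric and finite")
  structure(df[, c("complex_id", feature_names, "dg")],
            feature_names = feature_names,
            class = c("training_table", "data.frame"))
}

#' @rdname training_table
#' @param table a `training_table`.
#' @return `feature_names()` returns the feature column names.
#' @export
feature_names <- function(table) attr(table, "feature_names")

#' Read / write a training table as tab-delimited text
#' @param file path to a TSV with header columns `complex_id`, features, `dg`.
#' @return A `training_table`, or `file` invisibly for the writer.
#' @export
read_training_table <- function(file) {
  training_table(utils::read.table(file, header = TRUE, sep = "\t",
                                   stringsAsFactors = FALSE))
}

#' @rdname read_training_table
#' @param table a `training_table`.
#' @export
write_training_table <- function(table, file) {
  utils::write.table(table, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

.fit_lm <- function(table, features) {
  dat <- as.data.frame(table)[, c(features, "dg"), drop = FALSE]
  fml <- stats::as.formula(paste("dg ~", paste(c("1", features), collapse = " + ")))
  fit <- stats::lm(fml, data = dat)
  if (fit$rank < length(features) + 1L) {
    al <- stats::alias(fit)$Complete
    stop("rank-deficient design; collinear feature(s): ",
         paste(rownames(al), collapse = ", "))
  }
  fit
}

.as_affinity_fit <- function(fit, features, table) {
  cf <- stats::coef(fit)
  n <- nrow(table)
  rss <- sum(stats::residuals(fit)^2)
  model <- affinity_model(
    coefficients = if (length(features)) cf[features] else stats::setNames(numeric(0), character(0)),
    intercept = unname(cf["(Intercept)"]),
    feature_order = features)
  model$fit <- fit
  model$rss <- rss
  model$aic <- n * log(rss / n) + 2 * (length(features) + 1L)
  model$se <- sqrt(diag(stats::vcov(fit)))
  model$n <- n
  class(model) <- c("affinity_fit", "affinity_model")
  model
}

#' Fit the linear affinity model by ordinary least squares
#'
#' @param table a [training_table()].
#' @param features feature subset to fit on; default all features.
#' @return An `affinity_fit` (also an `affinity_model`) carrying the
#'   underlying `lm` fit, residual sum of squares, AIC
#'   (`n*ln(RSS/n) + 2*(p+1)`) and coefficient standard errors.
#' @export
fit_affinity <- function(table, features = feature_names(table)) {
  stopifnot(inherits(table, "training_table"))
  if (nrow(table) < length(features) + 1L)
    stop("need at least as many rows as coefficients")
  .as_affinity_fit(.fit_lm(table, features), features, table)
}

#' @export
summary.affinity_fit <- function(object, ...) {
  summary(object$fit, ...)
}

#' @export
print.affinity_fit <- function(x, digits = 6, ...) {
  cat("Affinity model fit (n =", x$n, "):\n")
  print(round(c(x$coefficients, `(Intercept)` = x$intercept), digits))
  cat(sprintf("RSS %.4f  AIC %.4f\n", x$rss, x$aic))
  invisible(x)
}

#' AIC stepwise feature selection
#'
#' Greedy add/drop search minimising `AIC = n*ln(RSS/n) + 2*(p+1)`: each step
#' applies the single feature addition or removal that lowers AIC most, and
#' stops when no move lowers it.  Deterministic given the table.
#'
#' @param table a [training_table()].
#' @param direction `"both"` (default, starting from the full model),
#'   `"forward"` (from the intercept-only model) or `"backward"`.
#' @param features candidate feature set; default all.
#' @return An `affinity_fit` on the selected features, with the selected
#'   names in `$feature_order` and the step trajectory in `$anova`.
#' @export
aic_stepwise <- function(table, direction = c("both", "forward", "backward"),
                         features = feature_names(table)) {
  stopifnot(inherits(table, "training_table"))
  direction <- match.arg(direction)
  full <- .fit_lm(table, features)
  dat <- as.data.frame(table)[, c(features, "dg"), drop = FALSE]
  scope <- list(lower = stats::as.formula("~ 1"),
                upper = stats::as.formula(paste("~", paste(features, collapse = " + "))))
  start <- if (direction == "forward")
    stats::lm(dg ~ 1, data = dat) else full
  sel <- stats::step(start, scope = scope, direction = direction, trace = 0)
  kept <- intersect(features, attr(stats::terms(sel), "term.labels"))
  out <- .as_affinity_fit(sel, kept, table)
  out$anova <- sel$anova
  out
}

#' Repeated k-fold cross-validation of the affinity model
#'
#' Rows are assigned to folds uniformly at random (no stratification) from
#' the seed.  For each repeat, each fold is held out in turn, the model is
#' fitted on the remaining folds, and the held-out predictions are pooled
#' before computing Pearson r, Kendall tau-b and RMSE for that repeat.
#'
#' @param table a [training_table()].
#' @param k number of folds.
#' @param repeats number of repeats.
#' @param seed integer RNG seed for fold assignment.
#' @param method `"stepwise"` (AIC selection inside each training fold) or
#'   `"ols"` (all features).
#' @param direction stepwise direction, see [aic_stepwise()].
#' @return A `cv_report`: per-repeat metrics plus their means and standard
#'   deviations, with the per-repeat fold assignments in `$folds`.
#' @export
cross_validate <- function(table, k = 4, repeats = 1, seed = 1,
                           method = c("stepwise", "ols"),
                           direction = "both") {
  stopifnot(inherits(table, "training_table"))
  method <- match.arg(method)
  n <- nrow(table)
  if (k > n) stop("k exceeds number of rows")
  if (k < 2) stop("k must be at least 2")
  feats <- feature_names(table)
  per <- data.frame(repeat_ = integer(0), pearson_r = numeric(0),
                    kendall_tau = numeric(0), rmse = numeric(0))
  rng <- .with_seed(seed, lapply(seq_len(repeats), function(r)
    sample(rep_len(seq_len(k), n))))
  for (r in seq_len(repeats)) {
    folds <- rng[[r]]
    pred <- numeric(n)
    for (f in seq_len(k)) {
      test <- folds == f
      train <- training_table(as.data.frame(table)[!test, , drop = FALSE],
                              feature_names = feats)
      fit <- if (method == "stepwise")
        aic_stepwise(train, direction = direction) else fit_affinity(train)
      newx <- as.matrix(as.data.frame(table)[test, feats, drop = FALSE])
      pred[test] <- if (length(fit$feature_order))
        dg_score(newx[, fit$feature_order, drop = FALSE], fit) else
        rep(fit$intercept, sum(test))
    }
    obs <- table$dg
    per <- rbind(per, data.frame(
      repeat_ = r,
      pearson_r = if (stats::sd(pred) > 0) stats::cor(pred, obs) else NA_real_,
      kendall_tau = stats::cor(pred, obs, method = "kendall"),
      rmse = sqrt(mean((pred - obs)^2))))
  }
  metrics <- c("pearson_r", "kendall_tau", "rmse")
  structure(list(k = k, repeats = repeats, per_repeat = per, folds = rng,
                 means = colMeans(per[metrics]),
                 sds = vapply(per[metrics], stats::sd, numeric(1L))),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation, %d repeat(s)\n", x$k, x$repeats))
  for (m in names(x$means))
    cat(sprintf("  %-12s %.4f +/- %s\n", m, x$means[[m]],
                if (x$repeats > 1) sprintf("%.4f", x$sds[[m]]) else "NA"))
  invisible(x)
}

# evaluate fn under a local RNG state, restoring the caller's state after
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
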