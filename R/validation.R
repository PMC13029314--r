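# Validation protocols: internal leave-one-out cross-validation, the
# predefined external split, and repeated random external splits; continuous
# metrics (MAE/RMSE/R^2) plus decision-level accuracy.

#' Continuous regression metrics
#'
#' `mae = mean(|e|)`, `rmse = sqrt(mean(e^2))`,
#' `r2 = 1 - sum(e^2) / sum((y - mean(y))^2)`. When the observed values have
#' zero variance R^2 is undefined; it is reported as 0 with
#' `zero_variance = TRUE` and a warning.
#'
#' @param y_obs Observed values.
#' @param y_pred Predicted values (same length).
#' @return List with `mae`, `rmse`, `r2`, `zero_variance`.
#' @export
regressionMetrics <- function(y_obs, y_pred) {
  if (length(y_obs) == 0 || length(y_obs) != length(y_pred)) {
    stop("y_obs and y_pred must have equal non-zero length", call. = FALSE)
  }
  e <- y_obs - y_pred
  ss_tot <- sum((y_obs - mean(y_obs))^2)
  zero_var <- ss_tot == 0
  if (zero_var) {
    warning("zero variance in observed values; R^2 reported as 0", call. = FALSE)
  }
  list(
    mae = mean(abs(e)),
    rmse = sqrt(mean(e^2)),
    r2 = if (zero_var) 0 else 1 - sum(e^2) / ss_tot,
    zero_variance = zero_var
  )
}

# Assemble a validation report from pooled observed/predicted matrices.
make_report <- function(scheme, obs, pred, names, extra = list()) {
  methods <- evMethods()
  per_method <- lapply(methods, function(m) {
    suppressWarnings(regressionMetrics(obs[, m], pred[, m]))
  })
  names(per_method) <- methods
  obs_opt <- methods[apply(obs, 1L, which.max)]
  pred_opt <- methods[apply(pred, 1L, which.max)]
  correct <- obs_opt == pred_opt
  rep <- c(
    list(
      scheme = scheme,
      per_method = per_method,
      n_correct = sum(correct),
      n_total = length(correct),
      decision_accuracy = mean(correct),
      per_compound = data.frame(
        name = names, observed_optimal = obs_opt,
        predicted_optimal = pred_opt, correct = correct,
        stringsAsFactors = FALSE
      )
    ),
    extra
  )
  structure(rep, class = "ev_validation")
}

#' @export
print.ev_validation <- function(x, ...) {
  cat(sprintf("<ev_validation> scheme = %s\n", x$scheme))
  cat(sprintf("  decision accuracy: %d/%d = %.1f%%\n",
              x$n_correct, x$n_total, 100 * x$decision_accuracy))
  tab <- metricsTable(x)
  tab[, -1] <- round(tab[, -1], 2)
  print(tab, row.names = FALSE)
  if (!is.null(x$rep_accuracy)) {
    cat(sprintf("  repeated splits: mean = %.1f%%, sd = %.1f%% over %d reps\n",
                100 * x$mean_accuracy, 100 * x$sd_accuracy, x$n_reps))
  }
  invisible(x)
}

#' Per-method metrics of a validation report as a table
#' @param report An `ev_validation`.
#' @return Data.frame with columns `method`, `mae`, `rmse`, `r2`.
#' @export
metricsTable <- function(report) {
  data.frame(
    method = methodLabel(names(report$per_method)),
    mae = sapply(report$per_method, `[[`, "mae"),
    rmse = sapply(report$per_method, `[[`, "rmse"),
    r2 = sapply(report$per_method, `[[`, "r2"),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Per-compound decision table of a validation report
#' @param report An `ev_validation`.
#' @return Data.frame with observed and predicted optimal methods.
#' @export
decisionTable <- function(report) {
  out <- report$per_compound
  out$observed_optimal <- methodLabel(out$observed_optimal)
  out$predicted_optimal <- methodLabel(out$predicted_optimal)
  out
}

#' Internal leave-one-out cross-validation
#'
#' For each fold, one compound is held out and the preprocessor and all five
#' models are refit on the remaining compounds; the held-out compound's five
#' efficiencies are then predicted. By default hyperparameters are re-tuned
#' inside every fold (fully nested leave-one-out grid search on the retained
#' compounds), so no statistic of the held-out compound influences
#' preprocessing, tuning, or fitting. Set `cfg$retune_per_fold = FALSE` to
#' tune once per method on the full training set and hold (alpha, lambda)
#' fixed across folds. Held-out predictions are pooled to give one
#' MAE/RMSE/R^2 per method and the decision-level accuracy.
#'
#' @param train An `ev_dataset` (n >= 3) with complete efficiencies.
#' @param cfg An `ev_fit_config`.
#' @return An `ev_validation` report (`scheme = "loocv"`).
#' @export
loocvValidate <- function(train, cfg = fitConfig()) {
  df <- as.data.frame(train)
  n <- nrow(df)
  if (n < 3) stop("need >= 3 compounds for leave-one-out", call. = FALSE)
  methods <- evMethods()
  hyper <- NULL
  if (!cfg$retune_per_fold) {
    hyper <- lapply(stats::setNames(methods, methods), function(m) {
      tuneHyperparameters(train, m, cfg)
    })
  }
  obs <- as.matrix(df[, methods])
  pred <- matrix(NA_real_, n, length(methods), dimnames = list(NULL, methods))
  for (i in seq_len(n)) {
    fold_train <- new_ev_dataset(df[-i, , drop = FALSE])
    ms <- tryCatch(
      fitAllMethods(fold_train, cfg, hyper = hyper),
      error = function(e) stop("fold ", i, " (held out: ", df$name[i], "): ",
                               conditionMessage(e), call. = FALSE)
    )
    pred[i, ] <- predictEfficiencies(ms, df[i, , drop = FALSE])
  }
  make_report("loocv", obs, pred, df$name,
              extra = list(hyper = hyper))
}

#' Predefined external validation
#'
#' Single fit on `train`, prediction of every compound in `external`,
#' continuous metrics and decision accuracy on the external set.
#'
#' @param train Training `ev_dataset`.
#' @param external External `ev_dataset` with observed efficiencies;
#'   must be disjoint from `train`.
#' @param cfg An `ev_fit_config`.
#' @return An `ev_validation` report (`scheme = "external"`) with the fitted
#'   `ev_model_set` attached as `$modelset`.
#' @export
externalValidate <- function(train, external, cfg = fitConfig()) {
  overlap <- intersect(train$name, external$name)
  if (length(overlap) > 0) {
    stop("train and external sets overlap: ", paste(overlap, collapse = ", "),
         call. = FALSE)
  }
  ms <- fitAllMethods(train, cfg)
  methods <- evMethods()
  ext <- as.data.frame(external)
  obs <- as.matrix(ext[, methods])
  pred <- predictEfficiencies(ms, ext)
  make_report("external", obs, pred, ext$name, extra = list(modelset = ms))
}

#' Repeated random external validation
#'
#' Repeats `n_reps` times: draw `test_size` compounds uniformly without
#' replacement as an external set, retrain all five models (with tuning) on
#' the remainder, and record the decision accuracy on the held-out set.
#' Reports per-repetition accuracies with their mean and sample (n-1)
#' standard deviation, plus pooled continuous metrics across all held-out
#' predictions.
#'
#' @param ds An `ev_dataset` with complete efficiencies.
#' @param n_reps Number of random splits (default 50).
#' @param test_size Held-out compounds per split (default 4).
#' @param seed Integer seed for the split generator.
#' @param cfg An `ev_fit_config`.
#' @return An `ev_validation` report (`scheme = "repeated_random"`) with
#'   `rep_accuracy`, `mean_accuracy`, `sd_accuracy`, `n_reps`, `seed`.
#' @export
repeatedRandomValidate <- function(ds, n_reps = 50, test_size = 4,
                                   seed = 1L, cfg = fitConfig()) {
  if (n_reps < 1) stop("n_reps must be >= 1", call. = FALSE)
  df <- as.data.frame(ds)
  n <- nrow(df)
  if (test_size >= n) stop("test_size must be smaller than the dataset", call. = FALSE)
  methods <- evMethods()
  rng <- local({ set.seed(as.integer(seed))
                 replicate(n_reps, sample.int(n, test_size), simplify = FALSE) })
  acc <- numeric(n_reps)
  obs_all <- pred_all <- NULL
  names_all <- character(0)
  for (r in seq_len(n_reps)) {
    idx <- rng[[r]]
    train <- new_ev_dataset(df[-idx, , drop = FALSE])
    test <- df[idx, , drop = FALSE]
    ms <- fitAllMethods(train, cfg)
    pred <- predictEfficiencies(ms, test)
    obs <- as.matrix(test[, methods])
    obs_opt <- methods[apply(obs, 1L, which.max)]
    pred_opt <- methods[apply(pred, 1L, which.max)]
    acc[r] <- mean(obs_opt == pred_opt)
    obs_all <- rbind(obs_all, obs)
    pred_all <- rbind(pred_all, pred)
    names_all <- c(names_all, test$name)
  }
  rep <- make_report("repeated_random", obs_all, pred_all, names_all,
                     extra = list(rep_accuracy = acc,
                                  mean_accuracy = mean(acc),
                                  sd_accuracy = if (n_reps > 1) stats::sd(acc) else 0,
                                  n_reps = n_reps, test_size = test_size,
                                  seed = as.integer(seed),
                                  test_sets = lapply(rng, function(i) df$name[i])))
  # decision accuracy of a repeated-splits report is the mean over splits
  rep$decision_accuracy <- mean(acc)
  rep
}

#' Serialize a validation report to a plain list (for JSON output)
#' @param report An `ev_validation`.
#' @return A list of plain vectors/tables.
#' @export
reportToList <- function(report) {
  out <- list(
    scheme = report$scheme,
    decision_accuracy = report$decision_accuracy,
    n_correct = report$n_correct,
    n_total = report$n_total,
    per_method = lapply(report$per_method, function(m) {
      m[c("mae", "rmse", "r2")]
    }),
    per_compound = report$per_compound
  )
  if (!is.null(report$rep_accuracy)) {
    out$repeated <- list(
      accuracies = report$rep_accuracy, mean = report$mean_accuracy,
      sd = report$sd_accuracy, n_reps = report$n_reps, seed = report$seed
    )
  }
  out
}
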