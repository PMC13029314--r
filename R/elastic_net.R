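# Per-method elastic-net models on standardized descriptors.
#
# The objective minimized is
#   (1/n) * sum_i (y_i - b0 - x_i'b)^2 + lambda * [ alpha*||b||_1 + (1-alpha)*||b||_2^2 ]
# with an unpenalized intercept. glmnet minimizes
#   (1/2n) * RSS + lambda_g * [ alpha_g*||b||_1 + (1-alpha_g)/2 * ||b||_2^2 ],
# so the two parameterizations coincide under the exact mapping
#   alpha_g  = alpha / (2 - alpha)
#   lambda_g = lambda * (1 - alpha/2)
# (divide the first objective by 2 and match term by term). Coefficients are
# identical; only the penalty bookkeeping differs.

#' Fitting configuration for the per-method models
#'
#' @param alpha_grid L1/L2 mixing values searched, each in (0, 1].
#'   Default `c(0.1, 0.3, 0.5, 0.7, 0.9)`.
#' @param lambda_grid Penalty weights searched; default 50 logarithmically
#'   spaced points from 1e-3 to 1e2 (on the scale of the objective above).
#' @param seed Integer seed for any stochastic component (the solver itself
#'   is deterministic; the seed is recorded for provenance and used by
#'   resampling routines that take a config).
#' @param retune_per_fold If `TRUE` (default), leave-one-out validation
#'   re-tunes (alpha, lambda) inside every fold (fully nested tuning: no
#'   statistic of the held-out compound can influence hyperparameter
#'   selection). If `FALSE`, hyperparameters are tuned once on the full
#'   training set and held fixed across folds.
#' @return An object of class `ev_fit_config`.
#' @export
fitConfig <- function(alpha_grid = c(0.1, 0.3, 0.5, 0.7, 0.9),
                      lambda_grid = 10^seq(-3, 2, length.out = 50),
                      seed = 1L,
                      retune_per_fold = TRUE) {
  if (length(alpha_grid) == 0 || length(lambda_grid) == 0) {
    stop("hyperparameter grids must be non-empty", call. = FALSE)
  }
  if (any(alpha_grid <= 0 | alpha_grid > 1)) {
    stop("alpha values must lie in (0, 1]", call. = FALSE)
  }
  if (any(lambda_grid < 0)) stop("lambda values must be >= 0", call. = FALSE)
  structure(
    list(alpha_grid = sort(alpha_grid),
         lambda_grid = sort(lambda_grid),
         seed = as.integer(seed),
         retune_per_fold = isTRUE(retune_per_fold)),
    class = "ev_fit_config"
  )
}

# Map (alpha, lambda) of the package objective onto glmnet's parameters.
glmnet_params <- function(alpha, lambda) {
  list(alpha = alpha / (2 - alpha), lambda = lambda * (1 - alpha / 2))
}

# Fit a glmnet path at the mapped lambda values and return coefficients
# aligned with the requested (ascending or arbitrary) lambda order.
# Returns list(intercepts, coefs [p x nlambda]).
enet_path <- function(Z, y, alpha, lambdas, thresh = 1e-18) {
  if (!all(is.finite(Z)) || !all(is.finite(y))) {
    stop("non-finite values in design or response", call. = FALSE)
  }
  if (stats::var(y) == 0) {
    p <- ncol(Z)
    return(list(intercepts = rep(y[1], length(lambdas)),
                coefs = matrix(0, p, length(lambdas))))
  }
  map <- glmnet_params(alpha, lambdas)
  ord <- order(map$lambda, decreasing = TRUE)
  lam_desc <- map$lambda[ord]
  # glmnet needs a strictly decreasing path; pad a 0-lambda target with a
  # short descending approach for warm starts.
  pad <- numeric(0)
  if (lam_desc[1] <= 0) {
    lmax <- max(abs(crossprod(Z, y - mean(y)))) / nrow(Z)
    pad <- lmax * 10^seq(0, -3, length.out = 8)
  }
  fit <- glmnet::glmnet(Z, y, family = "gaussian", alpha = map$alpha,
                        lambda = c(pad, lam_desc), standardize = FALSE,
                        intercept = TRUE, thresh = thresh, maxit = 1e7)
  keep <- (length(pad) + 1):(length(pad) + length(lam_desc))
  b0 <- fit$a0[keep]
  B <- as.matrix(fit$beta)[, keep, drop = FALSE]
  inv <- order(ord)
  list(intercepts = unname(b0[inv]), coefs = unname(B[, inv, drop = FALSE]))
}

#' Fit one elastic-net model at fixed hyperparameters
#'
#' Minimizes `(1/n) * RSS + lambda * (alpha*||b||_1 + (1-alpha)*||b||_2^2)`
#' with an unpenalized intercept, on an already-standardized design matrix.
#' With column-centered predictors the fitted intercept equals `mean(y)` for
#' every (alpha, lambda); at `lambda = 0` the fit is ordinary least squares.
#'
#' @param Z Numeric n x p matrix of standardized descriptors (columns
#'   centered).
#' @param y Numeric response vector (loading efficiencies, %).
#' @param alpha Mixing parameter in (0, 1].
#' @param lambda Penalty weight >= 0.
#' @param method Optional method name stored on the model.
#' @return An object of class `ev_enet` with fields `method`, `intercept`,
#'   `coefficients` (length-p named vector), `alpha`, `lambda`.
#' @export
fitElasticNet <- function(Z, y, alpha, lambda, method = NA_character_) {
  if (nrow(Z) < 2) stop("need at least 2 observations", call. = FALSE)
  if (length(y) != nrow(Z)) stop("length(y) must equal nrow(Z)", call. = FALSE)
  path <- enet_path(Z, y, alpha, lambda)
  co <- drop(path$coefs[, 1])
  names(co) <- colnames(Z)
  if (!all(is.finite(co))) {
    stop("solver returned non-finite coefficients (alpha=", alpha,
         ", lambda=", lambda, ")", call. = FALSE)
  }
  structure(
    list(method = method, intercept = unname(path$intercepts[1]),
         coefficients = co, alpha = alpha, lambda = lambda),
    class = "ev_enet"
  )
}

#' @export
print.ev_enet <- function(x, ...) {
  cat(sprintf("<ev_enet> %s: alpha=%.2g lambda=%.4g\n",
              ifelse(is.na(x$method), "(unnamed)", x$method),
              x$alpha, x$lambda))
  cat(formatEquation(x), "\n")
  invisible(x)
}

#' Tune (alpha, lambda) by leave-one-out cross-validation
#'
#' Grid search over `cfg$alpha_grid` x `cfg$lambda_grid` minimizing mean
#' squared leave-one-out error for one loading method. The preprocessor is
#' refit on each fold's retained compounds, so no held-out statistic enters
#' standardization. Ties (within relative 1e-12) are broken toward larger
#' lambda, then smaller alpha — the more regularized model on equal fit.
#'
#' @param train An `ev_dataset` with the method's efficiency column.
#' @param method One of [evMethods()].
#' @param cfg An `ev_fit_config`.
#' @return List with `alpha`, `lambda`, `cv_mse` (the winning mean LOO MSE),
#'   and `mse_grid` (matrix alpha x lambda).
#' @export
tuneHyperparameters <- function(train, method, cfg = fitConfig()) {
  stopifnot(inherits(cfg, "ev_fit_config"))
  if (!method %in% names(train)) {
    stop("efficiency column '", method, "' absent from training data",
         call. = FALSE)
  }
  df <- as.data.frame(train)
  df <- df[!is.na(df[[method]]), , drop = FALSE]
  n <- nrow(df)
  if (n < 3) stop("need >= 3 records with '", method, "' efficiency", call. = FALSE)
  a_grid <- cfg$alpha_grid
  l_grid <- cfg$lambda_grid
  sqerr <- array(NA_real_, dim = c(n, length(a_grid), length(l_grid)))
  for (i in seq_len(n)) {
    tr <- df[-i, , drop = FALSE]
    params <- fitPreprocessor(tr)
    Z_tr <- transformDescriptors(params, tr)
    z_te <- transformDescriptors(params, df[i, , drop = FALSE])
    y_tr <- tr[[method]]
    for (a in seq_along(a_grid)) {
      path <- enet_path(Z_tr, y_tr, a_grid[a], l_grid, thresh = 1e-9)
      pred <- path$intercepts + drop(z_te %*% path$coefs)
      sqerr[i, a, ] <- (pred - df[[method]][i])^2
    }
  }
  mse <- apply(sqerr, c(2L, 3L), mean)
  best <- min(mse)
  cand <- which(mse <= best * (1 + 1e-12), arr.ind = TRUE)
  # larger lambda first, then smaller alpha
  cand <- cand[order(-l_grid[cand[, 2]], a_grid[cand[, 1]]), , drop = FALSE]
  pick <- cand[1, ]
  list(alpha = a_grid[pick[1]], lambda = l_grid[pick[2]],
       cv_mse = mse[pick[1], pick[2]],
       mse_grid = matrix(mse, length(a_grid), length(l_grid),
                         dimnames = list(alpha = signif(a_grid, 3),
                                         lambda = signif(l_grid, 4))))
}

#' Fit all five per-method models on a training set
#'
#' Fits one elastic-net model per loading method: hyperparameters are tuned
#' independently per method by leave-one-out grid search, then each model is
#' refit on the full training set with a preprocessor shared across methods.
#'
#' @param train An `ev_dataset` with all five efficiency columns.
#' @param cfg An `ev_fit_config`.
#' @param hyper Optional named list `method -> list(alpha, lambda)` to skip
#'   tuning (used when hyperparameters are held fixed across folds).
#' @return An object of class `ev_model_set`: fields `preprocess`,
#'   `models` (named list of `ev_enet`), `config`, `n_train`.
#' @export
fitAllMethods <- function(train, cfg = fitConfig(), hyper = NULL) {
  methods <- evMethods()
  miss <- setdiff(methods, names(train))
  if (length(miss) > 0) {
    stop("missing efficiency column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  params <- fitPreprocessor(train)
  Z <- transformDescriptors(params, train)
  models <- stats::setNames(vector("list", length(methods)), methods)
  for (m in methods) {
    hp <- if (!is.null(hyper)) hyper[[m]] else tuneHyperparameters(train, m, cfg)
    models[[m]] <- fitElasticNet(Z, as.data.frame(train)[[m]],
                                 hp$alpha, hp$lambda, method = m)
  }
  structure(
    list(preprocess = params, models = models, config = cfg,
         n_train = nrow(train)),
    class = "ev_model_set"
  )
}

#' @export
print.ev_model_set <- function(x, ...) {
  cat(sprintf("<ev_model_set> 5 loading-method models, n_train = %d\n", x$n_train))
  for (m in names(x$models)) cat(" ", formatEquation(x$models[[m]]), "\n")
  invisible(x)
}

#' Export the fitted equations as a table
#'
#' One row per loading method: intercept, the seven standardized
#' coefficients, and the tuned hyperparameters, at full precision (round for
#' display as needed).
#'
#' @param modelset An `ev_model_set`.
#' @return A data.frame with columns `method`, `intercept`, one column per
#'   descriptor, `alpha`, `lambda`.
#' @export
exportEquations <- function(modelset) {
  stopifnot(inherits(modelset, "ev_model_set"))
  rows <- lapply(modelset$models, function(m) {
    data.frame(method = m$method, intercept = m$intercept,
               as.list(m$coefficients), alpha = m$alpha, lambda = m$lambda,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Render one model as a human-readable equation
#' @param model An `ev_enet`.
#' @param digits Display digits (default 2).
#' @return A single string like `"LE_passive = 60.33 + 7.74*z_logp + ..."`.
#' @export
formatEquation <- function(model, digits = 2) {
  co <- model$coefficients
  keep <- which(abs(co) > 0)
  lhs <- sprintf("LE_%s = %.*f", ifelse(is.na(model$method), "y", model$method),
                 digits, model$intercept)
  if (length(keep) == 0) return(lhs)
  terms <- sprintf("%s %.*f*z_%s", ifelse(co[keep] < 0, "-", "+"),
                   digits, abs(co[keep]), names(co)[keep])
  paste(lhs, paste(terms, collapse = " "))
}
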