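# Leverage-based applicability domain.
#
# Leverage of a (standardized, intercept-augmented) descriptor vector x0 is
# h = x0' (X'X)^{-1} x0, the prediction-point diagonal of the hat matrix
# H = X (X'X)^{-1} X'. The warning threshold is h* = 3(p+1)/n. Note that
# with n = 21 and p = 7, h* = 24/21 > 1 while every training leverage is
# <= 1: with this sample size the threshold can only ever flag *new*
# compounds, never rows of the training set itself.

#' Build an applicability-domain model from a standardized training design
#'
#' Augments the n x 7 standardized descriptor matrix with an intercept
#' column, checks full column rank, and stores the inverse Gram matrix
#' together with the threshold `h_star = 3(p+1)/n`.
#'
#' @param train_Z Numeric n x p matrix of standardized training descriptors
#'   (from [transformDescriptors()] with the same preprocessor the models
#'   use); requires `n > p + 1`.
#' @return An object of class `ev_domain` with fields `xtx_inv`, `h_star`,
#'   `n`, `p`, `train_leverage`.
#' @export
buildDomain <- function(train_Z) {
  train_Z <- as.matrix(train_Z)
  n <- nrow(train_Z)
  p <- ncol(train_Z)
  if (n <= p + 1) stop("need n > p + 1 training compounds", call. = FALSE)
  X <- cbind(intercept = 1, train_Z)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  xtx_inv <- chol2inv(qr.R(qx))
  dm <- structure(
    list(xtx_inv = xtx_inv, h_star = 3 * (p + 1) / n, n = n, p = p),
    class = "ev_domain"
  )
  dm$train_leverage <- leverage(dm, train_Z)
  dm
}

#' @export
print.ev_domain <- function(x, ...) {
  cat(sprintf("<ev_domain> n = %d, p = %d, h* = 3(p+1)/n = %.3f\n",
              x$n, x$p, x$h_star))
  cat(sprintf("  training leverages: [%.3f, %.3f], sum = %.3f\n",
              min(x$train_leverage), max(x$train_leverage),
              sum(x$train_leverage)))
  invisible(x)
}

#' Leverage of standardized descriptor vectors
#'
#' For each row z, computes `h = (1, z)' (X'X)^{-1} (1, z)`. For a training
#' row this equals the corresponding diagonal element of the hat matrix; for
#' a compound at the training descriptor means (z = 0 under a training-set
#' standardization) it equals `1/n` exactly.
#'
#' @param dm An `ev_domain`.
#' @param Z Numeric matrix (or single vector) of standardized descriptors,
#'   standardized with the same preprocessor as the training design.
#' @return Numeric vector of leverages.
#' @export
leverage <- function(dm, Z) {
  stopifnot(inherits(dm, "ev_domain"))
  if (is.null(dim(Z))) Z <- matrix(Z, nrow = 1)
  if (ncol(Z) != dm$p) {
    stop("descriptor dimension mismatch: expected ", dm$p, ", got ", ncol(Z),
         call. = FALSE)
  }
  X0 <- cbind(1, as.matrix(Z))
  h <- rowSums((X0 %*% dm$xtx_inv) * X0)
  stats::setNames(h, rownames(Z))
}

#' Assess applicability-domain membership for a set of compounds
#'
#' A compound is in-domain when its leverage does not exceed `h_star`
#' (boundary value counts as in-domain). Predictions for out-of-domain
#' compounds should be interpreted with caution: their descriptors lie
#' outside the chemical space covered by the training set.
#'
#' @param dm An `ev_domain`.
#' @param modelset_or_params An `ev_model_set` or `ev_preprocess` providing
#'   the standardization under which `dm` was built.
#' @param data Compound table with descriptor columns (may be empty).
#' @return A data.frame with columns `name`, `leverage`, `h_star`,
#'   `in_domain`.
#' @export
assessDomain <- function(dm, modelset_or_params, data) {
  params <- if (inherits(modelset_or_params, "ev_model_set")) {
    modelset_or_params$preprocess
  } else modelset_or_params
  stopifnot(inherits(params, "ev_preprocess"))
  if (nrow(as.data.frame(data)) == 0) {
    return(data.frame(name = character(0), leverage = numeric(0),
                      h_star = numeric(0), in_domain = logical(0)))
  }
  Z <- transformDescriptors(params, data)
  h <- leverage(dm, Z)
  data.frame(
    name = if ("name" %in% names(data)) as.character(data$name) else
      paste0("compound_", seq_along(h)),
    leverage = unname(h), h_star = dm$h_star, in_domain = unname(h) <= dm$h_star,
    stringsAsFactors = FALSE
  )
}
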