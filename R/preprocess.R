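# Leakage-free preprocessing: training-set median imputation followed by
# z-score standardization, z_j = (x_j - mu_j) / sigma_j.

#' Fit imputation and standardization parameters on a training set
#'
#' Computes, per descriptor: the median of the observed (non-missing)
#' training values (used to impute missing cells), then the mean and standard
#' deviation of the imputed training column. The standard deviation uses the
#' population convention (divide by n); the convention is immaterial to the
#' model's intercept/coefficient structure but is pinned so coefficients are
#' reproducible. Parameters are an explicit object passed to every transform,
#' so held-out data can never leak into them.
#'
#' @param train An `ev_dataset` (>= 2 rows) with all descriptor columns.
#' @return An object of class `ev_preprocess` with fields `descriptors`,
#'   `medians`, `means`, `sds`.
#' @export
fitPreprocessor <- function(train) {
  desc <- evDescriptors()
  miss <- setdiff(desc, names(train))
  if (length(miss) > 0) {
    stop("missing descriptor column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(train) < 2) stop("need at least 2 training records", call. = FALSE)
  X <- as.matrix(as.data.frame(train)[, desc, drop = FALSE])
  medians <- apply(X, 2L, function(v) {
    obs <- v[!is.na(v)]
    if (length(obs) == 0) stop("descriptor entirely missing in training set",
                               call. = FALSE)
    stats::median(obs)
  })
  for (j in seq_along(desc)) X[is.na(X[, j]), j] <- medians[j]
  means <- colMeans(X)
  sds <- sqrt(colMeans(sweep(X, 2L, means)^2))  # population SD
  zero <- sds <= .Machine$double.eps * 100
  if (any(zero)) {
    stop("zero-variance descriptor(s) in training set: ",
         paste(desc[zero], collapse = ", "), call. = FALSE)
  }
  structure(
    list(descriptors = desc, medians = medians, means = means, sds = sds),
    class = "ev_preprocess"
  )
}

#' @export
print.ev_preprocess <- function(x, ...) {
  cat("<ev_preprocess> median-impute + z-score, 7 descriptors\n")
  print(round(rbind(median = x$medians, mean = x$means, sd = x$sds), 4))
  invisible(x)
}

#' Standardize descriptors with fitted parameters
#'
#' Missing descriptor cells are replaced by the training medians, then each
#' descriptor is z-scored with the training mean and SD.
#'
#' @param params An `ev_preprocess` from [fitPreprocessor()].
#' @param data An `ev_dataset` or data.frame with the descriptor columns.
#' @return Numeric matrix (n x 7) of standardized descriptors, with row
#'   names taken from `data$name` when present.
#' @export
transformDescriptors <- function(params, data) {
  stopifnot(inherits(params, "ev_preprocess"))
  desc <- params$descriptors
  miss <- setdiff(desc, names(data))
  if (length(miss) > 0) {
    stop("missing descriptor column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  X <- as.matrix(as.data.frame(data)[, desc, drop = FALSE])
  if (nrow(X) > 0 && all(is.na(X[1, ])) && nrow(X) == 1) {
    stop("record has no descriptor values at all", call. = FALSE)
  }
  for (j in seq_along(desc)) X[is.na(X[, j]), j] <- params$medians[j]
  Z <- sweep(sweep(X, 2L, params$means), 2L, params$sds, "/")
  if (!all(is.finite(Z))) stop("non-finite standardized descriptor", call. = FALSE)
  if ("name" %in% names(data)) rownames(Z) <- as.character(data$name)
  Z
}

#' Invert the standardization for complete records
#'
#' @param params An `ev_preprocess`.
#' @param Z A standardized descriptor matrix.
#' @return Matrix on the original descriptor scales.
#' @export
inverseTransform <- function(params, Z) {
  stopifnot(inherits(params, "ev_preprocess"))
  sweep(sweep(Z, 2L, params$sds, "*"), 2L, params$means, "+")
}

#' Serialize preprocessing parameters to a plain list
#' @param params An `ev_preprocess`.
#' @return A list suitable for JSON/YAML serialization.
#' @export
preprocessToList <- function(params) {
  list(
    descriptors = params$descriptors,
    medians = as.list(params$medians),
    means = as.list(params$means),
    sds = as.list(params$sds)
  )
}

#' Rebuild preprocessing parameters from a serialized list
#' @param x A list produced by [preprocessToList()].
#' @return An `ev_preprocess`.
#' @export
preprocessFromList <- function(x) {
  desc <- unlist(x$descriptors)
  structure(
    list(
      descriptors = desc,
      medians = stats::setNames(unlist(x$medians), desc),
      means = stats::setNames(unlist(x$means), desc),
      sds = stats::setNames(unlist(x$sds), desc)
    ),
    class = "ev_preprocess"
  )
}
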