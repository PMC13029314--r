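# Portable trained-model bundles: preprocessor + five models + fit config +
# applicability domain + provenance, as a single JSON document.

dataset_hash <- function(ds) {
  tmp <- tempfile(fileext = ".csv")
  on.exit(unlink(tmp))
  writeCompounds(ds, tmp)
  unname(tools::md5sum(tmp))
}

#' Serialize a trained model set (plus applicability domain) to JSON
#'
#' The bundle holds everything needed to reproduce predictions: fitted
#' preprocessing parameters, the five per-method models with their tuned
#' hyperparameters, the fitting configuration, the applicability-domain
#' Gram inverse and threshold, and provenance (training-set hash, seed).
#' Identical inputs produce byte-identical bundles.
#'
#' @param modelset An `ev_model_set`.
#' @param path Output path for the JSON file.
#' @param domain Optional `ev_domain` built on the same training design.
#' @param train Optional training `ev_dataset`, hashed into provenance.
#' @return `path`, invisibly.
#' @export
writeBundle <- function(modelset, path, domain = NULL, train = NULL) {
  stopifnot(inherits(modelset, "ev_model_set"))
  bundle <- list(
    format = "evloadr-bundle",
    version = 1L,
    preprocess = preprocessToList(modelset$preprocess),
    models = lapply(modelset$models, function(m) {
      list(method = m$method, intercept = m$intercept,
           coefficients = as.list(m$coefficients),
           alpha = m$alpha, lambda = m$lambda)
    }),
    config = list(alpha_grid = modelset$config$alpha_grid,
                  lambda_grid = modelset$config$lambda_grid,
                  seed = modelset$config$seed,
                  retune_per_fold = modelset$config$retune_per_fold),
    n_train = modelset$n_train
  )
  if (!is.null(domain)) {
    bundle$domain <- list(xtx_inv = domain$xtx_inv, h_star = domain$h_star,
                          n = domain$n, p = domain$p,
                          train_leverage = as.numeric(domain$train_leverage))
  }
  if (!is.null(train)) bundle$provenance <- list(dataset_md5 = dataset_hash(train))
  json <- jsonlite::toJSON(bundle, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(json, path)
  invisible(path)
}

#' Load a trained model bundle from JSON
#'
#' @param path Path to a bundle written by [writeBundle()].
#' @return A list with `modelset` (`ev_model_set`) and `domain`
#'   (`ev_domain` or `NULL`).
#' @export
readBundle <- function(path) {
  if (!file.exists(path)) stop("bundle not found: ", path, call. = FALSE)
  b <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!identical(b$format, "evloadr-bundle")) {
    stop("not an evloadr model bundle: ", path, call. = FALSE)
  }
  params <- preprocessFromList(b$preprocess)
  models <- lapply(b$models, function(m) {
    structure(
      list(method = m$method, intercept = m$intercept,
           coefficients = stats::setNames(unlist(m$coefficients),
                                          names(m$coefficients)),
           alpha = m$alpha, lambda = m$lambda),
      class = "ev_enet"
    )
  })
  cfg <- fitConfig(alpha_grid = b$config$alpha_grid,
                   lambda_grid = b$config$lambda_grid,
                   seed = b$config$seed,
                   retune_per_fold = isTRUE(b$config$retune_per_fold))
  modelset <- structure(
    list(preprocess = params, models = models, config = cfg,
         n_train = b$n_train),
    class = "ev_model_set"
  )
  domain <- NULL
  if (!is.null(b$domain)) {
    domain <- structure(
      list(xtx_inv = as.matrix(b$domain$xtx_inv), h_star = b$domain$h_star,
           n = b$domain$n, p = b$domain$p,
           train_leverage = b$domain$train_leverage),
      class = "ev_domain"
    )
  }
  list(modelset = modelset, domain = domain)
}
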