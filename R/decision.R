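# Decision engine: per-method efficiency prediction and argmax
# recommendation of the loading method.

#' Predict loading efficiencies for all five methods
#'
#' Applies the fitted models' own preprocessor (median imputation +
#' z-scoring) and evaluates `y_m = b0_m + sum_j b_{j,m} z_j` per method.
#' Predictions are returned unclipped: a linear model can leave \[0, 100\],
#' and clipping before ranking is never applied.
#'
#' @param modelset An `ev_model_set`.
#' @param data An `ev_dataset` / data.frame with descriptor columns.
#' @return Numeric matrix (n x 5), columns in canonical method order, row
#'   names from `data$name` when present.
#' @export
predictEfficiencies <- function(modelset, data) {
  stopifnot(inherits(modelset, "ev_model_set"))
  Z <- transformDescriptors(modelset$preprocess, data)
  methods <- evMethods()
  out <- sapply(methods, function(m) {
    mod <- modelset$models[[m]]
    mod$intercept + drop(Z %*% mod$coefficients)
  })
  if (is.null(dim(out))) out <- matrix(out, nrow = 1, dimnames = list(rownames(Z), methods))
  if (!all(is.finite(out))) stop("non-finite prediction", call. = FALSE)
  out
}

#' Recommend a loading method from predicted efficiencies
#'
#' The recommended method is the argmax of the five predicted efficiencies;
#' ties are broken by canonical method order. The full descending ranking is
#' retained. Ranking is independent of the order in which predictions are
#' supplied: they are realigned to canonical order by name first.
#'
#' @param predicted Named numeric vector of five predictions (names from
#'   [evMethods()], any order), or a 1 x 5 matrix row.
#' @return List of class `ev_recommendation`: `predicted` (canonical order),
#'   `ranking` (methods by descending prediction), `recommended`.
#' @export
recommend <- function(predicted) {
  methods <- evMethods()
  p <- drop(predicted)
  if (is.null(names(p)) && length(p) == 5) names(p) <- methods
  miss <- setdiff(methods, names(p))
  if (length(miss) > 0) {
    stop("missing prediction(s) for: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  p <- p[methods]
  if (!all(is.finite(p))) stop("non-finite prediction", call. = FALSE)
  # stable sort: canonical position is the tie-break
  ord <- order(-p, seq_along(p))
  structure(
    list(predicted = p, ranking = methods[ord], recommended = methods[ord][1]),
    class = "ev_recommendation"
  )
}

#' @export
print.ev_recommendation <- function(x, ...) {
  cat("<ev_recommendation>", methodLabel(x$recommended), "\n")
  cat("  ranking:", paste(sprintf("%s (%.1f%%)", methodLabel(x$ranking),
                                  x$predicted[x$ranking]), collapse = " > "), "\n")
  invisible(x)
}

#' Predicted-optimal method for each row of a dataset
#'
#' Convenience wrapper: [predictEfficiencies()] followed by the argmax rule
#' per compound.
#'
#' @inheritParams predictEfficiencies
#' @return Character vector of recommended methods, one per row.
#' @export
predictedOptimal <- function(modelset, data) {
  pred <- predictEfficiencies(modelset, data)
  apply(pred, 1L, function(p) recommend(p)$recommended)
}

#' Full recommendation table for a set of compounds
#'
#' Per compound: the five predicted efficiencies, the recommended method,
#' and (when a domain model is supplied) the leverage and in-domain flag.
#' Out-of-domain compounds are reported with a caution note: their
#' descriptors lie outside the chemical space the models were trained on.
#'
#' @param modelset An `ev_model_set`.
#' @param data Compound table with descriptors.
#' @param domain Optional `ev_domain` from [buildDomain()].
#' @param clip If `TRUE`, clip *displayed* predictions to \[0, 100\]
#'   (ranking always uses unclipped values). Default `FALSE`.
#' @return A data.frame with one row per compound.
#' @export
recommendTable <- function(modelset, data, domain = NULL, clip = FALSE) {
  pred <- predictEfficiencies(modelset, data)
  rec <- apply(pred, 1L, function(p) recommend(p)$recommended)
  shown <- if (clip) pmin(pmax(pred, 0), 100) else pred
  out <- data.frame(
    name = if ("name" %in% names(data)) as.character(data$name) else
      paste0("compound_", seq_len(nrow(shown))),
    shown, recommended = rec,
    stringsAsFactors = FALSE, check.names = FALSE
  )
  if (!is.null(domain)) {
    Z <- transformDescriptors(modelset$preprocess, data)
    h <- leverage(domain, Z)
    out$leverage <- h
    out$in_domain <- h <= domain$h_star
  }
  rownames(out) <- NULL
  out
}
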