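# Compound tables: constructors, the embedded reference dataset, CSV IO,
# and the predefined train/external split.

#' Canonical loading-method order
#'
#' The five EV loading methods in their canonical order. This order is fixed
#' package-wide: it is the deterministic tie-break whenever two methods have
#' equal (predicted or measured) loading efficiency.
#'
#' @return Character vector of length 5.
#' @export
evMethods <- function() {
  c("passive", "electroporation", "saponin", "freeze_thaw", "sonication")
}

#' Descriptor names in canonical order
#'
#' The seven physicochemical descriptors used by all models:
#' LogP (octanol-water partition coefficient, dimensionless), molecular
#' weight (g/mol), aqueous solubility (ug/mL), hydrogen-bond donor and
#' acceptor counts, polar surface area (A^2) and formal charge at pH 7.4.
#'
#' @return Character vector of length 7.
#' @export
evDescriptors <- function() {
  c("logp", "mw", "solubility", "hbd", "hba", "psa", "charge")
}

#' Pretty display names for loading methods
#' @param methods Character vector of canonical method identifiers.
#' @return Character vector of display labels.
#' @export
methodLabel <- function(methods) {
  labels <- c(
    passive = "Passive Incubation", electroporation = "Electroporation",
    saponin = "Saponin", freeze_thaw = "Freeze-Thaw", sonication = "Sonication"
  )
  unname(labels[methods])
}

new_ev_dataset <- function(df) {
  stopifnot(is.data.frame(df))
  class(df) <- c("ev_dataset", "data.frame")
  df
}

#' Validate a compound dataset
#'
#' Checks the structural invariants of a compound table: unique non-empty
#' names, integer-valued non-negative HBD/HBA counts, integer charge, and
#' every present loading efficiency within \[0, 100\]. Missing descriptor
#' values are permitted (they are median-imputed at fit/predict time);
#' out-of-range efficiencies are an error.
#'
#' @param ds An `ev_dataset` (or plain data.frame with the same columns).
#' @return `ds`, invisibly, on success; otherwise an error.
#' @export
validateDataset <- function(ds) {
  desc <- evDescriptors()
  missing_cols <- setdiff(c("name", desc), names(ds))
  if (length(missing_cols) > 0) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(ds) == 0) stop("dataset has no rows", call. = FALSE)
  nm <- as.character(ds$name)
  if (any(is.na(nm) | !nzchar(nm))) stop("compound names must be non-empty", call. = FALSE)
  if (anyDuplicated(nm)) {
    stop("duplicate compound name(s): ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)
  }
  for (col in c("hbd", "hba", "charge")) {
    v <- ds[[col]]
    ok <- is.na(v) | abs(v - round(v)) < 1e-8
    if (!all(ok)) stop("column '", col, "' must be integer-valued", call. = FALSE)
  }
  for (col in c("hbd", "hba")) {
    v <- ds[[col]]
    if (any(!is.na(v) & v < 0)) stop("column '", col, "' must be non-negative", call. = FALSE)
  }
  for (m in intersect(evMethods(), names(ds))) {
    v <- ds[[m]]
    bad <- !is.na(v) & (v < 0 | v > 100)
    if (any(bad)) {
      stop("loading efficiency out of [0, 100] for method '", m, "' (compound ",
           paste(nm[bad], collapse = ", "), ")", call. = FALSE)
    }
  }
  invisible(ds)
}

#' @export
print.ev_dataset <- function(x, ...) {
  eff <- intersect(evMethods(), names(x))
  cat(sprintf("<ev_dataset> %d compounds, %d descriptor columns, %d efficiency columns\n",
              nrow(x), length(intersect(evDescriptors(), names(x))), length(eff)))
  print.data.frame(utils::head(as.data.frame(x), 6), row.names = FALSE)
  if (nrow(x) > 6) cat(sprintf("... and %d more rows\n", nrow(x) - 6))
  invisible(x)
}

#' The embedded 21-compound reference dataset
#'
#' Twenty-one structurally diverse small-molecule drugs with seven
#' physicochemical descriptors and experimentally determined loading
#' efficiencies (%) for all five EV loading methods. Four compounds
#' (Sildenafil, Caffeine, Ampicillin, Furosemide) carry `external = TRUE`:
#' they form the predefined external validation set. The `bcs` column is
#' opaque metadata (Biopharmaceutics Classification System annotation) and
#' is never used in any computation.
#'
#' @return An `ev_dataset` with 21 rows and columns `name`, `bcs`, the seven
#'   descriptors, the five efficiency columns, and `external`.
#' @export
evCompounds <- function() {
  df <- data.frame(
    name = c("Doxorubicin", "Paclitaxel", "Cisplatin", "Gemcitabine",
             "Docetaxel", "Methotrexate", "Riboflavin", "Ampicillin",
             "Furosemide", "Warfarin", "Digoxin", "Chloroquine", "Irinotecan",
             "5-Fluorouracil", "Caffeine", "Quercetin", "Resveratrol",
             "Sildenafil", "Curcumin", "Pirarubicin", "Tamoxifen"),
    bcs = c("NC(IV-only)", "NC(no FDA oral IR)", "NC(IV-only)", "NC(IV-only)",
            "NC(IV-only)", "IV", "III", "III", "IV", "II",
            "NC (conflicting II/III; NTI)", "I",
            "NC (primarily IV; insufficient FDA BCS)",
            "III/NC (limited oral IR context)", "I",
            "NC (not approved as drug)", "NC (not approved as drug)", "II",
            "NC (not approved as drug)", "NC (IV-only)", "II"),
    logp = c(1.27, 3.97, -2.50, -1.20, 4.10, -1.85, -0.60, 0.87, 2.03, 2.92,
             1.26, 3.81, 3.27, -0.89, 0.16, 1.83, 3.05, 2.71, 3.97, 1.34, 4.30),
    mw = c(543.5, 853.9, 300.0, 263.2, 861.9, 454.4, 376.4, 349.4, 330.7,
           308.3, 780.9, 319.9, 586.7, 130.1, 194.2, 302.2, 228.2, 474.6,
           368.4, 557.5, 371.4),
    solubility = c(50, 0.3, 3.5, 100, 0.1, 0.3, 1.2, 1.0, 0.5, 0.14, 0.05,
                   0.7, 0.2, 12.2, 21.5, 0.003, 0.3, 3.5, 0.003, 45, 0.01),
    hbd = c(4, 2, 0, 3, 2, 4, 5, 3, 2, 1, 5, 2, 2, 2, 0, 5, 3, 2, 2, 4, 1),
    hba = c(8, 11, 2, 5, 11, 9, 8, 8, 5, 4, 12, 4, 9, 3, 3, 7, 3, 6, 4, 8, 2),
    psa = c(124, 97, 0, 95, 98, 168, 149, 115, 99, 49, 206, 47, 106, 66, 58,
            131, 60, 87, 93, 126, 39),
    charge = c(1, 0, 0, 0, 0, -2, 0, -1, -1, 0, 0, 1, 0, 0, 0, 0, 0, 0, 0, 1, 0),
    passive = c(72, 75, 65, 68, 77, 5, 8, 3, 70, 72, 65, 68, 71, 55, 52, 69,
                73, 74, 76, 70, 79),
    electroporation = c(8, 2, 7, 9, 1.5, 52, 48, 55, 5, 3, 18, 8, 5, 10, 11,
                        4, 6, 4, 2, 9, 1),
    saponin = c(18, 25, 12, 22, 28, 68, 71, 74, 20, 18, 35, 22, 24, 15, 14,
                19, 21, 20, 26, 19, 15),
    freeze_thaw = c(15, 12, 18, 22, 10, 32, 38, 35, 8, 9, 40, 14, 11, 19, 21,
                    12, 13, 10, 9, 16, 7),
    sonication = c(4, 8, 6, 7, 6, 45, 48, 51, 15, 11, 38, 18, 13, 9, 11, 14,
                   16, 12, 7, 5, 5),
    stringsAsFactors = FALSE
  )
  df$external <- df$name %in% externalCompoundNames()
  validateDataset(new_ev_dataset(df))
  new_ev_dataset(df)
}

#' Names of the predefined external-validation compounds
#' @return Character vector of length 4.
#' @export
externalCompoundNames <- function() {
  c("Sildenafil", "Caffeine", "Ampicillin", "Furosemide")
}

#' Read a compound table from CSV
#'
#' Reads a comma-separated UTF-8 table with a header row. Column names may be
#' remapped through `schema`, a named character vector mapping canonical
#' identifiers (`name`, `logp`, `mw`, `solubility`, `hbd`, `hba`, `psa`,
#' `charge`, and optionally the five method names) to the column names used
#' in the file. Efficiency columns are optional, so prediction-only tables
#' are accepted; missing descriptor cells are allowed and flagged for
#' imputation downstream.
#'
#' @param path Path to a CSV file.
#' @param schema Optional named character vector `canonical = file_column`.
#' @return An `ev_dataset`.
#' @export
readCompounds <- function(path, schema = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                    fileEncoding = "UTF-8"),
    error = function(e) stop("cannot parse CSV '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (ncol(df) == 0 || nrow(df) == 0) {
    stop("empty or header-only CSV: ", path, call. = FALSE)
  }
  if (!is.null(schema)) {
    for (canon in names(schema)) {
      src <- schema[[canon]]
      if (!src %in% names(df)) {
        stop("schema column '", src, "' (for '", canon, "') not found in file",
             call. = FALSE)
      }
      names(df)[names(df) == src] <- canon
    }
  }
  keep <- intersect(c("name", "bcs", evDescriptors(), evMethods(), "external"),
                    names(df))
  df <- df[, keep, drop = FALSE]
  if ("external" %in% names(df)) df$external <- as.logical(df$external)
  for (col in intersect(c(evDescriptors(), evMethods()), names(df))) {
    df[[col]] <- as.numeric(df[[col]])
  }
  ds <- new_ev_dataset(df)
  validateDataset(ds)
  ds
}

#' Write a compound table to CSV
#'
#' Inverse of [readCompounds()]: writes the canonical column layout so that a
#' round trip reproduces the dataset exactly, byte-identically across runs.
#'
#' @param ds An `ev_dataset`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeCompounds <- function(ds, path) {
  utils::write.csv(as.data.frame(ds), path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Split the reference dataset into the predefined training and external sets
#'
#' Partitions a dataset into the 17-compound training set and the predefined
#' 4-compound external validation set (Sildenafil, Caffeine, Ampicillin,
#' Furosemide), preserving row order.
#'
#' @param ds An `ev_dataset` containing all four external compounds.
#' @return A list with elements `train` and `external`, both `ev_dataset`s.
#' @export
splitPredefined <- function(ds) {
  ext_names <- externalCompoundNames()
  absent <- setdiff(ext_names, ds$name)
  if (length(absent) > 0) {
    stop("predefined external compound(s) absent from dataset: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  is_ext <- ds$name %in% ext_names
  list(
    train = new_ev_dataset(as.data.frame(ds)[!is_ext, , drop = FALSE]),
    external = new_ev_dataset(as.data.frame(ds)[is_ext, , drop = FALSE])
  )
}

#' Observed-optimal loading method of a compound
#'
#' The experimentally optimal method: the technique with the highest measured
#' loading efficiency. Ties are broken by canonical method order.
#'
#' @param rec A one-row `ev_dataset` / data.frame, or a dataset with several
#'   rows (one result per row). All five efficiency columns must be present.
#' @return Character vector of canonical method names, one per row.
#' @export
observedOptimal <- function(rec) {
  methods <- evMethods()
  miss <- setdiff(methods, names(rec))
  if (length(miss) > 0) {
    stop("missing efficiency column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  eff <- as.matrix(as.data.frame(rec)[, methods, drop = FALSE])
  if (anyNA(eff)) stop("missing efficiency value(s); all five are required",
                       call. = FALSE)
  methods[apply(eff, 1L, which.max)]
}
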