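# Reading, validating and filtering per-layer abundance tables.

#' Create an omics abundance matrix
#'
#' An `omics_matrix` is a tibble whose first column (`feature`) holds unique
#' feature identifiers and whose remaining columns hold numeric abundance
#' values, one column per sample. The omics layer (e.g. `"mrna"`,
#' `"protein"`) and the sample-group label ("condition") travel with the
#' object as attributes; downstream network construction is always
#' per-layer and per-condition.
#'
#' @param data A data frame: first column feature identifiers (character),
#'   remaining columns numeric sample measurements. Missing values are
#'   allowed and handled by pairwise-complete correlation later.
#' @param layer Layer name, a single string.
#' @param condition Condition (sample-group) label, a single string.
#'
#' @return A tibble of class `omics_matrix` with attributes `layer` and
#'   `condition`.
#' @export
#' @examples
#' m <- omics_matrix(
#'   data.frame(feature = c("f1", "f2"), s1 = c(1, 2), s2 = c(3, 4)),
#'   layer = "protein", condition = "A"
#' )
#' layer_name(m)
omics_matrix <- function(data, layer, condition) {
  if (!is.data.frame(data) || ncol(data) < 2L) {
    abort("`data` must be a data frame with a feature column and at least one sample column.")
  }
  data <- as_tibble(data)
  names(data)[1L] <- "feature"
  data$feature <- as.character(data$feature)
  if (anyDuplicated(data$feature)) {
    dup <- unique(data$feature[duplicated(data$feature)])
    abort(paste0("Duplicate feature identifiers: ", paste(utils::head(dup, 5L), collapse = ", ")))
  }
  if (anyDuplicated(names(data))) {
    abort("Duplicate sample identifiers in column names.")
  }
  numeric_ok <- vapply(data[-1L], is.numeric, logical(1))
  if (!all(numeric_ok)) {
    abort(paste0(
      "Non-numeric sample columns: ",
      paste(names(data)[-1L][!numeric_ok], collapse = ", ")
    ))
  }
  stopifnot(is.character(layer) || is.factor(layer), length(layer) == 1L)
  stopifnot(length(condition) == 1L)
  structure(
    data,
    layer = as.character(layer),
    condition = as.character(condition),
    class = c("omics_matrix", class(data))
  )
}

#' Read a delimited abundance table into an omics matrix
#'
#' Expects features as rows: the first column carries feature identifiers,
#' the header row sample identifiers, and the body numeric abundances.
#' Files ending in `.csv` are read comma-separated, everything else as TSV.
#'
#' @param path Path to a TSV/CSV file.
#' @param layer,condition Layer name and condition label, attached to the
#'   result.
#' @param missing Character vector of tokens parsed as missing values.
#' @return An [omics_matrix()].
#' @export
read_omics_table <- function(path, layer, condition, missing = c("", "NA")) {
  reader <- if (grepl("\\.csv$", path, ignore.case = TRUE)) readr::read_csv else readr::read_tsv
  raw <- reader(path, na = missing, show_col_types = FALSE, progress = FALSE)
  if (ncol(raw) < 2L) abort(paste0("Malformed table (need >= 2 columns): ", path))
  raw[[1L]] <- as.character(raw[[1L]])
  bad <- !vapply(raw[-1L], is.numeric, logical(1))
  if (any(bad)) {
    abort(paste0(
      "Non-numeric cells (beyond the missing tokens) in columns: ",
      paste(names(raw)[-1L][bad], collapse = ", ")
    ))
  }
  omics_matrix(raw, layer = layer, condition = condition)
}

#' @rdname omics_matrix
#' @param m An `omics_matrix`.
#' @export
layer_name <- function(m) attr(m, "layer", exact = TRUE)

#' @rdname omics_matrix
#' @export
condition_label <- function(m) attr(m, "condition", exact = TRUE)

#' @rdname omics_matrix
#' @export
omics_features <- function(m) m$feature

#' Extract the numeric value matrix of an omics matrix
#'
#' @param m An [omics_matrix()].
#' @return A numeric matrix, features x samples, with feature identifiers as
#'   row names and sample identifiers as column names.
#' @export
omics_values <- function(m) {
  v <- as.matrix(m[, -1L, drop = FALSE])
  rownames(v) <- m$feature
  v
}

# rebuild an omics_matrix keeping only the given row index
subset_omics <- function(m, keep_idx) {
  omics_matrix(
    as_tibble(m)[keep_idx, , drop = FALSE],
    layer = layer_name(m), condition = condition_label(m)
  )
}

#' Remove features dominated by zero measurements
#'
#' Drops every feature whose fraction of exact-zero measurements over the
#' samples strictly exceeds `max_zero_frac` (a feature sitting exactly on
#' the threshold is kept). Missing entries are not zeros and do not count.
#' Typical use: RNAseq features that are zero in more than 90% of a
#' condition's samples.
#'
#' @param m An [omics_matrix()].
#' @param max_zero_frac Maximal tolerated zero fraction, default 0.9.
#' @return A filtered `omics_matrix`; surviving feature order is preserved.
#' @export
filter_zero_fraction <- function(m, max_zero_frac = 0.9) {
  stopifnot(inherits(m, "omics_matrix"))
  v <- omics_values(m)
  frac <- rowSums(v == 0, na.rm = TRUE) / ncol(v)
  subset_omics(m, which(!(frac > max_zero_frac)))
}

#' Remove features with too many missing values
#'
#' Drops every feature whose fraction of missing entries strictly exceeds
#' `max_missing_frac`; boundary features are kept. Typical use: proteins or
#' phosphosites missing in more than 20% of a condition's samples.
#'
#' @inheritParams filter_zero_fraction
#' @param max_missing_frac Maximal tolerated missing fraction, default 0.2.
#' @return A filtered `omics_matrix`.
#' @export
filter_missing_fraction <- function(m, max_missing_frac = 0.2) {
  stopifnot(inherits(m, "omics_matrix"))
  frac <- rowMeans(is.na(omics_values(m)))
  subset_omics(m, which(!(frac > max_missing_frac)))
}

#' Restrict an omics matrix to a feature subset
#'
#' Keeps the intersection of the matrix's features with `keep`, preserving
#' matrix order — e.g. restricting genetic layers to a curated list of
#' disease-related genes.
#'
#' @inheritParams filter_zero_fraction
#' @param keep Character vector of feature identifiers to retain.
#' @return A filtered `omics_matrix`.
#' @export
restrict_features <- function(m, keep) {
  stopifnot(inherits(m, "omics_matrix"))
  idx <- which(m$feature %in% keep)
  if (length(idx) == 0L) {
    abort("No features of the matrix are contained in `keep`.")
  }
  subset_omics(m, idx)
}

#' Read or validate a drug-target table
#'
#' A drug-target table has columns `drug_id`, `target_id` and
#' `target_layer`: one row per (drug, target) pair, targets addressed as
#' (layer, feature) so that the same name in different layers stays
#' distinct.
#'
#' @param x A file path (TSV) or a data frame with the three columns.
#' @return A tibble with columns `drug_id`, `target_id`, `target_layer`.
#' @export
read_drug_targets <- function(x) {
  tab <- if (is.character(x)) readr::read_tsv(x, show_col_types = FALSE, progress = FALSE) else as_tibble(x)
  need <- c("drug_id", "target_id", "target_layer")
  if (!all(need %in% names(tab))) {
    abort(paste0("Drug-target table needs columns: ", paste(need, collapse = ", ")))
  }
  tab <- dplyr::distinct(tab[, need])
  if (nrow(tab) == 0L) abort("Drug-target table is empty.")
  tab
}

#' Read or validate a drug-sensitivity table
#'
#' One row per sensitivity measurement with columns `cell_line_id`,
#' `condition`, `drug_id`, `sensitivity`. Used to construct the
#' Mann-Whitney ground truth via [ground_truth_mwu()].
#'
#' @param x A file path (TSV) or a data frame with the four columns.
#' @return A validated tibble.
#' @export
read_sensitivities <- function(x) {
  tab <- if (is.character(x)) readr::read_tsv(x, show_col_types = FALSE, progress = FALSE) else as_tibble(x)
  need <- c("cell_line_id", "condition", "drug_id", "sensitivity")
  if (!all(need %in% names(tab))) {
    abort(paste0("Sensitivity table needs columns: ", paste(need, collapse = ", ")))
  }
  if (!is.numeric(tab$sensitivity)) abort("`sensitivity` must be numeric.")
  tab[, need]
}
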