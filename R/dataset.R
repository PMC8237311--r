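#' Construct a descriptor dataset
#'
#' The basic container for tabular regression data: a numeric descriptor
#' matrix `X` (rows = samples), a continuous response `y`, and a per-column
#' `origin` flag distinguishing real descriptors from spiked random probe
#' variables.
#'
#' @param X Numeric matrix with unique column names.
#' @param y Numeric response vector, `length(y) == nrow(X)`.
#' @param origin Character vector, one of `"original"` or `"random_probe"`
#'   per column.
#' @return An object of class `vsb_dataset`: a list with elements `X`, `y`,
#'   `origin`.
#' @export
vsb_dataset <- function(X, y, origin = rep("original", ncol(X))) {
  X <- as.matrix(X)
  if (!is.numeric(X)) abort_("X must be a numeric matrix")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (anyDuplicated(colnames(X)))
    abort_("duplicate column names: ",
           paste(unique(colnames(X)[duplicated(colnames(X))]), collapse = ", "))
  if (length(y) != nrow(X))
    abort_("length(y) [", length(y), "] != nrow(X) [", nrow(X), "]")
  if (anyNA(X) || anyNA(y)) abort_("missing values are not allowed")
  if (length(origin) == 1L) origin <- rep(origin, ncol(X))
  if (!all(origin %in% c("original", "random_probe")))
    abort_("origin flags must be 'original' or 'random_probe'")
  if (length(origin) != ncol(X)) abort_("origin length must equal ncol(X)")
  structure(list(X = X, y = as.numeric(y), origin = origin),
            class = "vsb_dataset")
}

#' @method print vsb_dataset
#' @export
print.vsb_dataset <- function(x, ...) {
  cat(sprintf("<vsb_dataset> %d samples x %d variables (%d original, %d probe)\n",
              nrow(x$X), ncol(x$X), sum(x$origin == "original"),
              sum(x$origin == "random_probe")))
  invisible(x)
}

#' @method dim vsb_dataset
#' @export
dim.vsb_dataset <- function(x) dim(x$X)

#' Load a CSV table as a dataset
#'
#' Reads a CSV with a header row, takes `target_column` as the response and
#' every remaining column as a numeric descriptor. Any missing or non-numeric
#' cell is an error that names the offending row and column.
#'
#' @param path Path to a CSV file.
#' @param target_column Name of the response column.
#' @return A [vsb_dataset()] with all columns flagged `origin = "original"`.
#' @export
load_table <- function(path, target_column) {
  raw <- read.csv(path, check.names = FALSE, colClasses = "character")
  if (anyDuplicated(names(raw)))
    abort_("duplicate column names in ", path, ": ",
           paste(unique(names(raw)[duplicated(names(raw))]), collapse = ", "))
  if (!target_column %in% names(raw))
    abort_("target column '", target_column, "' not found in ", path,
           class = "varselbench_config_error")
  num <- lapply(raw, function(col) suppressWarnings(as.numeric(col)))
  for (j in names(raw)) {
    bad <- which(is.na(num[[j]]))
    if (length(bad))
      abort_("non-numeric or missing value in column '", j, "', row ", bad[1],
             " ('", raw[[j]][bad[1]], "')", class = "varselbench_parse_error")
  }
  y <- num[[target_column]]
  Xcols <- num[names(num) != target_column]
  X <- do.call(cbind, Xcols)
  colnames(X) <- names(Xcols)
  vsb_dataset(X, y)
}

# Subset a dataset's columns, keeping flags consistent.
dataset_cols <- function(ds, keep) {
  vsb_dataset(ds$X[, keep, drop = FALSE], ds$y, ds$origin[keep])
}
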