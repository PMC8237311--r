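#' Selection result container
#'
#' Shared return type of all selector modules: which columns were selected,
#' the per-variable decision, and method metadata (chosen hyperparameters,
#' seeds, fitness or hit histories).
#'
#' @param method Selector label, e.g. `"lasso"`, `"gapls"`, `"boruta"`.
#' @param selected Integer indices of selected columns.
#' @param names Column labels of the dataset the selection refers to.
#' @param status Per-column status in `{"selected", "rejected", "tentative"}`
#'   (Boruta uses `"confirmed"` as a synonym for selected); defaults to
#'   selected/rejected derived from `selected`.
#' @param meta Named list of method metadata.
#' @return An object of class `selection_result`.
#' @export
selection_result <- function(method, selected, names, status = NULL,
                             meta = list()) {
  selected <- sort(unique(as.integer(selected)))
  if (length(selected) && (min(selected) < 1 || max(selected) > length(names)))
    abort_("selected indices out of range")
  if (is.null(status)) {
    status <- rep("rejected", length(names))
    status[selected] <- "selected"
  }
  if (length(status) != length(names))
    abort_("status must have one entry per column")
  structure(list(method = method, selected = selected, names = names,
                 status = setNames(status, names), meta = meta),
            class = "selection_result")
}

#' @method print selection_result
#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> %s: %d/%d variables selected\n",
              x$method, length(x$selected), length(x$names)))
  if (length(x$selected))
    cat(" ", paste(head(x$names[x$selected], 12), collapse = " "),
        if (length(x$selected) > 12) "..." else "", "\n")
  invisible(x)
}

#' Serialize a selection result to JSON
#'
#' @param sel A `selection_result`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_selection <- function(sel, path) {
  stopifnot(inherits(sel, "selection_result"))
  jsonlite::write_json(
    list(method = sel$method,
         selected = as.list(sel$names[sel$selected]),
         status = as.list(sel$status),
         meta = sel$meta),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
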