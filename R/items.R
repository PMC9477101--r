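#' Define the set of items being ranked
#'
#' An item set records the `J` labelled objects presented in a ranking task,
#' the attribute subjects judge them on (e.g. "abstraction"), and optionally
#' the intended reference ordering against which submitted rankings can be
#' scored.
#'
#' @param labels character vector of distinct item identifiers (length >= 2).
#' @param attribute free-text name of the judged attribute.
#' @param intended_order optional reference ordering; must be a permutation of
#'   `labels`, with position 1 the item highest on the attribute.
#' @return An object of class `item_set`.
#' @examples
#' item_set(letters[1:5], "abstraction", intended_order = letters[1:5])
#' @export
item_set <- function(labels, attribute = "", intended_order = NULL) {
  labels <- as.character(labels)
  if (length(labels) < 2L) stop("an item set needs at least two items")
  if (anyDuplicated(labels)) {
    stop("item labels must be distinct: '", labels[duplicated(labels)][1L],
         "' appears more than once")
  }
  if (!is.null(intended_order)) {
    intended_order <- as.character(intended_order)
    if (!identical(sort(intended_order), sort(labels))) {
      stop("'intended_order' must be a permutation of the item labels")
    }
  }
  structure(list(labels = labels, attribute = attribute,
                 intended_order = intended_order),
            class = "item_set")
}

#' @export
print.item_set <- function(x, ...) {
  cat("Item set (J = ", length(x$labels), "): ",
      paste(x$labels, collapse = ", "), "\n", sep = "")
  if (nzchar(x$attribute)) cat("  attribute:", x$attribute, "\n")
  if (!is.null(x$intended_order)) {
    cat("  intended order:", paste(x$intended_order, collapse = " > "), "\n")
  }
  invisible(x)
}

n_items <- function(items) length(items$labels)

as_item_set <- function(items) {
  if (inherits(items, "item_set")) return(items)
  if (is.character(items)) return(item_set(items))
  stop("'items' must be an item_set or a character vector of labels")
}

# canonical pair order (1,2),(1,3),...,(1,J),(2,3),...,(J-1,J)
pc_pairs <- function(J) {
  j <- rep(seq_len(J - 1L), times = (J - 1L):1L)
  k <- unlist(lapply(seq_len(J - 1L), function(a) (a + 1L):J))
  cbind(j = j, k = k)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
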