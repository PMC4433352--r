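#' Canonical complex label
#'
#' Complexes are named by joining the labels of their constituents with `"|"`
#' in lexicographic order, so that `A|E` and `E|A` denote the same place.
#' Constituent lists are flattened: a complex of a complex inherits all
#' primitive constituents (e.g. binding `Raf1|RKIP` with `ERKPP` yields
#' `ERKPP|RKIP|Raf1`, a three-constituent complex).
#'
#' @param labels character vector of constituent labels; each must be free of
#'   `"|"` (decompose complexes with [constituents()] first).
#' @return a single character label.
#' @examples
#' make_complex_label(c("E", "A"))  # "A|E"
#' make_complex_label("A")          # "A"
#' @seealso [constituents()], [is_complex()]
#' @export
make_complex_label <- function(labels) {
  if (length(labels) == 0L) {
    stop("cannot build a complex label from an empty constituent list")
  }
  labels <- as.character(labels)
  if (any(grepl("|", labels, fixed = TRUE))) {
    stop("constituent labels must not contain '|'; decompose complexes first")
  }
  if (any(!nzchar(labels))) stop("constituent labels must be non-empty")
  paste(sort_labels(labels), collapse = "|")
}

#' Constituents of a reactant label
#'
#' @param label a reactant label, possibly a complex (`"A|E"`).
#' @return character vector of primitive constituent labels, in canonical
#'   (lexicographic) order.
#' @export
constituents <- function(label) {
  sort_labels(strsplit(label, "|", fixed = TRUE)[[1L]])
}

#' Is a label a complex?
#'
#' @param label character vector of reactant labels.
#' @return logical vector; `TRUE` where the label has two or more constituents.
#' @export
is_complex <- function(label) {
  grepl("|", label, fixed = TRUE)
}

# Canonicalise a possibly-complex label (flatten + sort constituents).
canonical_label <- function(label) {
  vapply(label, function(x) {
    if (is_complex(x)) make_complex_label(constituents(x)) else x
  }, character(1L), USE.NAMES = FALSE)
}

# Locale-independent lexicographic sort, so canonical labels do not depend
# on the session collation.
sort_labels <- function(x) {
  old <- Sys.getlocale("LC_COLLATE")
  on.exit(suppressWarnings(Sys.setlocale("LC_COLLATE", old)), add = TRUE)
  suppressWarnings(Sys.setlocale("LC_COLLATE", "C"))
  sort(x, method = "radix")
}

#' Product label of a species
#'
#' The third atomic component of an enzymatic reaction releases the enzyme
#' and a new product, named by suffixing `"P"` to the species label
#' (`A` becomes `AP`). Only primitive species take products.
#'
#' @param species a primitive species label.
#' @return the product label.
#' @export
product_label <- function(species) {
  if (is_complex(species)) {
    stop("products are generated for primitive species only, not complexes")
  }
  paste0(species, "P")
}
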