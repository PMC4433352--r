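#' Atomic reaction component
#'
#' A component is an atomic Petri-net reaction fragment: a multiset of input
#' reactants and a multiset of output reactants. Two shapes occur: a
#' *binding*-shaped component combines two or more reactants into one, and an
#' *unbinding*-shaped component splits one reactant into two or more.
#' Library-generated components (see [generate_library()]) additionally
#' satisfy the strict pattern invariants: a binding has exactly two inputs and
#' one output whose constituents are the union of the input constituents, and
#' an unbinding has exactly one complex input and two outputs. Encoded
#' pathway fixtures may contain reactions outside the strict patterns (for
#' instance a ternary complex splitting into three parts); use
#' [validate_component()] with `strict = TRUE` to check the pattern
#' invariants explicitly. Kinetic rate constants are deliberately not
#' represented: only structure is learned.
#'
#' @param inputs character vector (multiset) of input reactant labels.
#' @param outputs character vector (multiset) of output reactant labels.
#' @param kind `"binding"` or `"unbinding"`; inferred from the shape when
#'   omitted (more inputs than outputs binds, one input unbinds).
#' @return an object of class `qml_component`.
#' @examples
#' component(c("A", "E"), "A|E")            # binding
#' component("A|E", c("AP", "E"))           # unbinding (product release)
#' @export
component <- function(inputs, outputs, kind = NULL) {
  inputs <- canonical_label(as.character(inputs))
  outputs <- canonical_label(as.character(outputs))
  if (length(inputs) == 0L || length(outputs) == 0L) {
    stop("a component must have at least one input and one output reactant")
  }
  if (is.null(kind)) {
    kind <- if (length(inputs) >= 2L && length(outputs) == 1L) "binding"
            else if (length(inputs) == 1L && length(outputs) >= 2L) "unbinding"
            else if (length(inputs) == 1L && length(outputs) == 1L) "unbinding"
            else "binding"
  }
  kind <- match.arg(kind, c("binding", "unbinding"))
  x <- structure(
    list(kind = kind,
         inputs = sort_labels(inputs),
         outputs = sort_labels(outputs)),
    class = "qml_component")
  x
}

#' Validate a component
#'
#' @param x a `qml_component`.
#' @param strict if `TRUE`, enforce the strict binding/unbinding pattern
#'   invariants used for library generation (exactly 2 inputs / 1 output
#'   with constituent-union naming for a binding; exactly 1 complex input /
#'   2 outputs for an unbinding).
#' @return `TRUE` invisibly; errors otherwise.
#' @export
validate_component <- function(x, strict = FALSE) {
  stopifnot(inherits(x, "qml_component"))
  if (length(x$inputs) == 0L || length(x$outputs) == 0L) {
    stop("component has an empty side")
  }
  if (strict) {
    if (x$kind == "binding") {
      if (length(x$inputs) != 2L || length(x$outputs) != 1L) {
        stop("strict binding must have exactly 2 inputs and 1 output")
      }
      want <- make_complex_label(unlist(lapply(x$inputs, constituents)))
      if (!identical(x$outputs, want)) {
        stop("strict binding output must be the constituent union of its inputs")
      }
    } else {
      if (length(x$inputs) != 1L || length(x$outputs) != 2L) {
        stop("strict unbinding must have exactly 1 input and 2 outputs")
      }
      if (!is_complex(x$inputs)) {
        stop("strict unbinding input must be a complex")
      }
    }
  }
  invisible(TRUE)
}

#' Canonical component signature
#'
#' A name-free transition identity: sorted input multiset, `"=>"`, sorted
#' output multiset. Identical reactions in independently built models have
#' identical signatures, which is what arc matching across models requires.
#'
#' @param x a `qml_component`.
#' @return a single character string, e.g. `"A + E => A|E"`.
#' @export
component_signature <- function(x) {
  paste(paste(x$inputs, collapse = " + "), "=>",
        paste(x$outputs, collapse = " + "))
}

#' @export
format.qml_component <- function(x, ...) {
  arrow <- if (x$kind == "binding") "->" else "->"
  paste(paste(x$inputs, collapse = " + "), arrow,
        paste(x$outputs, collapse = " + "))
}

#' @export
print.qml_component <- function(x, ...) {
  cat("<component:", x$kind, "> ", format(x), "\n", sep = "")
  invisible(x)
}

#' Generate the atomic component library
#'
#' For every pair of a species `s` and an enzyme `e`, three atomic components
#' are generated from the enzymatic reaction `s + e <=> s|e -> sP + e`:
#' the binding `s + e -> s|e`, the unbinding `s|e -> s + e`, and the
#' product-releasing unbinding `s|e -> sP + e`, where `sP` is the new product
#' label of `s`. The library therefore holds exactly
#' `3 * |species| * |enzymes|` distinct components, in deterministic order.
#'
#' @param species non-empty character vector of primitive species labels.
#' @param enzymes non-empty character vector of primitive enzyme labels.
#' @return an object of class `qml_library` with elements `components`
#'   (list of [component()]s), `species` and `enzymes`.
#' @examples
#' lib <- generate_library("A", "E")
#' length(lib$components)  # 3
#' @export
generate_library <- function(species, enzymes) {
  species <- as.character(species)
  enzymes <- as.character(enzymes)
  if (length(species) == 0L) stop("species set must be non-empty")
  if (length(enzymes) == 0L) stop("enzymes set must be non-empty")
  if (anyDuplicated(species)) stop("duplicate species labels")
  if (anyDuplicated(enzymes)) stop("duplicate enzyme labels")
  if (any(is_complex(c(species, enzymes)))) {
    stop("library label sets must be primitive (no '|')")
  }
  comps <- vector("list", 3L * length(species) * length(enzymes))
  k <- 0L
  for (s in species) {
    for (e in enzymes) {
      cx <- make_complex_label(c(s, e))
      comps[[k + 1L]] <- component(c(s, e), cx, kind = "binding")
      comps[[k + 2L]] <- component(cx, c(s, e), kind = "unbinding")
      comps[[k + 3L]] <- component(cx, c(product_label(s), e),
                                   kind = "unbinding")
      k <- k + 3L
    }
  }
  sigs <- vapply(comps, component_signature, character(1L))
  if (anyDuplicated(sigs)) stop("label sets generate duplicate components")
  structure(list(components = comps, species = species, enzymes = enzymes),
            class = "qml_library")
}

#' @export
print.qml_library <- function(x, ...) {
  cat("<component library> ", length(x$components), " components from ",
      length(x$species), " species x ", length(x$enzymes), " enzymes\n",
      sep = "")
  invisible(x)
}

#' @export
length.qml_library <- function(x) length(x$components)
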