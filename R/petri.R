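#' Petri-net pathway model
#'
#' A model is a set of components merged over shared places: components that
#' mention the same canonical reactant label share the identical place. The
#' place set is derived from the components, so composition is place merging
#' by construction. Every model holds at least one component, which keeps the
#' stepwise addition/subtraction operators well defined.
#'
#' @param components a list of [component()]s (or a single component).
#' @return an object of class `qml_model` with elements `components` (list)
#'   and `places` (character vector, canonical order).
#' @export
petri_model <- function(components) {
  if (inherits(components, "qml_component")) components <- list(components)
  if (length(components) == 0L) {
    stop("a model must contain at least one component")
  }
  stopifnot(all(vapply(components, inherits, logical(1L), "qml_component")))
  sigs <- vapply(components, component_signature, character(1L))
  if (anyDuplicated(sigs)) stop("duplicate components in model")
  structure(list(components = components, places = model_places(components)),
            class = "qml_model")
}

model_places <- function(components) {
  sort_labels(unique(unlist(lapply(components, function(cc) {
    c(cc$inputs, cc$outputs)
  }))))
}

model_signatures <- function(model) {
  vapply(model$components, component_signature, character(1L))
}

#' Validate a model
#'
#' Checks the structural invariants: at least one component, no duplicate
#' components, every place used by at least one component, and canonical
#' place labels.
#'
#' @param model a `qml_model`.
#' @return `TRUE` invisibly; errors otherwise.
#' @export
validate_model <- function(model) {
  stopifnot(inherits(model, "qml_model"))
  if (length(model$components) < 1L) stop("model has no components")
  for (cc in model$components) validate_component(cc)
  sigs <- model_signatures(model)
  if (anyDuplicated(sigs)) stop("duplicate components in model")
  used <- model_places(model$components)
  if (!identical(sort_labels(model$places), used)) {
    stop("model place set does not match the places used by its components")
  }
  if (!identical(model$places, canonical_label(model$places))) {
    stop("model places are not canonical labels")
  }
  invisible(TRUE)
}

#' Is a component present in a model?
#'
#' Membership is by canonical signature, not object identity.
#'
#' @param model a `qml_model`.
#' @param comp a `qml_component`.
#' @return logical.
#' @export
component_in_model <- function(model, comp) {
  component_signature(comp) %in% model_signatures(model)
}

#' Compose a component into a model
#'
#' Appends the component and merges all places with identical canonical
#' labels. The input model is not modified. Composing a component already in
#' the model is rejected: a condition of class `qml_duplicate_component` is
#' signalled.
#'
#' @param model a `qml_model`.
#' @param comp a `qml_component` to add.
#' @return a new `qml_model`.
#' @export
compose <- function(model, comp) {
  stopifnot(inherits(model, "qml_model"), inherits(comp, "qml_component"))
  if (component_in_model(model, comp)) {
    stop(structure(
      class = c("qml_duplicate_component", "error", "condition"),
      list(message = paste0("component already present: ",
                            component_signature(comp)),
           call = sys.call())))
  }
  petri_model(c(model$components, list(comp)))
}

#' Remove a component from a model
#'
#' The component is removed and places left orphaned (used by no remaining
#' component) are dropped. Removing the last component is an error: a model
#' must keep at least one component for further stepwise construction.
#'
#' @param model a `qml_model`.
#' @param comp the `qml_component` to remove (matched by signature).
#' @return a new `qml_model`.
#' @export
subtract <- function(model, comp) {
  stopifnot(inherits(model, "qml_model"), inherits(comp, "qml_component"))
  sig <- component_signature(comp)
  sigs <- model_signatures(model)
  idx <- match(sig, sigs)
  if (is.na(idx)) stop("component not present in model: ", sig)
  if (length(model$components) < 2L) {
    stop("cannot remove the last component of a model")
  }
  petri_model(model$components[-idx])
}

#' Structural model equality
#'
#' Two models are equal when they hold the same set of component signatures
#' (and hence the same places).
#'
#' @param m1,m2 `qml_model` objects.
#' @return logical.
#' @export
models_equal <- function(m1, m2) {
  setequal(model_signatures(m1), model_signatures(m2))
}

#' Crossover of two models
#'
#' Exchanges a random non-empty proper subset of components between the two
#' parents. Offspring are repaired so that each keeps at least one component
#' and contains no duplicate components; the repair moves a would-be
#' duplicate copy to the other offspring, so the multiset union of components
#' over the two offspring always equals that over the two parents. When
#' either parent has a single component the operator degenerates to
#' swap-or-identity (equal probability) and the result carries the attribute
#' `degenerate = TRUE`.
#'
#' @param m1,m2 parent `qml_model`s.
#' @return list of two `qml_model` offspring (attribute `degenerate` set when
#'   the degenerate case was taken).
#' @export
crossover <- function(m1, m2) {
  n1 <- length(m1$components); n2 <- length(m2$components)
  if (n1 == 1L || n2 == 1L) {
    out <- if (stats::runif(1L) < 0.5) list(m2, m1) else list(m1, m2)
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  k1 <- sample.int(n1 - 1L, 1L)
  k2 <- sample.int(n2 - 1L, 1L)
  s1 <- sample.int(n1, k1)
  s2 <- sample.int(n2, k2)
  keep1 <- m1$components[-s1]; give1 <- m1$components[s1]
  keep2 <- m2$components[-s2]; give2 <- m2$components[s2]
  o1 <- c(keep1, give2)
  o2 <- c(keep2, give1)
  # Repair: a component duplicated within an offspring has both of its parent
  # copies there; send one copy to the other offspring (which then has none).
  fix <- function(a, b) {
    sa <- vapply(a, component_signature, character(1L))
    dup <- duplicated(sa)
    if (any(dup)) {
      b <- c(b, a[dup])
      a <- a[!dup]
    }
    list(a = a, b = b)
  }
  r <- fix(o1, o2); o1 <- r$a; o2 <- r$b
  r <- fix(o2, o1); o2 <- r$a; o1 <- r$b
  list(petri_model(o1), petri_model(o2))
}

#' Arcs of a model
#'
#' The bipartite place/transition graph as directed arcs. Each transition is
#' identified by its canonical signature (see [component_signature()]); the
#' arc set is the union of `(reactant, signature)` for every input and
#' `(signature, reactant)` for every output. Duplicate multiset entries
#' contribute one arc (the arc set is a set).
#'
#' @param model a `qml_model`.
#' @return a two-column character matrix with columns `from` and `to`.
#' @export
arcs <- function(model) {
  rows <- lapply(model$components, function(cc) {
    sig <- component_signature(cc)
    rbind(cbind(unique(cc$inputs), sig),
          cbind(sig, unique(cc$outputs)))
  })
  m <- do.call(rbind, rows)
  colnames(m) <- c("from", "to")
  m <- m[!duplicated(paste(m[, 1L], m[, 2L], sep = "\r")), , drop = FALSE]
  m[order(m[, 1L], m[, 2L], method = "radix"), , drop = FALSE]
}

arc_keys <- function(model) {
  a <- arcs(model)
  paste(a[, 1L], a[, 2L], sep = " -> ")
}

#' @export
print.qml_model <- function(x, ...) {
  cat("<petri model> ", length(x$components), " components, ",
      length(x$places), " places\n", sep = "")
  for (cc in x$components) cat("  ", format(cc), "\n", sep = "")
  invisible(x)
}

#' Rename places of a model
#'
#' Applies a whole-label substitution map to every place of the model. The
#' map expresses *identification* of reactant labels (typically a derived
#' species with its constructive complex, such as `H -> G|M` in the
#' methylglyoxal pathway); when an image coincides with an existing place the
#' two places merge. Transitions that the identification renders
#' self-regenerating (an output equal to one of the transition's own inputs)
#' carry no interaction information on the quotient and are dropped from the
#' model; `drop_degenerate = FALSE` keeps them.
#'
#' @param model a `qml_model`.
#' @param renaming named character vector, `names()` are the labels to
#'   replace and values their images. May be empty.
#' @param drop_degenerate drop transitions whose renamed outputs intersect
#'   their renamed inputs (default `TRUE`).
#' @return a new `qml_model`.
#' @export
rename_places <- function(model, renaming, drop_degenerate = TRUE) {
  if (length(renaming) == 0L) return(model)
  stopifnot(!is.null(names(renaming)))
  renaming <- stats::setNames(canonical_label(as.character(renaming)),
                              names(renaming))
  map1 <- function(x) {
    hit <- match(x, names(renaming))
    x[!is.na(hit)] <- renaming[hit[!is.na(hit)]]
    x
  }
  comps <- lapply(model$components, function(cc) {
    component(map1(cc$inputs), map1(cc$outputs), kind = cc$kind)
  })
  if (drop_degenerate) {
    keep <- vapply(comps, function(cc) {
      length(intersect(cc$inputs, cc$outputs)) == 0L
    }, logical(1L))
    comps <- comps[keep]
    if (length(comps) == 0L) {
      stop("renaming left no non-degenerate component in the model")
    }
  }
  sigs <- vapply(comps, component_signature, character(1L))
  petri_model(comps[!duplicated(sigs)])
}
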