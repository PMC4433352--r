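# Model and state-set serialization.

#' Serialize a model to JSON
#'
#' The document holds the place list and one record per component
#' (`kind`, `inputs`, `outputs`); [model_from_json()] round-trips it.
#'
#' @param model a `qml_model`.
#' @return a JSON string.
#' @export
model_to_json <- function(model) {
  doc <- list(
    places = model$places,
    components = lapply(model$components, function(cc) {
      list(kind = cc$kind, inputs = cc$inputs, outputs = cc$outputs)
    }))
  jsonlite::toJSON(doc, auto_unbox = FALSE, pretty = TRUE)
}

#' Deserialize a model from JSON
#'
#' @param txt a JSON string or connection/path accepted by
#'   [jsonlite::fromJSON()].
#' @return a `qml_model`.
#' @export
model_from_json <- function(txt) {
  doc <- jsonlite::fromJSON(txt, simplifyDataFrame = FALSE,
                            simplifyVector = TRUE)
  comps <- lapply(doc$components, function(cc) {
    component(unlist(cc$inputs), unlist(cc$outputs), kind = cc$kind)
  })
  petri_model(comps)
}

#' Write / read a model as a JSON file
#'
#' @param model a `qml_model`.
#' @param path file path.
#' @return `write_model()` returns `path` invisibly; `read_model()` a
#'   `qml_model`.
#' @export
write_model <- function(model, path) {
  writeLines(model_to_json(model), path)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  model_from_json(paste(readLines(path, warn = FALSE), collapse = "\n"))
}

#' Export a model as PNML
#'
#' Writes the bipartite place/transition graph in the standard Petri-net
#' interchange format (PNML, place/transition net). Transitions are named by
#' their canonical signatures.
#'
#' @param model a `qml_model`.
#' @param path file path for the `.pnml` document.
#' @return `path`, invisibly.
#' @export
write_pnml <- function(model, path) {
  if (!requireNamespace("xml2", quietly = TRUE)) {
    stop("PNML export needs the 'xml2' package")
  }
  doc <- xml2::xml_new_root("pnml",
    xmlns = "http://www.pnml.org/version-2009/grammar/pnml")
  net <- xml2::xml_add_child(doc, "net", id = "net1",
    type = "http://www.pnml.org/version-2009/grammar/ptnet")
  page <- xml2::xml_add_child(net, "page", id = "page1")
  pid <- stats::setNames(sprintf("p%d", seq_along(model$places)),
                         model$places)
  for (p in model$places) {
    pl <- xml2::xml_add_child(page, "place", id = pid[[p]])
    nm <- xml2::xml_add_child(pl, "name")
    xml2::xml_add_child(nm, "text", p)
  }
  aid <- 0L
  for (i in seq_along(model$components)) {
    cc <- model$components[[i]]
    tid <- sprintf("t%d", i)
    tr <- xml2::xml_add_child(page, "transition", id = tid)
    nm <- xml2::xml_add_child(tr, "name")
    xml2::xml_add_child(nm, "text", component_signature(cc))
    for (p in unique(cc$inputs)) {
      aid <- aid + 1L
      xml2::xml_add_child(page, "arc", id = sprintf("a%d", aid),
                          source = pid[[p]], target = tid)
    }
    for (p in unique(cc$outputs)) {
      aid <- aid + 1L
      xml2::xml_add_child(page, "arc", id = sprintf("a%d", aid),
                          source = tid, target = pid[[p]])
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}
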