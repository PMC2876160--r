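# Small worked-example ontology used in documentation and tests.

#' Organelle example ontology
#'
#' A minimal cellular-component DAG illustrating shared-function labeling:
#' `organelle envelope` is `part_of` both `membrane-bound organelle` and
#' `intracellular organelle`, which are both `is_a` children of `organelle`;
#' `intracellular membrane-bound organelle` is `is_a` child of both. A gene
#' annotated to `organelle envelope` and its duplicate annotated to
#' `intracellular membrane-bound organelle` share exactly
#' `membrane-bound organelle` and `intracellular organelle` as most specific
#' shared functions.
#'
#' @return an [ontology_graph()] with term ids `CC:0000` (root) through
#'   `CC:0005`.
#' @examples
#' g <- organelle_example_graph()
#' most_specific_shared_terms(g, "CC:0005", "CC:0004")
#' @export
organelle_example_graph <- function() {
  terms <- data.frame(
    id = sprintf("CC:%04d", 0:5),
    name = c("cellular_component", "organelle", "membrane-bound organelle",
             "intracellular organelle",
             "intracellular membrane-bound organelle", "organelle envelope"),
    namespace = "cellular_component",
    stringsAsFactors = FALSE)
  edges <- data.frame(
    child  = c("CC:0001", "CC:0002", "CC:0003", "CC:0004", "CC:0004",
               "CC:0005", "CC:0005"),
    parent = c("CC:0000", "CC:0001", "CC:0001", "CC:0002", "CC:0003",
               "CC:0002", "CC:0003"),
    relation = c("is_a", "is_a", "is_a", "is_a", "is_a",
                 "part_of", "part_of"),
    stringsAsFactors = FALSE)
  ontology_graph(terms, edges)
}

#' Resolve a term name to its accession in a graph
#'
#' @param graph an [ontology_graph()].
#' @param name exact term name.
#' @return term accession.
#' @export
term_by_name <- function(graph, name) {
  hit <- graph$terms$id[graph$terms$name == name]
  if (length(hit) != 1L) stopf("name %s matches %d terms", name, length(hit))
  hit
}
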