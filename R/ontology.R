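#' Construct an ontology graph
#'
#' Builds the rooted directed acyclic graph of ontology terms used throughout
#' the package. Edges point from child to parent and are restricted to the
#' `is_a` and `part_of` relations, which are pooled as equivalent for
#' reachability and depth (other relation types are dropped at parse time).
#' Each namespace must contain exactly one root (a term with no parents), and
#' edges may not cross namespaces.
#'
#' On construction the graph is topologically sorted (an error names a cycle
#' member if the input is cyclic), and per-term depths (shortest child-to-root
#' path counting both edge types) and reflexive ancestor closures are
#' precomputed.
#'
#' @param terms data.frame with columns `id`, `name`, `namespace`.
#' @param edges data.frame with columns `child`, `parent`, `relation`
#'   (values `"is_a"` or `"part_of"`); may have zero rows.
#' @param alt_ids optional named character vector mapping alternate term ids
#'   to primary ids.
#' @return an object of class `ontology_graph`: a list with elements
#'   `terms`, `edges`, `parents`, `children`, `roots` (named by namespace),
#'   `depth`, `ancestors` (reflexive, per term), and `alt_ids`.
#' @seealso [parse_obo()], [reflexive_ancestors()], [term_depth()]
#' @export
ontology_graph <- function(terms, edges, alt_ids = character(0)) {
  terms <- as.data.frame(terms, stringsAsFactors = FALSE)
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (nrow(terms) == 0L) stopf("ontology has no terms")
  if (anyDuplicated(terms$id)) {
    stopf("duplicate term id: %s", terms$id[duplicated(terms$id)][1])
  }
  valid_ns <- c("biological_process", "molecular_function", "cellular_component")
  bad_ns <- setdiff(unique(terms$namespace), valid_ns)
  if (length(bad_ns)) stopf("unknown namespace: %s", bad_ns[1])
  ns_of <- setNames(terms$namespace, terms$id)

  if (nrow(edges)) {
    unknown <- setdiff(c(edges$child, edges$parent), terms$id)
    if (length(unknown)) stopf("edge references unknown term: %s", unknown[1])
    bad_rel <- setdiff(unique(edges$relation), c("is_a", "part_of"))
    if (length(bad_rel)) stopf("unsupported relation: %s", bad_rel[1])
    cross <- ns_of[edges$child] != ns_of[edges$parent]
    if (any(cross)) {
      stopf("edge crosses namespaces: %s -> %s",
            edges$child[cross][1], edges$parent[cross][1])
    }
    edges <- edges[!duplicated(edges[c("child", "parent")]), , drop = FALSE]
  }

  ids <- terms$id
  parents <- split(edges$parent, factor(edges$child, levels = ids))
  children <- split(edges$child, factor(edges$parent, levels = ids))

  # Kahn topological sort from roots downward; leftovers indicate a cycle.
  indeg <- lengths(parents)           # edges into a term from its parents
  order <- character(0)
  queue <- ids[indeg == 0L]
  indeg_left <- indeg
  while (length(queue)) {
    t <- queue[1]; queue <- queue[-1]
    order <- c(order, t)
    for (c in children[[t]]) {
      indeg_left[[c]] <- indeg_left[[c]] - 1L
      if (indeg_left[[c]] == 0L) queue <- c(queue, c)
    }
  }
  if (length(order) < length(ids)) {
    stopf("ontology contains a cycle involving term %s",
          setdiff(ids, order)[1])
  }

  root_ids <- ids[lengths(parents) == 0L]
  root_ns <- ns_of[root_ids]
  if (anyDuplicated(root_ns)) {
    stopf("namespace %s has more than one root (parentless term)",
          root_ns[duplicated(root_ns)][1])
  }
  roots <- setNames(root_ids, root_ns)

  # depth and reflexive ancestor closure in topological (root-first) order
  depth <- setNames(rep(NA_integer_, length(ids)), ids)
  ancestors <- setNames(vector("list", length(ids)), ids)
  for (t in order) {
    ps <- parents[[t]]
    if (length(ps) == 0L) {
      depth[[t]] <- 0L
      ancestors[[t]] <- t
    } else {
      depth[[t]] <- min(depth[ps]) + 1L
      ancestors[[t]] <- unique(c(t, unlist(ancestors[ps], use.names = FALSE)))
    }
  }

  structure(
    list(terms = terms, edges = edges, parents = parents, children = children,
         roots = roots, depth = depth, ancestors = ancestors,
         topo_order = order, alt_ids = alt_ids),
    class = "ontology_graph")
}

#' @export
print.ontology_graph <- function(x, ...) {
  cat(sprintf("ontology_graph: %d terms, %d edges, namespaces: %s\n",
              nrow(x$terms), nrow(x$edges),
              paste(names(x$roots), collapse = ", ")))
  invisible(x)
}

resolve_term <- function(graph, term) {
  out <- term
  alt <- !(out %in% names(graph$ancestors)) & out %in% names(graph$alt_ids)
  out[alt] <- graph$alt_ids[out[alt]]
  out
}

check_term <- function(graph, term) {
  term <- resolve_term(graph, term)
  missing <- setdiff(term, names(graph$ancestors))
  if (length(missing)) stopf("unknown term: %s", missing[1])
  term
}

#' Parse an OBO 1.2 ontology file
#'
#' Reads `[Term]` stanzas and keeps the `id`, `name`, `namespace`, `is_a`,
#' `relationship: part_of`, `alt_id` and `is_obsolete` fields. Obsolete terms
#' are dropped entirely (with their edges); relations other than `is_a` and
#' `part_of` (e.g. `regulates`) are silently omitted while the term itself is
#' kept. Alternate ids are recorded so that downstream annotation parsing can
#' resolve them to primary ids.
#'
#' @param path path to an OBO file, or a character vector of OBO lines.
#' @return an [ontology_graph()].
#' @export
parse_obo <- function(path) {
  lines <- if (length(path) == 1L && file.exists(path)) readLines(path) else path
  lines <- sub("\\s+$", "", lines)
  term_starts <- which(lines == "[Term]")
  if (length(term_starts) == 0L) stopf("no [Term] stanzas found in OBO input")
  # stanza boundaries: a stanza runs until the next [...] header or EOF
  headers <- grep("^\\[.*\\]$", lines)
  recs <- list(); alt_tab <- character(0); obsolete <- character(0)
  for (s in term_starts) {
    nxt <- headers[headers > s]
    end <- if (length(nxt)) nxt[1] - 1L else length(lines)
    body <- lines[(s + 1L):end]
    field <- function(key) {
      vals <- body[startsWith(body, paste0(key, ":"))]
      vals <- sub(paste0("^", key, ":\\s*"), "", vals)
      sub("\\s*!.*$", "", vals)   # strip trailing OBO comments
    }
    id <- field("id")
    if (length(id) != 1L) stopf("stanza without a single id near line %d", s)
    if (any(field("is_obsolete") == "true")) {
      obsolete <- c(obsolete, id)
      next
    }
    name <- field("name"); ns <- field("namespace")
    is_a <- field("is_a")
    rels <- field("relationship")
    part_of <- sub("^part_of\\s+", "", rels[startsWith(rels, "part_of")])
    alts <- field("alt_id")
    if (length(alts)) alt_tab[alts] <- id
    recs[[id]] <- list(
      id = id,
      name = if (length(name)) name[1] else id,
      namespace = if (length(ns)) ns[1] else NA_character_,
      is_a = is_a, part_of = part_of)
  }
  if (length(recs) == 0L) stopf("OBO input contains no usable (non-obsolete) terms")
  terms <- data.frame(
    id = vapply(recs, `[[`, "", "id"),
    name = vapply(recs, `[[`, "", "name"),
    namespace = vapply(recs, `[[`, "", "namespace"),
    stringsAsFactors = FALSE, row.names = NULL)
  edge_list <- lapply(recs, function(r) {
    if (length(r$is_a) + length(r$part_of) == 0L) return(NULL)
    data.frame(child = r$id,
               parent = c(r$is_a, r$part_of),
               relation = c(rep("is_a", length(r$is_a)),
                            rep("part_of", length(r$part_of))),
               stringsAsFactors = FALSE)
  })
  edges <- do.call(rbind, edge_list)
  if (is.null(edges)) {
    edges <- data.frame(child = character(0), parent = character(0),
                        relation = character(0))
  } else {
    # edges whose parent stanza was obsolete vanish with the parent; a parent
    # id that never appeared in any stanza is a dangling reference
    known <- edges$parent %in% terms$id
    dangling <- !known & !(edges$parent %in% obsolete)
    if (any(dangling)) {
      stopf("term %s references unknown parent %s",
            edges$child[dangling][1], edges$parent[dangling][1])
    }
    edges <- edges[known, , drop = FALSE]
  }
  alt_tab <- alt_tab[alt_tab %in% terms$id]
  ontology_graph(terms, edges, alt_ids = alt_tab)
}

#' Reflexive ancestors of a term
#'
#' The term itself plus every term reachable by repeatedly following
#' child-to-parent `is_a`/`part_of` edges; always confined to the term's
#' namespace. Reflexivity matters downstream: a pair annotated to the same
#' leaf shares that leaf itself as its most specific shared function.
#'
#' @param graph an [ontology_graph()].
#' @param term a single term accession (alternate ids are resolved).
#' @return character vector of term accessions, including `term`.
#' @export
reflexive_ancestors <- function(graph, term) {
  stopifnot(inherits(graph, "ontology_graph"), length(term) == 1L)
  term <- check_term(graph, term)
  graph$ancestors[[term]]
}

#' Depth of a term
#'
#' Length of the shortest child-to-root path, counting both `is_a` and
#' `part_of` edges; a namespace root has depth 0.
#'
#' @inheritParams reflexive_ancestors
#' @return non-negative integer.
#' @export
term_depth <- function(graph, term) {
  stopifnot(inherits(graph, "ontology_graph"), length(term) == 1L)
  term <- check_term(graph, term)
  unname(graph$depth[[term]])
}

#' Most specific shared functions of two term sets
#'
#' Computes the common reflexive ancestors of two annotation profiles, drops
#' terms shallower than `min_depth`, and returns the minimal elements (terms
#' with no proper descendant also in the common set). This is the labeling a
#' duplicate pair receives: the deepest functions both copies demonstrably
#' share.
#'
#' @param graph an [ontology_graph()].
#' @param termsA,termsB nonempty character vectors of term accessions, all in
#'   one namespace.
#' @param min_depth minimum term depth retained (default 1: namespace roots
#'   are excluded).
#' @return character vector (possibly empty) of term accessions, sorted;
#'   an antichain under the ancestor relation.
#' @export
most_specific_shared_terms <- function(graph, termsA, termsB, min_depth = 1L) {
  stopifnot(inherits(graph, "ontology_graph"))
  if (length(termsA) == 0L || length(termsB) == 0L) {
    stopf("empty term set: cannot compute shared functions")
  }
  termsA <- check_term(graph, termsA)
  termsB <- check_term(graph, termsB)
  ancA <- unique(unlist(graph$ancestors[termsA], use.names = FALSE))
  ancB <- unique(unlist(graph$ancestors[termsB], use.names = FALSE))
  common <- intersect(ancA, ancB)
  common <- common[graph$depth[common] >= min_depth]
  if (length(common) == 0L) return(character(0))
  # minimal elements: no other common term has this term as proper ancestor
  keep <- vapply(common, function(t) {
    !any(vapply(common, function(c) {
      c != t && t %in% graph$ancestors[[c]]
    }, logical(1)))
  }, logical(1))
  sort(common[keep])
}
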