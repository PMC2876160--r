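# Parent-child union GO term enrichment: a term's study count is judged
# against the genes annotated to the union of its parents, which corrects
# the classic term-for-term test's inheritance bias.

#' Descendant-inclusive gene index for one namespace
#'
#' Maps every term of a namespace to the set of genes annotated to it or to
#' any of its descendants.
#'
#' @param annotations an [annotation_set()].
#' @param graph an [ontology_graph()].
#' @param namespace namespace to index.
#' @return named list term -> character vector of genes (terms with no
#'   annotated descendants map to empty vectors).
#' @export
term_gene_index <- function(annotations, graph, namespace) {
  rec <- annotations$records
  rec <- rec[rec$namespace == namespace, , drop = FALSE]
  inclusive <- split(rec$gene, factor(rec$term, levels = graph$terms$id))
  inclusive <- lapply(inclusive, unique)
  for (t in rev(graph$topo_order)) {
    kids <- graph$children[[t]]
    if (length(kids)) {
      inclusive[[t]] <- unique(c(inclusive[[t]],
                                 unlist(inclusive[kids], use.names = FALSE)))
    }
  }
  ns_terms <- graph$terms$id[graph$terms$namespace == namespace]
  inclusive[ns_terms]
}

#' Parent-child union over-representation test for one term
#'
#' Let `U` be the population genes annotated (descendant-inclusively) to the
#' union of the term's parents. The test asks whether the study set's genes
#' inside `U` hit the term more often than expected: a hypergeometric upper
#' tail with population `|U|`, successes `|term genes in U|`, draws
#' `|study genes in U|`, observed `k = |study genes annotated to the term|`.
#'
#' @param term term accession (must have at least one parent; the namespace
#'   root is skipped with a flag).
#' @param study_genes,population_genes character vectors, study a subset of
#'   population.
#' @param annotations an [annotation_set()].
#' @param graph an [ontology_graph()].
#' @param index optional precomputed [term_gene_index()] for the term's
#'   namespace (computed on the fly when `NULL`).
#' @return one-row data.frame (class keeps it composable): term,
#'   study_count, study_parent_count, pop_count, pop_parent_count, p;
#'   `p = 1` when there are no draws; `NA` row with flag for the root.
#' @export
parent_child_union_test <- function(term, study_genes, population_genes,
                                    annotations, graph, index = NULL) {
  term <- check_term(graph, term)
  extra <- setdiff(study_genes, population_genes)
  if (length(extra)) stopf("study gene %s not in population", extra[1])
  ns <- graph$terms$namespace[match(term, graph$terms$id)]
  if (is.null(index)) index <- term_gene_index(annotations, graph, ns)
  parents <- graph$parents[[term]]
  if (length(parents) == 0L) {
    return(data.frame(term = term, study_count = NA_integer_,
                      study_parent_count = NA_integer_,
                      pop_count = NA_integer_, pop_parent_count = NA_integer_,
                      p = NA_real_, flag = "root_skipped",
                      stringsAsFactors = FALSE))
  }
  U <- intersect(unique(unlist(index[parents], use.names = FALSE)),
                 population_genes)
  term_genes <- intersect(index[[term]], population_genes)
  m <- length(intersect(term_genes, U))          # term genes within U
  draws <- length(intersect(U, study_genes))
  k <- length(intersect(index[[term]], study_genes))
  p <- if (draws == 0L) 1 else {
    phyper(k - 1L, m, length(U) - m, draws, lower.tail = FALSE)
  }
  data.frame(term = term, study_count = k, study_parent_count = draws,
             pop_count = m, pop_parent_count = length(U),
             p = p, flag = "", stringsAsFactors = FALSE)
}

#' Enrichment profile of functional groups
#'
#' Runs the parent-child union test for every term annotated to at least one
#' study gene of each group (the study set is the union of both genes of
#' every pair in the group), against the population of all genes in the
#' retained pairs. Raw p-values are Bonferroni-corrected by the number of
#' terms actually tested in that group's run.
#'
#' @param groups data.frame from [cut_by_min_size()] or [cut_by_height()]
#'   (`pair_id`, `group`).
#' @param annotations an [annotation_set()].
#' @param graph an [ontology_graph()].
#' @param population character vector: all genes of the duplication set.
#' @param namespace namespace being analyzed.
#' @param top_n how many top terms to summarize per group (default 3).
#' @return list with `records` (per group x term: counts, p, p_adj) and
#'   `top` (top `top_n` terms per group by adjusted then raw p, ties by
#'   term accession); class `enrichment_result`.
#' @export
enrich_groups <- function(groups, annotations, graph, population, namespace,
                          top_n = 3L) {
  index <- term_gene_index(annotations, graph, namespace)
  pair_genes <- strsplit(groups$pair_id, "|", fixed = TRUE)
  recs <- list()
  for (g in sort(unique(groups$group))) {
    study <- unique(unlist(pair_genes[groups$group == g], use.names = FALSE))
    study <- intersect(study, population)
    if (length(study) == 0L) {
      warnf("group %s has no study genes; skipped", g)
      next
    }
    hit <- vapply(index, function(gs) any(study %in% gs), logical(1))
    tested <- setdiff(names(index)[hit], unname(graph$roots[namespace]))
    if (length(tested) == 0L) next
    rows <- do.call(rbind, lapply(tested, function(t) {
      parent_child_union_test(t, study, population, annotations, graph,
                              index = index)
    }))
    rows <- rows[rows$flag != "root_skipped", , drop = FALSE]
    rows$p_adj <- pmin(1, rows$p * nrow(rows))
    rows$group <- g
    rows$n_tested <- nrow(rows)
    recs[[as.character(g)]] <- rows[order(rows$p_adj, rows$p, rows$term), ]
  }
  if (length(recs) == 0L) stopf("no group yielded testable terms")
  records <- do.call(rbind, recs)
  rownames(records) <- NULL
  top <- do.call(rbind, lapply(recs, function(r) head(r, top_n)))
  rownames(top) <- NULL
  name_of <- setNames(graph$terms$name, graph$terms$id)
  records$name <- unname(name_of[records$term])
  top$name <- unname(name_of[top$term])
  structure(list(records = records, top = top, namespace = namespace),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("enrichment_result (%s): %d groups, %d tests\n",
              x$namespace, length(unique(x$records$group)),
              nrow(x$records)))
  invisible(x)
}
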