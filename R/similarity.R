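#' Information content of ontology terms from an annotation corpus
#'
#' For each term `t`, `p(t)` is the fraction of the namespace's annotated
#' genes that are annotated to `t` or to any of its descendants
#' (descendant-inclusive counting), and `IC(t) = -ln p(t)` in natural-log
#' units. Namespace roots therefore have IC 0, and IC never decreases along
#' a child-to-parent edge reversal (children are at least as informative as
#' their parents). Terms with zero inclusive count carry no IC and lookups
#' for them fail explicitly.
#'
#' @param annotations an [annotation_set()].
#' @param graph an [ontology_graph()].
#' @return object of class `ic_table`: list with `ic` (named numeric),
#'   `count` (inclusive gene counts), `p`, `corpus` (genes per namespace),
#'   and `namespace` (term -> namespace).
#' @export
information_content <- function(annotations, graph) {
  stopifnot(inherits(annotations, "annotation_set"),
            inherits(graph, "ontology_graph"))
  rec <- annotations$records
  if (nrow(rec) == 0L) stopf("empty annotation corpus")
  corpus <- vapply(names(graph$roots), function(ns) {
    length(unique(rec$gene[rec$namespace == ns]))
  }, integer(1))
  direct <- split(rec$gene, factor(rec$term, levels = graph$terms$id))
  # propagate gene sets child -> parent in reverse topological order
  inclusive <- lapply(direct, unique)
  for (t in rev(graph$topo_order)) {
    kids <- graph$children[[t]]
    if (length(kids)) {
      inclusive[[t]] <- unique(c(inclusive[[t]],
                                 unlist(inclusive[kids], use.names = FALSE)))
    }
  }
  count <- vapply(inclusive, length, integer(1))
  ns_of <- setNames(graph$terms$namespace, graph$terms$id)
  keep <- count > 0L
  denom <- unname(corpus[ns_of[names(count)]])
  p <- setNames(ifelse(denom > 0L, count / denom, NA_real_), names(count))
  ic <- -log(p)
  structure(list(ic = ic[keep], p = p[keep], count = count[keep],
                 corpus = corpus, namespace = ns_of),
            class = "ic_table")
}

#' @export
print.ic_table <- function(x, ...) {
  cat(sprintf("ic_table: %d terms with IC; corpus: %s\n", length(x$ic),
              paste(sprintf("%s=%d", names(x$corpus), x$corpus),
                    collapse = ", ")))
  invisible(x)
}

#' Look up the information content of a term
#'
#' @param ic an `ic_table` from [information_content()].
#' @param term term accession.
#' @return numeric IC value; error if the term carries no IC.
#' @export
ic_value <- function(ic, term) {
  v <- ic$ic[term]
  if (anyNA(v)) stopf("term %s has no information content (zero annotations)",
                      term[is.na(v)][1])
  unname(v)
}

#' Resnik similarity of two terms
#'
#' The information content of the most informative common ancestor:
#' `max IC(a)` over the common reflexive ancestors of `t1` and `t2`.
#' Ancestors without defined IC are skipped; if no common ancestor carries
#' IC the similarity is 0 (the namespace root guarantees the common set is
#' nonempty).
#'
#' @param ic an `ic_table`.
#' @param graph an [ontology_graph()].
#' @param t1,t2 term accessions in the same namespace.
#' @return non-negative numeric.
#' @export
resnik_similarity <- function(ic, graph, t1, t2) {
  t1 <- check_term(graph, t1); t2 <- check_term(graph, t2)
  if (ic$namespace[[t1]] != ic$namespace[[t2]]) {
    stopf("terms %s and %s are in different namespaces", t1, t2)
  }
  common <- intersect(graph$ancestors[[t1]], graph$ancestors[[t2]])
  vals <- ic$ic[common]
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0L) return(0)
  max(vals)
}

# All-pairs Resnik for a term vector, returned as a dense matrix; used to
# avoid recomputing term-term values across the O(n^2) profile comparisons.
resnik_matrix <- function(ic, graph, terms) {
  terms <- sort(unique(terms))
  n <- length(terms)
  m <- matrix(0, n, n, dimnames = list(terms, terms))
  anc <- graph$ancestors[terms]
  for (i in seq_len(n)) {
    for (j in i:n) {
      common <- intersect(anc[[i]], anc[[j]])
      vals <- ic$ic[common]
      vals <- vals[!is.na(vals)]
      v <- if (length(vals)) max(vals) else 0
      m[i, j] <- v; m[j, i] <- v
    }
  }
  m
}

# Exact maximum-weight injective assignment of the rows of `w` (the smaller
# side) into its columns, by dynamic programming over column subsets.
# Deterministic: the DP optimum is unique as a value; ties need no breaking.
assignment_value <- function(w) {
  a <- nrow(w); b <- ncol(w)
  stopifnot(a <= b)
  if (a == 0L) return(0)
  if (b > 24L) stopf("profile too large for exact assignment (%d terms)", b)
  full <- bitwShiftL(1L, a) - 1L
  dp <- rep(-Inf, bitwShiftL(1L, a))
  dp[1] <- 0
  n_assigned <- integer(bitwShiftL(1L, a))
  for (m in seq_len(full)) n_assigned[m + 1L] <- sum(bitwAnd(m, bitwShiftL(1L, 0:(a - 1L))) > 0L)
  # iterate over columns; dp[mask] = best value matching rows in `mask`
  # using columns seen so far (columns may also stay unmatched)
  for (j in seq_len(b)) {
    new <- dp
    for (m in full:1) {
      for (i in seq_len(a)) {
        bit <- bitwShiftL(1L, i - 1L)
        if (bitwAnd(m, bit)) {
          prev <- dp[bitwXor(m, bit) + 1L]
          cand <- prev + w[i, j]
          if (cand > new[m + 1L]) new[m + 1L] <- cand
        }
      }
    }
    dp <- new
  }
  dp[full + 1L]
}

#' Optimal-assignment similarity of two annotation profiles
#'
#' Each term of the smaller profile is assigned to exactly one term of the
#' larger profile so that the summed Resnik term similarities are maximal
#' (maximum-weight injective matching); the sum is divided by the number of
#' matched terms, giving an average per-term similarity.
#'
#' @param profile1,profile2 nonempty character vectors of term accessions in
#'   one namespace.
#' @param ic an `ic_table`.
#' @param graph an [ontology_graph()].
#' @param resnik optional precomputed term-term similarity matrix covering
#'   both profiles (from the internal all-pairs helper); computed on the fly
#'   when `NULL`.
#' @return non-negative numeric.
#' @export
optimal_assignment_similarity <- function(profile1, profile2, ic, graph,
                                          resnik = NULL) {
  if (length(profile1) == 0L || length(profile2) == 0L) {
    stopf("empty annotation profile")
  }
  profile1 <- sort(unique(profile1)); profile2 <- sort(unique(profile2))
  if (is.null(resnik)) {
    resnik <- resnik_matrix(ic, graph, c(profile1, profile2))
  }
  if (length(profile1) <= length(profile2)) {
    w <- resnik[profile1, profile2, drop = FALSE]
  } else {
    w <- resnik[profile2, profile1, drop = FALSE]
  }
  assignment_value(w) / nrow(w)
}

#' Pairwise functional similarity matrix of duplicate pairs
#'
#' Computes the optimal-assignment similarity between the shared-function
#' profiles of every two duplicate pairs in one namespace, normalized to
#' `[0, 1]` by the geometric mean of the self-similarities:
#' `s(i,j) / sqrt(s(i,i) * s(j,j))`, with the diagonal set to exactly 1.
#' Profiles whose self-similarity is zero (all terms with IC 0) are rejected.
#'
#' @param profiles named list (pair_id -> character vector of shared terms),
#'   e.g. one namespace of [filter_pairs()]`$profiles`.
#' @param ic an `ic_table`.
#' @param graph an [ontology_graph()].
#' @return object of class `profile_similarity`: list with `ids`, `matrix`
#'   (normalized), and `raw` (unnormalized, diagonal = self-similarity).
#' @export
profile_similarity_matrix <- function(profiles, ic, graph) {
  n <- length(profiles)
  if (n < 2L) stopf("need at least two profiles")
  ids <- names(profiles)
  all_terms <- sort(unique(unlist(profiles, use.names = FALSE)))
  rm_ <- resnik_matrix(ic, graph, all_terms)
  self <- vapply(seq_len(n), function(i) {
    optimal_assignment_similarity(profiles[[i]], profiles[[i]], ic, graph,
                                  resnik = rm_)
  }, numeric(1))
  zero <- self <= 0
  if (any(zero)) {
    stopf("profiles with zero self-similarity (only IC-0 terms): %s",
          paste(ids[zero], collapse = ", "))
  }
  raw <- matrix(0, n, n, dimnames = list(ids, ids))
  diag(raw) <- self
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      s <- optimal_assignment_similarity(profiles[[i]], profiles[[j]], ic,
                                         graph, resnik = rm_)
      raw[i, j] <- s; raw[j, i] <- s
    }
  }
  norm <- raw / sqrt(outer(self, self))
  norm[norm > 1] <- 1        # guard against floating round-off above 1
  diag(norm) <- 1
  structure(list(ids = ids, matrix = norm, raw = raw),
            class = "profile_similarity")
}

#' @export
print.profile_similarity <- function(x, ...) {
  cat(sprintf("profile_similarity: %d x %d pairs\n",
              length(x$ids), length(x$ids)))
  invisible(x)
}
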