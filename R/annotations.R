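#' Construct an annotation set
#'
#' Collection of gene-to-term assignments with evidence codes. Duplicate
#' (gene, term, evidence) triples are collapsed. Terms must exist in the
#' graph (alternate ids are resolved by the caller or [parse_gaf()]); the
#' namespace is taken from the graph.
#'
#' @param records data.frame with columns `gene`, `term`, `evidence`.
#' @param graph an [ontology_graph()] used to validate terms and assign
#'   namespaces.
#' @return object of class `annotation_set`: list with `records`
#'   (gene, term, evidence, namespace) and per-gene index.
#' @export
annotation_set <- function(records, graph) {
  stopifnot(inherits(graph, "ontology_graph"))
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  if (nrow(records) == 0L) stopf("annotation set is empty")
  records$term <- check_term(graph, records$term)
  records$namespace <- graph$terms$namespace[match(records$term, graph$terms$id)]
  records <- records[!duplicated(records[c("gene", "term", "evidence")]), ,
                     drop = FALSE]
  rownames(records) <- NULL
  structure(list(records = records,
                 by_gene = split(seq_len(nrow(records)), records$gene)),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("annotation_set: %d records, %d genes, %d terms\n",
              nrow(x$records), length(x$by_gene),
              length(unique(x$records$term))))
  invisible(x)
}

#' Terms annotated to a gene
#'
#' @param annotations an [annotation_set()].
#' @param gene gene identifier.
#' @param namespace optional namespace filter.
#' @param exclude_evidence evidence codes to drop (e.g. `c("IEA", "ND")`).
#' @return character vector of term accessions (possibly empty).
#' @export
gene_terms <- function(annotations, gene, namespace = NULL,
                       exclude_evidence = character(0)) {
  idx <- annotations$by_gene[[gene]]
  if (is.null(idx)) return(character(0))
  rec <- annotations$records[idx, , drop = FALSE]
  rec <- rec[!(rec$evidence %in% exclude_evidence), , drop = FALSE]
  if (!is.null(namespace)) rec <- rec[rec$namespace == namespace, , drop = FALSE]
  unique(rec$term)
}

#' Parse a GAF 2.x annotation file
#'
#' Tab-separated Gene Association File lines; comment lines start with `!`.
#' Uses the DB_Object_ID (column 2), Qualifier (4), GO_ID (5), and Evidence
#' Code (7) columns. Rows whose qualifier contains `NOT` are dropped,
#' alternate term ids are resolved against the graph, and rows referring to
#' unknown terms are dropped with a reported count.
#'
#' @param path path to a GAF file, or a character vector of GAF lines.
#' @param graph an [ontology_graph()].
#' @return an [annotation_set()]; attribute `dropped_unknown_terms` carries
#'   the number of discarded rows.
#' @export
parse_gaf <- function(path, graph) {
  lines <- if (length(path) == 1L && file.exists(path)) readLines(path) else path
  keep <- !startsWith(lines, "!") & nzchar(lines)
  lines <- lines[keep]
  lineno <- which(keep)
  if (length(lines) == 0L) stopf("GAF input contains no annotation lines")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- nf < 15L
  if (any(bad)) {
    stopf("malformed GAF line %d: expected >= 15 columns, found %d",
          lineno[bad][1], nf[bad][1])
  }
  gene <- vapply(fields, `[[`, "", 2L)
  qualifier <- vapply(fields, `[[`, "", 4L)
  term <- vapply(fields, `[[`, "", 5L)
  evidence <- vapply(fields, `[[`, "", 7L)
  keep <- !grepl("(^|\\|)NOT(\\||$)", qualifier)
  gene <- gene[keep]; term <- term[keep]; evidence <- evidence[keep]
  term <- resolve_term(graph, term)
  known <- term %in% names(graph$ancestors)
  n_dropped <- sum(!known)
  if (n_dropped > 0L) {
    message(sprintf("parse_gaf: dropped %d record(s) with unknown terms",
                    n_dropped))
  }
  records <- data.frame(gene = gene[known], term = term[known],
                        evidence = evidence[known], stringsAsFactors = FALSE)
  if (nrow(records) == 0L) stopf("GAF input yields zero usable records")
  out <- annotation_set(records, graph)
  attr(out, "dropped_unknown_terms") <- n_dropped
  out
}

#' Read a two-column duplicate-pair list
#'
#' Tab-separated gene identifier pairs; lines starting with `#` are comments
#' and a `gene1<TAB>gene2` header is tolerated. Pairs are canonically ordered
#' and deduplicated.
#'
#' @param path path to the TSV, or a character vector of lines.
#' @return data.frame with columns `gene1`, `gene2`, `pair_id`.
#' @export
read_pair_list <- function(path) {
  lines <- if (length(path) == 1L && file.exists(path)) readLines(path) else path
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(lines) && grepl("^gene1\\b", lines[1], ignore.case = TRUE)) {
    lines <- lines[-1]
  }
  if (length(lines) == 0L) stopf("pair list is empty")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 2L)) stopf("pair list line with fewer than 2 columns")
  g1 <- vapply(fields, `[[`, "", 1L)
  g2 <- vapply(fields, `[[`, "", 2L)
  make_pairs(g1, g2)
}

make_pairs <- function(gene1, gene2, copy_number_class = NULL) {
  if (any(gene1 == gene2)) stopf("pair with identical genes: %s",
                                 gene1[gene1 == gene2][1])
  swap <- gene1 > gene2
  tmp <- gene1[swap]; gene1[swap] <- gene2[swap]; gene2[swap] <- tmp
  df <- data.frame(gene1 = gene1, gene2 = gene2,
                   pair_id = paste(gene1, gene2, sep = "|"),
                   stringsAsFactors = FALSE)
  if (!is.null(copy_number_class)) df$copy_number_class <- copy_number_class
  df <- df[!duplicated(df$pair_id), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Evidence and shared-function filtering of duplicate pairs
#'
#' Applies the two-stage analysis funnel. Stage 1 drops a pair when either
#' gene has no annotation left after removing blacklisted evidence codes
#' (default `IEA` and `ND`: only electronically inferred or no-data
#' annotations do not count as curated). Stage 2 computes, per namespace,
#' the pair's most specific shared functions from the surviving annotations
#' and drops the pair from that namespace's analysis when the shared set is
#' empty at `min_depth` or deeper. A pair may therefore survive in one
#' namespace but not another.
#'
#' @param pairs data.frame with columns `gene1`, `gene2` (and optionally
#'   `copy_number_class`), e.g. from [read_pair_list()].
#' @param annotations an [annotation_set()].
#' @param graph an [ontology_graph()].
#' @param evidence_blacklist evidence codes treated as non-curated.
#' @param min_depth minimum depth of retained shared terms.
#' @return object of class `filtered_pairs`: list with `pairs` (stage-1
#'   survivors), `profiles` (per namespace: named list pair_id -> shared
#'   terms), and `funnel` (per-stage counts).
#' @export
filter_pairs <- function(pairs, annotations, graph,
                         evidence_blacklist = c("IEA", "ND"),
                         min_depth = 1L) {
  stopifnot(inherits(annotations, "annotation_set"),
            inherits(graph, "ontology_graph"))
  if (!all(c("gene1", "gene2") %in% names(pairs))) {
    stopf("pairs must have gene1 and gene2 columns")
  }
  pairs <- make_pairs(pairs$gene1, pairs$gene2, pairs$copy_number_class)
  n_input <- nrow(pairs)

  curated <- function(g, ns = NULL) {
    gene_terms(annotations, g, namespace = ns,
               exclude_evidence = evidence_blacklist)
  }
  has_curated <- vapply(seq_len(n_input), function(i) {
    length(curated(pairs$gene1[i])) > 0L && length(curated(pairs$gene2[i])) > 0L
  }, logical(1))
  stage1 <- pairs[has_curated, , drop = FALSE]

  namespaces <- names(graph$roots)
  profiles <- setNames(vector("list", length(namespaces)), namespaces)
  retained_ns <- integer(0)
  for (ns in namespaces) {
    prof <- list()
    for (i in seq_len(nrow(stage1))) {
      tA <- curated(stage1$gene1[i], ns)
      tB <- curated(stage1$gene2[i], ns)
      if (length(tA) == 0L || length(tB) == 0L) next
      shared <- most_specific_shared_terms(graph, tA, tB, min_depth = min_depth)
      if (length(shared)) prof[[stage1$pair_id[i]]] <- shared
    }
    profiles[[ns]] <- prof
    retained_ns[[ns]] <- length(prof)
  }

  funnel <- list(
    n_input = n_input,
    dropped_evidence = n_input - nrow(stage1),
    n_after_evidence = nrow(stage1),
    dropped_no_shared = setNames(nrow(stage1) - unlist(retained_ns),
                                 namespaces),
    n_retained = unlist(retained_ns))
  structure(list(pairs = stage1, profiles = profiles, funnel = funnel),
            class = "filtered_pairs")
}

#' @export
print.filtered_pairs <- function(x, ...) {
  f <- x$funnel
  cat(sprintf("filtered_pairs: %d input -> %d with curated annotation\n",
              f$n_input, f$n_after_evidence))
  for (ns in names(f$n_retained)) {
    cat(sprintf("  %s: %d pairs with shared functions\n", ns, f$n_retained[[ns]]))
  }
  invisible(x)
}
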