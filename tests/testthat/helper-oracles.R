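# Independent oracles used to validate the package's implementations:
# exhaustive enumerations, closed forms and direct numerical integration.
# These deliberately avoid the code paths they check.

# --- ontology -------------------------------------------------------------

# ancestor set by naive recursive walking of the parent lists
walk_ancestors <- function(graph, term) {
  seen <- character(0)
  recurse <- function(t) {
    if (t %in% seen) return(invisible(NULL))
    seen <<- c(seen, t)
    for (p in graph$parents[[t]]) recurse(p)
  }
  recurse(term)
  seen
}

# breadth-first-search depth oracle
bfs_depth <- function(graph, term) {
  frontier <- term
  d <- 0L
  repeat {
    if (any(lengths(graph$parents[frontier]) == 0L)) return(d)
    frontier <- unique(unlist(graph$parents[frontier], use.names = FALSE))
    d <- d + 1L
  }
}

# random layered DAG in one namespace, with a random annotation corpus
random_dag_corpus <- function(seed, n_terms = 12L, n_genes = 10L,
                              n_records = 25L) {
  set.seed(seed)
  ids <- sprintf("BP:%03d", seq_len(n_terms))
  child <- character(0); parent <- character(0); rel <- character(0)
  for (i in 2:n_terms) {
    np <- sample(1:min(2L, i - 1L), 1L)
    ps <- sample(ids[seq_len(i - 1L)], np)
    child <- c(child, rep(ids[i], np)); parent <- c(parent, ps)
    rel <- c(rel, sample(c("is_a", "part_of"), np, replace = TRUE))
  }
  graph <- funcdiv::ontology_graph(
    data.frame(id = ids, name = ids, namespace = "biological_process"),
    data.frame(child = child, parent = parent, relation = rel))
  genes <- sprintf("g%02d", seq_len(n_genes))
  rec <- data.frame(gene = sample(genes, n_records, replace = TRUE),
                    term = sample(ids, n_records, replace = TRUE),
                    evidence = "IDA", stringsAsFactors = FALSE)
  anns <- funcdiv::annotation_set(rec, graph)
  list(graph = graph, annotations = anns,
       ic = funcdiv::information_content(anns, graph))
}

# Resnik by exhaustive enumeration over walked ancestor sets
brute_resnik <- function(ic, graph, t1, t2) {
  common <- intersect(walk_ancestors(graph, t1), walk_ancestors(graph, t2))
  best <- 0
  for (a in common) {
    v <- unname(ic$ic[a])
    if (!is.na(v) && v > best) best <- v
  }
  best
}

# all permutations of 1..n (n small)
perms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    for (rest in perms(n - 1L)) {
      out[[length(out) + 1L]] <- c(i, setdiff(seq_len(n), i)[rest])
    }
  }
  out
}

# maximum-weight injective assignment by exhaustive enumeration
brute_assignment <- function(w) {
  a <- nrow(w); b <- ncol(w)
  stopifnot(a <= b)
  best <- -Inf
  cols <- utils::combn(b, a, simplify = FALSE)
  for (cs in cols) {
    for (p in perms(a)) {
      v <- sum(w[cbind(seq_len(a), cs[p])])
      if (v > best) best <- v
    }
  }
  best
}

# --- alignment ------------------------------------------------------------

# exhaustive global affine-gap alignment score: enumerate all alignments
# recursively, tracking the previous move for gap opening vs extension.
# Convention matches the implementation: a gap of length L costs
# open + L * ext, end gaps penalized.
brute_align_score <- function(s1, s2, sub, open = 10, ext = 0.5) {
  a <- strsplit(s1, "")[[1]]; b <- strsplit(s2, "")[[1]]
  n <- length(a); m <- length(b)
  best <- -Inf
  recurse <- function(i, j, prev, score) {
    if (i > n && j > m) {
      if (score > best) best <<- score
      return(invisible(NULL))
    }
    if (i <= n && j <= m) {
      recurse(i + 1L, j + 1L, "D", score + sub[a[i], b[j]])
    }
    if (i <= n) {   # gap in s2
      pen <- ext + if (prev == "U") 0 else open
      recurse(i + 1L, j, "U", score - pen)
    }
    if (j <= m) {   # gap in s1
      pen <- ext + if (prev == "L") 0 else open
      recurse(i, j + 1L, "L", score - pen)
    }
  }
  recurse(1L, 1L, "D", 0)
  best
}

random_protein <- function(len) {
  aas <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F","P",
           "S","T","W","Y","V")
  paste(sample(aas, len, replace = TRUE), collapse = "")
}

# --- studentized range ----------------------------------------------------

# P(Q <= q) for the studentized range of k groups with df error degrees of
# freedom, by direct double numerical integration (independent of ptukey)
tukey_cdf_numint <- function(q, k, df) {
  inner <- function(s) {
    f <- function(z) {
      k * stats::dnorm(z) * (stats::pnorm(z) - stats::pnorm(z - q * s))^(k - 1)
    }
    stats::integrate(f, -Inf, Inf, rel.tol = 1e-9)$value
  }
  # s = sqrt(X / df), X ~ chi^2_df  =>  density 2 s df dchisq(s^2 df, df)
  outer_f <- function(s) {
    vapply(s, function(si) {
      2 * si * df * stats::dchisq(si^2 * df, df) * inner(si)
    }, numeric(1))
  }
  stats::integrate(outer_f, 0, Inf, rel.tol = 1e-8)$value
}

# --- hypergeometric tail --------------------------------------------------

# explicit summation P(X >= k) for draws from an urn with m successes and
# n failures
hyper_tail_sum <- function(k, m, n, draws) {
  if (k <= 0) return(1)
  i <- k:min(m, draws)
  if (length(i) == 0L || k > min(m, draws)) return(0)
  sum(choose(m, i) * choose(n, draws - i)) / choose(m + n, draws)
}

# --- dendrograms ----------------------------------------------------------

# hand-built balanced binary hclust tree over 2^levels leaves; heights
# increase with merge level so the structure is a valid Ward-like tree
balanced_tree <- function(levels) {
  n <- 2^levels
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  prev <- -seq_len(n)   # current layer of node ids
  step <- 0L
  h <- 1
  while (length(prev) > 1L) {
    nxt <- integer(0)
    for (i in seq(1L, length(prev), 2L)) {
      step <- step + 1L
      merge[step, ] <- sort(c(prev[i], prev[i + 1L]))
      height[step] <- h
      nxt <- c(nxt, step)
    }
    prev <- nxt
    h <- h + 1
  }
  structure(list(merge = merge, height = height,
                 order = seq_len(n),
                 labels = sprintf("leaf%02d", seq_len(n)),
                 method = "ward"),
            class = c("funcdiv_dendrogram", "hclust"))
}
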